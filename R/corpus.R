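# Corpus construction: fuzzy key-phrase screening of bibliographic records,
# deduplication, journal-information filtering, labelling and negative
# downsampling.

#' Construct a key phrase for fuzzy matching
#'
#' A key phrase is an ordered list of lowercase words that must occur in a
#' text in the given order, with at most `max_gap` intervening words between
#' each consecutive pair. The default gap of 3 implements the proximity rule
#' used to retrieve neck-pain candidate articles: e.g. the phrase
#' `("cervical", "pain")` matches the title fragment "cervical spine joint
#' pain" because only two words separate the phrase words.
#'
#' @param words character vector of length >= 2; lowercase words, no
#'   whitespace inside a word.
#' @param max_gap non-negative integer; maximum number of intervening words
#'   allowed between consecutive phrase words (default 3).
#' @return An object of class `key_phrase`.
#' @examples
#' key_phrase(c("neck", "pain"))
#' @export
key_phrase <- function(words, max_gap = 3L) {
  words <- as.character(words)
  if (length(words) < 2L) {
    stop("a key phrase needs at least two words", call. = FALSE)
  }
  if (any(!nzchar(words)) || any(grepl("\\s", words))) {
    stop("phrase words must be non-empty and free of whitespace", call. = FALSE)
  }
  max_gap <- as.integer(max_gap)
  if (is.na(max_gap) || max_gap < 0L) {
    stop("max_gap must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(words = tolower(words), max_gap = max_gap),
    class = "key_phrase"
  )
}

#' @export
print.key_phrase <- function(x, ...) {
  cat(sprintf(
    "<key_phrase> %s (max gap %d)\n",
    paste(x$words, collapse = " ... "), x$max_gap
  ))
  invisible(x)
}

#' Default neck-pain key-phrase list
#'
#' The five phrases used to screen candidate articles on the diagnosis and
#' treatment of neck pain: "back pain", "pain back", "neck pain",
#' "pain neck" and "cervical pain". Both word orders are listed separately
#' because matching is order-sensitive.
#'
#' @param max_gap maximum intervening words per phrase (default 3).
#' @return list of [key_phrase] objects.
#' @export
default_phrases <- function(max_gap = 3L) {
  lapply(
    list(
      c("back", "pain"), c("pain", "back"),
      c("neck", "pain"), c("pain", "neck"),
      c("cervical", "pain")
    ),
    key_phrase,
    max_gap = max_gap
  )
}

#' Normalize free text into a token list
#'
#' Lowercases, replaces every punctuation character (hyphens included) with a
#' space, and splits on whitespace. Deterministic total function: empty or
#' all-punctuation input yields a zero-length character vector.
#'
#' @param text character scalar (may be empty or `NA`).
#' @return character vector of lowercase tokens.
#' @examples
#' normalize_tokens("Neck Pain, revisited!")
#' @export
normalize_tokens <- function(text) {
  if (length(text) != 1L) stop("text must be a single string", call. = FALSE)
  if (is.na(text)) text <- ""
  x <- tolower(text)
  x <- gsub("[[:punct:]]", " ", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1L]]
  tokens[nzchar(tokens)]
}

#' Match a key phrase against a token list
#'
#' Finds the leftmost occurrence of the phrase words in order such that at
#' most `phrase$max_gap` tokens lie strictly between each consecutive pair of
#' phrase words. The search backtracks over admissible positions, so a match
#' is found whenever one exists; the reported positions are the
#' lexicographically earliest valid tuple.
#'
#' @param tokens character vector of normalized tokens (see
#'   [normalize_tokens]).
#' @param phrase a [key_phrase].
#' @return list with elements `matched` (logical), `gap` (integer, total
#'   number of intervening tokens at the first match; `NA` when unmatched)
#'   and `positions` (integer vector of matched token indices; empty when
#'   unmatched).
#' @examples
#' phrase_match(c("chronic", "neck", "pain"), key_phrase(c("neck", "pain")))
#' @export
phrase_match <- function(tokens, phrase) {
  if (!inherits(phrase, "key_phrase")) {
    stop("phrase must be a key_phrase object", call. = FALSE)
  }
  words <- phrase$words
  g <- phrase$max_gap
  n <- length(tokens)
  k <- length(words)
  # depth-first search over admissible positions; candidates are tried in
  # increasing order, so the first complete tuple is the lexicographically
  # earliest one
  search <- function(word_idx, prev_pos) {
    lo <- prev_pos + 1L
    hi <- min(n, prev_pos + 1L + g)
    if (lo > n) {
      return(NULL)
    }
    for (p in (lo:hi)[tokens[lo:hi] == words[word_idx]]) {
      if (word_idx == k) {
        return(p)
      }
      rest <- search(word_idx + 1L, p)
      if (!is.null(rest)) {
        return(c(p, rest))
      }
    }
    NULL
  }
  for (s in which(tokens == words[1L])) {
    rest <- search(2L, s)
    if (!is.null(rest)) {
      positions <- c(s, rest)
      return(list(
        matched = TRUE,
        gap = as.integer(positions[k] - positions[1L] - (k - 1L)),
        positions = as.integer(positions)
      ))
    }
  }
  list(matched = FALSE, gap = NA_integer_, positions = integer(0))
}

#' Screen one bibliographic record against a phrase list
#'
#' A record passes when any phrase matches its title tokens or its abstract
#' tokens.
#'
#' @param record list or one-row data frame with `title` and `abstract`.
#' @param phrases list of [key_phrase] objects.
#' @return logical scalar.
#' @export
screen_record <- function(record, phrases = default_phrases()) {
  title_tok <- normalize_tokens(as.character(record$title)[1L])
  abstract <- record$abstract
  abstract_tok <- normalize_tokens(
    if (is.null(abstract) || length(abstract) == 0L) "" else as.character(abstract)[1L]
  )
  for (ph in phrases) {
    if (phrase_match(title_tok, ph)$matched ||
      phrase_match(abstract_tok, ph)$matched) {
      return(TRUE)
    }
  }
  FALSE
}

#' Screen a table of records
#'
#' @param records data frame with columns `id`, `title`, `abstract`.
#' @param phrases list of [key_phrase] objects.
#' @return the subset of `records` passing [screen_record], order preserved.
#' @export
screen_records <- function(records, phrases = default_phrases()) {
  check_columns(records, c("id", "title", "abstract"), "records")
  keep <- vapply(
    seq_len(nrow(records)),
    function(i) screen_record(records[i, , drop = FALSE], phrases),
    logical(1)
  )
  records[keep, , drop = FALSE]
}

#' Remove duplicate records
#'
#' Duplicates are records sharing an `id`, or failing that, an identical
#' normalized title. The first occurrence wins and the output order is
#' stable.
#'
#' @param records data frame with columns `id`, `title`.
#' @return data frame without duplicates.
#' @export
deduplicate <- function(records) {
  check_columns(records, c("id", "title"), "records")
  if (nrow(records) == 0L) {
    return(records)
  }
  norm_title <- vapply(
    as.character(records$title),
    function(t) paste(normalize_tokens(t), collapse = " "),
    character(1),
    USE.NAMES = FALSE
  )
  keep <- !duplicated(as.character(records$id)) & !duplicated(norm_title)
  records[keep, , drop = FALSE]
}

#' Discard records lacking journal information
#'
#' Keeps exactly the records whose `journal_id` appears in the journal
#' metrics table; records with a missing or unresolvable journal are dropped,
#' since journal features are part of the model input.
#'
#' @param records data frame with a `journal_id` column.
#' @param journal_table data frame with a `journal_id` column.
#' @return filtered data frame, order preserved.
#' @export
filter_journal_info <- function(records, journal_table) {
  check_columns(records, "journal_id", "records")
  check_columns(journal_table, "journal_id", "journal_table")
  jid <- as.character(records$journal_id)
  keep <- !is.na(jid) & nzchar(jid) &
    jid %in% as.character(journal_table$journal_id)
  records[keep, , drop = FALSE]
}

#' Label records as positive or negative
#'
#' An article is positive (`label = 1`) when its id appears in
#' `positive_ids` — in guideline development, when it is cited by the extant
#' clinical practice guidelines or systematic reviews. All other articles are
#' negative. Positive and negative subsets partition the input.
#'
#' @param records data frame with an `id` column.
#' @param positive_ids character vector of positive article ids. Ids absent
#'   from `records` trigger a warning, not an error.
#' @return `records` with an integer `label` column in `{0, 1}`.
#' @export
assign_labels <- function(records, positive_ids) {
  check_columns(records, "id", "records")
  positive_ids <- unique(as.character(positive_ids))
  ids <- as.character(records$id)
  unknown <- setdiff(positive_ids, ids)
  if (length(unknown) > 0L) {
    warning(sprintf(
      "%d positive id(s) not found among the records (e.g. %s)",
      length(unknown), unknown[1L]
    ), call. = FALSE)
  }
  records$label <- as.integer(ids %in% positive_ids)
  records
}

#' Downsample negative articles to a target class ratio
#'
#' Keeps every positive article and draws negatives uniformly without
#' replacement (equal per-sample probability) so that positives make up the
#' `target_pos_frac` fraction of the result. The draw size is
#' `round(n_pos * (1 - f) / f)`; with 1,005 positives and `f = 0.3` that is
#' exactly 2,345 negatives, giving a 3:7 class ratio.
#'
#' @param articles labelled data frame (see [assign_labels]).
#' @param target_pos_frac desired positive fraction in (0, 1); default 0.3.
#' @param seed integer seed making the draw reproducible.
#' @return data frame with all positives and the sampled negatives, in
#'   original row order.
#' @export
downsample_negatives <- function(articles, target_pos_frac = 0.3, seed = 1L) {
  check_columns(articles, "label", "articles")
  if (target_pos_frac <= 0 || target_pos_frac >= 1) {
    stop("target_pos_frac must lie strictly between 0 and 1", call. = FALSE)
  }
  pos_idx <- which(articles$label == 1L)
  neg_idx <- which(articles$label == 0L)
  n_pos <- length(pos_idx)
  if (n_pos == 0L) stop("no positive articles to anchor the ratio", call. = FALSE)
  n_neg_target <- round(n_pos * (1 - target_pos_frac) / target_pos_frac)
  if (length(neg_idx) < n_neg_target) {
    stop(sprintf(
      "need %d negatives for a positive fraction of %g but only %d are available",
      n_neg_target, target_pos_frac, length(neg_idx)
    ), call. = FALSE)
  }
  drawn <- with_seed(seed, sample(neg_idx, n_neg_target, replace = FALSE))
  keep <- sort(c(pos_idx, drawn))
  articles[keep, , drop = FALSE]
}

#' Token frequencies over a corpus
#'
#' Counts normalized tokens across titles and abstracts and returns the `k`
#' most frequent, ties broken lexicographically. This is the computation
#' behind a top-100 word cloud of the corpus.
#'
#' @param articles data frame with `title` and `abstract` columns.
#' @param k number of entries to return (>= 1); values beyond the vocabulary
#'   size return the full vocabulary.
#' @return data frame with columns `word`, `count`, ordered by decreasing
#'   count then word.
#' @export
word_frequencies <- function(articles, k = 100L) {
  check_columns(articles, c("title", "abstract"), "articles")
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  tokens <- unlist(lapply(seq_len(nrow(articles)), function(i) {
    c(
      normalize_tokens(as.character(articles$title[i])),
      normalize_tokens(as.character(articles$abstract[i]))
    )
  }))
  if (length(tokens) == 0L) {
    return(data.frame(word = character(0), count = integer(0)))
  }
  tab <- table(tokens)
  out <- data.frame(
    word = names(tab), count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$word), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Build a labelled, balanced corpus from raw records
#'
#' Runs the full dataset-construction pipeline: fuzzy key-phrase screening of
#' titles and abstracts, deduplication, removal of records without resolvable
#' journal information, positive/negative labelling, and downsampling of the
#' negative class to the target ratio.
#'
#' @param records data frame of raw records (`id`, `title`, `abstract`,
#'   `journal_id`).
#' @param journal_table journal metrics table (see [read_journal_table]).
#' @param positive_ids character vector of guideline-cited article ids.
#' @param phrases list of [key_phrase] objects (default [default_phrases]).
#' @param target_pos_frac positive fraction after downsampling (default 0.3).
#' @param seed integer seed for the negative draw.
#' @return list with `corpus` (labelled, downsampled data frame) and `counts`
#'   (named integer vector: screened, deduplicated, journal_filtered,
#'   positive, negative, downsampled).
#' @export
build_corpus <- function(records, journal_table, positive_ids,
                         phrases = default_phrases(),
                         target_pos_frac = 0.3, seed = 1L) {
  screened <- screen_records(records, phrases)
  deduped <- deduplicate(screened)
  filtered <- filter_journal_info(deduped, journal_table)
  labelled <- assign_labels(filtered, positive_ids)
  corpus <- downsample_negatives(labelled, target_pos_frac, seed)
  counts <- c(
    screened = nrow(screened),
    deduplicated = nrow(deduped),
    journal_filtered = nrow(filtered),
    positive = sum(labelled$label == 1L),
    negative = sum(labelled$label == 0L),
    downsampled = nrow(corpus)
  )
  list(corpus = corpus, counts = counts)
}
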