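# Synthetic corpus generator. Emulates the statistical structure the
# screening method relies on: every record contains one of the default key
# phrases (so the whole corpus passes the fuzzy screen), positive articles
# carry extra discriminative tokens with a configurable probability, and
# positives preferentially appear in journals whose bibliometric metrics sit
# higher. Text is emitted as plain token sequences — every downstream
# consumer tokenizes, so surface fluency is irrelevant.

#' Configuration for the synthetic corpus generator
#'
#' @param n_pos,n_neg number of positive / negative articles (each >= 1).
#' @param vocab_size size of the filler vocabulary (default 200; must be
#'   >= 20 so that filler, discriminative and phrase tokens stay distinct).
#' @param signal_strength probability that a positive article's title (and,
#'   independently, its abstract) carries discriminative tokens beyond the
#'   shared key phrases (default 0.9, calibrated so the planted text signal
#'   is comfortably recoverable from a 600-article corpus). Negatives never
#'   carry them, so 0 removes the text signal entirely.
#' @param journal_effect mean shift, in standard-deviation units of the
#'   latent journal-quality scale, of the journals hosting positive
#'   articles (default 2.5, calibrated so the journal block carries signal
#'   complementary to the text at fixture scale). 0 removes the journal
#'   signal.
#' @param missingness probability that any one journal metric is missing
#'   (default 0.1).
#' @param n_journals number of journals (default
#'   `max(10, (n_pos + n_neg) %/% 10)`).
#' @param seed integer seed; the generator is a pure function of
#'   configuration and seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_pos = 180L, n_neg = 420L, vocab_size = 200L,
                         signal_strength = 0.9, journal_effect = 2.5,
                         missingness = 0.1, n_journals = NULL, seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop("n_pos and n_neg must be >= 1", call. = FALSE)
  if (vocab_size < 20L) {
    stop("vocab_size must be at least 20 to keep token roles distinct", call. = FALSE)
  }
  if (signal_strength < 0 || signal_strength > 1) {
    stop("signal_strength must lie in [0, 1]", call. = FALSE)
  }
  if (journal_effect < 0) stop("journal_effect must be >= 0", call. = FALSE)
  if (missingness < 0 || missingness > 1) {
    stop("missingness must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(n_journals)) n_journals <- max(10L, (n_pos + n_neg) %/% 10L)
  structure(
    list(
      n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
      vocab_size = as.integer(vocab_size),
      signal_strength = signal_strength, journal_effect = journal_effect,
      missingness = missingness, n_journals = as.integer(n_journals),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Filler vocabulary and the discriminative token set.
synth_vocab <- function(cfg) {
  list(
    filler = sprintf("w%03d", seq_len(cfg$vocab_size)),
    disc = sprintf("sig%02d", 1:10)
  )
}

# One key phrase occurrence with a random admissible gap, as a token vector.
phrase_with_gap <- function(phrase, filler) {
  gap <- sample(0:phrase$max_gap, 1L)
  words <- phrase$words[1L]
  for (w in phrase$words[-1L]) {
    words <- c(words, sample(filler, gap, replace = TRUE), w)
  }
  words
}

#' Generate a synthetic screening corpus
#'
#' Produces raw bibliographic records, the positive-id set and a journal
#' metrics table with the planted structure described in [synth_config]:
#'
#' * every title or abstract contains at least one default key phrase with
#'   an intervening-word gap of at most 3, so the full corpus passes
#'   [screen_records] by construction;
#' * positives carry discriminative tokens in title/abstract with
#'   probability `signal_strength`;
#' * each journal has a latent quality score; impact factors, CiteScore,
#'   SJR, SNIP and H-index are right-skewed (log-normal-like) increasing
#'   functions of it, ranking zones are its quartiles, and positive
#'   articles choose journals with probability tilted toward high quality
#'   by `journal_effect`.
#'
#' @param config a [synth_config].
#' @return list with `records` (data frame: `id`, `title`, `abstract`,
#'   `journal_id`), `positive_ids` (character vector) and `journals`
#'   (metrics table as in [read_journal_table]).
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  vocab <- synth_vocab(cfg)
  phrases <- default_phrases()
  with_seed(cfg$seed, {
    # journals: latent quality -> right-skewed metrics, quartile zones
    quality <- stats::rnorm(cfg$n_journals)
    journals <- data.frame(
      journal_id = sprintf("J%04d", seq_len(cfg$n_journals)),
      stringsAsFactors = FALSE
    )
    for (col in paste0("if_", 2015:2021)) {
      journals[[col]] <- round(exp(0.8 + 0.6 * quality +
        stats::rnorm(cfg$n_journals, sd = 0.15)), 3)
    }
    journals$cite_score <- round(exp(1.0 + 0.6 * quality +
      stats::rnorm(cfg$n_journals, sd = 0.15)), 3)
    journals$sjr <- round(exp(0.2 + 0.6 * quality +
      stats::rnorm(cfg$n_journals, sd = 0.15)), 3)
    journals$snip <- round(exp(0.3 + 0.5 * quality +
      stats::rnorm(cfg$n_journals, sd = 0.15)), 3)
    journals$h_index <- pmax(1L, round(exp(3.5 + 0.5 * quality +
      stats::rnorm(cfg$n_journals, sd = 0.2))))
    journals$zone <- 5L - as.integer(cut(quality,
      breaks = stats::quantile(quality, probs = seq(0, 1, 0.25)),
      include.lowest = TRUE, labels = FALSE
    ))
    for (col in c(paste0("if_", 2015:2021), "cite_score", "sjr", "snip", "h_index")) {
      miss <- stats::runif(cfg$n_journals) < cfg$missingness
      journals[[col]][miss] <- NA
    }

    n_total <- cfg$n_pos + cfg$n_neg
    labels <- c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg))
    ids <- sprintf("A%05d", seq_len(n_total))

    # positives pick journals tilted toward high latent quality
    pos_weights <- exp(cfg$journal_effect * quality)
    journal_pick <- ifelse(
      labels == 1L,
      sample(cfg$n_journals, n_total, replace = TRUE, prob = pos_weights),
      sample(cfg$n_journals, n_total, replace = TRUE)
    )

    make_text <- function(label, n_tokens, with_phrase, phrase_prob_disc) {
      body <- sample(vocab$filler, n_tokens, replace = TRUE)
      if (label == 1L && stats::runif(1) < phrase_prob_disc) {
        # topical mixture: a signal-bearing positive field draws each token
        # from the discriminative vocabulary with probability 0.4, so the
        # class difference is spread over many tokens and survives mean
        # pooling over the whole sequence
        at <- which(stats::runif(length(body)) < 0.4)
        if (length(at) > 0L) {
          body[at] <- sample(vocab$disc, length(at), replace = TRUE)
        }
      }
      if (with_phrase) {
        ph <- phrase_with_gap(phrases[[sample(length(phrases), 1L)]], vocab$filler)
        insert_at <- sample(0:length(body), 1L)
        body <- append(body, ph, after = insert_at)
      }
      paste(body, collapse = " ")
    }

    titles <- character(n_total)
    abstracts <- character(n_total)
    for (i in seq_len(n_total)) {
      phrase_in_title <- stats::runif(1) < 0.7
      titles[i] <- make_text(
        labels[i], sample(6:12, 1L),
        with_phrase = phrase_in_title, cfg$signal_strength
      )
      abstracts[i] <- make_text(
        labels[i], sample(40:80, 1L),
        with_phrase = !phrase_in_title, cfg$signal_strength
      )
    }

    list(
      records = data.frame(
        id = ids, title = titles, abstract = abstracts,
        journal_id = journals$journal_id[journal_pick],
        stringsAsFactors = FALSE
      ),
      positive_ids = ids[labels == 1L],
      journals = journals
    )
  })
}

#' Generate a small attention test fixture
#'
#' Produces a batch matrix and attention parameter matrices with small
#' integer entries, suitable for hand-checkable or brute-force verification
#' of the attention computation.
#'
#' @param s batch size (>= 1).
#' @param d embedding dimension (>= 1).
#' @param seed integer seed.
#' @return list with `r` (`s x d` matrix) and `params` (`Wq`, `Wk`, `Wv`,
#'   each `d x d`), all entries in `-2..2`.
#' @export
generate_attention_fixture <- function(s, d, seed = 1L) {
  if (s < 1L || d < 1L) stop("s and d must be >= 1", call. = FALSE)
  with_seed(seed, {
    list(
      r = matrix(sample(-2:2, s * d, replace = TRUE), s, d),
      params = list(
        Wq = matrix(sample(-2:2, d * d, replace = TRUE), d, d),
        Wk = matrix(sample(-2:2, d * d, replace = TRUE), d, d),
        Wv = matrix(sample(-2:2, d * d, replace = TRUE), d, d)
      )
    )
  })
}
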