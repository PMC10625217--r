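# Independent reference implementations used to cross-check the package.
# These deliberately take the dumbest correct route (character walks,
# exhaustive enumeration, per-element loops) and share no code with R/.

# Character-walk tokenizer: no regex. Assumes ASCII input where every
# non-alphanumeric character is a separator (true for the letters / digits /
# punctuation / space alphabet the tests generate).
oracle_tokenize <- function(text) {
  chars <- strsplit(tolower(text), "")[[1]]
  tokens <- character(0)
  current <- ""
  for (ch in chars) {
    if (grepl("[a-z0-9]", ch)) {
      current <- paste0(current, ch)
    } else {
      if (nzchar(current)) tokens <- c(tokens, current)
      current <- ""
    }
  }
  if (nzchar(current)) tokens <- c(tokens, current)
  tokens
}

# Exhaustive phrase matcher: enumerates every increasing position tuple
# whose words match, keeps those whose consecutive gaps are all <= max_gap,
# and returns the lexicographically smallest.
oracle_phrase_match <- function(tokens, words, max_gap) {
  k <- length(words)
  cand <- lapply(words, function(w) which(tokens == w))
  if (any(vapply(cand, length, integer(1)) == 0L)) {
    return(list(matched = FALSE, gap = NA_integer_))
  }
  tuples <- list()
  recurse <- function(acc, idx) {
    if (idx > k) {
      tuples[[length(tuples) + 1L]] <<- acc
      return(invisible())
    }
    for (p in cand[[idx]]) {
      if (idx == 1L || (p > acc[idx - 1L] && p - acc[idx - 1L] - 1L <= max_gap)) {
        recurse(c(acc, p), idx + 1L)
      }
    }
  }
  recurse(integer(0), 1L)
  if (length(tuples) == 0L) {
    return(list(matched = FALSE, gap = NA_integer_))
  }
  ord <- do.call(order, as.data.frame(do.call(rbind, tuples)))
  best <- tuples[[ord[1L]]]
  list(matched = TRUE, gap = best[k] - best[1L] - (k - 1L), positions = best)
}

# Element-wise attention oracle evaluating the weight/output definitions
# with explicit loops.
oracle_attention <- function(r, Wq, Wk, Wv, scaled = FALSE) {
  s <- nrow(r)
  d <- ncol(r)
  q <- r %*% Wq
  k <- r %*% Wk
  v <- r %*% Wv
  out <- matrix(0, s, d)
  weights <- matrix(0, s, s)
  for (i in seq_len(s)) {
    scores <- numeric(s)
    for (j in seq_len(s)) scores[j] <- sum(q[i, ] * k[j, ])
    if (scaled) scores <- scores / sqrt(d)
    e <- exp(scores - max(scores))
    weights[i, ] <- e / sum(e)
    for (m in seq_len(d)) out[i, m] <- sum(weights[i, ] * v[, m])
  }
  list(output = out, weights = weights)
}

# Loop re-implementation of the toy encoding recipe: polynomial hash,
# signed bucket, mean pool with the reserved token, fixed projection.
oracle_toy_encode <- function(text, encoder) {
  tokens <- c("<cls>", oracle_tokenize(text))
  tokens <- tokens[seq_len(min(length(tokens), encoder$max_len))]
  d <- encoder$dim
  pooled <- numeric(d)
  for (tok in tokens) {
    h <- 0
    for (ch in utf8ToInt(tok)) h <- (h * 31 + ch) %% 2^31
    v <- numeric(d)
    v[(h %% d) + 1] <- if ((floor(h / d) %% 2) == 0) 1 else -1
    pooled <- pooled + v
  }
  pooled <- pooled / length(tokens)
  as.numeric(pooled %*% encoder$projection)
}

# Per-element confusion counting.
oracle_confusion <- function(prob, labels, threshold) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(prob)) {
    pred <- prob[i] >= threshold
    if (pred && labels[i] == 1L) tp <- tp + 1L
    if (pred && labels[i] == 0L) fp <- fp + 1L
    if (!pred && labels[i] == 1L) fn <- fn + 1L
    if (!pred && labels[i] == 0L) tn <- tn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Scalar focal-loss evaluation straight from the definition.
oracle_focal <- function(p, y, gamma, alpha) {
  pt <- if (y == 1L) p else 1 - p
  at <- if (y == 1L) alpha else 1 - alpha
  -at * (1 - pt)^gamma * log(pt)
}

# Small labelled fixture shared by several tests.
make_tiny_articles <- function() {
  data.frame(
    id = sprintf("A%02d", 1:8),
    title = c(
      "chronic neck pain management",
      "low back pain outcomes",
      "cervical spine joint pain consensus",
      "knee surgery trial",
      "pain in the neck region",
      "back injury and pain recovery",
      "cervical pain imaging",
      "shoulder mobility study"
    ),
    abstract = c(
      "study of neck pain", "", "guidelines", "no relevant phrase here",
      "pain of the neck", "pain after back strain", "", "neck pain mention"
    ),
    journal_id = sprintf("J%02d", c(1, 1, 2, 2, 3, 3, 4, 4)),
    stringsAsFactors = FALSE
  )
}

make_tiny_journals <- function() {
  jt <- data.frame(journal_id = sprintf("J%02d", 1:4), stringsAsFactors = FALSE)
  for (col in paste0("if_", 2015:2021)) jt[[col]] <- c(1.2, 3.4, 0.8, 5.1)
  jt$cite_score <- c(2.0, 4.5, 1.1, 6.2)
  jt$sjr <- c(0.5, 1.8, 0.3, 2.4)
  jt$snip <- c(0.9, 1.4, 0.6, 1.9)
  jt$h_index <- c(30, 80, 12, 150)
  jt$zone <- c(3L, 2L, 4L, 1L)
  jt
}
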