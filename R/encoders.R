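# Text encoders and the batch-level inter-sample attention layer.
#
# Titles and abstracts are first embedded per sample (the in-sample
# representation r_i / n_i, the analogue of a transformer's reserved
# classification-token embedding). A single-head attention layer then mixes
# the embeddings of all articles in a batch, so each article's final text
# representation is a convex combination of its batch-mates' value vectors.

CLS_TOKEN <- "<cls>"

#' Deterministic hash of a token string
#'
#' 31-ary polynomial rolling hash over the UTF-8 code points, reduced
#' modulo 2^31. Implemented in plain double arithmetic, which is exact here
#' because every intermediate stays far below 2^53.
#'
#' @param token character scalar.
#' @return non-negative integer-valued double below 2^31.
#' @export
hash_token <- function(token) {
  h <- 0
  for (ch in utf8ToInt(token)) {
    h <- (h * 31 + ch) %% 2147483648
  }
  h
}

#' Create a deterministic toy text encoder
#'
#' A transformer-free text encoder for desk-scale experiments: each token is
#' hashed into one of `dim` signed coordinates (feature hashing), token
#' vectors are mean-pooled together with a reserved classification token,
#' and the pooled vector is passed through a fixed random projection drawn
#' once from the seed. The encoder is a pure function of its configuration:
#' the same text always maps to the same vector.
#'
#' @param dim embedding dimension `d` (default 64).
#' @param max_len maximum number of tokens kept per text (default 512);
#'   longer texts are tail-truncated before pooling.
#' @param seed integer seed for the projection matrix.
#' @return object of class `toy_encoder`.
#' @export
toy_encoder <- function(dim = 64L, max_len = 512L, seed = 42L) {
  dim <- as.integer(dim)
  if (dim < 1L) stop("dim must be >= 1", call. = FALSE)
  projection <- with_seed(
    seed,
    matrix(stats::rnorm(dim * dim, sd = 1 / sqrt(dim)), dim, dim)
  )
  structure(
    list(
      kind = "toy", dim = dim, max_len = as.integer(max_len),
      seed = as.integer(seed), projection = projection
    ),
    class = "toy_encoder"
  )
}

#' @export
print.toy_encoder <- function(x, ...) {
  cat(sprintf(
    "<toy_encoder> d = %d, max_len = %d, seed = %d\n",
    x$dim, x$max_len, x$seed
  ))
  invisible(x)
}

# Signed one-hot hash embedding of a single token.
token_vector <- function(token, dim) {
  h <- hash_token(token)
  v <- numeric(dim)
  bucket <- (h %% dim) + 1
  sign <- if ((floor(h / dim) %% 2) == 0) 1 else -1
  v[bucket] <- sign
  v
}

#' Encode texts into embedding vectors
#'
#' Tokenizes each text with [normalize_tokens], prepends the reserved
#' classification token, truncates to the encoder's `max_len`, hash-embeds
#' each token, mean-pools, and applies the encoder's fixed projection. An
#' empty text encodes the classification token alone, so the result is
#' always a finite `d`-vector.
#'
#' @param texts character vector.
#' @param encoder a [toy_encoder].
#' @return numeric matrix of dim `length(texts)` x `d`.
#' @export
encode_text <- function(texts, encoder) {
  if (!inherits(encoder, "toy_encoder")) {
    stop("encoder must be a toy_encoder", call. = FALSE)
  }
  d <- encoder$dim
  pooled <- t(vapply(texts, function(txt) {
    tokens <- c(CLS_TOKEN, normalize_tokens(if (is.na(txt)) "" else txt))
    tokens <- utils::head(tokens, encoder$max_len)
    mat <- vapply(tokens, token_vector, numeric(d), dim = d)
    rowMeans(matrix(mat, nrow = d))
  }, numeric(d), USE.NAMES = FALSE))
  pooled <- matrix(pooled, ncol = d)
  out <- pooled %*% encoder$projection
  rownames(out) <- NULL
  out
}

#' Initialize inter-sample attention parameters
#'
#' Three trainable square `d x d` matrices (query, key, value), no bias
#' terms. Initialized with small Gaussian entries.
#'
#' @param d embedding dimension.
#' @param seed integer seed.
#' @param sd standard deviation of the initial entries.
#' @return list with `Wq`, `Wk`, `Wv`.
#' @export
attention_params <- function(d, seed = 1L, sd = 0.05) {
  with_seed(seed, list(
    Wq = matrix(stats::rnorm(d * d, sd = sd), d, d),
    Wk = matrix(stats::rnorm(d * d, sd = sd), d, d),
    Wv = matrix(stats::rnorm(d * d, sd = sd), d, d)
  ))
}

#' Batch-level inter-sample attention
#'
#' Given the batch embedding matrix `r` (one row per article) and projection
#' matrices, forms `Q = r Wq`, `K = r Wk`, `V = r Wv`, computes per-sample
#' weights `alpha_i = softmax(q_i K^T)` over the batch, and returns the
#' weighted representations `R_i = alpha_i V`. Scores are unscaled by
#' default; `scaled = TRUE` divides them by `sqrt(d)` (the conventional
#' scaled-dot-product form, identical when `d = 1`).
#'
#' Each output row is a convex combination of the rows of `V`, and the
#' operation is equivariant under permutations of the batch.
#'
#' @param r numeric `s x d` batch matrix of per-sample embeddings.
#' @param params list with `Wq`, `Wk`, `Wv` (see [attention_params]).
#' @param scaled logical; divide scores by `sqrt(d)` (default `FALSE`).
#' @return list with `output` (`s x d` matrix of weighted representations)
#'   and `weights` (`s x s` row-stochastic matrix; row i is `alpha_i`).
#' @export
intersample_attention <- function(r, params, scaled = FALSE) {
  r <- as.matrix(r)
  d <- ncol(r)
  for (nm in c("Wq", "Wk", "Wv")) {
    w <- params[[nm]]
    if (is.null(w) || !all(dim(w) == c(d, d))) {
      stop(sprintf("params$%s must be a %d x %d matrix", nm, d, d),
        call. = FALSE
      )
    }
  }
  q <- r %*% params$Wq
  k <- r %*% params$Wk
  v <- r %*% params$Wv
  scores <- q %*% t(k)
  if (scaled) scores <- scores / sqrt(d)
  alpha <- row_softmax(scores)
  list(output = alpha %*% v, weights = alpha)
}

# Backward pass for intersample_attention. Given the upstream gradient
# d_out (s x d) and the forward cache, returns gradients for Wq, Wk, Wv.
# The input r is treated as fixed (the toy encoder is not fine-tuned).
attention_backward <- function(r, params, d_out, scaled = FALSE) {
  d <- ncol(r)
  q <- r %*% params$Wq
  k <- r %*% params$Wk
  v <- r %*% params$Wv
  scores <- q %*% t(k)
  if (scaled) scores <- scores / sqrt(d)
  alpha <- row_softmax(scores)

  d_alpha <- d_out %*% t(v)
  d_v <- t(alpha) %*% d_out
  # softmax backward, row-wise: dA = P * (dP - rowSums(dP * P))
  d_scores <- alpha * (d_alpha - rowSums(d_alpha * alpha))
  if (scaled) d_scores <- d_scores / sqrt(d)
  d_q <- d_scores %*% k
  d_k <- t(d_scores) %*% q
  list(
    Wq = t(r) %*% d_q,
    Wk = t(r) %*% d_k,
    Wv = t(r) %*% d_v
  )
}
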