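# Classification head: journal feed-forward encoder, feature fusion,
# two-class softmax output and the focal loss used to handle the heavy
# positive/negative imbalance.

PROB_EPS <- 1e-7 # probability clamp keeping log() finite

#' Initialize the journal feed-forward encoder
#'
#' A single linear layer followed by ReLU that recombines the raw journal
#' feature vector `j_i` into an enhanced representation `J_i`. The output
#' width defaults to the input width.
#'
#' @param input_width width of the journal feature vector.
#' @param output_width width of `J_i` (default `input_width`).
#' @param seed integer seed for the Gaussian initialization.
#' @param sd standard deviation of initial weights.
#' @return list with weight matrix `W` (`output_width x input_width`) and
#'   bias `b`.
#' @export
journal_encoder_params <- function(input_width, output_width = input_width,
                                   seed = 1L, sd = 0.05) {
  with_seed(seed, list(
    W = matrix(stats::rnorm(output_width * input_width, sd = sd),
      output_width, input_width
    ),
    b = numeric(output_width)
  ))
}

#' Encode journal features through the feed-forward layer
#'
#' Computes `J_i = ReLU(W j_i + b)` for each row of `j`; all outputs are
#' non-negative.
#'
#' @param j numeric matrix (`s` x input width), one row per article.
#' @param params list with `W`, `b` (see [journal_encoder_params]).
#' @return numeric matrix `s` x output width.
#' @export
encode_journal <- function(j, params) {
  j <- as.matrix(j)
  if (ncol(j) != ncol(params$W)) {
    stop(sprintf(
      "journal feature width %d does not match encoder input width %d",
      ncol(j), ncol(params$W)
    ), call. = FALSE)
  }
  z <- j %*% t(params$W) + matrix(params$b, nrow(j), length(params$b), byrow = TRUE)
  pmax(z, 0)
}

#' Concatenate title, abstract and journal representations
#'
#' Builds the combined feature `X_i = (R_i, N_i, J_i)` in that fixed order.
#' Any of the blocks may be `NULL` (ablation variants); at least one must be
#' present.
#'
#' @param R title representations (`s x d` matrix) or `NULL`.
#' @param N abstract representations (`s x d` matrix) or `NULL`.
#' @param J journal representations (`s x h` matrix) or `NULL`.
#' @return numeric matrix of width equal to the sum of the block widths.
#' @export
combine_features <- function(R = NULL, N = NULL, J = NULL) {
  blocks <- Filter(Negate(is.null), list(R, N, J))
  if (length(blocks) == 0L) stop("no feature blocks given", call. = FALSE)
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("feature blocks have differing numbers of rows", call. = FALSE)
  }
  do.call(cbind, blocks)
}

#' Initialize the classifier head
#'
#' Linear map from the combined feature width to the two class logits,
#' followed by a softmax (applied in [predict_head]).
#'
#' @param input_width combined feature width.
#' @param seed integer seed.
#' @param sd standard deviation of initial weights.
#' @return list with `W` (`2 x input_width`) and `b` (length 2).
#' @export
classifier_head <- function(input_width, seed = 1L, sd = 0.05) {
  with_seed(seed, list(
    W = matrix(stats::rnorm(2L * input_width, sd = sd), 2L, input_width),
    b = numeric(2L)
  ))
}

#' Class probabilities from combined features
#'
#' Computes the two-class softmax of `W X_i + b` per sample and returns the
#' positive-class probability `p_i`.
#'
#' @param X combined feature matrix (`s` x width).
#' @param head list with `W`, `b` (see [classifier_head]).
#' @return list with `prob` (length-`s` vector of positive-class
#'   probabilities) and `probs` (`s x 2` matrix, columns negative/positive).
#' @export
predict_head <- function(X, head) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(head$W)) {
    stop(sprintf(
      "feature width %d does not match head width %d",
      ncol(X), ncol(head$W)
    ), call. = FALSE)
  }
  logits <- X %*% t(head$W) + matrix(head$b, nrow(X), 2L, byrow = TRUE)
  if (!all(is.finite(logits))) stop("non-finite logits", call. = FALSE)
  probs <- row_softmax(logits)
  colnames(probs) <- c("negative", "positive")
  list(prob = probs[, 2L], probs = probs)
}

#' Focal loss for imbalanced binary classification
#'
#' Per-sample loss `-alpha_t (1 - p_t)^gamma log(p_t)` where `p_t` is the
#' predicted probability of the true class (`p` for positives, `1 - p` for
#' negatives) and `alpha_t` is `alpha` for positives, `1 - alpha` for
#' negatives. The modulating factor `(1 - p_t)^gamma` down-weights easy,
#' well-classified samples so training concentrates on the hard ones. With
#' `gamma = 0, alpha = 0.5` the loss is exactly half the binary
#' cross-entropy. Returned value is the batch mean; probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` to keep the log finite.
#'
#' @param p numeric vector of positive-class probabilities.
#' @param y integer labels in `{0, 1}`.
#' @param gamma focusing exponent, >= 0 (default 2).
#' @param alpha positive-class weight in `[0, 1]` (default 0.8).
#' @return non-negative scalar, the mean focal loss.
#' @examples
#' focal_loss(0.9, 1L) # -0.8 * 0.1^2 * log(0.9)
#' @export
focal_loss <- function(p, y, gamma = 2, alpha = 0.8) {
  if (length(p) != length(y)) stop("p and y must have equal length", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  p <- pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
  pt <- ifelse(y == 1L, p, 1 - p)
  at <- ifelse(y == 1L, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

# Gradient of the mean focal loss with respect to the two class logits.
# probs: s x 2 softmax output; y: labels. Returns s x 2 matrix.
focal_loss_logit_grad <- function(probs, y, gamma, alpha) {
  s <- length(y)
  t_idx <- ifelse(y == 1L, 2L, 1L)
  pt <- probs[cbind(seq_len(s), t_idx)]
  pt <- pmin(pmax(pt, PROB_EPS), 1 - PROB_EPS)
  at <- ifelse(y == 1L, alpha, 1 - alpha)
  # dL_i/dpt; at gamma = 0 the modulating term vanishes identically, written
  # separately to avoid 0 * Inf when pt is at the upper clamp
  g <- if (gamma == 0) {
    -at / pt
  } else {
    -at * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
  }
  # dpt/dz_k = pt * (delta_tk - q_k)
  d_z <- matrix(0, s, 2L)
  for (kk in 1:2) {
    d_z[, kk] <- g * pt * ((t_idx == kk) - probs[, kk])
  }
  d_z / s
}
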