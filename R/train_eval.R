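# Training and evaluation: stratified splitting, focal-loss training of the
# attention classifier, confusion-matrix metrics, model comparison and
# ranked screening of new articles.

#' Training configuration for the screening model
#'
#' @param features character subset of `c("title", "abstract", "journal")`;
#'   the feature blocks the model consumes. The full model uses all three;
#'   ablation variants drop blocks.
#' @param dim text embedding dimension `d` (default 64; sized so the hashed
#'   vocabulary suffers few bucket collisions).
#' @param max_len token truncation length for the encoder (default 512).
#' @param batch_size attention batch size `s` (default 32). Inter-sample
#'   attention mixes embeddings within a batch, so predictions depend on the
#'   (seeded) batch composition.
#' @param epochs training epochs (default 20); 0 returns the initial
#'   parameters unchanged.
#' @param lr Adam learning rate (default 0.01).
#' @param weight_decay decoupled (AdamW-style) weight decay coefficient
#'   (default 0.01); regularizes the heavily over-parameterized attention
#'   matrices on small corpora.
#' @param gamma,alpha focal-loss hyperparameters (defaults 2 and 0.8).
#' @param journal_hidden width of the journal encoder output; `NULL` means
#'   equal to the journal feature width.
#' @param scaled_attention logical; use `1/sqrt(d)` score scaling (default
#'   `FALSE`).
#' @param seed master seed for initialization, shuffling and batching.
#' @return list of class `screener_config`.
#' @export
screener_config <- function(features = c("title", "abstract", "journal"),
                            dim = 64L, max_len = 512L, batch_size = 32L,
                            epochs = 20L, lr = 0.01, weight_decay = 0.01,
                            gamma = 2, alpha = 0.8,
                            journal_hidden = NULL, scaled_attention = FALSE,
                            seed = 1L) {
  features <- match.arg(features, c("title", "abstract", "journal"),
    several.ok = TRUE
  )
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  structure(
    list(
      features = features, dim = as.integer(dim),
      max_len = as.integer(max_len), batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), lr = lr, weight_decay = weight_decay,
      gamma = gamma, alpha = alpha,
      journal_hidden = journal_hidden, scaled_attention = scaled_attention,
      seed = as.integer(seed)
    ),
    class = "screener_config"
  )
}

#' Split labelled articles into training and test sets
#'
#' Random 80/20 split by default. Stratified splitting (the default) draws
#' the rounded fraction within each label class, preserving the class ratio
#' to within one article in each split.
#'
#' @param articles labelled data frame.
#' @param train_frac training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @param stratified logical; stratify by `label` (default `TRUE`).
#' @return list with `train` and `test` data frames (disjoint, covering).
#' @export
split_dataset <- function(articles, train_frac = 0.8, seed = 1L,
                          stratified = TRUE) {
  check_columns(articles, "label", "articles")
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly between 0 and 1 (both splits non-empty)",
      call. = FALSE
    )
  }
  n <- nrow(articles)
  if (stratified) {
    class_sizes <- table(articles$label)
    if (any(class_sizes < 2L)) {
      stop(paste(
        "a label class has fewer than 2 articles;",
        "use stratified = FALSE for unstratified splitting"
      ), call. = FALSE)
    }
    train_idx <- with_seed(seed, {
      unlist(lapply(sort(unique(articles$label)), function(lab) {
        idx <- which(articles$label == lab)
        n_train <- round(length(idx) * train_frac)
        n_train <- min(max(n_train, 1L), length(idx) - 1L)
        sample(idx, n_train)
      }))
    })
  } else {
    n_train <- min(max(round(n * train_frac), 1L), n - 1L)
    train_idx <- with_seed(seed, sample.int(n, n_train))
  }
  train_idx <- sort(train_idx)
  list(
    train = articles[train_idx, , drop = FALSE],
    test = articles[setdiff(seq_len(n), train_idx), , drop = FALSE]
  )
}

# ---- internal: forward / backward over one batch -------------------------

# Forward pass for one batch given precomputed inputs.
# r, n: s x d embedding matrices (or NULL); j: s x m journal features (or
# NULL); returns cache for the backward pass.
batch_forward <- function(params, cfg, r, n, j) {
  blocks <- list()
  if ("title" %in% cfg$features) {
    blocks$R <- intersample_attention(r, params$title_attn, cfg$scaled_attention)$output
  }
  if ("abstract" %in% cfg$features) {
    blocks$N <- intersample_attention(n, params$abs_attn, cfg$scaled_attention)$output
  }
  if ("journal" %in% cfg$features) {
    blocks$J <- encode_journal(j, params$journal)
  }
  X <- combine_features(blocks$R, blocks$N, blocks$J)
  pred <- predict_head(X, params$head)
  list(blocks = blocks, X = X, probs = pred$probs, prob = pred$prob)
}

# Analytic gradients of the mean focal loss for one batch.
batch_backward <- function(params, cfg, r, n, j, y, fwd) {
  d_z <- focal_loss_logit_grad(fwd$probs, y, cfg$gamma, cfg$alpha)
  grads <- list(head = list(
    W = t(d_z) %*% fwd$X,
    b = colSums(d_z)
  ))
  d_X <- d_z %*% params$head$W
  offset <- 0L
  if ("title" %in% cfg$features) {
    d <- ncol(fwd$blocks$R)
    d_R <- d_X[, offset + seq_len(d), drop = FALSE]
    grads$title_attn <- attention_backward(r, params$title_attn, d_R, cfg$scaled_attention)
    offset <- offset + d
  }
  if ("abstract" %in% cfg$features) {
    d <- ncol(fwd$blocks$N)
    d_N <- d_X[, offset + seq_len(d), drop = FALSE]
    grads$abs_attn <- attention_backward(n, params$abs_attn, d_N, cfg$scaled_attention)
    offset <- offset + d
  }
  if ("journal" %in% cfg$features) {
    h <- ncol(fwd$blocks$J)
    d_J <- d_X[, offset + seq_len(h), drop = FALSE]
    mask <- (fwd$blocks$J > 0) * 1
    d_pre <- d_J * mask
    grads$journal <- list(
      W = t(d_pre) %*% j,
      b = colSums(d_pre)
    )
  }
  grads
}

# Flat-vector views of the nested parameter list, used by Adam and by the
# finite-difference gradient checks in the test suite.
flatten_params <- function(params) {
  unlist(params, use.names = TRUE)
}

unflatten_params <- function(template, flat) {
  out <- template
  i <- 0L
  for (g in names(template)) {
    for (p in names(template[[g]])) {
      len <- length(template[[g]][[p]])
      vals <- flat[i + seq_len(len)]
      if (is.matrix(template[[g]][[p]])) {
        out[[g]][[p]] <- matrix(vals, nrow(template[[g]][[p]]), ncol(template[[g]][[p]]))
      } else {
        out[[g]][[p]] <- as.numeric(vals)
      }
      i <- i + len
    }
  }
  out
}

init_screener_params <- function(cfg, journal_width) {
  params <- list()
  if ("title" %in% cfg$features) {
    params$title_attn <- attention_params(cfg$dim, seed = cfg$seed + 101L)
  }
  if ("abstract" %in% cfg$features) {
    params$abs_attn <- attention_params(cfg$dim, seed = cfg$seed + 202L)
  }
  combined <- 0L
  if ("title" %in% cfg$features) combined <- combined + cfg$dim
  if ("abstract" %in% cfg$features) combined <- combined + cfg$dim
  if ("journal" %in% cfg$features) {
    h <- if (is.null(cfg$journal_hidden)) journal_width else as.integer(cfg$journal_hidden)
    params$journal <- journal_encoder_params(journal_width, h, seed = cfg$seed + 303L)
    combined <- combined + h
  }
  params$head <- classifier_head(combined, seed = cfg$seed + 404L)
  params
}

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = flat * 0, v = flat * 0, t = 0L)
}

# Adam with decoupled weight decay (AdamW).
adam_step <- function(flat, grad_flat, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad_flat
  state$v <- beta2 * state$v + (1 - beta2) * grad_flat^2
  m_hat <- state$m / (1 - beta1^state$t)
  v_hat <- state$v / (1 - beta2^state$t)
  list(
    flat = flat - lr * (m_hat / (sqrt(v_hat) + eps) + weight_decay * flat),
    state = state
  )
}

# ---- training ------------------------------------------------------------

#' Train the attention screening model
#'
#' Full training loop: titles and abstracts are embedded once with the toy
#' encoder, the journal scaler is fitted on the journals of the training
#' articles, and the attention/journal/head parameters are optimized with
#' Adam under the focal loss. Batches are re-shuffled every epoch from the
#' master seed, so runs are exactly reproducible.
#'
#' @param corpus labelled training data frame (`id`, `title`, `abstract`,
#'   `journal_id`, `label`).
#' @param journal_table journal metrics table covering the corpus journals.
#' @param config a [screener_config].
#' @return object of class `screener_model` holding the trained parameters,
#'   the toy encoder, the fitted journal scaler, the journal table, the
#'   configuration and the per-epoch mean-loss log.
#' @export
train_screener <- function(corpus, journal_table, config = screener_config()) {
  check_columns(corpus, c("id", "title", "abstract", "journal_id", "label"), "corpus")
  cfg <- config
  encoder <- toy_encoder(cfg$dim, cfg$max_len, seed = cfg$seed + 7L)
  train_journals <- journal_table[
    as.character(journal_table$journal_id) %in% unique(as.character(corpus$journal_id)), ,
    drop = FALSE
  ]
  scaler <- fit_scaler(train_journals)

  r_all <- if ("title" %in% cfg$features) encode_text(corpus$title, encoder) else NULL
  n_all <- if ("abstract" %in% cfg$features) encode_text(corpus$abstract, encoder) else NULL
  j_all <- if ("journal" %in% cfg$features) {
    journal_feature_matrix(corpus$journal_id, journal_table, scaler)
  } else {
    NULL
  }
  journal_width <- if (is.null(j_all)) 0L else ncol(j_all)
  y <- as.integer(corpus$label)
  n_obs <- nrow(corpus)

  params <- init_screener_params(cfg, journal_width)
  loss_log <- numeric(0)

  if (cfg$epochs > 0L) {
    state <- adam_init(params)
    with_seed(cfg$seed, {
      for (epoch in seq_len(cfg$epochs)) {
        order_idx <- sample.int(n_obs)
        batch_losses <- numeric(0)
        for (start in seq(1L, n_obs, by = cfg$batch_size)) {
          idx <- order_idx[start:min(start + cfg$batch_size - 1L, n_obs)]
          r_b <- if (is.null(r_all)) NULL else r_all[idx, , drop = FALSE]
          n_b <- if (is.null(n_all)) NULL else n_all[idx, , drop = FALSE]
          j_b <- if (is.null(j_all)) NULL else j_all[idx, , drop = FALSE]
          fwd <- batch_forward(params, cfg, r_b, n_b, j_b)
          loss <- focal_loss(fwd$prob, y[idx], cfg$gamma, cfg$alpha)
          if (!is.finite(loss)) {
            stop(sprintf(
              "non-finite loss at epoch %d (batch starting at %d); lower the learning rate",
              epoch, start
            ), call. = FALSE)
          }
          batch_losses <- c(batch_losses, loss)
          grads <- batch_backward(params, cfg, r_b, n_b, j_b, y[idx], fwd)
          upd <- adam_step(
            flatten_params(params), flatten_params(grads[names(params)]),
            state, cfg$lr, cfg$weight_decay
          )
          params <- unflatten_params(params, upd$flat)
          state <- upd$state
        }
        loss_log <- c(loss_log, mean(batch_losses))
      }
    })
  }

  structure(
    list(
      params = params, config = cfg, encoder = encoder, scaler = scaler,
      journal_table = journal_table, loss_log = loss_log,
      journal_width = journal_width
    ),
    class = "screener_model"
  )
}

#' @export
print.screener_model <- function(x, ...) {
  cat(sprintf(
    "<screener_model> features: %s | d = %d | %d epoch(s) trained\n",
    paste(x$config$features, collapse = "+"), x$config$dim,
    length(x$loss_log)
  ))
  if (length(x$loss_log) > 0L) {
    cat(sprintf(
      "  loss: %.4f -> %.4f\n", x$loss_log[1L],
      x$loss_log[length(x$loss_log)]
    ))
  }
  invisible(x)
}

#' Predict positive-class probabilities for articles
#'
#' Embeds the articles, forms seeded evaluation batches (inter-sample
#' attention needs batch context, so the batch composition is part of the
#' prediction procedure and is returned for logging) and runs the forward
#' pass.
#'
#' @param model a trained `screener_model`.
#' @param articles data frame with `id`, `title`, `abstract`, `journal_id`.
#' @param journal_table optional journal table; defaults to the one stored
#'   in the model.
#' @param seed seed for the evaluation batch composition (default: the
#'   model's training seed).
#' @return data frame with columns `id`, `prob` and `batch` (the evaluation
#'   batch index of each article), in input order.
#' @export
predict_screener <- function(model, articles, journal_table = NULL,
                             seed = NULL) {
  stopifnot(inherits(model, "screener_model"))
  check_columns(articles, c("id", "title", "abstract", "journal_id"), "articles")
  if (is.null(journal_table)) journal_table <- model$journal_table
  if (is.null(seed)) seed <- model$config$seed
  cfg <- model$config
  n_obs <- nrow(articles)
  if (n_obs == 0L) {
    return(data.frame(
      id = character(0), prob = numeric(0),
      batch = integer(0)
    ))
  }
  r_all <- if ("title" %in% cfg$features) encode_text(articles$title, model$encoder) else NULL
  n_all <- if ("abstract" %in% cfg$features) encode_text(articles$abstract, model$encoder) else NULL
  j_all <- if ("journal" %in% cfg$features) {
    journal_feature_matrix(articles$journal_id, journal_table, model$scaler)
  } else {
    NULL
  }
  # batches are formed over a canonical (id-sorted) order with a seeded
  # shuffle, so an article's prediction does not depend on input order
  canon <- order(as.character(articles$id))
  order_idx <- canon[with_seed(seed, sample.int(n_obs))]
  prob <- numeric(n_obs)
  batch_of <- integer(n_obs)
  b <- 0L
  for (start in seq(1L, n_obs, by = cfg$batch_size)) {
    b <- b + 1L
    idx <- order_idx[start:min(start + cfg$batch_size - 1L, n_obs)]
    fwd <- batch_forward(
      model$params, cfg,
      if (is.null(r_all)) NULL else r_all[idx, , drop = FALSE],
      if (is.null(n_all)) NULL else n_all[idx, , drop = FALSE],
      if (is.null(j_all)) NULL else j_all[idx, , drop = FALSE]
    )
    prob[idx] <- fwd$prob
    batch_of[idx] <- b
  }
  data.frame(
    id = as.character(articles$id), prob = prob, batch = batch_of,
    stringsAsFactors = FALSE
  )
}

# ---- metrics -------------------------------------------------------------

#' Area under the ROC curve
#'
#' Trapezoidal area under the true-positive-rate vs false-positive-rate
#' curve traced over all score thresholds (tied scores form a single curve
#' vertex).
#'
#' @param prob numeric score vector.
#' @param labels labels in `{0, 1}`.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
roc_auc <- function(prob, labels) {
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    return(NA_real_)
  }
  ord <- order(prob, decreasing = TRUE)
  p_sorted <- prob[ord]
  y_sorted <- labels[ord]
  groups <- cumsum(!duplicated(p_sorted))
  tp <- cumsum(y_sorted)
  fp <- cumsum(1L - y_sorted)
  last_of_group <- !duplicated(groups, fromLast = TRUE)
  tpr <- c(0, tp[last_of_group] / n_pos)
  fpr <- c(0, fp[last_of_group] / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' Average precision
#'
#' Area under the precision-recall curve using step interpolation over
#' score thresholds.
#'
#' @inheritParams roc_auc
#' @return average precision in `[0, 1]`, or `NA` for single-class labels.
#' @export
average_precision <- function(prob, labels) {
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || all(labels == 1L)) {
    return(NA_real_)
  }
  ord <- order(prob, decreasing = TRUE)
  y_sorted <- labels[ord]
  p_sorted <- prob[ord]
  groups <- cumsum(!duplicated(p_sorted))
  tp <- cumsum(y_sorted)
  nn <- seq_along(y_sorted)
  last_of_group <- !duplicated(groups, fromLast = TRUE)
  recall <- tp[last_of_group] / n_pos
  precision <- (tp / nn)[last_of_group]
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Predicts positive when `prob >= threshold` (default 0.5) and reports the
#' confusion counts together with the derived rates, each as a percentage:
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity `TN/(FP+TN)`,
#' accuracy `(TP+TN)/total`, F1 `2PR/(P+R)`, plus ROC AUC and average
#' precision computed from the raw probabilities.
#'
#' @param prob numeric vector of positive-class probabilities.
#' @param labels labels in `{0, 1}`.
#' @param threshold decision threshold in `[0, 1]` (default 0.5).
#' @return object of class `metrics_report`: a list with `tp`, `tn`, `fp`,
#'   `fn`, `precision`, `recall`, `specificity`, `accuracy`, `f1`, `auc`,
#'   `avg_precision` (rates in percent), `threshold` and `n`.
#' @export
evaluate_predictions <- function(prob, labels, threshold = 0.5) {
  if (length(prob) != length(labels)) {
    stop("prob and labels must have equal length", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  specificity <- if (fp + tn > 0L) tn / (fp + tn) else NA_real_
  accuracy <- (tp + tn) / length(labels)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(
    list(
      tp = tp, tn = tn, fp = fp, fn = fn,
      precision = 100 * precision, recall = 100 * recall,
      specificity = 100 * specificity, accuracy = 100 * accuracy,
      f1 = 100 * f1,
      auc = 100 * roc_auc(prob, labels),
      avg_precision = 100 * average_precision(prob, labels),
      threshold = threshold, n = length(labels)
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n = %d at threshold %.2f\n", x$n, x$threshold
  ))
  cat(sprintf(
    "  TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn
  ))
  for (m in c("precision", "recall", "specificity", "accuracy", "f1", "auc")) {
    cat(sprintf("  %-12s %6.2f%%\n", m, x[[m]]))
  }
  invisible(x)
}

#' Metric report from published table values
#'
#' Wraps already-computed percentage metrics (e.g. a published benchmark
#' row) so they can be fed to [compare_models].
#'
#' @param ... named percentage metrics, e.g. `precision = 59.11`.
#' @return object of class `metrics_report`.
#' @export
metrics_from_rates <- function(...) {
  structure(list(...), class = "metrics_report")
}

#' Per-metric difference between two models
#'
#' Computes `a - b` in percentage points for every rate metric present in
#' both reports. Positive values mean model `a` is better on that metric
#' (all reported metrics are higher-is-better).
#'
#' @param report_a,report_b `metrics_report` objects evaluated on the same
#'   test set.
#' @return named numeric vector of differences.
#' @export
compare_models <- function(report_a, report_b) {
  metric_names <- c(
    "precision", "recall", "specificity", "accuracy", "f1",
    "auc", "avg_precision"
  )
  shared <- intersect(
    intersect(metric_names, names(report_a)),
    names(report_b)
  )
  vapply(
    shared,
    function(m) as.numeric(report_a[[m]]) - as.numeric(report_b[[m]]),
    numeric(1)
  )
}

#' Rank-screen new articles
#'
#' Scores articles with a trained model, retains those at or above the
#' probability threshold and ranks all articles by decreasing probability
#' (ties broken by article id). In practice a threshold below 0.5 is used
#' so that few relevant articles are missed, and reviewers read down the
#' ranked list.
#'
#' @param model trained `screener_model`.
#' @param articles data frame of articles to screen.
#' @param threshold retention threshold in `[0, 1]` (default 0.5).
#' @param journal_table optional journal table override.
#' @param seed evaluation batching seed (see [predict_screener]).
#' @return data frame with `id`, `probability`, `rank`, `retained`, ordered
#'   by rank.
#' @export
rank_screen <- function(model, articles, threshold = 0.5,
                        journal_table = NULL, seed = NULL) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  preds <- predict_screener(model, articles, journal_table, seed)
  if (nrow(preds) == 0L) {
    return(data.frame(
      id = character(0), probability = numeric(0),
      rank = integer(0), retained = logical(0)
    ))
  }
  ord <- order(-preds$prob, preds$id)
  out <- data.frame(
    id = preds$id[ord],
    probability = preds$prob[ord],
    rank = seq_along(ord),
    retained = preds$prob[ord] >= threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Save / load a trained model
#'
#' The checkpoint is a single serialized file containing the parameters,
#' encoder, scaler, journal table, configuration and loss log; reloading
#' restores bit-identical evaluation behaviour.
#'
#' @param model trained `screener_model`.
#' @param path file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_screener <- function(model, path) {
  stopifnot(inherits(model, "screener_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_screener
#' @export
load_screener <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "screener_model"))
  model
}
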