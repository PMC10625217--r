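# Journal bibliometric features: zone one-hot encoding, train-split
# standardization with median imputation, and label-conditional summaries.

#' Continuous journal metric column names
#'
#' Seven yearly impact factors (2015-2021), CiteScore, SJR, SNIP and
#' H-index, in the fixed order used throughout the feature vector.
#'
#' @return character vector of length 11.
#' @export
journal_metric_columns <- function() {
  c(paste0("if_", 2015:2021), "cite_score", "sjr", "snip", "h_index")
}

# Metric families used for the missingness flags: the seven IF years form
# one family, the remaining metrics one family each.
journal_metric_families <- function() {
  list(
    if_years = paste0("if_", 2015:2021),
    cite_score = "cite_score",
    sjr = "sjr",
    snip = "snip",
    h_index = "h_index"
  )
}

#' One-hot encode a journal ranking zone
#'
#' Zones rank journals within a discipline by impact factor: zone 1 is the
#' top 5%, zone 2 the next 5-20%, zone 3 the 20-50% band and zone 4 the
#' remainder. A fifth "unknown" category absorbs missing zones.
#'
#' @param zone integer in 1..4, or `NA` for unknown.
#' @param journal_id optional id used in error messages.
#' @return numeric vector of length 5 with exactly one 1.
#' @examples
#' encode_zone(2)
#' encode_zone(NA)
#' @export
encode_zone <- function(zone, journal_id = NULL) {
  v <- numeric(5)
  if (is.na(zone)) {
    v[5L] <- 1
  } else {
    zone <- as.integer(zone)
    if (!(zone %in% 1:4)) {
      stop(sprintf(
        "zone must be 1..4 or missing%s (got %s)",
        if (is.null(journal_id)) "" else paste0(" for journal ", journal_id),
        zone
      ), call. = FALSE)
    }
    v[zone] <- 1
  }
  v
}

#' Fit a journal feature scaler on a training split
#'
#' Learns, per continuous metric, the mean and standard deviation over
#' non-missing training values (for z-scoring) and the median (for imputing
#' missing values). Statistics come from the training journals only so the
#' test split never leaks into the normalization. Metrics missing for every
#' training journal are dropped with a warning; constant metrics keep sd 0
#' and are flagged so that their z-scores collapse to zero.
#'
#' @param journal_table data frame as from [read_journal_table]; needs at
#'   least 2 rows.
#' @return object of class `journal_scaler` with fields `features`, `mean`,
#'   `sd`, `median`, `zero_variance`.
#' @export
fit_scaler <- function(journal_table) {
  check_columns(journal_table, "journal_id", "journal_table")
  if (nrow(journal_table) < 2L) {
    stop("need at least 2 journals to fit a scaler", call. = FALSE)
  }
  feats <- intersect(journal_metric_columns(), names(journal_table))
  mu <- sdv <- med <- stats::setNames(numeric(length(feats)), feats)
  keep <- logical(length(feats))
  names(keep) <- feats
  for (f in feats) {
    x <- journal_table[[f]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      warning(sprintf("metric '%s' missing for all journals; dropped", f),
        call. = FALSE
      )
      next
    }
    keep[f] <- TRUE
    mu[f] <- mean(x)
    sdv[f] <- if (length(x) > 1L) stats::sd(x) else 0
    med[f] <- stats::median(x)
  }
  feats <- feats[keep]
  structure(
    list(
      features = feats,
      mean = mu[feats],
      sd = sdv[feats],
      median = med[feats],
      zero_variance = sdv[feats] == 0
    ),
    class = "journal_scaler"
  )
}

#' @export
print.journal_scaler <- function(x, ...) {
  cat(sprintf(
    "<journal_scaler> %d continuous metric(s)%s\n", length(x$features),
    if (any(x$zero_variance)) {
      sprintf(" (%d zero-variance)", sum(x$zero_variance))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Feature-vector layout implied by a scaler
#'
#' The vector for one journal is, in order: the z-scored continuous metrics
#' retained by the scaler, the zone one-hot (widths 5, including "unknown"),
#' and one missingness flag per metric family (IF years, CiteScore, SJR,
#' SNIP, H-index).
#'
#' @param scaler a fitted `journal_scaler`.
#' @return character vector of feature-vector component names.
#' @export
journal_feature_names <- function(scaler) {
  c(
    paste0("z_", scaler$features),
    paste0("zone_", c(1:4, "unknown")),
    paste0("miss_", names(journal_metric_families()))
  )
}

#' Transform journal records into model feature vectors
#'
#' Missing metric values are imputed with the training median and the
#' corresponding family flag is set; continuous values are z-scored with the
#' training statistics (zero-variance metrics map to 0); the zone is one-hot
#' encoded with an explicit "unknown" category. The column layout is given
#' by [journal_feature_names].
#'
#' @param journal_table data frame of journal records to transform.
#' @param scaler fitted [fit_scaler] object.
#' @return numeric matrix, one row per journal, rownames = `journal_id`.
#' @export
transform_journals <- function(journal_table, scaler) {
  if (!inherits(scaler, "journal_scaler")) {
    stop("scaler must come from fit_scaler()", call. = FALSE)
  }
  check_columns(journal_table, "journal_id", "journal_table")
  n <- nrow(journal_table)
  fams <- journal_metric_families()
  cont <- matrix(0, n, length(scaler$features),
    dimnames = list(NULL, paste0("z_", scaler$features))
  )
  flags <- matrix(0, n, length(fams),
    dimnames = list(NULL, paste0("miss_", names(fams)))
  )
  for (j in seq_along(scaler$features)) {
    f <- scaler$features[j]
    x <- if (is.null(journal_table[[f]])) rep(NA_real_, n) else as.numeric(journal_table[[f]])
    miss <- is.na(x)
    x[miss] <- scaler$median[f]
    cont[, j] <- if (scaler$zero_variance[j]) 0 else (x - scaler$mean[f]) / scaler$sd[f]
    fam <- which(vapply(fams, function(cols) f %in% cols, logical(1)))
    flags[miss, fam] <- 1
  }
  zone <- if (is.null(journal_table$zone)) rep(NA_integer_, n) else journal_table$zone
  zones <- t(vapply(
    seq_len(n),
    function(i) encode_zone(zone[i], journal_table$journal_id[i]),
    numeric(5)
  ))
  colnames(zones) <- paste0("zone_", c(1:4, "unknown"))
  out <- cbind(cont, zones, flags)
  rownames(out) <- as.character(journal_table$journal_id)
  out
}

#' Look up feature vectors for a set of articles
#'
#' @param journal_ids character vector of journal ids (one per article).
#' @param journal_table journal metrics table.
#' @param scaler fitted scaler.
#' @return numeric matrix with one row per article.
#' @export
journal_feature_matrix <- function(journal_ids, journal_table, scaler) {
  journal_ids <- as.character(journal_ids)
  all_ids <- as.character(journal_table$journal_id)
  idx <- match(journal_ids, all_ids)
  if (anyNA(idx)) {
    stop(sprintf(
      "unknown journal_id(s): %s",
      paste(utils::head(unique(journal_ids[is.na(idx)]), 5L), collapse = ", ")
    ), call. = FALSE)
  }
  feats <- transform_journals(journal_table, scaler)
  out <- feats[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label-conditional five-number summaries of journal metrics
#'
#' For each continuous metric and each label class, computes the boxplot
#' statistics (lower whisker, first quartile, median, third quartile, upper
#' whisker, as in [grDevices::boxplot.stats]) over the articles of that
#' class. In well-behaved corpora the positive class sits visibly higher on
#' impact factor, CiteScore and SJR.
#'
#' @param articles labelled data frame with `journal_id` and `label`.
#' @param journal_table journal metrics table.
#' @return data frame with columns `feature`, `label`, `lower_whisker`,
#'   `q1`, `median`, `q3`, `upper_whisker`, `n`.
#' @export
summarize_by_label <- function(articles, journal_table) {
  check_columns(articles, c("journal_id", "label"), "articles")
  if (length(unique(articles$label)) < 2L) {
    stop("both label classes must be present", call. = FALSE)
  }
  idx <- match(
    as.character(articles$journal_id),
    as.character(journal_table$journal_id)
  )
  if (anyNA(idx)) stop("articles reference unknown journals", call. = FALSE)
  feats <- intersect(journal_metric_columns(), names(journal_table))
  rows <- list()
  for (f in feats) {
    vals <- journal_table[[f]][idx]
    for (lab in c(0L, 1L)) {
      x <- vals[articles$label == lab & !is.na(vals)]
      if (length(x) == 0L) next
      st <- grDevices::boxplot.stats(x)$stats
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, label = lab,
        lower_whisker = st[1L], q1 = st[2L], median = st[3L],
        q3 = st[4L], upper_whisker = st[5L], n = length(x),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
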