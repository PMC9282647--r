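# External validation: the 100-repeat balanced resampling protocol, the
# ACC/SE/SP/NPV quality metrics, AUC, KS model comparison and the
# docking-score decision threshold.

#' The balanced resampling protocol
#'
#' Each repeat sets aside an external validation set of
#' \code{external_n_per_class} randomly chosen compounds per class (the study
#' default is 50 + 50), balances the remaining compounds by undersampling the
#' majority class, trains a fresh classifier and evaluates it on the external
#' set. Per-repeat RNG streams derive from (seed, repeat index).
#'
#' @param n_repeats number of repeats (default 100)
#' @param external_n_per_class external compounds per class (default 50)
#' @param seed master seed
#' @return object of class \code{resampling_protocol}
#' @export
resampling_protocol <- function(n_repeats = 100, external_n_per_class = 50,
                                seed = 1) {
  stop_if_not(n_repeats >= 2, "n_repeats must be >= 2")
  stop_if_not(external_n_per_class >= 1, "external_n_per_class must be >= 1")
  structure(list(n_repeats = n_repeats,
                 external_n_per_class = external_n_per_class, seed = seed),
            class = "resampling_protocol")
}

#' Classification quality metrics from confusion counts
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN), SE = TP/(TP+FN), SP = TN/(TN+FP),
#' NPV = TN/(TN+FN). A metric with an empty denominator is reported as NA
#' rather than aborting the run.
#'
#' @param tp,fn,tn,fp confusion counts (non-negative integers)
#' @return named numeric vector (ACC, SE, SP, NPV)
#' @export
compute_metrics <- function(tp, fn, tn, fp) {
  stop_if_not(all(c(tp, fn, tn, fp) >= 0), "confusion counts must be non-negative")
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  c(ACC = safe_div(tp + tn, tp + tn + fp + fn),
    SE = safe_div(tp, tp + fn),
    SP = safe_div(tn, tn + fp),
    NPV = safe_div(tn, tn + fn))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' P(score of a random binder > score of a random nonbinder) + 1/2 P(tie),
#' computed from ranks.
#'
#' @param scores numeric classifier output scores (higher = more binder-like)
#' @param labels labels coercible by the binder/nonbinder convention
#' @return AUC in [0, 1]
#' @export
compute_auc <- function(scores, labels) {
  y <- encode_labels(labels)
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  stop_if_not(n_pos > 0 && n_neg > 0, "both classes required for AUC")
  r <- rank(scores)
  (sum(r[y > 0]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS statistic sup |ECDF_a - ECDF_b|; the p-value is exact for
#' small samples (min n <= 25) and asymptotic otherwise.
#'
#' @param a,b numeric samples
#' @return list(statistic, p_value)
#' @export
ks_two_sample <- function(a, b) {
  stop_if_not(length(a) > 0 && length(b) > 0, "samples must be non-empty")
  exact <- min(length(a), length(b)) <= 25
  res <- suppressWarnings(ks.test(a, b, exact = exact))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Compare two metric distributions by a KS test
#'
#' The study compares classifiers by KS tests on their per-repeat metric
#' samples (no multiple-testing correction).
#'
#' @param dist1,dist2 \code{\link{resample_evaluate}} results
#' @param metric one of "ACC", "SE", "SP", "NPV", "AUC"
#' @return the KS p-value
#' @export
compare_models <- function(dist1, dist2, metric = "ACC") {
  for (d in list(dist1, dist2)) {
    stop_if_not(metric %in% colnames(d) && !all(is.na(d[[metric]])),
                "metric %s not available in distribution", metric)
  }
  ks_two_sample(dist1[[metric]], dist2[[metric]])$p_value
}

#' Docking-score decision threshold of a DS-only classifier
#'
#' Scans the observed docking-score range at a fixed step (study default
#' 0.01), predicts at each grid point and returns the raw-unit DS at which
#' the predicted label flips from active (binder) to inactive — the
#' practically usable score cutoff. For a linear DS-only model the flip is
#' unique; the returned value is the midpoint of the two straddling grid
#' points, hence within half a step of the analytic crossing.
#'
#' @param model a DS-only \code{\link{lasso_svm}} with a stored standardizer
#' @param ds_range numeric range (min, max) of observed raw docking scores
#' @param step scan step in raw DS units (default 0.01)
#' @return raw-unit threshold, or NA (with a warning) if no flip occurs in
#'   range
#' @export
ds_threshold <- function(model, ds_range, step = 0.01) {
  stop_if_not(length(model$feature_names) == 1,
              "ds_threshold requires a DS-only (single-feature) model")
  stop_if_not(!is.null(model$standardizer), "model has no score standardizer")
  stop_if_not(step > 0, "step must be > 0")
  grid <- seq(min(ds_range), max(ds_range), by = step)
  x <- matrix(standardize_scores(grid, model$standardizer), ncol = 1,
              dimnames = list(NULL, model$feature_names))
  lab <- predict(model, x)$label
  flips <- which(lab[-1] != lab[-length(lab)])
  if (length(flips) == 0) {
    warning("no label change within the scanned DS range")
    return(NA_real_)
  }
  mean(grid[c(flips[1], flips[1] + 1L)])
}

#' Run the balanced resampling evaluation
#'
#' The full external-validation protocol: per repeat, (i) draw the external
#' set (\code{external_n_per_class} compounds per class, without
#' replacement), (ii) balance the remaining training compounds by
#' undersampling the majority class, (iii) fit the score standardizer on the
#' training scores only, build features (DS-only, or DS/IF when a
#' fingerprint table is given), train a \code{\link{lasso_svm}}, and (iv)
#' compute ACC/SE/SP/NPV (and optionally AUC and the DS threshold) on the
#' external compounds.
#'
#' @param ds raw docking scores named by compound id
#' @param labels binder/nonbinder labels aligned with \code{ds}
#' @param if_table optional 0/1 fingerprint matrix (compound-id rownames);
#'   supplying it switches to the DS/IF fused model
#' @param protocol a \code{\link{resampling_protocol}}
#' @param auc also compute the per-repeat AUC (default TRUE)
#' @param threshold also record the per-repeat DS threshold (DS-only models
#'   only; default TRUE when \code{if_table} is NULL)
#' @param threshold_step DS scan step (default 0.01)
#' @param trainer training function \code{function(x, y, seed)} returning an
#'   object with a \code{predict} method; default wraps
#'   \code{\link{lasso_svm}}
#' @param ... passed to \code{\link{lasso_svm}} by the default trainer
#' @return a \code{metric_distribution}: data.frame with one row per repeat
#'   (columns ACC, SE, SP, NPV, and optionally AUC, threshold)
#' @export
resample_evaluate <- function(ds, labels, if_table = NULL,
                              protocol = resampling_protocol(),
                              auc = TRUE,
                              threshold = is.null(if_table),
                              threshold_step = 0.01,
                              trainer = NULL, ...) {
  stopifnot(inherits(protocol, "resampling_protocol"))
  y <- encode_labels(labels)
  ids <- names(ds) %||% rownames(if_table) %||% paste0("cmp", seq_along(ds))
  names(ds) <- ids
  n_ext <- protocol$external_n_per_class
  pos <- which(y > 0); neg <- which(y < 0)
  need <- n_ext + 10
  stop_if_not(length(pos) >= need && length(neg) >= need,
              "need at least %d compounds per class (have %d binders, %d nonbinders)",
              need, length(pos), length(neg))
  threshold <- threshold && is.null(if_table)
  rows <- vector("list", protocol$n_repeats)
  for (r in seq_len(protocol$n_repeats)) {
    set.seed(derive_seed(protocol$seed, r))
    ext <- c(sample(pos, n_ext), sample(neg, n_ext))
    rem_pos <- setdiff(pos, ext); rem_neg <- setdiff(neg, ext)
    n_bal <- min(length(rem_pos), length(rem_neg))
    train <- c(sample(rem_pos, n_bal), sample(rem_neg, n_bal))

    std <- score_standardizer(ds[train])
    x_train <- build_features(ds[train], std, if_table)
    x_ext <- build_features(ds[ext], std, if_table)
    model <- if (is.null(trainer)) {
      lasso_svm(x_train, y[train], seed = derive_seed(protocol$seed, r + 10000),
                standardizer = std, ...)
    } else {
      trainer(x_train, y[train], derive_seed(protocol$seed, r + 10000))
    }
    pred <- predict(model, x_ext)
    is_pos <- y[ext] > 0
    pred_pos <- pred$label == "binder"
    met <- compute_metrics(tp = sum(is_pos & pred_pos),
                           fn = sum(is_pos & !pred_pos),
                           tn = sum(!is_pos & !pred_pos),
                           fp = sum(!is_pos & pred_pos))
    row <- as.list(met)
    if (auc) row$AUC <- compute_auc(pred$margin, y[ext])
    if (threshold) {
      row$threshold <- suppressWarnings(
        ds_threshold(model, range(ds[train]), step = threshold_step))
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  structure(out, class = c("metric_distribution", "data.frame"),
            protocol = protocol, mode = if (is.null(if_table)) "DS" else "DS/IF")
}

#' @export
summary.metric_distribution <- function(object, ...) {
  cols <- colnames(object)
  out <- data.frame(metric = cols,
                    mean = vapply(cols, function(m) mean(object[[m]], na.rm = TRUE), 0),
                    sd = vapply(cols, function(m) sd(object[[m]], na.rm = TRUE), 0),
                    row.names = NULL)
  class(out) <- c("summary.metric_distribution", "data.frame")
  attr(out, "mode") <- attr(object, "mode")
  out
}

#' @export
print.metric_distribution <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("%s model, %d resampling repeats (mean ± sd):\n",
              attr(x, "mode") %||% "?", nrow(x)))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s %.2f ± %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Box plot of per-repeat metric distributions
#'
#' @param x a \code{metric_distribution}
#' @param metrics which columns to show
#' @param ... passed to \code{boxplot}
#' @export
plot.metric_distribution <- function(x, metrics = intersect(colnames(x),
                                     c("ACC", "SE", "SP", "NPV", "AUC")), ...) {
  graphics::boxplot(as.data.frame(x)[, metrics, drop = FALSE],
                    ylab = "metric value", ...)
  invisible(x)
}

#' Write a metric distribution as CSV plus a JSON summary
#'
#' @param dist a \code{metric_distribution}
#' @param path output CSV (one row per repeat); summary goes to
#'   \code{<path>.summary.json}
#' @return invisibly, \code{path}
#' @export
write_metrics <- function(dist, path) {
  write.csv(as.data.frame(dist), path, row.names = FALSE)
  s <- summary(dist)
  jsonlite::write_json(
    setNames(lapply(seq_len(nrow(s)), function(i) {
      list(mean = s$mean[i], sd = s$sd[i])
    }), s$metric),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
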