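# The central model: a LASSO-regularised linear support vector machine.
# Hinge loss (Huber-smoothed) + lambda * ||w||_1, minimised by FISTA
# proximal gradient (soft-thresholding gives exact zero weights); the
# regularisation strength is tuned by minimum classification error on a
# held-out stratified split, preferring the sparser (larger lambda) model on
# ties.

#' Score standardizer
#'
#' Location/scale transform for docking scores, fit on training scores only
#' and applied unchanged to external compounds.
#'
#' @param ds numeric docking scores (training set)
#' @param mu,sigma explicit parameters (otherwise estimated from \code{ds})
#' @return object of class \code{score_standardizer} with fields mu, sigma
#' @export
score_standardizer <- function(ds = NULL, mu = NULL, sigma = NULL) {
  if (is.null(mu)) mu <- mean(ds)
  if (is.null(sigma)) sigma <- sd(ds)
  stop_if_not(is.finite(sigma) && sigma > 0,
              "docking scores are constant (sigma = 0); cannot standardize")
  structure(list(mu = mu, sigma = sigma), class = "score_standardizer")
}

#' Standardize docking scores
#'
#' \code{(ds - mu) / sigma} with the standardizer's parameters.
#'
#' @param ds numeric docking scores
#' @param std a \code{\link{score_standardizer}}
#' @return numeric vector of standardized scores
#' @export
standardize_scores <- function(ds, std) {
  stopifnot(inherits(std, "score_standardizer"))
  (ds - std$mu) / std$sigma
}

#' Build classifier feature vectors from scores and fingerprints
#'
#' DS-only mode (no fingerprint table) yields a single-column matrix of
#' standardized scores. DS/IF mode appends the fingerprint bits recoded to
#' -1 (absence) / +1 (presence), so continuous and binary predictors live in
#' one vector.
#'
#' @param ds raw docking scores, named by compound id (or accompanied by
#'   \code{compound_ids})
#' @param std a \code{\link{score_standardizer}} (fit on training data)
#' @param if_table optional 0/1 fingerprint matrix with compound-id rownames
#' @param compound_ids ids aligning \code{ds} rows (default \code{names(ds)})
#' @return numeric matrix (compounds x features); first column \code{ds_st}
#' @export
build_features <- function(ds, std, if_table = NULL, compound_ids = names(ds)) {
  if (is.null(compound_ids)) compound_ids <- rownames(if_table)[seq_along(ds)]
  stop_if_not(!is.null(compound_ids), "compound ids required to align features")
  x <- matrix(standardize_scores(ds, std), ncol = 1,
              dimnames = list(compound_ids, "ds_st"))
  if (!is.null(if_table)) {
    missing <- setdiff(compound_ids, rownames(if_table))
    stop_if_not(length(missing) == 0,
                "compounds without fingerprints: %s", paste(missing, collapse = ", "))
    bits <- if_table[compound_ids, , drop = FALSE]
    stop_if_not(all(bits %in% c(0L, 1L)), "fingerprint table must be 0/1")
    x <- cbind(x, 2 * bits - 1)
  }
  x
}

# Huberised hinge loss and derivative (smoothing half-width delta):
# z >= 1: 0; z <= 1-delta: 1 - z - delta/2; else (1-z)^2/(2 delta)
huber_hinge <- function(z, delta) {
  ifelse(z >= 1, 0, ifelse(z <= 1 - delta, 1 - z - delta / 2, (1 - z)^2 / (2 * delta)))
}
huber_hinge_grad <- function(z, delta) {
  ifelse(z >= 1, 0, ifelse(z <= 1 - delta, -1, -(1 - z) / delta))
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

# spectral norm of [X 1] via power iteration (Lipschitz constant of the
# smoothed-hinge gradient is ||A||_2^2 / (n * delta))
spec_norm2 <- function(x, iters = 60) {
  a <- cbind(x, 1)
  v <- rep(1 / sqrt(ncol(a)), ncol(a))
  for (i in seq_len(iters)) {
    u <- a %*% v
    v <- crossprod(a, u)
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(1)
    v <- v / nv
  }
  sum((a %*% v)^2)
}

# FISTA for min (1/n) sum huber_hinge(y * (xw + b)) + lambda ||w||_1
fit_l1_svm <- function(x, y, lambda, delta = 0.1, tol = 1e-6, max_iter = 1e4,
                       w0 = NULL, b0 = 0, lip = NULL) {
  n <- nrow(x); p <- ncol(x)
  if (is.null(lip)) lip <- spec_norm2(x) / (n * delta)
  step <- 1 / max(lip, .Machine$double.eps)
  w <- w0 %||% rep(0, p); b <- b0
  vw <- w; vb <- b
  t_k <- 1
  obj_old <- Inf
  objective <- function(w, b) {
    mean(huber_hinge(y * (drop(x %*% w) + b), delta)) + lambda * sum(abs(w))
  }
  for (it in seq_len(max_iter)) {
    z <- y * (drop(x %*% vw) + vb)
    g <- huber_hinge_grad(z, delta) * y / n
    gw <- drop(crossprod(x, g))
    gb <- sum(g)
    w_new <- soft_threshold(vw - step * gw, step * lambda)
    b_new <- vb - step * gb
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    vw <- w_new + ((t_k - 1) / t_new) * (w_new - w)
    vb <- b_new + ((t_k - 1) / t_new) * (b_new - b)
    w <- w_new; b <- b_new; t_k <- t_new
    if (it %% 10 == 0) {
      obj <- objective(w, b)
      if (abs(obj_old - obj) <= tol * max(1, abs(obj))) break
      obj_old <- obj
    }
  }
  list(w = w, b = b, iters = it, objective = objective(w, b))
}

#' Fit a LASSO-regularised linear SVM classifier
#'
#' Fits, for each value of the regularisation grid, a linear SVM with
#' Huber-smoothed hinge loss and an L1 penalty on the weights (bias
#' unpenalised), by FISTA proximal gradient with warm starts along the
#' lambda path. The regularisation strength is selected from the
#' classification error on held-out stratified tuning splits of the
#' training data, averaged over \code{tune_repeats} random splits: the
#' sparsest (largest) lambda within one standard error of the minimum
#' error is chosen, the standard guard against the over-selection of
#' minimum-error tuning. The model is then refit on the full training set
#' at the selected lambda.
#'
#' Binders are encoded +1, nonbinders -1; the decision is
#' \code{sign(w . x + b)} with ties (margin exactly 0) called nonbinder.
#'
#' @param x numeric feature matrix (e.g. \code{\link{build_features}});
#'   column names become the model's feature names
#' @param y labels: a factor with levels nonbinder/binder, a +-1 numeric
#'   vector, or a character vector of "binder"/"nonbinder"
#' @param lambda optional fixed regularisation strength (skips tuning)
#' @param lambda_grid grid searched when \code{lambda} is NULL; default 20
#'   log-spaced values in (1e-3, 1)
#' @param tune_fraction held-out fraction of the training set used for
#'   selecting lambda (stratified; default 0.2)
#' @param tune_repeats number of random tuning splits whose error curves
#'   are averaged before selecting lambda (default 5)
#' @param seed RNG seed for the tuning split
#' @param delta hinge smoothing half-width
#' @param tol,max_iter optimiser convergence controls
#' @param standardizer optional \code{\link{score_standardizer}} stored with
#'   the model (needed by \code{\link{ds_threshold}})
#' @return an object of class \code{lasso_svm}: list with weights, bias,
#'   lambda, feature_names, standardizer, tuning (per-lambda held-out error),
#'   and fit diagnostics
#' @seealso \code{\link{predict.lasso_svm}}, \code{\link{ds_threshold}},
#'   \code{\link{resample_evaluate}}
#' @export
lasso_svm <- function(x, y, lambda = NULL,
                      lambda_grid = 10^seq(-3, -0.02, length.out = 20),
                      tune_fraction = 0.2, tune_repeats = 5, seed = 1,
                      delta = 0.1, tol = 1e-6, max_iter = 1e4,
                      standardizer = NULL) {
  x <- as.matrix(x)
  stop_if_not(all(is.finite(x)), "non-finite feature values")
  yy <- encode_labels(y)
  stop_if_not(length(unique(yy)) == 2, "both classes must be present")
  stop_if_not(is.null(lambda_grid) ||
                (length(lambda_grid) > 0 && all(lambda_grid > 0 & lambda_grid < 1)),
              "lambda_grid values must lie in (0, 1)")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  tuning <- NULL
  if (is.null(lambda)) {
    grid <- sort(lambda_grid, decreasing = TRUE)   # path: sparse -> dense
    idx_pos <- which(yy > 0); idx_neg <- which(yy < 0)
    n_tune_pos <- max(1L, round(tune_fraction * length(idx_pos)))
    n_tune_neg <- max(1L, round(tune_fraction * length(idx_neg)))
    errs <- matrix(0, tune_repeats, length(grid))
    for (rep_i in seq_len(tune_repeats)) {
      set.seed(derive_seed(seed, rep_i - 1))
      tune_idx <- c(sample(idx_pos, n_tune_pos), sample(idx_neg, n_tune_neg))
      fit_idx <- setdiff(seq_len(nrow(x)), tune_idx)
      lip <- spec_norm2(x[fit_idx, , drop = FALSE]) / (length(fit_idx) * delta)
      w0 <- NULL; b0 <- 0
      for (k in seq_along(grid)) {
        f <- fit_l1_svm(x[fit_idx, , drop = FALSE], yy[fit_idx], grid[k],
                        delta = delta, tol = tol, max_iter = max_iter,
                        w0 = w0, b0 = b0, lip = lip)
        w0 <- f$w; b0 <- f$b
        marg <- drop(x[tune_idx, , drop = FALSE] %*% f$w) + f$b
        pred <- ifelse(marg > 0, 1, -1)
        errs[rep_i, k] <- mean(pred != yy[tune_idx])
      }
    }
    avg <- colMeans(errs)
    # one-standard-error rule: the sparsest lambda whose averaged held-out
    # error is within one standard error of the minimum (for a single split
    # the binomial standard error is used); ties -> largest lambda
    k_min <- which.min(avg)
    se_min <- if (tune_repeats > 1) {
      sd(errs[, k_min]) / sqrt(tune_repeats)
    } else {
      sqrt(avg[k_min] * (1 - avg[k_min]) / (n_tune_pos + n_tune_neg))
    }
    tuning <- data.frame(lambda = grid, error = avg)
    candidates <- grid[avg <= avg[k_min] + se_min]
    lambda <- candidates[1]
    fit <- fit_l1_svm(x, yy, lambda, delta = delta, tol = tol, max_iter = max_iter)
    # the largest tying lambda can sit exactly at the weight-collapse
    # boundary of the full training set; if the refit degenerates to an
    # all-zero model although the tuning data showed signal, step down
    # through the tying lambdas
    k <- 2
    while (all(fit$w == 0) && min(errs) < 0.45 && k <= length(candidates)) {
      lambda <- candidates[k]
      fit <- fit_l1_svm(x, yy, lambda, delta = delta, tol = tol, max_iter = max_iter)
      k <- k + 1
    }
    return(finish_lasso_svm(fit, lambda, colnames(x), standardizer, tuning,
                            delta, nrow(x)))
  }
  fit <- fit_l1_svm(x, yy, lambda, delta = delta, tol = tol, max_iter = max_iter)
  finish_lasso_svm(fit, lambda, colnames(x), standardizer, tuning, delta, nrow(x))
}

finish_lasso_svm <- function(fit, lambda, feature_names, standardizer,
                             tuning, delta, n) {
  structure(list(weights = setNames(fit$w, feature_names), bias = fit$b,
                 lambda = lambda, feature_names = feature_names,
                 standardizer = standardizer, tuning = tuning,
                 delta = delta, iters = fit$iters, objective = fit$objective,
                 n = n),
            class = "lasso_svm")
}

encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    stop_if_not(all(y %in% c("binder", "nonbinder")),
                "character labels must be 'binder'/'nonbinder'")
    return(ifelse(y == "binder", 1, -1))
  }
  stop_if_not(all(y %in% c(-1, 1)), "numeric labels must be -1/+1")
  as.numeric(y)
}

# bare constructor for a linear decision function (used for analytic models)
new_lasso_svm <- function(weights, bias, feature_names = names(weights),
                          standardizer = NULL) {
  structure(list(weights = setNames(as.numeric(weights), feature_names),
                 bias = bias, lambda = NA_real_, feature_names = feature_names,
                 standardizer = standardizer, tuning = NULL, delta = NA_real_,
                 iters = 0L, objective = NA_real_, n = 0L),
            class = "lasso_svm")
}

#' Predict binder/nonbinder labels and margins
#'
#' @param object a \code{\link{lasso_svm}}
#' @param newdata feature matrix with the model's feature columns
#' @param ... unused
#' @return data.frame with columns margin and label (binder iff margin > 0;
#'   a margin of exactly 0 is called nonbinder)
#' @export
predict.lasso_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object$feature_names)) {
    colnames(newdata) <- object$feature_names
  }
  stop_if_not(all(object$feature_names %in% colnames(newdata)),
              "newdata lacks feature column(s): %s",
              paste(setdiff(object$feature_names, colnames(newdata)), collapse = ", "))
  margin <- drop(newdata[, object$feature_names, drop = FALSE] %*% object$weights) +
    object$bias
  data.frame(margin = margin,
             label = factor(ifelse(margin > 0, "binder", "nonbinder"),
                            levels = c("nonbinder", "binder")),
             row.names = rownames(newdata))
}

#' @export
coef.lasso_svm <- function(object, ...) {
  c(`(bias)` = object$bias, object$weights)
}

#' @export
print.lasso_svm <- function(x, ...) {
  nnz <- sum(x$weights != 0)
  cat("LASSO-regularised linear SVM\n")
  cat(sprintf("  features: %d (%d with nonzero weight)\n",
              length(x$weights), nnz))
  cat(sprintf("  lambda:   %s\n",
              if (is.na(x$lambda)) "(fixed decision function)" else format(x$lambda, digits = 4)))
  cat(sprintf("  bias:     %.4f\n", x$bias))
  invisible(x)
}

#' @export
summary.lasso_svm <- function(object, ...) {
  w <- object$weights
  w_nz <- w[w != 0]
  out <- list(n_features = length(w), n_nonzero = length(w_nz),
              lambda = object$lambda,
              top = w_nz[order(-abs(w_nz))][seq_len(min(10, length(w_nz)))],
              tuning = object$tuning)
  class(out) <- "summary.lasso_svm"
  out
}

#' @export
print.summary.lasso_svm <- function(x, ...) {
  cat(sprintf("LASSO-SVM: %d/%d nonzero weights, lambda = %s\n",
              x$n_nonzero, x$n_features, format(x$lambda, digits = 4)))
  if (length(x$top)) {
    cat("largest |weights|:\n")
    print(round(x$top, 4))
  }
  invisible(x)
}

#' Plot a fitted LASSO-SVM
#'
#' Horizontal bar chart of the nonzero feature weights — the model's
#' interpretable readout of which docking-score / residue-interaction
#' features drive the binder call.
#'
#' @param x a \code{\link{lasso_svm}}
#' @param max_features show at most this many (by |weight|)
#' @param ... passed to \code{barplot}
#' @export
plot.lasso_svm <- function(x, max_features = 20, ...) {
  w <- x$weights[x$weights != 0]
  if (!length(w)) {
    graphics::barplot(0, main = "all weights zero")
    return(invisible(x))
  }
  w <- w[order(abs(w), decreasing = TRUE)]
  w <- rev(w[seq_len(min(max_features, length(w)))])
  graphics::barplot(w, horiz = TRUE, las = 1, xlab = "weight",
                    main = "LASSO-SVM feature weights", ...)
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model a \code{\link{lasso_svm}}
#' @param path JSON file path
#' @return \code{write_model}: invisibly, \code{path};
#'   \code{read_model}: the restored \code{lasso_svm}
#' @export
write_model <- function(model, path) {
  obj <- list(feature_names = model$feature_names,
              weights = unname(model$weights), bias = model$bias,
              lambda = model$lambda, delta = model$delta)
  if (!is.null(model$standardizer)) {
    obj$standardizer <- list(mu = model$standardizer$mu,
                             sigma = model$standardizer$sigma)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- if (!is.null(obj$standardizer)) {
    score_standardizer(mu = obj$standardizer$mu, sigma = obj$standardizer$sigma)
  }
  m <- new_lasso_svm(obj$weights, obj$bias, obj$feature_names, std)
  m$lambda <- obj$lambda %||% NA_real_
  m$delta <- obj$delta %||% NA_real_
  m
}
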