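# Quality metrics, AUC, KS tests, DS thresholds and the resampling protocol

test_that("quality metrics match their defining formulas", {
  m <- compute_metrics(tp = 50, fn = 0, tn = 50, fp = 0)
  expect_equal(unname(m), rep(1, 4))
  m2 <- compute_metrics(tp = 40, fn = 10, tn = 35, fp = 15)
  expect_equal(unname(m2["ACC"]), 0.75)
  expect_equal(unname(m2["SE"]), 0.80)
  expect_equal(unname(m2["SP"]), 0.70)
  expect_equal(unname(m2["NPV"]), 35 / 45)
  # empty predicted-negative set: NPV unavailable, not an error
  m3 <- compute_metrics(tp = 10, fn = 0, tn = 0, fp = 5)
  expect_true(is.na(m3["NPV"]))
  expect_error(compute_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("AUC equals brute-force pair counting on random small cases", {
  expect_equal(compute_auc(c(3, 2, 1, 0), c(1, 1, -1, -1)), 1)
  expect_equal(compute_auc(rep(1, 10), rep(c(1, -1), 5)), 0.5)
  expect_equal(compute_auc(c(3, 1, 2, 0), c(1, 1, -1, -1)), 0.75)
  set.seed(60)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    labels <- c(1, -1, sample(c(1, -1), n - 2, TRUE))
    scores <- sample(seq(0, 3, 0.5), n, TRUE)   # coarse grid forces ties
    expect_equal(compute_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(compute_auc(1:4, rep(1, 4)), "both classes")
})

test_that("the KS test matches exact permutation enumeration for small samples", {
  res_same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res_same$statistic, 0)
  expect_equal(res_same$p_value, 1)
  res_disj <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res_disj$statistic, 1)
  set.seed(70)
  for (i in 1:15) {
    n <- sample(3:4, 1); m <- sample(3:4, 1)
    a <- round(runif(n, 0, 4), 1)
    b <- round(runif(m, 0, 4), 1)
    res <- ks_two_sample(a, b)
    expect_equal(res$statistic, oracle_ks_stat(a, b), tolerance = 1e-12)
    expect_equal(res$p_value, oracle_ks_perm_p(a, b), tolerance = 1e-9)
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("model comparison via KS separates shifted metric distributions", {
  set.seed(80)
  d1 <- structure(data.frame(ACC = rnorm(100, 0.70, 0.01)),
                  class = c("metric_distribution", "data.frame"))
  d2 <- structure(data.frame(ACC = rnorm(100, 0.80, 0.01)),
                  class = c("metric_distribution", "data.frame"))
  expect_lt(compare_models(d1, d2, "ACC"), 1e-10)
  expect_equal(compare_models(d1, d1, "ACC"), 1)
  expect_error(compare_models(d1, d2, "AUC"), "not available")
})

test_that("KS comparison of same-generator draws rejects at the nominal rate", {
  set.seed(90)
  n_reject <- 0
  for (i in 1:200) {
    a <- rnorm(25); b <- rnorm(25)      # exact small-sample branch
    if (ks_two_sample(a, b)$p_value < 0.05) n_reject <- n_reject + 1
  }
  expect_gte(n_reject / 200, 0.01)
  expect_lte(n_reject / 200, 0.09)
})

test_that("the DS threshold scan recovers the analytic decision boundary", {
  # margin = w * (ds - mu)/sigma + b crosses zero at ds = mu - b*sigma/w
  model <- hergsift:::new_lasso_svm(c(ds_st = 1), bias = 0,
                                    standardizer = score_standardizer(mu = -6, sigma = 1))
  thr <- ds_threshold(model, c(-10, -2), step = 0.01)
  expect_equal(thr, -6, tolerance = 0.005 / 6)
  model2 <- hergsift:::new_lasso_svm(c(ds_st = 1), bias = -0.5,
                                     standardizer = score_standardizer(mu = -6, sigma = 1))
  expect_equal(ds_threshold(model2, c(-10, -2), step = 0.01), -5.5,
               tolerance = 0.01)
  # no crossing inside the range -> NA with a warning
  expect_warning(out <- ds_threshold(model, c(-3, -2), step = 0.01), "no label change")
  expect_true(is.na(out))
  expect_error(ds_threshold(hergsift:::new_lasso_svm(c(a = 1, b = 2), 0),
                            c(-1, 1)), "single-feature")
})

test_that("threshold scan stays within one step of random analytic models", {
  set.seed(100)
  for (i in 1:30) {
    w <- sample(c(-1, 1), 1) * runif(1, 0.2, 3)
    b <- runif(1, -1, 1)
    mu <- runif(1, -9, -4); sigma <- runif(1, 0.5, 2)
    model <- hergsift:::new_lasso_svm(c(ds_st = w), bias = b,
                                      standardizer = score_standardizer(mu = mu, sigma = sigma))
    analytic <- mu - b * sigma / w
    thr <- suppressWarnings(ds_threshold(model, analytic + c(-3, 3), step = 0.01))
    expect_lte(abs(thr - analytic), 0.01)
  }
})

test_that("the resampling protocol is deterministic and leak-free", {
  d <- make_dataset(synthetic_spec(n_binders = 80, n_nonbinders = 80, seed = 7))
  proto <- resampling_protocol(n_repeats = 4, external_n_per_class = 20, seed = 7)
  r1 <- resample_evaluate(d$ds, d$labels, protocol = proto)
  r2 <- resample_evaluate(d$ds, d$labels, protocol = proto)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 4L)
  # balanced external sets make ACC the average of SE and SP
  expect_equal(r1$ACC, (r1$SE + r1$SP) / 2, tolerance = 1e-12)
  expect_error(
    resample_evaluate(d$ds[1:70], d$labels[1:70],
                      protocol = resampling_protocol(n_repeats = 2,
                                                     external_n_per_class = 30)),
    "at least")
})

test_that("a perfectly separating score yields mean ACC 1 with zero spread", {
  n <- 80
  ds <- c(runif(n, -10, -8), runif(n, -6, -4))
  names(ds) <- paste0("c", seq_len(2 * n))
  labels <- rep(c("binder", "nonbinder"), each = n)
  dist <- resample_evaluate(ds, labels,
                            protocol = resampling_protocol(n_repeats = 5,
                                                           external_n_per_class = 20,
                                                           seed = 3))
  expect_equal(mean(dist$ACC), 1)
  expect_equal(sd(dist$ACC), 0)
  # the recorded DS threshold falls in the separating gap
  expect_true(all(dist$threshold > -8 & dist$threshold < -6))
})

test_that("metric distributions print, summarise and persist", {
  d <- make_dataset(synthetic_spec(n_binders = 80, n_nonbinders = 80, seed = 8))
  dist <- resample_evaluate(d$ds, d$labels,
                            protocol = resampling_protocol(n_repeats = 3,
                                                           external_n_per_class = 15,
                                                           seed = 2))
  s <- summary(dist)
  expect_true(all(c("ACC", "AUC") %in% s$metric))
  expect_output(print(dist), "ACC\\s+\\d\\.\\d{2} ± \\d\\.\\d{2}")
  tf <- tempfile(fileext = ".csv")
  write_metrics(dist, tf)
  expect_equal(nrow(read.csv(tf)), 3L)
  expect_true(file.exists(paste0(tf, ".summary.json")))
})
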