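test_that("bias report: zero-bias limit, hand-computed case, rescale invariance", {
  eq <- matrix(100, nrow = 5, ncol = 3,
               dimnames = list(paste0("m", 1:5), NULL))
  br <- bias_report(eq)
  expect_true(all(br$fc == 1))
  expect_equal(br$pct_within, 100)

  m <- matrix(c(1, 10, 100, 10000), ncol = 1,
              dimnames = list(paste0("m", 1:4), NULL))
  br2 <- bias_report(m)
  expect_equal(unname(br2$fc), c(1, 10, 100, 10000) / 55, tolerance = 1e-12)
  expect_equal(br2$pct_within, 50)  # only 10/55 and 100/55 lie in [0.1, 10]
  expect_equal(stats::median(br2$fc), 1)

  br3 <- bias_report(m * 7.3)  # global rescale leaves FC untouched
  expect_equal(br3$pct_within, br2$pct_within)
  expect_equal(br3$fc, br2$fc)

  expect_error(bias_report(matrix(0, 2, 2)), "all-zero")
})

test_that("bias report recovers simulated ligation-bias factors", {
  refs <- simulate_mature_refs(300, seed = 61)
  cfg <- sim_config(n_mirnas = 300, depth = 1e6, equimolar = TRUE,
                    bias_log10_sd = 0.5, seed = 62)
  sim <- simulate_library(cfg, default_panel, refs)
  endo <- sim$truth[sim$truth$class == "mirna", ]
  rpm <- matrix(endo$count / sum(endo$count) * 1e6,
                dimnames = list(endo$feature, NULL))
  br <- bias_report(rpm)
  true_fc <- endo$bias / stats::median(endo$bias)
  pct_true <- 100 * mean(true_fc >= 0.1 & true_fc <= 10)
  expect_lt(abs(br$pct_within - pct_true), 2)
})

test_that("bias correlation matrix behaves on self, reciprocal and noisy pairs", {
  set.seed(5)
  fc <- stats::setNames(10^stats::rnorm(50, 0, 0.5), paste0("m", 1:50))
  cm <- bias_correlation(list(a = fc, b = fc))
  expect_equal(unname(cm["a", "b"]), 1)
  expect_equal(diag(cm), c(a = 1, b = 1))
  cm2 <- bias_correlation(list(a = fc, r = 1 / fc))
  expect_equal(unname(cm2["a", "r"]), -1)
  # matches a direct-formula Pearson on log10 values
  fc_noisy <- fc * 10^stats::rnorm(50, 0, 0.1)
  cm3 <- bias_correlation(list(a = fc, b = fc_noisy))
  expect_equal(unname(cm3["a", "b"]),
               oracle_pearson(log10(fc), log10(fc_noisy)))
  expect_gt(cm3["a", "b"], 0.9)
  expect_error(bias_correlation(list(a = fc[1:2], b = fc[1:2])),
               "fewer than 3")
  expect_error(bias_correlation(list(a = fc)), "two datasets")
})

test_that("inconsistency percentage counts single-replicate detections", {
  ident <- matrix(5, nrow = 4, ncol = 3)
  expect_equal(inconsistency_pct(ident), 0)
  m <- rbind(c(1, 0, 0), c(2, 3, 1), c(9, 9, 9))
  expect_equal(inconsistency_pct(m), 100 / 3, tolerance = 1e-12)
  each_once <- diag(3)
  expect_equal(inconsistency_pct(each_once), 100)
  # invariant under replicate permutation
  expect_equal(inconsistency_pct(m[, c(3, 1, 2)]), inconsistency_pct(m))
  expect_error(inconsistency_pct(matrix(0, 2, 2)), "no feature")
  expect_error(inconsistency_pct(matrix(1, 2, 1)), "two replicates")
})

test_that("CV report uses sample sd and a strict threshold", {
  ident <- matrix(4, nrow = 3, ncol = 3,
                  dimnames = list(paste0("m", 1:3), NULL))
  cr <- cv_report(ident)
  expect_true(all(cr$cv == 0))
  expect_equal(cr$frac_below, 1)

  m <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("m1", NULL))
  cr2 <- cv_report(m)
  expect_equal(unname(cr2$cv), 50)   # sd = 1, mean = 2
  expect_equal(cr2$frac_below, 0)    # CV = 50 is NOT below 50 (strict)

  # undetected-in-some-replicate features are excluded by default
  m3 <- rbind(a = c(1, 1, 1), b = c(0, 5, 5))
  cr3 <- cv_report(m3)
  expect_equal(cr3$n_used, 1L)
  expect_equal(cr3$n_excluded, 1L)
})

test_that("CV decreases with mean abundance on Poisson replicates", {
  set.seed(9)
  mu <- 10^seq(0.5, 4, length.out = 60)
  m <- t(vapply(mu, function(x) rpois(6, x), numeric(6)))
  rownames(m) <- paste0("m", seq_along(mu))
  cr <- cv_report(m)
  rc <- stats::cor(rowMeans(m[names(cr$cv), ]), cr$cv, method = "spearman")
  expect_lt(rc, 0)
})

test_that("measurement range counts detected features within the spike bounds", {
  m <- matrix(c(0.5, 5, 500), ncol = 1, dimnames = list(paste0("m", 1:3),
                                                        "s1"))
  mr <- measurement_range(m, spike_rpm_low = 1, spike_rpm_high = 100)
  expect_equal(unname(mr$pct_within), 100 / 3, tolerance = 1e-12)

  all_in <- matrix(c(2, 20, 60), ncol = 1)
  expect_equal(measurement_range(all_in, 1, 100)$mean_pct, 100)

  # undetected features (RPM 0) are outside the denominator
  with_zero <- matrix(c(0, 5, 50), ncol = 1)
  expect_equal(measurement_range(with_zero, 1, 100)$mean_pct, 100)

  expect_error(measurement_range(m, 100, 1), "inverted")
  expect_error(measurement_range(m, 0, 100), "undetected")

  # per-sample bounds, order of samples irrelevant
  m2 <- cbind(s1 = c(0.5, 5, 500), s2 = c(0.5, 5, 500))
  mr2 <- measurement_range(m2, c(1, 0.1), c(100, 1000))
  expect_equal(unname(mr2$pct_within), c(100 / 3, 100))
  mr2r <- measurement_range(m2[, 2:1], c(0.1, 1), c(1000, 100))
  expect_equal(unname(sort(mr2r$pct_within)), unname(sort(mr2$pct_within)))
})

test_that("Fisher transform is odd, monotone, and matches closed forms", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)) && fisher_z(1) > 13)
})

test_that("accuracy report: perfect observation, scale consistency, exclusions", {
  feats <- paste0("m", 1:5)
  pureA <- stats::setNames(c(10, 20, 5, 8, 100), feats)
  pureB <- stats::setNames(c(1, 2, 0.5, 4, 10), feats)
  fr <- c(1 / 2, 1 / 6, 1 / 11)
  expected <- outer(pureA, fr) + outer(pureB, 1 - fr)
  ar <- accuracy_report(expected, pureA, pureB, fr)
  expect_true(all(ar$recovery_pct == 100))
  expect_equal(unname(ar$r), rep(1, 5))
  expect_true(all(ar$z > 13))         # capped-large
  expect_equal(ar$n_recovery_in_range, 5L)

  # multiplying observed and both pools by c leaves recovery unchanged
  ar2 <- accuracy_report(3 * expected, 3 * pureA, 3 * pureB, fr)
  expect_equal(ar2$recovery_pct, ar$recovery_pct)

  # a feature with zero expectation is excluded, not propagated
  pureB0 <- pureB; pureA0 <- pureA
  pureA0["m3"] <- 0; pureB0["m3"] <- 0
  exp0 <- outer(pureA0, fr) + outer(pureB0, 1 - fr)
  ar3 <- accuracy_report(exp0, pureA0, pureB0, fr)
  expect_equal(ar3$excluded, "m3")
  expect_equal(ar3$n_features, 4L)

  expect_error(accuracy_report(expected[, 1, drop = FALSE], pureA, pureB,
                               0.5), "two fractions")
})

test_that("subsampling preserves totals and expected proportions", {
  counts <- stats::setNames(c(5000L, 3000L, 1500L, 400L, 90L, 10L),
                            paste0("m", 1:6))
  ss <- subsample_counts(counts, target_depth = 2000, n_reps = 40,
                         seed = 13)
  expect_true(all(colSums(ss$counts) == 2000L))
  # hypergeometric mean: count * target / total
  expect_equal(rowMeans(ss$counts), counts * 2000 / sum(counts),
               tolerance = 0.08)
  # identity at full depth
  full <- subsample_counts(counts, sum(counts), n_reps = 2, seed = 1)
  expect_true(all(full$counts == counts))
  expect_true(all(full$detected == sum(counts >= 1)))
  expect_error(subsample_counts(counts, sum(counts) + 1), "exceeds")
})

test_that("subsampled detection matches the read-shuffling oracle in distribution", {
  set.seed(2)
  counts <- stats::setNames(as.integer(round(10^runif(80, 0, 2.3))),
                            paste0("m", 1:80))
  total <- sum(counts)
  target <- round(total / 10)
  ss <- subsample_counts(counts, target, n_reps = 200, seed = 3)
  set.seed(4)
  oracle <- replicate(200, oracle_subsample_detected(counts, target))
  ks <- suppressWarnings(stats::ks.test(ss$detected, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("detection curves are non-decreasing in depth in nested mode", {
  set.seed(8)
  counts <- stats::setNames(as.integer(round(10^runif(60, 0, 2))),
                            paste0("m", 1:60))
  depths <- round(sum(counts) * c(0.05, 0.1, 0.25, 0.5, 1))
  dc <- detection_curve(counts, depths, n_reps = 4, seed = 6, nested = TRUE)
  expect_true(all(apply(dc$detected, 2, function(col) all(diff(col) >= 0))))
  dc2 <- detection_curve(counts, depths, n_reps = 4, seed = 6)
  expect_equal(dim(dc2$detected), c(5L, 4L))
  expect_error(detection_curve(counts, sum(counts) * 2), "exceed")
})
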