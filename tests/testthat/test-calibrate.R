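test_that("exact linear counts give the exact slope and perfect log correlation", {
  panel <- mind_panel()
  counts <- stats::setNames(1000 * panel$amount_amol, panel$label)
  fit <- fit_calibration(counts, panel)
  expect_equal(fit$beta, 1000)
  expect_equal(fit$r_log, 1)
  expect_equal(unname(coef(fit)), 1000)
  expect_equal(unname(residuals(fit)), rep(0, 7))
  expect_equal(unname(fitted(fit)), unname(counts))
  expect_equal(unname(predict(fit, 2)), 2000)
})

test_that("the closed-form slope matches a grid minimiser on noisy data", {
  panel <- mind_panel()
  set.seed(1)
  for (i in 1:25) {
    beta <- runif(1, 100, 5000)
    rc <- rpois(7, beta * panel$amount_amol)
    fit <- fit_calibration(stats::setNames(rc, panel$label), panel)
    grid <- oracle_grid_beta(panel$amount_amol, rc)
    expect_equal(fit$beta, grid, tolerance = 1e-3)
  }
})

test_that("calibration requires at least two detected oligos", {
  panel <- mind_panel()
  counts <- stats::setNames(rep(0, 7), panel$label)
  expect_error(fit_calibration(counts, panel), "fewer than two")
  counts["I"] <- 50000
  expect_error(fit_calibration(counts, panel), "fewer than two")
  counts["K"] <- 10000
  expect_s3_class(fit_calibration(counts, panel), "mind_calibration")
})

test_that("slope is scale-equivariant and amol estimates are scale-consistent", {
  panel <- mind_panel()
  set.seed(3)
  rc <- rpois(7, 800 * panel$amount_amol)
  f1 <- fit_calibration(stats::setNames(rc, panel$label), panel)
  f2 <- fit_calibration(stats::setNames(3 * rc, panel$label), panel)
  expect_equal(f2$beta, 3 * f1$beta)
  # scaling spike and endogenous counts together leaves amol unchanged
  m1 <- matrix(c(rc, 120L), ncol = 1,
               dimnames = list(c(panel$label, "mirX"), "s"))
  m2 <- m1 * 3
  a1 <- to_amol(m1, list(s = f1), panel)
  a2 <- to_amol(m2, list(s = f2), panel)
  expect_equal(a1, a2)
})

test_that("counts convert to amol through the fitted slope", {
  panel <- mind_panel()
  counts <- stats::setNames(1000 * panel$amount_amol, panel$label)
  fit <- fit_calibration(counts, panel)
  m <- matrix(c(counts, 1000, 0), ncol = 1,
              dimnames = list(c(panel$label, "mir1", "mir2"), "s1"))
  amol <- to_amol(m, list(s1 = fit), panel)
  expect_equal(unname(amol["mir1", 1]), 1)   # RC = beta -> 1 amol
  expect_equal(unname(amol["mir2", 1]), 0)   # RC = 0 -> 0 amol
  # spike rows recover the panel amounts
  expect_equal(unname(amol[panel$label, 1]), panel$amount_amol)
  expect_error(to_amol(m, list(other = fit), panel), "missing calibration")
})

test_that("RPM normalisation follows its identity and exclusion rules", {
  panel <- mind_panel()
  m <- matrix(c(rep(1L, 7), 10L, 90L, 5L), ncol = 1,
              dimnames = list(c(panel$label, "mir1", "mir2", "unmapped"),
                              "s1"))
  rpm <- rpm_normalize(m, panel)
  # {10, 90} of 100 miRNA-mapped reads
  expect_equal(unname(rpm["mir1", 1]), 1e5)
  expect_equal(unname(rpm["mir2", 1]), 9e5)
  mirna_rows <- c("mir1", "mir2")
  expect_equal(sum(rpm[mirna_rows, 1]), 1e6)
  expect_false("unmapped" %in% rownames(rpm))
  # single endogenous feature holding all mapped reads
  m2 <- matrix(c(rep(1L, 7), 42L), ncol = 1,
               dimnames = list(c(panel$label, "only"), "s"))
  expect_equal(unname(rpm_normalize(m2, panel)["only", 1]), 1e6)
  # all-surviving denominator includes spike and unmapped reads
  rpm_all <- rpm_normalize(m, panel, denominator = "all_surviving")
  expect_equal(sum(rpm_all[c(panel$label, mirna_rows), 1]),
               1e6 * 107 / 112)
  m3 <- m; m3[c("mir1", "mir2"), 1] <- 0L
  expect_error(rpm_normalize(m3, panel), "zero denominator.*s1")
})

test_that("molecule conversions apply Avogadro and the volume chain", {
  m <- matrix(c(1, 0), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  vol <- sample_volumes(rna_input_ul = 1, elution_ul = 30,
                        biofluid_ul = 200)
  rna <- to_molecules_per_ul(m, vol, target = "rna")
  expect_equal(unname(rna["a", 1]), 602214.076)
  expect_equal(unname(rna["b", 1]), 0)

  vol2 <- sample_volumes(8.5, 30, 200)
  bio <- to_molecules_per_ul(m, vol2, target = "biofluid")
  expect_equal(unname(bio["a", 1]), 602214.076 / 8.5 * 30 / 200)

  # round trip back to amol
  back <- bio["a", 1] * 200 / 30 * 8.5 / AVOGADRO / 1e-18
  expect_equal(unname(back), 1)

  expect_error(sample_volumes(0, 30, 200), "positive")
  expect_error(sample_volumes(40, 30, 200), "exceed")
})

test_that("parameter recovery: fitted slope tracks the true capture slope", {
  refs <- simulate_mature_refs(60, seed = 55)
  rel_err <- vapply(1:8, function(i) {
    cfg <- sim_config(n_mirnas = 60, depth = 2e5, seed = 400 + i)
    sim <- simulate_library(cfg, default_panel, refs)
    counts <- stats::setNames(sim$truth$count, sim$truth$feature)
    fit <- fit_calibration(counts[default_panel$label], default_panel)
    abs(fit$beta - sim$capture_beta) / sim$capture_beta
  }, numeric(1))
  expect_lt(max(rel_err), 0.05)
})

test_that("model methods: summary table, simulate, per-sample calibration", {
  panel <- mind_panel()
  counts <- stats::setNames(round(500 * panel$amount_amol) + 1, panel$label)
  fit <- fit_calibration(counts, panel)
  s <- summary(fit)
  expect_s3_class(s, "summary.mind_calibration")
  expect_equal(s$table$est_amol, unname(counts / fit$beta))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(7L, 3L))
  expect_identical(simulate(fit, 3, seed = 1), simulate(fit, 3, seed = 1))

  m <- matrix(rep(counts, 2), ncol = 2,
              dimnames = list(panel$label, c("s1", "s2")))
  fits <- calibrate_samples(m, panel)
  expect_named(fits, c("s1", "s2"))
  expect_equal(fits$s1$beta, fits$s2$beta)
})
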