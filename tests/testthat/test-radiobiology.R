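test_that("surviving fractions are plating-efficiency normalized", {
  d <- data.frame(radiation_type = "photon",
                  dose_gy = c(0, 5), colonies = c(100, 25),
                  seeded = c(200, 200), replicate = 1)
  out <- surviving_fraction(d)
  expect_equal(out$surviving_fraction, c(1, 0.25))

  d0 <- data.frame(radiation_type = "photon", dose_gy = c(0, 2),
                   colonies = c(0, 5), seeded = c(100, 100), replicate = 1)
  expect_error(surviving_fraction(d0), "plating efficiency")
  d1 <- data.frame(radiation_type = "photon", dose_gy = c(2, 4),
                   colonies = c(10, 5), seeded = c(100, 100), replicate = 1)
  expect_error(surviving_fraction(d1), "dose-0")
})

test_that("noiseless curves are recovered to machine precision", {
  d <- simulate_survival_data(0.2, 0.02, lognormal_sd = 0, seed = 1)
  f <- fit_lq(d$dose_gy, d$surviving_fraction)
  expect_equal(f$alpha, 0.2, tolerance = 1e-9)
  expect_equal(f$beta, 0.02, tolerance = 1e-9)
  expect_false(f$constrained)
  # the fitted curve reaches exactly 10% survival at D10
  expect_equal(predict(f, f$D10), 0.10, tolerance = 1e-9)
})

test_that("the pure linear case gives D10 = ln(10)/alpha", {
  alpha <- log(10) / 10
  doses <- c(0, 4, 8, 12)
  f <- fit_lq(doses, exp(-alpha * doses))
  expect_equal(f$D10, 10, tolerance = 1e-9)
})

test_that("fits are invariant to dose and replicate ordering", {
  d <- simulate_survival_data(0.25, 0.015, lognormal_sd = 0.1,
                              n_replicates = 3, seed = 2)
  f1 <- fit_lq(d$dose_gy, d$surviving_fraction)
  perm <- sample(nrow(d))
  f2 <- fit_lq(d$dose_gy[perm], d$surviving_fraction[perm])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("non-identifiable and constraint-violating inputs are flagged", {
  expect_error(fit_lq(c(2, 2, 2), c(0.5, 0.4, 0.45)), "distinct doses")
  # survival increasing with dose pushes the unconstrained fit negative
  doses <- c(0, 2, 4, 6)
  expect_warning(f <- fit_lq(doses, c(1, 1.2, 1.5, 1.9)), "constraint")
  expect_true(f$constrained)
  expect_gte(f$alpha, 0)
  expect_gte(f$beta, 0)
})

test_that("model-object methods are mutually consistent", {
  d <- simulate_survival_data(0.3, 0.02, lognormal_sd = 0.05,
                              n_replicates = 2, seed = 3)
  f <- fit_lq(d$dose_gy, d$surviving_fraction)
  expect_named(coef(f), c("alpha", "beta"))
  expect_equal(predict(f, 0), 1)
  expect_equal(length(residuals(f)), nrow(d))
  expect_equal(dim(vcov(f)), c(2, 2))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 3))
  expect_output(print(f), "alpha")
})

test_that("RBE is the iso-survival dose ratio with its symmetries", {
  d <- simulate_survival_data(0.2, 0.02, lognormal_sd = 0, seed = 1)
  f <- fit_lq(d$dose_gy, d$surviving_fraction)
  expect_equal(compute_rbe(f, f)$rbe, 1.0)

  # D10 6 Gy vs 2.4 Gy -> RBE 2.5
  a_ref <- log(10) / 6
  a_test <- log(10) / 2.4
  doses <- c(0, 2, 4, 6)
  f_ref <- fit_lq(doses, exp(-a_ref * doses))
  f_test <- fit_lq(doses, exp(-a_test * doses))
  r <- compute_rbe(f_ref, f_test)
  expect_equal(r$rbe, 2.5, tolerance = 1e-9)
  expect_equal(r$rbe * compute_rbe(f_test, f_ref)$rbe, 1, tolerance = 1e-9)

  expect_error(compute_rbe(f_ref, f_test, s = 1.2), "in \\(0, 1\\)")
})

test_that("fit confidence intervals have near-nominal coverage", {
  alpha <- 0.25
  beta <- 0.02
  covered <- vapply(1:50, function(s) {
    d <- simulate_survival_data(alpha, beta, lognormal_sd = 0.1,
                                n_replicates = 3, seed = 100 + s)
    f <- fit_lq(d$dose_gy, d$surviving_fraction)
    if (f$constrained) return(NA)
    se <- sqrt(vcov(f)["alpha", "alpha"])
    abs(f$alpha - alpha) <= qt(0.975, nrow(d) - 2) * se
  }, logical(1))
  cov_rate <- mean(covered, na.rm = TRUE)
  expect_gte(cov_rate, 0.88)
  expect_lte(cov_rate, 0.99)
})

test_that("SASP score is the mean fold change over the factor list", {
  null_panel <- simulate_cytokine_panel(rep(1, 10), replicate_sd = 0, seed = 1)
  expect_equal(sasp_score(null_panel)$score, 1)

  set.seed(4)
  folds <- exp(rnorm(10, sd = 0.4))
  panel <- data.frame(analyte = sasp_factors(), replicate = 1,
                      fold_change = folds)
  expect_equal(sasp_score(panel)$score, mean(folds), tolerance = 1e-12)

  # a partial panel still scores, with a message naming the missing factors
  part <- panel[1:4, ]
  expect_message(s <- sasp_score(part), "missing")
  expect_equal(s$score, mean(folds[1:4]), tolerance = 1e-12)
  none <- data.frame(analyte = "GMCSF", replicate = 1, fold_change = 2)
  expect_error(sasp_score(none), "none of")
})

test_that("migration index normalizes beads and divides by control", {
  counts <- data.frame(
    sample = rep(c("ctrl", "rt"), each = 2),
    subset = rep(c("CD4 T", "CD8 T"), 2),
    count = c(100, 80, 150, 80),
    beads = 5000,
    is_control = rep(c(TRUE, FALSE), each = 2)
  )
  idx <- migration_index(counts)
  expect_equal(idx$migration_index[idx$subset == "CD4 T"], 1.5)
  expect_equal(idx$migration_index[idx$subset == "CD8 T"], 1.0)

  # doubling every bead count changes nothing
  counts2 <- counts
  counts2$beads <- counts2$beads * 2
  expect_equal(migration_index(counts2)$migration_index, idx$migration_index)

  # unequal bead acquisition is corrected before the ratio
  counts3 <- counts
  counts3$beads <- c(5000, 5000, 2500, 2500)
  counts3$count <- c(100, 80, 75, 40)
  idx3 <- migration_index(counts3)
  expect_equal(idx3$migration_index[idx3$subset == "CD4 T"], 1.5)

  # zero control count: undefined, reported missing
  counts4 <- counts
  counts4$count[1] <- 0
  expect_message(idx4 <- migration_index(counts4), "undefined")
  expect_true(is.na(idx4$migration_index[idx4$subset == "CD4 T"]))

  expect_error(migration_index(transform(counts, is_control = FALSE)),
               "control")
})
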