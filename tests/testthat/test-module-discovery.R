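toy_sce <- function(m, patient = "P1") {
  annotated_expression(m, patient = patient)
}

test_that("Spearman panel is exact on rank structure", {
  set.seed(1)
  base <- abs(rnorm(30))
  m <- cbind(a = base, b = base,            # duplicated column
             c = exp(base),                 # strictly monotone transform
             d = abs(rnorm(30)))
  x <- toy_sce(m)
  r <- spearman_panel(x, c("a", "b", "c", "d"))
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), 1)
  expect_lt(abs(r["a", "d"]), 1)
})

test_that("five-cell toy matrix matches rank-then-Pearson to 1e-12", {
  m <- cbind(g1 = c(1.2, 0.3, 2.2, 0.0, 5.1),
             g2 = c(0.4, 0.4, 1.9, 2.2, 0.1),
             g3 = c(3.0, 1.0, 0.0, 0.7, 2.5))
  x <- toy_sce(m)
  r <- spearman_panel(x, c("g1", "g2", "g3"))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(unname(r[i, j]),
                   spearman_bruteforce(m[, i], m[, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("missing panel genes and degenerate populations error cleanly", {
  m <- cbind(g1 = abs(rnorm(10)), g2 = abs(rnorm(10)))
  x <- toy_sce(m)
  expect_error(spearman_panel(x, c("g1", "nope")), "nope")
  expect_error(spearman_panel(x, "g1", population = rep(FALSE, 10)),
               "fewer than")
})

test_that("zero-variance genes are flagged and excluded from modules", {
  set.seed(2)
  base <- abs(rnorm(40))
  m <- cbind(g1 = base + abs(rnorm(40, sd = 0.1)),
             g2 = base + abs(rnorm(40, sd = 0.1)),
             flat = rep(2, 40))
  x <- toy_sce(m)
  r <- spearman_panel(x, c("g1", "g2", "flat"))
  expect_equal(attr(r, "zero_variance"), "flat")
  expect_equal(unname(r["flat", "g1"]), 0)
  ms <- extract_modules(r, linkage_distance = 1.0, min_mean_r = 0.15)
  expect_true("flat" %in% ms$unassigned)
})

test_that("ideal block-diagonal correlation yields exactly the blocks", {
  r <- block_corr(c(4, 3), r_within = 1, r_between = 0)
  ms <- extract_modules(r, linkage_distance = 1.0)
  expect_length(ms$modules, 2)
  sizes <- sort(lengths(ms$modules))
  expect_equal(unname(sizes), c(3, 4))

  # null case: no correlation anywhere
  r0 <- block_corr(c(4, 3), r_within = 0, r_between = 0)
  ms0 <- suppressMessages(extract_modules(r0, linkage_distance = 3))
  expect_length(ms0$modules, 0)
  expect_length(ms0$unassigned, 7)
})

test_that("planted modules are recovered from simulated expression", {
  mods <- planted_modules()
  for (s in 1:3) {
    x <- simulate_modular_expression(mods, n_background = 40, loading = 0.8,
                                     n_patients = 20, n_cells_per_patient = 100,
                                     seed = s)
    corr <- spearman_panel(x, rownames(x))
    ms <- extract_modules(corr, linkage_distance = 1.65)
    expect_gte(module_recovery_ari(ms, true_modules(x)), 0.9)
  }
})

test_that("module extraction is invariant to gene input order", {
  mods <- planted_modules(3, 4)
  x <- simulate_modular_expression(mods, n_background = 10, seed = 5,
                                   n_patients = 5, n_cells_per_patient = 100)
  panel <- rownames(x)
  ms1 <- extract_modules(spearman_panel(x, panel), 1.65)
  set.seed(1)
  ms2 <- extract_modules(spearman_panel(x, sample(panel)), 1.65)
  df1 <- as.data.frame(ms1)
  df2 <- as.data.frame(ms2)
  expect_equal(adjusted_rand_index(df1$module[order(df1$gene)],
                                   df2$module[order(df2$gene)]), 1)
})

test_that("every emitted module satisfies the mean-correlation criterion", {
  mods <- planted_modules(4, 5)
  for (s in 1:3) {
    x <- simulate_modular_expression(mods, n_background = 30, loading = 0.6,
                                     n_patients = 8, n_cells_per_patient = 60,
                                     seed = s)
    corr <- spearman_panel(x, rownames(x))
    ms <- suppressMessages(extract_modules(corr, 1.65, min_mean_r = 0.15))
    for (nm in names(ms$modules)) {
      g <- ms$modules[[nm]]
      sub <- corr[g, g]
      expect_gt(mean(sub[upper.tri(sub)]), 0.15)
    }
  }
})

test_that("raising the module criterion never adds modules", {
  mods <- planted_modules(4, 5)
  x <- simulate_modular_expression(mods, n_background = 20, loading = 0.7,
                                   n_patients = 6, n_cells_per_patient = 80,
                                   seed = 11)
  corr <- spearman_panel(x, rownames(x))
  thresholds <- c(0.05, 0.15, 0.3, 0.5, 0.9)
  counts <- vapply(thresholds, function(t) {
    length(suppressMessages(extract_modules(corr, 1.65, min_mean_r = t))$modules)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("flat clustering matches the Lance-Williams brute-force oracle", {
  set.seed(12)
  for (rep in 1:5) {
    n_genes <- sample(6:12, 1)
    m <- matrix(abs(rnorm(40 * n_genes)), 40, n_genes)
    colnames(m) <- paste0("g", seq_len(n_genes))
    r <- spearman_panel(toy_sce(m), colnames(m))
    prof <- unclass(r)
    d <- as.matrix(dist(prof))
    for (h in c(0.5, 1.0, 1.5)) {
      oracle <- average_linkage_flat_bruteforce(d, h)
      hc <- cutree(hclust(dist(prof), method = "average"), h = h)
      expect_equal(adjusted_rand_index(oracle, hc), 1)
    }
  }
})

test_that("patient-invariant structure is fully stable to leave-one-out", {
  mods <- planted_modules(3, 5)
  x <- simulate_modular_expression(mods, n_background = 10, loading = 0.9,
                                   n_patients = 10, n_cells_per_patient = 150,
                                   seed = 4)
  st <- leave_one_out_stability(x, rownames(x), linkage_distance = 1.65)
  expect_equal(attr(st, "n_iterations"), 10)
  expect_true(all(st >= 0 & st <= 1))
  expect_equal(st, t(st))
  tm <- true_modules(x)
  for (m in names(mods)) {
    g <- names(tm)[tm == m]
    other <- names(tm)[tm != m]
    expect_true(all(st[g, g] == 1))
    expect_true(all(st[g, other] == 0))
  }
})

test_that("a single-patient-driven module loses one leave-one-out iteration", {
  set.seed(13)
  n_pat <- 6
  cells_per <- 80
  n <- n_pat * cells_per
  patient <- rep(paste0("P", seq_len(n_pat)), each = cells_per)
  # module genes share a strong factor only in patient P1's cells
  f <- rnorm(n)
  active <- patient == "P1"
  m <- sapply(1:4, function(i) {
    v <- rnorm(n, sd = 0.3)
    v[active] <- v[active] + 3 * f[active] + 3
    v
  })
  colnames(m) <- paste0("mg", 1:4)
  m <- cbind(m, sapply(1:6, function(i) rnorm(n)))
  colnames(m)[5:10] <- paste0("bg", 1:6)
  m <- m - min(m)
  x <- annotated_expression(m, patient = patient)

  # the module is found whenever P1 is in the data; the cut height is
  # scaled to the 10-gene panel (profile distances grow with panel size)
  full <- extract_modules(spearman_panel(x, colnames(m)), 1.2)
  expect_true(any(vapply(full$modules, function(g)
    all(paste0("mg", 1:4) %in% g), logical(1))))

  st <- leave_one_out_stability(x, colnames(m), linkage_distance = 1.2)
  within <- st[paste0("mg", 1:4), paste0("mg", 1:4)]
  expect_equal(unique(within[upper.tri(within)]), (n_pat - 1) / n_pat)
})

test_that("module scores reduce to per-patient gene means", {
  set.seed(14)
  patient <- rep(c("P1", "P2", "P3"), each = 20)
  m <- cbind(g1 = abs(rnorm(60)), g2 = abs(rnorm(60)))
  x <- annotated_expression(m, patient = patient)
  sc <- score_modules_per_patient(x, list(solo = "g1"))
  for (p in c("P1", "P2", "P3")) {
    expect_equal(sc[p, "solo"], mean(m[patient == p, "g1"]))
  }
  # all-zero expression scores 0 and is never called expressed
  x0 <- annotated_expression(matrix(0, 30, 2,
                                    dimnames = list(NULL, c("a", "b"))),
                             patient = rep(c("P1", "P2"), 15))
  sc0 <- score_modules_per_patient(x0, list(m = c("a", "b")))
  expect_true(all(sc0 == 0))
  calls0 <- module_expression_calls(x0, list(m = c("a", "b")),
                                    expression_threshold = 0.01)
  expect_true(all(!calls0))
})

test_that("patients carrying the planted factor are the ones flagged", {
  mod <- list(module1 = sprintf("G%d", 1:6))
  active <- paste0("P", 1:18)
  x <- simulate_modular_expression(mod, n_background = 20, loading = 0.8,
                                   n_patients = 21, n_cells_per_patient = 60,
                                   module_active = list(module1 = active),
                                   activity_shift = 1.5, seed = 2)
  calls <- module_expression_calls(x, mod, expression_threshold = 3.2)
  expect_equal(sum(calls[, "module1"]), 18)
  expect_setequal(rownames(calls)[calls[, "module1"]], active)
})

test_that("module-infiltration correlation handles monotone and inverse data", {
  patients <- paste0("P", 1:21)
  sc <- matrix(1:21, 21, 1, dimnames = list(patients, "module1"))
  infil <- matrix(exp(seq(0.1, 2.1, by = 0.1)), 21, 1,
                  dimnames = list(patients, "Tcell"))
  res <- correlate_modules_with_infiltration(sc, infil)
  expect_equal(res$rho, 1)

  infil_rev <- matrix(rev(infil), 21, 1,
                      dimnames = list(patients, "Tcell"))
  res_rev <- correlate_modules_with_infiltration(sc, infil_rev)
  expect_equal(res_rev$rho, -1)

  # constant infiltration: undefined, reported missing
  infil_c <- matrix(5, 21, 1, dimnames = list(patients, "Tcell"))
  res_c <- correlate_modules_with_infiltration(sc, infil_c)
  expect_true(is.na(res_c$rho))
})

test_that("small-sample p values match the exhaustive permutation oracle", {
  set.seed(15)
  for (rep in 1:3) {
    xv <- rnorm(6)
    yv <- rnorm(6)
    st <- spearman_test(xv, yv)
    expect_equal(st$method, "exact permutation")
    expect_equal(st$p, spearman_exact_p_bruteforce(xv, yv), tolerance = 1e-12)
  }
})
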