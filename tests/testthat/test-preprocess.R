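make_matrix <- function(m) {
  colnames(m) <- paste0("g", seq_len(ncol(m)))
  m
}

test_that("gene detection filter applies its threshold at the boundary", {
  m <- matrix(0, nrow = 20, ncol = 3)
  m[1:9, 1] <- 1   # detected in 9 cells: removed at min_cells = 10
  m[1:10, 2] <- 1  # detected in exactly 10: retained
  m[, 3] <- 1      # everywhere
  m <- make_matrix(m)
  x <- annotated_expression(m, patient = "P1")
  out <- suppressMessages(filter_genes_min_cells(x, min_cells = 10))
  expect_setequal(rownames(out), c("g2", "g3"))
  expect_equal(attr(out, "removed_genes"), 1)
  expect_error(suppressMessages(filter_genes_min_cells(x, min_cells = 21)),
               "no genes")
})

test_that("dispersion ranking puts dominant-variance genes first", {
  set.seed(1)
  m <- matrix(rnorm(400 * 200, mean = 5), 400, 200)
  m[, 17] <- rnorm(400, mean = 5, sd = sqrt(10)) # 10x the variance, same mean
  m <- make_matrix(abs(m))
  hv <- select_highly_variable(m, 5)
  expect_equal(hv[1], "g17")
})

test_that("constant genes are never selected before varying genes", {
  set.seed(2)
  m <- matrix(5, nrow = 100, ncol = 10)
  m[, 1:4] <- abs(matrix(rnorm(400, mean = 5), 100, 4))
  m <- make_matrix(m)
  hv <- suppressWarnings(select_highly_variable(m, 4))
  expect_setequal(hv, c("g1", "g2", "g3", "g4"))
})

test_that("planted module genes carry selectable extra variance", {
  mods <- planted_modules()
  hits <- vapply(1:5, function(s) {
    x <- simulate_modular_expression(mods, n_background = 570, loading = 0.8,
                                     noise_sd = 0.6, n_patients = 10,
                                     n_cells_per_patient = 80, seed = s)
    sum(select_highly_variable(x, 30) %in% unlist(mods))
  }, numeric(1))
  expect_true(all(hits >= 25))
})

test_that("PC count rule floors at min_pcs on low-rank data", {
  set.seed(1)
  v <- rnorm(200)
  m <- make_matrix(outer(v, rnorm(60)))
  m <- m - min(m)
  p <- choose_pcs(m, min_pcs = 50, max_pcs = 100)
  expect_equal(p$chosen_pcs, 50)
  expect_gt(p$explained, 0.999)
})

test_that("PC decision matches a direct eigendecomposition oracle", {
  set.seed(3)
  m <- make_matrix(matrix(rnorm(120 * 40), 120, 40))
  p <- choose_pcs(m, variance_target = 0.25, min_pcs = 5, max_pcs = 20)
  ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  ratio <- ev / sum(ev)
  n_target <- which(cumsum(ratio) >= 0.25)[1]
  chosen_oracle <- min(max(n_target, 5), 20)
  expect_equal(p$chosen_pcs, chosen_oracle)
  expect_equal(p$explained, sum(ratio[seq_len(chosen_oracle)]),
               tolerance = 1e-10)
})

test_that("PC scores are mutually orthogonal", {
  set.seed(4)
  m <- make_matrix(matrix(rnorm(150 * 30), 150, 30))
  p <- choose_pcs(m, min_pcs = 10, max_pcs = 20)
  gram <- crossprod(p$scores)
  off <- max(abs(gram[upper.tri(gram)]))
  expect_lt(off, 1e-8 * max(diag(gram)))
})

test_that("fewer cells than min_pcs caps the PC count with a warning", {
  set.seed(5)
  m <- make_matrix(matrix(rnorm(30 * 80), 30, 80))
  expect_warning(p <- choose_pcs(m, min_pcs = 50), "capping")
  expect_lte(p$chosen_pcs, 29)
})

test_that("kNN community detection separates well-separated blobs", {
  set.seed(3)
  blobs <- rbind(matrix(rnorm(150, 0), 75, 2), matrix(rnorm(150, 6), 75, 2))
  cl <- knn_cluster(blobs, k = 15)
  expect_equal(length(unique(cl)), 2)
  expect_equal(adjusted_rand_index(cl, rep(1:2, each = 75)), 1)

  one <- matrix(rnorm(300), 150, 2)
  cl1 <- knn_cluster(one, k = 15, resolution = 0.02) # coarse setting
  expect_equal(length(unique(cl1)), 1)

  expect_error(knn_cluster(blobs, k = 0), "positive")
  expect_error(knn_cluster(blobs, k = 150), "smaller")
})

test_that("planted blob partitions are seed-invariant up to relabeling", {
  set.seed(7)
  pts <- do.call(rbind, lapply(c(0, 7, 14), function(mu)
    matrix(rnorm(120, mu), 60, 2)))
  parts <- lapply(1:10, function(s) knn_cluster(pts, k = 15, seed = s))
  for (i in 2:10) {
    expect_equal(rand_index(parts[[1]], parts[[i]]), 1)
  }
})

test_that("Rand index agrees with brute-force pair counting", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(rand_index(a, b), rand_index_bruteforce(a, b),
                 tolerance = 1e-12)
  }
  # partitions differing by a single relocated point, vs brute force
  a <- rep(1:2, each = 50)
  b <- a
  b[1] <- 2
  expect_equal(rand_index(a, b), rand_index_bruteforce(a, b), tolerance = 1e-12)
})

test_that("Rand index is symmetric, bounded, and 1 iff identical", {
  set.seed(9)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  expect_equal(rand_index(a, b), rand_index(b, a))
  expect_gte(rand_index(a, b), 0)
  expect_lte(rand_index(a, b), 1)
  relabeled <- c(9, 7, 8)[a]
  expect_equal(rand_index(a, relabeled), 1)
  expect_lt(rand_index(a, b), 1)
})

test_that("stability selection picks the smallest stable neighborhood size", {
  ident <- rep(1:3, 40)
  parts <- list(`10` = ident, `20` = ident, `30` = ident)
  st <- clustering_stability(parts)
  expect_true(all(st$rand == 1))
  expect_equal(st$selected_k, 10)

  # k = 20 stable against 30 and 40; k = 10 unstable
  set.seed(10)
  stable <- rep(1:2, 60)
  parts2 <- list(`10` = sample(1:6, 120, replace = TRUE),
                 `20` = stable, `30` = stable, `40` = stable)
  st2 <- clustering_stability(parts2, threshold = 0.8)
  expect_equal(st2$selected_k, 20)

  # nothing stable: NA plus the full matrix
  set.seed(11)
  parts3 <- list(`10` = sample(1:5, 80, replace = TRUE),
                 `20` = sample(1:5, 80, replace = TRUE),
                 `30` = sample(1:5, 80, replace = TRUE))
  st3 <- clustering_stability(parts3, threshold = 0.99)
  expect_true(is.na(st3$selected_k))
  expect_equal(dim(st3$rand), c(3, 3))
})
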