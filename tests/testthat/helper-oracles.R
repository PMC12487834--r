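# Independent brute-force oracles used to check the package's implementations.

# Rand index by explicit enumeration of all item pairs
rand_index_bruteforce <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / choose(n, 2)
}

# Spearman correlation as rank-then-Pearson, written independently of cor()
spearman_bruteforce <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Naive average-linkage agglomeration: inter-cluster distance is always
# recomputed as the mean of all pairwise point distances (the quantity the
# Lance-Williams average-linkage recurrence maintains). Returns the flat
# clustering obtained by merging while the closest pair is within height h.
average_linkage_flat_bruteforce <- function(dmat, h) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dd <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
  labels
}

# exact two-sided permutation p for a Spearman correlation, by full
# enumeration of permutations of y (n small)
spearman_exact_p_bruteforce <- function(x, y) {
  n <- length(x)
  perm_rec <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs <- spearman_bruteforce(x, y)
  perms <- perm_rec(seq_len(n))
  stats <- vapply(perms, function(p) spearman_bruteforce(x, y[p]), numeric(1))
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# distinct assignments of a label multiset, independent of the package's
# enumerator: filter duplicates out of all permutations
multiset_perms_bruteforce <- function(labels) {
  n <- length(labels)
  perm_rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- perm_rec(v[-i])
      out <- rbind(out, cbind(v[i], sub))
    }
    out
  }
  unique(perm_rec(labels))
}

# small block-structured correlation matrix with given block sizes and
# within/between correlations
block_corr <- function(sizes, r_within, r_between = 0) {
  n <- sum(sizes)
  genes <- paste0("g", seq_len(n))
  block <- rep(seq_along(sizes), sizes)
  r <- matrix(r_between, n, n, dimnames = list(genes, genes))
  for (b in seq_along(sizes)) {
    idx <- which(block == b)
    r[idx, idx] <- r_within
  }
  diag(r) <- 1
  r
}

# standard planted-module generator settings shared across tests
planted_modules <- function(n_modules = 5, genes_per_module = 6) {
  mods <- lapply(seq_len(n_modules),
                 function(i) sprintf("M%d_G%d", i, seq_len(genes_per_module)))
  names(mods) <- paste0("module", seq_len(n_modules))
  mods
}

# ARI of a module_set against generator truth, background mapped to the
# unassigned class
module_recovery_ari <- function(module_set, truth) {
  df <- as.data.frame(module_set)
  pred <- setNames(df$module, df$gene)
  truth <- ifelse(truth == "background", "unassigned", truth)
  adjusted_rand_index(pred[names(truth)], truth)
}
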