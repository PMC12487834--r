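#' Filter genes detected in too few cells
#'
#' Retains genes with nonzero expression in at least \code{min_cells} cells,
#' the standard gene-detection filter applied before feature selection.
#'
#' @param x \code{SingleCellExperiment} (or cells x genes matrix).
#' @param min_cells minimum number of cells a gene must be detected in (>= 1).
#' @return the filtered object, with the number of removed genes in
#'   \code{attr(, "removed_genes")} and reported via \code{message()}.
#' @export
filter_genes_min_cells <- function(x, min_cells = 10) {
  if (min_cells < 1) stop("'min_cells' must be >= 1")
  m <- .expr_matrix(x) # genes x cells
  detected <- rowSums(m > 0)
  keep <- detected >= min_cells
  if (!any(keep)) stop("no genes detected in at least ", min_cells, " cells")
  out <- if (methods::is(x, "SummarizedExperiment")) x[keep, ] else x[, keep]
  message(sum(!keep), " genes removed (detected in fewer than ", min_cells,
          " cells); ", sum(keep), " genes retained")
  attr(out, "removed_genes") <- sum(!keep)
  out
}

#' Select highly variable genes by binned dispersion
#'
#' Ranks genes by within-bin normalized dispersion: genes are split into
#' \code{n_bins} equal-frequency bins of mean expression and the dispersion
#' (variance / mean) of each gene is centred and scaled robustly within its
#' bin (median and MAD, the CellRanger-style normalization), so that genes
#' are compared only against genes of similar mean expression. The top
#' \code{n_top} genes by normalized dispersion are returned; ties are broken
#' by raw dispersion and then by gene identifier so the ranking is
#' deterministic. Bins whose genes all share one dispersion value cannot be
#' scaled; their genes keep a normalized dispersion of 0 (raw dispersion
#' breaks the ties) and a warning is raised.
#'
#' @param x \code{SingleCellExperiment} or cells x genes matrix.
#' @param n_top number of genes to select.
#' @param n_bins number of equal-frequency mean-expression bins.
#' @return character vector of \code{n_top} gene identifiers, ranked.
#' @export
select_highly_variable <- function(x, n_top, n_bins = 20) {
  m <- .expr_matrix(x)
  if (n_top > nrow(m)) stop("'n_top' exceeds the number of genes")
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)

  n_bins <- min(n_bins, max(1, floor(nrow(m) / 2)))
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) cut(mu, breaks = br, include.lowest = TRUE)
    else factor(rep(1, length(mu)))

  z <- disp
  degenerate <- FALSE
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- stats::mad(disp[i])
    if (length(i) > 1 && !is.na(s) && s > 0) {
      z[i] <- (disp[i] - median(disp[i])) / s
    } else {
      z[i] <- 0
      degenerate <- TRUE
    }
  }
  if (degenerate) {
    warning("degenerate dispersion bin(s): falling back to raw dispersion ",
            "ranking within affected bins")
    # within a degenerate bin all z are 0; raw dispersion decides via the
    # secondary sort key below
  }
  ids <- rownames(m)
  # zero-dispersion (constant) genes are not variable by definition and rank
  # after every gene with positive dispersion, whatever its bin score
  ord <- order(disp == 0, -z, -disp, ids)
  ids[ord][seq_len(n_top)]
}

#' Principal components under a variance-target rule
#'
#' Computes PCs on per-gene centered (not scaled) expression of the selected
#' genes and chooses the number to keep as: the smallest number explaining at
#' least \code{variance_target} of the total variance, or \code{min_pcs},
#' whichever is larger, capped at \code{max_pcs} (and at the number of
#' available dimensions).
#'
#' @param x \code{SingleCellExperiment} or cells x genes matrix.
#' @param genes optional gene subset to compute PCs on (default all).
#' @param variance_target fraction of total variance to aim for.
#' @param min_pcs,max_pcs floor and cap on the number of PCs.
#' @return list with \code{scores} (cells x chosen_pcs), \code{chosen_pcs},
#'   \code{explained} (fraction of total variance explained by the chosen
#'   set), \code{variance_ratio} (per-PC fractions), \code{target_met}.
#' @export
choose_pcs <- function(x, genes = NULL, variance_target = 0.25,
                       min_pcs = 50, max_pcs = 100) {
  m <- .expr_matrix(x) # genes x cells
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) stop("genes not present: ", paste(missing, collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  cells_by_genes <- t(m)
  n_cells <- nrow(cells_by_genes)
  rank_cap <- min(n_cells - 1, ncol(cells_by_genes))
  if (rank_cap < min_pcs) {
    warning("fewer available dimensions (", rank_cap, ") than min_pcs (",
            min_pcs, "); capping")
  }
  pc <- prcomp(cells_by_genes, center = TRUE, scale. = FALSE,
               rank. = min(max_pcs, rank_cap))
  # variance ratio relative to the total variance of the data, not just the
  # computed components
  total_var <- sum(apply(cells_by_genes, 2, var))
  ratio <- pc$sdev^2 / total_var
  cum <- cumsum(ratio)

  n_target <- if (any(cum >= variance_target)) which(cum >= variance_target)[1]
    else length(cum) + 1 # target unreachable within available PCs
  chosen <- max(n_target, min_pcs)
  chosen <- min(chosen, max_pcs, rank_cap, ncol(pc$x))
  list(
    scores = pc$x[, seq_len(chosen), drop = FALSE],
    chosen_pcs = chosen,
    explained = sum(ratio[seq_len(chosen)]),
    variance_ratio = ratio[seq_len(min(length(ratio), max_pcs))],
    target_met = sum(ratio[seq_len(chosen)]) >= variance_target
  )
}

#' Cluster cells on a k-nearest-neighbor graph
#'
#' Builds a Euclidean k-NN graph in PC space, weights edges by the Jaccard
#' overlap of the two endpoints' neighbor sets, and partitions the graph by
#' Leiden modularity optimisation. The community-detection step is the
#' pluggable part (any modularity-based method on the same graph is
#' admissible); the graph construction and determinism-given-seed are what
#' this function guarantees.
#'
#' @param scores cells x dimensions matrix (e.g. \code{choose_pcs(x)$scores}).
#' @param k number of nearest neighbors (> 0, < number of cells).
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed (community detection is stochastic).
#' @return integer vector of cluster labels (1-based).
#' @export
knn_cluster <- function(scores, k = 15, resolution = 0.1, seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k <= 0) stop("'k' must be positive")
  if (k >= n) stop("'k' must be smaller than the number of cells")
  d <- as.matrix(dist(scores))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))

  # Jaccard weight between each cell and its neighbors
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  nb_sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  w <- vapply(seq_len(nrow(edges)), function(e) {
    a <- nb_sets[[edges[e, 1]]]
    b <- nb_sets[[edges[e, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = "max")
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  as.integer(igraph::membership(cl))
}

#' Rand index between two partitions
#'
#' Pair-counting agreement: the fraction of item pairs on which two
#' partitions agree (same cluster in both, or different in both). Equals 1
#' iff the partitions are identical up to relabeling.
#'
#' @param a,b cluster label vectors of equal length.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  npairs <- choose(n, 2)
  # agreements = pairs together in both + pairs apart in both
  (npairs + 2 * sum_ij - sum_a - sum_b) / npairs
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie adjustment);
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @inheritParams rand_index
#' @return adjusted Rand index (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  npairs <- choose(length(a), 2)
  expected <- sum_a * sum_b / npairs
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Select a stable neighborhood size from partitions over a k grid
#'
#' Computes the pairwise Rand index between clusterings obtained at different
#' k-NN parameters and selects the smallest k whose partitions agree (Rand
#' index above \code{threshold}) with the next larger k values on the grid
#' (up to two of them, mirroring the adjacent-k stability readout).
#'
#' @param partitions named list of cluster label vectors; names are the k
#'   values as integers.
#' @param threshold Rand-index stability threshold.
#' @param n_adjacent how many next-larger k values must agree.
#' @return list with \code{selected_k} (NA if none passes), \code{rand}
#'   (full pairwise Rand matrix), \code{threshold}.
#' @export
clustering_stability <- function(partitions, threshold = 0.8, n_adjacent = 2) {
  if (length(partitions) < 2) stop("need at least 2 partitions")
  ks <- as.integer(names(partitions))
  if (anyNA(ks)) stop("'partitions' must be named by integer k values")
  ord <- order(ks)
  ks <- ks[ord]
  partitions <- partitions[ord]
  m <- length(ks)
  rand <- matrix(1, m, m, dimnames = list(ks, ks))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      rand[i, j] <- rand[j, i] <- rand_index(partitions[[i]], partitions[[j]])
    }
  }
  selected <- NA_integer_
  for (i in seq_len(m - 1)) {
    larger <- (i + 1):min(m, i + n_adjacent)
    if (all(rand[i, larger] > threshold)) {
      selected <- ks[i]
      break
    }
  }
  list(selected_k = selected, rand = rand, threshold = threshold)
}
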