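#' Curated chemokine to chemokine-receptor pairing table
#'
#' Reads the receptor-ligand map shipped with the package: consensus human
#' chemokine ligand -> receptor pairings assembled from the standard
#' pharmacology literature, with a mandatory provenance column. The map is a
#' default, fully replaceable by the user via \code{\link{read_rl_map}}.
#'
#' @return data.frame with columns \code{ligand}, \code{receptor},
#'   \code{source}.
#' @export
default_rl_map <- function() {
  read_rl_map(system.file("extdata", "chemokine_receptor_map.tsv",
                          package = "chemomodules"))
}

#' Read a receptor-ligand map TSV
#'
#' @param path TSV with columns \code{ligand}, \code{receptor}, \code{source}.
#' @return validated data.frame (unique pairs).
#' @export
read_rl_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "source")
  if (!all(need %in% names(df))) {
    stop("RL map must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df[, c("ligand", "receptor")])) {
    stop("RL map contains duplicated ligand-receptor pairs")
  }
  df
}

#' Count receptor-ligand interactions between two gene sets
#'
#' The number of map pairs whose ligand lies in the chemokine gene set and
#' whose receptor lies in the receptor gene set.
#'
#' @param chem_genes,rec_genes character vectors of gene ids.
#' @param rl_map receptor-ligand map (see \code{\link{read_rl_map}}).
#' @return integer count (0 for empty inputs).
#' @export
count_rl_interactions <- function(chem_genes, rec_genes, rl_map) {
  if (nrow(rl_map) == 0) return(0L)
  sum(rl_map$ligand %in% chem_genes & rl_map$receptor %in% rec_genes)
}

# normalize a module_set or named list of gene vectors to a named list
.module_list <- function(modules) {
  m <- if (inherits(modules, "module_set")) modules$modules else modules
  if (!length(m)) stop("module set is empty")
  if (is.null(names(m))) names(m) <- paste0("module", seq_along(m))
  m
}

#' Permutation test for receptor-ligand module redundancy
#'
#' For every (chemokine module, receptor module) pair the observed number of
#' receptor-ligand interactions is compared with a null obtained by randomly
#' shuffling gene-to-module assignments: in each iteration the chemokine
#' genes currently assigned to any module are permuted across the chemokine
#' modules (preserving module sizes), independently the receptor genes across
#' the receptor modules, and interactions are recounted. The p value is the
#' plain proportion of iterations with an equal or greater count than
#' observed; one shared shuffle stream serves all module pairs (joint null).
#'
#' @param chem_modules,rec_modules \code{module_set} objects or named lists
#'   of gene vectors.
#' @param rl_map receptor-ligand map.
#' @param n_iter number of shuffling iterations.
#' @param seed integer seed.
#' @param pseudo use the (k+1)/(n+1) estimator instead of the plain
#'   proportion.
#' @param store_null keep the full null count matrix (pairs x iterations).
#' @return object of class \code{rl_permutation}: data.frame \code{results}
#'   (chem_module, rec_module, observed, p, n_iter), plus \code{seed} and
#'   optionally \code{null_counts}.
#' @export
rl_permutation_test <- function(chem_modules, rec_modules, rl_map,
                                n_iter = 10000, seed = 1, pseudo = FALSE,
                                store_null = FALSE) {
  if (n_iter < 100) warning("n_iter < 100 gives poor p-value resolution")
  cm <- .module_list(chem_modules)
  rm_ <- .module_list(rec_modules)
  set.seed(seed)

  chem_genes <- unlist(cm, use.names = FALSE)
  rec_genes <- unlist(rm_, use.names = FALSE)
  chem_labels <- rep(seq_along(cm), lengths(cm))
  rec_labels <- rep(seq_along(rm_), lengths(rm_))
  Kc <- length(cm)
  Kr <- length(rm_)

  # only map pairs with both endpoints in the shuffle universe can ever count
  in_univ <- rl_map$ligand %in% chem_genes & rl_map$receptor %in% rec_genes
  li <- match(rl_map$ligand[in_univ], chem_genes)
  ri <- match(rl_map$receptor[in_univ], rec_genes)

  tab_counts <- function(cl, rl) {
    # cl, rl: module label per chemokine/receptor gene
    key <- cl[li] + (rl[ri] - 1L) * Kc
    matrix(tabulate(key, Kc * Kr), Kc, Kr)
  }
  observed <- tab_counts(chem_labels, rec_labels)

  geq <- matrix(0, Kc, Kr)
  null_counts <- if (store_null) array(NA_integer_, c(Kc, Kr, n_iter)) else NULL
  for (it in seq_len(n_iter)) {
    nc <- tab_counts(sample(chem_labels), sample(rec_labels))
    geq <- geq + (nc >= observed)
    if (store_null) null_counts[, , it] <- nc
  }
  p <- if (pseudo) (geq + 1) / (n_iter + 1) else geq / n_iter

  results <- expand.grid(chem_module = names(cm), rec_module = names(rm_),
                         stringsAsFactors = FALSE)
  results$observed <- as.vector(observed)
  results$p <- as.vector(p)
  results$n_iter <- n_iter
  structure(list(results = results, seed = seed, pseudo = pseudo,
                 null_counts = null_counts),
            class = "rl_permutation")
}

#' @export
print.rl_permutation <- function(x, ...) {
  cat("Receptor-ligand module permutation test (",
      x$results$n_iter[1], " iterations, seed ", x$seed, ")\n", sep = "")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Exact null of the receptor-ligand permutation test
#'
#' Enumerates every distinguishable assignment of module labels to the
#' participating genes on each side (multiset permutations preserving module
#' sizes) and computes the exact tail probability per module pair. Used as
#' the oracle against which the Monte-Carlo test is checked; refuses when
#' the number of assignment combinations exceeds \code{max_assignments}.
#'
#' @inheritParams rl_permutation_test
#' @param max_assignments combinatorial bound on (chemokine assignments) x
#'   (receptor assignments).
#' @return data.frame with \code{chem_module}, \code{rec_module},
#'   \code{observed}, \code{p_exact}.
#' @export
exhaustive_rl_null <- function(chem_modules, rec_modules, rl_map,
                               max_assignments = 1e6) {
  cm <- .module_list(chem_modules)
  rm_ <- .module_list(rec_modules)
  chem_genes <- unlist(cm, use.names = FALSE)
  rec_genes <- unlist(rm_, use.names = FALSE)
  chem_labels <- rep(seq_along(cm), lengths(cm))
  rec_labels <- rep(seq_along(rm_), lengths(rm_))
  Kc <- length(cm)
  Kr <- length(rm_)

  n_chem <- .n_multiset_perms(lengths(cm))
  n_rec <- .n_multiset_perms(lengths(rm_))
  if (n_chem * n_rec > max_assignments) {
    stop("exhaustive enumeration refused: ", format(n_chem * n_rec),
         " assignment combinations exceed the bound of ",
         format(max_assignments))
  }
  A <- .multiset_perms(chem_labels)
  B <- .multiset_perms(rec_labels)

  in_univ <- rl_map$ligand %in% chem_genes & rl_map$receptor %in% rec_genes
  li <- match(rl_map$ligand[in_univ], chem_genes)
  ri <- match(rl_map$receptor[in_univ], rec_genes)

  count_mat <- function(cl, rl) {
    key <- cl[li] + (rl[ri] - 1L) * Kc
    matrix(tabulate(key, Kc * Kr), Kc, Kr)
  }
  observed <- count_mat(chem_labels, rec_labels)

  geq <- matrix(0, Kc, Kr)
  for (a in seq_len(nrow(A))) {
    cl <- A[a, ]
    for (b in seq_len(nrow(B))) {
      geq <- geq + (count_mat(cl, B[b, ]) >= observed)
    }
  }
  out <- expand.grid(chem_module = names(cm), rec_module = names(rm_),
                     stringsAsFactors = FALSE)
  out$observed <- as.vector(observed)
  out$p_exact <- as.vector(geq) / (nrow(A) * nrow(B))
  out
}

.n_multiset_perms <- function(sizes) {
  exp(lfactorial(sum(sizes)) - sum(lfactorial(sizes)))
}

# all distinguishable orderings of a label multiset, rows = orderings
.multiset_perms <- function(labels) {
  labels <- as.integer(labels)
  rec <- function(remaining) {
    types <- sort(unique(remaining))
    if (length(remaining) == 1) return(matrix(remaining, 1, 1))
    out <- list()
    for (tp in types) {
      idx <- which(remaining == tp)[1]
      sub <- rec(remaining[-idx])
      out[[length(out) + 1]] <- cbind(tp, sub)
    }
    do.call(rbind, out)
  }
  res <- rec(labels)
  dimnames(res) <- NULL
  res
}
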