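#' Pairwise Spearman correlation of a gene panel in a cell population
#'
#' Computes midrank Spearman correlations between all panel genes over the
#' cells of the requested population. Genes with zero variance in that
#' population cannot be rank-correlated; they are kept in the matrix with
#' r = 0 to all other genes and flagged (they are excluded from module
#' clustering downstream).
#'
#' @param x \code{SingleCellExperiment} or cells x genes matrix.
#' @param panel character vector of panel gene identifiers.
#' @param population cell filter: NULL (all cells), cell-type value(s), or a
#'   logical/index vector over cells.
#' @param min_cells minimum cells required after filtering.
#' @return symmetric correlation matrix (class \code{spearman_panel}) with
#'   attributes \code{n_cells} and \code{zero_variance} (flagged gene ids).
#' @export
spearman_panel <- function(x, panel, population = NULL, min_cells = 3) {
  m <- .expr_matrix(x)
  missing <- setdiff(panel, rownames(m))
  if (length(missing)) {
    stop("panel genes absent from the matrix: ", paste(missing, collapse = ", "))
  }
  keep <- .population_cells(x, population)
  if (sum(keep) < min_cells) {
    stop("fewer than ", min_cells, " cells in the requested population")
  }
  sub <- t(m[panel, keep, drop = FALSE]) # cells x panel genes
  vars <- apply(sub, 2, var)
  zv <- colnames(sub)[vars == 0]
  r <- matrix(0, ncol(sub), ncol(sub), dimnames = list(panel, panel))
  ok <- vars > 0
  if (sum(ok) >= 2) {
    r[ok, ok] <- cor(sub[, ok, drop = FALSE], method = "spearman")
  }
  diag(r) <- 1
  structure(r, class = c("spearman_panel", class(r)),
            n_cells = sum(keep), zero_variance = zv)
}

#' Extract co-expression modules by average-linkage flat clustering
#'
#' Each gene's row of the correlation matrix is taken as its correlation
#' profile; Euclidean distances between profiles are clustered by
#' average-linkage agglomeration and cut into flat clusters at
#' \code{linkage_distance}. Clusters of size >= 2 whose mean within-cluster
#' pairwise Spearman r exceeds \code{min_mean_r} become modules; all other
#' genes (including singleton clusters and zero-variance genes) are reported
#' as unassigned.
#'
#' @param corr correlation matrix from \code{\link{spearman_panel}} (or any
#'   symmetric correlation matrix with gene dimnames).
#' @param linkage_distance flat-cluster cut height on the average-linkage
#'   dendrogram (1.65 for chemokine panels, 1.5 for receptor panels in the
#'   shipped defaults).
#' @param min_mean_r module criterion on the mean within-module pairwise
#'   Spearman correlation.
#' @return object of class \code{module_set}: list with \code{modules}
#'   (named list of gene vectors, ordered by decreasing size), \code{mean_r}
#'   (per module), \code{unassigned}, \code{linkage_distance},
#'   \code{min_mean_r}.
#' @export
extract_modules <- function(corr, linkage_distance, min_mean_r = 0.15) {
  genes <- rownames(corr)
  if (is.null(genes)) stop("correlation matrix must have gene dimnames")
  zv <- attr(corr, "zero_variance")
  use <- if (length(zv)) setdiff(genes, zv) else genes

  modules <- list()
  mean_rs <- numeric()
  unassigned <- setdiff(genes, use)
  if (length(use) >= 2) {
    prof <- unclass(corr)[use, , drop = FALSE]
    hc <- hclust(dist(prof), method = "average")
    cl <- cutree(hc, h = linkage_distance)
    for (id in sort(unique(cl))) {
      members <- use[cl == id]
      if (length(members) < 2) {
        unassigned <- c(unassigned, members)
        next
      }
      sub <- corr[members, members]
      mr <- mean(sub[upper.tri(sub)])
      if (mr > min_mean_r) {
        modules[[length(modules) + 1]] <- members
        mean_rs <- c(mean_rs, mr)
      } else {
        unassigned <- c(unassigned, members)
      }
    }
  } else {
    unassigned <- genes
  }
  if (length(modules)) {
    # deterministic module numbering: by decreasing size, ties by first gene
    ord <- order(-lengths(modules),
                 vapply(modules, function(g) sort(g)[1], character(1)))
    modules <- modules[ord]
    mean_rs <- mean_rs[ord]
    names(modules) <- paste0("module", seq_along(modules))
    names(mean_rs) <- names(modules)
  } else {
    message("no cluster met the module criterion (mean r > ", min_mean_r,
            "); all genes unassigned")
  }
  structure(
    list(modules = modules, mean_r = mean_rs,
         unassigned = sort(unique(unassigned)),
         linkage_distance = linkage_distance, min_mean_r = min_mean_r),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  cat("Co-expression module set:", length(x$modules), "module(s),",
      length(x$unassigned), "unassigned gene(s)\n")
  cat("  cut height:", x$linkage_distance,
      " module criterion: mean pairwise r >", x$min_mean_r, "\n")
  for (nm in names(x$modules)) {
    cat(sprintf("  %s (n=%d, mean r=%.3f): %s\n", nm, length(x$modules[[nm]]),
                x$mean_r[[nm]], paste(x$modules[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.module_set <- function(object, ...) {
  data.frame(
    module = names(object$modules),
    size = lengths(object$modules),
    mean_r = unname(object$mean_r),
    row.names = NULL
  )
}

#' @describeIn extract_modules gene-to-module assignment as a data.frame
#'   (columns \code{gene}, \code{module}; unassigned genes labelled
#'   \code{"unassigned"}).
#' @param x,row.names,optional,... standard \code{as.data.frame} arguments.
#' @export
as.data.frame.module_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- data.frame(
    gene = c(unlist(x$modules, use.names = FALSE), x$unassigned),
    module = c(rep(names(x$modules), lengths(x$modules)),
               rep("unassigned", length(x$unassigned)))
  )
  df[order(df$gene), , drop = FALSE]
}

#' Read/write a module set as TSV
#'
#' Flat two-column (\code{gene}, \code{module}) interchange format.
#' @param x a \code{module_set} (for writing).
#' @param path TSV path.
#' @return \code{read_modules_tsv}: named list module -> gene vector
#'   (unassigned dropped).
#' @export
write_modules_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules_tsv
#' @export
read_modules_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df <- df[df$module != "unassigned", , drop = FALSE]
  split(df$gene, df$module)
}

#' Leave-one-out co-clustering stability of modules
#'
#' Repeats correlation + module extraction with each patient held out in
#' turn and reports, for every gene pair, the fraction of iterations in
#' which both genes were assigned to the same module (genes unassigned in an
#' iteration count as not co-clustered). Iterations with fewer than
#' \code{min_cells} remaining cells are skipped with a warning and removed
#' from the denominator.
#'
#' @inheritParams spearman_panel
#' @param linkage_distance,min_mean_r module extraction parameters.
#' @return genes x genes frequency matrix in \[0, 1\] with attribute
#'   \code{n_iterations} (iterations actually used).
#' @export
leave_one_out_stability <- function(x, panel, population = NULL,
                                    linkage_distance, min_mean_r = 0.15,
                                    min_cells = 3) {
  labs <- .cell_labels(x)
  patients <- unique(labs$patient)
  if (length(patients) < 3) stop("need at least 3 patients")
  pop <- .population_cells(x, population)

  co <- matrix(0, length(panel), length(panel), dimnames = list(panel, panel))
  used <- 0
  for (p in patients) {
    keep <- pop & labs$patient != p
    if (sum(keep) < min_cells) {
      warning("holding out patient ", p, " leaves fewer than ", min_cells,
              " cells; iteration skipped")
      next
    }
    corr <- spearman_panel(x, panel, population = keep, min_cells = min_cells)
    ms <- suppressMessages(extract_modules(corr, linkage_distance, min_mean_r))
    for (genes in ms$modules) {
      co[genes, genes] <- co[genes, genes] + 1
    }
    used <- used + 1
  }
  if (used == 0) stop("no usable leave-one-out iterations")
  freq <- co / used
  diag(freq) <- 1
  structure(freq, n_iterations = used)
}

#' Per-patient module scores
#'
#' For each patient, the score of a module is the mean expression of its
#' genes over that patient's cells of the designated population. Patients
#' with no population cells get \code{NA} scores.
#'
#' @param x \code{SingleCellExperiment} with patient labels.
#' @param modules a \code{module_set} or a named list of gene vectors.
#' @param population cell filter (see \code{\link{spearman_panel}}).
#' @param z_score if TRUE, scores are additionally z-scored across patients
#'   per module (attached as \code{attr(, "z")}).
#' @return patients x modules numeric matrix.
#' @export
score_modules_per_patient <- function(x, modules, population = NULL,
                                      z_score = FALSE) {
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  if (!length(mods)) stop("'modules' is empty")
  m <- .expr_matrix(x)
  labs <- .cell_labels(x)
  pop <- .population_cells(x, population)
  patients <- unique(labs$patient)

  scores <- matrix(NA_real_, length(patients), length(mods),
                   dimnames = list(patients, names(mods)))
  for (p in patients) {
    keep <- pop & labs$patient == p
    if (!any(keep)) next
    for (nm in names(mods)) {
      scores[p, nm] <- mean(m[mods[[nm]], keep, drop = FALSE])
    }
  }
  if (z_score) {
    attr(scores, "z") <- scale(scores)
  }
  scores
}

#' Call modules "expressed" per patient against a gene-shuffling null
#'
#' A module is called expressed in a patient when its score exceeds a
#' threshold. With \code{expression_threshold = NULL} the threshold is built
#' per module from a null distribution obtained by shuffling gene labels:
#' random same-size gene sets are drawn from \code{panel} and scored per
#' patient, and the module's threshold is the \code{null_quantile} quantile
#' of the pooled null scores. This is scale-free across modules of different
#' baseline expression.
#'
#' @inheritParams score_modules_per_patient
#' @param panel gene universe to draw null gene sets from (defaults to the
#'   union of module genes).
#' @param expression_threshold fixed numeric threshold; overrides the null.
#' @param n_null null gene sets per module.
#' @param null_quantile quantile of the null defining the threshold.
#' @param seed integer seed for the null draws.
#' @return logical patients x modules matrix with per-module thresholds in
#'   \code{attr(, "thresholds")}.
#' @export
module_expression_calls <- function(x, modules, population = NULL,
                                    panel = NULL, expression_threshold = NULL,
                                    n_null = 200, null_quantile = 0.75,
                                    seed = 1) {
  mods <- if (inherits(modules, "module_set")) modules$modules else modules
  scores <- score_modules_per_patient(x, mods, population)
  if (!is.null(expression_threshold)) {
    thr <- setNames(rep(expression_threshold, length(mods)), names(mods))
  } else {
    if (is.null(panel)) panel <- unlist(mods, use.names = FALSE)
    set.seed(seed)
    thr <- vapply(names(mods), function(nm) {
      size <- length(mods[[nm]])
      null_scores <- vapply(seq_len(n_null), function(i) {
        fake <- list(null = sample(panel, size))
        s <- score_modules_per_patient(x, fake, population)
        mean(s, na.rm = TRUE)
      }, numeric(1))
      quantile(null_scores, null_quantile, names = FALSE)
    }, numeric(1))
  }
  calls <- sweep(scores, 2, thr, ">")
  calls[is.na(scores)] <- NA
  attr(calls, "thresholds") <- thr
  calls
}

#' Correlate module scores with immune infiltration
#'
#' Spearman correlation (midranks) between per-patient module scores and
#' per-patient immune cell-type abundance, with two-sided p values (exact
#' permutation distribution for n <= 8 complete pairs, t approximation
#' otherwise). Patients missing either value are pairwise-deleted; constant
#' columns give an undefined correlation, reported as \code{NA}.
#'
#' @param scores patients x modules matrix
#'   (\code{\link{score_modules_per_patient}}).
#' @param infiltration patients x cell-types matrix or data.frame of
#'   abundances (e.g. % of leukocytes); rownames are patient ids matching
#'   \code{scores}.
#' @param min_patients minimum complete pairs required per correlation.
#' @return data.frame with columns \code{module}, \code{cell_type}, \code{n},
#'   \code{rho}, \code{p}.
#' @export
correlate_modules_with_infiltration <- function(scores, infiltration,
                                                min_patients = 5) {
  infiltration <- as.matrix(infiltration)
  common <- intersect(rownames(scores), rownames(infiltration))
  if (length(common) < min_patients) {
    stop("fewer than ", min_patients, " patients with both values")
  }
  out <- expand.grid(module = colnames(scores),
                     cell_type = colnames(infiltration),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_
  out$rho <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    s <- scores[common, out$module[i]]
    a <- infiltration[common, out$cell_type[i]]
    ok <- !is.na(s) & !is.na(a)
    out$n[i] <- sum(ok)
    if (sum(ok) < min_patients) next
    res <- spearman_test(s[ok], a[ok])
    out$rho[i] <- res$rho
    out$p[i] <- res$p
  }
  out
}

#' Spearman correlation with exact small-sample p value
#'
#' Midrank Spearman rho with a two-sided p value from the exact permutation
#' distribution for n <= 8 and from the t approximation
#' \code{t = rho * sqrt((n-2)/(1-rho^2))} otherwise. Constant input gives
#' \code{rho = NA} (undefined, not zero).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with \code{rho}, \code{p}, \code{n}, \code{method}.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 8) {
    perms <- .permutations(n)
    cx <- rx - mean(rx)
    denom_x <- sqrt(sum(cx^2))
    cy <- ry - mean(ry)
    # rho for every permutation of y-ranks against fixed x-ranks
    pr <- (matrix(cy[perms], nrow(perms), n) %*% cx) /
      (denom_x * sqrt(sum(cy^2)))
    p <- mean(abs(pr) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

# all permutations of 1..n as an n! x n matrix (n <= 8)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, setdiff(seq_len(n), pos)] <- sub
  }
  out
}
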