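#' Simulate clonogenic survival data under the linear-quadratic model
#'
#' Surviving fraction per dose and replicate is
#' \code{SF(D) = exp(-alpha * D - beta * D^2) * exp(eps)} with
#' \code{eps ~ N(0, lognormal_sd^2)} (multiplicative lognormal replicate
#' noise). At \code{lognormal_sd = 0} the values are the exact model curve and
#' the surviving fraction at dose 0 is exactly 1.
#'
#' Optionally colony counts are emitted alongside: with plating efficiency
#' \code{pe} and \code{seeded} cells per dish, colonies =
#' \code{round(seeded * pe * SF)} (dose-0 dishes carry the plating
#' efficiency), matching the layout \code{\link{surviving_fraction}} consumes.
#'
#' @param alpha linear coefficient (1/Gy), >= 0.
#' @param beta quadratic coefficient (1/Gy^2), >= 0.
#' @param doses dose points in Gy (>= 0); a dose-0 point is prepended if absent.
#' @param n_replicates replicates per dose.
#' @param lognormal_sd SD of the log-scale replicate noise.
#' @param radiation_type label stored with the records.
#' @param seeded,plating_efficiency when \code{seeded} is given, colony counts
#'   are added (columns \code{colonies}, \code{seeded}).
#' @param seed integer seed.
#' @return data.frame with columns \code{radiation_type}, \code{dose_gy},
#'   \code{replicate}, \code{surviving_fraction} (and optionally colony
#'   columns). True parameters attached as \code{attr(, "truth")}.
#' @export
simulate_survival_data <- function(alpha, beta, doses = c(0, 1, 2, 4, 6, 8),
                                   n_replicates = 3, lognormal_sd = 0.1,
                                   radiation_type = "photon",
                                   seeded = NULL, plating_efficiency = 0.5,
                                   seed = 1) {
  if (alpha < 0 || beta < 0) stop("'alpha' and 'beta' must be non-negative")
  if (any(doses < 0)) stop("doses must be non-negative")
  if (n_replicates < 1) stop("'n_replicates' must be positive")
  if (lognormal_sd < 0) stop("'lognormal_sd' must be non-negative")
  if (!0 %in% doses) doses <- c(0, doses)
  doses <- sort(unique(doses))

  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_replicates), dose_gy = doses)
  sf_model <- exp(-alpha * grid$dose_gy - beta * grid$dose_gy^2)
  eps <- if (lognormal_sd > 0) rnorm(nrow(grid), sd = lognormal_sd) else 0
  out <- data.frame(
    radiation_type = radiation_type,
    dose_gy = grid$dose_gy,
    replicate = grid$replicate,
    surviving_fraction = sf_model * exp(eps)
  )
  if (!is.null(seeded)) {
    out$seeded <- seeded
    out$colonies <- round(seeded * plating_efficiency * out$surviving_fraction)
  }
  attr(out, "truth") <- list(alpha = alpha, beta = beta,
                             lognormal_sd = lognormal_sd, seed = seed)
  out
}

#' Simulate a cytokine fold-change panel with lognormal replicate noise
#'
#' Replicate fold changes are \code{fc * exp(eps)}, \code{eps ~ N(0,
#' replicate_sd^2)}. Analyte names default to the ten canonical SASP factors
#' (\code{\link{sasp_factors}}); extra analytes are labelled generically.
#'
#' @param fold_changes positive numeric vector of true fold changes, optionally
#'   named by analyte.
#' @param n_replicates replicates per analyte.
#' @param replicate_sd log-scale replicate noise SD.
#' @param seed integer seed.
#' @return data.frame with columns \code{analyte}, \code{replicate},
#'   \code{fold_change}; truth attached as \code{attr(, "truth")}.
#' @export
simulate_cytokine_panel <- function(fold_changes, n_replicates = 3,
                                    replicate_sd = 0.2, seed = 1) {
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  if (replicate_sd < 0) stop("'replicate_sd' must be non-negative")
  n <- length(fold_changes)
  if (is.null(names(fold_changes))) {
    nm <- sasp_factors()
    names(fold_changes) <- if (n <= length(nm)) nm[seq_len(n)] else
      c(nm, sprintf("analyte%02d", seq_len(n - length(nm))))
  }
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      analyte = names(fold_changes),
                      stringsAsFactors = FALSE)
  eps <- if (replicate_sd > 0) rnorm(nrow(grid), sd = replicate_sd) else 0
  out <- data.frame(
    analyte = grid$analyte,
    replicate = grid$replicate,
    fold_change = unname(fold_changes[grid$analyte]) * exp(eps)
  )
  attr(out, "truth") <- list(fold_changes = fold_changes,
                             replicate_sd = replicate_sd, seed = seed)
  out
}
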