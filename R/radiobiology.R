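#' Surviving fractions from colony counts
#'
#' Plating efficiency is taken from the dose-0 dish of each replicate within
#' each condition (\code{PE = colonies_0 / seeded_0}); the surviving fraction
#' of every dish is its colony yield divided by that plating efficiency.
#' Replicates are kept separate.
#'
#' @param data data.frame with columns \code{dose_gy}, \code{colonies},
#'   \code{seeded}, \code{replicate}, and optionally \code{radiation_type} /
#'   \code{condition} grouping columns.
#' @return the input with a \code{surviving_fraction} column added.
#' @export
surviving_fraction <- function(data) {
  need <- c("dose_gy", "colonies", "seeded", "replicate")
  if (!all(need %in% names(data))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  if (any(data$dose_gy < 0) || any(data$colonies < 0) || any(data$seeded <= 0)) {
    stop("doses and colonies must be non-negative and seeded positive")
  }
  groups <- intersect(c("condition", "radiation_type", "replicate"), names(data))
  key <- do.call(paste, c(data[groups], sep = "\r"))
  data$surviving_fraction <- NA_real_
  for (k in unique(key)) {
    rows <- key == k
    zero <- rows & data$dose_gy == 0
    if (!any(zero)) stop("no dose-0 record for group: ", gsub("\r", " / ", k))
    pe <- data$colonies[zero][1] / data$seeded[zero][1]
    if (pe == 0) stop("plating efficiency is zero for group: ",
                      gsub("\r", " / ", k))
    data$surviving_fraction[rows] <-
      (data$colonies[rows] / data$seeded[rows]) / pe
  }
  data
}

#' Fit the linear-quadratic survival model
#'
#' Least-squares fit of \code{ln SF = -alpha * D - beta * D^2} in
#' log-survival space with equal weights, under the physical constraints
#' \code{alpha >= 0}, \code{beta >= 0} (an active-set solve over the two
#' boundary cases; an active constraint is flagged). Replicates are fit
#' jointly (pooled), not averaged first. A variance-weighted fit is available
#' through \code{weights}.
#'
#' @param dose doses in Gy, or a data.frame with columns \code{dose_gy} and
#'   \code{surviving_fraction}.
#' @param sf surviving fractions in (0, 1\] (ignored when \code{dose} is a
#'   data.frame).
#' @param weights optional per-observation weights for the log-space fit.
#' @return object of class \code{lq_fit} with components \code{alpha} (1/Gy),
#'   \code{beta} (1/Gy^2), \code{vcov} (covariance of the unconstrained
#'   estimates; NA entries when a constraint is active), \code{D10} (dose at
#'   10% survival, Gy), \code{fitted}, \code{residuals} (log scale),
#'   \code{constrained}, \code{data}. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{vcov}, \code{predict}, \code{residuals}, \code{plot},
#'   \code{simulate}.
#' @export
fit_lq <- function(dose, sf = NULL, weights = NULL) {
  if (is.data.frame(dose)) {
    sf <- dose$surviving_fraction
    dose <- dose$dose_gy
  }
  if (length(dose) != length(sf)) stop("'dose' and 'sf' lengths differ")
  if (any(sf <= 0)) stop("surviving fractions must be positive")
  if (length(unique(dose)) < 3) stop("need at least 3 distinct doses")
  if (is.null(weights)) weights <- rep(1, length(dose))

  y <- -log(sf)
  X <- cbind(D = dose, D2 = dose^2)
  solve_ls <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    XtW <- t(Xs * weights)
    cf <- solve(XtW %*% Xs, XtW %*% y)
    full <- c(D = 0, D2 = 0)
    full[cols] <- cf
    full
  }
  rss <- function(cf) sum(weights * (y - X %*% cf)^2)

  cf <- solve_ls(c("D", "D2"))
  constrained <- FALSE
  # negative only to numerical precision: clamp silently, no active constraint
  tol <- 1e-9 * max(abs(cf), 1)
  if (any(cf < 0 & cf >= -tol)) cf[cf < 0 & cf >= -tol] <- 0
  if (any(cf < 0)) {
    # active-set over the two boundary candidates, keep the feasible best
    cand <- list(pmax(c(solve_ls("D")[1], 0), 0),
                 pmax(c(0, solve_ls("D2")[2]), 0),
                 c(0, 0))
    cand <- Filter(function(z) all(z >= 0), cand)
    cf <- cand[[which.min(vapply(cand, rss, numeric(1)))]]
    names(cf) <- c("D", "D2")
    constrained <- TRUE
    warning("non-negativity constraint active (alpha or beta pinned at 0)")
  }
  alpha <- unname(cf["D"])
  beta <- unname(cf["D2"])

  n <- length(y)
  resid <- as.vector(y - X %*% cf)
  vc <- matrix(NA_real_, 2, 2, dimnames = list(c("alpha", "beta"),
                                               c("alpha", "beta")))
  if (!constrained && n > 2) {
    sigma2 <- sum(weights * resid^2) / (n - 2)
    vc[] <- sigma2 * solve(t(X * weights) %*% X)
  }

  fit <- structure(
    list(alpha = alpha, beta = beta, vcov = vc,
         D10 = .lq_dose_at(alpha, beta, 0.10),
         fitted = exp(-as.vector(X %*% cf)),
         residuals = -resid, # log-SF residuals: observed - fitted
         constrained = constrained,
         data = data.frame(dose_gy = dose, surviving_fraction = sf),
         sigma = if (!constrained && n > 2) sqrt(sum(weights * resid^2) / (n - 2))
                 else NA_real_),
    class = "lq_fit"
  )
  fit
}

# dose at survival level s: alpha*D + beta*D^2 = -ln(s), positive root in the
# cancellation-free form 2t / (alpha + sqrt(alpha^2 + 4*beta*t))
.lq_dose_at <- function(alpha, beta, s) {
  target <- -log(s)
  denom <- alpha + sqrt(alpha^2 + 4 * beta * target)
  if (denom == 0) return(Inf)
  2 * target / denom
}

#' Iso-survival dose of a fitted linear-quadratic curve
#'
#' @param fit an \code{lq_fit}.
#' @param s survival level in (0, 1).
#' @return dose in Gy at which the fitted curve reaches survival \code{s}.
#' @export
survival_dose <- function(fit, s = 0.10) {
  if (!inherits(fit, "lq_fit")) stop("'fit' must be an lq_fit")
  if (s <= 0 || s >= 1) stop("'s' must be in (0, 1)")
  .lq_dose_at(fit$alpha, fit$beta, s)
}

#' @export
print.lq_fit <- function(x, ...) {
  cat("Linear-quadratic survival fit: SF(D) = exp(-alpha*D - beta*D^2)\n")
  cat(sprintf("  alpha = %.4g /Gy, beta = %.4g /Gy^2%s\n", x$alpha, x$beta,
              if (x$constrained) "  [non-negativity constraint active]" else ""))
  cat(sprintf("  D10 = %.3f Gy (dose at 10%% survival), n = %d observations\n",
              x$D10, nrow(x$data)))
  invisible(x)
}

#' @export
summary.lq_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  out <- data.frame(
    estimate = c(alpha = object$alpha, beta = object$beta),
    std_error = se
  )
  cat("Linear-quadratic survival fit (log-survival least squares)\n\n")
  print(out)
  cat(sprintf("\nResidual SD (log scale): %.4g on %d observations\nD10 = %.3f Gy\n",
              object$sigma, nrow(object$data), object$D10))
  invisible(list(coefficients = out, D10 = object$D10, sigma = object$sigma))
}

#' @export
coef.lq_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
vcov.lq_fit <- function(object, ...) object$vcov

#' @export
residuals.lq_fit <- function(object, ...) object$residuals

#' @export
predict.lq_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose_gy
       else if (is.data.frame(newdata)) newdata$dose_gy else newdata
  exp(-object$alpha * d - object$beta * d^2)
}

#' @export
plot.lq_fit <- function(x, ...) {
  d <- x$data$dose_gy
  grid <- seq(0, max(d), length.out = 200)
  plot(d, x$data$surviving_fraction, log = "y",
       xlab = "Dose (Gy)", ylab = "Surviving fraction",
       main = "Linear-quadratic clonogenic survival", ...)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

#' @export
simulate.lq_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- if (is.na(object$sigma)) 0 else object$sigma
  d <- object$data$dose_gy
  out <- replicate(nsim,
                   exp(-object$alpha * d - object$beta * d^2 +
                         rnorm(length(d), sd = sdlog)))
  as.data.frame(out)
}

#' Relative biological effectiveness at a survival level
#'
#' RBE at survival level \code{s} (default 10%) is the ratio of the
#' reference-radiation dose to the test-radiation dose achieving that
#' survival on their fitted linear-quadratic curves:
#' \code{RBE = D_s(reference) / D_s(test)}.
#'
#' @param reference \code{lq_fit} of the reference radiation (photons).
#' @param test \code{lq_fit} of the test radiation (e.g. carbon ions).
#' @param s survival level in (0, 1).
#' @return object of class \code{rbe_result}: list with \code{rbe},
#'   \code{dose_reference}, \code{dose_test}, \code{s}.
#' @export
compute_rbe <- function(reference, test, s = 0.10) {
  if (s <= 0 || s >= 1) stop("'s' must be in (0, 1)")
  d_ref <- survival_dose(reference, s)
  d_test <- survival_dose(test, s)
  structure(list(rbe = d_ref / d_test, dose_reference = d_ref,
                 dose_test = d_test, s = s),
            class = "rbe_result")
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("RBE at %.0f%% survival: %.3f (reference %.3f Gy / test %.3f Gy)\n",
              100 * x$s, x$rbe, x$dose_reference, x$dose_test))
  invisible(x)
}

#' The ten canonical SASP factors
#'
#' @return character vector of the analytes entering the SASP factor score.
#' @export
sasp_factors <- function() {
  c("CCL2", "CCL4", "CCL5", "CXCL1", "CXCL8", "CXCL10",
    "ICAM1", "IL1a", "IL6", "TNFa")
}

#' SASP factor score of a cytokine fold-change panel
#'
#' Per replicate, the mean fold change (treated over control) across the
#' listed SASP factors present in the panel; reported as mean and SD over
#' replicates. Listed factors missing from the panel are reported via
#' \code{message()}; the score is defined as long as at least one is present.
#'
#' @param panel data.frame with columns \code{analyte}, \code{replicate},
#'   \code{fold_change} (positive).
#' @param factors the factor list entering the score.
#' @return list with \code{score} (mean over replicates), \code{sd},
#'   \code{per_replicate}, \code{factors_used}, \code{factors_missing}.
#' @export
sasp_score <- function(panel, factors = sasp_factors()) {
  need <- c("analyte", "replicate", "fold_change")
  if (!all(need %in% names(panel))) {
    stop("panel needs columns: ", paste(need, collapse = ", "))
  }
  if (any(panel$fold_change <= 0)) stop("fold changes must be positive")
  present <- intersect(factors, unique(panel$analyte))
  missing <- setdiff(factors, present)
  if (!length(present)) stop("none of the listed SASP factors is present")
  if (length(missing)) {
    message("SASP factors missing from the panel: ",
            paste(missing, collapse = ", "))
  }
  sub <- panel[panel$analyte %in% present, ]
  per_rep <- tapply(sub$fold_change, sub$replicate, mean)
  list(score = mean(per_rep), sd = if (length(per_rep) > 1) sd(per_rep) else NA_real_,
       per_replicate = per_rep, factors_used = present,
       factors_missing = missing)
}

#' Migration index from bead-normalized flow-cytometry counts
#'
#' Migrated-cell counts are first normalized to the acquired bead counts
#' (\code{count * ref_beads / sample_beads}, with the maximum acquired bead
#' count as the fixed reference; any fixed reference gives identical indices
#' since it cancels in the ratio), then each test sample's normalized count
#' is divided by the negative-control sample's normalized count, per immune
#' subset. Subsets with a zero control count get \code{NA} (undefined).
#'
#' @param counts data.frame with columns \code{sample}, \code{subset},
#'   \code{count}, \code{beads} (> 0), \code{is_control} (logical; exactly
#'   one control sample).
#' @return data.frame with columns \code{sample}, \code{subset},
#'   \code{migration_index} for the non-control samples.
#' @export
migration_index <- function(counts) {
  need <- c("sample", "subset", "count", "beads", "is_control")
  if (!all(need %in% names(counts))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  if (any(counts$beads <= 0)) stop("bead counts must be positive")
  ctrl_samples <- unique(counts$sample[counts$is_control])
  if (length(ctrl_samples) != 1) stop("exactly one control sample required")

  ref_beads <- max(counts$beads)
  counts$norm <- counts$count * ref_beads / counts$beads
  ctrl <- counts[counts$is_control, ]
  test <- counts[!counts$is_control, ]
  ctrl_norm <- setNames(ctrl$norm, ctrl$subset)

  out <- test[, c("sample", "subset")]
  denom <- ctrl_norm[test$subset]
  out$migration_index <- ifelse(is.na(denom) | denom == 0, NA_real_,
                                test$norm / denom)
  if (any(is.na(out$migration_index))) {
    message("migration index undefined (zero/absent control count) for: ",
            paste(unique(out$subset[is.na(out$migration_index)]),
                  collapse = ", "))
  }
  rownames(out) <- NULL
  out
}
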