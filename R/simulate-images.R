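#' Simulate a DAPI / bright-field image pair with known cell counts
#'
#' Renders \code{n_cells} non-overlapping nuclei (Gaussian intensity profiles
#' on a dark noisy background, the DAPI channel) and, for a designated subset
#' of positive cells, a blue-dominant perinuclear stain disc on a uniform
#' light background (the bright-field RGB channel), emulating SA-beta-Gal /
#' DAPI costained microscopy. Nucleus centers are placed by rejection
#' sampling at a minimum separation of \code{2.5 * nucleus_radius}; the true
#' total and positive counts are returned with the images.
#'
#' Intensities are on an 8-bit-like 0-255 scale (numeric matrices, not
#' integers). \code{\link{write_image_pair}} writes the pair to TIFF (16-bit
#' DAPI, 8-bit RGB bright-field).
#'
#' @param n_cells number of nuclei to render (>= 0).
#' @param fraction_positive fraction of cells carrying stain, in \[0, 1\];
#'   the positive count is \code{round(fraction_positive * n_cells)}.
#' @param image_size image side length in pixels (square frame).
#' @param nucleus_radius nominal nucleus radius in pixels; the Gaussian
#'   profile has sigma \code{nucleus_radius / 1.5}.
#' @param stain_intensity stain depth in 8-bit units subtracted from the
#'   red/green channels inside the stain disc (blue loses only 20% of it, so
#'   the blue-dominance score inside the disc is about \code{0.8 *
#'   stain_intensity}).
#' @param background_sd SD of the additive Gaussian background noise.
#' @param nucleus_peak peak DAPI intensity of a nucleus above background.
#' @param stain_radius radius of the perinuclear stain disc (default
#'   \code{1.7 * nucleus_radius}).
#' @param max_tries placement retries per cell before giving up.
#' @param seed integer seed.
#' @return list with elements \code{dapi} (matrix), \code{brightfield}
#'   (array h x w x 3), \code{n_cells}, \code{n_positive}, \code{centers}
#'   (matrix row/col, 1-based), \code{positive} (logical per cell).
#' @export
simulate_cell_images <- function(n_cells, fraction_positive = 0.3,
                                 image_size = 256, nucleus_radius = 6,
                                 stain_intensity = 120, background_sd = 5,
                                 nucleus_peak = 200, stain_radius = NULL,
                                 max_tries = 5000, seed = 1) {
  if (n_cells < 0) stop("'n_cells' must be >= 0")
  if (fraction_positive < 0 || fraction_positive > 1) {
    stop("'fraction_positive' must be in [0, 1]")
  }
  if (is.null(stain_radius)) stain_radius <- 1.7 * nucleus_radius
  set.seed(seed)

  min_sep <- 2.5 * nucleus_radius
  margin <- ceiling(2 * nucleus_radius) + 2
  lo <- margin + 1
  hi <- image_size - margin
  if (n_cells > 0 && hi <= lo) stop("frame too small for the nucleus radius")

  centers <- matrix(numeric(0), ncol = 2)
  if (n_cells > 0) {
    centers <- matrix(NA_real_, nrow = n_cells, ncol = 2)
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- runif(2, lo, hi)
        if (i == 1 ||
            all(sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                   2, cand)^2)) >= min_sep)) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", n_cells, " nuclei at separation ",
             round(min_sep, 1), " px after ", max_tries, " retries")
      }
    }
  }
  colnames(centers) <- c("row", "col")

  n_positive <- round(fraction_positive * n_cells)
  positive <- rep(FALSE, n_cells)
  if (n_positive > 0) positive[sample.int(n_cells, n_positive)] <- TRUE

  rr <- matrix(seq_len(image_size), image_size, image_size)
  cc <- t(rr)
  sigma <- nucleus_radius / 1.5

  dapi <- matrix(10 + rnorm(image_size^2, sd = background_sd),
                 image_size, image_size)
  for (i in seq_len(n_cells)) {
    d2 <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
    dapi <- dapi + nucleus_peak * exp(-d2 / (2 * sigma^2))
  }
  dapi[dapi < 0] <- 0
  dapi[dapi > 255] <- 255

  bg_level <- 230
  red <- matrix(bg_level + rnorm(image_size^2, sd = background_sd / 2),
                image_size, image_size)
  green <- matrix(bg_level + rnorm(image_size^2, sd = background_sd / 2),
                  image_size, image_size)
  blue <- matrix(bg_level + rnorm(image_size^2, sd = background_sd / 2),
                 image_size, image_size)
  for (i in which(positive)) {
    d2 <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
    # smooth-edged disc: full depth inside, Gaussian falloff at the rim
    prof <- ifelse(d2 <= stain_radius^2, 1,
                   exp(-(sqrt(d2) - stain_radius)^2 / (2 * 1.5^2)))
    red <- red - stain_intensity * prof
    green <- green - stain_intensity * prof
    blue <- blue - 0.2 * stain_intensity * prof
  }
  clip255 <- function(m) { m[m < 0] <- 0; m[m > 255] <- 255; m }
  brightfield <- array(c(clip255(red), clip255(green), clip255(blue)),
                       dim = c(image_size, image_size, 3))

  list(dapi = dapi, brightfield = brightfield,
       n_cells = n_cells, n_positive = n_positive,
       centers = centers, positive = positive)
}

#' Write a simulated image pair to TIFF files
#'
#' DAPI is written as 16-bit grayscale, the bright-field as 8-bit RGB, using
#' the \code{<stem>_dapi.tif} / \code{<stem>_bf.tif} pairing convention that
#' \code{\link{batch_quantify}} discovers.
#'
#' @param pair result of \code{\link{simulate_cell_images}}.
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return invisibly, the two file paths.
#' @export
write_image_pair <- function(pair, dir, stem) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dapi_path <- file.path(dir, paste0(stem, "_dapi.tif"))
  bf_path <- file.path(dir, paste0(stem, "_bf.tif"))
  # EBImage images are x (col-major width) by y; transpose so that the
  # round-trip through readImage reproduces the row/col matrix layout
  EBImage::writeImage(EBImage::Image(t(pair$dapi) / 255), dapi_path,
                      type = "tiff", bits.per.sample = 16L)
  bf <- pair$brightfield / 255
  bf_img <- EBImage::Image(aperm(bf, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(bf_img, bf_path, type = "tiff", bits.per.sample = 8L)
  invisible(c(dapi = dapi_path, brightfield = bf_path))
}
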