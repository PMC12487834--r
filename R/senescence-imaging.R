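#' Segmentation parameters for SA-beta-Gal quantification
#'
#' Bundles the tunable settings of the semiautomated quantifier. In the
#' interactive workflow these are chosen per imaging batch; the defaults here
#' are published values matched to the synthetic image generator's scale
#' (8-bit-like 0-255 intensities, nuclei of ~6 px radius) and should be
#' re-tuned for other magnifications or cameras.
#'
#' @param gaussian_blur_radius Gaussian blur sigma in pixels.
#' @param min_threshold minimum intensity a maximum must exceed (8-bit units;
#'   a quantile in \[0, 1\] when \code{quantile_thresholds = TRUE}).
#' @param prominence topographic prominence a maximum must have over its
#'   merge saddle (8-bit units; a fraction of the robust intensity range in
#'   quantile mode).
#' @param min_positive_area minimum connected stain area (px^2) inside the
#'   enlarged nucleus area for a cell to count positive.
#' @param rolling_ball_radius rolling-ball background radius in pixels.
#' @param enlarge_px how far nucleus areas are enlarged when searching for
#'   nucleus-proximal stain.
#' @param stain_min_threshold,stain_prominence thresholds for the stain
#'   (blue-dominance) channel; default to the DAPI values.
#' @param quantile_thresholds express intensity thresholds as quantiles so
#'   counts are invariant to uniform intensity rescaling.
#' @return list of class \code{sabgal_params}.
#' @export
sabgal_params <- function(gaussian_blur_radius = 2, min_threshold = 30,
                          prominence = 40, min_positive_area = 150,
                          rolling_ball_radius = 15, enlarge_px = 10,
                          stain_min_threshold = NULL, stain_prominence = NULL,
                          quantile_thresholds = FALSE) {
  p <- list(
    gaussian_blur_radius = gaussian_blur_radius,
    min_threshold = min_threshold,
    prominence = prominence,
    min_positive_area = min_positive_area,
    rolling_ball_radius = rolling_ball_radius,
    enlarge_px = enlarge_px,
    stain_min_threshold = if (is.null(stain_min_threshold)) min_threshold
                          else stain_min_threshold,
    stain_prominence = if (is.null(stain_prominence)) prominence
                       else stain_prominence,
    quantile_thresholds = quantile_thresholds
  )
  if (any(unlist(p[1:8]) < 0)) stop("all parameters must be >= 0")
  class(p) <- "sabgal_params"
  p
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image by a
#' hemispherical ("ball") structuring element of the given radius —
#' erosion followed by dilation with the ball's height profile — and
#' subtracts it, clipping at zero. Structures narrower than the ball are
#' preserved; smooth background (gradients, vignetting) is removed.
#'
#' @param image numeric matrix.
#' @param rolling_ball_radius ball radius in pixels (> 0, smaller than the
#'   image).
#' @return background-subtracted matrix (>= 0).
#' @export
subtract_background <- function(image, rolling_ball_radius) {
  image <- as.matrix(image)
  if (rolling_ball_radius <= 0) stop("'rolling_ball_radius' must be > 0")
  if (rolling_ball_radius >= min(dim(image))) {
    stop("'rolling_ball_radius' must be smaller than the image")
  }
  bg <- cpp_ball_dilate(cpp_ball_erode(image, as.integer(rolling_ball_radius)),
                        as.integer(rolling_ball_radius))
  out <- image - bg
  out[out < 0] <- 0
  out
}

.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

# resolve intensity thresholds, optionally as quantiles of the image
.resolve_thresholds <- function(img, min_threshold, prominence, quantile_mode) {
  if (!quantile_mode) {
    return(list(min_threshold = min_threshold, prominence = prominence))
  }
  list(
    min_threshold = quantile(img, min(max(min_threshold, 0), 1), names = FALSE),
    prominence = prominence * diff(quantile(img, c(0.001, 0.999), names = FALSE))
  )
}

#' Find intensity maxima with topographic prominence
#'
#' Locates local maxima above \code{min_threshold} and grows one region per
#' accepted maximum by flooding in decreasing intensity order; a maximum
#' whose saddle to a higher region is shallower than \code{prominence} is
#' merged into that region.
#'
#' @param image numeric matrix.
#' @param prominence required peak-over-saddle height.
#' @param min_threshold background cut-off.
#' @return list with \code{labels} (integer matrix, 0 = background),
#'   \code{peaks} (data.frame row, col, value; 1-based), \code{count}.
#' @export
find_intensity_maxima <- function(image, prominence, min_threshold) {
  res <- cpp_find_maxima(as.matrix(image), prominence, min_threshold)
  peaks <- as.data.frame(res$peaks)
  list(labels = res$labels, peaks = peaks, count = nrow(peaks))
}

#' Segment and count DAPI nuclei
#'
#' Rolling-ball background subtraction, Gaussian blur, then
#' prominence-based maxima detection: one region per accepted maximum, the
#' total cell count being the number of regions.
#'
#' @param dapi DAPI channel as a numeric matrix.
#' @param params a \code{\link{sabgal_params}} object.
#' @return list with \code{count}, \code{labels} (region label matrix),
#'   \code{centroids} (data.frame label/row/col, 1-based), \code{processed}
#'   (the filtered image the maxima were found on).
#' @export
segment_nuclei <- function(dapi, params = sabgal_params()) {
  img <- as.matrix(dapi)
  if (params$rolling_ball_radius > 0) {
    img <- subtract_background(img, params$rolling_ball_radius)
  }
  img <- .gblur(img, params$gaussian_blur_radius)
  thr <- .resolve_thresholds(img, params$min_threshold, params$prominence,
                             params$quantile_thresholds)
  mx <- find_intensity_maxima(img, thr$prominence, thr$min_threshold)
  centroids <- if (mx$count > 0) {
    idx <- which(mx$labels > 0, arr.ind = TRUE)
    lab <- mx$labels[mx$labels > 0]
    data.frame(
      label = sort(unique(lab)),
      row = as.vector(tapply(idx[, 1], lab, mean)),
      col = as.vector(tapply(idx[, 2], lab, mean))
    )
  } else {
    data.frame(label = integer(), row = numeric(), col = numeric())
  }
  list(count = mx$count, labels = mx$labels, centroids = centroids,
       processed = img)
}

#' Detect SA-beta-Gal-positive cells near segmented nuclei
#'
#' Builds a stain map from the bright-field RGB image as the per-pixel
#' blue-dominance score (blue minus the mean of red and green, clipped at
#' zero), background-subtracts and blurs it, and segments stain regions with
#' the same prominence-based maxima detection used for nuclei. Nucleus areas
#' are enlarged by \code{enlarge_px} (each pixel within that distance of a
#' nucleus is attributed to its nearest nucleus), and a nucleus is scored
#' positive when a connected stain region overlaps its enlarged area by at
#' least \code{min_positive_area} pixels — restricting the analysis to
#' nucleus-proximal signal.
#'
#' @param brightfield RGB array (rows x cols x 3) on the same frame as the
#'   DAPI image.
#' @param nuclei result of \code{\link{segment_nuclei}}.
#' @param params a \code{\link{sabgal_params}} object.
#' @return list with \code{positive} (count), \code{positive_labels}
#'   (which nucleus labels scored positive), \code{stain_labels} (stain
#'   region matrix), \code{stain_map}.
#' @export
detect_positive_cells <- function(brightfield, nuclei,
                                  params = sabgal_params()) {
  if (length(dim(brightfield)) != 3 || dim(brightfield)[3] < 3) {
    stop("'brightfield' must be an RGB array")
  }
  if (!all(dim(brightfield)[1:2] == dim(nuclei$labels))) {
    stop("bright-field and DAPI images have mismatched dimensions")
  }
  stain <- brightfield[, , 3] - (brightfield[, , 1] + brightfield[, , 2]) / 2
  stain[stain < 0] <- 0
  if (params$rolling_ball_radius > 0) {
    stain <- subtract_background(stain, params$rolling_ball_radius)
  }
  stain <- .gblur(stain, params$gaussian_blur_radius)
  thr <- .resolve_thresholds(stain, params$stain_min_threshold,
                             params$stain_prominence,
                             params$quantile_thresholds)
  sx <- find_intensity_maxima(stain, thr$prominence, thr$min_threshold)

  if (nuclei$count == 0 || sx$count == 0) {
    return(list(positive = 0L, positive_labels = integer(),
                stain_labels = sx$labels, stain_map = stain))
  }

  # enlarged per-nucleus areas: every pixel within enlarge_px of a nucleus
  # region, attributed to its nearest nucleus by Voronoi-style propagation
  nmask <- nuclei$labels > 0
  dist_to_nucleus <- EBImage::imageData(
    EBImage::distmap(EBImage::Image(1 - nmask))
  )
  enlarged_mask <- dist_to_nucleus <= params$enlarge_px
  territory <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(matrix(0, nrow(nmask), ncol(nmask))),
    seeds = EBImage::Image(nuclei$labels),
    mask = EBImage::Image(enlarged_mask),
    lambda = 1e8
  ))

  both <- territory > 0 & sx$labels > 0
  if (!any(both)) {
    return(list(positive = 0L, positive_labels = integer(),
                stain_labels = sx$labels, stain_map = stain))
  }
  overlap <- table(territory[both], sx$labels[both])
  qualifying <- overlap >= params$min_positive_area
  positive_labels <- sort(as.integer(rownames(overlap)[rowSums(qualifying) > 0]))
  list(positive = length(positive_labels),
       positive_labels = positive_labels,
       stain_labels = sx$labels, stain_map = stain)
}

#' Percent senescent cells
#'
#' @param total total cell count (> 0 for a defined value).
#' @param positive SA-beta-Gal-positive cell count (0 <= positive <= total).
#' @return \code{100 * positive / total}; \code{NA} when \code{total} is 0
#'   (undefined, reported missing).
#' @export
percent_senescent <- function(total, positive) {
  if (total < 0 || positive < 0 || positive > total) {
    stop("need 0 <= positive <= total")
  }
  if (total == 0) {
    message("total cell count is 0; percent senescent undefined")
    return(NA_real_)
  }
  100 * positive / total
}

#' Quantify one DAPI / bright-field image pair
#'
#' @param dapi DAPI matrix.
#' @param brightfield RGB array registered to the DAPI frame.
#' @param params a \code{\link{sabgal_params}} object.
#' @return list with \code{total_cells}, \code{positive_cells},
#'   \code{percent_senescent}, \code{centroids}, \code{nuclei},
#'   \code{stain}.
#' @export
quantify_image_pair <- function(dapi, brightfield, params = sabgal_params()) {
  nuc <- segment_nuclei(dapi, params)
  pos <- detect_positive_cells(brightfield, nuc, params)
  list(
    total_cells = nuc$count,
    positive_cells = pos$positive,
    percent_senescent = if (nuc$count > 0)
      percent_senescent(nuc$count, pos$positive) else NA_real_,
    centroids = nuc$centroids,
    nuclei = nuc, stain = pos
  )
}

#' Quantify a directory of paired images
#'
#' Discovers image pairs by the \code{<stem>_dapi.<ext>} /
#' \code{<stem>_bf.<ext>} naming convention (TIFF or PNG), quantifies each,
#' and pools the condition-level percent senescent as
#' (sum of positives) / (sum of totals). Unpaired files are skipped with a
#' warning. Intensities read from file (\[0, 1\] scale) are rescaled to
#' 0-255 so the default thresholds apply regardless of bit depth.
#'
#' @param dir directory containing the images.
#' @param params a \code{\link{sabgal_params}} object.
#' @return list with \code{results} (data.frame image/total/positive/
#'   percent) and \code{pooled_percent}.
#' @export
batch_quantify <- function(dir, params = sabgal_params()) {
  files <- list.files(dir, pattern = "_(dapi|bf)\\.(tif|tiff|png)$",
                      ignore.case = TRUE)
  stems <- unique(sub("_(dapi|bf)\\.(tif|tiff|png)$", "", files,
                      ignore.case = TRUE))
  results <- data.frame(image = character(), total = integer(),
                        positive = integer(), percent = numeric())
  if (!length(stems)) {
    warning("no image pairs found in ", dir)
    return(list(results = results, pooled_percent = NA_real_))
  }
  for (stem in sort(stems)) {
    dapi_f <- files[grepl(paste0("^", stem, "_dapi\\."), files, ignore.case = TRUE)]
    bf_f <- files[grepl(paste0("^", stem, "_bf\\."), files, ignore.case = TRUE)]
    if (length(dapi_f) != 1 || length(bf_f) != 1) {
      warning("unpaired image stem '", stem, "' skipped")
      next
    }
    dapi_img <- EBImage::readImage(file.path(dir, dapi_f))
    bf_img <- EBImage::readImage(file.path(dir, bf_f))
    dapi <- t(EBImage::imageData(dapi_img)) * 255
    bf_data <- EBImage::imageData(bf_img)
    if (length(dim(bf_data)) != 3) stop("bright-field image is not RGB: ", bf_f)
    bf <- aperm(bf_data[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
    q <- quantify_image_pair(dapi, bf, params)
    results <- rbind(results, data.frame(
      image = stem, total = q$total_cells, positive = q$positive_cells,
      percent = q$percent_senescent
    ))
  }
  pooled <- if (nrow(results) && sum(results$total) > 0) {
    100 * sum(results$positive) / sum(results$total)
  } else NA_real_
  list(results = results, pooled_percent = pooled)
}
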