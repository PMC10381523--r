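## Profile roughness and macroporosity from binarized micrographs.
##
## The profile is traced stylus-like: one height per scan column, taken at
## the first material pixel encountered from the chosen image edge (the
## outer envelope; surface-connected pores deeper than the first hit are
## invisible). Heights increase outward from the material and are referenced
## to the mean plane by subtracting the arithmetic mean of the raw profile.

#' Construct a calibrated grayscale image
#'
#' @param pixels numeric matrix of gray levels, row 1 = image top.
#' @param pixel_size_um isotropic pixel size in micrometres (> 0).
#' @return a `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || nrow(pixels) < 2L || ncol(pixels) < 2L)
    gpls_error("pixels must be a numeric matrix of at least 2x2",
               "graftPLS_schema_error")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    gpls_error("pixel_size_um must be a positive scalar",
               "graftPLS_range_error")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "calibrated_image")
}

#' Read a PNG or TIFF grayscale image with its pixel size
#'
#' Multi-channel images are collapsed to grayscale by channel averaging.
#'
#' @param path PNG or TIFF file.
#' @param pixel_size_um micrometres per pixel.
#' @return a `calibrated_image` with gray levels in \[0, 1\].
#' @export
read_calibrated_image <- function(path, pixel_size_um) {
  if (!file.exists(path))
    gpls_error(paste0("no such file: ", path), "graftPLS_io_error")
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 3L) px <- apply(px, c(1L, 2L), mean)
  # EBImage stores images x-first; transpose to row 1 = image top
  calibrated_image(t(px), pixel_size_um)
}

#' Write a calibrated image (or mask) to PNG or TIFF
#'
#' @param image a `calibrated_image`, or a logical mask (written as 0/1).
#' @param path output path; format follows the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  EBImage::writeImage(EBImage::Image(t(px)), path)
  invisible(path)
}

#' Binarize a grayscale image into a material mask
#'
#' `"otsu"` picks the threshold maximizing between-class variance (via
#' \pkg{EBImage}); `"fixed"` uses the supplied gray level. Material is the
#' bright phase (gray level above the threshold), matching backscattered-
#' electron contrast where mineral is bright against resin.
#'
#' @param image a `calibrated_image`.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold gray level, required for `method = "fixed"`.
#' @return logical matrix, `TRUE` = material. Errors with a degenerate-mask
#'   condition when the result is all material or all background.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  method <- match.arg(method)
  px <- image$pixels
  if (method == "fixed") {
    if (is.null(threshold))
      gpls_error("fixed method requires a threshold", "graftPLS_schema_error")
  } else {
    rng <- range(px)
    if (diff(rng) < .Machine$double.eps)
      gpls_error("constant image: degenerate mask", "graftPLS_degenerate_mask")
    threshold <- EBImage::otsu(EBImage::Image(t(px)), range = rng)
  }
  mask <- px > threshold
  frac <- mean(mask)
  if (frac == 0 || frac == 1)
    gpls_error("degenerate mask: all background or all material",
               "graftPLS_degenerate_mask")
  mask
}

#' Extract a calibrated surface-height profile from a material mask
#'
#' Scans every column (or row, for lateral directions) from the chosen
#' image edge and records the distance to the first material pixel. The
#' sign is flipped so heights increase outward from the material (peaks
#' positive), and the profile is referenced to the mean plane by
#' subtracting its arithmetic mean. Columns containing no material are
#' dropped and flagged (`gaps`), never interpolated.
#'
#' @param mask logical matrix, `TRUE` = material, row 1 = image top.
#' @param pixel_size_um micrometres per pixel.
#' @param direction edge the scan starts from: `"top"`, `"bottom"`,
#'   `"left"`, `"right"`.
#' @param detrend subtract a least-squares line before mean-referencing
#'   (default `FALSE`: plain mean-plane referencing).
#' @return a `roughness_profile`: list with `heights` (micrometres,
#'   zero mean), `n_points`, `spacing_um`, `evaluation_length_um`
#'   (`(n-1) * spacing`), `gaps` (number of dropped columns), `direction`.
#' @export
extract_profile <- function(mask, pixel_size_um,
                            direction = c("top", "bottom", "left", "right"),
                            detrend = FALSE) {
  direction <- match.arg(direction)
  if (!is.logical(mask) || !is.matrix(mask))
    gpls_error("mask must be a logical matrix", "graftPLS_schema_error")
  if (pixel_size_um <= 0)
    gpls_error("pixel_size_um must be positive", "graftPLS_range_error")
  m <- switch(direction,
    top    = mask,
    bottom = mask[rev(seq_len(nrow(mask))), , drop = FALSE],
    left   = t(mask),
    right  = t(mask)[rev(seq_len(ncol(mask))), , drop = FALSE])
  first_hit <- apply(m, 2L, function(col) {
    i <- which(col)
    if (length(i) == 0L) NA_integer_ else i[1L]
  })
  gaps <- sum(is.na(first_hit))
  depth <- (first_hit[!is.na(first_hit)] - 1L) * pixel_size_um
  if (length(depth) < 2L)
    gpls_error("fewer than 2 usable scan columns", "graftPLS_degenerate_mask")
  heights <- -depth  # outward-positive
  if (detrend) {
    xi <- seq_along(heights)
    heights <- stats::lm.fit(cbind(1, xi), heights)$residuals
  }
  heights <- unname(heights - mean(heights))
  structure(list(heights = heights, n_points = length(heights),
                 spacing_um = pixel_size_um,
                 evaluation_length_um = (length(heights) - 1L) * pixel_size_um,
                 gaps = gaps, direction = direction),
            class = "roughness_profile")
}

#' Profile roughness parameters Pa, Pq, Pt (with Pp and Pv)
#'
#' On the mean-referenced heights y_i: Pa = mean(|y|), Pq = sqrt(mean(y^2)),
#' Pp = max(y), Pv = min(y), Pt = Pp - Pv. An evaluation length shorter than
#' `min_eval_length_um` raises a warning and sets the `short_length` flag,
#' but does not fail: the length threshold is an analysis choice, not a
#' validity bound.
#'
#' @param profile a `roughness_profile` (or numeric heights, assumed
#'   mean-referenced with unit spacing).
#' @param min_eval_length_um minimum evaluation length, default 40 um.
#' @return a `roughness_params`: list with `pa`, `pq`, `pt`, `pp`, `pv`
#'   (micrometres), `n_points`, `evaluation_length_um`, `short_length`.
#' @examples
#' roughness_params(extract_profile(
#'   matrix(c(FALSE, TRUE), 4, 5, byrow = TRUE), pixel_size_um = 1))
#' @export
roughness_params <- function(profile, min_eval_length_um = 40) {
  if (is.numeric(profile))
    profile <- structure(list(heights = profile - mean(profile),
                              n_points = length(profile), spacing_um = 1,
                              evaluation_length_um = length(profile) - 1,
                              gaps = 0L, direction = "top"),
                         class = "roughness_profile")
  stopifnot(inherits(profile, "roughness_profile"))
  y <- profile$heights
  if (length(y) < 2L)
    gpls_error("profile needs at least 2 points", "graftPLS_range_error")
  short <- profile$evaluation_length_um < min_eval_length_um
  if (short)
    warning(sprintf("evaluation length %.3g um below the minimum %.3g um",
                    profile$evaluation_length_um, min_eval_length_um),
            call. = FALSE)
  pp <- max(y); pv <- min(y)
  structure(list(pa = mean(abs(y)), pq = sqrt(mean(y^2)), pt = pp - pv,
                 pp = pp, pv = pv, n_points = length(y),
                 evaluation_length_um = profile$evaluation_length_um,
                 short_length = short),
            class = "roughness_params")
}

#' @export
print.roughness_params <- function(x, ...) {
  cat(sprintf("Pa = %.4g um, Pq = %.4g um, Pt = %.4g um (Pp = %.4g, Pv = %.4g)\n",
              x$pa, x$pq, x$pt, x$pp, x$pv))
  if (x$short_length) cat("  [warning: evaluation length below minimum]\n")
  invisible(x)
}

#' Roughness of a set of micrographs with mean +/- SD aggregation
#'
#' Each image is binarized, profiled and parameterized; per-image failures
#' are collected (not fatal unless every image fails). The aggregate is the
#' arithmetic mean and n-1 SD over the per-image parameters; SD is `NA`
#' for a single image.
#'
#' @param images list of `calibrated_image` objects (length >= 1).
#' @param method,threshold passed to [binarize()].
#' @param direction,detrend passed to [extract_profile()].
#' @param min_eval_length_um passed to [roughness_params()].
#' @return list with `per_image` (list of `roughness_params` or `NULL` for
#'   failures), `mean` and `sd` (named vectors over pa/pq/pt/pp/pv),
#'   `n_images`, `errors` (character messages).
#' @export
roughness_image_set <- function(images, method = "otsu", threshold = NULL,
                                direction = "top", detrend = FALSE,
                                min_eval_length_um = 40) {
  if (length(images) < 1L)
    gpls_error("need at least one image", "graftPLS_schema_error")
  errs <- character()
  per_image <- lapply(images, function(img) {
    tryCatch({
      mask <- binarize(img, method = method, threshold = threshold)
      prof <- extract_profile(mask, img$pixel_size_um, direction = direction,
                              detrend = detrend)
      roughness_params(prof, min_eval_length_um = min_eval_length_um)
    }, graftPLS_error = function(e) {
      errs[[length(errs) + 1L]] <<- conditionMessage(e)
      NULL
    })
  })
  ok <- !vapply(per_image, is.null, logical(1))
  if (!any(ok))
    gpls_error(paste0("all images failed: ", paste(errs, collapse = "; ")),
               "graftPLS_degenerate_mask")
  vals <- t(vapply(per_image[ok],
                   function(r) unlist(r[c("pa", "pq", "pt", "pp", "pv")]),
                   numeric(5)))
  list(per_image = per_image,
       mean = colMeans(vals),
       sd = if (sum(ok) > 1L) apply(vals, 2L, sd)
            else setNames(rep(NA_real_, 5), colnames(vals)),
       n_images = sum(ok), errors = errs)
}

#' Macroporosity as a colonized-area fraction
#'
#' 100 * (colonized pixels) / (total-zone pixels): the percentage of the
#' zonal area invaded by cell colonization (soft tissue and marrow spaces),
#' the proxy used for macropores and interparticle voids.
#'
#' @param total_zone logical mask of the zonal area.
#' @param colonized logical mask of the colonized area; must be a subset of
#'   `total_zone` and the same shape.
#' @return percentage in \[0, 100\].
#' @export
macroporosity <- function(total_zone, colonized) {
  if (!identical(dim(total_zone), dim(colonized)))
    gpls_error("mask shapes differ", "graftPLS_schema_error")
  if (!is.logical(total_zone) || !is.logical(colonized))
    gpls_error("masks must be logical", "graftPLS_schema_error")
  if (sum(total_zone) == 0L)
    gpls_error("empty total zone", "graftPLS_degenerate_mask")
  if (any(colonized & !total_zone))
    gpls_error("colonized pixels outside the total zone",
               "graftPLS_range_error")
  100 * sum(colonized) / sum(total_zone)
}

#' Macroporosity of a set of mask pairs with mean +/- SD aggregation
#'
#' @param pairs list (length >= 1) of `list(total, colonized)` mask pairs.
#' @return list with `values` (percent per pair), `mean`, `sd` (n-1
#'   denominator; `NA` for a single pair), `n`.
#' @export
macroporosity_set <- function(pairs) {
  if (length(pairs) < 1L)
    gpls_error("need at least one mask pair", "graftPLS_schema_error")
  values <- vapply(pairs, function(p) macroporosity(p[[1L]], p[[2L]]),
                   numeric(1))
  list(values = values, mean = mean(values),
       sd = if (length(values) > 1L) sd(values) else NA_real_,
       n = length(values))
}
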