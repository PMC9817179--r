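#' Project a nuclear z-stack to 2-D
#'
#' Collapses a z-stack along z. The maximum projection is used for peak
#' finding and roughness; the sum projection is used for punctate
#' percentage, where total fluorescence must be conserved.
#'
#' @param stack 3-D numeric array with dimensions (y, x, z), or a matrix
#'   (treated as a single plane). Intensities must be finite and >= 0.
#' @param method `"max"` or `"sum"`.
#' @return Numeric matrix (y, x).
#' @export
project <- function(stack, method = c("max", "sum")) {
  method <- match.arg(method)
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (!is.array(stack) || length(dim(stack)) != 3L || !is.numeric(stack))
    stop("stack must be a (y, x, z) numeric array or a matrix",
         call. = FALSE)
  if (any(!is.finite(stack)) || any(stack < 0))
    stop("stack intensities must be finite and >= 0", call. = FALSE)
  if (method == "max") {
    apply(stack, c(1L, 2L), max)
  } else {
    apply(stack, c(1L, 2L), sum)
  }
}

#' Normalize an image to unit total intensity within the nucleus
#'
#' Divides by the summed intensity inside the mask and zeroes everything
#' outside, so that live and fixed images of the same cell are compared on
#' the same scale: the sum of intensities within the nucleus equals 1.
#'
#' @param image Numeric matrix (y, x).
#' @param mask Logical nucleus mask, same shape.
#' @return Numeric matrix; masked pixels sum to 1, outside pixels are 0.
#' @export
normalize_to_mask <- function(image, mask) {
  check_image_mask(image, mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  total <- sum(image[mask])
  if (total <= 0)
    stop("total intensity within the mask is zero; cannot normalize",
         call. = FALSE)
  out <- image / total
  out[!mask] <- 0
  out
}

#' Surface roughness of the nuclear intensity distribution
#'
#' The standard deviation (population convention, divide by N) of the
#' pixel intensities within the nucleus mask, computed on the normalized
#' maximum projection. Puncta and other structure raise it; a perfectly
#' even nucleoplasm gives 0.
#'
#' @inheritParams normalize_to_mask
#' @return Single nonnegative number (dimensionless for normalized input).
#' @export
surface_roughness <- function(image, mask) {
  check_image_mask(image, mask)
  v <- image[mask]
  if (length(v) < 2L) stop("mask must contain at least 2 pixels",
                           call. = FALSE)
  sqrt(mean((v - mean(v))^2))
}

bilinear <- function(image, y, x) {
  nr <- nrow(image); nc <- ncol(image)
  y0 <- floor(y); x0 <- floor(x)
  y0 <- pmin(pmax(y0, 1L), nr - 1L)
  x0 <- pmin(pmax(x0, 1L), nc - 1L)
  fy <- y - y0; fx <- x - x0
  image[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    image[cbind(y0 + 1L, x0)] * fy * (1 - fx) +
    image[cbind(y0, x0 + 1L)] * (1 - fy) * fx +
    image[cbind(y0 + 1L, x0 + 1L)] * fy * fx
}

half_max_crossing <- function(s, prof, i_peak, half, dir) {
  # walk from the peak in direction dir (+1/-1) to the first sample below
  # half maximum; linear interpolation between the bracketing samples
  i <- i_peak
  repeat {
    j <- i + dir
    if (j < 1L || j > length(prof)) return(NA_real_)
    if (prof[j] < half) {
      frac <- (prof[i] - half) / (prof[i] - prof[j])
      return(s[i] + frac * (s[j] - s[i]))
    }
    i <- j
  }
}

#' Refine a punctum center and measure its FWHM by radial slicing
#'
#' Peak finding lands on a bright pixel that need not be the true punctum
#' center. This routine draws `n_slices` diameter profiles through the
#' preliminary center (default 36, i.e. 5 degree steps over 180 degrees),
#' samples each by bilinear interpolation at `step` px, and measures each
#' profile's full width at half maximum, taking the profile minimum as the
#' local baseline (puncta sit on a nonzero nucleoplasm background). The
#' punctum's FWHM is the maximum over slices — that slice must have passed
#' through the true center — and the refined center is the midpoint of the
#' two half-maximum crossings of that slice.
#'
#' @param image Numeric matrix, typically the normalized max projection.
#' @param preliminary_center Numeric `c(y, x)` pixel from [find_puncta()].
#' @param n_slices Number of radial slices (>= 1); default 36.
#' @param max_half_length Half-length of each slice in px; default 30.
#' @param step Sampling step along each slice in px; default 0.25.
#' @return A `punctum` list: `preliminary_center`, `refined_center`
#'   (`c(y, x)`, possibly fractional), `fwhm` (px), `angle` (degrees of the
#'   widest slice) and `resolved`. If no slice's profile falls below half
#'   maximum on both sides within `max_half_length`, the punctum is flagged
#'   unresolved (`fwhm = NA`) with a warning.
#' @export
refine_center_and_fwhm <- function(image, preliminary_center,
                                   n_slices = 36L, max_half_length = 30,
                                   step = 0.25) {
  stopifnot(is.matrix(image), length(preliminary_center) == 2L,
            n_slices >= 1L, max_half_length > 0, step > 0)
  y0 <- preliminary_center[[1L]]; x0 <- preliminary_center[[2L]]
  if (y0 < 1 || y0 > nrow(image) || x0 < 1 || x0 > ncol(image))
    stop("preliminary_center lies outside the image", call. = FALSE)
  angles <- (seq_len(n_slices) - 1L) * 180 / n_slices
  s <- seq(-max_half_length, max_half_length, by = step)
  best <- list(fwhm = -Inf, center = c(NA_real_, NA_real_),
               angle = NA_real_)
  for (a in angles) {
    th <- a * pi / 180
    yy <- y0 + s * sin(th)
    xx <- x0 + s * cos(th)
    ok <- yy >= 1 & yy <= nrow(image) & xx >= 1 & xx <= ncol(image)
    if (sum(ok) < 3L) next
    prof <- bilinear(image, yy[ok], xx[ok])
    ss <- s[ok]
    # skip effectively flat profiles (interpolation round-off only)
    if (max(prof) - min(prof) <= 1e-9 * max(abs(prof), 1e-300)) next
    i_peak <- which.max(prof)
    half <- min(prof) + (max(prof) - min(prof)) / 2
    left <- half_max_crossing(ss, prof, i_peak, half, -1L)
    right <- half_max_crossing(ss, prof, i_peak, half, +1L)
    if (is.na(left) || is.na(right)) next
    w <- right - left
    if (w > best$fwhm) {
      mid <- (left + right) / 2
      best <- list(fwhm = w,
                   center = c(y = y0 + mid * sin(th),
                              x = x0 + mid * cos(th)),
                   angle = a)
    }
  }
  resolved <- is.finite(best$fwhm) && best$fwhm > 0
  if (!resolved) {
    warning("punctum at (", y0, ", ", x0, ") unresolved: no profile ",
            "falls below half maximum within max_half_length", call. = FALSE)
    best$fwhm <- NA_real_
  }
  structure(list(preliminary_center = c(y = y0, x = x0),
                 refined_center = best$center, fwhm = best$fwhm,
                 angle = best$angle, resolved = resolved),
            class = "punctum")
}

#' Punctate percentage: fraction of nuclear fluorescence inside puncta
#'
#' On the sum z-projection, draws a disk of diameter equal to its FWHM
#' around each punctum's refined center, and reports 100 x (total
#' intensity inside the union of the disks, clipped to the nucleus mask) /
#' (total intensity inside the mask). Overlapping disks count once.
#'
#' @param stack 3-D (y, x, z) array or matrix; raw intensities.
#' @param mask Logical nucleus mask.
#' @param puncta List of `punctum` objects (see [refine_center_and_fwhm()]);
#'   unresolved puncta are skipped.
#' @return Percentage in `[0, 100]`.
#' @export
punctate_percentage <- function(stack, mask, puncta) {
  sum_img <- project(stack, "sum")
  check_image_mask(sum_img, mask)
  total <- sum(sum_img[mask])
  if (total <= 0) stop("zero total nuclear intensity", call. = FALSE)
  if (length(puncta) == 0L) return(0)
  in_disk <- matrix(FALSE, nrow(sum_img), ncol(sum_img))
  yy <- row(sum_img); xx <- col(sum_img)
  for (p in puncta) {
    if (inherits(p, "punctum") && !isTRUE(p$resolved)) next
    ctr <- p$refined_center
    r <- p$fwhm / 2
    in_disk <- in_disk |
      ((yy - ctr[[1L]])^2 + (xx - ctr[[2L]])^2 <= r^2)
  }
  100 * sum(sum_img[in_disk & mask]) / total
}

#' Quantify the three LLPS parameters of one cell image
#'
#' Runs the full single-image pipeline: maximum projection, normalization
#' to unit nuclear intensity, prominence-based peak detection, per-punctum
#' FWHM refinement, and punctate percentage on the sum projection. The
#' same `noise_tolerance` must be used for the live and fixed image of a
#' pair.
#'
#' @param stack 3-D (y, x, z) array or matrix of raw intensities.
#' @param mask Logical nucleus mask.
#' @param noise_tolerance Prominence threshold on the normalized max
#'   projection (see [find_puncta()]).
#' @param n_slices,max_half_length,step Passed to
#'   [refine_center_and_fwhm()].
#' @param exclude_edge Passed to [find_puncta()].
#' @return A `puncta_quant` list: `n_puncta`, `surface_roughness`,
#'   `punctate_percentage`, plus the detected `puncta` and the
#'   `noise_tolerance` used.
#' @export
quantify_puncta <- function(stack, mask, noise_tolerance,
                            n_slices = 36L, max_half_length = 30,
                            step = 0.25, exclude_edge = FALSE) {
  norm_max <- normalize_to_mask(project(stack, "max"), mask)
  peaks <- find_puncta(norm_max, mask, noise_tolerance,
                       exclude_edge = exclude_edge)
  puncta <- lapply(seq_len(nrow(peaks)), function(i)
    refine_center_and_fwhm(norm_max, c(peaks$y[i], peaks$x[i]),
                           n_slices = n_slices,
                           max_half_length = max_half_length, step = step))
  puncta <- Filter(function(p) isTRUE(p$resolved), puncta)
  structure(list(
    n_puncta = nrow(peaks),
    surface_roughness = surface_roughness(norm_max, mask),
    punctate_percentage = punctate_percentage(stack, mask, puncta),
    puncta = puncta,
    noise_tolerance = noise_tolerance), class = "puncta_quant")
}

#' @export
print.puncta_quant <- function(x, ...) {
  cat(sprintf(
    "<puncta_quant> %d puncta; roughness = %.4g; punctate = %.2f%%\n",
    x$n_puncta, x$surface_roughness, x$punctate_percentage))
  invisible(x)
}

#' Percent change of the LLPS parameters across fixation
#'
#' For each of the three parameters, reports the absolute change
#' (fixed - live) and the percent change `100 * (fixed - live) / live`.
#' A parameter whose live value is 0 has no defined percent change and is
#' flagged invalid (the absolute change is still reported).
#'
#' @param live,fixed `puncta_quant` results for the same cell, computed
#'   with the same noise tolerance.
#' @return A `paired_change` data.frame with one row per parameter:
#'   `parameter`, `live`, `fixed`, `absolute_change`, `percent_change`,
#'   `percent_valid`.
#' @export
compare_live_fixed <- function(live, fixed) {
  stopifnot(inherits(live, "puncta_quant"), inherits(fixed, "puncta_quant"))
  if (!isTRUE(all.equal(live$noise_tolerance, fixed$noise_tolerance)))
    stop("live and fixed images must be quantified with the same ",
         "noise tolerance", call. = FALSE)
  params <- c("n_puncta", "surface_roughness", "punctate_percentage")
  lv <- vapply(params, function(p) as.numeric(live[[p]]), numeric(1))
  fx <- vapply(params, function(p) as.numeric(fixed[[p]]), numeric(1))
  valid <- lv != 0
  pct <- ifelse(valid, 100 * (fx - lv) / lv, NA_real_)
  structure(data.frame(parameter = params, live = lv, fixed = fx,
                       absolute_change = fx - lv, percent_change = pct,
                       percent_valid = valid, row.names = NULL),
            class = c("paired_change", "data.frame"))
}

#' Otsu-threshold nucleus mask (convenience helper)
#'
#' A quick automatic foreground mask from a max projection using Otsu's
#' criterion on a 256-bin histogram. Nucleus borders are normally drawn
#' by hand; this helper only eases synthetic or exploratory use and is
#' not part of the measurement definitions.
#'
#' @param image Numeric matrix.
#' @param nbins Histogram bins (default 256).
#' @return Logical matrix, `TRUE` where `image` exceeds the Otsu threshold.
#' @export
mask_from_otsu <- function(image, nbins = 256L) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- range(image)
  if (rng[1L] == rng[2L]) return(matrix(FALSE, nrow(image), ncol(image)))
  breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(image, breaks, rightmost.closed = TRUE),
                nbins)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / w1
  m2 <- (sum(h * mids) - cumsum(h * mids)) / w2
  between <- w1 * w2 * (m1 - m2)^2
  between[!is.finite(between)] <- -Inf
  image > mids[which.max(between)]
}
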