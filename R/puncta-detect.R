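#' Detect puncta as prominence-filtered local maxima
#'
#' Finds punctum candidate centers in a (normalized) nuclear image the way
#' the ImageJ "find maxima" tool does: a pixel group is reported as a
#' maximum when its prominence — its height above the highest saddle
#' connecting it, within the mask, to any higher maximum — exceeds
#' `noise_tolerance`. Maxima whose prominence does not exceed the tolerance
#' are merged into the higher maximum they drain into (ties keep the first
#' in row-major order). Plateaus return a single representative pixel, the
#' rounded centroid of the plateau.
#'
#' The implementation is a single sweep over mask pixels in decreasing
#' intensity with union-find merging, so the reported prominences are exact
#' (for a component that never meets a higher one, the reference level is
#' the lowest mask pixel it drains over).
#'
#' @param image Numeric matrix (y rows, x columns), typically the
#'   normalized maximum z-projection (see [normalize_to_mask()]).
#' @param mask Logical matrix of the same shape; `TRUE` inside the nucleus.
#' @param noise_tolerance Minimum prominence (same intensity units as
#'   `image`) for a maximum to count; >= 0.
#' @param exclude_edge If `TRUE`, drop maxima whose representative pixel
#'   touches the mask boundary (default keeps them).
#' @return data.frame with one row per punctum: `y`, `x` (integer pixel of
#'   the representative point), `value` (peak intensity) and `prominence`,
#'   ordered by decreasing peak intensity.
#' @examples
#' img <- matrix(0, 32, 32)
#' img[16, 16] <- 1
#' find_puncta(img, matrix(TRUE, 32, 32), noise_tolerance = 0.1)
#' @export
find_puncta <- function(image, mask, noise_tolerance, exclude_edge = FALSE) {
  check_image_mask(image, mask)
  if (!is.numeric(noise_tolerance) || length(noise_tolerance) != 1L ||
      !is.finite(noise_tolerance) || noise_tolerance < 0)
    stop("noise_tolerance must be a single value >= 0", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)

  nr <- nrow(image); nc <- ncol(image)
  idx <- which(mask)                       # linear (column-major) indices
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  val <- image[idx]
  rowmajor <- (row - 1L) * nc + col
  ord <- order(-val, rowmajor)             # decreasing value, ties row-major

  # map linear index -> position in the masked-pixel arrays (0 = outside)
  pos_of <- integer(nr * nc)
  pos_of[idx] <- seq_along(idx)
  processed <- logical(length(idx))

  parent <- seq_along(idx)
  peak_val <- numeric(length(idx))         # indexed by root
  peak_rank <- numeric(length(idx))        # row-major rank of first peak px
  plat_sy <- numeric(length(idx))          # plateau centroid accumulators
  plat_sx <- numeric(length(idx))
  plat_n <- integer(length(idx))
  min_val <- numeric(length(idx))          # lowest level seen by component

  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  accepted <- list()
  n_acc <- 0L
  emit <- function(root, ref_level) {
    n_acc <<- n_acc + 1L
    accepted[[n_acc]] <<- c(
      y = round(plat_sy[root] / plat_n[root]),
      x = round(plat_sx[root] / plat_n[root]),
      value = peak_val[root],
      prominence = peak_val[root] - ref_level)
  }

  doff <- c(-1L, 0L, 1L)
  for (p in ord) {
    v <- val[p]
    r0 <- row[p]; c0 <- col[p]
    roots <- integer(0)
    for (dr in doff) for (dc in doff) {
      if (dr == 0L && dc == 0L) next
      rr <- r0 + dr; cc <- c0 + dc
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      q <- pos_of[(cc - 1L) * nr + rr]
      if (q == 0L || !processed[q]) next
      roots <- c(roots, find_root(q))
    }
    roots <- unique(roots)
    if (length(roots) == 0L) {
      # new candidate maximum
      peak_val[p] <- v
      peak_rank[p] <- rowmajor[p]
      plat_sy[p] <- r0; plat_sx[p] <- c0; plat_n[p] <- 1L
      min_val[p] <- v
      processed[p] <- TRUE
      next
    }
    # pick the surviving root: highest peak, ties -> earliest row-major
    pv <- peak_val[roots]
    pr <- peak_rank[roots]
    keep <- roots[order(-pv, pr)][1L]
    for (rt in roots) {
      if (rt == keep) next
      # component rt meets a higher (or tied) maximum at saddle level v
      if (peak_val[rt] - v > noise_tolerance) emit(rt, v)
      if (peak_val[rt] == v && peak_val[keep] == v) {
        # top-plateau union: combine plateau pixel sets
        plat_sy[keep] <- plat_sy[keep] + plat_sy[rt]
        plat_sx[keep] <- plat_sx[keep] + plat_sx[rt]
        plat_n[keep] <- plat_n[keep] + plat_n[rt]
        peak_rank[keep] <- min(peak_rank[keep], peak_rank[rt])
      }
      parent[rt] <- keep
    }
    parent[p] <- keep
    if (peak_val[keep] == v) {             # p extends the top plateau
      plat_sy[keep] <- plat_sy[keep] + r0
      plat_sx[keep] <- plat_sx[keep] + c0
      plat_n[keep] <- plat_n[keep] + 1L
    }
    min_val[keep] <- min(min_val[keep], v)
    processed[p] <- TRUE
  }

  # surviving components: prominence measured down to their lowest pixel
  for (rt in unique(vapply(which(processed), find_root, integer(1)))) {
    if (peak_val[rt] - min_val[rt] > noise_tolerance) emit(rt, min_val[rt])
  }

  if (n_acc == 0L)
    return(data.frame(y = integer(0), x = integer(0),
                      value = numeric(0), prominence = numeric(0)))
  out <- as.data.frame(do.call(rbind, accepted[seq_len(n_acc)]))
  out$y <- as.integer(out$y); out$x <- as.integer(out$x)
  out <- out[order(-out$value, (out$y - 1L) * nc + out$x), , drop = FALSE]
  rownames(out) <- NULL
  if (exclude_edge) {
    on_edge <- vapply(seq_len(nrow(out)), function(i) {
      yy <- out$y[i]; xx <- out$x[i]
      for (dr in doff) for (dc in doff) {
        rr <- yy + dr; cc <- xx + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc || !mask[rr, cc])
          return(TRUE)
      }
      FALSE
    }, logical(1))
    out <- out[!on_edge, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

check_image_mask <- function(image, mask) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(image)))
    stop("image must contain finite values", call. = FALSE)
  if (!is.matrix(mask) || !is.logical(mask) ||
      !identical(dim(mask), dim(image)))
    stop("mask must be a logical matrix with the same shape as image",
         call. = FALSE)
  invisible(TRUE)
}
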