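#' Read a nuclear z-stack from a multi-page grayscale TIFF
#'
#' @param path Path to a multi-page TIFF; each page becomes one z-plane.
#' @return Numeric (y, x, z) array.
#' @export
read_nucleus_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse grayscale channels
    p
  })
  array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
}

#' Read a nucleus or puncta mask image
#'
#' @param path Single-page TIFF; nonzero pixels are inside.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF masks requires the 'tiff' package", call. = FALSE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0
}

#' Read single-molecule trajectories from CSV
#'
#' Expects columns `trajectory_id`, `frame`, `x`, `y` (pixel units).
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trajectory_id", "frame", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("trajectory table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Write a fixation time course as CSV
#'
#' @param tc A `time_course` from [simulate_time_course()].
#' @param path Output CSV path (columns t, s1, s2, s3, s4).
#' @export
write_time_course <- function(tc, path) {
  out <- data.frame(t = tc$time, s1 = tc$s1, s2 = tc$s2,
                    s3 = tc$s3, s4 = tc$s4)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a phase diagram in long format
#'
#' @param pd A `phase_diagram` from [sweep_phase_diagram()].
#' @param path Output CSV path (columns start_pp, ratio, delta).
#' @export
write_phase_diagram <- function(pd, path) {
  utils::write.csv(as.data.frame(pd), path, row.names = FALSE)
  invisible(path)
}
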