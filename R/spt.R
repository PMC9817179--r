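#' Fraction of a trajectory's localizations inside puncta
#'
#' For each localization of a single-molecule trajectory, looks up the
#' temporally nearest puncta mask (masks are acquired every ~10 s while
#' localizations arrive every frame) and tests whether the localization's
#' pixel is inside a punctum. `F` is the fraction of localizations inside.
#'
#' @param traj data.frame with columns `frame` (strictly increasing
#'   integers), `y`, `x` (pixel coordinates, 1-based; rounded to the
#'   nearest pixel for the mask lookup).
#' @param masks A `mask_series`: list with `times` (seconds, increasing)
#'   and `masks` (list of logical matrices of a common shape, `TRUE`
#'   inside puncta).
#' @param frame_interval Seconds per trajectory frame (default 0.5).
#' @return `F` in `[0, 1]`.
#' @export
fraction_in_puncta <- function(traj, masks, frame_interval = 0.5) {
  check_trajectory(traj)
  check_mask_series(masks)
  t_loc <- (traj$frame - 1) * frame_interval
  shape <- dim(masks$masks[[1L]])
  yy <- round(traj$y); xx <- round(traj$x)
  if (any(yy < 1 | yy > shape[1L] | xx < 1 | xx > shape[2L]))
    stop("trajectory ", if (!is.null(traj$trajectory_id))
           traj$trajectory_id[1L] else "", " has localizations outside ",
         "the mask image bounds", call. = FALSE)
  nearest <- vapply(t_loc, function(t) which.min(abs(masks$times - t)),
                    integer(1))
  inside <- vapply(seq_along(t_loc), function(i)
    masks$masks[[nearest[i]]][yy[i], xx[i]], logical(1))
  mean(inside)
}

#' Classify a trajectory as in-puncta, out-of-puncta, or ambiguous
#'
#' A trajectory with `F > 0.5` is in-puncta and one with `F < 0.05` is
#' out-of-puncta; anything between is ambiguous and excluded from the
#' residence-time analysis (but retained, labelled).
#'
#' @inheritParams fraction_in_puncta
#' @return List with `trajectory`, `F` and `label` ("in", "out",
#'   "ambiguous").
#' @export
classify_trajectory <- function(traj, masks, frame_interval = 0.5) {
  F <- fraction_in_puncta(traj, masks, frame_interval)
  label <- if (F > 0.5) "in" else if (F < 0.05) "out" else "ambiguous"
  list(trajectory = traj, F = F, label = label)
}

#' Classify every trajectory in a table
#'
#' @param trajectories data.frame with columns `trajectory_id`, `frame`,
#'   `y`, `x`.
#' @inheritParams fraction_in_puncta
#' @return data.frame with one row per trajectory: `trajectory_id`, `F`,
#'   `label`, `n_localizations`, `first_frame`, `last_frame`.
#' @export
classify_trajectories <- function(trajectories, masks,
                                  frame_interval = 0.5) {
  stopifnot(is.data.frame(trajectories),
            all(c("trajectory_id", "frame", "y", "x") %in%
                  names(trajectories)))
  ids <- unique(trajectories$trajectory_id)
  rows <- lapply(ids, function(id) {
    tr <- trajectories[trajectories$trajectory_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    cl <- classify_trajectory(tr, masks, frame_interval)
    data.frame(trajectory_id = id, F = cl$F, label = cl$label,
               n_localizations = nrow(tr),
               first_frame = min(tr$frame), last_frame = max(tr$frame))
  })
  do.call(rbind, rows)
}

#' Dwell times of in-puncta trajectories
#'
#' Under slow tracking (long exposures blur out diffusing molecules) a
#' track exists exactly while the molecule is bound, so its dwell time is
#' its observed span: `(last_frame - first_frame + 1) * frame_interval`.
#' Tracks with fewer than 2 localizations are dropped.
#'
#' @param classified data.frame as returned by [classify_trajectories()];
#'   only rows with `label == "in"` are used.
#' @param frame_interval Seconds per frame (> 0).
#' @return Numeric vector of dwell times (s).
#' @export
dwell_times <- function(classified, frame_interval = 0.5) {
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  cl <- classified[classified$label == "in" &
                     classified$n_localizations >= 2L, , drop = FALSE]
  if (nrow(cl) == 0L) {
    warning("no in-puncta trajectories with >= 2 localizations",
            call. = FALSE)
    return(numeric(0))
  }
  (cl$last_frame - cl$first_frame + 1) * frame_interval
}

#' Empirical survival curve of dwell times
#'
#' `P(t)` is the fraction of dwell events lasting at least `t`, evaluated
#' on the grid of observed dwell values, so `P` starts at 1 and is
#' non-increasing.
#'
#' @param dwells Numeric vector of dwell times (s), non-empty.
#' @return data.frame with columns `t` (sorted unique dwell values) and
#'   `P`.
#' @export
survival_curve <- function(dwells) {
  if (length(dwells) == 0L) stop("empty dwell set", call. = FALSE)
  t <- sort(unique(dwells))
  P <- vapply(t, function(ti) mean(dwells >= ti), numeric(1))
  data.frame(t = t, P = P)
}

two_exp <- function(t, A, l_s, dl) {
  t <- pmax(t, 0)
  A * exp(-(l_s + dl) * t) + (1 - A) * exp(-l_s * t)
}

#' Fit the two-exponential residence-time model to a survival curve
#'
#' Fits \deqn{P(t) = A e^{-\lambda_{ns} t} + (1 - A) e^{-\lambda_s t}}
#' by constrained least squares on the empirical survival curve, with
#' `0 <= A <= 1` and `lambda_ns >= lambda_s > 0` (`A` weights the fast,
#' nonspecific component; `tau_ns = 1/lambda_ns <= tau_s = 1/lambda_s`).
#' The ordering is enforced by parameterising
#' `lambda_ns = lambda_s + delta, delta >= 0`, and the fit is restarted
#' from 5 log-spaced rate pairs spanning the observed time range, keeping
#' the lowest residual sum of squares.
#'
#' The model clock starts at `t0`, the shortest observable dwell (default
#' `min(curve$t)`): dwell times recorded in discrete frames are rounded up
#' to whole frames, so the empirical survival at a grid time `t` reflects
#' continuous survival beyond `t - t0`, and fitting without the offset
#' biases the recovered rates. For continuous (unquantized) dwells the
#' offset is negligible. The model form pins `P(t0) = 1`, and
#' [predict.survival_fit()] clamps earlier times so `P(0) = 1` exactly.
#'
#' @param curve data.frame from [survival_curve()]; a warning is issued
#'   when built from fewer than 50 dwells.
#' @param n_starts Number of multistarts (default 5).
#' @param t0 Model time origin (s); default `min(curve$t)`.
#' @return A `survival_fit` list: `A`, `lambda_ns`, `lambda_s`, `tau_ns`,
#'   `tau_s`, `t0`, `residual` (RSS), `n_points`, `boundary_A` (TRUE when
#'   A is pinned at 0 or 1, e.g. a pure single exponential).
#' @export
fit_two_exponential <- function(curve, n_starts = 5L,
                                t0 = min(curve$t)) {
  stopifnot(is.data.frame(curve), all(c("t", "P") %in% names(curve)))
  if (nrow(curve) < 4L)
    stop("survival curve has too few points to fit a two-exponential ",
         "model", call. = FALSE)
  if (nrow(curve) < 50L)
    warning("survival curve built from few dwells (< 50 distinct times); ",
            "fit may be unstable", call. = FALSE)
  # rate starts spanning the observed dwell range: slow rates near the
  # longest dwells, fast rates near the shortest
  t_pos <- curve$t[curve$t > t0]
  if (length(t_pos) == 0L) t_pos <- max(curve$t)
  rate_lo <- 0.5 / max(curve$t)
  rate_hi <- 2 / max(stats::quantile(t_pos - t0, 0.05), max(curve$t) / 1e4)
  starts <- 10 ^ seq(log10(rate_lo), log10(rate_hi),
                     length.out = n_starts)
  best <- NULL
  keep_best <- function(A, l_s, dl) {
    rss <- sum((curve$P - two_exp(curve$t - t0, A, l_s, dl))^2)
    if (is.null(best) || rss < best$rss)
      best <<- list(A = A, l_s = l_s, dl = dl, rss = rss)
  }
  for (l0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        P ~ two_exp(t - t0, A, l_s, dl), data = curve,
        start = list(A = 0.5, l_s = l0, dl = 10 * l0),
        lower = c(A = 0, l_s = 1e-12, dl = 0),
        upper = c(A = 1, l_s = Inf, dl = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    keep_best(unname(cf[["A"]]), unname(cf[["l_s"]]), unname(cf[["dl"]]))
  }
  # box-constrained quasi-Newton fallback: immune to the singular
  # gradients a degenerate (single-exponential) mixture induces in LM
  obj <- function(par) {
    sum((curve$P - two_exp(curve$t - t0, par[1L], exp(par[2L]),
                           exp(par[3L])))^2)
  }
  for (l0 in starts) {
    op <- tryCatch(
      stats::optim(c(0.5, log(l0), log(10 * l0)), obj,
                   method = "L-BFGS-B",
                   lower = c(0, -30, -30), upper = c(1, 30, 30)),
      error = function(e) NULL)
    if (is.null(op)) next
    keep_best(op$par[1L], exp(op$par[2L]), exp(op$par[3L]))
  }
  if (is.null(best))
    stop("two-exponential fit failed to converge from any start; ",
         "check the survival curve", call. = FALSE)
  A <- best$A; l_s <- best$l_s
  l_ns <- l_s + best$dl
  boundary_A <- A <= 1e-6 || A >= 1 - 1e-6
  structure(list(A = A, lambda_ns = l_ns, lambda_s = l_s,
                 tau_ns = 1 / l_ns, tau_s = 1 / l_s, t0 = t0,
                 residual = best$rss, n_points = nrow(curve),
                 boundary_A = boundary_A),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf(
    "<survival_fit> A = %.3f; tau_ns = %.3g s; tau_s = %.3g s (RSS %.3g)%s\n",
    x$A, x$tau_ns, x$tau_s, x$residual,
    if (x$boundary_A) " [A at boundary]" else ""))
  invisible(x)
}

#' Predict the fitted survival model
#'
#' @param object A `survival_fit`.
#' @param t Times (s).
#' @param ... Unused.
#' @return `P(t)` under the fitted model; exactly 1 at and before the
#'   model origin `t0`, hence exactly 1 at `t = 0`.
#' @export
predict.survival_fit <- function(object, t, ...) {
  tt <- pmax(t - object$t0, 0)
  object$A * exp(-object$lambda_ns * tt) +
    (1 - object$A) * exp(-object$lambda_s * tt)
}

#' Photobleaching correction of the specific residence time
#'
#' An apparent residence time is shortened by fluorophore photobleaching.
#' With H2B — effectively immobile on chromatin — as the bleach reference,
#' the true residence time follows from subtracting rates:
#' \deqn{\tau_{corrected} = \frac{1}{1/\tau_s - 1/\tau_{H2B}}}
#' which requires `tau_s < tau_H2B` (the apparent time cannot exceed the
#' bleach-limited reference).
#'
#' @param tau_s Fitted specific residence time (s), > 0.
#' @param tau_H2B Session-matched H2B specific residence time (s), > 0.
#' @return A `corrected_residence` list: `tau_s`, `tau_H2B`,
#'   `tau_corrected`.
#' @examples
#' photobleach_correct(10, 30)$tau_corrected  # 15
#' @export
photobleach_correct <- function(tau_s, tau_H2B) {
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be > 0",
                                            call. = FALSE)
  if (tau_H2B <= 0) stop("tau_H2B must be > 0", call. = FALSE)
  if (tau_s >= tau_H2B)
    stop("correction undefined: apparent residence time (", tau_s,
         " s) meets or exceeds the bleach-limited reference (", tau_H2B,
         " s)", call. = FALSE)
  structure(list(tau_s = tau_s, tau_H2B = tau_H2B,
                 tau_corrected = 1 / (1 / tau_s - 1 / tau_H2B)),
            class = "corrected_residence")
}

#' Summarize corrected residence times across cells
#'
#' Per-cell corrected residence times are averaged arithmetically with
#' standard error `sd/sqrt(n)`; when two conditions are given they are
#' compared by the two-sided Wilcoxon rank-sum test.
#'
#' @param per_cell Named list of numeric vectors, one per condition, each
#'   the per-cell corrected residence times (s); >= 2 cells per condition.
#' @return List with a `summary` data.frame (`condition`, `n`, `mean`,
#'   `sem`) and, when exactly two conditions are supplied, `p_value` and
#'   `statistic` of the rank-sum comparison.
#' @export
summarize_residence <- function(per_cell) {
  stopifnot(is.list(per_cell), length(per_cell) >= 1L)
  if (is.null(names(per_cell)))
    names(per_cell) <- paste0("condition", seq_along(per_cell))
  ns <- lengths(per_cell)
  if (any(ns < 2L))
    stop("each condition needs >= 2 cells", call. = FALSE)
  summary <- data.frame(
    condition = names(per_cell), n = as.integer(ns),
    mean = vapply(per_cell, mean, numeric(1)),
    sem = vapply(per_cell, function(x) stats::sd(x) / sqrt(length(x)),
                 numeric(1)),
    row.names = NULL)
  out <- list(summary = summary)
  if (length(per_cell) == 2L) {
    ht <- wilcoxon_rank_sum(per_cell[[1L]], per_cell[[2L]])
    out$p_value <- ht$p_value
    out$statistic <- ht$statistic
  }
  out
}

check_trajectory <- function(traj) {
  stopifnot(is.data.frame(traj),
            all(c("frame", "y", "x") %in% names(traj)))
  if (nrow(traj) < 1L) stop("trajectory has no localizations",
                            call. = FALSE)
  if (is.unsorted(traj$frame, strictly = TRUE))
    stop("trajectory frames must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

check_mask_series <- function(masks) {
  stopifnot(is.list(masks), all(c("times", "masks") %in% names(masks)))
  if (length(masks$times) != length(masks$masks) ||
      length(masks$masks) == 0L)
    stop("mask series must pair one time with each mask", call. = FALSE)
  if (is.unsorted(masks$times, strictly = TRUE))
    stop("mask times must be increasing", call. = FALSE)
  shapes <- vapply(masks$masks, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("all masks must share one shape", call. = FALSE)
  invisible(TRUE)
}

#' Construct a puncta mask time series
#'
#' @param times Acquisition times (s), strictly increasing.
#' @param masks List of logical matrices of a common shape.
#' @return A `mask_series` list.
#' @export
mask_series <- function(times, masks) {
  out <- list(times = times, masks = masks)
  check_mask_series(out)
  structure(out, class = "mask_series")
}
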