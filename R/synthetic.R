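#' Specification for a synthetic nucleus image
#'
#' Describes a synthetic fluorescence z-stack of one nucleus: an elliptical
#' nucleus region with diffuse background, a number of Gaussian-profile
#' puncta of controlled amplitude and width, and additive Gaussian noise.
#' Defaults give a 128 x 128 x 5 stack with 12 well-separated puncta at
#' 50:1 amplitude-to-noise — bright droplet-like condensates over an even
#' nucleoplasm, the regime in which the quantification pipeline is meant
#' to operate.
#'
#' The minimum separation must be at least `6 * sigma` so that planted
#' puncta stay individually resolvable (each is a distinct maximum).
#'
#' @param shape Integer `c(ny, nx, nz)`; default 128 x 128 x 5.
#' @param nucleus Named list `center = c(y, x)`, `semiaxes = c(ry, rx)`;
#'   defaults to an ellipse filling most of the frame.
#' @param n_puncta Number of puncta (>= 0).
#' @param sigma Lateral punctum width (px); axial width is `2 * sigma`.
#' @param amplitude Peak punctum intensity above background.
#' @param background Diffuse intensity inside the nucleus.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param min_separation Minimum center-to-center distance between planted
#'   puncta (px), >= `6 * sigma`.
#' @param seed Integer RNG seed; the generated stack is a pure function of
#'   the spec including this seed.
#' @return A `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(shape = c(128L, 128L, 5L),
                                 nucleus = NULL,
                                 n_puncta = 12L, sigma = 2,
                                 amplitude = 50, background = 10,
                                 noise_sd = 1, min_separation = 20,
                                 seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1L), n_puncta >= 0,
            sigma > 0, amplitude >= 0, background >= 0, noise_sd >= 0)
  if (min_separation < 6 * sigma)
    stop("min_separation must be >= 6 * sigma so planted puncta remain ",
         "resolvable", call. = FALSE)
  if (is.null(nucleus))
    nucleus <- list(center = (shape[1:2] + 1) / 2,
                    semiaxes = shape[1:2] / 2 - 4)
  structure(list(shape = as.integer(shape), nucleus = nucleus,
                 n_puncta = as.integer(n_puncta), sigma = sigma,
                 amplitude = amplitude, background = background,
                 noise_sd = noise_sd, min_separation = min_separation,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

ellipse_mask <- function(ny, nx, center, semiaxes) {
  yy <- row(matrix(0, ny, nx)); xx <- col(matrix(0, ny, nx))
  ((yy - center[1L]) / semiaxes[1L])^2 +
    ((xx - center[2L]) / semiaxes[2L])^2 <= 1
}

place_puncta <- function(spec, max_tries = 20000L) {
  cy <- spec$nucleus$center[1L]; cx <- spec$nucleus$center[2L]
  ry <- spec$nucleus$semiaxes[1L]; rx <- spec$nucleus$semiaxes[2L]
  margin <- 3 * spec$sigma
  centers <- matrix(numeric(0), ncol = 2L)
  tries <- 0L
  while (nrow(centers) < spec$n_puncta) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", spec$n_puncta, " puncta at separation ",
           spec$min_separation, " px inside the nucleus; request fewer ",
           "puncta or a larger nucleus", call. = FALSE)
    u <- stats::runif(1L, -1, 1); v <- stats::runif(1L, -1, 1)
    if (u^2 + v^2 > 1) next
    cand <- c(cy + u * (ry - margin), cx + v * (rx - margin))
    if (nrow(centers) > 0L &&
        min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) <
          spec$min_separation) next
    centers <- rbind(centers, cand)
  }
  centers
}

render_stack <- function(spec, centers, amplitudes) {
  ny <- spec$shape[1L]; nx <- spec$shape[2L]; nz <- spec$shape[3L]
  mask <- ellipse_mask(ny, nx, spec$nucleus$center, spec$nucleus$semiaxes)
  plane0 <- matrix(0, ny, nx)
  plane0[mask] <- spec$background
  yy <- row(plane0); xx <- col(plane0)
  sz <- 2 * spec$sigma
  cz <- (nz + 1) / 2
  stack <- array(0, dim = c(ny, nx, nz))
  for (z in seq_len(nz)) {
    plane <- plane0
    if (nrow(centers) > 0L) {
      zfac <- exp(-(z - cz)^2 / (2 * sz^2))
      for (i in seq_len(nrow(centers))) {
        plane <- plane + amplitudes[i] * zfac *
          exp(-((yy - centers[i, 1L])^2 + (xx - centers[i, 2L])^2) /
                (2 * spec$sigma^2))
      }
    }
    stack[, , z] <- plane
  }
  if (spec$noise_sd > 0)
    stack <- stack + stats::rnorm(length(stack), sd = spec$noise_sd)
  stack[stack < 0] <- 0
  list(stack = stack, mask = mask)
}

#' Generate a synthetic nucleus z-stack with ground truth
#'
#' Renders `background + sum of 3-D Gaussian puncta + Gaussian noise`
#' (clipped at 0) inside an elliptical nucleus, with punctum centers drawn
#' uniformly in the nucleus under the spec's minimum-separation
#' constraint. Deterministic: the same spec (including seed) reproduces
#' the identical stack.
#'
#' @param spec A [synthetic_image_spec()].
#' @return List with `stack` (y, x, z array), `mask` (logical nucleus
#'   mask) and `truth` (`synthetic_ground_truth`: planted `centers`,
#'   `sigma`, `amplitudes`, the generating `spec`).
#' @export
make_nucleus_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  centers <- place_puncta(spec)
  amplitudes <- rep(spec$amplitude, spec$n_puncta)
  r <- render_stack(spec, centers, amplitudes)
  truth <- structure(list(centers = centers, sigma = spec$sigma,
                          amplitudes = amplitudes, spec = spec,
                          seed = spec$seed),
                     class = "synthetic_ground_truth")
  list(stack = r$stack, mask = r$mask, truth = truth)
}

#' Generate a paired live/fixed synthetic cell with planted changes
#'
#' The live image is rendered from `base`; the fixed image reuses the live
#' ground truth with the punctum count scaled by
#' `effect$puncta_count_factor` (extra puncta placed with the same
#' separation constraint; removals drop the last-placed puncta) and
#' punctum amplitude scaled by `effect$amplitude_factor`, then re-rendered
#' with an independent noise realization. The planted sign of each LLPS
#' parameter change is recorded: more/brighter puncta raise roughness and
#' punctate percentage, fewer/dimmer lower them; when the two factors pull
#' in opposite directions the sign is recorded as `NA`.
#'
#' @param base A [synthetic_image_spec()] for the live image.
#' @param effect Named list with `puncta_count_factor` and
#'   `amplitude_factor` (both > 0; 1 = no change).
#' @return List with `live`, `fixed` (each as [make_nucleus_stack()]
#'   output) and `truth_signs` (named vector over `n_puncta`,
#'   `surface_roughness`, `punctate_percentage` with values -1, 0, 1 or
#'   NA).
#' @export
make_live_fixed_pair <- function(base,
                                 effect = list(puncta_count_factor = 1,
                                               amplitude_factor = 1)) {
  stopifnot(inherits(base, "synthetic_image_spec"))
  cf <- effect$puncta_count_factor %||% 1
  af <- effect$amplitude_factor %||% 1
  if (cf <= 0 || af <= 0) stop("effect factors must be > 0", call. = FALSE)
  live <- make_nucleus_stack(base)
  n_fixed <- as.integer(round(base$n_puncta * cf))
  set.seed(base$seed + 1000003L)
  centers <- live$truth$centers
  if (n_fixed < nrow(centers)) {
    centers <- centers[seq_len(n_fixed), , drop = FALSE]
  } else if (n_fixed > nrow(centers)) {
    spec_extra <- base
    spec_extra$n_puncta <- n_fixed
    # extend the live placement, keeping existing centers
    margin <- 3 * base$sigma
    tries <- 0L
    while (nrow(centers) < n_fixed) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("could not place additional fixed-image puncta; lower the ",
             "count factor", call. = FALSE)
      u <- stats::runif(1L, -1, 1); v <- stats::runif(1L, -1, 1)
      if (u^2 + v^2 > 1) next
      cand <- c(base$nucleus$center[1L] +
                  u * (base$nucleus$semiaxes[1L] - margin),
                base$nucleus$center[2L] +
                  v * (base$nucleus$semiaxes[2L] - margin))
      if (min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) <
            base$min_separation) next
      centers <- rbind(centers, cand)
    }
  }
  amplitudes <- rep(base$amplitude * af, nrow(centers))
  r <- render_stack(base, centers, amplitudes)
  fixed_truth <- structure(list(centers = centers, sigma = base$sigma,
                                amplitudes = amplitudes, spec = base,
                                seed = base$seed + 1000003L),
                           class = "synthetic_ground_truth")
  sign_of <- function(x) if (x > 0) 1 else if (x < 0) -1 else 0
  d_count <- sign_of(n_fixed - base$n_puncta)
  d_amp <- sign_of(af - 1)
  # roughness and punctate % increase with both count and amplitude
  combined <- if (d_count == 0 && d_amp == 0) 0
  else if (d_count >= 0 && d_amp >= 0) 1
  else if (d_count <= 0 && d_amp <= 0) -1
  else NA_real_
  list(live = live,
       fixed = list(stack = r$stack, mask = r$mask, truth = fixed_truth),
       truth_signs = c(n_puncta = d_count,
                       surface_roughness = combined,
                       punctate_percentage = combined))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification for synthetic dwell-time sets
#'
#' Parameters of the two-component exponential residence-time mixture with
#' photobleaching: a fraction `A` of binding events is nonspecific with
#' mean `tau_ns`, the rest specific with mean `tau_s`; bleaching truncates
#' every event with rate `1/tau_bleach` (observed rate = component rate +
#' bleach rate — the composition under which the rate-subtraction
#' correction is exact). Dwells are quantized up to multiples of the frame
#' interval (a molecule present during any part of a frame is seen in it)
#' and capped at the observation `window`.
#'
#' @param A Nonspecific mixture weight in `[0, 1]`.
#' @param tau_ns Nonspecific (fast) residence time (s); must be <
#'   `tau_s`.
#' @param tau_s Specific (slow) residence time (s).
#' @param tau_bleach Photobleaching time constant (s); `Inf` for no
#'   bleaching.
#' @param n Number of dwell events.
#' @param frame_interval Seconds per frame (default 0.5).
#' @param window Observation window (s), default `Inf`; a 2000-frame movie
#'   at 0.5 s gives 1000.
#' @param seed Integer RNG seed.
#' @return A `synthetic_dwell_spec` list.
#' @export
synthetic_dwell_spec <- function(A, tau_ns, tau_s, tau_bleach = Inf,
                                 n = 5000L, frame_interval = 0.5,
                                 window = Inf, seed = 1L) {
  stopifnot(A >= 0, A <= 1, tau_ns > 0, tau_s > 0, tau_bleach > 0,
            n >= 1, frame_interval > 0, window > 0)
  if (tau_ns >= tau_s)
    stop("tau_ns must be < tau_s (fast nonspecific, slow specific)",
         call. = FALSE)
  structure(list(A = A, tau_ns = tau_ns, tau_s = tau_s,
                 tau_bleach = tau_bleach, n = as.integer(n),
                 frame_interval = frame_interval, window = window,
                 seed = as.integer(seed)),
            class = "synthetic_dwell_spec")
}

#' Draw synthetic dwell times from the bleached two-exponential mixture
#'
#' @param spec A [synthetic_dwell_spec()].
#' @return List with `dwells` (numeric, s) and `truth` (the spec plus the
#'   per-event observed rates).
#' @export
make_dwell_times <- function(spec) {
  stopifnot(inherits(spec, "synthetic_dwell_spec"))
  set.seed(spec$seed)
  bleach_rate <- if (is.finite(spec$tau_bleach)) 1 / spec$tau_bleach else 0
  is_ns <- stats::runif(spec$n) < spec$A
  rate <- ifelse(is_ns, 1 / spec$tau_ns, 1 / spec$tau_s) + bleach_rate
  d <- stats::rexp(spec$n, rate)
  d <- pmin(d, spec$window)
  dt <- spec$frame_interval
  d <- ceiling(d / dt) * dt
  list(dwells = d,
       truth = structure(list(spec = spec, component_ns = is_ns,
                              seed = spec$seed),
                         class = "synthetic_ground_truth"))
}

#' Generate trajectories with known in/out/ambiguous labels
#'
#' Builds single-molecule trajectories against a puncta mask series with
#' controlled fraction-in-puncta: "in" trajectories localize entirely
#' inside puncta (F = 1), "out" entirely outside (F = 0), "ambiguous"
#' trajectories place 30% of localizations inside (F = 0.3, between the
#' 5% and 50% classification thresholds).
#'
#' @param masks A [mask_series()]; every mask must contain pixels of the
#'   classes being generated (inside for in/ambiguous, outside for
#'   out/ambiguous).
#' @param n_in,n_out,n_ambiguous Counts per class.
#' @param n_frames Localizations per trajectory (default 20).
#' @param frame_interval Seconds per frame (default 0.5).
#' @param seed Integer RNG seed.
#' @return List with `trajectories` (data.frame: `trajectory_id`, `frame`,
#'   `y`, `x`) and `truth` (data.frame: `trajectory_id`, `label`, `F`).
#' @export
make_trajectory_set <- function(masks, n_in, n_out, n_ambiguous = 0L,
                                n_frames = 20L, frame_interval = 0.5,
                                seed = 1L) {
  check_mask_series(masks)
  set.seed(seed)
  ok_in <- vapply(masks$masks, any, logical(1))
  ok_out <- vapply(masks$masks, function(m) any(!m), logical(1))
  if ((n_in > 0 || n_ambiguous > 0) && !all(ok_in))
    stop("a mask has no in-puncta pixels; cannot build in/ambiguous ",
         "trajectories", call. = FALSE)
  if ((n_out > 0 || n_ambiguous > 0) && !all(ok_out))
    stop("a mask has no out-of-puncta pixels; cannot build ",
         "out/ambiguous trajectories", call. = FALSE)
  nr <- nrow(masks$masks[[1L]])
  labels <- rep(c("in", "out", "ambiguous"),
                times = c(n_in, n_out, n_ambiguous))
  rows <- vector("list", length(labels))
  truth <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    n_inside <- switch(labels[i],
                       "in" = n_frames,
                       "out" = 0L,
                       "ambiguous" = max(1L, floor(0.3 * n_frames)))
    start <- sample.int(50L, 1L)
    frames <- start + seq_len(n_frames) - 1L
    t_loc <- (frames - 1L) * frame_interval
    nearest <- vapply(t_loc, function(t)
      which.min(abs(masks$times - t)), integer(1))
    inside <- rep(c(TRUE, FALSE), times = c(n_inside, n_frames - n_inside))
    # sample each localization from its temporally nearest mask so the
    # planted F survives time-varying mask series
    lin <- vapply(seq_len(n_frames), function(j) {
      m <- masks$masks[[nearest[j]]]
      pool <- if (inside[j]) which(m) else which(!m)
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    rows[[i]] <- data.frame(trajectory_id = paste0("traj", i),
                            frame = frames,
                            y = ((lin - 1L) %% nr) + 1L,
                            x = ((lin - 1L) %/% nr) + 1L)
    truth[[i]] <- data.frame(trajectory_id = paste0("traj", i),
                             label = labels[i],
                             F = n_inside / n_frames)
  }
  list(trajectories = do.call(rbind, rows),
       truth = do.call(rbind, truth))
}
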