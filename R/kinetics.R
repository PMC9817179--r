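#' Kinetic rate set for the four-state fixation model
#'
#' Bundles the four mass-action rate constants of the fixation model. A
#' protein of interest (POI) exchanges between an in-puncta pool (S1) and an
#' out-of-puncta pool (S2) with binding rate `k1` (S2 -> S1) and dissociation
#' rate `k2` (S1 -> S2). From the moment fixative is added, molecules are
#' irreversibly cross-linked in place: S1 -> S3 at rate `k3` (in-puncta
#' fixation) and S2 -> S4 at rate `k4` (out-of-puncta fixation).
#'
#' All rates are in 1/s. At least one of `k3`, `k4` must be positive,
#' otherwise fixation never completes.
#'
#' @param k1 Binding rate into puncta (1/s).
#' @param k2 Dissociation rate out of puncta (1/s).
#' @param k3 In-puncta fixation rate (1/s).
#' @param k4 Out-of-puncta fixation rate (1/s).
#' @return An object of class `rate_set`: a named list with elements
#'   `k1`, `k2`, `k3`, `k4` and the equilibrium constant `Keq = k1/k2`
#'   (`Inf` when `k2 = 0`).
#' @examples
#' rate_set(k1 = 0.5, k2 = 0.5, k3 = 0.1, k4 = 0.2)
#' @export
rate_set <- function(k1, k2, k3, k4) {
  rates <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  if (k3 + k4 <= 0)
    stop("k3 + k4 must be > 0: fixation never completes otherwise",
         call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                 Keq = if (k2 > 0) k1 / k2 else Inf),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf(
    "<rate_set> k1 = %g, k2 = %g, k3 = %g, k4 = %g (1/s); Keq = %g\n",
    x$k1, x$k2, x$k3, x$k4, x$Keq))
  invisible(x)
}

#' Exchange rates consistent with an equilibrium punctate percentage
#'
#' Solves for the binding/dissociation pair `(k1, k2)` that puts the
#' live-cell equilibrium at a given punctate percentage while constraining
#' the total exchange rate `k1 + k2`. At equilibrium the in-puncta fraction
#' is `k1 / (k1 + k2)` (from `Keq = k1/k2 = S1eq/S2eq`), so 0% maps to
#' `(0, total_exchange)` and 100% to `(total_exchange, 0)`.
#'
#' @param start_pp Starting (live-cell) punctate percentage, in `[0, 100]`.
#' @param total_exchange Total exchange rate `k1 + k2` (1/s), > 0.
#' @return Named numeric vector `c(k1 = , k2 = )`.
#' @examples
#' rates_from_equilibrium(50, 1)   # c(k1 = 0.5, k2 = 0.5)
#' rates_from_equilibrium(0, 1)    # c(k1 = 0,   k2 = 1)
#' @export
rates_from_equilibrium <- function(start_pp, total_exchange) {
  check_percent(start_pp)
  if (!is.finite(total_exchange) || total_exchange <= 0)
    stop("total_exchange must be > 0", call. = FALSE)
  k1 <- total_exchange * start_pp / 100
  c(k1 = k1, k2 = max(0, total_exchange - k1))
}

#' Initial state vector at the moment of fixative addition
#'
#' At t = 0 the fixed pools are empty (`s3 = s4 = 0`) and the unfixed
#' protein is partitioned at its live-cell equilibrium: `s1 = start_pp/100`,
#' `s2 = 1 - s1`. Total molarity is normalised to 1 mol/L.
#'
#' @inheritParams rates_from_equilibrium
#' @return Named numeric vector `c(s1, s2, s3, s4)` summing to 1.
#' @export
initial_state <- function(start_pp) {
  check_percent(start_pp)
  s1 <- start_pp / 100
  c(s1 = s1, s2 = 1 - s1, s3 = 0, s4 = 0)
}

#' Equilibrium punctate percentage implied by the exchange rates
#'
#' The live-cell equilibrium is set by binding and dissociation alone:
#' `100 * k1 / (k1 + k2)`. This is the natural starting point of every
#' fixation simulation; explicitly passing a different `start_pp` to the
#' simulation functions models a cell that is off its exchange
#' equilibrium at the moment of fixative addition.
#'
#' @param rates A [rate_set()] with `k1 + k2 > 0`.
#' @return Percentage in `[0, 100]`.
#' @export
equilibrium_start <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  if (rates$k1 + rates$k2 <= 0)
    stop("k1 + k2 must be > 0 to define an equilibrium start",
         call. = FALSE)
  100 * rates$k1 / (rates$k1 + rates$k2)
}

check_percent <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 100)
    stop("punctate percentage must be a single value in [0, 100]",
         call. = FALSE)
  invisible(p)
}

four_state_deriv <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    list(c(
      s1 = k1 * s2 - (k2 + k3) * s1,
      s2 = k2 * s1 - (k1 + k4) * s2,
      s3 = k3 * s1,
      s4 = k4 * s2
    ))
  })
}

#' Simulate the fixation time course
#'
#' Integrates the mass-action system
#' \deqn{dS1/dt = k_1 S2 - (k_2 + k_3) S1, \quad
#'       dS2/dt = k_2 S1 - (k_1 + k_4) S2, \quad
#'       dS3/dt = k_3 S1, \quad dS4/dt = k_4 S2}
#' from the live-cell equilibrium at `start_pp` using a stiff-capable
#' implicit solver (BDF, rtol 1e-8, atol 1e-10; rate ratios up to 1e3
#' are in scope).
#'
#' @param rates A [rate_set()].
#' @param start_pp Starting punctate percentage, in `[0, 100]`. Defaults
#'   to the equilibrium implied by `k1`, `k2` (see [equilibrium_start()]);
#'   pass a value explicitly to start off-equilibrium.
#' @param t_end Final time (s), > 0.
#' @param n_points Number of output time points (>= 2), equally spaced
#'   from 0 to `t_end`.
#' @return A `time_course` object: a data.frame with columns
#'   `time, s1, s2, s3, s4`.
#' @examples
#' tc <- simulate_time_course(rate_set(0.5, 0.5, 0.1, 0.1), 50,
#'                            t_end = 200, n_points = 101)
#' tail(tc, 1)  # ~ (0, 0, 0.5, 0.5)
#' @export
simulate_time_course <- function(rates, start_pp = equilibrium_start(rates),
                                 t_end, n_points = 200L) {
  stopifnot(inherits(rates, "rate_set"))
  check_percent(start_pp)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  times <- seq(0, t_end, length.out = n_points)
  out <- deSolve::ode(
    y = initial_state(start_pp), times = times, func = four_state_deriv,
    parms = unlist(rates[c("k1", "k2", "k3", "k4")]),
    method = "bdf", rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE solver failed to converge; diagnostics: ",
         paste(deSolve::diagnostics(out), collapse = " "), call. = FALSE)
  out <- as.data.frame(out)
  names(out)[1L] <- "time"
  class(out) <- c("time_course", "data.frame")
  out
}

#' Exact fixed-state composition at t = infinity
#'
#' Fixation to S3 and S4 is irreversible, so all protein eventually
#' ends up fixed. The terminal split is obtained in closed form: with the
#' transient generator
#' \deqn{M = \begin{pmatrix} -(k_2+k_3) & k_1 \\ k_2 & -(k_1+k_4) \end{pmatrix}}
#' and initial unfixed concentrations `x0`, the time-integrals of S1 and S2
#' are `I = solve(-M, x0)`, giving `s3_inf = k3 * I[1]` and
#' `s4_inf = k4 * I[2]`. This is exact; no finite-time truncation is
#' involved.
#'
#' @inheritParams simulate_time_course
#' @return Named numeric vector `c(s3_inf, s4_inf)` summing to 1.
#' @examples
#' final_fixed_state(rate_set(0.15, 0.15, 1, 2), 50)
#' # s3_inf = 0.46939, s4_inf = 0.53061
#' @export
final_fixed_state <- function(rates, start_pp = equilibrium_start(rates)) {
  stopifnot(inherits(rates, "rate_set"))
  check_percent(start_pp)
  k1 <- rates$k1; k2 <- rates$k2; k3 <- rates$k3; k4 <- rates$k4
  x0 <- initial_state(start_pp)[c("s1", "s2")]
  # det(-M) = k1*k3 + k2*k4 + k3*k4; zero only when some unfixed mass can
  # neither fix nor exchange into a pool that fixes
  det_negM <- k1 * k3 + k2 * k4 + k3 * k4
  if (det_negM <= 0) {
    if (k3 + k4 <= 0)
      stop("fixation never completes: k3 = k4 = 0", call. = FALSE)
    stop("degenerate rates: part of the protein pool can never be fixed ",
         "(singular transient generator)", call. = FALSE)
  }
  negM <- matrix(c(k2 + k3, -k2, -k1, k1 + k4), nrow = 2L)
  I <- solve(negM, x0)
  out <- c(s3_inf = k3 * I[[1L]], s4_inf = k4 * I[[2L]])
  stopifnot(abs(sum(out) - 1) < 1e-9)
  out
}

#' Fixation artifact statistic: change in punctate percentage
#'
#' The artifact statistic is the punctate percentage of the fully fixed
#' cell minus that of the live cell:
#' \deqn{\Delta PP = 100 \cdot \frac{S3_\infty}{S3_\infty + S4_\infty} -
#'   100 \cdot \frac{S1_0}{S1_0 + S2_0}}
#' A positive value means fixation over-represents the punctate (LLPS)
#' appearance; a negative value means it is diminished. For equilibrium
#' starts (the default), `delta = 0` whenever `k3 = k4`, and at the
#' 0%/100% boundaries (which equilibrium requires `k1 = 0` resp.
#' `k2 = 0`).
#'
#' @inheritParams simulate_time_course
#' @return An `artifact_result` list with `initial_punctate_percentage`,
#'   `final_punctate_percentage` and `delta` (percentage points).
#' @examples
#' delta_punctate_percentage(rate_set(0.15, 0.15, 1, 2), 50)$delta  # -3.06
#' @export
delta_punctate_percentage <- function(rates,
                                      start_pp = equilibrium_start(rates)) {
  fin <- final_fixed_state(rates, start_pp)
  final_pp <- 100 * fin[["s3_inf"]] / sum(fin)
  structure(list(initial_punctate_percentage = start_pp,
                 final_punctate_percentage = final_pp,
                 delta = final_pp - start_pp),
            class = "artifact_result")
}

#' @export
print.artifact_result <- function(x, ...) {
  cat(sprintf("<artifact_result> %.3f%% -> %.3f%% (delta = %+.3f pp)\n",
              x$initial_punctate_percentage, x$final_punctate_percentage,
              x$delta))
  invisible(x)
}

#' Phase diagram of the fixation artifact
#'
#' Sweeps the artifact statistic over a grid of starting punctate
#' percentages (rows of the returned matrix) against a rate-ratio axis
#' (columns), in one of two modes:
#'
#' * `"relative-in-puncta"`: the column axis is the in/out fixation-rate
#'   ratio `k3:k4` at constant overall rates (`k3 + k4 = 0.2`,
#'   `k1 + k2 = 1` by default).
#' * `"relative-overall"`: the column axis is the relative overall fixation
#'   rate `(k3+k4):(k1+k2)` at constant individual fixation rates
#'   (`k3 = 1`, `k4 = 2` by default).
#'
#' Default grids: `start_pp` 0..100 in steps of 2; ratios log-spaced over
#' `[1e-2, 1e2]` with 41 points (an order of magnitude beyond "10x faster
#' and slower" on each side).
#'
#' @param mode `"relative-in-puncta"` or `"relative-overall"`.
#' @param start_pp_grid Starting punctate percentages (percent).
#' @param ratio_grid Dimensionless rate ratios (positive).
#' @param constants Named list of held-constant rates. For
#'   `"relative-in-puncta"`: `k3_plus_k4` and `k1_plus_k2`; for
#'   `"relative-overall"`: `k3` and `k4`.
#' @return A `phase_diagram` object: list with `start_pp`, `ratio`, `mode`
#'   and `delta`, a `length(start_pp) x length(ratio)` matrix of artifact
#'   values in percentage points.
#' @examples
#' pd <- sweep_phase_diagram("relative-in-puncta",
#'                           start_pp_grid = seq(0, 100, 10),
#'                           ratio_grid = c(0.5, 1, 2))
#' pd$delta[, pd$ratio == 1]  # zero column: k3 = k4 preserves equilibrium
#' @export
sweep_phase_diagram <- function(mode = c("relative-in-puncta",
                                         "relative-overall"),
                                start_pp_grid = seq(0, 100, by = 2),
                                ratio_grid = 10 ^ seq(-2, 2,
                                                      length.out = 41L),
                                constants = NULL) {
  mode <- match.arg(mode)
  if (length(start_pp_grid) == 0L || length(ratio_grid) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  if (any(ratio_grid <= 0)) stop("ratios must be > 0", call. = FALSE)
  constants <- if (mode == "relative-in-puncta") {
    utils::modifyList(list(k3_plus_k4 = 0.2, k1_plus_k2 = 1), as.list(constants))
  } else {
    utils::modifyList(list(k3 = 1, k4 = 2), as.list(constants))
  }
  delta <- matrix(NA_real_, nrow = length(start_pp_grid),
                  ncol = length(ratio_grid),
                  dimnames = list(start_pp = signif(start_pp_grid, 6),
                                  ratio = signif(ratio_grid, 6)))
  for (j in seq_along(ratio_grid)) {
    r <- ratio_grid[j]
    if (mode == "relative-in-puncta") {
      # r = k3:k4 at fixed k3 + k4
      k3 <- constants$k3_plus_k4 * r / (1 + r)
      k4 <- constants$k3_plus_k4 / (1 + r)
      exch <- constants$k1_plus_k2
    } else {
      # r = (k3+k4):(k1+k2) at fixed k3, k4
      k3 <- constants$k3
      k4 <- constants$k4
      exch <- (k3 + k4) / r
    }
    for (i in seq_along(start_pp_grid)) {
      k12 <- rates_from_equilibrium(start_pp_grid[i], exch)
      rs <- rate_set(k12[["k1"]], k12[["k2"]], k3, k4)
      delta[i, j] <- delta_punctate_percentage(rs, start_pp_grid[i])$delta
    }
  }
  structure(list(start_pp = start_pp_grid, ratio = ratio_grid,
                 mode = mode, constants = constants, delta = delta),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> mode = %s; %d start_pp x %d ratios; delta in [%.3g, %.3g] pp\n",
              x$mode, length(x$start_pp), length(x$ratio),
              min(x$delta), max(x$delta)))
  invisible(x)
}

#' Long-format view of a phase diagram
#'
#' @param x A `phase_diagram`.
#' @param ... Unused.
#' @return data.frame with columns `start_pp`, `ratio`, `delta`.
#' @export
as.data.frame.phase_diagram <- function(x, ...) {
  data.frame(start_pp = rep(x$start_pp, times = length(x$ratio)),
             ratio = rep(x$ratio, each = length(x$start_pp)),
             delta = as.vector(x$delta))
}
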