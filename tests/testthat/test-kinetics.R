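test_that("equilibrium rate construction matches the boundary conventions", {
  expect_equal(rates_from_equilibrium(50, 1), c(k1 = 0.5, k2 = 0.5))
  expect_equal(rates_from_equilibrium(0, 1), c(k1 = 0, k2 = 1))
  expect_equal(rates_from_equilibrium(100, 1), c(k1 = 1, k2 = 0))
  k <- rates_from_equilibrium(37, 2.5)
  expect_equal(unname(k[1] + k[2]), 2.5)
  expect_equal(unname(100 * k[1] / (k[1] + k[2])), 37)
  expect_error(rates_from_equilibrium(101, 1), "punctate percentage")
  expect_error(rates_from_equilibrium(50, 0), "total_exchange")
})

test_that("initial state starts at equilibrium with empty fixed pools", {
  expect_equal(initial_state(50), c(s1 = 0.5, s2 = 0.5, s3 = 0, s4 = 0))
  expect_equal(initial_state(0), c(s1 = 0, s2 = 1, s3 = 0, s4 = 0))
  expect_equal(initial_state(100), c(s1 = 1, s2 = 0, s3 = 0, s4 = 0))
  expect_error(initial_state(-1), "punctate percentage")
})

test_that("rate_set rejects invalid rates", {
  expect_error(rate_set(-0.1, 1, 1, 1), "rates")
  expect_error(rate_set(1, 1, 0, 0), "fixation never completes")
  expect_equal(rate_set(1, 2, 3, 4)$Keq, 0.5)
})

test_that("time course conserves molarity and reaches the fixed split", {
  tc <- simulate_time_course(rate_set(0.5, 0.5, 0.1, 0.1), 50,
                             t_end = 200, n_points = 101L)
  sums <- rowSums(tc[, c("s1", "s2", "s3", "s4")])
  expect_true(all(abs(sums - 1) < 1e-9))
  # symmetry forces an equal fixed split
  last <- tc[nrow(tc), ]
  expect_equal(last$s3, 0.5, tolerance = 1e-6)
  expect_equal(last$s4, 0.5, tolerance = 1e-6)
  expect_lt(last$s1 + last$s2, exp(-0.1 * 200) + 1e-9)
  # s3, s4 non-decreasing; s1 + s2 non-increasing
  expect_true(all(diff(tc$s3) > -1e-12))
  expect_true(all(diff(tc$s4) > -1e-12))
  expect_true(all(diff(tc$s1 + tc$s2) < 1e-12))
  # terminal in-puncta fixed pool for an asymmetric rate set
  tc2 <- simulate_time_course(rate_set(0.15, 0.15, 1, 2), 50,
                              t_end = 100, n_points = 51L)
  expect_equal(tc2$s3[nrow(tc2)], 0.4693878, tolerance = 1e-5)
})

test_that("closed-form t = infinity split matches its derivation", {
  fin <- final_fixed_state(rate_set(0.15, 0.15, 1, 2), 50)
  expect_equal(unname(fin), c(0.46939, 0.53061), tolerance = 1e-5)
  expect_equal(sum(fin), 1, tolerance = 1e-12)
  # equal added decay preserves the equilibrium ratio exactly
  set.seed(11)
  for (i in 1:20) {
    k12 <- 10 ^ runif(2, -2, 1)
    rs <- rate_set(k12[1], k12[2], 0.37, 0.37)
    p <- equilibrium_start(rs)
    fin <- final_fixed_state(rs, p)
    expect_equal(unname(fin[["s3_inf"]]), p / 100, tolerance = 1e-12)
  }
  # with no out-of-puncta fixation, S3 is the only absorbing sink
  fin <- final_fixed_state(rate_set(0.4, 0.2, 0.5, 0), 30)
  expect_equal(unname(fin[["s3_inf"]]), 1, tolerance = 1e-12)
  # stranded mass: k3 = 0 and no route from S2 back into a fixing pool
  expect_error(final_fixed_state(rate_set(0, 0, 0, 1), 50), "never be fixed")
})

test_that("ODE terminal state agrees with the closed form (oracle grid)", {
  set.seed(101)
  for (i in 1:40) {
    rs <- random_rate_set()
    p <- runif(1, 0, 100)
    fin <- final_fixed_state(rs, p)
    t_end <- 50 / min(rs$k3, rs$k4)
    tc <- simulate_time_course(rs, p, t_end = t_end, n_points = 11L)
    expect_equal(tc$s3[11L], unname(fin[["s3_inf"]]), tolerance = 1e-6)
    expect_equal(tc$s4[11L], unname(fin[["s4_inf"]]), tolerance = 1e-6)
  }
})

test_that("artifact statistic obeys the zero, boundary and sign laws", {
  # derived example
  expect_equal(delta_punctate_percentage(rate_set(0.15, 0.15, 1, 2),
                                         50)$delta,
               -3.0612245, tolerance = 1e-6)
  res <- delta_punctate_percentage(rate_set(0.15, 0.15, 1, 2), 50)
  expect_equal(res$delta,
               res$final_punctate_percentage -
                 res$initial_punctate_percentage)
  set.seed(202)
  for (i in 1:100) {
    # equal fixation rates preserve any equilibrium start
    k12 <- 10 ^ runif(2, -2, 1)
    kf <- 10 ^ runif(1, -2, 1)
    expect_lt(abs(delta_punctate_percentage(
      rate_set(k12[1], k12[2], kf, kf))$delta), 1e-9)
    # boundary equilibria (one-sided exchange) are artifact-free for
    # arbitrary fixation rates
    kf2 <- 10 ^ runif(2, -2, 1)
    exch <- 10 ^ runif(1, -1, 1)
    lo <- rates_from_equilibrium(0, exch)
    hi <- rates_from_equilibrium(100, exch)
    expect_lt(abs(delta_punctate_percentage(
      rate_set(lo[1], lo[2], kf2[1], kf2[2]), 0)$delta), 1e-9)
    expect_lt(abs(delta_punctate_percentage(
      rate_set(hi[1], hi[2], kf2[1], kf2[2]), 100)$delta), 1e-9)
  }
  # sign law: delta > 0 iff k3 > k4 for interior equilibria
  for (p in c(10, 50, 90)) {
    k12 <- rates_from_equilibrium(p, 1)
    up <- delta_punctate_percentage(rate_set(k12[1], k12[2], 0.15, 0.05),
                                    p)$delta
    dn <- delta_punctate_percentage(rate_set(k12[1], k12[2], 0.05, 0.15),
                                    p)$delta
    expect_gt(up, 0)
    expect_lt(dn, 0)
  }
})

test_that("artifact shrinks monotonically as fixation outpaces exchange", {
  ratios <- 10 ^ seq(-2, 3, length.out = 21L)
  deltas <- vapply(ratios, function(r) {
    k12 <- rates_from_equilibrium(50, 3 / r)
    abs(delta_punctate_percentage(rate_set(k12[1], k12[2], 1, 2),
                                  50)$delta)
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))
  expect_lt(deltas[length(deltas)], 0.1)
})

test_that("phase diagrams have the documented structure", {
  pd <- sweep_phase_diagram("relative-in-puncta",
                            start_pp_grid = seq(0, 100, 10),
                            ratio_grid = c(0.25, 1, 4))
  expect_equal(dim(pd$delta), c(11L, 3L))
  # k3 = k4 column is the zero-artifact line
  expect_true(all(abs(pd$delta[, 2]) < 1e-9))
  # boundary rows are zero in every column
  expect_true(all(abs(pd$delta[c(1L, 11L), ]) < 1e-9))
  # sign follows k3 - k4 for interior rows
  expect_true(all(pd$delta[2:10, 3] > 0))
  expect_true(all(pd$delta[2:10, 1] < 0))

  pd2 <- sweep_phase_diagram("relative-overall",
                             start_pp_grid = c(0, 50, 100),
                             ratio_grid = c(0.1, 1, 1000))
  expect_true(all(abs(pd2$delta[c(1L, 3L), ]) < 1e-9))
  expect_lt(abs(pd2$delta[2L, 3L]), 0.1)
  # k3 < k4 throughout, so the interior artifact is negative
  expect_true(all(pd2$delta[2L, ] < 0))
  expect_error(sweep_phase_diagram("nope"), "arg")

  df <- as.data.frame(pd)
  expect_equal(nrow(df), 33L)
  expect_equal(df$delta[df$start_pp == 50 & df$ratio == 1],
               pd$delta[6L, 2L])
})
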