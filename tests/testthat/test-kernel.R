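test_that("deterministic sweep trajectory is the logistic solution", {
  expect_equal(deterministic_sweep(0.01, 0.05, 0), 0.01)
  expect_equal(deterministic_sweep(0.01, 0.05, 1e6), 1)
  # time to reach 1/2 is log((1-x0)/x0)/s
  x0 <- 1e-3; s <- 0.05
  t_half <- log((1 - x0) / x0) / s
  expect_equal(deterministic_sweep(x0, s, t_half), 0.5, tolerance = 1e-12)
  expect_error(deterministic_sweep(0, 0.05, 1), class = "sweeprate_param_error")
  expect_error(deterministic_sweep(1.2, 0.05, 1), class = "sweeprate_param_error")
})

test_that("pair fixation decouples at large distance and after the sweep", {
  s <- 0.02; N <- 1e6
  p0 <- 2 * s
  # unlinked: no loss
  expect_equal(pair_fixation(s, s, Inf, t_birth = 0, N)$p_fix, p0)
  # loosely linked: tiny loss
  far <- pair_fixation(s, s, r = 0.5, t_birth = 0, N)
  expect_lt(far$loss, 0.05)
  # born long after the sweep fixed: no loss
  late <- pair_fixation(s, s, r = 0.01 * s, t_birth = 3000, N)
  expect_lt(late$loss, 1e-3)
  # complete linkage: the ancestral background can never fix (the sweep is
  # destined to exclude it), so any focal allele born before the sweep is lost
  sol <- sweeprate:::solve_pair(s, s, r = 0, N = N)
  expect_lt(max(sol$pb), 1e-10)
  early <- pair_fixation(s, s, r = 0, t_birth = -log(2 * N * s) / s - 50, N)
  expect_gt(early$loss, 0.999)
  # at the midpoint half the mutations land on the (favoured) sweeping
  # background, so the average loss is intermediate
  mid <- pair_fixation(s, s, r = 0, t_birth = 0, N)
  expect_gt(mid$loss, 0.2)
  expect_lt(mid$loss, 0.6)
})

test_that("the kernel is non-negative, peaks near the sweep midpoint, and decays", {
  k <- interference_kernel(scaled_distances = c(0.01, 0.1, 1),
                           scaled_times = seq(-25, 8, length.out = 67),
                           s_sweep = 0.02, N = 1e6)
  expect_true(all(k$loss >= 0))
  tight <- dplyr::filter(k, scaled_distance == 0.01)
  peak_t <- tight$scaled_time[which.max(tight$loss)]
  # most interference is caused around/before the sweep becomes common
  expect_gt(max(tight$loss), 0.35)
  expect_true(peak_t > -20 && peak_t < 2)
  # decays in both time directions and with distance
  expect_lt(tight$loss[1], 0.5 * max(tight$loss))
  expect_lt(tight$loss[nrow(tight)], 0.1)
  by_d <- dplyr::summarise(dplyr::group_by(k, scaled_distance),
                           total = sum(loss))
  expect_true(all(diff(by_d$total) < 0))
})

test_that("kernels collapse across N and s on scaled axes", {
  sd_grid <- c(0.02, 0.2, 2)
  st_grid <- seq(-16, 4, length.out = 21)
  k1 <- interference_kernel(scaled_distances = sd_grid, scaled_times = st_grid,
                            s_sweep = 0.02, N = 1e6)
  # same N s, different s: exact collapse expected
  k2 <- interference_kernel(scaled_distances = sd_grid, scaled_times = st_grid,
                            s_sweep = 0.04, N = 5e5)
  expect_equal(k1$loss, k2$loss, tolerance = 1e-4)
  # different N at fixed scaled coordinates: endpoint effects only
  k3 <- interference_kernel(scaled_distances = sd_grid, scaled_times = st_grid,
                            s_sweep = 0.02, N = 1e8)
  expect_equal(k1$loss, k3$loss, tolerance = 0.05)
})

test_that("Z is stable under grid refinement and vanishes for a null kernel", {
  z_coarse <- compute_Z(n_r = 120, dt = 0.05, r_max = 400)
  z_fine <- compute_Z(n_r = 240, dt = 0.025, r_max = 400)
  expect_lt(abs(as.numeric(z_fine) - as.numeric(z_coarse)) / as.numeric(z_fine), 0.01)
  # a focal allele born far after every sweep loses nothing: zero integrand
  late <- pair_fixation(0.02, 0.02, r = 0.002, t_birth = 5000, N = 1e7)
  expect_lt(late$loss, 1e-6)
})

test_that("interference coefficient is monotone in the ratio and matches Z at 1", {
  co <- interference_coefficient(c(0.5, 1, 2), n_r = 60, dt = 0.1, r_max = 200)
  expect_true(all(diff(co$c_numeric) > 0))
  z <- compute_Z(n_r = 60, dt = 0.1, r_max = 200)
  expect_equal(co$c_numeric[co$ratio == 1], as.numeric(z), tolerance = 1e-6)
  # proportional approximation is good near ratio 1, overestimates for large
  expect_equal(co$c_numeric[2], co$c_crude[2], tolerance = 0.1)
  co8 <- interference_coefficient(8, n_r = 60, dt = 0.1, r_max = 200)
  expect_lt(co8$c_numeric, co8$c_crude)
  expect_equal(co8$c_numeric, co8$c_large_ratio, tolerance = 0.15)
  expect_error(interference_coefficient(-1), class = "sweeprate_param_error")
})

test_that("two sweeps interfere nearly additively", {
  # far apart in time: exactly additive
  far <- two_sweep_interaction(separation = 0.04, dt_offset = 4000, N = 1e5)
  expect_equal(far$additivity_ratio, 1, tolerance = 0.02)
  # simultaneous, in complete repulsion: still close to additive
  ld <- two_sweep_interaction(separation = 0.04, dt_offset = 0, N = 1e5, "LD")
  le <- two_sweep_interaction(separation = 0.04, dt_offset = 0, N = 1e5, "LE")
  expect_lt(abs(ld$additivity_ratio - 1), 0.25)
  expect_lt(abs(le$additivity_ratio - 1), 0.25)
})
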