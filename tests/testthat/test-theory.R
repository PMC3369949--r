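test_that("diffusion fixation probability: limits and Markov-chain oracle", {
  expect_equal(pfix_diffusion(100, 0), 1 / 100)
  expect_equal(pfix_diffusion(1e6, 0.01), 2 * 0.01, tolerance = 0.01)
  expect_equal(pfix_diffusion(100, 0.05), (1 - exp(-0.1)) / (1 - exp(-10)))
  # absorbing-chain oracle at N = 100: exact Wright-Fisher fixation
  # probability from one copy, binomial resampling with selection
  N <- 100; s <- 0.05
  P <- matrix(0, N + 1, N + 1)
  for (i in 0:N) {
    pw <- (i / N) * (1 + s) / (1 + s * i / N)
    P[i + 1, ] <- dbinom(0:N, N, pw)
  }
  Q <- P[2:N, 2:N]
  b <- P[2:N, N + 1]
  u <- solve(diag(N - 1) - Q, b)
  expect_equal(pfix_diffusion(N, s), u[1], tolerance = 0.02)
})

test_that("baseline rates follow the 2NUs arithmetic", {
  b <- baseline(N = 1e4, U = 1e-4, R = 1, s = 0.02, p0_method = "2s")
  expect_equal(b$Lambda0, 0.04)
  expect_equal(b$v0, 0.04 * 0.02)
  expect_equal(baseline(1e4, 0, 1, 0.02)$Lambda0, 0)
  expect_equal(baseline(2e4, 1e-4, 1, 0.02, "2s")$Lambda0, 0.08)  # linear in N
})

test_that("Lambert-W rate solves its fixed point", {
  expect_equal(lambertw_rate(exp(1), 1), 1)          # W(e) = 1
  expect_equal(lambertw_rate(1e-8, 4), 1e-8, tolerance = 1e-5)
  # damped fixed-point iteration oracle (damping keeps the map contracting)
  for (case in list(c(0.5, 1), c(2, 4), c(10, 8))) {
    v0 <- case[1]; a <- case[2]
    beta <- 1 / (1 + a * v0)
    v <- 0
    for (i in 1:20000) v <- (1 - beta) * v + beta * v0 * exp(-a * v)
    expect_equal(lambertw_rate(v0, a), v, tolerance = 1e-12)
  }
  # grows without bound but logarithmically
  big <- lambertw_rate(c(1e4, 1e8), 1)
  expect_gt(big[2], big[1])
  expect_lt(big[2], 2.3 * big[1])
})

test_that("additive density: limits, ceiling, monotonicity", {
  expect_equal(additive_density(0), 0)
  expect_equal(additive_density(1e-6), 1e-6, tolerance = 1e-5)
  expect_equal(additive_density(1e12, Z = 1), 0.5, tolerance = 1e-10)
  l0 <- 10^seq(-3, 3, length.out = 50)
  l <- additive_density(l0)
  expect_true(all(diff(l) > 0))
  expect_true(all(l <= 0.5))
  expect_true(all(l <= l0))
  # evaluating the printed relation at Lambda0 = 0.5, Z = 1:
  expect_equal(additive_density(0.5), 0.25)
  # cross-check: self-consistent solve of Lambda = Lambda0 (1 - 2 Z Lambda)
  z <- 1.05
  root <- uniroot(function(L) 0.7 * (1 - 2 * z * L) - L, c(0, 1))$root
  expect_equal(additive_density(0.7, Z = z), root, tolerance = 1e-8)
})

test_that("self-consistent density reduces to the additive form and is monotone", {
  # negligible s R: unlinked factor ~ 1
  th <- self_consistent_density(N = 1e6, U = 1e-5, R = 1e4, s = 1e-4, p0_method = "2s")
  expect_equal(th$Lambda, additive_density(th$Lambda0), tolerance = 1e-3)
  # monotone in each parameter
  base <- self_consistent_density(1e5, 1e-4, 10, 0.02, p0_method = "2s")$Lambda
  expect_gte(self_consistent_density(2e5, 1e-4, 10, 0.02, p0_method = "2s")$Lambda, base)
  expect_gte(self_consistent_density(1e5, 2e-4, 10, 0.02, p0_method = "2s")$Lambda, base)
  expect_gte(self_consistent_density(1e5, 1e-4, 20, 0.02, p0_method = "2s")$Lambda * 2,
             base)  # per-Morgan density with more map: genomic rate rises
  expect_gte(self_consistent_density(1e5, 1e-4, 10, 0.04, p0_method = "2s")$Lambda, base)
  # interference never helps
  th2 <- self_consistent_density(1e5, 1e-3, 10, 0.02)
  expect_lte(th2$Lambda, th2$Lambda0)
  expect_lte(th2$p_fix, pfix_diffusion(1e5, 0.02))
})

test_that("coalescence time: pure drift limit and draft monotonicity", {
  expect_equal(coalescence_time(500, 0.05, Lambda = 0)$T2, 500)
  l <- seq(0, 0.5, length.out = 11)
  t2 <- vapply(l, function(x) coalescence_time(1e4, 0.05, x)$T2, 0)
  expect_true(all(diff(t2) < 0))
  # T2 decreases with N in the draft-dominated regime when Lambda0 grows with N
  t2_of_N <- vapply(c(1e4, 1e5, 1e6), function(N) {
    th <- self_consistent_density(N, U = 1e-4, R = 10, s = 0.02, p0_method = "2s")
    coalescence_time(N, 0.02, th$Lambda, th$sigma2)$T2
  }, 0)
  expect_lt(t2_of_N[3], t2_of_N[1])
})

test_that("exponential effects double the interference term", {
  ee <- exp_effects(N = 1e5, U = 1e-4, R = 10, sbar = 0.02)
  expect_equal(ee$s_fixed_mean, 2 * 0.02, tolerance = 1e-6)
  expect_equal(ee$interference_term_exp / ee$interference_term_fixed, 2)
  # Lambda0 -> 0: profile tends to the baseline 2s for all s
  ee0 <- exp_effects(N = 1e3, U = 1e-9, R = 10, sbar = 0.02)
  prof <- attr(ee0, "pfix_profile")
  expect_equal(prof(0.05), 0.1, tolerance = 1e-3)
  # with interference the cutoff removes weak alleles
  prof1 <- attr(ee, "pfix_profile")
  expect_equal(prof1(ee$s_cutoff), 0)
  expect_gt(prof1(5 * ee$s_cutoff), 0)
})

test_that("weakly selected alleles are floored at the neutral probability", {
  w <- weak_selection_pfix(s = c(1e-6, 1e-4, 1e-3, 5e-3), N = 1e5,
                           Lambda = 0.2, sbar_successful = 0.04)
  expect_true(all(w$p_fix >= 1 / 1e5))
  expect_true(all(diff(w$p_fix) >= 0))
  expect_true(w$near_neutral[1])
  # no interference: baseline recovered
  w0 <- weak_selection_pfix(s = 0.01, N = 1e5, Lambda = 0, sbar_successful = 0.04)
  expect_equal(w0$p_fix, 0.02)
})

test_that("facultative sex: psi = 1 is the obligate case, lower psi means fewer sweeps", {
  args <- list(N = 1e5, U = 1e-4, R = 10, s = 0.02, p0_method = "2s")
  ob <- do.call(self_consistent_density, args)
  fac1 <- do.call(facultative_rescale, c(args, outcross_rate = 1))
  expect_equal(fac1$Lambda, ob$Lambda, tolerance = 1e-9)
  psis <- c(1, 0.5, 0.2, 0.05)
  lam <- vapply(psis, function(ps) do.call(facultative_rescale,
                                           c(args, outcross_rate = ps))$Lambda, 0)
  expect_true(all(diff(lam) < 0))
  # ceiling scales with psi
  hi <- facultative_rescale(1e7, 0.1, 10, 0.02, outcross_rate = 0.1, p0_method = "2s")
  expect_lt(hi$Lambda, 0.1 / 2 * 1.0001)
  # linked-dominance condition shifts proportionally to psi
  expect_equal(fac1$linked_dominance / 10,
               do.call(facultative_rescale, c(args, outcross_rate = 0.1))$linked_dominance,
               tolerance = 1e-9)
  expect_error(do.call(facultative_rescale, c(args, outcross_rate = 0)),
               class = "sweeprate_param_error")
})

test_that("conditioned sojourn density is symmetric and matches Monte Carlo", {
  st <- diffusion_sojourn_stats(N = 100, s = 0.05)
  expect_equal(st$mean[1], st$mean[2], tolerance = 1e-6)
  # conditioned Wright-Fisher Monte Carlo oracle
  set.seed(61)
  N <- 100; s <- 0.05
  one_run <- function() {
    i <- 1; below <- 0; above <- 0
    while (i > 0 && i < N) {
      if (i <= N / 2) below <- below + 1 else above <- above + 1
      pw <- (i / N) * (1 + s) / (1 + s * i / N)
      i <- rbinom(1, N, pw)
    }
    if (i == N) c(below, above) else NULL
  }
  res <- list()
  while (length(res) < 250) {
    r <- one_run()
    if (!is.null(r)) res[[length(res) + 1]] <- r
  }
  m <- do.call(rbind, res)
  se <- apply(m, 2, sd) / sqrt(nrow(m))
  expect_lt(abs(mean(m[, 1]) - st$mean[1]), 4 * se[1] + 0.05 * st$mean[1])
  expect_lt(abs(mean(m[, 2]) - st$mean[2]), 4 * se[2] + 0.05 * st$mean[2])
  # sd from the second-moment integral agrees with the Monte Carlo spread
  expect_equal(sd(m[, 1]), st$sd[1], tolerance = 0.25)
  # mean total sojourn time decreases with s
  tot <- vapply(c(0.02, 0.05, 0.1), function(ss)
    sum(diffusion_sojourn_stats(100, ss)$mean), 0)
  expect_true(all(diff(tot) < 0))
})
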