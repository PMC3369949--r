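test_that("complete recombination: no mutations, no substitutions", {
  p <- sim_params(N = 200, U = 0, R = 1, s = 0.05, generations = 100, seed = 1)
  out <- run_complete_recombination(p)
  expect_equal(nrow(out$fixations), 0)
})

test_that("complete recombination matches the product-log rate", {
  # strong enough supply that the e^{-v} feedback is unmistakable
  p <- sim_params(N = 300, U = 0.1, R = 1, s = 0.1, generations = 1200,
                  seed = 23, burn_in = 300)
  out <- run_complete_recombination(p)
  gs <- dplyr::filter(out$genstats, generation >= 300)
  v_meas <- (gs$mean_log_fitness[nrow(gs)] - gs$mean_log_fitness[1]) / (nrow(gs) - 1)
  v0 <- 2 * p$N * p$U * p$s * log(1 + p$s)  # baseline rate of log-fitness gain
  v_pred <- lambertw_rate(v0, alpha = 1)
  expect_gt(v_meas, 0)
  expect_equal(v_meas, v_pred, tolerance = 0.2)
  expect_lt(v_meas, 0.85 * v0)  # clearly below baseline: interference never helps
})

test_that("complete recombination has zero linkage disequilibrium at birth", {
  set.seed(3)
  p <- sim_params(N = 3000, U = 0.005, R = 1, s = 0.05, generations = 150, seed = 33)
  out <- run_complete_recombination(p)
  X <- out$population
  keep <- colMeans(X) > 0.1 & colMeans(X) < 0.9
  X <- X[, keep, drop = FALSE]
  expect_gte(ncol(X), 2)
  prs <- utils::combn(ncol(X), 2)
  for (k in seq_len(min(ncol(prs), 10))) {
    i <- prs[1, k]; j <- prs[2, k]
    pA <- mean(X[, i]); pB <- mean(X[, j])
    D <- mean(X[, i] & X[, j]) - pA * pB
    expect_lt(abs(D), 4 * sqrt(pA * (1 - pA) * pB * (1 - pB) / nrow(X)))
  }
})

test_that("uncorrelated fitness noise lowers the fixation probability", {
  # single-locus Monte Carlo: lone beneficial allele with and without noise
  pfix_mc <- function(noise_var, reps = 1500, seed = 77) {
    set.seed(seed)
    fixed <- 0; resolved <- 0
    for (i in seq_len(reps)) {
      sim <- run_simulation(
        sim_params(N = 150, U = 0, R = 1, s = 0.15, generations = 400,
                   fitness_noise_var = noise_var),
        init_mutations = data.frame(position = 0.5, s = 0.15, count = 1))
      f <- sim$mutations$fate[1]
      if (f != "segregating") {
        resolved <- resolved + 1
        fixed <- fixed + (f == "fixed")
      }
    }
    c(fixed = fixed, n = resolved)
  }
  quiet <- pfix_mc(0)
  noisy <- pfix_mc(1.0, seed = 78)
  p_quiet <- as.numeric(quiet["fixed"] / quiet["n"])
  p_noisy <- as.numeric(noisy["fixed"] / noisy["n"])
  expect_lt(p_noisy, p_quiet)
  # rough magnitude: reduction factor ~ exp(-noise_var)
  expect_equal(p_noisy / p_quiet, exp(-1), tolerance = 0.5)
  expect_error(run_fluctuating_fitness(sim_params(N = 100, U = 0.01, R = 1, s = 0.05)),
               class = "sweeprate_param_error")
})

test_that("infinitesimal model: sigma2 = 0 recovers the branching-process value", {
  # oracle: survival probability p of a Poisson(1 + s) branching process,
  # 1 - p = exp(-(1 + s) p)
  s <- 0.05
  oracle <- uniroot(function(p) 1 - p - exp(-(1 + s) * p), c(1e-6, 1))$root
  set.seed(41)
  est <- infinitesimal_pfix(z0 = 0, infinitesimal_params(
    s = s, sigma2 = 0, fix_threshold = 2000, min_fixed = 250))
  expect_gt(oracle, est$conf_lo)
  expect_lt(oracle, est$conf_hi)
})

test_that("fixation probability scales as the square of founder fitness (polygamy)", {
  set.seed(42)
  ip <- infinitesimal_params(s = 0.05, sigma2 = 0.04, fix_threshold = 2000,
                             min_fixed = 250)
  z0s <- c(-0.3, 0, 0.3)
  est <- vapply(z0s, function(z) infinitesimal_pfix(z, ip)$estimate, 0)
  slope <- coef(lm(log(est) ~ z0s))[2]
  expect_equal(as.numeric(slope), 2, tolerance = 0.25)
})

test_that("monogamy fixes less often than polygamy at equal variance", {
  set.seed(43)
  common <- list(s = 0.05, sigma2 = 0.08, fix_threshold = 2000, min_fixed = 250)
  poly <- infinitesimal_pfix(NULL, do.call(infinitesimal_params, c(common, mating = "polygamy")))
  mono <- infinitesimal_pfix(NULL, do.call(infinitesimal_params, c(common, mating = "monogamy")))
  expect_lt(mono$estimate, poly$estimate)
})

test_that("averaged infinitesimal fixation matches the exp(-alpha sigma2) reduction", {
  set.seed(44)
  s <- 0.05; sig2 <- 0.05
  base <- uniroot(function(p) 1 - p - exp(-(1 + s) * p), c(1e-6, 1))$root
  est <- infinitesimal_pfix(NULL, infinitesimal_params(
    s = s, sigma2 = sig2, fix_threshold = 2000, min_fixed = 300))
  target <- base * exp(-4 * sig2)
  expect_gt(target, est$conf_lo * 0.9)
  expect_lt(target, est$conf_hi * 1.1)
})
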