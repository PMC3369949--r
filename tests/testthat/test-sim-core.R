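test_that("parameter validation names the offending field", {
  expect_error(sim_params(N = 1, U = 0.01, R = 1, s = 0.05), "`N`",
               class = "sweeprate_param_error")
  expect_error(sim_params(N = 100, U = -1, R = 1, s = 0.05), "`U`",
               class = "sweeprate_param_error")
  expect_error(sim_params(N = 100, U = 0.01, R = 0, s = 0.05), "`R`",
               class = "sweeprate_param_error")
  expect_error(sim_params(N = 100, U = 0.01, R = 1), "`s`",
               class = "sweeprate_param_error")
  expect_error(sim_params(N = 100, U = 0.01, R = 1, s = 0.05, sbar = 0.05),
               class = "sweeprate_param_error")
})

test_that("populations start wild-type and seeded runs are bit-identical", {
  p <- sim_params(N = 100, U = 0.01, R = 1, s = 0.05, generations = 50, seed = 3)
  st <- init_population(p)
  expect_length(st$genomes, 100)
  expect_true(all(lengths(st$genomes) == 0))
  expect_equal(nrow(st$registry), 0)
  expect_equal(st$generation, 0L)
  a <- run_simulation(p)
  b <- run_simulation(p)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$genstats, b$genstats)
})

test_that("recombination between identical genomes is invisible; k = 0 copies a parent", {
  set.seed(1)
  g <- c(a = 0.1, b = 0.4, c = 0.9)
  for (i in 1:20) expect_identical(recombine(g, g, R = 2), g)
  # R tiny: crossover count almost surely 0, offspring equals one parent
  set.seed(2)
  picks <- replicate(2000, {
    off <- recombine(c(x = 0.1), c(y = 0.8), R = 1e-9)
    names(off)
  })
  expect_setequal(unique(picks), c("x", "y"))
  expect_gt(mean(picks == "x"), 0.45)  # fair coin
  expect_lt(mean(picks == "x"), 0.55)
})

test_that("two-locus recombinant frequency follows the Haldane map function", {
  set.seed(4)
  d <- 0.3
  n <- 3e4
  rec <- replicate(n, length(recombine(c(a = 1), c(b = 1 + d), R = 5)) != 1)
  expected <- (1 - exp(-2 * d)) / 2
  expect_lt(abs(mean(rec) - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("one generation matches the multiplicative-selection oracle", {
  # E[dp] = s p (1 - p) / (1 + s p) for a single segregating locus
  set.seed(11)
  N <- 200; s <- 0.1; p0 <- 0.3; reps <- 2500
  im <- data.frame(position = 0.5, s = s, count = round(p0 * N))
  dp <- replicate(reps, {
    sim <- run_simulation(sim_params(N = N, U = 0, R = 1, s = s, generations = 1), im)
    sim$mutations$count[1] / N - p0
  })
  theory <- s * p0 * (1 - p0) / (1 + s * p0)
  expect_lt(abs(mean(dp) - theory), 3 * sd(dp) / sqrt(reps))
})

test_that("neutral allele-frequency change is binomial sampling", {
  set.seed(12)
  N <- 200; reps <- 2500
  im <- data.frame(position = 0.5, s = 1e-9, count = N / 2)
  dp <- replicate(reps, {
    sim <- run_simulation(sim_params(N = N, U = 0, R = 1, s = 1e-9, generations = 1), im)
    sim$mutations$count[1] / N - 0.5
  })
  expect_lt(abs(mean(dp)), 3 * sd(dp) / sqrt(reps))
  v <- 0.25 / N
  expect_lt(abs(var(dp) - v), 4 * v * sqrt(2 / (reps - 1)))
})

test_that("mutation input and registry bookkeeping are consistent", {
  p <- sim_params(N = 150, U = 0.5, R = 2, s = 0.02, generations = 60, seed = 9)
  sim <- run_simulation(p)
  # mean new mutations per generation ~ N U
  expect_lt(abs(nrow(sim$mutations) / p$generations - p$N * p$U),
            4 * sqrt(p$N * p$U / p$generations))
  # fates are exclusive and counts respect them
  m <- sim$mutations
  expect_true(all(m$count[m$fate == "lost"] == 0))
  expect_true(all(m$count[m$fate == "fixed"] == p$N))
  expect_true(all(m$count >= 0 & m$count <= p$N))
  expect_true(all(m$count[m$fate == "segregating"] > 0 &
                    m$count[m$fate == "segregating"] < p$N))
  # fixation and loss times never precede origins
  res <- m[m$fate != "segregating", ]
  expect_true(all(res$t_fate >= res$t_origin))
})

test_that("U = 0 yields no mutations or fixations", {
  sim <- run_simulation(sim_params(N = 100, U = 0, R = 1, s = 0.05,
                                   generations = 100, seed = 2))
  expect_equal(nrow(sim$mutations), 0)
  expect_equal(nrow(sim$fixations), 0)
})

test_that("the R single-step reference implementation agrees with its contracts", {
  p <- sim_params(N = 120, U = 0.3, R = 1.5, s = 0.05, generations = 10, seed = 21)
  st <- init_population(p)
  for (i in 1:10) st <- step_generation(st)
  expect_equal(st$generation, 10L)
  # registry-genome count conservation
  carried <- tabulate(unlist(st$genomes), nbins = nrow(st$registry))
  seg <- st$registry$fate == "segregating"
  expect_equal(carried[which(seg)], st$registry$count[seg])
  expect_true(all(carried[which(!seg)] == 0))
  # genomes sorted by position, no duplicates
  pos <- st$registry$position
  for (g in st$genomes) {
    expect_true(!is.unsorted(pos[g], strictly = TRUE))
  }
})

test_that("trajectories track counts and respect the stride", {
  p <- sim_params(N = 100, U = 0.2, R = 1, s = 0.05, generations = 50, seed = 5,
                  record_trajectories = TRUE, traj_stride = 5)
  sim <- run_simulation(p)
  expect_true(all(sim$trajectories$generation %% 5 == 0))
  expect_true(all(sim$trajectories$frequency > 0 & sim$trajectories$frequency < 1))
})
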