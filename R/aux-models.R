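## Two simplified dynamics that admit closed-form rates: the
## complete-recombination ("mass meiosis") population, and the
## infinitesimal-model branching process for fixation under unlinked
## inherited fitness variance.

#' Complete-recombination ("mass meiosis") population model
#'
#' Every generation, each offspring draws the allele at every segregating
#' locus independently, with probability equal to the fitness-weighted
#' allele frequency: linkage disequilibrium is exactly zero at birth by
#' construction.  Mutation and fixation bookkeeping follow the main model.
#' The realised rate of increase of mean log fitness satisfies the
#' product-log relation `v = W(v0)` (see [lambertw_rate()] with
#' `alpha = 1`), because the fitness variance generated by the sweeps is
#' uncorrelated across generations.
#'
#' @param params A [sim_params()] object (`R` is ignored: all loci are
#'   exchangeable).
#' @return A `sweep_sim`-like list with `fixations`, `mutations`,
#'   `genstats`, `meta`; [glance.sweep_sim()] works on it.
#' @export
run_complete_recombination <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  N <- params$N
  X <- matrix(FALSE, nrow = N, ncol = 0)  # individuals x segregating loci
  reg <- list(position = numeric(0), s = numeric(0), t_origin = integer(0),
              fate = character(0), t_fate = integer(0), count = integer(0))
  live <- integer(0)  # registry ids of current columns
  gs <- vector("list", params$generations)
  fixed_logw <- 0
  for (gen in seq_len(params$generations)) {
    log1ps <- log1p(reg$s[live])
    lw <- if (length(live) > 0) as.numeric(X %*% log1ps) else numeric(N)
    gs[[gen]] <- c(gen - 1, mean(lw) + fixed_logw, var(lw) * (N - 1) / N, length(live))
    w <- exp(lw - max(lw))
    if (params$fitness_noise_var > 0) {
      w <- w * exp(rnorm(N, 0, sqrt(params$fitness_noise_var)))
    }
    ## fitness-weighted allele frequencies; offspring loci drawn independently
    if (length(live) > 0) {
      pw <- as.numeric(crossprod(X, w)) / sum(w)
      X <- matrix(runif(N * length(live)) < rep(pw, each = N), nrow = N)
    }
    M <- rpois(1, N * params$U)
    if (M > 0) {
      snew <- if (params$effect_model == "fixed") rep(params$s, M) else rexp(M, 1 / params$sbar)
      ids <- length(reg$s) + seq_len(M)
      reg$position <- c(reg$position, runif(M, 0, params$R))
      reg$s <- c(reg$s, snew)
      reg$t_origin <- c(reg$t_origin, rep(gen, M))
      reg$fate <- c(reg$fate, rep("segregating", M))
      reg$t_fate <- c(reg$t_fate, rep(NA_integer_, M))
      reg$count <- c(reg$count, rep(0L, M))
      Xnew <- matrix(FALSE, nrow = N, ncol = M)
      Xnew[cbind(sample.int(N, M, replace = TRUE), seq_len(M))] <- TRUE
      X <- cbind(X, Xnew)
      live <- c(live, ids)
    }
    if (length(live) > 0) {
      counts <- colSums(X)
      reg$count[live] <- counts
      lost <- counts == 0
      fixed <- counts == N
      reg$fate[live[lost]] <- "lost"
      reg$fate[live[fixed]] <- "fixed"
      reg$t_fate[live[lost | fixed]] <- gen
      fixed_logw <- fixed_logw + sum(log1p(reg$s[live[fixed]]))
      keep <- !(lost | fixed)
      X <- X[, keep, drop = FALSE]
      live <- live[keep]
    }
  }
  mutations <- tibble(id = seq_along(reg$s), position = reg$position, s = reg$s,
                      count = reg$count, t_origin = reg$t_origin, fate = reg$fate,
                      t_fate = reg$t_fate)
  gsm <- do.call(rbind, gs)
  structure(list(
    fixations = mutations |> dplyr::filter(.data$fate == "fixed") |>
      dplyr::select("id", "position", "s", "t_origin", t_fixed = "t_fate"),
    mutations = mutations,
    genstats = tibble(generation = gsm[, 1], mean_log_fitness = gsm[, 2],
                      var_log_fitness = gsm[, 3], n_segregating = gsm[, 4]),
    fixed_log_fitness = fixed_logw,
    population = X, live_ids = live,
    meta = list(params = params, burn_in = params$burn_in,
                generations_run = params$generations, engine = "complete_recombination",
                seed = params$seed)
  ), class = "sweep_sim")
}

#' Main model with uncorrelated fitness fluctuations
#'
#' Runs the linear-map individual-based model with iid non-heritable
#' Gaussian noise (variance `fitness_noise_var`) added to log fitness each
#' generation.  Uncorrelated noise inflates the offspring-number variance by
#' `exp(noise_var)` and reduces fixation probability (hence the realised
#' rate of sweeps) by the same factor.
#'
#' @param params A [sim_params()] object with `fitness_noise_var > 0`.
#' @return A `sweep_sim` object.
#' @export
run_fluctuating_fitness <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!(params$fitness_noise_var > 0)) {
    abort("fitness_noise_var must be > 0 (use run_simulation for the plain model)",
          class = "sweeprate_param_error")
  }
  run_simulation(params)
}

#' Parameters of the infinitesimal branching model
#'
#' @param s Advantage of the focal mutation.
#' @param sigma2 Stationary variance of background log fitness at linkage
#'   equilibrium.
#' @param mating `"polygamy"` (each offspring from an independent
#'   fitness-weighted mate) or `"monogamy"` (one random mate supplies all of
#'   a carrier's offspring, adding drift).
#' @param fix_threshold Lineage size at which a lineage is declared fixed
#'   (must be well above `1/s`).
#' @param max_lineages Maximum number of replicate lineages.
#' @param min_fixed Stop once this many lineages have fixed.
#' @return An `infinitesimal_params` list.
#' @export
infinitesimal_params <- function(s, sigma2, mating = c("polygamy", "monogamy"),
                                 fix_threshold = 5000, max_lineages = 4e5,
                                 min_fixed = 400) {
  mating <- match.arg(mating)
  if (sigma2 < 0) abort("sigma2 must be >= 0", class = "sweeprate_param_error")
  if (s <= 0) abort("s must be > 0", class = "sweeprate_param_error")
  if (fix_threshold < 10 / s) {
    abort(sprintf("fix_threshold (%g) too small: must be >> 1/s = %g", fix_threshold, 1 / s),
          class = "sweeprate_param_error")
  }
  structure(list(s = s, sigma2 = sigma2, mating = mating,
                 fix_threshold = fix_threshold, max_lineages = max_lineages,
                 min_fixed = min_fixed), class = "infinitesimal_params")
}

# one lineage: returns TRUE if it fixed
infinitesimal_lineage <- function(z0, p) {
  s <- p$s; v <- p$sigma2
  zeta <- z0
  repeat {
    n <- length(zeta)
    if (n == 0) return(FALSE)
    if (n >= p$fix_threshold) return(TRUE)
    if (p$mating == "polygamy") {
      ## Poisson offspring, expectation e^{zeta + s} / mean fitness; each
      ## offspring gets an independent fitness-weighted mate ~ N(sigma2, sigma2)
      counts <- rpois(n, exp(zeta + s - v / 2))
      parent <- rep(zeta, counts)
      mate <- rnorm(length(parent), v, sqrt(v))
    } else {
      ## one random mate per carrier; all offspring share it
      mate1 <- rnorm(n, 0, sqrt(v))
      counts <- rpois(n, exp(zeta + mate1 + s - v))
      parent <- rep(zeta, counts)
      mate <- rep(mate1, counts)
    }
    ## midparent inheritance with segregation variance sigma2/2, measured
    ## relative to the advancing population mean (v = sigma2 per generation)
    zeta <- (parent + mate) / 2 - v + rnorm(length(parent), 0, sqrt(v / 2))
  }
}

#' Fixation probability under the infinitesimal model
#'
#' Branching simulation of a focal mutant lineage with advantage `s` in a
#' population whose background log fitness is normally distributed with
#' stationary variance `sigma2` (unlinked loci, infinitesimal model).
#' Offspring trait values are normal about the mid-parent with segregation
#' variance `sigma2 / 2`; the population mean advances by `sigma2` per
#' generation (Fisher's theorem), and the mate pool is treated as infinite
#' and stationary.  A lineage is fixed when it reaches `fix_threshold`
#' members and lost at 0.  The fixation probability is proportional to the
#' square of the founder's fitness (`log p` has slope 2 in `z0`), and
#' averaging over founders drawn from the population reduces the baseline
#' `2s` by `exp(-4 sigma2)` under polygamy and `exp(-8 sigma2)` under
#' monogamy.
#'
#' @param z0 Founder background log fitness (deviation from the population
#'   mean), or `NULL` to draw founders at random from `N(0, sigma2)`.
#' @param params An [infinitesimal_params()] object.
#' @return One-row tibble with `estimate`, exact binomial `conf_lo` /
#'   `conf_hi`, `n_fixed`, `n_lineages`, `z0` (NA when random).
#' @export
infinitesimal_pfix <- function(z0 = NULL, params) {
  stopifnot(inherits(params, "infinitesimal_params"))
  n_fixed <- 0L
  n_run <- 0L
  while (n_run < params$max_lineages && n_fixed < params$min_fixed) {
    z <- if (is.null(z0)) rnorm(1, 0, sqrt(params$sigma2)) else z0
    n_fixed <- n_fixed + infinitesimal_lineage(z, params)
    n_run <- n_run + 1L
  }
  if (n_fixed < 5) {
    warning("fewer than 5 fixations; estimate may be unreliable (raise max_lineages)")
  }
  pf <- fixation_probability(n_fixed, n_run)
  dplyr::mutate(pf, z0 = if (is.null(z0)) NA_real_ else z0,
                n_lineages = n_run, .keep = "all")
}
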