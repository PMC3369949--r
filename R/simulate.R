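#' Initialise a wild-type population
#'
#' Creates the starting state of the individual-based model: `N` genomes with
#' no segregating mutations, an empty mutation registry, and the generation
#' counter at zero.  If `params$seed` is set, the R RNG is seeded so that the
#' whole run is reproducible.
#'
#' @param params A [sim_params()] object.
#' @return A `population_state`: list with elements `genomes` (list of integer
#'   id vectors, sorted by map position), `registry` (tibble of
#'   `MutationRecord`s), `fixed_log_fitness`, `generation` and `params`.
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  structure(list(
    genomes = replicate(params$N, integer(0), simplify = FALSE),
    registry = tibble(
      id = integer(0), position = numeric(0), s = numeric(0), count = integer(0),
      t_origin = integer(0), fate = character(0), t_fate = integer(0)),
    fixed_log_fitness = 0,
    generation = 0L,
    params = params
  ), class = "population_state")
}

#' Recombine two parental genomes
#'
#' Draws a Poisson(`R`) number of crossover points uniformly on `[0, R)`,
#' picks the starting parent by a fair coin, and builds the offspring from
#' alternating parental segments.  Genomes are sorted numeric vectors of
#' mutation map positions (optionally named by mutation id); the offspring is
#' returned in the same form.  Two loci at map distance `d` therefore
#' recombine with Haldane's frequency `(1 - exp(-2 d)) / 2`.
#'
#' @param parent_a,parent_b Sorted numeric vectors of mutation positions.
#' @param R Map length in Morgans.
#' @return Sorted numeric vector of offspring mutation positions.
#' @examples
#' set.seed(1)
#' recombine(c(a = 0.2), c(b = 0.9), R = 1)
#' @export
recombine <- function(parent_a, parent_b, R) {
  k <- rpois(1, R)
  if (k == 0) return(if (runif(1) < 0.5) parent_a else parent_b)
  cross <- sort(runif(k, 0, R))
  bounds <- c(0, cross, Inf)
  from_a <- (seq_len(k + 1) + (runif(1) < 0.5)) %% 2 == 0
  segs <- lapply(seq_len(k + 1), function(i) {
    p <- if (from_a[i]) parent_a else parent_b
    p[p >= bounds[i] & p < bounds[i + 1]]
  })
  out <- unlist(segs, use.names = TRUE)
  if (is.null(out)) out <- parent_a[0]
  out
}

#' Advance the population by one generation
#'
#' Reference (pure-R) implementation of one generation of the model:
#' relative fitness is the product of `(1 + s)` over carried segregating
#' mutations (times optional non-heritable lognormal noise); `N` parent pairs
#' are drawn independently with probability proportional to fitness (selfing
#' allowed); each pair yields one offspring via [recombine()]; a
#' Poisson(`N * U`) number of new mutations are placed at uniform positions
#' in uniformly chosen offspring; registry counts are refreshed, and
#' mutations hitting count 0 (lost) or `N` (fixed) are retired, fixed effects
#' being absorbed into `fixed_log_fitness`.
#'
#' This is the operation the compiled engine behind [run_simulation()]
#' repeats; the R version exists as an inspectable single-step API.
#'
#' @param state A `population_state` from [init_population()] or a previous
#'   step.
#' @return The updated `population_state`.
#' @export
step_generation <- function(state) {
  stopifnot(inherits(state, "population_state"))
  p <- state$params
  N <- p$N
  reg <- state$registry
  pos <- reg$position
  sel <- reg$s

  logw <- vapply(state$genomes, function(g) sum(log1p(sel[g])), 0)
  w <- exp(logw - max(logw))
  if (p$fitness_noise_var > 0) w <- w * exp(rnorm(N, 0, sqrt(p$fitness_noise_var)))
  if (!any(w > 0) || !all(is.finite(w))) {
    abort("degenerate state: total fitness is not positive", class = "sweeprate_state_error")
  }

  parents <- matrix(sample.int(N, 2 * N, replace = TRUE, prob = w), ncol = 2)
  offspring <- lapply(seq_len(N), function(i) {
    ga <- state$genomes[[parents[i, 1]]]
    gb <- state$genomes[[parents[i, 2]]]
    a_pos <- setNames(pos[ga], ga)
    b_pos <- setNames(pos[gb], gb)
    as.integer(names(recombine(a_pos, b_pos, p$R)))
  })

  gen <- state$generation + 1L
  M <- rpois(1, N * p$U)
  if (M > 0) {
    new_pos <- runif(M, 0, p$R)
    new_s <- if (p$effect_model == "fixed") rep(p$s, M) else rexp(M, 1 / p$sbar)
    ids <- nrow(reg) + seq_len(M)
    reg <- dplyr::bind_rows(reg, tibble(
      id = as.integer(ids), position = new_pos, s = new_s, count = 0L,
      t_origin = gen, fate = "segregating", t_fate = NA_integer_))
    pos <- reg$position
    recip <- sample.int(N, M, replace = TRUE)
    for (m in seq_len(M)) {
      g <- c(offspring[[recip[m]]], as.integer(ids[m]))
      offspring[[recip[m]]] <- g[order(pos[g])]
    }
  }

  counts <- tabulate(unlist(offspring), nbins = nrow(reg))
  active <- reg$fate == "segregating"
  reg$count[active] <- counts[which(active)]
  newly_lost <- active & reg$count == 0
  newly_fixed <- active & reg$count == N
  reg$fate[newly_lost] <- "lost"
  reg$fate[newly_fixed] <- "fixed"
  reg$t_fate[newly_lost | newly_fixed] <- gen
  fixed_logw <- state$fixed_log_fitness + sum(log1p(reg$s[newly_fixed]))
  if (any(newly_fixed)) {
    fixed_ids <- reg$id[newly_fixed]
    offspring <- lapply(offspring, function(g) g[!(g %in% fixed_ids)])
  }

  structure(list(genomes = offspring, registry = reg, fixed_log_fitness = fixed_logw,
                 generation = gen, params = p), class = "population_state")
}

#' Run the forward simulation
#'
#' Runs the individual-based model for `params$generations` generations using
#' the compiled engine (same dynamics as [step_generation()]), starting from
#' a purely wild-type population unless standing variation is supplied.
#'
#' @param params A [sim_params()] object.
#' @param init_mutations Optional data frame of standing variation with
#'   columns `position`, `s`, `count`; each mutation is placed in `count`
#'   distinct uniformly chosen genomes at generation 0.
#' @return A `sweep_sim` object: list with tibbles `fixations` (one row per
#'   fixed mutation: id, position, s, t_origin, t_fixed), `mutations` (every
#'   mutation ever arisen, with fate), `genstats` (per-generation mean and
#'   heritable variance of log fitness and number of segregating mutations),
#'   optional `trajectories` (id, generation, frequency) and
#'   `heterozygosity` (generation, H, n_alleles), plus `meta`.
#' @seealso [sim_params()], [glance.sweep_sim()], [substitution_density()]
#' @examples
#' sim <- run_simulation(sim_params(N = 200, U = 0.02, R = 2, s = 0.05,
#'                                  generations = 300, seed = 1))
#' glance(sim)
#' @export
run_simulation <- function(params, init_mutations = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  raw <- cpp_run_sim(
    N = params$N, U = params$U, R_len = params$R,
    effect_model = if (params$effect_model == "fixed") 0L else 1L,
    s_par = s_or_sbar(params),
    generations = params$generations,
    fitness_noise_sd = sqrt(params$fitness_noise_var),
    record_traj = params$record_trajectories,
    traj_stride = params$traj_stride,
    marker_pos = if (is.null(params$marker_position)) -1 else params$marker_position,
    paint_gen = if (is.null(params$paint_generation)) -1L else params$paint_generation,
    stop_at_marker_fixation = !is.null(params$marker_position),
    init_muts = init_mutations)

  mutations <- as_tibble(raw$mutations)
  fixations <- mutations |>
    dplyr::filter(.data$fate == "fixed") |>
    dplyr::select("id", "position", "s", "t_origin", t_fixed = "t_fate")
  out <- list(
    fixations = fixations,
    mutations = mutations,
    genstats = as_tibble(raw$genstats),
    fixed_log_fitness = raw$fixed_log_fitness,
    meta = list(params = params, burn_in = params$burn_in,
                generations_run = raw$generations_run,
                engine = "cpp", seed = params$seed,
                version = as.character(utils::packageVersion("sweeprate")))
  )
  if (!is.null(raw$trajectories)) {
    out$trajectories <- as_tibble(raw$trajectories) |>
      dplyr::mutate(frequency = .data$count / params$N)
  }
  if (!is.null(raw$heterozygosity)) out$heterozygosity <- as_tibble(raw$heterozygosity)
  structure(out, class = "sweep_sim")
}

#' @export
print.sweep_sim <- function(x, ...) {
  p <- x$meta$params
  cat(sprintf("<sweep_sim> N = %d, U = %g, R = %g: %d generations, %d fixations\n",
              p$N, p$U, p$R, x$meta$generations_run, nrow(x$fixations)))
  invisible(x)
}

#' Summarise a simulation run
#'
#' One-row summary of the post-burn-in steady state: the measured density of
#' sweeps per Morgan per generation, the baseline (no-interference) density,
#' their ratio, the fixation probability of post-burn-in mutations with
#' resolved fates, and the mean heritable variance in log fitness.
#'
#' @param x A `sweep_sim` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.sweep_sim <- function(x, ...) {
  p <- x$meta$params
  window <- c(x$meta$burn_in, x$meta$generations_run)
  Lambda <- substitution_density(x$fixations, window = window, R = p$R)
  resolved <- x$mutations |>
    dplyr::filter(.data$t_origin > window[1], .data$fate != "segregating")
  pf <- if (nrow(resolved) > 0) {
    fixation_probability(sum(resolved$fate == "fixed"), nrow(resolved))
  } else tibble(estimate = NA_real_, conf_lo = NA_real_, conf_hi = NA_real_)
  base <- baseline(N = p$N, U = p$U, R = p$R, s = s_or_sbar(p))
  gs <- x$genstats |> dplyr::filter(.data$generation >= window[1])
  tibble(
    Lambda = Lambda, Lambda0 = base$Lambda0, ratio = Lambda / base$Lambda0,
    p_fix = pf$estimate, p_fix_lo = pf$conf_lo, p_fix_hi = pf$conf_hi,
    sigma2 = mean(gs$var_log_fitness), n_fixations = nrow(x$fixations),
    window_lo = window[1], window_hi = window[2])
}
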