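#' Simulation parameters
#'
#' Bundle and validate the parameters of the individual-based model: a
#' well-mixed population of `N` haploids in which beneficial mutations arise
#' at genomic rate `U` per genome per generation, land at uniform positions on
#' a continuous linear map of total length `R` Morgans, and multiply fitness
#' by `1 + s`.  Mating is polygamous: each of the `N` offspring is produced by
#' a pair of parents drawn independently with probability proportional to
#' fitness (so selfing is possible), with crossovers at Poisson(`R`) uniform
#' positions.
#'
#' @param N Haploid population size (>= 2).
#' @param U Genomic beneficial mutation rate per genome per generation.
#' @param R Total genetic map length in Morgans (> 0).
#' @param s Selective advantage of every beneficial mutation (fixed-effects
#'   model).  Give exactly one of `s` or `sbar`.
#' @param sbar Mean selective advantage under the exponential-effects model.
#' @param generations Number of generations to run (>= 1).
#' @param seed Integer RNG seed; stored so a run can be reproduced exactly.
#' @param fitness_noise_var Variance of optional non-heritable per-generation
#'   Gaussian noise added to log fitness (uncorrelated across generations);
#'   default 0.
#' @param burn_in Generations discarded before measuring steady-state rates.
#'   Default `max(1000, 10 / s)` capped at half the run, reported in the run
#'   metadata.
#' @param record_trajectories Record per-generation copy numbers of every
#'   segregating mutation.
#' @param traj_stride Record trajectories every `traj_stride` generations.
#' @param marker_position Map position of a neutral marker locus, or `NULL`
#'   for none.  See [paint_markers()].
#' @param paint_generation Generation at which every individual receives a
#'   unique neutral marker allele (defaults to `burn_in`).
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(N = 500, U = 0.01, R = 5, s = 0.05, generations = 200, seed = 1)
#' @export
sim_params <- function(N, U, R, s = NULL, sbar = NULL, generations = 1000,
                       seed = NULL, fitness_noise_var = 0, burn_in = NULL,
                       record_trajectories = FALSE, traj_stride = 1L,
                       marker_position = NULL, paint_generation = NULL) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(sprintf("invalid `%s`: %s", field, msg), class = "sweeprate_param_error")
  }
  chk(is.numeric(N) && length(N) == 1 && N >= 2 && N == round(N), "N",
      "must be a single integer >= 2 (sexual reproduction needs two parents)")
  chk(is.numeric(U) && length(U) == 1 && U >= 0, "U", "must be a single number >= 0")
  chk(is.numeric(R) && length(R) == 1 && R > 0, "R", "must be a single positive map length in Morgans")
  chk(xor(is.null(s), is.null(sbar)), "s",
      "give exactly one of `s` (fixed effects) or `sbar` (exponential effects)")
  if (!is.null(s)) chk(is.numeric(s) && length(s) == 1 && s > 0, "s", "must be a single number > 0")
  if (!is.null(sbar)) chk(is.numeric(sbar) && length(sbar) == 1 && sbar > 0, "sbar", "must be a single number > 0")
  chk(is.numeric(generations) && length(generations) == 1 && generations >= 1,
      "generations", "must be >= 1")
  chk(is.numeric(fitness_noise_var) && length(fitness_noise_var) == 1 && fitness_noise_var >= 0,
      "fitness_noise_var", "must be >= 0")
  chk(is.numeric(traj_stride) && traj_stride >= 1, "traj_stride", "must be >= 1")
  s_scale <- if (is.null(s)) sbar else s
  if (is.null(burn_in)) burn_in <- min(floor(generations / 2), max(1000, ceiling(10 / s_scale)))
  chk(burn_in >= 0 && burn_in < generations, "burn_in", "must lie inside the run")
  if (!is.null(marker_position)) {
    chk(marker_position >= 0 && marker_position < R, "marker_position", "must lie in [0, R)")
    if (is.null(paint_generation)) paint_generation <- max(burn_in, 1L)
    chk(paint_generation >= 1 && paint_generation <= generations, "paint_generation",
        "must lie inside the run")
  }
  structure(list(
    N = as.integer(N), U = U, R = R, s = s, sbar = sbar,
    effect_model = if (is.null(s)) "exponential" else "fixed",
    generations = as.integer(generations), seed = seed,
    fitness_noise_var = fitness_noise_var, burn_in = as.integer(burn_in),
    record_trajectories = isTRUE(record_trajectories),
    traj_stride = as.integer(traj_stride),
    marker_position = marker_position,
    paint_generation = if (is.null(marker_position)) NULL else as.integer(paint_generation)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  eff <- if (x$effect_model == "fixed") sprintf("s = %g", x$s) else sprintf("sbar = %g (exponential)", x$sbar)
  cat(sprintf("<sim_params> N = %d, U = %g, R = %g Morgans, %s, %d generations (burn-in %d)\n",
              x$N, x$U, x$R, eff, x$generations, x$burn_in))
  invisible(x)
}

s_or_sbar <- function(params) if (params$effect_model == "fixed") params$s else params$sbar
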