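#' Density of adaptive substitutions per Morgan per generation
#'
#' Counts fixations whose fixation time falls inside `window` and divides by
#' the window length times the map length, giving the density of selective
#' sweeps per Morgan per generation.
#'
#' @param fixations Tibble with a `t_fixed` column (as in
#'   `sweep_sim$fixations`).
#' @param window Two-element numeric `(lo, hi]` generation span.
#' @param R Map length in Morgans.
#' @return Density of sweeps (numeric scalar).
#' @export
substitution_density <- function(fixations, window, R) {
  if (length(window) != 2 || !(window[2] > window[1])) {
    abort("`window` must be an increasing generation span", class = "sweeprate_param_error")
  }
  if (R <= 0) abort("`R` must be positive", class = "sweeprate_param_error")
  n <- sum(fixations$t_fixed > window[1] & fixations$t_fixed <= window[2])
  n / (diff(window) * R)
}

#' Fixation probability with an exact binomial confidence interval
#'
#' @param n_fixed Number of mutations that fixed.
#' @param n_mutations Number of mutations with resolved fates (fixed + lost);
#'   mutations still segregating should be excluded (right-censoring).
#' @param conf_level Confidence level for the Clopper-Pearson interval.
#' @return One-row tibble with `estimate`, `conf_lo`, `conf_hi`, `n_fixed`,
#'   `n_mutations`.
#' @export
fixation_probability <- function(n_fixed, n_mutations, conf_level = 0.95) {
  if (n_mutations <= 0) abort("`n_mutations` must be positive", class = "sweeprate_param_error")
  if (n_fixed > n_mutations) abort("`n_fixed` cannot exceed `n_mutations`", class = "sweeprate_param_error")
  bt <- binom.test(n_fixed, n_mutations, conf.level = conf_level)
  tibble(estimate = n_fixed / n_mutations,
         conf_lo = bt$conf.int[1], conf_hi = bt$conf.int[2],
         n_fixed = n_fixed, n_mutations = n_mutations)
}

#' Mean and heritable variance of log fitness
#'
#' Computes the mean and variance across individuals of the heritable log
#' fitness, i.e. the sum of `log(1 + s)` over carried mutations (segregating
#' plus fixed contribution); non-heritable per-generation noise is excluded
#' by construction.  By Fisher's fundamental theorem the variance equals the
#' expected per-generation increase of the mean at low interference.
#'
#' @param state A `population_state` (see [init_population()]).
#' @return One-row tibble with `mean_log_fitness` and `var_log_fitness`
#'   (population variance, denominator `N`).
#' @export
log_fitness_stats <- function(state) {
  stopifnot(inherits(state, "population_state"))
  sel <- state$registry$s
  lw <- vapply(state$genomes, function(g) sum(log1p(sel[g])), 0)
  n <- length(lw)
  tibble(mean_log_fitness = mean(lw) + state$fixed_log_fitness,
         var_log_fitness = var(lw) * (n - 1) / n)
}

#' Sojourn time of a sweep between two frequencies
#'
#' Time from the last up-crossing of `f_lo` before fixation to the first
#' subsequent crossing of `f_hi` (the last-up-crossing convention ignores
#' early stochastic dips).  Returns `NA` for lost mutations.
#'
#' @param traj Tibble for a single mutation with columns `generation` and
#'   `frequency`, ending at frequency 0 or 1 (resolved).
#' @param f_lo,f_hi Frequency band, `0 <= f_lo < f_hi <= 1`.
#' @return Sojourn time in generations, or `NA` if the mutation was lost.
#' @export
sojourn_time <- function(traj, f_lo = 0.1, f_hi = 0.9) {
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= 1)) {
    abort("need 0 <= f_lo < f_hi <= 1", class = "sweeprate_param_error")
  }
  traj <- traj[order(traj$generation), ]
  f_end <- traj$frequency[nrow(traj)]
  if (!(f_end %in% c(0, 1))) {
    abort("trajectory is unresolved (last frequency is neither 0 nor 1)",
          class = "sweeprate_state_error")
  }
  if (f_end == 0) return(NA_real_)
  below <- which(traj$frequency < f_lo)
  t_lo_idx <- if (length(below) == 0) 1L else max(below) + 1L
  above <- which(traj$frequency >= f_hi & traj$generation >= traj$generation[t_lo_idx])
  if (length(above) == 0) return(NA_real_)
  traj$generation[min(above)] - traj$generation[t_lo_idx]
}

#' Autocorrelation of the per-generation rate of adaptation
#'
#' Standard normalised autocorrelation of a series (typically the
#' per-generation change in mean log fitness).  Under strong interference
#' the rate of adaptation is negatively autocorrelated on the timescale over
#' which new alleles reach interfering frequencies.
#'
#' @param series Numeric vector, e.g. `diff(genstats$mean_log_fitness)`.
#' @param max_lag Largest lag to report.
#' @return Tibble with columns `lag` (0..max_lag) and `acf` (lag 0 is 1).
#' @export
rate_autocorrelation <- function(series, max_lag) {
  if (length(series) <= max_lag) {
    abort("series must be longer than `max_lag`", class = "sweeprate_param_error")
  }
  if (var(series) == 0) abort("series has zero variance", class = "sweeprate_state_error")
  a <- acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble(lag = 0:max_lag, acf = as.numeric(a$acf))
}
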