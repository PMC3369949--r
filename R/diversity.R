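#' Run a neutral-marker "painting" experiment
#'
#' After a burn-in that lets the population approach a steady rate of
#' adaptation, every individual is painted with a unique, selectively neutral
#' marker allele at a single map position (by default the middle of the
#' chromosome).  Markers are inherited through recombination like any locus
#' but contribute nothing to fitness; the simulation then continues until one
#' marker allele fixes (or the run ends), recording the marker heterozygosity
#' `H_t = 1 - sum(p_i^2)` each generation.  The long-term rate of decay of
#' `H_t` estimates the pairwise coalescence rate under drift plus genetic
#' draft from the sweeps.
#'
#' @param params A [sim_params()] object (its `marker_position` /
#'   `paint_generation` are overridden by the arguments here).
#' @param position Marker map position; default `R/2`.
#' @param paint_generation Generation at which to paint; default the burn-in
#'   (at least 1000 generations unless the run is shorter).
#' @param replicates Number of independent replicate runs.
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @return A `het_traces` object: tibble with columns `replicate`,
#'   `generation`, `H`, `n_alleles`, with the parameters in
#'   `attr(, "params")`.
#' @seealso [estimate_T2()]
#' @export
paint_markers <- function(params, position = params$R / 2,
                          paint_generation = NULL, replicates = 1,
                          seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (position < 0 || position >= params$R) {
    abort("marker `position` must lie in [0, R)", class = "sweeprate_param_error")
  }
  if (is.null(paint_generation)) paint_generation <- max(1L, min(1000L, params$burn_in))
  traces <- purrr::map_dfr(seq_len(replicates), function(i) {
    p <- params
    p$marker_position <- position
    p$paint_generation <- as.integer(paint_generation)
    p$seed <- if (is.null(seed)) NULL else seed + i - 1
    sim <- run_simulation(p)
    dplyr::mutate(sim$heterozygosity, replicate = i, .before = 1)
  })
  structure(traces, class = c("het_traces", class(traces)),
            params = params, position = position,
            paint_generation = paint_generation)
}

#' Heterozygosity of an allele-frequency vector
#'
#' `H = 1 - sum(p_i^2)`, the probability that two individuals sampled with
#' replacement carry different alleles.
#'
#' @param freqs Non-negative allele frequencies summing to 1.
#' @return Heterozygosity in `[0, 1 - 1/k]` for `k` alleles.
#' @export
heterozygosity <- function(freqs) {
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8) {
    abort("`freqs` must be non-negative and sum to 1", class = "sweeprate_param_error")
  }
  1 - sum(freqs^2)
}

#' Estimate the pairwise coalescence time from heterozygosity decay
#'
#' Fits the long-term exponential decay `H_t ~ H0 * exp(-(t - t0) / T2)` to
#' the replicate-averaged heterozygosity trace.  Replicates whose diversity
#' has already been lost contribute 0, so the average is an unbiased
#' estimate of `E[H_t]`, whose long-term log-linear slope is the pairwise
#' coalescence rate (fitting individual replicates on the log scale instead
#' is biased steep, because log is concave and single traces end in jumps).
#' The fitted offset absorbs the initial phase in which heterozygosity
#' decays only by drift at rate `1/N` before draft from linked sweeps takes
#' over; the fit window starts where a rolling log-linear slope stabilises
#' (relative change below `slope_tol` between consecutive windows) and stops
#' when the mean heterozygosity drops below `H_floor`, after which the
#' average is carried by a handful of surviving alleles.  The standard error
#' is computed by jackknifing whole replicates.
#'
#' @param traces A `het_traces` object (or tibble with `replicate`,
#'   `generation`, `H`).
#' @param window_frac Width of the rolling window as a fraction of the
#'   usable trace length (at least 10 points).
#' @param slope_tol Relative slope-change threshold declaring stability.
#' @param H_floor Mean heterozygosity below which points are excluded (the
#'   tail is carried by a handful of surviving replicates).
#' @param min_points Minimum number of usable points required.
#' @return A `T2_fit` object; see [tidy.T2_fit()] and [glance.T2_fit()].
#' @export
estimate_T2 <- function(traces, window_frac = 0.2, slope_tol = 0.2,
                        H_floor = 0.05, min_points = 12) {
  reps <- unique(traces$replicate)
  grid <- sort(unique(traces$generation))
  hmat <- vapply(reps, function(r) {
    d <- traces[traces$replicate == r, ]
    h <- stats::approx(d$generation, d$H, xout = grid, rule = 1)$y
    h[grid > max(d$generation)] <- 0  # diversity already lost
    h
  }, numeric(length(grid)))
  hmat <- matrix(hmat, nrow = length(grid))
  fit_one <- function(cols) {
    hbar <- rowMeans(hmat[, cols, drop = FALSE])
    keep <- !is.na(hbar) & hbar > 0
    t <- grid[keep]; hbar <- hbar[keep]
    below <- which(hbar < H_floor)
    if (length(below) > 0 && below[1] > min_points) {
      t <- t[seq_len(below[1] - 1)]
      hbar <- hbar[seq_len(below[1] - 1)]
    }
    if (length(t) < min_points) {
      abort(sprintf("only %d usable points above H_floor; traces too short for a stable fit",
                    length(t)), class = "sweeprate_fit_error")
    }
    lh <- log(hbar)
    n <- length(t)
    wl <- max(10, ceiling(window_frac * n))
    starts <- seq(1, max(1, n - wl), by = max(1, floor(wl / 2)))
    slopes <- vapply(starts, function(i) {
      idx <- i:min(n, i + wl - 1)
      coef(lm(lh[idx] ~ t[idx], weights = hbar[idx]))[2]
    }, 0)
    stable <- 1L
    if (length(slopes) > 1) {
      rel <- abs(diff(slopes)) / pmax(abs(slopes[-length(slopes)]), 1e-12)
      ok <- which(rel < slope_tol)
      stable <- if (length(ok) > 0) ok[1] else 1L
    }
    idx <- starts[stable]:n
    # weights ~ hbar: the sampling variance of log(hbar) scales as 1/hbar
    fit <- lm(lh[idx] ~ t[idx], weights = hbar[idx])
    list(rate = -unname(coef(fit)[2]), t_start = t[starts[stable]],
         n_points = length(idx),
         r_squared = suppressWarnings(summary(fit)$r.squared))
  }
  full <- fit_one(seq_along(reps))
  jack <- if (length(reps) > 2) {
    vapply(seq_along(reps), function(i) fit_one(setdiff(seq_along(reps), i))$rate, 0)
  } else NULL
  rate_se <- if (is.null(jack)) NA_real_ else {
    sqrt((length(reps) - 1) / length(reps) * sum((jack - mean(jack))^2))
  }
  structure(list(rate = full$rate, T2 = 1 / full$rate, rate_se = rate_se,
                 t_start = full$t_start, n_points = full$n_points,
                 r_squared = full$r_squared, n_replicates = length(reps),
                 jackknife_rates = jack),
            class = "T2_fit")
}

#' @export
print.T2_fit <- function(x, ...) {
  cat(sprintf("<T2_fit> T2 = %.1f generations (mean rate %.3g/gen over %d replicates)\n",
              x$T2, x$rate, x$n_replicates))
  invisible(x)
}

#' Jackknife coalescence-rate pseudo-fits
#' @param x A `T2_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per left-out replicate and the decay `rate`
#'   refitted from the remaining traces (empty when fewer than 3 replicates).
#' @export
tidy.T2_fit <- function(x, ...) {
  if (is.null(x$jackknife_rates)) return(tibble(left_out = integer(0), rate = numeric(0)))
  tibble(left_out = seq_along(x$jackknife_rates), rate = x$jackknife_rates)
}

#' One-row summary of a coalescence-time fit
#' @param x A `T2_fit` object.
#' @param ... Unused.
#' @return Tibble with `T2`, mean `rate`, its standard error and the number
#'   of replicates.
#' @export
glance.T2_fit <- function(x, ...) {
  tibble(T2 = x$T2, rate = x$rate, rate_se = x$rate_se,
         n_replicates = x$n_replicates, t_start = x$t_start,
         n_points = x$n_points, r_squared = x$r_squared)
}
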