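## Branching-process numerics: fixation probability of a focal beneficial
## allele near one (or two) deterministic selective sweeps, the interference
## kernel over time and map distance, and its integral Z.
##
## A rare focal allele with advantage s_f at recombination distance r from a
## sweeping allele (advantage s_w, frequency x(t)) is followed as a branching
## process on the two backgrounds.  Its fixation probabilities p_B (on the
## sweeping background) and p_b (ancestral) obey, backward in time,
##   -dp_B/dt = (s_f + s_w (1 - x)) p_B - p_B^2/2 + r (1 - x) (p_b - p_B)
##   -dp_b/dt = (s_f - s_w x)       p_b - p_b^2/2 + r x       (p_B - p_b)
## with Poisson offspring (drift term p^2/2), terminal value p0 = 2 s_f on
## the sweeping background after the sweep completes, and on the ancestral
## background the post-sweep equilibrium in which rescue is only possible by
## recombining onto the fixed background.

# positive root of  sigma p - p^2/2 + r (p_target - p) = 0
post_sweep_equilibrium <- function(sigma, r, p_target) {
  a <- sigma - r
  a + sqrt(a^2 + 2 * r * p_target)
}

#' Deterministic trajectory of a selective sweep
#'
#' Logistic solution `x(t) = x0 e^{st} / (1 - x0 + x0 e^{st})` for an
#' established allele of advantage `s` starting at frequency `x0` at `t = 0`.
#'
#' @param x0 Initial frequency in `(0, 1)` (the establishment frequency,
#'   typically `1/(2 N s)`).
#' @param s Selective advantage (> 0).
#' @param t Time in generations (vectorised).
#' @return Frequency at time `t`.
#' @export
deterministic_sweep <- function(x0, s, t) {
  if (any(x0 <= 0 | x0 >= 1)) abort("x0 must lie in (0, 1)", class = "sweeprate_param_error")
  if (s <= 0) abort("s must be > 0", class = "sweeprate_param_error")
  1 / (1 + ((1 - x0) / x0) * exp(-s * t))
}

# Backward solve of the two-background system for one sweep.
# Returns a tibble over birth times t (centred on the sweep midpoint x = 1/2)
# with columns x, pB, pb, pbar, loss.
solve_pair <- function(s_focal, s_sweep, r, N, x0 = NULL,
                       pad = 30 / s_focal, dt = 0.05 / max(s_focal, s_sweep),
                       rtol = 1e-8) {
  if (is.null(x0)) x0 <- 1 / (2 * N * s_sweep)
  xe <- 1 - 1 / (2 * N)
  A <- (1 - x0) / x0
  t_mid <- log(A) / s_sweep
  t_end <- log((xe / (1 - xe)) * A) / s_sweep
  p0 <- 2 * s_focal
  pb_end <- post_sweep_equilibrium(s_focal - s_sweep, r, p0)
  xfun <- function(t) ifelse(t < 0, 0, ifelse(t > t_end, 1, 1 / (1 + A * exp(-s_sweep * t))))
  deriv <- function(tau, y, parms) {
    t <- t_end - tau
    x <- xfun(t)
    pB <- y[1]; pb <- y[2]
    list(c((s_focal + s_sweep * (1 - x)) * pB - pB^2 / 2 + r * (1 - x) * (pb - pB),
           (s_focal - s_sweep * x) * pb - pb^2 / 2 + r * x * (pB - pb)))
  }
  taus <- seq(0, t_end + pad, by = dt)
  sol <- deSolve::lsoda(c(p0, pb_end), taus, deriv, rtol = rtol, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) {
    abort("backward integration failed to converge", class = "sweeprate_numeric_error")
  }
  t <- t_end - sol[, 1]
  x <- xfun(t)
  pbar <- x * sol[, 2] + (1 - x) * sol[, 3]
  tibble(t = t - t_mid, x = x, pB = sol[, 2], pb = sol[, 3], pbar = pbar,
         loss = pmin(pmax(1 - pbar / p0, 0), 1)) |>
    dplyr::arrange(t)
}

#' Fixation probability of a focal allele near one selective sweep
#'
#' Integrates the two-background branching-process equations backward from
#' after the sweep and averages over the background the focal mutation
#' arises on (weights `x(t_birth)` and `1 - x(t_birth)`).
#'
#' @param s_focal,s_sweep Selective advantages of the focal allele and the
#'   sweeping allele.
#' @param r Recombination rate per generation between the two loci (equal to
#'   the map distance in Morgans under tight linkage).  `Inf` decouples the
#'   loci.
#' @param t_birth Birth time(s) of the focal mutation relative to the sweep
#'   midpoint (frequency 1/2), in generations.
#' @param N Population size; sets the establishment frequency `x0` and the
#'   trajectory truncation at `1 - 1/(2N)`.
#' @param x0 Establishment frequency of the sweep; default `1/(2 N s_sweep)`.
#' @return Tibble with `t_birth`, `p_fix`, `p0` and `loss` (fractional
#'   reduction `1 - p_fix/p0`).
#' @export
pair_fixation <- function(s_focal, s_sweep, r, t_birth, N, x0 = NULL) {
  p0 <- 2 * s_focal
  if (!is.finite(r)) {
    return(tibble(t_birth = t_birth, p_fix = p0, p0 = p0, loss = 0))
  }
  sol <- solve_pair(s_focal, s_sweep, r, N, x0 = x0)
  pf <- stats::approx(sol$t, sol$pbar, xout = t_birth, rule = 2)$y
  tibble(t_birth = t_birth, p_fix = pf, p0 = p0,
         loss = pmin(pmax(1 - pf / p0, 0), 1))
}

# Time-integrated fractional loss caused by one sweep at distance r.
loss_time_integral <- function(s_focal, s_sweep, r, N, ...) {
  sol <- solve_pair(s_focal, s_sweep, r, N, ...)
  sum(diff(sol$t) * (head(sol$loss, -1) + tail(sol$loss, -1)) / 2)
}

#' Interference kernel of a single sweep
#'
#' Fractional loss of fixation probability `1 - p/p0` of a focal allele as a
#' function of the scaled map distance `r / s_sweep` and the scaled birth
#' time `s_sweep * (t - t_mid)` relative to the sweep midpoint.  On these
#' axes the surface is independent of `N` and `s` (for `N s >> 1`) apart
#' from endpoint effects of order `x0`.
#'
#' @param ratio `s_focal / s_sweep`.
#' @param scaled_distances,scaled_times Grid of scaled coordinates.
#' @param s_sweep Sweep advantage used for the computation (the result is
#'   scale-invariant; this only sets the numerical units).
#' @param N Population size used for the establishment frequency.
#' @return A `kernel_grid` tibble with columns `scaled_distance`,
#'   `scaled_time`, `loss`, and the parameters as attributes.
#' @export
interference_kernel <- function(ratio = 1,
                                scaled_distances = c(0, 10^seq(-3, 1, length.out = 13)),
                                scaled_times = seq(-30, 10, length.out = 81),
                                s_sweep = 0.02, N = 1e7) {
  s_focal <- ratio * s_sweep
  grid <- purrr::map_dfr(scaled_distances, function(d) {
    sol <- solve_pair(s_focal, s_sweep, r = d * s_sweep, N = N)
    loss <- stats::approx(sol$t * s_sweep, sol$loss, xout = scaled_times, rule = 2)$y
    tibble(scaled_distance = d, scaled_time = scaled_times, loss = loss)
  })
  structure(grid, class = c("kernel_grid", class(grid)),
            ratio = ratio, s_sweep = s_sweep, N = N)
}

#' The interference constant Z
#'
#' Integrates the fractional fixation-probability loss caused by a single
#' sweep over all birth times and over map positions uniformly distributed
#' on both sides of the sweep:
#' `Z = integral dt integral_0^Inf dr (1 - pbar(t, r) / p0)`,
#' so that a density `Lambda` of sweeps per Morgan per generation reduces the
#' average fixation probability by `2 Z Lambda`.  The integral is
#' dimensionless and, for `N s >> 1`, nearly independent of `N` and `s`.
#' The large-distance tail (which decays as `1/r^2`, Robertson's unlinked
#' limit) is added analytically beyond `r_max`.
#'
#' @param ratio `s_focal / s_sweep` (1 for the equal-effects constant).
#' @param s,N Reference selection coefficient and population size.
#' @param n_r Number of log-spaced map distances.
#' @param r_min,r_max Distance range in units of `s_sweep`.
#' @param dt Backward-integration output step in units of `1/s`.
#' @param pad Pre-sweep padding in units of `1/s`.
#' @return The constant `Z` (numeric scalar) with attributes `tail`
#'   (analytic tail contribution) and `n_r`.
#' @examples
#' \donttest{compute_Z()  # about 1.05 at the default convention}
#' @export
compute_Z <- function(ratio = 1, s = 0.02, N = 1e7, n_r = 160,
                      r_min = 1e-6, r_max = 400, dt = 0.03, pad = 30) {
  if (ratio <= 0) abort("ratio must be > 0", class = "sweeprate_param_error")
  s_focal <- ratio * s
  s_sweep <- s
  rs <- s_sweep * exp(seq(log(r_min), log(r_max), length.out = n_r))
  I <- vapply(rs, function(r) {
    loss_time_integral(s_focal, s_sweep, r, N,
                       pad = pad / s_focal, dt = dt / max(s_focal, s_sweep))
  }, 0)
  Z_main <- sum(diff(rs) * (head(I, -1) + tail(I, -1)) / 2)
  Z_tail <- I[n_r] * rs[n_r]  # integral of I(r_max) (r_max/r)^2 beyond r_max
  structure(Z_main + Z_tail, tail = Z_tail, n_r = n_r,
            distances = rs, integrand = I)
}

#' Interference coefficient for unequal selection coefficients
#'
#' How much a sweep with advantage `s_sweep = ratio * s_focal` interferes
#' with a focal allele: `c(ratio)` is the same time-and-map integral as
#' [compute_Z()], so `c(1) = Z`.  Alongside the numerical value, two closed
#' forms are reported: the proportional approximation `c = ratio` (accurate
#' for `ratio <~ 1`, overestimating interference for large ratios) and a
#' large-ratio form `a * ratio / (b + log(ratio))` with `a = 2.6`,
#' `b = 1.57` calibrated against the package's own kernel integration.
#'
#' @param ratio `s_sweep / s_focal` (> 0), vectorised.
#' @param ... Passed to [compute_Z()] (grid controls).
#' @return Tibble with `ratio`, `c_numeric`, `c_crude`, `c_large_ratio`.
#' @export
interference_coefficient <- function(ratio, ...) {
  if (any(ratio <= 0)) abort("ratio must be > 0", class = "sweeprate_param_error")
  cn <- vapply(ratio, function(z) as.numeric(compute_Z(ratio = 1 / z, ...)) , 0)
  tibble(ratio = ratio, c_numeric = cn, c_crude = ratio,
         c_large_ratio = 2.6 * ratio / (1.57 + pmax(log(ratio), 0.01)))
}

#' Interaction of two selective sweeps
#'
#' Solves the four-background generalisation of the branching-process
#' equations for a focal allele between two sweeps separated by `separation`
#' Morgans and offset by `dt_offset` generations, with the second sweep
#' introduced either in complete negative linkage disequilibrium with the
#' first (`"LD"`, as in a finite population) or in linkage equilibrium
#' (`"LE"`).  Returns the time-integrated combined fractional loss at the
#' focal position and its ratio to the sum of the two single-sweep losses; a
#' ratio near 1 means interference is additive.
#'
#' @param separation Map distance between the sweeps in Morgans.
#' @param dt_offset Start-time offset of the second sweep in generations.
#' @param N Population size (establishment frequency `1/(2 N s)`).
#' @param linkage_mode `"LD"` or `"LE"` initialisation of the second sweep.
#' @param s Selective advantage of both sweeps and the focal allele.
#' @param focal_frac Position of the focal locus between the sweeps, as a
#'   fraction of `separation` (default midway).
#' @return One-row tibble with `combined_loss`, `single_loss_sum`,
#'   `additivity_ratio` and the parameters.
#' @export
two_sweep_interaction <- function(separation, dt_offset = 0, N = 1e5,
                                  linkage_mode = c("LD", "LE"), s = 0.02,
                                  focal_frac = 0.5) {
  linkage_mode <- match.arg(linkage_mode)
  x0 <- 1 / (2 * N * s)
  xe <- 1 - 1 / (2 * N)
  r12 <- separation
  r1 <- focal_frac * separation
  r2 <- (1 - focal_frac) * separation
  p0 <- 2 * s

  ## forward genotype dynamics: y = (f00, f01, f10, f11); sweep 1 = third bit
  gderiv <- function(t, y, parms) {
    x1 <- y[3] + y[4]; x2 <- y[2] + y[4]
    D <- y[4] * y[1] - y[3] * y[2]
    sbar <- s * (x1 + x2)
    g <- c(0, s, s, 2 * s)
    eta <- c(1, -1, -1, 1)
    list(y * (g - sbar) - eta * r12 * D)
  }
  ## phase 1: sweep 1 alone from x0 until dt_offset (if positive)
  y <- c(1 - x0, 0, x0, 0)
  t1 <- max(dt_offset, 0)
  grid1 <- if (t1 > 0) seq(0, t1, length.out = max(2, ceiling(t1 * s / 0.05))) else numeric(0)
  if (t1 > 0) {
    sol1 <- deSolve::lsoda(y, grid1, gderiv, rtol = 1e-10, atol = 1e-14)
    y <- as.numeric(sol1[nrow(sol1), -1])
  } else {
    sol1 <- NULL
  }
  ## introduce sweep 2 at frequency x0
  x1_now <- y[3] + y[4]
  if (linkage_mode == "LD") {
    take <- min(x0, y[1])
    y <- y + c(-take, take, 0, 0)
    rem <- x0 - take
    y <- y + c(0, 0, -rem, rem)
  } else {
    y <- c(y[1] - x0 * (1 - x1_now), x0 * (1 - x1_now), y[3] - x0 * x1_now, x0 * x1_now)
  }
  ## phase 2: both sweeps to completion
  dur <- (2 * log((1 - x0) / x0) + 30) / s
  grid2 <- seq(t1, t1 + dur, by = 0.05 / s)
  sol2 <- deSolve::lsoda(y, grid2, gderiv, rtol = 1e-10, atol = 1e-14)
  tt <- c(if (t1 > 0) sol1[-nrow(sol1), 1] else numeric(0), sol2[, 1])
  ff <- rbind(if (t1 > 0) sol1[-nrow(sol1), -1, drop = FALSE] else NULL, sol2[, -1])
  ff <- pmin(pmax(ff, 0), 1)
  fget <- lapply(1:4, function(k) stats::approxfun(tt, ff[, k], rule = 2))
  t_all_end <- tt[length(tt)]

  ## terminal (post-fixation) focal equilibria on each background
  p11 <- p0
  p10 <- post_sweep_equilibrium(-s, r2, p11)  # carries sweep1, lacks sweep2
  p01 <- post_sweep_equilibrium(-s, r1, p11)
  a00 <- -2 * s - r1 - r2
  p00 <- a00 + sqrt(a00^2 + 2 * (r1 * p01 + r2 * p10))

  pderiv <- function(tau, p, parms) {
    t <- t_all_end - tau
    f <- vapply(fget, function(fn) fn(t), 0)
    f <- f / sum(f)
    x1 <- f[3] + f[4]; x2 <- f[2] + f[4]
    sig <- c(s - s * x1 - s * x2, 2 * s - s * x1 - s * x2,
             2 * s - s * x1 - s * x2, 3 * s - s * x1 - s * x2)
    ## focal lies between the sweeps: single-crossover moves change one locus
    d1 <- c(r1 * x1 * (p[3] - p[1]), r1 * x1 * (p[4] - p[2]),
            r1 * (1 - x1) * (p[1] - p[3]), r1 * (1 - x1) * (p[2] - p[4]))
    d2 <- c(r2 * x2 * (p[2] - p[1]), r2 * (1 - x2) * (p[1] - p[2]),
            r2 * x2 * (p[4] - p[3]), r2 * (1 - x2) * (p[3] - p[4]))
    list(sig * p - p^2 / 2 + d1 + d2)
  }
  pad <- 30 / s
  taus <- seq(0, t_all_end + pad, by = 0.05 / s)
  psol <- deSolve::lsoda(c(p00, p01, p10, p11), taus, pderiv, rtol = 1e-8, atol = 1e-12)
  tb <- t_all_end - psol[, 1]
  fmat <- vapply(fget, function(fn) fn(tb), numeric(length(tb)))
  fmat[tb < 0, ] <- matrix(rep(c(1, 0, 0, 0), each = sum(tb < 0)), ncol = 4)
  pbar <- rowSums(fmat * psol[, -1])
  loss <- pmin(pmax(1 - pbar / p0, 0), 1)
  o <- order(tb)
  combined <- sum(diff(tb[o]) * (head(loss[o], -1) + tail(loss[o], -1)) / 2)

  singles <- loss_time_integral(s, s, r1, N) + loss_time_integral(s, s, r2, N)
  tibble(separation = separation, dt_offset = dt_offset,
         linkage_mode = linkage_mode, combined_loss = combined,
         single_loss_sum = singles, additivity_ratio = combined / singles)
}
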