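## Closed-form and self-consistent calculators for the rate of adaptive
## substitution, its interference-limited ceiling, and neutral diversity.

# Multiplier by which inherited unlinked fitness variance inflates drift:
# variance transmitted with probability 1/2 per generation acts with
# cumulative weight (sum_k 2^-k)^2 = 4 under polygamy; with monogamy the
# shared mate doubles the effect.  Uncorrelated (non-heritable) variance has
# weight 1.
drift_exponent <- function(mating = c("polygamy", "monogamy")) {
  switch(match.arg(mating), polygamy = 4, monogamy = 8)
}

#' Diffusion fixation probability of a beneficial mutation
#'
#' Haploid Wright-Fisher diffusion value `(1 - exp(-2s)) / (1 - exp(-2Ns))`
#' for a single copy with advantage `s` and Poisson offspring.  Tends to the
#' neutral value `1/N` as `s -> 0` and to the weak-selection value `2s` for
#' `Ns >> 1`, `s` small.
#'
#' @param N Haploid population size.
#' @param s Selective advantage (>= 0).
#' @return Fixation probability.
#' @export
pfix_diffusion <- function(N, s) {
  if (any(N < 2)) abort("N must be >= 2", class = "sweeprate_param_error")
  ifelse(s == 0, 1 / N, -expm1(-2 * s) / -expm1(-2 * N * s))
}

#' Baseline (no-interference) rates
#'
#' In the absence of interference a new mutation fixes with probability
#' `p0`, substitutions accumulate at genomic rate `N * U * p0` (about
#' `2 N U s` for the weak-selection form), the density of sweeps per Morgan
#' per generation is `Lambda0 = N * U * p0 / R`, and the rate of increase of
#' mean log fitness is `v0 = N * U * p0 * s` (each substitution contributes
#' `log(1+s) ~ s`).
#'
#' @inheritParams pfix_diffusion
#' @param U Genomic beneficial mutation rate.
#' @param R Map length in Morgans.
#' @param p0_method `"diffusion"` (default) or `"2s"` (weak-selection form).
#' @return One-row tibble with `p0`, `Lambda0`, `v0`, and the convention
#'   used.
#' @export
baseline <- function(N, U, R, s, p0_method = c("diffusion", "2s")) {
  p0_method <- match.arg(p0_method)
  p0 <- if (p0_method == "diffusion") pfix_diffusion(N, s) else 2 * s
  tibble(p0 = p0, Lambda0 = N * U * p0 / R, v0 = N * U * p0 * s,
         p0_method = p0_method)
}

#' Lambert-W self-consistent rate of adaptation
#'
#' Solves `v = v0 * exp(-alpha * v)` for the realised rate of increase of
#' mean log fitness `v` given its baseline value `v0`, via the principal
#' branch of the Lambert W (product log) function: `v = W(alpha * v0) /
#' alpha`.  The exponent `alpha` encodes how fitness variance feeds back on
#' fixation probability: 1 when the variance is uncorrelated across
#' generations (the complete-recombination / "mass meiosis" model), 4 for
#' inherited unlinked variance under polygamy, 8 under monogamy.  For large
#' `alpha * v0` the realised rate grows only logarithmically.
#'
#' @param v0 Baseline variance in log fitness (= baseline rate of adaptation),
#'   per generation.
#' @param alpha Feedback exponent (> 0): 1 for uncorrelated variance, 4 for
#'   unlinked inherited variance under polygamy, 8 under monogamy.
#' @return Realised rate `v` (same units as `v0`).
#' @examples
#' lambertw_rate(exp(1), 1)  # W(e) = 1
#' @export
lambertw_rate <- function(v0, alpha = 1) {
  if (any(v0 < 0) || alpha <= 0) abort("need v0 >= 0, alpha > 0", class = "sweeprate_param_error")
  vapply(v0, function(v) if (v == 0) 0 else pracma::lambertWp(alpha * v) / alpha, 0)
}

#' Additive-approximation density of sweeps
#'
#' Under the approximation that the fixation-probability losses caused by
#' different sweeps add, a density `Lambda` of sweeps per Morgan per
#' generation reduces the average fixation probability by the factor
#' `(1 - 2 Z Lambda)`, so the self-consistent density solves
#' `Lambda = Lambda0 (1 - 2 Z Lambda)`, i.e.
#' `Lambda = Lambda0 / (1 + 2 Z Lambda0)`.  As `Lambda0 -> Inf` this tends
#' to the ceiling `1 / (2 Z)` - one sweep per centimorgan per 200 generations
#' for `Z = 1`.
#'
#' @param Lambda0 Baseline density of sweeps per Morgan per generation.
#' @param Z Interference constant from the kernel integral ([compute_Z()]);
#'   default 1 (the simplified convention), 1.05 when matching the kernel
#'   numerics.
#' @return Predicted density `Lambda` (per Morgan per generation).
#' @export
additive_density <- function(Lambda0, Z = 1) {
  if (any(Lambda0 < 0)) abort("Lambda0 must be >= 0", class = "sweeprate_param_error")
  Lambda0 / (1 + 2 * Z * Lambda0)
}

#' Self-consistent density of sweeps with linked and unlinked interference
#'
#' Jointly solves for the density of sweeps `Lambda` (per Morgan per
#' generation) including both tightly linked interference (the additive
#' `1 - 2 Z Lambda` factor) and the reduction from unlinked inherited
#' variance in log fitness, `exp(-alpha * sigma2)` with
#' `sigma2 = Lambda * R * s` at steady state:
#' `Lambda = Lambda0 (1 - 2 Z Lambda) exp(-alpha Lambda R s)`.
#'
#' @inheritParams baseline
#' @param Z Interference constant (default 1).
#' @param mating `"polygamy"` (alpha = 4) or `"monogamy"` (alpha = 8).
#' @param tol Convergence tolerance on `Lambda`.
#' @return A `theory_result`: one-row tibble with `Lambda0`, `Lambda`,
#'   `p_fix`, `sigma2`, `T2`, the strong-interference and near-neutral
#'   cutoffs, and diagnostics (`linked_dominance` > 1 means tightly linked
#'   loci dominate interference; `residual` is the fixed-point residual).
#' @export
self_consistent_density <- function(N, U, R, s, Z = 1,
                                    mating = c("polygamy", "monogamy"),
                                    p0_method = c("diffusion", "2s"),
                                    tol = 1e-10) {
  mating <- match.arg(mating)
  p0_method <- match.arg(p0_method)
  alpha <- drift_exponent(mating)
  base <- baseline(N, U, R, s, p0_method)
  L0 <- base$Lambda0
  f <- function(L) L0 * pmax(0, 1 - 2 * Z * L) * exp(-alpha * L * R * s) - L
  ub <- min(L0, 1 / (2 * Z))
  Lambda <- if (L0 == 0) 0 else uniroot(f, c(0, ub), tol = tol)$root
  sigma2 <- Lambda * R * s
  T2 <- coalescence_time(N, s, Lambda, sigma2, mating)$T2
  tibble(
    Lambda0 = L0, Lambda = Lambda,
    p_fix = base$p0 * (if (L0 > 0) Lambda / L0 else 1),
    sigma2 = sigma2, v = sigma2, T2 = T2,
    s_strong_cutoff = 4 * Z * Lambda * s,
    s_near_neutral = 1 / T2,
    linked_dominance = 2 * Z / (alpha * R * s),
    residual = if (L0 == 0) 0 else abs(f(Lambda)),
    Z = Z, mating = mating, p0_method = p0_method
  ) |> structure(class = c("theory_result", class(tibble())))
}

#' Expected pairwise coalescence time under recurrent sweeps
#'
#' Combines sampling drift, draft from linked sweeps and the drift inflation
#' from unlinked fitness variance:
#' `T2 = exp(-alpha * sigma2) / (1/N + Lambda * s / log(2 N s))`.
#' A sweep at map distance `r` coalesces a pair of neutral lineages with
#' probability `exp(-r * T_sweep)` (both lineages must stay associated with
#' the sweeping allele for the `T_sweep ~ (2/s) log(2 N s)` generations it
#' takes to go from one copy to near fixation); averaging over a long linear
#' map gives the `Lambda * s / log(2 N s)` term.  With `Lambda = 0` and
#' `sigma2 = 0` this reduces to the neutral value `T2 = N`.
#'
#' @inheritParams pfix_diffusion
#' @param Lambda Realised density of sweeps per Morgan per generation.
#' @param sigma2 Unlinked heritable variance in log fitness.
#' @param mating Mating system for the unlinked-variance exponent.
#' @return One-row tibble with `T2`, the separate `drift` and `draft` rates,
#'   and the sweep duration used.
#' @export
coalescence_time <- function(N, s, Lambda, sigma2 = 0,
                             mating = c("polygamy", "monogamy")) {
  alpha <- drift_exponent(match.arg(mating))
  if (Lambda < 0) abort("Lambda must be >= 0", class = "sweeprate_param_error")
  draft <- if (Lambda == 0) 0 else {
    if (2 * N * s <= exp(1)) abort("coalescence_time needs N s >> 1 when Lambda > 0",
                                   class = "sweeprate_param_error")
    Lambda * s / log(2 * N * s)
  }
  tibble(T2 = exp(-alpha * sigma2) / (1 / N + draft),
         drift_rate = 1 / N, draft_rate = draft,
         sweep_duration = if (s > 0) 2 * log(2 * N * s) / s else NA_real_)
}

#' Rate of sweeps and fixation profile with exponential effects
#'
#' With selective advantages drawn from an exponential distribution of mean
#' `sbar`, weakly selected alleles are disproportionately blocked by
#' interference.  Using the approximation that the interference coefficient
#' equals the ratio of selection coefficients, the fixation probability is
#' `p(s) = 2 (s - s_c)` above the cutoff `s_c = 2 Z Lambda * <s>_fixed`
#' (with the baseline value `<s>_fixed = 2 sbar`, so `s_c = 4 Z Lambda
#' sbar`), and the self-consistent density solves `Lambda = Lambda0 *
#' exp(-4 Z Lambda)`: the interference term is exactly twice that of the
#' fixed-effects relation `Lambda = Lambda0 exp(-2 Z Lambda)` (small-Lambda
#' form of [additive_density()]).
#'
#' @inheritParams baseline
#' @param sbar Mean selective advantage of new mutations.
#' @param Z Interference constant (default 1).
#' @return One-row tibble with `Lambda0`, `Lambda`, the cutoff `s_cutoff`,
#'   the mean advantage of successful mutations `s_fixed_mean`, and the
#'   interference terms of the exponential- and fixed-effects relations
#'   (ratio exactly 2).  The attribute `pfix_profile` is a function `p(s)`.
#' @export
exp_effects <- function(N, U, R, sbar, Z = 1) {
  if (sbar <= 0) abort("sbar must be > 0", class = "sweeprate_param_error")
  Lambda0 <- 2 * N * U * sbar / R
  # mean s among fixations at baseline: integral of s * (s/sbar) rho(s), = 2 sbar
  s_fixed_mean <- integrate(function(x) x^2 * exp(-x / sbar) / sbar^2, 0, Inf)$value
  Lambda <- if (Lambda0 == 0) 0 else lambertw_rate(Lambda0, 4 * Z)
  s_c <- 2 * Z * Lambda * s_fixed_mean
  profile <- function(s) pmin(pmax(2 * (s - s_c), 0), 1)
  out <- tibble(Lambda0 = Lambda0, Lambda = Lambda, s_cutoff = s_c,
                s_fixed_mean = s_fixed_mean,
                interference_term_exp = 2 * Z * Lambda * s_fixed_mean / sbar,
                interference_term_fixed = 2 * Z * Lambda,
                Z = Z)
  attr(out, "pfix_profile") <- profile
  out
}

#' Fixation probability of weakly selected alleles under interference
#'
#' For alleles with advantage `s` well below the typical advantage
#' `sbar_successful` of the alleles that do sweep, the additive
#' approximation gives `p(s) ~ 2 (s - 2 Z Lambda * sbar_successful)`,
#' floored at the neutral value `1/N` (beneficial mutations must fix at
#' least as often as neutral ones).  The formula assumes the allele's fate
#' is decided while rare, which fails in the near-neutral regime
#' `s * T2 <~ 1`; such inputs are flagged and the `1/N`-scale bound is
#' returned.
#'
#' @inheritParams pfix_diffusion
#' @param Lambda Realised density of sweeps per Morgan per generation.
#' @param sbar_successful Mean advantage of successfully sweeping alleles.
#' @param T2 Pairwise coalescence time (sets the near-neutral scale);
#'   defaults to `N`.
#' @param Z Interference constant.
#' @return Tibble with `s`, `p_fix`, and a logical `near_neutral` flag.
#' @export
weak_selection_pfix <- function(s, N, Lambda, sbar_successful, T2 = N, Z = 1) {
  p_raw <- 2 * (s - 2 * Z * Lambda * sbar_successful)
  p <- pmax(p_raw, 1 / N)
  flag <- s * T2 <= 1
  p[flag] <- pmax(1 / N, p[flag])
  tibble(s = s, p_fix = p, near_neutral = flag)
}

#' Facultative sex: density of sweeps with outcrossing rate psi
#'
#' For organisms that outcross every `1/psi` generations (with clonal
#' reproduction in between), selection and mutation accumulate over the
#' clonal epoch, so per outcrossing event effective coefficients are scaled
#' by `1/psi`.  Transplanting the additive self-consistent relation to
#' outcross-time units and converting back gives
#' `Lambda = Lambda0 (1 - 2 Z Lambda / psi) exp(-alpha Lambda R s / psi^2)`,
#' which reproduces the obligate-sex relation at `psi = 1` and caps the
#' density at `psi / (2 Z)`: rare outcrossing strengthens interference in
#' proportion.  Tightly linked loci dominate when `R * s <~ psi / 2`.
#'
#' @inheritParams self_consistent_density
#' @param outcross_rate Outcrossing frequency `psi` in `(0, 1]`.
#' @return A `theory_result` tibble as in [self_consistent_density()], with
#'   an `outcross_rate` column.
#' @export
facultative_rescale <- function(N, U, R, s, outcross_rate = 1, Z = 1,
                                mating = c("polygamy", "monogamy"),
                                p0_method = c("diffusion", "2s")) {
  if (!(outcross_rate > 0 && outcross_rate <= 1)) {
    abort("outcross_rate must be in (0, 1]", class = "sweeprate_param_error")
  }
  mating <- match.arg(mating)
  p0_method <- match.arg(p0_method)
  psi <- outcross_rate
  alpha <- drift_exponent(mating)
  base <- baseline(N, U, R, s, p0_method)
  L0 <- base$Lambda0
  f <- function(L) L0 * pmax(0, 1 - 2 * Z * L / psi) * exp(-alpha * L * R * s / psi^2) - L
  ub <- min(L0, psi / (2 * Z))
  Lambda <- if (L0 == 0) 0 else uniroot(f, c(0, ub), tol = 1e-10)$root
  sigma2 <- Lambda * R * s / psi^2
  tibble(Lambda0 = L0, Lambda = Lambda,
         p_fix = base$p0 * (if (L0 > 0) Lambda / L0 else 1),
         sigma2 = sigma2,
         linked_dominance = 2 * Z * psi / (alpha * R * s),
         outcross_rate = psi, Z = Z, mating = mating, p0_method = p0_method) |>
    structure(class = c("theory_result", class(tibble())))
}

#' Diffusion sojourn-time statistics of a fixing allele
#'
#' Mean and standard deviation of the time an allele destined to fix spends
#' in a frequency band, under the Wright-Fisher diffusion for a haploid
#' population with genic selection, for a mutation starting from a single
#' copy.  The conditional sojourn density is proportional to
#' `u(x) u(1-x) / (x (1-x))` (with `u` the fixation probability from
#' frequency `x`), which is symmetric about 1/2: absent interference a
#' fixing allele spends as long below frequency 1/2 as above it.  The
#' standard deviation comes from the second moment of the sojourn integral
#' over the conditioned Green function.
#'
#' @inheritParams pfix_diffusion
#' @param bands Two-column matrix (or list of length-2 vectors) of frequency
#'   bands.
#' @return Tibble with one row per band: `f_lo`, `f_hi`, `mean`, `sd`.
#' @export
diffusion_sojourn_stats <- function(N, s, bands = rbind(c(0, 0.5), c(0.5, 1))) {
  if (N < 2) abort("N must be >= 2", class = "sweeprate_param_error")
  if (is.list(bands)) bands <- do.call(rbind, bands)
  A <- 2 * N * s
  # scale function with S'(x) = exp(-A x); all expressions are arranged so
  # that exp(A y) never appears alone (cancellation-free for large A)
  Sfun <- function(x) if (A == 0) x else -expm1(-A * x) / A
  S1 <- Sfun(1)
  u <- function(x) Sfun(x) / S1
  # conditioned Green function: sojourn density at y for a lineage started
  # at x <= y (or from a single copy, x -> 0) and destined to fix:
  #   G*(y; x) = 2 N u(y) Sfun(1 - y) / (y (1 - y))        for y >= x
  #   G*(y; x) = 2 N e^{-A(x-y)} Sfun(1-x) Sfun(y)^2 /
  #              (S1 Sfun(x) y (1 - y))                     for y < x
  green_up <- function(y) 2 * N * u(y) * Sfun(1 - y) / (y * (1 - y))
  greenx <- function(y, x) {
    if (y >= x) green_up(y)
    else 2 * N * exp(-A * (x - y)) * Sfun(1 - x) * Sfun(y)^2 /
      (S1 * Sfun(x) * y * (1 - y))
  }
  eps <- 1 / (10 * N)
  res <- apply(bands, 1, function(b) {
    lo <- max(b[1], eps)
    hi <- min(b[2], 1 - eps)
    m <- integrate(green_up, lo, hi, rel.tol = 1e-8, subdivisions = 500L)$value
    # E[T^2] = 2 * int_x int_y G*(x; 0) G*(y; x) dy dx over the band
    inner <- function(x) {
      vapply(x, function(xx) {
        green_up(xx) * integrate(function(y) vapply(y, greenx, 0, x = xx), lo, hi,
                                 rel.tol = 1e-6, subdivisions = 500L)$value
      }, 0)
    }
    m2 <- 2 * integrate(inner, lo, hi, rel.tol = 1e-6, subdivisions = 500L)$value
    c(mean = m, sd = sqrt(max(m2 - m^2, 0)))
  })
  tibble(f_lo = bands[, 1], f_hi = bands[, 2],
         mean = res["mean", ], sd = res["sd", ])
}
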