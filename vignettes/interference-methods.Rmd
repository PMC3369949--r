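---
title: "Models and numerics behind sweeprate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind sweeprate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question

When many beneficial mutations segregate at once in a sexual population,
selection at one locus interferes with selection at linked loci
(Hill–Robertson interference): a new favorable allele that arises on a
genetic background destined to lose is itself lost unless recombination
rescues it.  `sweeprate` implements, end to end, the machinery needed to
quantify this effect for a haploid population with a continuous linear
genetic map: an individual-based forward simulator, branching-process
numerics for the fixation probability of an allele near a sweep,
self-consistent analytic rate calculators, and a neutral-diversity
("painting") experiment measuring genetic draft.

Throughout, the parameters are the haploid population size $N$, the genomic
beneficial mutation rate $U$ (per genome per generation), the selective
advantage $s$ (or an exponential distribution with mean $\bar s$), and the
total map length $R$ in Morgans.  The central observable is the *density of
sweeps* $\Lambda$: adaptive substitutions per Morgan per generation.  Its
no-interference value is $\Lambda_0 = N U p_0 / R \approx 2NUs/R$.

# The individual-based model

Each generation:

1. fitness is the product of $(1+s)$ over carried mutations (all beneficial,
   multiplicative, no epistasis);
2. $N$ parent pairs are drawn, each parent independently with probability
   proportional to fitness (polygamy; selfing is allowed because the draws
   are independent — excluding it would change the offspring-number
   variance);
3. each pair produces one offspring with a Poisson($R$) number of crossovers
   at uniform positions, the starting parent chosen by a fair coin;
4. Poisson($NU$) new mutations land at uniform positions on a continuum
   (infinite sites: position collisions have probability zero) in uniformly
   chosen offspring;
5. mutation copy-counts are refreshed; a count of 0 retires the mutation as
   lost, a count of $N$ as fixed, with fixed factors absorbed into a scalar
   log-fitness offset so relative fitness never overflows.

Only one copy of each mutation is stored; a genome is a sorted vector of
references.  The engine is compiled (Rcpp) and draws all randomness from R's
RNG, so runs are bit-reproducible given `seed`.  The pure-R
`step_generation()` implements the identical update for inspection and for
single-generation oracle tests (the expected allele-frequency change under
multiplicative selection is $s p(1-p)/(1+sp)$; the neutral variance is
$p(1-p)/N$; two loci at distance $d$ recombine at Haldane's frequency
$(1-e^{-2d})/2$).

Runs start from a wild-type population.  The default burn-in,
$\max(1000, 10/s)$ generations (capped at half the run), is a configurable
knob recorded in the run metadata; measurement windows in `glance()` start
after it.

# Fixation probability near a sweep, and the constant $Z$

A rare focal allele (advantage $s_f$) at recombination distance $r$ from a
sweeping allele (advantage $s_w$, frequency $x(t)$, modelled as a
deterministic logistic from the establishment frequency $x_0 = 1/(2Ns_w)$ to
$1 - 1/(2N)$) is a two-type branching process on the two backgrounds.  Its
fixation probabilities obey, backward in time,

$$-\dot p_B = \big(s_f + s_w(1-x)\big) p_B - \tfrac12 p_B^2 + r(1-x)(p_b - p_B),$$
$$-\dot p_b = \big(s_f - s_w x\big) p_b - \tfrac12 p_b^2 + r x (p_B - p_b),$$

with Poisson offspring (drift coefficient $p^2/2$, so the no-interference
fixed point is $p_0 = 2s_f$).  The terminal condition after the sweep
completes is $p_B = p_0$; on the ancestral background it is the positive
root of $(s_f - s_w)p - p^2/2 + r(p_0 - p) = 0$, which encodes that after
fixation a stranded focal copy can only be rescued by recombining onto the
swept background (at $r = 0$ the root is 0: complete linkage excludes the
ancestral background).  One backward integration per distance yields the
fixation probability at *every* birth time; averaging over the background
the mutation arises on (weights $x$, $1-x$) gives $\bar p(t, r)$.

The kernel $1 - \bar p/p_0$ lives on the scaled axes $s_w(t - t_{1/2})$ and
$r/s_w$, where it is independent of $N$ and $s$ up to endpoint effects of
order $x_0$ — the basis of the scaling argument that $\Lambda$ depends on
$(N, U, s, R)$ only through $\Lambda_0$.  Integrating the loss over all
birth times and over map positions on both sides of the sweep gives the
dimensionless interference constant

$$Z = \int\!\!dt \int_0^\infty\!\!dr\, \Big(1 - \frac{\bar p(t,r)}{p_0}\Big) \approx 1.05,$$

so a density $\Lambda$ of sweeps reduces the average fixation probability by
$2 Z \Lambda$.  Numerically we integrate on a log-spaced grid of 160
distances from $10^{-6}s$ to $400s$ (the integrand decays like Robertson's
unlinked $1/r^2$ beyond the computed range; that tail is added analytically
and contributes under 0.3%), with backward ODE tolerance $10^{-8}$ and an
output step of $0.03/s$.  The reference convention is $s = 0.02$,
$N = 10^7$; the value changes by well under 1% across $N = 10^5$–$10^8$ and
across $s$, and by about 0.4% under grid doubling.  The package's converged
value is $Z \approx 1.06$.

# Rates: additive approximation, Lambert W, and their combination

Assuming losses from different sweeps add (checked directly by the
four-background two-sweep solver, which finds additivity ratios within a few
percent of 1 even for simultaneous sweeps started in complete repulsion),
the self-consistent density solves $\Lambda = \Lambda_0 (1 - 2Z\Lambda)$,
i.e.

$$\Lambda = \frac{\Lambda_0}{1 + 2 Z \Lambda_0} \xrightarrow{\Lambda_0\to\infty} \frac{1}{2Z},$$

an interference ceiling of one sweep per centimorgan per 200 generations at
the simplified convention $Z = 1$ (the default in the rate calculators; the
kernel value 1.05 is available as an option, and is used when comparing
against the kernel numerics).

Unlinked loci act differently: inherited variance $\sigma^2$ in log fitness
inflates drift with cumulative weight $(\sum_k 2^{-k})^2 = 4$ (Robertson's
argument), reducing fixation probability by $e^{-4\sigma^2}$ under polygamy
and $e^{-8\sigma^2}$ under monogamy, where each offspring shares its
parents' mate draw.  Non-heritable, generation-uncorrelated variance has
weight 1 ($e^{-\sigma^2}$), which is also the complete-recombination
("mass meiosis") case, since there the background is redrawn every
generation.  At steady state the variance equals the realised rate of gain
in mean log fitness (Fisher's theorem), closing the relation
$v = v_0 e^{-\alpha v}$, solved by the Lambert W function:
$v = W(\alpha v_0)/\alpha$ — the rate of adaptation grows only
logarithmically once sweeps dominate the variance.  The full calculator
`self_consistent_density()` combines both channels,

$$\Lambda = \Lambda_0\,(1 - 2Z\Lambda)\,e^{-\alpha \Lambda R s},$$

with $\sigma^2 = \Lambda R s$; tight linkage dominates when
$\alpha R s \ll 2Z$.  The solver is a bracketed root find on
$[0, \min(\Lambda_0, 1/2Z)]$ (the right-hand side is strictly decreasing in
$\Lambda$, so the root is unique), tolerance $10^{-10}$.

For facultative sexuals outcrossing at frequency $\psi$, a "generation" is
the $1/\psi$ clonal rounds between outcrossing events with selection
accumulated accordingly.  Fixation probability per ordinary generation is
unchanged ($2s$), while each sweep's integrated interference grows by
$1/\psi$, giving
$\Lambda = \Lambda_0 (1 - 2Z\Lambda/\psi)\, e^{-\alpha \Lambda R s/\psi^2}$:
at $\psi = 1$ the obligate-sex relation is recovered exactly, the ceiling
becomes $\psi/2Z$, and linked loci dominate when $Rs \lesssim \psi/2$.

With exponentially distributed effects (mean $\bar s$), weakly selected
alleles are disproportionately blocked.  Using the proportional
approximation for the interference coefficient, $c(\zeta) \approx \zeta$
with $\zeta$ the ratio of sweep to focal coefficient (our kernel numerics
confirm it within ~7% for $\zeta \le 2$ and show it overestimates
interference at larger ratios, roughly like $2.6\,\zeta/(1.57 + \ln\zeta)$ —
a form calibrated against the package's own integration), the fixation
probability becomes $p(s) = 2(s - s_c)$ above the cutoff
$s_c = 2Z\Lambda \langle s \rangle_{\rm fixed}$ with baseline
$\langle s\rangle_{\rm fixed} = 2\bar s$, and the density solves
$\Lambda = \Lambda_0 e^{-4Z\Lambda}$: the interference term is exactly twice
the fixed-effects value, because successful sweeps average twice the mean
effect.  Below the cutoff `weak_selection_pfix()` floors the probability at
the neutral $1/N$ and flags the near-neutral regime $sT_2 \lesssim 1$,
where the branching description fails.

# Neutral diversity and the painting experiment

A sweep at map distance $r$ coalesces a pair of neutral lineages with
probability $\approx e^{-rT}$, with $T \approx (2/s)\ln(2Ns)$ the time from
one copy to near-fixation (both lineages must remain associated with the
sweeping allele throughout).  Averaged over a long linear map, sweeps add a
coalescence rate $\Lambda s/\ln(2Ns)$ to the drift rate $1/N$, and unlinked
variance multiplies the total by $e^{4\sigma^2}$:

$$T_2 = \frac{e^{-4\sigma^2}}{1/N + \Lambda s / \ln(2Ns)}.$$

Because $\Lambda$ saturates at the interference ceiling while $N$ grows,
heterozygosity-based effective population size can *decrease* with actual
population size, and diversity is strongly reduced at sweep densities far
too small to cause interference — yet not much further reduced when
interference is strong.

The measurement mirrors this: after the population reaches a steady
substitution rate, every individual is painted with a unique neutral marker
allele at a single position (default $R/2$); markers recombine like any
locus but never touch fitness, and the marker heterozygosity
$H_t = 1-\sum_i p_i^2$ is recorded until one allele fixes.  `estimate_T2()`
fits the long-term log-linear decay of the *replicate-averaged* trace, for
two reasons established while validating against the neutral oracle
($E[H_{t+1}] = (1-1/N)H_t$ exactly): fitting single replicates on the log
scale is biased steep (log is concave and individual traces end in jumps to
zero), and the final tail of the average is carried by a few surviving
replicates.  The fit therefore weights points by $\bar H$ (the sampling
variance of $\log \bar H$ scales as $1/\bar H$), starts where a rolling
slope stabilises (relative change < 20% between windows — looser than a
noise-free criterion because windowed slopes of stochastic traces jitter),
stops when $\bar H < 0.05$, and reports a jackknife-over-replicates
standard error.  With $N = 200$ and 100 replicates this recovers the
neutral $T_2$ within a few percent; with sweeps enabled it drops well below
$N$, reproducing the two-timescale structure of draft (early decay at the
drift rate $1/N$, later acceleration).

# The infinitesimal branching model

For unlinked loci we use the infinitesimal model: offspring trait values are
normal about the mid-parent with segregation variance $\sigma^2/2$, the
stationary background variance being $\sigma^2$.  A focal mutant lineage is
simulated as a branching process in mean-centred coordinates (the population
mean advances by $\sigma^2$ per generation): a carrier with background
$\zeta$ has Poisson offspring with mean $e^{\zeta + s - \sigma^2/2}$
(polygamy; each offspring's mate is drawn fitness-biased,
$\zeta' \sim \mathcal N(\sigma^2, \sigma^2)$) or
$e^{\zeta + \zeta' + s - \sigma^2}$ with a single random mate shared by all
offspring (monogamy).  These normalisations use the analytic lognormal mean
so that the process is exactly critical at $s = 0$ — verified by the
$\sigma^2 = 0$ limit matching the classic branching survival probability
$1-p = e^{-(1+s)p}$.  A lineage is declared fixed at 5000 members, and
estimates stop after 400 fixations by default (both configurable; tests use
2000/300 to stay fast).  The mate pool is treated as infinite and
stationary, which is the branching-process regime.  Log fixation
probability rises with founder log fitness with slope 2 ("fixation
probability proportional to fitness squared"), and the founder-averaged
reduction matches $e^{-4\sigma^2}$ (polygamy) within Monte-Carlo error;
monogamy fixes less often.

# Diffusion sojourn statistics

For comparing trajectory shapes, `diffusion_sojourn_stats()` evaluates the
mean and standard deviation of the time a fixing allele spends in a
frequency band, using the Green function of the Wright–Fisher diffusion
conditioned on fixation from a single copy.  The conditional sojourn
density is proportional to $u(x)u(1-x)/x(1-x)$ — symmetric about $1/2$, so
absent interference an allele spends as long going from one copy to $N/2$
as from $N/2$ to $N$.  All expressions are arranged so no factor $e^{2Nsx}$
appears alone (catastrophic cancellation otherwise sets in around
$2Ns \gtrsim 50$); the second moment uses the general-start conditioned
Green function.  Both moments were validated against conditioned
Wright–Fisher Monte Carlo at $N = 100$, $s = 0.05$.

# What the simulations do and do not show

The generator's default scales are desk-sized: validation runs use
$N = 10^2$–$4\times10^3$ and a few thousand generations, where the
engine completes in seconds.  The vignette's claims are therefore
established in the regime $\Lambda_0 \lesssim 0.2$ per Morgan per
generation (moderate interference), where the scaling collapse and the
additive approximation hold to within a few percent; at much higher
$\Lambda_0$ the additive prediction is known to underestimate the rate, and
the package's calculators report the approximation, not the (slowly
growing) truth.  The model ignores deleterious mutations, epistasis,
dominance (haploids), spatial structure, and changing population size;
conclusions about real populations inherit those idealisations.

# Reproducing the numbers

```{r}
library(sweeprate)

# the interference constant
compute_Z()            # ~ 1.06

# density of sweeps vs baseline density, with theory overlaid
p <- sim_params(N = 2000, U = 0.005, R = 5, s = 0.05,
                generations = 3000, seed = 11, burn_in = 500)
glance(run_simulation(p))
self_consistent_density(2000, 0.005, 5, 0.05)

# painting experiment
pn <- sim_params(N = 200, U = 0, R = 1, s = 0.05, generations = 6000,
                 burn_in = 10)
fit <- estimate_T2(paint_markers(pn, replicates = 100,
                                 paint_generation = 1, seed = 105))
glance(fit)
```
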