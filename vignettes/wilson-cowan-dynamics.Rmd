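---
title: "Wilson-Cowan dynamics across description levels: models, parameters, and design choices"
author: "wcdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wilson-Cowan dynamics across description levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcdyn)
```

This vignette is the package's account of the science it implements:
the model family, the assumptions behind each description level, the
parameters that matter and their defaults, what the synthetic
scenarios do and do not emulate, and the numerical and design choices
made where the problem left them open.

## The model family

Populations of binary neurons (quiescent or active) are described at
three levels.

**Mean field.** The two-population Wilson-Cowan equations for the
active fractions $E(t), I(t)$,

$$\tau \dot E = -E + (1 - rE)\, f_E[w_{EE}E - w_{EI}I + h_E], \qquad
  \tau \dot I = -I + (1 - rI)\, f_I[w_{IE}E - w_{II}I + h_I],$$

assume (i) that the population is large enough for fluctuations to be
negligible, (ii) that correlations between the quiescent fraction and
the suprathreshold fraction factorize, and (iii) that thresholds are
distributed across the population, which smooths the all-or-none
single-neuron response into a sigmoid $f$. The refractory factor
$(1 - rE)$ caps the recruitable pool. The shifted-logistic form
$f(x) = \mathrm{logistic}(a(x-\theta)) - \mathrm{logistic}(-a\theta)$
guarantees $f(0) = 0$, so quiescence is always a fixed point when
inputs vanish. (The shift makes $f$ slightly negative for $x < 0$;
the dynamics never leave $[0,1]$ because the leak dominates there,
and the classical parameter sets rely on this form.)

**Rate (stochastic-consistent) form.** The master-equation limit
replaces $-E + (1-rE)f$ by $-\alpha n + (1-n) f[s]$ with a
deactivation *rate* $\alpha$ (1/ms) and an activation-rate function
$f$, and has no refractory factor: the two-state Markov neuron has
only quiescent and active states. The two forms are kept as distinct
containers (`wc_params` vs `wc_symmetric`/`stoch_params`), and the
mean-field comparisons for stochastic runs always use the rate form,
which is the exact $N \to \infty$ limit of the master equation.

**Master equation.** $N_E + N_I$ binary neurons; a quiescent neuron
activates at rate $f[s]$, an active one deactivates at rate $\alpha$.
Inputs use population *fractions*, $s_E = w_{EE} n_E/N_E - w_{EI}
n_I/N_I + h_E$: with count-based inputs the rate equations would not
be the large-$N$ limit of the same weights, so the fraction
normalization is adopted throughout. The activation-rate function is
the rheobase-rectified saturating form $f(s) = \alpha_{\max}
\tanh(s/I_{TH})$ for $s > 0$, the low-noise analogue of the sigmoid:
zero below the threshold current, linear at onset, saturating at the
maximal transition rate.

## The balanced family and why it bursts

Under the symmetry conditions $w_{IE} = w_{EE} = w_E$, $w_{EI} =
w_{II} = w_I$, both populations feel the same current and the
half-sum/half-difference coordinates $\Sigma, \Delta$ decouple:
$\dot\Sigma = -\alpha\Sigma + (1-\Sigma) f[s]$, $\dot\Delta =
-\Delta(\alpha + f[s])$, $s = w_0\Sigma + (w_E + w_I)\Delta + h$. The
fixed point $(\Sigma_0, 0)$ depends only on $w_0 = w_E - w_I$ and
$h$ — not on the balance coordinate $w_E + w_I$. The linearization is
upper triangular,

$$A = \begin{pmatrix} -\lambda_1 & w_{ff} \\ 0 & -\lambda_2
\end{pmatrix},\qquad
\lambda_1 = (\alpha + f[s_0]) - (1-\Sigma_0) w_0 f'[s_0],\quad
\lambda_2 = \alpha + f[s_0],$$

with $w_{ff} = (1-\Sigma_0)(w_E+w_I) f'[s_0]$. A word on the sign in
$\lambda_1$: the net-excitatory recurrent feedback ($w_0 > 0$)
*weakens* the damping of the mean-activity mode, so $\lambda_1 \le
\lambda_2$; this is what direct differentiation of the $\Sigma$ flow
gives, and the package's finite-difference tests pin it. As $w_0 \to
0$ the eigenvalue gap closes while $w_{ff}$ survives and grows with
$w_E + w_I$ — the structure of the Bogdanov-Takens normal form
$\bigl(\begin{smallmatrix}0&1\\0&0\end{smallmatrix}\bigr) w_{ff}$.
The fixed point is weakly stable, fluctuations in the E-I imbalance
are amplified by $w_{ff}/\lambda$ into the mean activity, and the
linear-noise (van Kampen) approximation about $(\Sigma_0,0)$ carries
noise amplitude $\sqrt{\alpha\Sigma_0}$ per component.

At the shipped constants ($\alpha = 0.1$ ms$^{-1}$, $f = \tanh$,
$h = 0.001$, $w_0 = 0.2$) the fixed point is $\Sigma_0 = 0.5032$.
Raising $w_E + w_I$ from 0.8 to 13.8 leaves $\Sigma_0$ unchanged to
$10^{-8}$ while raising $w_{ff}$ from 0.39 to 6.8 ms$^{-1}$; the
exact simulation then switches from Poisson-like jitter (binned Fano
factor ~5 at 5-ms bins) to scale-free bursts (Fano factor ~500).

## Avalanche statistics

Events are binned at the mean inter-spike interval of the pooled
(E and I) activation raster — the self-normalizing choice that makes
the average frame hold one spike — and an avalanche is a maximal run
of non-blank frames strictly preceded and followed by blank frames;
runs touching the record edges are discarded and accounted
separately, so spikes are conserved.

The headline exponent is the least-squares slope of
$\log_{10}$ PMF against $\log_{10}$ size on logarithmically spaced
(octave) bins, with two corrections that the package's planted-data
tests motivated:

* **representative abscissa.** Placing a discrete bin at the
  geometric mean of its edges misplaces the small bins (the $[1,2)$
  bin holds only $n=1$) and bows the line; each bin is instead placed
  at the size where a power law with the current slope equals the bin
  average, iterated to a fixed point.
* **count weighting.** Sparse tail bins enter $\log$ with a downward
  (Jensen) bias; weighting the regression by bin counts keeps them
  from tilting the fit.

With both corrections, planted truncated power laws with exponents in
$[-2.5, -1.2]$ are recovered with bias below 0.01 at $10^5$ samples;
the naive fit shows bias up to $-0.19$ at the steep end. The default
fit range runs from size 1 to the last bin holding at least 5 sizes.
A discrete maximum-likelihood estimator on the truncated support is
provided as an independent cross-check, and a geometric model (MLE
$\hat p = 1/\bar n$) with a likelihood-ratio comparison decides
whether a power law is warranted at all.

In the balanced bursting regime (N = 800 per population, pooled over
seeds) the fitted exponent concentrates at $-1.47 \pm 0.01$
(maximum-likelihood cross-check $-1.47$ to $-1.49$), bracketing the
mean-field critical-branching value $-3/2$ that the shipped
Galton-Watson reference (`branching_avalanches`, Poisson(1)
offspring) reproduces at $-1.48$ over sizes 1-300. The binned PMF is
a clean power law over sizes 1 to ~400 with a finite-network pileup
near size 700; the fitted slope moves by under 0.01 across fit ranges
$x_{\max} \in \{100, 300, 800, 2000\}$. Published fits of this
simulation report slopes nearer $-1.6$; an uncorrected log-log fit
reproduces that steeper number here ($-1.54$) but fails the
planted-exponent recovery test, so the corrected estimator is kept
and the difference is noted rather than hidden.

## Spatial fields and wave metrology

The continuum equations couple sites through exponential kernels
$\beta(x) = b e^{-|x|/\sigma}$ (defaults $\tau = 10$ ms, $\sigma =
100\ \mu m$, packing densities folded into the kernel amplitudes).
Discretization samples $\beta$ at lattice offsets, truncated at
$6\sigma$, and requires $\Delta x \le \sigma/4$, which keeps the
Riemann sum within 1% of the continuum integral; boundaries are
periodic (default) or mirror-reflecting. Time stepping is fixed-step
RK4; the additive-noise variant advances the drift with the same RK4
stages and adds $\mathcal N(0, \sigma_\eta^2 \Delta t)$ per site and
step, so the zero-noise case reduces exactly to the deterministic
solver. Temporal coarse-graining is the causal one-pole exponential
filter with unit DC gain.

Wave metrology reduces a pulse response to per-distance peak
amplitudes and peak times; speed is the slope of distance against
peak time, the decay length $\lambda$ comes from the log-amplitude
regression, and the response is classified *propagating* when the
peak-time regression over distances $[2\sigma, 10\sigma]$ has
$R^2 > 0.9$ with positive slope, else *localized*. Peaks below
$10^{-3}$ of the maximum are treated as undetectable; if fewer than
four usable distances remain, the response is localized with speed
reported as 0 and flagged.

The pulse-response scenario (`fig21_weak` / `fig21_strong`) is a
**calibration**, not a reproduction — no lattice size, weights, or
stimulus amplitudes are published for the phenomenon it emulates. The
shipped preset uses $\tau = 10$ ms, $\sigma = 1.5$ mm, recurrent
linear gain $w_{EE} f'_E(0) = 0.8$ (sub-critical, so activity always
decays), and an inhibitory threshold (0.3, gain 40) set well above
the weak-pulse response. A weak pulse then propagates as a decaying
wave carried by repeated kernel convolutions — measured 0.16 mm/ms
with decay length 2.7 mm on this lattice, inside the observed
0.1-1 mm/ms decade whose experimental anchor is ~0.3 m/s — while a
strong pulse recruits inhibition at the source and stays localized
(amplitude at $10\sigma$ below $10^{-4}$ of the origin peak). The
domain is a 96 mm periodic ring: during calibration, smaller domains
produced spurious *backward-moving* peak sequences from wrap-around
and boundary-reflection interference, so domain size is part of the
preset, and the causality test checks that doubling the extent leaves
the central response unchanged.

## Correlations and spectra

Pair correlations are zero-lag Pearson coefficients per site pair,
averaged in distance bins (bin = lattice spacing; wrap-around
distances on periodic lattices), with constant sites excluded; the
correlation length is the exponential-fit scale. The spectrum
estimator is a Hann-tapered, segment-averaged (Welch) periodogram
scaled so that its integral matches the series variance; Lorentzian
fits $S(f) = a/(b + f^2)$ use Levenberg-Marquardt with a two-point
initialization (half-power frequency for $b$, low-frequency plateau
for $a$), and oscillatory peaks are removed by caller-specified
masking bands, never by automatic peak detection.

The resting-vs-driven correlation scenario is again a calibration:
at rest the sigmoid gain is high and shared input smooths noise over
an amplified length; a uniform drive pushes the rate function toward
saturation, cutting the gain, so correlations weaken *and* shorten.
Both noise routes are exercised — additive Gaussian noise on the
field equations, and intrinsic demographic noise via the exact
lattice Gillespie simulator. The drives (0.7 for additive, 0.1 for
intrinsic) are moderate deliberately: strong drives flatten the
driven profile into the sampling noise floor, which still satisfies
the ordering but leaves no decay to fit a length to.

## Numerical choices

* Fixed-step RK4 everywhere a trajectory is compared across runs;
  reproducibility beats adaptive step control for testing. Default
  $\Delta t = 0.01\tau$ (ODE) and 0.1-0.2 ms (fields). The master
  equation, a stiff linear system, uses `lsoda` with mass
  conservation checked to $10^{-6}$.
* Fixed points by damped Newton iteration (analytic Jacobians) from a
  grid of starts, deduplicated at $10^{-6}$; classification calls an
  eigenvalue nonhyperbolic when $|\mathrm{Re}\,\lambda| <
  10^{-6}/\tau$. A sign-change census on a $1000^2$ grid serves as
  the independent oracle in tests.
* The $(a, b) \to$ weights inverse for bifurcation scans is not
  unique; the default family sets $w_{EE} = w_{II} = \sqrt a$,
  $w_{IE} = w_{EI} = \sqrt b$, and any caller-supplied family is
  accepted. Saddle-node crossings are flagged by determinant sign
  changes along the continued branch *or* by a change in the number
  of fixed points between neighboring cells (a fold creates a pair,
  which continuation alone can miss).
* Gillespie runs are exact event-driven simulations; neuron identities
  (for raster realism) are assigned by an O(1) partition shuffle and
  never affect the dynamics, which are exchangeable. All stochastic
  outputs record their single integer seed.
* Galton-Watson total progeny is simulated generation-by-generation,
  vectorized across trials (the offspring sum of a generation of size
  $z$ is Poisson($mz$)), with a $10^5$-node truncation cap; truncated
  trials are flagged and excluded from fits.

## Problem sizes

The shipped tests and the acceptance script use: 10-20 Gillespie runs
of 2000-4000 ms at N = 800 per population for avalanche statistics
(~10^4-10^5 avalanches); $10^5$ branching trials; N = 20 with a
30-second run for the exact master-equation comparison (total
variation < 0.02); N = 100/400/1600 with 8 seeds for the system-size
convergence; 256-site, 120-ms field simulations for wave metrology;
and 6-seed ensembles of 400-600 ms for the correlation scenarios.
These sizes make every statistical assertion's sampling error small
against its tolerance while keeping the whole suite in minutes.

## What the scenarios do not show

The synthetic scenarios emulate the *mechanisms* — balanced
amplification, demographic noise, kernel-coupled spread, inhibitory
gating — under spatially homogeneous weights, instantaneous
(delay-free) coupling, and modest lattice sizes. They do not emulate
conduction delays, heterogeneous or distance-dependent connectivity
classes, 2-D cortical geometry at scale, or measurement forward
models (LFP/VSD point-spread); passing tests therefore validate the
implementation and the mechanisms, not quantitative agreement with
any particular recording. Quantities whose published values depend on
unpublished simulation settings (wave speed, correlation lengths) are
documented here as calibrations with their targets stated, and the
known sensitivity of the avalanche exponent to the fitting procedure
is reported alongside the corrected estimator's value.
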