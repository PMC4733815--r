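# wcdyn

Wilson–Cowan neural population dynamics across three levels of
description, with the statistical analyses that characterize each
regime.

Cortical activity can be described at the level of mean firing
fractions, of spatially extended activity fields, or of the exact
stochastic dynamics of finite populations of binary neurons. `wcdyn`
implements all three for the two-population (excitatory/inhibitory)
Wilson–Cowan model and the measurements used to compare them with
experiment: neuronal avalanche size distributions and power-law fits,
critical branching references, Lorentzian ("Brownian") power spectra,
pair correlations against cortical distance, and wave metrology for
pulse responses. It is aimed at computational neuroscientists studying
balanced networks, neural criticality, and propagating cortical
waves.

## The models

**Mean field.** The spatially homogeneous Wilson–Cowan equations for
the active fractions E(t), I(t):

    tau dE/dt = -E + (1 - rE) f_E[w_EE E - w_EI I + h_E]
    tau dI/dt = -I + (1 - rI) f_I[w_IE E - w_II I + h_I]

with sigmoidal rate functions f (shifted so f[0] = 0), refractory
period r, and weights w. `wcdyn` provides fixed-step RK4 integration,
nullclines, multi-start fixed-point location with eigenvalue
classification, and a bifurcation scan over the control parameters
a = w_EE·w_II, b = w_IE·w_EI organized around the Bogdanov–Takens
(double-zero) point.

**Balanced (symmetric) family.** Under the symmetry conditions
w_IE = w_EE = w_E, w_EI = w_II = w_I both populations feel the same
current s = w_E n_E − w_I n_I + h. In the half-sum/half-difference
coordinates Σ = (n_E + n_I)/2, Δ = (n_E − n_I)/2 the dynamics
decouple into an *effective feed-forward system*: the linearization at
the fixed point (Σ₀, 0) is upper triangular with eigenvalues −λ₁,
−λ₂ and feed-forward weight w_ff = (1−Σ₀)(w_E+w_I) f′[s₀]. Holding
w₀ = w_E − w_I fixed while raising w_E + w_I leaves the fixed point
and the spectrum unchanged but grows w_ff without bound — balanced
amplification, the proximity of the Bogdanov–Takens normal form, and
the origin of avalanche-like bursting.

**Stochastic master equation.** Binary neurons activate at rate
(N−n)·f[s] and deactivate at rate αn; the exact continuous-time Markov
dynamics is sampled with the Gillespie algorithm (`gillespie()`,
`gillespie_lattice()`), integrated exactly for small single
populations (`integrate_master()`), and approximated by the van Kampen
linear-noise Langevin equation (`langevin_lna()`) with noise amplitude
sqrt(αΣ₀) in the balanced coordinates.

**Spatial fields.** The continuum equations with exponential coupling
kernels β(x) = b·e^(−|x|/σ) on 1-D/2-D lattices
(`simulate_field()`, `additive_noise_field()`), plus wave metrology
(`measure_wave()`): per-distance peak amplitudes and times, speed,
exponential decay length, and a propagating/localized classification.

**Avalanches.** An avalanche is a maximal run of non-blank time bins
(bin width = the mean inter-spike interval), its size the summed spike
count. `fit_power_law()` fits the log-binned size PMF by least squares
(with representative-abscissa and count-weighting corrections that
remove the small-bin and tail biases of the naive fit);
`fit_geometric()` / `compare_fits()` decide power law versus
geometric; `branching_avalanches()` simulates the critical
Galton–Watson reference whose sizes follow the mean-field n^(−3/2)
law.

## Worked example: from balanced bursting to the avalanche exponent

```r
library(wcdyn)

sym <- wc_preset("benayoun_high")       # w_0 = 0.2, w_E + w_I = 13.8
ej  <- effective_jacobian(sym)
ej
#> <effective_jacobian> Sigma0=0.503215 s0=0.101643
#>   lambda1=0.102957 lambda2=0.201294 w_ff=6.78528 (1/ms)
#>   noise amplitude sqrt(alpha*Sigma0)=0.224325
```

The fixed point is weakly stable (λ ~ 0.1–0.2 ms⁻¹) while the
feed-forward weight is enormous (6.8 ms⁻¹): imbalance fluctuations are
amplified ~70-fold into the mean activity. Simulating the exact
stochastic dynamics and extracting avalanches:

```r
p  <- stoch_params_from_symmetric(sym, N_E = 800, N_I = 800)
r  <- gillespie(p, T = 2000, init = c(403, 403), seed = 1)
r
#> <wc_raster> N_E=800 N_I=800, 73335 events over 2000 ms (seed 1)

av <- avalanches_from_raster(r)         # bins at the mean ISI
av
#> <avalanche_dist> 749 avalanches (dt = 0.05487192 ms)
#>   sizes: min 1, median 3, max 2647; 369 edge spikes discarded

fit_power_law(av)
#> <power_law_fit> exponent -1.447 (se 0.023, R2 0.998) over [1, 2047], n = 749
compare_fits(av$sizes)$preferred
#> [1] "power_law"
```

One 2-second run already shows scale-free bursts spanning three and a
half decades with a slope near the mean-field critical-branching value
−3/2; pooling runs sharpens the estimate (see below). At
`wc_preset("benayoun_low")` (w_E + w_I = 0.8, same fixed point) the
same analysis yields a geometric size distribution instead — the
signature of near-independent Poisson-like firing.

A thin command-line dispatcher over the same functions ships in
`inst/cli/wcdyn.R` (`ode`, `fixedpoints`, `ssa`, `avalanches`,
`spectrum` subcommands).

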