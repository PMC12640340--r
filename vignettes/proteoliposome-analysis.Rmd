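---
title: "Quantifying aquaporin incorporation in liposomes: models and methods"
author: "vesiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aquaporin incorporation in liposomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiquant)
```

## The problem

Reconstituting a membrane protein such as the bacterial water channel AqpZ
into liposomes raises two quantitative questions: *how much protein
actually sits in the bilayer*, and *is it functional*. `vesiquant`
implements two complementary answers:

* a **small-angle X-ray scattering (SAXS)** forward model of the bilayer
  with embedded protein, refined globally across a protein concentration
  series, whose key refined quantity is the protein volume fraction $x$ of
  the hydrophobic bilayer region; and
* a **stopped-flow light-scattering (SF-LS)** kinetics workflow in which
  vesicles exposed to a hyperosmotic solution shrink, the scattered
  intensity rises, and the fitted rate constant $K$ is converted to an
  osmotic membrane permeability $P_f$ and a single-channel permeability
  $p_f$.

Because the underlying instrument data are not publicly deposited, the
package ships a seeded synthetic-data generator that emulates both
instruments under the published study conditions; every pipeline stage is
exercised against it.

## The SAXS model

The bilayer is described by three slabs: a hydrophobic core of half-width
$L_t$ (the lipid tails, which also host the protein) flanked by headgroup
layers of width $L_h$. With protein volume fraction $x$, the effective
scattering length densities (SLDs) are volume-weighted mixtures

$$\rho_i = x\rho_p + (1-x)\rho_t, \qquad \rho_o = x\rho_s + (1-x)\rho_h,$$

where $\rho_s, \rho_t, \rho_h, \rho_p$ are the fixed solvent, tail, head
and protein SLDs (defaults $9.46, 8.7, 11.8, 11.7 \times 10^{-6}$
Å$^{-2}$; the protein value can be recomputed from any sequence with
`sld_from_sequence()`). The solvent enters the outer layer because the
space above and below an embedded protein is assumed water-filled.

The flat-sheet (lamellar) intensity of this profile is

$$I_{lam}(q) = \frac{4\pi}{q^4 (L_h+L_t)}\Big(\Delta\rho_o\,[\sin(q(L_h+L_t)) - \sin(qL_t)] + \Delta\rho_i \sin(qL_t)\Big)^2,$$

with contrasts $\Delta\rho = \rho - \rho_s$. This is a per-unit-area sheet
model: it diverges as $q^{-2}$ at low $q$ and deliberately contains no
vesicle radius, because at these vesicle sizes the overall form factor
collapses below the measured $q$ window and including it did not describe
the data. Residual lipid aggregates are modelled as spherical core–shell
micelles that inherit the bilayer's geometry and SLDs (core radius $L_t$,
tail SLD; shell thickness $L_h$, head SLD — aggregates are lipid-only,
as established by ultracentrifugation in the source study). The full
model is

$$I(q) = C_1 I_{lam}(q)\,e^{-R^2q^2} + C_2 I_{mc}(q)\,e^{-R^2q^2} + B,$$

with per-curve scales $C_1, C_2$, constant background $B$, and a Gaussian
interface-roughness damping of length $R$ applied to both structured
terms.

```{r forward}
q <- exp(seq(log(0.004), log(0.35), length.out = 120))
m <- bilayer_model(L_t = 14.3, L_h = 6.65, x = 0.030, R = 5.37,
                   C2 = 5e-7, B = 1e-11)
head(combined_intensity(q, m))
```

### Numerical choices

* The sphere form-factor amplitude $F(u) = 3(\sin u - u\cos u)/u^3$
  switches to its two-term Taylor series for $u < 10^{-4}$ to avoid
  catastrophic cancellation; $F(0) = 1$.
* $q \le 0$ is a domain error (the $q^{-4}$ prefactor is singular);
  nothing is silently clamped.
* Model curves are validated in the test suite against independent
  quadrature oracles (a cosine transform of the step SLD profile for the
  sheet, a radial Fourier integral for the micelle) to relative error
  below $10^{-6}$.

## Global refinement

A concentration series is refined in one simultaneous fit
(`global_fit_problem()` + `fit_global()`): the geometry $L_t, L_h, R$ is
shared by all curves, while $x$, $C_1$, $C_2$ and $B$ are per-curve. The
protein-free control curve carries no refinable fraction — its $x$ is
fixed at zero, which pins the shared geometry and removes an otherwise
strong degeneracy between the headgroup length and all protein fractions
(the refined-values table of the source analysis likewise lists fractions
only for the protein-loaded preparations).

The objective is the standard weighted sum of squares
$\chi^2 = \sum_j\sum_i \big[(I_{obs} - I_{model})/\sigma\big]^2$,
minimized by bounded Levenberg–Marquardt (`minpack.lm`). The landscape is
rugged — sharp form-factor minima create secondary basins — so the
optimizer is wrapped in a deterministic two-stage multistart:

1. a seeded Latin-hypercube design over the shared geometry, with the
   per-curve fraction profiled on a small grid and the scales and
   background solved exactly by weighted linear least squares (they enter
   the model linearly), ranked by profiled $\chi^2$;
2. Levenberg–Marquardt polish from the best-ranked candidates (ten starts
   by default); the lowest minimum wins, ties going to the lowest start
   index.

Default bounds are physically motivated: $x \in [0, 0.5]$,
$L_t \in [8, 25]$ Å, $L_h \in [3, 12]$ Å, $R \in [0, 15]$ Å, scales and
background non-negative. A documented `q_window` option restricts fitting
to $q \ge 0.02$ Å$^{-1}$ where the sheet approximation is most reliable;
the default uses the full measured window 0.004–0.35 Å$^{-1}$.

Parameter uncertainty uses the 63.8% level conventional in this
refinement tradition. `fit_global()` reports quick curvature (Wald)
intervals; `profile_confidence_interval()` implements the rigorous
profile-likelihood interval: the parameter is scanned with all others
re-minimized until $\chi^2$ rises by the 1-d.o.f. chi-square quantile
($\Delta \approx 0.874$ at 63.8%), with endpoints located by bracketing
and bisection to a relative tolerance of $10^{-3}$ of the half-width.
Endpoints that run into a parameter bound are returned censored at the
bound and flagged. The profile machinery is verified against the exact
closed-form interval of a purely linear subproblem.

## Stopped-flow kinetics

Shots are averaged pointwise, auto-oriented so the signal rises toward
its plateau, and min–max normalized over the 0.4 s measurement window
(`average_and_normalize()`). Rates are invariant under affine amplitude
maps, so normalization is cosmetic for the fit but standardizes reporting.
The model is the biphasic exponential

$$y(t) = y_\infty - A_1 e^{-k_1 t} - A_2 e^{-k_2 t},$$

fitted on $t \ge$ the 10 ms dead time. The reported rate constant is the
amplitude-weighted mean $K = (A_1k_1 + A_2k_2)/(A_1+A_2)$, which always
lies between the component rates. This definition is one conventional
choice among several (the source study does not state its own); it is
isolated in one place so a fast-rate-only alternative is a one-line swap.
Degenerate second phases (amplitude ratio $<10^{-3}$ or rates equal to
0.1%) collapse to a flagged single exponential.

**A caveat that matters.** The amplitudes in $K$ are extrapolated to
$t = 0$, before the dead time. When the fast phase decays mostly inside
the dead time ($k_1 t_{dead} \gtrsim 2$, i.e. $K \gtrsim 150$ s$^{-1}$
under the default amplitude split), that extrapolation is ill-posed: the
Cramér–Rao bound for $K$ under the emulated conditions (signal-to-noise
50, ten averaged shots, 400 points over 10–400 ms) is about 1.7% of $K$
at $K = 26.7$ s$^{-1}$ but grows to ~21% at 152.5 s$^{-1}$ and exceeds
100% at 254 s$^{-1}$. No estimator can beat this; the package's fitter
approaches the bound via a deterministic multistart over rate splits. The
practical consequence — per-sample $K$ standard deviations of order 10%
for fast samples — matches the spread reported for the real measurements.
Corrected rate *ratios* remain informative because the control rate is
precisely determined.

Downstream quantities (`corrected_rate_ratios()`, `permeability_record()`):

* control-corrected ratios $(K_i - K_{empty})/(K_{ref} - K_{empty})$,
  with the reference entry exactly 1;
* osmotic permeability $P_f = K / ((3/r)\,V_w\,\Delta_{osm})$ with the
  vesicle radius $r$ from the post-extrusion hydrodynamic diameter,
  $V_w = 18$ cm$^3$/mol and $\Delta_{osm} = 0.5$ osmol/L by default
  (1:1 mixing with 0.5 M NaCl, van 't Hoff factor 2). The published
  analysis used a supplementary-only variant of this relation that is
  proportional to this default but smaller by a constant factor of about
  10.3 (reverse-engineered from the published per-sample values); since
  its exact form is unavailable, the formula slot is pluggable
  (`formula` argument) and absolute $P_f$/$p_f$ values from the default
  should be compared across samples, not to the published absolute scale;
* channels per vesicle from the reconstitution stoichiometry: lipids on
  both leaflets ($2 \cdot 4\pi r^2 / 0.7$ nm$^2$), divided by the molar
  lipid-per-tetramer ratio, times four pores per tetramer. Fed with the
  published corrected $P_f$ values this chain reproduces the published
  per-channel permeabilities to printed precision, which anchors the
  geometric stage independently of the $K \to P_f$ convention;
* single-channel permeability $p_f = P_f \cdot 4\pi r^2 / N$ in
  cm$^3$/s.

## The synthetic generator

`saxs_series_spec()` / `generate_saxs_series()` emulate the reduced SAXS
study: four curves (empty + three loadings with $x = 0, 0.0094, 0.012,
0.030$), shared geometry $L_t = 14.3$ Å, $L_h = 6.65$ Å, $R = 5.37$ Å,
120 log-spaced points over 0.004–0.35 Å$^{-1}$, multiplicative Gaussian
noise of 2% with $\sigma = 0.02\,I_{model}$ reported. Multiplicative
noise approximates photon statistics at laboratory count rates after
azimuthal averaging and re-binning. Scales were chosen once from
forward-curve inspection: $C_1 = 1$, $C_2 = 5\times10^{-7}$ (micelles
contribute a few percent of the mid-$q$ intensity and fill the sheet
form-factor minima, as in measured curves), $B = 10^{-11}$.

`trace_spec()` / `generate_traces()` emulate one stopped-flow sample: ten
shots of $1 - 0.7e^{-k_1t} - 0.3e^{-k_2t}$ with $k_1/k_2 = 5$ chosen so
the amplitude-weighted mean equals the requested $K$, additive Gaussian
noise of 0.02 (signal-to-noise 50), sampled from the dead time to 0.4 s.
The biphasic split makes the shape visibly non-single-exponential, since
the source analysis fits double exponentials without reporting component
values.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: instrument smearing and desmearing,
absolute-intensity calibration, the low-$q$ vesicle/aggregate population
the sheet model cannot describe, vesicle polydispersity in $L_t$/$L_h$,
possible vesicle rupture and reformation during osmotic shock, and the
bilayer-reorganization artefact seen in the highest-loading trace.

Both generators are pure functions of their spec including the seed;
`write_demo_bundle()` emits a byte-reproducible on-disk fixture set in the
package's file dialects.

## Validation studies and problem sizes

`recovery_study()` regenerates and refits the four-curve series; at the
defaults (50 repetitions, 2% noise, ten multistarts, empty-curve fraction
fixed) the recovered fractions are unbiased to better than $10^{-3}$
(e.g. $x_4 = 0.0300 \pm 0.0003$ against a generating 0.030), mean reduced
$\chi^2$ is 1.0, and every repetition identifies the concentration
ordering. The 120-point curves and 50 repetitions were chosen as the
smallest sizes at which these Monte-Carlo summaries are stable.
`rate_recovery_study()` does the same for the kinetics side and makes the
dead-time precision limit described above directly measurable.

## Known limitations

* The sheet model ignores multilamellar structure factors and vesicle
  curvature; fits below $q \approx 0.02$ Å$^{-1}$ inherit that
  approximation.
* Absolute $P_f$/$p_f$ values depend on the pluggable $K \to P_f$
  convention (see above); ratios and the geometric channel-count stage do
  not.
* The amplitude-weighted $K$ is intrinsically imprecise for rates whose
  fast phase decays inside the instrument dead time.
* The protein SLD is computed for the dry sequence with a fixed residue
  volume table; bound detergent or label corrections are the user's
  responsibility (the table is overridable).
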