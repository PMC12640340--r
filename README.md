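# vesiquant

Quantitative analysis of membrane-protein-loaded liposomes
(proteoliposomes) from two complementary measurements:

* **SAXS** — a forward model of the bilayer with embedded protein and a
  small core–shell micelle population, refined globally over a protein
  concentration series to extract the protein volume fraction of the
  bilayer;
* **Stopped-flow light scattering** — osmotic-shrinkage kinetics fitted
  with a double exponential to obtain the rate constant K, converted to
  the osmotic membrane permeability P_f and the single-channel water
  permeability p_f.

The package targets the workflow used for AqpZ (bacterial aquaporin)
reconstituted into soy PC liposomes, but all constants (SLDs, molar
masses, osmotic gradient, area per lipid) are arguments.

## The models in brief

The bilayer is three slabs: tails of half-width `L_t` hosting protein at
volume fraction `x`, flanked by headgroups of width `L_h`. Effective SLDs
mix linearly, `rho_i = x rho_p + (1-x) rho_t` and
`rho_o = x rho_s + (1-x) rho_h`, and the flat-sheet intensity is

    I_lam(q) = 4 pi / (q^4 (L_h+L_t)) *
               ( d_rho_o (sin(q(L_h+L_t)) - sin(q L_t)) + d_rho_i sin(q L_t) )^2

The full curve adds a core–shell micelle term for residual lipid
aggregates, Gaussian roughness damping `exp(-R^2 q^2)` and a constant
background; a concentration series is fitted simultaneously with
`L_t, L_h, R` shared and `x`, scales and background per curve. Errors are
63.8% intervals, either quick curvature estimates or rigorous
profile-likelihood scans.

On the kinetics side, normalized shrinkage traces are fitted with
`y(t) = y_inf - A1 exp(-k1 t) - A2 exp(-k2 t)` from the 10 ms dead time
onward; `K = (A1 k1 + A2 k2)/(A1 + A2)`, and the chain
K → P_f → channels per vesicle → p_f follows standard vesicle osmotics.
See the methods vignette (`vignettes/proteoliposome-analysis.Rmd`) for
assumptions, defaults and limitations.

## Worked example

Simulate the four-curve study twin (empty liposomes plus three protein
loadings) and refine it globally — the protein-free curve's fraction is
pinned at zero, as in the published refinement layout:

```r
library(vesiquant)
series  <- generate_saxs_series(saxs_series_spec(seed = 11))
problem <- global_fit_problem(series, init = c(x_1 = 0), fixed = "x_1")
fit     <- fit_global(problem, n_starts = 10, seed = 11)
print(fit)
#> Global SAXS fit: 4 datasets, 480 points, 18 free parameters
#>   reduced chi-square: 0.9626  (converged: TRUE)
#>   L_t    14.301 +/- 0.00368
#>   L_h    6.6501 +/- 0.00465
#>   R      5.3718 +/- 0.00761
#>   x_2    0.0093633 +/- 0.000281
#>   x_3    0.012266 +/- 0.000282
#>   x_4    0.030003 +/- 0.00028
#>   ...
```

The recovered geometry (tail half-width 14.3 Å, headgroup 6.65 Å,
roughness 5.37 Å) and fractions match the generating values; reduced
chi-square near 1 says the noise model is consistent.

Kinetics, from ten synthetic shots of a 96 s⁻¹ sample:

```r
shots <- generate_traces(trace_spec(K_true = 96, seed = 11))
kfit  <- fit_double_exponential(average_and_normalize(shots))
rec   <- permeability_record(K = kfit$K, K_empty = 26.7,
                             vesicle_diameter = 124.7, protein_conc = 0.05)
print(rec)
#> Permeability record 'aqpz_0.05':
#>   K = 93.63 1/s (control 26.7, corrected 66.93)
#>   P_f = 216.2 um/s (corrected 154.6)
#>   29.8 channels/vesicle -> p_f = 2.54e-13 cm^3/s
```

K is recovered within its sampling error; the channel count (~30 pores
per 125 nm vesicle at a lipid-to-tetramer ratio of 18750:1) is the
geometric stage that, fed with published corrected P_f values, reproduces
published per-channel permeabilities to printed precision. Note that
absolute P_f/p_f values depend on the K → P_f convention (pluggable via
the `formula` argument); ratios across samples do not:

```r
corrected_rate_ratios(c(96.0, 152.5, 254.1), 26.7)
#> [1] 1.000000 1.815296 3.281385
```

A command-line interface covers the same pipeline
(`exec/vesiquant simulate-saxs|simulate-sf|fit-saxs|fit-sf|permeability|report`),
reading a YAML config and writing JSON reports with provenance sidecars.

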