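# photoxkit

Sunlit organic matter is a photosensitizer: chromophores in dissolved or
particulate organic material absorb photons and generate reactive
intermediates — hydroxyl radical (•OH), singlet oxygen (¹O₂\*), and organic
triplet excited states (³C\*) — that drive oxidation chemistry in
atmospheric waters, cloud droplets, and surface waters. `photoxkit` is an R
package for quantifying that chemistry from laboratory measurements of
microbially derived chromophoric organic matter (e.g. bacterial cellular
organic matter, COM, and extracellular polymeric substances, EPS), and for
asking which optical and chemical properties of the material control its
oxidant production.

It is written for environmental photochemists and biogeochemists who have:
absorbance spectra, excitation–emission matrix (EEM) fluorescence, a lamp
photon-flux spectrum, and chemical-probe irradiation time courses — and who
want steady-state oxidant concentrations, apparent quantum yields, and an
interpretable statistical link back to the material's properties.

## What it computes

**Apparent quantum yields.** For each oxidant channel, the yield is moles
of oxidant produced per mole of photons absorbed,

    Phi = P / Ra,    Ra = integral  f(lambda) (1 - 10^(-A(lambda) l)) dlambda

with `Ra` evaluated by the trapezoidal rule (default 300–600 nm). Probe
inversion follows the standard scheme:

| Channel | Probe | Inversion |
|---|---|---|
| ¹O₂\* | furfuryl alcohol (FFA) decay, •OH quenched | `[1O2]ss = k_obs / k_FFA`, `P = [1O2]ss k_d` |
| •OH | phenol formation from excess benzene | `P = R0 / Y_phenol`, `[OH]ss = P / (k_benzene [benzene])` |
| oxidizing ³C\* | TMP decay, corrected for •OH and ¹O₂\* sinks | `k_corr = k_obs − k_TMP,OH [OH]ss − k_TMP,1O2 [1O2]ss`, `[3C*]ss = k_corr / k_TMP,3C*` |
| energy-transfer ³C\* | cis,cis-hexadienol formation vs [t,t-HDO]₀ | double-reciprocal line: `R_max = 1/intercept`, `P = R_max / f_iso` |

All rate constants sit in an overridable registry (`rate_constants()`),
each with a citation.

**Optical structure.** Absorbance indices (E₂/E₃, SUVA₂₅₄), fluorescence
indices (BIX, FIX, HIX), and a non-negative PARAFAC decomposition of the
EEM cube (masked alternating least squares with scatter excision, core
consistency, split-half validation, and library-based component labeling).

**Association.** Spearman correlation matrices with significance stars,
multiple linear regression with cross-validated forward selection, and an
in-house gradient-boosted tree ensemble with impurity and permutation
importance, Monte-Carlo Shapley attributions, and partial dependence.

**Synthetic ground truth.** A first-class generator
(`generate_dataset()`) emulates a bulk + molecular-weight-fraction study
design (two series × 6 ultrafiltration fractions at DOC = 5 mg C/L) with
known yields, spectra, component scores and kinetics, so every stage of
the pipeline is testable by parameter recovery.

## Worked example

```r
library(photoxkit)

ds <- generate_dataset(seed = 42)              # 14 samples, full truth known
ox <- oxidant_results(ds)                      # invert all four probe channels

dplyr::filter(ox, sample_id %in% c("C0", "C1", "C6"), channel == "1O2")
#> # A tibble: 3 × 6
#>   sample_id channel     riss production_rate         ra    phi
#>   <chr>     <chr>      <dbl>           <dbl>      <dbl>  <dbl>
#> 1 C0        1O2     1.19e-12     0.000000262 0.00000512 0.0511
#> 2 C1        1O2     7.45e-13     0.000000164 0.00000164 0.100
#> 3 C6        1O2     1.18e-12     0.000000259 0.0000135  0.0192
```

Read: the smallest molecular-weight fraction (`C1`) converts 10.0% of the
photons it absorbs into singlet oxygen; the largest (`C6`) only 1.9%; the
bulk sample (`C0`) sits between at 5.1%. `riss` is the steady-state
concentration (mol/L), `production_rate` and `ra` are in mol L⁻¹ s⁻¹.

```r
optical_indices(ds$absorbance[["C1"]], ds$eems[["C1"]], doc = 5)
#> # A tibble: 1 × 5   (flag columns omitted)
#>   e2_e3 suva254   bix   fix   hix
#> 1  12.6     1.2 0.635 0.762  5.14

compare_to_truth(ox, ds$truth) |> with(max(rel_err_phi))
#> [1] 8.4e-15
```

A noiseless synthetic dataset is recovered to machine precision — the
inversion chain is exact by construction, so any disagreement on real data
reflects the data or the constants, not the algebra.

The one-call orchestrator runs everything (indices → PARAFAC → kinetics →
correlations → models) from a config list or YAML file and writes tidy
CSV/JSON outputs:

```r
report <- run_pipeline(list(seed = 1, out_dir = "run1"))
report$truth_comparison   # present whenever ground truth is available
```

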