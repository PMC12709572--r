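---
title: "Methods: from optical spectra and probe kinetics to oxidant quantum yields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from optical spectra and probe kinetics to oxidant quantum yields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`photoxkit` quantifies the photochemical production of reactive
intermediates — hydroxyl radical (•OH), singlet oxygen (¹O₂*), and organic
triplet excited states (³C*) — by chromophoric organic matter such as
bacterial cellular organic matter (COM) and extracellular polymeric
substances (EPS), and relates production efficiency to the material's
optical and chemical properties. The chain is:

1. **Optical characterization** — absorbance indices (E₂/E₃, SUVA₂₅₄),
   fluorescence indices (BIX, FIX, HIX), and the wavelength-integrated rate
   of light absorption Rₐ.
2. **PARAFAC** — non-negative trilinear decomposition of
   excitation–emission matrix (EEM) cubes into fluorophore components.
3. **Kinetics inversion** — chemical-probe time series converted to
   steady-state oxidant concentrations [RI]ss, production rates, and
   apparent quantum yields Φ.
4. **Association** — Spearman correlation, multiple linear regression with
   cross-validated forward selection, and gradient-boosted regression trees
   with importance, Shapley, and partial-dependence interpretation.

Every stage is exercised against a synthetic-data generator with known
ground truth, so the package's correctness claims are parameter-recovery
claims.

## The probe scheme and its inversion

Apparent quantum yields are defined as moles of oxidant produced per mole
of photons absorbed, $\Phi = P / R_a$, with
$R_a = \int f(\lambda)\,(1 - 10^{-A(\lambda)\ell})\,d\lambda$ evaluated by
the trapezoidal rule over 300–600 nm (the lamp is long-pass filtered at
300 nm) on the common wavelength grid at the finer of the two spacings.

Four probe channels are inverted:

* **¹O₂\* (furfuryl alcohol, FFA).** With •OH quenched by isopropanol, FFA
  decays first order and $[^1O_2]_{ss} = k_{obs}/k_{FFA}$. The production
  rate is $P = [^1O_2]_{ss}\,k_d$ with $k_d$ the solvent deactivation rate:
  at steady state, production balances the dominant loss to water.
* **•OH (benzene → phenol).** In the scavenging regime (benzene in mM
  excess) essentially every •OH reacts with benzene, a fraction
  $Y_{phenol}$ giving phenol, so $P = R_0 / Y_{phenol}$ and
  $[OH]_{ss} = P / (k_{benzene}[benzene])$.
* **Oxidizing ³C\* (2,4,6-trimethylphenol, TMP).** TMP is also consumed by
  •OH and ¹O₂*, so the observed decay constant is corrected:
  $k_{corr} = k_{obs} - k_{TMP,OH}[OH]_{ss} - k_{TMP,^1O_2}[^1O_2]_{ss}$,
  then $[^3C^*]_{ss} = k_{corr}/k_{TMP,^3C^*}$ and $P = [^3C^*]_{ss} k_q'$,
  with $k_q'$ a pseudo-first-order triplet quenching rate. A negative
  corrected rate — expected under noise when the triplet signal is small —
  is floored at zero and flagged rather than propagated or errored.
* **Energy-transfer ³C\* (t,t-hexadienol isomerization).** The cis,cis
  isomer forms at
  $R([HDO]_0) = R_{max}[HDO]_0/(K + [HDO]_0)$; because the double
  reciprocal of a hyperbola is exactly linear, $R_{max}$ is recovered as
  the reciprocal intercept of a 1/R vs 1/[HDO]₀ regression over at least
  three initial concentrations spanning a ≥ 4-fold range (default
  0.025–0.5 mM). Then $P = R_{max}/f_{iso}$.

Rate fits are ordinary least squares on $\ln(C/C_0)$ vs $t$ (decay) or on
the early linear segment, defined as points where the product remains
below 10% of the precursor's initial concentration (formation).
Replicates (default 3) are fitted separately; the reported rate is the
replicate mean with the standard error of that mean, and uncertainties
propagate in quadrature through every ratio and difference.

The bimolecular rate constants, yields, and conversion factors live in one
overridable registry, `rate_constants()`, each with a citation string:
k(FFA, ¹O₂*) = 1.0×10⁸ M⁻¹s⁻¹, k_d = 2.2×10⁵ s⁻¹, Y_phenol = 0.53,
k(benzene, •OH) = 7.8×10⁹, k(TMP, •OH) = 1.9×10¹⁰, k(TMP, ¹O₂*) = 6×10⁷,
k(TMP, ³C*) = 3×10⁹ M⁻¹s⁻¹, k_q' = 2.8×10⁵ s⁻¹, f_iso = 0.22. These are
literature-typical values and are data, not code: a user with a different
constants set changes the registry, not the algebra. How a laboratory
converts triplet steady-state concentrations to production rates (the
choice of $k_q'$) varies between studies; it is exposed in the registry
for exactly that reason.

## Optical indices

Index definitions vary slightly across the literature; the package
centralizes one set and flags the variant in use:

* E₂/E₃ = A(250)/A(365), linearly interpolated — an inverse proxy of
  chromophore size.
* SUVA₂₅₄ = 100·A(254 nm, per cm)/DOC (L mgC⁻¹ m⁻¹) — an aromaticity
  proxy.
* FIX = I(ex 370, em 470)/I(ex 370, em 520),
  BIX = I(310, 380)/I(310, 430),
  HIX = mean I(254, em 435–480)/mean I(254, em 300–345), with the
  Ohno-normalized H/(H+L) form switchable by configuration
  (`hix_form = "ohno"`).

EEM positions snap to the nearest grid line because EEM grids are coarse
(10 nm excitation, 5 nm emission); interpolating would fabricate sub-grid
structure. Masked (scatter-excised) cells are excluded from HIX band sums
with renormalization by the number of contributing cells. A non-positive
denominator makes that index — and only that index — undefined (`NA` plus
a flag), never silently zero. All fluorescence indices are ratios and
therefore invariant to the arbitrary linear intensity units of the EEMs,
which is why the pipeline never needs to fix an absolute fluorescence
calibration.

## PARAFAC

EEM cubes (sample × excitation × emission) are decomposed as
$x_{nij} \approx \sum_f a_{nf}\,b_{if}\,c_{jf}$ with non-negativity in all
three modes, by alternating least squares: each mode update solves the
matricized normal equations for all rows at once and re-solves only rows
violating non-negativity with an active-set NNLS (Bro & de Jong's fast
NNLS). Initialization is random non-negative, with 10 restarts by default
and the best final sum of squared errors kept; convergence is declared at
a relative SSE change below 10⁻⁸, capped at 2000 iterations (a cap hit
returns `converged = FALSE` with a warning, never an error).

Rayleigh scatter is handled by masking cells within configurable
half-widths of the em = ex and em = 2·ex ridges. Masked cells are excluded
from the reported objective; numerically each sweep first completes them
with the current model reconstruction (a majorization step), which keeps
every update a dense matrix product while guaranteeing the masked SSE is
non-increasing — the completion is an internal device, not imputed data,
and no reported quantity depends on values at masked cells.

Diagnostics: explained variance; core consistency (CORCONDIA, computed
from the least-squares Tucker core of the model-completed tensor, 100 for
perfect trilinearity); split-half validation (independent fits on random
sample halves, compared by Tucker congruence after optimal matching).
Component labels are assigned against a reference library by exact
one-to-one matching maximizing summed excitation + emission congruence
(all permutations are scored — trivially cheap at rank 6; ties break by
component order), with matches below 0.8 congruence flagged. Rank is a
configuration choice (default 6); the diagnostics inform but do not
automate it.

## The synthetic study design

The generator emulates a two-series ultrafiltration design: bulk plus six
molecular-weight (MW) fractions for each of COM and EPS (14 samples), all
at DOC = 5 mg C/L. Its defaults encode the qualitative structure the
pipeline is meant to detect:

* **Quantum yields** decline log-linearly with MW fraction (factor
  e⁻⁰·³³ ≈ 0.72 per step): ¹O₂* from 10% in the smallest fraction to ~2%
  in the largest, oxidizing ³C* half of that, the energy-transfer ³C*
  channel at 3.5% (a smaller apparent yield, as probed), and •OH three
  orders of magnitude below ¹O₂*. Bulk is the mean of its fractions. These
  magnitudes sit inside the ranges reported for atmospheric particulate
  and aquatic organic matter; the decline with MW reflects charge-transfer
  quenching in larger chromophores.
* **Absorbance** is exponential, $A(\lambda) = A_{254}e^{-S(\lambda-254)}$,
  with SUVA₂₅₄ rising from 1.2 to 3.2 L mgC⁻¹ m⁻¹ and spectral slope
  falling from 0.022 to 0.012 nm⁻¹ across fractions — larger MW material
  is more aromatic and has a flatter spectrum, so E₂/E₃ falls with MW.
* **Fluorescence** mixes six Gaussian-profile components (flavin-,
  tryptophan-, tyrosine-like, two HULIS, fulvic-like) at
  literature-typical peak positions, with protein-like scores rising and
  flavin-/fulvic-like scores falling across MW; the fulvic-like decline is
  steeper than the flavin-like one so that FIX falls with MW. Protein
  content rises and polysaccharide content falls with MW.
* **Kinetics** follow exactly the probe algebra above, with steady-state
  truths derived from the yield truths through each sample's own Rₐ
  (computed with the package's integrator, making noiseless datasets
  exactly invertible). The lamp is a xenon-like spectrum with a 300 nm
  cutoff and a plateau flux of 10⁻⁶ mol photons L⁻¹ s⁻¹ nm⁻¹, which places
  [¹O₂*]ss near 10⁻¹² M and FFA decay constants near 10⁻⁴ s⁻¹ —
  magnitudes typical of such irradiation experiments. The HDO
  half-saturation constant is 10⁻⁴ M, inside the 0.025–0.5 mM design
  range, so the design spans both the linear and saturating limbs.
* **Noise** is multiplicative Gaussian clipped at zero (EEM noise is
  relative to the signal maximum), with triplicate replication. This is a
  deliberate simplification: real instruments add heteroscedastic,
  wavelength-dependent noise, inner-filter effects, and drift, none of
  which are simulated (scatter ridges are the one instrument artifact
  available, for mask testing). Passing recovery tests therefore
  demonstrates the inversion algebra and estimation machinery, not
  robustness to every laboratory artifact.

One consequence of deriving [RI]ss truths through Rₐ: because higher-MW
fractions absorb more light, their steady-state concentrations do not fall
as fast as their quantum yields; the generator's guaranteed monotone trend
is in Φ, which is the efficiency the analysis targets.

Everything derives from one global seed via a deterministic string hash
(`derive_seed()`), so a dataset regenerates bit-identically and different
stages consume independent streams.

## Association layer

Rows with flagged or non-positive oxidant results are excluded from the
log responses (counts are recorded). Spearman correlations use average
ranks and t-approximation p-values, displayed with raw-p significance
stars; Benjamini–Hochberg adjusted p-values are reported alongside for
readers who prefer a corrected display.

The MLR stage replaces brand-specific predictor filtering with
cross-validated forward selection: predictors are z-scored, and the
candidate whose addition most reduces 5-fold CV RMSE enters until no
candidate improves it. This keeps the scientific claim — which features
carry predictive information — while staying tool-agnostic. A
near-singular selected design (condition number > 10⁶) is pruned with a
warning, which also resolves exactly-duplicated predictors.

The tree ensemble is the package's own least-squares gradient boosting
over depth-limited CART base learners (grown by `rpart` with complexity
pruning disabled), with shrinkage and optional row subsampling;
hyperparameters come from a cross-validated grid search (defaults: depth
1–3, learning rate 0.05/0.1, 300 trees). With ≥ 20 samples an 80/20
train/test split (stratified by series when present) is reported in
addition to CV; below that — including the default 14-sample design — the
model runs in CV-only mode rather than pretending a 3-sample test set is
informative. Interpretation is model-agnostic: impurity importances
(normalized split gains), permutation importances (mean RMSE degradation
over 20 shuffles), Monte-Carlo permutation-sampling Shapley values
(attributions carry Monte-Carlo standard errors, and the efficiency axiom
is testable against them), and quantile-grid partial dependence. Exact
TreeSHAP is deliberately out of scope; the sampling estimator is
model-agnostic and auditable through the Shapley axioms.

## Numerical choices and degenerate inputs

* First-order fits drop non-positive concentrations with a warning and
  require ≥ 3 usable points; a zero-variance series has slope 0 and an
  undefined R².
* The HDO double-reciprocal extrapolation fails softly: a non-positive
  intercept flags the result as undefined instead of producing a negative
  saturation rate.
* Component fractions are undefined (flagged) for a sample with all-zero
  scores; defined rows sum to 1 within 10⁻⁹.
* PARAFAC loadings are reported at unit maximum with scale absorbed into
  scores; components are ordered by explained sum of squares for
  deterministic reporting.
* A constant GBT response yields the trivial constant model with zero
  importances and an undefined (flagged) training R².

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data: the 14-sample default design for end-to-end recovery (100
Monte-Carlo seeds at 2% noise for the noisy-recovery and
channel-ordering summaries), a 20-sample cube at rank 6 with 10 restarts
for PARAFAC recovery, and 40–100-row feature tables for the model layer.
These sizes were chosen so the full recovery distribution is estimated
with comfortable margins while any laptop reproduces the results in
minutes.

## Known limitations

* Absolute agreement with any particular laboratory's Φ values depends on
  that laboratory's rate-constant choices and SI conventions; the package
  ships a defensible default registry and makes substitution trivial.
* No inner-filter or light-screening corrections are applied to EEMs or
  probe kinetics; pH and temperature dependence are out of scope
  (experiments emulated at fixed pH 7, 25 °C).
* PARAFAC rank selection is a configuration choice informed by
  diagnostics, not automated.
* The synthetic generator's trends are log-linear by construction; it can
  show that the pipeline detects monotone structure, not what shape real
  MW dependence takes.
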