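---
title: "Isotope biosignatures and mat-microbiome comparison: models and methods"
author: "thromboSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope biosignatures and mat-microbiome comparison: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thromboSig)
```

# Scope

thromboSig serves studies that ask whether the microbial mats on lacustrine
thrombolites drive calcium carbonate precipitation, and how those mats
differ from non-lithifying mats on adjacent sediments. Two largely
independent machines live in the package: a carbonate-system stable-isotope
model that turns water chemistry into a testable equilibrium prediction for
aragonite δ¹³C, and a count-table comparison stage for post-annotation
metagenomic profiles. Both are fed by seeded synthetic-data generators so
that every stage can be verified end to end with known truth. Everything
upstream of these inputs — sequencing, read trimming, taxonomic/functional
annotation — is out of scope: the package consumes sample tables and
feature-by-sample count tables, not reads.

# The isotope model

## DIC speciation

Dissolved inorganic carbon is partitioned by mass action at a given pH
(hydrogen-ion activity) and temperature:

$$x_{CO_2(aq)} : x_{HCO_3^-} : x_{CO_3^{2-}} \;=\;
  1 : \frac{K_1}{a_H} : \frac{K_1 K_2}{a_H^2},
  \qquad a_H = 10^{-pH},$$

normalized to sum to one. `speciateDIC()` enforces pH in [2, 12] and
temperature in [0, 50] °C and guarantees the fractions sum to one within
1e-12 (a class validity condition). Two parameterizations of the apparent
constants are provided:

* **freshwater** (default): the classical dilute-solution temperature
  polynomials (Plummer & Busenberg 1982), pK₁(25 °C) = 6.352,
  pK₂(25 °C) = 10.329. Activity coefficients of the carbonate species are
  absorbed into the apparent constants; no Pitzer-style ionic-strength model
  is attempted, which matches the precision of this kind of field
  calculation.
* **saline**: the Dickson & Millero (1987) refit of Mehrbach's seawater
  measurements (default S = 35), pK₁(25 °C) ≈ 5.84.

The choice matters: in the saline parameterization apparent pK₁ is ~0.5
units lower, so at a fixed lake pH of ~7.5 the CO₂(aq) mole fraction is
several-fold smaller and the bicarbonate pool is barely enriched over bulk
DIC. With the default freshwater set the maximum equilibrium prediction for
δ¹³C_DIC = 1.55 ‰ at pH 7.54 is 5.37 ‰; the saline set gives 4.83 ‰. We
default to the freshwater constants because pH measured with a glass
electrode calibrated against dilute buffers is closest to an activity pH,
and report the variant switch so the sensitivity is explicit rather than
hidden.

## Isotope mass balance

Measured δ¹³C_DIC is a mixture of the three species. Assuming isotopic
equilibrium among them, each species is tied to bicarbonate by its
temperature-dependent enrichment ε(T), applied in the exact multiplicative
form

$$\delta_{species} = \alpha\,(\delta_{HCO_3^-} + 1000) - 1000,
  \qquad \alpha = 1 + \varepsilon/1000,$$

and `hco3DeltaFromDic()` solves

$$\delta_{DIC} = x_a \delta_{CO_2(aq)} + x_b \delta_{HCO_3^-}
  + x_c \delta_{CO_3^{2-}}$$

for δ_HCO₃⁻ in closed form. The exact α form costs nothing and avoids the
~0.01–0.05 ‰ error of the additive ε approximation; a property test checks
that recombining the species deltas reproduces the input δ_DIC to 1e-9 ‰.
Because CO₂(aq) is the ¹³C-depleted species (ε ≈ −9 ‰ relative to
bicarbonate), δ_HCO₃⁻ always sits above δ_DIC at circum-neutral pH — about
+0.5 ‰ at 25 °C and +0.8 ‰ at 10 °C for lake conditions.

## Fractionation coefficients

The default `fractionationSet()` uses:

| enrichment | equation (T in °C or K) | 25 °C value |
|---|---|---|
| aragonite − CO₂(g) | 13.88 − 0.13·T°C (Romanek et al. 1992) | 10.63 ‰ |
| HCO₃⁻ − CO₂(g) | 9483/T_K − 23.89 (Mook et al. 1974) | 7.92 ‰ |
| CO₂(aq) − HCO₃⁻ | −9866/T_K + 24.12 (Mook 1986) | −8.97 ‰ |
| CO₃²⁻ − HCO₃⁻ | −867/T_K + 2.52 (Mook 1986) | −0.39 ‰ |

The aragonite–bicarbonate enrichment is formed as the difference of the
first two rows; at 25 °C it is **2.71 ‰**, the anchor every alternative
coefficient set should reproduce within ±0.05 ‰ (a unit test enforces this
for the default set). It decreases monotonically from 2.98 ‰ at 10 °C to
2.29 ‰ at 40 °C. Custom enrichment functions can be injected — the closure
tests use an identically-zero set to check that the arithmetic is exact.

## The "maximum possible" equilibrium prediction

Field campaigns rarely publish the water temperature alongside each
isotope sample, so `maxEquilibriumPrediction()` treats temperature as a
nuisance parameter: for each water sample it evaluates δ_HCO₃⁻ at the
sample's measured temperature when present, otherwise over a grid (default
10–40 °C in 0.1 °C steps, endpoints included), takes the dataset-wide
maximum, and applies the aragonite enrichment at the grid temperature that
maximizes the final value. Both δ_HCO₃⁻ and ε(aragonite − HCO₃⁻) decrease
with temperature, so the maximum lands at the cold end of the window; the
cold endpoint is therefore the main user-facing sensitivity (for lake-like
chemistry the ceiling drops by about 0.55 ‰ if the cold end moves from
10 °C to 25 °C). The result is a ceiling:
the most ¹³C-enriched aragonite that could form in equilibrium with the
measured DIC pool anywhere in the temperature window.

`biosignatureOffsets()` then scores each measured carbonate as
offset = δ¹³C_CaCO₃ − ceiling. Positive offsets indicate photoautotrophic
¹²C drawdown of the local DIC reservoir, negative offsets heterotrophic
¹²C addition, and |offset| ≤ 0.1 ‰ is called "equilibrium" by default — an
order of magnitude above the ±0.01–0.03 ‰ analytical reproducibility of
carbonate and DIC measurements, so the class is not triggered by
instrument noise.

## Salinity from conductance

`salinityFromConductance()` encodes the log–log power-law regression for
Australian salt lakes (Williams 1986), TDS (g/L) = 0.4665·SC^1.0878 with SC
in mS/cm. It reproduces published endpoint pairs (121.4 mS/cm → 86.3 g/L;
188.2 mS/cm → 139.1 g/L) to better than 0.1 g/L and is monotone by
construction. It is a hypersaline-lake regression: do not use it in the
dilute range where lake-specific ion ratios dominate.

# The count-table stage

## Containers and normalization

Count tables live in `MatExperiment`, a `SummarizedExperiment` subclass
whose validity demands unique feature/sample ids, non-negative finite
counts, and a per-sample group label. Depth normalization
(`normalizeDepth()`) defaults to deterministic total-sum scaling to a
common depth (221,168 by default, a typical per-sample annotated-read
depth for this kind of design); seeded random subsampling ("rarefying") is
available behind a flag for workflows that insist on integer tables.
Scaling is the default because it is deterministic and keeps all reads.

## Beta diversity

Bray–Curtis dissimilarities come from `vegan::vegdist`; analytic
rarefaction curves use the exact hypergeometric expectation
E[S_n] = Σ_i (1 − C(N−N_i, n)/C(N, n)) via `vegan::rarefy` (checked against
Monte-Carlo subsampling in the tests). PCoA uses Gower centering through
`stats::cmdscale`; negative eigenvalues — expected for Bray–Curtis — are
retained and reported, but coordinates and variance fractions are computed
over positive eigenvalues only, with no Lingoes/Cailliez correction. UPGMA
trees come from average-linkage `hclust` converted to `phylo`, which places
each node at half the merge distance so cophenetic distances reproduce the
merge heights; `hclust`'s deterministic lowest-index tie handling makes
repeated runs identical.

PERMANOVA is implemented directly (the sums-of-squares partition on
squared distances, pseudo-F, R², and label-permutation p-values with
p = (1 + #{F_perm ≥ F_obs})/(1 + nPerm)) rather than delegated, because the
package guarantees three behaviours the usual wrappers leave unspecified:
an exactly seeded permutation stream, p-value resolution of exactly
1/(nPerm + 1) at any sample size, and a defined degenerate result
(R² = 0, p = 1) when all distances are zero. The partition is verified
against `vegan::adonis2` in the tests, and the permutation p against an
exhaustive-enumeration oracle on 4-sample toys; 999 permutations is the
default, matching the conventional p-floor of 0.001.

## Differential abundance

The NB Wald stage is a deliberately transparent reimplementation of the
standard count-model workflow, operating on raw (non-normalized) counts:

1. **Size factors** (`sizeFactorsMedianOfRatios()`): median-of-ratios over
   features positive in all samples, rescaled to unit geometric mean.
2. **Dispersions** (`estimateDispersionsMoM()`): per-feature method of
   moments on normalized counts, α = max((v − m)/m², 1e-8), with v the
   within-group pooled variance so true group effects do not inflate α.
3. **Wald test** (`nbWaldTest()`): per feature and group, the NB
   log-likelihood with fixed α and size-factor offsets is maximized by
   Newton steps on the log mean; log2fc = log₂(mean_focal/mean_other), the
   standard error is the inverse observed information mapped to the log2
   scale, and p is the two-sided normal tail. A group that is all zero
   receives a 0.5 pseudo-count on its normalized mean (so fold changes stay
   finite without perturbing typical features); features all-zero in both
   groups are emitted with log2fc = 0, p = 1.
4. **BH adjustment** (`bhAdjust()`) and the **enrichment filter**
   (`enrichmentFilter()`): padj < 0.05 AND |log2fc| strictly > 1 AND
   baseMean strictly > 2000, annotated with the direction of enrichment.

There is no empirical-Bayes dispersion shrinkage, no fold-change
shrinkage, no independent filtering and no outlier handling. The practical
consequence is worth stating plainly: with the true (or a well-estimated)
dispersion supplied, the Wald p-values are calibrated — the acceptance
suite verifies a ~5% type-I rate on a 2000-feature null at n = 3 vs 3 —
but plugging 4-degree-of-freedom moment estimates of α into the same
statistic produces t₄-like tails and roughly doubles the nominal rejection
rate. That is exactly the small-n pathology shrinkage machinery exists to
fix. In the full estimated pipeline the strict effect-size and abundance
filters absorb this inflation (near-null features essentially never clear
|log2fc| > 1 with baseMean > 2000), which the end-to-end closure test
quantifies: sensitivity ≥ 0.8 and realized FDR ≤ 0.1 for features planted
at |log2fc| ≥ 2 and mean abundance ≥ 4000. For inference without such
filters at n = 3, use a shrinkage-based tool instead.

# Synthetic data: what it emulates and what it does not

`simulateCountTable()` emulates the *structure* of an annotated
metagenomic count table for a 3 + 3 mat-type design: 2000 features with
log-normal(μ = 6, σ = 2) mean abundances (spanning the baseMean > 2000
regime on both sides), NB noise at α = 0.1, 200 differential features at
|log2fc| = 2 with random sign split symmetrically between groups, and
per-sample depth multipliers uniform in [0.5, 2]. It does **not** emulate
taxonomic correlation structure, compositional closure, annotation bias,
or sparsity patterns of real MetaCV/KEGG tables — so passing tests show
the statistical machinery is correct and calibrated under its stated
model, not that real mats will behave this way.

`simulateIsotopeStudy()` draws water samples inside the measured lake
(−4.30 to 1.55 ‰) and groundwater (−13.35 to −7.97 ‰) δ¹³C_DIC windows
with pH in [7.18, 7.63] and conductance in [121.4, 188.2] mS/cm, then
generates 18 carbonate subsamples (two cores, 5-cm depth intervals) at the
model's own equilibrium ceiling plus a +4.0 ‰ photoautotrophic offset and
0.3 ‰ Gaussian measurement noise. Because the carbonates are generated
through the same geochemical model that analyses them, offset recovery is
a closure test of the arithmetic and the pipeline plumbing, not an
independent validation of the fractionation coefficients.

# Numerical choices and degenerate inputs

* Speciation fraction sums are validated to 1e-12; mass-balance closure to
  1e-9 ‰.
* The Newton NB fit caps steps at ±5 on the log scale and stops at
  |step| < 1e-12 (≤ 100 iterations); the information is evaluated at the
  converged mean.
* PCoA treats eigenvalues below max|λ|·1e-10 as zero.
* Zero-total samples are hard errors naming the sample (normalization,
  Bray–Curtis) rather than silent drops.
* All simulators and permutation tests are pure functions of
  (config, seed); pipeline reruns with the same config are byte-identical.

# Problem sizes used in the test suite

The suite favours many small, sharply targeted checks: 2000-feature null
and closure simulations for the Wald stage, 200-replicate fold-change
recovery, 400 null PERMANOVA replicates at 199 permutations, and 4×10⁴
Monte-Carlo draws for the rarefaction oracle. These sizes give Monte-Carlo
standard errors comfortably inside the asserted 3-SE bands while keeping
the whole suite under a minute of simulation work.

# Known limitations

* The isotope model is aragonite-only, carbon-only (no oxygen or clumped
  isotopes), and equilibrium-only; kinetic fractionation during rapid
  degassing or precipitation is outside the model.
* The "maximum possible" ceiling depends on the temperature window and the
  constants variant (see above); both are explicit parameters, and results
  should be reported with them.
* The NB Wald stage is not a substitute for shrinkage-based tools at small
  n without the effect-size/abundance filters.
* PERMANOVA is one-way only; multi-factor designs and phylogeny-aware
  metrics (e.g. UniFrac) are out of scope.
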