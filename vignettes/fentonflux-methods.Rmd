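---
title: "Estimating cytosolic Fenton reaction flux from transcriptomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cytosolic Fenton reaction flux from transcriptomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fentonflux)
```

## The scientific problem

Cancer tissues run persistent cytosolic Fenton chemistry: with superoxide as
the reducing partner, Fe²⁺ catalyses
O₂•⁻ + H₂O₂ → ∙OH + OH⁻ + O₂, continuously producing hydroxide in the
cytosol. Cells that cannot neutralise this alkalinising load at a matching
rate lose intracellular pH homeostasis. The hypothesis this package
operationalises is that a portfolio of acid-producing reprogrammed
metabolisms (RMs) — nucleotide salvage, proline synthesis, sialic acid
synthesis, phospholipid synthesis, and others — is induced to produce
protons (or CO₂, a proton equivalent after hydration) at rates comparable
to the Fenton OH⁻ output.

Testing that quantitatively from transcriptomes needs four pieces of
machinery, each a module of this package:

1. a **relative flux estimator** for a curated iron/ROS metabolic map
   (`fit_flux_model()`, the central fitted model);
2. **single-sample enrichment scores** for the 43 RM gene sets
   (`ssgsea_matrix()`);
3. an **association stage** regressing Fenton flux on RM scores with an L1
   penalty (`lasso_fit()`, `contribution_summary()`), plus exact
   **proton/CO₂ bookkeeping** and **membrane-transport thermodynamics**
   (`net_protons()`, `coupled_exchange_deltaG()`, `solve_cancer_isc()`);
4. **phenotype statistics** (relative Fenton level, growth-rate conversion,
   quartile stratification, Mann–Whitney tests).

Because the study-scale inputs are consortium datasets, the package also
ships a first-class **synthetic cohort generator** with known ground truth
(`simulate_cohort()`), so every downstream stage is testable end to end.

## The metabolic map

The bundled map (`default_iron_map()`) is a factor graph of metabolite
pools and reaction modules with 15 modules: three sources of the cytosolic
Fe²⁺ pool (ferrous import; ferric import and reduction; heme import and
degradation), four sinks (Fe-S cluster synthesis, heme synthesis, Fe²⁺
export, Fenton reaction), ferritin-mediated storage of the Fe³⁺ the Fenton
reaction produces, and eight modules touching the superoxide and hydrogen
peroxide pools (the Fenton module is one of them, since it consumes both).

Flux balance is imposed on the pools that have both producers and
consumers: cytosolic Fe²⁺, cytosolic Fe³⁺, superoxide and hydrogen
peroxide. Terminal products (∙OH, OH⁻, stored Fe³⁺) are represented but not
penalised. Including cytosolic Fe³⁺ in the balanced set is deliberate:
without it the ferritin-synthesis flux would be entirely unconstrained by
the loss and therefore unidentifiable.

Gene membership per module is read from the bundled JSON file, never
hard-coded, and is editable. The memberships are representative
transporter/enzyme HGNC symbols per branch. The Fenton module itself is
non-enzymatic; its markers are 20S proteasome core subunits
(*PSMB5/6/7*), on the grounds that the 20S proteasome is solely responsible
for degrading the protein aggregates that hydroxyl radicals create, making
its expression a proxy for cytosolic ∙OH load.

## The flux model

For module $m$ with member-gene expression $G^m_j$ in sample $j$, the flux
is a small fully connected neural network
$\mathrm{Flux}_{m,j} = f^m_{nn}(G^m_j \mid \theta_m)$, and all modules are
trained jointly against

$$L \;=\; \sum_j \sum_{k \in \text{balanced}}
  \Big(\sum_{m \in F_{in}(C_k)} \mathrm{Flux}_{m,j}
     - \sum_{m' \in F_{out}(C_k)} \mathrm{Flux}_{m',j}\Big)^2
  \;+\; \lambda \sum_j \Big(\sum_m \mathrm{Flux}_{m,j} - TA_j\Big)^2 ,$$

where $TA_j$ is the total-activity surrogate: the summed expression of all
map genes in sample $j$ (or a constant). The first term penalises flux
imbalance on the balanced pools; the second anchors each sample's total
flux, which fixes the scale the imbalance term leaves free.

### Architecture and transforms

* Input: `log1p(TPM)` per gene, standardised per gene across samples.
  The log stabilises the heavy right tail of expression; standardisation
  equalises gradient scales across genes.
* Network: input → 8 → 4 → 1, `tanh` hidden activations.
* Output link: **softplus**, which is smooth and strictly positive, so
  predicted fluxes are nonnegative by construction. An absolute-value link
  is available (`output = "abs"`) but not default: its kink at zero lets
  individual samples get trapped on the wrong branch, which shows up as
  isolated large per-sample imbalances.
* $\lambda$ defaults to 1 **after scaling TA to mean 1**, making the two
  loss terms comparable without per-dataset tuning.
* Reported fluxes are normalised so the cohort-mean total flux equals the
  mean total activity — relative flux units, as all downstream analyses are
  scale-free (rank correlations, regressions, flux shares).

### Training: warm start, then joint descent

Training from a random initialisation minimises the loss well but can
settle in co-adapted optima in which modules cancel each other's errors
instead of tracking their own genes. The package therefore warm-starts
every module network on a *surrogate flux*: the exponentiated mean
standardised log-expression of its member genes, with the module's
empirical log-scale spread as the exponent (so the surrogate's dynamic
range matches the data rather than being artificially inflated to unit
log-variance). The surrogate is fitted at unit mean and moved to flux scale
through a fixed per-module output scale, which is exact because the output
layer is linear before the nonnegativity link.

The joint phase then minimises $L$ with full-batch Adam (learning rate
0.01, 500 warm-start epochs, up to 1000 joint epochs by default, early
stopping when the relative loss change over 50 epochs falls below `1e-6`).
Training is deterministic given the seed; a non-finite loss aborts with the
offending epoch.

Two numerical details matter for degenerate settings:

* At $\lambda = 0$ the loss is homogeneous of degree 2, so the overall flux
  scale is a flat "gauge" direction along which optimisers drift towards
  zero. The trainer pins this gauge each epoch by rescaling the output
  scales so the cohort-mean total flux stays at the anchor level. Balance
  is unaffected (the rescaling is common to all modules); only the
  meaningless global scale is fixed.
* Module genes missing from the matrix are imputed as zero rows with a
  warning (real matrices drop symbols routinely); a matrix sharing no genes
  with the map is an error.

### What the estimator can and cannot identify

The imbalance term constrains only sums of fluxes around each pool, so
identifiability of an individual module's flux comes from the conjunction
of (i) its own genes being its only inputs and (ii) balance being demanded
across samples whose fluxes vary. Fluxes are identified up to a monotone
distortion at best; all shipped validation therefore uses rank (Spearman)
agreement, flux shares, or balance residuals, never absolute flux values.

## The synthetic cohort generator

`generate_fluxes()` draws ground-truth fluxes that satisfy balance: source
modules log-normal LogNormal(0, 0.5²), sink apportionment by per-sample
Dirichlet shares (concentration 5), and a final alternating projection onto
the balance subspace and the nonnegative orthant for maps in which one
module couples several pools (the Fenton module consumes three).
`generate_expression()` emits per-gene loadings Uniform(0.5, 2) times a
monotone link of the module flux under multiplicative log-normal noise with
`noise_sd = 0.2` by default. `generate_rm_cohort()` produces
standard-normal RM scores and a Fenton vector that is a sparse linear
combination of them plus Gaussian noise. `shuffle_perturbation()`
implements the robustness probe: in a chosen fraction of samples, each map
gene's values are permuted among exactly those samples, preserving each
gene's marginal distribution while destroying the gene–flux dependency.

These defaults are the package's study conditions; they emulate a cohort
whose module-gene expression is a noisy monotone readout of balanced
fluxes. They deliberately do **not** emulate TCGA batch structure,
library-size variation, or single-cell dropout — so a passing test
demonstrates that the estimation machinery recovers structure that is
present, not that such structure is recoverable from any real cohort.

### Robustness-by-shuffling: the anchor convention

When refitting on shuffled cohorts, the total-activity anchor is computed
from the **unperturbed** matrix and held fixed. Shuffling per-gene across
samples destroys inter-gene correlation and therefore deflates the variance
of a recomputed anchor, which would lower the loss for a reason unrelated
to the dependency structure the probe is meant to measure. With the anchor
fixed, the final loss measures exactly the lost gene–flux dependency, and
the test asserts the median final loss over 5 seeds is non-decreasing over
shuffle fractions {0, 0.2, 0.4}.

## Enrichment scores

`ssgsea_score()` implements the single-sample GSEA running-sum statistic:
rank genes by descending expression, and accumulate at each rank the
difference between the $|expr|^\alpha$-weighted fraction of set genes seen
so far and the unweighted fraction of non-set genes; the score is the sum
over all ranks (the running-sum integral, not the Kolmogorov–Smirnov
extremum). Choices:

* `alpha = 0.75` by default (the ssGSEA2.0 convention).
* Ties in expression break by gene symbol, lexicographically —
  deterministic across platforms.
* If every set gene has zero weight (all at zero expression with
  $\alpha > 0$), weights fall back to ranks (the $\alpha = 0$ behaviour).
* At $\alpha = 0$ the score depends on ranks only, hence is invariant under
  any strictly monotone transform of the expression vector — a property the
  test suite checks, along with exhaustive agreement with a brute-force
  oracle on 5-gene universes.

Scores are reported unnormalised by default; `normalize = TRUE` divides by
the overall score range for cross-cohort comparability. Whether enrichment
scores should be normalised before the association stage is genuinely open;
the association functions accept either.

## Association and bookkeeping

`lasso_fit()` regresses the Fenton flux vector on the RM score matrix with
an L1 penalty via glmnet, with per-RM z-scoring (default on), seeded
10-fold cross-validation and the 1-SE rule for the penalty (the more
conservative standard choice; `rule = "min"` is available).
`contribution_summary()` aggregates per-cancer-type fits into the *averaged
contribution score* (mean positive coefficient over the types where the RM
was selected) and the *rate of contribution* (fraction of types selected,
with the number of types as a common denominator), filtered at a 40%
minimum rate by default. Counting only positive coefficients is the
default because the acid-production hypothesis concerns positive
association; a flag includes negatives. Averaging over selecting types
only (not all types) is the default resolution of an ambiguity in the
printed summaries; `average_over = "all"` gives the alternative.

The proton ledger (`rm_proton_ledger()`, `net_protons()`) stores exact
integer yields per product unit — e.g. +4 H⁺ per phosphatidylserine, +2 per
sialic acid, +1 CO₂ per proline — with conditional entries ("0 or +1")
carrying both values. ATP bookkeeping is three integers: fermentation-based
ATP production is pH-neutral per ATP, respiration consumes one proton per
ATP, hydrolysis releases one; so the Warburg effect coupled with hydrolysis
nets +1 H⁺ and respiration coupled with hydrolysis nets 0.

The transport thermodynamics evaluate
$\Delta G = ZFV + RT\,\ln(c_{dest}/c_{origin})$ per leg, with proton
activities $10^{-pH}$; for an electroneutral 1:1 antiport the electrical
terms cancel exactly, leaving $RT[\ln r_1 + \ln r_2]$ — a cancellation the
tests verify over a grid of membrane potentials. The two-compartment sodium
model solves the cancer intracellular sodium concentration from the
volume-weighted total: with extracellular:intracellular volumes 20:80, ESC
140 and normal ISC 12 mmol/l, the cancer-to-normal total-sodium ratio
$k \in [2, 3]$ gives ISC 59–106 mmol/l. Temperature defaults to 310 K —
body temperature, the value the worked free-energy numbers use — with `T`
always explicit in the transport specification.

## Phenotype statistics

* `relative_fenton_level()`: Fenton flux divided by the summed flux of the
  five cytosolic iron exit modules; scale-invariant by construction.
* `growth_rate()`: 365 / median doubling days (doublings per year); the
  bundled table carries doubling times for the 11 cancer subtypes.
  Metastasis rates must be user-supplied (their provenance and units are
  not standardised), so none are bundled.
* `stratify_quartiles()`: top/bottom `floor(q·n)` samples with ties broken
  by sample label; the two strata are taken from opposite ends of one
  deterministic ordering so they stay disjoint even under heavy ties.
* `mann_whitney()`: midrank U statistic; exact enumeration of all rank
  assignments when the pooled size is ≤ 16 (valid under ties), otherwise
  the normal approximation with tie and continuity corrections via
  `stats::wilcox.test`. No multiple-testing correction by default, since
  raw P values are the convention for these panels; Benjamini–Hochberg can
  be applied by the caller for many-test settings.

## Problem sizes used by the shipped tests

The test suite exercises the estimator at the sizes the package treats as
its reference conditions: parameter recovery on the 15-module map with
n = 500 samples at expression noise 0.2 (per-module Spearman ≥ 0.8 against
ground truth and a ≥ 100× reduction of the total loss); the two-module
chain balance property at n = 200, noise 0 (per-sample flux agreement
within 5%); and the shuffling robustness at n = 200 with 5 seeds per
fraction. Smaller cohorts appear throughout the unit tests where only
composition or determinism is at stake.

## Known limitations

* Fluxes are relative and monotone-identified; absolute rates would need
  calibration against metabolomics, which is out of scope.
* The curated map is small and cytosol-centric. Mitochondrial or
  extracellular Fenton variants are representable in the map format, but no
  default maps are shipped for them.
* The gene memberships per iron module are representative, not exhaustive;
  users with curated lists should edit the bundled JSON.
* The association stage reports no post-selection inference on lasso
  coefficients, matching standard practice for contribution summaries.
* The synthetic generator's couplings are linear (RM stage) and monotone
  (expression stage); estimator performance under adversarial nonlinearity
  or confounded noise is not characterised.
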