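---
title: "Screening tumor-infiltrating immune-related lncRNAs and building prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tumor-infiltrating immune-related lncRNAs and building prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilnc)
```

## The problem and the model

Bulk tumor expression profiles are mixtures: part of every transcript
count comes from malignant cells, part from infiltrating immune cells and
stroma. A lncRNA that is (a) highly expressed in at least one immune cell
type, (b) specific to immune cell types rather than ubiquitous, and
(c) essentially absent from pure tumor cell lines is, when detected in
bulk tumor tissue, a proxy for the immune infiltrate. `tilnc` screens for
such **Ti-lncRNAs** and models their prognostic value.

The screen works on a gene × cell-type profile of mean normalized
log-intensities (`cell_type_means()`), assumed nonnegative and already
normalized; probe-level processing and cross-cohort batch correction are
out of scope.

### Step 1 — top-decile candidates

Per cell type, the `ceiling(0.10 * G)` genes with the highest mean are
candidates. We include every gene tied with the cutoff value so the
selection is deterministic and independent of sort order; the candidate
set is the union over cell types (an intersection would be near-empty,
since specificity is the point).

### Step 2 — tissue specificity

For gene means `m_1..m_N` over `N >= 2` cell types, with
`x_i = m_i / max_j m_j`,

$$\mathrm{TSI} = \frac{\sum_{i=1}^{N} (1 - x_i)}{N - 1} \in [0, 1],$$

0 for uniform expression, 1 for single-type expression. Candidates with
TSI strictly above 0.1 proceed. TSI is scale-invariant (per-gene), so the
choice of linear versus log input rescales gene profiles nonlinearly and
*does* change TSI values; the package computes TSI on whatever scale the
profile carries, and the documented convention is log2-like intensities.
Genes whose means are all zero have no defined normalization and are
excluded with a message. Both threshold comparisons in the pipeline
(TSI > 0.1, FDR < 0.05, univariate p < 0.01) are strict inequalities.

### Step 3 — immune-versus-tumor differential screen

Each surviving candidate is tested with a Welch two-sample t-test of all
pooled immune samples against the tumor cell lines. Welch was chosen over
a pooled-variance test because the two sides have very different sample
sizes and no reason to share a variance; a rank test would discard the
intensity scale for no robustness gain on RMA-style data. FDR is
controlled by Benjamini–Hochberg *within the screened candidate set* —
the family actually tested — not genome-wide. The degenerate case of zero
variance on both sides with equal means is reported as p = 1 rather than
an error. A gene is flagged iff FDR < 0.05 *and* the immune mean exceeds
the tumor mean.

### Step 4 — survival modeling

`build_signature()` applies the two-stage selection: a univariate Cox
screen (Wald p < 0.01) followed by a single multivariate Cox fit of all
survivors, whose coefficients become the signature weights — no stepwise
or penalized selection is layered on top. Cox fits use Efron tie handling
(the standard default with the best small-sample behavior) and delegate
the partial-likelihood optimization to `survival::coxph()`; the tests
validate the fits against simulations with known hazards rather than
trusting the delegation. The risk score is the plain linear combination
of expression values, used as provided with no per-gene standardization:
the published coefficients were reported for normalized expression, and
the downstream median split is invariant to monotone per-cohort
transformations anyway.

`dichotomize_median()` assigns scores strictly above the median to the
high-risk group; ties at the median go to "low", a deterministic,
documented convention (the split is otherwise ambiguous for odd cohorts).
`survival_auc_at(scores, survival, t)` defines cases as deaths at or
before `t` and controls as patients followed beyond `t`; patients
censored before `t` are excluded rather than inverse-probability
weighted — a simpler estimator that is slightly optimistic under heavy
early censoring, which is the main known limitation of the AUC module.
The AUC itself is the Mann–Whitney concordance with ties counted 1/2.

The packaged `published_signature()` carries the nine reported
(gene, coefficient) pairs verbatim; whether those coefficients came from
a training-split fit or a whole-cohort refit is not resolvable from the
source report, so the package treats them as a fixed published constant
with provenance `"published"`.

## Tumor-microenvironment scores

`summary_score()` implements the per-sample *median of the absolute
expression values* of a signature gene set. The absolute value is taken
literally; on nonnegative log intensities it is the identity, and the
literal reading keeps the score defined for signed (centered) inputs.
Gene sets ship as editable GMT files rather than hard-coded lists (a
small synthetic example is in
`inst/extdata/example_genesets_synthetic.gmt`; it is a placeholder, not a
published hypoxia or CAF list). Continuous variables are compared between
risk groups with Welch tests, binary labels with two-sided Fisher exact
tests (chi-square reported alongside when all expected counts reach 5).

## What the synthetic generator emulates

`sim_config()` defaults encode the reference study design: 19 immune cell
types × 6 replicates (114 samples, mirroring a 115-sample compendium
whose per-type counts are uneven in reality but reported only in
aggregate — uniform replication is a simplification, not a claim of
fidelity), 34 tumor lines, 3477 lncRNAs, 300 patients.

* **Expression** is Gaussian on the log2-like scale
  (`background_mean = 5`, `background_sd = 1`), clipped at zero to meet
  the nonnegativity assumed by the TSI normalization.
* **Planted genes** (5 per cell type, 95 total) receive a pan-immune
  elevation (`immune_effect = +2`) in every immune sample plus a
  type-specific boost (`specific_effect = +4`) in their assigned type, and
  neither in tumor lines. Both components are needed: the specific boost
  creates the top-decile/TSI structure, while the pan-immune elevation is
  what gives the pooled immune-versus-tumor test its power — a boost in
  one type alone shifts the pooled immune mean by only `effect/19`,
  undetectable at these sample sizes.
* **Patients** are convex mixtures
  `f · immune-mean + (1 − f) · tumor-mean + noise` with
  `f ~ U(0.1, 0.6)`; the mixture uses the population mean profiles (not
  per-sample resampling), keeping generation linear in the number of
  genes.
* **Survival** is exponential with hazard
  `baseline_hazard · exp(Σ β_g z_g)` over the standardized expression of
  9 planted prognostic genes, plus independent exponential censoring.
  The exponential/exponential pair was chosen over Weibull because it has
  closed-form checks (mean `1/λ`, a Kolmogorov–Smirnov target in the
  `β = 0` limit) and the modeled study states no survival-time family.
  Acting on *standardized* expression makes `β` scale-free, so recovery
  tolerances can be stated independently of the expression scale. The
  default weights `β = ±0.5` (alternating) are detectable at n = 300 with
  roughly half the patients experiencing events, and exercise sign
  recovery in both directions. `censor_rate` may be set to 0 to disable
  censoring.

Every generator is a pure function of `(config, seed)`; sub-stages
(immune panel, prognostic-gene assignment, tumor panel, cohort) use fixed
offsets of the one seed so panels are independent draws yet jointly
reproducible.

What passing the planted-truth tests does **not** show: real immune
panels have correlated cell types, uneven replication, batch structure
and heavy-tailed intensities; real patient mixtures contain stromal and
subclonal components; and real censoring is not exponential. Recovery of
planted truth validates the *implementation*, not the biological
discovery rate on real cohorts — cohort-scale results depend on the
actual data and are deliberately not asserted by the test suite.

## Numerical conventions and problem sizes

* Top-decile size `ceiling(0.10 * G)` with boundary ties included.
* All-zero genes dropped from TSI; degenerate Welch inputs give p = 1
  (equal constants) or p = 0 (distinct constants); an all-low median
  split triggers a degeneracy warning rather than an error.
* `random_split()` takes `floor(fraction · n)` training samples (500
  patients at 0.6 give the conventional 300/200).
* The test suite validates against independent oracles: a brute-force
  step-up implementation of Benjamini–Hochberg, hand-built risk-table
  log-rank statistics, the definition-level product-limit estimator, and
  full hypergeometric enumeration for Fisher tests. Simulation-based
  checks use seeded replicates sized for stable assertions (e.g. 500
  null replicates for log-rank type-I error, n = 1000 for Cox recovery,
  the full default configuration for one end-to-end run); these sizes
  are the package's choice of statistical resolution.

## Known limitations

* The AUC-at-horizon estimator excludes early-censored patients instead
  of IPCW weighting.
* TSI values depend on the expression scale supplied; cross-study TSI
  comparisons require a shared normalization.
* The differential screen is a per-gene Welch test, not a moderated
  (limma-style) statistic; with few tumor lines a moderated variance
  would gain power, at the cost of an extra dependency and a different
  null model.
* The multivariate Cox stage refits all univariate survivors jointly
  with no shrinkage; with strongly collinear candidates the weights are
  unstable even when the risk score itself is not.
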