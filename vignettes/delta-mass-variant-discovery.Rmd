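---
title: "Discovering and annotating residue-localized delta-mass variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and annotating residue-localized delta-mass variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpscan)
```

## The problem

Open ("wildcard") database searches of tandem mass spectra allow an
unconstrained mass difference between the observed precursor and the coding
peptide. Each confidently localized peptide-spectrum match (PSM) then
carries a *delta mass*: the signed difference, in Da, attributable to a
chemical modification, an amino-acid substitution, or an adduct at the
reported residue. Pooled over a cohort, the delta masses of a reactive
residue such as tryptophan pile up into narrow peaks at the masses of real
modifications, on top of a diffuse background of mis-assignments.

`trpscan` implements the post-search pipeline that turns a table of such
PSMs into an annotated catalogue of residue variants and cohort-level
statistics:

1. **Confidence filtering** (`filter_psms()`): keep PSMs with search score
   ≥ 300, localization (delta-modification) score ≥ 10 and two-dimensional
   FDR ≤ 0.01, restricted to the target residue and to delta masses in
   [−150, 500] Da, excluding exact zeros. All comparisons are inclusive.
2. **Peak calling** (`call_variant_peaks()`): cut the delta-mass axis into
   1-Da half-open windows; fit each window with a one-dimensional Gaussian
   mixture by EM for k = 1..4 components; choose k by BIC; screen windows
   by a histogram goodness-of-fit R²; discard broad or weakly supported
   components; merge near-coincident survivors.
3. **Annotation** (`annotate_peaks()`): match each peak centre against a
   curated database of known variants (strict |error| < 10 mDa), and
   explain the remainder as cascades — a known base variant plus one
   secondary modification from a Unimod-style catalogue — through signed
   elemental-composition arithmetic (`parse_composition()`,
   `monoisotopic_mass()`).
4. **Cohort statistics** (`aggregate_sites()`,
   `differential_modification()`, `correlation_matrix()`,
   `optimal_cutpoint_survival()`): per-(protein, site, peak) spectral
   counts, paired tumour-vs-NAT tests, Spearman profiles and
   optimal-cutpoint log-rank survival.

## The mixture model and its selection

Within one window the deltas are modelled as

$$ x_i \sim \sum_{j=1}^{k} w_j\, \mathcal{N}(\mu_j, \sigma_j^2), $$

fitted by EM with quantile-spaced initial means plus 10 random restarts
(best likelihood kept), a standard-deviation floor of $10^{-4}$ Da against
degenerate components, and $k$ chosen to minimize
$\mathrm{BIC}(k) = -2\ell + (3k-1)\log n$; ties go to the smaller $k$.
$k=1$ is fitted in closed form.

**Goodness of fit.** The R² screen compares the fitted mixture with the
empirical histogram at 2-mDa bins. Two numerical choices matter and were
made after observing failure modes:

* *Expected counts use exact bin probabilities* (differences of the mixture
  CDF), not bin-width × density at the midpoint. With bins comparable in
  width to the peak (σ ≈ 2 mDa), the midpoint approximation misfits the
  peak top systematically and rejects genuine peaks.
* *The histogram spans the whole 1-Da window*, not just occupied bins.
  Restricted to occupied bins, a sparse uniform background yields counts
  that are all 1 — zero total variance, so R² degenerates; restricted to
  the data span, an isolated narrow peak leaves too few bins for a stable
  statistic. Over the full window, pure peaks score ≥ 0.97 and uniform
  backgrounds ≤ ~0.1 in simulation, so the default threshold of 0.90
  separates them with a wide margin.

**Background components.** EM happily dedicates a wide component to diffuse
background inside a peak-bearing window. Such a component can clear the
support threshold, so components with fitted σ above `max_sd` (default
0.02 Da) are discarded as background: genuine instrument-resolution peaks
have σ of a few mDa, and a planted peak as wide as 0.01 Da stays safely
under the cut.

**Merging.** Surviving components closer than `merge_tol` (default
0.01 Da) are chained and merged, with centre and spread recomputed from the
pooled member deltas. This reunifies a real peak that a window boundary
split in two (windows are hard 1-Da cuts) and collapses the occasional EM
overfit of one physical peak into nearly coincident components. At this
mass resolution, distinct chemistry closer than 10 mDa is not separable
anyway — that is also the annotation tolerance.

## Annotation: single matches, cascades, classification

Compositions are signed element→count maps in the Unimod dialect
(`"C(-1)O(2)"`; a bare symbol means +1, concatenation sums). Monoisotopic
masses use IUPAC monoisotopic atomic masses with C = 12 exactly, which
reproduces published 4-decimal tables; display rounding is R's default
round-half-to-even, and golden tests compare at 1e-4 Da because printed
tables are occasionally ambiguous in their last digit.

Stage one returns the database entry minimizing |centre − entry mass| if
that minimum is strictly below 10 mDa (ties: plausible entries first, then
name order). Stage two forms every (centre − base mass) residual against
the curated base table — for 19 unmatched centres and 62 base entries,
exactly 1178 residuals — and pairs each residual with every catalogue entry
within 10 mDa, ranking candidates per centre by |combined error|, then
joint plausibility, then implied reaction steps. Multi-step cascades beyond
base-plus-one-secondary are represented as precomposed catalogue entries
(`steps > 1`), keeping the search quadratic.

Classification is data, not code: each database entry carries a class label
(Reactive species, AA substitution, Chemical derivative, Artefact, Unknown)
and a plausibility flag, and a peak inherits the class of its matched (or
base) entry; a peak with no candidate, or only implausible ones, is
Unknown. Two consequences are worth knowing. First, the original analysis
chose among tied cascade candidates by expert review; the package
auto-selects the top-ranked plausible candidate but always attaches the
full ranked list (attribute `"candidates"`) for exactly that review.
Second, with a dense secondary catalogue almost every centre finds *some*
cascade within 10 mDa, so "Unknown" in automated output mainly reflects
curation of the plausibility flags rather than absence of arithmetic
matches — a faithful mirror of how such tables are actually produced.

## Cohort statistics

Spectral counts per (protein, site, peak) row and sample are the
quantitative unit. The normalized modification level is
`(count + 0.5) / (protein total + 0.5)` — a pseudocounted fraction of that
protein's spectra in that sample; the protein total should come from the
full filtered PSM table so other variants of the protein contribute.

*Differential testing* uses the paired two-sided Wilcoxon signed-rank test
across tumour/NAT pairs with Benjamini–Hochberg adjustment over the tested
rows. The exact p-value is used whenever `stats::wilcox.test` can compute
it (n < 50, no ties): with small cohorts the normal approximation's
granularity floor (p ≈ 0.006 at 10 pairs) is too coarse to survive
multiplicity adjustment. All-zero rows and single-pair designs are flagged
untested rather than given a p-value; identical paired vectors give p = 1.
A paired t-test on log levels is a reasonable alternative for heavier
tails; the Wilcoxon default was chosen for robustness to count skew.

*Correlation* profiles use Spearman's rank correlation with midranks for
ties and two-sided p-values; constant profiles are reported as missing,
never as 0.

*Optimal-cutpoint survival* scans all distinct marker values whose
quantile lies in [0.10, 0.90] (excluding the maximum, so both groups are
non-empty), computes the standardized two-group log-rank statistic at each
via a vectorized risk-set computation, and returns the cutpoint maximizing
|z|. The log-rank p at the selected cutpoint is reported as `p` because
that is the quantity conventionally quoted after cut-off optimisation —
but selecting the cutpoint that maximizes the statistic inflates type-I
error, so a permutation-adjusted p (maxima of |z| under marker-label
permutation, default 200 permutations) is always reported alongside it.
In null simulations the adjusted p rejects at ≈ 5%, the naive p far more
often; only the adjusted p should be used as evidence.

## What the synthetic generator emulates — and what it does not

`generate_psm_table()` draws planted peaks as
Normal(true delta, mass sd = 0.002 Da by default, the scatter of
high-resolution precursor mass errors), a uniform background over
[−150, 500] Da, confidence columns with a configurable fraction (default
0.9) passing all three thresholds (the rest fail exactly one, chosen at
random — only the pass/fail mix matters to a threshold filter), paired
tumour/NAT samples named `P<k>_T`/`P<k>_N`, and multiplicative tumour
enrichment of chosen (protein, site, peak) triples implemented as sampling
weights, so the expected tumour/NAT count ratio equals the stated effect.
A single seed governs everything; the same (spec, seed) gives a
byte-identical table.

`generate_survival_table()` draws a standard-normal marker and exponential
event times with hazard `baseline × HR^marker`, plus independent
exponential censoring.

The generator does **not** simulate spectra, retention times, fragment
ions, peptide-level abundance biology, inter-run batch effects, or a
realistic (structured) mis-assignment background — the uniform background
is a stand-in, not a claim about real open-search noise. A green test
therefore establishes that the pipeline recovers what it assumes
(Gaussian peaks on diffuse background with honest confidence columns), not
that it is robust to every failure mode of real data.

## Defaults at a glance

| Parameter | Default | Unit | Why |
|---|---|---|---|
| score / localization / FDR thresholds | 300 / 10 / 0.01 | — | conventional high-confidence open-search filter |
| delta range | [−150, 500] | Da | search-engine wildcard window |
| window width | 1 | Da | integer-Da binning of the delta axis |
| `k_max` | 4 | — | >4 resolvable shifts per Da is chemically implausible here |
| `min_support` | 10 | spectra | stability on synthetic data; configurable down to 1 (real tables contain frequency-1 variants) |
| `max_sd` | 0.02 | Da | peaks are instrument-limited (≤ ~0.01); wider = background |
| R² threshold | 0.90 | — | separates ≥0.97 (peaks) from ≤0.1 (uniform) in simulation |
| histogram bin width | 0.002 | Da | ≈ peak σ; exact bin probabilities make it usable |
| `merge_tol` | 0.01 | Da | annotation tolerance; closer peaks are not distinct chemistry |
| match tolerance | 0.010 (strict) | Da | published "< 10 mDa" rule |
| level pseudocount | 0.5 | counts | keeps levels defined at zero counts |
| survival scan quantiles | [0.10, 0.90] | — | avoids unstable extreme splits |
| permutations | 200 | — | adjusted-p resolution ~0.005 |

## Known limitations

* Pooled fitting only: clusters are fitted on the pooled cohort, not per
  run; run-level drift would widen peaks rather than split them.
* One row per (spectrum, site): a spectrum with several candidate
  localizations contributes once per reported site.
* The packaged modification databases are synthetic reconstructions of
  standard modification chemistry (62 curated base entries, 108 catalogue
  entries), suitable for testing and as a template; serious annotation
  work should load a current, curated Unimod export via
  `read_modification_db()`.
* Auto-selected cascade annotations are ranked suggestions; tied
  compositions are chemically indistinguishable at this resolution and
  need expert review, exactly as in the original manual workflow.
* Spectral counting is a semi-quantitative proxy; intensity-based
  quantification is out of scope.
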