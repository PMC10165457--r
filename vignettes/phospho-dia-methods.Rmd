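---
title: "Phospho-aware DIA window design and phosphosite differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phospho-aware DIA window design and phosphosite differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoDIA)
```

This vignette is the package's account of the models and procedures it
implements, the choices made where the methodology was genuinely open, and
what the test suite does and does not establish.

## 1. The scientific setting

Data-independent acquisition (DIA) fragments **all** precursors inside
predefined m/z isolation windows, cycling over the precursor range, instead
of picking the most intense survey-scan peaks as data-dependent acquisition
(DDA) does. For dilute, dynamic samples such as phosphopeptides enriched
from urinary extracellular vesicles, DIA's reproducibility is what makes
cohort-scale label-free quantification feasible. The package implements the
computational half of such an experiment: designing the acquisition windows,
demultiplexing staggered scans, rolling precursor quantities up to
phosphosites, and the downstream statistics used to separate patient groups
(healthy controls, chronic kidney disease, and low- versus high-grade clear
cell renal cell carcinoma in the motivating application).

## 2. Forbidden zones and window design

Tryptic peptide masses are not uniform on the m/z axis: elemental
composition constrains the mass defect, so precursors cluster around a line
of slope ~1.00045475 m/z per nominal-mass Da, leaving periodic bands --
*forbidden zones* -- where no precursor can fall. Phosphorylation (+79.966
Da) shifts the cluster; the shift is absorbed into an additive constant of
0.18 m/z. The boundary associated with integer nominal mass $m$ is

$$ B(m) = \left\lceil \frac{m}{1.00045475} \right\rceil \times 1.00045475 + 0.18 . $$

For $m < 2200$ the ceiling is the identity, so boundaries are exactly linear
in $m$; an ordinary least-squares fit over 400--1100 Da recovers the slope
and intercept to machine precision, which the acceptance checks exploit.
Window edges are *snapped* to the nearest boundary (`snap_to_forbidden_zone()`),
with exact ties broken toward the lower boundary so snapping is
deterministic. Snapping displaces an edge by at most half the boundary
spacing plus the constant.

Design choices worth stating:

* **Half-open windows.** Intervals are $[\ell, u)$: a shared edge belongs to
  exactly one window, so "which window owns a boundary ion" is unambiguous.
* **Ceiling division.** A span of 700 m/z at 8 m/z windows yields
  $\lceil 700/8 \rceil = 88$ windows per phase, the instrument loop count;
  the last window may overhang the span.
* **Stagger.** Phase B is phase A shifted up by half a window, so its first
  window starts half a width above the span start and its last extends half
  a width beyond the top. The first half-window of the span is therefore
  covered by one phase only; the demultiplexer flags it.
* **MS1 display range versus window span.** Instruments display a padded
  MS1 scan range (389.8--1109.8 for a 400--1100 window span); the package
  treats the window span as authoritative and the padding as metadata.
* The `8 m/z` loop count of 88 is reported **per phase**; whether an
  instrument counts one phase or both per duty cycle is a vendor convention,
  and the per-phase count is the unambiguous one.

Gas-phase fractionation (`build_gpf_plan()`) splits the range over several
injections of the same sample -- at the defaults, 110 m/z injections stepped
by 100 m/z (10 m/z overlap), each acquired with 4 m/z staggered windows that
demultiplex to 2 m/z -- the narrow-window data used to build an
experiment-specific chromatogram library. The package reproduces the
plan geometry; judging which precursor range is *best* needs real data and
is deliberately out of scope, as is any vendor method file or search engine.

## 3. Staggered demultiplexing

With half-width effective windows $e_1, \dots, e_K$, a phase-A scan $k$
observes $e_{2k-1} + e_{2k}$ and a phase-B scan $k$ observes
$e_{2k} + e_{2k+1}$ (per fragment channel). Half-windows beyond the span are
constrained to zero, which makes the per-cycle system square and full rank:
`demultiplex()` solves it by nonnegative least squares per cycle and
fragment channel, using an own Lawson--Hanson active-set solver.

Two alternatives were considered and rejected. Solving *local* sliding
groups of scans is attractive for streaming data, but any group of $m$
consecutive scans covers $m+1$ effective windows, so every local system is
rank-deficient: its NNLS solution is not unique and cannot guarantee exact
recovery of noiseless planted signal, which is the contract the tests
enforce. The full per-cycle system is banded and tiny (at most ~176
equations for the widest scheme), so there is no performance argument for
the local approximation. Second, an off-the-shelf NNLS routine was tried and
failed to converge on these sparse 0/1 systems with exact-zero observations;
the active-set solver in `R/demux.R` is ~30 lines and is verified against an
independent projected-gradient oracle and hand-solved systems.

On noiseless input, recovery is exact (to solver tolerance) and total
demultiplexed intensity equals the per-phase observed total. With additive
Gaussian noise at 1% of the maximum intensity, the median relative error of
recovered intensities stays below 5% across 100 seeded replicates. The
"nearly a factor of two" selectivity gain commonly quoted for staggering is
qualitative -- the halved effective window width -- and is reported as such
(`scheme_summary()$effective_width`), not asserted as a measured quantity.

## 4. From precursors to phosphosites

A precursor report row carries a modified peptide, protein accession,
charge, site assignments (1-based protein position, S/T/Y residue,
localization probability) and per-sample raw intensities.

* **Class-1 filtering** retains site assignments with localization
  probability at or above the cutoff -- 0.75 for library-based DIA, 0.99 for
  library-free, where the laxer cutoff is known to inflate error rates. For
  multiply phosphorylated peptides the rule is applied per site (a record
  keeps its confident sites and drops the rest); requiring *all* sites to
  pass is the stricter alternative reading, and per-site retention is the
  one implemented because it preserves quantifiable signal.
* **Rollup** sums, per sample, the abundances of all precursors containing a
  site; a doubly phosphorylated precursor contributes its full abundance to
  both its sites. A site-sample cell is missing iff every contributing
  precursor is missing. Summing charge states of the same modified peptide
  first would give identical totals (addition is associative), so no
  explicit grouping pass is made. Zero intensities are treated as missing on
  ingestion, because search-software exports use blanks and zeros
  interchangeably.
* Shared (multi-protein) peptides are assigned to the first-listed
  accession; conflicting residue letters at one accession/position abort
  with diagnostics rather than silently merging distinct sites.
* **Fragment-ion library rules** (for completeness of the library-building
  stage): m/z within [300, 1800], relative intensity >= 5%, at least three
  residues, neutral losses retained, then the 15 most intense ions.

## 5. The differential pipeline

The stage order is fixed and asserted by a regression test, because
imputation and normalization do not commute:

floor -> log2 -> normality gate -> completeness filter (per comparison) ->
imputation -> median normalization -> Welch test.

* **QC floor 30** (strict: below 30 becomes missing, 30 is kept): raw peak
  areas under ~30 are integration noise.
* **Normality gate.** Welch testing assumes roughly normal per-sample log2
  distributions. The test defaults to Shapiro--Wilk at alpha 0.01 and is
  configurable; which omnibus test a given study used is rarely stated, and
  the choice matters less than the cap described next. Because *every*
  label-free sample is mildly left-truncated by censoring, a goodness-of-fit
  test fed thousands of values rejects all samples for that irrelevant
  deviation; the gate therefore evaluates the test on a deterministic
  order-preserving subsample of at most 100 values, which keeps the nominal
  type-I rate and near-full power against gross failures (bimodal mixtures,
  failed runs) while tolerating censoring-induced skew. Samples with fewer
  than 8 observed values are flagged untestable and retained.
* **Completeness** is strict: a site is kept iff *more than* 70% of one
  group's samples observe it (at n = 14 that means >= 10).
* **Imputation** is per sample (column-wise, the Perseus convention): missing
  cells are drawn from a normal with mean `mean(obs) - 1.8 * sd(obs)` and SD
  `0.3 * sd(obs)`, the standard left-censored missing-value model. Draws are
  seeded; every stochastic stage derives its substream from one master seed
  via `stage_seed()`, so inserting a stage never scrambles another stage's
  stream.
* **Median normalization** shifts each sample to the grand median of sample
  medians -- keeping values on the intensity scale rather than centring at
  zero; either target leaves all within-sample contrasts, and hence every
  test statistic, unchanged.
* **Welch volcano.** Per site, Welch's t with Satterthwaite df and a
  two-sided p-value, classified `up` iff p <= 0.05 and log2 difference >=
  0.5 (~1.414-fold), `down` symmetrically. Classification uses raw p-values
  -- the convention of the volcano plots this mirrors -- and a
  Benjamini--Hochberg column is available (`adjust = TRUE`) but off by
  default. The implementation is vectorised closed-form row statistics
  (matrix-wide testing would be impractically slow via per-row `t.test`),
  verified against `stats::t.test` to 1e-10 on random instances, with a
  2000-site null simulation holding the 5% type-I rate.
* **Wilcoxon marker selection** for the heatmap: sites with rank-sum p <=
  0.1 *and* a positive shift in the target group against **each** of the
  other three groups. Reading the selection rule as "any one comparison" is
  plausible; the all-comparisons rule is the default because it is the one
  that yields group-exclusive markers, and `mode = "any"` provides the other
  reading.

## 6. Classification

* **Feature ranking** uses permutation importance from a seeded
  500-tree random forest (the ranger package), sqrt-features per split --
  standard defaults, all exposed. Candidates are typically the volcano-up
  sites of a comparison; the ranking returns the top 15.
* **Multiclass AUC** follows the Hand--Till convention: the average over
  class pairs of the pairwise rank AUCs of class-posterior scores. Scores
  come from a linear-discriminant classifier, leave-one-out cross-validated
  by default at these sample sizes (n ~ 14/group); resubstitution
  (`cv = "none"`) is available and is the optimistic option. Note two
  small-sample facts the tests document: leave-one-out scores of a
  label-independent feature are biased *below* 0.5, and per-replicate AUC is
  not monotone in effect size (the fitted discriminant direction can flip at
  tiny effects) although the replicate-averaged AUC is.
* **LDA projection** maximizes the between/within scatter ratio; at most
  `groups - 1` (here 2) axes. The implementation is an explicit generalized
  eigendecomposition with a shrinkage fallback
  ($W \leftarrow (1-\lambda)W + \lambda \bar{d} I$, $\lambda = 0.1$, with a
  warning) when the within-class scatter is singular -- panels close to the
  sample count, or collinear sites -- which is why `MASS::lda` is the
  cross-check oracle in the tests rather than the engine. Axis signs are
  fixed by forcing the largest-magnitude loading positive, so plots are
  reproducible.

## 7. The synthetic-data generator

`simulate_report()` emulates the *structure* of a cohort-scale urinary EV
phosphoproteome report; its defaults are the study conditions of the
motivating application:

| parameter | default | rationale |
|---|---|---|
| sites | 2584 | quantified unique phosphosites in the motivating cohort |
| groups | HC, CKD, low_grade, high_grade; 15 each | the cohort design |
| residue mix | 79/17/4% S/T/Y | observed phosphosite distribution |
| baseline log2 abundance | Normal(10, 2.5) per site | places ~2-3% of raw intensities below the QC floor of 30, so the floor does real work |
| within-group noise | 0.5 log2 SD | typical label-free site-level CV (~35-40%) |
| markers | 20 per disease group, +1.5 log2 | a strong but realistic group effect; disease-specific sets make all group pairs separable, as the observed data were |
| missingness | logistic in latent log2 intensity, midpoint 6, steepness 1.2 | left-censored (MNAR), the assumption behind downshift imputation; ~10% missing cells overall. An MCAR switch exists for null calibration |
| localization | 80% from Beta(40, 1.5), rest Beta(2, 2) | a well-localized majority with a diffuse tail straddling the 0.75 class-1 cutoff |
| precursors per site | 1-3, truncated geometric (p = 0.6) | distinct peptidoforms per site, so rollup summation is exercised; split weights are fixed per precursor so group contrasts survive the split exactly |

Effect sizes and missingness rates of the real study are unknown (they would
require reanalysing the deposited raw data), so these are *plausible*
settings, chosen once and not tuned. What the generator deliberately does
**not** model: fragment-level interference and isotope structure, retention
time, batch effects, and correlated missingness between co-eluting peptides.
Passing end-to-end tests therefore demonstrate that the pipeline recovers
planted structure under its own assumptions -- left-censored log-normal
abundances with additive group shifts -- not that it is robust to every
pathology of real data.

Ground truth (true group means, marker identities, per-cell missingness,
effective-window assignments for scan simulation) is returned alongside the
report, and a written report round-trips exactly (full-precision text
serialisation).

Under the defaults with a fixed seed, the full pipeline recovers 16 of 20
planted high-grade markers among volcano-up sites; the misses are markers
whose baseline falls below the detection limit or whose only precursor
fails class-1 localization -- the generator planting exactly the failure
modes the filters are designed to impose.

## 8. Numerical and reproducibility choices

* All randomness flows from one master seed; per-stage substreams come from
  a deterministic 31-bit hash of the stage name (`stage_seed()`).
* `impute_downshift()` restores the caller's RNG state, so pipelines are
  insensitive to stage insertion.
* NNLS tolerance is 1e-9 relative to the largest observation; demultiplexer
  and oracle agree to better than 1e-6 on all tested instances.
* Degenerate Welch inputs (zero variance in both groups, equal means) return
  p = 1 rather than NaN.
* Text outputs serialise numbers at full precision (`%.17g`), so regression
  comparisons can be byte-exact.
* Problem sizes in the test suite are the study conditions where the
  property concerns the pipeline (2584 sites x 60 samples; 50 seeded
  replicates for the ranking property) and reduced fixtures (hundreds of
  records, <= 20 effective windows) where the property is algebraic and
  size-independent.

## 9. Known limitations

* No raw-file or mzML ingestion; the package consumes search-software
  exports and synthetic reports only, and produces no localization
  probabilities of its own.
* The demultiplexer assumes intensities are constant within a duty cycle;
  chromatographic peak shape across cycles is not modelled (nor interpolated
  between neighbouring cycles).
* Marker selection and AUC estimates at n ~ 14 per group are exploratory;
  without an external validation cohort, leave-one-out AUCs remain
  optimistic model-selection quantities, a caveat that applies equally to
  the study design this package mirrors.
* No pathway or kinase enrichment: those depend on external annotation
  databases and are out of scope.
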