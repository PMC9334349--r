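---
title: "Models and methods behind masspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind masspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masspipe)
options(masspipe.log = FALSE)
```

This vignette explains the models, conventions and numerical choices the
package is built on: what each operation assumes, which parameters
matter, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open.

## The container and its contract

A `MassDataset` holds the expression matrix (variables × samples,
missing = `NA`), sample and variable metadata, note tables documenting
every metadata column, MS2 spectra, an annotation table and the process
history. The structural contract, checked by
`validate_mass_dataset()` after every operation:

* expression column names equal `sample_info$sample_id`, same order, no
  duplicates; row names equal `variable_info$variable_id` likewise;
* every metadata column appears exactly once in its note table;
* every MS2 link and every annotation row references a current
  `variable_id`;
* the process history is non-decreasing in time.

Missing measurements are `NA` and nothing else; zeros read from input
remain zeros, because a zero produced by an integrator is information,
not absence. Readers offer `zero_as_missing = TRUE` for exporters that
write missing cells as zeros. Intensities must be non-negative at
creation; downstream transformations (centering, scaling, logs) may of
course produce negative values, so non-negativity is a creation-time
check, not a permanent invariant.

Filters fail rather than return an empty dataset: in a scripted
pipeline an empty container is almost always a mis-specified predicate,
and failing at the filter beats failing three steps later. Removing a
sample does not remove MS2 spectra — spectra are tied to features, not
samples — while removing a variable clears the links that point at it.

## Provenance and replay

Every mutating operation appends one `process_record` (package,
function, time, parameter list). Parameters are restricted to numbers,
text, booleans and nested lists thereof, so the history serializes to
JSON and back without loss; numerics are normalized to doubles at
record-creation time for the same reason.

`replay(history, base)` re-executes the recorded operations through an
operation registry. Two choices make replay exact:

* **Filters replay from identifiers, not predicates.** An arbitrary R
  closure is not serializable; the record therefore stores the kept
  identifier set, which reproduces the filter deterministically.
* **Timestamps are excluded from equality.** Replayed records carry new
  times; `dataset_identical()` compares everything else bit-for-bit.

Operations that need an external object to re-run (a spectrum
collection, a compound database) record its identifier and take the
object again from a `resources` list; `verify_replay()` reports
`"unverifiable"` when a needed resource is absent rather than guessing.

Record clocks are wall-clock in interactive use. The pipeline runner
and the data generator instead use a deterministic counter clock (seed-
or history-derived), so that a pipeline configuration run twice
produces byte-identical archives — reproducibility down to the file
hash, which is what makes the archive a trustworthy unit of exchange.
Plot files are the one exception we do not hash: PNG encoders do not
guarantee byte stability, and plots are derived views, not data.

## The archive format

An archive is a directory of plain-text members: bit-stable CSV for all
tables (doubles written with 17 significant digits, missing cells as
empty strings, column classes in a JSON sidecar), MGF for spectra
(full-precision), and JSON for the process history (times stored as
epoch-second doubles). `read_archive(write_archive(ds))` reproduces the
dataset exactly, including the history.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of a
QC-bracketed untargeted LC-MS batch *after* peak picking:

* log2 baseline abundances per variable `~ N(15, 2)` (raw intensities
  of order 3 × 10⁴, the typical mid-range of a QTOF peak table);
* biological variation of subject samples `sd = 0.5` log2 units;
  analytical noise `sd = 0.03` log2 units (~2% RSD), so QC replicates —
  pooled-sample injections — sit well under the 5% a stable platform
  delivers;
* QCs at the first and last injection and evenly interleaved, the
  layout QC-based drift correction requires;
* drift: a per-variable multiplicative decay over injection order,
  reaching ~1/3 of the starting response at the last injection (a
  severe but realistic week-long decay), either log-linear or smoothstep
  (`"monotone-smooth"`), with per-variable coefficients varying ±20%;
* batch effects: per-(variable, batch) log2 offsets of chosen sd;
* missingness: MNAR-leaning censoring with
  `P(missing) = 2·mv_rate·(1 − u)` where `u` is the within-variable
  intensity percentile — low-intensity cells are censored
  preferentially, as in real LC-MS data, while the marginal rate equals
  `mv_rate` exactly in expectation (rank calibration);
* differential metabolites: a fixed log2 effect added to Case samples
  of a random `de_fraction` of variables.

Defaults (52 subjects + 8 QCs, 200 variables, 10% missingness, 10%
differential at 1 log2 unit) describe a modest single-batch study. The
generator is a pure function of its parameters and seed — including the
creation record's timestamp — and restores the caller's RNG state.

What it deliberately does **not** emulate: chromatographic peak shapes,
correlated adduct/isotope features, heteroscedastic noise floors, or
injection-order effects on subject biology. Tests passing on this
generator therefore demonstrate algorithmic correctness and calibration
under the stated model, not performance on any particular instrument.

`generate_ms2_and_database()` plants true identities: for selected
features a database compound whose exact mass is the feature m/z minus
the proton mass (1.007276 Da, protonated adduct), RT near the feature's,
and a library MS2 spectrum whose dataset-side copy carries jittered
precursor and fragment intensities. Decoy compounds (3× the planted
count) are rejection-sampled to lie ≥ 50 ppm from every planted mass, so
a decoy can never tie a planted hit. `generate_pathway_db()` builds one
pathway whose membership is ≥ 80% truly differential compounds plus
uniform background pathways.

## Cleaning

**Noisy features.** A feature is flagged when missing in more than 20%
of QC samples or in more than 50% of *every* study group. The
every-group reading is the conservative one — a feature fully observed
in one group is still informative for that group — and the any-group
alternative is exposed as `any_group = TRUE`.

**Outlier samples.** Four rules over the subject samples, reported with
their statistics and thresholds rather than silently applied. The PCA
preprocessing (per-variable median imputation, `log10(x + 1)`,
centering) is fixed and recorded so results are reproducible. Two
numerical facts shape the score rules: the mean ± 6·SD rule cannot fire
at all when `(n − 1)/√n ≤ 6`, i.e. below 38 samples, because the
outlier inflates the SD it is compared against — one reason the robust
median/MAD variant exists; and when the MAD itself is zero (replicated
samples) any deviating sample is infinitely many MADs away, so it is
flagged, while fully identical samples yield no flags. The Mahalanobis
rule works on the top `min(10, n − 1)` principal components with a
minimum-covariance-determinant estimate (falling back to the classical
covariance when `n` is too small for MCD) against the chi-square 0.975
quantile.

**Imputation.** KNN (the default, `k = 10`) finds, for each variable
with missing cells, the `k` most similar variables by root-mean-square
difference over mutually observed samples — scaling by the overlap
count makes distances comparable when overlap varies — and imputes the
inverse-distance-weighted average of their values in the target sample.
Variables with fewer than 3 mutually observed samples against every
neighbour fall back to their own mean, and the record lists them. SVD
completion iterates rank-`r` (default 5) approximation of the
mean-filled matrix until the relative change of the imputed cells drops
below `1e-6`. Observed cells are never modified, making imputation
idempotent.

**Normalization.** Sample-wise factors (total/median/mean) are rescaled
by the dataset-median factor so the data keep their intensity scale;
PQN uses the per-variable QC median as reference spectrum and the
median quotient as the dilution factor. QC-based drift correction fits
log2 QC intensity against scaled injection order — LOESS with span 0.75
and degree 1 (degree 1 stays stable down to the 4-QC minimum), or
epsilon-SVR with RBF kernel (`cost = 1`, `epsilon = 0.1`) — and divides
each measurement by `fit(order)/median(fit at QC orders)`, clipped to
`[0.1, 10]` to guard against wild extrapolation of a poorly determined
fit. Fitting on the log scale and correcting multiplicatively keeps
corrected intensities positive. Bracketing QCs are required because the
fit is not extrapolated beyond the observed order range. All
normalizations preserve the missingness pattern.

**Batch integration.** Per variable and batch,
`x ← x / batch_statistic × overall_statistic` with the statistic one of
QC/subject median/mean; a variable whose statistic is unusable in some
batch is skipped and listed in the record rather than half-corrected.

## Quality control

The report computes missing-value distributions, QC RSD
(`100·sd/mean`, ≥ 2 observed values required; pass rate at the 30%
cutoff counts only variables with a defined RSD), per-sample intensity
medians, QC–QC correlation and PCA. Correlations and PCA run on
`log10(x + 1)` to stabilize variance. Reporting never mutates the
dataset and appends no process record — observation is not processing.
The report is JSON (schema-versioned) plus PNG plots.

## Annotation

MS1 candidates come from
`theoretical mz = (exact_mass + mass_shift)/charge` over an adduct
table (defaults: [M+H]+, [M+Na]+, [M+NH4]+, [M−H]−, [M+CH3COO]−;
proton mass 1.007276 Da) at 25 ppm. RT filtering keeps candidates
within 30 s when the library has an RT and passes candidates through
with absent error otherwise — an RT-less library entry disables RT
evidence rather than penalizing the compound.

MS2 similarity is the cosine of square-root intensities with greedy
closest-first fragment matching at 0.02 Da, each fragment used once;
unmatched fragments contribute to the norms, so identical spectra score
1 and disjoint spectra 0. Square-root weighting is the standard damping
of dominant fragments; an optional m/z power weight is off by default.

The composite score is a weighted mean of linear tolerance-scaled
components (`1 − |error|/tolerance`, floored at 0) with weights
mz 0.25 / rt 0.25 / MS2 0.5; weights of absent evidence are
redistributed, so a candidate is always scored on what is known about
it, in `[0, 1]`. MSI levels: in-house database with matched RT and an
MS2 hit (similarity ≥ 0.5) → level 1; public MS2 library with an MS2
hit → level 2; otherwise level 3. Redundancy removal keeps the
top-scoring candidate per variable, ties broken by lower MSI level then
lexicographic compound id, with an optional level cutoff.

## Statistics

Scaling is the metabolomics family: UV (centre, divide by sd), Pareto
(divide by √sd — compresses rather than equalizes variance), range,
centre. The Welch unequal-variance t-test is the default, matching the
reference implementation's default; Wilcoxon (rank-sum, or signed-rank
when paired) is the non-parametric alternative. Intensities are
log-normal, so parametric testing is meant to follow `log_transform()`;
the type-I calibration of the null simulation holds on that scale. Fold
changes are ratios of observed-value means on the unlogged scale, with
division by zero reported as absent rather than infinite. BH adjustment
runs over the variables with a defined p value only.

PCA fixes the sign of every component (largest-magnitude loading
positive) so repeated runs are identical. PLS-DA is NIPALS PLS2 on the
UV-scaled matrix against the centered one-hot response; VIP scores use
normalized weights, which yields the defining identity mean(VIP²) = 1
exactly. Correlation-network edge p values come from the t
approximation of the correlation test; exact permutation is out of
scope.

## Pathway enrichment

Over-representation uses the upper-tail hypergeometric probability
`P(X ≥ k)` — the observed overlap included, so `k = 0` gives exactly 1 —
or the equivalent one-sided Fisher test, with BH correction across the
tested pathways. Pathway sizes are computed inside the user-supplied
universe (only measurable compounds count), and enrichment keys on
exact compound-id agreement between query, universe and pathway
members; no cross-namespace identifier mapping is attempted.

## Pipeline runner and CLI

The pipeline runner executes a YAML/JSON step list over the archive
format, writing output only when every step succeeded. The thin CLI in
`inst/cli/masspipe.R` exposes the same functions as subcommands with
exit codes 0 (success), 2 (validation), 3 (I/O), 4 (replay mismatch).

## Problem sizes and limitations

The test suite and the acceptance script run on deliberately small
problems — hundreds of variables, tens of samples, 100 random pipelines
of up to 8 steps, 50-seed null simulations — sizes chosen so the entire
evidence base regenerates from seeds in well under a minute while still
exercising every code path; the algorithms themselves are `O(V²)` at
worst (KNN distances) and comfortably handle desk-scale studies of a
few thousand features in memory. Known limitations: no on-disk or lazy
backing; no raw-spectra storage (the container holds processed data);
no ComBat-style empirical-Bayes batch correction; BPCA and
random-forest imputation are registry extension points rather than
implementations; SVR drift correction uses injection order as the only
predictor; vendor-specific peak-table dialects are not parsed — the
generic three-file contract is the import surface.
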