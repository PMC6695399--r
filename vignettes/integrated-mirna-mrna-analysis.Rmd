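---
title: "Integrated mRNA/miRNA biomarker discovery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated mRNA/miRNA biomarker discovery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intermiR)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and
the numerical and design choices that were genuinely open.

## The analysis problem

Two reversible substates of a pluripotent stem-cell culture are compared
on three single-channel microarray experiments — an mRNA array from
cells, and miRNA arrays from cells and from culture-medium exosomes —
with a small number of paired replicate chips per group (three by
default). The goal is a short, reliable list of mRNA biomarker
candidates. Because miRNAs repress their targets, an mRNA that is
observed up-regulated *and* predicted up-regulated by down-regulated
miRNAs seen in both cellular and exosomal compartments is a much
stronger candidate than either observation alone. The exosomal
requirement matters practically: an exosome-borne signature can be read
from spent medium without disturbing the culture.

## Normalization

Each chip is normalized independently in two steps, then the exosomal
chips may carry an additional mass correction:

* **Detection floor.** Linear signals below `floor_value` (default 1
  fluorescence unit) are raised to it. Sub-unit intensities on these
  arrays are scanner noise; flooring keeps them from exploding on the
  log scale.
* **Percentile shift.** Signals are log2-transformed and the chip's
  *P*th percentile of the log2 values is subtracted, so every chip's
  *P*th percentile becomes exactly zero. *P* = 75 for mRNA chips and
  *P* = 99 for miRNA chips: miRNA arrays have a large fraction of
  features near the detection floor, so a bulk percentile would track
  noise rather than signal, and the anchor is placed high in the signal
  range instead. Percentiles use linear interpolation between closest
  ranks (the convention is recorded in the run metadata; a
  multiplicative linear-scale variant is available via
  `shift_scale = "linear"`).
* **Mass correction.** Exosomal RNA yields vary per sample, so each
  exosomal chip can be multiplied by factor = 1 ng / loaded mass before
  normalization, putting all chips on a common 1-ng footing. Factors
  are user-supplied (default 1; loaded masses are experiment metadata
  the package cannot guess). Whether correction precedes or follows the
  floor is flag-controlled (`mass_correct_first`, default before: the
  correction is a property of the raw signal).

No per-feature baseline (median-centering) transformation exists in the
pipeline, deliberately: fold changes are taken between groups of the
same feature, where per-feature centering cancels, and the omission is
part of the normalization contract.

Double normalization is refused: a normalized matrix is flagged and
`normalize_chips()` errors on a flagged input rather than silently
shifting twice.

## Differential expression

**mRNA branch (Z-score selection).** With three replicates per group,
per-feature tests on mRNA arrays have little power, so selection is done
on the fold-change distribution itself: per-feature log2 fold change
(substate 2 minus substate 1 group means), standardized by the mean and
sample standard deviation (n − 1) of all features' fold changes, and
called at |z| ≥ `z_threshold`. The default threshold is 2.0 — the
conventional two-standard-deviation reading of a Z-score cut — and it is
deliberately a mandatory, visible configuration value. Centering is the
default (`center = TRUE`); an uncentered variant is exposed because the
definition "standard deviations of log fold change" admits both
readings, but uncentered scores make the up/down cutoffs asymmetric
whenever the fold-change distribution is not centered at zero.

**miRNA branch (fold filter + paired t + FDR).** Features must first
show a two-fold difference (|log2 FC| ≥ 1 on normalized values); only
that subset is tested with a two-sided paired t-test (pairing replicate
*i* of one group with replicate *i* of the other — replicate index is
the pairing contract), and Benjamini–Hochberg q-values are computed over
the tested subset, matching the stated order of operations (fold filter,
then significance analysis). Calls require q < 0.05. Flags expose
genome-wide correction (`genomewide_fdr`) and Bonferroni
(`correction = "bonferroni"`) as alternatives; BH is the default because
"multiple testing correction (q < 0.05)" is the standard q-value
reading and the default of the commercial array suites. Degenerate
features are defined exactly: all-zero paired differences give p = 1;
zero-variance nonzero differences (possible in tiny fixtures) give a
p = 0 sentinel with a warning rather than an error.

## Target integration

`coverage_targets()` implements the coverage filter: given a source set
of *m* miRNAs moving in one direction, a gene qualifies when it is
targeted by strictly more than `min_fraction` (default 0.5) of them,
and the prediction direction is inverted. Two counting conventions are
possible when a source miRNA is absent from the target table; the
default counts it in the denominator (an absent miRNA targets nothing),
which is conservative and gives the strict ">" boundary a fixed
meaning. `denominator = "in_table"` switches to observed-only counting.

Two intersection graphs are implemented because the narrative ("common
miRNAs first, then conversion") and the Venn-diagram framing ("predicted
mRNAs from cells and from exosomes as separate circles") describe
different graphs:

* `common_mirna_first` (default): intersect cell and exosome DE miRNA
  sets per direction, predict targets from each common set, intersect
  with the observed mRNA sets.
* `per_compartment`: predict separately per compartment and require the
  three-way intersection.

On data where compartment sharing is high the two mostly agree; the
report always names the strategy used. All final intersections are
computed in Entrez Gene ID space after `map_ids()`: symbols without an
ID drop out *before* intersection, mirroring how symbol-to-ID conversion
shrinks real gene lists, and the unmapped symbols are reported. Every
intermediate cardinality (the Venn numbers) is recorded in the
`CandidateSet`.

## qPCR confirmation

Relative quantification uses ΔCt = Ct(gene) − Ct(reference) per
replicate and fold = 2^(mean ΔCt₁ − mean ΔCt₂), with amplification
efficiency fixed at 2.0 (one-step kits; no efficiency correction). A
candidate is confirmed when the fold change reaches
`qpcr_fold_threshold` (default 1.5) in the candidate's direction *and*
an unpaired two-tailed t-test gives p < 0.05; tiers p < 0.1 / 0.05 /
0.01 are reported alongside. The test runs on per-replicate relative
expression values 2^−ΔCt by default — confirmation figures report mean ±
SD of expression, implying statistics on the expression scale — with a
`scale = "delta_ct"` flag for the Ct-scale alternative. Student's
(equal-variance) t is used, matching the classic unpaired two-tailed
test of desk statistics packages at n = 3. Candidates absent from the
qPCR panel are flagged `untested`, never failed.

## The synthetic-data generator

`generate_study()` emits every pipeline input plus the planted truth.
The signal model is log-normal: log2 signal = baseline + group effect +
pair offset + replicate noise, with

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `n_mirnas` | 2000, 300 | universe sizes |
| `replicates_per_group` | 3 | paired chips per group |
| `baseline_log2_mean`, `baseline_log2_sd` | 8, 2 | abundance distribution (log2 fluorescence) |
| `noise_sd` | 0.25 | per-replicate log2 noise, also the pair-offset sd |
| `effect_log2fc` | 2.0 | planted effect (four-fold) |
| `n_de_genes_up/down` | 60 / 60 | planted DE mRNAs |
| `n_de_mirnas_up/down` | 20 / 30 | planted DE miRNAs per compartment |
| `compartment_share_fraction` | 0.6 | DE miRNAs shared cell/exosome |
| `targets_per_mirna` | 25 | random decoy targets per miRNA |
| `biomarker_coverage` | 0.6 | fraction of shared opposite-direction miRNAs targeting each biomarker |
| `n_biomarkers_up/down` | 10 / 3 | planted biomarker genes |
| `de_baseline_quantile` | 0.9 | effects planted below this abundance quantile |
| `bright_noise_factor` | 0.2 | noise multiplier for features above that band |
| `qpcr_ct_sd` | 0.15 | Ct technical noise (cycles) |

Universe sizes, replicate counts, effect size and noise are the
package's reference study conditions. DE counts are round numbers of
the same order as the fractions seen on real substate arrays (a few
percent of miRNAs per direction, with the down set larger than the up
set); biomarker counts scale the confirmed-candidate regime (order ten
up, a few down) to this universe. Ct noise of 0.15 cycles is typical
replicate-to-replicate qPCR precision.

Three structural choices deserve explanation:

* **Pairing is real.** Replicate *i* of both groups shares a per-pair,
  per-feature offset (sd = `noise_sd`), emulating chip-batch
  correlation. Paired differences cancel it, so the paired t-test is
  strictly more powerful than an unpaired one on the same data — the
  pairing has a testable consequence (asserted in the test suite).
* **The normalization anchor is estimable.** Percentile-shift
  normalization presumes that the anchor percentile tracks
  non-differential, precisely measured signal. On real chips this holds
  because the top percent of probes are abundant constitutive species
  measured with a small log-scale coefficient of variation (array noise
  is strongly intensity-dependent). A generator that ignores this —
  planting effects anywhere and giving bright features the same log2
  noise as mid-range ones — produces studies in which the 99th
  percentile of a 300-feature chip (the ~297th order statistic of a
  sparse tail) jumps by up to ~0.9 log2 between chips, a failure mode
  of the scaled-down universe rather than of the method. The generator
  therefore (a) plants effects only below the `de_baseline_quantile`
  abundance band and (b) shrinks technical noise above it by
  `bright_noise_factor`. Baselines are drawn once per feature universe
  and shared between cellular and exosomal chips: abundance is treated
  as feature-intrinsic.
* **Decoys give the filters work.** Every miRNA receives
  `targets_per_mirna` random decoy targets among non-differential
  genes, so the >50 % coverage filter has realistic material to
  reject; biomarker genes are wired to `biomarker_coverage` (60 %) of
  the shared opposite-direction miRNAs, comfortably above the 50 %
  threshold so that recovery is determined by the DE stages, not by
  knife-edge coverage.

What the generator does **not** emulate: probe-level effects and
probe-to-gene collapsing (the feature ID is the analysis unit),
intensity-dependent noise *within* the analysis band, cross-hybridal
signal, miRNA family structure (arm variants are distinct features),
compartment-specific abundance differences beyond the DE sets, and GO
structure. Passing tests therefore demonstrate that the pipeline's
logic and statistics recover planted structure under the stated noise
model — not that the thresholds are optimal for any particular real
dataset.

A null generator (`generate_null_study()`) forces all effects and
planted sets to zero; on it the candidate set is empty in essentially
every run (the fold filter alone removes nearly all features when the
true fold change is 1).

## Numerical conventions and degenerate inputs

* Percentile: `quantile(type = 7)` — linear interpolation between
  closest ranks; chip percentile of the normalized output is zero to
  1e−12.
* Z-score: sample standard deviation (n − 1); a zero-sd fold-change
  distribution is an error, not a silent division.
* Paired t: closed-form row-wise computation (cross-checked against
  `t.test` in the suite); df = r − 1.
* BH: `p.adjust` step-up with enforced monotonicity (cross-checked
  against the explicit min-over-tails formula).
* Identifier matching: gene symbols upper-cased, miRNA identifiers
  lower-cased with the `miR` capitalization restored, before any set
  operation — case is the dominant mismatch source when joining lists
  from different tools. An optional arm-suffix-stripping fallback for
  matching DE miRNAs to target-table entries was considered and left
  out: the target tables the package reads use mature-arm identifiers,
  and silent arm collapsing can pair a miRNA with the other arm's
  targets; exact normalized match is the only default that cannot
  mislead.
* Missing values in expression tables are rejected, never imputed:
  single-channel exports are dense, and silent imputation would
  invalidate the paired test.
* Determinism: all randomness flows from one seed through R's
  Mersenne-Twister generator (recorded in run metadata); identical
  config and seed give bit-identical outputs.

## Problem sizes used in the checks

The reproduction script and acceptance tests run the default study
(2000 genes, 300 miRNAs, 3 paired replicates) over 20 seeds for
recovery and 50 seeds for the null control, and the oracle
cross-checks use ~1000 random small instances per primitive; unit
tests use studies of 40–120 genes. These sizes give stable Monte-Carlo
estimates (binomial sd of a 90 % sensitivity estimate over 260 planted
biomarkers is ~2 %) while keeping the whole suite fast.

## Known limitations

* The Z-score mRNA branch has no per-feature error model; a gene with
  a large fold change driven by one noisy replicate can be called.
  That is inherent to the method, and the integration step is the
  mitigation.
* The coverage filter treats all targets equally; no context-score
  weighting of target predictions is applied.
* With very small common miRNA sets the >50 % rule becomes coarse
  (with 3 miRNAs it means "at least 2"), and candidate sets become
  sensitive to single miRNA calls.
* qPCR confirmation assumes perfect amplification efficiency and a
  stable reference gene; neither is estimated from the data.
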