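---
title: "Small RNA signatures of exogenous dsRNA processing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA signatures of exogenous dsRNA processing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnasig)
library(dplyr)
```

## The question the package answers

When double-stranded RNA (dsRNA) is sprayed onto plant leaves, two fates are
possible. The RNAi machinery may take it up and process it: Dicer-like (DCL)
endonucleases dice the duplex into small interfering RNAs (siRNAs) of
characteristic sizes (21, 22 and 24 nt), RNA-directed RNA polymerase 6 (RDR6)
may amplify the signal into *secondary* siRNAs that map outside the sprayed
interval ("transitivity"), and processive dicing leaves siRNA 5' ends on a
fixed-size register ("phasing"). Or the dsRNA may simply be chewed up by
non-specific nucleases, which leaves an exponential read-length decay and no
size, strand or position structure.

`srnasig` operationalizes that distinction as a statistical battery over
small-RNA sequencing reads, using a three-condition design:

* **target_ds** — dsRNA-sprayed plants carrying the target transgene (GFP
  reporter line); primary *and* secondary siRNAs are possible.
* **wildtype_ds** — dsRNA-sprayed wild-type plants; no transgene, so no RDR6
  template: any reads mapping to the target are degradation products of the
  spray (or primary dicing products), never transitive.
* **target_water** — water-sprayed reporter plants; reads mapping to the
  target are decay products of the endogenous transcript, sense strand only.

The default design is 3 + 3 + 1 samples, matching the study layout this
package emulates.

## The synthetic-data generator

Real spray experiments require sequencing; the generator produces seeded
FASTQ read sets with exactly the statistical structure the analysis assumes,
so every downstream stage is testable offline.

* **Reference.** The target transgene sequence is not distributed, so the
  shipped fixture is a 720-nt seeded pseudorandom sequence with the published
  trigger-amplicon primer cores embedded verbatim at their published
  coordinates (the 139-bp trigger occupies positions 294–432). Only the
  coordinates and primer anchors are real; the filler is synthetic, which is
  why the default reference is named `GFP_synthetic`. Users can supply any
  FASTA instead.
* **Degradation reads** draw lengths from a truncated exponential,
  `P(L) ∝ exp(-λ(L - 17))` on the 17–29-nt quality-control window, with
  λ = 0.25/nt by default — only the qualitative "exponential decay" shape is
  documented for the emulated study, so the default was chosen once to give
  a realistic ~20-fold span across the window. Fragments are placed uniformly
  and emitted from both strands (dsRNA decay) or sense-only (mRNA decay).
* **DCL reads** draw lengths from `size_probs` (default 0.4/0.4/0.2 over
  21/22/24 nt). A `phase_fraction` of them carries its biological 5' end on
  the register `trigger_start + k·L`; both strands share the register. The
  2-nt 3' duplex overhang of real DCL products is *not* modelled: the
  analysis reasons entirely in 5'-end registers, and a 139-bp duplex yields
  `floor(139/22) = 6` phased 22-nt units either way.
* **Transitive reads** are antisense reads in the flanks, only generated for
  `target_ds` (the generator forces the fraction to zero elsewhere, because
  without a target transcript RDR6 has no template).
* **Background** reads come from an off-target pool that includes a fixed
  21-nt miR159 spike-in decoy at configurable weight, so functional
  normalization has something to normalize by.
* Quality strings are constant `I`: the analysis never reads qualities.

What the generator does **not** emulate: sequencing errors, quality
gradients, adapter dimers, ligation biases, multi-locus genomic backgrounds.
Passing tests therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to every artefact of real libraries.

## Read processing

Adapter trimming truncates at the first occurrence of the adapter's first
8 nt (standard small-RNA practice; the seed length is configurable upward).
Reads without an adapter hit are discarded if ≥ 30 nt and kept otherwise;
empty inserts are discarded. Length filtering retains 17–29 nt inclusive.

Mapping is exact (zero mismatches), strand-aware, and reports *all*
placements, including overlapping ones; antisense placements are reported in
sense coordinates. Exactness keeps the brute-force all-substrings oracle in
the test suite meaningful. Reads with more than one placement are discarded
from counts as ambiguous (the shipped reference is non-repetitive, so this
is rare) and tallied. Counting assigns each read to the region containing
its biological 5' end — `start` for sense reads, `start + length − 1` for
antisense reads — which resolves boundary-straddling deterministically.
Coordinates are 1-based and inclusive throughout. Flanks are derived as
`[1, trigger_start − 1]` and `[trigger_end + 1, reference_length]`.

## The statistical battery

**Length-decay fit.** Ordinary least squares of log counts on length over
nonzero lengths; `pearson_r` is the signed correlation of log counts with
length. Zero-count lengths are excluded and their number reported. Because
it is not documented whether the emulated study's "R" was computed on raw or
log counts, both correlations are reported; on a clean exponential they are
close, and the classifier uses the log-scale one.

**Raw size-class comparison.** Per-length two-sided pooled-variance Student
t between `target_ds` and `wildtype_ds` raw counts, no multiplicity
correction — each length is annotated on its own, mirroring per-length
figure annotations. Degenerate strata (zero variance in both groups, equal
means) get p = 1 by convention.

**Control-normalized ANOVA.** Per-replicate counts divided by the
water-control count at the same length, then a one-way ANOVA across
conditions per length with pairwise Bonferroni comparisons summarised as a
compact letter display. Because it is ambiguous whether such ANOVAs should
compare conditions within a length or lengths within a condition, both
orientations are computed and labelled (`normalized_anova`,
`normalized_anova_flipped`). A single-replicate water denominator is flagged
in the report notes as statistically fragile.

**Sliding-window profile.** Value at position p = mean of per-position
5'-end counts over a `window` (default 10 nt) centred at p, shrunk at the
edges, divided by the sample's total read count. The accounting identity
(sum of the profile × total = window-weighted read count) is asserted in the
tests to 1e-9.

**Transitivity.** The wild-type sprayed condition cannot contain transitive
reads, so its flank antisense counts estimate the spray-degradation
background rate. The target condition's total flank antisense count is
tested against a Poisson with that rate (one-sided exceedance). The verdict
additionally requires a mean of ≥ 5 antisense flank reads per target sample:
a minimum-signal floor so that one or two stray reads can never call
transitivity even when the background estimate is zero.

**Phasing.** No standard score exists for this design, so the package
defines one: among trigger reads of exactly the register length, the score
is the maximal fraction of 5' ends on one of the `L` phase offsets; the
p-value is a one-sided binomial test of that offset's occupancy against
1/L, Bonferroni-corrected for the L offsets. With fewer than 10 eligible
reads the score is reported but the p-value suppressed as underpowered. The
null is uniform *offsets*; note that uniform *positions* in a trigger whose
length is not a multiple of L induce a small structural offset bias, which
is visible at very large read counts.

**Long/short ratio.** A 2×2 two-sided Fisher exact test of
(> 24 nt vs < 25 nt) × (inside vs outside the trigger). The odds ratio is
reported as the plain cross-product (not the conditional MLE that
`fisher.test` estimates), with outside-long in the numerator so that a
flatter decay outside the trigger gives an odds ratio > 1.

**Dose arithmetic.** Molarity = 1000 × (ng/µl) / (length × unit mass), with
the conventional average unit masses 660 g/mol per duplex bp and 330 g/mol
per single-stranded nt; these reproduce every published worked molarity at
its printed rounding (20 ng/µl × 139 bp → 0.22 µM; 1.4 ng/µl × 22 bp →
0.1 µM). The `reference_molarity_override` argument exists because published
fold-comparisons divide by the *rounded* 0.1 µM reference; the unrounded
computation gives ≈ 27× instead of 26×. The ≈ 150× effective-molarity figure
is treated as a lower bound (the computation gives ≈ 157×).

## Classification policy

`classify_signature` returns:

* `DCL_PROCESSED` if any silencing size (21/22/24 nt) is significantly
  *enriched* in `target_ds` vs `wildtype_ds`, or the transitivity verdict is
  positive, or phasing is significant at α;
* `DEGRADATION_ONLY` if none of those holds *and* the decay fits of the
  dsRNA-sprayed samples are convincingly exponential;
* `INCONCLUSIVE` otherwise.

The decay requirement is `mean |pearson_r| ≥ 0.9` **per sprayed condition**
rather than per sample. This is a deliberate package policy: replicate-level
correlations computed on narrow length windows (e.g. the six lengths 20–25
of a published count table) are noisy even under clean exponential decay —
on the shipped fixture two wild-type replicates sit at |r| ≈ 0.897–0.899
while every condition mean is comfortably above 0.92 — and the scientific
claim ("degradation-shaped length profiles") is a condition-level claim.
The water-sprayed control is a normalization denominator, not a decay
subject, and is excluded. The threshold 0.9 itself is policy, set well below
the ≈ 0.999 that clean simulated degradation achieves and well above what
size-structured (diced) read sets produce.

## Numerical and design choices

* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state (`withr::with_seed`); per-sample seeds are derived
  deterministically from the experiment seed, and fixing the seed fixes the
  byte content of every emitted FASTQ.
* The mapper indexes all reference windows per read length and joins reads
  against that dictionary — exact, overlapping occurrences included, O(1)
  per read; it is cross-checked in the tests against both
  `Biostrings::matchPattern` (single-read `map_exact`) and an independent
  naive all-substrings scan.
* Ties in the phasing score (`which.max`) resolve to the smallest offset;
  the score is unaffected.
* Degenerate inputs error early and descriptively: empty count tables,
  all-zero control denominators, missing control conditions, regions
  shorter than the minimum read length, size probabilities not summing
  to 1.
* Problem sizes in the tests and the acceptance script — 100,000 reads for
  distribution-level checks, 10,000 Monte-Carlo replicates for test-size
  calibration, 20 seeded end-to-end recovery runs of 4,000 reads per sample —
  were chosen as the smallest sizes at which the checked quantities are
  stable to well within their asserted tolerances.

## Known limitations

* The classifier's enrichment arm inherits the low power of 3-vs-3 t tests;
  a weakly processed sample can honestly come out `INCONCLUSIVE`.
* Exact mapping means a single sequencing error unmaps a read; with real
  (error-containing) FASTQ input, mapped fractions will be lower than the
  simulator's, though the statistics are computed on mapped reads only.
* The transitivity test conditions on the wild-type background estimated
  from (by default) three samples; with zero observed background its Poisson
  rate is zero and the minimum-signal floor is the only guard.
* The published count-table fixture carries no strand or position
  information, so transitivity and phasing are "not assessed" on it — the
  classifier then relies on enrichment and decay evidence alone, and notes
  this in the report.
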