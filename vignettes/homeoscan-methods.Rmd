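---
title: "Detecting spontaneous chromosomal instability in selfed allotetraploid lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spontaneous chromosomal instability in selfed allotetraploid lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeoscan)
```

## The problem

Cultivated peanut (*Arachis hypogaea*) is an allotetraploid (AABB): every
nucleus carries two chromosome complements from the A-genome ancestor
(*A. duranensis*) and two from the B-genome ancestor (*A. ipaënsis*). The
subgenomes are similar enough — roughly 98% identical in genic regions —
that homeologous chromosomes occasionally pair and recombine at meiosis.
Such events convert a region's composition from the balanced AABB to
unbalanced states (ABBB, AAAB) or full tetrasomies (AAAA, BBBB), and
crossovers inside homeologous inversion loops can produce terminal
deletions in which one subgenome's copies are simply lost (an "AA" region).

`homeoscan` implements a pipeline for detecting such large-scale events in
a selfed, pedigree-tracked cohort, from two complementary data types:

1. **SNP-array allele dosage.** Each marker's A-allele signal fraction
   (theta) is scored on the tetraploid 0–4 scale — the count of
   A-subgenome alleles, so BBBB = 0, ABBB = 1, AABB = 2, AAAB = 3,
   AAAA = 4.
2. **WGS allele depths** at subgenome-diagnostic positions, normalized
   against a synthetic-tetraploid 1:1 baseline and classified in genomic
   windows.

Because the cohort descends from a single highly selfed founder by
single-seed descent (SSD) in pollinator-free greenhouses, every deviation
from AABB that is not shared cohort-wide is a *de novo* structural event,
and the pedigree pins down the generation in which it arose.

## The signal model

For a region with `a` A-copies and `b` B-copies, the array model expects

* theta = a / (a + b) — the five dosage clusters 0, 0.25, 0.5, 0.75, 1;
* total intensity = (a + b) / 4 — so a hemizygous deletion region
  (a, b) = (2, 0) sits at half intensity.

The synthetic generator draws theta from a Normal around its expectation,
clamped to [0, 1], and intensity from a Normal with a constant coefficient
of variation. That is deliberately not a model of array chemistry: the
pipeline consumes dosage structure, and the five-cluster geometry plus
noise, mis-scored markers, and missing calls are the features that matter
downstream. Mis-scored markers are emulated by letting each sample's theta
jump to a random cluster expectation, which simultaneously breaks control
uniformity, replicate concordance and positional coherence — exactly the
signatures the filter cascade keys on.

A real-world failure mode is built in: dosage genotyping tends to miscall
hemizygous deletion regions as the neighbouring 3:1 state, because theta
saturates (pure A reads theta = 1 regardless of copy number) while only
total intensity carries the copy loss. With `deletion_miscall = TRUE`
(the default) the generator renders B-loss regions at theta 0.75 and half
intensity, and the caller's low-intensity flag plus the sequencing branch
are responsible for resolving them.

## Dosage calling

The default caller is a fixed-bin assignment: score = the cluster whose
theta expectation is nearest (bin edges 0.125, 0.375, 0.625, 0.875),
confidence 1. An optional per-marker five-component Gaussian-mixture
caller (means initialized at the cluster expectations, common variance,
EM) returns maximum-posterior scores with posterior confidences; calls
under `min_confidence` (default 0.95) become missing, and posterior ties
break toward the euploid score 2. The fixed-bin caller is the default
because it is deterministic, exactly testable against a brute-force
nearest-cluster oracle, and sufficient at realistic theta noise: at
theta-SD 0.05 its accuracy is the Gaussian tail mass outside ±0.125,
about 0.990 over uniformly drawn scores (edge clusters only lose one
flank because theta is clamped).

Deletions are *flagged*, never called, at this stage: cells with
intensity below 0.7 carry a deletion-consistent flag that
run-calling and reconciliation consume later.

## The marker-filter cascade

Stages run in a fixed order; counts telescope and the cascade is
idempotent:

1. **complete** — markers scored in every lineage sample;
2. **controls** — the ancestor accessions and the 1:1 / 3:1 / 1:3 A:B DNA
   mixtures (emulating AABB, AAAB, ABBB) must each score uniformly, the
   two ancestors must differ by ≥ 2 score units (e.g. 3 vs 1), the 3:1
   and 1:3 mixtures must differ, and the 1:1 mixture must sit at modal
   score 2;
3. **replicates** — duplicate extractions of every generation-1 plant
   must agree exactly (the strictest reading; one-mismatch tolerance is a
   possible relaxation we did not take);
4. **modal rule** — a marker's cohort modal score must be 2 unless it
   belongs to a positional run of ≥ 2 consecutive markers deviating in
   the same direction (both toward A or both toward B). Isolated
   deviations are mis-scored probes; coherent runs are real composition
   differences. Modal ties break toward 2.
5. **orientation** — markers whose A-ancestor control scores below the
   B-ancestor are flipped (s → 4 − s) so that every retained marker
   counts A alleles; markers with equal ancestor scores are unorientable
   and dropped.

Optionally (default on), samples with an excess of *isolated* non-euploid
cells are excluded first, at a mean + 4 SD threshold. The metric counts
only run-length-1 deviations, orientation-blind: scattered isolated
deviations indicate low-quality DNA, whereas genuine events form long
positional runs and must not get their carriers excluded. The threshold
is a calibration choice — the underlying study reports excluding a few
such samples without stating its rule.

## Event detection and rates

On the filtered, A-counting matrix, every maximal run of ≥ `min_run`
(default 2, mirroring the consecutive-marker filter) markers sharing the
same non-2 score becomes one draft call; score 1 → ABBB, 3 → AAAB,
0 → BBBB, 4 → AAAA. Runs in which ≥ 50% of markers carry the
low-intensity flag become `DELETION_CANDIDATE` instead, whatever their
score — this is precisely the miscalled-deletion signature.

Reference lines of segmental allotetraploids already carry unbalanced
terminal compositions; these appear in essentially all plants. Calls
overlapping a same-composition region present in more than half the
cohort (or matching an explicit reference profile) are **background**;
the rest are candidates. Candidates are then traced through the pedigree
in generation order: a candidate whose parent carries an overlapping
same-composition call is **inherited**; otherwise it is **novel** and
counts as one independent origin regardless of how many descendants carry
it afterwards. A transient event — present in one plant, absent from its
progeny — is likewise a single origin. The instability rate is
`100 · origins / plants`, rounded half away from zero to one decimal:
3 origins among 233 plants is 1.3%.

## The sequencing branch

Diagnostic sites are positions where A- and B-source reads each reach
≥ 95% consensus on different alleles at a minimum depth. Read counts are
simulated as total ~ Poisson(depth · (a+b)/4) and A-count ~
Binomial(total, a/(a+b)); the default depth is 30.

Raw allele counts are normalized per site against the synthetic
tetraploid — an in-silico 1:1 A:B read combination with true copies
(2, 2) everywhere: `norm_a = 2·s·raw_a/baseline_a`, with the per-sample
scalar `s` fixing the genome-wide median of `(norm_a + norm_b)/2` at 2.
The scalar makes classification invariant to uniform depth rescaling.
Two numerical notes: sites with a zero baseline count are masked, and the
per-site count ratio is biased upward by O(1/depth) (about 2% at the
depths involved); the scalar absorbs most of it, window classification
tolerances absorb the rest, and the test suite checks convergence with a
depth-scaled allowance at depths 200 and 800.

Windows (default 1 Mb, ≥ 20 sites) take the median of each axis and
match to the nearest expected copy pair among (2,2), (1,3), (3,1),
(4,0), (0,4), the hemizygous deletions (2,0)/(0,2) and the trisomies
(3,2)/(2,3); a label is assigned only if both axes are within 0.35
copies, otherwise the window is `UNCLASSIFIED`. Medians rather than means
because real coverage has mapping artifacts that density plots smooth
over. The defaults (window size, 20-site minimum, 0.35-copy tolerance,
200 diagnostic sites per Mb) were chosen together so that the window
standard error at 30× (≈ 0.09 copies on the worst axis) sits well under
the tolerance; all are configurable.

Reconciliation lets overlapping classified windows vote per array event:
agreement confirms the call, and an AAAB/AAAA or `DELETION_CANDIDATE`
array call over AA-deletion windows is relabelled as a B-subgenome
terminal deletion (mirrored for A-losses). This reproduces the
array-to-sequencing resolution of the deletion miscall described above.

## The synthetic cohort and what passing tests do (and do not) show

The generator's default configuration reproduces the study design: one
founder, 6 generation-1 seeds split over two greenhouses, branching to 32
lineages by generation 2, SSD thereafter, two generation-6 plants
expanded to 16 progeny each — 233 plants in total; ten 10-Mb chromosome
sets with 140 markers each (≈ 1400 markers, the order of the study's
final panel); ancestor/mixture/replicate controls; and three implanted
truth events (a heritable generation-4 terminal B-deletion, a whole-set
ABBB in one generation-7 plant, and a transient whole-set ABBB in a
generation-6 plant). The published record fixes the cohort totals but not
the intermediate generation sizes; the default plan is the simplest
death-free realization of those totals. Array noise magnitudes are
likewise not published; the defaults (theta SD 0.03, intensity CV 0.1,
1% mis-scored markers, 0.5% missing calls) are calibration choices
exposed in the configuration.

Passing tests on this cohort demonstrate that the *procedure* is correct
and robust to the modeled noise: with zero noise the pipeline recovers
the implanted truth exactly, and at default noise it keeps ≥ 95% origin
sensitivity with ≤ 1 false origin per 100 plants over seeded replicates.
They do not validate array chemistry, alignment, variant calling, or
mapping bias — real data enter this pipeline downstream of all of those,
and the generator's Gaussian/Poisson idealizations are exactly that.

## Problem sizes and determinism

The shipped tests and the acceptance script run cohorts of 233 plants ×
1400 markers, 20 noisy pipeline replicates, 10^6–10^7 simulated caller
cells, and ~20,000 diagnostic sites per sequenced plant — sizes chosen so
the full suite completes in well under a minute per component on a single
CPU while keeping Monte-Carlo error far below every asserted margin. One
master seed drives each run; every stochastic stage derives a sub-seed
from it, so identical configuration + seed gives byte-identical tabular
outputs.

## Known limitations

* Trisomy states are classified by the sequencing branch but are
  invisible to the array branch (theta 0.6 or 0.4 falls in the euploid
  bin at realistic noise).
* The TSV round trip of a dosage matrix keeps scores and sample roles
  but not low-intensity flags or confidences; deletion-candidate
  labelling therefore requires the in-memory pipeline (or re-calling
  from signals).
* Background classification assumes shared compositions are either
  cohort-prevalent (> 50%) or enumerated in a reference profile;
  intermediate-prevalence ancestral heterogeneity would need the
  reference mode.
* The generator does not simulate read-level artifacts (FASTQ,
  alignment, mapping bias); allele depths are its primitive.
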