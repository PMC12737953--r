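# homeoscan

Detection of spontaneous large-scale chromosomal instability in selfed
allotetraploid lineages, from SNP-array allele dosage and whole-genome
sequencing allele depths.

## What it is for

Allotetraploids such as cultivated peanut (*Arachis hypogaea*, genome
AABB) carry two closely related subgenomes in every nucleus. Occasional
pairing between homeologous chromosomes converts regions from the
balanced AABB state into unbalanced compositions — ABBB, AAAB, or the
tetrasomies AAAA/BBBB — and crossovers inside homeologous inversion
loops can delete one subgenome's copies outright (an "AA" terminal
region). In a cohort descended from a single selfed founder by
single-seed descent, every such deviation that is not shared cohort-wide
is a de novo structural mutation, and the pedigree dates it.

`homeoscan` is aimed at researchers running exactly that kind of
experiment: a pedigree-tracked selfing cohort genotyped on a tetraploid
dosage scale, with WGS on selected plants. It provides

* a **tetraploid dosage caller** (0–4 = count of A-subgenome alleles;
  theta clusters at 0, 0.25, 0.5, 0.75, 1; fixed-bin default, Gaussian
  mixture optional), with a low-intensity flag for deletion-consistent
  cells;
* the **marker-filter cascade**: complete scoring → ancestor/mixture
  control consistency (ancestors ≥ 2 score units apart, 3:1 ≠ 1:3
  mixtures, 1:1 mixture modal 2) → replicate concordance → the
  euploid-modal / consecutive-deviation rule → orientation
  standardization to A-allele counting;
* **event detection**: maximal same-score marker runs → background
  separation (cohort-prevalent or reference-profile compositions) →
  pedigree inheritance tracing → independent-origin counting and the
  instability rate `100 · origins / plants` (rounded half away from
  zero, 1 decimal);
* the **sequencing branch**: allele depths at A/B-diagnostic sites,
  normalized per site against a synthetic-tetraploid 1:1 baseline with a
  per-sample median scalar, classified in 1-Mb windows against the
  expected copy pairs (2,2), (1,3), (3,1), (4,0), (0,4), (2,0), (0,2),
  (3,2), (2,3), and reconciled with array calls — resolving the classic
  miscall in which a hemizygous B-loss genotypes as AAAB;
* a **synthetic cohort generator** (233 plants, 7 generations, controls,
  replicates, implantable truth events, array noise, binomial read
  sampling) so every stage is testable against known truth without any
  external data.

## Worked example

Run the full pipeline on the default synthetic cohort — the study
design: 233 plants, three implanted events (a heritable generation-4
terminal B01 deletion, a whole-set ABBB on set 02 in one generation-7
plant, a transient whole-set ABBB on set 05 in a generation-6 plant),
default array noise, deletion-miscall behaviour on:

```r
library(homeoscan)
cfg <- default_config(seed = 11L)
res <- run_all(cfg)

res$cascade$report
#>         stage n_in n_out
#> 1    complete 1400   405
#> 2    controls  405   382
#> 3  replicates  382   369
#> 4  modal_rule  369   369
#> 5 orientation  369   369

res$origins[, c("plant", "chrom_set", "composition", "origin_generation",
                "n_carriers", "transient")]
#>                 plant chrom_set        composition origin_generation n_carriers transient
#> 1        T.3.3.1.1_G1         1 DELETION_CANDIDATE                 4         19     FALSE
#> 2    T.3.5.1.1.1.1_G2         5               ABBB                 6          1      TRUE
#> 3 T.3.3.1.1.1.1.11_G1         2               ABBB                 7          1     FALSE

res$rate
#> 3 independent origin(s) among 233 plants: 1.3%
```

The filter report telescopes: completeness dominates (each marker must
be scored in all 239 lineage samples), the control and replicate stages
strip mis-scored probes, and 369 oriented markers remain. Detection
finds exactly the three implanted origins: the deletion is first seen at
the generation-4 plant and inherited by its 18 genotyped descendants
(19 carriers), the set-05 ABBB is transient (its progeny lack it), and
the set-02 ABBB arises in a generation-7 plant on top of the inherited
deletion. Three origins among 233 plants give the 1.3% instability rate.

On the array the deletion run is only a *candidate* (a low-intensity
AAAB-scored run — theta saturates over hemizygous regions). The
sequencing branch settles it:

```r
res$wgs[["T.3.3.1.1.1.1.11_G1"]]$reconciliation[
  , c("chrom_set", "composition", "wgs_composition", "final_call", "agreement")]
#>    chrom_set        composition wgs_composition final_call  agreement
#> 15         1 DELETION_CANDIDATE     AA_DELETION DELETION_B relabelled
#> 16         2               ABBB            ABBB       ABBB  confirmed
```

Windows over the first 2 Mb of set 01 sit at (2, 0) normalized copies —
an AA region — so the candidate is relabelled as a B-subgenome terminal
deletion, while the whole-set ABBB is confirmed at (1, 3).

A thin CLI wraps the same functions
(`inst/cli/homeoscan simulate | call-dosage | filter | detect |
wgs-dose | reconcile | report | run-all`).

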