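---
title: "Methods: somatic SV landscape analysis with svscape"
author: "svscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic SV landscape analysis with svscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svscape)
```

# Scope and model

svscape analyses the landscape of somatic structural variants (SVs; events
of 50 bp and larger) across a tumour cohort. Its inputs are per-sample
somatic SV call sets from two callers with different VCF conventions — one
emitting typed records (DEL/DUP/INS/INV plus breakend pairs for
inter-chromosomal junctions), one emitting breakend (BND) records for every
junction — together with exon-resolved gene models (refFlat), gene-level
continuous copy-number values with per-sample high-level thresholds,
annotated small variants, allele-specific copy numbers, and cohort metadata
(ancestry, risk group). The package was designed around ethnic-disparity
cohorts of African, European and admixed prostate-cancer patients, but
nothing in the machinery is tissue-specific.

All internal coordinates are 1-based inclusive (refFlat's 0-based half-open
coordinates are converted on read). A breakend orientation of `+` means the
retained segment extends to the *left* of the breakpoint, `-` to the right;
the four VCF ALT bracket forms map to orientation pairs as
`t[p[` → (+,−), `t]p]` → (+,+), `]p]t` → (−,+), `[p[t` → (−,−).

## Breakend pairing and simple-event classification

BND records are paired by mutual `MATEID` reference; each mate pair is one
event. Inter-chromosomal pairs are translocations (TRA), stored once with
ends in canonical order (lexicographic chromosome, then position).
Intra-chromosomal pairs are classified from their orientations:
(+,−) deletion, (−,+) tandem duplication, (+,+) or (−,−) inversion; a pair
whose inserted sequence is longer than its span is an insertion and is
normalised to a single breakend. Unpaired breakends (a mate absent from the
file) are flagged and excluded from all downstream counts — this may
undercount events from callers that emit single breakends, a deliberate
choice because no principled pairing exists for them.

## Cross-caller concordance

Two calls from the two callers are *concordant* when they have the same SV
type, both breakpoint positions agree within a tolerance (default 5 bp; for
translocations both chromosomes must also agree after canonical ordering;
insertions are compared on their single position), and at least one of the
two calls is high-confidence (`FILTER == PASS`). The merge must be
one-to-one, which the callers' VCFs do not guarantee, so among all candidate
pairs a greedy matching by ascending total breakpoint distance is applied,
with ties broken by genomic order; greedy matching is deterministic and
directly checkable against a brute-force implementation of the same rule,
which the test suite does. Both knobs of the rule are exposed:
`high_conf_in_at_least = 2` gives the stricter both-caller variant, and
`require_presence_in_both = FALSE` additionally rescues unmatched
high-confidence calls from either caller, since the literature is not
uniform on whether presence in both call sets should be required.

## SV-type spectra and hyper-SV subtypes

Per tumour, events are tallied by type and expressed as counts and relative
frequencies (a translocation mate pair counts once). A tumour is a
*hyper-SV* subtype when it has at least 100 SVs in total — the cohort
average this definition is anchored to — of which at least 50% belong to a
single type; both thresholds are inclusive ("at least" in both clauses),
and the label follows the dominant type (hyper-deleted, hyper-duplicated,
hyper-inverted, hyper-translocated, hyper-inserted). The dominance
denominator is the full five-type total including insertions. At a
dominance threshold of 0.5 two labels can only coexist at an exact tie,
which is flagged and left unlabelled rather than resolved arbitrarily.
Ancestry contrasts report, per type, the ratio of African to European group
means of counts and of relative frequencies; admixed samples are reported
but excluded from the ratios.

## Breakpoint hotspots

Every breakend of every event contributes one count to its 1-Mbp window
(an intra-chromosomal event can contribute two counts to one window; a
single-breakend insertion contributes one). Per window the total breakpoint
count and the number of distinct samples with at least one breakpoint are
computed, and windows are flagged by Tukey's fences: a window is a hotspot
when its breakpoint count strictly exceeds `Q3 + 3·(Q3 − Q1)` — the
stringent "far out" fence, because clustered breakpoints can arise in a
single genome — or its sample count strictly exceeds `Q3 + 1.5·(Q3 − Q1)`.
Quartiles use linear interpolation at position `p·(n−1)` on the sorted
values (`stats::quantile` type 7), and the fence population excludes
zero-breakpoint windows by default (`include_empty` restores them): on a
real genome the windows without any breakpoint are dominated by assembly
gaps, and a fence computed over them collapses toward zero. The
distribution summary reports the median and the median absolute deviation
both unscaled and with the 1.4826 consistency factor, since descriptive
"median ± MAD" conventions differ. A z-score alternative (`sd_rule`,
mean + 3 SD) is provided for comparison but the fences are the primary
rule.

For each hotspot, the gene maximising the fraction of the window's
breakpoints inside its union span (strand-ignored; ties broken
lexicographically) is nominated as a candidate driver when either that
fraction or the fraction of contributing samples with a breakend in the
gene strictly exceeds 0.5. Ancestry composition per hotspot reports African
fractions of breakpoints and of contributing samples and a 2×2 Pearson
chi-squared test without continuity correction (in-window contribution
yes/no × African/European; admixed samples excluded).

## Gene fusions

An event is a gene-fusion candidate when its two breakends fall inside the
union spans of two *different* genes; a breakend in overlapping genes
yields one flagged candidate per qualifying pair. Partners are oriented by
asking which end retains its gene's transcription start (from breakend
orientation and gene strand): exactly one 5′-compatible and one
3′-compatible end gives an ordered fusion; anything else (e.g. the
head-to-head geometry of an inversion) is ordered alphabetically and
flagged, matching the antisense-type products such fusions can generate.

The mechanism behind a recurrent fusion locus is classified from all of the
sample's SVs with a breakend in the locus window (both gene spans plus a
100-kbp flank), in rule order: one linking deletion and nothing else
(*single-deletion*); one linking deletion plus exactly two translocations
whose local ends flank the deleted interval within 1 kbp
(*interstitial-retention* — the deleted segment survives elsewhere); a
linking deletion with other overlapping SVs; a sole linking inversion or
duplication; otherwise *complex-multi-SV* with the window SV count. A
linking deletion may end up to 100 kbp downstream (strand-aware) of the 3′
gene and is then flagged extended, accommodating fusion deletions whose
distal breakpoint falls beyond the gene body.

Junction mapping reports, per transcript pair, the last exon (in transcript
orientation) wholly upstream of the 5′-partner breakend and the first exon
wholly downstream of the 3′-partner breakend — the exons retained in the
fused product; a breakend inside an exon reports that exon with an
intra-exonic flag. This convention reproduces the canonical clustering of
androgen-receptor-driven fusions: breakpoints 3′ of exon 1 or 2 of the 5′
partner and 5′ of exon 3 or 4 of the 3′ partner.

## Copy-number states, biallelic inactivation, burden association

Gene-level CN values are discretised GISTIC-style: beyond the per-sample
high-level thresholds → ±2, beyond the fixed low-level thresholds
(±0.1) but not the high-level ones → ±1, else 0. Biallelic inactivation of
a gene in a sample is classified from assembled evidence in the order
Loss/Loss (two exon-overlapping deletions with allele-specific CN of zero
for both alleles), Loss/Mutation (one-allele loss plus a nonsynonymous
SNV), Loss/Break (one-allele loss plus an SV breakend inside an exon),
Mutation/Mutation (nonsynonymous germline *and* somatic SNVs); the order
prefers the most complete copy-number evidence when several rules hold, and
all satisfied classes are kept in an auxiliary column. "Driver-ness" of the
mutation is delegated to the supplied gene list rather than re-derived.

The association between SV burden and mutation status fits, per (gene, SV
type, burden measure), a univariate logistic regression of the binary
mutation indicator (default evidence: coding mutation, high-level CN
change, or SV break) on the burden, and reports the likelihood-ratio
p-value against the intercept-only model — preferred over the Wald test for
its stability near separation. Combinations with fewer than two samples in
either outcome class or a constant predictor are flagged untestable (a
tumour that does not meet the evaluation criteria is reported as such, not
silently dropped). Complete separation triggers a Firth-penalized fit whose
penalized LRT p-value is reported with a flag. Benjamini–Hochberg
adjustment is applied across all testable combinations of a run.

# The synthetic cohort generator

`simulateCohort()` produces a fully self-contained truth bundle so that
every stage can be tested without controlled-access data. Its defaults are
the study conditions the analysis assumes:

* **Cohort**: 180 tumours — 115 African, 61 European, 4 admixed — with
  high-risk fractions per ancestry matching the cohort composition
  (81/115, 53/61, 4/4).
* **Genome**: three 60-Mbp toy chromosomes (tests in seconds; real
  chromosome-size tables are accepted).
* **SV burden**: per-tumour totals are gamma-mixed Poisson (gamma shape
  1.2, mean 1), giving the heavy right tail real cohorts show (means near
  100 with maxima of several hundred). Mean per-type counts are
  ancestry-specific — African (44, 24, 0.1, 24, 24.9) and European
  (33, 9.6, 0.1, 18, 14.3) for (DEL, DUP, INS, INV, TRA) — planting a
  2.5-fold African excess of duplication counts and, because the totals
  differ by 1.5625-fold, a 1.6-fold excess in relative frequency. The
  insertion mean of 0.1 makes roughly 9% of tumours carry at least one
  insertion, mirroring how unreliable short-read insertion detection is.
  Per-tumour type mixtures are Dirichlet-distributed around the ancestry
  means (concentration 4), so relative frequencies vary realistically from
  tumour to tumour.
* **Plants**: five hyper-duplicated (African), five hyper-deleted (4
  African / 1 European) and five hyper-translocated (3/2) tumours with
  totals in 150–400 and dominance 0.55–0.8; five hotspot bins at 10× the
  baseline breakpoint rate; six fusion samples covering all six mechanisms
  at an emulated two-gene locus (a minus-strand 5′ partner with two
  14-exon transcripts and a minus-strand 3′ partner with ten transcripts
  sharing their first four exons, so the planted junctions land in introns
  common to all transcripts); biallelic inactivation evidence for all four
  classes on planted hyper tumours; and a logistic dependence of one
  driver gene's mutation probability on duplication relative frequency,
  `P(mutated) = plogis(−2.5 + 8·x)`, strong enough to be detectable at
  cohort scale, emulating the clearly significant duplication–mutation
  coupling reported for such cohorts.
* **Caller emulation**: caller A writes the typed dialect, caller B the
  breakend-only dialect (insertions become a 1-bp adjacency carrying the
  inserted sequence). Per caller, events drop out with probability 0.05,
  each breakend of the breakend-only caller is offset by an integer in
  \[−3, 3\] (the typed caller anchors the positions), high-confidence
  flags flip off with probability 0.02, and 2% private false calls are
  added, flagged by a missing truth id.

Two deliberate departures from realism: the fusion locus region is kept
free of background breakends so planted mechanisms remain identifiable
(real loci accumulate passenger SVs, which is precisely why the
complex-multi-SV class exists), and truth inversions are generated with the
canonical (+,+) junction only, because typed inversion records carry no
side information and a (−,−) truth event could never round-trip through
that dialect; the (−,−) classification path is covered by unit tests.
What passing tests on this generator do *not* show: robustness to
chromosome-scale rearrangement clusters (chromothripsis, chromoplexy),
purity/ploidy artefacts, or reference-alignment errors — none of which the
generator emulates.

A focused generator, `simulateBurdenCohort()`, backs the power and
calibration studies of the association test: duplication relative
frequencies drawn from Beta(0.8, 2) — right-skewed with occasional
duplication-dominated genomes, approximating the full spread observed
across real cohorts — and totals from the same gamma-Poisson family. Under
the planted effect `plogis(−2 + 3·x)` at n = 200 the adjusted-p power
exceeds 80%, and under the null the LRT holds its 5% level (both verified
in the test suite at 1,000 null replicates and 50 power replicates).

# Numerical and design choices

* Quartile interpolation is type 7 (the `p·(n−1)` rule); other
  `stats::quantile` types can be selected.
* Fences are strict inequalities; all hyper-SV thresholds are inclusive.
* Greedy concordance ties are broken by (chromosome, position) of the A
  then B call, then input order — fully deterministic.
* The dominant-type argmax breaks ties in the fixed order
  DEL < DUP < INV < TRA < INS and flags exact top ties.
* MAD is reported unscaled *and* scaled; the unscaled value is the
  descriptive default.
* Multi-allelic SV records are rejected: neither input dialect emits them
  for somatic SVs.
* Chi-squared tests use no continuity correction (the reference
  implementations of this analysis style do not apply one); hotspots with
  no African/European contributors are flagged undefined rather than
  tested.
* A single seeded RNG stream drives each simulation bundle; the bundle is
  byte-identical across runs with the same seed, and the RNG state of the
  calling session is restored afterwards.

## Problem sizes used in the checks

The test suite runs the concordance oracle on 20 samples of roughly 200
calls each; subtype recovery on 20 replicates of 33 spectra; hotspot
recovery on 20 replicates of 100 samples over 300 bins; association
calibration on 1,000 null fits of n = 180 and power on 50 replicates of
n = 200; and the end-to-end pipeline on a 10-sample bundle through the VCF
files on disk. These sizes were chosen so each property is measured with
comfortable statistical resolution while the whole suite stays fast enough
to run habitually.

# Known limitations

* Single breakends are excluded rather than modelled; cohorts from callers
  that emit many of them will be undercounted.
* Concordance is two-caller only; no multi-caller consensus.
* The mechanism classifier assumes an intra-chromosomal partner pair (the
  canonical androgen-driven fusion geometry); inter-chromosomal fusion
  loci are not windowed.
* Insertions are matched on position and insert presence only — insert
  sequences are not compared.
* The genome is treated as a flat coordinate space: no fragile-site,
  replication-timing or gap annotation is consulted when calling hotspots,
  so co-location of a large gene with a hotspot cannot be distinguished
  from chance by the package itself.
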