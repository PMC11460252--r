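---
title: "Decomposing DNA contamination in rAAV preps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing DNA contamination in rAAV preps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvseqr)
```

# The measurement model

An rAAV preparation is modelled as a mixture of DNA species: the vector
genome itself, producer-cell genomic DNA, the helper / Rep-Cap / vector
plasmids, *E. coli* carryover, optionally a lambda spike-in, and a
`foreign` remainder that maps to none of the known references. SSV-seq
library preparation denatures every molecule before adapter ligation, so
single-stranded vector genomes and double-stranded contaminants enter the
library on equal footing; the percentage of deduplicated read pairs
assigned to each species is the estimate of that species' molecule
fraction.

Two quantities summarise a prep:

* the **species profile** — the percentage decomposition of deduplicated
  read pairs over species plus an `unmapped` bucket;
* the **localization calls** — for each contaminant, whether it sits inside
  capsids (protected from DNase) or outside (digestible), inferred from a
  matched pair of profiles sequenced with and without DNase pretreatment.

## Competitive classification and homology masking

Reads are classified *competitively*: each mate is aligned against every
reference in a panel, and the pair goes to the species with the highest
summed best-hit score, provided it beats the runner-up species by a score
margin (default 5). Pairs within the margin are `ambiguous`; pairs with no
hit are `unmapped`. For the headline table, ambiguous pairs are folded into
`unmapped` (published decompositions have no "multi-mapping" row), and the
ambiguous count is kept separately on the profile object.

Competitive assignment is only well defined if no two references share
sequence. They do: the ~145 bp ITRs are present in both the vector genome
and the vector plasmid, and gene-editing donors carry homology arms copied
from the producer genome. The panel is therefore **masked** before
alignment: all local homologies between distinct records (k-mer seeding,
k = 15, ungapped x-drop extension on both strands; reported if ≥ 50 bp at
≥ 90% identity) are replaced by `N` on the *lower-priority* record. The
priority order is

rAAV genome (1) > plasmid backbone (2) > helper (3) > Rep-Cap (4) >
lambda (5) > baculovirus (6) > *E. coli* (7) > producer genome (8).

This order is a design decision, not something the underlying experiment
dictates: shared ITR / homology-arm sequence is counted toward the vector
genome because %rAAV is the purity figure of merit, and attributing
vector-plasmid ITR reads or producer-genome arm reads away from the vector
would understate it. The consequence to keep in mind when reading profiles:
reads genuinely originating from the masked copy (for example backbone ITR
reads) are credited to the rAAV genome. With default reference sizes this
bias is bounded by the masked fraction of each contaminant (≈ 10% of the
3 kb backbone, 0.8% of the 200 kb producer segment) and stays well inside
the ±2-point recovery tolerance used throughout.

Masking thresholds (50 bp, 0.90 identity) were chosen once, to catch ITRs
(145 bp) and diverged homology arms while ignoring chance k-mer matches;
the homology search uses match +1 / mismatch −2 with an x-drop of 16, which
extends cleanly through the ~2% substitution divergence typical of arms
while stopping at real boundaries. Boundary placement legitimately differs
between extension rules, so oracle comparisons allow ±5 bp at interval
ends. Masking is idempotent, and its defining property — re-running the
homology search on a masked panel finds nothing — is asserted over 20
seeded reference sets in the test suite.

## The aligner

The read aligner is an internal seed-and-extend implementation (exact
21-mer seeds over unmasked panel bases, diagonal clustering, banded
semi-global extension with affine gaps: match 1, mismatch −4, gap open −6,
extend −1; band half-width 4). Hits under 50 aligned bases or 90% identity
are discarded. It is deliberately not a wrapper around an external mapper,
for two reasons: the artifact must be runnable and testable with no
external binaries, and an internal implementation can be validated
directly against an exhaustive Smith–Waterman dynamic program with the same
scoring — an independent code path kept in the package for exactly that
purpose, which itself is cross-checked against
`Biostrings::pairwiseAlignment` in the tests. On 1,000 simulated reads the
heuristic matches the exhaustive scan's position in ≥ 99% of cases (100%
in practice); the oracle comparison runs on a scaled-down (~18 kb)
reference set so the quadratic DP finishes in seconds.

Adapter trimming is local alignment of the adapter within the read
(match 1, mismatch −1, gap −2, minimum score 10), cutting at the alignment
start. A minimum score of 10 admits occasional spurious matches on 150-nt
reads (~1–2% of pairs end up QC-rejected when the false cut leaves a mate
under 30 nt); these rejections are counted and excluded from the profile
denominator, mirroring a pipeline that filters before mapping. Because a
spurious hit is anchored to wherever a genome happens to contain an
adapter-like 10-mer, rejection is mildly locus-correlated and can shift a
species' recovered share by a few tenths of a point — visible in the
recovery checks but an order of magnitude inside their ±2-point tolerance. Whether the
published "unmapped" rows include QC failures is not stated in the source
material; here they do not, and the QC count is reported separately.

## UMI deduplication

Each molecule carries an 8-nt UMI. Mapped pairs identical in (UMI,
category, position ± 2 bp) collapse to one; UMIs at Hamming distance 1 at
the same position also collapse (UMI sequencing errors); unmapped pairs
deduplicate on (UMI, first 30 nt of mate 1). The ±2 bp window absorbs
alignment-start jitter from substitution errors near read ends. At the
simulator's default 5% PCR duplication, deduplication recovers the true
molecule count to within 0.1% at 20,000 pairs.

## Coverage and SNV aggregation

Per-base coverage over the vector genome is the count of deduplicated
alignments spanning each base, normalized so the track sums to 1,000
(`1000 * raw / sum(raw)`), making preps comparable regardless of depth. The
normalization conserves exactly (asserted to 1e-6) and is invariant under
duplication of every alignment.

SNVs are aggregated with a combined-alternative rule: per sample and
position, the alternative fraction is `(depth − ref count) / depth` — all
alternative alleles pooled. A position is *present* in a sample when that
fraction reaches `min_alt_fraction` at depth ≥ `min_depth`, and is reported
when present in at least `ceiling(S/2)` of `S` samples, with the reported
fraction the mean over present samples. `min_depth = 20` and
`min_alt_fraction = 0.01` are package defaults chosen to suppress calls
from the simulator's 0.001 per-base error rate (error piles reach ~0.3%
per position, a 3× safety margin below the threshold); the underlying
experiment published no numeric thresholds, so both are tunable. The
"half of all samples" rule is realized as `ceiling(S/2)` — the conservative
reading for odd `S`.

## DNase localization

Removing extra-capsid DNA renormalizes every surviving species upward, so
raw percentage changes conflate digestion with renormalization. Ratios are
therefore taken against the rAAV genome share, which is fully protected:

`log2_change = log2( (species%/rAAV%)[+DNase] / (species%/rAAV%)[−DNase] )`

The verdict thresholds — `extra_capsid` at log2_change ≤ −1,
`intra_capsid` at |log2_change| < 1 — encode "at least a 2-fold drop
relative to the protected genome" versus "did not change much". The 2-fold
boundary is a design decision calibrated on the published worked pair: in
the dirtiest transfection prep, human genomic DNA moves −2.51 log2 (clearly
digested) while helper plasmid moves −0.98 (essentially stable), and the
±1 threshold separates exactly these behaviours. Species below a 0.01%
floor in either profile give undefined ratios and are `indeterminate`, as
is a relative *increase* of 2-fold or more (no physical mechanism in this
model produces one; it flags a problem rather than a localization).
Partial encapsidation is deliberately reported only as a verdict, not as a
continuous estimate.

The lambda spike-in validates the DNase reaction itself: naked lambda DNA
added to both conditions must drop to ≤ 1% of its untreated count in the
treated aliquot (`spikeQC`), matching the binomial survival model the
simulator implements.

## Phenotype analysis

Downstream effects on CD34+ HSPCs are analysed with standard tools behind
thin, tested interfaces:

* **Clonogenicity**: `% CFU = 100 × colonies / cells plated` per plate
  (dilution series 300/100/25 cells, duplicate plates), averaged per
  condition.
* **Lineage**: erythroid = BFU-E + CFU-E, myeloid = CFU-GM + CFU-G + CFU-M;
  mixed CFU-GEMM colonies belong to neither dichotomy and are reported
  separately.
* **Purity–clonogenicity regression**: ordinary least squares of %CFU on
  %rAAV (via `lm`), p from the two-sided t test on the slope, checked
  against the normal equations at 1e-10 relative tolerance. The published
  regression's own numbers are not reproduction targets — the per-donor
  colony values behind them are not available — so the regression is
  validated by oracle equivalence and by synthetic parameter recovery
  instead (the 95% CI covers the generating slope in ≥ 90/100 seeded runs).
* **Expression**: the delta-delta-Ct method, `2^−((Ct_t − Ct_actb) −
  (Ct_t,mock − Ct_actb,mock))`, technical replicates averaged first;
  missing β-actin is an error, not a silent NA.
* **Group comparisons**: Welch's unequal-variance t test. The source
  experiments never name their test; Welch is the safest reading for
  starred pairwise comparisons at n = 3 donors, and it tracks an exhaustive
  permutation test within ±0.02 on 6+6 samples. Stars follow
  `* < 0.05`, `** < 0.01`, `*** < 0.0005`, `**** < 0.0001`. No
  multiple-testing correction is applied, matching per-comparison
  reporting; users running many contrasts should adjust externally.
* **Viability** is summarised descriptively (mean ± sd per condition and
  day) — the DNase effect on viability is a trend, not a tested claim.

# The synthetic-data generator

The generator defines the study conditions; it is not a tuning knob.

**References.** The vector genome (4.7 kb) is
`ITR(145) + arm(800) + cassette + arm(800) + ITR(145, inverted)`, with both
arms copied verbatim from random loci of a 200 kb producer-genome segment
and both ITRs shared with a 3 kb vector-plasmid backbone. Helper (10 kb),
Rep-Cap (7 kb), *E. coli* (50 kb), baculovirus (20 kb), lambda (48.5 kb)
and foreign (20 kb) records are i.i.d. uniform DNA. A 200 kb segment stands
in for the full producer genome (size chosen so that arm homology is a
realistic needle in a large haystack while panels build in ~1 s); there is
no repeat structure, GC bias or chromosome model.

**Reads.** Molecules are drawn multinomially from the prep's effective
fractions. Under DNase, species `s` has weight
`f_s × (enc_s + (1 − enc_s) × (1 − efficiency))`, renormalized — protected
molecules survive, a `(1 − efficiency)` remnant of exposed ones leaks
through. Fragments are Normal(300, 60) truncated to [50, 500] bases
(sonication-scale), a uniform random strand, read length 150 per mate,
i.i.d. substitution errors at 0.001/base, flat Q30 qualities, 8-nt uniform
UMIs, and 5% of molecules emitted twice as PCR duplicates. When a fragment
is shorter than the read, the read runs into the 3' adapter, exercising the
trimmer. Truncation of the fragment-length normal is by clamping, which
slightly inflates the density at the bounds — immaterial for any quantity
measured here. There are no indel errors, no chimeras, no full/empty capsid
model, and no quality-value information content (qualities exist only to
exercise the QC filter).

What passing tests on this generator do and do not show: they demonstrate
that the classification machinery recovers known compositions through the
real homology hazards (ITRs, arms) and the DNase/encapsidation arithmetic;
they do not certify performance on real reads with indels,
position-dependent error, coverage bias, or contaminants absent from the
panel — the `foreign` record is a stand-in for "unmappable", not a model of
real foreign DNA diversity.

**Phenotypes.** Expected %CFU is linear in purity (defaults: slope 0.2
%CFU per %purity, intercept 5, condition-by-donor Gaussian noise sd 2);
plate counts are Poisson around `cells × %CFU/100` and split across
morphology classes multinomially. Ct values are Gaussian (sd 0.1) around
`baseCt − log2(fold)` with an invariant β-actin reference; per-gene fold
changes scale with contamination via per-gene sensitivities. Negative
expected colony counts are clipped at zero with a warning.

**Published presets.** `prepCompositions()` carries the published
percentage decompositions of six preps (HEK293T and Sf9 production, ±DNase)
and `compositionFractions()` renormalizes a column (printed values sum to
100 ± rounding) into simulation fractions, with the unmapped row mapped to
`foreign`. These tables drive the composition-recovery checks and are
direct inputs to `localize()`.

# Numerical and edge-case decisions

* Coordinates are 0-based half-open everywhere; FASTA headers carry
  `species=` and `priority=` tags; masks serialize as BED-like TSV.
* Percentages are deduplicated *read-pair count* fractions, not
  base-coverage fractions — the UMI-consistent reading of "percentages of
  DNA species", and the one under which multinomial error bounds apply.
* Equal-priority homology pairs (not produced by the default order) break
  ties by record id so the masked member never depends on input order.
* Zero-coverage tracks normalize to all-zero with a warning rather than
  NaN; zero assignments refuse to profile; a zero rAAV share refuses to
  localize (the normalizing denominator would be meaningless).
* The spike amount in the DNase control is a free parameter of the
  simulator (`n`), since the underlying protocol reports different amounts
  in different roles.
* Problem sizes in the routine test-and-acceptance runs — 50,000 pairs for
  composition recovery, 20,000 for dedup accuracy, 1,000 reads for oracle
  agreement, 20 seeds for the masking fixed point, 100 seeded repetitions
  for CI coverage — were chosen so multinomial noise sits well inside the
  stated tolerances (≈ 0.2–0.3 points on major species at 50,000 pairs).

# Known limitations

* The aligner's banded extension (half-width 4) tolerates small indel
  drift but the simulator produces none; indel-rich real data would need
  the band widened and indel-aware identity accounting.
* Masking is all-or-nothing at 90% identity; homologies just below the
  threshold remain unmasked and will generate ambiguous pairs instead.
* Localization verdicts are qualitative by design; a continuous
  encapsidated-fraction estimate would require a titration model the
  ±DNase pair cannot identify on its own.
* The producer-genome segment conflates "human genome" with a single
  contiguous stand-in; chromosome-level density analysis reduces to a
  single-segment density and is not separately exposed.
* Whether DNase pretreatment changes infectious titer is outside what
  sequencing can answer and outside this package's scope.
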