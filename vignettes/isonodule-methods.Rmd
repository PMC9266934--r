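---
title: "Methods and design notes for isonodule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for isonodule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isonodule` implements the downstream, isoform-centric analyses that
follow a full-length transcriptome annotation of a two-condition
developmental time course: alternative-splicing (AS) event
classification, PSI-based differential splicing, major-isoform switch
detection, lncRNA positional classification with partner correlation, and
rule-based NMD screening. This vignette documents the statistical models,
the parameters that matter, the synthetic-data generator's assumptions,
and the design decisions taken where more than one defensible choice
existed.

## Coordinates and containers

All genomic coordinates are 0-based half-open internally; GTF/GFF3 input
and output use the formats' 1-based inclusive convention, converted at the
I/O boundary (`read_gtf()` / `write_gtf()`, backed by rtracklayer). A
transcript model is a strand-aware exon chain with an optional genomic CDS
span; an expression matrix couples a transcript × sample FPKM table to a
typed design (condition, time, replicate). The default design mirrors the
study layout the package targets: two conditions (inoculated /
uninoculated), nine time points (1–30 days post inoculation), three
replicates, i.e. 54 samples.

## Locus grouping

The grouping rule is single-linkage: two transcripts share a locus iff
they are connected by a chain of same-strand exonic overlaps of ≥ 1 nt.
This matches the semantics of common long-read isoform-collapsing tools
and is testable — the suite checks the partition against a brute-force
union-find over all transcript pairs. Overlap is evaluated on exons, not
spans, so a gene nested inside another gene's intron keeps its own locus.

## AS event grammar

Events are defined pairwise between two isoforms of a locus:

* **IR** — an intron of one isoform lies strictly inside an exon of the
  other (both boundaries interior). The retaining isoform is the
  inclusion form.
* **ES** — an internal exon whose two flanking introns have outer splice
  sites coinciding with a single intron of the partner. Skipping two
  adjacent exons does not match this template and falls through to
  `complex` — decomposing compound differences is ambiguous and is
  deliberately not attempted.
* **A5SS / A3SS** — two introns sharing exactly one boundary, named
  strand-aware in transcript orientation (A5SS: shared acceptor,
  differing donor). The isoform with the shorter intron is the inclusion
  form.
* **MXE** — each isoform holds exactly one of two non-overlapping internal
  exons with shared outer flanking splice sites; the inclusion form
  carries the 5′ exon in transcript orientation.

Differences outside the shared genomic span (alternative
transcription start/end) are not splicing events and are ignored;
remaining unexplained differences inside the span are merged into one
`complex` event per contiguous difference region. Locus-level enumeration
runs all unordered pairs and merges events identical in (type, variable
region, flanks), unioning inclusion/exclusion sets. Because the grammar
is pairwise rather than a flattened multi-transcript bubble grammar,
event counts are not comparable to tools using other grammars; the
package's own truth-set tests define correctness here.

## PSI and differential splicing

PSI is computed from transcript abundances: per sample,
PSI = Σ FPKM(inclusion) / (Σ FPKM(inclusion) + Σ FPKM(exclusion)),
undefined when the denominator is zero. This is a transcript-abundance
stand-in for read-level PSI estimation: it needs no alignments, at the
price of inheriting any abundance-estimation bias.

The per-time-point test is Welch's t on logit-transformed PSI with
boundary shrinkage to [0.01, 0.99]. Under multiplicative log-normal
replicate noise the logit of a two-isoform PSI is exactly normal, so the
test is calibrated by construction; the suite verifies empirical type-I
error within [0.03, 0.07] at α = 0.05 over 2,000 null events. FDR control
is Benjamini–Hochberg applied across events *within* each time point
(the pooling scheme is not dictated by anything in the data model; per
time point keeps each time's calls self-contained). The significance
filter is FDR < 0.05 AND |ΔPSI| > 0.1, with the absolute value taken on
ΔPSI. Events with fewer than two defined replicate PSI values per
condition are marked untestable and excluded from the FDR pool.

For temporal clustering, missing or untestable ΔPSI is imputed as 0 ("no
evidence of change"), and profiles are clustered hierarchically with
Euclidean distance and average linkage, cut at k (default 10). The
early/late split of differentially spliced genes uses 15 dpi as the first
late time point.

## Differential expression stand-in

Gene expression is defined as the sum of member-isoform FPKM — exactly
conserved by construction and verified to numerical precision. The DE
caller is Welch's t on log2(FPKM + 1) with BH adjustment (padj < 0.05).
This is a deliberate, documented stand-in: it is deterministic and
calibrated, but its gene counts are not comparable to count-model tools
(negative-binomial shrinkage estimators), and no claim of equivalence is
made. Expression thresholds are strict: a gene is expressed at
FPKM > 0.1, an isoform at FPKM > 0.01, in at least one sample.

## Major isoforms and switches

Dominance is evaluated on replicate-mean FPKM per (condition, time) cell,
over the locus's expressed isoforms (a constant denominator set across
cells). Averaging replicates before forming ratios was chosen for
stability; the alternative (per-replicate calls with a voting rule) adds
a tuning knob without a clear benefit at three replicates. The major
isoform must exceed ratio 0.5 strictly; a 50/50 cell has no major.

A switch is a cell pair with different (non-missing) majors. Its ratio
change is the maximum over the two involved isoforms of the absolute
usage-ratio change between the cells — the most conservative reading of a
"30 % cutoff" on a quantity the underlying procedure does not pin down —
and must exceed 0.3 strictly. Cross-time comparisons within a condition
count by default (`inter_condition_only = FALSE` restricts them off). The
former isoform is the one major at the earliest involved cell, ties
broken towards the control condition.

Categorisation uses the inter-condition same-time switch points T:
a single time gives `stage_specific`; T running uninterrupted from an
onset t0 ∈ {15, 20, 25} dpi to the final time point gives `continuous`,
upgraded to `irreversible_inoculated` when the inoculated arm switches
former → latter at t0 and keeps the latter while the uninoculated arm
keeps the former throughout; scattered recurrences are reported as one
stage-specific record per time. Former/latter isoforms are compared by
spliced CDS length with a paired Wilcoxon signed-rank test implemented
in-package: for n ≤ 25 non-zero pairs the exact sign-flip distribution is
computed by dynamic programming over doubled (hence integer) average
ranks, so tied differences are handled exactly — `stats::wilcox.test`
declines exact p-values under ties, which the worked example (ten equal
paired differences → p = 2/2¹⁰) requires; above n = 25 the normal
approximation with continuity and tie corrections is used.

## lncRNA classification

Candidates are transcripts labelled non-coding (externally supplied
labels; coding-potential model training is out of scope) with longest ORF
≤ 100 aa — strictly greater ORFs are removed. Classification priority is
antisense > sense-overlapping > proximal > intergenic; span overlap
decides the overlap categories, exon–exon overlap picks the
exonic/intronic subcategory, and transcript-boundary distance
(irrespective of strand) separates proximal (≤ 2000 nt) from intergenic
(lincRNA, > 2000 nt). The eight-subcategory scheme
(lncNAT exonic/intronic, sense exonic/intronic, proximal
upstream/downstream/bidirectional-promoter, distal lincRNA) is this
package's own stand-in consistent with the lincRNA/lncNAT definitions:
no canonical eight-label enumeration exists to adopt. Partner choice:
antisense lncRNAs pair with the maximally exon-overlapping anti-strand PC
transcript; all others with the nearest PC transcript, ties broken by
distance, then the lncRNA's 5′ side, then lexicographic id. Partner
correlation is Spearman across all samples, with per-category medians and
a rank-sum comparison between lncNATs and lincRNAs.

## NMD screen

The ORF finder scans all three sense frames for ATG-to-stop ORFs (stop
codon included in the reported CDS length), keeps the longest of ≥ 30 nt
(ties to the 5′-most start), and flags uORFs — ATG-initiated ORFs ≥ 9 nt
entirely within the 5′ UTR. The 30/9 nt minima are package choices; they
are parameters, not constants. The screen flags `long_utr3` when the
spliced 3′ UTR strictly exceeds 580 nt (the third-quartile convention;
`utr3_quartile()` re-derives the threshold on any dataset using type-7
linear interpolation) and `ptc_rule` when at least one exon–exon junction
lies 3′ of the stop and the stop-to-last-junction distance strictly
exceeds 50 nt. The two features are combined by OR into `nmd_candidate`;
both component flags are always exported so users can recombine them —
the feature list itself does not dictate a conjunction. Screening a
transcript without a stop codon is an error, not a silent negative.

## The synthetic-data generator

No generative model exists for the targeted study's data, so every
distributional choice below is a stand-in chosen once to look like
realistic desk-scale data, and the recovery results on it should be read
accordingly: they validate the *implementations* against planted truth,
not the biology of real nodulation data.

* Loci are placed non-overlapping on one chromosome with 6–9 kb gaps;
  exon lengths uniform on [80, 300] nt, introns on [100, 400] nt, exon
  counts Poisson with mean 8 (floored at 5 for multi-isoform loci so all
  five edit types are feasible).
* The isoforms-per-locus distribution defaults to ~65 % multi-isoform
  loci, most with 2–6 isoforms.
* Every extra isoform differs from its locus's base isoform by exactly
  one structured edit (retained intron, skipped exon, donor/acceptor
  shift of 6–25 nt, or exon replacement inside a downstream intron),
  recorded in the truth set. This makes classifier recovery exact by
  construction and is also the generator's main unrealism: real isoform
  sets differ by compound, correlated changes.
* Abundances are log-normal (log2 FPKM ~ N(3, 1.5)), constant over the
  design except where truth is planted; replicate noise is multiplicative
  log-normal with sd 0.25 on the log2 scale. Switch loci use 0.7/0.2
  former/latter proportions, swapped in the prescribed cells (ratio
  change 0.5, comfortably above the 0.3 cutoff). DS loci are generated
  with exactly two isoforms so the planted pair fully defines the
  event's inclusion/exclusion sets, with PSI 0.3 off-effect and
  0.3 + ΔPSI (default 0.4) in the inoculated arm at the planted time.
* lncRNA/partner correlation uses a latent temporal profile shared
  between the lncRNA and its partner locus, with independent noise
  calibrated via the bivariate-normal relation
  ρ_Pearson = 2 sin(π ρ_Spearman / 6) so the target Spearman rho holds in
  expectation, not per draw. lincRNA pairs are generated independent
  (target rho 0).
* Planted NMD isoforms alternate the long-3′UTR (600 nt) and
  stop-to-junction (60 nt) constructions; all other coding transcripts
  get a stop inside their last exon with a 3′ UTR ≤ ~400 nt, making them
  clean negatives.
* The junction support set keeps each junction independently with
  probability 1 − dropout; the dataset writer's default dropout of
  0.1784 emulates the ~82 % short-read junction support regime the
  analyses are calibrated against.

A single integer seed determines every output byte; the suite asserts
byte-identical regeneration.

## Problem sizes and degenerate inputs

The test suite and acceptance script use desk-scale sizes chosen as the
package's own verification conditions: 500 single-edit pairs per event
type for classifier accuracy; 200 loci with 30 planted switches (10 per
category) for switch recovery at noise 0.25 and the zero-false-positive
check at zero noise; 2,000 two-isoform null loci for type-I calibration;
20 planted ΔPSI = 0.4 events for recovery (mean estimate within 0.1, and
≥ 90 % of events individually within the noise-derived 0.1 band — a
simultaneous band across 20 events at ~2.4σ would fail by chance alone);
50 planted lncRNAs for placement and correlation recovery; 1,000 random
sequences against a brute-force ORF oracle.

Degenerate inputs are defined errors, not silent results: empty transcript
tables for summary statistics, empty junction sets for support fractions,
zero-variance count vectors for the DS/DE correlation, NMD screens
without a stop codon, and k larger than the event count for clustering.

## Known limitations

* Event counts from the pairwise grammar are not comparable to flattened
  multi-transcript event vocabularies.
* The DE and DS tests are calibrated stand-ins on FPKM; counts from
  negative-binomial or read-level tools will differ.
* PSI from transcript abundances conflates quantification error with
  splicing signal; no uncertainty in the abundance estimates is
  propagated.
* The generator plants single-edit isoforms, uncorrelated loci and
  time-constant baselines; passing recovery tests therefore demonstrates
  algorithmic correctness, not robustness to the full complexity of real
  long-read annotations (degraded 5′ ends, mono-exon fragments,
  overlapping loci), which is exercised only by the hand-built fixtures
  in the unit tests.
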