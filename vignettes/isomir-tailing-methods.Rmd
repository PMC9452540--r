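---
title: "Quantifying miRNA 3' tailing with isotail: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNA 3' tailing with isotail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isotail)
```

# The problem

Mature microRNAs are not a single sequence: small-RNA sequencing recovers a
cloud of 3' isoforms (isomiRs) around each annotated mature miRNA —
trimmed forms, templated extensions produced during biogenesis, and
non-templated (NT) tails added post-transcriptionally by terminal
nucleotidyltransferases (TENTs). Adenylating enzymes (TENT2-like) add
mostly A with some G; uridylating enzymes (TUT4/TUT7-like) add U. Because a
single-nucleotide extension can also arise from imprecise processing, the
only way to call a tail *non-templated* is to compare the extension with
the genomic sequence immediately downstream of the miRNA's locus — at
*every* locus, for miRNAs with paralogous copies.

`isotail` implements this analysis end to end: motif-based read assignment,
templated/NT decomposition, per-condition tailing metrics, differential
tailing between knockout/rescue conditions, spike-in based misread
estimation, miRNA-level regulation calls, and a ground-truth simulator that
makes every stage testable without external sequencing data.

# Read assignment

Reads are collapsed to distinct sequences and assigned by an exact match of
a **central motif**: the `motifLen` (default 13) nt substring starting at
0-based position `floor((L - motifLen)/2)` of each mature sequence.
Anchoring the middle of the read leaves both ends free to vary, which is
exactly the isomiR phenomenon being measured; no mismatches are tolerated
inside the motif. The default of 13 nt is long enough that motifs are
essentially unique across a miRBase-scale catalog yet short enough to sit
inside every mature sequence (16-30 nt); it is configurable.

Details that matter:

* If the motif occurs at several positions in a read (repetitive
  sequences), the anchor minimizing mismatches against the mature sequence
  over the aligned overlap is used, ties resolved toward the smallest end
  shift.
* If motifs of several distinct miRNAs occur, the read goes to the miRNA
  with the fewest mismatches over the anchored overlap; residual ties are
  counted as `ambiguous` and excluded from profiles rather than split,
  which avoids double counting at the cost of discarding a small number of
  reads.
* Identical paralogs are one catalog entry with several loci; counts are
  never split across paralogous loci — the loci matter only for the
  templated-tail check.
* Reads shorter than 16 or longer than 35 nt are filtered and reported in
  the run log, so count conservation (assigned + unassigned + ambiguous +
  filtered = total) is auditable.

# Templated vs non-templated 3' ends

For each assigned read the classifier walks 3'-ward from the anchored
motif along the mature sequence and then into the locus' downstream
genomic context, and computes the maximal templated length. Reads are
classified `canonical` (ends exactly at the annotated 3' end),
`trimmed` (templated but shorter), `tailed`, or `trimmed_tailed`
(templated body ends before the annotated end, then non-templated
letters). The 3' extension beyond the annotated end is *ambiguous*
(possibly templated) when it matches the downstream context at **any**
annotated locus, and NT otherwise — the conservative direction, since an
extension explainable by processing should not be credited to an enzyme.

Two decisions were genuinely open and are exposed as configuration:

* **Partially templated extensions** (first base genomic, second not): the
  full extension is taken as the tail and the isomiR is NT, because the
  rule compares the whole extension with the genome; `ntSuffixOnly = TRUE`
  switches to counting only the post-mismatch suffix.
* **Trimmed-then-retailed reads** count toward NT tailing with the
  post-mismatch suffix as their tail.

Tails longer than `maxTailLen` (default 8 nt — observed NT tails are
short, overwhelmingly 1-2 nt) are flagged and excluded from category
statistics; in practice they are almost always sequencing-error artifacts,
since a single internal misread turns the whole remaining suffix into an
apparent tail. Tail categories are `mono_A/C/G/U`, the A/U dinucleotides
`di_AA/di_UU/di_AU/di_UA`, and `mixed`; a coarse 3-way label (`A_tail`,
`U_tail`, `Mixed`) supports length-by-identity summaries.

# Per-condition metrics

Per miRNA and library, `profileCondition()` reports RPM (reads per million
assigned miRNA reads — the only normalization used), end-status fractions,
the NT-tail percentage of reads, nucleotide identity *within* NT tails
(per tail nucleotide, so a `UU` tail contributes two U), mono-NT-tail
percentages per letter, the tail length-by-identity decomposition, the
abundance-weighted mean read length, and the last templated nucleotide.

Cross-miRNA summaries select the top N (default 200) miRNAs by mean RPM
across *all* profiles being compared, so the miRNA set is fixed within a
comparison, then average per-miRNA percentages unweighted with a standard
error over the N miRNAs. Replicates are profiled separately and summarized
as means of replicate values.

# Differential tailing and regulation calls

Fold-changes are computed on replicate-mean RPM with a pseudocount of 0.5
reads in both numerator and denominator; isomiRs below 1 RPM in all
conditions are excluded. Cumulative curves report, per isomiR class
(canonical / ambiguous / NT), the fraction of isomiRs with fold-change at
or below each of 25 log2-spaced thresholds in [1/8, 8]. Heatmap values are
`min(100 * FC, 100)`, rendered "0 to >=100".

Enzyme sensitivity uses the fold-change of the NT mono-U percentage upon
knockout in two independent comparisons; the consensus sensitive set is
the intersection of both top-100 rankings (largest decreases). Terminal
nucleotide preference compares the last templated nucleotide frequencies
of the sensitive set against the expressed background with a two-sided
binomial test per letter — the simplest calibrated test for a
composition-vs-background question.

miRNA-level regulation calls use symmetric log2 fold-change thresholds of
0.2 (inclusive): "negatively regulated by the enzymes" requires
upregulation in every knockout comparison *and* downregulation upon
rescue; the mirrored pattern gives positive regulation. Whether every
rescue or any rescue is required is configurable (`rescueRule`), defaulting
to all. Calls additionally require a mean expression of 10 RPM by default
— lowly expressed miRNAs produce unstable ratios; analyses at modest
depth should raise this floor so that the floor corresponds to at least
~100 reads (the regulation examples in the test-suite use 2000 RPM at
1e5-read depth for exactly this reason).

The package's statistical primitives are deliberately standard: two-sided
Wilcoxon rank tests (`wilcox.test`, normal approximation with continuity
correction), Pearson correlation on log abundances, and raw p-values (an
optional Benjamini-Hochberg column is off by default since the analyses
report raw Wilcoxon p).

# The synthetic-data generator

`simulateReference()` draws mature sequences of 20-23 nt with unique
central motifs (rejection sampling; an error, not a hang, if uniqueness is
unattainable), 1-3 loci each with random 20-nt downstream contexts, and
alternating 5p/3p arms. `simulateLibrary()` then emulates, per read:

* **Expression**: heavy-tailed lognormal weights (sdlog 1.5), shared by
  all conditions and replicates of a design; optional per-condition
  multipliers plant abundance effects for regulation-call testing.
* **End heterogeneity**: 5' trimming of 0/1/2 nt (90/7/3%) and templated
  3' offsets of -2..+2 nt (3/10/77/6/4%), extensions copying the locus
  context — this is what creates ambiguous isomiRs.
* **Tailing**: each enzyme contributes a per-read rate
  `rate x substrateBias(last nt) x sensitivity(miRNA)`; the acting enzyme
  is drawn proportionally and appends letters i.i.d. from its propensity
  (TENT2-like: A 0.85 / G 0.10 / U 0.05; TUT4/TUT7-like: U 1.0) with
  geometric lengths (P(len = 1) = 0.5, capped at 6) — mostly
  mono-nucleotide tails with rare mixed oligo-tails. The TUT4 model
  carries a last-nucleotide substrate bias (G x2, U/C x0.5). Per-miRNA
  sensitivities are lognormal (sdlog 0.4) and shared across conditions,
  which is what makes knockout responses consistent between genetic
  backgrounds.
* **Competition**: when no uridylating enzyme is active but the design
  knows one (a TUT4/7 knockout), the adenylating rates are multiplied by
  `competition` (default 2.4), modelling improved 3'-end access. The
  default is chosen so that total tailing — and hence the weighted mean
  length — is approximately preserved in the double knockout while
  collapsing only in the triple knockout.
* **3p inheritance**: 3p-arm miRNAs get an extra uridylation rate (0.03)
  active only while a uridylating enzyme is, emulating
  precursor-inherited tails without simulating hairpins.
* **Misreads**: position-independent substitutions at 5e-4 per base
  (uniform over the other three letters) plus a dedicated A-to-G channel
  for spike-in studies; quality strings are constant.

Default rates (TENT2 0.085, TUT4 0.085, TUT7 0.02) place the catalog mean
NT-tail probability near 0.18 with U and A dominating tail nucleotides and
G a minor fraction; these defaults are calibration aids describing the
emulated regime, not biological claims, and every one of them is exposed
in `experimentDesign()`.

Ground truth comes in two forms. Each generated read carries its truth
label (end status, tail, origin, acting enzyme) computed by a maximal
templated walk over the miRNA's loci — at misread rate 0 the pipeline
reproduces these labels exactly. Independently, `ntTailProbability()`
computes the *closed-form* per-miRNA probability that a read is NT,
marginalizing analytically over 3' offsets, loci, enzymes, tail lengths
and letters (for a fixed decomposition, exactly one extension string per
length is templated per locus, so the ambiguity mass is a short sum of
letter-propensity products). Parameter-recovery tests compare measured
NT percentages against these probabilities with exact binomial intervals;
they run at misread rate 0 because the misread channel converts a small,
separately quantified fraction of reads into spurious one-base NT tails —
that channel is validated by the spike-in module instead.

## What the simulator does not emulate

Hairpin secondary structure and pre-miRNA processing kinetics, ligation
and PCR bias, UMI structure, position-dependent error profiles,
cross-mapping between near-identical miRNA families, and enzyme kinetics
beyond per-read rates. Passing tests therefore demonstrate that the
pipeline's inference is correct *for data matching its model of the
measurement*; they do not validate library-preparation artifacts in real
data.

# Numerical and determinism choices

All randomness derives from a single design seed through fixed integer
streams (expression, per-enzyme sensitivities, each condition x replicate
library), so simulated experiments are bit-reproducible and sensitivities
are shared across conditions. Collapsed reads order by descending count
then lexicographically; profile and comparison tables sort by miRNA name —
every output is deterministic for a given input. Fraction partitions are
validated to 1e-9. Degenerate inputs (empty classes in curves, zero
spike-in coverage, miRNAs absent from one condition) warn and are omitted
rather than silently imputed.

# Problem sizes used in the checks

The bundled verification uses catalogs of 10-200 miRNAs and libraries of
2e4 to 2e5 reads — sizes at which binomial intervals on per-miRNA
percentages are a few percentage points wide, which is what the recovery
claims require; the same code paths run unchanged on full-scale libraries.
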