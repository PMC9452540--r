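# isotail

IsomiR detection and 3′ non-templated tailing analysis for small-RNA
sequencing.

## What it does, and for whom

Mature miRNAs circulate as clouds of 3′ isoforms (isomiRs): trimmed reads,
templated extensions left by imprecise processing, and non-templated (NT)
tails added by terminal nucleotidyltransferases — adenylation/guanylation
by TENT2-like enzymes, uridylation by TUT4/TUT7-like enzymes. Telling an
enzymatic tail from a processing variant requires comparing each read's 3′
extension with the genomic sequence downstream of **every** annotated
locus of the miRNA. `isotail` is for small-RNA groups who want that
analysis as a tested, reusable R package: from raw reads to
templated/NT classification, per-miRNA tailing metrics, differential
tailing between knockout/rescue conditions, and consensus
miRNA-regulation calls.

The core procedure:

1. **Assign** — collapse reads and anchor each distinct sequence by an
   exact match of the central motif of a mature miRNA (the 13-nt substring
   starting at `floor((L − 13)/2)`, 0-based), leaving the 5′ and 3′ ends
   free to vary.
2. **Classify** — walk 3′-ward along the mature sequence, then into the
   locus' downstream genomic context. The extension beyond the annotated
   3′ end is *ambiguous* (possibly templated) if it matches the context at
   any locus, *NT* otherwise; reads are `canonical`, `trimmed`, `tailed`,
   or `trimmed_tailed`, and tails are `mono_A/C/G/U`, `di_AA/UU/AU/UA`, or
   `mixed`.
3. **Profile** — per miRNA: RPM, end-status fractions, `pct_NT`,
   nucleotide identity within NT tails, mono-tail percentages, the
   abundance-weighted mean read length
   `Σ(lenᵢ·countᵢ)/Σcountᵢ`.
4. **Compare** — isomiR fold-changes (pseudocount 0.5 reads), cumulative
   fold-change curves per isomiR class, capped relative-abundance heatmap
   values, uridylation-sensitivity consensus sets with
   terminal-nucleotide enrichment, Wilcoxon tests and Pearson
   correlations.
5. **Regulate** — miRNA-level consensus calls: |log2 FC| ≥ 0.2 up in every
   knockout *and* down upon rescue (and mirrored), above an expression
   floor.

A fully seeded synthetic-data generator (enzyme models with substrate
bias, per-miRNA sensitivities, competition, misread channels including
A→G) provides ground truth for every stage, including a closed-form
per-miRNA NT-tail probability.

## Worked example

```r
library(isotail)

catalog <- simulateReference(50, seed = 7)
design  <- experimentDesign(
  conditions = list(WT = c("TENT2", "TUT4", "TUT7"), DKO = "TENT2"),
  replicates = 2, depth = 50000, seed = 7)
libs <- simulateExperiment(catalog, design)

profiles <- lapply(names(libs), function(id) {
  asg <- assignLibrary(libs[[id]]$reads, catalog, verbose = FALSE)
  cls <- classifyTable(asg, catalog)
  profileCondition(cls, catalog, libs[[id]]$condition,
                   paste0("rep", libs[[id]]$replicate))
})
topNSummary(profiles, N = 50, metric = "pct_NT")
#>   condition replicate arm metric mean   se  n
#> 1        WT      rep1 all pct_NT 17.8 1.12 50
#> 2        WT      rep2 all pct_NT 18.2 1.25 50
#> 3       DKO      rep1 all pct_NT 19.3 1.35 50
#> 4       DKO      rep2 all pct_NT 18.3 1.29 50
```

About 18% of WT reads carry an NT tail (mean ± SE across the top
miRNAs). Losing both uridylating enzymes does not reduce overall tailing
— the adenylating enzyme, freed from competition, compensates — but it
transforms its composition:

```r
cls <- lapply(libs, function(l)
  classifyTable(assignLibrary(l$reads, catalog, verbose = FALSE), catalog))
cmp <- compareConditions(list(cls$WT_rep1,  cls$WT_rep2),
                         list(cls$DKO_rep1, cls$DKO_rep2),
                         conditions = c("WT", "DKO"))
cmp
#> ComparisonResult: WT vs DKO — 6005 isomiRs, 50 miRNAs
m <- mirnaFoldChanges(cmp)
median(m$fc_pct_U)   # 0.144 — mono-uridylation collapses in the DKO
median(m$fc_pct_A)   # 2.265 — mono-adenylation roughly doubles
```

`tailingCurves(cmp)` gives the cumulative fold-change curves by isomiR
class (canonical / ambiguous / NT), `sensitivityRanking()` intersects two
knockout comparisons into a consensus enzyme-sensitive miRNA set, and
`regulationCalls()` turns per-comparison log2 fold-changes into consensus
regulation calls. `runPipeline(pipelineConfig(...))` orchestrates all
stages from one validated config and `writeReport()` writes the TSV
bundle.

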