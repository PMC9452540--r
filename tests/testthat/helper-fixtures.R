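# Deterministic in-code fixtures shared across test files.

# Two-miRNA toy catalog with hand-chosen downstream contexts.
toy_catalog <- function(motifLen = 13L, maxTailLen = 8L) {
  mature <- c(
    mirX = "AGCUUCGAUGGACUCAGGCUAC",   # 22 nt
    mirY = "GGCAUUCAGGACUUAACGGGUU"    # 22 nt, two loci
  )
  loci <- data.frame(
    name = c("mirX", "mirY", "mirY"),
    locus_id = c("L1", "L1", "L2"),
    downstream = c("AAGGAAGGAAGGAAGGAAGG",
                   "AGGCCAUUGGCCAUUGGCCA",
                   "UGGCCAUUGGCCAUUGGCCA"),
    stringsAsFactors = FALSE
  )
  referenceCatalog(mature, loci, motifLen = motifLen,
                   maxTailLen = maxTailLen)
}

# Minimal classified table built by hand (already-classified isomiRs).
toy_classified <- function() {
  data.frame(
    mirna = c("mirA", "mirA", "mirB", "mirB", "mirB"),
    sequence = c(strrep("A", 22), paste0(strrep("A", 22), "U"),
                 strrep("C", 22), paste0(strrep("C", 22), "UU"),
                 paste0(strrep("C", 22), "A")),
    count = c(80L, 20L, 60L, 20L, 20L),
    end_status = c("canonical", "tailed", "canonical", "tailed", "tailed"),
    three_prime_offset = c(0L, 0L, 0L, 0L, 0L),
    templated_len = 22L,
    tail_seq = c("", "U", "", "UU", "A"),
    origin = c("none", "NT", "none", "NT", "NT"),
    category = c("none", "mono_U", "none", "di_UU", "mono_A"),
    coarse_label = c("none", "U_tail", "none", "U_tail", "A_tail"),
    tail_flagged = FALSE,
    stringsAsFactors = FALSE
  )
}

write_toy_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}
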