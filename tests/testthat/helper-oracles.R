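# Brute-force oracles, kept deliberately naive (character-by-character
# loops, exhaustive enumeration) and independent of the package's
# vectorised code paths.

# All (mirna, offset) pairs whose central motif occurs exactly in the read.
brute_assign <- function(read, catalog) {
  ml <- motifLength(catalog)
  hits <- list()
  for (nm in mirnaNames(catalog)) {
    mat <- matureSeqs(catalog)[[nm]]
    s0 <- (nchar(mat) - ml) %/% 2L
    motif <- substr(mat, s0 + 1L, s0 + ml)
    if (nchar(read) < ml) next
    for (off in 0:(nchar(read) - ml)) {
      if (substr(read, off + 1L, off + ml) == motif)
        hits[[length(hits) + 1L]] <- list(mirna = nm, offset = off)
    }
  }
  hits
}

# Enumerates every (locus, split point) decomposition of the read's 3' part
# and classifies by the longest templated walk; mirrors the written rule,
# not the implementation.
brute_classify <- function(read, mirna, catalog, motif_start = NULL) {
  ml <- motifLength(catalog)
  mat <- matureSeqs(catalog)[[mirna]]
  m0 <- (nchar(mat) - ml) %/% 2L
  motif <- substr(mat, m0 + 1L, m0 + ml)
  if (is.null(motif_start))
    motif_start <- regexpr(motif, read, fixed = TRUE)[1] - 1L
  stopifnot(motif_start >= 0L)
  rest <- strsplit(substr(read, motif_start + ml + 1L, nchar(read)),
                   "")[[1]]
  body <- strsplit(substr(mat, m0 + ml + 1L, nchar(mat)), "")[[1]]
  loci <- lociTable(catalog)
  downs <- loci$downstream[loci$name == mirna]
  best <- 0L
  fully <- FALSE
  for (d in downs) {
    tmpl <- c(body, strsplit(d, "")[[1]])
    t <- 0L
    while (t < length(rest) && t < length(tmpl) &&
           rest[t + 1L] == tmpl[t + 1L]) t <- t + 1L
    best <- max(best, t)
    if (t == length(rest)) fully <- TRUE
  }
  blen <- length(body)
  off <- length(rest) - blen
  if (fully) {
    if (off == 0L) list(end_status = "canonical", tail = "",
                        origin = "none")
    else if (off < 0L) list(end_status = "trimmed", tail = "",
                            origin = "none")
    else list(end_status = "tailed",
              tail = paste(rest[(blen + 1L):length(rest)], collapse = ""),
              origin = "ambiguous")
  } else if (best >= blen) {
    list(end_status = "tailed",
         tail = paste(rest[(blen + 1L):length(rest)], collapse = ""),
         origin = "NT")
  } else {
    list(end_status = "trimmed_tailed",
         tail = paste(rest[(best + 1L):length(rest)], collapse = ""),
         origin = "NT")
  }
}

# Random 3'-end variants of catalog miRNAs: trims, templated extensions and
# random tails in all combinations.
random_isomir_reads <- function(catalog, n, seed) {
  set.seed(seed)
  nms <- mirnaNames(catalog)
  loci <- lociTable(catalog)
  reads <- character(n)
  mirna <- character(n)
  for (i in seq_len(n)) {
    nm <- sample(nms, 1L)
    mat <- matureSeqs(catalog)[[nm]]
    downs <- loci$downstream[loci$name == nm]
    d <- sample(downs, 1L)
    off5 <- sample(0:2, 1L)
    trim3 <- sample(0:3, 1L, prob = c(.5, .25, .15, .1))
    ext3 <- if (trim3 == 0L) sample(0:2, 1L, prob = c(.6, .25, .15)) else 0L
    tail_len <- sample(0:4, 1L, prob = c(.35, .3, .15, .1, .1))
    tail <- paste(sample(c("A", "C", "G", "U"), tail_len, TRUE),
                  collapse = "")
    reads[i] <- paste0(substr(mat, off5 + 1L, nchar(mat) - trim3),
                       substr(d, 1L, ext3), tail)
    mirna[i] <- nm
  }
  data.frame(mirna = mirna, sequence = reads, stringsAsFactors = FALSE)
}
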