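#' Fine and coarse tail categories
#'
#' Length-1 tails are `mono_A`/`mono_C`/`mono_G`/`mono_U`; length-2
#' homogeneous or alternating A/U tails are `di_AA`/`di_UU`/`di_AU`/`di_UA`;
#' everything else is `mixed`. The coarse 3-way label used in
#' length-by-identity summaries is `A_tail` (all A), `U_tail` (all U), or
#' `Mixed` (heterogeneous tails and other nucleotides).
#'
#' @param tail_seq character vector of non-empty tail sequences.
#' @return character vector of categories.
#' @examples
#' tailCategory(c("U", "AU", "UUU", "GC"))
#' coarseTailLabel(c("U", "UUU", "AU"))
#' @export
tailCategory <- function(tail_seq) {
  if (any(!nzchar(tail_seq))) stop("empty tail", call. = FALSE)
  tail_seq <- as_rna(tail_seq)
  len <- nchar(tail_seq)
  out <- rep("mixed", length(tail_seq))
  out[len == 1L] <- paste0("mono_", tail_seq[len == 1L])
  di <- len == 2L & tail_seq %in% c("AA", "UU", "AU", "UA")
  out[di] <- paste0("di_", tail_seq[di])
  out
}

#' @rdname tailCategory
#' @export
coarseTailLabel <- function(tail_seq) {
  if (any(!nzchar(tail_seq))) stop("empty tail", call. = FALSE)
  tail_seq <- as_rna(tail_seq)
  ifelse(!grepl("[^A]", tail_seq), "A_tail",
         ifelse(!grepl("[^U]", tail_seq), "U_tail", "Mixed"))
}

#' Decompose a read into templated body and non-templated suffix
#'
#' Walks 3'-ward from the anchored motif along the mature sequence and then
#' the locus' downstream genomic context; the templated length is the
#' maximal match and the tail is the remaining read suffix (first mismatch
#' onward). A 3' extension that continues the genome exactly is fully
#' templated and leaves an empty suffix.
#'
#' @param read_seq the read sequence.
#' @param mirna miRNA name in `catalog`.
#' @param locus_id locus to walk into.
#' @param catalog a [ReferenceCatalog-class].
#' @param anchor 0-based offset of the miRNA's motif in the read; located
#'   automatically when `NULL`.
#' @return list with `templated_len` (nt of the read matching the reference
#'   from the motif start onward, motif included) and `tail_seq`.
#' @export
splitTemplated <- function(read_seq, mirna, locus_id, catalog, anchor = NULL) {
  read_seq <- as_rna(read_seq)
  mature <- catalog@mature[[mirna]]
  motif <- catalog@motifs[[mirna]]
  if (is.null(anchor))
    anchor <- best_anchor(read_seq, mature, motif, catalog@motifLen)$offset
  if (is.na(anchor) || anchor < 0L ||
      substr(read_seq, anchor + 1L, anchor + catalog@motifLen) != motif)
    stop("anchor inconsistent with read", call. = FALSE)
  loci <- catalog@loci
  down <- loci$downstream[loci$name == mirna & loci$locus_id == locus_id]
  if (length(down) != 1L) stop("unknown locus: ", locus_id, call. = FALSE)
  m0 <- (nchar(mature) - catalog@motifLen) %/% 2L
  read_after <- substr(read_seq, anchor + catalog@motifLen + 1L,
                       nchar(read_seq))
  template <- paste0(substr(mature, m0 + catalog@motifLen + 1L,
                            nchar(mature)), down)
  match_len <- common_prefix_len(read_after, template)
  list(
    templated_len = catalog@motifLen + match_len,
    tail_seq = substr(read_after, match_len + 1L, nchar(read_after))
  )
}

# Vectorised 3'-end classification of anchored reads. `df` needs columns
# sequence, mirna, motif_start. Walks every locus of the assigned miRNA and
# applies the any-locus rule: the isomiR is "ambiguous" (templated origin)
# if its full 3' extension beyond the annotated end matches the downstream
# genomic context at ANY locus, NT otherwise.
classify_core <- function(df, catalog, ntSuffixOnly = FALSE) {
  n <- nrow(df)
  motifLen <- catalog@motifLen
  mature <- catalog@mature[df$mirna]
  L <- nchar(mature)
  m0 <- (L - motifLen) %/% 2L
  read_after <- substr(df$sequence, df$motif_start + motifLen + 1L,
                       nchar(df$sequence))
  mature_after <- substr(mature, m0 + motifLen + 1L, L)
  body_after <- nchar(mature_after)

  # expand read rows over loci of their miRNA
  loci_by_mirna <- split(catalog@loci$downstream, catalog@loci$name)
  nloc <- lengths(loci_by_mirna)[df$mirna]
  rid <- rep.int(seq_len(n), nloc)
  down <- unlist(loci_by_mirna[df$mirna], use.names = FALSE)
  match_len_l <- common_prefix_len(read_after[rid],
                                   paste0(mature_after[rid], down))
  fully_l <- match_len_l == nchar(read_after)[rid]
  any_fully <- as.logical(rowsum(as.integer(fully_l), rid) > 0L)
  max_match <- unname(vapply(split(match_len_l, rid), max, integer(1)))

  ra_len <- nchar(read_after)
  ext <- ifelse(ra_len > body_after,
                substr(read_after, body_after + 1L, ra_len), "")

  end_status <- character(n)
  tail_seq <- character(n)
  origin <- character(n)
  offset <- integer(n)

  fully <- any_fully
  off_f <- ra_len - body_after
  end_status[fully & off_f == 0L] <- "canonical"
  end_status[fully & off_f < 0L] <- "trimmed"
  end_status[fully & off_f > 0L] <- "tailed"
  tail_seq[fully] <- ifelse(off_f[fully] > 0L, ext[fully], "")
  origin[fully] <- ifelse(off_f[fully] > 0L, "ambiguous", "none")
  offset[fully] <- off_f[fully]

  nt <- !fully
  reach <- nt & max_match >= body_after
  short <- nt & max_match < body_after
  end_status[reach] <- "tailed"
  end_status[short] <- "trimmed_tailed"
  origin[nt] <- "NT"
  offset[nt] <- max_match[nt] - body_after[nt]
  tail_seq[reach] <- ext[reach]
  tail_seq[short] <- substr(read_after[short], max_match[short] + 1L,
                            ra_len[short])
  if (ntSuffixOnly) {
    # alternative accounting: only the post-mismatch suffix counts as the
    # NT tail of a partially templated extension
    tail_seq[reach] <- substr(read_after[reach], max_match[reach] + 1L,
                              ra_len[reach])
  }

  has_tail <- nzchar(tail_seq)
  category <- rep("none", n)
  category[has_tail] <- tailCategory(tail_seq[has_tail])
  coarse <- rep("none", n)
  coarse[has_tail] <- coarseTailLabel(tail_seq[has_tail])
  flagged <- nchar(tail_seq) > catalog@maxTailLen

  data.frame(
    mirna = df$mirna, sequence = df$sequence,
    count = if ("count" %in% names(df)) df$count else rep(1L, n),
    end_status = end_status, three_prime_offset = offset,
    templated_len = motifLen + max_match, tail_seq = tail_seq,
    origin = origin, category = category, coarse_label = coarse,
    tail_flagged = flagged, stringsAsFactors = FALSE
  )
}

#' Classify the 3' end of one assigned isomiR
#'
#' Computes the read's 3' extension beyond the annotated mature end and
#' classifies the isomiR as `canonical`, `trimmed`, `tailed` or
#' `trimmed_tailed`, with a templated (`ambiguous`) or non-templated (`NT`)
#' origin for the tail. An extension matching the downstream genomic context
#' at any annotated locus is templated; everything else — including
#' partially templated extensions, whose full extension is taken as the
#' tail — is NT.
#'
#' @param read_seq the read sequence.
#' @param mirna miRNA name in `catalog`.
#' @param catalog a [ReferenceCatalog-class].
#' @param motif_start 0-based motif offset in the read (located if `NULL`).
#' @param ntSuffixOnly if TRUE, only the post-mismatch suffix of a partially
#'   templated extension is reported as the tail (default FALSE).
#' @return one-row data.frame with columns `mirna`, `sequence`, `count`,
#'   `end_status`, `three_prime_offset`, `templated_len`, `tail_seq`,
#'   `origin`, `category`, `coarse_label`, `tail_flagged`.
#' @export
classifyIsomir <- function(read_seq, mirna, catalog, motif_start = NULL,
                           ntSuffixOnly = FALSE) {
  read_seq <- as_rna(read_seq)
  if (is.null(motif_start)) {
    motif_start <- best_anchor(read_seq, catalog@mature[[mirna]],
                               catalog@motifs[[mirna]],
                               catalog@motifLen)$offset
    if (is.na(motif_start))
      stop("motif of ", mirna, " does not occur in the read", call. = FALSE)
  }
  classify_core(data.frame(sequence = read_seq, mirna = mirna,
                           motif_start = motif_start,
                           stringsAsFactors = FALSE),
                catalog, ntSuffixOnly = ntSuffixOnly)
}

#' Classify every isomiR of an assigned library
#'
#' @param assigned data.frame from [assignLibrary()] (columns `mirna`,
#'   `sequence`, `count`, `motif_start`).
#' @param catalog a [ReferenceCatalog-class].
#' @inheritParams classifyIsomir
#' @return data.frame with one row per isomiR (see [classifyIsomir()]);
#'   the `"stats"` attribute of the input is carried through.
#' @export
classifyTable <- function(assigned, catalog, ntSuffixOnly = FALSE) {
  stopifnot(all(c("mirna", "sequence", "motif_start") %in% names(assigned)))
  if (nrow(assigned) == 0L)
    stop("empty isomiR table", call. = FALSE)
  out <- classify_core(assigned, catalog, ntSuffixOnly = ntSuffixOnly)
  attr(out, "stats") <- attr(assigned, "stats")
  out
}
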