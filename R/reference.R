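#' Extract the central assignment motif of a mature sequence
#'
#' The motif is the `motifLen`-nt substring starting at 0-based position
#' `floor((L - motifLen) / 2)` of the mature sequence — the region of a read
#' that must match exactly for assignment, leaving both ends free to vary.
#'
#' @param sequence mature miRNA sequence(s), RNA or DNA alphabet.
#' @param motifLen motif length in nt (default 13).
#' @return character vector of motifs (RNA alphabet).
#' @examples
#' motifOf("ACGUACGUACGUACGUACGUAC", 13)
#' @export
motifOf <- function(sequence, motifLen = 13L) {
  sequence <- as_rna(sequence)
  L <- nchar(sequence)
  if (any(motifLen > L))
    stop("motifLen exceeds a mature sequence length", call. = FALSE)
  start0 <- (L - motifLen) %/% 2L
  substr(sequence, start0 + 1L, start0 + motifLen)
}

parse_arm <- function(name) {
  ifelse(grepl("-5p$", name), "5p", ifelse(grepl("-3p$", name), "3p",
                                           "unknown"))
}

#' Construct a ReferenceCatalog from in-memory components
#'
#' Lower-level constructor used by [loadReference()] and
#' [simulateReference()]. Sequences may be in DNA alphabet; they are
#' converted to RNA.
#'
#' @param mature named character vector of mature sequences.
#' @param loci data.frame with columns `name`, `locus_id`, `downstream`.
#' @param motifLen central motif length (default 13).
#' @param maxTailLen maximum 3' extension treated as a tail (default 8);
#'   every downstream context must be at least this long.
#' @return a validated [ReferenceCatalog-class] object.
#' @export
referenceCatalog <- function(mature, loci, motifLen = 13L, maxTailLen = 8L) {
  if (is.null(names(mature)) || any(names(mature) == ""))
    stop("mature sequences must be named", call. = FALSE)
  mature <- setNames(as_rna(mature), names(mature))
  check_rna_alphabet(mature, "mature sequence")
  loci <- data.frame(
    name = as.character(loci$name),
    locus_id = as.character(loci$locus_id),
    downstream = as_rna(as.character(loci$downstream)),
    stringsAsFactors = FALSE
  )
  check_rna_alphabet(loci$downstream, "downstream context")
  obj <- new("ReferenceCatalog",
    mature = mature,
    arm = setNames(parse_arm(names(mature)), names(mature)),
    loci = loci,
    motifs = setNames(motifOf(mature, motifLen), names(mature)),
    motifLen = as.integer(motifLen),
    maxTailLen = as.integer(maxTailLen)
  )
  validObject(obj)
  obj
}

#' Load a miRNA reference from a mature FASTA and a context table
#'
#' Reads mature miRNA sequences (miRBase-style FASTA; the first whitespace
#' token of each header is the name; T is accepted and converted to U) and a
#' tab-delimited context table with columns `name`, `locus_id`, `downstream`
#' giving, for every genomic locus of each mature miRNA, the genomic
#' sequence immediately 3' of the annotated mature end. Paralogous loci with
#' identical mature sequence are one catalog entry with several locus rows.
#'
#' @param matureFasta path to the mature miRNA FASTA.
#' @param contextTable path to the TSV context table (or a data.frame).
#' @inheritParams referenceCatalog
#' @return a [ReferenceCatalog-class].
#' @export
loadReference <- function(matureFasta, contextTable,
                          motifLen = 13L, maxTailLen = 8L) {
  if (!file.exists(matureFasta))
    stop("mature FASTA not found: ", matureFasta, call. = FALSE)
  fa <- Biostrings::readBStringSet(matureFasta)
  nm <- sub("\\s.*$", "", names(fa))
  mature <- setNames(as.character(fa), nm)
  if (is.data.frame(contextTable)) {
    ctx <- contextTable
  } else {
    if (!file.exists(contextTable))
      stop("context table not found: ", contextTable, call. = FALSE)
    ctx <- read.delim(contextTable, stringsAsFactors = FALSE)
  }
  missing_ctx <- setdiff(nm, ctx$name)
  if (length(missing_ctx))
    stop("miRNAs lacking context rows: ",
         paste(head(missing_ctx, 5L), collapse = ", "), call. = FALSE)
  ctx <- ctx[ctx$name %in% nm, , drop = FALSE]
  referenceCatalog(mature, ctx, motifLen = motifLen, maxTailLen = maxTailLen)
}

#' Write a catalog's context table to TSV
#'
#' @param catalog a [ReferenceCatalog-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeContextTable <- function(catalog, file) {
  write.table(lociTable(catalog), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Build a downstream-context table from a genome FASTA and a GFF3
#'
#' For each miRNA feature, emits the `k` genomic nucleotides immediately 3'
#' of the feature end (reverse-complemented on the minus strand). GFF3
#' coordinates are 1-based inclusive; a plus-strand feature ending at `p` on
#' contig `S` yields `S[p+1 .. p+k]`, a minus-strand feature starting at `p`
#' yields the reverse complement of `S[p-k .. p-1]`.
#'
#' @param genomeFasta path to the genome FASTA.
#' @param gff3 path to a GFF3 with miRNA features; feature names are taken
#'   from the `Name` (falling back to `ID`) attribute.
#' @param k context length in nt (default 20). Catalogs require the context
#'   to cover the maximum tail length (default 8), enforced on load.
#' @param featureType GFF3 type(s) to use (default `"miRNA"`).
#' @return data.frame with columns `name`, `locus_id`, `downstream`
#'   (RNA alphabet), suitable for [loadReference()].
#' @export
buildContextTable <- function(genomeFasta, gff3, k = 20L,
                              featureType = "miRNA") {
  stopifnot(k >= 1L)
  genome <- Biostrings::readDNAStringSet(genomeFasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff3)
  gr <- gr[as.character(gr$type) %in% featureType]
  if (length(gr) == 0L)
    stop("no features of type ", paste(featureType, collapse = "/"),
         " in GFF3", call. = FALSE)
  nm <- as.character(gr$Name %||% gr$ID)
  if (all(is.na(nm))) nm <- as.character(gr$ID)
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  st <- BiocGenerics::start(gr)
  en <- BiocGenerics::end(gr)
  down <- character(length(gr))
  for (i in seq_along(gr)) {
    if (!chr[i] %in% names(genome))
      stop("contig not in genome FASTA: ", chr[i], call. = FALSE)
    contig <- genome[[chr[i]]]
    if (strand[i] == "+") {
      if (en[i] + k > length(contig))
        stop("feature ", nm[i], " runs past the contig end", call. = FALSE)
      down[i] <- as.character(Biostrings::subseq(contig, en[i] + 1L,
                                                 en[i] + k))
    } else if (strand[i] == "-") {
      if (st[i] - k < 1L)
        stop("feature ", nm[i], " runs past the contig start", call. = FALSE)
      down[i] <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(contig, st[i] - k, st[i] - 1L)))
    } else {
      stop("unknown strand for feature ", nm[i], call. = FALSE)
    }
  }
  locus_id <- sprintf("%s:%d-%d:%s", chr, st, en, strand)
  data.frame(name = nm, locus_id = locus_id, downstream = as_rna(down),
             stringsAsFactors = FALSE)
}
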