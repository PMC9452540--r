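#' ReferenceCatalog: an indexed mature-miRNA reference
#'
#' Holds mature miRNA sequences (RNA alphabet), the arm each derives from,
#' the genomic sequence immediately downstream (3') of the annotated mature
#' end at every annotated locus, and the central-motif index used for read
#' assignment. Build one with [loadReference()] or [simulateReference()].
#'
#' @slot mature named character vector of mature sequences (RNA alphabet).
#' @slot arm named character vector, one of `"5p"`, `"3p"`, `"unknown"`,
#'   parsed from the name suffix.
#' @slot loci data.frame with columns `name`, `locus_id`, `downstream`; one
#'   row per genomic locus, `downstream` is the genomic sequence 3' of the
#'   annotated mature end (RNA alphabet, length >= `maxTailLen`).
#' @slot motifs named character vector: each miRNA's central motif, the
#'   substring of length `motifLen` starting at 0-based position
#'   `floor((L - motifLen) / 2)` of the mature sequence.
#' @slot motifLen integer, motif length (default 13).
#' @slot maxTailLen integer, longest 3' extension considered a tail
#'   (default 8); extensions beyond it are flagged.
#'
#' @seealso [mirnaNames()], [matureSeqs()], [lociTable()], [motifIndex()]
#' @export
setClass("ReferenceCatalog",
  representation(
    mature = "character",
    arm = "character",
    loci = "data.frame",
    motifs = "character",
    motifLen = "integer",
    maxTailLen = "integer"
  )
)

setValidity("ReferenceCatalog", function(object) {
  msg <- character()
  nm <- names(object@mature)
  if (length(object@mature) == 0L) msg <- c(msg, "catalog is empty")
  if (anyDuplicated(nm)) msg <- c(msg, "duplicate miRNA names")
  if (any(grepl("[^ACGU]", object@mature)))
    msg <- c(msg, "mature sequences must use the RNA alphabet (ACGU)")
  L <- nchar(object@mature)
  if (any(L < 16L | L > 30L))
    msg <- c(msg, "mature sequence lengths must be in [16, 30]")
  if (length(object@motifLen) != 1L || object@motifLen < 1L)
    msg <- c(msg, "motifLen must be a positive integer")
  else if (length(L) && object@motifLen > min(L))
    msg <- c(msg, "motifLen exceeds the shortest mature sequence")
  if (!identical(names(object@motifs), nm) ||
      !identical(names(object@arm), nm))
    msg <- c(msg, "motifs/arm must be named like mature")
  if (!all(c("name", "locus_id", "downstream") %in% names(object@loci)))
    msg <- c(msg, "loci needs columns name, locus_id, downstream")
  else {
    if (!all(nm %in% object@loci$name))
      msg <- c(msg, "every miRNA needs at least one locus context row")
    if (!all(object@loci$name %in% nm))
      msg <- c(msg, "loci rows refer to unknown miRNAs")
    if (anyDuplicated(object@loci[c("name", "locus_id")]))
      msg <- c(msg, "duplicate (name, locus_id) context rows")
    if (any(grepl("[^ACGU]", object@loci$downstream)))
      msg <- c(msg, "downstream contexts must use the RNA alphabet")
    if (any(nchar(object@loci$downstream) < object@maxTailLen))
      msg <- c(msg, sprintf(
        "every downstream context must be >= maxTailLen (%d) nt",
        object@maxTailLen))
  }
  if (length(msg)) msg else TRUE
})

#' ConditionProfile: per-condition, per-miRNA tailing metrics
#'
#' Produced by [profileCondition()] from a classified isomiR table. The
#' `metrics` table has one row per miRNA with normalized abundance (RPM over
#' assigned miRNA reads), 3'-end composition fractions, NT-tail percentage,
#' nucleotide identity within NT tails, mono-NT-tail percentages per letter,
#' the abundance-weighted mean read length, and the last templated
#' (annotated) 3' nucleotide. `lenIdentity` holds the tail length-by-identity
#' decomposition in long form.
#'
#' @slot condition,replicate character scalars identifying the library.
#' @slot metrics data.frame, one row per miRNA (see [mirnaMetrics()]).
#' @slot lenIdentity data.frame with columns `mirna`, `tail_len`, `label`
#'   (`A_tail`/`U_tail`/`Mixed`), `pct` (percent of the miRNA's reads).
#' @slot totalAssigned numeric, total assigned read count in the library.
#' @export
setClass("ConditionProfile",
  representation(
    condition = "character",
    replicate = "character",
    metrics = "data.frame",
    lenIdentity = "data.frame",
    totalAssigned = "numeric"
  )
)

setValidity("ConditionProfile", function(object) {
  m <- object@metrics
  msg <- character()
  need <- c("mirna", "rpm", "frac_canonical", "frac_trimmed", "frac_tailed",
            "frac_trimmed_tailed", "pct_NT", "weighted_len",
            "last_templated_nt")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("metrics missing columns:",
                        paste(setdiff(need, names(m)), collapse = ", ")))
  else if (nrow(m)) {
    fr <- m$frac_canonical + m$frac_trimmed + m$frac_tailed +
      m$frac_trimmed_tailed
    if (any(abs(fr - 1) > 1e-9))
      msg <- c(msg, "end-status fractions must sum to 1 per miRNA")
    if (abs(sum(m$rpm) - 1e6) > 1e-3)
      msg <- c(msg, "RPM must sum to 1e6 over miRNAs")
  }
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: tailing comparison between two conditions
#'
#' Produced by [compareConditions()]. Fold-changes are B over A on
#' pseudocounted replicate-mean RPM.
#'
#' @slot pair character(2): the (A, B) condition names.
#' @slot isomirFC data.frame per isomiR: `mirna`, `sequence`, `class`
#'   (canonical/ambiguous/NT), `rpm_A`, `rpm_B`, `fc`, `heat` (relative
#'   abundance `100 * fc` capped at `cap`).
#' @slot mirnaFC data.frame per miRNA: NT-tail percentage fold-changes by
#'   nucleotide (`fc_pct_U`, `fc_pct_A`, ...) and abundance `log2_fc`.
#' @slot curves data.frame: cumulative fold-change curves per isomiR class
#'   (`class`, `edge`, `frac`).
#' @slot cap numeric heatmap cap (rendered as ">=cap"; default 100).
#' @export
setClass("ComparisonResult",
  representation(
    pair = "character",
    isomirFC = "data.frame",
    mirnaFC = "data.frame",
    curves = "data.frame",
    cap = "numeric"
  )
)

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (length(object@pair) != 2L) msg <- c(msg, "pair must have length 2")
  if (nrow(object@isomirFC) && any(object@isomirFC$heat > object@cap + 1e-9))
    msg <- c(msg, "heatmap values must not exceed the cap")
  cv <- object@curves
  if (nrow(cv)) {
    for (cl in unique(cv$class)) {
      f <- cv$frac[cv$class == cl][order(cv$edge[cv$class == cl])]
      if (any(diff(f) < -1e-12))
        msg <- c(msg, "cumulative curves must be non-decreasing")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferenceCatalog compact display
#' @param object a `ReferenceCatalog`
#' @export
setMethod("show", "ReferenceCatalog", function(object) {
  cat(sprintf(
    "ReferenceCatalog: %d miRNAs (%d 5p / %d 3p), %d loci\n",
    length(object@mature), sum(object@arm == "5p"),
    sum(object@arm == "3p"), nrow(object@loci)))
  cat(sprintf("  motif length %d nt (central), max tail length %d nt\n",
              object@motifLen, object@maxTailLen))
  cat(sprintf("  %d distinct central motifs\n",
              length(unique(object@motifs))))
})

#' @describeIn ConditionProfile compact display
#' @param object a `ConditionProfile`
#' @export
setMethod("show", "ConditionProfile", function(object) {
  cat(sprintf(
    "ConditionProfile: %s / %s — %d miRNAs, %s assigned reads\n",
    object@condition, object@replicate, nrow(object@metrics),
    format(object@totalAssigned, big.mark = ",")))
  if (nrow(object@metrics))
    cat(sprintf("  mean NT-tail %%: %.2f\n", mean(object@metrics$pct_NT)))
})

#' @describeIn ComparisonResult compact display
#' @param object a `ComparisonResult`
#' @export
setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult: %s vs %s — %d isomiRs, %d miRNAs\n",
              object@pair[1], object@pair[2], nrow(object@isomirFC),
              nrow(object@mirnaFC)))
})
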