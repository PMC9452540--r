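#' Read a small-RNA library from FASTA/FASTQ
#'
#' Accepts FASTQ (qualities ignored), plain FASTA, or the collapsed-FASTA
#' dialect whose headers end in `_xCOUNT` (e.g. `seq1_x152`), optionally
#' gzip-compressed. Returns collapsed reads.
#'
#' @param path input file.
#' @return data.frame with columns `sequence` (RNA alphabet) and `count`,
#'   ordered by descending count then lexicographically.
#' @export
readSmallRNA <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  first <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path, n = 1L)
  if (length(first) == 0L)
    return(data.frame(sequence = character(), count = integer()))
  if (startsWith(first, "@")) {
    ss <- Biostrings::readBStringSet(path, format = "fastq")
    counts <- rep.int(1L, length(ss))
  } else {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    m <- regmatches(names(ss), regexpr("_x(\\d+)$", names(ss)))
    if (length(ss) && length(m) == length(ss)) {
      counts <- as.integer(sub("_x", "", m))
    } else {
      counts <- rep.int(1L, length(ss))
    }
  }
  seqs <- as_rna(as.character(ss))
  agg <- rowsum(counts, seqs)
  out <- data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]))
  out[order(-out$count, out$sequence), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Collapse identical reads into (sequence, count) pairs
#'
#' @param reads character vector of adapter-trimmed read sequences.
#' @return data.frame with columns `sequence` and `count`, ordered by
#'   descending count, ties broken lexicographically (deterministic).
#' @examples
#' collapseReads(c("AAA", "AAA", "CCC"))
#' @export
collapseReads <- function(reads) {
  if (length(reads) == 0L)
    return(data.frame(sequence = character(), count = integer()))
  reads <- as_rna(reads)
  agg <- rowsum(rep.int(1L, length(reads)), reads)
  out <- data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]))
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Core assignment over a vector of distinct sequences. Returns a data.frame
# (sequence, mirna, motif_start, status) where motif_start is the 0-based
# offset of the assigned miRNA's motif in the read and status is one of
# assigned / unassigned / ambiguous.
assign_sequences <- function(seqs, catalog) {
  n <- length(seqs)
  mirna <- rep(NA_character_, n)
  motif_start <- rep(NA_integer_, n)
  status <- rep("unassigned", n)
  if (n == 0L)
    return(data.frame(sequence = character(), mirna = character(),
                      motif_start = integer(), status = character()))
  motifs <- catalog@motifs
  umot <- unique(motifs)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(as_dna(umot)))
  hits <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(as_dna(seqs)))
  nhit_mirnas <- lapply(hits, function(h) {
    if (length(h) == 0L) character() else names(motifs)[motifs %in% umot[h]]
  })
  ncand <- lengths(nhit_mirnas)

  single <- which(ncand == 1L)
  if (length(single)) {
    mirna[single] <- unlist(nhit_mirnas[single], use.names = FALSE)
    status[single] <- "assigned"
  }
  multi <- which(ncand > 1L)
  for (i in multi) {
    cand <- nhit_mirnas[[i]]
    mm <- vapply(cand, function(nm) {
      best_anchor(seqs[i], catalog@mature[[nm]], motifs[[nm]],
                  catalog@motifLen)$mismatches
    }, numeric(1))
    best <- which(mm == min(mm))
    if (length(best) == 1L) {
      mirna[i] <- cand[best]
      status[i] <- "assigned"
    } else {
      status[i] <- "ambiguous"
    }
  }
  # anchor every assigned read at its best motif occurrence; the single-
  # occurrence case (the overwhelming majority) stays fully vectorised
  asg <- which(status == "assigned")
  if (length(asg)) {
    for (nm in unique(mirna[asg])) {
      idx <- asg[mirna[asg] == nm]
      mo <- motifs[[nm]]
      first <- as.integer(regexpr(mo, seqs[idx], fixed = TRUE)) - 1L
      again <- grepl(mo, substr(seqs[idx], first + 2L, nchar(seqs[idx])),
                     fixed = TRUE)
      motif_start[idx[!again]] <- first[!again]
      for (i in idx[again])
        motif_start[i] <- best_anchor(seqs[i], catalog@mature[[nm]], mo,
                                      catalog@motifLen)$offset
    }
  }
  data.frame(sequence = seqs, mirna = mirna, motif_start = motif_start,
             status = status, stringsAsFactors = FALSE)
}

# Choose, among all exact occurrences of the motif in the read, the anchor
# whose implied alignment to the mature sequence has the fewest mismatches
# over the overlap (ties: the smallest end shift, then leftmost). Repetitive
# sequences can contain the central motif more than once.
best_anchor <- function(seq, mature, motif, motifLen) {
  # all occurrences, including overlapping ones (1-based starts)
  pos <- integer(0)
  from <- 0L
  repeat {
    p <- regexpr(motif, substr(seq, from + 1L, nchar(seq)), fixed = TRUE)
    if (p == -1L) break
    pos <- c(pos, from + p)
    from <- from + p
  }
  if (!length(pos)) return(list(offset = NA_integer_, mismatches = Inf))
  m0 <- (nchar(mature) - motifLen) %/% 2L
  best <- list(offset = NA_integer_, mismatches = Inf)
  best_shift <- Inf
  for (s in pos - 1L) {
    shift <- m0 - s # mature coordinate of read position 0
    i0 <- max(0L, -shift)
    i1 <- min(nchar(seq), nchar(mature) - shift) - 1L
    if (i1 < i0) next
    rs <- substr(seq, i0 + 1L, i1 + 1L)
    ms <- substr(mature, i0 + shift + 1L, i1 + shift + 1L)
    mm <- sum(utf8ToInt(rs) != utf8ToInt(ms))
    if (mm < best$mismatches ||
        (mm == best$mismatches && abs(shift) < best_shift)) {
      best <- list(offset = s, mismatches = mm)
      best_shift <- abs(shift)
    }
  }
  best
}

#' Assign one read to a miRNA by exact central-motif match
#'
#' The read is scanned for an exact occurrence of any catalog motif; end
#' regions outside the motif-anchored mature body may mismatch freely. If
#' motifs of several distinct miRNAs occur, the read goes to the miRNA with
#' the fewest mismatches against its mature sequence over the anchored
#' overlap; a residual tie is reported as `ambiguous` and excluded from
#' profiles downstream.
#'
#' @param sequence a single read sequence (RNA or DNA alphabet).
#' @param catalog a [ReferenceCatalog-class].
#' @return list with `mirna` (name or `NA`), `motif_start` (0-based offset
#'   of the motif in the read, or `NA`) and `status`
#'   (`assigned`/`unassigned`/`ambiguous`).
#' @export
assignRead <- function(sequence, catalog) {
  stopifnot(length(sequence) == 1L)
  res <- assign_sequences(as_rna(sequence), catalog)
  list(mirna = res$mirna, motif_start = res$motif_start,
       status = res$status)
}

#' Assign a whole library to miRNAs
#'
#' Collapses reads (if not already collapsed) and assigns every distinct
#' sequence by exact central-motif match. Reads shorter than `minLen` or
#' longer than `maxLen` are filtered (counted, not errors).
#'
#' @param reads a file path (FASTA/FASTQ, see [readSmallRNA()]), a character
#'   vector of read sequences, or a data.frame with `sequence` and `count`.
#' @param catalog a [ReferenceCatalog-class].
#' @param minLen,maxLen read length bounds (defaults 16 and 35).
#' @param verbose log the assignment rate (default TRUE).
#' @return data.frame of assigned isomiRs with columns `mirna`, `sequence`,
#'   `count`, `motif_start`, ordered by miRNA then descending count. The
#'   attribute `"stats"` carries named counts: `total`, `assigned`,
#'   `unassigned`, `ambiguous`, `filtered` (summing to `total`).
#' @export
assignLibrary <- function(reads, catalog, minLen = 16L, maxLen = 35L,
                          verbose = TRUE) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- readSmallRNA(reads)
  } else if (is.character(reads)) {
    reads <- collapseReads(reads)
  } else {
    stopifnot(is.data.frame(reads),
              all(c("sequence", "count") %in% names(reads)))
    reads$sequence <- as_rna(reads$sequence)
  }
  total <- sum(reads$count)
  len <- nchar(reads$sequence)
  keep <- len >= minLen & len <= maxLen
  filtered <- sum(reads$count[!keep])
  reads <- reads[keep, , drop = FALSE]
  res <- assign_sequences(reads$sequence, catalog)
  res$count <- reads$count
  stats <- c(
    total = total,
    assigned = sum(res$count[res$status == "assigned"]),
    unassigned = sum(res$count[res$status == "unassigned"]),
    ambiguous = sum(res$count[res$status == "ambiguous"]),
    filtered = filtered
  )
  if (verbose)
    message(sprintf("assigned %d/%d reads (%.1f%%); %d ambiguous, %d filtered",
                    stats["assigned"], stats["total"],
                    100 * stats["assigned"] / max(stats["total"], 1),
                    stats["ambiguous"], stats["filtered"]))
  out <- res[res$status == "assigned",
             c("mirna", "sequence", "count", "motif_start")]
  out <- out[order(out$mirna, -out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stats") <- stats
  out
}
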