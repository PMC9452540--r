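# Per-condition tailing metrics.

count_letter <- function(x, letter) {
  nchar(x) - nchar(gsub(letter, "", x, fixed = TRUE))
}

#' Profile per-miRNA tailing metrics for one library
#'
#' Aggregates a classified isomiR table into per-miRNA metrics: RPM (reads
#' per million assigned miRNA reads), 3'-end composition fractions, the
#' percentage of reads carrying an NT tail, nucleotide identity within NT
#' tails (percent of tail nucleotides, not of reads), mono-NT-tail
#' percentages per letter, the abundance-weighted mean read length, the
#' last templated (annotated) 3' nucleotide, and a long-form tail
#' length-by-identity decomposition (lengths 1..maxTailLen; flagged
#' over-long tails are excluded from category statistics but kept in read
#' fractions and NT percentages).
#'
#' @param classified data.frame from [classifyTable()].
#' @param catalog the [ReferenceCatalog-class] used for classification.
#' @param condition,replicate labels stored on the profile.
#' @return a [ConditionProfile-class].
#' @export
profileCondition <- function(classified, catalog, condition = "cond",
                             replicate = "rep1") {
  if (nrow(classified) == 0L) stop("empty classified table", call. = FALSE)
  cl <- classified
  total <- sum(cl$count)
  mirnas <- sort(unique(cl$mirna))
  f <- factor(cl$mirna, levels = mirnas)
  tot_m <- as.numeric(rowsum(cl$count, f))

  frac_of <- function(mask) {
    as.numeric(rowsum(cl$count * as.numeric(mask), f)) / tot_m
  }
  nt_mask <- cl$origin == "NT"
  metrics <- data.frame(
    mirna = mirnas,
    rpm = 1e6 * tot_m / total,
    frac_canonical = frac_of(cl$end_status == "canonical"),
    frac_trimmed = frac_of(cl$end_status == "trimmed"),
    frac_tailed = frac_of(cl$end_status == "tailed"),
    frac_trimmed_tailed = frac_of(cl$end_status == "trimmed_tailed"),
    pct_NT = 100 * frac_of(nt_mask),
    stringsAsFactors = FALSE
  )
  # nucleotide identity within NT tails: frequency of each letter among the
  # tail nucleotides (a "UU" read contributes two U), percent per miRNA
  tail_nt_total <- as.numeric(rowsum(cl$count * nchar(cl$tail_seq) *
                                       as.numeric(nt_mask), f))
  for (letter in RNA_LETTERS) {
    cnt <- as.numeric(rowsum(
      cl$count * count_letter(cl$tail_seq, letter) * as.numeric(nt_mask), f))
    metrics[[paste0("nt_identity_", letter)]] <-
      ifelse(tail_nt_total > 0, 100 * cnt / tail_nt_total, 0)
  }
  for (letter in RNA_LETTERS) {
    metrics[[paste0("mono_NT_", letter)]] <-
      100 * frac_of(nt_mask & cl$category == paste0("mono_", letter))
  }
  metrics$weighted_len <-
    as.numeric(rowsum(cl$count * nchar(cl$sequence), f)) / tot_m
  metrics$last_templated_nt <-
    substr(catalog@mature[mirnas], nchar(catalog@mature[mirnas]),
           nchar(catalog@mature[mirnas]))
  metrics$arm <- unname(catalog@arm[mirnas])

  li <- cl[nt_mask & !cl$tail_flagged, , drop = FALSE]
  if (nrow(li)) {
    key <- interaction(factor(li$mirna, levels = mirnas),
                       nchar(li$tail_seq), li$coarse_label, drop = TRUE)
    agg <- rowsum(li$count, key)
    parts <- strsplit(rownames(agg), ".", fixed = TRUE)
    lenIdentity <- data.frame(
      mirna = vapply(parts, `[`, "", 1L),
      tail_len = as.integer(vapply(parts, `[`, "", 2L)),
      label = vapply(parts, `[`, "", 3L),
      stringsAsFactors = FALSE
    )
    lenIdentity$pct <- 100 * agg[, 1] /
      tot_m[match(lenIdentity$mirna, mirnas)]
    lenIdentity <- lenIdentity[order(lenIdentity$mirna, lenIdentity$tail_len,
                                     lenIdentity$label), , drop = FALSE]
    rownames(lenIdentity) <- NULL
  } else {
    lenIdentity <- data.frame(mirna = character(), tail_len = integer(),
                              label = character(), pct = numeric())
  }
  new("ConditionProfile", condition = condition, replicate = replicate,
      metrics = metrics, lenIdentity = lenIdentity,
      totalAssigned = total)
}

# miRNA names may contain "." only if input did; interaction() uses "." as
# separator, so guard against ambiguous splits.
select_topN <- function(profiles, N) {
  stopifnot(length(profiles) >= 1L)
  all_names <- sort(unique(unlist(lapply(profiles, function(p)
    mirnaMetrics(p)$mirna))))
  rpm <- vapply(profiles, function(p) {
    m <- mirnaMetrics(p)
    m$rpm[match(all_names, m$mirna)]
  }, numeric(length(all_names)))
  rpm[is.na(rpm)] <- 0
  mean_rpm <- if (is.matrix(rpm)) rowMeans(rpm) else rpm
  if (N > length(all_names)) {
    warning("N exceeds the number of profiled miRNAs; using all")
    N <- length(all_names)
  }
  all_names[order(-mean_rpm, all_names)][seq_len(N)]
}

#' Summarise a metric over the top-N expressed miRNAs
#'
#' Selects the top `N` miRNAs by mean RPM across all supplied profiles (so
#' the miRNA set is fixed within a comparison), then averages the chosen
#' per-miRNA metric UNWEIGHTED across miRNAs within each profile, reporting
#' mean and standard error over the N miRNAs, optionally split by arm.
#'
#' @param profiles list of [ConditionProfile-class] objects (replicates
#'   and/or conditions to be compared).
#' @param N number of top miRNAs (default 200).
#' @param metric metric column of [mirnaMetrics()] to summarise
#'   (default `"pct_NT"`).
#' @param byArm also split 5p vs 3p (default FALSE).
#' @return data.frame with columns `condition`, `replicate`, `arm`
#'   (`"all"` unless split), `metric`, `mean`, `se`, `n`.
#' @export
topNSummary <- function(profiles, N = 200L, metric = "pct_NT",
                        byArm = FALSE) {
  top <- select_topN(profiles, N)
  rows <- lapply(profiles, function(p) {
    m <- mirnaMetrics(p)
    m <- m[m$mirna %in% top, , drop = FALSE]
    groups <- if (byArm) split(m, m$arm) else list(all = m)
    do.call(rbind, lapply(names(groups), function(g) {
      v <- groups[[g]][[metric]]
      data.frame(condition = conditionName(p), replicate = replicateName(p),
                 arm = g, metric = metric, mean = mean(v),
                 se = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Abundance-weighted mean read length of a classified table
#'
#' `sum(length_i * count_i) / sum(count_i)` over the isomiRs of each miRNA.
#'
#' @param classified data.frame from [classifyTable()].
#' @return named numeric vector of weighted mean lengths per miRNA.
#' @export
weightedMeanLength <- function(classified) {
  f <- factor(classified$mirna)
  w <- as.numeric(rowsum(classified$count * nchar(classified$sequence), f)) /
    as.numeric(rowsum(classified$count, f))
  setNames(w, levels(f))
}

#' Per-miRNA weighted-length change between two conditions
#'
#' Computes `weighted_len(B) - weighted_len(A)` for the top-N miRNAs shared
#' by both profiles (replicates are averaged per miRNA first). miRNAs absent
#' from one condition are excluded.
#'
#' @param profilesA,profilesB a [ConditionProfile-class] or list of
#'   replicate profiles for each condition.
#' @param N top-N selection over all supplied profiles (default 200).
#' @return data.frame with columns `mirna`, `len_A`, `len_B`, `delta`;
#'   attribute `"summary"` holds the box-plot statistics (median, quartiles,
#'   Tukey whiskers) of the deltas.
#' @export
deltaLength <- function(profilesA, profilesB, N = 200L) {
  as_list <- function(x) if (is(x, "ConditionProfile")) list(x) else x
  profilesA <- as_list(profilesA); profilesB <- as_list(profilesB)
  top <- select_topN(c(profilesA, profilesB), N)
  mean_len <- function(profiles) {
    tabs <- lapply(profiles, function(p)
      with(mirnaMetrics(p), setNames(weighted_len, mirna)))
    nm <- sort(unique(unlist(lapply(tabs, names))))
    v <- rowMeans(vapply(tabs, function(t) t[nm], numeric(length(nm))),
                  na.rm = FALSE)
    setNames(v, nm)
  }
  la <- mean_len(profilesA); lb <- mean_len(profilesB)
  shared <- intersect(top, intersect(names(la)[!is.na(la)],
                                     names(lb)[!is.na(lb)]))
  dropped <- setdiff(top, shared)
  if (length(dropped))
    message(length(dropped), " top-N miRNAs absent from one condition; excluded")
  out <- data.frame(mirna = shared, len_A = unname(la[shared]),
                    len_B = unname(lb[shared]),
                    delta = unname(lb[shared] - la[shared]),
                    stringsAsFactors = FALSE)
  d <- out$delta
  q <- quantile(d, c(.25, .5, .75), names = FALSE)
  iqr <- q[3] - q[1]
  attr(out, "summary") <- c(
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(d[d >= q[1] - 1.5 * iqr]),
    whisker_high = max(d[d <= q[3] + 1.5 * iqr])
  )
  out
}

#' Estimate the A-to-G misread rate from spike-in reads
#'
#' Spike-in references carry annotated known-A positions (internal and at
#' the last nucleotide). Reads are matched to their spike-in by exact
#' identity over the first `anchorLen` nucleotides; for every known-A
#' position covered, the conversion rate is the fraction of reads showing G
#' there.
#'
#' @param reads character vector of read sequences, or a data.frame with
#'   `sequence` and `count`.
#' @param spikeins named character vector of spike-in reference sequences
#'   (RNA or DNA alphabet).
#' @param positions data.frame with columns `name` (spike-in), `pos`
#'   (1-based position, must hold an A in the reference) and `class`
#'   (`"internal"` or `"terminal"`).
#' @param anchorLen prefix length used to match reads to spike-ins
#'   (default 12).
#' @return data.frame per position class: `class`, `covered` (reads covering
#'   the position), `g_reads`, `rate` (fraction), `rate_pct`.
#' @export
estimateConversionRate <- function(reads, spikeins, positions,
                                   anchorLen = 12L) {
  if (is.character(reads)) reads <- collapseReads(reads)
  reads$sequence <- as_rna(reads$sequence)
  spikeins <- setNames(as_rna(spikeins), names(spikeins))
  stopifnot(all(c("name", "pos", "class") %in% names(positions)))
  refA <- substr(spikeins[positions$name], positions$pos, positions$pos)
  if (any(refA != "A"))
    stop("some annotated positions are not A in the reference", call. = FALSE)
  prefix <- substr(reads$sequence, 1L, anchorLen)
  ref_prefix <- substr(spikeins, 1L, anchorLen)
  hit <- match(prefix, ref_prefix)
  out <- do.call(rbind, lapply(split(positions, positions$class), function(pp) {
    covered <- 0; g <- 0
    for (i in seq_len(nrow(pp))) {
      ri <- which(hit == match(pp$name[i], names(spikeins)) &
                    nchar(reads$sequence) >= pp$pos[i])
      covered <- covered + sum(reads$count[ri])
      base <- substr(reads$sequence[ri], pp$pos[i], pp$pos[i])
      g <- g + sum(reads$count[ri][base == "G"])
    }
    if (covered == 0) {
      warning("zero coverage for position class ", pp$class[1])
      return(data.frame(class = pp$class[1], covered = 0, g_reads = 0,
                        rate = NA_real_, rate_pct = NA_real_))
    }
    data.frame(class = pp$class[1], covered = covered, g_reads = g,
               rate = g / covered, rate_pct = 100 * g / covered,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
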