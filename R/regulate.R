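# miRNA-level abundance and consensus regulation calls across knockout and
# rescue comparisons.

#' miRNA abundance from a classified isomiR table
#'
#' Sums all isomiR counts per miRNA and normalizes to reads per million
#' assigned miRNA reads.
#'
#' @param classified data.frame from [classifyTable()] (or any table with
#'   `mirna` and `count`).
#' @return data.frame with columns `mirna`, `count`, `rpm`.
#' @export
mirnaAbundance <- function(classified) {
  f <- factor(classified$mirna)
  cnt <- as.numeric(rowsum(classified$count, f))
  data.frame(mirna = levels(f), count = cnt, rpm = 1e6 * cnt / sum(cnt),
             stringsAsFactors = FALSE)
}

# per-miRNA log2 fold-change between two conditions (replicate-mean
# pseudocounted RPM)
mirna_log2fc <- function(classifiedA, classifiedB, pseudocount = 0.5) {
  as_list <- function(x) if (is.data.frame(x)) list(x) else x
  mean_rpm <- function(lst) {
    tabs <- lapply(as_list(lst), function(cl) {
      ab <- mirnaAbundance(cl)
      setNames(1e6 * (ab$count + pseudocount) / sum(ab$count), ab$mirna)
    })
    nm <- sort(unique(unlist(lapply(tabs, names))))
    m <- vapply(tabs, function(t) t[nm], numeric(length(nm)))
    v <- if (is.matrix(m)) rowMeans(m, na.rm = TRUE) else m
    setNames(v, nm)
  }
  a <- mean_rpm(classifiedA); b <- mean_rpm(classifiedB)
  nm <- intersect(names(a), names(b))
  list(log2fc = setNames(log2(b[nm] / a[nm]), nm),
       mean_rpm = setNames((a[nm] + b[nm]) / 2, nm))
}

call_one <- function(fc, threshold) {
  ifelse(is.na(fc), "none",
         ifelse(fc >= threshold, "up",
                ifelse(fc <= -threshold, "down", "none")))
}

#' Consensus miRNA regulation calls across knockout and rescue comparisons
#'
#' Each comparison supplies per-miRNA log2 fold-changes (B over A). A miRNA
#' is called `up` in a comparison when `log2FC >= threshold` (inclusive) and
#' `down` when `log2FC <= -threshold`. The consensus call "negatively
#' regulated by the enzyme(s)" (`up`) requires `up` in every knockout
#' comparison AND `down` in the required rescue comparisons; "positively
#' regulated" (`down`) is the mirrored pattern. miRNAs missing from a
#' comparison, or below the expression floor, are `none`.
#'
#' @param ko named list of per-miRNA log2FC vectors (named numeric), one per
#'   knockout-vs-control comparison.
#' @param rescue named list of per-miRNA log2FC vectors for rescue
#'   comparisons (rescue vs knockout).
#' @param threshold symmetric log2FC threshold (default 0.2, inclusive).
#' @param rescueRule `"all"` (default) requires the rescue response in every
#'   rescue comparison; `"any"` in at least one.
#' @param meanRpm optional named vector of mean RPM across the compared
#'   conditions; miRNAs below `rpmFloor` are not called.
#' @param rpmFloor expression floor (default 10 RPM).
#' @return data.frame with one row per miRNA: per-comparison calls
#'   (`ko_<name>`, `rescue_<name>`) and `consensus`
#'   (`up`/`down`/`none`). The attribute `"venn"` counts the consensus sets.
#' @export
regulationCalls <- function(ko, rescue = list(), threshold = 0.2,
                            rescueRule = c("all", "any"),
                            meanRpm = NULL, rpmFloor = 10) {
  rescueRule <- match.arg(rescueRule)
  stopifnot(length(ko) >= 1L)
  if (is.null(names(ko)) || any(names(ko) == ""))
    names(ko) <- paste0("cmp", seq_along(ko))
  if (length(rescue) && (is.null(names(rescue)) || any(names(rescue) == "")))
    names(rescue) <- paste0("cmp", seq_along(rescue))
  mirnas <- sort(unique(unlist(lapply(c(ko, rescue), names))))
  out <- data.frame(mirna = mirnas, stringsAsFactors = FALSE)
  ko_calls <- matrix("none", length(mirnas), length(ko))
  for (i in seq_along(ko)) {
    ko_calls[, i] <- call_one(ko[[i]][mirnas], threshold)
    out[[paste0("ko_", names(ko)[i])]] <- ko_calls[, i]
  }
  rs_calls <- matrix("none", length(mirnas), max(length(rescue), 1L))
  for (i in seq_along(rescue)) {
    rs_calls[, i] <- call_one(rescue[[i]][mirnas], threshold)
    out[[paste0("rescue_", names(rescue)[i])]] <- rs_calls[, i]
  }
  agg <- if (rescueRule == "all") function(x, v) all(x == v) else
    function(x, v) any(x == v)
  consensus <- vapply(seq_along(mirnas), function(j) {
    ko_up <- all(ko_calls[j, ] == "up")
    ko_down <- all(ko_calls[j, ] == "down")
    rs_down <- if (length(rescue)) agg(rs_calls[j, seq_along(rescue)], "down")
      else TRUE
    rs_up <- if (length(rescue)) agg(rs_calls[j, seq_along(rescue)], "up")
      else TRUE
    if (ko_up && rs_down) "up" else if (ko_down && rs_up) "down" else "none"
  }, "")
  if (!is.null(meanRpm)) {
    low <- mirnas[is.na(meanRpm[mirnas]) | meanRpm[mirnas] < rpmFloor]
    if (length(low))
      message(length(low), " miRNAs below the ", rpmFloor,
              " RPM floor; not called")
    consensus[mirnas %in% low] <- "none"
  }
  out$consensus <- consensus
  attr(out, "venn") <- c(up = sum(consensus == "up"),
                         down = sum(consensus == "down"),
                         none = sum(consensus == "none"))
  out
}
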