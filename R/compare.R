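# Condition-vs-condition comparisons: isomiR fold-changes, cumulative
# curves by isomiR class, enzyme-sensitivity consensus, terminal-nucleotide
# preference, and the statistical helpers used throughout.

default_curve_edges <- function(n = 25L) 2^seq(-3, 3, length.out = n)

#' Cumulative fold-change curves by isomiR class
#'
#' For each class, the fraction of isomiRs whose fold-change is less than or
#' equal to each threshold (bin edge) — an empirical CDF evaluated on a
#' fixed grid. Edges default to 25 log2-spaced thresholds in [1/8, 8].
#'
#' @param fold_changes positive finite fold-changes (pseudocounted
#'   upstream).
#' @param class_labels character vector parallel to `fold_changes`
#'   (e.g. `canonical`/`ambiguous`/`NT`).
#' @param edges threshold grid.
#' @return data.frame with columns `class`, `edge`, `frac`.
#' @export
cumulativeCurve <- function(fold_changes, class_labels,
                            edges = default_curve_edges()) {
  stopifnot(length(fold_changes) == length(class_labels))
  if (any(!is.finite(fold_changes) | fold_changes <= 0))
    stop("fold-changes must be finite and positive", call. = FALSE)
  out <- lapply(unique(class_labels), function(cl) {
    fc <- fold_changes[class_labels == cl]
    if (length(fc) == 0L) {
      warning("empty class omitted: ", cl)
      return(NULL)
    }
    data.frame(class = cl, edge = edges,
               frac = vapply(edges, function(e) mean(fc <= e), numeric(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# replicate-mean pseudocounted RPM per isomiR for a list of classified
# replicate tables
isomir_rpm <- function(classified_list, pseudocount = 0.5) {
  tabs <- lapply(classified_list, function(cl) {
    total <- sum(cl$count)
    data.frame(key = paste(cl$mirna, cl$sequence, sep = "\r"),
               rpm = 1e6 * (cl$count + pseudocount) / total,
               stringsAsFactors = FALSE)
  })
  totals <- vapply(classified_list, function(cl) sum(cl$count), numeric(1))
  keys <- sort(unique(unlist(lapply(tabs, `[[`, "key"))))
  rpm <- vapply(seq_along(tabs), function(i) {
    v <- tabs[[i]]$rpm[match(keys, tabs[[i]]$key)]
    # an isomiR absent from a replicate still gets the pseudocount
    v[is.na(v)] <- 1e6 * pseudocount / totals[i]
    v
  }, numeric(length(keys)))
  rpm <- if (is.matrix(rpm)) rowMeans(rpm) else rpm
  setNames(rpm, keys)
}

#' Compare tailing between two conditions
#'
#' Computes isomiR-level fold-changes of abundance (B over A, replicate-mean
#' RPM with a pseudocount of `pseudocount` reads), the relative-abundance
#' heatmap value `min(100 * FC, cap)`, per-miRNA fold-changes of the NT-tail
#' percentage by nucleotide plus the miRNA abundance log2 fold-change, and
#' cumulative fold-change curves split by isomiR class (canonical /
#' ambiguous / NT; trimmed isomiRs are labelled `trimmed` and not drawn in
#' the default curves).
#'
#' @param classifiedA,classifiedB classified isomiR tables
#'   (see [classifyTable()]) — one data.frame or a list of replicate tables.
#' @param conditions character(2) condition names `(A, B)`.
#' @param pseudocount reads added to numerator and denominator counts
#'   (default 0.5).
#' @param rpmFloor isomiRs below this replicate-mean RPM in both conditions
#'   are excluded from fold-changes (default 1).
#' @param cap heatmap cap (default 100, rendered as ">=100").
#' @param edges curve thresholds (default 25 log2-spaced in [1/8, 8]).
#' @return a [ComparisonResult-class].
#' @export
compareConditions <- function(classifiedA, classifiedB,
                              conditions = c("A", "B"),
                              pseudocount = 0.5, rpmFloor = 1,
                              cap = 100, edges = default_curve_edges()) {
  as_list <- function(x) if (is.data.frame(x)) list(x) else x
  la <- as_list(classifiedA); lb <- as_list(classifiedB)
  rpmA <- isomir_rpm(la, pseudocount)
  rpmB <- isomir_rpm(lb, pseudocount)
  keys <- union(names(rpmA), names(rpmB))
  minRpm <- function(r, keys, lst) {
    v <- r[keys]
    v[is.na(v)] <- 1e6 * pseudocount /
      mean(vapply(lst, function(cl) sum(cl$count), numeric(1)))
    v
  }
  a <- minRpm(rpmA, keys, la); b <- minRpm(rpmB, keys, lb)
  keep <- a >= rpmFloor | b >= rpmFloor
  a <- a[keep]; b <- b[keep]; keys <- keys[keep]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  mirna <- vapply(parts, `[`, "", 1L)
  sequence <- vapply(parts, `[`, "", 2L)

  # class of each isomiR, looked up from whichever table knows it
  cls_map <- new.env(parent = emptyenv())
  for (cl in c(la, lb)) {
    k <- paste(cl$mirna, cl$sequence, sep = "\r")
    lab <- ifelse(cl$origin == "NT", "NT",
                  ifelse(cl$origin == "ambiguous", "ambiguous",
                         ifelse(cl$end_status == "canonical", "canonical",
                                "trimmed")))
    for (i in seq_along(k)) if (is.null(cls_map[[k[i]]]))
      cls_map[[k[i]]] <- lab[i]
  }
  class_lab <- vapply(keys, function(k) cls_map[[k]] %||% "unknown", "")

  fc <- b / a
  isomirFC <- data.frame(
    mirna = mirna, sequence = sequence, class = unname(class_lab),
    rpm_A = unname(a), rpm_B = unname(b), fc = unname(fc),
    heat = pmin(100 * unname(fc), cap), stringsAsFactors = FALSE
  )
  isomirFC <- isomirFC[order(isomirFC$mirna, isomirFC$sequence), ,
                       drop = FALSE]
  rownames(isomirFC) <- NULL

  curves <- cumulativeCurve(
    isomirFC$fc[isomirFC$class %in% c("canonical", "ambiguous", "NT")],
    isomirFC$class[isomirFC$class %in% c("canonical", "ambiguous", "NT")],
    edges)

  mirnaFC <- mirna_pct_fc(la, lb, pseudocount)
  new("ComparisonResult", pair = conditions, isomirFC = isomirFC,
      mirnaFC = mirnaFC, curves = curves, cap = cap)
}

# per-miRNA NT-tail percentage (pseudocounted) and abundance, averaged over
# replicates, then B/A fold-changes
mirna_pct_fc <- function(la, lb, pseudocount = 0.5) {
  per_cond <- function(lst) {
    tabs <- lapply(lst, function(cl) {
      f <- factor(cl$mirna)
      tot <- as.numeric(rowsum(cl$count, f))
      nt <- cl$origin == "NT"
      res <- data.frame(mirna = levels(f), total = tot)
      for (letter in RNA_LETTERS) {
        cnt <- as.numeric(rowsum(
          cl$count * as.numeric(nt & cl$category == paste0("mono_", letter)),
          f))
        res[[paste0("pct_", letter)]] <-
          100 * (cnt + pseudocount) / (tot + pseudocount)
      }
      ntc <- as.numeric(rowsum(cl$count * as.numeric(nt), f))
      res$pct_NT <- 100 * (ntc + pseudocount) / (tot + pseudocount)
      res$rpm <- 1e6 * (tot + pseudocount) / sum(cl$count)
      res
    })
    nm <- sort(unique(unlist(lapply(tabs, `[[`, "mirna"))))
    cols <- setdiff(names(tabs[[1]]), "mirna")
    out <- data.frame(mirna = nm, stringsAsFactors = FALSE)
    for (cc in cols) {
      m <- vapply(tabs, function(t) t[[cc]][match(nm, t$mirna)],
                  numeric(length(nm)))
      out[[cc]] <- if (is.matrix(m)) rowMeans(m, na.rm = TRUE) else m
    }
    out
  }
  A <- per_cond(la); B <- per_cond(lb)
  nm <- intersect(A$mirna, B$mirna)
  A <- A[match(nm, A$mirna), ]; B <- B[match(nm, B$mirna), ]
  out <- data.frame(mirna = nm, stringsAsFactors = FALSE)
  for (letter in RNA_LETTERS)
    out[[paste0("fc_pct_", letter)]] <-
      B[[paste0("pct_", letter)]] / A[[paste0("pct_", letter)]]
  out$fc_pct_NT <- B$pct_NT / A$pct_NT
  out$rpm_A <- A$rpm; out$rpm_B <- B$rpm
  out$log2_fc <- log2(B$rpm / A$rpm)
  rownames(out) <- NULL
  out
}

#' Consensus enzyme-sensitivity set from two knockout comparisons
#'
#' Ranks miRNAs by the decrease of their NT mono-tail percentage (default
#' uridylation, `nucleotide = "U"`) in each comparison and returns the
#' miRNAs ranked in the top `topN` of BOTH — the consensus sensitive set.
#'
#' @param comp1,comp2 [ComparisonResult-class] objects (knockout over a
#'   shared miRNA universe), or data.frames with columns `mirna` and `fc`.
#' @param topN size of each ranking (default 100).
#' @param nucleotide tail letter whose percentage fold-change is ranked
#'   (default `"U"`).
#' @return data.frame of consensus miRNAs with both fold-changes (`fc1`,
#'   `fc2`), ordered by mean rank.
#' @export
sensitivityRanking <- function(comp1, comp2, topN = 100L, nucleotide = "U") {
  get_fc <- function(x) {
    if (is(x, "ComparisonResult")) {
      m <- mirnaFoldChanges(x)
      setNames(m[[paste0("fc_pct_", nucleotide)]], m$mirna)
    } else setNames(x$fc, x$mirna)
  }
  f1 <- get_fc(comp1); f2 <- get_fc(comp2)
  universe <- intersect(names(f1), names(f2))
  if (topN > length(universe))
    stop("topN exceeds the shared miRNA universe", call. = FALSE)
  f1 <- f1[universe]; f2 <- f2[universe]
  # biggest change upon knockout = biggest decrease = smallest fold-change
  top1 <- universe[order(f1, universe)][seq_len(topN)]
  top2 <- universe[order(f2, universe)][seq_len(topN)]
  sel <- intersect(top1, top2)
  out <- data.frame(mirna = sel, fc1 = unname(f1[sel]), fc2 = unname(f2[sel]),
                    stringsAsFactors = FALSE)
  out <- out[order(rank(out$fc1) + rank(out$fc2), out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Terminal-nucleotide composition of a miRNA set vs background
#'
#' Frequency of each nucleotide at the last templated (annotated mature 3')
#' position in a miRNA set, compared with a background set; per-letter
#' enrichment ratio and a two-sided binomial test against the background
#' frequency.
#'
#' @param mirna_set character vector of miRNA names.
#' @param catalog a [ReferenceCatalog-class].
#' @param background_set background miRNA names (e.g. the expressed
#'   universe).
#' @return data.frame with columns `letter`, `set_pct`, `bg_pct`, `ratio`,
#'   `p_value`.
#' @export
terminalNtComposition <- function(mirna_set, catalog, background_set) {
  stopifnot(length(mirna_set) > 0L, length(background_set) > 0L)
  last_nt <- function(nms) {
    s <- catalog@mature[nms]
    substr(s, nchar(s), nchar(s))
  }
  s <- last_nt(mirna_set); b <- last_nt(background_set)
  out <- do.call(rbind, lapply(RNA_LETTERS, function(letter) {
    ks <- sum(s == letter); kb <- sum(b == letter)
    p_bg <- kb / length(b)
    pval <- if (p_bg %in% c(0, 1)) NA_real_ else
      binom.test(ks, length(s), p = p_bg,
                 alternative = "two.sided")$p.value
    data.frame(letter = letter, set_pct = 100 * ks / length(s),
               bg_pct = 100 * p_bg,
               ratio = if (p_bg > 0) (ks / length(s)) / p_bg else NA_real_,
               p_value = pval, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two paired profiles
#'
#' @param a,b paired numeric vectors (abundances). With `log = TRUE`
#'   (default) values are log10-transformed after adding `offset`.
#' @param log log-transform before correlating.
#' @param offset added before the log (default 0).
#' @return Pearson correlation coefficient.
#' @export
correlateProfiles <- function(a, b, log = TRUE, offset = 0) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (log) { a <- log10(a + offset); b <- log10(b + offset) }
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in one profile", call. = FALSE)
  cor(a, b, method = "pearson")
}

#' Two-sided Wilcoxon test between two samples
#'
#' Rank-sum for independent samples, signed-rank when `paired = TRUE`.
#'
#' @param x,y numeric samples (`n >= 3` each).
#' @param paired use the signed-rank test (default FALSE).
#' @return two-sided p-value.
#' @export
wilcoxonCompare <- function(x, y, paired = FALSE) {
  if (length(x) < 3L || length(y) < 3L)
    stop("need n >= 3 per group", call. = FALSE)
  if (paired && length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  if (paired && all(x == y))
    stop("degenerate input: all pairs tied", call. = FALSE)
  suppressWarnings(
    wilcox.test(x, y, paired = paired, alternative = "two.sided",
                exact = FALSE, correct = TRUE)$p.value)
}
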