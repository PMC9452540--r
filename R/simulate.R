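# Synthetic small-RNA data with enzyme-specific 3' tailing and full ground
# truth. The generator emulates: heavy-tailed per-miRNA expression, 5'/3'
# end heterogeneity from processing (creating trimmed and templated-extended
# isomiRs), enzyme-specific non-templated tailing with per-miRNA
# sensitivities and last-nucleotide substrate bias, competition between
# adenylating and uridylating enzymes, extra precursor-inherited tailing on
# 3p arms, and a per-base misread model including a dedicated A-to-G
# channel. All randomness is keyed off the design seed, so output is
# reproducible bit for bit.

#' Enzyme tailing model
#'
#' Describes one terminal nucleotidyltransferase: the letters it adds, its
#' per-read action rate, its preference for the substrate's last templated
#' nucleotide, the spread of per-miRNA sensitivities, and its tail length
#' distribution (geometric, mostly mono-nucleotide tails).
#'
#' @param name enzyme name.
#' @param ntPropensity named probabilities over `A`,`C`,`G`,`U` for each
#'   added letter (must sum to 1).
#' @param rate baseline per-read probability of acting on a substrate.
#' @param substrateBias named multipliers on `rate` by the substrate's last
#'   templated nucleotide (default all 1).
#' @param tailLenP geometric parameter: `P(len = 1)` (default 0.5).
#' @param sensitivitySd sdlog of the lognormal per-miRNA sensitivity
#'   multipliers (default 0.4).
#' @param mirnaSensitivity optional explicit named multipliers; when NULL
#'   they are drawn per catalog from the design seed.
#' @return an object of class `enzyme_model`.
#' @examples
#' tut4Model()
#' @export
enzymeModel <- function(name, ntPropensity, rate,
                        substrateBias = c(A = 1, C = 1, G = 1, U = 1),
                        tailLenP = 0.5, sensitivitySd = 0.4,
                        mirnaSensitivity = NULL) {
  p <- setNames(rep(0, 4), RNA_LETTERS)
  p[names(ntPropensity)] <- ntPropensity
  if (abs(sum(p) - 1) > 1e-9)
    stop("ntPropensity must sum to 1", call. = FALSE)
  b <- setNames(rep(1, 4), RNA_LETTERS)
  b[names(substrateBias)] <- substrateBias
  if (any(b <= 0)) stop("substrate multipliers must be > 0", call. = FALSE)
  structure(list(name = name, ntPropensity = p, rate = rate,
                 substrateBias = b, tailLenP = tailLenP,
                 sensitivitySd = sensitivitySd,
                 mirnaSensitivity = mirnaSensitivity),
            class = "enzyme_model")
}

#' @rdname enzymeModel
#' @export
tent2Model <- function(rate = 0.085)
  enzymeModel("TENT2", c(A = 0.85, G = 0.10, U = 0.05), rate = rate)

#' @rdname enzymeModel
#' @export
tut4Model <- function(rate = 0.085)
  enzymeModel("TUT4", c(U = 1), rate = rate,
              substrateBias = c(A = 1, C = 0.5, G = 2, U = 0.5))

#' @rdname enzymeModel
#' @export
tut7Model <- function(rate = 0.02)
  enzymeModel("TUT7", c(U = 1), rate = rate)

is_uridylating <- function(enz) enz$ntPropensity[["U"]] >= 0.5

#' Knockout/rescue experiment design
#'
#' @param conditions named list: condition name -> character vector of
#'   active enzyme names (a knockout removes an enzyme; a rescue adds it
#'   back). Defaults to the six genotypes WT, TENT2KO, TUT4KO, TUT7KO,
#'   DKO (TUT4+TUT7 lost) and TKO (all three lost).
#' @param enzymes list of [enzymeModel()] objects the design knows about.
#' @param replicates replicates per condition (default 2).
#' @param depth reads per library (default 2e5).
#' @param seed master seed; every stream (expression, sensitivities, each
#'   library) is derived from it deterministically.
#' @param misreadRate per-base probability of a uniform substitution to one
#'   of the other three letters (default 5e-4).
#' @param agRate additional per-base A-to-G misread probability
#'   (default 0).
#' @param competition factor by which the rates of active adenylating
#'   enzymes are multiplied when no uridylating enzyme is active — models
#'   improved 3'-end access once the competing enzymes are gone
#'   (default 2.4).
#' @param arm3pExtra extra tailing rate on 3p-arm miRNAs emulating
#'   precursor-inherited uridylation; active only while a uridylating
#'   enzyme is (default 0.03).
#' @param p5 probabilities of 5' trimming offsets 0/1/2 nt.
#' @param p3 probabilities of templated 3' offsets -2..+2 nt (negative =
#'   trimming, positive = templated extension into the locus context).
#' @param expressionSdlog sdlog of the lognormal expression weights
#'   (default 1.5, heavy-tailed).
#' @param tailLenCap longest generated tail (default 6).
#' @param abundanceEffects optional named list: condition -> named
#'   per-miRNA abundance multipliers (planted regulation effects).
#' @return an object of class `experiment_design`.
#' @export
experimentDesign <- function(conditions = NULL,
                             enzymes = list(tent2Model(), tut4Model(),
                                            tut7Model()),
                             replicates = 2L, depth = 2e5, seed = 1L,
                             misreadRate = 5e-4, agRate = 0,
                             competition = 2.4, arm3pExtra = 0.03,
                             p5 = c(`0` = 0.90, `1` = 0.07, `2` = 0.03),
                             p3 = c(`-2` = 0.03, `-1` = 0.10, `0` = 0.77,
                                    `1` = 0.06, `2` = 0.04),
                             expressionSdlog = 1.5, tailLenCap = 6L,
                             abundanceEffects = NULL) {
  names(enzymes) <- vapply(enzymes, `[[`, "", "name")
  if (is.null(conditions))
    conditions <- list(
      WT = c("TENT2", "TUT4", "TUT7"), TENT2KO = c("TUT4", "TUT7"),
      TUT4KO = c("TENT2", "TUT7"), TUT7KO = c("TENT2", "TUT4"),
      DKO = "TENT2", TKO = character(0))
  if (anyDuplicated(names(conditions)))
    stop("duplicate condition names", call. = FALSE)
  unknown <- setdiff(unlist(conditions), names(enzymes))
  if (length(unknown))
    stop("conditions use unknown enzymes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  stopifnot(abs(sum(p5) - 1) < 1e-9, abs(sum(p3) - 1) < 1e-9)
  structure(list(conditions = conditions, enzymes = enzymes,
                 replicates = as.integer(replicates), depth = depth,
                 seed = as.integer(seed), misreadRate = misreadRate,
                 agRate = agRate, competition = competition,
                 arm3pExtra = arm3pExtra, p5 = p5, p3 = p3,
                 expressionSdlog = expressionSdlog,
                 tailLenCap = as.integer(tailLenCap),
                 abundanceEffects = abundanceEffects),
            class = "experiment_design")
}

#' Simulate a miRNA reference catalog
#'
#' Random mature sequences of 20-23 nt with unique central motifs (rejection
#' sampling), 1-3 loci each with random downstream genomic contexts, and
#' arms alternating 5p/3p.
#'
#' @param nMirnas number of miRNAs.
#' @param seed RNG seed (the function sets the RNG state).
#' @param motifLen,maxTailLen,downstreamLen catalog parameters.
#' @param maxLoci maximum loci per miRNA (default 3).
#' @return a [ReferenceCatalog-class].
#' @export
simulateReference <- function(nMirnas, seed = 1L, motifLen = 13L,
                              maxTailLen = 8L, downstreamLen = 20L,
                              maxLoci = 3L) {
  stopifnot(nMirnas >= 1L)
  set.seed(seed)
  rand_seq <- function(n) paste(sample(RNA_LETTERS, n, TRUE), collapse = "")
  mature <- character(nMirnas)
  motifs <- character(0)
  for (i in seq_len(nMirnas)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      s <- rand_seq(sample(20:23, 1L))
      mo <- motifOf(s, motifLen)
      if (!mo %in% motifs) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not draw ", nMirnas, " unique motifs at motifLen ",
           motifLen, call. = FALSE)
    mature[i] <- s
    motifs <- c(motifs, mo)
  }
  arm <- rep(c("5p", "3p"), length.out = nMirnas)
  names(mature) <- sprintf("syn-miR-%d-%s", seq_len(nMirnas), arm)
  nloc <- sample(seq_len(maxLoci), nMirnas, TRUE,
                 prob = c(0.7, 0.2, 0.1)[seq_len(maxLoci)])
  loci <- do.call(rbind, lapply(seq_len(nMirnas), function(i) {
    data.frame(name = names(mature)[i],
               locus_id = paste0("L", seq_len(nloc[i])),
               downstream = vapply(seq_len(nloc[i]),
                                   function(j) rand_seq(downstreamLen), ""),
               stringsAsFactors = FALSE)
  }))
  referenceCatalog(mature, loci, motifLen = motifLen,
                   maxTailLen = maxTailLen)
}

# Per-enzyme, per-miRNA sensitivity multipliers — drawn once per design so
# every condition and replicate shares them.
#' @rdname ntTailProbability
#' @export
enzymeSensitivities <- function(design, catalog) {
  nm <- mirnaNames(catalog)
  out <- lapply(seq_along(design$enzymes), function(e) {
    enz <- design$enzymes[[e]]
    if (!is.null(enz$mirnaSensitivity)) {
      s <- setNames(rep(1, length(nm)), nm)
      s[names(enz$mirnaSensitivity)] <- enz$mirnaSensitivity
      return(s)
    }
    set.seed(derive_seed(design$seed, 100L + e))
    setNames(rlnorm(length(nm), 0, enz$sensitivitySd), nm)
  })
  names(out) <- names(design$enzymes)
  out
}

#' @rdname ntTailProbability
#' @export
expressionWeights <- function(design, catalog, condition = NULL) {
  nm <- mirnaNames(catalog)
  set.seed(derive_seed(design$seed, 99L))
  w <- setNames(rlnorm(length(nm), 0, design$expressionSdlog), nm)
  if (!is.null(condition) && !is.null(design$abundanceEffects[[condition]])) {
    eff <- design$abundanceEffects[[condition]]
    w[names(eff)] <- w[names(eff)] * eff
  }
  w / sum(w)
}

# per-miRNA per-enzyme action rates in a condition (competition applied);
# the precursor pseudo-enzyme models 3p-arm inherited uridylation
enzyme_rates <- function(design, catalog, condition, sens = NULL) {
  if (!condition %in% names(design$conditions))
    stop("unknown condition: ", condition, call. = FALSE)
  active <- design$conditions[[condition]]
  if (is.null(sens)) sens <- enzymeSensitivities(design, catalog)
  nm <- mirnaNames(catalog)
  last_nt <- substr(catalog@mature, nchar(catalog@mature),
                    nchar(catalog@mature))
  any_urid_active <- any(vapply(design$enzymes[active], is_uridylating,
                                logical(1)))
  boost <- if (!any_urid_active &&
               any(vapply(design$enzymes, is_uridylating, logical(1))))
    design$competition else 1
  rates <- lapply(active, function(e) {
    enz <- design$enzymes[[e]]
    r <- enz$rate * enz$substrateBias[last_nt] * sens[[e]][nm]
    if (!is_uridylating(enz)) r <- r * boost
    setNames(r, nm)
  })
  names(rates) <- active
  pre <- ifelse(catalog@arm[nm] == "3p" & any_urid_active,
                design$arm3pExtra, 0)
  rates[["precursor"]] <- setNames(pre, nm)
  rates
}

geom_len_probs <- function(p, cap) {
  probs <- p * (1 - p)^(seq_len(cap) - 1L)
  probs[cap] <- 1 - sum(probs[-cap])
  probs
}

#' Simulate one small-RNA library with ground truth
#'
#' Draws each read's miRNA from heavy-tailed expression weights, applies 5'
#' and 3' end heterogeneity (trimming, templated extension into a randomly
#' chosen locus), an enzyme-specific tailing event, and the per-base
#' misread model. Truth labels (end status, tail, templated/NT origin,
#' acting enzyme) are recorded for the pre-misread read by a maximal
#' templated walk over all the miRNA's loci.
#'
#' @param catalog a [ReferenceCatalog-class].
#' @param design an [experimentDesign()].
#' @param condition condition name in the design.
#' @param replicate replicate number (default 1).
#' @return list with `condition`, `replicate`, `reads` (character vector of
#'   final read sequences, misreads applied) and `truth` (data.frame:
#'   `mirna`, `read`, `end_status`, `tail`, `origin`, `enzyme`, `locus`,
#'   `misread`).
#' @export
simulateLibrary <- function(catalog, design, condition, replicate = 1L) {
  if (!condition %in% names(design$conditions))
    stop("unknown condition: ", condition, call. = FALSE)
  nm <- mirnaNames(catalog)
  mature <- catalog@mature
  L <- nchar(mature)
  sens <- enzymeSensitivities(design, catalog)
  weights <- expressionWeights(design, catalog, condition)
  rates <- enzyme_rates(design, catalog, condition, sens)
  rate_mat <- do.call(cbind, rates) # miRNA x enzyme
  tot_rate <- pmin(rowSums(rate_mat), 1)
  enz_names <- colnames(rate_mat)

  cond_i <- match(condition, names(design$conditions))
  set.seed(derive_seed(design$seed, 1000L * cond_i + as.integer(replicate)))
  n <- as.integer(design$depth)
  mi <- sample.int(length(nm), n, replace = TRUE, prob = weights)

  loci_by <- split(seq_len(nrow(catalog@loci)), catalog@loci$name)[nm]
  nloc <- lengths(loci_by)
  li_local <- 1L + floor(runif(n) * nloc[mi]) # locus index within miRNA
  li <- vapply(seq_len(n), function(k) loci_by[[mi[k]]][li_local[k]],
               integer(1))
  down <- catalog@loci$downstream[li]
  locus_id <- catalog@loci$locus_id[li]

  off5 <- as.integer(names(design$p5))[
    sample.int(length(design$p5), n, TRUE, prob = design$p5)]
  off3 <- as.integer(names(design$p3))[
    sample.int(length(design$p3), n, TRUE, prob = design$p3)]

  tailed <- runif(n) < tot_rate[mi]
  enzyme <- rep("none", n)
  tail_str <- rep("", n)
  ti <- which(tailed)
  if (length(ti)) {
    # pick the acting enzyme per read, weights proportional to its rate
    P <- rate_mat / rowSums(rate_mat)
    cum <- P
    if (ncol(P) > 1L)
      for (e in 2L:ncol(P)) cum[, e] <- cum[, e - 1L] + cum[, e]
    u <- runif(length(ti))
    eidx <- rep(1L, length(ti))
    if (ncol(cum) > 1L)
      for (e in seq_len(ncol(cum) - 1L))
        eidx[u > cum[mi[ti], e]] <- e + 1L
    enzyme[ti] <- enz_names[eidx]
    for (e in enz_names) {
      sel <- ti[enzyme[ti] == e]
      if (!length(sel)) next
      enz <- if (e == "precursor")
        list(ntPropensity = setNames(c(0, 0, 0, 1), RNA_LETTERS),
             tailLenP = 0.5)
      else design$enzymes[[e]]
      lens <- sample.int(design$tailLenCap, length(sel), TRUE,
                         prob = geom_len_probs(enz$tailLenP,
                                               design$tailLenCap))
      letters <- sample(RNA_LETTERS, sum(lens), TRUE,
                        prob = enz$ntPropensity)
      tail_str[sel] <- vapply(split(letters, rep(seq_along(sel), lens)),
                              paste, "", collapse = "")
    }
  }

  trim3 <- pmax(-off3, 0L)
  ext3 <- pmax(off3, 0L)
  body <- substr(mature[mi], off5 + 1L, L[mi] - trim3)
  ext <- substr(down, 1L, ext3)
  read0 <- paste0(body, ext, tail_str)

  truth <- truth_labels(read0, mi, off5, catalog)
  truth$enzyme <- enzyme
  truth$locus <- locus_id
  reads <- apply_misreads(read0, design$misreadRate, design$agRate)
  truth$read <- reads
  truth$misread <- reads != read0
  truth <- truth[c("mirna", "read", "end_status", "tail", "origin",
                   "enzyme", "locus", "misread")]
  list(condition = condition, replicate = as.integer(replicate),
       reads = reads, truth = truth)
}

# Maximal templated walk from the (known) body start over every locus of
# the read's miRNA; mirrors the classification rules, anchored exactly.
truth_labels <- function(read0, mi, off5, catalog) {
  nm <- mirnaNames(catalog)
  mature <- catalog@mature
  L <- nchar(mature)
  n <- length(read0)
  key <- paste(mi, off5, read0, sep = "\r")
  u <- !duplicated(key)
  ui <- which(u)
  umap <- match(key, key[ui])

  umi <- mi[ui]; uoff <- off5[ui]; ur <- read0[ui]
  body_len <- L[umi] - uoff # templated length up to the annotated end
  loci_by <- split(catalog@loci$downstream, catalog@loci$name)[nm]
  nl <- lengths(loci_by)[umi]
  rid <- rep.int(seq_along(ui), nl)
  dn <- unlist(loci_by[umi], use.names = FALSE)
  template <- paste0(substr(mature[umi], uoff + 1L, L[umi])[rid], dn)
  ml <- common_prefix_len(ur[rid], template)
  fully <- ml == nchar(ur)[rid]
  any_fully <- as.logical(rowsum(as.integer(fully), rid) > 0L)
  max_match <- unname(vapply(split(ml, rid), max, integer(1)))

  rlen <- nchar(ur)
  ext <- ifelse(rlen > body_len, substr(ur, body_len + 1L, rlen), "")
  status <- character(length(ui))
  tail <- character(length(ui))
  origin <- character(length(ui))
  offf <- rlen - body_len
  f <- any_fully
  status[f & offf == 0L] <- "canonical"
  status[f & offf < 0L] <- "trimmed"
  status[f & offf > 0L] <- "tailed"
  tail[f] <- ifelse(offf[f] > 0L, ext[f], "")
  origin[f] <- ifelse(offf[f] > 0L, "ambiguous", "none")
  nt <- !f
  reach <- nt & max_match >= body_len
  status[reach] <- "tailed"
  status[nt & max_match < body_len] <- "trimmed_tailed"
  origin[nt] <- "NT"
  tail[reach] <- ext[reach]
  short <- nt & max_match < body_len
  tail[short] <- substr(ur[short], max_match[short] + 1L, rlen[short])

  data.frame(mirna = nm[mi], end_status = status[umap], tail = tail[umap],
             origin = origin[umap], stringsAsFactors = FALSE)
}

# Per-base substitutions: a uniform channel (rate, to one of the other
# three letters) plus a dedicated A->G channel (agRate).
apply_misreads <- function(reads, rate, agRate) {
  n <- length(reads)
  if (rate > 0) {
    len <- nchar(reads)
    nerr <- rbinom(n, len, rate)
    for (i in which(nerr > 0L)) {
      ch <- strsplit(reads[i], "")[[1]]
      pos <- sample.int(length(ch), min(nerr[i], length(ch)))
      for (p in pos) ch[p] <- sample(setdiff(RNA_LETTERS, ch[p]), 1L)
      reads[i] <- paste(ch, collapse = "")
    }
  }
  if (agRate > 0) {
    nA <- count_letter(reads, "A")
    nflip <- rbinom(n, nA, agRate)
    for (i in which(nflip > 0L)) {
      ch <- strsplit(reads[i], "")[[1]]
      apos <- which(ch == "A")
      ch[sample(apos, min(nflip[i], length(apos)))] <- "G"
      reads[i] <- paste(ch, collapse = "")
    }
  }
  reads
}

#' Simulate a whole experiment (all conditions x replicates)
#'
#' @param catalog a [ReferenceCatalog-class].
#' @param design an [experimentDesign()].
#' @param outDir optional directory; when given, per-library FASTQ
#'   (`<condition>_rep<k>.fastq.gz`), truth TSVs and a YAML manifest are
#'   written there.
#' @return named list of libraries (`<condition>_rep<k>`, see
#'   [simulateLibrary()]) with a `"manifest"` attribute describing files,
#'   seeds and parameters.
#' @export
simulateExperiment <- function(catalog, design, outDir = NULL) {
  libs <- list()
  files <- list()
  for (cond in names(design$conditions)) {
    for (r in seq_len(design$replicates)) {
      id <- sprintf("%s_rep%d", cond, r)
      libs[[id]] <- simulateLibrary(catalog, design, cond, r)
      if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        fq <- file.path(outDir, paste0(id, ".fastq.gz"))
        writeLibraryFastq(libs[[id]], fq)
        tr <- file.path(outDir, paste0(id, ".truth.tsv"))
        write.table(libs[[id]]$truth, tr, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files[[id]] <- list(fastq = fq, truth = tr)
      }
    }
  }
  manifest <- list(
    seed = design$seed, depth = design$depth,
    replicates = design$replicates,
    conditions = lapply(design$conditions, as.list),
    misreadRate = design$misreadRate, agRate = design$agRate,
    competition = design$competition, files = files)
  if (!is.null(outDir))
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  attr(libs, "manifest") <- manifest
  libs
}

#' Write a simulated library as FASTQ
#'
#' Reads are written in the DNA alphabet with a constant quality string.
#'
#' @param lib a library from [simulateLibrary()].
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
writeLibraryFastq <- function(lib, path) {
  x <- Biostrings::DNAStringSet(as_dna(lib$reads))
  names(x) <- sprintf("%s_%s_read%d", lib$condition, lib$replicate,
                      seq_along(x))
  q <- Biostrings::BStringSet(strrep("I", nchar(lib$reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate spike-in references and reads with an A-to-G misread channel
#'
#' Generates spike-in sequences with a known internal A and a terminal A,
#' then sequencing reads in which every A can be misread as G with
#' probability `agRate` (other positions read perfectly).
#'
#' @param nRefs number of spike-in species (default 11).
#' @param refLen spike-in length (default 22).
#' @param depth total reads, split evenly over spike-ins (default 2e5).
#' @param agRate per-base A-to-G misread probability.
#' @param seed RNG seed.
#' @param internalPos position of the annotated internal A (default 15).
#' @return list with `refs` (named sequences), `positions` (data.frame for
#'   [estimateConversionRate()]) and `reads` (data.frame `sequence`,
#'   `count`).
#' @export
simulateSpikeIns <- function(nRefs = 11L, refLen = 22L, depth = 2e5,
                             agRate = 0, seed = 1L, internalPos = 15L) {
  set.seed(seed)
  refs <- vapply(seq_len(nRefs), function(i) {
    s <- sample(RNA_LETTERS, refLen, TRUE)
    s[internalPos] <- "A"
    s[refLen] <- "A"
    paste(s, collapse = "")
  }, "")
  names(refs) <- sprintf("spike%d", seq_len(nRefs))
  positions <- rbind(
    data.frame(name = names(refs), pos = internalPos, class = "internal"),
    data.frame(name = names(refs), pos = refLen, class = "terminal"))
  per <- floor(depth / nRefs)
  out <- list()
  for (i in seq_len(nRefs)) {
    ref <- refs[i]
    if (agRate > 0) {
      ch <- strsplit(ref, "")[[1]]
      apos <- which(ch == "A")
      nflip <- rbinom(per, length(apos), agRate)
      variants <- vapply(which(nflip > 0L), function(k) {
        cc <- ch
        cc[sample(apos, nflip[k])] <- "G"
        paste(cc, collapse = "")
      }, "")
      tab <- c(rep(ref, per - length(variants)), variants)
    } else {
      tab <- rep(ref, per)
    }
    out[[i]] <- collapseReads(tab)
  }
  reads <- do.call(rbind, out)
  agg <- rowsum(reads$count, reads$sequence)
  reads <- data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
                      stringsAsFactors = FALSE)
  list(refs = refs, positions = positions, reads = reads)
}

#' Exact per-miRNA tail and NT-tail probabilities under a design
#'
#' Closed-form ground truth for parameter-recovery checks: for every miRNA,
#' the probability that a (misread-free) read carries a tailing event, and
#' the probability that the read is labelled NT — i.e. the tailing event is
#' not cancelled by coinciding with the genomic continuation at any locus.
#' The latter marginalises analytically over templated 3' offsets, locus
#' choice, the acting enzyme, tail lengths and tail letters, exploiting
#' that for a given decomposition exactly one extension string of each
#' length is templated per locus.
#'
#' `enzymeSensitivities()` and `expressionWeights()` expose the other
#' ground-truth ingredients of a design.
#'
#' @param catalog a [ReferenceCatalog-class].
#' @param design an [experimentDesign()].
#' @param condition condition name.
#' @return data.frame with columns `mirna`, `p_tail`, `p_nt`.
#' @export
ntTailProbability <- function(catalog, design, condition) {
  nm <- mirnaNames(catalog)
  mature <- catalog@mature
  L <- nchar(mature)
  rates <- enzyme_rates(design, catalog, condition)
  rate_mat <- do.call(cbind, rates)
  p_tail <- pmin(rowSums(rate_mat), 1)
  enz_names <- colnames(rate_mat)
  cap <- design$tailLenCap
  len_probs <- lapply(enz_names, function(e) {
    p <- if (e == "precursor") 0.5 else design$enzymes[[e]]$tailLenP
    geom_len_probs(p, cap)
  })
  props <- lapply(enz_names, function(e) {
    if (e == "precursor") setNames(c(0, 0, 0, 1), RNA_LETTERS)
    else design$enzymes[[e]]$ntPropensity
  })
  loci_by <- split(catalog@loci$downstream, catalog@loci$name)

  p_nt <- vapply(seq_along(nm), function(i) {
    if (p_tail[i] == 0) return(0)
    downs <- loci_by[[nm[i]]]
    e_w <- rate_mat[i, ] / sum(rate_mat[i, ])
    # enumerate (3' offset, locus) decompositions
    p_amb_given_tail <- 0
    for (oi in seq_along(design$p3)) {
      o <- as.integer(names(design$p3))[oi]
      po <- design$p3[[oi]]
      for (j in seq_along(downs)) {
        pj <- po / length(downs)
        # continuation strings that keep the read fully templated
        conts <- character(0)
        if (o <= 0) {
          t <- -o
          conts <- unique(vapply(downs, function(d)
            paste0(substr(mature[i], L[i] - t + 1L, L[i]),
                   substr(d, 1L, cap)), ""))
        } else {
          pref <- substr(downs[j], 1L, o)
          ok <- vapply(downs, function(d) substr(d, 1L, o) == pref,
                       logical(1))
          conts <- unique(vapply(downs[ok], function(d)
            substr(d, o + 1L, o + cap), ""))
        }
        # P(tail string == a continuation prefix), per enzyme and length
        p_amb <- 0
        for (e in seq_along(enz_names)) {
          if (e_w[e] == 0) next
          for (l in seq_len(cap)) {
            pres <- unique(substr(conts, 1L, l))
            pres <- pres[nchar(pres) == l]
            if (!length(pres)) next
            pr <- sum(vapply(pres, function(s) {
              prod(props[[e]][strsplit(s, "")[[1]]])
            }, numeric(1)))
            p_amb <- p_amb + e_w[e] * len_probs[[e]][l] * pr
          }
        }
        p_amb_given_tail <- p_amb_given_tail + pj * p_amb
      }
    }
    p_tail[i] * (1 - p_amb_given_tail)
  }, numeric(1))
  data.frame(mirna = nm, p_tail = unname(p_tail), p_nt = unname(p_nt),
             stringsAsFactors = FALSE)
}
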