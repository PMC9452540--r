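test_that("templated/tail decomposition walks mature then genome", {
  catg <- toy_catalog()
  mx <- matureSeqs(catg)[["mirX"]]   # ends ...ACGUAC, downstream AAGG...
  # identity read: everything after the anchor is templated, no tail
  sp <- splitTemplated(mx, "mirX", "L1", catg)
  m0 <- (nchar(mx) - 13L) %/% 2L
  expect_equal(sp$templated_len, nchar(mx) - m0)
  expect_equal(sp$tail_seq, "")
  # extension matching the first downstream base (A) is fully templated
  sp <- splitTemplated(paste0(mx, "A"), "mirX", "L1", catg)
  expect_equal(sp$tail_seq, "")
  expect_equal(sp$templated_len, nchar(mx) - m0 + 1L)
  # a U extension mismatches downstream "AA..." -> tail
  sp <- splitTemplated(paste0(mx, "U"), "mirX", "L1", catg)
  expect_equal(sp$tail_seq, "U")
  # inconsistent anchor is an error
  expect_error(splitTemplated(mx, "mirX", "L1", catg, anchor = 2L),
               "anchor")
  expect_error(splitTemplated(mx, "mirX", "L9", catg), "locus")
})

test_that("templated extensions are ambiguous, others NT, any locus counts", {
  catg <- toy_catalog()
  mx <- matureSeqs(catg)[["mirX"]]
  my <- matureSeqs(catg)[["mirY"]]
  # mirX downstream starts "AA": +A extension is ambiguous mono-A
  r <- classifyIsomir(paste0(mx, "A"), "mirX", catg)
  expect_equal(r$end_status, "tailed")
  expect_equal(r$origin, "ambiguous")
  expect_equal(r$category, "mono_A")
  expect_equal(r$three_prime_offset, 1L)
  # +U extension is NT mono-U
  r <- classifyIsomir(paste0(mx, "U"), "mirX", catg)
  expect_equal(r$origin, "NT")
  expect_equal(r$category, "mono_U")
  # mirY has loci starting "A..." and "U...": U extension matches locus 2
  r <- classifyIsomir(paste0(my, "U"), "mirY", catg)
  expect_equal(r$origin, "ambiguous")
  r <- classifyIsomir(paste0(my, "C"), "mirY", catg)
  expect_equal(r$origin, "NT")
  # canonical and trimmed reads carry no tail
  r <- classifyIsomir(mx, "mirX", catg)
  expect_equal(r$end_status, "canonical")
  expect_equal(r$tail_seq, "")
  expect_equal(r$origin, "none")
  r <- classifyIsomir(substr(mx, 1, nchar(mx) - 2L), "mirX", catg)
  expect_equal(r$end_status, "trimmed")
  expect_equal(r$three_prime_offset, -2L)
  # trimmed body followed by a non-matching letter: trimmed_tailed NT
  bad <- setdiff(c("A", "C", "G", "U"),
                 c(substr(mx, nchar(mx), nchar(mx)), "A"))[1]
  r <- classifyIsomir(paste0(substr(mx, 1, nchar(mx) - 1L), bad),
                      "mirX", catg)
  expect_equal(r$end_status, "trimmed_tailed")
  expect_equal(r$origin, "NT")
  expect_equal(r$tail_seq, bad)
})

test_that("tail categories follow the mono/di/mixed rule table", {
  expect_equal(tailCategory(c("U", "A", "G", "C")),
               c("mono_U", "mono_A", "mono_G", "mono_C"))
  expect_equal(tailCategory(c("AA", "UU", "AU", "UA")),
               c("di_AA", "di_UU", "di_AU", "di_UA"))
  expect_equal(tailCategory(c("UUU", "GC", "AAG", "AG")),
               rep("mixed", 4))
  expect_equal(coarseTailLabel(c("U", "UUU", "A", "AAAA", "AU", "GC")),
               c("U_tail", "U_tail", "A_tail", "A_tail", "Mixed", "Mixed"))
  expect_error(tailCategory(""), "empty")
})

test_that("every read gets exactly one status and fractions partition", {
  catg <- simulateReference(10, seed = 31)
  reads <- random_isomir_reads(catg, 400, seed = 32)
  tab <- collapseReads(reads$sequence)
  asg <- assignLibrary(tab, catg, verbose = FALSE)
  cls <- classifyTable(asg, catg)
  expect_true(all(cls$end_status %in%
    c("canonical", "trimmed", "tailed", "trimmed_tailed")))
  # origin/category are none exactly when the tail is empty
  expect_equal(cls$origin == "none", cls$tail_seq == "")
  expect_equal(cls$category == "none", cls$tail_seq == "")
  # canonical <=> offset 0 and no tail
  expect_equal(cls$end_status == "canonical",
               cls$three_prime_offset == 0L & cls$tail_seq == "")
  prof <- profileCondition(cls, catg)
  m <- mirnaMetrics(prof)
  expect_equal(m$frac_canonical + m$frac_trimmed + m$frac_tailed +
                 m$frac_trimmed_tailed, rep(1, nrow(m)))
})

test_that("classification matches the brute-force enumerator", {
  catg <- simulateReference(10, seed = 41)
  reads <- random_isomir_reads(catg, 500, seed = 42)
  cls <- classifyTable(
    data.frame(mirna = reads$mirna, sequence = reads$sequence,
               count = 1L,
               motif_start = vapply(seq_len(nrow(reads)), function(i)
                 regexpr(motifOf(matureSeqs(catg)[[reads$mirna[i]]], 13L),
                         reads$sequence[i], fixed = TRUE)[1] - 1L,
                 integer(1))),
    catg)
  for (i in seq_len(nrow(reads))) {
    bf <- brute_classify(reads$sequence[i], reads$mirna[i], catg)
    expect_equal(cls$end_status[i], bf$end_status)
    expect_equal(cls$origin[i], bf$origin)
    expect_equal(cls$tail_seq[i], bf$tail)
  }
})

test_that("appending the next genomic base keeps ambiguity, others break it", {
  catg <- simulateReference(8, seed = 51)
  loci <- lociTable(catalog <- catg)
  for (nm in mirnaNames(catg)) {
    mat <- matureSeqs(catg)[[nm]]
    downs <- loci$downstream[loci$name == nm]
    read <- mat
    for (k in 1:3) {
      nxt <- substr(downs[1], k, k)
      read_amb <- paste0(read, nxt)
      r <- classifyIsomir(read_amb, nm, catg)
      expect_true(r$origin %in% c("ambiguous"))
      other <- setdiff(c("A", "C", "G", "U"),
                       substr(downs, k, k))
      if (length(other)) {
        r2 <- classifyIsomir(paste0(read, other[1]), nm, catg)
        expect_equal(r2$origin, "NT")
      }
      read <- read_amb
    }
  }
})

test_that("noiseless simulated reads classify exactly as the truth table", {
  catg <- simulateReference(15, seed = 61)
  des <- experimentDesign(depth = 8000, seed = 61, misreadRate = 0)
  lib <- simulateLibrary(catg, des, "WT", 1)
  asg <- assignLibrary(collapseReads(lib$reads), catg, verbose = FALSE)
  cls <- classifyTable(asg, catg)
  key_t <- paste(lib$truth$mirna, lib$truth$read)
  key_c <- paste(cls$mirna, cls$sequence)
  m <- match(key_t, key_c)
  ok <- !is.na(m)
  expect_gt(mean(ok), 0.99)
  expect_true(all(lib$truth$end_status[ok] == cls$end_status[m[ok]]))
  expect_true(all(lib$truth$origin[ok] == cls$origin[m[ok]]))
  expect_true(all(lib$truth$tail[ok] == cls$tail_seq[m[ok]]))
})

test_that("over-long extensions are flagged and excluded from categories", {
  catg <- toy_catalog()
  mx <- matureSeqs(catg)[["mirX"]]
  long_tail <- strrep("U", 9L)
  r <- classifyIsomir(paste0(mx, long_tail), "mirX", catg)
  expect_true(r$tail_flagged)
  expect_equal(r$origin, "NT")
  cls <- rbind(r, classifyIsomir(paste0(mx, "U"), "mirX", catg))
  cls$count <- c(10L, 90L)
  prof <- profileCondition(cls, catg)
  li <- lengthIdentity(prof)
  expect_true(all(li$tail_len <= maxTailLength(catg)))
})
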