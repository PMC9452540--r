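test_that("read collapsing counts and orders deterministically", {
  expect_equal(collapseReads(c("AAA", "AAA", "CCC")),
               data.frame(sequence = c("AAA", "CCC"), count = c(2L, 1L)))
  expect_equal(collapseReads("ACGU"),
               data.frame(sequence = "ACGU", count = 1L))
  expect_equal(collapseReads(character()),
               data.frame(sequence = character(), count = integer()))
  # count ties break lexicographically, invariant to input order
  set.seed(1)
  reads <- c("GGG", "AAA", "CCC", "AAA", "GGG", "CCC")
  for (i in 1:3) {
    out <- collapseReads(sample(reads))
    expect_equal(out$sequence, c("AAA", "CCC", "GGG"))
    expect_equal(out$count, c(2L, 2L, 2L))
  }
})

test_that("single reads assign by exact central motif with free ends", {
  catg <- toy_catalog()
  mat <- matureSeqs(catg)[["mirX"]]
  # identity read
  a <- assignRead(mat, catg)
  expect_equal(a$mirna, "mirX")
  expect_equal(a$motif_start, (nchar(mat) - 13L) %/% 2L)
  # 3' end mismatches are allowed
  mod <- paste0(substr(mat, 1, nchar(mat) - 2L), "UU")
  expect_equal(assignRead(mod, catg)$mirna, "mirX")
  # a substitution inside the motif kills the match
  s0 <- (nchar(mat) - 13L) %/% 2L
  pos <- s0 + 7L
  bad <- mat
  substr(bad, pos, pos) <- setdiff(c("A", "C", "G", "U"),
                                   substr(mat, pos, pos))[1]
  expect_equal(assignRead(bad, catg)$status, "unassigned")
})

test_that("library assignment conserves counts and separates miRNAs", {
  catg <- toy_catalog()
  mx <- matureSeqs(catg)[["mirX"]]; my <- matureSeqs(catg)[["mirY"]]
  reads <- c(rep(mx, 100), rep(my, 40), rep("GGGGCCCCAAAAUUUUGGGG", 7),
             rep(substr(mx, 1, 10), 5))  # 7 unassignable, 5 too short
  tab <- suppressMessages(assignLibrary(reads, catg))
  stats <- attr(tab, "stats")
  expect_equal(unname(stats["total"]), 152)
  expect_equal(unname(stats["assigned"] + stats["unassigned"] +
                        stats["ambiguous"] + stats["filtered"]),
               unname(stats["total"]))
  expect_equal(unname(stats["filtered"]), 5)
  expect_equal(sum(tab$count[tab$mirna == "mirX"]), 100)
  expect_equal(sum(tab$count[tab$mirna == "mirY"]), 40)
})

test_that("assignment agrees with a brute-force (miRNA, offset) scan", {
  catg <- simulateReference(50, seed = 11)
  reads <- random_isomir_reads(catg, 300, seed = 12)$sequence
  reads <- unique(c(reads, "ACGUACGUACGUACGUACGUACGUA"))
  res <- isotail:::assign_sequences(reads, catg)
  for (i in seq_along(reads)) {
    hits <- brute_assign(reads[i], catg)
    mirnas <- unique(vapply(hits, `[[`, "", "mirna"))
    if (length(mirnas) == 0L) {
      expect_equal(res$status[i], "unassigned")
    } else if (length(mirnas) == 1L) {
      expect_equal(res$mirna[i], mirnas)
      expect_true(res$motif_start[i] %in%
                    vapply(hits, `[[`, 0L, "offset"))
    } else {
      expect_true(res$status[i] %in% c("assigned", "ambiguous"))
      if (res$status[i] == "assigned")
        expect_true(res$mirna[i] %in% mirnas)
    }
  }
})

test_that("assignment is invariant to read order and collapsing", {
  catg <- simulateReference(20, seed = 5)
  des <- experimentDesign(depth = 3000, seed = 5)
  reads <- simulateLibrary(catg, des, "WT", 1)$reads
  t1 <- suppressMessages(assignLibrary(reads, catg, verbose = FALSE))
  set.seed(99)
  t2 <- suppressMessages(assignLibrary(sample(reads), catg, verbose = FALSE))
  expect_identical(t1, t2)
  t3 <- suppressMessages(assignLibrary(collapseReads(reads), catg,
                                       verbose = FALSE))
  expect_identical(t1[names(t1) != "motif_start"],
                   t3[names(t3) != "motif_start"])
})

test_that("simulated libraries assign back to their true miRNA >= 99%", {
  catg <- simulateReference(50, seed = 21)
  des <- experimentDesign(depth = 2e4, seed = 21, misreadRate = 0)
  lib <- simulateLibrary(catg, des, "WT", 1)
  res <- isotail:::assign_sequences(unique(lib$reads), catg)
  truth <- lib$truth$mirna[match(unique(lib$reads), lib$truth$read)]
  ok <- res$status == "assigned" & res$mirna == truth
  expect_gt(mean(ok), 0.99)
})

test_that("collapsed-FASTA and FASTQ inputs read back identically", {
  catg <- toy_catalog()
  mx <- matureSeqs(catg)[["mirX"]]
  reads <- c(rep(mx, 3), paste0(mx, "U"))
  fq <- tempfile(fileext = ".fastq")
  writeLines(c(rbind(paste0("@r", seq_along(reads)),
                     chartr("U", "T", reads),
                     "+", strrep("I", nchar(reads)))), fq)
  fromFq <- readSmallRNA(fq)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">s1_x3\n", mx), paste0(">s2_x1\n", mx, "U")), fa)
  fromFa <- readSmallRNA(fa)
  expect_equal(fromFq, fromFa)
  expect_equal(sum(fromFq$count), 4L)
})
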