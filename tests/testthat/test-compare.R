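test_that("cumulative curves are ECDFs on the bin grid", {
  cc <- cumulativeCurve(c(0.5, 1, 2), rep("NT", 3), edges = c(0.25, 1, 4))
  expect_equal(cc$frac, c(0, 2 / 3, 1))
  # all-equal fold-changes give a step function at 1
  cc <- cumulativeCurve(rep(1, 10), rep("NT", 10),
                        edges = c(0.5, 0.99, 1, 2))
  expect_equal(cc$frac, c(0, 0, 1, 1))
  # brute-force empirical CDF agreement on random inputs
  set.seed(3)
  fc <- rlnorm(500, 0, 1)
  cls <- sample(c("canonical", "NT"), 500, TRUE)
  cc <- cumulativeCurve(fc, cls)
  for (k in sample(nrow(cc), 20)) {
    sel <- fc[cls == cc$class[k]]
    expect_equal(cc$frac[k], sum(sel <= cc$edge[k]) / length(sel))
  }
  # monotone non-decreasing, last bin 1 when edges cover the range
  for (cl in unique(cc$class)) {
    f <- cc$frac[cc$class == cl]
    expect_true(all(diff(f) >= 0))
  }
  expect_error(cumulativeCurve(c(1, -2), c("a", "a")), "positive")
  expect_warning(cumulativeCurve(numeric(), character()), NA)
})

test_that("sensitivity consensus is the intersection of both rankings", {
  c1 <- data.frame(mirna = c("m1", "m2", "m3"), fc = c(0.1, 0.5, 0.9))
  c2 <- data.frame(mirna = c("m1", "m2", "m3"), fc = c(0.1, 0.9, 0.5))
  out <- sensitivityRanking(c1, c2, topN = 1L)
  expect_equal(out$mirna, "m1")
  # identical comparisons: consensus equals the top-N set
  out_same <- sensitivityRanking(c1, c1, topN = 2L)
  expect_setequal(out_same$mirna, c("m1", "m2"))
  # permutation invariance and idempotence
  perm <- sample(3)
  out2 <- sensitivityRanking(c1[perm, ], c2[perm, ], topN = 1L)
  expect_equal(out, out2)
  expect_error(sensitivityRanking(c1, c2, topN = 5L), "universe")
})

test_that("terminal-nucleotide composition and enrichment behave", {
  mature <- setNames(
    paste0(strrep("C", 21), c("G", "G", "G", "U", "A", "C", "G", "U")),
    paste0("m", 1:8))
  catg <- referenceCatalog(
    mature, data.frame(name = names(mature), locus_id = "L1",
                       downstream = strrep("A", 20)))
  comp <- terminalNtComposition(paste0("m", 1:4), catg, paste0("m", 1:8))
  expect_equal(comp$set_pct[comp$letter == "G"], 75)
  # set == background: all ratios 1
  comp <- terminalNtComposition(names(mature), catg, names(mature))
  expect_equal(comp$ratio[!is.na(comp$ratio)],
               rep(1, sum(!is.na(comp$ratio))))
})

test_that("Pearson correlation of profiles matches expectations", {
  a <- c(1, 10, 100, 1000)
  expect_equal(correlateProfiles(a, a), 1)
  expect_equal(correlateProfiles(a, -a, log = FALSE), -1)
  set.seed(17)
  n <- 1000
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  r <- correlateProfiles(exp(x), exp(y))
  expect_true(r > 0.75 && r < 0.85)
  expect_error(correlateProfiles(1:2, 1:2), "3 paired")
  expect_error(correlateProfiles(rep(1, 5), 1:5), "variance")
})

test_that("the Wilcoxon wrapper is symmetric and calibrated", {
  set.seed(23)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(wilcoxonCompare(x, y), wilcoxonCompare(y, x))
  # location shift of 1 SD at n = 100 is detected
  set.seed(24)
  hits <- mean(replicate(50, {
    wilcoxonCompare(rnorm(100), rnorm(100, 1)) < 0.05
  }))
  expect_gt(hits, 0.95)
  expect_error(wilcoxonCompare(1:2, 1:5), "n >= 3")
  expect_error(wilcoxonCompare(1:5, 1:5, paired = TRUE), "degenerate")
})

test_that("comparing a condition with itself is the identity comparison", {
  catg <- simulateReference(10, seed = 81)
  des <- experimentDesign(depth = 5000, seed = 81)
  lib <- simulateLibrary(catg, des, "WT", 1)
  asg <- assignLibrary(collapseReads(lib$reads), catg, verbose = FALSE)
  cls <- classifyTable(asg, catg)
  cmp <- compareConditions(cls, cls, conditions = c("WT", "WT"))
  fc <- isomirFoldChanges(cmp)
  expect_true(all(abs(fc$fc - 1) < 1e-12))
  expect_true(all(fc$heat == 100))
  m <- mirnaFoldChanges(cmp)
  expect_true(all(abs(m$log2_fc) < 1e-12))
  # cumulative curves jump to 1 at fold-change 1
  cv <- tailingCurves(cmp)
  expect_true(all(cv$frac[cv$edge >= 1] == 1))
  expect_true(all(cv$frac[cv$edge < 1] == 0))
  # heatmap never exceeds the cap on a real contrast
  lib2 <- simulateLibrary(catg, des, "TKO", 1)
  cls2 <- classifyTable(
    assignLibrary(collapseReads(lib2$reads), catg, verbose = FALSE), catg)
  cmp2 <- compareConditions(cls, cls2, conditions = c("WT", "TKO"))
  expect_true(all(isomirFoldChanges(cmp2)$heat <= 100))
})

test_that("uridylation fold-changes correlate across independent KO contrasts", {
  # TUT4 loss measured in two genetic backgrounds shares the miRNA-specific
  # uridylation propensity, so per-miRNA responses should agree
  catg <- simulateReference(60, seed = 91)
  des <- experimentDesign(depth = 4e4, seed = 91, replicates = 1)
  cls <- function(cond) {
    lib <- simulateLibrary(catg, des, cond, 1)
    classifyTable(assignLibrary(collapseReads(lib$reads), catg,
                                verbose = FALSE), catg)
  }
  wt <- cls("WT"); t4 <- cls("TUT4KO"); t7 <- cls("TUT7KO"); dk <- cls("DKO")
  cmp1 <- compareConditions(wt, t4, conditions = c("WT", "TUT4KO"))
  cmp2 <- compareConditions(t7, dk, conditions = c("TUT7KO", "DKO"))
  m1 <- mirnaFoldChanges(cmp1); m2 <- mirnaFoldChanges(cmp2)
  shared <- intersect(m1$mirna, m2$mirna)
  r <- cor(log2(m1$fc_pct_U[match(shared, m1$mirna)]),
           log2(m2$fc_pct_U[match(shared, m2$mirna)]))
  expect_gt(r, 0.3)
})
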