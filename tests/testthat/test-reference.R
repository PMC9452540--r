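test_that("loading a mature FASTA with a context table builds a catalog", {
  fa <- write_toy_fasta(c(mirX = "ACGUACGUACGUACGUACGUAC"),
                        tempfile(fileext = ".fa"))
  ctx <- data.frame(name = "mirX", locus_id = "L1",
                    downstream = "AAGGAAGGAAGGAAGGAAGG")
  tsv <- tempfile(fileext = ".tsv")
  write.table(ctx, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cat1 <- loadReference(fa, tsv)
  expect_s4_class(cat1, "ReferenceCatalog")
  expect_equal(mirnaNames(cat1), "mirX")
  expect_equal(nrow(lociTable(cat1)), 1L)

  # DNA spelling of the same entry gives an identical catalog
  fa_t <- write_toy_fasta(c(mirX = "ACGTACGTACGTACGTACGTAC"),
                          tempfile(fileext = ".fa"))
  cat2 <- loadReference(fa_t, tsv)
  expect_identical(matureSeqs(cat1), matureSeqs(cat2))
  expect_identical(lociTable(cat1), lociTable(cat2))
})

test_that("downstream contexts must cover the configured max tail length", {
  mature <- c(mirX = "ACGUACGUACGUACGUACGUAC")
  ok <- data.frame(name = "mirX", locus_id = "L1",
                   downstream = "AAGGAAGGAA")  # 10 nt
  expect_s4_class(referenceCatalog(mature, ok, maxTailLen = 8L),
                  "ReferenceCatalog")
  short <- data.frame(name = "mirX", locus_id = "L1",
                      downstream = "AAGGAA")   # 6 nt
  expect_error(referenceCatalog(mature, short, maxTailLen = 8L),
               "maxTailLen")
})

test_that("catalog validation rejects malformed input", {
  mature <- c(mirX = "ACGUACGUACGUACGUACGUAC")
  ctx <- data.frame(name = "mirX", locus_id = "L1",
                    downstream = "AAGGAAGGAAGGAAGGAAGG")
  expect_error(referenceCatalog(c(mirX = "ACGXACGUACGUACGUACGUAC"), ctx),
               "non-ACGU")
  expect_error(referenceCatalog(mature, rbind(ctx, ctx)), "duplicate")
  expect_error(
    referenceCatalog(mature, data.frame(name = "other", locus_id = "L1",
                                        downstream = ctx$downstream)),
    "locus|unknown")
  fa <- write_toy_fasta(mature, tempfile(fileext = ".fa"))
  expect_error(loadReference(fa, data.frame(name = "other", locus_id = "L1",
                                            downstream = ctx$downstream)),
               "lacking context")
  expect_error(loadReference("/no/such/file.fa", ctx), "not found")
})

test_that("the central motif follows the centering rule", {
  s <- "ACGUACGUACGUACGUACGUAC"  # length 22
  # floor((22-13)/2) = 4 -> 0-based 4..16
  expect_equal(motifOf(s, 13L), substr(s, 5, 17))
  expect_equal(motifOf(s, nchar(s)), s)
  expect_error(motifOf(s, 23L), "exceeds")
  # motif is a substring of the mature sequence for all catalog entries
  catg <- simulateReference(50, seed = 42)
  motifs <- motifOf(matureSeqs(catg), motifLength(catg))
  expect_true(all(mapply(grepl, motifs, matureSeqs(catg), fixed = TRUE)))
})

test_that("miRNAs sharing a central motif share one motif index key", {
  # constructed so the central 13-mers coincide
  mature <- c(mirA = "AAAACGUACGUACGUACGAAA",
              mirB = "UUUACGUACGUACGUACGUUU")
  motifs <- motifOf(mature, 13L)
  expect_equal(unname(motifs[1]), unname(motifs[2]))
  ctx <- data.frame(name = c("mirA", "mirB"), locus_id = "L1",
                    downstream = "AAGGAAGGAAGGAAGGAAGG")
  catg <- referenceCatalog(mature, ctx)
  idx <- motifIndex(catg)
  expect_length(idx, 1L)
  expect_setequal(idx[[1]], c("mirA", "mirB"))
})

test_that("context tables round-trip through write and reload", {
  catg <- toy_catalog()
  tsv <- writeContextTable(catg, tempfile(fileext = ".tsv"))
  fa <- write_toy_fasta(matureSeqs(catg), tempfile(fileext = ".fa"))
  catg2 <- loadReference(fa, tsv)
  expect_identical(matureSeqs(catg), matureSeqs(catg2))
  expect_identical(lociTable(catg), lociTable(catg2))
  expect_identical(motifIndex(catg), motifIndex(catg2))
})

test_that("context extraction from genome + GFF3 matches direct slicing", {
  # hand-indexed example: k=3, plus-strand feature ending at 3
  gdir <- tempfile(); dir.create(gdir)
  gfa <- file.path(gdir, "g.fa")
  writeLines(c(">chr1", "AAACCCGGG"), gfa)
  gff <- file.path(gdir, "g.gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tmiRNA\t1\t3\t.\t+\t.\tID=f1;Name=mirP"),
             gff)
  ctx <- buildContextTable(gfa, gff, k = 3L)
  expect_equal(ctx$downstream, "CCC")

  # strand symmetry: minus-strand feature starting at p reads back the
  # reverse complement of S[p-k .. p-1]
  writeLines(c("##gff-version 3",
               "chr1\ttest\tmiRNA\t7\t9\t.\t-\t.\tID=f2;Name=mirM"),
             gff)
  ctx <- buildContextTable(gfa, gff, k = 3L)
  expect_equal(ctx$downstream, "GGG")  # revcomp of CCC

  # oracle equivalence on a simulated genome: direct string slicing
  set.seed(9)
  contig <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  writeLines(c(">chr1", contig), gfa)
  starts <- c(50L, 120L, 200L)
  ends <- starts + 21L
  strands <- c("+", "-", "+")
  writeLines(c("##gff-version 3", sprintf(
    "chr1\ttest\tmiRNA\t%d\t%d\t.\t%s\t.\tID=f%d;Name=m%d",
    starts, ends, strands, seq_along(starts), seq_along(starts))), gff)
  ctx <- buildContextTable(gfa, gff, k = 10L)
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (i in seq_along(starts)) {
    expected <- if (strands[i] == "+")
      substr(contig, ends[i] + 1L, ends[i] + 10L)
    else rc(substr(contig, starts[i] - 10L, starts[i] - 1L))
    expect_equal(ctx$downstream[i], chartr("T", "U", expected))
  }

  # errors: feature beyond contig end, unknown strand
  writeLines(c("##gff-version 3",
               "chr1\ttest\tmiRNA\t395\t400\t.\t+\t.\tID=f1;Name=mE"),
             gff)
  expect_error(buildContextTable(gfa, gff, k = 10L), "contig end")
})
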