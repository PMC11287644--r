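# build a replicate track list in which the element at [1001, 2000] is
# covered in the first k replicates
repsCovering <- function(k, nReps = 3) {
  lapply(seq_len(nReps), function(r)
    if (r <= k) GRanges("chr1", IRanges(901, 2100)) else GRanges())
}

elementAt <- function(kind, chrom = "chr1", start = 1001, end = 2000) {
  e <- GRanges(chrom, IRanges(start, end))
  mcols(e)$kind <- kind
  mcols(e)$element_id <- paste0(kind, "_1")
  e
}

test_that("replicate support counts overlapping replicates", {
  e <- elementAt("enhancer")
  expect_equal(replicateSupport(e, repsCovering(3)), 3L)
  expect_equal(replicateSupport(e, repsCovering(0)), 0L)
  expect_equal(replicateSupport(e, repsCovering(2)), 2L)
  expect_true(replicateSupport(e, repsCovering(2)) <= 3)
})

test_that("activity calls match the truth-table over all evidence combos", {
  # all combinations of ATAC presence x replicate counts 0..3 for the
  # required mark, H3K27ac and the off-target mark, for both element kinds
  grid <- expand.grid(kind = c("enhancer", "promoter"),
                      atac = c(TRUE, FALSE), req = 0:3, k27 = 0:3,
                      off = 0:3, stringsAsFactors = FALSE)
  n <- nrow(grid)
  pos <- seq_len(n) * 10000
  els <- GRanges("chr1", IRanges(pos + 1, pos + 1000))
  mcols(els)$kind <- grid$kind
  mcols(els)$element_id <- sprintf("e%03d", seq_len(n))
  cover <- function(sel) if (any(sel))
    GRanges("chr1", IRanges(pos[sel] + 1, pos[sel] + 1000)) else GRanges()
  reqMark <- ifelse(grid$kind == "promoter", "H3K4me3", "H3K4me1")
  offMark <- ifelse(grid$kind == "promoter", "H3K4me1", "H3K4me3")
  chip <- lapply(c(H3K4me1 = "H3K4me1", H3K4me3 = "H3K4me3",
                   H3K27ac = "H3K27ac"), function(m)
    lapply(1:3, function(r)
      cover((reqMark == m & grid$req >= r) |
              (offMark == m & grid$off >= r) |
              (m == "H3K27ac" & grid$k27 >= r))))
  ev <- peakEvidence(cover(grid$atac), chip)
  called <- classifyActivity(els, ev, chipMinReps = 2)
  truth <- grid$atac & grid$req >= 2 & grid$k27 >= 2
  expect_identical(unname(mcols(called)$active), unname(truth))
  expect_identical(unname(ifelse(grid$kind == "promoter",
                                 mcols(called)$k4me3_reps,
                                 mcols(called)$k4me1_reps)),
                   as.integer(grid$req))
})

test_that("activity is monotone in the evidence and has the degenerate limit", {
  e <- elementAt("promoter")
  partial <- peakEvidence(GRanges("chr1", IRanges(1, 3000)),
                          list(H3K4me1 = repsCovering(0),
                               H3K4me3 = repsCovering(2),
                               H3K27ac = repsCovering(1)))
  expect_false(mcols(classifyActivity(e, partial))$active)
  more <- peakEvidence(partial$atac,
                       list(H3K4me1 = repsCovering(1),
                            H3K4me3 = repsCovering(3),
                            H3K27ac = repsCovering(3)))
  expect_true(mcols(classifyActivity(e, more))$active)
  # chipMinReps = 0 plus genome-wide ATAC makes everything active
  everywhere <- peakEvidence(GRanges("chr1", IRanges(1, 1e6)),
                             list(H3K4me1 = repsCovering(0),
                                  H3K4me3 = repsCovering(0),
                                  H3K27ac = repsCovering(0)))
  both <- c(elementAt("promoter"), elementAt("enhancer", start = 5001,
                                             end = 6000))
  mcols(both)$element_id <- c("p1", "e1")
  expect_true(all(mcols(classifyActivity(both, everywhere,
                                         chipMinReps = 0))$active))
  bad <- elementAt("promoter")
  mcols(bad)$kind <- "silencer"
  expect_error(classifyActivity(bad, partial), "unknown element kind")
})

test_that("k-of-n consensus peaks require the replicate quorum per base", {
  reps <- list(GRanges("chr1", IRanges(1, 100)),
               GRanges("chr1", IRanges(51, 150)),
               GRanges("chr1", IRanges(61, 90)))
  cons <- consensusPeaks(reps, 2)
  expect_equal(start(cons), 51)
  expect_equal(end(cons), 100)
})

test_that("promoter-gene annotation matches a linear point-in-window scan", {
  p <- elementAt("promoter", start = 2001, end = 2500)
  genes <- data.frame(gene_id = c("near_up", "far_down"),
                      chrom = "chr1", tss = c(1000, 5000),
                      strand = c("+", "+"))
  got <- annotatePromoterGenes(p, genes)
  expect_equal(got$gene_id, "near_up")   # 1500 bp upstream captured
  set.seed(99)
  genes2 <- data.frame(gene_id = sprintf("g%02d", 1:50), chrom = "chr1",
                       tss = sample(10000, 50), strand = "+")
  got2 <- annotatePromoterGenes(p, genes2, up = 1500, down = 500)
  inWin <- genes2$tss >= start(p) - 1500 & genes2$tss <= end(p) + 500
  expect_setequal(got2$gene_id, genes2$gene_id[inWin])
})
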