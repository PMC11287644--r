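test_that("credible-set filtering uses a strict posterior threshold", {
  v <- data.frame(rsid = c("a", "b", "c", "d"), chrom = "chr1",
                  pos = 1:4 * 100, signal_id = "S1", lead_rsid = "a",
                  phenotype = "knee_oa", pp = c(0.04, 0.02, 0.03, 0.5))
  kept <- filterCredible(v)
  expect_setequal(kept$rsid, c("a", "d"))   # 0.03 exactly is dropped
  expect_equal(unname(attr(kept, "signal_counts")["S1"]), 2L)
  expect_equal(nrow(filterCredible(v[0, ])), 0L)
  v$pp[1] <- 1.2
  expect_error(filterCredible(v), "pp outside")
})

# a hand-planted scene: two chained loops plus one enhancer-promoter loop
#   L1: E1(variant) -- A2 holds only active enhancer E2
#   L2: shares A2 -- far anchor holds active promoter P1 (gene G1)
#   L3: E3(variant) -- active promoter P2 (gene G2); also inactive promoter
fixtureScene <- function() {
  loops <- LoopSet(
    GRanges("chr1", IRanges(c(10001, 50001, 110001), width = 5000)),
    GRanges("chr1", IRanges(c(50001, 90001, 150001), width = 5000)),
    caller = "m", loopId = c("L1", "L2", "L3"))
  els <- GRanges("chr1", IRanges(c(12001, 52001, 92001, 112001, 152001,
                                   153501),
                                 width = 800))
  mcols(els)$kind <- c("enhancer", "enhancer", "promoter", "enhancer",
                       "promoter", "promoter")
  mcols(els)$element_id <- c("E1", "E2", "P1", "E3", "P2", "Pinact")
  mcols(els)$active <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  genes <- data.frame(gene_id = c("G1", "G2", "Gfar"), chrom = "chr1",
                      tss = c(92101, 152101, 200000), strand = "+")
  vars <- data.frame(rsid = c("v1", "v3", "vanchor", "vout"),
                     chrom = "chr1", pos = c(12400, 112400, 14000, 30000),
                     signal_id = c("S1", "S2", "S1", "S2"),
                     lead_rsid = "v1", phenotype = "knee_oa",
                     pp = c(0.2, 0.3, 0.1, 0.1))
  list(loops = loops, els = els, genes = genes, vars = vars)
}

test_that("anchor overlay matches a brute-force containment scan", {
  fx <- fixtureScene()
  hits <- variantsInAnchors(fx$vars, fx$loops)
  # nested-loop oracle over every (variant, loop, side)
  oracle <- list()
  for (i in seq_len(nrow(fx$vars))) {
    for (j in seq_len(length(fx$loops))) {
      for (side in c("fwd", "rev")) {
        a <- if (side == "fwd") anchorFwd(fx$loops)[j] else
          anchorRev(fx$loops)[j]
        if (fx$vars$chrom[i] == as.vector(seqnames(a)) &&
            fx$vars$pos[i] >= start(a) && fx$vars$pos[i] <= end(a))
          oracle[[length(oracle) + 1L]] <-
            paste(fx$vars$rsid[i], loopIds(fx$loops)[j], side)
      }
    }
  }
  expect_setequal(paste(hits$rsid, hits$loop_id, hits$side),
                  unlist(oracle))
  expect_false("vout" %in% hits$rsid)
  s <- attr(hits, "summary")
  expect_equal(s$n_variants, 3L)
})

test_that("only variants inside active anchor-overlapping enhancers survive", {
  fx <- fixtureScene()
  hits <- variantsInAnchors(fx$vars, fx$loops)
  snpEnh <- variantsInActiveEnhancers(hits, fx$els)
  expect_setequal(snpEnh$rsid, c("v1", "v3"))
  expect_setequal(snpEnh$enhancer_id, c("E1", "E3"))
  # an inactive enhancer never qualifies
  els2 <- fx$els
  mcols(els2)$active[mcols(els2)$element_id == "E1"] <- FALSE
  expect_setequal(variantsInActiveEnhancers(hits, els2)$rsid, "v3")
})

test_that("one-hop chains link variant enhancers to opposite-anchor promoters", {
  fx <- fixtureScene()
  snpEnh <- variantsInActiveEnhancers(variantsInAnchors(fx$vars, fx$loops),
                                      fx$els)
  ep <- buildEpChains(snpEnh, fx$loops, fx$els, fx$genes)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$rsid, "v3")
  expect_equal(ep$promoter_id, "P2")
  expect_equal(ep$gene_ids, "G2")
  expect_equal(ep$n_hops, 1L)
  # the inactive promoter on the same anchor contributes nothing
  expect_false("Pinact" %in% ep$promoter_id)
  # deactivating P2 removes the chain entirely
  els2 <- fx$els
  mcols(els2)$active[mcols(els2)$element_id == "P2"] <- FALSE
  expect_equal(nrow(buildEpChains(snpEnh, fx$loops, els2, fx$genes)), 0L)
})

test_that("two-hop chains require an enhancer-only intermediate anchor", {
  fx <- fixtureScene()
  snpEnh <- variantsInActiveEnhancers(variantsInAnchors(fx$vars, fx$loops),
                                      fx$els)
  ee <- buildEeChains(snpEnh, fx$loops, fx$els, fx$genes)
  expect_equal(nrow(ee), 1L)
  expect_equal(ee$rsid, "v1")
  expect_equal(ee$hop_enhancer_id, "E2")
  expect_equal(ee$promoter_id, "P1")
  expect_equal(ee$loop_ids, "L1,L2")
  expect_equal(ee$n_hops, 2L)
  # an active promoter on the intermediate anchor suppresses the hop
  extra <- GRanges("chr1", IRanges(53001, 53800))
  mcols(extra)$kind <- "promoter"
  mcols(extra)$element_id <- "Pmid"
  mcols(extra)$active <- TRUE
  els2 <- c(fx$els, extra)
  expect_equal(nrow(buildEeChains(snpEnh, fx$loops, els2, fx$genes)), 0L)
  # no second loop from the intermediate anchor: no chain
  expect_equal(nrow(buildEeChains(snpEnh, fx$loops[c(1, 3)], fx$els,
                                  fx$genes)), 0L)
})

test_that("cCRE-free anchors are screened with the enhancer evidence rule", {
  loops <- LoopSet(
    GRanges("chr1", IRanges(c(10001, 110001, 210001), width = 5000)),
    GRanges("chr1", IRanges(c(50001, 150001, 250001), width = 5000)),
    caller = "m", loopId = c("La", "Lb", "Lc"))
  ccre <- GRanges("chr1", IRanges(52001, 52800))  # inside La's rev anchor
  mk <- function(w) GRanges("chr1", IRanges(w[1], w[2]))
  marked <- c(111001, 113000)  # inside Lb's fwd anchor
  ev <- peakEvidence(mk(marked),
                     list(H3K4me1 = list(mk(marked), mk(marked), GRanges()),
                          H3K4me3 = list(GRanges(), GRanges(), GRanges()),
                          H3K27ac = list(mk(marked), mk(marked),
                                         mk(marked))))
  out <- screenNoCcreAnchors(loops, ccre, ev)
  # La is excluded entirely (one anchor has a cCRE); only Lb's marked
  # forward anchor qualifies; Lc has no evidence
  expect_equal(length(out), 1L)
  expect_equal(mcols(out)$loop_id, "Lb")
  expect_equal(mcols(out)$side, "fwd")
})

test_that("QTL joining groups records by variant and deduplicates", {
  chains <- data.frame(signal_id = "S1", rsid = c("v1", "v2"),
                       phenotype = "knee_oa", enhancer_id = "E",
                       hop_enhancer_id = NA, promoter_id = "P",
                       gene_ids = "G", loop_ids = "L", n_hops = 1L)
  qtls <- data.frame(rsid = c("v1", "v1", "v1", "zzz"),
                     qtl_type = c("methQTL", "eQTL", "methQTL", "pQTL"),
                     target = c("cg001", "G", "cg001", "T"),
                     grade = c("low", "high", "low", "low"),
                     beta = 0.1, se = 0.05, p = 1e-6)
  expect_warning(joined <- joinQtls(chains, qtls), "duplicate")
  expect_equal(joined$qtls[joined$rsid == "v1"],
               "eQTL:G:high,methQTL:cg001:low")
  expect_equal(joined$qtls[joined$rsid == "v2"], "")
  # grouping equals a direct filter
  expect_setequal(strsplit(joined$qtls[1], ",")[[1]],
                  unique(sprintf("%s:%s:%s", qtls$qtl_type[qtls$rsid == "v1"],
                                 qtls$target[qtls$rsid == "v1"],
                                 qtls$grade[qtls$rsid == "v1"])))
})

test_that("LD r-squared is the squared Pearson correlation of dosages", {
  g <- c(0, 1, 2, 1, 0, 2)
  expect_equal(ldR2(g, g), 1.0)
  expect_equal(ldR2(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1.0)
  set.seed(5)
  for (k in 1:20) {
    g1 <- sample(0:2, 100, replace = TRUE)
    g2 <- sample(0:2, 100, replace = TRUE)
    expect_equal(ldR2(g1, g2), cor(g1, g2)^2, tolerance = 1e-12)
  }
  expect_error(ldR2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_error(ldR2(1:3, 1:4), "length")
})
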