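writeBedpe <- function(rows) {
  tmp <- withr::local_tempfile(fileext = ".bedpe",
                               .local_envir = parent.frame())
  writeLines(rows, tmp)
  tmp
}

test_that("BEDPE parsing canonicalises anchors and excludes trans rows", {
  f <- writeBedpe(c("chr1\t10000\t15000\tchr1\t90000\t95000",
                    "chr1\t90000\t95000\tchr1\t10000\t15000",
                    "chr1\t10000\t15000\tchr2\t90000\t95000"))
  ls <- suppressMessages(readLoopsBedpe(f, "mustache", 5000))
  expect_equal(length(ls), 2L)
  expect_equal(start(anchorFwd(ls)), c(10001, 10001))
  expect_equal(end(anchorRev(ls)), c(95000, 95000))
  expect_equal(loopMeta(ls)$n_interchromosomal_excluded, 1L)
})

test_that("malformed BEDPE rows fail with the offending line number", {
  f <- writeBedpe(c("chr1\t1\t2\tchr1\t5\t6",
                    "chr1\t1\tchr1\t5\t6"))
  expect_error(readLoopsBedpe(f, "c", 5000), "line 2")
  f2 <- writeBedpe(c("chr1\t100\t50\tchr1\t500\t600"))
  expect_error(readLoopsBedpe(f2, "c", 5000), "end <= start at line 1")
})

test_that("resolution merging groups loops whose anchors both overlap", {
  a <- dfAsLoopSet(data.frame(chrom = "chr1", f_start = 1001, f_end = 6000,
                              r_start = 50001, r_end = 55000, caller = "m"),
                   prefix = "r5_")
  b <- dfAsLoopSet(data.frame(chrom = "chr1", f_start = 501, f_end = 10500,
                              r_start = 48001, r_end = 58000, caller = "m"),
                   prefix = "r10_")
  m <- mergeResolutions(a, b)
  expect_equal(length(m), 1L)
  expect_equal(start(anchorFwd(m)), 501)
  expect_equal(end(anchorFwd(m)), 10500)
  expect_equal(end(anchorRev(m)), 58000)
  # overlapping forward but disjoint reverse anchors: both retained
  d <- dfAsLoopSet(data.frame(chrom = "chr1",
                              f_start = c(1001, 2001), f_end = c(6000, 7000),
                              r_start = c(50001, 90001),
                              r_end = c(55000, 95000), caller = "m"))
  expect_equal(length(mergeResolutions(d)), 2L)
  bad <- dfAsLoopSet(data.frame(chrom = "chr1", f_start = 1, f_end = 10,
                                r_start = 100, r_end = 110, caller = "other"))
  expect_error(mergeResolutions(a, bad), "single caller")
})

test_that("loop merging equals the union-find oracle on jittered fixtures", {
  set.seed(11)
  for (rep in 1:5) {
    df <- randomJitteredLoops(15, "m")  # 30 jittered loops, one caller
    got <- loopSetAsDf(mergeResolutions(dfAsLoopSet(df)))
    expect_equal(got[1:5], oracleLoopMerge(df)[1:5],
                 ignore_attr = TRUE)
  }
})

test_that("cross-caller union tracks supporting callers and matches the oracle", {
  set.seed(12)
  df <- randomJitteredLoops(8, c("fanc", "mustache", "sip"))
  byCaller <- lapply(split(df, df$caller), dfAsLoopSet)
  got <- loopSetAsDf(unionAcrossCallers(byCaller))
  expect_equal(got, oracleLoopMerge(df), ignore_attr = TRUE)
  # one caller passes through with provenance unchanged
  one <- byCaller[[1]]
  u1 <- unionAcrossCallers(byCaller[1])
  expect_setequal(loopCallers(u1), unique(loopCallers(one)))
})

test_that("merging is idempotent, order-independent and union-covering", {
  set.seed(13)
  df <- randomJitteredLoops(10, c("a", "b"))
  ls <- dfAsLoopSet(df)
  m1 <- unionAcrossCallers(list(ls))
  m2 <- unionAcrossCallers(list(m1))
  expect_equal(loopSetAsDf(m2), loopSetAsDf(m1))
  expect_true(length(m1) <= length(ls))
  perm <- sample(nrow(df))
  mP <- unionAcrossCallers(list(dfAsLoopSet(df[perm, ])))
  expect_equal(loopSetAsDf(mP), loopSetAsDf(m1))
  # every output anchor contains all member anchors of its component
  o <- oracleLoopMerge(df)
  g <- loopSetAsDf(m1)
  expect_equal(g$f_start, o$f_start)
  expect_equal(g$r_end, o$r_end)
})

test_that("self-overlapping loops are removed and counted", {
  df <- data.frame(chrom = "chr1",
                   f_start = c(1, 1), f_end = c(10000, 5000),
                   r_start = c(5001, 50001), r_end = c(20000, 55000),
                   caller = "m")
  ls <- dfAsLoopSet(df)
  kept <- dropSelfOverlapping(ls)
  expect_equal(length(kept), 1L)
  expect_equal(loopMeta(kept)$n_self_overlap_removed, 1L)
  expect_equal(length(kept) + loopMeta(kept)$n_self_overlap_removed,
               length(ls))
  empty <- dropSelfOverlapping(ls[integer()])
  expect_equal(length(empty), 0L)
})

test_that("CTCF anchor QC counts motif-bearing anchors exactly", {
  n <- 80
  f <- GRanges("chr1", IRanges(seq_len(n) * 10000 + 1, width = 1000))
  r <- GRanges("chr1", IRanges(seq_len(n) * 10000 + 5001, width = 1000))
  ls <- LoopSet(f, r, caller = "m")
  allFwd <- GRanges("chr1", IRanges(start(f) + 10, width = 19))
  qc <- ctcfQc(ls, allFwd)
  expect_equal(qc$ctcf_fwd_ratio, 1.0)
  expect_equal(qc$ctcf_rev_ratio, 0.0)
  expect_equal(ctcfQc(ls, GRanges())$ctcf_fwd_ratio, 0.0)
  # planted 60-of-80 forward hits
  some <- GRanges("chr1", IRanges(start(f)[1:60] + 10, width = 19))
  expect_equal(ctcfQc(ls, some)$ctcf_fwd_ratio, 0.75)
  expect_equal(ctcfQc(ls[integer()], some)$n_loops, 0L)
})

test_that("TAD boundary CTCF coverage is the planted fraction", {
  b <- GRanges("chr1", IRanges(seq_len(1000) * 20000 + 1, width = 10000))
  motifs <- GRanges("chr1", IRanges(start(b)[1:997] + 100, width = 19))
  expect_equal(tadBoundaryCtcfCoverage(b, motifs), 0.997)
  expect_equal(tadBoundaryCtcfCoverage(b, GRanges()), 0)
  expect_equal(tadBoundaryCtcfCoverage(b[1:10], motifs), 1)
  expect_error(tadBoundaryCtcfCoverage(GRanges(), motifs), "empty")
})

test_that("LoopSet validity rejects trans and mis-ordered loops", {
  expect_error(new("LoopSet",
                   anchor1 = GRanges("chr1", IRanges(1, 10)),
                   anchor2 = GRanges("chr2", IRanges(100, 110)),
                   loopData = S4Vectors::DataFrame(loop_id = "x",
                                                   callers = "c",
                                                   resolutions = "5000"),
                   metadata = list()),
               "intra-chromosomal")
  # the constructor swaps reversed pairs instead
  ls <- LoopSet(GRanges("chr1", IRanges(500, 600)),
                GRanges("chr1", IRanges(1, 10)), caller = "m")
  expect_equal(start(anchorFwd(ls)), 1)
})
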