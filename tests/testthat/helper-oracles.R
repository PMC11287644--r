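# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's interval/graph machinery: per-base
# boolean masks, an explicit union-find, and linear-space enumeration.

# per-base occupancy mask of a 1-based closed interval on a toy chromosome
maskOf <- function(start, end, chromLen) {
  m <- logical(chromLen)
  m[seq(max(1, start), min(chromLen, end))] <- TRUE
  m
}

maskOverlaps <- function(c1, s1, e1, c2, s2, e2, chromLen = 10000L) {
  if (c1 != c2) return(FALSE)
  any(maskOf(s1, e1, chromLen) & maskOf(s2, e2, chromLen))
}

# union of intervals on one chromosome via run-length extraction
maskUnionRuns <- function(starts, ends, chromLen = 10000L) {
  m <- logical(chromLen)
  for (k in seq_along(starts)) m <- m | maskOf(starts[k], ends[k], chromLen)
  r <- rle(m)
  pos <- cumsum(c(1L, r$lengths))
  i <- which(r$values)
  data.frame(start = pos[i], end = pos[i] + r$lengths[i] - 1L)
}

# explicit union-find
ufNew <- function(n) seq_len(n)
ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
ufUnion <- function(parent, i, j) {
  ri <- ufFind(parent, i)
  rj <- ufFind(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

closedOverlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

# oracle for the both-anchors-overlap connected-components loop merge:
# loops as a data.frame with chrom, f_start, f_end, r_start, r_end, caller
# (1-based closed coordinates); returns the expected merged loops as a
# sorted data.frame with comma-collapsed caller sets
oracleLoopMerge <- function(df) {
  n <- nrow(df)
  parent <- ufNew(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (df$chrom[i] == df$chrom[j] &&
          closedOverlap(df$f_start[i], df$f_end[i],
                        df$f_start[j], df$f_end[j]) &&
          closedOverlap(df$r_start[i], df$r_end[i],
                        df$r_start[j], df$r_end[j]))
        parent <- ufUnion(parent, i, j)
    }
  }
  root <- vapply(seq_len(n), function(i) ufFind(parent, i), 0L)
  comps <- split(seq_len(n), root)
  out <- do.call(rbind, lapply(comps, function(m) {
    data.frame(chrom = df$chrom[m[1]],
               f_start = min(df$f_start[m]), f_end = max(df$f_end[m]),
               r_start = min(df$r_start[m]), r_end = max(df$r_end[m]),
               callers = paste(sort(unique(df$caller[m])), collapse = ","))
  }))
  out[order(out$chrom, out$f_start, out$f_end, out$r_start, out$r_end), ,
      drop = FALSE]
}

loopSetAsDf <- function(ls) {
  df <- data.frame(chrom = as.vector(GenomicRanges::seqnames(anchorFwd(ls))),
                   f_start = GenomicRanges::start(anchorFwd(ls)),
                   f_end = GenomicRanges::end(anchorFwd(ls)),
                   r_start = GenomicRanges::start(anchorRev(ls)),
                   r_end = GenomicRanges::end(anchorRev(ls)),
                   callers = loopCallers(ls))
  df <- df[order(df$chrom, df$f_start, df$f_end, df$r_start, df$r_end), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# random jittered multi-caller loop fixture: nTrue true loops, each seen by
# every caller at two resolutions with jittered anchors
randomJitteredLoops <- function(nTrue, callers, jitterSd = 2000,
                                chromLen = 2e6) {
  centerF <- round(runif(nTrue, 2e4, chromLen - 4e5))
  span <- round(runif(nTrue, 5e4, 3e5))
  rows <- list()
  for (cl in callers) {
    for (half in c(2500L, 5000L)) {
      jf <- round(rnorm(nTrue, 0, jitterSd))
      jr <- round(rnorm(nTrue, 0, jitterSd))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr1",
        f_start = centerF + jf - half, f_end = centerF + jf + half,
        r_start = centerF + span + jr - half,
        r_end = centerF + span + jr + half,
        caller = cl)
    }
  }
  df <- do.call(rbind, rows)
  df$f_start <- pmax(df$f_start, 1)
  df$r_start <- pmax(df$r_start, 1)
  df
}

dfAsLoopSet <- function(df, prefix = "") {
  LoopSet(GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$f_start, df$f_end)),
          GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$r_start, df$r_end)),
          caller = df$caller,
          loopId = sprintf("%s%s_%04d", prefix, df$caller,
                           seq_len(nrow(df))))
}

# linear-space exhaustive enumeration of colocalisation posteriors for
# small panels: Wakefield ABFs computed directly, hypotheses enumerated as
# explicit causal configurations
oracleColoc <- function(beta1, se1, beta2, se2, sd1, sd2,
                        p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  abf <- function(beta, se, sd) {
    r <- sd^2 / (se^2 + sd^2)
    sqrt(1 - r) * exp(r * (beta / se)^2 / 2)
  }
  A1 <- abf(beta1, se1, sd1)
  A2 <- abf(beta2, se2, sd2)
  m <- length(A1)
  w0 <- 1
  w1 <- p1 * sum(A1)
  w2 <- p2 * sum(A2)
  w3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    w3 <- w3 + A1[i] * A2[j]
  w3 <- p1 * p2 * w3
  w4 <- p12 * sum(A1 * A2)
  w <- c(w0, w1, w2, w3, w4)
  setNames(w / sum(w), c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4"))
}

randomAssocPanelPair <- function(m) {
  mk <- function(label) {
    assocPanel(data.frame(rsid = sprintf("v%03d", seq_len(m)),
                          chrom = "chr1", pos = seq_len(m) * 1000,
                          beta = rnorm(m, 0, 0.2),
                          se = runif(m, 0.05, 0.2),
                          maf = runif(m, 0.05, 0.5), n = 1000,
                          trait_type = "quantitative"), label)
  }
  list(mk("t1"), mk("t2"))
}

# chain key used to compare recovered chains with planted ground truth
# (merged loop ids are derived hashes, so the path id is not compared)
chainKey <- function(df) {
  if (nrow(df) == 0) return(character())
  hop <- df$hop_enhancer_id
  hop[is.na(hop)] <- "-"
  sort(paste(df$signal_id, df$rsid, df$enhancer_id, hop, df$promoter_id,
             df$gene_ids, df$n_hops, sep = "|"))
}
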