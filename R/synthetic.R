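#' Specify a synthetic scene
#'
#' Parameters of the seeded synthetic-data generator. The defaults define a
#' miniature but complete study: 2 chromosomes of 5 Mb, 200 loops called by
#' 4 callers at two resolutions with anchor jitter, 20 fine-mapped GWAS
#' signals with planted causal variants, replicated peak tracks encoding
#' planted element activity, molecular QTL overlap and per-signal
#' GWAS/QTL association panels with planted colocalisation scenarios.
#'
#' @param seed Integer seed; every stochastic draw flows from it.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_signals Number of GWAS signals.
#' @param n_loops Total number of true loops.
#' @param anchor_width Anchor width (bp) at the base (5 kb) resolution.
#' @param jitter_sd SD (bp) of per-caller anchor jitter (truncated at
#'   0.4 * anchor_width so cross-caller overlap is preserved).
#' @param n_callers Number of loop callers emulated.
#' @param frac_active_enhancers Probability that a background regulatory
#'   element is planted active.
#' @param frac_ep_loops Fraction of signals planted as one-hop
#'   enhancer-promoter chains.
#' @param n_ee_chains Number of signals planted as two-hop
#'   enhancer-enhancer-promoter chains.
#' @param n_noccre_anchors Number of planted cCRE-free loops whose forward
#'   anchor carries full enhancer evidence (novel-region candidates).
#' @param qtl_overlap_frac Fraction of chain signals whose causal variant is
#'   also a molecular QTL.
#' @param m_snps,causal_z Size and planted causal |z| of each association
#'   panel pair.
#' @return A validated `sceneSpec` list.
#' @export
sceneSpec <- function(seed = 1L, n_chroms = 2L, chrom_length = 5e6,
                      n_signals = 20L, n_loops = 200L, anchor_width = 5000L,
                      jitter_sd = 500, n_callers = 4L,
                      frac_active_enhancers = 0.7, frac_ep_loops = 0.5,
                      n_ee_chains = 3L, n_noccre_anchors = 9L,
                      qtl_overlap_frac = 0.6, m_snps = 200L, causal_z = 8) {
  spec <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
               chrom_length = chrom_length, n_signals = as.integer(n_signals),
               n_loops = as.integer(n_loops),
               anchor_width = as.integer(anchor_width),
               jitter_sd = jitter_sd, n_callers = as.integer(n_callers),
               frac_active_enhancers = frac_active_enhancers,
               frac_ep_loops = frac_ep_loops,
               n_ee_chains = as.integer(n_ee_chains),
               n_noccre_anchors = as.integer(n_noccre_anchors),
               qtl_overlap_frac = qtl_overlap_frac,
               m_snps = as.integer(m_snps), causal_z = causal_z)
  counts <- spec[c("n_chroms", "n_signals", "n_loops", "anchor_width",
                   "n_callers", "n_ee_chains", "n_noccre_anchors", "m_snps")]
  if (any(unlist(counts) < 0)) stop("counts must be >= 0")
  fracs <- spec[c("frac_active_enhancers", "frac_ep_loops",
                  "qtl_overlap_frac")]
  if (any(unlist(fracs) < 0 | unlist(fracs) > 1))
    stop("fractions must be in [0, 1]")
  if (spec$chrom_length < 10 * spec$anchor_width)
    stop("chrom_length must be at least 10 * anchor_width")
  if (spec$n_chroms < 1 || spec$n_callers < 1 || spec$n_loops < 1)
    stop("need at least one chromosome, caller and loop")
  class(spec) <- "sceneSpec"
  spec
}

.callerLabels <- function(n) {
  base <- c("mustache", "sip", "fanc", "hicexplorer")
  if (n <= 4) base[seq_len(n)] else c(base, sprintf("caller%d", 5:n))
}

#' Conventional file layout of a scene directory
#'
#' @param dir Scene directory.
#' @return Named list of paths used by both [generateScene()] and
#'   [runConfig()].
#' @export
scenePaths <- function(dir) {
  list(dir = dir,
       loopsDir = file.path(dir, "loops"),
       ctcf = file.path(dir, "ctcf_motifs.bed"),
       tad = file.path(dir, "tad_boundaries.bed"),
       ccre = file.path(dir, "ccre.bed"),
       atac = file.path(dir, "atac_consensus.bed"),
       chipDir = file.path(dir, "chip"),
       genes = file.path(dir, "genes.tsv"),
       credible = file.path(dir, "credible_sets.tsv"),
       qtls = file.path(dir, "qtls.tsv"),
       colocDir = file.path(dir, "coloc"),
       groundTruth = file.path(dir, "ground_truth.json"))
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.grFrom0 <- function(chrom, start0, end0) {
  GRanges(chrom, IRanges(start0 + 1, end0))
}

#' Simulate a pair of association panels
#'
#' Generates summary statistics for two traits over the same `mSnps`
#' variants. Under `"shared"` one variant carries expected |z| = `causalZ`
#' in both panels (same effect sign); under `"distinct"` two different
#' variants carry the effect, one per panel; under `"null"` every z is a
#' standard normal draw. Non-causal z ~ N(0,1); `beta = z * se` with
#' `se = 1/sqrt(2 * maf * (1-maf) * n)` (quantitative-trait approximation).
#' Panels are LD-free by construction.
#'
#' @param scenario `"shared"`, `"distinct"` or `"null"`.
#' @param mSnps Number of variants (>= 2).
#' @param causalZ Planted causal |z|.
#' @param seed Integer seed (panels are a deterministic function of it).
#' @param n1,n2 Sample sizes of the two traits.
#' @return List with `panel1`, `panel2` (each an `AssocPanel`) and the
#'   planted `causal1`/`causal2` rsids (`NA` under the null).
#' @export
simulateAssocPanels <- function(scenario = c("shared", "distinct", "null"),
                                mSnps = 500L, causalZ = 8, seed = 1L,
                                n1 = 40000L, n2 = 1000L) {
  scenario <- match.arg(scenario)
  stopifnot(mSnps >= 2)
  set.seed(as.integer(seed))
  rsid <- sprintf("snp_%05d", seq_len(mSnps))
  pos <- 1e6 + seq_len(mSnps) * 1000
  maf <- runif(mSnps, 0.05, 0.5)
  se1 <- 1 / sqrt(2 * maf * (1 - maf) * n1)
  se2 <- 1 / sqrt(2 * maf * (1 - maf) * n2)
  z1 <- rnorm(mSnps)
  z2 <- rnorm(mSnps)
  causal1 <- causal2 <- NA_character_
  if (scenario == "shared") {
    i <- sample.int(mSnps, 1)
    sgn <- sample(c(-1, 1), 1)
    z1[i] <- sgn * causalZ + rnorm(1)
    z2[i] <- sgn * causalZ + rnorm(1)
    causal1 <- causal2 <- rsid[i]
  } else if (scenario == "distinct") {
    ij <- sample.int(mSnps, 2)
    z1[ij[1]] <- sample(c(-1, 1), 1) * causalZ + rnorm(1)
    z2[ij[2]] <- sample(c(-1, 1), 1) * causalZ + rnorm(1)
    causal1 <- rsid[ij[1]]
    causal2 <- rsid[ij[2]]
  }
  mk <- function(z, se, n, label, causal) {
    stats <- data.frame(rsid = rsid, chrom = "chrS", pos = pos,
                        beta = z * se, se = se, maf = maf, n = n,
                        trait_type = "quantitative",
                        stringsAsFactors = FALSE)
    lead <- if (is.na(causal)) rsid[which.max(abs(z))] else causal
    assocPanel(stats, label, lead)
  }
  list(panel1 = mk(z1, se1, n1, "trait1", causal1),
       panel2 = mk(z2, se2, n2, "trait2", causal2),
       causal1 = causal1, causal2 = causal2, scenario = scenario)
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Writes, under `dir`, every input the pipeline consumes — per-caller
#' per-resolution BEDPE loop files with jittered anchors, CTCF motif and TAD
#' boundary BEDs, a typed cCRE BED, an ATAC consensus BED and per-replicate
#' ChIP BEDs consistent with planted element activity, a gene table,
#' credible-set and QTL tables, and per-signal GWAS/QTL association panels —
#' plus `ground_truth.json` recording the planted chains, activity states,
#' CTCF ratios, funnel counts and colocalisation scenarios. Identical seeds
#' produce byte-identical files.
#'
#' @param spec A [sceneSpec()].
#' @param dir Output directory (created; must not contain a previous scene).
#' @return Invisibly, a list with `dir`, `paths` and `groundTruth`.
#' @export
generateScene <- function(spec, dir) {
  stopifnot(inherits(spec, "sceneSpec"))
  aw <- spec$anchor_width
  perChrom <- ceiling(spec$n_loops / spec$n_chroms)
  block <- floor(spec$chrom_length / perChrom)
  if (block < 10 * aw)
    stop("scene too dense: need chrom_length/ceiling(n_loops/n_chroms) >= ",
         "10 * anchor_width before any file is written")
  set.seed(spec$seed)

  idx <- seq_len(spec$n_loops)
  chromOf <- sprintf("chr%d", (idx - 1) %/% perChrom + 1)
  blockStart <- ((idx - 1) %% perChrom) * block
  fwdC <- blockStart + round(1.5 * aw)
  revC <- blockStart + round(6.5 * aw)

  # --- role assignment -------------------------------------------------
  nEp <- round(spec$frac_ep_loops * spec$n_signals)
  nEe <- min(spec$n_ee_chains, spec$n_signals - nEp)
  nRest <- spec$n_signals - nEp - nEe
  nInact <- floor(nRest / 2)
  nAnchorOnly <- nRest - nInact
  role <- rep("filler", spec$n_loops)
  signalOf <- rep(NA_integer_, spec$n_loops)
  cursor <- 1L
  take <- function(k) {
    if (k == 0) return(integer())
    if (cursor + k - 1 > spec$n_loops)
      stop("scene too small: n_loops cannot host all planted roles ",
           "before any file is written")
    out <- seq(cursor, cursor + k - 1)
    cursor <<- cursor + k
    out
  }
  sIdx <- 0L
  assignSignals <- function(loopIdx, tag) {
    for (i in loopIdx) {
      sIdx <<- sIdx + 1L
      role[i] <<- tag
      signalOf[i] <<- sIdx
    }
  }
  assignSignals(take(nEp), "ep")
  for (k in seq_len(nEe)) {
    pair <- take(2)
    if (chromOf[pair[1]] != chromOf[pair[2]])
      stop("scene too small: a two-hop chain pair crosses a chromosome ",
           "boundary; increase n_loops per chromosome")
    sIdx <- sIdx + 1L
    role[pair[1]] <- "ee_main"
    role[pair[2]] <- "ee_partner"
    signalOf[pair[1]] <- sIdx
  }
  assignSignals(take(nInact), "inactive_enh")
  assignSignals(take(nAnchorOnly), "anchor_only")
  role[take(spec$n_noccre_anchors)] <- "noccre"
  nSelf <- min(4L, spec$n_loops - cursor + 1L)
  role[take(nSelf)] <- "selfovl"
  nBg <- min(10L, spec$n_loops - cursor + 1L)
  role[take(nBg)] <- "bg_ep"

  # geometry overrides: two-hop partners share the main loop's reverse
  # anchor; self-overlapping loops get anchors too close to stay apart
  for (i in which(role == "ee_partner")) fwdC[i] <- revC[i - 1L]
  for (i in which(role == "selfovl")) revC[i] <- fwdC[i] + round(1.2 * aw)

  # --- regulatory elements, genes, variants ----------------------------
  elW <- 400L   # element half-width
  el <- list()
  genes <- list()
  vars <- list()
  gtChains <- list()
  addElement <- function(chrom, center, kind, active) {
    start0 <- center - elW
    end0 <- center + elW
    id <- sprintf("%s_%s_%d_%d", kind, chrom, start0, end0)
    el[[length(el) + 1L]] <<- data.frame(
      chrom = chrom, start0 = start0, end0 = end0, kind = kind,
      element_id = id, active = active, stringsAsFactors = FALSE)
    id
  }
  addGene <- function(chrom, promStart0, geneId) {
    genes[[length(genes) + 1L]] <<- data.frame(
      chrom = chrom, tss = promStart0 + 101L,
      strand = if (length(genes) %% 2 == 0) "+" else "-",
      gene_id = geneId, stringsAsFactors = FALSE)
  }
  phenos <- c("knee_oa", "hip_oa", "thr", "tjr", "hand_oa")
  addVariant <- function(sid, tag, chrom, pos1, pp) {
    vars[[length(vars) + 1L]] <<- data.frame(
      rsid = sprintf("rsS%02d%s", sid, tag), chrom = chrom, pos = pos1,
      signal_id = sprintf("S%02d", sid),
      lead_rsid = sprintf("rsS%02dc", sid),
      phenotype = phenos[(sid - 1) %% length(phenos) + 1],
      pp = pp, stringsAsFactors = FALSE)
  }
  addSignalDecoys <- function(sid, chrom, fwdCenter, bs) {
    addVariant(sid, "a", chrom, fwdCenter + round(0.3 * aw),
               runif(1, 0.035, 0.06))               # anchor, outside cCRE
    addVariant(sid, "o", chrom, bs + 9L * aw, runif(1, 0.035, 0.06))
    addVariant(sid, "b1", chrom, bs + 9L * aw + 500L, 0.03)  # boundary: drop
    addVariant(sid, "b2", chrom, bs + 9L * aw + 800L, runif(1, 0.005, 0.029))
  }

  for (i in idx) {
    ch <- chromOf[i]
    sid <- signalOf[i]
    bs <- blockStart[i]
    if (role[i] == "ep") {
      e1 <- addElement(ch, fwdC[i], "enhancer", TRUE)
      p <- addElement(ch, revC[i], "promoter", TRUE)
      g <- sprintf("GENE_S%02d", sid)
      addGene(ch, revC[i] - elW, g)
      addVariant(sid, "c", ch, fwdC[i], runif(1, 0.05, 0.5))
      addSignalDecoys(sid, ch, fwdC[i], bs)
      gtChains[[length(gtChains) + 1L]] <- data.frame(
        signal_id = sprintf("S%02d", sid), rsid = sprintf("rsS%02dc", sid),
        enhancer_id = e1, hop_enhancer_id = NA_character_,
        promoter_id = p, gene_ids = g, n_hops = 1L,
        stringsAsFactors = FALSE)
    } else if (role[i] == "ee_main") {
      e1 <- addElement(ch, fwdC[i], "enhancer", TRUE)
      e2 <- addElement(ch, revC[i], "enhancer", TRUE)  # shared hop anchor
      p <- addElement(ch, revC[i + 1L], "promoter", TRUE)
      g <- sprintf("GENE_S%02d", sid)
      addGene(ch, revC[i + 1L] - elW, g)
      addVariant(sid, "c", ch, fwdC[i], runif(1, 0.05, 0.5))
      addSignalDecoys(sid, ch, fwdC[i], bs)
      gtChains[[length(gtChains) + 1L]] <- data.frame(
        signal_id = sprintf("S%02d", sid), rsid = sprintf("rsS%02dc", sid),
        enhancer_id = e1, hop_enhancer_id = e2,
        promoter_id = p, gene_ids = g, n_hops = 2L,
        stringsAsFactors = FALSE)
    } else if (role[i] == "inactive_enh") {
      addElement(ch, fwdC[i], "enhancer", FALSE)
      p <- addElement(ch, revC[i], "promoter", TRUE)
      addGene(ch, revC[i] - elW, sprintf("GENE_S%02d", sid))
      addVariant(sid, "c", ch, fwdC[i], runif(1, 0.05, 0.5))
      addSignalDecoys(sid, ch, fwdC[i], bs)
    } else if (role[i] == "anchor_only") {
      p <- addElement(ch, revC[i], "promoter", TRUE)
      addGene(ch, revC[i] - elW, sprintf("GENE_S%02d", sid))
      addVariant(sid, "c", ch, fwdC[i], runif(1, 0.05, 0.5))
      addSignalDecoys(sid, ch, fwdC[i], bs)
    } else if (role[i] == "bg_ep") {
      addElement(ch, fwdC[i], "enhancer",
                 runif(1) < spec$frac_active_enhancers)
      p <- addElement(ch, revC[i], "promoter",
                      runif(1) < spec$frac_active_enhancers)
      addGene(ch, revC[i] - elW, sprintf("BGGENE_%d", i))
    } else if (role[i] == "filler") {
      if (runif(1) < 0.5)
        addElement(ch, fwdC[i], "enhancer",
                   runif(1) < spec$frac_active_enhancers)
      if (runif(1) < 0.3) {
        addElement(ch, revC[i], "promoter",
                   runif(1) < spec$frac_active_enhancers)
        addGene(ch, revC[i] - elW, sprintf("BGGENE_%d", i))
      }
      # background element and gene out in the inter-loop gap
      if (runif(1) < 0.3)
        addElement(ch, bs + 8L * aw, "enhancer",
                   runif(1) < spec$frac_active_enhancers)
      if (runif(1) < 0.2)
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = ch, tss = bs + round(8.4 * aw), strand = "+",
          gene_id = sprintf("GAPGENE_%d", i), stringsAsFactors = FALSE)
    }
    # "noccre" and "selfovl" loops get no cCRE elements
  }
  elements <- do.call(rbind, el)
  geneTab <- do.call(rbind, genes)
  variants <- do.call(rbind, vars)
  gtChains <- if (length(gtChains)) do.call(rbind, gtChains) else
    data.frame(signal_id = character(), rsid = character(),
               enhancer_id = character(), hop_enhancer_id = character(),
               promoter_id = character(), gene_ids = character(),
               n_hops = integer(), stringsAsFactors = FALSE)

  # --- peak evidence consistent with planted activity ------------------
  pad <- 100L
  nReps <- 3L
  peaks <- list(atac = list())
  for (m in CHIP_MARKS)
    peaks[[m]] <- rep(list(list()), nReps)
  addPeak <- function(track, rep, chrom, start0, end0) {
    row <- data.frame(chrom = chrom, start0 = start0, end0 = end0,
                      stringsAsFactors = FALSE)
    if (track == "atac") peaks$atac[[length(peaks$atac) + 1L]] <<- row
    else peaks[[track]][[rep]][[length(peaks[[track]][[rep]]) + 1L]] <<- row
  }
  plantMark <- function(mark, k, chrom, s0, e0) {
    for (r in sample.int(nReps, k)) addPeak(mark, r, chrom, s0, e0)
  }
  for (j in seq_len(nrow(elements))) {
    e <- elements[j, ]
    s0 <- e$start0 - pad
    e0 <- e$end0 + pad
    reqMark <- if (e$kind == "promoter") "H3K4me3" else "H3K4me1"
    offMark <- if (e$kind == "promoter") "H3K4me1" else "H3K4me3"
    if (e$active) {
      addPeak("atac", NA, e$chrom, s0, e0)
      plantMark(reqMark, sample(2:3, 1), e$chrom, s0, e0)
      plantMark("H3K27ac", sample(2:3, 1), e$chrom, s0, e0)
    } else {
      mode <- sample(c("no_atac", "one_rep", "no_k27ac"), 1)
      if (mode != "no_atac") addPeak("atac", NA, e$chrom, s0, e0)
      plantMark(reqMark, if (mode == "one_rep") 1L else sample(2:3, 1),
                e$chrom, s0, e0)
      plantMark("H3K27ac",
                if (mode == "no_k27ac") sample(0:1, 1) else sample(2:3, 1),
                e$chrom, s0, e0)
    }
    if (runif(1) < 0.3) plantMark(offMark, 1L, e$chrom, s0, e0)
  }
  # cCRE-free anchors with full enhancer evidence (novel-region candidates)
  noccreIdx <- which(role == "noccre")
  for (i in noccreIdx) {
    s0 <- fwdC[i] - 1000L
    e0 <- fwdC[i] + 1000L
    addPeak("atac", NA, chromOf[i], s0, e0)
    plantMark("H3K4me1", 2L, chromOf[i], s0, e0)
    plantMark("H3K27ac", 2L, chromOf[i], s0, e0)
  }
  bindPeaks <- function(rows) {
    if (length(rows) == 0)
      return(GRanges())
    df <- do.call(rbind, rows)
    GenomicRanges::sort(.grFrom0(df$chrom, df$start0, df$end0))
  }
  atacGr <- bindPeaks(peaks$atac)
  chipGr <- lapply(CHIP_MARKS, function(m) lapply(peaks[[m]], bindPeaks))
  names(chipGr) <- CHIP_MARKS
  evidence <- peakEvidence(atacGr, chipGr)

  # generator-side assertion: planted activity states are exactly what the
  # classification rule yields on the written evidence
  elGr <- .grFrom0(elements$chrom, elements$start0, elements$end0)
  mcols(elGr)$kind <- elements$kind
  mcols(elGr)$element_id <- elements$element_id
  called <- classifyActivity(elGr, evidence, chipMinReps = 2L)
  stopifnot(identical(unname(mcols(called)$active),
                      unname(elements$active)))

  # --- CTCF motifs and TAD boundaries ----------------------------------
  retained <- role != "selfovl"
  motifW <- 19L
  hasFwdMotif <- runif(spec$n_loops) < 0.90
  hasRevMotif <- runif(spec$n_loops) < 0.85
  motifRows <- list()
  addMotif <- function(chrom, center) {
    motifRows[[length(motifRows) + 1L]] <<- data.frame(
      chrom = chrom, start0 = center - 10L, end0 = center - 10L + motifW,
      stringsAsFactors = FALSE)
  }
  for (i in idx) {
    if (hasFwdMotif[i]) addMotif(chromOf[i], fwdC[i] - 100L)
    if (hasRevMotif[i]) addMotif(chromOf[i], revC[i] + 100L)
    if (role[i] == "filler" && runif(1) < 0.2)
      addMotif(chromOf[i], blockStart[i] + round(8.8 * aw))
  }
  # two-hop partners share an anchor region with their main loop, so a
  # motif planted for either side of that shared anchor is seen by both
  effFwd <- hasFwdMotif
  effRev <- hasRevMotif
  for (i in which(role == "ee_partner")) {
    shared <- hasFwdMotif[i] || hasRevMotif[i - 1L]
    effFwd[i] <- shared
    effRev[i - 1L] <- shared
  }
  nTads <- min(40L, spec$n_loops)
  tadLoopIdx <- unique(round(seq(1, spec$n_loops, length.out = nTads)))
  nTads <- length(tadLoopIdx)
  nTadWithMotif <- floor(0.95 * nTads)
  tadWith <- sort(sample(seq_len(nTads), nTadWithMotif))
  tadRows <- data.frame(
    chrom = chromOf[tadLoopIdx],
    start0 = blockStart[tadLoopIdx] + round(9.2 * aw),
    end0 = blockStart[tadLoopIdx] + round(9.2 * aw) + 4000L)
  for (k in tadWith)
    addMotif(tadRows$chrom[k], tadRows$start0[k] + 2000L)
  motifs <- do.call(rbind, motifRows)

  # --- per-caller, per-resolution loop files ---------------------------
  callers <- .callerLabels(spec$n_callers)
  maxJ <- round(0.4 * aw)
  jit <- function(n) pmax(-maxJ, pmin(maxJ, round(rnorm(n, 0, spec$jitter_sd))))
  loopFiles <- list()
  paths <- scenePaths(dir)
  for (d in c(paths$dir, paths$loopsDir, paths$chipDir, paths$colocDir))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (cl in callers) {
    for (res in c(5000L, 10000L)) {
      half <- res %/% 2L
      j1 <- jit(spec$n_loops)
      j2 <- jit(spec$n_loops)
      df <- data.frame(
        chrom1 = chromOf, start1 = fwdC + j1 - half, end1 = fwdC + j1 + half,
        chrom2 = chromOf, start2 = revC + j2 - half, end2 = revC + j2 + half)
      f <- file.path(paths$loopsDir, sprintf("%s_%d.bedpe", cl, res))
      write.table(df, f, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      loopFiles[[length(loopFiles) + 1L]] <- f
    }
  }

  # --- variant-level tables --------------------------------------------
  chainSignals <- sort(unique(gtChains$signal_id))
  nQtl <- round(spec$qtl_overlap_frac * length(chainSignals))
  qtlSignals <- sort(sample(chainSignals)[seq_len(nQtl)])
  qtlRows <- list()
  for (s in qtlSignals) {
    ch <- gtChains[gtChains$signal_id == s, ][1, ]
    rs <- ch$rsid
    qtlRows[[length(qtlRows) + 1L]] <- data.frame(
      rsid = rs, qtl_type = "eQTL", target = ch$gene_ids,
      grade = sample(c("low", "high"), 1), beta = round(rnorm(1, 0, 0.3), 4),
      se = round(runif(1, 0.02, 0.1), 4),
      p = signif(runif(1, 1e-12, 1e-5), 3), stringsAsFactors = FALSE)
    qtlRows[[length(qtlRows) + 1L]] <- data.frame(
      rsid = rs, qtl_type = "methQTL",
      target = sprintf("cg%08d", sample.int(1e7, 1)),
      grade = sample(c("low", "high"), 1), beta = round(rnorm(1, 0, 0.3), 4),
      se = round(runif(1, 0.02, 0.1), 4),
      p = signif(runif(1, 1e-12, 1e-5), 3), stringsAsFactors = FALSE)
  }
  for (k in seq_len(8)) {
    qtlRows[[length(qtlRows) + 1L]] <- data.frame(
      rsid = sprintf("rsdecoy%03d", k),
      qtl_type = sample(c("eQTL", "pQTL", "methQTL"), 1),
      target = sprintf("DECOY_T%d", k), grade = sample(c("low", "high"), 1),
      beta = round(rnorm(1, 0, 0.3), 4), se = round(runif(1, 0.02, 0.1), 4),
      p = signif(runif(1, 1e-6, 0.5), 3), stringsAsFactors = FALSE)
  }
  qtlTab <- do.call(rbind, qtlRows)

  # --- per-signal association panels -----------------------------------
  scenarios <- rep_len(c("shared", "distinct", "null"), spec$n_signals)
  colocGt <- list()
  for (s in seq_len(spec$n_signals)) {
    sid <- sprintf("S%02d", s)
    panelSeed <- (spec$seed * 1000 + s) %% 2147483647L
    sim <- simulateAssocPanels(scenarios[s], spec$m_snps, spec$causal_z,
                               seed = panelSeed)
    gf <- file.path(paths$colocDir, sprintf("signal_%s_gwas.tsv", sid))
    qf <- file.path(paths$colocDir, sprintf("signal_%s_qtl.tsv", sid))
    .writeTsv(panelStats(sim$panel1), gf)
    .writeTsv(panelStats(sim$panel2), qf)
    colocGt[[s]] <- data.frame(
      signal_id = sid, scenario = scenarios[s],
      causal1 = sim$causal1, causal2 = sim$causal2,
      stringsAsFactors = FALSE)
  }

  # --- write remaining inputs ------------------------------------------
  writeBed(.grFrom0(motifs$chrom, motifs$start0, motifs$end0), paths$ctcf)
  writeBed(.grFrom0(tadRows$chrom, tadRows$start0, tadRows$end0), paths$tad)
  ccreGr <- .grFrom0(elements$chrom, elements$start0, elements$end0)
  mcols(ccreGr)$name <- elements$kind
  writeBed(ccreGr, paths$ccre)
  writeBed(atacGr, paths$atac)
  for (m in CHIP_MARKS)
    for (r in seq_len(nReps))
      writeBed(chipGr[[m]][[r]],
               file.path(paths$chipDir, sprintf("%s_rep%d.bed", m, r)))
  .writeTsv(geneTab, paths$genes)
  .writeTsv(variants, paths$credible)
  .writeTsv(qtlTab, paths$qtls)

  # --- ground truth -----------------------------------------------------
  nPass <- sum(variants$pp > 0.03)
  inAnchorRs <- unique(variants$rsid[grepl("(c|a)$", variants$rsid) &
                                       variants$pp > 0.03])
  gt <- list(
    spec = unclass(spec),
    callers = callers,
    chains = gtChains,
    activity = elements[c("element_id", "kind", "active")],
    ctcf = list(fwd_ratio = mean(effFwd[retained]),
                rev_ratio = mean(effRev[retained]),
                n_retained_loops = sum(retained)),
    tad_coverage = nTadWithMotif / nTads,
    n_tad_boundaries = nTads,
    n_self_overlapping = nSelf,
    novel_anchors = data.frame(chrom = chromOf[noccreIdx],
                               center = fwdC[noccreIdx]),
    funnel = list(n_credible_total = nrow(variants),
                  n_credible_pass = nPass,
                  n_variants_in_anchors = length(inAnchorRs),
                  n_variants_in_active_enhancers =
                    length(unique(gtChains$rsid))),
    qtl_signals = qtlSignals,
    coloc = do.call(rbind, colocGt))
  jsonlite::write_json(gt, paths$groundTruth, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(list(dir = dir, paths = paths, groundTruth = gt))
}

#' Read a scene's ground-truth file
#'
#' @param path Path to `ground_truth.json` (or a scene directory).
#' @return The ground-truth list.
#' @export
readGroundTruth <- function(path) {
  if (dir.exists(path)) path <- scenePaths(path)$groundTruth
  jsonlite::read_json(path, simplifyVector = TRUE)
}
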