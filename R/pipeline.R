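#' Validate a pipeline run configuration
#'
#' Collects input paths (conventional scene layout, see [scenePaths()]) and
#' analysis thresholds, checking that every referenced file exists and every
#' threshold is within its documented range before any computation starts.
#'
#' @param sceneDir Directory holding the inputs in the conventional layout.
#' @param outDir Output directory (created on run).
#' @param ppMin Strict posterior-probability filter for credible variants.
#' @param chipMinReps Replicate threshold for ChIP marks.
#' @param promoterUp,promoterDown Promoter-to-gene window (bp).
#' @param colocPriors Numeric `c(p1, p2, p12)` colocalisation priors.
#' @param colocHalfWidth Half-width (bp) of the GWAS window around the lead
#'   variant.
#' @return A validated `runConfig` list.
#' @export
runConfig <- function(sceneDir, outDir,
                      ppMin = 0.03, chipMinReps = 2L,
                      promoterUp = 1500L, promoterDown = 500L,
                      colocPriors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                      colocHalfWidth = 1e6) {
  paths <- scenePaths(sceneDir)
  required <- c(paths$ctcf, paths$tad, paths$ccre, paths$atac,
                paths$genes, paths$credible, paths$qtls)
  missing <- required[!file.exists(required)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (!dir.exists(paths$loopsDir))
    stop("missing loops directory: ", paths$loopsDir)
  loopFiles <- list.files(paths$loopsDir, pattern = "\\.bedpe$")
  if (length(loopFiles) == 0)
    stop("no .bedpe loop files in ", paths$loopsDir)
  if (ppMin < 0 || ppMin >= 1) stop("ppMin must be in [0, 1)")
  if (chipMinReps < 0) stop("chipMinReps must be >= 0")
  if (promoterUp < 0 || promoterDown < 0)
    stop("promoter window extensions must be >= 0")
  if (length(colocPriors) != 3 || any(colocPriors <= 0) ||
      any(colocPriors >= 1))
    stop("colocPriors must be three probabilities in (0, 1)")
  if (colocHalfWidth < 0) stop("colocHalfWidth must be >= 0")
  structure(list(paths = paths, outDir = outDir, ppMin = ppMin,
                 chipMinReps = as.integer(chipMinReps),
                 promoterUp = as.integer(promoterUp),
                 promoterDown = as.integer(promoterDown),
                 colocPriors = colocPriors,
                 colocHalfWidth = colocHalfWidth),
            class = "runConfig")
}

.parseLoopFiles <- function(loopsDir) {
  files <- list.files(loopsDir, pattern = "\\.bedpe$", full.names = TRUE)
  m <- regmatches(basename(files),
                  regexec("^(.*)_(\\d+)\\.bedpe$", basename(files)))
  bad <- lengths(m) != 3
  if (any(bad))
    stop("loop file name(s) not of the form <caller>_<resolution>.bedpe: ",
         paste(basename(files)[bad], collapse = ", "))
  data.frame(path = files,
             caller = vapply(m, `[`, "", 2),
             resolution = as.integer(vapply(m, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

.readEvidence <- function(paths) {
  chipFiles <- list.files(paths$chipDir, pattern = "_rep\\d+\\.bed$",
                          full.names = TRUE)
  chip <- lapply(CHIP_MARKS, function(m) {
    fs <- sort(chipFiles[startsWith(basename(chipFiles), paste0(m, "_"))])
    lapply(fs, readBed)
  })
  names(chip) <- CHIP_MARKS
  peakEvidence(readBed(paths$atac), chip)
}

#' Per-caller summary table of loop and annotation counts
#'
#' One row per caller with the roles of the study's per-caller overview:
#' total retained loops, CTCF forward/reverse anchor motif ratios, number
#' of enhancer-promoter loops (active enhancer on one anchor, active
#' promoter on the opposite), counts of distinct active promoters (AP) and
#' active enhancers (AE) overlapping any anchor, and the number of active
#' anchor-overlapping enhancers containing a filtered credible variant
#' (SNP).
#'
#' @param perCaller Named list of processed `LoopSet`s, one per caller.
#' @param elements Classified elements from [classifyActivity()].
#' @param variants Filtered credible-set data.frame.
#' @param motifs CTCF motif `GRanges`.
#' @return data.frame with columns `caller`, `loops`, `ctcf_fwd`,
#'   `ctcf_rev`, `ep_loops`, `ap`, `ae`, `snp`.
#' @export
summarizeTable1 <- function(perCaller, elements, variants, motifs) {
  enh <- elements[mcols(elements)$kind == "enhancer" &
                    mcols(elements)$active]
  prom <- elements[mcols(elements)$kind == "promoter" &
                     mcols(elements)$active]
  vg <- .variantGRanges(variants)
  rows <- lapply(names(perCaller), function(cl) {
    ls <- perCaller[[cl]]
    qc <- ctcfQc(ls, motifs)
    if (length(ls) == 0)
      return(data.frame(caller = cl, loops = 0L, ctcf_fwd = 0,
                        ctcf_rev = 0, ep_loops = 0L, ap = 0L, ae = 0L,
                        snp = 0L, stringsAsFactors = FALSE))
    fE <- countOverlaps(anchorFwd(ls), enh, ignore.strand = TRUE) > 0
    rE <- countOverlaps(anchorRev(ls), enh, ignore.strand = TRUE) > 0
    fP <- countOverlaps(anchorFwd(ls), prom, ignore.strand = TRUE) > 0
    rP <- countOverlaps(anchorRev(ls), prom, ignore.strand = TRUE) > 0
    anchors <- c(anchorFwd(ls), anchorRev(ls))
    aeIdx <- unique(subjectHits(findOverlaps(anchors, enh,
                                             ignore.strand = TRUE)))
    apIdx <- unique(subjectHits(findOverlaps(anchors, prom,
                                             ignore.strand = TRUE)))
    snpEnh <- enh[aeIdx]
    nSnp <- sum(countOverlaps(snpEnh, vg, ignore.strand = TRUE) > 0)
    data.frame(caller = cl, loops = length(ls),
               ctcf_fwd = qc$ctcf_fwd_ratio, ctcf_rev = qc$ctcf_rev_ratio,
               ep_loops = sum((fE & rP) | (fP & rE)),
               ap = length(apIdx), ae = length(aeIdx), snp = nSnp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$caller), , drop = FALSE]
}

#' Run the full variant-to-effector-gene pipeline
#'
#' Executes loop integration (per-caller resolution merge, self-overlap
#' filter, CTCF QC, cross-caller union), element activity classification,
#' credible-variant filtering and chaining through enhancer-promoter and
#' enhancer-enhancer-promoter loops, the cCRE-free anchor screen, molecular
#' QTL joining, and — for chain signals whose variant is a QTL and whose
#' association panels are present — approximate Bayes factor
#' colocalisation. Writes tab-separated report tables plus a run-metadata
#' JSON under `config$outDir`; all outputs except the metadata timestamp
#' are byte-deterministic in the inputs.
#'
#' @param config A [runConfig()].
#' @return Invisibly, a list with elements `table1`, `chains`, `coloc`,
#'   `novelAnchors`, `funnel`, `loops` (the unioned `LoopSet`), `elements`
#'   and `tadCtcfCoverage`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  paths <- config$paths
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logMsg <- function(...) message("[loopGWAS] ", ...)

  motifs <- readBed(paths$ctcf)
  boundaries <- readBed(paths$tad)
  ccre <- readCcreBed(paths$ccre)
  evidence <- .readEvidence(paths)
  genes <- readGeneTable(paths$genes)
  credible <- readCredibleSets(paths$credible)
  qtls <- readQtlTable(paths$qtls)

  elements <- classifyActivity(ccre, evidence,
                               chipMinReps = config$chipMinReps)
  logMsg(length(elements), " cCRE elements, ",
         sum(mcols(elements)$active), " active")

  filtered <- filterCredible(credible, ppMin = config$ppMin)
  logMsg(nrow(credible), " credible variants, ", nrow(filtered),
         " pass pp > ", config$ppMin)

  loopTab <- .parseLoopFiles(paths$loopsDir)
  perCaller <- list()
  for (cl in sort(unique(loopTab$caller))) {
    sub <- loopTab[loopTab$caller == cl, , drop = FALSE]
    sets <- lapply(seq_len(nrow(sub)), function(k)
      readLoopsBedpe(sub$path[k], cl, sub$resolution[k]))
    merged <- .mergeLoopComponents(.concatLoopSets(sets))
    merged <- dropSelfOverlapping(merged)
    logMsg("caller ", cl, ": ", length(merged), " loops after merge (",
           loopMeta(merged)$n_self_overlap_removed,
           " self-overlapping removed)")
    perCaller[[cl]] <- merged
  }
  table1 <- summarizeTable1(perCaller, elements, filtered, motifs)

  loops <- dropSelfOverlapping(unionAcrossCallers(perCaller))
  logMsg(length(loops), " loops after cross-caller union")

  anchorHits <- variantsInAnchors(filtered, loops)
  snpEnh <- variantsInActiveEnhancers(anchorHits, elements)
  ep <- buildEpChains(snpEnh, loops, elements, genes,
                      up = config$promoterUp, down = config$promoterDown)
  ee <- buildEeChains(snpEnh, loops, elements, genes,
                      up = config$promoterUp, down = config$promoterDown)
  chains <- joinQtls(rbind(ep, ee), qtls)
  logMsg(nrow(ep), " one-hop and ", nrow(ee), " two-hop chains")

  novel <- screenNoCcreAnchors(loops, ccre, evidence,
                               chipMinReps = config$chipMinReps)
  tadCov <- tadBoundaryCtcfCoverage(boundaries, motifs)

  funnel <- data.frame(
    stage = c("credible_total", "credible_pass", "in_anchors",
              "in_active_enhancers", "chain_variants"),
    n = c(nrow(credible), nrow(filtered),
          length(unique(anchorHits$rsid)), length(unique(snpEnh$rsid)),
          length(unique(chains$rsid))))

  colocRows <- list()
  for (sid in sort(unique(chains$signal_id[chains$qtls != ""]))) {
    gf <- file.path(paths$colocDir, sprintf("signal_%s_gwas.tsv", sid))
    qf <- file.path(paths$colocDir, sprintf("signal_%s_qtl.tsv", sid))
    if (!file.exists(gf) || !file.exists(qf)) next
    gwas <- windowPanel(readAssocPanel(gf, paste0("GWAS_", sid)),
                        halfWidth = config$colocHalfWidth)
    qtlPanel <- readAssocPanel(qf, paste0("QTL_", sid))
    res <- colocalise(gwas, qtlPanel, priors = config$colocPriors)
    colocRows[[sid]] <- cbind(data.frame(signal_id = sid), res)
  }
  coloc <- if (length(colocRows)) do.call(rbind, colocRows) else
    data.frame(signal_id = character(), pp_h0 = numeric(),
               pp_h1 = numeric(), pp_h2 = numeric(), pp_h3 = numeric(),
               pp_h4 = numeric(), n_shared_snps = integer(),
               p1 = numeric(), p2 = numeric(), p12 = numeric())
  rownames(coloc) <- NULL
  logMsg(nrow(coloc), " colocalisation test(s)")

  novelDf <- data.frame(chrom = as.vector(seqnames(novel)),
                        start = start(novel) - 1L, end = end(novel),
                        loop_id = mcols(novel)$loop_id,
                        side = mcols(novel)$side)
  activityDf <- data.frame(element_id = mcols(elements)$element_id,
                           kind = mcols(elements)$kind,
                           active = mcols(elements)$active,
                           atac = mcols(elements)$atac,
                           k4me1_reps = mcols(elements)$k4me1_reps,
                           k4me3_reps = mcols(elements)$k4me3_reps,
                           k27ac_reps = mcols(elements)$k27ac_reps)
  .writeTsv(activityDf, file.path(config$outDir, "activity.tsv"))
  .writeTsv(table1, file.path(config$outDir, "table1.tsv"))
  .writeTsv(chains, file.path(config$outDir, "chains.tsv"))
  .writeTsv(coloc, file.path(config$outDir, "coloc.tsv"))
  .writeTsv(novelDf, file.path(config$outDir, "novel_anchors.tsv"))
  .writeTsv(funnel, file.path(config$outDir, "funnel.tsv"))
  writeLoopsBedpe(loops, file.path(config$outDir, "merged_loops.bedpe"))
  meta <- list(thresholds = config[setdiff(names(config),
                                           c("paths", "outDir"))],
               tad_boundary_ctcf_coverage = tadCov,
               n_self_overlap_removed =
                 loopMeta(loops)$n_self_overlap_removed,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(config$outDir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table1 = table1, chains = chains, coloc = coloc,
                 novelAnchors = novel, funnel = funnel, loops = loops,
                 elements = elements, tadCtcfCoverage = tadCov,
                 anchorHits = anchorHits, snpEnh = snpEnh))
}
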