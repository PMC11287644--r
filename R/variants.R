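#' Read a GWAS credible-set variant table
#'
#' Tab-separated with header columns `rsid`, `chrom`, `pos` (1-based
#' single-base position), `signal_id`, `lead_rsid`, `phenotype`, `pp`
#' (posterior probability of causality).
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
readCredibleSets <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "signal_id", "lead_rsid",
            "phenotype", "pp")
  if (!all(need %in% names(df)))
    stop("credible-set table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Filter credible-set variants on posterior probability
#'
#' Retains variants whose posterior probability of causality is strictly
#' greater than `ppMin` (default 0.03, i.e. the ">3%" convention for 95%
#' credible sets).
#'
#' @param variants Credible-set data.frame (see [readCredibleSets()]).
#' @param ppMin Strict lower threshold on `pp`.
#' @return Filtered data.frame; per-signal retained counts in
#'   `attr(, "signal_counts")`.
#' @export
filterCredible <- function(variants, ppMin = 0.03) {
  if (any(variants$pp < 0 | variants$pp > 1))
    stop("pp outside [0, 1]")
  out <- variants[variants$pp > ppMin, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "signal_counts") <- table(out$signal_id)
  out
}

.variantGRanges <- function(v) GRanges(v$chrom, IRanges(v$pos, v$pos))

#' Overlay variants with loop anchors
#'
#' Finds, for each variant, every (loop, anchor side) whose anchor interval
#' contains the variant position. A wide pair of anchors may both contain a
#' variant; both hits are retained.
#'
#' @param variants Filtered credible-set data.frame.
#' @param loops A `LoopSet`.
#' @return data.frame with one row per (variant, loop, side) hit: variant
#'   columns plus `loop_id`, `side` (`"fwd"`/`"rev"`) and anchor
#'   coordinates. Summary counts in `attr(, "summary")`.
#' @export
variantsInAnchors <- function(variants, loops) {
  vg <- .variantGRanges(variants)
  collect <- function(anchors, side) {
    h <- findOverlaps(vg, anchors, ignore.strand = TRUE)
    if (length(h) == 0) return(NULL)
    cbind(variants[queryHits(h), , drop = FALSE],
          data.frame(loop_id = loopIds(loops)[subjectHits(h)],
                     side = side,
                     anchor_chrom = as.vector(seqnames(anchors))[subjectHits(h)],
                     anchor_start = start(anchors)[subjectHits(h)],
                     anchor_end = end(anchors)[subjectHits(h)]))
  }
  out <- rbind(collect(anchorFwd(loops), "fwd"),
               collect(anchorRev(loops), "rev"))
  if (is.null(out))
    out <- cbind(variants[0, , drop = FALSE],
                 data.frame(loop_id = character(), side = character(),
                            anchor_chrom = character(),
                            anchor_start = integer(),
                            anchor_end = integer()))
  out <- out[order(out$signal_id, out$rsid, out$loop_id, out$side), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_variants = length(unique(out$rsid)),
    n_anchors = nrow(unique(out[c("loop_id", "side")])),
    n_signals = length(unique(out$signal_id)))
  out
}

#' Restrict anchor hits to variants inside active enhancers
#'
#' Keeps only (variant, loop, side) hits where the variant falls inside an
#' active enhancer element that itself overlaps the containing anchor.
#' Variants in inactive enhancers, or in the anchor but outside any cCRE,
#' are excluded (the latter remain anchor-only hits upstream).
#'
#' @param anchorHits Output of [variantsInAnchors()].
#' @param elements Classified elements from [classifyActivity()].
#' @return data.frame of hits with an added `enhancer_id` column.
#' @export
variantsInActiveEnhancers <- function(anchorHits, elements) {
  enh <- elements[mcols(elements)$kind == "enhancer" &
                    mcols(elements)$active]
  if (nrow(anchorHits) == 0 || length(enh) == 0) {
    out <- cbind(anchorHits[0, , drop = FALSE],
                 data.frame(enhancer_id = character()))
    return(out)
  }
  vg <- GRanges(anchorHits$chrom, IRanges(anchorHits$pos, anchorHits$pos))
  anchors <- GRanges(anchorHits$anchor_chrom,
                     IRanges(anchorHits$anchor_start, anchorHits$anchor_end))
  h <- findOverlaps(vg, enh, ignore.strand = TRUE)
  inAnchor <- intervalsOverlap(anchors[queryHits(h)], enh[subjectHits(h)])
  h <- h[inAnchor]
  out <- cbind(anchorHits[queryHits(h), , drop = FALSE],
               data.frame(enhancer_id =
                            mcols(enh)$element_id[subjectHits(h)]))
  out <- unique(out)
  out <- out[order(out$signal_id, out$rsid, out$loop_id, out$side,
                   out$enhancer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyChains <- function() {
  data.frame(signal_id = character(), rsid = character(),
             phenotype = character(), enhancer_id = character(),
             hop_enhancer_id = character(), promoter_id = character(),
             gene_ids = character(), loop_ids = character(),
             n_hops = integer(), stringsAsFactors = FALSE)
}

.geneMapCollapse <- function(activeProms, genes, up, down) {
  gm <- annotatePromoterGenes(activeProms, genes, up, down)
  collapsed <- vapply(split(gm$gene_id, gm$element_id),
                      function(g) paste(sort(unique(g)), collapse = ","), "")
  setNames(collapsed, names(collapsed))
}

.anchorOfSide <- function(loops, idx, side) {
  out <- anchorFwd(loops)[idx]
  rev <- side == "rev"
  if (any(rev)) out[rev] <- anchorRev(loops)[idx[rev]]
  out
}

.finishChains <- function(chains) {
  chains <- unique(chains)
  chains <- chains[order(chains$signal_id, chains$rsid, chains$promoter_id,
                         chains$enhancer_id, chains$loop_ids), ,
                   drop = FALSE]
  rownames(chains) <- NULL
  chains
}

#' Build one-hop enhancer-promoter chains
#'
#' For each variant sitting in an active enhancer on a loop anchor, the
#' opposite anchor of that loop is screened for active promoters; each such
#' promoter yields one chain, annotated with the genes whose TSS falls in
#' the promoter search window.
#'
#' @param snpEnh Output of [variantsInActiveEnhancers()].
#' @param loops `LoopSet` the hits refer to.
#' @param elements Classified elements (promoters are taken from here).
#' @param genes Gene table (see [readGeneTable()]).
#' @param up,down Promoter-to-gene window (bp).
#' @return Chain data.frame (`n_hops = 1`), deterministically ordered by
#'   (signal, variant, promoter).
#' @export
buildEpChains <- function(snpEnh, loops, elements, genes,
                          up = 1500L, down = 500L) {
  prom <- elements[mcols(elements)$kind == "promoter" &
                     mcols(elements)$active]
  if (nrow(snpEnh) == 0 || length(prom) == 0) return(.emptyChains())
  geneMap <- .geneMapCollapse(prom, genes, up, down)
  idx <- match(snpEnh$loop_id, loopIds(loops))
  opp <- .anchorOfSide(loops, idx, ifelse(snpEnh$side == "fwd", "rev", "fwd"))
  h <- findOverlaps(opp, prom, ignore.strand = TRUE)
  if (length(h) == 0) return(.emptyChains())
  pid <- mcols(prom)$element_id[subjectHits(h)]
  chains <- data.frame(
    signal_id = snpEnh$signal_id[queryHits(h)],
    rsid = snpEnh$rsid[queryHits(h)],
    phenotype = snpEnh$phenotype[queryHits(h)],
    enhancer_id = snpEnh$enhancer_id[queryHits(h)],
    hop_enhancer_id = NA_character_,
    promoter_id = pid,
    gene_ids = unname(ifelse(pid %in% names(geneMap), geneMap[pid], "")),
    loop_ids = snpEnh$loop_id[queryHits(h)],
    n_hops = 1L, stringsAsFactors = FALSE)
  .finishChains(chains)
}

#' Build two-hop enhancer-enhancer-promoter chains
#'
#' For variant-enhancer loops whose opposite anchor carries at least one
#' active enhancer but no active promoter, every other loop touching that
#' anchor is followed; when the far anchor of such a second loop overlaps an
#' active promoter, a two-hop chain is emitted. A loop whose opposite anchor
#' already has an active promoter is handled by [buildEpChains()] and yields
#' no two-hop chain.
#'
#' @inheritParams buildEpChains
#' @return Chain data.frame (`n_hops = 2`; `loop_ids` is the comma-joined
#'   two-loop path, `hop_enhancer_id` the intermediate active enhancer).
#' @export
buildEeChains <- function(snpEnh, loops, elements, genes,
                          up = 1500L, down = 500L) {
  prom <- elements[mcols(elements)$kind == "promoter" &
                     mcols(elements)$active]
  enh <- elements[mcols(elements)$kind == "enhancer" &
                    mcols(elements)$active]
  if (nrow(snpEnh) == 0 || length(enh) == 0) return(.emptyChains())
  geneMap <- .geneMapCollapse(prom, genes, up, down)
  promByFwd <- findOverlaps(anchorFwd(loops), prom, ignore.strand = TRUE)
  promByRev <- findOverlaps(anchorRev(loops), prom, ignore.strand = TRUE)
  hasPromFwd <- countOverlaps(anchorFwd(loops), prom, ignore.strand = TRUE) > 0
  hasPromRev <- countOverlaps(anchorRev(loops), prom, ignore.strand = TRUE) > 0
  chains <- .emptyChains()
  for (k in seq_len(nrow(snpEnh))) {
    i <- match(snpEnh$loop_id[k], loopIds(loops))
    oppSide <- if (snpEnh$side[k] == "fwd") "rev" else "fwd"
    opp <- .anchorOfSide(loops, i, oppSide)
    # the opposite anchor must carry an active enhancer and no active promoter
    hopEnh <- mcols(enh)$element_id[
      countOverlaps(enh, opp, ignore.strand = TRUE) > 0]
    hasProm <- if (oppSide == "rev") hasPromRev[i] else hasPromFwd[i]
    if (length(hopEnh) == 0 || hasProm) next
    # follow every other loop touching that anchor
    touchFwd <- which(countOverlaps(anchorFwd(loops), opp,
                                    ignore.strand = TRUE) > 0)
    touchRev <- which(countOverlaps(anchorRev(loops), opp,
                                    ignore.strand = TRUE) > 0)
    for (j2 in setdiff(union(touchFwd, touchRev), i)) {
      farSides <- c(if (j2 %in% touchFwd) "rev", if (j2 %in% touchRev) "fwd")
      for (farSide in farSides) {
        ph <- if (farSide == "rev") promByRev else promByFwd
        pid <- mcols(prom)$element_id[subjectHits(ph)[queryHits(ph) == j2]]
        if (length(pid) == 0) next
        chains <- rbind(chains, data.frame(
          signal_id = snpEnh$signal_id[k], rsid = snpEnh$rsid[k],
          phenotype = snpEnh$phenotype[k],
          enhancer_id = snpEnh$enhancer_id[k],
          hop_enhancer_id = rep(hopEnh, each = length(pid)),
          promoter_id = rep(pid, times = length(hopEnh)),
          gene_ids = rep(unname(ifelse(pid %in% names(geneMap),
                                       geneMap[pid], "")),
                         times = length(hopEnh)),
          loop_ids = paste(snpEnh$loop_id[k], loopIds(loops)[j2], sep = ","),
          n_hops = 2L, stringsAsFactors = FALSE))
      }
    }
  }
  .finishChains(chains)
}

#' Screen cCRE-free loop anchors for novel active regions
#'
#' Considers only loops where neither anchor overlaps any cCRE element, and
#' reports the anchors of those loops that themselves satisfy the enhancer
#' activity evidence rule (ATAC consensus overlap plus H3K4me1 and H3K27ac
#' each in at least `chipMinReps` replicates) — candidate regulatory regions
#' absent from the cCRE catalogue.
#'
#' @param loops A `LoopSet`.
#' @param elements cCRE `GRanges` (any kind).
#' @param evidence A [peakEvidence()] bundle.
#' @param chipMinReps Replicate threshold (default 2).
#' @return `GRanges` of qualifying anchors with `loop_id` and `side`
#'   metadata columns.
#' @export
screenNoCcreAnchors <- function(loops, elements, evidence, chipMinReps = 2L) {
  free <- countOverlaps(anchorFwd(loops), elements, ignore.strand = TRUE) == 0 &
    countOverlaps(anchorRev(loops), elements, ignore.strand = TRUE) == 0
  cand <- c(anchorFwd(loops)[free], anchorRev(loops)[free])
  if (length(cand) == 0) {
    mcols(cand)$loop_id <- character()
    mcols(cand)$side <- character()
    return(cand)
  }
  mcols(cand)$loop_id <- rep(loopIds(loops)[free], 2)
  mcols(cand)$side <- rep(c("fwd", "rev"), each = sum(free))
  atac <- countOverlaps(cand, evidence$atac, ignore.strand = TRUE) > 0
  k4me1 <- replicateSupport(cand, evidence$chip$H3K4me1)
  k27ac <- replicateSupport(cand, evidence$chip$H3K27ac)
  out <- cand[atac & k4me1 >= chipMinReps & k27ac >= chipMinReps]
  out[order(as.vector(seqnames(out)), start(out), mcols(out)$side)]
}

#' Read a molecular QTL table
#'
#' Tab-separated with header columns `rsid`, `qtl_type`
#' (`eQTL`/`pQTL`/`methQTL`), `target`, `grade` (`low`/`high`) and
#' pass-through statistics columns (`beta`, `se`, `p`).
#'
#' @param path File path.
#' @return data.frame.
#' @export
readQtlTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("rsid", "qtl_type", "target", "grade")
  if (!all(need %in% names(df)))
    stop("QTL table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$qtl_type %in% c("eQTL", "pQTL", "methQTL")))
    stop("qtl_type must be one of eQTL, pQTL, methQTL")
  if (!all(df$grade %in% c("low", "high")))
    stop("grade must be 'low' or 'high'")
  df
}

#' Attach molecular QTL annotations to chains
#'
#' Each chain gains the QTL records whose rsid equals the chain variant's
#' rsid, grouped (sorted, comma-collapsed as `qtl_type:target:grade`) in a
#' `qtls` column. Duplicate (rsid, qtl_type, target, grade) rows in the QTL
#' table are deduplicated with a warning.
#'
#' @param chains Chain data.frame from [buildEpChains()]/[buildEeChains()].
#' @param qtls QTL data.frame (see [readQtlTable()]).
#' @return `chains` with an added `qtls` column (empty string when the
#'   variant has no QTL record).
#' @export
joinQtls <- function(chains, qtls) {
  key <- c("rsid", "qtl_type", "target", "grade")
  dup <- duplicated(qtls[key])
  if (any(dup)) {
    warning(sum(dup), " duplicate QTL row(s) removed")
    qtls <- qtls[!dup, , drop = FALSE]
  }
  lab <- sprintf("%s:%s:%s", qtls$qtl_type, qtls$target, qtls$grade)
  byRsid <- split(lab, qtls$rsid)
  chains$qtls <- vapply(chains$rsid, function(r) {
    v <- byRsid[[r]]
    if (is.null(v)) "" else paste(sort(v), collapse = ",")
  }, "", USE.NAMES = FALSE)
  chains
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two genotype dosage vectors.
#'
#' @param g1,g2 Numeric dosage vectors of equal length (>= 2), each with
#'   non-zero variance.
#' @return r-squared in \[0, 1\].
#' @export
ldR2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  if (length(g1) < 2) stop("need at least 2 samples")
  d1 <- g1 - mean(g1)
  d2 <- g2 - mean(g2)
  v1 <- sum(d1^2)
  v2 <- sum(d2^2)
  if (v1 == 0 || v2 == 0) stop("monomorphic site: zero variance")
  (sum(d1 * d2)^2) / (v1 * v2)
}
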