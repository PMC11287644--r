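CHIP_MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac")

#' Bundle peak evidence for activity classification
#'
#' Collects the open-chromatin and histone-mark peak tracks used to decide
#' whether a candidate cis-regulatory element is active: one ATAC consensus
#' peak set plus per-replicate ChIP-seq peak sets for H3K4me1, H3K4me3 and
#' H3K27ac.
#'
#' @param atac `GRanges` of consensus ATAC (open chromatin) peaks.
#' @param chip Named list, one entry per histone mark in
#'   `c("H3K4me1","H3K4me3","H3K27ac")`, each a list of per-replicate
#'   `GRanges`.
#' @return A `peakEvidence` list (class `"peakEvidence"`).
#' @export
peakEvidence <- function(atac, chip) {
  stopifnot(is(atac, "GRanges"), is.list(chip))
  unknown <- setdiff(names(chip), CHIP_MARKS)
  if (length(unknown))
    stop("unknown ChIP mark(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(CHIP_MARKS, names(chip))
  if (length(missing))
    stop("missing ChIP mark(s): ", paste(missing, collapse = ", "))
  structure(list(atac = atac, chip = chip), class = "peakEvidence")
}

#' @export
print.peakEvidence <- function(x, ...) {
  cat("peakEvidence:", length(x$atac), "ATAC consensus peaks;",
      paste(sprintf("%s (%d reps)", names(x$chip), lengths(x$chip)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Build a k-of-n consensus peak set
#'
#' Returns the genomic regions covered by peaks in at least `minReps` of the
#' given replicate tracks (per-base coverage threshold), as is commonly done
#' to form an ATAC consensus from per-sample peak calls.
#'
#' @param reps List of per-replicate peak `GRanges`.
#' @param minReps Minimum number of supporting replicates per base.
#' @return Consensus `GRanges`.
#' @export
consensusPeaks <- function(reps, minReps) {
  stopifnot(length(reps) >= 1, minReps >= 1)
  # each replicate reduced first, so per-base coverage of the pooled set
  # counts supporting replicates
  pooled <- do.call(c, lapply(reps, function(r)
    GenomicRanges::reduce(granges(r), ignore.strand = TRUE)))
  GRanges(IRanges::slice(coverage(pooled), lower = minReps,
                         rangesOnly = TRUE))
}

#' Count supporting replicates for elements against one mark
#'
#' For each element, the number of replicate tracks in which the element
#' overlaps at least one peak of the given mark.
#'
#' @param elements `GRanges` of regulatory elements.
#' @param reps List of per-replicate peak `GRanges` for a single mark.
#' @return Integer vector parallel to `elements`.
#' @export
replicateSupport <- function(elements, reps) {
  if (length(reps) == 0) return(integer(length(elements)))
  Reduce(`+`, lapply(reps, function(r)
    as.integer(countOverlaps(elements, r, ignore.strand = TRUE) > 0)))
}

#' Classify regulatory elements as active or inactive
#'
#' A promoter is active when it overlaps the ATAC consensus AND is supported
#' by H3K4me3 in at least `chipMinReps` replicates AND by H3K27ac in at
#' least `chipMinReps` replicates. An enhancer is active under the same rule
#' with H3K4me1 in place of H3K4me3. The default replicate threshold is 2
#' (of 3 ChIP replicates).
#'
#' @param elements `GRanges` with metadata columns `element_id` and `kind`
#'   (`"enhancer"` or `"promoter"`).
#' @param evidence A [peakEvidence()] bundle.
#' @param chipMinReps Minimum supporting ChIP replicates per required mark.
#' @return `elements` with added metadata columns `atac` (logical),
#'   `k4me1_reps`, `k4me3_reps`, `k27ac_reps` (integer) and `active`
#'   (logical).
#' @export
classifyActivity <- function(elements, evidence, chipMinReps = 2L) {
  kind <- mcols(elements)$kind
  if (is.null(kind) || is.null(mcols(elements)$element_id))
    stop("elements need 'element_id' and 'kind' metadata columns")
  bad <- setdiff(unique(kind), c("enhancer", "promoter"))
  if (length(bad))
    stop("unknown element kind(s): ", paste(bad, collapse = ", "))
  atac <- countOverlaps(elements, evidence$atac, ignore.strand = TRUE) > 0
  k4me1 <- replicateSupport(elements, evidence$chip$H3K4me1)
  k4me3 <- replicateSupport(elements, evidence$chip$H3K4me3)
  k27ac <- replicateSupport(elements, evidence$chip$H3K27ac)
  markOk <- ifelse(kind == "promoter", k4me3, k4me1) >= chipMinReps
  active <- atac & markOk & k27ac >= chipMinReps
  mcols(elements)$atac <- atac
  mcols(elements)$k4me1_reps <- k4me1
  mcols(elements)$k4me3_reps <- k4me3
  mcols(elements)$k27ac_reps <- k27ac
  mcols(elements)$active <- active
  elements
}

#' Annotate active promoters to genes
#'
#' Searches for gene transcription start sites within a window extending
#' `up` bp upstream (genomically leftward, clamped at the chromosome origin)
#' and `down` bp downstream of each promoter element. The window is
#' strand-agnostic on the element; the TSS per gene is taken as given in the
#' gene table (strand-aware by construction of that table).
#'
#' @param promoters `GRanges` of promoter elements with `element_id`
#'   metadata column.
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (1-based
#'   TSS position), `strand`.
#' @param up,down Window extensions in bp (defaults 1500/500).
#' @return data.frame of (`element_id`, `gene_id`) pairs; zero rows when no
#'   gene falls in any window.
#' @export
annotatePromoterGenes <- function(promoters, genes, up = 1500L, down = 500L) {
  if (length(promoters) == 0 || nrow(genes) == 0)
    return(data.frame(element_id = character(), gene_id = character()))
  win <- expandInterval(promoters, up, down)
  tss <- GRanges(genes$chrom, IRanges(genes$tss, genes$tss))
  hits <- findOverlaps(win, tss, ignore.strand = TRUE)
  out <- data.frame(
    element_id = mcols(promoters)$element_id[queryHits(hits)],
    gene_id = genes$gene_id[subjectHits(hits)])
  out[order(out$element_id, out$gene_id), , drop = FALSE]
}

#' Read a cCRE BED file
#'
#' Column 4 carries the element kind (`enhancer` or `promoter`). Stable
#' element ids are derived from kind and 0-based coordinates.
#'
#' @param path BED file path.
#' @return `GRanges` with `element_id` and `kind` metadata columns.
#' @export
readCcreBed <- function(path) {
  gr <- readBed(path)
  kind <- mcols(gr)$name
  if (is.null(kind)) stop("cCRE BED needs a 4th (kind) column")
  mcols(gr) <- NULL
  mcols(gr)$kind <- kind
  mcols(gr)$element_id <- sprintf("%s_%s_%d_%d", kind,
                                  as.vector(seqnames(gr)),
                                  start(gr) - 1L, end(gr))
  gr
}

#' Read a gene table
#'
#' Tab-separated with header columns `chrom`, `tss`, `strand`, `gene_id`;
#' `tss` is the 1-based strand-aware transcription start position.
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
readGeneTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "tss", "strand", "gene_id")
  if (!all(need %in% names(df)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  df
}
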