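#' @import methods
#' @importFrom stats median rnorm runif setNames cor pnorm
#' @importFrom utils read.table write.table
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame metadata metadata<-
#' @importFrom IRanges IRanges poverlaps ranges slice
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps reduce coverage granges sort resize
NULL

#' Pairwise interval overlap predicate
#'
#' Tests, element by element, whether two parallel `GRanges` overlap by at
#' least one base on the same chromosome (bedtools-default semantics; no
#' distance slack). Both arguments are recycled to a common length the way
#' base R recycles vectors of length one.
#'
#' @param a,b `GRanges` of equal length (or either of length 1).
#' @return Logical vector, one element per pair.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20))
#' intervalsOverlap(a, b)  # FALSE: abutting, no shared base
#' @export
intervalsOverlap <- function(a, b) {
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  as.vector(seqnames(a) == seqnames(b)) &
    IRanges::poverlaps(ranges(a), ranges(b), type = "any")
}

#' Normalise an interval set
#'
#' Sorts by (chromosome, start) and fuses every run of overlapping intervals
#' into one maximal interval, so the result covers exactly the union of the
#' input. Idempotent and order-independent.
#'
#' @param gr A `GRanges`.
#' @return A reduced, sorted `GRanges`.
#' @export
mergeIntervals <- function(gr) {
  GenomicRanges::reduce(GenomicRanges::sort(gr), ignore.strand = TRUE)
}

#' Extend intervals upstream/downstream
#'
#' Widens each interval by a fixed number of bases on each side,
#' strand-agnostically: `upstream` bases are removed from the start
#' coordinate (clamped at the chromosome origin) and `downstream` bases are
#' added to the end. Used for the promoter-to-gene search window.
#'
#' @param gr A `GRanges`.
#' @param upstream,downstream Non-negative base-pair extensions.
#' @return A `GRanges` of the same length.
#' @export
expandInterval <- function(gr, upstream = 0L, downstream = 0L) {
  stopifnot(upstream >= 0, downstream >= 0)
  GRanges(seqnames(gr),
          IRanges(pmax(1L, start(gr) - as.integer(upstream)),
                  end(gr) + as.integer(downstream)))
}

#' Read a BED file as GRanges
#'
#' Thin wrapper over [rtracklayer::import()] for BED3+ input (tab-separated,
#' no header). Lines starting with `#` are skipped before parsing. BED's
#' 0-based half-open coordinates are converted to the 1-based closed GRanges
#' convention on read.
#'
#' @param path Path to a BED file.
#' @return `GRanges`, with a `name` metadata column when column 4 is present.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  if (any(startsWith(lines, "#"))) {
    tmp <- tempfile(fileext = ".bed")
    on.exit(unlink(tmp))
    writeLines(lines[!startsWith(lines, "#")], tmp)
    path <- tmp
  }
  rtracklayer::import(path, format = "BED")
}

#' Write GRanges as BED
#'
#' @param gr `GRanges`; a `name` metadata column, if present, becomes BED
#'   column 4.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
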