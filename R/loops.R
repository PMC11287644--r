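#' LoopSet: a set of intra-chromosomal chromatin loops
#'
#' Holds paired loop anchors as two parallel `GRanges` plus per-loop
#' provenance (supporting caller(s), resolution(s), stable id). Anchors are
#' stored in canonical order: `anchor1` (the "forward" anchor) always starts
#' at or before `anchor2` (the "reverse" anchor) on the same chromosome.
#'
#' @slot anchor1 `GRanges` of forward (left) anchors.
#' @slot anchor2 `GRanges` of reverse (right) anchors, parallel to `anchor1`.
#' @slot loopData `DataFrame` with columns `loop_id`, `callers`,
#'   `resolutions` (comma-collapsed label sets).
#' @slot metadata List of bookkeeping counts (e.g. rows excluded at parse
#'   time).
#' @export
setClass("LoopSet",
         representation(anchor1 = "GRanges", anchor2 = "GRanges",
                        loopData = "DataFrame", metadata = "list"))

setValidity("LoopSet", function(object) {
  msg <- character()
  n <- length(object@anchor1)
  if (length(object@anchor2) != n || nrow(object@loopData) != n)
    msg <- c(msg, "anchor1, anchor2 and loopData must be parallel")
  if (n > 0) {
    if (!all(as.vector(seqnames(object@anchor1)) ==
             as.vector(seqnames(object@anchor2))))
      msg <- c(msg, "loops must be intra-chromosomal")
    if (!all(start(object@anchor1) <= start(object@anchor2)))
      msg <- c(msg, "anchor1 must start at or before anchor2")
    if (anyDuplicated(object@loopData$loop_id))
      msg <- c(msg, "loop ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LoopSet
#'
#' Anchor pairs given in reversed coordinate order are swapped into canonical
#' (left, right) order automatically.
#'
#' @param anchor1,anchor2 Parallel `GRanges` (one anchor pair per loop, same
#'   chromosome within a pair).
#' @param caller Caller label(s), length 1 or one per loop.
#' @param resolution Bin size(s) in bp, length 1 or one per loop.
#' @param loopId Optional stable ids; generated from caller/resolution/index
#'   when omitted.
#' @param metadata Optional list of bookkeeping values.
#' @return A `LoopSet`.
#' @export
LoopSet <- function(anchor1, anchor2, caller = "caller",
                    resolution = NA_integer_, loopId = NULL,
                    metadata = list()) {
  anchor1 <- granges(anchor1)
  anchor2 <- granges(anchor2)
  n <- length(anchor1)
  swap <- start(anchor2) < start(anchor1)
  if (any(swap)) {
    tmp <- anchor1[swap]
    anchor1[swap] <- anchor2[swap]
    anchor2[swap] <- tmp
  }
  caller <- rep_len(as.character(caller), n)
  resolution <- rep_len(as.character(resolution), n)
  if (is.null(loopId)) {
    loopId <- sprintf("%s_%s_%05d", caller, resolution, seq_len(max(n, 0L)))
  }
  new("LoopSet", anchor1 = anchor1, anchor2 = anchor2,
      loopData = DataFrame(loop_id = as.character(loopId),
                           callers = caller, resolutions = resolution),
      metadata = metadata)
}

#' @describeIn LoopSet-class Number of loops.
#' @param x A `LoopSet`.
#' @export
setMethod("length", "LoopSet", function(x) length(x@anchor1))

#' Accessors for LoopSet slots
#'
#' `anchorFwd()`/`anchorRev()` return the left/right anchor `GRanges`;
#' `loopIds()` the stable per-loop ids; `loopCallers()` the comma-collapsed
#' supporting caller labels; `loopMeta()` the bookkeeping list.
#'
#' @param x A `LoopSet`.
#' @return See individual descriptions.
#' @export
anchorFwd <- function(x) x@anchor1

#' @rdname anchorFwd
#' @export
anchorRev <- function(x) x@anchor2

#' @rdname anchorFwd
#' @export
loopIds <- function(x) x@loopData$loop_id

#' @rdname anchorFwd
#' @export
loopCallers <- function(x) x@loopData$callers

#' @rdname anchorFwd
#' @export
loopMeta <- function(x) x@metadata

setMethod("show", "LoopSet", function(object) {
  cat("LoopSet with", length(object), "loops\n")
  if (length(object)) {
    callers <- sort(unique(unlist(strsplit(object@loopData$callers, ","))))
    cat("  callers:", paste(callers, collapse = ", "), "\n")
    cat("  chroms: ",
        paste(unique(as.vector(seqnames(object@anchor1))), collapse = ", "),
        "\n")
  }
  for (nm in names(object@metadata))
    cat("  ", nm, ": ", object@metadata[[nm]], "\n", sep = "")
})

#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = TRUE) {
  new("LoopSet", anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
      loopData = x@loopData[i, , drop = FALSE], metadata = x@metadata)
})

.concatLoopSets <- function(sets) {
  new("LoopSet",
      anchor1 = do.call(c, lapply(sets, anchorFwd)),
      anchor2 = do.call(c, lapply(sets, anchorRev)),
      loopData = do.call(rbind, lapply(sets, function(s) s@loopData)),
      metadata = list())
}

# Deterministic content hash for merged-loop ids: polynomial rolling hash of
# the sorted member-id string, computed in exact double arithmetic mod 2^47.
.loopHash <- function(memberIds) {
  s <- paste(sort(memberIds), collapse = "|")
  h <- 0
  m <- 2^47
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% m
  sprintf("L%.0f", h)
}

#' Read chromatin loops from a BEDPE file
#'
#' Parses a 6+ column tab-separated BEDPE file (0-based half-open anchors,
#' `#`-comment lines skipped) into a [LoopSet]. Anchor pairs are put into
#' canonical left/right order. Inter-chromosomal rows are excluded and
#' counted in the result's metadata (`n_interchromosomal_excluded`).
#'
#' @param path BEDPE file path.
#' @param caller Caller label recorded for every loop.
#' @param resolution Bin size in bp recorded for every loop.
#' @return A `LoopSet`.
#' @export
readLoopsBedpe <- function(path, caller, resolution) {
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineNo <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed BEDPE row (fewer than 6 columns) at line ",
         lineNo[which(nf < 6)[1]])
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  st1 <- suppressWarnings(as.numeric(m[, 2])); en1 <- suppressWarnings(as.numeric(m[, 3]))
  st2 <- suppressWarnings(as.numeric(m[, 5])); en2 <- suppressWarnings(as.numeric(m[, 6]))
  bad <- is.na(st1) | is.na(en1) | is.na(st2) | is.na(en2)
  if (any(bad))
    stop("malformed BEDPE row (non-numeric coordinate) at line ",
         lineNo[which(bad)[1]])
  degen <- en1 <= st1 | en2 <= st2
  if (any(degen))
    stop("anchor with end <= start at line ", lineNo[which(degen)[1]])
  cis <- m[, 1] == m[, 4]
  nTrans <- sum(!cis)
  if (nTrans > 0)
    message(nTrans, " inter-chromosomal row(s) excluded from ", basename(path))
  a1 <- GRanges(m[cis, 1], IRanges(st1[cis] + 1, en1[cis]))
  a2 <- GRanges(m[cis, 4], IRanges(st2[cis] + 1, en2[cis]))
  LoopSet(a1, a2, caller = caller, resolution = resolution,
          metadata = list(n_interchromosomal_excluded = nTrans,
                          source = basename(path)))
}

#' Write a LoopSet as BEDPE
#'
#' Emits BEDPE (0-based half-open) with extra columns `loop_id`,
#' `caller_support` and `resolutions`.
#'
#' @param x A `LoopSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLoopsBedpe <- function(x, path) {
  df <- data.frame(
    chrom1 = as.vector(seqnames(anchorFwd(x))),
    start1 = start(anchorFwd(x)) - 1L, end1 = end(anchorFwd(x)),
    chrom2 = as.vector(seqnames(anchorRev(x))),
    start2 = start(anchorRev(x)) - 1L, end2 = end(anchorRev(x)),
    loop_id = loopIds(x), caller_support = x@loopData$callers,
    resolutions = x@loopData$resolutions)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Connected-components merge: loops are joined when their forward anchors
# overlap AND their reverse anchors overlap; components are the transitive
# closure of that relation. Each component emits one loop whose anchors are
# the enclosing range of the member anchors.
.mergeLoopComponents <- function(ls) {
  n <- length(ls)
  if (n == 0) return(ls)
  h1 <- findOverlaps(ls@anchor1, ls@anchor1, ignore.strand = TRUE)
  h2 <- findOverlaps(ls@anchor2, ls@anchor2, ignore.strand = TRUE)
  key1 <- (queryHits(h1) - 1) * n + subjectHits(h1)
  key2 <- (queryHits(h2) - 1) * n + subjectHits(h2)
  both <- intersect(key1, key2)
  q <- (both - 1) %/% n + 1
  s <- (both - 1) %% n + 1
  g <- igraph::graph_from_edgelist(cbind(q, s), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  # enclosing range per component (single chromosome per component by
  # construction: overlap requires equal seqnames and loops are cis)
  f <- factor(comp)
  a1 <- unlist(range(S4Vectors::split(ls@anchor1, f)), use.names = FALSE)
  a2 <- unlist(range(S4Vectors::split(ls@anchor2, f)), use.names = FALSE)
  idsBy <- split(ls@loopData$loop_id, f)
  callersBy <- split(ls@loopData$callers, f)
  resBy <- split(ls@loopData$resolutions, f)
  collapseLabels <- function(v)
    paste(sort(unique(unlist(strsplit(v, ",")))), collapse = ",")
  sizes <- lengths(idsBy)
  newId <- ifelse(sizes == 1L, vapply(idsBy, `[`, "", 1L),
                  vapply(idsBy, .loopHash, ""))
  ld <- DataFrame(loop_id = unname(newId),
                  callers = unname(vapply(callersBy, collapseLabels, "")),
                  resolutions = unname(vapply(resBy, collapseLabels, "")))
  out <- new("LoopSet", anchor1 = a1, anchor2 = a2, loopData = ld,
             metadata = list(n_input = n, n_merged = length(a1)))
  validObject(out)
  out
}

#' Merge loop calls across resolutions within one caller
#'
#' Groups loops whose forward anchors overlap and whose reverse anchors
#' overlap (transitive closure over the pairwise both-anchors-overlap graph)
#' and replaces each group by a single loop whose anchors are the enclosing
#' union of the member anchors. Loops overlapping nothing pass through
#' unchanged.
#'
#' @param loops5kb,loops10kb `LoopSet`s from the same caller at the two
#'   resolutions (`loops10kb` may be `NULL`).
#' @return A merged `LoopSet`.
#' @export
mergeResolutions <- function(loops5kb, loops10kb = NULL) {
  sets <- Filter(Negate(is.null), list(loops5kb, loops10kb))
  callers <- unique(unlist(lapply(sets, loopCallers)))
  if (length(callers) > 1)
    stop("mergeResolutions expects loops from a single caller; got: ",
         paste(callers, collapse = ", "))
  .mergeLoopComponents(.concatLoopSets(sets))
}

#' Union loop calls across callers
#'
#' Applies the same both-anchors-overlap connected-components merge as
#' [mergeResolutions()], but across callers; each merged loop records the
#' set of supporting callers in its `callers` label.
#'
#' @param perCaller Named list of `LoopSet`s, one per caller.
#' @return A merged `LoopSet`.
#' @export
unionAcrossCallers <- function(perCaller) {
  if (length(perCaller) < 1) stop("need at least one caller")
  .mergeLoopComponents(.concatLoopSets(unname(perCaller)))
}

#' Remove loops whose two anchors overlap each other
#'
#' After union-anchor merging, a loop's two anchors can come to overlap;
#' such self-overlapping loops are dropped before downstream analysis. The
#' number removed is recorded in the result metadata
#' (`n_self_overlap_removed`).
#'
#' @param loops A `LoopSet`.
#' @return Filtered `LoopSet`.
#' @export
dropSelfOverlapping <- function(loops) {
  if (length(loops) == 0) {
    loops@metadata$n_self_overlap_removed <- 0L
    return(loops)
  }
  keep <- !intervalsOverlap(anchorFwd(loops), anchorRev(loops))
  out <- loops[keep]
  out@metadata <- loops@metadata
  out@metadata$n_self_overlap_removed <- sum(!keep)
  out
}

#' CTCF anchor quality control
#'
#' Fraction of loops whose forward (resp. reverse) anchor overlaps at least
#' one CTCF motif site. Anchor sides are positional (left/right by
#' coordinate); motif strand is ignored.
#'
#' @param loops A `LoopSet`.
#' @param motifs `GRanges` of CTCF motif sites.
#' @return One-row data.frame: `n_loops`, `ctcf_fwd_ratio`, `ctcf_rev_ratio`.
#' @export
ctcfQc <- function(loops, motifs) {
  n <- length(loops)
  if (n == 0)
    return(data.frame(n_loops = 0L, ctcf_fwd_ratio = 0, ctcf_rev_ratio = 0))
  data.frame(
    n_loops = n,
    ctcf_fwd_ratio = mean(countOverlaps(anchorFwd(loops), motifs,
                                        ignore.strand = TRUE) > 0),
    ctcf_rev_ratio = mean(countOverlaps(anchorRev(loops), motifs,
                                        ignore.strand = TRUE) > 0))
}

#' CTCF coverage of TAD boundaries
#'
#' Fraction of TAD boundary intervals overlapping at least one CTCF motif —
#' the standard quality metric for a TAD call set.
#'
#' @param boundaries `GRanges` of TAD boundary intervals.
#' @param motifs `GRanges` of CTCF motif sites.
#' @return A single fraction in \[0, 1\].
#' @export
tadBoundaryCtcfCoverage <- function(boundaries, motifs) {
  if (length(boundaries) == 0)
    stop("empty TAD boundary set: coverage fraction undefined")
  mean(countOverlaps(boundaries, motifs, ignore.strand = TRUE) > 0)
}
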