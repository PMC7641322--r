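## Unique assignment of sequenced fragments to repeat annotations, per-type
## aggregation, and per-million depth normalization.  A read pair is one
## counting unit spanning its outer coordinates; assignment is by maximal
## overlap with deterministic coordinate tie-breaking, so no fragment ever
## contributes to two repeat types.

#' Read a repeat annotation BED
#'
#' BED6-style file whose name field is `subfamily|family|class` (class one of
#' LTR, LINE, SINE, other).  Subfamily labels of LTR/internal pairs use the
#' `"LTRname::internal-name"` convention.
#'
#' @param path BED file path.
#' @param sizes Named chromosome lengths.
#' @return `GRanges` with metadata columns `subfamily`, `family`, `class`.
#' @export
read_repeat_bed <- function(path, sizes) {
  sizes <- validate_chrom_sizes(sizes)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = sizes)
    gr$subfamily <- gr$family <- gr$class <- character(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) stop("read_repeat_bed: need >= 4 columns")
  name <- vapply(fields, `[[`, "", 4L)
  parts <- strsplit(name, "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("read_repeat_bed: name field must be subfamily|family|class")
  chrom <- vapply(fields, `[[`, "", 1L)
  keep <- chrom %in% names(sizes)
  gr <- GenomicRanges::GRanges(
    factor(chrom[keep], levels = names(sizes)),
    IRanges::IRanges(as.integer(vapply(fields, `[[`, "", 2L))[keep] + 1L,
                     as.integer(vapply(fields, `[[`, "", 3L))[keep]),
    seqlengths = sizes)
  gr$subfamily <- vapply(parts, `[[`, "", 1L)[keep]
  gr$family <- vapply(parts, `[[`, "", 2L)[keep]
  gr$class <- vapply(parts, `[[`, "", 3L)[keep]
  gr
}

#' Assign fragments uniquely to repeat locations
#'
#' Each fragment (pair or singleton, as a single interval) is assigned to at
#' most one repeat: the overlapping repeat with the largest overlap length;
#' ties resolve to the repeat with the smallest (chromosome, start); fragments
#' overlapping no repeat get NA.  The result is independent of the order of
#' the input fragments.
#'
#' @param frags `GRanges` of fragments.
#' @param repeats `GRanges` repeat annotation (see [read_repeat_bed()]).
#' @return Integer vector, parallel to `frags`, of repeat indices or NA.
#' @export
assign_to_repeats <- function(frags, repeats) {
  out <- rep(NA_integer_, length(frags))
  if (length(frags) == 0L || length(repeats) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(frags, repeats, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits)
  sj <- S4Vectors::subjectHits(hits)
  ol <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(frags)[q], GenomicRanges::ranges(repeats)[sj]))
  ## rank repeats by (chrom, start) once for deterministic tie-breaking
  coord_rank <- order(order(as.factor(GenomicRanges::seqnames(repeats)),
                            GenomicRanges::start(repeats)))
  ord <- order(q, -ol, coord_rank[sj])
  first <- !duplicated(q[ord])
  out[q[ord][first]] <- sj[ord][first]
  out
}

#' Sum assigned fragments per repeat subfamily
#'
#' @param assignments Integer vector from [assign_to_repeats()].
#' @param repeats The repeat annotation the assignments refer to.
#' @return Named integer vector of counts per subfamily (every annotated
#'   subfamily appears, zeros included); sums to the number of assigned
#'   fragments.  The subfamily-to-family/class map is attached as attribute
#'   `"classification"`.
#' @export
count_by_type <- function(assignments, repeats) {
  types <- sort(unique(repeats$subfamily))
  assigned <- assignments[!is.na(assignments)]
  counts <- table(factor(repeats$subfamily[assigned], levels = types))
  out <- stats::setNames(as.integer(counts), types)
  cls <- unique(data.frame(subfamily = repeats$subfamily,
                           family = repeats$family,
                           class = repeats$class))
  attr(out, "classification") <- cls[order(cls$subfamily), , drop = FALSE]
  out
}

#' Depth-normalize a repeat count matrix
#'
#' `value = count * 1e6 / total_mapped` (counts per million mapped fragments),
#' per sample.
#'
#' @param counts Matrix (repeat type x sample) of integer counts, or a named
#'   vector for a single sample.
#' @param total_mapped Per-sample totals of genome-mapped fragments.
#' @return Numeric matrix of normalized counts.
#' @export
normalize_repeat_counts <- function(counts, total_mapped) {
  if (is.null(dim(counts))) counts <- cbind(sample = counts)
  if (length(total_mapped) != ncol(counts))
    stop("normalize_repeat_counts: one total per sample required")
  if (any(total_mapped <= 0))
    stop("normalize_repeat_counts: total_mapped must be > 0")
  sweep(counts, 2L, total_mapped, function(x, tot) x * 1e6 / tot)
}

#' Roll subfamily counts up to repeat classes
#'
#' @param counts Named subfamily count vector from [count_by_type()].
#' @return Named numeric vector of per-class sums (LTR/LINE/SINE/other).
#' @export
rollup_by_class <- function(counts) {
  cls <- attr(counts, "classification")
  if (is.null(cls)) stop("rollup_by_class: counts lack classification attribute")
  tapply(as.numeric(counts[cls$subfamily]), cls$class, sum)
}
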