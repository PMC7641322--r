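## Percentile-threshold peak calling with the 2-of-3 consecutive-window rule
## and mapping of peaks to six genomic compartments.
##
## Thresholds are derived once from a designated reference sample (the
## wild-type serum dataset in the original design) and reused verbatim for
## every other sample, so peak counts are directly comparable across samples.

#' Percentile threshold from a reference track
#'
#' Nearest-rank percentile over the reference's *enriched* windows only
#' (score > 0).  Including the zero-inflated majority of windows would
#' collapse the upper percentile toward zero on sparse data.
#'
#' @param ref Input-subtracted reference `WindowTrack`.
#' @param percentile Percentile in (0, 100]; default 95.
#' @param reference_name Label recorded on the threshold.
#' @return A `Threshold`: list with `value`, `percentile`, `reference_name`.
#' @export
reference_threshold <- function(ref, percentile = 95, reference_name = "reference") {
  stopifnot(inherits(ref, "WindowTrack"))
  if (percentile <= 0 || percentile > 100)
    stop("reference_threshold: percentile must be in (0, 100]")
  pos <- track_score_vector(ref)
  pos <- pos[pos > 0]
  if (length(pos) == 0L)
    stop("reference_threshold: no enriched signal in reference")
  sorted <- sort(pos)
  rank <- ceiling(percentile * length(sorted) / 100)
  structure(list(value = sorted[[rank]],
                 percentile = percentile,
                 reference_name = reference_name),
            class = "Threshold")
}

#' Call peaks with a consecutive-window rule
#'
#' A window qualifies when its score is strictly above the threshold value.
#' Every run of `region_windows` consecutive windows on one chromosome that
#' contains at least `min_qualifying` qualifying windows marks its full span;
#' overlapping or book-ended marked spans are merged into maximal peaks.  With
#' the defaults this is the 2-of-3 rule over 600 bp.
#'
#' @param track Input-subtracted `WindowTrack` on the same grid as the
#'   threshold's reference.
#' @param thr A `Threshold` from [reference_threshold()].
#' @param region_windows Length of the scanned window run (default 3).
#' @param min_qualifying Minimum qualifying windows per run (default 2).
#' @return `GRanges` of peaks with metadata columns `compartment`
#'   (initialized to `"unassigned"`) and `n_qualifying` (number of qualifying
#'   windows inside the peak).
#' @export
call_peaks <- function(track, thr, region_windows = 3L, min_qualifying = 2L) {
  stopifnot(inherits(track, "WindowTrack"), inherits(thr, "Threshold"))
  region_windows <- as.integer(region_windows)
  min_qualifying <- as.integer(min_qualifying)
  if (region_windows < min_qualifying || min_qualifying < 1L)
    stop("call_peaks: need region_windows >= min_qualifying >= 1")
  w <- track$window_size
  peaks <- lapply(names(track$scores), function(ch) {
    q <- track$scores[[ch]] > thr$value
    n <- length(q)
    if (n < region_windows) return(NULL)
    ## rolling count of qualifying windows in each length-k run
    cs <- cumsum(c(0L, as.integer(q)))
    runs <- which((cs[(region_windows + 1L):(n + 1L)] -
                     cs[1L:(n - region_windows + 1L)]) >= min_qualifying)
    if (length(runs) == 0L) return(NULL)
    marked <- logical(n)
    for (i in runs) marked[i:(i + region_windows - 1L)] <- TRUE
    r <- rle(marked)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    start0 <- (starts[sel] - 1L) * w
    end0 <- pmin(ends[sel] * w, track$chrom_sizes[[ch]])
    nq <- vapply(sel, function(i) sum(q[starts[i]:ends[i]]), 0L)
    GenomicRanges::GRanges(ch, IRanges::IRanges(start0 + 1L, end0),
                           compartment = "unassigned", n_qualifying = nq)
  })
  peaks <- peaks[!vapply(peaks, is.null, TRUE)]
  if (length(peaks) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$compartment <- character(0)
    gr$n_qualifying <- integer(0)
    return(gr)
  }
  do.call(c, peaks)
}

#' Strand-aware promoter windows around gene TSSs (internal)
#'
#' Returns the full interval out to `outer` bp from each TSS (the precedence
#' masking in [assign_compartments()] carves out the inner compartments).
#' `side = "symmetric"` extends in both directions; `"downstream"` only in the
#' strand-aware downstream direction (the literal reading of a "TSS + 1 kb"
#' notation).
#' @noRd
promoter_bands <- function(genes, outer, side = "symmetric") {
  tss <- gene_tss(genes)
  chrom <- as.character(GenomicRanges::seqnames(genes$body))
  minus <- as.character(GenomicRanges::strand(genes$body)) == "-"
  if (side == "symmetric") {
    s <- tss - outer
    e <- tss + outer
  } else {
    s <- ifelse(minus, tss - outer, tss)
    e <- ifelse(minus, tss, tss + outer)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pmax(s, 1L), e))
}

#' Assign each peak to one of six genomic compartments
#'
#' Labels are tested in strict precedence order: `promoter_core` (TSS +/- the
#' core radius), `promoter_proximal` (within the proximal bound of the TSS,
#' outside the core), `promoter_distal` (proximal-to-distal band), `exonic`,
#' `intronic` (overlapping a gene body), else `intergenic`.  Promoter bands
#' are strand-aware around each gene's TSS and, by default, symmetric
#' (upstream and downstream).
#'
#' @param peaks `GRanges` of peaks from [call_peaks()].
#' @param genes A `GeneSet`.
#' @param core_bp,proximal_bp,distal_bp Compartment bounds in bp
#'   (defaults 100, 1000, 2000).
#' @param promoter_side `"symmetric"` (default) or `"downstream"`.
#' @return The peaks with the `compartment` column filled in; label counts
#'   over the six compartments sum to the peak count.
#' @export
assign_compartments <- function(peaks, genes,
                                core_bp = 100L, proximal_bp = 1000L,
                                distal_bp = 2000L,
                                promoter_side = c("symmetric", "downstream")) {
  promoter_side <- match.arg(promoter_side)
  if (length(peaks) == 0L) return(peaks)
  core <- promoter_bands(genes, core_bp, "symmetric")
  proximal <- promoter_bands(genes, proximal_bp, promoter_side)
  distal <- promoter_bands(genes, distal_bp, promoter_side)
  exons <- unlist(genes$exons, use.names = FALSE)
  body <- genes$body
  lab <- rep("intergenic", length(peaks))
  hit <- function(subject) IRanges::overlapsAny(peaks, subject, ignore.strand = TRUE)
  in_core <- hit(core)
  in_prox <- hit(proximal) & !in_core
  in_dist <- hit(distal) & !in_core & !in_prox
  in_exon <- hit(exons) & !in_core & !in_prox & !in_dist
  in_body <- hit(body) & !in_core & !in_prox & !in_dist & !in_exon
  lab[in_body] <- "intronic"
  lab[in_exon] <- "exonic"
  lab[in_dist] <- "promoter_distal"
  lab[in_prox] <- "promoter_proximal"
  lab[in_core] <- "promoter_core"
  peaks$compartment <- lab
  peaks
}

#' Tabulate peak compartments
#'
#' @param peaks Peaks labelled by [assign_compartments()].
#' @return Named integer vector over the six compartment labels.
#' @export
compartment_counts <- function(peaks) {
  levels <- c("promoter_core", "promoter_proximal", "promoter_distal",
              "exonic", "intronic", "intergenic")
  table(factor(peaks$compartment, levels = levels))
}
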