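## Sliding-window average profiles over genomic features, stratified gene
## sets, nearest-gene mapping for TF binding sites, and consensus
## differential-expression intersections.
##
## Profiles are realized as fixed binning with overlap-length-weighted window
## averaging (step = bin width): each bin's value is the per-base-pair mean of
## the window scores under it.  Minus-strand features are reversed so bin 1 is
## always the 5'/upstream end.

## Mean window score over each of n_bins equal bins of the 0-based real
## interval [a, b) on one chromosome.  Bins that fall entirely outside the
## chromosome are NA; partially covered bins average over the available part.
segment_bin_means <- function(track, chrom, a, b, n_bins) {
  L <- as.numeric(track$chrom_sizes[[chrom]])
  w <- track$window_size
  s <- track$scores[[chrom]]
  edges <- a + (b - a) * (0:n_bins) / n_bins
  out <- rep(NA_real_, n_bins)
  for (k in seq_len(n_bins)) {
    lo <- max(edges[k], 0); hi <- min(edges[k + 1L], L)
    if (hi <= lo) next
    j0 <- floor(lo / w)
    j1 <- min(ceiling(hi / w) - 1, length(s) - 1L)
    js <- j0:j1
    ws <- js * w
    we <- pmin(ws + w, L)
    ol <- pmax(pmin(hi, we) - pmax(lo, ws), 0)
    tot <- sum(ol)
    if (tot > 0) out[k] <- sum(s[js + 1L] * ol) / tot
  }
  out
}

## Strand-aware 0-based anchor coordinate of the TSS edge: the 5' edge of the
## first transcribed base.  Using the base *edge* (not its center) makes
## profiles exactly mirror-symmetric under genome reversal.
tss_anchor0 <- function(genes) {
  tss <- gene_tss(genes)
  minus <- as.character(GenomicRanges::strand(genes$body)) == "-"
  ifelse(minus, tss, tss - 1L)
}

new_meta_profile <- function(feature_class, mat, bins) {
  colnames(mat) <- bins
  structure(list(feature_class = feature_class,
                 n_features = nrow(mat),
                 bins = bins,
                 mean_signal = colMeans(mat, na.rm = TRUE),
                 per_feature_matrix = mat),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf("MetaProfile (%s): %d features x %d bins; signal range [%.4g, %.4g]\n",
              x$feature_class, x$n_features, length(x$bins),
              min(x$mean_signal, na.rm = TRUE), max(x$mean_signal, na.rm = TRUE)))
  invisible(x)
}

#' Average signal profile across promoters
#'
#' The interval TSS +/- `flank` of every gene is cut into `n_bins` equal
#' bins; each bin's value is the overlap-length-weighted mean of the window
#' scores beneath it, minus-strand genes are reversed so bin 1 is upstream,
#' and the profile is averaged over genes.  Genes whose flank extends beyond
#' the chromosome contribute their available part; a gene is dropped only if
#' nothing overlaps.
#'
#' @param track A `WindowTrack`.
#' @param genes A `GeneSet`.
#' @param flank Flank in bp on each side of the TSS (default 2000).
#' @param n_bins Number of bins (even; default 40).
#' @return A `MetaProfile`.
#' @export
promoter_profile <- function(track, genes, flank = 2000, n_bins = 40L) {
  stopifnot(inherits(track, "WindowTrack"), inherits(genes, "GeneSet"))
  if (n_bins %% 2L != 0L) stop("promoter_profile: n_bins must be even")
  anchor <- tss_anchor0(genes)
  chrom <- as.character(GenomicRanges::seqnames(genes$body))
  minus <- as.character(GenomicRanges::strand(genes$body)) == "-"
  mat <- matrix(NA_real_, length(genes), n_bins,
                dimnames = list(names(genes$body), NULL))
  for (i in seq_along(anchor)) {
    v <- segment_bin_means(track, chrom[i], anchor[i] - flank,
                           anchor[i] + flank, n_bins)
    if (minus[i]) v <- rev(v)
    mat[i, ] <- v
  }
  keep <- rowSums(!is.na(mat)) > 0L
  new_meta_profile("promoter", mat[keep, , drop = FALSE],
                   sprintf("bin%02d", seq_len(n_bins)))
}

#' Length-normalized gene-body profile with proportional flanks
#'
#' The gene body is scaled to `body_bins` bins and each flank of length
#' `flank_fraction` times the gene length to `flank_bins` bins; minus-strand
#' genes are reversed; the profile is averaged over genes.
#'
#' @param track A `WindowTrack`.
#' @param genes A `GeneSet`.
#' @param flank_fraction Flank length as a fraction of gene length
#'   (default 0.25).
#' @param body_bins,flank_bins Bin counts (defaults 100 and 25).
#' @return A `MetaProfile` with bins `up01..`, `body001..`, `down01..`.
#' @export
genebody_profile <- function(track, genes, flank_fraction = 0.25,
                             body_bins = 100L, flank_bins = 25L) {
  stopifnot(inherits(track, "WindowTrack"), inherits(genes, "GeneSet"))
  body <- genes$body
  if (any(GenomicRanges::width(body) < 1L)) stop("genebody_profile: zero-length gene")
  chrom <- as.character(GenomicRanges::seqnames(body))
  minus <- as.character(GenomicRanges::strand(body)) == "-"
  s0 <- GenomicRanges::start(body) - 1
  e0 <- as.numeric(GenomicRanges::end(body))
  fl <- flank_fraction * (e0 - s0)
  nb <- flank_bins + body_bins + flank_bins
  mat <- matrix(NA_real_, length(genes), nb,
                dimnames = list(names(body), NULL))
  for (i in seq_along(s0)) {
    v <- c(segment_bin_means(track, chrom[i], s0[i] - fl[i], s0[i], flank_bins),
           segment_bin_means(track, chrom[i], s0[i], e0[i], body_bins),
           segment_bin_means(track, chrom[i], e0[i], e0[i] + fl[i], flank_bins))
    if (minus[i]) v <- rev(v)
    mat[i, ] <- v
  }
  keep <- rowSums(!is.na(mat)) > 0L
  bins <- c(sprintf("up%02d", seq_len(flank_bins)),
            sprintf("body%03d", seq_len(body_bins)),
            sprintf("down%02d", seq_len(flank_bins)))
  new_meta_profile("genebody", mat[keep, , drop = FALSE], bins)
}

#' Length-normalized profile over arbitrary elements
#'
#' Each element is scaled to `bins` bins and each flank of length
#' `flank_fraction` times the element length to `bins` bins (elements are
#' treated strandless).
#'
#' @param track A `WindowTrack`.
#' @param elements `GRanges` of elements (e.g. TF binding sites).
#' @param flank_fraction Flank length as a fraction of element length
#'   (default 1.0).
#' @param bins Bins per segment (default 25).
#' @return A `MetaProfile`.
#' @export
element_profile <- function(track, elements, flank_fraction = 1.0, bins = 25L) {
  stopifnot(inherits(track, "WindowTrack"))
  if (length(elements) == 0L) stop("element_profile: empty element list")
  chrom <- as.character(GenomicRanges::seqnames(elements))
  s0 <- GenomicRanges::start(elements) - 1
  e0 <- as.numeric(GenomicRanges::end(elements))
  fl <- flank_fraction * (e0 - s0)
  mat <- matrix(NA_real_, length(elements), 3L * bins)
  for (i in seq_along(s0)) {
    mat[i, ] <- c(
      segment_bin_means(track, chrom[i], s0[i] - fl[i], s0[i], bins),
      segment_bin_means(track, chrom[i], s0[i], e0[i], bins),
      segment_bin_means(track, chrom[i], e0[i], e0[i] + fl[i], bins))
  }
  keep <- rowSums(!is.na(mat)) > 0L
  binlab <- c(sprintf("up%02d", seq_len(bins)),
              sprintf("elem%02d", seq_len(bins)),
              sprintf("down%02d", seq_len(bins)))
  new_meta_profile("element", mat[keep, , drop = FALSE], binlab)
}

#' Per-gene mean signal over TSS +/- flank
#'
#' Overlap-length-weighted (equivalently per-base-pair) mean of window scores
#' over the promoter interval; linear in the track.
#'
#' @param track A `WindowTrack`.
#' @param genes A `GeneSet`.
#' @param flank Flank in bp (default 1000).
#' @return Named numeric vector, one value per gene (NA if the promoter lies
#'   entirely outside the chromosome).
#' @export
promoter_mean <- function(track, genes, flank = 1000) {
  stopifnot(inherits(track, "WindowTrack"), inherits(genes, "GeneSet"))
  anchor <- tss_anchor0(genes)
  chrom <- as.character(GenomicRanges::seqnames(genes$body))
  out <- vapply(seq_along(anchor), function(i)
    segment_bin_means(track, chrom[i], anchor[i] - flank,
                      anchor[i] + flank, 1L),
    0.0)
  stats::setNames(out, names(genes$body))
}

#' Stratify genes into expression quartiles
#'
#' Genes are ranked by expression in descending order (ties broken by gene id,
#' lexicographically); Q1 is the top (highest-expression) quartile and Q4 the
#' bottom.  Quartile sizes differ by at most one, with the earlier quartiles
#' taking the remainder.
#'
#' @param genes A `GeneSet` (or character vector of gene ids).
#' @param expression Named numeric vector of expression values covering all
#'   genes.
#' @return Named list `Q1..Q4` of gene-id character vectors.
#' @export
quartile_stratify <- function(genes, expression) {
  ids <- if (inherits(genes, "GeneSet")) names(genes$body) else as.character(genes)
  if (any(!ids %in% names(expression)))
    stop("quartile_stratify: expression missing for some genes")
  ex <- expression[ids]
  ord <- ids[order(-ex, ids)]
  n <- length(ord)
  base <- n %/% 4L
  sizes <- base + as.integer(seq_len(4L) <= n %% 4L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  stats::setNames(lapply(1:4, function(q)
    if (sizes[q] == 0L) character(0) else ord[starts[q]:ends[q]]),
    paste0("Q", 1:4))
}

#' Stratify genes by promoter peak state
#'
#' A gene is "enriched" when at least one peak overlaps its promoter
#' (TSS +/- `flank`), otherwise "depleted"; the two sets partition the genes.
#'
#' @param genes A `GeneSet`.
#' @param peaks `GRanges` of called peaks.
#' @param flank Promoter flank in bp (default 1000).
#' @return Named list with elements `enriched` and `depleted`.
#' @export
promoter_state_stratify <- function(genes, peaks, flank = 1000L) {
  stopifnot(inherits(genes, "GeneSet"))
  prom <- promoter_bands(genes, as.integer(flank), "symmetric")
  hit <- IRanges::overlapsAny(prom, peaks, ignore.strand = TRUE)
  ids <- names(genes$body)
  list(enriched = ids[hit], depleted = ids[!hit])
}

#' Nearest gene within a distance cutoff
#'
#' For each site, the gene whose body minimizes the gap distance to the site
#' (0 when overlapping), reported only when that distance is at most
#' `max_dist`; ties resolve to the lexicographically smaller gene id.
#'
#' @param sites `GRanges` of sites (e.g. TF binding sites).
#' @param genes A `GeneSet`.
#' @param max_dist Maximum gap in bp (default 10000).
#' @return Character vector of gene ids, NA where no gene is within range.
#' @export
nearest_gene_within <- function(sites, genes, max_dist = 10000) {
  stopifnot(inherits(genes, "GeneSet"))
  body <- genes$body
  out <- rep(NA_character_, length(sites))
  if (length(sites) == 0L || length(body) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(sites, body, maxgap = max_dist,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits)
  sj <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(sites[q], body[sj], ignore.strand = TRUE)
  gid <- names(body)[sj]
  keep <- !is.na(d) & d <= max_dist
  q <- q[keep]; d <- d[keep]; gid <- gid[keep]
  ord <- order(q, d, gid)
  first <- !duplicated(q[ord])
  out[q[ord][first]] <- gid[ord][first]
  out
}

#' Consensus differential-expression sets across conditions
#'
#' Per table, a gene is "up" when `log2FC >= log2(fc_threshold)` and
#' `adj_p <= alpha`, and "down" analogously with negated fold change; the
#' consensus sets are the intersections across all tables.  A gene called up
#' in one table and down in another lands in neither consensus set.
#'
#' @param tables List (>= 2) of data frames with columns `gene`, `log2FC`,
#'   `adj_p` sharing a gene universe.
#' @param fc_threshold Fold-change threshold on the linear scale (default 2).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
consensus_de_sets <- function(tables, fc_threshold = 2, alpha = 0.05) {
  if (length(tables) < 2L) stop("consensus_de_sets: need >= 2 tables")
  lfc <- log2(fc_threshold)
  sets <- lapply(tables, function(tb) {
    stopifnot(all(c("gene", "log2FC", "adj_p") %in% names(tb)))
    if (anyDuplicated(tb$gene)) stop("consensus_de_sets: duplicate gene in a table")
    list(up = tb$gene[tb$log2FC >= lfc & tb$adj_p <= alpha],
         down = tb$gene[tb$log2FC <= -lfc & tb$adj_p <= alpha])
  })
  list(up = sort(Reduce(intersect, lapply(sets, `[[`, "up"))),
       down = sort(Reduce(intersect, lapply(sets, `[[`, "down"))))
}
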