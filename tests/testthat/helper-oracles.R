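## Fixture builders and independent brute-force oracles used across tests.

## A track with given per-chromosome score vectors.
make_track <- function(scores, window_size = 200L, sizes = NULL,
                       library_total = NA_real_) {
  if (is.null(sizes))
    sizes <- setNames(as.integer(lengths(scores) * window_size), names(scores))
  window_track(window_grid(sizes, window_size), scores, library_total)
}

flat_track <- function(value, n_windows = 50L, window_size = 200L,
                       chrom = "chr1") {
  make_track(setNames(list(rep(value, n_windows)), chrom), window_size)
}

## Brute-force peak oracle: exhaustive enumeration of all k-window runs with
## >= m qualifying windows, then interval union (0-based window coordinates).
oracle_peaks <- function(qualifying, w, chrom_len, k = 3L, m = 2L) {
  n <- length(qualifying)
  marked <- logical(n)
  if (n >= k) {
    for (i in 1:(n - k + 1L)) {
      if (sum(qualifying[i:(i + k - 1L)]) >= m)
        marked[i:(i + k - 1L)] <- TRUE
    }
  }
  if (!any(marked)) return(matrix(numeric(0), 0, 2))
  idx <- which(marked)
  breaks <- c(0L, which(diff(idx) > 1L), length(idx))
  out <- matrix(0, length(breaks) - 1L, 2)
  for (j in seq_len(length(breaks) - 1L)) {
    run <- idx[(breaks[j] + 1L):breaks[j + 1L]]
    out[j, ] <- c((min(run) - 1L) * w, min(max(run) * w, chrom_len))
  }
  out
}

peaks_to_matrix <- function(peaks) {
  if (length(peaks) == 0L) return(matrix(numeric(0), 0, 2))
  cbind(GenomicRanges::start(peaks) - 1L, GenomicRanges::end(peaks))
}

## Nearest-rank percentile by sort-and-index.
oracle_nearest_rank <- function(x, p) {
  s <- sort(x)
  s[ceiling(p * length(s) / 100)]
}

## Full-enumeration two-tailed Mann-Whitney p for tie-free samples: every
## C(m+n, m) assignment of the pooled values to group "a" is equally likely
## under the null.
oracle_mwu_p <- function(a, b) {
  pool <- c(a, b)
  m <- length(a); n <- length(b)
  u_of <- function(av, bv) sum(rank(c(av, bv))[seq_along(av)]) - m * (m + 1) / 2
  u_obs <- u_of(a, b)
  combos <- combn(m + n, m)
  us <- apply(combos, 2, function(ix) u_of(pool[ix], pool[-ix]))
  center <- m * n / 2
  mean(abs(us - center) >= abs(u_obs - center) - 1e-12)
}

## Per-base-pair expansion oracle for interval mean signal on one chromosome:
## mean of per-bp scores over the 0-based interval [a, b), clipped to the
## chromosome.
oracle_bp_mean <- function(scores, w, chrom_len, a, b) {
  bp <- rep(scores, each = w)[seq_len(chrom_len)]
  lo <- max(a, 0) + 1L
  hi <- min(b, chrom_len)
  if (hi < lo) return(NA_real_)
  mean(bp[lo:hi])
}

## Brute-force compartment oracle over 0-based half-open peak coordinates.
## genes: data.frame(chrom, start0, end0, strand, exon list-column).
oracle_compartment <- function(peak_chrom, ps0, pe0, genes,
                               core = 100, prox = 1000, dist = 2000) {
  overlaps <- function(a0, a1, b0, b1) max(a0, b0) < min(a1, b1)
  hit_band <- function(lo0, hi0) overlaps(ps0, pe0, lo0, hi0)
  any_core <- any_prox <- any_dist <- any_exon <- any_body <- FALSE
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != peak_chrom) next
    tss0 <- if (g$strand == "+") g$start0 else g$end0 - 1
    if (hit_band(tss0 - core, tss0 + core + 1)) any_core <- TRUE
    if (hit_band(tss0 - prox, tss0 + prox + 1)) any_prox <- TRUE
    if (hit_band(tss0 - dist, tss0 + dist + 1)) any_dist <- TRUE
    for (ex in g$exons[[1]])
      if (overlaps(ps0, pe0, ex[1], ex[2])) any_exon <- TRUE
    if (hit_band(g$start0, g$end0)) any_body <- TRUE
  }
  if (any_core) "promoter_core"
  else if (any_prox) "promoter_proximal"
  else if (any_dist) "promoter_distal"
  else if (any_exon) "exonic"
  else if (any_body) "intronic"
  else "intergenic"
}

## All-pairs nearest-gene oracle (gap distance on 0-based half-open).
oracle_nearest_gene <- function(site_chrom, s0, e0, genes, max_dist) {
  best_d <- Inf; best_id <- NA_character_
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != site_chrom) next
    d <- max(0, g$start0 - e0, s0 - g$end0)
    if (d < best_d || (d == best_d && !is.na(best_id) && g$gene_id < best_id)) {
      best_d <- d; best_id <- g$gene_id
    }
  }
  if (best_d <= max_dist) best_id else NA_character_
}

## Two genes on one 20 kb chromosome, plus/minus strand, for small fixtures.
toy_genes <- function() {
  body <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(2001, 12001), c(6000, 16000)),
    strand = c("+", "-"), gene_id = c("gA", "gB"))
  exons <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2001, 5001), c(3000, 6000)),
                           strand = "+"),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(12001, 15001), c(13000, 16000)),
                           strand = "-"))
  gene_set(body, exons)
}
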