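## Fixed-width window quantification: bin fragments into a 200 bp genome
## grid, normalize by library depth, subtract the matched input, and flag
## enriched windows.

#' Build a fixed-width window grid over a genome
#'
#' Window `i` (0-based) of a chromosome of length `L` spans
#' `[i*w, min((i+1)*w, L))`; the last window may be shorter and is kept at
#' native width without rescaling.
#'
#' @param sizes Named integer vector of chromosome lengths.
#' @param window_size Window width in bp (default 200, the standard grid for
#'   this analysis).
#' @return A `WindowGrid`.
#' @export
window_grid <- function(sizes, window_size = 200L) {
  sizes <- validate_chrom_sizes(sizes)
  window_size <- as.integer(window_size)
  if (window_size < 1L) stop("window_grid: window_size must be >= 1")
  structure(list(chrom_sizes = sizes,
                 window_size = window_size,
                 n_windows = stats::setNames(
                   as.integer(ceiling(sizes / window_size)), names(sizes))),
            class = "WindowGrid")
}

#' Construct a window track from per-chromosome score vectors
#'
#' @param grid A `WindowGrid`.
#' @param scores Named list of numeric vectors, one per grid chromosome, with
#'   one score per window.
#' @param library_total Fragment count backing the track (used by
#'   [normalize_total()]); NA for derived tracks.
#' @return A `WindowTrack`.
#' @export
window_track <- function(grid, scores, library_total = NA_real_) {
  stopifnot(inherits(grid, "WindowGrid"))
  scores <- scores[names(grid$n_windows)]
  if (!identical(unname(lengths(scores)), unname(as.integer(grid$n_windows))))
    stop("window_track: score count must equal grid window count per chromosome")
  new_window_track(grid, scores, library_total)
}

new_window_track <- function(grid, scores, library_total) {
  stopifnot(identical(names(scores), names(grid$n_windows)))
  structure(list(scores = scores,
                 window_size = grid$window_size,
                 chrom_sizes = grid$chrom_sizes,
                 library_total = library_total),
            class = "WindowTrack")
}

#' @export
print.WindowTrack <- function(x, ...) {
  cat(sprintf("WindowTrack: %d windows of %d bp over %d chromosome(s); library_total = %s\n",
              sum(lengths(x$scores)), x$window_size, length(x$scores),
              format(x$library_total)))
  invisible(x)
}

track_grid <- function(track) {
  window_grid(track$chrom_sizes, track$window_size)
}

same_grid <- function(a, b) {
  identical(a$window_size, b$window_size) &&
    identical(a$chrom_sizes, b$chrom_sizes)
}

#' Count fragments into grid windows
#'
#' Each fragment contributes exactly 1 to the window containing its midpoint
#' `floor((start0 + end0) / 2)` (0-based coordinates), so the total count is
#' conserved: the sum of window scores equals the number of fragments.
#'
#' @param grid A `WindowGrid`.
#' @param frags `GRanges` of fragments (from [read_intervals()] or
#'   [simulate_fragments()]).
#' @return A `WindowTrack` of raw counts with `library_total = length(frags)`.
#' @export
count_fragments <- function(grid, frags) {
  stopifnot(inherits(grid, "WindowGrid"))
  chrom <- as.character(GenomicRanges::seqnames(frags))
  if (any(!chrom %in% names(grid$chrom_sizes)))
    stop("count_fragments: fragment on chromosome absent from grid")
  if (length(frags) &&
      any(GenomicRanges::end(frags) >
          grid$chrom_sizes[chrom]))
    stop("count_fragments: fragment beyond chromosome bounds")
  ## 0-based midpoint: floor((start0 + end0)/2) with start0 = start-1, end0 = end
  mid0 <- (GenomicRanges::start(frags) - 1L + GenomicRanges::end(frags)) %/% 2L
  widx <- mid0 %/% grid$window_size + 1L
  scores <- lapply(grid$n_windows, function(n) numeric(n))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    tb <- tabulate(widx[sel], nbins = grid$n_windows[[ch]])
    scores[[ch]] <- as.numeric(tb)
  }
  new_window_track(grid, scores, length(frags))
}

#' Normalize a track by total library size
#'
#' `score' = score * scale / library_total`, so the track sums to `scale`
#' (reads-per-million for the default scale).
#'
#' @param track A `WindowTrack` of raw counts.
#' @param scale Target total (default `1e6`).
#' @return Depth-normalized `WindowTrack` (keeps the original
#'   `library_total`, so renormalizing is idempotent).
#' @export
normalize_total <- function(track, scale = 1e6) {
  stopifnot(inherits(track, "WindowTrack"))
  if (is.na(track$library_total) || track$library_total <= 0)
    stop("normalize_total: library_total must be > 0")
  current <- sum(vapply(track$scores, sum, 0))
  if (current <= 0) stop("normalize_total: track has no signal")
  factor <- scale / current
  track$scores <- lapply(track$scores, function(s) s * factor)
  track
}

#' Subtract a matched input track from a signal track
#'
#' Both tracks must be on the same grid and depth-normalized.  The result is
#' floored at zero: only positive excess over the input background is kept.
#'
#' @param signal,input Depth-normalized `WindowTrack`s on the same grid.
#' @return Input-subtracted `WindowTrack`.
#' @export
subtract_input <- function(signal, input) {
  stopifnot(inherits(signal, "WindowTrack"), inherits(input, "WindowTrack"))
  if (!same_grid(signal, input)) stop("subtract_input: grid mismatch")
  signal$scores <- Map(function(s, b) pmax(s - b, 0), signal$scores, input$scores)
  signal
}

#' Enriched windows of an input-subtracted track
#'
#' A window is enriched when its input-subtracted score is strictly positive,
#' i.e. the signal exceeds the matched input background.
#'
#' @param track Input-subtracted `WindowTrack`.
#' @return `GRanges` of enriched windows with a `score` metadata column.
#' @export
enriched_windows <- function(track) {
  stopifnot(inherits(track, "WindowTrack"))
  w <- track$window_size
  out <- lapply(names(track$scores), function(ch) {
    s <- track$scores[[ch]]
    idx <- which(s > 0)
    if (length(idx) == 0L) return(NULL)
    start0 <- (idx - 1L) * w
    GenomicRanges::GRanges(ch,
                           IRanges::IRanges(start0 + 1L,
                                            pmin(start0 + w, track$chrom_sizes[[ch]])),
                           score = s[idx])
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$score <- numeric(0)
    return(gr)
  }
  do.call(c, out)
}

#' Per-window score vector in genome order (internal helper)
#' @noRd
track_score_vector <- function(track) {
  unlist(track$scores, use.names = FALSE)
}
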