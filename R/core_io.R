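## Interval / annotation data model and readers-writers.
##
## All files use the BED convention (0-based half-open); in memory everything
## is held in GenomicRanges objects (1-based closed), converted at the I/O
## boundary.  Fragments are counted strandless: MeDIP/ChIP fragments are
## double-stranded and strand carries no signal for window counting.

#' Read a two-column chromosome sizes file
#'
#' @param path Path to a tab- or space-separated file with columns
#'   `chrom` and `length` (bp).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  validate_chrom_sizes(stats::setNames(df$length, df$chrom))
}

validate_chrom_sizes <- function(sizes) {
  if (length(sizes) == 0L) stop("chrom sizes: no chromosomes")
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chrom sizes: chromosome names must be non-empty")
  if (anyDuplicated(names(sizes)))
    stop("chrom sizes: duplicated chromosome name")
  if (any(sizes <= 0)) stop("chrom sizes: all lengths must be > 0")
  storage.mode(sizes) <- "integer"
  sizes
}

#' Read aligned fragments from a BED3/BED6 file
#'
#' Records on chromosomes absent from `sizes` are dropped (a message reports
#' how many); malformed lines and records with `end <= start` are errors that
#' name the offending line.
#'
#' @param path BED3 or BED6 file of aligned fragment intervals.
#' @param sizes Named integer vector of chromosome lengths
#'   (see [read_chrom_sizes()]).
#' @return A `GRanges` of fragments (strandless) with `seqlengths` set; the
#'   fragment count is `length()` of the result.
#' @export
read_intervals <- function(path, sizes) {
  sizes <- validate_chrom_sizes(sizes)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_fragments(sizes))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop(sprintf("%s: line %d: expected >= 3 tab-separated columns", path, bad[1]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("%s: line %d: non-integer coordinates", path, bad[1]))
  bad <- which(end0 <= start0 | start0 < 0L)
  if (length(bad))
    stop(sprintf("%s: line %d: require 0 <= start < end", path, bad[1]))
  keep <- chrom %in% names(sizes)
  if (any(!keep))
    message(sprintf("read_intervals: dropped %d record(s) on chromosomes absent from sizes",
                    sum(!keep)))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom[keep], levels = names(sizes)),
    ranges = IRanges::IRanges(start = start0[keep] + 1L, end = end0[keep]),
    seqlengths = sizes)
  oob <- GenomicRanges::end(gr) > sizes[as.character(GenomicRanges::seqnames(gr))]
  if (any(oob)) stop("read_intervals: fragment extends beyond chromosome length")
  gr
}

empty_fragments <- function(sizes) {
  GenomicRanges::GRanges(seqlengths = validate_chrom_sizes(sizes))
}

## --- gene models -----------------------------------------------------------

#' Construct a gene set from parallel body/exon ranges
#'
#' @param body `GRanges` of gene bodies with strand and a `gene_id`
#'   metadata column (or names).
#' @param exons `GRangesList` of exon ranges, one element per gene, same order.
#' @return An object of class `GeneSet`: list with elements `body` (named
#'   `GRanges`) and `exons` (named `GRangesList`).
#' @export
gene_set <- function(body, exons) {
  ids <- if (!is.null(body$gene_id)) body$gene_id else names(body)
  if (is.null(ids)) stop("gene_set: gene ids required")
  if (anyDuplicated(ids)) stop("gene_set: duplicated gene id")
  names(body) <- ids
  names(exons) <- ids
  for (i in seq_along(body)) {
    ex <- exons[[i]]
    if (length(ex) == 0L)
      stop(sprintf("gene_set: gene %s has no exons", ids[i]))
    ex <- sort(ex)
    if (any(GenomicRanges::start(ex) < GenomicRanges::start(body[i])) ||
        any(GenomicRanges::end(ex) > GenomicRanges::end(body[i])))
      stop(sprintf("gene_set: exon outside gene body for gene %s", ids[i]))
    if (length(ex) > 1L &&
        any(GenomicRanges::start(ex)[-1L] <= GenomicRanges::end(ex)[-length(ex)]))
      stop(sprintf("gene_set: overlapping exons for gene %s", ids[i]))
    exons[[i]] <- ex
  }
  structure(list(body = body, exons = exons), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet with %d genes on %d chromosome(s)\n",
              length(x$body),
              length(unique(as.character(GenomicRanges::seqnames(x$body))))))
  invisible(x)
}

#' Number of genes in a GeneSet
#' @param x A `GeneSet`.
#' @export
length.GeneSet <- function(x) length(x$body)

#' Strand-aware transcription start sites
#'
#' The TSS is the 5' end of the gene body: `start` on the plus strand, `end`
#' on the minus strand (1-based position).
#'
#' @param genes A `GeneSet`.
#' @return Named integer vector of TSS positions (1-based).
#' @export
gene_tss <- function(genes) {
  body <- genes$body
  minus <- as.character(GenomicRanges::strand(body)) == "-"
  tss <- ifelse(minus, GenomicRanges::end(body), GenomicRanges::start(body))
  stats::setNames(as.integer(tss), names(body))
}

#' Read gene models from BED12 or GTF
#'
#' Format is chosen from the file extension (`.gtf`/`.gff` vs anything else
#' treated as BED12) unless given explicitly.  GTF 1-based closed coordinates
#' and BED12 0-based half-open blocks yield identical `GeneSet` objects for
#' equivalent annotations.
#'
#' @param path Annotation file.
#' @param format `"auto"`, `"bed12"` or `"gtf"`.
#' @return A `GeneSet`.
#' @export
read_genes <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  if (format == "gtf") read_genes_gtf(path) else read_genes_bed12(path)
}

read_genes_bed12 <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 12L) stop("read_genes: BED12 requires 12 columns")
  strand <- df[[6]]
  if (any(!strand %in% c("+", "-")))
    stop("read_genes: missing or invalid strand")
  start0 <- as.integer(df[[2]]); end0 <- as.integer(df[[3]])
  body <- GenomicRanges::GRanges(df[[1]],
                                 IRanges::IRanges(start0 + 1L, end0),
                                 strand = strand, gene_id = df[[4]])
  exl <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    n <- as.integer(df[i, 10])
    bs <- as.integer(strsplit(df[i, 11], ",")[[1]])[seq_len(n)]
    bo <- as.integer(strsplit(df[i, 12], ",")[[1]])[seq_len(n)]
    exl[[i]] <- GenomicRanges::GRanges(
      df[i, 1], IRanges::IRanges(start0[i] + bo + 1L, start0[i] + bo + bs),
      strand = strand[i])
  }
  gene_set(body, GenomicRanges::GRangesList(exl))
}

read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.null(gr$gene_id)) stop("read_genes: GTF lacks gene_id attribute")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop("read_genes: GTF contains no exon features")
  if (any(as.character(GenomicRanges::strand(ex)) == "*"))
    stop("read_genes: missing strand in GTF")
  exl <- GenomicRanges::split(GenomicRanges::granges(ex), ex$gene_id)
  body <- unlist(range(exl))
  body$gene_id <- names(body)
  gene_set(body, exl)
}

## --- track / peak serialization -------------------------------------------

#' Write a window track as bedGraph
#'
#' Scores are written with six decimal places so that write-then-read round
#' trips reproduce values exactly at that precision.  Zero-score windows are
#' written too, keeping the grid complete.
#'
#' @param track A `WindowTrack` (see [count_fragments()]).
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "WindowTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$scores)) {
    s <- track$scores[[chrom]]
    n <- length(s)
    if (n == 0L) next
    start0 <- (seq_len(n) - 1L) * track$window_size
    end0 <- pmin(start0 + track$window_size, track$chrom_sizes[[chrom]])
    writeLines(sprintf("%s\t%d\t%d\t%.6f", chrom, start0, end0, s), con)
  }
  invisible(path)
}

#' Read a bedGraph written by [write_track()] back into a WindowTrack
#'
#' @param path bedGraph path.
#' @param sizes Named chromosome lengths.
#' @param window_size Grid width in bp (default 200).
#' @param library_total Fragment count to record on the track (optional).
#' @return A `WindowTrack`.
#' @export
read_track <- function(path, sizes, window_size = 200L, library_total = NA_real_) {
  sizes <- validate_chrom_sizes(sizes)
  grid <- window_grid(sizes, window_size)
  scores <- lapply(grid$n_windows, function(n) numeric(n))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- as.integer(vapply(fields, `[[`, "", 2L))
    val <- as.numeric(vapply(fields, `[[`, "", 4L))
    if (any(!chrom %in% names(sizes)))
      stop("read_track: chromosome absent from sizes")
    idx <- start0 %/% as.integer(window_size) + 1L
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      scores[[ch]][idx[sel]] <- val[sel]
    }
  }
  new_window_track(grid, scores, library_total)
}

#' Write peaks as BED6 (name field = compartment label)
#'
#' @param peaks `GRanges` of peaks with metadata columns `compartment` and
#'   `n_qualifying`.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  if (length(peaks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   as.character(GenomicRanges::seqnames(peaks)),
                   GenomicRanges::start(peaks) - 1L,
                   GenomicRanges::end(peaks),
                   as.character(peaks$compartment),
                   as.integer(peaks$n_qualifying))
  writeLines(lines, path)
  invisible(path)
}

#' Read peaks written by [write_peaks()]
#'
#' @param path BED6 peak file.
#' @return `GRanges` with `compartment` and `n_qualifying` metadata columns.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$compartment <- character(0)
    gr$n_qualifying <- integer(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  gr <- GenomicRanges::GRanges(
    vapply(fields, `[[`, "", 1L),
    IRanges::IRanges(as.integer(vapply(fields, `[[`, "", 2L)) + 1L,
                     as.integer(vapply(fields, `[[`, "", 3L))))
  gr$compartment <- vapply(fields, `[[`, "", 4L)
  gr$n_qualifying <- as.integer(vapply(fields, `[[`, "", 5L))
  gr
}
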