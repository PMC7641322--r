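## Synthetic-data generators: every pipeline input with planted ground truth,
## deterministic per seed.  The defaults encode the study conditions the
## pipeline is meant for: sonicated fragments of 150-700 bp with a mean of
## 300 bp, a reference-vs-treated IP/input design with planted enriched
## regions, bisulfite clone matrices of >= 24 clones per condition, and a
## DigiWest 2x3 factorial (treatment x cell type) with two replicates per
## cell.

#' Simulation configuration
#'
#' @param seed Integer seed driving all generators.
#' @param chrom_lengths Named chromosome lengths (default one 1 Mb
#'   chromosome).
#' @param n_genes Number of genes to place (default 50).
#' @param n_planted,planted_width,planted_fold Planted enriched regions:
#'   count, width in bp and IP enrichment fold (defaults 10 regions of
#'   2 kb at fold 10).
#' @param planted_regions Optional `GRanges` with a `fold` column; overrides
#'   the automatic placement.
#' @param frag_len_min,frag_len_max,frag_len_mean Fragment-length bounds and
#'   mean in bp (defaults 150, 700, 300).
#' @param depth_ip,depth_input Fragment counts for IP and input libraries.
#' @param n_repeats,n_osn Repeat and TF-binding-site interval counts.
#' @param clone_p_meth Named per-condition methylation probabilities.
#' @param n_clones,n_cpgs Clone-matrix dimensions (defaults 24 clones, 20
#'   CpGs).
#' @param missing_rate Probability of a missing clone call (default 0.05).
#' @param expr_n_de_up,expr_n_de_down,expr_effect Planted shared
#'   differential-expression gene counts and log2 effect size.
#' @param dw_n_analytes Number of DigiWest analytes (default 72).
#' @param dw_treatment_effect,dw_cell_effect Per-analyte additive effects on
#'   band amplitude, in units of `dw_noise_sd` (recycled; defaults 0).
#' @param dw_noise_sd Between-replicate amplitude noise SD (default 1).
#' @param dw_n_per_cell Replicates per design cell (default 2).
#' @return A validated `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1000000L),
                       n_genes = 50L,
                       n_planted = 10L, planted_width = 2000L, planted_fold = 10,
                       planted_regions = NULL,
                       frag_len_min = 150L, frag_len_max = 700L,
                       frag_len_mean = 300,
                       depth_ip = 100000L, depth_input = 100000L,
                       n_repeats = 60L, n_osn = 30L,
                       clone_p_meth = c(serum = 0.8, `2i` = 0.2),
                       n_clones = 24L, n_cpgs = 20L, missing_rate = 0.05,
                       expr_n_de_up = 8L, expr_n_de_down = 12L,
                       expr_effect = 2.5,
                       dw_n_analytes = 72L,
                       dw_treatment_effect = 0, dw_cell_effect = 0,
                       dw_noise_sd = 1, dw_n_per_cell = 2L) {
  chrom_lengths <- validate_chrom_sizes(chrom_lengths)
  if (frag_len_min <= 0 || frag_len_min >= frag_len_max)
    stop("sim_config: need 0 < frag_len_min < frag_len_max")
  if (frag_len_mean <= frag_len_min || frag_len_mean >= frag_len_max)
    stop("sim_config: frag_len_mean must lie strictly inside the length bounds")
  if (any(clone_p_meth < 0 | clone_p_meth > 1) || missing_rate < 0 || missing_rate > 1)
    stop("sim_config: probabilities must be in [0, 1]")
  if (n_genes < 1L) stop("sim_config: n_genes must be >= 1")
  cfg <- structure(as.list(environment()), class = "SimConfig")
  if (!is.null(planted_regions)) {
    if (is.null(planted_regions$fold)) stop("sim_config: planted_regions need a fold column")
    check_within_genome(planted_regions, chrom_lengths,
                        "sim_config: planted region outside genome")
  }
  cfg
}

check_within_genome <- function(gr, sizes, msg) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (any(!chrom %in% names(sizes)) ||
      any(GenomicRanges::start(gr) < 1L) ||
      any(GenomicRanges::end(gr) > sizes[chrom]))
    stop(msg)
  invisible(gr)
}

## Uniform interval positions of given lengths over the genome,
## chromosome chosen proportionally to length.
random_intervals <- function(sizes, lens) {
  chrom <- names(sizes)[sample.int(length(sizes), length(lens),
                                   replace = TRUE, prob = as.numeric(sizes))]
  L <- as.numeric(sizes[chrom])
  lens <- pmin(lens, L)
  start0 <- floor(stats::runif(length(lens)) * (L - lens + 1))
  GenomicRanges::GRanges(factor(chrom, levels = names(sizes)),
                         IRanges::IRanges(start0 + 1L, start0 + lens),
                         seqlengths = sizes)
}

repeat_catalogue <- data.frame(
  subfamily = c("IAPEz-int", "RLTR10D::IAP-d-int", "RLTR13B2::ETnERV3-int",
                "MMERVK10D3_LTR", "L1Md_A", "L1Md_T", "B1_Mus1", "B2_Mm1a",
                "MTA_Mm", "MajorSatellite"),
  family = c("ERVK", "ERVK", "ERVK", "ERVK", "L1", "L1", "Alu", "B2",
             "ERVL-MaLR", "Satellite"),
  class = c("LTR", "LTR", "LTR", "LTR", "LINE", "LINE", "SINE", "SINE",
            "LTR", "other"),
  stringsAsFactors = FALSE)

#' Simulate a toy annotated genome
#'
#' Places non-overlapping stranded genes (each with 1-3 exons; the first and
#' last exon touch the gene ends), repeat intervals labelled from a small
#' retrotransposon catalogue, TF-binding-site ("OSN") intervals, and the
#' planted enriched regions.  Deterministic for a fixed seed.
#'
#' @param config A `SimConfig`.
#' @return List with `sizes`, `genes` (a `GeneSet`), `repeats` (`GRanges`
#'   with subfamily/family/class), `osn_sites` (`GRanges`) and `planted`
#'   (`GRanges` with a `fold` column).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  sizes <- config$chrom_lengths
  with_seed(config$seed + 101L, {
    ## genes per chromosome, proportional with largest remainder
    quota <- config$n_genes * as.numeric(sizes) / sum(as.numeric(sizes))
    n_per <- floor(quota)
    rem <- config$n_genes - sum(n_per)
    if (rem > 0) {
      extra <- order(quota - n_per, decreasing = TRUE)[seq_len(rem)]
      n_per[extra] <- n_per[extra] + 1L
    }
    bodies <- list(); exons <- list(); gid <- 0L
    for (ci in seq_along(sizes)) {
      ng <- n_per[ci]
      if (ng == 0L) next
      L <- as.numeric(sizes[ci])
      slot <- floor(L / ng)
      if (slot < 2400) stop("simulate_genome: chromosomes too short to host n_genes")
      for (k in seq_len(ng)) {
        gid <- gid + 1L
        slot_start0 <- (k - 1L) * slot
        glen <- sample(2000:min(8000, slot - 400), 1L)
        gstart0 <- slot_start0 + sample.int(slot - glen - 200L, 1L)
        strand <- sample(c("+", "-"), 1L)
        n_ex <- sample.int(3L, 1L)
        seg <- floor(glen / (2L * n_ex - 1L))
        ex_start0 <- gstart0 + (seq_len(n_ex) - 1L) * 2L * seg
        ex_end0 <- ex_start0 + seg
        ex_end0[n_ex] <- gstart0 + glen
        bodies[[gid]] <- GenomicRanges::GRanges(
          names(sizes)[ci], IRanges::IRanges(gstart0 + 1L, gstart0 + glen),
          strand = strand, gene_id = sprintf("gene%04d", gid))
        exons[[gid]] <- GenomicRanges::GRanges(
          names(sizes)[ci], IRanges::IRanges(ex_start0 + 1L, ex_end0),
          strand = strand)
      }
    }
    body <- do.call(c, bodies)
    GenomeInfoDb::seqlevels(body) <- names(sizes)
    GenomeInfoDb::seqlengths(body) <- sizes
    genes <- gene_set(body, GenomicRanges::GRangesList(exons))
    repeats <- if (config$n_repeats > 0L) {
      r <- random_intervals(sizes, sample(300:4000, config$n_repeats, replace = TRUE))
      pick <- sample.int(nrow(repeat_catalogue), config$n_repeats, replace = TRUE)
      r$subfamily <- repeat_catalogue$subfamily[pick]
      r$family <- repeat_catalogue$family[pick]
      r$class <- repeat_catalogue$class[pick]
      r
    } else {
      r <- GenomicRanges::GRanges(seqlengths = sizes)
      r$subfamily <- r$family <- r$class <- character(0)
      r
    }
    osn <- random_intervals(sizes, sample(150:400, config$n_osn, replace = TRUE))
    planted <- if (!is.null(config$planted_regions)) config$planted_regions
    else {
      p <- random_intervals(sizes, rep(config$planted_width, config$n_planted))
      p <- GenomicRanges::reduce(p)  # merged truth, disjoint by construction
      p$fold <- rep(config$planted_fold, length(p))
      p
    }
    list(sizes = sizes, genes = genes, repeats = repeats,
         osn_sites = osn, planted = planted)
  })
}

## Fragment lengths on [min, max] from a scaled Beta(2, beta) whose mean
## matches the configured mean (unimodal, right-skewed for the defaults,
## matching a sonication size distribution).
fragment_lengths <- function(config, n) {
  a <- config$frag_len_min; b <- config$frag_len_max
  mu <- (config$frag_len_mean - a) / (b - a)
  shape1 <- 2
  shape2 <- shape1 * (1 - mu) / mu
  round(a + (b - a) * stats::rbeta(n, shape1, shape2))
}

#' Simulate IP and matched-input fragment sets
#'
#' Input fragments are uniform over the genome.  IP fragments are drawn by
#' rejection sampling: a uniform candidate whose midpoint falls inside a
#' planted region is accepted with probability proportional to that region's
#' enrichment fold, so IP density inside a region is `fold` times the outside
#' density.  Fragment lengths follow the configured truncated distribution.
#'
#' @param config A `SimConfig`.
#' @param planted `GRanges` of planted regions with a `fold` column (the
#'   truth from [simulate_genome()]); may be empty for a null simulation.
#' @return List with `ip` and `input` fragment `GRanges`.
#' @export
simulate_fragments <- function(config, planted) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$depth_ip <= 0L || config$depth_input <= 0L)
    stop("simulate_fragments: depths must be > 0")
  sizes <- config$chrom_lengths
  check_within_genome(planted, sizes,
                      "simulate_fragments: planted region outside genome")
  fold <- if (length(planted)) planted$fold else numeric(0)
  if (any(fold < 1)) stop("simulate_fragments: enrichment fold must be >= 1")
  max_fold <- max(1, fold)
  with_seed(config$seed + 202L, {
    input <- random_intervals(sizes, fragment_lengths(config, config$depth_input))
    ip <- vector("list", 0L)
    got <- 0L
    while (got < config$depth_ip) {
      need <- config$depth_ip - got
      batch <- ceiling(need * max_fold * 1.2) + 100L
      cand <- random_intervals(sizes, fragment_lengths(config, batch))
      mid0 <- (GenomicRanges::start(cand) - 1L + GenomicRanges::end(cand)) %/% 2L
      mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(cand),
                                     IRanges::IRanges(mid0 + 1L, mid0 + 1L))
      w <- rep(1, batch)
      if (length(planted)) {
        hits <- GenomicRanges::findOverlaps(mids, planted, ignore.strand = TRUE)
        w[S4Vectors::queryHits(hits)] <- fold[S4Vectors::subjectHits(hits)]
      }
      keep <- stats::runif(batch) < w / max_fold
      acc <- cand[keep]
      if (length(acc) > need) acc <- acc[seq_len(need)]
      ip[[length(ip) + 1L]] <- acc
      got <- got + length(acc)
    }
    list(ip = do.call(c, ip), input = input)
  })
}

#' Simulate a bisulfite clone matrix for one condition
#'
#' Calls are Bernoulli with the condition's methylation probability; cells go
#' missing independently at `missing_rate`.
#'
#' @param config A `SimConfig`.
#' @param condition Name into `config$clone_p_meth` (default: first).
#' @return A `CloneMatrix`; the generating probability is attached as
#'   attribute `"truth_p"`.
#' @export
simulate_clone_matrix <- function(config, condition = names(config$clone_p_meth)[1]) {
  stopifnot(inherits(config, "SimConfig"))
  p <- config$clone_p_meth[[condition]]
  cond_idx <- match(condition, names(config$clone_p_meth))
  with_seed(config$seed + 303L + cond_idx, {
    calls <- matrix(stats::rbinom(config$n_clones * config$n_cpgs, 1L, p),
                    config$n_clones, config$n_cpgs)
    miss <- matrix(stats::runif(length(calls)) < config$missing_rate,
                   nrow(calls), ncol(calls))
    ## keep at least one observed call per clone so clones stay informative
    first_kept <- max.col(-miss, ties.method = "first")
    miss[cbind(seq_len(nrow(miss)), first_kept)] <- FALSE
    calls[miss] <- NA_integer_
    m <- clone_matrix(calls, amplicon_id = condition)
    attr(m, "truth_p") <- p
    m
  })
}

#' Simulate a DigiWest fraction matrix with a factorial design
#'
#' Each analyte has a Gaussian band at an analyte-specific fraction; the band
#' amplitude carries additive treatment and cell-type effects (in units of
#' the replicate noise SD) plus Gaussian replicate noise; small per-fraction
#' noise is added and everything is floored at 0 (background-subtracted
#' data).
#'
#' @param config A `SimConfig`.
#' @return A `FractionMatrix`; the per-analyte effect sizes and band windows
#'   are attached as attribute `"truth"`.
#' @export
simulate_fraction_matrix <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  treatments <- c("serum", "2i")
  celltypes <- c("J1", "TKO", "3B3l")
  design <- expand.grid(rep = seq_len(config$dw_n_per_cell),
                        treatment = treatments, celltype = celltypes,
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%s_r%d", design$celltype, design$treatment,
                           design$rep)
  na <- config$dw_n_analytes
  eff_t <- rep_len(config$dw_treatment_effect, na) * config$dw_noise_sd
  eff_c <- rep_len(config$dw_cell_effect, na) * config$dw_noise_sd
  with_seed(config$seed + 404L, {
    centers <- sample(10:87, na, replace = TRUE)
    sigma <- stats::runif(na, 1.2, 2.5)
    base_amp <- stats::runif(na, 20, 60)
    arr <- array(0, dim = c(na, nrow(design), 96L),
                 dimnames = list(sprintf("analyte%03d", seq_len(na)),
                                 design$sample, NULL))
    cell_score <- match(design$celltype, celltypes) - 2L  # -1, 0, 1
    is_2i <- as.numeric(design$treatment == "2i")
    for (i in seq_len(na)) {
      shape <- exp(-((1:96 - centers[i])^2) / (2 * sigma[i]^2))
      amp <- base_amp[i] + eff_t[i] * is_2i + eff_c[i] * cell_score +
        stats::rnorm(nrow(design), 0, config$dw_noise_sd)
      prof <- outer(amp, shape) +
        matrix(stats::rnorm(nrow(design) * 96L, 0, 0.02), nrow(design), 96L)
      arr[i, , ] <- pmax(prof, 0)
    }
    f <- fraction_matrix(arr, design[, c("sample", "treatment", "celltype")])
    attr(f, "truth") <- list(
      treatment_effect = eff_t, cell_effect = eff_c,
      bands = stats::setNames(lapply(seq_len(na), function(i) {
        lo <- max(1L, floor(centers[i] - 3 * sigma[i]))
        hi <- min(96L, ceiling(centers[i] + 3 * sigma[i]))
        lo:hi
      }), dimnames(arr)[[1]]))
    f
  })
}

#' Simulate per-epitype differential-expression tables
#'
#' Three epitype tables (gene, log2FC, adj_p) share planted consensus up- and
#' down-regulated gene sets with the configured log2 effect; all other genes
#' are null.  A baseline (lognormal) expression value per gene is returned
#' for expression-quartile stratification.
#'
#' @param config A `SimConfig`.
#' @param genes A `GeneSet` (from [simulate_genome()]).
#' @param epitypes Table names (default J1, TKO, 3B3l).
#' @return List with `tables` (named list of data frames), `baseline` (named
#'   numeric) and `truth` (list with `up` and `down` gene ids).
#' @export
simulate_expression <- function(config, genes,
                                epitypes = c("J1", "TKO", "3B3l")) {
  stopifnot(inherits(config, "SimConfig"), inherits(genes, "GeneSet"))
  ids <- names(genes$body)
  n_up <- min(config$expr_n_de_up, length(ids) %/% 3L)
  n_down <- min(config$expr_n_de_down, length(ids) %/% 3L)
  with_seed(config$seed + 505L, {
    de <- sample(ids, n_up + n_down)
    up <- sort(head(de, n_up)); down <- sort(tail(de, n_down))
    baseline <- stats::setNames(stats::rlnorm(length(ids), 4, 1.2), ids)
    tables <- lapply(epitypes, function(ep) {
      lfc <- stats::rnorm(length(ids), 0, 0.3)
      lfc[ids %in% up] <- stats::rnorm(n_up, config$expr_effect, 0.15)
      lfc[ids %in% down] <- stats::rnorm(n_down, -config$expr_effect, 0.15)
      adj_p <- stats::runif(length(ids), 0.1, 1)
      adj_p[ids %in% c(up, down)] <- stats::runif(n_up + n_down, 0, 0.01)
      data.frame(gene = ids, log2FC = lfc, adj_p = adj_p)
    })
    list(tables = stats::setNames(tables, epitypes),
         baseline = baseline,
         truth = list(up = up, down = down))
  })
}
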