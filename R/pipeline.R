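## End-to-end orchestration: run every stage on synthetic inputs with a
## single seed, write all outputs as plain-text files plus a manifest, and
## guarantee byte-identical reruns for the same configuration.

#' Pipeline configuration
#'
#' Collects the analysis parameters (at the values the method defines:
#' 200 bp windows, 95th-percentile reference threshold, 2-of-3 window rule,
#' 100/1000/2000 bp compartment bounds, 2 kb promoter flank, 25% gene-body
#' flanks, 100% element flanks, 1 kb promoter-mean flank, 10 kb nearest-gene
#' cutoff, fold-2 / 0.05 differential-expression thresholds, 1000-permutation
#' ANOVA at alpha 0.005) together with the synthetic-data configuration.
#'
#' @param seed Integer seed for the whole run.
#' @param sim A `SimConfig`; defaults to `sim_config(seed = seed)`.
#' @param window_size,percentile,region_windows,min_qualifying Peak-calling
#'   parameters.
#' @param core_bp,proximal_bp,distal_bp Compartment bounds in bp.
#' @param promoter_flank,body_flank_fraction,element_flank_fraction Profile
#'   flanks.
#' @param promoter_mean_flank Promoter-mean flank in bp.
#' @param nearest_max_dist Nearest-gene cutoff in bp.
#' @param fc_threshold,de_alpha Differential-expression thresholds.
#' @param n_perm,dw_alpha DigiWest ANOVA parameters.
#' @return A `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            window_size = 200L, percentile = 95,
                            region_windows = 3L, min_qualifying = 2L,
                            core_bp = 100L, proximal_bp = 1000L,
                            distal_bp = 2000L,
                            promoter_flank = 2000L,
                            body_flank_fraction = 0.25,
                            element_flank_fraction = 1.0,
                            promoter_mean_flank = 1000L,
                            nearest_max_dist = 10000L,
                            fc_threshold = 2, de_alpha = 0.05,
                            n_perm = 1000L, dw_alpha = 0.005) {
  num <- c(window_size, percentile, region_windows, min_qualifying, core_bp,
           proximal_bp, distal_bp, promoter_flank, body_flank_fraction,
           element_flank_fraction, promoter_mean_flank, nearest_max_dist,
           fc_threshold, de_alpha, n_perm, dw_alpha)
  if (any(num <= 0)) stop("pipeline_config: all numeric parameters must be positive")
  structure(as.list(environment())[setdiff(ls(), "num")],
            class = "PipelineConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole pipeline on synthetic data
#'
#' Generates a genome, IP/input fragment sets for a reference condition and a
#' treated condition with half the planted enriched territory, quantifies and
#' subtracts tracks, calls and maps peaks with the reference-derived
#' threshold, computes profiles and stratifications, counts repeats,
#' evaluates bisulfite and DigiWest statistics, and writes every result plus
#' a parameter manifest under `out_dir`.  Rerunning with the same
#' configuration writes byte-identical files.
#'
#' @param config A `PipelineConfig`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  genome <- simulate_genome(sim)

  ## reference condition: all planted regions; treated: half of them
  planted_ref <- genome$planted
  keep <- seq_len(max(0L, length(planted_ref) %/% 2L))
  planted_trt <- planted_ref[keep]
  sim_trt <- sim
  sim_trt$seed <- sim$seed + 7L
  frags_ref <- simulate_fragments(sim, planted_ref)
  frags_trt <- simulate_fragments(sim_trt, planted_trt)

  grid <- window_grid(genome$sizes, config$window_size)
  make_track <- function(fr) {
    subtract_input(normalize_total(count_fragments(grid, fr$ip)),
                   normalize_total(count_fragments(grid, fr$input)))
  }
  track_ref <- make_track(frags_ref)
  track_trt <- make_track(frags_trt)
  write_track(track_ref, file.path(out_dir, "track_reference.bedGraph"))
  write_track(track_trt, file.path(out_dir, "track_treated.bedGraph"))

  thr <- reference_threshold(track_ref, config$percentile, "reference")
  peaks_ref <- assign_compartments(
    call_peaks(track_ref, thr, config$region_windows, config$min_qualifying),
    genome$genes, config$core_bp, config$proximal_bp, config$distal_bp)
  peaks_trt <- assign_compartments(
    call_peaks(track_trt, thr, config$region_windows, config$min_qualifying),
    genome$genes, config$core_bp, config$proximal_bp, config$distal_bp)
  write_peaks(peaks_ref, file.path(out_dir, "peaks_reference.bed"))
  write_peaks(peaks_trt, file.path(out_dir, "peaks_treated.bed"))
  comp <- data.frame(compartment = names(compartment_counts(peaks_ref)),
                     reference = as.integer(compartment_counts(peaks_ref)),
                     treated = as.integer(compartment_counts(peaks_trt)))
  write_tsv(comp, file.path(out_dir, "compartments.tsv"))

  enr <- data.frame(
    sample = c("reference", "treated"),
    enriched_windows = c(length(enriched_windows(track_ref)),
                         length(enriched_windows(track_trt))))
  write_tsv(enr, file.path(out_dir, "enriched_windows.tsv"))

  prof <- promoter_profile(track_ref, genome$genes, config$promoter_flank)
  gb <- genebody_profile(track_ref, genome$genes, config$body_flank_fraction)
  el <- element_profile(track_ref, genome$osn_sites,
                        config$element_flank_fraction)
  profile_df <- function(p) data.frame(bin = p$bins,
                                       mean = sprintf("%.6f", p$mean_signal),
                                       n = p$n_features)
  write_tsv(profile_df(prof), file.path(out_dir, "profile_promoter.tsv"))
  write_tsv(profile_df(gb), file.path(out_dir, "profile_genebody.tsv"))
  write_tsv(profile_df(el), file.path(out_dir, "profile_element.tsv"))

  expr <- simulate_expression(sim, genome$genes)
  pm <- promoter_mean(track_ref, genome$genes, config$promoter_mean_flank)
  quart <- quartile_stratify(genome$genes, expr$baseline)
  state <- promoter_state_stratify(genome$genes, peaks_ref,
                                   config$promoter_mean_flank)
  strata <- rbind(
    data.frame(set = rep(names(quart), lengths(quart)),
               gene = unlist(quart, use.names = FALSE)),
    data.frame(set = rep(c("enriched", "depleted"), lengths(state)),
               gene = unlist(state, use.names = FALSE)))
  write_tsv(strata, file.path(out_dir, "stratified_sets.tsv"))
  write_tsv(data.frame(gene = names(pm), promoter_mean = sprintf("%.6f", pm)),
            file.path(out_dir, "promoter_means.tsv"))

  nearest <- nearest_gene_within(genome$osn_sites, genome$genes,
                                 config$nearest_max_dist)
  write_tsv(data.frame(site = sprintf("osn%03d", seq_along(nearest)),
                       gene = ifelse(is.na(nearest), "none", nearest)),
            file.path(out_dir, "osn_nearest_gene.tsv"))

  de <- consensus_de_sets(expr$tables, config$fc_threshold, config$de_alpha)
  write_tsv(data.frame(direction = rep(c("up", "down"), lengths(de)),
                       gene = unlist(de, use.names = FALSE)),
            file.path(out_dir, "consensus_de.tsv"))

  assign_ref <- assign_to_repeats(frags_ref$ip, genome$repeats)
  counts_ref <- count_by_type(assign_ref, genome$repeats)
  norm <- normalize_repeat_counts(cbind(reference = counts_ref),
                                  length(frags_ref$ip))
  write_tsv(data.frame(repeat_type = names(counts_ref),
                       count = as.integer(counts_ref),
                       cpm = sprintf("%.6f", norm[, 1])),
            file.path(out_dir, "repeat_counts.tsv"))

  cm <- lapply(names(sim$clone_p_meth), function(cond)
    simulate_clone_matrix(sim, cond))
  names(cm) <- names(sim$clone_p_meth)
  lv <- lapply(cm, clone_methylation_levels)
  mwu <- mann_whitney_u(lv[[1]], lv[[2]])
  bis <- data.frame(condition = names(cm),
                    percent_methylation = sprintf(
                      "%.4f", vapply(cm, percent_methylation, 0.0)))
  write_tsv(bis, file.path(out_dir, "bisulfite_percent.tsv"))
  write_tsv(data.frame(U = mwu$U, p = sprintf("%.6g", mwu$p)),
            file.path(out_dir, "bisulfite_mwu.tsv"))

  fm <- simulate_fraction_matrix(sim)
  bands <- attr(fm, "truth")$bands
  vals <- quantify_analyte(fm, bands)
  actin <- vals[1L, ]  # first analyte doubles as the loading control
  norm_vals <- normalize_to_actin(vals[-1L, , drop = FALSE], actin)
  aov2 <- permutation_anova2(norm_vals, fm$design$treatment,
                             fm$design$celltype, config$n_perm,
                             seed = sim$seed + 606L)
  aov_out <- aov2
  for (cn in c("F_A", "F_B", "F_AB", "p_A", "p_B", "p_AB"))
    aov_out[[cn]] <- sprintf("%.6g", aov_out[[cn]])
  write_tsv(aov_out, file.path(out_dir, "digiwest_anova.tsv"))
  clust <- suppressWarnings(cluster_significant(norm_vals, aov2, config$dw_alpha))
  write_tsv(data.frame(order = seq_along(clust$analytes),
                       analyte = clust$analytes),
            file.path(out_dir, "digiwest_significant.tsv"))

  manifest <- config[setdiff(names(config), "sim")]
  manifest$sim <- unclass(sim)
  manifest$sim$chrom_lengths <- as.list(sim$chrom_lengths)
  manifest$sim$planted_regions <- NULL
  manifest$package_version <- as.character(utils::packageVersion("epiwindow"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(genome = genome, tracks = list(reference = track_ref,
                                                treated = track_trt),
                 threshold = thr,
                 peaks = list(reference = peaks_ref, treated = peaks_trt),
                 profiles = list(promoter = prof, genebody = gb, element = el),
                 expression = expr, consensus_de = de,
                 repeat_counts = counts_ref, clone_matrices = cm,
                 mwu = mwu, anova = aov2, clusters = clust))
}
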