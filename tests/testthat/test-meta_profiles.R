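test_that("profiles of a constant track are constant", {
  genes <- toy_genes()
  tr <- flat_track(2.5, n_windows = 100L)  # 20 kb chromosome
  pp <- promoter_profile(tr, genes, flank = 1500, n_bins = 20L)
  expect_equal(unname(pp$mean_signal), rep(2.5, 20))
  gb <- genebody_profile(tr, genes, body_bins = 30L, flank_bins = 10L)
  expect_equal(unname(gb$mean_signal), rep(2.5, 50))
  el <- element_profile(tr, GenomicRanges::GRanges("chr1",
                                                   IRanges::IRanges(5001, 5200)),
                        bins = 10L)
  expect_equal(unname(el$mean_signal), rep(2.5, 30))
  expect_equal(unname(promoter_mean(tr, genes)), c(2.5, 2.5))
})

test_that("plus and minus genes with mirror-image signal give identical profiles", {
  ## genome of 20 kb; minus-strand track is the base-level mirror of the plus
  set.seed(41)
  n <- 100L
  sc <- round(runif(n, 0, 8), 3)
  tr_plus <- make_track(list(chr1 = sc))
  tr_minus <- make_track(list(chr1 = rev(sc)))
  L <- 20000L
  ## plus gene at [a0, b0); mirrored minus gene at [L-b0, L-a0)
  a0 <- 6000L; b0 <- 11000L
  gplus <- gene_set(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(a0 + 1, b0), strand = "+",
                           gene_id = "g"),
    GenomicRanges::GRangesList(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(a0 + 1, b0), strand = "+")))
  gminus <- gene_set(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(L - b0 + 1, L - a0),
                           strand = "-", gene_id = "g"),
    GenomicRanges::GRangesList(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(L - b0 + 1, L - a0), strand = "-")))
  pp_plus <- promoter_profile(tr_plus, gplus, flank = 2000, n_bins = 40L)
  pp_minus <- promoter_profile(tr_minus, gminus, flank = 2000, n_bins = 40L)
  expect_equal(pp_plus$mean_signal, pp_minus$mean_signal, tolerance = 1e-12)
  gb_plus <- genebody_profile(tr_plus, gplus)
  gb_minus <- genebody_profile(tr_minus, gminus)
  expect_equal(gb_plus$mean_signal, gb_minus$mean_signal, tolerance = 1e-12)
  expect_equal(unname(promoter_mean(tr_plus, gplus)),
               unname(promoter_mean(tr_minus, gminus)), tolerance = 1e-12)
})

test_that("signal at the TSS lands in the central promoter bins", {
  sc <- rep(0, 100); sc[31] <- 10   # window covering 0-based [6000, 6200)
  tr <- make_track(list(chr1 = sc))
  g <- gene_set(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(6001, 9000), strand = "+",
                           gene_id = "g"),
    GenomicRanges::GRangesList(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(6001, 9000), strand = "+")))
  pp <- promoter_profile(tr, g, flank = 2000, n_bins = 40L)
  central <- pp$mean_signal[21:22]
  expect_true(all(central >= max(pp$mean_signal[c(1:10, 31:40)])))
  expect_true(which.max(pp$mean_signal) %in% 19:24)
})

test_that("gene-body profile spans body plus proportional flanks", {
  ## signal only inside the body: body bins must dominate flanks
  L <- 40000L
  sc <- rep(0, 200)
  sc[51:100] <- 4   # 0-based [10000, 20000)
  tr <- make_track(list(chr1 = sc), sizes = c(chr1 = L))
  g <- gene_set(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000), strand = "+",
                           gene_id = "g"),
    GenomicRanges::GRangesList(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(10001, 20000), strand = "+")))
  gb <- genebody_profile(tr, g)
  body_mean <- mean(gb$mean_signal[26:125])
  flank_mean <- mean(gb$mean_signal[c(1:25, 126:150)])
  expect_gt(body_mean, flank_mean)
  expect_equal(unname(gb$mean_signal[50]), 4)
  ## 10 kb gene with 25% flanks profiles 15 kb: outermost flank bin sits
  ## at 0-based [7500, 7600), fully outside the signal
  expect_equal(unname(gb$mean_signal[1]), 0)
})

test_that("element profile recovers a depleted center", {
  sc <- rep(3, 100); sc[26:30] <- 0   # zero inside 0-based [5000, 6000)
  tr <- make_track(list(chr1 = sc))
  el <- element_profile(tr, GenomicRanges::GRanges("chr1",
                                                   IRanges::IRanges(5001, 6000)),
                        bins = 10L)
  expect_equal(unname(el$mean_signal[11:20]), rep(0, 10))
  expect_equal(unname(el$mean_signal[c(1:5, 26:30)]), rep(3, 10))
  expect_error(element_profile(tr, GenomicRanges::GRanges()), "empty")
})

test_that("promoter_mean matches the per-base oracle and is linear", {
  set.seed(42)
  for (rep_i in 1:25) {
    n <- 80L
    sc <- round(runif(n, 0, 10), 3)
    tr <- make_track(list(chr1 = sc))
    tss0 <- sample(500:15000, 1)
    strand <- sample(c("+", "-"), 1)
    body <- if (strand == "+")
      GenomicRanges::GRanges("chr1", IRanges::IRanges(tss0 + 1, tss0 + 1200),
                             strand = "+", gene_id = "g")
    else
      GenomicRanges::GRanges("chr1", IRanges::IRanges(tss0 - 1199, tss0 + 1),
                             strand = "-", gene_id = "g")
    g <- gene_set(body, GenomicRanges::GRangesList(GenomicRanges::granges(body)))
    got <- unname(promoter_mean(tr, g, flank = 1000))
    anchor0 <- if (strand == "+") tss0 else tss0 + 1
    want <- oracle_bp_mean(sc, 200L, n * 200L, anchor0 - 1000, anchor0 + 1000)
    expect_equal(got, want, tolerance = 1e-9)
    tr2 <- make_track(list(chr1 = sc * 2))
    expect_equal(unname(promoter_mean(tr2, g, flank = 1000)), 2 * got,
                 tolerance = 1e-12)
  }
})

test_that("expression quartiles rank descending with deterministic ties", {
  ids <- sprintf("g%02d", 1:8)
  ex <- setNames(c(8, 7, 6, 5, 4, 3, 2, 1), ids)
  q <- quartile_stratify(ids, ex)
  expect_equal(q$Q1, c("g01", "g02"))
  expect_equal(q$Q4, c("g07", "g08"))
  expect_equal(lengths(q), c(Q1 = 2L, Q2 = 2L, Q3 = 2L, Q4 = 2L))

  tied <- setNames(rep(1, 8), ids)
  q2 <- quartile_stratify(ids, tied)
  expect_equal(q2$Q1, c("g01", "g02"))  # lexicographic tie-break

  ids10 <- sprintf("g%02d", 1:10)
  q3 <- quartile_stratify(ids10, setNames(10:1, ids10))
  expect_equal(unname(lengths(q3)), c(3L, 3L, 2L, 2L))
  expect_true(!any(duplicated(unlist(q3))))
})

test_that("promoter peak-state stratification matches interval overlap", {
  genes <- toy_genes()
  none <- GenomicRanges::GRanges()
  st0 <- promoter_state_stratify(genes, none)
  expect_equal(st0$depleted, c("gA", "gB"))
  expect_equal(st0$enriched, character(0))

  at_tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 2001))
  st1 <- promoter_state_stratify(genes, at_tss)
  expect_equal(st1$enriched, "gA")

  set.seed(43)
  for (rep_i in 1:20) {
    s0 <- sample(0:19000, 5)
    pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1, s0 + 400))
    st <- promoter_state_stratify(genes, pk, flank = 1000L)
    tss <- gene_tss(genes)
    manual <- vapply(tss, function(t)
      any(pmax(s0 + 1, t - 1000) <= pmin(s0 + 400, t + 1000)), TRUE)
    expect_equal(sort(st$enriched), sort(names(tss)[manual]))
    expect_equal(sort(c(st$enriched, st$depleted)), c("gA", "gB"))
  }
})

test_that("nearest gene within cutoff matches the all-pairs oracle", {
  genes <- toy_genes()
  gdf <- data.frame(chrom = "chr1", start0 = c(2000, 12000),
                    end0 = c(6000, 16000), gene_id = c("gA", "gB"))
  ## 5 kb upstream of gA -> gA; beyond 10 kb of everything -> none
  near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  expect_equal(nearest_gene_within(near, genes), "gA")
  far_genes <- gene_set(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 52000), strand = "+",
                           gene_id = "g"),
    GenomicRanges::GRangesList(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(50001, 52000), strand = "+")))
  expect_true(is.na(nearest_gene_within(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(30001, 30200)), far_genes)))

  set.seed(44)
  s0 <- sample(0:30000, 40)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1, s0 + 150))
  got <- nearest_gene_within(sites, genes, max_dist = 10000)
  want <- vapply(seq_along(s0), function(i)
    oracle_nearest_gene("chr1", s0[i], s0[i] + 150, gdf, 10000), "")
  expect_equal(got, want)
})

test_that("consensus differential sets are per-table threshold intersections", {
  mk <- function(lfc, p) data.frame(gene = sprintf("g%d", seq_along(lfc)),
                                    log2FC = lfc, adj_p = p)
  tables <- list(A = mk(c(2, 0.9, -2.5), c(0.01, 0.01, 0.01)),
                 B = mk(c(1.5, 0.9, -1.2), c(0.02, 0.01, 0.04)),
                 C = mk(c(3, 0.9, -4), c(0.001, 0.01, 0.002)))
  de <- consensus_de_sets(tables)
  expect_equal(de$up, "g1")
  expect_equal(de$down, "g3")  # g2 below log2(2) everywhere -> excluded

  dup <- list(mk(c(1, 1), c(0.01, 0.01)), mk(c(1, 1), c(0.01, 0.01)))
  dup[[1]]$gene <- c("g1", "g1")
  expect_error(consensus_de_sets(dup), "duplicate")

  set.seed(45)
  for (rep_i in 1:20) {
    tabs <- lapply(1:3, function(i)
      mk(round(rnorm(30, 0, 2), 2), round(runif(30), 3)))
    de <- consensus_de_sets(tabs, fc_threshold = 2, alpha = 0.05)
    sel <- function(tb, sgn) tb$gene[sgn * tb$log2FC >= 1 & tb$adj_p <= 0.05]
    expect_equal(de$up, sort(Reduce(intersect, lapply(tabs, sel, sgn = 1))))
    expect_equal(de$down, sort(Reduce(intersect, lapply(tabs, sel, sgn = -1))))
  }
})
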