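toy_fraction_matrix <- function(seed = 71, n_analytes = 3L, effect = 0) {
  cfg <- sim_config(seed = seed, dw_n_analytes = n_analytes,
                    dw_treatment_effect = effect)
  simulate_fraction_matrix(cfg)
}

test_that("blot scaling sets the antibody-wide maximum to 1", {
  arr <- array(0, c(1, 3, 96), dimnames = list("ab", c("s1", "s2", "s3"), NULL))
  arr[1, , 10] <- c(0, 5, 10)
  f <- fraction_matrix(arr, data.frame(sample = c("s1", "s2", "s3"),
                                       treatment = c("serum", "2i", "serum"),
                                       celltype = "J1"))
  sc <- scale_blot(f, "ab")
  expect_equal(sc[, 10], c(s1 = 0, s2 = 0.5, s3 = 1))
  expect_equal(max(sc), 1)
  expect_equal(scale_blot(f, "ab"), sc)  # idempotent on already-scaled data
  arr0 <- arr; arr0[] <- 0
  f0 <- fraction_matrix(arr0, f$design)
  expect_error(scale_blot(f0, "ab"), "all-zero")

  fm <- toy_fraction_matrix()
  sc2 <- scale_blot(fm, 2L)
  expect_equal(max(sc2), 1)
  expect_equal(which.max(sc2), which.max(fm$intensities[2, , ]))
})

test_that("blot rendering blurs with conserved mass and fixed dimensions", {
  sc <- matrix(0, 2, 96)
  img0 <- render_blot(sc, element_height = 4L)
  expect_equal(dim(img0), c(96L * 4L, 2L * 4L))
  expect_true(all(img0 == 0))

  sc[1, 48] <- 1
  img <- render_blot(sc, element_height = 6L)
  expect_equal(sum(img), 6 * 6, tolerance = 0.01 * 36)  # mass of one element
  expect_gt(max(img[(47 * 6 + 1):(48 * 6), 1:6]), max(img[1:6, 1:6]))

  const <- render_blot(matrix(0.7, 2, 96), element_height = 4L)
  expect_equal(max(abs(const - 0.7)), 0, tolerance = 1e-12)
  expect_error(render_blot(sc, element_height = 1L), "element_height")
})

test_that("band quantification captures a planted Gaussian band", {
  arr <- array(0, c(1, 2, 96), dimnames = list("ab", c("s1", "s2"), NULL))
  arr[1, 1, 30] <- 7
  arr[1, 2, ] <- 1
  f <- fraction_matrix(arr, data.frame(sample = c("s1", "s2"),
                                       treatment = c("serum", "2i"),
                                       celltype = "J1"))
  v <- quantify_analyte(f, list(ab = 30L))
  expect_equal(unname(v["ab", ]), c(7, 1))
  v_all <- quantify_analyte(f, list(ab = 1:96))
  expect_equal(unname(v_all["ab", "s2"]), 96)
  expect_error(quantify_analyte(f, list(ab = integer(0))), "empty band")

  ## +/- 3 sigma window captures >= 99% of a planted Gaussian band
  center <- 40; sigma <- 2
  shape <- exp(-((1:96 - center)^2) / (2 * sigma^2))
  arr2 <- array(rep(shape, each = 2), c(1, 2, 96),
                dimnames = list("ab", c("s1", "s2"), NULL))
  f2 <- fraction_matrix(arr2, f$design)
  win <- (center - 3 * sigma):(center + 3 * sigma)
  expect_gte(unname(quantify_analyte(f2, list(ab = win))["ab", 1]) / sum(shape),
             0.99)
})

test_that("actin normalization is an invertible log2 ratio", {
  v <- rbind(a1 = c(4, 8), a2 = c(2, 2))
  actin <- c(4, 8)
  nv <- normalize_to_actin(v, actin)
  expect_equal(nv["a1", ], c(0, 0))
  v2 <- v; v2["a1", 2] <- 16
  expect_equal(unname(normalize_to_actin(v2, actin)["a1", 2] - nv["a1", 2]), 1)
  set.seed(72)
  vr <- matrix(runif(12, 1, 50), 3, 4,
               dimnames = list(c("x", "y", "z"), NULL))
  act <- runif(4, 1, 10)
  expect_equal(2^normalize_to_actin(vr, act), sweep(vr, 2, act, "/"),
               tolerance = 1e-12)
  expect_error(normalize_to_actin(vr, c(1, -1, 1, 1)), "actin")
  ## zero cells get a finite pseudo-floored ratio
  vz <- rbind(a = c(0, 4, 8))
  nz <- normalize_to_actin(vz, c(1, 1, 1))
  expect_true(all(is.finite(nz)))
  expect_equal(unname(nz[1, 1]), log2(2))  # half the smallest positive = 2
})

anova_design <- function(n_per_cell = 2L) {
  d <- expand.grid(rep = seq_len(n_per_cell), treatment = c("serum", "2i"),
                   celltype = c("J1", "TKO", "3B3l"))
  d
}

test_that("observed F statistics agree with base R aov on a balanced design", {
  set.seed(73)
  d <- anova_design()
  y <- rnorm(nrow(d), mean = 2 * (d$treatment == "2i") +
               0.8 * as.integer(factor(d$celltype)))
  res <- permutation_anova2(matrix(y, 1, length(y)), d$treatment, d$celltype,
                            n_perm = 100, seed = 1)
  fit <- summary(stats::aov(y ~ treatment * celltype, data = d))[[1]]
  f_vals <- fit[["F value"]]  # treatment, celltype, interaction, residuals
  expect_equal(res$F_A, f_vals[1], tolerance = 1e-10)
  expect_equal(res$F_B, f_vals[2], tolerance = 1e-10)
  expect_equal(res$F_AB, f_vals[3], tolerance = 1e-10)
})

test_that("permutation p-values are seeded, floored and affine-invariant", {
  d <- anova_design()
  set.seed(74)
  Y <- matrix(rnorm(5 * nrow(d)), 5, nrow(d),
              dimnames = list(sprintf("a%d", 1:5), NULL))
  r1 <- permutation_anova2(Y, d$treatment, d$celltype, n_perm = 300, seed = 9)
  r2 <- permutation_anova2(Y, d$treatment, d$celltype, n_perm = 300, seed = 9)
  expect_identical(r1, r2)
  ## affine rescaling leaves F (hence p) unchanged
  r3 <- permutation_anova2(Y * 3.7 + 2, d$treatment, d$celltype,
                           n_perm = 300, seed = 9)
  expect_equal(r1$F_A, r3$F_A, tolerance = 1e-9)
  expect_equal(r1$p_A, r3$p_A)

  ## constant analyte: F = 0, p = 1
  rc <- permutation_anova2(matrix(5, 1, nrow(d)), d$treatment, d$celltype,
                           n_perm = 100, seed = 2)
  expect_equal(rc$F_A, 0)
  expect_equal(rc$p_A, 1)

  ## a 10-SD treatment shift saturates the permutation floor
  y <- rnorm(nrow(d), 0, 1) + 10 * (d$treatment == "2i")
  rs <- permutation_anova2(matrix(y, 1, nrow(d)), d$treatment, d$celltype,
                           n_perm = 1000, seed = 3)
  expect_equal(rs$p_A, 1 / 1001)

  expect_error(permutation_anova2(Y, rep("serum", 12), d$celltype, 100, 1),
               "design cell|contrasts")
  expect_warning(permutation_anova2(Y[1, , drop = FALSE], d$treatment,
                                    d$celltype, n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("significant analytes cluster deterministically by Euclidean distance", {
  vals <- rbind(a_far = c(10, 10, 0, 0), b_same1 = c(1, 2, 3, 4),
                c_same2 = c(1, 2, 3, 4))
  p <- c(a_far = 0.001, b_same1 = 0.001, c_same2 = 0.001)
  cl <- cluster_significant(vals, p, alpha = 0.005)
  expect_s3_class(cl$tree, "hclust")
  ## identical pair merges first at height 0
  expect_equal(cl$tree$height[1], 0)
  first_merge <- cl$tree$labels[-cl$tree$merge[1, ]]
  expect_setequal(first_merge, c("b_same1", "c_same2"))

  p2 <- c(a_far = 0.5, b_same1 = 0.001, c_same2 = 0.5)
  expect_warning(cl2 <- cluster_significant(vals, p2), "fewer than 2")
  expect_null(cl2$tree)
  expect_equal(cl2$analytes, "b_same1")
  expect_warning(cl3 <- cluster_significant(vals, c(a_far = 1, b_same1 = 1,
                                                    c_same2 = 1)))
  expect_equal(cl3$analytes, character(0))
})

test_that("null DigiWest simulations reject near the nominal rate", {
  cfg <- sim_config(seed = 75, dw_n_analytes = 60L, dw_treatment_effect = 0)
  fm <- simulate_fraction_matrix(cfg)
  vals <- quantify_analyte(fm, attr(fm, "truth")$bands)
  nv <- normalize_to_actin(vals[-1, , drop = FALSE], vals[1, ])
  res <- permutation_anova2(nv, fm$design$treatment, fm$design$celltype,
                            n_perm = 400, seed = 76)
  rate <- mean(res$p_A < 0.05)
  ## loose 3-sigma binomial band around 0.05 with 59 analytes
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)) + 0.02)
})
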