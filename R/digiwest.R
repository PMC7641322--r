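## DigiWest 96-fraction analytics: blot-image reconstruction, band
## quantification, loading-control normalization, permutation two-factor
## ANOVA, and Euclidean clustering of significant analytes.
##
## A DigiWest run resolves each sample into 96 molecular-weight fractions
## read on a Luminex instrument; every antibody (analyte) therefore yields a
## sample x 96 intensity matrix that can be rendered as a mimicked western
## blot or collapsed to one value per sample over a band window.

#' Construct a DigiWest fraction matrix
#'
#' @param intensities 3-d array `[analyte, sample, fraction]` with exactly 96
#'   fractions, background-subtracted (all values >= 0).
#' @param design Data frame with columns `sample`, `treatment`, `celltype`
#'   describing the factorial design, rows matching the sample dimension.
#' @return A `FractionMatrix`.
#' @export
fraction_matrix <- function(intensities, design) {
  if (length(dim(intensities)) != 3L || dim(intensities)[3] != 96L)
    stop("fraction_matrix: intensities must be [analyte, sample, 96]")
  if (any(intensities < 0)) stop("fraction_matrix: intensities must be >= 0")
  stopifnot(all(c("sample", "treatment", "celltype") %in% names(design)),
            nrow(design) == dim(intensities)[2])
  structure(list(intensities = intensities, design = design),
            class = "FractionMatrix")
}

#' @export
print.FractionMatrix <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("FractionMatrix: %d analytes x %d samples x 96 fractions\n",
              d[1], d[2]))
  invisible(x)
}

#' Scale an antibody's fraction data to [0, 1]
#'
#' All intensities of the analyte are divided by the antibody-wide maximum,
#' so the highest measured signal becomes exactly 1.
#'
#' @param f A `FractionMatrix`.
#' @param analyte Analyte name or index.
#' @return `sample x 96` matrix in [0, 1].
#' @export
scale_blot <- function(f, analyte) {
  stopifnot(inherits(f, "FractionMatrix"))
  m <- f$intensities[analyte, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  top <- max(m)
  if (top <= 0) stop("scale_blot: all-zero antibody")
  rownames(m) <- f$design$sample
  m / top
}

gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g / sum(g)
}

## 1-d convolution along rows of `img` with reflective padding; symmetric
## kernel + reflection conserves total mass exactly.
conv1d_reflect <- function(img, g) {
  half <- (length(g) - 1L) %/% 2L
  n <- nrow(img)
  idx <- c(rev(seq_len(half)), seq_len(n), n + 1L - rev(seq_len(half)))
  padded <- img[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(img))
  for (k in seq_along(g))
    out <- out + g[k] * padded[k:(k + n - 1L), , drop = FALSE]
  out
}

#' Render a scaled antibody matrix as a mimicked western blot image
#'
#' Each (fraction, sample) cell is painted as an `element_height`-tall,
#' `element_width`-wide greyscale block (0 = white, 1 = black), then a
#' Gaussian diffusion with a radius of half the element height is applied
#' (reflective boundary, so total intensity is conserved).
#'
#' @param scaled `sample x 96` matrix from [scale_blot()].
#' @param element_height Block height in pixels (>= 2).
#' @param element_width Block width in pixels (default `element_height`).
#' @return Numeric image matrix with `96 * element_height` rows (fractions
#'   run down the image) and `n_samples * element_width` columns.
#' @export
render_blot <- function(scaled, element_height = 4L, element_width = element_height) {
  if (element_height < 2L) stop("render_blot: element_height must be >= 2")
  nf <- ncol(scaled)
  ns <- nrow(scaled)
  img <- matrix(0, nf * element_height, ns * element_width)
  for (s in seq_len(ns)) {
    cols <- (s - 1L) * element_width + seq_len(element_width)
    img[, cols] <- matrix(rep(scaled[s, ], each = element_height), ncol = 1L)
  }
  g <- gaussian_kernel(element_height / 2)
  img <- conv1d_reflect(img, g)
  t(conv1d_reflect(t(img), g))
}

#' Collapse fraction intensities to one value per analyte and sample
#'
#' The analyte value is the sum of intensities over its band window of
#' fractions (the molecular-weight range where the antibody's signal lives).
#'
#' @param f A `FractionMatrix`.
#' @param bands Named list mapping analyte name to an integer vector of
#'   fraction indices (within 1..96), e.g. `list(Dnmt1 = 40:52)`.
#' @return `analyte x sample` numeric matrix (pre-normalization).
#' @export
quantify_analyte <- function(f, bands) {
  stopifnot(inherits(f, "FractionMatrix"))
  analytes <- names(bands)
  if (is.null(analytes)) stop("quantify_analyte: bands must be named by analyte")
  out <- matrix(0, length(analytes), dim(f$intensities)[2],
                dimnames = list(analytes, f$design$sample))
  for (i in seq_along(bands)) {
    win <- bands[[i]]
    if (length(win) == 0L) stop("quantify_analyte: empty band window")
    if (any(win < 1L | win > 96L)) stop("quantify_analyte: band outside 1..96")
    slice <- f$intensities[analytes[i], , win, drop = FALSE]
    out[i, ] <- apply(slice, 2L, sum)
  }
  out
}

#' Normalize analyte values to a loading control and log2-transform
#'
#' `log2(value / actin)` per cell.  Zero values are lifted to a pseudo-floor
#' (default: half the smallest positive value of that analyte) before the
#' ratio, so the transform stays finite.
#'
#' @param values `analyte x sample` matrix from [quantify_analyte()].
#' @param actin Per-sample loading-control values (> 0), e.g. the beta-actin
#'   row of the same matrix.
#' @param pseudo_floor Optional fixed floor for zeros; default is derived per
#'   analyte.
#' @return `analyte x sample` matrix of log2 ratios.
#' @export
normalize_to_actin <- function(values, actin, pseudo_floor = NULL) {
  if (length(actin) != ncol(values))
    stop("normalize_to_actin: one actin value per sample required")
  if (any(actin <= 0)) stop("normalize_to_actin: actin must be > 0")
  vals <- values
  for (i in seq_len(nrow(vals))) {
    row <- vals[i, ]
    if (any(row == 0)) {
      floor_i <- if (!is.null(pseudo_floor)) pseudo_floor
      else if (any(row > 0)) min(row[row > 0]) / 2
      else stop(sprintf("normalize_to_actin: analyte %s has no positive value",
                        rownames(vals)[i]))
      row[row == 0] <- floor_i
      vals[i, ] <- row
    }
  }
  log2(sweep(vals, 2L, actin, "/"))
}

## Residual-maker matrix I - H for a model matrix.
resid_projector <- function(X) {
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  diag(nrow(X)) - tcrossprod(Q)
}

## Type-II sums of squares and F statistics for all analytes at once.
## Y: analyte x sample; M_*: residual projectors of the nested models.
anova2_F <- function(Y, M_A, M_B, M_add, M_full, df) {
  rss <- function(M) rowSums((Y %*% M)^2)
  rss_A <- rss(M_A); rss_B <- rss(M_B)
  rss_add <- rss(M_add); rss_E <- rss(M_full)
  ss_A <- pmax(rss_B - rss_add, 0)
  ss_B <- pmax(rss_A - rss_add, 0)
  ss_AB <- pmax(rss_add - rss_E, 0)
  mse <- rss_E / df$E
  total <- ss_A + ss_B + ss_AB + rss_E
  f <- function(ss, d) {
    out <- ifelse(mse > 0, (ss / d) / mse,
                  ifelse(ss / d > 0, Inf, 0))
    out[total <= .Machine$double.eps * ncol(Y)] <- 0  # constant analyte
    out
  }
  cbind(F_A = f(ss_A, df$A), F_B = f(ss_B, df$B), F_AB = f(ss_AB, df$AB))
}

#' Permutation two-factor ANOVA across analytes
#'
#' For every analyte, observed F statistics for the two main effects and the
#' interaction come from the standard two-way fixed-effects decomposition
#' (Type-II sums of squares; on a balanced design Type I/II/III coincide).
#' The null distribution is built by jointly permuting the sample labels
#' `n_perm` times -- the same permutations for every analyte, driven by
#' `seed` -- and `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so the
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param values `analyte x sample` matrix (normalized, log2), loading
#'   control excluded.
#' @param factorA,factorB Factors of length `ncol(values)` (e.g. treatment
#'   with levels serum/2i and cell type with three levels); every design cell
#'   must be observed.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation draw.
#' @return Data frame with columns `analyte`, `F_A`, `F_B`, `F_AB`, `p_A`,
#'   `p_B`, `p_AB`.
#' @export
permutation_anova2 <- function(values, factorA, factorB, n_perm = 1000L, seed = 1L) {
  values <- as.matrix(values)
  factorA <- droplevels(as.factor(factorA))
  factorB <- droplevels(as.factor(factorB))
  n <- ncol(values)
  stopifnot(length(factorA) == n, length(factorB) == n)
  if (any(table(factorA, factorB) == 0L))
    stop("permutation_anova2: empty design cell")
  if (n_perm < 100L) warning("permutation_anova2: n_perm < 100 gives coarse p-values")
  a <- nlevels(factorA); b <- nlevels(factorB)
  df <- list(A = a - 1L, B = b - 1L, AB = (a - 1L) * (b - 1L), E = n - a * b)
  if (df$E < 1L) stop("permutation_anova2: no residual degrees of freedom")
  M_A <- resid_projector(stats::model.matrix(~factorA))
  M_B <- resid_projector(stats::model.matrix(~factorB))
  M_add <- resid_projector(stats::model.matrix(~factorA + factorB))
  M_full <- resid_projector(stats::model.matrix(~factorA * factorB))
  F_obs <- anova2_F(values, M_A, M_B, M_add, M_full, df)
  exceed <- matrix(0L, nrow(values), 3L)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      idx <- sample.int(n)
      F_perm <- anova2_F(values[, idx, drop = FALSE],
                         M_A, M_B, M_add, M_full, df)
      exceed <- exceed + (F_perm >= F_obs)
    }
  })
  pvals <- (1 + exceed) / (1 + n_perm)
  analytes <- rownames(values)
  if (is.null(analytes)) analytes <- sprintf("analyte%03d", seq_len(nrow(values)))
  data.frame(analyte = analytes,
             F_A = F_obs[, "F_A"], F_B = F_obs[, "F_B"], F_AB = F_obs[, "F_AB"],
             p_A = pvals[, 1], p_B = pvals[, 2], p_AB = pvals[, 3],
             row.names = NULL)
}

#' Hierarchically cluster significant analytes
#'
#' Analytes whose smallest ANOVA p-value is at or below `alpha` are clustered
#' on their sample vectors with Euclidean distance and average linkage.
#' Input rows are pre-sorted by analyte name so the leaf order is
#' deterministic.
#'
#' @param values `analyte x sample` matrix.
#' @param p Per-analyte p-values: a numeric vector, or the data frame from
#'   [permutation_anova2()] (minimum of the three p columns is used).
#' @param alpha Significance cutoff (default 0.005).
#' @return List with `analytes` (ordered as in the dendrogram) and `tree`
#'   (an `hclust`, or NULL with a warning when fewer than two analytes are
#'   significant).
#' @export
cluster_significant <- function(values, p, alpha = 0.005) {
  values <- as.matrix(values)
  if (is.data.frame(p)) {
    pv <- stats::setNames(pmin(p$p_A, p$p_B, p$p_AB), p$analyte)
    p <- pv[rownames(values)]
  }
  stopifnot(length(p) == nrow(values))
  sig <- rownames(values)[!is.na(p) & p <= alpha]
  sig <- sort(sig)
  if (length(sig) < 2L) {
    warning("cluster_significant: fewer than 2 significant analytes; no tree")
    return(list(analytes = sig, tree = NULL))
  }
  tree <- stats::hclust(stats::dist(values[sig, , drop = FALSE],
                                    method = "euclidean"),
                        method = "average")
  list(analytes = sig[tree$order], tree = tree)
}
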