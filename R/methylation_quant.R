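## Percent methylation from bisulfite clone matrices, two-tailed
## Mann-Whitney U comparison of per-clone methylation levels, and global 5mC
## percent from HPLC peak areas.

#' Construct/validate a bisulfite clone matrix
#'
#' Rows are sequenced clones, columns CpG positions; cells are 1 (methylated),
#' 0 (unmethylated) or NA (missing data).
#'
#' @param calls Numeric/integer matrix with values in {0, 1, NA}.
#' @param amplicon_id Optional amplicon label.
#' @return A `CloneMatrix`.
#' @export
clone_matrix <- function(calls, amplicon_id = "amplicon") {
  calls <- as.matrix(calls)
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stop("clone_matrix: need >= 1 clone and >= 1 CpG")
  if (!all(calls %in% c(0, 1) | is.na(calls)))
    stop("clone_matrix: calls must be 0, 1 or NA")
  if (all(is.na(calls)))
    stop("clone_matrix: at least one non-missing call required")
  structure(list(amplicon_id = amplicon_id, calls = calls),
            class = "CloneMatrix")
}

#' @export
print.CloneMatrix <- function(x, ...) {
  cat(sprintf("CloneMatrix %s: %d clones x %d CpGs (%.1f%% missing)\n",
              x$amplicon_id, nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Percent methylated CpGs in a clone matrix
#'
#' `100 * methylated / (methylated + unmethylated)`, missing cells excluded.
#'
#' @param m A `CloneMatrix`.
#' @return Percent in [0, 100].
#' @export
percent_methylation <- function(m) {
  stopifnot(inherits(m, "CloneMatrix"))
  calls <- m$calls
  n <- sum(!is.na(calls))
  if (n == 0L) stop("percent_methylation: no non-missing calls")
  100 * sum(calls, na.rm = TRUE) / n
}

#' Per-clone methylation levels
#'
#' Fraction of methylated CpGs over the non-missing calls of each clone;
#' clones with no non-missing call are dropped with a warning.  The mean of
#' these levels weighted by per-clone non-missing counts reproduces
#' [percent_methylation()] / 100.
#'
#' @param m A `CloneMatrix`.
#' @return Named numeric vector in [0, 1], one entry per retained clone.
#' @export
clone_methylation_levels <- function(m) {
  stopifnot(inherits(m, "CloneMatrix"))
  calls <- m$calls
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("clone%03d", seq_len(nrow(calls)))
  nn <- rowSums(!is.na(calls))
  if (any(nn == 0L)) {
    warning(sprintf("clone_methylation_levels: dropped %d all-missing clone(s)",
                    sum(nn == 0L)))
    calls <- calls[nn > 0L, , drop = FALSE]
  }
  rowSums(calls, na.rm = TRUE) / rowSums(!is.na(calls))
}

#' Two-tailed Mann-Whitney U test
#'
#' U is the rank-sum statistic with midrank ties.  The two-tailed p-value is
#' exact (full enumeration of group assignments) when the combined sample
#' size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Numeric vectors (each non-empty), e.g. per-clone methylation
#'   levels of two conditions.
#' @return List with elements `U` (statistic for group `a`) and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("mann_whitney_u: empty group")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Construct HPLC peak-area input
#'
#' Absorbance peak areas for dCMP (read at 276 nm) and 5mdCMP (282 nm), with
#' the molar extinction coefficients used to convert area to molar amount
#' (defaults 8.86e3 and 9.0e3 respectively).
#'
#' @param a_dCMP,a_5mdCMP Peak areas (>= 0, not both 0).
#' @param eps_dCMP,eps_5mdCMP Extinction coefficients (> 0).
#' @return An `HplcAreas` list.
#' @export
hplc_areas <- function(a_dCMP, a_5mdCMP, eps_dCMP = 8.86e3, eps_5mdCMP = 9.0e3) {
  if (a_dCMP < 0 || a_5mdCMP < 0) stop("hplc_areas: areas must be >= 0")
  if (a_dCMP + a_5mdCMP <= 0) stop("hplc_areas: both areas are 0")
  if (eps_dCMP <= 0 || eps_5mdCMP <= 0)
    stop("hplc_areas: extinction coefficients must be > 0")
  structure(list(a_dCMP = a_dCMP, a_5mdCMP = a_5mdCMP,
                 eps_dCMP = eps_dCMP, eps_5mdCMP = eps_5mdCMP),
            class = "HplcAreas")
}

#' Global percent 5mC from HPLC peak areas
#'
#' Molar amounts are area / extinction coefficient; the result is
#' `100 * n_5mC / (n_C + n_5mC)` -- 5-methylcytosine as a percentage of all
#' cytosines, invariant to common rescaling of both areas.
#'
#' @param h An `HplcAreas` (or the peak areas via `...` passed to
#'   [hplc_areas()]).
#' @return Percent in [0, 100].
#' @export
hplc_percent_5mc <- function(h) {
  stopifnot(inherits(h, "HplcAreas"))
  n_c <- h$a_dCMP / h$eps_dCMP
  n_5mc <- h$a_5mdCMP / h$eps_5mdCMP
  100 * n_5mc / (n_c + n_5mc)
}
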