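# Nonparametric association of estimated cell fractions with phenotypes.
# Fractions are bounded in [0, 1] and typically skewed, so rank-based tests
# are used throughout: Wilcoxon signed-rank for paired designs, Wilcoxon
# rank-sum for unpaired groups, and a permutation test on the Spearman
# correlation for continuous covariates, with Benjamini-Hochberg control
# over the whole cell-type x trait grid.

assoc_row <- function(cell_type, trait, test, statistic, effect, p, z) {
  data.frame(cell_type = cell_type, trait = trait, test = test,
             statistic = statistic, effect = effect, p = p,
             p_adj = NA_real_, z_score = z, stringsAsFactors = FALSE)
}

# Standardized group separation: difference of group means over the pooled SD.
pooled_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) return(0)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Wilcoxon signed-rank test on paired fractions
#'
#' Two-sided; zero differences are dropped, the exact distribution is used
#' for small untied samples and a normal approximation with continuity
#' correction otherwise. The effect is the median paired difference `x - y`.
#'
#' @param x,y Paired numeric vectors of equal length (>= 3 non-zero
#'   differences required).
#' @param cell_type,trait Labels carried into the result row.
#' @return One-row data frame: cell_type, trait, test, statistic, effect, p,
#'   p_adj (NA until [adjust_bh()]), z_score.
#' @export
paired_test <- function(x, y, cell_type = NA_character_, trait = NA_character_) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0))
    return(assoc_row(cell_type, trait, "signed_rank", 0, 0, 1, 0))
  if (sum(d != 0) < 3L)
    stop("need >= 3 non-zero paired differences")
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  assoc_row(cell_type, trait, "signed_rank",
            unname(wt$statistic), stats::median(d), wt$p.value, pooled_z(x, y))
}

#' Wilcoxon rank-sum test on two groups of fractions
#'
#' Two-sided; exact for small untied samples, tie-corrected normal
#' approximation otherwise. The effect is the difference of group medians.
#'
#' @param x,y Numeric vectors, each of length >= 3.
#' @inheritParams paired_test
#' @return One-row association data frame (see [paired_test()]).
#' @export
unpaired_test <- function(x, y, cell_type = NA_character_, trait = NA_character_) {
  if (length(x) < 3L || length(y) < 3L)
    stop("both groups need >= 3 observations")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  assoc_row(cell_type, trait, "rank_sum",
            unname(wt$statistic), stats::median(x) - stats::median(y),
            wt$p.value, pooled_z(x, y))
}

#' Spearman permutation test for a continuous covariate
#'
#' Spearman's rho on (average-tie) ranks, with a two-sided permutation
#' p-value: `p = (#{|rho_perm| >= |rho_obs|} + 1) / (n_perm + 1)`.
#'
#' @param x Covariate (length >= 4, non-constant).
#' @param y Fractions, same length, non-constant.
#' @param n_perm Number of permutations (>= 99; default 10000).
#' @param seed Optional seed.
#' @inheritParams paired_test
#' @return One-row association data frame with `effect` = rho.
#' @export
spearman_perm <- function(x, y, n_perm = 10000L, seed = NULL,
                          cell_type = NA_character_, trait = NA_character_) {
  stopifnot(length(x) == length(y), length(x) >= 4L, n_perm >= 99L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate covariate")
  if (!is.null(seed)) set.seed(seed)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(rx)
  # all permutations at once: n x n_perm matrix of permuted covariate ranks
  perm <- matrix(rx[vapply(seq_len(n_perm), function(b) sample.int(n),
                           integer(n))], nrow = n)
  rho_perm <- drop(stats::cor(perm, ry))
  p <- (sum(abs(rho_perm) >= abs(rho) - 1e-12) + 1) / (n_perm + 1)
  assoc_row(cell_type, trait, "spearman_perm", rho, rho, p, NA_real_)
}

#' Benjamini-Hochberg adjustment over an association grid
#'
#' Step-up BH over all supplied p-values jointly; adds significance flags at
#' `alpha` for both the raw and the adjusted p-values.
#'
#' @param results Data frame with a `p` column (rows of the cell-type x trait
#'   grid).
#' @param alpha Significance level for the flags.
#' @return `results` with `p_adj`, `significant_raw`, `significant_adj`.
#' @export
adjust_bh <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), "p" %in% names(results),
            nrow(results) >= 1L)
  results$p_adj <- stats::p.adjust(results$p, method = "BH")
  results$significant_raw <- results$p < alpha
  results$significant_adj <- results$p_adj < alpha
  results
}

#' Associate estimated fractions with all phenotype traits
#'
#' Runs, for every cell type, the matching test for each requested trait:
#' grouping columns with a `pair_id` use the signed-rank test on within-pair
#' differences, other two-level groupings the rank-sum test, and numeric
#' covariates the Spearman permutation test. BH correction is applied over
#' the full grid.
#'
#' @param fractions Samples-by-cell-type matrix (or `td_deconv`).
#' @param pheno Phenotype data frame with `sample_id` and the trait columns.
#' @param group_traits Character vector of categorical trait columns.
#' @param covariate_traits Character vector of numeric trait columns.
#' @param pair_col Optional pairing column name; if given, group traits are
#'   tested paired within pairs.
#' @param n_perm,seed Passed to [spearman_perm()].
#' @return Association data frame with BH-adjusted p-values.
#' @export
associate_fractions <- function(fractions, pheno, group_traits = character(0),
                                covariate_traits = character(0),
                                pair_col = NULL, n_perm = 10000L, seed = NULL) {
  frac <- if (inherits(fractions, "td_deconv")) fractions$fractions
          else as.matrix(fractions)
  pheno <- pheno[match(rownames(frac), pheno$sample_id), , drop = FALSE]
  if (anyNA(pheno$sample_id)) stop("phenotype table missing some samples")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ct in colnames(frac)) {
    v <- frac[, ct]
    for (tr in group_traits) {
      g <- pheno[[tr]]
      lev <- sort(unique(g[!is.na(g)]))
      if (length(lev) != 2L) stop("trait '", tr, "' is not two-level")
      if (!is.null(pair_col)) {
        pid <- pheno[[pair_col]]
        keep <- !is.na(pid) & !is.na(g)
        x <- vapply(split(v[keep][g[keep] == lev[1L]],
                          pid[keep][g[keep] == lev[1L]]), mean, numeric(1))
        y <- vapply(split(v[keep][g[keep] == lev[2L]],
                          pid[keep][g[keep] == lev[2L]]), mean, numeric(1))
        common <- intersect(names(x), names(y))
        rows[[length(rows) + 1L]] <-
          paired_test(x[common], y[common], ct, tr)
      } else {
        ok <- !is.na(g)
        rows[[length(rows) + 1L]] <-
          unpaired_test(v[ok & g == lev[1L]], v[ok & g == lev[2L]], ct, tr)
      }
    }
    for (tr in covariate_traits) {
      z <- pheno[[tr]]
      ok <- !is.na(z)
      rows[[length(rows) + 1L]] <-
        spearman_perm(z[ok], v[ok], n_perm = n_perm, cell_type = ct, trait = tr)
    }
  }
  adjust_bh(do.call(rbind, rows))
}
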