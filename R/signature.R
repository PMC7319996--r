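# Signature-matrix construction: per-cell-type mean profiles, differential
# marker selection, and a condition-number-minimizing sweep over marker-set
# sizes. Lower condition number means the cell-type columns carry less
# mutually redundant information, i.e. the basis separates the types better.

#' Per-cell-type mean expression profiles
#'
#' Entry (i, j) is the arithmetic mean of linear-scale expression of feature i
#' over all reference samples labeled with cell type j.
#'
#' @param ref A `td_reference`.
#' @return Feature-by-cell-type numeric matrix.
#' @export
mean_profiles <- function(ref) {
  stopifnot(inherits(ref, "td_reference"))
  out <- vapply(ref$cell_types, function(ct) {
    cols <- ref$labels == ct
    rowMeans(ref$matrix[, cols, drop = FALSE])
  }, numeric(nrow(ref$matrix)))
  rownames(out) <- rownames(ref$matrix)
  out
}

# Row-wise Welch t statistics of group (lab == ct) against everything else.
# Cell types with a single replicate get their per-feature variance pooled
# from the residual variance of all other types (df-weighted), with a warning.
row_welch <- function(m, in_group, pooled_var = NULL) {
  x <- m[, in_group, drop = FALSE]
  y <- m[, !in_group, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- if (n1 > 1L) apply(x, 1L, stats::var) else pooled_var
  v2 <- if (n2 > 1L) apply(y, 1L, stats::var) else pooled_var
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / max(n1 - 1L, 1L) + (v2 / n2)^2 / max(n2 - 1L, 1L))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate zero-variance limit: distinct means separate perfectly
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  list(p = p, mean_in = m1, mean_out = m2)
}

# Residual variance per feature around each sample's own type mean.
residual_variance <- function(ref) {
  centered <- ref$matrix
  df <- 0L
  for (ct in ref$cell_types) {
    cols <- ref$labels == ct
    centered[, cols] <- ref$matrix[, cols, drop = FALSE] -
      rowMeans(ref$matrix[, cols, drop = FALSE])
    df <- df + sum(cols) - 1L
  }
  if (df < 1L) stop("no residual degrees of freedom in reference")
  rowSums(centered^2) / df
}

#' Differential features per cell type
#'
#' For each cell type, features are tested with a two-sided unequal-variance
#' t-test (that type's samples against all others), filtered at
#' Benjamini-Hochberg FDR `q_threshold` and fold-change `min_fold` of the
#' type's mean over the mean of the other samples, and ranked by decreasing
#' fold-change.
#'
#' @param ref A `td_reference` (linear scale).
#' @param q_threshold FDR cutoff in (0, 1]; default 0.3.
#' @param min_fold Fold-change floor (>= 1); default 1.
#' @return Named list, cell type -> character vector of ranked feature ids.
#'   Types with no passing feature contribute an empty vector (with warning).
#' @export
differential_features <- function(ref, q_threshold = 0.3, min_fold = 1) {
  stopifnot(inherits(ref, "td_reference"),
            q_threshold > 0, q_threshold <= 1, min_fold >= 1)
  sizes <- table(factor(ref$labels, levels = ref$cell_types))
  pooled <- NULL
  if (any(sizes == 1L)) {
    warning("cell type(s) with a single reference sample; pooling variance ",
            "from the other types' residuals: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "))
    pooled <- residual_variance(ref)
  }
  eps <- .Machine$double.eps
  out <- lapply(ref$cell_types, function(ct) {
    res <- row_welch(ref$matrix, ref$labels == ct, pooled)
    padj <- stats::p.adjust(res$p, method = "BH")
    fold <- res$mean_in / pmax(res$mean_out, eps)
    keep <- which(padj <= q_threshold & fold >= min_fold & res$mean_in > res$mean_out)
    if (!length(keep)) {
      warning("no differential features pass for cell type '", ct, "'")
      return(character(0))
    }
    names(sort(fold[keep], decreasing = TRUE))
  })
  names(out) <- ref$cell_types
  out
}

#' Condition number of a feature-by-type grid
#'
#' Ratio of the largest to the smallest singular value; `Inf` for
#' rank-deficient grids.
#'
#' @param values Numeric matrix with at least as many rows as columns and no
#'   all-zero column.
#' @return kappa >= 1 (or `Inf`).
#' @export
condition_number <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < ncol(values))
    stop("grid needs at least as many features as cell types")
  if (any(colSums(abs(values)) == 0)) stop("all-zero column in grid")
  d <- svd(values, nu = 0, nv = 0)$d
  tol <- max(dim(values)) * .Machine$double.eps * d[1L]
  if (d[length(d)] <= tol) return(Inf)
  d[1L] / d[length(d)]
}

#' Build a signature matrix by a condition-number sweep
#'
#' For each candidate per-type marker-set size G in `[g_min, g_max]`, the
#' union of every cell type's top-G differential features is taken, the mean
#' profile matrix is restricted to that union, and its condition number kappa
#' is computed. The G with minimal kappa wins; ties go to the smaller G
#' (more compact signature).
#'
#' @param ref A `td_reference` (linear scale).
#' @param g_min,g_max Sweep bounds for the per-type marker-set size.
#' @param q_threshold,min_fold Passed to [differential_features()].
#' @return A `td_signature`: list with `values` (features x types matrix),
#'   `feature_ids`, `cell_types`, `condition_number`, `per_type_set_size`,
#'   and `sweep` (data frame of G and kappa).
#' @export
build_signature <- function(ref, g_min = 50L, g_max = 150L,
                            q_threshold = 0.3, min_fold = 1) {
  stopifnot(g_min >= 1L, g_min <= g_max)
  feats <- differential_features(ref, q_threshold, min_fold)
  if (sum(lengths(feats) > 0L) < 2L)
    stop("differential selection succeeded for fewer than 2 cell types")
  profiles <- mean_profiles(ref)
  gs <- seq.int(g_min, g_max)
  kappas <- rep(Inf, length(gs))
  unions <- vector("list", length(gs))
  for (i in seq_along(gs)) {
    sel <- unique(unlist(lapply(feats, utils::head, gs[i]), use.names = FALSE))
    unions[[i]] <- sel
    if (length(sel) >= ncol(profiles))
      kappas[i] <- condition_number(profiles[sel, , drop = FALSE])
  }
  if (all(!is.finite(kappas)))
    stop("reference cannot separate cell types: every candidate signature is rank-deficient")
  best <- which.min(kappas)  # first minimum = smallest G
  sel <- unions[[best]]
  structure(list(values = profiles[sel, , drop = FALSE],
                 feature_ids = sel,
                 cell_types = colnames(profiles),
                 condition_number = kappas[best],
                 per_type_set_size = gs[best],
                 sweep = data.frame(G = gs, kappa = kappas),
                 q_threshold = q_threshold, min_fold = min_fold),
            class = "td_signature")
}

#' Wrap an existing feature-by-type matrix as a signature
#'
#' For signatures built elsewhere (e.g. read from TSV).
#'
#' @param values Feature-by-cell-type numeric matrix with dimnames.
#' @return A `td_signature`.
#' @export
as_signature <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("signature matrix needs feature and cell-type names")
  structure(list(values = values, feature_ids = rownames(values),
                 cell_types = colnames(values),
                 condition_number = condition_number(values),
                 per_type_set_size = NA_integer_,
                 sweep = NULL),
            class = "td_signature")
}

#' @export
print.td_signature <- function(x, ...) {
  cat(sprintf("Signature matrix: %d features x %d cell types\n",
              nrow(x$values), length(x$cell_types)))
  cat(sprintf("  condition number kappa = %.4g", x$condition_number))
  if (!is.na(x$per_type_set_size))
    cat(sprintf(" (chosen at G = %d markers/type)", x$per_type_set_size))
  cat("\n")
  invisible(x)
}

#' Read / write signature matrices as TSV
#'
#' @param path TSV with header `feature_id` + cell-type names.
#' @return `read_signature`: a `td_signature`; `write_signature`: the path.
#' @export
read_signature <- function(path) {
  as_signature(read_expression(path, format = "tsv"))
}

#' @rdname read_signature
#' @param sig A `td_signature`.
#' @export
write_signature <- function(sig, path) {
  write_expression(sig$values, path, format = "tsv")
}

#' Signature column correlations and clustering order
#'
#' Pearson correlations between signature columns, with a dendrogram from
#' average-linkage hierarchical clustering on the distance 1 - r.
#'
#' @param sig A `td_signature` with K >= 2 cell types.
#' @return A `td_sigcor`: list with `correlation` (K x K), `order` (leaf
#'   order) and `hclust`.
#' @export
signature_correlation <- function(sig) {
  stopifnot(inherits(sig, "td_signature"))
  v <- sig$values
  if (ncol(v) < 2L) stop("need at least 2 cell types")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant signature column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  r <- stats::cor(v)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(list(correlation = r, order = hc$order, hclust = hc),
            class = "td_sigcor")
}

#' @export
plot.td_sigcor <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$hclust, main = "Signature clustering (1 - r, average linkage)",
       xlab = "", sub = "")
  ord <- x$order
  graphics::image(x$correlation[ord, ord], axes = FALSE,
                  main = "Column correlations", ...)
  invisible(x)
}
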