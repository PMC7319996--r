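# Marker specificity scoring. For a mean-profile matrix g' (features x cell
# types) the primary criterion of a (gene, type) pair is the type's mean
# expression minus the largest mean in any other type: positive only for
# genes expressed above every other cell type, the property immunostaining
# markers need. The secondary criterion subtracts the mean over the other
# types instead, admitting genes shared by a few types; combinations of
# secondary markers identify types lacking a single specific marker.

#' Primary marker criterion
#'
#' `primary(i, j) = g'[i, j] - max over k != j of g'[i, k]`.
#'
#' @param profiles Feature-by-cell-type mean expression matrix (K >= 2).
#' @return Matrix of the same shape.
#' @export
primary_criterion <- function(profiles) {
  profiles <- as.matrix(profiles)
  K <- ncol(profiles)
  if (K < 2L) stop("need at least 2 cell types")
  out <- profiles
  for (j in seq_len(K)) {
    out[, j] <- profiles[, j] -
      apply(profiles[, -j, drop = FALSE], 1L, max)
  }
  out
}

#' Secondary marker criterion
#'
#' `secondary(i, j) = g'[i, j] - mean over k != j of g'[i, k]`.
#'
#' @inheritParams primary_criterion
#' @return Matrix of the same shape. Rows sum to zero across cell types.
#' @export
secondary_criterion <- function(profiles) {
  profiles <- as.matrix(profiles)
  K <- ncol(profiles)
  if (K < 2L) stop("need at least 2 cell types")
  # g - (rowSums - g) / (K - 1), vectorized over the whole grid
  (profiles - rowMeans(profiles)) * K / (K - 1)
}

#' Score all (feature, cell type) pairs
#'
#' @param ref A `td_reference`, or a precomputed mean-profile matrix.
#' @param log2_scale Score on `log2(x + 1)` of the means instead of the
#'   linear scale.
#' @return A `td_markers`: list with `primary` and `secondary` grids and the
#'   `profiles` they were computed from.
#' @export
marker_scores <- function(ref, log2_scale = FALSE) {
  profiles <- if (inherits(ref, "td_reference")) mean_profiles(ref) else as.matrix(ref)
  if (log2_scale) profiles <- log2(profiles + 1)
  structure(list(primary = primary_criterion(profiles),
                 secondary = secondary_criterion(profiles),
                 profiles = profiles),
            class = "td_markers")
}

#' @export
print.td_markers <- function(x, ...) {
  cat(sprintf("Marker scores for %d features x %d cell types\n",
              nrow(x$primary), ncol(x$primary)))
  invisible(x)
}

#' Ranked marker list for one cell type
#'
#' Features sorted by decreasing criterion value; ties broken lexicographically
#' by feature id. Negative-valued entries are flagged: a negative primary
#' criterion means some other cell type expresses the gene higher.
#'
#' @param scores A `td_markers`.
#' @param cell_type Cell type name.
#' @param criterion `"primary"` or `"secondary"`.
#' @param top_n Number of features to return (>= 1).
#' @return Data frame with `feature_id`, `score`, `rank`, `negative`.
#' @export
rank_markers <- function(scores, cell_type, criterion = c("primary", "secondary"),
                         top_n = 10L) {
  stopifnot(inherits(scores, "td_markers"), top_n >= 1L)
  criterion <- match.arg(criterion)
  grid <- scores[[criterion]]
  if (!cell_type %in% colnames(grid))
    stop("unknown cell type: ", cell_type)
  v <- grid[, cell_type]
  ord <- order(-v, rownames(grid))
  top <- utils::head(ord, top_n)
  data.frame(feature_id = rownames(grid)[top],
             score = unname(v[top]),
             rank = seq_along(top),
             negative = unname(v[top] < 0),
             stringsAsFactors = FALSE)
}

#' Full marker report across all cell types
#'
#' One row per (feature, cell type) pair with both criteria and within-type
#' ranks under each.
#'
#' @param scores A `td_markers`.
#' @return Data frame: `feature_id`, `cell_type`, `crit_primary`,
#'   `crit_secondary`, `rank_primary`, `rank_secondary`, `negative_primary`.
#' @export
marker_report <- function(scores) {
  stopifnot(inherits(scores, "td_markers"))
  feats <- rownames(scores$primary)
  do.call(rbind, lapply(colnames(scores$primary), function(ct) {
    p <- scores$primary[, ct]; s <- scores$secondary[, ct]
    data.frame(feature_id = feats, cell_type = ct,
               crit_primary = unname(p), crit_secondary = unname(s),
               rank_primary = order(order(-p, feats)),
               rank_secondary = order(order(-s, feats)),
               negative_primary = unname(p < 0),
               stringsAsFactors = FALSE)
  }))
}

#' Merge cell-type labels in a reference
#'
#' Relabels reference samples under a total map of old to new type names, so
#' marker criteria can be recomputed on coarser groups (e.g. pooling the
#' adipocyte depots to score pan-adipocyte markers rather than depot-specific
#' ones).
#'
#' @param ref A `td_reference`.
#' @param merge_map Named character vector, old type -> new type, covering
#'   every cell type in `ref`.
#' @return A `td_reference` with merged labels (>= 2 resulting types).
#' @export
merge_groups <- function(ref, merge_map) {
  stopifnot(inherits(ref, "td_reference"))
  miss <- setdiff(ref$cell_types, names(merge_map))
  if (length(miss))
    stop("merge map does not cover: ", paste(miss, collapse = ", "))
  new_labels <- stats::setNames(unname(merge_map[ref$labels]), names(ref$labels))
  if (length(unique(new_labels)) < 2L)
    stop("merging would leave fewer than 2 cell types")
  reference_set(ref$matrix, new_labels)
}
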