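# nu-SVR deconvolution. A bulk mixture profile is modeled as a non-negative
# weighted sum of the signature matrix columns. The weights are estimated by
# linear-kernel nu-support-vector regression of the standardized mixture on
# the standardized signature; nu controls the fraction of support vectors and
# is chosen from a small grid by reconstruction RMSE. Negative coefficients
# are clipped to zero and the remainder renormalized to sum to one, giving
# relative cell-type fractions.

svr_weights <- function(X, y, nu, cost) {
  fit <- e1071::svm(X, y, type = "nu-regression", kernel = "linear",
                    nu = nu, cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  stats::setNames(as.numeric(w), colnames(X))
}

deconvolve_one <- function(y, X, nus, cost) {
  best <- NULL
  for (nu in nus) {
    w <- svr_weights(X, y, nu, cost)
    w[w < 0] <- 0
    if (sum(w) == 0) next
    f <- w / sum(w)
    recon <- drop(X %*% f)
    rmse <- sqrt(mean((y - recon)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(fractions = f, nu = nu, rmse = rmse,
                   r = stats::cor(y, recon))
  }
  if (is.null(best))
    stop("no admissible composition: all coefficients non-positive")
  best
}

# Restrict mixture and signature to shared features and standardize:
# the signature over all of its entries jointly, the mixture over its own.
standardize_pair <- function(mix, sig, min_overlap = 0.5) {
  shared <- intersect(names(mix), rownames(sig$values))
  need <- ceiling(min_overlap * nrow(sig$values))
  if (length(shared) < need)
    stop(sprintf("feature overlap too low: %d of %d signature features present (need >= %d)",
                 length(shared), nrow(sig$values), need))
  X <- sig$values[shared, , drop = FALSE]
  X <- (X - mean(X)) / stats::sd(X)
  y <- mix[shared]
  if (stats::sd(y) == 0) stop("constant mixture profile")
  y <- (y - mean(y)) / stats::sd(y)
  list(X = X, y = y)
}

#' Deconvolve one bulk mixture profile
#'
#' @param mix Named numeric vector of linear-scale expression (names are
#'   feature ids). At least half of the signature's features must be present.
#' @param sig A `td_signature`.
#' @param nus Grid of nu values for the nu-SVR; the fit with the smallest
#'   reconstruction RMSE is kept.
#' @param cost SVR regularization constant.
#' @param n_perm Permutations for the empirical fit p-value (0 disables).
#' @param seed Optional seed for the permutation test.
#' @return List with `fractions` (named, non-negative, summing to 1),
#'   `nu`, `rmse`, `r` and `pvalue` (NA if `n_perm == 0`).
#' @export
deconvolve_sample <- function(mix, sig, nus = c(0.25, 0.5, 0.75), cost = 1,
                              n_perm = 0L, seed = NULL) {
  stopifnot(inherits(sig, "td_signature"))
  sp <- standardize_pair(mix, sig)
  best <- deconvolve_one(sp$y, sp$X, nus, cost)
  best$pvalue <- if (n_perm > 0L)
    fit_pvalue(best, sp$X, sp$y, nus = nus, cost = cost,
               n_perm = n_perm, seed = seed)
  else NA_real_
  best
}

#' Permutation p-value for a deconvolution fit
#'
#' The mixture's values are permuted across features `n_perm` times, each
#' permutation is deconvolved, and the p-value is the fraction of permutations
#' whose reconstruction correlation reaches the observed one:
#' `p = (# r_perm >= r_obs + 1) / (n_perm + 1)`.
#'
#' @param est Result of a single-sample fit (needs element `r`).
#' @param X,y Standardized signature and mixture used for the fit.
#' @param nus,cost As in [deconvolve_sample()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional seed.
#' @return Empirical p-value in (0, 1].
#' @export
fit_pvalue <- function(est, X, y, nus = c(0.25, 0.5, 0.75), cost = 1,
                       n_perm = 99L, seed = NULL) {
  stopifnot(n_perm >= 1L)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    rp <- tryCatch(deconvolve_one(sample(y), X, nus, cost)$r,
                   error = function(e) -Inf)
    if (rp >= est$r) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' Deconvolve a dataset of bulk mixtures
#'
#' Applies [deconvolve_sample()] to every column of a mixture matrix.
#' Per-sample failures are collected and reported as warnings, not errors;
#' the fit fails only if no sample succeeds.
#'
#' @param mixtures Feature-by-sample matrix of linear-scale expression.
#' @param sig A `td_signature`.
#' @inheritParams deconvolve_sample
#' @return A `td_deconv` object: list with `fractions` (samples x cell types,
#'   rows summing to 1), `diagnostics` (data frame of nu, RMSE, correlation,
#'   p-value per sample), `failed` (named character vector of error messages),
#'   `cell_types` and the call.
#' @export
deconvolve <- function(mixtures, sig, nus = c(0.25, 0.5, 0.75), cost = 1,
                       n_perm = 0L, seed = NULL) {
  stopifnot(inherits(sig, "td_signature"))
  mixtures <- as.matrix(mixtures)
  if (is.null(colnames(mixtures)))
    colnames(mixtures) <- paste0("sample_", seq_len(ncol(mixtures)))
  if (!is.null(seed)) set.seed(seed)
  fits <- vector("list", ncol(mixtures))
  ok <- logical(ncol(mixtures))
  errs <- character(0)
  for (i in seq_len(ncol(mixtures))) {
    res <- tryCatch(
      deconvolve_sample(mixtures[, i], sig, nus = nus, cost = cost,
                        n_perm = n_perm),
      error = function(e) e)
    if (inherits(res, "error")) {
      errs[colnames(mixtures)[i]] <- conditionMessage(res)
    } else {
      fits[[i]] <- res
      ok[i] <- TRUE
    }
  }
  if (!any(ok))
    stop("deconvolution failed for every sample; first error: ", errs[1L])
  if (length(errs))
    warning("deconvolution failed for ", length(errs), " sample(s): ",
            paste(names(errs), collapse = ", "))
  frac <- t(vapply(fits[ok], `[[`, numeric(length(sig$cell_types)), "fractions"))
  rownames(frac) <- colnames(mixtures)[ok]
  diag <- data.frame(
    sample_id = rownames(frac),
    nu = vapply(fits[ok], `[[`, numeric(1), "nu"),
    rmse = vapply(fits[ok], `[[`, numeric(1), "rmse"),
    correlation = vapply(fits[ok], `[[`, numeric(1), "r"),
    pvalue = vapply(fits[ok], `[[`, numeric(1), "pvalue"),
    stringsAsFactors = FALSE)
  structure(list(fractions = frac, diagnostics = diag, failed = errs,
                 cell_types = sig$cell_types, call = match.call()),
            class = "td_deconv")
}

#' @export
print.td_deconv <- function(x, ...) {
  cat(sprintf("Cell-type deconvolution of %d sample(s), %d cell types\n",
              nrow(x$fractions), length(x$cell_types)))
  if (length(x$failed))
    cat(sprintf("  (%d sample(s) failed)\n", length(x$failed)))
  cat(sprintf("  median reconstruction r = %.3f, median RMSE = %.3f\n",
              stats::median(x$diagnostics$correlation),
              stats::median(x$diagnostics$rmse)))
  invisible(x)
}

#' @export
summary.td_deconv <- function(object, ...) {
  s <- data.frame(
    cell_type = colnames(object$fractions),
    mean = colMeans(object$fractions),
    median = apply(object$fractions, 2L, stats::median),
    q25 = apply(object$fractions, 2L, stats::quantile, 0.25),
    q75 = apply(object$fractions, 2L, stats::quantile, 0.75),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = s, n = nrow(object$fractions),
                 failed = length(object$failed)),
            class = "summary.td_deconv")
}

#' @export
print.summary.td_deconv <- function(x, ...) {
  cat(sprintf("Estimated cell-type fractions over %d sample(s):\n", x$n))
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
coef.td_deconv <- function(object, ...) object$fractions

#' @export
plot.td_deconv <- function(x, max_samples = 40L, ...) {
  f <- t(x$fractions)
  if (ncol(f) > max_samples) f <- f[, seq_len(max_samples), drop = FALSE]
  graphics::barplot(f, col = grDevices::hcl.colors(nrow(f), "Spectral"),
                    las = 2, ylab = "estimated fraction",
                    legend.text = rownames(f),
                    args.legend = list(x = "topright", cex = 0.6, bg = "white"),
                    ...)
  invisible(x)
}

#' Write estimated fractions as TSV
#'
#' One row per sample: cell-type columns plus `P-value`, `Correlation`,
#' `RMSE`, sorted by sample id.
#'
#' @param fit A `td_deconv`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fractions <- function(fit, path) {
  stopifnot(inherits(fit, "td_deconv"))
  ord <- order(rownames(fit$fractions))
  df <- data.frame(sample_id = rownames(fit$fractions)[ord],
                   fit$fractions[ord, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[["P-value"]] <- fit$diagnostics$pvalue[ord]
  df[["Correlation"]] <- fit$diagnostics$correlation[ord]
  df[["RMSE"]] <- fit$diagnostics$rmse[ord]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Roll cell-type fractions up to archetypes
#'
#' Sums the fractions of all member cell types of each archetype; the total
#' of 1 per sample is preserved.
#'
#' @param est A `td_deconv`, or a samples-by-cell-type fraction matrix.
#' @param mapping Named character vector, cell type -> archetype, covering
#'   every cell type present.
#' @return Samples-by-archetype matrix (archetypes in first-appearance order
#'   of `mapping`).
#' @export
aggregate_archetypes <- function(est, mapping = at21_archetypes()) {
  frac <- if (inherits(est, "td_deconv")) est$fractions else as.matrix(est)
  miss <- setdiff(colnames(frac), names(mapping))
  if (length(miss))
    stop("unmapped cell type(s): ", paste(miss, collapse = ", "))
  arch <- unname(mapping[colnames(frac)])
  lev <- unique(unname(mapping))
  lev <- lev[lev %in% arch]
  out <- t(rowsum(t(frac), group = factor(arch, levels = lev)))
  out[, lev, drop = FALSE]
}

#' Default 21-type-to-archetype mapping
#'
#' The four archetypes of the adipose-tissue reference: 12 immune cell types
#' (platelets and erythroblasts are grouped with the blood lineage), 2
#' stem/stromal, 2 adipocyte depots, and 5 other structural types.
#'
#' @return Named character vector, cell type -> archetype.
#' @export
at21_archetypes <- function() {
  c(B_cells = "immune", CD4_T_cells = "immune", CD8_T_cells = "immune",
    NK_cells = "immune", monocytes = "immune", macrophages = "immune",
    myeloid_dendritic_cells = "immune", plasmacytoid_dendritic_cells = "immune",
    eosinophils = "immune", neutrophils = "immune", platelets = "immune",
    erythroblasts = "immune",
    ASC = "stem_stromal", MSC = "stem_stromal",
    adipocytes_SAT = "adipocyte", adipocytes_PAT = "adipocyte",
    endothelial_cells = "other", fibroblasts = "other",
    smooth_muscle_cells = "other", chondrocytes = "other",
    osteoblasts = "other")
}
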