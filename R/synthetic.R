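# Synthetic reference sets, bulk mixtures and phenotype designs with known
# ground truth. Baseline expression is log-normal (positive, right-skewed,
# like linear-scale microarray/RNA-Seq intensities); each cell type gets a
# disjoint block of planted marker features whose expression is multiplied
# by a fold-change; replicates and mixtures are perturbed by multiplicative
# log-normal noise parameterized by its coefficient of variation. Mixture
# fraction vectors are drawn from a Dirichlet distribution; for the default
# 4-type configuration the Dirichlet mean matches the average archetype
# composition of subcutaneous adipose tissue (74% adipocytes, 14.9%
# stem/stromal, 7.4% immune, 3.7% other).

#' Simulation configuration
#'
#' @param n_features Number of features.
#' @param n_types Number of cell types K.
#' @param markers_per_type Planted markers per type
#'   (`markers_per_type * n_types <= n_features`).
#' @param marker_effect Fold-change of a planted marker in its own type (> 1).
#' @param replicates_per_type Reference samples per type.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise (>= 0).
#' @param dirichlet_alpha Length-K positive Dirichlet weights for mixture
#'   fractions; default: proportional to the subcutaneous-adipose archetype
#'   composition when K = 4 (concentration 10), flat otherwise.
#' @param n_mixtures Number of bulk mixtures.
#' @param seed Integer seed; all generators are reproducible under it.
#' @return A validated `td_simconfig` list.
#' @export
sim_config <- function(n_features = 400L, n_types = 4L, markers_per_type = 10L,
                       marker_effect = 8, replicates_per_type = 5L,
                       noise_cv = 0.05, dirichlet_alpha = NULL,
                       n_mixtures = 50L, seed = 1L) {
  if (is.null(dirichlet_alpha)) {
    dirichlet_alpha <- if (n_types == 4L)
      10 * c(0.740, 0.149, 0.074, 0.037)
    else rep(1, n_types)
  }
  cfg <- list(n_features = as.integer(n_features),
              n_types = as.integer(n_types),
              markers_per_type = as.integer(markers_per_type),
              marker_effect = marker_effect,
              replicates_per_type = as.integer(replicates_per_type),
              noise_cv = noise_cv,
              dirichlet_alpha = dirichlet_alpha,
              n_mixtures = as.integer(n_mixtures),
              seed = as.integer(seed))
  with(cfg, {
    if (markers_per_type * n_types > n_features)
      stop("markers_per_type * n_types must be <= n_features")
    stopifnot(n_types >= 2L, marker_effect > 1, replicates_per_type >= 1L,
              noise_cv >= 0, length(dirichlet_alpha) == n_types,
              all(dirichlet_alpha > 0), n_mixtures >= 1L)
  })
  structure(cfg, class = "td_simconfig")
}

sim_type_names <- function(cfg) {
  if (cfg$n_types == 4L && isTRUE(all.equal(cfg$dirichlet_alpha,
                                            10 * c(0.740, 0.149, 0.074, 0.037))))
    c("adipocyte", "stem_stromal", "immune", "other")
  else paste0("type_", seq_len(cfg$n_types))
}

# Multiplicative log-normal noise with unit mean and the given CV.
mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a labeled reference set with planted markers
#'
#' @param cfg A [sim_config()].
#' @return List: `ref` (a `td_reference`), `profiles` (true noise-free
#'   feature-by-type means), `truth` (data frame `feature_id`, `cell_type`
#'   of the planted markers).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "td_simconfig"))
  set.seed(cfg$seed)
  types <- sim_type_names(cfg)
  feats <- sprintf("gene_%04d", seq_len(cfg$n_features))
  baseline <- stats::rlnorm(cfg$n_features, meanlog = log(100), sdlog = 1)
  profiles <- matrix(baseline, cfg$n_features, cfg$n_types,
                     dimnames = list(feats, types))
  truth <- data.frame(feature_id = character(0), cell_type = character(0),
                      stringsAsFactors = FALSE)
  for (j in seq_len(cfg$n_types)) {
    idx <- (j - 1L) * cfg$markers_per_type + seq_len(cfg$markers_per_type)
    profiles[idx, j] <- profiles[idx, j] * cfg$marker_effect
    truth <- rbind(truth, data.frame(feature_id = feats[idx],
                                     cell_type = types[j],
                                     stringsAsFactors = FALSE))
  }
  n_samp <- cfg$n_types * cfg$replicates_per_type
  m <- matrix(NA_real_, cfg$n_features, n_samp, dimnames = list(feats, NULL))
  labels <- character(n_samp)
  ids <- character(n_samp)
  k <- 0L
  for (j in seq_len(cfg$n_types)) {
    for (r in seq_len(cfg$replicates_per_type)) {
      k <- k + 1L
      m[, k] <- profiles[, j] * mult_noise(cfg$n_features, cfg$noise_cv)
      labels[k] <- types[j]
      ids[k] <- sprintf("%s_rep%d", types[j], r)
    }
  }
  colnames(m) <- ids
  list(ref = reference_set(m, stats::setNames(labels, ids)),
       profiles = profiles, truth = truth)
}

#' Simulate bulk mixtures from known fractions
#'
#' Each mixture is the profile matrix times a fraction vector drawn from
#' `Dirichlet(dirichlet_alpha)`, perturbed entrywise by multiplicative
#' log-normal noise with CV `noise_cv`.
#'
#' @param profiles Feature-by-type matrix of true cell-type mean profiles.
#' @param cfg A [sim_config()].
#' @return List: `mixtures` (feature-by-sample matrix), `fractions`
#'   (samples-by-type matrix of true fractions, rows summing to 1).
#' @export
simulate_mixtures <- function(profiles, cfg) {
  stopifnot(inherits(cfg, "td_simconfig"),
            ncol(profiles) == cfg$n_types)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_mixtures
  g <- matrix(stats::rgamma(n * cfg$n_types, shape = cfg$dirichlet_alpha),
              nrow = cfg$n_types)
  f <- t(g) / colSums(g)  # n x K, rows sum to 1
  colnames(f) <- colnames(profiles)
  rownames(f) <- sprintf("mix_%03d", seq_len(n))
  m <- profiles %*% t(f)
  noise <- matrix(mult_noise(length(m), cfg$noise_cv), nrow(m), ncol(m))
  m <- m * noise
  colnames(m) <- rownames(f)
  list(mixtures = m, fractions = f)
}

#' Simulate a phenotype design over known fractions
#'
#' Assigns samples to two groups (or pairs) and shifts the specified cell
#' types' true fractions in group B (or in the second member of each pair) by
#' the given additive effects, renormalizing rows to sum to 1. With no
#' effects the design is null-calibrated.
#'
#' @param fractions Samples-by-type matrix of true fractions.
#' @param effects Named numeric vector, cell type -> additive shift on the
#'   fraction scale (may be empty).
#' @param paired If `TRUE`, each sample becomes a pair (two pseudo-samples
#'   sharing a `pair_id`) with the shift applied within pairs.
#' @param seed Integer seed.
#' @return List: `pheno` (data frame `sample_id`, `group`, `pair_id`),
#'   `fractions` (possibly expanded/shifted matrix aligned to `pheno`).
#' @export
simulate_phenotypes <- function(fractions, effects = numeric(0),
                                paired = FALSE, seed = 1L) {
  fractions <- as.matrix(fractions)
  bad <- setdiff(names(effects), colnames(fractions))
  if (length(bad)) stop("effects name unknown cell type(s): ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  shift <- function(f) {
    f[, names(effects)] <- pmax(f[, names(effects), drop = FALSE] +
                                  rep(effects, each = nrow(f)), 0)
    f / rowSums(f)
  }
  if (paired) {
    n <- nrow(fractions)
    a <- fractions
    b <- shift(fractions)
    rownames(a) <- sprintf("subj%03d_A", seq_len(n))
    rownames(b) <- sprintf("subj%03d_B", seq_len(n))
    pheno <- data.frame(
      sample_id = c(rownames(a), rownames(b)),
      group = rep(c("A", "B"), each = n),
      pair_id = rep(sprintf("pair%03d", seq_len(n)), 2L),
      stringsAsFactors = FALSE)
    list(pheno = pheno, fractions = rbind(a, b))
  } else {
    n <- nrow(fractions)
    grp <- sample(rep(c("A", "B"), length.out = n))
    f <- fractions
    f[grp == "B", ] <- shift(fractions[grp == "B", , drop = FALSE])
    pheno <- data.frame(sample_id = rownames(fractions), group = grp,
                        pair_id = NA_character_, stringsAsFactors = FALSE)
    list(pheno = pheno, fractions = f)
  }
}
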