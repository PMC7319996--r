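# Shared small synthetic system for the deconvolution tests.
dc_setup <- function(seed = 42, n_mixtures = 20, cv = 0.05, n_types = 4) {
  cfg <- sim_config(n_features = 200, n_types = n_types, markers_per_type = 8,
                    marker_effect = 8, replicates_per_type = 4, noise_cv = cv,
                    dirichlet_alpha = rep(1, n_types),
                    n_mixtures = n_mixtures, seed = seed)
  sim <- simulate_reference(cfg)
  sig <- build_signature(sim$ref, g_min = 4, g_max = 10)
  list(cfg = cfg, sim = sim, sig = sig)
}

test_that("a pure signature column deconvolves to its own type", {
  s <- dc_setup()
  for (ct in s$sig$cell_types) {
    est <- deconvolve_sample(s$sig$values[, ct], s$sig)
    expect_gte(est$fractions[ct], 0.99)
    expect_true(all(est$fractions[setdiff(s$sig$cell_types, ct)] <= 0.01))
  }
})

test_that("a symmetric two-type mixture recovers (0.5, 0.5)", {
  s <- dc_setup()
  mix <- 0.5 * s$sig$values[, 1] + 0.5 * s$sig$values[, 2]
  est <- deconvolve_sample(mix, s$sig)
  expect_equal(unname(est$fractions[1]), 0.5, tolerance = 0.02)
  expect_equal(unname(est$fractions[2]), 0.5, tolerance = 0.02)
})

test_that("fractions are non-negative, sum to one, and are scale invariant", {
  s <- dc_setup(seed = 7, n_mixtures = 10)
  mix <- simulate_mixtures(s$sim$profiles, s$cfg)
  fit <- deconvolve(mix$mixtures, s$sig)
  f <- coef(fit)
  expect_true(all(f >= 0))
  expect_equal(unname(rowSums(f)), rep(1, nrow(f)), tolerance = 1e-9)
  # multiplying a mixture by a positive constant changes nothing
  est1 <- deconvolve_sample(mix$mixtures[, 1], s$sig)
  est2 <- deconvolve_sample(1234 * mix$mixtures[, 1], s$sig)
  # identical up to the SMO solver's numerical tolerance
  expect_equal(est1$fractions, est2$fractions, tolerance = 1e-3)
})

test_that("recovery degrades monotonically as noise grows from zero", {
  errs <- vapply(c(0, 0.1, 0.6), function(cv) {
    # at high noise some types may legitimately lose all their markers
    s <- suppressWarnings(dc_setup(seed = 5, n_mixtures = 12, cv = cv))
    mix <- simulate_mixtures(s$sim$profiles, s$cfg)
    fit <- deconvolve(mix$mixtures, s$sig)
    mean(abs(coef(fit) - mix$fractions))
  }, numeric(1))
  expect_lt(errs[1], 0.01)  # noiseless: near-exact recovery
  expect_true(all(diff(errs) > 0))
})

test_that("estimates agree with an NNLS-then-normalize oracle", {
  skip_if_not_installed("pracma")
  s <- dc_setup(seed = 11, n_mixtures = 15)
  mix <- simulate_mixtures(s$sim$profiles, s$cfg)
  fit <- deconvolve(mix$mixtures, s$sig)
  for (i in seq_len(ncol(mix$mixtures))) {
    y <- mix$mixtures[, i]
    sh <- intersect(names(y), rownames(s$sig$values))
    X <- s$sig$values[sh, ]
    Xs <- (X - mean(X)) / sd(X)
    ys <- (y[sh] - mean(y[sh])) / sd(y[sh])
    w <- pracma::lsqnonneg(Xs, ys)$x
    w <- w / sum(w)
    expect_lt(max(abs(w - coef(fit)[i, ])), 0.05)
  }
})

test_that("feature overlap below half the signature is an error", {
  s <- dc_setup()
  mix <- s$sig$values[, 1]
  few <- mix[seq_len(floor(0.4 * length(mix)))]
  expect_error(deconvolve_sample(few, s$sig), "overlap too low")
  # empty intersection at dataset level
  bad <- matrix(1:4, 2, 2, dimnames = list(c("x1", "x2"), c("s1", "s2")))
  expect_error(suppressWarnings(deconvolve(bad, s$sig)), "overlap")
})

test_that("per-sample failures are reported, not fatal", {
  s <- dc_setup()
  good <- s$sig$values[, 1]
  flat <- setNames(rep(1, length(good)), names(good))  # constant profile
  mm <- cbind(ok = good, bad = flat)
  expect_warning(fit <- deconvolve(mm, s$sig), "failed for 1")
  expect_identical(rownames(coef(fit)), "ok")
  expect_identical(names(fit$failed), "bad")
})

test_that("self-deconvolution assigns each sample its own type", {
  s <- dc_setup(seed = 3)
  fit <- deconvolve(s$sim$ref$matrix, s$sig)
  top <- colnames(coef(fit))[apply(coef(fit), 1, which.max)]
  expect_identical(top, unname(s$sim$ref$labels))
})

test_that("permutation p-values behave at both extremes", {
  s <- dc_setup()
  est <- deconvolve_sample(s$sig$values[, 1], s$sig, n_perm = 99, seed = 1)
  expect_equal(est$pvalue, 1 / 100)  # perfect reconstruction
  est0 <- deconvolve_sample(s$sig$values[, 2], s$sig, n_perm = 0)
  expect_true(is.na(est0$pvalue))  # disabled
  set.seed(3)
  noise <- setNames(rlnorm(nrow(s$sig$values)), rownames(s$sig$values))
  estn <- deconvolve_sample(noise, s$sig, n_perm = 99, seed = 2)
  expect_gte(estn$pvalue, 0.05)
})

test_that("archetype aggregation sums member fractions and preserves totals", {
  # uniform 1/21 over the default mapping reproduces the archetype counts
  map <- at21_archetypes()
  u <- matrix(1 / 21, 1, 21, dimnames = list("s1", names(map)))
  agg <- aggregate_archetypes(u, map)
  expect_equal(unname(agg[1, c("immune", "stem_stromal", "adipocyte", "other")]),
               c(12, 2, 2, 5) / 21)
  # one-hot on an immune member
  oh <- matrix(0, 1, 21, dimnames = list("s1", names(map)))
  oh[1, "macrophages"] <- 1
  expect_equal(unname(aggregate_archetypes(oh, map)[1, "immune"]), 1)
  # random fractions: equals brute-force grouping, rows still sum to 1
  set.seed(12)
  f <- matrix(rexp(5 * 21), 5, 21, dimnames = list(paste0("s", 1:5), names(map)))
  f <- f / rowSums(f)
  agg2 <- aggregate_archetypes(f, map)
  expect_equal(unname(rowSums(agg2)), rep(1, 5), tolerance = 1e-9)
  for (a in unique(map))
    expect_equal(agg2[, a], rowSums(f[, names(map)[map == a], drop = FALSE]))
  expect_error(aggregate_archetypes(cbind(f, extra = 0), map),
               "unmapped.*extra")
})

test_that("fraction TSVs carry diagnostics and sort by sample id", {
  s <- dc_setup(seed = 9, n_mixtures = 5)
  mix <- simulate_mixtures(s$sim$profiles, s$cfg)
  colnames(mix$mixtures) <- rev(colnames(mix$mixtures))  # unsorted on purpose
  fit <- deconvolve(mix$mixtures, s$sig)
  path <- tempfile(fileext = ".tsv")
  write_fractions(fit, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_identical(tab$sample_id, sort(rownames(coef(fit))))
  expect_true(all(c("P-value", "Correlation", "RMSE") %in% names(tab)))
})
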