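test_that("mean profiles equal brute-force per-type means", {
  set.seed(3)
  m <- matrix(rexp(60, 0.01), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  labels <- setNames(c("A", "A", "B", "B", "B", "C"), colnames(m))
  ref <- reference_set(m, labels)
  prof <- mean_profiles(ref)
  for (ct in c("A", "B", "C")) for (i in 1:10)
    expect_equal(prof[i, ct], mean(m[i, labels == ct]))
  # single-sample type: column equals that sample
  expect_equal(unname(prof[, "C"]), unname(m[, 6]))
  # two samples 1 and 3 -> mean 2
  m2 <- matrix(c(1, 5, 3, 7), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ref2 <- tryCatch(reference_set(m2, c(s1 = "A", s2 = "A")), error = identity)
  expect_s3_class(ref2, "error")  # needs 2 types; test the mean on 2x types
  m3 <- cbind(m2, s3 = c(10, 10))
  prof3 <- mean_profiles(reference_set(m3, c(s1 = "A", s2 = "A", s3 = "B")))
  expect_equal(unname(prof3["g1", "A"]), 2)
})

test_that("differential selection recovers planted markers and drops flat genes", {
  sim <- tiny_reference(n_features = 200, n_types = 4, markers = 10,
                        effect = 10, reps = 4, cv = 0.05, seed = 7)
  ref <- sim$ref
  # add a constant feature: must never be selected
  flat <- matrix(50, 1, ncol(ref$matrix),
                 dimnames = list("flatgene", colnames(ref$matrix)))
  ref2 <- reference_set(rbind(ref$matrix, flat), ref$labels)
  feats <- differential_features(ref2, q_threshold = 0.3, min_fold = 2)
  for (ct in ref2$cell_types) {
    planted <- sim$truth$feature_id[sim$truth$cell_type == ct]
    expect_true(all(planted %in% head(feats[[ct]], 10)),
                label = paste("planted markers top-10 for", ct))
    expect_false("flatgene" %in% feats[[ct]])
  }
})

test_that("a dominant marker ranks first for its type", {
  m <- matrix(1, 20, 6, dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  set.seed(1); m <- m + matrix(runif(120, 0, 0.05), 20, 6)
  m["g5", 1:3] <- c(99, 100, 101)
  ref <- reference_set(m, setNames(rep(c("A", "B"), each = 3), colnames(m)))
  # B has no upregulated feature, which warns and yields an empty list
  expect_warning(feats <- differential_features(ref), "no differential features")
  expect_identical(feats$A[1], "g5")
  expect_length(feats$B, 0)
})

test_that("single-replicate types fall back to pooled variance with a warning", {
  sim <- tiny_reference(n_features = 80, n_types = 3, markers = 5,
                        effect = 10, reps = 3, cv = 0.05, seed = 5)
  keep <- colnames(sim$ref$matrix)[-(1:2)]  # leave one replicate of type_1
  ref1 <- reference_set(sim$ref$matrix[, keep], sim$ref$labels[keep])
  expect_warning(feats <- differential_features(ref1), "single reference sample")
  expect_gt(length(feats$type_1), 0)
})

test_that("condition number matches SVD and handles degenerate grids", {
  expect_equal(condition_number(diag(5)), 1)
  expect_equal(condition_number(diag(c(1, 2))), 2)
  set.seed(21)
  g <- matrix(rexp(250), 50, 5)
  d <- svd(g)$d
  expect_equal(condition_number(g), max(d) / min(d))
  # invariant to global positive scaling
  expect_equal(condition_number(3.7 * g), condition_number(g))
  # rank-deficient: duplicated column
  expect_identical(condition_number(cbind(g, g[, 1])), Inf)
  expect_error(condition_number(matrix(1, 2, 3)), "at least as many")
  expect_error(condition_number(cbind(g[, 1], 0)), "all-zero")
})

test_that("the kappa sweep picks the minimum and prefers smaller G on ties", {
  sim <- tiny_reference(n_features = 200, n_types = 4, markers = 10,
                        effect = 8, reps = 4, cv = 0.05, seed = 13)
  sig <- build_signature(sim$ref, g_min = 4, g_max = 12)
  expect_s3_class(sig, "td_signature")
  expect_true(all(sig$condition_number <= sig$sweep$kappa + 1e-12))
  expect_identical(sig$per_type_set_size,
                   sig$sweep$G[which.min(sig$sweep$kappa)])
  # every planted marker set is represented among selected features
  sel_types <- unique(sim$truth$cell_type[sim$truth$feature_id %in% sig$feature_ids])
  expect_setequal(sel_types, sim$ref$cell_types)
  # degenerate single-point sweep
  sig1 <- build_signature(sim$ref, g_min = 6, g_max = 6)
  expect_identical(sig1$per_type_set_size, 6L)
  expect_identical(nrow(sig1$sweep), 1L)
})

test_that("duplicating a cell type under a new label drives kappa to infinity", {
  sim <- tiny_reference(n_features = 120, n_types = 3, markers = 6,
                        effect = 10, reps = 3, cv = 0, seed = 2)
  m <- sim$ref$matrix
  dup <- m[, sim$ref$labels == "type_1", drop = FALSE]
  colnames(dup) <- paste0(colnames(dup), "_copy")
  labels <- c(sim$ref$labels, setNames(rep("type_1_copy", ncol(dup)), colnames(dup)))
  ref <- reference_set(cbind(m, dup), labels)
  expect_error(build_signature(ref, g_min = 4, g_max = 8),
               "cannot separate")
})

test_that("signature restricted to one type's markers is near-zero elsewhere", {
  # noiseless disjoint markers on a tiny baseline
  profiles <- matrix(0.01, 30, 3,
                     dimnames = list(paste0("g", 1:30), c("A", "B", "C")))
  for (j in 1:3) profiles[(j - 1) * 10 + 1:10, j] <- 100
  sig <- as_signature(profiles)
  a_markers <- paste0("g", 1:10)
  expect_true(all(sig$values[a_markers, c("B", "C")] < 1))
  expect_true(all(sig$values[a_markers, "A"] > 99))
})

test_that("signature correlation clusters related types together", {
  const_col <- matrix(c(1, 1, 1, 1, 2, 3), 3, 2,
                      dimnames = list(paste0("g", 1:3), c("A", "B")))
  expect_error(signature_correlation(as_signature(const_col)), "constant")
  # duplicate columns: r = 1 and merged first
  set.seed(4)
  v <- matrix(rexp(40), 10, 4, dimnames = list(paste0("g", 1:10),
                                               c("A", "A2", "B", "C")))
  v[, "A2"] <- v[, "A"]
  sc <- signature_correlation(as_signature(v))
  expect_equal(sc$correlation["A", "A2"], 1)
  expect_setequal(sc$hclust$merge[1, ], -match(c("A", "A2"), colnames(v)))
  # anti-correlated one-hots for K=2 merge last (r < 0)
  oh <- as_signature(matrix(c(1, 0, 0, 1), 2, 2,
                            dimnames = list(c("g1", "g2"), c("A", "B"))))
  sc2 <- signature_correlation(oh)
  expect_lt(sc2$correlation["A", "B"], 0)
  # two types sharing half their markers cluster together
  sim <- tiny_reference(n_features = 150, n_types = 5, markers = 10,
                        effect = 10, reps = 3, cv = 0.02, seed = 31)
  m <- sim$ref$matrix
  shared <- sim$truth$feature_id[sim$truth$cell_type == "type_1"][1:5]
  m[shared, sim$ref$labels == "type_2"] <- m[shared, sim$ref$labels == "type_1"]
  ref <- reference_set(m, sim$ref$labels)
  sc3 <- signature_correlation(as_signature(mean_profiles(ref)))
  h <- stats::cutree(sc3$hclust, k = 4)
  expect_identical(h[["type_1"]], h[["type_2"]])
})
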