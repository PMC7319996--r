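# Shared fixtures, built in code at test time.

# Tiny labeled reference: K types, disjoint planted markers, optional noise.
tiny_reference <- function(n_features = 60, n_types = 3, markers = 5,
                           effect = 10, reps = 3, cv = 0.05, seed = 11) {
  cfg <- sim_config(n_features = n_features, n_types = n_types,
                    markers_per_type = markers, marker_effect = effect,
                    replicates_per_type = reps, noise_cv = cv,
                    dirichlet_alpha = rep(1, n_types), seed = seed)
  simulate_reference(cfg)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Exact two-sided signed-rank p-value by enumeration of all sign patterns.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mu <- n * (n + 1) / 4
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  min(1, p)
}

# Exact two-sided rank-sum p-value by enumeration of group assignments.
enum_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(r), n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12))
}

# Brute-force marker criteria by explicit double loops.
brute_primary <- function(g) {
  out <- g
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g)))
    out[i, j] <- g[i, j] - max(g[i, -j])
  out
}
brute_secondary <- function(g) {
  out <- g
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g)))
    out[i, j] <- g[i, j] - mean(g[i, -j])
  out
}
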