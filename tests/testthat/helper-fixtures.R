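# Small, fast fixtures used across test files. Everything is generated in
# code; sizes are kept small so the full suite stays quick.

# a reduced experimental design: short cycles keep integration cheap while
# preserving the schedule structure (migration window, bottleneck, sampling)
small_design <- function(M = 5L, n_cycles = 6L, migration_end = 4L,
                         N_total = 1e6, ...) {
  transfer_design(T_growth = 8, n_cycles = n_cycles,
                  migration_end = migration_end, D_transfer = 0.008,
                  N_total = N_total, N_regional = 8e4, N_global = 2e3,
                  M = M, ...)
}

# a handful of ASVs that all establish, with distinct carrying capacities
small_params <- function(S = 8L, sigma = 0.5, tau = 1) {
  K <- setNames(10^seq(-3, -1, length.out = S), sprintf("ASV%04d", seq_len(S)))
  slm_params(K = K, tau = tau, sigma = sigma)
}

small_progenitor <- function(S = 8L, seed = 42L) {
  generate_progenitor(S, mad_location = -5, mad_scale = 1.5, seed = seed)
}

# community table built directly from an abundance matrix (no dynamics):
# columns are replicates at the given transfers
table_from_matrix <- function(x, transfer, treatment = "none",
                              depth = 1e4, seed = 7L) {
  set.seed(seed)
  S <- nrow(x)
  counts <- apply(x, 2L, function(col) {
    if (sum(col) <= 0) integer(S) else
      drop(rmultinom(1L, depth, col / sum(col)))
  })
  rownames(counts) <- rownames(x)
  M <- ncol(x) / length(transfer)
  meta <- data.frame(
    sample_id = paste0("s", seq_len(ncol(x))),
    treatment = treatment,
    transfer = rep(transfer, each = M),
    replicate = rep(seq_len(M), times = length(transfer)))
  community_table(counts, meta)
}

# gamma-distributed abundances consistent with the SLM stationary state
gamma_community <- function(S, M, K, sigma, seed) {
  set.seed(seed)
  mom <- slm_stationary_moments(K, sigma)
  x <- t(vapply(seq_len(S), function(i)
    rgamma(M, shape = mom$beta[i], scale = mom$mean[i] / mom$beta[i]),
    numeric(M)))
  rownames(x) <- sprintf("ASV%04d", seq_len(S))
  x
}
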