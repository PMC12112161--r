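#' Integrate the SLM over one transfer cycle
#'
#' Euler-Maruyama integration (Ito convention) of
#' `dx = (x / tau) (1 - x / K) dt + sqrt(sigma / tau) x dW`
#' for each ASV independently, from `t = 0` to `t = T_growth`. The state is
#' clipped at zero after every step; zero is absorbing and ASVs with `K = 0`
#' are set to zero (they cannot grow and are lost within the cycle).
#'
#' @param x0 non-negative relative abundances: a vector of length S or an
#'   S x M matrix (ASVs x replicates).
#' @param params an [slm_params()] object with S ASVs.
#' @param config an [integrator_config()]; `dt` defaults to `min(tau)/100`
#'   over growing ASVs and must satisfy `dt <= min(tau)/10`.
#' @param T_growth integration time, > 0.
#' @param seed optional integer seed.
#' @return Relative abundances at `t = T_growth`, same shape as `x0`.
#' @export
integrate_cycle <- function(x0, params, config = integrator_config(),
                            T_growth, seed = NULL) {
  stopifnot(inherits(params, "slm_params"))
  check_scalar(T_growth, "T_growth", lower = 0, strict_lower = TRUE)
  vec <- is.null(dim(x0))
  x <- if (vec) matrix(x0, ncol = 1L) else as.matrix(x0)
  if (nrow(x) != length(params$K))
    stop_invalid("x0 must have one row per ASV")
  if (any(!is.finite(x)) || any(x < 0))
    stop_invalid("x0 must be finite and >= 0")
  grow <- params$K > 0
  tau_min <- if (any(grow)) min(params$tau[grow]) else min(params$tau)
  dt <- if (is.null(config$dt)) tau_min / 100 else config$dt
  if (dt > tau_min / 10 + 1e-12)
    stop_invalid("dt must be <= min(tau)/10 (got dt = ", dt, ")")
  # only rows that can grow need integrating; K = 0 rows are zero by contract
  out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  if (any(grow)) {
    out[grow, ] <- with_seed(seed %||% config$seed,
                             .em_integrate(x[grow, , drop = FALSE],
                                           params$K[grow], params$tau[grow],
                                           params$sigma[grow], dt, T_growth))
  }
  if (vec) drop(out) else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multinomial read sampling of a community
#'
#' Converts a relative-abundance vector into read counts by drawing a
#' multinomial sample of size `depth`.
#'
#' @param x relative abundances summing to 1 (renormalized internally if the
#'   sum differs by rounding; an all-zero vector is an error unless
#'   `depth = 0`).
#' @param depth total number of reads, `>= 0`.
#' @param seed optional integer seed.
#' @return Integer count vector summing to `depth`.
#' @export
sample_reads <- function(x, depth, seed = NULL) {
  if (!is.numeric(depth) || length(depth) != 1L || !is.finite(depth) ||
      depth < 0 || depth != round(depth))
    stop_invalid("depth must be a non-negative integer")
  if (any(x < 0)) stop_invalid("abundances must be non-negative")
  if (depth == 0) return(integer(length(x)))
  s <- sum(x)
  if (s <= 0) stop_invalid("cannot sample reads from an all-zero community")
  with_seed(seed, drop(rmultinom(1L, size = as.integer(depth), prob = x / s)))
}

#' Transfer bottleneck and migration between cycles
#'
#' Applies the serial-dilution bottleneck and, within the migration window,
#' adds migrant cells. Each replicate transfers
#' `round(D_transfer * N_total)` cells drawn multinomially from its
#' end-of-cycle relative abundances. Under the regional (mainland-island)
#' treatment, `N_regional` progenitor cells are added per replicate; under the
#' global (metacommunity) treatment, `N_global` cells drawn from the pooled
#' end-of-cycle composition of all replicates are added. Migrants are only
#' added for cycles `1..migration_end` (global migration needs a predecessor
#' cycle, so it acts from cycle 2). The resulting cell counts define the
#' initial relative abundances of the next cycle; the expected initial mean is
#' the mixture `(D_transfer N* <x_end> + N_mig x_source) / (D_transfer N* + N_mig)`.
#'
#' @param end_x S x M matrix of end-of-cycle abundances (each column is
#'   normalized internally).
#' @param design a [transfer_design()].
#' @param treatment one of `"none"`, `"regional"`, `"global"`.
#' @param prog a `progenitor_profile` (required for regional migration).
#' @param cycle the cycle being seeded (controls the migration window).
#' @param seed optional integer seed.
#' @return S x M integer matrix of post-transfer cell counts; each column sums
#'   exactly to `round(D_transfer * N_total)` plus the migrant count.
#' @export
dilute_and_migrate <- function(end_x, design, treatment = c("none", "regional",
                                                            "global"),
                               prog = NULL, cycle = 1L, seed = NULL) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(design, "transfer_design"))
  end_x <- as.matrix(end_x)
  if (any(end_x < 0)) stop_invalid("end-of-cycle abundances must be >= 0")
  M <- ncol(end_x)
  n_transfer <- round(design$D_transfer * design$N_total)
  migrate <- cycle >= 1L && cycle <= design$migration_end
  with_seed(seed, {
    out <- matrix(0L, nrow(end_x), M, dimnames = dimnames(end_x))
    for (m in seq_len(M)) {
      s <- sum(end_x[, m])
      if (s > 0)
        out[, m] <- drop(rmultinom(1L, n_transfer, end_x[, m] / s))
    }
    if (migrate && treatment == "regional") {
      if (is.null(prog))
        stop_invalid("regional migration requires a progenitor profile")
      for (m in seq_len(M))
        out[, m] <- out[, m] +
          drop(rmultinom(1L, round(design$N_regional), prog$abundances))
    }
    if (migrate && treatment == "global") {
      pooled <- rowSums(end_x)
      if (sum(pooled) <= 0)
        stop_invalid("global migration pool is extinct")
      pooled <- pooled / sum(pooled)
      for (m in seq_len(M))
        out[, m] <- out[, m] +
          drop(rmultinom(1L, round(design$N_global), pooled))
    }
    out
  })
}

#' Construct a community table
#'
#' An ASV x sample matrix of non-negative integer read counts plus per-sample
#' metadata (treatment, transfer cycle, replicate, depth).
#'
#' @param counts integer matrix, ASVs in rows, samples in columns.
#' @param meta data.frame with columns `sample_id`, `treatment`, `transfer`,
#'   `replicate`; depths are taken as column sums.
#' @return An object of class `community_table`.
#' @export
community_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_invalid("counts must be non-negative integers")
  req <- c("sample_id", "treatment", "transfer", "replicate")
  if (!all(req %in% names(meta)))
    stop_invalid("metadata must contain columns: ", paste(req, collapse = ", "))
  if (nrow(meta) != ncol(counts))
    stop_invalid("metadata rows must match count columns")
  meta$depth <- as.integer(colSums(counts))
  colnames(counts) <- meta$sample_id
  structure(list(counts = counts, meta = meta), class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat("Community table:", nrow(x$counts), "ASVs x", ncol(x$counts),
      "samples\n")
  cat("  treatments:", paste(unique(x$meta$treatment), collapse = ", "), "\n")
  cat("  transfers:", paste(sort(unique(x$meta$transfer)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Relative abundances of a community table
#'
#' @param ct a [community_table()].
#' @return Matrix of counts divided by sample depth.
#' @export
relative_abundance <- function(ct) {
  stopifnot(inherits(ct, "community_table"))
  sweep(ct$counts, 2L, pmax(ct$meta$depth, 1L), "/")
}

#' Subset a community table by metadata
#'
#' @param ct a [community_table()].
#' @param transfer,replicate,treatment optional filters.
#' @return A [community_table()].
#' @export
subset_table <- function(ct, transfer = NULL, replicate = NULL,
                         treatment = NULL) {
  stopifnot(inherits(ct, "community_table"))
  keep <- rep(TRUE, nrow(ct$meta))
  if (!is.null(transfer)) keep <- keep & ct$meta$transfer %in% transfer
  if (!is.null(replicate)) keep <- keep & ct$meta$replicate %in% replicate
  if (!is.null(treatment)) keep <- keep & ct$meta$treatment %in% treatment
  if (!any(keep)) stop_invalid("no samples match the requested subset")
  community_table(ct$counts[, keep, drop = FALSE],
                  ct$meta[keep, , drop = FALSE])
}

#' Simulate a serial-dilution community assembly experiment
#'
#' Runs `M` replicate communities for `n_cycles` transfer cycles. Replicates
#' are inoculated with `round(D_transfer * N_total)` cells sampled from the
#' progenitor; within each cycle the SLM is integrated for `T_growth`; at the
#' end of each sequenced cycle the community is converted to reads by
#' multinomial sampling at a depth drawn from the depth model; between cycles
#' the transfer bottleneck and (within the migration window) migration are
#' applied. The whole simulation is deterministic given `seed`.
#'
#' @param design a [transfer_design()].
#' @param params an [slm_params()] object (one entry per progenitor ASV).
#' @param treatment `"none"`, `"regional"`, or `"global"`.
#' @param prog a `progenitor_profile`.
#' @param depths a [depth_model()].
#' @param config an [integrator_config()].
#' @param sequenced_cycles integer vector of cycles to sequence (subset of
#'   `1..n_cycles`); defaults to `c(migration_end, n_cycles)`.
#' @param seed optional integer seed.
#' @return A [community_table()].
#' @export
simulate_experiment <- function(design, params,
                                treatment = c("none", "regional", "global"),
                                prog, depths = depth_model(),
                                config = integrator_config(),
                                sequenced_cycles = NULL, seed = NULL) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(design, "transfer_design"),
            inherits(params, "slm_params"),
            inherits(prog, "progenitor_profile"),
            inherits(depths, "depth_model"))
  if (length(params$K) != prog$S)
    stop_invalid("params must have one entry per progenitor ASV")
  if (is.null(sequenced_cycles))
    sequenced_cycles <- unique(c(design$migration_end, design$n_cycles))
  sequenced_cycles <- sort(unique(as.integer(sequenced_cycles)))
  if (any(sequenced_cycles < 1L) || any(sequenced_cycles > design$n_cycles))
    stop_invalid("sequenced_cycles must lie in 1..n_cycles")
  M <- design$M
  S <- prog$S
  with_seed(seed, {
    n_inoc <- round(design$D_transfer * design$N_total)
    cells <- rmultinom(M, n_inoc, prog$abundances)
    x <- sweep(cells, 2L, pmax(colSums(cells), 1), "/")
    rownames(x) <- names(prog$abundances)
    counts <- NULL
    meta <- NULL
    for (k in seq_len(design$n_cycles)) {
      x <- integrate_cycle(x, params, config, design$T_growth)
      if (k %in% sequenced_cycles) {
        dk <- sample_read_depths(M, depths)
        reads <- vapply(seq_len(M), function(m) {
          if (sum(x[, m]) <= 0) integer(S) else sample_reads(x[, m], dk[m])
        }, integer(S))
        reads <- matrix(reads, nrow = S, dimnames = list(rownames(x), NULL))
        counts <- cbind(counts, reads)
        meta <- rbind(meta, data.frame(
          sample_id = sprintf("%s_T%02d_R%02d", treatment, k, seq_len(M)),
          treatment = treatment, transfer = k, replicate = seq_len(M),
          stringsAsFactors = FALSE))
      }
      if (k < design$n_cycles) {
        cells <- dilute_and_migrate(x, design, treatment, prog,
                                    cycle = k + 1L)
        x <- sweep(cells, 2L, pmax(colSums(cells), 1), "/")
      }
    }
    community_table(counts, meta)
  })
}
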