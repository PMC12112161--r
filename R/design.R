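#' Experimental transfer design
#'
#' Demographic constants and schedule of a serial-dilution community assembly
#' experiment: replicate microcosms grow for `T_growth` hours, an aliquot of
#' relative volume `D_transfer` seeds the next cycle, and migrant cells are
#' added at the start of each cycle during the migration window. Defaults are
#' the experimentally imposed parameters of the glucose serial-dilution
#' experiment this package models: 18 cycles of 48 h, a 1:125 bottleneck
#' (4 uL / 500 uL = 0.008), end-of-cycle community size ~1e8 cells, 7.92e6
#' regional migrants or ~3.07e4 global migrants per replicate per cycle, and
#' migration during cycles 1-12 only.
#'
#' @param T_growth within-cycle growth time (hours).
#' @param n_cycles number of transfer cycles.
#' @param migration_end last cycle with migration (0 disables migration).
#' @param D_transfer transfer dilution rate in (0, 1].
#' @param N_total total community size at the end of a cycle, N*(T); assumed
#'   constant across cycles.
#' @param N_regional regional (progenitor) migrant cells per replicate per cycle.
#' @param N_global global (pooled) migrant cells per replicate per cycle.
#' @param D_regional,D_global nominal migration dilution rates (504/60000each);
#'   recorded for reference and reproducible arithmetic.
#' @param M number of replicate communities per treatment.
#' @return An object of class `transfer_design`.
#' @seealso [dilution_rate()] for recomputing the dilution-rate arithmetic.
#' @export
transfer_design <- function(T_growth = 48, n_cycles = 18L, migration_end = 12L,
                            D_transfer = 0.008, N_total = 1e8,
                            N_regional = 7.92e6, N_global = 3.07e4,
                            D_regional = 504 / 60000, D_global = 504 / 60000,
                            M = 10L) {
  check_scalar(T_growth, "T_growth", lower = 0, strict_lower = TRUE)
  n_cycles <- check_count(n_cycles, "n_cycles")
  migration_end <- check_count(migration_end, "migration_end", lower = 0L)
  if (migration_end > n_cycles)
    stop_invalid("migration_end must be <= n_cycles")
  check_scalar(D_transfer, "D_transfer", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(N_total, "N_total", lower = 1)
  check_scalar(N_regional, "N_regional", lower = 0)
  check_scalar(N_global, "N_global", lower = 0)
  M <- check_count(M, "M")
  structure(list(T_growth = T_growth, n_cycles = n_cycles,
                 migration_end = migration_end, D_transfer = D_transfer,
                 N_total = N_total, N_regional = N_regional,
                 N_global = N_global, D_regional = D_regional,
                 D_global = D_global, M = M),
            class = "transfer_design")
}

#' @export
print.transfer_design <- function(x, ...) {
  cat("Transfer design:", x$n_cycles, "cycles of", x$T_growth, "h,",
      "migration in cycles 1 -", x$migration_end, "\n")
  cat(sprintf("  D_transfer = %g, N*(T) = %g, N_regional = %g, N_global = %g, M = %d\n",
              x$D_transfer, x$N_total, x$N_regional, x$N_global, x$M))
  invisible(x)
}

#' Dilution rate from aliquot and total volumes
#'
#' The transfer bottleneck is a 4 uL aliquot into 500 uL (rate 0.008); the
#' migration redistributions use 504 uL out of a 60,000 uL pool (~0.0084).
#'
#' @param aliquot aliquot volume.
#' @param total total volume, in the same units.
#' @return `aliquot / total`.
#' @export
dilution_rate <- function(aliquot, total) {
  check_scalar(aliquot, "aliquot", lower = 0, strict_lower = TRUE)
  check_scalar(total, "total", lower = 0, strict_lower = TRUE)
  aliquot / total
}

#' Per-ASV SLM parameters
#'
#' Carrying capacities `K` (relative-abundance units; `K = 0` means the ASV
#' cannot grow), growth timescales `tau` (> 0) and environmental noise
#' strengths `sigma` (in (0, 2), the stationarity region of the gamma).
#' `tau` and `sigma` are recycled to the length of `K`.
#'
#' @param K numeric vector of carrying capacities, `>= 0`.
#' @param tau growth timescale(s), `> 0`.
#' @param sigma noise strength(s), in (0, 2).
#' @return An object of class `slm_params`.
#' @export
slm_params <- function(K, tau, sigma) {
  if (any(!is.finite(K)) || any(K < 0))
    stop_invalid("K must be finite and >= 0")
  S <- length(K)
  tau <- rep_len(tau, S)
  sigma <- rep_len(sigma, S)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop_invalid("all tau must be > 0")
  if (any(!is.finite(sigma)) || any(sigma <= 0) || any(sigma >= 2))
    stop_invalid("all sigma must lie in (0, 2)")
  if (!is.null(names(K))) nm <- names(K) else nm <- sprintf("ASV%04d", seq_len(S))
  structure(list(K = setNames(as.numeric(K), nm), tau = tau, sigma = sigma),
            class = "slm_params")
}

#' @export
print.slm_params <- function(x, ...) {
  cat("SLM parameters for", length(x$K), "ASVs;",
      sum(x$K > 0), "with K > 0\n")
  cat(sprintf("  tau in [%g, %g], sigma in [%g, %g]\n",
              min(x$tau), max(x$tau), min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' Stationary gamma moments of the SLM
#'
#' At stationarity the SLM abundance of an ASV is gamma distributed with mean
#' `K (1 - sigma / 2)`, squared coefficient of variation
#' `sigma / (2 - sigma) = 1 / beta` and shape `beta = 2 / sigma - 1`. These
#' moment relations are exposed so tests and users can pin the noise
#' convention.
#'
#' @param K carrying capacity (vectorized).
#' @param sigma noise strength in (0, 2) (vectorized).
#' @return A data.frame with columns `mean`, `beta` (gamma shape), `cv2`
#'   (squared CV) and `var`.
#' @export
slm_stationary_moments <- function(K, sigma) {
  if (any(sigma <= 0) || any(sigma >= 2))
    stop_invalid("sigma must lie in (0, 2)")
  m <- K * (1 - sigma / 2)
  beta <- 2 / sigma - 1
  cv2 <- 1 / beta
  data.frame(mean = m, beta = beta, cv2 = cv2, var = cv2 * m^2)
}

#' Integrator configuration for the SLM
#'
#' Fixed-step Euler-Maruyama under the Ito convention. The step `dt` must not
#' exceed one tenth of the smallest growth timescale; when `dt` is `NULL`,
#' `integrate_cycle()` uses `min(tau)/100`.
#'
#' @param dt time step (same units as `tau`), or `NULL` for the default.
#' @param seed optional integer seed recorded with the configuration.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(dt = NULL, seed = NULL) {
  if (!is.null(dt)) check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) check_count(seed, "seed", lower = 0L)
  structure(list(dt = dt, seed = seed, scheme = "euler-maruyama-ito"),
            class = "integrator_config")
}
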