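# Treatment-specific migration statistics with permutation nulls.
# All permutation p-values use the add-one convention
# p = (1 + #{null at least as extreme}) / (n_perm + 1), so p is never 0.

perm_result <- function(statistic, null, tail = c("two.sided", "greater",
                                                  "less")) {
  tail <- match.arg(tail)
  null <- null[is.finite(null)]
  extreme <- switch(tail,
                    two.sided = sum(abs(null) >= abs(statistic)),
                    greater = sum(null >= statistic),
                    less = sum(null <= statistic))
  structure(list(statistic = statistic, null = null,
                 p = (1 + extreme) / (length(null) + 1),
                 n_perm = length(null), tail = tail),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %d permutations): statistic = %.4g, p = %.4g\n",
              x$tail, x$n_perm, x$statistic, x$p))
  invisible(x)
}

#' Correlation between two mean abundance distributions
#'
#' Pearson correlation of log10 mean abundances over the ASVs shared (with
#' positive means) between two treatments, used to ask whether the typical
#' abundances of the regional-migration and no-migration treatments converge
#' after migration ceases.
#'
#' @param means_a,means_b named per-ASV mean abundances; names are matched and
#'   at least 4 shared ASVs with positive means in both are required.
#' @return Pearson correlation coefficient.
#' @export
mad_correlation <- function(means_a, means_b) {
  shared <- intersect(names(means_a)[means_a > 0], names(means_b)[means_b > 0])
  if (length(shared) < 4L)
    stop_invalid("need at least 4 shared ASVs with positive means")
  cor(log10(means_a[shared]), log10(means_b[shared]))
}

#' Fisher's Z statistic for a shift in correlation
#'
#' Tests whether the correlation changed between two time points:
#' `Z = (z_after - z_before) / sqrt(1/(M_before - 3) + 1/(M_after - 3))`,
#' where `z = atanh(rho)` and `M` counts the paired observations. The
#' half-log (atanh) transform is the one for which the standard error
#' `sqrt(1/(M - 3))` holds; set `half = FALSE` for the full-log variant.
#'
#' @param rho_before,rho_after correlations, `|rho| < 1`.
#' @param M_before,M_after numbers of paired observations, each `> 3`.
#' @param half use the conventional half-log transform (default `TRUE`).
#' @return The Z statistic (asymptotically standard normal under no change).
#' @export
fisher_z_shift <- function(rho_before, rho_after, M_before, M_after,
                           half = TRUE) {
  for (r in c(rho_before, rho_after))
    if (!is.finite(r) || abs(r) >= 1)
      stop_invalid("correlations must satisfy |rho| < 1")
  M_before <- check_count(M_before, "M_before", lower = 4L)
  M_after <- check_count(M_after, "M_after", lower = 4L)
  z <- function(r) if (half) atanh(r) else log((1 + r) / (1 - r))
  (z(rho_after) - z(rho_before)) /
    sqrt(1 / (M_before - 3) + 1 / (M_after - 3))
}

ols_slope <- function(x, y) {
  fit <- lm(y ~ x)
  s <- summary(fit)$coefficients
  c(slope = unname(coef(fit)[2L]), se = unname(s[2L, 2L]))
}

#' Progenitor dependence of the migration/no-migration abundance ratio
#'
#' Regresses the log10 ratio of mean abundances (regional / no migration) on
#' log10 progenitor abundance. A positive slope means regional migration
#' boosted ASVs according to their abundance in the progenitor pool.
#' Significance is assessed by permuting the pairing between ratios and
#' progenitor abundances.
#'
#' @param ratio named per-ASV abundance ratios (positive).
#' @param prog_abundance named per-ASV progenitor relative abundances.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return List with `slope`, `se` and a `perm_test` (two-sided).
#' @export
progenitor_slope <- function(ratio, prog_abundance, n_perm = 1000L,
                             seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm")
  shared <- intersect(names(ratio)[is.finite(ratio) & ratio > 0],
                      names(prog_abundance)[prog_abundance > 0])
  if (length(shared) < 4L)
    stop_invalid("need at least 4 ASVs shared with the progenitor")
  y <- log10(ratio[shared])
  x <- log10(prog_abundance[shared])
  if (sd(x) == 0) stop_invalid("degenerate predictor")
  obs <- ols_slope(x, y)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i)
      ols_slope(x, sample(y))[["slope"]], numeric(1))
    list(slope = obs[["slope"]], se = obs[["se"]], n = length(shared),
         test = perm_result(obs[["slope"]], null, "two.sided"))
  })
}

#' Permutation t-test for a change in progenitor-dependence slope
#'
#' Compares the progenitor-dependence slope at two transfers with
#' `t = (slope_after - slope_before) / sqrt(se_before^2 + se_after^2)`.
#' The null permutes, independently per ASV, which of its two ratios is
#' labeled "before" vs "after" (transfer-label exchangeability).
#'
#' @param ratio_before,ratio_after named per-ASV abundance ratios at the two
#'   transfers.
#' @param prog_abundance named progenitor relative abundances.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return List with the two slopes, the observed `t` and a two-sided
#'   `perm_test`.
#' @export
slope_change_test <- function(ratio_before, ratio_after, prog_abundance,
                              n_perm = 1000L, seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm")
  shared <- Reduce(intersect, list(
    names(ratio_before)[is.finite(ratio_before) & ratio_before > 0],
    names(ratio_after)[is.finite(ratio_after) & ratio_after > 0],
    names(prog_abundance)[prog_abundance > 0]))
  if (length(shared) < 4L)
    stop_invalid("need at least 4 ASVs shared across transfers and progenitor")
  x <- log10(prog_abundance[shared])
  yb <- log10(ratio_before[shared])
  ya <- log10(ratio_after[shared])
  tstat <- function(yb, ya) {
    b <- ols_slope(x, yb); a <- ols_slope(x, ya)
    (a[["slope"]] - b[["slope"]]) / sqrt(a[["se"]]^2 + b[["se"]]^2)
  }
  obs <- tstat(yb, ya)
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      swap <- runif(length(shared)) < 0.5
      pb <- ifelse(swap, ya, yb)
      pa <- ifelse(swap, yb, ya)
      tstat(pb, pa)
    }, numeric(1))
    list(t = obs, test = perm_result(obs, null, "two.sided"))
  })
}

#' Log-ratios of abundance between consecutive transfers
#'
#' `delta_ell = log(x[k + 1] / x[k])` (natural log), a discretized per-capita
#' growth rate that cancels multiplicative, time-independent sample biases.
#' Defined only where both abundances are positive; otherwise `NA`.
#'
#' @param ct a [community_table()] restricted to one replicate.
#' @return Matrix of log-ratios, ASVs x consecutive transfer pairs; columns
#'   named `"k->k+1"`.
#' @export
delta_ell <- function(ct) {
  stopifnot(inherits(ct, "community_table"))
  if (length(unique(ct$meta$replicate)) != 1L)
    stop_invalid("delta_ell expects a single replicate")
  ord <- order(ct$meta$transfer)
  tr <- ct$meta$transfer[ord]
  x <- relative_abundance(ct)[, ord, drop = FALSE]
  consec <- which(diff(tr) == 1L)
  if (length(consec) == 0L)
    stop_invalid("no consecutive transfer pairs available")
  out <- vapply(consec, function(j) {
    a <- x[, j]; b <- x[, j + 1L]
    ifelse(a > 0 & b > 0, log(b / a), NA_real_)
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x),
                                sprintf("%d->%d", tr[consec], tr[consec] + 1L)))
  out
}

#' Across-replicate CV of abundance log-ratios per transfer
#'
#' For each ASV and transfer step k, the coefficient of variation
#' `sd / |mean|` of `delta_ell` across replicate communities (at least 3
#' replicates with defined log-ratios required; otherwise `NA`).
#'
#' @param ct a [community_table()] with several replicates sequenced over
#'   consecutive transfers.
#' @return Matrix of CVs, ASVs x transfer steps (named by starting transfer).
#' @export
cv_across_replicates <- function(ct) {
  reps <- sort(unique(ct$meta$replicate))
  dls <- lapply(reps, function(r) delta_ell(subset_table(ct, replicate = r)))
  steps <- Reduce(intersect, lapply(dls, colnames))
  if (length(steps) == 0L) stop_invalid("replicates share no transfer steps")
  nA <- nrow(ct$counts)
  out <- vapply(steps, function(s) {
    m <- vapply(dls, function(d) d[, s], numeric(nA))
    apply(matrix(m, nrow = nA), 1L, function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 3L || mean(v) == 0) NA_real_ else sd(v) / abs(mean(v))
    })
  }, numeric(nA))
  matrix(out, nrow = nA,
         dimnames = list(rownames(ct$counts),
                         sub("->.*", "", steps)))
}

#' Permutation test for a shift in across-replicate fluctuation CVs
#'
#' Compares, per ASV, the across-replicate CVs of the abundance log-ratio in
#' the window after the cessation of migration against the window before,
#' using a Welch t statistic; the reported statistic is the mean t over ASVs
#' (`t_bar`). The null permutes transfer labels within each ASV. The test of
#' a CV *increase* after cessation is one-sided by default.
#'
#' @param cv matrix from [cv_across_replicates()] (ASVs x transfer steps,
#'   columns named by starting transfer).
#' @param before,after transfer windows; defaults 7-12 and 13-18, the
#'   stationary halves of an 18-cycle experiment with migration through 12.
#' @param n_perm number of permutations.
#' @param tail tail of the test (default `"greater"`: CV increased).
#' @param seed optional integer seed.
#' @return List with `t_bar`, per-ASV t values, and a `perm_test`.
#' @export
cv_shift_test <- function(cv, before = 7:12, after = 13:18, n_perm = 1000L,
                          tail = "greater", seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm")
  cols <- as.integer(colnames(cv))
  ib <- which(cols %in% before)
  ia <- which(cols %in% after)
  if (length(ib) == 0L || length(ia) == 0L)
    stop_invalid("both transfer windows must be non-empty")
  welch_t <- function(a, b) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  per_asv <- function(m) {
    t <- apply(m, 1L, function(v) welch_t(v[ia], v[ib]))
    mean(t, na.rm = TRUE)
  }
  obs_t <- apply(cv, 1L, function(v) welch_t(v[ia], v[ib]))
  t_bar <- mean(obs_t, na.rm = TRUE)
  if (!is.finite(t_bar)) stop_invalid("no ASV has enough defined CVs")
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      perm <- t(apply(cv, 1L, sample))
      colnames(perm) <- colnames(cv)
      per_asv(perm)
    }, numeric(1))
    list(t_bar = t_bar, t = obs_t, test = perm_result(t_bar, null, tail))
  })
}

#' F statistic comparing two coefficients of variation
#'
#' Compares the within-replicate CV of the abundance log-ratio after
#' (`cv_after`, over `M_gt` transfers) and before (`cv_before`, over `M_lt`
#' transfers) the cessation of migration:
#' `F = [cv_after^2 / (1 + cv_after^2 (M_gt - 1) / M_gt)] *
#'     [(1 + cv_before^2 (M_lt - 1) / M_lt) / cv_before^2]`.
#' Swapping the two windows inverts F.
#'
#' @param cv_before,cv_after coefficients of variation (`cv_before > 0`).
#' @param M_lt,M_gt numbers of transfers in each window, each `>= 2`.
#' @return The F statistic.
#' @export
f_cv <- function(cv_before, cv_after, M_lt, M_gt) {
  check_scalar(cv_before, "cv_before", lower = 0, strict_lower = TRUE)
  check_scalar(cv_after, "cv_after", lower = 0)
  M_lt <- check_count(M_lt, "M_lt", lower = 2L)
  M_gt <- check_count(M_gt, "M_gt", lower = 2L)
  (cv_after^2 / (1 + cv_after^2 * (M_gt - 1) / M_gt)) *
    ((1 + cv_before^2 * (M_lt - 1) / M_lt) / cv_before^2)
}

#' Within-replicate CVs and F statistics for a community table
#'
#' For each (ASV, replicate), computes the CV of the abundance log-ratio over
#' the transfers before and after the cessation of migration and the
#' corresponding [f_cv()] statistic.
#'
#' @param ct a [community_table()] sequenced over consecutive transfers.
#' @param before,after transfer windows (starting transfers of log-ratio
#'   steps), defaults 7-12 and 13-18.
#' @return data.frame keyed by (asv, replicate) with `cv_before`, `cv_after`,
#'   `f_cv`.
#' @export
f_cv_table <- function(ct, before = 7:12, after = 13:18) {
  reps <- sort(unique(ct$meta$replicate))
  res <- lapply(reps, function(r) {
    d <- delta_ell(subset_table(ct, replicate = r))
    start <- as.integer(sub("->.*", "", colnames(d)))
    ib <- which(start %in% before); ia <- which(start %in% after)
    cvw <- function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2L || mean(v) == 0) return(c(NA_real_, NA_real_))
      c(sd(v) / abs(mean(v)), length(v))
    }
    rows <- lapply(rownames(d), function(a) {
      b <- cvw(d[a, ib]); aa <- cvw(d[a, ia])
      f <- if (is.finite(b[1L]) && is.finite(aa[1L]) && b[1L] > 0)
        f_cv(b[1L], aa[1L], b[2L], aa[2L]) else NA_real_
      data.frame(asv = a, replicate = r, cv_before = b[1L],
                 cv_after = aa[1L], f_cv = f, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' KS test between two F_CV distributions, constrained on ASV identity
#'
#' Compares the distributions of per-(ASV, replicate) F statistics of two
#' treatments with a two-sample KS statistic whose null permutes treatment
#' labels *within each ASV*, so ASV identity is preserved under the null.
#'
#' @param f_a,f_b data.frames from [f_cv_table()] for the two treatments (or
#'   any data.frames with columns `asv` and `f_cv`).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return List with the observed `ks` and a one-sided (`greater`)
#'   `perm_test`.
#' @export
constrained_ks_test <- function(f_a, f_b, n_perm = 1000L, seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm")
  f_a <- f_a[is.finite(f_a$f_cv), c("asv", "f_cv")]
  f_b <- f_b[is.finite(f_b$f_cv), c("asv", "f_cv")]
  shared <- intersect(unique(f_a$asv), unique(f_b$asv))
  if (length(shared) == 0L) stop_invalid("no shared ASVs across treatments")
  f_a <- f_a[f_a$asv %in% shared, ]
  f_b <- f_b[f_b$asv %in% shared, ]
  ks_stat <- function(a, b)
    unname(suppressWarnings(ks.test(a, b)$statistic))
  obs <- ks_stat(f_a$f_cv, f_b$f_cv)
  pooled <- rbind(cbind(f_a, grp = "a"), cbind(f_b, grp = "b"))
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      g <- unlist(lapply(split(pooled$grp, pooled$asv), sample),
                  use.names = FALSE)
      v <- unlist(split(pooled$f_cv, pooled$asv), use.names = FALSE)
      ks_stat(v[g == "a"], v[g == "b"])
    }, numeric(1))
    list(ks = obs, test = perm_result(obs, null, "greater"))
  })
}

#' Per-ASV mean abundances of a community table
#'
#' Convenience accessor: mean relative abundance across samples, named by
#' ASV. Used to pair MADs across treatments.
#'
#' @param ct a [community_table()].
#' @return Named numeric vector.
#' @export
mean_abundances <- function(ct) {
  rowMeans(relative_abundance(ct))
}
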