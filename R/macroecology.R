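#' Fit the gamma abundance fluctuation distribution by moments
#'
#' Across replicate communities, the relative abundance of an ASV under the
#' SLM is gamma distributed. The two parameters are estimated by moments:
#' `mean = sample mean` and shape `beta = mean^2 / variance`. Zeros are kept
#' in the moments — the sampling layer of the model absorbs detection.
#'
#' @param abundances relative abundances of one ASV across `>= 2` replicates.
#' @return An object of class `gamma_afd`: list with `mean`, `beta`, `n`.
#' @export
fit_gamma_afd <- function(abundances) {
  if (length(abundances) < 2L)
    stop_invalid("need at least 2 replicates to fit the AFD")
  if (any(abundances < 0)) stop_invalid("abundances must be >= 0")
  m <- mean(abundances)
  v <- var(abundances)
  if (!is.finite(v) || v <= 0 || m <= 0)
    stop_invalid("degenerate AFD: zero variance or zero mean")
  structure(list(mean = m, beta = m^2 / v, n = length(abundances)),
            class = "gamma_afd")
}

#' @export
print.gamma_afd <- function(x, ...) {
  cat(sprintf("Gamma AFD fit: mean = %.4g, beta = %.4g (n = %d)\n",
              x$mean, x$beta, x$n))
  invisible(x)
}

#' @export
coef.gamma_afd <- function(object, ...) {
  c(mean = object$mean, beta = object$beta)
}

#' Gamma AFD fits for every ASV of a community table
#'
#' @param ct a [community_table()] (typically one treatment x transfer).
#' @return data.frame keyed by ASV with columns `mean`, `beta`,
#'   `observed_occupancy` (fraction of samples with >= 1 read). ASVs with zero
#'   mean or zero variance get `NA` parameters.
#' @export
gamma_afd_table <- function(ct) {
  x <- relative_abundance(ct)
  m <- rowMeans(x)
  v <- apply(x, 1L, var)
  beta <- ifelse(m > 0 & v > 0, m^2 / v, NA_real_)
  data.frame(asv = rownames(x), mean = m,
             beta = beta,
             observed_occupancy = rowMeans(ct$counts >= 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Occupancy predicted by the gamma AFD with multinomial sampling
#'
#' Under the Poisson limit of multinomial read sampling on a gamma AFD, the
#' probability of zero reads at depth `N` is `(beta / (beta + mean N))^beta`,
#' so the expected occupancy over `M` samples is
#' `1 - mean_m (beta / (beta + mean N_m))^beta`.
#'
#' @param fit a [fit_gamma_afd()] object, or a list/data.frame with `mean` and
#'   `beta`.
#' @param depths vector of per-sample sequencing depths `N_m >= 0`.
#' @param observed optional observed occupancy, to compute the relative error
#'   `|predicted - observed| / observed` (reported as `NA` with a flag when
#'   `observed = 0`).
#' @return List with `predicted`, and when `observed` is given, `observed`,
#'   `relative_error` and `error_defined`.
#' @export
predict_occupancy <- function(fit, depths, observed = NULL) {
  if (any(depths < 0)) stop_invalid("depths must be >= 0")
  m <- fit$mean
  beta <- fit$beta
  p0 <- vapply(depths, function(N) (beta / (beta + m * N))^beta, numeric(1))
  pred <- 1 - mean(p0)
  if (is.null(observed)) return(list(predicted = pred))
  defined <- observed > 0
  list(predicted = pred, observed = observed,
       relative_error = if (defined) abs(pred - observed) / observed else NA_real_,
       error_defined = defined)
}

#' Binned abundance-occupancy curve
#'
#' Averages observed and gamma-predicted occupancy over ASVs within
#' log-spaced bins of mean relative abundance.
#'
#' @param ct a [community_table()].
#' @param n_bins number of log10-spaced bins (default 10); empty bins are
#'   dropped.
#' @return data.frame with per-bin mean abundance, observed and predicted
#'   occupancy, and the number of ASVs in the bin.
#' @export
occupancy_curve <- function(ct, n_bins = 10L) {
  n_bins <- check_count(n_bins, "n_bins")
  tab <- gamma_afd_table(ct)
  tab <- tab[!is.na(tab$beta) & tab$mean > 0, , drop = FALSE]
  if (nrow(tab) == 0L) stop_invalid("no fittable ASVs in table")
  depths <- ct$meta$depth
  tab$predicted <- vapply(seq_len(nrow(tab)), function(i)
    predict_occupancy(tab[i, ], depths)$predicted, numeric(1))
  lm10 <- log10(tab$mean)
  edges <- seq(min(lm10), max(lm10), length.out = n_bins + 1L)
  bin <- findInterval(lm10, edges, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(tab)), bin), function(idx)
    data.frame(mean_abundance = 10^mean(lm10[idx]),
               observed = mean(tab$observed_occupancy[idx]),
               predicted = mean(tab$predicted[idx]),
               n_asv = length(idx))))
  rownames(out) <- NULL
  out
}

#' Standard-score rescaling of a log-transformed AFD
#'
#' Rescales the log10 of the positive abundances of one ASV by their mean and
#' standard deviation, giving the "standard score" used to collapse AFDs
#' across ASVs and treatments.
#'
#' @param abundances positive relative abundances (`>= 2` values required).
#' @return Numeric vector with mean 0 and sd 1.
#' @export
rescale_afd <- function(abundances) {
  x <- abundances[abundances > 0]
  if (length(x) < 2L)
    stop_invalid("need at least 2 positive abundances to rescale")
  l <- log10(x)
  s <- sd(l)
  if (s == 0) stop_invalid("zero variance on the log scale")
  (l - mean(l)) / s
}

#' Mean Kolmogorov-Smirnov shift between two snapshots of the AFD
#'
#' For each ASV present (>= 1 read) in every replicate of both tables,
#' computes the two-sample KS statistic between its across-replicate AFDs
#' (rescaled log10 abundances by default), then averages over ASVs. Used to
#' quantify how the shape of the AFD changed between the last transfer with
#' migration and the final transfer.
#'
#' @param ct_a,ct_b [community_table()] objects (e.g., transfers 12 and 18).
#' @param rescale rescale log abundances to standard scores per ASV per table
#'   (default `TRUE`); `FALSE` uses raw abundances.
#' @return List with `mean_ks`, per-ASV statistics `ks`, and the qualifying
#'   ASV ids.
#' @export
mean_ks_shift <- function(ct_a, ct_b, rescale = TRUE) {
  stopifnot(inherits(ct_a, "community_table"),
            inherits(ct_b, "community_table"))
  pa <- rowSums(ct_a$counts >= 1L) == ncol(ct_a$counts)
  pb <- rowSums(ct_b$counts >= 1L) == ncol(ct_b$counts)
  shared <- intersect(rownames(ct_a$counts)[pa], rownames(ct_b$counts)[pb])
  if (length(shared) == 0L)
    stop_invalid("no ASV is present in every replicate of both tables")
  xa <- relative_abundance(ct_a)[shared, , drop = FALSE]
  xb <- relative_abundance(ct_b)[shared, , drop = FALSE]
  ks <- vapply(shared, function(a) {
    va <- xa[a, ]; vb <- xb[a, ]
    if (rescale) { va <- rescale_afd(va); vb <- rescale_afd(vb) }
    unname(suppressWarnings(ks.test(va, vb)$statistic))
  }, numeric(1))
  list(mean_ks = mean(ks), ks = ks, asv = shared)
}

#' Fit Taylor's Law by ordinary least squares
#'
#' Regresses log10 variance on log10 mean of relative abundance across ASVs.
#' The slope is the Taylor exponent (2 means variance proportional to the
#' squared mean, i.e., a constant coefficient of variation across ASVs, which
#' is what the SLM with ASV-independent noise strength predicts).
#'
#' @param means,variances per-ASV mean and variance of relative abundance;
#'   only ASVs with both positive are used and at least 3 are required.
#' @return Object of class `taylor_fit` with `exponent`, `intercept` (log10
#'   scale), standard errors, `n`, and the underlying `lm` fit.
#' @export
fit_taylor <- function(means, variances) {
  ok <- is.finite(means) & is.finite(variances) & means > 0 & variances > 0
  if (sum(ok) < 3L)
    stop_invalid("need at least 3 ASVs with positive mean and variance")
  lx <- log10(means[ok]); ly <- log10(variances[ok])
  fit <- lm(ly ~ lx)
  se <- sqrt(diag(vcov(fit)))
  structure(list(exponent = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 se = c(intercept = unname(se[1L]), exponent = unname(se[2L])),
                 n = sum(ok), lm = fit,
                 log10_mean = lx, log10_var = ly),
            class = "taylor_fit")
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat(sprintf("Taylor's Law fit (n = %d ASVs):\n", x$n))
  cat(sprintf("  exponent  %.4f (se %.4f)\n", x$exponent, x$se["exponent"]))
  cat(sprintf("  intercept %.4f (se %.4f)\n", x$intercept, x$se["intercept"]))
  invisible(x)
}

#' @export
coef.taylor_fit <- function(object, ...) {
  c(intercept = object$intercept, exponent = object$exponent)
}

#' @export
summary.taylor_fit <- function(object, ...) summary(object$lm, ...)

#' @export
predict.taylor_fit <- function(object, means, ...) {
  10^(object$intercept + object$exponent * log10(means))
}

#' @export
residuals.taylor_fit <- function(object, ...) residuals(object$lm)

#' @export
plot.taylor_fit <- function(x, ...) {
  plot(x$log10_mean, x$log10_var,
       xlab = "log10 mean relative abundance",
       ylab = "log10 variance", pch = 19, col = "grey30", ...)
  abline(x$intercept, x$exponent, col = "firebrick", lwd = 2)
  legend("topleft", bty = "n",
         legend = sprintf("slope = %.2f", x$exponent))
  invisible(x)
}

#' Taylor fit straight from a community table
#'
#' @param ct a [community_table()]; moments are taken across samples.
#' @return A [fit_taylor()] object.
#' @export
fit_taylor_table <- function(ct) {
  x <- relative_abundance(ct)
  fit_taylor(rowMeans(x), apply(x, 1L, var))
}

#' Maximum-likelihood fit of a lower-truncated lognormal MAD
#'
#' The mean abundance distribution (MAD) across ASVs follows a lognormal;
#' finite sequencing depth imposes a detection limit `c` below which mean
#' abundances are unobservable, so the lognormal is renormalized on
#' `(c, Inf)`. Location `mu` and scale `s` are fit by maximizing the truncated
#' likelihood from a moment-based start (log-moments of the data).
#'
#' @param means per-ASV mean relative abundances; values `<= c` are dropped
#'   and at least 5 must remain.
#' @param c truncation threshold; defaults to the smallest positive observed
#'   mean (a proxy for the sampling detection limit). `c = 0` gives the
#'   untruncated MLE.
#' @return Object of class `lognormal_mad` with `mu`, `s`, `c`, `logLik`,
#'   `n`, and the optimizer's convergence code.
#' @export
fit_truncated_lognormal <- function(means, c = NULL) {
  means <- means[is.finite(means) & means > 0]
  if (is.null(c)) c <- min(means)
  check_scalar(c, "c", lower = 0)
  x <- means[means >= c]
  if (length(x) < 5L)
    stop_invalid("need at least 5 mean abundances above the threshold")
  lx <- log(x)
  start <- c(mu = mean(lx), log_s = log(max(sd(lx), 1e-3)))
  nll <- function(par) {
    mu <- par[1L]; s <- exp(par[2L])
    ll <- sum(dlnorm(x, mu, s, log = TRUE))
    if (c > 0) ll <- ll - length(x) * plnorm(c, mu, s, lower.tail = FALSE,
                                             log.p = TRUE)
    -ll
  }
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  structure(list(mu = unname(opt$par[1L]), s = exp(unname(opt$par[2L])),
                 c = c, logLik = -opt$value, n = length(x),
                 start = c(mu = unname(start[1L]), s = exp(unname(start[2L]))),
                 convergence = opt$convergence),
            class = "lognormal_mad")
}

#' @export
print.lognormal_mad <- function(x, ...) {
  cat(sprintf("Truncated-lognormal MAD fit (n = %d, c = %.3g):\n", x$n, x$c))
  cat(sprintf("  mu = %.4f, s = %.4f, logLik = %.2f\n", x$mu, x$s, x$logLik))
  invisible(x)
}

#' @export
coef.lognormal_mad <- function(object, ...) c(mu = object$mu, s = object$s)

#' @export
logLik.lognormal_mad <- function(object, ...) {
  structure(object$logLik, df = 2L, class = "logLik")
}
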