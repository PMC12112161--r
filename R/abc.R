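#' Configuration for ABC inference of the SLM parameters
#'
#' Rejection ABC draws `n_draws` parameter pairs {tau, sigma} uniformly from
#' the prior box, simulates the experiment once per draw, and selects the
#' draw whose summary statistic lies closest (Euclidean distance) to the
#' observed one; `n_predictive` further simulations at the selected pair give
#' the posterior-predictive distribution and its 95% interval.
#'
#' @param n_draws number of prior draws (default 1e4).
#' @param tau_range prior bounds for tau in hours; the default upper bound is
#'   the 48 h cycle length, the longest growth timescale of interest.
#' @param sigma_range prior bounds for sigma, inside (0, 2) (stationarity).
#' @param n_predictive number of posterior-predictive simulations (default
#'   1e3).
#' @param summary summary statistic name: `"ks"` (mean KS shift between the
#'   migration-end and final transfers), `"taylor_exponent"`,
#'   `"taylor_t"` (t for the change in Taylor exponent), `"cv_tbar"`,
#'   `"zrho"`, `"slope_change"`, or `"pattern"` (vector of two: the mean
#'   log10 squared CV of relative abundance at the final transfer, which
#'   pins the noise strength, and the mean absolute log10 shift of the MAD
#'   between the migration-end and final transfers, which pins the growth
#'   timescale through the speed of recovery from the migration
#'   perturbation; components are standardized by their spread across
#'   draws). The scalar statistics mirror the classical analyses;
#'   `"pattern"` is the package's composite for joint {tau, sigma}
#'   inference, since a scalar summary cannot pin down two parameters. A
#'   custom function `function(tables) -> numeric` is also accepted.
#' @param seed optional integer seed.
#' @return An object of class `abc_config`.
#' @export
abc_config <- function(n_draws = 10000L, tau_range = c(0.1, 48),
                       sigma_range = c(0.01, 1.9), n_predictive = 1000L,
                       summary = "pattern", seed = NULL) {
  n_draws <- check_count(n_draws, "n_draws")
  n_predictive <- check_count(n_predictive, "n_predictive")
  stopifnot(length(tau_range) == 2L, length(sigma_range) == 2L)
  if (tau_range[1L] <= 0 || diff(tau_range) <= 0)
    stop_invalid("tau_range must be positive and increasing")
  if (sigma_range[1L] <= 0 || sigma_range[2L] >= 2 || diff(sigma_range) <= 0)
    stop_invalid("sigma_range must lie inside (0, 2) and be increasing")
  structure(list(n_draws = n_draws, tau_range = tau_range,
                 sigma_range = sigma_range, n_predictive = n_predictive,
                 summary = summary, seed = seed),
            class = "abc_config")
}

# named summary statistics computed from simulated experiment tables ---------

summary_needs_pair <- function(summary) {
  is.character(summary) && summary %in% c("zrho", "slope_change")
}

summary_cycles <- function(summary, design) {
  if (is.character(summary) && summary == "cv_tbar")
    seq(max(1L, design$migration_end - 5L), design$n_cycles)
  else unique(c(design$migration_end, design$n_cycles))
}

# tables: list with $main (treatment of interest) and optionally $none
# (paired no-migration run); prog passed for slope summaries
compute_summary <- function(summary, tables, design, prog = NULL) {
  k_mig <- design$migration_end
  k_end <- design$n_cycles
  ct <- tables$main
  if (is.function(summary)) return(summary(tables))
  switch(summary,
    ks = mean_ks_shift(subset_table(ct, transfer = k_mig),
                       subset_table(ct, transfer = k_end))$mean_ks,
    taylor_exponent = fit_taylor_table(subset_table(ct, transfer = k_end))$exponent,
    taylor_t = {
      fb <- fit_taylor_table(subset_table(ct, transfer = k_mig))
      fa <- fit_taylor_table(subset_table(ct, transfer = k_end))
      (fa$exponent - fb$exponent) /
        sqrt(fa$se["exponent"]^2 + fb$se["exponent"]^2)
    },
    cv_tbar = {
      cv <- cv_across_replicates(ct)
      before <- (k_mig - 5L):k_mig
      after <- (k_mig + 1L):k_end
      cols <- as.integer(colnames(cv))
      welch <- function(v) {
        a <- v[cols %in% after]; b <- v[cols %in% before]
        a <- a[is.finite(a)]; b <- b[is.finite(b)]
        if (length(a) < 2L || length(b) < 2L) return(NA_real_)
        (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
      }
      mean(apply(cv, 1L, welch), na.rm = TRUE)
    },
    zrho = {
      rb <- mad_correlation(mean_abundances(subset_table(tables$main, transfer = k_mig)),
                            mean_abundances(subset_table(tables$none, transfer = k_mig)))
      ra <- mad_correlation(mean_abundances(subset_table(tables$main, transfer = k_end)),
                            mean_abundances(subset_table(tables$none, transfer = k_end)))
      fisher_z_shift(rb, ra, design$M, design$M)
    },
    slope_change = {
      ratio_at <- function(k) {
        a <- mean_abundances(subset_table(tables$main, transfer = k))
        b <- mean_abundances(subset_table(tables$none, transfer = k))
        shared <- intersect(names(a)[a > 0], names(b)[b > 0])
        setNames(a[shared] / b[shared], shared)
      }
      slope_change_test(ratio_at(k_mig), ratio_at(k_end),
                        prog$abundances, n_perm = 1L)$t
    },
    pattern = {
      ct_mig <- subset_table(ct, transfer = k_mig)
      ct_end <- subset_table(ct, transfer = k_end)
      x <- relative_abundance(ct_end)
      m <- rowMeans(x); v <- apply(x, 1L, var)
      ok <- m > 0 & v > 0
      m_mig <- mean_abundances(ct_mig)
      m_end <- mean_abundances(ct_end)
      both <- m_mig > 0 & m_end > 0
      c(log_cv2 = mean(log10(v[ok] / m[ok]^2)),
        mad_shift = mean(abs(log10(m_end[both] / m_mig[both]))))
    },
    stop_invalid("unknown summary statistic: ", summary)
  )
}

#' Compute an ABC summary statistic from community tables
#'
#' Evaluates one of the named summary statistics (see [abc_config()]) on an
#' observed or simulated [community_table()]. This is how the `observed`
#' argument of [slm_abc()] is produced from data.
#'
#' @param summary summary name or function, as in [abc_config()].
#' @param tables a [community_table()], or a named list with elements `main`
#'   and (for the paired statistics `"zrho"` and `"slope_change"`) `none`.
#' @param design the [transfer_design()] the table came from (fixes which
#'   transfers are compared).
#' @param prog progenitor profile, needed by `"slope_change"`.
#' @return Numeric summary value(s).
#' @export
abc_summary <- function(summary, tables, design, prog = NULL) {
  if (inherits(tables, "community_table")) tables <- list(main = tables)
  compute_summary(summary, tables, design, prog)
}

simulate_summary <- function(summary, tau, sigma, design, params_template,
                             treatment, prog, depths, steps_per_tau, seed) {
  params <- slm_params(params_template$K, tau = tau, sigma = sigma)
  config <- integrator_config(dt = tau / steps_per_tau)
  cycles <- summary_cycles(summary, design)
  tables <- list(main = simulate_experiment(design, params, treatment, prog,
                                            depths, config, cycles,
                                            seed = seed))
  if (summary_needs_pair(summary))
    tables$none <- simulate_experiment(design, params, "none", prog, depths,
                                       config, cycles,
                                       seed = sub_seed(seed, 777L))
  compute_summary(summary, tables, design, prog)
}

#' Infer SLM parameters {tau, sigma} by rejection ABC
#'
#' The central fitting function of the package. For each of `n_draws` uniform
#' prior draws of the growth timescale tau and the environmental noise
#' strength sigma (applied uniformly across ASVs), the transfer-cycle
#' experiment is simulated and the configured summary statistic computed; the
#' draw minimizing the Euclidean distance to the observed summary is selected
#' (ties broken by lowest draw index). `n_predictive` simulations at the
#' selected pair form the posterior-predictive distribution of the summary
#' with its 95% interval. Vector summaries are standardized component-wise by
#' their median absolute deviation across draws before distances are taken.
#'
#' @param observed observed summary value(s), finite.
#' @param config an [abc_config()].
#' @param design a [transfer_design()].
#' @param params_template an [slm_params()] object supplying the carrying
#'   capacities; tau and sigma are overridden by each draw.
#' @param treatment the simulated treatment (`"none"`, `"regional"`,
#'   `"global"`).
#' @param prog a `progenitor_profile`.
#' @param depths a [depth_model()].
#' @param steps_per_tau Euler-Maruyama resolution: `dt = tau / steps_per_tau`
#'   (default 100, i.e. dt = tau/100).
#' @param seed optional integer seed controlling all randomness.
#' @return An object of class `slm_abc`.
#' @export
slm_abc <- function(observed, config, design, params_template,
                    treatment = "regional", prog, depths = depth_model(),
                    steps_per_tau = 100, seed = NULL) {
  stopifnot(inherits(config, "abc_config"))
  if (any(!is.finite(observed)))
    stop_invalid("observed summary must be finite")
  seed <- seed %||% config$seed %||% 1L
  check_count(steps_per_tau, "steps_per_tau", lower = 10L)
  n <- config$n_draws
  with_seed(seed, {
    tau <- runif(n, config$tau_range[1L], config$tau_range[2L])
    sigma <- runif(n, config$sigma_range[1L], config$sigma_range[2L])
  })
  sims <- matrix(NA_real_, nrow = n, ncol = length(observed))
  for (i in seq_len(n)) {
    s <- try(simulate_summary(config$summary, tau[i], sigma[i], design,
                              params_template, treatment, prog, depths,
                              steps_per_tau, seed = sub_seed(seed, i)),
             silent = TRUE)
    if (!inherits(s, "try-error") && length(s) == length(observed))
      sims[i, ] <- s
  }
  ok <- apply(is.finite(sims), 1L, all)
  if (!any(ok)) stop_invalid("no simulation produced the summary statistic")
  scale <- apply(sims[ok, , drop = FALSE], 2L, function(v)
    max(stats::mad(v), 1e-12))
  dist <- rep(Inf, n)
  dist[ok] <- sqrt(colSums(((t(sims[ok, , drop = FALSE]) - observed) /
                              scale)^2))
  sel <- which.min(dist)  # which.min takes the first minimum: lowest index
  pred <- matrix(NA_real_, nrow = config$n_predictive,
                 ncol = length(observed))
  for (j in seq_len(config$n_predictive)) {
    s <- try(simulate_summary(config$summary, tau[sel], sigma[sel], design,
                              params_template, treatment, prog, depths,
                              steps_per_tau,
                              seed = sub_seed(seed, n + j)),
             silent = TRUE)
    if (!inherits(s, "try-error") && length(s) == length(observed))
      pred[j, ] <- s
  }
  ci95 <- apply(pred, 2L, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(observed = observed,
                 draws = data.frame(tau = tau, sigma = sigma,
                                    distance = dist),
                 summaries = sims,
                 selected = c(tau = tau[sel], sigma = sigma[sel]),
                 selected_index = sel,
                 predictive = pred, ci95 = ci95,
                 config = config, treatment = treatment, seed = seed),
            class = "slm_abc")
}

#' @export
print.slm_abc <- function(x, ...) {
  cat("ABC fit of the SLM (", x$config$n_draws, "prior draws,",
      x$treatment, "treatment )\n")
  cat(sprintf("  selected tau = %.3f h, sigma = %.3f (min distance %.4g)\n",
              x$selected["tau"], x$selected["sigma"],
              min(x$draws$distance)))
  cat("  posterior-predictive 95% interval per summary component:\n")
  print(signif(x$ci95, 4))
  invisible(x)
}

#' @export
coef.slm_abc <- function(object, ...) object$selected

#' @export
summary.slm_abc <- function(object, ...) {
  list(selected = object$selected,
       observed = object$observed,
       ci95 = object$ci95,
       inside_ci = predictive_check(object)$inside_ci,
       n_draws = object$config$n_draws,
       n_effective = sum(is.finite(object$draws$distance)))
}

#' @export
plot.slm_abc <- function(x, component = 1L, ...) {
  p <- x$predictive[, component]
  hist(p[is.finite(p)], breaks = 30, col = "grey80", border = "white",
       main = "Posterior-predictive distribution",
       xlab = "summary statistic", ...)
  abline(v = x$observed[component], col = "firebrick", lwd = 2)
  abline(v = x$ci95[, component], col = "grey30", lty = 2)
  invisible(x)
}

#' Simulate from a fitted ABC object
#'
#' Draws posterior-predictive summary statistics by re-simulating the
#' experiment at the selected {tau, sigma}.
#'
#' @param object an [slm_abc()] fit.
#' @param nsim number of simulations.
#' @param seed optional integer seed.
#' @param design,params_template,prog,depths,steps_per_tau simulation inputs,
#'   as in [slm_abc()].
#' @param ... unused.
#' @return Matrix of simulated summaries (nsim x components).
#' @export
simulate.slm_abc <- function(object, nsim = 1L, seed = NULL, design,
                             params_template, prog, depths = depth_model(),
                             steps_per_tau = 100, ...) {
  seed <- seed %||% object$seed
  out <- matrix(NA_real_, nsim, length(object$observed))
  for (j in seq_len(nsim))
    out[j, ] <- simulate_summary(object$config$summary,
                                 object$selected["tau"],
                                 object$selected["sigma"], design,
                                 params_template, object$treatment, prog,
                                 depths, steps_per_tau,
                                 seed = sub_seed(seed, 5e5 + j))
  out
}

#' Posterior-predictive interval check
#'
#' @param result an [slm_abc()] fit.
#' @param observed observed summary (defaults to the one stored in the fit).
#' @return List with `inside_ci` (TRUE iff every component of the observed
#'   summary lies inside its 95% predictive interval) and the interval.
#' @export
predictive_check <- function(result, observed = NULL) {
  stopifnot(inherits(result, "slm_abc"))
  obs <- observed %||% result$observed
  inside <- all(obs >= result$ci95[1L, ] & obs <= result$ci95[2L, ])
  list(inside_ci = inside, ci95 = result$ci95, observed = obs)
}

#' Grid scan of simulation error over {tau, sigma}
#'
#' For every grid cell, simulates the experiment `n_reps` times, computes the
#' summary statistic, and reports the mean relative error
#' `|sim - observed| / |observed|` (mean absolute error, flagged, when
#' `observed = 0`; for vector summaries the Euclidean norm is used).
#'
#' @param tau_grid,sigma_grid grid values (non-empty).
#' @param n_reps simulations per cell (>= 1).
#' @param observed observed summary value(s).
#' @param design,params_template,treatment,prog,depths,steps_per_tau,summary
#'   as in [slm_abc()].
#' @param seed optional integer seed.
#' @return Object of class `slm_grid`: list with `error` (tau x sigma
#'   matrix), the grids, and `metric` (`"relative"` or `"absolute"`).
#' @export
grid_scan <- function(tau_grid, sigma_grid, n_reps, observed, design,
                      params_template, treatment = "regional", prog,
                      depths = depth_model(), summary = "pattern",
                      steps_per_tau = 100, seed = NULL) {
  if (length(tau_grid) == 0L || length(sigma_grid) == 0L)
    stop_invalid("parameter grids must be non-empty")
  n_reps <- check_count(n_reps, "n_reps")
  seed <- seed %||% 1L
  denom <- sqrt(sum(observed^2))
  metric <- if (denom > 0) "relative" else "absolute"
  err <- matrix(NA_real_, length(tau_grid), length(sigma_grid),
                dimnames = list(signif(tau_grid, 4), signif(sigma_grid, 4)))
  idx <- 0L
  for (a in seq_along(tau_grid)) for (b in seq_along(sigma_grid)) {
    e <- vapply(seq_len(n_reps), function(r) {
      idx <<- idx + 1L
      s <- simulate_summary(summary, tau_grid[a], sigma_grid[b], design,
                            params_template, treatment, prog, depths,
                            steps_per_tau, seed = sub_seed(seed, idx))
      d <- sqrt(sum((s - observed)^2))
      if (metric == "relative") d / denom else d
    }, numeric(1))
    err[a, b] <- mean(e, na.rm = TRUE)
  }
  structure(list(error = err, tau_grid = tau_grid, sigma_grid = sigma_grid,
                 metric = metric, summary = summary),
            class = "slm_grid")
}

#' @export
print.slm_grid <- function(x, ...) {
  cat("Grid scan of", x$metric, "error (tau rows x sigma columns):\n")
  print(signif(x$error, 3))
  invisible(x)
}

#' @export
plot.slm_grid <- function(x, ...) {
  image(x$tau_grid, x$sigma_grid, x$error, xlab = "tau (h)",
        ylab = "sigma", main = paste("Mean", x$metric, "error"), ...)
  invisible(x)
}
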