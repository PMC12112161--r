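test_that("MAD correlations behave at the exact limits", {
  m <- setNames(10^seq(-4, -1, length.out = 10), paste0("a", 1:10))
  expect_equal(mad_correlation(m, m), 1)
  expect_equal(mad_correlation(m, 1 / m), -1)
  set.seed(1)
  a <- setNames(rlnorm(1000, -5, 1), paste0("x", 1:1000))
  b <- setNames(rlnorm(1000, -5, 1), paste0("x", 1:1000))
  expect_lt(abs(mad_correlation(a, b)), 0.1)
  expect_error(mad_correlation(m[1:3], m[1:3]), "at least 4")
})

test_that("Fisher's Z shift matches its closed form and guards its domain", {
  expect_equal(fisher_z_shift(0.5, 0.5, 20, 20), 0)
  # atanh transform: (atanh(.8) - atanh(.2)) / sqrt(2/27)
  z <- (atanh(0.8) - atanh(0.2)) / sqrt(1 / 27 + 1 / 27)
  expect_equal(fisher_z_shift(0.2, 0.8, 30, 30), z, tolerance = 1e-12)
  expect_equal(z, 3.29, tolerance = 0.01)
  # the as-printed full-log variant is exactly twice the half-log one
  expect_equal(fisher_z_shift(0.2, 0.8, 30, 30, half = FALSE), 2 * z)
  expect_error(fisher_z_shift(0.2, 0.8, 3, 30), "M_before")
  expect_error(fisher_z_shift(1, 0.5, 30, 30), "rho")
})

test_that("Fisher's Z shift holds its nominal type-I error under the null", {
  # equal true correlation at both time points: |Z| > 1.96 should occur ~5%
  set.seed(2)
  M <- 30; rho <- 0.5
  rej <- replicate(1000, {
    mk <- function() {
      x <- rnorm(M); y <- rho * x + sqrt(1 - rho^2) * rnorm(M)
      cor(x, y)
    }
    abs(fisher_z_shift(mk(), mk(), M, M)) > 1.96
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("progenitor-dependence slopes match closed-form OLS with valid permutation p", {
  nm <- paste0("a", 1:20)
  prog_ab <- setNames(10^seq(-6, -2, length.out = 20), nm)
  # flat ratios: zero slope
  flat <- setNames(rep(2, 20), nm)
  r0 <- progenitor_slope(flat + rnorm(20, sd = 1e-9), prog_ab, n_perm = 99,
                         seed = 3)
  expect_lt(abs(r0$slope), 1e-6)
  # exact linear relation: minimum achievable p = 1/(n_perm + 1)
  ratio <- setNames(prog_ab^0.5, nm)
  r1 <- suppressWarnings(progenitor_slope(ratio, prog_ab, n_perm = 999, seed = 4))
  expect_equal(r1$slope, 0.5, tolerance = 1e-10)
  expect_equal(r1$test$p, 1 / 1000)
  # closed-form normal equations oracle
  set.seed(5)
  ratio2 <- setNames(rlnorm(20, 0, 0.5), nm)
  r2 <- progenitor_slope(ratio2, prog_ab, n_perm = 9, seed = 6)
  lx <- log10(prog_ab); ly <- log10(ratio2)
  slope_cf <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  expect_equal(r2$slope, slope_cf, tolerance = 1e-12)
  expect_error(progenitor_slope(ratio, setNames(rep(1e-3, 20), nm)),
               "degenerate")
})

test_that("slope-change permutation test detects constructed shifts only", {
  nm <- paste0("a", 1:24)
  prog_ab <- setNames(10^seq(-6, -2, length.out = 24), nm)
  set.seed(7)
  noisy <- setNames(rlnorm(24, 0, 0.2), nm)
  same <- slope_change_test(noisy, noisy, prog_ab, n_perm = 199, seed = 8)
  expect_equal(same$t, 0, tolerance = 1e-10)
  expect_gt(same$test$p, 0.5)
  # strong slope before, none after
  before <- setNames(prog_ab^0.8 * rlnorm(24, 0, 0.05), nm)
  after <- setNames(rlnorm(24, 0, 0.05), nm)
  shift <- slope_change_test(before, after, prog_ab, n_perm = 199, seed = 9)
  expect_lte(shift$test$p, 0.02)
  expect_error(slope_change_test(before, after, prog_ab, n_perm = 0), "n_perm")
})

test_that("log-ratios are exact on constructed series and missing at zeros", {
  # relative abundance doubling each transfer: delta_ell = ln 2 each step
  a <- 1000L * 2L^(0:3)
  counts <- rbind(a = a, b = 1000000L - a)  # constant depth, exact ratios
  meta <- data.frame(sample_id = paste0("s", 1:4), treatment = "none",
                     transfer = 1:4, replicate = 1L)
  ct <- community_table(counts, meta)
  d <- delta_ell(ct)
  expect_equal(unname(d["a", ]), rep(log(2), 3), tolerance = 1e-12)
  # constant abundances give zero log-ratio
  ctc <- community_table(rbind(a = rep(500L, 4), b = rep(1500L, 4)), meta)
  expect_true(all(delta_ell(ctc) == 0))
  # zero at either endpoint -> missing, not zero
  counts2 <- counts; counts2["a", 2] <- 0
  ct2 <- community_table(counts2, meta)
  d2 <- delta_ell(ct2)
  expect_true(is.na(d2["a", 1]) && is.na(d2["a", 2]))
  expect_false(anyNA(d2["b", ]))
  expect_error(delta_ell(community_table(counts[, c(1, 3)], meta[c(1, 3), ])),
               "consecutive")
})

test_that("across-replicate CV shift test calibrates and detects", {
  make_ct <- function(seed, inflate_after = 1) {
    set.seed(seed)
    S <- 6; M <- 5; transfers <- 7:13
    counts <- NULL; meta <- NULL
    base <- 10^seq(-3, -1, length.out = S)
    for (k in transfers) for (m in 1:M) {
      sdl <- 0.2 * if (k >= 11) inflate_after else 1
      x <- base * rlnorm(S, 0, sdl)
      counts <- cbind(counts, rmultinom(1, 5e4, x / sum(x)))
      meta <- rbind(meta, data.frame(sample_id = sprintf("k%dm%d", k, m),
                                     treatment = "none", transfer = k,
                                     replicate = m))
    }
    rownames(counts) <- paste0("a", 1:S)
    community_table(counts, meta)
  }
  ct <- make_ct(10)
  cv <- cv_across_replicates(ct)
  expect_identical(dim(cv), c(6L, 6L))
  expect_true(all(cv[is.finite(cv)] >= 0))
  res <- cv_shift_test(cv, before = 7:9, after = 10:12, n_perm = 99, seed = 11)
  expect_true(is.finite(res$t_bar))
  expect_true(res$test$p > 0 && res$test$p <= 1)
  # CVs inflated for every ASV in the after window: detected at small p
  set.seed(12)
  cv_null <- matrix(abs(rnorm(8 * 10, 1, 0.15)), nrow = 8,
                    dimnames = list(paste0("a", 1:8), NULL))
  colnames(cv_null) <- as.character(7:16)
  cv_alt <- cv_null
  cv_alt[, as.character(12:16)] <- cv_alt[, as.character(12:16)] * 2
  det <- cv_shift_test(cv_alt, before = 7:11, after = 12:16, n_perm = 999,
                       seed = 13)
  expect_lte(det$test$p, 0.01)
  expect_error(cv_shift_test(cv, before = 100:101, after = 7:9), "window")
})

test_that("permutation machinery is calibrated under exchangeability", {
  # type-I error of the CV shift test at alpha = 0.2 over repeated null runs
  set.seed(14)
  rej <- replicate(120, {
    cv <- matrix(abs(rnorm(6 * 8, 1, 0.3)), nrow = 6,
                 dimnames = list(paste0("a", 1:6), NULL))
    colnames(cv) <- as.character(5:12)
    r <- cv_shift_test(cv, before = 5:8, after = 9:12, n_perm = 49)
    r$test$p <= 0.2
  })
  binom_se <- sqrt(0.2 * 0.8 / 120)
  expect_lt(abs(mean(rej) - 0.2), 4 * binom_se)
  # add-one convention: p is never zero and never above 1
  expect_true(all(replicate(20, {
    cv <- matrix(abs(rnorm(12, 1, 0.2)), nrow = 2,
                 dimnames = list(c("a", "b"), as.character(1:6)))
    p <- cv_shift_test(cv, before = 1:3, after = 4:6, n_perm = 19)$test$p
    p > 0 && p <= 1
  })))
})

test_that("F_CV matches its formula, symmetry and degenerate limits", {
  expect_equal(f_cv(0.3, 0.3, 6, 6), 1)
  # direct formula evaluation
  f <- (0.2^2 / (1 + 0.2^2 * 5 / 6)) * ((1 + 0.1^2 * 5 / 6) / 0.1^2)
  expect_equal(f_cv(0.1, 0.2, 6, 6), f)
  expect_equal(f, 3.903, tolerance = 1e-3)
  # swapping windows inverts the statistic
  expect_equal(f_cv(0.2, 0.1, 6, 6), 1 / f_cv(0.1, 0.2, 6, 6))
  expect_equal(f_cv(0.15, 0.4, 5, 9) * f_cv(0.4, 0.15, 9, 5), 1)
  expect_error(f_cv(0, 0.2, 6, 6), "cv_before")
  expect_error(f_cv(0.1, 0.2, 1, 6), "M_lt")
})

test_that("constrained KS test preserves ASV identity in its null", {
  nm <- rep(paste0("a", 1:10), each = 4)
  set.seed(15)
  fa <- data.frame(asv = nm, f_cv = rlnorm(40, 0, 0.5))
  # identical distributions: KS = 0 on itself, p not small on a copy
  same <- constrained_ks_test(fa, fa, n_perm = 99, seed = 16)
  expect_equal(same$ks, 0)
  expect_gt(same$test$p, 0.9)
  # disjoint supports: KS = 1, minimum p
  fb <- data.frame(asv = nm, f_cv = rlnorm(40, 5, 0.5))
  diffr <- constrained_ks_test(fa, fb, n_perm = 199, seed = 17)
  expect_equal(diffr$ks, 1)
  expect_equal(diffr$test$p, 1 / 200)
  expect_error(constrained_ks_test(fa, data.frame(asv = "zz", f_cv = 1)),
               "shared")
})

test_that("within-replicate F_CV tables flow from simulated experiments", {
  prog <- small_progenitor()
  params <- small_params(sigma = 0.6)
  des <- small_design(M = 4L, n_cycles = 8L, migration_end = 4L)
  ct <- simulate_experiment(des, params, "global", prog,
                            depths = depth_model(20000L),
                            config = integrator_config(dt = 0.05),
                            sequenced_cycles = 1:8, seed = 18)
  tab <- f_cv_table(ct, before = 1:4, after = 5:8)
  expect_true(all(c("asv", "replicate", "cv_before", "cv_after", "f_cv")
                  %in% names(tab)))
  ok <- is.finite(tab$f_cv)
  expect_gt(sum(ok), 0)
  expect_true(all(tab$f_cv[ok] > 0))
})
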