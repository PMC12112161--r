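#' Generate a synthetic progenitor community profile
#'
#' Draws `S` relative abundances from a lognormal distribution — the same form
#' the mean abundance distribution (MAD) of assembled communities follows —
#' and normalizes them to sum to one. The progenitor is the soil-derived
#' source community used to inoculate every replicate microcosm and to supply
#' regional (mainland-island) migrants; its richness is typically ~100-fold
#' larger than that of an assembled community.
#'
#' @param S richness (number of ASVs), a positive integer.
#' @param mad_location location of the generating lognormal on the natural-log
#'   scale. The default, with `mad_scale`'s default, spans more than four
#'   orders of magnitude of relative abundance at `S = 5000`.
#' @param mad_scale scale (natural-log standard deviation) of the generating
#'   lognormal; must be positive.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `progenitor_profile`: a list with elements
#'   `abundances` (named numeric vector summing to 1) and `S`.
#' @examples
#' prog <- generate_progenitor(100, seed = 1)
#' sum(prog$abundances)
#' @export
generate_progenitor <- function(S, mad_location = -log(5000) - 2.5^2 / 2,
                                mad_scale = 2.5, seed = NULL) {
  S <- check_count(S, "S")
  check_scalar(mad_scale, "mad_scale", lower = 0, strict_lower = TRUE)
  check_scalar(mad_location, "mad_location")
  with_seed(seed, {
    raw <- rlnorm(S, meanlog = mad_location, sdlog = mad_scale)
    ab <- raw / sum(raw)
    names(ab) <- sprintf("ASV%04d", seq_len(S))
    structure(list(abundances = ab, S = S), class = "progenitor_profile")
  })
}

#' @export
print.progenitor_profile <- function(x, ...) {
  cat("Progenitor community profile\n")
  cat("  richness S:", x$S, "\n")
  cat("  log10 abundance range:",
      sprintf("[%.2f, %.2f]", log10(min(x$abundances)),
              log10(max(x$abundances))), "\n")
  invisible(x)
}

#' Logistic presence model for descendant communities
#'
#' The probability that an ASV from the progenitor establishes (receives a
#' nonzero carrying capacity) in assembled communities increases with its
#' progenitor relative abundance and is modeled as a logistic regression on
#' log10 abundance. Defaults are chosen so that roughly 1% of progenitor ASVs
#' establish, matching the ~100-fold richness drop from progenitor to
#' descendant communities.
#'
#' @param intercept log-odds of presence at log10 abundance 0.
#' @param slope log-odds change per unit log10 progenitor abundance; `>= 0`
#'   makes presence monotone non-decreasing in abundance.
#' @return An object of class `presence_model`.
#' @export
presence_model <- function(intercept = 5, slope = 2.5) {
  check_scalar(intercept, "intercept")
  check_scalar(slope, "slope")
  structure(list(intercept = intercept, slope = slope),
            class = "presence_model")
}

#' Presence probability under a logistic presence model
#'
#' @param model a [presence_model()].
#' @param log10_abundance vector of log10 progenitor relative abundances.
#' @return Probabilities in (0, 1).
#' @export
presence_prob <- function(model, log10_abundance) {
  stopifnot(inherits(model, "presence_model"))
  plogis(model$intercept + model$slope * log10_abundance)
}

#' Assign per-ASV SLM parameters conditional on a progenitor profile
#'
#' Each progenitor ASV establishes with probability given by the logistic
#' presence model evaluated at its log10 progenitor abundance. Established
#' ASVs draw a carrying capacity `K` from a lognormal distribution
#' (independent of progenitor abundance, conditional on presence — observed
#' progenitor abundance shows essentially no correlation with descendant mean
#' abundance); non-established ASVs get `K = 0`. The noise strength `sigma`
#' and growth timescale `tau` are constant across ASVs, the choice implied by
#' Taylor's Law holding with exponent two.
#'
#' @param prog a [generate_progenitor()] profile.
#' @param presence a [presence_model()].
#' @param mad_location,mad_scale lognormal parameters for `K` of established
#'   ASVs (natural-log scale). The default location centres the sum of
#'   carrying capacities near one for ~50 surviving ASVs.
#' @param sigma environmental noise strength, in (0, 2) for stationarity.
#' @param tau growth timescale (same time units as the cycle length), > 0.
#' @param seed optional integer seed.
#' @return An [slm_params()] object with one entry per progenitor ASV.
#' @export
assign_slm_params <- function(prog, presence = presence_model(),
                              mad_location = log(0.02), mad_scale = 1,
                              sigma = 0.5, tau = 1, seed = NULL) {
  stopifnot(inherits(prog, "progenitor_profile"))
  check_scalar(sigma, "sigma", lower = 0, upper = 2,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(tau, "tau", lower = 0, strict_lower = TRUE)
  check_scalar(mad_scale, "mad_scale", lower = 0, strict_lower = TRUE)
  with_seed(seed, {
    p <- presence_prob(presence, log10(prog$abundances))
    present <- runif(prog$S) < p
    K <- numeric(prog$S)
    K[present] <- rlnorm(sum(present), meanlog = mad_location,
                         sdlog = mad_scale)
    names(K) <- names(prog$abundances)
    slm_params(K = K, tau = tau, sigma = sigma)
  })
}

#' Read-depth model
#'
#' Total read counts per sample are drawn from an empirical list of admissible
#' depths (uniformly, with replacement). The default is a discrete uniform
#' over 5,000..20,000 reads, a realistic range for 16S amplicon libraries; any
#' user-supplied vector of depths is used verbatim.
#'
#' @param depths vector of positive integer total read counts.
#' @return An object of class `depth_model`.
#' @export
depth_model <- function(depths = 5000:20000) {
  if (length(depths) == 0L)
    stop_invalid("depth model must contain at least one depth")
  if (any(!is.finite(depths)) || any(depths <= 0) || any(depths != round(depths)))
    stop_invalid("all depths must be positive integers")
  structure(list(depths = as.integer(depths)), class = "depth_model")
}

#' Sample sequencing depths from a depth model
#'
#' @param n number of depths to draw (positive integer).
#' @param model a [depth_model()].
#' @param seed optional integer seed.
#' @return Integer vector of `n` i.i.d. depths.
#' @export
sample_read_depths <- function(n, model = depth_model(), seed = NULL) {
  n <- check_count(n, "n")
  stopifnot(inherits(model, "depth_model"))
  with_seed(seed, model$depths[sample.int(length(model$depths), n,
                                          replace = TRUE)])
}

#' Write a progenitor profile as tab-separated text
#'
#' Two columns: ASV id and relative abundance.
#' @param prog a `progenitor_profile`.
#' @param path output file path.
#' @export
write_progenitor <- function(prog, path) {
  stopifnot(inherits(prog, "progenitor_profile"))
  df <- data.frame(asv = names(prog$abundances),
                   abundance = unname(prog$abundances))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a progenitor profile written by [write_progenitor()]
#' @param path input file path.
#' @return A `progenitor_profile`.
#' @export
read_progenitor <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ab <- setNames(df$abundance, df$asv)
  if (any(ab <= 0)) stop_invalid("progenitor abundances must be positive")
  ab <- ab / sum(ab)
  structure(list(abundances = ab, S = length(ab)),
            class = "progenitor_profile")
}
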