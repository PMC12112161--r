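# File formats, run configuration and the pipeline entry point.
# Count tables are plain tab-separated text (ASV x sample) with a companion
# metadata table; configs and manifests are YAML.

#' Write a community table to tab-separated text
#'
#' @param ct a [community_table()].
#' @param counts_path path for the ASV x sample count matrix (first column
#'   `asv`, header row of sample ids).
#' @param meta_path path for the metadata table (`sample_id`, `treatment`,
#'   `transfer`, `replicate`, `depth`).
#' @export
write_community_table <- function(ct, counts_path, meta_path) {
  stopifnot(inherits(ct, "community_table"))
  df <- data.frame(asv = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ct$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}

#' Read an ASV count table with metadata
#'
#' Expects a tab-separated matrix whose first column holds ASV ids and whose
#' header row holds sample ids, plus a metadata table with `sample_id`,
#' `treatment`, `transfer` and `replicate` columns. Counts must be
#' non-negative integers; metadata is joined by sample id and depths are the
#' column sums.
#'
#' @param counts_path,meta_path input paths.
#' @return A [community_table()].
#' @export
read_asv_table <- function(counts_path, meta_path) {
  df <- read.delim(counts_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_invalid("count table needs an ASV column and samples")
  counts <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop_invalid("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  rownames(counts) <- df[[1L]]
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(colnames(counts) %in% meta$sample_id))
    stop_invalid("metadata is missing samples present in the count table")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  community_table(counts, meta)
}

#' Write SLM parameters as tab-separated text
#'
#' Four columns: ASV id, K, tau, sigma.
#' @param params an [slm_params()] object.
#' @param path output path.
#' @export
write_slm_params <- function(params, path) {
  stopifnot(inherits(params, "slm_params"))
  df <- data.frame(asv = names(params$K), K = unname(params$K),
                   tau = params$tau, sigma = params$sigma)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SLM parameters written by [write_slm_params()]
#' @param path input path.
#' @return An [slm_params()] object.
#' @export
read_slm_params <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  slm_params(setNames(df$K, df$asv), df$tau, df$sigma)
}

#' Assemble a run configuration
#'
#' Every field is either explicitly set or a documented default; the full
#' configuration is serialized verbatim into each run's manifest so outputs
#' can be reproduced bit-identically.
#'
#' @param design a [transfer_design()].
#' @param integrator an [integrator_config()].
#' @param abc an [abc_config()].
#' @param out_dir output directory for pipeline stages.
#' @param seed integer seed for the run.
#' @param ... additional named fields (e.g., `S`, `treatment`, input paths)
#'   stored verbatim.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = transfer_design(),
                       integrator = integrator_config(),
                       abc = abc_config(), out_dir = ".", seed = 1L, ...) {
  structure(list(design = design, integrator = integrator, abc = abc,
                 out_dir = out_dir, seed = check_count(seed, "seed", 0L),
                 extra = list(...)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the [transfer_design()], [integrator_config()] and
#' [abc_config()] field names under `design:`, `integrator:` and `abc:`;
#' unknown top-level keys are kept as extra fields.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(transfer_design, y$design %||% list())
  integrator <- do.call(integrator_config, y$integrator %||% list())
  abc <- do.call(abc_config, y$abc %||% list())
  extra <- y[setdiff(names(y), c("design", "integrator", "abc", "out_dir",
                                 "seed"))]
  do.call(run_config, c(list(design = design, integrator = integrator,
                             abc = abc, out_dir = y$out_dir %||% ".",
                             seed = y$seed %||% 1L), extra))
}

write_manifest <- function(config, command, path) {
  man <- list(command = command,
              package = "slmeco",
              version = as.character(packageVersion("slmeco")),
              seed = config$seed,
              design = unclass(config$design),
              integrator = unclass(config$integrator),
              abc = unclass(config$abc[setdiff(names(config$abc), "summary")]),
              summary = if (is.character(config$abc$summary))
                config$abc$summary else "custom",
              extra = config$extra)
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Executes one named stage with logged seeds and a YAML manifest written
#' next to the outputs:
#' * `generate`: progenitor profile and SLM parameters (TSV).
#' * `simulate`: a simulated experiment (`counts.tsv`, `meta.tsv`).
#' * `patterns`: gamma AFD, Taylor, truncated-lognormal MAD and occupancy
#'   tables for an input count table.
#' * `migration-stats`: across-replicate CV matrix and per-replicate F_CV
#'   table.
#' * `abc`: ABC fit report (YAML) plus predictive samples (TSV).
#'
#' @param config a [run_config()]. For `simulate`/`abc`, the extra fields
#'   `treatment` (default `"none"`) and `S` (progenitor richness, default
#'   5000) are honoured; for `patterns`/`migration-stats`/`abc`,
#'   `counts_path`/`meta_path` point at the input table (defaulting to the
#'   files `simulate` writes); `abc` additionally uses `observed` (observed
#'   summary value(s), required).
#' @param command one of `"generate"`, `"simulate"`, `"patterns"`,
#'   `"migration-stats"`, `"abc"`.
#' @return Invisibly, a character vector of written files.
#' @export
run_pipeline <- function(config, command = c("generate", "simulate",
                                             "patterns", "migration-stats",
                                             "abc")) {
  stopifnot(inherits(config, "run_config"))
  command <- match.arg(command)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  extra <- config$extra
  treatment <- extra$treatment %||% "none"
  S <- extra$S %||% 5000L
  written <- character()
  gen_inputs <- function() {
    prog <- generate_progenitor(S, seed = config$seed)
    params <- assign_slm_params(prog, seed = sub_seed(config$seed, 1L))
    list(prog = prog, params = params)
  }
  if (command == "generate") {
    g <- gen_inputs()
    write_progenitor(g$prog, out("progenitor.tsv"))
    write_slm_params(g$params, out("slm_params.tsv"))
    written <- c(out("progenitor.tsv"), out("slm_params.tsv"))
  } else if (command == "simulate") {
    g <- gen_inputs()
    ct <- simulate_experiment(config$design, g$params, treatment, g$prog,
                              config = config$integrator,
                              sequenced_cycles = extra$sequenced_cycles,
                              seed = sub_seed(config$seed, 2L))
    write_community_table(ct, out("counts.tsv"), out("meta.tsv"))
    written <- c(out("counts.tsv"), out("meta.tsv"))
  } else {
    counts_path <- extra$counts_path %||% out("counts.tsv")
    meta_path <- extra$meta_path %||% out("meta.tsv")
    if (!file.exists(counts_path) || !file.exists(meta_path))
      stop_invalid("input table not found: ", counts_path)
    ct <- read_asv_table(counts_path, meta_path)
    if (command == "patterns") {
      afd <- gamma_afd_table(ct)
      write.table(afd, out("gamma_afd.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      ty <- fit_taylor_table(ct)
      write.table(data.frame(term = c("intercept", "exponent"),
                             estimate = coef(ty), se = ty$se),
                  out("taylor.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      mad_fit <- fit_truncated_lognormal(afd$mean[afd$mean > 0])
      write.table(data.frame(term = c("mu", "s", "c"),
                             estimate = c(mad_fit$mu, mad_fit$s, mad_fit$c)),
                  out("mad_lognormal.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      occ <- occupancy_curve(ct)
      write.table(occ, out("occupancy.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      written <- out(c("gamma_afd.tsv", "taylor.tsv", "mad_lognormal.tsv",
                       "occupancy.tsv"))
    } else if (command == "migration-stats") {
      cv <- cv_across_replicates(ct)
      write.table(data.frame(asv = rownames(cv), cv, check.names = FALSE),
                  out("cv_across.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      fcv <- f_cv_table(ct)
      write.table(fcv, out("f_cv.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      written <- out(c("cv_across.tsv", "f_cv.tsv"))
    } else {
      if (is.null(extra$observed))
        stop_invalid("abc requires an `observed` summary value in the config")
      g <- gen_inputs()
      fit <- slm_abc(extra$observed, config$abc, config$design, g$params,
                     treatment = extra$treatment %||% "regional",
                     prog = g$prog,
                     steps_per_tau = extra$steps_per_tau %||% 100,
                     seed = sub_seed(config$seed, 3L))
      yaml::write_yaml(list(selected = as.list(fit$selected),
                            observed = as.numeric(fit$observed),
                            ci95 = list(lower = as.numeric(fit$ci95[1L, ]),
                                        upper = as.numeric(fit$ci95[2L, ])),
                            inside_ci = predictive_check(fit)$inside_ci),
                       out("abc_report.yaml"))
      write.table(data.frame(fit$predictive), out("abc_predictive.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      written <- out(c("abc_report.yaml", "abc_predictive.tsv"))
    }
  }
  write_manifest(config, command, out(paste0("manifest_", command, ".yaml")))
  invisible(c(written, out(paste0("manifest_", command, ".yaml"))))
}
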