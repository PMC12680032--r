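#' Write a result table with a reproducibility header
#'
#' Prepends `#`-comment lines recording the package version, seed and a
#' digest of the run configuration, so every output table is
#' self-describing. Readers in this package skip `#` lines.
#'
#' @param df Data frame to write.
#' @param path Output TSV path.
#' @param seed Integer seed used for the producing computation (or `NA`).
#' @param config List echoed (digested) into the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, seed = NA, config = list()) {
  cfg_hash <- substr(.digest_config(config), 1, 12)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# smrlink %s", as.character(packageVersion("smrlink"))),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# config_hash: %s", cfg_hash)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.digest_config <- function(config) {
  # execution details (where results land) do not affect what was computed
  config$outdir <- NULL
  config$overwrite <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Default run configuration
#'
#' Nested configuration for [run_pipeline()], overridable from a YAML file
#' and/or named arguments (flags win over YAML, YAML over defaults).
#'
#' @return Nested list with `seed`, `outdir`, and per-stage blocks
#'   `simulate`, `qc`, `correlate`, `massresponse`.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "smrlink_out",
    overwrite = FALSE,
    simulate = list(preset = "default",
                    drug = list(n_cells = 1000, sensitivity = "sensitive",
                                mass_reduction_fraction = 0.20)),
    qc = list(min_total_reads = 1000, max_mito_fraction = 0.20,
              min_expressing_fraction = 0.10),
    correlate = list(scale = 10000, z_threshold = 2.5,
                     z_method = "standardize", n_iter = 1000,
                     percentile = 0.95),
    massresponse = list(n_boot = 10000, alpha = 0.05,
                        alternative = "greater", policy = "quantile"))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration from YAML with overrides
#'
#' @param yaml_path Optional YAML file with any subset of the fields of
#'   [default_run_config()].
#' @param overrides Named list applied on top of the YAML values.
#' @return The merged configuration list.
#' @export
load_run_config <- function(yaml_path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) {
      stop("config file not found: ", yaml_path, call. = FALSE)
    }
    cfg <- .merge_config(cfg, yaml::read_yaml(yaml_path))
  }
  .merge_config(cfg, overrides)
}

#' Run the analysis pipeline end-to-end
#'
#' Commands: `"simulate"` writes a synthetic linked dataset;
#' `"density"` computes the per-cell density table from an event file;
#' `"correlate"` runs [correlate_biophysics()] on an event file plus count
#' matrix; `"massresponse"` runs [mass_response_from_events()] given a
#' role map; `"full"` simulates a linked dataset and a drug triplet, then
#' runs both analyses on them. Every invocation writes a JSON run manifest
#' (configuration echo, package version, seed, input checksums) into the
#' output directory, and all tables carry a reproducibility header.
#'
#' @param command One of `"simulate"`, `"density"`, `"correlate"`,
#'   `"massresponse"`, `"full"`.
#' @param config Configuration list (see [default_run_config()]) or a
#'   YAML path.
#' @param events_path,counts_path Input paths for the file-driven
#'   commands.
#' @param roles Named vector (reference/vehicle/drug -> sample_id) for
#'   `"massresponse"`.
#' @return Invisible list of artifact paths and in-memory results.
#' @export
run_pipeline <- function(command = c("full", "simulate", "density",
                                     "correlate", "massresponse"),
                         config = default_run_config(),
                         events_path = NULL, counts_path = NULL,
                         roles = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- load_run_config(config)
  outdir <- config$outdir
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 &&
      !isTRUE(config$overwrite)) {
    stop("output directory ", outdir,
         " is non-empty; set overwrite: true to reuse it", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  artifacts <- list()
  results <- list()

  need_file <- function(p, what) {
    if (is.null(p) || !file.exists(p)) {
      stop(what, " input not found: ",
           if (is.null(p)) "(not given)" else p, call. = FALSE)
    }
    p
  }

  if (command %in% c("simulate", "full")) {
    sim_cfg <- linked_sim_config(preset = config$simulate$preset)
    sim <- simulate_linked(sim_cfg, seed = seed)
    artifacts$simulate <- write_linked_sim(sim, file.path(outdir, "sim"))
    results$sim <- sim
    events_path <- artifacts$simulate[["events"]]
    counts_path <- artifacts$simulate[["counts"]]
  }
  if (command == "density") {
    ev <- read_smr_events(need_file(events_path, "events"))
    dt <- density_table(ev)
    artifacts$density <- write_result_table(
      dt, file.path(outdir, "density.tsv"), seed = seed, config = config)
    results$density <- dt
  }
  if (command %in% c("correlate", "full")) {
    ev <- read_smr_events(need_file(events_path, "events"))
    cm <- read_count_matrix(need_file(counts_path, "counts"))
    paired <- pair_events_with_matrix(ev, cm)
    cc <- config$correlate
    res <- correlate_biophysics(
      paired,
      qc = qc_config(config$qc$min_total_reads,
                     config$qc$max_mito_fraction,
                     config$qc$min_expressing_fraction),
      scale = cc$scale, z_threshold = cc$z_threshold,
      z_method = cc$z_method, n_iter = cc$n_iter,
      percentile = cc$percentile, seed = seed)
    artifacts$correlation <- write_result_table(
      res$table, file.path(outdir, "correlation_table.tsv"),
      seed = seed, config = config)
    results$correlation <- res
  }
  if (command %in% c("massresponse", "full")) {
    mc <- config$massresponse
    if (command == "full") {
      dcfg <- drug_sim_config(
        n_cells = config$simulate$drug$n_cells,
        sensitivity = config$simulate$drug$sensitivity,
        mass_reduction_fraction =
          config$simulate$drug$mass_reduction_fraction)
      trip <- simulate_drug_triplet(dcfg, seed = seed + 1L)
      mr <- bootstrap_t_test(trip$drug, trip$vehicle, trip$reference,
                             n_boot = mc$n_boot, seed = seed + 2L,
                             alternative = mc$alternative,
                             alpha = mc$alpha, policy = mc$policy)
    } else {
      ev <- read_smr_events(need_file(events_path, "events"))
      if (is.null(roles)) {
        stop("massresponse requires a roles map (reference/vehicle/drug)",
             call. = FALSE)
      }
      mr <- mass_response_from_events(ev, roles, n_boot = mc$n_boot,
                                      seed = seed,
                                      alternative = mc$alternative,
                                      alpha = mc$alpha, policy = mc$policy)
    }
    mr_df <- data.frame(
      mass_response_drug = mr$mass_response_drug,
      mass_response_vehicle = mr$mass_response_vehicle,
      theta = mr$theta, se_boot = mr$se_boot, p_value = mr$p_value,
      decision = mr$decision, n_boot = mr$n_boot,
      harmonized_n = mr$harmonized_n, alternative = mr$alternative,
      alpha = mr$alpha)
    artifacts$massresponse <- write_result_table(
      mr_df, file.path(outdir, "mass_response.tsv"),
      seed = seed, config = config)
    results$massresponse <- mr
  }

  inputs <- Filter(function(p) !is.null(p) && file.exists(p),
                   list(events = events_path, counts = counts_path))
  manifest <- list(
    package = "smrlink",
    version = as.character(packageVersion("smrlink")),
    command = command,
    seed = seed,
    config = config,
    config_hash = .digest_config(config),
    input_checksums = lapply(inputs, function(p) unname(tools::md5sum(p))),
    artifacts = lapply(artifacts, unname),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifest_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  artifacts$manifest <- manifest_path
  invisible(list(artifacts = artifacts, results = results))
}

#' Read a result table written by this package
#'
#' @param path TSV path produced by [write_result_table()].
#' @return Data frame (header comments skipped).
#' @export
read_result_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
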