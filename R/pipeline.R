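#' Pipeline run configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Unknown
#' keys (top-level or within a section) are rejected by name, so typos fail
#' fast; the configuration round-trips losslessly through YAML via
#' [read_run_config()].
#'
#' @param out_dir Run directory (created if needed). Required.
#' @param seed Master seed; every stochastic stage derives a fixed substream
#'   from it (default 1).
#' @param stages Character vector of stages to run, a subset of
#'   `c("synth", "preprocess", "features", "network", "report")`.
#' @param paths List with `eeg_dir` and `cohort_csv` when the synth stage is
#'   not used and inputs come from disk.
#' @param synth Synthesis options: `group_sizes`, `duration_s`,
#'   `artifact_rate`, `age_range`.
#' @param preprocess Pre-processing options: `epoch_length_s`, `k_amp`,
#'   `k_pow`, `trim_minutes`, `notch_hz`, `band_hz`.
#' @param network Network options: `n_boot`, `n_subsample`, `threshold`,
#'   `fr_iterations`, `measures`.
#' @param report Report options: `p_adjust`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir,
                       seed = 1,
                       stages = c("synth", "preprocess", "features", "network", "report"),
                       paths = list(),
                       synth = list(),
                       preprocess = list(),
                       network = list(),
                       report = list()) {
  defaults <- list(
    paths = list(eeg_dir = NULL, cohort_csv = NULL),
    synth = list(group_sizes = c(10, 10, 10), duration_s = 600,
                 artifact_rate = 0, age_range = c(5, 9)),
    preprocess = list(epoch_length_s = 30, k_amp = 5, k_pow = 10,
                      trim_minutes = 5, notch_hz = 60, band_hz = c(0.1, 70)),
    network = list(n_boot = 1000, n_subsample = 20, threshold = 0.30,
                   fr_iterations = 500, measures = c("rp", "specen")),
    report = list(p_adjust = FALSE)
  )
  merge_section <- function(section, user) {
    d <- defaults[[section]]
    unknown <- setdiff(names(user), names(d))
    if (length(unknown) > 0) {
      abort_field(section, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
    }
    # NULL-preserving merge (modifyList would drop keys set to NULL)
    for (k in names(user)) d[k] <- list(user[[k]])
    d
  }
  bad_stages <- setdiff(stages, c("synth", "preprocess", "features", "network", "report"))
  if (length(bad_stages) > 0) {
    abort_field("stages", sprintf("unknown stage(s): %s", paste(bad_stages, collapse = ", ")))
  }
  assert_scalar_number(seed, "seed")
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    paths = merge_section("paths", paths),
    synth = merge_section("synth", synth),
    preprocess = merge_section("preprocess", preprocess),
    network = merge_section("network", network),
    report = merge_section("report", report)
  )
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()]; unknown keys are
#'   rejected with their names.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "stages", "paths", "synth", "preprocess",
             "network", "report")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort_field("config", sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (sec in c("synth", "preprocess", "network")) {
    for (k in c("group_sizes", "age_range", "band_hz", "measures", "stages")) {
      if (!is.null(raw[[sec]][[k]])) raw[[sec]][[k]] <- unlist(raw[[sec]][[k]])
    }
  }
  if (!is.null(raw$stages)) raw$stages <- unlist(raw$stages)
  do.call(run_config, raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates synthesize -> preprocess -> features -> network -> report.
#' Stages communicate through files under the run directory, so any stage
#' can be rerun in isolation; a manifest records the configuration hash,
#' seed, package version, per-stage counts and outcome. Reruns with the same
#' configuration and inputs produce identical feature and matrix files.
#' Missing inputs fail before any stage runs; if a stage fails, earlier
#' outputs are preserved and the manifest marks the failure point.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # fail before any stage if inputs are missing
  if (!"synth" %in% config$stages) {
    eeg_dir <- config$paths$eeg_dir %||% file.path(out, "edf")
    cohort_csv <- config$paths$cohort_csv %||% file.path(out, "cohort.csv")
    if ("preprocess" %in% config$stages && !dir.exists(eeg_dir)) {
      abort_field("paths$eeg_dir", sprintf("EEG directory not found: %s", eeg_dir))
    }
    if (!file.exists(cohort_csv) &&
        any(c("features", "network", "report") %in% config$stages)) {
      abort_field("paths$cohort_csv", sprintf("cohort table not found: %s", cohort_csv))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("osanet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = list(), status = "running"
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_run_config(config, file.path(out, "config.yaml"))

  runners <- list(synth = stage_synth, preprocess = stage_preprocess,
                  features = stage_features, network = stage_network,
                  report = stage_report)
  for (st in c("synth", "preprocess", "features", "network", "report")) {
    if (!st %in% config$stages) next
    info <- tryCatch(runners[[st]](config), error = function(e) e)
    if (inherits(info, "error")) {
      manifest$status <- "failed"
      manifest$failed_stage <- st
      manifest$error <- conditionMessage(info)
      write_manifest()
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", st, conditionMessage(info)),
                   parent = info)
    }
    manifest$stages[[st]] <- info
    write_manifest()
  }
  manifest$status <- "ok"
  write_manifest()
  invisible(out)
}

stage_synth <- function(config) {
  out <- config$out_dir
  dir.create(file.path(out, "edf"), showWarnings = FALSE)
  spec <- cohort_synthesis_spec(
    group_sizes = config$synth$group_sizes,
    age_range = config$synth$age_range,
    eeg = list(duration = config$synth$duration_s,
               artifact_rate = config$synth$artifact_rate),
    seed = substream_seed(config$seed, 1)
  )
  cohort <- synthesize_cohort(spec)
  for (i in seq_len(nrow(cohort))) {
    rec <- synthesize_eeg(cohort$eeg_spec[[i]])
    write_edf(rec, file.path(out, "edf", paste0(cohort$subject_id[i], ".edf")))
  }
  readr::write_csv(dplyr::select(cohort, -"eeg_spec"), file.path(out, "cohort.csv"))
  list(n_subjects = nrow(cohort), duration_s = config$synth$duration_s,
       seed = substream_seed(config$seed, 1))
}

stage_preprocess <- function(config) {
  out <- config$out_dir
  eeg_dir <- config$paths$eeg_dir %||% file.path(out, "edf")
  dir.create(file.path(out, "clean"), showWarnings = FALSE)
  dir.create(file.path(out, "masks"), showWarnings = FALSE)
  files <- sort(list.files(eeg_dir, pattern = "\\.edf$", full.names = TRUE))
  if (length(files) == 0) abort_field("paths$eeg_dir", "no EDF files found")
  kept <- integer(0)
  pp <- config$preprocess
  for (f in files) {
    rec <- read_edf(f)
    res <- preprocess_eeg(rec, epoch_length_s = pp$epoch_length_s, k_amp = pp$k_amp,
                          k_pow = pp$k_pow, trim_minutes = pp$trim_minutes,
                          band_hz = pp$band_hz, notch_hz = pp$notch_hz)
    id <- res$rec$subject_id
    write_edf(res$rec, file.path(out, "clean", paste0(id, ".edf")))
    jsonlite::write_json(
      list(subject_id = id, epoch_length = res$mask$epoch_length,
           keep = res$mask$keep, reject_reason = res$mask$reject_reason),
      file.path(out, "masks", paste0(id, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
    kept <- c(kept, sum(res$mask$keep))
  }
  list(n_recordings = length(files), epochs_kept_total = sum(kept))
}

read_mask_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_epoch_mask(m$epoch_length, m$keep,
                 if (is.null(m$reject_reason)) rep(NA_character_, length(m$keep))
                 else as.character(m$reject_reason))
}

stage_features <- function(config) {
  out <- config$out_dir
  cohort_csv <- config$paths$cohort_csv %||% file.path(out, "cohort.csv")
  cohort <- readr::read_csv(cohort_csv, show_col_types = FALSE)
  cohort$group <- factor(cohort$group, levels = severity_levels())
  clean_dir <- file.path(out, "clean")
  files <- sort(list.files(clean_dir, pattern = "\\.edf$", full.names = TRUE))
  spectra <- list()
  for (f in files) {
    rec <- read_edf(f)
    mask_path <- file.path(out, "masks", paste0(rec$subject_id, ".json"))
    mask <- if (file.exists(mask_path)) read_mask_json(mask_path) else NULL
    spectra[[rec$subject_id]] <- epoch_psd(rec, mask)
  }
  features <- build_feature_table(cohort, spectra)
  write_feature_table(features, file.path(out, "features.csv"))
  readr::write_csv(attr(features, "completeness"), file.path(out, "completeness.csv"))
  gms <- group_median_spectrum(spectra, cohort)
  readr::write_csv(gms, file.path(out, "group_spectra.csv"))
  peaks <- find_spectral_peak(gms)
  readr::write_csv(peaks, file.path(out, "so_peaks.csv"))
  list(n_subjects = nrow(features), n_excluded = nrow(attr(features, "completeness")),
       n_eeg_features = length(eeg_feature_columns(features)))
}

stage_network <- function(config) {
  out <- config$out_dir
  dir.create(file.path(out, "networks"), showWarnings = FALSE)
  features <- read_feature_table(file.path(out, "features.csv"))
  nw <- config$network
  produced <- character(0)
  combos <- expand.grid(group = severity_levels(), measure = nw$measures,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    g <- combos$group[i]; ms <- combos$measure[i]
    if (sum(features$group == g) < 2) next
    sub_seed <- substream_seed(config$seed, 100 + i)
    mat <- bootstrap_matrix(features, group = g, measure = ms,
                            n_boot = nw$n_boot, n_subsample = nw$n_subsample,
                            seed = sub_seed)
    base <- file.path(out, "networks", paste0(g, "_", ms))
    write_matrix_csv(mat$median, paste0(base, "_median.csv"))
    write_matrix_csv(mat$p2_5, paste0(base, "_p2_5.csv"))
    write_matrix_csv(mat$p97_5, paste0(base, "_p97_5.csv"))
    net <- threshold_network(mat, threshold = nw$threshold)
    net <- annotate_network(net, iterations = nw$fr_iterations,
                            seed = substream_seed(config$seed, 200 + i))
    write_network_json(net, paste0(base, "_network.json"))
    igraph::write_graph(net$graph, paste0(base, "_network.graphml"), format = "graphml")
    readr::write_csv(radar_summary(mat), paste0(base, "_radar.csv"))
    produced <- c(produced, paste0(g, "_", ms))
  }
  list(networks = produced, n_boot = nw$n_boot, threshold = nw$threshold)
}

write_matrix_csv <- function(M, path) {
  df <- tibble::as_tibble(M, rownames = "node")
  readr::write_csv(df, path)
}

#' Export an annotated network as JSON
#'
#' Nodes carry coordinates, module labels and centrality; edges carry signed
#' weights.
#'
#' @param net An annotated `cor_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(
    list(threshold = net$threshold,
         Q = net$Q,
         params = net$params[c("group", "measure", "n_boot", "n_subsample")],
         nodes = network_nodes(net),
         edges = tidy(net)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

stage_report <- function(config) {
  out <- config$out_dir
  dir.create(file.path(out, "report"), showWarnings = FALSE)
  features <- read_feature_table(file.path(out, "features.csv"))
  cg <- compare_groups(features, p_adjust = config$report$p_adjust)
  readr::write_csv(cg, file.path(out, "report", "comparisons.csv"))
  summ <- cohort_summary(features, p_adjust = config$report$p_adjust)
  readr::write_csv(summ, file.path(out, "report", "cohort_summary.csv"))
  lines <- c(
    "# Cohort report", "",
    sprintf("Subjects: %d (%s)", nrow(features),
            paste(sprintf("%s %d", levels(features$group),
                          table(features$group)), collapse = ", ")), "",
    "| Variable | Controls | Mild | Mod/severe | p < 0.05 |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s |", summ$variable, summ$controls,
            summ$mild, summ$mod_severe, summ$signif)
  )
  writeLines(lines, file.path(out, "report", "report.md"))
  list(n_variables = length(unique(cg$variable)))
}
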