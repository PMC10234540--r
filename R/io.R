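# CSV readers/writers with schema validation, run configuration, pipeline.
#
# All tables travel as plain CSV with fixed headers; missing values are
# empty fields. The configuration dialect is JSON (one file, all defaults
# overridable). File writes are atomic: temp file in the target directory,
# then rename.

cq_schemas <- list(
  spikes = c(unit_id = "character", time_s = "numeric"),
  events = c(time_s = "numeric", label = "character"),
  amplitudes = c(unit_id = "character", channel = "character",
                 amp_uv = "numeric"),
  channels = c(channel = "character", x_um = "numeric", y_um = "numeric"),
  cells = c(cell_id = "character", ap_mm = "numeric", dv_um = "numeric",
            ml_um = "numeric", pathway = "character", markers = "character",
            brain_id = "character", slice_id = "character"),
  axon_counts = c(pathway = "character", region = "character",
                  ap_mm = "numeric", nucleus = "character",
                  count = "numeric"))

#' Read and validate a pipeline CSV table
#'
#' Reads one of the package's CSV dialects, checks the header against the
#' schema, converts columns to their declared types and reports every row
#' whose values fail to parse, with line numbers.
#'
#' @param path CSV file path.
#' @param schema schema name: one of `"spikes"`, `"events"`,
#'   `"amplitudes"`, `"channels"`, `"cells"`, `"axon_counts"`.
#' @return the validated data frame; row-level problems (if any rows had to
#'   be dropped) are attached as attribute `"problems"`.
#' @export
read_table_checked <- function(path, schema) {
  if (!schema %in% names(cq_schemas)) stopf("unknown schema '%s'", schema)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sch <- cq_schemas[[schema]]
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(names(sch), names(raw))
  if (length(miss))
    stopf("%s: missing required column(s): %s", basename(path),
          paste(miss, collapse = ", "))
  raw <- raw[names(sch)]
  problems <- data.frame(line = integer(0), column = character(0),
                         value = character(0))
  for (col in names(sch)) {
    if (sch[[col]] == "numeric") {
      conv <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- is.na(conv) & nzchar(raw[[col]])
      if (any(bad))
        problems <- rbind(problems, data.frame(
          line = which(bad) + 1L, column = col, value = raw[[col]][bad]))
      raw[[col]] <- conv
    }
  }
  if (nrow(problems)) {
    warnf("%s: %d unparseable value(s), e.g. line %d column %s = '%s'; rows dropped",
          basename(path), nrow(problems), problems$line[1], problems$column[1],
          problems$value[1])
    drop_rows <- unique(problems$line - 1L)
    raw <- raw[-drop_rows, , drop = FALSE]
  }
  if (schema == "spikes") raw <- raw[order(raw$unit_id, raw$time_s), ]
  rownames(raw) <- NULL
  attr(raw, "problems") <- if (nrow(problems)) problems else NULL
  raw
}

#' Write a table atomically as CSV
#'
#' Writes to a temporary file in the destination directory, then renames it
#' into place, so a crash never leaves a half-written table. Missing values
#' are written as empty fields.
#'
#' @param df data frame.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_table_checked <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  write.csv(df, tmp, row.names = FALSE, na = "")
  if (!file.rename(tmp, path)) stopf("could not move temp file into %s", path)
  invisible(path)
}

cfg_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "colliquant-results",
    windows = list(whisker_pre = c(-50, -20), whisker_post = c(20, 50),
                   opto_spont = c(-18, -6), opto_evoked = c(6, 18),
                   alpha = 0.05, z_threshold = 1.96, p0 = 1 / 3, power = 0.8),
    qc = list(max_refractory_violation_fraction = 0.03, refractory_ms = 1.5,
              min_baseline_rate_hz = 0.1),
    bins = list(ap_from_mm = -3.08, ap_to_mm = -4.28, width_mm = 0.1),
    gmm = list(n_components = 2L, n_init = 10L, tol = 1e-6, grid_n = 200L),
    rounding = list(percent_digits = 1L),
    synthetic = list(
      ephys = list(n_units = 100L, n_trials = 30L),
      opto = list(n_units = 100L, n_trials = 40L,
                  fractions = c(mc_only = 0.1, bc_only = 0.1,
                                dual = 0.05, none = 0.75)),
      anatomy = list(n_cells = 400L, n_pair_cells = 1000L),
      axons = list(region = "diencephalon")))
}

check_cfg_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stopf("unknown config key(s)%s: %s",
          if (nzchar(path)) paste0(" under ", path) else "",
          paste(extra, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(cfg[[k]]))
      check_cfg_keys(cfg[[k]], ref[[k]], paste0(path, if (nzchar(path)) "$" else "", k))
  }
}

#' Default run configuration
#'
#' Builds the validated configuration driving [run_pipeline()]: analysis
#' windows and thresholds, QC criteria, rostro-caudal bin edges, mixture
#' settings, rounding rules, the master seed, and sizes for the synthetic
#' stand-in datasets. Any subset of keys can be overridden; unknown keys
#' are rejected.
#'
#' @param ... named overrides merged (recursively) over the defaults, e.g.
#'   `default_config(seed = 7, windows = list(alpha = 0.01))`.
#' @return validated configuration list of class `run_config`.
#' @export
default_config <- function(...) {
  over <- list(...)
  cfg <- cfg_defaults()
  check_cfg_keys(over, cfg)
  merge_in <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_in(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- merge_in(cfg, over)
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg configuration list (e.g. from [read_config()]).
#' @return the configuration, classed `run_config`, after range checks.
#' @export
validate_config <- function(cfg) {
  check_cfg_keys(cfg, cfg_defaults())
  w <- cfg$windows
  do.call(response_windows, w)           # window/threshold range checks
  do.call(qc_criteria, cfg$qc)
  if (cfg$bins$ap_from_mm <= cfg$bins$ap_to_mm || cfg$bins$width_mm <= 0)
    stopf("bins must run rostral to caudal with positive width")
  if (!is_count(abs(as.numeric(cfg$seed))))
    stopf("seed must be an integer")
  structure(cfg, class = "run_config")
}

#' Read a JSON run configuration
#'
#' Missing keys fall back to the package defaults; unknown keys are
#' rejected before any computation.
#'
#' @param path JSON file path.
#' @return validated `run_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, cfg)
}

#' Run the full synthetic-data pipeline
#'
#' Generates whisker-stimulation, dual-site optogenetic, soma-table and
#' axon-count datasets from the configuration's synthetic block, runs every
#' analysis stage (unit QC, whisker responsiveness and modulation, dual-input
#' classification, rostro-caudal distribution battery, marker proportions,
#' convergence statistics and mixture zone, axon maps), writes all result
#' tables plus a JSON summary, and records a manifest with the configuration
#' hash, seed, package version and an MD5 of every output. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config a `run_config` from [default_config()] / [read_config()].
#' @param out_dir output directory (default from the config).
#' @return list with `summary` (headline numbers), `manifest`, and the
#'   per-stage result objects, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(unclass(config))
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  windows <- do.call(response_windows, config$windows)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ephys <- stage("whisker", {
    sim <- gen_spike_dataset(do.call(synthetic_ephys_spec,
      c(config$synthetic$ephys, list(seed = seed))))
    qc <- qc_filter_units(sim$dataset, do.call(qc_criteria, config$qc))
    res <- test_whisker_modulation(qc$dataset, windows)
    list(sim = sim, qc = qc, results = res)
  })
  opto <- stage("opto", {
    sim <- gen_opto_dataset(do.call(synthetic_opto_spec,
      c(config$synthetic$opto, list(seed = seed + 1L))))
    list(sim = sim, results = classify_dual_input(sim$mc, sim$bc, windows))
  })
  anatomy <- stage("anatomy", {
    sim <- gen_soma_tables(synthetic_anatomy_spec(
      n_cells = setNames(rep(config$synthetic$anatomy$n_cells, 3L),
                         c("MC", "BC", "Bs")),
      n_pair_cells = config$synthetic$anatomy$n_pair_cells,
      seed = seed + 2L))
    cells <- sim$cells
    edges <- ap_bin_edges(config$bins$ap_from_mm, config$bins$ap_to_mm,
                          config$bins$width_mm)
    base <- cells[cells$pathway %in% c("MC", "BC", "Bs"), ]
    dist <- normalize_per_brain(bin_counts_along_ap(base, edges))
    battery <- compare_distributions(split(base$ap_mm, base$pathway))
    gaba <- proportion_summary(base[has_marker(base, "GABA"), ], base,
                               group_by = "slice_id",
                               digits = config$rounding$percent_digits)
    pairs <- names(table(cells$pathway[grepl("+", cells$pathway, fixed = TRUE)]))
    cvg_mat <- t(vapply(pairs, function(p) {
      pc <- cells[cells$pathway == p & has_marker(cells, "CVG"), ]
      tabulate(ap_bin_index(pc$ap_mm, edges), nbins = length(edges) - 1L)
    }, numeric(length(edges) - 1L)))
    rn_tot <- vapply(pairs, function(p) sum(cells$pathway == p), numeric(1))
    cvg <- convergence_stats(cvg_mat, rn_tot, group_a = "MC+BC")
    cvg_pts <- cells[cells$pathway == "MC+BC" & has_marker(cells, "CVG"),
                     c("dv_um", "ml_um")]
    zone <- fit_convergence_gmm(cvg_pts,
                                n_components = config$gmm$n_components,
                                seed = seed + 3L,
                                n_init = config$gmm$n_init,
                                tol = config$gmm$tol,
                                grid_n = config$gmm$grid_n)
    list(sim = sim, dist = dist, battery = battery, gaba = gaba,
         cvg = cvg, zone = zone)
  })
  axons <- stage("axons", {
    sim <- gen_axon_counts(synthetic_axon_spec(
      region = config$synthetic$axons$region, seed = seed + 4L))
    list(sim = sim, rac = relative_axon_count(sim$matrix),
         z = nucleus_zscores(sim$matrix))
  })

  res <- ephys$results
  summary <- list(
    n_units = nrow(res),
    n_responsive = sum(res$responsive),
    n_positive = sum(res$sign == "positive"),
    n_negative = sum(res$sign == "negative"),
    n_opto_mc = sum(opto$results$responsive_mc),
    n_opto_bc = sum(opto$results$responsive_bc),
    n_opto_dual = sum(opto$results$responsive_dual),
    gaba_percent = anatomy$gaba$percent_rounded,
    cvg_fold_difference = anatomy$cvg$fold_difference,
    gmm_mode_dv_um = unname(anatomy$zone$mode["dv_um"]),
    gmm_mode_ml_um = unname(anatomy$zone$mode["ml_um"]))

  write_table_checked(res, file.path(out_dir, "whisker_responses.csv"))
  write_table_checked(ephys$qc$report, file.path(out_dir, "unit_qc.csv"))
  write_table_checked(opto$results, file.path(out_dir, "opto_responses.csv"))
  write_table_checked(as.data.frame(anatomy$dist$counts),
                      file.path(out_dir, "ap_bin_counts.csv"))
  write_table_checked(as.data.frame(axons$rac),
                      file.path(out_dir, "axon_rac.csv"))
  write_table_checked(data.frame(nucleus = names(axons$z$z), z = axons$z$z,
                                 z_maxnorm = axons$z$z_maxnorm),
                      file.path(out_dir, "axon_zscores.csv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("colliquant")),
    seed = seed,
    config_hash = unname(digest_string(jsonlite::toJSON(unclass(config),
                                                        auto_unbox = TRUE))),
    outputs = setNames(as.list(unname(tools::md5sum(sort(outputs)))),
                       basename(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary, manifest = manifest, ephys = ephys,
                 opto = opto, anatomy = anatomy, axons = axons))
}

digest_string <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(x), tmp)
  unname(tools::md5sum(tmp))
}
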