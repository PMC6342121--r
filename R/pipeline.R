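#' Run the full index-development pipeline
#'
#' Orchestrates every stage end to end: simulate (or load) the data, build
#' the pressure gradient from log-transformed chemistry, normalize and
#' rare-filter each SST-level OTU table, run the stratified randomization
#' sweep, and write all result tables plus a run manifest. The manifest
#' (config echo, seeds, md5 of every output, package version) is
#' sufficient to re-run the pipeline bit-identically: the same config
#' yields the same hashes.
#'
#' The configuration is a named list (or a path to a YAML file holding
#' one) with keys: `seed` (required), `out_dir` (required), and optional
#' `scenario` (list of [otu_scenario()] arguments, seed filled from
#' `seed`), `sst_grid` (default `80:99`), `reps` (default 100),
#' `train_frac` (0.75), `dialect` (`"inverse_tolerance"`), `v_floor`
#' (`NULL`), `offset_policy` (`"half-min-positive"`), `rare_fraction`
#' (0.05), `low`/`high` (SST group bounds `c(80, 85)` / `c(90, 99)`).
#' Alternatively `env_table` and `tables_dir` paths may point at existing
#' chemistry and per-SST `.shared`/TSV tables with the same header
#' contract instead of `scenario`.
#'
#' Seed derivation: the scenario uses `seed`; the split plan uses
#' `seed + 1000`.
#'
#' Outputs written to `out_dir`: `chemistry.tsv`, `gradient.tsv` (+ JSON
#' sidecar), `sweep_metrics.tsv`, `sweep_summary.tsv`, `tradeoff.tsv`,
#' `group_test.json`, `sample_stability.tsv`, `manifest.json`.
#'
#' @param config Named list or path to a YAML config file.
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$env_table)) {
    chemistry <- read_env_table(cfg$env_table)
    tables <- load_table_dir(cfg$tables_dir)
  } else {
    scenario <- do.call(otu_scenario,
                        c(cfg$scenario, list(seed = cfg$seed)))
    sim <- simulate_dataset(scenario, sst_grid = cfg$sst_grid)
    chemistry <- sim$chemistry
    tables <- sim$tables
  }
  write_env_table(chemistry, file.path(cfg$out_dir, "chemistry.tsv"))

  gradient <- compute_gradient(log_transform(chemistry, cfg$offset_policy))
  write_gradient(gradient, file.path(cfg$out_dir, "gradient.tsv"))

  filtered <- lapply(tables, function(t) {
    filter_rare(to_relative(t), cfg$rare_fraction)$table
  })

  splits <- make_splits(gradient$scores, train_frac = cfg$train_frac,
                        reps = cfg$reps, seed = cfg$seed + 1000L)
  sweep <- suppressMessages(
    run_sweep(filtered, gradient, splits, cfg$dialect, cfg$v_floor))

  readr::write_tsv(tidy(sweep), file.path(cfg$out_dir, "sweep_metrics.tsv"))
  readr::write_tsv(sweep$summary, file.path(cfg$out_dir, "sweep_summary.tsv"))
  tradeoff <- summarize_tradeoff(sweep)
  readr::write_tsv(tradeoff, file.path(cfg$out_dir, "tradeoff.tsv"))
  gt <- compare_sst_groups(sweep, cfg$low, cfg$high)
  jsonlite::write_json(as.list(gt), file.path(cfg$out_dir, "group_test.json"),
                       auto_unbox = TRUE, digits = NA)
  # undefined on degenerate designs (e.g. too few reps for any per-sample
  # SD); recorded as such rather than failing the whole run
  stab <- tryCatch(
    suppressMessages(sample_stability_vs_richness(sweep, filtered)),
    error = function(e) list(r = NA_real_, p_value = NA_real_, n_pairs = 0L,
                             pairs = tibble::tibble(
                               sample = character(), sst = numeric(),
                               richness = integer(), richness_norm = numeric(),
                               sd_idx = numeric()),
                             note = conditionMessage(e)))
  readr::write_tsv(stab$pairs, file.path(cfg$out_dir, "sample_stability.tsv"))

  outputs <- c("chemistry.tsv", "gradient.tsv", "gradient.tsv.json",
               "sweep_metrics.tsv", "sweep_summary.tsv", "tradeoff.tsv",
               "group_test.json", "sample_stability.tsv")
  paths <- file.path(cfg$out_dir, outputs)
  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    seeds = list(master = cfg$seed, splits = cfg$seed + 1000L),
    version = as.character(utils::packageVersion("sstindex")),
    paired_splits = TRUE,
    files = stats::setNames(as.list(unname(tools::md5sum(paths))), outputs),
    richness_stability = list(r = stab$r, p_value = stab$p_value,
                              n_pairs = stab$n_pairs,
                              note = stab$note %||% NA_character_))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

validate_config <- function(config) {
  if (!is.list(config)) abort("config must be a named list or YAML path")
  required <- c("seed", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort(paste0("config is missing required key(s): ",
                 paste(missing, collapse = ", ")))
  }
  defaults <- list(scenario = list(), sst_grid = 80:99, reps = 100L,
                   train_frac = 0.75, dialect = "inverse_tolerance",
                   v_floor = NULL, offset_policy = "half-min-positive",
                   rare_fraction = 0.05, low = c(80, 85), high = c(90, 99),
                   env_table = NULL, tables_dir = NULL)
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$sst_grid <- as.integer(cfg$sst_grid)
  if (any(cfg$sst_grid < 1 | cfg$sst_grid > 100)) {
    abort("sst_grid levels must lie in 1..100")
  }
  if (cfg$reps < 1) abort("reps must be >= 1")
  for (p in c("env_table", "tables_dir")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      abort(paste0("config path does not exist: ", p, " = ", cfg[[p]]))
    }
  }
  cfg
}

# Load every per-SST table from a directory of files named <sst>.tsv or
# <sst>.shared (e.g. 90.shared).
load_table_dir <- function(dir) {
  if (is.null(dir)) abort("tables_dir is required when env_table is given")
  files <- list.files(dir, pattern = "\\.(tsv|shared)$", full.names = TRUE)
  if (length(files) == 0) abort(paste0("no tables found in ", dir))
  sst <- sub("\\.(tsv|shared)$", "", basename(files))
  tables <- lapply(files, function(f) {
    dialect <- if (grepl("\\.shared$", f)) "mothur-shared" else "tsv-wide"
    read_otu_table(f, dialect)
  })
  names(tables) <- sst
  tables[order(as.numeric(sst))]
}
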