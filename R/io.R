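# File formats and the end-to-end pipeline. Grids travel as a
# long-format CSV (cell_id,layer,value; UTF-8, comma-separated) with a
# JSON sidecar holding the geometry, crop set and national crop
# composition, so no geospatial dependency is required. Valuation
# records and economic tables are CSV/JSON. The pipeline runs
# screening, model enumeration and selection, the ES bootstrap, carbon
# valuation, rents, impact integration, Monte Carlo propagation and
# percentile reduction, and writes a manifest with seeds and file
# checksums.

mandatory_grid_layers <- function() {
  c(
    "country_id", "forest_loss_area", "agb_carbon", "bgb_carbon",
    "dom_carbon", "peat_depth", "travel_time", "fertilizer_usage",
    "pasture_fraction", "cattle_stocking", es_covariate_names()
  )
}

#' Write a landscape grid as long-format CSV plus JSON sidecar
#'
#' @param grid a `landscape_grid`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  layers <- setdiff(names(grid), "cell_id")
  long <- data.frame(
    cell_id = rep(grid$cell_id, length(layers)),
    layer = rep(layers, each = nrow(grid)),
    value = unlist(lapply(layers, function(l) as.numeric(grid[[l]])),
      use.names = FALSE
    )
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    nx = attr(grid, "nx"), ny = attr(grid, "ny"),
    cell_area = attr(grid, "cell_area"),
    crop_set = attr(grid, "crop_set"),
    crop_composition = attr(grid, "crop_composition")
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a landscape grid from long-format CSV
#'
#' @param path CSV path written by [write_grid()] (sidecar expected at
#'   `<path>.json`).
#' @return A `landscape_grid`.
#' @export
read_grid <- function(path) {
  long <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) {
      stop("failed to parse grid CSV '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  need <- c("cell_id", "layer", "value")
  if (!all(need %in% names(long))) {
    stop("grid CSV must have columns cell_id,layer,value", call. = FALSE)
  }
  ids <- sort(unique(long$cell_id))
  layers <- unique(long$layer)
  grid <- data.frame(cell_id = ids)
  for (l in layers) {
    sub <- long[long$layer == l, , drop = FALSE]
    grid[[l]] <- sub$value[match(ids, sub$cell_id)]
  }
  absent <- setdiff(mandatory_grid_layers(), names(grid))
  if (length(absent)) {
    stop(
      "grid is missing mandatory layers: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  grid$country_id <- as.integer(grid$country_id)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(grid, "nx") <- meta$nx
    attr(grid, "ny") <- meta$ny
    attr(grid, "cell_area") <- meta$cell_area
    attr(grid, "crop_set") <- meta$crop_set
    attr(grid, "crop_composition") <- as.data.frame(meta$crop_composition)
  }
  class(grid) <- c("landscape_grid", "data.frame")
  grid
}

#' Write / read valuation records as CSV
#'
#' @param records a `valuation_records` data frame.
#' @param path CSV path.
#' @return `path` (write) or the records (read).
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("value", "es_class", "method_class", "country")
  absent <- setdiff(need, names(rec))
  if (length(absent)) {
    stop(
      "records CSV missing columns: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"log_value" %in% names(rec)) rec$log_value <- log(rec$value)
  class(rec) <- c("valuation_records", "data.frame")
  rec
}

#' Write / read economic tables as a single JSON document
#'
#' @param econ an `econ_tables` list.
#' @param path JSON path.
#' @return `path` (write) or the tables (read).
#' @export
write_econ_tables <- function(econ, path) {
  jsonlite::write_json(unclass(econ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_econ_tables
#' @export
read_econ_tables <- function(path) {
  econ <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (el in c(
    "crop_prices", "crop_params", "country_params",
    "carbon_market_series", "internalization"
  )) {
    econ[[el]] <- as.data.frame(econ[[el]])
  }
  econ$scc_pool <- as.numeric(econ$scc_pool)
  class(econ) <- "econ_tables"
  econ
}

#' Write / read a synthetic-data configuration as YAML
#'
#' @param config a [synth_config()].
#' @param path YAML path.
#' @return `path` (write) or the config (read).
#' @export
write_synth_config <- function(config, path) {
  raw <- unclass(config)
  raw$true_beta <- as.list(raw$true_beta) # keep coefficient names in YAML
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$true_beta <- unlist(raw$true_beta)
  do.call(synth_config, raw)
}

#' Pipeline configuration
#'
#' Either paths to input files or in-memory objects (grid, records,
#' econ) may be supplied; a `synth` config generates all three.
#'
#' @param outdir output directory.
#' @param scenario scenario id or vector of ids from `{A, B, C, D}`.
#' @param synth optional [synth_config()] used to generate inputs.
#' @param grid,records,econ optional objects or file paths.
#' @param candidate_terms candidate fixed-effect terms.
#' @param multipliers ES-class service-type counts.
#' @param carbon a [carbon_price_model()].
#' @param carbon_price_type `"market"` or `"social"`.
#' @param B bootstrap replicates for the ES ensemble.
#' @param uncertainty an [uncertainty_spec()].
#' @param seed master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, scenario = "A", synth = NULL,
                            grid = NULL, records = NULL, econ = NULL,
                            candidate_terms = es_candidate_terms(),
                            multipliers = c(
                              cultural = 5, provisioning = 5,
                              regulating = 6
                            ),
                            carbon = carbon_price_model(),
                            carbon_price_type = "market",
                            B = 500L,
                            uncertainty = uncertainty_spec(),
                            seed = 1L) {
  if (!all(scenario %in% c("A", "B", "C", "D"))) {
    config_error("scenario", "must be within {A, B, C, D}")
  }
  for (nm in c("grid", "records", "econ")) {
    obj <- get(nm)
    if (is.character(obj) && !file.exists(obj)) {
      config_error(nm, sprintf("file '%s' does not exist", obj))
    }
  }
  if (is.null(synth) && (is.null(grid) || is.null(records) || is.null(econ))) {
    config_error("synth", "required when grid/records/econ are not all given")
  }
  structure(
    list(
      outdir = outdir, scenario = scenario, synth = synth, grid = grid,
      records = records, econ = econ, candidate_terms = candidate_terms,
      multipliers = multipliers, carbon = carbon,
      carbon_price_type = carbon_price_type, B = as.integer(B),
      uncertainty = uncertainty, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full trade-off pipeline
#'
#' Stages: load or generate inputs; screen records (when screening flags
#' are present); enumerate and select the ES models; bootstrap the TEV
#' surface; run the Monte Carlo propagation per scenario; reduce to
#' percentile maps and tables; write all artifacts and a JSON manifest
#' recording the seed, package version, stage log and MD5 checksum of
#' every output file. Re-running an identical configuration reproduces
#' identical checksums.
#'
#' @param config a [pipeline_config()].
#' @param force overwrite a non-empty output directory?
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop(
      "output directory '", outdir,
      "' is not empty; use force = TRUE to overwrite",
      call. = FALSE
    )
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stage <- function(name, value) {
    log[[length(log) + 1L]] <<- list(stage = name, at = length(log) + 1L)
    value
  }

  load_or <- function(obj, reader) {
    if (is.character(obj)) reader(obj) else obj
  }
  if (!is.null(config$synth)) {
    grid <- stage("generate_landscape", generate_landscape(config$synth))
    records <- stage(
      "generate_records", generate_valuation_dataset(config$synth, grid)
    )
    econ <- stage("generate_econ", generate_econ_tables(config$synth))
  } else {
    grid <- stage("read_grid", load_or(config$grid, read_grid))
    records <- stage("read_records", load_or(config$records, read_records))
    econ <- stage("read_econ", load_or(config$econ, read_econ_tables))
  }
  if (any(c("benefit_transfer", "is_npv") %in% names(records))) {
    records <- stage("screen_records", screen_records(records))
  }

  top <- stage(
    "select_models",
    select_top(enumerate_models(records, config$candidate_terms))
  )
  es <- stage(
    "bootstrap_es",
    bootstrap_es_maps(records, grid,
      B = config$B,
      candidate_terms = config$candidate_terms,
      multipliers = config$multipliers,
      seed = derive_seed(config$seed, "pipeline_es"),
      top_set = top
    )
  )

  write_grid(grid, file.path(outdir, "grid.csv"))
  write_records(records, file.path(outdir, "records.csv"))
  write_econ_tables(econ, file.path(outdir, "econ.json"))
  utils::write.csv(
    data.frame(cell_id = grid$cell_id, tev = as.numeric(es$point_map)),
    file.path(outdir, "tev_point.csv"),
    row.names = FALSE
  )
  model_summary <- lapply(seq_along(top$models), function(i) {
    list(
      terms = top$terms_list[[i]], aicc = top$aicc[i],
      delta_aicc = top$delta_aicc[i], weight = top$akaike_weight[i]
    )
  })
  jsonlite::write_json(model_summary, file.path(outdir, "model_set.json"),
    auto_unbox = TRUE, digits = NA
  )

  spec <- config$uncertainty
  spec$seed <- derive_seed(config$seed, "pipeline_mc")
  results <- list()
  for (sc in config$scenario) {
    ens <- stage(
      paste0("monte_carlo_", sc),
      run_monte_carlo(grid, es, econ, sc, spec,
        carbon = config$carbon,
        carbon_price_type = config$carbon_price_type
      )
    )
    pct <- reduce_percentiles(ens)
    utils::write.csv(
      cbind(data.frame(cell_id = grid$cell_id), as.data.frame(pct$cell)),
      file.path(outdir, paste0("impact_percentiles_", sc, ".csv")),
      row.names = FALSE
    )
    utils::write.csv(
      pct$aggregate,
      file.path(outdir, paste0("aggregate_percentiles_", sc, ".csv")),
      row.names = FALSE
    )
    utils::write.csv(
      ens$aggregates,
      file.path(outdir, paste0("aggregates_", sc, ".csv")),
      row.names = FALSE
    )
    results[[sc]] <- list(
      failures = ens$failures,
      global_median = stats::median(
        ens$aggregates$impact_total[ens$aggregates$level == "global"]
      )
    )
  }

  files <- dir(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "tevtrade",
    version = as.character(utils::packageVersion("tevtrade")),
    seed = config$seed,
    scenarios = as.list(results),
    stages = lapply(log, function(x) x$stage),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(files)), basename(files)
    ))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
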