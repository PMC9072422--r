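FORMAT_VERSION <- "1"

#' Published per-dataset summary of mouse V1 ON/OFF populations
#'
#' Loads the packaged summary table of the thirteen imaging volumes: per
#' dataset, the mouse, sex, number of optical planes, the counts of
#' mono-contrast ON and OFF cells, of dual-polarity (ON+OFF) cells with
#' their simple/complex split, and the split-half (top versus bottom optical
#' sections) correlation of the ON-OFF density map with its significance at
#' the 0.01 level.
#'
#' @return Data frame with 13 rows and columns `dataset`, `mouse_id`, `sex`,
#'   `n_planes`, `n_on`, `n_off`, `n_dual`, `n_simple`, `n_complex`,
#'   `layers_correlation`, `layers_significant`.
#' @examples
#' population_composition(v1_dataset_summary())
#' @export
v1_dataset_summary <- function() {
  utils::read.csv(system.file("extdata", "dataset_summary.csv",
                              package = "onoffdomains"),
                  stringsAsFactors = FALSE)
}

#' Write / read a cell table
#'
#' Cell tables are CSV files with a format-version header comment. Readers
#' validate that the coordinate columns are present and free of missing
#' values and fail loudly otherwise.
#'
#' @param cells data frame with at least `id`, `class`, `x1`, `x2`, `x3`.
#' @param path file path.
#' @return `read_cells` returns the validated data frame; `write_cells` the
#'   path, invisibly.
#' @export
write_cells <- function(cells, path) {
  stopifnot(is.data.frame(cells))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# onoffdomains cell table, format %s", FORMAT_VERSION), con)
  utils::write.csv(cells, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# onoffdomains cell table, format ", header))
    stop("not a cell table (missing format header): ", path)
  ver <- sub("^# onoffdomains cell table, format ", "", header)
  if (ver != FORMAT_VERSION)
    stop(sprintf("unknown cell-table format version '%s'", ver))
  cells <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("id", "class", "x1", "x2", "x3")) {
    if (!col %in% names(cells))
      stop(sprintf("cell table is missing required column '%s'", col))
  }
  for (col in c("x1", "x2", "x3")) {
    if (anyNA(cells[[col]]))
      stop(sprintf("NaN/NA in coordinate column '%s'", col))
  }
  cells
}

#' Write / read named numeric arrays as a plain-text store
#'
#' Each array is stored as `<name>.csv` (flattened column-major) under
#' `dir`, with a JSON sidecar `arrays.json` recording the format version
#' and each array's dimensions. Readers validate the sidecar and array
#' lengths and fail loudly on truncation or version mismatch.
#'
#' @param arrays named list of numeric vectors/matrices/arrays.
#' @param dir directory (created if needed).
#' @return `read_arrays` returns the named list with dimensions restored;
#'   `write_arrays` returns `dir`, invisibly.
#' @export
write_arrays <- function(arrays, dir) {
  stopifnot(is.list(arrays), length(names(arrays)) == length(arrays),
            all(nzchar(names(arrays))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = FORMAT_VERSION, arrays = list())
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    meta$arrays[[nm]] <- list(dim = if (is.null(dim(a))) length(a) else dim(a))
    utils::write.table(data.frame(value = as.numeric(a)),
                       file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE, col.names = TRUE, sep = ",")
  }
  jsonlite::write_json(meta, file.path(dir, "arrays.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_arrays
#' @export
read_arrays <- function(dir) {
  sidecar <- file.path(dir, "arrays.json")
  if (!file.exists(sidecar)) stop("missing arrays.json sidecar in ", dir)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(as.character(meta$format), FORMAT_VERSION))
    stop(sprintf("unknown array-store format version '%s'", meta$format))
  out <- list()
  for (nm in names(meta$arrays)) {
    dims <- unlist(meta$arrays[[nm]]$dim)
    v <- utils::read.csv(file.path(dir, paste0(nm, ".csv")))$value
    if (length(v) != prod(dims))
      stop(sprintf("array '%s' is truncated: expected %d values, found %d",
                   nm, prod(dims), length(v)))
    if (anyNA(v)) stop(sprintf("array '%s' contains missing values", nm))
    out[[nm]] <- if (length(dims) > 1) array(v, dims) else v
  }
  out
}

#' Read a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration file and merges it over
#' [default_config()]; unknown keys are rejected.
#'
#' @param path YAML/JSON file.
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  base <- default_config()
  extra <- setdiff(names(cfg), names(base))
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  base[names(cfg)] <- cfg
  structure(base, class = "pipeline_config")
}

#' Default end-to-end pipeline configuration
#'
#' Every tunable of the analysis appears exactly once, at its standard
#' value: the 18 x 8 stimulus grid with 10/10/80 percent tile statistics at
#' 1500 presentations, the 15-frame kernel delay window with significance
#' thresholds (peak normalized norm above 5, Gaussian variance explained at
#' least 0.5, simple/complex boundary at normalized distance 0.5), density
#' bandwidths of 30 um (native) and 0.25 (canonical), 1000 label shuffles
#' at alpha 0.001, and the k = 5 neighborhood model.
#'
#' @param ... overrides of individual fields.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    master_seed = 1L,
    # synthetic population
    n_on = 270, n_off = 550, n_simple = 90, n_complex = 90,
    bias_amplitude = 0.5, bias_blobs = 6, bias_length_scale = 25,
    scatter_sigma_on = 45, scatter_sigma_off = 30,
    rf_sigma = 8, dirichlet_conc = 0.3,
    # stimulus / responses
    n_stimuli = 1500, p_bright = 0.1, p_dark = 0.1, frame_rate = 15.6,
    gain = 2, baseline = 0.12, delay_frames = 5,
    # kernels / classification
    max_delay = 15, norm_threshold = 5, ve_threshold = 0.5,
    simple_threshold = 0.5,
    # density maps
    sigma_native = 30, sigma_canonical = 0.25,
    native_spacing = 10, canonical_spacing = 0.05,
    n_shuffles = 1000, alpha = 0.001,
    # neighborhood model
    k = 5, k_range = 1:8, saturation_epsilon = 0.02)
  over <- list(...)
  extra <- setdiff(names(over), names(cfg))
  if (length(extra)) stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Single-command driver tying the stages together: simulate a ground-truth
#' population, stimulus and responses; estimate and classify kernels; map
#' ON/OFF domains in native cortical space; align cortical and visual
#' coordinates by CCA; correlate the canonical fluctuation maps; and fit
#' the non-negative neighborhood model to the classified simple cells.
#' Stage seeds fan out deterministically from `master_seed`, so a given
#' configuration reproduces identical outputs (and identical output-file
#' digests when `out_dir` is set).
#'
#' @param config a [default_config()] list.
#' @param out_dir optional directory; when given, the classified cell table
#'   and stage summaries are written there and digested in the manifest.
#' @return Object of class `run_manifest`: list of per-stage results
#'   (`population`, `classification`, `domains`, `cca`, `map_correlation`,
#'   `neighborhood`), `seeds`, `timings` (seconds), `warnings`, and
#'   `digests` (md5, when `out_dir` is used).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  set.seed(config$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 8)
  timings <- c(); res <- list(); warns <- character(0)
  tick <- function(expr, nm) {
    t0 <- proc.time()[3]
    out <- withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, sprintf("%s: %s", nm, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timings[nm] <<- unname(proc.time()[3] - t0)
    out
  }

  grid <- stim_grid()
  bias <- tick(make_bias_field(grid, config$bias_blobs, config$bias_amplitude,
                               config$bias_length_scale, seed = seeds[1]),
               "bias_field")
  retino <- retinotopy_model(scatter_sigma_on = config$scatter_sigma_on,
                             scatter_sigma_off = config$scatter_sigma_off)
  pop <- tick(sample_population(bias, retino, config$n_on, config$n_off,
                                config$n_simple, config$n_complex,
                                rf_sigma = config$rf_sigma,
                                dirichlet_conc = config$dirichlet_conc,
                                seed = seeds[2]),
              "population")
  stim <- tick(make_stimulus(config$n_stimuli, grid, config$p_bright,
                             config$p_dark, config$frame_rate,
                             seed = seeds[3]),
               "stimulus")
  resp <- tick(simulate_responses(pop, stim, gain = config$gain,
                                  baseline = config$baseline,
                                  delay_frames = config$delay_frames,
                                  seed = seeds[4]),
               "responses")
  kern <- tick(estimate_kernels(resp, stim, config$max_delay), "kernels")
  cls <- tick(classify_population(kern, grid, config$norm_threshold,
                                  config$ve_threshold, config$simple_threshold),
              "classification")
  cells <- cbind(pop$cells[, c("x1", "x2", "x3")], cls)
  cells$true_class <- pop$cells$class

  mono <- cells[cells$class %in% c("ON", "OFF"), , drop = FALSE]
  fl <- tick(fluctuation_map(mono[mono$class == "ON", c("x1", "x2")],
                             mono[mono$class == "OFF", c("x1", "x2")],
                             config$sigma_native,
                             native_grid(config$native_spacing,
                                         2 * config$sigma_native),
                             config$n_shuffles, config$alpha,
                             seed = seeds[5]),
             "domains")
  doms <- extract_level_sets(fl)

  # CCA on mono-contrast cells: estimated RF center of the significant polarity
  mono$y1 <- ifelse(mono$class == "ON", mono$on_y1, mono$off_y1)
  mono$y2 <- ifelse(mono$class == "ON", mono$on_y2, mono$off_y2)
  cca <- tick(fit_cca(as.matrix(mono[, c("x1", "x2", "x3")]),
                      as.matrix(mono[, c("y1", "y2")])),
              "cca")
  xhat <- cca_transform(as.matrix(mono[, c("x1", "x2", "x3")]), cca, "cortical")
  yhat <- cca_transform(as.matrix(mono[, c("y1", "y2")]), cca, "visual")
  mc <- tick(map_correlation(xhat, yhat, mono$class == "ON",
                             sigma = config$sigma_canonical,
                             grid = canonical_grid(config$canonical_spacing),
                             n_shuffles = config$n_shuffles,
                             seed = seeds[6]),
             "map_correlation")

  # neighborhood model on classified simple cells
  simple_idx <- which(cells$class == "SIMPLE")
  nbh <- NULL
  if (length(simple_idx) >= 3 &&
      sum(mono$class == "ON") >= config$k && sum(mono$class == "OFF") >= config$k) {
    srfs <- lapply(simple_idx, function(i) simple_rf(kern[[i]]$on, kern[[i]]$off))
    mono_maps <- stats::setNames(lapply(mono$cell_id, function(i) {
      pol <- tolower(mono$class[mono$cell_id == i])
      kern[[i]][[pol]]$peak_map
    }), mono$cell_id)
    mono_tab <- data.frame(id = mono$cell_id, class = mono$class,
                           x1 = mono$x1, x2 = mono$x2, x3 = mono$x3)
    nbh <- tick(fit_neighborhood_model(
      data.frame(id = cells$cell_id[simple_idx],
                 x1 = cells$x1[simple_idx], x2 = cells$x2[simple_idx],
                 x3 = cells$x3[simple_idx]),
      srfs, mono_tab, mono_maps, k = config$k),
      "neighborhood")
  }

  digests <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cell_path <- file.path(out_dir, "cells.csv")
    write_cells(data.frame(id = cells$cell_id, class = cells$class,
                           x1 = cells$x1, x2 = cells$x2, x3 = cells$x3,
                           cells[, !(names(cells) %in%
                                       c("cell_id", "class", "x1", "x2", "x3"))]),
                cell_path)
    dom_path <- file.path(out_dir, "domains.csv")
    utils::write.csv(doms$domains, dom_path, row.names = FALSE)
    jsonlite::write_json(
      list(rho = cca$rho, map_r = mc$pearson_r, map_p = mc$p_value,
           config = unclass(config)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    digests <- tools::md5sum(c(cell_path, dom_path,
                               file.path(out_dir, "summary.json")))
  }

  structure(
    list(population = pop, classification = cells, kernels = kern,
         domains = doms, fluctuation = fl, cca = cca, map_correlation = mc,
         neighborhood = nbh, seeds = seeds, timings = timings,
         warnings = warns, digests = digests, config = config),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run\n")
  cat(sprintf("  cells: %d (%s)\n", nrow(x$classification),
              paste(sprintf("%s %d", names(table(x$classification$class)),
                            table(x$classification$class)), collapse = ", ")))
  cat(sprintf("  domains: %d polygons; CCA rho = %.3f/%.3f; map r = %.3f (p = %.3g)\n",
              nrow(x$domains$domains), x$cca$rho[1], x$cca$rho[2],
              x$map_correlation$pearson_r, x$map_correlation$p_value))
  if (!is.null(x$neighborhood))
    cat(sprintf("  neighborhood model: median fit r = %.3f over %d simple cells\n",
                stats::median(vapply(x$neighborhood, function(f) f$fit_corr,
                                     numeric(1)), na.rm = TRUE),
                length(x$neighborhood)))
  invisible(x)
}
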