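## Pipeline driver: configuration, orchestration of the sampling ->
## fitting -> selection -> thermodynamics/net-flux stages, and run
## manifests.

#' Pipeline configuration
#'
#' @param scenario scenario name (see [standard_scenarios()]).
#' @param conditions conditions to run (first is the reference for fold
#'   changes).
#' @param n_samples flux distributions sampled per condition.
#' @param top_n size of the selected ensemble.
#' @param seed master seed; each stage derives its own stream.
#' @param measurements_path,catalogue_path,partitions_path,keq_path,kcat_path
#'   input tables (defaults: the packaged fixtures; the packaged
#'   measurements are synthetic reference data).
#' @param lower_frac concentration lower-bound preset (0.90 or 0.99).
#' @param warmup,thin hit-and-run schedule.
#' @param chloroplast_fraction chloroplast share of cell volume (volume
#'   bookkeeping recorded in the manifest).
#' @param out_dir output directory (`NULL` for no files).
#' @return list of class `cbc_pipeline_config`.
#' @export
pipeline_config <- function(scenario = "rubisco",
                            conditions = c("HC", "LC*"),
                            n_samples = 5000, top_n = 1000, seed = 1L,
                            measurements_path = cbc_data_file("measurements"),
                            catalogue_path = cbc_data_file("catalogue"),
                            partitions_path = cbc_data_file("partitions"),
                            keq_path = cbc_data_file("keq"),
                            kcat_path = cbc_data_file("kcat"),
                            lower_frac = 0.90, warmup = 1000L, thin = 100L,
                            chloroplast_fraction = 0.3118,
                            out_dir = NULL) {
  if (n_samples < top_n)
    warning("n_samples (", n_samples, ") is below top_n (", top_n,
            "); the whole sample will be selected")
  structure(as.list(environment()), class = "cbc_pipeline_config")
}

#' Run the full pipeline
#'
#' For every condition: build the scenario model, sample the constrained
#' flux cone, fit the log-linear program per sample, score by chi-square
#' and select the best `top_n`; then compute reaction energetics for each
#' condition and the cross-condition net-flux/fold-change report.  When
#' `out_dir` is set, all results are written as CSV/JSON with a manifest
#' recording the configuration, every seed, the solver tolerances and the
#' MD5 hash of every output file.
#'
#' @param config a [pipeline_config()].
#' @return list of class `cbc_pipeline_result` with per-condition runs,
#'   fits, selections, energetics, and the fold-change `report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cbc_pipeline_config"))
  catalogue <- read_catalogue(config$catalogue_path)
  partitions <- read_partitions(config$partitions_path)
  measurements <- read_measurements(config$measurements_path)
  kcat <- read_kcat_bounds(config$kcat_path)
  thermo <- thermo_config(keq = read_keq(config$keq_path))
  scen <- standard_scenarios(catalogue)[[config$scenario]]
  if (is.null(scen)) stop("unknown scenario: ", config$scenario)

  runs <- list(); fits <- list(); ensembles <- list(); energetics <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    run <- run_condition(scen, cond, measurements, config$n_samples,
                         seed = config$seed + 101L * ci,
                         catalogue = catalogue, partitions = partitions,
                         kcat = kcat, warmup = config$warmup,
                         thin = config$thin,
                         lower_frac = config$lower_frac)
    f <- evaluate_fits(run$param_sets, measurements, cond)
    ens <- select_ensemble(run, f, config$top_n)
    runs[[cond]] <- run; fits[[cond]] <- f; ensembles[[cond]] <- ens
    energetics[[cond]] <- .ensemble_energetics(ens, thermo, cond)
  }
  report <- if (length(config$conditions) >= 2)
    fold_change_report(ensembles[[1]], ensembles[[2]],
                       labels = config$conditions[1:2]) else NULL
  out <- structure(list(config = config, runs = runs, fits = fits,
                        ensembles = ensembles, energetics = energetics,
                        report = report), class = "cbc_pipeline_result")
  if (!is.null(config$out_dir)) .write_pipeline(out)
  out
}

.ensemble_energetics <- function(ens, thermo, condition) {
  model <- ens$model
  enzymatic <- model$catalogue[model$catalogue$kind == "enzymatic", ]
  dc <- direction_classes(ens$V, model, "stroma")
  rows <- list()
  for (i in seq_len(nrow(enzymatic))) {
    id <- enzymatic$id[i]
    for (cmp in c("stroma", "pyrenoid")) {
      if (!any(model$reactions$catalogue_id == id &
               model$reactions$compartment == cmp)) next
      dg <- vapply(ens$param_sets, function(p)
        delta_g(id, p, thermo, cmp)$delta_G, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = id, condition = condition, compartment = cmp,
        mean_delta_G = mean(dg), sd_delta_G = stats::sd(dg),
        direction_class = dc$direction_class[match(id, dc$reaction)],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.write_pipeline <- function(res) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- res$config$out_dir
  files <- character()
  wr <- function(df, name) {
    p <- file.path(od, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  for (cond in names(res$runs)) {
    tag <- gsub("[^A-Za-z0-9]", "", cond)
    wr(as.data.frame(res$runs[[cond]]$samples$V),
       paste0("samples_", tag, ".csv"))
    wr(res$runs[[cond]]$samples$Q, paste0("qdraws_", tag, ".csv"))
    wr(res$fits[[cond]], paste0("fits_", tag, ".csv"))
    wr(res$ensembles[[cond]]$selection, paste0("selection_", tag, ".csv"))
    wr(res$energetics[[cond]], paste0("energetics_", tag, ".csv"))
  }
  if (!is.null(res$report)) {
    wr(res$report$fluxes, "netflux_foldchange.csv")
    wr(res$report$pools, "pools_bound_free.csv")
  }
  cfg <- res$config; cfg$eq <- NULL
  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    package_version = as.character(utils::packageVersion("pyrenoidCBC")),
    seeds = lapply(res$runs, function(r) r$samples$seed),
    steady_state_tolerance = res$runs[[1]]$cone$tolerance,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(od)
}

#' Write measurements / partitions tables
#'
#' Writers matching [read_measurements()] and [read_partitions()] so that
#' synthetic datasets round-trip through the same files as real data.
#'
#' @param x data frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  utils::write.table(x[, c("metabolite", "condition", "mean_uM",
                           "se_uM", "n")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
write_partitions <- function(x, path) {
  utils::write.table(x[, c("enzyme", "condition", "fraction_mean",
                           "fraction_se")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
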