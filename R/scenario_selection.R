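## Chi-square scoring of fitted parameter sets against measured metabolite
## totals, ranking/selection, scenario comparison and Pearson validation.

#' Default metabolite panel for the goodness-of-fit statistic
#'
#' The 11 Calvin-Benson intermediates measured in both conditions and
#' present in the model.
#' @export
default_panel <- function()
  c("RuBP", "3PGA", "DHAP", "FBP", "F6P", "SBP", "S7P", "R5P", "X5P",
    "Ru5P", "GAP")

#' Chi-square between modelled and measured metabolite totals
#'
#' Pearson-style statistic `sum((modelled - measured)^2 / measured)` over
#' the metabolite panel, with the measured total as the expectation
#' (default), or the measurement-variance weighted form
#' `sum(((modelled - measured)/se)^2)`.
#'
#' @param x a `cbc_paramset`, or a named vector of modelled totals (µM).
#' @param measurements table from [read_measurements()].
#' @param condition measurement condition.
#' @param panel metabolite ids to score; default [default_panel()]
#'   restricted to measured metabolites.
#' @param form `"pearson"` or `"variance"`.
#' @return the statistic (single number).
#' @export
chi_square <- function(x, measurements, condition,
                       panel = default_panel(),
                       form = c("pearson", "variance")) {
  form <- match.arg(form)
  meas <- measurements[measurements$condition == condition, , drop = FALSE]
  missing_m <- setdiff(panel, meas$metabolite)
  if (length(missing_m))
    stop("no measurement for panel metabolite(s): ",
         paste(missing_m, collapse = ", "))
  modelled <- if (inherits(x, "cbc_paramset"))
    vapply(panel, function(m) total_concentration(x, m), numeric(1))
  else {
    missing_x <- setdiff(panel, names(x))
    if (length(missing_x))
      stop("no modelled total for panel metabolite(s): ",
           paste(missing_x, collapse = ", "))
    x[panel]
  }
  i <- match(panel, meas$metabolite)
  measured <- meas$mean_uM[i]
  if (form == "pearson")
    sum((modelled - measured)^2 / measured)
  else
    sum(((modelled - measured) / meas$se_uM[i])^2)
}

#' Modelled chloroplast totals of a fitted set over a panel
#' @param param_set a `cbc_paramset`.
#' @param panel metabolite ids.
#' @return named vector, µM.
#' @export
modelled_totals <- function(param_set, panel = default_panel())
  vapply(panel, function(m) total_concentration(param_set, m), numeric(1))

#' Score a list of fitted parameter sets
#'
#' @param param_sets list of `cbc_paramset`.
#' @param measurements,condition,panel,form passed to [chi_square()].
#' @param alpha significance level: a fit is `significant` (not rejected)
#'   when its statistic is at or below the upper `1 - alpha` chi-square
#'   critical value at `length(panel)` degrees of freedom.
#' @return data frame: `sample_index`, `chi_square`, `significant`,
#'   `objective_value`.
#' @export
evaluate_fits <- function(param_sets, measurements, condition,
                          panel = default_panel(),
                          form = c("pearson", "variance"), alpha = 0.05) {
  form <- match.arg(form)
  x2 <- vapply(param_sets, chi_square, numeric(1),
               measurements = measurements, condition = condition,
               panel = panel, form = form)
  crit <- stats::qchisq(1 - alpha, df = length(panel))
  data.frame(
    sample_index = vapply(param_sets, function(p)
      as.integer(p$source_sample_index), integer(1)),
    chi_square = x2,
    significant = x2 <= crit,
    objective_value = vapply(param_sets, `[[`, numeric(1),
                             "objective_value"))
}

#' Rank fits by chi-square and keep the best
#'
#' Ascending chi-square, ties broken by objective value then sample index;
#' stable and deterministic.
#'
#' @param fits data frame from [evaluate_fits()].
#' @param top_n how many to keep (default 1000).
#' @return the selected rows, in rank order.
#' @export
rank_and_select <- function(fits, top_n = 1000) {
  if (top_n > nrow(fits))
    warning("only ", nrow(fits), " fits available; top_n = ", top_n,
            " requested — returning all")
  ord <- order(fits$chi_square, fits$objective_value, fits$sample_index,
               method = "radix")
  out <- fits[ord, , drop = FALSE][seq_len(min(top_n, nrow(fits))), ,
                                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run sampling and fitting for one scenario and condition
#'
#' Convenience wrapper: builds the scenario model and its flux cone,
#' samples `n_samples` steady-state flux distributions and fits each by
#' the log-linear program.
#'
#' @param scen a `cbc_scenario`.
#' @param condition `"HC"` or `"LC*"`.
#' @param measurements measurement table (for concentration bounds).
#' @param n_samples number of flux samples / fits.
#' @param seed RNG seed.
#' @param catalogue,partitions,kcat input tables.
#' @param warmup,thin hit-and-run schedule (see [sample_fluxes()]).
#' @param lower_frac lower-bound preset for [build_bounds()].
#' @return list with `model`, `cone`, `samples`, `param_sets`.
#' @export
run_condition <- function(scen, condition, measurements, n_samples,
                          seed = 1L, catalogue = read_catalogue(),
                          partitions = read_partitions(),
                          kcat = read_kcat_bounds(),
                          warmup = 1000L, thin = 100L, lower_frac = 0.90) {
  model <- build_model(catalogue, scen, condition)
  cone <- build_constraints(model, partitions, condition)
  samples <- sample_fluxes(cone, n_samples, seed = seed,
                           warmup = warmup, thin = thin)
  bounds <- build_bounds(measurements, model, condition,
                         lower_frac = lower_frac)
  param_sets <- lapply(seq_len(n_samples), function(i)
    fit(fluxdist(samples, i), model, bounds, kcat = kcat))
  list(model = model, cone = cone, samples = samples,
       param_sets = param_sets)
}

#' Compare pyrenoid-enzyme scenarios by mean chi-square
#'
#' Runs the sampling + fitting pipeline for each scenario and condition
#' with identical sample counts, reports the mean chi-square, and flags the
#' circular-transport artifact: a scenario whose pyrenoid copy of some
#' enzyme carries (almost) no catalytic flux while the diffusion reactions
#' of that enzyme's metabolites cycle material in and out of the pyrenoid.
#'
#' @param scenarios named list of `cbc_scenario`.
#' @param conditions character vector of conditions.
#' @param measurements measurement table.
#' @param n_samples samples per scenario and condition.
#' @param seed base seed; each scenario/condition gets a derived stream.
#' @param ... passed to [run_condition()].
#' @return object of class `cbc_scenario_comparison`: data frame with
#'   `scenario`, `condition`, `mean_chi_square`, `n`,
#'   `circular_transport`, plus the runs in `attr(, "runs")`.
#' @export
compare_scenarios <- function(scenarios, conditions, measurements,
                              n_samples, seed = 1L, ...) {
  rows <- list(); runs <- list()
  k <- 0L
  for (sn in names(scenarios)) for (cond in conditions) {
    k <- k + 1L
    run <- run_condition(scenarios[[sn]], cond, measurements, n_samples,
                         seed = seed + 1000L * k, ...)
    fits <- evaluate_fits(run$param_sets, measurements, cond)
    rows[[k]] <- data.frame(
      scenario = sn, condition = cond,
      mean_chi_square = mean(fits$chi_square), n = n_samples,
      circular_transport = .circular_transport_flag(run),
      stringsAsFactors = FALSE)
    runs[[paste(sn, cond, sep = "/")]] <- c(run, list(fits = fits))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cbc_scenario_comparison", class(out))
  attr(out, "runs") <- runs
  out
}

.circular_transport_flag <- function(run, cat_tol = 1e-3, cyc_tol = 1) {
  model <- run$model; rx <- model$reactions
  vbar <- colMeans(run$samples$V)
  for (e in model$scenario$pyrenoid_enzymes) {
    cat_p <- vbar[rx$id[rx$enzyme %in% e & rx$step_kind == "catalytic" &
                        rx$compartment == "pyrenoid"]]
    if (!length(cat_p) || sum(cat_p) > cat_tol) next
    mets <- transported_metabolites(model$catalogue,
                                    scenario("tmp", e))
    tr <- rx$catalogue_id[rx$kind == "transport"]
    for (m in setdiff(mets, "CO2")) {
      cid <- model$catalogue$id[model$catalogue$kind == "transport"][
        vapply(model$catalogue$eq[model$catalogue$kind == "transport"],
               function(z) z$substrates$species, "") == m]
      if (!length(cid) || !cid %in% tr) next
      f <- vbar[paste0(cid, "_f")]; b <- vbar[paste0(cid, "_b")]
      if (!is.na(f) && !is.na(b) && min(f, b) > cyc_tol) return(TRUE)
    }
  }
  FALSE
}

#' Pearson validation of selected parameter sets
#'
#' Correlates the ensemble-mean modelled totals of the selected sets with
#' the measured totals across the panel.
#'
#' @param param_sets list of `cbc_paramset` (the selected ensemble).
#' @param measurements,condition,panel as in [chi_square()].
#' @return list with `r`, `p_value`, `n` (panel size),
#'   `modelled` and `measured` vectors.
#' @export
pearson_validation <- function(param_sets, measurements, condition,
                               panel = default_panel()) {
  if (!length(param_sets)) stop("no parameter sets selected")
  M <- vapply(param_sets, modelled_totals, numeric(length(panel)),
              panel = panel)
  modelled <- rowMeans(matrix(M, nrow = length(panel),
                              dimnames = list(panel, NULL)))
  meas <- measurements[measurements$condition == condition, ]
  measured <- meas$mean_uM[match(panel, meas$metabolite)]
  ct <- stats::cor.test(modelled, measured, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(panel),
       modelled = modelled, measured = stats::setNames(measured, panel))
}
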