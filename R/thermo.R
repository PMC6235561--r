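## Post-processing of selected parameter ensembles: reaction Gibbs
## energies, net fluxes, fold changes, bound/free pools and
## diffusion-constant proxies.

#' Thermodynamic configuration
#'
#' @param T_K temperature in kelvin; default 297.15 K (24 °C culture).
#' @param R_J gas constant, J mol-1 K-1.
#' @param keq equilibrium-constant table (columns `reaction`, `keq`,
#'   `delta_n`); `delta_n` is the change in molecularity, so that Keq and
#'   the reaction quotient are on a consistent mol/L basis.
#' @param conc_to_M factor converting model concentrations (µM) to mol/L.
#' @return list of class `cbc_thermo`.
#' @export
thermo_config <- function(T_K = 297.15, R_J = 8.31446,
                          keq = read_keq(), conc_to_M = 1e-6) {
  stopifnot(T_K > 0, all(keq$keq > 0))
  structure(list(T_K = T_K, R_J = R_J, keq = keq, conc_to_M = conc_to_M),
            class = "cbc_thermo")
}

#' Read the equilibrium-constant table
#' @param path TSV with columns `reaction`, `keq`, `delta_n`, `note`.
#' @return data frame.
#' @export
read_keq <- function(path = cbc_data_file("keq")) {
  k <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction", "keq", "delta_n") %in% names(k)))
  k
}

#' Gibbs energy of one reaction in one compartment
#'
#' `delta_G = -R T (ln Keq - ln Q)` with Q the ratio of free product to
#' free reactant concentrations (converted to mol/L against the 1 M
#' standard state; enzymes and complexes never enter Q).
#'
#' @param reaction catalogue reaction id.
#' @param param_set a `cbc_paramset`.
#' @param thermo a `cbc_thermo`.
#' @param compartment `"stroma"` or `"pyrenoid"`.
#' @return list with `reaction`, `compartment`, `Q`, `keq`,
#'   `delta_G` (kJ/mol).
#' @export
delta_g <- function(reaction, param_set, thermo = thermo_config(),
                    compartment = "stroma") {
  model <- param_set$model
  i <- match(reaction, model$catalogue$id)
  if (is.na(i)) stop("unknown reaction: ", reaction)
  krow <- match(reaction, thermo$keq$reaction)
  if (is.na(krow)) stop("no equilibrium constant for reaction ", reaction)
  eq <- model$catalogue$eq[[i]]
  sfx <- .sfx(compartment)
  conc <- function(df) {
    ids <- paste0(df$species, sfx)
    cc <- param_set$c[ids]
    if (anyNA(cc)) stop("species missing from parameter set: ",
                        paste(ids[is.na(cc)], collapse = ", "))
    if (any(cc <= 0)) stop("nonpositive concentration for ",
                           paste(ids[cc <= 0], collapse = ", "))
    sum(df$coef * log(cc * thermo$conc_to_M))
  }
  lnQ <- conc(eq$products) - conc(eq$substrates)
  keq <- thermo$keq$keq[krow]
  dG <- -thermo$R_J * thermo$T_K * (log(keq) - lnQ) / 1000
  list(reaction = reaction, compartment = compartment, Q = exp(lnQ),
       keq = keq, delta_G = dG)
}

#' Net flux of a catalogue reaction in one flux distribution
#'
#' Non-enzymatic stroma-pyrenoid pairs report `v_f - v_b` (positive =
#' stroma to pyrenoid); an irreversible enzymatic reaction reports its
#' catalytic flux `v_cat` (binding/unbinding fluxes are not activity);
#' a reversible enzymatic reaction reports `v_cat_f - v_cat_b`; exchange
#' and pseudo-reactions report their single flux.
#'
#' @param v named flux vector over model reactions.
#' @param catalogue_reaction catalogue id.
#' @param model a `cbc_model`.
#' @param compartment compartment of an enzymatic reaction.
#' @return net flux, µM/s.
#' @export
net_flux <- function(v, catalogue_reaction, model,
                     compartment = "stroma") {
  i <- match(catalogue_reaction, model$catalogue$id)
  if (is.na(i)) stop("unknown reaction: ", catalogue_reaction)
  kind <- model$catalogue$kind[i]
  g <- function(id) { x <- v[id]; if (is.na(x)) 0 else unname(x) }
  if (kind == "transport")
    g(paste0(catalogue_reaction, "_f")) - g(paste0(catalogue_reaction, "_b"))
  else if (kind %in% c("exchange", "pseudo"))
    g(catalogue_reaction)
  else if (model$catalogue$eq[[i]]$reversible)
    g(paste0(catalogue_reaction, "_catf", .sfx(compartment))) -
      g(paste0(catalogue_reaction, "_catb", .sfx(compartment)))
  else
    g(paste0(catalogue_reaction, "_cat", .sfx(compartment)))
}

#' Free and bound pools of a metabolite in a fitted set
#'
#' @param param_set a `cbc_paramset`.
#' @param metabolite metabolite id.
#' @return named vector `free_stroma`, `free_pyrenoid`, `bound` (µM);
#'   the bound pool sums every complex containing the metabolite, weighted
#'   by its stoichiometry.
#' @export
bound_free_split <- function(param_set, metabolite) {
  model <- param_set$model
  sp <- model$species
  if (!metabolite %in% stats::na.omit(sp$metabolite))
    stop("unknown metabolite: ", metabolite)
  pick <- function(cmp) {
    id <- sp$id[!is.na(sp$metabolite) & sp$metabolite == metabolite &
                sp$compartment == cmp]
    if (length(id)) unname(param_set$c[id]) else 0
  }
  cc <- model$complex_composition
  bnd <- cc[cc$metabolite == metabolite, , drop = FALSE]
  c(free_stroma = pick("stroma"), free_pyrenoid = pick("pyrenoid"),
    bound = if (nrow(bnd)) sum(param_set$c[bnd$complex] * bnd$mult) else 0)
}

#' Diffusion-constant proxy
#'
#' First-order rate coefficient implied by a net transport flux and the
#' stroma-pyrenoid free-concentration difference: `flux / gradient`.
#' A zero gradient with nonzero flux is the no-gradient transport case
#' (diffusional equilibrium despite net flux, as for 3PGA): the proxy is
#' undefined and returned as `NA` with a `reason` attribute, never as 0/0.
#'
#' @param net_transport_flux µM/s.
#' @param gradient stroma minus pyrenoid free concentration, µM.
#' @return s-1, or flagged `NA`.
#' @export
diffusion_proxy <- function(net_transport_flux, gradient) {
  if (gradient == 0) {
    reason <- if (net_transport_flux != 0) "no-gradient transport"
              else "no flux, no gradient"
    return(structure(NA_real_, reason = reason))
  }
  net_transport_flux / gradient
}

#' Classify reaction directionality over an ensemble
#'
#' A reversible enzymatic reaction is `bidirectional` when both catalytic
#' directions carry at least `frac` of the larger one in at least `share`
#' of the selected flux distributions; otherwise it is forward-only or
#' backward-only by the sign of its mean net flux.  Irreversible reactions
#' are forward-only by construction.
#'
#' @param V matrix of selected flux samples (rows = samples).
#' @param model a `cbc_model`.
#' @param compartment compartment to classify.
#' @param frac,share thresholds (defaults 1% and 5%).
#' @return data frame `reaction`, `direction_class`.
#' @export
direction_classes <- function(V, model, compartment = "stroma",
                              frac = 0.01, share = 0.05) {
  cat_rows <- model$catalogue[model$catalogue$kind == "enzymatic", ]
  out <- lapply(seq_len(nrow(cat_rows)), function(i) {
    id <- cat_rows$id[i]
    if (!cat_rows$eq[[i]]$reversible)
      return(data.frame(reaction = id, direction_class = "forward-only"))
    fcol <- paste0(id, "_catf", .sfx(compartment))
    bcol <- paste0(id, "_catb", .sfx(compartment))
    if (!fcol %in% colnames(V))
      return(data.frame(reaction = id, direction_class = "absent"))
    f <- V[, fcol]; b <- V[, bcol]
    big <- pmax(f, b)
    both <- mean(pmin(f, b) > frac * pmax(big, 1e-12))
    cls <- if (both >= share) "bidirectional"
           else if (mean(f - b) >= 0) "forward-only" else "backward-only"
    data.frame(reaction = id, direction_class = cls)
  })
  do.call(rbind, out)
}

#' Ensemble net-flux and fold-change report between conditions
#'
#' For two selected ensembles (typically HC and LC*), reports the mean net
#' flux of every catalogue reaction (per compartment for enzymatic ones;
#' positive transport = stroma to pyrenoid), the LC*/HC fold change, and
#' the mean free/bound concentration split per metabolite and condition.
#'
#' @param ensemble_hc,ensemble_lc lists with elements `model`, `V`
#'   (selected flux samples) and `param_sets` (selected fitted sets); see
#'   [select_ensemble()].
#' @param labels condition labels for the two ensembles.
#' @return list of class `cbc_netflux_report` with data frames `fluxes`
#'   (`reaction`, `scope`, mean net flux per condition, `fold_change`)
#'   and `pools` (per metabolite and condition: free/bound means).
#' @export
fold_change_report <- function(ensemble_hc, ensemble_lc,
                               labels = c("HC", "LC*")) {
  mean_net <- function(ens, id, scope) {
    nf <- apply(ens$V, 1, function(v)
      net_flux(v, id, ens$model,
               compartment = if (scope %in% c("stroma", "pyrenoid"))
                 scope else "stroma"))
    mean(nf)
  }
  cat_df <- ensemble_hc$model$catalogue
  rows <- list()
  for (i in seq_len(nrow(cat_df))) {
    id <- cat_df$id[i]; kind <- cat_df$kind[i]
    scopes <- if (kind == "enzymatic") c("stroma", "pyrenoid") else kind
    for (sc in scopes) {
      if (sc == "pyrenoid" &&
          !any(ensemble_hc$model$reactions$catalogue_id == id &
               ensemble_hc$model$reactions$compartment == "pyrenoid") &&
          !any(ensemble_lc$model$reactions$catalogue_id == id &
               ensemble_lc$model$reactions$compartment == "pyrenoid"))
        next
      hc <- mean_net(ensemble_hc, id, sc)
      lc <- mean_net(ensemble_lc, id, sc)
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = id, scope = sc, hc = hc, lc = lc,
        fold_change = if (abs(hc) > 1e-12) lc / hc else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  fluxes <- do.call(rbind, rows)
  names(fluxes)[names(fluxes) == "hc"] <- labels[1]
  names(fluxes)[names(fluxes) == "lc"] <- labels[2]

  mets <- sort(unique(stats::na.omit(ensemble_hc$model$species$metabolite)))
  pool_rows <- list()
  for (ens_i in 1:2) {
    ens <- list(ensemble_hc, ensemble_lc)[[ens_i]]
    for (m in mets) {
      S <- vapply(ens$param_sets, bound_free_split, numeric(3),
                  metabolite = m)
      pool_rows[[length(pool_rows) + 1L]] <- data.frame(
        metabolite = m, condition = labels[ens_i],
        free_stroma = mean(S["free_stroma", ]),
        free_pyrenoid = mean(S["free_pyrenoid", ]),
        bound = mean(S["bound", ]), stringsAsFactors = FALSE)
    }
  }
  structure(list(fluxes = fluxes, pools = do.call(rbind, pool_rows),
                 sign_convention =
                   "positive transport flux = stroma to pyrenoid"),
            class = "cbc_netflux_report")
}

#' Select the top-ranked ensemble from a pipeline run
#'
#' @param run list from [run_condition()].
#' @param fits data frame from [evaluate_fits()].
#' @param top_n ensemble size.
#' @return list with `model`, `V` (selected flux samples) and
#'   `param_sets` (selected fitted sets).
#' @export
select_ensemble <- function(run, fits, top_n = 1000) {
  sel <- rank_and_select(fits, top_n)
  idx <- sel$sample_index
  list(model = run$model, V = run$samples$V[idx, , drop = FALSE],
       param_sets = run$param_sets[idx], selection = sel)
}

#' Steady-state mass balance at the pyrenoid boundary
#'
#' For every pyrenoid metabolite, net transport into the pyrenoid must
#' equal its net consumption by pyrenoid reactions; returns the largest
#' absolute imbalance (µM/s) over pyrenoid metabolites.
#'
#' @param model a `cbc_model`.
#' @param v flux vector.
#' @return max absolute imbalance.
#' @export
pyrenoid_mass_balance <- function(model, v) {
  sp <- model$species
  pyr_met <- sp$id[sp$compartment == "pyrenoid" & sp$role == "metabolite"]
  if (!length(pyr_met)) return(0)
  max(abs(as.numeric(model$N[pyr_met, , drop = FALSE] %*% v)))
}
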