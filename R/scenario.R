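#' Define a pyrenoid-enzyme scenario
#'
#' A scenario states which enzymes are catalytically active inside the
#' pyrenoid.  Stroma-pyrenoid exchange is then only allowed for metabolites
#' (including cofactors) that take part in reactions catalysed by those
#' enzymes; CO2 additionally always crosses by diffusion, since the carbon
#' concentrating mechanism requires CO2 enrichment around pyrenoid Rubisco.
#'
#' @param name scenario label.
#' @param pyrenoid_enzymes character vector of enzyme ids active in the
#'   pyrenoid (may be empty).
#' @return object of class `cbc_scenario`.
#' @seealso [standard_scenarios()]
#' @export
scenario <- function(name, pyrenoid_enzymes = character()) {
  structure(list(name = name,
                 pyrenoid_enzymes = unique(as.character(pyrenoid_enzymes))),
            class = "cbc_scenario")
}

#' Metabolites transported between stroma and pyrenoid under a scenario
#'
#' Derived, not user-set: exactly the metabolites appearing in reactions
#' catalysed by the scenario's pyrenoid enzymes, plus CO2.
#'
#' @param catalogue a `cbc_catalogue`.
#' @param scen a `cbc_scenario`.
#' @return character vector of metabolite ids.
#' @export
transported_metabolites <- function(catalogue, scen) {
  rows <- which(catalogue$kind == "enzymatic" &
                catalogue$enzyme %in% scen$pyrenoid_enzymes)
  mets <- unlist(lapply(catalogue$eq[rows], function(e)
    c(e$substrates$species, e$products$species)))
  unique(c("CO2", mets))
}

#' The scenarios compared in the study
#'
#' Three hypotheses about which Calvin-Benson enzymes are active inside the
#' pyrenoid: (i) PRK, Rubisco and GAPDH (both chloroplast isoforms),
#' (ii) PRK and Rubisco, (iii) Rubisco only; plus the `full` scenario in
#' which every catalogue enzyme is active in both compartments (used for
#' the model census).
#'
#' @param catalogue catalogue used to enumerate enzymes for `full`.
#' @return named list of `cbc_scenario` objects.
#' @export
standard_scenarios <- function(catalogue = read_catalogue()) {
  all_enz <- unique(stats::na.omit(catalogue$enzyme))
  list(
    prk_rubisco_gapdh = scenario("prk_rubisco_gapdh",
                                 c("PRK", "RBC", "GAP1", "GAP3")),
    prk_rubisco       = scenario("prk_rubisco", c("PRK", "RBC")),
    rubisco           = scenario("rubisco", "RBC"),
    full              = scenario("full", all_enz)
  )
}

#' @export
print.cbc_scenario <- function(x, ...) {
  cat("<cbc_scenario>", x$name, "\n  pyrenoid enzymes:",
      if (length(x$pyrenoid_enzymes)) paste(x$pyrenoid_enzymes, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
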