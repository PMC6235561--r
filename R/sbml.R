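## SBML Level 3 export/import of the elementary-reaction model.

.sbml_id <- function(prefix, x) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", x))

#' Export a model as SBML Level 3
#'
#' Species and irreversible elementary reactions with their stoichiometries
#' (the mass-action rate constants are parameters of the estimation, not of
#' the structural model, and are not embedded).  Original identifiers are
#' kept in the `name` attributes; SBML ids are sanitised.
#'
#' @param model a `cbc_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = .sbml_id("mod_", model$scenario$name))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in unique(model$species$compartment))
    xml2::xml_add_child(lc, "compartment", id = .sbml_id("c_", cmp),
                        constant = "true", spatialDimensions = "3",
                        size = "1")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$species))) {
    s <- model$species[i, ]
    xml2::xml_add_child(ls, "species", id = .sbml_id("S_", s$id),
                        name = s$id, compartment = .sbml_id("c_", s$compartment),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  N <- model$N
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    rn <- xml2::xml_add_child(lr, "reaction", id = .sbml_id("R_", r$id),
                              name = r$id, reversible = "false")
    col <- N[, j]
    subs <- which(col < 0); prods <- which(col > 0)
    if (length(subs)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in subs)
        xml2::xml_add_child(lre, "speciesReference",
                            species = .sbml_id("S_", rownames(N)[i]),
                            stoichiometry = format(-col[i]),
                            constant = "true")
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in prods)
        xml2::xml_add_child(lpr, "speciesReference",
                            species = .sbml_id("S_", rownames(N)[i]),
                            stoichiometry = format(col[i]),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import an SBML file written by [export_sbml()]
#'
#' @param path SBML file.
#' @return list with `species` (original ids), `reactions` (original ids)
#'   and the sparse stoichiometric matrix `N`.
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_sid <- xml2::xml_attr(sp_nodes, "id")
  sp_id <- xml2::xml_attr(sp_nodes, "name")
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rx_id <- xml2::xml_attr(rx_nodes, "name")
  trip <- list(i = integer(), j = integer(), x = numeric())
  for (j in seq_along(rx_nodes)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx_nodes[[j]],
                                 paste0("./", side, "/speciesReference"))
      if (!length(refs)) next
      i <- match(xml2::xml_attr(refs, "species"), sp_sid)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      sgn <- if (side == "listOfReactants") -1 else 1
      trip$i <- c(trip$i, i); trip$j <- c(trip$j, rep(j, length(i)))
      trip$x <- c(trip$x, sgn * st)
    }
  }
  N <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(length(sp_id), length(rx_id)),
                            dimnames = list(sp_id, rx_id))
  list(species = sp_id, reactions = rx_id, N = N)
}

#' Dump a model to JSON (stoichiometry as sparse triplets)
#'
#' @param model a `cbc_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  Nt <- Matrix::summary(model$N)
  jsonlite::write_json(list(
    species = model$species, reactions = model$reactions,
    stoichiometry = data.frame(species = rownames(model$N)[Nt$i],
                               reaction = colnames(model$N)[Nt$j],
                               coef = Nt$x),
    scenario = model$scenario$name, condition = model$condition),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
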