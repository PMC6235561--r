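## Model assembly: elementary-reaction decomposition and the stoichiometric
## matrix N (rows = species, columns = irreversible elementary reactions).

.sfx <- function(compartment) switch(compartment, stroma = "_s",
                                     pyrenoid = "_p",
                                     stop("bad compartment ", compartment))

#' Decompose a catalogue reaction into elementary reactions
#'
#' An irreversible enzymatic reaction A -> B catalysed by E becomes three
#' elementary steps (`A + E -> AE`, `AE -> A + E`, `AE -> B + E`); a
#' reversible one becomes six, with one enzyme-substrate complex per
#' direction.  All co-substrates bind in a single step, so each direction
#' has exactly one complex.  A reversible non-enzymatic transport becomes
#' its two irreversible directions; `exchange` and `pseudo` reactions pass
#' through as single irreversible reactions.  All elementary reactions are
#' irreversible by construction.
#'
#' @param reaction one row of a `cbc_catalogue` (a data frame of one row,
#'   e.g. `catalogue[3, ]`).
#' @param compartment `"stroma"` or `"pyrenoid"`; where to instantiate an
#'   enzymatic or pseudo reaction (ignored for transport/exchange).
#' @return list of elementary reactions, each a list with `id`,
#'   `catalogue_id`, `kind`, `step_kind`, `compartment`, `enzyme`,
#'   `stoich` (named net-stoichiometry vector over species ids) and,
#'   for binding/unbinding/catalytic steps, the complex id.
#' @export
decompose <- function(reaction, compartment = "stroma") {
  stopifnot(nrow(reaction) == 1L)
  eq <- reaction$eq[[1]]
  kind <- reaction$kind
  id <- reaction$id

  if (kind == "enzymatic") {
    if (is.na(reaction$enzyme))
      stop("enzymatic reaction ", id, " has no enzyme id")
    sfx <- .sfx(compartment)
    enz <- paste0(reaction$enzyme, sfx)
    tag_sp <- function(df) stats::setNames(df$coef, paste0(df$species, sfx))
    subs <- tag_sp(eq$substrates)
    prods <- tag_sp(eq$products)
    mk <- function(step, step_kind, stoich, cx)
      list(id = paste0(id, "_", step, sfx), catalogue_id = id, kind = kind,
           step_kind = step_kind, compartment = compartment,
           enzyme = reaction$enzyme, stoich = stoich, complex = cx)
    half <- function(sub, prod, bind, unbind, catal, cx) {
      list(
        mk(bind, "binding",
           c(-sub, stats::setNames(-1, enz), stats::setNames(1, cx)), cx),
        mk(unbind, "unbinding",
           c(sub, stats::setNames(1, enz), stats::setNames(-1, cx)), cx),
        mk(catal, "catalytic",
           c(prod, stats::setNames(1, enz), stats::setNames(-1, cx)), cx)
      )
    }
    if (!eq$reversible) {
      cx <- paste0(id, "_cx", sfx)
      half(subs, prods, "bind", "unbind", "cat", cx)
    } else {
      cxf <- paste0(id, "_cxf", sfx)
      cxb <- paste0(id, "_cxb", sfx)
      c(half(subs,  prods, "bindf", "unbindf", "catf", cxf),
        half(prods, subs,  "bindb", "unbindb", "catb", cxb))
    }
  } else if (kind == "transport") {
    sp <- eq$substrates$species
    from <- paste0(sp, "_", eq$substrates$tag)
    to <- paste0(sp, "_", eq$products$tag)
    mk <- function(d, step_kind, st)
      list(id = paste0(id, d), catalogue_id = id, kind = kind,
           step_kind = step_kind, compartment = "transport",
           enzyme = NA_character_, stoich = st, complex = NA_character_)
    list(mk("_f", "transport-forward",
            stats::setNames(c(-1, 1), c(from, to))),
         mk("_b", "transport-backward",
            stats::setNames(c(1, -1), c(from, to))))
  } else { # exchange or pseudo: single irreversible reaction, as written
    sp_side <- function(df, sign) {
      keep <- df$tag != "c"           # boundary species: open, not modelled
      if (!any(keep)) return(numeric())
      sfx <- ifelse(df$tag[keep] == "p", "_p", "_s")
      stats::setNames(sign * df$coef[keep], paste0(df$species[keep], sfx))
    }
    if (kind == "pseudo" && any(c(eq$substrates$tag, eq$products$tag) == ""))
      { # untagged pseudo species live in the requested compartment
        sfx <- .sfx(compartment)
        sp_side <- function(df, sign)
          stats::setNames(sign * df$coef, paste0(df$species, sfx))
      }
    st <- c(sp_side(eq$substrates, -1), sp_side(eq$products, 1))
    list(list(id = id, catalogue_id = id, kind = kind,
              step_kind = if (kind == "pseudo") "pseudo" else "exchange",
              compartment = if (kind == "pseudo") compartment else "envelope",
              enzyme = NA_character_, stoich = st,
              complex = NA_character_))
  }
}

#' Build the two-compartment stoichiometric model
#'
#' Instantiates the full Calvin-Benson cycle in the stroma, the
#' scenario-selected enzymatic reactions in the pyrenoid, stroma-pyrenoid
#' diffusion pairs for the scenario's transported metabolites, the cytosol
#' exchange reactions and the ATPase/FNR pseudo-reactions, all decomposed
#' into irreversible elementary reactions.  Species and reactions are
#' ordered lexicographically by (compartment, id) so that the stoichiometric
#' matrix is reproducible bit for bit.
#'
#' @param catalogue a `cbc_catalogue`.
#' @param scen a `cbc_scenario`; default the full (all-enzyme, all-transport)
#'   model used for the census.
#' @param condition free-text condition label stored with the model
#'   (e.g. `"HC"`, `"LC*"`).
#' @param moieties moiety table used to validate mass balance.
#' @return object of class `cbc_model` with elements `species` (data frame:
#'   id, name, compartment, role, parent_enzyme, metabolite), `reactions`
#'   (data frame: id, catalogue_id, kind, step_kind, compartment, enzyme,
#'   rate_constant_id), `N` (sparse species x reaction matrix),
#'   `complex_composition`, `scenario`, `condition`.
#' @export
build_model <- function(catalogue = read_catalogue(),
                        scen = standard_scenarios(catalogue)$full,
                        condition = "HC",
                        moieties = read_moieties()) {
  stopifnot(inherits(catalogue, "cbc_catalogue"), inherits(scen, "cbc_scenario"))
  unknown <- setdiff(scen$pyrenoid_enzymes, stats::na.omit(catalogue$enzyme))
  if (length(unknown))
    stop("scenario names enzyme(s) absent from the catalogue: ",
         paste(unknown, collapse = ", "))
  .check_catalogue_moieties(catalogue, moieties)
  transported <- transported_metabolites(catalogue, scen)

  elems <- list()
  for (i in seq_len(nrow(catalogue))) {
    row <- catalogue[i, ]
    if (row$kind == "enzymatic") {
      cmp <- row$compartments
      in_stroma <- cmp %in% c("both", "stroma")
      in_pyr <- cmp %in% c("both", "pyrenoid") &&
        row$enzyme %in% scen$pyrenoid_enzymes
      if (in_stroma) elems <- c(elems, decompose(row, "stroma"))
      if (in_pyr)    elems <- c(elems, decompose(row, "pyrenoid"))
    } else if (row$kind == "transport") {
      if (row$eq[[1]]$substrates$species %in% transported)
        elems <- c(elems, decompose(row))
    } else if (row$kind == "pseudo") {
      cmp <- if (row$compartments %in% c("stroma", "pyrenoid"))
        row$compartments else "stroma"
      elems <- c(elems, decompose(row, cmp))
    } else {
      elems <- c(elems, decompose(row))
    }
  }

  rx <- data.frame(
    id = vapply(elems, `[[`, "", "id"),
    catalogue_id = vapply(elems, `[[`, "", "catalogue_id"),
    kind = vapply(elems, `[[`, "", "kind"),
    step_kind = vapply(elems, `[[`, "", "step_kind"),
    compartment = vapply(elems, `[[`, "", "compartment"),
    enzyme = vapply(elems, `[[`, "", "enzyme"),
    stringsAsFactors = FALSE)
  rx$rate_constant_id <- rx$id
  ord <- order(rx$compartment, rx$id, method = "radix")
  rx <- rx[ord, ]; elems <- elems[ord]
  rownames(rx) <- NULL

  species <- .collect_species(elems, catalogue, moieties)
  spec_index <- stats::setNames(seq_len(nrow(species)), species$id)

  trip_i <- integer(); trip_j <- integer(); trip_x <- numeric()
  for (j in seq_along(elems)) {
    st <- elems[[j]]$stoich
    if (!length(st)) next
    trip_i <- c(trip_i, spec_index[names(st)])
    trip_j <- c(trip_j, rep.int(j, length(st)))
    trip_x <- c(trip_x, unname(st))
  }
  N <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nrow(species), nrow(rx)),
                            dimnames = list(species$id, rx$id))
  if (any(Matrix::colSums(N != 0) == 0))
    stop("internal error: all-zero reaction column in N")

  model <- structure(list(species = species, reactions = rx, N = N,
                          complex_composition =
                            .complex_composition(catalogue, species),
                          catalogue = catalogue, scenario = scen,
                          condition = condition, moieties = moieties),
                     class = "cbc_model")
  chk <- moiety_check(model)
  if (!chk$ok)
    stop("moiety imbalance in reaction(s): ",
         paste(unique(chk$violations$reaction), collapse = ", "))
  model
}

.collect_species <- function(elems, catalogue, moieties) {
  ids <- unique(unlist(lapply(elems, function(e) names(e$stoich))))
  base <- sub("_[sp]$", "", ids)
  comp <- ifelse(grepl("_p$", ids), "pyrenoid", "stroma")
  enzymes <- unique(stats::na.omit(catalogue$enzyme))
  role <- ifelse(base %in% moieties$metabolite, "metabolite",
          ifelse(base %in% enzymes, "enzyme", "complex"))
  cat_of_cx <- sub("_cx[fb]?$", "", base)
  parent <- rep(NA_character_, length(ids))
  is_cx <- role == "complex"
  parent[is_cx] <- catalogue$enzyme[match(cat_of_cx[is_cx], catalogue$id)]
  if (anyNA(parent[is_cx]))
    stop("unrecognised species id(s): ",
         paste(ids[is_cx][is.na(parent[is_cx])], collapse = ", "))
  sp <- data.frame(id = ids, name = base, compartment = comp, role = role,
                   parent_enzyme = ifelse(is_cx, paste0(parent,
                     ifelse(comp == "pyrenoid", "_p", "_s")), NA_character_),
                   metabolite = ifelse(role == "metabolite", base,
                                       NA_character_),
                   stringsAsFactors = FALSE)
  sp <- sp[order(sp$compartment, sp$id, method = "radix"), ]
  rownames(sp) <- NULL
  sp
}

## metabolite content of each enzyme-substrate complex (for bound pools)
.complex_composition <- function(catalogue, species) {
  cx <- species[species$role == "complex", ]
  if (!nrow(cx)) return(data.frame(complex = character(),
                                   metabolite = character(),
                                   mult = numeric()))
  out <- lapply(seq_len(nrow(cx)), function(i) {
    base <- cx$name[i]
    cat_id <- sub("_cx[fb]?$", "", base)
    side <- if (grepl("_cxb$", base)) "products" else "substrates"
    eq <- catalogue$eq[[match(cat_id, catalogue$id)]]
    df <- eq[[side]]
    data.frame(complex = cx$id[i], metabolite = df$species, mult = df$coef,
               compartment = cx$compartment[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.check_catalogue_moieties <- function(catalogue, moieties) {
  for (i in seq_len(nrow(catalogue))) {
    if (catalogue$kind[i] == "exchange") next   # open boundary
    eq <- catalogue$eq[[i]]
    bal <- function(col) {
      f <- function(df) sum(df$coef *
        moieties[[col]][match(df$species, moieties$metabolite)])
      f(eq$products) - f(eq$substrates)
    }
    unknown <- setdiff(c(eq$substrates$species, eq$products$species),
                       moieties$metabolite)
    if (length(unknown))
      stop("reaction ", catalogue$id[i],
           " uses metabolite(s) missing from the moiety table: ",
           paste(unknown, collapse = ", "))
    if (catalogue$kind[i] == "pseudo") next     # lumped light reactions
    if (abs(bal("carbon")) > 1e-9 || abs(bal("phosphate")) > 1e-9)
      stop("moiety imbalance in catalogue reaction ", catalogue$id[i])
  }
  invisible(TRUE)
}

#' Check conserved moieties of a built model
#'
#' Verifies, column by column of the stoichiometric matrix, that (a) every
#' enzyme moiety (free enzyme plus all of its complexes) is conserved by
#' every reaction and (b) carbon and phosphate balance in every
#' non-boundary reaction, with complexes carrying the moieties of their
#' bound metabolites.  Exchange reactions are exempt (open boundaries).
#'
#' @param model a `cbc_model`.
#' @return list with `ok`, `conserved_pools` (the enzyme moieties, each a
#'   character vector of species), and `violations` (data frame naming the
#'   offending reaction and moiety; empty when `ok`).
#' @export
moiety_check <- function(model) {
  sp <- model$species
  moieties <- model$moieties
  enz_ids <- sp$id[sp$role == "enzyme"]
  pools <- lapply(enz_ids, function(e)
    c(e, sp$id[!is.na(sp$parent_enzyme) & sp$parent_enzyme == e]))
  names(pools) <- enz_ids

  M <- matrix(0, nrow(sp), length(pools) + 2,
              dimnames = list(sp$id, c(names(pools), "carbon", "phosphate")))
  for (e in names(pools)) M[pools[[e]], e] <- 1
  met_rows <- sp$role == "metabolite"
  M[met_rows, "carbon"] <-
    moieties$carbon[match(sp$name[met_rows], moieties$metabolite)]
  M[met_rows, "phosphate"] <-
    moieties$phosphate[match(sp$name[met_rows], moieties$metabolite)]
  cc <- model$complex_composition
  if (nrow(cc)) {
    midx <- match(cc$metabolite, moieties$metabolite)
    carb <- rowsum(cc$mult * moieties$carbon[midx], cc$complex)
    phos <- rowsum(cc$mult * moieties$phosphate[midx], cc$complex)
    M[rownames(carb), "carbon"] <- M[rownames(carb), "carbon"] + carb[, 1]
    M[rownames(phos), "phosphate"] <-
      M[rownames(phos), "phosphate"] + phos[, 1]
  }

  B <- as.matrix(Matrix::t(model$N) %*% M)       # reactions x moieties
  exempt_c <- model$reactions$kind %in% c("exchange", "pseudo")
  B[exempt_c, c("carbon", "phosphate")] <- 0
  bad <- which(abs(B) > 1e-9, arr.ind = TRUE)
  violations <- data.frame(
    reaction = model$reactions$id[bad[, 1]],
    moiety = colnames(B)[bad[, 2]],
    imbalance = B[bad], stringsAsFactors = FALSE)
  list(ok = nrow(violations) == 0L, conserved_pools = pools,
       violations = violations)
}

#' Model census
#'
#' Reaction and component counts of a built model, broken down by kind,
#' together with the reference totals (226 irreversible reactions, 128
#' components) and the itemised reference census (2 x 65 elementary
#' reactions + 40 diffusion + 8 triose-phosphate exchanges + 2
#' pseudo-reactions = 180) that the literature model reports; the two
#' reference figures disagree with each other, so both are exposed and the
#' builder's own numbers are the operative ones.
#'
#' @param model a `cbc_model`.
#' @return list of counts; printed compactly.
#' @export
census <- function(model) {
  rx <- model$reactions; sp <- model$species
  by_kind <- table(rx$kind)
  per_copy <- table(rx$compartment[rx$kind == "enzymatic"])
  out <- list(
    n_reactions = nrow(rx),
    n_species = nrow(sp),
    reactions_by_kind = c(by_kind),
    enzymatic_by_compartment = c(per_copy),
    species_by_role = c(table(sp$role)),
    reference_totals = c(reactions = 226L, components = 128L),
    reference_itemised = c(per_copy = 65L, copies = 2L, diffusion = 40L,
                           cytosol_exchange = 8L, pseudo = 2L, total = 180L),
    delta_vs_totals = c(reactions = nrow(rx) - 226L,
                        components = nrow(sp) - 128L))
  class(out) <- "cbc_census"
  out
}

#' @export
print.cbc_census <- function(x, ...) {
  cat("model census:", x$n_reactions, "irreversible reactions,",
      x$n_species, "components\n")
  cat("  by kind:", paste(names(x$reactions_by_kind),
                          x$reactions_by_kind, collapse = ", "), "\n")
  cat("  by role:", paste(names(x$species_by_role),
                          x$species_by_role, collapse = ", "), "\n")
  cat("  reference totals: ", x$reference_totals[["reactions"]], "/",
      x$reference_totals[["components"]],
      " (delta ", x$delta_vs_totals[["reactions"]], "/",
      x$delta_vs_totals[["components"]], ")\n", sep = "")
  cat("  reference itemised census: 2x65 + 40 + 8 + 2 = 180\n")
  invisible(x)
}

#' @export
print.cbc_model <- function(x, ...) {
  cat("<cbc_model> scenario '", x$scenario$name, "', condition ",
      x$condition, "\n  ", nrow(x$species), " species x ",
      nrow(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Substrate-order matrix of mass-action kinetics
#'
#' Returns the matrix of substrate stoichiometries (`-n_ij` where
#' `n_ij < 0`, else 0) whose columns are the mass-action exponents of each
#' elementary reaction: `v_j = k_j * prod_i c_i ^ nminus_ij`.
#'
#' @param model a `cbc_model`.
#' @return sparse species x reaction matrix.
#' @export
nminus <- function(model) {
  N <- model$N
  Nm <- -N
  Nm@x[Nm@x < 0] <- 0
  Matrix::drop0(Nm)
}

#' Mass-action fluxes at given concentrations and rate constants
#'
#' @param model a `cbc_model`.
#' @param conc named (or model-ordered) nonnegative concentration vector, µM.
#' @param k named (or model-ordered) rate-constant vector.
#' @param constant_flux optional named vector of reactions whose flux is a
#'   fixed boundary value (zeroth order), e.g. the CO2 uptake.
#' @return flux vector over model reactions (µM/s).
#' @export
mass_action_flux <- function(model, conc, k, constant_flux = NULL) {
  conc <- .as_model_vector(conc, model$species$id, "concentration")
  k <- .as_model_vector(k, model$reactions$id, "rate constant")
  Nm <- nminus(model)
  lv <- log(k) + as.numeric(Matrix::t(Nm) %*% log(pmax(conc, 1e-300)))
  v <- exp(lv)
  zero_sub <- as.numeric(Matrix::t(Nm) %*% (conc <= 0)) > 0
  v[zero_sub] <- 0
  names(v) <- model$reactions$id
  if (!is.null(constant_flux)) v[names(constant_flux)] <- constant_flux
  v
}

.as_model_vector <- function(x, ids, what) {
  if (!is.null(names(x))) {
    miss <- setdiff(ids, names(x))
    if (length(miss)) stop("missing ", what, " for: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    unname(x[ids])
  } else {
    stopifnot(length(x) == length(ids))
    as.numeric(x)
  }
}
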