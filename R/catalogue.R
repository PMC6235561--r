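#' Built-in data files
#'
#' Paths to the tab-separated tables shipped with the package: the reaction
#' catalogue of the two-compartment Calvin-Benson cycle, the carbon/phosphate
#' moiety table used for mass-balance validation, the equilibrium-constant
#' table, literature turnover-number bounds, and the measured enzyme
#' partition fractions between pyrenoid and stroma.
#'
#' @param file one of `"catalogue"`, `"moieties"`, `"keq"`, `"kcat"`,
#'   `"partitions"`, `"measurements"` (the last is a synthetic reference
#'   dataset generated by the package's own ground-truth simulator).
#' @return path to the file.
#' @export
cbc_data_file <- function(file = c("catalogue", "moieties", "keq", "kcat",
                                   "partitions", "measurements")) {
  file <- match.arg(file)
  fn <- c(catalogue  = "cbc_catalogue.tsv",
          moieties   = "moieties.tsv",
          keq        = "keq.tsv",
          kcat       = "kcat_bounds.tsv",
          partitions = "partitions.tsv",
          measurements = "measurements_synthetic.tsv")[[file]]
  system.file("extdata", fn, package = "pyrenoidCBC", mustWork = TRUE)
}

#' Parse a reaction equation
#'
#' Equations use the text form `"A + 2 B -> C"` (irreversible) or
#' `"C <-> D"` (reversible).  Species tokens may carry a compartment tag:
#' `[s]` stroma, `[p]` pyrenoid, `[c]` cytosol/boundary (outside the
#' chloroplast; such species are treated as an open boundary and are not
#' instantiated in the model).  A bare integer token is the stoichiometric
#' coefficient of the following species.
#'
#' @param eq equation string.
#' @return list with data frames `substrates` and `products`
#'   (columns `species`, `coef`, `tag`) and logical `reversible`.
#' @keywords internal
parse_equation <- function(eq) {
  reversible <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("malformed equation: ", eq)
  parse_side <- function(s) {
    s <- trimws(s)
    if (s == "")
      return(data.frame(species = character(), coef = numeric(),
                        tag = character(), stringsAsFactors = FALSE))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(tm) {
      toks <- strsplit(tm, "[[:space:]]+")[[1]]
      coef <- 1
      if (length(toks) == 2L) {
        coef <- suppressWarnings(as.numeric(toks[1]))
        if (is.na(coef)) stop("bad coefficient in term '", tm, "'")
        toks <- toks[2]
      } else if (length(toks) != 1L) {
        stop("bad term '", tm, "' in equation: ", eq)
      }
      sp <- toks[1]
      tag <- ""
      m <- regmatches(sp, regexec("^(.+)\\[([spc])\\]$", sp))[[1]]
      if (length(m) == 3L) {
        sp <- m[2]; tag <- m[3]
      }
      data.frame(species = sp, coef = coef, tag = tag,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  list(substrates = parse_side(sides[1]),
       products   = parse_side(sides[2]),
       reversible = reversible)
}

#' Read a reaction catalogue
#'
#' The catalogue is a TSV with columns `id`, `equation`, `enzyme`, `kind`
#' (`enzymatic`, `transport`, `exchange` or `pseudo`) and `compartments`
#' (`both`, `stroma`, `pyrenoid` or `-`).  Enzymatic rows must name exactly
#' one enzyme; transport rows connect the same chemical species in stroma
#' and pyrenoid.
#'
#' @param path TSV file; default the packaged Calvin-Benson catalogue.
#' @return a `cbc_catalogue` data frame with a parsed `eq` list-column.
#' @export
read_catalogue <- function(path = cbc_data_file("catalogue")) {
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "equation", "enzyme", "kind", "compartments")
  missing <- setdiff(required, names(cat_df))
  if (length(missing))
    stop("catalogue is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(cat_df$id))
    stop("duplicate catalogue reaction id(s): ",
         paste(unique(cat_df$id[duplicated(cat_df$id)]), collapse = ", "))
  bad_kind <- setdiff(cat_df$kind,
                      c("enzymatic", "transport", "exchange", "pseudo"))
  if (length(bad_kind))
    stop("unknown reaction kind(s): ", paste(bad_kind, collapse = ", "))
  cat_df$enzyme[cat_df$enzyme %in% c("-", "")] <- NA_character_
  no_enz <- cat_df$kind == "enzymatic" & is.na(cat_df$enzyme)
  if (any(no_enz))
    stop("enzymatic reaction(s) without an enzyme id: ",
         paste(cat_df$id[no_enz], collapse = ", "))
  cat_df$eq <- lapply(cat_df$equation, parse_equation)
  for (i in which(cat_df$kind == "transport")) {
    e <- cat_df$eq[[i]]
    ok <- nrow(e$substrates) == 1L && nrow(e$products) == 1L &&
      e$substrates$species == e$products$species &&
      setequal(c(e$substrates$tag, e$products$tag), c("s", "p"))
    if (!ok)
      stop("transport reaction ", cat_df$id[i],
           " must connect one species between stroma [s] and pyrenoid [p]")
  }
  class(cat_df) <- c("cbc_catalogue", class(cat_df))
  cat_df
}

#' Read the metabolite moiety table
#'
#' Carbon and phosphate counts per metabolite.  Nicotinamide cofactors are
#' booked with zero carbon/phosphate (their internal atoms never transfer);
#' ATP/ADP carry only their transferable phosphates (3/2).
#'
#' @param path TSV file with columns `metabolite`, `carbon`, `phosphate`.
#' @return data frame.
#' @export
read_moieties <- function(path = cbc_data_file("moieties")) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite", "carbon", "phosphate") %in% names(m)))
  m
}
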