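## Log-linear mass-action parameter estimation: for a sampled steady-state
## flux distribution v*, find compartment-specific free concentrations c and
## rate constants k with log v*_j = log k_j + sum_i nminus_ij log c_i,
## minimising the total log-difference between paired pyrenoid and stroma
## rate constants (and the deviation from literature turnover numbers).

#' Read measured (or synthetic) chloroplast metabolite totals
#'
#' @param path TSV with columns `metabolite`, `condition`, `mean_uM`,
#'   `se_uM`, `n`.
#' @return data frame.
#' @export
read_measurements <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "condition", "mean_uM", "se_uM", "n")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("measurements table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(m$mean_uM <= 0)) stop("measured concentrations must be positive")
  m
}

#' Read literature rate-constant bounds
#'
#' @param path TSV with columns `enzyme`, `k_lit`, `k_min`, `k_max`,
#'   `source`; bounds apply to the catalytic steps of the enzyme
#'   (forward direction for reversible reactions).
#' @return data frame.
#' @export
read_kcat_bounds <- function(path = cbc_data_file("kcat")) {
  k <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("enzyme", "k_lit", "k_min", "k_max") %in% names(k)))
  if (any(k$k_min <= 0 | k$k_min > k$k_max))
    stop("invalid kinetic bounds (need 0 < k_min <= k_max)")
  k
}

#' Concentration bounds for the log-linear program
#'
#' Measured metabolites: the upper bound of every free pool is 100% of the
#' measured total; the lower bound is a configurable 90% (or 99%) of the
#' total, except 3PGA (50%) and RuBP/BPGA, which only get the generic
#' floor of 0.01 µM (their pools are mostly enzyme-bound).  Unmeasured
#' species — enzymes, complexes, cofactors and unmeasured metabolites —
#' get generic bounds.
#'
#' @param measurements table from [read_measurements()].
#' @param model a `cbc_model`.
#' @param condition measurement condition to use.
#' @param lower_frac preset lower-bound fraction for ordinary metabolites
#'   (0.90 default, 0.99 sensitivity).
#' @param generic generic \[min, max\] bounds, µM, for unmeasured
#'   metabolites (cofactor pools).
#' @param generic_enzyme generic \[min, max\] bounds, µM, for enzymes and
#'   enzyme-substrate complexes (protein pools are at most a couple of
#'   hundred µM in the chloroplast).
#' @param relaxed_lower metabolites whose lower bound is the generic floor.
#' @param half_lower metabolites whose lower bound is 50% of the total.
#' @return data frame: `species`, `c_min`, `c_max` (µM), `measured`.
#' @export
build_bounds <- function(measurements, model, condition,
                         lower_frac = 0.90,
                         generic = c(1e-3, 1e4),
                         generic_enzyme = c(1e-6, 200),
                         relaxed_lower = c("RuBP", "BPGA"),
                         half_lower = "3PGA") {
  meas <- measurements[measurements$condition == condition, , drop = FALSE]
  unknown <- setdiff(meas$metabolite,
                     stats::na.omit(model$species$metabolite))
  if (length(unknown))
    stop("measured metabolite(s) not in the model: ",
         paste(unknown, collapse = ", "),
         "; valid ids: ",
         paste(sort(unique(stats::na.omit(model$species$metabolite))),
               collapse = ", "))
  sp <- model$species
  c_min <- rep(generic[1], nrow(sp))
  c_max <- rep(generic[2], nrow(sp))
  protein <- sp$role %in% c("enzyme", "complex")
  c_min[protein] <- generic_enzyme[1]
  c_max[protein] <- generic_enzyme[2]
  measured <- rep(FALSE, nrow(sp))
  for (i in seq_len(nrow(meas))) {
    met <- meas$metabolite[i]; tot <- meas$mean_uM[i]
    idx <- which(!is.na(sp$metabolite) & sp$metabolite == met)
    lo <- if (met %in% relaxed_lower) generic[1]
          else if (met %in% half_lower) 0.5 * tot
          else lower_frac * tot
    c_min[idx] <- max(min(lo, tot), generic[1])
    c_max[idx] <- tot
    measured[idx] <- TRUE
  }
  data.frame(species = sp$id, c_min = c_min, c_max = c_max,
             measured = measured, stringsAsFactors = FALSE)
}

## expand the per-enzyme kcat table to per-elementary-reaction bounds
.kinetic_bounds <- function(model, kcat, generic_log10 = c(-3, 8)) {
  rx <- model$reactions
  k_min <- rep(10^generic_log10[1], nrow(rx))
  k_max <- rep(10^generic_log10[2], nrow(rx))
  ## the generic kinetic prior covers enzymatic elementary steps; exchange
  ## and pseudo-reactions are boundary conditions, and inter-compartment
  ## diffusion may be arbitrarily slow or fast a priori
  boundary <- rx$kind %in% c("exchange", "pseudo", "transport")
  k_min[boundary] <- 1e-12
  k_max[boundary] <- 1e12
  k_lit <- rep(NA_real_, nrow(rx))
  if (!is.null(kcat) && nrow(kcat)) {
    fwd_cat <- rx$step_kind == "catalytic" &
      !grepl("_catb_[sp]$", rx$id)
    for (i in seq_len(nrow(kcat))) {
      sel <- fwd_cat & rx$enzyme %in% kcat$enzyme[i]
      k_min[sel] <- kcat$k_min[i]
      k_max[sel] <- kcat$k_max[i]
      k_lit[sel] <- kcat$k_lit[i]
    }
  }
  data.frame(reaction = rx$id, k_min = k_min, k_max = k_max, k_lit = k_lit,
             stringsAsFactors = FALSE)
}

## pyrenoid elementary reactions paired with their stroma counterparts
.rate_pairs <- function(model) {
  rx <- model$reactions
  pyr <- which(rx$kind == "enzymatic" & rx$compartment == "pyrenoid")
  if (!length(pyr)) return(data.frame(pyr = integer(), str = integer()))
  str_id <- sub("_p$", "_s", rx$id[pyr])
  str <- match(str_id, rx$id)
  keep <- !is.na(str)
  data.frame(pyr = pyr[keep], str = str[keep])
}

#' Fit concentrations and rate constants to one flux distribution
#'
#' Solves the log-linear program: mass-action consistency as hard equality
#' for every active reaction, concentration and rate-constant boxes, and an
#' L1 objective that (a) pulls each pyrenoid rate constant towards its
#' stroma counterpart (elastic variables eps+ and eps-) and (b) pulls
#' literature-constrained catalytic constants towards their published
#' values (unit weight).  Rate constants are eliminated by substitution
#' (`log k_j = log v*_j - sum_i nminus_ij log c_i`), so the decision
#' variables are the log free concentrations plus the elastics.
#'
#' @param v_star flux vector over model reactions (named or model-ordered),
#'   or a list from [fluxdist()].
#' @param model a `cbc_model`.
#' @param bounds concentration bounds from [build_bounds()].
#' @param kcat literature table from [read_kcat_bounds()], or `NULL`.
#' @param generic_log10_k generic log10 rate-constant bounds.
#' @param lit_weight weight of the literature-deviation terms.
#' @param zero_tol fluxes at or below this are treated as inactive (their
#'   mass-action equations are dropped and k is set to the geometric mean
#'   of its bounds); the default matches the sub-tolerance scale of the
#'   flux sampler, below which a flux is numerically zero.
#' @param sample_index bookkeeping index stored in the result.
#' @return object of class `cbc_paramset`: `c` (µM, named), `k` (named),
#'   `epsilon` (data frame per pair), `objective_value`, `residual`
#'   (max mass-action log residual over active reactions), `active`,
#'   `source_sample_index`.
#' @export
fit <- function(v_star, model, bounds, kcat = read_kcat_bounds(),
                generic_log10_k = c(-3, 8), lit_weight = 1,
                zero_tol = 1e-4, sample_index = NA_integer_) {
  if (is.list(v_star) && !is.null(v_star$v)) {
    if (is.na(sample_index)) sample_index <- v_star$sample_index
    v_star <- v_star$v
  }
  v <- .as_model_vector(v_star, model$reactions$id, "flux")
  if (any(v < -zero_tol)) stop("fluxes must be nonnegative")
  sp_ids <- model$species$id
  stopifnot(identical(bounds$species, sp_ids))
  kb <- .kinetic_bounds(model, kcat, generic_log10_k)

  active <- v > zero_tol
  Nm <- as.matrix(nminus(model))
  nsp <- length(sp_ids)
  lv <- ifelse(active, log(pmax(v, zero_tol)), NA_real_)

  pairs <- .rate_pairs(model)
  pairs <- pairs[active[pairs$pyr] & active[pairs$str], , drop = FALSE]
  lit_idx <- which(!is.na(kb$k_lit) & active)
  npair <- nrow(pairs); nlit <- length(lit_idx)
  nvar <- nsp + 2 * npair + 2 * nlit

  obj <- c(rep(0, nsp), rep(1, 2 * npair), rep(lit_weight, 2 * nlit))
  lb <- c(log(pmax(bounds$c_min, 1e-12)), rep(0, 2 * (npair + nlit)))
  ub <- c(log(bounds$c_max), rep(60, 2 * (npair + nlit)))

  ## log k_j expressed in log c:  log k_j = lv_j - Nm[,j] . x
  A_eq <- NULL; b_eq <- NULL
  if (npair) {
    A <- matrix(0, npair, nvar)
    for (r in seq_len(npair)) {
      jp <- pairs$pyr[r]; js <- pairs$str[r]
      A[r, seq_len(nsp)] <- -(Nm[, jp] - Nm[, js])
      A[r, nsp + 2 * r - 1] <- -1
      A[r, nsp + 2 * r] <- 1
    }
    A_eq <- A
    b_eq <- -(lv[pairs$pyr] - lv[pairs$str])
  }
  if (nlit) {
    A <- matrix(0, nlit, nvar)
    for (r in seq_len(nlit)) {
      j <- lit_idx[r]
      A[r, seq_len(nsp)] <- -Nm[, j]
      A[r, nsp + 2 * npair + 2 * r - 1] <- -1
      A[r, nsp + 2 * npair + 2 * r] <- 1
    }
    A_eq <- rbind(A_eq, A)
    b_eq <- c(b_eq, log(kb$k_lit[lit_idx]) - lv[lit_idx])
  }

  ## k-box inequalities:  log kmin_j <= lv_j - Nm[,j] . x <= log kmax_j
  act_idx <- which(active)
  A_le <- matrix(0, 2 * length(act_idx), nvar)
  b_le <- numeric(2 * length(act_idx))
  for (r in seq_along(act_idx)) {
    j <- act_idx[r]
    A_le[2 * r - 1, seq_len(nsp)] <- -Nm[, j]        # -Nm.x <= log kmax - lv
    b_le[2 * r - 1] <- log(kb$k_max[j]) - lv[j]
    A_le[2 * r, seq_len(nsp)] <- Nm[, j]             #  Nm.x <= lv - log kmin
    b_le[2 * r] <- lv[j] - log(kb$k_min[j])
  }

  res <- solve_lp(obj, lb, ub, A_le = A_le, b_le = b_le,
                  A_eq = A_eq, b_eq = b_eq)
  if (!res$solved) {
    relax <- .diagnose_infeasible(obj, lb, ub, A_le, b_le, A_eq, b_eq, nsp)
    stop("log-linear program infeasible for this flux distribution; ",
         "relaxing the ", relax, " bounds restores feasibility")
  }
  x <- res$x[seq_len(nsp)]
  conc <- stats::setNames(exp(x), sp_ids)
  logk <- lv - as.numeric(crossprod(Nm, x))
  logk[!active] <- 0.5 * (log(kb$k_min) + log(kb$k_max))[!active]
  k <- stats::setNames(exp(logk), model$reactions$id)

  residual <- if (any(active))
    max(abs(log(pmax(v[active], zero_tol)) -
            (logk[active] + as.numeric(crossprod(Nm[, active, drop = FALSE],
                                                 x))))) else 0
  eps <- if (npair) data.frame(
    pyr = model$reactions$id[pairs$pyr],
    str = model$reactions$id[pairs$str],
    eps_plus = res$x[nsp + 2 * seq_len(npair) - 1],
    eps_minus = res$x[nsp + 2 * seq_len(npair)],
    stringsAsFactors = FALSE) else
    data.frame(pyr = character(), str = character(),
               eps_plus = numeric(), eps_minus = numeric())
  structure(list(c = conc, k = k, epsilon = eps,
                 objective_value = res$value, residual = residual,
                 active = stats::setNames(active, model$reactions$id),
                 v = stats::setNames(v, model$reactions$id),
                 model = model,
                 source_sample_index = sample_index),
            class = "cbc_paramset")
}

.diagnose_infeasible <- function(obj, lb, ub, A_le, b_le, A_eq, b_eq, nsp) {
  wide_k <- solve_lp(obj, lb, ub, A_le = A_le, b_le = b_le + 50,
                     A_eq = A_eq, b_eq = b_eq)
  if (wide_k$solved) return("kinetic (rate-constant)")
  lb2 <- lb; ub2 <- ub
  lb2[seq_len(nsp)] <- lb2[seq_len(nsp)] - 50
  ub2[seq_len(nsp)] <- ub2[seq_len(nsp)] + 50
  wide_c <- solve_lp(obj, lb2, ub2, A_le = A_le, b_le = b_le,
                     A_eq = A_eq, b_eq = b_eq)
  if (wide_c$solved) return("concentration")
  "concentration and kinetic"
}

#' @export
print.cbc_paramset <- function(x, ...) {
  cat("<cbc_paramset> sample", x$source_sample_index,
      "objective", signif(x$objective_value, 4),
      "max log-residual", signif(x$residual, 3), "\n")
  invisible(x)
}

#' Total chloroplast concentration of a metabolite in a fitted set
#'
#' The comparison convention of the study: free stroma pool + free pyrenoid
#' pool + all enzyme-bound amounts (each complex weighted by the
#' stoichiometry of the metabolite in it), summed as concentrations on the
#' common chloroplast-volume basis.
#'
#' @param param_set a `cbc_paramset`.
#' @param metabolite metabolite id (e.g. `"RuBP"`).
#' @return total concentration, µM.
#' @export
total_concentration <- function(param_set, metabolite) {
  model <- param_set$model
  sp <- model$species
  if (!metabolite %in% stats::na.omit(sp$metabolite))
    stop("unknown metabolite: ", metabolite)
  free_ids <- sp$id[!is.na(sp$metabolite) & sp$metabolite == metabolite]
  cc <- model$complex_composition
  bnd <- cc[cc$metabolite == metabolite, , drop = FALSE]
  sum(param_set$c[free_ids]) +
    if (nrow(bnd)) sum(param_set$c[bnd$complex] * bnd$mult) else 0
}
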