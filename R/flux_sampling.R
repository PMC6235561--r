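## Constrained flux cone (steady state, bounds, fixed boundary fluxes,
## enzyme-partition ratio constraints) and hit-and-run sampling from it.

#' Read measured enzyme partition fractions
#'
#' @param path TSV with columns `enzyme`, `condition`, `fraction_mean`,
#'   `fraction_se`.
#' @return data frame with derived `fraction_low`/`fraction_high`
#'   (mean +- 1 SE, clipped to \[0,1\]).
#' @export
read_partitions <- function(path = cbc_data_file("partitions")) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("enzyme", "condition", "fraction_mean", "fraction_se")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("partitions table missing column(s): ",
                         paste(miss, collapse = ", "))
  p$fraction_low <- pmax(0, p$fraction_mean - p$fraction_se)
  p$fraction_high <- pmin(1, p$fraction_mean + p$fraction_se)
  bad <- p$fraction_mean < 0 | p$fraction_mean > 1
  if (any(bad)) stop("partition fraction outside [0,1] for: ",
                     paste(p$enzyme[bad], collapse = ", "))
  p
}

## metabolite measurements refer to LC* cells; proteins were measured in LC
partition_condition <- function(condition)
  if (condition %in% c("LC*", "LC")) "LC" else condition

#' Draw a pyrenoid partition fraction q
#'
#' Uniform draw from the measured range, with two special cases: enzymes
#' whose measured pyrenoid share is below 5% are treated as stroma-only
#' (q = 0 exactly), and a degenerate range returns its single value.
#'
#' @param partition one row of a partitions table (list or 1-row data
#'   frame with `fraction_mean`, `fraction_low`, `fraction_high`).
#' @return a single fraction in \[0,1\].
#' @export
draw_q <- function(partition) {
  m <- partition$fraction_mean
  if (m < 0.05) return(0)
  lo <- partition$fraction_low; hi <- partition$fraction_high
  if (hi <= lo) return(lo)
  stats::runif(1, lo, hi)
}

#' Build the constrained flux cone of a model
#'
#' Imposes steady state `N v = 0`, flux bounds `0 <= v <= vmax` (the cap
#' does not apply to pseudo-reactions, which lump whole-membrane
#' activities), fixed boundary fluxes (CO2 uptake 398 µM/s, FNR 796 µM/s
#' NADPH, ATPase 1194 µM/s ATP, all derived from measured O2 evolution at
#' 2 NADPH per O2 and 1.5 ATP per NADPH), zero-pinned auxiliary envelope
#' exchanges, and per-enzyme flux-partition ratio constraints
#' `v_pyr = q (v_str + v_pyr)` on the catalytic steps of every pyrenoid
#' enzyme with a measured partition.
#'
#' @param model a `cbc_model`.
#' @param partitions partitions table from [read_partitions()].
#' @param condition `"HC"`, `"LC"` or `"LC*"` (LC* uses the LC protein
#'   partitions).
#' @param fixed named vector of fixed fluxes (reaction ids must exist in
#'   the model; defaults above).
#' @param vmax upper flux bound, µM/s.
#' @param pin_zero reaction ids pinned to zero flux; default the auxiliary
#'   envelope exchanges (net CO2 uptake measured; nucleotide translocator
#'   dark-active; malate valve closed at balanced redox).
#' @param ratio_mode `"equality"` (the ratio holds exactly) or `"bound"`
#'   (pyrenoid share at most q).
#' @param tolerance steady-state tolerance on `N v`.
#' @return object of class `cbc_fluxcone`.
#' @export
build_constraints <- function(model, partitions = read_partitions(),
                              condition = model$condition,
                              fixed = c(X_CO2_UPT = 398, FNR = 796,
                                        ATPASE = 1194),
                              vmax = 1000,
                              pin_zero = c("X_CO2_REL", "X_ATP_IMP",
                                           "X_ADP_EXP", "X_OAA_IMP",
                                           "X_OAA_EXP", "X_MAL_EXP",
                                           "X_MAL_IMP"),
                              ratio_mode = c("equality", "bound"),
                              tolerance = 1e-6 * vmax) {
  ratio_mode <- match.arg(ratio_mode)
  rx <- model$reactions
  fixed <- fixed[names(fixed) %in% rx$id]
  over <- names(fixed)[fixed > vmax &
                       rx$kind[match(names(fixed), rx$id)] != "pseudo"]
  if (length(over))
    stop("fixed flux exceeds vmax for: ", paste(over, collapse = ", "),
         " (vmax = ", vmax, ")")
  if (any(fixed < 0)) stop("fixed fluxes must be nonnegative")

  pin_zero <- intersect(pin_zero, rx$id)
  v_fix <- c(fixed, stats::setNames(rep(0, length(pin_zero)), pin_zero))
  fixed_idx <- match(names(v_fix), rx$id)
  free_idx <- setdiff(seq_len(nrow(rx)), fixed_idx)

  N <- as.matrix(model$N)
  b_eq <- -as.numeric(N[, fixed_idx, drop = FALSE] %*% v_fix)
  N_free <- N[, free_idx, drop = FALSE]

  pcond <- partition_condition(condition)
  if (!all(c("fraction_low", "fraction_high") %in% names(partitions))) {
    partitions$fraction_low <-
      pmax(0, partitions$fraction_mean - partitions$fraction_se)
    partitions$fraction_high <-
      pmin(1, partitions$fraction_mean + partitions$fraction_se)
  }
  part <- partitions[partitions$condition == pcond, , drop = FALSE]
  ratio_info <- list()
  for (e in model$scenario$pyrenoid_enzymes) {
    pe <- part[part$enzyme == e, , drop = FALSE]
    if (nrow(pe) == 0L) next
    cat_p <- which(rx$enzyme %in% e & rx$step_kind == "catalytic" &
                   rx$compartment == "pyrenoid")
    cat_s <- which(rx$enzyme %in% e & rx$step_kind == "catalytic" &
                   rx$compartment == "stroma")
    if (!length(cat_p)) next
    ratio_info[[e]] <- list(partition = pe[1, ],
                            cat_p = match(cat_p, free_idx),
                            cat_s = match(cat_s, free_idx),
                            rep_catalogue = rx$catalogue_id[cat_p[1]])
  }

  cone <- structure(list(
    model = model, condition = condition, vmax = vmax,
    fixed = v_fix, fixed_idx = fixed_idx, free_idx = free_idx,
    N_free = N_free, b_eq = b_eq, ratio_info = ratio_info,
    ratio_mode = ratio_mode, tolerance = tolerance,
    partitions = part), class = "cbc_fluxcone")

  ## feasibility witness at the mean q of every ratio-constrained enzyme
  q_mean <- vapply(ratio_info, function(ri)
    if (ri$partition$fraction_mean < 0.05) 0 else ri$partition$fraction_mean,
    numeric(1))
  wit <- .cone_witness(cone, q_mean)
  if (is.null(wit))
    stop("flux constraint set is infeasible for condition ", condition,
         ": no steady-state flux vector satisfies the fixed fluxes (",
         paste(names(fixed), fixed, sep = "=", collapse = ", "),
         "), bounds [0, ", vmax, "] and partition ratios")
  ## hit-and-run must start away from a vertex: average vertices found by
  ## optimising random objectives over the cone (ACHR-style warm-up)
  cone$witness <- .cone_center(cone, q_mean, wit)
  cone$q_witness <- q_mean
  cone$Z0 <- null_basis(N_free)
  cone$shift_dirs <- .ratio_shift_dirs(cone)
  cone
}

.ratio_rows <- function(cone, q) {
  ri <- cone$ratio_info
  if (!length(ri)) return(matrix(0, 0, length(cone$free_idx)))
  rows <- matrix(0, length(ri), length(cone$free_idx))
  for (i in seq_along(ri)) {
    rows[i, ri[[i]]$cat_p] <- 1 - q[[names(ri)[i]]]
    rows[i, ri[[i]]$cat_s] <- -q[[names(ri)[i]]]
  }
  rows
}

.cone_witness <- function(cone, q, obj = NULL, maximize = FALSE) {
  A_eq <- rbind(cone$N_free, .ratio_rows(cone, q))
  b_eq <- c(cone$b_eq, rep(0, length(cone$ratio_info)))
  if (is.null(obj)) obj <- rep(0, ncol(cone$N_free))
  res <- solve_lp(obj = obj, lb = 0, ub = cone$vmax,
                  A_eq = A_eq, b_eq = b_eq, maximize = maximize)
  if (!res$solved) NULL else pmin(pmax(res$x, 0), cone$vmax)
}

.cone_center <- function(cone, q, wit, n_dirs = 24L) {
  nf <- ncol(cone$N_free)
  pts <- list(wit)
  set.seed(20231L)   # internal, fixed: the centre is part of the cone object
  for (i in seq_len(n_dirs)) {
    w <- .cone_witness(cone, q, obj = stats::rnorm(nf))
    if (!is.null(w)) pts[[length(pts) + 1L]] <- w
  }
  Reduce(`+`, pts) / length(pts)
}

## Per-enzyme steady-state cycle that moves one unit of catalytic flux from
## the stroma copy into the pyrenoid copy (through the diffusion reactions
## of the reaction's substrates and products), leaving every other enzyme's
## catalytic fluxes untouched.  Used to retune a witness to a freshly drawn
## q without re-solving an LP.
.ratio_shift_dirs <- function(cone) {
  model <- cone$model; rx <- model$reactions
  dirs <- list()
  for (e in names(cone$ratio_info)) {
    cat_id <- cone$ratio_info[[e]]$rep_catalogue
    row <- model$catalogue[match(cat_id, model$catalogue$id), ]
    eq <- row$eq[[1]]
    d <- numeric(nrow(rx))
    step <- function(suffix) match(paste0(cat_id, suffix), rx$id)
    if (eq$reversible) {
      d[step("_bindf_p")] <- 1; d[step("_catf_p")] <- 1
      d[step("_bindf_s")] <- -1; d[step("_catf_s")] <- -1
    } else {
      d[step("_bind_p")] <- 1; d[step("_cat_p")] <- 1
      d[step("_bind_s")] <- -1; d[step("_cat_s")] <- -1
    }
    tr <- function(met, dir)
      match(paste0(model$catalogue$id[model$catalogue$kind == "transport"][
        match(met, vapply(model$catalogue$eq[model$catalogue$kind ==
          "transport"], function(z) z$substrates$species, ""))], dir), rx$id)
    for (i in seq_len(nrow(eq$substrates)))
      d[tr(eq$substrates$species[i], "_f")] <- eq$substrates$coef[i]
    for (i in seq_len(nrow(eq$products)))
      d[tr(eq$products$species[i], "_b")] <- eq$products$coef[i]
    if (anyNA(d)) stop("cannot build ratio shift for enzyme ", e)
    dirs[[e]] <- d[cone$free_idx]
  }
  dirs
}

#' Sample steady-state flux distributions from the cone
#'
#' For each sample a fresh partition fraction q is drawn per
#' ratio-constrained enzyme, the witness flux is retuned to satisfy the new
#' ratio exactly, and a hit-and-run chain (isotropic directions in the
#' equality null space, uniform step on the feasible chord) is run for
#' `warmup + thin` steps; the final state is the sample.
#'
#' @param cone a `cbc_fluxcone`.
#' @param n_samples number of flux distributions.
#' @param seed RNG seed (sampling is fully reproducible).
#' @param warmup,thin chain steps discarded before / taken between samples.
#' @return object of class `cbc_flux_samples`: list with matrix `V`
#'   (samples x reactions, µM/s), data frame `Q` of the q draws, `seed`,
#'   and the cone.
#' @export
sample_fluxes <- function(cone, n_samples, seed = 1L,
                          warmup = 1000L, thin = 100L) {
  stopifnot(inherits(cone, "cbc_fluxcone"))
  set.seed(seed)
  rx_ids <- cone$model$reactions$id
  nf <- length(cone$free_idx)
  V <- matrix(NA_real_, n_samples, length(rx_ids),
              dimnames = list(NULL, rx_ids))
  enz <- names(cone$ratio_info)
  Q <- matrix(NA_real_, n_samples, length(enz),
              dimnames = list(NULL, enz))
  for (s in seq_len(n_samples)) {
    q <- vapply(cone$ratio_info, function(ri) draw_q(ri$partition),
                numeric(1))
    if (cone$ratio_mode == "bound" && length(q))
      q <- q * stats::runif(length(q))   # share anywhere below the drawn cap
    x <- .retune_witness(cone, q)
    Z <- .cone_null(cone, q)
    if (ncol(Z))
      x <- .hit_and_run(x, Z, lb = 0, ub = cone$vmax, steps = warmup + thin)
    v <- numeric(length(rx_ids))
    v[cone$free_idx] <- x
    v[cone$fixed_idx] <- cone$fixed
    .assert_cone_member(cone, v, q)
    V[s, ] <- v
    if (length(enz)) Q[s, ] <- q
  }
  structure(list(V = V, Q = as.data.frame(Q), seed = seed, cone = cone),
            class = "cbc_flux_samples")
}

.cone_null <- function(cone, q) {
  R <- .ratio_rows(cone, q)
  if (!nrow(R)) return(cone$Z0)
  B <- R %*% cone$Z0
  cone$Z0 %*% null_basis(B)
}

.retune_witness <- function(cone, q) {
  x <- cone$witness
  for (e in names(cone$ratio_info)) {
    ri <- cone$ratio_info[[e]]
    catp <- sum(x[ri$cat_p]); cats <- sum(x[ri$cat_s])
    lam <- q[[e]] * (catp + cats) - catp
    x <- x + lam * cone$shift_dirs[[e]]
  }
  if (any(x < -1e-9) || any(x > cone$vmax + 1e-9)) {
    x2 <- .cone_witness(cone, q)         # rare: fall back to an LP
    if (is.null(x2)) stop("infeasible ratio draw q = ",
                          paste(signif(q, 3), collapse = ", "))
    x <- x2
  }
  pmin(pmax(x, 0), cone$vmax)
}

.hit_and_run <- function(x, Z, lb, ub, steps) {
  n <- length(x); d <- ncol(Z)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  for (i in seq_len(steps)) {
    u <- as.numeric(Z %*% stats::rnorm(d))
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) next
    u <- u / nu
    act <- abs(u) > 1e-12
    hi <- (ub[act] - x[act]) / u[act]
    lo <- (lb[act] - x[act]) / u[act]
    tmax <- min(pmax(hi, lo))
    tmin <- max(pmin(hi, lo))
    if (!is.finite(tmin) || !is.finite(tmax) || tmax <= tmin) next
    x <- x + stats::runif(1, tmin, tmax) * u
    x <- pmin(pmax(x, lb), ub)
  }
  x
}

.assert_cone_member <- function(cone, v, q) {
  res <- max(abs(as.numeric(cone$model$N %*% v)))
  if (res > cone$tolerance)
    stop("sampled flux violates steady state: max |N v| = ", signif(res, 3))
  if (any(v < -1e-9))
    stop("sampled flux has negative components")
  for (e in names(cone$ratio_info)) {
    ri <- cone$ratio_info[[e]]
    catp <- sum(v[cone$free_idx][ri$cat_p])
    tot <- catp + sum(v[cone$free_idx][ri$cat_s])
    if (cone$ratio_mode == "equality" &&
        abs(catp - q[[e]] * tot) > 1e-6 * max(tot, 1))
      stop("partition ratio violated for enzyme ", e)
  }
  invisible(TRUE)
}

#' Extract one sampled flux distribution
#'
#' @param samples a `cbc_flux_samples`.
#' @param i sample index.
#' @return list with `v` (named flux vector), `q_draws`, `sample_index`,
#'   `seed`.
#' @export
fluxdist <- function(samples, i) {
  stopifnot(inherits(samples, "cbc_flux_samples"),
            i >= 1, i <= nrow(samples$V))
  list(v = samples$V[i, ], q_draws = unlist(samples$Q[i, , drop = FALSE]),
       sample_index = as.integer(i), seed = samples$seed)
}

#' Uniform sampling from a generic flux polytope
#'
#' Hit-and-run over `{x : A x = b, lb <= x <= ub}` starting from a given
#' interior (or boundary) point.  Used for small reference polytopes with
#' known uniform moments.
#'
#' @param A,b equality constraints (may be 0-row).
#' @param lb,ub bounds.
#' @param x0 feasible starting point; found by LP when `NULL`.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param warmup,thin chain schedule.
#' @return matrix of samples (n x length(lb)).
#' @export
sample_polytope <- function(A, b, lb, ub, n, seed = 1L, x0 = NULL,
                            warmup = 200L, thin = 20L) {
  set.seed(seed)
  A <- matrix(A, ncol = length(lb))
  if (is.null(x0)) {
    res <- solve_lp(rep(0, length(lb)), lb, ub, A_eq = A, b_eq = b)
    if (!res$solved) stop("polytope is empty")
    x0 <- res$x
  }
  Z <- null_basis(A)
  X <- matrix(NA_real_, n, length(lb))
  x <- x0
  x <- .hit_and_run(x, Z, lb, ub, warmup)
  for (i in seq_len(n)) {
    x <- .hit_and_run(x, Z, lb, ub, thin)
    X[i, ] <- x
  }
  X
}
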