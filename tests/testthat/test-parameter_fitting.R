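test_that("concentration bounds follow the measured-total rules", {
  m <- rubisco_model()
  meas <- data.frame(metabolite = c("3PGA", "RuBP", "F6P"),
                     condition = "LC*", mean_uM = c(600, 250, 80),
                     se_uM = 5, n = 4)
  b <- build_bounds(meas, m, "LC*")
  pick <- function(id) b[match(id, b$species), ]
  ## 3PGA: lower bound 50% of the measured total
  expect_equal(pick("3PGA_s")$c_min, 300)
  expect_equal(pick("3PGA_s")$c_max, 600)
  ## RuBP: generic floor, upper bound 100% of total
  expect_equal(pick("RuBP_s")$c_min, 1e-3)
  expect_equal(pick("RuBP_p")$c_max, 250)
  ## ordinary metabolite: the 90% preset
  expect_equal(pick("F6P_s")$c_min, 0.9 * 80)
  expect_equal(pick("F6P_s")$c_max, 80)
  ## 99% sensitivity preset
  b99 <- build_bounds(meas, m, "LC*", lower_frac = 0.99)
  expect_equal(b99[match("F6P_s", b99$species), "c_min"], 0.99 * 80)
  ## unmeasured species get generic bounds; enzymes a protein-scale cap
  expect_equal(pick("CO2_s")$c_min, 1e-3)
  expect_equal(pick("RBC_s")$c_max, 200)
  ## unknown metabolite is a named mapping error listing valid ids
  bad <- data.frame(metabolite = "hexokinase", condition = "LC*",
                    mean_uM = 1, se_uM = 0, n = 4)
  expect_error(build_bounds(bad, m, "LC*"), "hexokinase")
  expect_error(build_bounds(bad, m, "LC*"), "valid ids")
})

test_that("a single-reaction fit recovers k = v / (c_A c_E) exactly", {
  m <- toy_model()
  v <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
  v["R1_bind_s"] <- 10; v["R1_cat_s"] <- 10; v["R1_unbind_s"] <- 1
  b <- free_bounds(m)
  b$c_min[b$species == "A_s"] <- 2; b$c_max[b$species == "A_s"] <- 2
  b$c_min[b$species == "E1_s"] <- 1; b$c_max[b$species == "E1_s"] <- 1
  ps <- fit(v, m, b, kcat = NULL)
  expect_equal(unname(ps$k["R1_bind_s"]), 5, tolerance = 1e-9)
  ## zero-flux reactions are set to the geometric mean of their bounds
  expect_equal(unname(ps$k["R1_bind_p"]), 10^((-3 + 8) / 2),
               tolerance = 1e-9)
  expect_false(ps$active[["R1_bind_p"]])
})

test_that("every fitted set satisfies the log-linear mass-action equalities", {
  m <- rubisco_model()
  meas <- synthetic_measurements()
  b <- build_bounds(meas, m, "LC*")
  s <- rubisco_samples(n = 20)
  Nm <- as.matrix(nminus(m))
  for (i in 1:5) {
    ps <- fit(fluxdist(s, i), m, b)
    expect_lt(ps$residual, 1e-6)
    act <- ps$active
    lhs <- log(ps$v[act])
    rhs <- log(ps$k[act]) +
      as.numeric(crossprod(Nm[, act, drop = FALSE], log(ps$c)))
    expect_lt(max(abs(lhs - rhs)), 1e-6)
    expect_true(all(ps$epsilon$eps_plus >= -1e-9 &
                    ps$epsilon$eps_minus >= -1e-9))
    ## rate constants honour their boxes
    kb <- pyrenoidCBC:::.kinetic_bounds(m, read_kcat_bounds())
    expect_true(all(ps$k[act] >= kb$k_min[act] * (1 - 1e-6)))
    expect_true(all(ps$k[act] <= kb$k_max[act] * (1 + 1e-6)))
  }
})

test_that("relaxing concentration bounds never increases the optimum", {
  m <- toy_model()
  s <- sample_fluxes(toy_cone(), 3, seed = 21, warmup = 200, thin = 20)
  for (i in 1:3) {
    v <- fluxdist(s, i)
    tight <- fit(v, m, free_bounds(m, 2, 20), kcat = NULL)
    loose <- fit(v, m, free_bounds(m, 0.5, 80), kcat = NULL)
    expect_lte(loose$objective_value, tight$objective_value + 1e-8)
  }
})

test_that("the LP optimum matches a brute-force log-space grid oracle", {
  m <- toy_model()
  s <- sample_fluxes(toy_cone(), 2, seed = 33, warmup = 200, thin = 20)
  b <- free_bounds(m, 0.5, 50)
  for (i in 1:2) {
    v <- fluxdist(s, i)$v
    ## wide-open rate-constant boxes: the grid explores concentrations only
    ps <- fit(v, m, b, kcat = NULL, generic_log10_k = c(-8, 10))
    ## exhaustive grid over the six species that enter the paired steps
    grid_vars <- c("A_s", "A_p", "E1_s", "E1_p", "R1_cx_s", "R1_cx_p")
    lg <- seq(log(0.5), log(50), length.out = 7)
    g <- as.matrix(expand.grid(rep(list(lg), 6)))
    dv <- function(id) log(v[[id]])
    ## pair residuals: bind (A, E), unbind (cx), cat (cx)
    d_bind <- (dv("R1_bind_p") - dv("R1_bind_s")) -
      (g[, 2] + g[, 4] - g[, 1] - g[, 3])
    d_unb <- (dv("R1_unbind_p") - dv("R1_unbind_s")) - (g[, 6] - g[, 5])
    d_cat <- (dv("R1_cat_p") - dv("R1_cat_s")) - (g[, 6] - g[, 5])
    best <- min(abs(d_bind) + abs(d_unb) + abs(d_cat))
    expect_lte(ps$objective_value, best + 1e-6)
    expect_gte(ps$objective_value, -1e-9)
  }
})

test_that("infeasible bound sets are diagnosed by elastic relaxation", {
  m <- toy_model()
  v <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
  v["R1_bind_s"] <- 10; v["R1_cat_s"] <- 10; v["R1_unbind_s"] <- 1
  b <- free_bounds(m)
  ## pin the complex so k_cat = 10 / 1 = 10, then forbid it kinetically
  b$c_min[b$species == "R1_cx_s"] <- 1; b$c_max[b$species == "R1_cx_s"] <- 1
  kc <- data.frame(enzyme = "E1", k_lit = 0.01, k_min = 0.005, k_max = 0.02,
                   source = "test")
  expect_error(fit(v, m, b, kcat = kc), "kinetic")
})

test_that("chloroplast totals aggregate free and bound pools", {
  m <- toy_model()
  v <- stats::setNames(rep(1, nrow(m$reactions)), m$reactions$id)
  b <- free_bounds(m)
  ps <- fit(v, m, b, kcat = NULL)
  ps$c[c("A_s", "A_p", "R1_cx_s", "R1_cx_p")] <- c(1, 2, 3, 0.5)
  expect_equal(total_concentration(ps, "A"), 1 + 2 + 3 + 0.5)
  ## B is not part of any complex: free pools only
  ps$c[c("B_s", "B_p")] <- c(4, 0.25)
  expect_equal(total_concentration(ps, "B"), 4.25)
  expect_error(total_concentration(ps, "nonexistent"), "unknown")
})
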