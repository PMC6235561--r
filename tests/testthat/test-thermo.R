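test_that("Gibbs energies follow -RT (ln Keq - ln Q) exactly", {
  m <- rubisco_model()
  meas <- synthetic_measurements()
  ps <- fit(fluxdist(rubisco_samples(n = 20), 1), m,
            build_bounds(meas, m, "LC*"))
  th <- thermo_config(T_K = 298.15)

  ## at Q = Keq the reaction is at equilibrium
  dg <- delta_g("TPI", ps, th, "stroma")
  keq <- th$keq$keq[th$keq$reaction == "TPI"]
  ps_eq <- ps
  ps_eq$c["GAP_s"] <- 10
  ps_eq$c["DHAP_s"] <- 10 * keq
  expect_equal(delta_g("TPI", ps_eq, th, "stroma")$delta_G, 0,
               tolerance = 1e-10)

  ## Keq = 10, Q = 1: -RT ln 10 = -5.71 kJ/mol at 298.15 K
  th10 <- th
  th10$keq <- data.frame(reaction = "TPI", keq = 10, delta_n = 0)
  ps1 <- ps
  ps1$c[c("GAP_s", "DHAP_s")] <- 1e6      # 1 M each: Q = 1
  expect_equal(delta_g("TPI", ps1, th10, "stroma")$delta_G,
               -8.31446 * 298.15 * log(10) / 1000, tolerance = 1e-9)
  expect_equal(round(delta_g("TPI", ps1, th10, "stroma")$delta_G, 2), -5.71)

  ## errors: unknown reaction, nonpositive concentration
  expect_error(delta_g("NOPE", ps, th), "unknown")
  ps_bad <- ps; ps_bad$c["GAP_s"] <- 0
  expect_error(delta_g("TPI", ps_bad, th, "stroma"), "nonpositive")
})

test_that("net fluxes follow the elementary-step conventions", {
  m <- rubisco_model()
  v <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
  ## transport pair: vf - vb, positive = stroma to pyrenoid
  v["T_CO2_f"] <- 5; v["T_CO2_b"] <- 2
  expect_equal(net_flux(v, "T_CO2", m), 3)
  ## irreversible enzymatic: the catalytic flux, binding ignored
  v["RBC_bind_s"] <- 999; v["RBC_unbind_s"] <- 753; v["RBC_cat_s"] <- 246
  expect_equal(net_flux(v, "RBC", m, "stroma"), 246)
  ## reversible enzymatic: vcat_f - vcat_b
  v["PGK_catf_s"] <- 7; v["PGK_catb_s"] <- 4
  expect_equal(net_flux(v, "PGK", m, "stroma"), 3)
  expect_error(net_flux(v, "NOPE", m), "unknown")
})

test_that("diffusion proxies reproduce the worked arithmetic and flag degeneracy", {
  expect_equal(diffusion_proxy(246.12, 0.02399), 246.12 / 0.02399)
  expect_equal(round(diffusion_proxy(246.12, 0.02399)), 10259)
  expect_equal(round(diffusion_proxy(86.664, 0.008158)), 10623)
  p0 <- diffusion_proxy(5, 0)
  expect_true(is.na(p0))
  expect_identical(attr(p0, "reason"), "no-gradient transport")
  p00 <- diffusion_proxy(0, 0)
  expect_true(is.na(p00))
  expect_identical(attr(p00, "reason"), "no flux, no gradient")
})

test_that("bound/free splits aggregate complexes by stoichiometry", {
  m <- rubisco_model()
  meas <- synthetic_measurements()
  ps <- fit(fluxdist(rubisco_samples(n = 20), 2), m,
            build_bounds(meas, m, "LC*"))
  ps$c[c("3PGA_s", "3PGA_p")] <- c(1, 2)
  ps$c[grep("cx", names(ps$c))] <- 3
  bf <- bound_free_split(ps, "3PGA")
  expect_equal(unname(bf["free_stroma"]), 1)
  expect_equal(unname(bf["free_pyrenoid"]), 2)
  ## 3PGA sits (with unit stoichiometry) in the reverse PGK complex only
  cc <- m$complex_composition
  n_cx <- sum(cc$mult[cc$metabolite == "3PGA"])
  expect_equal(unname(bf["bound"]), 3 * n_cx)
  ## a metabolite bound nowhere has zero bound pool
  expect_equal(unname(bound_free_split(ps, "CO2")["bound"]),
               3 * sum(cc$mult[cc$metabolite == "CO2"]))
})

test_that("pyrenoid metabolites balance transport against consumption per sample", {
  m <- rubisco_model()
  s <- rubisco_samples(n = 20)
  for (i in 1:5)
    expect_lt(pyrenoid_mass_balance(m, fluxdist(s, i)$v), 1e-6)
})

test_that("identical ensembles give unit fold changes", {
  m <- rubisco_model()
  meas <- synthetic_measurements()
  s <- rubisco_samples(n = 20)
  sets <- lapply(1:3, function(i) fit(fluxdist(s, i), m,
                                      build_bounds(meas, m, "LC*")))
  ens <- list(model = m, V = s$V[1:3, , drop = FALSE], param_sets = sets)
  rep <- fold_change_report(ens, ens, labels = c("HC", "LC*"))
  fc <- rep$fluxes$fold_change
  expect_true(all(abs(fc[!is.na(fc)] - 1) < 1e-9))
  ## sign convention documented
  expect_match(rep$sign_convention, "stroma to pyrenoid")
})
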