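test_that("elementary decomposition follows the 3/6/2 step rules", {
  cat_df <- read_catalogue()
  rbc <- decompose(cat_df[cat_df$id == "RBC", ], "stroma")
  expect_length(rbc, 3L)
  expect_setequal(vapply(rbc, `[[`, "", "step_kind"),
                  c("binding", "unbinding", "catalytic"))
  ## one new complex species shared by the three steps
  expect_equal(unique(vapply(rbc, `[[`, "", "complex")), "RBC_cx_s")
  ## binding consumes one free enzyme and the free co-substrates
  bind <- rbc[[1]]$stoich
  expect_equal(unname(bind[c("RuBP_s", "CO2_s", "RBC_s", "RBC_cx_s")]),
               c(-1, -1, -1, 1))
  ## carboxylation produces two 3PGA
  expect_equal(unname(rbc[[3]]$stoich[["3PGA_s"]]), 2)

  pgk <- decompose(cat_df[cat_df$id == "PGK", ], "pyrenoid")
  expect_length(pgk, 6L)
  expect_length(unique(na.omit(vapply(pgk, `[[`, "", "complex"))), 2L)

  tr <- decompose(cat_df[cat_df$id == "T_RUBP", ])
  expect_length(tr, 2L)
  expect_setequal(vapply(tr, `[[`, "", "step_kind"),
                  c("transport-forward", "transport-backward"))
  expect_false(any(grepl("cx", unlist(lapply(tr, function(x)
    names(x$stoich))))))

  bad <- cat_df[cat_df$id == "RBC", ]
  bad$enzyme <- NA_character_
  expect_error(decompose(bad, "stroma"), "no enzyme")
})

test_that("the full two-compartment model has 226 reactions and 128 components", {
  m <- full_model()
  cen <- census(m)
  expect_identical(cen$n_reactions, 226L)
  expect_identical(cen$n_species, 128L)
  expect_identical(unname(cen$delta_vs_totals), c(0L, 0L))
  ## the builder also reports the itemised reference census and its total
  expect_identical(unname(cen$reference_itemised[["total"]]), 180L)
  expect_identical(sum(2L * 65L, 40L, 8L, 2L),
                   unname(cen$reference_itemised[["total"]]))
  ## structural breakdown
  expect_identical(unname(cen$reactions_by_kind[["transport"]]), 40L)
  expect_identical(unname(cen$reactions_by_kind[["pseudo"]]), 2L)
  expect_identical(unname(cen$species_by_role[["complex"]]), 56L)
})

test_that("scenario restriction prunes the pyrenoid as specified", {
  m <- rubisco_model()
  rx <- m$reactions
  pyr_enz <- rx[rx$kind == "enzymatic" & rx$compartment == "pyrenoid", ]
  expect_identical(sort(pyr_enz$id),
                   sort(c("RBC_bind_p", "RBC_unbind_p", "RBC_cat_p")))
  transported <- unique(rx$catalogue_id[rx$kind == "transport"])
  expect_setequal(transported, c("T_CO2", "T_RUBP", "T_3PGA"))

  ## empty pyrenoid-enzyme set: only the CO2 diffusion pair remains and it
  ## can carry no net flux at steady state
  m0 <- build_model(read_catalogue(), scenario("empty", character()), "HC")
  expect_setequal(unique(m0$reactions$catalogue_id[
    m0$reactions$kind == "transport"]), "T_CO2")
  cone0 <- build_constraints(m0, condition = "HC")
  s0 <- sample_fluxes(cone0, 3, seed = 9, warmup = 200, thin = 20)
  nets <- apply(s0$V, 1, function(v) net_flux(v, "T_CO2", m0))
  expect_lt(max(abs(nets)), 1e-6)
})

test_that("model building is deterministic: identical catalogue gives bit-identical N", {
  m1 <- build_model()
  m2 <- build_model()
  expect_identical(m1$species$id, m2$species$id)
  expect_identical(m1$reactions$id, m2$reactions$id)
  expect_identical(as.matrix(m1$N), as.matrix(m2$N))
})

test_that("enzyme moieties are conserved and corruption is flagged", {
  m <- full_model()
  chk <- moiety_check(m)
  expect_true(chk$ok)
  expect_identical(nrow(chk$violations), 0L)
  ## every enzyme pool: summing its rows of N gives a zero row
  for (e in sample(names(chk$conserved_pools), 4)) {
    rows <- Matrix::colSums(m$N[chk$conserved_pools[[e]], , drop = FALSE])
    expect_lt(max(abs(rows)), 1e-12)
  }
  ## corrupt one complex stoichiometry: the check names the reaction and
  ## the broken enzyme moiety
  m_bad <- m
  j <- match("RBC_bind_s", m_bad$reactions$id)
  m_bad$N["RBC_cx_s", j] <- 2
  chk_bad <- moiety_check(m_bad)
  expect_false(chk_bad$ok)
  expect_true("RBC_bind_s" %in% chk_bad$violations$reaction)
  expect_true("RBC_s" %in% chk_bad$violations$moiety)
})

test_that("SBML and JSON exports round-trip the stoichiometry", {
  m <- rubisco_model()
  p <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, p)
  imp <- import_sbml(p)
  expect_identical(imp$species, m$species$id)
  expect_identical(imp$reactions, m$reactions$id)
  expect_identical(as.matrix(imp$N), unname(as.matrix(m$N)) * 1,
                   ignore_attr = TRUE)

  pj <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, pj)
  dump <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_identical(length(dump$species$id), nrow(m$species))
  expect_identical(length(dump$stoichiometry$coef), Matrix::nnzero(m$N))
})
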