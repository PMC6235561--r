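test_that("ground truths are exact steady states inside the constrained cone", {
  tr <- reference_truth("LC*")
  expect_lt(tr$residual, 1e-8 * max(tr$v))
  expect_true(all(tr$v >= 0))
  expect_equal(unname(tr$v["X_CO2_UPT"]), 398)
  ## flux partition equals the enzyme allocation at the measured mean
  expect_equal(unname(flux_partition(tr)["RBC"]), 0.618, tolerance = 1e-9)
  ## pyrenoid/stroma rate-constant pairs are exactly equal
  rx <- tr$model$reactions
  pyr <- rx$id[rx$kind == "enzymatic" & rx$compartment == "pyrenoid"]
  for (p in pyr)
    expect_equal(unname(tr$k[p]), unname(tr$k[sub("_p$", "_s", p)]),
                 tolerance = 1e-9)
})

test_that("synthetic datasets are seeded, deterministic and schema-compatible", {
  tr <- reference_truth("LC*")
  d1 <- emit_measurements(tr, noise_cv = 0.1, seed = 5)
  d2 <- emit_measurements(tr, noise_cv = 0.1, seed = 5)
  expect_identical(d1$measurements, d2$measurements)
  expect_identical(d1$partitions, d2$partitions)
  d3 <- emit_measurements(tr, noise_cv = 0.1, seed = 6)
  expect_false(identical(d1$measurements$mean_uM, d3$measurements$mean_uM))
  expect_true(all(d1$measurements$n == 4))
  expect_true(all(d1$measurements$mean_uM > 0))
  ## the emitted files round-trip through the real-data readers
  pm <- withr::local_tempfile(fileext = ".tsv")
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_measurements(d1$measurements, pm)
  write_partitions(d1$partitions, pp)
  expect_equal(read_measurements(pm), d1$measurements, tolerance = 1e-12)
  expect_equal(read_partitions(pp)[, 1:4], d1$partitions,
               tolerance = 1e-12)
  ## stroma-only enzymes are emitted below the 5% detection rule
  parts <- d1$partitions
  expect_lt(max(parts$fraction_mean[!parts$enzyme %in% "RBC"]), 0.05)
})

test_that("zero noise reproduces the true totals; replicate SE scales with the CV", {
  tr <- reference_truth("LC*")
  d0 <- emit_measurements(tr, noise_cv = 0, seed = 1)
  tots <- vapply(d0$measurements$metabolite,
                 function(m) pyrenoidCBC:::.truth_total(tr, m), numeric(1))
  expect_equal(d0$measurements$mean_uM, unname(tots), tolerance = 1e-9)
  expect_true(all(d0$measurements$se_uM < 1e-9))
  ## with cv = 0.1 and 4 replicates, SE/mean ~ 0.05 in expectation
  rel <- unlist(lapply(1:8, function(s) {
    d <- emit_measurements(tr, noise_cv = 0.1, seed = s)
    d$measurements$se_uM / d$measurements$mean_uM
  }))
  expect_equal(mean(rel), 0.05, tolerance = 0.25)
})

test_that("a symmetric closed enzymatic cycle relaxes to uniform pools", {
  cat_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tenzyme\tkind\tcompartments",
               "RA\tA -> B\tE1\tenzymatic\tstroma",
               "RB\tB -> C\tE2\tenzymatic\tstroma",
               "RC\tC -> A\tE3\tenzymatic\tstroma"), cat_path)
  moi_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\tcarbon\tphosphate",
               "A\t1\t0", "B\t1\t0", "C\t1\t0"), moi_path)
  m <- build_model(read_catalogue(cat_path), scenario("closed", character()),
                   "HC", moieties = read_moieties(moi_path))
  k <- stats::setNames(rep(1, nrow(m$reactions)), m$reactions$id)
  c0 <- stats::setNames(rep(1, nrow(m$species)), m$species$id)
  c0[c("A_s", "B_s", "C_s")] <- c(2.4, 0.3, 0.3)
  res <- relax_to_steady_state(m, c0, k)
  expect_true(res$converged)
  pools <- res$c[c("A_s", "B_s", "C_s")]
  expect_lt(diff(range(pools)), 1e-6)
  ## carbon and enzyme moieties are conserved by the closed dynamics
  cx <- m$species$id[m$species$role == "complex"]
  carbon <- function(cc) sum(cc[c("A_s", "B_s", "C_s")]) + sum(cc[cx])
  expect_equal(carbon(res$c), carbon(c0), tolerance = 1e-6)
})
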