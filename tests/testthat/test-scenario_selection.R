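toy_meas <- function(mets, means, condition = "HC")
  data.frame(metabolite = mets, condition = condition, mean_uM = means,
             se_uM = pmax(means * 0.05, 1e-6), n = 4)

test_that("chi-square matches hand evaluation and its invariances", {
  meas <- toy_meas(c("m1", "m2"), c(10, 20))
  expect_equal(chi_square(c(m1 = 12, m2 = 18), meas, "HC",
                          panel = c("m1", "m2")), 4 / 10 + 4 / 20)
  ## perfect fit
  expect_equal(chi_square(c(m1 = 10, m2 = 20), meas, "HC",
                          panel = c("m1", "m2")), 0)
  ## panel-order invariance
  expect_equal(chi_square(c(m1 = 12, m2 = 18), meas, "HC",
                          panel = c("m2", "m1")), 0.6)
  ## scaling both modelled and measured by s scales the statistic by s
  meas5 <- toy_meas(c("m1", "m2"), 5 * c(10, 20))
  expect_equal(chi_square(5 * c(m1 = 12, m2 = 18), meas5, "HC",
                          panel = c("m1", "m2")), 5 * 0.6)
  ## variance-weighted alternative
  expect_equal(chi_square(c(m1 = 12, m2 = 18), meas, "HC",
                          panel = c("m1", "m2"), form = "variance"),
               (2 / 0.5)^2 + (2 / 1)^2)
  ## missing panel metabolite is a named error
  expect_error(chi_square(c(m1 = 1), meas, "HC", panel = c("m1", "m3")),
               "m3")
})

test_that("ranking is ascending, tie-broken and boundary-safe", {
  fits <- data.frame(sample_index = c(3L, 1L, 2L, 4L),
                     chi_square = c(5, 1, 5, 0.2),
                     significant = TRUE,
                     objective_value = c(0.1, 0.5, 0.05, 1))
  sel <- rank_and_select(fits, 3)
  expect_identical(sel$sample_index, c(4L, 1L, 2L))  # ties by objective
  ## all-equal chi-square: deterministic tie-break order
  fits2 <- data.frame(sample_index = c(2L, 1L, 3L), chi_square = 1,
                      significant = TRUE, objective_value = c(2, 2, 1))
  expect_identical(rank_and_select(fits2, 2)$sample_index, c(3L, 1L))
  expect_identical(nrow(rank_and_select(fits2, 0)), 0L)
  expect_warning(sel_all <- rank_and_select(fits2, 10), "top_n")
  expect_identical(nrow(sel_all), 3L)
})

test_that("Pearson validation behaves at the identities", {
  meas <- toy_meas(c("m1", "m2", "m3", "m4"), c(1, 2, 3, 4))
  ## stand-in parameter sets whose totals are injected directly
  with_mocked_bindings(
    modelled_totals = function(param_set, panel) param_set$tots[panel],
    {
      mk <- function(tots) structure(list(tots = tots,
                                          source_sample_index = 1L),
                                     class = "cbc_paramset")
      pv <- pearson_validation(list(mk(c(m1 = 1, m2 = 2, m3 = 3, m4 = 4))),
                               meas, "HC", panel = paste0("m", 1:4))
      expect_equal(pv$r, 1, tolerance = 1e-12)
      pv2 <- pearson_validation(list(mk(c(m1 = 4, m2 = 3, m3 = 2, m4 = 1))),
                                meas, "HC", panel = paste0("m", 1:4))
      expect_equal(pv2$r, -1, tolerance = 1e-12)
    })
})

test_that("fit evaluation flags significance at the chi-square critical value", {
  m <- rubisco_model()
  meas <- synthetic_measurements()
  b <- build_bounds(meas, m, "LC*")
  s <- rubisco_samples(n = 20)
  sets <- lapply(1:6, function(i) fit(fluxdist(s, i), m, b))
  f <- evaluate_fits(sets, meas, "LC*")
  expect_identical(nrow(f), 6L)
  crit <- qchisq(0.95, df = length(default_panel()))
  expect_identical(f$significant, f$chi_square <= crit)
  expect_true(all(f$chi_square >= 0))
})

test_that("a single-sample comparison degenerates to that sample's statistic", {
  meas <- synthetic_measurements()
  comp <- compare_scenarios(standard_scenarios()["rubisco"], "LC*", meas,
                            n_samples = 1, seed = 3, warmup = 200,
                            thin = 20)
  run <- attr(comp, "runs")[["rubisco/LC*"]]
  expect_equal(comp$mean_chi_square, run$fits$chi_square[1])
  expect_identical(comp$n, 1)
})
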