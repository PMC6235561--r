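test_that("partition draws follow the measured-range and 5% rules", {
  set.seed(1)
  p <- list(fraction_mean = 0.618, fraction_low = 0.598,
            fraction_high = 0.638)
  qs <- replicate(200, draw_q(p))
  expect_true(all(qs >= 0.598 & qs <= 0.638))
  expect_gt(diff(range(qs)), 0.02)          # actually spread out
  ## below 5%: stroma-only
  expect_identical(draw_q(list(fraction_mean = 0.012, fraction_low = 0.007,
                               fraction_high = 0.017)), 0)
  ## degenerate range returns its value
  expect_identical(draw_q(list(fraction_mean = 0.218, fraction_low = 0.218,
                               fraction_high = 0.218)), 0.218)
})

test_that("constraint building checks feasibility and names the culprit", {
  cone <- rubisco_cone()
  w <- numeric(nrow(rubisco_model()$reactions))
  w[cone$free_idx] <- cone$witness
  w[cone$fixed_idx] <- cone$fixed
  expect_lt(max(abs(as.numeric(rubisco_model()$N %*% w))), 1e-6)
  expect_identical(unname(cone$fixed["X_CO2_UPT"]), 398)

  expect_error(build_constraints(rubisco_model(), vmax = 300),
               "X_CO2_UPT")
  ## FNR is stoichiometrically tied to 2 NADPH per CO2: any other value
  ## leaves the energy budget unbalanceable
  expect_error(build_constraints(rubisco_model(),
                                 fixed = c(X_CO2_UPT = 398, FNR = 500,
                                           ATPASE = 1194)),
               "infeasible")
})

test_that("every sampled flux distribution lies in the constrained cone", {
  m <- rubisco_model()
  cone <- rubisco_cone()
  s <- rubisco_samples(n = 20)
  expect_identical(nrow(s$V), 20L)
  for (i in seq_len(10)) {
    v <- fluxdist(s, i)$v
    expect_lt(max(abs(as.numeric(m$N %*% v))), cone$tolerance)
    expect_true(all(v >= -1e-9))
    expect_true(all(v[cone$free_idx] <= cone$vmax + 1e-6))
    expect_equal(unname(v["X_CO2_UPT"]), 398)
    expect_equal(unname(v["FNR"]), 796)
    expect_equal(unname(v["ATPASE"]), 1194)
    ## the drawn partition ratio holds exactly for Rubisco
    q <- s$Q$RBC[i]
    catp <- v["RBC_cat_p"]; cats <- v["RBC_cat_s"]
    expect_equal(unname(catp / (catp + cats)), q, tolerance = 1e-8)
  }
  ## q redrawn per sample, uniformly within the measured range
  expect_gt(diff(range(s$Q$RBC)), 0.001)
  expect_true(all(s$Q$RBC >= 0.598 & s$Q$RBC <= 0.638))
  ## seeded reproducibility
  s2 <- sample_fluxes(cone, 5, seed = 404, warmup = 300, thin = 30)
  expect_identical(s2$V[1:5, ], s$V[1:5, ])
})

test_that("hit-and-run reproduces uniform moments on a reference polytope", {
  ## segment {v1 = v2, 0 <= v <= 1}: uniform mean 1/2, variance 1/12
  A <- matrix(c(1, -1), 1, 2)
  X <- sample_polytope(A, 0, lb = c(0, 0), ub = c(1, 1), n = 500,
                       seed = 7, warmup = 100, thin = 10)
  expect_lt(max(abs(X[, 1] - X[, 2])), 1e-9)
  expect_lt(abs(mean(X[, 1]) - 0.5), 0.05)
  expect_lt(abs(var(X[, 1]) - 1 / 12), 0.025)
  ## 2-simplex {x1+x2+x3 = 1, x >= 0}: uniform marginal mean 1/3
  X3 <- sample_polytope(matrix(1, 1, 3), 1, lb = rep(0, 3), ub = rep(1, 3),
                        n = 500, seed = 8, warmup = 100, thin = 10)
  expect_lt(max(abs(colMeans(X3) - 1 / 3)), 0.05)
})

test_that("pyrenoid Rubisco flux scales with the measured partition between conditions", {
  s_lc <- rubisco_samples("LC*", n = 20)
  s_hc <- rubisco_samples("HC", n = 20)
  lc <- mean(s_lc$V[, "RBC_cat_p"])
  hc <- mean(s_hc$V[, "RBC_cat_p"])
  ## total fixation pinned at 398 in both: ratio ~ 0.618/0.218
  expect_equal(lc / hc, 0.618 / 0.218, tolerance = 0.05)
})
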