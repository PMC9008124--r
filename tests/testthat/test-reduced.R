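test_that("correction factors match archived snapshot values and limits", {
  m <- ref_model()
  s <- snapshot_records()
  cf1 <- correction_factors(m, s$s1$y)
  expect_close_abs(cf1$r1, 1.94e-6, rel = 5e-3, ulp = 0.005e-6)
  expect_close_abs(cf1$r2, 8.98e-4, rel = 5e-3, ulp = 0.005e-4)
  cf2 <- correction_factors(m, s$s2$y)
  expect_close_abs(cf2$r1, 4.53e-6, rel = 5e-3, ulp = 0.005e-6)
  expect_close_abs(cf2$r2, 4.78e-3, rel = 5e-3, ulp = 0.005e-3)
  # vanishing binding: r2 -> koff/denominator-free limit, r1 -> k1 a / kdeg
  m0 <- fcrn_model(fcrn_params(kon = 1e-12, koff = 1e-12))
  cf0 <- correction_factors(m0, c(1, 1, 1, 1))
  expect_lt(cf0$r2, 1e-10)
  expect_equal(cf0$r1, uptake_rate(m0$params) * vol_ratio(m0$params) /
                 m0$params$kdeg, tolerance = 1e-6)
  # fast-binding-free limit: Lambda -> 1/(1+a)
  cf_lim <- correction_factors(m, c(1, 1e-6, 1e12, 1e-6))
  expect_equal(cf_lim$Lambda, 1 / (1 + vol_ratio(m$params)), tolerance = 1e-6)
})

test_that("corrected constraint collapses to plain QSSA when corrections vanish", {
  m <- ref_model()
  y <- c(1e4, 1, 1e12, 10)  # huge free receptor drives r1, r2 -> 0
  expect_equal(corrected1_approx(m, y), qssa1_approx(m, y),
               tolerance = 1e-9)
  # balanced uptake and degradation: the QSSA expressions vanish
  p <- m$params
  y_bal <- c(1e4, uptake_rate(p) * 1e4 / p$kdeg, 100, 100)
  expect_equal(qssa1_approx(m, y_bal), 0, tolerance = 1e-9)
  expect_equal(qssa2_approx(m, y_bal), 0, tolerance = 1e-9)
})

test_that("CSP constraint expression is invariant to dual-vector rescaling", {
  m <- ref_model()
  s <- snapshot_records()$s1
  amp <- list(f = s$f, c = s$c, R = s$R, g = s$g)
  amp10 <- amp
  amp10$c[1, ] <- 10 * amp10$c[1, ]
  expect_equal(csp_constraint_approx(amp, 1), csp_constraint_approx(amp10, 1))
  amp10$c[2, ] <- -3 * amp10$c[2, ]
  expect_equal(csp_constraint_approx(amp, 2), csp_constraint_approx(amp10, 2))
  bad <- amp; bad$c[1, 3] <- 0
  expect_error(csp_constraint_approx(bad, 1), "pivot")
})

test_that("error metrics have the expected magnitudes and period flags", {
  er <- err_table()
  expect_equal(er$period[er$t == 1e-2], 1)
  expect_equal(er$period[er$t == 1e2], 2)
  # net binding rate: plain QSSA commits ~1e-3 relative error at 1e-2 h
  expect_close_abs(er$er1_1[er$t == 1e-2], 0.89e-3, rel = 0.1)
  # corrected and CSP expressions are both higher order than plain QSSA
  expect_true(all(abs(er$er1_2) <= 0.1 * abs(er$er1_1)))
  expect_true(all(abs(er$er1_3) <= 0.1 * abs(er$er1_1)))
  # recycling-rate constraint in its validity period: corrected and CSP
  # expressions are both an order of magnitude better than plain QSSA
  late <- er$t >= 5
  expect_true(all(abs(er$er2_2[late]) <= 0.1 * abs(er$er2_1[late])))
  expect_true(all(abs(er$er2_3[late]) <= 0.1 * abs(er$er2_1[late])))
  # deep in the slow period the CSP constraint is at least comparable
  deep <- er$t >= 50
  expect_true(all(abs(er$er2_3[deep]) <= 1.5 * abs(er$er2_2[deep])))
  # the recycling QSSA improves deeper into the slow period
  expect_lt(abs(er$er2_1[er$t == 1000]), abs(er$er2_1[er$t == 50]))
})

test_that("error metrics agree with direct evaluation from the rates", {
  m <- ref_model()
  s <- snapshot_records()$s1
  er <- err_table()
  R <- s$R
  direct <- ((R[3] - R[4]) - (R[1] - R[2])) / (R[3] - R[4])
  expect_equal(unname(direct), er$er1_1[er$t == 1e-2], tolerance = 1e-6)
})

test_that("one-constraint reduced models track the full solution in their period", {
  m <- ref_model()
  tt <- c(1e-2, 0.1, 0.5, 1, 2, 3)
  full <- solve_model(m, times = tt, rtol = 1e-12, atol = 1e-10)
  for (w in c("qssa1", "corrected1")) {
    red <- simulate_reduced(m, w, times = tt)
    i <- match(tt, red$times)
    relerr <- abs(red$states[i, 1] - full$states[, 1]) / full$states[, 1]
    expect_lt(max(relerr), 0.01)
    # conservation law holds along the reduced trajectory
    cons <- apply(red$states, 1, function(y) .conservation_err_for_tests(m, y))
    expect_lt(max(cons), 1e-10)
    # the defining constraint is satisfied on the reduced states
    resid <- vapply(i, function(j) {
      y <- red$states[j, ]; R <- reaction_rates(m, y)
      approx <- if (w == "qssa1") qssa1_approx(m, y) else corrected1_approx(m, y)
      abs((R[3] - R[4]) - approx) / abs(R[3] - R[4])
    }, numeric(1))
    expect_lt(max(resid), 1e-8)
  }
})

test_that("two-constraint reduced models track the full solution in their period", {
  m <- ref_model()
  tt <- c(5, 10, 50, 100, 500, 1000)
  full <- solve_model(m, times = tt, rtol = 1e-12, atol = 1e-10)
  for (w in c("qssa2", "corrected2")) {
    red <- simulate_reduced(m, w, times = tt)
    i <- match(tt, red$times)
    relerr <- abs(red$states[i, 1] - full$states[, 1]) / full$states[, 1]
    # the Lambda correction is what keeps the two-constraint model on track:
    # plain QSSA overestimates plasma clearance by ~20% at 1000 h
    expect_lt(max(relerr), if (w == "corrected2") 0.01 else 0.25)
    cons <- apply(red$states, 1, function(y) .conservation_err_for_tests(m, y))
    expect_lt(max(cons), 1e-10)
  }
})
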