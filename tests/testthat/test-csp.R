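test_that("basis of a diagonal matrix is the identity with sorted timescales", {
  b <- csp_basis(diag(c(-100, -1)))
  expect_equal(abs(b$A), diag(2))
  expect_equal(abs(b$B), diag(2))
  expect_equal(b$tau, c(0.01, 1))
  expect_equal(b$n_conserved, 0L)
})

test_that("basis satisfies duality and resolves the identity for random stable systems", {
  set.seed(21)
  for (k in 1:10) {
    lam <- -sort(10^stats::runif(4, -2, 3), decreasing = TRUE)
    V <- matrix(stats::rnorm(16), 4)
    J <- V %*% diag(lam) %*% solve(V)
    b <- csp_basis(J)
    expect_lt(max(abs(b$B %*% b$A - diag(4))), 1e-10)
    expect_lt(max(abs(b$A %*% b$B - diag(4))), 1e-9)
    expect_true(all(diff(b$tau) >= 0))
  }
})

test_that("complex eigenvalue pairs are rejected with a named error", {
  J <- rbind(c(0, -1), c(1, 0)) # pure rotation
  expect_error(csp_basis(J), "complex eigenvalue pair")
})

test_that("snapshot timescales, amplitudes and coefficients match archive", {
  s <- snapshot_records()
  ref <- fcrn_reference()
  nd <- 3
  expect_close_abs(s$s1$tau[1:nd], ref$snapshot1$tau$v, rel = 5e-3,
                   ulp = ref$snapshot1$tau$ulp)
  expect_close_abs(s$s2$tau[1:nd], ref$snapshot2$tau$v, rel = 5e-3,
                   ulp = ref$snapshot2$tau$ulp)
  expect_close_abs(abs(s$s1$f[1:nd]), ref$snapshot1$f$v, rel = 5e-3,
                   ulp = ref$snapshot1$f$ulp)
  expect_close_abs(abs(s$s2$f[1:nd]), ref$snapshot2$f$v, rel = 5e-3,
                   ulp = ref$snapshot2$f$ulp)
  expect_close_abs(s$s1$c[1:nd, ], ref$snapshot1$c$v, rel = 5e-3,
                   ulp = ref$snapshot1$c$ulp)
  expect_close_abs(s$s2$c[1:nd, ], ref$snapshot2$c$v, rel = 5e-3,
                   ulp = ref$snapshot2$c$ulp)
  # the fastest eigenvalue at the first snapshot: 1/tau_1 ~ 0.36e-4 h
  expect_close_abs(s$s1$tau[1], 0.36e-4, rel = 5e-3, ulp = 0.005e-4)
})

test_that("conserved mode is detected last with zero amplitude and infinite timescale", {
  s <- snapshot_records()
  set.seed(31)
  states <- lapply(1:5, function(k) random_state())
  for (rec in c(list(s$s1, s$s2),
                lapply(states, function(y) diagnose_state(ref_model(), y)))) {
    expect_equal(rec$tau[4], Inf)
    expect_lt(abs(rec$f[4]), 1e-6 * max(abs(rec$f)))
    expect_lt(max(abs(rec$c[4, ])), 1e-8)
  }
})

test_that("amplitude expansion is consistent: f = c R = b g, forward/backward antisymmetry", {
  m <- ref_model()
  set.seed(41)
  for (k in 1:5) {
    y <- random_state()
    basis <- csp_basis(model_jacobian(m, y), S = m$S)
    amp <- csp_amplitudes(basis, m, y)
    expect_lt(max(abs(drop(amp$c %*% amp$R) - drop(basis$B %*% amp$g))) /
                max(abs(amp$f)), 1e-8)
    expect_equal(amp$c[, 3], -amp$c[, 4])
    # reconstruction: sum_n a_n f^n = g
    expect_lt(max(abs(drop(basis$A %*% amp$f) - amp$g)) / max(abs(amp$g)), 1e-8)
  }
})

test_that("participation, timescale and importance indices are normalized", {
  s <- snapshot_records()
  for (rec in list(s$s1, s$s2)) {
    # the conserved mode has no reaction content: its P/J rows are flagged
    # undefined rather than normalized
    expect_equal(unname(rowSums(abs(rec$P))[1:3]), rep(1, 3))
    expect_equal(unname(rowSums(abs(rec$J))[1:3]), rep(1, 3))
    expect_true(attr(rec$P, "undefined")[4])
    expect_equal(unname(rowSums(abs(rec$I))), rep(1, 4))
    expect_equal(unname(colSums(rec$D)), rep(1, 4))
  }
})

test_that("index matrices match the archived snapshots within 0.01", {
  s <- snapshot_records()
  ref <- fcrn_reference()
  expect_index_match(s$s1$P[1:3, ], ref$snapshot1$P$v)
  expect_index_match(s$s1$J[1:3, ], ref$snapshot1$J$v)
  expect_index_match(s$s1$D[1:3, ], ref$snapshot1$D$v)
  expect_index_match(s$s2$P[1:3, ], ref$snapshot2$P$v)
  expect_index_match(s$s2$J[1:3, ], ref$snapshot2$J$v)
  expect_index_match(s$s2$D[1:3, ], ref$snapshot2$D$v)
  # headline entries
  expect_lt(abs(s$s1$P[2, 1] - 0.992), 0.01)
  expect_lt(abs(s$s1$P[1, 3] - (-0.500)), 0.01)
  expect_lt(abs(s$s1$J[1, 3] - (-0.998)), 0.01)
  expect_lt(abs(s$s1$D[1, 2] - 0.999), 0.01)
  expect_lt(abs(s$s2$J[2, 5] - (-0.668)), 0.01)
  expect_lt(abs(s$s2$D[2, 4] - 0.831), 0.01)
})

test_that("timescale decomposition sums to the eigenvalue per mode", {
  m <- ref_model()
  set.seed(51)
  for (k in 1:5) {
    y <- random_state()
    basis <- csp_basis(model_jacobian(m, y), S = m$S)
    Jidx <- timescale_participation(basis, m, y)
    lam_k <- attr(Jidx, "lambda_k")
    expect_lt(max(abs(rowSums(lam_k) - basis$lambda)) /
                max(abs(basis$lambda)), 1e-8)
  }
})

test_that("indices are invariant under rescaling of any basis pair", {
  m <- ref_model()
  y <- snapshot_records()$s1$y
  basis <- csp_basis(model_jacobian(m, y), S = m$S)
  scaled <- basis
  set.seed(61)
  sc <- stats::runif(4, 0.1, 10) * sample(c(-1, 1), 4, replace = TRUE)
  scaled$A <- sweep(basis$A, 2, sc, `*`)
  scaled$B <- sweep(basis$B, 1, sc, `/`)
  amp <- csp_amplitudes(basis, m, y)
  amp_s <- csp_amplitudes(scaled, m, y)
  # P rows follow the sign of the dual vector, so only |P| is sign-invariant
  expect_equal(abs(amplitude_participation(amp_s)),
               abs(amplitude_participation(amp)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(timescale_participation(scaled, m, y),
               timescale_participation(basis, m, y),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(csp_pointers(scaled), csp_pointers(basis), tolerance = 1e-12)
  expect_equal(importance_index(scaled, amp_s, 1),
               importance_index(basis, amp, 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a single-reaction system has participation +-1", {
  p <- fcrn_params()
  m1 <- kinetic_model(species = c("A", "B"),
                      reactions = list(list(name = "1", stoich = c(-1, 1),
                                            k = 2, reactants = 1L)),
                      params = p, y0 = c(1, 0),
                      conserved = list(list(coef = c(1, 1), total = 1)))
  basis <- csp_basis(model_jacobian(m1, c(0.5, 0.5)), S = m1$S)
  amp <- csp_amplitudes(basis, m1, c(0.5, 0.5))
  P <- amplitude_participation(amp)
  expect_equal(unname(abs(P[1, 1])), 1)
})

test_that("exhausted-mode count reproduces the period structure", {
  s <- snapshot_records()
  expect_equal(s$s1$M, 1L)
  expect_equal(s$s2$M, 2L)
  early <- diagnose_state(ref_model(),
                          solve_model(ref_model(), times = 1e-5)$states[1, ],
                          1e-5)
  expect_equal(early$M, 0L)
})

test_that("M(t) steps 0 -> 1 -> 2 with onsets near the known boundaries", {
  an <- scan_analysis()
  Ms <- an$summary$M
  expect_true(all(diff(Ms) >= 0))
  expect_setequal(unique(Ms), c(0L, 1L, 2L))
  pb <- period_boundaries(an)
  t1 <- pb$t_onset[pb$M == 1]
  t2 <- pb$t_onset[pb$M == 2]
  expect_gt(t1, 3e-4 / 3); expect_lt(t1, 3e-4 * 3)
  expect_gt(t2, 3 / 3);    expect_lt(t2, 3 * 3)
})

test_that("fast and slow timescales keep a two-order gap across the run", {
  an <- scan_analysis()
  s <- an$summary
  inside <- s$t >= 1e-3 & s$t <= 1e3
  expect_true(all(s$tau_1[inside] / s$tau_2[inside] < 1e-2))
})

test_that("importance index reconstructs the rhs at M = 0 and flips reaction-1 influence", {
  m <- ref_model()
  set.seed(71)
  for (k in 1:3) {
    y <- random_state()
    basis <- csp_basis(model_jacobian(m, y), S = m$S)
    amp <- csp_amplitudes(basis, m, y)
    I0 <- importance_index(basis, amp, 0)
    expect_lt(max(abs(rowSums(attr(I0, "w")) - amp$g)) / max(abs(amp$g)), 1e-8)
  }
  s <- snapshot_records()
  # pinocytosis feeds endosomal IgG while one mode is exhausted, but drains it
  # once the recycling equilibrium is established
  expect_gt(s$s1$I[2, 1], 0)
  expect_lt(s$s2$I[2, 1], 0)
  # forward and backward binding contributions nearly cancel in the slow phase
  expect_lt(abs(s$s2$I[2, 3] + s$s2$I[2, 4]), 0.01)
})
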