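# shared fixtures; expensive solves are computed once per test run
.cache <- new.env(parent = emptyenv())

ref_model <- function() {
  if (is.null(.cache$model)) .cache$model <- fcrn_model()
  .cache$model
}

# high-accuracy states + diagnostics at the two snapshot times
snapshot_records <- function() {
  if (is.null(.cache$snaps)) {
    m <- ref_model()
    traj <- solve_model(m, times = c(1e-2, 1e2), rtol = 1e-13, atol = 1e-11)
    .cache$snaps <- list(
      s1 = diagnose_state(m, traj$states[1, ], 1e-2),
      s2 = diagnose_state(m, traj$states[2, ], 1e2))
  }
  .cache$snaps
}

# constraint-error metrics at the twelve reference times
err_table <- function() {
  if (is.null(.cache$err))
    .cache$err <- reduction_errors(ref_model(), fcrn_reference()$errors$t)
  .cache$err
}

# moderately dense diagnostic scan of the full span (for M(t) structure)
scan_analysis <- function() {
  if (is.null(.cache$scan)) {
    tt <- 10^seq(-5, log10(1.9e3), length.out = 150)
    .cache$scan <- diagnose_trajectory(ref_model(), times = tt,
                                       rtol = 1e-12, atol = 1e-10)
  }
  .cache$scan
}

# |value| within max(rel*|ref|, ulp) of |ref| (archived values are rounded,
# and raw amplitudes/coefficients carry an arbitrary overall mode sign)
expect_close_abs <- function(value, ref, rel, ulp = 0) {
  tol <- pmax(rel * abs(ref), ulp)
  expect_true(all(abs(abs(value) - abs(ref)) <= tol),
              label = paste0(deparse(substitute(value)), " within band of ",
                             deparse(substitute(ref))))
}

# signed comparison for index matrices (absolute band)
expect_index_match <- function(value, ref, tol = 0.01) {
  expect_true(max(abs(value - ref)) <= tol,
              label = paste0(deparse(substitute(value)), " within ", tol,
                             " of reference"))
}

random_state <- function(scale = c(1e5, 10, 5e4, 1e3)) {
  stats::runif(4) * scale
}

.conservation_err_for_tests <- function(m, y) {
  max(csppk:::.conservation_error(m, y))
}
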