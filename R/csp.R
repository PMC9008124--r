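#' CSP basis from a Jacobian
#'
#' Leading-order CSP basis: the right eigenvectors of the Jacobian are the
#' mode columns `a_n`, the rows of the inverse eigenvector matrix the dual
#' vectors `b^n`, with `b^i . a_j = delta^i_j` by construction. Modes are
#' ordered by descending eigenvalue magnitude (fastest first); eigenvalues
#' with `|lambda| < zero_tol * max|lambda|` are classified as conserved modes
#' and placed last with infinite timescale.
#'
#' Each eigenvector pair carries an arbitrary scale and sign. The convention
#' used here scales every column `a_n` so its largest-magnitude entry equals
#' one (with `b^n` rescaled reciprocally, preserving duality); the sign of
#' the pair is then fixed by requiring a nonnegative projection of the first
#' reaction's stoichiometric direction, `b^n . S_1 >= 0`, when a
#' stoichiometric matrix is supplied. All four normalized diagnostics
#' (P, J, D, I) are invariant under any rescaling; the convention only makes
#' the raw constraint coefficients `c^n_k` and amplitudes `f^n` comparable
#' across states and runs.
#'
#' @param J square real Jacobian matrix (1/h)
#' @param zero_tol relative threshold below which an eigenvalue is treated as
#'   an exact zero (a conserved moiety)
#' @param S optional stoichiometric matrix used only for the sign convention
#' @return A `csp_basis`: list with `A` (columns `a_n`), `B` (rows `b^n`),
#'   `lambda`, `tau` (`Inf` for conserved modes), `n_conserved`, and
#'   `n_dissipative`.
#' @export
csp_basis <- function(J, zero_tol = 1e-13, S = NULL) {
  J <- as.matrix(J)
  N <- nrow(J)
  stopifnot(ncol(J) == N, all(is.finite(J)))
  e <- eigen(J)
  im <- abs(Im(e$values))
  if (any(im > 1e-9 * max(abs(e$values), 1e-300))) {
    bad <- which(im > 1e-9 * max(abs(e$values)))
    stop("complex eigenvalue pair (modes ", paste(bad, collapse = ","),
         "): oscillatory timescales are outside the real leading-order basis",
         call. = FALSE)
  }
  lambda <- Re(e$values)
  A <- Re(e$vectors)
  ord <- order(-abs(lambda))
  lambda <- lambda[ord]; A <- A[, ord, drop = FALSE]
  lmax <- max(abs(lambda))
  conserved <- abs(lambda) < zero_tol * lmax
  ord2 <- c(which(!conserved), which(conserved))
  lambda <- lambda[ord2]; A <- A[, ord2, drop = FALSE]
  n_cons <- sum(conserved)

  # scale: largest-|entry| of each a_n to +1; fix pair sign via b.S_1 >= 0
  for (n in seq_len(N)) {
    s <- A[which.max(abs(A[, n])), n]
    A[, n] <- A[, n] / s
  }
  B <- solve(A)
  if (qr(A)$rank < N)
    stop("defective Jacobian: eigenvectors do not span the state space",
         call. = FALSE)
  if (!is.null(S)) {
    c1 <- drop(B %*% S[, 1])
    flip <- c1 < 0
    A[, flip] <- -A[, flip, drop = FALSE]
    B[flip, ] <- -B[flip, , drop = FALSE]
  }
  tau <- ifelse(seq_len(N) > N - n_cons, Inf, 1 / abs(lambda))
  structure(list(A = A, B = B, lambda = lambda, tau = tau,
                 n_conserved = n_cons, n_dissipative = N - n_cons),
            class = "csp_basis")
}

#' @export
print.csp_basis <- function(x, ...) {
  cat("CSP basis:", x$n_dissipative, "dissipative mode(s),",
      x$n_conserved, "conserved mode(s)\n")
  cat("  timescales (h):", paste(sprintf("%.4g", x$tau), collapse = ", "), "\n")
  invisible(x)
}

#' Mode amplitudes and constraint coefficients
#'
#' The amplitude of mode n is the projection of the right-hand side on its
#' dual vector, `f^n = b^n . g(y)`; expanded over reactions it becomes
#' `f^n = sum_k c^n_k R^k` with constraint coefficients `c^n_k = b^n . S_k`.
#' Exhausted fast modes have `f^n ~ 0`: the reaction contributions cancel,
#' which is exactly the algebraic constraint the reduced models exploit.
#' Conserved modes have `c^n_k = 0` for every k, hence `f^n = 0` identically.
#'
#' @param basis a [csp_basis()] computed at this state
#' @param model the `kinetic_model`
#' @param y state vector (nM)
#' @return List with `f` (length N, nM/h), `c` (`N x K`), `R` (length K) and
#'   `g` (length N).
#' @export
csp_amplitudes <- function(basis, model, y) {
  R <- reaction_rates(model, y)
  g <- drop(model$S %*% R)
  cmat <- basis$B %*% model$S
  if (basis$n_conserved > 0) {
    # conserved dual vectors are left null vectors of S: their coefficient
    # rows are zero in exact arithmetic, so suppress round-off residue
    cons <- seq.int(basis$n_dissipative + 1L, nrow(cmat))
    cmat[cons, ] <- 0
  }
  f <- drop(cmat %*% R)
  list(f = f, c = cmat, R = R, g = g)
}

# guard for index normalization: all-zero denominators are flagged, not NaN
.normalize_rows <- function(M) {
  den <- rowSums(abs(M))
  out <- M / ifelse(den == 0, 1, den)
  attr(out, "undefined") <- den == 0
  out
}

#' Amplitude participation index
#'
#' `P^r_k = c^r_k R^k / sum_j |c^r_j R^j|` measures the share of reaction k
#' in the cancellations that form the r-th constraint `f^r ~ 0`; rows are
#' normalized so `sum_k |P^r_k| = 1`. Rows whose denominator vanishes (an
#' exact equilibrium) are returned as zero and flagged in the `"undefined"`
#' attribute.
#'
#' @param amp output of [csp_amplitudes()]
#' @return `N x K` matrix of indices.
#' @export
amplitude_participation <- function(amp) {
  .normalize_rows(sweep(amp$c, 2, amp$R, `*`))
}

#' Timescale participation index
#'
#' Decomposes each eigenvalue over reactions:
#' `lambda^n_k = (b^n . S_k) (dR^k/dy . a_n)`, so that
#' `sum_k lambda^n_k = lambda_n` exactly, and normalizes,
#' `J^n_k = lambda^n_k / sum_j |lambda^n_j|`. Negative entries mark
#' dissipative contributions of reaction k to timescale `tau_n`, positive
#' entries explosive ones.
#'
#' @param basis a [csp_basis()]
#' @param model the `kinetic_model`
#' @param y state vector (nM)
#' @return `N x K` matrix; the per-mode eigenvalue decomposition is attached
#'   as attribute `"lambda_k"`.
#' @export
timescale_participation <- function(basis, model, y) {
  G <- rate_gradients(model, y)              # K x N, rows dR^k/dy
  cmat <- basis$B %*% model$S                # N x K
  if (basis$n_conserved > 0)
    cmat[seq.int(basis$n_dissipative + 1L, nrow(cmat)), ] <- 0
  proj <- G %*% basis$A                      # K x N, (dR^k/dy . a_n)
  lam_k <- cmat * t(proj)                    # N x K
  out <- .normalize_rows(lam_k)
  attr(out, "lambda_k") <- lam_k
  out
}

#' Mode pointers
#'
#' `D^n_i = a_n(i) b^n(i)`, the i-th diagonal entry of the n-th mode's
#' projector `a_n b^n`. Because the projectors resolve the identity,
#' `sum_n D^n_i = 1` for every variable i. A pointer near one identifies the
#' variable slaved to (equilibrated by) that mode: the QSSA candidate for a
#' fast mode, and the variable that responds first when the corresponding
#' constraint is perturbed. The pointer is invariant under any rescaling of
#' the `(a_n, b^n)` pair.
#'
#' @param basis a [csp_basis()]
#' @return `N x N` matrix, rows = modes, columns = variables.
#' @export
csp_pointers <- function(basis) {
  t(basis$A) * basis$B
}

#' Number of exhausted modes
#'
#' A fast mode is exhausted when the displacement its remaining amplitude can
#' produce over its own decay time is below the error tolerance of every
#' variable: M is the largest count such that
#' `|a_m(i) f^m| * tau_m < eps_rel |y_i| + eps_abs` for every mode `m <= M`
#' and variable i. Conserved modes (zero amplitude, infinite timescale) are
#' never counted.
#'
#' The defaults were calibrated once against the reference parameter set so
#' that the M = 0 -> 1 and 1 -> 2 transitions fall at the onset of the two
#' quasi-steady regimes (~3e-4 h and ~3 h).
#'
#' @param basis a [csp_basis()]
#' @param amp matching [csp_amplitudes()]
#' @param y state vector (nM)
#' @param eps_rel relative exhaustion tolerance
#' @param eps_abs absolute exhaustion tolerance (nM)
#' @return Integer M >= 0.
#' @export
exhausted_modes <- function(basis, amp, y, eps_rel = 1e-3, eps_abs = 1e-3) {
  nd <- basis$n_dissipative
  bound <- eps_rel * abs(y) + eps_abs
  M <- 0L
  for (m in seq_len(nd)) {
    move <- abs(basis$A[, m] * amp$f[m]) * basis$tau[m]
    if (any(move >= bound)) break
    M <- m
  }
  M
}

#' Importance index
#'
#' With M modes exhausted the system evolves in the slow subspace spanned by
#' modes M+1..N. The slow-subspace contribution of reaction k to variable n
#' is `w^n_k = sum_{m > M} a_m(n) c^m_k R^k`; normalized per variable,
#' `I^n_k = w^n_k / sum_j |w^n_j|`. Positive (negative) entries mean reaction
#' k drives variable n up (down) within the established constraints --
#' which can differ in sign from the reaction's raw stoichiometric effect,
#' because the constraints re-route its influence. For M = 0 the row sums
#' `sum_k w^n_k` reproduce the full right-hand side.
#'
#' @param basis a [csp_basis()]
#' @param amp matching [csp_amplitudes()]
#' @param M exhausted-mode count from [exhausted_modes()]
#' @return `N x K` matrix; raw contributions in attribute `"w"`.
#' @export
importance_index <- function(basis, amp, M) {
  N <- nrow(basis$A)
  slow <- seq.int(M + 1L, N)
  # w = A_slow %*% (c_slow * R broadcast over columns)
  cR <- sweep(amp$c[slow, , drop = FALSE], 2, amp$R, `*`)
  w <- basis$A[, slow, drop = FALSE] %*% cR
  out <- .normalize_rows(w)
  attr(out, "w") <- w
  out
}

#' Full CSP diagnostics at one state
#'
#' Convenience wrapper assembling basis, amplitudes, the four indices and the
#' exhausted-mode count at a single state.
#'
#' @param model a `kinetic_model`
#' @param y state vector (nM)
#' @param t time stamp (h) carried into the record
#' @param eps_rel,eps_abs exhaustion tolerances, see [exhausted_modes()]
#' @return A `csp_record`: list with `t`, `y`, `R`, `g`, `tau`, `f`, `c`,
#'   `P`, `J`, `D`, `I`, `M`.
#' @export
diagnose_state <- function(model, y, t = NA_real_,
                           eps_rel = 1e-3, eps_abs = 1e-3) {
  y <- as.numeric(y)
  basis <- csp_basis(model_jacobian(model, y), S = model$S)
  amp <- csp_amplitudes(basis, model, y)
  M <- exhausted_modes(basis, amp, y, eps_rel, eps_abs)
  structure(list(t = t, y = stats::setNames(y, model$species),
                 R = amp$R, g = amp$g,
                 lambda = basis$lambda, tau = basis$tau,
                 f = amp$f, c = amp$c,
                 P = amplitude_participation(amp),
                 J = timescale_participation(basis, model, y),
                 D = csp_pointers(basis),
                 I = importance_index(basis, amp, M),
                 M = M, basis = basis),
            class = "csp_record")
}

#' @export
print.csp_record <- function(x, digits = 4, ...) {
  cat(sprintf("CSP diagnostics at t = %g h: M = %d exhausted mode(s)\n",
              x$t, x$M))
  cat("  y (nM):   ", paste(sprintf("%.*g", digits + 3, x$y), collapse = "  "), "\n")
  cat("  tau (h):  ", paste(sprintf("%.*g", digits, x$tau), collapse = "  "), "\n")
  cat("  |f| (nM/h):", paste(sprintf("%.*g", digits, abs(x$f)), collapse = "  "), "\n")
  invisible(x)
}

#' CSP diagnostics along a trajectory
#'
#' Runs [diagnose_state()] at each requested time of a solved trajectory.
#' Mode identity across adjacent times follows the sorted-timescale position
#' (no eigenvalue crossings occur for this model class; see the package
#' vignette for the limitation).
#'
#' @param model a `kinetic_model`
#' @param traj a `kin_trajectory`; if `NULL`, the model is solved first at
#'   `rtol`/`atol` over a grid containing `times`
#' @param times evaluation times (h); defaults to the trajectory grid
#' @param eps_rel,eps_abs exhaustion tolerances
#' @param rtol,atol solver tolerances used when `traj` is `NULL`
#' @return A `csp_analysis`: list of `csp_record`s plus a summary data frame
#'   (`$summary` with t, M, tau_n, |f^n|).
#' @export
diagnose_trajectory <- function(model, traj = NULL, times = NULL,
                                eps_rel = 1e-3, eps_abs = 1e-3,
                                rtol = 1e-10, atol = 1e-8) {
  if (is.null(traj)) {
    if (is.null(times)) times <- default_grid()
    grid <- sort(unique(c(default_grid(), times)))
    grid <- grid[grid <= max(times)]
    traj <- solve_model(model, times = grid, rtol = rtol, atol = atol)
  }
  if (is.null(times)) times <- traj$times[traj$times > 0]
  records <- lapply(times, function(t)
    diagnose_state(model, state_at(traj, t), t, eps_rel, eps_abs))
  nd <- records[[1]]$basis$n_dissipative
  summ <- data.frame(
    t = times,
    M = vapply(records, `[[`, integer(1), "M"),
    do.call(rbind, lapply(records, function(r)
      stats::setNames(r$tau[seq_len(nd)], paste0("tau_", seq_len(nd))))),
    do.call(rbind, lapply(records, function(r)
      stats::setNames(abs(r$f[seq_len(nd)]), paste0("f_", seq_len(nd)))))
  )
  structure(list(records = records, summary = summ, model = model,
                 eps_rel = eps_rel, eps_abs = eps_abs),
            class = "csp_analysis")
}

#' @export
print.csp_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("CSP analysis: %d states over [%g, %g] h\n",
              nrow(s), min(s$t), max(s$t)))
  runs <- rle(s$M)
  bounds <- cumsum(runs$lengths)
  starts <- c(1, head(bounds, -1) + 1)
  for (i in seq_along(runs$values))
    cat(sprintf("  M = %d for t in [%.3g, %.3g] h\n", runs$values[i],
                s$t[starts[i]], s$t[bounds[i]]))
  invisible(x)
}

#' @export
summary.csp_analysis <- function(object, ...) object$summary

#' @export
plot.csp_analysis <- function(x, what = c("tau", "f", "M"), ...) {
  what <- match.arg(what)
  s <- x$summary
  nd <- sum(startsWith(names(s), "tau_"))
  if (what == "M") {
    plot(s$t, s$M, type = "s", log = "x", xlab = "t (h)", ylab = "M", ...)
  } else {
    cols <- paste0(what, "_", seq_len(nd))
    matplot(s$t, s[cols], type = "l", lty = 1, log = "xy", xlab = "t (h)",
            ylab = if (what == "tau") "timescale (h)" else "|f| (nM/h)", ...)
    legend("topleft", legend = cols, col = seq_len(nd), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Reduced-model period boundaries
#'
#' Extracts from a [diagnose_trajectory()] result the first time each
#' exhausted-mode count is reached, i.e. the onset of each reduced-model
#' validity period.
#'
#' @param analysis a `csp_analysis`
#' @return Data frame with columns `M` and `t_onset` (h).
#' @export
period_boundaries <- function(analysis) {
  s <- analysis$summary
  Ms <- sort(unique(s$M))
  data.frame(M = Ms,
             t_onset = vapply(Ms, function(m) min(s$t[s$M == m]), numeric(1)))
}
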