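#' Correction factors for the higher-order QSSA expressions
#'
#' The first-order corrections to the two quasi-steady-state approximations
#' are controlled by three dimensionless state-dependent ratios and a derived
#' factor:
#' `r1 = k1 a / (kon C_FcRn + kdeg)`,
#' `r2 = (kon C_IgG_e + koff) / (kon C_FcRn + kdeg)`,
#' `m = kdeg / k1`, and
#' `Lambda = (1 + m r2) / (1 + a + r1 (1 - m) + r2 (a + m))`.
#' As `r1, r2 -> 0` the corrected expressions collapse to the plain QSSA
#' forms and `Lambda -> 1/(1 + a)`.
#'
#' @param model the FcRn `kinetic_model`
#' @param y state vector (nM)
#' @return List with `r1`, `r2`, `m`, `Lambda`.
#' @export
correction_factors <- function(model, y) {
  p <- model$params
  a <- vol_ratio(p); k1 <- uptake_rate(p)
  den <- p$kon * y[3] + p$kdeg
  r1 <- k1 * a / den
  r2 <- (p$kon * y[2] + p$koff) / den
  m <- p$kdeg / k1
  Lambda <- (1 + m * r2) / (1 + a + r1 * (1 - m) + r2 * (a + m))
  list(r1 = unname(r1), r2 = unname(r2), m = m, Lambda = unname(Lambda))
}

#' Constraint approximations for the fast reaction rates
#'
#' Four algebraic approximations of the two fast net rates, each evaluated at
#' a state of the full model:
#'
#' * `qssa1_approx()`: QSSA of free endosomal IgG,
#'   `R3f - R3b ~ R1 - R2`;
#' * `corrected1_approx()`: its first-order correction, obtained by
#'   differentiating the QSSA relation in time and substituting the full
#'   equations, `((1 + r1) R1 - R2 + (r2 - r1) R4) / (1 + r2)`;
#' * `qssa2_approx()`: QSSA of the IgG-FcRn complex, `R4 ~ R1 - R2`;
#' * `corrected2_approx()`: its first-order correction,
#'   `R1 - Lambda R2`.
#'
#' @param model the FcRn `kinetic_model`
#' @param y state vector (nM)
#' @return Approximated rate (nM/h).
#' @export
qssa1_approx <- function(model, y) {
  R <- reaction_rates(model, y)
  unname(R[1] - R[2])
}

#' @rdname qssa1_approx
#' @export
corrected1_approx <- function(model, y) {
  R <- reaction_rates(model, y)
  cf <- correction_factors(model, y)
  unname(((1 + cf$r1) * R[1] - R[2] + (cf$r2 - cf$r1) * R[5]) / (1 + cf$r2))
}

#' @rdname qssa1_approx
#' @export
qssa2_approx <- function(model, y) {
  R <- reaction_rates(model, y)
  unname(R[1] - R[2])
}

#' @rdname qssa1_approx
#' @export
corrected2_approx <- function(model, y) {
  R <- reaction_rates(model, y)
  cf <- correction_factors(model, y)
  unname(R[1] - cf$Lambda * R[2])
}

#' CSP-derived constraint approximation
#'
#' Solves the exhausted-mode relation `f^n = sum_k c^n_k R^k ~ 0` for the
#' fast rate it constrains: mode 1 for the net binding rate
#' `R3f - R3b = -(c1_1 R1 + c1_2 R2 + c1_4 R4) / c1_3f`, mode 2 for the
#' recycling rate
#' `R4 = -(c2_1 R1 + c2_2 R2 + c2_3f R3f + c2_3b R3b) / c2_4`.
#' Being a ratio of coefficients of one dual vector, the result is invariant
#' under any rescaling of the basis.
#'
#' @param amp [csp_amplitudes()] at the state
#' @param mode 1 or 2, selecting which constraint is solved
#' @return Approximated rate (nM/h).
#' @export
csp_constraint_approx <- function(amp, mode) {
  stopifnot(mode %in% c(1, 2))
  cc <- amp$c[mode, ]
  R <- amp$R
  if (mode == 1) {
    if (abs(cc[3]) < 1e-300) stop("zero pivot coefficient c1_3f", call. = FALSE)
    unname(-(cc[1] * R[1] + cc[2] * R[2] + cc[5] * R[5]) / cc[3])
  } else {
    if (abs(cc[5]) < 1e-300) stop("zero pivot coefficient c2_4", call. = FALSE)
    unname(-(cc[1] * R[1] + cc[2] * R[2] + cc[3] * R[3] + cc[4] * R[4]) / cc[5])
  }
}

#' Constraint-error metrics along the trajectory
#'
#' At each requested time, evaluates the relative error of the three
#' approximations of the net binding rate `R3f - R3b` (QSSA, first-order
#' corrected, CSP constraint: `er1_1`, `er1_2`, `er1_3`) and of the recycling
#' rate `R4` (`er2_1`, `er2_2`, `er2_3`), all on the full-model state:
#' `er = (true - approx) / true`. The `period` column records the
#' exhausted-mode count at that time; the `er2_*` metrics are meaningful as
#' reduced-model errors only where `M >= 2` but are computed everywhere for
#' visibility.
#'
#' @param model the FcRn `kinetic_model`
#' @param times evaluation times (h)
#' @param traj optional pre-computed `kin_trajectory` covering `times`
#' @param rtol,atol solver tolerances when `traj` is `NULL`; the tight
#'   defaults matter here because the CSP residuals involve many digits of
#'   cancellation
#' @return Data frame with columns `t, er1_1, er1_2, er1_3, er2_1, er2_2,
#'   er2_3, period`.
#' @export
reduction_errors <- function(model, times, traj = NULL,
                             rtol = 1e-13, atol = 1e-11) {
  times <- sort(unique(as.numeric(times)))
  if (is.null(traj))
    traj <- solve_model(model, times = times, rtol = rtol, atol = atol)
  rows <- lapply(times, function(t) {
    y <- state_at(traj, t)
    rec <- diagnose_state(model, y, t)
    R <- rec$R
    x1 <- R[3] - R[4]   # net binding rate
    x2 <- R[5]          # recycling rate
    amp <- list(f = rec$f, c = rec$c, R = R, g = rec$g)
    data.frame(t = t,
               er1_1 = unname((x1 - qssa1_approx(model, y)) / x1),
               er1_2 = unname((x1 - corrected1_approx(model, y)) / x1),
               er1_3 = unname((x1 - csp_constraint_approx(amp, 1)) / x1),
               er2_1 = unname((x2 - qssa2_approx(model, y)) / x2),
               er2_2 = unname((x2 - corrected2_approx(model, y)) / x2),
               er2_3 = unname((x2 - csp_constraint_approx(amp, 2)) / x2),
               period = rec$M)
  })
  do.call(rbind, rows)
}

# damped Newton for the algebraic constraints of the reduced models.
# x0: start, fn: function returning residual, returns the root.
.newton <- function(fn, x0, tol = 1e-10, maxit = 100L) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- fn(x)
    h <- pmax(abs(x), 1e-8) * 1e-7
    J <- if (length(x) == 1L) {
      (fn(x + h) - fn(x - h)) / (2 * h)
    } else {
      vapply(seq_along(x), function(j) {
        e <- numeric(length(x)); e[j] <- h[j]
        (fn(x + e) - fn(x - e)) / (2 * h[j])
      }, numeric(length(x)))
    }
    step <- if (length(x) == 1L) fx / J else solve(J, fx)
    lam <- 1
    repeat {
      xn <- x - lam * step
      if (all(is.finite(fn(xn))) && sum(fn(xn)^2) <= sum(fx^2) || lam < 1e-6)
        break
      lam <- lam / 2
    }
    x <- x - lam * step
    if (all(abs(lam * step) <= tol * pmax(abs(x), 1e-12))) return(x)
  }
  stop("constraint root-finding did not converge", call. = FALSE)
}

# fast-variable solves for the four reduced variants ---------------------

# QSSA1: Ce from the linear constraint kon Ce Cf - koff Cx = k1 Cp - kdeg Ce
.ce_qssa1 <- function(p, Cp, Cx) {
  k1 <- uptake_rate(p)
  Cf <- p$FcRn0 - Cx
  (k1 * Cp + p$koff * Cx) / (p$kon * Cf + p$kdeg)
}

# corrected1: Ce from the corrected constraint (r2 depends on Ce -> Newton)
.ce_corrected1 <- function(p, Cp, Cx) {
  k1 <- uptake_rate(p); a <- p$Ve / p$Vp
  Cf <- p$FcRn0 - Cx
  den <- p$kon * Cf + p$kdeg
  r1 <- k1 * a / den
  fn <- function(ce) {
    r2 <- (p$kon * ce + p$koff) / den
    p$kon * ce * Cf - p$koff * Cx -
      ((1 + r1) * k1 * Cp - p$kdeg * ce + (r2 - r1) * k1 * Cx) / (1 + r2)
  }
  .newton(fn, .ce_qssa1(p, Cp, Cx))
}

# closed-form start for the two-constraint solves: substituting the
# complex constraint cx = Cp - m ce into the binding QSSA gives a quadratic
# in ce (exact for the plain two-QSSA model, a good start for the corrected)
.cecx_start <- function(p, Cp) {
  k1 <- uptake_rate(p); m <- p$kdeg / k1
  A <- p$kon * m
  B <- p$kon * (p$FcRn0 - Cp) + p$koff * m + p$kdeg
  C <- -(p$koff + k1) * Cp
  ce <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  cx <- min(max(Cp - m * ce, 0), p$FcRn0 * (1 - 1e-12))
  c(ce, cx)
}

# QSSA2: (Ce, Cx) from the two constraints of the two-QSSA model
.cecx_qssa2 <- function(p, Cp, start) {
  k1 <- uptake_rate(p); m <- p$kdeg / k1
  fn <- function(z) {
    ce <- z[1]; cx <- z[2]
    cf <- p$FcRn0 - cx
    c(p$kon * ce * cf - p$koff * cx - (k1 * Cp - p$kdeg * ce),
      cx - (Cp - m * ce))
  }
  .newton(fn, start)
}

# corrected2: (Ce, Cx) from the two corrected constraints
.cecx_corrected2 <- function(p, Cp, start) {
  k1 <- uptake_rate(p); a <- p$Ve / p$Vp; m <- p$kdeg / k1
  fn <- function(z) {
    ce <- z[1]; cx <- z[2]
    cf <- p$FcRn0 - cx
    den <- p$kon * cf + p$kdeg
    r1 <- k1 * a / den
    r2 <- (p$kon * ce + p$koff) / den
    Lam <- (1 + m * r2) / (1 + a + r1 * (1 - m) + r2 * (a + m))
    c(p$kon * ce * cf - p$koff * cx -
        ((1 + r1) * k1 * Cp - p$kdeg * ce + (r2 - r1) * k1 * cx) / (1 + r2),
      k1 * cx - (k1 * Cp - Lam * p$kdeg * ce))
  }
  .newton(fn, start)
}

#' Integrate a reduced (QSSA or corrected) model
#'
#' Integrates one of the four reduced models as a differential-algebraic
#' system: the slow variables evolve by the reduced ODEs while the fast
#' variable(s) are solved from the algebraic constraint(s) at every
#' evaluation (damped Newton, relative tolerance 1e-10); the FcRn
#' conservation law replaces the free-receptor ODE throughout.
#'
#' * `"qssa1"` / `"corrected1"`: one constraint (free endosomal IgG is fast);
#'   slow ODEs for plasma IgG and the complex.
#' * `"qssa2"` / `"corrected2"`: two constraints (free IgG and the complex
#'   are fast); a single slow ODE for plasma IgG,
#'   `dCp/dt = -a R2` (QSSA) or `-a Lambda R2` (corrected).
#'
#' A reduced model is meaningless during the initial transient, so the
#' integration starts at `t0` -- by default the onset of the corresponding
#' validity period (1e-3 h for the one-constraint models, 4 h for the
#' two-constraint ones) -- from the full-model state projected onto the
#' constraint(s).
#'
#' @param model the FcRn `kinetic_model`
#' @param which one of `"qssa1"`, `"corrected1"`, `"qssa2"`, `"corrected2"`
#' @param times output times (h); defaults to a log grid from `t0` to 2e3 h
#' @param t0 start of the reduced integration (h)
#' @param rtol,atol solver tolerances
#' @return A `kin_trajectory` whose states contain all four variables (fast
#'   variables reconstructed from the constraints at each output time).
#' @export
simulate_reduced <- function(model, which = c("qssa1", "corrected1",
                                              "qssa2", "corrected2"),
                             times = NULL, t0 = NULL,
                             rtol = 1e-10, atol = 1e-8) {
  which <- match.arg(which)
  p <- model$params
  a <- vol_ratio(p); k1 <- uptake_rate(p)
  one_constraint <- which %in% c("qssa1", "corrected1")
  if (is.null(t0)) t0 <- if (one_constraint) 1e-3 else 4
  if (is.null(times)) times <- 10^seq(log10(t0), log10(2e3), length.out = 400)
  times <- sort(unique(c(t0, as.numeric(times))))
  if (any(times < t0)) stop("times must not precede t0", call. = FALSE)

  full0 <- solve_model(model, times = t0, rtol = rtol, atol = atol)
  yf <- full0$states[nrow(full0$states), ]

  rates_of <- function(y) reaction_rates(model, y)
  if (one_constraint) {
    ce_of <- if (which == "qssa1") .ce_qssa1 else .ce_corrected1
    # state z = (Cp, Cx); Ce from constraint, Cf from conservation
    expand <- function(z) {
      ce <- ce_of(p, z[1], z[2])
      c(z[1], ce, p$FcRn0 - z[2], z[2])
    }
    dz <- function(t, z, parms) {
      y <- expand(z)
      R <- rates_of(y)
      if (which == "qssa1") {
        list(c(-a * (R[1] - R[5]), R[1] - R[2] - R[5]))
      } else {
        cf <- correction_factors(model, y)
        list(c(-a * (R[1] - R[5]),
               ((1 + cf$r1) * (R[1] - R[5]) - R[2]) / (1 + cf$r2)))
      }
    }
    z0 <- c(yf[1], yf[4])
  } else {
    solve_fast <- if (which == "qssa2") .cecx_qssa2 else .cecx_corrected2
    start_env <- new.env()
    start_env$z <- c(yf[2], yf[4])
    expand <- function(Cp) {
      z <- tryCatch(solve_fast(p, Cp, start_env$z),
                    error = function(e) solve_fast(p, Cp, .cecx_start(p, Cp)))
      start_env$z <- z
      c(Cp, z[1], p$FcRn0 - z[2], z[2])
    }
    dz <- function(t, z, parms) {
      y <- expand(z[1])
      R <- rates_of(y)
      if (which == "qssa2") list(-a * R[2])
      else list(-a * correction_factors(model, y)$Lambda * R[2])
    }
    z0 <- yf[1]
  }

  out <- deSolve::ode(y = z0, times = times, func = dz, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 500000L)
  if (nrow(out) < length(times))
    stop("reduced-model integration failed at t = ", out[nrow(out), 1],
         call. = FALSE)
  states <- t(apply(out[, -1, drop = FALSE], 1, function(z)
    if (one_constraint) expand(z) else expand(z[1])))
  colnames(states) <- model$species
  structure(list(times = out[, 1], states = states, model = model,
                 rtol = rtol, atol = atol, reduced = which),
            class = "kin_trajectory")
}
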