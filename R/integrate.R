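#' Default logarithmic output grid
#'
#' Log-spaced time grid spanning the full multiscale range of the recycling
#' process, from well inside the initial fast transient (1e-6 h) to the slow
#' terminal decay (2e3 h). The default density of 400 points per decade
#' resolves both reduced-model period boundaries (near 3e-4 h and 3 h).
#'
#' @param t_min,t_max span of the grid (h)
#' @param points_per_decade output density
#' @param include_zero prepend t = 0 (the initial condition)
#' @return Strictly increasing numeric vector of times (h).
#' @export
default_grid <- function(t_min = 1e-6, t_max = 2e3, points_per_decade = 400,
                         include_zero = TRUE) {
  stopifnot(t_min > 0, t_max > t_min, points_per_decade >= 1)
  ndec <- log10(t_max / t_min)
  g <- 10^seq(log10(t_min), log10(t_max),
              length.out = max(2L, ceiling(ndec * points_per_decade) + 1L))
  if (include_zero) g <- c(0, g)
  g
}

# deSolve hooks: rhs and analytic Jacobian in the calling convention lsoda
# expects. The model is captured in `parms`. Trial steps may transiently
# overshoot below zero before the error control rejects them, so rates are
# evaluated on the clamped state without complaint; negativity is checked on
# the accepted output states in solve_model() instead.
.desolve_rhs <- function(t, y, parms) list(model_rhs(parms$model, y, Inf))
.desolve_jac <- function(t, y, parms) model_jacobian(parms$model, y, Inf)

.integrate_segment <- function(model, y0, times, rtol, atol, hmax, clamp_tol) {
  parms <- list(model = model)
  args <- list(y = y0, times = times, func = .desolve_rhs, parms = parms,
               jacfunc = .desolve_jac, jactype = "fullusr",
               method = "lsoda", rtol = rtol, atol = atol, maxsteps = 500000L)
  if (is.finite(hmax)) args$hmax <- hmax
  out <- do.call(deSolve::ode, args)
  if (nrow(out) < length(times)) {
    stop("integration failed at t = ", out[nrow(out), 1],
         " h (last successful output time)", call. = FALSE)
  }
  out
}

#' Integrate a kinetic model with a stiff solver
#'
#' Solves the model ODEs with `deSolve`'s lsoda (BDF when stiff) using the
#' analytic Jacobian. The fastest timescale of the reference model is ~4e-5 h
#' while the span is ~2e3 h, so a stiff method is mandatory. For output times
#' below `t_fast` the maximum internal step is capped at `hmax_fast` so the
#' initial fast transient (where the first equilibrium forms) is genuinely
#' resolved rather than stepped over.
#'
#' @param model a `kinetic_model`
#' @param times requested output times (h); strictly increasing, `t = 0` is
#'   prepended internally when absent so every trajectory starts at `y0`
#' @param rtol,atol relative / absolute (nM) solver tolerances
#' @param y0 optional initial state overriding `model$y0`
#' @param t0 time of the initial state (default 0)
#' @param hmax_fast,t_fast step cap (h) applied while t < `t_fast`
#' @param clamp_tol negative-concentration tolerance applied to the accepted
#'   solver output (internal trial steps are clamped without complaint)
#' @return A `kin_trajectory`: list with `times`, `states` (rows = times,
#'   columns = species), the `model`, and solver settings. Supports
#'   `as.data.frame()`, `plot()`, and dense evaluation via [state_at()].
#' @export
solve_model <- function(model, times = default_grid(), rtol = 1e-10,
                        atol = 1e-8, y0 = NULL, t0 = 0,
                        hmax_fast = 1e-5, t_fast = 1e-3, clamp_tol = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  times <- sort(unique(as.numeric(times)))
  if (any(times < t0)) stop("requested times precede t0", call. = FALSE)
  if (is.null(y0)) y0 <- model$y0
  # stiff steppers can undershoot zero slightly; what counts as "genuinely
  # negative" must scale with the problem (the solver controls error as
  # atol + rtol|y|, so components crossing zero carry absolute round-off
  # proportional to the trajectory scale)
  if (is.null(clamp_tol))
    clamp_tol <- max(100 * atol, 1e-9 * max(abs(y0)))
  prepend <- !any(times == t0)
  tt <- if (prepend) c(t0, times) else times

  split <- t0 < t_fast && any(tt > t_fast) && is.finite(hmax_fast)
  if (split) {
    t1 <- c(tt[tt <= t_fast], t_fast)
    t1 <- sort(unique(t1))
    out1 <- .integrate_segment(model, y0, t1, rtol, atol, hmax_fast, clamp_tol)
    y_mid <- out1[nrow(out1), -1]
    t2 <- c(t_fast, tt[tt > t_fast])
    out2 <- .integrate_segment(model, y_mid, t2, rtol, atol, Inf, clamp_tol)
    keep1 <- out1[, 1] %in% tt
    keep2 <- out2[, 1] %in% tt & out2[, 1] > t_fast
    out <- rbind(out1[keep1, , drop = FALSE], out2[keep2, , drop = FALSE])
  } else {
    out <- .integrate_segment(model, y0, tt, rtol, atol,
                              if (max(tt) <= t_fast) hmax_fast else Inf,
                              clamp_tol)
  }
  if (prepend) out <- out[-1, , drop = FALSE]
  if (min(out[, -1]) < -clamp_tol)
    stop("negative concentration beyond tolerance in solver output: min = ",
         min(out[, -1]), call. = FALSE)
  states <- pmax(out[, -1, drop = FALSE], 0)
  colnames(states) <- model$species
  structure(list(times = out[, 1], states = states, model = model,
                 rtol = rtol, atol = atol),
            class = "kin_trajectory")
}

#' Evaluate a trajectory state at an arbitrary time
#'
#' For times on the stored grid the stored state is returned. Otherwise the
#' model is re-integrated from the nearest stored time at or before `t`, at
#' the trajectory's own tolerances, which reproduces the solver's dense
#' accuracy rather than interpolating.
#'
#' @param traj a `kin_trajectory`
#' @param t a single time (h) within the trajectory span
#' @return Named state vector (nM).
#' @export
state_at <- function(traj, t) {
  stopifnot(inherits(traj, "kin_trajectory"), length(t) == 1L)
  if (t < traj$times[1] || t > traj$times[length(traj$times)])
    stop("t outside trajectory span", call. = FALSE)
  hit <- which(traj$times == t)
  if (length(hit)) return(traj$states[hit[1], ])
  i0 <- max(which(traj$times < t))
  sub <- solve_model(traj$model, times = t, rtol = traj$rtol, atol = traj$atol,
                     y0 = traj$states[i0, ], t0 = traj$times[i0])
  sub$states[nrow(sub$states), ]
}

#' @export
as.data.frame.kin_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d output times over [%g, %g] h, rtol = %g\n",
              length(x$times), x$times[1], x$times[length(x$times)], x$rtol))
  ce <- max(0, .conservation_error(x$model,
                                   x$states[nrow(x$states), ]))
  cat(sprintf("  final state (nM): %s\n",
              paste(sprintf("%.4g", x$states[nrow(x$states), ]),
                    collapse = ", ")))
  if (length(x$model$conserved))
    cat(sprintf("  conservation error at final time: %.2e relative\n", ce))
  invisible(x)
}

#' @export
plot.kin_trajectory <- function(x, log = "xy", ...) {
  df <- as.data.frame(x)
  pos <- df$t > 0
  matplot(df$t[pos], df[pos, -1], type = "l", lty = 1, log = log,
          xlab = "t (h)", ylab = "concentration (nM)", ...)
  legend("bottomleft", legend = colnames(x$states), col = seq_len(ncol(x$states)),
         lty = 1, bty = "n")
  invisible(x)
}

#' Export a trajectory to CSV or JSON
#'
#' CSV uses the header `t,C_IgG_p,C_IgG_e,C_FcRn_e,C_IgG_FcRn_e` (times in h,
#' concentrations in nM); JSON writes an array of per-time records with the
#' same fields.
#'
#' @param traj a `kin_trajectory`
#' @param path output file path
#' @param format `"csv"` or `"json"`
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(traj)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}
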