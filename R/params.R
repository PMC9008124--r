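#' Parameter set for the FcRn-IgG recycling model
#'
#' Constructs and validates the parameter set of the two-compartment
#' FcRn-mediated IgG recycling model. Defaults are the reference set used
#' throughout the package: physiological plasma and endosomal volumes, binding
#' kinetics of IgG to FcRn at endosomal pH, the endosomal degradation rate of
#' free IgG, and the pinocytosis/exocytosis clearance.
#'
#' The two derived quantities -- the volume ratio `a = Ve/Vp` and the uptake
#' rate constant `k1 = CLup/Ve` (1/h) -- are never stored; they are recomputed
#' on demand by [vol_ratio()] and [uptake_rate()] so they can never drift out
#' of sync with the primitive parameters.
#'
#' @param Vp plasma volume (L)
#' @param Ve endosomal volume (L)
#' @param CLup pinocytosis/exocytosis clearance (L/h)
#' @param kon IgG-FcRn association rate constant (1/(nM h))
#' @param koff IgG-FcRn dissociation rate constant (1/h)
#' @param kdeg endosomal degradation rate constant of free IgG (1/h)
#' @param FcRn0 total endosomal FcRn concentration (nM)
#' @param Dose administered IgG amount (nmol)
#'
#' @return An object of class `fcrn_params`.
#' @examples
#' p <- fcrn_params()
#' vol_ratio(p)    # 0.34 / 3.10
#' uptake_rate(p)  # 0.167 / 0.34 (1/h)
#' @export
fcrn_params <- function(Vp = 3.10, Ve = 0.34, CLup = 0.167,
                        kon = 0.559, koff = 23.9, kdeg = 25.0,
                        FcRn0 = 4.98e4, Dose = 24.0e4) {
  p <- list(Vp = Vp, Ve = Ve, CLup = CLup, kon = kon, koff = koff,
            kdeg = kdeg, FcRn0 = FcRn0, Dose = Dose)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  structure(p, class = "fcrn_params")
}

#' @rdname fcrn_params
#' @param p an `fcrn_params` object
#' @export
vol_ratio <- function(p) {
  stopifnot(inherits(p, "fcrn_params"))
  p$Ve / p$Vp
}

#' @rdname fcrn_params
#' @export
uptake_rate <- function(p) {
  stopifnot(inherits(p, "fcrn_params"))
  p$CLup / p$Ve
}

#' @export
print.fcrn_params <- function(x, ...) {
  cat("FcRn-IgG recycling model parameters\n")
  cat(sprintf("  Vp    = %g L        Ve    = %g L\n", x$Vp, x$Ve))
  cat(sprintf("  CLup  = %g L/h      kon   = %g 1/(nM h)\n", x$CLup, x$kon))
  cat(sprintf("  koff  = %g 1/h      kdeg  = %g 1/h\n", x$koff, x$kdeg))
  cat(sprintf("  FcRn0 = %g nM       Dose  = %g nmol\n", x$FcRn0, x$Dose))
  cat(sprintf("  derived: a = Ve/Vp = %.6g, k1 = CLup/Ve = %.6g 1/h\n",
              vol_ratio(x), uptake_rate(x)))
  invisible(x)
}

#' Read model parameters from a YAML configuration file
#'
#' The configuration is a flat YAML document with any subset of the keys
#' `Vp, Ve, CLup, kon, koff, kdeg, FcRn0, Dose`. Keys left unspecified take
#' the reference values of [fcrn_params()].
#'
#' @param path path to a YAML file
#' @return An `fcrn_params` object.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("Vp", "Ve", "CLup", "kon", "koff", "kdeg", "FcRn0", "Dose")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(fcrn_params, cfg[intersect(names(cfg), known)])
}

#' Reproducible randomized parameter sets
#'
#' Draws a parameter set log-uniformly within a factor `span` of the reference
#' values, independently per parameter. Used by the property-test suite to
#' exercise the diagnostics away from the reference point; any draw retains
#' the model's conservation law and nonnegativity by construction, since only
#' rate constants, volumes and totals are varied.
#'
#' @param seed integer seed; the same seed always returns the same set
#' @param span multiplicative half-range (each parameter is drawn in
#'   `[ref/span, ref*span]`); `span = 1` returns the reference set exactly
#' @return An `fcrn_params` object.
#' @export
random_params <- function(seed, span = 10) {
  stopifnot(is.numeric(seed), length(seed) == 1L, span >= 1)
  ref <- unclass(fcrn_params())
  if (span == 1) return(fcrn_params())
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  f <- span^stats::runif(length(ref), -1, 1)
  do.call(fcrn_params, as.list(unlist(ref) * f))
}
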