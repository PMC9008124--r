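#' Mass-action kinetic network
#'
#' A `kinetic_model` bundles an ordered species list, a set of unidirectional
#' mass-action reactions (stoichiometric vector plus first- or second-order
#' rate law), the parameter set, the initial state, and any conserved moieties
#' (left null vectors of the stoichiometric matrix together with their
#' conserved totals). Reversible reactions are always stored as a
#' forward/backward pair of unidirectional reactions, because every
#' diagnostic in this package attributes fast and slow contributions to the
#' two directions separately.
#'
#' @param species character vector of species names (concentrations in nM)
#' @param reactions list of reactions; each is a list with elements
#'   `name` (label), `stoich` (signed numeric vector, one entry per species),
#'   `k` (rate constant), and `reactants` (indices of the one or two species
#'   whose concentrations multiply `k`; first order for one index, second
#'   order for two)
#' @param params the parameter object the rate constants were derived from
#' @param y0 initial concentrations (nM), one per species
#' @param conserved list of conservation laws, each a list with `coef`
#'   (numeric vector) and `total` (conserved value); every `coef` must lie in
#'   the left null space of the stoichiometric matrix
#'
#' @return An object of class `kinetic_model`.
#' @seealso [fcrn_model()] for the bundled FcRn-IgG recycling instance.
#' @export
kinetic_model <- function(species, reactions, params, y0, conserved = list()) {
  N <- length(species)
  stopifnot(N >= 1, length(y0) == N, all(is.finite(y0)))
  for (rx in reactions) {
    stopifnot(is.list(rx), !is.null(rx$name), length(rx$stoich) == N,
              is.numeric(rx$k), rx$k >= 0,
              length(rx$reactants) %in% c(1L, 2L),
              all(rx$reactants >= 1L), all(rx$reactants <= N))
  }
  S <- vapply(reactions, function(rx) as.numeric(rx$stoich), numeric(N))
  colnames(S) <- vapply(reactions, function(rx) as.character(rx$name), "")
  rownames(S) <- species
  for (cl in conserved) {
    if (max(abs(drop(cl$coef %*% S))) > 1e-12 * max(1, max(abs(S))))
      stop("conserved coefficient vector is not in the left null space of S",
           call. = FALSE)
  }
  structure(list(species = species, reactions = reactions, S = S,
                 params = params, y0 = as.numeric(y0), conserved = conserved),
            class = "kinetic_model")
}

#' The FcRn-mediated IgG recycling model
#'
#' Builds the two-compartment pharmacokinetic model of IgG salvage by the
#' neonatal Fc receptor. The state vector is
#' `y = (C_p^IgG, C_e^IgG, C_e^FcRn, C_e^IgG.FcRn)` (nM): IgG in plasma, and
#' free IgG, free FcRn and IgG-FcRn complex in the endosomal compartment.
#' Five unidirectional mass-action reactions act on it:
#'
#' * `1`  pinocytotic uptake of plasma IgG, rate `k1*C_p^IgG`, with the
#'   plasma concentration diluted/scaled by the volume ratio `a = Ve/Vp`;
#' * `2`  lysosomal degradation of free endosomal IgG, rate `kdeg*C_e^IgG`;
#' * `3f` IgG + FcRn association, rate `kon*C_e^IgG*C_e^FcRn`;
#' * `3b` complex dissociation, rate `koff*C_e^IgG.FcRn`;
#' * `4`  exocytotic recycling of the complex back to plasma, rate
#'   `k1*C_e^IgG.FcRn`, releasing FcRn in the endosome.
#'
#' Total FcRn (free plus complexed) is conserved:
#' `C_e^FcRn + C_e^IgG.FcRn = FcRn0` at all times. The initial state places
#' the entire dose in plasma and all FcRn free:
#' `y(0) = (Dose/Vp, 0, FcRn0, 0)`.
#'
#' @param params an [fcrn_params()] object
#' @return A `kinetic_model` with 4 species and 5 reactions.
#' @examples
#' m <- fcrn_model()
#' reaction_rates(m, m$y0)   # only the uptake reaction is active at t = 0
#' @export
fcrn_model <- function(params = fcrn_params()) {
  stopifnot(inherits(params, "fcrn_params"))
  a <- vol_ratio(params)
  k1 <- uptake_rate(params)
  species <- c("C_IgG_p", "C_IgG_e", "C_FcRn_e", "C_IgG_FcRn_e")
  reactions <- list(
    list(name = "1",  stoich = c(-a, 1, 0, 0),  k = k1,          reactants = 1L),
    list(name = "2",  stoich = c(0, -1, 0, 0),  k = params$kdeg, reactants = 2L),
    list(name = "3f", stoich = c(0, -1, -1, 1), k = params$kon,  reactants = c(2L, 3L)),
    list(name = "3b", stoich = c(0, 1, 1, -1),  k = params$koff, reactants = 4L),
    list(name = "4",  stoich = c(a, 0, 1, -1),  k = k1,          reactants = 4L)
  )
  y0 <- c(params$Dose / params$Vp, 0, params$FcRn0, 0)
  kinetic_model(species, reactions, params, y0,
                conserved = list(list(coef = c(0, 0, 1, 1),
                                      total = params$FcRn0)))
}

# clamp small solver undershoots to zero; anything below -tol is a real error
.clamp_state <- function(y, tol = 1e-8) {
  if (any(y < -tol))
    stop("negative concentration beyond tolerance: min(y) = ", min(y),
         call. = FALSE)
  pmax(y, 0)
}

#' Reaction rates, right-hand side, Jacobian and rate gradients
#'
#' `reaction_rates()` evaluates the K unidirectional mass-action rates at a
#' state (nM/h). `model_rhs()` assembles the time derivative
#' `g(y) = sum_k S_k R^k`. `model_jacobian()` returns the analytic `N x N`
#' Jacobian `dg/dy` (1/h), and `rate_gradients()` the `K x N` matrix whose
#' k-th row is `dR^k/dy`. The four are mutually consistent:
#' `J = S %*% rate_gradients(...)`, and every conserved coefficient vector is
#' a left null vector of both `S` and `J`.
#'
#' States within `clamp_tol` below zero are clamped to zero before rate
#' evaluation (stiff solvers may undershoot); more negative components raise
#' an error.
#'
#' @param model a `kinetic_model`
#' @param y numeric state vector (nM)
#' @param clamp_tol negative-concentration tolerance (nM)
#' @return `reaction_rates`: length-K named vector; `model_rhs`: length-N
#'   vector; `model_jacobian`: `N x N` matrix; `rate_gradients`: `K x N`
#'   matrix.
#' @export
reaction_rates <- function(model, y, clamp_tol = 1e-8) {
  y <- .clamp_state(as.numeric(y), clamp_tol)
  r <- vapply(model$reactions, function(rx) rx$k * prod(y[rx$reactants]),
              numeric(1))
  names(r) <- colnames(model$S)
  r
}

#' @rdname reaction_rates
#' @export
model_rhs <- function(model, y, clamp_tol = 1e-8) {
  drop(model$S %*% reaction_rates(model, y, clamp_tol))
}

#' @rdname reaction_rates
#' @export
rate_gradients <- function(model, y, clamp_tol = 1e-8) {
  y <- .clamp_state(as.numeric(y), clamp_tol)
  N <- length(model$species)
  G <- matrix(0, nrow = length(model$reactions), ncol = N,
              dimnames = list(colnames(model$S), model$species))
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    if (length(rx$reactants) == 1L) {
      G[j, rx$reactants] <- rx$k
    } else {
      i1 <- rx$reactants[1]; i2 <- rx$reactants[2]
      G[j, i1] <- rx$k * y[i2]
      G[j, i2] <- rx$k * y[i1]
    }
  }
  G
}

#' @rdname reaction_rates
#' @export
model_jacobian <- function(model, y, clamp_tol = 1e-8) {
  model$S %*% rate_gradients(model, y, clamp_tol)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Mass-action kinetic model:", length(x$species), "species,",
      length(x$reactions), "unidirectional reactions\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  stoichiometric matrix:\n")
  print(x$S)
  if (length(x$conserved)) {
    for (cl in x$conserved)
      cat("  conserved: [", paste(cl$coef, collapse = ", "), "] . y =",
          cl$total, "\n")
  }
  invisible(x)
}

# residual of each conservation law at a state, relative to its total
.conservation_error <- function(model, y) {
  vapply(model$conserved,
         function(cl) abs(sum(cl$coef * y) - cl$total) / abs(cl$total),
         numeric(1))
}
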