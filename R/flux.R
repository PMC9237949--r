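#' Mass-action flux of a single reaction
#'
#' Evaluates the instantaneous flux of a reaction under mass-action kinetics.
#' For an irreversible law the flux is \code{k * prod(reactants^stoich)}; for a
#' reversible law it is \code{kf * prod(reactants^stoich) - kr *
#' prod(products^stoich)}. Modifier species multiply the forward term but carry
#' no stoichiometry.
#'
#' @param reaction A [reaction()] object.
#' @param state Named numeric vector of species concentrations (uM). Must
#'   contain every species the reaction references.
#' @param params Named numeric vector resolving the reaction's rate-constant
#'   references (s^-1 or uM^-1 s^-1 depending on molecularity).
#' @return Flux in uM/s (scalar).
#' @export
mass_action_flux <- function(reaction, state, params) {
  stopifnot(inherits(reaction, "modkir_reaction"))
  needed <- unique(c(names(reaction$reactants), names(reaction$products),
                     reaction$modifiers))
  missing <- setdiff(needed, names(state))
  if (length(missing) > 0L) {
    stop("invalid state: missing species ", paste(missing, collapse = ", "))
  }
  if (any(state[needed] < 0)) {
    stop("invalid state: negative concentration for ",
         paste(needed[state[needed] < 0], collapse = ", "))
  }
  eval_flux(reaction, state, params)
}

# internal, unchecked flux kernel shared with the ODE right-hand side
eval_flux <- function(reaction, state, params) {
  k <- function(ref) {
    v <- params[[ref]]
    if (is.null(v)) stop("unresolved rate constant '", ref, "'")
    v
  }
  mod <- if (length(reaction$modifiers) > 0L) {
    prod(pmax(state[reaction$modifiers], 0))
  } else 1
  switch(reaction$law,
    mass_action_irreversible = {
      k(reaction$constants[["k"]]) * mod *
        conc_product(state, reaction$reactants)
    },
    mass_action_reversible = {
      k(reaction$constants[["kf"]]) * mod *
        conc_product(state, reaction$reactants) -
        k(reaction$constants[["kr"]]) *
          conc_product(state, reaction$products)
    },
    hill = {
      hill_flux(max(state[[reaction$hill_species]], 0),
                k(reaction$constants[["vmax"]]),
                k(reaction$constants[["khalf"]]),
                k(reaction$constants[["n"]]))
    },
    stop("unknown rate law '", reaction$law, "'")
  )
}

conc_product <- function(state, stoich) {
  if (length(stoich) == 0L) return(1)
  prod(pmax(state[names(stoich)], 0) ^ stoich)
}

#' Hill flux
#'
#' Saturating Hill kinetics \code{VMP * C^np / (Kp^np + C^np)}, used for the
#' SERCA-type pump returning cytosolic calcium to the stores.
#'
#' @param C Substrate concentration (uM), >= 0.
#' @param VMP Maximum velocity (uM/s).
#' @param Kp Half-maximal concentration (uM), > 0.
#' @param np Hill coefficient (dimensionless), > 0.
#' @return Flux in uM/s.
#' @export
hill_flux <- function(C, VMP, Kp, np) {
  if (Kp <= 0) stop("parameter error: Kp must be > 0")
  if (np <= 0) stop("parameter error: np must be > 0")
  if (C < 0) stop("invalid state: C must be >= 0")
  if (C == 0) return(0)
  VMP * C^np / (Kp^np + C^np)
}
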