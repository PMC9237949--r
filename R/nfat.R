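#' Parameters of the NFAT futile cycle
#'
#' Four-state phosphorylation/translocation cycle of the NFAT transcription
#' factor: activated calcineurin (CaN) dephosphorylates cytosolic
#' phospho-NFAT (kf_21, reversed by kr_21 scaled by the inactive CaN
#' fraction); dephosphorylated NFAT is imported into the nucleus (kf_22);
#' nuclear NFAT is rephosphorylated (kf_23, with a bimolecular reverse step
#' kr_23 involving active CaN); phospho-NFAT is exported back to the cytosol
#' (kf_24). Translocations have no back reactions, so the cycle is a closed
#' loop and total NFAT is conserved exactly.
#'
#' The CaN activation fraction \code{act_N} enters the rate laws but is not a
#' cycle species: standalone it is held at a constant, and the full pathway
#' drives it from cytosolic calcium.
#'
#' @param ... Overrides of any default constant.
#' @return Named numeric vector.
#' @export
nfat_parameters <- function(...) {
  base <- c(
    kf_21 = 0.0516,  # uM^-1 s^-1 CaN-NFATp_c binding/dephosphorylation
    kr_21 = 2.0772,  # s^-1
    kf_22 = 0.0030,  # s^-1       nuclear import of dephospho-NFAT
    kf_23 = 0.0022,  # s^-1       nuclear rephosphorylation
    kr_23 = 0.3345,  # uM^-1 s^-1 reverse (CaN-mediated) nuclear dephosphorylation
    kf_24 = 0.9844,  # s^-1       nuclear export of phospho-NFAT
    N_tot = 1.0,     # uM         total calcineurin
    act_N = 0.5      # -          standalone CaN activation fraction
  )
  dots <- c(...)
  if (length(dots) > 0L) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad) > 0L) stop("unknown constants ", paste(bad, collapse = ", "))
    base[names(dots)] <- dots
  }
  if (any(base < 0)) stop("rates must be >= 0")
  if (base[["act_N"]] > 1) stop("act_N must lie in [0, 1]")
  base
}

#' Default NFAT pool initial conditions
#'
#' The source futile-cycle model's pools are not printed in this pathway's
#' description. The default total pool (1e-5 uM, starting fully
#' phosphorylated in the cytosol) is calibrated so that the full-pathway
#' scenario reproduces the order of magnitude of the measured cytokine
#' concentrations (~1e-4 uM); downstream cytokine production is linear in
#' the pool size. Override to explore other pool sizes.
#' @return Named numeric vector (uM).
#' @export
nfat_initial_conditions <- function() {
  c(NFATp_c = 1e-5, NFATN_c = 0, NFATN_n = 0, NFATp_n = 0)
}

#' Build the NFAT futile-cycle sub-model
#'
#' @param params A [nfat_parameters()] vector.
#' @param ics Named initial concentrations of the four NFAT states (uM).
#' @param name Sub-model name.
#' @return A [submodel()] with ports \code{NFATN_n} (the transcriptionally
#'   active pool) and \code{act_N}.
#' @export
build_nfat_cooling <- function(params = nfat_parameters(),
                               ics = nfat_initial_conditions(),
                               name = "NFAT") {
  species <- c(ics[c("NFATp_c", "NFATN_c", "NFATN_n", "NFATp_n")],
               act_N = unname(params[["act_N"]]))
  pnames <- stats::setNames(paste0(name, "/", names(params)), names(params))
  rates <- function(t, state, params) {
    p <- function(s) params[[pnames[[s]]]]
    a <- min(max(state[["act_N"]], 0), 1)
    J1 <- p("kf_21") * state[["NFATp_c"]] * p("N_tot") * a -
      p("kr_21") * state[["NFATN_c"]] * (1 - a)
    J2 <- p("kf_22") * state[["NFATN_c"]]
    J3 <- p("kf_23") * state[["NFATN_n"]] -
      p("kr_23") * state[["NFATp_n"]] * p("N_tot") * a
    J4 <- p("kf_24") * state[["NFATp_n"]]
    c(NFATp_c = J4 - J1, NFATN_c = J1 - J2,
      NFATN_n = J2 - J3, NFATp_n = J3 - J4)
  }
  attr(rates, "kernel") <- list(
    name = "nfat_cooling",
    params = paste0(name, "/", c("kf_21", "kr_21", "kf_22", "kf_23",
                                 "kr_23", "kf_24", "N_tot")),
    states = c("NFATp_c", "NFATN_c", "NFATN_n", "NFATp_n", "act_N"),
    outputs = c("NFATp_c", "NFATN_c", "NFATN_n", "NFATp_n"))
  submodel(name, species = species,
           parameters = params[setdiff(names(params), "act_N")],
           reactions = list(), clamped = "act_N",
           ports = c("NFATN_n", "NFATp_c", "act_N"),
           custom_rates = rates)
}

#' Instantaneous NFAT cycle fluxes
#'
#' Convenience evaluation of the four cycle fluxes at a given state, mainly
#' for inspection and testing.
#'
#' @param params A [nfat_parameters()] vector.
#' @param state Named vector with the four NFAT pools (uM).
#' @param act_N CaN activation fraction in [0, 1].
#' @return Named vector \code{c(J1, J2, J3, J4)} (uM/s).
#' @export
nfat_fluxes <- function(params, state, act_N) {
  a <- min(max(act_N, 0), 1)
  c(J1 = params[["kf_21"]] * state[["NFATp_c"]] * params[["N_tot"]] * a -
      params[["kr_21"]] * state[["NFATN_c"]] * (1 - a),
    J2 = params[["kf_22"]] * state[["NFATN_c"]],
    J3 = params[["kf_23"]] * state[["NFATN_n"]] -
      params[["kr_23"]] * state[["NFATp_n"]] * params[["N_tot"]] * a,
    J4 = params[["kf_24"]] * state[["NFATp_n"]])
}
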