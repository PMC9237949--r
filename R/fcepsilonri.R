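#' Rate constants of the FC-epsilon-RI-gamma cascade
#'
#' The cascade couples receptor engagement to Grb2 phosphorylation through
#' seven reaction groups: pLyn binds the aggregated receptor (k_f1/k_r1) and
#' phosphorylates it (k_f2, releasing unphosphorylated Lyn), Lyn is
#' rephosphorylated from the clamped phosphate pool (k_f3), Syk docks on the
#' phosphorylated receptor (k_f4/k_r4) and is activated (k_f5, releasing free
#' pSyk and regenerating the catalytic receptor), pSyk binds Grb2 (k_f6/k_r6)
#' and phosphorylates it (k_f7).
#'
#' Two published parameterisations ship with the package: \code{"tsang"}
#' (best fit to Grb2-phosphorylation kinetics in B cells) and
#' \code{"faeder"} (the subsequent re-fit of the insensitive constants to
#' receptor/Syk phosphorylation kinetics in RBL cells, keeping k_f2, k_f4,
#' k_f6, k_f7 fixed).
#'
#' @param set \code{"tsang"} or \code{"faeder"}, or \code{NULL} to pass every
#'   constant explicitly.
#' @param ... Individual overrides, e.g. \code{k_f3 = 0}.
#' @return Named numeric vector of the 10 rate constants plus the clamped
#'   phosphate concentration \code{Pi} (uM).
#' @export
fc_parameters <- function(set = c("tsang", "faeder"), ...) {
  base <- c(
    # best fit to the Grb2-phosphorylation time course (B cells)
    k_f1 = 58.3902,  # uM^-1 s^-1 receptor-pLyn binding
    k_f2 = 0.0082,   # s^-1      receptor phosphorylation
    k_f3 = 1.0887,   # uM^-1 s^-1 Lyn rephosphorylation
    k_f4 = 10.5797,  # uM^-1 s^-1 pFC-Syk binding
    k_f5 = 63.6727,  # s^-1      Syk phosphorylation
    k_f6 = 0.4143,   # uM^-1 s^-1 pSyk-Grb2 binding
    k_f7 = 11.4185,  # s^-1      Grb2 phosphorylation
    k_r1 = 0.0136,   # s^-1
    k_r4 = 0.0807,   # s^-1
    k_r6 = 0.7313,   # s^-1
    Pi   = 1.0       # uM, clamped phosphate pool (fitted bounded elsewhere)
  )
  if (!is.null(set)) {
    set <- match.arg(set)
    if (set == "faeder") {
      base[c("k_f1", "k_f3", "k_f5", "k_r1", "k_r4", "k_r6")] <-
        c(54.7678, 0.0035, 33.7157, 0.0031, 0.1174, 0.481)
    }
  }
  dots <- c(...)
  if (length(dots) > 0L) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad) > 0L) stop("unknown constants ", paste(bad, collapse = ", "))
    base[names(dots)] <- dots
  }
  if (any(base < 0)) stop("rate constants must be >= 0")
  base
}

#' Initial conditions for the FC-epsilon-RI-gamma cascade
#'
#' All complexes and phospho-forms other than pLyn start at 0 uM.
#'
#' @param FC,Syk,Grb2,pLyn Initial concentrations (uM).
#' @return Named numeric vector.
#' @export
fc_initial_conditions <- function(FC, Syk, Grb2, pLyn) {
  ics <- c(FC = FC, Syk = Syk, Grb2 = Grb2, pLyn = pLyn)
  if (any(ics < 0)) stop("initial concentrations must be >= 0")
  ics
}

#' Build the FC-epsilon-RI-gamma sub-model
#'
#' @param params A [fc_parameters()] vector.
#' @param ics A [fc_initial_conditions()] vector.
#' @param name Sub-model name (namespace for the constants).
#' @param receptor Name to use for the engaged-receptor species; the full
#'   pathway sets this to the HLA-G/KIR2DL4/FC ternary complex so that the
#'   engaged receptor, not free FC, is the substrate pLyn phosphorylates.
#' @return A [submodel()] with ports \code{pGrb2}, \code{pSyk}, \code{pFC}
#'   and the receptor species.
#' @export
build_fcepsilonri <- function(params = fc_parameters("tsang"),
                              ics = tsang_initial_conditions(),
                              name = "FCepsilonRI",
                              receptor = "FC") {
  cx1 <- paste0(receptor, "_pLyn")
  pfc <- paste0("p", receptor)
  cx4 <- paste0(pfc, "_Syk")
  species <- c(stats::setNames(ics[["FC"]], receptor),
               pLyn = unname(ics[["pLyn"]]),
               Syk = unname(ics[["Syk"]]),
               Grb2 = unname(ics[["Grb2"]]),
               Lyn = 0, pSyk = 0, pGrb2 = 0,
               Pi = unname(params[["Pi"]]))
  species[[cx1]] <- 0
  species[[pfc]] <- 0
  species[[cx4]] <- 0
  species["pSyk_Grb2"] <- 0

  rx <- list(
    reaction("R1", stats::setNames(c(1, 1), c(receptor, "pLyn")),
             stats::setNames(1, cx1),
             law = "mass_action_reversible", constants = c(kf = "k_f1", kr = "k_r1")),
    reaction("R2", stats::setNames(1, cx1),
             stats::setNames(c(1, 1), c(pfc, "Lyn")),
             constants = c(k = "k_f2")),
    reaction("R3", c(Lyn = 1, Pi = 1), c(pLyn = 1), constants = c(k = "k_f3")),
    reaction("R4", stats::setNames(c(1, 1), c(pfc, "Syk")),
             stats::setNames(1, cx4),
             law = "mass_action_reversible", constants = c(kf = "k_f4", kr = "k_r4")),
    reaction("R5", stats::setNames(1, cx4),
             stats::setNames(c(1, 1), c(pfc, "pSyk")),
             constants = c(k = "k_f5")),
    reaction("R6", c(pSyk = 1, Grb2 = 1), c(pSyk_Grb2 = 1),
             law = "mass_action_reversible", constants = c(kf = "k_f6", kr = "k_r6")),
    reaction("R7", c(pSyk_Grb2 = 1), c(pSyk = 1, pGrb2 = 1),
             constants = c(k = "k_f7"))
  )

  submodel(name, species = species,
           parameters = params[setdiff(names(params), "Pi")],
           reactions = rx, clamped = "Pi",
           ports = c("pGrb2", "pSyk", pfc, receptor, "Pi"))
}

#' Tsang-protocol initial conditions
#'
#' 1 uM engaged receptor, 0.005 uM Syk, with the Grb2 and pLyn pools
#' estimated at 6.47 and 6.5 uM.
#' @return Named numeric vector for [build_fcepsilonri()].
#' @export
tsang_initial_conditions <- function() {
  fc_initial_conditions(FC = 1, Syk = 0.005, Grb2 = 6.47, pLyn = 6.5)
}

#' The Grb2-phosphorylation scenario (B-cell protocol)
#'
#' Cascade with the best-fit rate constants and the B-cell protocol initial
#' conditions, simulated over the 3600 s the underlying kinase assay ran.
#'
#' @return List with elements \code{model} (sub-model) and \code{spec}
#'   (simulation settings, 0-3600 s).
#' @export
tsang_scenario <- function() {
  list(model = build_fcepsilonri(fc_parameters("tsang"),
                                 tsang_initial_conditions()),
       spec = simulation_spec(0, 3600))
}

#' The receptor/Syk-phosphorylation scenario (RBL-cell protocol)
#'
#' @param variant \code{"reported"} uses the initial conditions derived from
#'   the RBL-cell experimental protocol; \code{"refit"} uses the initial
#'   conditions estimated during model fitting (including the 0.01 uM fitted
#'   Grb2 pool).
#' @return List with elements \code{model} and \code{spec} (0-4000 s).
#' @export
faeder_scenario <- function(variant = c("refit", "reported")) {
  variant <- match.arg(variant)
  ics <- switch(variant,
    reported = fc_initial_conditions(FC = 0.474, Syk = 0.432,
                                     Grb2 = 0.01, pLyn = 0.0332),
    refit = fc_initial_conditions(FC = 0.0474, Syk = 0.025,
                                  Grb2 = 0.01, pLyn = 0.0474))
  list(model = build_fcepsilonri(fc_parameters("faeder"), ics),
       spec = simulation_spec(0, 4000))
}

#' Conserved moieties of the FC-epsilon-RI-gamma cascade
#'
#' @param receptor Engaged-receptor species name (see [build_fcepsilonri()]).
#' @return Named list of species groups sharing a conserved core.
#' @export
fc_moieties <- function(receptor = "FC") {
  cx1 <- paste0(receptor, "_pLyn")
  pfc <- paste0("p", receptor)
  cx4 <- paste0(pfc, "_Syk")
  list(receptor = c(receptor, cx1, pfc, cx4),
       Lyn = c("pLyn", "Lyn", cx1),
       Syk = c("Syk", cx4, "pSyk", "pSyk_Grb2"),
       Grb2 = c("Grb2", "pSyk_Grb2", "pGrb2"))
}
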