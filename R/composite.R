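#' Connector rate constants of the full pathway
#'
#' Rates of the reactions that wire the sub-models together: HLA-G capture by
#' KIR2DL4, recruitment of the FC-epsilon-RI-gamma adaptor by the
#' receptor-ligand complex, PI3K engagement and activation by
#' phosphorylated Grb2, PLC activation by active PI3K, calcium-driven
#' calcineurin activation, and NFAT-driven cytokine production and release.
#' Defaults are the best-fit values for NK-cell cytokine-release kinetics.
#'
#' @param ... Overrides, using the names below.
#' @return Named numeric vector.
#' @export
connector_parameters <- function(...) {
  base <- c(
    k_f10  = 0.0141,     # uM^-1 s^-1 KIR2DL4-HLA-G binding
    k_r10  = 0.0140,     # s^-1       KIR2DL4-HLA-G dissociation
    k_f21  = 0.0165,     # uM^-1 s^-1 complex-FC binding
    k_r21  = 0.0517,     # s^-1       complex-FC dissociation
    pi3k_k_f2 = 8.9165,  # uM^-1 s^-1 pGrb2-PI3K binding
    pi3k_k_r2 = 0.0061,  # s^-1       pGrb2-PI3K dissociation
    pi3k_k_f3 = 14.6231, # s^-1       PI3K activation
    k_plc  = 1.0,        # uM^-1 s^-1 PLC activation by active PI3K (package choice)
    nfat_k_f = 0.0065,   # s^-1       Ca -> CaN activation relaxation rate
    K_actN = 0.5,        # uM         Ca half-activation of CaN (package choice)
    k_f4   = 0.0684,     # s^-1       IFNg production per nuclear NFAT
    k_f5   = 23.1163,    # s^-1       TNFa production per nuclear NFAT
    kf_31  = 0.0291,     # s^-1       TNFa secretion
    kf_32  = 9.7858e-03  # s^-1       IFNg secretion
  )
  dots <- c(...)
  if (length(dots) > 0L) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad) > 0L) stop("unknown constants ", paste(bad, collapse = ", "))
    base[names(dots)] <- dots
  }
  if (any(base < 0)) stop("connector rates must be >= 0")
  base
}

#' Initial conditions of the full-pathway scenario
#'
#' @param KIR2DL4,HLA_G,PI3K,plc Initial concentrations (uM); all complexes
#'   start at 0.
#' @return Named numeric vector.
#' @export
composite_initial_conditions <- function(KIR2DL4 = 0.098, HLA_G = 0.1052,
                                         PI3K = 0.01, plc = 1.3) {
  ics <- c(KIR2DL4 = KIR2DL4, HLA_G = HLA_G, PI3K = PI3K, plc = plc)
  if (any(ics < 0)) stop("initial concentrations must be >= 0")
  ics
}

#' FC-cascade rates used inside the full pathway
#'
#' Constants fixed from the sub-model calibration (k_f2, k_f3, k_f4, k_f6,
#' k_f7) combined with the values re-fitted at the pathway level (k_f1,
#' k_f5, k_r1, k_r4, k_r6).
#' @return A [fc_parameters()] vector.
#' @export
fc_parameters_composite <- function() {
  fc_parameters("faeder",
                k_f1 = 6.1804, k_f5 = 0.8040,
                k_r1 = 0.0015, k_r4 = 0.13486, k_r6 = 0.71853)
}

#' Build the full KIR2DL4/HLA-G to cytokine pathway
#'
#' Wires the receptor-engagement reactions, the FC-epsilon-RI-gamma cascade,
#' PI3K/PLC activation, the calcium oscillator, calcineurin-driven NFAT
#' cycling and cytokine production/release into one flattened model. The
#' engaged ternary complex (HLA-G:KIR2DL4:FC) is the receptor species that
#' enters the phosphorylation cascade; active PLC scales IP3 synthesis; and
#' the calcineurin activation fraction relaxes toward a saturating function
#' of cytosolic calcium at the coupling rate \code{nfat_k_f}.
#'
#' @param connectors A [connector_parameters()] vector.
#' @param fc A [fc_parameters()] vector (cascade rates).
#' @param ca A [ca_parameters()] vector.
#' @param nfat A [nfat_parameters()] vector.
#' @param ics A [composite_initial_conditions()] vector.
#' @param fc_ics Cascade pool initial conditions ([fc_initial_conditions()];
#'   the engaged-receptor entry is ignored, the complex starts at 0).
#' @param nfat_ics NFAT pool initial conditions.
#' @return A flattened \code{modkir_composite}.
#' @export
build_full_pathway <- function(connectors = connector_parameters(),
                               fc = fc_parameters_composite(),
                               ca = ca_parameters(),
                               nfat = nfat_parameters(),
                               ics = composite_initial_conditions(),
                               fc_ics = fc_initial_conditions(
                                 FC = 0, Syk = 0.025, Grb2 = 0.01,
                                 pLyn = 0.0474),
                               nfat_ics = nfat_initial_conditions()) {
  cp <- connectors

  hg <- submodel("hGactivating",
    species = c(hG = unname(ics[["HLA_G"]]), KIR2DL4 = unname(ics[["KIR2DL4"]]),
                hG2DL4 = 0),
    parameters = cp[c("k_f10", "k_r10")],
    reactions = list(
      reaction("C1", c(hG = 1, KIR2DL4 = 1), c(hG2DL4 = 1),
               law = "mass_action_reversible",
               constants = c(kf = "k_f10", kr = "k_r10"))))

  hgfc <- submodel("hG_FC",
    species = c(hG2DL4 = 0, FC = 0.0474, hG2DL4FC = 0),
    parameters = cp[c("k_f21", "k_r21")],
    reactions = list(
      reaction("C2", c(hG2DL4 = 1, FC = 1), c(hG2DL4FC = 1),
               law = "mass_action_reversible",
               constants = c(kf = "k_f21", kr = "k_r21"))))

  fcmod <- build_fcepsilonri(fc, fc_ics, receptor = "hG2DL4FC")

  pi3k <- submodel("PI3K",
    species = c(pGrb2 = 0, PI3K = unname(ics[["PI3K"]]), pGrb2_PI3K = 0,
                PI3K_act = 0, plc = unname(ics[["plc"]]), plc_act = 0),
    parameters = c(k_f2 = unname(cp[["pi3k_k_f2"]]),
                   k_r2 = unname(cp[["pi3k_k_r2"]]),
                   k_f3 = unname(cp[["pi3k_k_f3"]]),
                   k_plc = unname(cp[["k_plc"]])),
    reactions = list(
      reaction("C3a", c(pGrb2 = 1, PI3K = 1), c(pGrb2_PI3K = 1),
               law = "mass_action_reversible",
               constants = c(kf = "k_f2", kr = "k_r2")),
      reaction("C3b", c(pGrb2_PI3K = 1), c(pGrb2 = 1, PI3K_act = 1),
               constants = c(k = "k_f3")),
      reaction("C4", c(plc = 1), c(plc_act = 1), modifiers = "PI3K_act",
               constants = c(k = "k_plc"))))

  camod <- build_dupont_ca(ca, ics = c(stim = 0)) # synthesis via active PLC

  plc_tot <- unname(ics[["plc"]])
  plcip3_rates <- function(t, state, params) {
    c(IP3 = params[["PLC_IP3/Vplc"]] *
        max(state[["plc_act"]], 0) / params[["PLC_IP3/plc_tot"]])
  }
  attr(plcip3_rates, "kernel") <- list(
    name = "plc_ip3", params = c("PLC_IP3/Vplc", "PLC_IP3/plc_tot"),
    states = "plc_act", outputs = "IP3")
  plcip3 <- submodel("PLC_IP3",
    species = c(plc_act = 0, IP3 = 0),
    parameters = c(Vplc = unname(ca[["Vplc"]]), plc_tot = plc_tot),
    custom_rates = plcip3_rates)

  canfat_rates <- function(t, state, params) {
    C <- max(state[["Ccyto"]], 0)
    K <- params[["dupont_NFAT/K_actN"]]
    sat <- C^2 / (C^2 + K^2)
    c(act_N = params[["dupont_NFAT/k_f"]] * (sat - state[["act_N"]]))
  }
  attr(canfat_rates, "kernel") <- list(
    name = "ca_nfat", params = c("dupont_NFAT/k_f", "dupont_NFAT/K_actN"),
    states = c("Ccyto", "act_N"), outputs = "act_N")
  canfat <- submodel("dupont_NFAT",
    species = c(Ccyto = 0, act_N = 0),
    parameters = c(k_f = unname(cp[["nfat_k_f"]]),
                   K_actN = unname(cp[["K_actN"]])),
    custom_rates = canfat_rates)

  nfatmod <- build_nfat_cooling(nfat, nfat_ics)

  cyto <- submodel("NFAT_cytokine",
    species = c(NFATN_n = 0, TNFa = 0, IFNg = 0,
                TNFa_released = 0, IFNg_released = 0),
    parameters = cp[c("k_f4", "k_f5", "kf_31", "kf_32")],
    reactions = list(
      reaction("C6a", products = c(IFNg = 1), modifiers = "NFATN_n",
               constants = c(k = "k_f4")),
      reaction("C6b", products = c(TNFa = 1), modifiers = "NFATN_n",
               constants = c(k = "k_f5")),
      reaction("C7a", c(TNFa = 1), c(TNFa_released = 1),
               constants = c(k = "kf_31")),
      reaction("C7b", c(IFNg = 1), c(IFNg_released = 1),
               constants = c(k = "kf_32"))))

  compose(
    list(hg, hgfc, fcmod, pi3k, camod, plcip3, canfat, nfatmod, cyto),
    list(
      port_mapping(c("hGactivating", "hG2DL4"), c("hG_FC", "hG2DL4")),
      port_mapping(c("hG_FC", "hG2DL4FC"), c("FCepsilonRI", "hG2DL4FC")),
      port_mapping(c("FCepsilonRI", "pGrb2"), c("PI3K", "pGrb2")),
      port_mapping(c("PI3K", "plc_act"), c("PLC_IP3", "plc_act"),
                   mode = "flux_coupling"),
      port_mapping(c("dupont_Ca", "IP3"), c("PLC_IP3", "IP3")),
      port_mapping(c("dupont_Ca", "Ccyto"), c("dupont_NFAT", "Ccyto"),
                   mode = "flux_coupling"),
      port_mapping(c("dupont_NFAT", "act_N"), c("NFAT", "act_N")),
      port_mapping(c("NFAT", "NFATN_n"), c("NFAT_cytokine", "NFATN_n"),
                   mode = "flux_coupling")
    ))
}

#' The NK-cell cytokine-release scenario
#'
#' Full pathway with the published best-fit connector rates and the
#' soluble-HLA-G stimulation initial conditions, simulated over the 60000 s
#' horizon of the cytokine-secretion experiment.
#'
#' @return List with elements \code{model} and \code{spec}.
#' @export
rajagopalan_scenario <- function() {
  list(model = build_full_pathway(),
       spec = simulation_spec(0, 60000,
                              output_times = seq(0, 60000, by = 120)))
}

#' Conserved moieties of the full pathway
#'
#' @return Named list of species groups.
#' @export
composite_moieties <- function() {
  downstream <- c("hG2DL4FC", "hG2DL4FC_pLyn", "phG2DL4FC", "phG2DL4FC_Syk")
  list(
    KIR2DL4 = c("KIR2DL4", "hG2DL4", downstream),
    HLA_G = c("hG", "hG2DL4", downstream),
    FC = c("FC", downstream),
    Lyn = c("pLyn", "Lyn", "hG2DL4FC_pLyn"),
    Syk = c("Syk", "phG2DL4FC_Syk", "pSyk", "pSyk_Grb2"),
    Grb2 = c("Grb2", "pSyk_Grb2", "pGrb2", "pGrb2_PI3K"),
    PI3K = c("PI3K", "pGrb2_PI3K", "PI3K_act"),
    plc = c("plc", "plc_act"),
    NFAT = c("NFATp_c", "NFATN_c", "NFATN_n", "NFATp_n"))
}
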