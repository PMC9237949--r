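#' Parameters of the IP3-driven cytosolic calcium oscillator
#'
#' Core kinetics of store-operated calcium cycling: IP3-gated release from
#' the intracellular stores, a Hill-type (SERCA) pump returning calcium to
#' the stores, and IP3 metabolism by a calcium-activated 3-kinase (producing
#' IP4) and a 5-phosphatase. The cytosolic balance is
#' \deqn{dC/dt = k_1 (b + I_{ra}) (Ca_{tot} - C(\alpha+1))
#'   - V_{MP} C^{n_p} / (K_p^{n_p} + C^{n_p})}
#' where \code{Ira} is the fraction of active release channels, \code{b} a
#' basal efflux fraction and \code{alpha} the store/cytosol volume ratio.
#'
#' Channel gating is two-stage: \code{Ira} relaxes quickly to the product of
#' IP3 and calcium activation terms times a slow inactivation gate \code{h}
#' that closes at high cytosolic calcium. The fast positive and slow negative
#' calcium feedback produce sustained oscillations; because the 3-kinase is
#' calcium-activated, each calcium spike transiently converts IP3 to IP4,
#' which is what makes IP3 oscillate. Setting \code{V3k = 0} removes the
#' IP3/IP4 oscillation while leaving the calcium oscillation intact.
#'
#' Only the cytosolic-balance constants are published for this pathway; the
#' gating and IP3-metabolism constants are the package's own calibration of
#' the oscillator (see the methods vignette) and are exposed here so users
#' can substitute values of their choice.
#'
#' @param ... Overrides of any default constant.
#' @return Named numeric vector of oscillator constants.
#' @export
ca_parameters <- function(...) {
  base <- c(
    k_1   = 2.0,   # s^-1      store release kinetic rate
    b     = 0.01,  # -         basal efflux fraction
    alpha = 0.1,   # -         store/cytosol volume ratio
    VMP   = 2.0,   # uM/s      max pump velocity
    Kp    = 0.3,   # uM        pump half-max
    np    = 2.0,   # -         pump Hill coefficient
    K_act = 0.5,   # uM        Ca activation of the channel
    K_inh = 0.6,   # uM        Ca inactivation of the channel
    K_ip  = 0.5,   # uM        IP3 activation of the channel
    tau_a = 0.5,   # s         fast gating relaxation
    tau_h = 8.0,   # s         slow inactivation relaxation
    Vplc  = 0.03,  # uM/s      maximal IP3 synthesis (scaled by stim)
    V3k   = 0.05,  # uM/s      maximal IP3 3-kinase velocity (0 disables IP4 path)
    K_d3k = 0.4,   # uM        Ca half-activation of the 3-kinase
    K_3k  = 0.5,   # uM        IP3 half-saturation of the 3-kinase
    r_5p  = 0.05,  # s^-1      5-phosphatase rate
    r_ip4 = 0.05   # s^-1      IP4 degradation rate
  )
  dots <- c(...)
  if (length(dots) > 0L) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad) > 0L) {
      stop("configuration error: unknown constants ",
           paste(bad, collapse = ", "))
    }
    base[names(dots)] <- dots
  }
  if (any(base < 0)) stop("oscillator constants must be >= 0")
  if (base[["np"]] < 1) stop("np must be >= 1")
  base
}

#' Build the calcium-oscillator sub-model
#'
#' States: cytosolic calcium \code{Ccyto}, total calcium \code{Catot}
#' (clamped: closed-cell assumption), active-channel fraction \code{Ira},
#' slow inactivation gate \code{h_gate}, \code{IP3}, \code{IP4}, and the
#' dimensionless stimulation input \code{stim} (clamped; the full pathway
#' drives it with the activated-PLC fraction).
#'
#' @param params A [ca_parameters()] vector.
#' @param zero_v3k Logical; if TRUE the IP3 3-kinase flux is zeroed so no IP4
#'   is produced and IP3 settles to \code{Vplc*stim/r_5p}.
#' @param name Sub-model name.
#' @param ics Optional named overrides of the initial state.
#' @return A [submodel()] with ports \code{Ccyto}, \code{IP3}, \code{stim}.
#' @export
build_dupont_ca <- function(params = ca_parameters(), zero_v3k = FALSE,
                            name = "dupont_Ca", ics = numeric()) {
  required <- names(ca_parameters())
  missing <- setdiff(required, names(params))
  if (length(missing) > 0L) {
    stop("configuration error: missing oscillator constants ",
         paste(missing, collapse = ", "))
  }
  if (zero_v3k) params[["V3k"]] <- 0
  species <- c(Ccyto = 0.1, Catot = 5.0, Ira = 0, h_gate = 1,
               IP3 = 0.1, IP4 = 0, stim = 1)
  if (length(ics) > 0L) {
    bad <- setdiff(names(ics), names(species))
    if (length(bad) > 0L) stop("unknown species ", paste(bad, collapse = ", "))
    species[names(ics)] <- ics
  }
  pnames <- stats::setNames(paste0(name, "/", names(params)), names(params))

  rates <- function(t, state, params) {
    p <- function(s) params[[pnames[[s]]]]
    C <- max(state[["Ccyto"]], 0)
    IP3 <- max(state[["IP3"]], 0)
    Ira <- state[["Ira"]]
    h <- state[["h_gate"]]
    release <- p("k_1") * (p("b") + Ira) *
      (state[["Catot"]] - C * (p("alpha") + 1))
    pump <- hill_flux(C, p("VMP"), p("Kp"), p("np"))
    a_inf <- (IP3^2 / (IP3^2 + p("K_ip")^2)) * (C^2 / (C^2 + p("K_act")^2))
    h_inf <- p("K_inh")^2 / (p("K_inh")^2 + C^2)
    J3k <- p("V3k") * (C^2 / (C^2 + p("K_d3k")^2)) * IP3 / (IP3 + p("K_3k"))
    Jsyn <- p("Vplc") * max(state[["stim"]], 0)
    c(Ccyto = release - pump,
      Ira = (a_inf * h - Ira) / p("tau_a"),
      h_gate = (h_inf - h) / p("tau_h"),
      IP3 = Jsyn - J3k - p("r_5p") * IP3,
      IP4 = J3k - p("r_ip4") * max(state[["IP4"]], 0))
  }

  attr(rates, "kernel") <- list(
    name = "dupont_ca",
    params = paste0(name, "/", names(ca_parameters())),
    states = c("Ccyto", "Catot", "Ira", "h_gate", "IP3", "IP4", "stim"),
    outputs = c("Ccyto", "Ira", "h_gate", "IP3", "IP4"))
  submodel(name, species = species, parameters = params,
           reactions = list(), clamped = c("Catot", "stim"),
           ports = c("Ccyto", "IP3", "stim"),
           custom_rates = rates)
}

#' Peak-to-trough amplitude of an oscillating observable
#'
#' @param ts A trajectory from [simulate_model()].
#' @param species Column to measure.
#' @param after Discard the transient before this time (s).
#' @return Peak-to-trough amplitude (uM).
#' @export
oscillation_amplitude <- function(ts, species, after = 0) {
  x <- ts[ts$time_s >= after, species]
  if (length(x) == 0L) stop("no samples after t = ", after)
  max(x) - min(x)
}
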