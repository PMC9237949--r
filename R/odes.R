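#' Assemble the ODE right-hand side of a composite model
#'
#' Builds the derivative function d[s]/dt = sum_r stoich(s, r) * J_r plus any
#' custom rate contributions, with clamped species forced to zero derivative.
#' Concentrations are clipped to zero inside rate evaluation only (a guard
#' against integrator undershoot); the trajectory itself is never altered.
#'
#' @param model A \code{modkir_composite} (or a [submodel()], coerced).
#' @return A function \code{(t, state, params)} returning a list whose first
#'   element is the derivative vector, as expected by \pkg{deSolve}.
#' @export
assemble_odes <- function(model) {
  model <- as_composite(model)
  spn <- names(model$species)
  nsp <- length(spn)
  clamped_idx <- match(model$clamped, spn)

  # precompute stoichiometry as index/coefficient pairs per reaction
  rx <- lapply(model$reactions, function(r) {
    net <- numeric()
    for (s in names(r$reactants)) {
      net[s] <- (if (s %in% names(net)) net[[s]] else 0) - r$reactants[[s]]
    }
    for (s in names(r$products)) {
      net[s] <- (if (s %in% names(net)) net[[s]] else 0) + r$products[[s]]
    }
    list(r = r, idx = match(names(net), spn), coef = unname(net))
  })
  crates <- model$custom_rates

  function(t, state, params) {
    st <- state[spn]
    d <- numeric(nsp)
    names(d) <- spn
    for (e in rx) {
      J <- eval_flux(e$r, st, params)
      d[e$idx] <- d[e$idx] + e$coef * J
    }
    if (length(crates) > 0L) {
      for (fn in crates) {
        add <- fn(t, st, params)
        if (length(add) > 0L) {
          ii <- match(names(add), spn)
          d[ii] <- d[ii] + add
        }
      }
    }
    if (length(clamped_idx) > 0L) d[clamped_idx] <- 0
    list(d)
  }
}

#' Simulation settings
#'
#' @param t_start,t_end Time span in seconds.
#' @param output_times Output grid (s); defaults to 201 evenly spaced points.
#' @param rel_tol,abs_tol Integrator tolerances.
#' @param method Stiff-capable \pkg{deSolve} method identifier.
#' @return A \code{modkir_simspec} list.
#' @export
simulation_spec <- function(t_start = 0, t_end, output_times = NULL,
                            rel_tol = 1e-9, abs_tol = 1e-9,
                            method = "lsoda") {
  if (t_end <= t_start) stop("t_end must exceed t_start")
  if (is.null(output_times)) {
    output_times <- seq(t_start, t_end, length.out = 201L)
  }
  if (any(output_times < t_start) || any(output_times > t_end)) {
    stop("output_times must lie within [t_start, t_end]")
  }
  structure(list(t_start = t_start, t_end = t_end,
                 output_times = sort(unique(output_times)),
                 rel_tol = rel_tol, abs_tol = abs_tol, method = method),
            class = "modkir_simspec")
}

#' Simulate a model
#'
#' Integrates the flattened ODE system with a stiff-capable solver and returns
#' the trajectory on the requested output grid.
#'
#' @param model A \code{modkir_composite} or [submodel()].
#' @param spec A [simulation_spec()].
#' @param overrides Named numeric vector overriding parameters (namespaced,
#'   e.g. \code{"FCepsilonRI/k_f2"}) and/or initial concentrations (species
#'   name).
#' @return A data frame of class \code{modkir_timeseries}: column
#'   \code{time_s} then one column per species (uM). Attributes carry the
#'   model parameters used.
#' @export
simulate_model <- function(model, spec, overrides = numeric()) {
  model <- as_composite(model)
  y0 <- model$species
  params <- model$parameters
  if (length(overrides) > 0L) {
    for (nm in names(overrides)) {
      if (nm %in% names(params)) {
        params[[nm]] <- overrides[[nm]]
      } else if (nm %in% names(y0)) {
        y0[[nm]] <- overrides[[nm]]
      } else {
        stop("override '", nm, "' matches no parameter or species")
      }
    }
  }
  if (any(y0 < 0)) stop("initial concentrations must be >= 0")
  rhs <- compile_rhs(model, params)
  times <- spec$output_times
  if (times[1L] > spec$t_start) times <- c(spec$t_start, times)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = params,
                      method = spec$method,
                      rtol = spec$rel_tol, atol = spec$abs_tol,
                      maxsteps = 50000L)
  if (attr(out, "istate")[1L] < 0 || nrow(out) < length(times)) {
    stop("integrator failure at t = ", out[nrow(out), 1L], " s")
  }
  df <- as.data.frame(out)
  names(df)[1L] <- "time_s"
  df <- df[df$time_s %in% spec$output_times, , drop = FALSE]
  rownames(df) <- NULL
  if (any(!is.finite(as.matrix(df)))) stop("non-finite state in trajectory")
  structure(df, class = c("modkir_timeseries", "data.frame"),
            parameters = params, model_species = names(model$species))
}

#' Maximum relative drift of conserved moieties
#'
#' For each named species group, computes
#' \code{max_t |total(t) - total(0)| / total(0)}. A closed moiety in a
#' mass-action network should drift only at the integrator tolerance.
#'
#' @param ts A trajectory from [simulate_model()].
#' @param moieties Named list of character vectors (species groups).
#' @return Named numeric vector of maximal relative drifts.
#' @export
conserved_totals <- function(ts, moieties) {
  stopifnot(is.list(moieties), length(moieties) > 0L)
  vapply(moieties, function(group) {
    if (length(group) == 0L) stop("empty moiety group")
    bad <- setdiff(group, names(ts))
    if (length(bad) > 0L) stop("unknown species ", paste(bad, collapse = ", "))
    tot <- rowSums(ts[, group, drop = FALSE])
    if (tot[1L] == 0) return(max(abs(tot - tot[1L])))
    max(abs(tot - tot[1L]) / tot[1L])
  }, numeric(1L))
}

#' Totals of species groups along a trajectory
#'
#' @param ts A trajectory from [simulate_model()].
#' @param moieties Named list of character vectors.
#' @return Data frame: time_s plus one total column per moiety.
#' @export
moiety_totals <- function(ts, moieties) {
  out <- data.frame(time_s = ts$time_s)
  for (nm in names(moieties)) {
    out[[nm]] <- rowSums(ts[, moieties[[nm]], drop = FALSE])
  }
  out
}
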