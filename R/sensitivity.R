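#' One-at-a-time sensitivity sweep
#'
#' Varies a single parameter over a log-spaced grid spanning its exponent
#' bounds while all other parameters stay at the reference (best-fit) point,
#' and records the sum-of-squares error against the datasets at each grid
#' point. Grid points whose simulation fails score \code{Inf}.
#'
#' @param model Sub-model or composite.
#' @param datasets List of [dataset()] objects defining the error.
#' @param parameter Namespaced parameter name to sweep.
#' @param bounds Exponent pair \code{c(lower_exp, upper_exp)} for the sweep.
#' @param reference Named numeric overrides fixing all other parameters
#'   (typically the best fit); may include \code{parameter}, whose reference
#'   value is recorded but overridden grid point by grid point.
#' @param grid_size Number of log-spaced grid points (default 25).
#' @param sim_tol Integration tolerance for the sweep simulations.
#' @return A \code{modkir_oat} profile: \code{parameter}, \code{exponents},
#'   \code{errors}, \code{reference_value}.
#' @export
oat_sweep <- function(model, datasets, parameter, bounds,
                      reference = numeric(), grid_size = 25L,
                      sim_tol = 1e-8) {
  model <- as_composite(model)
  if (!parameter %in% names(model$parameters)) {
    stop("unknown parameter '", parameter, "'")
  }
  if (length(bounds) != 2L || bounds[1L] >= bounds[2L]) stop("invalid bounds")
  if (grid_size < 3L) stop("grid_size must be >= 3")
  exps <- seq(bounds[1L], bounds[2L], length.out = grid_size)
  pseudo <- list(datasets = datasets, weights = rep(1, length(datasets)))
  errors <- vapply(exps, function(e) {
    ov <- reference
    ov[parameter] <- 10^e
    tryCatch(sum(fit_residuals(model, pseudo, ov, sim_tol = sim_tol)^2),
             error = function(err) Inf)
  }, numeric(1L))
  ref_val <- if (parameter %in% names(reference)) reference[[parameter]] else
    model$parameters[[parameter]]
  structure(list(parameter = parameter, exponents = exps, errors = errors,
                 reference_value = ref_val),
            class = "modkir_oat")
}

#' Classify an OAT error profile
#'
#' Three-way classification of a one-at-a-time error curve:
#' \describe{
#'   \item{flat}{relative error variation \code{(max - min) / max(min, eps)}
#'     below \code{flat_tol}: the model is insensitive to the parameter.}
#'   \item{edge_minimum}{the minimum sits within \code{edge_margin} grid
#'     steps of a bound; the error keeps improving toward (or is flat
#'     beyond) the edge of the searched space.}
#'   \item{sensitive}{an interior minimum: the data constrain the
#'     parameter.}
#' }
#' The classification is invariant to uniform rescaling of the error curve.
#'
#' @param profile A profile from [oat_sweep()].
#' @param flat_tol Relative variation below which the curve counts as flat
#'   (default 0.01).
#' @param edge_margin Grid steps from a boundary within which a minimum
#'   counts as an edge minimum (default 1).
#' @return A \code{modkir_classification}: \code{label}, \code{argmin_exp},
#'   \code{rel_range}, \code{one_side_flat}.
#' @export
classify <- function(profile, flat_tol = 0.01, edge_margin = 1L) {
  err <- profile$errors
  n <- length(err)
  fin <- is.finite(err)
  if (!any(fin)) stop("unclassifiable: every grid point failed to simulate")
  rel_range <- if (all(fin)) {
    (max(err) - min(err)) / max(min(err), .Machine$double.eps)
  } else {
    Inf
  }
  i <- which.min(ifelse(fin, err, Inf))
  near_edge <- (i <= 1L + edge_margin) || (i >= n - edge_margin)
  # flatness of the curve on the boundary side of the minimum
  side <- if (i <= 1L + edge_margin) seq_len(min(n, edge_margin + 1L)) else
    seq(max(1L, n - edge_margin), n)
  side_err <- err[side]
  one_side_flat <- all(is.finite(side_err)) &&
    (max(side_err) - min(side_err)) /
      max(min(side_err), .Machine$double.eps) < flat_tol
  label <- if (rel_range < flat_tol) {
    "flat"
  } else if (near_edge) {
    "edge_minimum"
  } else {
    "sensitive"
  }
  structure(list(label = label,
                 argmin_exp = profile$exponents[i],
                 rel_range = rel_range,
                 one_side_flat = one_side_flat),
            class = "modkir_classification")
}

#' Cytokine acceptance band for the feasible-parameter census
#'
#' "Physiologically feasible" is read as: every checked prediction lies
#' within \code{multiplier} times the measured mean, inclusive, i.e. in
#' \code{[0, multiplier * mean]} per observable. The measured standard
#' deviations equal the means in the packaged summary table, which makes
#' mean + 1 sd coincide with 2 x mean; the multiplier stays configurable.
#'
#' @param means Named numeric vector: observable species -> measured mean
#'   (uM), all > 0.
#' @param multiplier Acceptance multiplier (default 2).
#' @return A \code{modkir_band}.
#' @export
acceptance_band <- function(means, multiplier = 2) {
  if (any(means <= 0)) stop("means must be > 0")
  if (multiplier <= 0) stop("multiplier must be > 0")
  structure(list(means = means, multiplier = multiplier),
            class = "modkir_band")
}

#' Feasible-parameter census (alternate solutions)
#'
#' Saltelli-samples the bounded parameter space, simulates every sample, and
#' accepts those whose predictions for each banded observable stay within
#' the acceptance band at every dataset time point. Failed simulations are
#' logged and rejected.
#'
#' @param model Sub-model or composite.
#' @param bounds Named list of exponent-bound pairs (the sampled space).
#' @param band An [acceptance_band()].
#' @param datasets List of [dataset()] objects; they define both the checked
#'   time points and the reported objective value.
#' @param N Saltelli scaling factor (total samples \code{N * (2D + 2)}).
#' @param seed Design seed (census is reproducible for a fixed seed).
#' @param fixed Named overrides applied to every sample.
#' @param sim_tol Integration tolerance.
#' @return Data frame of accepted parameter sets (linear units) with an
#'   \code{ssq} column, sorted by ssq. Attributes: \code{n_total},
#'   \code{n_failed}, \code{seed}.
#' @export
find_alternate_solutions <- function(model, bounds, band, datasets,
                                     N, seed = 1L, fixed = numeric(),
                                     sim_tol = 1e-8) {
  model <- as_composite(model)
  design <- saltelli_design(N, bounds, seed = seed)
  check_times <- sort(unique(unlist(lapply(datasets, `[[`, "times"))))
  spec <- simulation_spec(0, max(check_times),
                          output_times = union(0, check_times),
                          rel_tol = sim_tol, abs_tol = sim_tol * 10)
  obs <- names(band$means)
  upper <- band$multiplier * band$means
  n_failed <- 0L
  keep <- logical(nrow(design))
  ssq <- rep(NA_real_, nrow(design))
  for (r in seq_len(nrow(design))) {
    ov <- c(unlist(design[r, , drop = TRUE]), fixed)
    ts <- tryCatch(simulate_model(model, spec, ov), error = function(e) NULL)
    if (is.null(ts)) {
      n_failed <- n_failed + 1L
      next
    }
    at <- match(check_times, ts$time_s)
    ok <- TRUE
    for (o in obs) {
      v <- ts[at, o]
      if (any(v < 0) || any(v > upper[[o]])) { # inclusive upper bound
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    s <- 0
    for (d in datasets) {
      pred <- ts[match(d$times, ts$time_s), d$observable]
      s <- s + sum((pred - d$values)^2)
    }
    keep[r] <- TRUE
    ssq[r] <- s
  }
  out <- design[keep, , drop = FALSE]
  out$ssq <- ssq[keep]
  out <- out[order(out$ssq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_total") <- nrow(design)
  attr(out, "n_failed") <- n_failed
  attr(out, "seed") <- seed
  out
}
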