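#' Gaussian additive noise model
#'
#' @param sigma Standard deviation; absolute (uM) when
#'   \code{relative = FALSE}, else a fraction of each simulated value.
#' @param relative Interpret sigma as a relative fraction.
#' @return A \code{modkir_noise} object.
#' @export
noise_model <- function(sigma = 0, relative = FALSE) {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(kind = "gaussian-additive", sigma = sigma,
                 relative = relative),
            class = "modkir_noise")
}

#' Generate a synthetic time-course dataset from a model
#'
#' Simulates the model under the given parameter overrides and adds seeded
#' Gaussian noise, producing one [dataset()] per observable. The generating
#' parameter vector is hashed into each dataset's provenance so calibration
#' tests can verify exact provenance.
#'
#' @param model A sub-model or composite.
#' @param overrides Named numeric parameter/IC overrides used to generate the
#'   data (the "true" values a recovery experiment should find).
#' @param observables Character vector of species to observe.
#' @param times Strictly increasing observation times (s), all > t = 0.
#' @param noise A [noise_model()]; default noiseless.
#' @param seed Integer seed for the noise draw.
#' @param rel_tol,abs_tol Integration tolerances.
#' @return Named list of [dataset()] objects (one per observable), each with
#'   provenance \code{"synthetic"}, attribute \code{"params_hash"} and
#'   attribute \code{"seed"}.
#' @export
generate_synthetic_timecourse <- function(model, overrides = numeric(),
                                          observables, times,
                                          noise = noise_model(0),
                                          seed = 1L,
                                          rel_tol = 1e-9, abs_tol = 1e-9) {
  if (any(times <= 0) || any(diff(times) <= 0)) {
    stop("times must be strictly increasing and positive")
  }
  spec <- simulation_spec(0, max(times), output_times = c(0, times),
                          rel_tol = rel_tol, abs_tol = abs_tol)
  ts <- simulate_model(model, spec, overrides)
  missing <- setdiff(observables, names(ts))
  if (length(missing) > 0L) {
    stop("unknown observables: ", paste(missing, collapse = ", "))
  }
  hash <- params_hash(overrides)
  out <- list()
  for (i in seq_along(observables)) {
    obs <- observables[i]
    clean <- ts[match(times, ts$time_s), obs]
    sd_vec <- if (noise$relative) noise$sigma * abs(clean) else
      rep(noise$sigma, length(clean))
    eps <- if (noise$sigma == 0) {
      rep(0, length(clean))
    } else {
      # one independent substream per observable so adding an observable
      # does not change the others' draws
      with_local_seed(seed + (i - 1L), stats::rnorm(length(clean), 0, sd_vec))
    }
    d <- dataset(obs, times, clean + eps,
                 sigma = if (noise$sigma > 0) sd_vec else NULL,
                 provenance = "synthetic")
    attr(d, "params_hash") <- hash
    attr(d, "seed") <- seed
    out[[obs]] <- d
  }
  out
}

# deterministic short hash of a named numeric vector (order-insensitive)
params_hash <- function(overrides) {
  if (length(overrides) == 0L) return("none")
  o <- overrides[order(names(overrides))]
  txt <- paste(names(o), formatC(o, digits = 15, format = "g"),
               sep = "=", collapse = ";")
  raw <- charToRaw(txt)
  # FNV-1a 32-bit, dependency-free; arithmetic kept in doubles below 2^53
  # (bitwXor only sees the low byte, multiplication is split 16/16)
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(raw)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("fnv1a-%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
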