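#' Load a packaged parameter/initial-condition table
#'
#' The published parameter and initial-condition tables for this pathway are
#' shipped verbatim as a structured text fixture. Tables that print
#' conflicting values for the same constant are kept as-is; both readings are
#' returned, flagged under the fixture's \code{conflicts} element, and never
#' silently resolved.
#'
#' @param table_id One of \code{"T1"}, \code{"T2"}, \code{"T3-bounds"},
#'   \code{"T4"} ... \code{"T11"}.
#' @return A list with at least \code{title}, \code{provenance} and either
#'   \code{values} (named list) or \code{rows} (list of records); any
#'   conflicts touching the table are attached as \code{conflicts}.
#' @examples
#' load_fixture("T10")$values[["hGactivating/k_f10"]] # 0.0141
#' @export
load_fixture <- function(table_id) {
  all <- fixture_db()
  ids <- setdiff(names(all), "conflicts")
  if (!table_id %in% ids) {
    stop("unknown fixture '", table_id, "'; available: ",
         paste(ids, collapse = ", "))
  }
  fx <- all[[table_id]]
  fx$id <- table_id
  hits <- Filter(function(cf) table_id %in% sub("-row.*$", "", names(cf$readings)),
                 all$conflicts)
  if (length(hits) > 0L) fx$conflicts <- hits
  fx
}

#' List available fixture table identifiers
#' @return Character vector of table ids.
#' @export
fixture_ids <- function() {
  setdiff(names(fixture_db()), "conflicts")
}

fixture_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "fixtures.yaml", package = "modkir")
      if (path == "") { # not installed (development tree)
        path <- file.path("inst", "extdata", "fixtures.yaml")
      }
      cache <<- yaml::read_yaml(path)
    }
    cache
  }
})

#' Exponent bounds of the composite calibration as a named list
#'
#' Convenience accessor over the \code{"T3-bounds"} fixture: deduplicates the
#' repeated row and returns bounds keyed by namespaced parameter name, ready
#' for [saltelli_design()] or [fit_spec()].
#'
#' @return Named list of \code{c(lower_exp, upper_exp)} pairs (23 entries).
#' @export
composite_bounds <- function() {
  rows <- load_fixture("T3-bounds")$rows
  out <- list()
  for (r in rows) {
    out[[r$parameter]] <- c(r$lower, r$upper)
  }
  out
}

#' Convert a mass density to a molar concentration
#'
#' Implements the concentration conversion c_i = P_i / M_i with explicit unit
#' handling: pg/ml -> g/L -> mol/L -> uM.
#'
#' @param density Mass density in pg/ml (>= 0).
#' @param molar_mass Molar mass in g/mol (> 0).
#' @return Concentration in uM.
#' @examples
#' pg_per_ml_to_micromolar(17000, 17000) # 1e-3 uM
#' @export
pg_per_ml_to_micromolar <- function(density, molar_mass) {
  if (any(molar_mass <= 0)) stop("molar_mass must be > 0")
  if (any(density < 0)) stop("density must be >= 0")
  g_per_l <- density * 1e-9      # pg/ml = 1e-12 g / 1e-3 L
  mol_per_l <- g_per_l / molar_mass
  mol_per_l * 1e6
}
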