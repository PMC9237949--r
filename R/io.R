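# Plain-text interchange: trajectory CSV, dataset CSV, and YAML model /
# override configs. Numeric CSV output is fixed to 12 significant digits so
# identical runs produce byte-identical files.

fmt12 <- function(x) formatC(x, digits = 12, format = "g")

#' Write a simulated trajectory to CSV
#'
#' First column is \code{time_s}, one column per species, header mandatory,
#' numbers at 12 significant digits.
#'
#' @param ts A trajectory from [simulate_model()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(ts, path) {
  stopifnot(names(ts)[1L] == "time_s")
  out <- as.data.frame(lapply(ts, fmt12), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#' @param path File path.
#' @return Data frame with \code{time_s} first.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time_s") stop("not a trajectory CSV: ", path)
  df
}

#' Write a dataset to CSV (columns time_s, value_uM[, sigma_uM])
#' @param d A [dataset()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset_csv <- function(d, path) {
  df <- data.frame(time_s = fmt12(d$times), value_uM = fmt12(d$values))
  if (!is.null(d$sigma)) df$sigma_uM <- fmt12(d$sigma)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset CSV
#' @param path File path.
#' @param observable Species name the values refer to.
#' @param provenance Provenance tag recorded on the dataset.
#' @return A [dataset()].
#' @export
read_dataset_csv <- function(path, observable,
                             provenance = c("user", "synthetic", "fixture")) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "value_uM")
  if (!all(need %in% names(df))) {
    stop("dataset CSV must have columns time_s, value_uM[, sigma_uM]")
  }
  dataset(observable, df$time_s, df$value_uM,
          sigma = if ("sigma_uM" %in% names(df)) df$sigma_uM,
          provenance = match.arg(provenance))
}

#' Serialise a sub-model to a YAML config
#'
#' Covers species (with clamps), parameters, reactions and ports; the result
#' reloads to an equivalent sub-model via [submodel_from_config()]. Sub-models
#' carrying non-reaction custom dynamics (e.g. channel gating) cannot be
#' expressed in the config dialect and must be rebuilt through their builder
#' functions; serialising one is an error.
#'
#' @param sm A [submodel()].
#' @param path Output YAML path.
#' @return \code{path}, invisibly.
#' @export
submodel_to_config <- function(sm, path) {
  if (!inherits(sm, "modkir_submodel")) stop("not a sub-model")
  if (!is.null(sm$custom_rates)) {
    stop("sub-model '", sm$name, "' has custom dynamics; ",
         "rebuild it from its builder function instead of a config file")
  }
  cfg <- list(
    name = sm$name,
    species = as.list(sm$species),
    clamped = as.list(sm$clamped),
    parameters = as.list(sm$parameters),
    ports = as.list(sm$ports),
    reactions = lapply(unname(sm$reactions), function(r) {
      list(id = r$id, law = r$law,
           reactants = as.list(r$reactants),
           products = as.list(r$products),
           modifiers = as.list(r$modifiers),
           constants = as.list(r$constants),
           hill_species = r$hill_species)
    }))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Rebuild a sub-model from a YAML config
#' @param path Config written by [submodel_to_config()].
#' @return A [submodel()].
#' @export
submodel_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rxs <- lapply(cfg$reactions, function(r) {
    reaction(r$id,
             reactants = unlist(r$reactants) %||% numeric(),
             products = unlist(r$products) %||% numeric(),
             modifiers = as.character(unlist(r$modifiers)),
             law = r$law,
             constants = unlist(r$constants),
             hill_species = r$hill_species)
  })
  submodel(cfg$name,
           species = unlist(cfg$species),
           parameters = unlist(cfg$parameters) %||% numeric(),
           reactions = rxs,
           clamped = as.character(unlist(cfg$clamped)),
           ports = as.character(unlist(cfg$ports)))
}

#' Write parameter/IC overrides to YAML
#' @param overrides Named numeric vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_overrides <- function(overrides, path) {
  yaml::write_yaml(as.list(overrides), path, precision = 15L)
  invisible(path)
}

#' Read parameter/IC overrides from YAML
#' @param path YAML file of \code{name: value} pairs.
#' @return Named numeric vector.
#' @export
read_overrides <- function(path) {
  unlist(yaml::read_yaml(path))
}
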