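#' Define a reaction
#'
#' A reaction couples reactant and product species through a rate law. Rate
#' constants are referenced by name and resolved against the (namespaced)
#' parameter vector at evaluation time, so the same reaction object can be
#' simulated under parameter overrides.
#'
#' @param id Reaction identifier, unique within a sub-model.
#' @param reactants,products Named numeric vectors: species name ->
#'   stoichiometric coefficient. Either may be empty.
#' @param modifiers Character vector of species that enter the forward rate
#'   law multiplicatively but are neither consumed nor produced.
#' @param law One of \code{"mass_action_irreversible"},
#'   \code{"mass_action_reversible"}, \code{"hill"}.
#' @param constants Named character vector of rate-constant references:
#'   \code{c(k=)} for irreversible, \code{c(kf=, kr=)} for reversible,
#'   \code{c(vmax=, khalf=, n=)} for Hill.
#' @param hill_species For the Hill law, the species whose concentration
#'   drives the flux.
#' @return An object of class \code{modkir_reaction}.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     modifiers = character(),
                     law = c("mass_action_irreversible",
                             "mass_action_reversible", "hill"),
                     constants, hill_species = NULL) {
  law <- match.arg(law)
  req <- switch(law,
    mass_action_irreversible = "k",
    mass_action_reversible = c("kf", "kr"),
    hill = c("vmax", "khalf", "n"))
  if (!all(req %in% names(constants))) {
    stop("reaction '", id, "': law '", law, "' requires constants ",
         paste(req, collapse = ", "))
  }
  if (law == "hill" && is.null(hill_species)) {
    stop("reaction '", id, "': hill law needs hill_species")
  }
  structure(list(id = id,
                 reactants = reactants, products = products,
                 modifiers = modifiers, law = law,
                 constants = constants, hill_species = hill_species),
            class = "modkir_reaction")
}

#' Define a sub-model
#'
#' A sub-model is a self-contained unit of species, parameters and reactions
#' with named ports through which it can be wired to other sub-models. Species
#' initial concentrations are in uM; time is in seconds throughout.
#'
#' @param name Sub-model name; parameters are namespaced as
#'   \code{"name/parameter"} when the sub-model is flattened into a composite.
#' @param species Named numeric vector of initial concentrations (uM, >= 0).
#' @param parameters Named numeric vector of local rate constants.
#' @param reactions List of [reaction()] objects. Rate-constant references are
#'   local parameter names.
#' @param clamped Character vector of species held constant during
#'   integration (their derivative is forced to zero).
#' @param ports Character vector of exposed species names available for
#'   mapping. Defaults to all species.
#' @param custom_rates Optional \code{function(t, state, params)} returning a
#'   named vector of additional derivative contributions (uM/s), for dynamics
#'   that are not elementary reactions (e.g. channel gating). \code{params}
#'   receives namespaced names.
#' @return An object of class \code{modkir_submodel}.
#' @export
submodel <- function(name, species, parameters = numeric(),
                     reactions = list(), clamped = character(),
                     ports = names(species), custom_rates = NULL) {
  if (any(species < 0)) {
    stop("sub-model '", name, "': initial concentrations must be >= 0")
  }
  if (anyDuplicated(names(species))) {
    stop("sub-model '", name, "': duplicated species names")
  }
  if (!all(clamped %in% names(species))) {
    stop("sub-model '", name, "': clamped species not declared")
  }
  if (!all(ports %in% c(names(species), names(parameters)))) {
    stop("sub-model '", name, "': ports must reference declared variables")
  }
  for (r in reactions) {
    refs <- c(names(r$reactants), names(r$products), r$modifiers,
              r$hill_species)
    bad <- setdiff(refs, names(species))
    if (length(bad) > 0L) {
      stop("sub-model '", name, "': reaction '", r$id,
           "' references unknown species ", paste(bad, collapse = ", "))
    }
    badk <- setdiff(unname(r$constants), names(parameters))
    if (length(badk) > 0L) {
      stop("sub-model '", name, "': reaction '", r$id,
           "' references unknown constants ", paste(badk, collapse = ", "))
    }
  }
  structure(list(name = name, species = species, parameters = parameters,
                 reactions = reactions, clamped = clamped, ports = ports,
                 custom_rates = custom_rates),
            class = "modkir_submodel")
}

#' Define a port mapping between two sub-models
#'
#' \code{identity} mappings collapse the two ports onto a single shared state;
#' the source's initial concentration and clamp status win. In
#' \code{flux_coupling} mode the source state is made readable by the target's
#' rate laws (it replaces the target species as a modifier) but is never
#' consumed or produced by the target's reactions.
#'
#' @param source,target Length-2 character vectors \code{c(submodel, port)}.
#' @param mode \code{"identity"} or \code{"flux_coupling"}.
#' @return An object of class \code{modkir_mapping}.
#' @export
port_mapping <- function(source, target,
                         mode = c("identity", "flux_coupling")) {
  mode <- match.arg(mode)
  stopifnot(length(source) == 2L, length(target) == 2L)
  structure(list(source = source, target = target, mode = mode),
            class = "modkir_mapping")
}

#' Compose sub-models into a flattened model
#'
#' Flattens a set of sub-models wired by port mappings into a single species
#' list and reaction list ready for ODE assembly. Parameter names are
#' namespaced \code{"submodel/parameter"}; species names are kept plain and
#' must be unique across sub-models unless merged by an identity mapping.
#'
#' @param submodels List of [submodel()] objects.
#' @param mappings List of [port_mapping()] objects.
#' @return An object of class \code{modkir_composite} with elements
#'   \code{species}, \code{clamped}, \code{parameters}, \code{reactions},
#'   \code{custom_rates}.
#' @export
compose <- function(submodels, mappings = list()) {
  names(submodels) <- vapply(submodels, `[[`, "", "name")
  if (anyDuplicated(names(submodels))) stop("duplicated sub-model names")

  # validate mappings against ports
  for (m in mappings) {
    for (end in list(m$source, m$target)) {
      sm <- submodels[[end[1L]]]
      if (is.null(sm)) stop("composition error: unknown sub-model '",
                            end[1L], "'")
      if (!end[2L] %in% sm$ports) {
        stop("composition error: '", end[2L],
             "' is not a port of sub-model '", end[1L], "'")
      }
    }
  }
  tgt_keys <- vapply(mappings, function(m) paste(m$target, collapse = "/"), "")
  if (anyDuplicated(tgt_keys[vapply(mappings, `[[`, "", "mode") == "identity"])) {
    stop("composition error: a port is the target of two identity mappings")
  }

  # per-submodel rename tables implementing the mappings; mapped targets do
  # not contribute their own state (the source sub-model owns it)
  rename <- lapply(submodels, function(sm) {
    nm <- names(sm$species)
    stats::setNames(nm, nm)
  })
  mapped_in <- lapply(submodels, function(sm) character())
  demote <- lapply(submodels, function(sm) character()) # flux-coupled inputs
  for (m in mappings) {
    src_name <- rename[[m$source[1L]]][[m$source[2L]]]
    rename[[m$target[1L]]][[m$target[2L]]] <- src_name
    mapped_in[[m$target[1L]]] <- c(mapped_in[[m$target[1L]]], m$target[2L])
    if (m$mode == "flux_coupling") {
      demote[[m$target[1L]]] <- c(demote[[m$target[1L]]], m$target[2L])
    }
  }

  species <- numeric()
  clamped <- character()
  parameters <- numeric()
  reactions <- list()
  custom_rates <- list()
  merged_away <- character()

  for (sm in submodels) {
    map <- rename[[sm$name]]
    gone <- unique(mapped_in[[sm$name]]) # mapped-target species: state owned elsewhere
    merged_away <- c(merged_away, unname(map[gone]))
    local_new <- setdiff(names(sm$species), gone)
    dup <- intersect(map[local_new], names(species))
    if (length(dup) > 0L) {
      stop("composition error: species ", paste(dup, collapse = ", "),
           " declared in two sub-models without a mapping")
    }
    add <- sm$species[local_new]
    names(add) <- map[local_new]
    species <- c(species, add)
    clamped <- c(clamped, unname(map[intersect(sm$clamped, local_new)]))

    if (length(sm$parameters) > 0L) {
      pp <- sm$parameters
      names(pp) <- paste0(sm$name, "/", names(pp))
      parameters <- c(parameters, pp)
    }

    dem <- demote[[sm$name]]
    for (r in sm$reactions) {
      r$reactants <- rename_stoich(r$reactants, map)
      r$products <- rename_stoich(r$products, map)
      r$modifiers <- unname(map[r$modifiers])
      if (!is.null(r$hill_species)) r$hill_species <- map[[r$hill_species]]
      # flux-coupled inputs become modifiers: read, never consumed/produced
      for (d in dem) {
        gname <- map[[d]]
        if (gname %in% names(r$reactants)) {
          r$modifiers <- c(r$modifiers, rep(gname, r$reactants[[gname]]))
          r$reactants <- r$reactants[names(r$reactants) != gname]
        }
        r$products <- r$products[names(r$products) != gname]
      }
      r$constants <- stats::setNames(paste0(sm$name, "/", unname(r$constants)),
                                     names(r$constants))
      r$id <- paste0(sm$name, ".", r$id)
      reactions[[r$id]] <- r
    }
    if (!is.null(sm$custom_rates)) {
      custom_rates[[sm$name]] <- make_renamed_rate(sm$custom_rates, map)
    }
  }

  structure(list(submodels = names(submodels),
                 species = species, clamped = unique(clamped),
                 parameters = parameters, reactions = reactions,
                 custom_rates = custom_rates),
            class = "modkir_composite")
}

rename_stoich <- function(stoich, map) {
  if (length(stoich) == 0L) return(stoich)
  names(stoich) <- unname(map[names(stoich)])
  stoich
}

make_renamed_rate <- function(fn, map) {
  kern <- attr(fn, "kernel")
  if (!is.null(kern)) {
    kern$states <- unname(ifelse(kern$states %in% names(map),
                                 map[kern$states], kern$states))
    kern$outputs <- unname(ifelse(kern$outputs %in% names(map),
                                  map[kern$outputs], kern$outputs))
  }
  out_fn <- if (!any(map != names(map))) {
    fn
  } else {
    local_names <- names(map)
    global_names <- unname(map)
    function(t, state, params) {
      loc <- state[global_names]
      names(loc) <- local_names
      out <- fn(t, c(state[setdiff(names(state), global_names)], loc), params)
      if (length(out) > 0L) {
        hit <- names(out) %in% local_names
        names(out)[hit] <- map[names(out)[hit]]
      }
      out
    }
  }
  attr(out_fn, "kernel") <- kern
  out_fn
}

#' Coerce a single sub-model to a composite
#'
#' Convenience wrapper so a sub-model can be simulated standalone with the
#' same machinery as a full composite.
#' @param sm A [submodel()].
#' @return A \code{modkir_composite}.
#' @export
as_composite <- function(sm) {
  if (inherits(sm, "modkir_composite")) return(sm)
  compose(list(sm))
}

#' @export
print.modkir_composite <- function(x, ...) {
  cat("<modkir composite model>\n")
  cat("  sub-models:", paste(x$submodels, collapse = ", "), "\n")
  cat("  species:   ", length(x$species),
      " (", length(x$clamped), " clamped)\n", sep = "")
  cat("  reactions: ", length(x$reactions), "\n", sep = "")
  cat("  parameters:", length(x$parameters), "\n")
  invisible(x)
}

#' @export
print.modkir_submodel <- function(x, ...) {
  cat("<modkir sub-model '", x$name, "'>\n", sep = "")
  cat("  species:  ", paste(names(x$species), collapse = ", "), "\n")
  cat("  reactions:", length(x$reactions), "\n")
  invisible(x)
}
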