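# Precompiled right-hand side: resolves species and rate-constant references
# to integer indices and numeric values once per simulation, so the inner
# integration loop avoids all name lookups. assemble_odes() is the readable
# reference implementation; the two must agree to rounding (tested).

compile_rhs <- function(model, params) {
  model <- as_composite(model)
  spn <- names(model$species)
  nsp <- length(spn)
  clamped_idx <- match(model$clamped, spn)

  rx <- lapply(model$reactions, function(r) {
    net <- numeric()
    for (s in names(r$reactants)) {
      net[s] <- (if (s %in% names(net)) net[[s]] else 0) - r$reactants[[s]]
    }
    for (s in names(r$products)) {
      net[s] <- (if (s %in% names(net)) net[[s]] else 0) + r$products[[s]]
    }
    rep_idx <- function(stoich) {
      if (length(stoich) == 0L) return(integer())
      rep(match(names(stoich), spn), times = stoich)
    }
    kval <- function(ref) {
      v <- params[[r$constants[[ref]]]]
      if (is.null(v)) stop("unresolved rate constant '", r$constants[[ref]], "'")
      v
    }
    out <- list(net_idx = match(names(net), spn), net_coef = unname(net))
    if (r$law == "mass_action_irreversible") {
      out$type <- 1L
      out$k1 <- kval("k")
      out$fidx <- c(rep_idx(r$reactants), match(r$modifiers, spn))
    } else if (r$law == "mass_action_reversible") {
      out$type <- 2L
      out$k1 <- kval("kf")
      out$k2 <- kval("kr")
      out$fidx <- c(rep_idx(r$reactants), match(r$modifiers, spn))
      out$pidx <- rep_idx(r$products)
    } else {
      out$type <- 3L
      out$k1 <- kval("vmax")
      out$k2 <- kval("khalf")
      out$k3 <- kval("n")
      out$fidx <- match(r$hill_species, spn)
    }
    out
  })
  crates <- unname(model$custom_rates)
  crate_idx <- vector("list", length(crates)) # learned on first call

  # fast path: every custom rate is a known compiled kernel
  kernel_codes <- c(dupont_ca = 1L, nfat_cooling = 2L,
                    plc_ip3 = 3L, ca_nfat = 4L)
  kerns <- lapply(crates, attr, "kernel")
  if (all(vapply(kerns, function(k) {
        !is.null(k) && k$name %in% names(kernel_codes)
      }, logical(1L)))) {
    rx_c <- lapply(rx, function(e) {
      list(type = e$type,
           k = c(e$k1, if (!is.null(e$k2)) e$k2, if (!is.null(e$k3)) e$k3),
           fidx = as.integer(e$fidx - 1L),
           pidx = as.integer(if (is.null(e$pidx)) integer() else e$pidx - 1L),
           net_idx = as.integer(e$net_idx - 1L), net_coef = e$net_coef)
    })
    kn_c <- lapply(kerns, function(k) {
      pv <- params[k$params]
      if (anyNA(pv)) stop("kernel '", k$name, "': unresolved parameters")
      list(type = kernel_codes[[k$name]], par = unname(pv),
           sidx = as.integer(match(k$states, spn) - 1L),
           oidx = as.integer(match(k$outputs, spn) - 1L))
    })
    ptr <- rhs_build(nsp, unname(rx_c), kn_c,
                     as.integer(clamped_idx - 1L))
    return(function(t, y, p) list(rhs_eval(ptr, t, y)))
  }

  function(t, y, p) {
    st <- pmax(y, 0)
    d <- numeric(nsp)
    for (e in rx) {
      J <- if (e$type == 1L) {
        e$k1 * prod(st[e$fidx])
      } else if (e$type == 2L) {
        e$k1 * prod(st[e$fidx]) - e$k2 * prod(st[e$pidx])
      } else {
        C <- st[e$fidx]
        if (C == 0) 0 else e$k1 * C^e$k3 / (e$k2^e$k3 + C^e$k3)
      }
      d[e$net_idx] <- d[e$net_idx] + e$net_coef * J
    }
    if (length(crates) > 0L) {
      names(st) <- spn
      for (i in seq_along(crates)) {
        add <- crates[[i]](t, st, params)
        ii <- crate_idx[[i]]
        if (is.null(ii)) {
          ii <- match(names(add), spn)
          crate_idx[[i]] <<- ii
        }
        d[ii] <- d[ii] + add
      }
    }
    if (length(clamped_idx) > 0L) d[clamped_idx] <- 0
    list(d)
  }
}
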