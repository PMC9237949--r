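toy <- function(name = "A", sp = c(X = 1, Y = 0), k = c(kx = 0.5)) {
  # one first-order conversion between the first two species, whatever
  # they are called
  submodel(name, species = sp, parameters = k,
           reactions = list(reaction("r1",
                                     stats::setNames(1, names(sp)[1L]),
                                     stats::setNames(1, names(sp)[2L]),
                                     constants = c(k = "kx"))))
}

test_that("reaction constructor validates its law", {
  expect_error(reaction("r", c(A = 1), c(B = 1), constants = c(kf = "a")),
               "requires constants")
  expect_error(reaction("r", c(A = 1), c(B = 1), law = "hill",
                        constants = c(vmax = "v", khalf = "k", n = "n")),
               "hill_species")
})

test_that("submodel constructor validates species and references", {
  expect_error(submodel("m", c(X = -1)), ">= 0")
  expect_error(submodel("m", c(X = 1, X = 2)), "duplicated")
  expect_error(submodel("m", c(X = 1), clamped = "Z"), "clamped")
  expect_error(
    submodel("m", c(X = 1), parameters = c(k = 1),
             reactions = list(reaction("r", c(Q = 1), c(X = 1),
                                       constants = c(k = "k")))),
    "unknown species")
  expect_error(
    submodel("m", c(X = 1, Q = 0),
             reactions = list(reaction("r", c(Q = 1), c(X = 1),
                                       constants = c(k = "kmiss")))),
    "unknown constants")
})

test_that("composing without mappings yields the disjoint union", {
  m <- compose(list(toy("A"), toy("B", sp = c(P = 2, Q = 0))))
  expect_setequal(names(m$species), c("X", "Y", "P", "Q"))
  expect_equal(length(m$reactions), 2L)
  expect_setequal(names(m$parameters), c("A/kx", "B/kx"))
})

test_that("same species in two sub-models without a mapping errors", {
  expect_error(compose(list(toy("A"), toy("B"))), "composition error")
})

test_that("mapping to a nonexistent port errors", {
  expect_error(
    compose(list(toy("A"), toy("B", sp = c(P = 2, Q = 0))),
            list(port_mapping(c("A", "Y"), c("B", "Zz")))),
    "not a port")
  expect_error(
    compose(list(toy("A")),
            list(port_mapping(c("Nope", "Y"), c("A", "X")))),
    "unknown sub-model")
})

test_that("identity mapping collapses two ports onto one shared state", {
  a <- toy("A")                              # X -> Y
  b <- submodel("B", species = c(Yb = 0.25, Z = 0), parameters = c(kz = 1),
                reactions = list(reaction("r1", c(Yb = 1), c(Z = 1),
                                          constants = c(k = "kz"))))
  m <- compose(list(a, b), list(port_mapping(c("A", "Y"), c("B", "Yb"))))
  expect_setequal(names(m$species), c("X", "Y", "Z"))
  # source initial concentration wins
  expect_equal(unname(m$species[["Y"]]), 0)
  ts <- simulate_model(m, simulation_spec(0, 10, seq(0, 10, 1)))
  # X + Y + Z conserved through the shared state
  drift <- conserved_totals(ts, list(all = c("X", "Y", "Z")))
  expect_lt(drift[["all"]], 1e-8)
  expect_gt(ts$Z[nrow(ts)], 0)
})

test_that("a port may not be the target of two identity mappings", {
  a <- toy("A")
  b <- submodel("B2", species = c(W = 1, V = 0))
  c2 <- submodel("C", species = c(T1 = 0))
  expect_error(
    compose(list(a, b, c2),
            list(port_mapping(c("A", "Y"), c("C", "T1")),
                 port_mapping(c("B2", "V"), c("C", "T1")))),
    "two identity mappings")
})

test_that("composition neutrality: standalone vs composite trajectories", {
  sc <- tsang_scenario()
  bystander <- submodel("bystander", species = c(B1 = 1, B2 = 0),
                        parameters = c(kb = 0.01),
                        reactions = list(reaction("r", c(B1 = 1), c(B2 = 1),
                                                  constants = c(k = "kb"))))
  comp <- compose(list(sc$model, bystander))
  spec <- simulation_spec(0, 3600, output_times = seq(0, 3600, 300))
  ts1 <- simulate_model(sc$model, spec)
  ts2 <- simulate_model(comp, spec)
  # absolute comparison: the extra bystander states change the integrator's
  # step-size history, so agreement is to integration accuracy, not bitwise
  for (sp in setdiff(names(ts1), "time_s")) {
    expect_lt(max(abs(ts2[[sp]] - ts1[[sp]])), 1e-6)
  }
})

test_that("flux coupling reads the source but never consumes it", {
  src <- submodel("src", species = c(S = 2))
  tgt <- submodel("tgt", species = c(Driver = 0, Out = 0),
                  parameters = c(k = 0.1),
                  reactions = list(reaction("r", c(Driver = 1), c(Out = 1),
                                            constants = c(k = "k"))))
  m <- compose(list(src, tgt),
               list(port_mapping(c("src", "S"), c("tgt", "Driver"),
                                 mode = "flux_coupling")))
  ts <- simulate_model(m, simulation_spec(0, 10, seq(0, 10, 1)))
  # the source state is read (Out grows at k*S) but not consumed
  expect_equal(ts$S, rep(2, nrow(ts)), tolerance = 1e-9)
  expect_equal(ts$Out[nrow(ts)], 2 * 0.1 * 10, tolerance = 1e-6)
})

test_that("flattening preserves reaction count", {
  sc <- rajagopalan_scenario()
  n_rx <- length(sc$model$reactions)
  expect_gt(n_rx, 10L)
  # every reaction id carries its sub-model namespace
  expect_true(all(grepl("\\.", names(sc$model$reactions))))
})
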