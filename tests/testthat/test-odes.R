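test_that("assembled ODEs agree with the hand-coded oracle on random states", {
  m <- as_composite(tsang_scenario()$model)
  rhs <- assemble_odes(m)
  for (st in random_fc_states(100)) {
    got <- rhs(0, st[names(m$species)], m$parameters)[[1L]]
    want <- fc_oracle_deriv(st, m$parameters)[names(m$species)]
    denom <- pmax(abs(want), 1)
    expect_lt(max(abs(got - unname(want)) / denom), 1e-12)
  }
})

test_that("compiled RHS agrees with the interpreted reference", {
  m <- as_composite(tsang_scenario()$model)
  ref <- assemble_odes(m)
  fast <- modkir:::compile_rhs(m, m$parameters)
  for (st in random_fc_states(25, seed = 7L)) {
    y <- unname(st[names(m$species)])
    a <- unname(ref(0, st[names(m$species)], m$parameters)[[1L]])
    b <- unname(fast(0, y, m$parameters)[[1L]])
    expect_equal(b, a, tolerance = 1e-12)
  }
})

test_that("compiled kernels agree with the interpreted reference", {
  for (model in list(build_dupont_ca(), build_nfat_cooling(),
                     rajagopalan_scenario()$model)) {
    m <- as_composite(model)
    ref <- assemble_odes(m)
    fast <- modkir:::compile_rhs(m, m$parameters)
    set.seed(11)
    for (i in 1:10) {
      st <- stats::setNames(stats::runif(length(m$species), 0, 2),
                            names(m$species))
      a <- unname(ref(0, st, m$parameters)[[1L]])
      b <- unname(fast(0, unname(st), m$parameters)[[1L]])
      expect_equal(b, a, tolerance = 1e-10)
    }
  }
})

test_that("clamped species keep a zero derivative", {
  m <- as_composite(tsang_scenario()$model)
  rhs <- assemble_odes(m)
  st <- random_fc_states(1)[[1L]]
  d <- rhs(0, st[names(m$species)], m$parameters)[[1L]]
  expect_equal(unname(d[match("Pi", names(m$species))]), 0)
})

test_that("all rate constants zero give a constant trajectory", {
  m <- build_fcepsilonri(fc_parameters("tsang",
    k_f1 = 0, k_f2 = 0, k_f3 = 0, k_f4 = 0, k_f5 = 0, k_f6 = 0, k_f7 = 0,
    k_r1 = 0, k_r4 = 0, k_r6 = 0))
  ts <- simulate_model(m, simulation_spec(0, 100, seq(0, 100, 10)))
  for (sp in setdiff(names(ts), "time_s")) {
    expect_equal(ts[[sp]], rep(ts[[sp]][1L], nrow(ts)))
  }
})

test_that("simulation output is non-negative within tolerance and finite", {
  sc <- tsang_scenario()
  ts <- simulate_model(sc$model, sc$spec)
  vals <- as.matrix(ts[, -1L])
  expect_true(all(is.finite(vals)))
  expect_gt(min(vals), -sc$spec$abs_tol)
})

test_that("halving rel_tol barely changes the final state", {
  sc <- tsang_scenario()
  spec1 <- simulation_spec(0, 3600, c(0, 3600), rel_tol = 1e-9, abs_tol = 1e-9)
  spec2 <- simulation_spec(0, 3600, c(0, 3600), rel_tol = 5e-10, abs_tol = 5e-10)
  f1 <- unlist(simulate_model(sc$model, spec1)[2L, -1L])
  f2 <- unlist(simulate_model(sc$model, spec2)[2L, -1L])
  # absolute agreement well above the tolerance floor but far below any
  # concentration of interest (largest pool is 6.5 uM)
  expect_lt(max(abs(f1 - f2)), 1e-6)
})

test_that("overrides hit parameters and species; unknown names error", {
  sc <- tsang_scenario()
  spec <- simulation_spec(0, 10, c(0, 10))
  ts <- simulate_model(sc$model, spec, c("FCepsilonRI/k_f7" = 0, Syk = 0))
  expect_equal(ts$pGrb2, c(0, 0))
  expect_error(simulate_model(sc$model, spec, c(bogus = 1)),
               "matches no parameter or species")
  expect_error(simulate_model(sc$model, spec, c(Syk = -1)), ">= 0")
})

test_that("simulation_spec validates its span", {
  expect_error(simulation_spec(10, 5), "exceed")
  expect_error(simulation_spec(0, 5, output_times = c(0, 9)), "within")
})

test_that("conserved_totals flags drift and rejects empty groups", {
  sc <- tsang_scenario()
  ts <- simulate_model(sc$model, sc$spec)
  expect_error(conserved_totals(ts, list(bad = character())), "empty")
  expect_error(conserved_totals(ts, list(bad = "nope")), "unknown species")
  # produced-only species: nonzero drift reported, no error
  d <- conserved_totals(ts, list(pg = "pGrb2"))
  expect_gt(d[["pg"]], 1)
})

test_that("integrator failure raises a diagnostic error", {
  # dX/dt = k X^2 blows up in finite time (t = 1)
  stiffbomb <- submodel("bomb", species = c(X = 1), parameters = c(k = 1),
                        reactions = list(reaction("r", c(X = 2), c(X = 3),
                                                  constants = c(k = "k"))))
  # lsoda emits step-size warnings on its way to the failure; only the
  # final diagnostic error is the contract under test
  suppressWarnings(expect_error(
    simulate_model(stiffbomb, simulation_spec(0, 100, c(0, 100))),
    "integrator failure|non-finite"))
})
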