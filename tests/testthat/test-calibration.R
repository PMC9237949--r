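test_that("objective_ssq matches its arithmetic contract", {
  expect_equal(objective_ssq(c(1, 2), c(1, 2)), 0)
  expect_equal(objective_ssq(c(1, 2), c(0, 0)), 5)
  expect_equal(objective_ssq(3, 0), 9)
  expect_error(objective_ssq(1:3, 1:2), "equal length")
  expect_error(objective_ssq(numeric(), numeric()), "at least one")
})

test_that("objective_ssq is invariant under row permutation", {
  set.seed(3)
  p <- runif(20)
  o <- runif(20)
  idx <- sample(20)
  expect_equal(objective_ssq(p, o), objective_ssq(p[idx], o[idx]))
})

test_that("exponent bounds map to linear bounds", {
  expect_identical(exponent_bounds_to_linear(-3, 2), c(1e-3, 1e2))
  expect_identical(exponent_bounds_to_linear(-10, -6), c(1e-10, 1e-6))
  # degenerate narrow band is fine
  expect_silent(exponent_bounds_to_linear(0, 1e-9))
  expect_error(exponent_bounds_to_linear(2, -3), "below")
})

test_that("saltelli_design row count is exactly N(2D+2)", {
  for (N in c(1L, 2L, 7L)) {
    for (D in c(1L, 3L, 5L)) {
      b <- stats::setNames(rep(list(c(-3, 2)), D), paste0("p", 1:D))
      d <- saltelli_design(N, b, seed = 5L)
      expect_identical(nrow(d), N * (2L * D + 2L))
      expect_identical(ncol(d), D)
    }
  }
  expect_identical(nrow(saltelli_design(2, list(a = c(-3, 2), b = c(0, 1),
                                                c = c(-1, 1)))), 16L)
})

test_that("saltelli_design is deterministic, bounded, and seed-sensitive", {
  b <- list(x = c(-3, 2), y = c(-1, 1))
  d1 <- saltelli_design(10, b, seed = 99L)
  d2 <- saltelli_design(10, b, seed = 99L)
  expect_identical(d1, d2)
  d3 <- saltelli_design(10, b, seed = 100L)
  expect_false(identical(d1$x, d3$x))
  expect_true(all(d1$x >= 1e-3 & d1$x <= 1e2))
  expect_true(all(d1$y >= 1e-1 & d1$y <= 1e1))
  # sampling is uniform in exponent space: exponents span the box
  ex <- attr(d1, "exponents")
  expect_true(all(ex[, 1] >= -3 & ex[, 1] <= 2))
})

test_that("saltelli_design cross-structure holds", {
  b <- list(x = c(0, 1), y = c(0, 1))
  N <- 4L
  d <- attr(saltelli_design(N, b, seed = 2L), "exponents")
  A <- d[1:N, ]
  B <- d[(N + 1):(2 * N), ]
  AB1 <- d[(2 * N + 1):(3 * N), ]
  expect_equal(AB1[, 1], B[, 1])
  expect_equal(AB1[, 2], A[, 2])
})

test_that("saltelli_design validates input", {
  expect_error(saltelli_design(0, list(a = c(0, 1))), "N")
  expect_error(saltelli_design(2, list(a = c(2, -3))), "invalid bounds")
  expect_error(saltelli_design(2, list()), "at least one")
})

test_that("dataset constructor validates rows", {
  expect_error(dataset("x", c(1, 1), c(0, 0)), "strictly increasing")
  expect_error(dataset("x", c(1, 2), c(0, NA)), "finite")
  expect_error(dataset("x", 1:3, 1:2), "length mismatch")
  d <- dataset("x", c(1, 2), c(0.1, 0.2), provenance = "synthetic")
  expect_s3_class(d, "modkir_dataset")
})

test_that("fit_spec rejects overlapping free/fixed sets", {
  d <- dataset("pGrb2", 1, 0.5)
  expect_error(fit_spec(list("a" = c(-3, 2)), list(d), fixed = c(a = 1)),
               "disjoint")
})

test_that("a sample at the generating parameters scores ~0 and refines to it", {
  d <- tsang_grb2_dataset()
  sc <- tsang_scenario()
  truth <- unname(fc_parameters("tsang")[["k_f7"]])
  # one free parameter; narrow bounds centred on the truth so the design
  # contains near-optimal starts
  spec <- fit_spec(list("FCepsilonRI/k_f7" = c(log10(truth) - 0.5,
                                               log10(truth) + 0.5)),
                   datasets = list(d), N = 4L, top_k = 2L)
  fits <- multistart_fit(sc$model, spec, seed = 11L)
  expect_gt(length(fits), 0L)
  best <- fits[[1L]]
  expect_lt(best$ssq, 1e-8)
  expect_lt(abs(best$estimates[[1L]] - truth) / truth, 0.01)
})

test_that("refinement never increases ssq relative to its start", {
  d <- tsang_grb2_dataset()
  sc <- tsang_scenario()
  spec <- fit_spec(list("FCepsilonRI/k_f6" = c(-3, 2),
                        "FCepsilonRI/k_f7" = c(-3, 2)),
                   datasets = list(d), N = 2L, top_k = 3L)
  fits <- multistart_fit(sc$model, spec, seed = 4L)
  samples <- attr(fits, "samples")
  for (f in fits) {
    start_ssq <- samples$ssq[f$start_rank]
    expect_lte(f$ssq, start_ssq * (1 + 1e-6))
  }
  # results sorted by final ssq
  ssqs <- vapply(fits, `[[`, 0, "ssq")
  expect_true(!is.unsorted(ssqs))
})

test_that("estimates stay within their exponent bounds", {
  d <- tsang_grb2_dataset()
  sc <- tsang_scenario()
  spec <- fit_spec(list("FCepsilonRI/k_f6" = c(-2, 1)),
                   datasets = list(d), N = 2L, top_k = 2L)
  fits <- multistart_fit(sc$model, spec, seed = 8L)
  for (f in fits) {
    expect_true(all(f$estimates >= 1e-2 & f$estimates <= 1e1))
  }
})
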