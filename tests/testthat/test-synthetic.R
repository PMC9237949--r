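test_that("noiseless synthetic data closes the loop: ssq against truth is 0", {
  sc <- tsang_scenario()
  times <- c(300, 900, 1800, 3600)
  d <- generate_synthetic_timecourse(sc$model, observables = "pGrb2",
                                     times = times)$pGrb2
  spec <- simulation_spec(0, 3600, output_times = c(0, times))
  ts <- simulate_model(sc$model, spec)
  expect_equal(objective_ssq(ts$pGrb2[match(times, ts$time_s)], d$values), 0)
  expect_equal(d$provenance, "synthetic")
  expect_null(d$sigma)
})

test_that("same seed reproduces the draw exactly; different seed differs", {
  sc <- tsang_scenario()
  nm <- noise_model(0.05)
  times <- seq(100, 3600, by = 500)
  d1 <- generate_synthetic_timecourse(sc$model, observables = "pGrb2",
                                      times = times, noise = nm, seed = 7L)
  d2 <- generate_synthetic_timecourse(sc$model, observables = "pGrb2",
                                      times = times, noise = nm, seed = 7L)
  d3 <- generate_synthetic_timecourse(sc$model, observables = "pGrb2",
                                      times = times, noise = nm, seed = 8L)
  expect_identical(d1$pGrb2$values, d2$pGrb2$values)
  expect_false(identical(d1$pGrb2$values, d3$pGrb2$values))
  expect_equal(attr(d1$pGrb2, "seed"), 7L)
})

test_that("generation does not disturb the global RNG state", {
  set.seed(123)
  before <- .Random.seed
  generate_synthetic_timecourse(tsang_scenario()$model,
                                observables = "pGrb2",
                                times = c(600, 3600),
                                noise = noise_model(0.01), seed = 2L)
  expect_identical(.Random.seed, before)
})

test_that("additive noise has the declared dispersion", {
  # a clamped-everything model is constant, so residuals are pure noise
  m <- submodel("const", species = c(X = 1), clamped = "X", ports = "X")
  sigma <- 0.05
  times <- seq_len(1000)
  d <- generate_synthetic_timecourse(m, observables = "X", times = times,
                                     noise = noise_model(sigma),
                                     seed = 5L)$X
  res <- d$values - 1
  expect_lt(abs(stats::sd(res) - sigma) / sigma, 0.1)
  expect_lt(abs(mean(res)), 3 * sigma / sqrt(1000))
  expect_equal(d$sigma, rep(sigma, 1000))
})

test_that("relative noise scales sigma with the clean value", {
  m <- submodel("const", species = c(X = 4), clamped = "X", ports = "X")
  d <- generate_synthetic_timecourse(m, observables = "X", times = 1:500,
                                     noise = noise_model(0.05,
                                                         relative = TRUE),
                                     seed = 9L)$X
  expect_equal(d$sigma, rep(0.05 * 4, 500))
  expect_lt(abs(stats::sd(d$values - 4) - 0.2) / 0.2, 0.15)
})

test_that("the provenance hash tracks the generating parameters", {
  sc <- tsang_scenario()
  t1 <- c(600, 3600)
  h0 <- attr(generate_synthetic_timecourse(sc$model, observables = "pGrb2",
                                           times = t1)$pGrb2, "params_hash")
  h1 <- attr(generate_synthetic_timecourse(
    sc$model, overrides = c("FCepsilonRI/k_f2" = 0.01),
    observables = "pGrb2", times = t1)$pGrb2, "params_hash")
  h2 <- attr(generate_synthetic_timecourse(
    sc$model, overrides = c("FCepsilonRI/k_f2" = 0.01),
    observables = "pGrb2", times = t1)$pGrb2, "params_hash")
  expect_false(identical(h0, h1))
  expect_identical(h1, h2)
  expect_equal(h0, "none")
  # order of the override vector does not matter
  ov <- c("FCepsilonRI/k_f2" = 0.01, "FCepsilonRI/k_f4" = 2)
  expect_identical(modkir:::params_hash(ov), modkir:::params_hash(rev(ov)))
})

test_that("per-observable substreams keep draws stable when adding one", {
  sc <- tsang_scenario()
  nm <- noise_model(0.02)
  t1 <- c(600, 1800, 3600)
  a <- generate_synthetic_timecourse(sc$model, observables = "pGrb2",
                                     times = t1, noise = nm, seed = 3L)
  b <- generate_synthetic_timecourse(sc$model,
                                     observables = c("pGrb2", "pSyk"),
                                     times = t1, noise = nm, seed = 3L)
  expect_identical(a$pGrb2$values, b$pGrb2$values)
})

test_that("input validation rejects bad times and observables", {
  sc <- tsang_scenario()
  expect_error(generate_synthetic_timecourse(sc$model, observables = "pGrb2",
                                             times = c(0, 10)),
               "strictly increasing")
  expect_error(generate_synthetic_timecourse(sc$model, observables = "nope",
                                             times = c(10, 20)),
               "unknown observables")
  expect_error(noise_model(-1), ">= 0")
})
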