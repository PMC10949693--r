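# Small spectral system used for the GA mechanics tests: 20 wavelengths so
# chromosome evaluation is cheap.
ga_small <- local({
  grid <- wavelength_grid(240, 259, 1)
  pures <- list(
    pure_component_model("A", list(gaussian_band(246, 3, 0.02))),
    pure_component_model("B", list(gaussian_band(253, 3, 0.02))))
  d <- brereton_design(analytes = c("A", "B"))
  sp <- simulate_mixtures(d, pures, grid, sigma_abs = 0.002, seed = 17)
  list(spectra = sp, C = d$concentrations)
})

test_that("GA configs validate their ranges and expose the reference values", {
  expect_error(ga_config(population_size = 3), "population_size")
  expect_error(ga_config(mutation_rate = 0), "mutation_rate")
  expect_error(ga_config(init_fraction = 0), "init_fraction")
  expect_error(ga_config(convergence_fraction = 1.5), "convergence")
  ref1 <- ga_config_reference(1)
  expect_equal(ref1$population_size, 40L)
  expect_equal(ref1$max_generations, 65L)
  ref2 <- ga_config_reference(2)
  expect_equal(ref2$population_size, 36L)
  expect_equal(ref2$max_generations, 52L)
  for (ref in list(ref1, ref2)) {
    expect_equal(ref$mutation_rate, 0.005)
    expect_equal(ref$init_fraction, 0.15)
    expect_equal(ref$window_width, 2L)
    expect_equal(ref$convergence_fraction, 0.8)
    expect_equal(ref$crossover, "double")
    expect_equal(ref$max_latent, 3L)
    expect_equal(ref$cv_subsets, 5L)
    expect_equal(ref$cv_iterations, 2L)
  }
})

test_that("the reference configuration runs and is echoed in the result", {
  cfg <- ga_config_reference(1)
  res <- run_ga(ga_small$spectra, ga_small$C, cfg, seed = 4)
  expect_identical(res$config, cfg)
  expect_lte(res$generations_run, cfg$max_generations)
  expect_gte(sum(res$selected_mask), 1L)
})

test_that("a fixed seed reproduces the selected mask exactly", {
  cfg <- ga_config(population_size = 8, max_generations = 6)
  a <- run_ga(ga_small$spectra, ga_small$C, cfg, seed = 42)
  b <- run_ga(ga_small$spectra, ga_small$C, cfg, seed = 42)
  expect_identical(a$selected_mask, b$selected_mask)
  expect_identical(a$fitness_trace, b$fitness_trace)
})

test_that("the best-fitness trace never rises and the reduction identity holds", {
  cfg <- ga_config(population_size = 10, max_generations = 10)
  for (seed in c(1, 2, 3)) {
    res <- run_ga(ga_small$spectra, ga_small$C, cfg, seed = seed)
    expect_true(all(diff(res$fitness_trace$best) <= 0))
    expect_equal(res$reduction_fraction,
                 1 - sum(res$selected_mask) / length(res$selected_mask))
    expect_gte(res$reduction_fraction, 0)
    expect_lt(res$reduction_fraction, 1)
  }
})

test_that("a converged initial population is a fixed point", {
  # init_fraction 1 makes every initial chromosome all-on, so the run stops
  # in generation 1 with the all-true mask
  cfg <- ga_config(population_size = 8, max_generations = 20,
                   init_fraction = 1)
  res <- run_ga(ga_small$spectra, ga_small$C, cfg, seed = 9)
  expect_equal(res$generations_run, 1L)
  expect_true(all(res$selected_mask))
})

test_that("all-off chromosomes are repaired to one active window", {
  set.seed(1)
  ch <- duospec:::repair_chromosome(rep(FALSE, 12))
  expect_equal(sum(ch), 1L)
  on <- rep(c(TRUE, FALSE), 6)
  expect_identical(duospec:::repair_chromosome(on), on)
})

test_that("an all-true mask makes GA-PLS coincide with plain PLS", {
  cfg <- ga_config(population_size = 8, max_generations = 5,
                   init_fraction = 1, max_latent = 3)
  gam <- fit_ga_pls(ga_small$spectra, ga_small$C, cfg, seed = 3)
  expect_true(all(gam$ga$selected_mask))
  plain <- fit_pls(ga_small$spectra, ga_small$C, n_latent = gam$n_latent)
  expect_equal(unname(gam$coefficients), unname(plain$coefficients),
               tolerance = 1e-12)
  expect_equal(predict(gam, ga_small$spectra)[-1],
               predict(plain, ga_small$spectra)[-1], tolerance = 1e-12)
})

test_that("GA-PLS predicts through the non-contiguous mask on wider grids", {
  sc <- default_scenario()
  d <- brereton_design(analytes = sc$analytes)
  cal <- simulate_scenario(d, sc, seed = 21)
  cfg <- ga_config(population_size = 10, max_generations = 6)
  gam <- fit_ga_pls(cal$spectra, cal$concentrations, cfg, seed = 8)
  val <- lhs_design(seed = 31, analytes = sc$analytes)
  full <- simulate_mixtures(val, sc$pures, sc$grid, sigma_abs = 0.002,
                            seed = 22)            # untrimmed 200-400 grid
  trimmed <- trim_spectra(full, 210, 400)
  expect_equal(predict(gam, full), predict(gam, trimmed))
  pred <- predict(gam, trimmed)
  truth <- as.matrix(val$concentrations[sc$analytes])
  expect_lt(max(abs(as.matrix(pred[sc$analytes]) - truth)), 1)
})
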