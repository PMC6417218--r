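test_that("noiseless events reduce to the generative constants", {
  np <- noiseless_flow_noise(50)
  s <- simulate_flow_sample(80, 80, np, seed = 1)
  expect_true(all(s$events$green == s$events$red))
  s2 <- simulate_flow_sample(50, 100, np, seed = 1)
  m <- sample_means(s2)
  expect_equal(unname(m[["mean_green"]] / m[["mean_red"]]), 0.5,
               tolerance = 1e-12)
  expect_equal(unique(s2$events$green), 50)
  expect_equal(unique(s2$events$red), 100)
})

test_that("the shared copy-number factor cancels from the ratio of means", {
  np <- flow_noise_params(copy_number_cv = 0.5, autofluor_mean = 0,
                          spillover_green_to_red = 0, channel_noise_cv = 0,
                          n_events = 20000)
  s <- simulate_flow_sample(38, 100, np, seed = 42)
  m <- sample_means(s)
  expect_equal(unname(m[["mean_green"]] / m[["mean_red"]]), 0.38,
               tolerance = 0.01)
})

test_that("dose modulation scales the green channel linearly", {
  np <- noiseless_flow_noise(10)
  dose <- dose_response_params(slope = 0.9, baseline = 0.1)
  ratios <- vapply(dose$conc_grid, function(conc) {
    s <- simulate_flow_sample(200, 500, np, inducer_conc = conc,
                              dose = dose, seed = 3)
    m <- sample_means(s)
    unname(m[["mean_green"]] / m[["mean_red"]])
  }, numeric(1))
  expect_equal(ratios, (0.1 + 0.9 * dose$conc_grid) * 200 / 500,
               tolerance = 1e-12)
  expect_true(all(diff(ratios) > 0))

  # slope 0: the response is flat across the grid
  flat <- dose_response_params(slope = 0, baseline = 0.5)
  flat_ratios <- vapply(flat$conc_grid, function(conc) {
    s <- simulate_flow_sample(200, 500, np, inducer_conc = conc,
                              dose = flat, seed = 3)
    m <- sample_means(s)
    unname(m[["mean_green"]] / m[["mean_red"]])
  }, numeric(1))
  expect_equal(flat_ratios, rep(0.5 * 200 / 500, 6), tolerance = 1e-12)
})

test_that("a dose series emits one deterministic sample per concentration x replicate", {
  dose <- dose_response_params()
  np <- flow_noise_params(n_events = 200)
  ser <- simulate_dose_series(100, dose, np, replicates = 3, seed = 5)
  expect_length(ser, 18L)
  meta <- data.frame(conc = vapply(ser, `[[`, numeric(1), "inducer_conc"),
                     rep = vapply(ser, `[[`, integer(1), "replicate"))
  expect_equal(sort(unique(meta$conc)), dose$conc_grid)
  expect_true(all(table(meta$conc) == 3L))
  ser2 <- simulate_dose_series(100, dose, np, replicates = 3, seed = 5)
  expect_identical(lapply(ser, `[[`, "events"),
                   lapply(ser2, `[[`, "events"))
  # flat response: red means stay put across concentrations
  reds <- vapply(ser, function(s) sample_means(s)[["mean_red"]], numeric(1))
  expect_lt(diff(range(reds)) / mean(reds), 0.2)
})

test_that("flow samples validate their arguments", {
  expect_error(simulate_flow_sample(10, 0, noiseless_flow_noise()),
               class = "invalid_argument")
  expect_error(simulate_flow_sample(-1, 10, noiseless_flow_noise()),
               class = "invalid_argument")
  expect_error(flow_noise_params(spillover_green_to_red = 1),
               class = "invalid_argument")
  expect_error(flow_noise_params(n_events = 0), class = "invalid_argument")
  expect_error(dose_response_params(conc_grid = c(0.4, 0.2)),
               class = "invalid_argument")
  expect_error(dose_response_params(conc_grid = numeric()),
               class = "invalid_argument")
  expect_error(flow_sample(data.frame(green = -1, red = 2), "s", "c"),
               class = "invalid_argument")
})

test_that("flow samples round-trip through CSV event tables", {
  np <- flow_noise_params(n_events = 100)
  samples <- list(
    simulate_flow_sample(50, 100, np, seed = 1, sample_id = "a",
                         construct_id = "X", replicate = 1),
    simulate_flow_sample(50, 100, np, seed = 2, sample_id = "b",
                         construct_id = "X", replicate = 2,
                         inducer_conc = 0.4)
  )
  dir <- withr::local_tempdir()
  write_flow_samples(samples, dir)
  back <- read_flow_samples(dir)
  expect_length(back, 2L)
  expect_equal(back[[2]]$inducer_conc, 0.4)
  expect_equal(back[[1]]$events$green, samples[[1]]$events$green,
               tolerance = 1e-9)
})
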