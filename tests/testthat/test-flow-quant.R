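mk_sample <- function(green, red, id = "s1", construct = "c1", rep = 1L,
                      conc = 0) {
  flow_sample(data.frame(green = green, red = red), id, construct, rep, conc)
}

test_that("compensation solves the two-channel linear system", {
  s <- mk_sample(100, 60)
  out <- compensate(s, spillover_matrix(green_to_red = 0.1))
  expect_equal(out$events$green, 100)
  expect_equal(out$events$red, 50)
  # hand oracle for a full matrix: observed = S %*% true
  S <- spillover_matrix(green_to_red = 0.2, red_to_green = 0.05)
  true <- c(green = 80, red = 40)
  obs <- as.vector(unclass(S) %*% true)
  rec <- compensate(mk_sample(obs[1], obs[2]), S)
  expect_equal(rec$events$green, 80, tolerance = 1e-12)
  expect_equal(rec$events$red, 40, tolerance = 1e-12)
  # identity leaves events untouched bit-for-bit
  id <- compensate(s, spillover_matrix())
  expect_identical(id$events, s$events)
  expect_equal(id$n_clamped, 0L)
})

test_that("compensation clamps negative corrections and counts them", {
  s <- mk_sample(c(100, 0), c(5, 10))
  out <- compensate(s, spillover_matrix(green_to_red = 0.1))
  expect_equal(out$events$red, c(0, 10))
  expect_equal(out$n_clamped, 1L)
})

test_that("QC boundary is inclusive at exactly the event floor", {
  pass <- mk_sample(rep(1, 20000), rep(1, 20000))
  expect_true(qc_events(pass)$qc_pass)
  fail <- mk_sample(rep(1, 19999), rep(1, 19999))
  expect_message(fail <- qc_events(fail), "flagged")
  expect_false(fail$qc_pass)
  expect_true(qc_events(fail, min_events = 0)$qc_pass)
})

test_that("channel means are plain arithmetic means", {
  s <- mk_sample(c(1, 3), c(2, 4))
  expect_equal(unname(sample_means(s)), c(2, 3))
  one <- mk_sample(7, 9)
  expect_equal(unname(sample_means(one)), c(7, 9))
})

test_that("the dual ratio averages replicate means before dividing", {
  reps <- list(mk_sample(rep(1000, 5), rep(2000, 5), "a", "X", 1),
               mk_sample(rep(1010, 5), rep(2020, 5), "b", "X", 2),
               mk_sample(rep(990, 5), rep(1980, 5), "c", "X", 3))
  m <- dual_ratio(reps)
  expect_equal(m$ratio, 0.5, tolerance = 1e-12)
  expect_equal(m$n_replicates, 3L)
  expect_equal(m$n_events_total, 15L)
  expect_equal(m$sd, 0, tolerance = 1e-12) # per-replicate ratios all 0.5
  expect_warning(single <- dual_ratio(reps[[1]]), "single replicate")
  expect_equal(single$sd, 0)
  bad <- list(reps[[1]], mk_sample(1, 1, "d", "Y", 1))
  expect_error(dual_ratio(bad), class = "invalid_argument")
})

test_that("scaling the green channel scales the ratio linearly", {
  np <- flow_noise_params(copy_number_cv = 0.3, autofluor_mean = 0,
                          spillover_green_to_red = 0,
                          channel_noise_cv = 0.1, n_events = 5000)
  base <- simulate_flow_sample(50, 100, np, seed = 8)
  m0 <- suppressWarnings(dual_ratio(list(base)))
  k <- 3.7
  scaled <- base
  scaled$events$green <- scaled$events$green * k
  mk <- suppressWarnings(dual_ratio(list(scaled)))
  expect_equal(mk$ratio, m0$ratio * k, tolerance = 1e-12)
})

test_that("relative RBS strength is the induced minus uninduced ratio", {
  ind <- suppressWarnings(dual_ratio(list(
    mk_sample(rep(30, 3), rep(100, 3), "i", "rbs1", 1, conc = 0.8))))
  unind <- suppressWarnings(dual_ratio(list(
    mk_sample(rep(5, 3), rep(100, 3), "u", "rbs1", 1, conc = 0))))
  expect_equal(rbs_relative_strength(ind, unind), 0.25, tolerance = 1e-12)

  self <- ind
  self$inducer_conc <- 0
  expect_equal(rbs_relative_strength(ind, self), 0)

  other <- suppressWarnings(dual_ratio(list(
    mk_sample(5, 100, "u", "rbs2", 1, conc = 0))))
  expect_error(rbs_relative_strength(ind, other),
               class = "invalid_argument")
  expect_error(rbs_relative_strength(ind, unind2 <- ind),
               class = "invalid_argument") # uninduced not at conc 0
})

test_that("measure_constructs groups by construct and concentration", {
  np <- flow_noise_params(n_events = 500)
  samples <- c(
    lapply(1:2, function(r) simulate_flow_sample(
      50, 100, np, seed = r, sample_id = paste0("a", r),
      construct_id = "P1", replicate = r)),
    lapply(1:2, function(r) simulate_flow_sample(
      150, 100, np, seed = 10 + r, sample_id = paste0("b", r),
      construct_id = "P2", replicate = r))
  )
  out <- measure_constructs(samples)
  expect_equal(nrow(out), 2L)
  expect_equal(out$construct_id, c("P1", "P2"))
  expect_true(out$ratio[2] > out$ratio[1])
  expect_equal(out$n_replicates, c(2L, 2L))
})
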