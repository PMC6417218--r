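#' Flow-event noise parameters
#'
#' Bundles the nuisance components of the two-channel event model:
#' a per-cell plasmid copy-number factor (lognormal, mean 1, coefficient of
#' variation `copy_number_cv`) shared by both channels; independent
#' multiplicative channel noise (`channel_noise_cv`); additive
#' autofluorescence background per channel (exponential with the given
#' means); and linear spectral spillover of the green fluorophore into the
#' red detector.
#'
#' @param copy_number_cv lognormal CV of per-cell copies (>= 0).
#' @param autofluor_mean length-2 (green, red) or scalar mean
#'   autofluorescence, arbitrary units (>= 0).
#' @param spillover_green_to_red fraction of green signal read in the red
#'   channel, in \[0, 1).
#' @param channel_noise_cv per-channel multiplicative noise CV (>= 0).
#' @param n_events events per sample (> 0); the default matches the
#'   common quality floor of 20,000 analyzed events.
#' @return A `"flow_noise_params"` list.
#' @export
flow_noise_params <- function(copy_number_cv = 0.25,
                              autofluor_mean = c(green = 2, red = 2),
                              spillover_green_to_red = 0.02,
                              channel_noise_cv = 0.15,
                              n_events = 20000L) {
  if (length(autofluor_mean) == 1L)
    autofluor_mean <- c(green = autofluor_mean, red = autofluor_mean)
  stopifnot(length(autofluor_mean) == 2L)
  names(autofluor_mean) <- c("green", "red")
  if (copy_number_cv < 0 || channel_noise_cv < 0 || any(autofluor_mean < 0))
    stop_dualprom("noise magnitudes must be >= 0", "invalid_argument")
  if (spillover_green_to_red < 0 || spillover_green_to_red >= 1)
    stop_dualprom("spillover_green_to_red must lie in [0, 1)",
                  "invalid_argument")
  if (n_events < 1)
    stop_dualprom("n_events must be > 0", "invalid_argument")
  structure(list(copy_number_cv = copy_number_cv,
                 autofluor_mean = autofluor_mean,
                 spillover_green_to_red = spillover_green_to_red,
                 channel_noise_cv = channel_noise_cv,
                 n_events = as.integer(n_events)),
            class = "flow_noise_params")
}

#' Inducer dose-response parameters
#'
#' Linear response of the test promoter to inducer concentration over the
#' window in which the response is linear: relative activity
#' `g(conc) = baseline + slope * conc`. The default grid is the standard
#' tetracycline titration 0-1.0 ug/mL in 0.2 steps.
#'
#' @param conc_grid strictly increasing, non-negative concentrations (ug/mL).
#' @param slope activity gain per ug/mL.
#' @param baseline activity at zero inducer (>= 0).
#' @return A `"dose_response_params"` list.
#' @export
dose_response_params <- function(conc_grid = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
                                 slope = 1, baseline = 0.1) {
  if (length(conc_grid) == 0L)
    stop_dualprom("conc_grid must be non-empty", "invalid_argument")
  if (any(conc_grid < 0) || is.unsorted(conc_grid, strictly = TRUE))
    stop_dualprom("conc_grid must be strictly increasing and non-negative",
                  "invalid_argument")
  if (baseline < 0)
    stop_dualprom("baseline must be >= 0", "invalid_argument")
  structure(list(conc_grid = conc_grid, slope = slope, baseline = baseline),
            class = "dose_response_params")
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_cv1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one two-channel flow-cytometry sample
#'
#' Event model: each cell carries a copy-number factor `C` (lognormal, mean
#' 1) common to both reporters;
#' `green = C * g(conc) * green_strength * (1 + e) + autofluor_g` and
#' `red   = C * red_strength * (1 + e') + autofluor_r + s * green`,
#' where `e`, `e'` are independent mean-zero Gaussian channel noises, the
#' autofluorescence terms are exponential, and `s` is the green-to-red
#' spillover fraction. `g(conc) = baseline + slope * conc` when `dose` is
#' supplied, 1 otherwise. Negative values are clamped to 0. Identical
#' arguments and seed give byte-identical events.
#'
#' Because `C` multiplies both channels, it cancels from the ratio of channel
#' means — the property the dual-reporter readout relies on.
#'
#' @param green_strength mean green signal per unit copy at `g = 1` (>= 0).
#' @param red_strength mean red signal per unit copy (> 0).
#' @param noise a [flow_noise_params()].
#' @param inducer_conc inducer concentration (ug/mL).
#' @param dose optional [dose_response_params()] modulating the green channel.
#' @param seed integer RNG seed.
#' @param sample_id,construct_id,replicate metadata carried on the sample.
#' @return A `"flow_sample"`: list with metadata fields and an `events`
#'   data.frame (`green`, `red`).
#' @examples
#' s <- simulate_flow_sample(50, 100, flow_noise_params(n_events = 1000),
#'                           seed = 1)
#' sample_means(s)
#' @export
simulate_flow_sample <- function(green_strength, red_strength,
                                 noise = flow_noise_params(),
                                 inducer_conc = 0, dose = NULL, seed = 1L,
                                 sample_id = "sample1",
                                 construct_id = "construct1",
                                 replicate = 1L) {
  if (green_strength < 0)
    stop_dualprom("green_strength must be >= 0", "invalid_argument")
  if (red_strength <= 0)
    stop_dualprom("red_strength must be > 0", "invalid_argument")
  stopifnot(inherits(noise, "flow_noise_params"))
  g <- if (is.null(dose)) 1 else {
    stopifnot(inherits(dose, "dose_response_params"))
    dose$baseline + dose$slope * inducer_conc
  }
  n <- noise$n_events
  with_seed(seed, {
    copies <- rlnorm_cv1(n, noise$copy_number_cv)
    eg <- if (noise$channel_noise_cv > 0)
      rnorm(n, 0, noise$channel_noise_cv) else numeric(n)
    er <- if (noise$channel_noise_cv > 0)
      rnorm(n, 0, noise$channel_noise_cv) else numeric(n)
    af_g <- if (noise$autofluor_mean[["green"]] > 0)
      rexp(n, 1 / noise$autofluor_mean[["green"]]) else numeric(n)
    af_r <- if (noise$autofluor_mean[["red"]] > 0)
      rexp(n, 1 / noise$autofluor_mean[["red"]]) else numeric(n)
    green <- copies * g * green_strength * (1 + eg) + af_g
    red <- copies * red_strength * (1 + er) + af_r +
      noise$spillover_green_to_red * green
    flow_sample(
      events = data.frame(green = pmax(green, 0), red = pmax(red, 0)),
      sample_id = sample_id, construct_id = construct_id,
      replicate = replicate, inducer_conc = inducer_conc
    )
  })
}

#' Construct a flow sample from an event table
#'
#' @param events data.frame with non-negative, finite `green` and `red`
#'   columns, one row per event.
#' @param sample_id,construct_id,replicate,inducer_conc sample metadata.
#' @return A `"flow_sample"` object.
#' @export
flow_sample <- function(events, sample_id, construct_id, replicate = 1L,
                        inducer_conc = 0) {
  if (!is.data.frame(events) || !all(c("green", "red") %in% names(events)))
    stop_dualprom("events needs 'green' and 'red' columns",
                  "invalid_argument")
  if (!all(is.finite(events$green)) || !all(is.finite(events$red)) ||
      any(events$green < 0) || any(events$red < 0))
    stop_dualprom("channel values must be finite and non-negative",
                  "invalid_argument")
  if (inducer_conc < 0)
    stop_dualprom("inducer_conc must be >= 0", "invalid_argument")
  structure(list(sample_id = sample_id, construct_id = construct_id,
                 replicate = as.integer(replicate),
                 inducer_conc = inducer_conc,
                 n_events = nrow(events),
                 events = events[, c("green", "red")]),
            class = "flow_sample")
}

#' @export
print.flow_sample <- function(x, ...) {
  cat(sprintf(
    "<flow_sample> %s (construct %s, rep %d, %g ug/mL): %d events\n",
    x$sample_id, x$construct_id, x$replicate, x$inducer_conc, x$n_events))
  invisible(x)
}

#' Simulate an inducer titration series
#'
#' One sample per (concentration, replicate) pair for a single inducible
#' construct. The red calibration channel does not depend on the inducer;
#' only the green test channel scales with `g(conc)`.
#'
#' @param strength_scale green signal per unit copy at `g = 1`.
#' @param dose a [dose_response_params()] giving the grid and response line.
#' @param noise a [flow_noise_params()].
#' @param replicates replicate samples per concentration (>= 1).
#' @param red_strength red calibration signal per unit copy.
#' @param seed integer RNG seed; each sample uses an independent substream.
#' @param construct_id metadata label.
#' @return List of `"flow_sample"` objects, length
#'   `length(conc_grid) * replicates`.
#' @export
simulate_dose_series <- function(strength_scale, dose = dose_response_params(),
                                 noise = flow_noise_params(), replicates = 3L,
                                 red_strength = 100, seed = 1L,
                                 construct_id = "Ptet") {
  stopifnot(inherits(dose, "dose_response_params"))
  if (replicates < 1)
    stop_dualprom("replicates must be >= 1", "invalid_argument")
  grid <- expand.grid(replicate = seq_len(replicates),
                      conc = dose$conc_grid, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    simulate_flow_sample(
      green_strength = strength_scale, red_strength = red_strength,
      noise = noise, inducer_conc = grid$conc[i], dose = dose,
      seed = (as.integer(seed) %% 200000L) * 10000L + i,
      sample_id = sprintf("%s_c%0.1f_r%d", construct_id, grid$conc[i],
                          grid$replicate[i]),
      construct_id = construct_id, replicate = grid$replicate[i]
    )
  })
}

#' Write / read flow samples as CSV event tables plus a metadata sheet
#'
#' Each sample becomes `<sample_id>.csv` with columns `event_index`, `green`,
#' `red`; `samples.tsv` records `sample_id`, `construct_id`, `replicate`,
#' `inducer_conc`, `events_file`.
#'
#' @param samples list of `"flow_sample"` objects.
#' @param dir output directory.
#' @return Invisibly, the metadata sheet path.
#' @export
write_flow_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(samples, function(s) {
    f <- paste0(s$sample_id, ".csv")
    write.csv(data.frame(event_index = seq_len(s$n_events), s$events),
              file.path(dir, f), row.names = FALSE, quote = FALSE)
    data.frame(sample_id = s$sample_id, construct_id = s$construct_id,
               replicate = s$replicate, inducer_conc = s$inducer_conc,
               events_file = f, stringsAsFactors = FALSE)
  }))
  path <- file.path(dir, "samples.tsv")
  write_tsv(meta, path)
  invisible(path)
}

#' @rdname write_flow_samples
#' @export
read_flow_samples <- function(dir) {
  meta <- read_tsv(file.path(dir, "samples.tsv"))
  lapply(seq_len(nrow(meta)), function(i) {
    ev <- read.csv(file.path(dir, meta$events_file[i]))
    flow_sample(ev, sample_id = meta$sample_id[i],
                construct_id = meta$construct_id[i],
                replicate = meta$replicate[i],
                inducer_conc = meta$inducer_conc[i])
  })
}
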