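#' Two-channel spillover matrix
#'
#' Entry (i, j) is the fraction of fluorophore j's true signal read in
#' channel i; the diagonal is 1. Channel/fluorophore order is (green, red).
#'
#' @param green_to_red fraction of green signal bleeding into the red
#'   detector, in \[0, 1).
#' @param red_to_green fraction of red signal bleeding into the green
#'   detector, in \[0, 1).
#' @return A 2x2 `"spillover_matrix"`.
#' @export
spillover_matrix <- function(green_to_red = 0, red_to_green = 0) {
  if (green_to_red < 0 || green_to_red >= 1 ||
      red_to_green < 0 || red_to_green >= 1)
    stop_dualprom("off-diagonal spillover fractions must lie in [0, 1)",
                  "invalid_argument")
  m <- matrix(c(1, green_to_red, red_to_green, 1), nrow = 2,
              dimnames = list(c("green", "red"), c("green", "red")))
  structure(m, class = c("spillover_matrix", "matrix", "array"))
}

#' Compensate spectral spillover in a flow sample
#'
#' Inverts the spillover matrix and applies it to every event's
#' (green, red) vector, recovering the per-fluorophore signals from the
#' detector readings. The identity matrix returns the sample unchanged.
#' Compensation can push events slightly negative; those values are clamped
#' to 0 and the number of clamped values is recorded in the returned
#' sample's `n_clamped` field.
#'
#' @param sample a `"flow_sample"`.
#' @param spillover a [spillover_matrix()].
#' @return The compensated `"flow_sample"`.
#' @examples
#' s <- flow_sample(data.frame(green = 100, red = 60), "s1", "c1")
#' compensate(s, spillover_matrix(green_to_red = 0.1))$events
#' @export
compensate <- function(sample, spillover) {
  stopifnot(inherits(sample, "flow_sample"),
            inherits(spillover, "spillover_matrix"))
  if (abs(det(spillover)) < 1e-12)
    stop_dualprom("spillover matrix is singular", "invalid_argument")
  if (identical(unclass(spillover)[1:4], c(1, 0, 0, 1))) {
    sample$n_clamped <- 0L
    return(sample)
  }
  corrected <- t(solve(spillover,
                       t(as.matrix(sample$events[, c("green", "red")]))))
  n_clamped <- sum(corrected < 0)
  corrected[corrected < 0] <- 0
  sample$events <- data.frame(green = corrected[, 1], red = corrected[, 2])
  sample$n_clamped <- n_clamped
  sample
}

#' Event-count quality control
#'
#' A sample passes QC iff it holds at least `min_events` events (inclusive
#' boundary). QC never discards data; it attaches a `qc_pass` flag that
#' aggregation honours by default.
#'
#' @param sample a `"flow_sample"`.
#' @param min_events minimum analyzed events; default 20,000.
#' @return The sample with a logical `qc_pass` field.
#' @export
qc_events <- function(sample, min_events = 20000L) {
  stopifnot(inherits(sample, "flow_sample"))
  sample$qc_pass <- sample$n_events >= min_events
  if (!sample$qc_pass)
    message(sample$sample_id, ": ", sample$n_events, " events < ",
            min_events, " minimum; flagged")
  sample
}

#' Per-channel mean fluorescence intensity
#'
#' @param sample a `"flow_sample"` with at least one event.
#' @param geometric use geometric instead of arithmetic means (zeros are
#'   offset by 1 AU before taking logs).
#' @return Named numeric vector `c(mean_green, mean_red)`.
#' @export
sample_means <- function(sample, geometric = FALSE) {
  stopifnot(inherits(sample, "flow_sample"))
  if (sample$n_events < 1L)
    stop_dualprom("sample has no events", "invalid_argument")
  if (geometric) {
    c(mean_green = exp(mean(log1p(sample$events$green))) - 1,
      mean_red = exp(mean(log1p(sample$events$red))) - 1)
  } else {
    c(mean_green = mean(sample$events$green),
      mean_red = mean(sample$events$red))
  }
}

#' Dual-reporter strength readout from replicate samples
#'
#' Computes per-replicate channel means, averages them across replicates,
#' and reports the ratio of average green (test reporter) to average red
#' (calibration reporter) as the strength readout. The across-replicate
#' standard deviation of the per-replicate ratios is attached as the error
#' estimate; with a single replicate the SD is 0 by convention and a warning
#' is emitted.
#'
#' @param samples list of `"flow_sample"` replicates of one construct at one
#'   inducer concentration.
#' @param require_qc drop samples failing [qc_events()] flags (samples with
#'   no flag are treated as passing).
#' @param geometric forwarded to [sample_means()].
#' @return One-row data.frame of class `"dual_reporter_measurement"`:
#'   `construct_id`, `inducer_conc`, `mean_green`, `mean_red`, `ratio`,
#'   `sd`, `n_replicates`, `n_events_total`.
#' @examples
#' reps <- lapply(1:3, function(r)
#'   simulate_flow_sample(50, 100, flow_noise_params(n_events = 2000),
#'                        seed = r, replicate = r))
#' dual_ratio(reps)
#' @export
dual_ratio <- function(samples, require_qc = FALSE, geometric = FALSE) {
  if (inherits(samples, "flow_sample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, logical(1), "flow_sample")))
  constructs <- unique(vapply(samples, `[[`, character(1), "construct_id"))
  concs <- unique(vapply(samples, `[[`, numeric(1), "inducer_conc"))
  if (length(constructs) != 1L)
    stop_dualprom("replicates mix constructs", "invalid_argument")
  if (length(concs) != 1L)
    stop_dualprom("replicates mix inducer concentrations",
                  "invalid_argument")
  if (require_qc) {
    keep <- vapply(samples, function(s) isTRUE(s$qc_pass %||% TRUE),
                   logical(1))
    if (!any(keep))
      stop_dualprom("no replicate passes QC", "degenerate_measurement")
    samples <- samples[keep]
  }
  means <- t(vapply(samples, sample_means, numeric(2),
                    geometric = geometric))
  avg_green <- mean(means[, "mean_green"])
  avg_red <- mean(means[, "mean_red"])
  if (avg_red <= 0)
    stop_dualprom("average red signal is zero: ratio undefined",
                  "degenerate_measurement")
  rep_ratios <- means[, "mean_green"] / means[, "mean_red"]
  if (length(samples) == 1L) {
    warning("single replicate: SD reported as 0")
    sd_ratio <- 0
  } else {
    sd_ratio <- sd(rep_ratios)
  }
  structure(
    data.frame(construct_id = constructs, inducer_conc = concs,
               mean_green = avg_green, mean_red = avg_red,
               ratio = avg_green / avg_red, sd = sd_ratio,
               n_replicates = length(samples),
               n_events_total = sum(vapply(samples, `[[`, integer(1),
                                           "n_events")),
               stringsAsFactors = FALSE),
    class = c("dual_reporter_measurement", "data.frame")
  )
}

#' Relative RBS strength: induced minus uninduced ratio
#'
#' For an inducible construct, the element's calibrated strength is the
#' dual-reporter ratio with inducer minus the ratio of the same construct
#' without inducer. Negative values (weak elements within noise) are
#' preserved, not clamped.
#'
#' @param induced,uninduced `"dual_reporter_measurement"` rows for the same
#'   construct; `uninduced` must be at concentration 0.
#' @return Numeric scalar.
#' @export
rbs_relative_strength <- function(induced, uninduced) {
  stopifnot(inherits(induced, "dual_reporter_measurement"),
            inherits(uninduced, "dual_reporter_measurement"))
  if (!identical(induced$construct_id, uninduced$construct_id))
    stop_dualprom("construct mismatch between induced and uninduced",
                  "invalid_argument")
  if (uninduced$inducer_conc != 0)
    stop_dualprom("uninduced measurement must be at concentration 0",
                  "invalid_argument")
  induced$ratio - uninduced$ratio
}

#' Aggregate many flow samples into a measurement table
#'
#' Groups samples by (construct, inducer concentration), applies optional
#' compensation and QC, and runs [dual_ratio()] per group.
#'
#' @param samples list of `"flow_sample"` objects.
#' @param spillover optional [spillover_matrix()] applied to every sample.
#' @param min_events QC floor; `NULL` disables QC.
#' @param geometric forwarded to [sample_means()].
#' @return data.frame, one row per (construct, concentration).
#' @export
measure_constructs <- function(samples, spillover = NULL, min_events = NULL,
                               geometric = FALSE) {
  if (!is.null(spillover))
    samples <- lapply(samples, compensate, spillover = spillover)
  if (!is.null(min_events))
    samples <- lapply(samples, qc_events, min_events = min_events)
  key <- vapply(samples, function(s)
    paste(s$construct_id, s$inducer_conc, sep = "\r"), character(1))
  groups <- split(samples, key)
  out <- do.call(rbind, lapply(groups, dual_ratio,
                               require_qc = !is.null(min_events),
                               geometric = geometric))
  rownames(out) <- NULL
  out[order(out$construct_id, out$inducer_conc), , drop = FALSE]
}
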