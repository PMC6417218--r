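#' Fit a linear inducer dose-response
#'
#' Ordinary least squares of the dual-reporter ratio on inducer
#' concentration, the calibration check for an inducible test promoter:
#' over the linear window the ratio should rise linearly with inducer.
#' `r_squared` is the squared Pearson correlation of ratio with
#' concentration. A series with zero ratio variance has an undefined
#' correlation; it is reported as `r_squared = 0` with `degenerate = TRUE`
#' rather than propagating `NaN`.
#'
#' @param measurements data.frame with `inducer_conc` and `ratio` columns
#'   (e.g. rows from [dual_ratio()] / [measure_constructs()]).
#' @return One-row data.frame of class `"dose_fit"`: `construct_id`,
#'   `slope`, `intercept`, `r_squared`, `n_points`, `degenerate`.
#' @examples
#' d <- data.frame(inducer_conc = c(0, .2, .4, .6),
#'                 ratio = 0.1 + 0.3 * c(0, .2, .4, .6))
#' linear_dose_fit(d)
#' @export
linear_dose_fit <- function(measurements) {
  stopifnot(all(c("inducer_conc", "ratio") %in% names(measurements)))
  m <- measurements[is.finite(measurements$ratio), ]
  if (nrow(m) >= 3L && length(unique(m$inducer_conc)) == 1L)
    stop_dualprom("zero concentration variance", "invalid_argument")
  if (length(unique(m$inducer_conc)) < 3L)
    stop_dualprom("need >= 3 distinct concentrations for a dose fit",
                  "insufficient_data")
  fit <- lm(ratio ~ inducer_conc, data = m)
  degenerate <- sd(m$ratio) == 0
  r2 <- if (degenerate) 0 else cor(m$inducer_conc, m$ratio)^2
  out <- data.frame(
    construct_id = if (!is.null(m$construct_id)) m$construct_id[1] else NA,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, n_points = nrow(m), degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dose_fit", "data.frame")
  out
}

#' Prediction-versus-measurement correlation per omics platform
#'
#' Correlates each platform's per-gene omics summary (`mean_log2`) with the
#' measured dual-reporter ratio over genes where both are available. The
#' ratio can be correlated raw or after a log2 transform (the default
#' headline, since the predictor axis is itself log2-scaled). Spearman's
#' rank correlation is invariant to that monotone choice; Pearson's is not.
#'
#' @param joined long data.frame with columns `gene_id`, `platform`,
#'   `mean_log2`, `ratio`.
#' @param transform `"log2_ratio"` (default) or `"raw_ratio"`.
#' @return data.frame, one row per platform: `platform`, `n`, `pearson_r`,
#'   `r_squared`, `spearman_rho`, `transform`, `n_excluded`.
#' @export
prediction_correlation <- function(joined,
                                   transform = c("log2_ratio",
                                                 "raw_ratio")) {
  transform <- match.arg(transform)
  stopifnot(all(c("gene_id", "platform", "mean_log2", "ratio") %in%
                  names(joined)))
  out <- lapply(split(joined, joined$platform), function(d) {
    ok <- is.finite(d$mean_log2) & is.finite(d$ratio) & d$ratio > 0
    n_excluded <- sum(!ok)
    d <- d[ok, ]
    if (nrow(d) < 3L)
      stop_dualprom(sprintf("platform %s: fewer than 3 complete pairs",
                            d$platform[1] %||% "?"), "insufficient_data")
    y <- if (transform == "log2_ratio") log2(d$ratio) else d$ratio
    r <- cor(d$mean_log2, y)
    data.frame(platform = d$platform[1], n = nrow(d), pearson_r = r,
               r_squared = r^2,
               spearman_rho = cor(d$mean_log2, y, method = "spearman"),
               transform = transform, n_excluded = n_excluded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Strength-class ordering of measured ratios
#'
#' Computes per-class mean and SD of measured dual-reporter ratios over
#' candidates carrying measurements, and checks the qualitative prediction
#' that the classes separate: mean(strong) > mean(medium) > mean(weak).
#'
#' @param candidates data.frame with `gene_id` and `class`
#'   (strong/medium/weak), e.g. [candidate_table()].
#' @param measurements data.frame mapping `gene_id` (or `construct_id`) to
#'   `ratio`.
#' @return List of class `"class_ordering"`: `per_class` data.frame
#'   (`class`, `n`, `mean_ratio`, `sd`) and logical `is_monotone`.
#' @export
class_ordering <- function(candidates, measurements) {
  stopifnot(all(c("gene_id", "class") %in% names(candidates)))
  id_col <- if ("gene_id" %in% names(measurements)) "gene_id" else
    "construct_id"
  stopifnot("ratio" %in% names(measurements))
  merged <- merge(candidates,
                  measurements[, c(id_col, "ratio")],
                  by.x = "gene_id", by.y = id_col)
  merged <- merged[is.finite(merged$ratio), ]
  classes <- c("strong", "medium", "weak")
  if (!all(classes %in% merged$class))
    stop_dualprom("every strength class needs at least one measured member",
                  "insufficient_data")
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    r <- merged$ratio[merged$class == cl]
    data.frame(class = cl, n = length(r), mean_ratio = mean(r),
               sd = if (length(r) > 1) sd(r) else 0,
               stringsAsFactors = FALSE)
  }))
  mono <- per_class$mean_ratio[1] > per_class$mean_ratio[2] &&
    per_class$mean_ratio[2] > per_class$mean_ratio[3]
  structure(list(per_class = per_class, is_monotone = mono),
            class = "class_ordering")
}

#' @export
print.class_ordering <- function(x, ...) {
  print(x$per_class)
  cat("monotone strong > medium > weak:", x$is_monotone, "\n")
  invisible(x)
}
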