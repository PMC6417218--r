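#' Draw a latent promoter-strength map with planted strength classes
#'
#' Assigns each gene a true promoter strength on the log2 expression scale,
#' together with a ground-truth class label used by parameter-recovery tests.
#' Class latents are drawn from disjoint uniform blocks separated by gaps, an
#' idealization that makes the planted classes recoverable in principle:
#'
#' * weak: 10% of genes, latent in \[3.0, 4.6\]
#' * unlabeled low background: latent in \[5.8, 9.4\]
#' * medium: 20% of genes, latent in \[9.9, 10.5\] (the 40-60 percentile band)
#' * unlabeled high background: latent in \[11.0, 14.2\]
#' * strong: 10% of genes, latent in \[15.0, 16.4\]
#'
#' The spans mirror the roughly one-log2-unit separation seen between
#' strength clusters on a microarray scale, and the strong/weak fractions
#' match the top/bottom-decile classification rule.
#'
#' @param gene_ids character vector of gene identifiers (unique).
#' @param strong_frac,weak_frac,medium_frac planted class fractions.
#' @param seed integer RNG seed.
#' @return data.frame with `gene_id`, `latent_log2`, `class_truth`
#'   (factor: strong/medium/weak/none).
#' @examples
#' truth <- simulate_latent_strength(sprintf("g%03d", 1:100), seed = 1)
#' table(truth$class_truth)
#' @export
simulate_latent_strength <- function(gene_ids, strong_frac = 0.10,
                                     weak_frac = 0.10, medium_frac = 0.20,
                                     seed = 1L) {
  if (anyDuplicated(gene_ids))
    stop_dualprom("gene_ids must be unique", "invalid_argument")
  n <- length(gene_ids)
  if (n < 10L)
    stop_dualprom("need >= 10 genes for a meaningful strength map",
                  "invalid_argument")
  if (strong_frac + weak_frac + medium_frac >= 1)
    stop_dualprom("class fractions must sum to < 1", "invalid_argument")
  with_seed(seed, {
    n_strong <- round(strong_frac * n)
    n_weak <- round(weak_frac * n)
    n_medium <- round(medium_frac * n)
    n_none <- n - n_strong - n_weak - n_medium
    n_low <- floor(n_none / 2)
    n_high <- n_none - n_low
    cls <- c(rep("weak", n_weak), rep("none", n_low), rep("medium", n_medium),
             rep("none", n_high), rep("strong", n_strong))
    lat <- c(runif(n_weak, 3.0, 4.6), runif(n_low, 5.8, 9.4),
             runif(n_medium, 9.9, 10.5), runif(n_high, 11.0, 14.2),
             runif(n_strong, 15.0, 16.4))
    perm <- sample.int(n)
    data.frame(
      gene_id = gene_ids,
      latent_log2 = lat[perm],
      class_truth = factor(cls[perm],
                           levels = c("strong", "medium", "weak", "none")),
      stringsAsFactors = FALSE
    )
  })
}

#' Construct an omics expression dataset
#'
#' Light S3 container for one platform's genes-by-conditions matrix of
#' log2-scale expression (or abundance) values.
#'
#' @param matrix numeric matrix, rownames = gene ids, colnames = condition
#'   ids; all values finite.
#' @param platform one of `"microarray"`, `"rnaseq"`, `"proteomics"`.
#' @return An `"omics_dataset"` object.
#' @export
omics_dataset <- function(matrix, platform = c("microarray", "rnaseq",
                                               "proteomics")) {
  platform <- match.arg(platform)
  if (!is.matrix(matrix) || !is.numeric(matrix) || nrow(matrix) < 1L ||
      ncol(matrix) < 1L)
    stop_dualprom("matrix must be a non-empty numeric matrix",
                  "invalid_argument")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop_dualprom("matrix needs unique gene ids as rownames",
                  "invalid_argument")
  if (!all(is.finite(matrix)))
    stop_dualprom("all expression values must be finite", "invalid_argument")
  if (is.null(colnames(matrix)))
    colnames(matrix) <- sprintf("cond%03d", seq_len(ncol(matrix)))
  structure(list(platform = platform, matrix = matrix,
                 n_conditions = ncol(matrix)),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("<omics_dataset> %s: %d genes x %d conditions\n",
              x$platform, nrow(x$matrix), x$n_conditions))
  invisible(x)
}

#' Simulate a three-platform omics compendium from latent strengths
#'
#' Generates one genes-by-conditions matrix per platform. Each value is
#' `latent_log2 + platform_offset + condition_effect + noise`, with the
#' condition effect shared by all genes in a column (batch/growth-condition
#' shift) and independent Gaussian noise per cell. Proteomics values are
#' left-censored at a detection floor: any value below `proteomics_floor` is
#' replaced by the floor itself, so genes whose true abundance sits below the
#' limit of detection all report one identical value.
#'
#' Default condition counts (109 / 8 / 4) reproduce the size structure of a
#' typical compendium of public microarray, RNA-seq and proteomics
#' experiments for a model bacterium.
#'
#' @param truth data.frame from [simulate_latent_strength()].
#' @param n_conditions named integer vector of conditions per platform.
#' @param noise_sd named numeric vector, per-cell Gaussian noise SD.
#' @param platform_offset named numeric vector, additive scale offset that
#'   moves the shared latent onto each platform's reporting scale.
#' @param condition_sd SD of the per-condition (column) shift.
#' @param proteomics_floor detection floor on the proteomics scale;
#'   `NULL` disables censoring.
#' @param seed integer RNG seed.
#' @return Named list of three [omics_dataset()] objects.
#' @examples
#' truth <- simulate_latent_strength(sprintf("g%03d", 1:50), seed = 1)
#' suite <- simulate_omics_suite(truth, seed = 2)
#' sapply(suite, function(d) d$n_conditions)
#' @export
simulate_omics_suite <- function(truth,
                                 n_conditions = c(microarray = 109L,
                                                  rnaseq = 8L,
                                                  proteomics = 4L),
                                 noise_sd = c(microarray = 1.5,
                                              rnaseq = 1.0,
                                              proteomics = 0.8),
                                 platform_offset = c(microarray = 0,
                                                     rnaseq = -3.5,
                                                     proteomics = -6),
                                 condition_sd = 0.5,
                                 proteomics_floor = 0.07,
                                 seed = 1L) {
  if (is.null(truth) || nrow(truth) == 0L)
    stop_dualprom("truth map is empty", "invalid_argument")
  platforms <- c("microarray", "rnaseq", "proteomics")
  stopifnot(all(platforms %in% names(n_conditions)),
            all(platforms %in% names(noise_sd)),
            all(platforms %in% names(platform_offset)))
  if (any(noise_sd < 0) || condition_sd < 0)
    stop_dualprom("noise SDs must be >= 0", "invalid_argument")
  if (!is.null(proteomics_floor) && !is.finite(proteomics_floor))
    stop_dualprom("proteomics_floor must be finite (or NULL to disable)",
                  "invalid_argument")

  with_seed(seed, {
    out <- lapply(platforms, function(p) {
      nc <- as.integer(n_conditions[[p]])
      mat <- outer(truth$latent_log2 + platform_offset[[p]], rep(1, nc)) +
        outer(rep(1, nrow(truth)), rnorm(nc, 0, condition_sd)) +
        matrix(rnorm(nrow(truth) * nc, 0, noise_sd[[p]]),
               nrow = nrow(truth))
      if (p == "proteomics" && !is.null(proteomics_floor))
        mat <- pmax(mat, proteomics_floor)
      rownames(mat) <- truth$gene_id
      colnames(mat) <- sprintf("%s_cond%03d", p, seq_len(nc))
      omics_dataset(mat, p)
    })
    names(out) <- platforms
    out
  })
}

#' Write / read an omics matrix as TSV
#'
#' Rows are genes (first column `gene_id`), remaining columns are condition
#' ids; values on the log2 scale.
#'
#' @param dataset an [omics_dataset()].
#' @param path TSV path.
#' @return `write_omics_tsv` the path, invisibly; `read_omics_tsv` an
#'   [omics_dataset()].
#' @export
write_omics_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "omics_dataset"))
  df <- data.frame(gene_id = rownames(dataset$matrix), dataset$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_omics_tsv
#' @param platform platform label for the loaded matrix.
#' @export
read_omics_tsv <- function(path, platform) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  omics_dataset(mat, platform)
}
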