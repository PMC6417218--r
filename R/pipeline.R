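# strength-to-signal coupling used by the synthetic end-to-end study:
# green reporter strength per unit copy for a promoter with latent strength
# `latent`, scaled so the strongest latent reaches `max_ratio * red_strength`
coupled_green_strength <- function(latent, latent_max, red_strength,
                                   max_ratio = 0.38, coupling = 0.4) {
  red_strength * max_ratio * 2^(coupling * (latent - latent_max))
}

#' Run the full synthetic study in memory
#'
#' End-to-end exercise of the pipeline on generated data: simulate a genome
#' with operons, latent promoter strengths and a three-platform omics
#' compendium; classify and intersect into consensus candidates; extract
#' candidate promoter regions; simulate replicate dual-reporter flow samples
#' for every candidate (green strength log-linearly coupled to the latent,
#' red calibration constant); compensate, QC and aggregate to ratios; then
#' report prediction-measurement correlations, class ordering, and recovery
#' of the planted strong/weak sets.
#'
#' @param n_genes genome size (default 1000).
#' @param seed integer seed driving every stage.
#' @param replicates flow replicates per candidate.
#' @param noise [flow_noise_params()] for event simulation.
#' @param red_strength red calibration signal per unit copy.
#' @param max_ratio dual ratio of the strongest promoter.
#' @param coupling log2-ratio units per latent log2 unit.
#' @param thresholds [quantile_thresholds()].
#' @param operon_fraction forwarded to [simulate_annotation()].
#' @return List with elements `annotation`, `truth`, `calls`, `consensus`,
#'   `promoters`, `measurements`, `correlations`, `ordering`, `recovery`.
#' @examples
#' \donttest{
#' res <- run_synthetic_study(n_genes = 200, seed = 1,
#'                            noise = flow_noise_params(n_events = 1000))
#' res$recovery
#' }
#' @export
run_synthetic_study <- function(n_genes = 1000L, seed = 1L, replicates = 3L,
                                noise = flow_noise_params(),
                                red_strength = 500, max_ratio = 0.38,
                                coupling = 0.4,
                                thresholds = quantile_thresholds(),
                                operon_fraction = 0.25) {
  seed <- as.integer(seed)
  ann <- simulate_annotation(n_genes, operon_fraction = operon_fraction,
                             seed = seed)
  truth <- simulate_latent_strength(ann$genes$gene_id, seed = seed + 1L)
  suite <- simulate_omics_suite(truth, seed = seed + 2L)

  calls <- lapply(suite, function(d)
    classify_by_quantile(summarize_dataset(d), thresholds))
  consensus <- consensus_select(calls)
  cand <- candidate_table(consensus)

  promoters <- extract_promoters(cand$gene_id, ann$genes, ann$operons,
                                 genome = ann$genome)

  latent <- setNames(truth$latent_log2, truth$gene_id)
  lmax <- max(truth$latent_log2)
  spill <- spillover_matrix(green_to_red = noise$spillover_green_to_red)
  base <- (seed %% 20000L) * 100000L
  measurements <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    g <- cand$gene_id[i]
    gs <- coupled_green_strength(latent[[g]], lmax, red_strength,
                                 max_ratio, coupling)
    reps <- lapply(seq_len(replicates), function(r) {
      s <- simulate_flow_sample(
        gs, red_strength, noise, seed = base + i * 10L + r,
        sample_id = sprintf("%s_r%d", g, r), construct_id = g, replicate = r)
      qc_events(compensate(s, spill), min_events = noise$n_events)
    })
    dual_ratio(reps, require_qc = TRUE)
  }))

  joined <- do.call(rbind, lapply(calls, function(cl) {
    m <- merge(cl[, c("gene_id", "platform", "mean_log2")],
               measurements[, c("construct_id", "ratio")],
               by.x = "gene_id", by.y = "construct_id")
    m
  }))
  correlations <- prediction_correlation(joined, transform = "log2_ratio")
  ordering <- class_ordering(cand, measurements)

  recovery <- data.frame(
    class = c("strong", "weak"),
    precision = c(
      mean(truth$class_truth[match(consensus$strong, truth$gene_id)] ==
             "strong"),
      mean(truth$class_truth[match(consensus$weak, truth$gene_id)] ==
             "weak")),
    recall = c(
      sum(consensus$strong %in%
            truth$gene_id[truth$class_truth == "strong"]) /
        sum(truth$class_truth == "strong"),
      sum(consensus$weak %in% truth$gene_id[truth$class_truth == "weak"]) /
        sum(truth$class_truth == "weak")),
    stringsAsFactors = FALSE
  )

  list(annotation = ann, truth = truth, calls = calls,
       consensus = consensus, promoters = promoters,
       measurements = measurements, correlations = correlations,
       ordering = ordering, recovery = recovery)
}

#' Generate a complete on-disk input set for the pipeline
#'
#' Writes a simulated study to `dir` in the pipeline's file contracts:
#' `annotation.gff3`, `genome.fasta`, `operons.tsv`, one
#' `omics_<platform>.tsv` per platform, a `flow/` directory of per-sample
#' event CSVs with `samples.tsv` metadata (flow samples are generated for
#' the consensus candidates, i.e. the constructs a measurement campaign
#' would build), and `truth.tsv` with the planted latent strengths.
#'
#' @inheritParams run_synthetic_study
#' @param dir output directory.
#' @return A [pipeline_config()] pointing at the written files.
#' @export
simulate_study <- function(dir, n_genes = 80L, seed = 1L, replicates = 3L,
                           noise = flow_noise_params(n_events = 2000L),
                           red_strength = 500, max_ratio = 0.38,
                           coupling = 0.4,
                           thresholds = quantile_thresholds()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  ann <- simulate_annotation(n_genes, operon_fraction = 0.25, seed = seed)
  truth <- simulate_latent_strength(ann$genes$gene_id, seed = seed + 1L)
  suite <- simulate_omics_suite(truth, seed = seed + 2L)
  write_annotation(ann, dir)
  omics_paths <- vapply(names(suite), function(p) {
    path <- file.path(dir, sprintf("omics_%s.tsv", p))
    write_omics_tsv(suite[[p]], path)
    path
  }, character(1))
  write_tsv(truth, file.path(dir, "truth.tsv"))

  calls <- lapply(suite, function(d)
    classify_by_quantile(summarize_dataset(d), thresholds))
  cand <- candidate_table(consensus_select(calls))
  latent <- setNames(truth$latent_log2, truth$gene_id)
  lmax <- max(truth$latent_log2)
  base <- (seed %% 20000L) * 100000L
  samples <- unlist(lapply(seq_len(nrow(cand)), function(i) {
    g <- cand$gene_id[i]
    gs <- coupled_green_strength(latent[[g]], lmax, red_strength,
                                 max_ratio, coupling)
    lapply(seq_len(replicates), function(r)
      simulate_flow_sample(gs, red_strength, noise,
                           seed = base + i * 10L + r,
                           sample_id = sprintf("%s_r%d", g, r),
                           construct_id = g, replicate = r))
  }), recursive = FALSE)
  write_flow_samples(samples, file.path(dir, "flow"))

  pipeline_config(
    annotation = file.path(dir, "annotation.gff3"),
    genome = file.path(dir, "genome.fasta"),
    operons = file.path(dir, "operons.tsv"),
    omics = as.list(omics_paths),
    flow_dir = file.path(dir, "flow"),
    thresholds = thresholds,
    min_events = noise$n_events,
    spillover = spillover_matrix(noise$spillover_green_to_red),
    seed = seed
  )
}

#' Pipeline configuration
#'
#' Validates paths and analysis options for [run_pipeline()]. All referenced
#' paths must exist when the config is built.
#'
#' @param annotation GFF3 gene annotation path.
#' @param genome FASTA genome path.
#' @param operons operon table TSV path (may be `NULL` for no operons).
#' @param omics named list of per-platform omics TSV paths; names must be
#'   `microarray`, `rnaseq`, `proteomics` (any non-empty subset).
#' @param flow_dir directory of event CSVs with a `samples.tsv` sheet.
#' @param thresholds [quantile_thresholds()].
#' @param min_events QC floor for flow samples.
#' @param spillover [spillover_matrix()] applied before aggregation
#'   (identity by default: ratios are computed on detector signals unless a
#'   measured matrix is supplied).
#' @param transform correlation transform, see [prediction_correlation()].
#' @param extra_weak manually added weak candidates.
#' @param seed integer seed recorded in output headers.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(annotation, genome, operons, omics, flow_dir,
                            thresholds = quantile_thresholds(),
                            min_events = 20000L,
                            spillover = spillover_matrix(),
                            transform = "log2_ratio",
                            extra_weak = character(), seed = 1L) {
  paths <- c(annotation = annotation, genome = genome,
             unlist(omics), flow_dir = flow_dir)
  if (!is.null(operons)) paths <- c(paths, operons = operons)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_dualprom(paste("missing input path(s):",
                        paste(missing, collapse = ", ")),
                  "invalid_argument")
  if (is.null(names(omics)) ||
      !all(names(omics) %in% c("microarray", "rnaseq", "proteomics")))
    stop_dualprom("omics must be a named list keyed by platform",
                  "invalid_argument")
  stopifnot(inherits(thresholds, "quantile_thresholds"),
            inherits(spillover, "spillover_matrix"))
  structure(list(annotation = annotation, genome = genome,
                 operons = operons, omics = omics, flow_dir = flow_dir,
                 thresholds = thresholds, min_events = min_events,
                 spillover = spillover, transform = transform,
                 extra_weak = extra_weak, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the promoter characterization pipeline on files
#'
#' Executes the stages in order — omics summary, quantile classification,
#' cross-platform consensus, operon-aware promoter extraction, flow
#' quantification, validation — reading the inputs named in `config` and
#' writing `calls.tsv`, `candidates.tsv`, `promoters.tsv`,
#' `promoters.fasta`, `measurements.tsv`, `validation_report.json` and
#' `manifest.json` under `out_dir`. Outputs carry the seed and a config
#' checksum in their headers; identical config and seed reproduce identical
#' files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_json <- jsonlite::toJSON(
    list(omics = config$omics, thresholds = unclass(config$thresholds),
         min_events = config$min_events, transform = config$transform,
         seed = config$seed),
    auto_unbox = TRUE)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  hdr <- c(sprintf("dualprom %s", as.character(packageVersion("dualprom"))),
           sprintf("config_md5 %s", cfg_hash),
           sprintf("seed %d", config$seed))

  annotation <- read_annotation_gff3(config$annotation)
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  operons <- if (is.null(config$operons)) NULL else read_tsv(config$operons)

  suite <- lapply(names(config$omics), function(p)
    read_omics_tsv(config$omics[[p]], p))
  names(suite) <- names(config$omics)
  calls <- lapply(suite, function(d)
    classify_by_quantile(summarize_dataset(d), config$thresholds))
  consensus <- consensus_select(calls, extra_weak = config$extra_weak)
  cand <- candidate_table(consensus)
  write_tsv(do.call(rbind, c(calls, list(make.row.names = FALSE))),
            file.path(out_dir, "calls.tsv"), hdr)
  write_tsv(consensus$provenance, file.path(out_dir, "candidates.tsv"), hdr)

  promoters <- extract_promoters(cand$gene_id, annotation, operons,
                                 genome = genome)
  write_promoters(promoters, file.path(out_dir, "promoters.tsv"),
                  file.path(out_dir, "promoters.fasta"))

  samples <- read_flow_samples(config$flow_dir)
  measurements <- measure_constructs(samples, spillover = config$spillover,
                                     min_events = config$min_events)
  write_tsv(measurements, file.path(out_dir, "measurements.tsv"), hdr)

  joined <- do.call(rbind, lapply(calls, function(cl)
    merge(cl[, c("gene_id", "platform", "mean_log2")],
          measurements[, c("construct_id", "ratio")],
          by.x = "gene_id", by.y = "construct_id")))
  correlations <- prediction_correlation(joined,
                                         transform = config$transform)
  ordering <- class_ordering(cand, measurements)

  report <- list(
    seed = config$seed, config_md5 = cfg_hash,
    n_candidates = nrow(cand),
    class_counts = as.list(table(cand$class)),
    correlations = correlations,
    class_ordering = c(list(is_monotone = ordering$is_monotone),
                       list(per_class = ordering$per_class))
  )
  jsonlite::write_json(report, file.path(out_dir, "validation_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(
    tool = "dualprom",
    version = as.character(packageVersion("dualprom")),
    seed = config$seed, config_md5 = cfg_hash,
    outputs = c("calls.tsv", "candidates.tsv", "promoters.tsv",
                "promoters.fasta", "measurements.tsv",
                "validation_report.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(calls = calls, consensus = consensus,
                 promoters = promoters, measurements = measurements,
                 correlations = correlations, ordering = ordering))
}
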