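# frozen md5 sums of the packaged reference tables; load_* refuse to return
# silently corrupted fixtures
.fixture_md5 <- c(
  table1.tsv = "8ee861bff62be106ddc52209c3847ca6",
  table2.tsv = "23845a8ba6f907fca25269cab0ad6e6c"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "dualprom")
  if (p == "")
    stop_dualprom(paste("packaged fixture not found:", file),
                  "fixture_corruption")
  if (unname(tools::md5sum(p)) != .fixture_md5[[file]])
    stop_dualprom(paste("fixture checksum mismatch:", file),
                  "fixture_corruption")
  p
}

#' Load the packaged table of characterized candidate promoters
#'
#' Returns the transcribed reference table of 38 candidate promoters
#' (19 strong, 9 medium, 10 weak) with, per promoter: the driving gene's
#' average log2 expression on each omics platform (microarray `array_log2`,
#' RNA-seq `rnaseq_log2`, proteomics `proteomics_log2`) and the measured
#' dual-reporter EGFP/opmCherry ratio with replicate SD in exponential
#' (`ratio_log`, `sd_log`) and stationary (`ratio_sta`, `sd_sta`) growth
#' phase. One plasmid-borne promoter row (Po1721) has no chromosomal gene
#' and hence no omics values; every weak promoter's proteomics value sits at
#' the platform's 0.07 detection floor. Row count, class counts and a file
#' checksum are verified at load time.
#'
#' @return data.frame with 38 rows.
#' @examples
#' t1 <- load_table1_fixture()
#' table(t1$class)
#' @export
load_table1_fixture <- function() {
  df <- read_tsv(fixture_path("table1.tsv"))
  counts <- table(factor(df$class, levels = c("strong", "medium", "weak")))
  ok <- nrow(df) == 38L && counts[["strong"]] == 19L &&
    counts[["medium"]] == 9L && counts[["weak"]] == 10L &&
    all(df$sd_log >= 0, na.rm = TRUE) && all(df$sd_sta >= 0, na.rm = TRUE) &&
    sum(is.na(df$array_log2)) == 1L &&
    df$gene_id[is.na(df$array_log2)] == "Po1721"
  if (!ok)
    stop_dualprom("candidate promoter table failed validation",
                  "fixture_corruption")
  df
}

#' Load the packaged synthetic RBS designs
#'
#' Four synthetic ribosome binding sites spanning predicted translation
#' initiation rates of 10, 1,000, 10,000 and 15,000 (arbitrary
#' thermodynamic-calculator units), with their nucleotide sequences.
#'
#' @return data.frame with `name`, `predicted_tir`, `sequence` (4 rows).
#' @examples
#' load_table2_fixture()
#' @export
load_table2_fixture <- function() {
  df <- read_tsv(fixture_path("table2.tsv"))
  ok <- nrow(df) == 4L &&
    setequal(df$predicted_tir, c(10, 1000, 10000, 15000)) &&
    all(grepl("^[ACGT]+$", df$sequence)) && all(df$predicted_tir > 0)
  if (!ok)
    stop_dualprom("RBS design table failed validation", "fixture_corruption")
  df
}
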