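#' Per-gene summary of an omics dataset
#'
#' Collapses a genes-by-conditions matrix to one value per gene: the
#' arithmetic mean of the gene's log2 values across all of the dataset's
#' conditions. This is the per-platform quantity on which strength classes
#' are assigned.
#'
#' @param dataset an [omics_dataset()].
#' @return data.frame with `gene_id`, `platform`, `mean_log2`.
#' @examples
#' m <- matrix(c(10, 12, 2, 4), 2, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), c("c1", "c2")))
#' summarize_dataset(omics_dataset(m, "rnaseq"))
#' @export
summarize_dataset <- function(dataset) {
  if (!inherits(dataset, "omics_dataset"))
    stop_dualprom("dataset must be an omics_dataset", "invalid_argument")
  data.frame(
    gene_id = rownames(dataset$matrix),
    platform = dataset$platform,
    mean_log2 = rowMeans(dataset$matrix),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Percentile thresholds for strength classification
#'
#' Defaults encode the decile rule: genes at or above the 90th percentile of
#' a platform's per-gene means are strong, at or below the 10th percentile
#' weak, and inside the 40-60th band medium; everything else is unlabeled.
#'
#' @param strong_min_pr minimum percentile rank for strong.
#' @param weak_max_pr maximum percentile rank for weak.
#' @param medium_lo,medium_hi inclusive percentile band for medium.
#' @return A `"quantile_thresholds"` list.
#' @export
quantile_thresholds <- function(strong_min_pr = 0.90, weak_max_pr = 0.10,
                                medium_lo = 0.40, medium_hi = 0.60) {
  ok <- weak_max_pr >= 0 && weak_max_pr < medium_lo &&
    medium_lo <= medium_hi && medium_hi < strong_min_pr && strong_min_pr <= 1
  if (!ok)
    stop_dualprom(
      "need 0 <= weak_max_pr < medium_lo <= medium_hi < strong_min_pr <= 1",
      "invalid_argument")
  structure(list(strong_min_pr = strong_min_pr, weak_max_pr = weak_max_pr,
                 medium_lo = medium_lo, medium_hi = medium_hi),
            class = "quantile_thresholds")
}

#' Classify genes into strength classes by percentile rank
#'
#' Percentile rank is ascending rank divided by the number of genes, with
#' ties given their mean rank — so a block of genes sharing one value (for
#' example, proteomics hits pinned at the detection floor) receives one
#' common rank and classifies identically. Labels follow
#' [quantile_thresholds()] with inclusive boundaries on the side of each
#' class: `pr >= strong_min_pr` is strong, `pr <= weak_max_pr` weak,
#' `medium_lo <= pr <= medium_hi` medium, anything else unlabeled.
#'
#' A constant summary vector carries no ordering information: every gene is
#' returned unlabeled, with a warning. Fewer than 10 genes triggers a warning
#' because the decile classes degenerate.
#'
#' @param summary data.frame from [summarize_dataset()].
#' @param thresholds a [quantile_thresholds()].
#' @return data.frame with `gene_id`, `platform`, `mean_log2`,
#'   `percentile_rank`, `label` (factor strong/medium/weak/unlabeled).
#' @examples
#' s <- data.frame(gene_id = letters[1:10], platform = "rnaseq",
#'                 mean_log2 = 1:10)
#' subset(classify_by_quantile(s), label != "unlabeled")
#' @export
classify_by_quantile <- function(summary, thresholds = quantile_thresholds()) {
  stopifnot(inherits(thresholds, "quantile_thresholds"),
            all(c("gene_id", "platform", "mean_log2") %in% names(summary)))
  n <- nrow(summary)
  if (n == 0L)
    stop_dualprom("empty summary", "invalid_argument")
  if (n < 10L)
    warning("fewer than 10 genes: quantile classes degenerate")
  pr <- rank(summary$mean_log2, ties.method = "average") / n
  label <- rep("unlabeled", n)
  if (length(unique(summary$mean_log2)) == 1L) {
    warning("all summary values identical: no ordering information, ",
            "every gene left unlabeled")
  } else {
    label[pr >= thresholds$strong_min_pr] <- "strong"
    label[pr <= thresholds$weak_max_pr] <- "weak"
    label[pr >= thresholds$medium_lo & pr <= thresholds$medium_hi] <- "medium"
  }
  data.frame(
    gene_id = summary$gene_id, platform = summary$platform,
    mean_log2 = summary$mean_log2, percentile_rank = pr,
    label = factor(label, levels = c("strong", "medium", "weak", "unlabeled")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Cross-platform consensus candidate selection
#'
#' A gene enters a consensus class only if it carries that class label on
#' every required platform (set intersection, the Venn-diagram rule). Genes
#' absent from any required platform are excluded from consensus and
#' reported via a message. `extra_weak` gene ids are appended to the weak
#' class with provenance `"manual"`, mirroring hand-picked additions made
#' for broader coverage of the weak range.
#'
#' @param calls named list of per-platform classification data.frames from
#'   [classify_by_quantile()].
#' @param required_platforms platforms that must agree; default all of
#'   `names(calls)`.
#' @param extra_weak character vector of manually added weak candidates.
#' @return A `"candidate_set"`: list with `strong`, `medium`, `weak`
#'   (character vectors) and `provenance` (data.frame: `gene_id`, `class`,
#'   `provenance`, plus one `label_<platform>` column per platform).
#' @examples
#' s <- data.frame(gene_id = letters[1:10], platform = "x", mean_log2 = 1:10)
#' cl <- classify_by_quantile(s)
#' consensus_select(list(a = cl, b = cl))$strong
#' @export
consensus_select <- function(calls, required_platforms = names(calls),
                             extra_weak = character()) {
  if (!is.list(calls) || is.null(names(calls)) || any(names(calls) == ""))
    stop_dualprom("calls must be a named list of classification tables",
                  "invalid_argument")
  missing_p <- setdiff(required_platforms, names(calls))
  if (length(missing_p))
    stop_dualprom(paste("required platform(s) absent from calls:",
                        paste(missing_p, collapse = ", ")),
                  "invalid_argument")
  req <- calls[required_platforms]
  all_genes <- unique(unlist(lapply(calls, `[[`, "gene_id")))
  shared <- Reduce(intersect, lapply(req, `[[`, "gene_id"))
  dropped <- setdiff(unique(unlist(lapply(req, `[[`, "gene_id"))), shared)
  if (length(dropped))
    message(length(dropped),
            " gene(s) absent from at least one required platform; ",
            "excluded from consensus")

  label_of <- lapply(calls, function(cl)
    setNames(as.character(cl$label), cl$gene_id))
  classes <- c("strong", "medium", "weak")
  consensus <- lapply(classes, function(cls) {
    hits <- vapply(shared, function(g)
      all(vapply(required_platforms,
                 function(p) label_of[[p]][[g]] == cls, logical(1))),
      logical(1))
    sort(shared[hits])
  })
  names(consensus) <- classes

  extra_weak <- setdiff(extra_weak, consensus$weak)
  prov <- do.call(rbind, c(
    lapply(classes, function(cls) {
      g <- consensus[[cls]]
      if (!length(g)) return(NULL)
      data.frame(gene_id = g, class = cls, provenance = "consensus",
                 stringsAsFactors = FALSE)
    }),
    list(if (length(extra_weak))
      data.frame(gene_id = extra_weak, class = "weak", provenance = "manual",
                 stringsAsFactors = FALSE))
  ))
  if (is.null(prov))
    prov <- data.frame(gene_id = character(), class = character(),
                       provenance = character(), stringsAsFactors = FALSE)
  for (p in names(calls)) {
    lab <- label_of[[p]][prov$gene_id]
    prov[[paste0("label_", p)]] <- ifelse(is.na(lab), "absent", lab)
  }
  structure(
    list(strong = consensus$strong, medium = consensus$medium,
         weak = c(consensus$weak, sort(extra_weak)), provenance = prov),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> strong %d | medium %d | weak %d (%d manual)\n",
              length(x$strong), length(x$medium), length(x$weak),
              sum(x$provenance$provenance == "manual")))
  invisible(x)
}

#' All candidate genes of a candidate set, with class labels
#'
#' @param x a `"candidate_set"`.
#' @return data.frame with `gene_id` and `class`.
#' @export
candidate_table <- function(x) {
  stopifnot(inherits(x, "candidate_set"))
  x$provenance[, c("gene_id", "class")]
}
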