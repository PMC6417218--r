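#' Resolve a gene to its promoter-bearing anchor
#'
#' A gene transcribed as part of an operon does not carry its own promoter:
#' the promoter sits upstream of the operon's first gene in transcription
#' order. For operon members this returns that lead gene; for all other
#' genes it returns the gene itself. Vectorized over `gene_id`.
#'
#' @param gene_id character vector of query gene ids.
#' @param operons operon table (`operon_id`, `gene_id`, `position_in_operon`).
#' @param annotation optional gene annotation data.frame; when given, unknown
#'   query ids raise a not-found error.
#' @return Character vector of anchor gene ids, same length as `gene_id`.
#' @examples
#' ops <- data.frame(operon_id = "op1", gene_id = c("g1", "g2", "g3"),
#'                   position_in_operon = 1:3)
#' resolve_anchor(c("g3", "g9"), ops)
#' @export
resolve_anchor <- function(gene_id, operons, annotation = NULL) {
  if (!is.null(annotation)) {
    unknown <- setdiff(gene_id, annotation$gene_id)
    if (length(unknown))
      stop_dualprom(paste("unknown gene(s):", paste(unknown, collapse = ", ")),
                    "not_found")
  }
  if (is.null(operons) || nrow(operons) == 0L) return(gene_id)
  stopifnot(all(c("operon_id", "gene_id", "position_in_operon") %in%
                  names(operons)))
  leads <- operons[operons$position_in_operon == 1L, ]
  lead_of <- setNames(leads$gene_id, leads$operon_id)
  op_of <- setNames(operons$operon_id, operons$gene_id)
  vapply(gene_id, function(g) {
    if (g %in% names(op_of)) lead_of[[op_of[[g]]]] else g
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the intergenic promoter region upstream of an anchor gene
#'
#' The promoter is taken as the entire intergenic region between the anchor
#' gene and the nearest preceding open reading frame on either strand:
#' for a `+` strand anchor, from one base past the rightmost gene end lying
#' strictly left of the anchor start, up to the base before the anchor
#' start; for a `-` strand anchor the mirror image (from one base past the
#' anchor end to the base before the leftmost gene start lying strictly
#' right of the anchor end). Coordinates are 1-based inclusive.
#'
#' Anchors at a contig edge have no flanking ORF on the promoter side; the
#' region is then truncated at position 1 (or the contig end) and flagged
#' `truncated = TRUE`. Adjacent or overlapping ORFs leave no intergenic
#' space and raise a degenerate-region error naming both genes.
#'
#' @param anchor anchor gene id (scalar).
#' @param annotation data.frame with `gene_id`, `contig`, `strand`, `start`,
#'   `end`.
#' @param contig_lengths optional named vector of contig lengths, required to
#'   truncate `-` strand promoters at a contig's right edge.
#' @return One-row data.frame: `anchor_gene_id`, `contig`, `strand`, `start`,
#'   `end`, `length`, `truncated`.
#' @examples
#' ann <- data.frame(gene_id = c("gA", "gB"), contig = "c1",
#'                   strand = "+", start = c(101, 501), end = c(400, 1000))
#' extract_promoter("gB", ann)
#' @export
extract_promoter <- function(anchor, annotation, contig_lengths = NULL) {
  row <- annotation[annotation$gene_id == anchor, ]
  if (nrow(row) != 1L)
    stop_dualprom(paste("anchor gene not found:", anchor), "not_found")
  same <- annotation[annotation$contig == row$contig &
                       annotation$gene_id != anchor, ]
  truncated <- FALSE
  if (row$strand == "+") {
    prev_ends <- same$end[same$end < row$start]
    if (length(prev_ends)) {
      from <- max(prev_ends) + 1L
    } else {
      from <- 1L
      truncated <- TRUE
    }
    to <- row$start - 1L
    if (from > to) {
      idx <- same$end < row$start
      offender <- same$gene_id[idx][which.max(same$end[idx])]
      stop_dualprom(
        sprintf("no intergenic space upstream of %s (abuts %s)", anchor,
                if (length(offender)) offender else "contig edge"),
        "degenerate_region")
    }
  } else {
    next_starts <- same$start[same$start > row$end]
    from <- row$end + 1L
    if (length(next_starts)) {
      to <- min(next_starts) - 1L
    } else {
      clen <- contig_lengths[[row$contig]] %||% NA_integer_
      if (is.na(clen))
        stop_dualprom(
          sprintf("anchor %s is last on contig; contig_lengths required",
                  anchor), "degenerate_region")
      to <- as.integer(clen)
      truncated <- TRUE
    }
    if (from > to) {
      idx <- same$start > row$end
      offender <- same$gene_id[idx][which.min(same$start[idx])]
      stop_dualprom(
        sprintf("no intergenic space upstream of %s (abuts %s)", anchor,
                if (length(offender)) offender else "contig edge"),
        "degenerate_region")
    }
  }
  data.frame(anchor_gene_id = anchor, contig = row$contig,
             strand = row$strand, start = as.integer(from),
             end = as.integer(to), length = as.integer(to - from + 1L),
             truncated = truncated, stringsAsFactors = FALSE)
}

#' Extract promoters for a set of candidate genes
#'
#' Resolves each candidate to its anchor ([resolve_anchor()]), deduplicates
#' anchors (all members of one operon share a promoter), and extracts each
#' anchor's intergenic region. Candidates whose region is degenerate are
#' dropped with a message rather than aborting the batch.
#'
#' @param gene_ids candidate gene ids.
#' @param annotation gene annotation data.frame.
#' @param operons operon table (may be empty).
#' @param contig_lengths optional named contig lengths.
#' @param genome optional [Biostrings::DNAStringSet]; when supplied, regions
#'   gain a `sequence` column via [fetch_sequence()] and contig lengths are
#'   taken from it.
#' @return data.frame of promoter regions, one row per distinct anchor, with
#'   a `gene_id` -> `anchor_gene_id` map in attribute `"anchor_map"`.
#' @export
extract_promoters <- function(gene_ids, annotation, operons = NULL,
                              contig_lengths = NULL, genome = NULL) {
  if (!is.null(genome) && is.null(contig_lengths))
    contig_lengths <- setNames(Biostrings::width(genome), names(genome))
  anchors <- resolve_anchor(gene_ids, operons, annotation)
  amap <- data.frame(gene_id = gene_ids, anchor_gene_id = anchors,
                     stringsAsFactors = FALSE)
  out <- lapply(unique(anchors), function(a) {
    tryCatch(extract_promoter(a, annotation, contig_lengths),
             degenerate_region = function(e) {
               message("skipping ", a, ": ", conditionMessage(e))
               NULL
             })
  })
  regions <- do.call(rbind, Filter(Negate(is.null), out))
  if (!is.null(genome) && !is.null(regions))
    regions <- fetch_sequence(regions, genome)
  attr(regions, "anchor_map") <- amap
  regions
}

#' Attach genomic sequence to promoter regions
#'
#' Slices each region out of the genome (1-based inclusive coordinates) and
#' reverse-complements it when the region is on the `-` strand, so the
#' returned sequence always reads 5' to 3' on the transcribed strand.
#'
#' @param regions promoter region data.frame from [extract_promoter()].
#' @param genome named [Biostrings::DNAStringSet] (or named character vector)
#'   of contig sequences.
#' @return `regions` with an uppercase `sequence` character column.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "AACGT"))
#' r <- data.frame(anchor_gene_id = "x", contig = "c1", strand = "-",
#'                 start = 2, end = 4, length = 3, truncated = FALSE)
#' fetch_sequence(r, g)$sequence  # reverse complement of "ACG"
#' @export
fetch_sequence <- function(regions, genome) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)))
    stop_dualprom("genome contigs must be named", "invalid_argument")
  seqs <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    contig <- regions$contig[i]
    if (!contig %in% names(genome))
      stop_dualprom(paste("contig not in genome:", contig), "not_found")
    clen <- length(genome[[contig]])
    if (regions$start[i] < 1L || regions$end[i] > clen)
      stop_dualprom(sprintf("region %d-%d out of bounds for %s (1-%d)",
                            regions$start[i], regions$end[i], contig, clen),
                    "range_error")
    s <- Biostrings::subseq(genome[[contig]], regions$start[i],
                            regions$end[i])
    if (regions$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    s <- toupper(as.character(s))
    if (grepl("[^ACGTN]", s))
      stop_dualprom("non-nucleotide characters in extracted sequence",
                    "format_error")
    seqs[i] <- s
  }
  regions$sequence <- seqs
  regions
}

#' Write promoter regions to TSV and FASTA
#'
#' TSV columns: `anchor_gene_id`, `contig`, `strand`, `start`, `end`,
#' `length`, `truncated`. FASTA headers read
#' `>anchor_gene_id contig:start-end(strand)`.
#'
#' @param regions promoter data.frame carrying a `sequence` column.
#' @param tsv_path,fasta_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_promoters <- function(regions, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path)) {
    cols <- c("anchor_gene_id", "contig", "strand", "start", "end",
              "length", "truncated")
    write_tsv(regions[, cols], tsv_path)
  }
  if (!is.null(fasta_path)) {
    if (is.null(regions$sequence))
      stop_dualprom("regions carry no sequences; run fetch_sequence() first",
                    "invalid_argument")
    ss <- Biostrings::DNAStringSet(regions$sequence)
    names(ss) <- sprintf("%s %s:%d-%d(%s)", regions$anchor_gene_id,
                         regions$contig, regions$start, regions$end,
                         regions$strand)
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(c(tsv = tsv_path, fasta = fasta_path))
}
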