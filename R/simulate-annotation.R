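#' Simulate a bacterial genome annotation with operons
#'
#' Generates a random single- or multi-contig genome, a non-overlapping gene
#' annotation on both strands, and an operon membership table. Consecutive
#' same-strand genes are grouped into operons (2-4 members) so that the
#' operon-aware promoter extraction rules can be exercised: all members of an
#' operon share the promoter upstream of the operon's lead gene.
#'
#' Genes are laid down left to right on each contig with intergenic gaps of at
#' least `min_gap` bp (plus an exponential excess with mean `mean_extra_gap`),
#' so every gene has a non-empty upstream intergenic region except possibly at
#' contig edges. Output is byte-identical for identical arguments and seed.
#'
#' @param n_genes total number of genes (>= 2, and >= `n_contigs`).
#' @param n_contigs number of contigs; genes are split evenly across them.
#' @param operon_fraction target fraction of transcription-unit starts that
#'   open a multi-gene operon, in \[0, 1\]. At 1 every gene is an operon
#'   member; at 0 there are no operons.
#' @param min_gap minimum intergenic gap in bp (>= 0).
#' @param seed integer RNG seed.
#' @param gene_length_range integer range of gene lengths in bp.
#' @param mean_extra_gap mean of the exponential excess gap in bp.
#'
#' @return A list of class `"synthetic_annotation"` with elements
#'   \describe{
#'     \item{genes}{data.frame: `gene_id`, `contig`, `strand`, `start`, `end`
#'       (1-based inclusive).}
#'     \item{operons}{data.frame: `operon_id`, `gene_id`,
#'       `position_in_operon` (transcription order, 1 = lead), `strand`.}
#'     \item{genome}{[Biostrings::DNAStringSet] of contig sequences.}
#'   }
#' @examples
#' ann <- simulate_annotation(n_genes = 20, operon_fraction = 0.4, seed = 1)
#' head(ann$genes)
#' @export
simulate_annotation <- function(n_genes, n_contigs = 1L, operon_fraction = 0.25,
                                min_gap = 60L, seed = 1L,
                                gene_length_range = c(300L, 1500L),
                                mean_extra_gap = 150) {
  if (!is.numeric(n_genes) || n_genes < 2)
    stop_dualprom("n_genes must be >= 2", "invalid_argument")
  if (min_gap < 0)
    stop_dualprom("min_gap must be >= 0", "invalid_argument")
  if (operon_fraction < 0 || operon_fraction > 1)
    stop_dualprom("operon_fraction must lie in [0, 1]", "invalid_argument")
  n_genes <- as.integer(n_genes)
  n_contigs <- as.integer(n_contigs)
  if (n_contigs < 1L || n_genes < n_contigs)
    stop_dualprom("need at least one gene per contig", "invalid_argument")
  if (diff(range(gene_length_range)) < 0 || min(gene_length_range) < 3)
    stop_dualprom("gene_length_range must be increasing and >= 3 bp",
                  "generation_error")

  with_seed(seed, {
    per_contig <- diff(floor(seq(0, n_genes, length.out = n_contigs + 1L)))
    gene_counter <- 0L
    operon_counter <- 0L
    genes <- vector("list", n_contigs)
    operons <- vector("list", n_contigs)
    seqs <- character(n_contigs)

    for (ci in seq_len(n_contigs)) {
      n_here <- per_contig[ci]
      # transcription units: runs of 1 (monocistronic) or 2-4 (operon) genes
      unit_sizes <- integer(0)
      remaining <- n_here
      while (remaining > 0L) {
        is_operon <- remaining >= 2L && runif(1) < operon_fraction
        k <- if (is_operon) min(sample(2:4, 1L), remaining) else 1L
        if (operon_fraction >= 1 && remaining - k == 1L) k <- k + 1L # no orphan
        unit_sizes <- c(unit_sizes, k)
        remaining <- remaining - k
      }
      unit_strand <- sample(c("+", "-"), length(unit_sizes), replace = TRUE)
      # guarantee both strands appear somewhere in the annotation
      if (ci == 1L && length(unit_strand) >= 2L &&
          length(unique(unit_strand)) == 1L) {
        unit_strand[1L] <- setdiff(c("+", "-"), unit_strand[1L])
      }

      lens <- sample(seq(gene_length_range[1], gene_length_range[2], by = 3L),
                     n_here, replace = TRUE)
      gaps <- min_gap + floor(rexp(n_here, rate = 1 / mean_extra_gap))
      starts <- integer(n_here)
      ends <- integer(n_here)
      pos <- 1L
      for (gi in seq_len(n_here)) {
        pos <- pos + as.integer(gaps[gi])
        starts[gi] <- pos
        ends[gi] <- pos + as.integer(lens[gi]) - 1L
        pos <- ends[gi] + 1L
      }
      contig_len <- ends[n_here] + as.integer(min_gap) +
        as.integer(floor(rexp(1, rate = 1 / mean_extra_gap)))

      strand <- rep(unit_strand, unit_sizes)
      gid <- sprintf("gene%04d", gene_counter + seq_len(n_here))
      gene_counter <- gene_counter + n_here
      genes[[ci]] <- data.frame(
        gene_id = gid, contig = sprintf("contig%d", ci), strand = strand,
        start = starts, end = ends, stringsAsFactors = FALSE
      )

      # operon table, members ordered by transcription (5' -> 3')
      unit_of <- rep(seq_along(unit_sizes), unit_sizes)
      op_rows <- lapply(which(unit_sizes >= 2L), function(u) {
        members <- gid[unit_of == u]
        if (unit_strand[u] == "-") members <- rev(members)
        operon_counter <<- operon_counter + 1L
        data.frame(
          operon_id = sprintf("operon%03d", operon_counter),
          gene_id = members,
          position_in_operon = seq_along(members),
          strand = unit_strand[u],
          stringsAsFactors = FALSE
        )
      })
      operons[[ci]] <- if (length(op_rows)) do.call(rbind, op_rows) else NULL
      seqs[ci] <- paste(sample(c("A", "C", "G", "T"), contig_len,
                               replace = TRUE), collapse = "")
    }

    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- sprintf("contig%d", seq_len(n_contigs))
    op_tab <- do.call(rbind, Filter(Negate(is.null), operons))
    if (is.null(op_tab)) {
      op_tab <- data.frame(operon_id = character(), gene_id = character(),
                           position_in_operon = integer(),
                           strand = character(), stringsAsFactors = FALSE)
    }
    structure(
      list(genes = do.call(rbind, genes), operons = op_tab, genome = genome),
      class = "synthetic_annotation"
    )
  })
}

#' Write a simulated annotation to standard file formats
#'
#' Emits GFF3 (via rtracklayer; 1-based inclusive `gene` features with `ID`
#' attributes), FASTA (via Biostrings), and a TSV operon table
#' (`operon_id`, `gene_id`, `position_in_operon`, `strand`).
#'
#' @param ann a `"synthetic_annotation"` from [simulate_annotation()].
#' @param dir output directory (created if absent).
#' @return Invisibly, named paths of the three files written.
#' @export
write_annotation <- function(ann, dir) {
  stopifnot(inherits(ann, "synthetic_annotation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    gff3 = file.path(dir, "annotation.gff3"),
    fasta = file.path(dir, "genome.fasta"),
    operons = file.path(dir, "operons.tsv")
  )
  gr <- GenomicRanges_from_genes(ann$genes)
  rtracklayer::export(gr, paths[["gff3"]], format = "gff3")
  Biostrings::writeXStringSet(ann$genome, paths[["fasta"]])
  write_tsv(ann$operons, paths[["operons"]])
  invisible(paths)
}

# genes data.frame -> GRanges with gene type/ID metadata (for GFF3 export)
GenomicRanges_from_genes <- function(genes) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  gr
}

#' Read a gene annotation from GFF3
#'
#' Loads `gene` features (or all features if no `type` column) from a GFF3
#' file into the plain data.frame layout used throughout the package.
#'
#' @param path GFF3 file.
#' @return data.frame with `gene_id`, `contig`, `strand`, `start`, `end`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% colnames(md)) gr <- gr[as.character(md$type) == "gene"]
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% colnames(md)) as.character(md$ID) else
    sprintf("gene%04d", seq_along(gr))
  data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}
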