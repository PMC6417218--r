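ann_plus <- data.frame(
  gene_id = c("gA", "gB"), contig = "c1", strand = "+",
  start = c(101L, 501L), end = c(400L, 1000L), stringsAsFactors = FALSE
)

test_that("operon members resolve to the transcription lead", {
  ops <- data.frame(operon_id = "op1", gene_id = c("g1", "g2", "g3"),
                    position_in_operon = 1:3, strand = "+",
                    stringsAsFactors = FALSE)
  expect_identical(resolve_anchor("g3", ops), "g1")
  expect_identical(resolve_anchor("g1", ops), "g1")
  expect_identical(resolve_anchor("solo", ops), "solo")
  expect_identical(resolve_anchor(c("g1", "g2", "g3"), ops),
                   rep("g1", 3))
  ann <- data.frame(gene_id = c("g1", "g2", "g3"), contig = "c",
                    strand = "+", start = 1:3, end = 4:6)
  expect_error(resolve_anchor("nope", ops, ann), class = "not_found")
})

test_that("plus-strand extraction takes the interval between the flanking ORFs", {
  r <- extract_promoter("gB", ann_plus)
  expect_equal(r$start, 401L)
  expect_equal(r$end, 500L)
  expect_equal(r$length, 100L)
  expect_false(r$truncated)
})

test_that("contig-edge anchors truncate at position 1 with a flag", {
  r <- extract_promoter("gA", ann_plus)
  expect_equal(c(r$start, r$end), c(1L, 100L))
  expect_true(r$truncated)
})

test_that("adjacent ORFs raise a degenerate-region error naming the genes", {
  ann <- data.frame(gene_id = c("gA", "gB"), contig = "c1", strand = "+",
                    start = c(101L, 401L), end = c(400L, 900L))
  err <- expect_error(extract_promoter("gB", ann),
                      class = "degenerate_region")
  expect_match(conditionMessage(err), "gB")
  expect_match(conditionMessage(err), "gA")
})

test_that("minus-strand extraction mirrors the plus-strand rule", {
  ann <- data.frame(gene_id = c("gA", "gB"), contig = "c1",
                    strand = c("-", "-"),
                    start = c(100L, 501L), end = c(400L, 1000L))
  r <- extract_promoter("gA", ann)
  expect_equal(c(r$start, r$end), c(401L, 500L))
  expect_equal(r$strand, "-")

  # mirror-image oracle: reverse-complement the coordinate system and
  # re-run the plus-strand rule
  set.seed(17)
  genome <- Biostrings::DNAStringSet(
    c(c1 = paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")))
  fl <- flip_annotation(ann, genome)
  r_flip <- extract_promoter("gA", fl$genes)
  expect_equal(r_flip$start, fl$lens[["c1"]] - r$end + 1L)
  expect_equal(r_flip$end, fl$lens[["c1"]] - r$start + 1L)
  seq_direct <- fetch_sequence(r, genome)$sequence
  seq_mirror <- fetch_sequence(r_flip, fl$genome)$sequence
  expect_identical(seq_direct, seq_mirror)
})

test_that("sequence slicing is 1-based inclusive with strand-aware orientation", {
  g <- Biostrings::DNAStringSet(c(c1 = "AACGT"))
  base <- data.frame(anchor_gene_id = "x", contig = "c1", strand = "+",
                     start = 2L, end = 4L, length = 3L, truncated = FALSE)
  expect_identical(fetch_sequence(base, g)$sequence, "ACG")
  base$strand <- "-"
  expect_identical(fetch_sequence(base, g)$sequence, "CGT")
  base$end <- 9L
  expect_error(fetch_sequence(base, g), class = "range_error")
  base$end <- 4L
  base$contig <- "nope"
  expect_error(fetch_sequence(base, g), class = "not_found")
})

test_that("fetched promoter sequences re-locate to their coordinates by string search", {
  ann <- simulate_annotation(n_genes = 40, operon_fraction = 0.3, seed = 13)
  prom <- extract_promoters(ann$genes$gene_id, ann$genes, ann$operons,
                            genome = ann$genome)
  expect_gt(nrow(prom), 10)
  for (i in sample(nrow(prom), 8)) {
    contig <- ann$genome[[prom$contig[i]]]
    q <- Biostrings::DNAString(prom$sequence[i])
    if (prom$strand[i] == "-") q <- Biostrings::reverseComplement(q)
    hits <- Biostrings::matchPattern(q, contig)
    expect_true(prom$start[i] %in% Biostrings::start(hits))
  }
})

test_that("every operon member maps to one shared promoter region", {
  ann <- simulate_annotation(n_genes = 60, operon_fraction = 0.5, seed = 19)
  for (op in split(ann$operons, ann$operons$operon_id)) {
    regions <- lapply(op$gene_id, function(g) {
      a <- resolve_anchor(g, ann$operons)
      extract_promoter(a, ann$genes,
                       setNames(Biostrings::width(ann$genome),
                                names(ann$genome)))
    })
    expect_length(unique(vapply(regions, function(r)
      paste(r$contig, r$start, r$end, r$strand), character(1))), 1L)
  }
})

test_that("extracted regions never overlap annotated ORFs (interval-tree oracle)", {
  for (seed in c(23, 29, 31)) {
    ann <- simulate_annotation(n_genes = 80, operon_fraction = 0.3,
                               seed = seed)
    prom <- extract_promoters(ann$genes$gene_id, ann$genes, ann$operons,
                              genome = ann$genome)
    ov <- GenomicRanges::countOverlaps(
      GenomicRanges::GRanges(prom$contig,
                             IRanges::IRanges(prom$start, prom$end)),
      GenomicRanges::GRanges(ann$genes$contig,
                             IRanges::IRanges(ann$genes$start,
                                              ann$genes$end)))
    expect_true(all(ov == 0L))
  }
})
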