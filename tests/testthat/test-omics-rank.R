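test_that("summaries are arithmetic means over the dataset's conditions", {
  m <- matrix(c(10, 12, 7, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  s <- summarize_dataset(omics_dataset(m, "microarray"))
  expect_equal(s$mean_log2[s$gene_id == "gA"], 11)
  one <- omics_dataset(m[, 1, drop = FALSE], "rnaseq")
  expect_equal(summarize_dataset(one)$mean_log2, unname(m[, 1]))
})

test_that("decile rule matches the hand-computed example on values 1..10", {
  s <- data.frame(gene_id = paste0("g", 1:10), platform = "microarray",
                  mean_log2 = 1:10)
  cl <- classify_by_quantile(s)
  expect_setequal(cl$gene_id[cl$label == "strong"], c("g9", "g10"))
  expect_setequal(cl$gene_id[cl$label == "weak"], "g1")
  expect_setequal(cl$gene_id[cl$label == "medium"], c("g4", "g5", "g6"))
})

test_that("a constant vector yields no labels and a warning", {
  s <- data.frame(gene_id = paste0("g", 1:20), platform = "rnaseq",
                  mean_log2 = 5)
  expect_warning(cl <- classify_by_quantile(s), "identical")
  expect_true(all(cl$label == "unlabeled"))
})

test_that("labels are monotone in the summary value within a platform", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(50)
    cl <- classify_by_quantile(
      data.frame(gene_id = paste0("g", 1:50), platform = "p",
                 mean_log2 = x))
    ord <- order(cl$mean_log2)
    expect_true(all(diff(cl$percentile_rank[ord]) >= 0))
    # every weak value sits below every medium value, which sits below
    # every strong value: raising a gene's mean never weakens its label
    w <- cl$mean_log2[cl$label == "weak"]
    m <- cl$mean_log2[cl$label == "medium"]
    s <- cl$mean_log2[cl$label == "strong"]
    if (length(w) && length(m)) expect_lt(max(w), min(m))
    if (length(m) && length(s)) expect_lt(max(m), min(s))
  }
})

test_that("tied floor values classify identically", {
  x <- c(rep(0.07, 5), seq(1, 5, length.out = 15))
  cl <- classify_by_quantile(
    data.frame(gene_id = paste0("g", 1:20), platform = "proteomics",
               mean_log2 = x))
  floor_labels <- unique(cl$label[cl$mean_log2 == 0.07])
  expect_length(floor_labels, 1L)
})

test_that("classifier recovers planted strong genes on a low-noise suite", {
  tr <- simulate_latent_strength(sprintf("g%03d", 1:200), seed = 21)
  suite <- simulate_omics_suite(
    tr, noise_sd = c(microarray = 0.1, rnaseq = 0.1, proteomics = 0.1),
    condition_sd = 0, seed = 22)
  cl <- classify_by_quantile(summarize_dataset(suite$microarray))
  planted <- sort(tr$gene_id[tr$class_truth == "strong"])
  strong <- sort(cl$gene_id[cl$label == "strong"])
  # the inclusive >= 90th percentile rule takes ceiling(0.1 n) + 1 genes for
  # n = 200, so at most one background gene rides along with the planted set
  expect_true(all(planted %in% strong))
  expect_lte(length(setdiff(strong, planted)), 1L)
  # percentile rank tracks the latent ordering
  rho <- cor(tr$latent_log2[match(cl$gene_id, tr$gene_id)],
             cl$percentile_rank, method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("consensus is the per-class intersection across required platforms", {
  vals <- setNames(1:10, paste0("g", 1:10))
  calls <- list(microarray = make_calls(vals, "microarray"),
                rnaseq = make_calls(vals, "rnaseq"),
                proteomics = make_calls(vals, "proteomics"))
  cs <- consensus_select(calls)
  one <- calls$microarray
  expect_setequal(cs$strong, one$gene_id[one$label == "strong"])
  expect_setequal(cs$weak, one$gene_id[one$label == "weak"])
  expect_setequal(cs$medium, one$gene_id[one$label == "medium"])

  # brute-force intersection oracle on shuffled platforms
  v2 <- setNames(c(10:1), paste0("g", 1:10))
  calls2 <- list(a = make_calls(vals, "microarray"),
                 b = make_calls(v2, "rnaseq"))
  cs2 <- consensus_select(calls2)
  sa <- calls2$a$gene_id[calls2$a$label == "strong"]
  sb <- calls2$b$gene_id[calls2$b$label == "strong"]
  expect_setequal(cs2$strong, intersect(sa, sb))
})

test_that("manually added weak candidates carry manual provenance", {
  vals <- setNames(1:10, paste0("g", 1:10))
  calls <- list(microarray = make_calls(vals, "microarray"))
  cs <- consensus_select(calls, extra_weak = "gX")
  expect_true("gX" %in% cs$weak)
  prov <- cs$provenance
  expect_equal(prov$provenance[prov$gene_id == "gX"], "manual")
  expect_equal(prov$label_microarray[prov$gene_id == "gX"], "absent")
  # consensus members are subsets of each platform's class (extras aside)
  non_manual <- prov[prov$provenance == "consensus", ]
  for (cl in c("strong", "medium", "weak")) {
    expect_true(all(non_manual$label_microarray[non_manual$class == cl] ==
                      cl))
  }
})

test_that("genes missing from one platform are excluded, not errored", {
  vals_a <- setNames(1:12, paste0("g", 1:12))
  vals_b <- setNames(2:12, paste0("g", 2:12)) # g1 absent
  calls <- list(a = make_calls(vals_a, "microarray"),
                b = make_calls(vals_b, "rnaseq"))
  expect_message(cs <- consensus_select(calls), "excluded")
  expect_false("g1" %in% unlist(cs[c("strong", "medium", "weak")]))
})
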