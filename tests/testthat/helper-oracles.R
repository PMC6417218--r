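# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# mean-rank percentile by direct counting: (#below + (#equal + 1)/2) / n
oracle_percentile <- function(x) {
  n <- length(x)
  vapply(x, function(v) (sum(x < v) + (sum(x == v) + 1) / 2) / n, numeric(1))
}

oracle_label <- function(pr, strong = 0.90, weak = 0.10,
                         med_lo = 0.40, med_hi = 0.60) {
  lab <- rep("unlabeled", length(pr))
  lab[pr >= strong] <- "strong"
  lab[pr <= weak] <- "weak"
  lab[pr >= med_lo & pr <= med_hi] <- "medium"
  lab
}

# mirror a gene annotation and genome onto the reverse complement
flip_annotation <- function(genes, genome) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  flipped <- genes
  flipped$start <- lens[genes$contig] - genes$end + 1L
  flipped$end <- lens[genes$contig] - genes$start + 1L
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  list(genes = flipped,
       genome = Biostrings::reverseComplement(genome),
       lens = lens)
}

# quick classification of a named value vector (used to build call tables)
make_calls <- function(values, platform) {
  classify_by_quantile(data.frame(gene_id = names(values),
                                  platform = platform,
                                  mean_log2 = unname(values)))
}

noiseless_flow_noise <- function(n_events = 100L) {
  flow_noise_params(copy_number_cv = 0, autofluor_mean = 0,
                    spillover_green_to_red = 0, channel_noise_cv = 0,
                    n_events = n_events)
}
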