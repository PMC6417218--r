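# dualprom

Omics-driven prediction of bacterial promoter strength, and its
quantification by a dual fluorescent reporter measured with flow cytometry.

## The problem

Metabolic engineering of bacteria such as *Zymomonas mobilis* needs
promoters and ribosome binding sites (RBSs) spanning a wide, known range of
strengths. Two obstacles stand in the way. First, most native promoters have
never been characterized, although years of systems-biology experiments
(microarray, RNA-seq, proteomics) already encode how strongly each gene is
expressed. Second, single-reporter measurements of promoter activity are
confounded by per-cell nuisances — above all plasmid copy number — that can
swamp the signal.

`dualprom` implements both halves of the answer:

1. **Predict.** Each platform's genes-by-conditions log2 expression matrix is
   collapsed to per-gene means. Within a platform, genes are classified by
   percentile rank: at or above the 90th percentile **strong**, at or below
   the 10th **weak**, inside the 40–60th band **medium**. A gene becomes a
   candidate only if all platforms agree on its class (Venn-style
   intersection). Each candidate is resolved to its promoter: the entire
   intergenic region between the gene — or, for operon members, the operon's
   lead gene — and the preceding open reading frame on either strand.
2. **Measure.** A two-reporter construct expresses EGFP from the element
   under test and opmCherry from a constitutive promoter. For a sample of
   ≥ 20,000 flow-cytometry events, the strength readout is

   ```
   ratio = mean(EGFP) / mean(opmCherry)
   ```

   Because plasmid copy number multiplies both channels of the same cell, it
   cancels from the ratio of means. Spectral spillover of EGFP into the red
   detector is removed by inverting a 2×2 spillover matrix. For inducible
   elements, strength is calibrated against a tetracycline titration
   (0–1.0 µg/mL), where the ratio responds linearly to concentration; an
   RBS's relative strength is the induced ratio minus the uninduced ratio.

Seeded simulators generate annotations (GFF3/FASTA/operon TSV), omics
matrices with a proteomics detection floor, and lognormal two-channel flow
events with copy-number variation, autofluorescence and spillover — so the
whole pipeline is testable end-to-end, and planted truths can be compared
with what the analysis recovers.

## Worked example

The package ships the reference table of 38 characterized *Z. mobilis*
promoters (19 strong, 9 medium, 10 weak). Their measured log-phase ratios
order the predicted classes:

```r
library(dualprom)
t1 <- load_table1_fixture()
ord <- class_ordering(data.frame(gene_id = t1$gene_id, class = t1$class),
                      data.frame(gene_id = t1$gene_id, ratio = t1$ratio_log))
print(ord)
#>    class  n mean_ratio         sd
#> 1 strong 19  0.1210526 0.09521290
#> 2 medium  9  0.0700000 0.04183300
#> 3   weak 10  0.0420000 0.01549193
#> monotone strong > medium > weak: TRUE
```

Strong promoters average a ratio of 0.121 against 0.042 for weak ones; the
strongest single promoter (P*gap*, ZMO0177) reaches 0.38.

Copy-number cancellation in action — triplicate simulated samples with a
50% CV in per-cell plasmid copies still return the true ratio 190/500 = 0.38
to a fraction of a percent:

```r
reps <- lapply(1:3, function(r)
  simulate_flow_sample(green_strength = 190, red_strength = 500,
                       flow_noise_params(copy_number_cv = 0.5), seed = r,
                       construct_id = "Pgap", replicate = r))
dual_ratio(reps)
#>   construct_id inducer_conc mean_green mean_red     ratio           sd
#> 1         Pgap            0   191.8496 505.7118 0.3793655 0.0008869485
```

And a simulated tetracycline titration of an inducible promoter recovers its
generative dose-response line (true ratio slope 0.4 per µg/mL):

```r
ser <- simulate_dose_series(200, dose_response_params(slope = 1, baseline = 0.1),
                            flow_noise_params(n_events = 20000),
                            replicates = 3, red_strength = 500, seed = 1)
linear_dose_fit(measure_constructs(ser, min_events = 20000))
#>   construct_id     slope  intercept r_squared n_points degenerate
#> 1         Ptet 0.3948535 0.04403472 0.9999953        6      FALSE
```

`run_synthetic_study()` runs the full chain — genome, omics, classification,
consensus, promoter extraction, flow measurement, validation — in memory and
reports how well the planted strong/weak promoter sets were recovered;
`simulate_study()` + `run_pipeline()` do the same through the on-disk file
contracts (GFF3, FASTA, TSV matrices, CSV event tables) and write
`calls.tsv`, `candidates.tsv`, `promoters.tsv/.fasta`, `measurements.tsv`
and `validation_report.json`.

## Documentation

The methods vignette (`vignettes/promoter-strength-pipeline.Rmd`) describes
the statistical model behind each stage, the simulators' assumptions, the
tunable parameters and their defaults, and known limitations.
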