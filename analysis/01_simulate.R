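#!/usr/bin/env Rscript
# Step 1 -- simulate the mapping experiment.
#
# Generates the synthetic F2 bulk-sequencing dataset the rest of the
# analysis runs on: 11 scaled 1 Mb chromosomes with ~2000 SNPs fixed
# between two inbred parents, 200 F2 plants segregating one fully
# penetrant recessive sterility locus (central SNP of chr6), bulks of
# 30 sterile and 30 fertile plants, pooled sequencing at 34x with 1%
# base error. Writes a four-sample VCF plus a truth sidecar (used only
# for scoring, never by the pipeline).

library(bsascan)

seed <- 1
dir.create("results", showWarnings = FALSE)

layout <- default_layout()
config <- sim_config(n_f2 = 200, bulk_size = 30, mean_depth = 34,
                     base_error = 0.01, seed = seed)
ds <- simulate_bsa_dataset(layout, config)
paths <- write_simulation(ds, "results/sim")

pop_sterile <- sum(ds$truth$is_causal)  # sanity: exactly one causal site
cat("simulated", nrow(ds$variants), "SNPs on",
    nrow(layout$chromosomes), "chromosomes\n")
cat("causal locus:", layout$causal$chrom, layout$causal$pos, "\n")
cat("mean pool depth (sterile bulk):",
    round(mean(ds$variants$ref_sterile + ds$variants$alt_sterile), 2), "\n")
cat("wrote", paths[["vcf"]], "and", paths[["truth"]], "\n")
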