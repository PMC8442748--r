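#!/usr/bin/env Rscript
# Step 2 -- four-rule variant filtering.
#
# Reads the simulated VCF back (the pipeline only ever sees the VCF,
# not the truth sidecar) and applies the four filtering rules:
# multiallelic sites, low read support (< 4 reads in a pool), same
# inferred genotype in both pools, and sterile-pool alleles absent
# from the sterile parent. Most unlinked loci fall to the same-genotype
# rule -- both bulks look heterozygous away from the trait locus --
# so the survivors concentrate on the causal chromosome.

library(bsascan)

variants <- read_bsa_vcf("results/sim.vcf")
res <- filter_variants(variants, min_support = 4)

counts <- filter_report_counts(res$report)
print(res$report)
cat("surviving sites:", counts[["output"]], "of", counts[["input"]], "\n")

utils::write.table(res$report, "results/filter_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_bsa_vcf(res$variants, "results/sim.filtered.vcf")
cat("wrote results/filter_report.tsv and results/sim.filtered.vcf\n")
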