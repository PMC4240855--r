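#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study bundle.
#
# Emulates the study inputs at 1/50 scale: ~401 protein-coding and ~259
# lncRNA genes (the genome-wide 20,074:12,933 composition), three disease
# phenotypes with four loci each, a quarter of loci shared across diseases,
# and some top SNPs withheld from the LD panels to exercise the 1 Mb
# fallback. Everything downstream reads the files written here.

suppressMessages(library(aidlnc))

seed <- 20260925
bundle_dir <- "results/synthetic_input"
b <- synth_bundle(bundle_dir, seed = seed,
                  n_diseases = 3, loci_per_disease = 4,
                  shared_fraction = 0.25, withheld_fraction = 0.15)

cat("Synthetic bundle written to", bundle_dir, "\n")
cat(sprintf("  genes: %d coding, %d lncRNA (ratio 1:%.1f)\n",
            b$truth$n_coding, b$truth$n_lncRNA,
            round(b$truth$n_coding / b$truth$n_lncRNA, 1)))
cat(sprintf("  planted loci: %d (%d fallback)\n",
            nrow(b$snp$locus_truth), sum(b$snp$locus_truth$fallback)))
cat(sprintf("  planted shared intervals: %d\n",
            if (is.null(b$snp$shared_truth)) 0 else nrow(b$snp$shared_truth)))
cat(sprintf("  expression: %d genes x %d cell types\n",
            nrow(b$expr$rpkm), ncol(b$expr$rpkm)))
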