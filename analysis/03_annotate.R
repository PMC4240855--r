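#!/usr/bin/env Rscript
# Stage 3: annotate loci with gene models; biotype composition and
# cross-disease gene sharing.

suppressMessages(library(aidlnc))

models <- parse_gtf("results/synthetic_input/annotation.gtf")
loci <- read_tsv("results/loci.tsv")

tab <- assign_genes_to_loci(models, loci)
write_tsv(tab, "results/locus_genes.tsv")

comp <- table(unique(tab[c("gene_id", "biotype_class")])$biotype_class)
cat(sprintf("%d distinct genes in %d loci: %s\n",
            length(unique(tab$gene_id)), length(unique(tab$locus_id)),
            paste(sprintf("%s=%d", names(comp), as.integer(comp)),
                  collapse = ", ")))
if (all(c("lncRNA", "protein_coding") %in% names(comp))) {
  cat(sprintf("  in-locus lncRNA:coding ratio 1:%.1f\n",
              comp[["protein_coding"]] / comp[["lncRNA"]]))
}

for (cls in c("lncRNA", "protein_coding")) {
  sh <- gene_sharing_matrix(tab, cls)
  write_tsv(data.frame(disease = rownames(sh$matrix), sh$matrix,
                       check.names = FALSE),
            sprintf("results/sharing_%s.tsv", cls))
  cat(sprintf("  %s: %d shared across >=2 diseases, %d disease-unique\n",
              cls, sh$n_shared, sh$n_unique))
}
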