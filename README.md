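# aidlnc

Disease-locus definition and immune-cell lncRNA expression analysis.

Most genome-wide significant risk variants for autoimmune and
immune-mediated diseases lie outside protein-coding sequence, often near
long non-coding RNA (lncRNA) genes. `aidlnc` is an R package plus a small
analysis workflow for researchers who want to ask, from top-SNP tables, LD
data, a gene annotation and per-cell-type RNA-seq expression: *which
immune cell types preferentially express the genes inside disease risk
loci, and what might the lncRNAs among them do?*

The pipeline:

- **Locus building** — a disease locus is the closed interval spanning a
  genome-wide significant top SNP (P ≤ 5×10⁻⁸) and its LD proxies
  (r² ≥ 0.5 within ±500 kb, both boundaries inclusive), with a 1 Mb
  fallback (SNP ±500 kb) for SNPs absent from every LD reference panel.
  Loci contained in a larger locus of the same disease are removed, and
  regions covered by ≥2 diseases are decomposed into shared regions with
  exact disease sets.
- **Annotation** — Gencode-style GTF parsing, lncRNA / protein-coding /
  other classification, ≥1 bp gene-to-locus assignment, cross-disease
  gene-sharing matrices.
- **Quantification** — SAM flag-1796 filtering, read counting under the
  inclusive ≥30%-of-read-length exon-union overlap rule, and
  RPKM = 10⁹·C/(N·L). A gene is *expressed* at RPKM > 2; log display maps
  0 to log₁₀(10⁻⁶) = −6.
- **Enrichment** — two-tailed Fisher's exact test on expressed-fraction
  2×2 tables per cell type, Bonferroni-corrected within each dataset
  (m = 7 peripheral cell types, m = 4 cord-blood T-helper lineages) with
  */**/*** tiers at α = 0.05/0.01/0.005; Wilcoxon rank-sum distribution
  comparisons; UPGMA/Euclidean sample clustering.
- **Co-expression** — guilt-by-association partner ranking by |Pearson r|
  on log₁₀ profiles, hypergeometric gene-set enrichment of the top
  partners, and within-locus lncRNA × coding pair reports.
- **Synthetic data** — a deterministic generator that plants loci, shared
  regions, biotype ratios, expressed fractions and read counts with known
  truth, so every stage is testable offline.

## Worked example

The bundled workflow (`analysis/01_simulate.R` … `06_coexpression.R`)
runs the whole study on a synthetic bundle at 1/50 genome scale. Stage 2,
locus definition on the generated inputs, prints:

```
12 top SNPs -> 12 loci after containment deduplication
  fallback (1 Mb) loci: 3; mean locus width 344 kb
  shared regions (>=2 diseases): 1
  widest shared region: chr1:2394904-2530723 (D01;D02;D03)
```

i.e. 12 genome-wide significant SNPs yield 12 loci (three defined by the
1 Mb fallback because their SNPs were withheld from the LD panels), and
one region is covered by loci of all three simulated diseases — exactly
the planted interval. Stage 5, the enrichment scan, prints:

```
enrichment scan: 88 tests (8 gene sets x 11 cell types)
  Bonferroni thresholds, peripheral (m=7): 0.007 / 0.001 / 0.0007
  Bonferroni thresholds, cord blood (m=4): 0.012 / 0.002 / 0.0012
  pooled locus lncRNAs: tier>=1 in 3/11 cell types (max stars '*')
```

The thresholds are the per-test significance cut-offs after Bonferroni
correction within each cell-type dataset, and the last line says the
planted two-fold expressed-fraction enrichment of in-locus lncRNAs is
detected in three cell types at this small scale.

In code, the same machinery directly:

```r
library(aidlnc)
b <- synth_bundle(tempfile(), seed = 1)
loci <- deduplicate_loci(build_loci(b$snp$top_snps, b$snp$ld_tables))
find_shared_regions(loci)
rp <- b$expr$rpkm
expressed_fraction_test(rp, rownames(rp)[b$genes$in_locus],
                        rownames(rp), "NK", m = 7)
```

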