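---
title: "Methods: disease-locus definition and immune-cell lncRNA expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-locus definition and immune-cell lncRNA expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidlnc)
```

## The problem

Most risk variants for autoimmune and immune-mediated diseases fall outside
protein-coding sequence, in regions that increasingly turn out to harbour
long non-coding RNA (lncRNA) genes. `aidlnc` implements a locus-centric
workflow for asking which immune cell types preferentially express the
genes — coding and non-coding — that sit inside disease-associated loci:

1. define a genomic locus around each genome-wide significant top SNP from
   its linkage-disequilibrium (LD) proxies;
2. annotate loci with gene models classified as lncRNA, protein-coding or
   other;
3. quantify expression (read counting and RPKM) across immune cell types;
4. test whether locus genes are expressed in a cell type more often than
   the genome-wide background (expressed-fraction enrichment);
5. rank co-expression partners of individual lncRNAs
   (guilt-by-association).

A deterministic synthetic-data generator plants known structure at every
stage so the whole pipeline is testable without any external download.

## Locus definition

A top SNP is admitted when its association P-value is at most
$5\times10^{-8}$. Its locus is the closed 1-based interval spanning the SNP
and all LD proxies with $r^2 \ge 0.5$ within $\pm 500$ kb; both boundaries
are inclusive. Internally every interval is 1-based closed, which makes
printed locus coordinates round-trip bit-exactly; BED emission converts to
0-based half-open.

Two LD reference panels are accepted as an ordered list; the first panel
containing the SNP is used. A top SNP found in no panel falls back to a
1 Mb locus (SNP $\pm 500$ kb). A SNP that *is* in a panel but has no proxy
passing the $r^2$ filter yields a singleton interval with a warning — the
fallback rule is reserved for SNPs absent from the references — with
`no_proxy_fallback = TRUE` available to apply the 1 Mb rule there too. A
flank running off the chromosome start is clipped at base 1, with a
warning. No padding is added beyond the outermost proxy: the locus ends at
the outermost qualifying SNP position.

A locus wholly contained in a larger locus of the *same* disease is
removed (`deduplicate_loci`); identical intervals of different diseases
are all kept, because locus counts are reported per disease. The operation
is idempotent and order-stable.

`find_shared_regions` decomposes the loci of all diseases into maximal
segments covered by at least two distinct diseases, each annotated with
its exact disease set. Touching segments with identical disease sets are
merged; segments separated by a gap are not, even if their disease sets
agree. One subtlety is deliberate: when two loci of one disease tile a
region without either covering all of it, the merged segment's
`source_loci` field lists only loci containing the *entire* segment, so
that every reported region is guaranteed to be a subset of each of its
source loci. The decomposition is verified in the test suite against a
per-base labelling oracle.

## Annotation

`parse_gtf` ingests a Gencode-style GTF (via `rtracklayer`) and computes
each gene's exonic length $L_g$ as the length of the union of its exon
intervals — overlapping exons count once. Biotype classification is a
configurable map; the default sends the Gencode-v14-era long-non-coding
biotypes (`lincRNA`, `antisense`, `sense_intronic`, `sense_overlapping`,
`3prime_overlapping_ncrna`, `processed_transcript`) to `lncRNA`,
`protein_coding` to itself, and everything else to `other`. The annotation
itself is authoritative for class membership; no coding-potential
prediction is attempted.

Gene-to-locus assignment uses whole-gene-body overlap of at least one base
(closed intervals, so adjacency is not overlap); an exon-only mode is
available behind `mode = "exon"`. A gene may appear under many loci and
diseases; within one disease it counts once. `gene_sharing_matrix` then
counts distinct genes per disease pair and reports the per-gene number of
diseases — the input for circular sharing diagrams.

## Expression quantification

Alignment records are filtered by SAM flag mask 1796 (unmapped, secondary,
QC-fail, duplicate); the number of surviving records is the sample's
mapped-read total $N$. A read counts toward gene $g$ when the overlap of
its aligned blocks with $g$'s exon union is at least 30% of the read
length, inclusively at the boundary. A read qualifying for several genes
counts toward each by default (independent per-feature evaluation, the
behaviour of interval-intersection counting); `assignment = "unique"`
keeps the best-overlap gene and drops ties, for sensitivity analysis.

$$\mathrm{RPKM}_g = 10^9 \cdot \frac{C_g}{N \cdot L_g}$$

A gene is *expressed* when RPKM is strictly greater than 2; a value of
exactly 2 is not expressed. For log display and correlation, zeros are
replaced by $10^{-6}$ before $\log_{10}$ (so 0 maps to exactly $-6$);
non-zero values are transformed unchanged. Adding the offset to every
value is available behind `offset_all = TRUE` as the common alternative.

## Enrichment statistics

For a gene set (e.g. the lncRNAs of one disease's loci) and one cell
type, `expressed_fraction_test` builds the 2×2 table of expressed versus
not, set versus background, and applies the two-tailed Fisher's exact
test. The two-sided convention is the standard one — the sum of
hypergeometric point probabilities not exceeding the observed table's
(with the usual $1+10^{-7}$ relative tolerance). By default the
background is the full annotation, a superset that includes the set
itself; `background_mode = "disjoint"` subtracts it first.

Multiple testing uses Bonferroni with $m$ = the number of cell types in
the dataset containing the tested cell type — 7 for the peripheral
immune panel and 4 for the cord-blood T-helper lineages — and *not* the
number of diseases; the two datasets are corrected independently. Star
tiers are assigned at $\alpha = 0.05, 0.01, 0.005$, i.e. per-test
thresholds $\alpha/m$. For reporting, thresholds are truncated (not
rounded) to one more decimal place than the significance level, which
renders the corrected thresholds as 0.007/0.001/0.0007 ($m=7$) and
0.012/0.002/0.0012 ($m=4$).

Distribution-level comparisons use the two-sided Wilcoxon rank-sum test:
exact for small untied samples, normal approximation with tie correction
otherwise; two identical constant groups give $P = 1$ by convention.
Heat-map ordering uses unsupervised UPGMA (average-linkage) clustering of
sample columns on Euclidean distances of the log10 matrix.

## Guilt-by-association co-expression

`coexpression_rank` correlates a query lncRNA's log10 profile across cell
types with every other gene's and ranks partners by $|r|$ (ties broken by
gene id). Genes with profile standard deviation below `min_sd` (default
$10^{-8}$) are excluded; a constant query is an error. Pearson correlation
on the log10 scale is the default and Spearman is available — the metric
behind published co-expression predictors is not fixed, so ours is an
explicit, documented stand-in. `gene_set_enrichment` scores the top-$k$
partners (default $k = 100$; no canonical value exists, and results
should be read as a ranking, not a calibrated P) against user-supplied
gene sets (GMT) with the upper-tail hypergeometric test.
`locus_pair_report` lists all lncRNA × protein-coding pairs co-located in
a locus with their correlation — the candidate cis-regulated pairs.

## The synthetic study

The generator's defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| gene counts | 20,074 coding : 12,933 lncRNA, scaled 1/50 (401:259) | genome-wide composition; the 1:1.6 coding:lncRNA ratio |
| expressed fraction | 0.47 coding, 0.15 lncRNA | genome-wide per-cell-type probability of being "on" |
| enrichment multiplier | 2 | in-locus fold increase of the "on" probability |
| in-locus composition | 1 lncRNA : 3 coding per locus block | the in-locus 1:3 ratio |
| cell types | 7 peripheral + 4 cord-blood | the Bonferroni datasets |
| expressed values | shifted log-normal above 2 RPKM; coding mean 14, in-locus lncRNA mean 7, background lncRNA 2.8 | in-locus lncRNAs ~2-fold below coding; locus lncRNAs ~2.5-fold above background lncRNAs |
| library size | 137,411,294 | nominal mapped reads per sample |

Biotype and in-locus allocation is deterministic (exact counts, not
sampling), so small fixtures hit the configured ratios exactly; only
positions, expression draws and $r^2$ values are random, from one seeded
stream per generator stage derived from the master seed. Loci are planted
as blocks of consecutive genes: the top SNP sits at the block midpoint and
the boundary proxies at the block's outer gene coordinates, so a correct
locus builder recovers the planted interval bit-exactly. Shared loci are
planted by letting a later disease reuse an earlier disease's block;
withheld top SNPs exercise the 1 Mb fallback. Read-level records straddle
the 30% boundary (one read exactly at threshold, decoys one base below)
and carry each filtered flag bit, so `filter_alignments` +
`count_reads` must recover the planted counts exactly.

What the generator does *not* emulate: nucleotide sequence, realistic LD
decay or population structure, spliced-alignment complications beyond the
provided blocks, between-sample library-size variation, and correlated
expression modules beyond the planted on/off structure. Passing tests
therefore demonstrate the correctness of the interval logic, counting
rules and statistics under controlled conditions — not robustness to
alignment artefacts or annotation errors in real data.

## Numerical and design choices

- Intervals: 1-based closed everywhere internally; conversion happens only
  at the BED boundary. Closed-interval adjacency is not overlap.
- Fisher two-sided: point-probability convention (not doubling the
  one-sided P); the test suite checks it against exhaustive enumeration
  for all tables with total count ≤ 30.
- Truncation, not rounding, for threshold display, matching how corrected
  thresholds are conventionally quoted.
- Clustering ties: `hclust` is deterministic given the input order;
  column permutations preserve merge heights (checked in tests).
- Degenerate inputs: all-zero contingency tables, zero-length genes,
  zero-read libraries and constant co-expression queries are errors;
  proxy-less referenced SNPs and clipped flanks are warnings.
- The deduplication worked example (33 → 32 psoriasis loci via the two
  nested chr19 intervals) and the six printed Bonferroni thresholds are
  recomputed in the acceptance suite.

## Problem sizes

The bundled analysis scripts and the test suite run the study at 1/50
genome scale (660 genes, 12 loci, 11 cell types), which keeps every stage
in seconds while preserving the planted ratios exactly. The statistical
property suites use 500 null replicates (family-wise error control of the
scan at 2,240 genes — the error-rate property is scale-free) and 200
power replicates at the full 240-versus-12,933 gene-set size, where the
planted two-fold enrichment is designed to be detected in at least 80% of
runs. Full-scale gene counts are available via `synth_truth(scale = 1)`.

## Known limitations

- Locus membership for fallback (1 Mb) loci is position-driven, so the
  realised in-locus biotype ratio of a whole synthetic study drifts from
  the planted 1:3 toward the genome-wide mixture as fallback loci widen.
- The expressed-fraction test treats cell types independently; no attempt
  is made to model correlation between cell types of one donor.
- Gene-level aggregation only: isoform-level quantification is out of
  scope, as is read alignment itself (records arrive aligned).
- The co-expression module ranks partners within the provided matrix; it
  does not reproduce any external multi-tissue co-expression database.
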