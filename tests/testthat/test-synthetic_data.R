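test_that("annotation generator hits configured biotype counts exactly and round-trips", {
  truth <- synth_truth(seed = 3, n_coding = 160, n_lncRNA = 100)
  m <- generate_annotation(truth)
  tab <- table(m$genes$biotype_class)
  expect_equal(as.integer(tab["protein_coding"]), 160)
  expect_equal(as.integer(tab["lncRNA"]), 100)
  expect_equal(160 / 100, 1.6)  # planted genome-wide style ratio 1:1.6

  # genes never overlap within a chromosome
  for (ch in unique(m$genes$chrom)) {
    g <- m$genes[m$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }

  # determinism: same (parameters, seed) gives byte-identical GTF
  p1 <- tempfile(); p2 <- tempfile()
  generate_annotation(truth, gtf_path = p1)
  generate_annotation(synth_truth(seed = 3, n_coding = 160, n_lncRNA = 100),
                      gtf_path = p2)
  expect_identical(readLines(p1), readLines(p2))

  # parser recovers every planted span, biotype and exon union
  back <- parse_gtf(p1)
  expect_equal(back$genes$start, m$genes$start)
  expect_equal(back$genes$end, m$genes$end)
  expect_equal(back$genes$biotype_class, m$genes$biotype_class)
  expect_equal(back$genes$exonic_length, m$genes$exonic_length)

  expect_error(generate_annotation(synth_truth(n_coding = 4, n_lncRNA = 2),
                                   n_locus_blocks = 10), "too small")
})

test_that("planted loci are recovered exactly by the locus builder", {
  truth <- synth_truth(seed = 5)
  m <- generate_annotation(truth, n_locus_blocks = 10)
  snp <- generate_ld_and_snps(truth, m, n_diseases = 3, loci_per_disease = 4,
                              shared_fraction = 0.25, withheld_fraction = 0.25)
  loci <- build_loci(snp$top_snps, snp$ld_tables)
  lt <- snp$locus_truth
  expect_equal(nrow(loci), nrow(lt))
  for (i in seq_len(nrow(lt))) {
    got <- loci[loci$top_snp == lt$top_snp[i], ]
    expect_equal(c(got$start, got$end), c(lt$start[i], lt$end[i]))
    expect_equal(got$fallback, lt$fallback[i])
  }
  # withheld SNPs produce exactly the fallback width
  fb <- loci[loci$fallback, ]
  expect_true(nrow(fb) > 0)
  expect_true(all(fb$end - fb$start + 1 == 1000001))

  # planted shared intervals are recovered with the planted disease pairs
  shared <- find_shared_regions(loci)
  st <- snp$shared_truth
  for (i in seq_len(nrow(st))) {
    hit <- shared[shared$chrom == st$chrom[i] & shared$start <= st$start[i] &
                    shared$end >= st$end[i], ]
    expect_equal(nrow(hit), 1)
    expect_true(all(strsplit(st$diseases[i], ";")[[1]] %in%
                      strsplit(hit$diseases, ";")[[1]]))
  }

  # zero shared fraction plants no cross-disease overlap
  truth0 <- synth_truth(seed = 6)
  m0 <- generate_annotation(truth0, n_locus_blocks = 12)
  snp0 <- generate_ld_and_snps(truth0, m0, n_diseases = 3,
                               loci_per_disease = 4, shared_fraction = 0,
                               withheld_fraction = 0)
  loci0 <- build_loci(snp0$top_snps, snp0$ld_tables)
  expect_equal(nrow(find_shared_regions(loci0)), 0)
})

test_that("expression generator plants recoverable expressed fractions", {
  truth <- synth_truth(seed = 13)
  genes <- data.frame(gene_id = sprintf("g%d", 1:10000),
                      biotype_class = rep(c("lncRNA", "protein_coding"), 5000),
                      in_locus = FALSE)
  ex <- generate_expression(truth, genes)
  expect_true(all(ex$rpkm >= 0))
  # planted "on" entries sit strictly above the threshold, "off" at or below
  expect_true(all(ex$rpkm[ex$on] > 2))
  expect_true(all(ex$rpkm[!ex$on] <= 2))
  # observed expressed fraction within 3 binomial SDs of the planted fraction
  for (cls in c("lncRNA", "protein_coding")) {
    idx <- genes$biotype_class == cls
    p <- truth$expressed_frac[cls]
    for (ct in truth$cell_types[c(1, 8)]) {
      obs <- mean(is_expressed(ex$rpkm[idx, ct]))
      expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / sum(idx)))
    }
  }
  # determinism
  ex2 <- generate_expression(synth_truth(seed = 13), genes)
  expect_identical(ex$rpkm, ex2$rpkm)
})

test_that("read generator plants counts recovered exactly through filter and count", {
  truth <- synth_truth(seed = 17, n_coding = 8, n_lncRNA = 4,
                       gene_gap = c(500, 900), n_chroms = 1)
  m <- generate_annotation(truth)
  targets <- setNames(c(7L, 0L, 3L, 1L),
                      m$genes$gene_id[c(1, 3, 5, 8)])
  rec <- generate_reads(truth, m, targets, n_fail_boundary = 3, n_flagged = 2)
  kept <- filter_alignments(rec)
  counts <- count_reads(kept, m)
  got <- setNames(counts$count, counts$gene_id)[names(targets)]
  expect_equal(got, targets)
  # untargeted genes get zero
  expect_true(all(counts$count[!counts$gene_id %in% names(targets)] == 0L))

  # all reads carrying a filtered flag bit leave N = 0, and rpkm then errors
  all_flagged <- rec[bitwAnd(rec$flag, 1796L) != 0L, ]
  expect_equal(nrow(filter_alignments(all_flagged)), 0)
  expect_error(rpkm(0, 1000, nrow(filter_alignments(all_flagged))),
               "mapped reads")
})

test_that("the synthetic bundle is reproducible byte for byte", {
  d1 <- tempfile("b1"); d2 <- tempfile("b2")
  b1 <- synth_bundle(d1, seed = 23)
  b2 <- synth_bundle(d2, seed = 23)
  for (f in c("annotation.gtf", "top_snps.tsv", "ld_panel1.tsv",
              "ld_panel2.tsv", "expression.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # generated files are accepted by the parsers without warnings
  expect_no_warning(parse_gtf(b1$paths$gtf))
  expect_no_warning(read_top_snps(b1$paths$top_snps))
  expect_no_warning(read_ld_table(b1$paths$ld[1]))
  expect_no_warning(read_expression_tsv(b1$paths$expression))
  unlink(c(d1, d2), recursive = TRUE)
})
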