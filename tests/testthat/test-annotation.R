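test_that("exonic length is the union of exon intervals", {
  genes <- data.frame(gene_id = c("gA", "gB"), name = c("gA", "gB"),
                      chrom = "chr1", strand = "+",
                      start = c(1, 10), end = c(150, 109),
                      biotype_raw = "protein_coding")
  exons <- data.frame(gene_id = c("gA", "gA", "gB"), chrom = "chr1",
                      start = c(1, 51, 10), end = c(100, 150, 109))
  m <- gene_models(genes, exons)
  # overlapping exons [1,100] and [51,150] count once: union length 150
  expect_equal(m$genes$exonic_length[m$genes$gene_id == "gA"], 150)
  expect_equal(m$genes$exonic_length[m$genes$gene_id == "gB"], 100)
})

test_that("exonic length equals a per-base union oracle on random toy genes", {
  set.seed(5)
  for (rep in 1:20) {
    ne <- sample(1:6, 1)
    start <- sample(1:500, ne)
    exons <- data.frame(gene_id = "g", chrom = "chr1", start = start,
                        end = start + sample(10:100, ne, replace = TRUE))
    genes <- data.frame(gene_id = "g", name = "g", chrom = "chr1",
                        strand = "+", start = min(exons$start),
                        end = max(exons$end), biotype_raw = "lincRNA")
    m <- gene_models(genes, exons)
    per_base <- length(unique(unlist(mapply(seq, exons$start, exons$end,
                                            SIMPLIFY = FALSE))))
    expect_equal(m$genes$exonic_length, per_base)
  }
})

test_that("biotype classification follows the configured map with an other default", {
  expect_equal(classify_biotype("protein_coding"), "protein_coding")
  expect_equal(classify_biotype("lincRNA"), "lncRNA")
  expect_equal(classify_biotype("antisense"), "lncRNA")
  expect_equal(classify_biotype("miRNA"), "other")
  expect_equal(classify_biotype("made_up_biotype"), "other")
  # a custom map overrides the default
  expect_equal(classify_biotype("miRNA", c(miRNA = "lncRNA")), "lncRNA")
})

test_that("GTF round-trip recovers spans, biotypes and exon unions", {
  m <- toy_models()
  path <- tempfile(fileext = ".gtf")
  write_gtf(m, path)
  back <- parse_gtf(path)
  expect_equal(back$genes$gene_id, m$genes$gene_id)
  expect_equal(back$genes$start, m$genes$start)
  expect_equal(back$genes$end, m$genes$end)
  expect_equal(back$genes$biotype_class, m$genes$biotype_class)
  expect_equal(back$genes$exonic_length, m$genes$exonic_length)
  # round-trip through BED-style span export preserves intervals
  bed <- tempfile(fileext = ".bed")
  write_locus_bed(data.frame(chrom = m$genes$chrom, start = m$genes$start,
                             end = m$genes$end, locus_id = m$genes$gene_id),
                  bed)
  spans <- read_locus_bed(bed)
  expect_equal(spans$start, m$genes$start)
  expect_equal(spans$end, m$genes$end)
})

test_that("gene-to-locus assignment uses >= 1 bp overlap, closed intervals", {
  genes <- data.frame(gene_id = c("g1", "g2"), name = c("g1", "g2"),
                      chrom = "chr1", strand = "+",
                      start = c(100, 100), end = c(200, 200),
                      biotype_raw = "protein_coding")
  exons <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(100, 100), end = c(200, 200))
  m <- gene_models(genes, exons)
  loci <- data.frame(locus_id = c("L1", "L2"), disease = c("RA", "RA"),
                     chrom = "chr1", start = c(150, 201), end = c(400, 400))
  tab <- assign_genes_to_loci(m, loci)
  # partial overlap qualifies; adjacency (locus starting at 201) does not
  expect_true(all(tab$locus_id == "L1"))
  expect_setequal(tab$gene_id, c("g1", "g2"))
})

test_that("assignment agrees with a brute-force pairwise overlap oracle", {
  set.seed(21)
  for (rep in 1:10) {
    ng <- 12
    gs <- sample(1:2000, ng)
    genes <- data.frame(gene_id = sprintf("g%d", 1:ng),
                        name = sprintf("g%d", 1:ng), chrom = "chr1",
                        strand = "+", start = gs,
                        end = gs + sample(20:300, ng, replace = TRUE),
                        biotype_raw = "lincRNA")
    exons <- data.frame(gene_id = genes$gene_id, chrom = "chr1",
                        start = genes$start, end = genes$end)
    m <- gene_models(genes, exons)
    nl <- 5
    ls <- sample(1:2000, nl)
    loci <- data.frame(locus_id = sprintf("L%d", 1:nl), disease = "X",
                       chrom = "chr1", start = ls,
                       end = ls + sample(50:500, nl, replace = TRUE))
    tab <- assign_genes_to_loci(m, loci)
    want <- expand.grid(g = 1:ng, l = 1:nl)
    want$hit <- genes$start[want$g] <= loci$end[want$l] &
      genes$end[want$g] >= loci$start[want$l]
    got_pairs <- paste(tab$locus_id, tab$gene_id)
    want_pairs <- paste(loci$locus_id[want$l[want$hit]],
                        genes$gene_id[want$g[want$hit]])
    expect_setequal(got_pairs, want_pairs)
  }
})

test_that("gene-sharing matrix counts distinct genes per disease pair", {
  tab <- data.frame(
    locus_id = c("L1", "L2", "L3", "L4", "L5", "L6"),
    disease = c("RA", "CeD", "RA", "RA", "UC", "CeD"),
    gene_id = c("g1", "g1", "g2", "g2", "g2", "g3"),
    biotype_class = "lncRNA")
  sh <- gene_sharing_matrix(tab, "lncRNA")
  # g1 in {RA, CeD}; g2 in {RA, UC} (twice in RA counts once); g3 unique
  expect_equal(sh$matrix["RA", "CeD"], 1)
  expect_equal(sh$matrix["RA", "UC"], 1)
  expect_equal(sh$matrix["CeD", "UC"], 0)
  expect_true(isSymmetric(sh$matrix))
  expect_true(all(diag(sh$matrix) == 0))
  expect_equal(sh$n_shared, 2)
  expect_equal(sh$n_unique, 1)
  expect_equal(sh$per_gene$n_diseases[sh$per_gene$gene_id == "g2"], 2)

  # no multi-disease genes: zero matrix
  solo <- data.frame(locus_id = c("L1", "L2"), disease = c("RA", "UC"),
                     gene_id = c("a", "b"), biotype_class = "lncRNA")
  expect_true(all(gene_sharing_matrix(solo, "lncRNA")$matrix == 0))
})

test_that("sharing matrix matches a set-intersection oracle on random tables", {
  set.seed(33)
  diseases <- c("RA", "CeD", "UC", "PS")
  for (rep in 1:15) {
    n <- 40
    tab <- data.frame(
      locus_id = sprintf("L%d", sample(1:10, n, replace = TRUE)),
      disease = sample(diseases, n, replace = TRUE),
      gene_id = sprintf("g%d", sample(1:15, n, replace = TRUE)),
      biotype_class = "lncRNA")
    sh <- gene_sharing_matrix(tab, "lncRNA")
    sets <- lapply(split(tab$gene_id, tab$disease), unique)
    for (d1 in names(sets)) for (d2 in names(sets)) {
      if (d1 == d2) next
      expect_equal(sh$matrix[d1, d2], length(intersect(sets[[d1]], sets[[d2]])))
    }
    # histogram identity: genes in >= 2 diseases
    expect_equal(sh$n_shared + sh$n_unique, length(unique(tab$gene_id)))
    # per-disease identity: unique + shared = distinct genes of the disease
    for (d in names(sets)) {
      pg <- sh$per_gene[sh$per_gene$gene_id %in% sets[[d]], ]
      expect_equal(sum(pg$n_diseases == 1) + sum(pg$n_diseases >= 2),
                   length(sets[[d]]))
    }
  }
})
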