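test_that("proxy expansion applies inclusive r2 and window boundaries", {
  top <- list(rsid = "rs1", pos = 1000000)
  ld <- data.frame(
    rsid_a = "rs1", pos_a = 1000000,
    rsid_b = c("rs2", "rs3", "rs4", "rs5"),
    pos_b = c(1050000, 1100000, 1600001, 1500000),
    r2 = c(0.80, 0.49, 0.90, 0.50))
  got <- expand_proxies(top, ld)
  # rs2 passes both filters; rs3 fails r2; rs4 is 600,001 bp away;
  # rs5 sits exactly at r2 = 0.5 and exactly 500,000 bp away
  expect_setequal(got$rsid, c("rs2", "rs5"))

  # symmetric pairs: top SNP on the b side is found too
  ld_sym <- data.frame(rsid_a = "rs9", pos_a = 990000,
                       rsid_b = "rs1", pos_b = 1000000, r2 = 0.7)
  expect_equal(expand_proxies(top, ld_sym)$rsid, "rs9")

  # missing partner position: skipped with a warning, not fatal
  ld_na <- data.frame(rsid_a = "rs1", pos_a = 1000000,
                      rsid_b = c("rs2", "rs6"), pos_b = c(1050000, NA),
                      r2 = c(0.8, 0.9))
  expect_warning(got <- expand_proxies(top, ld_na), "missing position")
  expect_equal(got$rsid, "rs2")
})

test_that("locus definition spans proxies, falls back to 1 Mb, and clips", {
  top <- list(rsid = "rs1", chrom = "chr1", pos = 1000000, disease = "RA")
  prox <- data.frame(rsid = c("a", "b"), pos = c(950000, 1050000))
  loc <- define_locus(top, prox)
  expect_equal(c(loc$start, loc$end), c(950000, 1050000))
  expect_false(loc$fallback)
  expect_true(loc$start <= top$pos && top$pos <= loc$end)

  # absent from every LD reference: 1 Mb region centred on the SNP
  fb <- define_locus(top, NULL, snp_in_reference = FALSE)
  expect_equal(fb$end - fb$start + 1, 1000001)
  expect_true(fb$fallback)

  # flank running off the chromosome start is clipped at 1
  near <- list(rsid = "rs2", chrom = "chr1", pos = 400000, disease = "RA")
  expect_warning(cl <- define_locus(near, NULL, snp_in_reference = FALSE),
                 "clipped")
  expect_equal(c(cl$start, cl$end), c(1, 900000))

  # in-reference SNP with zero passing proxies: singleton interval
  expect_warning(sg <- define_locus(top, prox[0, ]), "singleton")
  expect_equal(c(sg$start, sg$end), c(top$pos, top$pos))
  # ... unless the no-proxy fallback switch applies the 1 Mb rule
  nf <- suppressWarnings(define_locus(top, prox[0, ], no_proxy_fallback = TRUE))
  expect_true(nf$fallback)
  expect_equal(nf$end - nf$start + 1, 1000001)
})

test_that("build_loci admits only genome-wide significant SNPs and honours panel order", {
  snps <- data.frame(
    disease = "RA", rsid = c("rs1", "rs2", "rs3"), chrom = "chr1",
    pos = c(1e6, 3e6, 8e6), pvalue = c(1e-9, 5e-8, 1e-6))
  panel1 <- data.frame(rsid_a = "rs1", pos_a = 1e6, rsid_b = "p1",
                       pos_b = 1.1e6, r2 = 0.9)
  panel2 <- data.frame(rsid_a = c("rs1", "rs2"), pos_a = c(1e6, 3e6),
                       rsid_b = c("q1", "q2"), pos_b = c(1.4e6, 3.2e6),
                       r2 = c(0.8, 0.7))
  expect_warning(loci <- build_loci(snps, list(panel1, panel2)), "excluded")
  expect_equal(nrow(loci), 2)  # rs3 at P = 1e-6 is out
  # rs1 is in panel1, so panel2's wider proxy q1 must not be used
  expect_equal(loci$end[loci$top_snp == "rs1"], 1.1e6)
  expect_equal(loci$end[loci$top_snp == "rs2"], 3.2e6)
})

test_that("containment deduplication removes nested loci per disease only", {
  mk <- function(d, s, e) data.frame(chrom = "chr19", start = s, end = e,
                                     disease = d)
  # three nested loci of one disease collapse to the outermost
  nested <- rbind(mk("PS", 100, 1000), mk("PS", 200, 900), mk("PS", 300, 400))
  got <- deduplicate_loci(nested)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 100)

  # no containment: input unchanged (up to deterministic order)
  flat <- rbind(mk("PS", 100, 500), mk("PS", 400, 900))
  expect_equal(nrow(deduplicate_loci(flat)), 2)

  # identical intervals of different diseases are both kept
  cross <- rbind(mk("PS", 100, 500), mk("RA", 100, 500), mk("RA", 200, 300))
  got <- deduplicate_loci(cross)
  expect_setequal(got$disease, c("PS", "RA"))
  expect_equal(nrow(got), 2)

  # idempotent and never increasing
  again <- deduplicate_loci(got)
  expect_equal(again, got)
})

test_that("shared-region decomposition matches the worked three-disease example", {
  loci <- data.frame(chrom = "toy",
                     start = c(100, 200, 250),
                     end = c(300, 400, 350),
                     disease = c("X", "Y", "Z"))
  got <- find_shared_regions(loci)
  expect_equal(got$start, c(200, 250, 301))
  expect_equal(got$end, c(249, 300, 350))
  expect_equal(got$diseases, c("X;Y", "X;Y;Z", "Y;Z"))

  # pairwise intersection
  two <- data.frame(chrom = "toy", start = c(100, 150), end = c(200, 250),
                    disease = c("X", "Y"))
  got2 <- find_shared_regions(two)
  expect_equal(c(got2$start, got2$end), c(150, 200))

  # disjoint loci share nothing
  dj <- data.frame(chrom = "toy", start = c(100, 500), end = c(200, 600),
                   disease = c("X", "Y"))
  expect_equal(nrow(find_shared_regions(dj)), 0)
})

test_that("every shared region is contained in each contributing locus", {
  set.seed(11)
  for (rep in 1:25) {
    loci <- random_toy_loci(sample(3:8, 1), 2000, c("A", "B", "C"))
    loci$locus_id <- sprintf("L%d", seq_len(nrow(loci)))
    sh <- find_shared_regions(loci)
    if (nrow(sh) == 0) next
    for (i in seq_len(nrow(sh))) {
      src <- strsplit(sh$source_loci[i], ";")[[1]]
      for (s in src) {
        lc <- loci[loci$locus_id == s, ]
        expect_true(lc$start <= sh$start[i] && lc$end >= sh$end[i])
      }
      # source-locus diseases are within the region's disease set (a locus
      # covering only part of a merged region is not listed as a source)
      expect_true(all(unique(loci$disease[loci$locus_id %in% src]) %in%
                        strsplit(sh$diseases[i], ";")[[1]]))
    }
  }
})

test_that("shared regions equal the per-base disease-set oracle on random loci", {
  set.seed(42)
  for (rep in 1:60) {
    loci <- random_toy_loci(sample(2:7, 1), 500, c("A", "B", "C", "D"))
    got <- find_shared_regions(loci)
    want <- shared_regions_per_base(loci, 500)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$diseases, want$diseases)
    }
  }
})

test_that("BED emission converts closed 1-based loci to 0-based half-open and back", {
  loci <- data.frame(chrom = "chr19", start = 10745764, end = 10894728,
                     disease = "PS", locus_id = "PS_1")
  bed_path <- tempfile(fileext = ".bed")
  bed <- write_locus_bed(loci, bed_path)
  expect_equal(bed$start, 10745763)
  expect_equal(bed$end, 10894728)
  back <- read_locus_bed(bed_path)
  expect_equal(back$start, loci$start)
  expect_equal(back$end, loci$end)
})
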