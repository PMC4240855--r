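#' Parameters of the synthetic study, with planted truth
#'
#' Bundles every parameter the generators need. Defaults emulate the study
#' conditions: a genome-wide lncRNA:protein-coding ratio of 12,933:20,074
#' (scaled to 1/50 by default, ~259:401, so second-scale tests still hit
#' the printed ratios exactly), genome-wide expressed fractions of 15%
#' (lncRNA) and 47% (protein-coding), a two-fold expressed-fraction
#' enrichment inside disease loci, a 1:3 lncRNA:coding gene ratio inside
#' loci, and 11 immune cell types split into 7 peripheral populations and 4
#' cord-blood T-helper lineages.
#'
#' @param seed master seed; each generator stage derives its own stream.
#' @param scale fraction of the genome-wide gene counts to simulate.
#' @param n_coding,n_lncRNA gene counts (override `scale`).
#' @param expressed_frac named genome-wide expressed fractions per biotype.
#' @param enrichment_multiplier in-locus multiplier on the expressed
#'   fraction (>= 1).
#' @param locus_lnc_coding lncRNA and coding genes per planted locus block
#'   (default c(1, 3), the in-locus 1:3 ratio).
#' @param n_chroms,gene_gap,exon_len,intron_len,n_exons layout ranges (bp /
#'   counts) for the annotation generator.
#' @param cell_types,cell_groups cell-type labels and dataset partition.
#' @param on_mean_coding mean RPKM of expressed coding genes; expressed
#'   in-locus lncRNAs average half of it, background lncRNAs
#'   `on_mean_lnc_bg`.
#' @param on_mean_lnc_bg mean RPKM of expressed background lncRNAs.
#' @param on_sdlog log-normal sdlog of expressed values.
#' @param zero_fraction fraction of non-expressed entries that are exact
#'   zeros.
#' @param library_size nominal total mapped reads per sample.
#' @return list of class `synth_truth`.
#' @export
synth_truth <- function(seed = 1, scale = 1 / 50,
                        n_coding = round(20074 * scale),
                        n_lncRNA = round(12933 * scale),
                        expressed_frac = c(protein_coding = 0.47, lncRNA = 0.15),
                        enrichment_multiplier = 2,
                        locus_lnc_coding = c(1, 3),
                        n_chroms = 4,
                        gene_gap = c(20000, 60000),
                        exon_len = c(100, 500),
                        intron_len = c(50, 500),
                        n_exons = c(1, 10),
                        cell_types = c("granulocytes", "monocytes", "NK", "B",
                                       "memory_T", "naive_CD4", "naive_CD8",
                                       "ThP", "Th0", "Th1", "Th2"),
                        cell_groups = list(peripheral = 1:7, cord_blood = 8:11),
                        on_mean_coding = 14, on_mean_lnc_bg = 2.8,
                        on_sdlog = 0.8, zero_fraction = 0.3,
                        library_size = 137411294) {
  stopifnot(n_coding >= 1, n_lncRNA >= 1,
            all(expressed_frac >= 0 & expressed_frac <= 1),
            enrichment_multiplier >= 1)
  groups <- lapply(cell_groups, function(ix) cell_types[ix])
  structure(list(seed = seed, n_coding = n_coding, n_lncRNA = n_lncRNA,
                 expressed_frac = expressed_frac,
                 enrichment_multiplier = enrichment_multiplier,
                 locus_lnc_coding = locus_lnc_coding,
                 n_chroms = n_chroms, gene_gap = gene_gap,
                 exon_len = exon_len, intron_len = intron_len,
                 n_exons = n_exons, cell_types = cell_types,
                 cell_groups = groups,
                 on_mean_coding = on_mean_coding,
                 on_mean_lnc_bg = on_mean_lnc_bg,
                 on_sdlog = on_sdlog, zero_fraction = zero_fraction,
                 library_size = library_size),
            class = "synth_truth")
}

r_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a Gencode-style synthetic annotation
#'
#' Lays out non-overlapping genes with 1-10 exons each across the synthetic
#' chromosomes. Biotypes are allocated deterministically so the configured
#' lncRNA:coding counts are hit exactly. `n_locus_blocks` consecutive-gene
#' blocks (the future disease-locus neighbourhoods) are embedded with the
#' exact in-locus biotype pattern (default 1 lncRNA : 3 coding); their gene
#' indices are recorded in the `locus_blocks` attribute for the LD
#' generator.
#'
#' @param truth `synth_truth` object.
#' @param n_locus_blocks number of planted locus neighbourhoods.
#' @param gtf_path optional path; when given the annotation is also written
#'   as GTF.
#' @return `gene_models` object with attribute `locus_blocks` (list of
#'   integer gene-index vectors).
#' @export
generate_annotation <- function(truth, n_locus_blocks = 0, gtf_path = NULL) {
  set.seed(truth$seed + 1L)
  n_total <- truth$n_coding + truth$n_lncRNA
  blk_lnc <- truth$locus_lnc_coding[1]
  blk_cod <- truth$locus_lnc_coding[2]
  blk_size <- blk_lnc + blk_cod
  if (n_locus_blocks * blk_size > n_total) {
    stop("genome too small for the requested number of locus blocks")
  }
  block_pattern <- c(rep("protein_coding", blk_cod), rep("lncRNA", blk_lnc))
  n_blk_cod <- n_locus_blocks * blk_cod
  n_blk_lnc <- n_locus_blocks * blk_lnc
  if (n_blk_cod > truth$n_coding || n_blk_lnc > truth$n_lncRNA) {
    stop("genome too small: locus blocks need more genes of one biotype than configured")
  }
  # spread blocks evenly through the gene order, then fill the remainder
  # with a seeded permutation of the remaining exact biotype counts
  rest <- sample(c(rep("protein_coding", truth$n_coding - n_blk_cod),
                   rep("lncRNA", truth$n_lncRNA - n_blk_lnc)))
  biotype <- character(n_total)
  blocks <- list()
  if (n_locus_blocks > 0) {
    gap_between <- floor((n_total - n_locus_blocks * blk_size) / (n_locus_blocks + 1))
    if (gap_between < 1) stop("genome too small to separate locus blocks")
    pos <- gap_between + 1
    for (b in seq_len(n_locus_blocks)) {
      idx <- pos:(pos + blk_size - 1)
      biotype[idx] <- block_pattern
      blocks[[b]] <- idx
      pos <- pos + blk_size + gap_between
    }
  }
  biotype[biotype == ""] <- rest

  per_chrom <- ceiling(n_total / truth$n_chroms)
  chrom_of <- rep(paste0("chr", seq_len(truth$n_chroms)), each = per_chrom)[1:n_total]
  # keep every block on one chromosome
  if (n_locus_blocks > 0) {
    for (b in blocks) {
      chrom_of[b] <- chrom_of[b[1]]
    }
  }
  genes <- vector("list", n_total)
  exons <- vector("list", n_total)
  cursor <- stats::setNames(rep(1, truth$n_chroms), paste0("chr", seq_len(truth$n_chroms)))
  for (i in seq_len(n_total)) {
    ch <- chrom_of[i]
    gap <- r_int(1, truth$gene_gap)
    gstart <- cursor[ch] + gap
    ne <- r_int(1, truth$n_exons)
    elen <- r_int(ne, truth$exon_len)
    ilen <- if (ne > 1) r_int(ne - 1, truth$intron_len) else integer(0)
    estart <- gstart + c(0, cumsum(elen[-ne] + ilen))
    eend <- estart + elen - 1
    gid <- sprintf("SYNG%05d", i)
    strand <- if (i %% 2 == 0) "-" else "+"
    genes[[i]] <- data.frame(gene_id = gid, name = gid, chrom = ch,
                             strand = strand, start = gstart, end = max(eend),
                             biotype_raw = if (biotype[i] == "lncRNA") "lincRNA" else biotype[i],
                             stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid, chrom = ch, start = estart,
                             end = eend, stringsAsFactors = FALSE)
    cursor[ch] <- max(eend)
  }
  models <- gene_models(do.call(rbind, genes), do.call(rbind, exons))
  attr(models, "locus_blocks") <- blocks
  if (!is.null(gtf_path)) write_gtf(models, gtf_path)
  models
}

#' Write gene models as a Gencode-style GTF
#'
#' @param models `gene_models` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  g <- models$genes
  attr_str <- function(gene_id, name, biotype) {
    sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";',
            gene_id, biotype, name)
  }
  gene_lines <- sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$chrom, g$start, g$end, g$strand,
                        attr_str(g$gene_id, g$name, g$biotype_raw))
  e <- models$exons
  ix <- match(e$gene_id, g$gene_id)
  exon_lines <- sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\t%s",
                        e$chrom, e$start, e$end, g$strand[ix],
                        attr_str(e$gene_id, g$name[ix], g$biotype_raw[ix]))
  # genes then their exons, in annotation order
  ord <- order(c(match(g$gene_id, g$gene_id), ix + 0.5))
  writeLines(c(gene_lines, exon_lines)[ord], path)
  invisible(path)
}

#' Generate top SNPs and LD panels with planted disease loci
#'
#' Every planted locus is anchored on one locus block of the annotation:
#' the top SNP sits at the block's midpoint, and proxies at r2 >= 0.5 span
#' exactly the block's gene span, so the locus a correct builder recovers
#' equals the planted interval. Decoy partners (r2 < 0.5, or beyond the
#' window) are added around each SNP. A configured fraction of loci is
#' shared: diseases after the first reuse the first disease's blocks, so
#' the planted shared region equals the common block interval. A configured
#' fraction of top SNPs is withheld from both LD panels to exercise the
#' 1 Mb fallback. Non-withheld SNPs alternate between the two panels.
#'
#' @param truth `synth_truth`.
#' @param models annotation from [generate_annotation()] (must carry enough
#'   `locus_blocks`).
#' @param n_diseases,loci_per_disease study layout.
#' @param shared_fraction fraction of each later disease's loci planted on
#'   the first disease's blocks.
#' @param withheld_fraction fraction of each disease's (non-shared) loci
#'   whose top SNP is absent from both panels.
#' @return list: `top_snps`, `ld_tables` (list of 2 data frames),
#'   `locus_truth` (planted interval, fallback flag per locus),
#'   `shared_truth` (planted shared intervals with disease pairs).
#' @export
generate_ld_and_snps <- function(truth, models, n_diseases = 3,
                                 loci_per_disease = 4, shared_fraction = 0.25,
                                 withheld_fraction = 0.15) {
  stopifnot(n_diseases >= 1, loci_per_disease >= 1)
  set.seed(truth$seed + 2L)
  blocks <- attr(models, "locus_blocks")
  n_shared <- round(shared_fraction * loci_per_disease)
  n_unique_blocks <- loci_per_disease +
    (n_diseases - 1) * (loci_per_disease - n_shared)
  if (length(blocks) < n_unique_blocks) {
    stop(sprintf("annotation has %d locus blocks but %d are needed",
                 length(blocks), n_unique_blocks))
  }
  diseases <- sprintf("D%02d", seq_len(n_diseases))
  n_withheld <- round(withheld_fraction * loci_per_disease)

  g <- models$genes
  snp_rows <- list(); ld_rows <- list(); truth_rows <- list(); shared <- list()
  next_block <- loci_per_disease + 1
  snp_i <- 0
  for (d in seq_len(n_diseases)) {
    for (l in seq_len(loci_per_disease)) {
      is_shared <- d > 1 && l <= n_shared
      if (is_shared) {
        blk <- blocks[[l]]
      } else {
        blk <- if (d == 1) blocks[[l]] else blocks[[next_block]]
        if (d > 1) next_block <- next_block + 1
      }
      span_start <- min(g$start[blk]); span_end <- max(g$end[blk])
      ch <- g$chrom[blk[1]]
      pos <- floor((span_start + span_end) / 2)
      snp_i <- snp_i + 1
      rsid <- sprintf("rs%06d", snp_i)
      # withheld loci are drawn from the non-shared tail of each disease
      withheld <- l > loci_per_disease - n_withheld && !is_shared
      snp_rows[[length(snp_rows) + 1]] <- data.frame(
        disease = diseases[d], rsid = rsid, chrom = ch, pos = pos,
        pvalue = stats::runif(1, 1e-12, 4.9e-8), stringsAsFactors = FALSE)
      if (withheld) {
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          disease = diseases[d], top_snp = rsid, chrom = ch,
          start = max(1, pos - 500000), end = pos + 500000,
          fallback = TRUE, stringsAsFactors = FALSE)
      } else {
        n_inner <- sample(2:5, 1)
        prox_pos <- c(span_start, span_end,
                      sort(sample(seq(span_start + 1, span_end - 1), n_inner)))
        prox_r2 <- c(stats::runif(2, 0.6, 0.99), stats::runif(n_inner, 0.5, 1))
        # decoys: below the r2 cut-off and outside the window
        dec_pos <- c(pos + sample(1000:20000, 2), pos + 500000 + sample(1:99999, 1))
        dec_r2 <- c(stats::runif(2, 0.05, 0.49), 0.95)
        panel <- 1L + (snp_i %% 2L)
        ld_rows[[length(ld_rows) + 1]] <- data.frame(
          rsid_a = rsid, pos_a = pos,
          rsid_b = sprintf("%s_p%d", rsid, seq_along(c(prox_pos, dec_pos))),
          pos_b = c(prox_pos, dec_pos), r2 = c(prox_r2, dec_r2),
          panel = panel, stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          disease = diseases[d], top_snp = rsid, chrom = ch,
          start = span_start, end = span_end, fallback = FALSE,
          stringsAsFactors = FALSE)
        if (is_shared) {
          shared[[length(shared) + 1]] <- data.frame(
            chrom = ch, start = span_start, end = span_end,
            diseases = paste(sort(c(diseases[1], diseases[d])), collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  ld_all <- do.call(rbind, ld_rows)
  ld_tables <- lapply(1:2, function(p) {
    df <- ld_all[ld_all$panel == p, c("rsid_a", "pos_a", "rsid_b", "pos_b", "r2")]
    rownames(df) <- NULL
    df
  })
  list(top_snps = do.call(rbind, snp_rows), ld_tables = ld_tables,
       locus_truth = do.call(rbind, truth_rows),
       shared_truth = if (length(shared)) unique(do.call(rbind, shared)) else NULL)
}

#' Generate a per-cell-type RPKM matrix with planted expression structure
#'
#' Each gene is "on" in each cell type with probability
#' `base fraction x multiplier` (multiplier applied inside disease loci,
#' capped at 1). "On" genes draw RPKM from a shifted log-normal strictly
#' above the 2-RPKM expression threshold; "off" genes draw below it, with a
#' configured fraction of exact zeros. Expressed in-locus lncRNAs average
#' half the coding mean, echoing the roughly two-fold lower expression of
#' locus lncRNAs relative to locus coding genes.
#'
#' @param truth `synth_truth`.
#' @param genes data frame with `gene_id`, `biotype_class` and logical
#'   `in_locus`.
#' @param cell_types labels (default from `truth`).
#' @param threshold the expression cut-off the planting straddles
#'   (default 2).
#' @return list: `rpkm` (gene x cell matrix), `on` (logical planted-truth
#'   matrix), `N` (per-sample nominal library sizes), `params`.
#' @export
generate_expression <- function(truth, genes, cell_types = truth$cell_types,
                                threshold = 2) {
  set.seed(truth$seed + 3L)
  stopifnot(all(c("gene_id", "biotype_class", "in_locus") %in% names(genes)))
  ng <- nrow(genes); nc <- length(cell_types)
  base <- truth$expressed_frac[genes$biotype_class]
  base[is.na(base)] <- 0.05
  p_on <- pmin(1, base * ifelse(genes$in_locus, truth$enrichment_multiplier, 1))
  on <- matrix(stats::rbinom(ng * nc, 1, rep(p_on, nc)) == 1, ng, nc,
               dimnames = list(genes$gene_id, cell_types))
  on_mean <- ifelse(genes$biotype_class == "protein_coding",
                    truth$on_mean_coding,
                    ifelse(genes$in_locus, truth$on_mean_coding / 2,
                           truth$on_mean_lnc_bg))
  # shifted log-normal: threshold + lognormal with the target mean
  mu <- log(pmax(on_mean - threshold, 0.5)) - truth$on_sdlog^2 / 2
  vals <- matrix(0, ng, nc, dimnames = dimnames(on))
  n_on <- sum(on)
  if (n_on > 0) {
    mu_mat <- matrix(rep(mu, nc), ng, nc)
    vals[on] <- threshold + stats::rlnorm(n_on, mu_mat[on], truth$on_sdlog)
  }
  off_idx <- which(!on)
  if (length(off_idx) > 0) {
    zero <- stats::runif(length(off_idx)) < truth$zero_fraction
    off_vals <- stats::runif(length(off_idx), 0, threshold)
    off_vals[zero] <- 0
    vals[off_idx] <- off_vals
  }
  list(rpkm = vals, on = on,
       N = stats::setNames(rep(truth$library_size, nc), cell_types),
       params = list(p_on_in_locus = pmin(1, truth$expressed_frac * truth$enrichment_multiplier),
                     p_on_background = truth$expressed_frac))
}

#' Generate alignment records that recover target per-gene counts exactly
#'
#' For each gene with a positive target count, plants one read overlapping
#' the gene's exon union by exactly the counting threshold (30% of the read
#' length by default) and the rest fully inside an exon. Adds, per gene,
#' `n_fail_boundary` reads one base short of the threshold and `n_flagged`
#' records carrying bits of SAM flag 1796, none of which may survive a
#' correct filter-and-count. Assumes the annotation leaves at least
#' `read_length` bp of intergenic space after each gene (the synthetic
#' annotation does).
#'
#' @param truth `synth_truth`.
#' @param models `gene_models`.
#' @param target_counts named integer vector (gene id -> wanted count).
#' @param read_length read length in bp (default 100).
#' @param min_overlap_frac counting threshold the boundary reads straddle.
#' @param n_fail_boundary,n_flagged decoy records per targeted gene.
#' @return data frame of alignment records (`read_id`, `flag`, `chrom`,
#'   `blocks`, `read_length`).
#' @export
generate_reads <- function(truth, models, target_counts, read_length = 100,
                           min_overlap_frac = 0.30, n_fail_boundary = 0,
                           n_flagged = 0) {
  set.seed(truth$seed + 4L)
  g <- models$genes
  rows <- list(); rid <- 0
  bad_flags <- c(4L, 256L, 512L, 1024L, 272L, 1796L)
  thr <- ceiling(min_overlap_frac * read_length)
  mk <- function(flag, ch, start, len) {
    rid <<- rid + 1
    data.frame(read_id = sprintf("read%06d", rid), flag = flag, chrom = ch,
               blocks = sprintf("%d-%d", start, start + len - 1),
               read_length = len, stringsAsFactors = FALSE)
  }
  for (gid in names(target_counts)) {
    gi <- match(gid, g$gene_id)
    if (is.na(gi)) stop("unknown gene in target_counts: ", gid)
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    wide <- ex[which.max(ex$end - ex$start), ]
    last_end <- max(ex$end)
    ch <- g$chrom[gi]
    tc <- target_counts[[gid]]
    if (tc >= 1) {
      # exactly at the threshold: thr bases inside the last exon
      rows[[length(rows) + 1]] <- mk(0L, ch, last_end - thr + 1, read_length)
      for (k in seq_len(tc - 1)) {
        rows[[length(rows) + 1]] <- mk(0L, ch, wide$start, read_length)
      }
    }
    for (k in seq_len(n_fail_boundary)) {
      rows[[length(rows) + 1]] <- mk(0L, ch, last_end - thr + 2, read_length)
    }
    for (k in seq_len(n_flagged)) {
      rows[[length(rows) + 1]] <- mk(bad_flags[1 + (k - 1) %% length(bad_flags)],
                                     ch, wide$start, read_length)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(read_id = character(0), flag = integer(0),
                      chrom = character(0), blocks = character(0),
                      read_length = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate and write the full synthetic study bundle
#'
#' Runs every generator stage and writes the files the pipeline consumes:
#' `annotation.gtf`, `top_snps.tsv`, `ld_panel1.tsv`, `ld_panel2.tsv`,
#' `expression.tsv`, `sample_n.tsv` and a `truth.json` sidecar with the
#' planted parameters and intervals. In-locus labels for the expression
#' stage are derived from overlap of each gene with the planted locus
#' intervals.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param n_diseases,loci_per_disease,shared_fraction,withheld_fraction see
#'   [generate_ld_and_snps()].
#' @param truth optional `synth_truth` (defaults to `synth_truth(seed)`).
#' @return list with `truth`, `models`, `snp` (LD/SNP bundle), `expr`,
#'   `genes` (gene table with `in_locus`), and the written `paths`.
#' @export
synth_bundle <- function(out_dir, seed = 1, n_diseases = 3,
                         loci_per_disease = 4, shared_fraction = 0.25,
                         withheld_fraction = 0.15, truth = synth_truth(seed)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_shared <- round(shared_fraction * loci_per_disease)
  n_blocks <- loci_per_disease + (n_diseases - 1) * (loci_per_disease - n_shared)
  models <- generate_annotation(truth, n_locus_blocks = n_blocks,
                                gtf_path = file.path(out_dir, "annotation.gtf"))
  snp <- generate_ld_and_snps(truth, models, n_diseases = n_diseases,
                              loci_per_disease = loci_per_disease,
                              shared_fraction = shared_fraction,
                              withheld_fraction = withheld_fraction)
  genes <- models$genes[c("gene_id", "biotype_class", "chrom", "start", "end")]
  lt <- snp$locus_truth
  genes$in_locus <- vapply(seq_len(nrow(genes)), function(i) {
    any(lt$chrom == genes$chrom[i] & lt$start <= genes$end[i] &
          lt$end >= genes$start[i])
  }, logical(1))
  expr <- generate_expression(truth, genes)

  paths <- list(
    gtf = file.path(out_dir, "annotation.gtf"),
    top_snps = file.path(out_dir, "top_snps.tsv"),
    ld = file.path(out_dir, c("ld_panel1.tsv", "ld_panel2.tsv")),
    expression = file.path(out_dir, "expression.tsv"),
    sample_n = file.path(out_dir, "sample_n.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_tsv(snp$top_snps, paths$top_snps)
  write_tsv(snp$ld_tables[[1]], paths$ld[1])
  write_tsv(snp$ld_tables[[2]], paths$ld[2])
  expr_df <- data.frame(gene_id = rownames(expr$rpkm), expr$rpkm,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr_df, paths$expression)
  write_tsv(data.frame(sample = names(expr$N), N = unname(expr$N)),
            paths$sample_n)
  jsonlite::write_json(list(
    seed = seed, n_coding = truth$n_coding, n_lncRNA = truth$n_lncRNA,
    expressed_frac = as.list(truth$expressed_frac),
    enrichment_multiplier = truth$enrichment_multiplier,
    locus_truth = snp$locus_truth, shared_truth = snp$shared_truth),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(truth = truth, models = models, snp = snp, expr = expr,
       genes = genes, paths = paths)
}
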