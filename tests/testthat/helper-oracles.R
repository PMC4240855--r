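# Independent brute-force oracles used to cross-check the implementation.
# Each is deliberately naive (per-base labelling, exhaustive enumeration)
# and shares no code with the package internals it checks.

# label every base of a toy chromosome with its covering disease set and
# read off the maximal runs covered by >= min_diseases distinct diseases
shared_regions_per_base <- function(loci, chrom_size, min_diseases = 2) {
  out <- list()
  for (ch in unique(loci$chrom)) {
    lc <- loci[loci$chrom == ch, , drop = FALSE]
    labels <- vector("list", chrom_size)
    for (i in seq_len(nrow(lc))) {
      for (b in lc$start[i]:lc$end[i]) {
        labels[[b]] <- union(labels[[b]], lc$disease[i])
      }
    }
    key <- vapply(labels, function(d) {
      if (length(d) >= min_diseases) paste(sort(d), collapse = ";") else ""
    }, "")
    b <- 1
    while (b <= chrom_size) {
      if (key[b] != "") {
        e <- b
        while (e < chrom_size && key[e + 1] == key[b]) e <- e + 1
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = b, end = e, diseases = key[b],
          stringsAsFactors = FALSE)
        b <- e + 1
      } else b <- b + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), diseases = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# two-sided Fisher P by exhaustive hypergeometric enumeration over all
# admissible tables with the observed margins; same point-probability
# convention (relative tolerance 1e-7) as the two-sided definition
fisher_two_sided_enum <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  x <- max(0, k - m2):min(k, m1)
  probs <- dhyper(x, m1, m2, k)
  p0 <- dhyper(a, m1, m2, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# O(n^3) average-linkage (UPGMA) agglomeration on a distance matrix;
# returns the sorted merge heights
upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# per-read brute-force overlap: total bases of a read's blocks falling in
# the per-base exon set of each gene
count_reads_per_base <- function(records, models, min_overlap_frac = 0.30) {
  genes <- models$genes
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  for (r in seq_len(nrow(records))) {
    blocks <- strsplit(strsplit(records$blocks[r], ",")[[1]], "-")
    read_bases <- unlist(lapply(blocks, function(se) {
      as.numeric(se[1]):as.numeric(se[2])
    }))
    for (gi in which(genes$chrom == records$chrom[r])) {
      ex <- models$exons[models$exons$gene_id == genes$gene_id[gi], ]
      exon_bases <- unique(unlist(mapply(seq, ex$start, ex$end,
                                         SIMPLIFY = FALSE)))
      ov <- sum(read_bases %in% exon_bases)
      if (ov >= min_overlap_frac * records$read_length[r]) {
        counts[gi] <- counts[gi] + 1L
      }
    }
  }
  counts
}

# hypergeometric upper tail by enumeration: P(overlap >= ov) for a draw of
# size k from a universe with |set| successes
hyper_upper_enum <- function(ov, set_size, universe_size, k) {
  xs <- ov:min(set_size, k)
  sum(choose(set_size, xs) * choose(universe_size - set_size, k - xs)) /
    choose(universe_size, k)
}

# small random locus set on a toy chromosome
random_toy_loci <- function(n, chrom_size, diseases) {
  start <- sample(seq_len(chrom_size - 10), n, replace = TRUE)
  len <- sample(5:round(chrom_size / 3), n, replace = TRUE)
  data.frame(chrom = "toy", start = start,
             end = pmin(start + len, chrom_size),
             disease = sample(diseases, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# tiny deterministic gene-model fixture: 3 genes, mixed biotypes
toy_models <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    name = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(100, 1000, 50),
    end = c(400, 1600, 500),
    biotype_raw = c("protein_coding", "lincRNA", "miRNA"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(100, 300, 1000, 1400, 50),
    end = c(200, 400, 1200, 1600, 500),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}
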