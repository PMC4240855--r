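#' Default biotype-to-class map
#'
#' Maps Gencode-era `gene_type` strings to the three classes used throughout
#' the pipeline. The long-non-coding set covers the biotypes that Gencode
#' v14-era annotation files labelled as long non-coding transcript classes;
#' everything not listed maps to `other`.
#'
#' @return named character vector mapping `gene_type` to class.
#' @export
default_biotype_map <- function() {
  c(lincRNA = "lncRNA", antisense = "lncRNA", sense_intronic = "lncRNA",
    sense_overlapping = "lncRNA", `3prime_overlapping_ncrna` = "lncRNA",
    processed_transcript = "lncRNA",
    protein_coding = "protein_coding")
}

#' Classify a raw biotype string
#'
#' @param biotype_raw character vector of `gene_type` strings.
#' @param biotype_map named map from raw biotype to class; anything not in
#'   the map becomes `"other"`.
#' @return character vector over `{lncRNA, protein_coding, other}`.
#' @export
classify_biotype <- function(biotype_raw, biotype_map = default_biotype_map()) {
  out <- unname(biotype_map[biotype_raw])
  out[is.na(out)] <- "other"
  out
}

#' Parse a Gencode-style GTF into gene models
#'
#' Reads `gene` and `exon` features, computes each gene's exonic length as
#' the length of the union of its exon intervals (overlapping exons counted
#' once), and classifies biotypes. Exons without a parent `gene` feature are
#' skipped with a warning.
#'
#' @param path GTF file with `gene_id` and `gene_type` attributes.
#' @param biotype_map see [classify_biotype()].
#' @return a `gene_models` object: list with `genes` (data frame: `gene_id`,
#'   `name`, `chrom`, `strand`, `start`, `end`, `biotype_raw`,
#'   `biotype_class`, `exonic_length`) and `exons` (data frame: `gene_id`,
#'   `chrom`, `start`, `end`).
#' @export
parse_gtf <- function(path, biotype_map = default_biotype_map()) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  is_gene <- meta$type == "gene"
  is_exon <- meta$type == "exon"
  if (!any(is_gene)) stop("GTF contains no gene features: ", path)
  g <- gr[is_gene]
  gm <- S4Vectors::mcols(g)
  name <- if ("gene_name" %in% names(gm)) as.character(gm$gene_name) else as.character(gm$gene_id)
  genes <- data.frame(
    gene_id = as.character(gm$gene_id),
    name = name,
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    biotype_raw = as.character(gm$gene_type),
    stringsAsFactors = FALSE)
  genes$biotype_class <- classify_biotype(genes$biotype_raw, biotype_map)

  e <- gr[is_exon]
  em <- S4Vectors::mcols(e)
  exons <- data.frame(
    gene_id = as.character(em$gene_id),
    chrom = as.character(GenomicRanges::seqnames(e)),
    start = GenomicRanges::start(e),
    end = GenomicRanges::end(e),
    stringsAsFactors = FALSE)
  orphan <- !(exons$gene_id %in% genes$gene_id)
  if (any(orphan)) {
    warning(sprintf("%d exon(s) without a parent gene feature skipped", sum(orphan)))
    exons <- exons[!orphan, , drop = FALSE]
  }
  gene_models(genes, exons)
}

#' Construct a gene_models object from gene and exon tables
#'
#' Exonic length is the per-gene interval-union length; a gene with no exon
#' rows falls back to its full span.
#'
#' @param genes data frame as in [parse_gtf()] (without `exonic_length`).
#' @param exons data frame with `gene_id`, `chrom`, `start`, `end`.
#' @return `gene_models` S3 object.
#' @export
gene_models <- function(genes, exons) {
  if (!"biotype_class" %in% names(genes)) {
    genes$biotype_class <- classify_biotype(genes$biotype_raw)
  }
  union_len <- vapply(split(exons[c("start", "end")], exons$gene_id),
                      function(df) {
                        ir <- IRanges::reduce(IRanges::IRanges(df$start, df$end))
                        sum(IRanges::width(ir))
                      }, numeric(1))
  genes$exonic_length <- unname(union_len[genes$gene_id])
  no_exon <- is.na(genes$exonic_length)
  if (any(no_exon)) genes$exonic_length[no_exon] <- genes$end[no_exon] - genes$start[no_exon] + 1
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%s) on %d chromosome(s)\n",
              nrow(x$genes),
              paste(sprintf("%s=%d", names(table(x$genes$biotype_class)),
                            as.integer(table(x$genes$biotype_class))), collapse = ", "),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Reduced exon union per gene as an IRangesList keyed by chromosome
#' @keywords internal
exon_union_by_chrom <- function(models, chrom) {
  ex <- models$exons[models$exons$chrom == chrom, , drop = FALSE]
  ir <- IRanges::IRanges(ex$start, ex$end)
  pieces <- IRanges::reduce(S4Vectors::split(ir, ex$gene_id))
  pieces
}

#' Assign genes to disease loci by interval overlap
#'
#' A gene is listed under every locus its interval overlaps by at least one
#' base (closed-interval semantics: adjacency is not overlap). By default the
#' whole gene body is used; `mode = "exon"` requires at least one exon to
#' overlap the locus instead.
#'
#' @param models `gene_models` object.
#' @param loci locus data frame with `locus_id`, `disease`, `chrom`,
#'   `start`, `end`.
#' @param mode `"gene"` (gene-body overlap, default) or `"exon"`.
#' @return data frame (`locus_id`, `disease`, `gene_id`, `biotype_class`),
#'   one row per (locus, gene) pair, deterministically ordered.
#' @export
assign_genes_to_loci <- function(models, loci, mode = c("gene", "exon")) {
  mode <- match.arg(mode)
  genes <- models$genes
  out <- list()
  for (ch in intersect(unique(loci$chrom), unique(genes$chrom))) {
    lc <- loci[loci$chrom == ch, , drop = FALSE]
    lr <- IRanges::IRanges(lc$start, lc$end)
    if (mode == "gene") {
      gn <- genes[genes$chrom == ch, , drop = FALSE]
      gr <- IRanges::IRanges(gn$start, gn$end)
      hits <- IRanges::findOverlaps(gr, lr)
      gid <- gn$gene_id[S4Vectors::queryHits(hits)]
      lid <- S4Vectors::subjectHits(hits)
    } else {
      ex <- models$exons[models$exons$chrom == ch, , drop = FALSE]
      er <- IRanges::IRanges(ex$start, ex$end)
      hits <- IRanges::findOverlaps(er, lr)
      gid <- ex$gene_id[S4Vectors::queryHits(hits)]
      lid <- S4Vectors::subjectHits(hits)
    }
    if (length(gid) == 0) next
    df <- unique(data.frame(locus_id = lc$locus_id[lid],
                            disease = lc$disease[lid],
                            gene_id = gid, stringsAsFactors = FALSE))
    out[[length(out) + 1]] <- df
  }
  if (length(out) == 0) {
    return(data.frame(locus_id = character(0), disease = character(0),
                      gene_id = character(0), biotype_class = character(0)))
  }
  tab <- do.call(rbind, out)
  tab$biotype_class <- genes$biotype_class[match(tab$gene_id, genes$gene_id)]
  tab <- tab[order(tab$locus_id, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Cross-disease gene-sharing counts
#'
#' From a locus-gene table, counts for every disease pair the distinct genes
#' of one biotype class assigned to loci of both diseases. A gene hit by two
#' loci of the same disease counts once for that disease. Also reports, per
#' gene, the number of diseases it belongs to, and the totals of shared
#' (>= 2 diseases) versus unique (exactly 1) genes -- the input for
#' circular sharing diagrams.
#'
#' @param table data frame from [assign_genes_to_loci()].
#' @param biotype_class class to restrict to, or `NULL` for all genes.
#' @return list with `matrix` (disease x disease symmetric counts, zero
#'   diagonal), `per_gene` (data frame `gene_id`, `n_diseases`, `diseases`),
#'   `n_shared`, `n_unique`.
#' @export
gene_sharing_matrix <- function(table, biotype_class = NULL) {
  stopifnot(nrow(table) > 0)
  if (!is.null(biotype_class)) {
    table <- table[table$biotype_class %in% biotype_class, , drop = FALSE]
  }
  pairs <- unique(table[c("gene_id", "disease")])
  diseases <- sort(unique(table$disease))
  sets <- split(pairs$disease, pairs$gene_id)
  n_dis <- vapply(sets, function(d) length(unique(d)), integer(1))
  per_gene <- data.frame(
    gene_id = names(sets),
    n_diseases = unname(n_dis),
    diseases = vapply(sets, function(d) paste(sort(unique(d)), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  per_gene <- per_gene[order(per_gene$gene_id), , drop = FALSE]
  rownames(per_gene) <- NULL
  m <- matrix(0L, length(diseases), length(diseases),
              dimnames = list(diseases, diseases))
  for (d in sets) {
    u <- sort(unique(d))
    if (length(u) < 2) next
    cmb <- utils::combn(u, 2)
    for (k in seq_len(ncol(cmb))) {
      m[cmb[1, k], cmb[2, k]] <- m[cmb[1, k], cmb[2, k]] + 1L
      m[cmb[2, k], cmb[1, k]] <- m[cmb[2, k], cmb[1, k]] + 1L
    }
  }
  list(matrix = m, per_gene = per_gene,
       n_shared = sum(per_gene$n_diseases >= 2),
       n_unique = sum(per_gene$n_diseases == 1))
}
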