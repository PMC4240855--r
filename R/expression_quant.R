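# SAM flag 1796 = 4 (unmapped) + 256 (secondary) + 512 (QC fail) + 1024 (duplicate)
FLAG_FILTER <- 1796L

#' Filter alignment records by SAM flag
#'
#' Keeps records whose flag shares no bit with the filter mask 1796
#' (read unmapped, not primary alignment, fails quality check, PCR/optical
#' duplicate). The number of surviving records is the sample's total mapped
#' read count N used for RPKM normalisation.
#'
#' @param records data frame with at least a `flag` column of SAM bitfields.
#' @param flag_mask bitmask of flags to reject (default 1796).
#' @return the surviving records.
#' @export
filter_alignments <- function(records, flag_mask = FLAG_FILTER) {
  if (any(records$flag < 0)) stop("negative SAM flag in alignment records")
  records[bitwAnd(as.integer(records$flag), as.integer(flag_mask)) == 0L, ,
          drop = FALSE]
}

# "s1-e1,s2-e2" -> data.frame(start, end)
parse_blocks <- function(blocks) {
  parts <- strsplit(blocks, ",", fixed = TRUE)
  n <- lengths(parts)
  flat <- unlist(parts)
  se <- matrix(as.numeric(unlist(strsplit(flat, "-", fixed = TRUE))),
               ncol = 2, byrow = TRUE)
  data.frame(read_idx = rep(seq_along(blocks), n),
             start = se[, 1], end = se[, 2])
}

#' Count reads per gene under the fractional exon-overlap rule
#'
#' A read counts toward a gene when the total overlap of its aligned blocks
#' with the gene's exon union is at least `min_overlap_frac` of the read's
#' length (the boundary is inclusive: a 100 bp read overlapping exons by
#' exactly 30 bases counts at the default 30% rule). Under the default
#' `assignment = "independent"` a read satisfying the rule for several genes
#' counts toward each of them; `assignment = "unique"` keeps only the gene
#' with the largest overlap and drops ties.
#'
#' @param records alignment data frame with `read_id`, `chrom`, `blocks`
#'   (character, `"start-end,start-end"` 1-based closed), `read_length`, and
#'   optionally `flag` (records are NOT flag-filtered here; see
#'   [filter_alignments()]).
#' @param models `gene_models` object.
#' @param min_overlap_frac minimum overlap as a fraction of read length
#'   (default 0.30).
#' @param assignment `"independent"` (default) or `"unique"`.
#' @return data frame `gene_id`, `count` covering every gene in `models`
#'   (zeros included), ordered as in `models$genes`.
#' @export
count_reads <- function(records, models, min_overlap_frac = 0.30,
                        assignment = c("independent", "unique")) {
  assignment <- match.arg(assignment)
  genes <- models$genes
  counts <- stats::setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(records) > 0) {
    hits_all <- list()
    for (ch in intersect(unique(records$chrom), unique(models$exons$chrom))) {
      rc <- records[records$chrom == ch, , drop = FALSE]
      blk <- parse_blocks(rc$blocks)
      br <- IRanges::IRanges(blk$start, blk$end)
      ex_by_gene <- exon_union_by_chrom(models, ch)
      ex_flat <- unlist(ex_by_gene, use.names = FALSE)
      ex_gene <- rep(names(ex_by_gene), lengths(ex_by_gene))
      ov <- IRanges::findOverlaps(br, ex_flat)
      if (length(ov) == 0) next
      w <- IRanges::width(IRanges::pintersect(
        br[S4Vectors::queryHits(ov)], ex_flat[S4Vectors::subjectHits(ov)]))
      key <- data.frame(
        read = blk$read_idx[S4Vectors::queryHits(ov)],
        gene = ex_gene[S4Vectors::subjectHits(ov)],
        w = w, stringsAsFactors = FALSE)
      agg <- stats::aggregate(w ~ read + gene, data = key, FUN = sum)
      agg$frac_ok <- agg$w >= min_overlap_frac * rc$read_length[agg$read]
      agg <- agg[agg$frac_ok, , drop = FALSE]
      if (nrow(agg) == 0) next
      if (assignment == "unique") {
        keep <- unlist(lapply(split(seq_len(nrow(agg)), agg$read), function(ix) {
          wmax <- max(agg$w[ix])
          best <- ix[agg$w[ix] == wmax]
          if (length(best) > 1) integer(0) else best   # ties dropped
        }))
        agg <- agg[keep, , drop = FALSE]
      }
      hits_all[[length(hits_all) + 1]] <- agg
    }
    if (length(hits_all) > 0) {
      agg <- do.call(rbind, hits_all)
      tab <- table(agg$gene)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  data.frame(gene_id = genes$gene_id, count = unname(counts),
             stringsAsFactors = FALSE)
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' `RPKM = 1e9 * C / (N * L)` where `C` is the read count of the gene, `L`
#' its exonic length in bp and `N` the sample's total mapped read count
#' after flag filtering.
#'
#' @param C read counts (non-negative).
#' @param L exonic lengths in bp (>= 1).
#' @param N total mapped reads for the sample (>= 1).
#' @return RPKM values; a zero count gives exactly 0.
#' @export
rpkm <- function(C, L, N) {
  if (any(L < 1)) stop("invalid gene: exonic length L must be >= 1")
  if (any(N < 1)) stop("invalid library: total mapped reads N must be >= 1")
  if (any(C < 0)) stop("negative read count")
  1e9 * C / (N * L)
}

#' Expressed-gene call
#'
#' A gene is expressed in a sample when its RPKM is strictly greater than
#' the threshold (default 2); a value of exactly 2 is not expressed.
#'
#' @param rpkm_value numeric RPKM values.
#' @param threshold expression cut-off (default 2).
#' @return logical vector.
#' @export
is_expressed <- function(rpkm_value, threshold = 2) {
  rpkm_value > threshold
}

#' log10 transform with zero offset
#'
#' Zero RPKM values are replaced by 1e-6 before taking log10 (so zeros map
#' to exactly -6); non-zero values are log10-transformed as they are. Set
#' `offset_all = TRUE` to add the offset to every value instead.
#'
#' @param rpkm_value numeric RPKM values (>= 0).
#' @param offset value replacing (or added to) zeros, default 1e-6.
#' @param offset_all add the offset to all values, not just zeros.
#' @return log10-transformed values.
#' @export
log_transform <- function(rpkm_value, offset = 1e-6, offset_all = FALSE) {
  if (any(rpkm_value < 0)) stop("negative RPKM")
  if (offset_all) return(log10(rpkm_value + offset))
  ifelse(rpkm_value == 0, log10(offset), log10(rpkm_value))
}

#' Assemble an expression matrix from per-sample counts
#'
#' @param count_list named list (sample id -> data frame from
#'   [count_reads()]).
#' @param models `gene_models` object supplying exonic lengths and biotypes.
#' @param N named numeric vector of per-sample total mapped reads; defaults
#'   to the per-sample sum of counts (appropriate only when every mapped
#'   read was counted).
#' @return an `expression_matrix` object: list with `rpkm` (gene x sample
#'   matrix), `counts`, `N`, `gene_info` (exonic length, biotype class).
#' @export
build_expression_matrix <- function(count_list, models, N = NULL) {
  samples <- names(count_list)
  stopifnot(length(samples) > 0)
  genes <- models$genes
  cmat <- sapply(count_list, function(df) {
    df$count[match(genes$gene_id, df$gene_id)]
  })
  cmat <- matrix(cmat, nrow = nrow(genes),
                 dimnames = list(genes$gene_id, samples))
  if (is.null(N)) N <- colSums(cmat)
  N <- N[samples]
  rmat <- sweep(1e9 * cmat / genes$exonic_length, 2, N, "/")
  structure(list(rpkm = rmat, counts = cmat, N = N,
                 gene_info = data.frame(gene_id = genes$gene_id,
                                        exonic_length = genes$exonic_length,
                                        biotype_class = genes$biotype_class,
                                        stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (RPKM)\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}
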