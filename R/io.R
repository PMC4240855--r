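#' Write a data frame as TSV
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header
#' @param path input file.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a top-SNP table (disease, rsid, chrom, pos, pvalue)
#' @param path TSV file.
#' @return data frame.
#' @export
read_top_snps <- function(path) {
  df <- read_tsv(path)
  need <- c("disease", "rsid", "chrom", "pos", "pvalue")
  assert_that(all(need %in% names(df)),
              paste("top-SNP table must have columns:", paste(need, collapse = ", ")))
  df
}

#' Read an LD pair table (rsid_a, pos_a, rsid_b, pos_b, r2)
#' @param path TSV file.
#' @return data frame.
#' @export
read_ld_table <- function(path) {
  df <- read_tsv(path)
  need <- c("rsid_a", "pos_a", "rsid_b", "pos_b", "r2")
  assert_that(all(need %in% names(df)),
              paste("LD table must have columns:", paste(need, collapse = ", ")))
  assert_that(all(df$r2 >= 0 & df$r2 <= 1), "r2 values must lie in [0,1]")
  df
}

#' Read a gene x sample expression TSV (first column gene_id)
#' @param path TSV file.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write loci as BED (0-based half-open) alongside printed-style TSV
#'
#' Internal coordinates are 1-based closed, matching printed locus
#' coordinates; BED output converts to 0-based half-open (start-1, end).
#'
#' @param loci locus data frame.
#' @param bed_path BED output path (or NULL to skip).
#' @param tsv_path TSV output path (or NULL to skip).
#' @return invisibly, the BED data frame.
#' @export
write_locus_bed <- function(loci, bed_path = NULL, tsv_path = NULL) {
  bed <- data.frame(chrom = loci$chrom, start = loci$start - 1, end = loci$end,
                    name = if ("locus_id" %in% names(loci)) loci$locus_id else ".",
                    stringsAsFactors = FALSE)
  if (!is.null(bed_path)) {
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) write_tsv(loci, tsv_path)
  invisible(bed)
}

#' Read a locus BED file back into 1-based closed coordinates
#' @param path BED file (chrom, start, end, [name]).
#' @return data frame with `chrom`, `start`, `end` (1-based closed).
#' @export
read_locus_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- df$start + 1
  df
}
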