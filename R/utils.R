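#' Numeric-aware chromosome ordering
#'
#' Orders chromosome names so that `chr2 < chr10` and non-numeric names
#' (chrX, chrY, chrM) sort lexicographically after the numeric ones.
#'
#' @param chrom character vector of chromosome names.
#' @return integer ranks usable with `order()`.
#' @keywords internal
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(core))
  # non-numeric chromosomes sort after all numeric ones, alphabetically
  key <- ifelse(is.na(num), 1e6 + as.numeric(factor(core, levels = sort(unique(core)))), num)
  key
}

#' Order a locus-like data frame deterministically
#'
#' Sorts by (chromosome with numeric-aware order, start, end, disease) so that
#' outputs are reproducible across runs and platforms.
#'
#' @param df data frame with columns `chrom`, `start`, `end` and optionally
#'   `disease`.
#' @return the reordered data frame, row names dropped.
#' @keywords internal
order_loci <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- chrom_rank(df$chrom)
  o <- if ("disease" %in% names(df)) {
    order(key, df$start, df$end, df$disease)
  } else {
    order(key, df$start, df$end)
  }
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Truncate (not round) a number to a fixed number of decimals
#' @keywords internal
trunc_decimals <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

# stopifnot-style check with a readable message
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
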