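#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Two-sided P under the standard convention: the sum of hypergeometric
#' probabilities (margins fixed) of every table whose point probability does
#' not exceed that of the observed table (up to a relative tolerance of
#' 1e-7, as in `stats::fisher.test`).
#'
#' @param a,b,c,d the cells: `a` set-and-expressed, `b` set-not-expressed,
#'   `c` background-expressed, `d` background-not-expressed (any 2x2 layout;
#'   the P-value is invariant to transposition).
#' @return the two-sided P-value.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != trunc(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero contingency table")
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Per-test Bonferroni significance threshold
#'
#' @param alpha family-wise significance level in (0,1).
#' @param m number of tests (here: number of cell types in the dataset).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Render a Bonferroni threshold at reporting precision
#'
#' Truncates (does not round) the corrected threshold to one more decimal
#' place than its significance level: 0.05/7 -> "0.007", 0.05/4 = 0.0125 ->
#' "0.012", 0.005/7 = 0.000714... -> "0.0007", 0.005/4 = 0.00125 ->
#' "0.0012". Without `alpha`, three decimals are used, or four when three
#' would print zero.
#'
#' @param threshold numeric threshold from [bonferroni_threshold()].
#' @param alpha the significance level the threshold was derived from
#'   (optional, vectorised with `threshold`).
#' @return character representation.
#' @export
format_threshold <- function(threshold, alpha = NULL) {
  if (!is.null(alpha)) {
    digits <- ceiling(-log10(alpha)) + 1
    return(mapply(function(x, d) sprintf("%.*f", d, trunc_decimals(x, d)),
                  threshold, digits, USE.NAMES = FALSE))
  }
  vapply(threshold, function(x) {
    t3 <- trunc_decimals(x, 3)
    if (t3 > 0) sprintf("%.3f", t3) else sprintf("%.4f", trunc_decimals(x, 4))
  }, character(1))
}

#' Significance tier (star count) after Bonferroni correction
#'
#' Tier k means the P-value passes the k-th (and all looser) corrected
#' thresholds `alpha_k / m`; 0 means not significant. With the default
#' alphas, tiers 1..3 correspond to *, **, *** at alpha = 0.05, 0.01, 0.005.
#'
#' @param p P-values.
#' @param alphas strictly decreasing significance levels.
#' @param m number of tests for the Bonferroni correction.
#' @return integer tiers in `0:length(alphas)`.
#' @export
significance_tier <- function(p, alphas = c(0.05, 0.01, 0.005), m = 1) {
  stopifnot(all(diff(alphas) < 0))
  thr <- alphas / m
  vapply(p, function(pp) sum(pp <= thr), integer(1))
}

#' Expressed-fraction enrichment test for one gene set in one cell type
#'
#' Builds the 2x2 table of expressed (> `threshold` RPKM) versus not, gene
#' set versus background, and runs the two-tailed Fisher's exact test. By
#' default the background is a superset that may include the gene set
#' (comparison against the whole annotation); `background_mode = "disjoint"`
#' removes the set genes from the background first.
#'
#' @param mat `expression_matrix` object or plain RPKM matrix with gene ids
#'   as rownames.
#' @param gene_set character vector of gene ids.
#' @param background_genes character vector of gene ids (superset of
#'   `gene_set` under the default mode).
#' @param cell_type column to test.
#' @param threshold RPKM expression cut-off (default 2).
#' @param alphas,m significance levels and Bonferroni divisor for the tier.
#' @param background_mode `"all"` (default) or `"disjoint"`.
#' @return one-row data frame: counts `set_expressed`, `set_not`,
#'   `bg_expressed`, `bg_not`, `pvalue`, `tier`, `stars`.
#' @export
expressed_fraction_test <- function(mat, gene_set, background_genes, cell_type,
                                    threshold = 2,
                                    alphas = c(0.05, 0.01, 0.005), m = 1,
                                    background_mode = c("all", "disjoint")) {
  background_mode <- match.arg(background_mode)
  rp <- if (inherits(mat, "expression_matrix")) mat$rpkm else mat
  if (length(gene_set) == 0) stop("empty gene set")
  if (background_mode == "disjoint") {
    background_genes <- setdiff(background_genes, gene_set)
  }
  ex <- is_expressed(rp[, cell_type], threshold)
  se <- sum(ex[gene_set]); sn <- length(gene_set) - se
  be <- sum(ex[background_genes]); bn <- length(background_genes) - be
  p <- fisher_exact_two_tailed(se, sn, be, bn)
  tier <- significance_tier(p, alphas, m)
  data.frame(cell_type = cell_type,
             set_expressed = se, set_not = sn,
             bg_expressed = be, bg_not = bn,
             pvalue = p, tier = tier,
             stars = strrep("*", tier), stringsAsFactors = FALSE)
}

#' Scan expressed-fraction enrichment over diseases, biotypes and cell types
#'
#' Runs [expressed_fraction_test()] for every combination of gene set
#' (typically one per disease and biotype class) and cell type. Cell types
#' are partitioned into datasets (e.g. 7 peripheral immune cell types and 4
#' cord-blood T-helper lineages) and the Bonferroni divisor m is the number
#' of cell types within the dataset of the tested cell type; diseases are
#' not folded into m.
#'
#' @param mat `expression_matrix` or RPKM matrix.
#' @param gene_sets named list of lists; each element has `genes` (ids) and
#'   optionally `disease` and `biotype_class` labels (defaults parsed from
#'   the element name).
#' @param background named list mapping biotype class (or `"all"`) to the
#'   background gene ids for sets of that class.
#' @param cell_groups named list partitioning the tested cell types into
#'   datasets, e.g. `list(peripheral = c(...7...), cord_blood = c(...4...))`.
#' @param threshold,alphas,background_mode see [expressed_fraction_test()].
#' @return data frame with one row per (set, cell type).
#' @export
enrichment_scan <- function(mat, gene_sets, background, cell_groups,
                            threshold = 2, alphas = c(0.05, 0.01, 0.005),
                            background_mode = c("all", "disjoint")) {
  background_mode <- match.arg(background_mode)
  rows <- list()
  for (set_name in names(gene_sets)) {
    gs <- gene_sets[[set_name]]
    cls <- if (!is.null(gs$biotype_class)) gs$biotype_class else "all"
    bg <- if (cls %in% names(background)) background[[cls]] else background[["all"]]
    for (grp in names(cell_groups)) {
      cells <- cell_groups[[grp]]
      m <- length(cells)
      for (ct in cells) {
        r <- expressed_fraction_test(mat, gs$genes, bg, ct,
                                     threshold = threshold, alphas = alphas,
                                     m = m, background_mode = background_mode)
        r <- cbind(data.frame(set = set_name,
                              disease = if (!is.null(gs$disease)) gs$disease else set_name,
                              biotype_class = cls, dataset = grp, m = m,
                              stringsAsFactors = FALSE), r)
        rows[[length(rows) + 1]] <- r
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact P by enumeration for small untied samples (both groups at most
#' `exact_cutoff`), normal approximation with tie correction otherwise.
#' Two identical constant groups give P = 1.
#'
#' @param values_a,values_b numeric vectors (nonempty).
#' @param exact_cutoff largest per-group size for the exact path
#'   (default 50).
#' @return the two-sided P-value.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b, exact_cutoff = 50) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) return(1)
  has_ties <- any(duplicated(pooled))
  exact <- !has_ties && length(values_a) <= exact_cutoff &&
    length(values_b) <= exact_cutoff
  suppressWarnings(stats::wilcox.test(values_a, values_b, exact = exact,
                                      correct = !exact)$p.value)
}

#' Average-linkage hierarchical clustering of samples
#'
#' UPGMA clustering of the sample columns on pairwise Euclidean distances,
#' as used to order expression heat maps. Input should be log10-transformed
#' RPKM (see [log_transform()]).
#'
#' @param matrix_log10 numeric matrix, genes x samples.
#' @return list with `hclust` (the tree) and `order` (leaf labels left to
#'   right).
#' @export
cluster_samples <- function(matrix_log10) {
  stopifnot(ncol(matrix_log10) >= 2)
  d <- stats::dist(t(matrix_log10), method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = colnames(matrix_log10)[hc$order])
}
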