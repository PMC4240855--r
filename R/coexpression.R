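#' Rank genes by co-expression with a query gene
#'
#' Guilt-by-association profile: correlation between the query gene's
#' log10-expression profile across cell types and every other gene's,
#' ranked by absolute correlation (ties broken by gene id). Genes whose
#' profile standard deviation is below `min_sd` are excluded because their
#' correlation is undefined or numerically unstable.
#'
#' @param matrix_log10 numeric matrix, genes x cell types (log10 RPKM).
#' @param query gene id (rowname) of the query lncRNA.
#' @param min_sd minimum profile standard deviation (default 1e-8).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `query`, `n_cell_types`, and `partners` (data frame
#'   `gene_id`, `r`, ranked by `|r|` descending).
#' @export
coexpression_rank <- function(matrix_log10, query, min_sd = 1e-8,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(query %in% rownames(matrix_log10), ncol(matrix_log10) >= 3)
  q <- matrix_log10[query, ]
  if (stats::sd(q) < min_sd) stop("query gene has (near-)zero variance")
  others <- matrix_log10[setdiff(rownames(matrix_log10), query), , drop = FALSE]
  sds <- apply(others, 1, stats::sd)
  others <- others[sds >= min_sd, , drop = FALSE]
  r <- as.vector(stats::cor(t(others), q, method = method))
  df <- data.frame(gene_id = rownames(others), r = r, stringsAsFactors = FALSE)
  df <- df[order(-abs(df$r), df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  list(query = query, n_cell_types = ncol(matrix_log10), partners = df)
}

#' Hypergeometric gene-set enrichment of top co-expression partners
#'
#' Upper-tail hypergeometric P for the overlap between the top-k
#' co-expressed partners and each user-supplied gene set, within a stated
#' gene universe. This re-implements the mechanism behind co-expression
#' pathway prediction with gene sets supplied by the user (e.g. GO
#' biological processes in GMT format).
#'
#' @param top_partners character vector of gene ids (the top-k list).
#' @param gene_sets named list of character vectors (each a subset of
#'   `universe`).
#' @param universe character vector of all eligible gene ids.
#' @return data frame (`set`, `overlap`, `set_size`, `universe_size`,
#'   `k`, `pvalue`), sorted by P then set name.
#' @export
gene_set_enrichment <- function(top_partners, gene_sets, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  top_partners <- intersect(top_partners, universe)
  k <- length(top_partners)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(gs, top_partners))
    # P(X >= ov), X ~ Hypergeometric(|set| successes, k draws, |universe|)
    p <- stats::phyper(ov - 1, length(gs), length(universe) - length(gs), k,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(gs),
               universe_size = length(universe), k = k, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pvalue, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' lncRNA / protein-coding co-expression pairs within loci
#'
#' For every locus, forms all (lncRNA, protein-coding) gene pairs among the
#' genes assigned to it and reports their expression correlation -- the
#' candidate cis-regulatory pairs co-located in a single disease locus.
#'
#' @param matrix_log10 numeric matrix, genes x cell types (log10 RPKM).
#' @param locus_gene_table data frame from [assign_genes_to_loci()].
#' @param method correlation method, see [coexpression_rank()].
#' @return data frame (`locus_id`, `disease`, `lncRNA`, `coding_gene`, `r`,
#'   `same_locus`). `r` is `NA` when either profile is constant.
#' @export
locus_pair_report <- function(matrix_log10, locus_gene_table,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rows <- list()
  for (lid in unique(locus_gene_table$locus_id)) {
    sub <- locus_gene_table[locus_gene_table$locus_id == lid, , drop = FALSE]
    lnc <- sub$gene_id[sub$biotype_class == "lncRNA"]
    cod <- sub$gene_id[sub$biotype_class == "protein_coding"]
    if (length(lnc) == 0 || length(cod) == 0) next
    for (l in lnc) for (cg in cod) {
      r <- if (l %in% rownames(matrix_log10) && cg %in% rownames(matrix_log10) &&
               stats::sd(matrix_log10[l, ]) > 0 && stats::sd(matrix_log10[cg, ]) > 0) {
        stats::cor(matrix_log10[l, ], matrix_log10[cg, ], method = method)
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        locus_id = lid, disease = sub$disease[1], lncRNA = l,
        coding_gene = cg, r = r, same_locus = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(locus_id = character(0), disease = character(0),
                      lncRNA = character(0), coding_gene = character(0),
                      r = numeric(0), same_locus = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}
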