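#' Assemble a pipeline configuration
#'
#' Collects the file paths and analysis parameters of a full run. All
#' thresholds default to the study settings; the configuration is echoed
#' (with a hash) into every output so mixed-provenance outputs are
#' detectable.
#'
#' @param top_snps,ld,gtf,expression,sample_n input file paths (`ld` is an
#'   ordered character vector of LD panel paths, first panel wins).
#' @param r2_min,window,fallback_flank locus-building parameters.
#' @param min_overlap_frac read-counting threshold.
#' @param rpkm_threshold expressed-gene cut-off.
#' @param alphas significance levels for the star tiers.
#' @param cell_groups named list partitioning sample columns into datasets
#'   for the Bonferroni divisor.
#' @param seed seed recorded with the run.
#' @return list of class `pipeline_config` with a `hash` element.
#' @export
pipeline_config <- function(top_snps, ld, gtf, expression, sample_n = NULL,
                            r2_min = 0.5, window = 500000,
                            fallback_flank = 500000, min_overlap_frac = 0.30,
                            rpkm_threshold = 2, alphas = c(0.05, 0.01, 0.005),
                            cell_groups = NULL, seed = 1) {
  cfg <- list(top_snps = top_snps, ld = ld, gtf = gtf,
              expression = expression, sample_n = sample_n,
              r2_min = r2_min, window = window,
              fallback_flank = fallback_flank,
              min_overlap_frac = min_overlap_frac,
              rpkm_threshold = rpkm_threshold, alphas = alphas,
              cell_groups = cell_groups, seed = seed)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg)), tmp)
  cfg$hash <- unname(tools::md5sum(tmp))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes locus building, containment deduplication, shared-region
#' decomposition, gene annotation and assignment, enrichment scanning,
#' sample clustering and the in-locus co-expression pair report, writing
#' every stage's table under `out_dir` together with a JSON run report
#' (config echo, config hash, per-stage record counts).
#'
#' @param config from [pipeline_config()].
#' @param out_dir output directory.
#' @return list with the in-memory stage results and `report`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_counts <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    res
  }

  top <- stage("read_top_snps", read_top_snps(config$top_snps))
  ld_tables <- stage("read_ld", lapply(config$ld, read_ld_table))
  log_counts$top_snps <- nrow(top)

  loci <- stage("build_loci", build_loci(
    top, ld_tables, r2_min = config$r2_min, window = config$window,
    fallback_flank = config$fallback_flank))
  loci <- deduplicate_loci(loci)
  log_counts$loci <- nrow(loci)
  write_locus_bed(loci, file.path(out_dir, "loci.bed"),
                  file.path(out_dir, "loci.tsv"))

  shared <- stage("find_shared_regions", find_shared_regions(loci))
  log_counts$shared_regions <- nrow(shared)
  write_tsv(shared, file.path(out_dir, "shared_regions.tsv"))

  models <- stage("parse_gtf", parse_gtf(config$gtf))
  log_counts$genes <- nrow(models$genes)
  table_lg <- stage("assign_genes_to_loci", assign_genes_to_loci(models, loci))
  log_counts$locus_gene_rows <- nrow(table_lg)
  write_tsv(table_lg, file.path(out_dir, "locus_genes.tsv"))

  for (cls in c("lncRNA", "protein_coding")) {
    if (any(table_lg$biotype_class == cls)) {
      sh <- gene_sharing_matrix(table_lg, cls)
      write_tsv(data.frame(disease = rownames(sh$matrix), sh$matrix,
                           check.names = FALSE),
                file.path(out_dir, paste0("sharing_", cls, ".tsv")))
    }
  }

  rp <- stage("read_expression", read_expression_tsv(config$expression))
  log_counts$expression_genes <- nrow(rp)
  cell_groups <- config$cell_groups
  if (is.null(cell_groups)) cell_groups <- list(all = colnames(rp))

  gene_sets <- list()
  for (d in unique(table_lg$disease)) for (cls in c("lncRNA", "protein_coding")) {
    ids <- unique(table_lg$gene_id[table_lg$disease == d &
                                     table_lg$biotype_class == cls])
    ids <- intersect(ids, rownames(rp))
    if (length(ids) > 0) {
      gene_sets[[paste(d, cls, sep = ".")]] <-
        list(genes = ids, disease = d, biotype_class = cls)
    }
  }
  cls_of <- models$genes$biotype_class[match(rownames(rp), models$genes$gene_id)]
  background <- list(
    lncRNA = rownames(rp)[cls_of %in% "lncRNA"],
    protein_coding = rownames(rp)[cls_of %in% "protein_coding"],
    all = rownames(rp))
  enr <- if (length(gene_sets) > 0) {
    stage("enrichment_scan", enrichment_scan(
      rp, gene_sets, background, cell_groups,
      threshold = config$rpkm_threshold, alphas = config$alphas))
  } else data.frame()
  log_counts$enrichment_rows <- nrow(enr)
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))

  lg <- log_transform(rp)
  clus <- stage("cluster_samples", cluster_samples(lg))
  writeLines(clus$order, file.path(out_dir, "sample_order.txt"))
  write_tsv(data.frame(gene_id = rownames(lg),
                       lg[, clus$order, drop = FALSE], check.names = FALSE),
            file.path(out_dir, "heatmap_matrix.tsv"))

  pairs <- stage("locus_pair_report", locus_pair_report(lg, table_lg))
  log_counts$locus_pairs <- nrow(pairs)
  write_tsv(pairs, file.path(out_dir, "locus_pairs.tsv"))

  report <- list(
    config = config[setdiff(names(config), "hash")],
    config_hash = config$hash,
    thresholds = lapply(cell_groups, function(cells) {
      stats::setNames(format_threshold(config$alphas / length(cells),
                                       config$alphas),
                      paste0("alpha_", config$alphas))
    }),
    stage_counts = log_counts)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(loci = loci, shared = shared, models = models,
                 locus_genes = table_lg, enrichment = enr,
                 clustering = clus, pairs = pairs, report = report))
}
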