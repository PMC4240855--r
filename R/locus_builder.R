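#' Find LD proxies of a top SNP
#'
#' Returns every SNP in linkage disequilibrium with the top SNP at
#' `r2 >= r2_min` and within `window` base pairs of it. Both boundaries are
#' inclusive: a partner at exactly `r2 = r2_min` or exactly `window` bp away
#' qualifies. LD pairs are treated as symmetric, so the top SNP may appear on
#' either side of a pair.
#'
#' @param top a list or one-row data frame with at least `rsid` and `pos`.
#' @param ld data frame of LD pairs with columns `rsid_a`, `pos_a`,
#'   `rsid_b`, `pos_b`, `r2`.
#' @param r2_min minimum squared allelic correlation (default 0.5).
#' @param window maximum distance from the top SNP in bp (default 500000,
#'   i.e. a +/-500 kb window).
#' @return data frame with columns `rsid`, `pos`, one row per qualifying
#'   proxy. Partners with a missing position are skipped with a warning.
#' @export
expand_proxies <- function(top, ld, r2_min = 0.5, window = 500000) {
  stopifnot(all(c("rsid_a", "pos_a", "rsid_b", "pos_b", "r2") %in% names(ld)))
  hit_a <- ld$rsid_a == top$rsid
  hit_b <- ld$rsid_b == top$rsid
  partners <- rbind(
    data.frame(rsid = ld$rsid_b[hit_a], pos = ld$pos_b[hit_a], r2 = ld$r2[hit_a]),
    data.frame(rsid = ld$rsid_a[hit_b], pos = ld$pos_a[hit_b], r2 = ld$r2[hit_b])
  )
  if (nrow(partners) == 0) {
    return(data.frame(rsid = character(0), pos = numeric(0)))
  }
  bad <- is.na(partners$pos)
  if (any(bad)) {
    warning(sprintf("skipping %d LD partner(s) of %s with missing position",
                    sum(bad), top$rsid))
    partners <- partners[!bad, , drop = FALSE]
  }
  keep <- partners$r2 >= r2_min & abs(partners$pos - top$pos) <= window
  out <- unique(partners[keep, c("rsid", "pos"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Define a disease locus from a top SNP and its proxies
#'
#' The locus is the closed 1-based interval spanning the top SNP and all of
#' its qualifying proxy SNPs. A top SNP absent from every LD reference panel
#' gets the fallback definition: a 1 Mb region centred on the SNP
#' (top SNP +/- `fallback_flank`). A top SNP that is present in a reference
#' but has no proxy passing the r2 filter yields a singleton interval
#' (with a warning) unless `no_proxy_fallback = TRUE`, in which case the
#' 1 Mb rule is applied to it as well.
#'
#' @param top list or one-row data frame with `rsid`, `chrom`, `pos`,
#'   `disease`.
#' @param proxies data frame from [expand_proxies()] (may have zero rows).
#' @param snp_in_reference logical; was the top SNP found in any LD panel?
#' @param fallback_flank half-width of the fallback region in bp
#'   (default 500000).
#' @param no_proxy_fallback apply the fallback rule when a referenced SNP has
#'   zero passing proxies, instead of emitting a singleton interval.
#' @return one-row data frame: `chrom`, `start`, `end`, `disease`, `top_snp`,
#'   `proxy_count`, `fallback`. Coordinates are clipped at 1 with a warning
#'   when the flank runs off the chromosome start.
#' @export
define_locus <- function(top, proxies, snp_in_reference = TRUE,
                         fallback_flank = 500000, no_proxy_fallback = FALSE) {
  n_prox <- if (is.null(proxies)) 0L else nrow(proxies)
  use_fallback <- !snp_in_reference || (n_prox == 0L && no_proxy_fallback)
  if (use_fallback) {
    start <- top$pos - fallback_flank
    end <- top$pos + fallback_flank
    if (start < 1) {
      warning(sprintf("locus for %s clipped at chromosome start", top$rsid))
      start <- 1
    }
    fb <- TRUE
  } else if (n_prox == 0L) {
    warning(sprintf("top SNP %s has no proxies at the r2 threshold; emitting singleton locus",
                    top$rsid))
    start <- end <- top$pos
    fb <- FALSE
  } else {
    pos_all <- c(top$pos, proxies$pos)
    start <- min(pos_all)
    end <- max(pos_all)
    fb <- FALSE
  }
  data.frame(chrom = top$chrom, start = start, end = end,
             disease = top$disease, top_snp = top$rsid,
             proxy_count = n_prox, fallback = fb,
             stringsAsFactors = FALSE)
}

#' Build all disease loci from a top-SNP table and LD reference panels
#'
#' For each genome-wide significant top SNP (association P <= `p_max`), the
#' first LD panel in `ld_tables` that contains the SNP is used to extract
#' proxies; SNPs absent from every panel fall back to the 1 Mb rule. This
#' mirrors using one reference panel *or* another, in order of preference.
#'
#' @param top_snps data frame with columns `disease`, `rsid`, `chrom`, `pos`,
#'   `pvalue`.
#' @param ld_tables ordered list of LD pair data frames (see
#'   [expand_proxies()]); the first panel containing the SNP wins.
#' @param r2_min,window,fallback_flank,no_proxy_fallback passed through to
#'   [expand_proxies()] and [define_locus()].
#' @param p_max genome-wide significance cut-off for admission
#'   (default 5e-8).
#' @return data frame of loci (one row per admitted top SNP) with a
#'   `locus_id` column, ordered by (chrom, start, end, disease).
#' @export
build_loci <- function(top_snps, ld_tables, r2_min = 0.5, window = 500000,
                       fallback_flank = 500000, no_proxy_fallback = FALSE,
                       p_max = 5e-8) {
  stopifnot(is.list(ld_tables))
  admitted <- top_snps[top_snps$pvalue <= p_max, , drop = FALSE]
  if (nrow(admitted) < nrow(top_snps)) {
    warning(sprintf("%d top SNP(s) above P = %g excluded from locus building",
                    nrow(top_snps) - nrow(admitted), p_max))
  }
  rows <- lapply(seq_len(nrow(admitted)), function(i) {
    top <- admitted[i, ]
    panel <- NULL
    for (ld in ld_tables) {
      if (top$rsid %in% c(ld$rsid_a, ld$rsid_b)) { panel <- ld; break }
    }
    if (is.null(panel)) {
      define_locus(top, NULL, snp_in_reference = FALSE,
                   fallback_flank = fallback_flank)
    } else {
      prox <- expand_proxies(top, panel, r2_min = r2_min, window = window)
      define_locus(top, prox, snp_in_reference = TRUE,
                   fallback_flank = fallback_flank,
                   no_proxy_fallback = no_proxy_fallback)
    }
  })
  loci <- do.call(rbind, rows)
  loci <- order_loci(loci)
  loci$locus_id <- sprintf("%s_%s_%d", loci$disease, loci$chrom,
                           seq_len(nrow(loci)))
  loci
}

#' Remove loci fully contained in a larger locus of the same disease
#'
#' A locus whose interval lies entirely within another locus of the same
#' disease carries no additional region and is dropped. Deduplication is per
#' disease: identical intervals belonging to different diseases are all
#' kept. Of two identical intervals of the same disease only the first (in
#' sorted order) is retained. The operation is idempotent.
#'
#' @param loci data frame with at least `chrom`, `start`, `end`, `disease`.
#' @param per_disease if `FALSE`, containment is tested across diseases too.
#' @return the surviving loci, ordered by (chrom, start, end, disease).
#' @export
deduplicate_loci <- function(loci, per_disease = TRUE) {
  if (nrow(loci) == 0) return(loci)
  loci <- order_loci(loci)
  grp <- if (per_disease) paste(loci$disease, loci$chrom) else loci$chrom
  drop <- logical(nrow(loci))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    s <- loci$start[idx]; e <- loci$end[idx]
    for (j in seq_along(idx)) {
      # contained in any other member; identical intervals keep the first
      inside <- s <= s[j] & e >= e[j] & seq_along(idx) != j
      identical_iv <- s == s[j] & e == e[j]
      container <- inside & (!identical_iv | seq_along(idx) < j)
      if (any(container & !drop[idx])) drop[idx[j]] <- TRUE
    }
  }
  out <- loci[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose loci of multiple diseases into shared regions
#'
#' Reports every maximal interval covered by loci of at least two distinct
#' diseases, annotated with the exact disease set over the interval and the
#' contributing loci. Adjacent segments are merged only when they touch
#' (no gap) and carry an identical disease set, so the decomposition is the
#' unique coarsest partition consistent with per-base disease membership.
#'
#' @param loci data frame with `chrom`, `start`, `end`, `disease` and
#'   optionally `locus_id`.
#' @param min_diseases minimum number of distinct diseases (default 2).
#' @return data frame with `chrom`, `start`, `end`, `diseases`
#'   (semicolon-joined, sorted), `n_diseases`, `source_loci`
#'   (semicolon-joined locus ids).
#' @export
find_shared_regions <- function(loci, min_diseases = 2) {
  stopifnot(length(unique(loci$disease)) >= 1)
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- sprintf("locus%d", seq_len(nrow(loci)))
  }
  res <- list()
  for (ch in unique(loci$chrom)) {
    lc <- loci[loci$chrom == ch, , drop = FALSE]
    # elementary intervals between consecutive breakpoints
    bp <- sort(unique(c(lc$start, lc$end + 1)))
    if (length(bp) < 2) next
    seg_start <- bp[-length(bp)]
    seg_end <- bp[-1] - 1
    segs <- list()
    for (k in seq_along(seg_start)) {
      cover <- lc$start <= seg_start[k] & lc$end >= seg_end[k]
      dis <- sort(unique(lc$disease[cover]))
      if (length(dis) < min_diseases) next
      segs[[length(segs) + 1]] <- list(
        start = seg_start[k], end = seg_end[k],
        diseases = paste(dis, collapse = ";"))
    }
    if (length(segs) == 0) next
    # merge touching segments with identical disease sets
    merged <- list(segs[[1]])
    for (k in seq_along(segs)[-1]) {
      last <- merged[[length(merged)]]
      cur <- segs[[k]]
      if (cur$start == last$end + 1 && cur$diseases == last$diseases) {
        last$end <- cur$end
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1]] <- cur
      }
    }
    for (m in merged) {
      # source loci: those containing the whole merged region, so every
      # reported region is a subset of each of its source loci
      src <- lc$locus_id[lc$start <= m$start & lc$end >= m$end]
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = m$start, end = m$end, diseases = m$diseases,
        n_diseases = length(strsplit(m$diseases, ";")[[1]]),
        source_loci = paste(sort(src), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), diseases = character(0),
                      n_diseases = integer(0), source_loci = character(0)))
  }
  order_loci(do.call(rbind, res))
}
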