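# Regulatory overlap statistics: loop-connected DMRs, hypergeometric motif
# enrichment, fine-mapped SNP overlap (Fisher), SNP-gene linking through
# loops, and the jackknife-SE heritability-enrichment difference t-test.

#' Published fine-mapping tally used for summary statistics
#'
#' The schizophrenia fine-mapping input consists of 190 independent loci
#' containing 569 autosomal high-confidence putative causal SNPs (posterior
#' inclusion probability > 0.1).
#' @export
finemap_counts <- list(n_loci = 190L, n_snps = 569L)

#' Mean credible-set size from fine-mapping counts
#' @param n_snps total high-confidence SNPs.
#' @param n_loci number of independent loci.
#' @return mean SNPs per credible set.
#' @export
mean_credible_set_size <- function(n_snps = finemap_counts$n_snps,
                                   n_loci = finemap_counts$n_loci) {
  n_snps / n_loci
}

overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(intervals_to_granges(query),
                                intervals_to_granges(subject)))
  seq_len(nrow(query)) %in% S4Vectors::queryHits(hits)
}

#' Loop-connected DMRs
#'
#' DMRs overlapping (>= 1 bp) any loop anchor of the matching cell type.
#'
#' @param dmrs interval table with a cell_type column.
#' @param loops loop table with chrom, bin1, bin2 and cell_type.
#' @param resolution anchor bin size in bp.
#' @return the loop-connected subset of `dmrs`.
#' @export
loop_connected_dmrs <- function(dmrs, loops, resolution = 1e4) {
  dmrs <- data.table::as.data.table(dmrs)
  loops <- loop_anchor_intervals(loops, resolution)
  anchors <- data.table::rbindlist(list(
    loops[, list(chrom = chrom, start = start1, end = end1, cell_type = cell_type)],
    loops[, list(chrom = chrom, start = start2, end = end2, cell_type = cell_type)]))
  keep <- logical(nrow(dmrs))
  for (ct in unique(dmrs$cell_type)) {
    di <- which(dmrs$cell_type == ct)
    an <- anchors[anchors$cell_type == ct, ]
    if (nrow(an)) keep[di] <- overlaps_any(dmrs[di, ], an)
  }
  dmrs[keep, ]
}

extend_from_edges <- function(x, flank) {
  x <- data.table::as.data.table(x)
  x$start <- pmax(0L, x$start - as.integer(flank)); x$end <- x$end + as.integer(flank)
  x
}

extend_from_centre <- function(x, flank) {
  x <- data.table::as.data.table(x)
  centre <- as.integer(floor((x$start + x$end) / 2))
  x$start <- pmax(0L, centre - as.integer(flank)); x$end <- centre + as.integer(flank)
  x
}

#' Hypergeometric motif enrichment in DMRs
#'
#' Foreground DMRs are extended 250 bp from their edges, background DMRs
#' 250 bp from their centres; overlap with motif hits requires >= 1 bp.
#' With N background DMRs of which K overlap a hit, and n foreground DMRs
#' of which x overlap, the enrichment p value is the upper-tail
#' hypergeometric `P(X >= x)` and the fold is `(x/n)/(K/N)`.
#'
#' @param fg_dmrs,bg_dmrs interval tables.
#' @param motif_hits interval table of motif hits.
#' @param flank extension in bp.
#' @return list with x, n, K, N, fold and p.
#' @export
motif_enrichment <- function(fg_dmrs, bg_dmrs, motif_hits, flank = 250L) {
  fg <- extend_from_edges(fg_dmrs, flank)
  bg <- extend_from_centre(bg_dmrs, flank)
  x <- sum(overlaps_any(fg, motif_hits))
  K <- sum(overlaps_any(bg, motif_hits))
  N <- nrow(bg); n <- nrow(fg)
  p <- if (x == 0) 1 else stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K > 0) (x / n) / (K / N) else Inf
  list(x = x, n = n, K = K, N = N, fold = fold, p = p)
}

#' Overlap between fine-mapped SNPs and an annotation
#'
#' SNPs are filtered to PIP > `pip_threshold`; the 2x2 table (fine-mapped
#' vs background) x (in vs out of the annotation) gives the odds ratio
#' ad/bc and a two-sided Fisher exact p. Per locus, the hit indicator is
#' whether any retained SNP of the locus falls in the annotation.
#'
#' @param snps table with chrom, pos (1-based), locus, pip.
#' @param annotation interval table (0-based half-open).
#' @param background_snps table with chrom, pos of all background SNPs.
#' @param pip_threshold PIP filter.
#' @return list with the table cells a/b/c/d, odds_ratio, p, and per-locus
#'   hit table.
#' @export
finemap_overlap <- function(snps, annotation, background_snps,
                            pip_threshold = 0.1) {
  snps <- data.table::as.data.table(snps)
  snps <- snps[snps$pip > pip_threshold, ]
  stop_if_not(nrow(snps) > 0, "no SNPs pass the PIP filter")
  snp_iv <- function(s) data.table::data.table(chrom = s$chrom,
                                               start = s$pos - 1L, end = s$pos)
  in_fm <- overlaps_any(snp_iv(snps), annotation)
  in_bg <- overlaps_any(snp_iv(background_snps), annotation)
  a <- sum(in_fm); b <- sum(!in_fm)
  c <- sum(in_bg); d <- sum(!in_bg)
  or <- if (b > 0 && c > 0) (a * d) / (b * c) else Inf
  p <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  loci <- data.table::data.table(locus = snps$locus, hit = in_fm)
  loci <- loci[, list(hit = any(hit)), by = "locus"]
  list(a = a, b = b, c = c, d = d, odds_ratio = or, p = p,
       per_locus = loci, n_loci_hit = sum(loci$hit))
}

#' Link putative causal SNPs to genes through chromatin loops
#'
#' A (snp, gene) pair is emitted when the SNP lies in a DMR overlapping one
#' loop anchor and the gene's TSS lies within `max_tss_dist` of the *other*
#' anchor (cross-anchor only); duplicates are collapsed.
#'
#' @param snps table with chrom, pos (1-based) and a snp id column.
#' @param dmrs interval table.
#' @param loops loop table with chrom, bin1, bin2.
#' @param tss_table table with gene, chrom, tss (0-based bp).
#' @param resolution anchor bin size in bp.
#' @param max_tss_dist TSS-anchor distance in bp.
#' @return `data.table` of unique (snp, gene) pairs.
#' @export
link_snp_to_genes <- function(snps, dmrs, loops, tss_table,
                              resolution = 1e4, max_tss_dist = 5e3) {
  snps <- data.table::as.data.table(snps)
  loops <- loop_anchor_intervals(loops, resolution)
  snp_iv <- data.table::data.table(chrom = snps$chrom, start = snps$pos - 1L,
                                   end = snps$pos)
  in_dmr <- overlaps_any(snp_iv, dmrs)
  pairs <- list()
  for (l in seq_len(nrow(loops))) {
    lp <- loops[l, ]
    for (side in 1:2) {
      s <- if (side == 1) lp$start1 else lp$start2
      e <- if (side == 1) lp$end1 else lp$end2
      os <- if (side == 1) lp$start2 else lp$start1
      oe <- if (side == 1) lp$end2 else lp$end1
      snp_here <- in_dmr & snps$chrom == lp$chrom &
        snps$pos - 1L >= s & snps$pos - 1L < e
      if (!any(snp_here)) next
      tss_near <- tss_table$chrom == lp$chrom &
        point_interval_gap(tss_table$tss, os, oe) <= max_tss_dist
      if (!any(tss_near)) next
      pairs[[length(pairs) + 1L]] <- data.table::CJ(
        snp = snps$snp[snp_here], gene = tss_table$gene[tss_near])
    }
  }
  if (!length(pairs))
    return(data.table::data.table(snp = character(), gene = character()))
  unique(data.table::rbindlist(pairs))
}

#' t-test for a difference of heritability enrichments
#'
#' Compares two S-LDSC-style enrichment estimates with block-jackknife
#' standard errors: `t = (e1 - e2) / sqrt(se1^2 + se2^2)` with
#' `2 * n_blocks - 2` degrees of freedom (398 at the default 200 blocks),
#' two-sided.
#'
#' @param e1,se1,e2,se2 enrichments and their jackknife SEs.
#' @param n_blocks jackknife block count per annotation.
#' @return list with t, df and p.
#' @export
enrichment_difference_test <- function(e1, se1, e2, se2, n_blocks = 200L) {
  stop_if_not(se1 > 0 && se2 > 0, "standard errors must be positive")
  tt <- (e1 - e2) / sqrt(se1^2 + se2^2)
  df <- 2L * n_blocks - 2L
  list(t = tt, df = df, p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}
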