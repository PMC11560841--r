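# Methylome features: cell QC, region-level methylation fractions with the
# coverage filter/imputation rule, 3C gene scores (3CGS) and cross-feature
# correlations.

#' Single-cell quality control
#'
#' A cell passes iff mCCC < 0.03, global mCG > 0.5, global mCH < 0.2 and
#' total cis contacts > 100,000 (all strict, as printed).
#'
#' @param metadata table with columns mccc_level, global_mcg, global_mch,
#'   n_contacts (one row per cell).
#' @return input with a logical `pass` column and a `fail_reason` column.
#' @export
cell_qc <- function(metadata) {
  x <- data.table::as.data.table(metadata)
  need <- c("mccc_level", "global_mcg", "global_mch", "n_contacts")
  miss <- setdiff(need, names(x))
  stop_if_not(length(miss) == 0,
              paste("missing QC metrics:", paste(miss, collapse = ", ")))
  stop_if_not(!anyNA(x[, need, with = FALSE]), "missing QC metric values")
  ok_mccc <- x$mccc_level < 0.03
  ok_mcg <- x$global_mcg > 0.5
  ok_mch <- x$global_mch < 0.2
  ok_n <- x$n_contacts > 1e5
  x$pass <- ok_mccc & ok_mcg & ok_mch & ok_n
  reason <- character(nrow(x))
  reason[!ok_n] <- "contacts"
  reason[!ok_mch] <- "mCH"
  reason[!ok_mcg] <- "mCG"
  reason[!ok_mccc] <- "mCCC"
  x$fail_reason <- reason
  x
}

# context 3-mer -> context class. CG sites start with "CG"; CCC is its own
# class (a non-conversion proxy); CH is any non-CG context.
context_class <- function(context, class = c("CG", "CH", "CCC")) {
  class <- match.arg(class)
  switch(class,
         CG = startsWith(context, "CG"),
         CH = !startsWith(context, "CG"),
         CCC = context == "CCC")
}

#' Methylation fraction of one cell over a set of regions
#'
#' fraction = sum(mc) / sum(cov) over records of the requested context
#' class falling inside each region (0-based half-open intervals).
#'
#' @param allc an allc table (see [allc_table()]).
#' @param regions interval table (chrom, start, end); for gene bodies,
#'   pre-expand with [expand_regions()].
#' @param context "CG", "CH" or "CCC".
#' @return `data.table` with region index, fraction (NA when the region has
#'   no coverage) and coverage.
#' @export
region_methylation <- function(allc, regions, context = "CG") {
  allc <- allc_table(allc)
  regions <- validate_intervals(regions)
  keep <- context_class(allc$context, context)
  sub <- allc[keep, ]
  gr_sites <- GenomicRanges::GRanges(sub$chrom,
                                     IRanges::IRanges(sub$pos, sub$pos))
  gr_regions <- intervals_to_granges(regions)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_sites, gr_regions))
  mc <- cov <- rep(0, nrow(regions))
  if (length(hits)) {
    agg <- data.table::data.table(
      region = S4Vectors::subjectHits(hits),
      mc = sub$mc[S4Vectors::queryHits(hits)],
      cov = sub$cov[S4Vectors::queryHits(hits)])
    agg <- agg[, list(mc = sum(mc), cov = sum(cov)), by = "region"]
    mc[agg$region] <- agg$mc
    cov[agg$region] <- agg$cov
  }
  data.table::data.table(region = seq_len(nrow(regions)),
                         fraction = ifelse(cov > 0, mc / cov, NA_real_),
                         coverage = cov)
}

#' Expand intervals on both sides (gene body +/- flank)
#' @param regions interval table.
#' @param flank bp added to each side.
#' @param chrom_length optional clipping bound.
#' @return expanded interval table.
#' @export
expand_regions <- function(regions, flank = 2e3, chrom_length = NULL) {
  x <- data.table::as.data.table(regions)
  x$start <- pmax(0L, x$start - as.integer(flank))
  x$end <- x$end + as.integer(flank)
  if (!is.null(chrom_length)) x$end <- pmin(x$end, as.integer(chrom_length))
  x
}

#' Cell-by-region methylation feature matrices
#'
#' @param allc_list named list of per-cell allc tables.
#' @param regions interval table.
#' @param context "CG" or "CH".
#' @return list with `fractions` and `coverage` matrices (cells x regions).
#' @export
methylation_feature_matrix <- function(allc_list, regions, context = "CG") {
  per <- lapply(allc_list, region_methylation, regions = regions,
                context = context)
  list(fractions = do.call(rbind, lapply(per, `[[`, "fraction")),
       coverage = do.call(rbind, lapply(per, `[[`, "coverage")))
}

#' Coverage filter and by-sample imputation of methylation features
#'
#' Features (columns) with mean coverage below `min_mean_cov` are dropped;
#' entries with coverage below `impute_below` are replaced by the mean
#' feature value of the cell's sample, computed over entries with adequate
#' coverage. Features for which some sample has no adequately covered entry
#' are dropped (and reported).
#'
#' @param fractions,coverage matrices (cells x features).
#' @param samples sample label per cell.
#' @param min_mean_cov mean-coverage filter (features).
#' @param impute_below entry-coverage threshold for imputation.
#' @return list with filtered/imputed `fractions`, matching `coverage`,
#'   and the integer indices of `dropped` features.
#' @export
filter_impute_features <- function(fractions, coverage, samples,
                                   min_mean_cov = 10, impute_below = 5) {
  stop_if_not(all(dim(fractions) == dim(coverage)),
              "fractions/coverage shape mismatch")
  stop_if_not(nrow(fractions) == length(samples), "samples/cells mismatch")
  keep <- which(colMeans(coverage) >= min_mean_cov)
  dropped <- setdiff(seq_len(ncol(fractions)), keep)
  fr <- fractions[, keep, drop = FALSE]
  cv <- coverage[, keep, drop = FALSE]
  su <- unique(samples)
  bad <- logical(ncol(fr))
  for (s in su) {
    rows <- which(samples == s)
    good <- cv[rows, , drop = FALSE] >= impute_below
    means <- colSums(fr[rows, , drop = FALSE] * good, na.rm = TRUE) /
      colSums(good)
    bad <- bad | colSums(good) == 0
    for (jj in seq_len(ncol(fr))) {
      low <- rows[!good[, jj]]
      if (length(low)) fr[low, jj] <- means[jj]
    }
  }
  if (any(bad)) {
    message(sprintf("dropping %d features with no covered entry in some sample",
                    sum(bad)))
    dropped <- sort(c(dropped, keep[bad]))
    fr <- fr[, !bad, drop = FALSE]
    cv <- cv[, !bad, drop = FALSE]
    keep <- keep[!bad]
  }
  list(fractions = fr, coverage = cv, kept = keep, dropped = dropped)
}

#' 3C gene score (3CGS) of one gene in one cell
#'
#' The sum of off-diagonal imputed contact values over upper-triangle
#' pixels having at least one end in the gene's TSS..TES bin span,
#' restricted to the imputed distance band. Strand is handled by taking the
#' min/max of the TSS and TES bins, so - strand genes score identically.
#'
#' @param Q the cell's imputed 10-kb `band_matrix`.
#' @param tss_bin,tes_bin 0-based bins of the TSS and TES.
#' @return the score, with attribute `truncated` = TRUE when the gene span
#'   exceeds the imputation band (distal pixels not summed).
#' @export
gene_3cgs <- function(Q, tss_bin, tes_bin) {
  g1 <- min(tss_bin, tes_bin); g2 <- max(tss_bin, tes_bin)
  n <- Q$n_bins
  stop_if_not(g1 >= 0 && g2 < n, "gene outside matrix")
  total <- 0
  for (d in seq_len(Q$max_offset)) {
    i <- seq_len(n - d)
    v <- Q$mat[d + 1L, i]
    b1 <- i - 1L
    b2 <- b1 + d
    ing <- (b1 >= g1 & b1 <= g2) | (b2 >= g1 & b2 <= g2)
    total <- total + sum(v[ing], na.rm = TRUE)
  }
  attr(total, "truncated") <- max(g2, n - 1L - g1) > Q$max_offset
  total
}

#' 3CGS for a gene table across cells
#' @param Q_list list of per-cell `band_matrix` objects at 10 kb.
#' @param genes interval table with strand (see [gene_tss_tes()]).
#' @param resolution bin size in bp.
#' @return matrix (cells x genes).
#' @export
gene_3cgs_matrix <- function(Q_list, genes, resolution = 1e4) {
  genes <- gene_tss_tes(genes)
  tssb <- pos_to_bin(genes$tss + 1L, resolution)
  tesb <- pos_to_bin(genes$tes + 1L, resolution)
  g1 <- pmin(tssb, tesb); g2 <- pmax(tssb, tesb)
  ng <- length(g1)
  # prefix-sum fast path: for offset d the pixels with an end in [g1, g2]
  # have left bin i in [g1-d, g2] (one interval when d <= span, else two)
  score_cell <- function(Q) {
    n <- Q$n_bins
    tot <- numeric(ng)
    for (d in seq_len(Q$max_offset)) {
      v <- Q$mat[d + 1L, seq_len(n - d)]
      cs <- c(0, cumsum(v))
      seg <- function(a, b) {  # sum of v over 0-based left bins [a, b]
        a <- max(a, 0L); b <- min(b, n - d - 1L)
        if (a > b) 0 else cs[b + 2L] - cs[a + 1L]
      }
      for (g in seq_len(ng)) {
        span <- g2[g] - g1[g]
        tot[g] <- tot[g] + if (d <= span) seg(g1[g] - d, g2[g]) else
          seg(g1[g] - d, g2[g] - d) + seg(g1[g], g2[g])
      }
    }
    tot
  }
  out <- t(vapply(Q_list, score_cell, numeric(ng)))
  rownames(out) <- names(Q_list)
  colnames(out) <- genes$name
  out
}

#' Per-feature Pearson correlations between two paired matrices
#'
#' @param matrix_a,matrix_b matrices with matched rows (cells/meta-cells)
#'   and shared feature columns.
#' @return named numeric vector of per-feature r (NA for features with
#'   fewer than 3 complete pairs or zero variance).
#' @export
feature_correlations <- function(matrix_a, matrix_b) {
  stop_if_not(nrow(matrix_a) == nrow(matrix_b), "unmatched observations")
  shared <- intersect(colnames(matrix_a) %||% seq_len(ncol(matrix_a)),
                      colnames(matrix_b) %||% seq_len(ncol(matrix_b)))
  r <- vapply(shared, function(f) {
    a <- matrix_a[, f]; b <- matrix_b[, f]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }, numeric(1))
  names(r) <- shared
  r
}
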