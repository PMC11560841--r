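# Domain analysis at 25-kb resolution: insulation scores, per-cell boundary
# calls, group boundary probabilities and the chi-square differential
# boundary test.

#' Insulation score of a contact matrix
#'
#' `score(b)` is the mean of Q over bin pairs (i, j) with
#' `b - window <= i <= b < j <= b + window`, i.e. the contacts crossing the
#' gap between bins b and b+1 within a `window`-bin square, clipped at the
#' chromosome ends. Raw means are reported (no log-ratio normalization).
#'
#' @param Q a `band_matrix` (pseudobulk or single-cell imputed matrix).
#' @param window window size in bins.
#' @return numeric vector of per-bin scores (the last bin, which has no
#'   crossing pairs, is `NA`).
#' @export
insulation_score <- function(Q, window = 10L) {
  stop_if_not(window >= 1L, "window must be >= 1")
  as.vector(insulation_cpp(Q$mat, as.integer(window)))
}

# strict local minima/maxima of a numeric profile (NA-tolerant at the ends)
local_extrema <- function(x, maxima = FALSE) {
  if (maxima) x <- -x
  n <- length(x)
  out <- logical(n)
  for (i in 2:(n - 1L)) {
    if (is.na(x[i]) || is.na(x[i - 1L]) || is.na(x[i + 1L])) next
    out[i] <- x[i] < x[i - 1L] && x[i] < x[i + 1L]
  }
  out
}

#' Per-cell domain boundary calls from insulation minima
#'
#' A bin is a boundary when the cell's insulation profile has a strict local
#' minimum there that lies below both flanking local maxima (or the running
#' maximum toward the profile end) by at least `margin_frac` of the
#' profile's range.
#'
#' @param Q the cell's imputed 25-kb `band_matrix`.
#' @param window insulation window in bins.
#' @param margin_frac prominence threshold as a fraction of the profile
#'   range; `Inf` suppresses all calls.
#' @return logical vector of per-bin boundary indicators.
#' @export
percell_boundaries <- function(Q, window = 10L, margin_frac = 0.02) {
  n <- Q$n_bins
  stop_if_not(n >= 2L * window, "chromosome shorter than 2*window bins")
  prof <- insulation_score(Q, window)
  out <- logical(n)
  ok <- which(!is.na(prof))
  if (length(ok) < 3L) return(out)
  rng <- diff(range(prof[ok]))
  if (!is.finite(rng) || rng == 0) return(out)
  margin <- margin_frac * rng
  if (!is.finite(margin)) return(out)
  mins <- which(local_extrema(prof))
  maxs <- which(local_extrema(prof, maxima = TRUE))
  for (b in mins) {
    left <- maxs[maxs < b]
    right <- maxs[maxs > b]
    lmax <- if (length(left)) prof[max(left)] else max(prof[ok[ok < b]], -Inf)
    rmax <- if (length(right)) prof[min(right)] else max(prof[ok[ok > b]], -Inf)
    if (is.finite(lmax) && is.finite(rmax) &&
        lmax - prof[b] >= margin && rmax - prof[b] >= margin)
      out[b] <- TRUE
  }
  out
}

#' Boundary probability per group
#'
#' @param calls logical matrix (cells x bins) of boundary calls.
#' @param groups group label per cell.
#' @return matrix (groups x bins) of exact per-bin fractions.
#' @export
boundary_probability <- function(calls, groups) {
  stop_if_not(nrow(calls) == length(groups), "calls/groups mismatch")
  gs <- sort(unique(as.character(groups)))
  out <- t(vapply(gs, function(g) {
    idx <- which(groups == g)
    stop_if_not(length(idx) > 0, "empty group")
    colMeans(calls[idx, , drop = FALSE])
  }, numeric(ncol(calls))))
  rownames(out) <- gs
  out
}

#' Pearson chi-square statistic of an n x 2 contingency table
#' @param tab matrix with groups in rows, (boundary, not boundary) columns.
#' @return list with statistic, df and p (no continuity correction).
#' @export
chisq_stat <- function(tab) {
  n <- sum(tab)
  exp <- outer(rowSums(tab), colSums(tab)) / n
  stop_if_not(all(exp > 0), "zero expected count; chi-square undefined")
  stat <- sum((tab - exp)^2 / exp)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Differential domain boundaries between cell groups
#'
#' Per 25-kb bin, a group x (boundary, not) contingency table is formed
#' from the per-cell calls and its Pearson chi-square computed (bins with a
#' zero expected count are excluded and logged). P values are
#' Benjamini-Hochberg adjusted across all bins; candidate peaks are local
#' maxima of the chi-square profile with FDR < `fdr_threshold`; peaks
#' closer than `merge_bins` bins keep only the higher statistic. Surviving
#' peaks must additionally satisfy a genome-wide z-scored chi-square above
#' `z_threshold`, a max/min insulation fold change above `fc_threshold`
#' and a boundary-probability range above `prob_range_threshold`.
#'
#' @param calls logical matrix (cells x bins).
#' @param groups group label per cell.
#' @param insulation matrix (groups x bins) of group insulation scores.
#' @param fdr_threshold BH-adjusted p cutoff for peaks.
#' @param z_threshold z cutoff (default `qnorm(0.975)`).
#' @param fc_threshold insulation max/min fold-change cutoff.
#' @param prob_range_threshold boundary-probability range cutoff.
#' @param merge_bins peaks closer than this many bins are merged.
#' @return `data.table` with per-bin statistics and the is_peak flag;
#'   excluded bins carry `NA` statistics.
#' @export
differential_boundaries <- function(calls, groups, insulation,
                                    fdr_threshold = 1e-3,
                                    z_threshold = qnorm(0.975),
                                    fc_threshold = 1.2,
                                    prob_range_threshold = 0.05,
                                    merge_bins = 5L) {
  gs <- sort(unique(as.character(groups)))
  stop_if_not(length(gs) >= 2L, "need at least 2 groups")
  stop_if_not(all(gs %in% rownames(insulation)),
              "insulation rows must match groups")
  insulation <- insulation[gs, , drop = FALSE]
  nb <- ncol(calls)
  k_g <- boundary_probability(calls, groups)
  n_g <- as.vector(table(factor(groups, levels = gs)))
  chi2 <- rep(NA_real_, nb); pval <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    yes <- round(k_g[, b] * n_g)
    tab <- cbind(yes, n_g - yes)
    if (any(colSums(tab) == 0)) next
    cs <- chisq_stat(tab)
    chi2[b] <- cs$statistic; pval[b] <- cs$p
  }
  ok <- !is.na(chi2)
  fdr <- rep(NA_real_, nb)
  fdr[ok] <- p.adjust(pval[ok], method = "BH")
  z <- rep(NA_real_, nb)
  if (sum(ok) > 1L) z[ok] <- (chi2[ok] - mean(chi2[ok])) / sd(chi2[ok])
  prof <- chi2
  prof[is.na(prof)] <- -Inf
  is_max <- c(FALSE, vapply(2:(nb - 1L), function(b)
    prof[b] > prof[b - 1L] && prof[b] >= prof[b + 1L], logical(1)), FALSE)
  peaks <- which(is_max & ok & fdr < fdr_threshold)
  # merge peaks within < merge_bins of each other, keeping the higher chi2;
  # repeated until stable so the result is scan-order independent
  repeat {
    if (length(peaks) < 2L) break
    gaps <- diff(peaks)
    close_idx <- which(gaps < merge_bins)
    if (!length(close_idx)) break
    i <- close_idx[1]
    drop <- if (chi2[peaks[i]] >= chi2[peaks[i + 1]]) i + 1L else i
    peaks <- peaks[-drop]
  }
  ins_fc <- apply(insulation, 2L, function(v)
    if (all(is.finite(v)) && min(v) > 0) max(v) / min(v) else NA_real_)
  prob_range <- apply(k_g, 2L, function(v) max(v) - min(v))
  is_peak <- logical(nb)
  is_peak[peaks] <- z[peaks] > z_threshold &
    !is.na(ins_fc[peaks]) & ins_fc[peaks] > fc_threshold &
    prob_range[peaks] > prob_range_threshold
  data.table::data.table(
    bin = seq_len(nb) - 1L, chi2 = chi2, p = pval, fdr = fdr, z_chi2 = z,
    insulation_fc = ins_fc, prob_range = prob_range,
    is_candidate_peak = seq_len(nb) %in% peaks, is_peak = is_peak)
}
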