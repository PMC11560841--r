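# A/B compartment analysis at 1-Mb resolution: O/E matrices, correlation-
# matrix eigenvectors signed by GC content, saddle sums with
# compartmentalization strength and dominance, and A<->B transition
# methylation statistics.

#' Observed/expected matrix from a pseudobulk contact matrix
#'
#' Each diagonal is divided by its mean (the distance-decay expectation);
#' empty diagonals map to 0.
#'
#' @param M dense symmetric contact matrix.
#' @return dense O/E matrix of the same shape.
#' @export
oe_matrix <- function(M) {
  n <- nrow(M)
  OE <- matrix(0, n, n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    v <- M[cbind(i, i + d)]
    mu <- mean(v)
    w <- if (is.finite(mu) && mu > 0) v / mu else rep(0, length(v))
    OE[cbind(i, i + d)] <- w
    OE[cbind(i + d, i)] <- w
  }
  OE
}

#' Compartment eigenvector of a pseudobulk matrix
#'
#' The O/E matrix is computed per diagonal, its Pearson correlation matrix
#' formed over informative bins, and among the top 3 eigenvectors the one
#' with the highest |Pearson correlation| with the GC-content track is
#' chosen; its sign is flipped so the correlation is non-negative, making
#' positive values the A compartment. The magnitude is the strength of the
#' compartment assignment.
#'
#' @param M dense symmetric pseudobulk matrix (1-Mb bins).
#' @param gc_track numeric GC content per bin, aligned with `M`.
#' @return numeric eigenvector (NA at uninformative bins), with attributes
#'   `eigen_index` and `gc_cor`.
#' @export
compartment_eigenvector <- function(M, gc_track) {
  n <- nrow(M)
  stop_if_not(length(gc_track) == n, "gc track must match the matrix bins")
  stop_if_not(any(M > 0), "all-zero matrix")
  OE <- oe_matrix(M)
  inf_bins <- which(rowSums(OE) > 0 & apply(OE, 1L, sd) > 0)
  stop_if_not(length(inf_bins) >= 10L, "need >= 10 informative bins")
  C <- suppressWarnings(cor(OE[inf_bins, inf_bins]))
  C[!is.finite(C)] <- 0
  ev <- eigen(C, symmetric = TRUE)
  k_top <- seq_len(min(3L, ncol(ev$vectors)))
  cors <- vapply(k_top, function(k)
    suppressWarnings(cor(ev$vectors[, k], gc_track[inf_bins])), numeric(1))
  cors[!is.finite(cors)] <- 0
  best <- which.max(abs(cors))
  v <- ev$vectors[, best]
  if (cors[best] < 0) v <- -v
  out <- rep(NA_real_, n)
  out[inf_bins] <- v
  attr(out, "eigen_index") <- best
  attr(out, "gc_cor") <- abs(cors[best])
  out
}

#' Saddle statistics and compartmentalization strength
#'
#' Among A bins (eigenvector > 0) and B bins (< 0), the bins whose
#' assignment strengths are in the top `top_pct` percentile of their
#' compartment are selected, and the O/E sums over AA, BB, AB and BA pairs
#' of selected bins are formed. Strength is
#' `(sum AA + sum BB) / (sum AB + sum BA)`; AA/BB dominance is the fraction
#' of the four sums explained by AA (resp. BB). Pseudobulks below
#' `min_contacts` total contacts are flagged, not dropped.
#'
#' @param OE dense O/E matrix.
#' @param track compartment eigenvector aligned with `OE`.
#' @param top_pct percentile (in percent) defining the strongest bins.
#' @param n_contacts total contacts of the pseudobulk (for the flag).
#' @param min_contacts flag threshold.
#' @return list with the four sums, strength, AA_dominance, BB_dominance
#'   and low_contact flag.
#' @export
saddle_stats <- function(OE, track, top_pct = 20, n_contacts = NA,
                         min_contacts = 30e6) {
  a_bins <- which(!is.na(track) & track > 0)
  b_bins <- which(!is.na(track) & track < 0)
  stop_if_not(length(a_bins) > 0 && length(b_bins) > 0,
              "need both A and B bins for saddle statistics")
  top_of <- function(bins) {
    s <- abs(track[bins])
    bins[s >= quantile(s, 1 - top_pct / 100)]
  }
  ta <- top_of(a_bins); tb <- top_of(b_bins)
  AA <- sum(OE[ta, ta]); BB <- sum(OE[tb, tb])
  AB <- sum(OE[ta, tb]); BA <- sum(OE[tb, ta])
  tot <- AA + BB + AB + BA
  list(AA = AA, BB = BB, AB = AB, BA = BA,
       strength = (AA + BB) / (AB + BA),
       AA_dominance = AA / tot, BB_dominance = BB / tot,
       low_contact = is.finite(n_contacts) && n_contacts < min_contacts)
}

#' A<->B compartment transitions between two ages
#'
#' @param track_early,track_late compartment eigenvectors on the same grid.
#' @return list with integer bin sets (0-based) `AB` (A at the early age, B
#'   at the late age) and `BA`; zero or NA bins are excluded.
#' @export
compartment_transitions <- function(track_early, track_late) {
  stop_if_not(length(track_early) == length(track_late), "grid mismatch")
  ok <- !is.na(track_early) & !is.na(track_late) &
    track_early != 0 & track_late != 0
  list(AB = which(ok & track_early > 0 & track_late < 0) - 1L,
       BA = which(ok & track_early < 0 & track_late > 0) - 1L)
}

#' Methylation dynamics of transitioning compartment bins
#'
#' Per-bin mCG levels are normalized by subtracting the earliest age's
#' level; at each age, AB versus BA bins are compared with a two-sided
#' Wilcoxon rank-sum (Mann-Whitney U) test.
#'
#' @param transitions output of [compartment_transitions()].
#' @param mcg_by_age matrix (bins x ages) of mCG levels, ages in temporal
#'   order.
#' @return list with delta matrices `AB` and `BA` (bins x ages) and a
#'   `data.table` of per-age p values.
#' @export
transition_methylation <- function(transitions, mcg_by_age) {
  stop_if_not(ncol(mcg_by_age) >= 2L, "need at least 2 ages")
  stop_if_not(length(transitions$AB) + length(transitions$BA) > 0,
              "empty transition sets")
  deltas <- mcg_by_age - mcg_by_age[, 1L]
  ab <- deltas[transitions$AB + 1L, , drop = FALSE]
  ba <- deltas[transitions$BA + 1L, , drop = FALSE]
  ages <- colnames(mcg_by_age) %||% paste0("age", seq_len(ncol(mcg_by_age)))
  ps <- vapply(seq_len(ncol(deltas)), function(a) {
    if (a == 1L || !nrow(ab) || !nrow(ba)) return(NA_real_)
    suppressWarnings(wilcox.test(ab[, a], ba[, a], exact = FALSE)$p.value)
  }, numeric(1))
  list(AB = ab, BA = ba,
       tests = data.table::data.table(age = ages, p = ps))
}
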