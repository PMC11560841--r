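# Contact-distance decay analysis: the 143-bin log2 histogram, the
# percentage-median / percentage-long conformation metrics and SE/INT/LE
# classes, k-means conformation clusters, cluster enrichment and the
# empirical cluster-similarity statistic.

N_DIST_BINS <- 143L
VALID_BINS <- 38:141
MEDIAN_BINS <- 38:89
LONG_BINS <- 90:141

#' Distance-bin edges of the 143-bin logarithmic scheme
#'
#' Bin 1 holds contacts separated by less than 1 kb (read as 2^10 bp so the
#' base-2 ladder is exact); bin k >= 2 covers
#' `[2^(10+(k-2)/8), 2^(10+(k-1)/8))` bp -- an exponent step of 0.125 in
#' base 2.
#'
#' @return numeric vector of length 144: lower edges of bins 1..143 plus the
#'   upper edge of bin 143.
#' @export
distance_bin_edges <- function() {
  c(0, 2^(10 + (0:142) / 8))
}

#' Histogram cis contact distances into the 143 logarithmic bins
#'
#' @param contacts table with pos1, pos2 (1-based bp; cis contacts only).
#' @return integer vector of 143 counts with attribute `n_dropped`, the
#'   number of contacts beyond the last bin edge.
#' @export
bin_distances <- function(contacts) {
  d <- as.double(contacts$pos2) - as.double(contacts$pos1)
  stop_if_not(all(d >= 0), "contacts must have pos1 <= pos2")
  k <- ifelse(d < 1024, 1L, 2L + floor(8 * (log2(pmax(d, 1)) - 10)))
  dropped <- sum(k > N_DIST_BINS)
  k <- k[k <= N_DIST_BINS]
  counts <- tabulate(k, nbins = N_DIST_BINS)
  attr(counts, "n_dropped") <- dropped
  counts
}

#' Conformation metrics from a distance histogram
#'
#' Bins 1-37 are treated as noise and bins 142-143 as beyond the valid
#' range; bins 38-141 are the valid bins. Percentage median is the fraction
#' of valid contacts in bins 38-89, percentage long the fraction in bins
#' 90-141, and cells are classed as SE (short-range enriched) when
#' `log2(pct_median/pct_long) > 0.4`, LE when `< -0.4`, INT otherwise
#' (closed interval; ties at +/-0.4 are INT).
#'
#' @param hist integer vector of 143 bin counts (see [bin_distances()]).
#' @return list with pct_median, pct_long, ratio and conformation_class.
#' @export
distance_metrics <- function(hist) {
  stop_if_not(length(hist) == N_DIST_BINS, "histogram must have 143 bins")
  valid <- sum(hist[VALID_BINS])
  stop_if_not(valid > 0, "no contacts in the valid bins; metrics undefined")
  pm <- sum(hist[MEDIAN_BINS]) / valid
  pl <- sum(hist[LONG_BINS]) / valid
  ratio <- log2(pm / pl)
  list(pct_median = pm, pct_long = pl, ratio = ratio,
       conformation_class = classify_ratio(ratio))
}

#' Classify a log2 median/long ratio into SE / INT / LE
#' @param ratio numeric vector of log2(pct_median/pct_long) values.
#' @return character vector in \{"SE", "INT", "LE"\}.
#' @export
classify_ratio <- function(ratio) {
  ifelse(ratio > 0.4, "SE", ifelse(ratio < -0.4, "LE", "INT"))
}

valid_profiles <- function(hists) {
  X <- hists[, VALID_BINS, drop = FALSE]
  rs <- rowSums(X)
  stop_if_not(all(rs > 0), "every cell needs contacts in the valid bins")
  X / rs
}

# Deterministic, input-order-invariant Lloyd k-means: initial centers are
# profiles at evenly spaced ranks of the ratio ordering, ties broken to the
# lowest center index; empty clusters keep their previous center.
lloyd_kmeans <- function(X, centers, iter_max = 100L) {
  k <- nrow(centers)
  lab <- integer(nrow(X))
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, nrow(X)), rowSums(centers^2))
    newlab <- max.col(-d2, ties.method = "first")
    if (it > 1L && all(newlab == lab)) break
    lab <- newlab
    for (c in seq_len(k)) {
      idx <- which(lab == c)
      if (length(idx)) centers[c, ] <- colMeans(X[idx, , drop = FALSE])
    }
  }
  lab
}

#' Cluster cells by their contact-distance profiles
#'
#' k-means (Lloyd, deterministic rank-based initialization) on the
#' L1-normalized valid-bin (38-141) profiles. Cluster labels are renumbered
#' so that cluster 1 has the highest mean log2(pct_median/pct_long), i.e.
#' the most short-range dominated conformation.
#'
#' @param hists matrix (cells x 143) of distance-bin counts.
#' @param k number of clusters.
#' @param seed unused (the initialization is deterministic); kept so callers
#'   can record an intended seed.
#' @return integer vector of cluster labels in 1..k.
#' @export
cluster_profiles <- function(hists, k = 10L, seed = NULL) {
  stop_if_not(nrow(hists) >= k, "fewer cells than clusters")
  X <- valid_profiles(hists)
  ratio <- apply(hists, 1L,
                 function(h) log2(sum(h[MEDIAN_BINS]) / sum(h[LONG_BINS])))
  uniq <- !duplicated(X)
  k_eff <- min(k, sum(uniq))
  ord <- order(ratio, X[, 1], method = "radix")
  ord_uniq <- ord[ord %in% which(uniq)]
  pick <- ord_uniq[unique(pmax(1L, round(seq(1, length(ord_uniq),
                                             length.out = k_eff))))]
  centers <- X[pick, , drop = FALSE]
  lab <- lloyd_kmeans(X, centers)
  means <- vapply(seq_len(k_eff), function(c) {
    idx <- which(lab == c)
    if (length(idx)) mean(ratio[idx]) else -Inf
  }, numeric(1))
  new_id <- integer(k_eff)
  new_id[order(means, decreasing = TRUE)] <- seq_len(k_eff)
  new_id[lab]
}

#' Cell-type enrichment of conformation clusters
#'
#' `enrichment[t, c]` is the fraction of type-t cells found in cluster c
#' divided by the fraction of all cells in cluster c; empty clusters yield
#' `NA`.
#'
#' @param labels integer cluster labels.
#' @param cell_types character/factor vector aligned with `labels`.
#' @return matrix (types x clusters) of enrichment scores.
#' @export
cluster_enrichment <- function(labels, cell_types) {
  stop_if_not(length(labels) == length(cell_types),
              "labels and cell_types must be aligned")
  cl <- sort(unique(labels))
  ty <- sort(unique(as.character(cell_types)))
  n <- length(labels)
  out <- matrix(NA_real_, length(ty), length(cl),
                dimnames = list(ty, as.character(cl)))
  size_frac <- vapply(cl, function(c) sum(labels == c) / n, numeric(1))
  for (t in seq_along(ty)) {
    in_t <- cell_types == ty[t]
    for (c in seq_along(cl)) {
      if (size_frac[c] > 0)
        out[t, c] <- (sum(labels[in_t] == cl[c]) / sum(in_t)) / size_frac[c]
    }
  }
  out
}

#' Empirical similarity counts between conformation clusters
#'
#' For each cluster pair, `n_iter` random cross-cluster cell pairs are drawn
#' and the number of pairs whose valid-bin profiles have Pearson correlation
#' above `r_threshold` is counted.
#'
#' @param hists matrix (cells x 143) of distance-bin counts.
#' @param labels cluster labels.
#' @param n_iter number of sampled pairs per cluster pair.
#' @param r_threshold correlation threshold.
#' @param seed RNG seed.
#' @return symmetric matrix of counts (diagonal `NA`).
#' @export
cluster_similarity_pvalues <- function(hists, labels, n_iter = 1000L,
                                       r_threshold = 0.8, seed = NULL) {
  cl <- sort(unique(labels))
  stop_if_not(length(cl) >= 2L, "need at least 2 clusters")
  stop_if_not(all(table(labels) > 0), "empty cluster")
  X <- valid_profiles(hists)
  out <- matrix(NA_real_, length(cl), length(cl),
                dimnames = list(cl, cl))
  with_seed(seed, {
    for (a in seq_along(cl)) for (b in seq_along(cl)) {
      if (b <= a) next
      ia <- which(labels == cl[a]); ib <- which(labels == cl[b])
      sa <- ia[sample.int(length(ia), n_iter, replace = TRUE)]
      sb <- ib[sample.int(length(ib), n_iter, replace = TRUE)]
      r <- vapply(seq_len(n_iter),
                  function(i) suppressWarnings(cor(X[sa[i], ], X[sb[i], ])),
                  numeric(1))
      cnt <- sum(r > r_threshold, na.rm = TRUE)
      out[a, b] <- cnt
      out[b, a] <- cnt
    }
  })
  out
}

#' Per-cell conformation metrics table for a cohort
#'
#' @param contacts_by_cell named list of per-cell contact tables.
#' @param k number of conformation clusters (skipped if fewer cells).
#' @return `data.table` with cell_id, pct_median, pct_long, ratio, class and
#'   (when computed) cluster.
#' @export
distance_metrics_table <- function(contacts_by_cell, k = 10L) {
  hists <- do.call(rbind, lapply(contacts_by_cell, bin_distances))
  mets <- apply(hists, 1L, distance_metrics)
  dt <- data.table::data.table(
    cell_id = names(contacts_by_cell),
    pct_median = vapply(mets, `[[`, numeric(1), "pct_median"),
    pct_long = vapply(mets, `[[`, numeric(1), "pct_long"),
    ratio = vapply(mets, `[[`, numeric(1), "ratio"),
    class = vapply(mets, `[[`, character(1), "conformation_class"))
  if (nrow(hists) >= k) dt$cluster <- cluster_profiles(hists, k = k)
  dt
}
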