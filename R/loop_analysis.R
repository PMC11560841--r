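# Loop calling from pseudobulk summary statistics: pseudobulk t-statistics,
# empirical FDR against diagonal-shuffled backgrounds, HiCCUPS-style local
# fold-change filters, summary-statistic one-way ANOVA for differential
# loops, super-interactive promoters (SIPs) and cumulative loop scores.

#' Values of a band matrix at given pixels
#' @param bm a `band_matrix`.
#' @param bin1,bin2 0-based bin indices with bin1 < bin2.
#' @return numeric vector of values.
#' @export
band_values <- function(bm, bin1, bin2) {
  d <- bin2 - bin1
  stop_if_not(all(d >= 0 & d <= bm$max_offset), "pixel outside band")
  bm$mat[cbind(d + 1L, bin1 + 1L)]
}

#' Pseudobulk t-statistic of E or T against zero
#'
#' `t = mean / sqrt(max(meansq - mean^2, eps) / n_cell)`, i.e. the one-sample
#' t computed from the stored means of values and of squares; `eps` guards
#' zero variance.
#'
#' @param stats a `pseudobulk_stats` object.
#' @param which "E" or "T".
#' @param eps variance floor.
#' @return a `band_matrix` of t values.
#' @export
pseudobulk_tstat <- function(stats, which = c("E", "T"), eps = 1e-12) {
  which <- match.arg(which)
  stop_if_not(stats$n_cell >= 2L, "need at least 2 cells for a t-statistic")
  m <- stats[[which]]$mat
  m2 <- stats[[paste0(which, "2")]]$mat
  v <- pmax(m2 - m^2, eps)
  out <- stats[[which]]
  out$mat <- m / sqrt(v / stats$n_cell)
  out
}

#' Empirical FDR from observed versus shuffled statistics
#'
#' `FDR(x) = min(1, [#shuffle >= x / N_shuffle] / [#obs >= x / N_obs])`
#' evaluated at each observed value, then made monotone non-increasing in
#' the statistic by a running minimum over less stringent cutoffs.
#'
#' @param t_obs numeric vector of observed statistics.
#' @param t_shuffle numeric vector of shuffled-background statistics.
#' @return numeric vector of FDR values aligned with `t_obs`.
#' @export
empirical_fdr <- function(t_obs, t_shuffle) {
  stop_if_not(length(t_shuffle) > 0, "empty shuffle set")
  N_o <- length(t_obs); N_s <- length(t_shuffle)
  ss <- sort(t_shuffle)
  so <- sort(t_obs)
  n_sh_ge <- N_s - findInterval(t_obs, ss, left.open = TRUE)
  n_ob_ge <- N_o - findInterval(t_obs, so, left.open = TRUE)
  raw <- pmin(1, (n_sh_ge / N_s) / (n_ob_ge / N_o))
  ord <- order(t_obs, method = "radix")
  q <- raw
  q[ord] <- cummin(raw[ord])
  # equal statistics share the same (last, i.e. smallest) running minimum
  q
}

oe_normalize <- function(Q) {
  OE <- Q
  for (d in 0:Q$max_offset) {
    v <- Q$mat[d + 1L, ]
    mu <- mean(v, na.rm = TRUE)
    OE$mat[d + 1L, ] <- if (is.finite(mu) && mu > 0) v / mu else 0 * v
  }
  OE
}

# Sum of M over the offset rectangle [i+a1, i+a2] x [j+b1, j+b2], clipped to
# the matrix, for every (i, j); prefix-table based.
rect_off_sum <- function(M, a1, a2, b1, b2) {
  n <- nrow(M); m <- ncol(M)
  C <- matrix(0, n + 1L, m + 1L)
  C[-1L, -1L] <- M
  C <- apply(C, 2L, cumsum)
  C <- t(apply(C, 1L, cumsum))
  rhi <- clip(seq_len(n) + a2, 0L, n) + 1L; rlo <- clip(seq_len(n) + a1 - 1L, 0L, n) + 1L
  chi <- clip(seq_len(m) + b2, 0L, m) + 1L; clo <- clip(seq_len(m) + b1 - 1L, 0L, m) + 1L
  C[rhi, chi, drop = FALSE] - C[rlo, chi, drop = FALSE] -
    C[rhi, clo, drop = FALSE] + C[rlo, clo, drop = FALSE]
}

#' HiCCUPS-style background fold changes of a pseudobulk Q
#'
#' Q is observed/expected-normalized per diagonal, then each pixel is
#' compared with four local backgrounds: donut (Chebyshev radii 2-5
#' excluding the center row and column), lower-left quadrant (row offsets
#' 1..5, column offsets -5..-1), horizontal (same row, column offsets of
#' absolute value 2..5) and vertical (same column, row offsets 2..5).
#' Fold change is pixel / background mean; an empty or zero background
#' yields `Inf`.
#'
#' @param Q_bulk pseudobulk Q as a `band_matrix` (10-kb loop pipeline).
#' @return list of four `band_matrix` objects: fc_donut, fc_lowerleft,
#'   fc_horizontal, fc_vertical.
#' @export
background_fold_changes <- function(Q_bulk) {
  OE <- oe_normalize(Q_bulk)
  X <- band_to_dense(OE)          # NA outside the band
  W <- 1 - is.na(X)
  X[is.na(X)] <- 0
  sums <- function(a1, a2, b1, b2)
    list(s = rect_off_sum(X, a1, a2, b1, b2),
         c = rect_off_sum(W, a1, a2, b1, b2))
  box5 <- sums(-5, 5, -5, 5); box1 <- sums(-1, 1, -1, 1)
  hs5 <- sums(0, 0, -5, 5); hs1 <- sums(0, 0, -1, 1)
  vs5 <- sums(-5, 5, 0, 0); vs1 <- sums(-1, 1, 0, 0)
  ll <- sums(1, 5, -5, -1)
  mean_of <- function(s, c) ifelse(c > 0, s / c, 0)
  bg <- list(
    fc_donut = mean_of(box5$s - box1$s - (hs5$s - hs1$s) - (vs5$s - vs1$s),
                       box5$c - box1$c - (hs5$c - hs1$c) - (vs5$c - vs1$c)),
    fc_lowerleft = mean_of(ll$s, ll$c),
    fc_horizontal = mean_of(hs5$s - hs1$s, hs5$c - hs1$c),
    fc_vertical = mean_of(vs5$s - vs1$s, vs5$c - vs1$c))
  out <- lapply(bg, function(B) {
    fc <- OE
    for (d in 0:OE$max_offset) {
      i <- seq_len(OE$n_bins - d)
      b <- B[cbind(i, i + d)]
      v <- OE$mat[d + 1L, i]
      fc$mat[d + 1L, i] <- ifelse(b > 0, v / b, Inf)
    }
    fc
  })
  out
}

#' Quantile thresholds used by the differential statistics
#'
#' The differential-loop rule thresholds z-scored log F statistics at the
#' 85th percentile of the standard normal; the differential-boundary rule
#' thresholds z-scored chi-square statistics at the 97.5th percentile.
#'
#' @param p percentile in (0, 1).
#' @return the standard normal quantile.
#' @export
normal_quantile_threshold <- function(p) qnorm(p)

#' Call chromatin loops from observed and shuffled pseudobulk statistics
#'
#' Candidate pixels are bin pairs separated by 50 kb to 5 Mb. A pixel is a
#' loop when the mean E across cells is positive, the four local fold
#' changes exceed their thresholds (1.33 donut / lower-left, 1.2 horizontal
#' / vertical), and the empirical FDRs of the pseudobulk t-statistics of E
#' (global background) and T (local background) against the shuffled
#' pseudobulks are both below `fdr_threshold`.
#'
#' @param stats observed `pseudobulk_stats`.
#' @param shuffle_stats diagonal-shuffled `pseudobulk_stats`.
#' @param min_distance,max_distance candidate distance range in bp.
#' @param fdr_threshold empirical FDR cutoff.
#' @param fc_thresholds named list of the four fold-change cutoffs.
#' @return `data.table` with one row per candidate pixel: bins, distance,
#'   E_mean, t statistics, FDRs, fold changes and the is_loop flag.
#' @export
call_loops <- function(stats, shuffle_stats,
                       min_distance = 5e4, max_distance = 5e6,
                       fdr_threshold = 0.01,
                       fc_thresholds = list(donut = 1.33, lowerleft = 1.33,
                                            horizontal = 1.2, vertical = 1.2)) {
  res <- stats$Q$resolution
  offs <- seq_len(stats$Q$max_offset)
  offs <- offs[offs * res >= min_distance & offs * res <= max_distance]
  t_E <- pseudobulk_tstat(stats, "E")
  t_T <- pseudobulk_tstat(stats, "T")
  t_Es <- pseudobulk_tstat(shuffle_stats, "E")
  t_Ts <- pseudobulk_tstat(shuffle_stats, "T")
  fc <- background_fold_changes(stats$Q)
  rows <- lapply(offs, function(d) {
    i <- seq_len(stats$Q$n_bins - d)
    data.table::data.table(
      chrom = stats$Q$chrom,
      bin1 = i - 1L, bin2 = i - 1L + d, distance = d * res,
      E_mean = stats$E$mat[d + 1L, i],
      t_E = t_E$mat[d + 1L, i], t_T = t_T$mat[d + 1L, i],
      t_E_shuffle = t_Es$mat[d + 1L, i], t_T_shuffle = t_Ts$mat[d + 1L, i],
      fc_donut = fc$fc_donut$mat[d + 1L, i],
      fc_lowerleft = fc$fc_lowerleft$mat[d + 1L, i],
      fc_horizontal = fc$fc_horizontal$mat[d + 1L, i],
      fc_vertical = fc$fc_vertical$mat[d + 1L, i])
  })
  dt <- data.table::rbindlist(rows)
  dt$fdr_global <- empirical_fdr(dt$t_E, dt$t_E_shuffle)
  dt$fdr_local <- empirical_fdr(dt$t_T, dt$t_T_shuffle)
  dt$is_loop <- dt$E_mean > 0 &
    dt$fc_donut > fc_thresholds$donut &
    dt$fc_lowerleft > fc_thresholds$lowerleft &
    dt$fc_horizontal > fc_thresholds$horizontal &
    dt$fc_vertical > fc_thresholds$vertical &
    dt$fdr_global < fdr_threshold & dt$fdr_local < fdr_threshold
  dt
}

#' Merge called loop pixels into summits
#'
#' Called pixels are grouped into 8-connected clusters in (bin1, bin2)
#' space (Chebyshev distance 1). Each cluster is reported once, located at
#' its rounded pixel centroid (imputation smears a focal loop into a
#' flat-topped blob centred on it, and per-diagonal z-scoring tilts any
#' extremum statistic toward larger distances, so the centroid is the
#' unbiased summit); the row's statistics are those of the cluster's
#' maximum-t_E pixel.
#'
#' @param calls output of [call_loops()].
#' @return `data.table` of summit pixels with cluster sizes.
#' @export
merge_loop_calls <- function(calls) {
  hits <- calls[calls$is_loop, ]
  if (!nrow(hits)) return(hits)
  key <- paste(hits$bin1, hits$bin2)
  idx <- seq_len(nrow(hits))
  lookup <- new.env(hash = TRUE, size = nrow(hits))
  for (i in idx) assign(key[i], i, envir = lookup)
  comp <- integer(nrow(hits))
  cur <- 0L
  for (i in idx) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (da in -1:1) for (db in -1:1) {
        if (da == 0 && db == 0) next
        kk <- paste(hits$bin1[j] + da, hits$bin2[j] + db)
        m <- mget(kk, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(m) && !comp[m]) { comp[m] <- cur; queue <- c(queue, m) }
      }
    }
  }
  hits$cluster <- comp
  cent <- hits[, list(c1 = as.integer(round(mean(bin1))),
                      c2 = as.integer(round(mean(bin2))),
                      cluster_size = .N), by = "cluster"]
  hits <- hits[order(comp, -hits$t_E), ]
  summit <- hits[!duplicated(hits$cluster), ]
  summit <- merge(summit, cent, by = "cluster")
  res_bp <- calls$distance[1] / (calls$bin2[1] - calls$bin1[1])
  summit$bin1 <- summit$c1
  summit$bin2 <- summit$c2
  summit$distance <- (summit$bin2 - summit$bin1) * res_bp
  summit[, setdiff(names(summit), c("c1", "c2")), with = FALSE]
}

#' One-way ANOVA F statistics from pseudobulk summaries
#'
#' For each pixel, the between/within sum of squares are recovered from the
#' per-group cell counts, means and means of squares:
#' `SSB = sum n_g m_g^2 - N mbar^2`, `SSW = sum n_g (q2_g - m_g^2)`,
#' `F = (SSB/(G-1)) / (SSW/(N-G))`; `SSW = 0` yields `Inf`.
#'
#' @param group_stats list of `pseudobulk_stats`, one per cell group.
#' @param which "Q" or "T".
#' @param pixels table with bin1, bin2 (0-based) selecting the tested loops.
#' @return numeric vector of F statistics aligned with `pixels`.
#' @export
anova_from_summaries <- function(group_stats, which = c("Q", "T"), pixels) {
  which <- match.arg(which)
  G <- length(group_stats)
  stop_if_not(G >= 2L, "need at least 2 groups")
  n_g <- vapply(group_stats, `[[`, numeric(1), "n_cell")
  stop_if_not(all(n_g >= 2L), "each group needs n >= 2")
  N <- sum(n_g)
  stop_if_not(N > G, "need N > G")
  m <- vapply(group_stats, function(s)
    band_values(s[[which]], pixels$bin1, pixels$bin2), numeric(nrow(pixels)))
  q2 <- vapply(group_stats, function(s)
    band_values(s[[paste0(which, "2")]], pixels$bin1, pixels$bin2),
    numeric(nrow(pixels)))
  m <- matrix(m, nrow = nrow(pixels)); q2 <- matrix(q2, nrow = nrow(pixels))
  grand <- as.vector(m %*% n_g) / N
  ssb <- as.vector((m^2) %*% n_g) - N * grand^2
  ssw <- as.vector((q2 - m^2) %*% n_g)
  ssb <- pmax(ssb, 0); ssw <- pmax(ssw, 0)
  ifelse(ssw > 0, (ssb / (G - 1)) / (ssw / (N - G)), Inf)
}

#' Select differential loops from F statistics
#'
#' `F_Q` and `F_T` are log-transformed (natural log, with a 1e-12 offset),
#' z-scored across all tested loops, and loops with both z-scores above the
#' 85th standard-normal percentile (1.036) are flagged; under normality this
#' selects roughly the top 5%.
#'
#' @param F_Q,F_T numeric vectors of F statistics over the tested loops.
#' @param z_threshold z cutoff (default `qnorm(0.85)`).
#' @param eps offset added before the log.
#' @return `data.table` with z_FQ, z_FT and is_differential.
#' @export
select_differential <- function(F_Q, F_T, z_threshold = qnorm(0.85),
                                eps = 1e-12) {
  stop_if_not(length(F_Q) >= 2L, "need at least 2 tested loops")
  zf <- function(f) {
    x <- log(pmin(f, .Machine$double.xmax) + eps)
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z_FQ <- zf(F_Q); z_FT <- zf(F_T)
  data.table::data.table(z_FQ = z_FQ, z_FT = z_FT,
                         is_differential = z_FQ > z_threshold &
                           z_FT > z_threshold)
}

# distance (bp) from a point to 0-based half-open intervals [s, e)
point_interval_gap <- function(pos, s, e) {
  pmax(0, pmax(s - pos, pos - e + 1L))
}

#' Cumulative loop score per promoter
#'
#' Sums the strengths of loops having an anchor whose 10-kb interval lies
#' within `max_tss_dist` bp of the promoter's TSS (inclusive). Each loop
#' counts once even if both anchors qualify.
#'
#' @param loops table with chrom, bin1, bin2 and a strength column.
#' @param promoters table with gene, chrom and tss (0-based bp).
#' @param resolution anchor bin size in bp.
#' @param strength name of the strength column (default "strength"); use a
#'   column of 1s to count loops instead.
#' @param max_tss_dist maximum TSS-anchor distance in bp.
#' @return `data.table` with gene and score.
#' @export
cumulative_loop_score <- function(loops, promoters, resolution = 1e4,
                                  strength = "strength", max_tss_dist = 5e3) {
  loops <- loop_anchor_intervals(loops, resolution)
  score <- vapply(seq_len(nrow(promoters)), function(g) {
    same <- loops$chrom == promoters$chrom[g]
    if (!any(same)) return(0)
    lp <- loops[same, ]
    tss <- promoters$tss[g]
    near <- point_interval_gap(tss, lp$start1, lp$end1) <= max_tss_dist |
      point_interval_gap(tss, lp$start2, lp$end2) <= max_tss_dist
    sum(lp[[strength]][near])
  }, numeric(1))
  data.table::data.table(gene = promoters$gene, score = score)
}

#' Call super-interactive promoters (SIPs)
#'
#' Cumulative loop scores are modelled by a half-Gaussian with mean 0 and
#' standard deviation equal to the standard deviation of the scores;
#' promoters with `p = 2 (1 - Phi(score / sigma)) < 0.001` are SIPs.
#'
#' @param scores `data.table` from [cumulative_loop_score()] (gene, score).
#' @return input with sigma, p_halfgauss, is_SIP and a `threshold` attribute
#'   (`sigma * qnorm(0.9995)`).
#' @export
call_sips <- function(scores) {
  stop_if_not(nrow(scores) >= 2L, "need at least 2 promoters")
  sigma <- sd(scores$score)
  stop_if_not(is.finite(sigma) && sigma > 0, "zero variance in loop scores")
  out <- data.table::as.data.table(scores)
  out$sigma <- sigma
  out$p_halfgauss <- 2 * pnorm(out$score / sigma, lower.tail = FALSE)
  out$is_SIP <- out$p_halfgauss < 0.001
  data.table::setattr(out, "threshold", sigma * qnorm(0.9995))
  out
}

#' Per-promoter cumulative differential-loop score trajectory
#'
#' @param diff_loops table with chrom, bin1, bin2 of differential loops.
#' @param strength_by_stage matrix (differential loops x stages) of
#'   per-stage pseudobulk strengths.
#' @param promoters table with gene, chrom, tss.
#' @param resolution anchor bin size in bp.
#' @param max_tss_dist maximum TSS-anchor distance in bp.
#' @return matrix (genes x stages) of cumulative scores.
#' @export
cumulative_differential_score <- function(diff_loops, strength_by_stage,
                                          promoters, resolution = 1e4,
                                          max_tss_dist = 5e3) {
  stages <- colnames(strength_by_stage) %||%
    paste0("stage", seq_len(ncol(strength_by_stage)))
  out <- sapply(seq_len(ncol(strength_by_stage)), function(s) {
    lp <- data.table::as.data.table(diff_loops)
    lp$strength <- strength_by_stage[, s]
    cumulative_loop_score(lp, promoters, resolution = resolution,
                          max_tss_dist = max_tss_dist)$score
  })
  out <- matrix(out, nrow = nrow(promoters),
                dimnames = list(promoters$gene, stages))
  out
}
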