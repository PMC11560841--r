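# Per-cell contact-matrix machinery: banded matrices, random-walk imputation
# (Q), per-diagonal z-scoring (E), local-background subtraction (T), diagonal
# shuffling, pseudobulk aggregation and the SVD cell embedding.
#
# All distance-limited matrices are stored in *band form*: a (D+1) x n matrix
# whose row d+1 holds the d-th super-diagonal, i.e. mat[d+1, i] is the value
# at 0-based bin pair (i-1, i-1+d). Entries beyond the chromosome end are NA.
# The underlying full matrix is symmetric, so the band carries everything.

#' Construct a banded symmetric matrix
#'
#' @param mat numeric matrix, (max_offset+1) x n_bins; row d+1 is diagonal d.
#' @param resolution bin size in bp.
#' @param chrom chromosome name.
#' @return a `band_matrix` object.
#' @export
band_matrix <- function(mat, resolution, chrom = "chr") {
  n <- ncol(mat)
  D <- nrow(mat) - 1L
  stop_if_not(D <= n - 1L, "max offset exceeds matrix size")
  for (d in seq_len(D)) mat[d + 1L, seq.int(n - d + 1L, n)] <- NA_real_
  structure(list(mat = mat, n_bins = n, max_offset = D,
                 resolution = resolution, chrom = chrom),
            class = "band_matrix")
}

band_empty <- function(n_bins, max_offset, resolution, chrom = "chr", fill = 0) {
  band_matrix(matrix(fill, max_offset + 1L, n_bins), resolution, chrom)
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %s, %d bins @ %g bp, offsets 0..%d\n",
              x$chrom, x$n_bins, x$resolution, x$max_offset))
  invisible(x)
}

#' Expand a band matrix to a dense symmetric matrix
#' @param bm a `band_matrix`.
#' @param fill value to place outside the band (default `NA`).
#' @return dense n x n symmetric matrix.
#' @export
band_to_dense <- function(bm, fill = NA_real_) {
  band_to_dense_cpp(bm$mat, fill)
}

#' Restrict a dense symmetric matrix to a band
#' @param M dense symmetric matrix.
#' @param max_offset largest |i - j| kept.
#' @param resolution bin size in bp.
#' @param chrom chromosome name.
#' @return a `band_matrix`.
#' @export
dense_to_band <- function(M, max_offset, resolution, chrom = "chr") {
  D <- min(max_offset, nrow(M) - 1L)
  band_matrix(dense_to_band_cpp(M, D), resolution, chrom)
}

#' Bin a cell's contacts into a dense symmetric count matrix
#'
#' @param contacts table with pos1, pos2 (1-based bp, cis).
#' @param chrom_length chromosome length in bp.
#' @param resolution bin size in bp.
#' @return dense n x n count matrix (n = ceiling(chrom_length/resolution)).
#' @export
contacts_to_matrix <- function(contacts, chrom_length, resolution) {
  n <- as.integer(ceiling(chrom_length / resolution))
  M <- matrix(0, n, n)
  if (nrow(contacts)) {
    i <- pos_to_bin(contacts$pos1, resolution)
    j <- pos_to_bin(contacts$pos2, resolution)
    keep <- i < n & j < n
    dt <- data.table::data.table(i = pmin(i, j)[keep], j = pmax(i, j)[keep])
    agg <- dt[, .N, by = c("i", "j")]
    M[cbind(agg$i + 1L, agg$j + 1L)] <- agg$N
    lo <- agg$i != agg$j
    M[cbind(agg$j + 1L, agg$i + 1L)[lo, , drop = FALSE]] <- agg$N[lo]
  }
  M
}

# Clipped-window box sum of radius r via a summed-area table.
box_sum <- function(M, r) box_sum_cpp(M, as.integer(r))

#' Impute a single-cell contact matrix (scHiCluster-style Q)
#'
#' Box-filter convolution of half-width `pad`, row normalization, then a
#' random walk with restart (restart probability `restart`). The default
#' method solves the stationary point `Q = restart * (I - (1-restart) P)^-1`
#' in closed form; `method = "iterative"` runs the fixed-point iteration
#' until the total absolute change drops below `tol` or `max_iter` sweeps.
#' The result is symmetrized as (M + t(M))/2 and restricted to
#' `|i - j| <= max_distance/resolution`.
#'
#' @param M dense symmetric raw count matrix (see [contacts_to_matrix()]).
#' @param resolution bin size in bp.
#' @param pad box-filter half width (1 or 2).
#' @param max_distance band limit in bp (multiple of `resolution`).
#' @param restart restart probability of the random walk.
#' @param method "exact" (closed form) or "iterative".
#' @param tol,max_iter stopping rule for `method = "iterative"`.
#' @param chrom chromosome name carried on the result.
#' @return imputed matrix Q as a `band_matrix`; non-negative.
#' @export
impute <- function(M, resolution, pad = 2L, max_distance = 5.05e6,
                   restart = 0.5, method = c("exact", "iterative"),
                   tol = 1e-2, max_iter = 20L, chrom = "chr") {
  method <- match.arg(method)
  stop_if_not(pad %in% c(1L, 2L), "pad must be 1 or 2")
  stop_if_not(max_distance %% resolution == 0,
              "max_distance must be a multiple of resolution")
  n <- nrow(M)
  D <- as.integer(max_distance / resolution)
  B <- box_sum(M, pad)
  rs <- rowSums(B)
  if (all(rs == 0)) {
    warning("empty contact matrix: returning all-zero Q")
    return(band_empty(n, min(D, n - 1L), resolution, chrom))
  }
  if (method == "exact") {
    Q <- rwr_impute_cpp(B, restart)
  } else {
    P <- B / ifelse(rs > 0, rs, 1)
    P[rs == 0, ] <- 0
    Q <- diag(n)
    for (it in seq_len(max_iter)) {
      Qn <- (1 - restart) * (Q %*% P)
      diag(Qn) <- diag(Qn) + restart
      if (sum(abs(Qn - Q)) < tol) { Q <- Qn; break }
      Q <- Qn
    }
    Q <- (Q + t(Q)) / 2
    Q[Q < 0] <- 0
  }
  dense_to_band(Q, D, resolution, chrom)
}

#' Per-diagonal z-score of log counts (E)
#'
#' `E[i,j] = (log(1 + Q[i,j]) - mu_d) / sd_d` with the mean and population
#' standard deviation taken over diagonal `d = j - i` inside the band;
#' constant diagonals map to 0.
#'
#' @param Q a `band_matrix` from [impute()].
#' @return a `band_matrix` E with per-diagonal mean 0.
#' @export
diagonal_zscore <- function(Q) {
  E <- Q
  for (d in 0:Q$max_offset) {
    v <- Q$mat[d + 1L, ]
    ok <- !is.na(v)
    if (!any(ok)) next
    x <- log1p(v[ok])
    mu <- mean(x)
    sdd <- sqrt(max(mean(x^2) - mu^2, 0))
    E$mat[d + 1L, ok] <- if (sdd > 0) (x - mu) / sdd else 0
  }
  E
}

#' Subtract the local ring background from E (T)
#'
#' For each pixel the mean of E over offsets with Chebyshev radius strictly
#' between `inner` and `outer` bins (radius 4 only at the defaults, i.e.
#' >30 kb and <50 kb at 10-kb resolution) is subtracted. Ring positions
#' falling outside the matrix or the band are clipped.
#'
#' @param E a `band_matrix` from [diagonal_zscore()].
#' @param inner,outer exclusive Chebyshev radii bounding the ring.
#' @return a `band_matrix` T.
#' @export
subtract_local_background <- function(E, inner = 3L, outer = 5L) {
  stop_if_not(outer - inner >= 2L, "empty background ring")
  TT <- E
  TT$mat <- ring_subtract_cpp(E$mat, as.integer(inner), as.integer(outer))
  TT
}

#' Shuffle E independently within each diagonal
#' @param E a `band_matrix`.
#' @param seed integer seed (reproducible).
#' @return a `band_matrix` with each diagonal's values permuted.
#' @export
shuffle_diagonals <- function(E, seed = NULL) {
  with_seed(seed, {
    S <- E
    for (d in 0:E$max_offset) {
      ok <- which(!is.na(E$mat[d + 1L, ]))
      if (length(ok) > 1L)
        S$mat[d + 1L, ok] <- E$mat[d + 1L, sample(ok)]
    }
    S
  })
}

#' Q/E/T (and shuffled) triplet for one cell
#'
#' Convenience wrapper running [impute()], [diagonal_zscore()],
#' [subtract_local_background()] and the diagonal shuffle for one cell.
#'
#' @param M dense raw count matrix.
#' @param resolution bin size in bp.
#' @param pad,max_distance,method,chrom see [impute()].
#' @param shuffle_seed seed for the diagonal shuffle (NULL skips shuffling).
#' @return list with band matrices Q, E, T and, when shuffled, Es and Ts.
#' @export
cell_matrix_triplet <- function(M, resolution, pad = 2L, max_distance = 5.05e6,
                                method = "exact", shuffle_seed = NULL,
                                chrom = "chr") {
  Q <- impute(M, resolution, pad = pad, max_distance = max_distance,
              method = method, chrom = chrom)
  E <- diagonal_zscore(Q)
  TT <- subtract_local_background(E)
  out <- list(Q = Q, E = E, T = TT)
  if (!is.null(shuffle_seed)) {
    Es <- shuffle_diagonals(E, seed = shuffle_seed)
    out$Es <- Es
    out$Ts <- subtract_local_background(Es)
  }
  out
}

# --- pseudobulk accumulation -------------------------------------------------

#' Streaming pseudobulk accumulator
#'
#' `pseudobulk_accumulate()` folds one cell's Q/E/T triplet into running
#' sums of values and squares; `pseudobulk_finalize()` divides by the cell
#' count, yielding the six pseudobulk matrices
#' \{Q, Q2, E, E2, T, T2\} (means of values and of squares).
#'
#' @param acc accumulator (NULL to start).
#' @param triplet list with band matrices Q, E, T (see
#'   [cell_matrix_triplet()]); for shuffled pseudobulks pass Es/Ts as E/T.
#' @return updated accumulator / a `pseudobulk_stats` object.
#' @export
pseudobulk_accumulate <- function(acc, triplet) {
  mats <- list(Q = triplet$Q$mat, E = triplet$E$mat, T = triplet$T$mat)
  if (is.null(acc)) {
    acc <- list(n_cell = 0L, template = triplet$Q,
                sums = lapply(mats, function(m) m * 0),
                sqsums = lapply(mats, function(m) m * 0))
  }
  stop_if_not(ncol(acc$sums$Q) == ncol(mats$Q) &&
                nrow(acc$sums$Q) == nrow(mats$Q), "shape mismatch across cells")
  for (k in names(mats)) {
    acc$sums[[k]] <- acc$sums[[k]] + mats[[k]]
    acc$sqsums[[k]] <- acc$sqsums[[k]] + mats[[k]]^2
  }
  acc$n_cell <- acc$n_cell + 1L
  acc
}

#' @rdname pseudobulk_accumulate
#' @export
pseudobulk_finalize <- function(acc) {
  stop_if_not(acc$n_cell >= 1L, "no cells accumulated")
  tpl <- acc$template
  mk <- function(m) band_matrix(m, tpl$resolution, tpl$chrom)
  structure(list(
    n_cell = acc$n_cell,
    Q = mk(acc$sums$Q / acc$n_cell), Q2 = mk(acc$sqsums$Q / acc$n_cell),
    E = mk(acc$sums$E / acc$n_cell), E2 = mk(acc$sqsums$E / acc$n_cell),
    T = mk(acc$sums$T / acc$n_cell), T2 = mk(acc$sqsums$T / acc$n_cell)),
    class = "pseudobulk_stats")
}

#' Aggregate per-cell triplets into pseudobulk summary matrices
#' @param cells list of Q/E/T triplets with identical shapes.
#' @return a `pseudobulk_stats` object.
#' @export
aggregate_pseudobulk <- function(cells) {
  acc <- NULL
  for (tr in cells) acc <- pseudobulk_accumulate(acc, tr)
  pseudobulk_finalize(acc)
}

#' @export
print.pseudobulk_stats <- function(x, ...) {
  cat(sprintf("pseudobulk_stats: %d cells, %d bins @ %g bp\n", x$n_cell,
              x$Q$n_bins, x$Q$resolution))
  invisible(x)
}

# --- cell embedding ----------------------------------------------------------

#' SVD embedding of cells from imputed contacts
#'
#' Features are the imputed contact values at bin-pair offsets in
#' `(min_distance, max_distance)` (exclusive on both sides; at 100-kb
#' resolution the defaults select distances >100 kb and <1 Mb). The
#' cell-by-feature matrix is decomposed by SVD; components are normalized by
#' their singular values and each cell's coordinate vector is L2-normalized.
#'
#' @param Q_list list of per-cell `band_matrix` objects (common shape).
#' @param dims number of dimensions to keep.
#' @param min_distance,max_distance feature distance range in bp (exclusive).
#' @return matrix (cells x dims) with unit-norm rows; rownames from names of
#'   `Q_list`.
#' @export
embed_cells <- function(Q_list, dims = 10L, min_distance = 1e5,
                        max_distance = 1e6) {
  stop_if_not(length(Q_list) >= 2L, "need at least 2 cells")
  tpl <- Q_list[[1]]
  res <- tpl$resolution
  offs <- seq_len(tpl$max_offset)
  offs <- offs[offs * res > min_distance & offs * res < max_distance]
  stop_if_not(length(offs) > 0, "no offsets in the requested distance range")
  feat_of <- function(bm) {
    v <- as.vector(t(bm$mat[offs + 1L, , drop = FALSE]))
    v[!is.na(v)]
  }
  X <- do.call(rbind, lapply(Q_list, feat_of))
  dims_eff <- min(dims, nrow(X), ncol(X))
  if (dims_eff < dims) warning("requested dims exceed rank; truncating")
  sv <- svd(X, nu = dims_eff, nv = dims_eff)
  U <- sv$u
  # fix sign: largest-|loading| feature of each component is made positive
  for (k in seq_len(dims_eff)) {
    ld <- sv$v[, k]
    if (ld[which.max(abs(ld))] < 0) U[, k] <- -U[, k]
  }
  nrm <- sqrt(rowSums(U^2))
  U <- U / ifelse(nrm > 0, nrm, 1)
  rownames(U) <- names(Q_list)
  U
}
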