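# Meta-cell construction (kNN pooling with overlap deduplication) and the
# loop-strength versus anchor-mCG cross-correlation lag analysis along a
# pseudotime trajectory.

#' Build meta-cells as k-nearest-neighbour pools
#'
#' Each cell seeds one meta-cell consisting of itself and its k-1 nearest
#' neighbours (Euclidean distance in the embedding); distance ties are
#' broken by cell id.
#'
#' @param embedding matrix (cells x dims) with rownames as cell ids.
#' @param k meta-cell size (self-included).
#' @return named list of member-id character vectors, one per seed cell.
#' @export
build_metacells <- function(embedding, k = 20L) {
  n <- nrow(embedding)
  stop_if_not(n >= k, "fewer cells than k")
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  D <- as.matrix(dist(embedding))
  out <- lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], ids, method = "radix")
    ids[ord[seq_len(k)]]
  })
  names(out) <- ids
  out
}

metacell_overlap_matrix <- function(metacells) {
  ids <- sort(unique(unlist(metacells)))
  M <- vapply(metacells, function(m) ids %in% m, logical(length(ids)))
  crossprod(M * 1)
}

#' Remove highly overlapping meta-cells
#'
#' Repeatedly finds the pair of meta-cells sharing the most members and
#' removes, from that pair, the meta-cell with the larger total overlap
#' against all remaining meta-cells (ties broken by id), until no pair
#' shares more than `max_shared` cells.
#'
#' @param metacells named list of member-id vectors.
#' @param max_shared maximum allowed shared members per pair.
#' @return the retained subset of `metacells`.
#' @export
deduplicate_metacells <- function(metacells, max_shared = 5L) {
  mc <- metacells
  repeat {
    if (length(mc) < 2L) break
    O <- metacell_overlap_matrix(mc)
    diag(O) <- 0L
    worst <- max(O)
    if (worst <= max_shared) break
    w <- which(O == worst, arr.ind = TRUE)[1L, ]
    tot <- rowSums(O)
    pair <- sort(c(w[[1]], w[[2]]))
    pick <- if (tot[pair[1]] > tot[pair[2]]) pair[1]
    else if (tot[pair[2]] > tot[pair[1]]) pair[2]
    else pair[order(names(mc)[pair] %||% pair)[2]]
    mc <- mc[-pick]
  }
  mc
}

#' Downsample meta-cells of one origin
#'
#' @param metacells named list of member vectors.
#' @param origins origin label per meta-cell.
#' @param origin label to downsample.
#' @param fraction fraction kept (ceiling of fraction * n matching).
#' @param seed RNG seed.
#' @return list with the retained `metacells` and their `origins`.
#' @export
downsample_origin <- function(metacells, origins, origin = "RG-1",
                              fraction = 0.5, seed = NULL) {
  stop_if_not(length(metacells) == length(origins),
              "origins must align with metacells")
  idx <- which(origins == origin)
  if (!length(idx)) return(list(metacells = metacells, origins = origins))
  keep_n <- as.integer(ceiling(fraction * length(idx)))
  kept <- with_seed(seed, sort(sample(idx, keep_n)))
  sel <- sort(c(setdiff(seq_along(metacells), idx), kept))
  list(metacells = metacells[sel], origins = origins[sel])
}

#' Meta-cell methylation, loop-strength and pseudotime profiles
#'
#' Meta-cell mCG per bin is the pooled count fraction (sum of methylated
#' over sum of total basecalls across members -- not the mean of member
#' fractions); loop strength is the mean imputed interaction across
#' members; pseudotime is the mean member pseudotime.
#'
#' @param metacells named list of member-id vectors.
#' @param mc_counts,cov_counts matrices (cells x bins) of methylated and
#'   total CG basecalls, rownames = cell ids.
#' @param loop_strength matrix (cells x loops) of imputed values at loop
#'   pixels, rownames = cell ids.
#' @param pseudotime named numeric vector per cell.
#' @return list with matrices `mcg` (metacells x bins), `loops`
#'   (metacells x loops) and vector `pseudotime`, ordered by pseudotime.
#' @export
metacell_profiles <- function(metacells, mc_counts, cov_counts,
                              loop_strength, pseudotime) {
  miss <- setdiff(unique(unlist(metacells)), rownames(mc_counts))
  stop_if_not(length(miss) == 0,
              paste("members without methylome:", paste(head(miss), collapse = ",")))
  prof <- function(members) {
    mc <- colSums(mc_counts[members, , drop = FALSE])
    cv <- colSums(cov_counts[members, , drop = FALSE])
    list(mcg = ifelse(cv > 0, mc / cv, NA_real_),
         loops = colMeans(loop_strength[members, , drop = FALSE]),
         pt = mean(pseudotime[members]))
  }
  ps <- lapply(metacells, prof)
  mcg <- do.call(rbind, lapply(ps, `[[`, "mcg"))
  loops <- do.call(rbind, lapply(ps, `[[`, "loops"))
  pt <- vapply(ps, `[[`, numeric(1), "pt")
  ord <- order(pt, names(metacells) %||% seq_along(metacells),
               method = "radix")
  list(mcg = mcg[ord, , drop = FALSE], loops = loops[ord, , drop = FALSE],
       pseudotime = pt[ord])
}

# Pearson correlation between x[t] and y[t - s] on the overlapping segment.
shifted_cor <- function(x, y, s) {
  n <- length(x)
  if (s >= 0) { xs <- x[(s + 1):n]; ys <- y[1:(n - s)] }
  else { m <- -s; xs <- x[1:(n - m)]; ys <- y[(m + 1):n] }
  if (length(xs) < 2L || sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
  cor(xs, ys)
}

#' Cross-correlation lag between loop strength and anchor methylation
#'
#' Meta-cells are ordered by pseudotime. For each loop, the loop-strength
#' series and the mean anchor-mCG series are standardized and the Pearson
#' correlation r(s) between the loop series at time t and the methylation
#' series at time t - s is computed for shifts s in `[-max_shift,
#' max_shift]` (in meta-cell rank steps) over the overlapping segment.
#' Only loops with r(0) < 0 are scored; the recorded shift is the argmin of
#' r(s). A negative shift means the interaction changes before the
#' methylation (methylation must be moved backward to align), so a
#' left-skewed shift distribution indicates conformation leading.
#'
#' @param profiles output of [metacell_profiles()] (already pseudotime
#'   ordered).
#' @param loop_anchor_bins matrix/data.frame (loops x 2) of 0-based anchor
#'   bin indices into the mcg columns.
#' @param max_shift maximum |shift| in meta-cell steps.
#' @param min_overlap minimum overlapping points per correlation.
#' @return list with per-loop `data.table` (r0, shift, r_min), the shift
#'   `curves` matrix, and `median_shift`.
#' @export
loop_methylation_crosscorr <- function(profiles, loop_anchor_bins,
                                       max_shift = 5L, min_overlap = 10L) {
  n_meta <- nrow(profiles$loops)
  stop_if_not(n_meta >= 2L * max_shift + min_overlap,
              "too few meta-cells along the trajectory")
  shifts <- seq.int(-max_shift, max_shift)
  n_loops <- nrow(loop_anchor_bins)
  curves <- matrix(NA_real_, n_loops, length(shifts),
                   dimnames = list(NULL, shifts))
  r0 <- rep(NA_real_, n_loops)
  best <- rep(NA_integer_, n_loops)
  for (l in seq_len(n_loops)) {
    x <- profiles$loops[, l]
    y <- rowMeans(profiles$mcg[, c(loop_anchor_bins[l, 1],
                                   loop_anchor_bins[l, 2]) + 1L, drop = FALSE])
    if (anyNA(x) || anyNA(y) || sd(x) == 0 || sd(y) == 0) next
    x <- as.vector(scale(x)); y <- as.vector(scale(y))
    cc <- vapply(shifts, function(s) {
      if (n_meta - abs(s) < min_overlap) return(NA_real_)
      shifted_cor(x, y, s)
    }, numeric(1))
    curves[l, ] <- cc
    r0[l] <- cc[shifts == 0]
    if (is.finite(r0[l]) && r0[l] < 0) {
      cand <- which(cc == min(cc, na.rm = TRUE))
      # ties: smallest |shift|, then the negative one
      cand <- cand[order(abs(shifts[cand]), shifts[cand])]
      best[l] <- shifts[cand[1]]
    }
  }
  per_loop <- data.table::data.table(
    loop = seq_len(n_loops), r0 = r0, shift = best,
    r_min = apply(curves, 1L, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)))
  list(per_loop = per_loop, curves = curves,
       median_shift = median(best[!is.na(best)]))
}
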