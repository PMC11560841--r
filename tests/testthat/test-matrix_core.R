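test_that("band/dense conversions are exact inverses inside the band", {
  bm <- random_band(20, 6, seed = 1)
  M <- band_to_dense(bm)
  expect_true(isSymmetric(unname(ifelse(is.na(M), 0, M))))
  back <- dense_to_band(M, 6, bm$resolution)
  expect_equal(back$mat, bm$mat)
})

test_that("box filter matches brute-force window sums", {
  set.seed(2)
  M <- matrix(rpois(12 * 12, 2), 12, 12)
  for (r in 1:2) {
    B <- sc3dmulti:::box_sum(M, r)
    for (i in c(1, 5, 12)) for (j in c(1, 7, 12)) {
      ii <- max(1, i - r):min(12, i + r)
      jj <- max(1, j - r):min(12, j + r)
      expect_equal(B[i, j], sum(M[ii, jj]))
    }
  }
  # a single count far from edges smears into an equal (2r+1)^2 footprint
  M1 <- matrix(0, 11, 11); M1[6, 6] <- 1
  B1 <- sc3dmulti:::box_sum(M1, 1)
  expect_equal(B1[5:7, 5:7], matrix(1, 3, 3))
  expect_equal(sum(B1), 9)
})

test_that("impute is symmetric, non-negative, and exact matches iterative", {
  coh <- tiny_cohort()
  M <- contacts_to_matrix(coh$cells[[1]], 4e6, 2.5e4)
  Q <- impute(M, 2.5e4, max_distance = 1e6)
  Qd <- band_to_dense(Q, fill = 0)
  expect_true(all(Q$mat >= 0, na.rm = TRUE))
  expect_lt(max(abs(Qd - t(Qd))), 1e-12)
  Qi <- impute(M, 2.5e4, max_distance = 1e6, method = "iterative")
  # 20 iterations at restart 0.5 sit well inside the 1e-2 L1 tolerance
  expect_lt(sum(abs(Q$mat - Qi$mat), na.rm = TRUE), 1e-2)
  expect_warning(Q0 <- impute(matrix(0, 40, 40), 1e4, max_distance = 1e5),
                 "zero")
  expect_true(all(Q0$mat == 0, na.rm = TRUE))
})

test_that("diagonal z-score has the documented closed forms", {
  B <- matrix(NA_real_, 3, 6)
  B[1, ] <- 5                       # constant diagonal -> 0
  B[2, 1:5] <- c(1, 3, 1, 3, 1)
  B[3, 1:4] <- c(2, 2, 7, 7)        # two-value diagonal -> +/-1
  E <- diagonal_zscore(band_matrix(B, 1e4))
  expect_true(all(E$mat[1, ] == 0))
  expect_equal(sort(unique(round(E$mat[3, 1:4], 12))), c(-1, 1))
  for (d in 1:3)
    expect_lt(abs(mean(E$mat[d, ], na.rm = TRUE)), 1e-10)
})

test_that("E is invariant to adding a constant to a diagonal of log(1+Q)", {
  Q <- random_band(16, 6, seed = 99)
  E <- diagonal_zscore(Q)
  Q2 <- Q
  for (d in 0:6) {
    shift <- runif(1, 0.1, 1)
    Q2$mat[d + 1, ] <- expm1(log1p(Q$mat[d + 1, ]) + shift)
  }
  expect_equal(diagonal_zscore(Q2)$mat, E$mat, tolerance = 1e-9)
})

test_that("local background ring matches brute-force enumeration", {
  E <- diagonal_zscore(random_band(12, 8, seed = 3))
  got <- subtract_local_background(E)
  want <- ring_subtract_bruteforce(E)
  expect_equal(got$mat, want$mat, tolerance = 1e-12)
  # constant E -> T = 0; isolated spike is preserved
  Bc <- band_matrix(matrix(1, 5, 20), 1e4)
  expect_true(all(abs(subtract_local_background(Bc)$mat) < 1e-12, na.rm = TRUE))
  # spike far enough from the diagonal that its mirror image is outside the
  # ring (Chebyshev distance 2d > 4)
  Bs <- band_matrix(matrix(0, 13, 30), 1e4)
  Bs$mat[11, 10] <- 3
  Ts <- subtract_local_background(Bs)
  expect_equal(Ts$mat[11, 10], 3)
})

test_that("diagonal shuffling preserves each diagonal's multiset", {
  E <- diagonal_zscore(random_band(15, 10, seed = 4))
  S <- shuffle_diagonals(E, seed = 7)
  for (d in 0:10)
    expect_equal(sort(S$mat[d + 1, ]), sort(E$mat[d + 1, ]))
  expect_identical(shuffle_diagonals(E, seed = 7)$mat, S$mat)
  # a length-1 diagonal cannot move
  one <- band_matrix(matrix(c(1, 2), 2, 2), 1e4)
  expect_identical(shuffle_diagonals(one, seed = 1)$mat, one$mat)
})

test_that("pseudobulk aggregation equals brute-force means", {
  mk <- function(seed) {
    Q <- random_band(10, 5, seed = seed)
    list(Q = Q, E = diagonal_zscore(Q),
         T = subtract_local_background(diagonal_zscore(Q)))
  }
  cells <- lapply(1:4, mk)
  pb <- aggregate_pseudobulk(cells)
  expect_equal(pb$n_cell, 4L)
  for (w in c("Q", "E", "T")) {
    want <- Reduce(`+`, lapply(cells, function(c) c[[w]]$mat)) / 4
    want2 <- Reduce(`+`, lapply(cells, function(c) c[[w]]$mat^2)) / 4
    expect_equal(pb[[w]]$mat, want, tolerance = 1e-12)
    expect_equal(pb[[paste0(w, "2")]]$mat, want2, tolerance = 1e-12)
    expect_true(all(pb[[paste0(w, "2")]]$mat - pb[[w]]$mat^2 >= -1e-12,
                    na.rm = TRUE))
  }
  # one cell: Q2 = Q^2 exactly; two cells {1,3} at a pixel -> Q=2, Q2=5
  pb1 <- aggregate_pseudobulk(cells[1])
  expect_equal(pb1$Q2$mat, pb1$Q$mat^2)
  a <- band_matrix(matrix(1, 2, 4), 1e4)
  b <- band_matrix(matrix(3, 2, 4), 1e4)
  pb2 <- aggregate_pseudobulk(list(list(Q = a, E = a, T = a),
                                   list(Q = b, E = b, T = b)))
  expect_equal(pb2$Q$mat[1, 1], 2)
  expect_equal(pb2$Q2$mat[1, 1], 5)
})

test_that("cell embedding separates planted populations with unit norms", {
  set.seed(11)
  mk <- function(hot) {
    B <- matrix(rpois(12 * 40, 4) * 1.0, 12, 40)
    B[3, hot] <- B[3, hot] + 25
    band_matrix(B, 1e5)
  }
  cells <- c(lapply(1:8, function(i) mk(1:10)),
             lapply(1:8, function(i) mk(25:34)))
  names(cells) <- sprintf("c%02d", 1:16)
  emb <- embed_cells(cells, dims = 4)
  expect_equal(unname(sqrt(rowSums(emb^2))), rep(1, 16), tolerance = 1e-12)
  # linear separation of the two planted populations in the top dims
  lab <- rep(c(0, 1), each = 8)
  fit <- suppressWarnings(glm(lab ~ emb[, 1] + emb[, 2], family = binomial))
  expect_gte(mean((predict(fit) > 0) == (lab == 1)), 15 / 16)
  # deterministic (sign convention fixed)
  expect_identical(embed_cells(cells, dims = 4), emb)
  expect_warning(embed_cells(cells[1:3], dims = 10), "truncating")
})
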