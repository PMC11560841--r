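test_that("pseudobulk t equals direct computation from raw cells", {
  # closed forms
  a <- band_matrix(matrix(0, 2, 4), 1e4)
  pb0 <- aggregate_pseudobulk(list(list(Q = a, E = a, T = a),
                                   list(Q = a, E = a, T = a)))
  expect_true(all(pseudobulk_tstat(pb0, "E")$mat == 0, na.rm = TRUE))
  x1 <- band_matrix(matrix(1, 2, 4), 1e4)
  x3 <- band_matrix(matrix(3, 2, 4), 1e4)
  pb <- aggregate_pseudobulk(list(list(Q = x1, E = x1, T = x1),
                                  list(Q = x3, E = x3, T = x3)))
  expect_equal(pseudobulk_tstat(pb, "E")$mat[1, 1], 2 / sqrt(1 / 2),
               tolerance = 1e-12)
  # oracle equivalence on 100 random instances
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    vals <- rnorm(n)
    cells <- lapply(vals, function(v) {
      b <- band_matrix(matrix(v, 1, 1), 1e4)
      list(Q = b, E = b, T = b)
    })
    t_pkg <- pseudobulk_tstat(aggregate_pseudobulk(cells), "E")$mat[1, 1]
    t_direct <- mean(vals) / sqrt(mean(vals^2) - mean(vals)^2) * sqrt(n)
    expect_equal(t_pkg, t_direct, tolerance = 1e-8)
  }
})

test_that("empirical FDR matches its definition and is monotone", {
  expect_equal(empirical_fdr(c(1, 2, 5), c(0, 0.5))[3], 0)
  # identical obs/shuffle distributions: FDR ~ 1 at the median
  x <- seq(-3, 3, length.out = 201)
  f <- empirical_fdr(x, x)
  expect_gt(f[which.min(abs(x - median(x)))], 0.9)
  set.seed(14)
  for (rep in 1:10) {
    obs <- rnorm(200); sh <- rnorm(300)
    q <- empirical_fdr(obs, sh)
    ord <- order(obs)
    expect_true(all(diff(q[ord]) <= 1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }
  expect_error(empirical_fdr(1, numeric(0)), "empty")
})

test_that("background fold changes match brute-force offset enumeration", {
  # uniform matrix: all four fold changes are 1
  U <- band_matrix(matrix(2, 8, 30), 1e4)
  fc <- background_fold_changes(U)
  # interior pixels are exactly 1; pixels whose background is fully clipped
  # away carry the Inf sentinel
  for (f in fc) {
    v <- f$mat[is.finite(f$mat)]
    expect_true(all(abs(v - 1) < 1e-9))
  }

  # single bright pixel on a zero background: infinite fold changes
  Z <- band_matrix(matrix(0, 10, 30), 1e4)
  Z$mat[8, 10] <- 4
  fcz <- background_fold_changes(Z)
  for (f in fcz) expect_identical(f$mat[8, 10], Inf)

  # random instance vs brute force
  Q <- random_band(15, 14, seed = 15)
  fcr <- background_fold_changes(Q)
  OE <- band_to_dense(sc3dmulti:::oe_normalize(Q))
  n <- 15
  off <- list(
    fc_donut = {
      o <- expand.grid(a = -5:5, b = -5:5)
      o[pmax(abs(o$a), abs(o$b)) >= 2 & pmax(abs(o$a), abs(o$b)) <= 5 &
          o$a != 0 & o$b != 0, ]
    },
    fc_lowerleft = expand.grid(a = 1:5, b = -5:-1),
    fc_horizontal = {
      o <- expand.grid(a = 0, b = -5:5); o[abs(o$b) >= 2, ]
    },
    fc_vertical = {
      o <- expand.grid(a = -5:5, b = 0); o[abs(o$a) >= 2, ]
    })
  for (nm in names(off)) {
    for (pix in list(c(2, 9), c(5, 12), c(1, 14))) {
      i <- pix[1]; j <- pix[2]
      vals <- c()
      for (k in seq_len(nrow(off[[nm]]))) {
        ii <- i + off[[nm]]$a[k]; jj <- j + off[[nm]]$b[k]
        if (ii < 1 || jj < 1 || ii > n || jj > n) next
        v <- OE[ii, jj]
        if (!is.na(v)) vals <- c(vals, v)
      }
      want <- OE[i, j] / mean(vals)
      expect_equal(fcr[[nm]]$mat[j - i + 1, i], want, tolerance = 1e-10)
    }
  }
})

test_that("ANOVA from summaries equals direct one-way ANOVA", {
  mkpb <- function(vals) {
    cells <- lapply(vals, function(v) {
      b <- band_matrix(matrix(v, 1, 1), 1e4)
      list(Q = b, E = b, T = b)
    })
    aggregate_pseudobulk(cells)
  }
  pix <- data.table::data.table(bin1 = 0L, bin2 = 0L)
  # equal group means -> F = 0
  expect_equal(anova_from_summaries(list(mkpb(c(1, 2)), mkpb(c(2, 1))),
                                    "Q", pix), 0)
  # hand computation: G1 = {0,2}, G2 = {3,5} -> F = 4.5
  expect_equal(anova_from_summaries(list(mkpb(c(0, 2)), mkpb(c(3, 5))),
                                    "Q", pix), 4.5, tolerance = 1e-12)
  # oracle equivalence on 100 random instances
  set.seed(16)
  for (rep in 1:100) {
    g <- lapply(1:3, function(i) rnorm(sample(2:6, 1)))
    F_pkg <- anova_from_summaries(lapply(g, mkpb), "Q", pix)
    df <- data.frame(y = unlist(g),
                     grp = factor(rep(seq_along(g), lengths(g))))
    F_lm <- anova(lm(y ~ grp, data = df))$`F value`[1]
    expect_equal(F_pkg, F_lm, tolerance = 1e-8)
  }
  # zero within-group variance -> Inf sentinel
  expect_identical(anova_from_summaries(list(mkpb(c(1, 1)), mkpb(c(2, 2))),
                                        "Q", pix), Inf)
})

test_that("differential selection thresholds and invariances", {
  expect_equal(round(normal_quantile_threshold(0.85), 3), 1.036)
  set.seed(17)
  Fq <- c(rlnorm(40), 300, 400)
  Ft <- c(rlnorm(40), 250, 500)
  sel <- select_differential(Fq, Ft)
  expect_true(all(sel$is_differential[41:42]))
  expect_false(any(sel$is_differential[1:40]))
  # invariant to scaling all F by a constant (z of logs)
  sel2 <- select_differential(10 * Fq, 0.1 * Ft)
  expect_equal(sel2$is_differential, sel$is_differential)
  expect_equal(sel2$z_FQ, sel$z_FQ, tolerance = 1e-10)
  # constant F -> nothing selected
  expect_false(any(select_differential(rep(2, 5), rep(3, 5))$is_differential))
})

test_that("cumulative loop scores respect the 5-kb TSS rule", {
  loops <- data.table::data.table(chrom = "chr1", bin1 = c(10L, 10L, 40L),
                                  bin2 = c(30L, 50L, 80L),
                                  strength = c(1.5, 2.5, 10))
  # anchor 1 of the first two loops spans [1e5, 1.1e5)
  prom <- data.table::data.table(
    gene = c("in_anchor", "at_5kb", "at_5001", "far"),
    chrom = "chr1", tss = c(100500L, 95000L, 94999L, 700000L))
  sc <- cumulative_loop_score(loops, prom)
  expect_equal(sc$score[sc$gene == "in_anchor"], 4.0)
  expect_equal(sc$score[sc$gene == "at_5kb"], 4.0)
  expect_equal(sc$score[sc$gene == "at_5001"], 0)
  expect_equal(sc$score[sc$gene == "far"], 0)
})

test_that("SIP calling follows the half-Gaussian model", {
  set.seed(18)
  sc <- data.table::data.table(gene = sprintf("g%03d", 1:200),
                               score = abs(rnorm(200)))
  sips <- call_sips(sc)
  sigma <- sd(sc$score)
  expect_equal(attr(sips, "threshold"), sigma * qnorm(0.9995))
  expect_equal(sips$p_halfgauss[1], 2 * (1 - pnorm(sc$score[1] / sigma)))
  # p at score = sigma is 2(1 - Phi(1)) ~ 0.3173
  sc2 <- data.table::copy(sc); sc2$score[1] <- sigma
  p1 <- call_sips(sc2)
  expect_equal(p1$p_halfgauss[1], 2 * (1 - pnorm(sc2$score[1] / sd(sc2$score))),
               tolerance = 1e-12)
  # doubling all scores doubles the threshold, SIP set unchanged
  sc3 <- data.table::copy(sc); sc3$score <- sc3$score * 2
  sips3 <- call_sips(sc3)
  expect_equal(attr(sips3, "threshold"), 2 * attr(sips, "threshold"))
  expect_equal(sips3$is_SIP, sips$is_SIP)
  expect_error(call_sips(data.table::data.table(gene = c("a", "b"),
                                                score = c(1, 1))), "variance")
})

test_that("differential score trajectories sum per stage", {
  dl <- data.table::data.table(chrom = "chr1", bin1 = c(10L, 40L),
                               bin2 = c(30L, 80L))
  S <- cbind(stageA = c(1, 10), stageB = c(2, 20))
  prom <- data.table::data.table(gene = c("g1", "none"), chrom = "chr1",
                                 tss = c(100500L, 2e6))
  tr <- cumulative_differential_score(dl, S, prom)
  expect_equal(tr["g1", ], c(stageA = 1, stageB = 2))
  expect_equal(unname(tr["none", ]), c(0, 0))
  # stage permutation permutes the trajectory
  tr2 <- cumulative_differential_score(dl, S[, 2:1], prom)
  expect_equal(unname(tr2["g1", ]), c(2, 1))
  # no differential loops -> all-zero trajectory
  tr0 <- cumulative_differential_score(dl[0, ], S[0, , drop = FALSE], prom)
  expect_true(all(tr0 == 0))
})

test_that("loop summit merging reports one centroid per cluster", {
  calls <- data.table::data.table(
    chrom = "c", bin1 = c(10L, 10L, 11L, 40L), bin2 = c(30L, 31L, 30L, 80L),
    distance = c(20L, 21L, 19L, 40L) * 1e4,
    t_E = c(5, 7, 6, 3), E_mean = 1, is_loop = TRUE)
  s <- merge_loop_calls(calls)
  expect_equal(nrow(s), 2L)
  expect_equal(sort(s$cluster_size), c(1L, 3L))
  big <- s[s$cluster_size == 3, ]
  expect_equal(big$bin1, 10L)   # round(mean(c(10,10,11)))
  expect_equal(big$bin2, 30L)
  expect_equal(big$t_E, 7)      # stats from the max-t_E member
})
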