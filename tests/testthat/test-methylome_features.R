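test_that("cell QC is the exact four-way strict conjunction", {
  meta <- data.table::data.table(
    mccc_level = c(0.01, 0.05, 0.01, 0.01, 0.01, 0.029),
    global_mcg = c(0.8, 0.8, 0.5, 0.8, 0.8, 0.51),
    global_mch = c(0.05, 0.05, 0.05, 0.25, 0.05, 0.19),
    n_contacts = c(2e5, 2e5, 2e5, 2e5, 1e5, 100001))
  qc <- cell_qc(meta)
  expect_equal(qc$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(qc$fail_reason[2:5], c("mCCC", "mCG", "mCH", "contacts"))
  # each threshold violated alone flips pass -> fail (strictness at bounds)
  base <- data.table::data.table(mccc_level = 0.01, global_mcg = 0.8,
                                 global_mch = 0.05, n_contacts = 2e5)
  for (col in names(base)) {
    m <- data.table::copy(base)
    m[[col]] <- c(mccc_level = 0.03, global_mcg = 0.5, global_mch = 0.2,
                  n_contacts = 1e5)[[col]]
    expect_false(cell_qc(m)$pass)
  }
  expect_error(cell_qc(base[, 1:3]), "missing")
})

test_that("region methylation sums counts inside intervals", {
  allc <- data.table::data.table(
    chrom = "c", pos = c(150L, 250L, 260L, 900L),
    strand = "+", context = c("CGA", "CGT", "CAT", "CGA"),
    mc = c(3L, 1L, 5L, 2L), cov = c(10L, 10L, 6L, 4L))
  regions <- data.table::data.table(chrom = "c", start = c(100L, 500L),
                                    end = c(300L, 600L))
  rm_cg <- region_methylation(allc, regions, "CG")
  expect_equal(rm_cg$fraction[1], 0.2)    # (3+1)/(10+10); CH record excluded
  expect_true(is.na(rm_cg$fraction[2]))   # empty region -> missing
  rm_ch <- region_methylation(allc, regions, "CH")
  expect_equal(rm_ch$fraction[1], 5 / 6)
  # brute-force interval filter agreement on a random instance
  set.seed(41)
  allc2 <- data.table::data.table(
    chrom = "c", pos = sample.int(5000, 300), strand = "+",
    context = sample(c("CGA", "CAT"), 300, TRUE),
    cov = rpois(300, 8) + 1L)
  allc2$mc <- rbinom(300, allc2$cov, 0.5)
  regions2 <- data.table::data.table(chrom = "c", start = c(0L, 1000L, 2500L),
                                     end = c(800L, 2200L, 5000L))
  got <- region_methylation(allc2, regions2, "CG")
  for (r in 1:3) {
    keep <- startsWith(allc2$context, "CG") &
      allc2$pos > regions2$start[r] & allc2$pos <= regions2$end[r]
    expect_equal(got$fraction[r], sum(allc2$mc[keep]) / sum(allc2$cov[keep]))
  }
})

test_that("coverage filter and by-sample imputation follow the printed rule", {
  fr <- rbind(c(0.1, 0.5, 0.9), c(0.3, 0.7, 0.8), c(0.5, 0.9, 0.7),
              c(0.7, 0.2, 0.6))
  cv <- rbind(c(20, 9, 20), c(20, 10, 4), c(20, 11, 20), c(20, 9.6, 20))
  out <- filter_impute_features(fr, cv, samples = c("s1", "s1", "s2", "s2"))
  # feature 2 mean coverage 9.9 -> dropped
  expect_equal(out$kept, c(1L, 3L))
  # entry with coverage 4 imputed as its sample's mean over covered entries
  expect_equal(out$fractions[2, 2], 0.9)
  expect_equal(out$fractions[1, 1], 0.1)
  # all coverage >= thresholds: unchanged
  out2 <- filter_impute_features(fr[, 1, drop = FALSE],
                                 cv[, 1, drop = FALSE],
                                 samples = rep("s", 4))
  expect_equal(out2$fractions, fr[, 1, drop = FALSE])
  # idempotence
  again <- filter_impute_features(out$fractions, out$coverage,
                                  samples = c("s1", "s1", "s2", "s2"))
  expect_equal(again$fractions, out$fractions)
})

test_that("3CGS equals brute-force pixel enumeration", {
  B <- matrix(NA_real_, 3, 3)
  B[1, ] <- 0
  B[2, 1:2] <- c(2, 3)
  B[3, 1] <- 1
  Q <- band_matrix(B, 1e4)   # Q[0,1]=2, Q[1,2]=3, Q[0,2]=1
  expect_equal(as.numeric(gene_3cgs(Q, 1L, 1L)), 5)
  expect_equal(as.numeric(gene_3cgs(Q, 0L, 2L)), 6)
  # all-zero matrix -> 0
  Z <- band_matrix(matrix(0, 3, 6), 1e4)
  expect_equal(as.numeric(gene_3cgs(Z, 1L, 2L)), 0)
  # widening the span never decreases the score; brute force on random Q
  Qr <- random_band(30, 15, seed = 42)
  prev <- 0
  for (g2 in 5:12) {
    sc <- as.numeric(gene_3cgs(Qr, 5L, g2))
    expect_gte(sc, prev - 1e-12)
    prev <- sc
    dense <- band_to_dense(Qr)
    want <- 0
    for (i in 1:30) for (j in 1:30) {
      if (j <= i || j - i > 15) next
      if ((i - 1) %in% 5:g2 || (j - 1) %in% 5:g2)
        want <- want + dense[i, j]
    }
    expect_equal(sc, want)
  }
  expect_error(gene_3cgs(Qr, 1L, 40L), "outside")
  # matrix fast path agrees with the per-gene reference
  genes <- data.table::data.table(chrom = "c", start = c(5e4, 1.2e5),
                                  end = c(9e4, 2.6e5), name = c("a", "b"),
                                  score = 0, strand = c("+", "-"))
  m <- gene_3cgs_matrix(list(cell = Qr), genes)
  gt <- gene_tss_tes(genes)
  for (g in 1:2) {
    ref <- gene_3cgs(Qr, pos_to_bin(gt$tss[g] + 1, 1e4),
                     pos_to_bin(gt$tes[g] + 1, 1e4))
    expect_equal(m[1, g], as.numeric(ref))
  }
})

test_that("feature correlations are exact and die under permutation", {
  set.seed(43)
  A <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, letters[1:10]))
  r <- feature_correlations(A, -A)
  expect_equal(unname(r), rep(-1, 10))
  B <- A + matrix(rnorm(200, 0, 0.1), 20, 10)
  colnames(B) <- colnames(A)
  rp <- feature_correlations(A, B[sample(20), ])
  expect_lt(abs(median(rp)), 0.35)
  expect_gt(median(feature_correlations(A, B)), 0.9)
  # zero-variance feature -> NA
  A2 <- A; A2[, 1] <- 1
  expect_true(is.na(feature_correlations(A2, B)[1]))
})
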