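test_that("cohort counts and determinism follow the config", {
  coh <- tiny_cohort()
  expect_length(coh$cells, 20L)
  expect_length(coh$allc, 20L)
  expect_equal(nrow(coh$truth$cells), 20L)
  coh2 <- simulate_cohort(tiny_config())
  expect_identical(coh$cells, coh2$cells)
  expect_identical(coh$allc, coh2$allc)
  expect_identical(coh$annotations, coh2$annotations)
  # different seed changes the draws
  coh3 <- simulate_cohort(tiny_config(seed = 202L))
  expect_false(identical(coh$cells[[1]], coh3$cells[[1]]))
})

test_that("config validation rejects bad worlds", {
  expect_error(sim_config(genome = data.frame(chrom = "c", length = 0)),
               "too short")
  lp <- data.frame(bin1 = 0L, bin2 = 2L, onset = 0, is_differential = FALSE,
                   fold_A = 3, fold_B = 3)
  expect_error(sim_config(genome = data.frame(chrom = "c", length = 4e6),
                          cell_types = tiny_config()$cell_types,
                          planted_loops = lp),
               "50 kb - 5 Mb")
})

test_that("distance mixture hits its pi_short targets", {
  cfg <- tiny_config()
  tp <- sc3dmulti:::type_params(cfg, 1)
  # degenerate mixtures
  tp1 <- tp; tp1$pi_short <- 1; tp1$loops <- tp1$loops[0, ]
  cc <- simulate_contacts_for_cell(tp1, 5e3, 0.5, seed = 1)
  expect_true(all(cc$pos2 - cc$pos1 < 2e6))
  tp0 <- tp; tp0$pi_short <- 0; tp0$loops <- tp0$loops[0, ]
  cc0 <- simulate_contacts_for_cell(tp0, 1e4, 0.5, seed = 2)
  frac_long <- mean(cc0$pos2 - cc0$pos1 >= 2e6)
  # binomial error around 1 (boundary rounding can leak a handful below)
  expect_gt(frac_long, 0.995)

  # Monte-Carlo calibration at 1e5 contacts: the SE type's measured
  # log2(pct_median/pct_long) exceeds the 0.4 SE threshold
  cc85 <- simulate_contacts_for_cell(tp, 1e5, 0.25, seed = 3)
  m <- distance_metrics(bin_distances(cc85))
  expect_gt(m$ratio, 0.4)
  expect_identical(m$conformation_class, "SE")
})

test_that("planted loops enrich their pixel; fold 1 stays at background", {
  cfg <- sim_config(
    genome = data.frame(chrom = "chrT", length = 4e6),
    cell_types = data.frame(name = "A", n_cells = 1L, pi_short = 0.7,
                            pseudotime_center = 0.5, pseudotime_spread = 0,
                            comp_amplitude = 0),
    planted_loops = data.frame(bin1 = 100L, bin2 = 130L, onset = 0,
                               is_differential = FALSE, fold_A = 1),
    weights = list(domain = 0),
    seed = 5)
  tp <- sc3dmulti:::type_params(cfg, 1)
  n <- 2e5
  cc <- simulate_contacts_for_cell(tp, n, 0.5, seed = 6)
  i <- pos_to_bin(cc$pos1, 1e4); j <- pos_to_bin(cc$pos2, 1e4)
  obs <- sum(i == 100 & j == 130)
  lam <- expected_short_pixel_rate(n * 0.7, 30e4, 4e6)
  # fold-1 loop emits nothing extra: count within Poisson range of background
  expect_lte(obs, qpois(0.9995, lam))
  expect_gte(obs, qpois(0.0005, lam))
  # fold-3 loop is far above that range
  cfg3 <- sim_config(
    genome = cfg$genome, cell_types = cfg$cell_types,
    planted_loops = data.frame(bin1 = 100L, bin2 = 130L, onset = 0,
                               is_differential = FALSE, fold_A = 3),
    weights = list(domain = 0), seed = 5)
  cc3 <- simulate_contacts_for_cell(sc3dmulti:::type_params(cfg3, 1), n, 0.5,
                                    seed = 6)
  i3 <- pos_to_bin(cc3$pos1, 1e4); j3 <- pos_to_bin(cc3$pos2, 1e4)
  expect_gt(sum(i3 == 100 & j3 == 130), qpois(0.9995, lam))
})

test_that("methylome generator obeys its logistic anchor model", {
  cfg <- tiny_config()
  tp <- sc3dmulti:::type_params(cfg, 1)
  baseline <- sc3dmulti:::mcg_baseline(cfg)

  # amplitude 0: all bins at baseline within binomial error
  tp0 <- tp; tp0$methylome$anchor_amp <- 0
  a <- simulate_methylome_for_cell(tp0, baseline, 0.9, seed = 9)
  cg <- a[sc3dmulti:::context_class(a$context, "CG"), ]
  b <- pos_to_bin(cg$pos, 1e4)
  mc <- tapply(cg$mc, b, sum); cv <- tapply(cg$cov, b, sum)
  frac <- mc / cv
  expect_lt(max(abs(frac - baseline[as.integer(names(frac)) + 1L]) -
                  3 * sqrt(baseline[as.integer(names(frac)) + 1L] *
                             (1 - baseline[as.integer(names(frac)) + 1L]) / cv)),
            0)

  # lag 0, late pseudotime: anchor bins hypomethylated by ~the amplitude
  tpL <- tp; tpL$methylome$lag_delta <- 0
  aL <- simulate_methylome_for_cell(tpL, baseline, 5, seed = 10)
  cgL <- aL[sc3dmulti:::context_class(aL$context, "CG"), ]
  bL <- pos_to_bin(cgL$pos, 1e4)
  anchors <- unique(c(tp$loops$bin1, tp$loops$bin2))
  an <- bL %in% anchors
  f_anchor <- sum(cgL$mc[an]) / sum(cgL$cov[an])
  exp_anchor <- mean(baseline[anchors + 1L]) - tp$methylome$anchor_amp
  expect_lt(abs(f_anchor - exp_anchor), 0.05)

  # constant coverage law: every bin total equals the constant
  tpC <- tp; tpC$methylome$coverage <- list(dist = "constant", value = 10)
  aC <- simulate_methylome_for_cell(tpC, baseline, 0.5, seed = 11)
  cgC <- aC[sc3dmulti:::context_class(aC$context, "CG"), ]
  totC <- tapply(cgC$cov, pos_to_bin(cgC$pos, 1e4), sum)
  expect_true(all(totC == 10))
})

test_that("cohort QC table feeds cell_qc with sane global levels", {
  coh <- tiny_cohort()
  qc <- cell_qc(cohort_qc_table(coh))
  expect_true(all(qc$global_mcg > 0.5))
  expect_true(all(qc$global_mch < 0.2))
  expect_true(all(qc$mccc_level < 0.03))
  # tiny cells fail only on the contact threshold
  expect_true(all(qc$fail_reason %in% c("", "contacts")))
})

test_that("cohort writes to plain text and reads back", {
  coh <- tiny_cohort()
  dir <- file.path(tempdir(), "cohort_io")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$cells), length(coh$cells))
  expect_equal(as.data.frame(back$cells[[1]]),
               as.data.frame(coh$cells[[1]]))
  expect_equal(back$truth$loops$bin1, coh$truth$loops$bin1)
  a0 <- coh$allc[[1]]; a1 <- back$allc[[names(coh$allc)[1]]]
  expect_equal(as.data.frame(a1), as.data.frame(a0))
})
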