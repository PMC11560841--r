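test_that("loop-connected DMRs require >= 1 bp anchor overlap in type", {
  loops <- data.table::data.table(chrom = "c", bin1 = 10L, bin2 = 40L,
                                  cell_type = "t1")
  dmrs <- data.table::data.table(
    chrom = "c",
    start = c(100500L, 99000L, 98000L, 100500L),
    end = c(100900L, 100001L, 99999L, 100900L),
    cell_type = c("t1", "t1", "t1", "t2"))
  lc <- loop_connected_dmrs(dmrs, loops)
  # inside anchor [1e5, 1.1e5): kept; 1-bp overlap: kept; 1 bp outside: no;
  # wrong cell type: no
  expect_equal(nrow(lc), 2L)
  expect_equal(lc$start, c(100500L, 99000L))
  # brute-force intersection on a random instance
  set.seed(61)
  dr <- data.table::data.table(chrom = "c",
                               start = sample.int(8e5, 200), cell_type = "t1")
  dr$end <- dr$start + sample.int(2000, 200)
  lp2 <- data.table::data.table(chrom = "c", bin1 = c(5L, 30L),
                                bin2 = c(20L, 70L), cell_type = "t1")
  got <- loop_connected_dmrs(dr, lp2)
  anchors <- rbind(c(5e4, 6e4), c(2e5, 2.1e5), c(3e5, 3.1e5), c(7e5, 7.1e5))
  want <- dr[apply(outer(dr$start, anchors[, 2], `<`) &
                     outer(dr$end, anchors[, 1], `>`), 1, any), ]
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("motif enrichment is the exact hypergeometric upper tail", {
  set.seed(62)
  mk_iv <- function(starts, width = 50L)
    data.table::data.table(chrom = "c", start = starts, end = starts + width)
  # x = n and K = N -> p = 1, fold = 1
  fg <- mk_iv(c(1000L, 5000L))
  hits <- mk_iv(c(1010L, 5010L), 10L)
  res <- motif_enrichment(fg, fg, hits)
  expect_equal(res$p, 1)
  expect_equal(res$fold, 1)
  # x = 0 -> p = 1
  res0 <- motif_enrichment(mk_iv(90000L), fg, hits)
  expect_equal(res0$p, 1)
  # pmf summation oracle on all instances with N <= 200
  for (rep in 1:25) {
    N <- sample(20:200, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    x <- sample.int(min(n, K), 1)
    oracle <- sum(dhyper(x:min(n, K), K, N - K, n))
    expect_equal(phyper(x - 1, K, N - K, n, lower.tail = FALSE), oracle,
                 tolerance = 1e-12)
  }
  # the fg/bg extension conventions: edges vs centre
  fg2 <- data.table::data.table(chrom = "c", start = 1000L, end = 1100L)
  ext_fg <- sc3dmulti:::extend_from_edges(fg2, 250L)
  expect_equal(c(ext_fg$start, ext_fg$end), c(750L, 1350L))
  ext_bg <- sc3dmulti:::extend_from_centre(fg2, 250L)
  expect_equal(c(ext_bg$start, ext_bg$end), c(800L, 1300L))
})

test_that("fine-mapped SNP overlap builds the printed 2x2 and locus table", {
  snps <- data.table::data.table(
    chrom = "c", pos = c(100L, 200L, 5000L, 5100L, 9000L),
    locus = c("L1", "L1", "L2", "L2", "L3"),
    snp = paste0("rs", 1:5),
    pip = c(0.5, 0.05, 0.3, 0.2, 0.9))
  annot <- data.table::data.table(chrom = "c", start = c(50L, 5050L),
                                  end = c(150L, 5150L))
  bg <- data.table::data.table(chrom = "c", pos = c(60L, 3000L, 4000L, 8000L))
  ov <- finemap_overlap(snps, annot, bg)
  # rs2 removed by PIP filter; rs1 and rs4 overlap
  expect_equal(c(ov$a, ov$b, ov$c, ov$d), c(2, 2, 1, 3))
  expect_equal(ov$odds_ratio, (2 * 3) / (2 * 1))
  expect_equal(ov$p, fisher.test(matrix(c(2, 2, 1, 3), 2, byrow = TRUE))$p.value)
  # locus L2 has one overlapping SNP of two -> counted once
  expect_equal(ov$n_loci_hit, 2L)
  expect_equal(sort(ov$per_locus$locus[ov$per_locus$hit]), c("L1", "L2"))
  # OR arithmetic example: a=8, b=2, c=100, d=900 -> 36
  expect_equal((8 * 900) / (2 * 100), 36)
})

test_that("SNP-gene links are cross-anchor only", {
  loops <- data.table::data.table(chrom = "c", bin1 = 10L, bin2 = 40L)
  dmrs <- data.table::data.table(chrom = "c", start = 100200L, end = 100800L)
  snps <- data.table::data.table(chrom = "c", pos = 100500L, snp = "rs1")
  tss <- data.table::data.table(gene = c("gA", "gB"), chrom = "c",
                                tss = c(401000L, 100600L))
  links <- link_snp_to_genes(snps, dmrs, loops, tss)
  # gA's TSS is at the other anchor -> linked; gB shares the SNP anchor -> not
  expect_equal(nrow(links), 1L)
  expect_equal(links$gene, "gA")
  # brute-force join on a random instance
  set.seed(63)
  lp <- data.table::data.table(chrom = "c", bin1 = sample(5:20, 4),
                               bin2 = sample(40:80, 4))
  sn <- data.table::data.table(chrom = "c", pos = sample.int(9e5, 60),
                               snp = paste0("s", 1:60))
  dm <- data.table::data.table(chrom = "c", start = sample.int(9e5, 30))
  dm$end <- dm$start + 400L
  ts <- data.table::data.table(gene = paste0("g", 1:25), chrom = "c",
                               tss = sample.int(9e5, 25))
  got <- link_snp_to_genes(sn, dm, lp, ts)
  in_dmr <- sapply(sn$pos, function(p) any(p - 1L >= dm$start & p - 1L < dm$end))
  want <- 0L
  pairs <- character()
  for (l in seq_len(nrow(lp))) {
    a1 <- c(lp$bin1[l], lp$bin1[l] + 1L) * 1e4
    a2 <- c(lp$bin2[l], lp$bin2[l] + 1L) * 1e4
    for (side in 1:2) {
      sa <- if (side == 1) a1 else a2
      oa <- if (side == 1) a2 else a1
      s_here <- in_dmr & sn$pos - 1L >= sa[1] & sn$pos - 1L < sa[2]
      t_near <- pmax(0, pmax(oa[1] - ts$tss, ts$tss - oa[2] + 1L)) <= 5e3
      if (any(s_here) && any(t_near))
        pairs <- c(pairs, as.vector(outer(sn$snp[s_here], ts$gene[t_near],
                                          paste)))
    }
  }
  expect_setequal(paste(got$snp, got$gene), unique(pairs))
})

test_that("enrichment difference t-test with jackknife d.f.", {
  r <- enrichment_difference_test(10, 2, 6, 1)
  expect_equal(r$t, 4 / sqrt(5), tolerance = 1e-12)
  expect_equal(r$df, 398L)
  expect_equal(r$p, 2 * pt(4 / sqrt(5), 398, lower.tail = FALSE))
  same <- enrichment_difference_test(3, 1, 3, 1)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  swapped <- enrichment_difference_test(6, 1, 10, 2)
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)
  expect_error(enrichment_difference_test(1, 0, 2, 1), "positive")
})

test_that("mean credible-set size from the published tally", {
  expect_equal(round(mean_credible_set_size(), 1), 3.0)
  expect_equal(mean_credible_set_size(6, 2), 3)
})
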