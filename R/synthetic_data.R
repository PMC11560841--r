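# Synthetic snm3C-seq-like cohort generator.
#
# The generator states a small, explicit world: one toy chromosome; cell
# types that differ in their short- versus long-range contact mixture
# (pi_short), in compartment amplitude and in developmental pseudotime;
# planted 10-kb loops whose intensity follows a logistic onset along
# pseudotime; planted 25-kb domain boundaries realized per cell with a
# per-type probability; a 2-Mb compartment pattern of irregular alternating blocks; and a
# methylome whose loop-anchor mCG decreases with a configurable pseudotime
# lag after the loop gain. Every planted object is recorded in a truth
# ledger so downstream statistics can be validated by recovery.

LOOP_MIN_BP <- 5e4
LOOP_MAX_BP <- 5e6
SHORT_RANGE <- c(25e3, 2e6)   # log-uniform short-range distance support
LONG_MIN <- 2e6

#' Build a simulation configuration
#'
#' All defaults are the generator's stated world; see the methods vignette
#' for the rationale behind each value.
#'
#' @param genome data.frame with chrom and length (bp); one chromosome.
#' @param cell_types data.frame with name, n_cells, pi_short,
#'   pseudotime_center, pseudotime_spread and comp_amplitude.
#' @param contacts_per_cell log-normal law (meanlog, sdlog) of per-cell
#'   contact counts.
#' @param planted_loops data.frame with bin1, bin2 (0-based 10-kb bins),
#'   onset (pseudotime of loop gain) and one fold_<type> column per cell
#'   type; NULL builds a default set spanning the chromosome.
#' @param planted_boundaries data.frame with bin (0-based 25-kb bin) and
#'   one prob_<type> column per type; NULL builds defaults.
#' @param compartment_blocks list with block_size (bp), gc_high, gc_low.
#' @param methylome list with mcg_global, mch_global, mccc_global,
#'   baseline_sd, anchor_amp, lag_delta (pseudotime units), tau (logistic
#'   width) and coverage (list(dist = "poisson"|"constant", mean/value)).
#' @param weights list with domain (fraction of short-range contacts that
#'   respect the cell's domain segmentation).
#' @param n_genes number of annotated genes.
#' @param seed master seed; identical seed + config reproduce the cohort
#'   byte for byte.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(genome = data.frame(chrom = "chrS", length = 2e7),
                       cell_types = NULL,
                       contacts_per_cell = list(meanlog = log(2e5), sdlog = 0.25),
                       planted_loops = NULL,
                       planted_boundaries = NULL,
                       compartment_blocks = list(block_size = 2e6,
                                                 gc_high = 0.46, gc_low = 0.38),
                       methylome = list(),
                       weights = list(domain = 0.7),
                       loop_catchment = 75,
                       n_genes = 40L,
                       seed = 1L) {
  stop_if_not(nrow(genome) == 1L, "one chromosome is supported")
  stop_if_not(genome$length >= 2.5e6, "chromosome too short (need >= 2.5 Mb)")
  L <- genome$length
  if (is.null(cell_types))
    cell_types <- data.frame(
      name = c("RG_early", "Neu_late"), n_cells = c(150L, 150L),
      pi_short = c(0.85, 0.45), pseudotime_center = c(0.25, 0.75),
      pseudotime_spread = c(0.15, 0.15), comp_amplitude = c(0.3, 0.6))
  stop_if_not(all(cell_types$pi_short >= 0 & cell_types$pi_short <= 1),
              "pi_short must be in [0, 1]")
  stop_if_not(all(cell_types$comp_amplitude >= 0 & cell_types$comp_amplitude <= 1),
              "comp_amplitude must be in [0, 1]")
  me_def <- list(mcg_global = 0.75, mch_global = 0.03, mccc_global = 0.005,
                 baseline_sd = 0.05, anchor_amp = 0.3, lag_delta = 0.15,
                 tau = 0.08, coverage = list(dist = "poisson", mean = 20))
  methylome <- utils::modifyList(me_def, methylome)
  stop_if_not(is.finite(methylome$lag_delta), "lag_delta must be finite")
  if (is.null(planted_loops))
    planted_loops <- default_planted_loops(L, cell_types$name)
  dist_bins <- planted_loops$bin2 - planted_loops$bin1
  stop_if_not(all(dist_bins * 1e4 >= LOOP_MIN_BP &
                    dist_bins * 1e4 <= LOOP_MAX_BP),
              "planted loop pixels must be 50 kb - 5 Mb apart")
  stop_if_not(all(planted_loops$bin2 * 1e4 < L), "loop pixel outside genome")
  if (is.null(planted_boundaries))
    planted_boundaries <- default_planted_boundaries(L, cell_types$name)
  pcols <- grep("^prob_", names(planted_boundaries), value = TRUE)
  for (pc in pcols)
    stop_if_not(all(planted_boundaries[[pc]] >= 0 & planted_boundaries[[pc]] <= 1),
                "boundary probabilities must be in [0, 1]")
  structure(list(genome = genome,
                 resolutions = c(loop = 1e4, domain = 2.5e4,
                                 embed = 1e5, compartment = 1e6),
                 cell_types = cell_types,
                 contacts_per_cell = contacts_per_cell,
                 planted_loops = planted_loops,
                 planted_boundaries = planted_boundaries,
                 compartment_blocks = compartment_blocks,
                 methylome = methylome, weights = weights,
                 loop_catchment = loop_catchment,
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "sim_config")
}

# Default loops: evenly spread along the chromosome, distances cycling over
# 100 kb - 1.2 Mb; one in five is differential (absent early, present late,
# onset at pseudotime 0.5); the rest are constitutive 3-fold loops.
default_planted_loops <- function(L, type_names, fold = 3) {
  n_loops <- max(6L, as.integer(round(L / 2e7 * 30)))
  dists <- rep(c(10L, 25L, 50L, 80L, 120L), length.out = n_loops)
  dists <- pmin(dists, as.integer(L / 1e4 * 0.4))
  margin <- 2L
  span <- as.integer(L / 1e4) - max(dists) - 2L * margin
  bin1 <- margin + as.integer(round(seq(0, span, length.out = n_loops)))
  lp <- data.frame(bin1 = bin1, bin2 = bin1 + dists, onset = 0)
  is_diff <- seq_len(n_loops) %% 5L == 0L
  lp$onset[is_diff] <- 0.5
  lp$is_differential <- is_diff
  for (t in seq_along(type_names)) {
    f <- rep(fold, n_loops)
    if (t == 1L) f[is_diff] <- 1      # earliest type lacks the gained loops
    lp[[paste0("fold_", type_names[t])]] <- f
  }
  lp
}

# Default boundaries: 12 per 20 Mb at 25-kb bins; one in three differential
# (probability 0.6 in the first type, 0.05 in the others).
default_planted_boundaries <- function(L, type_names) {
  nb <- max(4L, as.integer(round(L / 2e7 * 12)))
  bins <- as.integer(round(seq(0.08, 0.92, length.out = nb) * L / 2.5e4))
  pb <- data.frame(bin = bins)
  is_diff <- seq_len(nb) %% 3L == 0L
  pb$is_differential <- is_diff
  for (t in seq_along(type_names)) {
    p <- rep(0.6, nb)
    if (t > 1L) p[is_diff] <- 0.05
    pb[[paste0("prob_", type_names[t])]] <- p
  }
  pb
}

# Compartment partition: alternating-sign blocks of irregular length
# (0.7-1.6 x block_size), drawn once from the master seed. A strictly
# periodic checkerboard would be invisible to per-diagonal O/E
# normalization (homogeneous diagonals absorb their own enrichment), so
# irregularity is essential, as it is in real genomes.
compartment_partition <- function(seed, L, block_size) {
  with_seed(derive_seed(seed, 103L), {
    lens <- numeric(0)
    while (sum(lens) < L)
      lens <- c(lens, block_size * runif(1, 0.7, 1.6))
    ends <- pmin(cumsum(lens), L)
    starts <- c(0, head(ends, -1))
    keep <- ends > starts
    data.frame(start = starts[keep], end = ends[keep],
               sign = rep_len(c(1, -1), sum(keep)))
  })
}

# sign of each fixed-width bin (block sign at the bin centre)
compartment_signs <- function(partition, L, resolution = 1e6) {
  n <- as.integer(ceiling(L / resolution))
  centre <- pmin((seq_len(n) - 0.5) * resolution, L - 1)
  partition$sign[findInterval(centre, partition$start)]
}

# Expected short-range background contacts per 10-kb pixel at distance
# `distance` bp, for `n_short_bg` log-uniform short-range contacts.
#' Expected background contact rate of a 10-kb pixel
#' @param n_short_bg expected number of background short-range contacts.
#' @param distance pixel distance in bp.
#' @param L chromosome length in bp.
#' @param resolution pixel size in bp.
#' @return expected contacts in the pixel.
#' @export
expected_short_pixel_rate <- function(n_short_bg, distance, L,
                                      resolution = 1e4) {
  n_short_bg * resolution^2 /
    (distance * log(SHORT_RANGE[2] / SHORT_RANGE[1]) * (L - distance))
}

# per-type parameter bundle handed to the per-cell simulators
type_params <- function(config, type_idx) {
  ct <- config$cell_types[type_idx, ]
  tn <- ct$name
  lp <- config$planted_loops
  list(L = config$genome$length, chrom = config$genome$chrom,
       name = tn, pi_short = ct$pi_short,
       pt_center = ct$pseudotime_center, pt_spread = ct$pseudotime_spread,
       amplitude = ct$comp_amplitude,
       loops = data.frame(bin1 = lp$bin1, bin2 = lp$bin2, onset = lp$onset,
                          fold = lp[[paste0("fold_", tn)]]),
       boundaries = data.frame(bin = config$planted_boundaries$bin,
                               prob = config$planted_boundaries[[paste0("prob_", tn)]]),
       w_domain = config$weights$domain,
       catchment = config$loop_catchment %||% 75,
       comp_blocks = compartment_partition(config$seed, config$genome$length,
                                           config$compartment_blocks$block_size),
       methylome = config$methylome,
       tau = config$methylome$tau)
}

loop_fold_at <- function(fold, onset, pt, tau) {
  1 + (fold - 1) * stats::plogis((pt - onset) / tau)
}

#' Simulate one cell's contact list
#'
#' Contacts are drawn from a mixture: planted-loop contacts (Poisson counts
#' with rate (fold - 1) x background over a 3x3 pixel halo), then with
#' probability pi_short a short-range contact (log-uniform 25 kb - 2 Mb)
#' that with probability w_domain respects the cell's sampled domain
#' segmentation, else a long-range contact (log-uniform 2 Mb - span) that
#' with probability comp_amplitude joins two same-sign compartment blocks.
#'
#' @param params per-type parameter bundle (see [sim_config()] internals).
#' @param n_contacts number of contacts to draw (> 0).
#' @param pseudotime the cell's pseudotime.
#' @param seed RNG seed.
#' @return `data.table` with chrom, pos1, pos2 (1-based, pos1 <= pos2).
#' @export
simulate_contacts_for_cell <- function(params, n_contacts, pseudotime,
                                       seed = NULL) {
  stop_if_not(n_contacts > 0, "n_contacts must be > 0")
  L <- params$L
  with_seed(seed, {
    # planted loop extras: rate (fold - 1) x background x catchment. The
    # catchment (default 25, the pad-2 smoothing footprint) is the pixel
    # area whose looping contacts the anchor fragments concentrate, so that
    # a fold-x loop remains ~fold-x after box smoothing.
    lp <- params$loops
    n_loop <- integer(nrow(lp))
    if (nrow(lp)) {
      lam_bg <- n_contacts * params$pi_short * (1 - params$w_domain)
      folds <- loop_fold_at(lp$fold, lp$onset, pseudotime, params$tau)
      lam <- (folds - 1) * params$catchment *
        expected_short_pixel_rate(lam_bg, (lp$bin2 - lp$bin1) * 1e4, L)
      n_loop <- rpois(nrow(lp), pmax(lam, 0))
    }
    n_rem <- max(n_contacts - sum(n_loop), 0L)
    n_short <- rbinom(1L, n_rem, params$pi_short)
    n_long <- n_rem - n_short
    n_dom <- rbinom(1L, n_short, params$w_domain)
    n_bgs <- n_short - n_dom

    pieces <- list()
    # loop contacts: both anchors uniform within their 10-kb anchor bin, so
    # the enrichment is focal (the catchment factor in lam above represents
    # a ~30-kb anchor region concentrating its looping contacts onto the
    # anchor fragment, as CTCF anchors do)
    if (sum(n_loop) > 0) {
      li <- rep(seq_len(nrow(lp)), n_loop)
      a1 <- lp$bin1[li] * 1e4 + runif(length(li)) * 1e4
      a2 <- lp$bin2[li] * 1e4 + runif(length(li)) * 1e4
      pieces$loop <- data.table::data.table(pos1 = pmin(a1, a2),
                                            pos2 = pmax(a1, a2))
    }
    # background short range
    if (n_bgs > 0) {
      d <- exp(runif(n_bgs, log(SHORT_RANGE[1]), log(SHORT_RANGE[2])))
      p1 <- runif(n_bgs) * (L - d)
      pieces$short <- data.table::data.table(pos1 = p1, pos2 = p1 + d)
    }
    # domain-respecting short range
    if (n_dom > 0) {
      act <- params$boundaries$bin[runif(nrow(params$boundaries)) <
                                     params$boundaries$prob]
      cuts <- sort(unique(c(0, act * 2.5e4, L)))
      seg_s <- head(cuts, -1); seg_e <- tail(cuts, -1)
      len <- seg_e - seg_s
      ok <- len >= 5e4
      if (any(ok)) {
        seg_s <- seg_s[ok]; len <- len[ok]
        si <- sample.int(length(len), n_dom, replace = TRUE, prob = len^2)
        # cap at 0.8 x segment length: an uncapped draw piles contacts at
        # the segment corner and plants unintended corner-dot loops
        dmax <- pmax(pmin(0.8 * len[si], SHORT_RANGE[2]), 3e4)
        d <- exp(runif(n_dom, log(SHORT_RANGE[1]), log(dmax)))
        p1 <- seg_s[si] + runif(n_dom) * (len[si] - d)
        pieces$dom <- data.table::data.table(pos1 = p1, pos2 = p1 + d)
      } else n_long <- n_long + n_dom
    }
    # long range: compartment-structured or background. Structured draws
    # join two same-sign blocks separated by >= 2 Mb so they stay in the
    # long-range distance regime.
    if (n_long > 0) {
      n_comp <- rbinom(1L, n_long, params$amplitude)
      blocks <- params$comp_blocks
      pair_idx <- which(outer(blocks$sign, blocks$sign, `==`) &
                          outer(blocks$end, blocks$start,
                                function(e, s) s - e >= LONG_MIN),
                        arr.ind = TRUE)
      if (n_comp > 0 && nrow(pair_idx) > 0) {
        # weight pairs ~ 1/distance so the homotypic enrichment is even
        # across diagonals instead of piling into the rarely sampled
        # longest distances
        mid <- (blocks$start + blocks$end) / 2
        wts <- 1 / abs(mid[pair_idx[, 2]] - mid[pair_idx[, 1]])
        pk <- pair_idx[sample.int(nrow(pair_idx), n_comp, replace = TRUE,
                                  prob = wts), , drop = FALSE]
        b1 <- pk[, 1]; b2 <- pk[, 2]
        p1 <- blocks$start[b1] + runif(n_comp) *
          (blocks$end[b1] - blocks$start[b1])
        p2 <- blocks$start[b2] + runif(n_comp) *
          (blocks$end[b2] - blocks$start[b2])
        pieces$comp <- data.table::data.table(pos1 = pmin(p1, p2),
                                              pos2 = pmax(p1, p2))
      } else n_comp <- 0L
      n_bgl <- n_long - n_comp
      if (n_bgl > 0 && L > LONG_MIN + 1e4) {
        d <- exp(runif(n_bgl, log(LONG_MIN), log(L - 1e4)))
        p1 <- runif(n_bgl) * (L - d)
        pieces$long <- data.table::data.table(pos1 = p1, pos2 = p1 + d)
      }
    }
    out <- data.table::rbindlist(pieces)
    out$pos1 <- pmax(1L, pmin(as.integer(floor(out$pos1)) + 1L, as.integer(L)))
    out$pos2 <- pmax(1L, pmin(as.integer(floor(out$pos2)) + 1L, as.integer(L)))
    sw <- out$pos1 > out$pos2
    if (any(sw)) {
      tmp <- out$pos1[sw]; out$pos1[sw] <- out$pos2[sw]; out$pos2[sw] <- tmp
    }
    data.table::data.table(chrom = params$chrom, pos1 = out$pos1,
                           pos2 = out$pos2)
  })
}

# cohort-level per-10-kb-bin mCG baseline, drawn once from the master seed
mcg_baseline <- function(config) {
  n <- as.integer(ceiling(config$genome$length / 1e4))
  with_seed(derive_seed(config$seed, 101L),
            clip(rnorm(n, config$methylome$mcg_global,
                       config$methylome$baseline_sd), 0.05, 0.95))
}

#' Simulate one cell's methylome (allc table)
#'
#' Per 10-kb bin, the CG coverage follows the configured coverage law and
#' the methylated count is binomial with success probability equal to the
#' bin's baseline mCG, lowered at planted loop-anchor bins by a logistic
#' decrease of amplitude `anchor_amp` whose midpoint sits `lag_delta`
#' pseudotime units after the loop onset. CH and CCC contexts are emitted
#' at their configured global levels.
#'
#' @param params per-type parameter bundle.
#' @param baseline per-bin mCG baseline (see `mcg_baseline`).
#' @param pseudotime the cell's pseudotime.
#' @param seed RNG seed.
#' @return an allc `data.table`.
#' @export
simulate_methylome_for_cell <- function(params, baseline, pseudotime,
                                        seed = NULL) {
  me <- params$methylome
  L <- params$L
  nb <- length(baseline)
  m <- baseline
  lp <- params$loops
  if (nrow(lp)) {
    anchors <- unique(c(lp$bin1, lp$bin2)) + 1L
    onset <- c(lp$onset, lp$onset)[match(anchors - 1L, c(lp$bin1, lp$bin2))]
    drop_ <- me$anchor_amp *
      stats::plogis((pseudotime - (onset + me$lag_delta)) / me$tau)
    m[anchors] <- clip(m[anchors] - drop_, 0.01, 0.99)
  }
  with_seed(seed, {
    cov_tot <- switch(me$coverage$dist,
                      constant = rep(as.integer(me$coverage$value), nb),
                      poisson = rpois(nb, me$coverage$mean),
                      stop("unknown coverage law"))
    mc_tot <- rbinom(nb, cov_tot, m)
    cov1 <- cov_tot %/% 2L
    mc1 <- rhyper(nb, mc_tot, cov_tot - mc_tot, cov1)
    starts <- (seq_len(nb) - 1L) * 1e4
    ch_cov <- rpois(2L * nb, 5)
    ch_mc <- rbinom(2L * nb, ch_cov, me$mch_global)
    ccc_cov <- rpois(nb, 4)
    ccc_mc <- rbinom(nb, ccc_cov, me$mccc_global)
    allc <- data.table::data.table(
      chrom = params$chrom,
      pos = c(starts + 2500L, starts + 7500L, starts + 1250L,
              starts + 8750L, starts + 5000L),
      strand = rep(c("+", "-", "+", "-", "+"), each = nb),
      context = rep(c("CGA", "CGT", "CAT", "CCT", "CCC"), each = nb),
      mc = c(mc1, mc_tot - mc1, ch_mc[seq_len(nb)],
             ch_mc[nb + seq_len(nb)], ccc_mc),
      cov = c(cov1, cov_tot - cov1, ch_cov[seq_len(nb)],
              ch_cov[nb + seq_len(nb)], ccc_cov))
    allc <- allc[allc$cov > 0 & allc$pos <= L, ]
    data.table::setkeyv(allc, c("chrom", "pos"))
    allc[]
  })
}

# annotation tables: genes, GC track, DMRs, SNPs, motif hits
simulate_annotations <- function(config) {
  L <- config$genome$length
  chrom <- config$genome$chrom
  lp <- config$planted_loops
  with_seed(derive_seed(config$seed, 202L), {
    n_genes <- config$n_genes
    glen <- round(exp(runif(n_genes, log(2e4), log(3e5))))
    gstart <- floor(runif(n_genes) * pmax(L - glen - 1, 1))
    genes <- data.table::data.table(
      chrom = chrom, start = as.integer(gstart),
      end = as.integer(gstart + glen),
      name = sprintf("g%03d", seq_len(n_genes)), score = 0L,
      strand = sample(c("+", "-"), n_genes, replace = TRUE))
    genes <- genes[order(genes$start), ]
    genes$name <- sprintf("g%03d", seq_len(n_genes))

    part <- compartment_partition(config$seed, L,
                                  config$compartment_blocks$block_size)
    signs <- compartment_signs(part, L)
    gc <- ifelse(signs > 0, config$compartment_blocks$gc_high,
                 config$compartment_blocks$gc_low) +
      rnorm(length(signs), 0, 0.004)

    # DMRs: one per loop anchor with fold > 1 in the type, plus background
    dmr_list <- list()
    for (tn in config$cell_types$name) {
      fold <- lp[[paste0("fold_", tn)]]
      abin <- unique(c(lp$bin1[fold > 1], lp$bin2[fold > 1]))
      if (length(abin)) {
        ctr <- abin * 1e4 + 5e3
        dmr_list[[length(dmr_list) + 1L]] <- data.table::data.table(
          chrom = chrom, start = as.integer(ctr - 500L),
          end = as.integer(ctr + 500L), cell_type = tn, at_anchor = TRUE)
      }
      nbg <- max(10L, length(abin))
      bs <- as.integer(floor(runif(nbg) * (L - 2000L)))
      dmr_list[[length(dmr_list) + 1L]] <- data.table::data.table(
        chrom = chrom, start = bs, end = bs + 1000L, cell_type = tn,
        at_anchor = FALSE)
    }
    dmrs <- data.table::rbindlist(dmr_list)

    # fine-mapped SNPs: some loci planted inside anchor DMRs
    n_loci <- 25L
    snps_per_locus <- pmax(1L, rpois(n_loci, 2))
    anchor_dmrs <- dmrs[dmrs$at_anchor & dmrs$cell_type ==
                          config$cell_types$name[1], ]
    planted_locus <- seq_len(n_loci) %% 3L == 0L & nrow(anchor_dmrs) > 0
    rows <- list()
    for (lc in seq_len(n_loci)) {
      k <- snps_per_locus[lc]
      pos <- as.integer(floor(runif(k) * (L - 2L))) + 1L
      if (planted_locus[lc]) {
        ad <- anchor_dmrs[sample.int(nrow(anchor_dmrs), 1L), ]
        pos[1] <- as.integer(ad$start + floor(runif(1) * (ad$end - ad$start))) + 1L
      }
      rows[[lc]] <- data.table::data.table(
        chrom = chrom, pos = pos, locus = sprintf("locus%02d", lc),
        snp = sprintf("rs%02d_%d", lc, seq_len(k)),
        pip = runif(k, 0.11, 0.9))
    }
    snps <- data.table::rbindlist(rows)
    background_snps <- data.table::data.table(
      chrom = chrom, pos = as.integer(floor(runif(20000L) * (L - 2L))) + 1L)

    # motif hits: half planted inside the first type's DMRs
    n_mot <- 300L
    ms <- as.integer(floor(runif(n_mot) * (L - 12L)))
    t1 <- dmrs[dmrs$cell_type == config$cell_types$name[1], ]
    n_pl <- min(150L, nrow(t1))
    pick <- t1[sample.int(nrow(t1), n_pl, replace = TRUE), ]
    ms[seq_len(n_pl)] <- as.integer(pick$start +
                                      floor(runif(n_pl) * (pick$end - pick$start - 10L)))
    motifs <- data.table::data.table(chrom = chrom, start = ms, end = ms + 10L,
                                     name = "motifA")
    list(genes = genes, gc = gc, dmrs = dmrs, snps = snps,
         background_snps = background_snps, motifs = motifs)
  })
}

expected_conformation_class <- function(config, type_idx) {
  tp <- type_params(config, type_idx)
  n_exp <- exp(config$contacts_per_cell$meanlog +
                 config$contacts_per_cell$sdlog^2 / 2)
  lam_bg <- n_exp * tp$pi_short * (1 - tp$w_domain)
  folds <- loop_fold_at(tp$loops$fold, tp$loops$onset, tp$pt_center, tp$tau)
  lam <- (folds - 1) * tp$catchment *
    expected_short_pixel_rate(lam_bg, (tp$loops$bin2 - tp$loops$bin1) * 1e4,
                              tp$L)
  loop_frac <- sum(pmax(lam, 0)) / n_exp
  p_short <- loop_frac + (1 - loop_frac) * tp$pi_short
  classify_ratio(log2(p_short / (1 - p_short)))
}

#' Simulate a full synthetic cohort
#'
#' @param config a `sim_config`.
#' @return list with `cells` (named list of contact tables), `allc` (named
#'   list of allc tables), `annotations` (genes, gc, dmrs, snps,
#'   background_snps, motifs), `truth` (the ledger: per-cell table, planted
#'   loops/boundaries, compartment signs and amplitudes, lag_delta) and the
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  baseline <- mcg_baseline(config)
  cells <- list(); allc <- list()
  cell_rows <- list()
  cell_idx <- 0L
  for (t in seq_len(nrow(config$cell_types))) {
    tp <- type_params(config, t)
    ct <- config$cell_types[t, ]
    pts <- with_seed(derive_seed(config$seed, 300L + t),
                     clip(runif(ct$n_cells, ct$pseudotime_center - ct$pseudotime_spread,
                                ct$pseudotime_center + ct$pseudotime_spread), 0, 1))
    ns <- with_seed(derive_seed(config$seed, 400L + t),
                    pmax(1000L, as.integer(round(rlnorm(ct$n_cells,
                                                        config$contacts_per_cell$meanlog,
                                                        config$contacts_per_cell$sdlog)))))
    for (i in seq_len(ct$n_cells)) {
      cell_idx <- cell_idx + 1L
      id <- sprintf("%s_c%04d", ct$name, i)
      cc <- simulate_contacts_for_cell(tp, ns[i], pts[i],
                                       seed = derive_seed(config$seed, 1000L + cell_idx))
      cc <- data.table::data.table(cell_id = id, cc)
      cells[[id]] <- cc
      allc[[id]] <- simulate_methylome_for_cell(tp, baseline, pts[i],
                                                seed = derive_seed(config$seed, 50000L + cell_idx))
      cell_rows[[cell_idx]] <- data.table::data.table(
        cell_id = id, cell_type = ct$name, pseudotime = pts[i],
        n_contacts = nrow(cc),
        conformation_class = expected_conformation_class(config, t))
    }
  }
  anns <- simulate_annotations(config)
  truth <- list(
    cells = data.table::rbindlist(cell_rows),
    loops = data.table::as.data.table(config$planted_loops),
    boundaries = data.table::as.data.table(config$planted_boundaries),
    compartment_partition = compartment_partition(
      config$seed, config$genome$length,
      config$compartment_blocks$block_size),
    compartment_signs = compartment_signs(
      compartment_partition(config$seed, config$genome$length,
                            config$compartment_blocks$block_size),
      config$genome$length),
    compartment_amplitude = setNames(config$cell_types$comp_amplitude,
                                     config$cell_types$name),
    mcg_baseline = baseline,
    lag_delta = config$methylome$lag_delta)
  list(cells = cells, allc = allc, annotations = anns, truth = truth,
       config = config)
}

#' QC metrics table of a simulated cohort
#'
#' Computes per-cell global mCG/mCH/mCCC fractions from the allc tables and
#' counts cis contacts, in the shape expected by [cell_qc()].
#'
#' @param cohort output of [simulate_cohort()].
#' @return `data.table` with cell_id, mccc_level, global_mcg, global_mch,
#'   n_contacts.
#' @export
cohort_qc_table <- function(cohort) {
  rows <- lapply(names(cohort$allc), function(id) {
    a <- cohort$allc[[id]]
    cg <- context_class(a$context, "CG")
    ch <- context_class(a$context, "CH")
    ccc <- context_class(a$context, "CCC")
    data.table::data.table(
      cell_id = id,
      mccc_level = sum(a$mc[ccc]) / max(sum(a$cov[ccc]), 1),
      global_mcg = sum(a$mc[cg]) / max(sum(a$cov[cg]), 1),
      global_mch = sum(a$mc[ch]) / max(sum(a$cov[ch]), 1),
      n_contacts = nrow(cohort$cells[[id]]))
  })
  data.table::rbindlist(rows)
}

#' Write a cohort to disk (TSV/BED/JSON)
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contacts(data.table::rbindlist(cohort$cells),
                 file.path(dir, "contacts.tsv"))
  adir <- file.path(dir, "allc")
  dir.create(adir, showWarnings = FALSE)
  for (id in names(cohort$allc))
    write_allc(cohort$allc[[id]], file.path(adir, paste0(id, ".tsv")))
  write_intervals(cohort$annotations$genes, file.path(dir, "genes.bed"))
  dmr_out <- data.table::data.table(
    chrom = cohort$annotations$dmrs$chrom,
    start = cohort$annotations$dmrs$start,
    end = cohort$annotations$dmrs$end,
    name = cohort$annotations$dmrs$cell_type)
  write_intervals(dmr_out, file.path(dir, "dmrs.bed"))
  write_intervals(cohort$annotations$motifs, file.path(dir, "motifs.bed"))
  data.table::fwrite(cohort$annotations$snps, file.path(dir, "snps.tsv"),
                     sep = "\t")
  data.table::fwrite(data.table::data.table(gc = cohort$annotations$gc),
                     file.path(dir, "gc_1mb.tsv"), sep = "\t")
  truth <- cohort$truth
  truth$cells <- as.data.frame(truth$cells)
  truth$loops <- as.data.frame(truth$loops)
  truth$boundaries <- as.data.frame(truth$boundaries)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
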