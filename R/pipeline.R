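# End-to-end orchestration of the analysis stages on a (simulated or
# loaded) cohort, plus the command-line entry point.

#' Run the full analysis pipeline on a cohort
#'
#' Stages: per-cell QC; contact-distance metrics and conformation clusters;
#' per-group pseudobulk loop calling with shuffled-background FDR;
#' summary-statistic differential loops; SIPs; per-cell domain boundaries
#' and differential boundaries; compartment eigenvectors, saddle strength
#' and transition methylation; SVD embedding; meta-cell loop-vs-mCG
#' cross-correlation; regulatory overlap statistics.
#'
#' The meta-cell stage needs per-cell imputed values at loop pixels; to
#' keep one pass over the cells, a pixel panel is pre-ranked by raw
#' pseudobulk O/E enrichment (no planted truth is consulted) and per-cell Q
#' is recorded on that panel.
#'
#' @param cohort output of [simulate_cohort()].
#' @param seed seed driving the diagonal shuffles and any other randomness.
#' @param stages character vector of stages to run.
#' @param impute_method passed to [impute()].
#' @param panel_size loop-pixel panel size for the meta-cell stage.
#' @param metacell_k meta-cell size.
#' @param verbose print stage progress.
#' @return named list of per-stage results.
#' @export
analyze_cohort <- function(cohort,
                           seed = 1L,
                           stages = c("qc", "distance", "loops",
                                      "differential", "sips", "domains",
                                      "compartments", "embedding",
                                      "methylome", "metacells", "overlap"),
                           impute_method = "exact",
                           panel_size = 200L,
                           metacell_k = 20L,
                           verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  L <- cohort$config$genome$length
  chrom <- cohort$config$genome$chrom
  types <- cohort$config$cell_types$name
  cell_meta <- cohort$truth$cells
  ids <- cell_meta$cell_id
  grp <- setNames(cell_meta$cell_type, ids)
  res <- list()

  if ("qc" %in% stages) {
    say("stage: qc")
    res$qc <- cell_qc(cohort_qc_table(cohort))
  }
  if ("distance" %in% stages) {
    say("stage: distance")
    res$distance <- distance_metrics_table(cohort$cells,
                                           k = min(10L, length(ids)))
  }

  heavy <- intersect(stages, c("loops", "differential", "sips", "domains",
                               "compartments", "embedding", "methylome",
                               "metacells"))
  if (length(heavy)) {
    n10 <- as.integer(ceiling(L / 1e4))
    d10 <- as.integer(5.05e6 / 1e4)
    # pixel panel from raw pooled counts (meta-cell stage support)
    panel <- NULL
    if ("metacells" %in% stages) {
      say("stage: pixel panel")
      raw10 <- matrix(0, min(d10, n10 - 1L) + 1L, n10)
      for (id in ids) {
        cc <- cohort$cells[[id]]
        i <- pos_to_bin(cc$pos1, 1e4); j <- pos_to_bin(cc$pos2, 1e4)
        d <- abs(j - i); b <- pmin(i, j)
        keep <- d <= min(d10, n10 - 1L) & b + d < n10
        dt <- data.table::data.table(d = d[keep], b = b[keep])
        agg <- dt[, .N, by = c("d", "b")]
        raw10[cbind(agg$d + 1L, agg$b + 1L)] <-
          raw10[cbind(agg$d + 1L, agg$b + 1L)] + agg$N
      }
      rb <- band_matrix(raw10, 1e4, chrom)
      oeb <- oe_normalize(rb)
      cand <- data.table::rbindlist(lapply(5:min(500L, rb$max_offset),
                                           function(d) {
        i <- seq_len(n10 - d)
        data.table::data.table(bin1 = i - 1L, bin2 = i - 1L + d,
                               oe = oeb$mat[d + 1L, i],
                               n = rb$mat[d + 1L, i])
      }))
      cand <- cand[is.finite(cand$oe) & cand$n >= 5, ]
      cand <- cand[order(-cand$oe), ]
      panel <- head(cand, panel_size)[, c("bin1", "bin2")]
    }

    say("stage: per-cell matrices (%d cells)", length(ids))
    accs <- list(); accs_sh <- list(); acc25 <- list(); acc1m <- list()
    n1m <- as.integer(ceiling(L / 1e6))
    bounds <- list(); feats100 <- list(); cgs <- list()
    qpanel <- if (!is.null(panel))
      matrix(NA_real_, length(ids), nrow(panel), dimnames = list(ids, NULL))
    genes <- cohort$annotations$genes
    ci <- 0L
    for (id in ids) {
      ci <- ci + 1L
      g <- grp[[id]]
      cc <- cohort$cells[[id]]
      M10 <- contacts_to_matrix(cc, L, 1e4)
      tr <- cell_matrix_triplet(M10, 1e4, pad = 2L, max_distance = 5.05e6,
                                method = impute_method, chrom = chrom,
                                shuffle_seed = derive_seed(seed, 7000L + ci))
      accs[[g]] <- pseudobulk_accumulate(accs[[g]], tr)
      accs_sh[[g]] <- pseudobulk_accumulate(
        accs_sh[[g]], list(Q = tr$Q, E = tr$Es, T = tr$Ts))
      if (!is.null(panel))
        qpanel[id, ] <- band_values(tr$Q, panel$bin1, panel$bin2)
      if ("methylome" %in% stages)
        cgs[[id]] <- gene_3cgs_matrix(setNames(list(tr$Q), id), genes)[1, ]
      if ("domains" %in% stages) {
        M25 <- contacts_to_matrix(cc, L, 2.5e4)
        Q25 <- impute(M25, 2.5e4, pad = 2L, max_distance = 10.05e6,
                      method = impute_method, chrom = chrom)
        bounds[[id]] <- percell_boundaries(Q25)
        if (is.null(acc25[[g]]))
          acc25[[g]] <- list(sum = Q25$mat * 0, n = 0L, tpl = Q25)
        acc25[[g]]$sum <- acc25[[g]]$sum + Q25$mat
        acc25[[g]]$n <- acc25[[g]]$n + 1L
      }
      if (any(c("embedding", "metacells") %in% stages)) {
        M100 <- contacts_to_matrix(cc, L, 1e5)
        Q100 <- impute(M100, 1e5, pad = 1L,
                       max_distance = min(1e6, (nrow(M100) - 1L) * 1e5),
                       method = impute_method)
        feats100[[id]] <- Q100
      }
      if ("compartments" %in% stages) {
        if (is.null(acc1m[[g]])) acc1m[[g]] <- matrix(0, n1m, n1m)
        acc1m[[g]] <- acc1m[[g]] + contacts_to_matrix(cc, L, 1e6)
      }
    }
    pb <- lapply(accs, pseudobulk_finalize)
    pb_sh <- lapply(accs_sh, pseudobulk_finalize)

    if ("loops" %in% stages) {
      say("stage: loops")
      res$loops <- lapply(setNames(types, types), function(g) {
        calls <- call_loops(pb[[g]], pb_sh[[g]])
        summits <- merge_loop_calls(calls)
        list(calls = calls, summits = summits)
      })
    }
    if ("differential" %in% stages && length(types) >= 2L) {
      say("stage: differential loops")
      pix <- unique(data.table::rbindlist(lapply(types, function(g)
        res$loops[[g]]$summits[, c("bin1", "bin2")])))
      if (nrow(pix) >= 2L) {
        F_Q <- anova_from_summaries(pb, "Q", pix)
        F_T <- anova_from_summaries(pb, "T", pix)
        sel <- select_differential(F_Q, F_T)
        strengths <- vapply(types, function(g)
          band_values(pb[[g]]$E, pix$bin1, pix$bin2), numeric(nrow(pix)))
        res$differential <- data.table::data.table(
          chrom = chrom, pix, F_Q = F_Q, F_T = F_T, sel,
          matrix(strengths, nrow = nrow(pix),
                 dimnames = list(NULL, paste0("E_", types))))
      }
    }
    promoters <- {
      gt <- gene_tss_tes(genes)
      data.table::data.table(gene = gt$name, chrom = gt$chrom, tss = gt$tss)
    }
    if ("sips" %in% stages && !is.null(res$loops)) {
      say("stage: sips")
      res$sips <- lapply(setNames(types, types), function(g) {
        s <- res$loops[[g]]$summits
        if (!nrow(s)) return(NULL)
        lp <- data.table::data.table(chrom = s$chrom, bin1 = s$bin1,
                                     bin2 = s$bin2, strength = s$E_mean)
        sc <- cumulative_loop_score(lp, promoters)
        tryCatch(call_sips(sc), error = function(e) sc)
      })
      if (!is.null(res$differential) && any(res$differential$is_differential)) {
        dl <- res$differential[res$differential$is_differential, ]
        res$sip_trajectories <- cumulative_differential_score(
          dl, as.matrix(dl[, paste0("E_", types), with = FALSE]), promoters)
      }
    }
    if ("domains" %in% stages) {
      say("stage: domains")
      calls <- do.call(rbind, bounds)
      ins <- do.call(rbind, lapply(types, function(g) {
        a <- acc25[[g]]
        insulation_score(band_matrix(a$sum / a$n, 2.5e4, chrom))
      }))
      rownames(ins) <- types
      bp <- boundary_probability(calls, grp[rownames(calls)])
      res$domains <- list(
        calls = calls, boundary_probability = bp, insulation = ins,
        differential = differential_boundaries(calls, grp[rownames(calls)],
                                               ins))
    }
    if ("compartments" %in% stages) {
      say("stage: compartments")
      gc <- cohort$annotations$gc
      res$compartments <- tryCatch({
        evs <- lapply(setNames(types, types), function(g)
          compartment_eigenvector(acc1m[[g]], gc))
        saddles <- lapply(setNames(types, types), function(g)
          saddle_stats(oe_matrix(acc1m[[g]]), evs[[g]],
                       n_contacts = sum(acc1m[[g]]) / 2))
        trans <- compartment_transitions(evs[[1]], evs[[length(evs)]])
        bc1m <- allc_bin_counts(cohort$allc, 1e6, n1m)
        mcg1m <- vapply(types, function(g) {
          sel <- grp[rownames(bc1m$mc)] == g
          mc <- colSums(bc1m$mc[sel, , drop = FALSE])
          cv <- colSums(bc1m$cov[sel, , drop = FALSE])
          ifelse(cv > 0, mc / cv, NA_real_)
        }, numeric(n1m))
        list(eigenvectors = evs, saddles = saddles, transitions = trans,
             transition_methylation = tryCatch(
               transition_methylation(trans, mcg1m), error = function(e) NULL))
      }, error = function(e) {
        say("compartments skipped: %s", conditionMessage(e))
        NULL
      })
    }
    if (any(c("embedding", "metacells") %in% stages)) {
      say("stage: embedding")
      res$embedding <- embed_cells(feats100, dims = min(10L, length(ids)))
    }
    if ("methylome" %in% stages) {
      say("stage: methylome features")
      n100 <- as.integer(ceiling(L / 1e5))
      bc100 <- allc_bin_counts(cohort$allc, 1e5, n100)
      fm_bins <- list(fractions = ifelse(bc100$cov > 0, bc100$mc / bc100$cov,
                                         NA_real_),
                      coverage = bc100$cov)
      gene_regions <- expand_regions(genes, 2e3, L)
      fm_genes <- region_counts_fast(cohort$allc, gene_regions)
      colnames(fm_genes$fractions) <- colnames(fm_genes$coverage) <- genes$name
      samples <- grp[names(cohort$allc)]
      res$methylome <- list(
        bins = filter_impute_features(fm_bins$fractions, fm_bins$coverage,
                                      samples),
        genes = filter_impute_features(fm_genes$fractions, fm_genes$coverage,
                                       samples),
        gene_3cgs = do.call(rbind, cgs))
      res$methylome$cgs_mcg_cor <- feature_correlations(
        res$methylome$gene_3cgs, fm_genes$fractions)
    }
    if ("metacells" %in% stages && !is.null(panel) && nrow(panel) &&
        length(ids) >= metacell_k) {
      say("stage: metacells")
      mcset <- deduplicate_metacells(build_metacells(res$embedding,
                                                     k = metacell_k))
      bc10 <- allc_bin_counts(cohort$allc, 1e4, n10)
      pt <- setNames(cell_meta$pseudotime, ids)
      prof <- metacell_profiles(mcset, bc10$mc, bc10$cov, qpanel, pt)
      # correlate on the differential loops present in the panel (fall back
      # to the whole panel when no differential call is available)
      use <- seq_len(nrow(panel))
      if (!is.null(res$differential)) {
        key <- paste(panel$bin1, panel$bin2)
        dkey <- paste(res$differential$bin1,
                      res$differential$bin2)[res$differential$is_differential]
        hit <- which(key %in% dkey)
        if (length(hit) >= 3L) use <- hit
      }
      n_meta <- nrow(prof$loops)
      max_shift <- min(5L, as.integer((n_meta - 10L) / 2))
      res$metacells <- list(metacells = mcset, profiles = prof,
                            panel = panel, panel_used = use)
      if (max_shift >= 1L) {
        prof_use <- list(mcg = prof$mcg,
                         loops = prof$loops[, use, drop = FALSE],
                         pseudotime = prof$pseudotime)
        res$metacells$crosscorr <- loop_methylation_crosscorr(
          prof_use, as.matrix(panel[use, c("bin1", "bin2")]),
          max_shift = max_shift)
      }
    }
  }
  if ("overlap" %in% stages && !is.null(res$loops)) {
    say("stage: regulatory overlap")
    summits <- data.table::rbindlist(lapply(types, function(g) {
      s <- res$loops[[g]]$summits
      if (!nrow(s)) return(NULL)
      data.table::data.table(chrom = s$chrom, bin1 = s$bin1, bin2 = s$bin2,
                             cell_type = g)
    }), use.names = TRUE)
    dmrs <- cohort$annotations$dmrs
    lc <- if (nrow(summits)) loop_connected_dmrs(dmrs, summits) else dmrs[0, ]
    t1 <- types[1]
    res$overlap <- list(
      loop_connected_dmrs = lc,
      motif = motif_enrichment(dmrs[dmrs$cell_type == t1, ], dmrs,
                               cohort$annotations$motifs))
    if (nrow(lc)) {
      annot <- lc[, c("chrom", "start", "end"), with = FALSE]
      res$overlap$finemap <- finemap_overlap(cohort$annotations$snps, annot,
                                             cohort$annotations$background_snps)
      gt <- gene_tss_tes(cohort$annotations$genes)
      res$overlap$snp_genes <- link_snp_to_genes(
        cohort$annotations$snps, dmrs[dmrs$cell_type == t1, ],
        summits[summits$cell_type == t1, ],
        data.table::data.table(gene = gt$name, chrom = gt$chrom, tss = gt$tss))
    }
  }
  res
}

#' Command-line entry point
#'
#' `sc3dmulti simulate --config cfg.json --seed S --out DIR` writes a
#' simulated cohort; `sc3dmulti <stage> --in DIR --seed S --out DIR2` loads
#' it back and runs the requested stage(s) (`all` runs everything),
#' writing a JSON summary.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
sc3d_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sc3dmulti <simulate|distance|loops|domains|compartments|",
    "methylome|metacells|overlap|all> [--config cfg.json] [--in dir]",
    "[--seed int] [--out path]")
  if (!length(argv)) { message(usage); return(invisible(1L)) }
  cmd <- argv[1]
  opt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) && i < length(argv)) argv[i + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "sc3d_out")
  if (cmd == "simulate") {
    cfg_path <- opt("--config")
    args <- if (!is.null(cfg_path)) {
      js <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
      lapply(js, function(x) if (is.list(x) && !is.data.frame(x)) x else x)
    } else list()
    args$seed <- seed
    cfg <- do.call(sim_config, args)
    write_cohort(simulate_cohort(cfg), out)
    message("cohort written to ", out)
    return(invisible(0L))
  }
  indir <- opt("--in")
  stop_if_not(!is.null(indir), "missing --in <cohort dir>")
  cohort <- read_cohort(indir)
  stage_map <- list(distance = "distance",
                    loops = c("loops", "differential", "sips"),
                    domains = "domains", compartments = "compartments",
                    methylome = c("qc", "methylome"),
                    metacells = c("loops", "differential", "embedding",
                                  "metacells"),
                    overlap = c("loops", "overlap"))
  stages <- if (cmd == "all") eval(formals(analyze_cohort)$stages)
  else stage_map[[cmd]]
  stop_if_not(!is.null(stages), usage)
  resl <- analyze_cohort(cohort, seed = seed, stages = stages)
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(summarize_results(resl), out, auto_unbox = TRUE,
                       digits = NA, force = TRUE, na = "null")
  message("results written to ", out)
  invisible(0L)
}

#' Reload a cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @return a cohort list (cells, allc, annotations, truth, config).
#' @export
read_cohort <- function(dir) {
  contacts <- read_contacts(file.path(dir, "contacts.tsv"))
  cells <- split(contacts, contacts$cell_id)
  allc_files <- list.files(file.path(dir, "allc"), full.names = TRUE)
  allc <- lapply(allc_files, read_allc)
  names(allc) <- sub("\\.tsv$", "", basename(allc_files))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$cells <- data.table::as.data.table(truth$cells)
  truth$loops <- data.table::as.data.table(truth$loops)
  truth$boundaries <- data.table::as.data.table(truth$boundaries)
  genes <- read_intervals(file.path(dir, "genes.bed"))
  dmrs <- read_intervals(file.path(dir, "dmrs.bed"))
  data.table::setnames(dmrs, "name", "cell_type")
  types <- unique(truth$cells$cell_type)
  L <- max(vapply(cells, function(x) max(x$pos2), numeric(1)))
  ct <- truth$cells[, list(n_cells = .N), by = "cell_type"]
  config <- list(genome = data.frame(chrom = contacts$chrom[1],
                                     length = as.numeric(L)),
                 cell_types = data.frame(name = ct$cell_type,
                                         n_cells = ct$n_cells))
  list(cells = cells, allc = allc,
       annotations = list(
         genes = genes, dmrs = dmrs,
         motifs = read_intervals(file.path(dir, "motifs.bed")),
         snps = data.table::fread(file.path(dir, "snps.tsv")),
         background_snps = NULL,
         gc = data.table::fread(file.path(dir, "gc_1mb.tsv"))$gc),
       truth = truth, config = config)
}

# Pooled per-cell CG counts per fixed-width bin (one data.table pass over
# all cells; used by the compartment, methylome and meta-cell stages).
allc_bin_counts <- function(allc_list, resolution, n_bins) {
  ids <- names(allc_list)
  all <- data.table::rbindlist(allc_list, idcol = "cell")
  all <- all[startsWith(all$context, "CG"), ]
  all$bin <- pos_to_bin(all$pos, resolution)
  agg <- all[, list(mc = sum(mc), cov = sum(cov)), by = c("cell", "bin")]
  mc <- cv <- matrix(0, length(ids), n_bins, dimnames = list(ids, NULL))
  idx <- cbind(match(agg$cell, ids), agg$bin + 1L)
  mc[idx] <- agg$mc
  cv[idx] <- agg$cov
  list(mc = mc, cov = cv)
}

# Cell-by-region CG fractions where all cells share one site layout: the
# site-to-region overlap is computed once and reused.
region_counts_fast <- function(allc_list, regions) {
  ids <- names(allc_list)
  all <- data.table::rbindlist(allc_list, idcol = "cell")
  all <- all[startsWith(all$context, "CG"), ]
  sites <- unique(all$pos)
  gr_sites <- GenomicRanges::GRanges(regions$chrom[1],
                                     IRanges::IRanges(sites, sites))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_sites, intervals_to_granges(regions)))
  map <- data.table::data.table(pos = sites[S4Vectors::queryHits(hits)],
                                region = S4Vectors::subjectHits(hits))
  joined <- merge(all, map, by = "pos", allow.cartesian = TRUE)
  agg <- joined[, list(mc = sum(mc), cov = sum(cov)),
                by = c("cell", "region")]
  fr <- cv <- matrix(NA_real_, length(ids), nrow(regions),
                     dimnames = list(ids, NULL))
  cv[] <- 0
  idx <- cbind(match(agg$cell, ids), agg$region)
  fr[idx] <- agg$mc / agg$cov
  cv[idx] <- agg$cov
  list(fractions = fr, coverage = cv)
}

summarize_results <- function(res) {
  out <- list()
  if (!is.null(res$qc))
    out$qc <- list(n = nrow(res$qc), n_pass = sum(res$qc$pass))
  if (!is.null(res$distance))
    out$distance <- as.list(table(res$distance$class))
  if (!is.null(res$loops))
    out$loops <- lapply(res$loops, function(x)
      list(n_called = sum(x$calls$is_loop), n_summits = nrow(x$summits)))
  if (!is.null(res$differential))
    out$differential <- list(n_tested = nrow(res$differential),
                             n_differential = sum(res$differential$is_differential))
  if (!is.null(res$domains))
    out$domains <- list(n_peaks = sum(res$domains$differential$is_peak))
  if (!is.null(res$compartments))
    out$compartments <- lapply(res$compartments$saddles, function(s)
      list(strength = s$strength, AA_dominance = s$AA_dominance))
  if (!is.null(res$metacells))
    out$metacells <- list(n_metacells = length(res$metacells$metacells),
                          median_shift = res$metacells$crosscorr$median_shift)
  if (!is.null(res$overlap)) {
    out$overlap <- list(n_loop_connected_dmrs = nrow(res$overlap$loop_connected_dmrs),
                        motif_p = res$overlap$motif$p)
    if (!is.null(res$overlap$finemap))
      out$overlap$finemap_or <- res$overlap$finemap$odds_ratio
  }
  out
}
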