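#' Simulation studies: calibration, recovery, regional stability
#'
#' Multi-seed studies over the synthetic-cohort generator used to
#' characterize the pipeline's statistical behaviour: null calibration of
#' the site- and promoter-level tests, recovery of planted effects at every
#' level (sites, chromosomes, 1-Mbp blocks, promoters), and MB/MT regional
#' stability. These back the package's validation suite and the
#' reproducibility script.
#'
#' @name studies
#' @keywords internal
NULL

#' Null calibration of site- and promoter-level testing
#'
#' Simulates cohorts with no group effect (`delta = 0`, no blocks or
#' promoter shifts) and measures, per seed, the Kolmogorov-Smirnov distance
#' of the site p-values from uniform and the fractions of sites and
#' promoter windows flagged at FDR < `alpha`.
#'
#' @param config an `msre_sim_config`; its `delta`, `block_spec` and
#'   `promoter_spec` are overridden to the null.
#' @param seeds integer vector of seeds (one simulated cohort per seed).
#' @param alpha FDR level (default 0.05).
#' @return data frame, one row per seed: `ks_d`, `site_flagged_frac`,
#'   `promoter_flagged_frac`, `n_sites`, `n_promoters`.
#' @export
run_calibration <- function(config = sim_config(), seeds = 1:20, alpha = 0.05) {
  config$delta <- 0
  config$block_spec <- NULL
  config$promoter_spec <- NULL
  rows <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    cohort <- simulate_cohort(cfg, conditions = "MB")
    depth <- suppressMessages(common_sites(cohort$depth, min_depth = 1))
    scores <- normalize_depth(depth, cohort$design)
    res <- run_differential(scores, alpha = alpha)
    ks <- stats::ks.test(res$pvalue, "punif")$statistic
    windows <- build_windows(cohort$annotations$tss_table, cohort$catalog)
    keep <- vapply(windows$member_sites,
                   function(v) all(v %in% rownames(scores$scores)), logical(1))
    windows <- windows[keep, , drop = FALSE]
    loads <- promoter_loads(scores, windows)
    prom <- test_promoters(loads, scores$design, windows = windows, alpha = alpha)
    data.frame(seed = s, ks_d = unname(ks),
               site_flagged_frac = mean(res$significant),
               promoter_flagged_frac = mean(prom$significant),
               n_sites = nrow(res), n_promoters = nrow(prom))
  })
  do.call(rbind, rows)
}

#' Recovery of planted effects
#'
#' Simulates cohorts under the configured planted effects and measures, per
#' seed: site-level sensitivity (fraction of planted DM sites flagged) and
#' empirical FDR (flagged sites whose group methylation probabilities are
#' truly equal), whether each enriched chromosome is flagged by the Fisher
#' test, the fraction of planted 1-Mbp blocks flagged with the correct
#' sign, and promoter-level sensitivity.
#'
#' @param config an `msre_sim_config` with planted effects.
#' @param seeds integer vector of seeds.
#' @param alpha FDR level (default 0.05).
#' @return data frame, one row per seed: `sensitivity`, `empirical_fdr`,
#'   `enriched_detected` (all planted enriched chromosomes flagged),
#'   `block_correct_frac`, `promoter_sensitivity`.
#' @export
run_recovery <- function(config = sim_config(), seeds = 1:20, alpha = 0.05) {
  rows <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    cohort <- simulate_cohort(cfg, conditions = "MB")
    truth <- cohort$truth
    depth <- suppressMessages(common_sites(cohort$depth, min_depth = 1))
    scores <- normalize_depth(depth, cohort$design)
    res <- run_differential(scores, alpha = alpha)
    tr <- truth[match(res$site_id, truth$site_id), ]
    planted <- res$site_id %in% attr(truth, "dm_sites")
    flagged <- res$significant
    sens <- if (any(planted)) mean(flagged[planted]) else NA_real_
    efdr <- if (any(flagged)) mean(!tr$dm_flag[flagged]) else 0
    enr <- chromosome_enrichment(res, alpha = alpha)
    enr_ok <- all(cfg$enriched_chroms %in% enr$chrom[enr$enriched])
    bins <- flag_bins(bin_logfc(res))
    blocks <- attr(truth, "blocks")
    block_ok <- NA_real_
    if (!is.null(blocks) && nrow(blocks) > 0) {
      ok <- vapply(seq_len(nrow(blocks)), function(i) {
        bi <- floor((blocks$start[i] - 1) / 1e6)
        row <- bins[bins$chrom == blocks$chrom[i] & bins$bin_index == bi, ]
        nrow(row) == 1 &&
          row$flag == (if (blocks$effect[i] > 0) "hyper" else "hypo")
      }, logical(1))
      block_ok <- mean(ok)
    }
    windows <- build_windows(cohort$annotations$tss_table, cohort$catalog)
    keep <- vapply(windows$member_sites,
                   function(v) all(v %in% rownames(scores$scores)), logical(1))
    windows <- windows[keep, , drop = FALSE]
    loads <- promoter_loads(scores, windows)
    prom <- test_promoters(loads, scores$design, windows = windows, alpha = alpha)
    planted_prom <- attr(truth, "promoters")
    prom_sens <- NA_real_
    if (!is.null(planted_prom) && nrow(planted_prom) > 0) {
      key_p <- paste(planted_prom$chrom, planted_prom$tss_pos)
      m <- match(prom$gene_id, windows$gene_id)
      key_w <- paste(windows$chrom[m], windows$tss_pos[m])
      hit <- prom$significant[key_w %in% key_p]
      prom_sens <- if (length(hit)) mean(hit) else NA_real_
    }
    data.frame(seed = s, sensitivity = sens, empirical_fdr = efdr,
               enriched_detected = enr_ok, block_correct_frac = block_ok,
               promoter_sensitivity = prom_sens)
  })
  do.call(rbind, rows)
}

#' Regional stability between cell conditions
#'
#' Simulates MB and MT from one shared ground truth (independent coverage
#' noise) and measures the Pearson correlation of their 1-Mbp binned
#' methylation-load logFCs.
#'
#' @param config an `msre_sim_config`.
#' @param seeds integer vector of seeds.
#' @return data frame, one row per seed: `bin_r`, `n_shared`.
#' @export
run_stability <- function(config = sim_config(), seeds = 1:20) {
  rows <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    cohort <- simulate_cohort(cfg, conditions = c("MB", "MT"))
    depth <- suppressMessages(common_sites(cohort$depth, min_depth = 1))
    scores <- normalize_depth(depth, cohort$design)
    bins <- lapply(c("MB", "MT"), function(cc) {
      bin_logfc(run_differential(subset_condition(scores, cc)))
    })
    r <- bin_correlation(bins[[1]], bins[[2]])
    data.frame(seed = s, bin_r = r$r, n_shared = r$n_shared)
  })
  do.call(rbind, rows)
}
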