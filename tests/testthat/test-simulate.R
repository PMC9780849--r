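small_cfg <- function(...) {
  defaults <- list(chrom_spec = data.frame(name = c("chr1", "chr12"),
                                           length = c(7.5e6, 2.5e6)),
                   site_density = 1, block_spec = NULL, promoter_spec = NULL)
  dots <- list(...)
  for (nm in names(dots)) defaults[nm] <- dots[nm]
  do.call(sim_config, defaults)
}

test_that("null configuration plants no group difference", {
  cfg <- small_cfg(delta = 0, seed = 5)
  catalog <- random_site_catalog(cfg)
  truth <- simulate_truth(cfg, catalog)
  expect_false(any(truth$dm_flag))
  expect_identical(truth$theta_cp, truth$theta_control)
  expect_true(all(truth$planted_logfc == 0))
})

test_that("DM allocation is exact-count and errors when none plantable", {
  cfg <- small_cfg(frac_dm = 0.02, seed = 9)
  catalog <- random_site_catalog(cfg)
  truth <- simulate_truth(cfg, catalog)
  expect_identical(length(attr(truth, "dm_sites")),
                   as.integer(floor(0.02 * nrow(catalog))))
  expect_identical(sum(truth$dm_flag), length(attr(truth, "dm_sites")))

  tiny <- make_catalog("chr1", c(100, 200))
  cfg2 <- small_cfg(frac_dm = 0.01)
  expect_error(simulate_truth(cfg2, tiny), "no DM sites plantable")
})

test_that("enriched chromosomes receive the configured DM density multiple", {
  ratios <- vapply(1:20, function(s) {
    cfg <- small_cfg(frac_dm = 0.02, enriched_chroms = "chr12",
                     enrich_multiple = 4, seed = s)
    catalog <- random_site_catalog(cfg)
    truth <- simulate_truth(cfg, catalog)
    dm <- truth$dm_flag
    on_enr <- truth$chrom == "chr12"
    (mean(dm[on_enr]) / mean(dm[!on_enr]))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4), 0.5)
})

test_that("theta and sign structure of planted effects is on the logit scale", {
  cfg <- small_cfg(frac_dm = 0.05, delta = 1.2, seed = 21)
  catalog <- random_site_catalog(cfg)
  truth <- simulate_truth(cfg, catalog)
  dm <- truth[truth$dm_flag, ]
  shift <- stats::qlogis(dm$theta_cp) - stats::qlogis(dm$theta_control)
  expect_true(all(abs(abs(shift) - 1.2) < 1e-9))
  expect_true(any(shift > 0) && any(shift < 0))   # both directions planted
  expect_true(all(truth$theta_cp > 0 & truth$theta_cp < 1))
})

test_that("block and promoter effects shift all member sites additively", {
  cfg <- small_cfg(frac_dm = 0.001, delta = 0,
                   block_spec = data.frame(chrom = "chr1", start = 1e6 + 1,
                                           end = 2e6, effect = 0.5),
                   promoter_spec = data.frame(chrom = "chr12", tss_pos = 1e6,
                                              effect = -0.7),
                   seed = 2)
  catalog <- random_site_catalog(cfg)
  truth <- simulate_truth(cfg, catalog)
  shift <- stats::qlogis(truth$theta_cp) - stats::qlogis(truth$theta_control)
  in_block <- truth$chrom == "chr1" & truth$pos >= 1e6 + 1 & truth$pos <= 2e6
  in_prom <- truth$chrom == "chr12" & abs(truth$pos - 1e6) <= 1000
  expect_true(all(abs(shift[in_block] - 0.5) < 1e-9))
  expect_true(all(abs(shift[in_prom] + 0.7) < 1e-9))
  expect_true(all(abs(shift[!in_block & !in_prom]) < 1e-9))
})

test_that("unmethylated sites draw zero coverage and means track the NB contract", {
  cfg <- small_cfg(seed = 4)
  design <- simulate_design(cfg, conditions = "MB")
  zero_truth <- data.frame(site_id = format_site_id("chr1", 1:50 * 10),
                           chrom = "chr1", pos = 1:50 * 10,
                           theta_control = 0, theta_cp = 0)
  expect_true(all(simulate_depth_matrix(zero_truth, cfg, design) == 0))

  # Monte-Carlo mean check: theta = 0.5, depth_mean = 100, per-library size
  # factor divided out; NB mean is s * 100 * 0.5
  cfg2 <- small_cfg(depth_mean = 100, seed = 8)
  mc_truth <- data.frame(site_id = format_site_id("chr1", seq_len(10000) * 10),
                         chrom = "chr1", pos = seq_len(10000) * 10,
                         theta_control = 0.5, theta_cp = 0.5)
  depth <- simulate_depth_matrix(mc_truth, cfg2, design)
  s <- attr(depth, "size_factors")
  scaled <- sweep(depth, 2, s, "/")
  se <- stats::sd(scaled[, 1]) / sqrt(nrow(scaled))
  expect_lt(abs(mean(scaled[, 1]) - 50), 3 * se + 0.5)
})

test_that("depth simulation is deterministic in the seed and validates groups", {
  cfg <- small_cfg(seed = 6)
  catalog <- random_site_catalog(cfg)
  truth <- simulate_truth(cfg, catalog)
  design <- simulate_design(cfg)
  d1 <- simulate_depth_matrix(truth, cfg, design)
  d2 <- simulate_depth_matrix(truth, cfg, design)
  expect_identical(d1, d2)
  cfg2 <- cfg; cfg2$seed <- 7L
  expect_false(identical(d1, simulate_depth_matrix(truth, cfg2, design)))

  bad <- design; bad$group[1] <- "case"
  expect_error(simulate_depth_matrix(truth, cfg, bad), "unknown group label.*case")
})

test_that("mean depth per library scales linearly with its size factor", {
  slopes <- vapply(1:20, function(s) {
    cfg <- small_cfg(delta = 0, seed = s,
                     chrom_spec = data.frame(name = "chr1", length = 2e6))
    catalog <- random_site_catalog(cfg)
    truth <- simulate_truth(cfg, catalog)
    design <- simulate_design(cfg)
    depth <- simulate_depth_matrix(truth, cfg, design)
    sf <- attr(depth, "size_factors")
    fit <- stats::lm(colMeans(depth) ~ 0 + sf)
    unname(stats::coef(fit)) / (cfg$depth_mean * mean(truth$theta_control))
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.05)
})

test_that("emitted annotations honour their construction constraints", {
  cfg <- sim_config(n_genes = 50, seed = 13)
  cohort <- simulate_cohort(cfg, conditions = "MB")
  ann <- cohort$annotations
  genes <- ann$genes
  expect_identical(nrow(genes), 50L)
  # pairwise non-overlap within each chromosome
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # every auto-planted promoter window contains >= 2 catalogue sites
  prom <- cohort$config$promoter_spec
  expect_gte(nrow(prom), 1)
  for (i in seq_len(nrow(prom))) {
    n_in <- sum(cohort$catalog$chrom == prom$chrom[i] &
                  abs(cohort$catalog$pos - prom$tss_pos[i]) <= 1000)
    expect_gte(n_in, 2)
  }
  # enhancer BED round-trips
  bed <- tempfile(fileext = ".bed")
  utils::write.table(ann$enhancers[, c("chrom", "start", "end", "name")],
                     bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back <- read_bed(bed)
  expect_identical(back$start, ann$enhancers$start)
  expect_identical(back$end, ann$enhancers$end)
})

test_that("cohort files round-trip through write_cohort", {
  cfg <- sim_config(chrom_spec = data.frame(name = "chr1", length = 3e6),
                    site_density = 0.5, n_genes = 10,
                    block_spec = NULL, seed = 17)
  cohort <- simulate_cohort(cfg)
  dir <- tempfile()
  write_cohort(cohort, dir)
  depth <- read_matrix_tsv(file.path(dir, "depth.tsv"))
  expect_identical(dim(depth), dim(cohort$depth))
  expect_identical(unname(depth[, 1]), unname(cohort$depth[, 1]))
  design <- read_design(file.path(dir, "design.tsv"))
  expect_identical(design$column_id, cohort$design$column_id)
  expect_identical(readLines(file.path(dir, "muscle_genes.txt")),
                   cohort$annotations$muscle_genes)
})

test_that("flat key=value config files parse into a sim_config", {
  path <- tempfile()
  writeLines(c("n_per_group = 4", "seed = 99", "depth_mean = 120",
               "chrom_spec = chrA:1000000,chrB:2000000",
               "baseline_beta = 2,5", "enriched_chroms = chrB",
               "block_spec = none"), path)
  cfg <- read_sim_config(path)
  expect_identical(cfg$n_per_group, 4)
  expect_identical(cfg$seed, 99L)
  expect_identical(cfg$chrom_spec$name, c("chrA", "chrB"))
  expect_null(cfg$block_spec)
  writeLines("not_a_key = 1", path)
  expect_error(read_sim_config(path), "unknown config key")
})
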