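grp6 <- rep(c("control", "CP"), each = 3)

test_that("the LRT reproduces direct residual-sum-of-squares arithmetic", {
  got <- lrt_two_group(c(0, 1, 2, 3, 4, 5), grp6, p_method = "chisq")
  # RSS0 = 17.5, RSS1 = 4, stat = 6 ln(17.5/4)
  expect_equal(got$stat, 6 * log(17.5 / 4), tolerance = 1e-7)
  expect_equal(got$stat, 8.8555, tolerance = 1e-4)
  expect_equal(got$p, 0.0029, tolerance = 1e-2)

  same <- lrt_two_group(rep(1, 6), grp6)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)
})

test_that("exact-F p-values agree with one-way ANOVA and rank like the t-test", {
  set.seed(10)
  g <- rep(c("control", "CP"), each = 6)
  pvals_f <- pvals_chisq <- pvals_aov <- pvals_t <- numeric(200)
  for (i in 1:200) {
    y <- rnorm(12)
    pvals_f[i] <- lrt_two_group(y, g, p_method = "f")$p
    pvals_chisq[i] <- lrt_two_group(y, g, p_method = "chisq")$p
    pvals_aov[i] <- summary(stats::aov(y ~ g))[[1]][["Pr(>F)"]][1]
    pvals_t[i] <- stats::t.test(y[g == "CP"], y[g == "control"],
                                var.equal = TRUE)$p.value
  }
  expect_equal(pvals_f, pvals_aov, tolerance = 1e-6)
  # both p-value flavours are monotone transforms of the same statistic
  expect_identical(order(pvals_f), order(pvals_t))
  expect_identical(order(pvals_chisq), order(pvals_t))
})

test_that("logFC is the CP-minus-control mean difference and antisymmetric", {
  expect_identical(logfc(c(1, 2, 3, 1, 2, 3), grp6), 0)
  expect_identical(logfc(c(0, 0, 0, 1, 1, 1), grp6), 1)
  set.seed(2)
  y <- rnorm(6)
  swapped <- c("CP", "CP", "CP", "control", "control", "control")
  expect_equal(logfc(y, grp6), -logfc(y, swapped))
  expect_error(logfc(1:3, c("CP", "CP", "CP")), "non-empty")
})

test_that("BH adjustment matches the brute-force step-up on a dense grid", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  grid <- c(0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9, 1)
  combos <- as.matrix(expand.grid(grid, grid, grid, grid))
  for (i in seq_len(nrow(combos))) {
    p <- unname(combos[i, ])
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("per-site testing is total, deterministic and permutation-equivariant", {
  set.seed(20)
  mat <- matrix(rnorm(80 * 12), 80, 12)
  sc <- make_scores(mat, rep(c("control", "CP"), each = 6))
  res <- run_differential(sc)
  expect_identical(nrow(res), 80L)
  expect_true(all(res$fdr >= res$pvalue))
  expect_identical(res$significant, res$fdr < 0.05)
  expect_identical(sign(res$logFC),
                   unname(sign(rowMeans(sc$scores[, 7:12]) - rowMeans(sc$scores[, 1:6]))))

  perm <- sample(12)
  sc_perm <- make_scores(mat[, perm], rep(c("control", "CP"), each = 6)[perm])
  res_perm <- run_differential(sc_perm)
  expect_equal(res_perm$pvalue, res$pvalue, tolerance = 1e-12)
  expect_equal(res_perm$logFC, res$logFC, tolerance = 1e-12)

  # vectorized pipeline equals the scalar per-site functions
  for (i in c(1, 40, 80)) {
    one <- lrt_two_group(mat[i, ], rep(c("control", "CP"), each = 6))
    expect_equal(res$lrt_stat[i], one$stat, tolerance = 1e-9)
    expect_equal(res$pvalue[i], one$p, tolerance = 1e-9)
  }
  expect_error(run_differential(make_scores(mat[, 1:3, drop = FALSE],
                                            c("control", "CP", "CP"))),
               "at least 2 samples")
})

test_that("PCA on informative sites separates planted group structure", {
  set.seed(30)
  mat <- matrix(rnorm(200 * 12, sd = 0.3), 200, 12)
  mat[1:50, 7:12] <- mat[1:50, 7:12] + 2   # block signal in the CP samples
  groups <- rep(c("control", "CP"), each = 6)
  sc <- make_scores(mat, groups)
  res <- run_differential(sc)
  pca <- pca_informative(sc, res, p_cutoff = 0.01)
  expect_true(all(diff(pca$var_frac) <= 1e-12))
  expect_lte(sum(pca$var_frac[1:2]), 1 + 1e-12)
  # nearest-group-centroid assignment recovers every sample's label
  centroids <- vapply(split(seq_len(12), groups),
                      function(ix) colMeans(pca$coords[ix, , drop = FALSE]),
                      numeric(2))
  assign <- apply(pca$coords, 1, function(pt) {
    names(which.min(apply(centroids, 2, function(ctr) sum((pt - ctr)^2))))
  })
  expect_identical(unname(assign), groups)
  expect_named(pca$ellipses, c("CP", "control"))

  # duplicating every sample leaves the leading axis unchanged up to sign
  sc2 <- make_scores(cbind(mat, mat), rep(groups, 2))
  res2 <- run_differential(sc2)
  pca2 <- pca_informative(sc2, res2, p_cutoff = 0.01)
  r <- stats::cor(pca$coords[, 1], pca2$coords[1:12, 1])
  expect_gt(abs(r), 0.999)

  expect_error(pca_informative(sc, res, p_cutoff = 1e-12), "informative sites")
})

test_that("top-site selection is deterministic and clusters like the brute oracle", {
  set.seed(40)
  mat <- matrix(rnorm(30 * 12), 30, 12)
  sc <- make_scores(mat, rep(c("control", "CP"), each = 6))
  res <- run_differential(sc)
  top1 <- select_top_sites(res, sc, n = 1)
  expect_identical(top1$site_ids,
                   res$site_id[order(res$fdr, res$pvalue)][1])

  top10 <- select_top_sites(res, sc, n = 10)
  shuffled <- res[sample(nrow(res)), ]
  top10b <- select_top_sites(shuffled, sc, n = 10)
  expect_setequal(top10$site_ids, top10b$site_ids)
  expect_identical(top10$site_ids, top10b$site_ids)  # same dendrogram order

  expect_warning(all_sites <- select_top_sites(res, sc, n = 100), "using all")
  expect_identical(length(all_sites$site_ids), 30L)

  tiny <- select_top_sites(res, sc, n = 4)
  expect_equal(sort(tiny$hclust$height),
               brute_complete_linkage_heights(tiny$matrix[order(rownames(tiny$matrix)), ]),
               tolerance = 1e-9)
})

test_that("annotation containment follows the half-open convention and a quadratic oracle", {
  # 1-based pos p lies in 0-based half-open [s, e) iff s <= p - 1 < e:
  # pos 200 (0-based 199) is the last base of [100, 200); pos 201 is outside
  sites <- data.frame(site_id = format_site_id("chr1", c(150, 200, 201)),
                      chrom = "chr1", pos = c(150, 200, 201))
  genes <- data.frame(chrom = "chr1", start = 100, end = 200, name = "G1")
  enh <- data.frame(chrom = "chr1", start = 0, end = 10, name = "E1")
  ann <- annotate_sites(sites, genes, enh, muscle_genes = "G1")
  expect_identical(ann$annotated$gene, c("G1", "G1", NA))
  expect_identical(ann$summary$n_in_genes, 2L)
  expect_identical(ann$summary$n_in_muscle_genes, 2L)
  expect_identical(ann$summary$n_in_enhancers, 0L)
  expect_error(annotate_sites(sites, data.frame(chrom = "chr1", start = 5,
                                                end = 5, name = "bad"), enh),
               "end <= start")

  set.seed(50)
  pos <- sample.int(1000, 40)
  sites2 <- data.frame(site_id = format_site_id("chr9", pos),
                       chrom = "chr9", pos = pos)
  starts <- sample.int(900, 15)
  ends <- starts + sample.int(80, 15)
  feats <- data.frame(chrom = "chr9", start = starts, end = ends,
                      name = paste0("F", 1:15))
  ann2 <- annotate_sites(sites2, feats, enh)
  want <- brute_containment(pos, starts, ends)
  expect_identical(!is.na(ann2$annotated$gene), rowSums(want) > 0)
  expect_identical(ann2$summary$n_in_genes, sum(rowSums(want) > 0))
})

test_that("cross-condition overlap classification matches a truth-table oracle", {
  a <- data.frame(site_id = c("chr1.0000000001", "chr1.0000000002"),
                  logFC = c(1, -1), significant = TRUE)
  b <- data.frame(site_id = c("chr1.0000000003", "chr1.0000000004"),
                  logFC = c(1, -1), significant = TRUE)
  empty <- common_significant(a, b)
  expect_identical(attr(empty, "counts")$n_total, 0L)

  set.seed(60)
  ids <- format_site_id("chr2", 1:100)
  res_a <- data.frame(site_id = ids, logFC = rnorm(100),
                      significant = runif(100) < 0.5)
  res_b <- data.frame(site_id = ids, logFC = rnorm(100),
                      significant = runif(100) < 0.5)
  ov <- common_significant(res_a, res_b)
  both <- res_a$significant & res_b$significant
  expect_identical(attr(ov, "counts")$n_total, sum(both))
  for (k in seq_len(nrow(ov))) {
    la <- ov$logFC_a[k]; lb <- ov$logFC_b[k]
    want <- if (la > 0 && lb > 0) "hypermethylated"
            else if (la < 0 && lb < 0) "hypomethylated" else "discordant"
    expect_identical(ov$class[k], want)
  }
  ct <- attr(ov, "counts")
  expect_identical(ct$n_hyper + ct$n_hypo + ct$n_discordant, ct$n_total)
})
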