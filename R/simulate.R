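#' Simulation configuration for a synthetic MSRE-seq cohort
#'
#' Defines the study conditions emulated by the synthetic-cohort generator:
#' a two-group design (CP vs control, `n_per_group` each) assayed under two
#' paired cell conditions (proliferating myoblasts MB, differentiating
#' myotubes MT), with per-site baseline methylation probabilities, a planted
#' subset of differentially methylated (DM) sites, chromosome-level
#' concentration of DM sites, planted 1-Mbp hyper/hypomethylated blocks, and
#' planted promoter-window shifts. Intact-fragment coverage is
#' negative-binomial with mean proportional to the methylation probability
#' (methylated CCGG sites resist HpaII digestion, so their fragments survive
#' to be sequenced).
#'
#' @param n_per_group samples per cohort (default 6).
#' @param chrom_spec data frame with columns `name`, `length` (bp).
#' @param site_density expected CCGG sites per kbp.
#' @param baseline_beta length-2 shape parameters `(a, b)` of the Beta
#'   distribution of per-site baseline methylation probability.
#' @param frac_dm fraction of sites planted with a group effect (exact count
#'   `floor(frac_dm * n_sites)`, allocated without replacement).
#' @param delta effect size on the log-odds of methylation in the CP group at
#'   planted sites; the sign is drawn per site so both hyper- and
#'   hypomethylation are planted.
#' @param enriched_chroms chromosome names whose DM-site density is a multiple
#'   of the genome average.
#' @param enrich_multiple that multiple (default 4).
#' @param block_spec data frame `(chrom, start, end, effect)` of planted
#'   blocks: `effect` is added on the log-odds scale to the CP group at every
#'   member site (1-based inclusive interval). `"auto"` places four 1-Mbp
#'   blocks (two hyper, two hypo) at fixed bins; `NULL` plants none.
#' @param promoter_spec data frame `(chrom, tss_pos, effect)` of planted
#'   TSS±1000 bp promoter shifts (log-odds scale, CP group), `"auto"` to pick
#'   `n_planted_promoters` promoters from the emitted annotations, or `NULL`.
#' @param n_genes number of synthetic gene models to emit.
#' @param n_planted_promoters promoters planted when `promoter_spec = "auto"`.
#' @param promoter_effect absolute log-odds shift for auto-planted promoters
#'   (signs alternate).
#' @param block_effect absolute log-odds shift for auto-planted blocks.
#' @param depth_mean expected intact-fragment depth at a fully methylated
#'   site for a size-factor-1 sample.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a list of class `msre_sim_config`.
#' @export
sim_config <- function(n_per_group = 6,
                       chrom_spec = data.frame(name = paste0("chr", 1:4),
                                               length = rep(12e6, 4)),
                       site_density = 0.4,
                       baseline_beta = c(2, 5),
                       frac_dm = 0.015,
                       delta = 1.2,
                       enriched_chroms = "chr3",
                       enrich_multiple = 4,
                       block_spec = "auto",
                       promoter_spec = "auto",
                       n_genes = 100,
                       n_planted_promoters = 5,
                       promoter_effect = 1.2,
                       block_effect = 0.25,
                       depth_mean = 300,
                       nb_dispersion = 0.02,
                       seed = 1) {
  cfg <- list(n_per_group = n_per_group, chrom_spec = chrom_spec,
              site_density = site_density, baseline_beta = baseline_beta,
              frac_dm = frac_dm, delta = delta,
              enriched_chroms = enriched_chroms,
              enrich_multiple = enrich_multiple,
              block_spec = block_spec, promoter_spec = promoter_spec,
              n_genes = n_genes, n_planted_promoters = n_planted_promoters,
              promoter_effect = promoter_effect, block_effect = block_effect,
              depth_mean = depth_mean, nb_dispersion = nb_dispersion,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "msre_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.data.frame(cfg$chrom_spec),
            all(c("name", "length") %in% names(cfg$chrom_spec)))
  if (!(cfg$frac_dm > 0 && cfg$frac_dm < 1)) stopf("frac_dm must be in (0, 1)")
  if (cfg$depth_mean <= 0) stopf("depth_mean must be > 0")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (cfg$n_per_group < 2) stopf("need at least 2 samples per group")
  for (spec_name in c("block_spec", "promoter_spec")) {
    spec <- cfg[[spec_name]]
    if (is.data.frame(spec) && nrow(spec) > 0) {
      len <- stats::setNames(cfg$chrom_spec$length, cfg$chrom_spec$name)
      if (!all(spec$chrom %in% names(len))) {
        stopf("%s names a chromosome absent from chrom_spec", spec_name)
      }
      hi <- if (spec_name == "block_spec") spec$end else spec$tss_pos + 1000
      if (any(hi > len[spec$chrom])) {
        stopf("%s interval outside chromosome bounds", spec_name)
      }
    }
  }
  invisible(cfg)
}

#' Read a flat key=value simulation config file
#'
#' Keys are the arguments of [sim_config()]; `chrom_spec` is encoded as
#' `name:length` pairs separated by commas (e.g. `chr1:12000000,chr2:12000000`),
#' `baseline_beta` and `enriched_chroms` as comma-separated values. Unknown
#' keys are an error. Keys not present keep their defaults.
#'
#' @param path config file path.
#' @return an `msre_sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  args <- list()
  numeric_keys <- c("n_per_group", "site_density", "frac_dm", "delta",
                    "enrich_multiple", "n_genes", "n_planted_promoters",
                    "promoter_effect", "block_effect", "depth_mean",
                    "nb_dispersion", "seed")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% numeric_keys) {
      args[k] <- list(as.numeric(v))
    } else if (k == "baseline_beta") {
      args[k] <- list(as.numeric(strsplit(v, ",")[[1]]))
    } else if (k == "enriched_chroms") {
      args[k] <- list(strsplit(v, ",")[[1]])
    } else if (k == "chrom_spec") {
      parts <- strsplit(strsplit(v, ",")[[1]], ":")
      args[k] <- list(data.frame(name = vapply(parts, `[[`, character(1), 1L),
                                 length = as.numeric(vapply(parts, `[[`, character(1), 2L))))
    } else if (k %in% c("block_spec", "promoter_spec")) {
      args[k] <- list(if (identical(v, "none")) NULL else v)
    } else {
      stopf("unknown config key: '%s'", k)
    }
  }
  do.call(sim_config, args)
}

#' Synthetic site catalogue without a genome sequence
#'
#' Places CCGG site positions along the configured chromosomes as a Poisson
#' process at `site_density` sites/kbp. Used for large simulations where only
#' site coordinates (not sequence) matter; [random_genome()] +
#' [scan_ccgg_sites()] provides the sequence-backed route.
#'
#' @param config an `msre_sim_config`.
#' @return an `msre_catalog`.
#' @export
random_site_catalog <- function(config) {
  with_seed(config$seed + 101L, {
    chrom <- character(0); pos <- integer(0)
    for (i in seq_len(nrow(config$chrom_spec))) {
      nm <- config$chrom_spec$name[i]
      len <- config$chrom_spec$length[i]
      n <- stats::rpois(1, len / 1000 * config$site_density)
      p <- sort(unique(sample.int(len - 3L, n)))
      chrom <- c(chrom, rep(nm, length(p)))
      pos <- c(pos, p)
    }
    new_site_catalog(chrom, pos,
                     chrom_lengths = stats::setNames(config$chrom_spec$length,
                                                     config$chrom_spec$name))
  })
}

#' Synthetic genome with planted CCGG motifs
#'
#' Builds an A/T background sequence (which cannot form CCGG by chance) and
#' plants `CCGG` motifs as a Poisson process at the configured density, so
#' that [scan_ccgg_sites()] on the result recovers exactly the planted sites.
#'
#' @param config an `msre_sim_config`.
#' @return a named character vector of sequences (one per chromosome).
#' @export
random_genome <- function(config) {
  with_seed(config$seed + 101L, {
    out <- character(nrow(config$chrom_spec))
    names(out) <- config$chrom_spec$name
    for (i in seq_len(nrow(config$chrom_spec))) {
      len <- as.integer(config$chrom_spec$length[i])
      n <- stats::rpois(1, len / 1000 * config$site_density)
      p <- sort(unique(sample.int(len - 3L, n)))
      # drop planted positions closer than 4 bp so motifs stay intact
      if (length(p) > 1) p <- p[c(TRUE, diff(p) >= 4L)]
      s <- sample(c("A", "T"), len, replace = TRUE)
      for (off in 0:3) s[p + off] <- c("C", "C", "G", "G")[off + 1L]
      out[i] <- paste(s, collapse = "")
    }
    out
  })
}

resolve_block_spec <- function(config, catalog) {
  spec <- config$block_spec
  if (is.null(spec)) return(NULL)
  if (is.data.frame(spec)) return(spec)
  # "auto": four 1-Mbp blocks on the first two chromosomes, alternating sign
  ch <- config$chrom_spec$name[seq_len(min(2, nrow(config$chrom_spec)))]
  bins <- c(2, 7, 3, 9)[seq_len(2 * length(ch))]
  chrom <- rep(ch, each = 2)
  data.frame(chrom = chrom,
             start = bins * 1e6 + 1,
             end = (bins + 1) * 1e6,
             effect = config$block_effect * c(1, -1, 1, -1)[seq_along(chrom)],
             stringsAsFactors = FALSE)
}

resolve_promoter_spec <- function(config, annotations) {
  spec <- config$promoter_spec
  if (is.null(spec)) return(NULL)
  if (is.data.frame(spec)) return(spec)
  tss <- annotations$tss_table
  tss <- tss[!duplicated(tss$gene_id), , drop = FALSE]
  n <- min(config$n_planted_promoters, nrow(tss))
  if (n == 0) return(NULL)
  pick <- tss[seq_len(n), , drop = FALSE]
  data.frame(chrom = pick$chrom, tss_pos = pick$tss_pos,
             gene_id = pick$gene_id,
             effect = config$promoter_effect * rep_len(c(1, -1), n),
             stringsAsFactors = FALSE)
}

#' Plant per-site ground truth for a synthetic cohort
#'
#' Draws baseline methylation probabilities theta_i ~ Beta(a, b), plants an
#' exact-count subset of DM sites (log-odds shift `delta`, random sign,
#' allocation weighted toward `enriched_chroms` at `enrich_multiple`), then
#' adds block and promoter effects additively on the log-odds of the CP
#' group. `block_spec`/`promoter_spec` of `"auto"` must be resolved first
#' (see [simulate_cohort()]); here they are taken as given data frames.
#'
#' @param config an `msre_sim_config` (with resolved specs or `NULL`s).
#' @param catalog an `msre_catalog`.
#' @return data frame of class `msre_truth`: per site `theta_baseline`,
#'   `theta_control`, `theta_cp`, `dm_flag` (TRUE iff the two group
#'   probabilities differ), `planted_logfc` = log2(theta_cp / theta_control);
#'   attributes `dm_sites` (the exact-count planted subset), `blocks`,
#'   `promoters` (resolved planted-effect records).
#' @export
simulate_truth <- function(config, catalog) {
  if (nrow(catalog) == 0) stopf("catalog is empty")
  blocks <- if (is.data.frame(config$block_spec) || is.null(config$block_spec)) {
    config$block_spec
  } else {
    resolve_block_spec(config, catalog)
  }
  promoters <- if (is.data.frame(config$promoter_spec) || is.null(config$promoter_spec)) {
    config$promoter_spec
  } else {
    stopf("promoter_spec 'auto' requires annotations; use simulate_cohort() or pass a data frame")
  }
  n <- nrow(catalog)
  n_dm <- floor(config$frac_dm * n)
  if (n_dm < 1) stopf("no DM sites plantable: frac_dm * n_sites < 1")
  with_seed(config$seed + 202L, {
    a <- config$baseline_beta[1]; b <- config$baseline_beta[2]
    th0 <- stats::rbeta(n, a, b)
    w <- ifelse(catalog$chrom %in% config$enriched_chroms,
                config$enrich_multiple, 1)
    dm_idx <- sample.int(n, n_dm, prob = w)
    sgn <- sample(c(-1, 1), n_dm, replace = TRUE)
    shift <- numeric(n)
    shift[dm_idx] <- shift[dm_idx] + sgn * config$delta
    if (!is.null(blocks)) {
      for (i in seq_len(nrow(blocks))) {
        m <- catalog$chrom == blocks$chrom[i] &
          catalog$pos >= blocks$start[i] & catalog$pos <= blocks$end[i]
        shift[m] <- shift[m] + blocks$effect[i]
      }
    }
    if (!is.null(promoters)) {
      for (i in seq_len(nrow(promoters))) {
        m <- catalog$chrom == promoters$chrom[i] &
          catalog$pos >= promoters$tss_pos[i] - 1000 &
          catalog$pos <= promoters$tss_pos[i] + 1000
        shift[m] <- shift[m] + promoters$effect[i]
      }
    }
    # apply shifts only where nonzero so unshifted sites keep theta exactly
    # (a logit/expit round trip would perturb them at machine precision)
    th_cp <- th0
    moved <- shift != 0
    th_cp[moved] <- stats::plogis(stats::qlogis(th0[moved]) + shift[moved])
    truth <- data.frame(site_id = catalog$site_id, chrom = catalog$chrom,
                        pos = catalog$pos, theta_baseline = th0,
                        theta_control = th0, theta_cp = th_cp,
                        dm_flag = th_cp != th0,
                        planted_logfc = log2(th_cp / th0),
                        stringsAsFactors = FALSE)
    structure(truth,
              dm_sites = catalog$site_id[sort(dm_idx)],
              blocks = blocks, promoters = promoters,
              class = c("msre_truth", "data.frame"))
  })
}

#' Cohort design table for the synthetic study
#'
#' One row per sample x cell condition: control samples CN1..CNk, CP samples
#' CP1..CPk, each assayed as proliferating myoblasts (MB) and differentiating
#' myotubes (MT).
#'
#' @param config an `msre_sim_config`.
#' @param conditions cell conditions to include (default both).
#' @return data frame with `column_id`, `sample_id`, `group`, `condition`.
#' @export
simulate_design <- function(config, conditions = c("MB", "MT")) {
  k <- config$n_per_group
  samples <- data.frame(
    sample_id = c(paste0("CN", seq_len(k)), paste0("CP", seq_len(k))),
    group = rep(c("control", "CP"), each = k),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(conditions, function(cc) {
    d <- samples; d$condition <- cc; d
  }))
  out$column_id <- paste(out$sample_id, out$condition, sep = "_")
  out[, c("column_id", "sample_id", "group", "condition")]
}

#' Simulate an intact-fragment depth matrix
#'
#' Depth at site i in sample j is negative-binomial with mean
#' `s_j * depth_mean * theta_i(group(j))` and dispersion `nb_dispersion`
#' (variance mu + phi mu^2). Per-sample size factors s_j are drawn
#' log-uniform on [0.7, 1.4] — bounded away from zero so no library is
#' empty. The coverage-methylation link is linear in theta: unmethylated
#' sites are always cut, so theta = 0 gives zero coverage.
#'
#' @param truth an `msre_truth`.
#' @param config the `msre_sim_config` that produced it.
#' @param design a design data frame as from [simulate_design()]; each row
#'   must carry `group` in {control, CP}.
#' @return integer matrix (sites x design rows) with `site_id` rownames and
#'   `column_id` colnames; attribute `size_factors`.
#' @export
simulate_depth_matrix <- function(truth, config, design) {
  bad <- setdiff(unique(design$group), c("control", "CP"))
  if (length(bad) > 0) stopf("unknown group label in design: '%s'", bad[[1L]])
  n <- nrow(truth); m <- nrow(design)
  with_seed(config$seed + 303L, {
    s <- exp(stats::runif(m, log(0.7), log(1.4)))
    depth <- matrix(0L, n, m,
                    dimnames = list(truth$site_id,
                                    if (!is.null(design$column_id)) design$column_id
                                    else design$sample_id))
    size <- 1 / config$nb_dispersion
    for (j in seq_len(m)) {
      th <- if (design$group[j] == "CP") truth$theta_cp else truth$theta_control
      mu <- s[j] * config$depth_mean * th
      depth[, j] <- stats::rnbinom(n, size = size, mu = mu)
    }
    storage.mode(depth) <- "integer"
    attr(depth, "size_factors") <- stats::setNames(s, colnames(depth))
    depth
  })
}

#' Emit synthetic gene/TSS, enhancer, and muscle-gene annotations
#'
#' Constructs non-overlapping gene models whose TSSs sit at the midpoint of
#' two adjacent catalogue sites less than 1500 bp apart, so every emitted
#' promoter window (TSS±1000 bp) contains at least two catalogue sites and
#' survives the promoter-inclusion filter. About a quarter of genes get a
#' second transcript (TSS shifted +300 bp) to exercise one-transcript-per-gene
#' deduplication. Enhancer intervals (1 kbp) are placed uniformly; a random
#' fifth of genes is labelled as the muscle-physiology list.
#'
#' @param config an `msre_sim_config`.
#' @param catalog an `msre_catalog`.
#' @return list with `tss_table` (gene_id, transcript_id, chrom, strand,
#'   tss_pos, class), `genes` (chrom, start, end, name; 0-based half-open),
#'   `enhancers` (same convention), `muscle_genes` (character vector).
#' @export
emit_annotations <- function(config, catalog) {
  classes <- c("protein coding", "lincRNA", "miRNA", "snRNA", "pseudogene")
  with_seed(config$seed + 404L, {
    cand <- list()
    for (nm in unique(catalog$chrom)) {
      p <- catalog$pos[catalog$chrom == nm]
      if (length(p) < 2) next
      gap <- diff(p)
      ok <- which(gap <= 1500)
      if (length(ok) == 0) next
      cand[[nm]] <- data.frame(chrom = nm,
                               tss_pos = as.integer(floor((p[ok] + p[ok + 1L]) / 2)),
                               stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand) || nrow(cand) == 0) {
      stopf("no adjacent-site pairs available to anchor promoters")
    }
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    accepted <- list(); occupied <- list()
    body_len <- 3000L
    for (i in seq_len(nrow(cand))) {
      if (length(accepted) >= config$n_genes) break
      ch <- cand$chrom[i]; tss <- cand$tss_pos[i]
      strand <- sample(c("+", "-"), 1)
      lo <- if (strand == "+") tss - 1000L else tss - body_len
      hi <- if (strand == "+") tss + body_len else tss + 1000L
      if (lo < 1) next
      occ <- occupied[[ch]]
      if (!is.null(occ) && any(lo <= occ$hi & hi >= occ$lo)) next
      occupied[[ch]] <- rbind(occ, data.frame(lo = lo, hi = hi))
      accepted[[length(accepted) + 1L]] <-
        data.frame(chrom = ch, tss_pos = tss, strand = strand,
                   stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, accepted)
    ng <- nrow(genes)
    genes$gene_id <- sprintf("GENE%04d", seq_len(ng))
    genes$transcript_id <- sprintf("GENE%04d.T1", seq_len(ng))
    genes$class <- sample(classes, ng, replace = TRUE,
                          prob = c(0.5, 0.2, 0.1, 0.1, 0.1))
    genes$start0 <- ifelse(genes$strand == "+", genes$tss_pos - 1L,
                           genes$tss_pos - body_len - 1L)
    genes$end0 <- ifelse(genes$strand == "+", genes$tss_pos + body_len,
                         genes$tss_pos)
    tss_table <- genes[, c("gene_id", "transcript_id", "chrom", "strand",
                           "tss_pos", "class")]
    extra_idx <- which(stats::runif(ng) < 0.25)
    if (length(extra_idx) > 0) {
      extra <- tss_table[extra_idx, , drop = FALSE]
      extra$transcript_id <- sub("T1$", "T2", extra$transcript_id)
      extra$tss_pos <- extra$tss_pos + 300L
      tss_table <- rbind(tss_table, extra)
    }
    tss_table <- tss_table[order(tss_table$gene_id, tss_table$transcript_id), ]
    rownames(tss_table) <- NULL
    gene_intervals <- data.frame(chrom = genes$chrom, start = genes$start0,
                                 end = genes$end0, name = genes$gene_id,
                                 stringsAsFactors = FALSE)
    n_enh <- max(10L, ceiling(config$n_genes / 2))
    enh <- list()
    for (k in seq_len(n_enh)) {
      ci <- sample.int(nrow(config$chrom_spec), 1)
      st <- sample.int(max(1, config$chrom_spec$length[ci] - 1000L), 1)
      enh[[k]] <- data.frame(chrom = config$chrom_spec$name[ci],
                             start = st, end = st + 1000L,
                             name = sprintf("ENH%04d", k),
                             stringsAsFactors = FALSE)
    }
    enhancers <- do.call(rbind, enh)
    muscle_genes <- sort(sample(genes$gene_id, max(1L, round(0.2 * ng))))
    list(tss_table = tss_table, genes = gene_intervals,
         enhancers = enhancers, muscle_genes = muscle_genes)
  })
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates catalogue, annotations, planted-effect resolution, ground
#' truth, design and depth matrices for both cell conditions. Fully
#' reproducible from `config$seed`.
#'
#' @param config an `msre_sim_config`.
#' @param conditions cell conditions to simulate.
#' @return list of class `msre_cohort`: `config` (with resolved specs),
#'   `catalog`, `annotations`, `truth`, `design`, `depth`.
#' @export
simulate_cohort <- function(config = sim_config(), conditions = c("MB", "MT")) {
  catalog <- random_site_catalog(config)
  annotations <- emit_annotations(config, catalog)
  config$block_spec <- resolve_block_spec(config, catalog)
  config$promoter_spec <- resolve_promoter_spec(config, annotations)
  truth <- simulate_truth(config, catalog)
  design <- simulate_design(config, conditions)
  depth <- simulate_depth_matrix(truth, config, design)
  structure(list(config = config, catalog = catalog,
                 annotations = annotations, truth = truth,
                 design = design, depth = depth),
            class = "msre_cohort")
}

#' @export
print.msre_cohort <- function(x, ...) {
  cat(sprintf("Synthetic MSRE-seq cohort: %d sites x %d libraries (%d per group, conditions: %s)\n",
              nrow(x$truth), nrow(x$design), x$config$n_per_group,
              paste(unique(x$design$condition), collapse = ", ")))
  cat(sprintf("  planted DM sites: %d; blocks: %d; promoters: %d; seed %d\n",
              length(attr(x$truth, "dm_sites")),
              if (is.null(attr(x$truth, "blocks"))) 0L else nrow(attr(x$truth, "blocks")),
              if (is.null(attr(x$truth, "promoters"))) 0L else nrow(attr(x$truth, "promoters")),
              x$config$seed))
  invisible(x)
}

#' Write the synthetic cohort's files to a directory
#'
#' Emits depth matrix TSV (site_id + one column per library), design TSV,
#' truth TSV, gene/TSS TSV, enhancer BED, and muscle-gene list.
#'
#' @param cohort an `msre_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  depth_df <- data.frame(site_id = rownames(cohort$depth),
                         cohort$depth, check.names = FALSE)
  write_tsv(depth_df, file.path(dir, "depth.tsv"))
  write_tsv(cohort$design, file.path(dir, "design.tsv"))
  write_tsv(as.data.frame(cohort$truth), file.path(dir, "truth.tsv"))
  write_tsv(cohort$annotations$tss_table, file.path(dir, "tss_table.tsv"))
  utils::write.table(cohort$annotations$enhancers[, c("chrom", "start", "end", "name")],
                     file.path(dir, "enhancers.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(cohort$annotations$muscle_genes, file.path(dir, "muscle_genes.txt"))
  write_catalog(cohort$catalog, file.path(dir, "catalog.tsv"))
  invisible(dir)
}

#' Read a BED file of intervals
#'
#' Minimal three/four column BED reader (0-based half-open intervals).
#'
#' @param path BED file path.
#' @return data frame `chrom`, `start`, `end` and, if present, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df[, seq_len(min(4, ncol(df)))]
}
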