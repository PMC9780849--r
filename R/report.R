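#' Cohort demographic summary
#'
#' Per-group sample count, sex counts, arithmetic mean age and sample
#' (n - 1) standard deviation. Values are returned at full precision; the
#' print method displays one decimal, the convention used for reporting
#' cohort ages.
#'
#' @param design data frame with `sample_id`, `group` and `age`, optionally
#'   `sex`.
#' @return data frame of class `msre_cohort_summary`: one row per group with
#'   `group`, `n`, `n_male`, `n_female`, `mean_age`, `sd_age`.
#' @export
cohort_summary <- function(design) {
  if (is.null(design$age) || anyNA(design$age)) stopf("ages must be present")
  if (any(design$age <= 0)) stopf("ages must be positive")
  groups <- unique(design$group)
  rows <- lapply(groups, function(g) {
    d <- design[design$group == g, , drop = FALSE]
    sd_age <- if (nrow(d) < 2) {
      warnf("group '%s' has fewer than 2 samples; SD omitted", g)
      NA_real_
    } else {
      stats::sd(d$age)
    }
    data.frame(group = g, n = nrow(d),
               n_male = if (is.null(d$sex)) NA_integer_ else sum(d$sex == "M"),
               n_female = if (is.null(d$sex)) NA_integer_ else sum(d$sex == "F"),
               mean_age = mean(d$age), sd_age = sd_age,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("msre_cohort_summary", "data.frame"))
}

#' @export
print.msre_cohort_summary <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s: n = %d (males = %s, females = %s), age %.1f +/- %.1f years\n",
                x$group[i], x$n[i],
                ifelse(is.na(x$n_male[i]), "?", x$n_male[i]),
                ifelse(is.na(x$n_female[i]), "?", x$n_female[i]),
                x$mean_age[i], x$sd_age[i]))
  }
  invisible(x)
}

#' Read a cohort design table
#'
#' @param path TSV with columns `sample_id`, `group` and any of `age`,
#'   `sex`, `gmfcs`, `tissue_source`, `condition`.
#' @return the design data frame.
#' @export
read_design <- function(path) {
  d <- read_tsv(path)
  if (!all(c("sample_id", "group") %in% names(d))) {
    stopf("design table must carry sample_id and group columns")
  }
  if (length(unique(d$group)) < 1) stopf("design has no groups")
  d
}

#' End-to-end analysis of a (simulated or file-based) cohort
#'
#' Runs the full pipeline: site catalogue -> synthetic cohort (or files) ->
#' common-site filtering -> log2-CPM scoring -> per-condition differential
#' methylation -> cross-condition overlap -> chromosome enrichment -> 1-Mbp
#' bins with flagging and MB/MT correlation -> promoter windows and testing
#' -> run report. Idempotent for a fixed seed; each stage logs its counts to
#' standard error.
#'
#' @param config an `msre_sim_config` (simulation route), or a list with
#'   element `inputs` naming files: `depth` (TSV matrix), `design` (TSV),
#'   `tss_table` (TSV), `enhancers` (BED), `muscle_genes` (text), in which
#'   case the cohort is loaded rather than simulated.
#' @param alpha FDR level for all stages (default 0.05).
#' @param min_depth common-site depth threshold (default 1).
#' @param outdir optional directory; when given, stage outputs and the JSON
#'   report are written there.
#' @return list of class `msre_report` with per-stage results and a `counts`
#'   summary.
#' @export
run_pipeline <- function(config = sim_config(), alpha = 0.05, min_depth = 1,
                         outdir = NULL) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (f in unlist(inp)) if (!file.exists(f)) stopf("input path does not exist: %s", f)
    msg_stage("load", "reading cohort from files")
    depth <- read_matrix_tsv(inp$depth)
    design <- read_design(inp$design)
    annotations <- list(
      tss_table = read_tsv(inp$tss_table),
      enhancers = read_bed(inp$enhancers),
      muscle_genes = readLines(inp$muscle_genes))
    loc <- parse_site_id(rownames(depth))
    catalog <- new_site_catalog(loc$chrom, loc$pos, chrom_lengths = NULL)
    cohort <- list(config = config, catalog = catalog,
                   annotations = annotations, truth = NULL,
                   design = design, depth = depth)
    seed <- if (is.null(config$seed)) NA_integer_ else config$seed
  } else {
    msg_stage("simulate", "generating synthetic cohort (seed %d)", config$seed)
    cohort <- simulate_cohort(config)
    depth <- cohort$depth; design <- cohort$design
    annotations <- cohort$annotations; catalog <- cohort$catalog
    seed <- config$seed
  }
  msg_stage("catalog", "%d sites", nrow(catalog))

  depth_common <- common_sites(depth, min_depth = min_depth)
  scores <- normalize_depth(depth_common, design)
  msg_stage("score", "%d common sites scored across %d libraries",
            nrow(scores$scores), ncol(scores$scores))

  conditions <- unique(design$condition)
  diff <- lapply(stats::setNames(conditions, conditions), function(cc) {
    res <- run_differential(subset_condition(scores, cc), alpha = alpha)
    msg_stage("diff", "%s: %d significant of %d sites", cc,
              sum(res$significant), nrow(res))
    res
  })

  overlap <- NULL
  if (length(conditions) == 2) {
    overlap <- common_significant(diff[[1]], diff[[2]])
    msg_stage("overlap", "%d sites significant in both conditions",
              attr(overlap, "counts")$n_total)
  }

  enrich <- lapply(diff, chromosome_enrichment, alpha = alpha)
  enriched_both <- if (length(conditions) == 2) {
    enrichment_intersection(enrich[[1]], enrich[[2]])
  } else {
    enrich[[1]]$chrom[enrich[[1]]$enriched]
  }
  msg_stage("enrich", "enriched in all conditions: %s",
            if (length(enriched_both)) paste(enriched_both, collapse = ", ") else "none")

  bins <- lapply(diff, function(res) flag_bins(bin_logfc(res)))
  bin_r <- NULL
  if (length(conditions) == 2) {
    bin_r <- bin_correlation(bins[[1]], bins[[2]])
    msg_stage("bins", "MB/MT bin correlation r = %.3f over %d shared bins",
              bin_r$r, bin_r$n_shared)
  }

  windows <- build_windows(annotations$tss_table, catalog)
  prom <- lapply(stats::setNames(conditions, conditions), function(cc) {
    sc <- subset_condition(scores, cc)
    keep <- vapply(windows$member_sites,
                   function(v) all(v %in% rownames(sc$scores)), logical(1))
    win <- windows[keep, , drop = FALSE]
    loads <- promoter_loads(sc, win)
    res <- test_promoters(loads, sc$design, windows = win, alpha = alpha)
    msg_stage("promoters", "%s: %d significant of %d windows", cc,
              sum(res$significant), nrow(res))
    res
  })

  ann <- lapply(diff, function(res) {
    sig <- res[res$significant, , drop = FALSE]
    if (nrow(sig) == 0) return(NULL)
    annotate_sites(sig, annotations$genes %||% gene_intervals_from_tss(annotations$tss_table),
                   annotations$enhancers, annotations$muscle_genes)
  })

  counts <- list(
    n_sites = nrow(catalog),
    n_common = nrow(scores$scores),
    n_significant = lapply(diff, function(r) sum(r$significant)),
    overlap = if (is.null(overlap)) NULL else attr(overlap, "counts"),
    enriched_chroms = lapply(enrich, function(e) e$chrom[e$enriched]),
    enriched_both = enriched_both,
    n_bins_flagged = lapply(bins, function(b) sum(b$flag != "neutral")),
    bin_correlation = if (is.null(bin_r)) NULL else bin_r$r,
    n_promoter_windows = lapply(prom, nrow),
    n_significant_promoters = lapply(prom, function(r) sum(r$significant)))
  report <- structure(list(counts = counts, diff = diff, overlap = overlap,
                           enrichment = enrich, bins = bins, bin_r = bin_r,
                           promoters = prom, annotations_summary = lapply(ann, `[[`, "summary"),
                           windows = windows, scores = scores,
                           cohort = cohort, alpha = alpha, seed = seed,
                           version = as.character(utils::packageVersion("msremeth"))),
                      class = "msre_report")
  validate_report(report)
  if (!is.null(outdir)) write_report_files(report, outdir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gene_intervals_from_tss <- function(tss_table) {
  # fallback gene intervals when only TSSs are known: the promoter window
  data.frame(chrom = tss_table$chrom,
             start = pmax(tss_table$tss_pos - 1001L, 0L),
             end = tss_table$tss_pos + 1000L,
             name = tss_table$gene_id, stringsAsFactors = FALSE)
}

validate_report <- function(report) {
  ct <- report$counts
  if (!is.null(ct$overlap)) {
    if (ct$overlap$n_total > min(unlist(ct$n_significant))) {
      stopf("inconsistent report: overlap exceeds per-condition significant counts")
    }
    with_counts <- ct$overlap$n_hyper + ct$overlap$n_hypo + ct$overlap$n_discordant
    if (with_counts != ct$overlap$n_total) {
      stopf("inconsistent report: overlap classes do not sum to total")
    }
  }
  if (ct$n_common > ct$n_sites) stopf("inconsistent report: common sites exceed catalogue")
  invisible(report)
}

#' @export
print.msre_report <- function(x, ...) {
  ct <- x$counts
  cat("MSRE-seq methylation analysis report\n")
  cat(sprintf("  catalogue sites:        %d\n", ct$n_sites))
  cat(sprintf("  common sites tested:    %d\n", ct$n_common))
  for (cc in names(ct$n_significant)) {
    cat(sprintf("  significant sites %s:   %d\n", cc, ct$n_significant[[cc]]))
  }
  if (!is.null(ct$overlap)) {
    cat(sprintf("  overlap (both cond.):   %d (%d hyper, %d hypo)\n",
                ct$overlap$n_total, ct$overlap$n_hyper, ct$overlap$n_hypo))
  }
  cat(sprintf("  enriched chromosomes:   %s\n",
              if (length(ct$enriched_both)) paste(ct$enriched_both, collapse = ", ") else "none"))
  if (!is.null(ct$bin_correlation)) {
    cat(sprintf("  MB/MT bin correlation:  %.3f\n", ct$bin_correlation))
  }
  for (cc in names(ct$n_significant_promoters)) {
    cat(sprintf("  significant promoters %s: %d of %d\n", cc,
                ct$n_significant_promoters[[cc]], ct$n_promoter_windows[[cc]]))
  }
  invisible(x)
}

write_report_files <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (cc in names(report$diff)) {
    write_tsv(as.data.frame(report$diff[[cc]]),
              file.path(outdir, sprintf("diff_%s.tsv", cc)))
    write_tsv(as.data.frame(report$enrichment[[cc]]),
              file.path(outdir, sprintf("enrichment_%s.tsv", cc)))
    write_tsv(as.data.frame(report$bins[[cc]]),
              file.path(outdir, sprintf("bins_%s.tsv", cc)))
    prom <- report$promoters[[cc]]
    write_tsv(as.data.frame(prom), file.path(outdir, sprintf("promoters_%s.tsv", cc)))
  }
  if (!is.null(report$overlap)) {
    write_tsv(as.data.frame(report$overlap), file.path(outdir, "overlap.tsv"))
  }
  write_report_json(report, file.path(outdir, "report.json"))
  invisible(outdir)
}

#' Serialize the run report's counts to JSON
#'
#' @param report an `msre_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  payload <- c(report$counts,
               list(alpha = report$alpha, seed = report$seed,
                    version = report$version))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Paths of the published summary-table fixtures shipped with the package
#'
#' Machine-readable transcriptions of the published cohort summaries from
#' the 12-subject spastic-CP myogenic-cell methylation study: the cohort
#' design table, the shared differentially-methylated site table, the
#' per-chromosome enrichment counts, and the significant promoter tables for
#' each cell condition.
#'
#' @param name one of "design", "overlap", "enrichment", "promoters_mb",
#'   "promoters_mt".
#' @return path to the TSV fixture.
#' @export
fixture_path <- function(name = c("design", "overlap", "enrichment",
                                  "promoters_mb", "promoters_mt")) {
  name <- match.arg(name)
  file <- switch(name,
                 design = "cohort_design.tsv",
                 overlap = "overlap_sites.tsv",
                 enrichment = "chromosome_enrichment_counts.tsv",
                 promoters_mb = "promoters_mb.tsv",
                 promoters_mt = "promoters_mt.tsv")
  path <- system.file("extdata", file, package = "msremeth")
  if (!nzchar(path)) stopf("fixture not found: %s", file)
  path
}
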