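#' Chromosome-level enrichment of significant sites
#'
#' For each chromosome, a one-sided (greater) Fisher exact test on the 2x2
#' table (significant on-chromosome, significant elsewhere; non-significant
#' on-chromosome, non-significant elsewhere). One-sided because enrichment is
#' the question asked — depleted chromosomes then report p near 1. The
#' universe is the set of tested sites, not all genomic CCGG motifs. The p
#' equals the hypergeometric upper-tail sum and is computed with
#' `stats::phyper`.
#'
#' @param results an `msre_diff` (or data frame with `chrom`, `significant`).
#' @param alpha enrichment significance level (default 0.05).
#' @param chroms chromosome universe to report on; defaults to the
#'   chromosomes present in `results`. Chromosomes with zero tested sites
#'   are excluded with a warning.
#' @return data frame of class `msre_enrichment`: `chrom`, `n_sig`,
#'   `n_total`, `p_enrich`, `enriched`.
#' @export
chromosome_enrichment <- function(results, alpha = 0.05, chroms = NULL) {
  if (is.null(chroms)) chroms <- chrom_order(results$chrom)
  n_tot <- as.vector(table(factor(results$chrom, levels = chroms)))
  empty <- n_tot == 0
  if (any(empty)) {
    warnf("excluding chromosome(s) with zero tested sites: %s",
          paste(chroms[empty], collapse = ", "))
    chroms <- chroms[!empty]; n_tot <- n_tot[!empty]
  }
  sig_tab <- table(factor(results$chrom[results$significant], levels = chroms))
  n_sig <- as.vector(sig_tab)
  S <- sum(results$significant)   # white balls
  N <- nrow(results)
  # P(X >= n_sig) with X ~ Hypergeometric(S sig, N - S nonsig, draw n_tot)
  p <- stats::phyper(n_sig - 1, S, N - S, n_tot, lower.tail = FALSE)
  out <- data.frame(chrom = chroms, n_sig = n_sig, n_total = n_tot,
                    p_enrich = p, enriched = p < alpha,
                    stringsAsFactors = FALSE)
  structure(out, alpha = alpha, class = c("msre_enrichment", "data.frame"))
}

#' @export
print.msre_enrichment <- function(x, ...) {
  cat(sprintf("Chromosome enrichment (one-sided Fisher, alpha = %g): %d of %d enriched\n",
              attr(x, "alpha"), sum(x$enriched), nrow(x)))
  if (any(x$enriched)) {
    cat("  enriched:", paste(x$chrom[x$enriched], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Chromosomes enriched under both conditions
#'
#' @param enrich_a,enrich_b `msre_enrichment` tables (e.g. MB and MT).
#' @return character vector of chromosome names enriched in both.
#' @export
enrichment_intersection <- function(enrich_a, enrich_b) {
  both <- intersect(enrich_a$chrom[enrich_a$enriched],
                    enrich_b$chrom[enrich_b$enriched])
  chrom_order(c(both, both))[seq_along(both)]
}

#' Mean methylation-load logFC over fixed-width genomic bins
#'
#' A site with 1-based position p maps to bin `floor((p - 1) / bin_width)`;
#' bins are anchored at coordinate 0 of each chromosome, trailing partial
#' bins included, empty bins omitted.
#'
#' @param results data frame with `chrom`, `pos`, `logFC` (all tested sites).
#' @param bin_width bin width in bp (default 1 Mbp).
#' @return data frame of class `msre_bins`: `chrom`, `bin_index`,
#'   `bin_start`, `bin_end` (0-based half-open), `n_sites`, `mean_logfc`.
#' @export
bin_logfc <- function(results, bin_width = 1e6) {
  bin <- floor((results$pos - 1) / bin_width)
  key <- paste(results$chrom, bin, sep = "\r")
  agg_mean <- tapply(results$logFC, key, mean)
  agg_n <- tapply(results$logFC, key, length)
  parts <- strsplit(names(agg_mean), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[[`, character(1), 1L)
  idx <- as.integer(vapply(parts, `[[`, character(1), 2L))
  out <- data.frame(chrom = chrom, bin_index = idx,
                    bin_start = idx * bin_width,
                    bin_end = (idx + 1) * bin_width,
                    n_sites = as.integer(agg_n),
                    mean_logfc = as.numeric(agg_mean),
                    stringsAsFactors = FALSE)
  out <- out[order(factor(out$chrom, levels = chrom_order(out$chrom)),
                   out$bin_index), ]
  rownames(out) <- NULL
  structure(out, bin_width = bin_width, class = c("msre_bins", "data.frame"))
}

#' Flag bins outside the genome-wide 95% interval
#'
#' Computes the mean mu and standard deviation sigma of bin `mean_logfc`
#' genome-wide and flags a bin hypermethylated if its value exceeds
#' mu + 1.96 sigma, hypomethylated below mu - 1.96 sigma, else neutral
#' (`method = "sd"`, the default). `method = "percentile"` uses the
#' empirical [2.5%, 97.5%] interval of the bin values instead.
#'
#' @param bins an `msre_bins` table with >= 2 rows.
#' @param method "sd" or "percentile".
#' @return the bins with a `flag` column (hyper/hypo/neutral); attributes
#'   `center`, `lower`, `upper`.
#' @export
flag_bins <- function(bins, method = c("sd", "percentile")) {
  method <- match.arg(method)
  if (nrow(bins) < 2) stopf("need at least 2 bins to flag")
  v <- bins$mean_logfc
  if (method == "sd") {
    mu <- mean(v); sigma <- stats::sd(v)
    if (sigma == 0) {
      warnf("zero variance across bins; all flagged neutral")
      lo <- -Inf; hi <- Inf
    } else {
      lo <- mu - 1.96 * sigma; hi <- mu + 1.96 * sigma
    }
  } else {
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    mu <- mean(v); lo <- qs[1]; hi <- qs[2]
  }
  bins$flag <- ifelse(v > hi, "hyper", ifelse(v < lo, "hypo", "neutral"))
  attr(bins, "center") <- mu; attr(bins, "lower") <- lo; attr(bins, "upper") <- hi
  bins
}

#' Correlation of regional methylation loads between two analyses
#'
#' Pearson correlation of `mean_logfc` over the bins present in both tables
#' (matched on chromosome and bin index).
#'
#' @param bins_a,bins_b `msre_bins` tables.
#' @return list with `r` (Pearson correlation) and `n_shared`.
#' @export
bin_correlation <- function(bins_a, bins_b) {
  m <- merge(bins_a[, c("chrom", "bin_index", "mean_logfc")],
             bins_b[, c("chrom", "bin_index", "mean_logfc")],
             by = c("chrom", "bin_index"))
  if (nrow(m) < 3) stopf("fewer than 3 shared bins (%d)", nrow(m))
  list(r = stats::cor(m$mean_logfc.x, m$mean_logfc.y), n_shared = nrow(m))
}

#' Per-chromosome scatter of binned loads
#'
#' @param x a flagged `msre_bins`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.msre_bins <- function(x, ...) {
  xs <- seq_len(nrow(x))
  cols <- c(hyper = "red3", hypo = "blue3", neutral = "grey60")
  flag <- if (is.null(x$flag)) rep("neutral", nrow(x)) else x$flag
  graphics::plot(xs, x$mean_logfc, col = cols[flag], pch = 20,
                 xlab = "1 Mbp bin (genome order)", ylab = "mean logFC", ...)
  for (a in c("lower", "upper", "center")) {
    if (!is.null(attr(x, a))) graphics::abline(h = attr(x, a), lty = 3)
  }
  invisible(x)
}
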