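#' Build TSS-promoter windows over the site catalogue
#'
#' A promoter window spans the 1-based positions [tss - w, tss + w]
#' inclusive (2w + 1 positions; symmetric, hence strand-independent).
#' Windows with fewer than `min_sites` member catalogue sites are dropped
#' (methylation of a promoter summarized by one site is not a load). At most
#' one transcript per gene is retained: the transcript whose window holds
#' the most member sites, ties broken by smaller TSS position, then
#' lexicographic transcript ID — a deterministic rule, stable under row
#' shuffling of the input.
#'
#' @param tss_table data frame with `gene_id`, `transcript_id`, `chrom`,
#'   `tss_pos` (1-based) and optionally `class`.
#' @param catalog an `msre_catalog` (or data frame with `chrom`, `pos`,
#'   `site_id`).
#' @param w window half-width in bp (default 1000).
#' @param min_sites minimum member sites for a window to be tested
#'   (default 2).
#' @return data frame of class `msre_promoters`: one row per retained gene
#'   with `gene_id`, `transcript_id`, `chrom`, `tss_pos`, `window_start`,
#'   `window_end` (1-based inclusive), `n_sites`, `class`, and a list column
#'   `member_sites` of site IDs.
#' @export
build_windows <- function(tss_table, catalog, w = 1000, min_sites = 2) {
  need <- c("gene_id", "transcript_id", "chrom", "tss_pos")
  if (!all(need %in% names(tss_table))) {
    stopf("tss_table must carry columns: %s", paste(need, collapse = ", "))
  }
  lo <- as.integer(tss_table$tss_pos - w)
  if (any(lo < 1)) {
    warnf("%d window(s) truncated at position 1", sum(lo < 1))
    lo <- pmax(lo, 1L)
  }
  hi <- as.integer(tss_table$tss_pos + w)
  gr_win <- GenomicRanges::GRanges(tss_table$chrom, IRanges::IRanges(lo, hi))
  gr_sites <- GenomicRanges::GRanges(catalog$chrom,
                                     IRanges::IRanges(catalog$pos, catalog$pos))
  hits <- GenomicRanges::findOverlaps(gr_win, gr_sites, ignore.strand = TRUE)
  members <- split(catalog$site_id[S4Vectors::subjectHits(hits)],
                   factor(S4Vectors::queryHits(hits),
                          levels = seq_len(nrow(tss_table))))
  n_sites <- lengths(members)
  out <- data.frame(gene_id = tss_table$gene_id,
                    transcript_id = tss_table$transcript_id,
                    chrom = tss_table$chrom, tss_pos = tss_table$tss_pos,
                    window_start = lo, window_end = hi,
                    n_sites = as.integer(n_sites),
                    class = if (is.null(tss_table$class)) NA_character_
                            else tss_table$class,
                    stringsAsFactors = FALSE)
  out$member_sites <- lapply(members, function(v) sort(unname(v)))
  out <- out[out$n_sites >= min_sites, , drop = FALSE]
  # one transcript per gene: most member sites, then smallest TSS, then ID
  ord <- order(out$gene_id, -out$n_sites, out$tss_pos, out$transcript_id)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  out <- out[order(factor(out$chrom, levels = chrom_order(out$chrom)),
                   out$tss_pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, w = w, min_sites = min_sites,
            class = c("msre_promoters", "data.frame"))
}

#' Per-window, per-sample promoter methylation loads
#'
#' The load of a window in a sample is the arithmetic mean of its member
#' sites' scores in that sample.
#'
#' @param scores an `msre_scores`.
#' @param windows an `msre_promoters` from [build_windows()].
#' @return numeric matrix (windows x libraries), rownames `gene_id`.
#' @export
promoter_loads <- function(scores, windows) {
  mat <- scores$scores
  loads <- matrix(NA_real_, nrow(windows), ncol(mat),
                  dimnames = list(windows$gene_id, colnames(mat)))
  for (i in seq_len(nrow(windows))) {
    idx <- match(windows$member_sites[[i]], rownames(mat))
    if (anyNA(idx)) {
      miss <- windows$member_sites[[i]][is.na(idx)][1L]
      stopf("member site '%s' of window for gene '%s' missing from score matrix",
            miss, windows$gene_id[i])
    }
    loads[i, ] <- colMeans(mat[idx, , drop = FALSE])
  }
  loads
}

#' Two-group testing of promoter loads
#'
#' Applies the two-group LRT and logFC to each window's load vector, with
#' BH-FDR adjustment across windows.
#'
#' @param loads matrix from [promoter_loads()].
#' @param design design data frame matching the load columns (`group`).
#' @param windows optional `msre_promoters` supplying per-gene metadata for
#'   the output (matched by rowname / gene_id).
#' @param alpha FDR significance level (default 0.05).
#' @param p_method see [lrt_two_group()].
#' @return data frame of class `msre_prom_test`: `gene_id`, `tss` ("chrom:pos"
#'   when `windows` given), `logFC`, `lrt_stat`, `pvalue`, `fdr`,
#'   `significant`, `class`.
#' @export
test_promoters <- function(loads, design, windows = NULL, alpha = 0.05,
                           p_method = c("f", "chisq")) {
  p_method <- match.arg(p_method)
  g <- design$group
  if (sum(g == "CP") < 2 || sum(g == "control") < 2) {
    stopf("each group needs at least 2 samples")
  }
  is_cp <- g == "CP"; is_cn <- g == "control"
  n <- ncol(loads)
  m_cp <- rowMeans(loads[, is_cp, drop = FALSE])
  m_cn <- rowMeans(loads[, is_cn, drop = FALSE])
  gm <- rowMeans(loads)
  eps <- 1e-8
  rss0 <- rowSums((loads - gm)^2)
  rss1 <- rowSums((loads[, is_cp, drop = FALSE] - m_cp)^2) +
    rowSums((loads[, is_cn, drop = FALSE] - m_cn)^2)
  stat <- n * log((rss0 + eps) / (rss1 + eps))
  p <- lrt_pvalue(rss0, rss1, n, stat, p_method, eps)
  q <- bh_fdr(p)
  out <- data.frame(gene_id = rownames(loads), logFC = m_cp - m_cn,
                    lrt_stat = stat, pvalue = p, fdr = q,
                    significant = q < alpha, stringsAsFactors = FALSE)
  if (!is.null(windows)) {
    m <- match(out$gene_id, windows$gene_id)
    out$tss <- sprintf("%s:%d", windows$chrom[m], windows$tss_pos[m])
    out$class <- windows$class[m]
    out$n_sites <- windows$n_sites[m]
  }
  rownames(out) <- NULL
  structure(out, alpha = alpha, p_method = p_method,
            class = c("msre_prom_test", "data.frame"))
}

#' @export
print.msre_prom_test <- function(x, ...) {
  cat(sprintf("Promoter-load testing: %d windows, %d significant (FDR < %g)\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    print(sig[order(sig$fdr),
              intersect(c("gene_id", "tss", "logFC", "fdr", "class"), names(sig))],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}
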