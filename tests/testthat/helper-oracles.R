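# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# O(L) sliding-window motif scan on a plain character string
naive_ccgg_scan <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 4) return(integer(0))
  pos <- integer(0)
  for (i in seq_len(n - 3)) {
    if (substr(seq, i, i + 3) == "CCGG") pos <- c(pos, i)
  }
  pos
}

# BH step-up by direct definition: q_i = min over ranks j with p_(j) >= p_(i)
# of m * p_(j) / j, clipped at 1
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- (m * ps / seq_len(m))[seq(i, m)]
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# hypergeometric upper tail P(X >= a) by direct log-binomial summation
brute_hyper_tail <- function(a, n_white, n_black, n_draw) {
  ks <- max(a, max(0, n_draw - n_black)):min(n_draw, n_white)
  if (length(ks) == 0 || a > min(n_draw, n_white)) return(0)
  sum(exp(lchoose(n_white, ks) + lchoose(n_black, n_draw - ks) -
            lchoose(n_white + n_black, n_draw)))
}

# quadratic-scan containment: 1-based site pos p in 0-based half-open [s, e)
brute_containment <- function(pos, starts, ends) {
  hits <- matrix(FALSE, length(pos), length(starts))
  for (i in seq_along(pos)) {
    for (j in seq_along(starts)) {
      hits[i, j] <- starts[j] <= pos[i] - 1 && pos[i] - 1 < ends[j]
    }
  }
  hits
}

# exhaustive agglomerative clustering with complete linkage on a tiny matrix;
# returns the sorted merge heights
brute_complete_linkage_heights <- function(mat) {
  clusters <- lapply(seq_len(nrow(mat)), identity)
  d <- as.matrix(dist(mat))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# build an msre_scores object from a bare matrix and group labels, placing
# all sites on one synthetic chromosome unless positions are supplied
make_scores <- function(mat, groups, conditions = NULL,
                        chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(nrow(mat)) * 100L
  rownames(mat) <- sprintf("%s.%010d", chrom, pos)
  design <- data.frame(column_id = paste0("S", seq_len(ncol(mat))),
                       sample_id = paste0("S", seq_len(ncol(mat))),
                       group = groups, stringsAsFactors = FALSE)
  if (!is.null(conditions)) design$condition <- conditions
  colnames(mat) <- design$column_id
  score_matrix(mat, design)
}

# small catalogue straight from coordinates
make_catalog <- function(chrom, pos) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos),
                   site_id = format_site_id(chrom, pos),
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$pos)
  structure(df[ord, ], class = c("msre_catalog", "data.frame"))
}
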