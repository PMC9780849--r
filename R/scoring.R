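#' Methylation score matrices
#'
#' The commercial scoring step behind the assay is undisclosed; this package's
#' documented stand-in converts intact-fragment depth to counts-per-million
#' and takes log2(CPM + 0.5). Because methylated CCGG sites resist HpaII
#' digestion, intact-fragment coverage — and hence the score — increases with
#' the probability that the site is methylated, and the log scale puts the
#' response in the operating range of log-scaled expression data that the
#' downstream linear-model machinery assumes. Externally computed score
#' matrices can be supplied through [score_matrix()], so the stand-in is
#' swappable.
#'
#' @name scoring
#' @keywords internal
NULL

new_score_matrix <- function(scores, design) {
  if (ncol(scores) != nrow(design)) {
    stopf("score matrix has %d columns but design has %d rows",
          ncol(scores), nrow(design))
  }
  bad <- setdiff(unique(design$group), c("control", "CP"))
  if (length(bad) > 0) stopf("unknown group label in design: '%s'", bad[[1L]])
  if (!is.null(design$condition)) {
    badc <- setdiff(unique(design$condition), c("MB", "MT"))
    if (length(badc) > 0) stopf("unknown condition label in design: '%s'", badc[[1L]])
  }
  if (anyNA(scores)) stopf("score matrix contains missing values")
  loc <- parse_site_id(rownames(scores))
  ord <- order_sites(loc$chrom, loc$pos)
  structure(list(scores = scores[ord, , drop = FALSE],
                 chrom = loc$chrom[ord], pos = loc$pos[ord],
                 design = design),
            class = "msre_scores")
}

#' Construct a score matrix from externally computed scores
#'
#' @param scores numeric matrix (log2 scale), rownames canonical site IDs,
#'   one column per library.
#' @param design data frame with one row per column of `scores`, carrying
#'   `group` (control/CP) and optionally `condition` (MB/MT).
#' @return an `msre_scores` object.
#' @export
score_matrix <- function(scores, design) new_score_matrix(scores, design)

#' Depth-to-score normalization (log2 CPM stand-in)
#'
#' Per library j: CPM_ij = depth_ij / sum_i(depth_ij) * 1e6;
#' score_ij = log2(CPM_ij + 0.5). Library-size differences cancel:
#' multiplying a library's depths by any constant leaves its scores
#' unchanged. The pseudo-count 0.5 keeps retained-but-shallow sites finite.
#'
#' @param depth non-negative integer matrix (sites x libraries), rownames
#'   canonical site IDs.
#' @param design design data frame (one row per column).
#' @return an `msre_scores` object.
#' @export
normalize_depth <- function(depth, design) {
  if (any(depth < 0)) stopf("depths must be non-negative")
  libsize <- colSums(depth)
  if (any(libsize == 0)) {
    stopf("all-zero depth column for sample '%s'",
          colnames(depth)[which(libsize == 0)[1L]])
  }
  cpm <- sweep(depth, 2L, libsize, "/") * 1e6
  scores <- log2(cpm + 0.5)
  new_score_matrix(scores, design)
}

#' Restrict a depth matrix to sites covered in every library
#'
#' Retains exactly the sites with depth >= `min_depth` in all columns — the
#' common-site intersection across subjects that downstream per-site testing
#' operates on.
#'
#' @param depth depth matrix (sites x libraries).
#' @param min_depth minimum depth required in every library (default 1).
#' @return the filtered matrix; attribute `n_retained` records the count.
#' @export
common_sites <- function(depth, min_depth = 1) {
  keep <- rowSums(depth >= min_depth) == ncol(depth)
  if (!any(keep)) {
    stopf("no sites retained at min_depth = %d in every library; lower min_depth",
          min_depth)
  }
  out <- depth[keep, , drop = FALSE]
  msg_stage("common_sites", "%d of %d sites retained (min_depth = %d)",
            nrow(out), nrow(depth), min_depth)
  attr(out, "n_retained") <- nrow(out)
  out
}

#' Subset a score matrix by cell condition
#'
#' @param scores an `msre_scores`.
#' @param condition condition label (e.g. "MB").
#' @return an `msre_scores` restricted to that condition's libraries.
#' @export
subset_condition <- function(scores, condition) {
  if (is.null(scores$design$condition)) stopf("design carries no condition column")
  keep <- scores$design$condition == condition
  if (!any(keep)) stopf("no libraries with condition '%s'", condition)
  new_score_matrix(scores$scores[, keep, drop = FALSE],
                   scores$design[keep, , drop = FALSE])
}

#' @export
print.msre_scores <- function(x, ...) {
  cat(sprintf("Methylation score matrix: %d sites x %d libraries (log2 scale)\n",
              nrow(x$scores), ncol(x$scores)))
  tab <- table(x$design$group,
               if (is.null(x$design$condition)) "all" else x$design$condition)
  print(tab)
  invisible(x)
}

#' @export
dim.msre_scores <- function(x) dim(x$scores)

#' Write / read a score or depth matrix as TSV
#'
#' First column `site_id`, one column per library.
#'
#' @param m matrix with site-ID rownames (or `msre_scores`).
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix; writers return the
#'   path invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (methods::is(m, "msre_scores")) m <- m$scores
  write_tsv(data.frame(site_id = rownames(m), m, check.names = FALSE), path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
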