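#' Catalogue of HpaII-target CpG sites
#'
#' HpaII cuts unmethylated CCGG motifs, so MSRE-seq interrogates exactly the
#' CpG dinucleotides inside C(CpG)G restriction sites. A site catalogue is the
#' ordered table of these motifs in a reference genome: one row per occurrence
#' of the literal motif `CCGG` on the forward strand (the motif is its own
#' reverse complement, so a forward scan is strand-complete), anchored at the
#' 1-based position of the first C.
#'
#' @name site-catalog
#' @keywords internal
NULL

new_site_catalog <- function(chrom, pos, chrom_lengths) {
  ord <- order_sites(chrom, pos)
  df <- data.frame(chrom = chrom[ord], pos = as.integer(pos[ord]),
                   stringsAsFactors = FALSE)
  df$site_id <- format_site_id(df$chrom, df$pos)
  if (anyDuplicated(df$site_id)) stopf("duplicate site IDs in catalogue")
  structure(df, chrom_lengths = chrom_lengths,
            class = c("msre_catalog", "data.frame"))
}

#' Scan a genome for HpaII CCGG target sites
#'
#' Finds every occurrence of the literal motif `CCGG` (case-insensitive) on
#' the forward strand of each sequence. Windows containing `N` never match:
#' HpaII recognition cannot be inferred across ambiguity. Sites on excluded
#' chromosomes (sex chromosomes by default, to avoid spurious cohort signal
#' from mixed-sex designs) are omitted.
#'
#' @param genome a `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or the path to a FASTA file.
#' @param exclude_chroms chromosome names to drop from the catalogue
#'   (default `c("chrX", "chrY")`). Use `character(0)` to keep everything.
#' @return an object of class `msre_catalog`: a data frame with columns
#'   `chrom`, `pos` (1-based position of the first C) and `site_id`, sorted by
#'   (chrom, pos), with a `chrom_lengths` attribute.
#' @examples
#' cat <- scan_ccgg_sites(c(chr1 = "TTCCGGACCGG"), exclude_chroms = character(0))
#' cat$pos  # 3 and 8
#' @export
scan_ccgg_sites <- function(genome, exclude_chroms = c("chrX", "chrY")) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    if (!file.exists(genome)) stopf("FASTA file not found: %s", genome)
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stopf("character genome input must be named by chromosome")
    bad_char <- regmatches(genome, regexpr("[^ACGTNacgtn]", genome))
    bad_char <- unlist(bad_char)
    if (length(bad_char) > 0) {
      stopf("non-nucleotide character in genome: '%s'", bad_char[[1L]])
    }
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stopf("genome must be a FASTA path, named character vector, or DNAStringSet")
  }
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    stopf("empty genome: no sequence to scan")
  }
  if (is.null(names(genome))) stopf("genome sequences must be named")
  freq <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
  present <- names(freq)[freq > 0]
  bad <- setdiff(present, c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stopf("non-nucleotide character in genome: '%s'", bad[[1L]])
  }
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  keep <- !(names(genome) %in% exclude_chroms)
  scanned <- genome[keep]
  hits <- Biostrings::vmatchPattern("CCGG", scanned, fixed = TRUE)
  starts <- lapply(hits, BiocGenerics::start)
  n_per <- lengths(starts)
  new_site_catalog(chrom = rep(names(scanned), n_per),
                   pos = unlist(starts, use.names = FALSE),
                   chrom_lengths = chrom_lengths)
}

#' Canonical site identifier
#'
#' A site is identified as `<chrom>.<pos>` with the 1-based position
#' zero-padded to 10 digits, e.g. `chr2.0003882321`.
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s) of the first C of the CCGG motif.
#' @return character vector of site IDs.
#' @export
format_site_id <- function(chrom, pos) {
  pos <- as.numeric(pos)
  if (any(is.na(pos)) || any(pos < 1) || any(pos != floor(pos))) {
    stopf("pos must be a positive integer")
  }
  if (any(pos >= 1e10)) stopf("pos exceeds 10 digits: %s", format(max(pos), scientific = FALSE))
  sprintf("%s.%010d", chrom, as.integer(pos))
}

#' Parse a canonical site identifier
#'
#' Inverse of [format_site_id()].
#'
#' @param site_id character vector of IDs like `chr12.0003241735`.
#' @return data frame with columns `chrom` (character) and `pos` (integer).
#' @export
parse_site_id <- function(site_id) {
  m <- regmatches(site_id, regexec("^(.+)\\.([0-9]{10})$", site_id))
  ok <- lengths(m) == 3L
  if (!all(ok)) stopf("malformed site ID: '%s'", site_id[!ok][[1L]])
  chrom <- vapply(m, `[[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[[`, character(1), 3L))
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' @export
print.msre_catalog <- function(x, ...) {
  cl <- attr(x, "chrom_lengths")
  cat(sprintf("HpaII CCGG site catalogue: %d sites on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (!is.null(cl)) {
    cat(sprintf("  genome: %d record(s), %.3g bp\n", length(cl), sum(as.numeric(cl))))
  }
  tab <- table(factor(x$chrom, levels = chrom_order(x$chrom)))
  cat("  sites per chromosome:\n")
  print(tab)
  invisible(x)
}

#' Write / read a site catalogue as TSV
#'
#' @param catalog an `msre_catalog`.
#' @param path output (input) file path.
#' @return `read_catalog` returns an `msre_catalog`; the writers return the
#'   path invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv(catalog[, c("chrom", "pos", "site_id")], path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read_tsv(path)
  new_site_catalog(df$chrom, df$pos, chrom_lengths = NULL)
}

#' @rdname write_catalog
#' @details `write_catalog_bed` emits the 4-bp motif intervals in BED
#'   convention (0-based half-open): `[pos - 1, pos + 3)`.
#' @export
write_catalog_bed <- function(catalog, path) {
  bed <- data.frame(chrom = catalog$chrom,
                    start = catalog$pos - 1L,
                    end = catalog$pos + 3L,
                    name = catalog$site_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
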