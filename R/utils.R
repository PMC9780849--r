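# internal helpers shared across modules

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All package randomness flows through this; no function
# leaves the global RNG perturbed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

msg_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# deterministic ordering of chromosome names: chr1..chr22 numerically, then
# the rest alphabetically (chrX, chrY, others)
chrom_order <- function(chroms) {
  u <- unique(chroms)
  num <- suppressWarnings(as.integer(sub("^chr", "", u)))
  ord <- order(is.na(num), num, u)
  u[ord]
}

order_sites <- function(chrom, pos) {
  order(factor(chrom, levels = chrom_order(chrom)), pos)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, fill = TRUE, ...)
}
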