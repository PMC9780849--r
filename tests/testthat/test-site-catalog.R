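test_that("scan finds exactly the naive sliding-window matches", {
  expect_identical(scan_ccgg_sites(c(chr1 = "AAAATTTT"),
                                   exclude_chroms = character(0))$pos,
                   integer(0))
  cat <- scan_ccgg_sites(c(chr1 = "TTCCGGACCGG"), exclude_chroms = character(0))
  expect_identical(cat$pos, c(3L, 8L))
  expect_identical(cat$site_id, c("chr1.0000000003", "chr1.0000000008"))

  set.seed(42)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 3000, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    got <- scan_ccgg_sites(stats::setNames(s, "chrZ"),
                           exclude_chroms = character(0))
    expect_identical(got$pos, naive_ccgg_scan(s))
  }
})

test_that("scan handles case, overlapping motif context and multi-record input", {
  cat <- scan_ccgg_sites(c(chr1 = "ttccggaCCGG", chr2 = "CCGGCCGG"),
                         exclude_chroms = character(0))
  expect_identical(cat$chrom, c("chr1", "chr1", "chr2", "chr2"))
  expect_identical(cat$pos, c(3L, 8L, 1L, 5L))
  # motif split by N never matches
  expect_identical(nrow(scan_ccgg_sites(c(chr1 = "CCNGG"),
                                        exclude_chroms = character(0))), 0L)
})

test_that("reverse-complementing the genome preserves the site count", {
  set.seed(7)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
    fwd <- scan_ccgg_sites(c(chr1 = s), exclude_chroms = character(0))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rev <- scan_ccgg_sites(c(chr1 = rc), exclude_chroms = character(0))
    expect_identical(nrow(rev), nrow(fwd))
    # positions map to L - pos - 2 (1-based anchor of the palindromic motif)
    expect_identical(sort(rev$pos), sort(nchar(s) - fwd$pos - 2L))
  }
})

test_that("sex chromosomes are excluded by default and configurably", {
  g <- c(chr1 = "CCGGAA", chrX = "CCGGAA", chrY = "TTCCGG")
  expect_identical(unique(scan_ccgg_sites(g)$chrom), "chr1")
  expect_setequal(unique(scan_ccgg_sites(g, exclude_chroms = "chr1")$chrom),
                  c("chrX", "chrY"))
  # excluded records still contribute their lengths
  expect_named(attr(scan_ccgg_sites(g), "chrom_lengths"),
               c("chr1", "chrX", "chrY"))
})

test_that("scan rejects empty or non-nucleotide input with the offending character", {
  expect_error(scan_ccgg_sites(c(chr1 = "")), "empty genome")
  expect_error(scan_ccgg_sites(c(chr1 = "ACGTRACGT"), exclude_chroms = character(0)),
               "'R'")
})

test_that("FASTA files round-trip through the scanner", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 assembled", "TTCCGGA", "CCGG", ">chr2", "AAAA"), fa)
  cat <- scan_ccgg_sites(fa, exclude_chroms = character(0))
  # wrapped sequence is concatenated before scanning
  expect_identical(cat$pos, c(3L, 8L))
  expect_identical(unname(attr(cat, "chrom_lengths")), c(11L, 4L))
})

test_that("site IDs format, parse and round-trip", {
  expect_identical(format_site_id("chr2", 3882321), "chr2.0003882321")
  expect_identical(format_site_id("chr1", 1), "chr1.0000000001")
  expect_identical(parse_site_id("chr12.0003241735"),
                   data.frame(chrom = "chr12", pos = 3241735L,
                              stringsAsFactors = FALSE))
  expect_error(format_site_id("chr1", 1e10), "10 digits")
  expect_error(format_site_id("chr1", 0), "positive")
  expect_error(parse_site_id("chrX.12"), "chrX.12")

  set.seed(11)
  chrom <- sample(paste0("chr", c(1:22, "X")), 50, replace = TRUE)
  pos <- sample.int(2^31 - 1, 50)
  rt <- parse_site_id(format_site_id(chrom, pos))
  expect_identical(rt$chrom, chrom)
  expect_identical(rt$pos, as.integer(pos))
})

test_that("catalogue TSV and BED serialization round-trip", {
  cat <- scan_ccgg_sites(c(chr2 = "CCGGTTCCGG", chr10 = "ACCGGA"),
                         exclude_chroms = character(0))
  tsv <- tempfile(fileext = ".tsv")
  write_catalog(cat, tsv)
  back <- read_catalog(tsv)
  expect_identical(back$site_id, cat$site_id)

  bed <- tempfile(fileext = ".bed")
  write_catalog_bed(cat, bed)
  intervals <- read_bed(bed)
  expect_identical(intervals$start, cat$pos - 1L)
  expect_identical(intervals$end, cat$pos + 3L)
  expect_identical(intervals$name, cat$site_id)
})

test_that("generated genomes contain exactly their planted motifs", {
  cfg <- sim_config(chrom_spec = data.frame(name = c("chr1", "chr2"),
                                            length = c(50000, 30000)),
                    site_density = 0.5, seed = 3)
  g <- random_genome(cfg)
  cat <- scan_ccgg_sites(g, exclude_chroms = character(0))
  expect_identical(cat$pos, naive_ccgg_scan(g[["chr1"]]) |> c(naive_ccgg_scan(g[["chr2"]])))
  expect_gt(nrow(cat), 0)
})
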