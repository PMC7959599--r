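test_that("FASTA write/read round-trips ids, bases and metadata", {
  recs <- seq_records(c("p1", "p 2 with spaces", "p3"),
                      c("ACGTACGT", "ttgacca", "GGGCCC"),
                      species = c("yeast", NA, "human"),
                      label = c(1L, NA, 0L))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, fa)
  back <- read_fasta(fa)
  expect_equal(back$id, recs$id)
  expect_equal(back$bases, toupper(recs$bases))
  expect_equal(back$species, recs$species)
  expect_equal(back$label, recs$label)
})

test_that("read_fasta handles case, order, empty files and bad content", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">b", "acgt", ">a", "TTAA"), fa)
  recs <- read_fasta(fa)
  expect_equal(recs$id, c("b", "a"))  # order preserved, not sorted
  expect_equal(recs$bases, c("ACGT", "TTAA"))

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_equal(nrow(read_fasta(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("", "this is not fasta"), bad)
  expect_error(read_fasta(bad), "line 2")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")

  ws_empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">y", "", ">z", "AA"), ws_empty)
  expect_error(read_fasta(ws_empty), "empty sequence")
})

test_that("write_fasta of an empty record set yields a readable empty file", {
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seq_records(character(), character()), fa)
  expect_true(file.exists(fa))
  expect_equal(nrow(read_fasta(fa)), 0)
})

test_that("clean_records drops wrong-length and non-ACGT records, idempotently", {
  recs <- seq_records(c("ok", "hasN", "short"),
                      c(strrep("ACGT", 250), paste0(strrep("A", 999), "N"),
                        strrep("A", 999)))
  expect_message(kept <- clean_records(recs, 1000), "kept 1/3")
  expect_equal(kept$id, "ok")
  # identity on all-valid input, and idempotent
  suppressMessages({
    again <- clean_records(kept, 1000)
    expect_equal(again, kept)
    expect_equal(clean_records(recs[0, ], 1000), recs[0, ])
  })
})

test_that("promoter windows follow strand-relative -700/+300 arithmetic", {
  plus <- promoter_interval(10000, "+")
  expect_equal(c(plus$start, plus$end), c(9300, 10300))
  minus <- promoter_interval(10000, "-")
  expect_equal(c(minus$start, minus$end), c(9700, 10700))
  expect_equal(plus$end - plus$start, 1000)
  expect_error(promoter_interval(500, "+"), "below coordinate 0")
  # window length is constant for arbitrary inputs on both strands
  tss <- seq(1000, 9000, by = 517)
  iv <- promoter_interval(tss, rep(c("+", "-"), length.out = length(tss)))
  expect_true(all(iv$end - iv$start == 1000))
})

test_that("extract_promoters takes the strand-aware 5' end and reverse-complements", {
  genome <- seq_records("chr1", paste(rep(c("A", "C", "G", "T"), 75), collapse = ""))
  bed <- data.frame(chrom = "chr1", start = c(100L, 50L), end = c(120L, 80L),
                    name = c("g_plus", "g_minus"), score = ".",
                    strand = c("+", "-"))
  pr <- extract_promoters(genome, bed, upstream = 20, downstream = 10)
  expect_equal(nchar(pr$bases), c(30, 30))
  # plus: window [80, 110) verbatim
  expect_equal(pr$bases[1], substr(genome$bases, 81, 110))
  # minus: TSS = end-1 = 79; window [69, 99) reverse-complemented
  fwd <- substr(genome$bases, 70, 99)
  expect_equal(pr$bases[2], as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd))))
  expect_error(extract_promoters(genome, transform(bed, chrom = "chrX"),
                                 upstream = 20, downstream = 10),
               "not in genome")
})

test_that("random subsequence sampling is uniform-valid, verbatim and seeded", {
  genome <- seq_records("chr1", random_acgt(1, 10000, seed = 9))
  bg <- sample_random_subsequences(genome, n = 600, length = 1000, seed = 4)
  expect_equal(nrow(bg), 600)
  expect_true(all(nchar(bg$bases) == 1000))
  # every window exists verbatim in the forward strand
  expect_true(all(vapply(bg$bases[1:25], function(w)
    grepl(w, genome$bases, fixed = TRUE), logical(1))))
  bg2 <- sample_random_subsequences(genome, n = 600, length = 1000, seed = 4)
  expect_identical(bg, bg2)
  expect_error(sample_random_subsequences(genome, 5, length = 20000),
               "no valid window")
  # rejection budget: genome saturated with N-adjacent windows
  ngen <- seq_records("chrN", paste0(strrep("AN", 3000)))
  expect_error(suppressWarnings(
    sample_random_subsequences(ngen, 5, length = 100, seed = 1,
                               max_tries = 50)), "budget|no valid window")
})
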