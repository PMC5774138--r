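# build a mapping + collapsed pair from (sequence, start, strand, count)
make_sr_data <- function(df, chrom = "chr1") {
  cr <- make_collapsed(list(L1 = tapply(df$count, df$sequence, sum)))
  mp <- data.frame(sequence = df$sequence, chrom = chrom, start = df$start,
                   end = df$start + nchar(df$sequence), strand = df$strand,
                   stringsAsFactors = FALSE)
  mp <- unique(mp)
  list(mapping = mp, reads = cr)
}

test_that("two dense regions far apart give two tight clusters", {
  set.seed(111)
  mk <- function(base, n) {
    data.frame(sequence = vapply(1:n, function(i) random_dna(29), character(1)),
               start = base + sort(sample(0:1950, n)), strand = "+", count = 1)
  }
  df <- rbind(mk(1000, 100), mk(15000, 100))
  d <- make_sr_data(df)
  cl <- detect_clusters(d$mapping, d$reads, genome_length = 1e6)
  expect_equal(nrow(cl), 2L)
  expect_true(all(diff(cl$start) > 0))
  # disjoint, sorted intervals
  expect_true(all(cl$end[-nrow(cl)] < cl$start[-1]))
  expect_gte(min(cl$count), 100 - 5)
})

test_that("uniform sparse scatter yields no clusters", {
  set.seed(112)
  df <- data.frame(
    sequence = vapply(1:40, function(i) random_dna(29), character(1)),
    start = seq(1, 4e5, length.out = 40), strand = "+", count = 1)
  d <- make_sr_data(df)
  cl <- detect_clusters(d$mapping, d$reads, genome_length = 4e5)
  expect_equal(nrow(cl), 0L)
})

test_that("cluster statistics: strand bias, 1U fraction, mean length", {
  set.seed(113)
  seqs <- paste0("T", vapply(1:50, function(i) random_dna(28), character(1)))
  df <- data.frame(sequence = seqs, start = 500 + seq(0, 980, 20),
                   strand = "+", count = 2)
  d <- make_sr_data(df)
  cl <- detect_clusters(d$mapping, d$reads, genome_length = 1e6)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$u1_fraction, 1)
  expect_equal(cl$strand_bias, 1)
  expect_equal(cl$majority_strand, "+")
  expect_equal(cl$mean_length, 29)
})

test_that("fraction in clusters hits the trivial extremes", {
  set.seed(114)
  seqs <- vapply(1:30, function(i) random_dna(29), character(1))
  df <- data.frame(sequence = seqs, start = 100 + seq(0, 580, 20),
                   strand = "+", count = 1)
  d <- make_sr_data(df)
  inside <- data.frame(chrom = "chr1", start = 50, end = 1000,
                       count = 30, majority_strand = "+")
  expect_equal(fraction_in_clusters(d$mapping, d$reads, inside), 1)
  outside <- data.frame(chrom = "chr1", start = 5000, end = 6000,
                        count = 0, majority_strand = "+")
  expect_equal(fraction_in_clusters(d$mapping, d$reads, outside), 0)
  expect_warning(
    f23 <- fraction_in_clusters(d$mapping, d$reads, inside,
                                focal_length = 23),
    "undefined")
  expect_true(is.na(f23))
})

test_that("fraction in clusters grows as min_reads loosens", {
  set.seed(115)
  mk <- function(base, n) data.frame(
    sequence = vapply(seq_len(n), function(i) random_dna(29), character(1)),
    start = base + sort(sample(0:900, n)), strand = "+", count = 1)
  df <- rbind(mk(1000, 80), mk(20000, 30))
  d <- make_sr_data(df)
  f_strict <- fraction_in_clusters(d$mapping, d$reads,
    detect_clusters(d$mapping, d$reads, min_reads = 50, genome_length = 1e6))
  f_loose <- fraction_in_clusters(d$mapping, d$reads,
    detect_clusters(d$mapping, d$reads, min_reads = 20, genome_length = 1e6))
  expect_gte(f_loose, f_strict)
})

test_that("feature overlap agrees with a brute-force interval oracle", {
  set.seed(116)
  gm <- data.frame(gene = "g1", feature = "exon", chrom = "chr1",
                   start = c(1000, 3000), end = c(1500, 3600), strand = "+")
  df <- data.frame(
    sequence = vapply(1:120, function(i) random_dna(sample(c(22, 29), 1)),
                      character(1)),
    start = sample(0:4000, 120), strand = "+", count = 1)
  d <- make_sr_data(df)
  fe <- feature_enrichment(d$mapping, d$reads, gm, "exon")
  # brute-force recomputation of the focal fraction
  len <- nchar(d$mapping$sequence)
  ov <- vapply(seq_len(nrow(d$mapping)), function(i) {
    overlaps_any(d$mapping$start[i], d$mapping$end[i], gm$start, gm$end)
  }, logical(1))
  focal <- len == 29
  expect_equal(fe$focal_fraction, mean(ov[focal]))
  expect_equal(fe$background_fraction, mean(ov[!focal]))
})

test_that("feature enrichment detects planted exon bias and flags empties", {
  set.seed(117)
  gm <- data.frame(gene = "g1", feature = "exon", chrom = "chr1",
                   start = 1000, end = 3000, strand = "+")
  in_ex <- data.frame(
    sequence = vapply(1:160, function(i) random_dna(29), character(1)),
    start = sample(1000:2950, 160), strand = "+", count = 1)
  out_ex <- data.frame(
    sequence = vapply(1:40, function(i) random_dna(29), character(1)),
    start = sample(5000:20000, 40), strand = "+", count = 1)
  bg <- data.frame(
    sequence = vapply(1:200, function(i) random_dna(22), character(1)),
    start = sample(0:20000, 200), strand = "+", count = 1)
  d <- make_sr_data(rbind(in_ex, out_ex, bg))
  fe <- feature_enrichment(d$mapping, d$reads, gm, "exon")
  expect_lt(fe$p, 0.01)

  expect_error(feature_enrichment(d$mapping, d$reads, gm[0, ], "exon"),
               "empty")
  fe2 <- feature_enrichment(d$mapping, d$reads, gm, "exon",
                            focal_length = 31)
  expect_equal(fe2$status, "undefined")
})
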