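make_hits <- function(n, query = "q1", qlen = 71, start0 = 100, gap = 200,
                      span = NULL) {
  span <- span %||% qlen
  starts <- start0 + gap * (seq_len(n) - 1)
  data.frame(query = query, chrom = "chr1", start = starts,
             end = starts + span, strand = "+", score = span,
             evalue = 1e-20, qlen = qlen, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a verbatim planted query is a significant self-hit", {
  set.seed(21)
  hp <- make_hairpin_seq(23, 15)
  g <- c(chr1 = paste0(random_dna(400), hp, random_dna(400)))
  hits <- homology_search(c(q1 = hp), g)
  expect_gte(nrow(hits), 1)
  best <- hits[which.min(hits$evalue), ]
  expect_lt(best$evalue, 1e-6)
  expect_gte(best$score, 0.9 * nchar(hp))
  expect_equal(best$start, 400)
  expect_error(homology_search(c(q1 = hp), c(chr1 = "")), "empty genome")
})

test_that("the 30-hit query filter is exact at its boundary", {
  cfg <- annot_config()
  h30 <- make_hits(30)
  expect_equal(nrow(filter_hits(h30, cfg)), 0L)
  h29 <- make_hits(29)
  expect_equal(nrow(filter_hits(h29, cfg)), 29L)
})

test_that("the hairpin length filter is exact at its boundary", {
  cfg <- annot_config()
  h55 <- make_hits(1, qlen = 55, span = 55)
  expect_equal(nrow(filter_hits(h55, cfg)), 0L)
  h56 <- make_hits(1, qlen = 56, span = 56)
  expect_equal(nrow(filter_hits(h56, cfg)), 1L)
  expect_equal(nrow(filter_hits(h56[0, ], cfg)), 0L)
})

test_that("hit filters are evaluated jointly and commute", {
  cfg <- annot_config()
  hits <- rbind(make_hits(35, query = "qa"),            # multi-hit query
                make_hits(5, query = "qb", qlen = 40, span = 40),  # short
                make_hits(7, query = "qc"))             # survives
  out <- filter_hits(hits, cfg)
  expect_setequal(unique(out$query), "qc")
  expect_equal(nrow(out), 7L)
  # joint-set oracle: survivors = hits minus multi-hit queries minus short
  n_hits <- table(hits$query)
  keep <- as.vector(n_hits[hits$query]) < cfg$max_hits_per_query &
    pmax(hits$qlen, hits$end - hits$start) >= cfg$min_hairpin_len
  expect_equal(nrow(out), sum(keep))
  # idempotence
  expect_equal(filter_hits(out, cfg)$query, out$query)
})

test_that("hairpin extension pads the aligned interval to the query length", {
  cfg <- annot_config()
  h <- make_hits(1, qlen = 80, span = 60)
  out <- filter_hits(h, cfg)
  expect_equal(out$hp_end - out$hp_start, 80)
  expect_equal(out$hp_start, h$start - 10)
})

test_that("abundance filter boundary and family rescue", {
  hp <- data.frame(id = c("h1", "h2", "h3", "h4"),
                   family = c("mir-1", "mir-2", "mir-2", NA),
                   stringsAsFactors = FALSE)
  counts <- matrix(c(99, 5000, 0, 0), ncol = 1,
                   dimnames = list(hp$id, "L1"))
  out <- abundance_filter(hp, counts)
  expect_setequal(out$id, c("h2", "h3"))  # h1 at 99 dies; h3 rescued by h2

  counts["h1", 1] <- 100
  expect_true("h1" %in% abundance_filter(hp, counts)$id)

  empty <- matrix(0, 0, 1, dimnames = list(NULL, "L1"))
  expect_equal(nrow(abundance_filter(hp, empty)), 0L)
})

test_that("arm assignment picks the most abundant side reads with a tie rule", {
  set.seed(31)
  arm <- random_dna(23)
  hp_seq <- paste0("AAAAA", arm, random_dna(15), revcomp(arm), "AAAAA")
  g <- c(chr1 = paste0(random_dna(100), hp_seq, random_dna(100)))
  hairpins <- data.frame(id = "h1", chrom = "chr1", start = 100,
                         end = 100 + nchar(hp_seq), strand = "+",
                         loop_start = 28, loop_end = 44,
                         stringsAsFactors = FALSE)
  x <- substr(hp_seq, 6, 28)       # full 5p arm
  y <- substr(hp_seq, 7, 28)       # 1-nt 5' trimmed variant
  z <- substr(hp_seq, 44, 66)      # 3p arm
  cr <- make_collapsed(list(L1 = setNames(c(100, 10, 50), c(x, y, z))))
  m <- map_exact(cr$counts$sequence, g)
  out <- assign_arms(hairpins, m, cr)
  expect_equal(out$mature_5p, x)
  expect_equal(out$mature_3p, z)

  # count tie resolves to the lexicographically smaller sequence
  cr2 <- make_collapsed(list(L1 = setNames(c(100, 100, 50), c(x, y, z))))
  out2 <- assign_arms(hairpins, map_exact(cr2$counts$sequence, g), cr2)
  expect_equal(out2$mature_5p, min(x, y))
})

test_that("diverged queries still annotate and shuffled genomes stay silent", {
  set.seed(51)
  cfg_sim <- sim_config(seed = 15, genome_length = 20000, n_hairpin_loci = 6,
                        n_novel_loci = 0, repeat_copies = 0, de_spec = list(),
                        arm_switch_spec = list(), depth_per_library = 0)
  gt <- generate_genome(cfg_sim)
  q <- truth_precursors(gt$truth, divergence = 0.1, seed = 99)
  hits <- homology_search(q, gt$genome)
  hit_queries <- unique(hits$query[hits$evalue < 1e-6])
  expect_gte(length(hit_queries), 5)  # >= 5/6 diverged queries recover

  shuffled <- c(chr1 = shuffle_dinucleotide(
    substr(as.character(gt$genome[["chr1"]]), 1, 10000)))
  hits0 <- homology_search(q, shuffled)
  ex <- extract_hairpins(filter_hits(hits0, annot_config(),
                                     c(chr1 = 10000L)), shuffled)
  expect_equal(nrow(ex$hairpins), 0L)
})

test_that("dinucleotide shuffle preserves dinucleotide composition", {
  set.seed(61)
  s <- random_dna(500)
  sh <- shuffle_dinucleotide(s)
  dinuc <- function(x) {
    ch <- strsplit(x, "")[[1]]
    sort(table(paste0(ch[-length(ch)], ch[-1])))
  }
  expect_equal(dinuc(sh), dinuc(s))
  expect_equal(nchar(sh), nchar(s))
})
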