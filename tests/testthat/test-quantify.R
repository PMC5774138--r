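test_that("reads count fully to every containing hairpin", {
  set.seed(71)
  core <- random_dna(22)
  # two hairpin intervals, both containing a copy of the read
  g <- c(chr1 = paste0(random_dna(40), core, random_dna(60), core,
                       random_dna(40)))
  hairpins <- data.frame(id = c("h1", "h2"), chrom = "chr1",
                         start = c(30, 110), end = c(80, 160),
                         strand = "+", stringsAsFactors = FALSE)
  cr <- make_collapsed(list(L1 = setNames(7, core)))
  m <- map_exact(core, g)
  cm <- count_to_hairpins(m, hairpins, cr)
  expect_equal(unname(cm[, "L1"]), c(7, 7))
  cmf <- count_to_hairpins(m, hairpins, cr, policy = "fractional")
  expect_equal(unname(cmf[, "L1"]), c(3.5, 3.5))
})

test_that("family read counts tally multi-mapping reads once per family", {
  set.seed(72)
  core <- random_dna(22)
  g <- c(chr1 = paste0(random_dna(40), core, random_dna(60), core,
                       random_dna(40)))
  hairpins <- data.frame(id = c("h1", "h2"), chrom = "chr1",
                         start = c(30, 110), end = c(80, 160),
                         strand = "+", family = "mir-427",
                         stringsAsFactors = FALSE)
  cr <- make_collapsed(list(L1 = setNames(7, core)))
  fr <- family_read_counts(map_exact(core, g), hairpins, cr)
  expect_equal(unname(fr["mir-427", "L1"]), 7)
})

test_that("RPM normalisation uses the genome-matched denominator", {
  cm <- matrix(c(10, 20), 1, 2, dimnames = list("h1", c("L1", "L2")))
  rpm <- rpm_normalize(cm, c(L1 = 1e5, L2 = 2e5))
  expect_equal(unname(rpm[1, ]), c(100, 100))
  expect_error(rpm_normalize(cm, c(L1 = 1e5)), "cover")
})

test_that("isomiR offsets are signed end shifts in hairpin coordinates", {
  expect_equal(classify_isomir(10, 32, 10, 32), list(offset5 = 0, offset3 = 0))
  expect_equal(classify_isomir(12, 32, 10, 32), list(offset5 = 2, offset3 = 0))
  expect_equal(classify_isomir(9, 30, 10, 32), list(offset5 = -1, offset3 = -2))
  expect_error(classify_isomir(40, 60, 10, 32), "overlap")
})

test_that("isomiR classification is inverse-consistent", {
  set.seed(73)
  for (i in 1:50) {
    r_start <- sample(5:20, 1); r_end <- r_start + sample(20:23, 1)
    o5 <- sample(-5:5, 1); o3 <- sample(-5:5, 1)
    v_start <- r_start + o5; v_end <- r_end + o3
    got <- classify_isomir(v_start, v_end, r_start, r_end)
    expect_equal(r_start + got$offset5, v_start)
    expect_equal(r_end + got$offset3, v_end)
  }
})

test_that("isomiR table recovers planted offset distribution shape", {
  sim <- small_sim()
  ann <- annotate_hairpins(truth_precursors(sim$gt$truth), sim$gt$genome,
                           sim$pp$reads, sim$mapping)
  iso <- isomir_table(ann$hairpins, sim$mapping, sim$pp$reads)
  expect_true(all(abs(iso$offset5) <= 5) && all(abs(iso$offset3) <= 5))
  libs <- names(sim$pp$reads$totals)
  tot <- rowSums(iso[, libs])
  canon <- sum(tot[iso$offset5 == 0 & iso$offset3 == 0]) / sum(tot)
  # canonical form planted at 0.70 of arm reads
  expect_gt(canon, 0.6)
  expect_lt(canon, 0.8)
})

test_that("arm switching is detected from planted profiles only", {
  tissue_map <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  mk <- function(id, ra, rb, n = 200) {
    do.call(rbind, lapply(names(tissue_map), function(l) {
      r <- if (tissue_map[[l]] == "A") ra else rb
      data.frame(hairpin = id, library = l, n5 = r * n, n3 = (1 - r) * n,
                 ratio = r, stringsAsFactors = FALSE)
    }))
  }
  prof <- rbind(mk("switched", 0.9, 0.05), mk("flat", 0.5, 0.5),
                mk("low", 0.9, 0.05, n = 10))
  out <- detect_arm_switch(prof, tissue_map, "A", "B")
  expect_equal(out$status[out$hairpin == "switched"], "switched")
  expect_equal(out$status[out$hairpin == "flat"], "not_switched")
  expect_equal(out$status[out$hairpin == "low"], "insufficient_data")
  expect_error(detect_arm_switch(prof, tissue_map, "A", "C"), "absent")
})

test_that("profile views compute family fractions and exclusions", {
  counts <- matrix(c(670, 330), 2, 1, dimnames = list(c("h1", "h2"), "L1"))
  rpm <- counts * 10
  fams <- c(h1 = "mir-427", h2 = "mir-7")
  v <- profile_views(counts, rpm, fams, c(L1 = "NC"))
  expect_equal(unname(v$family_fraction["mir-427", "NC"]), 0.67)
  v2 <- profile_views(counts, rpm, fams, c(L1 = "NC"), exclude = "mir-427",
                      n = 10)
  expect_equal(v2$top$family, "mir-7")
  expect_equal(v2$top$rank, 1L)
})

test_that("hairpin count column sums never exceed genome-matched totals", {
  sim <- small_sim()
  ann <- annotate_hairpins(truth_precursors(sim$gt$truth), sim$gt$genome,
                           sim$pp$reads, sim$mapping)
  prof <- size_class_profile(sim$pp$reads, sim$mapping)
  fr <- family_read_counts(sim$mapping, ann$hairpins, sim$pp$reads)
  # read-level family counts are bounded by the genome-matched totals
  expect_true(all(colSums(fr) <= prof$genome_matched + 1e-9))
})
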