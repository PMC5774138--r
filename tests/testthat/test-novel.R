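test_that("a uniform read pile forms one stack with perfect 5' homogeneity", {
  set.seed(101)
  core <- random_dna(22)
  g <- c(chr1 = paste0(random_dna(100), core, random_dna(100)))
  cr <- make_collapsed(list(L1 = setNames(100, core)))
  st <- find_stacks(map_exact(core, g), cr)
  expect_equal(nrow(st), 1L)
  expect_equal(st$count, 100)
  expect_equal(st$homogeneity, 1)
  expect_equal(st$dominant, core)
})

test_that("scattered single reads form no stacks", {
  set.seed(102)
  g <- c(chr1 = random_dna(5000))
  seqs <- vapply(seq(1, 4000, 500), function(p) substr(g, p, p + 21),
                 character(1))
  cr <- make_collapsed(list(L1 = setNames(rep(1, length(seqs)), seqs)))
  st <- find_stacks(map_exact(cr$counts$sequence, g), cr, min_count = 10)
  expect_equal(nrow(st), 0L)
})

test_that("masked annotation intervals produce no stacks", {
  set.seed(103)
  core <- random_dna(22)
  g <- c(chr1 = paste0(random_dna(100), core, random_dna(100)))
  cr <- make_collapsed(list(L1 = setNames(100, core)))
  mask <- data.frame(chrom = "chr1", start = 90, end = 140)
  st <- find_stacks(map_exact(core, g), cr, mask = mask)
  expect_equal(nrow(st), 0L)
})

test_that("low 5'-homogeneity stacks are rejected as imprecise", {
  stack <- data.frame(chrom = "chr1", start = 10, end = 40, strand = "+",
                      count = 50, dominant = strrep("A", 22),
                      dominant_count = 25, homogeneity = 0.5,
                      stringsAsFactors = FALSE)
  stack$members <- list(data.frame())
  out <- call_novel(stack[1, ], c(chr1 = random_dna(400)))
  expect_s3_class(out, "novel_reject")
  expect_equal(out$reason, "imprecise_processing")
})

test_that("unstructured loci are rejected and planted hairpins are called", {
  set.seed(104)
  # unstructured: an A/C-only region cannot base pair with itself at all,
  # so every candidate window around the stack folds to nothing
  ac_region <- paste(sample(c("A", "C"), 500, replace = TRUE), collapse = "")
  g_flat <- c(chr1 = paste0(random_dna(100), ac_region, random_dna(100)))
  core <- substr(g_flat, 100 + 240 + 1, 100 + 240 + 22)
  cr <- make_collapsed(list(L1 = setNames(60, core)))
  st <- find_stacks(map_exact(core, g_flat), cr)
  expect_equal(nrow(st), 1L)
  out <- call_novel(st[1, ], g_flat)
  expect_s3_class(out, "novel_reject")
  expect_equal(out$reason, "no_hairpin")

  # planted: expressed 5p arm of a clean stem-loop
  arm <- random_dna(23)
  hp <- paste0(arm, random_dna(15), revcomp(arm))
  g <- c(chr1 = paste0(random_dna(150), hp, random_dna(150)))
  cr2 <- make_collapsed(list(L1 = setNames(80, arm)))
  st2 <- find_stacks(map_exact(arm, g), cr2)
  out2 <- call_novel(st2[1, ], g)
  expect_s3_class(out2, "novel_prediction")
  expect_equal(out2$mature, arm)
  # the called hairpin overlaps the planted stem-loop and contains the arm
  expect_lt(out2$start, 150 + nchar(hp))
  expect_gt(out2$end, 150)
  expect_lte(out2$start, 150)
  expect_gte(out2$end, 150 + 23)
})

test_that("longest-window selection matches exhaustive enumeration", {
  set.seed(105)
  arm <- random_dna(23)
  hp <- paste0(arm, random_dna(15), revcomp(arm))
  g <- c(chr1 = paste0(random_dna(300), hp, random_dna(300)))
  cr <- make_collapsed(list(L1 = setNames(80, arm)))
  st <- find_stacks(map_exact(arm, g), cr)
  pred <- call_novel(st[1, ], g)
  # enumerate the same candidate windows and find the longest passing one
  gchr <- as.character(g)
  span <- st$end[1] - st$start[1]
  best_len <- 0
  for (L in seq(60, 200, 10)) {
    if (L < span + 16) next
    for (orient in c("star3", "star5")) {
      ws <- if (orient == "star3") st$start[1] - 8 else st$end[1] + 8 - L
      ws <- max(0, min(ws, nchar(gchr) - L))
      seqn <- substr(gchr, ws + 1, ws + L)
      fold <- fold_hairpin(seqn)
      if (validate_hairpin(fold)$pass) {
        h_start <- st$start[1] - ws; h_end <- st$end[1] - ws
        a5 <- fold$stem_arms$arm5; a3 <- fold$stem_arms$arm3
        in5 <- h_start + 1 >= a5[1] - 4 && h_end <= a5[2] + 4
        in3 <- h_start + 1 >= a3[1] - 4 && h_end <= a3[2] + 4
        if (in5 || in3) best_len <- max(best_len, L)
      }
    }
  }
  expect_equal(pred$length, best_len)
})

test_that("star support requires the 2-nt 3' overhang geometry", {
  set.seed(106)
  arm <- random_dna(23)
  loop <- random_dna(15)
  hp <- paste0(arm, loop, revcomp(arm))
  g <- c(chr1 = paste0(random_dna(150), hp, random_dna(150)))
  # mature = 5p arm; candidate star = 3p reads with and without overhang
  star_blunt <- revcomp(arm)                         # blunt duplex
  star_oh <- substr(hp, 41, 61)                      # 3' end at pos 61
  cr <- make_collapsed(list(L1 = setNames(c(80, 20), c(arm, star_oh))))
  st <- find_stacks(map_exact(cr$counts$sequence, g), cr, max_gap = 30,
                    max_span = 70)
  pred <- call_novel(st[1, ], g)
  expect_s3_class(pred, "novel_prediction")
  # partner of mature 5' end is the last 3p base; star 3' must end 2 nt
  # beyond it, which an in-stem read cannot; blunt-ended stars fail
  cr2 <- make_collapsed(list(L1 = setNames(c(80, 20), c(arm, star_blunt))))
  st2 <- find_stacks(map_exact(cr2$counts$sequence, g), cr2, max_gap = 30,
                     max_span = 70)
  pred2 <- call_novel(st2[1, ], g)
  expect_s3_class(pred2, "novel_prediction")
  expect_false(pred2$star_support)
})

test_that("grouping counts: fixture with one 3-copy family and 2 singletons", {
  mk_pred <- function(id, chrom, start, mature) {
    data.frame(id = id, chrom = chrom, start = start, end = start + 80,
               strand = "+", mature = mature, mature_arm = "5p",
               mature_h_start = 10, mature_h_end = 10 + nchar(mature),
               star_support = FALSE, hairpin_length = 80,
               sequence = strrep("A", 80), stringsAsFactors = FALSE)
  }
  set.seed(107)
  fam <- random_dna(22); s1 <- random_dna(22); s2 <- random_dna(22)
  preds <- rbind(mk_pred("p1", "chr1", 100, fam),
                 mk_pred("p2", "chr1", 5000, fam),
                 mk_pred("p3", "chr2", 300, fam),
                 mk_pred("p4", "chr2", 9000, s1),
                 mk_pred("p5", "chr3", 100, s2))
  g <- group_predictions(preds)
  expect_equal(g$n_hairpins, 5L)
  expect_equal(g$n_groups, 3L)
  expect_equal(g$n_unique_matures, 3L)

  # near-identical matures at one locus group by coordinate offsets
  preds2 <- rbind(mk_pred("p1", "chr1", 100, s1), mk_pred("p2", "chr1", 100, s2))
  preds2$mature_h_start[2] <- 12
  preds2$mature_h_end[2] <- 12 + 22
  g2 <- group_predictions(preds2)
  expect_equal(g2$n_groups, 1L)
  expect_equal(g2$n_unique_matures, 2L)

  # disjoint matures stay apart
  preds3 <- rbind(mk_pred("p1", "chr1", 100, s1), mk_pred("p2", "chr1", 900, s2))
  expect_equal(group_predictions(preds3)$n_groups, 2L)
})

test_that("grouping count invariants hold on random prediction sets", {
  set.seed(108)
  for (trial in 1:10) {
    n <- sample(2:12, 1)
    matures <- replicate(n, if (runif(1) < 0.4) "ACGTACGTACGTACGTACGTAC"
                         else random_dna(22))
    preds <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(id = paste0("p", i), chrom = "chr1", start = i * 500,
                 end = i * 500 + 80, strand = "+", mature = matures[i],
                 mature_arm = "5p", mature_h_start = 10,
                 mature_h_end = 32, star_support = FALSE,
                 hairpin_length = 80, sequence = strrep("A", 80),
                 stringsAsFactors = FALSE)
    }))
    g <- group_predictions(preds)
    expect_lte(g$n_groups, g$n_hairpins)
    expect_lte(g$n_groups, g$n_unique_matures + 0L)
    expect_gte(g$n_unique_matures, g$n_groups)
  }
})
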