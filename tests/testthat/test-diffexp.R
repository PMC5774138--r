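test_that("size factors: identity, scaling and the median-of-ratios oracle", {
  k <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(size_factors(k)), c(1, 1))

  k2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  sf <- size_factors(k2)
  expect_equal(unname(sf["b"] / sf["a"]), 2)

  set.seed(91)
  k3 <- matrix(rnbinom(600, mu = 150, size = 10), 100, 6,
               dimnames = list(NULL, paste0("L", 1:6)))
  expect_equal(unname(size_factors(k3)), unname(size_factors_oracle(k3)),
               tolerance = 0.05)
})

test_that("all-zero rows are dropped from the test output", {
  k <- rbind(h1 = c(5, 7, 6, 30, 28, 25), h2 = rep(0, 6))
  colnames(k) <- paste0("L", 1:6)
  res <- nb_wald_test(k, setNames(rep(1, 6), colnames(k)),
                      paste0("L", 1:3), paste0("L", 4:6))
  expect_equal(res$id, "h1")
  expect_error(nb_wald_test(k, setNames(rep(1, 6), colnames(k)),
                            "L1", paste0("L", 4:6)), "at least 2")
})

test_that("planted log2 fold changes are recovered", {
  set.seed(92)
  n <- 300
  mu <- rep(200, n)
  lfc <- c(rep(2, 50), rep(0, 250))
  k <- sapply(1:6, function(j) {
    up <- if (j > 3) 2^lfc else 1
    rnbinom(n, mu = mu * up, size = 10)
  })
  dimnames(k) <- list(paste0("h", 1:n), paste0("L", 1:6))
  sf <- size_factors(k)
  res <- nb_wald_test(k, sf, paste0("L", 1:3), paste0("L", 4:6))
  est <- median(res$log2FC[match(paste0("h", 1:50), res$id)], na.rm = TRUE)
  expect_lt(abs(est - 2), 0.3)
})

test_that("null p-values are roughly uniform at small replicate numbers", {
  set.seed(93)
  n <- 400
  k <- matrix(rnbinom(6 * n, mu = 200, size = 10), n, 6,
              dimnames = list(paste0("h", 1:n), paste0("L", 1:6)))
  res <- nb_wald_test(k, size_factors(k), paste0("L", 1:3), paste0("L", 4:6))
  expect_gt(mean(res$pvalue > 0.5), 0.4)
  expect_lt(mean(res$pvalue < 0.05), 0.1)
})

test_that("BH adjustment matches the hand-computed example and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(94)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
})

test_that("enrichment sets follow the pairwise up/down logic", {
  tissues <- c("NC", "neural", "ectoderm", "blastula")
  ids <- c("nc_only", "shared", "flat")
  mk <- function(a, b, up_in_b) {
    # log2FC is b over a
    data.frame(id = ids,
               log2FC = ifelse(ids %in% up_in_b, 3, 0),
               padj = ifelse(ids %in% up_in_b, 1e-6, 0.9),
               stringsAsFactors = FALSE)
  }
  pw <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    a <- tissues[i]; b <- tissues[j]
    up_b <- character(0)
    if (b == "NC") up_b <- c("nc_only", "shared")
    if (b == "blastula" && a %in% c("neural", "ectoderm")) up_b <- "shared"
    res <- mk(a, b, up_b)
    if (a == "NC") {  # up in a means negative log2FC
      up_a <- c("nc_only", "shared")
      if (b == "blastula") up_a <- "nc_only"
      res$log2FC <- ifelse(ids %in% up_a, -3, 0)
      res$padj <- ifelse(ids %in% up_a, 1e-6, 0.9)
    }
    pw[[paste0(a, "_vs_", b)]] <- res
  }
  sets <- build_enrichment_sets(pw)
  expect_equal(sets$nc_enriched, "nc_only")
  expect_equal(sets$shared_nc_blastula, "shared")
  expect_error(build_enrichment_sets(pw[-1]), "missing comparison")
})

test_that("planted DE lands in the right enrichment set end to end", {
  sim <- small_sim()
  ann <- annotate_hairpins(truth_precursors(sim$gt$truth), sim$gt$genome,
                           sim$pp$reads, sim$mapping)
  cm <- count_to_hairpins(sim$mapping, ann$hairpins, sim$pp$reads)
  tm <- setNames(rep(sim$cfg$tissues, each = 2), names(sim$pp$reads$totals))
  de <- de_all_pairs(cm, tm)
  expect_length(de, 6)
  expect_true(all(vapply(de, function(r) all(r$padj >= r$pvalue), logical(1))))
})
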