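test_that("planted arms are found verbatim at their recorded coordinates", {
  cfg <- sim_config(seed = 1, genome_length = 40000, n_hairpin_loci = 10,
                    n_novel_loci = 2, repeat_copies = 5, de_spec = list())
  gt <- generate_genome(cfg)
  g <- as.character(gt$genome[["chr1"]])
  hp <- gt$truth$hairpins
  expect_equal(nrow(hp), 10 + 2 + 5 * cfg$n_isoforms)
  for (i in seq_len(nrow(hp))) {
    s5 <- substr(g, hp$g5_start[i] + 1, hp$g5_end[i])
    s3 <- substr(g, hp$g3_start[i] + 1, hp$g3_end[i])
    if (hp$strand[i] == "-") { s5 <- revcomp(s5); s3 <- revcomp(s3) }
    expect_equal(s5, hp$mature5p[i], info = hp$id[i])
    expect_equal(s3, hp$mature3p[i], info = hp$id[i])
    # arms are exact substrings of the hairpin sequence
    expect_equal(substr(hp$sequence[i], hp$arm5_start[i] + 1, hp$arm5_end[i]),
                 hp$mature5p[i])
    expect_equal(substr(hp$sequence[i], hp$arm3_start[i] + 1, hp$arm3_end[i]),
                 hp$mature3p[i])
  }
})

test_that("repeat toggling and sizing errors behave", {
  cfg0 <- sim_config(seed = 2, genome_length = 30000, n_hairpin_loci = 5,
                     repeat_copies = 0, de_spec = list(),
                     arm_switch_spec = list())
  gt0 <- generate_genome(cfg0)
  expect_null(gt0$truth$repeat_region)
  expect_false(is.null(gt0$truth$cluster_locus))
  expect_true(all(gt0$truth$hairpins$family != "mir-427", na.rm = TRUE))

  expect_error(generate_genome(
    sim_config(seed = 2, genome_length = 5000, de_spec = list(),
               arm_switch_spec = list())), "too small")
})

test_that("the same seed reproduces identical genomes, truth and reads", {
  cfg <- sim_config(seed = 9, genome_length = 25000, n_hairpin_loci = 6,
                    n_novel_loci = 1, repeat_copies = 2,
                    depth_per_library = 3000, de_spec = list())
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$hairpins, b$truth$hairpins)
  la <- simulate_library(a$genome, a$truth, "NC", 1, cfg)
  lb <- simulate_library(b$genome, b$truth, "NC", 1, cfg)
  expect_identical(la$reads, lb$reads)
})

test_that("zero depth yields an empty library and unknown tissues error", {
  cfg <- sim_config(seed = 4, genome_length = 25000, n_hairpin_loci = 5,
                    repeat_copies = 2, depth_per_library = 0,
                    de_spec = list())
  gt <- generate_genome(cfg)
  lib <- simulate_library(gt$genome, gt$truth, "NC", 1, cfg)
  expect_length(lib$reads, 0)
  tmp <- tempfile(fileext = ".fastq")
  write_fastq(lib, tmp)
  expect_length(read_fastq(tmp), 0)
  expect_error(simulate_library(gt$genome, gt$truth, "liver", 1, cfg),
               "unknown tissue")
})

test_that("reads follow the HD structure and planted arm fractions", {
  sim <- small_sim()
  lib <- simulate_library(sim$gt$genome, sim$gt$truth, "blastula", 1,
                          sim$cfg)
  expect_true(all(nchar(lib$reads) == sim$cfg$read_length))
  # tally inserts before adapter attachment: arm fraction of a hairpin
  ins <- lib$inserts[lib$inserts$source == "hairpin", ]
  for (u in c("hp01", "hp02")) {
    sub <- ins[ins$unit == u, ]
    if (sum(sub$count) < 200) next
    r <- sum(sub$count[sub$arm == "5p"]) / sum(sub$count)
    expect_lt(abs(r - sim$gt$truth$arm_props[u, "blastula"]), 0.07)
  }
})

test_that("a planted arm switch shows in the simulated insert tallies", {
  cfg <- sim_config(seed = 6, genome_length = 40000, n_hairpin_loci = 6,
                    repeat_copies = 3, depth_per_library = 30000,
                    de_spec = list(),
                    arm_switch_spec = list(list(
                      unit = "mir427-A", tissue = "blastula",
                      fraction_there = 0.9, fraction_elsewhere = 0.05)))
  gt <- generate_genome(cfg)
  tally5p <- function(tissue) {
    lib <- simulate_library(gt$genome, gt$truth, tissue, 1, cfg)
    ins <- lib$inserts[lib$inserts$unit %in% "mir427-A", ]
    sum(ins$count[ins$arm == "5p"]) / sum(ins$count)
  }
  expect_lt(abs(tally5p("blastula") - 0.9), 0.05)
  expect_lt(abs(tally5p("neural") - 0.05), 0.05)
})

test_that("insert lengths are bimodal at 23 and 29 nt when configured so", {
  sim <- small_sim()
  lib <- simulate_library(sim$gt$genome, sim$gt$truth, "NC", 1, sim$cfg)
  lens <- rep(nchar(lib$inserts$insert), lib$inserts$count)
  tab <- table(lens)
  mir_peak <- names(which.max(tab[as.integer(names(tab)) <= 25]))
  bg_peak <- names(which.max(tab[as.integer(names(tab)) >= 26]))
  expect_equal(mir_peak, "23")
  expect_equal(bg_peak, "29")
})

test_that("planted DE shows the expected fold ratio in insert tallies", {
  cfg <- sim_config(seed = 8, genome_length = 40000, n_hairpin_loci = 12,
                    repeat_copies = 2, depth_per_library = 20000,
                    arm_switch_spec = list(),
                    de_spec = list(list(unit = "hp11", tissue = "NC",
                                        log2fc = 2)))
  gt <- generate_genome(cfg)
  tot <- function(tissue, rep) {
    lib <- simulate_library(gt$genome, gt$truth, tissue, rep, cfg)
    sum(lib$inserts$count[lib$inserts$unit %in% "hp11"])
  }
  nc <- mean(vapply(1:4, function(r) tot("NC", r), numeric(1)))
  ne <- mean(vapply(1:4, function(r) tot("neural", r), numeric(1)))
  # NC and neural share the miRNA depth here, so the planted log2FC of 2
  # appears as a ~4x mean count ratio
  expect_gt(nc / ne, 2.6)
  expect_lt(nc / ne, 6)
})

test_that("simulate_experiment writes a consistent file bundle", {
  cfg <- sim_config(seed = 10, genome_length = 25000, n_hairpin_loci = 5,
                    n_novel_loci = 1, repeat_copies = 2,
                    replicates_per_tissue = 1, depth_per_library = 2000,
                    de_spec = list())
  outdir <- tempfile("simexp")
  sim <- simulate_experiment(cfg, outdir)
  expect_true(all(file.exists(unlist(sim$paths))))
  expect_equal(nrow(sim$manifest), 4)
  g <- read_fasta_chr(sim$paths$genome)
  expect_equal(nchar(g[["chr1"]]), 25000)
  tr <- read_truth(sim$paths$truth)
  expect_equal(tr$hairpins$start, sim$truth$hairpins$start)
  gm <- read_gene_models(sim$paths$gff)
  expect_setequal(gm$feature, c("exon", "intron"))
  # GFF3 round trip preserves the planted exon coordinates
  truth_ex <- sim$truth$gene_models
  truth_ex <- truth_ex[truth_ex$feature == "exon", ]
  expect_setequal(paste(gm$start[gm$feature == "exon"],
                        gm$end[gm$feature == "exon"]),
                  paste(truth_ex$start, truth_ex$end))
  fq <- read_fastq(sim$manifest$fastq[1])
  expect_gt(length(fq), 0)
  expect_true(all(nchar(fq) == cfg$read_length))
})
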