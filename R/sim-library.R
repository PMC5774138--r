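#' Simulate one HD-adapter small RNA-seq library
#'
#' Draws per-hairpin insert counts from a negative binomial
#' (`var = m + alpha * m^2`) around the tissue's expected means, splits
#' each hairpin's reads between 5p and 3p arms according to the planted
#' arm proportions, applies isomiR end offsets, adds the ~29-nt background
#' (partly from the planted cluster locus, partly uniform over the
#' genome), and assembles fixed-length reads of the form
#' `[4 degenerate nt][insert][4 degenerate nt][3' adapter ...]` truncated
#' to the configured read length (adapter run-through).
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character) from
#'   [generate_genome()].
#' @param truth The matching `sim_truth`.
#' @param tissue Tissue label; must be one of `config$tissues`.
#' @param replicate Replicate index (1-based).
#' @param config The [sim_config()] used to build the genome.
#' @return An object of class `sim_library`: list with `reads` (character
#'   vector of read sequences), `names`, `tissue`, `replicate` and
#'   `inserts`, a data.frame tally of the simulated inserts before adapter
#'   attachment (columns `insert`, `source`, `unit`, `arm`, `offset5`,
#'   `offset3`, `count`, `recoverable`); `recoverable` is FALSE for inserts
#'   that contain the adapter octamer and are therefore lost to trimming
#'   by construction.
#' @export
simulate_library <- function(genome, truth, tissue, replicate, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!tissue %in% config$tissues) {
    stopf("unknown tissue '%s' (expected one of %s)", tissue,
          paste(config$tissues, collapse = ", "))
  }
  genome_chr <- as_genome_chr(genome)
  gseq <- genome_chr[[truth$chrom]]
  t_idx <- match(tissue, config$tissues)
  set.seed(derive_seed(config$seed, 100L + t_idx * 20L + replicate))

  units <- truth$units
  mu <- truth$expected_mean[, tissue]
  arm5f <- truth$arm_props[, tissue]
  disp <- config$nb_dispersion

  n_unit <- if (disp > 0) {
    rnbinom(nrow(units), mu = mu, size = 1 / disp)
  } else {
    rpois(nrow(units), mu)
  }

  off <- config$isomir_offset_probs
  rows <- list()
  for (u in seq_len(nrow(units))) {
    n <- n_unit[u]
    if (n == 0) next
    n5 <- rbinom(1, n, arm5f[u])
    useq <- units$sequence[u]
    ulen <- nchar(useq)
    for (arm in c("5p", "3p")) {
      na <- if (arm == "5p") n5 else n - n5
      if (na == 0) next
      k <- as.vector(rmultinom(1, na, off$prob))
      a <- if (arm == "5p") c(units$arm5_start[u], units$arm5_end[u]) else
        c(units$arm3_start[u], units$arm3_end[u])
      for (v in which(k > 0)) {
        s <- max(0L, a[1] + off$offset5[v])
        e <- min(ulen, a[2] + off$offset3[v])
        ins <- substr(useq, s + 1L, e)
        rows[[length(rows) + 1L]] <- data.frame(
          insert = ins, source = "hairpin", unit = units$unit[u], arm = arm,
          offset5 = s - a[1], offset3 = e - a[2], count = k[v],
          stringsAsFactors = FALSE)
      }
    }
  }

  # background: ~29-nt inserts from the cluster locus and random positions
  bg_frac <- config$background_29nt_fraction[[tissue]]
  n_bg <- rpois(1, config$depth_per_library * bg_frac)
  if (n_bg > 0) {
    lens <- pmin(33L, pmax(25L, as.integer(round(rnorm(n_bg, 29, 1)))))
    in_cl <- runif(n_bg) < config$cluster_fraction & !is.null(truth$cluster_locus)
    starts <- integer(n_bg)
    cl <- truth$cluster_locus
    if (any(in_cl)) {
      starts[in_cl] <- cl$start +
        sample.int(cl$end - cl$start - 33L, sum(in_cl), replace = TRUE) - 1L
    }
    if (any(!in_cl)) {
      starts[!in_cl] <- sample.int(truth$genome_length - 33L, sum(!in_cl),
                                   replace = TRUE) - 1L
    }
    strands <- sample(c("+", "-"), n_bg, replace = TRUE)
    bseq <- substring(gseq, starts + 1L, starts + lens)
    neg <- strands == "-"
    if (any(neg)) bseq[neg] <- revcomp(bseq[neg])
    bg <- data.frame(insert = bseq,
                     source = ifelse(in_cl, "cluster", "background"),
                     unit = NA_character_, arm = NA_character_,
                     offset5 = NA_integer_, offset3 = NA_integer_,
                     count = 1L, stringsAsFactors = FALSE)
    bg <- stats::aggregate(count ~ insert + source, data = bg, FUN = sum)
    bg$unit <- NA_character_; bg$arm <- NA_character_
    bg$offset5 <- NA_integer_; bg$offset3 <- NA_integer_
    rows[[length(rows) + 1L]] <- bg[, c("insert", "source", "unit", "arm",
                                        "offset5", "offset3", "count")]
  }

  inserts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(insert = character(0), source = character(0),
               unit = character(0), arm = character(0),
               offset5 = integer(0), offset3 = integer(0),
               count = integer(0))
  inserts$recoverable <- !grepl("TGGAATTC", inserts$insert, fixed = TRUE)

  # read assembly with HD signatures and adapter run-through
  nr <- sum(inserts$count)
  reads <- character(0)
  if (nr > 0) {
    ivec <- rep(inserts$insert, inserts$count)
    hd <- function() {
      if (config$hd_len == 0) return(rep("", nr))
      m <- matrix(sample(BASES, config$hd_len * nr, replace = TRUE),
                  nrow = nr)
      do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    }
    reads <- paste0(hd(), ivec, hd(), config$adapter_sequence)
    short <- nchar(reads) < config$read_length
    if (any(short)) {
      pad <- strrep("A", config$read_length)
      reads[short] <- paste0(reads[short], pad)
    }
    reads <- substr(reads, 1L, config$read_length)
    reads <- reads[sample.int(nr)]
  }

  structure(list(
    tissue = tissue, replicate = replicate,
    reads = reads,
    names = if (nr > 0) sprintf("%s_rep%d_read%d", tissue, replicate,
                                seq_len(nr)) else character(0),
    inserts = inserts
  ), class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("sim_library: %s replicate %d, %d reads (%d distinct inserts)\n",
              x$tissue, x$replicate, length(x$reads), nrow(x$inserts)))
  invisible(x)
}

as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    genome
  } else {
    stopf("genome must be a DNAStringSet or a named character vector")
  }
}

#' Write a simulated library as FASTQ
#'
#' Phred+33 records with constant dummy quality "I".
#'
#' @param lib A `sim_library`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lib, path) {
  n <- length(lib$reads)
  if (n == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(lib$reads))
  out <- as.vector(rbind(paste0("@", lib$names), lib$reads, "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Simulate and persist a full multi-library experiment
#'
#' Generates the genome and ground truth, then one FASTQ per
#' tissue/replicate, writing genome FASTA, gene-model GFF3, precursor
#' query FASTA, ground-truth JSON, FASTQ files and a library manifest TSV
#' into `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `genome`, `truth`, `manifest`
#'   (data.frame: library_id, tissue, replicate, fastq) and `paths`.
#' @export
simulate_experiment <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gt <- generate_genome(config)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gff = file.path(outdir, "genes.gff3"),
    precursors = file.path(outdir, "precursors.fa"),
    truth = file.path(outdir, "truth.json"),
    manifest = file.path(outdir, "manifest.tsv")
  )
  Biostrings::writeXStringSet(gt$genome, paths$genome)
  write_gene_models_gff3(gt$truth$gene_models, paths$gff)
  Biostrings::writeXStringSet(truth_precursors(gt$truth), paths$precursors)
  write_truth(gt$truth, paths$truth)

  man <- list()
  libs <- list()
  for (t in config$tissues) {
    for (r in seq_len(config$replicates_per_tissue)) {
      lib <- simulate_library(gt$genome, gt$truth, t, r, config)
      id <- sprintf("%s_rep%d", t, r)
      fq <- file.path(outdir, paste0(id, ".fastq"))
      write_fastq(lib, fq)
      man[[length(man) + 1L]] <- data.frame(
        library_id = id, tissue = t, replicate = r, fastq = fq,
        stringsAsFactors = FALSE)
      libs[[id]] <- lib
    }
  }
  manifest <- do.call(rbind, man)
  write_tsv(manifest, paths$manifest)
  invisible(list(genome = gt$genome, truth = gt$truth, manifest = manifest,
                 libraries = libs, paths = paths))
}
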