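#' Generate a synthetic genome with planted small-RNA ground truth
#'
#' Builds a random genome hosting: `n_hairpin_loci` known miRNA stem-loops
#' and `n_novel_loci` withheld ("novel") stem-loops on random strands; a
#' tandem repeat region of `repeat_copies` x `repeat_unit_length` nt whose
#' units each carry `n_isoforms` isoform hairpins of one family
#' (miR-427-like organisation); a 29-nt small-RNA cluster locus; and gene
#' models with exons and introns on both strands. All coordinates, arm
#' sequences, expected tissue expression, arm proportions and planted
#' differential expression are recorded in the returned ground truth.
#'
#' Planted stems are the reverse complement of the 5p arm with up to
#' `stem_mismatches` transition substitutions, enclosed by a loop of
#' `loop_length` nt and short unstructured flanks. Arm sequences are
#' resampled if they would contain the adapter octamer, which would make
#' their reads unrecoverable by construction of the trimming chemistry.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (class `sim_truth`): hairpin table (0-based half-open
#'   coordinates), simulation units, per-tissue expected means and arm
#'   proportions, planted DE table, cluster locus, gene models and repeat
#'   region.
#' @examples
#' gt <- generate_genome(sim_config(seed = 1, genome_length = 30000,
#'                                  n_hairpin_loci = 5, n_novel_loci = 2,
#'                                  repeat_copies = 2, de_spec = list()))
#' nrow(gt$truth$hairpins)
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(derive_seed(cfg$seed, 1L))

  hp_len <- 2L * cfg$arm_length + cfg$loop_length + 2L * cfg$flank_length
  has_repeat <- cfg$repeat_copies > 0 && cfg$n_isoforms > 0

  # --- feature layout -------------------------------------------------
  feats <- list()
  add_feat <- function(name, type, len) {
    feats[[length(feats) + 1L]] <<- list(name = name, type = type, len = len)
  }
  for (i in seq_len(cfg$n_hairpin_loci)) {
    add_feat(sprintf("hp%02d", i), "hairpin", hp_len)
  }
  for (i in seq_len(cfg$n_novel_loci)) {
    add_feat(sprintf("nov%02d", i), "novel", hp_len)
  }
  if (has_repeat) {
    add_feat("repeat", "repeat", cfg$repeat_copies * cfg$repeat_unit_length)
  }
  add_feat("cluster", "cluster", cfg$cluster_length)
  gene_len <- cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
  for (g in seq_len(cfg$n_genes)) add_feat(sprintf("gene%d", g), "gene", gene_len)

  total <- sum(vapply(feats, `[[`, numeric(1), "len"))
  n_gap <- length(feats) + 1L
  if (total + n_gap > cfg$genome_length) {
    stopf("genome_length %d too small to host all loci (need > %d)",
          cfg$genome_length, total + n_gap)
  }
  feats <- feats[sample(length(feats))]
  gaps <- as.vector(rmultinom(1, cfg$genome_length - total, rep(1, n_gap)))
  starts <- integer(length(feats))
  pos <- gaps[1]
  for (k in seq_along(feats)) {
    starts[k] <- pos
    pos <- pos + feats[[k]]$len + gaps[k + 1L]
  }

  genome_seq <- random_dna(cfg$genome_length)

  # --- stem-loop construction -----------------------------------------
  make_stemloop <- function() {
    for (try in 1:100) {
      arm5 <- random_dna(cfg$arm_length)
      loop <- random_dna(cfg$loop_length)
      arm3 <- inject_transitions(revcomp(arm5), cfg$stem_mismatches)
      seqn <- paste0(random_dna(cfg$flank_length), arm5, loop, arm3,
                     random_dna(cfg$flank_length))
      if (!grepl("TGGAATTC", seqn, fixed = TRUE)) return(seqn)
    }
    stopf("failed to draw an adapter-free stem-loop")
  }

  hp_rows <- list()
  unit_rows <- list()
  a5s <- cfg$flank_length; a5e <- a5s + cfg$arm_length
  a3s <- a5e + cfg$loop_length; a3e <- a3s + cfg$arm_length
  add_hairpin <- function(id, unit, family, isoform, known, start, strand, seqn) {
    end <- start + hp_len
    if (strand == "+") {
      g5 <- c(start + a5s, start + a5e); g3 <- c(start + a3s, start + a3e)
    } else {
      g5 <- c(end - a5e, end - a5s); g3 <- c(end - a3e, end - a3s)
    }
    hp_rows[[length(hp_rows) + 1L]] <<- data.frame(
      id = id, unit = unit, chrom = "chr1", start = start, end = end,
      strand = strand, family = family, isoform = isoform, known = known,
      sequence = seqn,
      arm5_start = a5s, arm5_end = a5e, arm3_start = a3s, arm3_end = a3e,
      mature5p = substr(seqn, a5s + 1L, a5e),
      mature3p = substr(seqn, a3s + 1L, a3e),
      g5_start = g5[1], g5_end = g5[2], g3_start = g3[1], g3_end = g3[2],
      stringsAsFactors = FALSE)
  }
  add_unit <- function(unit, family, known, seqn) {
    unit_rows[[length(unit_rows) + 1L]] <<- data.frame(
      unit = unit, family = family, known = known, sequence = seqn,
      arm5_start = a5s, arm5_end = a5e, arm3_start = a3s, arm3_end = a3e,
      stringsAsFactors = FALSE)
  }

  cluster_locus <- NULL
  repeat_region <- NULL
  gene_rows <- list()

  # repeat unit: isoform stem-loops at fixed offsets within one unit,
  # identical across tandem copies
  iso_letters <- LETTERS[seq_len(cfg$n_isoforms)]
  iso_seqs <- character(0)
  iso_offsets <- integer(0)
  if (has_repeat) {
    if (cfg$repeat_unit_length < cfg$n_isoforms * (hp_len + 20L)) {
      stopf("repeat_unit_length too small for %d isoform hairpins",
            cfg$n_isoforms)
    }
    iso_seqs <- vapply(iso_letters, function(.) make_stemloop(), character(1))
    span <- cfg$repeat_unit_length - hp_len - 20L
    iso_offsets <- as.integer(round(seq(10L, span,
                                        length.out = cfg$n_isoforms)))
    unit_seq <- random_dna(cfg$repeat_unit_length)
    for (k in seq_len(cfg$n_isoforms)) {
      substr(unit_seq, iso_offsets[k] + 1L, iso_offsets[k] + hp_len) <- iso_seqs[k]
    }
    repeat_seq <- paste(rep(unit_seq, cfg$repeat_copies), collapse = "")
  }

  for (k in seq_along(feats)) {
    f <- feats[[k]]; s <- starts[k]
    if (f$type %in% c("hairpin", "novel")) {
      seqn <- make_stemloop()
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "+") seqn else revcomp(seqn)
      substr(genome_seq, s + 1L, s + hp_len) <- planted
      known <- f$type == "hairpin"
      idx <- as.integer(sub("^(hp|nov)", "", f$name))
      family <- if (!known) NA_character_
        else if (idx <= 2L) "mir-130" else sprintf("mir-%d", 100L + idx)
      add_hairpin(f$name, f$name, family, NA_character_, known, s, strand, seqn)
      add_unit(f$name, family, known, seqn)
    } else if (f$type == "repeat") {
      substr(genome_seq, s + 1L, s + nchar(repeat_seq)) <- repeat_seq
      repeat_region <- list(chrom = "chr1", start = s,
                            end = s + nchar(repeat_seq),
                            copies = cfg$repeat_copies,
                            unit_length = cfg$repeat_unit_length)
      for (cp in seq_len(cfg$repeat_copies)) {
        for (j in seq_len(cfg$n_isoforms)) {
          hs <- s + (cp - 1L) * cfg$repeat_unit_length + iso_offsets[j]
          add_hairpin(sprintf("mir427-%s.c%d", iso_letters[j], cp),
                      sprintf("mir427-%s", iso_letters[j]),
                      "mir-427", iso_letters[j], TRUE, hs, "+", iso_seqs[j])
        }
      }
      for (j in seq_len(cfg$n_isoforms)) {
        add_unit(sprintf("mir427-%s", iso_letters[j]), "mir-427", TRUE,
                 iso_seqs[j])
      }
    } else if (f$type == "cluster") {
      cluster_locus <- list(chrom = "chr1", start = s, end = s + f$len)
    } else if (f$type == "gene") {
      strand <- sample(c("+", "-"), 1)
      p <- s
      for (e in seq_len(cfg$exons_per_gene)) {
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene = f$name, feature = "exon", chrom = "chr1",
          start = p, end = p + cfg$exon_length, strand = strand,
          stringsAsFactors = FALSE)
        p <- p + cfg$exon_length
        if (e < cfg$exons_per_gene) {
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene = f$name, feature = "intron", chrom = "chr1",
            start = p, end = p + cfg$intron_length, strand = strand,
            stringsAsFactors = FALSE)
          p <- p + cfg$intron_length
        }
      }
    }
  }

  hairpins <- do.call(rbind, hp_rows)
  hairpins <- hairpins[order(hairpins$start), ]
  rownames(hairpins) <- NULL
  units <- do.call(rbind, unit_rows)
  rownames(units) <- NULL
  gene_models <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene = character(0), feature = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0))

  truth <- list(
    chrom = "chr1", genome_length = cfg$genome_length,
    hairpins = hairpins, units = units,
    cluster_locus = cluster_locus, repeat_region = repeat_region,
    gene_models = gene_models
  )
  truth <- add_expression_model(truth, cfg)
  class(truth) <- "sim_truth"

  genome <- Biostrings::DNAStringSet(setNames(genome_seq, "chr1"))
  list(genome = genome, truth = truth)
}

# Attach the tissue expression model to the truth: expected per-library
# mean insert counts per simulation unit, expected 5p arm proportions,
# and the planted DE table.
add_expression_model <- function(truth, cfg) {
  units <- truth$units
  tissues <- cfg$tissues
  nu <- nrow(units)
  w <- matrix(0, nu, length(tissues), dimnames = list(units$unit, tissues))

  is_rep <- units$family %in% "mir-427" & units$known
  rfw <- cfg$repeat_family_weight
  for (t in tissues) {
    w427 <- if (any(is_rep)) unname(
      if (t %in% names(rfw)) rfw[[t]] else rfw[["default"]]) else 0
    if (any(is_rep)) {
      shares <- if (sum(is_rep) == 5) c(0.15, 0.10, 0.40, 0.20, 0.15) else
        rep(1 / sum(is_rep), sum(is_rep))
      w[is_rep, t] <- w427 * shares
    }
    # the top-10 share is defined over the known non-repeat pool; novel
    # loci get the same per-hairpin weight as the remaining known loci
    pool <- 1 - w427
    known_idx <- which(!is_rep & units$known)
    novel_idx <- which(!units$known)
    top <- known_idx[seq_len(min(10L, length(known_idx)))]
    rest <- setdiff(known_idx, top)
    if (length(rest) == 0) {
      if (length(top)) w[top, t] <- pool / length(top)
      w_rest <- if (length(top)) pool / length(top) / 4 else
        pool / max(1, length(novel_idx))
    } else {
      if (length(top)) w[top, t] <- pool * cfg$top10_share / length(top)
      w_rest <- pool * (1 - cfg$top10_share) / length(rest)
      w[rest, t] <- w_rest
    }
    if (length(novel_idx)) w[novel_idx, t] <- w_rest
  }

  de_kept <- list()
  for (d in cfg$de_spec) {
    if (!d$unit %in% units$unit || !d$tissue %in% tissues) {
      warning(sprintf("de_spec entry for absent unit/tissue '%s'/'%s' skipped",
                      d$unit, d$tissue))
      next
    }
    w[d$unit, d$tissue] <- w[d$unit, d$tissue] * 2^d$log2fc
    de_kept[[length(de_kept) + 1L]] <- data.frame(
      unit = d$unit, tissue = d$tissue, log2fc = d$log2fc,
      stringsAsFactors = FALSE)
  }

  arm5 <- matrix(rep(ifelse(runif(nu) < 0.5, 0.85, 0.15), length(tissues)),
                 nu, length(tissues), dimnames = list(units$unit, tissues))
  sw_kept <- list()
  for (s in cfg$arm_switch_spec) {
    if (!s$unit %in% units$unit || !s$tissue %in% tissues) {
      warning(sprintf("arm_switch_spec entry for absent unit/tissue '%s'/'%s' skipped",
                      s$unit, s$tissue))
      next
    }
    arm5[s$unit, ] <- s$fraction_elsewhere
    arm5[s$unit, s$tissue] <- s$fraction_there
    sw_kept[[length(sw_kept) + 1L]] <- as.data.frame(s,
                                                     stringsAsFactors = FALSE)
  }

  bg <- cfg$background_29nt_fraction
  mu <- w * 0
  for (t in tissues) {
    mu[, t] <- cfg$depth_per_library * (1 - bg[[t]]) * w[, t]
  }

  truth$unit_weights <- w
  truth$expected_mean <- mu
  truth$arm_props <- arm5
  truth$de <- if (length(de_kept)) do.call(rbind, de_kept) else
    data.frame(unit = character(0), tissue = character(0),
               log2fc = numeric(0))
  truth$arm_switches <- if (length(sw_kept)) do.call(rbind, sw_kept) else NULL
  truth
}

#' Build the known-precursor query set from the ground truth
#'
#' Returns the planted known hairpin sequences as a miRBase-style FASTA
#' query set (one query per distinct simulation unit, i.e. one per repeat
#' isoform rather than one per tandem copy), optionally diverged by random
#' transition substitutions to emulate cross-species homology.
#'
#' @param truth A `sim_truth` from [generate_genome()].
#' @param divergence Fraction of positions substituted (transitions only).
#' @param seed Optional seed controlling the substitution draw.
#' @return A named [Biostrings::DNAStringSet] of precursor queries.
#' @export
truth_precursors <- function(truth, divergence = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- truth$units[truth$units$known, , drop = FALSE]
  seqs <- units$sequence
  if (divergence > 0) {
    seqs <- vapply(seqs, function(s) {
      k <- round(divergence * nchar(s))
      inject_transitions(s, k)
    }, character(1), USE.NAMES = FALSE)
  }
  suffix <- ifelse(is.na(units$family), units$unit,
                   sub("^mir427-", "", sub("^hp", "", units$unit)))
  nm <- sprintf("xla-%s-%s", ifelse(is.na(units$family), "mir-999",
                                    units$family), tolower(suffix))
  Biostrings::DNAStringSet(setNames(seqs, nm))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("sim_truth: %d hairpin loci (%d known, %d novel) on %s",
                     " (%d nt)\n"),
              nrow(x$hairpins), sum(x$hairpins$known), sum(!x$hairpins$known),
              x$chrom, x$genome_length))
  if (!is.null(x$repeat_region)) {
    cat(sprintf("  repeat region: %d x %d nt at %d-%d\n",
                x$repeat_region$copies, x$repeat_region$unit_length,
                x$repeat_region$start, x$repeat_region$end))
  }
  cat(sprintf("  cluster locus: %d-%d; %d gene-model rows\n",
              x$cluster_locus$start, x$cluster_locus$end,
              nrow(x$gene_models)))
  invisible(x)
}
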