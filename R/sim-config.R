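#' Configuration for the synthetic small RNA-seq experiment
#'
#' Defines the study conditions the generator emulates: a 12-library design
#' (three replicates of four explant tissue types), HD-adapter read
#' structure (4 degenerate nt on each side of the insert, 3' adapter
#' beginning TGGAATTC), a bimodal insert-length structure (23-nt miRNA arms
#' over a ~29-nt background), a miR-427-like tandem repeat of ~1.2 kb units
#' carrying five isoform hairpins, tissue-dependent arm switching,
#' negative-binomial replicate noise, planted differential expression and a
#' planted 29-nt cluster locus.
#'
#' @param seed Integer root seed; every downstream random draw derives from it.
#' @param genome_length Genome size in nt (single chromosome `chr1`).
#' @param n_hairpin_loci Number of planted known (annotatable) hairpin loci
#'   outside the repeat region.
#' @param n_novel_loci Number of planted expressed hairpins withheld from the
#'   precursor query set (ground truth for novel-miRNA prediction).
#' @param repeat_unit_length Length of one tandem repeat unit in nt
#'   (default 1200, echoing the ~1.2 kb genomic repeat that carries the
#'   miR-427 isoforms).
#' @param repeat_copies Number of tandem copies of the unit (0 disables the
#'   repeat region).
#' @param n_isoforms Number of isoform hairpins per repeat unit (default 5).
#' @param tissues Tissue labels (default NC, neural, ectoderm, blastula).
#' @param replicates_per_tissue Biological replicates per tissue (default 3).
#' @param depth_per_library Expected reads per library.
#' @param nb_dispersion Negative-binomial dispersion alpha in the
#'   parameterisation `var = m + alpha * m^2` (matches the DE model).
#' @param arm_switch_spec List of arm switches to plant; each element a list
#'   with `unit` (hairpin/isoform id), `tissue`, `fraction_there` (expected
#'   5p/(5p+3p) in that tissue) and `fraction_elsewhere`.
#' @param de_spec List of planted differential expression effects; each
#'   element a list with `unit`, `tissue` and `log2fc` (applied
#'   multiplicatively to that tissue's expected mean).
#' @param background_29nt_fraction Proportion of each library drawn from the
#'   ~29-nt background rather than miRNA arms; a scalar or a named
#'   per-tissue vector. The default makes blastula background-dominated
#'   (unimodal 29-nt size profile) and the other tissues bimodal.
#' @param cluster_fraction Fraction of background reads drawn from the
#'   planted cluster locus (default 0.05).
#' @param repeat_family_weight Fraction of miRNA reads from the repeat
#'   (miR-427-like) family; named vector with a `default` entry and
#'   optional per-tissue overrides (default 0.67, blastula 0.74).
#' @param top10_share Fraction of the non-repeat miRNA reads carried by the
#'   ten most abundant planted hairpins (default 0.8).
#' @param isomir_offset_probs Data frame with columns `offset5`, `offset3`,
#'   `prob`: the distribution of isomiR end offsets relative to the
#'   reference mature. The default puts most mass on the canonical form
#'   with the remainder dominated by 5' end shifts.
#' @param adapter_sequence 3' adapter; must begin with TGGAATTC.
#' @param hd_len Number of degenerate HD nucleotides on each side (4).
#' @param read_length Fixed sequencing read length with adapter
#'   run-through (default 50 nt).
#' @param arm_length Mature arm length in nt (default 23).
#' @param loop_length Terminal loop length in nt (default 15).
#' @param flank_length Unstructured flank retained on each side of the
#'   planted stem-loop inside the recorded hairpin interval (default 5).
#' @param stem_mismatches Transition mismatches injected into the 3' arm of
#'   each planted stem (default 2; transitions keep folds stable while
#'   exercising mismatch tolerance of the homology search).
#' @param cluster_length Length of the planted 29-nt cluster locus.
#' @param n_genes,exons_per_gene,exon_length,intron_length Gene-model
#'   geometry for the degradation/intron checks.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       n_hairpin_loci = 20L,
                       n_novel_loci = 5L,
                       repeat_unit_length = 1200L,
                       repeat_copies = 5L,
                       n_isoforms = 5L,
                       tissues = c("NC", "neural", "ectoderm", "blastula"),
                       replicates_per_tissue = 3L,
                       depth_per_library = 200000L,
                       nb_dispersion = 0.1,
                       arm_switch_spec = list(list(
                         unit = "mir427-A", tissue = "blastula",
                         fraction_there = 0.90, fraction_elsewhere = 0.05)),
                       de_spec = list(
                         list(unit = "hp11", tissue = "NC", log2fc = 2),
                         list(unit = "hp12", tissue = "NC", log2fc = 2),
                         list(unit = "hp13", tissue = "NC", log2fc = 2),
                         list(unit = "hp14", tissue = "NC", log2fc = 2),
                         list(unit = "hp14", tissue = "blastula", log2fc = 2),
                         list(unit = "hp15", tissue = "neural", log2fc = 2)),
                       background_29nt_fraction = c(NC = 0.45, neural = 0.45,
                                                    ectoderm = 0.40,
                                                    blastula = 0.80),
                       cluster_fraction = 0.05,
                       repeat_family_weight = c(default = 0.67,
                                                blastula = 0.74),
                       top10_share = 0.8,
                       isomir_offset_probs = data.frame(
                         offset5 = c(0L, -1L, 1L, 0L, 0L),
                         offset3 = c(0L, 0L, 0L, -1L, 1L),
                         prob = c(0.70, 0.06, 0.06, 0.09, 0.09)),
                       adapter_sequence = "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC",
                       hd_len = 4L,
                       read_length = 50L,
                       arm_length = 23L,
                       loop_length = 15L,
                       flank_length = 5L,
                       stem_mismatches = 2L,
                       cluster_length = 2000L,
                       n_genes = 5L,
                       exons_per_gene = 3L,
                       exon_length = 200L,
                       intron_length = 300L) {
  cfg <- as.list(environment())
  cfg$adapter_sequence <- dna_normalize(adapter_sequence)
  if (!startsWith(cfg$adapter_sequence, "TGGAATTC")) {
    stopf("adapter_sequence must begin with TGGAATTC")
  }
  if (depth_per_library < 0) stopf("depth_per_library must be >= 0")
  if (nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (hd_len < 0) stopf("hd_len must be >= 0")
  bg <- background_29nt_fraction
  if (is.null(names(bg))) bg <- setNames(rep(bg[1], length(tissues)), tissues)
  if (!all(tissues %in% names(bg))) {
    stopf("background_29nt_fraction must cover every tissue or be a scalar")
  }
  cfg$background_29nt_fraction <- bg[tissues]
  props <- c(cfg$background_29nt_fraction, cluster_fraction, top10_share,
             repeat_family_weight, isomir_offset_probs$prob)
  if (any(props < 0 | props > 1)) stopf("all proportions must lie in [0, 1]")
  if (abs(sum(isomir_offset_probs$prob) - 1) > 1e-8) {
    stopf("isomir_offset_probs$prob must sum to 1")
  }
  if (!"default" %in% names(cfg$repeat_family_weight)) {
    names(cfg$repeat_family_weight)[1] <- "default"
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d nt genome, %d known + %d novel hairpins, ",
    "%d x %d nt repeat units (%d isoforms)\n",
    "  %s; %d replicates; %s reads/library; NB dispersion %.3g; seed %d\n"),
    x$genome_length, x$n_hairpin_loci, x$n_novel_loci,
    x$repeat_copies, x$repeat_unit_length, x$n_isoforms,
    paste(x$tissues, collapse = "/"), x$replicates_per_tissue,
    format(x$depth_per_library, big.mark = ","), x$nb_dispersion,
    as.integer(x$seed)))
  invisible(x)
}
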