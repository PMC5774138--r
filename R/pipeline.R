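#' Build a pipeline run configuration
#'
#' @param genome Path to the genome FASTA.
#' @param precursors Path to the known precursor FASTA.
#' @param annotation Path to the gene-model GFF3.
#' @param manifest Path to a library manifest TSV with columns
#'   library_id, tissue, replicate, fastq.
#' @param outdir Output directory.
#' @param trim A [trim_config()].
#' @param annot An [annot_config()].
#' @param alpha DE call threshold (default 0.01).
#' @param seed Root seed recorded in the report.
#' @return List of class `run_config`.
#' @export
run_config <- function(genome, precursors, annotation, manifest, outdir,
                       trim = trim_config(), annot = annot_config(),
                       alpha = 0.01, seed = 1L) {
  structure(list(genome = genome, precursors = precursors,
                 annotation = annotation, manifest = manifest,
                 outdir = outdir, trim = trim, annot = annot,
                 alpha = alpha, seed = seed), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Flat per-module sections: `paths` (genome, precursors, annotation,
#' manifest, outdir), `trim`, `annot`, `de` (alpha) and `seed`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  tc <- do.call(trim_config, y$trim %||% list())
  ac <- do.call(annot_config, y$annot %||% list())
  run_config(genome = y$paths$genome, precursors = y$paths$precursors,
             annotation = y$paths$annotation, manifest = y$paths$manifest,
             outdir = y$paths$outdir, trim = tc, annot = ac,
             alpha = (y$de %||% list())$alpha %||% 0.01,
             seed = y$seed %||% 1L)
}

#' Run the full small RNA-seq analysis pipeline
#'
#' Executes trim -> collapse -> map -> size profile -> annotate ->
#' quantify (counts, RPM, isomiRs, arm profiles, arm switches) -> DE
#' (all tissue pairs + enrichment sets) -> novel prediction -> 29-nt
#' cluster/enrichment analysis, persisting every intermediate as TSV,
#' FASTA, GFF3, BED or JSON in `config$outdir`. Re-running with an
#' identical configuration reproduces byte-identical data outputs (the
#' run report additionally carries wall-clock timings).
#'
#' @param config A `run_config` (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the in-memory stage results plus
#'   `report` (per-stage tallies, parameters and timings, also written
#'   to `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c("genome", "precursors", "annotation", "manifest")) {
    if (!file.exists(config[[p]])) {
      stopf("pipeline validation: %s path '%s' does not exist", p, config[[p]])
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(
    trim = unclass(config$trim),
    annot = unclass(config$annot)[setdiff(names(unclass(config$annot)),
                                          "karlin")],
    alpha = config$alpha, seed = config$seed))
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    val
  }
  out <- function(f) file.path(config$outdir, f)

  genome <- Biostrings::readDNAStringSet(config$genome)
  manifest <- read_tsv(config$manifest)
  tissue_map <- setNames(manifest$tissue, manifest$library_id)

  pp <- tick("preprocess", {
    fq <- setNames(as.list(manifest$fastq), manifest$library_id)
    preprocess_fastq(fq, config$trim)
  })
  write_collapsed(pp$reads, out("collapsed.fa"), out("collapsed_counts.tsv"))
  write_tsv(pp$audit, out("trim_audit.tsv"))
  report$preprocess <- list(libraries = nrow(pp$audit),
                            raw = sum(pp$audit$raw),
                            kept = sum(pp$audit$kept))

  mapping <- tick("map", map_exact(pp$reads$counts$sequence, genome))
  write_tsv(as.data.frame(mapping), out("mapping.tsv"))
  report$map <- list(sequences = nrow(pp$reads$counts),
                     mapped = length(unique(mapping$sequence)),
                     loci = nrow(mapping))

  ann <- tick("annotate", {
    queries <- Biostrings::readDNAStringSet(config$precursors)
    annotate_hairpins(queries, genome, pp$reads, mapping, config$annot)
  })
  write_tsv(ann$hairpins[, setdiff(names(ann$hairpins), "sequence")],
            out("hairpins.tsv"))
  write_hairpins_gff3(ann$hairpins, out("hairpins.gff3"))
  if (nrow(ann$hairpins)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
      setNames(ann$hairpins$sequence, ann$hairpins$id)), out("hairpins.fa"))
    mat <- ann$hairpins[!is.na(ann$hairpins$mature_5p) |
                          !is.na(ann$hairpins$mature_3p), ]
    mseq <- c(setNames(mat$mature_5p, paste0(mat$id, "-5p")),
              setNames(mat$mature_3p, paste0(mat$id, "-3p")))
    mseq <- mseq[!is.na(mseq)]
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(mseq),
                                out("matures.fa"))
  }
  write_tsv(ann$audit, out("annotation_audit.tsv"))
  report$annotate <- list(hairpins = nrow(ann$hairpins),
                          families = length(unique(ann$hairpins$family)))

  prof <- tick("size_profile",
               size_class_profile(pp$reads, mapping, ann$hairpins))
  write_tsv(data.frame(length = rownames(prof$rpm), prof$rpm,
                       check.names = FALSE), out("size_profile_rpm.tsv"))

  counts <- ann$counts
  rpm <- rpm_normalize(counts, prof$genome_matched)
  write_tsv(data.frame(id = rownames(counts), counts, check.names = FALSE),
            out("hairpin_counts.tsv"))
  write_tsv(data.frame(id = rownames(rpm), rpm, check.names = FALSE),
            out("hairpin_rpm.tsv"))

  iso <- tick("isomir", isomir_table(ann$hairpins, mapping, pp$reads))
  write_tsv(iso, out("isomirs.tsv"))
  arms <- arm_profiles(ann$hairpins, mapping, pp$reads)
  write_tsv(arms, out("arm_profiles.tsv"))
  tissues <- unique(manifest$tissue)
  switches <- list()
  for (i in seq_along(tissues)) for (j in seq_along(tissues)) {
    if (j <= i) next
    sw <- detect_arm_switch(arms, tissue_map, tissues[i], tissues[j])
    sw$tissue_a <- tissues[i]; sw$tissue_b <- tissues[j]
    switches[[length(switches) + 1L]] <- sw
  }
  switches <- do.call(rbind, switches)
  write_tsv(switches, out("arm_switches.tsv"))
  fams <- setNames(ann$hairpins$family, ann$hairpins$id)
  fam_reads <- family_read_counts(mapping, ann$hairpins, pp$reads)
  views <- profile_views(counts, rpm, fams, tissue_map,
                         exclude = "mir-427", family_counts = fam_reads)
  write_tsv(views$top, out("top_families.tsv"))
  write_tsv(data.frame(family = rownames(views$family_fraction),
                       views$family_fraction, check.names = FALSE),
            out("family_fraction.tsv"))
  write_tsv(data.frame(family = rownames(views$heatmap), views$heatmap,
                       check.names = FALSE), out("heatmap_rpm.tsv"))

  de <- tick("diffexp", de_all_pairs(counts, tissue_map, config$alpha))
  for (nm in names(de)) {
    write_tsv(as.data.frame(de[[nm]]), out(sprintf("de_%s.tsv", nm)))
  }
  sets <- build_enrichment_sets(de, alpha = config$alpha)
  jsonlite::write_json(sets, out("enrichment_sets.json"),
                       auto_unbox = FALSE, digits = NA)
  report$diffexp <- list(comparisons = length(de),
                         nc_enriched = length(sets$nc_enriched),
                         shared_nc_blastula = length(sets$shared_nc_blastula))

  nov <- tick("novel", novel_scan(mapping, pp$reads, genome,
                                  known_hairpins = ann$hairpins))
  grp <- group_predictions(nov$predictions)
  write_tsv(grp$predictions[, setdiff(names(grp$predictions), "sequence")],
            out("novel_predictions.tsv"))
  if (nrow(grp$predictions)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
      setNames(grp$predictions$sequence, grp$predictions$id)),
      out("novel_hairpins.fa"))
  }
  report$novel <- list(hairpins = grp$n_hairpins, groups = grp$n_groups,
                       unique_matures = grp$n_unique_matures)

  lsr <- tick("long_srna", {
    cl <- detect_clusters(mapping, pp$reads)
    gm <- read_gene_models(config$annotation)
    list(clusters = cl,
         fraction29 = fraction_in_clusters(mapping, pp$reads, cl),
         exon = feature_enrichment(mapping, pp$reads, gm, "exon"),
         intron = feature_enrichment(mapping, pp$reads, gm, "intron"))
  })
  write_tsv(lsr$clusters, out("clusters.tsv"))
  write_clusters_bed(lsr$clusters, out("clusters.bed"))
  jsonlite::write_json(list(fraction_29nt_in_clusters = lsr$fraction29,
                            exon_enrichment = lsr$exon,
                            intron_enrichment = lsr$intron),
                       out("long_srna.json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  report$long_srna <- list(clusters = nrow(lsr$clusters),
                           fraction_29nt_in_clusters = lsr$fraction29)

  report$timings <- timings
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(list(reads = pp$reads, audit = pp$audit, mapping = mapping,
                 annotation = ann, profile = prof, counts = counts,
                 rpm = rpm, isomirs = iso, arm_profiles = arms,
                 arm_switches = switches, views = views, de = de,
                 enrichment_sets = sets, novel = grp, long_srna = lsr,
                 report = report))
}
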