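#' Read FASTQ sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the read
#' sequences as a character vector.
#'
#' @param path FASTQ file path.
#' @return Character vector of read sequences (possibly empty).
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_chr <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# Deterministic TSV writer used for every tabular output.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write ground truth as JSON
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  # matrices serialise as data frames with an explicit unit column
  for (f in c("unit_weights", "expected_mean", "arm_props")) {
    if (!is.null(x[[f]])) {
      m <- x[[f]]
      x[[f]] <- cbind(data.frame(unit = rownames(m), stringsAsFactors = FALSE),
                      as.data.frame(m))
    }
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read ground truth written by [write_truth()]
#' @param path JSON path.
#' @return A `sim_truth` list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("unit_weights", "expected_mean", "arm_props")) {
    if (!is.null(x[[f]])) {
      df <- as.data.frame(x[[f]])
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df$unit
      x[[f]] <- m
    }
  }
  for (f in c("hairpins", "units", "gene_models", "de")) {
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]])
  }
  class(x) <- "sim_truth"
  x
}

# Gene models (exon/intron table, 0-based half-open) -> GFF3 via
# rtracklayer. Exports gene and exon features; introns are implicit.
write_gene_models_gff3 <- function(gene_models, path) {
  if (nrow(gene_models) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  ex <- gene_models[gene_models$feature == "exon", , drop = FALSE]
  genes <- do.call(rbind, lapply(split(gene_models, gene_models$gene),
                                 function(g) {
    data.frame(gene = g$gene[1], chrom = g$chrom[1], start = min(g$start),
               end = max(g$end), strand = g$strand[1],
               stringsAsFactors = FALSE)
  }))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end), strand = genes$strand,
    type = "gene", ID = genes$gene)
  gr_exon <- GenomicRanges::GRanges(ex$chrom,
    IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand,
    type = "exon", ID = paste0(ex$gene, ".exon",
                               stats::ave(seq_len(nrow(ex)), ex$gene,
                                          FUN = seq_along)),
    Parent = ex$gene)
  gr <- c(gr_gene, gr_exon)
  gr <- gr[order(GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 annotation and returns the exon/intron table used by the
#' degradation and intron-enrichment checks (0-based half-open
#' coordinates). Introns are derived as the per-gene gaps between exons.
#'
#' @param path GFF3 path (1-based inclusive coordinates per the standard).
#' @return data.frame with columns gene, feature (exon|intron), chrom,
#'   start, end, strand.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) {
    return(data.frame(gene = character(0), feature = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  gene_id <- as.character(if (!is.null(ex$Parent)) unlist(ex$Parent) else ex$ID)
  df <- data.frame(gene = gene_id, feature = "exon",
                   chrom = as.character(GenomicRanges::seqnames(ex)),
                   start = GenomicRanges::start(ex) - 1L,
                   end = GenomicRanges::end(ex),
                   strand = as.character(GenomicRanges::strand(ex)),
                   stringsAsFactors = FALSE)
  introns <- do.call(rbind, lapply(split(df, df$gene), function(g) {
    g <- g[order(g$start), ]
    if (nrow(g) < 2) return(NULL)
    data.frame(gene = g$gene[1], feature = "intron", chrom = g$chrom[1],
               start = g$end[-nrow(g)], end = g$start[-1],
               strand = g$strand[1], stringsAsFactors = FALSE)
  }))
  out <- rbind(df, introns)
  rownames(out) <- NULL
  out[order(out$gene, out$start), ]
}

# hairpin annotation table -> GFF3
write_hairpins_gff3 <- function(hairpins, path) {
  if (nrow(hairpins) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(hairpins$chrom,
    IRanges::IRanges(hairpins$start + 1L, hairpins$end),
    strand = hairpins$strand, type = "miRNA_primary_transcript",
    ID = hairpins$id, family = hairpins$family)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# cluster table -> BED6 (0-based half-open, as BED requires)
write_clusters_bed <- function(clusters, path) {
  if (nrow(clusters) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(clusters$chrom, clusters$start, clusters$end,
                    sprintf("cluster_%d", seq_len(nrow(clusters))),
                    clusters$count, clusters$majority_strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
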