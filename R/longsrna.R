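#' Detect dense clusters of long (25-33 nt) small RNAs
#'
#' Density-based cluster detection in the spirit of piRNA cluster
#' finders, simplified to deterministic interval merging: loci of
#' 25-33 nt reads (both strands pooled) are merged when separated by at
#' most `max_gap` nt, and merged intervals with at least `min_reads`
#' total read count are reported with descriptive piRNA-signature
#' statistics (majority-strand bias, 1U fraction, mean length).
#'
#' @param mapping `match_loci` of the collapsed sequences.
#' @param reads A `collapsed_reads`.
#' @param min_len,max_len Read length window (default 25-33).
#' @param min_reads Minimum total count per cluster (default 50).
#' @param max_gap Maximum merge gap in nt (default 500).
#' @param min_density_ratio Minimum cluster read density relative to the
#'   genome-wide density of same-length reads (default 3).
#' @param genome_length Total genome length used for the global density;
#'   when NULL it is approximated by the rightmost mapped coordinate per
#'   chromosome.
#' @param trim_gap After merging, terminal reads separated from the
#'   cluster body by more than this many nt are trimmed off (default
#'   100); this keeps cluster boundaries tight while still bridging
#'   internal gaps up to `max_gap`.
#' @return data.frame of clusters: chrom, start, end, count,
#'   majority_strand, strand_bias, u1_fraction, mean_length; intervals
#'   are disjoint and sorted.
#' @export
detect_clusters <- function(mapping, reads, min_len = 25L, max_len = 33L,
                            min_reads = 50, max_gap = 500L,
                            min_density_ratio = 3, genome_length = NULL,
                            trim_gap = 100L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), count = numeric(0),
                      majority_strand = character(0),
                      strand_bias = numeric(0), u1_fraction = numeric(0),
                      mean_length = numeric(0))
  if (nrow(mapping) == 0) return(empty)
  len <- nchar(mapping$sequence)
  mp <- mapping[len >= min_len & len <= max_len, , drop = FALSE]
  if (nrow(mp) == 0) return(empty)
  cnt <- reads$counts
  libs <- names(reads$totals)
  total <- rowSums(cnt[, libs, drop = FALSE])
  mp$count <- total[match(mp$sequence, cnt$sequence)]
  mp <- mp[!is.na(mp$count), , drop = FALSE]
  if (is.null(genome_length)) {
    genome_length <- sum(tapply(mp$end, mp$chrom, max))
  }
  global_density <- sum(mp$count) / genome_length
  gr <- as_granges0(mp)
  cl <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                              ignore.strand = TRUE, with.revmap = TRUE)
  rows <- list()
  for (k in seq_along(cl)) {
    idx <- S4Vectors::mcols(cl)$revmap[[k]]
    sub <- mp[idx, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    # trim loosely attached terminal reads
    repeat {
      n <- nrow(sub)
      if (n < 2) break
      drop_head <- sub$start[2] - sub$end[1] > trim_gap
      drop_tail <- sub$start[n] - max(sub$end[seq_len(n - 1)]) > trim_gap
      if (!drop_head && !drop_tail) break
      keep <- rep(TRUE, n)
      if (drop_head) keep[1] <- FALSE
      if (drop_tail) keep[n] <- FALSE
      sub <- sub[keep, , drop = FALSE]
    }
    count <- sum(sub$count)
    if (count < min_reads) next
    width <- max(sub$end) - min(sub$start)
    if (count / width < min_density_ratio * global_density) next
    plus <- sum(sub$count[sub$strand == "+"])
    maj <- if (plus >= count - plus) "+" else "-"
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = sub$chrom[1], start = min(sub$start), end = max(sub$end),
      count = count, majority_strand = maj,
      strand_bias = max(plus, count - plus) / count,
      u1_fraction = sum(sub$count[substr(sub$sequence, 1, 1) == "T"]) / count,
      mean_length = sum(sub$count * nchar(sub$sequence)) / count,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count-weighted fraction of focal-length reads inside clusters
#'
#' @param mapping,reads As for [detect_clusters()].
#' @param clusters Cluster table from [detect_clusters()].
#' @param focal_length Read length profiled (default 29).
#' @return Proportion in `[0, 1]`, or NA (with a warning) when no read
#'   of the focal length exists.
#' @export
fraction_in_clusters <- function(mapping, reads, clusters,
                                 focal_length = 29L) {
  cnt <- reads$counts
  libs <- names(reads$totals)
  total <- setNames(rowSums(cnt[, libs, drop = FALSE]), cnt$sequence)
  mp <- mapping[nchar(mapping$sequence) == focal_length, , drop = FALSE]
  seqs <- unique(mp$sequence)
  if (length(seqs) == 0) {
    warning("no reads of the focal length; fraction undefined")
    return(NA_real_)
  }
  inside <- character(0)
  if (nrow(clusters) > 0 && nrow(mp) > 0) {
    ov <- GenomicRanges::findOverlaps(as_granges0(mp), as_granges0(clusters),
                                      type = "within", ignore.strand = TRUE)
    inside <- unique(mp$sequence[S4Vectors::queryHits(ov)])
  }
  sum(total[inside]) / sum(total[seqs])
}

#' Feature enrichment test for a read length class
#'
#' Tests whether reads of the focal length overlap a feature class
#' (exons or introns) more often than reads of all other lengths: the
#' count-weighted overlap fractions are compared with a one-sided
#' two-proportion z test (focal > background). Overlap is any overlap of
#' at least 1 nt, strand-agnostic.
#'
#' @param mapping,reads As for [detect_clusters()].
#' @param gene_models Gene model table (gene, feature, chrom, start, end,
#'   strand; 0-based half-open), e.g. from [read_gene_models()].
#' @param feature `"exon"` or `"intron"`.
#' @param focal_length Read length tested (default 29).
#' @return List with `focal_fraction`, `background_fraction`, `z`, `p`
#'   and `status` (`"ok"` or `"undefined"` when either class is empty).
#' @export
feature_enrichment <- function(mapping, reads, gene_models,
                               feature = c("exon", "intron"),
                               focal_length = 29L) {
  feature <- match.arg(feature)
  if (is.null(gene_models) || nrow(gene_models) == 0) {
    stopf("empty gene-model annotation")
  }
  fm <- gene_models[gene_models$feature == feature, , drop = FALSE]
  if (nrow(fm) == 0) stopf("no '%s' features in annotation", feature)
  cnt <- reads$counts
  libs <- names(reads$totals)
  total <- setNames(rowSums(cnt[, libs, drop = FALSE]), cnt$sequence)
  len <- nchar(mapping$sequence)
  overlaps <- rep(FALSE, nrow(mapping))
  ov <- GenomicRanges::findOverlaps(as_granges0(mapping), as_granges0(fm),
                                    ignore.strand = TRUE)
  overlaps[unique(S4Vectors::queryHits(ov))] <- TRUE
  # per-sequence: overlapping if any locus overlaps
  seq_ov <- tapply(overlaps, mapping$sequence, any)
  seq_len_ <- tapply(len, mapping$sequence, function(v) v[1])
  w <- total[names(seq_ov)]
  focal <- seq_len_ == focal_length
  n1 <- sum(w[focal]); n0 <- sum(w[!focal])
  if (n1 == 0 || n0 == 0) {
    return(list(focal_fraction = NA_real_, background_fraction = NA_real_,
                z = NA_real_, p = NA_real_, status = "undefined"))
  }
  p1 <- sum(w[focal & seq_ov]) / n1
  p0 <- sum(w[!focal & seq_ov]) / n0
  phat <- (sum(w[focal & seq_ov]) + sum(w[!focal & seq_ov])) / (n1 + n0)
  se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n0))
  z <- if (se > 0) (p1 - p0) / se else 0
  list(focal_fraction = p1, background_fraction = p0, z = z,
       p = pnorm(z, lower.tail = FALSE), status = "ok")
}
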