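#' Count reads to hairpins
#'
#' A sequence contributes its full per-library count to every hairpin
#' whose interval fully contains at least one of its loci on the same
#' strand (full-count multi-mapper policy: reads of a tandem repeat
#' family count once for each containing hairpin copy). A fractional
#' policy (count split evenly over containing hairpins) is available.
#'
#' @param mapping `match_loci` from [map_exact()].
#' @param hairpins Hairpin annotation (columns id, chrom, start, end,
#'   strand).
#' @param reads A `collapsed_reads`.
#' @param policy `"full"` (default) or `"fractional"`.
#' @return Numeric matrix, hairpins x libraries.
#' @export
count_to_hairpins <- function(mapping, hairpins, reads,
                              policy = c("full", "fractional")) {
  policy <- match.arg(policy)
  libs <- names(reads$totals)
  out <- matrix(0, nrow(hairpins), length(libs),
                dimnames = list(hairpins$id, libs))
  if (nrow(mapping) == 0 || nrow(hairpins) == 0) return(out)
  q <- as_granges0(mapping)
  s <- as_granges0(hairpins)
  ov <- GenomicRanges::findOverlaps(q, s, type = "within")
  if (length(ov) == 0) return(out)
  pair <- unique(data.frame(seq = mapping$sequence[S4Vectors::queryHits(ov)],
                            hp = hairpins$id[S4Vectors::subjectHits(ov)],
                            stringsAsFactors = FALSE))
  cnt <- reads$counts
  m <- match(pair$seq, cnt$sequence)
  w <- rep(1, nrow(pair))
  if (policy == "fractional") {
    nhp <- table(pair$seq)
    w <- 1 / as.vector(nhp[pair$seq])
  }
  for (l in libs) {
    v <- cnt[[l]][m] * w
    v[is.na(v)] <- 0
    agg <- rowsum(v, pair$hp)
    out[rownames(agg), l] <- agg[, 1]
  }
  out
}

#' RPM-normalise a count matrix
#'
#' Reads per million genome-matched reads: the denominator is the
#' per-library total of genome-matched reads, not the miRNA total.
#'
#' @param counts Hairpin x library count matrix.
#' @param genome_matched Named per-library totals of genome-matched reads
#'   (e.g. from [size_class_profile()]).
#' @return Matrix of RPM values.
#' @export
rpm_normalize <- function(counts, genome_matched) {
  libs <- colnames(counts)
  if (!all(libs %in% names(genome_matched))) {
    stopf("genome_matched must cover every library column")
  }
  sweep(counts, 2, genome_matched[libs], "/") * 1e6
}

#' Classify an isomiR against its reference mature
#'
#' Offsets are signed nucleotide shifts of the variant's ends relative to
#' the reference mature, in hairpin coordinates (5' to 3' of the
#' precursor): `offset5 = variant 5' start - reference 5' start` and
#' `offset3 = variant 3' end - reference 3' end`.
#'
#' @param v_start,v_end Variant interval on the hairpin (0-based
#'   half-open).
#' @param r_start,r_end Reference mature interval, same coordinates.
#' @return List with `offset5` and `offset3`.
#' @export
classify_isomir <- function(v_start, v_end, r_start, r_end) {
  if (v_end <= r_start || v_start >= r_end) {
    stopf("variant does not overlap the reference mature")
  }
  list(offset5 = v_start - r_start, offset3 = v_end - r_end)
}

#' Tabulate isomiRs for annotated hairpins
#'
#' Classifies every read fully contained in an arm against that arm's
#' reference mature.
#'
#' @param hairpins Annotated hairpins with matures (from [assign_arms()]).
#' @param mapping,reads As for [count_to_hairpins()].
#' @param max_offset Variants with |offset| beyond this are dropped
#'   (default 5).
#' @return data.frame with hairpin, arm, sequence, offset5, offset3 and
#'   per-library counts.
#' @export
isomir_table <- function(hairpins, mapping, reads, max_offset = 5L) {
  libs <- names(reads$totals)
  rih <- reads_in_hairpins(mapping, hairpins, reads)
  rows <- list()
  for (i in seq_len(nrow(hairpins))) {
    hp <- hairpins[i, ]
    sub <- rih[rih$hairpin == hp$id, , drop = FALSE]
    for (arm in c("5p", "3p")) {
      ref_seq <- if (arm == "5p") hp$mature_5p else hp$mature_3p
      ref_off <- if (arm == "5p") hp$mature_5p_offset else hp$mature_3p_offset
      if (is.na(ref_seq)) next
      ss <- sub[sub$side == arm, , drop = FALSE]
      if (nrow(ss) == 0) next
      r_start <- ref_off; r_end <- ref_off + nchar(ref_seq)
      keep <- ss$h_end > r_start & ss$h_start < r_end
      ss <- ss[keep, , drop = FALSE]
      if (nrow(ss) == 0) next
      o5 <- ss$h_start - r_start
      o3 <- ss$h_end - r_end
      ok <- abs(o5) <= max_offset & abs(o3) <= max_offset
      ss <- ss[ok, , drop = FALSE]
      if (nrow(ss) == 0) next
      df <- data.frame(hairpin = hp$id, arm = arm, sequence = ss$sequence,
                       offset5 = o5[ok], offset3 = o3[ok],
                       stringsAsFactors = FALSE)
      df <- cbind(df, ss[, libs, drop = FALSE])
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    df <- data.frame(hairpin = character(0), arm = character(0),
                     sequence = character(0), offset5 = integer(0),
                     offset3 = integer(0))
    for (l in libs) df[[l]] <- numeric(0)
    df
  }
  rownames(out) <- NULL
  out
}

#' Per-library arm expression profiles
#'
#' For each hairpin and library: counts of reads fully contained in the
#' 5p and 3p sides of the loop and the ratio `r = 5p / (5p + 3p)`
#' (NA when both are zero).
#'
#' @param hairpins Hairpin annotation with loop columns.
#' @param mapping,reads As for [count_to_hairpins()].
#' @return data.frame with hairpin, library, n5, n3, ratio.
#' @export
arm_profiles <- function(hairpins, mapping, reads) {
  libs <- names(reads$totals)
  rih <- reads_in_hairpins(mapping, hairpins, reads)
  rows <- list()
  for (i in seq_len(nrow(hairpins))) {
    id <- hairpins$id[i]
    sub <- rih[rih$hairpin == id, , drop = FALSE]
    for (l in libs) {
      n5 <- sum(sub[[l]][sub$side == "5p"])
      n3 <- sum(sub[[l]][sub$side == "3p"])
      rows[[length(rows) + 1L]] <- data.frame(
        hairpin = id, library = l, n5 = n5, n3 = n3,
        ratio = if (n5 + n3 > 0) n5 / (n5 + n3) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hairpin = character(0), library = character(0),
               n5 = numeric(0), n3 = numeric(0), ratio = numeric(0))
  rownames(out) <- NULL
  out
}

#' Detect tissue-dependent arm switching
#'
#' A hairpin is flagged as arm-switched between two tissues when its
#' replicate-mean 5p ratio is at least `hi` in one tissue and at most
#' `lo` in the other. Libraries with fewer than `min_total` arm reads for
#' the hairpin are excluded; a hairpin with no usable library in a tissue
#' is reported as `insufficient_data`.
#'
#' @param profiles Output of [arm_profiles()].
#' @param tissue_map Named character vector library -> tissue.
#' @param tissue_a,tissue_b The two tissues compared.
#' @param hi,lo Ratio thresholds (defaults 0.7 / 0.3).
#' @param min_total Minimum 5p+3p count per library (default 50).
#' @return data.frame with hairpin, ratio_a, ratio_b, status
#'   (`switched`, `not_switched` or `insufficient_data`).
#' @export
detect_arm_switch <- function(profiles, tissue_map, tissue_a, tissue_b,
                              hi = 0.7, lo = 0.3, min_total = 50) {
  for (t in c(tissue_a, tissue_b)) {
    if (!t %in% tissue_map) stopf("tissue '%s' absent from tissue_map", t)
  }
  profiles$tissue <- tissue_map[profiles$library]
  rows <- list()
  for (id in unique(profiles$hairpin)) {
    sub <- profiles[profiles$hairpin == id & !is.na(profiles$tissue), ]
    sub <- sub[sub$n5 + sub$n3 >= min_total, , drop = FALSE]
    ra <- mean(sub$ratio[sub$tissue == tissue_a])
    rb <- mean(sub$ratio[sub$tissue == tissue_b])
    status <- if (!nrow(sub[sub$tissue == tissue_a, ]) ||
                  !nrow(sub[sub$tissue == tissue_b, ])) {
      "insufficient_data"
    } else if ((ra >= hi && rb <= lo) || (ra <= lo && rb >= hi)) {
      "switched"
    } else "not_switched"
    rows[[length(rows) + 1L]] <- data.frame(
      hairpin = id, ratio_a = ra, ratio_b = rb, status = status,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read-level family counts
#'
#' Counts each sequence once per family per library (a read mapping to
#' several tandem copies of one family contributes once), giving
#' read-level family fractions that match count-weighted read tallies.
#'
#' @param mapping,reads As for [count_to_hairpins()].
#' @param hairpins Hairpin annotation with a `family` column.
#' @return Family x library numeric matrix.
#' @export
family_read_counts <- function(mapping, hairpins, reads) {
  libs <- names(reads$totals)
  fams <- sort(unique(hairpins$family[!is.na(hairpins$family)]))
  out <- matrix(0, length(fams), length(libs), dimnames = list(fams, libs))
  if (nrow(mapping) == 0 || nrow(hairpins) == 0) return(out)
  q <- as_granges0(mapping)
  s <- as_granges0(hairpins)
  ov <- GenomicRanges::findOverlaps(q, s, type = "within")
  if (length(ov) == 0) return(out)
  pair <- unique(data.frame(
    seq = mapping$sequence[S4Vectors::queryHits(ov)],
    fam = hairpins$family[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE))
  pair <- pair[!is.na(pair$fam), , drop = FALSE]
  cnt <- reads$counts
  m <- match(pair$seq, cnt$sequence)
  for (l in libs) {
    v <- cnt[[l]][m]
    v[is.na(v)] <- 0
    agg <- rowsum(v, pair$fam)
    out[rownames(agg), l] <- agg[, 1]
  }
  out
}

#' Tissue profiling views
#'
#' Produces the three standard profiling views: the per-tissue top-`n`
#' most highly expressed families by replicate-mean RPM (after excluding
#' listed families), the per-tissue family fraction of all miRNA-assigned
#' reads, and the family x tissue replicate-mean RPM matrix for heatmap
#' display.
#'
#' @param counts Raw hairpin x library count matrix.
#' @param rpm RPM-normalised version of `counts`.
#' @param families Named character vector hairpin id -> family.
#' @param tissue_map Named character vector library -> tissue.
#' @param exclude Families excluded from the top-`n` view (e.g. the
#'   dominant repeat family).
#' @param n Number of top families per tissue (default 10); when larger
#'   than the number of families, all are returned.
#' @param family_counts Optional read-level family x library count matrix
#'   (each read counted once per family, see [family_read_counts()]);
#'   when supplied it replaces the hairpin-count aggregation for the
#'   family fractions, which otherwise overcount tandem-repeat families
#'   whose reads multi-map across member hairpins.
#' @return List with `top` (data.frame tissue, rank, family, mean_rpm),
#'   `family_fraction` (family x tissue matrix of read fractions) and
#'   `heatmap` (family x tissue replicate-mean RPM matrix).
#' @export
profile_views <- function(counts, rpm, families, tissue_map,
                          exclude = character(0), n = 10L,
                          family_counts = NULL) {
  libs <- colnames(counts)
  if (!all(libs %in% names(tissue_map))) stopf("tissue_map must cover all libraries")
  fam <- families[rownames(counts)]
  tissues <- unique(tissue_map[libs])
  fam_counts <- if (!is.null(family_counts)) {
    family_counts[, libs, drop = FALSE]
  } else {
    rowsum(counts, fam)
  }
  fam_rpm <- rowsum(rpm, fam)
  t_mean <- function(m) {
    vapply(tissues, function(t) {
      rowMeans(m[, libs[tissue_map[libs] == t], drop = FALSE])
    }, numeric(nrow(m)))
  }
  heat <- t_mean(fam_rpm)
  frac <- vapply(tissues, function(t) {
    v <- rowSums(fam_counts[, libs[tissue_map[libs] == t], drop = FALSE])
    if (sum(v) > 0) v / sum(v) else v * NA_real_
  }, numeric(nrow(fam_counts)))
  rownames(heat) <- rownames(fam_rpm)
  rownames(frac) <- rownames(fam_counts)
  top <- list()
  keep <- !(rownames(heat) %in% exclude)
  for (t in tissues) {
    vv <- heat[keep, t, drop = FALSE]
    v <- sort(setNames(vv[, 1], rownames(vv)), decreasing = TRUE)
    k <- min(n, length(v))
    if (k > 0) {
      top[[length(top) + 1L]] <- data.frame(
        tissue = t, rank = seq_len(k), family = names(v)[seq_len(k)],
        mean_rpm = as.numeric(v[seq_len(k)]), stringsAsFactors = FALSE)
    }
  }
  list(top = if (length(top)) do.call(rbind, top) else
         data.frame(tissue = character(0), rank = integer(0),
                    family = character(0), mean_rpm = numeric(0)),
       family_fraction = frac, heatmap = heat)
}
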