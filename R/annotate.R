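#' Apply the homology hit filters
#'
#' Implements the two hit-level filters of the annotation ladder: every
#' hit of any query with `max_hits_per_query` (default 30) or more hits is
#' removed, and hits whose extracted hairpin interval is shorter than
#' `min_hairpin_len` (i.e. length <= 55 by default) are removed. Both
#' conditions are evaluated on the input hit set, so the two sub-filters
#' commute and the operation is idempotent only up to hit counts already
#' being below threshold.
#'
#' The hairpin interval of a hit is the aligned genomic interval extended
#' symmetrically to the query's full length (clamped at chromosome ends),
#' recorded in columns `hp_start`/`hp_end`.
#'
#' @param hits Hit table from [homology_search()].
#' @param config An [annot_config()].
#' @param chrom_lengths Optional named vector of chromosome lengths used
#'   to clamp extended intervals.
#' @return The surviving hits with `hp_start`, `hp_end` columns added.
#' @export
filter_hits <- function(hits, config = annot_config(),
                        chrom_lengths = NULL) {
  if (nrow(hits) == 0) {
    hits$hp_start <- integer(0); hits$hp_end <- integer(0)
    return(hits)
  }
  n_hits <- table(hits$query)
  multi_ok <- as.vector(n_hits[hits$query]) < config$max_hits_per_query
  pad <- pmax(0L, hits$qlen - (hits$end - hits$start))
  left <- pad %/% 2L
  hp_start <- pmax(0L, hits$start - left)
  hp_end <- hits$end + (pad - left)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[hits$chrom]
    over <- hp_end > lim
    hp_end[over] <- lim[over]
  }
  hits$hp_start <- hp_start
  hits$hp_end <- hp_end
  len_ok <- (hits$hp_end - hits$hp_start) >= config$min_hairpin_len
  out <- hits[multi_ok & len_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract candidate hairpin loci from filtered hits
#'
#' Collapses overlapping same-strand hit intervals from different queries
#' into one candidate locus each (best E-value wins), extracts the
#' genomic sequence, folds it and applies [validate_hairpin()]. The
#' family id is transferred from the query name
#' (e.g. `xla-mir-130b-2 -> mir-130b`).
#'
#' @param hits Filtered hits from [filter_hits()].
#' @param genome Genome as named [Biostrings::DNAStringSet] or character.
#' @return List with `hairpins` (data.frame: id, chrom, start, end,
#'   strand, family, query, score, evalue, sequence, plus fold summary
#'   columns) and `audit` (per-candidate keep/drop record with reasons).
#' @export
extract_hairpins <- function(hits, genome) {
  gchr <- as_genome_chr(genome)
  empty <- data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), family = character(0),
                      query = character(0), score = numeric(0),
                      evalue = numeric(0), sequence = character(0),
                      loop_start = integer(0), loop_end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) {
    return(list(hairpins = empty,
                audit = data.frame(candidate = character(0),
                                   kept = logical(0), reason = character(0))))
  }
  df <- hits
  df$start <- df$hp_start; df$end <- df$hp_end
  gr <- as_granges0(df)
  # a stem-loop is close to its own reverse complement, so the same locus
  # is often hit on both strands; loci are deduplicated strand-agnostically
  # and the best-scoring hit decides the annotated strand
  cl <- GenomicRanges::reduce(gr, with.revmap = TRUE, ignore.strand = TRUE)
  audit <- list()
  rows <- list()
  folds <- list()
  for (k in seq_along(cl)) {
    members <- S4Vectors::mcols(cl)$revmap[[k]]
    best <- members[which.min(df$evalue[members])]
    cand <- df[best, ]
    seqn <- substr(gchr[[cand$chrom]], cand$start + 1L, cand$end)
    if (cand$strand == "-") seqn <- revcomp(seqn)
    fold <- fold_hairpin(seqn)
    val <- validate_hairpin(fold)
    cand_id <- sprintf("%s:%d-%d(%s)", cand$chrom, cand$start, cand$end,
                       cand$strand)
    audit[[length(audit) + 1L]] <- data.frame(
      candidate = cand_id, kept = val$pass, reason = val$reason,
      stringsAsFactors = FALSE)
    if (!val$pass) next
    rows[[length(rows) + 1L]] <- data.frame(
      id = "", chrom = cand$chrom, start = cand$start, end = cand$end,
      strand = cand$strand, family = family_from_name(cand$query),
      query = cand$query, score = cand$score, evalue = cand$evalue,
      sequence = seqn,
      loop_start = fold$stem_arms$arm5[2],      # 1-based, last 5'-arm base
      loop_end = fold$stem_arms$arm3[1],        # 1-based, first 3'-arm base
      stringsAsFactors = FALSE)
    folds[[length(folds) + 1L]] <- fold
  }
  hairpins <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(hairpins)) {
    ord <- order(hairpins$chrom, hairpins$start)
    hairpins <- hairpins[ord, , drop = FALSE]
    folds <- folds[ord]
    hairpins$id <- sprintf("hpl%03d", seq_len(nrow(hairpins)))
    rownames(hairpins) <- NULL
  }
  list(hairpins = hairpins, folds = folds,
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(candidate = character(0), kept = logical(0),
                    reason = character(0)))
}

#' Abundance filter with family rescue
#'
#' Keeps a hairpin when at least `abundance_min` reads (default 100) map
#' to it summed over all samples, or when any other hairpin of the same
#' family passes that condition (family rescue: all hairpins are retained
#' for a family if at least one member has alignments).
#'
#' @param hairpins Hairpin table (needs `id`, `family`).
#' @param counts Count matrix (hairpins x libraries) from
#'   [count_to_hairpins()]; hairpins absent from it count as zero.
#' @param config An [annot_config()].
#' @return The surviving hairpin rows.
#' @export
abundance_filter <- function(hairpins, counts, config = annot_config()) {
  if (nrow(hairpins) == 0) return(hairpins)
  tot <- setNames(rep(0, nrow(hairpins)), hairpins$id)
  present <- intersect(hairpins$id, rownames(counts))
  if (length(present)) {
    tot[present] <- rowSums(counts[present, , drop = FALSE])
  }
  self_ok <- tot >= config$abundance_min
  fam_ok <- self_ok
  for (f in unique(hairpins$family[!is.na(hairpins$family)])) {
    idx <- which(hairpins$family == f)
    if (any(self_ok[idx])) fam_ok[idx] <- TRUE
  }
  out <- hairpins[fam_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Reads mapped fully inside hairpin intervals (same strand), with
# hairpin-space coordinates. One row per (hairpin, sequence, locus).
reads_in_hairpins <- function(mapping, hairpins, reads) {
  libs <- names(reads$totals)
  empty <- data.frame(hairpin = character(0), sequence = character(0),
                      h_start = integer(0), h_end = integer(0),
                      side = character(0), total = numeric(0))
  if (nrow(mapping) == 0 || nrow(hairpins) == 0) return(empty)
  q <- as_granges0(mapping)
  s <- as_granges0(hairpins)
  ov <- GenomicRanges::findOverlaps(q, s, type = "within")
  if (length(ov) == 0) return(empty)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  hp <- hairpins[sh, ]
  mp <- mapping[qh, ]
  h_start <- ifelse(hp$strand == "+", mp$start - hp$start, hp$end - mp$end)
  h_end <- ifelse(hp$strand == "+", mp$end - hp$start, hp$end - mp$start)
  # side assignment: a read belongs to the arm it overlaps, provided it
  # does not reach into the opposite arm; reads touching both arms span
  # the loop, reads inside the loop only belong to neither
  touch5 <- h_start + 1L <= hp$loop_start   # overlaps the 5' arm
  touch3 <- h_end >= hp$loop_end            # overlaps the 3' arm
  side <- rep("loop_only", length(qh))
  side[touch5 & !touch3] <- "5p"
  side[touch3 & !touch5] <- "3p"
  side[touch5 & touch3] <- "loop_spanning"
  df <- data.frame(hairpin = hp$id, sequence = mp$sequence,
                   h_start = h_start, h_end = h_end, side = side,
                   stringsAsFactors = FALSE)
  cnt <- reads$counts
  m <- match(df$sequence, cnt$sequence)
  for (l in libs) df[[l]] <- cnt[[l]][m]
  df$total <- rowSums(df[, libs, drop = FALSE])
  # a sequence can hit one hairpin at several loci; keep one row per
  # (hairpin, sequence) so its count is not double-counted
  df <- df[!duplicated(paste(df$hairpin, df$sequence)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assign mature arms to validated hairpins
#'
#' For each side of the terminal loop the mature is the most abundant
#' read sequence fully contained in that side (counts summed over all
#' libraries); count ties break to the lexicographically smaller
#' sequence. Sides with no reads get no mature (NA). Reads spanning the
#' loop are assigned to neither arm.
#'
#' @param hairpins Hairpin table with `loop_start`/`loop_end` columns.
#' @param mapping `match_loci` for the collapsed sequences.
#' @param reads The `collapsed_reads`.
#' @return `hairpins` with columns `mature_5p`, `mature_5p_offset`,
#'   `mature_3p`, `mature_3p_offset` added (offsets are 0-based positions
#'   of the mature 5' end on the hairpin sequence).
#' @export
assign_arms <- function(hairpins, mapping, reads) {
  rih <- reads_in_hairpins(mapping, hairpins, reads)
  hairpins$mature_5p <- NA_character_
  hairpins$mature_5p_offset <- NA_integer_
  hairpins$mature_3p <- NA_character_
  hairpins$mature_3p_offset <- NA_integer_
  for (i in seq_len(nrow(hairpins))) {
    sub <- rih[rih$hairpin == hairpins$id[i], , drop = FALSE]
    for (side in c("5p", "3p")) {
      ss <- sub[sub$side == side, , drop = FALSE]
      if (nrow(ss) == 0) next
      ss <- ss[order(-ss$total, ss$sequence), , drop = FALSE]
      if (side == "5p") {
        hairpins$mature_5p[i] <- ss$sequence[1]
        hairpins$mature_5p_offset[i] <- ss$h_start[1]
      } else {
        hairpins$mature_3p[i] <- ss$sequence[1]
        hairpins$mature_3p_offset[i] <- ss$h_start[1]
      }
    }
  }
  hairpins
}

#' Run the full homology annotation ladder
#'
#' [homology_search()] -> [filter_hits()] -> [extract_hairpins()] (fold +
#' structure validation) -> [count_to_hairpins()] -> [abundance_filter()]
#' -> [assign_arms()].
#'
#' @param queries Precursor query set (named DNAStringSet or character).
#' @param genome Genome.
#' @param reads A `collapsed_reads` (trimmed, length-filtered inserts).
#' @param mapping `match_loci` for those inserts.
#' @param config An [annot_config()].
#' @return List with `hairpins` (final annotation with matures), `counts`
#'   (hairpin x library matrix for the final set) and `audit` (filter
#'   audit trail: one row per candidate with stage and reason).
#' @export
annotate_hairpins <- function(queries, genome, reads, mapping,
                              config = annot_config()) {
  gchr <- as_genome_chr(genome)
  hits <- homology_search(queries, genome, config)
  fh <- filter_hits(hits, config, chrom_lengths = nchar(gchr))
  ex <- extract_hairpins(fh, genome)
  audit <- ex$audit
  if (nrow(audit)) audit$stage <- "structure"
  hp <- ex$hairpins
  if (nrow(hp)) {
    cm <- count_to_hairpins(mapping, hp, reads)
    kept <- abundance_filter(hp, cm, config)
    dropped <- setdiff(hp$id, kept$id)
    if (length(dropped)) {
      audit <- rbind(audit, data.frame(
        candidate = dropped, kept = FALSE, reason = "low_abundance",
        stage = "abundance", stringsAsFactors = FALSE))
    }
    hp <- kept
    hp <- assign_arms(hp, mapping, reads)
    cm <- cm[hp$id, , drop = FALSE]
  } else {
    cm <- matrix(0, 0, length(reads$totals),
                 dimnames = list(NULL, names(reads$totals)))
  }
  list(hairpins = hp, counts = cm, audit = audit)
}
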