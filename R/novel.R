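#' Find candidate read stacks for novel miRNA prediction
#'
#' Clusters same-strand loci of Dicer-sized reads (16-24 nt by default)
#' with gaps of at most `max_gap` nt, after masking annotated hairpin
#' intervals. Stacks with total count below `min_count` or genomic span
#' above `max_span` are discarded. The 5'-homogeneity of a stack is the
#' count-weighted fraction of its reads sharing the modal 5' end.
#'
#' @param mapping `match_loci` from [map_exact()].
#' @param reads A `collapsed_reads`.
#' @param mask Optional data.frame of intervals (chrom, start, end) to
#'   exclude, e.g. annotated hairpins.
#' @param min_count Minimum total read count per stack (default 10).
#' @param max_gap Maximum gap between member loci (default 3).
#' @param max_span Maximum stack span in nt (default 40).
#' @param min_len,max_len Read length gate (default 16-24 nt, the
#'   Dicer product size range; this also keeps the ~29-nt background
#'   class out of miRNA stack building).
#' @return data.frame of stacks: chrom, start, end, strand, count,
#'   dominant (sequence), dominant_count, homogeneity, plus a `members`
#'   list-column of per-stack member tables.
#' @export
find_stacks <- function(mapping, reads, mask = NULL, min_count = 10,
                        max_gap = 3L, max_span = 40L,
                        min_len = 16L, max_len = 24L) {
  libs <- names(reads$totals)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      count = numeric(0), dominant = character(0),
                      dominant_count = numeric(0), homogeneity = numeric(0))
  if (nrow(mapping) == 0) { empty$members <- list(); return(empty) }
  len <- nchar(mapping$sequence)
  mp <- mapping[len >= min_len & len <= max_len, , drop = FALSE]
  if (nrow(mp) == 0) { empty$members <- list(); return(empty) }
  if (!is.null(mask) && nrow(mask) > 0) {
    ov <- GenomicRanges::findOverlaps(as_granges0(mp),
                                      as_granges0(mask),
                                      ignore.strand = TRUE)
    if (length(ov)) mp <- mp[-unique(S4Vectors::queryHits(ov)), , drop = FALSE]
    if (nrow(mp) == 0) { empty$members <- list(); return(empty) }
  }
  cnt <- reads$counts
  total <- rowSums(cnt[, libs, drop = FALSE])
  mp$count <- total[match(mp$sequence, cnt$sequence)]
  gr <- as_granges0(mp)
  cl <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                              with.revmap = TRUE)
  rows <- list()
  members <- list()
  for (k in seq_along(cl)) {
    idx <- S4Vectors::mcols(cl)$revmap[[k]]
    sub <- mp[idx, , drop = FALSE]
    span <- max(sub$end) - min(sub$start)
    count <- sum(sub$count)
    if (count < min_count || span > max_span) next
    five <- ifelse(sub$strand == "+", sub$start, sub$end)
    by5 <- rowsum(sub$count, five)
    homog <- max(by5) / count
    dom <- which.max(sub$count)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = sub$chrom[1], start = min(sub$start), end = max(sub$end),
      strand = sub$strand[1], count = count,
      dominant = sub$sequence[dom], dominant_count = sub$count[dom],
      homogeneity = homog, stringsAsFactors = FALSE)
    members[[length(members) + 1L]] <- sub
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out$members <- members
  rownames(out) <- NULL
  out
}

#' Call a novel miRNA hairpin from a read stack
#'
#' Excises candidate precursor windows of 60-200 nt anchored at the
#' stack, in both flank orientations (the star arm may lie on either
#' side of the mature), folds each window and applies
#' [validate_hairpin()]. Among windows that pass with the stack's
#' dominant sequence fully inside one stem arm of the dominant stem, the
#' LONGEST passing hairpin is selected (ties break to the highest paired
#' fraction). Anchoring the windows at the stack rather than folding
#' arbitrary flanked windows matters: maximum base pairing over long
#' random flanks fragments the true stem into branched structures, while
#' the excised precursor folds cleanly. Stacks with 5'-homogeneity below
#' `min_homogeneity` are rejected as imprecisely processed. Star support
#' is flagged when reads exist on the opposite arm whose duplex with the
#' mature shows the Dicer-typical 2-nt 3' overhang (within 1 nt).
#'
#' @param stack One row of [find_stacks()] output (with `members`).
#' @param genome Genome (named DNAStringSet or character).
#' @param min_homogeneity Minimum 5'-homogeneity (default 0.8).
#' @param window_lengths Candidate window lengths (default
#'   `seq(60, 200, 10)`).
#' @param anchor_pad Unpaired buffer left outside the stack on its
#'   anchored side (default 8 nt).
#' @param arm_slack Tolerance, in nt, by which the dominant read may
#'   overhang the stem arm on either side (default 4; maximum-pairing
#'   arm boundaries are fuzzy by a few nt and matures commonly end a
#'   couple of nt inside the loop).
#' @return On success a list of class `novel_prediction` with the hairpin
#'   interval/sequence/fold, mature sequence and star support flag; on
#'   failure a list of class `novel_reject` with element `reason`
#'   (`imprecise_processing` or `no_hairpin`).
#' @export
call_novel <- function(stack, genome, min_homogeneity = 0.8,
                       window_lengths = seq(60L, 200L, 10L),
                       anchor_pad = 8L, arm_slack = 4L) {
  if (stack$homogeneity < min_homogeneity) {
    return(structure(list(reason = "imprecise_processing"),
                     class = "novel_reject"))
  }
  gchr <- as_genome_chr(genome)
  glen <- nchar(gchr[[stack$chrom]])
  span <- stack$end - stack$start
  mem <- stack$members[[1]]
  dom_row <- mem[mem$sequence == stack$dominant, , drop = FALSE][1, ]
  best <- NULL
  for (L in window_lengths) {
    if (L < span + 2L * anchor_pad) next
    for (orient in c("star3", "star5")) {
      if (orient == "star3") {
        ws <- stack$start - anchor_pad
      } else {
        ws <- stack$end + anchor_pad - L
      }
      ws <- max(0L, min(ws, glen - L))
      we <- ws + L
      seqn <- substr(gchr[[stack$chrom]], ws + 1L, we)
      if (stack$strand == "-") seqn <- revcomp(seqn)
      fold <- fold_hairpin(seqn)
      val <- validate_hairpin(fold)
      if (!val$pass) next
      if (stack$strand == "+") {
        h_start <- dom_row$start - ws; h_end <- dom_row$end - ws
      } else {
        h_start <- we - dom_row$end; h_end <- we - dom_row$start
      }
      if (h_start < 0 || h_end > L) next
      a5 <- fold$stem_arms$arm5; a3 <- fold$stem_arms$arm3
      in5 <- h_start + 1L >= a5[1] - arm_slack && h_end <= a5[2] + arm_slack
      in3 <- h_start + 1L >= a3[1] - arm_slack && h_end <= a3[2] + arm_slack
      if (in5 && in3) in3 <- FALSE   # ambiguous tiny folds resolve 5p
      if (!in5 && !in3) next
      cand <- list(chrom = stack$chrom, start = ws, end = we,
                   strand = stack$strand, sequence = seqn, fold = fold,
                   mature = stack$dominant, mature_arm = if (in5) "5p" else "3p",
                   mature_h_start = h_start, mature_h_end = h_end,
                   length = L)
      if (is.null(best) || L > best$length ||
          (L == best$length &&
           fold$paired_fraction > best$fold$paired_fraction)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(reason = "no_hairpin"), class = "novel_reject"))
  }
  best$star_support <- has_star_support(best, stack)
  class(best) <- "novel_prediction"
  best
}

# 2-nt 3' overhang check (+-1 nt) for reads on the arm opposite the mature.
has_star_support <- function(pred, stack) {
  fold <- pred$fold
  pairs <- fold$pairs
  if (nrow(pairs) == 0) return(FALSE)
  mem <- stack$members[[1]]
  partner_of <- function(pos) {
    i <- match(pos, pairs[, 1])
    if (!is.na(i)) return(pairs[i, 2])
    j <- match(pos, pairs[, 2])
    if (!is.na(j)) return(pairs[j, 1])
    NA_integer_
  }
  # pair partner of the mature 5' end; the star's 3' end should lie 2 nt
  # past it (Dicer leaves 2-nt 3' overhangs on both strands)
  p <- partner_of(pred$mature_h_start + 1L)
  if (is.na(p)) return(FALSE)
  for (r in seq_len(nrow(mem))) {
    if (mem$sequence[r] == pred$mature) next
    if (pred$strand == "+") {
      rh_start <- mem$start[r] - pred$start; rh_end <- mem$end[r] - pred$start
    } else {
      rh_start <- pred$end - mem$end[r]; rh_end <- pred$end - mem$start[r]
    }
    if (abs(rh_end - (p + 2L)) <= 1L) return(TRUE)
  }
  FALSE
}

#' Scan for novel miRNA hairpins
#'
#' [find_stacks()] with annotated hairpins masked, then [call_novel()]
#' per stack.
#'
#' @param mapping,reads As for [find_stacks()].
#' @param genome Genome.
#' @param known_hairpins Annotation to mask (data.frame with chrom,
#'   start, end), or NULL.
#' @param ... Passed to [find_stacks()] and [call_novel()].
#' @return List with `predictions` (data.frame: id, chrom, start, end,
#'   strand, mature, mature_arm, star_support, hairpin_length, sequence)
#'   and `rejected` (data.frame: chrom, start, end, reason).
#' @export
novel_scan <- function(mapping, reads, genome, known_hairpins = NULL,
                       min_count = 10, min_homogeneity = 0.8) {
  stacks <- find_stacks(mapping, reads, mask = known_hairpins,
                        min_count = min_count)
  preds <- list()
  rej <- list()
  for (k in seq_len(nrow(stacks))) {
    p <- call_novel(stacks[k, ], genome, min_homogeneity = min_homogeneity)
    if (inherits(p, "novel_reject")) {
      rej[[length(rej) + 1L]] <- data.frame(
        chrom = stacks$chrom[k], start = stacks$start[k],
        end = stacks$end[k], reason = p$reason,
        stringsAsFactors = FALSE)
    } else {
      preds[[length(preds) + 1L]] <- data.frame(
        id = "", chrom = p$chrom, start = p$start, end = p$end,
        strand = p$strand, mature = p$mature, mature_arm = p$mature_arm,
        mature_h_start = p$mature_h_start, mature_h_end = p$mature_h_end,
        star_support = p$star_support, hairpin_length = p$length,
        sequence = p$sequence, stringsAsFactors = FALSE)
    }
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else
    data.frame(id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               mature = character(0), mature_arm = character(0),
               mature_h_start = integer(0), mature_h_end = integer(0),
               star_support = logical(0), hairpin_length = integer(0),
               sequence = character(0))
  if (nrow(predictions)) {
    predictions$id <- sprintf("nov_pred%03d", seq_len(nrow(predictions)))
  }
  list(predictions = predictions,
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), reason = character(0)))
}

#' Group novel predictions by mature sequence
#'
#' Single-linkage grouping: two predictions share a group when their
#' mature sequences are identical, or their mature loci overlap on the
#' same strand with both end offsets at most `max_offset` nt. Reports
#' the hairpin/group/unique-mature tallies.
#'
#' @param predictions Prediction table from [novel_scan()].
#' @param max_offset Maximum end offset for coordinate-based linkage
#'   (default 2).
#' @return List with `predictions` (with a `group` column), `n_hairpins`,
#'   `n_groups`, `n_unique_matures`.
#' @export
group_predictions <- function(predictions, max_offset = 2L) {
  n <- nrow(predictions)
  if (n == 0) {
    return(list(predictions = cbind(predictions, group = integer(0)),
                n_hairpins = 0L, n_groups = 0L, n_unique_matures = 0L))
  }
  # mature genomic interval
  g_start <- ifelse(predictions$strand == "+",
                    predictions$start + predictions$mature_h_start,
                    predictions$end - predictions$mature_h_end)
  g_end <- ifelse(predictions$strand == "+",
                  predictions$start + predictions$mature_h_end,
                  predictions$end - predictions$mature_h_start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_seq <- predictions$mature[i] == predictions$mature[j]
      same_locus <- predictions$chrom[i] == predictions$chrom[j] &&
        predictions$strand[i] == predictions$strand[j] &&
        g_start[i] < g_end[j] && g_start[j] < g_end[i] &&
        abs(g_start[i] - g_start[j]) <= max_offset &&
        abs(g_end[i] - g_end[j]) <= max_offset
      if (same_seq || same_locus) union2(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  group <- match(roots, unique(roots))
  predictions$group <- group
  list(predictions = predictions,
       n_hairpins = n,
       n_groups = length(unique(group)),
       n_unique_matures = length(unique(predictions$mature)))
}
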