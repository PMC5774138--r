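#' Fold a candidate hairpin by maximum base pairing
#'
#' Computes the Nussinov maximum base-pairing structure of a sequence with a
#' minimum hairpin-loop size, allowing Watson-Crick and G:U wobble pairs
#' (on the DNA alphabet, T stands for U). The traceback is deterministic:
#' at each position the 5' base is paired with the smallest admissible
#' partner attaining the optimum, in preference to leaving it unpaired.
#'
#' Maximum pairing is used here as a fast, dependency-free and fully
#' deterministic stand-in for thermodynamic folding: the downstream
#' validation asks only whether the molecule folds into a single dominant
#' stem-loop, a question maximum pairing answers reliably for
#' miRNA-precursor-sized sequences.
#'
#' @param sequence A single DNA/RNA string, length 20-300 nt.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (default 3): a pair `(i, j)` is admissible only when `j - i > min_loop`.
#' @return An object of class `structure_fold`: a list with elements
#'   `pairs` (two-column integer matrix of 1-based paired positions, sorted
#'   by the 5' position), `n_paired` (number of pairs), `length`,
#'   `paired_fraction` (fraction of bases involved in a pair), `stems`
#'   (data.frame of helical stems, see Details), `loop_len` (size of the
#'   terminal loop of the dominant stem) and `stem_arms` (list with the
#'   5' and 3' position ranges of the dominant stem).
#'
#' @details Stems are maximal runs of pairs in which consecutive pairs
#'   advance by at most 3 nt on either side (i.e. bulges and interior
#'   loops up to 3 nt are absorbed into one stem). The dominant stem is
#'   the one with the most pairs.
#' @export
fold_hairpin <- function(sequence, min_loop = 3L) {
  sequence <- dna_normalize(sequence)
  n <- nchar(sequence)
  if (n < 20 || n > 300) {
    stopf("fold_hairpin: sequence length %d outside the supported 20-300 nt", n)
  }
  pr <- .nussinov_pairs(sequence, as.integer(min_loop))
  if (nrow(pr) > 1) pr <- pr[order(pr[, 1]), , drop = FALSE]
  stems <- segment_stems(pr)
  dom <- if (nrow(stems)) which.max(stems$n_pairs) else integer(0)
  loop_len <- NA_integer_
  stem_arms <- NULL
  if (length(dom)) {
    loop_len <- stems$j_min[dom] - stems$i_max[dom] - 1L
    stem_arms <- list(
      arm5 = c(stems$i_min[dom], stems$i_max[dom]),
      arm3 = c(stems$j_min[dom], stems$j_max[dom])
    )
  }
  structure(list(
    pairs = pr,
    n_paired = nrow(pr),
    length = n,
    paired_fraction = if (n > 0) 2 * nrow(pr) / n else 0,
    stems = stems,
    dominant_stem = if (length(dom)) dom else NA_integer_,
    loop_len = loop_len,
    stem_arms = stem_arms
  ), class = "structure_fold")
}

# Group pairs into helical stems: consecutive pairs (sorted by 5' position)
# stay in one stem while both sides advance by 1-3 nt.
segment_stems <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(data.frame(i_min = integer(0), i_max = integer(0),
                      j_min = integer(0), j_max = integer(0),
                      n_pairs = integer(0)))
  }
  i <- pairs[, 1]; j <- pairs[, 2]
  stem_id <- integer(nrow(pairs))
  stem_id[1] <- 1L
  if (nrow(pairs) > 1) {
    for (k in 2:nrow(pairs)) {
      di <- i[k] - i[k - 1]
      dj <- j[k - 1] - j[k]
      stem_id[k] <- if (di >= 1 && di <= 3 && dj >= 1 && dj <= 3) {
        stem_id[k - 1]
      } else {
        stem_id[k - 1] + 1L
      }
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(pairs)), stem_id), function(idx) {
    data.frame(i_min = min(i[idx]), i_max = max(i[idx]),
               j_min = min(j[idx]), j_max = max(j[idx]),
               n_pairs = length(idx))
  }))
  rownames(out) <- NULL
  out
}

#' Validate that a fold is a typical single stem-loop hairpin
#'
#' Automates the "typical hairpin structure" check applied to candidate
#' miRNA precursors. A fold passes when (a) its dominant stem carries at
#' least `min_stem_pairs` base pairs, (b) at least `min_paired_frac` of all
#' bases are paired, and (c) the structure has exactly one terminal loop:
#' among stems with at least `min_branch_pairs` pairs, exactly one is
#' innermost (has no such stem nested inside it). Small incidental helices
#' (fewer than `min_branch_pairs` pairs) do not count as branches.
#'
#' @param fold A `structure_fold` from [fold_hairpin()].
#' @param sequence Optional sequence (unused; kept for call symmetry).
#' @param min_stem_pairs Minimum pairs in the dominant stem (default 15).
#' @param min_paired_frac Minimum paired fraction of the sequence (default 0.4).
#' @param min_branch_pairs Minimum pairs for a stem to count as a structural
#'   branch when counting terminal loops (default 4).
#' @return A list with `pass` (logical) and `reason` (`"ok"`, `"short_stem"`,
#'   `"paired_fraction"` or `"multi_loop"`).
#' @export
validate_hairpin <- function(fold, sequence = NULL, min_stem_pairs = 15L,
                             min_paired_frac = 0.4, min_branch_pairs = 4L) {
  stopifnot(inherits(fold, "structure_fold"))
  st <- fold$stems
  big <- st[st$n_pairs >= min_branch_pairs, , drop = FALSE]
  if (fold$paired_fraction < min_paired_frac) {
    return(list(pass = FALSE, reason = "paired_fraction"))
  }
  # terminal loops: innermost big stems
  if (nrow(big) > 1) {
    innermost <- vapply(seq_len(nrow(big)), function(a) {
      !any(vapply(seq_len(nrow(big)), function(b) {
        b != a && big$i_min[b] > big$i_max[a] && big$j_max[b] < big$j_min[a]
      }, logical(1)))
    }, logical(1))
    if (sum(innermost) > 1) {
      return(list(pass = FALSE, reason = "multi_loop"))
    }
  }
  if (!nrow(st) || max(st$n_pairs) < min_stem_pairs) {
    return(list(pass = FALSE, reason = "short_stem"))
  }
  list(pass = TRUE, reason = "ok")
}

#' @export
print.structure_fold <- function(x, ...) {
  cat(sprintf("structure_fold: %d nt, %d pairs (%.2f paired), %d stem(s)\n",
              x$length, x$n_paired, x$paired_fraction, nrow(x$stems)))
  if (!is.na(x$dominant_stem)) {
    d <- x$stems[x$dominant_stem, ]
    cat(sprintf("  dominant stem: %d pairs, 5' arm %d-%d, 3' arm %d-%d, loop %d nt\n",
                d$n_pairs, d$i_min, d$i_max, d$j_min, d$j_max, x$loop_len))
  }
  invisible(x)
}
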