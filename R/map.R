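#' Build an exact-match genome index
#'
#' Hashes every fixed-width prefix window of the genome (default 16 nt,
#' the minimum kept insert length) to its positions. Queries look up their
#' 5' prefix and verify the full-length match by substring comparison, so
#' mapping is exact, full-length, gap-free and mismatch-free by
#' construction.
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param width Index word width; mapped sequences must be at least this
#'   long (default 16).
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(genome, width = 16L) {
  chr <- as_genome_chr(genome)
  lens <- nchar(chr)
  offsets <- c(0, cumsum(as.numeric(lens)))[seq_along(chr)]
  all_kmers <- character(0)
  all_pos <- numeric(0)
  for (i in seq_along(chr)) {
    L <- lens[i]
    if (L < width) next
    all_kmers <- c(all_kmers, substring(chr[i], 1:(L - width + 1L), width:L))
    all_pos <- c(all_pos, seq_len(L - width + 1L) + offsets[i])
  }
  env <- list2env(split(all_pos, all_kmers),
                  envir = new.env(hash = TRUE, size = max(16L, sum(lens))))
  structure(list(env = env, chr = chr, lens = lens, offsets = offsets,
                 chrom_names = names(chr), width = as.integer(width)),
            class = "genome_index")
}

#' Map sequences exactly to a genome, both strands
#'
#' Reports every locus on either strand at which the full-length sequence
#' matches the genome exactly (no gaps, no mismatches). A minus-strand
#' locus is an interval whose reverse complement equals the sequence.
#' Sequences with no locus are absent from the result (flag them with
#' `setdiff` against the input if needed).
#'
#' @param sequences Character vector of distinct sequences (ACGT only),
#'   each at least as long as the index width.
#' @param genome Genome as for [genome_index()], or an existing
#'   `genome_index`.
#' @return data.frame of class `match_loci` with columns `sequence`,
#'   `chrom`, `start` (0-based), `end` (half-open) and `strand`.
#' @examples
#' map_exact("TAGGTAGTTTCATGTTGTTGG",
#'           c(chr1 = "CCCTAGGTAGTTTCATGTTGTTGGCCC"))
#' @export
map_exact <- function(sequences, genome) {
  idx <- if (inherits(genome, "genome_index")) genome else genome_index(genome)
  sequences <- unique(dna_normalize(sequences))
  if (any(nchar(sequences) < idx$width)) {
    stopf("all sequences must be >= index width (%d nt)", idx$width)
  }
  if (any(grepl("[^ACGT]", sequences))) {
    stopf("sequences must be over ACGT (N-containing reads are discarded upstream)")
  }
  env <- idx$env
  w <- idx$width
  boundaries <- c(idx$offsets, sum(as.numeric(idx$lens)))
  rc <- revcomp(sequences)
  scan_strand <- function(strand) {
    qry <- if (strand == "+") sequences else rc
    cand <- mget(substr(qry, 1L, w), envir = env, ifnotfound = list(NULL))
    nc <- lengths(cand)
    if (sum(nc) == 0) return(NULL)
    si <- rep(seq_along(qry), nc)
    pos <- unlist(cand, use.names = FALSE)
    ci <- findInterval(pos - 0.5, boundaries)
    local <- pos - idx$offsets[ci]
    len <- nchar(qry)[si]
    ok <- local + len - 1L <= idx$lens[ci]
    si <- si[ok]; ci <- ci[ok]; local <- local[ok]; len <- len[ok]
    match_ok <- logical(length(si))
    for (c1 in unique(ci)) {
      g <- ci == c1
      match_ok[g] <- substring(idx$chr[c1], local[g], local[g] + len[g] - 1L) ==
        qry[si[g]]
    }
    si <- si[match_ok]; ci <- ci[match_ok]; local <- local[match_ok]
    if (!length(si)) return(NULL)
    data.frame(sequence = sequences[si],
               chrom = idx$chrom_names[ci],
               start = local - 1L,
               end = local - 1L + nchar(sequences[si]),
               strand = strand, stringsAsFactors = FALSE)
  }
  res <- list(scan_strand("+"), scan_strand("-"))
  res <- res[!vapply(res, is.null, logical(1))]
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(sequence = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  out <- out[order(match(out$sequence, sequences), out$chrom, out$start,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("match_loci", class(out))
  out
}

#' Unmapped sequences
#' @param sequences Input sequences given to [map_exact()].
#' @param mapping The resulting `match_loci`.
#' @return Character vector of sequences with zero genome loci.
#' @export
unmapped_sequences <- function(sequences, mapping) {
  setdiff(unique(dna_normalize(sequences)), unique(mapping$sequence))
}

#' Size-class distribution of genome-matched reads
#'
#' Per library, sums the counts of genome-matched sequences at each insert
#' length (16-35 nt) and scales to reads per million genome-matched reads
#' (RPM). When a hairpin annotation is supplied, also reports the fraction
#' of each length class assigned to miRNA hairpins (a sequence counts as
#' miRNA when any of its loci is fully contained, same strand, in an
#' annotated hairpin interval).
#'
#' @param reads A `collapsed_reads`.
#' @param mapping `match_loci` for its sequences.
#' @param hairpins Optional hairpin annotation data.frame (columns chrom,
#'   start, end, strand; 0-based half-open).
#' @param lengths Length range profiled (default 16:35).
#' @return List with `rpm` (length x library matrix), `counts` (raw),
#'   `mirna_fraction` (length x library matrix or NULL) and
#'   `genome_matched` (per-library totals).
#' @export
size_class_profile <- function(reads, mapping, hairpins = NULL,
                               lengths = 16:35) {
  stopifnot(inherits(reads, "collapsed_reads"))
  cnt <- reads$counts
  mapped <- cnt$sequence %in% unique(mapping$sequence)
  libs <- names(reads$totals)
  m <- cnt[mapped, , drop = FALSE]
  totals <- vapply(libs, function(l) sum(m[[l]]), numeric(1))
  if (any(totals == 0)) {
    stopf("library with zero genome-matched reads: %s",
          paste(libs[totals == 0], collapse = ", "))
  }
  len <- nchar(m$sequence)
  counts <- matrix(0, length(lengths), length(libs),
                   dimnames = list(lengths, libs))
  for (l in libs) {
    tab <- tapply(m[[l]], factor(len, levels = lengths), sum)
    counts[, l] <- ifelse(is.na(tab), 0, tab)
  }
  rpm <- sweep(counts, 2, totals, "/") * 1e6
  mirna_fraction <- NULL
  if (!is.null(hairpins) && nrow(hairpins) > 0) {
    is_mir_seq <- mirna_sequences(mapping, hairpins)
    mir <- m$sequence %in% is_mir_seq
    mirna_fraction <- matrix(NA_real_, length(lengths), length(libs),
                             dimnames = list(lengths, libs))
    for (l in libs) {
      tot <- tapply(m[[l]], factor(len, levels = lengths), sum)
      mirc <- tapply(m[[l]][mir], factor(len[mir], levels = lengths), sum)
      tot[is.na(tot)] <- 0; mirc[is.na(mirc)] <- 0
      mirna_fraction[, l] <- ifelse(tot > 0, mirc / tot, NA_real_)
    }
  }
  list(rpm = rpm, counts = counts, mirna_fraction = mirna_fraction,
       genome_matched = totals)
}

# Sequences with >=1 locus fully contained (same strand) in a hairpin.
mirna_sequences <- function(mapping, hairpins) {
  if (nrow(mapping) == 0 || nrow(hairpins) == 0) return(character(0))
  q <- as_granges0(mapping)
  s <- as_granges0(hairpins)
  ov <- GenomicRanges::findOverlaps(q, s, type = "within")
  unique(mapping$sequence[S4Vectors::queryHits(ov)])
}
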