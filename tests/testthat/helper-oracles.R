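# Independent oracles and fixture builders used across the test suite.

# Naive exact mapper: compares the read against the genome window at
# EVERY position on both strands (windows materialised per read length,
# then compared directly). Independent of the prefix-hash index.
naive_map <- function(sequences, genome_chr) {
  rows <- list()
  sequences <- unique(sequences)
  for (ci in seq_along(genome_chr)) {
    g <- genome_chr[ci]
    L <- nchar(g)
    for (n in sort(unique(nchar(sequences)))) {
      if (n > L) next
      windows <- substring(g, 1:(L - n + 1), n:L)
      for (s in sequences[nchar(sequences) == n]) {
        rc <- crestmir::revcomp(s)
        for (strand in c("+", "-")) {
          probe <- if (strand == "+") s else rc
          hit <- which(windows == probe)
          if (length(hit)) {
            rows[[length(rows) + 1]] <- data.frame(
              sequence = s, chrom = names(genome_chr)[ci],
              start = hit - 1L, end = hit - 1L + n, strand = strand,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, rows)
}

# canonical hit-set key for comparing mappings
map_key <- function(df) {
  sort(paste(df$sequence, df$chrom, df$start, df$end, df$strand))
}

# Exhaustive maximum base pairing: enumerates every nested structure by
# explicit recursion over "first position unpaired / paired with k" and
# returns the maximum number of pairs. No memoization, no DP tables.
can_pair_oracle <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

enumerate_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (can_pair_oracle(ch[i], ch[k])) {
        inner <- rec(i + 1L, k - 1L)
        rest <- if (k < j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + rest)
      }
    }
    best
  }
  rec(1L, length(ch))
}

# Brute-force BH step-up from the definition.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  padj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    padj_sorted[k] <- min(1, min(m * ps[k:m] / (k:m)))
  }
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

# Independent median-of-ratios reference.
size_factors_oracle <- function(counts) {
  ref <- apply(counts, 1, function(r) exp(mean(log(r))))
  ok <- is.finite(ref) & ref > 0
  apply(counts, 2, function(col) median(col[ok] / ref[ok]))
}

# Brute-force interval overlap (any-overlap, 0-based half-open).
overlaps_any <- function(start, end, f_start, f_end) {
  any(start < f_end & f_start < end)
}

# Build a perfect stem-loop: arm + loop + reverse complement of arm.
make_hairpin_seq <- function(arm_len = 25, loop_len = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arm <- crestmir::random_dna(arm_len)
  paste0(arm, crestmir::random_dna(loop_len), crestmir::revcomp(arm))
}

# Minimal collapsed_reads object from a named list of count vectors
# (sequence -> count per library).
make_collapsed <- function(lib_counts) {
  seqs <- sort(unique(unlist(lapply(lib_counts, names))))
  counts <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (id in names(lib_counts)) {
    v <- lib_counts[[id]][seqs]
    v[is.na(v)] <- 0
    counts[[id]] <- as.numeric(v)
  }
  totals <- vapply(names(lib_counts), function(id) sum(counts[[id]]),
                   numeric(1))
  structure(list(counts = counts, totals = totals),
            class = "collapsed_reads")
}

# small default simulation shared by a few tests (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 3, genome_length = 30000, n_hairpin_loci = 8,
                        n_novel_loci = 2, repeat_copies = 2,
                        depth_per_library = 8000,
                        de_spec = list(list(unit = "hp05", tissue = "NC",
                                            log2fc = 2)))
      gt <- generate_genome(cfg)
      libs <- list()
      for (t in cfg$tissues) for (r in 1:2) {
        libs[[sprintf("%s_rep%d", t, r)]] <-
          simulate_library(gt$genome, gt$truth, t, r, cfg)$reads
      }
      pp <- preprocess_fastq(libs)
      mapping <- map_exact(pp$reads$counts$sequence, gt$genome)
      cache <<- list(cfg = cfg, gt = gt, pp = pp, mapping = mapping)
    }
    cache
  }
})
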