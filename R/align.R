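#' Annotation configuration
#'
#' Parameters of the whole-genome homology annotation ladder: local
#' alignment scoring, seed word size, the E-value cutoff, the multi-hit
#' and hairpin-length hit filters, and the all-sample abundance filter.
#'
#' @param evalue_max Maximum E-value for a reported hit (default 1e-06).
#' @param max_hits_per_query Queries with at least this many hits are
#'   removed entirely (default 30).
#' @param min_hairpin_len Minimum extracted hairpin length; loci of length
#'   55 or shorter are removed (default 56).
#' @param abundance_min Minimum all-sample read total for a hairpin to be
#'   kept without family rescue (default 100).
#' @param match,mismatch,gap_open,gap_extend Local alignment scoring
#'   (defaults +1/-2/-5/-2).
#' @param seed_word Exact seed word length for candidate detection
#'   (default 11).
#' @param karlin Optional list with `lambda` and `K` for the E-value
#'   formula `E = K * m * n * exp(-lambda * S)`. When NULL (default) the
#'   constants are fitted empirically once per session by
#'   [estimate_karlin()] under a fixed internal seed and cached.
#' @return A list of class `annot_config`.
#' @export
annot_config <- function(evalue_max = 1e-6, max_hits_per_query = 30L,
                         min_hairpin_len = 56L, abundance_min = 100L,
                         match = 1, mismatch = -2, gap_open = -5,
                         gap_extend = -2, seed_word = 11L, karlin = NULL) {
  if (match <= 0 || mismatch >= 0) stopf("scoring requires match > 0 > mismatch")
  if (evalue_max <= 0 || max_hits_per_query <= 0 || min_hairpin_len <= 0 ||
      abundance_min <= 0) {
    stopf("thresholds must be positive")
  }
  structure(as.list(environment()), class = "annot_config")
}

the_karlin_cache <- new.env(parent = emptyenv())

#' Fit Karlin-Altschul constants for the configured gapped scoring
#'
#' Estimates `lambda` and `K` of the extreme-value law
#' `P(S >= x) = 1 - exp(-K m n exp(-lambda x))` for maximal local
#' alignment scores of random sequences under the configured scoring,
#' by the method of moments on `nsim` simulated score maxima
#' (`lambda = pi / (sd * sqrt(6))`, `K` from the fitted location).
#' Random sequences are i.i.d. uniform ACGT, matching the composition of
#' shuffled queries.
#'
#' @param config An [annot_config()].
#' @param m,n Pattern and subject lengths of the simulated alignments.
#' @param nsim Number of simulated score maxima.
#' @param seed Seed for the simulation (the global RNG state is restored
#'   afterwards).
#' @return List with `lambda` and `K`.
#' @export
estimate_karlin <- function(config = annot_config(), m = 100L, n = 4000L,
                            nsim = 120L, seed = 20090429L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = TRUE)
  sc <- replicate(nsim, {
    p <- random_dna(m)
    s <- random_dna(n)
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(p), Biostrings::DNAString(s), type = "local",
      substitutionMatrix = mat, gapOpening = -config$gap_open,
      gapExtension = -config$gap_extend))
  })
  lambda <- pi / (sd(sc) * sqrt(6))
  mu <- mean(sc) - 0.57721566 / lambda
  K <- exp(lambda * mu) / (m * n)
  list(lambda = lambda, K = K)
}

get_karlin <- function(config) {
  if (!is.null(config$karlin)) return(config$karlin)
  key <- paste(config$match, config$mismatch, config$gap_open,
               config$gap_extend, sep = "/")
  if (is.null(the_karlin_cache[[key]])) {
    the_karlin_cache[[key]] <- estimate_karlin(config)
  }
  the_karlin_cache[[key]]
}

#' Seed-and-extend homology search of precursor queries against a genome
#'
#' Exact `seed_word`-nt word matches between query and genome nominate
#' candidate windows; each window is aligned locally (gapped, under the
#' configured scoring) and hits with `E < evalue_max` are reported, where
#' `E = K * m * n_eff * exp(-lambda * S)` with `m` the query length and
#' `n_eff` twice the genome length (both strands are searched).
#'
#' @param queries Named [Biostrings::DNAStringSet] (or named character) of
#'   known precursor hairpins, miRBase-style names.
#' @param genome Named [Biostrings::DNAStringSet] or named character.
#' @param config An [annot_config()].
#' @return data.frame with columns `query`, `chrom`, `start`, `end`
#'   (0-based half-open, genomic), `strand`, `score`, `evalue`, `qlen`.
#' @export
homology_search <- function(queries, genome, config = annot_config()) {
  qchr <- if (methods::is(queries, "DNAStringSet")) {
    setNames(as.character(queries), names(queries))
  } else queries
  if (length(qchr) == 0) stopf("queries must be non-empty")
  gchr <- as_genome_chr(genome)
  if (length(gchr) == 0 || sum(nchar(gchr)) == 0) stopf("empty genome")
  qchr[] <- dna_normalize(qchr)
  w <- config$seed_word
  kar <- get_karlin(config)
  n_eff <- 2 * sum(as.numeric(nchar(gchr)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = TRUE)

  # seed index of the forward genome
  idx <- new.env(hash = TRUE)
  for (ci in seq_along(gchr)) {
    L <- nchar(gchr[ci])
    if (L < w) next
    kmers <- substring(gchr[ci], 1:(L - w + 1L), w:L)
    sp <- split(seq_len(L - w + 1L), kmers)
    for (k in names(sp)) idx[[k]] <- rbind(idx[[k]], cbind(ci, sp[[k]]))
  }

  rows <- list()
  for (qi in seq_along(qchr)) {
    qname <- names(qchr)[qi] %||% paste0("query", qi)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") qchr[qi] else revcomp(qchr[qi])
      qlen <- nchar(q)
      if (qlen < w) next
      qk <- substring(q, 1:(qlen - w + 1L), w:qlen)
      hits <- list()
      for (p in seq_along(qk)) {
        hh <- idx[[qk[p]]]
        if (!is.null(hh)) {
          hits[[length(hits) + 1L]] <- cbind(hh, p)
        }
      }
      if (!length(hits)) next
      hits <- do.call(rbind, hits)  # columns: chrom idx, gpos, qpos
      for (ci in unique(hits[, 1])) {
        h <- hits[hits[, 1] == ci, , drop = FALSE]
        # candidate windows around the implied query start
        ws <- pmax(1L, h[, 2] - h[, 3] + 1L - qlen)
        win <- IRanges::reduce(IRanges::IRanges(start = ws, width = 3L * qlen))
        for (wi in seq_along(win)) {
          a <- IRanges::start(win)[wi]
          b <- min(IRanges::end(win)[wi], nchar(gchr[ci]))
          subj <- substr(gchr[ci], a, b)
          aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(q), Biostrings::DNAString(subj),
            type = "local", substitutionMatrix = mat,
            gapOpening = -config$gap_open, gapExtension = -config$gap_extend)
          S <- Biostrings::score(aln)
          E <- kar$K * qlen * n_eff * exp(-kar$lambda * S)
          if (E >= config$evalue_max) next
          sv <- Biostrings::subject(aln)
          g_start <- a + Biostrings::start(sv) - 1L  # 1-based genomic
          g_end <- a + Biostrings::end(sv) - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            query = qname, chrom = names(gchr)[ci],
            start = g_start - 1L, end = g_end, strand = strand,
            score = S, evalue = E, qlen = qlen, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               score = numeric(0), evalue = numeric(0), qlen = integer(0))
  # merged candidate windows can nominate the same locus more than once
  if (nrow(out) > 1) {
    key <- paste(out$query, out$chrom, out$start, out$end, out$strand)
    out <- out[!duplicated(key), , drop = FALSE]
    # drop overlapping same-query hits, keeping the best score
    out <- out[order(out$query, -out$score), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    gr <- as_granges0(out)
    ov <- GenomicRanges::findOverlaps(gr, gr)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    same <- out$query[qh] == out$query[sh] & qh < sh
    for (k in which(same)) {
      if (keep[qh[k]]) keep[sh[k]] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: permutes a sequence while preserving its
#' exact dinucleotide composition, via a random Eulerian walk over the
#' dinucleotide transition multigraph.
#'
#' @param sequence A single DNA string.
#' @return A shuffled string with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(sequence) {
  s <- strsplit(dna_normalize(sequence), "")[[1]]
  n <- length(s)
  if (n < 3) return(sequence)
  verts <- unique(s)
  edges <- lapply(setNames(verts, verts), function(v) s[which(s == v) + 1L])
  edges <- lapply(edges, function(e) e[!is.na(e)])
  last_char <- s[n]
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last_char || length(edges[[v]]) == 0) NA_character_
      else if (length(edges[[v]]) == 1) edges[[v]]
      else sample(edges[[v]], 1)
    }, character(1))
    # the "last edge" graph must lead every vertex to the final character
    ok <- TRUE
    for (v in verts) {
      if (v == last_char || is.na(last_edge[[v]])) next
      cur <- v
      for (step in seq_along(verts)) {
        cur <- last_edge[[cur]]
        if (is.na(cur) || cur == last_char) break
      }
      if (is.na(cur) || cur != last_char) { ok <- FALSE; break }
    }
    if (ok) break
  }
  shuffled <- lapply(setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (!is.na(last_edge[[v]])) {
      drop1 <- match(last_edge[[v]], e)
      e <- e[-drop1]
    }
    c(sample(e), if (!is.na(last_edge[[v]])) last_edge[[v]])
  })
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  cur <- s[1]
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
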