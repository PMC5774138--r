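#' @importFrom methods is
NULL

BASES <- c("A", "C", "G", "T")

# enable native data.table syntax inside this package
.datatable.aware <- TRUE

#' Normalise nucleotide strings to the uppercase DNA alphabet
#'
#' Mature miRNAs are conventionally printed as RNA; sequencing reads are DNA.
#' All package internals work on uppercase DNA, so U is mapped to T.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector over A, C, G, T (and any untouched ambiguity
#'   codes such as N).
#' @export
dna_normalize <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA
#'
#' Uniform i.i.d. bases; uses the current RNG state.
#'
#' @param n Sequence length.
#' @return A single DNA string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Transition partner for each base (A<->G, C<->T).
transition <- function(b) {
  c(A = "G", G = "A", C = "T", T = "C")[b]
}

# Inject k transition substitutions at distinct positions of a string.
inject_transitions <- function(seq, k, positions = NULL) {
  if (k == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(seq_along(ch), k)
  ch[positions] <- unname(transition(ch[positions]))
  paste(ch, collapse = "")
}

# Derive a stage seed from a root seed; kept within 32-bit integer range.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 97 + stage * 7919) %% 2147483629 + 1
}

# 0-based half-open data.frame intervals -> GRanges (1-based inclusive).
as_granges0 <- function(df, strand_col = "strand") {
  strand <- if (strand_col %in% names(df)) df[[strand_col]] else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Extract a miRNA family id from a miRBase-style precursor name,
# e.g. "xla-mir-130b-2" -> "mir-130b" and "hsa-let-7a-1" -> "let-7a".
family_from_name <- function(x) {
  res <- character(length(x))
  for (i in seq_along(x)) {
    mm <- regmatches(x[i], regexpr("(mir|let)-?[0-9]+[a-z]*", x[i],
                                   ignore.case = TRUE))
    res[i] <- if (length(mm)) tolower(mm) else x[i]
  }
  res
}
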