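#' Trimming configuration
#'
#' Parameters of HD-adapter read cleaning: the 3' adapter is located by a
#' perfect match to its first 8 nucleotides, the 4-nt HD signatures are
#' removed from both ends of the remainder, and inserts of 16-35 nt are
#' kept.
#'
#' @param adapter_prefix First 8 nt of the 3' adapter (default TGGAATTC).
#' @param hd_len HD signature length on each side (default 4).
#' @param min_len,max_len Closed insert-length keep window (default 16-35).
#' @return A list of class `trim_config`.
#' @export
trim_config <- function(adapter_prefix = "TGGAATTC", hd_len = 4L,
                        min_len = 16L, max_len = 35L) {
  adapter_prefix <- dna_normalize(adapter_prefix)
  if (nchar(adapter_prefix) != 8L) stopf("adapter_prefix must be 8 nt")
  if (min_len > max_len) stopf("min_len must be <= max_len")
  if (hd_len < 0) stopf("hd_len must be >= 0")
  structure(list(adapter_prefix = adapter_prefix, hd_len = as.integer(hd_len),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "trim_config")
}

#' Trim HD adapters from reads
#'
#' Locates the leftmost exact occurrence of the adapter prefix, truncates
#' the read there, and removes `hd_len` bases from each end of the
#' remainder; the rest is the insert. Reads are discarded (with a reason
#' code) when no adapter occurs (`no_adapter`), when the pre-adapter
#' remainder is shorter than `2*hd_len + 1` so that no insert base can
#' exist (`insert_too_short`), or when the insert contains an N
#' (`contains_n`) -- downstream mapping is exact-match. Trimming is not
#' iterated: an adapter-free insert passed back in is discarded, never
#' double-trimmed.
#'
#' @param reads Character vector of reads over A, C, G, T, N (U accepted
#'   and normalised to T).
#' @param config A [trim_config()].
#' @return data.frame with columns `insert` (NA when discarded) and
#'   `reason` (`kept`, `no_adapter`, `insert_too_short`, `contains_n`).
#' @examples
#' trim_reads("AACGTAGGTAGTTTCATGTTGTTGGGGTCTGGAATTCTCGG")$insert
#' @export
trim_reads <- function(reads, config = trim_config()) {
  reads <- dna_normalize(reads)
  n <- length(reads)
  hd <- config$hd_len
  pos <- regexpr(config$adapter_prefix, reads, fixed = TRUE)  # 1-based
  reason <- rep("kept", n)
  insert <- rep(NA_character_, n)
  reason[pos == -1L] <- "no_adapter"
  rem <- as.integer(pos) - 1L  # length of pre-adapter remainder
  too_short <- pos != -1L & rem < 2L * hd + 1L
  reason[too_short] <- "insert_too_short"
  ok <- reason == "kept"
  if (any(ok)) {
    ins <- substr(reads[ok], hd + 1L, rem[ok] - hd)
    has_n <- grepl("N", ins, fixed = TRUE)
    insert[ok] <- ifelse(has_n, NA_character_, ins)
    reason[ok][has_n] <- "contains_n"
  }
  data.frame(insert = insert, reason = reason, stringsAsFactors = FALSE)
}

#' @rdname trim_reads
#' @param read A single read.
#' @return `trim_read()`: the insert string, or NA with attribute `reason`.
#' @export
trim_read <- function(read, config = trim_config()) {
  r <- trim_reads(read, config)
  out <- r$insert[1]
  attr(out, "reason") <- r$reason[1]
  out
}

#' Length-filter inserts
#'
#' Keeps inserts whose length lies in the closed interval
#' `[min_len, max_len]`.
#'
#' @param inserts Character vector of inserts.
#' @param config A [trim_config()].
#' @return Logical vector, TRUE = keep.
#' @export
length_filter <- function(inserts, config = trim_config()) {
  len <- nchar(inserts)
  !is.na(inserts) & len >= config$min_len & len <= config$max_len
}

#' Collapse kept inserts into a per-library count table
#'
#' @param libraries Named list of character vectors of kept inserts, one
#'   element per library; names are the library ids.
#' @return An object of class `collapsed_reads`: list with `counts`
#'   (data.frame: `sequence` then one integer column per library) and
#'   `totals` (named integer vector of kept reads per library).
#' @export
collapse_reads <- function(libraries) {
  ids <- names(libraries)
  if (is.null(ids) || any(ids == "") ) stopf("libraries must be named")
  if (anyDuplicated(ids)) stopf("duplicate library ids")
  dt <- data.table::rbindlist(lapply(ids, function(id) {
    v <- libraries[[id]]
    if (length(v) == 0) {
      data.table::data.table(sequence = character(0), library = character(0))
    } else {
      data.table::data.table(sequence = v, library = id)
    }
  }))
  if (nrow(dt) == 0) {
    counts <- data.frame(sequence = character(0))
    for (id in ids) counts[[id]] <- integer(0)
    return(structure(list(counts = counts,
                          totals = setNames(integer(length(ids)), ids)),
                     class = "collapsed_reads"))
  }
  sequence <- library <- N <- NULL  # data.table NSE
  agg <- dt[, list(N = .N), by = list(sequence, library)]
  wide <- data.table::dcast(agg, sequence ~ library, value.var = "N",
                            fill = 0L)
  for (id in setdiff(ids, names(wide))) wide[[id]] <- 0L
  counts <- as.data.frame(wide)[, c("sequence", ids)]
  counts <- counts[order(counts$sequence), , drop = FALSE]
  rownames(counts) <- NULL
  totals <- vapply(ids, function(id) sum(counts[[id]]), integer(1))
  structure(list(counts = counts, totals = totals),
            class = "collapsed_reads")
}

#' @export
print.collapsed_reads <- function(x, ...) {
  cat(sprintf("collapsed_reads: %d distinct sequences, %d libraries, %s kept reads\n",
              nrow(x$counts), length(x$totals),
              format(sum(x$totals), big.mark = ",")))
  invisible(x)
}

#' Preprocess FASTQ libraries to a collapsed read set
#'
#' Runs [trim_reads()] and [length_filter()] on each library and collapses
#' the kept inserts, keeping a per-library audit of discard reasons.
#'
#' @param fastqs Named character vector (or list) of FASTQ paths, or a
#'   named list of character vectors of raw read sequences.
#' @param config A [trim_config()].
#' @return List with `reads` (a `collapsed_reads`) and `audit`
#'   (data.frame: library, raw, no_adapter, insert_too_short, contains_n,
#'   too_short, too_long, kept). Raw counts always equal the sum of kept
#'   and all discard reasons.
#' @export
preprocess_fastq <- function(fastqs, config = trim_config()) {
  ids <- names(fastqs)
  if (is.null(ids)) stopf("fastqs must be named by library id")
  if (anyDuplicated(ids)) stopf("duplicate library ids")
  kept <- list()
  audit <- list()
  for (id in ids) {
    x <- fastqs[[id]]
    reads <- if (length(x) == 1 && file.exists(x)) read_fastq(x) else x
    tr <- trim_reads(reads, config)
    reason <- tr$reason
    lens <- nchar(tr$insert)
    reason[reason == "kept" & !is.na(lens) & lens < config$min_len] <- "too_short"
    reason[reason == "kept" & !is.na(lens) & lens > config$max_len] <- "too_long"
    kept[[id]] <- tr$insert[reason == "kept"]
    audit[[id]] <- data.frame(
      library = id, raw = length(reads),
      no_adapter = sum(reason == "no_adapter"),
      insert_too_short = sum(reason == "insert_too_short"),
      contains_n = sum(reason == "contains_n"),
      too_short = sum(reason == "too_short"),
      too_long = sum(reason == "too_long"),
      kept = sum(reason == "kept"), stringsAsFactors = FALSE)
  }
  list(reads = collapse_reads(kept), audit = do.call(rbind, audit))
}

#' Write a collapsed read set as FASTA plus a count TSV
#'
#' FASTA headers follow the `seq_<rank>_x<count>` convention (rank by
#' total count, count = all-library total).
#'
#' @param reads A `collapsed_reads`.
#' @param fasta,tsv Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_collapsed <- function(reads, fasta, tsv) {
  cnt <- reads$counts
  total <- if (nrow(cnt)) rowSums(cnt[, -1, drop = FALSE]) else numeric(0)
  ord <- order(-total, cnt$sequence)
  cnt <- cnt[ord, , drop = FALSE]
  total <- total[ord]
  if (nrow(cnt)) {
    hdr <- sprintf("seq_%d_x%d", seq_len(nrow(cnt)), as.integer(total))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(cnt$sequence, hdr)), fasta)
  } else {
    writeLines(character(0), fasta)
  }
  write_tsv(cnt, tsv)
  invisible(list(fasta = fasta, tsv = tsv))
}
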