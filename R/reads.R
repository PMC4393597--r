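# Small-RNA read processing: adapter trimming, length filtering, read
# collapsing.  All functions are vectorized over reads.

#' Trim a 3' sequencing adapter from reads
#'
#' Finds the leftmost position at which the read matches a prefix of the
#' adapter of length at least `min_overlap` -- either the adapter itself
#' occurring inside the read, or a shorter adapter prefix overhanging the
#' read's 3' end -- and returns the read sequence 5' of that position.
#' Matching is exact (no mismatches).  Reads without a match are returned
#' unchanged.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter prefix length that counts as a match.
#' @return character vector of trimmed reads.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  stopifnot(is.character(adapter), length(adapter) == 1L, nzchar(adapter))
  min_overlap <- min(as.integer(min_overlap), nchar(adapter))
  seed <- substr(adapter, 1L, min_overlap)
  out <- reads
  n <- nchar(reads)
  # fast path: first occurrence of the minimal adapter prefix, extended to
  # the read end or the full adapter; accept iff the extension still
  # matches the adapter
  pos <- as.integer(regexpr(seed, reads, fixed = TRUE))
  idx <- which(pos > 0L)
  if (length(idx)) {
    span <- pmin(n[idx] - pos[idx] + 1L, nchar(adapter))
    ok <- substring(reads[idx], pos[idx], pos[idx] + span - 1L) ==
      substring(adapter, 1L, span)
    good <- idx[ok]
    out[good] <- substring(reads[good], 1L, pos[good] - 1L)
    # slow path: the leftmost seed occurrence failed extension; try every
    # later occurrence
    for (i in idx[!ok]) {
      hits <- gregexpr(seed, reads[i], fixed = TRUE)[[1]]
      for (p in hits[-1]) {
        span <- min(n[i] - p + 1L, nchar(adapter))
        if (substr(reads[i], p, p + span - 1L) ==
            substr(adapter, 1L, span)) {
          out[i] <- substr(reads[i], 1L, p - 1L)
          break
        }
      }
    }
  }
  out
}

#' Filter reads to a length window
#'
#' @param reads character vector.
#' @param min_len,max_len inclusive length bounds (defaults keep the
#'   canonical mature-miRNA window of 20-23 nt).
#' @return the reads whose length falls in `[min_len, max_len]`, in input
#'   order.
#' @export
filter_by_length <- function(reads, min_len = 20L, max_len = 23L) {
  stopifnot(min_len <= max_len)
  n <- nchar(reads)
  reads[n >= min_len & n <= max_len]
}

#' Drop reads containing ambiguous bases
#'
#' Downstream perfect genome matching requires unambiguous bases, so reads
#' containing anything outside ACGT are discarded after trimming.
#' @param reads character vector.
#' @return reads consisting solely of ACGT.
#' @export
discard_ambiguous <- function(reads) {
  reads[!grepl("[^ACGT]", reads)]
}

#' Collapse reads to distinct sequences with counts
#'
#' @param reads character vector of trimmed, length-filtered reads.
#' @param tissue tissue label attached to every record.
#' @return data frame with columns `sequence`, `count`, `tissue`, sorted
#'   lexicographically by sequence; counts sum to `length(reads)`.
#' @export
collapse_reads <- function(reads, tissue) {
  if (length(reads) == 0L)
    return(data.frame(sequence = character(0), count = integer(0),
                      tissue = character(0), stringsAsFactors = FALSE))
  tab <- table(reads)
  data.frame(sequence = names(tab), count = as.integer(tab),
             tissue = tissue, row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full small-RNA preprocessing for a set of tissue libraries
#'
#' Adapter-trims, length-filters, drops ambiguous reads, and collapses each
#' tissue's library.
#'
#' @param libraries named list (tissue -> character vector of raw reads) or
#'   named character vector of FASTQ paths.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len length window.
#' @param min_overlap minimum adapter overlap for trimming.
#' @return data frame of collapsed reads across tissues (columns
#'   `sequence`, `count`, `tissue`).
#' @export
process_small_rna <- function(libraries, adapter, min_len = 20L,
                              max_len = 23L, min_overlap = 5L) {
  if (is.character(libraries))
    libraries <- lapply(setNames(as.list(libraries), names(libraries)),
                        read_fastq)
  stopifnot(!is.null(names(libraries)))
  out <- lapply(names(libraries), function(tis) {
    r <- trim_adapter(unname(libraries[[tis]]), adapter, min_overlap)
    r <- filter_by_length(r, min_len, max_len)
    r <- discard_ambiguous(r)
    collapse_reads(r, tis)
  })
  do.call(rbind, out)
}
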