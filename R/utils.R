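DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Derive an independent, reproducible sub-seed from a root seed.  Keeps the
# result a valid positive 32-bit integer so stage-level streams are decoupled
# but fully determined by the root seed.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 11 * offset) %% 2147483647L) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  random_dna_vec(rep.int(len, n))
}

# vector of random sequences with per-element lengths, drawn from one
# contiguous base stream (fast for many short sequences)
random_dna_vec <- function(lens) {
  if (!length(lens)) return(character(0))
  codes <- utf8ToInt("ACGT")[sample.int(4L, sum(lens), replace = TRUE)]
  big <- intToUtf8(codes)
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

# Encode sequences as an integer matrix (rows = sequences), A/C/G/T -> 1..4,
# right-padded with 0 up to `width`.  Padding never equals a base code, so a
# full-width rowwise comparison of two encoded sequences counts Hamming
# mismatches over the common prefix plus the length difference.
seq_int_matrix <- function(seqs, width) {
  n <- length(seqs)
  m <- matrix(0L, nrow = n, ncol = width)
  if (n == 0L) return(m)
  code <- integer(128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt("a")] <- 1L; code[utf8ToInt("c")] <- 2L
  code[utf8ToInt("g")] <- 3L; code[utf8ToInt("t")] <- 4L
  for (i in seq_len(n)) {
    v <- code[utf8ToInt(seqs[i])]
    if (length(v) > width)
      stop("sequence longer than encoding width")
    if (length(v)) m[i, seq_along(v)] <- v
  }
  m
}

# End-anchored (5'-aligned) mismatch counts between every sequence in `seqs`
# and every reference in `refs`: Hamming distance over the common prefix plus
# the 3' length difference; pairs whose length difference exceeds
# `max_len_diff` get Inf.  Returns a length(seqs) x length(refs) matrix.
mismatch_matrix <- function(seqs, refs, max_len_diff = 2L) {
  width <- max(nchar(c(seqs, refs)), 1L)
  tM <- t(seq_int_matrix(seqs, width))
  out <- matrix(Inf, nrow = length(seqs), ncol = length(refs))
  ls <- nchar(seqs)
  for (j in seq_along(refs)) {
    r <- seq_int_matrix(refs[j], width)[1L, ]
    mm <- as.numeric(colSums(tM != r))
    mm[abs(ls - nchar(refs[j])) > max_len_diff] <- Inf
    out[, j] <- mm
  }
  out
}

# Apply `k` random substitutions to a DNA sequence at distinct positions.
mutate_seq <- function(seq, k) {
  if (k == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
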