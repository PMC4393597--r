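# RNA secondary structure for precursor classification.

#' Fold an RNA sequence by base-pair maximization
#'
#' Computes a maximum base-pairing nested secondary structure
#' (Watson-Crick plus GU wobble) with hairpin loops of at least `min_loop`
#' unpaired bases, via dynamic programming.  The traceback is
#' deterministic: among co-optimal structures the 5'-most pairing partner
#' is preferred at every step.  An optional thermodynamic backend delegates
#' to ViennaRNA's RNAfold binary when it is available; the pair count then
#' reflects the minimum-free-energy structure rather than the pairing
#' maximum.
#'
#' @param seq a single DNA/RNA sequence (T and U are equivalent).
#' @param min_loop minimum hairpin loop length (bases), base-pair
#'   maximization backend only.
#' @param backend `"maxpair"` (default) or `"vienna"`.
#' @return a `FoldResult` list: `structure` (dot-bracket), `pair_count`,
#'   and `pairs`, a 2-column matrix of 1-based (i, j) partners.
#' @export
fold <- function(seq, min_loop = 3L, backend = c("maxpair", "vienna")) {
  backend <- match.arg(backend)
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGUTacgut]", seq))
    stop("fold: sequence contains a non-ACGU(T) character")
  if (backend == "vienna") return(fold_vienna(seq))
  res <- fold_maxpair_cpp(seq, as.integer(min_loop))
  structure(res, class = "FoldResult")
}

#' @export
print.FoldResult <- function(x, ...) {
  cat(sprintf("FoldResult: %d base pairs\n%s\n", x$pair_count, x$structure))
  invisible(x)
}

# Minimum-free-energy fold via the RNAfold command-line tool.
fold_vienna <- function(seq) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe))
    stop("vienna backend requested but RNAfold is not on the PATH")
  out <- system2(exe, c("--noPS"), input = seq, stdout = TRUE)
  db <- strsplit(out[2], " ")[[1]][1]
  pairs_from_dotbracket(db)
}

# Parse a dot-bracket string into a FoldResult.
pairs_from_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  plist <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      plist[[length(plist) + 1L]] <- c(j, i)
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  if (length(plist)) {
    pairs <- do.call(rbind, plist)
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  }
  structure(list(structure = db, pair_count = nrow(pairs), pairs = pairs),
            class = "FoldResult")
}

#' Classify a candidate precursor hairpin
#'
#' Decides whether a folded precursor supports the mature sequence as a
#' genuine miRNA arm.  Pass requires that, in the folded structure:
#' (a) the mature region lies entirely on one arm (all pairing partners of
#' its bases fall on the same side, i.e. it does not span the terminal
#' loop); (b) at least `min_paired_frac` of the mature bases are paired;
#' (c) the partners form a contiguous star window on the opposite arm
#' (partner span at most mature length + `bulge_tol`).  The arm is `5p`
#' when the partners lie 3' of the mature region, `3p` otherwise.
#'
#' @param precursor precursor sequence.
#' @param mature_offset 1-based offset of the mature within the precursor.
#' @param mature_len mature length.
#' @param fold_result a `FoldResult` for `precursor`; folded on demand when
#'   omitted.
#' @param min_paired_frac minimum fraction of paired mature bases.
#' @param bulge_tol slack (nt) allowed in the star window span.
#' @param backend fold backend used when `fold_result` is missing.
#' @return list with `pass` (logical) and `arm` (`"5p"`, `"3p"`, or
#'   `"none"`).
#' @export
classify_hairpin <- function(precursor, mature_offset, mature_len,
                             fold_result = NULL, min_paired_frac = 0.75,
                             bulge_tol = 4L,
                             backend = c("maxpair", "vienna")) {
  if (is.null(fold_result))
    fold_result <- fold(precursor, backend = match.arg(backend))
  n <- nchar(precursor)
  if (nchar(fold_result$structure) != n)
    stop("fold result does not match precursor length")
  if (mature_offset < 1L || mature_offset + mature_len - 1L > n)
    stop("mature region outside precursor")
  partner <- rep(NA_integer_, n)
  if (nrow(fold_result$pairs)) {
    partner[fold_result$pairs[, 1]] <- fold_result$pairs[, 2]
    partner[fold_result$pairs[, 2]] <- fold_result$pairs[, 1]
  }
  idx <- mature_offset:(mature_offset + mature_len - 1L)
  p <- partner[idx]
  p <- p[!is.na(p)]
  fail <- list(pass = FALSE, arm = "none")
  # The stem containing the mature is a contiguous star window of width
  # mature_len + bulge_tol on one side of the mature; pass requires that
  # at least min_paired_frac of the mature bases pair into one such
  # window.  Partners within the mature itself (self-pairing) belong to
  # no stem, a stray long-range pair falls outside every window, and a
  # mature spanning the terminal loop splits its partners between sides
  # so neither window can reach the threshold.
  width <- mature_len + bulge_tol
  best_in_window <- function(q) {
    if (!length(q)) return(0L)
    q <- sort(q)
    max(vapply(seq_along(q), function(i)
      sum(q >= q[i] & q <= q[i] + width - 1L), integer(1)))
  }
  down <- best_in_window(p[p > max(idx)])
  up <- best_in_window(p[p < min(idx)])
  if (max(down, up) / mature_len < min_paired_frac) return(fail)
  list(pass = TRUE, arm = if (down >= up) "5p" else "3p")
}
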