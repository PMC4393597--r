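# miRNA locus discovery: catalog matching, contaminant filtering, perfect
# genome mapping, precursor extraction, hairpin classification, and the
# locus-calling pipeline that strings them together.

#' Match small-RNA sequences against a conserved-miRNA catalog
#'
#' Ungapped, 5'-end-anchored comparison of each query against every catalog
#' mature sequence, tolerating a 3' length difference of up to 2 nt (the
#' length difference counts towards the mismatch total, as do substitutions
#' over the shared prefix).  Returns the family of the best-matching entry
#' or `NA` when the best exceeds `max_mismatch`; ties are broken by
#' lexicographic family name.
#'
#' @param seqs character vector of query sequences (typically 20-23 nt).
#' @param catalog data frame with columns `sequence`, `family` (and
#'   optionally `source`).
#' @param max_mismatch maximum tolerated mismatches.
#' @return character vector of family labels (`NA` = no match).
#' @export
match_conserved <- function(seqs, catalog, max_mismatch = 2L) {
  if (length(seqs) == 0L) return(character(0))
  if (is.null(catalog) || nrow(catalog) == 0L)
    return(rep(NA_character_, length(seqs)))
  ord <- order(catalog$family)  # ties resolved towards earlier family name
  catalog <- catalog[ord, , drop = FALSE]
  mm <- mismatch_matrix(seqs, catalog$sequence, max_len_diff = 2L)
  best <- apply(mm, 1L, which.min)
  bestmm <- mm[cbind(seq_along(seqs), best)]
  fam <- catalog$family[best]
  fam[bestmm > max_mismatch] <- NA_character_
  fam
}

#' Remove sequences occurring inside contaminant records
#'
#' Drops every query that is an exact substring of any contaminant sequence
#' on either strand (rRNA, snoRNA, snRNA, tRNA and similar small-RNA
#' contaminants).
#'
#' @param seqs character vector of query sequences.
#' @param contaminants named character vector of contaminant sequences.
#' @return the retained sequences, in input order.
#' @export
filter_contaminants <- function(seqs, contaminants) {
  if (length(seqs) == 0L || length(contaminants) == 0L) return(seqs)
  subject <- paste(c(contaminants, revcomp(contaminants)), collapse = "N")
  hit <- vapply(seqs, function(s) grepl(s, subject, fixed = TRUE),
                logical(1), USE.NAMES = FALSE)
  seqs[!hit]
}

#' Find all perfect genomic matches of a sequence
#'
#' Exhaustive exact matching on both strands of every contig.  Minus-strand
#' placements report plus-strand coordinates of the reverse complement
#' occurrence.
#'
#' @param seq a single query sequence.
#' @param genome named character vector of contig sequences.
#' @return data frame with columns `contig`, `start`, `end` (1-based
#'   inclusive), `strand`, sorted by (contig, start, strand); zero rows if
#'   unmatched.
#' @export
map_perfect <- function(seq, genome) {
  stopifnot(length(seq) == 1L)
  rows <- list()
  rc <- revcomp(seq)
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else rc
      m <- Biostrings::matchPattern(pat, subj)
      if (length(m))
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = Biostrings::start(m),
          end = Biostrings::end(m), strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

#' Extract a candidate precursor around a genomic match
#'
#' Returns the genomic window from `start - flank` to `end + flank`,
#' truncated at contig edges (with truncation flagged), reverse-complemented
#' for minus-strand placements so the precursor always reads 5'->3' with
#' respect to the mature sequence.
#'
#' @param placement one-row data frame with contig/start/end/strand.
#' @param genome named character vector of contigs.
#' @param flank flanking bases on each side.
#' @return list with `sequence`, `contig`, `start`, `end` (plus-strand
#'   coordinates of the window), `strand`, `mature_offset` (1-based offset
#'   of the mature inside the precursor), `truncated_5p`, `truncated_3p`.
#' @export
extract_precursor <- function(placement, genome, flank = 140L) {
  ctg <- genome[[placement$contig]]
  n <- nchar(ctg)
  w_start <- max(1L, placement$start - flank)
  w_end <- min(n, placement$end + flank)
  seq <- substr(ctg, w_start, w_end)
  trunc_left <- placement$start - flank < 1L
  trunc_right <- placement$end + flank > n
  if (placement$strand == "+") {
    mature_offset <- placement$start - w_start + 1L
    t5 <- trunc_left; t3 <- trunc_right
  } else {
    seq <- revcomp(seq)
    mature_offset <- w_end - placement$end + 1L
    t5 <- trunc_right; t3 <- trunc_left
  }
  list(sequence = seq, contig = placement$contig, start = w_start,
       end = w_end, strand = placement$strand,
       mature_offset = mature_offset, truncated_5p = t5,
       truncated_3p = t3)
}

#' Call conserved and novel miRNA loci from collapsed small-RNA reads
#'
#' The discovery pipeline: (1) match collapsed sequences against the
#' conserved catalog; (2) remove contaminant-matching sequences from the
#' unmatched set; (3) map surviving sequences perfectly to the genome (both
#' strands, exhaustive); (4) extract precursors with `flank` bases of
#' context; (5) fold each precursor and (6) classify the hairpin.
#' Candidates sharing a precursor window (same contig/strand, overlapping
#' extents) are merged into a single locus with 5p/3p arms.  Conserved loci
#' are named by family; surviving unmatched sequences with at least
#' `min_novel_support` raw reads become `NOVEL` loci with serial names.
#'
#' @param collapsed data frame of collapsed reads across tissues
#'   (`sequence`, `count`, `tissue`), as from [process_small_rna()].
#' @param catalog conserved catalog data frame (`sequence`, `family`).
#' @param contaminants named character vector of contaminant sequences.
#' @param genome named character vector of contigs.
#' @param flank flanking bases for precursor extraction.
#' @param max_mismatch catalog-matching tolerance.
#' @param min_novel_support minimum summed raw reads for a novel candidate.
#' @param map_min_count minimum summed raw reads before a sequence is
#'   mapped to the genome at all (suppresses one-off error variants).
#' @param backend fold backend for precursor classification.
#' @param min_paired_frac,bulge_tol hairpin classification thresholds, see
#'   [classify_hairpin()].
#' @param local_flank when the full retrieval window fails classification,
#'   the candidate is re-folded on a `local_flank` window around the
#'   mature before rejection (pre-miRNA hairpins are local structures).
#' @return data frame of loci: `locus_id`, `family` (`NA` for novel),
#'   `contig`, `start`, `end`, `strand`, `arm5_seq`, `arm5_start`,
#'   `arm3_seq`, `arm3_start` (arm starts are 1-based offsets within the
#'   precursor), `novel`, `support`.
#' @export
call_loci <- function(collapsed, catalog, contaminants, genome,
                      flank = 140L, max_mismatch = 2L,
                      min_novel_support = 10L, map_min_count = 5L,
                      backend = c("vienna", "maxpair"),
                      min_paired_frac = 0.75, bulge_tol = 4L,
                      local_flank = 70L) {
  backend <- match.arg(backend)
  if (backend == "vienna" && !nzchar(Sys.which("RNAfold")))
    backend <- "maxpair"
  empty <- data.frame(locus_id = character(0), family = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      arm5_seq = character(0), arm5_start = integer(0),
                      arm3_seq = character(0), arm3_start = integer(0),
                      novel = logical(0), support = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(collapsed) || nrow(collapsed) == 0L) return(empty)

  support <- tapply(collapsed$count, collapsed$sequence, sum)
  seqs <- names(support)
  support <- as.integer(support)

  fam <- match_conserved(seqs, catalog, max_mismatch)
  unmatched <- seqs[is.na(fam)]
  kept_unmatched <- filter_contaminants(unmatched, contaminants)

  # candidate sequences for genomic placement
  cand <- data.frame(sequence = seqs, family = fam,
                     support = support, stringsAsFactors = FALSE)
  cand <- cand[!is.na(cand$family) | cand$sequence %in% kept_unmatched, ,
               drop = FALSE]
  cand <- cand[cand$support >= map_min_count, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  hits <- list()
  for (i in seq_len(nrow(cand))) {
    pl <- map_perfect(cand$sequence[i], genome)
    if (nrow(pl) == 0L) next
    for (r in seq_len(nrow(pl))) {
      prec <- extract_precursor(pl[r, ], genome, flank)
      mlen <- nchar(cand$sequence[i])
      fr <- fold(prec$sequence, backend = backend)
      cls <- classify_hairpin(prec$sequence, prec$mature_offset, mlen, fr,
                              min_paired_frac = min_paired_frac,
                              bulge_tol = bulge_tol)
      if (!cls$pass && local_flank < flank) {
        # distal structure in the full retrieval window can outcompete
        # the local stem; pre-miRNA hairpins are local, so re-fold a
        # window of local_flank around the mature before rejecting
        s2 <- max(1L, prec$mature_offset - local_flank)
        e2 <- min(nchar(prec$sequence),
                  prec$mature_offset + mlen - 1L + local_flank)
        sub <- substr(prec$sequence, s2, e2)
        cls <- classify_hairpin(sub, prec$mature_offset - s2 + 1L, mlen,
                                fold(sub, backend = backend),
                                min_paired_frac = min_paired_frac,
                                bulge_tol = bulge_tol)
      }
      if (!cls$pass) next
      hits[[length(hits) + 1L]] <- data.frame(
        sequence = cand$sequence[i], family = cand$family[i],
        support = cand$support[i], contig = prec$contig,
        start = prec$start, end = prec$end, strand = prec$strand,
        arm = cls$arm, m_start = if (prec$strand == "+") pl$start[r]
                                 else pl$end[r],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)

  # drop novel candidates lacking read support
  h <- h[!is.na(h$family) | h$support >= min_novel_support, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)

  # merge candidates sharing a precursor window on the same contig/strand
  h <- h[order(h$contig, h$strand, h$start, h$end), , drop = FALSE]
  grp <- integer(nrow(h)); g <- 0L
  last_end <- -Inf; last_key <- ""
  for (i in seq_len(nrow(h))) {
    key <- paste(h$contig[i], h$strand[i])
    if (key != last_key || h$start[i] > last_end) {
      g <- g + 1L; last_end <- h$end[i]
    } else last_end <- max(last_end, h$end[i])
    last_key <- key
    grp[i] <- g
  }

  loci <- lapply(split(h, grp), function(d) {
    fam_d <- d$family[!is.na(d$family)]
    family <- if (length(fam_d)) {
      sup <- tapply(d$support[!is.na(d$family)], fam_d, sum)
      names(sup)[order(-sup, names(sup))][1]
    } else NA_character_
    start <- min(d$start); end <- max(d$end)
    arm_pick <- function(a) {
      da <- d[d$arm == a, , drop = FALSE]
      if (nrow(da) == 0L) return(list(seq = NA_character_, start = NA_integer_))
      da <- da[order(-da$support, da$sequence), , drop = FALSE]
      off <- if (da$strand[1] == "+") da$m_start[1] - start + 1L
             else end - da$m_start[1] + 1L
      list(seq = da$sequence[1], start = off)
    }
    a5 <- arm_pick("5p"); a3 <- arm_pick("3p")
    data.frame(family = family, contig = d$contig[1], start = start,
               end = end, strand = d$strand[1], arm5_seq = a5$seq,
               arm5_start = a5$start, arm3_seq = a3$seq,
               arm3_start = a3$start, novel = is.na(family),
               support = sum(d$support), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  n_novel <- 0L
  ids <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (out$novel[i]) {
      n_novel <- n_novel + 1L
      ids[i] <- sprintf("novel-%d", n_novel)
    } else ids[i] <- out$family[i]
  }
  # distinct loci of the same family get a positional suffix
  dup <- ave(seq_along(ids), ids, FUN = seq_along)
  ids[dup > 1] <- paste0(ids[dup > 1], "-", dup[dup > 1])
  out <- cbind(data.frame(locus_id = ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
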