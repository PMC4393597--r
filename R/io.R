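# File-format plumbing.  Standard formats go through Biostrings /
# rtracklayer; TRANSFAC-like matrices and OBO term stanzas have small
# purpose-built readers.

#' Read / write FASTA
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a character vector of reads
#' @param path file path.
#' @return character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write reads as FASTQ with a fixed quality string
#' @param reads character vector of read sequences.
#' @param path file path.
#' @param ids optional read identifiers.
#' @param qual_char single Phred+33 quality character applied to every base.
#' @export
write_fastq <- function(reads, path, ids = NULL, qual_char = "I") {
  ids <- ids %||% sprintf("read%06d", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n)
    strrep(qual_char, n), character(1))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con, sep = "\n")
  invisible(path)
}

#' Export miRNA loci as GFF3
#'
#' One `pre_miRNA` feature per locus (1-based inclusive coordinates) with
#' `miRNA` child features for the 5p/3p arms; attributes carry the family
#' label or the novel flag.
#' @param loci data frame of loci as returned by [call_loci()] or found in a
#'   simulation truth table.
#' @param path output file.
#' @export
write_loci_gff3 <- function(loci, path) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = l$contig, start = l$start, end = l$end, strand = l$strand,
      type = "pre_miRNA", ID = l$locus_id,
      Name = if (is.na(l$family)) l$locus_id else l$family,
      novel = is.na(l$family), stringsAsFactors = FALSE)
    for (arm in c("5p", "3p")) {
      seq_col <- paste0("arm", substr(arm, 1, 1), "_seq")
      off_col <- paste0("arm", substr(arm, 1, 1), "_start")
      if (!is.na(l[[seq_col]])) {
        astart <- l$start + l[[off_col]] - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = l$contig, start = astart,
          end = astart + nchar(l[[seq_col]]) - 1L, strand = l$strand,
          type = "miRNA", ID = paste0(l$locus_id, "-", arm),
          Name = paste0(l$locus_id, "-", arm), novel = is.na(l$family),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$seqnames, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID, Name = df$Name, novel = df$novel)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#' @param df data frame with columns contig, start, end (1-based inclusive),
#'   name, strand.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(df$contig, df$start - 1L, df$end, df$name,
                    0L, df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TRANSFAC-like count matrices
#'
#' Parses plain-text records of the form used by TRANSFAC-style matrix
#' libraries: an `ID` (or `NA`) line naming the matrix, a `P0  A  C  G  T`
#' header, numbered rows of per-position counts, and a `//` terminator.
#' @param path file path.
#' @param ... passed to [pwm()] (pseudocount, core size).
#' @return list of [pwm()] objects.
#' @export
read_transfac <- function(path, ...) {
  lines <- readLines(path)
  pwms <- list()
  name <- NULL
  counts <- NULL
  col_order <- c("A", "C", "G", "T")
  flush <- function() {
    if (!is.null(counts) && length(counts)) {
      m <- t(do.call(rbind, counts))
      rownames(m) <- col_order
      pwms[[length(pwms) + 1L]] <<- pwm(m, name = name %||%
                                          paste0("M", length(pwms) + 1L), ...)
    }
    name <<- NULL; counts <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "XX")) next
    if (startsWith(ln, "//")) { flush(); next }
    fields <- strsplit(ln, "\\s+")[[1]]
    tag <- fields[1]
    if (tag %in% c("ID", "NA")) {
      name <- fields[length(fields)]
    } else if (tag == "P0" || tag == "PO") {
      col_order <- toupper(fields[2:5])
      counts <- list()
    } else if (grepl("^[0-9]+$", tag)) {
      counts[[length(counts) + 1L]] <- as.numeric(fields[2:5])
    }
  }
  flush()
  pwms
}

#' Write PWMs in the TRANSFAC-like layout accepted by [read_transfac()]
#' @param pwms list of [pwm()] objects.
#' @param path output file.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(sprintf("ID %s", p$name), "P0 A C G T"), con)
    for (i in seq_len(ncol(p$counts)))
      writeLines(sprintf("%02d %s", i,
                         paste(format(p$counts[, i], trim = TRUE),
                               collapse = " ")), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Minimal OBO reader for GO-style term stanzas
#'
#' Extracts `[Term]` stanzas with their id, name, namespace, `is_a` and
#' `relationship: part_of` parents; obsolete terms are dropped.
#' @param path OBO file.
#' @return a list with `terms` (data frame) and `edges` (child, parent),
#'   suitable for [go_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- list(); edges <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        id = cur$id, name = cur$name %||% cur$id,
        namespace = cur$namespace %||% NA_character_,
        stringsAsFactors = FALSE)
      for (p in cur$parents)
        edges[[length(edges) + 1L]] <<- data.frame(
          child = cur$id, parent = p, stringsAsFactors = FALSE)
    }
    cur <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); in_term <- TRUE; cur <- list(parents = character(0)); next }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; next }
    if (!in_term || is.null(cur)) next
    if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
    else if (startsWith(ln, "name: ")) cur$name <- sub("^name: ", "", ln)
    else if (startsWith(ln, "namespace: ")) cur$namespace <- sub("^namespace: ", "", ln)
    else if (startsWith(ln, "is_a: "))
      cur$parents <- c(cur$parents, sub("\\s*!.*$", "", sub("^is_a: ", "", ln)))
    else if (grepl("^relationship: part_of ", ln))
      cur$parents <- c(cur$parents,
                       sub("\\s*!.*$", "", sub("^relationship: part_of ", "", ln)))
    else if (ln == "is_obsolete: true") cur$obsolete <- TRUE
  }
  flush()
  list(terms = do.call(rbind, terms),
       edges = if (length(edges)) do.call(rbind, edges)
               else data.frame(child = character(0), parent = character(0)))
}

#' Read a gene-to-GO annotation table
#' @param path TSV with columns gene, term (one pair per line).
#' @return named list mapping gene to a character vector of term ids.
#' @export
read_gene2go <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  split(df[[2]], df[[1]])
}
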