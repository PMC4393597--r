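#' Expression matrix with an explicit transform state
#'
#' A numeric features-by-tissues matrix carrying a `state` attribute that
#' records where it sits in the fixed transform pipeline
#' raw -> normalized -> filtered -> transformed, plus a `ledger` of the
#' operations applied.  Stage functions refuse matrices in the wrong state,
#' so e.g. the 16-read expression filter can only ever see normalized
#' counts.
#'
#' @param x numeric matrix (rows = features such as miRNA arms or genes,
#'   columns = tissues).
#' @param state one of `"raw"`, `"normalized"`, `"filtered"`,
#'   `"transformed"`.
#' @param ledger character vector describing the transforms applied so far.
#' @return an `ExpressionMatrix`.
#' @export
expression_matrix <- function(x, state = "raw", ledger = character(0)) {
  stopifnot(is.matrix(x), is.numeric(x))
  state <- match.arg(state, EM_STATES)
  if (is.null(rownames(x)) && nrow(x) > 0)
    rownames(x) <- paste0("f", seq_len(nrow(x)))
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("t", seq_len(ncol(x)))
  structure(x, class = c("ExpressionMatrix", class(matrix())),
            state = state, ledger = ledger)
}

EM_STATES <- c("raw", "normalized", "filtered", "transformed")

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d tissues [state: %s]\n",
              nrow(x), ncol(x), em_state(x)))
  ledger <- attr(x, "ledger")
  if (length(ledger)) cat(paste0("  - ", ledger, "\n"), sep = "")
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(head(y, 6), ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' State of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return the state string.
#' @export
em_state <- function(x) attr(x, "state") %||% "raw"

check_state <- function(x, required) {
  if (!inherits(x, "ExpressionMatrix"))
    stop("expected an ExpressionMatrix (see expression_matrix())")
  if (!em_state(x) %in% required)
    stop(sprintf("matrix is in state '%s'; this step requires state %s",
                 em_state(x), paste(sQuote(required), collapse = " or ")))
  invisible(TRUE)
}

advance_state <- function(x, new_state, note) {
  expression_matrix(strip_em(x), state = new_state,
                    ledger = c(attr(x, "ledger"), note))
}

# plain numeric matrix view
strip_em <- function(x) {
  y <- unclass(x)
  attr(y, "state") <- NULL
  attr(y, "ledger") <- NULL
  y
}

#' Write / read an ExpressionMatrix as TSV
#'
#' First column `feature`, remaining columns the tissue labels; the state is
#' stored in a `# state:` header comment.
#' @param x an `ExpressionMatrix`.
#' @param path file path.
#' @return `path` (write) or an `ExpressionMatrix` (read).
#' @export
write_expression_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# state: %s", em_state(x)), con)
  df <- data.frame(feature = rownames(x), strip_em(x), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  state <- if (grepl("^# state: ", first)) sub("^# state: ", "", first)
           else "raw"
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, state = state, ledger = sprintf("read from %s", path))
}
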