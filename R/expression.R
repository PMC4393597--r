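# Arm-level quantification and the expression transform pipeline:
# counting with mismatch tolerance, median-depth + linear normalization,
# minimum-expression filtering, log2 median-centered clamped transform,
# tissue distances, complete-linkage clustering, and fold-change
# differential screening.

arm_table <- function(loci) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    for (arm in c("5p", "3p")) {
      seq_col <- paste0("arm", substr(arm, 1, 1), "_seq")
      s <- loci[[seq_col]][i]
      if (!is.na(s))
        rows[[length(rows) + 1L]] <- data.frame(
          arm_id = paste0(loci$locus_id[i], "-", arm),
          locus_id = loci$locus_id[i], arm = arm, sequence = s,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(arm_id = character(0), locus_id = character(0),
                      arm = character(0), sequence = character(0)))
  do.call(rbind, rows)
}

#' Count 5p/3p arm expression per tissue with mismatch tolerance
#'
#' Each collapsed read is compared against every mature arm sequence under
#' the relaxed standard used for quantification: 5'-anchored ungapped
#' comparison allowing up to `max_mismatch` mismatches, where 3' length
#' differences of up to 2 nt count as mismatches (accommodating
#' non-template 3' additions and sequencing errors).  A read matching
#' several arms is assigned to the arm with fewest mismatches; exact ties
#' are discarded and logged.  5p and 3p products are counted separately.
#'
#' @param collapsed collapsed read data frame (`sequence`, `count`,
#'   `tissue`).
#' @param loci locus data frame from [call_loci()] or a simulation truth
#'   table.
#' @param max_mismatch mismatch tolerance.
#' @param tissues optional tissue order for the matrix columns (defaults to
#'   order of appearance).
#' @return a raw-state [expression_matrix()] (rows = arm ids, columns =
#'   tissues) with attribute `discarded`, the total count lost to ties.
#' @export
count_arm_expression <- function(collapsed, loci, max_mismatch = 2L,
                                 tissues = NULL) {
  arms <- arm_table(loci)
  tissues <- tissues %||% unique(collapsed$tissue)
  m <- matrix(0, nrow = nrow(arms), ncol = length(tissues),
              dimnames = list(arms$arm_id, tissues))
  discarded <- 0
  if (nrow(collapsed) && nrow(arms)) {
    uniq <- unique(collapsed$sequence)
    mm <- mismatch_matrix(uniq, arms$sequence, max_len_diff = 2L)
    best <- max.col(-mm, ties.method = "first")
    bestmm <- mm[cbind(seq_along(uniq), best)]
    tie <- rowSums(mm == bestmm) > 1L
    assign_arm <- ifelse(!tie & bestmm <= max_mismatch, best, NA_integer_)
    tied_ok <- tie & bestmm <= max_mismatch
    ix <- match(collapsed$sequence, uniq)
    a <- assign_arm[ix]
    tj <- match(collapsed$tissue, tissues)
    ok <- !is.na(a) & !is.na(tj)
    if (any(ok)) {
      cell <- (tj[ok] - 1L) * nrow(arms) + a[ok]
      sums <- rowsum(collapsed$count[ok], cell)
      m[as.integer(rownames(sums))] <- m[as.integer(rownames(sums))] +
        sums[, 1L]
    }
    discarded <- sum(collapsed$count[is.na(a) & tied_ok[ix]])
  }
  out <- expression_matrix(m, state = "raw",
                           ledger = "counted arm expression")
  attr(out, "discarded") <- discarded
  out
}

#' Map reads from another species onto this species' precursor arms
#'
#' Applies the identical mismatch-tolerant counting contract to a read set
#' from a second species lacking its own genome assembly; columns are
#' labeled with the foreign tissues.
#'
#' @inheritParams count_arm_expression
#' @param species label prefixed to the column names.
#' @return a raw-state [expression_matrix()].
#' @export
map_to_foreign_precursors <- function(collapsed, loci, max_mismatch = 2L,
                                      species = NULL) {
  out <- count_arm_expression(collapsed, loci, max_mismatch)
  if (!is.null(species)) colnames(out) <- paste(species, colnames(out),
                                                sep = ":")
  out
}

#' Normalize a raw count matrix
#'
#' Step 1 corrects for sequencing depth: each column is scaled by
#' (median of column totals) / (column total), after which all column
#' totals equal the median total.  Step 2 is a linear normalization: each
#' column is divided by the slope of a zero-intercept least-squares fit of
#' that column against the across-column mean profile, computed on rows
#' that are nonzero in every column.
#'
#' @param x raw-state [expression_matrix()].
#' @param linear apply the second (linear regression) step.
#' @return normalized-state [expression_matrix()].
#' @export
normalize_expression <- function(x, linear = TRUE) {
  check_state(x, "raw")
  m <- strip_em(x)
  totals <- colSums(m)
  if (any(totals == 0))
    stop(sprintf("all-zero tissue column(s): %s",
                 paste(colnames(m)[totals == 0], collapse = ", ")))
  m <- sweep(m, 2L, median(totals) / totals, "*")
  if (linear && ncol(m) > 1L) {
    shared <- rowSums(m == 0) == 0L
    if (any(shared)) {
      ref <- rowMeans(m[shared, , drop = FALSE])
      for (j in seq_len(ncol(m))) {
        y <- m[shared, j]
        slope <- sum(ref * y) / sum(ref * ref)
        if (slope > 0) m[, j] <- m[, j] / slope
      }
    }
  }
  advance_state(expression_matrix(m, em_state(x), attr(x, "ledger")),
                "normalized",
                sprintf("normalized (median depth%s)",
                        if (linear) " + linear" else ""))
}

#' Drop arms below a minimum normalized expression
#'
#' Retains rows reaching at least `min_reads` normalized reads in at least
#' one tissue (inclusive boundary).
#'
#' @param x normalized-state [expression_matrix()].
#' @param min_reads threshold in normalized reads.
#' @return filtered-state [expression_matrix()].
#' @export
filter_min_expression <- function(x, min_reads = 16) {
  check_state(x, "normalized")
  m <- strip_em(x)
  keep <- apply(m, 1L, max) >= min_reads
  advance_state(expression_matrix(m[keep, , drop = FALSE], em_state(x),
                                  attr(x, "ledger")),
                "filtered",
                sprintf("filtered at >= %g normalized reads", min_reads))
}

#' Log2 transform, median-center, and clamp
#'
#' Values become `log2(v + pseudocount)`, each row is centered by its
#' median, and the result is clipped to `[-clamp, +clamp]`.
#'
#' @param x filtered-state [expression_matrix()].
#' @param pseudocount added before the log.
#' @param clamp symmetric clipping bound.
#' @return transformed-state [expression_matrix()].
#' @export
log_median_center <- function(x, pseudocount = 1, clamp = 3) {
  check_state(x, "filtered")
  m <- log2(strip_em(x) + pseudocount)
  m <- m - apply(m, 1L, median)
  m <- pmin(pmax(m, -clamp), clamp)
  advance_state(expression_matrix(m, em_state(x), attr(x, "ledger")),
                "transformed",
                sprintf("log2(v+%g), median-centered, clamped to [-%g,%g]",
                        pseudocount, clamp, clamp))
}

#' Pairwise tissue distances
#'
#' @param x transformed-state [expression_matrix()].
#' @param metric `"euclidean"` (column-wise L2) or `"pearson"`
#'   (1 - Pearson correlation of columns).
#' @return symmetric distance matrix over tissues with zero diagonal.
#' @export
tissue_distance <- function(x, metric = c("euclidean", "pearson")) {
  metric <- match.arg(metric)
  check_state(x, c("transformed", "normalized", "filtered"))
  m <- strip_em(x)
  if (ncol(m) < 2L) stop("need at least two tissues")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(t(m)))
  } else {
    v <- apply(m, 2L, sd)
    if (any(v == 0))
      stop(sprintf("zero-variance tissue column(s) under pearson: %s",
                   paste(colnames(m)[v == 0], collapse = ", ")))
    d <- 1 - cor(m)
  }
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering where the inter-cluster distance is the
#' maximum pairwise distance; merge heights are monotone non-decreasing.
#'
#' @param d symmetric distance matrix (e.g. from [tissue_distance()]).
#' @return an object of class `hclust`.
#' @export
complete_linkage <- function(d) {
  if (nrow(as.matrix(d)) < 2L) stop("need at least two items to cluster")
  hclust(as.dist(d), method = "complete")
}

#' Serialize a dendrogram as a Newick string
#' @param hc an `hclust` object.
#' @return single Newick string with branch lengths.
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Screen for differential miRNAs between electric organ and muscle
#'
#' The fold change is `(mean over EO tissues + pseudocount) /
#' (muscle + pseudocount)` on normalized values; an arm is called when the
#' fold change is strictly greater than `fold` (up) or strictly less than
#' `1/fold` (down).
#'
#' @param x normalized- or filtered-state [expression_matrix()].
#' @param eo_tissues electric-organ tissue labels (averaged).
#' @param muscle_tissue skeletal-muscle tissue label.
#' @param fold fold-change threshold (strict).
#' @param pseudocount added to numerator mean and denominator.
#' @return data frame `arm_id`, `direction` (`up`/`down`), `fold_change`,
#'   `log2_fc`, plus per-EO fold-change columns.
#' @export
select_differential <- function(x, eo_tissues, muscle_tissue, fold = 4,
                                pseudocount = 1) {
  check_state(x, c("normalized", "filtered"))
  m <- strip_em(x)
  missing_t <- setdiff(c(eo_tissues, muscle_tissue), colnames(m))
  if (length(missing_t))
    stop(sprintf("tissue(s) not in matrix: %s",
                 paste(missing_t, collapse = ", ")))
  eo <- rowMeans(m[, eo_tissues, drop = FALSE])
  fc <- (eo + pseudocount) / (m[, muscle_tissue] + pseudocount)
  per_eo <- sapply(eo_tissues, function(t)
    (m[, t] + pseudocount) / (m[, muscle_tissue] + pseudocount))
  called <- fc > fold | fc < 1 / fold
  out <- data.frame(arm_id = rownames(m)[called],
                    direction = ifelse(fc[called] > fold, "up", "down"),
                    fold_change = unname(fc[called]),
                    log2_fc = unname(log2(fc[called])),
                    stringsAsFactors = FALSE)
  cbind(out, setNames(as.data.frame(per_eo[called, , drop = FALSE],
                                    row.names = seq_len(sum(called))),
                      paste0("fc_", eo_tissues)))
}
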