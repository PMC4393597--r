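# Promoter PWM scanning with information-weighted core/matrix similarity
# scores and binomial enrichment against a random-gene background.

#' Position weight matrix with information weights
#'
#' Wraps a 4 x L count matrix.  Columns are normalized to frequencies with
#' a pseudocount; the per-position information weight is
#' `Ci = (100/ln 4) * (ln 4 + sum_b p(i,b) ln p(i,b))` (0 for a uniform
#' column, 100 for a deterministic one), and the core is the `core_size`
#' consecutive positions maximizing the summed Ci (leftmost on ties).
#'
#' @param counts 4 x L non-negative matrix with rows A, C, G, T.
#' @param name matrix label.
#' @param core_size number of consecutive core positions.
#' @param pseudocount added to every count before normalization.
#' @return a `Pwm` object.
#' @export
pwm <- function(counts, name = "pwm", core_size = 4L, pseudocount = 0.01) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, all(counts >= 0))
  rownames(counts) <- DNA_BASES
  L <- ncol(counts)
  freq <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount),
                "/")
  info <- information_vector(freq)
  core_size <- min(as.integer(core_size), L)
  sums <- vapply(seq_len(L - core_size + 1L), function(i)
    sum(info[i:(i + core_size - 1L)]), numeric(1))
  cs <- which.max(sums)  # leftmost maximal window
  structure(list(counts = counts, freq = freq, info = info,
                 core_positions = cs:(cs + core_size - 1L), name = name),
            class = "Pwm")
}

#' @export
print.Pwm <- function(x, ...) {
  cat(sprintf("Pwm '%s': %d positions, core %s, consensus %s\n", x$name,
              ncol(x$counts),
              paste(range(x$core_positions), collapse = "-"),
              paste(DNA_BASES[apply(x$freq, 2, which.max)], collapse = "")))
  invisible(x)
}

#' Per-position information weights of a frequency matrix
#'
#' `Ci = (100/ln 4) * (ln 4 + sum_b p ln p)` with `0 * ln 0 = 0`; columns
#' must sum to 1 within 1e-6.
#'
#' @param freq 4 x L matrix of column probability vectors.
#' @return numeric vector of length L in [0, 100].
#' @export
information_vector <- function(freq) {
  if (any(abs(colSums(freq) - 1) > 1e-6))
    stop("frequency columns must sum to 1")
  plogp <- ifelse(freq > 0, freq * log(freq), 0)
  (100 / log(4)) * (log(4) + colSums(plogp))
}

# Ci-weighted score matrix (4 x L) used by similarity and scanning
pwm_weights <- function(p) sweep(p$freq, 2L, p$info, "*")

#' Information-weighted similarity of a window to a PWM
#'
#' `score = sum_i Ci * p(i, w_i) / sum_i Ci * max_b p(i, b)`, optionally
#' restricted to the core positions.  A fully degenerate PWM (all columns
#' uniform) has denominator 0 and scores 0 with a warning.
#'
#' @param p a [pwm()].
#' @param window sequence of length `ncol(p$counts)`, unambiguous bases.
#' @param core restrict to the core positions.
#' @return similarity in [0, 1].
#' @export
matrix_similarity <- function(p, window, core = FALSE) {
  L <- ncol(p$counts)
  stopifnot(nchar(window) == L)
  idx <- match(strsplit(toupper(window), "")[[1]], DNA_BASES)
  if (anyNA(idx)) stop("window contains an ambiguous base")
  w <- pwm_weights(p)
  pos <- if (core) p$core_positions else seq_len(L)
  denom <- sum(apply(w[, pos, drop = FALSE], 2L, max))
  if (denom <= 0) {
    warning("degenerate PWM (all columns uniform); score defined as 0")
    return(0)
  }
  sum(w[cbind(idx[pos], pos)]) / denom
}

#' Scan a promoter with a PWM on both strands
#'
#' Slides the PWM over every offset of the promoter and of its reverse
#' complement, reporting windows whose core similarity and matrix
#' similarity both reach their thresholds.  Minus-strand hits are reported
#' at the forward offset of the window they occupy.  The number of
#' scanned positions (binomial trials) for a promoter of length n is
#' `2 * (n - L + 1)`.
#'
#' @param p a [pwm()].
#' @param promoter promoter sequence (length >= motif length).
#' @param core_threshold,matrix_threshold similarity thresholds.
#' @return data frame `offset`, `strand`, `core_sim`, `matrix_sim` with
#'   attribute `n_trials`.
#' @export
scan_promoter <- function(p, promoter, core_threshold = 0.75,
                          matrix_threshold = 0.85) {
  L <- ncol(p$counts)
  n <- nchar(promoter)
  if (n < L) stop("promoter shorter than the PWM")
  w <- pwm_weights(p)
  if (sum(apply(w, 2L, max)) <= 0) {
    warning("degenerate PWM (all columns uniform); no hits reported")
    out <- data.frame(offset = integer(0), strand = character(0),
                      core_sim = numeric(0), matrix_sim = numeric(0))
    attr(out, "n_trials") <- 2L * (n - L + 1L)
    return(out)
  }
  # minus strand: scan with the reverse-complemented weight matrix
  w_rc <- w[4:1, L:1, drop = FALSE]
  rownames(w_rc) <- DNA_BASES
  core_rc <- sort(L + 1L - p$core_positions)
  fwd <- pwm_scan_cpp(promoter, w, as.integer(p$core_positions),
                      core_threshold, matrix_threshold)
  rev <- pwm_scan_cpp(promoter, w_rc, as.integer(core_rc),
                      core_threshold, matrix_threshold)
  out <- data.frame(
    offset = as.integer(c(fwd[, 1], rev[, 1])),
    strand = c(rep("+", nrow(fwd)), rep("-", nrow(rev))),
    core_sim = c(fwd[, 2], rev[, 2]),
    matrix_sim = c(fwd[, 3], rev[, 3]), stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_trials") <- 2L * (n - L + 1L)
  out
}

# hit count + trials over a set of promoters; promoters are joined with
# N separators and scanned in one pass per strand (windows containing N
# are skipped by the scanner, so no cross-boundary hits arise)
scan_set <- function(p, promoters, core_threshold, matrix_threshold) {
  L <- ncol(p$counts)
  n <- nchar(promoters)
  per_trials <- pmax(2L * (n - L + 1L), 0L)
  w <- pwm_weights(p)
  if (sum(apply(w, 2L, max)) <= 0) {
    warning("degenerate PWM (all columns uniform); no hits reported")
    return(list(hits = 0L, trials = sum(per_trials),
                per = integer(length(promoters)),
                per_trials = per_trials))
  }
  big <- paste(promoters, collapse = "N")
  starts <- cumsum(c(1L, n + 1L))[seq_along(promoters)]
  w_rc <- w[4:1, L:1, drop = FALSE]
  core_rc <- sort(L + 1L - p$core_positions)
  per <- integer(length(promoters))
  for (pass in 1:2) {
    hits <- if (pass == 1L)
      pwm_scan_cpp(big, w, as.integer(p$core_positions), core_threshold,
                   matrix_threshold)
    else
      pwm_scan_cpp(big, w_rc, as.integer(core_rc), core_threshold,
                   matrix_threshold)
    if (nrow(hits)) {
      idx <- findInterval(hits[, 1L], starts)
      tab <- tabulate(idx, nbins = length(promoters))
      per <- per + tab
    }
  }
  list(hits = sum(per), trials = sum(per_trials), per = per,
       per_trials = per_trials)
}

#' Binomial upper-tail enrichment p-value
#'
#' `p = P(X >= observed)` for `X ~ Binomial(n_trials, bg_rate)`, the
#' cumulative probability of seeing at least the observed number of
#' binding sites under the background rate.
#'
#' @param observed observed hit count.
#' @param n_trials number of scanned positions.
#' @param bg_rate background per-position hit rate in [0, 1].
#' @return the p-value (1 when `observed` is 0).
#' @export
binomial_enrichment <- function(observed, n_trials, bg_rate) {
  if (any(bg_rate < 0 | bg_rate > 1)) stop("bg_rate must lie in [0, 1]")
  stopifnot(all(observed >= 0), all(observed <= n_trials))
  pbinom(observed - 1, n_trials, bg_rate, lower.tail = FALSE)
}

#' Binding-site enrichment of a foreground promoter set
#'
#' Estimates a per-position background hit rate for every PWM from a
#' (sub)sampled background promoter set, then compares the foreground as a
#' group, an optional top subset, and each single foreground gene against
#' that rate with [binomial_enrichment()].  Trials are pooled scanned
#' positions (both strands).  Raw p-values are reported; Benjamini-
#' Hochberg correction is available but off by default.
#'
#' @param foreground,background named character vectors of promoter
#'   sequences.
#' @param pwms list of [pwm()] objects.
#' @param core_threshold,matrix_threshold scan thresholds.
#' @param top_subset optional names of foreground promoters forming the
#'   top subset scope.
#' @param background_sample_size background promoters used for the rate
#'   (sampled without replacement when the pool is larger).
#' @param seed seed for the background subsample.
#' @param scopes which scopes to emit.
#' @param bh also report BH-adjusted p-values.
#' @return data frame: `pwm`, `scope`, `gene`, `observed`, `n_trials`,
#'   `expected`, `bg_rate`, `p_value` (and `p_adjusted` with `bh`).
#' @export
run_enrichment <- function(foreground, background, pwms,
                           core_threshold = 0.75, matrix_threshold = 0.85,
                           top_subset = NULL,
                           background_sample_size = 2984L, seed = 1L,
                           scopes = c("group", "top-subset",
                                      "single-gene"),
                           bh = FALSE) {
  if (length(foreground) == 0L) stop("empty foreground promoter set")
  scopes <- match.arg(scopes, several.ok = TRUE)
  if (length(background) > background_sample_size)
    background <- with_seed(derive_seed(seed, 6L),
                            background[sample(length(background),
                                              background_sample_size)])
  rows <- list()
  for (p in pwms) {
    bg <- scan_set(p, background, core_threshold, matrix_threshold)
    rate <- if (bg$trials > 0) bg$hits / bg$trials else 0
    fg <- scan_set(p, foreground, core_threshold, matrix_threshold)
    add <- function(scope, gene, obs, trials) {
      rows[[length(rows) + 1L]] <<- data.frame(
        pwm = p$name, scope = scope, gene = gene, observed = obs,
        n_trials = trials, expected = trials * rate, bg_rate = rate,
        p_value = binomial_enrichment(obs, trials, rate),
        stringsAsFactors = FALSE)
    }
    if ("group" %in% scopes)
      add("group", NA_character_, fg$hits, fg$trials)
    if ("top-subset" %in% scopes && !is.null(top_subset)) {
      sel <- names(foreground) %in% top_subset
      add("top-subset", NA_character_, sum(fg$per[sel]),
          sum(fg$per_trials[sel]))
    }
    if ("single-gene" %in% scopes)
      for (i in seq_along(foreground))
        add("single-gene", names(foreground)[i] %||% as.character(i),
            fg$per[i], fg$per_trials[i])
  }
  out <- do.call(rbind, rows)
  if (bh) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
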