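# Independent oracles used to check the package implementations.
# Deliberately naive: exhaustive recursion and closed-form arithmetic.

rna_can_pair <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AU", "UA", "CG", "GC", "GU", "UG",
           "AT", "TA", "GT", "TG")
}

# Exhaustive maximum base-pairing over all nested structures of s[i..j]:
# either j is unpaired, or j pairs with some k (loop >= min_loop) and the
# inside/outside intervals are solved recursively.  No memoization; only
# usable for short sequences.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (rna_can_pair(s[k], s[j])) {
        cand <- 1L + (if (k > i) rec(i, k - 1L) else 0L) +
          (if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else 0L)
        if (cand > best) best <- cand
      }
    }
    best
  }
  if (length(s) < 2L) return(0L)
  rec(1L, length(s))
}

# Naive both-strand substring scan of a query against a set of subjects.
oracle_substring_hit <- function(query, subjects) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(subjects)))
  any(vapply(c(subjects, rc), function(s) grepl(query, s, fixed = TRUE),
             logical(1)))
}

# Naive exhaustive exact matcher (both strands) returning 1-based starts.
oracle_map <- function(query, contig) {
  rcq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(query)))
  find_all <- function(pat) {
    out <- integer(0)
    from <- 1L
    repeat {
      p <- regexpr(pat, substr(contig, from, nchar(contig)), fixed = TRUE)
      if (p == -1L) break
      out <- c(out, from + p - 1L)
      from <- from + p
    }
    out
  }
  list(plus = find_all(query), minus = find_all(rcq))
}

# Best end-anchored mismatch count of a query against one reference
# (Hamming over the shared prefix + 3' length difference, capped at 2 nt).
oracle_end_anchored_mm <- function(query, ref) {
  lq <- nchar(query); lr <- nchar(ref)
  if (abs(lq - lr) > 2L) return(Inf)
  n <- min(lq, lr)
  q <- strsplit(query, "")[[1]][1:n]
  r <- strsplit(ref, "")[[1]][1:n]
  sum(q != r) + abs(lq - lr)
}

# Exact hypergeometric upper tail P(X >= q) from the closed form.
oracle_hyper_tail <- function(q, m, n, k) {
  xs <- q:min(m, k)
  xs <- xs[xs >= max(0L, k - n)]
  if (!length(xs)) return(0)
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# Exact binomial upper tail P(X >= obs) by direct summation in log space.
oracle_binom_tail <- function(obs, n, p) {
  if (obs <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  ks <- obs:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# Ancestor closure of a node in a child->parent edge list by repeated
# expansion (independent of the igraph-based implementation).
oracle_ancestors <- function(term, edges) {
  anc <- character(0)
  frontier <- term
  while (length(frontier)) {
    parents <- unique(edges$parent[edges$child %in% frontier])
    parents <- setdiff(parents, anc)
    anc <- c(anc, parents)
    frontier <- parents
  }
  anc
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
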