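# Shared fixtures built in code.

# small, fast simulation configuration for unit tests
small_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, n_contigs = 1L, contig_len = 20000L,
             n_conserved = 4L, n_novel = 1L, n_contaminants = 2L,
             depth = 2000L, ...)
}

# noise-free configuration: reads are exact arm copies
clean_config <- function(seed = 11L, nta_prob = 0, ...) {
  small_config(seed = seed, error_rate = 0, nta_prob = nta_prob, ...)
}

# two-term chain DAG where all of the parent's cluster signal comes from
# the child: child annotates g1..g5 (the cluster), parent adds g6..g8
chain_fixture <- function() {
  genes <- sprintf("g%d", 1:20)
  gene2go <- c(lapply(setNames(genes[1:5], genes[1:5]),
                      function(g) "T:child"),
               lapply(setNames(genes[6:8], genes[6:8]),
                      function(g) "T:parent"))
  dag <- go_dag(terms = data.frame(id = c("T:child", "T:parent"),
                                   name = c("child", "parent")),
                edges = data.frame(child = "T:child", parent = "T:parent"),
                gene2go = gene2go)
  list(dag = dag, cluster = genes[1:5], background = genes)
}

# random toy DAG: terms ordered so edges always point to earlier indices
random_toy_dag <- function(n_terms = 10L, n_genes = 30L, p_edge = 0.3) {
  ids <- sprintf("T:%02d", seq_len(n_terms))
  edges <- list()
  for (i in 2:n_terms) {
    parents <- which(runif(i - 1L) < p_edge)
    if (!length(parents)) parents <- sample(i - 1L, 1L)
    for (p in parents)
      edges[[length(edges) + 1L]] <- data.frame(child = ids[i],
                                                parent = ids[p])
  }
  genes <- sprintf("g%02d", seq_len(n_genes))
  gene2go <- lapply(setNames(genes, genes), function(g)
    sample(ids, sample(1:3, 1L)))
  go_dag(terms = data.frame(id = ids, name = ids),
         edges = do.call(rbind, edges), gene2go = gene2go)
}

# hand PWM with exact column probabilities (pseudocount 0):
# col1 deterministic A (Ci=100), col2 A/C even (Ci=50), col3 uniform (Ci=0)
hand_pwm <- function() {
  counts <- matrix(c(4, 0, 0, 0,
                     2, 2, 0, 0,
                     1, 1, 1, 1), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm(counts, name = "hand", core_size = 2L, pseudocount = 0)
}

# find the smallest dendrogram cluster containing all of `members`
smallest_containing_cluster <- function(hc, members) {
  labs <- hc$labels
  for (k in rev(seq_len(length(labs) - 1L))) {
    ct <- stats::cutree(hc, k = k)
    cl <- unique(ct[members])
    if (length(cl) == 1L) return(labs[ct == cl])
  }
  labs
}
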