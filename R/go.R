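# mRNA co-expression clustering and Gene Ontology enrichment with the
# elim graph-decorrelation algorithm.

#' Covariance filter: keep the most variable genes
#'
#' Ranks genes by coefficient of variation across tissues (sd/mean on
#' normalized values with a pseudocount of 1) and keeps the top
#' `keep_frac` fraction (ceiling), discarding low-covariance genes before
#' clustering.
#'
#' @param x normalized-state [expression_matrix()].
#' @param keep_frac fraction of genes to retain, in (0, 1].
#' @return filtered-state [expression_matrix()].
#' @export
covariance_filter <- function(x, keep_frac = 0.25) {
  if (!is.numeric(keep_frac) || keep_frac <= 0 || keep_frac > 1)
    stop("keep_frac must lie in (0, 1]")
  check_state(x, "normalized")
  if (ncol(x) < 2L) stop("need at least two tissues")
  m <- strip_em(x) + 1
  cv <- apply(m, 1L, sd) / rowMeans(m)
  n_keep <- ceiling(nrow(m) * keep_frac)
  keep <- order(cv, decreasing = TRUE)[seq_len(n_keep)]
  keep <- sort(keep)  # preserve row order
  advance_state(expression_matrix(strip_em(x)[keep, , drop = FALSE],
                                  em_state(x), attr(x, "ledger")),
                "filtered",
                sprintf("covariance filter, kept top %.0f%% by CV",
                        100 * keep_frac))
}

#' K-means co-expression clustering
#'
#' Lloyd's algorithm with Euclidean distance, best of `n_restarts` random
#' starts by within-cluster sum of squares; deterministic given `seed`.
#' Restarts that collapse a cluster to empty are retried with derived
#' seeds.
#'
#' @param x transformed-state [expression_matrix()] (genes x tissues).
#' @param k number of clusters.
#' @param n_restarts random restarts.
#' @param seed RNG seed.
#' @return list with `assignment` (named integer vector), `centers`, and
#'   `wcss`.
#' @export
kmeans_cluster <- function(x, k = 12L, n_restarts = 10L, seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  check_state(x, c("transformed", "filtered", "normalized"))
  m <- strip_em(x)
  if (nrow(m) < k) stop("fewer rows than clusters")
  fit <- NULL
  for (try in 0:19) {
    fit <- tryCatch(
      with_seed(derive_seed(seed, 10L + try),
                kmeans(m, centers = k, nstart = n_restarts,
                       iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("k-means failed to produce k non-empty clusters")
  list(assignment = setNames(fit$cluster, rownames(m)),
       centers = fit$centers, wcss = fit$tot.withinss)
}

#' Build a Gene Ontology DAG with gene annotations
#'
#' @param terms data frame with columns `id`, `name` (optional
#'   `namespace`).
#' @param edges data frame with columns `child`, `parent` (is_a/part_of).
#' @param gene2go named list mapping gene -> character vector of directly
#'   annotated term ids.
#' @return a `GoDag` with annotations propagated to ancestors and term
#'   levels (longest path from a root) precomputed.
#' @export
go_dag <- function(terms, edges, gene2go = list()) {
  ids <- terms$id
  stopifnot(!anyDuplicated(ids))
  bad <- setdiff(unique(c(edges$child, edges$parent)), ids)
  if (length(bad)) stop("edges reference unknown terms: ",
                        paste(bad, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = ids))
  if (!igraph::is_dag(g)) stop("term graph is cyclic")

  # topological order child -> parent (children first)
  topo <- names(igraph::topo_sort(g, mode = "out"))
  parents <- split(edges$parent, edges$child)
  children <- split(edges$child, edges$parent)

  # level = longest path to a root (term with no parents)
  level <- setNames(integer(length(ids)), ids)
  for (t in rev(topo)) {   # parents before children
    p <- parents[[t]]
    if (length(p)) level[t] <- max(level[p]) + 1L
  }

  # direct annotations per term, restricted to known terms
  direct <- setNames(vector("list", length(ids)), ids)
  for (gene in names(gene2go)) {
    for (t in intersect(unique(gene2go[[gene]]), ids))
      direct[[t]] <- c(direct[[t]], gene)
  }
  # propagate to ancestors: ann(t) = direct(t) U ann(children)
  ann <- setNames(vector("list", length(ids)), ids)
  for (t in topo) {   # children first
    kids <- children[[t]]
    ann[[t]] <- unique(c(direct[[t]], unlist(ann[kids], use.names = FALSE)))
  }
  structure(list(terms = terms, edges = edges, graph = g,
                 gene2go = gene2go, parents = parents,
                 children = children, level = level, direct = direct,
                 annotated = ann),
            class = "GoDag")
}

#' @export
print.GoDag <- function(x, ...) {
  cat(sprintf("GoDag: %d terms, %d edges, %d annotated genes\n",
              nrow(x$terms), nrow(x$edges), length(x$gene2go)))
  invisible(x)
}

#' All ancestors of a term (excluding itself)
#' @param dag a `GoDag`.
#' @param term term id.
#' @return character vector of ancestor term ids.
#' @export
go_ancestors <- function(dag, term) {
  setdiff(names(igraph::subcomponent(dag$graph, term, mode = "out")), term)
}

#' Transfer annotations through an ortholog map and drop rare terms
#'
#' Cluster genes are annotated via their ortholog's GO assignments; terms
#' directly annotating fewer than `min_occurrence` cluster genes are
#' dropped (so a single-gene term cannot drive an enrichment).  Genes
#' absent from the ortholog map contribute no annotations but remain in
#' the cluster for counting.
#'
#' @param genes character vector of cluster gene ids.
#' @param ortholog_map named character vector, gene -> ortholog gene id
#'   used in `dag$gene2go` (may be partial).
#' @param dag a `GoDag` whose `gene2go` is keyed by ortholog ids.
#' @param min_occurrence minimum direct-annotation count within the
#'   cluster.
#' @return list with `gene2go` (gene -> terms, post-filter) and
#'   `terms_kept`.
#' @export
map_and_prefilter_go <- function(genes, ortholog_map, dag,
                                 min_occurrence = 2L) {
  transferred <- lapply(setNames(genes, genes), function(g) {
    o <- unname(ortholog_map[g])
    if (is.na(o)) character(0) else unique(dag$gene2go[[o]] %||% character(0))
  })
  counts <- table(unlist(transferred, use.names = FALSE))
  kept <- names(counts)[counts >= min_occurrence]
  list(gene2go = lapply(transferred, intersect, y = kept),
       terms_kept = kept)
}

#' One-sided Fisher's exact enrichment test
#'
#' Hypergeometric upper tail P(X >= overlap) for the 2x2 table of cluster
#' membership against term annotation within the background universe.
#'
#' @param cluster_genes genes in the cluster (subset of background).
#' @param background_genes the gene universe.
#' @param term_genes genes annotated to the term.
#' @return the enrichment p-value.
#' @export
fisher_term_test <- function(cluster_genes, background_genes, term_genes) {
  if (length(background_genes) == 0L) stop("empty background")
  cluster_genes <- intersect(cluster_genes, background_genes)
  term_genes <- intersect(term_genes, background_genes)
  overlap <- length(intersect(cluster_genes, term_genes))
  phyper(overlap - 1L, length(term_genes),
         length(background_genes) - length(term_genes),
         length(cluster_genes), lower.tail = FALSE)
}

#' GO enrichment with the elim graph-decorrelation algorithm
#'
#' Terms are processed level by level from the most specific (greatest
#' depth, ties by lexicographic id) upward.  Each term is tested by
#' [fisher_term_test()] on its *current* gene set; terms with fewer than
#' `min_node_size` annotated background genes are skipped.  Under the elim
#' method, when a term's p-value is at most `alpha_elim`, its annotated
#' genes are removed from all ancestors' gene sets before those ancestors
#' are tested, decorrelating the graph so that enrichment concentrated in
#' a specific child does not propagate to general parents.  The classic
#' method tests every term on its full annotation.
#'
#' @param dag a `GoDag`.
#' @param cluster_genes genes of interest.
#' @param background_genes gene universe (default: all genes carrying at
#'   least one annotation in the DAG).
#' @param alpha_elim elimination threshold.
#' @param min_node_size minimum annotated background genes for a term to
#'   be tested.
#' @param report_alpha report terms with p below this (set to `Inf` to
#'   get every tested term).
#' @param method `"elim"` or `"classic"`.
#' @return data frame: `term`, `name`, `level`, `annotated_in_background`,
#'   `annotated_in_cluster`, `p_value`, `method`, ordered by p-value.
#' @export
elim_enrichment <- function(dag, cluster_genes, background_genes = NULL,
                            alpha_elim = 0.01, min_node_size = 3L,
                            report_alpha = 0.01,
                            method = c("elim", "classic")) {
  method <- match.arg(method)
  stopifnot(inherits(dag, "GoDag"))
  background_genes <- background_genes %||%
    unique(unlist(dag$annotated, use.names = FALSE))
  cluster_genes <- intersect(cluster_genes, background_genes)

  ord <- order(-dag$level, dag$terms$id)
  term_order <- dag$terms$id[ord]
  removed <- setNames(vector("list", length(term_order)), term_order)
  rows <- list()
  for (t in term_order) {
    genes_t <- setdiff(intersect(dag$annotated[[t]], background_genes),
                       removed[[t]])
    if (length(genes_t) < min_node_size) next
    in_cluster <- intersect(genes_t, cluster_genes)
    p <- phyper(length(in_cluster) - 1L, length(genes_t),
                length(background_genes) - length(genes_t),
                length(cluster_genes), lower.tail = FALSE)
    rows[[t]] <- data.frame(
      term = t,
      name = dag$terms$name[match(t, dag$terms$id)],
      level = unname(dag$level[t]),
      annotated_in_background = length(genes_t),
      annotated_in_cluster = length(in_cluster),
      p_value = p, method = method, stringsAsFactors = FALSE)
    if (method == "elim" && p <= alpha_elim) {
      for (a in go_ancestors(dag, t))
        removed[[a]] <- union(removed[[a]], genes_t)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(term = character(0), name = character(0),
                         level = integer(0),
                         annotated_in_background = integer(0),
                         annotated_in_cluster = integer(0),
                         p_value = numeric(0), method = character(0))
  out <- out[out$p_value < report_alpha, , drop = FALSE]
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Induced GO subgraph of enriched terms and their ancestors
#'
#' @param enriched result of [elim_enrichment()].
#' @param dag a `GoDag`.
#' @param graph_alpha include terms with `p_value < graph_alpha`.
#' @return list with `nodes` (term, p_value or NA for pure ancestors,
#'   counts) and `edges` (child, parent) restricted to the induced node
#'   set.
#' @export
export_go_graph <- function(enriched, dag, graph_alpha = 0.05) {
  sig <- enriched$term[enriched$p_value < graph_alpha]
  nodes <- unique(c(sig, unlist(lapply(sig, go_ancestors, dag = dag),
                                use.names = FALSE)))
  edges <- dag$edges[dag$edges$child %in% nodes &
                       dag$edges$parent %in% nodes, , drop = FALSE]
  ndf <- data.frame(term = nodes,
                    p_value = enriched$p_value[match(nodes, enriched$term)],
                    annotated_in_cluster =
                      enriched$annotated_in_cluster[match(nodes,
                                                          enriched$term)],
                    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  list(nodes = ndf, edges = edges)
}

#' Write an induced GO graph as DOT and TSV edge list
#' @param graph result of [export_go_graph()].
#' @param dot_path,tsv_path output files (either may be NULL).
#' @export
write_go_graph <- function(graph, dot_path = NULL, tsv_path = NULL) {
  if (!is.null(dot_path)) {
    lines <- c("digraph GO {",
               sprintf("  \"%s\" [label=\"%s\\np=%s\"];",
                       graph$nodes$term, graph$nodes$term,
                       ifelse(is.na(graph$nodes$p_value), "NA",
                              signif(graph$nodes$p_value, 3))),
               sprintf("  \"%s\" -> \"%s\";", graph$edges$child,
                       graph$edges$parent),
               "}")
    writeLines(lines, dot_path)
  }
  if (!is.null(tsv_path)) write_tsv(graph$edges, tsv_path)
  invisible(NULL)
}
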