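# Covariance filtering, k-means clustering, GO DAG handling, Fisher node
# tests, and the elim enrichment algorithm.

test_that("covariance_filter keeps the top CV fraction", {
  sim <- simulate_expression_matrix(1000, 8, seed = 4, flat_frac = 0.5)
  f <- covariance_filter(sim$matrix, keep_frac = 0.25)
  expect_equal(nrow(f), 250L)
  expect_identical(em_state(f), "filtered")
  expect_error(covariance_filter(sim$matrix, 0))
  expect_error(covariance_filter(sim$matrix, 1.2))
  # a constant gene is dropped whenever structured genes exist
  m <- unclass(sim$matrix)
  m["gene0001", ] <- 42
  expect_false("gene0001" %in%
                 rownames(covariance_filter(
                   expression_matrix(m, "normalized"), 0.25)))
})

test_that("covariance filtering retains the structured genes", {
  sim <- simulate_expression_matrix(1200, 12, seed = 6, flat_frac = 0.75)
  f <- covariance_filter(sim$matrix, keep_frac = 0.25)
  structured <- names(sim$truth)[!is.na(sim$truth)]
  retained <- mean(structured %in% rownames(f))
  expect_gte(retained, 0.9)
})

test_that("k-means recovers separated planted blobs deterministically", {
  sim <- simulate_expression_matrix(600, 12, seed = 7, flat_frac = 0,
                                    noise_sd = 0.1)
  tr <- log_median_center(covariance_filter(sim$matrix, 1))
  km <- kmeans_cluster(tr, k = 12, n_restarts = 10, seed = 3)
  km2 <- kmeans_cluster(tr, k = 12, n_restarts = 10, seed = 3)
  expect_identical(km$assignment, km2$assignment)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(km$assignment,
                                   sim$truth[names(km$assignment)])
  expect_gte(ari, 0.95)
})

test_that("k-means handles degenerate and boundary inputs", {
  m <- expression_matrix(matrix(c(0, 0, 10, 10, 20, 20), nrow = 3,
                                byrow = TRUE), state = "normalized")
  km <- kmeans_cluster(m, k = 3, seed = 1)
  expect_equal(km$wcss, 0)
  expect_equal(length(unique(km$assignment)), 3L)
  expect_error(kmeans_cluster(m, k = 0))
  expect_error(kmeans_cluster(m, k = 5, seed = 1))
})

test_that("go_dag validates structure and propagates annotations", {
  fix <- chain_fixture()
  dag <- fix$dag
  # child's genes propagate to the parent
  expect_setequal(dag$annotated[["T:parent"]],
                  sprintf("g%d", 1:8))
  expect_setequal(dag$annotated[["T:child"]], sprintf("g%d", 1:5))
  expect_identical(unname(dag$level[c("T:child", "T:parent")]), c(1L, 0L))
  expect_identical(go_ancestors(dag, "T:child"), "T:parent")
  # closure: parents annotate at least as many genes as any child
  for (i in 1:5) {
    d <- random_toy_dag()
    for (e in seq_len(nrow(d$edges)))
      expect_gte(length(d$annotated[[d$edges$parent[e]]]),
                 length(d$annotated[[d$edges$child[e]]]))
  }
  # cycles are rejected
  expect_error(go_dag(data.frame(id = c("a", "b"), name = c("a", "b")),
                      data.frame(child = c("a", "b"),
                                 parent = c("b", "a"))),
               "cyclic")
})

test_that("ortholog transfer drops terms occurring fewer than twice", {
  dag <- chain_fixture()$dag
  orth <- c(eelA = "g1", eelB = "g2", eelC = "g6")
  res <- map_and_prefilter_go(c("eelA", "eelB", "eelC", "eelD"), orth, dag,
                              min_occurrence = 2L)
  # T:child annotates eelA and eelB (2x, kept); T:parent only eelC (dropped)
  expect_identical(res$terms_kept, "T:child")
  expect_setequal(res$gene2go$eelA, "T:child")
  expect_identical(res$gene2go$eelC, character(0))
  # unmapped gene contributes nothing but stays present
  expect_true("eelD" %in% names(res$gene2go))
  # boundary: min_occurrence 1 keeps the singleton term
  res1 <- map_and_prefilter_go(c("eelA", "eelB", "eelC"), orth, dag, 1L)
  expect_setequal(res1$terms_kept, c("T:child", "T:parent"))
})

test_that("fisher_term_test equals the hypergeometric closed form", {
  bg <- sprintf("g%d", 1:20)
  cl <- bg[1:5]
  term <- bg[1:4]
  p <- fisher_term_test(cl, bg, term)
  expect_equal(p, 16 / 15504, tolerance = 1e-12)
  expect_equal(p, oracle_hyper_tail(4, 4, 16, 5), tolerance = 1e-12)
  # overlap 0 and degenerate term = background
  expect_equal(fisher_term_test(bg[6:10], bg, bg[1:2]),
               oracle_hyper_tail(0, 2, 18, 5))
  expect_equal(fisher_term_test(cl, bg, bg), 1)
  expect_error(fisher_term_test(cl, character(0), term))
  # agreement with fisher.test across a grid
  for (m in c(3, 8)) for (k in c(4, 9)) for (q in 0:min(m, k)) {
    mine <- fisher_term_test(bg[1:k], bg, bg[c(seq_len(q),
                                               k + seq_len(m - q))])
    ft <- stats::fisher.test(matrix(c(q, m - q, k - q, 20 - m - k + q),
                                    2, 2), alternative = "greater")$p.value
    expect_equal(mine, ft, tolerance = 1e-10)
  }
  # invariance under gene relabeling
  relab <- setNames(sprintf("x%d", 1:20), bg)
  expect_equal(fisher_term_test(relab[cl], relab[bg], relab[term]), p)
})

test_that("elim reduces to classic Fisher when elimination is disabled", {
  set.seed(12)
  for (i in 1:20) {
    dag <- random_toy_dag(n_terms = sample(6:12, 1))
    cluster <- sample(names(dag$gene2go), 8)
    off <- elim_enrichment(dag, cluster, alpha_elim = 0,
                           report_alpha = Inf, method = "elim")
    classic <- elim_enrichment(dag, cluster, report_alpha = Inf,
                               method = "classic")
    expect_equal(off$p_value[order(off$term)],
                 classic$p_value[order(classic$term)])
  }
})

test_that("a flat DAG gives identical classic and elim results", {
  genes <- sprintf("g%d", 1:20)
  dag <- go_dag(data.frame(id = c("t1", "t2"), name = c("t1", "t2")),
                data.frame(child = character(0), parent = character(0)),
                lapply(setNames(genes, genes), function(g)
                  if (g %in% genes[1:6]) "t1" else "t2"))
  cl <- genes[1:6]
  e <- elim_enrichment(dag, cl, report_alpha = Inf, method = "elim")
  c_ <- elim_enrichment(dag, cl, report_alpha = Inf, method = "classic")
  expect_equal(e$p_value, c_$p_value)
})

test_that("elim strips inherited signal from the parent term", {
  fix <- chain_fixture()
  classic <- elim_enrichment(fix$dag, fix$cluster, fix$background,
                             report_alpha = Inf, method = "classic")
  elim <- elim_enrichment(fix$dag, fix$cluster, fix$background,
                          report_alpha = Inf, method = "elim")
  p_classic <- classic$p_value[classic$term == "T:parent"]
  p_elim <- elim$p_value[elim$term == "T:parent"]
  expect_equal(p_classic, 56 / 15504, tolerance = 1e-12)  # significant
  expect_lt(p_classic, 0.01)
  expect_equal(p_elim, 1)                                  # decorrelated
  # the child is significant either way
  expect_lt(classic$p_value[classic$term == "T:child"], 1e-4)
  expect_lt(elim$p_value[elim$term == "T:child"], 1e-4)
})

test_that("terms below the minimum node size are never tested", {
  fix <- chain_fixture()
  # shrink the child to 2 annotated genes
  g2g <- fix$dag$gene2go
  g2g <- g2g[!names(g2g) %in% c("g3", "g4", "g5")]
  dag <- go_dag(fix$dag$terms, fix$dag$edges, g2g)
  res <- elim_enrichment(dag, c("g1", "g2"), fix$background,
                         min_node_size = 3L, report_alpha = Inf)
  expect_false("T:child" %in% res$term)
  expect_true("T:parent" %in% res$term)
})

test_that("the induced GO graph is the ancestor closure of enriched terms", {
  set.seed(33)
  dag <- random_toy_dag(n_terms = 12)
  enriched <- data.frame(term = c("T:10", "T:07"), p_value = c(0.001, 0.2),
                         annotated_in_cluster = c(3L, 2L))
  g <- export_go_graph(enriched, dag, graph_alpha = 0.05)
  expect_setequal(g$nodes$term,
                  c("T:10", oracle_ancestors("T:10", dag$edges)))
  expect_true(all(g$edges$child %in% g$nodes$term &
                    g$edges$parent %in% g$nodes$term))
  # no enriched terms: empty graph
  empty <- export_go_graph(enriched[0, ], dag)
  expect_equal(nrow(empty$nodes), 0L)
  # DOT and TSV export writes parseable text
  tmp <- tempfile(); tmp2 <- tempfile()
  write_go_graph(g, tmp, tmp2)
  expect_true(any(grepl("digraph", readLines(tmp))))
  expect_equal(nrow(read.table(tmp2, header = TRUE, sep = "\t")),
               nrow(g$edges))
})

test_that("OBO stanzas and annotation tables round-trip into a GoDag", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: GO:0000001", "name: root",
           "namespace: biological_process", "",
           "[Term]", "id: GO:0000002", "name: mid",
           "is_a: GO:0000001 ! root", "",
           "[Term]", "id: GO:0000003", "name: leaf",
           "is_a: GO:0000002 ! mid",
           "relationship: part_of GO:0000001 ! root", "",
           "[Term]", "id: GO:0000004", "name: gone",
           "is_obsolete: true", "",
           "[Typedef]", "id: part_of")
  f <- tempfile(fileext = ".obo")
  writeLines(obo, f)
  parsed <- read_obo(f)
  expect_setequal(parsed$terms$id, sprintf("GO:000000%d", 1:3))
  expect_equal(nrow(parsed$edges), 3L)
  g2g_file <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tterm", "gA\tGO:0000003", "gB\tGO:0000002"), g2g_file)
  dag <- go_dag(parsed$terms, parsed$edges, read_gene2go(g2g_file))
  expect_setequal(dag$annotated[["GO:0000001"]], c("gA", "gB"))
  expect_identical(unname(dag$level["GO:0000003"]), 2L)
})
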