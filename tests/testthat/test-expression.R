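# Arm quantification, normalization, filtering, transformation, tissue
# clustering, and differential screening.

toy_loci <- function() {
  data.frame(locus_id = c("mir-x", "mir-y"),
             family = c("mir-x", NA), contig = "ctg", start = c(1L, 200L),
             end = c(60L, 260L), strand = "+",
             arm5_seq = c("ACGTGCATTACGGATCCAGTA", "TTGCACGGGTTTAACCGGTTA"),
             arm5_start = 1L,
             arm3_seq = c("TGCTGGATCCGTAATGCACGA", "TGACCGGTTAAACCCGTGCAG"),
             arm3_start = 36L, novel = c(FALSE, TRUE),
             stringsAsFactors = FALSE)
}

test_that("count_arm_expression applies the two-mismatch 3' tolerance", {
  loci <- toy_loci()
  arm <- loci$arm5_seq[1]
  col <- data.frame(
    sequence = c(arm, paste0(arm, "AA"), paste0(arm, "AAA")),
    count = c(5L, 3L, 2L), tissue = "SKM", stringsAsFactors = FALSE)
  m <- count_arm_expression(col, loci, tissues = c("SKM", "HEO"))
  expect_equal(m["mir-x-5p", "SKM"], 8)   # exact + 2-nt extension
  expect_equal(sum(m), 8)                 # 3-nt extension rejected
  expect_equal(m["mir-x-5p", "HEO"], 0)   # zero column, not an error
  expect_identical(em_state(m), "raw")
})

test_that("ties between arms are discarded and logged", {
  loci <- toy_loci()
  loci$arm3_seq[1] <- loci$arm5_seq[1]  # two identical arm sequences
  col <- data.frame(sequence = loci$arm5_seq[1], count = 4L,
                    tissue = "SKM", stringsAsFactors = FALSE)
  m <- count_arm_expression(col, loci, tissues = "SKM")
  expect_equal(sum(m), 0)
  expect_equal(attr(m, "discarded"), 4L)
})

test_that("noise-free simulated counts equal the truth table exactly", {
  sim <- simulate_genome(clean_config())
  libs <- simulate_small_rna_libraries(sim)
  col <- process_small_rna(libs$reads, sim$config$adapter)
  m <- count_arm_expression(col, sim$truth$loci,
                            tissues = sim$config$tissues)
  expect_equal(unclass(m)[rownames(libs$realized), ],
               libs$realized + 0, ignore_attr = TRUE)
})

test_that("foreign-species reads map onto precursor arms with tolerance", {
  loci <- toy_loci()
  arm <- loci$arm5_seq[2]
  two_subs <- paste0("GG", substr(arm, 3, nchar(arm)))     # TT -> GG
  four_subs <- paste0("AACG", substr(arm, 5, nchar(arm)))  # TTGC -> AACG
  col <- data.frame(sequence = c(two_subs, four_subs),
                    count = c(7L, 9L), tissue = "EO",
                    stringsAsFactors = FALSE)
  m <- map_to_foreign_precursors(col, loci, species = "smac")
  expect_equal(m["mir-y-5p", "smac:EO"], 7)
  expect_equal(sum(m), 7)  # the 4-mismatch arm is not detected
  empty <- map_to_foreign_precursors(col[0, ], loci)
  expect_true(all(empty == 0))
})

test_that("normalization equalizes depth then applies the linear fit", {
  m0 <- matrix(c(10, 90, 30, 170, 120, 280), nrow = 2,
               dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  x <- expression_matrix(m0)   # totals 100, 200, 400
  n1 <- normalize_expression(x, linear = FALSE)
  expect_equal(unname(colSums(n1)), rep(200, 3))
  expect_equal(unclass(n1)[, "t1"], m0[, "t1"] * 2)
  expect_equal(unclass(n1)[, "t3"], m0[, "t3"] * 0.5)
  # all columns identical: both steps are the identity
  same <- expression_matrix(matrix(c(5, 10, 5, 10, 5, 10), nrow = 2,
                                   dimnames = list(c("a", "b"), NULL)))
  expect_equal(unclass(normalize_expression(same)), unclass(same) + 0,
               ignore_attr = TRUE)
  # single column: unchanged
  one <- expression_matrix(matrix(c(3, 7), ncol = 1,
                                  dimnames = list(c("a", "b"), "t")))
  expect_equal(unclass(normalize_expression(one))[, 1], c(a = 3, b = 7))
  # all-zero column names the tissue
  z <- expression_matrix(matrix(c(1, 2, 0, 0), nrow = 2,
                                dimnames = list(NULL, c("ok", "dead"))))
  expect_error(normalize_expression(z), "dead")
  # post-step-1 totals agree to 1e-9 relative tolerance on random input
  set.seed(8)
  r <- expression_matrix(matrix(rpois(80, 40), nrow = 10))
  tot <- colSums(normalize_expression(r, linear = FALSE))
  expect_lt(diff(range(tot)) / mean(tot), 1e-9)
})

test_that("the 16-read expression filter is inclusive at the boundary", {
  m <- expression_matrix(
    matrix(c(15.99, 3, 16, 2, 100, 40), nrow = 3, byrow = TRUE,
           dimnames = list(c("below", "at", "above"), c("t1", "t2"))),
    state = "normalized")
  f <- filter_min_expression(m)
  expect_identical(rownames(f), c("at", "above"))
  # all rows passing: unchanged
  all_in <- filter_min_expression(
    expression_matrix(matrix(20, 2, 2), state = "normalized"))
  expect_equal(nrow(all_in), 2L)
  # empty result is allowed
  none <- filter_min_expression(
    expression_matrix(matrix(1, 2, 2), state = "normalized"))
  expect_equal(nrow(none), 0L)
})

test_that("log2 median-centering clamps to the +/-3 band", {
  m <- expression_matrix(
    matrix(c(7, 7, 7, 100 * 31, 31, 31), nrow = 2, byrow = TRUE,
           dimnames = list(c("const", "spike"), c("t1", "t2", "t3"))),
    state = "filtered")
  tr <- log_median_center(m)
  expect_equal(unname(unclass(tr)["const", ]), c(0, 0, 0))
  expect_equal(unclass(tr)["spike", "t1"], 3)  # 100x clamps at +3
  set.seed(3)
  r <- expression_matrix(matrix(rexp(60, 0.01), nrow = 6),
                         state = "filtered")
  expect_true(all(unclass(log_median_center(r)) >= -3 &
                    unclass(log_median_center(r)) <= 3))
})

test_that("the transform pipeline enforces its state machine", {
  raw <- expression_matrix(matrix(1:4, 2))
  expect_error(filter_min_expression(raw), "state")
  expect_error(log_median_center(raw), "state")
  expect_error(normalize_expression(normalize_expression(raw)), "state")
  expect_error(count_arm_expression(NULL, toy_loci()))
})

test_that("tissue distances match hand arithmetic for both metrics", {
  m <- expression_matrix(
    matrix(c(1, 2, 3,  1, 2, 3,  4, 0, 2), nrow = 3,
           dimnames = list(NULL, c("a", "b", "c"))),
    state = "transformed")
  d <- tissue_distance(m, "euclidean")
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], sqrt(9 + 4 + 1))
  expect_equal(d, t(d))
  # pearson: perfectly anticorrelated columns sit at distance 2
  m2 <- expression_matrix(
    matrix(c(1, 0, -1, -1, 0, 1), nrow = 3,
           dimnames = list(NULL, c("x", "y"))), state = "transformed")
  expect_equal(tissue_distance(m2, "pearson")["x", "y"], 2)
  # zero-variance column errors with its name
  m3 <- expression_matrix(
    matrix(c(1, 2, 3, 5, 5, 5), nrow = 3,
           dimnames = list(NULL, c("ok", "flat"))), state = "transformed")
  expect_error(tissue_distance(m3, "pearson"), "flat")
})

test_that("complete linkage reproduces hand-computed merge orders", {
  d <- matrix(c(0, 1, 5, 1, 0, 6, 5, 6, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- complete_linkage(d)
  expect_equal(hc$height, c(1, 6))     # (A,B) at 1, then +C at max(5,6)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("A", "B"))
  # identical items merge at height zero
  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(complete_linkage(d0)$height, rep(0, 3))
  expect_error(complete_linkage(matrix(0, 1, 1)))
  # Newick serialization round-trips through ape
  tree <- ape::read.tree(text = as_newick(hc))
  expect_setequal(tree$tip.label, c("A", "B", "C"))
})

test_that("a four-point fixture merges in the hand-computed order", {
  # d(A,B)=1, d(C,D)=2, then complete linkage joins the pairs at 10
  d <- matrix(c(0, 1, 8, 9,
                1, 0, 9, 10,
                8, 9, 0, 2,
                9, 10, 2, 0), nrow = 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  hc <- complete_linkage(d)
  expect_equal(hc$height, c(1, 2, 10))
})

test_that("differential screening uses strict 4-fold bounds", {
  m <- expression_matrix(
    matrix(c(300, 10, 10, 10,  40, 10, 10, 10,  39, 10, 10, 10,
             2, 110, 100, 120), ncol = 4, byrow = TRUE,
           dimnames = list(c("muscle30x", "at4", "near4", "eo55x"),
                           c("SKM", "HEO", "SEO", "MEO"))),
    state = "normalized")
  calls <- select_differential(m, c("HEO", "SEO", "MEO"), "SKM",
                               pseudocount = 0)
  expect_setequal(calls$arm_id, c("muscle30x", "eo55x"))
  expect_identical(calls$direction[calls$arm_id == "muscle30x"], "down")
  expect_identical(calls$direction[calls$arm_id == "eo55x"], "up")
  # ratio exactly 4 (at4) and just below (near4) are not called (strict >)
  expect_false(any(c("at4", "near4") %in% calls$arm_id))
  expect_error(select_differential(m, c("HEO", "XXX"), "SKM"), "XXX")
})

test_that("planted EO/muscle fold changes are recovered across seeds", {
  hits <- 0L; nulls_ok <- TRUE
  eo <- c("HEO", "SEO", "MEO")
  n_true <- 0L; n_called_true <- 0L; n_null <- 0L; n_false <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, depth = 100000L)
    sim <- simulate_genome(cfg)
    libs <- simulate_small_rna_libraries(sim)
    col <- process_small_rna(libs$reads, cfg$adapter)
    m <- count_arm_expression(col, sim$truth$loci, tissues = cfg$tissues)
    norm <- normalize_expression(m, linear = FALSE)
    calls <- select_differential(norm, eo, "SKM")
    af <- eelmir:::arm_fractions(sim)
    planted_fc <- (rowMeans(af[, eo]) ) / (af[, "SKM"])
    truly_diff <- planted_fc > 4 | planted_fc < 1 / 4
    n_true <- n_true + sum(truly_diff)
    n_called_true <- n_called_true +
      sum(rownames(af)[truly_diff] %in% calls$arm_id)
    null_arms <- planted_fc > 1 / 2 & planted_fc < 2
    n_null <- n_null + sum(null_arms)
    n_false <- n_false + sum(rownames(af)[null_arms] %in% calls$arm_id)
  }
  expect_gte(n_called_true / n_true, 0.9)
  expect_lte(n_false / max(n_null, 1), 0.05)
})
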