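toy_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(2^stats::rnorm(n_genes * n_samples, 8), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

test_that("correlation_ranks ranks mutual best partners first", {
  m <- toy_matrix(5, 10, 411)
  # make g002 an exact copy of g001 (identical profile)
  m["g002", ] <- m["g001", ]
  r <- expect_silent(correlation_ranks(m, transform = "none"))
  expect_equal(r["g001", "g002"], 1L)
  expect_equal(r["g002", "g001"], 1L)
  # every row is a permutation of 1..n-1
  expect_true(all(apply(r, 1, function(x) sort(x[!is.na(x)]) == 1:4)))
  expect_error(correlation_ranks(m[, 1:2]), "3 samples")
})

test_that("constant genes are excluded with a warning", {
  m <- toy_matrix(5, 10, 412)
  m["g003", ] <- 7
  expect_warning(r <- correlation_ranks(m), "constant")
  expect_false("g003" %in% rownames(r))
})

test_that("ranks match brute-force recomputation on a toy matrix", {
  m <- toy_matrix(5, 12, 413)
  r <- correlation_ranks(m, transform = "log2p1")
  cm <- attr(r, "cor")
  ids <- rownames(m)
  for (i in 1:5) {
    for (j in setdiff(1:5, i)) {
      manual <- 1L
      for (k in setdiff(1:5, c(i, j))) {
        if (cm[i, k] > cm[i, j] ||
            (cm[i, k] == cm[i, j] && ids[k] < ids[j])) manual <- manual + 1L
      }
      expect_equal(r[i, j], manual)
    }
  }
})

test_that("HRR edges require reciprocity within the cutoff", {
  # ranks: 1<->1 edge, 1 vs cutoff+1 no edge
  r <- matrix(NA_integer_, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  r["a", "b"] <- 1L; r["b", "a"] <- 1L
  r["a", "c"] <- 2L; r["c", "a"] <- 31L
  r["b", "c"] <- 2L; r["c", "b"] <- 2L
  net <- build_hrr_network(r, cutoff = 30)
  expect_equal(nrow(net$edges), 2)
  expect_true(any(net$edges$gene1 == "a" & net$edges$gene2 == "b" &
                    net$edges$hrr == 1))
  expect_false(any(net$edges$gene1 == "a" & net$edges$gene2 == "c"))
  # symmetry / cutoff compliance by construction
  expect_true(all(net$edges$hrr >= 1 & net$edges$hrr <= net$cutoff))
})

test_that("HRR edge set equals the brute-force definition", {
  m <- toy_matrix(30, 20, 414)
  net <- build_hrr_network(correlation_ranks(m), cutoff = 5)
  got <- sort(paste(net$edges$gene1, net$edges$gene2, sep = "|"))
  expect_equal(got, oracle_hrr_edges(m, 5))
})

test_that("hcca_cluster recovers simple planted structures", {
  # two disjoint triangles -> exactly the two triangles
  net <- structure(list(
    edges = data.frame(gene1 = c("a1", "a1", "a2", "b1", "b1", "b2"),
                       gene2 = c("a2", "a3", "a3", "b2", "b3", "b3"),
                       hrr = 1L, stringsAsFactors = FALSE),
    genes = c("a1", "a2", "a3", "b1", "b2", "b3", "lonely"),
    cutoff = 30), class = "hrr_network")
  mods <- hcca_cluster(net)
  grps <- split(mods$modules$gene, mods$modules$module)
  expect_equal(length(grps), 2)
  expect_true(any(vapply(grps, setequal, logical(1), c("a1", "a2", "a3"))))
  expect_true(any(vapply(grps, setequal, logical(1), c("b1", "b2", "b3"))))
  # isolated node stays unassigned
  expect_true(is.na(mods$modules$module[mods$modules$gene == "lonely"]))
  # a full clique within the size bound becomes one cluster
  cl <- t(utils::combn(paste0("k", 1:6), 2))
  net2 <- structure(list(
    edges = data.frame(gene1 = cl[, 1], gene2 = cl[, 2], hrr = 1L,
                       stringsAsFactors = FALSE),
    genes = paste0("k", 1:6), cutoff = 30), class = "hrr_network")
  mods2 <- hcca_cluster(net2)
  expect_equal(length(unique(mods2$modules$module)), 1)
  expect_error(hcca_cluster(net, step_size = 0), "step_size")
})

test_that("clustering is deterministic", {
  sim <- simulate_expression(expression_scenario(
    80, 30, modules = list(list(size = 15, categories = "stress", cor = 0.8)),
    seed = 415))
  net <- build_hrr_network(correlation_ranks(sim$matrix), cutoff = 10)
  m1 <- hcca_cluster(net, seed = 2)
  m2 <- hcca_cluster(net, seed = 2)
  expect_identical(m1, m2)
})

test_that("module_category_matrix counts labels per module", {
  mods <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     module = c(1L, 1L, 2L, NA))
  gc <- data.frame(gene = c("g1", "g2", "g2"),
                   category = c("stress", "stress", "calcium_signaling"))
  cm <- module_category_matrix(mods, gc)
  expect_equal(unname(cm["1", "stress"]), 2)
  expect_equal(unname(cm["1", "calcium_signaling"]), 1)
  # unlabeled module -> empty category set
  expect_equal(sum(cm["2", ]), 0)
  expect_error(
    module_category_matrix(mods, data.frame(gene = "g1", category = "wrong")),
    "wrong")
})

test_that("cooccurrence_frequencies enumerates multi-category modules", {
  cm <- matrix(0L, 3, 3, dimnames = list(1:3, c("A", "B", "C")))
  cm[1, c("A", "B")] <- 1L       # {A, B}
  cm[2, "A"] <- 2L               # {A}
  cm[3, c("B", "C")] <- c(1L, 3L) # {B, C}
  co <- cooccurrence_frequencies(cm)
  expect_equal(co$n_multi, 2)
  expect_equal(co$pairs$count[co$pairs$category1 == "A" &
                                co$pairs$category2 == "B"], 1)
  expect_equal(co$pairs$count[co$pairs$category1 == "B" &
                                co$pairs$category2 == "C"], 1)
  expect_equal(co$pairs$count[co$pairs$category1 == "A" &
                                co$pairs$category2 == "C"], 0)
  # symmetric, zero diagonal
  expect_equal(co$matrix, t(co$matrix))
  expect_true(all(diag(co$matrix) == 0))
  # all single-category -> zero multi, empty table
  cm2 <- diag(3L); dimnames(cm2) <- dimnames(cm)
  co2 <- cooccurrence_frequencies(cm2)
  expect_equal(co2$n_multi, 0)
  expect_equal(nrow(co2$pairs), 0)
  # every module contains all categories -> every pair count = n modules
  cm3 <- matrix(1L, 4, 3, dimnames = list(1:4, c("A", "B", "C")))
  co3 <- cooccurrence_frequencies(cm3)
  expect_true(all(co3$pairs$count == 4))
  expect_true(all(co3$pairs$fraction == 1))
})
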