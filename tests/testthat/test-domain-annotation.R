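test_that("read_domain_hits parses the plain TSV dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "p1\tPF00069\t10\t260\t1e-30\t95.2"), f)
  hits <- read_domain_hits(f, "tsv")
  expect_equal(hits$protein_id, "p1")
  expect_equal(hits$family, "PF00069")
  expect_equal(hits$start, 10L)
  expect_equal(hits$end, 260L)
  expect_equal(hits$evalue, 1e-30)
  expect_equal(hits$score, 95.2)
  # headers/comments only -> empty
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# only a comment", f2)
  expect_equal(nrow(read_domain_hits(f2, "tsv")), 0)
  # malformed rows name the offending line
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tPF1\t1\t50\t1e-5\t10", "p2\tPF2\tbad\t60\t1e-5\t10"), f3)
  expect_error(read_domain_hits(f3, "tsv"), "line 2")
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tPF1\t1", f4)
  expect_error(read_domain_hits(f4, "tsv"), "line 1")
})

test_that("domtblout dialect round-trips through write_domtblout", {
  hits <- data.frame(
    protein_id = c("p1", "p1", "p2"), family = c("PF1", "PF2", "PF1"),
    start = c(5L, 120L, 10L), end = c(90L, 300L, 200L),
    evalue = c(1e-20, 1e-8, 1e-15), score = c(55.5, 20.1, 44.4),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout(hits, f)
  back <- read_domain_hits(f, "domtblout")
  expect_equal(back$protein_id, hits$protein_id)
  expect_equal(back$family, hits$family)
  expect_equal(back$start, hits$start)
  expect_equal(back$end, hits$end)
  expect_equal(back$evalue, hits$evalue, tolerance = 0.05)
  # 3 hits on 2 proteins, grouped 2 + 1
  expect_equal(as.vector(table(back$protein_id)), c(2L, 1L))
})

test_that("resolve_overlaps drops dominated overlapping hits", {
  # two disjoint hits: both retained
  h <- data.frame(protein_id = "p", family = c("A", "B"),
                  start = c(10L, 200L), end = c(100L, 300L),
                  evalue = c(1e-20, 1e-10), score = c(80, 40))
  expect_equal(nrow(resolve_overlaps(h)), 2)
  # A 10-100 (1e-20) vs B 50-120 (1e-5): overlap 51 of shorter 71 > 0.5
  h2 <- data.frame(protein_id = "p", family = c("A", "B"),
                   start = c(10L, 50L), end = c(100L, 120L),
                   evalue = c(1e-20, 1e-5), score = c(80, 40))
  expect_equal(resolve_overlaps(h2)$family, "A")
  # single hit above cutoff -> empty
  h3 <- data.frame(protein_id = "p", family = "A", start = 1L, end = 50L,
                   evalue = 1e-3, score = 10)
  expect_equal(nrow(resolve_overlaps(h3)), 0)
  expect_error(resolve_overlaps(h, overlap_fraction = 0), "overlap_fraction")
  expect_error(resolve_overlaps(h, overlap_fraction = 1.5), "overlap_fraction")
})

test_that("resolved hits obey the pairwise overlap bound and idempotence", {
  set.seed(405)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    start <- sample(1:300, n)
    h <- data.frame(protein_id = "p",
                    family = sample(LETTERS[1:4], n, replace = TRUE),
                    start = start, end = start + sample(20:120, n, TRUE),
                    evalue = 10^-stats::runif(n, 6, 30),
                    score = stats::runif(n, 10, 100))
    res <- resolve_overlaps(h, overlap_fraction = 0.5)
    if (nrow(res) >= 2) {
      for (i in 1:(nrow(res) - 1)) {
        for (j in (i + 1):nrow(res)) {
          ov <- min(res$end[i], res$end[j]) -
            max(res$start[i], res$start[j]) + 1L
          shorter <- min(res$end[i] - res$start[i],
                         res$end[j] - res$start[j]) + 1L
          expect_lte(ov / shorter, 0.5)
        }
      }
    }
    expect_equal(resolve_overlaps(res, overlap_fraction = 0.5), res,
                 ignore_attr = TRUE)
  }
})

test_that("build_architectures orders domains and emits combinations", {
  h <- data.frame(protein_id = "p", family = c("A", "B", "A"),
                  start = c(10L, 50L, 90L), end = c(30L, 70L, 110L),
                  evalue = 1e-20, score = 10)
  a <- build_architectures(h)
  expect_equal(a$ordered_domains[[1]], c("A", "B", "A"))
  expect_equal(a$combination, "A+B")
  # single-domain protein: no combination
  a1 <- build_architectures(h[1, ])
  expect_true(is.na(a1$combination))
  # repeated single family: still no combination
  a2 <- build_architectures(h[c(1, 3), ])
  expect_true(is.na(a2$combination))
  # lectin-kinase exemplar: extracellular lectin domain + kinase domain
  h3 <- data.frame(protein_id = "Zci_10218",
                   family = c("Lectin_legB", "Pkinase"),
                   start = c(30L, 400L), end = c(260L, 650L),
                   evalue = c(1e-40, 1e-60), score = c(120, 200))
  expect_equal(build_architectures(h3)$combination, "Lectin_legB+Pkinase")
})

test_that("genome_feature_tables counts domains and combinations", {
  # genome with no proteins -> empty tables
  empty_hits <- data.frame(protein_id = character(0), family = character(0),
                           start = integer(0), end = integer(0),
                           evalue = numeric(0), score = numeric(0))
  tabs0 <- genome_feature_tables(list(gE = empty_hits))
  expect_equal(nrow(tabs0$domains), 0)
  expect_equal(nrow(tabs0$combinations), 0)
  # two proteins both carrying {A, B} -> combination count 2
  h <- data.frame(protein_id = rep(c("p1", "p2"), each = 2),
                  family = rep(c("A", "B"), 2),
                  start = rep(c(10L, 200L), 2), end = rep(c(100L, 300L), 2),
                  evalue = 1e-20, score = 50)
  tabs <- genome_feature_tables(list(g1 = h))
  expect_equal(unname(tabs$combinations["A+B", "g1"]), 2)
  expect_equal(unname(tabs$domains["A", "g1"]), 2)
  expect_lte(max(tabs$combinations), length(unique(h$protein_id)))
})

test_that("feature tables match synthetic generator truth", {
  sc <- clade_scenario(groups = c("X", "Y"), genomes_per_group = 2,
                       n_families = 30, seed = 406)
  sim <- simulate_clade_annotations(sc)
  tabs <- genome_feature_tables(sim$hits)
  truth <- sim$truth$copy_counts
  expect_setequal(rownames(tabs$domains), rownames(truth))
  expect_equal(unclass(tabs$domains)[rownames(truth), colnames(truth)],
               truth, ignore_attr = TRUE)
})
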