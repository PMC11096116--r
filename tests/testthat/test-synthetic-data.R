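test_that("clade scenario validation catches bad configurations", {
  expect_error(clade_scenario(groups = "only_one"), "2 distinct groups")
  expect_error(clade_scenario(genomes_per_group = 0), "zero genomes")
  expect_error(clade_scenario(dropout_rate = 1.5), "dropout_rate")
  expect_error(clade_scenario(
    planted_exclusives = list("Zygnematophyceae+Atlantis" = 2L)), "Atlantis")
  expect_error(clade_scenario(
    groups = c("A", "B"),
    planted_exclusives = list("A" = c("f1", "f2"), "B" = c("f2"))),
    "disjoint")
})

test_that("degenerate clade scenario puts every family everywhere", {
  sc <- clade_scenario(groups = c("A", "B"), genomes_per_group = 3,
                       n_families = 25, dropout_rate = 0, seed = 430)
  sim <- simulate_clade_annotations(sc)
  expect_true(all(sim$truth$copy_counts >= 1))
  tabs <- genome_feature_tables(sim$hits)
  expect_true(all(unclass(tabs$domains) >= 1))
})

test_that("clade simulation is deterministic and truth is consistent", {
  sc <- clade_scenario(
    planted_exclusives = list("Zygnematophyceae+Embryophyta" = 12L),
    seed = 431)
  s1 <- simulate_clade_annotations(sc)
  s2 <- simulate_clade_annotations(sc)
  expect_identical(s1, s2)
  # planted families appear in the truth table exactly once, with the
  # planted region
  tr <- s1$truth$regions
  planted <- tr$family[tr$region == "Zygnematophyceae+Embryophyta"]
  expect_equal(length(planted), 12)
  expect_equal(anyDuplicated(tr$family), 0)
  # planted exclusives have zero copies outside their region
  out_genomes <- s1$partition$genome[
    !s1$partition$group %in% c("Zygnematophyceae", "Embryophyta")]
  expect_true(all(s1$truth$copy_counts[planted, out_genomes] == 0))
})

test_that("planted expansions shift per-group copy count means", {
  sc <- clade_scenario(
    groups = c("uni", "multi"), genomes_per_group = 30, n_families = 2,
    planted_expansions = list(BG_0001 = c(uni = 2, multi = 8)),
    seed = 432)
  sim <- simulate_clade_annotations(sc)
  cc <- sim$truth$copy_counts
  uni <- sim$partition$genome[sim$partition$group == "uni"]
  multi <- sim$partition$genome[sim$partition$group == "multi"]
  expect_gt(mean(cc["BG_0001", multi]), 2 * mean(cc["BG_0001", uni]))
})

test_that("expression scenario validation and limit cases", {
  expect_error(expression_scenario(10, 5, modules = list(
    list(size = 20, categories = "stress", cor = 0.5))), "exceed")
  expect_error(expression_scenario(30, 5, modules = list(
    list(size = 3, categories = "stress", cor = 1.5))), "correlation")
  expect_error(expression_scenario(30, 5, modules = list(
    list(size = 3, categories = "not_a_label", cor = 0.5))), "not_a_label")
  # correlation 1, noise 0: module profiles are identical
  sim <- simulate_expression(expression_scenario(
    10, 8, modules = list(list(size = 4, categories = "stress", cor = 1)),
    noise_sd = 0, seed = 433))
  prof <- log2(sim$matrix[1:4, ])
  expect_true(all(apply(prof, 2, function(col) max(col) - min(col)) < 1e-12))
  expect_true(all(sim$matrix >= 0))
})

test_that("planted modules reach the requested correlation", {
  sim <- simulate_expression(expression_scenario(
    100, 60,
    modules = list(list(size = 20, categories = "stress", cor = 0.9),
                   list(size = 20, categories = "transporters", cor = 0.9)),
    seed = 434))
  lm <- log2(sim$matrix + 1)
  for (mod in 1:2) {
    idx <- which(sim$truth$module == mod)
    cm <- stats::cor(t(lm[idx, ]))
    expect_gte(mean(cm[upper.tri(cm)]), 0.8)
  }
  # background stays uncorrelated
  bg <- which(is.na(sim$truth$module))
  cm_bg <- stats::cor(t(lm[bg, ]))
  expect_lt(mean(abs(cm_bg[upper.tri(cm_bg)])), 0.2)
  # categories cycle through the module label list
  expect_setequal(unique(sim$gene_categories$category),
                  c("stress", "transporters"))
})

test_that("null expression matrix has no planted structure", {
  sim <- simulate_expression(expression_scenario(50, 60, seed = 435))
  cm <- stats::cor(t(log2(sim$matrix + 1)))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.2)
  expect_equal(nrow(sim$gene_categories), 0)
})

test_that("paralog scenario validation and zero-divergence limit", {
  expect_error(paralog_scenario(5, n_codons = 10), "50")
  expect_error(paralog_scenario(5, kappa = -1), "kappa")
  expect_error(paralog_scenario(5, ks_distribution = list(c(0.5, 0.1, 0.7))),
               "sum to 1")
  sim <- simulate_paralog_pairs(paralog_scenario(
    3, 60, ks_distribution = list(c(0, 0, 1)), seed = 436))
  expect_identical(as.character(sim$cds[[1]]), as.character(sim$cds[[2]]))
  expect_true(all(sim$truth$ks_drawn == 0))
})

test_that("drawn Ks follows the requested mixture", {
  sim <- simulate_paralog_pairs(paralog_scenario(
    1000, 60, ks_distribution = list(c(0.5, 0.05, 1)), seed = 437))
  expect_equal(mean(sim$truth$ks_drawn), 0.5, tolerance = 0.02 / 0.5)
  # bimodal truth draws: both components populated, separated cleanly
  sim2 <- simulate_paralog_pairs(paralog_scenario(
    400, 60, ks_distribution = list(c(0.3, 0.05, 0.5), c(1.2, 0.1, 0.5)),
    seed = 438))
  expect_gt(min(table(sim2$truth$component)), 100)
  lows <- sim2$truth$ks_drawn[sim2$truth$component == 1]
  highs <- sim2$truth$ks_drawn[sim2$truth$component == 2]
  expect_lt(max(lows), min(highs))
})

test_that("synthetic sequences never contain internal stop codons", {
  sim <- simulate_paralog_pairs(paralog_scenario(
    20, 80, ks_distribution = list(c(2, 0.5, 1)), seed = 439))
  gc <- Biostrings::GENETIC_CODE
  for (s in as.character(sim$cds)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(gc[cods] == "*"))
  }
})

test_that("write_fixture_set emits a complete, reproducible manifest", {
  d0 <- withr::local_tempdir()
  # empty scenario list -> empty manifest
  m0 <- write_fixture_set(list(), d0)
  expect_equal(nrow(m0), 0)
  # collision unless overwrite
  expect_error(write_fixture_set(list(), d0), "manifest")
  expect_silent(write_fixture_set(list(), d0, overwrite = TRUE))
  scen <- list(
    clade = clade_scenario(groups = c("A", "B"), genomes_per_group = 2,
                           n_families = 10, seed = 440),
    expression = expression_scenario(20, 10, modules = list(
      list(size = 5, categories = "stress", cor = 0.8)), seed = 441),
    paralog = paralog_scenario(4, 60, seed = 442))
  d1 <- withr::local_tempdir()
  m1 <- write_fixture_set(scen, d1)
  expect_true(all(file.exists(file.path(d1, m1$file))))
  expect_true("orthogroups.tsv" %in% m1$file)
  expect_true("paralogs.fasta" %in% m1$file)
  expect_true(any(grepl("domtblout$", m1$file)))
  # rerun with same seeds: identical checksums
  d2 <- withr::local_tempdir()
  m2 <- write_fixture_set(scen, d2)
  expect_identical(m1$md5, m2$md5)
  # written files round-trip through the readers
  part <- read_partition(file.path(d1, "partition.tsv"))
  expect_equal(partition_groups(part), c("A", "B"))
  og <- read_orthogroups(file.path(d1, "orthogroups.tsv"))
  expect_equal(nrow(og), 10)
  expr <- read_expression(file.path(d1, "expression.tsv"))
  expect_equal(dim(expr), c(20, 10))
})
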