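## Every generator seeds its own stream and restores the caller's RNG
## state afterwards, so simulation never leaks into or depends on global
## RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Scenario for synthetic clade-partitioned domain annotations
#'
#' Describes a world of genomes partitioned into groups, with background
#' domain families present everywhere, families planted exclusive to a
#' region (a subset of groups), per-group abundance (expansion) means, and
#' an annotation-dropout rate.  The default shape mirrors a 4-super-group,
#' 16-genome comparative design.
#'
#' @param groups Character vector of group names (>= 2).
#' @param genomes_per_group Positive integer (scalar or one per group).
#' @param n_families Total number of domain families, background included.
#' @param planted_exclusives Named list: region key (group names joined by
#'   `"+"`) -> character vector of family names planted exclusive to that
#'   region, or a single integer (auto-named families).  Families must be
#'   disjoint across regions.
#' @param planted_expansions Named list: family name -> named numeric
#'   vector of mean copy counts per group (unnamed groups keep the default
#'   mean of 2).
#' @param dropout_rate Probability in \[0, 1\] that a truly present family
#'   is unannotated in a given genome.
#' @param seed Integer seed for the scenario's private RNG stream.
#' @return Object of class `clade_scenario`.
#' @export
clade_scenario <- function(groups = c("Chlorophyta", "Streptophyte_algae",
                                      "Zygnematophyceae", "Embryophyta"),
                           genomes_per_group = 4L,
                           n_families = 200L,
                           planted_exclusives = list(),
                           planted_expansions = list(),
                           dropout_rate = 0,
                           seed = 1L) {
  groups <- as.character(groups)
  if (length(groups) < 2L || anyDuplicated(groups))
    stop("need >= 2 distinct groups")
  genomes_per_group <- rep_len(as.integer(genomes_per_group), length(groups))
  if (any(genomes_per_group < 1L)) stop("zero genomes in a group")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]")
  planted <- list()
  auto <- 0L
  for (key in names(planted_exclusives)) {
    region <- strsplit(key, "+", fixed = TRUE)[[1]]
    bad <- setdiff(region, groups)
    if (length(bad))
      stop("region '", key, "' names unknown group(s): ",
           paste(bad, collapse = ", "))
    fams <- planted_exclusives[[key]]
    if (is.numeric(fams) && length(fams) == 1L) {
      fams <- sprintf("EXC_%s_%03d", gsub("[^A-Za-z]", "", key),
                      auto + seq_len(fams))
      auto <- auto + length(fams)
    }
    planted[[key]] <- as.character(fams)
  }
  all_planted <- unlist(planted, use.names = FALSE)
  if (anyDuplicated(all_planted))
    stop("planted families must be disjoint across regions")
  if (length(all_planted) > n_families)
    stop("more planted families than n_families")
  structure(list(groups = groups, genomes_per_group = genomes_per_group,
                 n_families = as.integer(n_families),
                 planted_exclusives = planted,
                 planted_expansions = planted_expansions,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "clade_scenario")
}

#' Simulate per-genome domain annotations with planted clade truth
#'
#' Realizes a [clade_scenario()]: every family present in a genome
#' contributes Poisson-distributed copies (floored at 1, so planted
#' presence is never lost to sampling) as single-domain proteins with
#' plausible coordinates and E-values; annotation dropout then removes the
#' family from individual genomes at the scenario rate.  A parallel
#' orthogroup table maps each family to the proteins carrying it, giving
#' orthogroups the same planted exclusivity structure.
#'
#' @param scenario A [clade_scenario()].
#' @return List: `hits` (named list genome -> 6-column hit data frame),
#'   `orthogroups` (data frame: `orthogroup` + one comma-separated gene
#'   list column per genome), `partition` (a [clade_partition()]), `truth`
#'   (list: `regions` data frame `family`/`region`, and `copy_counts`
#'   family x genome matrix recording the realized pre-dropout counts,
#'   with dropped cells set to 0).
#' @export
simulate_clade_annotations <- function(scenario) {
  stopifnot(inherits(scenario, "clade_scenario"))
  with_seed(scenario$seed, {
    groups <- scenario$groups
    genome_group <- rep(groups, scenario$genomes_per_group)
    genomes <- unlist(lapply(seq_along(groups), function(i)
      sprintf("%s_g%d", groups[i], seq_len(scenario$genomes_per_group[i]))))
    partition <- clade_partition(genomes, genome_group, group_order = groups)

    planted <- scenario$planted_exclusives
    planted_fams <- unlist(planted, use.names = FALSE)
    n_bg <- scenario$n_families - length(planted_fams)
    bg <- if (n_bg > 0) sprintf("BG_%04d", seq_len(n_bg)) else character(0)
    fam_region <- c(
      stats::setNames(rep(names(planted), lengths(planted)), planted_fams),
      stats::setNames(rep(region_key(groups), n_bg), bg))
    families <- names(fam_region)

    copy_counts <- matrix(0L, length(families), length(genomes),
                          dimnames = list(families, genomes))
    for (fam in families) {
      region <- strsplit(fam_region[[fam]], "+", fixed = TRUE)[[1]]
      means <- scenario$planted_expansions[[fam]]
      for (gi in seq_along(genomes)) {
        grp <- genome_group[gi]
        if (!grp %in% region) next
        mu <- if (!is.null(means) && grp %in% names(means))
          means[[grp]] else 2
        copy_counts[fam, gi] <- max(1L, stats::rpois(1, mu))
      }
    }
    if (scenario$dropout_rate > 0) {
      present <- which(copy_counts > 0)
      drop <- present[stats::runif(length(present)) < scenario$dropout_rate]
      copy_counts[drop] <- 0L
    }

    hits <- list()
    og_cells <- matrix("", length(families), length(genomes),
                       dimnames = list(families, genomes))
    for (gi in seq_along(genomes)) {
      g <- genomes[gi]
      fams_here <- rep(families, copy_counts[, gi])
      n_prot <- length(fams_here)
      prots <- sprintf("%s_p%05d", g, seq_len(n_prot))
      dom_len <- 80L + stats::rpois(n_prot, 40)
      start <- 1L + stats::rpois(n_prot, 15)
      hits[[g]] <- data.frame(
        protein_id = prots, family = fams_here,
        start = start, end = start + dom_len - 1L,
        evalue = 10^(-stats::runif(n_prot, 10, 50)),
        score = round(stats::runif(n_prot, 50, 400), 1),
        stringsAsFactors = FALSE)
      by_fam <- split(prots, fams_here)
      og_cells[names(by_fam), gi] <-
        vapply(by_fam, paste, character(1), collapse = ",")
    }
    orthogroups <- data.frame(orthogroup = paste0("OG_", families),
                              stringsAsFactors = FALSE, check.names = FALSE)
    for (g in genomes) orthogroups[[g]] <- og_cells[, g]

    list(hits = hits, orthogroups = orthogroups, partition = partition,
         truth = list(
           regions = data.frame(family = families,
                                region = unname(fam_region),
                                stringsAsFactors = FALSE),
           copy_counts = copy_counts))
  })
}

#' Scenario for synthetic expression matrices with planted modules
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param modules List of planted modules, each a list with `size` (gene
#'   count), `categories` (labels from [study_categories()]) and `cor`
#'   (within-module Pearson correlation target, in (0, 1\]).
#' @param noise_sd Scale of the independent noise relative to the module
#'   signal; 1 (default) yields exactly the requested correlation, larger
#'   values attenuate it.
#' @param seed Integer seed.
#' @return Object of class `expression_scenario`.
#' @export
expression_scenario <- function(n_genes, n_samples, modules = list(),
                                noise_sd = 1, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  sizes <- vapply(modules, function(m) as.integer(m$size), integer(1))
  if (sum(sizes) > n_genes)
    stop("module gene counts exceed n_genes")
  for (m in modules) {
    if (m$cor <= 0 || m$cor > 1)
      stop("within-module correlation must be in (0, 1]")
    bad <- setdiff(m$categories, study_categories())
    if (length(bad))
      stop("unknown category label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 modules = modules, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "expression_scenario")
}

#' Simulate an expression matrix with planted co-expressed modules
#'
#' Genes of a planted module share a latent per-sample factor:
#' on the log2 scale a module gene is
#' `sqrt(r) * factor + noise_sd * sqrt(1 - r) * noise`, so at the default
#' `noise_sd = 1` the pairwise within-module Pearson correlation is exactly
#' the requested `r`.  Background genes are independent noise.  The emitted
#' matrix is `2^(8 + log2signal)` — strictly positive, roughly lognormal,
#' so the default `log2p1` transform of [correlation_ranks()] recovers the
#' planted structure.
#'
#' @param scenario An [expression_scenario()].
#' @return List: `matrix` (genes x samples), `gene_categories` (data frame
#'   `gene`, `category`; module genes only, labels cycled through the
#'   module's category list), `truth` (data frame `gene`, `module`, `NA`
#'   for background genes).
#' @export
simulate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "expression_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n_genes; s <- scenario$n_samples
    genes <- sprintf("gene%04d", seq_len(n))
    z <- matrix(scenario$noise_sd * stats::rnorm(n * s), n, s)
    module_of <- rep(NA_integer_, n)
    cat_rows <- list()
    at <- 0L
    for (mi in seq_along(scenario$modules)) {
      m <- scenario$modules[[mi]]
      idx <- at + seq_len(m$size)
      at <- at + m$size
      f <- stats::rnorm(s)
      r <- m$cor
      z[idx, ] <- sqrt(r) * matrix(f, m$size, s, byrow = TRUE) +
        scenario$noise_sd * sqrt(1 - r) * matrix(stats::rnorm(m$size * s),
                                                 m$size, s)
      module_of[idx] <- mi
      cat_rows[[mi]] <- data.frame(
        gene = genes[idx],
        category = rep_len(m$categories, m$size),
        stringsAsFactors = FALSE)
    }
    mat <- 2^(8 + z)
    dimnames(mat) <- list(genes, sprintf("sample%03d", seq_len(s)))
    list(matrix = mat,
         gene_categories = if (length(cat_rows)) do.call(rbind, cat_rows)
           else data.frame(gene = character(0), category = character(0),
                           stringsAsFactors = FALSE),
         truth = data.frame(gene = genes, module = module_of,
                            stringsAsFactors = FALSE))
  })
}

#' Scenario for synthetic paralog pairs at known synonymous divergence
#'
#' @param n_pairs Number of paralog pairs.
#' @param n_codons Codons per sequence (>= 50).
#' @param ks_distribution List of mixture components, each
#'   `c(mean, sd, weight)`; weights must sum to 1.  A separate component
#'   models a WGD burst.
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process (> 0; default 2, a typical nuclear-gene value).
#' @param seed Integer seed.
#' @return Object of class `paralog_scenario`.
#' @export
paralog_scenario <- function(n_pairs, n_codons = 300L,
                             ks_distribution = list(c(mean = 0.5,
                                                      sd = 0.05,
                                                      weight = 1)),
                             kappa = 2, seed = 1L) {
  if (n_codons < 50L) stop("n_codons must be >= 50")
  if (kappa <= 0) stop("kappa must be > 0")
  comp <- lapply(ks_distribution, function(x) {
    x <- unname(as.numeric(x))
    if (length(x) != 3L) stop("each component must be (mean, sd, weight)")
    x
  })
  w <- vapply(comp, `[`, numeric(1), 3)
  if (abs(sum(w) - 1) > 1e-8) stop("component weights must sum to 1")
  structure(list(n_pairs = as.integer(n_pairs),
                 n_codons = as.integer(n_codons),
                 components = comp, kappa = kappa, seed = as.integer(seed)),
            class = "paralog_scenario")
}

## evolve one branch: synonymous-only third-position jumps, expected number
## of synonymous substitutions per codon = branch_ks * (syn third-position
## changes / 3), jump targets weighted kappa (transition) : 1 (transversion)
evolve_branch <- function(codons, branch_ks, kappa, tabs) {
  for (i in seq_along(codons)) {
    nb <- tabs$syn3[[codons[i]]]
    if (!length(nb)) next
    s3 <- length(nb) / 3
    n_ev <- stats::rpois(1, branch_ks * s3)
    for (e in seq_len(n_ev)) {
      nb <- tabs$syn3[[codons[i]]]
      third <- substr(codons[i], 3, 3)
      w <- vapply(substr(nb, 3, 3), function(b)
        if (is_transition(third, b)) kappa else 1, numeric(1))
      codons[i] <- nb[sample.int(length(nb), 1, prob = w)]
    }
  }
  codons
}

#' Simulate paralog CDS pairs with exact synonymous-divergence truth
#'
#' Each pair descends from a random stop-free ancestor of `n_codons`
#' codons; both copies evolve independently for half the drawn Ks under a
#' synonymous-only third-position substitution process with
#' transition/transversion ratio `kappa`.  Because every substitution is
#' synonymous, the drawn Ks is the expected realized synonymous divergence
#' by construction, amino-acid sequences stay identical, and no internal
#' stop codon can arise.
#'
#' @param scenario A [paralog_scenario()].
#' @return List: `cds` (a `Biostrings::DNAStringSet`, two entries per pair
#'   named `<pair>_a` / `<pair>_b`), `truth` (data frame `pair`,
#'   `ks_drawn`, `component`).
#' @export
simulate_paralog_pairs <- function(scenario) {
  stopifnot(inherits(scenario, "paralog_scenario"))
  tabs <- codon_tables()
  with_seed(scenario$seed, {
    w <- vapply(scenario$components, `[`, numeric(1), 3)
    seqs <- character(2 * scenario$n_pairs)
    ids <- character(2 * scenario$n_pairs)
    pair_ids <- sprintf("pair%04d", seq_len(scenario$n_pairs))
    comp_idx <- integer(scenario$n_pairs)
    ks_drawn <- numeric(scenario$n_pairs)
    for (p in seq_len(scenario$n_pairs)) {
      ci <- sample.int(length(w), 1, prob = w)
      comp <- scenario$components[[ci]]
      ks <- max(0, stats::rnorm(1, comp[1], comp[2]))
      comp_idx[p] <- ci; ks_drawn[p] <- ks
      anc <- sample(tabs$sense, scenario$n_codons, replace = TRUE)
      a <- evolve_branch(anc, ks / 2, scenario$kappa, tabs)
      b <- evolve_branch(anc, ks / 2, scenario$kappa, tabs)
      seqs[2 * p - 1] <- paste(a, collapse = "")
      seqs[2 * p] <- paste(b, collapse = "")
      ids[2 * p - 1] <- paste0(pair_ids[p], "_a")
      ids[2 * p] <- paste0(pair_ids[p], "_b")
    }
    cds <- Biostrings::DNAStringSet(seqs)
    names(cds) <- ids
    list(cds = cds,
         truth = data.frame(pair = pair_ids, ks_drawn = ks_drawn,
                            component = comp_idx, stringsAsFactors = FALSE))
  })
}

#' Write a full synthetic fixture set to disk
#'
#' Emits every file format the downstream modules consume — per-genome hit
#' tables (plain TSV and domtblout dialect), the orthogroup table, the
#' partition, the expression matrix, gene categories, paralog CDS FASTA —
#' plus the generator truth tables and a manifest listing every file with
#' its MD5 checksum and originating seed.
#'
#' @param scenarios List with any of the named entries `clade`
#'   (a [clade_scenario()]), `expression` (an [expression_scenario()]),
#'   `paralog` (a [paralog_scenario()]).  An empty list yields an empty
#'   manifest.
#' @param dir Output directory (created if needed).
#' @param overwrite Overwrite an existing manifest (default `FALSE`;
#'   a collision is otherwise an error).
#' @return The manifest data frame (`file`, `type`, `seed`, `md5`),
#'   invisibly also written to `manifest.tsv`.
#' @export
write_fixture_set <- function(scenarios = list(), dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists at ", manifest_path,
         " (use overwrite = TRUE)")
  rows <- list()
  note <- function(file, type, seed) {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, type = type, seed = seed,
      md5 = unname(tools::md5sum(file.path(dir, file))),
      stringsAsFactors = FALSE)
  }
  wtsv <- function(df, file, rn = FALSE) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = rn, col.names = TRUE)
  }
  if (!is.null(scenarios$clade)) {
    sim <- simulate_clade_annotations(scenarios$clade)
    seed <- scenarios$clade$seed
    for (g in names(sim$hits)) {
      f <- paste0(g, "_hits.tsv")
      wtsv(sim$hits[[g]], f); note(f, "domain_hits_tsv", seed)
      f2 <- paste0(g, ".domtblout")
      write_domtblout(sim$hits[[g]], file.path(dir, f2))
      note(f2, "domain_hits_domtblout", seed)
    }
    wtsv(sim$orthogroups, "orthogroups.tsv")
    note("orthogroups.tsv", "orthogroups", seed)
    wtsv(as.data.frame(sim$partition), "partition.tsv")
    note("partition.tsv", "partition", seed)
    wtsv(sim$truth$regions, "clade_truth_regions.tsv")
    note("clade_truth_regions.tsv", "truth", seed)
    wtsv(as.data.frame(sim$truth$copy_counts), "clade_truth_counts.tsv",
         rn = TRUE)
    note("clade_truth_counts.tsv", "truth", seed)
  }
  if (!is.null(scenarios$expression)) {
    sim <- simulate_expression(scenarios$expression)
    seed <- scenarios$expression$seed
    wtsv(as.data.frame(sim$matrix), "expression.tsv", rn = TRUE)
    note("expression.tsv", "expression_matrix", seed)
    wtsv(sim$gene_categories, "gene_categories.tsv")
    note("gene_categories.tsv", "gene_categories", seed)
    wtsv(sim$truth, "expression_truth.tsv")
    note("expression_truth.tsv", "truth", seed)
  }
  if (!is.null(scenarios$paralog)) {
    sim <- simulate_paralog_pairs(scenarios$paralog)
    seed <- scenarios$paralog$seed
    Biostrings::writeXStringSet(sim$cds, file.path(dir, "paralogs.fasta"))
    note("paralogs.fasta", "paralog_cds", seed)
    wtsv(sim$truth, "ks_truth.tsv")
    note("ks_truth.tsv", "truth", seed)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), type = character(0),
               seed = integer(0), md5 = character(0),
               stringsAsFactors = FALSE)
  wtsv(manifest, "manifest.tsv")
  manifest
}

#' Write domain hits in hmmscan domtblout dialect
#'
#' Produces the 23-column whitespace-delimited per-domain format, with the
#' hit coordinates in the envelope columns, so [read_domain_hits()] with
#' `dialect = "domtblout"` round-trips the table.
#'
#' @param hits 6-column hit data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", "target name  accession  tlen  query name",
                   "accession  qlen  E-value  score  bias  #  of",
                   "c-Evalue  i-Evalue  score  bias  from  to",
                   "ali-from  ali-to  env-from  env-to  acc description"),
             con)
  if (nrow(hits)) {
    len <- hits$end - hits$start + 1L
    lines <- sprintf(
      "%s %s %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 1 %d %d %d %d %d 0.99 -",
      hits$family, hits$family, len, hits$protein_id, hits$end + 20L,
      hits$evalue, ifelse(is.na(hits$score), 0, hits$score),
      hits$evalue, hits$evalue, ifelse(is.na(hits$score), 0, hits$score),
      len, hits$start, hits$end, hits$start, hits$end)
    writeLines(lines, con)
  }
  invisible(path)
}
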