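# Independent brute-force oracles and small fixture builders.  These
# deliberately re-derive every quantity from first principles (bitmask
# enumeration, nested loops) so they share no code path with the package.

# random feature x genome count matrix
random_count_matrix <- function(n_feat, n_genomes, lambda = 1,
                                p_zero = 0.5) {
  m <- matrix(ifelse(stats::runif(n_feat * n_genomes) < p_zero, 0L,
                     1L + stats::rpois(n_feat * n_genomes, lambda)),
              n_feat, n_genomes,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              sprintf("g%03d", seq_len(n_genomes))))
  presence_matrix(m, "domain")
}

random_partition <- function(genomes, n_groups) {
  n_groups <- min(n_groups, length(genomes))
  grp_names <- LETTERS[seq_len(n_groups)]
  # guarantee every group non-empty
  g <- c(grp_names, sample(grp_names, length(genomes) - n_groups,
                           replace = TRUE))
  clade_partition(genomes, g[seq_along(genomes)], group_order = grp_names)
}

# oracle: per-feature region assignment by direct looping
oracle_venn <- function(mat, partition) {
  grp <- partition_groups(partition)
  out <- list()
  absent <- character(0)
  for (f in rownames(mat)) {
    present_groups <- character(0)
    for (g in grp) {
      members <- partition$genome[partition$group == g]
      any_present <- FALSE
      for (mem in members)
        if (mem %in% colnames(mat) && mat[f, mem] >= 1) any_present <- TRUE
      if (any_present) present_groups <- c(present_groups, g)
    }
    if (!length(present_groups)) {
      absent <- c(absent, f)
    } else {
      key <- paste(present_groups, collapse = "+")
      out[[key]] <- c(out[[key]], f)
    }
  }
  list(regions = out, absent = absent)
}

# oracle: exact Wilcoxon rank-sum p by bitmask subset enumeration
oracle_wilcox_p <- function(x, y, alternative) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ws <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != n1) next
    ws <- c(ws, sum(r[bits == 1]))
  }
  eps <- 1e-9
  switch(alternative,
         greater = mean(ws >= w_obs - eps),
         less = mean(ws <= w_obs + eps),
         two_sided = mean(abs(ws - mu) >= abs(w_obs - mu) - eps))
}

# oracle: hypergeometric enrichment tail via stats::dhyper summation
oracle_fisher_p <- function(a, b, c_, d) {
  K <- a + c_; N <- a + b + c_ + d; n <- a + b
  sum(stats::dhyper(a:min(K, n), K, N - K, n))
}

# oracle: HRR edge set from the raw expression matrix by explicit counting,
# replicating the declared tie-break (descending correlation, then gene id)
oracle_hrr_edges <- function(mat, cutoff, transform = "log2p1") {
  m <- if (transform == "log2p1") log2(mat + 1) else mat
  cm <- stats::cor(t(m))
  ids <- rownames(mat)
  n <- length(ids)
  rank_of <- function(i, j) {
    cnt <- 1L
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      if (cm[i, k] > cm[i, j] ||
          (cm[i, k] == cm[i, j] && ids[k] < ids[j])) cnt <- cnt + 1L
    }
    cnt
  }
  edges <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      hrr <- max(rank_of(i, j), rank_of(j, i))
      if (hrr <= cutoff)
        edges <- c(edges, paste(sort(c(ids[i], ids[j])), collapse = "|"))
    }
  }
  sort(edges)
}

# oracle: reciprocal best hits by double argmax loops
oracle_rbbh <- function(scores, cutoff) {
  scores <- scores[scores$query != scores$subject &
                     scores$evalue <= cutoff, , drop = FALSE]
  ids <- unique(scores$query)
  best <- character(0)
  for (q in ids) {
    sub <- scores[scores$query == q, , drop = FALSE]
    sub <- sub[order(-sub$score, sub$evalue, sub$subject), , drop = FALSE]
    best[q] <- sub$subject[1]
  }
  pairs <- character(0)
  for (q in names(best)) {
    s <- best[[q]]
    if (!is.na(best[s]) && identical(unname(best[s]), q) && q < s)
      pairs <- c(pairs, paste(q, s, sep = "|"))
  }
  sort(pairs)
}

# adjusted Rand index between two label vectors (NA = singleton)
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.character(a); b <- as.character(b)
  a[is.na(a)] <- paste0(".singA", seq_along(a))[is.na(a)]
  b[is.na(b)] <- paste0(".singB", seq_along(b))[is.na(b)]
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# pairwise Ks table for a simulated paralog set
pairwise_ks <- function(sim) {
  n <- nrow(sim$truth)
  vapply(seq_len(n), function(p) {
    aln <- codon_alignment(as.character(sim$cds[[2 * p - 1]]),
                           as.character(sim$cds[[2 * p]]))
    compute_ks(aln)$ks
  }, numeric(1))
}
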