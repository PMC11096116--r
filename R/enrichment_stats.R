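#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control.  Implemented directly (sort,
#' cumulative minimum of `p * m / rank`, cap at 1) so that the adjustment
#' is self-contained and testable against the hand formula; ties are stable
#' and the output is order-preserving.
#'
#' @param p Numeric vector of p-values in \[0, 1\].  `NA`/`NaN` are rejected.
#' @return Vector of BH-adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p)) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

## Exact rank-sum null: enumerate every split of the pooled midranks into
## group-1 positions.  The index matrix depends only on (n1, n) and is
## cached, so batches of features with common group sizes pay the
## enumeration cost once.
rank_split_cache <- new.env(parent = emptyenv())

rank_splits <- function(n1, n) {
  key <- paste(n1, n, sep = "_")
  if (is.null(rank_split_cache[[key]]))
    rank_split_cache[[key]] <- utils::combn(n, n1)
  rank_split_cache[[key]]
}

#' Exact or approximate Wilcoxon rank-sum p-value
#'
#' Midranks handle ties.  When `n1 + n2 <= 2 * exact_max` genomes and both
#' groups have at most `exact_max`, the null distribution of the group-1
#' rank sum is obtained by enumerating all `choose(n1+n2, n1)` index splits
#' of the pooled sample; otherwise a normal approximation with tie
#' correction and continuity correction is used.  `alternative` refers to
#' the location of `x` (group 1) relative to `y`.
#'
#' @param x,y Numeric samples for the two groups.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @param exact_max Largest per-group size for which exact enumeration is
#'   used (default 10).
#' @return List with `p`, the rank-biserial correlation `effect`
#'   (positive when `x` tends larger), and `exact` (logical).
#' @export
wilcox_rank_sum <- function(x, y,
                            alternative = c("two_sided", "greater", "less"),
                            exact_max = 10) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  u1 <- w_obs - n1 * (n1 + 1) / 2
  effect <- 2 * u1 / (n1 * n2) - 1
  eps <- 1e-9
  if (n1 <= exact_max && n2 <= exact_max) {
    splits <- rank_splits(n1, n)
    w_null <- colSums(matrix(r[splits], nrow = n1))
    p <- switch(alternative,
      greater   = mean(w_null >= w_obs - eps),
      less      = mean(w_null <= w_obs + eps),
      two_sided = mean(abs(w_null - mu) >= abs(w_obs - mu) - eps))
    return(list(p = p, effect = effect, exact = TRUE))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(p = 1, effect = effect, exact = FALSE))
  z_num <- w_obs - mu
  cc <- 0.5  # continuity correction
  p <- switch(alternative,
    greater = stats::pnorm((z_num - cc) / sqrt(sigma2), lower.tail = FALSE),
    less    = stats::pnorm((z_num + cc) / sqrt(sigma2)),
    two_sided = {
      zz <- (abs(z_num) - cc) / sqrt(sigma2)
      2 * stats::pnorm(max(zz, 0), lower.tail = FALSE)
    })
  list(p = min(p, 1), effect = effect, exact = FALSE)
}

#' Two-group abundance (expansion/contraction) test per feature
#'
#' For every feature row, compares per-genome copy counts between the two
#' groups of the partition with the Wilcoxon rank-sum test (exact when both
#' groups have at most 10 genomes).  Features with zero counts in every
#' genome carry no information and are skipped with a flag rather than
#' tested.  BH adjustment is applied across the tested features.
#'
#' @param mat A [presence_matrix()] (or plain count matrix with dimnames)
#'   of non-negative integer counts.
#' @param partition A [clade_partition()] with exactly 2 groups, each
#'   holding at least 2 genomes.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`;
#'   refers to the first group of the partition relative to the second.
#' @return Data frame with one row per feature: `feature`, `p`, `q`,
#'   `effect` (rank-biserial correlation, positive when group 1 counts tend
#'   larger), `direction` (`"expanded"`/`"contracted"` describing group 2
#'   relative to group 1, `"none"` when balanced), `skipped`.
#' @export
abundance_test_two_groups <- function(mat, partition,
                                      alternative = c("two_sided", "greater",
                                                      "less")) {
  alternative <- match.arg(alternative)
  grp <- partition_groups(partition)
  if (length(grp) != 2L) stop("exactly 2 groups required")
  g1 <- intersect(partition$genome[partition$group == grp[1]], colnames(mat))
  g2 <- intersect(partition$genome[partition$group == grp[2]], colnames(mat))
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least 2 genomes with data")
  counts <- unclass(mat)
  if (any(counts != round(counts)))
    stop("counts must be integers")
  feats <- rownames(mat)
  p <- effect <- rep(NA_real_, length(feats))
  skipped <- logical(length(feats))
  for (i in seq_along(feats)) {
    x <- counts[i, g1]; y <- counts[i, g2]
    if (all(x == 0) && all(y == 0)) { skipped[i] <- TRUE; next }
    res <- wilcox_rank_sum(x, y, alternative)
    p[i] <- res$p; effect[i] <- res$effect
  }
  q <- rep(NA_real_, length(feats))
  q[!skipped] <- bh_adjust(p[!skipped])
  direction <- ifelse(skipped, NA_character_,
                      ifelse(effect < 0, "expanded",
                             ifelse(effect > 0, "contracted", "none")))
  data.frame(feature = feats, p = p, q = q, effect = effect,
             direction = direction, skipped = skipped,
             stringsAsFactors = FALSE)
}

## One-sided hypergeometric upper tail P(X >= a), X ~ Hypergeom with
## K feature-positive genes among N, n drawn (foreground).  Computed from
## log binomial coefficients to stay exact-at-double-precision.
hyper_tail <- function(a, K, N, n) {
  hi <- min(K, n)
  if (a > hi) return(0)
  i <- a:hi
  min(1, sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))))
}

#' Fisher/hypergeometric enrichment of features in a foreground gene set
#'
#' For every feature annotated to at least one foreground gene, computes the
#' one-sided (enrichment) hypergeometric tail probability of the 2x2 table
#' foreground/background x with/without feature, plus the sample odds ratio
#' `(a*d)/(b*c)` (reported as `Inf` or 0 when a zero cell makes it so, never
#' imputed).  Features absent from the foreground are not tested.
#'
#' @param foreground Character vector of foreground gene ids.
#' @param background Character vector of background gene ids
#'   (universe = foreground + background; the two must be disjoint).
#' @param gene_features Data frame with columns `gene` and `feature`
#'   (a gene may carry several features).
#' @return Data frame per tested feature: `feature`, `a`, `b`, `c`, `d`,
#'   `p`, `q` (BH), `odds_ratio`, `direction`
#'   (`"enriched"` if the foreground proportion exceeds the background
#'   proportion, else `"depleted"`).
#' @export
fisher_enrichment <- function(foreground, background, gene_features) {
  if (!length(foreground)) stop("empty foreground")
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  both <- intersect(foreground, background)
  if (length(both))
    stop("foreground and background overlap: ",
         paste(utils::head(both, 3), collapse = ", "))
  stopifnot(all(c("gene", "feature") %in% names(gene_features)))
  universe <- c(foreground, background)
  gf <- unique(gene_features[gene_features$gene %in% universe,
                             c("gene", "feature")])
  n_fg <- length(foreground); N <- length(universe)
  fg_tab <- table(gf$feature[gf$gene %in% foreground])
  if (!length(fg_tab))
    return(data.frame(feature = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p = numeric(0),
                      q = numeric(0), odds_ratio = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  all_tab <- table(gf$feature)
  feats <- names(fg_tab)
  a <- as.integer(fg_tab)
  K <- as.integer(all_tab[feats])
  b <- n_fg - a
  cc <- K - a
  d <- (N - n_fg) - cc
  p <- vapply(seq_along(feats), function(i) hyper_tail(a[i], K[i], N, n_fg),
              numeric(1))
  or <- ifelse(b * cc == 0,
               ifelse(a * d == 0, NaN, Inf),
               (a * d) / (b * cc))
  or[a * d == 0 & b * cc > 0] <- 0
  direction <- ifelse(a / n_fg >= cc / (N - n_fg), "enriched", "depleted")
  data.frame(feature = feats, a = a, b = b, c = cc, d = d,
             p = p, q = bh_adjust(p), odds_ratio = or,
             direction = direction, stringsAsFactors = FALSE)
}
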