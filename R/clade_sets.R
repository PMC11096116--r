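#' Clade partition of genomes into groups
#'
#' A partition assigns every genome to exactly one group (clade, super-group
#' or body-plan class).  It is the substrate of all presence/exclusivity
#' algebra: Venn regions, clade-exclusive features and repertoire similarity
#' are defined relative to a partition.
#'
#' @param genomes Character vector of genome identifiers.
#' @param groups Character vector, same length, giving the group of each
#'   genome.  At least two distinct groups are required.
#' @param group_order Optional character vector fixing the display order of
#'   the groups; defaults to order of first appearance.
#' @return An object of class `clade_partition`: a data frame with columns
#'   `genome` and `group`, plus a `groups` attribute holding the ordered
#'   group names.
#' @examples
#' clade_partition(c("g1", "g2", "g3", "g4"),
#'                 c("uni", "uni", "multi", "multi"))
#' @export
clade_partition <- function(genomes, groups, group_order = NULL) {
  genomes <- as.character(genomes)
  groups <- as.character(groups)
  stopifnot(length(genomes) == length(groups), length(genomes) > 0L)
  if (anyDuplicated(genomes))
    stop("duplicated genome ids: ",
         paste(unique(genomes[duplicated(genomes)]), collapse = ", "))
  if (anyNA(genomes) || anyNA(groups))
    stop("genome and group labels must be non-missing")
  if (is.null(group_order)) group_order <- unique(groups)
  if (!setequal(group_order, unique(groups)))
    stop("'group_order' must name exactly the groups present")
  if (length(group_order) < 2L)
    stop("a clade partition needs at least 2 groups")
  out <- data.frame(genome = genomes, group = groups,
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- group_order
  class(out) <- c("clade_partition", "data.frame")
  out
}

#' @export
print.clade_partition <- function(x, ...) {
  grp <- partition_groups(x)
  cat("clade_partition: ", nrow(x), " genomes in ", length(grp),
      " groups\n", sep = "")
  tab <- table(factor(x$group, levels = grp))
  for (g in grp) cat("  ", g, ": ", tab[[g]], " genome(s)\n", sep = "")
  invisible(x)
}

#' Ordered group names of a partition
#' @param partition A [clade_partition()].
#' @return Character vector of group names.
#' @export
partition_groups <- function(partition) attr(partition, "groups")

#' Read a genome-to-group partition from a TSV file
#'
#' Expects two tab-separated columns, `genome` and `group`, with or without
#' a header line.
#'
#' @param path Path to the file.
#' @return A [clade_partition()].
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) stop("partition file needs 2 columns: genome, group")
  if (identical(tolower(df[1, 1]), "genome")) df <- df[-1, , drop = FALSE]
  clade_partition(df[[1]], df[[2]])
}

#' Feature-by-genome count matrix with derived presence
#'
#' Wraps a non-negative integer count matrix (features in rows, genomes in
#' columns) together with the kind of feature it holds.  Presence is always
#' derived as `count >= 1`, never stored.
#'
#' @param counts Numeric matrix, features x genomes, with row and column
#'   names.  Counts must be non-negative.
#' @param kind One of `"domain"`, `"combination"`, `"orthogroup"`.
#' @return An object of class `presence_matrix` (a matrix with a `kind`
#'   attribute).
#' @export
presence_matrix <- function(counts,
                            kind = c("domain", "combination", "orthogroup")) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("counts must have feature rownames and genome colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  attr(counts, "kind") <- kind
  class(counts) <- c("presence_matrix", class(counts))
  counts
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix [", attr(x, "kind"), "]: ", nrow(x), " features x ",
      ncol(x), " genomes; ", sum(x >= 1), " present cells\n", sep = "")
  invisible(x)
}

#' Read a tab-separated orthogroup membership table
#'
#' One row per orthogroup: first column the orthogroup id, remaining columns
#' (one per genome, named in the header) comma-separated gene lists.  Empty
#' cells mean no member in that genome.
#'
#' @param path Path to the file.
#' @return Data frame with column `orthogroup` and one character column per
#'   genome holding comma-separated gene ids.
#' @export
read_orthogroups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("orthogroup table needs an id column and >=1 genome")
  names(df)[1] <- "orthogroup"
  df
}

#' Orthogroup gene-count matrix under a partition
#'
#' Converts an orthogroup membership table into a [presence_matrix()] whose
#' entries count genes per genome per orthogroup, checking that all genome
#' columns are covered by the partition.
#'
#' @param og_table Data frame as returned by [read_orthogroups()].
#' @param partition A [clade_partition()] covering all genome columns.
#' @return A `presence_matrix` of kind `"orthogroup"`.
#' @export
presence_from_orthogroups <- function(og_table, partition) {
  genomes <- setdiff(names(og_table), "orthogroup")
  missing <- setdiff(genomes, partition$genome)
  if (length(missing))
    stop("genomes in orthogroup table absent from partition: ",
         paste(missing, collapse = ", "))
  n_genes <- function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(0L)
    length(strsplit(trimws(cell), ",[ ]*")[[1]])
  }
  counts <- matrix(0L, nrow = nrow(og_table), ncol = length(genomes),
                   dimnames = list(og_table$orthogroup, genomes))
  for (g in genomes)
    counts[, g] <- vapply(og_table[[g]], n_genes, integer(1),
                          USE.NAMES = FALSE)
  presence_matrix(counts, "orthogroup")
}

#' Per-group presence of features
#'
#' A feature is present in a group iff it is present (count >= 1) in at
#' least one genome of that group.
#'
#' @param mat A [presence_matrix()].
#' @param partition A [clade_partition()] covering the matrix genomes.
#' @return Logical matrix, features x groups.
#' @export
group_presence <- function(mat, partition) {
  missing <- setdiff(colnames(mat), partition$genome)
  if (length(missing))
    stop("genomes missing from partition: ", paste(missing, collapse = ", "))
  grp <- partition_groups(partition)
  out <- vapply(grp, function(g) {
    members <- intersect(partition$genome[partition$group == g], colnames(mat))
    if (!length(members)) return(rep(FALSE, nrow(mat)))
    rowSums(mat[, members, drop = FALSE] >= 1) > 0
  }, logical(nrow(mat)))
  matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), grp))
}

region_key <- function(groups) paste(groups, collapse = "+")

#' Venn partition of features over group-presence regions
#'
#' Assigns every group-present feature to exactly one of the `2^k - 1`
#' non-empty subsets of groups: the exact set of groups in which it is
#' present.  Features present in no group are excluded from the regions and
#' reported via the `"absent"` attribute.
#'
#' @param gp Logical feature-x-group matrix from [group_presence()].
#' @return Named list mapping region keys (group names joined by `"+"`, in
#'   partition group order) to character vectors of features.  All
#'   `2^k - 1` regions are present, possibly empty.  Attribute `absent`
#'   lists features present nowhere.
#' @export
venn_partition <- function(gp) {
  grp <- colnames(gp)
  k <- length(grp)
  if (k < 1L) stop("at least one group required")
  keys <- character(2^k - 1L)
  regions <- vector("list", 2^k - 1L)
  idx <- 0L
  for (size in seq_len(k)) {
    for (sel in utils::combn(k, size, simplify = FALSE)) {
      idx <- idx + 1L
      keys[idx] <- region_key(grp[sel])
      regions[[idx]] <- character(0)
    }
  }
  names(regions) <- keys
  present_any <- rowSums(gp) > 0
  if (any(present_any)) {
    feat_keys <- apply(gp[present_any, , drop = FALSE], 1,
                       function(p) region_key(grp[p]))
    split_feats <- split(rownames(gp)[present_any], feat_keys)
    for (kk in names(split_feats)) regions[[kk]] <- split_feats[[kk]]
  }
  attr(regions, "absent") <- rownames(gp)[!present_any]
  regions
}

#' Features exclusive to a region of the partition
#'
#' Under `any_genome` universality a feature qualifies when it is present in
#' at least one genome of every in-region group and in zero genomes of every
#' out-region group ("present in at least one representative").  Under
#' `all_genomes` it must additionally be present in every genome of every
#' in-region group (the per-genome "shared by all" sense).
#'
#' @param mat A [presence_matrix()].
#' @param partition A [clade_partition()].
#' @param region Character vector of group names forming the region.
#' @param universality `"any_genome"` (default) or `"all_genomes"`.
#' @return Character vector of qualifying feature names.
#' @export
exclusive_features <- function(mat, partition, region,
                               universality = c("any_genome", "all_genomes")) {
  universality <- match.arg(universality)
  grp <- partition_groups(partition)
  unknown <- setdiff(region, grp)
  if (length(unknown))
    stop("unknown group(s): ", paste(unknown, collapse = ", "))
  if (!length(region)) stop("region must be a non-empty set of groups")
  pres <- mat >= 1
  in_ok <- rep(TRUE, nrow(mat))
  for (g in region) {
    members <- intersect(partition$genome[partition$group == g], colnames(mat))
    sub <- pres[, members, drop = FALSE]
    in_ok <- in_ok & if (universality == "any_genome")
      rowSums(sub) > 0 else rowSums(sub) == length(members)
  }
  out_ok <- rep(TRUE, nrow(mat))
  for (g in setdiff(grp, region)) {
    members <- intersect(partition$genome[partition$group == g], colnames(mat))
    out_ok <- out_ok & rowSums(pres[, members, drop = FALSE]) == 0
  }
  rownames(mat)[in_ok & out_ok]
}

#' Pairwise repertoire similarity between groups
#'
#' Compares the group-present feature sets of every pair of groups.  The
#' default (and currently only) metric is the Jaccard index
#' \eqn{|F_A \cap F_B| / |F_A \cup F_B|}.  Two empty repertoires are defined
#' as similarity 1 with a warning.
#'
#' @param mat A [presence_matrix()].
#' @param partition A [clade_partition()].
#' @param metric Only `"jaccard"` is implemented.
#' @return Data frame with columns `group1`, `group2`, `similarity` for all
#'   unordered group pairs.
#' @export
repertoire_similarity <- function(mat, partition, metric = "jaccard") {
  metric <- match.arg(metric, "jaccard")
  gp <- group_presence(mat, partition)
  grp <- colnames(gp)
  pairs <- utils::combn(grp, 2, simplify = FALSE)
  sim <- vapply(pairs, function(p) {
    a <- gp[, p[1]]; b <- gp[, p[2]]
    union_n <- sum(a | b)
    if (union_n == 0) {
      warning("both repertoires empty for pair ", p[1], " / ", p[2],
              "; similarity defined as 1")
      return(1)
    }
    sum(a & b) / union_n
  }, numeric(1))
  data.frame(group1 = vapply(pairs, `[`, character(1), 1),
             group2 = vapply(pairs, `[`, character(1), 2),
             similarity = sim, stringsAsFactors = FALSE)
}
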