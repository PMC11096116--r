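#' Per-gene co-expression correlation ranks
#'
#' Computes Pearson correlations between gene expression profiles (rows)
#' and, for each gene, ranks every other gene by descending correlation
#' (best co-expressed partner = rank 1).  Ties are broken lexicographically
#' by gene id so the ranking is deterministic.  Genes with zero variance
#' cannot be correlated and are excluded with a warning.
#'
#' @param mat Numeric genes x samples matrix with row names (>= 3 samples).
#' @param transform `"log2p1"` (default, `log2(x + 1)`) or `"none"`.
#' @return Integer matrix `R` with `R[i, j]` = rank of gene `j` in gene
#'   `i`'s descending-correlation list (1..n-1, `NA` diagonal).  The
#'   correlation matrix is attached as attribute `"cor"`.
#' @export
correlation_ranks <- function(mat, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L) stop("at least 3 samples required")
  if (is.null(rownames(mat))) stop("gene row names required")
  if (anyNA(mat)) stop("missing values in expression matrix")
  if (transform == "log2p1") {
    if (any(mat < 0)) stop("log2p1 transform needs non-negative values")
    mat <- log2(mat + 1)
  }
  v <- apply(mat, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " constant-profile gene(s): ",
            paste(utils::head(rownames(mat)[v == 0], 5), collapse = ", "))
    mat <- mat[v > 0, , drop = FALSE]
  }
  n <- nrow(mat)
  if (n < 2L) stop("fewer than 2 non-constant genes")
  ids <- rownames(mat)
  cm <- stats::cor(t(mat))
  ranks <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-cm[i, others], ids[others])]
    ranks[i, ord] <- seq_along(ord)
  }
  attr(ranks, "cor") <- cm
  ranks
}

#' Highest-reciprocal-rank (HRR) co-expression network
#'
#' Connects genes `i` and `j` when `max(rank_i(j), rank_j(i)) <= cutoff`,
#' weighting the edge by that maximum (lower = stronger mutual
#' co-expression).  The resulting graph is undirected by construction.
#'
#' @param ranks Rank matrix from [correlation_ranks()].
#' @param cutoff Largest HRR admitted as an edge (default 30).
#' @return An object of class `hrr_network`: list with `edges` (data frame
#'   `gene1`, `gene2`, `hrr`, with `gene1 < gene2`), `genes` and `cutoff`.
#' @export
build_hrr_network <- function(ranks, cutoff = 30) {
  if (cutoff < 1) stop("cutoff must be >= 1")
  ids <- rownames(ranks)
  n <- length(ids)
  hrr <- pmax(ranks, t(ranks))
  keep <- which(upper.tri(hrr) & hrr <= cutoff, arr.ind = TRUE)
  edges <- data.frame(gene1 = ids[keep[, 1]], gene2 = ids[keep[, 2]],
                      hrr = as.integer(hrr[keep]), stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, genes = ids, cutoff = cutoff),
            class = "hrr_network")
}

#' @export
print.hrr_network <- function(x, ...) {
  cat("hrr_network: ", length(x$genes), " genes, ", nrow(x$edges),
      " edges (HRR cutoff ", x$cutoff, ")\n", sep = "")
  invisible(x)
}

## adjacency as a named list of integer neighbor indices
adjacency_list <- function(net) {
  n <- length(net$genes)
  idx <- stats::setNames(seq_len(n), net$genes)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- integer(0)
  if (nrow(net$edges)) {
    i <- idx[net$edges$gene1]; j <- idx[net$edges$gene2]
    for (e in seq_along(i)) {
      adj[[i[e]]] <- c(adj[[i[e]]], j[e])
      adj[[j[e]]] <- c(adj[[j[e]]], i[e])
    }
  }
  lapply(adj, sort)
}

## grow the neighborhood of v one step at a time, chiseling after every
## expansion so loosely attached bridge nodes cannot drag in foreign
## subgraphs on the next step
grow_candidate <- function(adj, v, steps) {
  nodes <- v
  for (s in seq_len(steps)) {
    expanded <- sort(unique(c(nodes, unlist(adj[nodes]))))
    if (length(expanded) == length(nodes)) break
    nodes <- chisel(adj, expanded)
    if (!length(nodes)) return(integer(0))
  }
  nodes
}

## chisel: repeatedly drop nodes with more edges leaving the candidate set
## than inside it, until stable
chisel <- function(adj, nodes) {
  repeat {
    if (!length(nodes)) return(integer(0))
    inside <- vapply(nodes, function(v) sum(adj[[v]] %in% nodes), integer(1))
    outside <- lengths(adj[nodes]) - inside
    drop <- outside > inside
    if (!any(drop)) return(nodes)
    nodes <- nodes[!drop]
  }
}

#' Cluster an HRR network by heuristic cluster chiseling (HCCA)
#'
#' For every node, grows its neighborhood one step at a time up to
#' `step_size` steps; after every expansion, nodes with more edges leaving
#' the candidate set than inside it are chiseled away until stable, so
#' loosely attached bridge nodes cannot drag in foreign subgraphs on the
#' next expansion.  Surviving candidates within the size bounds are scored by their
#' internal-edge fraction (internal edges / all edges incident to the
#' candidate) and accepted greedily, best first, skipping candidates that
#' overlap an accepted cluster.  All remaining genes stay unassigned.
#' Ties in score are broken by size (larger first) and then smallest member
#' id, so the procedure is deterministic; `seed` is accepted for interface
#' symmetry with the simulators and recorded, but no randomness is used.
#'
#' @param net An [build_hrr_network()] object.
#' @param step_size Neighborhood radius in steps (default 3).
#' @param max_cluster_size Largest admissible cluster (default 100).
#' @param min_cluster_size Smallest admissible cluster (default 3).
#' @param seed Integer, recorded in the result.
#' @return An object of class `module_set`: list with `modules` (data frame
#'   `gene`, `module`; `NA` module = unassigned), `scores` (per accepted
#'   module) and the parameters.
#' @export
hcca_cluster <- function(net, step_size = 3, max_cluster_size = 100,
                         min_cluster_size = 3, seed = 1L) {
  if (step_size < 1) stop("step_size must be >= 1")
  adj <- adjacency_list(net)
  n <- length(net$genes)
  candidates <- list()
  scores <- numeric(0)
  for (v in seq_len(n)) {
    if (!length(adj[[v]])) next
    cand <- grow_candidate(adj, v, step_size)
    if (length(cand) < min_cluster_size || length(cand) > max_cluster_size)
      next
    inside <- sum(vapply(cand, function(u) sum(adj[[u]] %in% cand),
                         integer(1))) / 2
    incident <- inside + sum(lengths(adj[cand])) - 2 * inside
    if (incident == 0) next
    key <- paste(cand, collapse = ",")
    if (!is.null(candidates[[key]])) next
    candidates[[key]] <- cand
    scores[key] <- inside / incident
  }
  ord <- order(-scores,
               -lengths(candidates),
               vapply(candidates, function(x) x[1], integer(1)))
  assignment <- rep(NA_integer_, n)
  mod_scores <- numeric(0)
  next_id <- 0L
  for (k in ord) {
    cand <- candidates[[k]]
    if (any(!is.na(assignment[cand]))) next
    next_id <- next_id + 1L
    assignment[cand] <- next_id
    mod_scores[next_id] <- scores[k]
  }
  structure(list(
    modules = data.frame(gene = net$genes, module = assignment,
                         stringsAsFactors = FALSE),
    scores = mod_scores,
    step_size = step_size, max_cluster_size = max_cluster_size,
    min_cluster_size = min_cluster_size, seed = seed),
    class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- length(x$scores)
  cat("module_set: ", n_mod, " modules, ",
      sum(!is.na(x$modules$module)), "/", nrow(x$modules),
      " genes assigned\n", sep = "")
  invisible(x)
}

#' Per-module functional-category membership
#'
#' Counts, for every module, how many member genes carry each functional
#' category label.  Unlabeled genes contribute nothing; a gene may carry
#' several labels.  Labels must come from the declared category set.
#'
#' @param modules A `module_set` from [hcca_cluster()], or a data frame
#'   with columns `gene` and `module`.
#' @param gene_categories Data frame with columns `gene` and `category`.
#' @param categories Character vector of admissible labels; defaults to the
#'   seven study categories ([study_categories()]).
#' @return Integer matrix modules x categories of member-gene counts.
#' @export
module_category_matrix <- function(modules, gene_categories,
                                   categories = study_categories()) {
  if (inherits(modules, "module_set")) modules <- modules$modules
  stopifnot(all(c("gene", "module") %in% names(modules)))
  stopifnot(all(c("gene", "category") %in% names(gene_categories)))
  bad <- setdiff(unique(gene_categories$category), categories)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "))
  assigned <- modules[!is.na(modules$module), , drop = FALSE]
  mods <- sort(unique(assigned$module))
  out <- matrix(0L, length(mods), length(categories),
                dimnames = list(as.character(mods), categories))
  gc <- unique(gene_categories[, c("gene", "category")])
  merged <- merge(assigned, gc, by = "gene")
  if (nrow(merged)) {
    tab <- table(factor(merged$module, levels = mods),
                 factor(merged$category, levels = categories))
    out[] <- as.integer(tab)
  }
  out
}

#' The seven functional categories tracked in module annotation
#'
#' Homolog categories used when annotating co-expression modules: cell
#' division and development, multicellularity, stress response,
#' transporters, phytohormones, calcium signaling, and plant-microbe
#' interaction.
#' @return Character vector of length 7.
#' @export
study_categories <- function() {
  c("cell_division_development", "multicellularity", "stress",
    "transporters", "phytohormones", "calcium_signaling",
    "plant_microbe_interaction")
}

#' Functional-category co-occurrence across modules
#'
#' A module is multi-category when at least two distinct categories have a
#' member gene in it.  For every unordered category pair, co-occurrence is
#' the number of multi-category modules containing both, reported both as a
#' raw count and as a fraction of multi-category modules (the figure-style
#' normalization is not uniquely defined, so both are returned).
#'
#' @param cat_matrix Module x category count matrix from
#'   [module_category_matrix()].
#' @return List with `n_modules`, `n_multi` (modules with >= 2 categories),
#'   `pairs` (data frame `category1`, `category2`, `count`, `fraction`) and
#'   `matrix` (symmetric count matrix with zero diagonal).
#' @export
cooccurrence_frequencies <- function(cat_matrix) {
  if (!nrow(cat_matrix)) stop("at least one module required")
  pres <- cat_matrix >= 1
  multi <- rowSums(pres) >= 2
  n_multi <- sum(multi)
  cats <- colnames(cat_matrix)
  co <- matrix(0L, length(cats), length(cats), dimnames = list(cats, cats))
  if (n_multi > 0) {
    pm <- pres[multi, , drop = FALSE]
    co <- crossprod(pm) # pairwise co-membership counts
    diag(co) <- 0L
    storage.mode(co) <- "integer"
  }
  pair_idx <- which(upper.tri(co), arr.ind = TRUE)
  pairs <- data.frame(
    category1 = cats[pair_idx[, 1]], category2 = cats[pair_idx[, 2]],
    count = co[pair_idx],
    fraction = if (n_multi > 0) co[pair_idx] / n_multi else
      rep(NA_real_, nrow(pair_idx)),
    stringsAsFactors = FALSE)
  if (n_multi == 0) pairs <- pairs[0, , drop = FALSE]
  rownames(pairs) <- NULL
  list(n_modules = nrow(cat_matrix), n_multi = n_multi,
       pairs = pairs, matrix = co)
}
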