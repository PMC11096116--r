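## ---- codon machinery ------------------------------------------------------

NUCS <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

is_transition <- function(a, b) {
  (a %in% PURINES) == (b %in% PURINES)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

## prefixes whose third position is fully degenerate (fourfold family)
fourfold_prefixes <- function() {
  gc <- Biostrings::GENETIC_CODE
  prefixes <- unique(substr(names(gc), 1, 2))
  keep <- vapply(prefixes, function(p) {
    aas <- gc[paste0(p, NUCS)]
    length(unique(aas)) == 1L && aas[1] != "*"
  }, logical(1))
  prefixes[keep]
}

## NG86 synonymous site count of one codon: at each position, the fraction
## of the 3 possible changes that preserve the amino acid.  Changes creating
## a stop codon count as nonsynonymous.
syn_sites_codon <- function(codon) {
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      alt_aa <- translate_codon(alt)
      if (!is.na(alt_aa) && alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
  }
  s
}

codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (is.null(codon_env$syn_sites)) {
    sc <- sense_codons()
    codon_env$sense <- sc
    codon_env$syn_sites <- vapply(sc, syn_sites_codon, numeric(1))
    codon_env$fourfold <- fourfold_prefixes()
    ## synonymous third-position neighbors of every sense codon
    codon_env$syn3 <- lapply(stats::setNames(sc, sc), function(cd) {
      aa <- translate_codon(cd)
      alt3 <- paste0(substr(cd, 1, 2), setdiff(NUCS, substr(cd, 3, 3)))
      alt3[vapply(alt3, function(a) {
        x <- translate_codon(a); !is.na(x) && x == aa
      }, logical(1))]
    })
  }
  codon_env
}

## NG86 pathway counting: average synonymous/nonsynonymous differences over
## all orderings of the differing positions, excluding paths through stop
## codons (all paths used if every path hits a stop).
perms2 <- list(1:2, 2:1)
perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
               c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

codon_diff_counts <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k, list(1L), perms2, perms3)
  path_counts <- matrix(NA_real_, length(perms), 2)
  valid <- logical(length(perms))
  for (pi in seq_along(perms)) {
    cur <- c1
    sd <- nd <- 0
    ok <- TRUE
    for (step in diff_pos[perms[[pi]]]) {
      nxt <- cur
      substr(nxt, step, step) <- substr(c2, step, step)
      aa1 <- translate_codon(cur); aa2 <- translate_codon(nxt)
      if (is.na(aa2) || aa2 == "*") { ok <- FALSE }
      if (!is.na(aa1) && !is.na(aa2) && aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    path_counts[pi, ] <- c(sd, nd)
    valid[pi] <- ok
  }
  use <- if (any(valid)) valid else rep(TRUE, length(perms))
  c(sd = mean(path_counts[use, 1]), nd = mean(path_counts[use, 2]))
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Pairwise codon alignment container
#'
#' Validates a codon-level alignment of two coding sequences: equal
#' lengths, a multiple of 3, no internal stop codons.  Codon pairs with
#' non-ACGT characters are tolerated at construction and skipped by the
#' estimators.
#'
#' @param seq1,seq2 Aligned CDS strings (no gaps; use
#'   [backtranslate_alignment()] to produce them from a protein alignment).
#' @return Object of class `codon_alignment` (list of codon vectors).
#' @export
codon_alignment <- function(seq1, seq2) {
  c1 <- split_codons(seq1); c2 <- split_codons(seq2)
  if (length(c1) != length(c2)) stop("aligned sequences differ in length")
  gc <- Biostrings::GENETIC_CODE
  for (cods in list(c1, c2)) {
    clean <- cods[grepl("^[ACGT]{3}$", cods)]
    if (any(gc[clean] == "*"))
      stop("internal stop codon in alignment")
  }
  structure(list(codons1 = c1, codons2 = c2), class = "codon_alignment")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces every aligned residue by its codon from the corresponding CDS
#' and drops alignment columns containing a gap on either side, at codon
#' granularity.  Each CDS must be exactly 3x the ungapped protein length
#' (a trailing stop codon is not tolerated; trim it first).
#'
#' @param prot_aln Character vector of 2 aligned protein strings
#'   (gap = `-`).
#' @param cds1,cds2 Ungapped coding sequences.
#' @param on_stop `"error"` (default) to fail on an internal stop codon in
#'   the retained columns, `"drop"` to drop the offending codon column.
#' @return A [codon_alignment()].
#' @export
backtranslate_alignment <- function(prot_aln, cds1, cds2,
                                    on_stop = c("error", "drop")) {
  on_stop <- match.arg(on_stop)
  stopifnot(length(prot_aln) == 2L)
  a1 <- strsplit(prot_aln[1], "")[[1]]
  a2 <- strsplit(prot_aln[2], "")[[1]]
  if (length(a1) != length(a2)) stop("aligned proteins differ in length")
  cod1 <- split_codons(cds1); cod2 <- split_codons(cds2)
  if (sum(a1 != "-") * 3 != nchar(cds1) || sum(a2 != "-") * 3 != nchar(cds2))
    stop("CDS length must be 3x the ungapped protein length")
  i1 <- cumsum(a1 != "-"); i2 <- cumsum(a2 != "-")
  keep <- a1 != "-" & a2 != "-"
  k1 <- cod1[i1[keep]]; k2 <- cod2[i2[keep]]
  if (on_stop == "drop") {
    gc <- Biostrings::GENETIC_CODE
    is_stop <- function(cd) grepl("^[ACGT]{3}$", cd) & !is.na(gc[cd]) &
      gc[cd] == "*"
    bad <- is_stop(k1) | is_stop(k2)
    k1 <- k1[!bad]; k2 <- k2[!bad]
  }
  codon_alignment(paste(k1, collapse = ""), paste(k2, collapse = ""))
}

#' Synonymous and nonsynonymous divergence (NG86)
#'
#' Nei-Gojobori (1986) counting: synonymous/nonsynonymous sites as the
#' fraction of possible changes preserving the amino acid, differences
#' averaged over all substitution orderings between each codon pair
#' (stop-crossing paths excluded), and Jukes-Cantor correction of the
#' proportions.  Ks is flagged undefined when the corrected log argument is
#' non-positive (saturation, pS >= 3/4).
#'
#' @param aln A [codon_alignment()].
#' @param method Only `"NG86"` is implemented (the method slot exists so
#'   that alternative estimators can be added).
#' @param min_codons Minimum alignment length in codons (default 30).
#' @return List: `ks`, `ka` (`NA` when undefined), `S`, `N` (site counts),
#'   `Sd`, `Nd` (difference counts), `pS`, `pN`, `n_codons`, `saturated`.
#' @export
compute_ks <- function(aln, method = "NG86", min_codons = 30) {
  method <- match.arg(method, "NG86")
  stopifnot(inherits(aln, "codon_alignment"))
  tabs <- codon_tables()
  ok <- grepl("^[ACGT]{3}$", aln$codons1) & grepl("^[ACGT]{3}$", aln$codons2)
  c1 <- aln$codons1[ok]; c2 <- aln$codons2[ok]
  if (length(c1) < min_codons)
    stop("alignment shorter than ", min_codons, " usable codons")
  S <- sum((tabs$syn_sites[c1] + tabs$syn_sites[c2]) / 2)
  N <- 3 * length(c1) - S
  sd_nd <- vapply(seq_along(c1), function(i) {
    if (c1[i] == c2[i]) c(0, 0) else codon_diff_counts(c1[i], c2[i])
  }, numeric(2))
  Sd <- sum(sd_nd[1, ]); Nd <- sum(sd_nd[2, ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) NA_real_ else -3 / 4 * log(arg)
  }
  ks <- jc(pS); ka <- jc(pN)
  list(ks = ks, ka = ka, S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, n_codons = length(c1),
       saturated = is.na(ks))
}

#' Transversion divergence at fourfold-degenerate sites (4dtv)
#'
#' A site pair qualifies when both codons share identical first two
#' positions belonging to a fourfold-degenerate codon family; the statistic
#' is the fraction of those third positions differing by a transversion.
#' The corrected value applies a TN93/HKY-style transversion distance,
#' `-2*gR*gY*log(1 - Q / (2*gR*gY))`, with purine/pyrimidine frequencies
#' `gR`, `gY` estimated from the pooled bases at the qualifying sites, so
#' the correction uses the observed composition rather than assuming
#' uniform frequencies.  Undefined values (`n4 = 0`, or a saturated log
#' argument) are returned as `NA` with a flag, never as an error.
#'
#' @param aln A [codon_alignment()].
#' @return List: `fourdtv_raw`, `fourdtv_corrected`, `n4`, `n_transversion`,
#'   `n_transition`, `defined`.
#' @export
compute_4dtv <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tabs <- codon_tables()
  ok <- grepl("^[ACGT]{3}$", aln$codons1) & grepl("^[ACGT]{3}$", aln$codons2)
  c1 <- aln$codons1[ok]; c2 <- aln$codons2[ok]
  pre1 <- substr(c1, 1, 2); pre2 <- substr(c2, 1, 2)
  four <- pre1 == pre2 & pre1 %in% tabs$fourfold
  n4 <- sum(four)
  if (n4 == 0)
    return(list(fourdtv_raw = NA_real_, fourdtv_corrected = NA_real_,
                n4 = 0L, n_transversion = 0L, n_transition = 0L,
                defined = FALSE))
  t1 <- substr(c1[four], 3, 3); t2 <- substr(c2[four], 3, 3)
  differs <- t1 != t2
  tv <- differs & (t1 %in% PURINES) != (t2 %in% PURINES)
  ts <- differs & !tv
  q <- sum(tv) / n4
  bases <- c(t1, t2)
  gR <- mean(bases %in% PURINES)
  gY <- 1 - gR
  b <- 2 * gR * gY
  corrected <- if (q == 0) 0 else
    if (b > 0 && q < b) -b * log(1 - q / b) else NA_real_
  list(fourdtv_raw = q, fourdtv_corrected = corrected, n4 = n4,
       n_transversion = sum(tv), n_transition = sum(ts),
       defined = !is.na(corrected))
}

## ---- reciprocal best hits -------------------------------------------------

#' Reciprocal best-hit paralog pairs
#'
#' From a directed hit table (query, subject, score, evalue), determines
#' each protein's best hit (highest score; ties by lowest evalue, then
#' lexicographic subject id) after discarding self-hits and hits above the
#' E-value cutoff, and retains unordered pairs that are mutual best hits.
#' Alternatively, an `AAStringSet` of protein sequences may be supplied, in
#' which case all-vs-all global alignment scores (BLOSUM62) are computed
#' internally — suitable for small inputs only.
#'
#' @param scores Data frame with columns `query`, `subject`, `score`,
#'   `evalue`, or a `Biostrings::AAStringSet`.
#' @param evalue_cutoff Maximum evalue admitted (default `1e-6`).
#' @return Data frame of unordered pairs: `id1`, `id2` (`id1 < id2`),
#'   `score`, sorted by id.
#' @export
rbbh_pairs <- function(scores, evalue_cutoff = 1e-6) {
  if (inherits(scores, "AAStringSet")) scores <- alignment_scores(scores)
  if (!nrow(scores)) stop("empty score table")
  stopifnot(all(c("query", "subject", "score", "evalue") %in% names(scores)))
  if (any(scores$evalue < 0)) stop("negative evalue")
  scores <- scores[scores$query != scores$subject &
                     scores$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(scores))
    return(data.frame(id1 = character(0), id2 = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  ord <- order(scores$query, -scores$score, scores$evalue, scores$subject)
  scores <- scores[ord, , drop = FALSE]
  best <- scores[!duplicated(scores$query), , drop = FALSE]
  best_of <- stats::setNames(best$subject, best$query)
  mutual <- best$query < best$subject &
    !is.na(best_of[best$subject]) &
    best_of[best$subject] == best$query
  out <- data.frame(id1 = best$query[mutual], id2 = best$subject[mutual],
                    score = best$score[mutual], stringsAsFactors = FALSE)
  out <- out[order(out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All-vs-all global alignment scores for a small protein set
#'
#' Convenience score table for [rbbh_pairs()] when no external search
#' results are available; uses Needleman-Wunsch with BLOSUM62 via
#' Biostrings.  Quadratic in the number of sequences — small inputs only.
#'
#' @param aa An `AAStringSet` with names.
#' @return Data frame `query`, `subject`, `score`, `evalue` (evalue set to
#'   0, as alignment scores carry no E-value).
#' @export
alignment_scores <- function(aa) {
  stopifnot(inherits(aa, "AAStringSet"), !is.null(names(aa)))
  ids <- names(aa)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      sc <- Biostrings::pairwiseAlignment(
        aa[[i]], aa[[j]], substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(query = ids[i], subject = ids[j], score = sc,
                   evalue = 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## ---- distribution summary -------------------------------------------------

#' Filtered divergence distribution with Gaussian KDE and peak calls
#'
#' Removes undefined values, exact zeros (uninformative identical pairs,
#' typically recent tandem duplicates or annotation artifacts) and values
#' above `ceiling` (saturation guard), then fits a Gaussian kernel density
#' (Scott's rule bandwidth by default) on a fixed 512-point grid over
#' \[0, ceiling\] and reports local maxima with density above
#' `peak_min_fraction` of the global maximum.
#'
#' @param values Numeric vector of Ks or 4dtv values (NAs allowed).
#' @param bandwidth Numeric bandwidth, or `NULL` for Scott's rule.
#' @param ceiling Upper filter bound (default 5, appropriate for Ks; use 1
#'   for 4dtv).
#' @param min_values Minimum surviving values required (default 20).
#' @param peak_min_fraction Minimum peak height as a fraction of the
#'   density maximum (default 0.05), suppressing numerical ripples.
#' @return List: `values` (filtered), `n_removed_zero`, `n_removed_high`,
#'   `density` (data frame `x`, `y`), `peaks` (x locations, ascending),
#'   `bandwidth`.
#' @export
distribution_summary <- function(values, bandwidth = NULL, ceiling = 5,
                                 min_values = 20, peak_min_fraction = 0.05) {
  v <- values[!is.na(values)]
  n_zero <- sum(v == 0)
  v <- v[v != 0]
  n_high <- sum(v > ceiling)
  v <- v[v <= ceiling]
  if (length(v) < min_values)
    stop("only ", length(v), " values survive filtering (need ",
         min_values, ")")
  bw <- if (is.null(bandwidth)) stats::bw.nrd(v) else bandwidth
  den <- stats::density(v, bw = bw, n = 512, from = 0, to = ceiling)
  y <- den$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n], FALSE)
  is_peak <- is_peak & y >= peak_min_fraction * max(y)
  # consolidate ripples: a local maximum within 2 bandwidths of a taller
  # retained peak is grid-level noise, not a separate mode
  cand <- order(y, decreasing = TRUE)[is_peak[order(y, decreasing = TRUE)]]
  kept <- numeric(0)
  for (i in cand)
    if (!length(kept) || all(abs(den$x[i] - kept) > 2 * bw))
      kept <- c(kept, den$x[i])
  list(values = v, n_removed_zero = n_zero, n_removed_high = n_high,
       density = data.frame(x = den$x, y = den$y),
       peaks = sort(kept), bandwidth = bw)
}
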