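#' Read a protein domain hit table
#'
#' Supports two dialects: `"tsv"`, a plain 6-column table
#' (protein, family, start, end, evalue, score), and `"domtblout"`, the
#' whitespace-delimited per-domain output of hmmscan.  For domtblout,
#' coordinates are taken from the envelope columns, the per-domain
#' independent E-value is used, and the family is the target accession when
#' available (target name otherwise).  Comment lines starting with `#` are
#' skipped in both dialects.
#'
#' @param path Path to the hit file.
#' @param dialect `"tsv"` or `"domtblout"`.
#' @return Data frame with columns `protein_id`, `family`, `start`, `end`,
#'   `evalue`, `score` (1-based inclusive residue coordinates).
#' @export
read_domain_hits <- function(path, dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(0), family = character(0),
                      start = integer(0), end = integer(0),
                      evalue = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parse_num <- function(txt, line_no, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- is.na(v)
    if (any(bad))
      stop("line ", line_no[bad][1], ": non-numeric ", what, " '",
           txt[bad][1], "'")
    v
  }
  line_no <- which(!grepl("^#", readLines(path)))[seq_along(lines)]
  if (dialect == "tsv") {
    # tolerate a single header line
    first <- strsplit(lines[1], "\t| +")[[1]]
    if (length(first) >= 4 && is.na(suppressWarnings(as.numeric(first[3]))) &&
        is.na(suppressWarnings(as.numeric(first[4])))) {
      lines <- lines[-1]
      line_no <- line_no[-1]
      if (!length(lines)) return(empty)
    }
    parts <- strsplit(lines, "\t| +")
    nc <- lengths(parts)
    if (any(nc < 5L))
      stop("line ", line_no[nc < 5L][1],
           ": expected >=5 columns (protein, family, start, end, evalue)")
    get <- function(i) vapply(parts, function(p)
      if (length(p) >= i) p[i] else NA_character_, character(1))
    hits <- data.frame(
      protein_id = get(1), family = get(2),
      start = as.integer(parse_num(get(3), line_no, "start")),
      end = as.integer(parse_num(get(4), line_no, "end")),
      evalue = parse_num(get(5), line_no, "evalue"),
      score = suppressWarnings(as.numeric(get(6))),
      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, " +")
    nc <- lengths(parts)
    if (any(nc < 22L))
      stop("line ", line_no[nc < 22L][1],
           ": domtblout rows need >=22 columns, got ", nc[nc < 22L][1])
    get <- function(i) vapply(parts, `[`, character(1), i)
    fam <- ifelse(get(2) == "-", get(1), sub("\\.\\d+$", "", get(2)))
    hits <- data.frame(
      protein_id = get(4), family = fam,
      start = as.integer(parse_num(get(20), line_no, "envelope start")),
      end = as.integer(parse_num(get(21), line_no, "envelope end")),
      evalue = parse_num(get(13), line_no, "i-Evalue"),
      score = parse_num(get(14), line_no, "domain score"),
      stringsAsFactors = FALSE)
  }
  bad <- hits$start > hits$end
  if (any(bad)) stop("line ", line_no[bad][1], ": start > end")
  if (any(hits$evalue < 0)) stop("negative evalue")
  hits
}

#' Resolve overlapping domain hits on one protein
#'
#' Hits with E-value above `evalue_cutoff` are removed.  Surviving hits are
#' considered greedily by ascending E-value (score descending, then start,
#' as tie-breaks): a hit is dropped when it overlaps an already-retained hit
#' by more than `overlap_fraction` of the shorter of the two hit lengths.
#' The result is sorted by start coordinate.
#'
#' @param hits Data frame of hits for a single protein
#'   (see [read_domain_hits()]).
#' @param evalue_cutoff Maximum E-value retained (default `1e-5`).
#' @param overlap_fraction Maximum tolerated overlap as a fraction of the
#'   shorter hit, in (0, 1] (default 0.5).
#' @return The retained hits, sorted by `start`.
#' @export
resolve_overlaps <- function(hits, evalue_cutoff = 1e-5,
                             overlap_fraction = 0.5) {
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in (0, 1]")
  if (length(unique(hits$protein_id)) > 1L)
    stop("resolve_overlaps() expects hits of a single protein")
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) <= 1L)
    return(hits[order(hits$start), , drop = FALSE])
  ord <- order(hits$evalue, -ifelse(is.na(hits$score), -Inf, hits$score),
               hits$start, hits$family)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      if (ov <= 0) next
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j]) + 1L
      if (ov / shorter > overlap_fraction) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Build per-protein domain architectures
#'
#' The architecture of a protein is its retained domains in ascending start
#' order; its combination is the unordered set of distinct families, emitted
#' only when at least two distinct families co-occur (repeats of a single
#' family do not make a combination).  Combination ids are the sorted
#' distinct family names joined by `"+"`.
#'
#' @param hits Data frame of resolved hits, possibly spanning many proteins.
#' @return Data frame, one row per protein: `protein_id`, `ordered_domains`
#'   (list column of family vectors in start order), `combination`
#'   (character id or `NA` for 0-1 distinct families), `n_domains`.
#' @export
build_architectures <- function(hits) {
  if (!nrow(hits))
    return(data.frame(protein_id = character(0),
                      ordered_domains = I(list()),
                      combination = character(0), n_domains = integer(0),
                      stringsAsFactors = FALSE))
  hits <- hits[order(hits$protein_id, hits$start, hits$end), , drop = FALSE]
  by_prot <- split(hits$family, hits$protein_id)
  combo <- vapply(by_prot, function(fams) {
    u <- sort(unique(fams))
    if (length(u) >= 2L) paste(u, collapse = "+") else NA_character_
  }, character(1))
  data.frame(protein_id = names(by_prot),
             ordered_domains = I(unname(by_prot)),
             combination = unname(combo),
             n_domains = unname(lengths(by_prot)),
             stringsAsFactors = FALSE)
}

#' Per-genome domain and combination count tables
#'
#' For each genome, resolves overlapping hits, builds architectures and
#' counts: domain count = retained hits of that family; combination count =
#' proteins carrying exactly that combination.  Presence downstream is
#' derived as count >= 1.
#'
#' @param hits_by_genome Named list, genome id -> raw hit data frame.
#' @param evalue_cutoff,overlap_fraction Passed to [resolve_overlaps()].
#' @return List with `domains` and `combinations`, both [presence_matrix()]
#'   objects (features x genomes), and `architectures`, a named list of
#'   per-genome architecture tables.
#' @export
genome_feature_tables <- function(hits_by_genome, evalue_cutoff = 1e-5,
                                  overlap_fraction = 0.5) {
  stopifnot(is.list(hits_by_genome), !is.null(names(hits_by_genome)))
  genomes <- names(hits_by_genome)
  dom_counts <- list(); com_counts <- list(); archs <- list()
  for (g in genomes) {
    hits <- hits_by_genome[[g]]
    resolved <- if (nrow(hits)) {
      do.call(rbind, lapply(split(hits, hits$protein_id), resolve_overlaps,
                            evalue_cutoff = evalue_cutoff,
                            overlap_fraction = overlap_fraction))
    } else hits
    arch <- build_architectures(resolved)
    archs[[g]] <- arch
    dom_counts[[g]] <- table(resolved$family)
    com_counts[[g]] <- table(arch$combination[!is.na(arch$combination)])
  }
  tab_to_matrix <- function(tabs, kind) {
    feats <- sort(unique(unlist(lapply(tabs, names))))
    m <- matrix(0L, nrow = length(feats), ncol = length(genomes),
                dimnames = list(feats, genomes))
    for (g in genomes) m[names(tabs[[g]]), g] <- as.integer(tabs[[g]])
    if (!length(feats))
      m <- matrix(0L, 0, length(genomes), dimnames = list(NULL, genomes))
    presence_matrix(m, kind)
  }
  list(domains = tab_to_matrix(dom_counts, "domain"),
       combinations = tab_to_matrix(com_counts, "combination"),
       architectures = archs)
}
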