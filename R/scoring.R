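#' Count premature stop codons in a candidate locus
#'
#' Each member hit's scaffold span is translated in its own frame (the span
#' is read from its own strand, so the hit's reading frame is preserved) and
#' internal `*` codons are counted, excluding a stop at the very end of the
#' span. The locus-level count is the sum over member hits. In-frame stops
#' interrupting a homology-defined coding span are the classic signature of
#' pseudogenised, endogenised viral sequence.
#'
#' @param locus One row of a [merge_adjacent_hits()] locus table (or a list
#'   with a `members` data.frame).
#' @param scaffolds Named list of [seq_record()]s covering the locus.
#' @return Integer stop count (with per-member counts as attribute
#'   `per_member`).
#' @export
detect_premature_stops <- function(locus, scaffolds) {
  members <- if (is.data.frame(locus)) locus$members[[1]] else locus$members
  sid <- members$scaffold_id[1]
  scf <- scaffolds[[sid]]
  if (is.null(scf)) stop("scaffold not found: ", sid)
  s <- seq_string(scf)
  L <- nchar(s)
  per <- integer(nrow(members))
  for (i in seq_len(nrow(members))) {
    a <- members$s_start[i]; b <- members$s_end[i]
    if (a < 1 || b > L) stop("hit coordinates outside scaffold ", sid)
    span <- substring(s, a, b)
    if (members$strand[i] == "-") span <- revcomp(span)
    n <- nchar(span) %/% 3L
    if (n == 0L) next
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(substring(span, 1L, 3L * n)),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
    stops <- gregexpr("*", pep, fixed = TRUE)[[1]]
    stops <- stops[stops > 0]
    per[i] <- sum(stops < n)   # terminal stop at span end excluded
  }
  structure(sum(per), per_member = per)
}

#' Extract the six evidence features for a candidate locus
#'
#' Implements the feature definitions of the additive confidence scheme:
#' \itemize{
#'   \item `premature_stop`: at least one internal stop codon in the locus
#'     ([detect_premature_stops()]).
#'   \item `depth_comparable`: the locus scaffold's sequencing depth lies
#'     within `[median/f, median*f]` of the host background median
#'     (`f = depth_comparable_factor`).
#'   \item `eukaryotic_gene_on_scaffold`: any `gene` annotation flagged as
#'     insect-assigned (`taxon=insect` in its attributes) on the scaffold.
#'   \item `te_on_scaffold`: any transposable-element annotation on the
#'     scaffold.
#'   \item `gc_similar`: scaffold GC within `gc_similarity_delta` (absolute)
#'     of the host background mean.
#'   \item `scaffold_exceeds_viral_size`: scaffold longer than
#'     `long_scaffold_bp` (default 500 kb, above known exogenous
#'     naldaviricete genome sizes).
#' }
#' Every boolean is accompanied by the numeric value that produced it, so
#' users can re-threshold without rerunning. A missing depth entry makes
#' that criterion unavailable: it scores 0 and a warning is logged.
#'
#' @param locus One locus row ([merge_adjacent_hits()]).
#' @param annotations Annotation `data.frame` ([annotation_record()]).
#' @param depth_table Named depth vector ([read_depth_table()]).
#' @param host_stats Host background, list with `depth_median` and `gc_mean`
#'   (see [host_background()]).
#' @param scaffolds Named list of [seq_record()]s.
#' @param config An [eve_config()].
#' @return A one-row `data.frame` of booleans plus supporting numbers
#'   (`stop_count`, `locus_depth`, `host_depth_median`, `scaffold_gc`,
#'   `host_gc_mean`, `scaffold_length`).
#' @export
extract_evidence <- function(locus, annotations, depth_table, host_stats,
                             scaffolds, config = eve_config()) {
  sid <- if (is.data.frame(locus)) locus$scaffold_id[1] else locus$scaffold_id
  scf <- scaffolds[[sid]]
  if (is.null(scf)) stop("scaffold metadata unavailable for ", sid)
  stop_count <- as.integer(detect_premature_stops(locus, scaffolds))
  sc_len <- seq_length(scf)
  sc_gc <- gc_content(scf)
  ann <- annotations[annotations$scaffold_id == sid, , drop = FALSE]
  has_gene <- any(ann$kind == "gene" & attr_flag(ann$attributes, "taxon", "insect"))
  has_te <- any(ann$kind == "transposable_element")
  depth <- unname(depth_table[sid])
  f <- config$depth_comparable_factor
  med <- host_stats$depth_median
  if (is.null(depth) || length(depth) == 0L || is.na(depth)) {
    warning("no depth entry for scaffold ", sid,
            "; depth criterion scored as unavailable (0 points)")
    depth <- NA_real_
    depth_ok <- FALSE
  } else {
    depth_ok <- !is.na(med) && depth >= med / f && depth <= med * f
  }
  gc_ok <- !is.na(host_stats$gc_mean) &&
    abs(sc_gc - host_stats$gc_mean) <= config$gc_similarity_delta
  data.frame(
    locus_id = if (is.data.frame(locus)) locus$locus_id[1] else
      sprintf("%s:%d-%d", sid, locus$start, locus$end),
    scaffold_id = sid,
    premature_stop = stop_count >= 1L,
    depth_comparable = depth_ok,
    eukaryotic_gene_on_scaffold = has_gene,
    te_on_scaffold = has_te,
    gc_similar = gc_ok,
    scaffold_exceeds_viral_size = sc_len > config$long_scaffold_bp,
    stop_count = stop_count,
    locus_depth = depth,
    host_depth_median = med,
    scaffold_gc = sc_gc,
    host_gc_mean = host_stats$gc_mean,
    scaffold_length = sc_len,
    stringsAsFactors = FALSE)
}

#' Host background statistics
#'
#' The comparison background for the depth and GC criteria: scaffolds that
#' carry at least one insect-assigned gene and no candidate locus are taken
#' as host scaffolds; their depth median and GC mean/sd form the background.
#'
#' @param scaffolds Named list of [seq_record()]s.
#' @param annotations Annotation `data.frame`.
#' @param depth_table Named depth vector.
#' @param loci Candidate locus table (may be empty).
#' @return List: `depth_median`, `gc_mean`, `gc_sd`, `scaffold_ids`.
#' @export
host_background <- function(scaffolds, annotations, depth_table, loci) {
  ids <- names(scaffolds)
  gene_ok <- vapply(ids, function(sid) {
    ann <- annotations[annotations$scaffold_id == sid, , drop = FALSE]
    any(ann$kind == "gene" & attr_flag(ann$attributes, "taxon", "insect"))
  }, TRUE)
  locus_free <- !ids %in% (if (nrow(loci)) loci$scaffold_id else character())
  host_ids <- ids[gene_ok & locus_free]
  if (!length(host_ids)) {
    warning("no background host scaffolds (insect gene present, locus absent)")
    return(list(depth_median = NA_real_, gc_mean = NA_real_, gc_sd = NA_real_,
                scaffold_ids = character()))
  }
  gcs <- vapply(host_ids, function(sid) gc_content(scaffolds[[sid]]), 0)
  depths <- depth_table[host_ids]
  list(depth_median = median(depths, na.rm = TRUE),
       gc_mean = mean(gcs), gc_sd = stats::sd(gcs),
       scaffold_ids = host_ids)
}

#' Score evidence and classify confidence
#'
#' `score_eve` sums the feature weights over the evidence booleans (premature
#' stops worth 2 points, the five scaffold features 1 point each, 0--7
#' total); `classify_score` maps points to the confidence class: high above
#' 4 points, medium at 3--4, low at 2 or below.
#'
#' @param evidence Evidence `data.frame` (one or more rows,
#'   [extract_evidence()] layout) or a named logical vector/list.
#' @param weights Named list of per-feature points (default from
#'   [eve_config()]).
#' @param config An [eve_config()] providing the class bounds.
#' @return `score_eve`: the evidence with `points` (integer) and `class`
#'   (`"low"`, `"medium"`, `"high"`) columns appended. `classify_score`: a
#'   character vector of classes.
#' @examples
#' ev <- c(premature_stop = TRUE, depth_comparable = FALSE,
#'         eukaryotic_gene_on_scaffold = FALSE, te_on_scaffold = FALSE,
#'         gc_similar = FALSE, scaffold_exceeds_viral_size = FALSE)
#' score_eve(ev)$points  # 2
#' classify_score(0:7)
#' @export
score_eve <- function(evidence, weights = NULL, config = eve_config()) {
  weights <- weights %||% config$score_weights
  feats <- c("premature_stop", "depth_comparable",
             "eukaryotic_gene_on_scaffold", "te_on_scaffold",
             "gc_similar", "scaffold_exceeds_viral_size")
  if (!is.data.frame(evidence))
    evidence <- as.data.frame(as.list(evidence), stringsAsFactors = FALSE)
  missing_f <- setdiff(feats, names(evidence))
  if (length(missing_f))
    stop("evidence lacks feature(s): ", paste(missing_f, collapse = ", "))
  w <- unlist(weights[feats])
  bools <- as.matrix(evidence[feats])
  storage.mode(bools) <- "integer"   # NA (unavailable) scores 0, conservatively
  bools[is.na(bools)] <- 0L
  evidence$points <- as.integer(bools %*% w)
  evidence$class <- classify_score(evidence$points, config)
  evidence
}

#' @rdname score_eve
#' @param points Integer vector of total points.
#' @export
classify_score <- function(points, config = eve_config()) {
  ifelse(points > config$class_high_gt, "high",
         ifelse(points >= config$class_medium_min, "medium", "low"))
}

#' Census of scored candidate loci
#'
#' Summarises a scored locus table: total candidate count, count per
#' confidence class, per-scaffold counts, and a presence/absence matrix of
#' viral genes (a gene is present for a species/assembly when at least one
#' locus with that `best_query` reaches `threshold_class`).
#'
#' @param scores Scored locus table: needs `class`, `best_query`,
#'   `scaffold_id` columns (join of loci and [score_eve()] output).
#' @param threshold_class Minimum class for presence (`"low"`, `"medium"`,
#'   `"high"`; default `"high"`).
#' @param scaffold_species Optional named character vector mapping scaffold
#'   ids to species; defaults to one pseudo-species per scaffold.
#' @return List: `n_candidates`, `by_class` (named integer vector),
#'   `per_scaffold`, and `presence` (logical species x gene matrix).
#' @export
census <- function(scores, threshold_class = "high", scaffold_species = NULL) {
  lv <- c("low", "medium", "high")
  stopifnot(threshold_class %in% lv)
  need <- setdiff(c("class", "best_query", "scaffold_id"), names(scores))
  if (length(need))
    stop("scored locus table lacks column(s): ", paste(need, collapse = ", "))
  if (!nrow(scores)) {
    return(list(n_candidates = 0L,
                by_class = setNames(integer(3), lv),
                per_scaffold = integer(),
                presence = matrix(logical(), 0, 0)))
  }
  by_class <- setNames(vapply(lv, function(cl) sum(scores$class == cl), 0L), lv)
  species <- if (is.null(scaffold_species)) scores$scaffold_id
             else unname(scaffold_species[scores$scaffold_id])
  ok <- match(scores$class, lv) >= match(threshold_class, lv)
  sp_lv <- sort(unique(species))
  gene_lv <- sort(unique(scores$best_query))
  presence <- matrix(FALSE, length(sp_lv), length(gene_lv),
                     dimnames = list(sp_lv, gene_lv))
  if (any(ok)) {
    idx <- cbind(match(species[ok], sp_lv), match(scores$best_query[ok], gene_lv))
    presence[idx] <- TRUE
  }
  list(n_candidates = nrow(scores),
       by_class = by_class,
       per_scaffold = table(scores$scaffold_id),
       presence = presence)
}
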