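#' Six-frame translation
#'
#' Frames `+1..+3` are the forward strand at offsets 0..2, `-1..-3` the
#' reverse complement likewise. Trailing partial codons are dropped, stop
#' codons render `*`, and codons containing N render `X`.
#'
#' @param seq A [seq_record()] or nucleotide string.
#' @return A named character vector of six peptides
#'   (`"+1","+2","+3","-1","-2","-3"`).
#' @examples
#' six_frame_translate("ATGAAATAA")[["+1"]]  # "MK*"
#' @export
six_frame_translate <- function(seq) {
  s <- seq_string(seq)
  rc <- revcomp(s)
  tr1 <- function(x, off) {
    n <- (nchar(x) - off) %/% 3L
    if (n <= 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substring(x, off + 1L, off + 3L * n)),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  c("+1" = tr1(s, 0L), "+2" = tr1(s, 1L), "+3" = tr1(s, 2L),
    "-1" = tr1(rc, 0L), "-2" = tr1(rc, 1L), "-3" = tr1(rc, 2L))
}

blosum62 <- function() {
  if (is.null(.evescreen_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .evescreen_env$blosum62 <- e$BLOSUM62
  }
  .evescreen_env$blosum62
}

encode_aa <- function(pep) {
  codes <- match(strsplit(pep, "", fixed = TRUE)[[1]], rownames(blosum62()))
  if (anyNA(codes))
    stop("illegal amino-acid symbol(s): ",
         paste(unique(strsplit(pep, "")[[1]][is.na(codes)]), collapse = ", "))
  codes
}

#' Translated homology search of proteins against nucleotide scaffolds
#'
#' A desk-scale TBLASTN-like screen: each query protein is compared against
#' all six reading frames of every scaffold by exact k-mer seeding (default
#' word size 4) followed by Smith-Waterman local alignment with BLOSUM62 and
#' affine gaps (open 11, extend 1) on the seeded region. Seeding requires two
#' seeds on the same diagonal neighbourhood, so the search is a heuristic in
#' the same sense BLAST is; alignments are exact within each seeded window.
#' E-values use the Karlin-Altschul form `E = K m n exp(-lambda S)` with
#' fixed published ungapped BLOSUM62 constants (lambda 0.3176, K 0.134),
#' where `m` is the query length in residues and `n` the scaffold length in
#' nucleotides; they are approximate and intended for ranking and for the
#' downstream e-value filter at matched scale. Results are sorted by e-value
#' and are deterministic given the inputs.
#'
#' @param queries Named character vector of protein sequences.
#' @param scaffolds Named list of [seq_record()]s (or named character vector).
#' @param config An [eve_config()]; fields `search_*` control word size, raw
#'   score floor, gap costs and the e-value constants.
#' @return A hit `data.frame` in the [read_tabular_hits()] layout plus
#'   `frame` and raw `score` columns.
#' @export
search_translated <- function(queries, scaffolds, config = eve_config()) {
  stopifnot(length(queries) >= 1, length(scaffolds) >= 1)
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    stop("queries must be named")
  if (inherits(scaffolds, "seq_record")) scaffolds <- list(scaffolds)
  if (is.character(scaffolds)) scaffolds <- as.list(scaffolds)
  sub_mat <- blosum62()
  k <- config$search_word_size
  qcodes <- lapply(queries, encode_aa)
  out <- list()
  for (si in seq_along(scaffolds)) {
    scf <- scaffolds[[si]]
    sid <- if (inherits(scf, "seq_record")) scf$id else
      (names(scaffolds)[si] %||% paste0("scaffold", si))
    L <- seq_length(scf)
    frames <- six_frame_translate(scf)
    fcodes <- lapply(frames, function(p)
      if (nzchar(p)) match(strsplit(p, "", fixed = TRUE)[[1]],
                           rownames(sub_mat)) else integer())
    for (fi in seq_along(frames)) {
      fc <- fcodes[[fi]]
      if (length(fc) < k) next
      fname <- names(frames)[fi]
      f_off <- abs(as.integer(fname))      # 1..3
      f_neg <- startsWith(fname, "-")
      for (qi in seq_along(queries)) {
        qc <- qcodes[[qi]]
        if (length(qc) < k) next
        seeds <- .kmer_seeds(qc, fc, k)
        if (!nrow(seeds)) next
        for (win in seed_windows(seeds, length(qc), length(fc))) {
          aln <- .sw_align(qc, fc[win[1]:win[2]], sub_mat,
                           config$search_gap_open, config$search_gap_extend)
          if (aln$score < config$search_min_raw_score) next
          for (seg in split_alignment(aln, config$search_x_drop)) {
            if (seg$score < config$search_min_raw_score) next
            sa <- seg$s_start + win[1] - 1L
            se <- seg$s_end + win[1] - 1L
            nt <- aa_to_nt_span(sa, se, f_off, f_neg, L)
            evalue <- config$search_K * length(qc) * L *
              exp(-config$search_lambda * seg$score)
            out[[length(out) + 1L]] <- data.frame(
              query_id = names(queries)[qi], scaffold_id = sid,
              identity = seg$n_ident / seg$aln_len,
              aln_length_aa = seg$aln_len,
              mismatches = seg$aln_len - seg$n_ident - seg$n_gap,
              gap_opens = NA_integer_,
              q_start = seg$q_start, q_end = seg$q_end,
              s_start = nt[1], s_end = nt[2],
              strand = if (f_neg) "-" else "+",
              frame = if (f_neg) -f_off else f_off,
              evalue = evalue,
              bitscore = (config$search_lambda * seg$score -
                            log(config$search_K)) / log(2),
              score = seg$score,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    h <- empty_hits(); h$score <- numeric(); return(h)
  }
  hits <- do.call(rbind, out)
  hits <- hits[!duplicated(hits[c("query_id", "scaffold_id", "frame",
                                  "s_start", "s_end")]), , drop = FALSE]
  hits <- hits[order(hits$evalue, hits$scaffold_id, hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  log_stage("scan", c(n_queries = length(queries),
                      n_scaffolds = length(scaffolds), n_hits = nrow(hits)))
  hits
}

# X-drop style alignment splitting: the optimal local alignment is cut at
# internal score dips deeper than x_drop (running max minus running sum),
# so unrelated segments bridged by a chance island are reported separately
# — the same role the X-drop plays in BLAST extension. Returns a list of
# segment summaries in window-local coordinates.
split_alignment <- function(aln, x_drop) {
  sc <- aln$col_score
  n <- length(sc)
  segs <- list()
  emit <- function(i0, bi) {
    if (bi < i0) return()
    idx <- i0:bi
    qn <- aln$col_q[idx]; sn <- aln$col_s[idx]
    segs[[length(segs) + 1L]] <<- list(
      score = sum(sc[idx]),
      q_start = min(qn[qn > 0]), q_end = max(qn[qn > 0]),
      s_start = min(sn[sn > 0]), s_end = max(sn[sn > 0]),
      n_ident = sum(aln$col_ident[idx]), aln_len = length(idx),
      n_gap = sum(qn == 0 | sn == 0))
  }
  i0 <- 1L; cum <- 0L; best <- 0L; bi <- 0L
  for (k in seq_len(n)) {
    cum <- cum + sc[k]
    if (cum > best) { best <- cum; bi <- k }
    if (cum < 0L) {                       # fell below the segment start
      if (best > 0L) emit(i0, bi)
      i0 <- k + 1L; cum <- 0L; best <- 0L; bi <- k
    } else if (best - cum > x_drop) {     # X-drop: close at the peak
      emit(i0, bi)
      i0 <- k + 1L; cum <- 0L; best <- 0L; bi <- k
    }
  }
  if (best > 0L) emit(i0, bi)
  segs
}

# cluster seeds into candidate subject windows (two-hit rule within a
# diagonal neighbourhood); returns list of c(window_start, window_end) in
# subject (frame peptide) coordinates
seed_windows <- function(seeds, qlen, slen, diag_tol = 5L, gap_tol = 200L) {
  d <- seeds[, 2] - seeds[, 1]
  o <- order(d, seeds[, 2])
  d <- d[o]; sp <- seeds[o, 2]; qp <- seeds[o, 1]
  grp <- cumsum(c(1L, (diff(d) > diag_tol) | (abs(diff(sp)) > gap_tol)))
  wins <- list()
  for (g in split(seq_along(grp), grp)) {
    if (length(g) < 2L) next
    s1 <- min(sp[g]); s2 <- max(sp[g])
    margin <- qlen + 10L
    wins[[length(wins) + 1L]] <- c(max(1L, s1 - margin),
                                   min(slen, s2 + margin))
  }
  # merge overlapping windows so SW runs once per region
  if (length(wins) <= 1L) return(wins)
  m <- do.call(rbind, wins)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- merged[[length(merged)]]
    if (m[i, 1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
    else merged[[length(merged) + 1L]] <- m[i, ]
  }
  merged
}

# aa positions (start <= end) in a frame -> forward-strand nt span
aa_to_nt_span <- function(aa_start, aa_end, f_off, f_neg, L) {
  p1 <- f_off + 3L * (aa_start - 1L)
  p2 <- f_off + 3L * aa_end - 1L
  if (!f_neg) return(c(p1, p2))
  c(L - p2 + 1L, L - p1 + 1L)
}

#' Filter hits on e-value and query coverage
#'
#' Keeps a hit iff its e-value is strictly below `max_evalue` and its query
#' coverage `(q_end - q_start + 1) / query length` strictly above
#' `min_query_coverage` (both bounds are exclusive, matching "smaller than
#' 1e-5" and "more than 20%"). Input order is preserved; input and survivor
#' counts are logged and attached as attributes `n_input` / `n_kept`.
#'
#' @param hits Hit `data.frame` ([read_tabular_hits()] layout).
#' @param query_lengths Named vector of query protein lengths (aa).
#' @param max_evalue,min_query_coverage Thresholds (defaults `1e-5`, `0.20`).
#' @return The surviving rows, with a `coverage` column added.
#' @export
filter_hits <- function(hits, query_lengths, max_evalue = 1e-5,
                        min_query_coverage = 0.20) {
  unknown <- setdiff(unique(hits$query_id), names(query_lengths))
  if (length(unknown))
    stop("hit references unknown query id(s): ",
         paste(unknown, collapse = ", "))
  if (!nrow(hits)) {
    out <- hits; out$coverage <- numeric()
  } else {
    cov <- (hits$q_end - hits$q_start + 1) /
      as.numeric(query_lengths[hits$query_id])
    keep <- hits$evalue < max_evalue & cov > min_query_coverage
    out <- hits[keep, , drop = FALSE]
    out$coverage <- cov[keep]
    rownames(out) <- NULL
  }
  attr(out, "n_input") <- nrow(hits)
  attr(out, "n_kept") <- nrow(out)
  log_stage("filter", c(n_input = nrow(hits), n_kept = nrow(out),
                        max_evalue = max_evalue,
                        min_query_coverage = min_query_coverage))
  out
}

#' Merge adjacent hits into candidate EVE loci
#'
#' Per scaffold, hits sorted by subject start are merged transitively
#' whenever the next hit starts within `max_gap_bp` of the current merged
#' end (`next s_start - current end <= max_gap_bp`; overlapping hits always
#' merge). Hits from different query proteins and strands merge by default —
#' a single degraded viral gene often fragments across frames and queries —
#' unless `same_query_only`. The partition is independent of input order.
#'
#' @param hits Hit `data.frame`.
#' @param max_gap_bp Maximum merge gap in bp (default 10).
#' @param same_query_only Restrict merging to hits of the same query.
#' @return A locus `data.frame`: `locus_id`, `scaffold_id`, `start`, `end`,
#'   `n_hits`, `best_query`, `best_evalue`, `strand` (of the best hit), and a
#'   list-column `members` holding each locus's member hits sorted by
#'   `s_start`.
#' @export
merge_adjacent_hits <- function(hits, max_gap_bp = 10L,
                                same_query_only = FALSE) {
  if (!nrow(hits)) {
    out <- data.frame(locus_id = character(), scaffold_id = character(),
                      start = integer(), end = integer(), n_hits = integer(),
                      best_query = character(), best_evalue = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  key <- if (same_query_only) paste(hits$scaffold_id, hits$query_id, sep = "\r")
         else hits$scaffold_id
  loci <- list()
  for (grp in split(seq_len(nrow(hits)), key)) {
    h <- hits[grp, , drop = FALSE]
    h <- h[order(h$s_start, h$s_end, h$query_id), , drop = FALSE]
    cur_end <- h$s_end[1]
    cluster <- cumsum(c(1L, rep(0L, nrow(h) - 1L)))
    cid <- 1L
    for (i in seq_len(nrow(h))[-1]) {
      if (h$s_start[i] - cur_end > max_gap_bp) { cid <- cid + 1L; cur_end <- h$s_end[i] }
      else cur_end <- max(cur_end, h$s_end[i])
      cluster[i] <- cid
    }
    for (cl in split(seq_len(nrow(h)), cluster)) {
      m <- h[cl, , drop = FALSE]
      best <- which.min(m$evalue)
      loci[[length(loci) + 1L]] <- list(
        scaffold_id = m$scaffold_id[1],
        start = min(m$s_start), end = max(m$s_end),
        n_hits = nrow(m), best_query = m$query_id[best],
        best_evalue = m$evalue[best], strand = m$strand[best],
        members = m)
    }
  }
  out <- data.frame(
    locus_id = vapply(loci, function(x)
      sprintf("%s:%d-%d", x$scaffold_id, x$start, x$end), ""),
    scaffold_id = vapply(loci, `[[`, "", "scaffold_id"),
    start = vapply(loci, `[[`, 0, "start"),
    end = vapply(loci, `[[`, 0, "end"),
    n_hits = vapply(loci, `[[`, 0, "n_hits"),
    best_query = vapply(loci, `[[`, "", "best_query"),
    best_evalue = vapply(loci, `[[`, 0, "best_evalue"),
    strand = vapply(loci, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  out$members <- lapply(loci, `[[`, "members")
  o <- order(out$scaffold_id, out$start, out$end)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  log_stage("merge", c(n_hits = nrow(hits), n_loci = nrow(out),
                       max_gap_bp = max_gap_bp))
  out
}
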