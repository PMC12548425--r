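# Independent brute-force oracles. Each recomputes a quantity by a different
# route than the implementation (enumeration, exhaustive scan, graph search)
# so agreement is evidence, not tautology.

rc_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# every ATG in every frame on both strands, extended to the first in-frame
# stop; longest-ORF-per-stop rule applied afterwards
orf_oracle <- function(s, min_len) {
  gc_tab <- Biostrings::GENETIC_CODE
  stops3 <- c("TAA", "TAG", "TGA")
  scan_one <- function(x, strand) {
    L <- nchar(x)
    out <- list()
    for (a in seq_len(L - 2L)) {
      if (substring(x, a, a + 2L) != "ATG") next
      b <- a + 3L
      found <- NA
      while (b + 2L <= L) {
        if (substring(x, b, b + 2L) %in% stops3) { found <- b + 2L; break }
        b <- b + 3L
      }
      if (is.na(found)) next
      len <- found - a + 1L
      if (len < min_len) next
      out[[length(out) + 1L]] <- c(a, found)
    }
    if (!length(out)) return(NULL)
    m <- unique(do.call(rbind, out))
    # longest per stop: keep smallest start per (end)
    keep <- !duplicated(m[, 2])
    m <- m[order(m[, 2], m[, 1]), , drop = FALSE]
    m <- m[!duplicated(m[, 2]), , drop = FALSE]
    data.frame(start = m[, 1], end = m[, 2], strand = strand)
  }
  fwd <- scan_one(s, "+")
  L <- nchar(s)
  rev_ <- scan_one(rc_str(s), "-")
  if (!is.null(rev_)) {
    tmp <- L - rev_$end + 1L
    rev_$end <- L - rev_$start + 1L
    rev_$start <- tmp
  }
  out <- rbind(fwd, rev_)
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  out[order(out$start, out$end, out$strand), ]
}

# transitive closure of the "within gap" relation via union-find
merge_oracle <- function(starts, ends, gap) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- max(starts[i], starts[j]) - min(ends[i], ends[j])
    if (d <= gap) union_(i, j)   # overlap gives negative d
  }
  comp <- vapply(seq_len(n), find, 0L)
  split(seq_len(n), comp)
}

# consensus score of a putative tandem array, written independently:
# per unit position the majority base contributes matches, the rest
# mismatches, so score = 2 * sum(max counts) - total positions
tandem_rescore <- function(s, start, end, unit) {
  arr <- strsplit(substring(s, start, end), "")[[1]]
  copies <- length(arr) %/% unit
  arr <- arr[seq_len(copies * unit)]
  mat <- matrix(match(arr, c("A", "C", "G", "T")), nrow = unit)
  maxc <- vapply(seq_len(unit), function(r) max(tabulate(mat[r, ], 4L)), 0L)
  2L * sum(maxc) - copies * unit
}

# exhaustive tandem scan: every unit length and start, greedy longest array
# of exact period matches (bridging single substitutions), scored vs
# consensus; returns best non-overlapping arrays
tandem_oracle <- function(s, min_score, min_unit, max_unit) {
  L <- nchar(s)
  found <- list()
  for (u in min_unit:min(max_unit, L %/% 2)) {
    for (a in seq_len(L - 2 * u + 1L)) {
      copies <- 2L
      while (a + (copies + 1L) * u - 1L <= L) {
        sc_more <- tandem_rescore(s, a, a + (copies + 1L) * u - 1L, u)
        sc_now <- tandem_rescore(s, a, a + copies * u - 1L, u)
        if (sc_more <= sc_now) break
        copies <- copies + 1L
      }
      sc <- tandem_rescore(s, a, a + copies * u - 1L, u)
      if (sc >= min_score)
        found[[length(found) + 1L]] <- data.frame(
          start = a, end = a + copies * u - 1L, unit = u, score = sc)
    }
  }
  if (!length(found)) return(data.frame(start = integer(), end = integer(),
                                        unit = integer(), score = integer()))
  f <- do.call(rbind, found)
  f <- f[order(-f$score, f$unit, f$start), ]
  used <- logical(L); keep <- logical(nrow(f))
  for (i in seq_len(nrow(f))) {
    idx <- f$start[i]:f$end[i]
    if (!any(used[idx])) { keep[i] <- TRUE; used[idx] <- TRUE }
  }
  out <- f[keep, ]
  out[order(out$start), ]
}

# exhaustive inverted-repeat scan along every diagonal of S vs revcomp(S)
ir_oracle <- function(s, min_len, min_ident) {
  L <- nchar(s)
  chS <- strsplit(s, "")[[1]]
  chR <- strsplit(rc_str(s), "")[[1]]
  out <- list()
  for (d in (-(L - min_len)):(L - min_len)) {
    a_lo <- max(1L, 1L + d); a_hi <- min(L, L + d)
    if (a_hi - a_lo + 1L < min_len) next
    av <- a_lo:a_hi
    m <- chS[av] == chR[av - d]
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      a1 <- av[starts[k]]; a2 <- av[ends[k]]
      b1 <- a1 - d; b2 <- a2 - d
      s2 <- L - b2 + 1L; e2 <- L - b1 + 1L
      arm1 <- c(a1, a2); arm2 <- c(s2, e2)
      if (arm1[1] > arm2[1]) { t_ <- arm1; arm1 <- arm2; arm2 <- t_ }
      if (arm1[2] >= arm2[1]) next
      out[[length(out) + 1L]] <- data.frame(start1 = arm1[1], end1 = arm1[2],
                                            start2 = arm2[1], end2 = arm2[2])
    }
  }
  if (!length(out)) return(data.frame(start1 = integer(), end1 = integer(),
                                      start2 = integer(), end2 = integer()))
  unique(do.call(rbind, out))
}

# patristic distances as shortest paths on the weighted tree graph
patristic_oracle <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length  # edge order preserved
  n <- length(tree$tip.label)
  idx <- match(as.character(seq_len(n)), igraph::V(g)$name)
  d <- igraph::distances(g, v = idx, to = idx, algorithm = "dijkstra")
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# brute-force reciprocal best hits
rbh_oracle <- function(ab, ba) {
  top <- function(h) {
    ev <- if (is.null(h$evalue)) rep(0, nrow(h)) else h$evalue
    h$subject_id[order(-h$bitscore, ev, h$subject_id)][1]
  }
  pairs <- list()
  for (a in unique(ab$query_id)) {
    b <- top(ab[ab$query_id == a, ])
    hb <- ba[ba$query_id == b, ]
    if (!nrow(hb)) next
    if (top(hb) == a) pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (!length(pairs)) return(data.frame(a_id = character(), b_id = character()))
  m <- do.call(rbind, pairs)
  out <- data.frame(a_id = m[, 1], b_id = m[, 2], stringsAsFactors = FALSE)
  out[order(out$a_id), ]
}

# random tree with branch lengths
random_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves)
  tr$edge.length <- round(tr$edge.length, 4) + 0.01
  tr
}

make_hits <- function(...) {
  # build a hit data.frame from vectors, filling defaults
  df <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(identity = 1, aln_length_aa = 50L, mismatches = 0L,
                   gap_opens = 0L, q_start = 1L, q_end = 50L,
                   s_start = 1L, s_end = 150L, strand = "+",
                   frame = 1L, evalue = 1e-20, bitscore = 100)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df
}
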