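#' Find tandem direct repeat arrays
#'
#' An etandem-style consensus scorer: for each candidate unit length, maximal
#' arrays of two or more adjacent unit copies are located via period-u
#' self-agreement, each array's consensus unit is formed by per-column
#' majority over its copies, and the array score is
#' (positions matching the consensus) - (positions mismatching). Arrays
#' scoring at or above `min_score` are reported; overlapping reports at
#' different unit lengths collapse to the highest-scoring one (ties prefer
#' the shorter unit, then the leftmost array). Trailing partial copies are
#' not counted.
#'
#' @param seq A [seq_record()] or nucleotide string.
#' @param min_score Consensus score cutoff (default 100, the published
#'   cutoff).
#' @param min_unit,max_unit Unit length range searched; requires
#'   `2 <= min_unit <= max_unit <= length/2`.
#' @param bridge Maximum run of period-u disagreements bridged inside one
#'   array (tolerates isolated substitutions; default 3).
#' @return A `data.frame`: `kind` ("tandem_direct"), `start`, `end`,
#'   `unit_length`, `copies`, `score`, `consensus`.
#' @export
find_tandem_repeats <- function(seq, min_score = 100L, min_unit = 10L,
                                max_unit = 100L, bridge = 3L) {
  s <- seq_string(seq)
  L <- nchar(s)
  stopifnot(min_unit >= 2, min_unit <= max_unit)
  max_unit <- min(max_unit, L %/% 2L)
  if (max_unit < min_unit) return(empty_repeats())
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  cand <- list()
  for (u in min_unit:max_unit) {
    m <- ch[seq_len(L - u)] == ch[(u + 1L):L]
    for (run0 in bridged_runs(m, bridge)) {
      # trim to the maximal-scoring stretch of period-u agreement so chance
      # flank matches do not drag the array boundary outward
      run <- max_score_segment(m, run0[1], run0[2])
      a <- run[1]
      span <- run[2] - a + 1L + u          # array region length
      copies <- span %/% u
      if (copies < 2L) next
      arr <- ch[a:(a + copies * u - 1L)]
      cols <- matrix(arr, nrow = u)       # u positions x copies
      cons <- apply(cols, 1L, majority_char)
      matches <- sum(cols == cons)
      score <- 2L * matches - copies * u
      if (score < min_score) next
      cand[[length(cand) + 1L]] <- data.frame(
        kind = "tandem_direct", start = a, end = a + copies * u - 1L,
        unit_length = u, copies = copies, score = score,
        consensus = paste(cons, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty_repeats())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$unit_length, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  used <- logical(L)
  for (i in seq_len(nrow(cand))) {
    idx <- cand$start[i]:cand$end[i]
    if (!any(used[idx])) { keep[i] <- TRUE; used[idx] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_repeats <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             unit_length = integer(), copies = integer(), score = integer(),
             consensus = character(), stringsAsFactors = FALSE)
}

majority_char <- function(x) {
  t <- table(x)
  names(t)[which.max(t)]   # deterministic: table() orders names, first max
}

# maximal runs of TRUE, merging across FALSE runs of length <= bridge;
# returns list of c(start, end) with TRUE endpoints
bridged_runs <- function(m, bridge) {
  r <- rle(m)
  n <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_idx <- which(r$values)
  if (!length(true_idx)) return(list())
  runs <- list()
  i <- 1L
  while (i <= length(true_idx)) {
    j <- i
    while (j < length(true_idx) &&
           (starts[true_idx[j + 1L]] - ends[true_idx[j]] - 1L) <= bridge)
      j <- j + 1L
    runs[[length(runs) + 1L]] <- c(starts[true_idx[i]], ends[true_idx[j]])
    i <- j + 1L
  }
  runs
}

#' Find inverted repeat pairs
#'
#' Seed-and-extend comparison of the sequence against its own reverse
#' complement. Exact `seed_k`-mer matches seed ungapped extensions along each
#' diagonal; maximal well-matching segments (disagreement runs up to `bridge`
#' are bridged, segment ends trimmed to matching positions) become candidate
#' arm pairs. Pairs are kept when both arms are at least `min_length` long,
#' arm identity (matches / arm length) is at least `min_identity`, and the
#' arms do not overlap. Reported pairs are selected greedily by descending
#' identity x length with each genome position used at most once, so discrete
#' non-overlapping ir pairs are returned.
#'
#' @param seq A [seq_record()] or nucleotide string.
#' @param min_length Minimum arm length in bp (>= 20).
#' @param min_identity Minimum arm identity in `[0, 1]`.
#' @param seed_k Seed word size (default 12).
#' @param bridge Maximum bridged mismatch run during extension (default 5).
#' @return A `data.frame`: `kind` ("inverted"), `start1`, `end1`, `start2`,
#'   `end2` (arm coordinates, arm 1 upstream), `length`, `identity`.
#' @export
find_inverted_repeats <- function(seq, min_length = 100L, min_identity = 0.90,
                                  seed_k = 12L, bridge = 5L) {
  stopifnot(min_length >= 20)
  s <- seq_string(seq)
  L <- nchar(s)
  if (L < 2L * min_length) return(empty_ir())
  r <- revcomp(s)
  chS <- strsplit(s, "", fixed = TRUE)[[1]]
  chR <- strsplit(r, "", fixed = TRUE)[[1]]
  kS <- substring(s, seq_len(L - seed_k + 1L), seed_k:L)
  kR <- substring(r, seq_len(L - seed_k + 1L), seed_k:L)
  rmap <- split(seq_along(kR), kR)
  hitlist <- rmap[kS]
  a_pos <- rep(seq_along(kS), lengths(hitlist))
  b_pos <- unlist(hitlist, use.names = FALSE)
  if (!length(a_pos)) return(empty_ir())
  diags <- unique(a_pos - b_pos)
  cand <- list()
  for (d in diags) {
    a_lo <- max(1L, 1L + d); a_hi <- min(L, L + d)
    if (a_hi - a_lo + 1L < min_length) next
    av <- a_lo:a_hi
    m <- chS[av] == chR[av - d]
    for (run0 in bridged_runs(m, bridge)) {
      # trim to the maximal-scoring subsegment (match +1 / mismatch -1)
      run <- max_score_segment(m, run0[1], run0[2])
      len <- run[2] - run[1] + 1L
      if (len < min_length) next
      a1 <- av[run[1]]; a2 <- av[run[2]]
      ident <- mean(m[run[1]:run[2]])
      if (ident < min_identity) next
      b1 <- a1 - d; b2 <- a2 - d
      # arm2 in forward coordinates (revcomp position mapping)
      s2 <- L - b2 + 1L; e2 <- L - b1 + 1L
      arm1 <- c(a1, a2); arm2 <- c(s2, e2)
      if (arm1[1] > arm2[1]) { tmp <- arm1; arm1 <- arm2; arm2 <- tmp }
      if (arm1[2] >= arm2[1]) next   # overlapping arms (palindrome centre)
      cand[[length(cand) + 1L]] <- data.frame(
        kind = "inverted", start1 = arm1[1], end1 = arm1[2],
        start2 = arm2[1], end2 = arm2[2], length = len,
        identity = ident, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty_ir())
  cand <- unique(do.call(rbind, cand))
  cand <- cand[order(-(cand$identity * cand$length), cand$start1), , drop = FALSE]
  used <- logical(L)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    idx <- c(cand$start1[i]:cand$end1[i], cand$start2[i]:cand$end2[i])
    if (!any(used[idx])) { keep[i] <- TRUE; used[idx] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal-scoring contiguous subsegment of a +1/-1 coded logical vector
# (Kadane); ties resolve to the shortest, then leftmost segment
max_score_segment <- function(m, from, to) {
  x <- ifelse(m[from:to], 1L, -1L)
  best <- -Inf; best_i <- 1L; best_j <- 1L
  cur <- 0L; cur_i <- 1L
  for (j in seq_along(x)) {
    if (cur <= 0L) { cur <- 0L; cur_i <- j }
    cur <- cur + x[j]
    if (cur > best || (cur == best && (j - cur_i) < (best_j - best_i))) {
      best <- cur; best_i <- cur_i; best_j <- j
    }
  }
  c(from + best_i - 1L, from + best_j - 1L)
}

empty_ir <- function() {
  data.frame(kind = character(), start1 = integer(), end1 = integer(),
             start2 = integer(), end2 = integer(), length = integer(),
             identity = numeric(), stringsAsFactors = FALSE)
}
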