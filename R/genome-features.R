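#' GC content, ignoring Ns
#'
#' Fraction (G+C)/(A+C+G+T); N positions count toward sequence length but are
#' excluded from both numerator and denominator. With `window` set, a
#' per-window track tiling the sequence is returned as well (the final window
#' may be short).
#'
#' @param seq A [seq_record()] or nucleotide string.
#' @param window Optional window size in bp for a positional track.
#' @return The GC fraction, or (with `window`) a list with `gc` and a
#'   `data.frame` `track` (`start`, `end`, `gc`; windows of only Ns get `NA`).
#' @examples
#' gc_content("GGCC")    # 1
#' gc_content("ATATAT")  # 0
#' @export
gc_content <- function(seq, window = NULL) {
  s <- seq_string(seq)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  is_gc <- ch == "G" | ch == "C"
  is_at <- ch == "A" | ch == "T"
  denom <- sum(is_gc) + sum(is_at)
  if (denom == 0L)
    stop("GC content undefined: sequence '", seq_id(seq), "' contains only Ns")
  gc <- sum(is_gc) / denom
  if (is.null(window)) return(gc)
  stopifnot(window >= 1)
  starts <- seq(1L, length(ch), by = as.integer(window))
  ends <- pmin(starts + as.integer(window) - 1L, length(ch))
  cg <- cumsum(is_gc); ca <- cumsum(is_at)
  wgc <- cg[ends] - c(0, cg)[starts]
  wat <- ca[ends] - c(0, ca)[starts]
  list(gc = gc,
       track = data.frame(start = starts, end = ends,
                          gc = ifelse(wgc + wat == 0, NA_real_,
                                      wgc / (wgc + wat))))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon vector of a string for a 0-based frame offset; drops trailing partials
codons_of <- function(s, offset = 0L) {
  L <- nchar(s)
  n <- (L - offset) %/% 3L
  if (n <= 0L) return(character())
  starts <- offset + 1L + 3L * (seq_len(n) - 1L)
  substring(s, starts, starts + 2L)
}

#' Predict open reading frames
#'
#' Scans all six reading frames on both strands for ATG-initiated ORFs under
#' the standard genetic code (TAA/TAG/TGA stops). Each reported ORF is the
#' maximal ATG-to-stop span in its frame (the longest-ORF-per-stop rule:
#' internal ATGs of a longer same-frame ORF are not reported separately). On
#' circular sequences frames continue across the origin and ORFs may wrap,
#' flagged by `wraps_origin`; wrapped coordinates keep `start` within the
#' sequence and `end` re-enters from position 1 (`end < start`).
#'
#' @param seq A [seq_record()] (topology respected) or nucleotide string
#'   (treated as linear).
#' @param min_length_nt Minimum ORF length in nt, stop codon included; must
#'   be >= 6 and divisible by 3.
#' @param require_stop When `FALSE`, ATG-initiated runs truncated by the end
#'   of a linear sequence are also reported, with `has_stop = FALSE`.
#' @return A `data.frame`: `scaffold_id`, `start`, `end`, `strand`, `frame`,
#'   `length_nt`, `length_aa` (= nt/3 - 1 when a stop is present),
#'   `wraps_origin`, `has_stop`, ordered by `start`.
#' @examples
#' find_orfs("ATGAAATAA", min_length_nt = 9)
#' @export
find_orfs <- function(seq, min_length_nt = 150L, require_stop = TRUE) {
  stopifnot(min_length_nt >= 6, min_length_nt %% 3 == 0)
  s <- seq_string(seq)
  L <- nchar(s)
  circular <- seq_topology(seq) == "circular"
  scan_s <- if (circular) paste0(s, s) else s
  allow_trunc <- !require_stop && !circular
  fwd <- orf_scan_linear(scan_s, min_length_nt, allow_trunc)
  rc <- revcomp(scan_s)
  rev_ <- orf_scan_linear(rc, min_length_nt, allow_trunc)
  # map minus-strand coordinates back onto the forward sequence
  if (nrow(rev_)) {
    Ls <- nchar(scan_s)
    new_start <- Ls - rev_$end + 1L
    new_end <- Ls - rev_$start + 1L
    rev_$start <- new_start; rev_$end <- new_end
    rev_$strand <- "-"
    rev_$frame <- -rev_$frame
  }
  orfs <- rbind(fwd, rev_)
  if (circular && nrow(orfs)) {
    orfs <- orfs[orfs$start <= L & orfs$length_nt <= L, , drop = FALSE]
    orfs$wraps_origin <- orfs$end > L
    orfs$end <- ifelse(orfs$wraps_origin, orfs$end - L, orfs$end)
    # frame label relative to the (doubled) scan is kept modulo 3 of position
    orfs <- orfs[!duplicated(orfs[c("start", "end", "strand")]), , drop = FALSE]
  } else if (nrow(orfs)) {
    orfs$wraps_origin <- FALSE
  } else {
    orfs$wraps_origin <- logical()
  }
  orfs$scaffold_id <- rep(seq_id(seq), nrow(orfs))
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs[c("scaffold_id", "start", "end", "strand", "frame", "length_nt",
         "length_aa", "wraps_origin", "has_stop")]
}

# plus-strand linear scan over frames 1..3 of string s
orf_scan_linear <- function(s, min_length_nt, allow_trunc) {
  out <- list()
  for (off in 0:2) {
    cod <- codons_of(s, off)
    if (!length(cod)) next
    stops <- which(cod %in% STOP_CODONS)
    atgs <- cod == "ATG"
    segs <- cbind(start = c(1L, stops + 1L),
                  stop = c(stops, NA_integer_))
    for (k in seq_len(nrow(segs))) {
      a <- segs[k, "start"]; b <- segs[k, "stop"]
      open_end <- is.na(b)
      last <- if (open_end) length(cod) else b
      if (a > last) next
      if (open_end && !allow_trunc) next
      hit <- which(atgs[a:last])
      if (!length(hit)) next
      first_atg <- a + hit[1] - 1L
      ncod <- last - first_atg + 1L
      len_nt <- 3L * ncod
      if (len_nt < min_length_nt) next
      out[[length(out) + 1L]] <- data.frame(
        start = off + 1L + 3L * (first_atg - 1L),
        end = off + 3L * last,
        strand = "+", frame = off + 1L,
        length_nt = len_nt,
        length_aa = if (open_end) ncod else ncod - 1L,
        has_stop = !open_end,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length_nt = integer(), length_aa = integer(),
                      has_stop = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Coding density
#'
#' Ratio of ORF bases to genome bases, as a percentage. `sum` mode (default)
#' is the literal "base number of all ORFs over base number of the genome":
#' overlapping ORFs are double-counted. `union` mode counts each covered
#' position once. `union <= sum`, with equality iff no ORFs overlap.
#'
#' @param orfs ORF table from [find_orfs()] (columns `start`, `end`,
#'   `length_nt`, `wraps_origin`).
#' @param genome_length_nt Genome length in nt.
#' @param mode `"sum"` or `"union"`.
#' @return Percentage in `[0, 100]` (`sum` mode can exceed 100 with heavy
#'   overlap).
#' @export
coding_density <- function(orfs, genome_length_nt, mode = c("sum", "union")) {
  mode <- match.arg(mode)
  if (genome_length_nt <= 0) stop("genome length must be positive")
  if (!nrow(orfs)) return(0)
  if (any(orfs$length_nt > genome_length_nt))
    stop("ORF longer than the genome")
  if (mode == "sum") return(100 * sum(orfs$length_nt) / genome_length_nt)
  ranges <- list()
  for (i in seq_len(nrow(orfs))) {
    if (isTRUE(orfs$wraps_origin[i])) {
      ranges[[length(ranges) + 1L]] <- c(orfs$start[i], genome_length_nt)
      ranges[[length(ranges) + 1L]] <- c(1L, orfs$end[i])
    } else {
      ranges[[length(ranges) + 1L]] <- c(orfs$start[i], orfs$end[i])
    }
  }
  m <- do.call(rbind, ranges)
  ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1], end = m[, 2]))
  100 * sum(IRanges::width(ir)) / genome_length_nt
}
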