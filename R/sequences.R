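#' Sequence records
#'
#' A `seq_record` is the basic substrate of the pipeline: a named nucleotide
#' sequence over the alphabet A, C, G, T, N together with a topology flag
#' (`"linear"` or `"circular"`). Large dsDNA viral genomes of the
#' *Naldaviricetes* are circular; host scaffolds are linear.
#'
#' @param id Non-empty sequence identifier.
#' @param seq Nucleotide string; lower case is normalised to upper case.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return An object of class `seq_record` with elements `id`, `seq`,
#'   `topology`.
#' @examples
#' r <- seq_record("chr1", "acgtACGT")
#' r$seq           # "ACGTACGT"
#' seq_length(r)   # 8
#' @export
seq_record <- function(id, seq, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a non-empty string")
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence '", id, "' is empty")
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop("sequence '", id, "' contains illegal symbols: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  structure(list(id = id, seq = seq, topology = topology),
            class = "seq_record")
}

#' @rdname seq_record
#' @param x A `seq_record` or plain character string.
#' @export
seq_length <- function(x) nchar(seq_string(x))

# accept either a seq_record or a bare string everywhere internally
seq_string <- function(x) {
  if (inherits(x, "seq_record")) x$seq
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a seq_record or a single character string")
}

seq_topology <- function(x) {
  if (inherits(x, "seq_record")) x$topology else "linear"
}

seq_id <- function(x) {
  if (inherits(x, "seq_record")) x$id else "seq"
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %d nt (%s)\n", x$id, nchar(x$seq), x$topology))
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' @param x A `seq_record` or nucleotide string.
#' @return A character string (the reverse complement; N stays N).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_string(x))))
}

#' Annotation records
#'
#' Builds the flat annotation table used as scoring evidence: genes and
#' transposable elements on host scaffolds, plus ORF/repeat/EVE features
#' emitted by the pipeline. Coordinates are 1-based inclusive, matching GFF3.
#'
#' @param scaffold_id,start,end,strand,kind,attributes Vectors, recycled to a
#'   common length. `kind` must be one of `gene`, `transposable_element`,
#'   `orf`, `repeat`, `eve`; `strand` one of `+`, `-`, `.`; `attributes` is a
#'   `key=value;key=value` string (e.g. `taxon=insect` on host genes).
#' @return A `data.frame` with one row per annotation.
#' @export
annotation_record <- function(scaffold_id, start, end, strand = ".",
                              kind = "gene", attributes = "") {
  kinds <- c("gene", "transposable_element", "orf", "repeat", "eve")
  df <- data.frame(scaffold_id = as.character(scaffold_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), kind = as.character(kind),
                   attributes = as.character(attributes),
                   stringsAsFactors = FALSE)
  if (any(!df$kind %in% kinds))
    stop("annotation kind must be one of: ", paste(kinds, collapse = ", "))
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("annotation strand must be '+', '-' or '.'")
  if (any(df$start < 1L) || any(df$end < df$start))
    stop("annotation coordinates must satisfy 1 <= start <= end")
  df
}

# does an attributes string carry key (optionally = value)?
attr_flag <- function(attributes, key, value = NULL) {
  pat <- if (is.null(value)) paste0("(^|;)\\s*", key, "($|;|=)")
         else paste0("(^|;)\\s*", key, "=", value, "($|;)")
  grepl(pat, attributes)
}
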