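#' Read a FASTA file into sequence records
#'
#' A light validation pass over the raw lines reports malformed headers,
#' empty sequences and duplicate identifiers with their line numbers; parsing
#' itself is done by [Biostrings::readDNAStringSet()] (or
#' [Biostrings::readAAStringSet()] for `alphabet = "AA"`). Record order is
#' preserved and nucleotide sequences are normalised to upper case.
#'
#' @param path FASTA file path.
#' @param topology Topology assigned to every record (`"linear"` default), or
#'   a character vector of ids in `circular_ids` to mark circular.
#' @param circular_ids Optional ids to flag as circular.
#' @param alphabet `"DNA"` (default) or `"AA"`; amino-acid sets are returned
#'   as a plain named character vector.
#' @return A named list of [seq_record()] objects (names = ids), or a named
#'   character vector for `alphabet = "AA"`.
#' @export
read_fasta <- function(path, topology = "linear", circular_ids = NULL,
                       alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("FASTA parse error at line 1: no '>' header found")
  pre <- which(nzchar(trimws(lines)) & seq_along(lines) < hdr[1])
  if (length(pre))
    stop("FASTA parse error at line ", pre[1], ": sequence before first header")
  ids <- sub("^>\\s*(\\S*).*$", "\\1", lines[hdr])
  empty_id <- which(!nzchar(ids))
  if (length(empty_id))
    stop("FASTA parse error at line ", hdr[empty_id[1]], ": empty header")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("FASTA parse error: duplicate sequence id(s): ",
         paste(unique(dup), collapse = ", "))
  ends <- c(hdr[-1] - 1L, length(lines))
  rec_seq <- vapply(seq_along(hdr), function(i) {
    if (ends[i] < hdr[i] + 1L) return("")
    gsub("\\s", "", paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""))
  }, "")
  bad <- which(!nzchar(rec_seq))
  if (length(bad))
    stop("FASTA parse error at line ", hdr[bad[1]],
         ": record '", ids[bad[1]], "' has an empty sequence")
  if (alphabet == "AA") {
    ss <- Biostrings::readAAStringSet(path)
    out <- toupper(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i) {
    id <- names(ss)[i]
    topo <- if (id %in% circular_ids) "circular" else topology
    seq_record(id, as.character(ss[[i]]), topo)
  })
  names(out) <- names(ss)
  out
}

#' Write sequence records to FASTA
#'
#' @param seqs A named list of [seq_record()]s or a named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(seqs, "seq_record")) seqs <- list(seqs)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    id <- if (inherits(s, "seq_record")) s$id else names(seqs)[i]
    sq <- seq_string(s)
    writeLines(paste0(">", id), con)
    writeLines(substring(sq, seq(1, nchar(sq), width),
                         pmin(seq(1, nchar(sq), width) + width - 1L, nchar(sq))),
               con)
  }
  invisible(path)
}

#' Read translated-homology hits in 12-column BLAST tabular format
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, evalue, bitscore. Subject
#' coordinates are normalised so that `s_start <= s_end` with the strand
#' recorded as `-` when the input had `sstart > send` (the TBLASTN convention
#' for minus-frame hits).
#'
#' @param path Tab- or whitespace-separated hit file.
#' @return A `data.frame` of hits with columns `query_id`, `scaffold_id`,
#'   `identity` (fraction), `aln_length_aa`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `strand`, `frame` (NA when not
#'   derivable), `evalue`, `bitscore`.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("hit file parse error at row ", which(nf != 12L)[1],
         ": expected 12 columns, found ", nf[which(nf != 12L)[1]])
  m <- do.call(rbind, fields)
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  minus <- sstart > send
  hits <- data.frame(
    query_id = m[, 1], scaffold_id = m[, 2],
    identity = as.numeric(m[, 3]) / 100,
    aln_length_aa = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = ifelse(minus, send, sstart),
    s_end = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    frame = NA_integer_,
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (anyNA(hits$evalue) || any(hits$evalue < 0))
    stop("hit file parse error: unparseable or negative e-value")
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), scaffold_id = character(),
             identity = numeric(), aln_length_aa = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             strand = character(), frame = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with the validation the distance analyses need:
#' unique leaf labels and, when `require_lengths = TRUE`, a branch length on
#' every edge.
#'
#' @param path Newick file.
#' @param require_lengths Error when any branch length is missing.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, require_lengths = FALSE) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("failed to parse Newick file: ", path)
  if (inherits(tree, "multiPhylo"))
    stop("expected a single tree, found ", length(tree))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  if (require_lengths &&
      (is.null(tree$edge.length) || anyNA(tree$edge.length)))
    stop("branch lengths required but missing from tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch lengths in tree")
  tree
}

#' Read a per-scaffold sequencing depth table
#'
#' Two tab-separated columns: scaffold id and mean depth (reads per base).
#'
#' @param path TSV path (header optional, detected).
#' @return A named numeric vector of depths.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("depth table needs 2 columns (scaffold, depth)")
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  depth <- as.numeric(df[[2]])
  if (anyNA(depth) || any(depth < 0)) stop("depths must be non-negative numbers")
  setNames(depth, as.character(df[[1]]))
}

#' @rdname read_depth_table
#' @param depths Named numeric vector.
#' @export
write_depth_table <- function(depths, path) {
  write.table(data.frame(scaffold = names(depths), depth = unname(depths)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write annotations as GFF3
#'
#' A column-faithful GFF3 reader/writer that preserves attribute strings
#' verbatim, so annotation tables round-trip losslessly (BED input is
#' accepted for transposable-element tracks, converted to 1-based inclusive
#' coordinates). The `kind` vocabulary maps to/from the GFF3 `type` column
#' (`gene`, `transposable_element`, `orf` as `CDS`, `repeat` as
#' `repeat_region`, `eve`).
#'
#' @param path GFF3 (or `.bed`) file.
#' @param default_kind Kind assigned to BED features (default
#'   `"transposable_element"`).
#' @return A `data.frame` in [annotation_record()] layout.
#' @export
read_annotations <- function(path, default_kind = "transposable_element") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    return(annotation_record(df[[1]], df[[2]] + 1L, df[[3]],
                             if (ncol(df) >= 6) df[[6]] else ".",
                             default_kind,
                             if (ncol(df) >= 4) paste0("name=", df[[4]]) else ""))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines))
    return(annotation_record(character(), integer(), integer())[0, ])
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) stop("GFF3 parse error at feature row ", bad[1],
                        ": expected 9 columns")
  m <- do.call(rbind, f)
  annotation_record(m[, 1], as.integer(m[, 4]), as.integer(m[, 5]), m[, 7],
                    gff_type_to_kind(m[, 3]),
                    ifelse(m[, 9] == ".", "", m[, 9]))
}

gff_type_to_kind <- function(type) {
  map <- c(gene = "gene", transposable_element = "transposable_element",
           CDS = "orf", ORF = "orf", repeat_region = "repeat", eve = "eve")
  k <- unname(map[type])
  ifelse(is.na(k), "gene", k)
}

kind_to_gff_type <- function(kind) {
  map <- c(gene = "gene", transposable_element = "transposable_element",
           orf = "CDS", "repeat" = "repeat_region", eve = "eve")
  unname(map[kind])
}

#' @rdname read_annotations
#' @param ann Annotation `data.frame` ([annotation_record()] layout).
#' @param source Value for the GFF3 source column.
#' @export
write_annotations <- function(ann, path, source = "evescreen") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann)) {
    writeLines(paste(ann$scaffold_id, source, kind_to_gff_type(ann$kind),
                     ann$start, ann$end, ".", ann$strand, ".",
                     ifelse(nzchar(ann$attributes), ann$attributes, "."),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a stage report
#'
#' Deterministic tabular/JSON output: fixed column order, fixed float
#' formatting (`%.6g`), and a config + version snapshot so two runs with the
#' same inputs produce byte-identical files.
#'
#' @param results A `data.frame` of stage results.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param config Optional `eve_config` snapshot to embed.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json"),
                         config = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  ver <- as.character(packageVersion("evescreen"))
  if (format == "json") {
    payload <- list(tool = "evescreen", version = ver,
                    config = if (!is.null(config)) unclass(config),
                    results = results)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(path))
  }
  fmt <- results
  for (j in seq_along(fmt))
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]]))
      fmt[[j]] <- sprintf("%.8g", fmt[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# evescreen ", ver), con)
  if (!is.null(config)) {
    flat <- unlist(unclass(config))
    writeLines(paste0("# config: ",
                      paste(names(flat), flat, sep = "=", collapse = " ")), con)
  }
  writeLines(paste(names(fmt), collapse = "\t"), con)
  if (nrow(fmt))
    writeLines(do.call(paste, c(unname(as.list(fmt)), sep = "\t")), con)
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path Report path.
#' @return A `data.frame` (comment lines dropped).
#' @export
read_report <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

# stage logging: input counts, survivor counts, thresholds actually used
log_stage <- function(stage, ...) {
  message(sprintf("[evescreen:%s] %s", stage,
                  paste(names(c(...)), c(...), sep = "=", collapse = " ")))
}
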