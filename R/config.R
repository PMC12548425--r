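#' Run configuration
#'
#' All tunable thresholds of the pipeline in one validated list. Defaults
#' reproduce the published screen: hits kept only with e-value strictly below
#' `1e-5` and query coverage strictly above 20%, adjacent hits merged within
#' 10 bp, tandem repeats reported at a score cutoff of 100, and the
#' scaffold-length criterion set at 500 kb (the upper genome-size bound of
#' known exogenous naldaviricetes). Where the source analysis left a threshold
#' unstated (ORF minimum length, "comparable" depth, "similar" GC) the default
#' is a conventional choice and is exposed here so users can re-threshold.
#'
#' @param ... Named overrides of any default field.
#' @return A validated list of class `eve_config`.
#' @section Fields:
#' \describe{
#'   \item{max_evalue}{strict upper bound on hit e-values (default `1e-5`).}
#'   \item{min_query_coverage}{strict lower bound on aligned query fraction
#'     (default `0.20`).}
#'   \item{merge_gap_bp}{maximum scaffold gap between hits merged into one
#'     locus (default `10`).}
#'   \item{orf_min_length_nt}{minimum ORF length in nt including the stop
#'     codon; default `150` (50 aa), a conventional small-protein floor.}
#'   \item{tandem_score_cutoff}{minimum consensus score (+1 match / -1
#'     mismatch) for a tandem array (default `100`).}
#'   \item{ir_min_length_bp, ir_min_identity}{inverted-repeat arm thresholds
#'     (defaults `100` bp, `0.90`).}
#'   \item{depth_comparable_factor}{a locus scaffold depth within
#'     `[median/f, median*f]` of the host background counts as comparable
#'     (default `2`).}
#'   \item{gc_similarity_delta}{absolute GC distance to the host mean counted
#'     as similar (default `0.05`).}
#'   \item{long_scaffold_bp}{scaffold length that must be exceeded to score
#'     the size criterion (default `5e5`).}
#'   \item{score_weights}{points per evidence feature, premature stops worth 2
#'     and the five scaffold features 1 each.}
#'   \item{class_high_gt, class_medium_min}{classification bounds: high
#'     confidence above 4 points, medium at 3--4, low otherwise.}
#'   \item{search_*}{built-in translated search: seed word size, raw score
#'     floor, affine gap open/extend, Karlin-Altschul constants.}
#'   \item{seed}{random seed used by the synthetic-data generators.}
#' }
#' @examples
#' cfg <- eve_config(merge_gap_bp = 5)
#' cfg$merge_gap_bp
#' @export
eve_config <- function(...) {
  cfg <- list(
    max_evalue = 1e-5,
    min_query_coverage = 0.20,
    merge_gap_bp = 10L,
    merge_same_query_only = FALSE,
    orf_min_length_nt = 150L,
    orf_require_stop = TRUE,
    tandem_score_cutoff = 100L,
    tandem_min_unit = 10L,
    tandem_max_unit = 100L,
    ir_min_length_bp = 100L,
    ir_min_identity = 0.90,
    depth_comparable_factor = 2.0,
    gc_similarity_delta = 0.05,
    long_scaffold_bp = 500000L,
    score_weights = list(premature_stop = 2L, depth_comparable = 1L,
                         eukaryotic_gene_on_scaffold = 1L, te_on_scaffold = 1L,
                         gc_similar = 1L, scaffold_exceeds_viral_size = 1L),
    class_high_gt = 4L,
    class_medium_min = 3L,
    search_word_size = 4L,
    search_min_raw_score = 40L,
    search_x_drop = 25L,
    search_gap_open = 11L,
    search_gap_extend = 1L,
    search_lambda = 0.3176,
    search_K = 0.134,
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "eve_config"))
}

#' @rdname eve_config
#' @param cfg An `eve_config` object to validate.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$max_evalue) && cfg$max_evalue > 0, "max_evalue must be > 0")
  chk(num1(cfg$min_query_coverage) && cfg$min_query_coverage >= 0 &&
        cfg$min_query_coverage < 1, "min_query_coverage must be in [0,1)")
  chk(num1(cfg$merge_gap_bp) && cfg$merge_gap_bp >= 0, "merge_gap_bp >= 0")
  chk(num1(cfg$orf_min_length_nt) && cfg$orf_min_length_nt >= 6 &&
        cfg$orf_min_length_nt %% 3 == 0,
      "orf_min_length_nt must be >= 6 and divisible by 3")
  chk(num1(cfg$tandem_score_cutoff) && cfg$tandem_score_cutoff > 0,
      "tandem_score_cutoff > 0")
  chk(num1(cfg$ir_min_length_bp) && cfg$ir_min_length_bp >= 20,
      "ir_min_length_bp >= 20")
  chk(num1(cfg$ir_min_identity) && cfg$ir_min_identity > 0 &&
        cfg$ir_min_identity <= 1, "ir_min_identity in (0,1]")
  chk(num1(cfg$depth_comparable_factor) && cfg$depth_comparable_factor >= 1,
      "depth_comparable_factor >= 1")
  chk(num1(cfg$gc_similarity_delta) && cfg$gc_similarity_delta >= 0 &&
        cfg$gc_similarity_delta <= 1, "gc_similarity_delta in [0,1]")
  chk(num1(cfg$long_scaffold_bp) && cfg$long_scaffold_bp > 0,
      "long_scaffold_bp > 0")
  w <- cfg$score_weights
  chk(is.list(w) && all(vapply(w, num1, TRUE)) && all(unlist(w) >= 0),
      "score_weights must be non-negative numbers")
  chk(num1(cfg$class_medium_min) && num1(cfg$class_high_gt) &&
        cfg$class_medium_min <= cfg$class_high_gt,
      "class_medium_min must not exceed class_high_gt")
  chk(num1(cfg$seed), "seed must be numeric")
  cfg
}

#' Read / write a run configuration
#'
#' Configurations round-trip losslessly through YAML or JSON, chosen by file
#' extension.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @param cfg An `eve_config`.
#' @return `read_config` returns an `eve_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  raw$score_weights <- as.list(raw$score_weights)
  eve_config(raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}
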