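#' Back-translate a protein alignment to a codon alignment
#'
#' Expands every amino-acid column of a gapped protein alignment to its
#' source codon (gap columns become `---`), after verifying that each CDS
#' translates exactly to its degapped protein row. Codon alignments built
#' this way feed [ng86_dnds()].
#'
#' @param protein_alignment Named character vector of equal-length gapped
#'   protein rows.
#' @param cds_by_id Named character vector of coding sequences (a trailing
#'   stop codon is allowed and ignored).
#' @return Named character vector of gapped codon rows (class
#'   `codon_alignment`).
#' @export
back_translate_alignment <- function(protein_alignment, cds_by_id) {
  stopifnot(length(protein_alignment) >= 2)
  if (length(unique(nchar(protein_alignment))) != 1L)
    stop("protein alignment rows differ in length")
  out <- vapply(names(protein_alignment), function(id) {
    prot <- protein_alignment[[id]]
    cds <- cds_by_id[[id]]
    if (is.null(cds)) stop("no CDS for alignment row '", id, "'")
    cds <- toupper(cds)
    if (nchar(cds) %% 3 != 0)
      stop("CDS '", id, "' length not divisible by 3")
    cod <- codons_of(cds, 0L)
    if (length(cod) && cod[length(cod)] %in% STOP_CODONS)
      cod <- cod[-length(cod)]
    if (any(cod %in% STOP_CODONS))
      stop("CDS '", id, "' has an internal stop codon at codon ",
           which(cod %in% STOP_CODONS)[1])
    aa <- strsplit(gsub("-", "", prot), "", fixed = TRUE)[[1]]
    if (length(aa) != length(cod))
      stop("CDS '", id, "' encodes ", length(cod),
           " residues but the protein row has ", length(aa))
    trans <- translate_codons(cod)
    mism <- which(trans != aa)
    if (length(mism))
      stop("CDS '", id, "' does not translate to its protein row: first ",
           "mismatch at residue ", mism[1], " (", trans[mism[1]], " vs ",
           aa[mism[1]], ")")
    cols <- strsplit(prot, "", fixed = TRUE)[[1]]
    expanded <- character(length(cols))
    expanded[cols == "-"] <- "---"
    expanded[cols != "-"] <- cod
    paste(expanded, collapse = "")
  }, "")
  structure(out, class = "codon_alignment")
}

translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}

# ---- NG86 machinery -------------------------------------------------------

# Precompute, once: per-codon synonymous site counts and per-codon-pair
# (Sd, Nd) differences averaged over all shortest substitution paths.
# Mutations to stop codons count as nonsynonymous sites (keeps S + N = 3 per
# codon); substitution paths through stop codons are excluded from the path
# average unless every path is blocked.
ng86_tables <- function() {
  if (!is.null(.evescreen_env$ng86)) return(.evescreen_env$ng86)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  aa <- unname(gc_tab)
  bases <- c("A", "C", "G", "T")
  n <- length(codons)
  syn_sites <- setNames(numeric(n), codons)
  for (ci in seq_len(n)) {
    if (aa[ci] == "*") { syn_sites[ci] <- NA_real_; next }
    cod <- strsplit(codons[ci], "")[[1]]
    s <- 0
    for (p in 1:3) for (b in setdiff(bases, cod[p])) {
      mut <- cod; mut[p] <- b
      mcod <- paste(mut, collapse = "")
      if (gc_tab[mcod] == aa[ci]) s <- s + 1 / 3
    }
    syn_sites[ci] <- s
  }
  step_class <- function(c1, c2) {
    # one-step substitution: 1 if synonymous, 0 if nonsynonymous
    if (gc_tab[c1] == gc_tab[c2]) 1L else 0L
  }
  Sd <- matrix(0, n, n, dimnames = list(codons, codons))
  Nd <- matrix(0, n, n, dimnames = list(codons, codons))
  perms <- list(`1` = matrix(1), `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (aa[i] == "*" || aa[j] == "*") { Sd[i, j] <- NA; Nd[i, j] <- NA; next }
    c1 <- strsplit(codons[i], "")[[1]]
    c2 <- strsplit(codons[j], "")[[1]]
    diffpos <- which(c1 != c2)
    nd <- length(diffpos)
    if (nd == 0L) next
    P <- perms[[as.character(nd)]]
    path_s <- numeric(0); path_n <- numeric(0)
    blocked_s <- numeric(0); blocked_n <- numeric(0)
    for (r in seq_len(nrow(P))) {
      cur <- c1; s <- 0L; ns <- 0L; blocked <- FALSE
      for (step in P[r, ]) {
        nxt <- cur; nxt[diffpos[step]] <- c2[diffpos[step]]
        ncod <- paste(nxt, collapse = "")
        if (gc_tab[ncod] == "*") blocked <- TRUE
        k <- step_class(paste(cur, collapse = ""), ncod)
        s <- s + k; ns <- ns + (1L - k)
        cur <- nxt
      }
      if (blocked) { blocked_s <- c(blocked_s, s); blocked_n <- c(blocked_n, ns) }
      else { path_s <- c(path_s, s); path_n <- c(path_n, ns) }
    }
    if (length(path_s)) { Sd[i, j] <- mean(path_s); Nd[i, j] <- mean(path_n) }
    else { Sd[i, j] <- mean(blocked_s); Nd[i, j] <- mean(blocked_n) }
  }
  .evescreen_env$ng86 <- list(syn_sites = syn_sites, Sd = Sd, Nd = Nd,
                              codons = codons, aa = aa)
  .evescreen_env$ng86
}

#' Nei-Gojobori (1986) dN/dS estimate for a pairwise codon alignment
#'
#' The unweighted counting method: synonymous/nonsynonymous site counts per
#' codon are the per-position fractions of single-base changes that preserve
#' the encoded amino acid (averaged over the two sequences; changes creating
#' stop codons count as nonsynonymous, so each codon contributes exactly 3
#' sites); observed differences between unequal codons are averaged over all
#' shortest substitution paths, excluding paths through stop codons. The
#' proportions `pN = Nd/N`, `pS = Sd/S` receive the Jukes-Cantor multiple-hit
#' correction `d = -3/4 log(1 - 4/3 p)`, and `omega = dN/dS` when `dS > 0`.
#' This is a closed-form approximation to the codon-model ML estimate; the
#' supported inference is the binary purifying-selection call (`omega < 1`),
#' not the exact ML value.
#'
#' @param seq1,seq2 Gap-aligned coding sequences of equal length (gaps `-`
#'   in whole-codon units), or a 2-row `codon_alignment` as `seq1`.
#' @return A list of class `selection_result`: `dN`, `dS`, `omega`,
#'   `N_sites`, `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `n_codons`, `purifying`
#'   (NA when omega undefined), `dS_defined`, `dN_defined`.
#' @examples
#' r <- ng86_dnds("TTTGGG", "TTCGGG")  # one synonymous difference
#' r$Sd; r$Nd
#' @export
ng86_dnds <- function(seq1, seq2 = NULL) {
  if (is.null(seq2)) {
    stopifnot(length(seq1) == 2)
    seq2 <- seq1[[2]]; seq1 <- seq1[[1]]
  }
  s1 <- toupper(seq1); s2 <- toupper(seq2)
  if (nchar(s1) != nchar(s2)) stop("aligned sequences differ in length")
  if (nchar(s1) %% 3 != 0) stop("alignment length not divisible by 3")
  c1 <- codons_of(s1, 0L); c2 <- codons_of(s2, 0L)
  ok <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  c1 <- c1[ok]; c2 <- c2[ok]
  if (any(c1 %in% STOP_CODONS) || any(c2 %in% STOP_CODONS))
    stop("internal stop codon in compared codons")
  ncod <- length(c1)
  if (ncod < 1) stop("no ungapped codon columns to compare")
  tab <- ng86_tables()
  S <- sum((tab$syn_sites[c1] + tab$syn_sites[c2]) / 2)
  N <- 3 * ncod - S
  idx <- cbind(match(c1, tab$codons), match(c2, tab$codons))
  Sd <- sum(tab$Sd[idx]); Nd <- sum(tab$Nd[idx])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    if (p <= 0) return(0)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega,
                 N_sites = N, S_sites = S, Nd = Nd, Sd = Sd,
                 pN = pN, pS = pS, n_codons = ncod,
                 purifying = if (is.na(omega)) NA else omega < 1,
                 dS_defined = !is.na(dS), dN_defined = !is.na(dN)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("NG86: dN=%.4f dS=%.4f omega=%s (N=%.1f S=%.1f Nd=%.2f Sd=%.2f, %d codons)\n",
              x$dN, x$dS,
              if (is.na(x$omega)) "undefined" else sprintf("%.4f", x$omega),
              x$N_sites, x$S_sites, x$Nd, x$Sd, x$n_codons))
  invisible(x)
}

#' Purifying-selection screen over a set of dN/dS results
#'
#' Flags results with `omega < threshold`; undefined omegas (saturated or
#' zero synonymous divergence) are excluded from the flag counts and counted
#' separately.
#'
#' @param results List of `selection_result`s ([ng86_dnds()]).
#' @param threshold Omega threshold (default 1, the neutral boundary).
#' @return List: `purifying` (logical vector, NA = undefined), `n_purifying`,
#'   `n_not`, `n_undefined`, `omegas`.
#' @export
purifying_screen <- function(results, threshold = 1.0) {
  if (inherits(results, "selection_result")) results <- list(results)
  om <- vapply(results, function(r) r$omega %||% NA_real_, 0)
  flag <- ifelse(is.na(om), NA, om < threshold)
  list(purifying = flag,
       n_purifying = sum(flag, na.rm = TRUE),
       n_not = sum(!flag, na.rm = TRUE),
       n_undefined = sum(is.na(flag)),
       omegas = om)
}

#' Patristic distance matrix of a tree
#'
#' Pairwise leaf-to-leaf distances as path sums of branch lengths (computed
#' with \pkg{ape}). Requires a branch length on every edge.
#'
#' @param tree A `phylo` object ([read_newick()]).
#' @return A symmetric numeric matrix with zero diagonal, leaf labels as
#'   dimnames.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("need at least 2 leaves")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("branch lengths required for patristic distances")
  n <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Within- and between-family patristic distance summary
#'
#' Splits all leaf pairs into within-family and between-family sets and
#' reports min/max/mean per family pair plus pooled ranges — the comparison
#' used to place a new virus lineage relative to established families.
#'
#' @param dist_matrix Patristic matrix ([patristic_matrix()]).
#' @param family_map Named character vector (leaf -> family) or a
#'   `data.frame` with columns `leaf`, `family`. Every leaf must be assigned.
#' @return List with `pairs` (per family-pair `data.frame`: `family_a`,
#'   `family_b`, `type`, `n_pairs`, `min`, `max`, `mean`) and `pooled`
#'   (`data.frame` by `type`).
#' @export
family_distance_summary <- function(dist_matrix, family_map) {
  if (is.data.frame(family_map))
    family_map <- setNames(as.character(family_map$family), family_map$leaf)
  leaves <- rownames(dist_matrix)
  missing_l <- setdiff(leaves, names(family_map))
  if (length(missing_l))
    stop("no family assigned to leaf(s): ", paste(missing_l, collapse = ", "))
  fam <- unname(family_map[leaves])
  singles <- names(which(table(fam) == 1))
  if (length(singles))
    warning("singleton family(ies) contribute no within-family pairs: ",
            paste(singles, collapse = ", "))
  n <- length(leaves)
  ij <- which(upper.tri(dist_matrix), arr.ind = TRUE)
  d <- dist_matrix[ij]
  fa <- pmin(fam[ij[, 1]], fam[ij[, 2]])
  fb <- pmax(fam[ij[, 1]], fam[ij[, 2]])
  key <- paste(fa, fb, sep = "\r")
  agg <- function(idx) c(n_pairs = length(idx), min = min(d[idx]),
                         max = max(d[idx]), mean = mean(d[idx]))
  groups <- split(seq_along(d), key)
  stats <- t(vapply(groups, agg, numeric(4)))
  ga <- sub("\r.*", "", names(groups)); gb <- sub(".*\r", "", names(groups))
  pairs <- data.frame(family_a = ga, family_b = gb,
                      type = ifelse(ga == gb, "within", "between"),
                      stats, row.names = NULL, stringsAsFactors = FALSE)
  pooled <- do.call(rbind, lapply(c("within", "between"), function(ty) {
    idx <- which((fa == fb) == (ty == "within"))
    if (!length(idx)) return(NULL)
    data.frame(type = ty, n_pairs = length(idx), min = min(d[idx]),
               max = max(d[idx]), mean = mean(d[idx]),
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs[order(pairs$type, pairs$family_a, pairs$family_b), ],
       pooled = pooled)
}

#' Reciprocal best hits
#'
#' A pair `(a, b)` is kept iff `b` is `a`'s best hit by bitscore in the
#' A-vs-B table and `a` is `b`'s best in B-vs-A. Ties break by lower
#' e-value, then lexicographic subject id, so the output is deterministic.
#'
#' @param hits_ab,hits_ba `data.frame`s with columns `query_id`,
#'   `subject_id`, `bitscore` and optionally `evalue`.
#' @return A `data.frame` of homolog pairs: `a_id`, `b_id`, `bitscore_ab`,
#'   `bitscore_ba`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best_of <- function(h) {
    if (!nrow(h)) return(setNames(character(), character()))
    if (is.null(h$evalue)) h$evalue <- 0
    o <- order(h$query_id, -h$bitscore, h$evalue, h$subject_id)
    h <- h[o, , drop = FALSE]
    first <- !duplicated(h$query_id)
    setNames(h$subject_id[first], h$query_id[first])
  }
  ba <- best_of(hits_ab); bb <- best_of(hits_ba)
  a_ids <- names(ba)
  keep <- !is.na(bb[ba]) & bb[ba] == a_ids
  keep[is.na(keep)] <- FALSE
  a <- a_ids[keep]; b <- unname(ba[keep])
  sc <- function(h, q, s) {
    m <- match(paste(q, s), paste(h$query_id, h$subject_id))
    h$bitscore[m]
  }
  out <- data.frame(a_id = a, b_id = b,
                    bitscore_ab = sc(hits_ab, a, b),
                    bitscore_ba = sc(hits_ba, b, a),
                    stringsAsFactors = FALSE)
  out[order(out$a_id), , drop = FALSE]
}

#' Gene-order ranks for a synteny dot plot
#'
#' Ranks each genome's genes by start coordinate and emits one point per
#' homolog pair: identical gene order gives the diagonal, a full reversal
#' the anti-diagonal. The strand-agreement flag marks pairs whose members
#' lie on the same strand in both genomes.
#'
#' @param orfs_a,orfs_b Gene tables with columns `id`, `start`, `strand`.
#' @param homolog_pairs `data.frame` with columns `a_id`, `b_id`
#'   ([reciprocal_best_hits()] output works directly).
#' @return A `data.frame` sorted by `rank_a`: `rank_a`, `rank_b`, `gene_a`,
#'   `gene_b`, `strand_agree`.
#' @export
synteny_orders <- function(orfs_a, orfs_b, homolog_pairs) {
  if (anyDuplicated(homolog_pairs$a_id) || anyDuplicated(homolog_pairs$b_id))
    stop("a gene appears more than once in homolog_pairs")
  rank_of <- function(orfs) {
    o <- order(orfs$start, orfs$id)
    rk <- integer(nrow(orfs)); rk[o] <- seq_len(nrow(orfs))
    setNames(rk, orfs$id)
  }
  ra <- rank_of(orfs_a); rb <- rank_of(orfs_b)
  ma <- match(homolog_pairs$a_id, orfs_a$id)
  mb <- match(homolog_pairs$b_id, orfs_b$id)
  if (anyNA(ma) || anyNA(mb))
    stop("homolog pair references a gene missing from the ORF tables")
  out <- data.frame(rank_a = unname(ra[homolog_pairs$a_id]),
                    rank_b = unname(rb[homolog_pairs$b_id]),
                    gene_a = homolog_pairs$a_id,
                    gene_b = homolog_pairs$b_id,
                    strand_agree = orfs_a$strand[ma] == orfs_b$strand[mb],
                    stringsAsFactors = FALSE)
  out[order(out$rank_a), , drop = FALSE]
}
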