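#' Synthetic data generators with known ground truth
#'
#' These generators build host scaffolds, annotated viral genomes and
#' implanted, degraded viral elements whose location, degradation state and
#' expected evidence profile are recorded exactly, so the whole screen
#' (scan, filter, merge, evidence, score, census) can be validated against
#' truth without any external data. Background host GC defaults to 0.38 and
#' viral sequence to 0.52, so the GC-similarity criterion is exercised in
#' both directions. All generators are pure functions of their arguments
#' including `seed`.
#'
#' @param length Scaffold length in bp.
#' @param gc Target GC fraction; G and C (and A and T) are equiprobable
#'   within their class.
#' @param seed Integer seed; when `NULL` the current RNG stream is used.
#' @param id Sequence id.
#' @return A [seq_record()].
#' @export
generate_host_scaffold <- function(length, gc = 0.38, seed = NULL,
                                   id = "scaffold1") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  run <- function() seq_record(id, random_dna(length, gc), "linear")
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))

# random coding sequence: ATG + (n_codons - 1) non-stop codons
# (+ terminal stop when include_stop)
generate_cds <- function(n_codons, seed = NULL, include_stop = FALSE) {
  stopifnot(n_codons >= 2)
  run <- function() {
    body <- sample(NONSTOP_CODONS, n_codons - 1L, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""),
           if (include_stop) sample(STOP_CODONS, 1L) else "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate an annotated circular viral genome
#'
#' Emulates the structure of a large dsDNA (naldaviricete-like) genome: a
#' circular sequence carrying non-overlapping ATG-to-stop ORFs on both
#' strands at recorded coordinates, optionally with implanted tandem
#' direct-repeat arrays and inverted-repeat arm pairs. After assembly the
#' genome is verified with [find_orfs()] and any block producing a spurious
#' or altered ORF call is re-drawn (block lengths, and hence all recorded
#' coordinates, are preserved), so the recovered ORF set equals the
#' implanted one exactly.
#'
#' @param n_orfs Number of ORFs.
#' @param gc GC fraction of spacers and codon draws (default 0.52).
#' @param dr_spec Optional tandem-repeat spec:
#'   `list(unit_length=, copies=, n=)`.
#' @param ir_spec Optional inverted-repeat spec:
#'   `list(arm_length=, identity=, n=)`.
#' @param seed Integer seed.
#' @param orf_aa_range Range of ORF lengths in aa (stop excluded).
#' @param spacer_range Range of intergenic spacer lengths in bp.
#' @param min_orf_length_nt ORF length floor used in the verification scan.
#' @return List: `genome` (circular [seq_record()]), `orfs` (`id`, `start`,
#'   `end`, `strand`, `length_nt`, `cds`, `protein`), `repeats`
#'   (`dr`, `ir` tables with recorded coordinates), `annotations`
#'   ([annotation_record()] layout).
#' @export
generate_viral_genome <- function(n_orfs = 20L, gc = 0.52, dr_spec = NULL,
                                  ir_spec = NULL, seed = 1L,
                                  orf_aa_range = c(80L, 300L),
                                  spacer_range = c(40L, 120L),
                                  min_orf_length_nt = 150L) {
  withr::with_seed(seed, {
    blocks <- list()
    add <- function(type, len, payload = NULL)
      blocks[[length(blocks) + 1L]] <<- list(type = type, len = len,
                                             payload = payload)
    add("spacer", sample(spacer_range[1]:spacer_range[2], 1L))
    for (i in seq_len(n_orfs)) {
      aa <- sample(orf_aa_range[1]:orf_aa_range[2], 1L)
      add("orf", 3L * (aa + 1L),
          list(id = sprintf("orf%02d", i), n_codons = aa,
               strand = sample(c("+", "-"), 1L)))
      add("spacer", sample(spacer_range[1]:spacer_range[2], 1L))
    }
    n_dr <- if (is.null(dr_spec)) 0L else dr_spec$n %||% 1L
    for (i in seq_len(n_dr)) {
      add("dr", dr_spec$unit_length * dr_spec$copies,
          list(id = sprintf("dr%02d", i), unit = dr_spec$unit_length,
               copies = dr_spec$copies))
      add("spacer", sample(spacer_range[1]:spacer_range[2], 1L))
    }
    n_ir <- if (is.null(ir_spec)) 0L else ir_spec$n %||% 1L
    for (i in seq_len(n_ir)) {
      add("ir_arm1", ir_spec$arm_length,
          list(id = sprintf("ir%02d", i), identity = ir_spec$identity))
      add("spacer", max(spacer_range), list(ir_gap = TRUE))
      add("ir_arm2", ir_spec$arm_length, list(id = sprintf("ir%02d", i)))
      add("spacer", sample(spacer_range[1]:spacer_range[2], 1L))
    }
    # materialise block contents (lengths fixed; content re-drawable)
    draw_block <- function(b) {
      switch(b$type,
        spacer = random_dna(b$len, gc),
        orf = {
          # aa coding codons (incl the M) + stop => nt length 3*(aa+1)
          s <- generate_cds(b$payload$n_codons, include_stop = TRUE)
          if (b$payload$strand == "-") revcomp(s) else s
        },
        dr = {
          # unit screened so the periodic array cannot harbour an ORF call
          repeat {
            unit <- random_dna(b$payload$unit, gc)
            probe <- strrep(unit, ceiling(300 / b$payload$unit) + 2L)
            if (!nrow(find_orfs(probe, min_length_nt = min_orf_length_nt)))
              break
          }
          paste(rep(unit, b$payload$copies), collapse = "")
        },
        ir_arm1 = random_dna(b$len, gc),
        ir_arm2 = NA_character_)  # filled after arm1 is known
    }
    content <- lapply(blocks, draw_block)
    fill_arm2 <- function() {
      for (i in seq_along(blocks)) {
        if (blocks[[i]]$type != "ir_arm2") next
        j <- which(vapply(blocks, function(b)
          b$type == "ir_arm1" && b$payload$id == blocks[[i]]$payload$id, TRUE))
        arm <- content[[j]]
        n_sub <- round((1 - blocks[[j]]$payload$identity) * nchar(arm))
        if (n_sub > 0) {
          ch <- strsplit(arm, "")[[1]]
          pos <- sample(nchar(arm), n_sub)
          for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          arm <- paste(ch, collapse = "")
        }
        content[[i]] <<- revcomp(arm)
      }
    }
    fill_arm2()
    lens <- vapply(blocks, `[[`, 0L, "len")
    starts <- cumsum(c(1L, lens[-length(lens)]))
    ends <- starts + lens - 1L
    truth_orfs <- function() {
      idx <- which(vapply(blocks, function(b) b$type == "orf", TRUE))
      data.frame(id = vapply(idx, function(i) blocks[[i]]$payload$id, ""),
                 start = starts[idx], end = ends[idx],
                 strand = vapply(idx, function(i) blocks[[i]]$payload$strand, ""),
                 length_nt = lens[idx], stringsAsFactors = FALSE)
    }
    # verification / repair loop: redraw blocks involved in any ORF-call
    # discrepancy until the scan reproduces exactly the implanted set
    for (iter in 1:60) {
      genome <- seq_record("viral_genome", paste(unlist(content), collapse = ""),
                           "circular")
      found <- find_orfs(genome, min_length_nt = min_orf_length_nt)
      want <- truth_orfs()
      key_f <- sprintf("%d:%d:%s", found$start,
                       ifelse(found$wraps_origin, -1L, found$end), found$strand)
      key_w <- sprintf("%d:%d:%s", want$start, want$end, want$strand)
      bad <- c(setdiff(key_f, key_w), setdiff(key_w, key_f))
      if (!length(bad)) break
      if (iter == 60)
        stop("could not realise a clean viral genome; relax the feature specs")
      # redraw every re-drawable block overlapping an offending call
      bad_rows <- found[!key_f %in% key_w, , drop = FALSE]
      L <- nchar(genome$seq)
      ivs <- list()
      for (k in seq_len(nrow(bad_rows))) {
        if (bad_rows$wraps_origin[k]) {
          ivs[[length(ivs) + 1L]] <- c(bad_rows$start[k], L)
          ivs[[length(ivs) + 1L]] <- c(1L, bad_rows$end[k])
        } else ivs[[length(ivs) + 1L]] <- c(bad_rows$start[k], bad_rows$end[k])
      }
      for (k in which(!key_w %in% key_f))
        ivs[[length(ivs) + 1L]] <- c(want$start[k], want$end[k])
      lo <- vapply(ivs, `[`, 0L, 1L); hi <- vapply(ivs, `[`, 0L, 2L)
      redrawn <- FALSE
      for (bi in seq_along(blocks)) {
        if (blocks[[bi]]$type == "ir_arm2") next
        if (any(starts[bi] <= hi & ends[bi] >= lo)) {
          content[[bi]] <- draw_block(blocks[[bi]])
          redrawn <- TRUE
        }
      }
      if (!redrawn) stop("viral genome repair stalled; widen the specs")
      fill_arm2()
    }
    orfs <- truth_orfs()
    seqs <- substring(genome$seq, orfs$start, orfs$end)
    orfs$cds <- ifelse(orfs$strand == "-",
                       vapply(seqs, revcomp, "", USE.NAMES = FALSE), seqs)
    orfs$protein <- vapply(orfs$cds, function(x) {
      p <- paste(translate_codons(codons_of(x, 0L)), collapse = "")
      sub("\\*$", "", p)
    }, "", USE.NAMES = FALSE)
    dr_idx <- which(vapply(blocks, function(b) b$type == "dr", TRUE))
    dr <- data.frame(id = vapply(dr_idx, function(i) blocks[[i]]$payload$id, ""),
                     start = starts[dr_idx], end = ends[dr_idx],
                     unit_length = vapply(dr_idx, function(i)
                       blocks[[i]]$payload$unit, 0L),
                     copies = vapply(dr_idx, function(i)
                       blocks[[i]]$payload$copies, 0L),
                     stringsAsFactors = FALSE)
    a1 <- which(vapply(blocks, function(b) b$type == "ir_arm1", TRUE))
    a2 <- which(vapply(blocks, function(b) b$type == "ir_arm2", TRUE))
    ir <- data.frame(id = vapply(a1, function(i) blocks[[i]]$payload$id, ""),
                     start1 = starts[a1], end1 = ends[a1],
                     start2 = starts[a2], end2 = ends[a2],
                     identity = vapply(a1, function(i)
                       blocks[[i]]$payload$identity, 0),
                     stringsAsFactors = FALSE)
    ann <- rbind(
      annotation_record(genome$id, orfs$start, orfs$end, orfs$strand, "orf",
                        paste0("ID=", orfs$id)),
      if (nrow(dr)) annotation_record(genome$id, dr$start, dr$end, ".",
                                      "repeat", paste0("ID=", dr$id)),
      if (nrow(ir)) annotation_record(genome$id, c(ir$start1, ir$start2),
                                      c(ir$end1, ir$end2), ".", "repeat",
                                      paste0("ID=", rep(ir$id, 2))))
    list(genome = genome, orfs = orfs, repeats = list(dr = dr, ir = ir),
         annotations = ann)
  })
}

# substitutions (never creating or destroying stops) + injected internal
# stop codons at recorded positions; first/last two codons are left intact
# so alignment spans reach the fragment edges
mutate_cds <- function(cds, sub_rate, n_stops) {
  ch <- strsplit(cds, "")[[1]]
  ncod <- length(ch) %/% 3L
  n_sub <- rpois(1L, sub_rate * length(ch))
  protected <- integer(0)
  if (n_stops > 0L) {
    lo <- max(2L, ceiling(ncod * 0.2)); hi <- min(ncod - 1L, floor(ncod * 0.8))
    if (hi - lo + 1L < n_stops)
      stop("profile unsatisfiable: too many stops for a ", ncod, "-codon gene")
    stop_idx <- sort(sample(lo:hi, n_stops))
    protected <- stop_idx
  } else stop_idx <- integer(0)
  if (n_sub > 0L) {
    cand <- setdiff(seq_len(length(ch)),
                    c(1:6, (length(ch) - 5L):length(ch),
                      as.vector(outer(3L * (protected - 1L), 1:3, `+`))))
    pos <- sample(cand, min(n_sub, length(cand)))
    for (p in pos) {
      old_cod_i <- (p - 1L) %/% 3L + 1L
      for (try in 1:10) {
        b <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        tmp <- ch
        tmp[p] <- b
        cod <- paste(tmp[(3L * old_cod_i - 2L):(3L * old_cod_i)], collapse = "")
        if (!cod %in% STOP_CODONS) { ch <- tmp; break }
      }
    }
  }
  for (k in stop_idx) {
    ch[(3L * k - 2L):(3L * k)] <- strsplit(sample(c("TAA", "TAG"), 1L), "")[[1]]
  }
  list(seq = paste(ch, collapse = ""), stop_codon_idx = stop_idx)
}

#' Build a deterministic implant cohort specification
#'
#' A profile table cycling through evidence combinations that force total
#' scores 0, 2, 3, 4, 5 and 7 (covering every class boundary) and through
#' fragmentation patterns on both sides of the merge rule: single fragments,
#' fragments with gaps of 4--5 bp (merge into one locus) and gaps of
#' 17--20 bp (stay separate loci).
#'
#' @param genes Named character vector of viral CDS (as in [implant_eves()]);
#'   each element is assigned a gene long enough that every fragment stays
#'   independently detectable (>= 50 aa and > 20% query coverage).
#' @param n Number of elements (default 50).
#' @return A `data.frame`, one row per element, understood by
#'   [implant_eves()].
#' @export
eve_profiles <- function(genes, n = 50L) {
  stopifnot(!is.null(names(genes)))
  ncod <- nchar(genes) %/% 3L
  combos <- list( # n_stops>0, depth, gene, te, gc, len -> points
    list(st = 0L, d = FALSE, g = FALSE, t = FALSE, gc = FALSE, l = FALSE), # 0
    list(st = 1L, d = FALSE, g = FALSE, t = FALSE, gc = FALSE, l = FALSE), # 2
    list(st = 1L, d = TRUE,  g = FALSE, t = FALSE, gc = FALSE, l = FALSE), # 3
    list(st = 0L, d = TRUE,  g = TRUE,  t = TRUE,  gc = FALSE, l = FALSE), # 3
    list(st = 1L, d = TRUE,  g = TRUE,  t = FALSE, gc = FALSE, l = FALSE), # 4
    list(st = 1L, d = TRUE,  g = TRUE,  t = TRUE,  gc = FALSE, l = FALSE), # 5
    list(st = 2L, d = TRUE,  g = TRUE,  t = TRUE,  gc = TRUE,  l = FALSE), # 6
    list(st = 1L, d = TRUE,  g = TRUE,  t = TRUE,  gc = TRUE,  l = TRUE))  # 7
  # inter-fragment gaps are kept off multiples of 3 so the pad frameshifts
  # the downstream fragment: each fragment then yields its own hit and the
  # merge rule is exercised purely on the recorded gap distance
  frags <- list(c(1L, 0L), c(2L, 4L), c(2L, 20L), c(1L, 0L),
                c(3L, 5L), c(2L, 17L))
  rates <- c(0, 0.02, 0.05)
  rows <- lapply(seq_len(n), function(i) {
    cb <- combos[[(i - 1L) %% length(combos) + 1L]]
    fr <- frags[[(i - 1L) %% length(frags) + 1L]]
    need <- if (fr[1] > 1L && fr[2] > 10L) 140L else 40L
    ok <- names(genes)[3L * ncod * 0.9 / fr[1] >= 150 & ncod >= need]
    if (!length(ok))
      stop("no gene long enough for ", fr[1], " detectable fragments")
    data.frame(element_id = sprintf("eve%03d", i),
               gene = ok[(i - 1L) %% length(ok) + 1L],
               sub_rate = rates[(i - 1L) %% length(rates) + 1L],
               n_stops = cb$st, n_fragments = fr[1], frag_gap_bp = fr[2],
               ev_depth = cb$d, ev_gene = cb$g, ev_te = cb$t,
               ev_gc = cb$gc, ev_len = cb$l, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Implant degraded viral elements into synthetic host scaffolds
#'
#' Each profile row yields one scaffold carrying copies of one viral gene,
#' degraded per the profile (substitutions at `sub_rate`, `n_stops` injected
#' internal stop codons per fragment, split into `n_fragments` pieces
#' separated by `frag_gap_bp` of stop-codon padding) and scaffold-level
#' annotations, depth and GC arranged to realise exactly the requested
#' evidence booleans. Background host scaffolds (insect genes, no implants)
#' provide the depth/GC reference. Expected per-locus points and classes are
#' computed from the profile with the configured weights and stored, forming
#' the end-to-end truth table.
#'
#' @param viral_genes Named character vector of viral CDS (no terminal stop
#'   needed; internal stops not allowed). Typically
#'   `setNames(vg$orfs$cds, vg$orfs$id)` from [generate_viral_genome()].
#' @param profiles Profile table from [eve_profiles()].
#' @param seed Integer seed.
#' @param config An [eve_config()] (weights/class bounds for expected
#'   scores).
#' @param host_gc Background host GC (default 0.38).
#' @param n_background Number of pure host scaffolds (default 4).
#' @param base_depth Host sequencing depth level (default 30).
#' @return List of class `synthetic_truth`: `scaffolds` (named list),
#'   `annotations`, `depth_table`, `elements` (realised profile table),
#'   `loci` (expected locus table: `element_id`, `scaffold_id`, `start`,
#'   `end`, `gene`, `n_stops`, evidence booleans, `expected_points`,
#'   `expected_class`), `proteins` (query set for the scan),
#'   `query_lengths`, and `config`.
#' @export
implant_eves <- function(viral_genes, profiles, seed = 1L,
                         config = eve_config(), host_gc = 0.38,
                         n_background = 4L, base_depth = 30) {
  stopifnot(nrow(profiles) >= 1, !is.null(names(viral_genes)))
  missing_g <- setdiff(profiles$gene, names(viral_genes))
  if (length(missing_g))
    stop("profiles reference unknown gene(s): ", paste(missing_g, collapse = ", "))
  withr::with_seed(seed, {
    scaffolds <- list(); ann <- list(); depth <- numeric()
    loci <- list()
    # background host scaffolds: insect genes, no implants
    for (i in seq_len(n_background)) {
      sid <- sprintf("host_scf%02d", i)
      len <- sample(30000:40000, 1L)
      scaffolds[[sid]] <- seq_record(sid, random_dna(len, host_gc))
      g1 <- sample(1000:(len - 3000L), 1L)
      ann[[length(ann) + 1L]] <- annotation_record(
        sid, g1, g1 + 1800L, "+", "gene", "taxon=insect")
      depth[sid] <- base_depth * runif(1, 0.85, 1.2)
    }
    for (r in seq_len(nrow(profiles))) {
      p <- profiles[r, ]
      sid <- sprintf("scf_%s", p$element_id)
      cds <- sub(paste0("(", paste(STOP_CODONS, collapse = "|"), ")$"), "",
                 toupper(viral_genes[[p$gene]]))
      ncod <- nchar(cds) %/% 3L
      if (3L * ncod * 0.9 / p$n_fragments < 150)
        stop("profile unsatisfiable: gene ", p$gene, " too short for ",
             p$n_fragments, " detectable fragments")
      scf_len <- if (p$ev_len) 501000L + sample(0:4000, 1L)
                 else sample(20000:40000, 1L)
      scf_gc <- if (p$ev_gc) host_gc else 0.52
      # fragmentation plan: candidate cut vectors, tried in order until the
      # package's own screen reproduces the element's expected locus
      # structure exactly (the analogue of the ORF repair loop in the viral
      # genome generator: truth is realised by construction, then verified)
      nf <- p$n_fragments
      split_case <- nf > 1L && p$frag_gap_bp > config$merge_gap_bp
      if (split_case && p$frag_gap_bp %% 3L == 0L)
        stop("profile unsatisfiable: split gaps must not be multiples of 3 ",
             "(a same-frame pad can be read through as one alignment)")
      base_cuts <- floor(ncod * seq_len(nf - 1L) / nf)
      min_cod <- 52L
      cand_cuts <- if (nf == 1L) {
        list(integer())
      } else if (split_case && nf == 2L) {
        # try extension-hostile junctions first: the stop pad reads leftward
        # from the downstream hit as a constant residue (I for gap = 2 mod 3,
        # N for 1 mod 3); cuts whose upstream residues score worst against it
        # give the aligner the least to nibble on
        k <- p$frag_gap_bp %/% 3L
        pad_aa <- if (p$frag_gap_bp %% 3L == 2L) "I" else "N"
        B <- blosum62()
        prot_res <- translate_codons(codons_of(cds, 0L))
        cands <- min_cod:(ncod - min_cod)
        badness <- vapply(cands, function(cc)
          max(cumsum(B[prot_res[cc - seq_len(k) + 1L], pad_aa])), 0)
        lapply(cands[order(badness, cands)][seq_len(min(30L, length(cands)))],
               identity)
      } else {
        offs <- c(0L, as.vector(rbind(seq(4L, 40L, 4L), -seq(4L, 40L, 4L))))
        cc <- lapply(offs, function(o) base_cuts + o)
        Filter(function(ct) all(diff(c(0L, ct, ncod)) >= min_cod), cc)
      }
      pad <- function(g) if (g <= 0L) "" else
        substring(strrep("TAA", ceiling(g / 3)), 1L, g)
      insert_len <- 3L * ncod + (nf - 1L) * p$frag_gap_bp
      pos <- sample(5000:(scf_len - insert_len - 5000L), 1L)
      left <- random_dna(pos - 1L, scf_gc)
      right <- random_dna(scf_len - (pos - 1L) - insert_len, scf_gc)
      prot_q <- paste(translate_codons(codons_of(cds, 0L)), collapse = "")
      realised <- FALSE
      for (cuts in cand_cuts) {
        bounds <- cbind(c(1L, cuts + 1L), c(cuts, ncod))
        frag_parts <- lapply(seq_len(nf), function(fi)
          mutate_cds(substring(cds, 3L * (bounds[fi, 1] - 1L) + 1L,
                               3L * bounds[fi, 2]),
                     p$sub_rate, p$n_stops)$seq)
        pieces <- character(2L * nf - 1L)
        pieces[seq(1L, length(pieces), 2L)] <- unlist(frag_parts)
        if (nf > 1L)
          pieces[seq(2L, length(pieces), 2L)] <- pad(p$frag_gap_bp)
        insert <- paste(pieces, collapse = "")
        scf <- seq_record(sid, paste0(left, insert, right))
        frag_starts <- pos + cumsum(c(0L, head(nchar(pieces), -1L)))[
          seq(1L, length(pieces), 2L)]
        frag_ends <- frag_starts + nchar(unlist(frag_parts)) - 1L
        exp_spans <- if (nf == 1L || !split_case)
          cbind(frag_starts[1], frag_ends[nf])
        else cbind(frag_starts, frag_ends)
        # verify: the screen must see exactly the expected loci with the
        # expected stop evidence
        hts <- suppressMessages(search_translated(
          setNames(prot_q, p$gene), setNames(list(scf), sid), config))
        kept <- suppressMessages(filter_hits(
          hts, setNames(nchar(prot_q), p$gene),
          config$max_evalue, config$min_query_coverage))
        lc <- suppressMessages(merge_adjacent_hits(
          kept, config$merge_gap_bp, config$merge_same_query_only))
        ok <- nrow(lc) == nrow(exp_spans) &&
          all(lc$start >= pos - 30L) &&
          all(lc$end <= pos + insert_len - 1L + 30L)
        if (ok) for (li in seq_len(nrow(lc))) {
          hit_span <- which(exp_spans[, 1] <= lc$end[li] &
                              exp_spans[, 2] >= lc$start[li])
          st <- detect_premature_stops(lc[li, ], setNames(list(scf), sid))
          if (length(hit_span) != 1L ||
              (as.integer(st) >= 1L) != (p$n_stops > 0L)) { ok <- FALSE; break }
        }
        if (ok) { realised <- TRUE; break }
      }
      if (!realised)
        stop("could not realise element ", p$element_id, " (gene ", p$gene,
             ") with the requested fragmentation; relax the profile")
      scaffolds[[sid]] <- seq_record(sid, paste0(left, insert, right))
      depth[sid] <- if (p$ev_depth) base_depth * runif(1, 0.85, 1.2)
                    else base_depth * 5
      if (p$ev_gene) {
        gpos <- sample(500:3000, 1L)
        ann[[length(ann) + 1L]] <- annotation_record(
          sid, gpos, gpos + 1500L, "+", "gene", "taxon=insect")
      }
      if (p$ev_te) {
        tpos <- scf_len - sample(3000:5000, 1L)
        ann[[length(ann) + 1L]] <- annotation_record(
          sid, tpos, tpos + 800L, "-", "transposable_element", "family=synthetic")
      }
      # expected loci under the configured merge gap
      merged <- p$n_fragments == 1L || p$frag_gap_bp <= config$merge_gap_bp
      idx_sets <- if (merged) list(seq_len(p$n_fragments))
                  else as.list(seq_len(p$n_fragments))
      for (g in idx_sets) {
        w <- unlist(config$score_weights)
        ev <- c(premature_stop = p$n_stops > 0L,
                depth_comparable = p$ev_depth,
                eukaryotic_gene_on_scaffold = p$ev_gene,
                te_on_scaffold = p$ev_te, gc_similar = p$ev_gc,
                scaffold_exceeds_viral_size = p$ev_len)
        pts <- as.integer(sum(w[names(ev)] * ev))
        loci[[length(loci) + 1L]] <- data.frame(
          element_id = p$element_id, scaffold_id = sid,
          start = min(frag_starts[g]), end = max(frag_ends[g]),
          gene = p$gene, n_stops = p$n_stops * length(g),
          t(ev), expected_points = pts,
          expected_class = classify_score(pts, config),
          stringsAsFactors = FALSE)
      }
    }
    proteins <- vapply(viral_genes, function(x) {
      x <- sub(paste0("(", paste(STOP_CODONS, collapse = "|"), ")$"), "",
               toupper(x))
      paste(translate_codons(codons_of(x, 0L)), collapse = "")
    }, "")
    truth_loci <- do.call(rbind, loci)
    rownames(truth_loci) <- NULL
    structure(list(
      scaffolds = scaffolds,
      annotations = do.call(rbind, ann),
      depth_table = depth,
      elements = profiles,
      loci = truth_loci,
      proteins = proteins,
      query_lengths = nchar(proteins),
      config = config), class = "synthetic_truth")
  })
}

#' Evolve a coding sequence under a fixed dN/dS
#'
#' Event-based codon simulation: substitution events (uniform random
#' position, uniform random alternative base — a Jukes-Cantor mutation
#' kernel) are accepted with relative rate 1 when synonymous and `omega`
#' when nonsynonymous; proposals creating stop codons are rejected outright.
#' The number of accepted substitutions is Poisson with mean
#' `t * n_codons`, so `t` is the expected number of accepted substitutions
#' per codon. True counts are recorded for oracle tests.
#'
#' @param cds Coding sequence (no internal stops; length divisible by 3).
#' @param omega Relative nonsynonymous acceptance rate (>= 0).
#' @param t Expected substitutions per codon (>= 0).
#' @param seed Integer seed.
#' @return List: `cds` (mutated sequence), `n_syn`, `n_nonsyn`, `n_events`.
#' @export
evolve_codons <- function(cds, omega, t, seed = NULL) {
  cds <- toupper(cds)
  stopifnot(nchar(cds) %% 3 == 0, omega >= 0, t >= 0)
  cod0 <- codons_of(cds, 0L)
  if (any(cod0 %in% STOP_CODONS)) stop("CDS contains an internal stop codon")
  gc_tab <- Biostrings::GENETIC_CODE
  run <- function() {
    ch <- strsplit(cds, "")[[1]]
    ncod <- length(ch) %/% 3L
    n_target <- rpois(1L, t * ncod)
    n_syn <- 0L; n_nonsyn <- 0L
    guard <- 0L
    while ((n_syn + n_nonsyn) < n_target) {
      guard <- guard + 1L
      if (guard > 1000L * max(n_target, 1L))
        stop("substitution simulation failed to accept enough events")
      p <- sample.int(length(ch), 1L)
      b <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      ci <- (p - 1L) %/% 3L + 1L
      old_cod <- paste(ch[(3L * ci - 2L):(3L * ci)], collapse = "")
      new <- ch; new[p] <- b
      new_cod <- paste(new[(3L * ci - 2L):(3L * ci)], collapse = "")
      if (gc_tab[new_cod] == "*") next
      syn <- gc_tab[new_cod] == gc_tab[old_cod]
      # relative acceptance rates 1 : omega (synonymous : nonsynonymous),
      # scaled into [0, 1] so omega > 1 is representable
      p_acc <- if (syn) min(1, 1 / max(omega, 1)) else min(1, omega)
      if (runif(1) < p_acc) {
        ch <- new
        if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      }
    }
    list(cds = paste(ch, collapse = ""), n_syn = n_syn, n_nonsyn = n_nonsyn,
         n_events = n_syn + n_nonsyn)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
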