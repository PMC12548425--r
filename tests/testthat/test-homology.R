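test_that("six-frame translation follows the codon table", {
  fr <- six_frame_translate("ATGAAATAA")
  expect_equal(fr[["+1"]], "MK*")
  expect_equal(fr[["+2"]], "*N")     # TGA AAT
  expect_equal(fr[["+3"]], "EI")     # GAA ATA
  expect_equal(unname(nchar(six_frame_translate("AT"))), rep(0L, 6))
  frN <- six_frame_translate("ATGANATAA")
  expect_equal(frN[["+1"]], "MX*")   # codon with N renders X
})

test_that("translated search recovers implanted segments exactly", {
  gene <- evescreen:::generate_cds(90, seed = 71)
  prot <- paste(evescreen:::translate_codons(evescreen:::codons_of(gene, 0)),
                collapse = "")
  host <- withr::with_seed(72, evescreen:::random_dna(12000, 0.4))
  pos <- 4001
  splice <- function(insert) paste0(substring(host, 1, pos - 1), insert,
                                    substring(host, pos + nchar(insert), 12000))
  fwd <- seq_record("scf", splice(gene))
  h <- suppressMessages(search_translated(c(g = prot), list(scf = fwd)))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1)
  expect_equal(h$q_start, 1)
  expect_equal(h$q_end, nchar(prot))         # full query covered
  expect_equal(h$s_start, pos)
  expect_equal(h$s_end, pos + nchar(gene) - 1)
  expect_equal(h$strand, "+")

  rev <- seq_record("scf", splice(revcomp(gene)))
  h2 <- suppressMessages(search_translated(c(g = prot), list(scf = rev)))
  expect_equal(nrow(h2), 1)
  expect_equal(h2$s_start, pos)              # mirrored nt coordinates
  expect_equal(h2$s_end, pos + nchar(gene) - 1)
  expect_equal(h2$strand, "-")
  expect_lt(h2$frame, 0)

  expect_error(search_translated(c(g = "MK@Q"), list(scf = fwd)), "illegal")
})

test_that("seeded search matches a full Smith-Waterman oracle above the floor", {
  skip_if_not_installed("Biostrings")
  withr::local_seed(73)
  host <- evescreen:::random_dna(9000, 0.45)
  genes <- lapply(1:2, function(i) evescreen:::generate_cds(70))
  positions <- c(2001, 6001)
  s <- host
  for (i in 1:2)
    s <- paste0(substring(s, 1, positions[i] - 1), genes[[i]],
                substring(s, positions[i] + nchar(genes[[i]]), nchar(s)))
  # degrade second implant lightly
  queries <- vapply(genes, function(g)
    paste(evescreen:::translate_codons(evescreen:::codons_of(g, 0)),
          collapse = ""), "")
  names(queries) <- c("q1", "q2")
  extra <- vapply(1:3, function(i)
    paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 60, TRUE),
          collapse = ""), "")
  names(extra) <- paste0("rand", 1:3)
  queries <- c(queries, extra)
  scf <- seq_record("scf", s)
  floor_score <- 60
  cfg <- eve_config(search_min_raw_score = floor_score)
  got <- suppressMessages(search_translated(queries, list(scf = scf), cfg))

  # oracle: optimal local alignment per query x frame via pairwiseAlignment
  data("BLOSUM62", package = "Biostrings", envir = environment())
  frames <- six_frame_translate(scf)
  oracle <- list()
  for (qn in names(queries)) for (fn in names(frames)) {
    if (!nzchar(frames[[fn]])) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(queries[[qn]]), Biostrings::AAString(frames[[fn]]),
      type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = 11, gapExtension = 1)
    if (Biostrings::score(pa) >= floor_score)
      oracle[[length(oracle) + 1L]] <- data.frame(
        query_id = qn, frame = fn, score = Biostrings::score(pa),
        q_start = pa@pattern@range@start,
        s_start_aa = pa@subject@range@start)
  }
  oracle <- do.call(rbind, oracle)
  got_key <- sort(paste(got$query_id, ifelse(got$frame > 0, "+", "-"),
                        abs(got$frame), got$score))
  want_key <- sort(paste(oracle$query_id, substr(oracle$frame, 1, 1),
                         substr(oracle$frame, 2, 2), oracle$score))
  expect_equal(got_key, want_key)
})

test_that("hit filtering is strict at both published boundaries", {
  qlen <- c(q = 100L)
  base <- make_hits(query_id = "q", scaffold_id = "s")
  at_e <- base; at_e$evalue <- 1e-5; at_e$q_start <- 1; at_e$q_end <- 50
  expect_equal(nrow(filter_hits(at_e, qlen)), 0)        # e-value == 1e-5 fails
  at_c <- base; at_c$evalue <- 1e-9; at_c$q_start <- 1; at_c$q_end <- 20
  expect_equal(nrow(filter_hits(at_c, qlen)), 0)        # coverage == 0.20 fails
  ok <- base; ok$evalue <- 9.9e-6; ok$q_start <- 1; ok$q_end <- 21
  expect_equal(nrow(filter_hits(ok, qlen)), 1)          # 9.9e-6 and 0.21 pass
  expect_error(filter_hits(make_hits(query_id = "zz", scaffold_id = "s"), qlen),
               "unknown query")
})

test_that("filtering is idempotent and monotone in its thresholds", {
  withr::local_seed(74)
  hits <- make_hits(query_id = sample(c("a", "b"), 40, TRUE),
                    scaffold_id = "s",
                    evalue = 10^runif(40, -12, 0),
                    q_start = 1L, q_end = sample(10:100, 40, TRUE))
  qlen <- c(a = 100L, b = 100L)
  f1 <- filter_hits(hits, qlen)
  f2 <- filter_hits(f1, qlen)
  expect_equal(f1$evalue, f2$evalue)
  # tightening either threshold never adds survivors
  for (ev in c(1e-3, 1e-5, 1e-8)) for (cv in c(0.1, 0.2, 0.5)) {
    sub <- filter_hits(hits, qlen, ev, cv)
    tighter <- filter_hits(hits, qlen, ev / 10, cv + 0.1)
    expect_true(all(paste(tighter$evalue, tighter$q_end) %in%
                      paste(sub$evalue, sub$q_end)))
    expect_lte(nrow(tighter), nrow(sub))
  }
})

test_that("merging follows the 10-bp rule and is order-independent", {
  two <- make_hits(query_id = c("a", "b"), scaffold_id = "s",
                   s_start = c(100L, 205L), s_end = c(200L, 300L))
  m1 <- merge_adjacent_hits(two, 10)
  expect_equal(nrow(m1), 1)                 # gap 4 merges
  expect_equal(m1$start, 100)
  expect_equal(m1$end, 300)
  expect_equal(m1$n_hits, 2)

  two$s_start[2] <- 215L                    # gap 14 stays split
  m2 <- merge_adjacent_hits(two, 10)
  expect_equal(nrow(m2), 2)

  # permuting input rows changes nothing
  many <- make_hits(query_id = letters[1:6], scaffold_id = "s",
                    s_start = c(1L, 50L, 200L, 206L, 400L, 402L),
                    s_end = c(40L, 120L, 205L, 300L, 401L, 500L))
  a <- merge_adjacent_hits(many, 10)
  b <- merge_adjacent_hits(many[sample(6), ], 10)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$n_hits, b$n_hits)
})

test_that("merging equals union-find transitive closure on random intervals", {
  withr::local_seed(75)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    starts <- sort(sample.int(2000, n))
    ends <- starts + sample(10:120, n, TRUE)
    hits <- make_hits(query_id = paste0("q", seq_len(n)), scaffold_id = "s",
                      s_start = as.integer(starts), s_end = as.integer(ends))
    got <- merge_adjacent_hits(hits, 10)
    want <- merge_oracle(starts, ends, 10)
    expect_equal(nrow(got), length(want))
    want_spans <- t(vapply(want, function(idx)
      c(min(starts[idx]), max(ends[idx])), c(0, 0)))
    o <- order(want_spans[, 1])
    expect_equal(got$start, unname(want_spans[o, 1]))
    expect_equal(got$end, unname(want_spans[o, 2]))
    # loci are pairwise separated by more than the gap; re-merge is a no-op
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] - got$end[-nrow(got)] > 10))
    asm <- make_hits(query_id = got$best_query, scaffold_id = "s",
                     s_start = as.integer(got$start),
                     s_end = as.integer(got$end))
    expect_equal(nrow(merge_adjacent_hits(asm, 10)), nrow(got))
  }
})
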