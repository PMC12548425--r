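make_locus <- function(scaffold_seq, spans, strands = "+", id = "scf") {
  scf <- seq_record(id, scaffold_seq)
  members <- make_hits(query_id = paste0("q", seq_len(nrow(spans))),
                       scaffold_id = id,
                       s_start = as.integer(spans[, 1]),
                       s_end = as.integer(spans[, 2]),
                       strand = rep_len(strands, nrow(spans)))
  locus <- list(scaffold_id = id, start = min(spans[, 1]),
                end = max(spans[, 2]), members = members,
                locus_id = sprintf("%s:%d-%d", id, min(spans[, 1]),
                                   max(spans[, 2])))
  list(locus = locus, scaffolds = setNames(list(scf), id))
}

test_that("premature stops are counted per member frame, terminal excluded", {
  gene <- evescreen:::generate_cds(60, seed = 81)       # intact: no stops
  host <- withr::with_seed(82, evescreen:::random_dna(1000, 0.4))
  s <- paste0(substring(host, 1, 200), gene, substring(host, 201 + nchar(gene), 1000))
  lx <- make_locus(s, cbind(201, 200 + nchar(gene)))
  expect_equal(as.integer(detect_premature_stops(lx$locus, lx$scaffolds)), 0)

  # mutate codon 30 to TAA: exactly one internal stop
  ch <- strsplit(gene, "")[[1]]
  ch[88:90] <- c("T", "A", "A")
  s2 <- paste0(substring(host, 1, 200), paste(ch, collapse = ""),
               substring(host, 201 + nchar(gene), 1000))
  lx2 <- make_locus(s2, cbind(201, 200 + nchar(gene)))
  expect_equal(as.integer(detect_premature_stops(lx2$locus, lx2$scaffolds)), 1)

  # a stop in the final codon of the span is terminal, not premature
  ch2 <- strsplit(gene, "")[[1]]
  ch2[(length(ch2) - 2):length(ch2)] <- c("T", "G", "A")
  s3 <- paste0(substring(host, 1, 200), paste(ch2, collapse = ""),
               substring(host, 201 + nchar(gene), 1000))
  lx3 <- make_locus(s3, cbind(201, 200 + nchar(gene)))
  expect_equal(as.integer(detect_premature_stops(lx3$locus, lx3$scaffolds)), 0)

  # minus strand: same count through the hit's own frame
  s4 <- paste0(substring(host, 1, 200), revcomp(paste(ch, collapse = "")),
               substring(host, 201 + nchar(gene), 1000))
  lx4 <- make_locus(s4, cbind(201, 200 + nchar(gene)), strands = "-")
  expect_equal(as.integer(detect_premature_stops(lx4$locus, lx4$scaffolds)), 1)

  # generator bookkeeping oracle: injected stop count is recovered
  withr::with_seed(83, {
    for (k in c(1L, 2L, 3L)) {
      mut <- evescreen:::mutate_cds(gene, 0.02, k)
      s5 <- paste0(substring(host, 1, 200), mut$seq,
                   substring(host, 201 + nchar(gene), 1000))
      lx5 <- make_locus(s5, cbind(201, 200 + nchar(gene)))
      expect_equal(as.integer(detect_premature_stops(lx5$locus, lx5$scaffolds)), k)
    }
  })
})

test_that("evidence extraction applies the stated numeric rules", {
  gene <- evescreen:::generate_cds(60, seed = 84)
  host <- withr::with_seed(85, evescreen:::random_dna(2000, 0.4))
  s <- paste0(substring(host, 1, 500), gene,
              substring(host, 501 + nchar(gene), 2000))
  lx <- make_locus(s, cbind(501, 500 + nchar(gene)))
  ann <- annotation_record(c("scf", "scf"), c(10L, 1500L), c(200L, 1900L),
                           c("+", "-"), c("gene", "transposable_element"),
                           c("taxon=insect", ""))
  host_stats <- list(depth_median = 28, gc_mean = 0.38)
  cfg <- eve_config()
  ev <- extract_evidence(lx$locus, ann, c(scf = 30), host_stats,
                         lx$scaffolds, cfg)
  expect_true(ev$depth_comparable)            # 30 in [14, 56]
  expect_true(ev$eukaryotic_gene_on_scaffold)
  expect_true(ev$te_on_scaffold)
  expect_false(ev$premature_stop)
  expect_false(ev$scaffold_exceeds_viral_size)  # 2 kb << 500 kb
  expect_equal(ev$scaffold_length, 2000)

  ev2 <- extract_evidence(lx$locus, ann, c(scf = 57), host_stats,
                          lx$scaffolds, cfg)
  expect_false(ev2$depth_comparable)          # 57 > 28*2

  # gc similarity: |scaffold GC - host mean| <= 0.05
  host_stats3 <- list(depth_median = 28, gc_mean = gc_content(s) - 0.03)
  ev3 <- extract_evidence(lx$locus, ann, c(scf = 30), host_stats3,
                          lx$scaffolds, cfg)
  expect_true(ev3$gc_similar)
  host_stats4 <- list(depth_median = 28, gc_mean = gc_content(s) - 0.09)
  ev4 <- extract_evidence(lx$locus, ann, c(scf = 30), host_stats4,
                          lx$scaffolds, cfg)
  expect_false(ev4$gc_similar)

  # missing depth: warning, criterion scores 0
  expect_warning(
    ev5 <- extract_evidence(lx$locus, ann, c(other = 30), host_stats,
                            lx$scaffolds, cfg),
    "no depth entry")
  expect_false(ev5$depth_comparable)
  expect_true(is.na(ev5$locus_depth))
})

test_that("scoring weights and class partition match the published scheme", {
  feats <- c("premature_stop", "depth_comparable",
             "eukaryotic_gene_on_scaffold", "te_on_scaffold",
             "gc_similar", "scaffold_exceeds_viral_size")
  none <- setNames(rep(FALSE, 6), feats)

  only_stop <- none; only_stop["premature_stop"] <- TRUE
  r <- score_eve(only_stop)
  expect_equal(r$points, 2L)
  expect_equal(r$class, "low")

  all_true <- setNames(rep(TRUE, 6), feats)
  r2 <- score_eve(all_true)
  expect_equal(r2$points, 7L)
  expect_equal(r2$class, "high")

  r3 <- score_eve(none)
  expect_equal(r3$points, 0L)
  expect_equal(r3$class, "low")

  # every single-feature score
  for (f in feats) {
    e <- none; e[f] <- TRUE
    expect_equal(score_eve(e)$points, if (f == "premature_stop") 2L else 1L)
  }

  # the classes partition 0..7 exactly as {0,1,2}, {3,4}, {5,6,7}
  expect_equal(classify_score(0:7),
               c("low", "low", "low", "medium", "medium",
                 "high", "high", "high"))
  # monotone step function
  expect_true(all(diff(match(classify_score(0:7),
                             c("low", "medium", "high"))) >= 0))
})

test_that("scoring is evidence-order independent and idempotent", {
  feats <- c("premature_stop", "depth_comparable",
             "eukaryotic_gene_on_scaffold", "te_on_scaffold",
             "gc_similar", "scaffold_exceeds_viral_size")
  withr::local_seed(86)
  ev <- as.data.frame(setNames(lapply(feats, function(f)
    sample(c(TRUE, FALSE), 20, TRUE)), feats))
  a <- score_eve(ev)
  b <- score_eve(ev[, sample(feats)])
  expect_equal(a$points, b$points)
  expect_equal(score_eve(a)$points, a$points)
})

test_that("census counts classes and builds the presence matrix", {
  scores <- data.frame(
    scaffold_id = c("s1", "s1", "s2"),
    best_query = c("pif1", "dnapol", "pif1"),
    class = c("high", "medium", "low"),
    stringsAsFactors = FALSE)
  cs <- census(scores, threshold_class = "low")
  expect_equal(cs$n_candidates, 3L)
  expect_equal(cs$by_class, c(low = 1L, medium = 1L, high = 1L))
  expect_true(all(cs$presence[cbind(c("s1", "s1", "s2"),
                                    c("pif1", "dnapol", "pif1"))]))
  cs_high <- census(scores, threshold_class = "high")
  expect_equal(sum(cs_high$presence), 1L)
  expect_true(cs_high$presence["s1", "pif1"])

  empty <- census(scores[0, ])
  expect_equal(empty$n_candidates, 0L)
  expect_equal(sum(empty$by_class), 0L)
})
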