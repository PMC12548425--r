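test_that("back-translation expands columns and validates the CDS", {
  prot <- c(a = "M-K", b = "MGK")
  cds <- c(a = "ATGAAA", b = "ATGGGGAAA")
  ca <- back_translate_alignment(prot, cds)
  expect_equal(unname(ca["a"]), "ATG---AAA")
  expect_equal(unname(ca["b"]), "ATGGGGAAA")

  # round-trip: degap + translate returns the inputs
  degap <- unname(gsub("-", "", ca["a"]))
  expect_equal(degap, unname(cds["a"]))
  expect_equal(paste(evescreen:::translate_codons(
    evescreen:::codons_of(degap, 0)), collapse = ""), "MK")

  expect_error(back_translate_alignment(prot, c(a = "ATGTAAAAA", b = cds[["b"]])),
               "internal stop")
  expect_error(back_translate_alignment(prot, c(a = "ATGCCC", b = cds[["b"]])),
               "mismatch at residue 2")
  # trailing stop on the CDS is tolerated
  ca2 <- back_translate_alignment(prot, c(a = "ATGAAATAA", b = cds[["b"]]))
  expect_equal(unname(ca2["a"]), "ATG---AAA")
})

test_that("NG86 identities on hand-counted cases", {
  cds <- evescreen:::generate_cds(100, seed = 91)
  r0 <- ng86_dnds(cds, cds)
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$omega))                 # 0/0 undefined
  expect_equal(r0$N_sites + r0$S_sites, 3 * r0$n_codons)

  # TTT vs TTC among nine invariant GGG codons, all by hand:
  # TTT/TTC contribute 1/3 synonymous site each, GGG exactly 1;
  # the single difference is synonymous (Phe -> Phe)
  s1 <- paste0("TTT", strrep("GGG", 9))
  s2 <- paste0("TTC", strrep("GGG", 9))
  r <- ng86_dnds(s1, s2)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S_sites, 28 / 3)
  expect_equal(r$N_sites, 62 / 3)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, -3 / 4 * log(1 - 4 / 3 * (3 / 28)))
  expect_equal(r$omega, 0)
  expect_true(r$purifying)

  # one nonsynonymous difference: TTT -> ATT (Phe -> Ile)
  r2 <- ng86_dnds(paste0("TTT", strrep("GGG", 9)),
                  paste0("ATT", strrep("GGG", 9)))
  expect_equal(r2$Sd, 0)
  expect_equal(r2$Nd, 1)
  expect_equal(r2$dS, 0)
  expect_true(is.na(r2$omega))                 # dS = 0

  # gap columns are excluded
  r3 <- ng86_dnds(paste0("---", strrep("GGG", 9)),
                  paste0("TTC", strrep("GGG", 9)))
  expect_equal(r3$n_codons, 9)
  expect_error(ng86_dnds("TAAGGG", "TAAGGG"), "stop")
})

test_that("NG86 estimates are invariant to codon-column permutation", {
  withr::local_seed(92)
  cds <- evescreen:::generate_cds(80)
  mut <- evolve_codons(cds, omega = 0.5, t = 0.4)$cds
  r1 <- ng86_dnds(cds, mut)
  idx <- sample(80)
  shuffle <- function(s) paste(evescreen:::codons_of(s, 0)[idx], collapse = "")
  r2 <- ng86_dnds(shuffle(cds), shuffle(mut))
  expect_equal(r1$omega, r2$omega)
  expect_equal(r1$Sd, r2$Sd)
  expect_equal(r1$Nd, r2$Nd)
})

test_that("NG86 recovers simulated omega at moderate divergence", {
  ests <- vapply(1:5, function(i) {
    cds <- evescreen:::generate_cds(300, seed = 400 + i)
    mut <- evolve_codons(cds, omega = 0.2, t = 0.3, seed = 500 + i)
    ng86_dnds(cds, mut$cds)$omega
  }, 0)
  expect_true(all(abs(ests - 0.2) < 0.15))
})

test_that("purifying screen flags omega < 1 and sets undefined aside", {
  mk <- function(om) structure(list(omega = om), class = "selection_result")
  res <- list(mk(0.3), mk(1.2), mk(NA_real_), mk(0.99))
  ps <- purifying_screen(res)
  expect_equal(ps$purifying, c(TRUE, FALSE, NA, TRUE))
  expect_equal(ps$n_purifying, 2)
  expect_equal(ps$n_not, 1)
  expect_equal(ps$n_undefined, 1)
})

test_that("patristic distances are path sums of branch lengths", {
  tr <- ape::read.tree(text = "((A:1,B:2):3,C:4);")
  d <- patristic_matrix(tr)
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 8)
  expect_equal(d["B", "C"], 9)
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))

  star <- ape::read.tree(text = "(A:2.5,B:2.5,C:2.5,D:2.5);")
  ds <- patristic_matrix(star)
  expect_true(all(ds[upper.tri(ds)] == 5))
})

test_that("patristic matrix equals graph shortest paths on random trees", {
  skip_if_not_installed("igraph")
  withr::local_seed(93)
  for (i in 1:3) {
    tr <- random_tree(20)
    got <- patristic_matrix(tr)
    want <- patristic_oracle(tr)
    expect_equal(got, want[rownames(got), colnames(got)], tolerance = 1e-9)
    expect_equal(got, t(got))
    # four-point condition on random quartets (tree metric)
    for (k in 1:10) {
      q <- sample(rownames(got), 4)
      sums <- c(got[q[1], q[2]] + got[q[3], q[4]],
                got[q[1], q[3]] + got[q[2], q[4]],
                got[q[1], q[4]] + got[q[2], q[3]])
      expect_lte(max(sums) - sort(sums, decreasing = TRUE)[2], 1e-9)
    }
  }
})

test_that("family distance summaries enumerate within/between pairs", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  d <- patristic_matrix(tr)
  fam <- c(A = "X", B = "X", C = "Y", D = "Y")
  s <- family_distance_summary(d, fam)
  within <- s$pooled[s$pooled$type == "within", ]
  between <- s$pooled[s$pooled$type == "between", ]
  expect_equal(within$n_pairs, 2)
  expect_equal(within$min, 2)
  expect_equal(within$max, 2)
  expect_equal(between$n_pairs, 4)
  expect_equal(between$min, 6)
  expect_equal(between$max, 6)
  xy <- s$pairs[s$pairs$family_a == "X" & s$pairs$family_b == "Y", ]
  expect_equal(xy$type, "between")
  expect_equal(xy$mean, 6)

  one <- family_distance_summary(d, c(A = "F", B = "F", C = "F", D = "F"))
  expect_true(!"between" %in% one$pooled$type)   # between summary empty

  expect_warning(
    family_distance_summary(d, c(A = "X", B = "X", C = "Y", D = "Z")),
    "singleton")
  expect_error(family_distance_summary(d, c(A = "X", B = "X", C = "Y")),
               "no family")

  # clustered clades: pooled within max < between min by construction
  fam_tree <- ape::read.tree(
    text = "(((A:0.1,B:0.2):3,(C:0.1,D:0.3):3):1,((E:0.2,F:0.1):3,G:4):1);")
  dd <- patristic_matrix(fam_tree)
  fm <- c(A = "f1", B = "f1", C = "f2", D = "f2", E = "f3", F = "f3", G = "f4")
  s2 <- suppressWarnings(family_distance_summary(dd, fm))  # f4 is singleton
  w <- s2$pooled[s2$pooled$type == "within", ]
  b <- s2$pooled[s2$pooled$type == "between", ]
  expect_lt(w$max, b$min)
})

test_that("reciprocal best hits require mutual bests with stable tie-breaks", {
  ab <- data.frame(query_id = c("a1", "a1", "a2"),
                   subject_id = c("b1", "b2", "b2"),
                   bitscore = c(100, 90, 80), evalue = c(1e-30, 1e-20, 1e-10))
  ba <- data.frame(query_id = c("b1", "b2"),
                   subject_id = c("a1", "a2"),
                   bitscore = c(95, 70), evalue = c(1e-28, 1e-9))
  r <- reciprocal_best_hits(ab, ba)
  expect_equal(r$a_id, c("a1", "a2"))
  expect_equal(r$b_id, c("b1", "b2"))

  # a's best is b, but b's best is c != a: no pair for a
  ab2 <- data.frame(query_id = "a1", subject_id = "b1", bitscore = 50)
  ba2 <- data.frame(query_id = "b1", subject_id = "c9", bitscore = 60)
  expect_equal(nrow(reciprocal_best_hits(ab2, ba2)), 0)

  # random bipartite score matrices agree with brute force and are symmetric
  withr::local_seed(94)
  for (i in 1:5) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    grid <- expand.grid(a = paste0("a", 1:na), b = paste0("b", 1:nb),
                        stringsAsFactors = FALSE)
    sc <- sample(1000, nrow(grid))
    ab3 <- data.frame(query_id = grid$a, subject_id = grid$b, bitscore = sc)
    ba3 <- data.frame(query_id = grid$b, subject_id = grid$a, bitscore = sc)
    got <- reciprocal_best_hits(ab3, ba3)
    want <- rbh_oracle(ab3, ba3)
    expect_equal(got$a_id, want$a_id)
    expect_equal(got$b_id, want$b_id)
    swapped <- reciprocal_best_hits(ba3, ab3)
    expect_setequal(paste(got$a_id, got$b_id),
                    paste(swapped$b_id, swapped$a_id))
  }
})

test_that("synteny ranks trace gene order", {
  orfs_a <- data.frame(id = paste0("g", 1:5), start = c(10, 200, 400, 600, 800),
                       strand = c("+", "+", "-", "+", "-"))
  pairs <- data.frame(a_id = paste0("g", 1:5), b_id = paste0("h", 1:5))

  same <- orfs_a; same$id <- paste0("h", 1:5)
  sy <- synteny_orders(orfs_a, same, pairs)
  expect_equal(sy$rank_a, 1:5)
  expect_equal(sy$rank_b, 1:5)
  expect_true(all(sy$strand_agree))

  revd <- data.frame(id = paste0("h", 1:5), start = rev(c(10, 200, 400, 600, 800)),
                     strand = c("+", "+", "-", "+", "-"))
  sy2 <- synteny_orders(orfs_a, revd, pairs)
  expect_equal(sy2$rank_b, 5:1)

  withr::local_seed(95)
  perm <- sample(5)
  shuf <- data.frame(id = paste0("h", 1:5), start = c(10, 200, 400, 600, 800)[perm],
                     strand = "+")
  sy3 <- synteny_orders(orfs_a, shuf, pairs)
  expect_equal(sy3$rank_b, perm)   # start of h_i is the perm[i]-th smallest

  expect_error(synteny_orders(orfs_a, same,
                              rbind(pairs, data.frame(a_id = "g1", b_id = "h9"))),
               "more than once")
})
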