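---
title: "Detecting and scoring endogenous viral elements with evescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring endogenous viral elements with evescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evescreen)
```

## The problem

Large double-stranded DNA viruses of arthropods (class *Naldaviricetes* —
baculoviruses, nudiviruses, hytrosaviruses, filamentoviruses and their
relatives, including the recently described filamentous viruses of ants and
bees) occasionally integrate fragments of their genomes into the germline of
their hosts. These endogenous viral elements (EVEs) persist as slowly
decaying fossils: they accumulate premature stop codons and indels, sit next
to host genes and transposable elements, and are inherited vertically.
Finding them in genome assemblies, and deciding whether a match is a real
chromosomal insertion rather than contaminating exogenous virus, is the core
analytical task this package automates, together with the descriptive
genomics around it: viral genome features (GC, ORFs, coding density, repeat
structure), selection analysis on EVE/virus homolog pairs, and
phylogenetic/synteny summaries.

The package is organised as a pipeline of small, testable operations:

1. **Feature computation** — `gc_content()`, `find_orfs()`,
   `coding_density()`, `find_tandem_repeats()`, `find_inverted_repeats()`.
2. **Translated homology screen** — `six_frame_translate()`,
   `search_translated()`, `filter_hits()`, `merge_adjacent_hits()`.
3. **Confidence scoring** — `detect_premature_stops()`,
   `extract_evidence()`, `score_eve()`, `census()`.
4. **Molecular evolution** — `ng86_dnds()`, `purifying_screen()`,
   `patristic_matrix()`, `family_distance_summary()`,
   `reciprocal_best_hits()`, `synteny_orders()`.
5. **Synthetic data with ground truth** — `generate_host_scaffold()`,
   `generate_viral_genome()`, `implant_eves()`, `evolve_codons()`.

## The screen and the scoring model

Viral proteins are compared against host scaffolds in all six reading
frames. Hits survive only with an e-value strictly below `1e-5` **and**
query coverage strictly above 20%; surviving hits on the same scaffold are
merged into one locus whenever the next hit starts within 10 bp of the
current merged end. These three thresholds are the published screen and are
the defaults in `eve_config()`.

Each merged locus is then scored with an additive six-feature scheme:

| evidence feature                          | points |
|-------------------------------------------|:------:|
| premature stop codons in the locus         | 2 |
| sequencing depth comparable to host scaffolds | 1 |
| annotated (insect-assigned) gene on the scaffold | 1 |
| transposable element on the scaffold       | 1 |
| GC content similar to host scaffolds       | 1 |
| scaffold longer than 500 kb                | 1 |

Total points classify the locus as **high** confidence (more than 4 points),
**medium** (3–4), or **low** (2 or fewer). The three classes partition the
score range 0–7 exactly as {0,1,2}, {3,4}, {5,6,7}; this partition is
asserted verbatim in the test suite.

Two of the six criteria are qualitative in the original description
("comparable" depth, "similar" GC). The package fixes them as: depth within
a factor `depth_comparable_factor` (default 2) of the median depth of
background host scaffolds, and GC within `gc_similarity_delta` (default
0.05, absolute) of the background mean. Both knobs sit in `eve_config()`,
and `extract_evidence()` always reports the underlying numbers next to the
booleans so a user can re-threshold without rerunning the screen. The
background itself is the set of scaffolds that carry at least one
insect-assigned gene and no candidate locus (`host_background()`) — a
BUSCO-free approximation of "host scaffolds". Unavailable evidence (e.g. a
scaffold missing from the depth table) scores 0 rather than being imputed;
the additive scheme makes this the conservative choice.

Insect taxonomy assignment of genes is consumed as an input flag
(`taxon=insect` in the GFF3 attributes), not computed: the original
assignment requires a protein database search that is out of scope here.

## The built-in translated search

`search_translated()` is a desk-scale TBLASTN analogue: exact 4-mer seeds
(two seeds within a diagonal neighbourhood are required, as in BLAST's
two-hit heuristic), followed by exact Smith–Waterman alignment with BLOSUM62
and affine gaps (open 11, extend 1) over the seeded window, implemented in
C++. As in BLAST, alignments are cut at internal score dips deeper than an
X-drop threshold (`search_x_drop`, default 25), so unrelated neighbouring
segments bridged by a chance high-scoring island are reported as separate
hits rather than one alignment spanning junk. E-values use the
Karlin–Altschul form `E = K·m·n·exp(−λS)` with fixed
published ungapped BLOSUM62 constants (λ = 0.3176, K = 0.134), with `m` the
query length in residues and `n` the scaffold length in nucleotides. Two
consequences users should know:

* the e-values are approximate (ungapped constants, no edge-length or
  composition corrections) and are meant for ranking and for the 1e-5
  filter at matched scale — not for cross-tool comparison;
* the search is a heuristic in the same sense BLAST is: alignments are
  optimal within seeded windows, and the test suite checks agreement with a
  full dynamic-programming oracle for everything above the reporting floor.
  For production-scale screens, tabular hits from an external search can be
  supplied instead (`read_tabular_hits()`); the filter/merge/score stages
  are exact and identical in both routes.

Stops encountered in a translated frame align like any other column (the
BLOSUM62 `*` row, −4 against residues), so a single premature stop inside an
otherwise well-conserved region does not split the alignment — which is what
lets `detect_premature_stops()` see those stops inside hit spans.

## ORF calling and repeat conventions

`find_orfs()` reports maximal ATG-to-stop spans per frame (nested ATGs are
not reported separately), on both strands, with the standard genetic code.
On circular sequences frames continue across the origin and wrapped calls
are flagged. The minimum length default is 150 nt (50 aa) including the
stop codon — a conventional small-protein floor; the original ORF counts
depend on an unstated threshold, so the value is config-exposed.
`coding_density()` reports both the literal "sum of ORF bases over genome
bases" (overlaps double-counted; the default, matching the stated
definition) and the union variant; `union <= sum` always, with equality iff
no ORFs overlap.

`find_tandem_repeats()` follows the etandem convention: arrays of two or
more adjacent unit copies scored +1 per position matching the per-column
majority consensus and −1 per mismatch, reported at score ≥ 100 (the
published cutoff). Overlapping arrays at different unit lengths collapse to
the highest score, ties preferring the shorter unit then the leftmost
start. `find_inverted_repeats()` seeds 12-mers of the sequence against its
reverse complement, extends along diagonals, and trims each candidate to
its maximal-scoring stretch (+1/−1, Kadane) — this trimming, rather than
greedy run-bridging, is what makes arm boundaries reproducible; arm pairs
are selected greedily by identity × length with each position used once.
Exact EMBOSS tie-breaking is not reproduced, so repeat *counts* on real
genomes should be compared with tolerance.

## NG86 selection analysis

The dN/dS machinery replaces a maximum-likelihood codon model with the
Nei–Gojobori (1986) counting method plus Jukes–Cantor correction:
synonymous site counts per codon are the per-position fractions of
single-base changes preserving the amino acid (changes creating stops count
as nonsynonymous, so every codon contributes exactly 3 sites and
`N + S = 3 × codons` holds as an invariant); differences are averaged over
all shortest substitution paths, excluding paths through stop codons unless
every path is blocked. `omega = dN/dS` is undefined when `dS = 0` or when a
proportion reaches the Jukes–Cantor pole (`p ≥ 3/4`); such results carry
explicit flags and are excluded-but-counted by `purifying_screen()`.

This is a deliberate approximation: NG86 is closed-form, dependency-free
and unbiased under the unweighted substitution model the synthetic
generator uses, but it ignores transition/transversion bias and codon
frequencies. The supported claim is therefore the binary purifying call
(`omega < 1`), not the exact omega. On simulated data (500 codons, one
expected substitution per codon), the estimator recovers the ordering of
omegas {0.1, 0.5, 1.0, 2.0} in 100/100 seeded replicates and mildly
underestimates high omegas (mean ≈ 1.7 at true 2.0) — the JC correction
amplifies dS noise when synonymous events are few; the tests assert the
ordering property, which is robust to this bias.

## What the synthetic generator emulates — and what it does not

`implant_eves()` builds a cohort in which every downstream number is known
in advance: host scaffolds at GC 0.38 (viral implants at 0.52, so the GC
criterion is exercised in both directions), sequencing depth 30× for host
background with 5× inflation marking "non-comparable" scaffolds, gene/TE
annotations placed per profile, scaffold lengths crossing the 500 kb bound
when the length criterion is requested, and viral gene copies degraded by
substitutions (rate 0–0.05), injected internal stop codons, and
fragmentation with gaps on both sides of the 10-bp merge rule. The default
50-element cohort (`eve_profiles()`) forces total scores 0, 2, 3, 4, 5, 6
and 7, covering every class boundary.

Fragmentation details matter for exact truth bookkeeping and are worth
stating: inter-fragment gaps are padded with stop codons and kept off
multiples of 3, so the downstream fragment is frameshifted and each
fragment yields its own hit; split-fate junctions (gaps 17–20 bp) are
preferentially placed where the upstream protein residues are
alignment-hostile to the pad's translation, so neither hit can nibble into
the pad and drag the observed gap under the merge threshold. Like the viral
genome generator — which verifies its implanted ORF set with `find_orfs()`
and re-draws offending blocks — the implant generator verifies each
element with the screen itself (search, filter, merge, stop detection) and
moves the fragmentation cut to the next candidate until the element's
recorded locus structure is exactly realised; a profile that cannot be
realised raises an error rather than silently shifting the truth. Problem sizes
throughout (scaffolds of 20–40 kb, long-scaffold cases at ~500 kb, 10-gene
viral genomes, 500-codon selection simulations, 100-replicate sweeps) were
chosen as the smallest sets that exercise every rule and boundary; the full
suite runs in a few minutes on one CPU.

What the generator does **not** emulate: sequencing error and assembly
artefacts, indel degradation of EVEs (substitutions and stops only, so
codon alignments never need gap handling in the screen), host repeat
families that could cross-hit viral queries, transcriptional activity, and
real phylogenetic structure among implants. Passing the end-to-end recovery
test therefore demonstrates that the pipeline's logic is exact under its
stated model of endogenisation — not that recall on real, deeply diverged
EVEs matches the synthetic recall of 1.0.

## Numerical and design choices

* Coordinates are 1-based inclusive at every interface (GFF3/BLAST
  convention); BED input is converted on read. Ns count toward length,
  never toward GC numerators or match counts; codons containing N translate
  to X and are dropped from dN/dS comparisons.
* Merging treats "within 10 bp" as `next start − current end <= 10`, merges
  across queries and strands by default (a degraded gene fragments across
  frames and queries; `merge_same_query_only` restricts it), and is
  provably order-independent (sorted per scaffold before clustering).
* Filter boundaries are strict inequalities on both sides, following the
  published wording ("smaller than", "more than"); hits exactly at 1e-5 or
  exactly 20% coverage are removed, and tests pin this.
* Tandem consensus ties take the alphabetically first base; the score is
  tie-invariant, so this only stabilises the reported consensus string.
* Trees are inputs, never inferred; patristic distances are path sums
  computed via ape, checked in tests against an independent graph
  shortest-path oracle. Reported family summaries separate within- from
  between-family leaf pairs and warn on singleton families.
* Reciprocal-best-hit ties break by lower e-value then lexicographic
  subject id, making homolog pairing deterministic.
* All generators are pure functions of their arguments including the seed;
  a fixed `eve_config()` plus seed reproduces every byte of output.

## Known limitations

The e-value model is approximate (see above). The repeat finders are faithful
to the published conventions but not bit-compatible with EMBOSS binaries.
NG86 is a counting approximation to ML omega estimation. The BLASTX-vs-nr
back-validation step of the original screen needs a protein database and is
represented only as an optional annotation column, never computed. Published
headline censuses (thousands of loci across dozens of genome assemblies)
require those assemblies and are out of desk scale; what this package
guarantees is that, given those inputs, every rule it applies is the stated
one.
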