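---
title: "Mining olfactory receptor gene repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining olfactory receptor gene repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ursor)
```

## The problem

Olfactory receptor (OR) genes form the largest mammalian gene family:
intron-less G-protein-coupled receptors of roughly 310 amino acids with
seven transmembrane (TM) helices. A species' olfactory capacity is commonly
summarized by the size and composition of its OR repertoire — how many loci
are intact ("functional": an open reading frame of at least 250 aa), how
many are truncated but undisrupted ("partial"), and how many are
pseudogenized by premature stop codons or frameshifts. Comparative studies
in Ursidae relate these numbers to diet: the bamboo-specialist giant panda
carries a visibly higher pseudogene load than its carnivorous relatives and
lacks matches to several fruit-odorant human receptors.

`ursor` implements the full mining protocol as a reusable, testable
pipeline: translated homology search, locus reconstruction, classification,
family/subfamily clustering, Class I/II placement, odorant-specificity
transfer, motif discovery — plus a synthetic-genome generator that makes
every stage verifiable against planted ground truth at desk scale.

## Search: seeded translated alignment

Queries (known mammalian OR proteins) are compared against all six
translated frames of each chromosome. The search is seed-and-extend:

* exact amino-acid k-mer seeds (`seed_k = 4`), with BLAST-style two-hit
  triggering — an extension is attempted only where two non-overlapping
  seeds fall on one diagonal within a 40-residue window;
* full Smith–Waterman–Gotoh extension (BLOSUM62, gap open 11 / extend 1)
  of the query against a window around the triggered diagonals;
* Karlin–Altschul statistics with the standard gapped-BLOSUM62 parameters
  λ = 0.267, K = 0.041; the search space is the raw product of query
  length and total translated length (no edge correction). Hits with
  E ≤ 1e-10 are kept.

On instances small enough to check exhaustively, the seeded search attains
exactly the optimum found by an unseeded Smith–Waterman over every frame
(tested against an independent implementation); by construction it can
never exceed it. The two-hit heuristic costs sensitivity only below ~40%
identity, beneath the family threshold this pipeline operates at.

Overlapping hits (>50% of the shorter genomic interval) are reduced to the
best one — lowest E-value, ties broken by longer alignment, then query id.
Surviving fragments of one query on one strand are chained into loci when
their genomic gap is at most 5 kb and their query coordinates are colinear
(monotone, overlap ≤ 15 aa). A pseudogene whose reading frame is split by a
frameshift therefore arrives at the next stage as a single chained locus.

## Gene models: frameshift-aware realignment

Each chained locus, extended by 300 bp of flank, is realigned against its
best query with a protein-vs-DNA dynamic program in codon space: codons
normally consume 3 bp, but 2 bp and 4 bp steps are allowed at a penalty of
15 (about the score of three conserved positions — cheap enough to cross a
real lesion, expensive enough not to appear spuriously), and stop codons
align to any residue at the same −15 so the path runs *through* lesions
instead of stopping at them. The model's translation starts at the first
in-frame ATG at or upstream of the aligned start (falling back to the
aligned start — a truncated assembly may have no Met) and runs to the next
stop codon or the aligned end.

Every in-frame stop inside the aligned region becomes a `premature_stop`,
every non-multiple-of-3 step a `frameshift`. Classification is then exactly
the published rule: any disruption ⇒ pseudogene; otherwise ≥250 aa ⇒
functional, else partial. The three labels are exhaustive and exclusive,
so composition counts always add up.

Instead of a profile-HMM check of the 7TM fold, models get a
Kyte–Doolittle hydropathy scan (window 19, threshold 1.6); maximal runs of
hydrophobic windows approximate the helix count, and functional models with
fewer than five are *flagged* low-confidence, never dropped — homology to
an OR query is already required by the search, and a hard structural filter
would silently remove diverged receptors.

## Clustering and classes

Pairwise identity is global (Needleman–Wunsch, BLOSUM62 11/1) with gap
columns counted in the denominator — a stricter and more reproducible
definition than coverage-based shortcuts. Families (>40% identity) and
subfamilies (>60%) come from CD-HIT-style greedy clustering: sequences
sorted by length (ties by id), each joining the first cluster whose
founder it matches at the threshold, else founding a new one. Subfamilies
are clustered within families, so the hierarchy is nested by construction.
A best-fit assignment mode exists behind a flag; the default follows the
first-fit semantics of the reference tool.

Class I ("fish-like", the human OR51/OR52/OR55/OR56 clade) versus Class II
placement does not reimplement maximum-likelihood phylogenetics: each
functional gene takes the class of its nearest human anchor under the
1 − identity distance (ties go to Class II with a warning), and a joint
neighbor-joining tree is emitted for inspection. NJ here is the canonical
Saitou–Nei algorithm with deterministic smallest-index tie-breaking;
negative branch lengths are clamped to zero and counted. On additive
distances it provably recovers the generating topology, which the tests
exercise against an independent implementation.

## Annotation

Genes on one chromosome closer than 1 Mb (gap between gene intervals, not
midpoints) chain into genomic clusters. Odorant specificity is transferred
from a human OR table when the best global identity reaches 60%; the
output keeps the per-human-OR per-species count matrix and, per species,
the human receptors with *no* match — the "lacking" list that drives the
diet interpretation. N-glycosylation sites are the N-X-[S/T] sequon with
the standard X ≠ P exclusion (a consensus scan; no neural network).
Because real human OR protein sequences cannot be bundled, the shipped
reference table carries the published gene/accession/odorant metadata with
synthetic receptor sequences generated by the package itself — sufficient
for exercising every code path, and clearly labelled synthetic.

## Motif discovery

Conserved ungapped motifs are found by ZOOPS (zero-or-one occurrence per
sequence) expectation-maximization: site posteriors in the E-step, a
position frequency matrix with pseudocount 0.1 against the input's 0-order
background in the M-step, convergence at ΔlogL < 1e-4 (cap 200
iterations). Width is searched on the coarse grid {5, 8, 12, 16, 21, 29,
41, 50} within the 5–50 bound; candidates are ranked by the relative log
likelihood penalized BIC-style for the 19 free parameters per column, so
noise columns never pay for themselves and the planted width wins. Because
EM's characteristic failure mode here is a phase-shifted optimum, the best
run of each width is refined by re-seeding from ±1/±2-column shifts of its
site alignment until the likelihood stops improving. Found sites are
masked before the next motif is sought, so the top-k site sets are
disjoint. Everything is deterministic given `rng_seed`.

The log-likelihood is asserted non-decreasing in every run. Logo heights
use the standard scaling: letter probability times column information
content against a uniform alphabet.

## The synthetic generator

The generator is the package's measuring instrument, not a demo. It
emulates exactly the structure the analysis assumes:

* a 7-TM template protein (~307 aa): hydrophobic 23-aa blocks alternating
  with loops, a conserved DRY-like 8-mer after TM3, an initial Met;
* a three-level hierarchy by Poisson substitution — 0.70 expected
  substitutions per mutable site between families, 0.24 between
  subfamilies, 0.10 within subfamilies. Substitutions inside TM blocks are
  drawn from a hydrophobic alphabet (architecture survives divergence);
  the motif and the Met never mutate. The between-subfamily rate is chosen
  so that same-subfamily pairs sit clearly above 60% identity,
  same-family/different-subfamily pairs inside the (40%, 60%) band, and
  cross-family pairs below 40% — the regime the published thresholds
  presuppose — verified empirically over 100 seeds in the tests;
* uniform reverse translation plus a terminal stop, planted on either
  strand of i.i.d. 40% GC background across 3 chromosomes × 3 Mb; a new
  gene joins the current tandem cluster with probability 0.8 at a gap
  below 1 Mb, otherwise starts elsewhere;
* lesions: 20% of genes get 1–3 in-frame stops or ±1 bp frameshifts, 10%
  are 3'-truncated below 250 codons. Lesions stay ≥30 codons from the gene
  ends so that recovery tests measure classification, not boundary-case
  search sensitivity (`lesion_guard_codons = 0` removes the guard).

Search queries are derived by mutating each family consensus at 0.15 —
emulating a cross-species reference set rather than handing the pipeline
its own answers.

What the generator does *not* model, and hence what passing tests do not
show: realistic codon usage and dN/dS structure, repeats and transposons,
assembly gaps and sequencing error, segmental duplications, and genuinely
gradual divergence (real OR families are not clean Poisson clades). Results
on real assemblies depend on query-set coverage in a way no synthetic test
can certify.

## Numerical and boundary choices

* Coordinates are 1-based inclusive externally (GFF3 convention); BED
  output converts to 0-based half-open at the boundary.
* `N` translates to `X`; loci with >10% N are flagged, not dropped.
* A terminal stop codon is never a disruption.
* Percentages round half-up at 2 decimals, matching the printed style of
  repertoire tables (`round()`'s banker's rounding would differ on exact
  halves); a published per-subfamily mean that appears truncated rather
  than rounded is reproduced by recomputation, not by imitating the
  truncation.
* Greedy clustering ties (equal lengths) break lexicographically; NJ ties
  take the smallest index pair; class-assignment ties go to Class II with
  a warning.
* Problem sizes in tests: oracle-checked search instances ≤5 kb,
  brute-force clustering ≤20 sequences, exhaustive motif enumeration at
  width 3 on 4 short sequences, end-to-end recovery on the default 9 Mb /
  60-gene condition.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_or_genome(simulation_spec(rng_seed = 1))
rep <- or_mine(sim$genome, sim$queries,
               anchors = synthetic_human_or_table(seed = 1))
print(rep)
table(truth = sim$truth$class_label)
```

## Known limitations

Single-exon assumption throughout (true for OR coding sequences, wrong for
almost everything else); no composition-based E-value correction, so very
biased sequences can inflate scores; greedy clustering is order-dependent
by design (that is what it reimplements); nearest-anchor class assignment
inherits any bias in the anchor set; odorant annotations are homology
transfer, not evidence of ligand binding.
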