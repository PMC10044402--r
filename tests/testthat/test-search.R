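test_that("six-frame translation matches the standard code", {
  fr <- translate_six_frames("ATGAAATAG")
  expect_equal(fr[["+1"]]$aa, "MK*")
  fr <- translate_six_frames("ATG")
  expect_equal(fr[["+2"]]$aa, "")
  expect_equal(fr[["+3"]]$aa, "")
})

test_that("all six frames agree with an independent codon-table oracle", {
  set.seed(42)
  for (rep in 1:5) {
    dna <- random_dna_t(300 + sample(0:2, 1))
    fr <- translate_six_frames(dna)
    rc <- revcomp_oracle(dna)
    for (off in 1:3) {
      expect_equal(fr[[sprintf("+%d", off)]]$aa,
                   translate_oracle(substr(dna, off, nchar(dna))))
      expect_equal(fr[[sprintf("-%d", off)]]$aa,
                   translate_oracle(substr(rc, off, nchar(rc))))
    }
  }
})

test_that("frame coordinates map back to the right codons", {
  dna <- random_dna_t(99)
  fr <- translate_six_frames(dna)
  for (f in c(1, 2, 3, -1, -2, -3)) {
    key <- sprintf("%+d", f)
    aa <- fr[[key]]$aa
    p <- sample(nchar(aa), 1)
    bp <- aa_to_genome(f, p, p, 99)
    codon <- substr(dna, bp[1], bp[2])
    if (f < 0) codon <- revcomp_oracle(codon)
    expect_equal(translate_oracle(codon), substr(aa, p, p))
  }
})

test_that("a planted identical gene yields one full-coverage identity-1 HSP", {
  set.seed(7)
  q <- random_protein(300)
  fx <- plant_gene_fixture(q, chrom_len = 10000)
  hsps <- search_genome(setNames(q, "q1"), fx$genome)
  expect_gte(nrow(hsps), 1)
  top <- hsps[which.min(hsps$evalue), ]
  expect_equal(top$identity, 1.0)
  expect_equal(c(top$q_start, top$q_end), c(1L, 300L))
  expect_lte(top$evalue, 1e-10)
})

test_that("an unrelated query finds nothing in random sequence", {
  set.seed(8)
  genome <- data.frame(chrom_id = "chr1", sequence = random_dna_t(10000),
                       length_bp = 10000L, stringsAsFactors = FALSE)
  hsps <- search_genome(setNames(random_protein(300), "q1"), genome)
  expect_equal(nrow(hsps), 0)
})

test_that("seeded search attains the exhaustive Smith-Waterman optimum", {
  set.seed(9)
  for (rep in 1:3) {
    q <- random_protein(250)
    hom <- mutate_identity(q, 75)   # ~70% identity homolog
    fx <- plant_gene_fixture(hom, chrom_len = 5000,
                             strand = sample(c("+", "-"), 1))
    hsps <- search_genome(setNames(q, "q1"), fx$genome)
    expect_gte(nrow(hsps), 1)
    best <- max(hsps$raw_score)
    frames <- translate_six_frames(fx$genome$sequence)
    oracle <- max(vapply(frames, function(fr) bs_local_score(q, fr$aa), 0))
    expect_equal(best, oracle)
  }
})

test_that("seeded search never exceeds the exhaustive optimum", {
  set.seed(10)
  q <- random_protein(200)
  hom <- mutate_identity(q, 90)
  fx <- plant_gene_fixture(hom, chrom_len = 4000)
  hsps <- search_genome(setNames(q, "q1"), fx$genome,
                        or_config(evalue_threshold = 1e-3))
  frames <- translate_six_frames(fx$genome$sequence)
  oracle <- max(vapply(frames, function(fr) bs_local_score(q, fr$aa), 0))
  expect_true(all(hsps$raw_score <= oracle + 1e-9))
})

test_that("every HSP interval lies inside its chromosome", {
  set.seed(11)
  q <- random_protein(150)
  fx <- plant_gene_fixture(q, chrom_len = 3000, at = 10)
  hsps <- search_genome(setNames(q, "q1"), fx$genome)
  expect_true(all(hsps$g_start >= 1 & hsps$g_end <= fx$genome$length_bp))
  expect_true(all(hsps$g_start <= hsps$g_end))
})

test_that("lowering the E-value threshold never increases the hit count", {
  set.seed(12)
  q <- random_protein(250)
  fx <- plant_gene_fixture(mutate_identity(q, 60), chrom_len = 8000)
  thresholds <- c(1e-3, 1e-10, 1e-30, 1e-80)
  counts <- vapply(thresholds, function(tt)
    nrow(search_genome(setNames(q, "q1"), fx$genome,
                       or_config(evalue_threshold = tt))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("best-hit retention keeps lowest evalue, then longest alignment", {
  h <- data.frame(query_id = c("qa", "qb"), chrom_id = "chr1",
                  frame = 1L, q_start = 1L, q_end = 280L,
                  g_start = c(1000L, 1100L), g_end = c(1900L, 1950L),
                  raw_score = c(900, 300), score = c(250, 90),
                  evalue = c(1e-30, 1e-12), identity = c(0.9, 0.5),
                  length = c(300L, 290L), stringsAsFactors = FALSE)
  kept <- retain_best_hits(h)
  expect_equal(kept$query_id, "qa")

  h$evalue <- c(1e-20, 1e-20)
  h$length <- c(280L, 200L)
  kept <- retain_best_hits(h)
  expect_equal(kept$query_id, "qa")
  expect_equal(kept$length, 280L)

  h$g_start <- c(1000L, 50000L); h$g_end <- c(1900L, 50900L)
  expect_equal(nrow(retain_best_hits(h)), 2)
})

test_that("chaining merges colinear fragments and splits the rest", {
  base <- data.frame(query_id = "q1", chrom_id = "chr1", frame = 1L,
                     q_start = c(1L, 60L), q_end = c(50L, 110L),
                     g_start = c(1000L, 1300L), g_end = c(1150L, 1450L),
                     raw_score = 100, score = 50, evalue = c(1e-20, 1e-18),
                     identity = 0.9, length = 50L, stringsAsFactors = FALSE)
  ch <- chain_hsps(base)
  expect_equal(nrow(ch), 1)
  expect_equal(c(ch$span_start, ch$span_end), c(1000L, 1450L))
  expect_equal(ch$best_query_id, "q1")

  far <- base; far$g_start[2] <- 51300L; far$g_end[2] <- 51450L
  expect_equal(nrow(chain_hsps(far)), 2)

  anti <- base; anti$q_start <- c(60L, 1L); anti$q_end <- c(110L, 50L)
  expect_equal(nrow(chain_hsps(anti)), 2)
})

test_that("each HSP lands in exactly one chain", {
  set.seed(13)
  sim <- simulate_or_genome(simulation_spec(
    n_chromosomes = 1L, chromosome_length_bp = 400000L, n_families = 2L,
    subfamilies_per_family = 1L, genes_per_subfamily = 3L,
    fraction_pseudogene = 0.3, fraction_partial = 0, rng_seed = 13L))
  hsps <- retain_best_hits(search_genome(sim$queries, sim$genome))
  chains <- chain_hsps(hsps)
  members <- unlist(chains$members)
  expect_equal(sort(members), seq_len(nrow(hsps)))
})
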