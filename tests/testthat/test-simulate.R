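test_that("zero divergence reproduces the consensus exactly", {
  spec <- simulation_spec(within_subfamily_divergence = 0,
                          between_subfamily_divergence = 0,
                          between_family_divergence = 0, rng_seed = 81L)
  gen <- generate_or_proteins(spec)
  expect_true(all(gen$proteins$sequence == gen$template$sequence))
})

test_that("generator calibration: same subfamily > 60%, different family < 40%", {
  same_ok <- 0; diff_ok <- 0
  for (seed in 1:100) {
    spec <- simulation_spec(n_families = 2L, subfamilies_per_family = 1L,
                            genes_per_subfamily = 2L, rng_seed = seed)
    gen <- generate_or_proteins(spec)
    p <- gen$proteins
    same <- pairwise_identity(p$sequence[p$subfamily_id == "F01.S01"][1],
                              p$sequence[p$subfamily_id == "F01.S01"][2])
    diff <- pairwise_identity(p$sequence[p$family_id == "F01"][1],
                              p$sequence[p$family_id == "F02"][1])
    same_ok <- same_ok + (same > 0.60)
    diff_ok <- diff_ok + (diff < 0.40)
  }
  expect_gte(same_ok, 99)
  expect_gte(diff_ok, 99)
})

test_that("lesion fractions translate into planted class labels", {
  spec <- simulation_spec(n_chromosomes = 1L,
                          chromosome_length_bp = 800000L,
                          n_families = 2L, subfamilies_per_family = 2L,
                          genes_per_subfamily = 5L,
                          fraction_pseudogene = 0, fraction_partial = 0,
                          rng_seed = 82L)
  gen <- generate_or_proteins(spec)
  planted <- plant_genes(gen, spec)
  expect_true(all(planted$truth$class_label == "functional"))
  expect_true(all(planted$truth$lesions == ""))

  spec2 <- simulation_spec(n_chromosomes = 1L,
                           chromosome_length_bp = 800000L,
                           n_families = 2L, subfamilies_per_family = 2L,
                           genes_per_subfamily = 5L,
                           fraction_pseudogene = 0.2,
                           fraction_partial = 0.1, rng_seed = 83L)
  planted2 <- plant_genes(generate_or_proteins(spec2), spec2)
  tab <- table(planted2$truth$class_label)
  expect_equal(unname(tab["pseudogene"]), 4L)    # 20% of 20
  expect_equal(unname(tab["partial"]), 2L)       # 10% of 20
  expect_true(all(nchar(planted2$truth$protein[
    planted2$truth$class_label == "partial"]) < 250))
  expect_true(all(nzchar(planted2$truth$lesions) ==
                    (planted2$truth$class_label == "pseudogene")))
})

test_that("lesion-free planted genes retranslate to their source protein", {
  spec <- simulation_spec(n_chromosomes = 1L,
                          chromosome_length_bp = 600000L,
                          n_families = 2L, subfamilies_per_family = 1L,
                          genes_per_subfamily = 3L,
                          fraction_pseudogene = 0, fraction_partial = 0,
                          rng_seed = 84L)
  planted <- plant_genes(generate_or_proteins(spec), spec)
  tr <- planted$truth
  for (i in seq_len(nrow(tr))) {
    seg <- substr(planted$genome$sequence[
      match(tr$chrom_id[i], planted$genome$chrom_id)],
      tr$start[i], tr$end[i])
    if (tr$strand[i] == "-") seg <- revcomp_oracle(seg)
    aa <- translate_oracle(seg)
    expect_equal(sub("\\*$", "", aa), tr$protein[i])
  }
})

test_that("planted coordinates are non-overlapping and inside chromosomes", {
  spec <- simulation_spec(rng_seed = 85L)
  planted <- plant_genes(generate_or_proteins(spec), spec)
  tr <- planted$truth
  expect_true(all(tr$start >= 1))
  expect_true(all(tr$end <= spec$chromosome_length_bp))
  for (ch in unique(tr$chrom_id)) {
    tt <- tr[tr$chrom_id == ch, ]
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1)
      expect_true(all(tt$start[-1] > tt$end[-nrow(tt)]))
  }
})

test_that("truth cluster membership matches the 1 Mb rule applied directly", {
  spec <- simulation_spec(rng_seed = 86L)
  planted <- plant_genes(generate_or_proteins(spec), spec)
  tr <- planted$truth
  # independent single-linkage enumeration of the <1 Mb rule
  for (ch in unique(tr$chrom_id)) {
    tt <- tr[tr$chrom_id == ch, ]
    tt <- tt[order(tt$start), ]
    expected_breaks <- which(tt$start[-1] - tt$end[-nrow(tt)] >= 1e6)
    got_breaks <- which(tt$cluster_id[-1] != tt$cluster_id[-nrow(tt)])
    expect_equal(got_breaks, expected_breaks)
  }
})

test_that("generation is byte-identical under a fixed seed", {
  s1 <- simulate_or_genome(simulation_spec(
    n_chromosomes = 1L, chromosome_length_bp = 500000L, n_families = 2L,
    subfamilies_per_family = 1L, genes_per_subfamily = 3L, rng_seed = 87L))
  s2 <- simulate_or_genome(simulation_spec(
    n_chromosomes = 1L, chromosome_length_bp = 500000L, n_families = 2L,
    subfamilies_per_family = 1L, genes_per_subfamily = 3L, rng_seed = 87L))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$queries, s2$queries)
})

test_that("simulation spec validates fractions and divergence ordering", {
  expect_error(simulation_spec(fraction_pseudogene = 0.8,
                               fraction_partial = 0.3), "fractions")
  expect_error(simulation_spec(within_subfamily_divergence = 0.9,
                               between_family_divergence = 0.5),
               "divergence")
})
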