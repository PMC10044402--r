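test_that("pairwise identity matches hand-checked examples", {
  expect_equal(pairwise_identity("MKTW", "MKTW"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAC"), 0.75)
})

test_that("global alignment scores equal the Biostrings oracle", {
  set.seed(31)
  for (rep in 1:20) {
    a <- random_protein(50)
    b <- if (rep %% 2) random_protein(50) else mutate_identity(a, 15)
    al <- ursor:::cpp_global_align(a, b, ursor:::blosum62(), 11, 1)
    expect_equal(al$score, bs_global_score(a, b))
  }
})

test_that("identity matrix is symmetric with unit diagonal", {
  set.seed(32)
  seqs <- setNames(vapply(1:5, function(i) random_protein(40), ""),
                   paste0("p", 1:5))
  im <- identity_matrix(seqs)
  expect_equal(im, t(im))
  expect_equal(unname(diag(im)), rep(1, 5))
  expect_true(all(im >= 0 & im <= 1))
})

test_that("greedy clustering respects the family/subfamily thresholds", {
  set.seed(33)
  a <- random_protein(100)
  near <- mutate_identity(a, 25)    # ~75% identity pair
  id <- pairwise_identity(a, near)
  expect_gt(id, 0.60)
  cl <- greedy_cluster(setNames(c(a, near), c("x", "y")), 0.60)
  expect_equal(nrow(cl), 1)
  far <- mutate_identity(a, 55)     # between the two thresholds
  idf <- pairwise_identity(a, far)
  expect_true(idf > 0.40 && idf < 0.60)
  cl40 <- greedy_cluster(setNames(c(a, far), c("x", "y")), 0.40)
  cl60 <- greedy_cluster(setNames(c(a, far), c("x", "y")), 0.60)
  expect_equal(nrow(cl40), 1)
  expect_equal(nrow(cl60), 2)
})

test_that("greedy clustering equals the brute-force oracle", {
  set.seed(34)
  for (rep in 1:3) {
    base <- random_protein(60)
    seqs <- c(vapply(1:4, function(i) mutate_identity(base, 10), ""),
              vapply(1:3, function(i) random_protein(55 + i), ""),
              vapply(1:3, function(i) mutate_identity(base, 30), ""))
    names(seqs) <- sprintf("s%02d", 1:10)
    im <- identity_matrix(seqs)
    for (thr in c(0.4, 0.6)) {
      cl <- greedy_cluster(seqs, thr)
      got <- setNames(rep(cl$representative_id, cl$n_members)[
        order(unlist(cl$members))], sort(unlist(cl$members)))
      want <- greedy_oracle(seqs, thr, im)
      expect_equal(got[names(want)], want)
    }
  }
})

test_that("clusters partition the input and grow with the threshold", {
  set.seed(35)
  base <- random_protein(80)
  seqs <- setNames(c(vapply(1:6, function(i) mutate_identity(base, sample(5:40, 1)), ""),
                     vapply(1:6, function(i) random_protein(75), "")),
                   sprintf("q%02d", 1:12))
  n_prev <- 0
  for (thr in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
    cl <- greedy_cluster(seqs, thr)
    expect_setequal(unlist(cl$members), names(seqs))
    expect_equal(sum(cl$n_members), length(seqs))
    expect_gte(nrow(cl), n_prev)
    n_prev <- nrow(cl)
  }
})

test_that("every member matches its representative at the threshold", {
  set.seed(36)
  base <- random_protein(70)
  seqs <- setNames(vapply(1:8, function(i) mutate_identity(base, sample(3:30, 1)), ""),
                   sprintf("m%d", 1:8))
  cl <- greedy_cluster(seqs, 0.6)
  for (i in seq_len(nrow(cl))) {
    rep_seq <- seqs[[cl$representative_id[i]]]
    for (m in cl$members[[i]])
      expect_gte(pairwise_identity(seqs[[m]], rep_seq), 0.6)
  }
})

test_that("subfamilies nest inside families and planted structure is recovered", {
  spec <- simulation_spec(n_families = 3L, subfamilies_per_family = 2L,
                          genes_per_subfamily = 3L, rng_seed = 37L)
  gen <- generate_or_proteins(spec)
  seqs <- setNames(gen$proteins$sequence, gen$proteins$id)
  cl <- cluster_families(seqs)
  expect_equal(nrow(cl$families), 3)
  expect_equal(nrow(cl$subfamilies), 6)
  # nesting: each subfamily's members are a subset of its family's members
  for (i in seq_len(nrow(cl$subfamilies))) {
    fam <- cl$subfamilies$family_id[i]
    fmem <- cl$families$members[[match(fam, cl$families$cluster_id)]]
    expect_true(all(cl$subfamilies$members[[i]] %in% fmem))
  }
  # recovered families equal the planted partition
  truth_split <- split(gen$proteins$id, gen$proteins$family_id)
  got_split <- cl$families$members
  expect_setequal(lapply(got_split, sort), lapply(truth_split, sort))
})

test_that("species cluster comparison matches exhaustive enumeration", {
  cl <- data.frame(cluster_id = paste0("C", 1:3))
  cl$species_set <- list(c("A", "B"), "A", "A")
  res <- compare_species_clusters(cl)
  uc <- attr(res, "unique_counts")
  expect_equal(unname(uc["A"]), 2L)
  expect_equal(res$n_clusters[res$species_subset == "A+B"], 1L)

  cl$species_set <- list(c("A", "B"), c("A", "B"), c("A", "B"))
  res <- compare_species_clusters(cl)
  expect_equal(length(attr(res, "unique_counts")), 0)

  set.seed(38)
  sp <- c("A", "B", "C")
  sets <- lapply(1:12, function(i) sort(sample(sp, sample(1:3, 1))))
  cl <- data.frame(cluster_id = paste0("R", 1:12))
  cl$species_set <- sets
  res <- compare_species_clusters(cl)
  sig <- vapply(sets, paste, "", collapse = "+")
  for (i in seq_len(nrow(res)))
    expect_equal(res$n_clusters[i],
                 sum(sig == res$species_subset[i]))
  expect_equal(sum(res$n_clusters), 12L)
})
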