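planted_motif_seqs <- function(n = 20, len = 50, motif = "DRYVAICK",
                               noise = 0) {
  w <- nchar(motif)
  vapply(1:n, function(i) {
    bg <- sample(AA20_T, len, TRUE)
    off <- sample(len - w + 1, 1)
    site <- strsplit(motif, "")[[1]]
    if (noise > 0) {
      flip <- runif(w) < noise
      site[flip] <- sample(AA20_T, sum(flip), TRUE)
    }
    bg[off:(off + w - 1)] <- site
    paste(bg, collapse = "")
  }, "")
}

test_that("logo heights follow the standard scaling", {
  pfm <- matrix(1 / 20, 3, 20, dimnames = list(NULL, ursor:::AA20))
  pfm[2, ] <- 0; pfm[2, "W"] <- 1
  h <- motif_logo_table(pfm)
  expect_equal(unname(h[1, ]), rep(0, 20))        # uniform column
  expect_equal(unname(h[2, "W"]), log2(20))       # fully conserved column
  # heights per column sum to the column information content
  ic2 <- log2(20) + sum(ifelse(pfm[2, ] > 0, pfm[2, ] * log2(pfm[2, ]), 0))
  expect_equal(sum(h[2, ]), ic2)
})

test_that("EM log-likelihood never decreases across iterations", {
  set.seed(61)
  seqs <- planted_motif_seqs(12, 40, noise = 0.1)
  names(seqs) <- paste0("s", seq_along(seqs))
  enc <- ursor:::encode_aa(seqs)
  bg <- ursor:::background_freqs(enc)
  th <- ursor:::init_theta_from_site(enc[[1]], 3L, 8L, bg)
  run <- ursor:::zoops_em(enc, 8L, th, bg)
  expect_true(all(diff(run$trace) > -1e-6))
})

test_that("a planted 8-mer is recovered with its sites", {
  set.seed(62)
  seqs <- planted_motif_seqs(20, 50)
  names(seqs) <- paste0("s", seq_along(seqs))
  mot <- discover_motifs(seqs, or_config(motif_top_k = 1L, rng_seed = 62L),
                         widths = c(5L, 8L, 12L))
  m <- mot[[1]]
  expect_equal(m$width, 8L)
  expect_equal(m$consensus, "DRYVAICK")
  expect_gte(nrow(m$sites), 18)
})

test_that("EM attains the best single-alignment likelihood at width 3", {
  set.seed(63)
  seqs <- vapply(1:4, function(i)
    paste0(paste(sample(AA20_T, sample(2:3, 1), TRUE), collapse = ""),
           "WWC",
           paste(sample(AA20_T, sample(2:3, 1), TRUE), collapse = "")), "")
  names(seqs) <- paste0("s", 1:4)
  enc <- ursor:::encode_aa(seqs)
  bg <- ursor:::background_freqs(enc)
  w <- 3L
  # exhaustive oracle: evaluate the ZOOPS likelihood of the PFM implied by
  # every possible hard offset assignment (one site per sequence)
  offsets <- lapply(enc, function(s) seq_len(length(s) - w + 1L))
  grid <- expand.grid(offsets)
  lls <- numeric(nrow(grid))
  thetas <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    offs <- as.list(as.integer(grid[r, ]))
    names(offs) <- seq_along(enc)
    theta <- ursor:::theta_from_offsets(enc, offs, w, bg)
    run1 <- ursor:::zoops_em(enc, w, theta, bg, gamma = 0.99, max_iter = 1L)
    lls[r] <- run1$trace[1]   # likelihood of (theta, gamma) before updating
    thetas[[r]] <- theta
  }
  best_oracle <- max(lls)
  # EM started from the oracle optimum cannot degrade below it
  run <- ursor:::zoops_em(enc, w, thetas[[which.max(lls)]], bg,
                          gamma = 0.99)
  expect_gte(run$loglik, best_oracle - 1e-6)
  # and the top restart from random seeds gets at least as far
  set.seed(63)
  runs <- lapply(1:5, function(r) {
    i0 <- sample(length(enc), 1)
    th <- ursor:::init_theta_from_site(enc[[i0]],
      sample(length(enc[[i0]]) - w + 1L, 1), w, bg)
    ursor:::shift_refine(ursor:::zoops_em(enc, w, th, bg, gamma = 0.99),
                         enc, w, bg, NULL)
  })
  em_ll <- max(vapply(runs, `[[`, 0, "loglik"))
  expect_gte(em_ll, best_oracle - 1e-6)
})

test_that("successive motifs occupy disjoint sites", {
  set.seed(64)
  seqs <- vapply(1:12, function(i) {
    bg <- sample(AA20_T, 60, TRUE)
    bg[10:17] <- strsplit("DRYVAICK", "")[[1]]
    bg[35:42] <- strsplit("NPMLYWFH", "")[[1]]
    paste(bg, collapse = "")
  }, "")
  names(seqs) <- paste0("s", seq_along(seqs))
  mot <- discover_motifs(seqs, or_config(motif_top_k = 2L, rng_seed = 64L),
                         widths = 8L)
  expect_equal(length(mot), 2)
  for (sq in names(seqs)) {
    s1 <- mot[[1]]$sites
    s2 <- mot[[2]]$sites
    o1 <- s1$offset[s1$sequence_id == sq]
    o2 <- s2$offset[s2$sequence_id == sq]
    if (length(o1) && length(o2))
      expect_true(o2 + 7 < o1 || o1 + 7 < o2)
  }
  expect_setequal(c(mot[[1]]$consensus, mot[[2]]$consensus),
                  c("DRYVAICK", "NPMLYWFH"))
})

test_that("PFM rows are proper distributions within the width bounds", {
  set.seed(65)
  seqs <- planted_motif_seqs(20, 40, noise = 0.15)
  names(seqs) <- paste0("s", seq_along(seqs))
  mot <- discover_motifs(seqs, or_config(motif_top_k = 1L, rng_seed = 65L),
                         widths = c(5L, 8L))
  m <- mot[[1]]
  expect_true(all(abs(rowSums(m$pfm) - 1) < 1e-9))
  expect_gte(m$width, 5L)
  expect_lte(m$width, 50L)
})
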