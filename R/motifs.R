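# Conserved-motif discovery in OR proteins: ZOOPS (zero-or-one occurrence
# per sequence) expectation-maximization over a grid of widths, with
# iterative masking to extract the top-k motifs.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# encode sequences as integer vectors; 0 = masked/unknown (scores as
# background in the E-step and is excluded from count accumulation)
encode_aa <- function(seqs) {
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    v <- match(ch, AA20)
    v[is.na(v)] <- 0L
    v
  })
}

background_freqs <- function(enc) {
  tab <- tabulate(unlist(enc), nbins = 20L)
  p <- tab + 1
  p / sum(p)
}

# one ZOOPS EM run at fixed width from a given PFM initialisation;
# returns theta, gamma, per-sequence site posteriors and the logL trace
zoops_em <- function(enc, w, theta, bg, gamma = 0.5, max_iter = 200L,
                     tol = 1e-4, masked = NULL) {
  n <- length(enc)
  loglik <- -Inf
  trace <- numeric(0)
  log_bg <- log(bg)
  for (iter in seq_len(max_iter)) {
    log_theta <- log(theta)
    z <- vector("list", n)      # posterior site weight per offset
    q <- numeric(n)             # posterior "has a site"
    ll <- 0
    for (i in seq_len(n)) {
      s <- enc[[i]]
      m <- length(s) - w + 1L
      if (m < 1L) { z[[i]] <- numeric(0); next }
      lr <- numeric(m)
      for (k in seq_len(w)) {
        a <- s[k:(k + m - 1L)]
        ok <- a > 0L
        contrib <- numeric(m)
        contrib[ok] <- log_theta[k, a[ok]] - log_bg[a[ok]]
        lr <- lr + contrib
      }
      if (!is.null(masked) && length(masked[[i]])) {
        bad <- vapply(seq_len(m), function(j)
          any(masked[[i]] >= j & masked[[i]] <= j + w - 1L), TRUE)
        lr[bad] <- -Inf
      }
      mx <- max(lr)
      if (!is.finite(mx)) { # every offset masked: sequence has no site
        z[[i]] <- numeric(m)
        q[i] <- 0
        ll <- ll + log(1 - gamma)
        next
      }
      r <- exp(lr - mx)
      denom_site <- (gamma / m) * sum(r)
      denom <- (1 - gamma) * exp(-mx) + denom_site
      z[[i]] <- (gamma / m) * r / denom
      q[i] <- denom_site / denom
      ll <- ll + mx + log(denom)
    }
    # M-step
    counts <- matrix(0, w, 20L)
    for (i in seq_len(n)) {
      s <- enc[[i]]
      zi <- z[[i]]
      if (!length(zi)) next
      m <- length(zi)
      for (k in seq_len(w)) {
        a <- s[k:(k + m - 1L)]
        ok <- a > 0L & zi > 0
        if (any(ok)) {
          sm <- rowsum(zi[ok], a[ok])
          idx <- as.integer(rownames(sm))
          counts[k, idx] <- counts[k, idx] + sm[, 1]
        }
      }
    }
    theta <- sweep(counts + 0.1 * rep(bg, each = w), 1,
                   rowSums(counts) + 0.1, "/")
    gamma <- min(max(mean(q), 1e-3), 0.999)
    trace <- c(trace, ll)
    if (is.finite(loglik) && ll - loglik < tol) { loglik <- ll; break }
    loglik <- ll
  }
  list(theta = theta, gamma = gamma, z = z, q = q, loglik = loglik,
       trace = trace)
}

theta_from_offsets <- function(enc, offs, w, bg) {
  # PFM from hard site assignments (named offsets per sequence index)
  counts <- matrix(0, w, 20L)
  n_used <- 0
  for (i in seq_along(offs)) {
    off <- offs[[i]]
    if (is.na(off)) next
    s <- enc[[as.integer(names(offs)[i])]]
    if (off < 1 || off + w - 1L > length(s)) next
    a <- s[off:(off + w - 1L)]
    ok <- a > 0L
    counts[cbind(which(ok), a[ok])] <- counts[cbind(which(ok), a[ok])] + 1
    n_used <- n_used + 1
  }
  sweep(counts + 0.5 * rep(bg, each = w), 1, rowSums(counts) + 0.5, "/")
}

# after EM convergence, test phase-shifted restarts of the converged site
# alignment (the classic EM failure mode is a solution offset by 1-3
# columns); keeps the best-likelihood run
shift_refine <- function(run, enc, w, bg, masked) {
  repeat {
    offs <- lapply(seq_along(enc), function(i)
      if (length(run$z[[i]]) && run$q[i] > 0.5) which.max(run$z[[i]])
      else NA_integer_)
    names(offs) <- seq_along(enc)
    improved <- FALSE
    for (delta in c(-2L, -1L, 1L, 2L)) {
      sh <- lapply(offs, function(o) if (is.na(o)) o else o + delta)
      names(sh) <- names(offs)
      theta <- theta_from_offsets(enc, sh, w, bg)
      cand <- zoops_em(enc, w, theta, bg, gamma = run$gamma,
                       masked = masked)
      if (cand$loglik > run$loglik + 1e-6) {
        run <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) return(run)
  }
}

init_theta_from_site <- function(enc_i, off, w, bg) {
  theta <- matrix(rep(bg, each = w), w, 20L)
  for (k in seq_len(w)) {
    a <- enc_i[off + k - 1L]
    if (a > 0L) {
      theta[k, ] <- 0.5 * bg
      theta[k, a] <- theta[k, a] + 0.5
    }
    theta[k, ] <- theta[k, ] / sum(theta[k, ])
  }
  theta
}

column_ic <- function(theta, bg) {
  # relative entropy (bits) of each motif column against the background
  rowSums(theta * log2(sweep(theta, 2, bg, "/")))
}

#' Discover conserved ungapped motifs by ZOOPS EM
#'
#' MEME-style motif discovery under the zero-or-one-occurrence-per-sequence
#' model: for each candidate width on a coarse grid within
#' `[motif_width_min, motif_width_max]`, EM is run from several seeded
#' site initialisations (best of `n_restarts`); candidate motifs are ranked
#' by expected site count times background-corrected information content;
#' the sites of each reported motif are masked before the next motif is
#' sought, so the k site sets are disjoint. Deterministic given
#' `config$rng_seed`.
#'
#' @param proteins named character vector (>= 5 sequences, each at least
#'   `motif_width_min` long).
#' @param config an [or_config()].
#' @param widths width grid; defaults to `{5,8,12,16,21,29,41,50}` clipped
#'   to the configured bounds.
#' @param n_restarts EM restarts per width.
#' @return a list of `or_motif` objects (fields `width`, `pfm`,
#'   `sites` data.frame, `information_content`, `consensus`, `loglik`).
#' @export
discover_motifs <- function(proteins, config = or_config(),
                            widths = NULL, n_restarts = 5L) {
  if (length(proteins) < 5)
    stop("motif discovery needs at least 5 sequences")
  if (any(nchar(proteins) < config$motif_width_min))
    stop("all sequences must be at least motif_width_min long")
  if (is.null(widths)) {
    widths <- c(5L, 8L, 12L, 16L, 21L, 29L, 41L, 50L)
    widths <- widths[widths >= config$motif_width_min &
                       widths <= config$motif_width_max]
    if (length(widths) == 0) widths <- config$motif_width_min
  }
  set.seed(config$rng_seed)
  enc <- encode_aa(proteins)
  bg <- background_freqs(enc)
  n <- length(enc)
  masked <- replicate(n, integer(0), simplify = FALSE)
  motifs <- list()
  for (mi in seq_len(config$motif_top_k)) {
    best <- NULL
    for (w in widths) {
      usable <- which(vapply(enc, length, 0L) >= w)
      if (length(usable) < 5) next
      best_run <- NULL
      for (r in seq_len(n_restarts)) {
        i0 <- sample(usable, 1L)
        off0 <- sample.int(length(enc[[i0]]) - w + 1L, 1L)
        theta0 <- init_theta_from_site(enc[[i0]], off0, w, bg)
        run <- zoops_em(enc, w, theta0, bg, masked = masked)
        if (is.null(best_run) || run$loglik > best_run$loglik)
          best_run <- run
      }
      best_run <- shift_refine(best_run, enc, w, bg, masked)
      exp_sites <- sum(best_run$q)
      ic <- column_ic(best_run$theta, bg)
      # BIC-style width selection: the relative log likelihood (vs the
      # background-only model) penalized for the 19 free parameters of
      # each motif column, so extra noise columns never pay for themselves
      score <- best_run$loglik - 0.5 * 19 * w * log(length(enc))
      if (is.null(best) || score > best$score)
        best <- list(run = best_run, w = w, score = score, ic = ic)
    }
    if (is.null(best) || best$score <= 0) break
    run <- best$run
    w <- best$w
    # site extraction: argmax offset in sequences with posterior > 0.5
    sites <- list()
    for (i in seq_len(n)) {
      if (!length(run$z[[i]]) || run$q[i] <= 0.5) next
      off <- which.max(run$z[[i]])
      sites[[length(sites) + 1L]] <- data.frame(
        sequence_id = names(proteins)[i], offset = off,
        site = substr(proteins[[i]], off, off + w - 1L),
        posterior = run$q[i], stringsAsFactors = FALSE)
      masked[[i]] <- c(masked[[i]], off:(off + w - 1L))
    }
    pfm <- run$theta
    dimnames(pfm) <- list(NULL, AA20)
    motif <- structure(list(
      width = w, pfm = pfm,
      sites = if (length(sites)) do.call(rbind, sites) else
        data.frame(sequence_id = character(), offset = integer(),
                   site = character(), posterior = numeric()),
      information_content = sum(best$ic),
      consensus = paste(AA20[apply(pfm, 1, which.max)], collapse = ""),
      loglik = run$loglik, loglik_trace = run$trace,
      background = bg), class = "or_motif")
    motifs[[mi]] <- motif
  }
  motifs
}

#' @export
print.or_motif <- function(x, ...) {
  cat(sprintf("ZOOPS motif  width %d  consensus %s\n", x$width, x$consensus))
  cat(sprintf("  %d sites, %.1f bits relative entropy\n", nrow(x$sites),
              x$information_content))
  invisible(x)
}

#' Sequence-logo letter heights for a motif
#'
#' Standard logo scaling: the height of letter `a` in column `k` is
#' `p(a) * IC_k`, where `IC_k = log2(20) - H_k` is the column information
#' content against a uniform alphabet.
#'
#' @param motif an `or_motif` from [discover_motifs()], or a bare PFM
#'   matrix (rows = positions, columns = the 20 amino acids).
#' @return a width x 20 matrix of letter heights (bits).
#' @export
motif_logo_table <- function(motif) {
  pfm <- if (inherits(motif, "or_motif")) motif$pfm else motif
  stopifnot(all(abs(rowSums(pfm) - 1) < 1e-9))
  h <- ifelse(pfm > 0, pfm * log2(pfm), 0)
  ic <- log2(20) + rowSums(h)
  sweep(pfm, 1, ic, "*")
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs list of `or_motif` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", ""),
             con)
  bg <- if (length(motifs)) motifs[[1]]$background else rep(0.05, 20)
  writeLines("Background letter frequencies", con)
  writeLines(paste(sprintf("%s %.5f", AA20, bg), collapse = " "), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(c("", sprintf("MOTIF M%d %s", i, m$consensus),
                 sprintf("letter-probability matrix: alength= 20 w= %d nsites= %d",
                         m$width, nrow(m$sites))), con)
    for (k in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$pfm[k, ]), collapse = " "), con)
  }
  invisible(path)
}
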