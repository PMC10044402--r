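# Translated homology search: six-frame translation, seeded protein search
# with Karlin-Altschul statistics, best-hit retention and fragment chaining.

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

translate_dna <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(dna, 1L, n)),
                                     if.fuzzy.codon = "solve",
                                     no.init.codon = TRUE))
}

#' Six-frame translation with coordinate maps
#'
#' Frames +1/+2/+3 read the forward strand from offsets 1/2/3; -1/-2/-3 read
#' the reverse complement the same way. Stop codons are rendered `*`, and
#' codons containing `N` translate to `X`.
#'
#' @param sequence a DNA string over A/C/G/T/N.
#' @return a list with one element per frame (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`),
#'   each holding `frame`, the translated `aa` string, and the source
#'   `length_bp`. Use [aa_to_genome()] to map amino-acid positions back to
#'   forward-strand bp coordinates.
#' @export
translate_six_frames <- function(sequence) {
  L <- nchar(sequence)
  rc <- if (L >= 3) revcomp(sequence) else ""
  frames <- list()
  for (off in 1:3) {
    fwd <- if (L - off + 1 >= 3) substr(sequence, off, L) else ""
    rev <- if (L - off + 1 >= 3) substr(rc, off, L) else ""
    frames[[sprintf("+%d", off)]] <-
      list(frame = off, aa = translate_dna(fwd), length_bp = L)
    frames[[sprintf("-%d", off)]] <-
      list(frame = -off, aa = translate_dna(rev), length_bp = L)
  }
  frames[c("+1", "+2", "+3", "-1", "-2", "-3")]
}

#' Map translated-frame positions to genome coordinates
#'
#' @param frame frame number in `{+-1, +-2, +-3}`.
#' @param aa_start,aa_end 1-based amino-acid positions within the frame.
#' @param length_bp chromosome length.
#' @return integer vector `c(start, end)` of 1-based inclusive
#'   forward-strand bp coordinates of the spanned codons.
#' @export
aa_to_genome <- function(frame, aa_start, aa_end, length_bp) {
  off <- abs(frame)
  b1 <- off + 3L * (aa_start - 1L)
  b2 <- off + 3L * aa_end - 1L
  if (frame > 0) c(b1, b2) else c(length_bp - b2 + 1L, length_bp - b1 + 1L)
}

empty_hsps <- function() {
  data.frame(query_id = character(), chrom_id = character(),
             frame = integer(), q_start = integer(), q_end = integer(),
             g_start = integer(), g_end = integer(), raw_score = numeric(),
             score = numeric(), evalue = numeric(), identity = numeric(),
             length = integer(), stringsAsFactors = FALSE)
}

#' Translated homology search of protein queries against a genome
#'
#' Seed-and-extend search of each query against all six translated frames of
#' every chromosome: exact k-mer seeds (two-hit triggering), Smith-Waterman
#' extension with BLOSUM62 and affine gaps, and Karlin-Altschul E-values
#' computed from the bit score and the raw search space (query length x
#' total translated length). Only hits with `evalue <= evalue_threshold`
#' are returned.
#'
#' @param queries protein data.frame ([read_protein_fasta()]) or named
#'   character vector.
#' @param genome genome data.frame ([read_genome_fasta()]).
#' @param config an [or_config()].
#' @return an HSP data.frame: query/chromosome ids, frame, 1-based aa
#'   coordinates in the query, 1-based forward-strand bp coordinates
#'   (`g_start <= g_end`), bit `score`, `evalue` and `identity`.
#' @export
search_genome <- function(queries, genome, config = or_config()) {
  qseq <- if (is.data.frame(queries)) setNames(queries$sequence, queries$id)
          else queries
  if (length(qseq) == 0) stop("empty query set")
  qseq <- sub("\\*$", "", toupper(qseq))
  short <- nchar(qseq) < config$seed_k
  if (any(short)) {
    warning("skipping query shorter than seed length: ",
            paste(names(qseq)[short], collapse = ", "))
    qseq <- qseq[!short]
  }
  sub <- blosum62()
  # raw m x n search space (no edge correction)
  n_space <- sum(floor(3 * (nchar(genome$sequence) / 3) * 2))
  out <- list()
  for (ci in seq_len(nrow(genome))) {
    frames <- translate_six_frames(genome$sequence[ci])
    for (fr in frames) {
      if (!nzchar(fr$aa)) next
      for (qi in seq_along(qseq)) {
        hits <- cpp_seeded_search(qseq[[qi]], fr$aa, sub,
                                  config$seed_k, 40L,
                                  config$gap_open, config$gap_ext, 25)
        if (nrow(hits) == 0) next
        bits <- (config$lambda * hits[, "score"] - log(config$karlin_k)) / log(2)
        m <- nchar(qseq[[qi]])
        evalue <- m * n_space * 2^(-bits)
        keep <- evalue <= config$evalue_threshold
        if (!any(keep)) next
        hits <- hits[keep, , drop = FALSE]
        g <- t(vapply(seq_len(nrow(hits)), function(r) {
          as.integer(aa_to_genome(fr$frame, hits[r, "s_start"],
                                  hits[r, "s_end"], fr$length_bp))
        }, integer(2)))
        out[[length(out) + 1L]] <- data.frame(
          query_id = names(qseq)[qi], chrom_id = genome$chrom_id[ci],
          frame = fr$frame,
          q_start = as.integer(hits[, "q_start"]),
          q_end = as.integer(hits[, "q_end"]),
          g_start = g[, 1], g_end = g[, 2],
          raw_score = hits[, "score"], score = bits[keep],
          evalue = evalue[keep],
          identity = hits[, "matches"] / hits[, "columns"],
          length = as.integer(hits[, "columns"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty_hsps())
  res <- do.call(rbind, out)
  res[order(res$chrom_id, res$g_start, res$evalue), , drop = FALSE]
}

#' Retain the best hit among overlapping HSPs
#'
#' Among HSPs whose genomic intervals overlap by more than 50% (of the
#' shorter interval), the hit with the lowest E-value is kept; ties are
#' broken by longer alignment, then lexicographic query id.
#'
#' @param hsps an HSP data.frame from [search_genome()].
#' @return the retained subset, in genomic order.
#' @export
retain_best_hits <- function(hsps) {
  if (nrow(hsps) == 0) return(hsps)
  ord <- order(hsps$evalue, -hsps$length, hsps$query_id)
  kept <- list()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (hsps$chrom_id[i] != hsps$chrom_id[k]) next
      ov <- min(hsps$g_end[i], hsps$g_end[k]) -
        max(hsps$g_start[i], hsps$g_start[k]) + 1
      shorter <- min(hsps$g_end[i] - hsps$g_start[i],
                     hsps$g_end[k] - hsps$g_start[k]) + 1
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- i
  }
  idx <- sort(unlist(kept))
  hsps[idx, , drop = FALSE]
}

#' Chain HSP fragments into candidate loci
#'
#' Same-chromosome, same-strand fragments of one query whose genomic gap is
#' at most `chain_gap_bp` and whose query coordinates are colinear (monotone
#' along the strand, overlapping by at most `chain_overlap_aa`) are merged
#' into one locus chain. Every HSP belongs to exactly one chain.
#'
#' @param hsps an HSP data.frame.
#' @param config an [or_config()].
#' @return a data.frame of locus chains with `chrom_id`, `strand`,
#'   `span_start`, `span_end`, `best_query_id`, `n_hsps`, `min_evalue` and a
#'   `members` list-column of row indices into `hsps`.
#' @export
chain_hsps <- function(hsps, config = or_config()) {
  if (nrow(hsps) == 0) {
    return(data.frame(chrom_id = character(), strand = character(),
                      span_start = integer(), span_end = integer(),
                      best_query_id = character(), n_hsps = integer(),
                      min_evalue = numeric(), stringsAsFactors = FALSE))
  }
  hsps$strand <- ifelse(hsps$frame > 0, "+", "-")
  key <- paste(hsps$chrom_id, hsps$strand, hsps$query_id, sep = "\r")
  chains <- list()
  for (grp in split(seq_len(nrow(hsps)), key)) {
    grp <- grp[order(hsps$g_start[grp])]
    cur <- grp[1]
    for (i in grp[-1]) {
      last <- cur[length(cur)]
      gap <- hsps$g_start[i] - max(hsps$g_end[cur])
      colinear <- if (hsps$strand[i] == "+") {
        hsps$q_start[i] >= hsps$q_end[last] - config$chain_overlap_aa &&
          hsps$q_start[i] > hsps$q_start[last]
      } else {
        hsps$q_end[i] <= hsps$q_start[last] + config$chain_overlap_aa &&
          hsps$q_end[i] < hsps$q_end[last]
      }
      if (gap <= config$chain_gap_bp && colinear) {
        cur <- c(cur, i)
      } else {
        chains[[length(chains) + 1L]] <- cur
        cur <- i
      }
    }
    chains[[length(chains) + 1L]] <- cur
  }
  res <- do.call(rbind, lapply(chains, function(m) {
    data.frame(chrom_id = hsps$chrom_id[m[1]], strand = hsps$strand[m[1]],
               span_start = min(hsps$g_start[m]),
               span_end = max(hsps$g_end[m]),
               best_query_id = hsps$query_id[m[which.min(hsps$evalue[m])]],
               n_hsps = length(m), min_evalue = min(hsps$evalue[m]),
               stringsAsFactors = FALSE)
  }))
  res$members <- chains
  res[order(res$chrom_id, res$span_start), , drop = FALSE]
}
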