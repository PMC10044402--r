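# Gene-model reconstruction from chained loci: frameshift-aware
# protein-vs-DNA realignment, disruption detection, and the
# functional/partial/pseudogene classification.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# translation of the codon ENDING at every position of `dna`; '?' marks
# positions < 3 (no complete codon ends there)
aa_by_codon_end <- function(dna) {
  n <- nchar(dna)
  if (n < 3) return(strrep("?", n))
  res <- rep("?", n)
  for (off in 1:3) {
    aa <- translate_dna(substr(dna, off, n))
    if (!nzchar(aa)) next
    ends <- off + 3L * seq_len(nchar(aa)) - 1L
    res[ends] <- strsplit(aa, "")[[1]]
  }
  paste(res, collapse = "")
}

#' Reconstruct one OR gene model from a locus chain
#'
#' The chained span is extended by `flank_bp` on both sides, the best query
#' protein is realigned to the genomic DNA with a frameshift-aware local
#' alignment (codons may consume 2 or 4 bp at a penalty, stop codons score a
#' flat penalty so the path runs through pseudogene lesions), and the model
#' is read off the alignment path: translation starts at the first in-frame
#' ATG at or upstream of the aligned start (falling back to the aligned
#' start) and runs to the next stop codon or the aligned end. Every in-frame
#' stop inside the aligned region is recorded as a `premature_stop`, every
#' non-multiple-of-3 jump as a `frameshift`.
#'
#' @param chain one row of [chain_hsps()] output (data.frame).
#' @param genome genome data.frame.
#' @param query_seqs named character vector of query proteins.
#' @param config an [or_config()].
#' @param gene_id identifier for the model.
#' @return a one-row gene-model data.frame, or `NULL` if no alignment
#'   survives.
#' @export
build_gene_model <- function(chain, genome, query_seqs, config = or_config(),
                             gene_id = "gene1") {
  gi <- match(chain$chrom_id, genome$chrom_id)
  L <- genome$length_bp[gi]
  ext_start <- max(1L, chain$span_start - config$flank_bp)
  ext_end <- min(L, chain$span_end + config$flank_bp)
  seg <- substr(genome$sequence[gi], ext_start, ext_end)
  if (chain$strand == "-") seg <- revcomp(seg)
  n <- nchar(seg)
  query <- sub("\\*$", "", toupper(query_seqs[[chain$best_query_id]]))
  aa_end <- aa_by_codon_end(seg)
  # stop codons cost the same as frameshifts: the path should only cross a
  # stop when genuine homology continues beyond it, not on a lucky
  # background extension past a true ORF end
  al <- cpp_fs_align(query, aa_end, config$frameshift_cost,
                     -config$frameshift_cost, blosum62(), config$gap_open,
                     config$gap_ext)
  if (al$score <= 0) return(NULL)
  d_start <- al$d_start
  d_end <- al$d_end
  events <- data.frame(start = al$fs_start, step = al$fs_step)
  # first in-frame ATG at or upstream of the aligned start; scanning stops at
  # an in-frame stop codon or the edge of the extracted flank
  model_start <- d_start
  found <- FALSE
  p <- d_start
  while (p >= 1) {
    codon <- substr(seg, p, p + 2)
    if (codon %in% STOP_CODONS && p < d_start) break
    if (codon == "ATG") { model_start <- p; found <- TRUE; break }
    p <- p - 3L
  }
  if (!found) model_start <- d_start
  # walk codons from model_start, honouring frameshift events on the path
  gc_map <- genetic_code_map()
  p <- model_start
  aa_chars <- character(0)
  dis_kind <- character(0)
  dis_pos_seg <- integer(0)
  last_bp <- model_start - 1L
  while (p + 1L <= n) {
    ev <- which(events$start == p)
    if (length(ev) == 1L) {
      step <- events$step[ev]
      aa <- "X"
      dis_kind <- c(dis_kind, "frameshift")
      dis_pos_seg <- c(dis_pos_seg, p)
    } else {
      if (p + 2L > n) break
      step <- 3L
      codon <- substr(seg, p, p + 2)
      aa <- if (grepl("[^ACGT]", codon)) "X" else unname(gc_map[codon])
      if (is.na(aa)) aa <- "X"
      if (aa == "*") {
        if (p > d_end - 2L) { # terminal stop: ends the model, not a lesion
          break
        }
        dis_kind <- c(dis_kind, "premature_stop")
        dis_pos_seg <- c(dis_pos_seg, p)
        aa <- "X"
      }
    }
    aa_chars <- c(aa_chars, aa)
    last_bp <- p + step - 1L
    p <- p + step
  }
  if (length(aa_chars) == 0) return(NULL)
  protein <- paste(aa_chars, collapse = "")
  # map oriented segment coordinates back to the forward strand
  seg2gen <- function(pos) {
    if (chain$strand == "+") ext_start + pos - 1L else ext_end - pos + 1L
  }
  g1 <- seg2gen(model_start)
  g2 <- seg2gen(last_bp)
  dis <- data.frame(kind = dis_kind,
                    position_bp = vapply(dis_pos_seg, seg2gen, integer(1)),
                    stringsAsFactors = FALSE)
  dis <- dis[order(dis$position_bp), , drop = FALSE]
  span <- sort(c(g1, g2))
  seq_span <- substr(genome$sequence[gi], span[1], span[2])
  n_frac <- mean(strsplit(seq_span, "")[[1]] == "N")
  data.frame(gene_id = gene_id, chrom_id = chain$chrom_id,
             strand = chain$strand, start = span[1], end = span[2],
             protein = protein, length_aa = nchar(protein),
             class_label = NA_character_,
             disruptions = disruptions_to_string(dis),
             best_query_id = chain$best_query_id,
             tm_helix_count = NA_integer_, low_confidence = FALSE,
             high_n_fraction = n_frac > 0.10,
             stringsAsFactors = FALSE)
}

#' Classify a gene model as functional, partial or pseudogene
#'
#' A model with any recorded disruption is a pseudogene; otherwise it is
#' functional when its protein reaches `min_functional_aa` (default 250 aa)
#' and partial when shorter.
#'
#' @param model one-row gene-model data.frame.
#' @param config an [or_config()].
#' @return one of `"functional"`, `"partial"`, `"pseudogene"`.
#' @export
classify_model <- function(model, config = or_config()) {
  if (nzchar(model$disruptions)) return("pseudogene")
  if (model$length_aa >= config$min_functional_aa) "functional" else "partial"
}

#' Kyte-Doolittle transmembrane helix count
#'
#' Sliding-window (width 19) Kyte-Doolittle hydropathy; maximal runs of
#' window centres with mean hydropathy at or above the threshold are counted
#' as helices. Used as a confidence flag on OR gene models (intact receptors
#' show 7 helices; models with fewer than 5 are flagged, not removed).
#'
#' @param protein amino-acid string.
#' @param window window width (odd).
#' @param threshold mean-hydropathy cutoff.
#' @return integer helix count.
#' @export
tm_helix_count <- function(protein, window = 19L, threshold = 1.6) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2, X = 0, U = 0, B = -3.5, Z = -3.5)
  aa <- strsplit(toupper(protein), "")[[1]]
  h <- unname(kd[aa])
  h[is.na(h)] <- 0
  L <- length(h)
  if (L < window) return(0L)
  cs <- cumsum(c(0, h))
  means <- (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
  above <- means >= threshold
  sum(diff(c(FALSE, above)) == 1L)
}

#' Build and classify gene models for all locus chains
#'
#' Runs [build_gene_model()] on every chain, classifies each model, attaches
#' the hydropathy helix count, and flags functional models with fewer than 5
#' predicted helices as low confidence.
#'
#' @param chains output of [chain_hsps()].
#' @param genome genome data.frame.
#' @param queries query proteins (data.frame or named vector).
#' @param config an [or_config()].
#' @return a gene-model data.frame, one row per recovered model.
#' @export
build_gene_models <- function(chains, genome, queries,
                              config = or_config()) {
  qseq <- if (is.data.frame(queries)) setNames(queries$sequence, queries$id)
          else queries
  rows <- list()
  for (i in seq_len(nrow(chains))) {
    m <- build_gene_model(chains[i, , drop = FALSE], genome, qseq, config,
                          gene_id = sprintf("ORg%04d", i))
    if (is.null(m)) {
      message("locus ", chains$chrom_id[i], ":", chains$span_start[i],
              " produced no alignment; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- m
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(), chrom_id = character(),
                      strand = character(), start = integer(),
                      end = integer(), protein = character(),
                      length_aa = integer(), class_label = character(),
                      disruptions = character(), best_query_id = character(),
                      tm_helix_count = integer(), low_confidence = logical(),
                      high_n_fraction = logical(), stringsAsFactors = FALSE))
  }
  models <- do.call(rbind, rows)
  # one model per locus: chains over-extended past a lesion can both cover
  # the same gene; keep the model with the longest protein (ties: earliest)
  ord <- order(-models$length_aa, models$start)
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (k in kept) {
      if (models$chrom_id[i] != models$chrom_id[k]) next
      ov <- min(models$end[i], models$end[k]) -
        max(models$start[i], models$start[k]) + 1
      shorter <- min(models$end[i] - models$start[i],
                     models$end[k] - models$start[k]) + 1
      if (ov > 0.5 * shorter) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  models <- models[sort(kept), , drop = FALSE]
  models$gene_id <- sprintf("ORg%04d", seq_len(nrow(models)))
  rownames(models) <- NULL
  models$class_label <- vapply(seq_len(nrow(models)), function(i)
    classify_model(models[i, , drop = FALSE], config), "")
  models$tm_helix_count <- vapply(models$protein, tm_helix_count,
                                  integer(1), USE.NAMES = FALSE)
  models$low_confidence <- models$class_label == "functional" &
    models$tm_helix_count < 5L
  models
}
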