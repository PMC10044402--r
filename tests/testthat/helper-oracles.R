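# Shared fixtures and independent oracles used across the suite.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20_T, n, TRUE), collapse = "")

mutate_identity <- function(seq, n_changes) {
  aa <- strsplit(seq, "")[[1]]
  idx <- sample(length(aa), n_changes)
  for (i in idx) aa[i] <- sample(setdiff(AA20_T, aa[i]), 1)
  paste(aa, collapse = "")
}

# independent codon-table oracle for translation (hand-built, not Biostrings)
codon_table_oracle <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16),
                   rep(rep(bases, each = 4), 4),
                   rep(bases, 16))
  # standard code enumerated in TCAG order
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aas, codons)
})

translate_oracle <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  cods <- substring(dna, seq(1, n - 2, 3), seq(3, n, 3))
  aa <- unname(codon_table_oracle[cods])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp_oracle <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(dna, "")[[1]]])), collapse = "")
}

# Biostrings alignment oracles (independent of the package's C++ kernels)
bs_global_score <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global", scoreOnly = TRUE)
}

bs_local_score <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "local", scoreOnly = TRUE)
}

# brute-force reimplementation of the greedy clustering rule, driven by a
# precomputed identity matrix rather than the package's clustering code
greedy_oracle <- function(proteins, threshold, im) {
  ids <- names(proteins)
  ord <- ids[order(-nchar(proteins), ids)]
  reps <- character(0)
  member_of <- setNames(character(length(ids)), ids)
  for (id in ord) {
    placed <- NA_character_
    for (r in reps) {
      if (im[id, r] >= threshold) { placed <- r; break }
    }
    if (is.na(placed)) { reps <- c(reps, id); placed <- id }
    member_of[id] <- placed
  }
  member_of
}

# uniform reverse translation used to plant genes by hand in tests
reverse_translate_oracle <- function(protein) {
  a2c <- split(names(codon_table_oracle), unname(codon_table_oracle))
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) sample(a2c[[a]], 1), "",
               USE.NAMES = FALSE), collapse = "")
}

random_dna_t <- function(n) paste(sample(c("A","C","G","T"), n, TRUE),
                                  collapse = "")

# plant a protein-coding gene (plus TAA) into random background DNA
plant_gene_fixture <- function(protein, chrom_len = 6000, at = NULL,
                               strand = "+") {
  dna <- paste0(reverse_translate_oracle(protein), "TAA")
  if (is.null(at)) at <- as.integer(chrom_len / 3)
  bg <- random_dna_t(chrom_len)
  insert <- if (strand == "-") revcomp_oracle(dna) else dna
  seq <- paste0(substr(bg, 1, at - 1), insert,
                substr(bg, at + nchar(insert), chrom_len))
  list(genome = data.frame(chrom_id = "chr1", sequence = seq,
                           length_bp = nchar(seq),
                           stringsAsFactors = FALSE),
       start = at, end = at + nchar(insert) - 1L, dna = dna)
}
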