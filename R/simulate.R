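# Synthetic-data generator: family/subfamily-structured OR proteins built
# from a 7-TM template, planted into multi-chromosome genomes in tandem
# clusters with controlled pseudogene/partial fractions, with full ground
# truth for recovery testing.

HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V")
LOOP_AA <- setdiff(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                   character(0))
OR_MOTIF <- "DRYVAICK"   # the conserved DRY-like motif planted after TM3

#' Specification of a synthetic OR genome
#'
#' Defaults describe the desk-scale study condition: 3 chromosomes of 3 Mb,
#' 4 families x 3 subfamilies x 5 genes = 60 planted OR genes, 20%
#' pseudogenized (1-3 in-frame stops or +-1 bp frameshifts), 10% truncated
#' below 250 aa, genes placed in tandem clusters (< 1 Mb gaps) with
#' probability 0.8, background DNA i.i.d. at 40% GC. Divergences are in
#' expected substitutions per mutable site (Poisson): 0.10 within a
#' subfamily, 0.24 between subfamilies of a family, 0.70 between families.
#'
#' @param n_chromosomes,chromosome_length_bp genome shape.
#' @param n_families,subfamilies_per_family,genes_per_subfamily planted
#'   hierarchy.
#' @param fraction_pseudogene,fraction_partial lesion fractions (sum <= 1).
#' @param within_subfamily_divergence,between_subfamily_divergence,between_family_divergence
#'   substitution rates per mutable site at the three hierarchy levels.
#' @param cluster_tandem_prob probability that a gene is placed in the
#'   current tandem cluster rather than at a fresh location.
#' @param intergene_gap_bp upper bound of the uniform within-cluster gap.
#' @param protein_length_aa length of the template receptor.
#' @param lesion_guard_codons lesions are kept this many codons away from
#'   both gene ends (set 0 for the hard mode that also stresses search
#'   sensitivity).
#' @param rng_seed integer seed; all generation is reproducible from it.
#' @return a validated `or_simspec` list.
#' @export
simulation_spec <- function(n_chromosomes = 3L,
                            chromosome_length_bp = 3000000L,
                            n_families = 4L,
                            subfamilies_per_family = 3L,
                            genes_per_subfamily = 5L,
                            fraction_pseudogene = 0.20,
                            fraction_partial = 0.10,
                            within_subfamily_divergence = 0.10,
                            between_subfamily_divergence = 0.24,
                            between_family_divergence = 0.70,
                            cluster_tandem_prob = 0.8,
                            intergene_gap_bp = 200000L,
                            protein_length_aa = 307L,
                            lesion_guard_codons = 30L,
                            rng_seed = 1L) {
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               chromosome_length_bp = as.integer(chromosome_length_bp),
               n_families = as.integer(n_families),
               subfamilies_per_family = as.integer(subfamilies_per_family),
               genes_per_subfamily = as.integer(genes_per_subfamily),
               fraction_pseudogene = fraction_pseudogene,
               fraction_partial = fraction_partial,
               within_subfamily_divergence = within_subfamily_divergence,
               between_subfamily_divergence = between_subfamily_divergence,
               between_family_divergence = between_family_divergence,
               cluster_tandem_prob = cluster_tandem_prob,
               intergene_gap_bp = as.integer(intergene_gap_bp),
               protein_length_aa = as.integer(protein_length_aa),
               lesion_guard_codons = as.integer(lesion_guard_codons),
               rng_seed = as.integer(rng_seed))
  if (spec$fraction_pseudogene < 0 || spec$fraction_partial < 0 ||
      spec$fraction_pseudogene + spec$fraction_partial > 1)
    stop("lesion fractions must be in [0,1] and sum to at most 1")
  if (!(spec$within_subfamily_divergence <= spec$between_family_divergence))
    stop("within-subfamily divergence must be below between-family divergence")
  class(spec) <- "or_simspec"
  spec
}

# 7-TM template: N-terminal loop, 7 hydrophobic blocks separated by loops,
# the conserved DRY-like motif straight after TM3, short C-terminal tail.
# Returns the sequence plus masks used to steer mutation.
or_template <- function(spec) {
  tm_len <- 23L
  loop_len <- 14L
  parts <- list()
  tm_mask <- logical(0)
  motif_mask <- logical(0)
  add <- function(seq, tm, motif) {
    parts[[length(parts) + 1L]] <<- seq
    tm_mask <<- c(tm_mask, rep(tm, nchar(seq)))
    motif_mask <<- c(motif_mask, rep(motif, nchar(seq)))
  }
  rloop <- function(k) paste(sample(LOOP_AA, k, replace = TRUE),
                             collapse = "")
  rtm <- function(k) paste(sample(HYDROPHOBIC, k, replace = TRUE),
                           collapse = "")
  add("M", FALSE, TRUE)
  add(rloop(20L), FALSE, FALSE)
  for (tm in 1:7) {
    add(rtm(tm_len), TRUE, FALSE)
    if (tm == 3L) add(OR_MOTIF, FALSE, TRUE)
    if (tm < 7L) add(rloop(loop_len), FALSE, FALSE)
  }
  add(rloop(10L), FALSE, FALSE)
  seq <- paste(unlist(parts), collapse = "")
  # pad/trim loops to the requested protein length
  if (nchar(seq) > spec$protein_length_aa) {
    seq <- substr(seq, 1, spec$protein_length_aa)
    tm_mask <- tm_mask[1:spec$protein_length_aa]
    motif_mask <- motif_mask[1:spec$protein_length_aa]
  } else if (nchar(seq) < spec$protein_length_aa) {
    extra <- spec$protein_length_aa - nchar(seq)
    seq <- paste0(seq, rloop(extra))
    tm_mask <- c(tm_mask, rep(FALSE, extra))
    motif_mask <- c(motif_mask, rep(FALSE, extra))
  }
  list(sequence = seq, tm_mask = tm_mask, motif_mask = motif_mask)
}

# Poisson substitution process: expected `divergence` substitutions per
# mutable site; TM positions mutate conservatively within the hydrophobic
# alphabet, loops over the full alphabet; the initial Met and the planted
# motif never mutate.
mutate_protein <- function(seq, divergence, tm_mask, motif_mask) {
  aa <- strsplit(seq, "")[[1]]
  mutable <- which(!motif_mask)
  n_sub <- rpois(1, divergence * length(mutable))
  if (n_sub == 0) return(seq)
  pos <- sample(mutable, min(n_sub, length(mutable)), replace = FALSE)
  for (p in pos) {
    pool <- if (tm_mask[p]) HYDROPHOBIC else LOOP_AA
    pool <- setdiff(pool, aa[p])
    if (length(pool)) aa[p] <- sample(pool, 1)
  }
  paste(aa, collapse = "")
}

#' Generate a family/subfamily-structured synthetic OR protein set
#'
#' One 7-TM template is drawn; family consensus sequences are derived from
#' it at `between_family_divergence`, subfamily consensuses from their
#' family at `between_subfamily_divergence`, and genes from their subfamily
#' at `within_subfamily_divergence`. The initial Met and the planted
#' conserved motif are protected; TM positions mutate within a hydrophobic
#' alphabet so the receptor architecture survives divergence.
#'
#' @param spec a [simulation_spec()].
#' @return a list with `proteins` (data.frame: `id`, `family_id`,
#'   `subfamily_id`, `sequence`), `family_consensus`, `subfamily_consensus`
#'   (named vectors), and `template`.
#' @export
generate_or_proteins <- function(spec) {
  set.seed(spec$rng_seed)
  tpl <- or_template(spec)
  fams <- character(0)
  subs <- character(0)
  rows <- list()
  for (f in seq_len(spec$n_families)) {
    fid <- sprintf("F%02d", f)
    fcons <- mutate_protein(tpl$sequence, spec$between_family_divergence,
                            tpl$tm_mask, tpl$motif_mask)
    fams[fid] <- fcons
    for (s in seq_len(spec$subfamilies_per_family)) {
      sid <- sprintf("%s.S%02d", fid, s)
      scons <- mutate_protein(fcons, spec$between_subfamily_divergence,
                              tpl$tm_mask, tpl$motif_mask)
      subs[sid] <- scons
      for (g in seq_len(spec$genes_per_subfamily)) {
        gid <- sprintf("%s.G%02d", sid, g)
        gseq <- mutate_protein(scons, spec$within_subfamily_divergence,
                               tpl$tm_mask, tpl$motif_mask)
        rows[[length(rows) + 1L]] <- data.frame(
          id = gid, family_id = fid, subfamily_id = sid, sequence = gseq,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(proteins = do.call(rbind, rows), family_consensus = fams,
       subfamily_consensus = subs, template = tpl)
}

#' Derive a diverged query set from the planted families
#'
#' Emulates a cross-species OR reference set: each family consensus is
#' mutated at the given divergence and used as a search query.
#'
#' @param generated output of [generate_or_proteins()].
#' @param spec the [simulation_spec()] used.
#' @param divergence substitutions per mutable site between the reference
#'   and the planted family consensus.
#' @return named character vector of query proteins.
#' @export
reference_queries <- function(generated, spec, divergence = 0.15) {
  set.seed(spec$rng_seed + 101L)
  tpl <- generated$template
  out <- vapply(generated$family_consensus, function(fc)
    mutate_protein(fc, divergence, tpl$tm_mask, tpl$motif_mask), "")
  names(out) <- paste0("refOR_", names(generated$family_consensus))
  out
}

reverse_translate <- function(protein) {
  a2c <- aa_to_codons()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- a2c[[a]]
    cods[sample.int(length(cods), 1)]
  }, "", USE.NAMES = FALSE), collapse = "")
}

random_dna <- function(n, gc = 0.40) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

apply_lesions <- function(dna, n_codons, guard, n_lesions) {
  # 1-3 lesions: in-frame stop codons or +-1 bp frameshifts, kept `guard`
  # codons away from both ends; returns the lesioned DNA and a record
  lo <- guard + 1L
  hi <- n_codons - guard
  codons <- sort(sample(lo:hi, n_lesions))
  kinds <- sample(c("premature_stop", "frameshift"), n_lesions,
                  replace = TRUE)
  # apply right-to-left so earlier coordinates stay valid
  rec <- character(0)
  for (i in rev(seq_len(n_lesions))) {
    p <- (codons[i] - 1L) * 3L + 1L
    if (kinds[i] == "premature_stop") {
      stop_codon <- sample(STOP_CODONS, 1)
      dna <- paste0(substr(dna, 1, p - 1), stop_codon,
                    substr(dna, p + 3, nchar(dna)))
    } else if (runif(1) < 0.5) { # 1 bp deletion
      dna <- paste0(substr(dna, 1, p - 1), substr(dna, p + 1, nchar(dna)))
    } else {                      # 1 bp insertion
      dna <- paste0(substr(dna, 1, p - 1), sample(c("A", "C", "G", "T"), 1),
                    substr(dna, p, nchar(dna)))
    }
    rec <- c(sprintf("%s@codon%d", kinds[i], codons[i]), rec)
  }
  list(dna = dna, record = paste(rec, collapse = ","))
}

#' Plant OR genes into synthetic chromosomes
#'
#' Proteins are reverse-translated with uniform codon usage and planted,
#' with a terminal stop codon, on either strand of i.i.d. background DNA
#' (40% GC). Genes join the current tandem cluster (gap uniform up to
#' `intergene_gap_bp`) with probability `cluster_tandem_prob`, otherwise
#' start a new cluster at a fresh location. A controlled fraction is
#' pseudogenized (1-3 in-frame stops or +-1 bp frameshifts) or 3'-truncated
#' below 250 codons; every planted gene is recorded in the truth table.
#'
#' @param generated output of [generate_or_proteins()].
#' @param spec a [simulation_spec()].
#' @return a list with `genome` (data.frame as from [read_genome_fasta()])
#'   and `truth` (data.frame: gene id, coordinates, strand, class label,
#'   family/subfamily, lesion record, planted protein).
#' @export
plant_genes <- function(generated, spec) {
  set.seed(spec$rng_seed + 1L)
  prot <- generated$proteins
  n <- nrow(prot)
  n_pseudo <- round(spec$fraction_pseudogene * n)
  n_partial <- round(spec$fraction_partial * n)
  labels <- rep("functional", n)
  pick <- sample.int(n, n_pseudo + n_partial)
  labels[pick[seq_len(n_pseudo)]] <- "pseudogene"
  if (n_partial > 0)
    labels[pick[n_pseudo + seq_len(n_partial)]] <- "partial"

  chroms <- vapply(seq_len(spec$n_chromosomes), function(i)
    random_dna(spec$chromosome_length_bp), "")
  names(chroms) <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  placed <- lapply(chroms, function(x) integer(0)) # used interval bounds
  occupied <- lapply(chroms, function(x)
    data.frame(start = integer(), end = integer()))
  truth <- list()
  cur_chrom <- NA_character_
  cur_end <- NA_integer_
  L <- spec$chromosome_length_bp
  margin <- 2000L

  for (i in seq_len(n)) {
    protein <- prot$sequence[i]
    lesions <- ""
    truncated_len <- NA_integer_
    if (labels[i] == "partial") {
      truncated_len <- sample(100:240, 1)
      protein <- substr(protein, 1, truncated_len)
    }
    dna <- paste0(reverse_translate(protein), sample(STOP_CODONS, 1))
    n_codons <- nchar(protein)
    if (labels[i] == "pseudogene") {
      les <- apply_lesions(dna, n_codons, spec$lesion_guard_codons,
                           sample(1:3, 1))
      dna <- les$dna
      lesions <- les$record
    }
    strand <- sample(c("+", "-"), 1)
    insert <- if (strand == "-") revcomp(dna) else dna
    glen <- nchar(insert)

    pos <- NA_integer_
    tandem <- !is.na(cur_chrom) && runif(1) < spec$cluster_tandem_prob
    for (attempt in 1:50) {
      if (tandem && attempt == 1) {
        gap <- sample.int(spec$intergene_gap_bp, 1) + 500L
        cand_chrom <- cur_chrom
        cand <- cur_end + gap
      } else {
        cand_chrom <- sample(names(chroms), 1)
        cand <- sample.int(L - glen - 2L * margin, 1) + margin
      }
      if (cand + glen - 1L > L - margin) { tandem <- FALSE; next }
      occ <- occupied[[cand_chrom]]
      clash <- any(cand <= occ$end + 500L & cand + glen - 1L >= occ$start - 500L)
      if (!clash) { pos <- cand; break }
      tandem <- FALSE
    }
    if (is.na(pos))
      stop("could not place gene ", prot$id[i],
           "; increase chromosome_length_bp or reduce gene count")
    substr(chroms[[cand_chrom]], pos, pos + glen - 1L) <- insert
    occupied[[cand_chrom]] <- rbind(occupied[[cand_chrom]],
                                    data.frame(start = pos,
                                               end = pos + glen - 1L))
    cur_chrom <- cand_chrom
    cur_end <- pos + glen - 1L
    truth[[i]] <- data.frame(
      gene_id = prot$id[i], chrom_id = cand_chrom, start = pos,
      end = pos + glen - 1L, strand = strand, class_label = labels[i],
      family_id = prot$family_id[i], subfamily_id = prot$subfamily_id[i],
      lesions = lesions, protein = protein,
      stringsAsFactors = FALSE)
  }
  genome <- data.frame(chrom_id = names(chroms),
                       sequence = unname(chroms),
                       length_bp = nchar(unname(chroms)),
                       stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$chrom_id, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  # tandem-cluster membership of the planted coordinates under the <1 Mb
  # rule (random placement can fuse intended clusters, so membership is
  # defined on the final coordinates)
  gcl <- genomic_clusters(truth)
  cl_of <- setNames(rep(gcl$cluster_id, gcl$n_genes),
                    unlist(gcl$gene_ids))
  truth$cluster_id <- unname(cl_of[truth$gene_id])
  list(genome = genome, truth = truth)
}

#' Generate a complete synthetic OR genome with ground truth
#'
#' Convenience wrapper: [generate_or_proteins()] + [plant_genes()] +
#' [reference_queries()].
#'
#' @param spec a [simulation_spec()].
#' @return a list with `genome`, `truth`, `proteins`, `queries`, `spec`.
#' @export
simulate_or_genome <- function(spec = simulation_spec()) {
  gen <- generate_or_proteins(spec)
  planted <- plant_genes(gen, spec)
  queries <- reference_queries(gen, spec)
  list(genome = planted$genome, truth = planted$truth,
       proteins = gen$proteins, queries = queries,
       family_consensus = gen$family_consensus,
       subfamily_consensus = gen$subfamily_consensus,
       template = gen$template, spec = spec)
}

#' Synthetic human OR reference table
#'
#' Attaches synthetic receptor sequences to the published human OR
#' gene/accession/odorant metadata shipped with the package. Class I
#' entries (OR51/OR52/OR55/OR56 families) derive from one template, Class
#' II entries from another, each anchor mutated away from its class
#' template, so nearest-anchor class assignment is well defined. The
#' sequences are synthetic stand-ins, not the real human receptors.
#'
#' @param seed RNG seed.
#' @param anchor_divergence substitutions per site between an anchor and
#'   its class template.
#' @param path TSV of gene/accession/odorants/or_class metadata; defaults
#'   to the copy shipped in `inst/extdata`.
#' @return the metadata data.frame with a `sequence` column added.
#' @export
synthetic_human_or_table <- function(seed = 42L, anchor_divergence = 0.35,
                                     path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "human_or_reference_synthetic.tsv",
                        package = "ursor")
  tab <- read_human_or_table(path)
  set.seed(seed)
  spec <- simulation_spec(rng_seed = seed)
  tpl1 <- or_template(spec)
  tpl2 <- or_template(spec)
  tab$sequence <- vapply(seq_len(nrow(tab)), function(i) {
    tpl <- if (tab$or_class[i] == "I") tpl1 else tpl2
    mutate_protein(tpl$sequence, anchor_divergence, tpl$tm_mask,
                   tpl$motif_mask)
  }, "")
  tab
}
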