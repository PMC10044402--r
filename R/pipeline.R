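# Top-level pipeline: search -> best-hit retention -> chaining -> gene
# models -> clustering -> (optional) class assignment and odorant mapping,
# wrapped in a classed result object.

#' Mine the OR gene repertoire of a genome
#'
#' Runs the full pipeline: translated homology search of the query proteins
#' against the genome, best-hit retention, chaining of hit fragments into
#' loci, frameshift-aware gene-model reconstruction and
#' functional/partial/pseudogene classification, greedy family/subfamily
#' clustering of the functional proteins, genomic tandem-cluster detection,
#' and (when anchors or a human OR table are supplied) Class I/II
#' assignment and odorant-specificity transfer.
#'
#' @param genome genome data.frame ([read_genome_fasta()]) or path to a
#'   FASTA file.
#' @param queries query proteins (data.frame, named vector, or FASTA path).
#' @param config an [or_config()].
#' @param anchors optional human anchor table (`gene`, `or_class`,
#'   `sequence`) for Class I/II assignment.
#' @param human_table optional human OR odorant table with sequences for
#'   odorant transfer.
#' @param species label used in summaries.
#' @return an object of class `or_repertoire`; see [print.or_repertoire()].
#'   Components: `models`, `hsps`, `chains`, `families`, `subfamilies`,
#'   `genomic_clusters`, `chromosome_table`, `summary`, and optionally
#'   `class_assignments`, `class_split`, `odorant_map`.
#' @export
or_mine <- function(genome, queries, config = or_config(), anchors = NULL,
                    human_table = NULL, species = "synthetic") {
  if (is.character(genome) && length(genome) == 1)
    genome <- read_genome_fasta(genome)
  if (is.character(queries) && length(queries) == 1 && file.exists(queries))
    queries <- read_protein_fasta(queries)
  hsps <- search_genome(queries, genome, config)
  best <- retain_best_hits(hsps)
  chains <- chain_hsps(best, config)
  models <- build_gene_models(chains, genome, queries, config)
  fun <- models[models$class_label == "functional", , drop = FALSE]
  fun_seqs <- setNames(fun$protein, fun$gene_id)
  clusters <- if (length(fun_seqs) > 0) {
    cluster_families(fun_seqs,
                     species = setNames(rep(species, length(fun_seqs)),
                                        names(fun_seqs)),
                     config = config)
  } else list(families = NULL, subfamilies = NULL)
  sub_of <- if (!is.null(clusters$subfamilies)) {
    setNames(rep(clusters$subfamilies$cluster_id,
                 clusters$subfamilies$n_members),
             unlist(clusters$subfamilies$members))
  } else NULL
  res <- list(
    species = species,
    models = models,
    hsps = hsps,
    chains = chains,
    families = clusters$families,
    subfamilies = clusters$subfamilies,
    genomic_clusters = genomic_clusters(models, config),
    chromosome_table = chromosome_table(models,
                                        chromosomes = sort(genome$chrom_id),
                                        subfamily_of = sub_of),
    summary = summarize_repertoire(
      sum(models$class_label == "functional"),
      sum(models$class_label == "partial"),
      sum(models$class_label == "pseudogene"),
      n_families = if (is.null(clusters$families)) NA_integer_
                   else nrow(clusters$families),
      n_subfamilies = if (is.null(clusters$subfamilies)) NA_integer_
                      else nrow(clusters$subfamilies),
      species = species),
    config = config)
  if (!is.null(anchors) && nrow(fun) > 0) {
    res$class_assignments <- assign_class(fun_seqs, anchors,
                                          config = config)
    res$class_split <- class_split_summary(res$class_assignments)
  }
  if (!is.null(human_table) && nrow(fun) > 0) {
    fun$species <- species
    res$odorant_map <- map_odorants(fun, human_table, config)
  }
  class(res) <- "or_repertoire"
  res
}

#' @export
print.or_repertoire <- function(x, ...) {
  s <- x$summary
  cat("OR repertoire (", x$species, ")\n", sep = "")
  cat(sprintf("  %d OR gene models: %d functional (%.2f%%), %d partial (%.2f%%), %d pseudogenes (%.2f%%)\n",
              s$n_total, s$n_functional, s$pct_functional, s$n_partial,
              s$pct_partial, s$n_pseudogene, s$pct_pseudogene))
  if (!is.na(s$n_families))
    cat(sprintf("  functional genes in %d families / %d subfamilies\n",
                s$n_families, s$n_subfamilies))
  cat(sprintf("  %d genomic clusters (<%s bp gaps) on %d chromosome(s)\n",
              nrow(x$genomic_clusters),
              format(x$config$cluster_gap_bp, big.mark = ","),
              length(unique(x$models$chrom_id))))
  if (!is.null(x$class_split))
    cat(sprintf("  Class I: %d (%.2f%%)  Class II: %d (%.2f%%)\n",
                x$class_split$n[1], x$class_split$pct[1],
                x$class_split$n[2], x$class_split$pct[2]))
  invisible(x)
}

#' @export
summary.or_repertoire <- function(object, ...) {
  print(object)
  cat("\nPer-chromosome composition:\n")
  print(object$chromosome_table, row.names = FALSE)
  invisible(object$summary)
}

#' Plot the chromosomal distribution of OR gene models
#'
#' Simple coordinate plot: one horizontal line per chromosome with gene
#' models drawn as ticks coloured by class.
#'
#' @param x an `or_repertoire`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.or_repertoire <- function(x, ...) {
  m <- x$models
  chroms <- sort(unique(m$chrom_id))
  cols <- c(functional = "forestgreen", partial = "orange",
            pseudogene = "firebrick")
  graphics::plot(NULL, xlim = c(0, max(m$end)), ylim = c(0.5,
                 length(chroms) + 0.5), yaxt = "n", xlab = "position (bp)",
                 ylab = "", main = "OR gene models", ...)
  graphics::axis(2, at = seq_along(chroms), labels = chroms, las = 1)
  for (i in seq_along(chroms)) {
    mm <- m[m$chrom_id == chroms[i], ]
    graphics::segments(0, i, max(m$end), i, col = "grey80")
    graphics::segments(mm$start, i - 0.2, mm$start, i + 0.2,
                       col = cols[mm$class_label], lwd = 2)
  }
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
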