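# Genomic tandem-cluster detection, per-chromosome repertoire tables,
# odorant-specificity transfer from human ORs, and N-glycosylation sequon
# scanning.

#' Genomic OR gene clusters
#'
#' Per chromosome, genes are sorted by start and chained single-linkage:
#' consecutive genes whose gap (next start minus previous end) is smaller
#' than `cluster_gap_bp` (default 1 Mb) belong to one cluster.
#'
#' @param models gene-model data.frame with `chrom_id`, `start`, `end`.
#' @param config an [or_config()].
#' @return a data.frame with `cluster_id`, `chrom_id`, `start`, `end`,
#'   `n_genes` and a `gene_ids` list-column (members ordered by start).
#' @export
genomic_clusters <- function(models, config = or_config()) {
  out <- list()
  for (chrom in sort(unique(models$chrom_id))) {
    mm <- models[models$chrom_id == chrom, , drop = FALSE]
    mm <- mm[order(mm$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(mm$start[-1] - mm$end[-nrow(mm)] >=
                                     config$cluster_gap_bp)))
    for (g in split(seq_len(nrow(mm)), grp)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom_id = chrom, start = min(mm$start[g]), end = max(mm$end[g]),
        n_genes = length(g), stringsAsFactors = FALSE)
      attr(out[[length(out)]], "gene_ids") <- mm$gene_id[g]
    }
  }
  if (length(out) == 0) {
    return(data.frame(cluster_id = character(), chrom_id = character(),
                      start = integer(), end = integer(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$gene_ids <- lapply(out, attr, "gene_ids")
  res$cluster_id <- sprintf("GC%03d", seq_len(nrow(res)))
  res[, c("cluster_id", "chrom_id", "start", "end", "n_genes", "gene_ids")]
}

#' Per-chromosome repertoire composition table
#'
#' One row per chromosome with functional/partial/pseudogene/total counts
#' and, when a subfamily assignment is given, the number of distinct
#' subfamilies, plus a `Total` row equal to the column sums.
#'
#' @param models gene-model data.frame.
#' @param chromosomes optional character vector of chromosomes to report
#'   (zero rows are kept); defaults to those present.
#' @param subfamily_of optional named vector mapping gene id to subfamily id.
#' @return a data.frame with columns `chrom_id`, `functional`, `partial`,
#'   `pseudogene`, `total`, `subfamilies`.
#' @export
chromosome_table <- function(models, chromosomes = NULL,
                             subfamily_of = NULL) {
  if (is.null(chromosomes)) chromosomes <- sort(unique(models$chrom_id))
  rows <- lapply(chromosomes, function(ch) {
    mm <- models[models$chrom_id == ch, , drop = FALSE]
    nsub <- if (is.null(subfamily_of)) NA_integer_ else
      length(unique(stats::na.omit(subfamily_of[mm$gene_id])))
    data.frame(chrom_id = ch,
               functional = sum(mm$class_label == "functional"),
               partial = sum(mm$class_label == "partial"),
               pseudogene = sum(mm$class_label == "pseudogene"),
               total = nrow(mm), subfamilies = nsub,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  total <- data.frame(chrom_id = "Total",
                      functional = sum(res$functional),
                      partial = sum(res$partial),
                      pseudogene = sum(res$pseudogene),
                      total = sum(res$total),
                      subfamilies = if (is.null(subfamily_of)) NA_integer_
                        else length(unique(stats::na.omit(
                          subfamily_of[models$gene_id]))),
                      stringsAsFactors = FALSE)
  rbind(res, total)
}

#' Transfer odorant specificity from annotated human ORs
#'
#' Each functional OR gene is matched to its best human OR by global
#' identity; an annotation is emitted only when the identity reaches
#' `odorant_identity` (default 60%). Also returns the per-human-OR,
#' per-species count matrix and, for every species, the list of human ORs
#' with no match at the threshold (the species' "lacking" list).
#'
#' @param models functional gene-model data.frame (a `species` column is
#'   used when present, otherwise all genes count as one species).
#' @param human_table data.frame from [read_human_or_table()] with
#'   sequences.
#' @param config an [or_config()].
#' @return a list with `annotations` (gene, human OR, accession, identity,
#'   odorants), `counts` (human OR x species matrix of matched functional
#'   genes) and `lacking` (named list of human OR genes absent per species).
#' @export
map_odorants <- function(models, human_table, config = or_config()) {
  if (!"sequence" %in% names(human_table))
    stop("human OR table has no 'sequence' column")
  fun <- models[models$class_label == "functional", , drop = FALSE]
  species <- if ("species" %in% names(fun)) fun$species
             else rep("all", nrow(fun))
  ann <- list()
  for (i in seq_len(nrow(fun))) {
    idents <- vapply(human_table$sequence, function(h)
      pairwise_identity(fun$protein[i], h, config), 0, USE.NAMES = FALSE)
    best <- which.max(idents)
    if (idents[best] >= config$odorant_identity) {
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = fun$gene_id[i], species = species[i],
        human_or_name = human_table$gene[best],
        human_accession = human_table$accession[best],
        identity = idents[best],
        odorants = human_table$odorants[best], stringsAsFactors = FALSE)
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(gene_id = character(), species = character(),
               human_or_name = character(), human_accession = character(),
               identity = numeric(), odorants = character(),
               stringsAsFactors = FALSE)
  stopifnot(all(annotations$identity >= config$odorant_identity))
  sp_levels <- sort(unique(species))
  if (length(sp_levels) == 0) sp_levels <- "all"
  counts <- table(factor(annotations$human_or_name,
                         levels = human_table$gene),
                  factor(annotations$species, levels = sp_levels))
  counts <- unclass(as.matrix(counts))
  lacking <- lapply(sp_levels, function(sp)
    human_table$gene[counts[, sp] == 0])
  names(lacking) <- sp_levels
  list(annotations = annotations, counts = counts, lacking = lacking)
}

#' Scan a protein for N-glycosylation sequons
#'
#' Finds all N-X-[S/T] sequons with the standard X != P exclusion,
#' including overlapping ones.
#'
#' @param protein amino-acid string.
#' @return integer vector of 1-based positions of the asparagine.
#' @export
scan_nglyc_sequons <- function(protein) {
  stopifnot(nzchar(protein))
  m <- gregexpr("N(?=[^P][ST])", toupper(protein), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Write genomic clusters as BED
#'
#' @param clusters output of [genomic_clusters()].
#' @param path output file (BED: 0-based half-open).
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(clusters, path) {
  bed <- data.frame(chrom = clusters$chrom_id,
                    start = clusters$start - 1L, end = clusters$end,
                    name = clusters$cluster_id, score = clusters$n_genes,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
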