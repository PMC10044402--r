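#' Run configuration for the OR mining pipeline
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow the published OR-mining protocol: translated-search E-value
#' cutoff 1e-10, functional genes require an intact ORF of at least 250 aa,
#' families/subfamilies at >40%/>60% amino-acid identity, genomic clusters
#' chain genes less than 1 Mb apart, odorant transfer requires >=60% identity
#' to an annotated human OR, and motifs are searched at widths 5--50.
#'
#' @param evalue_threshold maximum E-value for a translated-search hit.
#' @param min_functional_aa minimum intact ORF length (aa) for a functional
#'   gene call.
#' @param family_identity,subfamily_identity greedy-clustering identity
#'   thresholds (fractions); must satisfy 0 < family < subfamily <= 1.
#' @param cluster_gap_bp maximum gap (bp) between neighbouring OR genes in
#'   one genomic cluster.
#' @param odorant_identity minimum identity to a human OR for odorant
#'   transfer.
#' @param motif_width_min,motif_width_max motif width search bounds (aa).
#' @param motif_top_k number of motifs to report.
#' @param seed_k exact-match seed length of the translated search.
#' @param chain_gap_bp maximum genomic gap (bp) when chaining hit fragments
#'   into one locus.
#' @param chain_overlap_aa tolerated query-coordinate overlap (aa) between
#'   chained fragments.
#' @param gap_open,gap_ext affine gap penalties (BLOSUM62 scale).
#' @param frameshift_cost penalty for a +-1/2 bp jump in the gene-model
#'   alignment.
#' @param flank_bp genomic flank added around a chained locus before gene
#'   model reconstruction.
#' @param lambda,karlin_k Karlin-Altschul parameters for gapped BLOSUM62
#'   (11/1) statistics.
#' @param rng_seed integer seed for the stochastic stages (motif EM
#'   restarts).
#' @return an object of class `or_config` (a validated named list).
#' @export
or_config <- function(evalue_threshold = 1e-10,
                      min_functional_aa = 250L,
                      family_identity = 0.40,
                      subfamily_identity = 0.60,
                      cluster_gap_bp = 1000000L,
                      odorant_identity = 0.60,
                      motif_width_min = 5L,
                      motif_width_max = 50L,
                      motif_top_k = 5L,
                      seed_k = 4L,
                      chain_gap_bp = 5000L,
                      chain_overlap_aa = 15L,
                      gap_open = 11,
                      gap_ext = 1,
                      frameshift_cost = 15,
                      flank_bp = 300L,
                      lambda = 0.267,
                      karlin_k = 0.041,
                      rng_seed = 1L) {
  cfg <- list(evalue_threshold = evalue_threshold,
              min_functional_aa = as.integer(min_functional_aa),
              family_identity = family_identity,
              subfamily_identity = subfamily_identity,
              cluster_gap_bp = as.integer(cluster_gap_bp),
              odorant_identity = odorant_identity,
              motif_width_min = as.integer(motif_width_min),
              motif_width_max = as.integer(motif_width_max),
              motif_top_k = as.integer(motif_top_k),
              seed_k = as.integer(seed_k),
              chain_gap_bp = as.integer(chain_gap_bp),
              chain_overlap_aa = as.integer(chain_overlap_aa),
              gap_open = gap_open,
              gap_ext = gap_ext,
              frameshift_cost = frameshift_cost,
              flank_bp = as.integer(flank_bp),
              lambda = lambda,
              karlin_k = karlin_k,
              rng_seed = as.integer(rng_seed))
  if (!(cfg$evalue_threshold > 0)) stop("evalue_threshold must be > 0")
  if (!(cfg$min_functional_aa > 0)) stop("min_functional_aa must be > 0")
  if (!(cfg$family_identity > 0 && cfg$family_identity < cfg$subfamily_identity &&
        cfg$subfamily_identity <= 1))
    stop("need 0 < family_identity < subfamily_identity <= 1")
  if (cfg$motif_width_min < 2 || cfg$motif_width_max < cfg$motif_width_min)
    stop("invalid motif width bounds")
  class(cfg) <- "or_config"
  cfg
}

#' @export
print.or_config <- function(x, ...) {
  cat("OR mining configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a run configuration as JSON
#'
#' @param config an `or_config` object.
#' @param path file path.
#' @return `read_config` returns an `or_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "or_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(or_config, vals)
}

fasta_precheck <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0)
    stop("empty FASTA file: ", path, " (line 1)")
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA header at line ", first, " of ", path)
  invisible(lines)
}

#' Read a genome FASTA
#'
#' Sequences are case-folded to upper case; record order is preserved.
#'
#' @param path FASTA file of DNA sequences (alphabet A/C/G/T/N).
#' @return a data.frame with columns `chrom_id`, `sequence`, `length_bp`.
#' @export
read_genome_fasta <- function(path) {
  fasta_precheck(path)
  set <- Biostrings::readBStringSet(path)
  ids <- unname(vapply(strsplit(names(set), "\\s+"), `[`, "", 1))
  if (anyDuplicated(ids)) stop("duplicate chromosome ids in ", path)
  seqs <- unname(toupper(as.character(set)))
  data.frame(chrom_id = ids, sequence = seqs,
             length_bp = nchar(seqs), stringsAsFactors = FALSE)
}

#' Read a protein FASTA
#'
#' Headers of the form `>id species=NAME free text` populate the `species`
#' and `annotation` columns; a bare `>id` leaves them `NA`. A `*` is allowed
#' only as the final character of a sequence.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return a data.frame with columns `id`, `species`, `sequence`,
#'   `annotation`.
#' @export
read_protein_fasta <- function(path) {
  fasta_precheck(path)
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  ids <- unname(vapply(strsplit(hdr, "\\s+"), `[`, "", 1))
  species <- ifelse(grepl("species=(\\S+)", hdr),
                    sub(".*species=(\\S+).*", "\\1", hdr), NA_character_)
  ann <- sub("^\\S+\\s*", "", hdr)
  ann <- sub("species=\\S+\\s*", "", ann)
  ann[!nzchar(trimws(ann))] <- NA_character_
  seqs <- toupper(as.character(set))
  bad <- grepl("\\*.", seqs)
  if (any(bad))
    stop("'*' before the final position in record(s): ",
         paste(ids[bad], collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence in ", path)
  data.frame(id = ids, species = species, sequence = unname(seqs),
             annotation = trimws(ann), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x a data.frame from [read_genome_fasta()] / [read_protein_fasta()],
#'   or a named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.data.frame(x)) {
    if ("chrom_id" %in% names(x)) {
      ids <- x$chrom_id
    } else {
      ids <- x$id
      extra <- character(nrow(x))
      if ("species" %in% names(x))
        extra <- ifelse(is.na(x$species), "", paste0(" species=", x$species))
      if ("annotation" %in% names(x))
        extra <- paste0(extra, ifelse(is.na(x$annotation), "",
                                      paste0(" ", x$annotation)))
      ids <- paste0(ids, extra)
    }
    seqs <- x$sequence
  } else {
    ids <- names(x)
    seqs <- unname(x)
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

disruptions_to_string <- function(d) {
  if (is.null(d) || nrow(d) == 0) return("")
  paste(paste0(d$kind, ":", d$position_bp), collapse = ",")
}

string_to_disruptions <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(kind = character(), position_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, ",")[[1]], ":")
  data.frame(kind = vapply(parts, `[`, "", 1),
             position_bp = as.integer(vapply(parts, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#'
#' Emits 1-based inclusive coordinates with the class label and any
#' disruptions carried in the attribute column.
#'
#' @param models a gene-model data.frame (see [build_gene_models()]).
#' @param path output file.
#' @param genome optional genome data.frame used to validate coordinates.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, genome = NULL) {
  if (!is.null(genome) && nrow(models) > 0) {
    len <- setNames(genome$length_bp, genome$chrom_id)
    bad <- models$start < 1 | models$end > len[models$chrom_id] |
      is.na(len[models$chrom_id])
    if (any(bad))
      stop("gene model coordinates out of chromosome bounds: ",
           paste(models$gene_id[bad], collapse = ", "))
  }
  if (nrow(models) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom_id,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = models$strand)
  S4Vectors::mcols(gr)$ID <- models$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$class_label <- models$class_label
  S4Vectors::mcols(gr)$disruptions <- models$disruptions
  S4Vectors::mcols(gr)$best_query_id <- models$best_query_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models back from GFF3
#'
#' @param path a GFF3 file written by [write_gff3()].
#' @return a data.frame with coordinates, class labels and disruptions.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(data.frame(gene_id = character(), chrom_id = character(),
                      strand = character(), start = integer(),
                      end = integer(), class_label = character(),
                      disruptions = character(), best_query_id = character(),
                      stringsAsFactors = FALSE))
  }
  mc <- S4Vectors::mcols(gr)
  data.frame(gene_id = as.character(mc$ID),
             chrom_id = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             class_label = as.character(mc$class_label),
             disruptions = ifelse(is.na(as.character(mc$disruptions)), "",
                                  as.character(mc$disruptions)),
             best_query_id = as.character(mc$best_query_id),
             stringsAsFactors = FALSE)
}

#' Read a human OR reference table
#'
#' A TSV with columns `gene`, `accession`, `odorants` (semicolon-separated),
#' `or_class` (`I`/`II`) and optionally `sequence`. The copy shipped with the
#' package (`human_or_reference_synthetic.tsv`) carries the published
#' gene/accession/odorant metadata with synthetic receptor sequences
#' generated by [synthetic_human_or_table()].
#'
#' @param path TSV file.
#' @param require_sequence error if the `sequence` column is absent.
#' @return a data.frame.
#' @export
read_human_or_table <- function(path, require_sequence = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "accession", "odorants", "or_class")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("human OR table missing column(s): ", paste(miss, collapse = ", "))
  if (require_sequence && !"sequence" %in% names(tab))
    stop("human OR table has no 'sequence' column")
  tab
}
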