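# Pairwise identity, CD-HIT-style greedy incremental clustering into
# families (>40%) and subfamilies (>60%), and cross-species cluster
# comparison.

#' Global pairwise amino-acid identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) with identity
#' defined as matches / alignment columns, gap columns counted in the
#' denominator.
#'
#' @param a,b amino-acid strings.
#' @param config an [or_config()] supplying gap penalties.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, config = or_config()) {
  stopifnot(nzchar(a), nzchar(b))
  al <- cpp_global_align(toupper(a), toupper(b), blosum62(),
                         config$gap_open, config$gap_ext)
  al$identity
}

#' All-vs-all identity matrix
#'
#' @param proteins named character vector of sequences.
#' @param config an [or_config()].
#' @return a symmetric matrix of identities with unit diagonal.
#' @export
identity_matrix <- function(proteins, config = or_config()) {
  n <- length(proteins)
  ids <- names(proteins)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2) return(m)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- pairwise_identity(proteins[[i]], proteins[[j]],
                                              config)
    }
  }
  m
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style greedy clustering: sequences are sorted by length
#' (descending; ties by id ascending); the first founds cluster 1, and each
#' subsequent sequence joins the first existing cluster whose representative
#' (founder, the longest member) it matches at or above the threshold,
#' otherwise founds a new cluster.
#'
#' @param proteins named character vector of sequences.
#' @param threshold identity threshold in `(0, 1]`.
#' @param species optional named character vector mapping sequence id to
#'   species; populates each cluster's species set.
#' @param level label stored on the clusters (`"family"`/`"subfamily"`).
#' @param best_fit if `TRUE`, join the best-matching cluster above the
#'   threshold instead of the first (non-default variant).
#' @param config an [or_config()].
#' @return a data.frame with `cluster_id`, `level`, `representative_id`,
#'   `n_members`, a `members` list-column, and a `species_set` list-column.
#' @export
greedy_cluster <- function(proteins, threshold, species = NULL,
                           level = "family", best_fit = FALSE,
                           config = or_config()) {
  stopifnot(threshold > 0, threshold <= 1)
  ids <- names(proteins)
  ord <- order(-nchar(proteins), ids)
  reps <- integer(0)          # indices (into proteins) of representatives
  membership <- integer(length(proteins))
  for (i in ord) {
    assigned <- 0L
    if (length(reps) > 0) {
      if (best_fit) {
        idents <- vapply(reps, function(r)
          pairwise_identity(proteins[[i]], proteins[[r]], config), 0)
        best <- which.max(idents)
        if (idents[best] >= threshold) assigned <- best
      } else {
        for (ci in seq_along(reps)) {
          if (pairwise_identity(proteins[[i]], proteins[[reps[ci]]],
                                config) >= threshold) {
            assigned <- ci
            break
          }
        }
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, i)
      assigned <- length(reps)
    }
    membership[i] <- assigned
  }
  res <- data.frame(cluster_id = sprintf("%s%03d", toupper(substr(level, 1, 1)),
                                         seq_along(reps)),
                    level = level,
                    representative_id = ids[reps],
                    n_members = as.integer(table(factor(membership,
                                                 seq_along(reps)))),
                    stringsAsFactors = FALSE)
  res$members <- lapply(seq_along(reps), function(ci) ids[membership == ci])
  res$species_set <- lapply(res$members, function(m) {
    if (is.null(species)) character(0) else sort(unique(unname(species[m])))
  })
  res
}

#' Hierarchical family/subfamily clustering
#'
#' Families are clustered over all sequences at `family_identity`; each
#' family is then re-clustered at `subfamily_identity`, so every subfamily
#' is nested in exactly one family.
#'
#' @param proteins named character vector of sequences.
#' @param species optional id-to-species map.
#' @param config an [or_config()].
#' @return a list with `families` and `subfamilies` data.frames; subfamily
#'   ids are `<family>.Sxx` and carry a `family_id` column.
#' @export
cluster_families <- function(proteins, species = NULL,
                             config = or_config()) {
  fams <- greedy_cluster(proteins, config$family_identity, species,
                         level = "family", config = config)
  subs <- list()
  for (fi in seq_len(nrow(fams))) {
    mem <- fams$members[[fi]]
    s <- greedy_cluster(proteins[mem], config$subfamily_identity, species,
                        level = "subfamily", config = config)
    s$cluster_id <- sprintf("%s.S%02d", fams$cluster_id[fi],
                            seq_len(nrow(s)))
    s$family_id <- fams$cluster_id[fi]
    subs[[fi]] <- s
  }
  list(families = fams, subfamilies = do.call(rbind, subs))
}

#' Cross-species cluster sharing
#'
#' Counts, for every observed species subset, the clusters whose species set
#' equals that subset (Venn-style). Clusters private to one species are the
#' "unique" clusters of that species.
#'
#' @param clusters a cluster data.frame from [greedy_cluster()] with
#'   populated `species_set`.
#' @return a data.frame with `species_subset` (`+`-joined names), `n_species`
#'   and `n_clusters`, plus an attribute `unique_counts` (named vector of
#'   single-species cluster counts).
#' @export
compare_species_clusters <- function(clusters) {
  sig <- vapply(clusters$species_set, paste, "", collapse = "+")
  tab <- table(sig)
  res <- data.frame(species_subset = names(tab),
                    n_species = lengths(strsplit(names(tab), "\\+")),
                    n_clusters = as.integer(tab),
                    stringsAsFactors = FALSE)
  res <- res[order(res$n_species, res$species_subset), , drop = FALSE]
  rownames(res) <- NULL
  singles <- res$n_species == 1
  attr(res, "unique_counts") <- setNames(res$n_clusters[singles],
                                         res$species_subset[singles])
  res
}

#' Write clusters in a CD-HIT-like .clstr layout
#'
#' @param clusters cluster data.frame.
#' @param proteins the clustered sequences (for lengths).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(clusters, proteins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(clusters))) {
    writeLines(sprintf(">Cluster %d", i - 1L), con)
    mem <- clusters$members[[i]]
    for (j in seq_along(mem)) {
      star <- if (mem[j] == clusters$representative_id[i]) "*" else ""
      writeLines(sprintf("%d\t%daa, >%s... %s", j - 1L,
                         nchar(proteins[[mem[j]]]), mem[j], star), con)
    }
  }
  invisible(path)
}
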