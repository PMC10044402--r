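# Distance-based phylogenetics: canonical neighbor-joining and Class I/II
# assignment of functional OR genes against human anchor sequences.

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining with deterministic tie-breaking
#' (the smallest index pair wins). Negative branch lengths are clamped to
#' zero and recorded in the `n_clamped` attribute.
#'
#' @param d symmetric distance matrix (zero diagonal) with dimnames, or a
#'   `dist` object.
#' @return an [ape::phylo] tree whose tips are the matrix ids.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  labels <- rownames(d)
  node <- as.list(labels)     # newick fragment per active node
  clamped <- 0L
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 2) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # smallest index pair among minima (row-major upper triangle)
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; lj <- lj + li; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; li <- li + lj; lj <- 0 }
    newd <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    merged <- sprintf("(%s:%s,%s:%s)", node[[i]], fmt(li), node[[j]], fmt(lj))
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    node <- c(node[keep], merged)
    n <- n - 1
  }
  lb <- max(d[1, 2], 0)
  if (d[1, 2] < 0) clamped <- clamped + 1L
  # attach the remaining node to the last merged node, giving the usual
  # unrooted (trifurcating) NJ layout
  inner <- sub("^\\((.*)\\)$", "\\1", node[[2]])
  nwk <- sprintf("(%s,%s:%s);", inner, node[[1]], fmt(lb))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "n_clamped") <- clamped
  tr
}

#' Identity-based distance matrix
#'
#' Distance is `1 - identity` from [pairwise_identity()]; an optional
#' Poisson correction `-log(identity)` is available for multiple hits.
#'
#' @param proteins named character vector.
#' @param correction `"none"` (default) or `"poisson"`.
#' @param config an [or_config()].
#' @return a symmetric distance matrix.
#' @export
identity_distance <- function(proteins, correction = c("none", "poisson"),
                              config = or_config()) {
  correction <- match.arg(correction)
  im <- identity_matrix(proteins, config)
  d <- 1 - im
  if (correction == "poisson") {
    eps <- 1e-6
    d <- -log(pmax(im, eps))
    diag(d) <- 0
  }
  d
}

#' Assign functional OR genes to Class I or Class II
#'
#' Each gene takes the class of its nearest human anchor under the
#' `1 - identity` distance. Class I anchors are human OR51/OR52/OR55/OR56
#' family receptors ("fish-like" clade); all other anchors are Class II.
#' Exact ties go to Class II with a warning. A joint neighbor-joining tree
#' of genes plus anchors is attached for inspection when `tree = TRUE`.
#'
#' @param proteins named character vector of functional OR proteins.
#' @param anchors data.frame with columns `gene`, `or_class` (`"I"`/`"II"`)
#'   and `sequence` (e.g. from [read_human_or_table()]).
#' @param tree also build the joint NJ tree (attribute `"tree"`).
#' @param config an [or_config()].
#' @return a data.frame with `gene_id`, `or_class`, `nearest_anchor`,
#'   `identity`.
#' @export
assign_class <- function(proteins, anchors, tree = FALSE,
                         config = or_config()) {
  stopifnot(all(c("gene", "or_class", "sequence") %in% names(anchors)))
  if (!all(c("I", "II") %in% anchors$or_class))
    stop("anchor set must contain both Class I and Class II sequences")
  res <- do.call(rbind, lapply(seq_along(proteins), function(i) {
    idents <- vapply(anchors$sequence, function(a)
      pairwise_identity(proteins[[i]], a, config), 0, USE.NAMES = FALSE)
    best <- max(idents)
    hit <- which(idents == best)
    cls <- unique(anchors$or_class[hit])
    if (length(cls) > 1) {
      warning("class tie for ", names(proteins)[i], "; assigning Class II")
      cls <- "II"
      hit <- hit[anchors$or_class[hit] == "II"]
    }
    data.frame(gene_id = names(proteins)[i], or_class = cls,
               nearest_anchor = anchors$gene[hit[1]], identity = best,
               stringsAsFactors = FALSE)
  }))
  if (tree) {
    all_seqs <- c(proteins, setNames(anchors$sequence, anchors$gene))
    attr(res, "tree") <- nj_tree(identity_distance(all_seqs,
                                                   config = config))
  }
  res
}
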