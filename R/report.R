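# Repertoire summary arithmetic: the publication-shaped tables
# (composition percentages, Class I/II split, odorant-match totals).

#' Round half away from zero at a given number of decimals
#'
#' Matches the half-up rounding style of printed repertoire tables (R's
#' `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  # the tiny offset keeps binary representations of exact halves (.x5)
  # from rounding down
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Summarize an OR repertoire
#'
#' Composition counts with half-up percentages at two decimals, family and
#' subfamily counts, and the mean number of functional genes per subfamily.
#'
#' @param n_functional,n_partial,n_pseudogene non-negative counts.
#' @param n_families,n_subfamilies optional cluster counts.
#' @param species label for the row.
#' @return a one-row data.frame of class `or_repertoire_summary`.
#' @export
summarize_repertoire <- function(n_functional, n_partial, n_pseudogene,
                                 n_families = NA_integer_,
                                 n_subfamilies = NA_integer_,
                                 species = "synthetic") {
  stopifnot(n_functional >= 0, n_partial >= 0, n_pseudogene >= 0)
  total <- n_functional + n_partial + n_pseudogene
  if (total == 0) stop("empty repertoire: total count is zero")
  res <- data.frame(
    species = species,
    n_functional = n_functional, n_partial = n_partial,
    n_pseudogene = n_pseudogene, n_total = total,
    pct_functional = round_half_up(100 * n_functional / total),
    pct_partial = round_half_up(100 * n_partial / total),
    pct_pseudogene = round_half_up(100 * n_pseudogene / total),
    n_families = n_families, n_subfamilies = n_subfamilies,
    mean_genes_per_subfamily = if (!is.na(n_subfamilies) && n_subfamilies > 0)
      round_half_up(n_functional / n_subfamilies) else NA_real_,
    stringsAsFactors = FALSE)
  class(res) <- c("or_repertoire_summary", "data.frame")
  res
}

#' Class I/II split of functional OR genes
#'
#' @param class_assignments output of [assign_class()], or a character
#'   vector of `"I"`/`"II"` labels.
#' @return a data.frame with counts and half-up percentages per class.
#' @export
class_split_summary <- function(class_assignments) {
  cls <- if (is.data.frame(class_assignments)) class_assignments$or_class
         else class_assignments
  stopifnot(length(cls) > 0)
  n1 <- sum(cls == "I")
  n2 <- sum(cls == "II")
  total <- n1 + n2
  data.frame(or_class = c("I", "II"), n = c(n1, n2),
             pct = round_half_up(100 * c(n1, n2) / total),
             stringsAsFactors = FALSE)
}

#' Odorant-match summary tables
#'
#' Per-species counts of distinct functional genes matched to annotated
#' human ORs, and the human-OR x species matrix whose column sums equal
#' those counts.
#'
#' @param odorant_map output of [map_odorants()], or a bare human-OR x
#'   species count matrix.
#' @return a list with `per_species` (named integer vector) and `counts`
#'   (the matrix).
#' @export
odorant_match_summary <- function(odorant_map) {
  counts <- if (is.list(odorant_map) && !is.null(odorant_map$counts))
    odorant_map$counts else odorant_map
  per_species <- colSums(counts)
  list(per_species = per_species, counts = counts)
}
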