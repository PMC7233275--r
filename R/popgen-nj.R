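#' Neighbour-joining clustering of populations
#'
#' Saitou-Nei neighbour joining on a pairwise population
#' differentiation matrix (typically Jost's D), returning an unrooted
#' `phylo` tree whose tips are the population ids. Use
#' [ape::write.tree()] for newick text.
#'
#' @param matrix symmetric differentiation matrix with population row
#'   names (e.g. from [pairwise_differentiation()]).
#' @return an unrooted `phylo` object.
#' @export
nj_populations <- function(matrix) {
  if (!isSymmetric(unclass(matrix), tol = 1e-8,
                   check.attributes = FALSE)) {
    abort("differentiation matrix must be symmetric")
  }
  if (nrow(matrix) < 3) abort("need at least three populations")
  ape::nj(as.dist(matrix))
}
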