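#' Mantel test for isolation by distance
#'
#' Pearson correlation between the lower triangles of a genetic
#' differentiation matrix and a geographic distance matrix, with the
#' one-sided (positive-association) permutation test: rows and columns
#' are permuted simultaneously and `p = (1 + #{r_perm >= r_obs}) /
#' (n_perm + 1)`. The permutation machinery is vegan's; both r and its
#' square are reported because squared values are what isolation-by-
#' distance studies usually print.
#'
#' @param genetic symmetric differentiation matrix (e.g. from
#'   [pairwise_differentiation()]).
#' @param geographic symmetric distance matrix from [geo_distances()],
#'   linear or log scale.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional RNG seed for reproducible permutations.
#' @return an `hrm_mantel` object: `r`, `r_squared`, `p_value`,
#'   `n_perm`, `n_pops`, `transform`.
#' @export
mantel_ibd <- function(genetic, geographic, n_perm = 9999, seed = NULL) {
  stopifnot(n_perm >= 99)
  if (!isTRUE(all.equal(dim(genetic), dim(geographic)))) {
    abort("matrices must cover the same populations")
  }
  if (!is.null(rownames(genetic)) && !is.null(rownames(geographic)) &&
      !identical(rownames(genetic), rownames(geographic))) {
    abort("population sets (row order) differ between the two matrices")
  }
  lt <- lower.tri(genetic)
  if (sd(genetic[lt]) == 0 || sd(geographic[lt]) == 0) {
    abort("constant matrix: correlation undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(as.dist(genetic), as.dist(geographic),
                       method = "pearson", permutations = n_perm)
  structure(list(r = unname(fit$statistic),
                 r_squared = unname(fit$statistic)^2,
                 p_value = fit$signif,
                 n_perm = n_perm,
                 n_pops = nrow(genetic),
                 transform = attr(geographic, "transform") %||% "linear",
                 measure = attr(genetic, "measure") %||% "genetic"),
            class = "hrm_mantel")
}

#' @export
print.hrm_mantel <- function(x, ...) {
  cat(sprintf(
    "Mantel IBD (%s vs %s distance): r = %.3f (r^2 = %.3f), p = %.4g [%d permutations]\n",
    x$measure, x$transform, x$r, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

#' @method tidy hrm_mantel
#' @export
tidy.hrm_mantel <- function(x, ...) {
  tibble(measure = x$measure, transform = x$transform, r = x$r,
         r_squared = x$r_squared, p_value = x$p_value)
}

#' @method glance hrm_mantel
#' @export
glance.hrm_mantel <- function(x, ...) {
  tibble(n_pops = x$n_pops, n_perm = x$n_perm, r = x$r,
         r_squared = x$r_squared, p_value = x$p_value)
}
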