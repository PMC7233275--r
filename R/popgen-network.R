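#' Statistical parsimony haplotype network
#'
#' Builds a tie-preserving minimum spanning network over haplotypes:
#' pairwise mutational steps are counted on the indel-coded alignment,
#' candidate edges are added in increasing step order, and at each step
#' level every edge joining components that were still separate when
#' the level began is kept (so co-minimal alternative connections are
#' retained). Edges longer than the parsimony connection limit are
#' never added, which can leave the network disconnected, exactly as in
#' statistical parsimony. Multi-step edges are annotated with the
#' inferred intermediate nodes they imply.
#'
#' @param haplotypes a [haplotype_set()] (indel-coded automatically).
#' @param frequencies optional named vector of haplotype frequencies
#'   (e.g. total counts) carried onto the nodes.
#' @param limit `"auto"` for the 95% parsimony connection limit from
#'   [parsimony_limit()], or an integer step limit.
#' @return an `hrm_spnet` object: `nodes` (tibble `id`, `frequency`),
#'   `edges` (tibble `from`, `to`, `steps`, `intermediates`), `limit`.
#' @export
sp_network <- function(haplotypes, frequencies = NULL, limit = "auto") {
  if (nrow(haplotypes) == 0) abort("empty haplotype set")
  set <- if (!isTRUE(attr(haplotypes, "indel_coded"))) reduce_indels(haplotypes)
         else haplotypes
  D <- haplotype_distances(set)
  lim <- if (identical(limit, "auto")) {
    parsimony_limit(nchar(set$sequence[1]))
  } else {
    as.integer(limit)
  }
  labs <- set$label
  n <- length(labs)
  comp <- seq_len(n)                      # union-find by relabel
  edges <- tibble(from = character(), to = character(), steps = integer())
  if (n > 1) {
    pairs <- which(upper.tri(D), arr.ind = TRUE)
    steps <- D[upper.tri(D)]
    ord <- order(steps, labs[pairs[, 1]], labs[pairs[, 2]])
    pairs <- pairs[ord, , drop = FALSE]
    steps <- steps[ord]
    for (level in sort(unique(steps))) {
      if (level > lim) break
      at <- which(steps == level)
      comp_before <- comp
      for (e in at) {
        i <- pairs[e, 1]; j <- pairs[e, 2]
        if (comp_before[i] != comp_before[j]) {
          edges <- dplyr::bind_rows(edges,
            tibble(from = labs[i], to = labs[j], steps = as.integer(level)))
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
  }
  edges$intermediates <- lapply(seq_len(nrow(edges)), function(k) {
    s <- edges$steps[k]
    if (s <= 1) character(0)
    else sprintf("%s-%s.%d", edges$from[k], edges$to[k], seq_len(s - 1))
  })
  freq <- rep(NA_real_, n)
  if (!is.null(frequencies)) freq <- unname(frequencies[labs])
  structure(list(nodes = tibble(id = labs, frequency = freq),
                 edges = edges, limit = lim),
            class = "hrm_spnet")
}

#' 95% parsimony connection limit
#'
#' The largest number of steps for which a parsimonious connection
#' between two haplotypes retains at least `1 - alpha` probability,
#' computed under a no-multiple-hit approximation: for j mutations
#' placed uniformly over m sites, the chance that all hit distinct
#' sites is `prod_{i=1}^{j-1}(1 - i/m)`; the limit is the largest j
#' keeping that above `1 - alpha`. For the alignment lengths in scope
#' this limit comfortably exceeds the observed distances.
#'
#' @param seq_length aligned sequence length m.
#' @param alpha tail probability (default 0.05).
#' @export
parsimony_limit <- function(seq_length, alpha = 0.05) {
  m <- as.numeric(seq_length)
  j <- 1L
  repeat {
    p <- prod(1 - seq_len(j) / m)          # j+1 mutations all distinct
    if (p < 1 - alpha || j >= m) break
    j <- j + 1L
  }
  j
}

#' @export
print.hrm_spnet <- function(x, ...) {
  cat(sprintf("<hrm_spnet> %d haplotypes, %d edges, connection limit %d steps\n",
              nrow(x$nodes), nrow(x$edges), x$limit))
  print(x$edges[c("from", "to", "steps")], n = Inf)
  invisible(x)
}

#' @method tidy hrm_spnet
#' @export
tidy.hrm_spnet <- function(x, ...) {
  dplyr::mutate(x$edges, n_intermediates = lengths(.data$intermediates),
                intermediates = NULL)
}

#' Convert a parsimony network to an igraph object
#' @param x an `hrm_spnet`.
#' @param expand_intermediates insert the inferred intermediate nodes
#'   of multi-step edges as degree-2 vertices.
#' @export
as_igraph <- function(x, expand_intermediates = FALSE) {
  stopifnot(inherits(x, "hrm_spnet"))
  if (!expand_intermediates || nrow(x$edges) == 0) {
    g <- igraph::graph_from_data_frame(
      x$edges[c("from", "to", "steps")], directed = FALSE,
      vertices = x$nodes)
    return(g)
  }
  el <- purrr::map_dfr(seq_len(nrow(x$edges)), function(k) {
    chain <- c(x$edges$from[k], x$edges$intermediates[[k]], x$edges$to[k])
    tibble(from = head(chain, -1), to = tail(chain, -1), steps = 1L)
  })
  verts <- tibble(id = unique(c(x$nodes$id, unlist(x$edges$intermediates))))
  verts$frequency <- x$nodes$frequency[match(verts$id, x$nodes$id)]
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}
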