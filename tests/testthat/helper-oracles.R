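# independent oracles shared by module tests and the acceptance suite

# brute-force confusion counts: enumerate every cell against the
# modal-cluster definition
oracle_confusion <- function(counts, n, hap) {
  modal <- colnames(counts)[which.max(counts[hap, ])]
  tp <- 0; fp <- 0
  for (h in rownames(counts)) {
    for (cl in colnames(counts)) {
      if (cl == modal && h == hap) tp <- tp + counts[h, cl]
      if (cl == modal && h != hap) fp <- fp + counts[h, cl]
    }
  }
  c(tp = tp, fn = unname(n[hap]) - tp, fp = fp,
    tn = sum(n[rownames(counts) != hap]) - fp)
}

# literal per-pair transcription of the differentiation formulas
oracle_pair_measure <- function(ci, cj, measure) {
  ni <- sum(ci); nj <- sum(cj)
  pi <- ci / ni; pj <- cj / nj
  hs <- mean(c(ni / (ni - 1) * (1 - sum(pi^2)),
               nj / (nj - 1) * (1 - sum(pj^2))))
  nh <- 2 / (1 / ni + 1 / nj)
  ht <- 1 - sum(((pi + pj) / 2)^2) + hs / (2 * nh)
  k <- 2
  if (ht <= 1e-12) return(0)
  v <- switch(measure,
              gst = (ht - hs) / ht,
              gpp_st = k * (ht - hs) / ((k * ht - hs) * (1 - hs)),
              jost_d = (k / (k - 1)) * (ht - hs) / (1 - hs))
  max(0, v)
}

rand_count_matrix <- function(nh, nc) {
  m <- matrix(rpois(nh * nc, 2), nh, nc, dimnames = list(LETTERS[1:nh], 1:nc))
  m[cbind(1:nh, sample(nc, nh, TRUE))] <- 5
  m
}

rand_pop_table <- function(npop = 3, nhap = 4) {
  m <- matrix(rpois(npop * nhap, 3), npop, nhap)
  m[cbind(seq_len(npop), sample(nhap, npop, TRUE))] <- 5
  out <- tibble::as_tibble(m, .name_repair = ~LETTERS[seq_len(nhap)])
  out$population <- sprintf("P%d", seq_len(npop))
  out
}

# MSN membership by definition: an edge belongs iff its endpoints are
# disconnected in the strictly-shorter-edge graph
oracle_msn_edges <- function(D) {
  n <- nrow(D)
  want <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    g <- igraph::graph_from_adjacency_matrix((D < D[i, j]) & D > 0,
                                             mode = "undirected")
    comp <- igraph::components(g)$membership
    if (comp[i] != comp[j]) {
      want <- c(want, paste(sort(c(rownames(D)[i], rownames(D)[j])),
                            collapse = "|"))
    }
  }
  sort(want)
}
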