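#' Parse a population haplotype table
#'
#' The population table mirrors the field layout: one row per
#' population with `population`, `latitude`, `longitude`, optionally
#' `group` (e.g. mountain range) and `n`, plus one count column per
#' haplotype. Any numeric column that is not one of the reserved names
#' is treated as a haplotype count.
#'
#' @param table population tibble.
#' @return list: `counts` (population x haplotype integer matrix),
#'   `coords` (tibble), `groups` (named vector or NULL).
#' @export
parse_population_table <- function(table) {
  reserved <- c("population", "name", "latitude", "longitude", "group", "n")
  hap_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                      reserved)
  if (length(hap_cols) == 0) abort("no haplotype count columns found")
  counts <- as.matrix(table[hap_cols])
  counts[is.na(counts)] <- 0
  storage.mode(counts) <- "integer"
  rownames(counts) <- table$population
  if (any(counts < 0)) abort("haplotype counts must be non-negative")
  if (any(rowSums(counts) == 0)) {
    abort(sprintf("population with zero total count: %s",
                  rownames(counts)[rowSums(counts) == 0][1]))
  }
  coords <- NULL
  if (all(c("latitude", "longitude") %in% names(table))) {
    if (any(abs(table$latitude) > 90) || any(abs(table$longitude) > 180)) {
      abort("coordinates out of range")
    }
    coords <- tibble(population = table$population,
                     latitude = table$latitude, longitude = table$longitude)
  }
  groups <- if ("group" %in% names(table)) {
    setNames(as.character(table$group), table$population)
  }
  list(counts = counts, coords = coords, groups = groups)
}

# per-pair Hs / Ht. The default estimator applies the small-sample
# correction n/(n-1) per population before averaging and adds the
# Nei-Chesser correction Hs/(k*n_harmonic) to Ht; "harmonic" applies a
# single harmonic-mean correction after averaging (the classical
# Nei-Chesser form); "raw" uses plain frequencies.
pair_diversity <- function(ci, cj, estimator) {
  ni <- sum(ci); nj <- sum(cj)
  pi_ <- ci / ni; pj <- cj / nj
  hi <- 1 - sum(pi_^2); hj <- 1 - sum(pj^2)
  nh <- 2 / (1 / ni + 1 / nj)
  hs <- switch(estimator,
    corrected = mean(c(ni / (ni - 1) * hi, nj / (nj - 1) * hj)),
    harmonic = nh / (nh - 1) * mean(c(hi, hj)),
    raw = mean(c(hi, hj)))
  ht_raw <- 1 - sum(((pi_ + pj) / 2)^2)
  ht <- if (estimator == "raw") ht_raw else ht_raw + hs / (2 * nh)
  c(hs = hs, ht = ht)
}

#' Pairwise population differentiation matrices
#'
#' Computes, for every pair of populations, one of the haplotype
#' frequency differentiation measures:
#' Gst = (Ht-Hs)/Ht; G''st = k(Ht-Hs)/((k Ht - Hs)(1-Hs));
#' Jost's D = (k/(k-1)) (Ht-Hs)/(1-Hs) (k = 2 per pair); or the
#' Prevosti distance, the mean over polymorphic sites of the
#' indel-coded alignment of half the L1 distance between the two
#' populations' per-site allele frequencies (so a collapsed indel is
#' one event). Pairs in which both populations are fixed for the same
#' haplotype have Hs = Ht = 0; Gst-family measures are undefined there
#' and are reported as 0 (no differentiation) by default, or `NA` with
#' `undefined = "na"`. Small negative estimates from the sample-size
#' corrections are truncated to 0.
#'
#' @param table population table (see [parse_population_table()]).
#' @param measure `"gst"`, `"gpp_st"`, `"jost_d"` or `"prevosti"`.
#' @param haplotypes a [haplotype_set()]; required for `"prevosti"`
#'   (indel-coded automatically).
#' @param estimator `"corrected"` (default), `"harmonic"` or `"raw"`.
#' @param undefined `"zero"` or `"na"` for fixed-same pairs.
#' @return symmetric population x population matrix, zero diagonal,
#'   with attributes `measure` and `estimator`.
#' @export
pairwise_differentiation <- function(table,
                                     measure = c("gst", "gpp_st", "jost_d",
                                                 "prevosti"),
                                     haplotypes = NULL,
                                     estimator = c("corrected", "harmonic",
                                                   "raw"),
                                     undefined = c("zero", "na")) {
  measure <- match.arg(measure)
  estimator <- match.arg(estimator)
  undefined <- match.arg(undefined)
  pt <- parse_population_table(table)
  cnt <- pt$counts
  npop <- nrow(cnt)
  if (npop < 2) abort("need at least two populations")
  site_freqs <- NULL
  if (measure == "prevosti") {
    if (is.null(haplotypes)) abort("prevosti requires haplotype sequences")
    site_freqs <- prevosti_site_setup(haplotypes, colnames(cnt))
  }
  m <- matrix(0, npop, npop, dimnames = list(rownames(cnt), rownames(cnt)))
  for (i in seq_len(npop - 1)) {
    for (j in (i + 1):npop) {
      v <- if (measure == "prevosti") {
        prevosti_pair(cnt[i, ], cnt[j, ], site_freqs)
      } else {
        hh <- pair_diversity(cnt[i, ], cnt[j, ], estimator)
        gst_family(hh["hs"], hh["ht"], measure, undefined)
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  structure(m, measure = measure, estimator = estimator)
}

gst_family <- function(hs, ht, measure, undefined, k = 2) {
  eps <- 1e-12
  if (ht <= eps) {
    return(if (undefined == "zero") 0 else NA_real_)
  }
  v <- switch(measure,
    gst = (ht - hs) / ht,
    gpp_st = k * (ht - hs) / ((k * ht - hs) * (1 - hs)),
    jost_d = (k / (k - 1)) * (ht - hs) / (1 - hs))
  unname(max(0, v))
}

# per-polymorphic-site allele indicator matrices, one per site:
# rows = haplotypes (in count-column order), cols = alleles
prevosti_site_setup <- function(haplotypes, hap_order) {
  set <- if (!isTRUE(attr(haplotypes, "indel_coded"))) reduce_indels(haplotypes)
         else haplotypes
  if (!all(hap_order %in% set$label)) {
    abort("population table haplotypes missing from the alignment")
  }
  m <- seq_matrix(set)[match(hap_order, set$label), , drop = FALSE]
  poly <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  lapply(poly, function(j) {
    al <- sort(unique(m[, j]))
    stats::model.matrix(~ 0 + factor(m[, j], levels = al))
  })
}

prevosti_pair <- function(ci, cj, site_freqs) {
  pi_ <- ci / sum(ci); pj <- cj / sum(cj)
  per_site <- vapply(site_freqs, function(ind) {
    0.5 * sum(abs(as.numeric(pi_ %*% ind) - as.numeric(pj %*% ind)))
  }, numeric(1))
  mean(per_site)
}

#' Within- and total gene diversity of a population set
#'
#' Hs is the mean small-sample-corrected within-population gene
#' diversity, Ht the diversity of the mean allele frequencies with the
#' Nei-Chesser correction.
#'
#' @inheritParams pairwise_differentiation
#' @return one-row tibble `hs`, `ht`, `k`.
#' @export
diversity_components <- function(table, estimator = c("corrected", "harmonic",
                                                      "raw")) {
  estimator <- match.arg(estimator)
  cnt <- parse_population_table(table)$counts
  k <- nrow(cnt)
  ns <- rowSums(cnt)
  p <- cnt / ns
  h <- 1 - rowSums(p^2)
  nh <- k / sum(1 / ns)
  hs <- switch(estimator,
    corrected = mean(ns / (ns - 1) * h),
    harmonic = nh / (nh - 1) * mean(h),
    raw = mean(h))
  ht_raw <- 1 - sum(colMeans(p)^2)
  ht <- if (estimator == "raw") ht_raw else ht_raw + hs / (k * nh)
  tibble(hs = hs, ht = ht, k = k)
}
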