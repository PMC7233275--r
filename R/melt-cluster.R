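#' Melt-curve clustering configuration
#'
#' Mirrors the three instrument settings used for haplotype calling: a
#' delta-Tm threshold, a curve-shape similarity threshold, and a
#' temperature-correction allowance. Two wells may share a cluster only
#' if their melt peaks differ by at most `delta_tm` *and* their
#' normalised curve shapes agree at least `shape_similarity` (shape
#' similarity is 1 minus the mean squared difference of the normalised
#' curves over the melt window, after an optimal horizontal alignment of
#' at most `temp_correction` grid increments, which absorbs
#' plate-position temperature bias; set it to 0 to disable). Clustering
#' is agglomerative with complete linkage, so the pairwise conditions
#' hold for every pair within a cluster; the vendor algorithm itself is
#' proprietary and these are explicit, documented knobs with the same
#' semantics as its three settings.
#'
#' @param delta_tm melt-peak difference threshold, degrees C.
#' @param shape_similarity minimum shape similarity, in (0, 1].
#' @param temp_correction maximum horizontal alignment, grid increments
#'   (20 increments = 4 degrees C at the 0.2 degree protocol step).
#' @param reference reference-curve rule for difference plots:
#'   `"largest_medoid"` (medoid of the largest cluster) or a well id.
#' @export
clustering_config <- function(delta_tm = 0.05, shape_similarity = 0.70,
                              temp_correction = 20L,
                              reference = "largest_medoid") {
  stopifnot(delta_tm > 0, shape_similarity > 0, shape_similarity <= 1,
            temp_correction >= 0)
  structure(list(delta_tm = delta_tm, shape_similarity = shape_similarity,
                 temp_correction = as.integer(temp_correction),
                 reference = reference),
            class = "clustering_config")
}

# shape similarity = 1 - min over grid shifts of the mean squared
# difference of the two normalised curves, restricted to `window`
shape_similarity_pair <- function(a, b, window, max_shift) {
  if (!isTRUE(all.equal(a$temperature, b$temperature))) {
    b <- tibble(temperature = a$temperature,
                fluorescence = stats::approx(b$temperature, b$fluorescence,
                                             xout = a$temperature, rule = 2)$y)
  }
  idx <- which(a$temperature >= window[1] & a$temperature <= window[2])
  n <- nrow(a)
  best <- Inf
  for (k in -max_shift:max_shift) {
    src <- idx + k
    ok <- src >= 1 & src <= n
    if (sum(ok) < 5) next
    msd <- mean((a$fluorescence[idx[ok]] - b$fluorescence[src[ok]])^2)
    if (msd < best) best <- msd
  }
  1 - best
}

# pairwise combined dissimilarity; mergeable iff d <= 1. Pairs whose
# Tm gap already exceeds the threshold skip the (more expensive) shape
# comparison: their dissimilarity is > 1 either way.
cluster_dissimilarity <- function(tm, curves, config) {
  n <- length(tm)
  window <- c(min(tm) - 2, max(tm) + 2)
  grid <- curves[[1]]$temperature
  fmat <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    ci <- curves[[i]]
    fmat[i, ] <- if (isTRUE(all.equal(ci$temperature, grid))) ci$fluorescence
    else stats::approx(ci$temperature, ci$fluorescence, xout = grid,
                       rule = 2)$y
  }
  idx <- which(grid >= window[1] & grid <= window[2])
  np <- length(grid)
  shifts <- -config$temp_correction:config$temp_correction
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    fi <- fmat[i, ]
    for (j in (i + 1):n) {
      dt <- abs(tm[i] - tm[j]) / config$delta_tm
      if (dt > 1) {
        d[i, j] <- d[j, i] <- dt
        next
      }
      fj <- fmat[j, ]
      best <- Inf
      for (k in shifts) {
        src <- idx + k
        ok <- src >= 1 & src <= np
        if (sum(ok) < 5) next
        msd <- mean((fi[idx[ok]] - fj[src[ok]])^2)
        if (msd < best) best <- msd
      }
      sim <- 1 - best
      ds <- if (config$shape_similarity >= 1) {
        if (sim >= 1 - 1e-12) 0 else Inf
      } else {
        (1 - sim) / (1 - config$shape_similarity)
      }
      d[i, j] <- d[j, i] <- max(dt, ds)
    }
  }
  d
}

# complete-linkage agglomeration, cut at height 1, canonical tie-breaks:
# always merge the pair with the smallest linkage, ties resolved by the
# lexicographically smallest (representative_i, representative_j) where a
# cluster's representative is its smallest member id. Order-independent.
complete_linkage_cut <- function(d, ids) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  link <- d
  repeat {
    k <- length(members)
    if (k == 1) break
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        v <- link[i, j]
        if (v > 1) next
        ri <- min(ids[members[[i]]]); rj <- min(ids[members[[j]]])
        key <- c(sort(c(ri, rj)))
        if (is.null(best) || v < best$v - 1e-12 ||
            (abs(v - best$v) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(v = v, i = i, j = j, key = key)
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    merged <- c(members[[i]], members[[j]])
    newlink <- pmax(link[i, ], link[j, ])[-c(i, j)]
    members <- c(members[-c(i, j)], list(merged))
    link <- rbind(cbind(link[-c(i, j), -c(i, j), drop = FALSE], newlink),
                  c(newlink, 0))
  }
  members
}

#' Cluster normalised melt curves into putative haplotypes
#'
#' @param features tibble from [normalize_plate()]: must carry `well_id`,
#'   `tm` and the `normalized` list-column.
#' @param config a [clustering_config()].
#' @return the input rows (sorted by well id) with an integer `cluster`
#'   column; clusters are labelled `1..k` in order of increasing mean
#'   Tm. Class `hrm_clusters`.
#' @export
cluster_curves <- function(features, config = clustering_config()) {
  if (nrow(features) == 0) abort("empty well group: nothing to cluster")
  ord <- order(features$well_id)
  features <- features[ord, ]
  if (nrow(features) == 1) {
    features$cluster <- 1L
  } else {
    d <- cluster_dissimilarity(features$tm, features$normalized, config)
    groups <- complete_linkage_cut(d, features$well_id)
    mean_tm <- vapply(groups, function(g) mean(features$tm[g]), numeric(1))
    min_id <- vapply(groups, function(g) min(features$well_id[g]), character(1))
    rank <- order(mean_tm, min_id)
    lab <- integer(nrow(features))
    for (k in seq_along(rank)) lab[groups[[rank[k]]]] <- k
    features$cluster <- lab
  }
  class(features) <- c("hrm_clusters", class(features))
  attr(features, "config") <- config
  features
}

#' Cluster melt curves independently per population well group
#'
#' Field screens cluster each population's wells separately (the
#' instrument's well-group function) to avoid PCR-quality variation
#' between population extractions contaminating clusters. Cluster
#' labels are local to each group.
#'
#' @inheritParams cluster_curves
#' @param group column name holding the grouping factor (default
#'   `"population_id"`).
#' @return tibble of all wells with `group_id` and local `cluster`.
#' @export
cluster_by_group <- function(features, config = clustering_config(),
                             group = "population_id") {
  g <- features[[group]]
  if (is.null(g) || anyNA(g)) {
    abort(sprintf("grouped clustering requires a complete '%s' column", group))
  }
  out <- purrr::map_dfr(split(features, g), function(part) {
    res <- cluster_curves(part, config)
    res$group_id <- part[[group]][1]
    as_tibble(res)
  })
  class(out) <- c("hrm_clusters", class(out))
  attr(out, "config") <- config
  out
}

#' Difference curves against a reference well
#'
#' Subtracts a reference well's normalised melt curve from every other
#' well's, the standard visualisation for separating clusters. The
#' default reference is the medoid of the largest cluster (smallest
#' total squared distance to its cluster mates).
#'
#' @inheritParams cluster_curves
#' @param reference a well id, or `NULL` to use the configured rule.
#' @return long tibble `well_id`, `temperature`, `delta_fluorescence`
#'   (class `hrm_difference`); the reference's own difference curve is
#'   identically zero.
#' @export
difference_curves <- function(features, reference = NULL,
                              config = clustering_config()) {
  if (is.null(reference)) {
    cl <- if ("cluster" %in% names(features)) features else
      cluster_curves(features, config)
    big <- names(which.max(table(cl$cluster)))
    in_big <- which(cl$cluster == as.integer(big))
    if (length(in_big) == 1) {
      reference <- cl$well_id[in_big]
    } else {
      window <- c(min(cl$tm) - 2, max(cl$tm) + 2)
      cost <- vapply(in_big, function(i) {
        sum(vapply(setdiff(in_big, i), function(j) {
          1 - shape_similarity_pair(cl$normalized[[i]], cl$normalized[[j]],
                                    window, 0L)
        }, numeric(1)))
      }, numeric(1))
      reference <- cl$well_id[in_big[which.min(cost)]]
    }
    features <- cl
  }
  ri <- match(reference, features$well_id)
  if (is.na(ri)) abort(sprintf("reference well '%s' not in the collection", reference))
  ref <- features$normalized[[ri]]
  out <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    cur <- features$normalized[[i]]
    f <- if (isTRUE(all.equal(cur$temperature, ref$temperature))) {
      cur$fluorescence
    } else {
      stats::approx(cur$temperature, cur$fluorescence,
                    xout = ref$temperature, rule = 2)$y
    }
    tibble(well_id = features$well_id[i], temperature = ref$temperature,
           delta_fluorescence = f - ref$fluorescence)
  })
  attr(out, "reference") <- reference
  class(out) <- c("hrm_difference", class(out))
  out
}
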