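#' Replicate matrix: haplotypes x melt clusters
#'
#' Builds the replicate-count matrix used to score HRM discrimination:
#' rows are known haplotypes, columns are melt clusters, cells count the
#' replicates of a haplotype assigned to a cluster. `n` is the number of
#' passed replicates per haplotype; it defaults to the row sums but can
#' be given explicitly because published tables occasionally print an
#' `N` that disagrees with the cell counts, and `N` is treated as
#' authoritative (rows where they disagree are flagged downstream).
#'
#' @param counts long tibble with `haplotype`, `cluster`, `count`, or a
#'   haplotype-by-cluster matrix.
#' @param n optional named vector of passed replicates per haplotype.
#' @export
replicate_matrix <- function(counts, n = NULL) {
  if (is.matrix(counts)) {
    m <- counts
  } else {
    stopifnot(all(c("haplotype", "cluster", "count") %in% names(counts)))
    haps <- sort(unique(counts$haplotype))
    cls <- sort(unique(as.integer(counts$cluster)))
    m <- matrix(0L, length(haps), length(cls), dimnames = list(haps, cls))
    for (i in seq_len(nrow(counts))) {
      m[counts$haplotype[i], as.character(as.integer(counts$cluster[i]))] <-
        as.integer(counts$count[i])
    }
  }
  if (any(m < 0)) abort("replicate counts must be non-negative")
  nn <- rowSums(m)
  if (!is.null(n)) {
    nn[names(n)] <- as.integer(n)
  }
  structure(list(counts = m, n = nn), class = "replicate_matrix")
}

#' @export
print.replicate_matrix <- function(x, ...) {
  cat(sprintf("<replicate_matrix> %d haplotypes x %d clusters, n = %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$n)))
  print(cbind(x$counts, N = x$n))
  invisible(x)
}

#' Confusion counts for one haplotype of a replicate matrix
#'
#' True positives are the focal haplotype's replicates in its *modal*
#' cluster (largest count, ties to the lowest cluster label); false
#' negatives are its remaining replicates; false positives are other
#' haplotypes' replicates in that modal cluster; true negatives are the
#' other haplotypes' remaining replicates. Two haplotypes may share a
#' modal cluster - that is exactly the specificity-below-100 case - so
#' no uniqueness is forced.
#'
#' @param x a [replicate_matrix()].
#' @param haplotype focal haplotype (row name).
#' @return one-row tibble: `haplotype`, `modal_cluster`, `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_from_matrix <- function(x, haplotype) {
  stopifnot(inherits(x, "replicate_matrix"))
  if (!haplotype %in% rownames(x$counts)) {
    abort(sprintf("haplotype '%s' not in matrix", haplotype))
  }
  row <- x$counts[haplotype, ]
  if (all(row == 0)) abort(sprintf("haplotype '%s': no passed replicates", haplotype))
  modal <- which(row == max(row))[1]          # columns sorted by label
  others <- setdiff(rownames(x$counts), haplotype)
  tp <- row[modal]
  fn <- x$n[haplotype] - tp
  fp <- sum(x$counts[others, modal, drop = TRUE])
  tn <- sum(x$n[others]) - fp
  tibble(haplotype = haplotype,
         modal_cluster = colnames(x$counts)[modal],
         tp = as.integer(tp), fn = as.integer(fn),
         fp = as.integer(fp), tn = as.integer(tn))
}

#' Score HRM discrimination for every haplotype of a replicate matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and accuracy =
#' (TP+TN)/(TP+FP+TN+FN), per haplotype, as percentages. Both the exact
#' values and integer round-half-up percentages are reported (published
#' tables round inconsistently, so exact values are kept alongside).
#' Rows whose declared `n` disagrees with the cell counts are flagged.
#'
#' @param x a [replicate_matrix()].
#' @return tibble with one row per haplotype: confusion counts, exact
#'   percentages (`sensitivity`, `specificity`, `accuracy`) and rounded
#'   integer percentages (`*_pct`), plus `n` and `count_mismatch`.
#' @export
score_discrimination <- function(x) {
  stopifnot(inherits(x, "replicate_matrix"))
  out <- purrr::map_dfr(rownames(x$counts), function(h) confusion_from_matrix(x, h))
  out$n <- as.integer(x$n[out$haplotype])
  out$count_mismatch <- rowSums(x$counts)[out$haplotype] != x$n[out$haplotype]
  out$sensitivity <- 100 * out$tp / (out$tp + out$fn)
  out$specificity <- 100 * out$tn / (out$tn + out$fp)
  out$accuracy <- 100 * (out$tp + out$tn) / (out$tp + out$fn + out$fp + out$tn)
  out$sensitivity_pct <- round_half_up(out$sensitivity)
  out$specificity_pct <- round_half_up(out$specificity)
  out$accuracy_pct <- round_half_up(out$accuracy)
  out[c("haplotype", "n", "modal_cluster", "tp", "fn", "fp", "tn",
        "sensitivity", "specificity", "accuracy",
        "sensitivity_pct", "specificity_pct", "accuracy_pct",
        "count_mismatch")]
}

#' Build and score a replicate matrix from a live cluster assignment
#'
#' Cross-tabulates a cluster assignment against known haplotype truth
#' and scores it. Every clustered well must have a truth label.
#'
#' @param assignment tibble with `well_id` and `cluster` (e.g. from
#'   [cluster_curves()]).
#' @param truth tibble with `well_id` and `haplotype`, or a named
#'   character vector keyed by well id.
#' @return list with the `replicate_matrix` and the `summary` tibble
#'   from [score_discrimination()].
#' @export
evaluate_run <- function(assignment, truth) {
  if (!is.data.frame(truth)) {
    truth <- tibble(well_id = names(truth), haplotype = unname(truth))
  }
  lab <- truth$haplotype[match(assignment$well_id, truth$well_id)]
  if (anyNA(lab)) {
    abort(sprintf("no truth label for well(s): %s",
                  paste(head(assignment$well_id[is.na(lab)], 3), collapse = ", ")))
  }
  counts <- dplyr::count(tibble(haplotype = lab,
                                cluster = as.integer(assignment$cluster)),
                         .data$haplotype, .data$cluster, name = "count")
  rm <- replicate_matrix(counts)
  list(matrix = rm, summary = score_discrimination(rm))
}

#' Pool wild-screen discrimination across population groups
#'
#' Field screens cluster per population; discrimination of the whole
#' screen is scored by summing each population's confusion counts and
#' recomputing the percentages from the pooled counts.
#'
#' @param assignments grouped assignment tibble (from
#'   [cluster_by_group()]) with a `group_id` column.
#' @param truth as in [evaluate_run()].
#' @return list of `per_group` summaries and a `pooled` tibble of
#'   overall sensitivity/specificity/accuracy.
#' @export
evaluate_screen <- function(assignments, truth) {
  per <- lapply(split(as_tibble(assignments), assignments$group_id),
                function(part) evaluate_run(part, truth)$summary)
  counts <- purrr::map_dfr(per, ~.x) |>
    dplyr::summarise(tp = sum(.data$tp), fn = sum(.data$fn),
                     fp = sum(.data$fp), tn = sum(.data$tn))
  pooled <- dplyr::mutate(counts,
    sensitivity = 100 * .data$tp / (.data$tp + .data$fn),
    specificity = 100 * .data$tn / (.data$tn + .data$fp),
    accuracy = 100 * (.data$tp + .data$tn) /
      (.data$tp + .data$fn + .data$fp + .data$tn))
  list(per_group = per, pooled = pooled)
}
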