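#' Aligned haplotype sequences for one locus
#'
#' A small container for the aligned haplotype sequences of a locus:
#' a tibble of `label` and `sequence` (aligned, `-` for gaps) with the
#' locus name and an indel-coding flag as attributes.
#'
#' @param labels haplotype labels (unique).
#' @param sequences aligned sequences, equal lengths.
#' @param locus locus name.
#' @param indel_coded whether gap runs have been collapsed already.
#' @export
haplotype_set <- function(labels, sequences, locus = "locus",
                          indel_coded = FALSE) {
  sequences <- toupper(sequences)
  if (anyDuplicated(labels)) abort("haplotype labels must be unique")
  if (length(unique(nchar(sequences))) != 1) {
    abort("ragged alignment: sequences must have equal aligned lengths")
  }
  structure(tibble(label = as.character(labels), sequence = sequences),
            locus = locus, indel_coded = indel_coded,
            class = c("haplotype_set", class(tibble())))
}

#' Read a haplotype alignment from FASTA
#' @param path FASTA file (aligned; `-` gaps allowed).
#' @param locus locus name recorded on the set.
#' @export
read_haplotype_fasta <- function(path, locus = "locus") {
  x <- Biostrings::readBStringSet(path)
  haplotype_set(names(x), as.character(x), locus = locus)
}

#' Write a haplotype set to FASTA
#' @param set a [haplotype_set()].
#' @param path output path.
#' @export
write_haplotype_fasta <- function(set, path) {
  x <- Biostrings::BStringSet(setNames(set$sequence, set$label))
  Biostrings::writeXStringSet(x, path)
  invisible(set)
}

seq_matrix <- function(set) {
  do.call(rbind, strsplit(set$sequence, "", fixed = TRUE))
}

#' Collapse every shared gap run to a single indel column
#'
#' Downstream distance-based analyses (parsimony networks, AMOVA,
#' Prevosti) must count a multi-base indel as one mutational event, so
#' each maximal run of alignment columns sharing an identical gap
#' pattern is reduced to a single column in which the gap is a fifth
#' character state. Point-substitution columns are untouched.
#'
#' @param set a [haplotype_set()].
#' @return the indel-coded set (flagged, so repeated application is a
#'   no-op on gapless alignments).
#' @export
reduce_indels <- function(set) {
  m <- seq_matrix(set)
  if (!any(m == "-")) {
    attr(set, "indel_coded") <- TRUE
    return(set)
  }
  pat <- apply(m == "-", 2, function(col) paste(which(col), collapse = ","))
  keep <- rep(TRUE, ncol(m))
  run_start <- 1L
  for (j in seq_len(ncol(m))) {
    new_run <- j == 1 || pat[j] != pat[j - 1] || pat[j] == ""
    if (new_run) run_start <- j
    if (pat[j] != "" && j > run_start) keep[j] <- FALSE
  }
  m2 <- m[, keep, drop = FALSE]
  haplotype_set(set$label, apply(m2, 1, paste, collapse = ""),
                locus = attr(set, "locus"), indel_coded = TRUE)
}

#' Pairwise mutational differences between haplotypes
#'
#' Counts columns at which two haplotypes differ on the (indel-coded)
#' alignment; the gap state counts as a fifth character, so a collapsed
#' indel is one difference.
#'
#' @param set a [haplotype_set()], indel-coded for event counting.
#' @return symmetric integer matrix of difference counts.
#' @export
haplotype_distances <- function(set) {
  m <- seq_matrix(set)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(set$label, set$label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

#' Tidy table of variable sites between haplotypes
#'
#' Lists the variable columns of an alignment relative to a reference
#' haplotype, classifying substitutions into the four melt-behaviour
#' SNP classes (1: transition; 2: C/A or G/T transversion; 3: C/G
#' transversion; 4: A/T transversion) and reporting gap runs as indels.
#'
#' @param set a [haplotype_set()] (not yet indel-coded).
#' @param reference reference haplotype label (default: first).
#' @return tibble `position`, `type`, `snp_class`, `ref`, plus one
#'   allele column per haplotype.
#' @export
haplotype_differences <- function(set, reference = set$label[1]) {
  m <- seq_matrix(set)
  rownames(m) <- set$label
  varying <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  if (length(varying) == 0) {
    return(tibble(position = integer(), type = character(),
                  snp_class = integer(), ref = character()))
  }
  rows <- lapply(varying, function(j) {
    col <- m[, j]
    ref <- col[reference]
    if (any(col == "-")) {
      tibble(position = j, type = "indel", snp_class = NA_integer_, ref = ref)
    } else {
      alt <- setdiff(unique(col), ref)[1]
      tibble(position = j, type = "substitution",
             snp_class = snp_class(ref, alt), ref = ref)
    }
  })
  out <- dplyr::bind_rows(rows)
  for (h in set$label) out[[h]] <- m[h, varying]
  # merge contiguous columns of one indel event into a single row
  is_indel <- out$type == "indel"
  run_id <- cumsum(!(is_indel & dplyr::lag(is_indel, default = FALSE) &
                       out$position == dplyr::lag(out$position, default = -5L) + 1L))
  out |>
    dplyr::mutate(.run = run_id) |>
    dplyr::group_by(.data$.run) |>
    dplyr::summarise(position = min(.data$position), type = .data$type[1],
                     snp_class = .data$snp_class[1], ref = .data$ref[1],
                     length = dplyr::n(),
                     dplyr::across(dplyr::all_of(set$label), ~.x[1]),
                     .groups = "drop") |>
    dplyr::select(-".run")
}

# melt-behaviour SNP classes: transitions shift Tm the most, C<->G and
# A<->T transversions are GC/length neutral and shift it least
snp_class <- function(a, b) {
  pair <- paste(sort(c(a, b)), collapse = "")
  switch(pair,
         "AG" = 1L, "CT" = 1L,
         "AC" = 2L, "GT" = 2L,
         "CG" = 3L,
         "AT" = 4L,
         NA_integer_)
}

#' Assign verified haplotype identities to duplicate-run samples
#'
#' Each sample runs in duplicate; both wells belong to a per-population
#' cluster, and each (group, cluster) has been verified by sequencing a
#' minimum number of its members. Samples whose duplicates agree get the
#' cluster's verified haplotype (`inferred`, or `confirmed` when the
#' sample itself was sequenced); duplicates landing in clusters with
#' different verified identities are flagged `conflict` and excluded
#' from downstream frequency tables until an explicit sequencing
#' override resolves them (no majority vote).
#'
#' @param assignments tibble with `group_id`, `well_id`, `sample_id`,
#'   `cluster` (from [cluster_by_group()]).
#' @param verification tibble `group_id`, `cluster`, `haplotype`,
#'   `n_sequenced` mapping each cluster to its sequenced identity.
#' @param sequenced character vector of sample ids that were themselves
#'   sequenced (become `confirmed`).
#' @param overrides optional tibble `sample_id`, `haplotype` of
#'   sequencing resolutions for conflicted samples.
#' @return tibble `sample_id`, `group_id`, `haplotype`, `status`
#'   (`confirmed` / `inferred` / `conflict`).
#' @export
assign_haplotypes <- function(assignments, verification,
                              sequenced = character(), overrides = NULL) {
  need <- dplyr::distinct(as_tibble(assignments),
                          .data$group_id, .data$cluster)
  ver <- dplyr::left_join(need, as_tibble(verification),
                          by = c("group_id", "cluster"))
  if (anyNA(ver$haplotype)) {
    miss <- ver[is.na(ver$haplotype), ]
    abort(paste0("unverified cluster(s) need sequencing: ",
                 paste(sprintf("%s/cluster %s", miss$group_id, miss$cluster),
                       collapse = ", ")))
  }
  if (anyDuplicated(verification[c("group_id", "cluster")])) {
    abort("each (group, cluster) must map to exactly one haplotype")
  }
  joined <- dplyr::left_join(as_tibble(assignments), as_tibble(verification),
                             by = c("group_id", "cluster"))
  calls <- joined |>
    dplyr::group_by(.data$sample_id, .data$group_id) |>
    dplyr::summarise(haps = list(unique(.data$haplotype)), .groups = "drop") |>
    dplyr::arrange(.data$sample_id)
  calls$haplotype <- vapply(calls$haps, function(h) {
    if (length(h) == 1) h else NA_character_
  }, character(1))
  calls$status <- ifelse(is.na(calls$haplotype), "conflict",
                         ifelse(calls$sample_id %in% sequenced,
                                "confirmed", "inferred"))
  if (!is.null(overrides)) {
    i <- match(calls$sample_id, overrides$sample_id)
    hit <- !is.na(i) & calls$status == "conflict"
    calls$haplotype[hit] <- overrides$haplotype[i[hit]]
    calls$status[hit] <- "confirmed"
  }
  calls[c("sample_id", "group_id", "haplotype", "status")]
}

#' Sequencing burden of a verification design
#'
#' Counts the samples that must be Sanger-sequenced under the
#' cluster-verification rule: a minimum number per cluster per
#' population (clusters smaller than the minimum sequence all members)
#' plus every duplicate-conflicted sample.
#'
#' @inheritParams assign_haplotypes
#' @param min_per_cluster verification minimum (default 3).
#' @return one-row tibble: `n_verification`, `n_conflict`, `n_total`,
#'   `fraction` of distinct samples.
#' @export
sequencing_burden <- function(assignments, min_per_cluster = 3L) {
  a <- as_tibble(assignments)
  per_sample <- a |>
    dplyr::group_by(.data$group_id, .data$sample_id) |>
    dplyr::summarise(n_clusters = dplyr::n_distinct(.data$cluster),
                     cluster = .data$cluster[1], .groups = "drop")
  conflicts <- per_sample[per_sample$n_clusters > 1, ]
  consistent <- per_sample[per_sample$n_clusters == 1, ]
  ver <- consistent |>
    dplyr::count(.data$group_id, .data$cluster) |>
    dplyr::mutate(seq_n = pmin(.data$n, min_per_cluster))
  n_samples <- dplyr::n_distinct(a$sample_id)
  tibble(n_verification = sum(ver$seq_n),
         n_conflict = nrow(conflicts),
         n_total = sum(ver$seq_n) + nrow(conflicts),
         fraction = (sum(ver$seq_n) + nrow(conflicts)) / n_samples)
}

#' Concatenate per-locus haplotype calls and alignments
#'
#' Chloroplast loci are maternally co-inherited without recombination,
#' so per-locus calls are concatenated into multilocus haplotypes.
#' Every sample must have a call at every locus.
#'
#' @param calls tibble `sample_id`, `locus`, `haplotype` covering all
#'   loci (e.g. stacked [assign_haplotypes()] outputs).
#' @param sets named list of [haplotype_set()]s, one per locus, in
#'   concatenation order.
#' @param labels optional named character vector renaming the observed
#'   locus combinations (names are `"hapA/hapB"` combination strings).
#' @return list: `set` (the concatenated [haplotype_set()], one
#'   sequence per observed combination) and `calls` (per-sample
#'   concatenated haplotype).
#' @export
concatenate_loci <- function(calls, sets, labels = NULL) {
  loci <- names(sets)
  wide <- tidyr::pivot_wider(as_tibble(calls)[c("sample_id", "locus", "haplotype")],
                             names_from = "locus", values_from = "haplotype")
  bad <- wide$sample_id[!stats::complete.cases(wide[loci])]
  if (length(bad) > 0) {
    abort(sprintf("missing locus call for sample(s): %s",
                  paste(head(bad, 3), collapse = ", ")))
  }
  combo <- apply(wide[loci], 1, paste, collapse = "/")
  combos <- sort(unique(combo))
  seqs <- vapply(combos, function(cb) {
    parts <- strsplit(cb, "/", fixed = TRUE)[[1]]
    paste(vapply(seq_along(loci), function(k) {
      s <- sets[[k]]
      s$sequence[match(parts[k], s$label)]
    }, character(1)), collapse = "")
  }, character(1))
  if (anyNA(seqs) || any(!nzchar(seqs))) abort("locus call without matching haplotype sequence")
  out_labels <- if (!is.null(labels)) unname(labels[combos]) else combos
  set <- haplotype_set(out_labels, unname(seqs),
                       locus = paste(loci, collapse = "+"),
                       indel_coded = all(vapply(sets, attr, TRUE, "indel_coded")))
  call_lab <- setNames(out_labels, combos)
  list(set = set,
       calls = tibble(sample_id = wide$sample_id,
                      haplotype = unname(call_lab[combo])))
}
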