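#' Collapse identical locus sequences to unique alleles
#'
#' Multilocus haplotypes can be identical at a single locus; clustering
#' and verification at that locus operate on the distinct locus
#' alleles. Alleles are labelled `<locus>.1`, `<locus>.2`, ... in order
#' of first appearance.
#'
#' @param set per-locus [haplotype_set()] (labels = multilocus
#'   haplotypes, sequences possibly duplicated).
#' @return list: `set` (unique-allele [haplotype_set()]) and `map`
#'   (tibble `haplotype`, `allele`).
#' @export
locus_alleles <- function(set) {
  locus <- attr(set, "locus")
  uniq <- !duplicated(set$sequence)
  allele_of_seq <- setNames(sprintf("%s.%d", locus, seq_len(sum(uniq))),
                            set$sequence[uniq])
  map <- tibble(haplotype = set$label,
                allele = unname(allele_of_seq[set$sequence]))
  list(set = haplotype_set(unname(allele_of_seq), names(allele_of_seq),
                           locus = locus),
       map = map)
}

#' Derive a cluster-verification table from per-well truth
#'
#' Emulates the sequencing-verification step in simulation studies:
#' each per-population cluster is assigned the modal true haplotype of
#' its wells, with `n_sequenced` the number of members sequenced under
#' the minimum-per-cluster rule.
#'
#' @param assignments grouped cluster assignment (from
#'   [cluster_by_group()]).
#' @param well_truth tibble `well_id`, `haplotype` (true identity per
#'   well).
#' @param min_per_cluster verification minimum.
#' @export
verify_from_truth <- function(assignments, well_truth, min_per_cluster = 3L) {
  joined <- dplyr::left_join(as_tibble(assignments)[c("group_id", "well_id",
                                                      "cluster")],
                             well_truth[c("well_id", "haplotype")],
                             by = "well_id")
  joined |>
    dplyr::group_by(.data$group_id, .data$cluster) |>
    dplyr::summarise(
      haplotype = names(sort(table(.data$haplotype), decreasing = TRUE))[1],
      n_sequenced = min(min_per_cluster, dplyr::n()),
      .groups = "drop")
}

#' Simulate and analyse a full wild-population screen
#'
#' Runs the whole field workflow on simulated data, locus by locus:
#' simulate duplicate-well melt plates from the population table,
#' normalise, cluster per population, verify clusters against the
#' simulator's truth (the stand-in for Sanger sequencing), call sample
#' haplotypes, resolve duplicate conflicts by sequencing override,
#' concatenate loci and tabulate haplotype frequencies per population.
#'
#' @param table population table (counts per multilocus haplotype +
#'   coordinates/groups).
#' @param sets named list of per-locus [haplotype_set()]s whose labels
#'   are the multilocus haplotypes (e.g.
#'   `list("atpI-atpH" = hrm_wild_haplotypes("atpI-atpH"), ...)`).
#' @param model a [snp_class_model()].
#' @param config a [sim_config()]; per-locus runs use
#'   `seed + (locus index - 1)`.
#' @param cluster_config a [clustering_config()].
#' @return list: `calls` (per-sample concatenated haplotype + status),
#'   `frequencies` (population x haplotype counts recovered),
#'   `discrimination` (pooled per-locus sensitivity/specificity/
#'   accuracy), `burden` (sequencing burden per locus), `conflicts`
#'   (samples whose duplicates split), `truth` (simulated sample
#'   truth).
#' @export
run_wild_screen <- function(table, sets = list(
                              "atpI-atpH" = hrm_wild_haplotypes("atpI-atpH"),
                              "ndhA" = hrm_wild_haplotypes("ndhA")),
                            model = snp_class_model(),
                            config = sim_config(),
                            cluster_config = clustering_config()) {
  loci <- names(sets)
  per_locus <- vector("list", length(loci))
  names(per_locus) <- loci
  truth <- screen_design(table, config)
  for (k in seq_along(loci)) {
    la <- locus_alleles(sets[[k]])
    cfg <- config
    cfg$seed <- config$seed + (k - 1L)
    sim <- simulate_population_screen(table, sets[[k]], model, cfg,
                                      design = truth)
    allele_truth <- tibble(
      well_id = sim$well_truth$well_id,
      haplotype = la$map$allele[match(sim$well_truth$haplotype,
                                      la$map$haplotype)])
    feats <- normalize_plate(screen_plate(sim$wells))
    cl <- cluster_by_group(feats, cluster_config)
    ver <- verify_from_truth(cl, allele_truth)
    calls <- assign_haplotypes(cl, ver)
    # sequencing override for duplicate conflicts: the simulator's
    # sample-level truth stands in for the Sanger result
    conflicted <- calls$sample_id[calls$status == "conflict"]
    if (length(conflicted) > 0) {
      tru <- sim$truth[match(conflicted, sim$truth$sample_id), ]
      overrides <- tibble(
        sample_id = conflicted,
        haplotype = la$map$allele[match(tru$haplotype, la$map$haplotype)])
      calls <- assign_haplotypes(cl, ver, overrides = overrides)
      calls$status[calls$sample_id %in% conflicted] <- "confirmed"
    }
    per_locus[[k]] <- list(
      calls = dplyr::mutate(calls, locus = loci[k],
                            conflicted = .data$sample_id %in% conflicted),
      allele_map = la, discrimination = evaluate_screen(cl, allele_truth),
      burden = sequencing_burden(cl))
  }
  locus_calls <- purrr::map_dfr(per_locus, function(x) {
    dplyr::rename(x$calls[c("sample_id", "locus", "haplotype")],
                  haplotype = "haplotype")
  })
  # label the observed allele combinations with the multilocus names
  maps <- purrr::map(per_locus, function(x) x$allele_map$map)
  hap_names <- maps[[1]]$haplotype
  combos <- vapply(hap_names, function(h) {
    paste(vapply(maps, function(m) m$allele[match(h, m$haplotype)],
                 character(1)), collapse = "/")
  }, character(1))
  conc <- concatenate_loci(locus_calls, purrr::map(per_locus, function(x)
    x$allele_map$set), labels = setNames(hap_names, combos))
  calls <- conc$calls
  calls$population_id <- truth$population_id[match(calls$sample_id,
                                                   truth$sample_id)]
  calls$conflicted <- calls$sample_id %in%
    unlist(purrr::map(per_locus, function(x)
      x$calls$sample_id[x$calls$conflicted]))
  freq <- calls |>
    dplyr::count(.data$population_id, .data$haplotype) |>
    tidyr::pivot_wider(names_from = "haplotype", values_from = "n",
                       values_fill = 0L)
  list(calls = calls,
       frequencies = freq,
       discrimination = purrr::map(per_locus, function(x)
         x$discrimination$pooled),
       burden = purrr::map_dfr(per_locus, function(x) x$burden,
                               .id = "locus"),
       conflicts = unique(calls$sample_id[calls$conflicted]),
       truth = truth)
}
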