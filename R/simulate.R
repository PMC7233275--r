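#' SNP-class melt-effect model
#'
#' Expected melt-peak shifts per nucleotide difference, by melt
#' behaviour class: transitions (class 1) shift Tm the most, C/A and
#' G/T transversions (class 2) less, and the GC-neutral C/G (class 3)
#' and A/T (class 4) transversions produce near-negligible changes.
#' Indels shift Tm per deleted/inserted base pair. The magnitudes are
#' simulator parameters motivated by those qualitative orderings, not
#' measured values. The shift sign follows the GC change of the
#' derived allele (GC-increasing substitutions melt higher); GC-neutral
#' classes shift positive by convention. `shape_distortion` perturbs
#' the melt transition width per accumulated difference, giving
#' variant curves slightly different shapes as well as shifted peaks.
#'
#' @param class_dtm length-4 numeric, degrees C per SNP of classes 1-4.
#' @param indel_dtm_per_bp degrees C per indel base pair (deletions
#'   melt lower).
#' @param shape_distortion transition-width change per difference,
#'   degrees C.
#' @export
snp_class_model <- function(class_dtm = c(0.5, 0.25, 0.05, 0.05),
                            indel_dtm_per_bp = 0.05,
                            shape_distortion = 0.002) {
  stopifnot(length(class_dtm) == 4, all(class_dtm >= 0),
            indel_dtm_per_bp >= 0, shape_distortion >= 0)
  if (!(class_dtm[1] >= class_dtm[2] && class_dtm[2] >= class_dtm[3])) {
    abort("class effects must be ordered class1 >= class2 >= class3")
  }
  structure(list(class_dtm = class_dtm, indel_dtm_per_bp = indel_dtm_per_bp,
                 shape_distortion = shape_distortion),
            class = "snp_class_model")
}

#' Simulation run configuration
#'
#' @param seed RNG seed for the run.
#' @param replicates replicates per haplotype in primer-evaluation
#'   designs (protocol default 16).
#' @param noise_sd fluorescence noise, raw units (amplitude is 1000).
#' @param tm_jitter_sd per-well melt-peak jitter, degrees C.
#' @param failure_rate probability a well fails to amplify.
#' @param split_rate probability a field sample's second duplicate well
#'   amplifies a different haplotype (pipetting/contamination model);
#'   such samples are what duplicate screening is designed to catch.
#' @param melt_steepness logistic melt transition scale, degrees C.
#' @export
sim_config <- function(seed = 1L, replicates = 16L, noise_sd = 1,
                       tm_jitter_sd = 0.005, failure_rate = 0,
                       split_rate = 0, melt_steepness = 0.4) {
  stopifnot(noise_sd >= 0, tm_jitter_sd >= 0,
            failure_rate >= 0, failure_rate <= 1,
            split_rate >= 0, split_rate <= 1, melt_steepness > 0)
  structure(list(seed = as.integer(seed), replicates = as.integer(replicates),
                 noise_sd = noise_sd, tm_jitter_sd = tm_jitter_sd,
                 failure_rate = failure_rate, split_rate = split_rate,
                 melt_steepness = melt_steepness),
            class = "sim_config")
}

#' Empirical amplicon melting temperature
#'
#' The empirical amplicon formula `Tm = 81.5 + 0.41 * %GC - 675 / length`
#' (degrees C). Deterministic; sequences must be gap-free ACGT of at
#' least 50 bp.
#'
#' @param sequence DNA string (ACGT).
#' @export
predict_tm <- function(sequence) {
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(s) < 50) abort("sequence too short for the amplicon Tm model (< 50 bp)")
  if (!all(s %in% c("A", "C", "G", "T"))) {
    abort("non-ACGT character in sequence (degap before calling)")
  }
  gc <- 100 * mean(s %in% c("G", "C"))
  81.5 + 0.41 * gc - 675 / length(s)
}

#' Model melt peaks for each haplotype of an alignment
#'
#' The reference (default: first) haplotype melts at its
#' [predict_tm()]; every other haplotype is offset by the sum of its
#' signed SNP-class effects and indel effects relative to the
#' reference.
#'
#' @param set a [haplotype_set()].
#' @param model a [snp_class_model()].
#' @param reference reference haplotype label.
#' @return tibble `label`, `tm`, `n_diff` (differences vs reference).
#' @export
haplotype_tm <- function(set, model = snp_class_model(),
                         reference = set$label[1]) {
  base <- predict_tm(gsub("-", "", set$sequence[match(reference, set$label)],
                          fixed = TRUE))
  diffs <- haplotype_differences(set, reference)
  out <- tibble(label = set$label, tm = base, n_diff = 0L)
  if (nrow(diffs) == 0) return(out)
  for (h in set$label) {
    if (h == reference) next
    offs <- 0
    nd <- 0L
    for (k in seq_len(nrow(diffs))) {
      ref_a <- diffs$ref[k]
      hap_a <- diffs[[h]][k]
      if (hap_a == ref_a) next
      nd <- nd + 1L
      if (diffs$type[k] == "indel") {
        len <- diffs$length[k]
        offs <- offs + if (hap_a == "-") -len * model$indel_dtm_per_bp
                       else len * model$indel_dtm_per_bp
      } else {
        mag <- model$class_dtm[diffs$snp_class[k]]
        gc_ref <- ref_a %in% c("G", "C")
        gc_hap <- hap_a %in% c("G", "C")
        sign <- if (gc_hap && !gc_ref) 1 else if (gc_ref && !gc_hap) -1 else 1
        offs <- offs + sign * mag
      }
    }
    i <- match(h, out$label)
    out$tm[i] <- base + offs
    out$n_diff[i] <- nd
  }
  out
}

melt_grid <- function() seq(65, 95, by = 0.2)

# raw melt curve: linear dye drift + logistic dissociation + noise
simulate_melt_curve <- function(tm, config, distortion = 0) {
  tmps <- melt_grid()
  s <- config$melt_steepness + distortion
  drift <- 400 - 3 * (tmps - 65)
  f <- drift + 1000 * stats::plogis((tm - tmps) / s) +
    rnorm(length(tmps), sd = config$noise_sd)
  tibble(temperature = tmps, fluorescence = f)
}

simulate_amp_curve <- function(config, failed = FALSE) {
  cyc <- 1:40
  f <- if (failed) {
    50 + rnorm(40, sd = config$noise_sd)
  } else {
    50 + 1500 * stats::plogis((cyc - 22) / 1.8) + rnorm(40, sd = config$noise_sd)
  }
  tibble(cycle = cyc, fluorescence = f)
}

#' Simulate one well's melt and amplification curves
#'
#' @param tm true melt peak for the well, degrees C.
#' @param config a [sim_config()] (the caller controls the RNG state;
#'   seed once per run).
#' @param failed simulate an amplification failure (flat curve, melt
#'   still recorded as baseline noise).
#' @param distortion melt-width distortion, degrees C.
#' @return list `melt`, `amplification`, `tm` (jittered truth).
#' @export
simulate_melt <- function(tm, config = sim_config(), failed = FALSE,
                          distortion = 0) {
  tm_actual <- tm + rnorm(1, sd = config$tm_jitter_sd)
  melt <- if (failed) {
    tibble(temperature = melt_grid(),
           fluorescence = 60 + rnorm(length(melt_grid()), sd = config$noise_sd))
  } else {
    simulate_melt_curve(tm_actual, config, distortion)
  }
  list(melt = melt, amplification = simulate_amp_curve(config, failed),
       tm = tm_actual)
}

#' Simulate a primer-evaluation plate (replicates of known haplotypes)
#'
#' Emulates the primer-testing design: every haplotype amplified in
#' `config$replicates` replicate wells on one plate, with optional
#' designated amplification failures.
#'
#' @param set a [haplotype_set()] of the amplicon's haplotypes.
#' @param model a [snp_class_model()].
#' @param config a [sim_config()] (its seed is set here).
#' @param fail_wells optional character vector of well ids forced to
#'   fail; otherwise failures are drawn at `config$failure_rate`.
#' @return list: `wells` (plate tibble as from [read_plate()]),
#'   `truth` (tibble `well_id`, `haplotype`, `tm_true`, `failed`).
#' @export
simulate_primer_test <- function(set, model = snp_class_model(),
                                 config = sim_config(), fail_wells = NULL) {
  set.seed(config$seed)
  tms <- haplotype_tm(set, model)
  design <- tidyr::expand_grid(haplotype = set$label,
                               replicate_index = seq_len(config$replicates))
  design$well_id <- sprintf("%s%02d",
                            LETTERS[match(design$haplotype, set$label)],
                            design$replicate_index)
  design$failed <- if (is.null(fail_wells)) {
    runif(nrow(design)) < config$failure_rate
  } else {
    design$well_id %in% fail_wells
  }
  sims <- purrr::map(seq_len(nrow(design)), function(i) {
    tm <- tms$tm[match(design$haplotype[i], tms$label)]
    dist <- model$shape_distortion * tms$n_diff[match(design$haplotype[i], tms$label)]
    simulate_melt(tm, config, failed = design$failed[i], distortion = dist)
  })
  wells <- tibble(plate_id = "SIM1", well_id = design$well_id,
                  sample_id = design$haplotype,
                  population_id = NA_character_,
                  replicate_index = design$replicate_index,
                  known_haplotype = design$haplotype,
                  amplification = purrr::map(sims, "amplification"),
                  melt = purrr::map(sims, "melt"))
  truth <- tibble(well_id = design$well_id, haplotype = design$haplotype,
                  tm_true = vapply(sims, function(x) x$tm, numeric(1)),
                  failed = design$failed)
  list(wells = wells, truth = truth)
}

#' Simulate a wild-population HRM screen for one locus
#'
#' Each accession of the population table is run in duplicate; wells
#' are grouped per population (the instrument well-group design).
#' Sample haplotypes follow the table's exact counts (no resampling).
#' With `config$split_rate > 0`, a sample may have its second well
#' amplify a different haplotype drawn from the locus set (the
#' contamination/pipetting error duplicates are designed to catch);
#' such samples are marked in the truth table.
#'
#' @param table population table (counts per haplotype).
#' @param set [haplotype_set()] for the locus, labels covering the
#'   table's haplotype columns.
#' @param model a [snp_class_model()].
#' @param config a [sim_config()] (seed set here).
#' @param design optional precomputed [screen_design()]; pass the same
#'   design to several loci so duplicate-splits (extract contamination)
#'   are consistent across them.
#' @return list: `wells` plate tibble, `truth` per sample
#'   (`sample_id`, `population_id`, `haplotype`, `split`,
#'   `contaminant`), `well_truth` per well (`well_id`, `haplotype`, the
#'   haplotype that actually melted).
#' @export
simulate_population_screen <- function(table, set,
                                       model = snp_class_model(),
                                       config = sim_config(),
                                       design = NULL) {
  set.seed(config$seed)
  pt <- parse_population_table(table)
  tms <- haplotype_tm(set, model)
  samples <- design %||% screen_design(table, config)
  wells <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    hap2 <- if (samples$split[i]) samples$contaminant[i]
            else samples$haplotype[i]
    tibble(sample_id = samples$sample_id[i],
           population_id = samples$population_id[i],
           replicate_index = 1:2,
           haplotype = c(samples$haplotype[i], hap2))
  })
  wells$well_id <- sprintf("%s.%d", wells$sample_id, wells$replicate_index)
  sims <- purrr::map(seq_len(nrow(wells)), function(i) {
    k <- match(wells$haplotype[i], tms$label)
    simulate_melt(tms$tm[k], config,
                  distortion = model$shape_distortion * tms$n_diff[k])
  })
  plate <- tibble(plate_id = "SCREEN1", well_id = wells$well_id,
                  sample_id = wells$sample_id,
                  population_id = wells$population_id,
                  replicate_index = wells$replicate_index,
                  known_haplotype = NA_character_,
                  amplification = purrr::map(sims, "amplification"),
                  melt = purrr::map(sims, "melt"))
  list(wells = plate,
       truth = samples,
       well_truth = tibble(well_id = wells$well_id,
                           haplotype = wells$haplotype,
                           tm_true = vapply(sims, function(x) x$tm, numeric(1))))
}

#' Sample design for a wild-population screen
#'
#' Expands a population table into its accessions (one per counted
#' haplotype copy, no resampling) and draws which samples suffer a
#' duplicate split: their second well amplifies a contaminant
#' haplotype, preferentially another haplotype of the same population
#' (neighbouring-well carry-over), falling back to any other haplotype
#' of the table for monomorphic populations.
#'
#' @param table population table.
#' @param config a [sim_config()] (`split_rate`, `seed`).
#' @return tibble `sample_id`, `population_id`, `haplotype`, `split`,
#'   `contaminant`.
#' @export
screen_design <- function(table, config = sim_config()) {
  set.seed(config$seed)
  pt <- parse_population_table(table)
  samples <- purrr::map_dfr(rownames(pt$counts), function(p) {
    tibble(population_id = p,
           haplotype = rep(colnames(pt$counts), pt$counts[p, ]))
  })
  samples$sample_id <- sprintf("%s-%03d", samples$population_id,
                               stats::ave(seq_len(nrow(samples)),
                                          samples$population_id,
                                          FUN = seq_along))
  samples$split <- runif(nrow(samples)) < config$split_rate
  samples$contaminant <- NA_character_
  for (i in which(samples$split)) {
    pop_haps <- colnames(pt$counts)[pt$counts[samples$population_id[i], ] > 0]
    alt <- setdiff(pop_haps, samples$haplotype[i])
    if (length(alt) == 0) alt <- setdiff(colnames(pt$counts),
                                         samples$haplotype[i])
    samples$contaminant[i] <- alt[1 + (i %% length(alt))]
  }
  samples[c("sample_id", "population_id", "haplotype", "split", "contaminant")]
}
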