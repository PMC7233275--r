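#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions squared inter-haplotype distances across a
#' group / population / individual hierarchy in the classical
#' sums-of-squared-deviations framework: variance components for
#' among-groups, among-populations-within-groups and
#' within-populations, their percentages, the Phi statistics
#' (Phi_CT, Phi_SC, Phi_ST) and permutation p-values. The inter-
#' haplotype distance is the mismatch count on the indel-coded
#' alignment, used directly as the squared distance (set
#' `square = TRUE` to square the counts instead).
#'
#' Permutation schemes follow the standard per-level designs:
#' individuals among populations across the whole data set (Phi_ST),
#' individuals among populations within groups (Phi_SC), and whole
#' populations among groups (Phi_CT).
#'
#' @param table population table with a `group` column (the hierarchy).
#' @param haplotypes a [haplotype_set()] covering the count columns
#'   (indel-coded automatically).
#' @param n_perm permutations per level.
#' @param seed RNG seed.
#' @param square square the mismatch counts before use.
#' @return an `hrm_amova` object; `tidy()` gives the component table.
#' @export
amova <- function(table, haplotypes, n_perm = 999, seed = NULL,
                  square = FALSE) {
  pt <- parse_population_table(table)
  if (is.null(pt$groups)) abort("population table lacks a 'group' column")
  groups <- pt$groups[rownames(pt$counts)]
  if (length(unique(groups)) < 2) {
    abort("only one group: use a one-level AMOVA instead")
  }
  set <- if (!isTRUE(attr(haplotypes, "indel_coded"))) reduce_indels(haplotypes)
         else haplotypes
  D <- haplotype_distances(set)
  if (!all(colnames(pt$counts) %in% rownames(D))) {
    abort("population table haplotypes missing from the alignment")
  }
  D <- D[colnames(pt$counts), colnames(pt$counts)]
  if (square) D <- D^2
  obs <- amova_components(pt$counts, groups, D)

  if (!is.null(seed)) set.seed(seed)
  # individual-level representation for the permutation schemes
  ind_hap <- rep(rep(colnames(pt$counts), nrow(pt$counts)), as.vector(t(pt$counts)))
  ind_pop <- rep(rownames(pt$counts), rowSums(pt$counts))
  pops <- rownames(pt$counts)
  perm_stats <- matrix(NA_real_, n_perm, 3)
  for (b in seq_len(n_perm)) {
    # Phi_ST: shuffle individuals among all populations
    st <- amova_components(tabulate_counts(ind_pop, sample(ind_hap), pops,
                                           colnames(pt$counts)), groups, D)
    # Phi_SC: shuffle individuals among populations within each group
    hap_sc <- ind_hap
    for (g in unique(groups)) {
      in_g <- ind_pop %in% pops[groups == g]
      hap_sc[in_g] <- sample(hap_sc[in_g])
    }
    sc <- amova_components(tabulate_counts(ind_pop, hap_sc, pops,
                                           colnames(pt$counts)), groups, D)
    # Phi_CT: shuffle whole populations among groups
    ct <- amova_components(pt$counts, setNames(sample(groups), pops), D)
    perm_stats[b, ] <- c(st$phi["phi_st"], sc$phi["phi_sc"], ct$phi["phi_ct"])
  }
  pvals <- c(
    phi_ct = (1 + sum(perm_stats[, 3] >= obs$phi["phi_ct"])) / (n_perm + 1),
    phi_sc = (1 + sum(perm_stats[, 2] >= obs$phi["phi_sc"])) / (n_perm + 1),
    phi_st = (1 + sum(perm_stats[, 1] >= obs$phi["phi_st"])) / (n_perm + 1))
  structure(c(obs, list(p_values = pvals, n_perm = n_perm)),
            class = "hrm_amova")
}

tabulate_counts <- function(pop, hap, pops, haps) {
  t(vapply(pops, function(p) {
    tabulate(factor(hap[pop == p], levels = haps), nbins = length(haps))
  }, integer(length(haps))))
}

# Excoffier-style sums of squared deviations; `sq` holds delta^2
amova_components <- function(counts, groups, sq) {
  groups <- groups[rownames(counts)]
  np <- rowSums(counts)
  N <- sum(np)
  P <- nrow(counts)
  G <- length(unique(groups))
  ss <- function(v) as.numeric(t(v) %*% sq %*% v)    # over ordered pairs
  ssd_total <- ss(colSums(counts)) / (2 * N)
  ssd_wp <- sum(vapply(seq_len(P), function(p) ss(counts[p, ]) / (2 * np[p]),
                       numeric(1)))
  ssd_wg <- sum(vapply(unique(groups), function(g) {
    v <- colSums(counts[groups == g, , drop = FALSE])
    ss(v) / (2 * sum(v))
  }, numeric(1)))
  ssd_ap <- ssd_wg - ssd_wp
  ssd_ag <- ssd_total - ssd_wg
  df <- c(ag = G - 1, ap = P - G, wp = N - P)
  ms <- c(ssd_ag, ssd_ap, ssd_wp) / df
  s2g <- sum(vapply(unique(groups), function(g) {
    sum(np[groups == g]^2) / sum(np[groups == g])
  }, numeric(1)))
  a <- (N - s2g) / (P - G)
  b <- (s2g - sum(np^2) / N) / (G - 1)
  cc <- (N - sum(tapply(np, groups, sum)^2) / N) / (G - 1)
  # negative components are truncated to zero (hierarchically), so the
  # reported percentages stay in [0, 100] and sum to 100
  sig_c <- unname(ms[3])
  sig_b <- max(0, unname(ms[2] - sig_c) / a)
  sig_a <- max(0, unname(ms[1] - sig_c - b * sig_b) / cc)
  tot <- sig_a + sig_b + sig_c
  phi <- c(phi_ct = sig_a / tot,
           phi_sc = sig_b / (sig_b + sig_c),
           phi_st = (sig_a + sig_b) / tot)
  list(ssd = c(ag = ssd_ag, ap = ssd_ap, wp = ssd_wp, total = ssd_total),
       df = df, ms = setNames(ms, names(df)),
       sigma = c(ag = sig_a, ap = sig_b, wp = sig_c),
       percent = 100 * c(ag = sig_a, ap = sig_b, wp = sig_c) / tot,
       phi = phi)
}

#' @export
print.hrm_amova <- function(x, ...) {
  cat("AMOVA\n")
  print(tidy(x), n = Inf)
  cat(sprintf("Phi_CT = %.3f (p = %.4g), Phi_SC = %.3f (p = %.4g), Phi_ST = %.3f (p = %.4g)\n",
              x$phi["phi_ct"], x$p_values["phi_ct"],
              x$phi["phi_sc"], x$p_values["phi_sc"],
              x$phi["phi_st"], x$p_values["phi_st"]))
  invisible(x)
}

#' @method tidy hrm_amova
#' @export
tidy.hrm_amova <- function(x, ...) {
  tibble(source = c("among_groups", "among_populations_within_groups",
                    "within_populations"),
         df = as.integer(x$df),
         sum_sq = unname(x$ssd[c("ag", "ap", "wp")]),
         mean_sq = unname(x$ms),
         variance = unname(x$sigma),
         percent = unname(x$percent))
}

#' @method glance hrm_amova
#' @export
glance.hrm_amova <- function(x, ...) {
  tibble(phi_ct = unname(x$phi["phi_ct"]), phi_sc = unname(x$phi["phi_sc"]),
         phi_st = unname(x$phi["phi_st"]),
         p_phi_ct = unname(x$p_values["phi_ct"]),
         p_phi_sc = unname(x$p_values["phi_sc"]),
         p_phi_st = unname(x$p_values["phi_st"]),
         n_perm = x$n_perm)
}
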