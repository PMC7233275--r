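# shared builders for melt-curve tests

hrm_grid <- seq(65, 95, by = 0.2)

# raw (unnormalised) logistic melt curve with linear dye drift
raw_melt <- function(tm, s = 0.4, drift_slope = -3, noise = 0, amp = 1000) {
  f <- 400 + drift_slope * (hrm_grid - 65) + amp * plogis((tm - hrm_grid) / s)
  if (noise > 0) f <- f + rnorm(length(f), sd = noise)
  tibble::tibble(temperature = hrm_grid, fluorescence = f)
}

# already-normalised logistic melt curve
norm_melt <- function(tm, s = 0.4) {
  tibble::tibble(temperature = hrm_grid,
                 fluorescence = plogis((tm - hrm_grid) / s))
}

# feature rows ready for cluster_curves(): one row per (well, tm)
feature_rows <- function(tms, ids = sprintf("W%02d", seq_along(tms)),
                         s = 0.4) {
  tibble::tibble(
    well_id = ids,
    tm = tms,
    normalized = lapply(tms, norm_melt, s = s))
}

# sigmoid amplification curve
raw_amp <- function(amp = 1500, noise = 0) {
  f <- 50 + amp * plogis((1:40 - 22) / 1.8)
  if (noise > 0) f <- f + rnorm(40, sd = noise)
  tibble::tibble(cycle = 1:40, fluorescence = f)
}

# toy alignment: A reference; haplotype k carries k-1 GC-raising
# transitions, so model melt peaks are spaced 0.5 degrees C apart
toy_haps <- function(n_haps = 4, len = 120, seed = 42) {
  set.seed(seed)
  # low-GC composition keeps the modelled amplicon Tm near 85 C, well
  # inside the 65-95 melt window
  base <- sample(c("A", "T", "G", "C"), len, TRUE, prob = c(.39, .39, .11, .11))
  if (n_haps > 1) {
    base[11:(9 + n_haps)] <- rep(c("T", "A"), length.out = n_haps - 1)
  }
  seqs <- vapply(seq_len(n_haps), function(k) {
    s <- base
    if (k > 1) {
      at <- 10 + seq_len(k - 1)
      s[at] <- c(T = "C", A = "G")[s[at]]    # transitions, GC-raising
    }
    paste(s, collapse = "")
  }, character(1))
  haplotype_set(LETTERS[seq_len(n_haps)], seqs, locus = "toy")
}
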