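mk_assign <- function(df) {
  df$well_id <- paste0(df$sample_id, ".", ave(seq_len(nrow(df)),
                                              df$sample_id, FUN = seq_along))
  df
}

test_that("duplicate-consistent samples inherit the cluster's verified haplotype", {
  a <- mk_assign(tibble::tibble(group_id = "P1",
                                sample_id = c("s1", "s1", "s2", "s2"),
                                cluster = c(1L, 1L, 1L, 2L)))
  ver <- tibble::tibble(group_id = "P1", cluster = 1:2,
                        haplotype = c("HapA", "HapB"), n_sequenced = 3L)
  calls <- assign_haplotypes(a, ver, sequenced = "s1")
  expect_equal(calls$haplotype[calls$sample_id == "s1"], "HapA")
  expect_equal(calls$status[calls$sample_id == "s1"], "confirmed")
  expect_equal(calls$status[calls$sample_id == "s2"], "conflict")
  expect_true(is.na(calls$haplotype[calls$sample_id == "s2"]))
  # explicit sequencing override resolves the conflict
  fixed <- assign_haplotypes(a, ver,
    overrides = tibble::tibble(sample_id = "s2", haplotype = "HapB"))
  expect_equal(fixed$haplotype[fixed$sample_id == "s2"], "HapB")
  expect_equal(fixed$status[fixed$sample_id == "s2"], "confirmed")
  # every sample has exactly one status
  expect_setequal(calls$status, c("confirmed", "conflict"))
  expect_equal(nrow(calls), 2)
})

test_that("calls fail loudly when a cluster lacks verification", {
  a <- mk_assign(tibble::tibble(group_id = "P1",
                                sample_id = c("s1", "s1"), cluster = 3L))
  ver <- tibble::tibble(group_id = "P1", cluster = 1L, haplotype = "HapA",
                        n_sequenced = 3L)
  expect_error(assign_haplotypes(a, ver), "cluster 3")
})

test_that("assignment is invariant to input row order", {
  set.seed(3)
  a <- mk_assign(tibble::tibble(
    group_id = rep("P1", 20),
    sample_id = rep(sprintf("s%02d", 1:10), each = 2),
    cluster = sample(1:2, 20, TRUE)))
  ver <- tibble::tibble(group_id = "P1", cluster = 1:2,
                        haplotype = c("HapA", "HapB"), n_sequenced = 3L)
  c1 <- assign_haplotypes(a, ver)
  c2 <- assign_haplotypes(a[sample(nrow(a)), ], ver)
  expect_identical(c1, c2)
})

test_that("indel runs collapse to single mutational events", {
  s1 <- strsplit("ACGTACGTACGTACG", "")[[1]]
  s2 <- s1
  s2[4:10] <- "-"                     # 7 bp deletion
  s2[13] <- "G"                       # plus one substitution
  set <- haplotype_set(c("H1", "H2"),
                       c(paste(s1, collapse = ""), paste(s2, collapse = "")))
  red <- reduce_indels(set)
  expect_true(attr(red, "indel_coded"))
  d <- haplotype_distances(red)
  expect_equal(unname(d["H1", "H2"]), 2)  # one 7 bp gap + one substitution
  # gapless alignments pass through unchanged
  set2 <- haplotype_set(c("a", "b"), c("ACGT", "ACTT"))
  expect_identical(reduce_indels(set2)$sequence, set2$sequence)
})

test_that("post-reduction distances match a brute-force event-counting oracle", {
  oracle_pair <- function(s1, s2) {
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    both <- a != "-" & b != "-"
    subs <- sum(both & a != b)
    gap_state <- (a == "-") | (b == "-")
    # maximal runs where the gap pattern (which sequence is gapped) is constant
    pat <- ifelse(a == "-" & b == "-", "both",
                  ifelse(a == "-", "a", ifelse(b == "-", "b", "none")))
    runs <- rle(pat)
    events <- sum(runs$values %in% c("a", "b"))
    subs + events
  }
  set.seed(21)
  for (rep in 1:30) {
    len <- 40
    base <- sample(c("A", "C", "G", "T"), len, TRUE)
    mk <- function() {
      s <- base
      s[sample(len, 3)] <- sample(c("A", "C", "G", "T"), 3, TRUE)
      g0 <- sample(len - 6, 1)
      if (runif(1) < 0.7) s[g0:(g0 + sample(2:5, 1))] <- "-"
      paste(s, collapse = "")
    }
    set <- haplotype_set(c("x", "y"), c(mk(), mk()))
    got <- haplotype_distances(reduce_indels(set))["x", "y"]
    expect_equal(unname(got), oracle_pair(set$sequence[1], set$sequence[2]))
  }
})

test_that("locus concatenation produces the combined alignment and calls", {
  s1 <- hrm_wild_haplotypes("atpI-atpH")
  s2 <- hrm_wild_haplotypes("ndhA")
  calls <- tidyr::expand_grid(sample_id = sprintf("s%d", 1:5),
                              locus = c("atpI-atpH", "ndhA"))
  calls$haplotype <- rep(LETTERS[1:5], each = 2)
  out <- concatenate_loci(calls, list("atpI-atpH" = s1, "ndhA" = s2))
  expect_equal(unique(nchar(out$set$sequence)), 217 + 344)
  expect_equal(nrow(out$set), 5)
  # single locus is an identity on the label set
  one <- concatenate_loci(calls[calls$locus == "atpI-atpH", ],
                          list("atpI-atpH" = s1))
  expect_equal(sort(unique(one$calls$haplotype)),
               sort(unique(calls$haplotype[calls$locus == "atpI-atpH"])))
  # missing locus call is an error naming the sample
  expect_error(concatenate_loci(calls[-1, ],
                                list("atpI-atpH" = s1, "ndhA" = s2)), "s1")
  # when every sample is identical at locus 2, concatenated richness
  # equals locus-1 richness
  calls2 <- calls
  calls2$haplotype[calls2$locus == "ndhA"] <- "A"
  out2 <- concatenate_loci(calls2, list("atpI-atpH" = s1, "ndhA" = s2))
  l1 <- length(unique(calls2$haplotype[calls2$locus == "atpI-atpH"]))
  expect_equal(nrow(out2$set), l1)
})

test_that("sequencing burden on the reference population design stays below 29%", {
  res <- run_wild_screen(hrm_table5(),
                         config = sim_config(seed = 1, noise_sd = 0,
                                             tm_jitter_sd = 0))
  expect_true(all(res$burden$fraction < 0.29))
})
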