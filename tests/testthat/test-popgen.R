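test_that("differentiation is zero for identical populations and maximal for fixed differences", {
  t5 <- hrm_table5()
  for (ms in c("gst", "gpp_st", "jost_d")) {
    m <- pairwise_differentiation(t5, ms)
    expect_true(isSymmetric(unclass(m)))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1 + 1e-9))
    # both fixed for the same haplotype: no differentiation
    expect_equal(m["BP", "KNYS"], 0)
    # fixed for different haplotypes: complete differentiation
    if (ms == "jost_d") expect_equal(unname(m["GAR", "BP"]), 1, tolerance = 1e-12)
  }
  # standardisation inflates: G''st >= Gst whenever Hs > 0
  g <- pairwise_differentiation(t5, "gst")
  gp <- pairwise_differentiation(t5, "gpp_st")
  expect_true(all(gp >= g - 1e-9))
})

test_that("differentiation matrices match the literal-transcription oracle on random tables", {
  set.seed(31)
  for (rep in 1:30) {
    tab <- rand_pop_table()
    cnt <- as.matrix(tab[LETTERS[1:4]])
    for (ms in c("gst", "gpp_st", "jost_d")) {
      m <- pairwise_differentiation(tab, ms)
      for (i in 1:2) for (j in (i + 1):3) {
        expect_equal(unname(m[i, j]),
                     oracle_pair_measure(cnt[i, ], cnt[j, ], ms),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("prevosti distance counts indels as single events on per-site frequencies", {
  tab <- tibble::tibble(population = c("P1", "P2"),
                        A = c(10L, 0L), D = c(0L, 10L))
  haps <- hrm_wild_haplotypes()
  m <- pairwise_differentiation(tab, "prevosti",
                                haplotypes = haps[haps$label %in% c("A", "D"), ])
  # restricted to A and D the polymorphic columns are exactly their
  # differences (one SNP + the collapsed indel), each fixed between the
  # two populations -> mean per-site half-L1 distance is 1
  expect_equal(unname(m["P1", "P2"]), 1)
  expect_error(pairwise_differentiation(tab, "prevosti"), "sequences")
})

test_that("haversine distances satisfy closed-form and external-oracle checks", {
  t5 <- hrm_table5()
  gd <- geo_distances(t5)
  expect_true(all(diag(gd) == 0))
  # antipodal points: half the great circle
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-6)
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(c(22.40, -33.88), c(22.67, -33.91),
                                  r = 6371008.8) / 1000
  expect_equal(unname(gd["OUT", "BP"]), ref, tolerance = 0.005)
  # log transform rejects coincident populations
  t5b <- t5; t5b$latitude[2] <- t5b$latitude[1]; t5b$longitude[2] <- t5b$longitude[1]
  expect_error(geo_distances(t5b, "log"), "zero distance")
})

test_that("mantel test recovers perfect association and rejects constants", {
  t5 <- hrm_table5()
  gd <- geo_distances(t5)
  gen <- 0.001 * gd + 0.01          # affine transform of distance
  attr(gen, "transform") <- NULL
  res <- mantel_ibd(gen, gd, n_perm = 999, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(res$r_squared, res$r^2)
  const <- gd * 0
  expect_error(mantel_ibd(const, gd), "constant")
})

test_that("AMOVA handles degenerate and hand-computed cases exactly", {
  haps <- toy_haps(2)               # one transition apart
  # identical frequency vectors everywhere: all variance within
  tab <- tibble::tibble(population = sprintf("P%d", 1:4),
                        group = rep(c("G1", "G2"), each = 2),
                        A = 5L, B = 5L)
  res <- amova(tab, haps, n_perm = 49, seed = 1)
  expect_equal(unname(res$percent["wp"]), 100, tolerance = 1e-9)
  expect_equal(unname(res$percent["ag"] + res$percent["ap"]), 0,
               tolerance = 1e-9)
  # two groups fixed for private haplotypes one step apart, n = 2:
  # hand calculation gives sigma = (0.5, 0, 0) -> 100% among groups
  tab2 <- tibble::tibble(population = sprintf("P%d", 1:4),
                         group = rep(c("G1", "G2"), each = 2),
                         A = c(2L, 2L, 0L, 0L), B = c(0L, 0L, 2L, 2L))
  res2 <- amova(tab2, haps, n_perm = 49, seed = 1)
  expect_equal(unname(res2$sigma), c(0.5, 0, 0), tolerance = 1e-12)
  expect_equal(unname(res2$percent["ag"]), 100, tolerance = 1e-9)
  expect_equal(sum(res2$percent), 100, tolerance = 1e-6)
  expect_equal(unname(res2$phi["phi_ct"]), 1, tolerance = 1e-12)
  # permutation p-values reproducible under a fixed seed
  res3 <- amova(tab2, haps, n_perm = 49, seed = 1)
  expect_identical(res2$p_values, res3$p_values)
  tab2$group <- "G1"
  expect_error(amova(tab2, haps, n_perm = 9), "one group")
})

test_that("neighbour joining recovers additive tree metrics exactly", {
  # 3 populations: unique unrooted topology, additive branch lengths
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("P1", "P2", "P3"), c("P1", "P2", "P3")))
  tr <- nj_populations(m)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("P1", "P2", "P3"))
  # branch lengths solve the three-point system: x+y=3, x+z=4, y+z=5
  lens <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(unname(lens[c("P1", "P2", "P3")]), c(1, 2, 3))
  # additive 5x5 metric from a known tree is recovered exactly
  set.seed(9)
  tree <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
  dm <- ape::cophenetic.phylo(tree)
  rec <- nj_populations(dm)
  expect_equal(ape::dist.topo(ape::unroot(tree), rec), 0,
               ignore_attr = TRUE)
  expect_error(nj_populations(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("parsimony networks are tie-preserving minimum spanning networks", {
  # two haplotypes one step apart: a single direct edge
  pairset <- haplotype_set(c("u", "v"), c("ACGTACGT", "ACGTACGA"))
  net <- sp_network(pairset)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 1L)
  expect_length(net$edges$intermediates[[1]], 0)
  # the packaged wild haplotypes radiate from the ancestral haplotype
  net5 <- sp_network(hrm_wild_haplotypes())
  expect_equal(nrow(net5$edges), 4)
  expect_true(all(net5$edges$from == "A" | net5$edges$to == "A"))
  # oracle: an edge is in the MSN iff its endpoints are disconnected in
  # the strictly-shorter-edge graph
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    seqs <- replicate(n, paste(sample(c("A", "C"), 12, TRUE), collapse = ""))
    while (anyDuplicated(seqs)) {
      seqs <- replicate(n, paste(sample(c("A", "C"), 12, TRUE), collapse = ""))
    }
    hs <- haplotype_set(sprintf("h%d", 1:n), seqs)
    D <- haplotype_distances(hs)
    net <- sp_network(hs, limit = 12)
    got <- sort(paste(pmin(net$edges$from, net$edges$to),
                      pmax(net$edges$from, net$edges$to), sep = "|"))
    expect_identical(got, oracle_msn_edges(D))
  }
})

test_that("the parsimony connection limit grows with alignment length", {
  l1 <- parsimony_limit(100)
  l2 <- parsimony_limit(561)
  l3 <- parsimony_limit(2000)
  expect_true(l1 <= l2 && l2 <= l3)
  expect_gte(l2, 4)   # comfortably above the observed wild distances
})
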