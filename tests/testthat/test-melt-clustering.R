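test_that("identical noiseless curves form a single cluster", {
  feats <- feature_rows(rep(85, 16))
  cl <- cluster_curves(feats)
  expect_equal(unique(cl$cluster), 1L)
})

test_that("two melt families 0.5 degrees apart are always resolved, never merged", {
  for (seed in 1:20) {
    set.seed(seed)
    tms <- c(rnorm(8, 85.0, 0.005), rnorm(8, 85.5, 0.005))
    feats <- feature_rows(tms)
    cl <- cluster_curves(feats)
    fam <- rep(1:2, each = 8)[match(cl$well_id, feats$well_id)]
    expect_equal(length(unique(cl$cluster)), 2)
    expect_true(all(table(fam, cl$cluster) %in% c(0, 8)))
  }
})

test_that("a sub-threshold Tm offset does not split a cluster", {
  feats <- feature_rows(c(rep(85, 8), rep(85.02, 8)))
  cl <- cluster_curves(feats)
  expect_equal(unique(cl$cluster), 1L)
})

test_that("cluster partition is invariant to well input order", {
  set.seed(7)
  tms <- c(rnorm(6, 84, 0.01), rnorm(6, 84.3, 0.01), rnorm(6, 85.1, 0.01))
  feats <- feature_rows(tms)
  cl1 <- cluster_curves(feats)
  cl2 <- cluster_curves(feats[sample(nrow(feats)), ])
  expect_identical(as.data.frame(cl1[c("well_id", "cluster")]),
                   as.data.frame(cl2[c("well_id", "cluster")]))
})

test_that("raising the delta-Tm threshold never increases the cluster count", {
  for (seed in 1:5) {
    set.seed(seed)
    tms <- c(rnorm(5, 84, 0.03), rnorm(5, 84.15, 0.03), rnorm(5, 84.6, 0.03))
    feats <- feature_rows(tms)
    ks <- vapply(c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1), function(dt) {
      length(unique(cluster_curves(feats,
        clustering_config(delta_tm = dt))$cluster))
    }, numeric(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("grouped clustering is independent per population", {
  feats <- feature_rows(c(84, 84, 85, 85), ids = c("W1", "W2", "W3", "W4"))
  feats$population_id <- c("P1", "P1", "P2", "P2")
  out <- cluster_by_group(feats)
  expect_equal(unname(vapply(split(out$cluster, out$group_id),
                             function(x) length(unique(x)), numeric(1))),
               c(1, 1))
  # identical curve sets in two groups give identical partitions
  f2 <- feature_rows(rep(c(84, 85), 2), ids = sprintf("W%d", 1:4))
  f2$population_id <- rep(c("P1", "P2"), each = 2)
  o2 <- cluster_by_group(f2)
  expect_equal(o2$cluster[o2$group_id == "P1"],
               o2$cluster[o2$group_id == "P2"])
  feats$population_id[2] <- NA
  expect_error(cluster_by_group(feats), "population")
})

test_that("difference curves are zero against self and show one signed lobe for a Tm shift", {
  feats <- feature_rows(c(84, 84, 84.5), ids = c("R", "S", "T"))
  d <- difference_curves(feats, reference = "R")
  ref_curve <- d[d$well_id == "R", ]
  expect_true(all(ref_curve$delta_fluorescence == 0))
  expect_true(all(abs(d$delta_fluorescence[d$well_id == "S"]) < 1e-12))
  lobe <- d[d$well_id == "T", ]
  # single-signed lobe with its extremum between the two melt peaks
  expect_true(all(lobe$delta_fluorescence >= -1e-12))
  peak_t <- lobe$temperature[which.max(lobe$delta_fluorescence)]
  expect_gt(peak_t, 84)
  expect_lt(peak_t, 84.5)
  expect_error(difference_curves(feats, reference = "nope"), "reference")
})
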