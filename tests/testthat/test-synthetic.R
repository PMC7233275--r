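test_that("the simulator is fully reproducible under a fixed seed", {
  haps <- toy_haps(3)
  cfg <- sim_config(seed = 17, noise_sd = 2)
  s1 <- simulate_primer_test(haps, config = cfg)
  s2 <- simulate_primer_test(haps, config = cfg)
  expect_identical(s1, s2)
  t5 <- hrm_table5()
  w1 <- simulate_population_screen(t5, hrm_wild_haplotypes("ndhA"),
                                   config = cfg)
  w2 <- simulate_population_screen(t5, hrm_wild_haplotypes("ndhA"),
                                   config = cfg)
  expect_identical(w1, w2)
})

test_that("the amplicon Tm model follows its stated arithmetic", {
  seq50 <- paste(rep(c("G", "C", "A", "T"), length.out = 676)[1:675],
                 collapse = "")
  # ~50% GC at length 675: 81.5 + 0.41*50 - 1
  expect_equal(predict_tm(seq50), 81.5 + 0.41 * (100 * 338 / 675) - 1,
               tolerance = 1e-9)
  at <- paste(rep("AT", 50), collapse = "")
  gc_half <- paste(c(rep("G", 50), rep("A", 50)), collapse = "")
  expect_gt(predict_tm(gc_half), predict_tm(at))      # GC raises Tm
  expect_error(predict_tm("ACGTN"), "short|ACGT")
  expect_error(predict_tm(paste(rep("N", 60), collapse = "")), "ACGT")
})

test_that("simulated per-haplotype mean Tm converges to the model Tm", {
  cfg <- sim_config(seed = 5, tm_jitter_sd = 0.05)
  set.seed(cfg$seed)
  tm_model <- 84.2
  tms <- replicate(200, simulate_melt(tm_model, cfg)$tm)
  expect_lt(abs(mean(tms) - tm_model), 4 * 0.05 / sqrt(200))
})

test_that("transition effects exceed GC-neutral transversion effects", {
  model <- snp_class_model()
  base <- strsplit(toy_haps(1)$sequence, "")[[1]]
  mk <- function(mut_from, mut_to) {
    s <- base
    i <- which(s == mut_from)[1]
    s[i] <- mut_to
    haplotype_set(c("ref", "alt"),
                  c(paste(base, collapse = ""), paste(s, collapse = "")))
  }
  d_class1 <- abs(diff(haplotype_tm(mk("A", "G"), model)$tm))
  d_class4 <- abs(diff(haplotype_tm(mk("A", "T"), model)$tm))
  expect_gt(d_class1, d_class4)
})

test_that("a replicate design pipes through clustering and scoring to perfect recovery", {
  haps <- toy_haps(4)
  sim <- simulate_primer_test(haps, config = sim_config(seed = 23))
  feats <- normalize_plate(screen_plate(sim$wells))
  cl <- cluster_curves(feats)
  res <- evaluate_run(cl, sim$truth)
  expect_equal(nrow(res$matrix$counts), 4)
  expect_true(all(res$summary$accuracy == 100))
})

test_that("a zero-noise population screen recovers the reference table exactly", {
  t5 <- hrm_table5()
  res <- run_wild_screen(t5, config = sim_config(seed = 11, noise_sd = 0,
                                                 tm_jitter_sd = 0))
  freq <- res$frequencies
  for (h in c("A", "B", "C", "D", "E")) {
    got <- if (h %in% names(freq)) freq[[h]][match(t5$population,
                                                   freq$population_id)]
    else rep(0L, nrow(t5))
    got[is.na(got)] <- 0L
    expect_equal(got, t5[[h]], ignore_attr = TRUE)
  }
  expect_length(res$conflicts, 0)
  # per-population haplotype richness equals the table's
  rich <- table(res$calls$population_id,
                res$calls$haplotype)
  expect_equal(unname(rowSums(rich > 0)[t5$population]),
               unname(rowSums(t5[c("A", "B", "C", "D", "E")] > 0)))
})

test_that("injected duplicate splits are flagged exactly", {
  t5 <- hrm_table5()
  res <- run_wild_screen(t5, config = sim_config(seed = 41, split_rate = 0.04))
  expect_identical(sort(res$conflicts),
                   sort(res$truth$sample_id[res$truth$split]))
  expect_gt(length(res$conflicts), 0)
})
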