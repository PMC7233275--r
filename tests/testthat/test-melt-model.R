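test_that("plate write/read round trip preserves metadata and curves exactly", {
  set.seed(1)
  wells <- tibble::tibble(
    plate_id = "P1", well_id = c("A01", "A02"),
    sample_id = c("s1", "s2"), population_id = c("POP1", "POP1"),
    replicate_index = c(1L, 2L), known_haplotype = c("A", NA),
    amplification = list(raw_amp(noise = 2), raw_amp(noise = 2)),
    melt = list(raw_melt(82, noise = 1), raw_melt(83, noise = 1)))
  plate <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".tsv")
  write_plate(wells, plate, meta)
  back <- read_plate(plate, meta)
  expect_equal(nrow(back), 2)
  expect_identical(back$sample_id, wells$sample_id)
  expect_identical(back$known_haplotype, wells$known_haplotype)
  expect_identical(back$melt[[1]]$fluorescence, wells$melt[[1]]$fluorescence)
  expect_identical(back$amplification[[2]]$fluorescence,
                   wells$amplification[[2]]$fluorescence)
  expect_equal(nrow(back$melt[[1]]), 151)
  expect_equal(nrow(attr(back, "rejected")), 0)
})

test_that("invalid plate files are rejected with informative errors", {
  plate <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plate_id\twell_id\tstage\tx\tfluorescence",
               "P1\tA01\tMELT\t66\t1.0",
               "P1\tA01\tMELT\t65.8\t0.9",
               "P1\tA01\tMELT\t65.9\t0.8",
               "P1\tA01\tMELT\t66.1\t0.7",
               "P1\tA01\tMELT\t66.2\t0.6"), plate)
  writeLines(c("plate_id\twell_id\tsample_id\tpopulation_id\treplicate_index\tknown_haplotype",
               "P1\tA01\ts1\tPOP1\t1\t"), meta)
  expect_error(read_plate(plate, meta), "strictly increasing")

  meta_dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plate_id\twell_id\tsample_id\tpopulation_id\treplicate_index\tknown_haplotype",
               "P1\tA01\ts1\tPOP1\t1\t",
               "P1\tA01\ts2\tPOP1\t1\t"), meta_dup)
  expect_error(read_plate(plate, meta_dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plate_id\twell_id\tstage\tx\tfluorescence",
               "P1\tA01\tMELT\t65\toops"), bad)
  expect_error(read_plate(bad, meta), "malformed")
})

test_that("amplification screening separates real curves from failures", {
  expect_true(screen_amplification(raw_amp(amp = 1500))$pass)
  flat <- tibble::tibble(cycle = 1:40, fluorescence = rep(0, 40))
  res <- screen_amplification(flat)
  expect_false(res$pass)
  expect_match(res$reason, "no amplification")
  # low plateau relative to the plate median
  res2 <- screen_amplification(raw_amp(amp = 50), reference_plateau = 1500)
  expect_false(res2$pass)
})

test_that("a 16-replicate run with 2 designated failures passes exactly 14", {
  haps <- toy_haps(1)
  sim <- simulate_primer_test(haps, config = sim_config(seed = 3),
                              fail_wells = c("A03", "A11"))
  screened <- screen_plate(sim$wells)
  expect_equal(sum(screened$qc_pass), 14)
  expect_identical(sort(screened$well_id[!screened$qc_pass]),
                   c("A03", "A11"))
})

test_that("normalisation is an identity on already-normalised curves", {
  cur <- norm_melt(82)
  out <- normalize_melt(cur)
  expect_lt(max(abs(out$normalized$fluorescence - cur$fluorescence)), 1e-9)
  expect_equal(out$tm, 82, tolerance = 1e-6)
  # idempotence
  out2 <- normalize_melt(out$normalized)
  expect_lt(max(abs(out2$normalized$fluorescence -
                      out$normalized$fluorescence)), 1e-9)
})

test_that("Tm is recovered under drift and is affine-invariant", {
  cur <- raw_melt(82.0, drift_slope = -4)
  out <- normalize_melt(cur)
  expect_lt(abs(out$tm - 82.0), 0.1)
  # affine transform of raw fluorescence leaves tm unchanged
  aff <- cur
  aff$fluorescence <- 3.7 * aff$fluorescence + 250
  expect_equal(normalize_melt(aff)$tm, out$tm, tolerance = 1e-9)
})

test_that("smoothed-derivative Tm agrees with naive finite differences when noiseless", {
  for (tm in c(78.3, 82.0, 88.55)) {
    cur <- raw_melt(tm)
    out <- normalize_melt(cur)
    f <- out$normalized$fluorescence
    t <- out$normalized$temperature
    naive <- -(diff(f) / diff(t))
    tm_naive <- t[which.max(naive)] + 0.1      # midpoint of the step
    expect_lt(abs(out$tm - tm_naive), 0.2)
    expect_lt(abs(out$tm - tm), 0.05)
  }
})

test_that("normalisation rejects bad windows and degenerate baselines", {
  cur <- raw_melt(82)
  expect_error(normalize_melt(cur, pre_window = c(80, 94), post_window = c(83, 95)),
               "below")
  # inverted curve: 'upper' baseline below 'lower'
  inv <- cur
  inv$fluorescence <- -inv$fluorescence
  expect_error(normalize_melt(inv), "degenerate")
})
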