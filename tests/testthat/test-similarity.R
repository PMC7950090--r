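test_that("the unmodified index applies the threshold and the random cap", {
  cfg <- shift_config(unmodified_cap = 50L)
  psms <- rbind(
    make_psms(rep(0.0005, 60), peptide = "PEPTIDEK"),
    make_psms(0.002, peptide = "GTHERPEK"),
    make_psms(-0.0009, peptide = "ACDK"))
  idx <- build_unmodified_index(psms, cfg)
  expect_equal(nrow(idx[["e1|PEPTIDEK|2"]]), 50L)   # 60 capped to 50
  expect_equal(nrow(idx[["e1|ACDK|2"]]), 1L)        # below threshold indexed
  expect_null(idx[["e1|GTHERPEK|2"]])               # 0.002 not indexed
  # reproducible under the seed
  idx2 <- build_unmodified_index(psms, cfg)
  expect_identical(idx[["e1|PEPTIDEK|2"]], idx2[["e1|PEPTIDEK|2"]])
})

test_that("grid cosine matches hand arithmetic and its invariances", {
  a <- list(mz = c(100, 200), intensity = c(3, 4))
  b <- list(mz = c(100, 200), intensity = c(4, 3))
  expect_equal(spectrum_cosine(a, b), 24 / 25)
  expect_equal(spectrum_cosine(a, a), 1.0)
  d <- list(mz = c(300, 400), intensity = c(1, 1))
  expect_equal(spectrum_cosine(a, d), 0.0)
  expect_equal(spectrum_cosine(a, list(mz = numeric(), intensity = numeric())), 0)
  # scale invariance
  b10 <- list(mz = b$mz, intensity = b$intensity * 10)
  expect_equal(spectrum_cosine(a, b10), spectrum_cosine(a, b), tolerance = 1e-12)
  # bounds on random nonnegative spectra
  set.seed(13)
  for (i in 1:25) {
    x <- list(mz = sort(runif(8, 100, 900)), intensity = rexp(8))
    y <- list(mz = sort(runif(8, 100, 900)), intensity = rexp(8))
    s <- spectrum_cosine(x, y)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("delta RT is the modified RT minus the counterpart mean", {
  cfg <- shift_config()
  psms <- rbind(make_psms(15.9949, rt = 500, spectrum_id = "m.1"),
                make_psms(c(0, 0), rt = c(480, 520), spectrum_id = c("u.1", "u.2")))
  idx <- build_unmodified_index(psms, cfg)
  cmp <- compare_modified_psm(psms[1, ], idx, list(), cfg)
  expect_equal(cmp$delta_rt, 0)
  expect_equal(cmp$n_counterparts, 2L)
  # no counterpart for a different charge
  psm3 <- make_psms(15.9949, rt = 500, charge = 3L, spectrum_id = "m.2")
  expect_null(compare_modified_psm(psm3[1, ], idx, list(), cfg))
})

test_that("comparisons never cross charge states on mixed-charge fixtures", {
  cfg <- shift_config()
  psms <- rbind(make_psms(c(0, 0), rt = c(100, 900), charge = 2L,
                          spectrum_id = c("a.1", "a.2")),
                make_psms(0, rt = 500, charge = 3L, spectrum_id = "a.3"),
                make_psms(15.9949, rt = 520, charge = 3L, spectrum_id = "a.4"))
  idx <- build_unmodified_index(psms, cfg)
  cmp <- compare_modified_psm(psms[4, ], idx, list(), cfg)
  # only the charge-3 unmodified PSM (RT 500) is eligible
  expect_equal(cmp$n_counterparts, 1L)
  expect_equal(cmp$delta_rt, 20)
})

test_that("the zero-shift bin has zero mean delta RT against itself", {
  cfg <- shift_config(jitter_half_width = 0)
  set.seed(31)
  psms <- make_psms(spread(20, 4e-4), rt = runif(20, 100, 3000),
                    spectrum_id = sprintf("z.%d", 1:20))
  es <- assemble_experiment_set(list(psms))
  ps <- assign_psms_to_peaks(pick_peaks(smooth_histogram(
    build_histogram(es, cfg)), cfg), es)
  idx <- build_unmodified_index(es, cfg)
  cmp <- compare_peakset(ps, idx, list(), cfg)
  expect_equal(mean(cmp$delta_rt), 0, tolerance = 1e-9)
})

test_that("in-source and pre-elution populations separate in per-PSM delta RT", {
  sh <- data.frame(
    mass = c(-18.010565, -18.010565),
    name = c("water_insource", "water_preelution"),
    residue = c("E", "E"), frequency = c(0.2, 0.2),
    rt_offset = c(0, 450), site_fidelity = c(0.9, 0.9))
  fx <- generate_dataset(fixture_spec(n_experiments = 1, n_psms = 400,
                                      n_peptides = 40, shifts = sh,
                                      rng_seed = 17))
  es <- assemble_experiment_set(fx$psm_tables, fx$spectra)
  cfg <- shift_config(top_n_peaks = 10)
  ps <- assign_psms_to_peaks(pick_peaks(smooth_histogram(
    build_histogram(es, cfg)), cfg), es)
  idx <- build_unmodified_index(es, cfg)
  cmp <- compare_peakset(ps, idx, es$spectra, cfg)
  truth <- fx$manifest$rt_offset[cmp$psm_row]
  shifted <- !is.na(ps$psms$peak[cmp$psm_row]) &
    abs(ps$psms$delta_mass[cmp$psm_row] + 18.01) < 0.05
  d0 <- cmp$delta_rt[shifted & truth == 0]
  d450 <- cmp$delta_rt[shifted & truth == 450]
  expect_gt(length(d0), 10)
  expect_gt(length(d450), 10)
  expect_lt(abs(mean(d0)), 30)
  expect_gt(mean(d450), 400)
  expect_lt(abs(mean(d0)) + abs(mean(d450) - 450), 100)
})

test_that("comparison profiles aggregate fractions and means per peak", {
  cfg <- shift_config(jitter_half_width = 0)
  # 10 modified PSMs on one peptide; only 7 have unmodified counterparts
  withcp <- make_psms(15.9949 + spread(7), peptide = "ACDEFGHK", rt = 700,
                      spectrum_id = sprintf("m.%d", 1:7))
  nocp <- make_psms(15.9949 + spread(3, 4e-4), peptide = "WYNQRAK", rt = 700,
                    spectrum_id = sprintf("n.%d", 1:3))
  unmod <- make_psms(spread(4, 4e-4), peptide = "ACDEFGHK", rt = 650,
                     spectrum_id = sprintf("u.%d", 1:4))
  es <- assemble_experiment_set(list(rbind(withcp, nocp, unmod)))
  ps <- assign_psms_to_peaks(pick_peaks(smooth_histogram(
    build_histogram(es, cfg)), cfg), es)
  idx <- build_unmodified_index(es, cfg)
  cmp <- compare_peakset(ps, idx, list(), cfg)
  prof <- aggregate_comparison_profile(cmp, ps)
  ox <- which.min(abs(ps$peaks$reported_mass - 15.9949))
  row <- prof[prof$peak == ox, ]
  expect_equal(row$n_assigned, 10)
  expect_equal(row$n_compared, 7)
  expect_equal(row$fraction_with_counterpart, 0.7)
  expect_equal(row$mean_delta_rt, 50)
})
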