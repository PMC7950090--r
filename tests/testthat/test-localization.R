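test_that("theoretical b/y fragments match hand-computed monoisotopic values", {
  fr <- theoretical_fragments("GG")
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$mz[fr$ion == "b"], 58.0287, tolerance = 1e-4)
  expect_equal(fr$mz[fr$ion == "y"], 76.0393, tolerance = 1e-4)
  # L residues -> 2(L-1) singly charged ions
  for (pep in c("PEPTIDEK", "ACDK", "MK"))
    expect_equal(nrow(theoretical_fragments(pep)), 2L * (nchar(pep) - 1L))
  expect_error(theoretical_fragments("PEPZ"), "invalid peptide")
})

test_that("a shift at position k moves b ions at >= k and y ions covering k", {
  pep <- "ACDEFK"
  L <- nchar(pep)
  base <- theoretical_fragments(pep)
  s1 <- theoretical_fragments(pep, shift_mass = 10, shift_pos = 1)
  expect_equal(s1$mz[s1$ion == "b"], base$mz[base$ion == "b"] + 10)
  dy <- s1$mz[s1$ion == "y"] - base$mz[base$ion == "y"]
  expect_equal(dy, rep(0, L - 1))  # no generated y ion covers position 1
  s4 <- theoretical_fragments(pep, shift_mass = 10, shift_pos = 4)
  db <- s4$mz[s4$ion == "b"] - base$mz[base$ion == "b"]
  expect_equal(db, c(0, 0, 0, 10, 10))
  dy4 <- s4$mz[s4$ion == "y"] - base$mz[base$ion == "y"]
  expect_equal(dy4, c(0, 0, 10, 10, 10))  # y_j shifted for j >= L - k + 1 = 3
  # applied search modifications shift fragments the same way
  m <- theoretical_fragments(pep, data.frame(pos = 2, mass = 57.0215))
  expect_equal(m$mz[m$ion == "b"] - base$mz[base$ion == "b"],
               c(0, rep(57.0215, 4)))
})

test_that("hyperscore reproduces its closed form and degenerate cases", {
  cfg <- shift_config(fragment_tol = 0.01, fragment_tol_unit = "da")
  empty <- hyperscore(list(mz = numeric(), intensity = numeric()),
                      theoretical_fragments("PEPK"), cfg)
  expect_equal(empty$score, 0)
  expect_equal(empty$n_matched, 0L)
  # 2 b and 2 y matches with summed intensities 10 each -> log10(2!2!*10*10)
  fr <- data.frame(ion = c("b", "b", "y", "y"), index = c(1, 2, 1, 2),
                   mz = c(100, 200, 300, 400))
  sp <- list(mz = c(100, 200, 300, 400), intensity = c(4, 6, 3, 7))
  sc <- hyperscore(sp, fr, cfg)
  expect_equal(sc$Nb, 2L)
  expect_equal(sc$Ny, 2L)
  expect_equal(sc$score, log10(2 * 2 * 10 * 10), tolerance = 1e-12)
  # no fragment within tolerance -> zero counts, zero score
  none <- hyperscore(list(mz = 150, intensity = 5), fr, cfg)
  expect_equal(none$score, 0)
})

test_that("hyperscore equals the exhaustive matcher on random small spectra", {
  set.seed(301)
  cfg <- shift_config(fragment_tol = 0.02, fragment_tol_unit = "da")
  peps <- c("ACDK", "PEPTIDEK", "GASPVK", "WYNQR")
  for (rep in 1:100) {
    pep <- sample(peps, 1)
    fr <- theoretical_fragments(pep)
    npk <- sample(1:20, 1)
    # mix of near-fragment peaks (some within tolerance) and random ones
    mz <- c(fr$mz[sample(nrow(fr), min(npk, nrow(fr)))] +
              runif(min(npk, nrow(fr)), -0.03, 0.03),
            runif(max(0, npk - nrow(fr)), 100, 900))
    o <- order(mz)
    sp <- list(mz = mz[o], intensity = rexp(length(mz))[o])
    got <- hyperscore(sp, fr, cfg)$score
    want <- oracle_hyperscore(sp, fr, rep(0.02, nrow(fr)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("localization recovers the implanted site and distributes ties", {
  cfg <- shift_config()
  pep <- "ACDEFGHK"
  psm <- make_psms(79.9663, peptide = pep)
  sp <- generate_peptide_spectrum(pep, 79.9663, 4, noise_peaks = 0)
  loc <- localize_psm(psm[1, ], sp, 79.9663, cfg)
  expect_true(loc$localizable)
  expect_equal(loc$site_weights[4], 1)
  expect_equal(sum(loc$site_weights), 1)
  expect_false(loc$nterm_flag)
  # spectrum without any shifted ions: not localizable, weights all zero
  sp0 <- generate_peptide_spectrum(pep, 0, NA, noise_peaks = 0)
  loc0 <- localize_psm(psm[1, ], sp0, 79.9663, cfg)
  expect_false(loc0$localizable)
  expect_equal(sum(loc0$site_weights), 0)
})

test_that("indistinguishable adjacent placements share weight equally", {
  cfg <- shift_config()
  # a shift on either of two adjacent identical residues gives tied scores
  pep <- "GAASSAAK"
  psm <- make_psms(79.9663, peptide = pep)
  sp <- generate_peptide_spectrum(pep, 79.9663, 4, noise_peaks = 0)
  # remove the single fragment pair (b4/y4) that separates S4 from S5
  keep <- !sapply(seq_along(sp$mz), function(i) {
    fr <- theoretical_fragments(pep, shift_mass = 79.9663, shift_pos = 4)
    any(abs(fr$mz[fr$index == 4] - sp$mz[i]) < 1e-6)
  })
  sp2 <- list(mz = sp$mz[keep], intensity = sp$intensity[keep])
  loc <- localize_psm(psm[1, ], sp2, 79.9663, cfg)
  expect_true(loc$localizable)
  expect_equal(loc$site_weights[4], loc$site_weights[5])
  expect_equal(sum(loc$site_weights), 1)
})

test_that("site-weight conservation holds across a fixture peak set", {
  fx <- generate_dataset(fixture_spec(n_experiments = 1, n_psms = 120,
                                      shifts = fixture_shifts()[c(1, 6), ],
                                      rng_seed = 5))
  es <- assemble_experiment_set(fx$psm_tables, fx$spectra)
  cfg <- shift_config(top_n_peaks = 10)
  ps <- assign_psms_to_peaks(pick_peaks(smooth_histogram(
    build_histogram(es, cfg)), cfg), es)
  loc <- localize_peakset(ps, es$spectra, cfg)
  sums <- vapply(loc$site_weights, sum, numeric(1))
  expect_true(all(abs(sums - 0) < 1e-12 | abs(sums - 1) < 1e-12))
  expect_true(all(abs(sums[loc$localizable] - 1) < 1e-12))
})

test_that("enrichment follows its definition and the identity sums to one", {
  # counts {S: 30 of 60}, background fraction S = 0.25 -> enrichment 2.0
  loc <- data.frame(psm_row = 1:2, peak = 1L, experiment = "e1",
                    peptide = c("SSSK", "AAAK"), localizable = TRUE,
                    nterm = FALSE, stringsAsFactors = FALSE)
  loc$site_weights <- list(c(1, 1, 1, 0) / 3, c(1, 1, 1, 0) / 3)
  # dataset background: SSSK + AAAK = {S:3, A:3, K:2}; S fraction 0.375
  prof <- aggregate_localization_profile(loc, "dataset_psm")
  enr <- prof$enrichment[[1]]
  expect_equal(unname(enr["S"]), (0.5) / (3 / 8))
  bg <- prof$background_counts[[1]]
  ok <- bg > 0
  expect_equal(sum((bg[ok] / sum(bg)) * enr[ok]), 1, tolerance = 1e-12)
})

test_that("the enrichment identity holds for every peak and scope on fixtures", {
  fx <- generate_dataset(fixture_spec(n_experiments = 2, n_psms = 150,
                                      shifts = fixture_shifts()[c(2, 6), ],
                                      rng_seed = 9))
  es <- assemble_experiment_set(fx$psm_tables, fx$spectra)
  cfg <- shift_config(top_n_peaks = 10)
  ps <- assign_psms_to_peaks(pick_peaks(smooth_histogram(
    build_histogram(es, cfg)), cfg), es)
  loc <- localize_peakset(ps, es$spectra, cfg)
  for (scope in c("dataset_psm", "dataset_peptide", "bin_psm", "bin_peptide")) {
    prof <- aggregate_localization_profile(loc, scope)
    for (r in seq_len(nrow(prof))) {
      rc <- prof$residue_counts[[r]]
      if (sum(rc) == 0) next
      bg <- prof$background_counts[[r]]
      enr <- prof$enrichment[[r]]
      ok <- bg > 0
      expect_equal(sum((bg[ok] / sum(bg)) * enr[ok]), 1, tolerance = 1e-9)
    }
  }
})

test_that("a Ser-implanted phosphorylation ranks Ser top in enrichment", {
  fx <- generate_dataset(fixture_spec(n_experiments = 1, n_psms = 150,
                                      shifts = fixture_shifts()[6, ],
                                      rng_seed = 21))
  es <- assemble_experiment_set(fx$psm_tables, fx$spectra)
  cfg <- shift_config(top_n_peaks = 5)
  ps <- assign_psms_to_peaks(pick_peaks(smooth_histogram(
    build_histogram(es, cfg)), cfg), es)
  loc <- localize_peakset(ps, es$spectra, cfg)
  prof <- aggregate_localization_profile(loc, "dataset_psm")
  phospho_peak <- which.min(abs(ps$peaks$reported_mass - 79.9663))
  row <- prof[prof$peak == phospho_peak, ]
  expect_equal(row$top_residue, "S")
  expect_gt(row$top_enrichment, 1)
})
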