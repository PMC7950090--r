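test_that("flattening replaces bin groups by their minimum", {
  expect_equal(flatten_for_prominence(c(5, 4, 6, 2, 9, 1), 2),
               c(4, 4, 2, 2, 1, 1))
  w <- c(3, 1, 4, 1, 5)
  expect_identical(flatten_for_prominence(w, 1), w)
  # partial trailing group flattened to its own minimum
  expect_equal(flatten_for_prominence(c(5, 4, 6, 2, 9), 2),
               c(4, 4, 2, 2, 9))
  set.seed(11)
  for (i in 1:20) {
    w <- runif(sample(3:30, 1))
    s <- sample(1:5, 1)
    expect_true(all(flatten_for_prominence(w, s) <= w))
  }
})

test_that("prominence follows the monotone-descent shoulder rule", {
  expect_equal(compute_prominence(c(0, 1, 3, 1, 0), 3), 1.0)
  expect_equal(compute_prominence(c(2, 3, 2.5), 2), (3 - 2.5) / 3)
  expect_lt(compute_prominence(c(2, 3, 2.5), 2), 0.3)  # not callable
  expect_true(is.na(compute_prominence(c(0, 0, 0), 2)))
})

test_that("SNR is the signal mean minus the flank mean", {
  w <- c(rep(1, 25), rep(5, 20), rep(1, 25))
  # signal window of 20 bins centred in the plateau, flanks of 25 bins
  expect_equal(compute_snr(w, 36L, 0.004, 0.005, 0.0002), 4)
  expect_equal(compute_snr(rep(3, 100), 50L, 0.004, 0.005, 0.0002), 0)
  expect_error(compute_snr(w, 35L, 0.004, 0.00001, 0.0002), "flank")
})

test_that("monotone weight vectors yield no peaks", {
  h <- make_hist(seq(1, 0.1, length.out = 60))
  expect_warning(ps <- pick_peaks(h, unit_config()), "no peaks")
  expect_equal(nrow(ps$peaks), 0L)
})

test_that("pick_peaks equals the brute-force enumeration oracle", {
  set.seed(202)
  cfg_base <- unit_config()
  for (rep in 1:200) {
    n <- sample(20:200, 1)
    w <- rexp(n, 1)
    # sprinkle spikes and plateaus so local maxima are non-trivial
    spikes <- sample(n, max(1, n %/% 15))
    w[spikes] <- w[spikes] + rexp(length(spikes), 1 / 5)
    if (rep %% 4 == 0) w <- round(w, 1)  # force ties/plateaus
    cfg <- if (rep %% 5 == 0)
      shift_config(flatten_width = 0.0006, prominence_threshold = 0.4,
                      top_n_peaks = 5) else cfg_base
    h <- make_hist(w)
    got <- suppressWarnings(pick_peaks(h, cfg))$peaks
    want <- oracle_pick_peaks(h, cfg)
    expect_equal(got$apex_index, want$apex_index)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
    expect_equal(got$snr, want$snr, tolerance = 1e-12)
  }
})

test_that("raising the prominence threshold only removes peaks", {
  set.seed(203)
  w <- rexp(150)
  w[c(30, 70, 110)] <- w[c(30, 70, 110)] + c(4, 8, 2)
  lows <- suppressWarnings(
    pick_peaks(make_hist(w), unit_config(prominence_threshold = 0.2))$peaks)
  highs <- suppressWarnings(
    pick_peaks(make_hist(w), unit_config(prominence_threshold = 0.6))$peaks)
  expect_true(all(highs$apex_index %in% lows$apex_index))
})

test_that("implanted histogram peaks are recovered within one bin", {
  set.seed(204)
  n <- 5000L
  truth <- sort(sample(seq(100, n - 100, by = 80), 10))
  w <- rep(0.3, n)  # flat background
  for (t in truth) {
    span <- (t - 10):(t + 10)
    w[span] <- w[span] + 30 * dnorm(span - t, sd = 3)
  }
  ps <- pick_peaks(make_hist(w), shift_config())
  expect_equal(nrow(ps$peaks), 10L)
  found <- vapply(truth, function(t) min(abs(ps$peaks$apex_index - t)),
                  numeric(1))
  expect_true(all(found <= 1))
})

test_that("doubling every PSM changes no peak calls and doubles SNR", {
  cfg <- shift_config(jitter_half_width = 0)
  m <- rep(c(0, 15.9949, 79.9663), times = c(50, 30, 20)) +
    c(spread(50), spread(30), spread(20))
  h1 <- smooth_histogram(build_histogram(make_psms(m), cfg))
  h2 <- smooth_histogram(build_histogram(make_psms(c(m, m)), cfg))
  p1 <- pick_peaks(h1, cfg)$peaks
  p2 <- pick_peaks(h2, cfg)$peaks
  expect_equal(p2$apex_mass, p1$apex_mass)
  expect_equal(p2$prominence, p1$prominence, tolerance = 1e-12)
  expect_equal(p2$snr, 2 * p1$snr, tolerance = 1e-12)
})

test_that("PSMs are assigned to the covering peak with the nearer apex", {
  cfg <- shift_config(jitter_half_width = 0)
  psms <- make_psms(c(15.9952, 14.5, 0.0001, 15.9949, 0.0))
  ps <- structure(list(
    peaks = data.frame(apex_index = c(1L, 2L),
                       apex_mass = c(0.0, 15.9949),
                       apex_height = c(5, 3), prominence = c(1, 1),
                       snr = c(5, 3),
                       left_bound = c(-0.002, 15.9929),
                       right_bound = c(0.002, 15.9969),
                       reported_mass = c(0.0, 15.9949)),
    lo = -5, bin_width = 2e-4, config = cfg), class = "peak_set")
  ps <- assign_psms_to_peaks(ps, psms)
  expect_equal(ps$psms$peak, c(2L, NA, 1L, 2L, 1L))
  expect_lte(sum(!is.na(ps$psms$peak)), nrow(psms))
  # overlapping boundaries: the peak with the nearer apex wins
  ps$peaks$right_bound[1] <- 8.0
  ps$peaks$left_bound[2] <- 7.9
  psms2 <- make_psms(c(7.95, 8.2, 0.0001))
  ps2 <- assign_psms_to_peaks(ps, psms2)
  expect_equal(ps2$psms$peak, c(1L, 2L, 1L))  # 7.95 nearer apex 0 than 15.99
})

test_that("quantification normalizes counts to experiment size", {
  cfg <- shift_config(jitter_half_width = 0)
  a <- make_psms(c(spread(180), 15.9949 + spread(20)), experiment = "A")
  b <- make_psms(c(spread(380), 15.9949 + spread(20)), experiment = "B")
  es <- assemble_experiment_set(list(a, b))
  ps <- assign_psms_to_peaks(pick_peaks(smooth_histogram(
    build_histogram(es, cfg)), cfg), es)
  q <- quantify_peaks(ps)
  ox <- which.min(abs(ps$peaks$reported_mass - 15.9949))
  expect_equal(q$norm_count[q$peak == ox & q$experiment == "A"], 0.10)
  expect_equal(q$count[q$peak == ox & q$experiment == "B"], 20L)
  expect_equal(q$norm_count[q$peak == ox & q$experiment == "B"], 20 / 400)
  for (e in c("A", "B"))
    expect_lte(sum(q$norm_count[q$experiment == e]), 1)
})
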