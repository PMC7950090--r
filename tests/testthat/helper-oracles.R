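# Independent brute-force oracles and small fixture builders shared by the
# suite. The oracles implement the stated rules in the most direct scalar way
# and share no code with the package internals they check.

# --- peak-picking oracle -----------------------------------------------------

# Group flattening, scalar version.
oracle_flatten <- function(w, set_size) {
  out <- numeric(length(w))
  i <- 1L
  while (i <= length(w)) {
    j <- min(i + set_size - 1L, length(w))
    out[i:j] <- min(w[i:j])
    i <- j + 1L
  }
  out
}

# Per-bin local-maximality on a flattened vector: the bin's plateau must sit
# strictly above the adjacent values on both sides (vector ends fail), and the
# bin must be the first argmax of the raw weights within its plateau.
oracle_is_apex <- function(flat, raw, i) {
  n <- length(flat)
  l <- i
  while (l > 1 && flat[l - 1] == flat[i]) l <- l - 1
  r <- i
  while (r < n && flat[r + 1] == flat[i]) r <- r + 1
  if (l == 1 || r == n) return(FALSE)
  if (flat[l - 1] >= flat[i] || flat[r + 1] >= flat[i]) return(FALSE)
  plateau <- l:r
  i == plateau[which.max(raw[plateau])]
}

oracle_prominence <- function(flat, i) {
  n <- length(flat)
  l <- i
  while (l > 1 && flat[l - 1] <= flat[l]) l <- l - 1
  r <- i
  while (r < n && flat[r + 1] <= flat[r]) r <- r + 1
  (flat[i] - max(flat[l], flat[r])) / flat[i]
}

oracle_snr <- function(w, i, signal_window, background_flank, bw) {
  ns <- max(1L, as.integer(round(signal_window / bw)))
  nb <- as.integer(round(background_flank / bw))
  lo <- i - ns %/% 2L
  hi <- lo + ns - 1L
  sig <- w[max(1L, lo):min(length(w), hi)]
  bg <- c()
  for (j in c((lo - nb):(lo - 1L), (hi + 1L):(hi + nb)))
    if (j >= 1L && j <= length(w)) bg <- c(bg, w[j])
  mean(sig) - if (length(bg)) mean(bg) else 0
}

# Full enumeration oracle: every bin tested directly; returns a data.frame in
# the same order as pick_peaks (snr desc, apex index asc).
oracle_pick_peaks <- function(hist, config) {
  w <- hist$weights
  set_size <- max(1L, as.integer(round(config$flatten_width / hist$bin_width)))
  flat <- oracle_flatten(w, set_size)
  rows <- list()
  for (i in seq_along(w)) {
    if (flat[i] <= 0 || !oracle_is_apex(flat, w, i)) next
    prom <- oracle_prominence(flat, i)
    if (prom <= config$prominence_threshold) next
    rows[[length(rows) + 1L]] <- data.frame(
      apex_index = i, prominence = prom,
      snr = oracle_snr(w, i, config$snr_signal_window,
                       config$snr_background_flank, hist$bin_width))
  }
  if (!length(rows))
    return(data.frame(apex_index = integer(), prominence = numeric(),
                      snr = numeric()))
  df <- do.call(rbind, rows)
  df <- df[order(-df$snr, df$apex_index), , drop = FALSE]
  head(df, config$top_n_peaks)
}

# --- hyperscore matching oracle ----------------------------------------------

# Greedy nearest-peak matcher, direct scan over all peaks per fragment.
oracle_hyperscore <- function(spectrum, fragments, tol_da) {
  used <- rep(FALSE, length(spectrum$mz))
  Nb <- 0L; Ny <- 0L; sIb <- 0; sIy <- 0
  for (f in seq_len(nrow(fragments))) {
    d <- abs(spectrum$mz - fragments$mz[f])
    d[used | d > tol_da[f]] <- NA
    if (all(is.na(d))) next
    i <- which.min(d)
    used[i] <- TRUE
    if (fragments$ion[f] == "b") { Nb <- Nb + 1L; sIb <- sIb + spectrum$intensity[i] }
    else { Ny <- Ny + 1L; sIy <- sIy + spectrum$intensity[i] }
  }
  (lfactorial(Nb) + lfactorial(Ny)) / log(10) +
    log10(max(sIb, 1)) + log10(max(sIy, 1))
}

# --- fixture builders --------------------------------------------------------

# Minimal PSM data.frame for unit tests.
make_psms <- function(delta, experiment = "e1", peptide = "PEPTIDEK",
                      rt = 1000, charge = 2L, spectrum_id = NULL) {
  n <- length(delta)
  data.frame(
    spectrum_id = if (is.null(spectrum_id)) sprintf("%s.%d", experiment, seq_len(n))
                  else spectrum_id,
    experiment = rep_len(experiment, n),
    peptide = rep_len(peptide, n),
    delta_mass = delta,
    retention_time = rep_len(rt, n),
    charge = rep_len(as.integer(charge), n),
    proteins = rep_len("P1", n), mods = rep_len("", n),
    stringsAsFactors = FALSE)
}

# Histogram built directly from a weight vector (bypasses binning) so peak
# tests can control bin weights exactly.
make_hist <- function(weights, lo = 0, bin_width = 0.0002) {
  structure(list(lo = lo, bin_width = bin_width,
                 weights = as.numeric(weights),
                 total_weight = sum(weights)),
            class = "mass_shift_histogram")
}

# Config with a tiny flatten width so unit-scale weight vectors are not
# flattened unless a test asks for it.
unit_config <- function(...) {
  shift_config(flatten_width = 0.0002, ...)
}

# Deterministic sub-millidalton spread: delta-mass populations in tests need
# a realistic within-peak width, since block flattening (5 bins at defaults)
# suppresses structures narrower than the flatten set.
spread <- function(n, half = 8e-4) {
  if (n == 1) return(0)
  seq(-half, half, length.out = n)
}
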