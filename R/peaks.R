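# Peak calling on the smoothed delta-mass histogram: prominence-based
# detection, SNR ranking, boundary fixing, PSM assignment, quantification.

#' Flatten adjacent bins to their group minimum
#'
#' Consecutive, non-overlapping groups of \code{set_size} bins are each
#' replaced by the group's minimum height (the last, possibly partial, group
#' by its own minimum). Used only inside the prominence computation to make
#' peaks monotone.
#'
#' @param weights Numeric bin vector.
#' @param set_size Bins per group (>= 1); 1 is the identity.
#' @return Numeric vector, same length, elementwise <= \code{weights}.
#' @export
flatten_for_prominence <- function(weights, set_size) {
  stopifnot(set_size >= 1)
  set_size <- as.integer(set_size)
  if (set_size == 1L || length(weights) == 0) return(weights)
  grp <- (seq_along(weights) - 1L) %/% set_size
  mins <- vapply(split(weights, grp), min, numeric(1))
  as.numeric(mins[as.character(grp)])
}

# Walk outward from the apex while heights are non-increasing; returns the
# index where the descent stops (next bin would rise, or the vector end).
.descend <- function(w, apex, dir) {
  i <- apex
  n <- length(w)
  while ((i + dir) >= 1 && (i + dir) <= n && w[i + dir] <= w[i]) i <- i + dir
  i
}

#' Normalized prominence of a histogram peak
#'
#' Walks left and right from the apex while heights are non-increasing; each
#' shoulder is the height where the descent stops (the height at the vector
#' end if the walk reaches it). Prominence is
#' \code{(apex - max(shoulders)) / apex}, in [0, 1].
#'
#' @param weights Numeric bin vector (normally the flattened vector).
#' @param apex_index Index of a local maximum.
#' @return Prominence ratio; \code{NA} if the apex height is 0.
#' @export
compute_prominence <- function(weights, apex_index) {
  apex <- weights[apex_index]
  if (apex <= 0) return(NA_real_)
  sl <- weights[.descend(weights, apex_index, -1L)]
  sr <- weights[.descend(weights, apex_index, +1L)]
  (apex - max(sl, sr)) / apex
}

#' Signal-to-noise remainder of a histogram peak
#'
#' Mean bin height within a signal window centred on the apex minus the mean
#' height of the two background flanks adjacent to the window, flanks
#' truncated at the histogram ends.
#'
#' @param weights Numeric bin vector.
#' @param apex_index Apex bin index.
#' @param signal_window Signal window width (Da).
#' @param background_flank Width of each background flank (Da).
#' @param bin_width Histogram bin width (Da).
#' @return SNR in weight units.
#' @export
compute_snr <- function(weights, apex_index, signal_window, background_flank,
                        bin_width) {
  n <- length(weights)
  ns <- max(1L, as.integer(round(signal_window / bin_width)))
  nb <- as.integer(round(background_flank / bin_width))
  if (nb < 1L)
    stop("background flank narrower than one histogram bin", call. = FALSE)
  s_lo <- apex_index - ns %/% 2L
  s_hi <- s_lo + ns - 1L
  sig <- weights[max(1L, s_lo):min(n, s_hi)]
  bg_idx <- c(seq(s_lo - nb, s_lo - 1L), seq(s_hi + 1L, s_hi + nb))
  bg_idx <- bg_idx[bg_idx >= 1L & bg_idx <= n]
  bg <- if (length(bg_idx)) mean(weights[bg_idx]) else 0
  mean(sig) - bg
}

#' Call mass-shift peaks from a smoothed histogram
#'
#' Local maxima of the flattened bin vector (plateau runs strictly above both
#' neighbouring runs) whose normalized prominence exceeds the threshold are
#' candidate peaks; candidates are ranked by SNR and the top
#' \code{top_n_peaks} retained. Boundaries are the bin edges where the
#' monotonic descent from the apex ends, clipped to apex +/-
#' \code{precursor_tol}, whichever is closer.
#'
#' @param hist A smoothed \code{mass_shift_histogram}.
#' @param config A \code{\link{shift_config}}.
#' @return Object of class \code{"peak_set"}: list with \code{peaks} (a
#'   data.frame ordered by descending SNR: \code{apex_index},
#'   \code{apex_mass}, \code{apex_height}, \code{prominence}, \code{snr},
#'   \code{left_bound}, \code{right_bound}, \code{reported_mass}) plus the
#'   histogram geometry and a config snapshot.
#' @export
pick_peaks <- function(hist, config = shift_config()) {
  w <- hist$weights
  n <- length(w)
  if (n == 0) stop("empty histogram", call. = FALSE)
  set_size <- max(1L, as.integer(round(config$flatten_width / hist$bin_width)))
  flat <- flatten_for_prominence(w, set_size)

  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  is_max <- rep(FALSE, nr)
  if (nr >= 3)
    is_max[2:(nr - 1)] <- r$values[2:(nr - 1)] > r$values[1:(nr - 2)] &
                          r$values[2:(nr - 1)] > r$values[3:nr]
  cand <- which(is_max & r$values > 0)

  rows <- lapply(cand, function(ri) {
    span <- starts[ri]:ends[ri]
    apex <- span[which.max(w[span])]
    prom <- compute_prominence(flat, apex)
    if (is.na(prom) || prom <= config$prominence_threshold) return(NULL)
    snr <- compute_snr(w, apex, config$snr_signal_window,
                       config$snr_background_flank, hist$bin_width)
    li <- .descend(flat, apex, -1L)
    riix <- .descend(flat, apex, +1L)
    apex_mass <- bin_center(hist, apex)
    lb <- max(hist$lo + (li - 1L) * hist$bin_width, apex_mass - config$precursor_tol)
    rb <- min(hist$lo + riix * hist$bin_width, apex_mass + config$precursor_tol)
    data.frame(apex_index = apex, apex_mass = apex_mass, apex_height = w[apex],
               prominence = prom, snr = snr, left_bound = lb, right_bound = rb)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    warning("no peaks called from histogram", call. = FALSE)
    peaks <- data.frame(apex_index = integer(), apex_mass = numeric(),
                        apex_height = numeric(), prominence = numeric(),
                        snr = numeric(), left_bound = numeric(),
                        right_bound = numeric())
  } else {
    peaks <- do.call(rbind, rows)
    peaks <- peaks[order(-peaks$snr, peaks$apex_index), , drop = FALSE]
    peaks <- utils::head(peaks, config$top_n_peaks)
    rownames(peaks) <- NULL
  }
  peaks$reported_mass <- peaks$apex_mass
  structure(list(peaks = peaks, lo = hist$lo, bin_width = hist$bin_width,
                 config = config), class = "peak_set")
}

#' Assign PSMs to called peaks
#'
#' Each PSM is assigned to the peak whose boundary interval contains its
#' (raw, unjittered) delta mass; where retained peak boundaries overlap, the
#' peak with the nearer apex wins. Adds an integer column \code{peak} (row
#' index into \code{peakset$peaks}, \code{NA} when uncovered) and sets each
#' peak's \code{reported_mass} to the mean raw delta mass of its PSMs.
#'
#' @param peakset A \code{peak_set}.
#' @param psms PSM data.frame or \code{experiment_set}.
#' @return The \code{peak_set} with \code{$psms} attached (the input PSM
#'   data.frame plus the \code{peak} column) and per-peak counts.
#' @export
assign_psms_to_peaks <- function(peakset, psms) {
  if (inherits(psms, "experiment_set")) {
    exps <- psms$experiments
    psms <- psms$psms
  } else exps <- unique(psms$experiment)
  pk <- peakset$peaks
  dm <- psms$delta_mass
  best <- rep(NA_integer_, length(dm))
  best_d <- rep(Inf, length(dm))
  for (i in seq_len(nrow(pk))) {
    inside <- dm >= pk$left_bound[i] & dm <= pk$right_bound[i]
    d <- abs(dm - pk$apex_mass[i])
    take <- inside & d < best_d
    best[take] <- i
    best_d[take] <- d[take]
  }
  psms$peak <- best
  if (nrow(pk)) {
    means <- tapply(dm[!is.na(best)], best[!is.na(best)], mean)
    pk$reported_mass <- pk$apex_mass
    pk$reported_mass[as.integer(names(means))] <- as.numeric(means)
    pk$n_psms <- tabulate(best[!is.na(best)], nrow(pk))
  }
  peakset$peaks <- pk
  peakset$psms <- psms
  peakset$experiments <- exps
  peakset
}

#' Quantify peaks per experiment
#'
#' Spectral counts and size-normalized counts (count divided by the
#' experiment's total PSMs) for every peak and experiment, plus pooled totals.
#'
#' @param peakset A \code{peak_set} after \code{\link{assign_psms_to_peaks}}.
#' @return Long-format data.frame: \code{peak}, \code{experiment},
#'   \code{count}, \code{norm_count}, \code{total_psms}.
#' @export
quantify_peaks <- function(peakset) {
  psms <- peakset$psms
  if (is.null(psms)) stop("assign PSMs before quantifying", call. = FALSE)
  exps <- peakset$experiments
  npk <- nrow(peakset$peaks)
  totals <- table(factor(psms$experiment, levels = exps))
  grid <- expand.grid(peak = seq_len(npk), experiment = exps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  assigned <- psms[!is.na(psms$peak), c("peak", "experiment")]
  cnt <- table(factor(assigned$peak, levels = seq_len(npk)),
               factor(assigned$experiment, levels = exps))
  grid$count <- as.integer(cnt[cbind(grid$peak, match(grid$experiment, exps))])
  grid$total_psms <- as.integer(totals[grid$experiment])
  grid$norm_count <- ifelse(grid$total_psms > 0,
                            grid$count / grid$total_psms, 0)
  grid
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d peak(s), bin width %.4g Da\n",
              nrow(x$peaks), x$bin_width))
  if (nrow(x$peaks)) {
    top <- utils::head(x$peaks, 10)
    cat(sprintf("  %9.4f Da  snr %8.2f  prominence %.2f\n",
                top$reported_mass, top$snr, top$prominence), sep = "")
    if (nrow(x$peaks) > 10) cat("  ...\n")
  }
  invisible(x)
}
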