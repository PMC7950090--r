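# Delta-mass histogram construction and Gaussian smoothing.
#
# All experiments are pooled with unit PSM weight: summing per-experiment
# histograms with weight 1 per PSM is proportional to averaging them weighted
# by each experiment's share of total PSMs, so peak calling is unchanged.

#' Add uniform tie-break jitter to delta masses
#'
#' Bin boundaries can coincide exactly with repeated delta-mass values; a
#' small uniform jitter breaks such ties before binning. Order is preserved
#' and the result is reproducible for a fixed seed.
#'
#' @param delta_masses Numeric vector of delta masses (Da).
#' @param half_width Jitter half-width in Da; 0 is the identity.
#' @param seed Integer RNG seed.
#' @return Jittered numeric vector, same length and order.
#' @export
apply_tiebreak_jitter <- function(delta_masses, half_width, seed) {
  stopifnot(half_width >= 0)
  if (half_width == 0 || length(delta_masses) == 0) return(delta_masses)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  delta_masses + stats::runif(length(delta_masses), -half_width, half_width)
}

#' Build the aggregate delta-mass histogram
#'
#' Bins jittered delta masses from all PSMs (all experiments pooled, unit
#' weight per PSM) into fixed-width bins, extending the range by
#' \code{histogram_extension} Da on either side of the most extreme values so
#' edge peaks survive smoothing.
#'
#' @param psms PSM data.frame (needs a \code{delta_mass} column) or an
#'   \code{experiment_set}.
#' @param config A \code{\link{shift_config}}.
#' @return Object of class \code{"mass_shift_histogram"}: list with \code{lo}
#'   (left edge, Da), \code{bin_width}, \code{weights}, \code{total_weight},
#'   and the jittered masses used.
#' @export
build_histogram <- function(psms, config = shift_config()) {
  if (inherits(psms, "experiment_set")) psms <- psms$psms
  dm <- psms$delta_mass
  if (length(dm) == 0) stop("no PSMs: cannot build histogram", call. = FALSE)
  jit <- apply_tiebreak_jitter(dm, config$jitter_half_width, config$rng_seed)
  lo <- min(jit) - config$histogram_extension
  hi <- max(jit) + config$histogram_extension
  nbins <- max(1L, as.integer(ceiling((hi - lo) / config$bin_width)))
  idx <- bin_index(jit, lo, config$bin_width)
  idx[idx > nbins] <- nbins  # right edge
  weights <- tabulate(idx, nbins)
  structure(list(lo = lo, bin_width = config$bin_width,
                 weights = as.numeric(weights),
                 total_weight = length(dm), jittered = jit),
            class = "mass_shift_histogram")
}

#' Bin index of a mass within a histogram
#'
#' @param m Numeric masses (Da).
#' @param lo Histogram left edge (Da).
#' @param bin_width Bin width (Da).
#' @return 1-based integer bin indices, \code{floor((m - lo)/bin_width) + 1}.
#' @export
bin_index <- function(m, lo, bin_width) {
  as.integer(floor((m - lo) / bin_width)) + 1L
}

#' Center mass of histogram bins
#' @param hist A \code{mass_shift_histogram}.
#' @param idx Bin indices (default all).
#' @return Numeric vector of bin-center masses (Da).
#' @export
bin_center <- function(hist, idx = seq_along(hist$weights)) {
  hist$lo + (idx - 0.5) * hist$bin_width
}

#' Gaussian smoothing kernel over histogram bins
#'
#' Sigma (in bin units) is fixed so that the central \code{bins} bins cover
#' \code{mass_fraction} of the Gaussian mass:
#' \code{sigma = (bins/2) / qnorm((1 + mass_fraction)/2)}. The kernel is the
#' per-bin integral of that Gaussian, renormalized to sum to 1.
#'
#' @param bins Odd kernel length in bins.
#' @param mass_fraction Gaussian mass the kernel span covers.
#' @return Numeric vector of length \code{bins} summing to 1.
#' @export
smoothing_kernel <- function(bins, mass_fraction) {
  stopifnot(bins >= 1, bins %% 2 == 1, mass_fraction > 0, mass_fraction < 1)
  if (bins == 1) return(1)
  sigma <- (bins / 2) / stats::qnorm((1 + mass_fraction) / 2)
  h <- (bins - 1L) / 2L
  j <- -h:h
  k <- stats::pnorm((j + 0.5) / sigma) - stats::pnorm((j - 0.5) / sigma)
  k / sum(k)
}

#' Smooth a delta-mass histogram
#'
#' Discrete convolution with the truncated, renormalized Gaussian kernel of
#' \code{\link{smoothing_kernel}}. Near the histogram ends the kernel is
#' re-truncated and renormalized per source bin so no weight is lost off the
#' edges: total weight is conserved exactly (to float tolerance).
#'
#' @param hist A \code{mass_shift_histogram}.
#' @param smoothing_bins Odd kernel length.
#' @param smoothing_mass_fraction Gaussian mass within the kernel span.
#' @return A smoothed \code{mass_shift_histogram}.
#' @export
smooth_histogram <- function(hist, smoothing_bins = 5L,
                             smoothing_mass_fraction = 0.95) {
  w <- hist$weights
  n <- length(w)
  k <- smoothing_kernel(smoothing_bins, smoothing_mass_fraction)
  h <- (smoothing_bins - 1L) / 2L
  if (h == 0L || n == 1L) return(hist)
  # kept fraction per source bin (differs from 1 only within h of an edge)
  ck <- c(0, cumsum(k))
  i <- seq_len(n)
  jmin <- pmax(-h, 1L - i)
  jmax <- pmin(h, n - i)
  kept <- ck[jmax + h + 2L] - ck[jmin + h + 1L]
  src <- w / kept
  out <- numeric(n)
  for (j in -h:h) {
    kj <- k[j + h + 1L]
    if (j >= 0) {
      out[(1L + j):n] <- out[(1L + j):n] + src[1:(n - j)] * kj
    } else {
      out[1:(n + j)] <- out[1:(n + j)] + src[(1L - j):n] * kj
    }
  }
  res <- hist
  res$weights <- out
  res$total_weight <- sum(out)
  res
}

#' @export
print.mass_shift_histogram <- function(x, ...) {
  cat(sprintf(
    "Mass-shift histogram: %d bins of %.4g Da over [%.4f, %.4f] Da, total weight %.6g\n",
    length(x$weights), x$bin_width, x$lo,
    x$lo + length(x$weights) * x$bin_width, x$total_weight))
  invisible(x)
}

#' Dump a histogram as a two-column TSV (bin center, weight)
#'
#' Only bins with nonzero weight are written unless \code{all = TRUE}.
#'
#' @param hist A \code{mass_shift_histogram}.
#' @param path Output path.
#' @param all Write empty bins too.
#' @return \code{path}, invisibly.
#' @export
write_histogram_tsv <- function(hist, path, all = FALSE) {
  idx <- if (all) seq_along(hist$weights) else which(hist$weights > 0)
  df <- data.frame(mass = sprintf("%.6f", bin_center(hist, idx)),
                   weight = sprintf("%.8g", hist$weights[idx]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
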