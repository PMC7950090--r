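#' Configuration for a mass-shift profiling run
#'
#' Collects every tunable parameter of the pipeline with the defaults used
#' throughout: histogram binning and smoothing, peak calling, annotation,
#' localization, and modified/unmodified comparison settings.
#'
#' @param bin_width Histogram bin width in Da.
#' @param histogram_extension Da added on either side of the most extreme
#'   delta masses so edge peaks survive smoothing.
#' @param jitter_half_width Half-width in Da of the uniform tie-break jitter
#'   added to delta masses before binning. The default (0.0001 Da, half a
#'   default bin) breaks bin-boundary ties without blurring sub-millidalton
#'   structure; larger values remain selectable.
#' @param smoothing_bins Odd number of bins the Gaussian smoothing kernel
#'   spans.
#' @param smoothing_mass_fraction Fraction of the Gaussian mass the central
#'   \code{smoothing_bins} bins cover; fixes the kernel sigma.
#' @param prominence_threshold Minimum normalized prominence
#'   \code{(apex - shoulder)/apex} for a peak to be called.
#' @param snr_signal_window Width in Da of the signal window centred on the
#'   apex for the signal-to-noise remainder.
#' @param snr_background_flank Width in Da of each background flank adjacent
#'   to the signal window.
#' @param top_n_peaks Number of called peaks, ranked by SNR, retained for
#'   downstream processing.
#' @param precursor_tol Cap in Da on the distance from apex to either peak
#'   boundary.
#' @param annotation_tol Tolerance in Da for matching a peak mass against
#'   modification masses (single entries and two-component sums).
#' @param max_components Maximum modifications a peak may be decomposed into
#'   (fixed at 2).
#' @param prioritize_user_mods If TRUE, any annotation candidate containing a
#'   user-supplied shift outranks any candidate that does not.
#' @param unmodified_threshold Absolute delta mass in Da below which a PSM
#'   counts as unmodified.
#' @param unmodified_cap Maximum unmodified spectra retained per
#'   (peptide, charge) key; excess keys are randomly subsampled.
#' @param isotope_spacing Da spacing used to generate isotopic-error
#'   annotation entries (peptide averagine spacing).
#' @param fragment_tol Fragment match tolerance; interpreted in ppm when
#'   \code{fragment_tol_unit = "ppm"}, in Da when \code{"da"}.
#' @param fragment_tol_unit One of \code{"ppm"}, \code{"da"}.
#' @param background_scope Residue-background normalization for enrichment:
#'   \code{"dataset_psm"} (default), \code{"dataset_peptide"},
#'   \code{"bin_psm"} or \code{"bin_peptide"}.
#' @param flatten_width Da span of the bin groups flattened to their minimum
#'   before the prominence walk (5 bins at defaults).
#' @param similarity_grid Fixed m/z grid width in Th used when accumulating
#'   intensities for the cosine similarity.
#' @param rng_seed Integer seed driving jitter and subsampling.
#'
#' @return An object of class \code{"shift_config"} (a validated list).
#' @examples
#' cfg <- shift_config(top_n_peaks = 100)
#' cfg$bin_width
#' @export
shift_config <- function(bin_width = 0.0002,
                            histogram_extension = 5.0,
                            jitter_half_width = 0.0001,
                            smoothing_bins = 5L,
                            smoothing_mass_fraction = 0.95,
                            prominence_threshold = 0.3,
                            snr_signal_window = 0.004,
                            snr_background_flank = 0.005,
                            top_n_peaks = 500L,
                            precursor_tol = 0.01,
                            annotation_tol = 0.01,
                            max_components = 2L,
                            prioritize_user_mods = TRUE,
                            unmodified_threshold = 0.001,
                            unmodified_cap = 50L,
                            isotope_spacing = 1.00235,
                            fragment_tol = 20,
                            fragment_tol_unit = c("ppm", "da"),
                            background_scope = c("dataset_psm", "dataset_peptide",
                                                 "bin_psm", "bin_peptide"),
                            flatten_width = 0.0010,
                            similarity_grid = 0.05,
                            rng_seed = 42L) {
  fragment_tol_unit <- match.arg(fragment_tol_unit)
  background_scope <- match.arg(background_scope)
  stopifnot(
    bin_width > 0, histogram_extension > 0, jitter_half_width >= 0,
    snr_signal_window > 0, snr_background_flank > 0,
    precursor_tol > 0, annotation_tol > 0, unmodified_threshold > 0,
    fragment_tol > 0, flatten_width > 0, similarity_grid > 0,
    top_n_peaks >= 1, unmodified_cap >= 1, max_components == 2L
  )
  if (smoothing_bins < 1L || smoothing_bins %% 2L == 0L)
    stop("`smoothing_bins` must be an odd positive integer", call. = FALSE)
  if (smoothing_mass_fraction <= 0 || smoothing_mass_fraction >= 1)
    stop("`smoothing_mass_fraction` must lie in (0, 1)", call. = FALSE)
  if (prominence_threshold <= 0 || prominence_threshold >= 1)
    stop("`prominence_threshold` must lie in (0, 1)", call. = FALSE)

  structure(list(
    bin_width = bin_width,
    histogram_extension = histogram_extension,
    jitter_half_width = jitter_half_width,
    smoothing_bins = as.integer(smoothing_bins),
    smoothing_mass_fraction = smoothing_mass_fraction,
    prominence_threshold = prominence_threshold,
    snr_signal_window = snr_signal_window,
    snr_background_flank = snr_background_flank,
    top_n_peaks = as.integer(top_n_peaks),
    precursor_tol = precursor_tol,
    annotation_tol = annotation_tol,
    max_components = 2L,
    prioritize_user_mods = isTRUE(prioritize_user_mods),
    unmodified_threshold = unmodified_threshold,
    unmodified_cap = as.integer(unmodified_cap),
    isotope_spacing = isotope_spacing,
    fragment_tol = fragment_tol,
    fragment_tol_unit = fragment_tol_unit,
    background_scope = background_scope,
    flatten_width = flatten_width,
    similarity_grid = similarity_grid,
    rng_seed = as.integer(rng_seed)
  ), class = "shift_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments are
#' ignored. Keys must be formal arguments of \code{\link{shift_config}}.
#'
#' @param path Path to the configuration file.
#' @return A \code{shift_config} object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(shift_config)))
      stop("unknown config key: '", key, "'", call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(toupper(val))
      else val
  }
  do.call(shift_config, args)
}

#' @export
print.shift_config <- function(x, ...) {
  cat("Mass-shift profiling configuration\n")
  cat(sprintf("  histogram: %.4g Da bins, +/-%.3g Da extension, %d-bin smoothing (%.0f%%)\n",
              x$bin_width, x$histogram_extension, x$smoothing_bins,
              100 * x$smoothing_mass_fraction))
  cat(sprintf("  peaks: prominence > %.2f, SNR windows %.4g/%.4g Da, top %d\n",
              x$prominence_threshold, x$snr_signal_window,
              x$snr_background_flank, x$top_n_peaks))
  cat(sprintf("  annotation: tol %.4g Da, <= %d components, user mods %s\n",
              x$annotation_tol, x$max_components,
              if (x$prioritize_user_mods) "prioritized" else "not prioritized"))
  cat(sprintf("  comparison: unmodified < %.4g Da, cap %d; fragment tol %g %s\n",
              x$unmodified_threshold, x$unmodified_cap,
              x$fragment_tol, x$fragment_tol_unit))
  cat(sprintf("  background scope: %s; seed %d\n", x$background_scope, x$rng_seed))
  invisible(x)
}
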