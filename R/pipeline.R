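#' Profile mass shifts across one or more open-search experiments
#'
#' The main driver: pools delta masses from every experiment into one
#' jittered, smoothed histogram; calls peaks by prominence and ranks them by
#' signal-to-noise remainder; assigns and quantifies PSMs per experiment;
#' annotates peak masses by staged decomposition into at most two known
#' modifications; localizes each peak's shift within its PSMs by exhaustive
#' single-site rescoring; and compares modified PSMs with unmodified
#' counterparts (cosine similarity, retention-time delta).
#'
#' @param exset An \code{\link{assemble_experiment_set}} result.
#' @param config A \code{\link{shift_config}}.
#' @param entries Modification entry table
#'   (\code{\link{load_modification_table}}); NULL loads the shipped
#'   catalogue with no user shifts.
#' @param stages Character subset of \code{c("annotation", "localization",
#'   "similarity")} to run beyond detection/quantification.
#' @return Object of class \code{"shift_profile"}: list with
#'   \code{histogram} (smoothed), \code{peakset}, \code{quant},
#'   \code{annotations}, \code{localization} (aggregated profiles),
#'   \code{localization_psm} (per-PSM results), \code{comparison},
#'   \code{comparison_psm}, \code{global} (the joined per-peak table),
#'   \code{config}.
#' @examples
#' fx <- generate_dataset(fixture_spec(n_experiments = 1, n_psms = 150,
#'                                     shifts = fixture_shifts()[1:2, ]))
#' exset <- assemble_experiment_set(fx$psm_tables, fx$spectra)
#' prof <- shift_profile(exset, shift_config(top_n_peaks = 20))
#' prof
#' @export
shift_profile <- function(exset, config = shift_config(), entries = NULL,
                          stages = c("annotation", "localization", "similarity")) {
  stopifnot(inherits(exset, "experiment_set"))
  if (is.null(entries))
    entries <- load_modification_table(isotope_spacing = config$isotope_spacing)

  hist_raw <- build_histogram(exset, config)
  hist <- smooth_histogram(hist_raw, config$smoothing_bins,
                           config$smoothing_mass_fraction)
  peakset <- pick_peaks(hist, config)
  peakset <- assign_psms_to_peaks(peakset, exset)
  quant <- quantify_peaks(peakset)

  annotations <- NULL
  if ("annotation" %in% stages && nrow(peakset$peaks))
    annotations <- annotate_peaks(peakset, entries, config)

  loc_psm <- NULL; loc <- NULL
  if ("localization" %in% stages && length(exset$spectra)) {
    loc_psm <- localize_peakset(peakset, exset$spectra, config)
    if (nrow(loc_psm))
      loc <- aggregate_localization_profile(loc_psm, config$background_scope)
  }

  cmp_psm <- NULL; cmp <- NULL
  if ("similarity" %in% stages) {
    index <- build_unmodified_index(exset, config)
    cmp_psm <- compare_peakset(peakset, index, exset$spectra, config)
    cmp <- aggregate_comparison_profile(cmp_psm, peakset)
  }

  global <- build_global_profile(peakset, quant, annotations, loc, cmp)
  structure(list(histogram = hist, histogram_raw = hist_raw,
                 peakset = peakset, quant = quant,
                 annotations = annotations,
                 localization = loc, localization_psm = loc_psm,
                 comparison = cmp, comparison_psm = cmp_psm,
                 global = global, config = config),
            class = "shift_profile")
}

#' @export
print.shift_profile <- function(x, ...) {
  cat("Mass-shift profile\n")
  cat(sprintf("  %d PSMs in %d experiment(s); %d peak(s) called\n",
              nrow(x$peakset$psms), length(x$peakset$experiments),
              nrow(x$peakset$peaks)))
  g <- utils::head(x$global, 8)
  if (nrow(g)) {
    cat("  top mass shifts by PSM count:\n")
    for (i in seq_len(nrow(g)))
      cat(sprintf("    %9.4f Da  %6d PSMs  %s\n", g$reported_mass[i],
                  g$n_psms[i],
                  if (is.na(g$annotation[i])) "" else g$annotation[i]))
  }
  invisible(x)
}

#' @export
summary.shift_profile <- function(object, ...) {
  g <- object$global
  cat("Mass-shift profile summary\n")
  cat(sprintf("  peaks: %d; assigned PSMs: %d of %d (%.1f%%)\n",
              nrow(object$peakset$peaks),
              sum(!is.na(object$peakset$psms$peak)),
              nrow(object$peakset$psms),
              100 * mean(!is.na(object$peakset$psms$peak))))
  if (!is.null(object$annotations)) {
    st <- table(object$annotations$stage)
    cat("  annotation stages:",
        paste(names(st), st, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(object$localization))
    cat(sprintf("  median localized fraction: %.2f\n",
                stats::median(object$localization$localized_fraction)))
  if (!is.null(object$comparison) && nrow(object$comparison))
    cat(sprintf("  mean spectral similarity (over profiles): %.2f\n",
                mean(object$comparison$mean_similarity, na.rm = TRUE)))
  invisible(g)
}

#' Plot a mass-shift profile
#'
#' Smoothed delta-mass histogram with called peak apexes marked.
#'
#' @param x A \code{shift_profile}.
#' @param xlim Optional mass range (Da).
#' @param ... Passed to \code{plot}.
#' @export
plot.shift_profile <- function(x, xlim = NULL, ...) {
  h <- x$histogram
  ctr <- bin_center(h)
  keep <- h$weights > 0
  if (!is.null(xlim)) keep <- keep & ctr >= xlim[1] & ctr <= xlim[2]
  plot(ctr[keep], h$weights[keep], type = "h", col = "grey40",
       xlab = "delta mass (Da)", ylab = "smoothed weight", ...)
  if (nrow(x$peakset$peaks))
    graphics::points(x$peakset$peaks$apex_mass, x$peakset$peaks$apex_height,
                     col = "red3", pch = 17, cex = 0.8)
  invisible(x)
}
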