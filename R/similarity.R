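# Modified vs unmodified comparisons: cosine spectral similarity on a fixed
# m/z grid and retention-time deltas, aggregated per peak and experiment.

#' Build the unmodified-PSM index
#'
#' PSMs with |delta mass| below \code{unmodified_threshold} are grouped by
#' (peptide, charge) within each experiment; groups larger than
#' \code{unmodified_cap} are randomly subsampled to the cap (reproducibly
#' under \code{rng_seed}).
#'
#' @param psms PSM data.frame or \code{experiment_set}.
#' @param config A \code{\link{shift_config}}.
#' @return Object of class \code{"unmodified_index"}: a list keyed by
#'   \code{experiment|peptide|charge}, each element a data.frame with
#'   \code{spectrum_id}, \code{retention_time}.
#' @export
build_unmodified_index <- function(psms, config = shift_config()) {
  if (inherits(psms, "experiment_set")) psms <- psms$psms
  unmod <- psms[abs(psms$delta_mass) < config$unmodified_threshold, , drop = FALSE]
  key <- paste(unmod$experiment, unmod$peptide, unmod$charge, sep = "|")
  idx <- split(unmod[, c("spectrum_id", "retention_time")], key)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$rng_seed)
  idx <- lapply(idx, function(df) {
    if (nrow(df) > config$unmodified_cap)
      df <- df[sort(sample.int(nrow(df), config$unmodified_cap)), , drop = FALSE]
    df
  })
  structure(idx, class = "unmodified_index")
}

#' Cosine similarity between two spectra on a fixed m/z grid
#'
#' Intensities are accumulated into fixed-width m/z cells; the similarity is
#' the cosine of the two resulting nonnegative vectors (0 when either
#' spectrum is empty).
#'
#' @param a,b Spectra (lists with \code{mz}, \code{intensity}).
#' @param grid_width Cell width in Th.
#' @return Similarity in [0, 1].
#' @export
spectrum_cosine <- function(a, b, grid_width = 0.05) {
  stopifnot(grid_width > 0)
  if (!length(a$mz) || !length(b$mz)) return(0)
  ga <- floor(a$mz / grid_width)
  gb <- floor(b$mz / grid_width)
  va <- vapply(split(a$intensity, ga), sum, numeric(1))
  vb <- vapply(split(b$intensity, gb), sum, numeric(1))
  keys <- union(names(va), names(vb))
  x <- stats::setNames(numeric(length(keys)), keys)
  y <- x
  x[names(va)] <- va
  y[names(vb)] <- vb
  den <- sqrt(sum(x^2)) * sqrt(sum(y^2))
  if (den == 0) return(0)
  min(1, sum(x * y) / den)
}

#' Compare one modified PSM with its unmodified counterparts
#'
#' Looks up unmodified PSMs of the same peptide and charge (same experiment),
#' and returns the average cosine similarity against their spectra and the
#' average retention-time difference (modified RT minus mean counterpart RT).
#'
#' @param psm One-row PSM data.frame.
#' @param index An \code{unmodified_index}.
#' @param spectra Named spectrum store.
#' @param config A \code{\link{shift_config}}.
#' @return List with \code{similarity}, \code{delta_rt}, \code{n_counterparts},
#'   or \code{NULL} when the peptide has no unmodified counterpart.
#' @export
compare_modified_psm <- function(psm, index, spectra,
                                 config = shift_config()) {
  key <- paste(psm$experiment, psm$peptide, psm$charge, sep = "|")
  cp <- index[[key]]
  if (is.null(cp) || nrow(cp) == 0) return(NULL)
  # a PSM in the unmodified bin must not be compared against itself
  cp <- cp[cp$spectrum_id != psm$spectrum_id, , drop = FALSE]
  if (nrow(cp) == 0) return(NULL)
  sims <- NA_real_
  sp <- spectra[[psm$spectrum_id]]
  if (!is.null(sp)) {
    cps <- cp$spectrum_id[cp$spectrum_id %in% names(spectra)]
    if (length(cps))
      sims <- mean(vapply(cps, function(id)
        spectrum_cosine(sp, spectra[[id]], config$similarity_grid), numeric(1)))
  }
  list(similarity = sims,
       delta_rt = psm$retention_time - mean(cp$retention_time),
       n_counterparts = nrow(cp))
}

#' Compare every assigned PSM in a peak set with its unmodified counterparts
#'
#' @param peakset A \code{peak_set} after \code{\link{assign_psms_to_peaks}}.
#' @param index An \code{unmodified_index}.
#' @param spectra Named spectrum store.
#' @param config A \code{\link{shift_config}}.
#' @return data.frame, one row per assigned PSM with a counterpart:
#'   \code{psm_row}, \code{peak}, \code{experiment}, \code{similarity},
#'   \code{delta_rt}.
#' @export
compare_peakset <- function(peakset, index, spectra,
                            config = shift_config()) {
  psms <- peakset$psms
  cand <- which(!is.na(psms$peak))
  rows <- list()
  for (i in cand) {
    cmp <- compare_modified_psm(psms[i, ], index, spectra, config)
    if (is.null(cmp)) next
    rows[[length(rows) + 1L]] <- data.frame(
      psm_row = i, peak = psms$peak[i], experiment = psms$experiment[i],
      similarity = cmp$similarity, delta_rt = cmp$delta_rt)
  }
  if (!length(rows))
    return(data.frame(psm_row = integer(), peak = integer(),
                      experiment = character(), similarity = numeric(),
                      delta_rt = numeric()))
  do.call(rbind, rows)
}

#' Aggregate modified/unmodified comparison profiles per peak and experiment
#'
#' @param cmp Result of \code{\link{compare_peakset}}.
#' @param peakset The \code{peak_set} the comparisons came from.
#' @return data.frame: \code{peak}, \code{experiment}, \code{n_assigned},
#'   \code{n_compared}, \code{fraction_with_counterpart},
#'   \code{mean_similarity}, \code{mean_delta_rt}.
#' @export
aggregate_comparison_profile <- function(cmp, peakset) {
  psms <- peakset$psms
  assigned <- psms[!is.na(psms$peak), c("peak", "experiment")]
  keys <- unique(assigned)
  out <- lapply(seq_len(nrow(keys)), function(r) {
    pa <- assigned$peak == keys$peak[r] & assigned$experiment == keys$experiment[r]
    pc <- cmp$peak == keys$peak[r] & cmp$experiment == keys$experiment[r]
    n_a <- sum(pa)
    n_c <- sum(pc)
    sims <- cmp$similarity[pc]
    data.frame(
      peak = keys$peak[r], experiment = keys$experiment[r],
      n_assigned = n_a, n_compared = n_c,
      fraction_with_counterpart = if (n_a) n_c / n_a else 0,
      mean_similarity = if (n_c && any(!is.na(sims))) mean(sims, na.rm = TRUE)
                        else NA_real_,
      mean_delta_rt = if (n_c) mean(cmp$delta_rt[pc]) else NA_real_)
  })
  res <- do.call(rbind, out)
  res[order(res$peak, res$experiment), , drop = FALSE]
}
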