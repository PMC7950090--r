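# Mass-shift localization: exhaustive single-site rescoring of each PSM with
# an MSFragger-style hyperscore, and per-peak residue-enrichment profiles.

#' Theoretical singly charged b/y fragment m/z values
#'
#' Generates b1..b(L-1) and y1..y(L-1) at charge 1 for a peptide, applying
#' any search modifications (position, mass) and optionally a mass shift at
#' one position: with the shift at position k, b ions at and beyond k and y
#' ions covering k (index j >= L - k + 1) are shifted.
#'
#' @param peptide Uppercase amino-acid string.
#' @param applied_mods data.frame with columns \code{pos}, \code{mass} (may
#'   be empty).
#' @param shift_mass Mass shift in Da (ignored when \code{shift_pos} is NA).
#' @param shift_pos 1-based residue position carrying the shift, or NA.
#' @return data.frame with columns \code{ion} (\code{"b"}/\code{"y"}),
#'   \code{index}, \code{mz}; \code{2*(L-1)} rows.
#' @export
theoretical_fragments <- function(peptide, applied_mods = NULL,
                                  shift_mass = 0, shift_pos = NA) {
  aa <- strsplit(peptide, "")[[1]]
  L <- length(aa)
  if (L < 1 || any(!aa %in% names(AA_MONO)))
    stop("invalid peptide '", peptide, "'", call. = FALSE)
  res <- unname(AA_MONO[aa])
  if (!is.null(applied_mods) && nrow(applied_mods)) {
    if (any(applied_mods$pos < 1 | applied_mods$pos > L))
      stop("applied modification position out of range", call. = FALSE)
    res[applied_mods$pos] <- res[applied_mods$pos] + applied_mods$mass
  }
  if (!is.na(shift_pos)) {
    if (shift_pos < 1 || shift_pos > L)
      stop("shift position out of range", call. = FALSE)
    res[shift_pos] <- res[shift_pos] + shift_mass
  }
  if (L == 1)
    return(data.frame(ion = character(), index = integer(), mz = numeric()))
  bcum <- cumsum(res)
  b <- bcum[1:(L - 1)] + PROTON_MASS
  ycum <- cumsum(rev(res))
  y <- ycum[1:(L - 1)] + WATER_MASS + PROTON_MASS
  data.frame(ion = rep(c("b", "y"), each = L - 1L),
             index = rep(seq_len(L - 1L), 2),
             mz = c(b, y))
}

.tol_da <- function(mz, config) {
  if (config$fragment_tol_unit == "ppm") mz * config$fragment_tol * 1e-6
  else rep_len(config$fragment_tol, length(mz))
}

#' MSFragger-style hyperscore of a fragment match
#'
#' Fragments are matched to spectrum peaks greedily (nearest peak within
#' tolerance, each spectrum peak usable once), then scored as
#' \code{log10(Nb! * Ny! * max(sum_Ib, 1) * max(sum_Iy, 1))}, factorials in
#' log space.
#'
#' @param spectrum List with sorted \code{mz} and \code{intensity}.
#' @param fragments data.frame from \code{\link{theoretical_fragments}}.
#' @param config A \code{\link{shift_config}} (fragment tolerance).
#' @return List with \code{Nb}, \code{Ny}, \code{sum_Ib}, \code{sum_Iy},
#'   \code{n_matched}, \code{score}.
#' @export
hyperscore <- function(spectrum, fragments, config = shift_config()) {
  mz <- spectrum$mz
  used <- rep(FALSE, length(mz))
  Nb <- 0L; Ny <- 0L; sIb <- 0; sIy <- 0
  if (length(mz) && nrow(fragments)) {
    tol <- .tol_da(fragments$mz, config)
    pos <- findInterval(fragments$mz, mz)
    for (f in seq_len(nrow(fragments))) {
      best <- 0L; bd <- Inf
      for (i in c(pos[f], pos[f] + 1L)) {
        # widen around the insertion point until peaks fall outside tolerance
        step <- if (i <= pos[f]) -1L else 1L
        while (i >= 1L && i <= length(mz) && abs(mz[i] - fragments$mz[f]) <= tol[f]) {
          d <- abs(mz[i] - fragments$mz[f])
          # strict < keeps the first (lower m/z) peak on exact-distance ties
          if (!used[i] && d < bd) { best <- i; bd <- d }
          i <- i + step
        }
      }
      if (best > 0L) {
        used[best] <- TRUE
        if (fragments$ion[f] == "b") { Nb <- Nb + 1L; sIb <- sIb + spectrum$intensity[best] }
        else { Ny <- Ny + 1L; sIy <- sIy + spectrum$intensity[best] }
      }
    }
  }
  score <- (lfactorial(Nb) + lfactorial(Ny)) / log(10) +
    log10(max(sIb, 1)) + log10(max(sIy, 1))
  list(Nb = Nb, Ny = Ny, sum_Ib = sIb, sum_Iy = sIy,
       n_matched = Nb + Ny, score = score)
}

#' Localize a PSM's mass shift by exhaustive single-site rescoring
#'
#' Scores the PSM with the shift placed at every residue position in turn,
#' plus an unshifted baseline. The PSM is localizable iff some placement
#' matches strictly more fragment ions than the baseline; localization weight
#' is distributed uniformly over the top-scoring positions.
#'
#' @param psm One-row PSM data.frame (needs \code{peptide}, \code{mods}).
#' @param spectrum The PSM's spectrum.
#' @param shift_mass The peak's mass shift (Da).
#' @param config A \code{\link{shift_config}}.
#' @return List with \code{localizable}, \code{site_weights} (length L,
#'   summing to 1 iff localizable else all 0), \code{best_score},
#'   \code{baseline_matched}, \code{nterm_flag}.
#' @export
localize_psm <- function(psm, spectrum, shift_mass, config = shift_config()) {
  peptide <- psm$peptide
  L <- nchar(peptide)
  mods <- parse_mods(psm$mods)[[1]]
  base <- hyperscore(spectrum, theoretical_fragments(peptide, mods), config)
  scores <- numeric(L)
  matched <- integer(L)
  for (k in seq_len(L)) {
    fr <- theoretical_fragments(peptide, mods, shift_mass, k)
    sc <- hyperscore(spectrum, fr, config)
    scores[k] <- sc$score
    matched[k] <- sc$n_matched
  }
  weights <- numeric(L)
  localizable <- max(matched) > base$n_matched
  if (localizable) {
    top <- which(scores >= max(scores) - 1e-12)
    weights[top] <- 1 / length(top)
  }
  list(localizable = localizable, site_weights = weights,
       best_score = max(scores), baseline_matched = base$n_matched,
       nterm_flag = localizable && weights[1] > 0)
}

# Residue counts of a character vector of peptides (background helper).
.residue_counts <- function(peptides) {
  tab <- table(factor(unlist(strsplit(peptides, "")), levels = names(AA_MONO)))
  stats::setNames(as.numeric(tab), names(AA_MONO))
}

#' Run localization for every assigned PSM in a peak set
#'
#' @param peakset A \code{peak_set} after \code{\link{assign_psms_to_peaks}}.
#' @param spectra Named spectrum store.
#' @param config A \code{\link{shift_config}}.
#' @return data.frame, one row per localizable-candidate PSM (assigned to a
#'   peak and with a resolvable spectrum): \code{psm_row}, \code{peak},
#'   \code{experiment}, \code{peptide}, \code{localizable}, \code{nterm},
#'   plus a list column \code{site_weights}.
#' @export
localize_peakset <- function(peakset, spectra, config = shift_config()) {
  psms <- peakset$psms
  cand <- which(!is.na(psms$peak) &
                  (if ("has_spectrum" %in% names(psms)) psms$has_spectrum
                   else psms$spectrum_id %in% names(spectra)))
  rows <- vector("list", length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    shift <- peakset$peaks$reported_mass[psms$peak[i]]
    loc <- localize_psm(psms[i, ], spectra[[psms$spectrum_id[i]]], shift, config)
    rows[[j]] <- list(psm_row = i, peak = psms$peak[i],
                      experiment = psms$experiment[i],
                      peptide = psms$peptide[i],
                      localizable = loc$localizable,
                      nterm = loc$nterm_flag,
                      site_weights = loc$site_weights)
  }
  out <- data.frame(
    psm_row = vapply(rows, `[[`, numeric(1), "psm_row"),
    peak = vapply(rows, `[[`, numeric(1), "peak"),
    experiment = vapply(rows, `[[`, character(1), "experiment"),
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    localizable = vapply(rows, `[[`, logical(1), "localizable"),
    nterm = vapply(rows, `[[`, logical(1), "nterm"),
    stringsAsFactors = FALSE
  )
  out$site_weights <- lapply(rows, `[[`, "site_weights")
  out
}

#' Aggregate residue-enrichment localization profiles
#'
#' Sums localization site weights by residue identity for each peak and
#' experiment, normalizes to the within-peak localization rate per residue,
#' and divides by the residue's background content under the chosen scope:
#' background counted over every localizable PSM in the entire data set
#' (\code{dataset_psm}, default), over unique peptides
#' (\code{dataset_peptide}), or restricted to the peak's own PSMs/peptides
#' (\code{bin_psm}, \code{bin_peptide}).
#'
#' @param loc Result of \code{\link{localize_peakset}}.
#' @param background_scope One of the four scopes above.
#' @return data.frame, one row per (peak, experiment) with any candidate
#'   PSMs: \code{peak}, \code{experiment}, \code{n_candidates},
#'   \code{localized_fraction}, \code{nterm_rate}, \code{top_residue},
#'   \code{top_enrichment}, \code{second_residue}, \code{second_enrichment},
#'   plus list columns \code{residue_counts}, \code{background_counts},
#'   \code{enrichment} (named per residue; enrichment NA where background is
#'   absent).
#' @export
aggregate_localization_profile <- function(loc, background_scope = "dataset_psm") {
  stopifnot(background_scope %in% c("dataset_psm", "dataset_peptide",
                                    "bin_psm", "bin_peptide"))
  lset <- loc[loc$localizable, , drop = FALSE]
  bg_all <- switch(background_scope,
    dataset_psm = .residue_counts(lset$peptide),
    dataset_peptide = .residue_counts(unique(lset$peptide)),
    NULL)
  keys <- unique(loc[, c("peak", "experiment")])
  out <- vector("list", nrow(keys))
  for (r in seq_len(nrow(keys))) {
    sel <- loc$peak == keys$peak[r] & loc$experiment == keys$experiment[r]
    grp <- loc[sel, , drop = FALSE]
    lgrp <- grp[grp$localizable, , drop = FALSE]
    rc <- stats::setNames(numeric(length(AA_MONO)), names(AA_MONO))
    for (j in seq_len(nrow(lgrp))) {
      aa <- strsplit(lgrp$peptide[j], "")[[1]]
      w <- lgrp$site_weights[[j]]
      nz <- which(w > 0)
      for (k in nz) rc[aa[k]] <- rc[aa[k]] + w[k]
    }
    bg <- switch(background_scope,
      bin_psm = .residue_counts(lgrp$peptide),
      bin_peptide = .residue_counts(unique(lgrp$peptide)),
      bg_all)
    enr <- rep(NA_real_, length(AA_MONO))
    names(enr) <- names(AA_MONO)
    if (sum(rc) > 0 && sum(bg) > 0) {
      ok <- bg > 0
      enr[ok] <- (rc[ok] / sum(rc)) / (bg[ok] / sum(bg))
    }
    ord <- order(-enr, na.last = TRUE)
    top <- ord[rc[ord] > 0 & !is.na(enr[ord])]
    out[[r]] <- list(
      peak = keys$peak[r], experiment = keys$experiment[r],
      n_candidates = nrow(grp),
      localized_fraction = if (nrow(grp)) nrow(lgrp) / nrow(grp) else 0,
      nterm_rate = if (nrow(lgrp)) mean(lgrp$nterm) else NA_real_,
      top_residue = if (length(top) >= 1) names(AA_MONO)[top[1]] else NA_character_,
      top_enrichment = if (length(top) >= 1) enr[top[1]] else NA_real_,
      second_residue = if (length(top) >= 2) names(AA_MONO)[top[2]] else NA_character_,
      second_enrichment = if (length(top) >= 2) enr[top[2]] else NA_real_,
      residue_counts = rc, background_counts = bg, enrichment = enr)
  }
  res <- data.frame(
    peak = vapply(out, `[[`, numeric(1), "peak"),
    experiment = vapply(out, `[[`, character(1), "experiment"),
    n_candidates = vapply(out, `[[`, numeric(1), "n_candidates"),
    localized_fraction = vapply(out, `[[`, numeric(1), "localized_fraction"),
    nterm_rate = vapply(out, `[[`, numeric(1), "nterm_rate"),
    top_residue = vapply(out, `[[`, character(1), "top_residue"),
    top_enrichment = vapply(out, `[[`, numeric(1), "top_enrichment"),
    second_residue = vapply(out, `[[`, character(1), "second_residue"),
    second_enrichment = vapply(out, `[[`, numeric(1), "second_enrichment"),
    stringsAsFactors = FALSE
  )
  res$residue_counts <- lapply(out, `[[`, "residue_counts")
  res$background_counts <- lapply(out, `[[`, "background_counts")
  res$enrichment <- lapply(out, `[[`, "enrichment")
  res
}
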