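# Global per-peak summary table, multi-experiment profile matrix, and
# deterministic TSV report writing.

#' Assemble the global per-peak profile table
#'
#' Joins quantification, annotation, localization, and comparison results on
#' peak identity into one row per retained peak, ordered by pooled PSM count
#' descending. Missing sub-profiles render as NA (empty cells on write),
#' never fabricated zeros.
#'
#' @param peakset A \code{peak_set} after assignment.
#' @param quant Result of \code{\link{quantify_peaks}}.
#' @param annotations Result of \code{\link{annotate_peaks}} (or NULL).
#' @param localization Result of \code{\link{aggregate_localization_profile}}
#'   (or NULL).
#' @param comparison Result of \code{\link{aggregate_comparison_profile}}
#'   (or NULL).
#' @return data.frame, one row per peak: \code{reported_mass}, \code{apex_mass},
#'   \code{prominence}, \code{snr}, \code{n_psms} (pooled), one
#'   \code{count.<experiment>} and \code{norm.<experiment>} pair per
#'   experiment, \code{annotation}, \code{pct_in_unmodified},
#'   \code{mean_similarity}, \code{mean_delta_rt}, \code{nterm_rate},
#'   \code{top_residue}, \code{top_enrichment}, \code{second_residue},
#'   \code{second_enrichment}.
#' @export
build_global_profile <- function(peakset, quant, annotations = NULL,
                                 localization = NULL, comparison = NULL) {
  pk <- peakset$peaks
  npk <- nrow(pk)
  if (npk && anyDuplicated(pk$apex_index))
    stop("duplicate peak identity in peak set", call. = FALSE)
  out <- data.frame(peak = seq_len(npk),
                    reported_mass = pk$reported_mass,
                    apex_mass = pk$apex_mass,
                    prominence = pk$prominence,
                    snr = pk$snr)
  pooled <- tapply(quant$count, quant$peak, sum)
  out$n_psms <- as.integer(pooled[as.character(out$peak)])
  out$n_psms[is.na(out$n_psms)] <- 0L
  for (e in peakset$experiments) {
    qe <- quant[quant$experiment == e, ]
    out[[paste0("count.", e)]] <- qe$count[match(out$peak, qe$peak)]
    out[[paste0("norm.", e)]] <- qe$norm_count[match(out$peak, qe$peak)]
  }
  out$annotation <- rep(NA_character_, npk)
  if (!is.null(annotations))
    out$annotation <- annotations$annotation[match(out$peak, annotations$peak)]

  .pool_mean <- function(df, value, weight) {
    # experiment-level means pooled to a per-peak mean, weighted by n
    ok <- !is.na(df[[value]]) & df[[weight]] > 0
    if (!any(ok)) return(stats::setNames(numeric(0), character(0)))
    v <- tapply(df[[value]][ok] * df[[weight]][ok], df$peak[ok], sum) /
      tapply(df[[weight]][ok], df$peak[ok], sum)
    v
  }
  out$pct_in_unmodified <- rep(NA_real_, npk)
  out$mean_similarity <- rep(NA_real_, npk)
  out$mean_delta_rt <- rep(NA_real_, npk)
  if (!is.null(comparison) && nrow(comparison)) {
    frac <- .pool_mean(comparison, "fraction_with_counterpart", "n_assigned")
    sim <- .pool_mean(comparison, "mean_similarity", "n_compared")
    drt <- .pool_mean(comparison, "mean_delta_rt", "n_compared")
    out$pct_in_unmodified <- 100 * as.numeric(frac[as.character(out$peak)])
    out$mean_similarity <- as.numeric(sim[as.character(out$peak)])
    out$mean_delta_rt <- as.numeric(drt[as.character(out$peak)])
  }
  out$nterm_rate <- rep(NA_real_, npk)
  out$top_residue <- rep(NA_character_, npk)
  out$top_enrichment <- rep(NA_real_, npk)
  out$second_residue <- rep(NA_character_, npk)
  out$second_enrichment <- rep(NA_real_, npk)
  if (!is.null(localization) && nrow(localization)) {
    nt <- .pool_mean(localization, "nterm_rate", "n_candidates")
    out$nterm_rate <- as.numeric(nt[as.character(out$peak)])
    # residue ranking from the pooled (all-experiment) enrichment
    for (p in out$peak) {
      sel <- localization$peak == p
      if (!any(sel)) next
      rc <- Reduce(`+`, localization$residue_counts[sel])
      bg <- Reduce(`+`, localization$background_counts[sel])
      if (sum(rc) == 0 || sum(bg) == 0) next
      enr <- rep(NA_real_, length(rc)); names(enr) <- names(rc)
      ok <- bg > 0
      enr[ok] <- (rc[ok] / sum(rc)) / (bg[ok] / sum(bg))
      ord <- order(-enr, na.last = TRUE)
      top <- ord[rc[ord] > 0 & !is.na(enr[ord])]
      if (length(top) >= 1) {
        out$top_residue[out$peak == p] <- names(enr)[top[1]]
        out$top_enrichment[out$peak == p] <- enr[top[1]]
      }
      if (length(top) >= 2) {
        out$second_residue[out$peak == p] <- names(enr)[top[2]]
        out$second_enrichment[out$peak == p] <- enr[top[2]]
      }
    }
  }
  out <- out[order(-out$n_psms, out$peak), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the experiment-by-peak profile matrix
#'
#' Rows are experiments, columns are peaks, cells are size-normalized
#' spectral counts; optionally column-wise z-scored (sample standard
#' deviation; constant columns map to zeros).
#'
#' @param quant Result of \code{\link{quantify_peaks}}.
#' @param zscore Standardize columns.
#' @return Numeric matrix with experiment rownames and peak colnames.
#' @export
build_experiment_matrix <- function(quant, zscore = FALSE) {
  exps <- unique(quant$experiment)
  peaks <- sort(unique(quant$peak))
  if (length(exps) == 0 || length(peaks) == 0)
    return(matrix(numeric(), max(length(exps), 0), 0,
                  dimnames = list(exps, character())))
  m <- matrix(0, length(exps), length(peaks),
              dimnames = list(exps, paste0("peak", peaks)))
  m[cbind(match(quant$experiment, exps), match(quant$peak, peaks))] <-
    quant$norm_count
  if (zscore) {
    z <- apply(m, 2, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s == 0) rep(0, length(col))
      else (col - mean(col)) / s
    })
    m <- matrix(z, nrow = length(exps),
                dimnames = list(exps, paste0("peak", peaks)))
  }
  m
}

.fmt <- function(x, digits) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write the deterministic TSV reports
#'
#' Writes \code{global.profile.tsv}, \code{peaks.tsv}, \code{localization.tsv},
#' \code{similarity.tsv} and \code{experiment.matrix.tsv} with fixed float
#' precision (masses 4 dp; rates, similarities and enrichments 2 dp), so
#' identical inputs and seed yield byte-identical files.
#'
#' @param profile An object of class \code{shift_profile} (see
#'   \code{\link{shift_profile}}).
#' @param dir Output directory (created if absent).
#' @return Character vector of file paths, invisibly.
#' @export
write_reports <- function(profile, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- profile$global
  g <- data.frame(mass = .fmt(gp$reported_mass, 4))
  for (e in profile$peakset$experiments) {
    g[[paste0("count_", e)]] <- gp[[paste0("count.", e)]]
    g[[paste0("norm_", e)]] <- .fmt(gp[[paste0("norm.", e)]], 6)
  }
  g$psms <- gp$n_psms
  g$annotation <- ifelse(is.na(gp$annotation), "", gp$annotation)
  g$pct_in_unmodified <- .fmt(gp$pct_in_unmodified, 2)
  g$similarity <- .fmt(gp$mean_similarity, 2)
  g$delta_rt <- .fmt(gp$mean_delta_rt, 2)
  g$nterm_rate <- .fmt(100 * gp$nterm_rate, 2)
  g$AA_1 <- ifelse(is.na(gp$top_residue), "",
                   paste0(gp$top_residue, " (", .fmt(gp$top_enrichment, 2), ")"))
  g$AA_2 <- ifelse(is.na(gp$second_residue), "",
                   paste0(gp$second_residue, " (", .fmt(gp$second_enrichment, 2), ")"))
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(g, "global.profile.tsv")

  pk <- profile$peakset$peaks
  pt <- data.frame(mass = .fmt(pk$reported_mass, 4),
                   apex = .fmt(pk$apex_mass, 4),
                   prominence = .fmt(pk$prominence, 4),
                   snr = .fmt(pk$snr, 4),
                   left_bound = .fmt(pk$left_bound, 4),
                   right_bound = .fmt(pk$right_bound, 4),
                   psms = if (nrow(pk)) pk$n_psms else integer())
  w(pt, "peaks.tsv")

  loc <- profile$localization
  lt <- if (!is.null(loc) && nrow(loc)) data.frame(
    mass = .fmt(pk$reported_mass[loc$peak], 4),
    experiment = loc$experiment,
    localized_fraction = .fmt(loc$localized_fraction, 2),
    nterm_rate = .fmt(100 * loc$nterm_rate, 2),
    AA_1 = ifelse(is.na(loc$top_residue), "",
                  paste0(loc$top_residue, " (", .fmt(loc$top_enrichment, 2), ")")),
    AA_2 = ifelse(is.na(loc$second_residue), "",
                  paste0(loc$second_residue, " (", .fmt(loc$second_enrichment, 2), ")")))
  else data.frame(mass = character(), experiment = character(),
                  localized_fraction = character(), nterm_rate = character(),
                  AA_1 = character(), AA_2 = character())
  w(lt, "localization.tsv")

  cm <- profile$comparison
  st <- if (!is.null(cm) && nrow(cm)) data.frame(
    mass = .fmt(pk$reported_mass[cm$peak], 4),
    experiment = cm$experiment,
    similarity = .fmt(cm$mean_similarity, 2),
    delta_rt = .fmt(cm$mean_delta_rt, 2),
    n_compared = cm$n_compared,
    pct_in_unmodified = .fmt(100 * cm$fraction_with_counterpart, 2))
  else data.frame(mass = character(), experiment = character(),
                  similarity = character(), delta_rt = character(),
                  n_compared = integer(), pct_in_unmodified = character())
  w(st, "similarity.tsv")

  em <- build_experiment_matrix(profile$quant, zscore = TRUE)
  emd <- data.frame(experiment = rownames(em))
  for (j in seq_len(ncol(em))) {
    nm <- .fmt(pk$reported_mass[as.integer(sub("peak", "", colnames(em)[j]))], 4)
    emd[[nm]] <- .fmt(em[, j], 4)
  }
  w(emd, "experiment.matrix.tsv")
  invisible(paths)
}
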