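# Mass-shift annotation: staged decomposition of peak masses into at most two
# known modification masses (catalogue entries, residue insertions/deletions,
# isotopic-error spacings, user-defined shifts).

#' Load the modification entry table
#'
#' Reads a TSV catalogue (columns \code{name}, \code{mass}, \code{source})
#' and augments it with single-residue insertion/deletion entries for all 20
#' amino acids, isotopic-error entries at +/- 1 and 2 times
#' \code{isotope_spacing}, user-defined shifts, and signed "misattributed"
#' counterparts for searched variable modifications (a variable modification
#' assigned during search but actually absent appears as its negative mass in
#' the shift).
#'
#' @param path Catalogue TSV; defaults to the table shipped with the package.
#' @param user_shifts Optional data.frame with columns \code{name},
#'   \code{mass}: user-defined shifts (source \code{"user"}).
#' @param variable_mods Character vector of catalogue entry names searched as
#'   variable modifications; each gains a negative-mass counterpart.
#' @param exclude Character vector of entry names to drop (rare or
#'   protocol-specific entries that confound annotation).
#' @param isotope_spacing Da spacing for isotopic-error entries.
#' @return data.frame with columns \code{name}, \code{mass}, \code{source};
#'   unique on (name, source).
#' @export
load_modification_table <- function(path = system.file("extdata", "modifications.tsv",
                                                       package = "massshiftr"),
                                    user_shifts = NULL,
                                    variable_mods = "Oxidation",
                                    exclude = character(),
                                    isotope_spacing = 1.00235) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("name", "mass") %in% names(tab)))
    stop("modification table needs 'name' and 'mass' columns", call. = FALSE)
  if (is.null(tab$source)) tab$source <- "unimod"
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$mass))))
  if (length(bad))
    stop("malformed modification table row ", bad[1], call. = FALSE)
  tab$mass <- as.numeric(tab$mass)
  tab <- tab[, c("name", "mass", "source")]

  aa3 <- names(AA_MONO)
  ins <- data.frame(name = paste("Addition of", aa3), mass = unname(AA_MONO),
                    source = "residue_insertion")
  del <- data.frame(name = paste("Deletion of", aa3), mass = -unname(AA_MONO),
                    source = "residue_deletion")
  iso <- data.frame(
    name = c("+1 isotopic error", "+2 isotopic error",
             "-1 isotopic error", "-2 isotopic error"),
    mass = c(1, 2, -1, -2) * isotope_spacing,
    source = "isotope")
  mis <- tab[tab$name %in% variable_mods, , drop = FALSE]
  if (nrow(mis)) {
    mis$name <- paste("Misattributed", mis$name)
    mis$mass <- -mis$mass
  }
  usr <- NULL
  if (!is.null(user_shifts) && nrow(user_shifts)) {
    usr <- data.frame(name = as.character(user_shifts$name),
                      mass = as.numeric(user_shifts$mass), source = "user")
  }
  all <- rbind(tab, mis, ins, del, iso, usr)
  all <- all[!all$name %in% exclude, , drop = FALSE]
  all <- all[!duplicated(all[, c("name", "source")]), , drop = FALSE]
  rownames(all) <- NULL
  all
}

# Rank candidate annotations: user-containing first (when prioritized), then
# smaller |residual|, then fewer components, then first-listed. `cands` is a
# data.frame with columns residual, n_comp, has_user; returns the best index.
.best_candidate <- function(cands, prioritize_user) {
  key <- order(if (prioritize_user) !cands$has_user else rep(FALSE, nrow(cands)),
               abs(cands$residual), cands$n_comp, seq_len(nrow(cands)))
  key[1]
}

#' Annotate peaks by staged mass decomposition
#'
#' Peaks are processed in descending SNR order. For each peak mass m:
#' \enumerate{
#'   \item \emph{single}: the best catalogue entry within
#'     \code{annotation_tol} of m;
#'   \item \emph{user_combo}: the best pair (user-defined shift + any entry)
#'     whose masses sum to within tolerance of m;
#'   \item \emph{pair_combo}: the best pair drawn (with replacement) from the
#'     pool of entries already used in completed single annotations of this
#'     run, plus the masses of peaks so far left unannotated.
#' }
#' A peak failing all three stages is marked unannotated and its mass joins
#' the candidate component pool for later peaks. When
#' \code{prioritize_user_mods} is set, any candidate containing a user entry
#' outranks any that does not; remaining ties go to the smaller absolute
#' residual, then to fewer components.
#'
#' @param peakset A \code{peak_set} (peaks already in SNR order), or a
#'   numeric vector of peak masses in processing order.
#' @param entries Modification entry table from
#'   \code{\link{load_modification_table}}.
#' @param config A \code{\link{shift_config}}.
#' @return data.frame, one row per peak: \code{peak}, \code{mass},
#'   \code{stage} (\code{single}, \code{user_combo}, \code{pair_combo},
#'   \code{unannotated}), \code{annotation} (component names joined by
#'   \code{" + "}), \code{residual}, \code{n_components}; plus a list column
#'   \code{components} of per-peak data.frames (\code{name}, \code{mass}).
#' @export
annotate_peaks <- function(peakset, entries, config = shift_config()) {
  masses <- if (inherits(peakset, "peak_set")) peakset$peaks$reported_mass
            else as.numeric(peakset)
  tol <- config$annotation_tol
  prio <- config$prioritize_user_mods
  is_user <- entries$source == "user"
  pool <- entries[0, ]  # entries used in completed single annotations, in order

  res <- vector("list", length(masses))
  for (p in seq_along(masses)) {
    m <- masses[p]
    ann <- NULL

    # stage 1: single entry
    d <- m - entries$mass
    hit <- which(abs(d) <= tol)
    if (length(hit)) {
      cands <- data.frame(residual = d[hit], n_comp = 1L, has_user = is_user[hit])
      b <- hit[.best_candidate(cands, prio)]
      ann <- list(stage = "single", comp = entries[b, c("name", "mass")],
                  residual = d[b])
      if (!entries$name[b] %in% pool$name) pool <- rbind(pool, entries[b, ])
    }

    # stage 2: user entry + any entry
    if (is.null(ann) && any(is_user)) {
      ui <- which(is_user)
      best <- NULL
      for (u in ui) {
        need <- m - entries$mass[u]
        d2 <- need - entries$mass
        hit2 <- which(abs(d2) <= tol)
        for (e in hit2) {
          r <- d2[e]
          if (is.null(best) || abs(r) < abs(best$residual)) {
            best <- list(stage = "user_combo",
                         comp = rbind(entries[u, c("name", "mass")],
                                      entries[e, c("name", "mass")]),
                         residual = r)
          }
        }
      }
      ann <- best
    }

    # stage 3: pair from the used/unannotated pool
    if (is.null(ann) && nrow(pool) >= 1) {
      pm <- pool$mass
      ord <- order(pm)
      pms <- pm[ord]
      best <- NULL
      for (a in seq_along(pm)) {
        need <- m - pm[a]
        loi <- findInterval(need - tol, pms) + 1L
        hii <- findInterval(need + tol, pms)
        if (loi > hii) next
        for (bi in loi:hii) {
          b <- ord[bi]
          r <- need - pm[b]
          has_u <- any(pool$source[c(a, b)] == "user")
          better <- is.null(best) ||
            (prio && has_u && !best$has_user) ||
            ((has_u == best$has_user || !prio) && abs(r) < abs(best$residual))
          if (better) {
            best <- list(stage = "pair_combo",
                         comp = pool[c(a, b), c("name", "mass")],
                         residual = r, has_user = has_u)
          }
        }
      }
      if (!is.null(best)) ann <- best[c("stage", "comp", "residual")]
    }

    if (is.null(ann)) {
      pseudo <- data.frame(name = sprintf("unannotated %.4f", m), mass = m,
                           source = "unannotated")
      pool <- rbind(pool, pseudo)
      res[[p]] <- list(stage = "unannotated",
                       comp = data.frame(name = character(), mass = numeric()),
                       residual = NA_real_)
    } else res[[p]] <- ann
  }

  out <- data.frame(
    peak = seq_along(masses),
    mass = masses,
    stage = vapply(res, `[[`, character(1), "stage"),
    annotation = vapply(res, function(r)
      if (nrow(r$comp)) paste(r$comp$name, collapse = " + ") else "unannotated",
      character(1)),
    residual = vapply(res, `[[`, numeric(1), "residual"),
    n_components = vapply(res, function(r) nrow(r$comp), integer(1)),
    stringsAsFactors = FALSE
  )
  out$components <- lapply(res, function(r) { rownames(r$comp) <- NULL; r$comp })
  out
}
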