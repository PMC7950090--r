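# Synthetic fixture generation: tryptic-like peptides, theoretical b/y
# spectra with noise, implanted mass shifts at known residues with known
# per-experiment frequencies and RT offsets, plus a ground-truth manifest.

#' Default implanted-shift table for synthetic fixtures
#'
#' Eight mass shifts with residue targets and retention-time offsets loosely
#' mirroring the modification landscape of labelled quality-control samples:
#' oxidation enriched on Pro (hydroxyproline-like), TMT overlabelling and
#' formylation on Ser, deamidation on Asn, pre-elution dehydration and
#' ammonia loss (+450 s RT offsets), phosphorylation on Ser, and the
#' failed-alkylation + trioxidation composite on Cys.
#'
#' @return data.frame with columns \code{mass}, \code{name}, \code{residue},
#'   \code{frequency}, \code{rt_offset}, \code{site_fidelity}.
#' @export
fixture_shifts <- function() {
  data.frame(
    mass = c(15.994915, 229.162932, 0.984016, -18.010565,
             27.994915, 79.966331, -17.026549, -9.036800),
    name = c("oxidation", "tmt_overlabel", "deamidation", "dehydration",
             "formylation", "phosphorylation", "ammonia_loss",
             "failed_alkylation_trioxidation"),
    residue = c("P", "S", "N", "E", "S", "S", "Q", "C"),
    frequency = c(0.050, 0.045, 0.040, 0.035, 0.030, 0.025, 0.020, 0.015),
    rt_offset = c(-30, -70, 36, 450, 65, 50, 450, 60),
    site_fidelity = rep(0.9, 8),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic dataset
#'
#' @param n_experiments Number of experiments.
#' @param n_psms PSMs per experiment.
#' @param n_peptides Size of the shared peptide pool (unmodified counterparts
#'   require peptides to recur).
#' @param peptide_length Length range \code{c(min, max)}.
#' @param shifts Implanted-shift table (see \code{\link{fixture_shifts}});
#'   frequencies must sum to < 1, the remainder is unmodified.
#' @param noise_peaks Uniform random noise peaks added per spectrum.
#' @param mass_error_sd Gaussian measurement error on delta masses (Da).
#' @param rt_sigma Gaussian RT noise (seconds).
#' @param rt_range Base elution window (seconds).
#' @param charges Precursor charges sampled per PSM.
#' @param intensity_meanlog,intensity_sdlog Log-normal fragment intensity
#'   model.
#' @param rng_seed Integer seed; fixes the dataset completely.
#' @return Object of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(n_experiments = 3, n_psms = 2000, n_peptides = 150,
                         peptide_length = c(7, 16), shifts = fixture_shifts(),
                         noise_peaks = 6, mass_error_sd = 5e-4,
                         rt_sigma = 10, rt_range = c(300, 3300),
                         charges = c(2, 3),
                         intensity_meanlog = log(100), intensity_sdlog = 0.6,
                         rng_seed = 7L) {
  stopifnot(n_experiments >= 1, n_psms >= 1, n_peptides >= 1,
            length(peptide_length) == 2, peptide_length[1] >= 2,
            all(shifts$frequency >= 0), all(shifts$frequency <= 1),
            sum(shifts$frequency) < 1,
            all(shifts$site_fidelity >= 0 & shifts$site_fidelity <= 1),
            noise_peaks >= 0, mass_error_sd >= 0, rt_sigma >= 0)
  structure(list(n_experiments = n_experiments, n_psms = n_psms,
                 n_peptides = n_peptides, peptide_length = peptide_length,
                 shifts = shifts, noise_peaks = noise_peaks,
                 mass_error_sd = mass_error_sd, rt_sigma = rt_sigma,
                 rt_range = rt_range, charges = charges,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

#' Generate a synthetic fragmentation spectrum for one peptide
#'
#' The spectrum contains all singly charged b/y ions of the peptide with the
#' shift applied at \code{site} (none when \code{site} is NA), log-normal
#' intensities, plus uniform random noise peaks.
#'
#' @param peptide Peptide string.
#' @param shift_mass Mass shift (Da).
#' @param site Shift position or NA.
#' @param noise_peaks Number of noise peaks.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters.
#' @param base_intensity Optional per-fragment base intensities (length
#'   \code{2*(L-1)}); replicate spectra of a peptide share these, modelling
#'   fragment intensity as a peptide property.
#' @param intensity_jitter Log-sd of the per-spectrum multiplicative jitter
#'   applied to \code{base_intensity}.
#' @return Spectrum (sorted \code{mz}, \code{intensity}).
#' @export
generate_peptide_spectrum <- function(peptide, shift_mass = 0, site = NA,
                                      noise_peaks = 0,
                                      intensity_meanlog = log(100),
                                      intensity_sdlog = 0.6,
                                      base_intensity = NULL,
                                      intensity_jitter = 0.1) {
  fr <- theoretical_fragments(peptide, NULL, shift_mass, site)
  nf <- nrow(fr)
  mz <- fr$mz
  int <- if (is.null(base_intensity))
    stats::rlnorm(nf, intensity_meanlog, intensity_sdlog)
  else base_intensity * stats::rlnorm(nf, 0, intensity_jitter)
  if (noise_peaks > 0) {
    hi <- if (nf) max(mz) + 50 else 1500
    mz <- c(mz, stats::runif(noise_peaks, 100, hi))
    int <- c(int, stats::rlnorm(noise_peaks, intensity_meanlog - log(5),
                                intensity_sdlog))
  }
  o <- order(mz)
  list(mz = mz[o], intensity = int[o])
}

.random_peptides <- function(n, len_range) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  vapply(lens, function(L) {
    body <- sample(names(AA_MONO), L - 1L, replace = TRUE)
    paste(c(body, sample(c("K", "R"), 1)), collapse = "")
  }, character(1))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Emits per-experiment PSM tables and spectra consumable by
#' \code{\link{read_psm_table}} / \code{\link{read_spectra}}, together with a
#' row-for-row truth manifest. Delta masses in the PSM tables are the true
#' shift plus Gaussian measurement error; retention times are a per-peptide
#' base elution plus the shift's RT offset plus noise.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param dir Optional directory; when given, writes
#'   \code{psm_<experiment>.tsv} and one spectrum file per experiment and
#'   records the paths.
#' @param spectrum_format \code{"mgf"} (default) or \code{"mzml"} when
#'   writing files.
#' @return List with \code{psm_tables} (list of data.frames),
#'   \code{spectra} (named list), \code{manifest} (data.frame with
#'   \code{experiment}, \code{spectrum_id}, \code{peptide}, \code{charge},
#'   \code{true_shift}, \code{shift_name}, \code{true_site},
#'   \code{rt_offset}), \code{expected_counts} (per shift and experiment),
#'   \code{spec}, and \code{files} when \code{dir} was given.
#' @export
generate_dataset <- function(spec = fixture_spec(), dir = NULL,
                             spectrum_format = c("mgf", "mzml")) {
  spectrum_format <- match.arg(spectrum_format)
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$rng_seed)

  pool <- .random_peptides(spec$n_peptides, spec$peptide_length)
  base_rt <- stats::runif(spec$n_peptides, spec$rt_range[1], spec$rt_range[2])
  # fragment intensity is a property of the peptide: replicate spectra agree
  pool_int <- lapply(pool, function(p)
    stats::rlnorm(2L * (nchar(p) - 1L), spec$intensity_meanlog,
                  spec$intensity_sdlog))
  sh <- spec$shifts
  probs <- c(1 - sum(sh$frequency), sh$frequency)  # class 0 = unmodified

  tables <- list(); spectra <- list(); manifest <- list()
  for (e in seq_len(spec$n_experiments)) {
    lab <- sprintf("exp%02d", e)
    cls <- sample(0:nrow(sh), spec$n_psms, replace = TRUE, prob = probs)
    rows <- vector("list", spec$n_psms)
    for (i in seq_len(spec$n_psms)) {
      k <- cls[i]
      if (k == 0) {
        pi <- sample.int(spec$n_peptides, 1)
        site <- NA_integer_; shift <- 0; off <- 0; sname <- "none"
      } else {
        target <- sh$residue[k]
        repeat {
          pi <- sample.int(spec$n_peptides, 1)
          if (is.na(target) || grepl(target, pool[pi], fixed = TRUE)) break
        }
        aa <- strsplit(pool[pi], "")[[1]]
        hits <- if (is.na(target)) seq_along(aa) else which(aa == target)
        on_target <- stats::runif(1) < sh$site_fidelity[k]
        site <- if (on_target || length(hits) == length(aa))
          hits[sample.int(length(hits), 1)]
        else {
          others <- setdiff(seq_along(aa), hits)
          others[sample.int(length(others), 1)]
        }
        shift <- sh$mass[k]; off <- sh$rt_offset[k]; sname <- sh$name[k]
      }
      sid <- sprintf("%s.%d", lab, i)  # run.scan convention (mzML compatible)
      spectra[[sid]] <- generate_peptide_spectrum(
        pool[pi], shift, site, spec$noise_peaks,
        spec$intensity_meanlog, spec$intensity_sdlog,
        base_intensity = pool_int[[pi]])
      rows[[i]] <- data.frame(
        spectrum_id = sid, peptide = pool[pi],
        delta_mass = shift + stats::rnorm(1, 0, spec$mass_error_sd),
        retention_time = base_rt[pi] + off + stats::rnorm(1, 0, spec$rt_sigma),
        charge = sample(spec$charges, 1),
        true_shift = shift, shift_name = sname, true_site = site,
        rt_offset = off, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    tab <- data.frame(spectrum_id = df$spectrum_id, experiment = lab,
                      peptide = df$peptide, delta_mass = df$delta_mass,
                      retention_time = df$retention_time, charge = df$charge,
                      proteins = "synthetic", mods = "",
                      stringsAsFactors = FALSE)
    attr(tab, "experiment") <- lab
    tables[[lab]] <- tab
    df$experiment <- lab
    manifest[[lab]] <- df[, c("experiment", "spectrum_id", "peptide", "charge",
                              "true_shift", "shift_name", "true_site", "rt_offset")]
  }
  manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
  expected <- as.data.frame(table(manifest$shift_name, manifest$experiment),
                            stringsAsFactors = FALSE)
  names(expected) <- c("shift_name", "experiment", "count")

  out <- list(psm_tables = tables, spectra = spectra, manifest = manifest,
              expected_counts = expected, spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character()
    for (lab in names(tables)) {
      tp <- file.path(dir, paste0("psm_", lab, ".tsv"))
      t <- tables[[lab]]
      utils::write.table(
        data.frame(Spectrum = t$spectrum_id, Peptide = t$peptide,
                   `Delta Mass` = sprintf("%.6f", t$delta_mass),
                   Retention = sprintf("%.3f", t$retention_time),
                   Charge = t$charge, Protein = t$proteins,
                   `Assigned Modifications` = t$mods, check.names = FALSE),
        tp, sep = "\t", quote = FALSE, row.names = FALSE)
      sp <- spectra[startsWith(names(spectra), paste0(lab, "."))]
      spp <- file.path(dir, paste0(lab, if (spectrum_format == "mgf") ".mgf"
                                        else ".mzML"))
      if (spectrum_format == "mgf") write_mgf(sp, spp) else write_mzml(sp, spp)
      files <- c(files, tp, spp)
    }
    mp <- file.path(dir, "truth_manifest.tsv")
    utils::write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- c(files, mp)
  }
  out
}
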