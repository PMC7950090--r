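# PSM table and spectrum I/O plus experiment assembly.
#
# PSMs are held as a plain data.frame (one row per PSM) rather than a list of
# record objects: every downstream stage is vectorized over rows. Applied
# search modifications are encoded per row as "pos(mass), pos(mass)".

.default_column_map <- c(
  spectrum_id = "Spectrum",
  peptide = "Peptide",
  delta_mass = "Delta Mass",
  retention_time = "Retention",
  charge = "Charge",
  proteins = "Protein",
  mods = "Assigned Modifications"
)

#' Read a PSM table
#'
#' Reads a tab-separated PSM list (one row per peptide-spectrum match) as
#' produced by an FDR-filtered open search. The default column names follow
#' the MSFragger/Philosopher PSM.tsv convention and can be overridden with
#' \code{column_map}.
#'
#' @param path Path to the TSV file.
#' @param experiment Experiment label attached to every row.
#' @param column_map Named character vector mapping internal field names
#'   (\code{spectrum_id}, \code{peptide}, \code{delta_mass},
#'   \code{retention_time}, \code{charge}, and optionally \code{proteins},
#'   \code{mods}) to column headers in the file.
#' @param rt_unit Unit of the retention-time column; \code{"s"} (default) or
#'   \code{"min"}. Values are normalized to seconds on load.
#'
#' @return A data.frame with columns \code{spectrum_id}, \code{experiment},
#'   \code{peptide}, \code{delta_mass}, \code{retention_time} (seconds),
#'   \code{charge}, \code{proteins}, \code{mods}, rows in file order.
#' @export
read_psm_table <- function(path, experiment,
                           column_map = .default_column_map,
                           rt_unit = c("s", "min")) {
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stop("PSM table not found: ", path, call. = FALSE)
  cmap <- .default_column_map
  cmap[names(column_map)] <- column_map
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  mandatory <- c("spectrum_id", "peptide", "delta_mass", "retention_time", "charge")
  for (field in mandatory) {
    if (!cmap[[field]] %in% names(tab))
      stop("PSM table '", path, "' lacks mandatory column '", cmap[[field]],
           "' (field ", field, ")", call. = FALSE)
  }
  num <- function(field) {
    raw <- tab[[cmap[[field]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & nzchar(trimws(raw)))
    if (length(bad) == 0) bad <- which(is.na(val))
    if (length(bad) > 0)
      stop("unparseable ", field, " in '", path, "' at data row ", bad[1],
           ": '", raw[bad[1]], "'", call. = FALSE)
    val
  }
  out <- data.frame(
    spectrum_id = tab[[cmap[["spectrum_id"]]]],
    experiment = rep_len(experiment, nrow(tab)),
    peptide = toupper(tab[[cmap[["peptide"]]]]),
    delta_mass = num("delta_mass"),
    retention_time = num("retention_time") * if (rt_unit == "min") 60 else 1,
    charge = as.integer(num("charge")),
    proteins = if (cmap[["proteins"]] %in% names(tab))
      tab[[cmap[["proteins"]]]] else "",
    mods = if (cmap[["mods"]] %in% names(tab)) tab[[cmap[["mods"]]]] else "",
    stringsAsFactors = FALSE
  )
  bad_pep <- grepl(sprintf("[^%s]", paste(names(AA_MONO), collapse = "")), out$peptide)
  if (any(bad_pep))
    stop("peptide with non-standard residue at data row ", which(bad_pep)[1],
         ": '", out$peptide[which(bad_pep)[1]], "'", call. = FALSE)
  if (any(out$charge < 1)) stop("charge < 1 in '", path, "'", call. = FALSE)
  if (any(!is.finite(out$delta_mass)))
    stop("non-finite delta mass in '", path, "'", call. = FALSE)
  attr(out, "experiment") <- experiment
  out
}

#' Parse an applied-modification string into positions and masses
#'
#' @param mods Character vector of strings like \code{"3(15.9949), 7(57.0215)"}.
#' @return A list (one element per input) of data.frames with columns
#'   \code{pos}, \code{mass}.
#' @export
parse_mods <- function(mods) {
  lapply(mods, function(s) {
    if (is.na(s) || !nzchar(trimws(s)))
      return(data.frame(pos = integer(), mass = numeric()))
    parts <- regmatches(s, gregexpr("(\\d+)\\(([-0-9.eE+]+)\\)", s))[[1]]
    pos <- as.integer(sub("\\(.*", "", parts))
    mass <- as.numeric(sub(".*\\(", "", sub("\\)$", "", parts)))
    data.frame(pos = pos, mass = mass)
  })
}

#' Read fragmentation spectra from MGF or mzML
#'
#' MS2 scans are exposed under stable spectrum identifiers matching the PSM
#' table convention (MGF: the \code{TITLE} line; mzML: \code{run.scan} built
#' from the file base name and scan number). Peak lists are sorted by m/z.
#'
#' @param path Path to a \code{.mgf}, \code{.mzml} or \code{.mzML} file.
#' @return A named list of spectra; each spectrum is a list with numeric
#'   vectors \code{mz} and \code{intensity}.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
    mgf = .read_mgf(path),
    mzml = .read_mzml(path),
    stop("unrecognized spectrum file extension '", ext,
         "' (expected mgf or mzML): ", path, call. = FALSE)
  )
  lapply(out, function(sp) {
    o <- order(sp$mz)
    if (any(sp$mz <= 0)) stop("non-positive m/z in spectrum", call. = FALSE)
    list(mz = sp$mz[o], intensity = sp$intensity[o])
  })
}

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF (unbalanced BEGIN/END IONS): ", path, call. = FALSE)
  out <- vector("list", length(begins))
  ids <- character(length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1):(ends[k] - 1)]
    title <- block[startsWith(block, "TITLE=")]
    ids[k] <- if (length(title)) sub("^TITLE=", "", title[1]) else
      paste0(tools::file_path_sans_ext(basename(path)), ".", k)
    pk <- block[grepl("^[0-9]", block)]
    if (length(pk)) {
      m <- do.call(rbind, strsplit(pk, "[ \t]+"))
      out[[k]] <- list(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
    } else {
      out[[k]] <- list(mz = numeric(), intensity = numeric())
    }
  }
  names(out) <- ids
  out
}

.read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package", call. = FALSE)
  run <- tools::file_path_sans_ext(basename(path))
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  keep <- which(hdr$msLevel >= 2 | is.na(hdr$msLevel))
  out <- lapply(keep, function(i) {
    m <- pk[[i]]
    list(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
  })
  scan <- hdr$acquisitionNum[keep]
  if (all(is.na(scan))) scan <- hdr$seqNum[keep]
  names(out) <- paste0(run, ".", scan)
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra Named list of spectra (\code{mz}, \code{intensity}); names
#'   become TITLE lines.
#' @param path Output path.
#' @param pepmass Optional numeric vector of precursor m/z values.
#' @param charge Optional integer vector of precursor charges.
#' @return \code{path}, invisibly.
#' @export
write_mgf <- function(spectra, path, pepmass = NULL, charge = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(spectra)) {
    sp <- spectra[[k]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", names(spectra)[k]), con)
    if (!is.null(pepmass)) writeLines(sprintf("PEPMASS=%.6f", pepmass[k]), con)
    if (!is.null(charge)) writeLines(sprintf("CHARGE=%d+", charge[k]), con)
    if (length(sp$mz))
      writeLines(sprintf("%.6f %.4f", sp$mz, sp$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Write spectra to a minimal mzML file
#'
#' Emits an uncompressed 64-bit little-endian mzML document sufficient for
#' round-tripping synthetic MS2 spectra through standard readers. Spectrum k
#' is written with scan number k, so identifiers read back as
#' \code{<basename>.<k>}.
#'
#' @inheritParams write_mgf
#' @return \code{path}, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  b64 <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8, endian = "little"))
  spectrum_xml <- function(k) {
    sp <- spectra[[k]]
    n <- length(sp$mz)
    mzb <- b64(sp$mz); inb <- b64(sp$intensity)
    paste0(
      '<spectrum index="', k - 1L, '" id="controllerType=0 controllerNumber=1 scan=',
      k, '" defaultArrayLength="', n, '">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="', nchar(mzb), '">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<binary>', mzb, '</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="', nchar(inb), '">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
      '<binary>', inb, '</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'
    )
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="massshiftr" version="0.1.0"/></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="massshiftr">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="', tools::file_path_sans_ext(basename(path)), '">',
    '<spectrumList count="', length(spectra), '" defaultDataProcessingRef="dp1">',
    paste(vapply(seq_along(spectra), spectrum_xml, character(1)), collapse = ""),
    '</spectrumList></run></mzML>'
  )
  # xml2 validates well-formedness and handles the final serialization
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}

#' Assemble PSM tables and spectra into an experiment set
#'
#' Pools per-experiment PSM tables and a spectrum store into the container the
#' pipeline consumes. PSMs whose spectrum identifier does not resolve are
#' retained for histogram construction and quantification but flagged so the
#' localization and similarity stages skip them.
#'
#' @param psm_tables A list of PSM data.frames from \code{\link{read_psm_table}},
#'   or a list of \code{c(path, label)} pairs to read.
#' @param spectra A named list of spectra, or a character vector of
#'   MGF/mzML paths to read and merge.
#' @return An object of class \code{"experiment_set"}: list with \code{psms}
#'   (pooled data.frame, logical column \code{has_spectrum} added) and
#'   \code{spectra}.
#' @export
assemble_experiment_set <- function(psm_tables, spectra = list()) {
  if (is.data.frame(psm_tables)) psm_tables <- list(psm_tables)
  tabs <- lapply(psm_tables, function(el) {
    if (is.data.frame(el)) el else read_psm_table(el[[1]], el[[2]])
  })
  labels <- vapply(tabs, function(t) {
    lab <- attr(t, "experiment")
    if (!is.null(lab)) lab
    else if (nrow(t)) t$experiment[1]
    else NA_character_
  }, character(1))
  labels[is.na(labels)] <- paste0("empty_", which(is.na(labels)))
  if (anyDuplicated(labels))
    stop("duplicate experiment label: ",
         labels[duplicated(labels)][1], call. = FALSE)
  psms <- do.call(rbind, tabs)
  if (is.null(psms) || nrow(psms) == 0)
    stop("experiment set contains no PSMs", call. = FALSE)
  if (is.character(spectra)) {
    store <- list()
    for (p in spectra) store <- c(store, read_spectra(p))
    spectra <- store
  }
  psms$has_spectrum <- psms$spectrum_id %in% names(spectra)
  n_missing <- sum(!psms$has_spectrum)
  if (n_missing > 0 && length(spectra) > 0)
    warning(n_missing, " PSM(s) reference missing spectra; excluded from ",
            "localization and similarity but kept for quantification",
            call. = FALSE)
  structure(list(psms = psms, spectra = spectra,
                 experiments = unique(c(labels, psms$experiment))),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat("Experiment set:", length(x$experiments), "experiment(s),",
      nrow(x$psms), "PSMs,", length(x$spectra), "spectra\n")
  counts <- table(factor(x$psms$experiment, levels = x$experiments))
  for (e in names(counts)) cat(sprintf("  %s: %d PSMs\n", e, counts[[e]]))
  invisible(x)
}
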