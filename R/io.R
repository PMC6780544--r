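# Peak-list I/O. The interchange format is a TSV dialect with header
# `sample_id, polarity, mz, rt_sec, intensity` (UTF-8, tab-separated, dot
# decimal); centroided mzML is read through mzR when available, and a
# minimal uncompressed mzML writer is provided for round-trip fixtures.

#' Read a centroided peak list
#'
#' @param path Path to a `.tsv` peak list (dialect columns `sample_id`,
#'   `polarity`, `mz`, `rt_sec`, `intensity`) or a centroided `.mzML` file.
#' @param format `"auto"` (by extension), `"tsv"` or `"mzml"`.
#' @param sample_id Run identifier; defaults to the file column (TSV) or the
#'   file stem (mzML).
#' @param polarity Required for mzML files that do not record polarity.
#' @return A tibble `peak_id`, `sample_id`, `polarity`, `mz`, `rt`
#'   (seconds), `intensity`.
#' @export
read_peaks <- function(path, format = c("auto", "tsv", "mzml"),
                       sample_id = NULL, polarity = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  }
  if (format == "tsv") {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("sample_id", "polarity", "mz", "rt_sec", "intensity")
    if (!all(need %in% names(tbl))) {
      rlang::abort(sprintf("peak list %s lacks dialect columns: %s", path,
                           paste(setdiff(need, names(tbl)), collapse = ", ")))
    }
    out <- tibble::tibble(
      sample_id = if (is.null(sample_id)) as.character(tbl$sample_id) else sample_id,
      polarity = as.character(tbl$polarity),
      mz = tbl$mz, rt = tbl$rt_sec, intensity = tbl$intensity
    )
    return(as_peak_table(out))
  }
  read_peaks_mzml(path, sample_id = sample_id, polarity = polarity)
}

read_peaks_mzml <- function(path, sample_id = NULL, polarity = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    rlang::abort("reading mzML requires the mzR package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hd <- mzR::header(handle)
  if (nrow(hd) == 0L) {
    return(as_peak_table(tibble::tibble(
      sample_id = character(), polarity = character(),
      mz = numeric(), rt = numeric(), intensity = numeric())))
  }
  if (any(!is.na(hd$centroided) & !hd$centroided)) {
    rlang::abort(sprintf("%s contains profile-mode spectra; centroid first", path))
  }
  if (is.null(polarity)) {
    pol <- unique(hd$polarity[!is.na(hd$polarity)])
    polarity <- if (length(pol) == 1L && pol %in% c(0, 1)) {
      c("negative", "positive")[pol + 1L]
    } else {
      rlang::abort("polarity not recorded in mzML; pass `polarity=`")
    }
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.mzml$", "", basename(path), ignore.case = TRUE)
  }
  spectra <- mzR::peaks(handle)
  if (is.matrix(spectra)) spectra <- list(spectra)
  rows <- purrr::map2(spectra, hd$retentionTime, function(sp, rt) {
    if (nrow(sp) == 0L) return(NULL)
    tibble::tibble(mz = as.numeric(sp[, 1]), rt = rt,
                   intensity = as.numeric(sp[, 2]))
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  out$sample_id <- sample_id
  out$polarity <- polarity
  as_peak_table(dplyr::relocate(out, "sample_id", "polarity"))
}

#' Write a peak list in the TSV dialect
#'
#' @param peaks Peak tibble with `sample_id`, `polarity`, `mz`, `rt`,
#'   `intensity`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path) {
  out <- tibble::tibble(
    sample_id = peaks$sample_id, polarity = peaks$polarity,
    mz = peaks$mz, rt_sec = peaks$rt, intensity = peaks$intensity
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a peak list as minimal centroided mzML
#'
#' Emits uncompressed 64-bit little-endian arrays, one MS1 spectrum per
#' distinct retention time, flagged centroided. Intended for round-trip
#' testing of [read_peaks()] and small interchange files.
#'
#' @inheritParams write_peaks_tsv
#' @return `path`, invisibly.
#' @export
write_peaks_mzml <- function(peaks, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    rlang::abort("writing mzML requires the jsonlite package (base64 encoding)")
  }
  peaks <- as_peak_table(peaks, require_one_run = TRUE)
  pol_acc <- if (peaks$polarity[1] %||% "positive" == "negative") {
    c("MS:1000129", "negative scan")
  } else {
    c("MS:1000130", "positive scan")
  }
  b64 <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8, endian = "little"))
  scans <- split(peaks[order(peaks$rt, peaks$mz), ], peaks$rt[order(peaks$rt, peaks$mz)])
  body <- vapply(seq_along(scans), function(i) {
    sp <- scans[[i]]
    mzb <- b64(sp$mz); inb <- b64(sp$intensity)
    paste0(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">', i - 1L, i, nrow(sp)),
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value=""/>', pol_acc[1], pol_acc[2]),
      '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
      sprintf('<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan></scanList>',
              sp$rt[1]),
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(mzb)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      sprintf('<binary>%s</binary></binaryDataArray>', mzb),
      sprintf('<binaryDataArray encodedLength="%d">', nchar(inb)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
      sprintf('<binary>%s</binary></binaryDataArray>', inb),
      '</binaryDataArrayList></spectrum>'
    )
  }, character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="UNIT-ONTOLOGY" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="iroapairs"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC1">\n', peaks$sample_id[1]),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">\n', length(scans)),
    paste0(body, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>\n'
  )
  writeLines(doc, path)
  invisible(path)
}
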