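# mzML input/output.
#
# Reading goes through mzR (proteowizard backend), which normalizes scan
# start times to seconds regardless of the unit declared in the file.
# Writing serializes a minimal standalone mzML 1.1.0 document with
# uncompressed 64-bit little-endian base64 arrays; files written here
# round-trip through mzR and are readable by standard mzML tooling.

#' Read a centroided mzML file into a run
#'
#' @param path Path to an mzML file with centroided MS1 (and optionally DDA
#'   MS2) scans.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param group Group label attached to the run.
#' @param strict If `TRUE` (default), profile-mode spectra and unsorted peak
#'   lists are errors; if `FALSE`, profile flags are warned about and
#'   unsorted peaks are sorted with a message.
#' @return A [ms_run()] with retention times in seconds.
#' @export
read_mzml <- function(path, sample_id = NULL, group = NA_character_,
                      strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f), add = TRUE)
  h <- mzR::header(f)
  if (!nrow(h) || !any(h$msLevel == 1L))
    stop("no MS1 scans in ", path)
  if (any(!is.na(h$centroided) & !h$centroided)) {
    msg <- paste0("profile-mode spectra in ", path,
                  "; only centroided data are supported")
    if (strict) stop(msg) else warning(msg)
  }
  pk <- mzR::peaks(f)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- vector("list", nrow(h))
  for (i in seq_len(nrow(h))) {
    m <- pk[[i]]
    spectra[[i]] <- ms_spectrum(
      ms_level = h$msLevel[i],
      rt = h$retentionTime[i],
      mz = m[, 1], intensity = m[, 2],
      precursor_mz = if (h$msLevel[i] > 1L) h$precursorMZ[i] else NA_real_,
      precursor_intensity = if (h$msLevel[i] > 1L) h$precursorIntensity[i]
                            else NA_real_,
      iso_halfwidth = if (h$msLevel[i] > 1L &&
                          !is.null(h$isolationWindowLowerOffset))
                        h$isolationWindowLowerOffset[i] else NA_real_,
      strict = strict)
  }
  o <- order(vapply(spectra, `[[`, numeric(1), "rt"))
  ms_run(sample_id, group, spectra[o])
}

.b64_doubles <- function(x) {
  gsub("[\r\n]", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8L,
                                                   endian = "little")))
}

.mzml_binary_array <- function(x, kind = c("mz", "intensity")) {
  kind <- match.arg(kind)
  b <- .b64_doubles(x)
  arr <- if (kind == "mz")
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>'
  sprintf(paste0(
    '<binaryDataArray encodedLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '%s<binary>%s</binary></binaryDataArray>'), nchar(b), arr, b)
}

.mzml_spectrum <- function(s, index, rt_unit) {
  rt <- if (rt_unit == "minute") s$rt / 60 else s$rt
  unit <- if (rt_unit == "minute")
    'unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"'
  else
    'unitCvRef="UO" unitAccession="UO:0000010" unitName="second"'
  prec <- ""
  if (s$ms_level == 2L) {
    hw <- if (is.na(s$iso_halfwidth)) 0.5 else s$iso_halfwidth
    pint <- if (is.na(s$precursor_intensity)) 0 else s$precursor_intensity
    prec <- sprintf(paste0(
      '<precursorList count="1"><precursor><isolationWindow>',
      '<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.8f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="%.4f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="%.4f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '</isolationWindow><selectedIonList count="1"><selectedIon>',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.8f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<cvParam cvRef="MS" accession="MS:1000042" name="peak intensity" value="%.4f" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
      '</selectedIon></selectedIonList><activation>',
      '<cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/>',
      '</activation></precursor></precursorList>'),
      s$precursor_mz, hw, hw, s$precursor_mz, pint)
  }
  sprintf(paste0(
    '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.10f" %s/></scan></scanList>',
    '%s<binaryDataArrayList count="2">%s%s</binaryDataArrayList></spectrum>'),
    index, index + 1L, length(s$mz), s$ms_level, rt, unit, prec,
    .mzml_binary_array(s$mz, "mz"), .mzml_binary_array(s$intensity, "intensity"))
}

#' Write a run to a standalone mzML file
#'
#' @param run A [ms_run()].
#' @param path Output path.
#' @param rt_unit Unit used to declare scan start times in the file
#'   (`"second"`, the default, or `"minute"`); the stored values are
#'   converted so that any conforming reader recovers the same seconds.
#' @return `path`, invisibly. Output is byte-identical for identical runs.
#' @export
write_mzml <- function(run, path, rt_unit = c("second", "minute")) {
  stopifnot(inherits(run, "ms_run"))
  rt_unit <- match.arg(rt_unit)
  n <- length(run$spectra)
  specs <- vapply(seq_len(n), function(i)
    .mzml_spectrum(run$spectra[[i]], i - 1L, rt_unit), character(1))
  header <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="dnadduct"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="', run$sample_id, '" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="', n, '" defaultDataProcessingRef="dp1">\n')
  con <- file(path, open = "wb")  # binary mode: newline-stable across platforms
  on.exit(close(con), add = TRUE)
  writeLines(c(header, specs, '</spectrumList>\n</run>\n</mzML>'), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}
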