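# In-memory model of an LC-MS acquisition: a Run is an ordered list of
# centroided Spectrum objects (MS1 and DDA MS2). Retention times are stored
# in seconds throughout; user-facing reports print minutes.

#' Construct a centroided spectrum
#'
#' @param ms_level 1 or 2.
#' @param rt Retention time in seconds (>= 0).
#' @param mz,intensity Numeric peak vectors; `mz` ascending, intensities >= 0.
#' @param precursor_mz,precursor_intensity MS2 precursor metadata (`NA` for MS1).
#' @param iso_halfwidth Isolation window half-width in Da (MS2 only).
#' @param strict If `TRUE` (default) unsorted peak lists are an error; if
#'   `FALSE` they are sorted with a message.
#' @return A `ms_spectrum` object.
#' @export
ms_spectrum <- function(ms_level, rt, mz, intensity,
                        precursor_mz = NA_real_,
                        precursor_intensity = NA_real_,
                        iso_halfwidth = NA_real_,
                        strict = TRUE) {
  stopifnot(ms_level %in% c(1L, 2L), rt >= 0, length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative intensities")
  if (is.unsorted(mz)) {
    if (strict) stop("peak m/z values are not sorted ascending")
    message("sorting unsorted peak list (lenient mode)")
    o <- order(mz); mz <- mz[o]; intensity <- intensity[o]
  }
  structure(list(
    ms_level = as.integer(ms_level), rt = as.numeric(rt),
    mz = as.numeric(mz), intensity = as.numeric(intensity),
    precursor_mz = as.numeric(precursor_mz),
    precursor_intensity = as.numeric(precursor_intensity),
    iso_halfwidth = as.numeric(iso_halfwidth)
  ), class = "ms_spectrum")
}

#' Construct an LC-MS run
#'
#' @param sample_id Sample identifier.
#' @param group Group label (e.g. `"treated"` / `"control"`).
#' @param spectra List of [ms_spectrum()] objects ordered by retention time.
#' @return A `ms_run` object.
#' @export
ms_run <- function(sample_id, group, spectra) {
  stopifnot(is.list(spectra))
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (is.unsorted(rts)) stop("spectra are not ordered by retention time")
  structure(list(sample_id = sample_id, group = group, spectra = spectra),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat("<ms_run> ", x$sample_id, " [", x$group, "]: ",
      sum(lv == 1L), " MS1 + ", sum(lv == 2L), " MS2 scans\n", sep = "")
  invisible(x)
}

#' Extract the MS1 (or MS2) scans of a run
#'
#' @param run A [ms_run()].
#' @param level MS level to keep.
#' @return List of `ms_spectrum` objects.
#' @export
ms_scans <- function(run, level = 1L) {
  stopifnot(inherits(run, "ms_run"))
  Filter(function(s) s$ms_level == level, run$spectra)
}
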