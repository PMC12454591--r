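# DNA-adduct verification: diagnostic-fragment filtering of DDA MS2
# spectra, deoxyribose neutral-loss detection, in-source fragment pairing
# by retention-time match and EIC correlation, and annotation against an
# adduct hypothesis space.

# monoisotopic mass of the deoxyribose remainder C5H8O3 (116.0473 Da)
.dr_loss_mass <- function() monoisotopic_mass("C5H8O3")

#' Diagnostic fragment ions of DNA adducts
#'
#' The default set covers the DNA-specific fragments used to filter
#' candidate features: the deoxyribose oxocarbenium ion (deoxyribose + H -
#' H2O), protonated guanine, adenine, deoxyguanosine and deoxyadenosine.
#' All values are computed from elemental formulas, not tabulated. The set
#' is user-extensible by `rbind`ing further rows.
#'
#' @param tol_mz Per-ion match tolerance in Da (default 0.01).
#' @return Data frame `name`, `mz`, `tol_mz`, with attribute
#'   `neutral_loss` = 116.0473 (deoxyribose remainder mass).
#' @export
diagnostic_ions <- function(tol_mz = 0.01) {
  out <- data.frame(
    name = c("deoxyribose", "guanine", "adenine", "dG", "dA"),
    mz = c(protonated_mz("C5H10O4") - monoisotopic_mass("H2O"),
           protonated_mz("C5H5N5O"),
           protonated_mz("C5H5N5"),
           protonated_mz("C10H13N5O4"),
           protonated_mz("C10H13N5O3")),
    tol_mz = tol_mz,
    stringsAsFactors = FALSE
  )
  attr(out, "neutral_loss") <- .dr_loss_mass()
  out
}

# MS2 spectra of any run matching a precursor m/z and rt window
.matching_ms2 <- function(runs, mz, rt, rt_tol, precursor_tol) {
  hits <- list()
  for (run in runs) {
    for (s in ms_scans(run, 2L)) {
      ptol <- max(precursor_tol,
                  if (is.na(s$iso_halfwidth)) 0 else s$iso_halfwidth)
      if (!is.na(s$precursor_mz) &&
          abs(s$precursor_mz - mz) <= ptol &&
          abs(s$rt - rt) <= rt_tol)
        hits[[length(hits) + 1L]] <- s
    }
  }
  hits
}

#' Filter features for diagnostic MS2 evidence
#'
#' For each feature, DDA MS2 scans whose precursor matches the feature m/z
#' (within the isolation half-width or `precursor_tol`, whichever is
#' larger) and retention time are gathered. A feature is flagged
#' `has_diagnostic_fragment` if any diagnostic ion is present above
#' `intensity_floor` of the MS2 base peak, and `has_ms2_neutral_loss` if
#' any fragment sits at precursor minus the deoxyribose remainder mass
#' (116.0473 Da) within `frag_tol`.
#'
#' @param runs A [ms_run()] or list of runs containing DDA MS2 scans.
#' @param features Data frame with columns `mz` and `rt_s` (e.g. selected
#'   rows of a feature matrix).
#' @param ions Diagnostic ion set, see [diagnostic_ions()].
#' @param frag_tol Fragment match tolerance in Da (default 0.01).
#' @param rt_tol Retention-time window around the feature in seconds
#'   (default 6).
#' @param precursor_tol Minimum precursor match tolerance in Da
#'   (default 0.5).
#' @param intensity_floor Relative intensity floor for a fragment to count,
#'   as a fraction of the MS2 base peak (default 0.01).
#' @return `features` plus columns `has_diagnostic_fragment`,
#'   `diagnostic_ion`, `has_ms2_neutral_loss`, `n_ms2`. If no run contains
#'   MS2 scans, all flags are `FALSE` and a warning is issued.
#' @export
filter_diagnostic_ms2 <- function(runs, features, ions = diagnostic_ions(),
                                  frag_tol = 0.01, rt_tol = 6,
                                  precursor_tol = 0.5,
                                  intensity_floor = 0.01) {
  if (inherits(runs, "ms_run")) runs <- list(runs)
  nl_mass <- attr(ions, "neutral_loss") %||% .dr_loss_mass()
  features$has_diagnostic_fragment <- FALSE
  features$diagnostic_ion <- NA_character_
  features$has_ms2_neutral_loss <- FALSE
  features$n_ms2 <- 0L
  if (!any(vapply(runs, function(r) length(ms_scans(r, 2L)) > 0,
                  logical(1)))) {
    warning("no MS2 scans in any run; diagnostic filtering skipped")
    return(features)
  }
  for (i in seq_len(nrow(features))) {
    hits <- .matching_ms2(runs, features$mz[i], features$rt_s[i],
                          rt_tol, precursor_tol)
    features$n_ms2[i] <- length(hits)
    for (s in hits) {
      if (!length(s$mz)) next
      floor_i <- intensity_floor * max(s$intensity)
      ok <- s$intensity >= floor_i
      frag <- s$mz[ok]
      for (j in seq_len(nrow(ions))) {
        if (any(abs(frag - ions$mz[j]) <= ions$tol_mz[j])) {
          features$has_diagnostic_fragment[i] <- TRUE
          if (is.na(features$diagnostic_ion[i]))
            features$diagnostic_ion[i] <- ions$name[j]
        }
      }
      if (any(abs(s$precursor_mz - frag - nl_mass) <= frag_tol))
        features$has_ms2_neutral_loss[i] <- TRUE
    }
  }
  features
}

#' Pair features with their in-source deoxyribose-loss fragments
#'
#' Exhaustively tests all ordered (heavy, light) feature pairs for a mass
#' difference of `delta_mass` (the deoxyribose remainder, by default),
#' matching retention times, and high Pearson correlation of their EICs in
#' a reference run (the sample with the largest heavy-feature area).
#' Co-eluting, correlated pairs indicate that the lighter feature is an
#' in-source fragment of the intact (heavier) species.
#'
#' @param features Data frame with `mz`, `rt_s` and sample area columns
#'   (e.g. a feature matrix or a selected subset of one).
#' @param runs List of [ms_run()] objects the features came from.
#' @param delta_mass Expected mass difference in Da (default 116.0473).
#' @param mass_tol Tolerance on the difference in Da (default 0.01, the
#'   verification extraction window).
#' @param rt_tol Apex retention-time tolerance in seconds (default 6).
#' @param min_corr Minimum EIC Pearson correlation (default 0.90).
#' @param eic_tol_da EIC extraction half-window in Da (default 0.01).
#' @return Data frame of pairs: `heavy`, `light` (row indices into
#'   `features`), `heavy_mz`, `light_mz`, `delta`, `rt_diff_s`, `corr`.
#' @export
pair_insource <- function(features, runs, delta_mass = NULL,
                          mass_tol = 0.01, rt_tol = 6, min_corr = 0.90,
                          eic_tol_da = 0.01) {
  if (is.null(delta_mass)) delta_mass <- .dr_loss_mass()
  if (inherits(runs, "ms_run")) runs <- list(runs)
  empty <- data.frame(heavy = integer(0), light = integer(0),
                      heavy_mz = numeric(0), light_mz = numeric(0),
                      delta = numeric(0), rt_diff_s = numeric(0),
                      corr = numeric(0))
  n <- nrow(features)
  if (n < 2L) return(empty)
  sample_ids <- vapply(runs, `[[`, character(1), "sample_id")
  areas <- .matrix_areas(features[, setdiff(names(features),
    c("has_diagnostic_fragment", "diagnostic_ion", "has_ms2_neutral_loss",
      "n_ms2")), drop = FALSE])
  flat_cache <- list()
  rows <- list()
  for (h in seq_len(n)) {
    for (l in seq_len(n)) {
      if (h == l) next
      d <- features$mz[h] - features$mz[l]
      if (abs(d - delta_mass) > mass_tol) next
      rtd <- features$rt_s[h] - features$rt_s[l]
      if (abs(rtd) > rt_tol) next
      # reference run: largest heavy-feature area among runs we have
      av <- areas[h, intersect(colnames(areas), sample_ids)]
      if (all(is.na(av))) next
      ref_id <- names(which.max(av))
      if (is.null(flat_cache[[ref_id]]))
        flat_cache[[ref_id]] <-
          .flat_ms1(runs[[match(ref_id, sample_ids)]])
      fl <- flat_cache[[ref_id]]
      eh <- .eic_from_flat(fl, features$mz[h], eic_tol_da)
      el <- .eic_from_flat(fl, features$mz[l], eic_tol_da)
      r <- suppressWarnings(stats::cor(eh$intensity, el$intensity))
      if (is.na(r) || r < min_corr) next
      rows[[length(rows) + 1L]] <- data.frame(
        heavy = h, light = l, heavy_mz = features$mz[h],
        light_mz = features$mz[l], delta = d, rt_diff_s = rtd, corr = r)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate candidate features against an adduct hypothesis space
#'
#' Each candidate m/z gets the nearest hypothesis within `tol_ppm`; ties go
#' to the smaller absolute error, then the fewer biotransformation steps.
#' Unmatched candidates keep an empty annotation but are retained, so
#' unknown adducts are still reported.
#'
#' @param candidates Data frame with an `mz` column.
#' @param hypotheses Hypothesis data frame from [enumerate_hypotheses()].
#' @param tol_ppm Annotation tolerance in ppm (default 5).
#' @return `candidates` plus `hypothesis_name`, `expected_mz`, `error_ppm`,
#'   `annotated`.
#' @export
annotate_candidates <- function(candidates, hypotheses, tol_ppm = 5) {
  n_cand <- nrow(candidates)
  candidates$hypothesis_name <- rep(NA_character_, n_cand)
  candidates$expected_mz <- rep(NA_real_, n_cand)
  candidates$error_ppm <- rep(NA_real_, n_cand)
  candidates$annotated <- rep(FALSE, n_cand)
  if (!nrow(candidates) || is.null(hypotheses) || !nrow(hypotheses))
    return(candidates)
  for (i in seq_len(nrow(candidates))) {
    err <- ppm_error(candidates$mz[i], hypotheses$expected_mz)
    ok <- which(abs(err) <= tol_ppm)
    if (!length(ok)) next
    o <- ok[order(abs(err[ok]), hypotheses$n_steps[ok])]
    best <- o[1]
    candidates$hypothesis_name[i] <- hypotheses$name[best]
    candidates$expected_mz[i] <- hypotheses$expected_mz[best]
    candidates$error_ppm[i] <- err[best]
    candidates$annotated[i] <- TRUE
  }
  candidates
}

#' Run the full adduct screen on a treated-versus-control study
#'
#' Composes the pipeline: feature assembly, volcano selection, diagnostic
#' MS2 filtering, in-source pairing and hypothesis annotation. Candidates
#' are ranked by verification evidence count (diagnostic fragment, MS2
#' neutral loss, in-source partner), then ascending p-value, then
#' descending area. Evidence is never mandatory: a volcano-only candidate
#' is reported with a rank penalty, and only the heavier member of an
#' in-source pair is treated as the intact species for annotation.
#'
#' @param runs List of [ms_run()] objects with group labels.
#' @param group_a,group_b Control and treated group labels.
#' @param hypotheses Optional hypothesis data frame from
#'   [enumerate_hypotheses()].
#' @param tol_ppm Mass tolerance in ppm (default 5).
#' @param rt_tol Retention-time tolerance in seconds (default 6).
#' @param fc_thresh,alpha,impute_floor_frac,adjust Volcano parameters, see
#'   [volcano()].
#' @param min_corr Minimum EIC correlation for in-source pairing
#'   (default 0.90).
#' @param min_snr,min_points Peak detection parameters.
#' @return An `adduct_report` list: `candidates` (ranked data frame),
#'   `features` (full matrix), `volcano`, `pairs`, `params`.
#' @export
screen_study <- function(runs, group_a = "control", group_b = "treated",
                         hypotheses = NULL, tol_ppm = 5, rt_tol = 6,
                         fc_thresh = 2, alpha = 0.05,
                         impute_floor_frac = 0.2, adjust = FALSE,
                         min_corr = 0.90, min_snr = 3, min_points = 3L) {
  mat <- assemble_features(runs, tol_ppm = tol_ppm, rt_tol = rt_tol,
                           min_snr = min_snr, min_points = min_points)
  vol <- volcano(mat, group_a, group_b, fc_thresh = fc_thresh,
                 alpha = alpha, impute_floor_frac = impute_floor_frac,
                 adjust = adjust)
  sel <- which(vol$selected & vol$log2fc > 0)  # treatment-elevated
  params <- list(group_a = group_a, group_b = group_b, tol_ppm = tol_ppm,
                 rt_tol = rt_tol, fc_thresh = fc_thresh, alpha = alpha,
                 impute_floor_frac = impute_floor_frac, adjust = adjust,
                 min_corr = min_corr, min_snr = min_snr,
                 min_points = min_points)
  if (!length(sel)) {
    cand <- cbind(mat[integer(0), c("mz", "rt_s")],
                  data.frame(log2fc = numeric(0), p = numeric(0),
                             area = numeric(0),
                             has_diagnostic_fragment = logical(0),
                             diagnostic_ion = character(0),
                             has_ms2_neutral_loss = logical(0),
                             partner_mz = numeric(0),
                             partner_corr = numeric(0),
                             evidence = integer(0), rank = integer(0)))
    cand <- annotate_candidates(cand, hypotheses, tol_ppm)
    return(structure(list(candidates = cand, features = mat, volcano = vol,
                          pairs = NULL, params = params),
                     class = "adduct_report"))
  }
  cand <- mat[sel, , drop = FALSE]
  treated <- Filter(function(r) r$group == group_b, runs)
  cand <- filter_diagnostic_ms2(if (length(treated)) treated else runs,
                                cand, rt_tol = rt_tol)
  pairs <- pair_insource(cand, runs, rt_tol = rt_tol, min_corr = min_corr)
  cand$partner_mz <- NA_real_
  cand$partner_corr <- NA_real_
  cand$is_insource_fragment <- FALSE
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      h <- pairs$heavy[k]; l <- pairs$light[k]
      cand$partner_mz[h] <- pairs$light_mz[k]
      cand$partner_corr[h] <- pairs$corr[k]
      cand$partner_mz[l] <- pairs$heavy_mz[k]
      cand$partner_corr[l] <- pairs$corr[k]
      cand$is_insource_fragment[l] <- TRUE
    }
  }
  cand <- annotate_candidates(cand, hypotheses, tol_ppm)
  # the lighter member of a pair is the in-source fragment, not an intact
  # adduct: it keeps its pair evidence but no annotation
  if (any(cand$is_insource_fragment)) {
    frag <- cand$is_insource_fragment
    cand$hypothesis_name[frag] <- NA_character_
    cand$expected_mz[frag] <- NA_real_
    cand$error_ppm[frag] <- NA_real_
    cand$annotated[frag] <- FALSE
  }
  area_cols <- intersect(colnames(.matrix_areas(mat)), names(cand))
  cand$area <- rowMeans(as.matrix(cand[, area_cols, drop = FALSE]),
                        na.rm = TRUE)
  cand$log2fc <- vol$log2fc[sel]
  cand$p <- vol$p[sel]
  cand$evidence <- cand$has_diagnostic_fragment +
    cand$has_ms2_neutral_loss + !is.na(cand$partner_mz)
  o <- order(-cand$evidence, cand$p, -cand$area)
  cand <- cand[o, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  structure(list(candidates = cand, features = mat, volcano = vol,
                 pairs = pairs, params = params),
            class = "adduct_report")
}

#' @export
print.adduct_report <- function(x, ...) {
  cat("<adduct_report> ", nrow(x$features), " features, ",
      nrow(x$candidates), " candidates\n", sep = "")
  if (nrow(x$candidates)) {
    cols <- intersect(c("rank", "mz", "rt_s", "log2fc", "p", "evidence",
                        "hypothesis_name", "error_ppm"),
                      names(x$candidates))
    print(utils::head(x$candidates[, cols], 10))
  }
  invisible(x)
}

#' Write a candidate report to CSV (and optionally JSON)
#'
#' @param report An `adduct_report` from [screen_study()].
#' @param path Output CSV path; retention times are printed in minutes.
#' @param json_path Optional path for a JSON report with the full evidence
#'   tables (candidates, pairs, parameters).
#' @export
write_candidate_report <- function(report, path, json_path = NULL) {
  cand <- report$candidates
  out <- data.frame(
    mz = cand$mz, rt_min = round(cand$rt_s / 60, 2),
    log2fc = cand$log2fc, p = cand$p,
    diagnostic_ion = cand$diagnostic_ion,
    ms2_neutral_loss = cand$has_ms2_neutral_loss,
    partner_mz = cand$partner_mz, partner_corr = cand$partner_corr,
    hypothesis_name = cand$hypothesis_name,
    expected_mz = cand$expected_mz, error_ppm = cand$error_ppm,
    rank = cand$rank)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(params = report$params, candidates = cand, pairs = report$pairs),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
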