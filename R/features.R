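# Extracted ion chromatograms, chromatographic peak detection and
# cross-sample feature alignment.
#
# This is the package's own feature finder for narrow-window qToF data:
# candidate m/z centroids come from greedy ppm-linkage clustering of all
# MS1 peaks (no fixed m/z grid), EICs are built per centroid, peaks are
# picked at local maxima above an MAD-based noise threshold with boundaries
# at the surrounding minima, and per-run features are aligned across
# samples by m/z and retention-time gap clustering.

# flatten the MS1 scans of a run into parallel vectors sorted by m/z
.flat_ms1 <- function(run) {
  ms1 <- ms_scans(run, 1L)
  if (!length(ms1)) stop("run has no MS1 scans")
  rts <- vapply(ms1, `[[`, numeric(1), "rt")
  mz <- unlist(lapply(ms1, `[[`, "mz"), use.names = FALSE)
  it <- unlist(lapply(ms1, `[[`, "intensity"), use.names = FALSE)
  scan <- rep.int(seq_along(ms1), vapply(ms1, function(s) length(s$mz),
                                         integer(1)))
  o <- order(mz)
  list(rt = rts, mz = mz[o], intensity = it[o], scan = scan[o],
       n_scans = length(ms1))
}

.eic_from_flat <- function(flat, target_mz, tol) {
  lo <- findInterval(target_mz - tol, flat$mz) + 1L
  hi <- findInterval(target_mz + tol, flat$mz)
  int <- numeric(flat$n_scans)
  if (hi >= lo) {
    idx <- lo:hi
    agg <- rowsum(flat$intensity[idx], flat$scan[idx])
    int[as.integer(rownames(agg))] <- agg[, 1]
  }
  structure(data.frame(rt = flat$rt, intensity = int),
            class = c("eic", "data.frame"),
            target_mz = target_mz, tol = tol)
}

#' Build an extracted ion chromatogram
#'
#' One point per MS1 scan: the summed intensity of all peaks within the
#' extraction window, zero where no peak falls inside it.
#'
#' @param run A [ms_run()].
#' @param target_mz Target m/z in Da.
#' @param tol_ppm Extraction half-window in ppm (default 5, the usual qToF
#'   mass accuracy); ignored when `tol_da` is given.
#' @param tol_da Absolute half-window in Da (e.g. 0.01 for verification
#'   EICs); overrides `tol_ppm`.
#' @return An `eic` data frame with columns `rt` (s) and `intensity`.
#' @export
build_eic <- function(run, target_mz, tol_ppm = 5, tol_da = NULL) {
  tol <- if (!is.null(tol_da)) tol_da else tol_ppm * 1e-6 * target_mz
  if (!is.numeric(tol) || tol <= 0) stop("tolerance must be positive")
  .eic_from_flat(.flat_ms1(run), target_mz, tol)
}

#' Export an EIC to CSV
#'
#' @param eic An `eic` from [build_eic()].
#' @param path Output CSV path with columns `rt_s`, `intensity`.
#' @export
write_eic <- function(eic, path) {
  utils::write.csv(data.frame(rt_s = eic$rt, intensity = eic$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Detect chromatographic peaks in an EIC
#'
#' Local maxima above `min_snr` times the noise level (noise = median
#' absolute deviation of the trace scaled by 1.4826); peak boundaries at the
#' surrounding local minima or trace zeros; at least `min_points`
#' consecutive nonzero points are required. The apex retention time is the
#' vertex of a parabola through the three points around the maximum; the
#' area is the trapezoidal integral between the boundaries.
#'
#' @param eic An `eic` from [build_eic()].
#' @param min_snr Minimum signal-to-noise ratio (default 3); 0 disables
#'   thresholding.
#' @param min_points Minimum consecutive nonzero points (default 3).
#' @param valley_frac Two adjacent maxima are merged into one peak when the
#'   valley between them stays above this fraction of the lower maximum
#'   (default 0.5), so noise ripples on a peak flank do not split it; a
#'   4-sigma-separated Gaussian pair (valley ~0.14) still resolves.
#' @return Data frame of features: `mz` (intensity-weighted, see
#'   [assemble_features()]; here the EIC target), `rt` apex (s), `area`,
#'   `height`, `snr`. Zero rows when nothing is found.
#' @export
detect_peaks <- function(eic, min_snr = 3, min_points = 3L,
                         valley_frac = 0.5) {
  y <- eic$intensity
  rt <- eic$rt
  n <- length(y)
  empty <- data.frame(mz = numeric(0), rt = numeric(0), area = numeric(0),
                      height = numeric(0), snr = numeric(0))
  if (n < 3L || !any(y > 0)) return(empty)
  noise <- stats::mad(y)             # 1.4826 * median |y - median(y)|
  if (noise <= 0) noise <- .Machine$double.eps
  thresh <- min_snr * noise
  # local maxima (plateaus resolve to their left edge)
  mx <- which(y > 0 & y >= c(-Inf, y[-n]) & y > c(y[-1], -Inf))
  mx <- mx[y[mx] >= thresh]
  if (!length(mx)) return(empty)
  # merge maxima separated by shallow valleys (or by a zero gap: never)
  repeat {
    if (length(mx) < 2L) break
    merged <- FALSE
    for (k in seq_len(length(mx) - 1L)) {
      seg <- mx[k]:mx[k + 1L]
      valley <- min(y[seg])
      if (valley > 0 && valley > valley_frac * min(y[mx[k]], y[mx[k + 1L]])) {
        mx <- mx[-(k + if (y[mx[k]] < y[mx[k + 1L]]) 0L else 1L)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # peak boundaries: outer edges walk down the slope; between kept maxima
  # the split sits at the valley minimum (deeper valleys separate peaks)
  bounds <- matrix(NA_integer_, length(mx), 2L)
  floor_v <- if (noise > .Machine$double.eps) noise else 0
  for (k in seq_along(mx)) {
    i <- mx[k]
    # extend to where the trace falls to the noise floor (noise ripples on
    # the flanks must not truncate the peak)
    l <- i; while (l > 1L && y[l - 1L] > floor_v) l <- l - 1L
    r <- i; while (r < n && y[r + 1L] > floor_v) r <- r + 1L
    if (k > 1L) {
      seg <- mx[k - 1L]:i
      l <- max(l, seg[which.min(y[seg])])
    }
    if (k < length(mx)) {
      seg <- i:mx[k + 1L]
      r <- min(r, seg[which.min(y[seg])])
    }
    bounds[k, ] <- c(l, r)
  }
  rows <- list()
  for (k in seq_along(mx)) {
    i <- mx[k]
    l <- bounds[k, 1L]; r <- bounds[k, 2L]
    if (sum(y[l:r] > 0) < min_points) next
    # apex: intensity-weighted centroid of the points above half height
    # (robust for wide peaks); 3-point parabola vertex when the top is
    # too narrow to average
    top <- l:r
    top <- top[y[top] >= 0.5 * y[i]]
    if (length(top) >= 3L) {
      rt_apex <- sum(rt[top] * y[top]) / sum(y[top])
    } else {
      rt_apex <- rt[i]
      if (i > 1L && i < n) {
        denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
        if (denom < 0) {
          delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
          step <- if (delta > 0) rt[i + 1L] - rt[i] else rt[i] - rt[i - 1L]
          rt_apex <- rt[i] + delta * step
        }
      }
    }
    seg <- l:r
    area <- sum(diff(rt[seg]) * (y[seg][-1] + y[seg][-length(seg)]) / 2)
    rows[[length(rows) + 1L]] <- data.frame(
      mz = attr(eic, "target_mz") %||% NA_real_,
      rt = rt_apex, area = area, height = y[i], snr = y[i] / noise)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# greedy ppm-linkage clustering of a run's MS1 peaks into candidate
# centroids; a cluster breaks where the sorted m/z gap exceeds the tolerance
.candidate_centroids <- function(flat, tol_ppm, min_points) {
  mz <- flat$mz
  if (!length(mz)) return(numeric(0))
  gap <- diff(mz) > tol_ppm * 1e-6 * mz[-length(mz)]
  grp <- cumsum(c(TRUE, gap))
  w <- flat$intensity
  cent <- vapply(split(seq_along(mz), grp), function(idx) {
    if (length(unique(flat$scan[idx])) < min_points) return(NA_real_)
    sum(mz[idx] * w[idx]) / sum(w[idx])
  }, numeric(1))
  cent[!is.na(cent)]
}

# per-run peak table over candidate centroids (or a provided target list)
.run_features <- function(run, targets, tol_ppm, min_snr, min_points) {
  flat <- .flat_ms1(run)
  cents <- if (is.null(targets))
    .candidate_centroids(flat, tol_ppm, min_points) else targets
  rows <- lapply(cents, function(mz0) {
    eic <- .eic_from_flat(flat, mz0, tol_ppm * 1e-6 * mz0)
    pk <- detect_peaks(eic, min_snr = min_snr, min_points = min_points)
    if (!nrow(pk)) return(NULL)
    pk$sample_id <- run$sample_id
    pk
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mz = numeric(0), rt = numeric(0), area = numeric(0),
                      height = numeric(0), snr = numeric(0),
                      sample_id = character(0))
  out
}

#' Detect and align features across runs
#'
#' Per-run peak detection over candidate m/z centroids (from greedy
#' ppm-linkage clustering of MS1 peaks, or a provided target list), followed
#' by alignment across runs: pooled features are clustered by m/z gaps
#' larger than `tol_ppm` and, within an m/z group, by retention-time gaps
#' larger than `rt_tol`. Consensus m/z and rt are area-weighted means. The
#' procedure is symmetric in run order.
#'
#' @param runs List of [ms_run()] objects (>= 1).
#' @param targets Optional numeric vector of target m/z values; `NULL`
#'   (default) derives candidates from the data.
#' @param tol_ppm Mass tolerance in ppm for extraction and alignment
#'   (default 5).
#' @param rt_tol Retention-time alignment tolerance in seconds (default 6,
#'   i.e. 0.1 min).
#' @param min_snr,min_points Peak detection parameters, see [detect_peaks()].
#' @return A `feature_matrix` data frame: `mz`, `rt_s`, then one area column
#'   per sample (`NA` = not detected), with a `groups` attribute mapping
#'   sample ids to group labels.
#' @export
assemble_features <- function(runs, targets = NULL, tol_ppm = 5, rt_tol = 6,
                              min_snr = 3, min_points = 3L) {
  if (!length(runs)) stop("empty run list")
  stopifnot(all(vapply(runs, inherits, logical(1), "ms_run")))
  sample_ids <- vapply(runs, `[[`, character(1), "sample_id")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids across runs")
  per_run <- lapply(runs, .run_features, targets = targets,
                    tol_ppm = tol_ppm, min_snr = min_snr,
                    min_points = min_points)
  pool <- do.call(rbind, per_run)
  groups <- stats::setNames(vapply(runs, function(r) as.character(r$group),
                                   character(1)), sample_ids)
  if (is.null(pool) || !nrow(pool)) {
    out <- cbind(data.frame(mz = numeric(0), rt_s = numeric(0)),
                 stats::setNames(as.data.frame(
                   matrix(numeric(0), 0, length(sample_ids))), sample_ids))
    attr(out, "groups") <- groups
    class(out) <- c("feature_matrix", "data.frame")
    return(out)
  }
  # m/z gap clustering of the pooled features (order-independent)
  o <- order(pool$mz, pool$rt, pool$sample_id)
  pool <- pool[o, ]
  gap <- diff(pool$mz) > tol_ppm * 1e-6 * pool$mz[-nrow(pool)]
  mz_grp <- cumsum(c(TRUE, gap))
  rows <- list()
  for (idx in split(seq_len(nrow(pool)), mz_grp)) {
    sub <- pool[idx, ]
    so <- order(sub$rt)
    sub <- sub[so, ]
    rt_gap <- diff(sub$rt) > rt_tol
    rt_grp <- cumsum(c(TRUE, rt_gap))
    for (jdx in split(seq_len(nrow(sub)), rt_grp)) {
      g <- sub[jdx, ]
      # one value per sample: keep the largest area if a sample repeats
      g <- g[order(-g$area), ]
      g <- g[!duplicated(g$sample_id), ]
      areas <- stats::setNames(rep(NA_real_, length(sample_ids)), sample_ids)
      areas[g$sample_id] <- g$area
      w <- g$area
      rows[[length(rows) + 1L]] <- c(
        mz = sum(g$mz * w) / sum(w), rt_s = sum(g$rt * w) / sum(w), areas)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out <- out[order(out$mz, out$rt_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  class(out) <- c("feature_matrix", "data.frame")
  out
}
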