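# Deterministic simulator of DDA LC-MS studies of digested DNA.
#
# A simulated run emulates the structure the screen assumes: the four
# 2'-deoxynucleosides as dominant background (dG highest, so dG
# normalization and diagnostic ions are realistic), optional random matrix
# species, and spiked adduct species with Gaussian elution profiles,
# partial in-source loss of deoxyribose (a co-eluting ion 116.0473 Da
# below the intact species), ppm-scale mass jitter, replicate-level
# intensity variation, and top-N DDA MS2 events near the elution apex.
# Everything is reproducible from the config seed.

#' Default digested-DNA background species
#'
#' The protonated 2'-deoxynucleosides at high abundance, dG highest.
#'
#' @return Data frame `name`, `mz`, `rt`, `sigma`, `area`.
#' @export
default_background <- function() {
  data.frame(
    name = c("dC", "dG", "dT", "dA"),
    mz = c(protonated_mz("C9H13N3O4"), protonated_mz("C10H13N5O4"),
           protonated_mz("C10H14N2O5"), protonated_mz("C10H13N5O3")),
    rt = c(60, 120, 150, 180),
    sigma = 5,
    area = c(2e7, 5e7, 2.5e7, 3e7),
    stringsAsFactors = FALSE
  )
}

#' Define a spiked adduct species
#'
#' @param name Species label.
#' @param mz Intact-ion m/z: a number, a formula string (protonated), or a
#'   one-row hypothesis data frame (its `expected_mz`).
#' @param rt Elution apex in seconds.
#' @param area Chromatographic peak area (arbitrary units) in treated
#'   samples at multiplier 1.
#' @param sigma Gaussian peak width in seconds (default 5).
#' @param insource_loss_fraction Fraction of the signal appearing as the
#'   co-eluting in-source deoxyribose-loss ion at `mz - 116.0473`
#'   (default 0 = intact only).
#' @param ms2_fragments Numeric vector of fragment m/z values emitted in
#'   DDA MS2 spectra of this species (`NULL` = never selected).
#' @param ms2_rel_intensity Fragment intensities relative to the precursor
#'   intensity (recycled; default 0.5).
#' @return A `sim_spike` list.
#' @export
sim_spike <- function(name, mz, rt, area, sigma = 5,
                      insource_loss_fraction = 0,
                      ms2_fragments = NULL, ms2_rel_intensity = 0.5) {
  if (is.data.frame(mz)) mz <- mz$expected_mz[1]
  else if (is.character(mz)) mz <- protonated_mz(mz)
  stopifnot(is.numeric(mz), mz > 0, rt >= 0, area >= 0, sigma > 0,
            insource_loss_fraction >= 0, insource_loss_fraction <= 1)
  structure(list(name = name, mz = mz, rt = rt, area = area, sigma = sigma,
                 insource_loss_fraction = insource_loss_fraction,
                 ms2_fragments = ms2_fragments,
                 ms2_rel_intensity = ms2_rel_intensity),
            class = "sim_spike")
}

#' Configure a simulated DDA LC-MS study
#'
#' @param seed Integer seed fixing all randomness of the study (background
#'   generation, per-run jitter, DDA selection).
#' @param gradient_length Run length in seconds (default 600).
#' @param scan_interval MS1 scan interval in seconds (default 1).
#' @param background Background species table (see [default_background()]).
#' @param n_background Number of additional random matrix species shared by
#'   all runs (default 0); drawn uniformly in `bg_mz_range` / `bg_rt_range`
#'   with log-uniform areas in `bg_area_range`.
#' @param bg_mz_range,bg_rt_range,bg_area_range Ranges for random matrix
#'   species.
#' @param spikes List of [sim_spike()] species.
#' @param ppm_sigma Gaussian m/z jitter per peak, in ppm (default 2,
#'   qToF-like).
#' @param intensity_cv Replicate-to-replicate coefficient of variation of
#'   species areas (default 0.1).
#' @param scan_noise_cv Per-scan relative intensity noise (default 0.02).
#' @param control_multiplier Spike multiplier applied to control runs
#'   (default 0 = absent; a small value simulates trace carryover).
#' @param ms2_top_n DDA precursors fragmented per cycle (default 2).
#' @param ms2_min_intensity Minimum precursor intensity to trigger MS2
#'   (default 1000).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, gradient_length = 600, scan_interval = 1,
                       background = default_background(), n_background = 0L,
                       bg_mz_range = c(150, 600), bg_rt_range = c(30, 570),
                       bg_area_range = c(1e4, 1e6), spikes = list(),
                       ppm_sigma = 2, intensity_cv = 0.1,
                       scan_noise_cv = 0.02, control_multiplier = 0,
                       ms2_top_n = 2L, ms2_min_intensity = 1000) {
  stopifnot(scan_interval > 0, gradient_length > scan_interval,
            ppm_sigma >= 0, intensity_cv >= 0, scan_noise_cv >= 0,
            control_multiplier >= 0, n_background >= 0)
  if (n_background > 0) {
    extras <- .with_seed(seed, {
      data.frame(
        name = sprintf("bg%03d", seq_len(n_background)),
        mz = stats::runif(n_background, bg_mz_range[1], bg_mz_range[2]),
        rt = stats::runif(n_background, bg_rt_range[1], bg_rt_range[2]),
        sigma = 5,
        area = exp(stats::runif(n_background, log(bg_area_range[1]),
                                log(bg_area_range[2]))),
        stringsAsFactors = FALSE)
    })
    background <- rbind(background, extras)
  }
  structure(list(seed = as.integer(seed), gradient_length = gradient_length,
                 scan_interval = scan_interval, background = background,
                 spikes = spikes, ppm_sigma = ppm_sigma,
                 intensity_cv = intensity_cv, scan_noise_cv = scan_noise_cv,
                 control_multiplier = control_multiplier,
                 ms2_top_n = as.integer(ms2_top_n),
                 ms2_min_intensity = ms2_min_intensity),
            class = "sim_config")
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# species table for one run: background + spikes (+ in-source partners)
.run_species <- function(cfg, spike_multiplier) {
  sp <- cfg$background
  sp$is_spike <- FALSE
  sp$partner_of <- NA_character_
  sp$spike_idx <- NA_integer_
  dr <- monoisotopic_mass("C5H8O3")
  for (k in seq_along(cfg$spikes)) {
    s <- cfg$spikes[[k]]
    a <- s$area * spike_multiplier
    if (a <= 0) next
    frac <- s$insource_loss_fraction
    sp <- rbind(sp, data.frame(
      name = s$name, mz = s$mz, rt = s$rt, sigma = s$sigma,
      area = a * (1 - frac), is_spike = TRUE, partner_of = NA_character_,
      spike_idx = k, stringsAsFactors = FALSE))
    if (frac > 0)
      sp <- rbind(sp, data.frame(
        name = paste0(s$name, "_insource"), mz = s$mz - dr, rt = s$rt,
        sigma = s$sigma, area = a * frac, is_spike = TRUE,
        partner_of = s$name, spike_idx = k, stringsAsFactors = FALSE))
  }
  sp
}

#' Simulate one DDA LC-MS run
#'
#' @param cfg A [sim_config()].
#' @param sample_id Sample identifier.
#' @param group Group label.
#' @param spike_multiplier Multiplier applied to all spike areas (1 for
#'   treated, `cfg$control_multiplier` for control runs).
#' @param seed Run-level seed; defaults to `cfg$seed`.
#' @return List with `run` (a [ms_run()]) and `truth` (data frame of the
#'   realized species: `name`, `mz`, `rt`, `area`, `is_spike`,
#'   `partner_of`) plus `ms2_events`.
#' @export
simulate_run <- function(cfg, sample_id, group = "treated",
                         spike_multiplier = 1, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(seed, {
    times <- seq(0, cfg$gradient_length, by = cfg$scan_interval)
    n_scan <- length(times)
    sp <- .run_species(cfg, spike_multiplier)
    # replicate-level area factors: lognormal with mean 1, CV = intensity_cv
    slog <- sqrt(log(1 + cfg$intensity_cv^2))
    fac <- stats::rlnorm(nrow(sp), meanlog = -slog^2 / 2, sdlog = slog)
    # in-source partners share their parent's replicate factor so the
    # intact/fragment ratio stays stable within a run
    for (i in which(!is.na(sp$partner_of)))
      fac[i] <- fac[match(sp$partner_of[i], sp$name)]
    sp$area_realized <- sp$area * fac
    peak_scan <- vector("list", n_scan)
    peak_mz <- vector("list", n_scan)
    peak_int <- vector("list", n_scan)
    trace <- matrix(0, nrow(sp), n_scan)
    for (i in seq_len(nrow(sp))) {
      lo <- max(1L, findInterval(sp$rt[i] - 4 * sp$sigma[i], times))
      hi <- min(n_scan, findInterval(sp$rt[i] + 4 * sp$sigma[i], times) + 1L)
      if (hi < lo) next
      idx <- lo:hi
      y <- sp$area_realized[i] * stats::dnorm(times[idx], sp$rt[i],
                                              sp$sigma[i])
      if (cfg$scan_noise_cv > 0)
        y <- pmax(0, y * (1 + stats::rnorm(length(y), 0,
                                           cfg$scan_noise_cv)))
      mzj <- sp$mz[i] * (1 + stats::rnorm(length(y), 0,
                                          cfg$ppm_sigma * 1e-6))
      keep <- y > 0
      trace[i, idx] <- y
      for (j in which(keep)) {
        k <- idx[j]
        peak_mz[[k]] <- c(peak_mz[[k]], mzj[j])
        peak_int[[k]] <- c(peak_int[[k]], y[j])
      }
    }
    # assemble MS1 scans and DDA MS2 events (top-N at/after apex, one
    # event per species per elution peak)
    spectra <- list()
    fragmented <- rep(FALSE, nrow(sp))
    has_ms2 <- !vapply(seq_len(nrow(sp)), function(i) {
      k <- sp$spike_idx[i]
      is.na(k) || is.na(sp$partner_of[i]) == FALSE ||
        is.null(cfg$spikes[[k]]$ms2_fragments)
    }, logical(1))
    ms2_events <- list()
    for (k in seq_len(n_scan)) {
      mzv <- peak_mz[[k]] %||% numeric(0)
      intv <- peak_int[[k]] %||% numeric(0)
      o <- order(mzv)
      spectra[[length(spectra) + 1L]] <-
        ms_spectrum(1L, times[k], mzv[o], intv[o])
      cand <- which(has_ms2 & !fragmented &
                    trace[, k] >= cfg$ms2_min_intensity &
                    times[k] >= sp$rt)
      if (length(cand)) {
        cand <- cand[order(-trace[cand, k])]
        cand <- cand[seq_len(min(length(cand), cfg$ms2_top_n))]
        for (ci in seq_along(cand)) {
          i <- cand[ci]
          s <- cfg$spikes[[sp$spike_idx[i]]]
          pint <- trace[i, k]
          fmz <- s$ms2_fragments *
            (1 + stats::rnorm(length(s$ms2_fragments), 0,
                              cfg$ppm_sigma * 1e-6))
          fint <- pint * rep_len(s$ms2_rel_intensity, length(fmz))
          # residual precursor peak
          fmz <- c(fmz, sp$mz[i])
          fint <- c(fint, 0.2 * pint)
          o <- order(fmz)
          spectra[[length(spectra) + 1L]] <- ms_spectrum(
            2L, times[k] + ci * 0.1 * cfg$scan_interval,
            fmz[o], fint[o], precursor_mz = sp$mz[i],
            precursor_intensity = pint, iso_halfwidth = 0.5)
          fragmented[i] <- TRUE
          ms2_events[[length(ms2_events) + 1L]] <- data.frame(
            name = sp$name[i], rt = times[k], precursor_mz = sp$mz[i])
        }
      }
    }
    truth <- sp[sp$area_realized > 0,
                c("name", "mz", "rt", "sigma", "area_realized", "is_spike",
                  "partner_of")]
    names(truth)[names(truth) == "area_realized"] <- "area"
    truth$sample_id <- sample_id
    rownames(truth) <- NULL
    list(run = ms_run(sample_id, group, spectra),
         truth = truth,
         ms2_events = if (length(ms2_events)) do.call(rbind, ms2_events)
                      else NULL)
  })
}

#' Simulate a treated-versus-control study
#'
#' Control runs receive spike multiplier `cfg$control_multiplier` (0 by
#' default); per-replicate areas vary by `cfg$intensity_cv`. Run-level
#' seeds are derived deterministically from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param n_treated,n_control Replicates per group (>= 1).
#' @param dir Optional output directory; when given, one mzML file per run
#'   and a `manifest.json` ground-truth manifest are written there.
#' @return List: `runs` (list of [ms_run()]), `truth` (combined
#'   ground-truth data frame), `ms2_events`, `groups` (named vector).
#' @export
simulate_study <- function(cfg, n_treated = 3L, n_control = 3L, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n_treated >= 1L, n_control >= 1L)
  n <- n_treated + n_control
  run_seeds <- .with_seed(cfg$seed, sample.int(2^30, n))
  ids <- c(sprintf("T%02d", seq_len(n_treated)),
           sprintf("C%02d", seq_len(n_control)))
  grps <- c(rep("treated", n_treated), rep("control", n_control))
  mult <- c(rep(1, n_treated), rep(cfg$control_multiplier, n_control))
  sims <- lapply(seq_len(n), function(i)
    simulate_run(cfg, ids[i], grps[i], spike_multiplier = mult[i],
                 seed = run_seeds[i]))
  runs <- lapply(sims, `[[`, "run")
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  ms2 <- do.call(rbind, lapply(sims, `[[`, "ms2_events"))
  groups <- stats::setNames(grps, ids)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      write_mzml(runs[[i]], file.path(dir, paste0(ids[i], ".mzML")))
    jsonlite::write_json(
      list(seed = cfg$seed, groups = as.list(groups), truth = truth),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  list(runs = runs, truth = truth, ms2_events = ms2, groups = groups)
}
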