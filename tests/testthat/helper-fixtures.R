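# Shared fixtures: all inputs are generated in code at test time.

# independent atom-by-atom mass oracle: a separately typed isotope table,
# summed one atom at a time (never via the package's vectorized path)
oracle_masses <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Cl = 34.96885268)

oracle_mass <- function(f) {
  total <- 0
  for (el in names(f)) {
    cnt <- unclass(f)[[el]]
    for (i in seq_len(cnt)) total <- total + oracle_masses[[el]]
  }
  total
}

# random plausible organic formula as a string
rand_formula_string <- function() {
  els <- c("C", "H", "N", "O", "S", "P", "Cl")
  pick <- sort(sample(seq_along(els), sample(2:5, 1)))
  counts <- sample(1:30, length(pick), replace = TRUE)
  paste0(els[pick], counts, collapse = "")
}

# minimal synthetic EIC with a Gaussian peak (area A) plus optional noise
gaussian_eic <- function(apex, sigma, area, rt = seq(0, 300, by = 1),
                         noise_sd = 0, target_mz = 300, extra = NULL) {
  y <- area * dnorm(rt, apex, sigma)
  if (!is.null(extra)) y <- y + extra$area * dnorm(rt, extra$apex, extra$sigma)
  if (noise_sd > 0) y <- pmax(0, y + rnorm(length(rt), 0, noise_sd))
  structure(data.frame(rt = rt, intensity = y),
            class = c("eic", "data.frame"), target_mz = target_mz,
            tol = 0.01)
}

# build a run directly from a species table (mz, rt, sigma, area rows),
# independent of the package simulator
run_from_species <- function(species, sample_id = "S1", group = "treated",
                             t_max = 300, dt = 1, ppm_sigma = 0,
                             ms2 = NULL) {
  times <- seq(0, t_max, by = dt)
  spectra <- list()
  for (t in times) {
    mzv <- numeric(0); intv <- numeric(0)
    for (i in seq_len(nrow(species))) {
      y <- species$area[i] * dnorm(t, species$rt[i], species$sigma[i])
      if (y > 1e-6) {
        mz <- species$mz[i]
        if (ppm_sigma > 0) mz <- mz * (1 + rnorm(1, 0, ppm_sigma * 1e-6))
        mzv <- c(mzv, mz); intv <- c(intv, y)
      }
    }
    o <- order(mzv)
    spectra[[length(spectra) + 1L]] <- ms_spectrum(1L, t, mzv[o], intv[o])
    if (!is.null(ms2)) {
      for (j in seq_len(nrow(ms2))) {
        if (abs(t - ms2$rt[j]) < dt / 2) {
          fr <- sort(ms2$fragments[[j]])
          spectra[[length(spectra) + 1L]] <- ms_spectrum(
            2L, t + 0.1 * dt, fr, rep(1000, length(fr)),
            precursor_mz = ms2$precursor[j], precursor_intensity = 5000,
            iso_halfwidth = 0.5)
        }
      }
    }
  }
  ms_run(sample_id, group, spectra)
}

# standard small screening fixture: 3 spiked adducts (with DDA MS2 evidence
# and in-source partners) among random background features, 3v3 design
screen_fixture <- function(seed = 7, n_background = 200) {
  afb <- adduct_hypothesis(
    "C17H12O6",
    list(biotransformations()$epoxidation, biotransformations()$hydration),
    target = "Gua", binding_loss = "H2O", parent_name = "AFB1")
  bap <- adduct_hypothesis(
    "C20H12",
    list(biotransformations()$epoxidation, biotransformations()$hydration,
         biotransformations()$epoxidation),
    target = "dG", parent_name = "BaP")
  asa <- adduct_hypothesis(
    "C12H16O3", list(biotransformations()$epoxidation),
    target = "dA", parent_name = "AS")
  dr <- monoisotopic_mass("C5H8O3")
  gua <- protonated_mz("C5H5N5O")
  spikes <- list(
    sim_spike("AFB1-Gua", afb, rt = 300, area = 2e6,
              ms2_fragments = c(gua)),
    sim_spike("BaP-dG", bap, rt = 360, area = 1.5e6,
              insource_loss_fraction = 0.3,
              ms2_fragments = c(bap$expected_mz - dr, gua)),
    sim_spike("AS-dA", asa, rt = 420, area = 1e6,
              insource_loss_fraction = 0.25,
              ms2_fragments = c(asa$expected_mz - dr,
                                protonated_mz("C10H13N5O3"),
                                protonated_mz("C5H5N5"),
                                protonated_mz("C12H16O4"))))
  hyp <- rbind(
    enumerate_hypotheses("C17H12O6", parent_name = "AFB1"),
    enumerate_hypotheses("C20H12", parent_name = "BaP"),
    enumerate_hypotheses("C12H16O3", parent_name = "AS"))
  hyp <- hyp[order(hyp$expected_mz), ]
  cfg <- sim_config(seed = seed, n_background = n_background,
                    spikes = spikes)
  list(cfg = cfg, hypotheses = hyp,
       spiked = data.frame(name = c("AFB1-Gua", "BaP-dG", "AS-dA"),
                           mz = c(afb$expected_mz, bap$expected_mz,
                                  asa$expected_mz),
                           rt = c(300, 360, 420),
                           hypothesis = c(afb$name, bap$name, asa$name)))
}
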