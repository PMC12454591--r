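test_that("diagnostic MS2 filtering flags base ions and neutral losses", {
  gua <- protonated_mz("C5H5N5O")
  afb_gua <- 480.1150
  as_da <- 476.2140
  dr <- monoisotopic_mass("C5H8O3")
  species <- data.frame(mz = c(afb_gua, as_da, 333.10),
                        rt = c(100, 150, 200), sigma = 5, area = 1e6)
  ms2 <- data.frame(rt = c(100, 150, 200),
                    precursor = c(afb_gua, as_da, 333.10))
  ms2$fragments <- list(c(gua, 300.05),          # guanine fragment
                        c(as_da - dr, 225.1121), # deoxyribose neutral loss
                        c(77.04, 105.03))        # neither
  run <- run_from_species(species, ms2 = ms2)
  feats <- data.frame(mz = species$mz, rt_s = species$rt)
  ev <- filter_diagnostic_ms2(run, feats)
  expect_true(ev$has_diagnostic_fragment[1])
  expect_identical(ev$diagnostic_ion[1], "guanine")
  expect_true(ev$has_ms2_neutral_loss[2])
  expect_false(ev$has_diagnostic_fragment[3])
  expect_false(ev$has_ms2_neutral_loss[3])
  # a run without MS2 warns and returns all-unflagged
  run_ms1 <- run_from_species(species)
  expect_warning(ev0 <- filter_diagnostic_ms2(run_ms1, feats), "no MS2")
  expect_false(any(ev0$has_diagnostic_fragment))
})

test_that("in-source pairing requires mass delta, co-elution and correlation", {
  dr <- monoisotopic_mass("C5H8O3")
  set.seed(51)
  species <- data.frame(
    mz = c(570.1983, 570.1983 - dr,     # co-eluting pair
           500.20, 500.20 - dr),        # right delta, 30 s apart
    rt = c(150, 150, 80, 110), sigma = 5, area = c(1e6, 4e5, 1e6, 8e5))
  run <- run_from_species(species, ppm_sigma = 1)
  feats <- data.frame(mz = species$mz, rt_s = species$rt,
                      S1 = species$area)
  pairs <- pair_insource(feats, list(run), rt_tol = 6, min_corr = 0.9)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$heavy, 1L)
  expect_equal(pairs$light, 2L)
  expect_gt(pairs$corr, 0.99)
  expect_lt(abs(pairs$delta - dr), 0.01)
})

test_that("pairing equals a brute-force all-pairs oracle on random features", {
  dr <- monoisotopic_mass("C5H8O3")
  set.seed(52)
  n <- 50
  mz <- runif(n, 150, 600)
  # force some true mass relationships
  pair_idx <- sample(which(mz > 300), 8)
  mz[pair_idx[5:8]] <- mz[pair_idx[1:4]] - dr
  rt <- runif(n, 30, 270)
  rt[pair_idx[5:7]] <- rt[pair_idx[1:3]] + runif(3, -3, 3)  # co-eluting
  species <- data.frame(mz = mz, rt = rt, sigma = 5,
                        area = 10^runif(n, 5, 6.5))
  run <- run_from_species(species, ppm_sigma = 1)
  feats <- data.frame(mz = mz, rt_s = rt, S1 = species$area)
  got <- pair_insource(feats, list(run), rt_tol = 6, min_corr = 0.9)
  # independently coded exhaustive filter
  expected <- list()
  for (h in seq_len(n)) for (l in seq_len(n)) {
    if (h == l) next
    if (abs((mz[h] - mz[l]) - dr) > 0.01) next
    if (abs(rt[h] - rt[l]) > 6) next
    eh <- build_eic(run, mz[h], tol_da = 0.01)
    el <- build_eic(run, mz[l], tol_da = 0.01)
    r <- suppressWarnings(cor(eh$intensity, el$intensity))
    if (is.na(r) || r < 0.9) next
    expected[[length(expected) + 1L]] <- c(h, l)
  }
  exp_mat <- if (length(expected)) do.call(rbind, expected)
             else matrix(0L, 0, 2)
  expect_equal(nrow(got), nrow(exp_mat))
  got_keys <- paste(got$heavy, got$light)
  exp_keys <- paste(exp_mat[, 1], exp_mat[, 2])
  expect_setequal(got_keys, exp_keys)
  expect_gte(nrow(got), 3L)          # the constructed pairs are found
})

test_that("EIC correlation is exact on self and scale invariant", {
  set.seed(53)
  species <- data.frame(mz = 300, rt = 150, sigma = 5, area = 1e6)
  run <- run_from_species(species, ppm_sigma = 1)
  e <- build_eic(run, 300, tol_da = 0.01)
  expect_equal(cor(e$intensity, e$intensity), 1, tolerance = 1e-12)
  expect_equal(cor(e$intensity, 3.7 * e$intensity + 0), 1,
               tolerance = 1e-12)
})

test_that("annotation picks the nearest hypothesis with sane tie-breaks", {
  h <- enumerate_hypotheses(
    "C17H12O6", targets = c("Gua", "dG"), max_chain = 2,
    parent_name = "AFB1")
  exp_mz <- h$expected_mz[h$chain == "epoxidation" & h$target == "Gua" &
                            h$binding_loss == "none"]
  cand <- data.frame(mz = c(480.1155, 480.20))
  ann <- annotate_candidates(cand, h, tol_ppm = 5)
  expect_true(ann$annotated[1])
  expect_equal(ann$expected_mz[1], exp_mz, tolerance = 1e-9)
  expect_lt(abs(ann$error_ppm[1]), 5)
  expect_gt(ann$error_ppm[1], 0)     # observed sits above calculated
  expect_false(ann$annotated[2])     # 0.08 Da off: out of tolerance
  # closer hypothesis wins; at equal distance the shorter chain wins
  fake <- data.frame(
    name = c("far", "near", "tie_long", "tie_short"),
    parent_formula = "C10H10", chain = c("a", "b", "a+b", ""),
    target = "Gua", binding_loss = "none", adduct_formula = "C10H10",
    expected_mz = c(400.0000 * (1 - 2e-6), 400.0000 * (1 + 1e-6),
                    500.0000 * (1 - 1e-6), 500.0000 * (1 + 1e-6)),
    n_steps = c(1L, 1L, 2L, 0L), is_nucleoside = FALSE, base = "Gua")
  ann2 <- annotate_candidates(data.frame(mz = c(400.0, 500.0)), fake,
                              tol_ppm = 5)
  expect_identical(ann2$hypothesis_name, c("near", "tie_short"))
})

test_that("the screen ranks spiked adducts on top with correct annotation", {
  fx <- screen_fixture(seed = 7, n_background = 200)
  study <- simulate_study(fx$cfg, 3, 3)
  report <- screen_study(study$runs, hypotheses = fx$hypotheses)
  cand <- report$candidates
  top5 <- cand[cand$rank <= 5, ]
  for (i in seq_len(nrow(fx$spiked))) {
    hit <- which(abs(ppm_error(top5$mz, fx$spiked$mz[i])) <= 5)
    expect_length(hit, 1L)
    expect_true(top5$annotated[hit])
    expect_lt(abs(top5$error_ppm[hit]), 5)
    expect_equal(top5$expected_mz[hit], fx$spiked$mz[i], tolerance = 1e-6)
  }
  # in-source partners were found for the two species that shed deoxyribose
  paired <- top5$mz[!is.na(top5$partner_mz) & !top5$is_insource_fragment]
  expect_gte(length(paired), 2L)
  # deterministic: identical ranked report on rerun
  report2 <- screen_study(study$runs, hypotheses = fx$hypotheses)
  expect_identical(report$candidates, report2$candidates)
  # report writer produces the documented CSV layout
  csv <- withr::local_tempfile(fileext = ".csv")
  jsn <- withr::local_tempfile(fileext = ".json")
  write_candidate_report(report, csv, json_path = jsn)
  back <- utils::read.csv(csv)
  expect_identical(names(back)[1:4], c("mz", "rt_min", "log2fc", "p"))
  expect_true(file.exists(jsn))
})

test_that("a spiked adduct missing from the hypothesis space is reported", {
  fx <- screen_fixture(seed = 8, n_background = 50)
  study <- simulate_study(fx$cfg, 3, 3)
  hyp_afb_only <- fx$hypotheses[grepl("^AFB1", fx$hypotheses$name), ]
  report <- screen_study(study$runs, hypotheses = hyp_afb_only)
  cand <- report$candidates
  as_row <- cand[abs(ppm_error(cand$mz, fx$spiked$mz[3])) <= 5, ]
  expect_equal(nrow(as_row), 1L)
  expect_false(as_row$annotated)     # unknown-adduct path: kept, unannotated
})

test_that("a study without treatment effects yields no candidates", {
  cfg <- sim_config(seed = 9, n_background = 60)   # no spikes at all
  study <- simulate_study(cfg, 3, 3)
  report <- screen_study(study$runs)
  expect_equal(nrow(report$candidates), 0L)
})
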