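# dnadduct

Untargeted LC-MS screening and targeted analysis of DNA adducts in R.

## What this is for

Covalent DNA adducts of (bioactivated) xenobiotics are initiating lesions
of chemical carcinogenesis. After enzymatic digestion of DNA to
2'-deoxynucleosides, adducts are detectable by LC-MS — but most methods
target a few known lesions. `dnadduct` is for analytical chemists and
toxicologists who want to *screen* centroided data-dependent-acquisition
(DDA) LC-MS runs of digested DNA for unknown adducts and then follow up
with targeted MRM analysis.

The workflow rests on the subunit structure of DNA adducts
(deoxyribose + DNA base + xenobiotic):

* an intact adduct hypothesis has formula
  `parent + Σ biotransformation deltas + target − binding_loss`, and its
  `[M+H]+` m/z is the monoisotopic mass plus the proton mass
  (1.00727646688 Da);
* cleavage of the sugar produces a neutral loss of C5H8O3 = 116.0473 Da —
  in MS2 spectra and as a co-eluting in-source fragment in MS1;
* protonated guanine (m/z 152.0567), adenine (136.0618), dG (268.1040),
  dA (252.1091) and the deoxyribose oxocarbenium (117.0546) are
  diagnostic fragments of DNA adducts.

The pipeline: assemble features from mzML runs → volcano selection of
treatment-specific features (Welch t-test on log2 areas, fold-change
threshold) → verify candidates by diagnostic MS2 fragments, the 116.0473
neutral loss, and in-source pairing (Δm = 116.0473, matching RT, EIC
Pearson r ≥ 0.9) → annotate against an enumerated hypothesis space
(≤ 5 ppm) → design MRM transitions → quantify with external calibration,
normalized to adducts per 10^8 dG. One-way ANOVA + Tukey HSD covers
multi-group comparisons. A deterministic simulator generates full DDA
studies with ground-truth manifests for validation.

## Worked example

Enumerate hypotheses for glycidol (the reactive epoxide metabolite of
3-MCPD) on guanine, simulate a 3 vs 3 study with that adduct spiked into
treated samples, and screen it:

```r
library(dnadduct)

h <- enumerate_hypotheses("C3H6O2", steps = list(), targets = "Gua",
                          max_chain = 0, binding_losses = "none",
                          parent_name = "glycidol")
round(h$expected_mz, 4)
#> [1] 226.0935

cfg <- sim_config(seed = 5, n_background = 30, spikes = list(
  sim_spike("glycidol-Gua", h, rt = 150, area = 2e6,
            ms2_fragments = protonated_mz("C5H5N5O"))))
study <- simulate_study(cfg, n_treated = 3, n_control = 3)
report <- screen_study(study$runs,
                       hypotheses = enumerate_hypotheses("C3H6O2"))
report
#> <adduct_report> 80 features, 1 candidates
#>   rank       mz     rt_s   log2fc            p evidence hypothesis_name
#> 1    1 226.0934 149.8878 23.11324 2.138224e-05        1      C3H6O2-Gua
#>    error_ppm
#> 1 -0.1845835
```

The single selected feature matches the expected glycidol–guanine adduct
within 0.2 ppm, carries a guanine diagnostic fragment in its MS2
spectrum, and is absent from all control runs (the large log2 fold change
reflects the imputation floor). `design_transitions()` then yields its
targeted transitions, and `normalize_to_dG()` converts quantified amounts
into the adducts-per-10^8-dG reporting unit.

The same workflow runs from the shell via the thin CLI in
`inst/cli/dnadduct` (subcommands `masses`, `simulate`, `screen`, `mrm`,
`quantify`).

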