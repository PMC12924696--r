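# fpvs — frequency-tagging EEG analysis for FPVS oddball paradigms

`fpvs` is an R package for quantifying steady-state and category-selective
(oddball) responses in fast periodic visual stimulation (FPVS) EEG
experiments, the paradigm used to measure e.g. face-selective brain
responses in adults and preverbal infants. Stimuli appear at a fixed base
rate `f_b` (typically 6 Hz) with the category of interest embedded as every
n-th image (1 Hz). Category-selective activity then shows up in the EEG
amplitude spectrum exactly at 1 Hz and its harmonics, while the response
common to all stimuli sits at 6 Hz and its harmonics.

The package implements the full analysis chain used in this literature:

* **Preprocessing** — zero-phase Butterworth bandpass (0.1–100 Hz, order 4),
  Fourier resampling to 200 Hz, 36-s segment cropping at sequence onsets,
  blink-component removal (adult) or ±500 µV artifact blocking (infant),
  bad-channel interpolation, symmetric-average re-referencing.
* **Spectral quantification** — exact-cycle 34-s epochs (harmonics fall on
  exact FFT bins, Δf = 1/34 ≈ 0.029 Hz), single-sided amplitude spectra in
  µV, neighbor-bin noise estimates (adult 12-bins-per-side and infant
  16-bins-per-side-with-detrending recipes, 20 values each after
  exclusions), baseline-corrected amplitudes `a − ā_noise`, spectral
  Z-scores `(a − ā_noise)/s_noise`, data-driven harmonic selection
  (consecutive Z > 1.64, overlap harmonics skipped, 50-Hz cap) and harmonic
  summation.
* **Quantification** — infant epoch screening (Z > 2.32 over POz/O1/Oz/O2 at
  6 or 12 Hz), preset and ranked region-of-interest construction, group and
  individual significance summaries.
* **Statistics** — repeated-measures ANOVA with Mauchly/Greenhouse–Geisser
  handling and partial eta squared, Benjamini–Hochberg FDR, paired post-hoc
  t-tests, JZS Bayes factors (Monte Carlo g-prior integration), split-half
  reliability and the Fisher-z comparison of dependent correlations, and
  G*Power-style effect-size/sample-size conversion
  (`f = sqrt(η²/(1−η²))`, e.g. η² = 0.29 → f = 0.639).
* **Synthetic data** — a seeded FPVS-EEG generator (harmonic series ×
  topography × contrast envelope + 1/f noise + blinks/spikes) with a
  ground-truth manifest, single recordings or whole cohorts with
  condition-by-group amplitude structure; EDF and BrainVision I/O; a CLI.

## Worked example

Simulate a small infant cohort (two age groups, Classic vs New stimulus set,
known true amplitudes) and run the full pipeline:

```r
library(fpvs)

montage  <- fpvs_montage("infant_32")
schedule <- build_sequence_schedule()      # 6 Hz base, 1 Hz oddball, 35.666 s
design   <- cohort_design(n_per_group = 4, trials_per_condition = 3, seed = 42,
                          oddball_mean_by_cell = matrix(c(0.4, 1.6, 0.6, 1.0), 2, 2))
cohort   <- simulate_cohort(design, montage, schedule,
                            noise = noise_model(noise_scale = 6, blink_rate = 2))

config <- infant_exp2_config(seed = 42,
                             stats = list(split_condition = FALSE,
                                          bayes_iterations = 2000))
res <- run_pipeline(config, cohort)

res$harmonics$general
#> <fpvs_harmonic_set: fundamental 6 Hz, 6 harmonics [1,2,3,4,5,6]>

head(subset(res$roi_table, response == "face" & participant == "P001"))
#>   participant group condition response roi  amplitude         z
#> 1        P001 young   Classic     face rOT 0.14826819 1.8950169
#> 2        P001 young   Classic     face lOT 0.07850768 0.9589167
#> 3        P001 young   Classic     face  mO 0.15507950 1.6335746
#> 5        P001 young       New     face rOT 0.44575299 1.8927131
#> 6        P001 young       New     face lOT 0.13912317 0.5493652
#> 7        P001 young       New     face  mO 0.37169612 2.0851307

res$anova$face[, c("effect", "F", "df_num", "df_den", "p", "partial_eta_sq")]
#>                effect          F   df_num    df_den          p partial_eta_sq
#> 1               group  0.7285333 1.000000  6.000000 0.42611613      0.1082752
#> 2           condition  1.1008158 1.000000  6.000000 0.33449887      0.1550267
#> 3     condition:group 10.0986410 1.000000  6.000000 0.01912816      0.6272977
#> 4                 roi 10.3840024 1.022305  6.133831 0.01727040      0.6337891
#> 5           roi:group  1.3003145 1.022305  6.133831 0.29824858      0.1781176
#> 6       condition:roi  4.6120113 2.000000 12.000000 0.03266790      0.4346029
#> 7 condition:roi:group  6.7826426 2.000000 12.000000 0.01069507      0.5306135
```

Reading the output: each row of `roi_table` is one participant's summed
baseline-corrected oddball amplitude (µV) and summed-chunk Z over one region
of interest — for participant P001 the New set roughly triples the
right-occipito-temporal response (0.45 vs 0.15 µV), mirroring the injected
cell structure in which the younger group benefits most from the New set
(true means 1.6 vs 0.4 µV young, 1.0 vs 0.6 µV old). With only 8 simulated
infants the Set main effect is not significant, but the condition × group
interaction is (F(1,6) = 10.1, p = 0.019, ηp² = 0.63): the ANOVA recovers
the age-dependent benefit. The `roi` rows carry Greenhouse–Geisser-corrected
degrees of freedom (ε ≈ 0.51, applied because Mauchly's test rejected).
All 48 simulated epochs passed the 6/12-Hz screening
(`res$screening_log`), and the Bayes factor for the (weak, n = 8) Set main
effect is `res$bayes$bf10 ≈ 0.52`, i.e. inconclusive, as expected at this
sample size.

## Command line

```sh
Rscript inst/cli/fpvs run-all --population infant --seed 3 \
        --n-per-group 4 --trials 3 --out results_dir
Rscript inst/cli/fpvs simulate --population adult --seed 1 --out edf_dir
```

`run-all` writes `roi_table.csv`, `anova_*.csv`, `posthoc.csv`, `bayes.csv`,
`split_half.csv`, `screening_log.csv`, `harmonics.json` and `config.json`,
every table stamped with a configuration hash for provenance.

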