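# glycomig

Serum IgG Fc N-glycopeptide profiling by linear-mode MALDI-TOF mass
spectrometry, with a feedforward-network case/control classifier — an R
package for glycoproteomics researchers studying immune correlates of
disease (the motivating application is migraine vs healthy controls).

Tryptic digestion of IgG yields subclass-specific Fc glycopeptides
(IgG1 EEQYNSTYR, IgG2 EEQFNSTFR, IgG3/4 as one isomeric class), whose
glycoform distribution is informative about immune state. The package
implements, end to end:

* **Mass library** — glycoform shorthand algebra (`G0F`, `G0-NF`,
  `G2S2`, …) over the 22-name vocabulary, monoisotopic [M+H]⁺ masses,
  and flagging of IgG3/4 species whose masses collide with IgG1/IgG2
  species (a hexose-for-fucose swap almost exactly compensates the
  one-oxygen backbone difference).
* **Spectrum processing** — top-hat (morphological opening) baseline
  subtraction, 0.050 mV threshold peak picking with noise-robust apex
  interpolation, m/z export windowing, and internal affine calibration
  against four theoretical calibrant masses (m/z 2602.1, 2796.1,
  2958.2, 3217.3).
* **Quantification** — nearest-match peak assignment with
  missing-to-zero, relative intensities (each height over the summed
  heights, so profiles sum to 1), averaging of 4 technical replicates,
  and RSD repeatability QC at six minor components against a 15% bound.
* **Derived traits** — bisecting GlcNAc, fucosylation (total /
  neutral / sialylated), sialylation, galactosylation classes
  G0/G1/G2 and the Gal-ratio `G0/(G1 + 2·G2)`.
* **Cohort statistics** — pooled-variance two-tailed Student's t per
  glycopeptide and trait, Pearson χ² for 2×2 baselines, ANOVA-F feature
  ranking.
* **Classifier** — the 7–6–4–2 feedforward network
  `Y = Softmax(W₃ᵀσ(W₂ᵀσ(W₁ᵀX + B₁) + B₂) + B₃)` with min-max scaling,
  full-batch gradient-descent training, stratified 5-fold
  cross-validation and Mann–Whitney AUC. By default scaling and
  feature selection are fitted inside each training fold;
  `paper_mode = TRUE` reproduces the full-dataset (leaky) protocol.
* **Synthetic cohorts** — logistic-normal subject variation around a
  documented template profile, targeted case/subgroup fold changes
  (default: IgG1 G0-NF × 1.5 in cases), and synthetic linear-mode
  spectra (Gaussian peaks, baseline drift, affine mass error,
  replicate jitter), so the whole chain is testable with known ground
  truth.

## Worked example

```r
library(glycomig)

glycopeptide_mz("IgG2", "G0F")
#> [1] 2602.056        # printed QC mass: 2602.1

build_library()
#> <glyco_library> 66 entries (12 overlap-flagged), m/z 2399.0-3452.3
#>   subclass glycoform hex hexnac fuc neuac       mz overlapped
#> 1     IgG2     G0-NF   3      3   1     0 2398.977      FALSE
#> 2     IgG2      G1-N   4      3   0     0 2414.972      FALSE
#> 3   IgG3/4     G0-NF   3      3   1     0 2414.972       TRUE
#> ...

# simulate a 20 + 20 cohort (4 replicate spectra each) and analyse it
cohort <- generate_cohort(seed = 7)           # IgG1 G0-NF x1.5 in cases
write_cohort(cohort, "simdir", n_replicates = 4)
res <- run_pipeline("simdir/cohort.csv", synth_config(seed = 7), "rundir")

subset(res$stats, feature == "IgG1 G0-NF")[c("mean_a", "mean_b", "p")]
#>   mean_a  mean_b        p
#> 3 0.0116 0.00766 5.34e-11   # the seeded case elevation is recovered

res$cv
#> <cv_result> 5 folds (seed 7): AUCs 0.625, 0.688, 0.750, 0.750, 0.875; mean 0.738
```

`mean_a`/`mean_b` are case/control mean relative abundances recovered
from the synthetic spectra; the cross-validated AUC of 0.738 is what a
single seeded effect on one glycopeptide supports at n = 40 under
leakage-free evaluation.

The same stages are scriptable via the CLI
(`library | simulate | process | traits | stats | train | crossval |
predict | pipeline`):

```sh
Rscript -e 'glycomig::glycomig_main()' simulate --out simdir --seed 7
Rscript -e 'glycomig::glycomig_main()' pipeline --manifest simdir/cohort.csv --out rundir
```

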