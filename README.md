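# somatomap

Does it matter whether a digit map in primary somatosensory cortex (SI) is
measured with an *active* task (the participant moves each digit) or a
*passive* one (each digit is stimulated)? `somatomap` implements the full
analysis pipeline for that comparison as a tested R package over synthetic
data with known ground truth:

* **synthetic cohorts** — five overlapping Gaussian digit fields along the
  dorsomedial–ventrolateral axis, a task gain $g$, an inter-digit
  enslavement mixing matrix $E$ (true pattern for digit $d$:
  $\mu_d(x) = g \sum_e E_{de} a_e e^{-(x-c_e)^2/2w_e^2}$), run-level betas
  with matched GLM residuals, and travelling-wave localiser BOLD series;
* **cluster localisation** — 20 lagged HRF-convolved reference models,
  Fisher-z averaged over four lags per digit and forward/backward runs,
  winner-take-all assignment, per-digit Benjamini–Hochberg FDR (q < 0.01);
* **spatial overlap** — minimum-normalised Dice,
  $|A \cap B| / \min(|A|,|B|)$, on $Z > 2$ thresholded maps, grouped into
  same / neighbouring / non-neighbouring digit pairs;
* **somatotopic index** — z-weighted digit preference per node, circularly
  correlated with cortical position (Jammalamadaka–SenGupta);
* **neighbourhood relationships** — within-cluster selectivity ratios
  (target − neighbours)/target with a 2×2 repeated-measures ANOVA and
  Wilcoxon follow-ups;
* **crossnobis RSA** — residual-prewhitened cross-validated squared
  Mahalanobis distances (unbiased; may be negative), information content,
  leave-one-out typicality with a 3σ outlier rule, Procrustes-averaged MDS;
* **cortical model** — five laterally connected units,
  $r = (I-W)^{-1} u$, probing whether a gain scalar, enslavement mixing, or
  digit-specific input changes reproduce active-vs-passive differences.

See `vignettes/somatomap-methods.Rmd` for the model, conventions and design
choices.

## Worked example

```r
library(somatomap)

# a node responding z = 3 to D2 and D3 and 0 elsewhere prefers "digit 2.5"
digit_preference_index(c(0, 3, 3, 0, 0))
#> [1] 2.5

# a full synthetic study: 15 participants, active gain 1.5 vs passive 1.0
cfg <- pipeline_config(seed = 42)
rep <- run_pipeline(cfg)
unlist(rep$overlap$means)
#>         same    neighbour nonneighbour
#>   0.90423286   0.31496398   0.05517765
c(rep$rsa$info_mean_active, rep$rsa$info_mean_passive)
#> [1] 13.0320015  5.8024428
```

Same-digit overlap dominates neighbours, which dominate non-neighbours —
the spatial signature of a shared somatotopy — while the active task's
higher gain roughly doubles (gain² = 2.25×) the mean inter-digit crossnobis
distance without changing the representational shape.

The numbered drivers under `analysis/` run each stage on that cohort and
write tables under `results/`; e.g.

```sh
Rscript analysis/03_spatial_overlap.R
# mean Dice: same 0.90, neighbour 0.31, non-neighbour 0.06
# same > neighbour p = 9.1e-19; neighbour > non-neighbour p = 4.1e-13 (alpha .025)
Rscript analysis/06_rsa.R
# information content: active 13.03 vs passive 5.80 (p = 2.1e-19)
Rscript analysis/07_cortical_model.R
# hypothesis losses: gain 0.009, enslavement 0.009, digit-specific 0.00856 -> best: digit_specific
# predicted active/passive RDM ratio under digit_specific: 2.14
```

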