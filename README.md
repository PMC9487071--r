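# faceval

Validation toolkit for 3D facial surface models, for clinical researchers
(orthodontics, maxillofacial surgery, facial anthropometry) who need to
quantify how well a reconstructed 3D face model — e.g. one built from
calibrated 2D photographs — agrees with a reference optical face scan.

## What it computes

Given a reference scan and a test model (triangulated meshes in mm, with
named soft-tissue landmarks), the pipeline reproduces the standard
accuracy-validation methodology:

1. **Two-step rigid registration.** A Kabsch least-squares alignment on four
   registration landmarks (bilateral lateral canthus, nose tip, soft-tissue
   nasion) seeds a point-to-surface iterative-closest-point refinement
   (≥ 50 iterations, RMS-change convergence threshold 10⁻³ mm,
   correspondence rejection tolerance 2 mm, 100 % vertex sampling).
2. **Anatomical frame.** Origin at the midpoint of the bilateral tragions;
   x along the tragion line; the soft-tissue Frankfort horizontal plane
   (tragions + right suborbital point) is the x–y plane; left, anterior and
   superior are positive.
3. **Deviation analysis.** Signed point-to-surface distances over
   landmark-cropped regions (facial, perioral), summarized as
   `RMS = sqrt( (1/n) * Σ (x₁ᵢ − x₂ᵢ)² )`, with cohort mean ± t-based 95 %
   CI, color-coded PLY deviation maps, and per-landmark deviations
   decomposed as D, Dx, Dy, Dz in the anatomical axes.
4. **Soft-tissue anthropometry.** The 12 standard measurements: 8 linear
   (Sn–Sto, Sl–Li, Ls–Sto, Li–Sto, Sn–Ls, CphR–CphL, Lch–Rch, N′–Gn′) and
   4 angular (Prn-Sn-Ls, Gl-Sn-Pg′, N′-Prn-Sn, Gl-N′-Prn).
5. **Method-error statistics.** Paired t test; two-way absolute-agreement
   average-measures ICC(A,k) with F-based CI; Bland–Altman bias, limits of
   agreement and their t-based CIs; and exact noncentral-t paired-design
   sample size.
6. **2D photo repositioning geometry.** Leveling angle of the lateral-canthus
   line, the vertical canthus-to-cheilion distance H1, and the lateral-photo
   rotation that matches it.

Because clinical scan pairs cannot be shipped, the package includes a
first-class synthetic generator: smooth face-like height-field meshes with
all landmarks placed analytically, deformed by Gaussian radial-basis bumps
(largest at forehead and cheeks), rigid misalignment and sensor noise — with
the exact per-vertex displacement field returned as ground truth.

## Worked example

```r
library(faceval)

pair <- generate_face_pair(synthetic_face_spec(seed = 1),
                           default_deformation(seed = 1))
reg <- two_step_register(pair$test, pair$reference,
                         pair$test_landmarks, pair$reference_landmarks)
test_reg <- transform_object(reg$transform, pair$test)
frame <- build_facial_frame(pair$reference_landmarks)
for (rg in c("facial", "perioral")) {
  crop <- crop_region(test_reg, pair$reference_landmarks, frame, rg)
  s <- rmse(deviation_field(crop, pair$reference, rg))
  cat(sprintf("%-8s RMSE %.3f mm (mean signed %+0.3f, n = %d)\n",
              rg, s$rmse, s$mean, s$n))
}
paired_sample_size(delta = 0.42, sd = 0.68, alpha = 0.05, power = 0.80)
```

prints

```
facial   RMSE 1.596 mm (mean signed -0.039, n = 5357)
perioral RMSE 0.925 mm (mean signed -0.067, n = 1058)
[1] 23
```

i.e. on the default synthetic pair the reconstruction deviates from the
reference by 1.60 mm RMS over the facial region and 0.93 mm over the
perioral region (both under the 2 mm clinical-acceptability threshold, with
the perioral area reconstructed more faithfully), and a paired validation
study able to detect a 0.42 mm mean difference with SD 0.68 at α = 0.05 and
80 % power needs at least 23 subjects.

`run_validation(run_config(...))` performs the whole sequence and writes
`transform.json`, `report.json`, `colormap.ply` and `run.log`; the CLI
equivalent is `Rscript inst/cli/faceval.R run --config run.json` (after
install: `Rscript -e 'faceval::faceval_main()' ...` or the installed
`cli/faceval.R`). Subcommands: `simulate`, `register`, `deviate`, `measure`,
`reposition`, `agreement`, `samplesize`, `run`.

## Layout

- `R/`, `src/` — implementation (R plus one Rcpp translation unit with the
  grid-accelerated exact point-to-triangle-mesh closest-point query).
- `tests/testthat/` — unit, property and acceptance suites with independent
  oracles (exhaustive closest-point search, brute-force axis-angle rigid
  fitting, explicit two-way ANOVA variance components).
- `vignettes/faceval-methods.Rmd` — the methods vignette: model,
  parameters, numerical choices, limitations.
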