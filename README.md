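# cinemotion

Surrogate-driven respiratory motion models from interleaved 2D cine-MRI.

## The problem

On an MR-Linac, 2D cine-MR images can be acquired throughout treatment by
alternating between two fixed slice locations: a *surrogate* slice from
which low-dimensional breathing signals are extracted, and a *motion* slice
in which the deformation of the internal anatomy (tumour, diaphragm,
vessels) must be estimated. A **surrogate-driven motion model** links the
two: it is built from a short acquisition and afterwards estimates the full
deformation from the signals alone, capturing breath-to-breath variability
and hysteresis that simple phase-based models miss.

`cinemotion` implements and evaluates this workflow for 2D slices, for
researchers in MR-guided radiotherapy and medical image analysis:

* **Surrogate signals** — sub-pixel diaphragm (SI) and skin (AP) edge
  tracking; PCA scores of the surrogate-image intensities; PCA scores of
  the control-point displacements (CPD) from B-spline registration of the
  surrogate slice. Signals are carried to motion-frame times by smoothing
  splines, with analytic temporal derivatives.
* **Motion parameterization** — cubic B-spline control-point displacements
  with **two sliding regions** (lung/mediastinum/abdomen vs chest wall), so
  the composed deformation field may be discontinuous across the sliding
  interface.
* **Correspondence models** — per CPD component `i`, a linear model fitted
  by ordinary least squares:

  `M_i(s1, s2) = c2*s2 + c1*s1 + c0`   (and `+ c3*s3` for 3-signal models)

  over a zoo of 7 two-signal and 3 three-signal surrogate combinations,
  plus a no-model baseline (estimated motion = 0).
* **Evaluation** — deformation field error (DFE, the per-pixel L2 norm of
  estimated minus reference displacement, in mm), pooled mean and 95th
  percentile within evaluation and tumour masks, over a building/test split
  with evenly spaced training subsets (n = 20 … 6) and 4-fold
  cross-validation.
* **Synthetic data** — a seedable cine-MR generator (analytic thorax
  phantom, Lujan-type variable breathing with hysteresis and optional
  breath-holds, exactly linear ground-truth motion on the control-point
  grids, interleaved rendering with noise and pre-steady-state frames), so
  the whole pipeline is testable end to end without patient data.

## Worked example

```r
library(cinemotion)

sim <- simulate_dataset(seed = 1)                       # ~63 s at 1.9 fps, 128x128
ds  <- prepare_synthetic_dataset(sim, registration = FALSE)
cat("discarded pre-steady-state surrogate frames:", ds$n_pre_steady_discarded, "\n")
cat("motion frames retained:", length(ds$motion_times), "\n")

zoo <- model_zoo()[c("dia+deriv", "dia+skin", "pc1_pc2_int", "skin+deriv", "no_model")]
res <- run_experiment(ds, zoo, make_split(length(ds$motion_times), n_grid = 10))
subset(attr(res, "fold_averaged"), mask == "evaluation")
```

Output:

```
discarded pre-steady-state surrogate frames: 3
motion frames retained: 115
       model n_train       mask pooled_mean_mm pooled_p95_mm
   dia+deriv      10 evaluation      0.1046052     0.3597051
    dia+skin      10 evaluation      0.1629422     0.4529418
 pc1_pc2_int      10 evaluation      0.1665064     0.4805100
  skin+deriv      10 evaluation      0.7388003     2.2346480
no-model baseline: mean 1.87 mm, p95 4.81 mm
```

Reading the numbers: without any model, the test frames contain 1.87 mm of
mean residual motion within the evaluation mask (4.81 mm at the 95th
percentile). Driven by ten evenly spaced training frames, the
diaphragm-based and PCA-based two-signal models reduce the mean error by
roughly an order of magnitude on this noise-controlled synthetic dataset,
while the deliberately weak skin-and-derivative model trails the rest —
the qualitative pattern reported on patient data, reproduced under known
ground truth. `plot_training_curves(res)` draws the error as a function of
the training-set size.

Adding `registration = TRUE` (the default) also computes the CPD-based PCA
signals by registering every surrogate frame to an automatically selected
reference frame (~1 min for a full series on one CPU).

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cinemotion.R", package="cinemotion"))')" \
    run-all --seed 1 --out out/
```

## Layout

* `R/` — phantom and breathing generators, B-spline/sliding deformation
  machinery, FFD registration, signal extraction, PCA, correspondence
  models, evaluation protocol, NIfTI/CSV/YAML I/O.
* `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code).
* `vignettes/motion-modelling-methods.Rmd` — the model, the generator's
  design and its limitations, and every numerical choice.
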