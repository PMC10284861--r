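# l2ocert — implicit learning-to-optimize models with trustworthiness certificates

Many scientific imaging and signal-recovery problems come with hard prior
knowledge — pixel values live in [0, 1], reconstructions must agree with the
measurements up to the noise level, signals admit sparse codes — that ordinary
black-box networks can neither guarantee nor explain.  `l2ocert` implements an
alternative: **implicit learning-to-optimize (L2O) models**, whose inference is
the solution of a data-dependent optimization problem

```
N_Θ(d) = argmin_{x ∈ C_Θ(d)} f_Θ(x; d),
```

computed by iterating a tunable operator `x ← T_Θ(x; d)` to its fixed point.
Constraints are enforced by construction, and every design element of the
objective corresponds to a measurable property of the inference.  On top of
this the package provides **trustworthiness certificates**: each inference is
scored by interpretable property values (sparsity, relative measurement error
`‖Ax−d‖/‖d‖`, distance to the constraint set, total variation `‖∇x‖₁`, iterate
residual, proximal residual), each value is ranked against an empirically
calibrated distribution, and labelled `pass` / `warning` / `fail` — `fail`
meaning "worse than 95% of the calibration mass" under the default
(0.95, 0, 0.05) policy.

The package is aimed at researchers in computational imaging and sparse
recovery.  It ships:

* a linear-operator layer with verified adjoints, including an exact
  pixel–line-intersection **parallel-beam Radon operator** (the sparse-angle
  setup — 128×128 image, 30 angles × 183 beams — gives the 5490 × 16384
  system);
* proximal primitives (soft-thresholding, ball and box projections) and a
  spectrally-normalized, provably 1-Lipschitz **learned proximal operator**;
* a **linearized-ADMM** engine for `min f(Kx) + h(x) s.t. ‖Mx − d‖ ≤ δ`;
* three implicit models: LISTA-style sparse recovery, the **implicit
  dictionary model** (`argmin ‖Kx‖₁ s.t. Ax = d` with a learned transform K),
  and constrained **sparse-angle CT reconstruction**
  (`argmin_{x∈[0,1]ⁿ} f_Ω(Kx) s.t. ‖Ax−d‖ ≤ δ`);
* memory-constant **Jacobian-free (JFB) training** — only the final solver
  step is differentiated;
* the certificate system (property values, empirical-CDF calibration,
  labelling, JSON serialization);
* seeded synthetic-data generators for both experiments, so everything runs
  without downloads.

## Worked example: certified CT reconstruction

```r
library(l2ocert)

geom  <- ct_preset_geometry("desk")          # 32x32 image, 10 angles x 47 beams
radon <- build_radon_map(geom)
radon
#> <linear_map 1024 -> 470, norm bound 17.94, explicit matrix>

cal  <- generate_ct_dataset(geom, count = 30, seed = 1, radon = radon)
test <- generate_ct_dataset(geom, count = 1,  seed = 2, radon = radon)

prox  <- learned_prox(1024, image_side = 32, seed = 1)   # 1-Lipschitz by construction
model <- implicit_model("ct", ct_weights(prox), radon, max_iter = 3000)
res   <- infer(model, test$sino_noisy[, 1])
res$state
#> <fixed_point_state: 1820 iterations, residual 4.93e-06, converged>
```

The reconstruction respects the pixel box exactly and the fidelity ball
`‖Ax − d‖ ≤ 0.015‖d‖` up to solver slack, and clearly beats unfiltered
backprojection:

```r
psnr(test$phantoms[[1]], matrix(res$x, 32, 32, byrow = TRUE))
#> PSNR 23.41 dB   (backprojection: 10.74 dB);  SSIM 0.881
```

Certificates are calibrated here on ground-truth property values of the
training split and attached to the inference:

```r
props   <- ct_properties()
records <- lapply(1:30, function(i)
  list(x = as.vector(t(cal$phantoms[[i]])), A = radon,
       d = cal$sino_noisy[, i], prox = prox))
tables  <- lapply(props, calibrate, records = records, source = "ground-truths")
names(tables) <- sapply(props, `[[`, "name")

certify(list(x = res$x, A = radon, d = test$sino_noisy[, 1], prox = prox),
        props, tables, label_policy(0.95, 0, 0.05))
#> certificates:
#>   box_constraint           [ok]    value 0          cdf 0.000
#>   fidelity                 [ok]    value 0.0150002  cdf 0.600
#>   data_regularization      [ok]    value 8.35257    cdf 0.600
#>   => trustworthy
```

Reading the output: the box-constraint distance is exactly 0 (the solver's
last operation is the box projection), the relative measurement error sits at
the fidelity radius 0.015, and the proximal residual is unremarkable relative
to calibration — all three labels pass, so the inference is trustworthy.  An
inference violating any design assumption would be flagged, and the failing
certificate names the model part that erred.

The dictionary experiment runs the same way via
`run_experiment(run_config("dictionary", preset = "desk", seed = 1))`:
it generates signals `x = M s` with hidden `M` and 3-sparse codes, trains the
transform `K` by JFB (about 90 s), and reports reconstruction error, code
sparsity, and certificate fail rates.

## Package layout

```
R/linops.R        linear maps, power-iteration norms, Radon system matrix
R/prox.R          shrink / projections / learned proximal operator
R/solvers.R       fixed-point engine and linearized ADMM
R/models.R        the three implicit models behind one infer() interface
R/training.R      JFB training (closed-form and finite-difference backward)
R/certificates.R  property values, calibration, empirical CDF, labels
R/synthetic.R     dictionary and CT data generators
R/metrics.R       PSNR / SSIM
R/experiment.R    run configs, full experiment pipeline, JSON reports
vignettes/        methods vignette (model, algorithms, design choices)
```
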