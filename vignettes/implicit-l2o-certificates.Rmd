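---
title: "Implicit learning-to-optimize models and trustworthiness certificates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implicit learning-to-optimize models and trustworthiness certificates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l2ocert)
```

## The model class

This package implements *implicit learning-to-optimize* (L2O) models: models
whose inference is defined as the solution of a data-dependent optimization
problem,

$$\mathcal{N}_\Theta(d) \;=\; \operatorname*{arg\,min}_{x \in C_\Theta(d)} f_\Theta(x; d),$$

rather than as a fixed feed-forward computation.  The weights $\Theta$
parameterise parts of the objective and constraints (a step matrix, a
sparsifying transform, a learned proximal operator, step sizes).  Inference is
carried out by iterating a *model operator* $T_\Theta(\cdot\,; d)$ to a fixed
point,

$$x^{k+1} = T_\Theta(x^k; d), \qquad \mathcal{N}_\Theta(d) = \lim_k x^k,$$

which has two consequences that ordinary networks lack:

* **Guarantees.** If $T_\Theta$ is *averaged* — $T = (1-\alpha)\,\mathrm{Id} +
  \alpha Q$ with $Q$ 1-Lipschitz and $\alpha \in (0,1)$ — the iteration
  provably converges, and prior knowledge written into the constraint set
  (pixel ranges, measurement-fidelity balls, linear equations) holds at the
  returned solution up to solver tolerance.  Tightening the stopping tolerance
  approximates the limit to arbitrary precision
  (`iterate_to_fixed_point(tol=)`).
* **Explainability.** Every design element of the objective corresponds to a
  measurable property of the inference (sparsity of a code, distance to a
  constraint set, residual of a proximal operator), so deviations can be
  traced back to the model part that should have enforced them.

Three concrete models are provided behind one interface
(`implicit_model()` / `infer()`):

| kind | problem | iteration |
|---|---|---|
| `sparse_recovery` | $\min_x \tau\|x\|_1 + \|Ax-d\|^2 + \text{(learned quadratic)}$ | $x \mapsto \eta_\theta(x - W(Ax-d))$ |
| `idm` | $\min_x \|Kx\|_1 \ \text{s.t.}\ Ax = d$ | linearized ADMM |
| `ct` | $\min_{x\in[0,1]^n} f_\Omega(Kx) \ \text{s.t.}\ \|Ax-d\|\le\delta$ | linearized ADMM |

Here $\eta_\theta$ is the soft-threshold (shrink) operator, the proximal map
of $\theta\|\cdot\|_1$; `sign(0)` is taken as 0 so the map is continuous.

## The linearized ADMM engine

Both constrained models are instances of

$$\min_x f(Kx) + h(x) \quad \text{s.t.} \quad \|Mx - d\| \le \delta,$$

solved by a linearized ADMM that touches $f$ and $h$ only through proximal
operators and needs only forward/adjoint actions of $K$ and $M$.  Each
iteration updates, in order: the auxiliary $p$ (prox of $f$), the auxiliary
$w$ (projection onto the fidelity ball $B(d,\delta)$), the two dual ascents,
the linearized gradient $r = K^\top(2\nu_1^+ - \nu_1) + M^\top(2\nu_2^+ -
\nu_2)$, and finally the primal $x$ (prox of $h$).  Because the primal update
is the *last* operation, properties enforced by $\mathrm{prox}_h$ — e.g. the
$[0,1]$ pixel box in CT — hold for the returned iterate exactly, not just in
the limit.  Fixed points of the iteration satisfy the KKT conditions of the
problem.

**Step sizes.** The defaults are the conservative rule $\lambda = \alpha =
1/L$ with $L = 1.01\,\max(\|K\|,\|M\|)^2$ and $\beta = \lambda/2$, with
operator norms taken from certified power-iteration bounds
(`estimate_norm()`, safety factor 1.01).  In development we verified that
$\beta = 0.9\lambda$ already diverges on random basis-pursuit instances while
$\beta = \lambda/2$ matches an interior-point LP oracle to below $10^{-8}$
relative error, so the margin in this rule is real, not cosmetic.  The model
constructors rescale $M$, $d$ and $\delta$ by $1/\|M\|$ (an equivalent
problem) so that $L \approx 1$; without this, a Radon matrix with
$\|A\| \sim 30$ would force uselessly small primal steps.

**Stopping.** The residual is the norm of the change of the whole state
tuple $(p, w, \nu_1, \nu_2, x)$ in relative form; stopping on $x$ alone can
trigger prematurely when only the primal stalls.  Runs that hit the iteration
cap are *flagged*, not fatal — surfacing unconverged inferences is precisely
the job of the convergence certificate.

**Initialisation.** Deterministic warm starts: $x_0 = 0$ for the dictionary
model, the rescaled backprojection $A^\top d$ clipped into the box for CT;
auxiliaries at their consistency values $p = Kx_0$, $w = Mx_0$, zero duals.

## Training: Jacobian-free backpropagation

Backpropagating through hundreds of solver iterations would store every
intermediate state.  Instead, training differentiates **only the final
application** of the iteration map at the approximate fixed point (JFB): the
forward solve runs with no derivative tracking, then one tracked step gives
the gradient.  `jfb_forward()` exposes this contract directly — its backward
tape has constant size whatever the fixed-point depth.

Since the environment has no automatic differentiation, the one-step
derivatives are computed in closed form for the shrink operator (w.r.t.
$W, \theta$) and for the L-ADMM step (w.r.t. $K$); the closed forms are
verified against finite differences in the test suite.  For the learned
proximal operator, whose parameter count is tiny (two 3×3 kernels and two
biases), the one-step derivative is taken by central finite differences
(`jfb_gradient()`).  Optimisation uses Adam (defaults
$\beta_1 = 0.9, \beta_2 = 0.999$); batches advance as matrix columns, so a
batch costs a few matrix products per solver iteration.

### The dictionary experiment and its training objective

The implicit dictionary model (IDM) learns a square transform $K$ such that
signals $x = Ms$ with hidden dense $M$ and sparse codes $s$ are recovered
from under-determined measurements $d = Ax$ by
$\arg\min \|Kx\|_1 \ \text{s.t.}\ Ax = d$.  A transform that (nearly)
annihilates the signal subspace $\mathrm{range}(M)$ makes every true signal
the unique minimiser, so training can in principle reach exact recovery.

Three design choices matter here, all found necessary during development:

1. **Spectral normalization of $K$** after every Adam step.  The argmin is
   invariant to the scale of $K$, but the finite-iteration training loss is
   not: without normalization the optimizer inflates $\|K\|$, which shrinks
   the solver's step sizes and "improves" the truncated-solve loss without
   improving the model.
2. **A sparsity term on the training targets.**  Reconstruction MSE alone
   reaches good recovery but leaves $\|Kx\|_0$ high: once inferences match
   targets the MSE gradient vanishes and nothing pushes $K$ to sparsify
   the signal range.  The default IDM objective therefore adds
   $\mu\,\overline{\|Kx^\star\|_1}$ (transform learning on the known training
   targets, $\mu = 0.05$) — the classic dictionary-learning objective, and
   the stated purpose of the model.
3. **A rank-preserving penalty** $\rho\,\|KK^\top K - K\|_F^2$
   ($\rho = 0.5$), which pushes singular values towards $\{0, 1\}$.  The
   sparsity term alone collapses too many singular values, and once
   $\mathrm{null}(K)$ grows past $\mathrm{range}(M)$ it intersects
   $\mathrm{null}(A)$ and the argmin stops being unique.

With these defaults (120 epochs, batch 50, lr $3\times10^{-3}$ with a
1, 1/3, 1/10 piecewise decay, 300 solver iterations per training solve), the
reduced-scale problem ($n=60$, code dimension 12, $m=24$, 3-sparse codes,
500 training / 100 test instances) trains in about 90 seconds on one CPU and
reaches: mean relative reconstruction error $\approx 0.003$, 100% of test
instances below 0.1, and mean $\|K\hat x\|_0$ (tolerance $10^{-3}$) dropping
from $\approx 24$ (the basis-pursuit vertex count at the measurement number)
to $\approx 0$.  These numbers are recomputed, never stored, by the test
suite and `scripts/acceptance.R`.

### CT training

The CT model's learnable parts are the two spectrally-normalized 3×3
convolution kernels (plus biases) of the learned proximal operator
$x \mapsto \tfrac12 x + \tfrac12 g(x)$ with $g$ 1-Lipschitz by construction
(spectral normalization re-imposed after every step, so the averagedness
guarantee survives training).  The constraint certificates below do not
require training — the box and fidelity constraints hold by construction for
trained and untrained weights alike — and the packaged experiments default to
the untrained operator for speed.

## Certificates

Each certificate attaches a `(name, label)` pair to an inference.  A
*property value* maps the inference to a nonnegative scalar where small is
good:

* sparsity: $\|x\|_0$ with a scale-aware tolerance (iterative solvers return
  near-zeros), or the $\ell_1$ norm of the code $K\hat x$ for the IDM;
* fidelity: relative measurement error $\|Ax - d\|/\|d\|$ (rejected for
  $d = 0$, where it is undefined);
* constraints: Euclidean distance to the constraint set;
* smoothness: anisotropic total variation $\|\nabla x\|_1$ (forward
  differences, no wraparound — the simplest faithful reading of the symbol);
* convergence: the final iterate residual $\|x^k - x^{k-1}\|$;
* data-driven regularization: the proximal residual
  $\|x - \mathrm{prox}_{f_\Omega}(x)\|$, zero exactly at fixed points of the
  learned operator.

Calibration (`calibrate()`) evaluates a property on reference records —
either model inferences on training data or ground truths; both sources are
supported and recorded in the table's provenance — and stores the sorted
sample.  A new inference's value $\alpha$ is ranked by the empirical CDF and
labelled **pass** if $\mathrm{CDF}(\alpha) < p_p$, **warning** on
$[p_p, 1 - p_f)$, **fail** otherwise; the default policy is
$(p_p, p_w, p_f) = (0.95, 0, 0.05)$, i.e. fail means "worse than 95% of the
calibration mass".

**Ties.** `empirical_cdf()` defaults to inclusive counting
$\#\{\alpha_i \le \alpha\}/N$ (the right-continuous empirical CDF).  For
*labelling*, `certify()` uses the left-continuous variant
$\#\{\alpha_i < \alpha\}/N$.  The two differ only at atoms, and the
difference is deliberate: a constraint-satisfying model produces a box
distance of *exactly zero* for every calibration record and every new
inference, and a value tied with the entire calibration mass must rank
*with* it (CDF 0, pass), not above it (CDF 1, fail).  This is what "worse
than 95% of the inferences" means, and it yields the by-construction 0%
fail rates for constraint certificates that the whole design promises.

**Calibration source for CT.** The packaged CT experiment calibrates on
ground-truth property values.  Ground-truth images carry the full
measurement-noise norm ($\|Ax^\star - d\| \approx$ noise level $\times
\|d\|$), while the model is constrained to $\|A\hat x - d\| \le \delta$ with
the discrepancy-principle default $\delta = 0.015\|d\|$; inferences therefore
sit at or below the calibration mass and the fidelity certificate passes by
construction, failing only if the solver were to leave the ball materially.

## Synthetic data

The generators define the study conditions and are first-class, tested code:

* `generate_dictionary_dataset()`: one hidden $(M, A)$ pair per dataset
  (Gaussian, columns of $M$ normalized), fresh sparse codes per instance
  with uniform supports and Gaussian magnitudes.  Full-scale defaults
  $n = 250$, $r = 50$, $m = 100$, 5-sparse; the reduced training experiment
  uses $n = 60$, $r = 12$, $m = 24$, 3-sparse (25% of the code dimension,
  comfortably within the recovery regime at $m = 24$).  The suite checks
  that plain least squares fails on these instances (mean relative error
  > 0.3) — the failure that motivates the model.
* `generate_phantom()`: random signed ellipses clipped to $[0,1]$, the first
  ellipse always a positive "body" so every phantom has support (an all-zero
  image has no defined relative error and no anatomical meaning).
* `add_beam_noise()`: per-beam multiplicative noise
  $d_i(1 + \varepsilon_i)$, $\varepsilon_i \sim N(0, 0.015^2)$ — "1.5% noise
  on each individual beam" read as relative noise per beam, the natural
  reading for detector noise.  Zero beams stay zero.
* Geometry presets: `"full"` (128×128, 30 angles × 183 beams — the
  5490 × 16384 sparse-angle system) and `"desk"` (32×32, 10 × 47), the
  latter sized so a full certificate run takes a couple of minutes.

What the generators do *not* emulate: chest-CT anatomy, detector physics
beyond the noise model, correlated codes.  Green tests on these conditions
show the algorithms and certificate mechanics behave as designed; they are
not evidence about clinical data.

## The Radon operator

`build_radon_map()` assembles the exact-intersection (Siddon-style)
parallel-beam system matrix: angles equally spaced on $[0, \pi)$, beam
offsets cell-centred across the image diagonal, entries equal to the exact
chord length of each ray in each pixel, pixels row-major and centred at the
origin.  The adjoint is the exact transpose (unfiltered backprojection).
These conventions are fixed so fixtures are bit-reproducible; correctness is
tested against hand-computed 4×4 rays, per-ray chord-length oracles on
constant images, and one-hot/column identities.

## Numerical choices and limitations

* Power-iteration norm bounds use 40–60 iterations from a seeded start and a
  1.01 safety factor; bounds enter step sizes only as upper bounds, so
  under-estimation is the only failure mode and the safety factor plus
  monotonicity of the estimate guard it.
* `project_ball` treats points within a few ulps of the sphere as inside so
  the projection is exactly idempotent.
* Default solver depths: 6 000 state iterations for the IDM (relative
  state tolerance $10^{-9}$), 3 000 for desk-scale CT.  At these depths the
  remaining fidelity-ball overshoot is below 1% of $\delta$, far inside the
  ~5% gap to the calibration quantile that the fidelity certificate relies
  on.
* Problem sizes in the packaged experiments (desk geometry, 500/100
  dictionary split, 50 CT test instances, 20 basis-pursuit oracle instances)
  were chosen so the full suite and the acceptance script each run in a few
  minutes on one CPU; all are configurable upward.
* The LP oracle (`pracma::linprog`) appears only in tests, as an independent
  cross-check of the L-ADMM implementation — never as the implementation.
* Exact implicit differentiation (solving the adjoint fixed-point equation)
  is out of scope; JFB's preconditioned gradient is the only training path.
* The trading application of the same framework (Davis–Yin splitting over
  market-constraint sets) is out of scope.
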