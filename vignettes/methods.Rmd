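---
title: "cryoperm: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cryoperm: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the membrane transport model and its assumptions, the microfluidic mixer
model, the segmentation backends, what the synthetic data emulate (and do
not), and the numerical and design choices that were genuinely open.

## The two-parameter transport model

A cell exposed to a step in extracellular osmolality exchanges water and
permeant solute across its membrane. The two-parameter (2-p) formalism
tracks the intracellular water volume $V_w$ (µm³) and the amount of
permeant cryoprotectant $N_s$, with no explicit solvent–solute
interaction (reflection) coefficient:

$$\frac{dV_w}{dt} = -L_p A RT\left[(m_{salt}^e + m_{cpa}^e(t)) -
  \frac{N_{salt} + N_s}{V_w}\right], \qquad
\frac{dN_s}{dt} = P_s A\left(m_{cpa}^e(t) - \frac{N_s}{V_w}\right),$$

with total volume $V = V_w + N_s\bar v + v_b V_0$. Here $L_p$
(µm min⁻¹ atm⁻¹) is the hydraulic conductivity, $P_s$ (µm s⁻¹) the CPA
permeability, $\bar v$ the CPA partial molar volume, $v_b$ the
osmotically inactive volume fraction and $N_{salt}$ the fixed
intracellular impermeant content set by isotonic equilibrium. The
water equation is driven by total osmolality, the solute equation by the
CPA concentration difference alone; a permeant step therefore gives the
characteristic shrink–swell excursion whose depth and timing jointly
identify $(L_p, P_s)$.

Assumptions, each a deliberate modelling choice:

* **Constant area.** $A$ is held at the isotonic spherical value
  $4\pi r_0^2$. Captured oocytes stay near-spherical — the zona pellucida
  mechanically supports the membrane — and the alternative
  (volume-dependent $A \propto V^{2/3}$) changes fitted values by a few
  percent while adding a modelling degree of freedom the data cannot
  resolve. `cell_geometry(A =)` overrides the default if wanted.
* **Ideal-dilute osmolality.** Osmolar and osmolal are identified and
  activity coefficients set to one. At ≤ 1.5 M this is a few-percent
  approximation and no virial data for these solutions are bundled.
* **Boundary condition.** The default extracellular schedule is an
  instantaneous step at $t=0$. The capture-region washout time at
  10–20 µL/min is a fraction of a second (`washout_time`), two orders of
  magnitude below the osmotic response time, so the step is adequate; an
  exponential ramp (`perfusion_env(schedule = "ramp")`) is available and
  its time constant can be taken from the mixer model.

Declared default constants (stand-ins a practitioner would refine
per experiment, not measured quantities): isotonic osmolality
0.29 osmol/L, $v_b = 0.19$, cytoplasm radius 35 µm, $T = 296.15$ K
(room temperature), EG $\bar v = 0.0558$ L/mol, PG $\bar v = 0.0735$
L/mol, hydrodynamic radii 0.22 / 0.26 nm and solution viscosity
$10^{-3}$ Pa s for the Stokes–Einstein diffusivities.

### Numerics

`simulate_2p` integrates with `deSolve::lsoda` at `rtol = 1e-10`,
`atol = 1e-12`; at these tolerances the solution is independent of the
step-size control. The reference integrator `simulate_2p_rk4` is a
fixed-step classical RK4 written in C++ and shares no code with the
adaptive path; the suite requires agreement within $10^{-5}$ relative at
1 ms steps across all six EG/PG × concentration scenarios. Closed-form
equilibria (`equilibrium_volume`) pin the long-time limits: the
Boyle–van 't Hoff volume for impermeant challenges and the
equal-concentration balance for permeant ones.

## Fitting

`fit_2p` minimises unweighted squared residuals on normalised volume with
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`, `ftol = ptol =
1e-10`), bounds $L_p \in (0, 100]$, $P_s \in [0, 100]$. Measurement
noise on image-derived volumes has no strong structure across a
trajectory, so unweighted least squares is the natural loss. Five
log-spaced multi-starts around (0.5, 0.5), drawn from a seeded stream
(seed 1729), guard against the shallow valley that couples the two
parameters; supplying `init` replaces the multi-start. The covariance is
the Jacobian linearisation at the optimum. Trajectories whose excursion
stays above 0.97 carry almost no information and are flagged weakly
identifiable rather than silently fitted. Forward solves inside the fit
run at `rtol = 1e-8`, tight enough that fitted parameters move by far
less than the Monte-Carlo spread.

The recovery study (`analysis/04_permeability_fits.R`, mirrored in the
tests) is the module's calibration: noise-free self-fits return the
generating parameters to better than 0.1%, and 50 replicates at noise
sd 0.01 recover both parameters with median absolute relative error
under 5%.

## The serpentine mixer

At 10 µL/min in a 200 × 150 µm duct the Reynolds number is ≪ 1 and the
axial Péclet number ≫ 1: momentum is the analytic laminar profile,
axial diffusion is negligible against advection, and there are no Dean
vortices to fold the interface. The full 3-D finite-element model
therefore reduces to the parabolized equation
$u(y)\,\partial_x c = D\,\partial_y^2 c$ across the channel width, with
plane-Poiseuille $u(y)$, zero-flux side walls, and the two streams
entering side by side with the interface placed at the Poiseuille
flux fraction $Q_1/(Q_1+Q_2)$ (a fractional interface cell keeps the
inlet flux-weighted mean exact). Serpentine bends are straightened into
an equivalent unrolled length.

The axial march is backward Euler; the cross-stream operator is the
standard second-order zero-flux Laplacian on a cell-centred grid, and
the constant tridiagonal system is LU-factorised once per solve. The
scheme conserves the flux-weighted mean exactly (the discrete operator
has zero column sums against the velocity weights) and satisfies the
maximum principle; both are asserted on every solve. Grid studies that
refine $\Delta y$ with $\Delta x \propto \Delta y^2$ observe order ≈ 2.

The paper-facing operating point: EG diffusivity $9.86\times10^{-10}$
m²/s at 296.15 K gives 99% mixing after ≈ 155 mm of unrolled channel;
mixing-complete results therefore use an unrolled length of 300 mm
(`channel_geometry(L = 3e5)`), the package's reading of "long enough to
mix" — the physical chip's unrolled length is not a bundled constant.
At that point the flux-weighted outlet concentration of a 1.5/0.5 M
equal-flow pair is 1.0 M (the inlet average) and a single-inlet tracer
homogenises to half its feed value, the two printed mixer facts the
acceptance script recomputes. The capture-region wall shear estimate is
the wide-duct formula $6Q/(WH^2)$ — 222 s⁻¹ at 10 µL/min.

## Segmentation

Masks follow the 255/0 convention and cover the cytoplasm only; the zona
pellucida ring is excluded, matching how the training annotations are
defined. Volumes use the equivalent-sphere rule
$r_{eq} = \sqrt{A_{px}\,s^2/\pi}$, $V = \tfrac43\pi r_{eq}^3$; normalised
volumes are pixel-size invariant.

**Classical backend.** Gaussian smoothing, then a two-threshold
(three-class) Otsu: the intensity histogram is trimodal (dark cytoplasm,
intermediate zona, light background) and a single two-class threshold
reliably lands on the zona mode. The final cytoplasm cut is placed at
the midpoint of the cytoplasm and zona class medians — the
half-intensity contour of a symmetric blurred edge, which is unbiased in
radius (a plain erosion of the object by a nominal zona thickness is
available as an alternative). Largest-component and hole-filling
cleanups enforce the single-object convention, a contrast guard returns
an empty mask on featureless frames, and detections under 500 px are
treated as "not found".

**Network backend.** A compact contracting/expanding architecture:
`depth` levels of two 3×3 convolutions + ReLU and 2×2 max-pooling, a
two-convolution bottleneck, mirrored expanding levels with nearest
up-sampling and skip concatenation, one final 1×1 convolution and
sigmoid. Loss is binary cross-entropy; inputs are standardised per
frame; optimisation is per-image Adam; the best-validation checkpoint
is returned; the only randomness is the seeded shuffle, so runs are
exactly reproducible. It is implemented natively in R (im2col + BLAS
GEMM with hand-written backprop, gradient-checked against finite
differences in the suite). The default working scale for training
demonstrations is a 64 px canvas with `depth = 2`, `base_filters = 8`
(≈ 30k parameters) and a 200/25 train/validation split over 10 epochs —
a deliberate scale-down of a 2000/250, 100-epoch, 256 px training
campaign that the generator can also produce (`paper_scale = TRUE`);
the architecture itself is size-agnostic and the 256 px shape contract
is tested. At the working scale the network reaches ≈ 0.99 validation
pixel accuracy, the skip-connection ablation strictly lowers it, and
network and classical masks agree at Dice ≥ 0.97 on clean frames.

## Synthetic data: what it does and does not emulate

Rendered frames contain one circular oocyte — cytoplasm disk, zona
annulus of fixed outer radius (the zona does not shrink with the
cytoplasm), logistic-soft edges — on a brighter background with optional
linear illumination gradient and i.i.d. Gaussian pixel noise clipped to
[0, 255]; intensities default to cytoplasm 90 / zona 140 / background
180, a declared bright-field-like contrast. The cytoplasm radius follows
$r(t) = r_0\,v(t)^{1/3}$ from a 2-p trajectory, so mask area is strictly
monotone in volume and the area minimum lands at the trajectory minimum.
Default frame cadence is one frame per 2 s over 600 s at 1 µm/px —
declared values, as acquisition settings are rig-specific.

Circularity is the modelled regime on purpose: irregular or aspherical
cells are excluded upstream in this kind of analysis, so the generator
produces only what the estimator is meant to see. The generator does
not emulate optics (PSF, depth of field), cumulus debris, pillar
shadows, or motion; passing the recovery suite therefore demonstrates
correctness of the computational chain, not robustness to real-world
image artefacts. Every generator output is a pure function of its spec
and seed.

## Degenerate inputs and tie-breaks

Non-increasing time grids, non-positive volumes and out-of-range
parameters are rejected at construction. `min_volume` breaks ties by
earliest time. Empty masks are valid "not found" results for single
frames; in sequences, isolated interior gaps are linearly interpolated
and anything worse (edge gaps, runs, or > 20% empties) invalidates the
trajectory. Fits that fail every start return `converged = FALSE` with
diagnostics rather than a silent result; the concentration series marks
itself partial if any member fit fails. The trend label uses the sign
of the Spearman correlation with a 2% relative spread floor below which
the series is called flat.

## Problem sizes

The suite and the analysis scripts run everything at sizes chosen to
make a complete desk verification quick while preserving the phenomena:
61–301-point trajectories, 50-replicate Monte-Carlo, a 200/25 benchmark
(256 px for the classical backend, 64 px for network training), and
mixer grids of 30–240 cross-stream cells. Each scale is stated where it
is used and is the package's own choice of working size.

## Known limitations

* No three-parameter (reflection-coefficient) variant, no temperature
  dependence (Arrhenius) and no intracellular ice: concentration
  dependence at one temperature is the target analysis.
* The mixer model is 2-D parabolized; it does not resolve the pillar
  wakes or the capture-structure comparison, and its shear estimate is
  the wide-duct formula.
* Default cell constants ($v_b$, isotonic osmolality, CPA constants)
  are field-typical stand-ins; absolute fitted values track them, while
  the recovery properties (self-consistency, trend detection) do not.
* The network backend is CPU-native and compact; it is built for
  verifiable correctness at desk scale, not for GPU-scale training.
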