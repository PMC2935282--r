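---
title: "Smooth bulk-solvent models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smooth bulk-solvent models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoothsolv)
```

# The model

Disordered solvent fills the channels of a macromolecular crystal and
scatters as a near-featureless continuum. `smoothsolv` models that
continuum through a solute *characteristic function* $\chi(\mathbf{r})$
on a grid over one unit cell — 1 inside the molecule, 0 in bulk — and
combines its Fourier transform with the atomic structure factors by
Babinet's principle:

$$ F_t(h) \;=\; F_c(h) \;-\; k_s\, e^{-B_s s^2/4}\, F_m(h), $$

with $F_m$ the transform of $\chi$ (electron-count convention, cell
volume over grid points), $s = 1/d$, $k_s$ the bulk electron density in
e Å$^{-3}$ and $B_s$ an isotropic smearing factor in Å$^2$. Because the
transform of a constant volume vanishes at every non-origin frequency,
subtracting the scaled solute-mask transform is identical to adding the
transform of the solvent region; the package's tests pin this identity
to FFT round-off for all three mask models. The zero-frequency term
F(000) is excluded from every reflection list.

Two smooth masks are provided, plus the classical binary reference:

* **Gaussian**: atoms contribute unit-height Gaussians with
  $\sigma_i = 0.55\, r^{vdW}_i$; the summed density $\rho$ is
  thresholded as $\chi = 1 - e^{-A\rho}$, $A = 11.5$. The transition is
  smooth everywhere and approaches its 0/1 limits exponentially — the
  solvent side reaches bulk density a few Å beyond the van der Waals
  surface, about where the first hydration shell sits in solvent radial
  distributions around proteins.
* **Polynomial**: a multiplicative cubic switch with compact support.
  With window coordinate $d = r - a + w$ and $t = d/2w$:
  $S = 1 - 3t^2 + 2t^3$ for $0 < d < 2w$, clamped to 1 and 0 outside;
  solvent density $\prod_i (1 - occ_i S_i)$. $S$ is $C^1$ at both
  endpoints, the mask is *exactly* 0/1 outside the transition shells,
  and one pass over the atoms suffices.
* **Binary**: solute = points within $r^{vdW} + probe$ of an atom,
  then every solute point within *shrink* of a solvent point is
  reassigned to solvent (both radii 1.0 Å by default). Indicator-valued,
  hence not differentiable; `coordinateGradients` refuses it.

Both smooth masks are differentiable in the atomic coordinates. For the
Gaussian model
$\partial\chi/\partial\alpha_i = A\,\rho_{solv}(\mathbf{r}_g)\,occ_i\,
e^{-r^2/2\sigma_i^2} (r_{g,\alpha}-r_{i,\alpha})/\sigma_i^2$, which is
why the real-space *solvent* mask ($1-\chi$) is retained after the
forward pass; the polynomial analogue divides the solvent product by the
atom's own factor and multiplies by the switch slope. The gradient of
any reflection-space target then needs three steps: scale the
per-reflection target derivative by $-k_s e^{-B_s s^2/4}$, inverse-FFT
those coefficients into a real-space derivative map, and accumulate each
atom's mask derivative against that map over the atom's support.
Contributions arriving through symmetry images are rotated back onto the
unique atom with the Cartesian form of the operator rotation.

The refinement target is the least-squares amplitude residual
$T = \sum_{work} w\,(|F_{obs}| - k|F_{model}|)^2$ with unit weights and
the overall scale $k$ refit in closed form at every evaluation; by the
envelope theorem the refit leaves all analytic derivatives valid. A
log-likelihood target would slot into the same machinery — the solvent
chain consumes any per-reflection derivative — but only least squares is
implemented. R factors use a single overall scale fit on the work set
and applied unchanged to the free set.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `A` | 11.5 | — | Gaussian threshold sharpness |
| `sigmaScale` | 0.55 | — | $\sigma$ as a fraction of the vdW radius |
| `supportSigma` | 5 | $\sigma$ | Gaussian truncation radius |
| `w` | 0.8 | Å | polynomial window half-width |
| `probe`, `shrink` | 1.0, 1.0 | Å | binary surface radii |
| `ks`, `bs` (start) | 0.33, 50 | e Å$^{-3}$, Å$^2$ | bulk water density; boundary smearing |
| grid spacing | $d_{min}/3$, clamped to [0.57, 0.9] | Å | mask sampling |

`A` is treated as dimensionless: it scales the summed density inside the
thresholding exponential, and with $\sigma = 0.55\,r^{vdW}$ it places
the half-height of an isolated atom's transition a little outside the
vdW radius — for a 1.75 Å atom both models cross $\chi = 0.5$ within
1 Å of each other, so the two masks describe the boundary similarly.
An alternative convention multiplies each atomic exponent instead;
either yields characteristic-function behavior, differing only in
transition sharpness, and the summed-density placement is the one
implemented. Grid dimensions are rounded up to 2/3/5/7-smooth integers
for FFT efficiency. vdW radii come from a bundled Bondi-style table with
per-atom overrides, since no single authoritative set exists.

# Periodicity and symmetry

The solvent density is many-body: a grid point may be covered by several
atoms, including symmetry- and lattice-related copies. The package
expands the unique atoms once per symmetry operator
(`expandSymmetryShell(model, 0)`) and handles *lattice* periodicity
exactly by minimum-image distance inside every grid query: with all
support cutoffs below half the smallest perpendicular cell width
(enforced), no grid point can see two lattice copies of the same atom,
so the minimum image is the only image. This replaces the common
implementation device of instantiating explicit atom copies in a
fixed-width (e.g. 4 Å) shell around the cell: the shell's inclusion test
makes the target minutely discontinuous when an atom crosses the shell
boundary during finite-difference probes, whereas the minimum-image
formulation is continuous by construction and has no shell-width
parameter to tune against the mask support. `expandSymmetryShell` with a
positive shell width remains available as a spatial-decomposition
utility (and is pinned by a brute-force enumeration test), but mask
accumulation must receive each physical atom exactly once.

# Numerical choices

* **Gaussian truncation.** Each atomic Gaussian is truncated at
  `supportSigma` = 5$\sigma$ by *tail subtraction*,
  $\max(g(r) - g(5\sigma), 0)$, so $\rho$ is continuous at the support
  edge; the per-atom error is below $4\times10^{-6}$. A hard cutoff
  would make the target jump by a comparable amount whenever a grid
  point crosses the support sphere — harmless for mask values, but
  large relative to a $10^{-4}$ Å finite-difference probe.
* **Polynomial zeros.** The solvent product is formed directly (no log
  accumulation): exact zeros inside atom cores are meaningful, and the
  gradient's $\rho_{solv}/h_i$ ratio is guarded to zero where $h_i$
  underflows — there the switch slope is itself vanishingly small, so
  the discarded contribution is negligible by construction.
* **Degenerate inputs.** Cells with non-positive volume, windows wider
  than an atom radius, cutoffs beyond half the cell width, empty work
  sets, F(000) in a reflection list, and gradient requests for the
  binary mask are all errors, not warnings.
* **Relative gradient error.** Gradient verification uses
  $|g_{ana} - g_{fd}|/(|g_{ana}| + 10^{-12})$ with double-wide central
  differences at $\Delta x = 10^{-4}$ Å. When a single component passes
  near zero this statistic is dominated by ordinary finite-difference
  truncation error (the absolute discrepancy stays at the $10^{-6}$
  level and vanishes as $\Delta x \to 0$); the verification experiments
  therefore fix the seed of the fixture they quote.
* **Optimizer.** L-BFGS-B over $(k_s, B_s)$, both bounded below at
  zero, analytic derivatives, restarted until the rms *projected*
  gradient falls below $10^{-5}$; an optional coarse grid search over
  $k_s \in [0, 0.6]$, $B_s \in [0, 300]$ can precede it. The
  anisotropic overall scale is available as a separate multiplicative
  correction (`applyAnisoScale`) with the quadratic form evaluated in
  the Cartesian reciprocal metric.

# The synthetic fixtures

`toyCrystal` places a seeded cluster of C/N/O/S atoms (periodic minimum
separation 2 Å, B factors uniform in [10, 30] Å$^2$, unit occupancy)
inside a P1 cell of a few tens of Å, plus one water-like oxygen
2.8–3.4 Å outside the cluster surface — the atom the translation-scan
experiments move into bulk in 0.05 Å steps with the solvent scale held
fixed. `syntheticObservations` generates $|F_{obs}| = |F_t|$ under a
chosen true mask model and $(k_s, B_s)$, optionally with relative
Gaussian noise on amplitudes (noise on amplitudes, not intensities,
because the target operates on amplitudes), and flags 10% of
reflections free. The standard verification fixture is 20 atoms in an
18×20×22 Å cell at $d_{min} = 2$ Å (≈2100 reflections, 27×30×35 mask
grid), truth Gaussian at $(0.40, 70)$, evaluated from the standard
start $(0.33, 50)$; these sizes keep a full per-coordinate
finite-difference sweep of both smooth models inside a few seconds
while exercising triclinic-capable code paths elsewhere in the suite.

What the toys emulate: a compact solute in majority solvent, a
low-resolution–dominated solvent signal, surface waters, symmetry
images, free-set bookkeeping. What they do not: realistic
macromolecular packing, chains and residues, experimental error
models, anisotropy of real data, or the deposited-structure scaling
pipelines of production refinement programs — so passing tests show the
*mathematics* (masks, transforms, derivatives, optimization) is
implemented correctly, not that R factors on real structures will match
any particular published run.

# The continuity contrast

The discriminating experiment between binary and smooth models moves
the water atom into bulk and compares derivative traces. The atomic
scattering term $F_c$ contributes an identical, smoothly varying
derivative to every model; the models differ only in the solvent term.
The package therefore reports fluctuation (`scanFluctuation`) on the
*solvent-term* numerical derivative — the finite difference minus the
analytic atomic chain term, which exists for every model including the
binary one — as the standard deviation of its step-to-step differences.
For the smooth models this trace is the (smooth, slowly varying)
solvent derivative; for the binary model it spikes whenever mask points
flip, and the finite-difference step is widened to 0.01 Å there to
avoid aliasing against the mask grid. On the raw total-derivative
sequence the contrast would be diluted by the moving atom's own
scattering curvature, which on a 20-atom toy is far larger relative to
the solvent term than in a real structure.

# Limitations

* Least-squares target only; the likelihood target is an extension
  point, not implemented.
* P1 plus user-supplied operator lists; no space-group tables, no
  mmCIF coordinate input, no alternate conformers, no TLS/ANISOU
  refinement (ANISOU records are read and ignored).
* $(k_s, B_s)$ and overall scales are the only fitted parameters;
  coordinate refinement itself (minimization, annealing) is out of
  scope — the gradients are the interface to it.
* The binary mask's shrink pass operates on the grid (solvent dilation
  by the shrink radius), equivalent on-grid to an atom-sphere re-scan
  and pinned by a brute-force oracle test.
* Higher-order (quintic and beyond) switches and per-element $\sigma$
  tables are not provided.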