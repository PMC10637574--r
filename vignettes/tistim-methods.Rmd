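---
title: "Methods: interferential-field modeling in tistim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interferential-field modeling in tistim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and limitations behind
`tistim`. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The interference model

Interferential stimulation injects two transcranial current patterns
$\mathbf{s}_1, \mathbf{s}_2$ (mA, each summing to zero) at nearby
frequencies $\omega_1, \omega_2$. With the lead field $A(\mathbf r)$ — the
linear map from electrode currents (against a fixed reference) to the
E-field vector at brain location $\mathbf r$ — the total field is

$$\mathbf E(\mathbf r, t) = \sin(\omega_1 t + \varphi_1)\, A(\mathbf r)\mathbf s_1
 + \sin(\omega_2 t + \varphi_2)\, A(\mathbf r)\mathbf s_2 .$$

At every point this vector stays in the plane spanned by the two static
per-montage fields and its tip traces a Lissajous curve (`lissajous()`
returns the orthonormal plane basis and the 2-D trace; the out-of-plane
residual is zero up to round-off by construction).

Along a unit direction field $\mathbf d(\mathbf r)$ the scalar signal
$x(t) = \mathbf d^\top \mathbf E$ is a two-tone; its amplitude envelope is
the absolute analytic signal $|x + j\,\mathcal H[x]|$, and its
peak-to-trough depth — the **modulation depth** — has the closed form

$$\mathrm{MD}(\mathbf r) = 2\,\min\bigl(|\mathbf d^\top A \mathbf s_1|,\;
 |\mathbf d^\top A \mathbf s_2|\bigr),$$

i.e. the modulation is set by the weaker of the two projected components.
`md_static()` uses this closed form (cheap, exact); the numeric envelope
route exists independently in `envelope()` and serves as its oracle in the
tests: over the trusted region, $\max - \min$ of the envelope must agree
with the closed form. The instantaneous depth
$\mathrm{MD}(\mathbf r, t) = |\tilde E| - \min_t |\tilde E|$ (`md_instant()`)
is a visualization quantity: zero at the envelope's trough, equal to the
static MD at its crest.

Conventions: positive current flows into the head; $\varphi_1 = 0,
\varphi_2 = \pi$ by default (a cosmetic choice that makes the two drives
visibly counter-phased; both are configurable); direction modes are
`radial_in` (unit vector toward the head-centre origin; at the origin
itself the radial direction is undefined and an arbitrary fixed unit vector
is used) and `posterior_anterior` (constant $+y$).

## 2. The spherical forward model

MRI-derived finite-element head models are not redistributable, so the
package generates its own volume conductor: concentric spheres sampled on a
regular cubic grid. The default phantom is brain 85 / CSF 88 / skull 91 /
scalp 92 mm with conductivities 0.2 / 1.65 / 0.01 / 0.465 S/m — standard
literature values, configurable; they are a stand-in, not a reproduction of
any individual head.

`solve_laplace()` discretizes $\nabla\!\cdot\!(\sigma\nabla V) = 0$ with a
7-point finite-difference stencil. Face conductances use the harmonic mean
of the two adjacent node conductivities (the correct series composition for
flux across an interface); faces leaving the head mask carry no current
(insulating Neumann boundary). Electrodes are circular scalp patches
(default radius 6 mm, a high-definition electrode) receiving a uniform
share of the injected current over the patch's outer-shell nodes — point
sources would make the discrete potential singular. The pure-Neumann system
is singular with a constant null space; the gauge is zero mean over the
head. The E-field ($-\nabla V$ by central differences, one-sided at mask
edges) is gauge-invariant.

Solvers: sparse Cholesky with one grounded node for systems up to 2e5
unknowns (exact up to the gauge, and the factorization cost is amortized
over the 1-per-electrode solves of `build_leadfield()`), Jacobi-
preconditioned conjugate gradients with null-space deflation above that
(default relative-residual tolerance 1e-8). Validation is against the
truncated Legendre series for a point-source pair on a homogeneous sphere:
the suite checks < 5% relative L2 error on a near-surface shell at 4 mm
spacing (excluding two patch radii around each electrode, where the
patch/point discrepancy and the discretization singularity live) and
non-increasing error at 2 mm.

Grid defaults: 4 mm spacing for production phantoms, 8 mm in the examples,
demo pipeline and tests, where a 17-electrode lead field builds in a few
seconds; all sizes in the tests were chosen as desk-scale study conditions.

## 3. The envelope estimator

The analytic signal is computed by FFT half-spectrum doubling. Finite
records leak spectral energy across DC, which corrupts the envelope near
the record edges, so:

* records that already wrap around smoothly — first sample within 3% of the
  linear extrapolation of the last two, e.g. an integer number of carrier
  and beat cycles — are transformed as-is (the FFT is near-exact there, and
  any padding would only inject spurious content);
* all other records are mirror-padded by one beat period per side, with the
  padding tapered to zero by a cosine ramp (plain mirror padding merely
  relocates the wrap-around jump; the taper removes it), then cropped.

The first and last 5% of samples are flagged untrusted in every case and
excluded from envelope-derived statistics. Protocol time grids exclude the
endpoint (samples $t_k = k/f_s$, $k = 0..N-1$), the convention under which
integer-cycle records are exactly periodic.

One limitation is intrinsic, not numerical: when a record holds only a few
carrier cycles (e.g. 10 Hz over 1 s at frequencies that do not divide the
record), *no* estimator recovers the envelope to better than a few percent
— the positive- and negative-frequency components are not separable. The
property tests therefore draw carriers log-uniformly from 10–2000 Hz with
beat frequencies 5–20% of the carrier and records covering at least two
beat cycles *and* 100 carrier cycles; the kilohertz regime of practical
stimulation easily satisfies this. The protocol validator enforces a
sample rate of at least 50 x the faster carrier (default 100 x) and at
least two beat cycles.

## 4. Montage optimization

**Two pairs** (`search_pairs()`): exhaustive enumeration over all disjoint
anode–cathode pairs (the reference electrode is an eligible pair member)
and a current split $r, 1-r$ over a ratio grid (default
$0.1, \dots, 1.0$). The selection key is (1) maximal MD at the target along
the requested direction, (2) minimal focality length among MD ties, (3) a
lexicographic electrode-label key — making the result deterministic and
order-invariant. Within a pair the anode is the lexicographically smaller
label, which is WLOG because MD is sign-invariant. Enumeration is
$O(n^4 |grid|)$ and vectorized; it is intended for layouts up to a few
dozen electrodes.

**Two arrays** (`optimize_arrays()`): minimizes
$J = -\mathrm{MD}(\mathbf r_t) + \lambda \sum_{\mathbf r \ne \mathbf r_t}
\mathrm{MD}(\mathbf r)^2 v(\mathbf r)$ over both current vectors, with node
volumes $v$ in cm³, subject to per-electrode bounds, a per-frequency budget
on total injected current, and zero net current. Three numerical choices
matter:

* *Homogeneity.* MD is degree-1 and the energy degree-2 under a uniform
  current rescaling, so for any fixed current *pattern* the optimal scale
  is closed-form: $c^\ast = \min(1, \mathrm{MD}/2\lambda E)$ on the
  feasible segment. The optimizer (BFGS, multi-start) searches patterns
  scaled to the feasible boundary and applies $c^\ast$ analytically. This
  keeps all iterates exactly feasible and sidesteps the ill-conditioning of
  penalized formulations, where iterates collapse to current scales at
  which the soft-min temperature is no longer meaningful. A corollary used
  as a property test: scaling the bounds by $c$ and $\lambda$ by $1/c$
  scales the optimal MD by $c$.
* *Smoothing.* $\min(|p_1|, |p_2|)$ is non-smooth; the search uses a
  log-sum-exp soft-min at temperature $\mu = 10^{-3}$ V/m on
  $\sqrt{p^2 + \varepsilon}$; all reported values use the exact hard form.
* *Restarts.* The problem is non-convex; 8 seeded random starts by default,
  plus the two-pair solution when supplied as `init`. Diagnostics record
  every start's objective and convergence flag, and the seed.

With $\lambda > 0$ the energy term sets the optimal current scale, which
typically sits well below the bounds: the optimizer trades absolute target
MD for relative focality (a warning reports when the target MD falls below
the `init` montage's). This matches the method's purpose — the comparison
with the pair search is at *matched* MD shape, and focality is
scale-invariant. With $\lambda = 0$ the bounds saturate and the target MD
is maximal. The value of $\lambda$ (default 1, in units of
(V/m)$^{-1}$cm$^{-3}$) is an explicit configuration choice, not a claim
about any published calibration.

## 5. Metrics

Focality is $\bigl(\sum_{\mathrm{MD} > 0.5\,\mathrm{MD}_t} v\bigr)^{1/3}$
in cm — invariant to map rescaling, monotone under dilation of the
suprathreshold set. Node volume is the grid-spacing cube restricted to the
brain mask; no partial-volume correction. Hotspots are 6-connected
components above a relative threshold (default 0.5, mirroring the focality
definition), sorted by peak MD; the paper-style observation that hotspots
need not lie midway between electrode pairs, and need not be unique, is
directly visible in `hotspots()` output on the demo phantom.

## 6. Visualization and pipeline

All figures are built data-first: `render_montage()`, `render_slice()` and
`animation_frames()` return the exact arrays they draw (tested for
bit-identity with the interference module; rendering style is not part of
any contract). Slice maps never interpolate. Animation color limits are
fixed across frames. Per-frame slice maps use the closed-form two-tone
envelope (pointwise exact for a two-tone) rather than re-running the
Hilbert pass over every node and frame; the probed-node traces use the
numeric `envelope()` so that what is drawn *is* the EnvelopeSeries.
`animate()` writes a PNG frame sequence ready for an external encoder;
no video codec bindings are assumed.

`run_pipeline()` chains phantom → lead field → optimization → simulation →
report (→ frames) from one config; every artifact is checksummed into a
manifest and all randomness flows from the single configured seed, so a
config plus seed reproduces byte-identical outputs.

## 7. What the phantom does and does not show

The synthetic head reproduces the *physics* of interferential stimulation —
superposition, envelope formation, direction sensitivity, the array-vs-pair
focality trade-off — under idealized geometry. It does not reproduce
numbers tied to a specific segmented head: realistic electrode positions,
montage tables, or centimeter-level focality values from FEM studies.
Conclusions drawn from the tests are about the correctness of the
implementation and the qualitative structure of the method, not about any
individual anatomy. Cortical-sheet-aligned direction fields, neuronal
response models and multi-subject statistics are out of scope.
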