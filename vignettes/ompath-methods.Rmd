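---
title: "Transition states from Onsager-Machlup action minimization: models, numerics and design choices"
author: "ompath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition states from Onsager-Machlup action minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ompath)
```

## The model

Functional conformational changes of proteins — domain motions, induced
fit, the opening and closing of binding sites — are largely rigid-body
rearrangements that a coarse elastic description captures well.  `ompath`
represents the two equilibrium structures $a$ and $b$ as minima of two
anisotropic-network-model (ANM) harmonic wells: every heavy-atom pair
within a cutoff (default 15 Å) is connected by a spring of uniform
stiffness $\gamma$ (default 0.01), giving a $3N \times 3N$ Hessian per
well.  The most probable stochastic path between the wells is the
minimizer of the Onsager–Machlup (OM) action; within each harmonic well
the Euler–Lagrange equations decouple in the Hessian's eigenbasis and
every mode follows a hyperbolic-sine time course,

$$x_l(t) = V\,\mathrm{diag}\!\left(\frac{\sinh(\lambda_i t)}{\sinh(\lambda_i \bar t)}\right) V^\top (\bar x - a) + a ,$$

with the zero (rigid-body) modes interpolating linearly in $t$.  The
right branch mirrors this from $b$.  The two branches meet at the cusp
$\bar x$ — the transition state — where position and velocity are
continuous.  Velocity continuity is a linear condition,

$$\left(V L V^\top - W R W^\top\right)\bar x \;=\; V L V^\top a - W R W^\top b ,$$

where $L$ and $R$ are diagonal with entries
$\lambda_i \coth(\lambda_i \bar t_l)$ and
$\lambda_i \coth(\lambda_i (\bar t_l - t_f))$ (zero modes: $1/\bar t_l$
and $1/(\bar t_l - t_f)$).  `solve_transition_state()` solves this
system directly — never by explicit inversion — and reports the relative
velocity-continuity residual and the condition number.  The energy gap
between the wells follows from the cusp,
$\Delta E = \tfrac12 (\bar x - b)^\top H_b (\bar x - b) -
\tfrac12 (\bar x - a)^\top H_a (\bar x - a)$,
the difference between the transition-state energies measured relative
to each minimum.

## The non-iterative barrier time

Classically, the barrier time $\bar t$ had to be found by iterating the
continuity solve against a user-supplied $\Delta E$ at a chosen total
time $t_f$, and the pair $(t_f, \Delta E)$ selects one of a whole
surface of locally minimum-action paths (the *convergence surface*,
which `convergence_surface()` tabulates for the 1D model).  `ompath`
instead uses the closed-form observation that in the asymptotic
(large-$\bar t$) regime each branch approaches
$x(t) = a + (\bar x - a)e^{-k(\bar t - t)}$: requiring the system to
have covered 10% of the distance to the cusp gives
$e^{-k(\bar t - t)} = 0.1$, i.e. a time offset of $-\ln(0.1)/k$, quoted
throughout as $2.302/k$.  Evaluated at the average force constant of a
well, $\bar k = \mathrm{tr}(H)/3N$, this yields the per-well barrier
times

$$\bar t_l = 2.302/\bar k_a, \qquad \bar t_r = 2.302/\bar k_b,$$

with no iteration at all.  Errors in the uniform $\gamma = 0.01$
assumption partially cancel because both branch times scale the same
way.  `optimal_barrier_time()` uses the constant 2.302 as
conventionally quoted; the three-decimal rounding of $\ln 10$ carries a
$6\times10^{-4}$ relative error, so "10% progress" statements hold to
about three significant figures under the quoted constant and exactly
under $-\ln(0.1)$.

## Truncation of the invariant ends

The hyperbolic time course spends almost all of its time exponentially
close to the end states; this is a property of the OM equations, not of
the molecule.  `truncate_trajectory()` removes the leading frames in
which the system has progressed less than a set fraction (default 10%,
deliberately configurable since the choice is arbitrary) of the distance
to the transition state, and the trailing frames symmetrically.  The
retained path starts at the last frame still below the threshold, so the
truncation vanishes smoothly as the fraction goes to zero.  Replacing
the 10% rule by a 1% rule shifts the computed transition state by well
under 5% of the end-to-end RMSD on our fixtures — the transition state
is insensitive to this choice.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 15 | Å | ANM connectivity radius |
| `gamma` | 0.01 | energy/Å² (arb.) | uniform spring constant, both wells |
| `truncation_fraction` | 0.1 | — | progress threshold for trimming |
| `n_frames` | 100 | — | trajectory sampling (split ∝ branch times) |
| `zero_tol` | 1e-8 | relative | eigenvalue threshold for rigid-body modes |

Energies and times are in arbitrary ANM units ($\gamma$ sets the energy
scale, $1/\bar k$ the time scale); only ratios and structures are
physically meaningful.  No mass weighting is applied (standard ANM
convention; no masses are available at this resolution).

## Numerical choices

- **Hyperbolic functions** are evaluated through exponentials of
  non-positive arguments: $\sinh$ ratios as
  $e^{\lambda(t-\bar t)}(1-e^{-2\lambda t})/(1-e^{-2\lambda\bar t})$ and
  $\coth$ via $(1+e^{-2|x|})/(1-e^{-2|x|})$, switching to the
  asymptote for $|\lambda t| > 30$ and to a series below $10^{-6}$.
  Stiff modes ($\lambda\bar t$ of several hundred under
  $\bar t = 2.302/\bar k$) therefore cannot overflow.  Modes just above
  the zero threshold fall back to linear interpolation.
- **Zero modes** are detected at $\lambda < 10^{-8}\lambda_{\max}$; a 3D
  non-collinear connected structure has exactly six, and more triggers a
  degeneracy warning (collinear, planar or disconnected input — the
  planar-ring fixture exercises this deliberately).
- **Superposition**: the final state is Kabsch-fitted onto the initial
  state before any Hessian or path computation (configurable with
  `superpose = FALSE`), so branch displacements carry no rigid-body
  offset.  Note that superposition composes a proper rotation onto the
  input map; exactly symmetric constructions (the mirror fixture) should
  be solved unsuperposed to observe their exact symmetry.
- **Degenerate inputs**: identical end states return $\bar x = a$ with a
  degenerate-trajectory warning; pairing failures and singular
  continuity systems abort with the failing stage named.

## The 1D diatomic reference model

`double_well_1d()` and friends implement the scalar two-well problem
exactly: branch positions in closed form, the cusp from a bracketed root
search on the monotone velocity-continuity residual (tolerance
$10^{-12}$), and the convergence surface on a $(t_f, \bar t/t_f)$ grid.
This model is the package's independent cross-check — the $3N$ solver
must reproduce it on a diatomic embedded along one axis (the projection
onto the stretch eigenvector carries force constant $2\gamma$) — and the
vehicle for two asymptotic facts: at large $t_f$ the cusp tends to the
stiffness-weighted mean $(k_l a + k_r b)/(k_l + k_r)$, and the system
dwells longer near the minimum of the *narrower* well while climbing out
of it faster.

One subtlety worth recording: the large-$t_f$ invariance of $\Delta E$
is exponential in the 1D model and for the embedded diatomic, but for
generic 3D pairs the rotational zero-mode spaces of the two wells nearly
coincide, leaving near-null directions in the continuity operator that
are regularized only by the $1/\bar t$ entries.  $\Delta E$ then
approaches its limit as slowly as $O(1/\bar t)$, and "invariant" should
be read asymptotically.  The flatness property is therefore asserted on
the diatomic, where the claim is exact.

## Free-energy-surface analytics

For validating transition states against sampled ensembles, 2D
collective-variable samples (e.g. Twist/Hinge angles) are segregated
into an equal-size bin grid (default $15\times15 = 225$ bins) and
Boltzmann-inverted, $\Delta G = -k_BT\,\ln(100\,n_i/N)$, in units of
$k_BT$ (temperature is a pure scale factor and cancels in the saddle
location).  Empty bins are masked rather than imputed: $-\ln 0$ is
undefined and any ceiling value would bias the fitted saddle.

The binned surface is fitted with two anisotropic Gaussian basins with
cross terms over a quadratic background (`fes_model()`), by
Levenberg–Marquardt least squares.  Two design choices here were
genuinely open:

- **Identifiability.**  A background written as
  $C + D(X - Tw_t) + F(X - Tw_t)^2 + \dots$ is over-parameterized: the
  offset, the linear coefficients and the saddle coordinates span only
  five polynomial degrees of freedom among seven parameters.  The fit
  therefore uses the centered convention $D = G = 0$, which makes
  $(Tw_t, H_t)$ the stationary point of the quadratic background and
  every remaining parameter identifiable.  The full uncentered form
  stays available for evaluation.
- **Determinism.**  Initialization is rule-based, never random: the two
  deepest separated local minima of the binned surface seed the basin
  centers, widths start at two bin widths squared, and a quadratic
  regression seeds the background, so refitting the same surface always
  returns the same parameters.  If no second separated minimum exists,
  the second basin is seeded at the farthest occupied bin, and a nested
  refit without the second Gaussian decides whether the surface is
  effectively single-basin (in which case the second amplitude is
  reported as exactly zero rather than left to mimic background
  curvature).

`profile_against_trajectory()` closes the loop with external methods: it
computes, for every frame of any multi-model PDB trajectory, the RMSD to
a reference structure and the two harmonic well energies.  The frame
minimizing $|PE_a - PE_b|$ is the trajectory's implied transition state;
on the package's own paths this frame coincides with the barrier-time
frame, and the same consistency is the basis for comparing against
trajectories from cusp-hopping or string-type methods.

## What the synthetic fixtures do and do not show

`make_two_state_pair()` builds seeded bead structures with 3.8 Å
spacing (so the 15 Å cutoff yields realistic coordination numbers) in
chain, helix or planar-ring templates, displaced by a hinge rotation, a
rigid translation (a deliberately degenerate pair) or a point inversion
through the centroid.  The inversion ("mirror") pair is the canonical
symmetric case: both Hessians share a spectrum exactly and the
transition state is the exact per-coordinate midpoint.
`make_fes_samples()` draws collective-variable samples from the
two-basin density implied by the surface model (cross terms are not used
in sampling).

These fixtures exercise every contract of the pipeline — pairing,
superposition, spectra, continuity, truncation, binning, fitting — with
known ground truth and no downloads.  They do not emulate real force
fields, side-chain packing, solvent, or the B-factor-calibrated spring
constants of crystallographic ANM work, so passing tests demonstrate
the correctness of the mathematics and the numerics, not the biological
accuracy of any particular transition state.  Claims about real systems
(e.g. that heavy-atom and Cα-only transition states nearly coincide for
a myosin converter domain) require the corresponding crystal structures
as input.

## Problem sizes

The test suite and examples run on bead toys of 3–20 atoms and
$15\times15$ binned surfaces, where the dense eigendecompositions and
the Levenberg–Marquardt fits complete in milliseconds and every
closed-form oracle (discretized-action minimization, rotation-grid
superposition, extended-precision hyperbolics) is affordable.  The
implementation itself is dense-linear-algebra throughout and handles
structures of a few thousand heavy atoms (Hessians of order $10^4$) in
desk memory, which covers the single-domain systems this method is
designed for.

## Known limitations

- The ANM double-well is a linearization; strongly anharmonic or
  unfolding transitions are outside its validity.
- $\bar t$ is a parameter of the action, not a physical rate; kinetic
  and thermodynamic interpretation of branch times is deliberately out
  of scope.
- The analytical bi-sigmoid form of the convergence surface is not
  implemented; the surface is tabulated numerically.
- Collective-variable definitions (Twist/Hinge) are not computed from
  structures; any two-column sample table is accepted.
- mmCIF input, NMR ensembles beyond the first model, and ligand
  parameterization are not supported.
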