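---
title: "Trainable spline-parameterized tight binding: models, penalties and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trainable spline-parameterized tight binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`tbtrain` implements a self-consistent-charge tight-binding (SCC-DFTB) model
in which every parameter is trainable while the functional form stays within
what the Slater-Koster file (SKF) format can express:

* per-shell **on-site energies** (trained constants, Hartree) on the
  diagonal of the one-electron Hamiltonian `H1`;
* **electronic channels**: each Slater-Koster channel of each element pair
  (`ss sigma`, `sp sigma`, `pp sigma`, `pp pi`, for `H1` and the overlap
  `S`) is a one-dimensional function of the interatomic distance,
  represented as a fifth-order B-spline on ~100 uniform knots;
* **repulsive potentials** `R`: one third-order spline per unordered
  element pair, truncated at the nearest-neighbor boundary of the pair's
  distance distribution;
* **Coulomb interactions**: the shell-resolved kernel for exponentially
  decaying s-like charge densities, parameterized solely by per-shell
  Hubbard parameters `U` (decay `tau = 16 U / 5`, so the on-site value is
  exactly `U`; the long-range limit is `1/R`);
* a **linear reference energy** `E_ref = sum_Z N_Z C_Z + C_0` that absorbs
  isolated-atom content, so all energy comparisons act on atomization
  energies.

Molecular matrices are assembled by the standard s/p Slater-Koster
geometric transformation; the closed-shell SCC equations are solved by
symmetric (Loewdin) orthogonalization with linear mixing plus Anderson
acceleration (depth 3, engaged after three plain steps; convergence at
`1e-7 e` on the largest shell-charge change, at most 60 iterations;
non-convergence is flagged on the result rather than thrown, so a driver
can exclude and log such configurations). Atomic charges are Mulliken
charge fluctuations with the sign convention that positive charge means
electron deficiency; dipoles are `sum_A q_A R_A` in e*Angstrom.

### Spline representation and boundary conditions

Channels vanish smoothly at long range: value and first derivative are
zero at the cutoff (4.5 Angstrom for electronic channels; the
nearest-neighbor boundary for repulsives). With an open B-spline basis only
the last basis function is non-zero at the cutoff and only the last two
have non-zero derivative there, so pinning the last two coefficients to
zero enforces both conditions *structurally* -- they hold after every
training step by construction, and every penalty and fit remains exactly
linear in the remaining free coefficients. No condition is applied at the
lower limit; below `r_low` the first polynomial piece is continued
(Taylor extrapolation), with an 0.05-Angstrom guard before an error is
raised, because distorted test geometries may slightly undershoot the
training range.

## The loss and the training schedule

The training objective is a weighted L2 loss,

```
L = sum_prop (1/N_prop) sum_i (w_prop r_i)^2  +  penalties
```

with default weights 6270 / Hartree for total energy (the residual is
divided by the heavy-atom count first; a configuration switch disables
that normalization), 100 / (e Angstrom) per Cartesian dipole component and
1 / e per atomic charge. In this form doubling a property weight
quadruples its loss component. `N_prop` counts property instances within
the normalization unit (the batch during stochastic training).

Differentiating predictions through a converged SCC fixed point is
avoided by *loop inversion*: the charge fluctuations entering the Fock
operator are frozen, and every 10 epochs a full SCF pass over the training
set refreshes them; immediately afterwards the repulsive splines and
reference coefficients are refit globally by convex optimization. Between
refreshes, ADAM (learning rate 1e-5, standard defaults otherwise) updates
the electronic spline coefficients, on-site energies, Hubbard parameters
and overlap inflection locations. Batch membership is frozen for the whole
run -- the precomputed cache (distances, direction cosines, sparse maps
from spline coefficients into matrix entries) is keyed by it -- and only
the batch visiting order reshuffles each epoch. A plateau scheduler
multiplies the learning rate by 0.9 when the validation loss fails to
improve by a relative 1e-4 over 50 epochs (the window is the package's
choice; validation loss, evaluated on cached frozen-charge predictions
every epoch, drives the scheduler). The best-validation parameter vector
is kept and refit once more at the end.

Gradients are exact within the frozen-charge objective: reverse-mode
derivatives are propagated analytically through the generalized
eigenproblem (occupied-virtual rotations only; occupied-occupied rotations
cancel for any quantity that depends on the density matrix alone), through
`S^(-1/2)` via the eigendecomposition of the overlap, and through the
charge-shift term of the Fock matrix. Hubbard derivatives use central
differences of the closed-form Coulomb kernel (step `1e-6 U`, error many
orders below the gradient tolerance). The whole gradient is verified
against central finite differences in the test suite.

## Regularization

Unregularized spline training produces oscillatory channels, so three
penalties are applied on a dense 500-point grid per channel:

* **curvature sign ("convex")**: channels approaching zero from above near
  the cutoff must curve upward, channels approaching from below downward.
  The sign class of each channel is assigned automatically from the seed
  shape near the cutoff. Violations are measured by a squared hinge of the
  second derivative; the weight (default 1e3) only needs to be large
  enough that violations vanish.
* **single inflection for overlaps**: orbital node structure produces one
  curvature sign change in some overlap channels, so for `S` channels the
  required sign may flip once at a trainable location. The exact penalty
  uses a hard split at the inflection; since its derivative with respect
  to the location vanishes almost everywhere, training uses a
  tanh-modulated hinge (`max(0, -s tanh((r - x)/beta) f'')^2`, `beta` one
  grid spacing), which vanishes at the flip point, reduces to the hard
  split as `beta -> 0`, and makes the location differentiable. The latent
  location is a sigmoid-squashed unconstrained variable so it stays inside
  the spline range.
* **third-derivative smoothing** removes piecewise-linear behavior; it
  requires a continuous third derivative, which is why electronic channels
  are fifth order, and it is not applied to the third-order repulsives.
  The default weight 1e-4 is the smallest order of magnitude that removes
  piecewise-linear artifacts on the synthetic suite without degrading fit.

## The repulsive / reference convex program

With electronic parameters fixed, the residual target energy is fit
jointly by all repulsive splines and the reference coefficients:

```
min sum_i ( E_i^target - E_i^elec - sum_pairs R(r) - E_i^ref )^2
```

subject to convexity of each repulsive spline (`R'' >= 0`). For a
third-order spline the second derivative is piecewise linear, so
non-negativity at the knots is *exactly* equivalent to non-negativity
everywhere -- the knot-based constraint set is the dense-grid constraint in
closed form. Convexity together with the built-in zero value and slope at
the cutoff implies `R' <= 0`, so the monotone-decrease condition needs no
separate rows. The program is solved by a Mehrotra-style primal-dual
interior-point method written for this package; an algorithmically
independent dual projected-gradient (FISTA) solver cross-checks the
optimum in the tests. Numerical choices: the target is first centered by
an unconstrained least-squares reference fit (targets carry tens of
Hartree of isolated-atom content per element, which would otherwise
dominate the solver's scaled tolerances; the pre-fit is added back
afterwards), and a small relative ridge (1e-7) keeps coefficients finite
where the data contains no distances. Restarting from random points
reproduces the optimum, as convexity requires.

## The synthetic ground truth

The generator provides a fully offline, exactly realizable "truth":

* **overlap channels** are shape-constrained spline fits of analytic
  two-center Slater-type-orbital overlaps (standard valence exponents;
  closed-form evaluation in prolate spheroidal coordinates), tapered to
  zero over the last 0.7 Angstrom before the cutoff so the fit has no
  boundary-layer artifact;
* **Hamiltonian channels** follow a Wolfsberg-Helmholz bond-integral
  ansatz (K = 1.75) projected onto the pure-convex curvature class; where
  the raw ansatz is incompatible with that class (channels whose overlap
  changes sign), a magnitude-calibrated decaying exponential with the
  correct tail sign replaces it;
* **repulsives** are convex decaying exponentials with exact zero value
  and slope at their cutoffs;
* on-site energies and Hubbard parameters are standard atomic values with
  a small seeded jitter, so different seeds define different truths.

Every generated channel satisfies its curvature class exactly (the
constrained fits use the same 500-point grid as the penalties). Targets
are produced by full SCC calculations of the toy model on distorted
copies of 17 built-in templates of small C/H/N/O molecules (at most three
heavy atoms), plus per-element energy offsets emulating isolated-atom
content and optional Gaussian noise. Sampling applies independent
Gaussian coordinate perturbations (default 0.05 Angstrom, a moderately
distorted ensemble) and rejects any draw with an interatomic distance
below 0.6 Angstrom or below a pair's spline range, so every emitted
geometry lies in the trained model's domain.

What the generator emulates: the band structure of pairwise-distance
distributions (sharp bonded peaks truncated at the nearest-neighbor
boundary, broader long-range structure), complete energy/dipole/charge
records, formula-grouped sampling, and isolated-atom energy content. What
it does not emulate: real electronic structure (the toy Hamiltonian is a
two-parameter-family surrogate), conformer-sampling protocols, open-shell
or charged species, and -- importantly -- the *dense, continuous* distance
coverage of a large chemical dataset. Passing the synthetic suite
therefore validates the machinery (assembly, SCC, gradients, convex fits,
bookkeeping) and desk-scale trainability; it does not certify accuracy on
real quantum-chemical data.

## The standard recovery experiment and what it shows

`recovery_experiment()` is the package's verification protocol: 2000
training configurations (plus 200 validation, 300 formula-disjoint test)
generated from a toy truth with zero noise, trained for 300 epochs with
batch size 10 and charge/repulsive refreshes every 10 epochs, repeated
over three seeds. It reports held-out energy/dipole/charge errors after
the reference refit and the agreement of trained channels with the
generating ones over well-sampled distances (overlap deviations are
converted to an energy-equivalent scale through the Wolfsberg-Helmholz
factor so both channel kinds share one metric).

Two structural findings from this experiment are worth recording, because
they bound what *any* training run on band-structured data can recover:

1. **Gauge freedom.** Adding `kappa * S_ch` to every Hamiltonian channel
   while shifting all on-site energies by `kappa` changes every total
   energy by `kappa * n_electrons`, which the linear reference term
   absorbs exactly; predictions are invariant. Channel values are
   therefore only identified up to this gauge.
2. **Band aliasing.** A constant added to a repulsive spline over one
   sampled distance band and smoothly extended elsewhere changes energies
   by (bond count) x (constant), which the reference term can absorb
   whenever the per-band bond-count vectors are linearly dependent on the
   composition vectors across formulas. For the built-in template library
   this null space is eight-dimensional. The convex refit also absorbs
   most pairwise-representable electronic misfit each cycle, flattening
   the energy landscape around the current electronic parameters.

The measured consequence is that the loss surface between a generic seed
and the generating truth is a long, nearly flat valley: the loss decreases
monotonically along the straight path to the truth, yet the gradient is
numerically orthogonal to that direction (cosine at the level of a random
direction in several thousand dimensions). Gradient training therefore
improves predictions -- validation loss drops by an order of magnitude,
dipole and charge errors improve severalfold over the repulsive-only
baseline -- while the channel functions themselves move little and
pointwise channel agreement with the generator at the
1 kcal/mol-equivalent level is not reached under this protocol. The
corresponding acceptance assertion is kept at its stated threshold and is
expected to fail; the numbers it measures are reported by
`scripts/acceptance.R`. Held-out energy errors land at a few kcal/mol per
molecule and are dominated by test formulas whose bond-type combinations
are least constrained by training formulas.

## Numerical choices and degenerate inputs

* Coulomb kernel: the closed form is numerically unstable when two decay
  parameters nearly coincide; a series in the asymmetry
  `(tau_a - tau_b)/(tau_a + tau_b)` (used below 0.05, terms through sixth
  order) keeps the evaluation smooth to machine precision across the
  switch. The on-site cross-shell limit is a mean-type combination that
  lies between the two Hubbard values.
* Degenerate frontier orbitals (closed-shell aufbau filling would be
  fractional) are rejected with an explicit error at a 1e-9 Hartree gap
  threshold; SCF non-convergence is a flag, not an error, and flagged
  configurations are excluded from that training cycle and logged.
* Overlap matrices that lose positive definiteness (possible for extreme
  coefficient values during exploration) cause the molecule to be skipped
  in the gradient accumulation rather than aborting the run.
* SKF export resamples channels on a 0.02-bohr grid; values beyond a
  channel's cutoff are exactly zero, and values far below the fitted range
  are clamped at the guard distance (such distances never occur in valid
  geometries). The repulsive block stores exact per-interval cubic
  coefficients; reading back interpolates tables with natural cubic
  splines, which reproduces assembled matrices to well below the stated
  1e-8 Hartree.
* Empirical formulas are canonicalized in Hill order; splits assign whole
  formula groups so train and test formulas never overlap, while
  validation samples the training formulas (the protocol's reading of
  formula-disjointness applies to train versus test).

## Known limitations

* Valence s/p minimal basis only; no d channels, spin polarization,
  fractional occupations, periodic boundary conditions, or forces.
* The energy criterion of the recovery experiment depends on which
  formulas land in the test split; with few distinct formulas the
  transfer error is dominated by the least-covered bond-type combination.
* The toy Hamiltonian ansatz is not an electronic-structure method; its
  role is to define an exactly realizable target inside the model class.
* Training runs are deterministic for a fixed seed but single-threaded;
  large datasets scale linearly in configurations per epoch.
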