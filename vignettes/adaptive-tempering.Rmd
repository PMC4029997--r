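---
title: "Adaptive temperature replica exchange: model, feedback ladder, and what the synthetic tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive temperature replica exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrex)
```

## The problem

Temperature replica exchange (T-ReX, parallel tempering) runs $N$ copies of a
system at temperatures $T_1 < \dots < T_N$ and periodically lets neighboring
clients swap temperatures through a Metropolis test, so that cold replicas
escape local minima by taking excursions through the hot end of the ladder.
The conventional ladder is static and geometric,

$$T_i = T_{\min}\left(\frac{T_\max}{T_\min}\right)^{i/(N-1)},\qquad i = 0,\dots,N-1,$$

which gives a roughly constant acceptance profile for systems whose heat
capacity varies slowly. Near a sharp energetic transition — protein
folding–unfolding, or more generally any temperature where the mean energy
changes steeply — neighbor acceptance collapses and the ladder splits into
poorly communicating halves. The adaptive ("dynamic walker") scheme re-places
the interior temperatures from feedback statistics so that clients accumulate
where exchanges are scarce, with the goal of maximizing the rate of round
trips $T_{\min} \to T_{\max} \to T_{\min}$.

## The algorithm as implemented

**Swaps.** Neighboring clients $a, b$ swap temperatures with probability
$\min\!\left(1, e^{(\beta_a-\beta_b)(E_a-E_b)}\right)$, $\beta = 1/k_BT$.
Disjoint neighbor pairs are attempted on alternating even/odd parity, so
every pair is attempted once per two rounds; configurations stay in place and
the two clients exchange window assignments. On an accepted swap the momenta
(and the momentum memory, below) are rescaled by $\sqrt{T_\mathrm{new}/T_\mathrm{old}}$
(configurable off), the standard way to keep kinetic energy consistent with
the new bath.

**Walker labels and feedback.** A replica is labeled *cold* or *hot* by the
last temperature extreme it visited. Per-window counters $n_\mathrm{cold}(T)$,
$n_\mathrm{hot}(T)$ accumulate the labeled visits and define the fraction-cold
profile $f(T) = n_\mathrm{cold}/(n_\mathrm{cold}+n_\mathrm{hot})$, which runs
from 1 at $T_{\min}$ to 0 at $T_{\max}$. Adaptation asks for $f$ to be linear
in the client *index*: the empirical profile is made invertible by decreasing
isotonic regression (finite samples are noisy, and the minimal monotone
repair keeps the fit honest), interpolated piecewise
linearly in temperature, and inverted at the targets $1 - i/(N-1)$. The index
convention is 0-based; the 1-based form $i/(N-1)$ exceeds 1 at the top index,
so the boundary-consistent decreasing-in-index form is used, which is the
same profile up to relabeling the ends.

**Spacing constraint.** To keep the windows from collapsing onto one
temperature and depleting the extremes, no neighbor pair may be more than two
geometric spacing units apart: $T_{i+1}/T_i \le r^2$ with
$r = (T_{\max}/T_{\min})^{1/(N-1)}$. The projection is deterministic: a
forward sweep lowers any upper neighbor above $T_i r^2$, a backward sweep
raises any lower neighbor below $T_{i+1}/r^2$, and the endpoints are
re-clamped. Feasibility requires $T_{\max}/T_{\min} \le r^{2(N-1)}$, which
holds by construction for the ladder's own $r$. Inverting a flat (for
example step-like) profile can map adjacent targets onto numerically tied
temperatures; tied runs are respread geometrically between their nearest
distinct neighbors so the ladder stays strictly increasing. Windows with no
labeled visits are excluded from the interpolation knots rather than imputed.

**Self-guided Langevin dynamics.** Sampling uses SGLD: Langevin dynamics
augmented by a guiding force $\lambda\gamma\langle p\rangle_L$, where
$\langle p\rangle_L$ is a moving average of the momentum over an averaging
time $t_L$, maintained recursively as

$$\langle p\rangle \leftarrow (1-\delta t/t_L)\,\langle p\rangle + (\delta t/t_L)\,p ,$$

the $O(1)$-memory exponential form used by the method's originators (a box
window would need $L = t_L/\delta t$ stored frames for the same effect).
$\lambda = 0$ recovers plain Langevin dynamics exactly. Discretization is a
BAOAB splitting with the guiding force added to the systematic force in the
B sub-steps; the O sub-step applies the exact Ornstein–Uhlenbeck update,
which realizes fluctuation–dissipation at the window temperature. The
physical parameter set mirrors refinement practice: $\delta t = 2$ fs,
$\gamma = 1\ \mathrm{ps}^{-1}$, $\lambda = 1$, $t_L = 1$ ps, exchanges every
1 ps (500 steps); reduced-unit toy models default to $\gamma = 1$,
$t_L = 50\,\delta t$, $k_B = 1$. The kinetic temperature matches the bath to
within 2% for $\lambda = 0$; with $\lambda > 0$ SGLD is known to run
slightly warm in configurational space — this is recorded by the tests but
deliberately not asserted.

**Schedule.** The ladder adapts every 100 swap rounds (configurable), with
histograms accumulated cumulatively across updates (a reset switch exists)
and the first update
deferred until both extreme windows have at least 10 labeled visits, so an
all-undefined profile is never inverted.

## Metrics

The refinement metric is the fraction of native contacts $f_N$: native
contacts are all side-chain-center pairs $(i,j)$, $j>i$, strictly closer
than 6.5 Å in the reference structure, and $f_N$ of a decoy is the fraction
of those pairs also within the cutoff in the decoy. Contacts are defined by
the native structure only; ties at exactly 6.5 Å are excluded ("less than").
No minimum sequence separation is applied by default — the definition says
only $j > i$ — but a `min_sep` flag exists for sensitivity analysis.
Side-chain centers are mass-weighted means over side-chain atoms, with
glycine falling back to Cα, the standard fallback. RMSD is the Kabsch optimal superposition with the determinant
correction, so reflections are never used.

## The synthetic world

No protein data ships with the package. The stand-ins are:

- **Harmonic well** ($E = k|x|^2/2$): analytic moments
  ($\langle x^2\rangle = k_BT/k$ per degree of freedom) make it the
  integrator oracle.
- **Double well** ($E = b\,((x/x_0)^2-1)^2$ per coordinate): minima at
  $\pm x_0$, barrier $b$ at 0. A *single* 1-dof double well provably cannot
  produce an exchange-acceptance collapse — its energy is
  $\chi^2_1$-distributed up to scale, and neighbor-energy overlap stays high
  at any temperature ratio — so experiments that need a cooperative
  transition use $D$ independent double-well coordinates (default 16 in the
  acceptance experiment): the latent-heat-like jump grows like $D$ while
  fluctuations grow like $\sqrt D$, the standard desk-scale sharpening. For
  $b = 5\,k_BT_{\min}$ the potential-energy heat-capacity peak sits at
  $T \approx T_{\min}$ (verified by quadrature), so the exchange bottleneck
  is at the cold edge of a $[1, 5]$ ladder, which straddles the measured
  hopping onset.
- **Gō-type bead model**: one bead per residue at the side-chain center,
  harmonic chain bonds at native lengths, a 12–10 well of depth
  $\varepsilon$ at the native distance for native contact pairs, and
  short-range repulsion for non-native pairs — a funneled landscape with its
  global minimum at the supplied native structure.
- **Decoys**: native plus isotropic per-coordinate Gaussian noise
  (σ in Å, seeded). Cartesian rather than dihedral noise is the simplest
  controllable $f_N$/RMSD dial; real decoy generators produce correlated,
  physically plausible deformations that this does not emulate, so a green
  decoy test establishes metric arithmetic, not realism.
- **Synthetic native**: a deterministic helical chain with α-helix CA
  geometry (3.8 Å neighbor spacing, contacts up to $i, i\pm4$), labeled
  synthetic everywhere it appears.

## Numerical choices

- Endpoints of a geometric ladder are assigned exactly, not accumulated
  through powers, so they are bit-equal to the bounds.
- `interpolate_inverse` resolves flat stretches at the target by the
  midpoint of the level set (ties = mean); a fully flat regressed profile
  maps targets above/below the constant to the cold/hot end.
- The acceptance probability is evaluated in its closed form; no logarithm
  rearrangement, so `swap_probability(βa, βb, Ea, Eb)` is exactly symmetric
  under relabeling.
- The compiled (C++) integrator draws noise from R's RNG in exactly the
  per-dof, per-step order of the pure-R reference path, so compiled and
  modular runs are reproducible from the same seed and are compared
  step-by-step in the tests (tolerance $10^{-12}$; the pure-R λ = 0 SGLD
  path is bit-identical to the independent plain-Langevin implementation).
- Dynamics blow-ups raise an error naming the first non-finite coordinate.

## What the acceptance experiment found

The package's double-well comparison (10 seeds × $10^5$ swap rounds,
barrier $5\,k_BT_{\min}$, 8 clients on $[1,5]$, 16 coordinates) shows the
feedback ladder doing exactly what it is designed to do — the static
acceptance profile (≈0.45 at the cold edge rising to ≈0.64) becomes flat
(≈0.53) and the tightest adaptive spacing lands near the hopping onset,
well below the geometric spacing — yet the mean round-trip count is
consistently 2–4% *lower* than the static ladder's, far outside the seed
noise. With only a mild heat-capacity peak, geometric spacing is already
near-optimal for round trips, and continual re-placement adds jitter that
costs more than the equalized profile gains. The corresponding test asserts
the qualitative claim (adaptive ≥ static) as stated and therefore fails on
this world; this is consistent with the broader experience that
feedback-optimized ladders earn their keep at sharp folding–unfolding
transitions but offer only limited improvement for weakly cooperative,
refinement-scale transitions.

## Score-table analytics

The packaged fixture `refinement_scores.csv` carries the published benchmark
grid (eight 49–92-residue targets × {adaptive, static} × four scoring
functions, top-scoring $f_N$ and top-16 mean). The aggregation operation
reproduces its headline margins: adaptive 0.62, static 0.60, RWplus pooled
highest at ≈0.63, force field lowest at 0.60 (raw means 0.6225, 0.6025,
0.635, 0.59875; rounding to 2 decimals mirrors the table's precision and raw
means are always reported alongside). One internal inconsistency in the
benchmark's reporting is preserved rather than repaired: a quoted top
initial-range value of 0.64 for target 1shfA against a tabulated 1shfA
range of 0.32–0.59; the fixture stores the tabulated values. Scoring
functions are a pluggable interface
(lower = better); the statistical potentials themselves are out of scope and
external score columns can be ingested from CSV.

## Limitations

- Toy energy models only; no force field, implicit solvent, constraints
  (SHAKE), or nonbonded cutoff machinery.
- Neighbor-pair exchanges only; no all-pairs or Hamiltonian exchange.
- The thermal-current machinery behind the feedback scheme (diffusivity
  $D(T)$, residence probability $\eta(T)$) is not computed; the current
  enters only through the index-linearity target.
- Single-process execution; replicas interact only at swap points, so
  results are independent of within-segment execution order by
  construction.
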