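---
title: "Model and inference methods in sarcotwitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and inference methods in sarcotwitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sarcotwitch` couples a spatially explicit stochastic model of the cardiac
half-sarcomere to an amortized Bayesian inverse-inference pipeline. This
vignette is the package's account of the science: the model and its
assumptions, the parameters that matter, the numerical choices, and the
design decisions taken where the underlying literature leaves the design
open. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## The half-sarcomere model

### Lattice mechanics

The contractile lattice is four thick (myosin) and eight thin (actin)
filaments in a transversely periodic hexagonal box: thick filaments on a
triangular lattice, thin filaments at the trigonal positions, so each thick
filament faces six thin neighbours and each thin filament three thick ones.
Each filament is a serial chain of linear springs. Filament stiffnesses are
quoted per crystallographic repeat — 2020 pN/nm per 43 nm for thick, 1743
pN/nm per 38.7 nm for thin — and rescaled to the node spacing, so grid
refinement preserves whole-filament compliance. Thick-filament nodes are
crowns every 14.33 nm, each bearing one myosin head by default
(`heads_per_node` is configurable). Thin-filament nodes are *regulatory
units*: one troponin/tropomyosin target zone per 38.7 nm repeat. Placing the
binding sites at the regulatory-unit pitch, rather than at single-actin
resolution, keeps the thin-filament state machine aligned with the
nearest-neighbour cooperativity model it implements (adjacent regulatory
units boost each other) and sets the natural spacing of binding
opportunities.

Thin filaments are given deterministic axial register offsets, uniform over
one repeat across the eight filaments (`thin_stagger`). Real lattices have
register disorder; without the stagger the 14.33/38.7 nm commensurability
would leave only three distinct head-to-site offsets per filament pair and
the model's behaviour would be dominated by aliasing.

Thick filaments anchor at the M-line (x = 0), thin filaments at the Z-disc
(x = L, the fixed half-sarcomere length — the model is strictly isometric).
Titin connects each thick filament free end to the Z-disc as a passive
exponential spring `F = a exp(b dL)` with a = 220 pN, b = 0.0045 /nm, and
rest span equal to the thick-tip-to-Z gap by default.

A crossbridge is a linear plus torsional spring pair. Its configuration is
reduced to polar coordinates relative to the binding site: with a fixed
radial gap `xb_span` between the filament pair and axial offset `dx` (site
minus head), the lever length is `r = sqrt(span^2 + dx^2)` and the lever
angle `theta = atan2(span, dx)`. Strain energies are quadratic in both
coordinates with separate rest pairs for the weak (pre-powerstroke) and
strong (post-powerstroke) states; the printed rest angles (47.16, 73.2)
exceed 2*pi* if read as radians, so they are interpreted as degrees
(`theta_unit` switches this). Energies are in units of kT; `kT_pN_nm`
(default 4.14 pN nm) converts forces to pN.

The isometric force balance is solved at fixed radial spacing by fixed-point
iteration: each filament chain is a tridiagonal linear system given the
current crossbridge and titin loads, and the loads are re-evaluated at the
updated geometry until the largest node displacement change is below
`mech_tol` (default 1e-4 nm, cap 100 iterations). Filament springs are
linear and crossbridge loads are weak relative to them, so the iteration
contracts quickly; the solver is verified in the test suite against direct
minimisation of the total elastic energy. Reported stress is the Z-disc
boundary force (thin-filament anchor tensions plus titin) divided by the
cross-sectional area of four rhombic unit cells,
`4 * lattice_spacing^2 * sin(60 deg)`, with the unit cell containing one
thick and two thin filaments.

### Kinetics

Each head cycles through six states: 1 free (DRX, ATP), 2 loosely bound,
3 post-powerstroke, 4 rigor-like, 5 free (ADP), 6 super-relaxed (SRX,
reachable only from state 1). Free energies are
`G1 = -2.3`, `G2 = U_W - 4.3`, `G3 = U_S - 18.6`, `G4 = U_S - 20.72` (kT),
with `dG_ATP = -23` closing the cycle. Forward rates:

* `rx12 = tau exp(-U_W)`, `tau` = 7.2 /ms, gated on the paired site being in
  the open state and unoccupied;
* `rx23 = A (1 + tanh(B + C (U_W - U_S)))`, A = 0.8 /ms, B = 5, C = 0.4;
* `rx34`: the published expression contains a self-cancelling term. The
  default `"strain"` variant keeps the literal remainder
  `D (1 + tanh(exp(-F_S)))` — bounded in [D, 2D] and decreasing in the axial
  strong-state force `F_S` (kT/nm) — and a `"kappa"` variant
  `D (1 + tanh(kappa F_S))` is provided for load-dependent ADP-release
  studies. D = 0.9 /ms.
* `rx45`: the published expression is negative (about -22 kT times E) at low
  strain, which would trap rigor heads forever; the default `"detach"`
  variant flips the sign of the ATP term,
  `E max(0, U_S - dG_ATP + exp(-F_S))`, making ATP-induced detachment from
  rigor fast and strain-accelerated, which matches solution kinetics at
  physiological ATP. The printed form (clamped at zero) remains available.
* `rx51 = H` = 0.1 /ms; `rx15 = rx54 = 0` structurally.

Reverse rates follow detailed balance as `r_ji = r_ij exp(G_j - G_i)`, so an
isolated reversible pair equilibrates at the Boltzmann ratio
`pi_j/pi_i = exp(G_i - G_j)` (the published reverse-rate sentence has the
opposite sign, which would make strained states the favoured ones; the
package follows thermodynamics). A convenient consequence:
`rx21 = tau exp(c2 - G1) = tau e^{-2}` is strain independent.

DRX/SRX exchange uses `rx16` = 50 /s (calcium independent) and a Hill-shaped
`rx61` rising from 50 /s to `rx61_max` (default 10x) with `ca50` = 1 uM and
Hill coefficient 4. These unprinted SRX parameters follow the upstream
modelling convention; at resting calcium the pair is symmetric, which is
what pins the resting SRX fraction near one half.

Thin-filament activation is a four-state chain per regulatory unit:
calcium binding (`rt12 = 37650 [Ca] /ms`, concentration in molar), the
TnC-TnI switch (`rt23` = 33.4 /ms), tropomyosin movement exposing the site
(`rt34` = 0.13 /ms), and an irreversible reset `rt41` = 0.77 /ms
(`rt14 = 0`). Reverse rates derive from the equilibrium constants
`Kt1 = 260000 [Ca]` (calcium cancels in `rt21`), `Kt2` = 130,
`Kt3` = 0.91. A site whose nearest neighbour is calcium bound (states 2-4)
has its activation-direction forward rates (`rt12`, `rt23`, `rt34`)
multiplied by 100; the boost deliberately excludes the deactivating `rt41`,
which would otherwise cancel the cooperativity it is meant to produce
(config switch `coop_on_rt41`). Myosin binding is admitted only in site
state 4.

### Calcium transient

All simulations are driven by one parametric intracellular transient,
`ca(t) = ca_dia + (ca_sys - ca_dia) g(t)` with
`g(t) ~ exp(-b (t^a - t_p)^2 / w^2)` rescaled to be 0 at the stimulus and 1
at its peak and clamped to [0, 1]. The asymmetry exponent a < 1 makes decay
slower than the upstroke. Defaults (a = 0.25, time-to-peak 30 ms, w = 0.15)
give a mouse-like transient: fast upstroke, peak near 30 ms, roughly 100 ms
half-decay. The diastolic/systolic anchors default to pCa 7 and pCa 6.
`fit_ca_transient()` recovers the three shape parameters from a measured
trace so users can calibrate to their own recordings.

### State propagation

Per head and per site, each 1 ms step builds the rate matrix Q (off-diagonal
rates at the current geometry and calcium, diagonal set so rows sum to
zero) and converts it to transition probabilities with the matrix
exponential `P = expm(Q dt)` (scaling-and-squaring Pade). This conserves
probability exactly for any step size and captures multi-step paths —
`p15 > 0` even though the direct rate is zero — which is what allows 1 ms
steps despite near-instantaneous detachment rates at extreme strain (rates
are additionally clipped at 1000 /ms to keep Q well conditioned). The new
state is drawn by cumulative inversion of the current row against one
uniform variate, so a trajectory is a deterministic function of
(configuration, factors, seed). Heads update before sites within a step;
cooperativity flags are frozen at the step start to avoid order artefacts.

Initial states are drawn from the long-time limit row of `expm(Q T)` taken
from the free (respectively blocked) state at the resting calcium — the
"dt to infinity" reading of the propagator. This matters numerically: a
plain null-space solve assigns spurious stationary mass to unreachable bound
states for heads whose binding rate underflows, which manifests as large
static forces from heads that could never have bound.

Two per-call caches make the simulation fast without changing its
semantics: transition matrices are memoised on the quantised pair (axial
offset to 1/64 nm, log-calcium to ~0.8%), and site matrices on
(calcium, cooperativity flag). The quantisation error is bounded by ~3% on
the most calcium-sensitive rate, far below replicate-to-replicate
Monte-Carlo spread; caches are shared across the replicates of one call,
which is why replicate loops live inside the core.

### Calibration

Two occupancy anchors calibrate the model's unprinted parameters, mirroring
how the original model constants were chosen: at resting calcium about half
the heads should sit in SRX (guaranteed analytically by the symmetric
resting exchange rates), and at maximal activation (pCa 4) roughly a tenth
of the heads should be bound. The second anchor fixes the one influential
unprinted geometry parameter, the crossbridge radial reach `xb_span`: the
default 13.5 nm was chosen, before any inference experiments, as the value
maximising the maximal-activation bound fraction over an a-priori scan.
`scripts/acceptance.R` recomputes both anchors from scratch on an 80-head
lattice (20 crowns x 10 regulatory units, 20 replicate seeds, >= 1-2 s of
model time).

### Known limitations

With the printed spring constants, the weak and strong rest geometries are
about 9 nm apart axially at any fixed radial gap, while the powerstroke
releases only 14.3 kT. Under strictly isometric conditions the
post-powerstroke state is therefore reachable only through a narrow window
of offsets where binding is already slow. Three consequences users should
know: bound heads are predominantly weakly bound; absolute active stress is
roughly an order of magnitude below experimental twitches (peak stresses of
a few mN/mm^2 at the default geometry), although twitch *shape* and its
dependence on the activation-side rates are preserved; and the
`rx23`/`rx34`/`rx45` factor dimensions move the trace only weakly, so their
posteriors stay close to the prior. Inference experiments in this package
therefore focus on the strongly identified dimensions (`rt12`, `rt41`,
`rx16`, `rx12`) — which are also the biologically central ones for the
calcium-desensitization and myosin-activator use cases. Weak-binding
forces are nearly zero-mean, so baseline-subtracted stress can dip below
zero; summary statistics are computed on the baseline-subtracted trace and
a trace with no positive excursion is reported as "no twitch" rather than
summarised. Non-isometric protocols, compliant radial spacing and
multi-half-sarcomere coupling are out of scope.

## The inverse problem

### Training corpus

`generate_dataset()` draws rate-factor vectors log-uniformly over the prior
box (0.1, 100) per coordinate — optionally freezing a named subset or
re-centring the box on a supplied combination (same log-width, shifted,
clipped to the global range) — and stores the mean of `replicates`
independently seeded twitches per combination. Record i uses the seed
`record_seed(master, i)`, a 64-bit hash, so any record can be regenerated
standalone and bit-identically: generation is embarrassingly parallel and
resumable by construction. The reference protocol averages 50 replicates
per record; the package's own reduced-scale experiments use 8.

Standardization subtracts the global (scalar) mean and divides by the global
standard deviation of the *training* traces only; the stored statistics are
applied unchanged to validation records and to inference-time targets
(per-timepoint statistics are available behind a switch). Factors are
regressed on the log10 scale mapped affinely to the unit box.

What the generator emulates: stochastic crossbridge cycling noise,
replicate averaging, the full factor-to-trace forward map of the mechanical
model. What it does not emulate: measurement noise of a force transducer,
preparation-to-preparation variability, calcium-handling feedback (one
transient for all simulations), or the absolute stress scale of real
trabeculae. Passing calibration and recovery tests on this corpus therefore
demonstrates the estimator is faithful to *this simulator*, not that its
posteriors transfer unchanged to experimental traces.

### The conditional variational autoencoder

The estimator is the standard three-network conditional VAE for
simulation-based inference: a recognition encoder Q1 (trace + true factors
-> diagonal latent Gaussian), a conditional-prior encoder R1 (trace -> m
component latent Gaussian mixture), and a decoder R2 (trace + latent point
-> m-component Gaussian mixture over factor space), all sharing one
convolutional feature extractor. No deep-learning runtime is available to
this package, so the networks are implemented in base R matrix code with
hand-derived reverse-mode gradients; the test suite checks every parameter
block against central finite differences. The shared extractor uses strided
(non-overlapping) 1-D convolutions — 1000 -> 125 -> 25 -> 5 positions by
default — followed by a dense feature layer; heads are two-layer
perceptrons. Widths, depths, latent dimension (default nz = 8) and mixture
order (default m = 16) are unpublished in the source material and are all
config-exposed; the reduced-scale experiments keep nz = 8, m = 16
with a 96-unit feature layer.

The loss is `-L + alpha KL`: L is the decoder mixture log-density at the
true factors with the latent point drawn from Q1 by reparameterisation, and
KL is the single-sample Monte-Carlo estimate of KL(Q1 || R1) evaluated at
that point (no closed form exists against a mixture). The weight alpha is 0
for the first 30 epochs, ramps linearly to 1 over the next 60, then stays
at 1 — without annealing the optimiser can pin the KL term at its zero
minimum before the reconstruction term is learned. Optimisation is Adam
(default lr 3e-4, batch 128), seed-reproducible, with early stopping on
validation loss once annealing is complete, and the parameters reported for
inference are the best-validation checkpoint — at these corpus sizes the
final iterate is measurably over-confident relative to the checkpoint.
Training can be checkpointed and resumed bit-exactly (`cvae_resume()`
stores the optimiser and RNG state).

At inference time `predict()` draws ancestrally: z from R1's mixture, then
one factor draw from R2(trace, z), repeated n times (default 5000). Q1 is
used only in training, R1 only at inference. Draws outside the prior box
are kept, not clipped, and their fraction is reported as a diagnostic.

### Diagnostics and workflows

`pp_curve()` computes, per validation record and factor, the fraction of
posterior samples below the truth (randomized tie-breaking; ties have
measure zero for continuous samples) and plots the empirical CDF of those
values: the diagonal is perfect calibration, and systematic departures
above/below flag under-/over-confidence. `corner_summary()` reports 1-D
marginals, pairwise 2-D kernel densities (Scott's bandwidth on log10
samples) and the joint peak — the sample maximising a product-Gaussian KDE,
refined by mean-shift ascent; per-marginal modes are reported alongside
because the source figures do not disambiguate joint versus marginal peaks.
`signed_ks()` is the classical two-sample KS distance signed negative
exactly when the reference (control) CDF is the smaller one at the
maximising point. `hybrid_factors()` grafts named coordinates (default the
calcium-affinity pair `rt12`, `rt41`) from a variant's inferred peak onto a
control peak; `infer_intervention()` freezes the thin-filament rates at
such a hybrid, generates a reduced corpus over the thick-filament rates
(optionally centred on the hybrid), trains a reduced CVAE, and simulates
the posterior peak as the proposed intervention. Freezing every factor
degenerates to returning the input.

## Problem sizes and reproducibility

The package's own experiments are scaled to desk hardware as a deliberate
design point: the acceptance anchors use an 80-head lattice with 20
replicate seeds; the inverse-problem validation uses a 24-head lattice,
3000 records x 8 replicates with 3 varied factors (`rt12`, `rt41`, `rx16`),
an 8% validation split (220 of the 240 held-out records are used for
probability-probability curves), and 20 held-out records for
credible-interval coverage. The full-scale
protocol the pipeline is designed around — about 1.1 million records of 50
replicates and a 9-factor posterior — is reachable with the same code via
the per-record seed contract, which makes corpus generation trivially
distributable. Every stage (corpus, training, posterior sampling) is
bit-reproducible from its seeds on one platform; simulation randomness uses
a package-internal xorshift/splitmix stream, so traces are also independent
of R's global RNG state.

## Shape of the package

The simulator side follows the module layout natural to a tool (config
objects, a lattice builder, a simulation function returning a classed
trace); the estimator follows the classic R modelling idiom — one fitting
function `cvae()` returning a classed object with `print`, `summary`,
`plot` and `predict` methods — because a fitted model object is exactly
what an amortized posterior is. A thin command-line front end
(`exec/sarcotwitch`) wraps simulation, corpus generation, training,
inference and comparison for shell use.
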