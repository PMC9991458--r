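---
title: "From tropomyosin mechanics to thin-filament function: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tropomyosin mechanics to thin-filament function: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `thinfilament`, their
assumptions, the parameters that matter, and the numerical and design
choices made where the design was genuinely open. The package links three
scales: per-residue tropomyosin flexibility, blocked/closed-state
energetics, and a stochastic regulatory model of the cardiac thin filament,
supporting wild-type versus mutant comparisons such as TPM1 S215L.

## The scientific problem

Tropomyosin is a coiled-coil protein that lies along the actin filament and
sterically gates myosin binding. Its azimuthal position on actin takes three
functional states: blocked (B, myosin binding prevented, stabilized by the
troponin I inhibitory peptide), closed (C), and myosin-bound/open (M). A
point mutation can change (i) the mechanical stiffness of the tropomyosin
chain and (ii) the energetic balance between the B and C positions. Both
quantities are measurable in molecular-dynamics-style simulations but their
functional consequences — calcium sensitivity of sliding velocity, twitch
force — emerge only at the level of a regulated filament. The package
propagates the two molecular changes to those functional predictions.

## Chain mechanics: flexibility to effective stiffness

Each tropomyosin half-molecule (142 residues by default, half of the full
284) is modeled as a cable of torsional springs, one spring element per
residue. A flexibility profile gives the fluctuation amplitude
$\delta_i$ (degrees) of the superhelical backbone at residue $i$;
equipartition converts it to a per-element stiffness

$$\kappa_i = \frac{RT}{\langle\delta_i^2\rangle},$$

with $\delta_i$ in radians and $\kappa_i$ in kJ mol$^{-1}$ rad$^{-2}$. This
choice is parameter-free and preserves the relative stiffness profile; more
flexible residues are softer ($\kappa \propto \delta^{-2}$).

One chain end is pinned at azimuthal angle 0 and the other displaced to
$\theta \in [0, 35]^\circ$; interior node angles relax exactly (the
stationarity conditions are a symmetric tridiagonal linear system, solved
directly). For springs in series the relaxed energy has the closed form
$E(\theta) = \tfrac12 \gamma_{\mathrm{ser}}\theta^2$ with
$1/\gamma_{\mathrm{ser}} = \sum_i 1/\kappa_i$; the test suite uses this as
an independent oracle against the linear-algebra route. The effective chain
stiffness $\gamma$ is the unweighted least-squares coefficient of
$E = \tfrac12\gamma\theta^2$ through the origin (the origin constraint is
exact because $E(0)=0$), on a uniform $\theta$ grid. $\gamma$ is reported
both per rad$^2$ and per deg$^2$ because the literature is inconsistent
about the angular unit; all downstream uses are unit-free ratios.

The synthetic mutant profile is the baseline plus a single Gaussian-shaped
flexibility increase (in residue index) near the substitution site
(residue 108 of the half-molecule span, i.e. position 215 of the second
half-molecule). Since absolute flexibility levels are unconstrained by
published per-residue values, the bump amplitude default is solved in closed
form (`calibrate_bump_amplitude()`) so that the mutant/wild-type stiffness
ratio equals the ratio used by the regulatory model, 31.6/60. The baseline
(3°) and bump width (5 residues) are plausible round values; only the
*ratio* of stiffnesses matters downstream.

## Energetics: the Gibbs mapping of $K_{BC}$

The blocked-closed equilibrium constant of the wild type is a calibration
constant, $K_{BC} = 0.76$ (it is not computed from structure). The Gibbs
relation gives its free energy, $\Delta G_{\mathrm{ref}} = -RT\ln K_{BC}$.
Interaction-energy summaries for the B and C states (means over 500-frame
ensembles, kcal/mol) are differenced as

$$\Delta E = \bar E_C - \bar E_B,$$

which is positive when the blocked state is the more favorable one — the
energetic cost of leaving B. (The sign convention is deliberate: raw
interaction energies are large negative numbers, and the B state includes
the stabilizing troponin I contacts.) The mutant's free energy is scaled
proportionally, $\Delta G_{\mathrm{mut}} = (\Delta E_{\mathrm{mut}}/\Delta
E_{\mathrm{ref}})\,\Delta G_{\mathrm{ref}}$, and the relation inverted:

$$K_{BC,\mathrm{mut}} = e^{-\Delta G_{\mathrm{mut}}/RT} =
K_{BC}^{\,\Delta E_{\mathrm{mut}}/\Delta E_{\mathrm{ref}}}.$$

The temperature cancels algebraically in $K_{BC,\mathrm{mut}}$ — the
package asserts this numerically over 270–320 K — and only affects the
reported $\Delta G$ values (default 300 K, the structural-simulation
temperature). Note that this proportional scaling maps interaction-energy
differences of order $10^3$ kcal/mol onto free energies of order
$10^{-1}$ kcal/mol; the package reproduces the procedure as specified
without endorsing it thermodynamically.

## The 24-state regulatory-unit model

The thin filament is 26 regulatory units in series. Each unit is the
product of four factors:

* `ca` — Ca$^{2+}$ on troponin C: free / bound;
* `sp` — troponin I switch peptide on troponin C: unbound / bound;
* `ip` — troponin I inhibitory peptide: bound to actin / released;
* `tm` — tropomyosin position: B / C / M;

giving $2\times2\times2\times3 = 24$ enumerable states. Two steric
constraints make eight of them inaccessible: tropomyosin can occupy B only
while the inhibitory peptide is on actin, and myosin can bind (M) only
while it is released. The second constraint is required for calcium
regulation at all: without it, the closed-open equilibrium
($k_{MD+}/k_{MD-} = 2.44$) would activate the filament even at pCa 9
through the IP-bound block.

Only single-factor transitions carry rate. The wiring is:

* Ca$^{2+}$: on-rate $k_{Ca+}[\mathrm{Ca}]$, off-rate $k_{Ca-}$, the latter
  multiplied by $\lambda$ while the switch peptide is bound.
* Switch peptide: on-rate $k_{SP+}$, multiplied by $\lambda$ when Ca is not
  bound; off-rate $k_{SP-}$, multiplied by $\lambda$ while the inhibitory
  peptide is released.
* Inhibitory peptide: release $k_{IP+}$, multiplied by $\lambda$ when the
  switch peptide is unbound; rebinding $k_{IP-}$. Both occur only while
  tropomyosin is closed (release under B, or rebinding under M, would
  create a forbidden combination).
* Tropomyosin: B↔C while the IP is on actin, C↔M while it is released.

The paired $\lambda$ gates (on one side of the Ca/SP cycle and the
SP/IP cycle each, with the compensating gate on the reverse rate of the
other factor) make every thermodynamic cycle of the single-unit model
consistent: the free-standing unit satisfies detailed balance, which the
test suite verifies on the B↔C edge with myosin attachment switched off.
A single $\lambda = 0.008$ both permits weak out-of-context transitions and
sets the coupling strength of each troponin cycle.

### Chain coupling

Tropomyosin positions carry azimuthal angles: C at 0, B at $-\eta$ and M at
$+\mu$ offset counts. The angular unit is **2° per count**, so with
$\eta=\mu=9$ the B and M positions sit 18° on either side of C — within
the range of azimuthal shifts described for steric-blocking models. A unit
at angle $\theta$ with neighbors at $\theta_L, \theta_R$ carries strain
energy $E = \tfrac12\gamma[(\theta-\theta_L)^2 + (\theta-\theta_R)^2]$
(kJ/mol, $\gamma$ per rad$^2$); end units have one neighbor and a free end
contributes nothing (no periodic closure is assumed for the 26-unit chain).

Tropomyosin transitions use a thermodynamic split: for equilibrium constant
$K$, reference rate $f$ and strain change $\Delta E$,

$$k_{\mathrm{fwd}} = f K^{\delta} e^{-\delta \Delta E / RT}, \qquad
  k_{\mathrm{rev}} = f K^{\delta-1} e^{(1-\delta)\Delta E / RT},$$

with $\delta = 0.48$, so that $k_{\mathrm{fwd}}/k_{\mathrm{rev}} =
K e^{-\Delta E/RT}$ exactly: the coupling modulates kinetics while
preserving every local equilibrium, and the whole 26-unit chain is
reversible with respect to the summed state and interface energies. B↔C
uses $f = k_{refBC} = 675\,$s$^{-1}$ and $K = K_{BC}$; C↔M uses
$f = f_{XY} = 225\,$s$^{-1}$ and $K = k_{MD+}/k_{MD-}$. An isolated unit
(zero strain) therefore has B↔C equilibrium constant exactly $K_{BC}$.

The angular unit is the one genuinely free constant of this reconstruction
and was fixed once: at 2° per count the wild-type force–pCa relation has
its midpoint near pCa 5.6 with Hill coefficient ≈ 1.7, and the
$\gamma$/$K_{BC}$ decomposition reproduces the expected directional
pattern — a $K_{BC}$-only increase shifts activation leftward and raises
maximal force, a $\gamma$-only reduction lowers maximal force. At 1° per
count the coupling is too weak for $\gamma$ to affect maximal activation
at all; at 3° per count strain-boosted rates become so fast that the
integrator step collapses.

### Integrator

The engine is fixed-step kinetic Monte Carlo (per unit and step, at most
one transition with probability rate × dt), chosen over event-driven
simulation because the twitch protocol has time-varying Ca$^{2+}$ and the
coupling makes every unit's rates depend on its neighbors' current
positions. Units are updated in index order within a step; at the enforced
step guard (max total exit rate × dt ≤ 0.1) the sequencing bias is
negligible, which the suite checks by comparing single-unit occupancy
against the exact stationary distribution (total variation < 0.02). By
default dt is auto-selected as the largest step satisfying the guard,
capped at 2×10⁻⁵ s; passing an explicit dt that violates the guard is an
error naming the offending state and neighbor context. The random stream is
a per-trajectory xoshiro256++ generator seeded deterministically from the
user seed, so trajectories are bit-reproducible and independent of R's
global RNG state.

### Protocols and observables

*Steady state:* 5 simulated seconds at constant Ca$^{2+}$, force averaged
over the final 25% (force = number of myosin-bound units, 0–26). Velocity
is proportional to force (effective filament viscosity); the
proportionality constant cancels from the Hill fit's midpoint and
steepness. The Hill equation is fitted in pCa form,
$v = v_{max}/(1 + 10^{\,n(\mathrm{pCa}-\mathrm{pCa}_{50})})$, by
Levenberg–Marquardt started from (and falling back to) a dense grid search
with $v_{max}$ profiled out analytically.

*Twitch:* equilibration at diastolic 0.1 µM until the stimulus, then a
difference-of-exponentials transient normalized to peak at 1 µM (rise
τ = 20 ms, decay τ = 150 ms — round cardiac-myocyte-like values; the
comparisons downstream are mutant/WT ratios, which are insensitive to
modest shape changes). Metrics: diastolic force (pre-stimulus mean), peak,
time to peak (stimulus to peak), RT50 (peak to 50% relaxation toward the
diastolic level, linearly interpolated), and the force–time integral above
the diastolic baseline. Because the ensemble-mean twitch has a broad, flat
peak (≈ 40 ms wide), the raw argmax is ill-conditioned even at 2000
trajectories; `twitch_metrics(smooth = 9)` locates the peak on a lightly
smoothed trace (9 samples ≈ 18 ms), which the comparison pipeline uses.

### Problem sizes

Reference ensemble sizes are 1920 trajectories with 10 averaged twitch
runs. The shipped analysis scripts and tests use desk-scale sizes — 24–48
trajectories per steady-state point and 200-trajectory twitches (10 × 200
for the converged comparison) — chosen because a 26-unit filament
self-averages substantially over the 1.25 s steady-state window, and the
standard error of ensemble means scales as $1/\sqrt{n}$ (verified
empirically in the suite).

## The synthetic-data generator

`generate_flexibility_profile()` and `sample_energy_frames()` emulate the
*format and statistics* of structural-simulation outputs: a smooth
per-residue flexibility curve with a localized mutant perturbation, and
i.i.d. Gaussian energy frames matching tabulated means and SDs (Gaussian
because only mean ± SD are reported). They do not emulate autocorrelation
between frames, anharmonicity of fluctuations, or long-range structural
propagation of the mutation. Tests passing on synthetic inputs therefore
demonstrate the correctness of the downstream pipeline, not the realism of
any particular flexibility profile.

## Known limitations

* The 24-state wiring is a reconstruction; the defining reference for the
  prior model was not available, so rate roles beyond those named above are
  documented defaults, overridable through `model_parameters()`.
* The combined mutant reproduces the expected two-fold twitch peak
  increase, slower relaxation, and raised diastolic force, but its time to
  peak converges to ≈ 1.0× wild type rather than the expected ≈ 17%
  faster: in this wiring the kinetic speed-up from lower $\gamma$ and
  higher $K_{BC}$ is offset by the longer rise to a two-fold-higher peak.
  The corresponding test asserts the faster-direction expectation and is
  an accepted failure, kept as a marker of this reconstruction gap.
* Simulated Hill coefficients (≈ 1.3–1.7) are steeper than in vitro
  motility values (≈ 0.4–0.7); motility assays are known to compress
  cooperativity, and all comparisons are made within the model.
* Crossbridge mechanics, sarcomere-length dependence, and thick-filament
  regulation are outside the model: force is simply the myosin-bound unit
  count.
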