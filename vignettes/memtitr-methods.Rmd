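---
title: "Methods: constant-pH enhanced sampling and pKa profiling on an exactly solvable membrane surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constant-pH enhanced sampling and pKa profiling on an exactly solvable membrane surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtitr)
```

## The surrogate model

Estimating how the proton-binding affinity of a titratable residue changes
as it buries into a lipid bilayer requires simulation machinery with many
interacting parts: constant-pH dynamics that couple conformational and
protonation sampling, enhanced-sampling schemes (pH replica exchange,
umbrella sampling, replica-exchange umbrella sampling) to reach rarely
visited insertion depths, and an analysis stack (WHAM, reweighting,
sliding-bin Henderson–Hasselbalch fits, bootstrap and jackknife errors)
that turns biased trajectories into pKa and free-energy profiles.  Each of
those parts can fail silently.  `memtitr` reimplements the full machinery
on a surrogate for which *every* target quantity has a closed form, so each
estimator can be checked against exact ground truth rather than against
another simulation.

The surrogate is a single titratable particle at position $z$ (nm) along
the membrane normal ($z = 0$ near the phosphate plane, water on the
positive side).  Each protonation state $s \in \{\mathrm{prot},
\mathrm{deprot}\}$ feels its own potential $U_s(z)$, a sum of Gaussian
wells/barriers and sigmoid steps anchored so that
$U_s(z_\mathrm{w}) = 0$ at a water reference $z_\mathrm{w}$ (default
2 nm = +20 Å, the outermost water umbrella of the published ladders).
Together with the aqueous reference $\mathrm{p}K_a^\mathrm{w}$ this fixes
the complete semi-grand-canonical thermodynamics:

* local affinity:
  $\mathrm{p}K_a(z) = \mathrm{p}K_a^\mathrm{w} +
  \beta\,[U_\mathrm{deprot}(z) - U_\mathrm{prot}(z)]/\ln 10$;
* titration: $f_\mathrm{deprot}(z, \mathrm{pH}) =
  1/(1 + 10^{\mathrm{p}K_a(z) - \mathrm{pH}})$ (Henderson–Hasselbalch);
* position density at fixed pH:
  $\rho(z) \propto \sum_s w_s(\mathrm{pH})\, e^{-\beta U_s(z)}$ with
  $w_\mathrm{deprot}/w_\mathrm{prot} = 10^{\mathrm{pH} -
  \mathrm{p}K_a^\mathrm{w}}$, and the PMF $-k_BT \ln \rho$.

The state-weight ratio $10^{\mathrm{pH} - \mathrm{p}K_a^\mathrm{w}}$ is the
same for acids and bases: the residue class only decides which state counts
as *ionized* (deprotonated for Asp/Glu/Cys/Tyr/C-ter-like acids, protonated
for His/Lys/N-ter-like bases).  Writing it once this way keeps the
conditional used by the titration kernel and the marginal used by the
density oracle consistent — they must be, or the stationarity tests would
fail.

The shipped `asp_like_model()` (acid, $\mathrm{p}K_a^\mathrm{w} = 3.94$)
gives the neutral form a shallow interface well (−4 kJ/mol Gaussian near
$z = 0.2$ nm) and the ionized form an 18 kJ/mol sigmoid desolvation step,
shifting the pKa up by ≈3 units at full insertion; `his_like_model()`
(base, 6.54) is the mirror image.  Those magnitudes are typical of the
shifts reported for titratable residues at lipid interfaces.  The potential
family (Gaussian + sigmoid) is deliberately minimal — enough to emulate
interface wells and core barriers; other shapes can be added to
`validate_term()` as an extension point.

Internal units are nm and kJ/mol (the units in which umbrella force
constants are quoted, kJ mol⁻¹ nm⁻²); user-facing profiles are reported in
Å and, for PMFs, kcal/mol (1 kcal = 4.184 kJ), matching how such profiles
are usually plotted.  Temperature defaults to 300 K.

## Dynamics and titration

The engine is overdamped Brownian dynamics in $z$ — the conformational
MD of the original methodology contributes nothing to the *sampling-scheme*
questions the package addresses, so thermostats, constraints and inertia
are deliberately absent.  Between dynamics segments the protonation state
is resampled from its exact conditional
$P(\mathrm{deprot} \mid z, \mathrm{pH})$, an exact heat-bath kernel.  This
mirrors the role of the Poisson–Boltzmann/Monte-Carlo step of
stochastic-titration constant-pH MD (full protonation re-equilibration at
fixed conformation) and makes detailed balance provable rather than
approximate.

Time is measured in "toy picoseconds": titration attempts every 20 units
starting at $t = 0$, exchange attempts every 20 units starting at $t = 10$
(offset so the two never coincide), and the first 25 units of every
replicate flagged — not deleted — as equilibration, so the discard rule is
owned by the analysis layer.  All cadences are configurable; the titration
period in particular is not prescribed by the original protocol and simply
mirrors the exchange cadence by default.

One numerical point matters.  A plain Euler–Maruyama step is unstable for
the stiff umbrellas at this cadence ($\beta D k\,\Delta t \approx 4$ for
$k = 1000$ kJ mol⁻¹ nm⁻², $\Delta t = 0.1$, $D = 0.1$ nm²/time).  The
engine therefore integrates each step by splitting: the harmonic bias is
applied as an exact Ornstein–Uhlenbeck update (decay factor
$e^{-\beta D k \Delta t}$, exact stationary variance $k_BT/k$), and the
soft model force explicitly.  This is unconditionally stable, exact for a
pure harmonic window, and leaves the documented single-step
`brownian_step()` (plain Euler, used in closed-form unit tests) untouched.

## Exchange kernels

*pH replica exchange.*  Replicas at the rungs of a pH ladder periodically
attempt Metropolis swaps of their pH labels between adjacent rungs.  For
one site with proton count $N$, $P(N \mid \mathrm{pH}) \propto
10^{(\mathrm{p}K_a - \mathrm{pH})N}$, so the ratio of the swapped to the
current assignment is $10^{(\mathrm{pH}_i - \mathrm{pH}_j)(N_i - N_j)}$ and
the Metropolis exponent is
$\Delta = \ln 10\,(\mathrm{pH}_j - \mathrm{pH}_i)(N_i - N_j)$: moving the
more protonated configuration to the lower pH is favourable.  The package's
discrete-state flux test verifies this kernel's detailed balance exactly;
the derivation is spelled out here because sign conventions in this
criterion are easy to get backwards (an inverted sign *preferentially*
swaps protonated replicas to high pH and still "runs fine").

*Replica-exchange umbrella sampling.*  Adjacent umbrella windows swap
configurations with exponent
$\Delta = \beta[V_m(\xi_j) - V_m(\xi_i) - V_n(\xi_j) + V_n(\xi_i)]$, where
$V_m(\xi) = \tfrac{k_m}{2}(\xi - \xi_m)^2$.  Accepted swaps exchange the
ladder labels (window reference or pH value), not the coordinates —
equivalent and cheaper, at the cost of replica trajectories that hop along
the ladder; the record table tags every frame with both its replica id and
its current label so either view can be reconstructed.  Sweeps alternate
even/odd adjacent pairs deterministically (the alternation itself is a
reproducibility choice; attempting all pairs every cycle is equally valid
and not what is implemented).  A one-rung ladder disables exchange with a
warning.

Window ladders follow the published geometry: 2 Å spacing from +20 Å down
to the per-residue maximum insertion (17 windows for +20…−12 Å), force
constant 1000 kJ mol⁻¹ nm⁻², or the split rule 500 (20…8 Å) / 1000
(6…−12 Å), plus the 1 Å variant spanning +12…−10 Å (23 windows).  pH
ladders are the four printed simulation values per residue, extendable by
two rungs on the ionized side (higher pH for acids, lower for bases); the
extension continues the ladder's own spacing, which is unit spacing for
all printed ladders.

## The analysis stack

**WHAM.**  Window histograms share one $\xi$ grid (0.2 Å bins, the same
grid as the ionized-population profiles) and are unbiased by the standard
self-consistent iteration, converged when every window free energy moves
by less than $10^{-7}\,k_BT$ (at most $10^5$ iterations; exceeding them is
an error, not a warning).  Non-overlapping adjacent windows are an error
naming the gap.  The PMF is anchored to min 0 over covered bins; empty
bins are `NA`, never zero.

**Jackknife.**  PMF errors come from leave-one-out resampling over
replicates: each leave-one-out profile is a full WHAM solution of the
pooled histograms of the remaining replicates, profiles are re-anchored at
a common reference bin (default: the water-side end of the common
coverage, where all profiles are flat), and the error is
$\sqrt{\tfrac{n-1}{n}\sum_i(\mathrm{PMF}_i - \overline{\mathrm{PMF}})^2}$
per bin.  With three replicates each leave-one-out profile comes from a
pair, which is the published reading of "combining PMF pairs".

**Reweighting.**  Per-frame weights
$w(\xi) \propto 1/\sum_j N_j e^{\beta(f_j - V_j(\xi))}$ (the
WHAM-consistent umbrella estimator) turn biased populations into unbiased
averages; weights are normalised to mean 1, strictly positive, and frames
outside the histogram support are still weighted by the global formula
(with a tail warning) rather than dropped.

**Ionized populations.**  Half-open 0.2 Å bins from −15 to 25 Å count
ionized configurations over all replicates and pH values, equilibration
excluded.  Whether the published "probability of the ionized species" is a
per-bin fraction or a normalised density of ionized frames is ambiguous;
both columns (`fraction`, `density`) are emitted.

**pKa profiles.**  A 1 Å bin slides from −12 to 22 Å in 0.25 Å steps
(left-edge anchored, half-open, final left edge 21 Å → 133 bins).  Within
each bin, frames are pooled over replicates and pH, protonation is
averaged per pH, and a one-parameter Henderson–Hasselbalch curve (Hill
slope fixed at 1 — the published protocol names the HH equation, not a
Hill fit) is fitted by least squares — but only when every gate holds:
at least 50 frames in *each* protonation state (frames, not per-pH
averages), each state seen at ≥2 pH values and ≥2 replicates, and per-pH
mean protonation non-increasing with pH within an absolute slack of 0.02
(configurable; zero slack would reject bins for pure counting noise).
Gate failures are statuses, not exceptions, and the gates are evaluated in
a fixed order (points → pH → replicas → monotonicity), so a bin failing
several gates reports the first.  Row order of the input never changes a
status or an estimate.

**Bootstrap errors.**  Fitted bins get a Bayesian bootstrap: 1000
resamples drawing flat-Dirichlet weights over frames within each pH group,
refitting the weighted titration curve each time; the error is the sd of
the bootstrap pKa distribution and failed refits are counted.  Resampling
at frame level within pH groups is the default reading of bootstrapping
"average protonation samples"; a replicate-level option
(`level = "replicate"`) is provided for the other reading.

**Alignment.**  Profiles from different window ladders are made comparable
by adding the constant that minimises their mean-squared difference over a
stated region (in practice the flat water region).

## Membrane geometry

For all-atom coordinate data the package carries the geometric estimators
as well.  Insertion is the signed distance (water-positive) from the
titratable site to the mean height of the *closest leaflet's* phosphate
atoms within a 6 Å radius, falling back to the whole closest leaflet —
with a flag — when fewer than 5 atoms are inside (the published rule
states the ≥5-atom proviso but not the alternative; the whole-leaflet mean
is the only reference that is always defined).  The 6 Å neighbourhood is a
3-D Euclidean ball about the site by default, with a lateral-only option,
since the published text does not specify which; the two differ only when
the site is well above the surface.  Local deformation is the mean
phosphate height within 6 Å minus that of bulk phosphates beyond 15 Å,
same leaflet.  Distances are minimum-image in the membrane plane; $z$ is
non-periodic.  The GRO reader handles the fixed-column dialect (with or
without velocities) and assigns leaflets by the phosphate $z$ median.

The synthetic surface generator provides ground truth for these
estimators: jittered-lattice phosphate pseudo-atoms (default 0.25 nm
spacing), an upper-leaflet dimple of depth $A$ under the site, and
optional Gaussian vertical roughness.  The dimple is a plateau of exactly
$-A$ out to 6 Å with a cosine taper to exactly zero at 14 Å — flat where
the local estimator looks, zero where the bulk estimator looks — so at
zero roughness both estimators reproduce the recorded truth to machine
precision, by construction rather than approximately.  (A Gaussian dimple
cannot deliver that: its local average is shallower than $-A$ and its tail
leaks past the bulk radius.)  Two estimator properties worth knowing: with
roughness and a site *above* the surface, the 3-D ball preferentially
captures upward-fluctuating atoms, biasing the local mean slightly toward
the site (the lateral option avoids this); and elevated sites legitimately
trigger the whole-leaflet fallback.

## What the tests do and do not show

The test suite validates every estimator against the surrogate's closed
forms: WHAM against the analytic PMF (17-window, 2 Å ladder at force
constant 250 kJ mol⁻¹ nm⁻², three replicates of 2×10⁵ exactly distributed
draws per window, agreement within 0.1 $k_BT$ on all bins with ≥100
counts), the pKa pipeline against the analytic profile (≥90% of fitted
bins within twice their bootstrap error; flat models give flat profiles),
exchange kernels against brute-force two-sampler estimates and exact
discrete-state flux balance, and the aqueous titration pipeline against
the printed reference pKa values (closed form to 0.02; 10⁵ heat-bath
resamples per pH to 0.05).  The WHAM study draws i.i.d. samples from the
exact biased law rather than running Brownian dynamics: that isolates
estimator error from sampler error, which is the point of an oracle test;
the sampler itself is validated separately by stationarity tests.  The
force constant 250 for that study (rather than the production 1000) is an
overlap choice made at design time: with $\sigma \approx 1$ Å and 2 Å
spacing every report bin keeps high expected counts, so the 0.1 $k_BT$
band measures WHAM, not shot noise.

Problem sizes throughout (10³–10⁵ frames per series, 10⁵ titration
resamples, 1000 bootstraps) are desk-scale choices: large enough that
statistical error sits well inside each stated tolerance, small enough to
run in seconds to minutes.

What passing these tests does **not** show: anything about force fields,
real lipid structure, multi-site coupling, or the conformational kinetics
of real peptides.  The surrogate has no slow orthogonal degrees of
freedom, so it cannot exhibit the kinetic trapping of charged species that
motivates enhanced sampling in the first place — it verifies that the
schemes and estimators are *correct*, not that they are *necessary*.
Known limitations, in one place: single titratable site (proton count 0
or 1, no site–site coupling); one-dimensional reaction coordinate;
exchange swaps labels rather than coordinates (bookkeeping, not physics);
the Euler step of `brownian_step()` requires $\beta D k\,\Delta t \ll 1$
if used directly with stiff restraints; and the ionized-population
ambiguity noted above.
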