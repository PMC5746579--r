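---
title: "glycoflow: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glycoflow: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The luminal surface of endothelial cells carries a glycocalyx: membrane-anchored
proteoglycan core proteins (stiff, largely alpha-helical dimers) bearing flexible,
negatively charged heparan-sulfate sugar chains. Blood flow past this brush both
deforms it and is disturbed by it, and the resulting spatial structure of the
shear stress is believed to drive mechanotransduction. Resolving this coupling
experimentally, inside a layer tens of nanometres thick, is not currently
possible; fully atomistic simulations of such systems require millions of atoms
and supercomputer allocations.

`glycoflow` implements both halves of a desk-scale computational analogue:

1. a coarse-grained, nonequilibrium particle simulator producing trajectories
   with the statistical structure such analyses assume — thermally noisy solvent
   driven by a uniform body force in x, flowing past wall-anchored stiff cores
   with flexible tethered chains, confined between a frozen wall and a frozen
   ceiling; and
2. the complete post-processing stack: region-partitioned velocity profiles and
   temporal contours, planar velocity fields with streamline integration and
   vorticity, forward-difference shear-stress statistics with two-sample
   Kolmogorov–Smirnov comparisons and ratio-exceedance reports, and
   polar-coordinate tracking of chain segments (swing, swirling, uncoiling,
   motion correlation).

The analyses communicate with the simulator only through the trajectory file
contract (extended XYZ plus a plain-text topology sidecar), so externally
produced trajectories can be analysed through the same interfaces.

## The simulator

### Force field and integration

The simulator runs in reduced units, $\epsilon = \sigma = m = k_B = 1$. Forces
are the sum of:

* a purely repulsive (WCA) pair force truncated at $\min(r_c, 2^{1/6})$ between
  all particle pairs;
* harmonic bonds ($k = 100$, rest length $1$) along chains and at the
  chain-to-core tether; stiffer bonds ($k = 400$) plus a cosine angle term
  ($E = k_\theta(1 + \cos\theta)$, $k_\theta = 100$) along core oligomers only,
  so cores are rigid lumps and chains are freely flexible — the core/chain
  stiffness contrast the reference system exhibits;
* harmonic tethers pinning each core's two bottom beads above its wall anchor
  (two tethers fix both position and orientation);
* a constant body force $f_x$ on every solvent bead above the wall surface.

Time stepping is velocity Verlet; temperature is controlled by a Lowe–Andersen
thermostat: each mobile pair within $r_c$ has probability $\Gamma\,\Delta t$ per
step of resampling the component of its relative velocity along the pair axis
from the Maxwell distribution at temperature $T$, applied symmetrically. The
update conserves pair momentum exactly and depends only on relative velocities
(Galilean invariance), which is why this thermostat — unlike velocity-rescaling
or Langevin schemes — does not bias a mean flow. Pairs are visited in sorted
index order from one seeded stream, so runs are bit-reproducible.

Walls are single frozen lattices at $z = 0$ and $z = L_z$ with a deterministic
checkerboard corrugation of $\pm 0.25\,\sigma$. Frozen particles exert forces
but never move; the corrugation makes them exchange x-momentum with the fluid
(a smooth frozen plane would be free-slip and the body-forced flow would
accelerate without bound, since the thermostat conserves momentum). Soft
containment planes at $z = 0$ and $z = L_z$ catch the rare bead that penetrates
the lattice; they are active only when frozen walls exist.

### System construction

`build_system()` places the lattices, the cores (vertical bead rods), and the
chains (initially straight rods fanning upward from each core apex). Chains
from neighbouring cores can intersect at construction; a deterministic
overlap-resolution pass pushes any polymer bead pair to at least
$0.6\,\sigma$ before solvation. Solvent is placed by random sequential
insertion with minimum pair distance $0.8\,r_c$; velocities are
Maxwell–Boltzmann at $T$ with the net drift removed. Because random sequential
insertion jams near number density $\approx 0.45\,\sigma^{-3}$ at this minimum
distance, the package's stated solvent density is $0.40\,\sigma^{-3}$.

A thermostatted zero-force equilibration segment precedes production (the
analogue of a pre-equilibration protocol); during equilibration only, the net
force on each particle is capped at $50$ reduced units so the freshly
constructed geometry relaxes instead of detonating.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `f_x` | 0.05 (full), 0.08 (desk preset) | $\epsilon/\sigma$ | body force per solvent bead; sets the flow amplitude |
| `temperature` | 1 | $\epsilon/k_B$ | thermostat target |
| `gamma` | 2 | $1/\tau$ | pair collision rate; $\Gamma\,\Delta t < 1$ required |
| `r_c` | 1.3 | $\sigma$ | pair list / thermostat range (repulsion truncated at $2^{1/6}$) |
| `dt` | 0.005 | $\tau$ | integration step |
| `n_cores` | 3 | — | 0 = no-brush control, 1 and 3 mirror the one- and three-dimer scenarios |

Trajectories carry an explicit unit-scale map (default 1 length unit = 1 nm,
1 time unit = 1 ps), so analyses can report physical units; shear stresses are
reported through a user-supplied viscosity, with the TIP3P-water value
0.321 mPa s as the conventional default. For reduced-unit work,
`estimate_viscosity()` recovers $\mu$ from a chain-free body-forced channel
profile via the Poiseuille relation $\mu = -\rho f_x / (2a)$, $a$ the fitted
quadratic coefficient.

### The desk-scale stated world

`desk_preset()` / `desk_regions()` define the configuration used by the
seed-replicated qualitative checks: box $12 \times 12 \times 36\,\sigma$,
regions ending at $7.2 / 21.6 / 30\,\sigma$ — the reference geometry's
12/36/50 nm in a 72 nm box at half scale, so the "flow" region stays clear of
the ceiling boundary layer and the chain brush (cores of 7 beads, chains of 10)
tops out inside the dendritic region. Production is 12 000 steps of
$\Delta t = 0.005\,\tau$ (60 $\tau$, about 30 s on one CPU), sized to the
stated per-suite budget of the acceptance checks.

Two deliberate calibrations, made once and then frozen:

* **Density 0.40 $\sigma^{-3}$** — the highest density the packing contract
  (minimum pair distance $0.8\,r_c$ by random sequential insertion) can reach
  reliably.
* **Body force $f_x = 0.08$ (desk preset)** — at desk scale the time-averaged
  profile of the *control* fluctuates with slowly decaying transverse
  hydrodynamic modes (decay time $\sim \rho L_z^2/(\pi^2\mu) \approx 26\,\tau$,
  commensurate with the 60 $\tau$ window), a noise floor independent of the
  forcing. The brush-induced velocity structure is proportional to the forcing.
  The force was therefore set so the structural signal is not a priori buried
  in that floor. The physical-velocity interpretation is not affected: the
  mapping from the reference system's femtonewton-scale forcing to reduced
  units is free, and the flow stays laminar ($Re \approx 20$ on box scale).

### What the generator does and does not emulate

It emulates: a slab geometry with distinct near-wall / dendritic / flow layers;
thermal noise at a set temperature; momentum-conserving thermostatting
compatible with flow; stiff anchored lumps versus flexible tethered chains; the
no-brush control and one- versus three-core scenarios; zigzag velocity
perturbations and brush damping of flow fluctuations.

It does not emulate: molecular chemistry (no electrostatics, ions, water
structure, or residue detail — one bead is roughly a sugar residue, not an
atom); hexagonal cross-sections (the box is rectangular-periodic); hydrodynamic
scale separation — desk-scale chains are as thick as an analysis bin, whereas
real sugar chains are far thinner than 12 nm bins, so chain-scale disturbance
and bin-scale statistics are not cleanly separated the way they are in a
multi-million-particle system. A green qualitative test therefore establishes
that the analysis stack detects the stated contrast in data with this
structure; it does not validate the reference system's absolute numbers, which
are out of desk-scale reach by construction.

## The analyses

### Regions and profiles

`partition_regions()` fixes the three stacked half-open intervals above the
wall: near-wall (wg), dendritic (d), flow (f). The printed reference heights
12 / 36 / 50 nm are read as *cumulative upper bounds* (thicknesses would
overfill the box). `slice_profile()` bins solvent (bead, frame) samples into
25 equal z-bins over the ectodomain, pooling all samples per bin
(count-weighted; whether one should pool or average per-frame first is
unspecified in the reference — pooling is the documented choice). Empty bins
propagate as missing, never as zero, because zero is a legal velocity. A
sample exactly at the ectodomain top is clamped into the last bin so no sample
is lost; region *membership* (used for regional statistics) stays strictly
half-open.

"Smoothness" of a profile is operationalised as the mean absolute second
difference of bin means over consecutive non-missing triples (`roughness()`):
zero for any linear profile, $4a$ for an alternating $\pm a$ profile. The
statistical test behind the reference's smoothness p-values is not described
there; `compare_roughness()` therefore replicates roughness over disjoint time
sub-windows and applies the package's two-sample K–S test, and is documented
as a stand-in, not a reproduction.

### Planar fields, streamlines, vorticity

`grid_field()` averages solvent samples from a 2-unit-thick slab into a
regular periodic grid; cells left empty are filled by inverse-distance
weighting from the 4 nearest sampled cells and flagged (a field with more than
half its cells empty is refused). Streamlines are advected with fixed-step
RK4 through the bilinearly interpolated *direction* field (unit-speed
parameterisation), step $0.25\times$ cell width, terminating on region-of-
interest exit, a step cap, or stagnation (speed below $10^{-6}$ of the field
RMS). Using the direction field makes streamline geometry exactly invariant
under uniform rescaling of the velocities, which is also what makes arc length
a well-defined statistic. The reference does not define its streamline length
or seeding; here length is the polyline arc length and seeds are cell centres
inside the ROI (deterministic, density-controllable). The ROI defaults to a
centred rectangle holding half the box area.

Vorticity is $\omega_z = \partial_x v_y - \partial_y v_x$ by central
differences with periodic wrap. On a linear field the interior stencil is
exact; the wrapped edge rows are exact only for periodic fields, so analytic
(non-periodic) test fields are checked on interior nodes.

Probability densities are histograms on a shared support with a convergence
trace: the curve is recomputed from the first 25/50/75/100% of the sample and
flagged converged when the final successive L1 distance is below 0.05.

### Shear stress

$\tau = \mu\,\partial v_x/\partial z$ estimated by the forward difference on
bin-centre heights, assigned to the lower bin of each pair; the topmost bin
has no value. With a unit velocity gradient and $\mu = 0.321$ mPa s every
interior bin reports 0.321 mPa — the package's exact worked example.
`shear_series()` evaluates the instantaneous 25-bin whole-extent profile at
each cadence tick and averages per-bin stresses, unweighted, over the bins
whose centres fall in each region (the reference does not state a weighting;
unweighted is the documented reading). Near-zero denominators in ratio
exceedances are excluded and counted rather than propagated as infinities.

The two-sample K–S statistic is computed on the pooled evaluation points
(ties handled exactly); p-values use the asymptotic distribution with
effective size $n_a n_b/(n_a+n_b)$, standard at the hundreds-of-instants
sample sizes these series produce, and verified against exhaustive ECDF
enumeration for all small multisets in the test-suite.

### Segment dynamics

Frames are aligned by translating the reference (core) centre of mass to the
origin — translation only, because the polar angle $\theta$ is measured from
the fixed +x flow axis and a rotational superposition would destroy it.
Tracked segments are 5-bead windows: P1/P2 centred at 40% of the contour of
two chains (bead-count reading of "40% of total length"), P3/P4 the five
terminal beads, plus the core oligomer. The two tracked chains are
auto-selected as those with the largest centre-of-mass x-displacement range,
since the reference's chain labelling is arbitrary. Chains are made whole
across periodic images by walking consecutive beads with minimum-image
displacements before any centre-of-mass computation.

$\theta$ is unwrapped by nearest-branch continuation; frames with $R$
numerically zero have undefined angle and are linearly interpolated (an error
if more than 10% of frames). The winding number is
$\mathrm{sign}(\Delta\theta)\lfloor|\Delta\theta|/2\pi\rfloor$ on the
unwrapped series; direction reversals are counted separately. "Weak
correlation" of segment motions is quantified as Pearson correlation of the
x-deviation series (and of its first differences) with a moving-block
bootstrap interval, block length one tenth of the series — the reference
gives no quantitative definition, so this is the package's documented
operationalisation. Uncoiling is monitored by end-to-end distance and radius
of gyration with a Mann–Kendall trend statistic.

## Numerical choices and degenerate inputs

* Half-open bins everywhere; the single clamp at the ectodomain top is the
  only exception and exists so no sample is silently dropped.
* Missing data propagate as NA (never zero) through profiles, contours,
  series and stresses.
* Hard floor: any mobile pair closer than $0.3\,\sigma$ aborts the run with
  the offending pair — at that separation the WCA force is far beyond what
  $\Delta t = 0.005$ can integrate, so continuing would only manufacture NaNs.
* $\Gamma\,\Delta t \ge 1$ is refused (not a probability).
* K–S p-value at $D = 0$ is defined as 1 (the asymptotic series does not
  converge there).
* All RNG consumed by the simulator flows from the single config seed
  (splitmix64-seeded xoshiro256+ in the compiled core; R's RNG only for
  construction), so identical configuration and seed give byte-identical
  trajectories on a given platform.

## Known limitations

* Two of the four seed-replicated qualitative checks do not hold in this
  stated world and their acceptance tests are deliberately left failing
  rather than weakened. (i) The no-chain control's profile is *rougher* than
  the chain system's: the brush damps the slowly decaying transverse
  hydrodynamic fluctuations that dominate desk-scale profile noise (itself a
  real effect — chains narrow the flow's velocity variation) more strongly
  than its bead-thick chains add systematic zigzag. (ii) The median regional
  stress hierarchy places the dendritic region highest, not lowest, because
  $\sigma$-thick chains windmilling about their apex tethers stir that region
  at the same length scale as the 25-bin difference stencil. Both are
  desk-scale artefacts of the brush being a bin-scale object; in the
  reference system the chains are far thinner than an analysis bin.
* The qualitative seed-replicated checks inherit desk-scale noise: regional
  instantaneous shear statistics mix the physical velocity-gradient signal
  with per-bin sampling noise whose spatial structure (solvent depletion by
  cores and chains) itself mirrors the brush geometry. The methods cannot and
  do not claim to reproduce the reference system's absolute stresses,
  p-values, or the vorticity crossover value.
* The simulator's chains are bead-thick relative to the analysis bins; the
  scale separation of a multi-million-particle system is not reproduced.
* Streamline and ROI conventions are package definitions (documented above),
  not reconstructions of the reference figures.
* The block-bootstrap interval in `motion_correlation()` uses the session RNG
  and is reproducible only under an external `set.seed()`.
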