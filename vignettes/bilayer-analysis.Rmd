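---
title: "Membrane trajectory analysis with ommtraj: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane trajectory analysis with ommtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommtraj)
```

## Scope

`ommtraj` analyzes molecular-dynamics trajectories of planar lipid
bilayers, with defaults tuned to multi-component outer-mitochondrial-
membrane (OMM) models built from POPC, POPE, POPS and PI(3,4)P2 in
150 mM NaCl. It computes three groups of observables:

* **structure** — area per lipid (APL), partial density profiles along
  the membrane normal, phosphate peak-to-peak thickness, the deuterium
  order parameter $S_{CD}$, and charge bookkeeping (total lipid charge,
  surface charge density);
* **dynamics** — lateral diffusion coefficients from multi-origin mean
  squared displacement (MSD), and the first-rank rotational
  autocorrelation function (RAF) of the headgroup vector;
* **interface** — geometric lipid–water and lipid–lipid hydrogen bonds,
  equal-affinity expected hydrogen-bond counts, choline–oxygen charge
  pairs, and Na⁺–lipid contact statistics.

A synthetic trajectory generator produces bilayer trajectories whose
diffusion constants, rotational correlation rates, per-carbon order
parameters, thickness and contact counts are known by construction, so
every analysis stage can be validated without running MD.

## The observables and their definitions

**Area per lipid.** Per frame, $\mathrm{APL} = L_x L_y / N_\text{leaflet}$,
reported as mean ± SD over analyzed frames. Leaflets must be equal in
size; otherwise the function asks for an explicit per-leaflet
normalization rather than silently averaging. The ideal-mixing estimate
$\sum_i x_i\,\mathrm{APL}_i$ over single-component reference areas is
provided for sanity checks against two-component mixtures.

**Thickness.** Phosphate number densities are histogrammed along z after
re-centering each frame on the bilayer midplane (the mean phosphate z).
Thickness is the distance between the two leaflet density maxima, each
refined by a 3-point parabolic interpolation around the maximal bin.
Interpolation matters because the reported precision (0.01 nm) is finer
than any reasonable bin; the default bin width is 0.02 nm. For PI(3,4)P2,
the glycerol-linked phosphate is the bookkeeping phosphate; the ring
phosphates play no role in leaflet assignment or thickness.

**Order parameter.** For carbon $i$ of the saturated sn-1 chain,
$S_{CD} = \langle \tfrac{3}{2}\cos^2\theta_i - \tfrac{1}{2}\rangle$,
where $\theta_i$ is the angle between the C–H bond and the bilayer
normal, averaged over molecules, the two attached hydrogens, and frames.
The normal is fixed to the z axis — the intended systems are planar and
stable, so no per-frame director fit is attempted. Values are stored as
$+S_{CD}$; the plot method draws $-S_{CD}$, the customary axis
convention.

**Diffusion.** Lateral centers of mass are unwrapped by accumulating
minimum-image frame-to-frame displacements (molecules are first made
whole across the periodic boundary, valid while a molecule spans less
than half the box). The mean lateral drift of each leaflet is subtracted
at every step; leaflets can drift antisymmetrically, so drift removal is
per leaflet, not per system. MSD uses every frame as a time origin by
default, with lags to half the trajectory. $D$ is the fitted slope over
the fit window divided by $2N_f$ with $N_f = 2$; the intercept is free,
so a constant offset (e.g. from internal motion) does not bias $D$. The
error estimate is $|D_{\text{first half}} - D_{\text{second half}}|$ of
the fit window. The default window spans 10–50% of the available lags
and is always recorded in the output. Diffusion is reported in
$10^{-8}\,\mathrm{cm^2/s}$ ($= 10^{-3}\,\mathrm{nm^2/ns}$), the natural
magnitude for lipid lateral diffusion.

**Rotational autocorrelation.**
$C_1(\tau) = \langle \mathbf{n}(t_0)\cdot\mathbf{n}(t_0+\tau)\rangle$
over molecules and origins, with $\mathbf{n}$ the unit headgroup vector:
phosphate→nitrogen for POPC/POPE/POPS, inositol C2→C5 for PI(3,4)P2.
Only the first Legendre rank is computed. `fit_raf_decay` fits
$\log C_1$ over the contiguous region above a floor (default 0.1); for
isotropic rotational diffusion the decay rate equals $2D_r$.

**Hydrogen bonds.** Geometric criterion: donor–acceptor distance
< 0.35 nm and the angle between D→A and the D–H covalent bond < 35°.
Each bond is attributed to its donor molecule; if several hydrogens of
one donor satisfy the angle test for the same acceptor, only the
best (smallest-angle) hydrogen counts, so a D–A pair contributes at most
one bond. Intramolecular pairs are excluded. The lipid–lipid interaction
matrix reports donor-capable species from the donor side; POPC, which
has no donor hydrogens, is reported from the acceptor side (bonds it
accepts per POPC molecule). Water hydration counts every lipid–water
bond by default; a water doubly bonded to one lipid counts twice, with a
`count = "waters"` toggle for distinct-partner counting, since the
choice is ambiguous in hydration tables of this kind.

**Equal-affinity expected bonds.** Given a species' observed total bonds
per molecule, the expected count toward each partner is the total times
the partner mole fraction among eligible partners. For donor-capable
rows all lipids are eligible; for the POPC (acceptor-side) row only
donor-capable partners are, and the fractions renormalize over that
subset. Reported values are rounded half-away-from-zero to two decimals.

**Charge pairs and Na⁺ contacts.** Charge pairs are choline methyl
carbons of POPC within 0.4 nm of negatively charged lipid oxygens
(phosphate, carboxylate and phosphoinositide oxygens by default;
carbonyls via a toggle, since the exact oxygen set is a convention). A
Na⁺ is membrane bound when ≥ 1 lipid oxygen lies within 0.325 nm;
multiplicity is the mean number of coordinating lipid oxygens per bound
ion, and the same statistic restricted to carbonyl oxygens is reported
separately.

All distance searches run through a cell list over the orthorhombic
periodic box, constructed to return exactly the all-pairs minimum-image
result (and falling back to the all-pairs path when the box holds fewer
than three cells per dimension). Triclinic boxes are rejected
explicitly.

## Composition bookkeeping

The five OMM model compositions are built in as mole fractions
(`omm_model_fractions`). Integer counts come from nearest-integer
rounding of fraction × total, with the residual absorbed by the most
abundant species; per-leaflet counts are half of each species count,
with odd counts alternated between leaflets. With formal charges
{0, 0, −1, −4} e for POPC/POPE/POPS/PI(3,4)P2 — the PI(3,4)P2 form with
a protonated 4-phosphate — this rounding reproduces the published total
lipid charges of models 1, 2 and 4 (−312, −328, −338 e) exactly. Model
3's published charge (−332 e) is not reproducible from its printed
percentages under any rounding of 6% PI(3,4)P2 (which gives −345 e);
the generator therefore exposes explicit per-species count overrides,
and nothing downstream depends on model 3 charges. Surface charge
density defaults to total charge over four times the leaflet area, the
convention consistent with the published model-1 and model-4 values.

## The synthetic generator

The generator builds "role skeleton" lipids: one atom per role the
analyses touch (phosphate, headgroup nitrogen or inositol carbons,
phosphate/carbonyl/carboxylate oxygens, choline methyls, sn-1 carbons
with two hydrogens each). The four degrees of freedom are generated
independently, each with a closed-form ground truth:

* **Lateral:** independent 2D Brownian walks, per-step Gaussian
  increments of variance $2D\,\Delta t$ per axis, wrapped into the box;
  the unwrapped walk is stored so unwrapping can be checked exactly.
  Default $D$ values are the per-species, per-model published
  magnitudes (e.g. 6.3 × 10⁻³ nm²/ns for POPC in model 2).
* **Headgroup rotation:** isotropic diffusion on the unit sphere via
  tangential Gaussian kicks, for which
  $C_1(\tau) = e^{-2D_r\tau}$ exactly (the conditional mean of a
  spherically diffusing unit vector contracts by that factor regardless
  of its current direction, so the non-equilibrium start does not bias
  $C_1$). The projected-kick scheme has an $O(\sigma^2)$ rate bias at
  large steps, so frame steps are internally subdivided until the
  per-substep angular variance is ≤ 0.0025 rad² per tangent dimension,
  keeping the bias below 1%. Defaults (0.15–0.4 rad²/ns) give
  correlation times of 1–3 ns, a realistic magnitude for headgroup P–N
  vectors; the published account shows curves, not numbers, so these
  are package choices. A deterministic planar-rotor mode
  ($C_1 = \cos\omega\tau$) exists for analytic tests.
* **Tails:** C–H unit vectors drawn at the fixed polar angle
  $\cos^2\theta = (2S+1)/3$ with uniform azimuth and random hemisphere,
  so the ensemble $S_{CD}$ equals the target exactly in expectation.
  The default profile is a 0.22 plateau (carbons 2–8) declining to 0.10
  at carbon 16, the typical shape of a palmitoyl sn-1 profile.
* **Transverse:** phosphate z ~ Normal(±d_PP/2, σ_z²) by leaflet,
  redrawn each frame (i.e. undulations decorrelate instantly), so
  density-profile sampling grows with frame count. Defaults
  d_PP = 4.13 nm and σ_z = 0.15 nm; σ_z is a package choice of a
  realistic phosphate-peak width.

Waters and ions are placed at canonical contact geometries: each lipid
receives its per-species number of hydrogen-bonded waters on a tight
cone above a dedicated acceptor oxygen elevated above the headgroup;
bound Na⁺ sit below the carbonyl region with exactly k ∈ {1,2,3}
coordinating oxygens moved onto a 0.30 nm sphere around the ion; one
choline–oxygen charge pair per POPC is constructed against the nearest
POPC/POPE neighbor. The skeleton offsets were chosen so that every
unintended atom pair stays outside the relevant cutoff with a margin
dominated by the lateral lipid spacing — which is why constructed
hydration, charge-pair and Na⁺ counts are recovered *exactly* on static
snapshots (`n_frames = 1`). In dynamic mode lipids diffuse, waters and
bound ions ride rigidly with their host lipid, and close encounters can
add rare spurious contacts; the charge-pair construction is disabled
there, and contact ground truths are flagged as approximate
(`contacts_exact`). Default water counts (7/8/13/19 per
POPC/POPE/POPS/PI(3,4)P2) and Na⁺ targets (0.29 bound per lipid,
multiplicity 3) are integer-rounded versions of the published
hydration and ion-contact magnitudes. Counter-ion numbers neutralize
the lipid charge exactly, plus a configurable number of bulk salt pairs
(default 110, the 150 mM magnitude for this box volume).

What the generator deliberately does **not** emulate: inter-lipid
forces, realistic molecular geometry (the skeletons are contact-metric
scaffolds, not CHARMM molecules), coupled degrees of freedom (area ↔
order ↔ thickness correlations), slow undulations, water dynamics, or
ion exchange kinetics. Passing the recovery suite therefore shows that
the *analysis* code measures what it claims to measure — it does not
validate force fields or sampling of real trajectories.

## Numerical choices and degenerate inputs

* Units are nm and ps internally everywhere; PDB Å are converted on
  read; GRO is written at its native 0.001 nm precision.
* Leaflets are assigned once, from frame 1, by the sign of the
  phosphate z against the mean phosphate z; flip-flop is assumed absent
  on the hundreds-of-ns scale. A one-sided assignment warns rather than
  errors (degenerate but analyzable input).
* The equilibration skip defaults to 20 ns in the pipeline and is
  applied uniformly; single-frame inputs skip nothing.
* Unwrapping refuses steps of half a box or more (ambiguous under
  minimum image) and names the offending frame.
* `fit_diffusion` requires at least 4 points per half-window;
  `fit_raf_decay` fits only the contiguous head of the curve above its
  floor, so noisy late-time oscillations around zero cannot leak into
  the log fit.
* Ties in the density-profile argmax resolve to the first bin;
  parabolic refinement is skipped at profile edges and for flat
  3-point neighborhoods.
* RNG: every generator stream derives from the single spec seed;
  identical seeds give bit-identical trajectories.

## Validation design and problem sizes

The test suite checks each metric along two independent routes:
analytic limits (parallel/perpendicular/isotropic C–H bonds; planar
rotor; ballistic and static MSD; constructed donor–acceptor geometries
at the criterion boundaries) and brute-force oracles (explicit
double-loop MSD and C₁; 27-image all-pairs contact enumeration) that
the production routines must match to 10⁻¹² or exactly. Parameter
recovery runs at 392 lipids × 2000 frames (dt = 100 ps) for diffusion
and rotation, 392 × 500 samples for $S_{CD}$ (tolerance ±0.01), 784
lipids × 2000 frames for thickness (tolerance one bin, 0.02 nm), and a
784-lipid static snapshot for exact contact recovery. These sizes were
chosen as the smallest at which the estimators' sampling error sits
comfortably inside the stated tolerances.

## Limitations

* XTC trajectories are not read; convert to DCD or multi-frame GRO.
* Orthorhombic boxes only.
* No electron-density thickness, Voronoi per-lipid areas, $P_2$
  rotational correlation, wobble-in-cone fits, finite-size hydrodynamic
  corrections to $D$, or water-bridge analysis — all outside the
  analysis set this package reproduces.
* Roles come entirely from the species map; no bond perception is
  attempted. The shipped CHARMM36-flavored map covers the seven default
  species; other force fields need only a new YAML map.
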