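---
title: "Methods behind lipidbank: observables, quality scores and transport analyses for lipid bilayer simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind lipidbank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidbank)
```

## Scope

`lipidbank` implements the computational core of an overlay-style databank of
lipid bilayer molecular dynamics (MD) simulations. In an overlay databank the
raw trajectories stay wherever they are publicly archived; the databank layer
itself holds only metadata (one YAML entry per simulation, named by a hash of
the raw files), universal molecule/atom naming, computed observables, and
automatic quality scores against experiments. This package provides that
layer's data model and every calculator behind it: C–H bond order parameters,
electron density profiles and X-ray scattering form factors, area per lipid
and bilayer thickness, PCA-based sampling-convergence estimates, quality
evaluation and ranking against NMR and X-ray data, rare-event transport
analyses (lipid flip-flops, water permeation, diffusion anisotropy), and a
composition-to-property regression. Seeded synthetic generators with
analytically known ground truth stand in for trajectory downloads, so the
entire pipeline is exercisable on a laptop.

## The metadata layer

A simulation entry (`parseSimulationEntry()`) requires a raw-data link (DOI),
trajectory and topology file names, software, temperature, trajectory length,
the user-declared equilibration period to discard (`TIMELEFTOUT`, removed
before every analysis), and a composition block mapping each universal
molecule name to its force-field residue name, mapping table and copy number.
We fixed this minimal core as the required schema and preserve all unknown
keys as opaque extras that round-trip unchanged — the on-disk schema of a
community databank grows over time, and rejecting unknown keys would make old
code refuse new entries.

Entry identifiers are an md5 digest of the topology digest concatenated with
the trajectory digest, in that fixed order, so identical raw data always map
to the same folder name, any byte flip changes it, and swapping the two files
changes it too.

Mapping tables translate force-field atom names to universal names and tag
each atom with its fragment (headgroup, glycerol backbone, acyl chain sn-1 or
sn-2). All analyses address atoms by universal names only.

### Matching simulations to experiments

An experiment matches a simulation when (i) every membrane molecule's molar
percentage agrees within 3 percentage units, (ii) charged lipids have
identical counterions, (iii) temperatures agree within 2 K, and (iv) the
hydration is compatible: systems with a molar water/lipid ratio of at least
25 are treated as fully hydrated and not compared further; below that
threshold the water percentage enters the same 3-unit rule. Molar percentages
are computed over membrane molecules only (water and ions excluded), which
keeps the composition rule orthogonal to the hydration carve-out. Matching is
monotone by construction: widening any tolerance can only add matches.

## Membrane observables

**Order parameters.** For each C–H bond,
$S_{\mathrm{CH}} = \tfrac12\langle 3\cos^2\theta - 1\rangle$ with $\theta$
the angle between the bond vector and the membrane normal (the z axis).
The average is taken per lipid first (over frames), and the mean, variance
and SEM are then computed over the per-lipid values: lipids are the
independent samples of the ensemble, frames are not. With equal frames per
lipid this equals the pooled average, which the tests verify. United-atom
topologies without explicit hydrogens are rejected with a clear error —
hydrogen reconstruction is out of scope.

**Electron density and form factor.** Atom positions are centred per frame
on the (electron-weighted) centre of the lipid selection, wrapped into the
box, histogrammed along z with a bin width of 1/3 Å and weighted by electron
counts; the per-frame histograms are averaged. The scattering contrast
$\Delta\rho_e(z)$ subtracts the solvent density completed to its bulk
plateau: the plateau is estimated from the outer 20 % of the box and the
measured solvent profile is raised to it wherever it falls below (i.e.
inside the membrane core where solvent is depleted). This makes
$\Delta\rho_e \to 0$ in bulk by construction, and a uniform solvent
subtracts to exactly zero. The form factor
$F(q) = \left|\int \Delta\rho_e(z)\, e^{iqz}\, dz\right|$ is evaluated by
the midpoint rule on the histogram grid over $q \in [0, 1]$ Å⁻¹ with spacing
0.005 Å⁻¹; no membrane symmetry is assumed. The midpoint rule on a 1/3 Å
grid carries a relative error below 0.5 % over this q range (the tests
compare against the closed-form slab sinc), and the minima locations — the
quantity the quality score uses — are invariant under padding the box with
zero-contrast solvent.

**Area per lipid.** APL $= 2\,\langle L_x L_y\rangle_t / N$ with $N$ the
total number of membrane molecules. The literal reading "box area divided by
total molecule count" halves the conventional 40–75 Å² scale of fluid
bilayers; the per-leaflet denominator ($N/2$ molecules per leaflet)
reproduces it, and is the convention implemented and documented.

**Thickness.** The distance between the two z positions where the lipid and
water electron densities cross, one per side, located by linear
interpolation between bins. Noisy profiles can produce several sign changes
per side; the outermost crossing on each side is used, which is robust to
interdigitation noise near the bilayer centre.

## Sampling convergence (tau_rel)

Conformational sampling of each flexible lipid type is scored by PCA on
heavy-atom Cartesian coordinates. Each configuration (one lipid, one frame)
is superposed onto the average structure of its type — a two-pass procedure:
align to the initial mean, recompute the mean, align again; rotations come
from the SVD-based optimal superposition. All lipids of a type are pooled
into one covariance (`prcomp`); the alternative of averaging per-lipid
covariances would weight lipids equally regardless of their excursions, and
pooling matches the "all heavy atoms of the lipid type" construction. The
slowest mode is PC1; its projection autocorrelation is computed per lipid,
averaged over lipids, and the decay time is the first 1/e crossing, linearly
interpolated between lags. The distribution-convergence time is
$\tau_{\mathrm{conv}} = k\,\tau_{\mathrm{auto}}$ with the empirical
calibration $k = 49$, a fixed constant determined from long reference
trajectories and insensitive to the force field; we do not re-fit it.
Finally $\tau_{\mathrm{rel}} = \tau_{\mathrm{conv}} / \tau_{\mathrm{sim}}$:
values above 1 flag trajectories whose lipids may not have sampled their
conformational ensemble, and ranking discards entries with
$\tau_{\mathrm{rel}} > 1.3$. Rigid molecules (sterols, by a configurable
blacklist) are excluded — their "conformational convergence" is meaningless
and the alignment would be degenerate. A 1/e decay time on the
Ornstein–Uhlenbeck fixture with $\tau = 5$ ns and $10^5$ steps is recovered
within 10 %.

## Quality evaluation

**Per bond.** Treating per-lipid means as independent samples,
$(S_{\mathrm{CH}} - \mu)/(\sqrt{s}/\sqrt{n})$ is t-distributed. The
probability that the simulated order parameter lies within the experimental
error bars $S_{\exp} \pm \Delta S_{\exp}$ (default
$\Delta S_{\exp} = 0.02$) is the CDF mass of that interval. Two numerical
choices matter:

* *Degrees of freedom.* With dozens of lipids the t distribution is nearly
  normal, but poor force fields can sit so far from experiment that normal
  tail probabilities underflow. The 1-degree-of-freedom form (Cauchy) keeps
  far-away simulations on a finite, ordered scale; the dof is configurable.
* *Sign convention.* Written naively the CDF difference comes out negative;
  the implementation uses the argument order that yields the positive
  probability, equal in magnitude by the symmetry of the t distribution.

Bonds whose simulation SEM exceeds the experimental error are excluded
rather than scored: artificially slow dynamics widens the distribution and
would reward the simulation for being poorly converged. At
$S_{\mathrm{CH}} = S_{\exp}$ and SEM $= \Delta S_{\exp}$ the probability is
exactly $F_1(1) - F_1(-1) = 0.5$, a closed-form anchor the tests assert.

**Per fragment and system.** The fragment quality multiplies the mean of the
available per-bond probabilities by the fraction of the fragment's bonds
with a quality available — bonds excluded for large error or lacking an
experimental value count against the score, so sparse coverage cannot
inflate it. The "total" fragment spans all bonds of the molecule, including
the glycerol backbone. System-level scores are molar-fraction-weighted
averages over the scored lipids, with "tails" the per-lipid mean of the two
acyl-chain scores. Fragments with nothing available are absent, never zero.

**Form factor.** Experimental intensities are relative; they are placed on
the simulation scale by the weighted least-squares coefficient
$k_e = \sum |F_s||F_e|/\Delta F^2 \,\big/\, \sum |F_e|^2/\Delta F^2$ (the
tests check it against a numerical 1-D minimizer to $10^{-8}$). Because lobe
heights depend on the simulation box size while minima locations do not, the
quality score is built on the first minimum only: both curves are smoothed
with a Savitzky–Golay filter and the first local minimum at
$q > 0.1$ Å⁻¹ is located in each;
$FF_q = |q_{\min}^{\mathrm{sim}} - q_{\min}^{\mathrm{exp}}| \times 100$.
Numerical choices: the conventional window of 30 points is even, which the
filter definition disallows, so 31 points (order 1) are used; a point-count
window implies a q resolution, so curves are first resampled onto a 0.001 Å⁻¹
grid, making the filter width independent of the input grid; the discrete
minimum is refined by a parabola through its three surrounding points, since
the score is meaningful at resolutions below any practical grid spacing;
ties resolve to the smallest q. The second minimum is deliberately not used —
it is hard to locate automatically in noisy experimental sets.

## Transport analyses

**Leaflets and flip-flops.** Molecules are assigned to leaflets by their
headgroup z relative to the midplane, with a 1 nm midplane zone inside which
the previous label is retained. A flip-flop requires confirmed residence: a
maximal run of at least 100 frames in the opposite leaflet (zone frames
retain the label and continue the run). A crossing that returns before the
cutoff contributes no event in either direction; a crossing that dwells past
the cutoff and then returns (again past the cutoff) is two translocations.
This endpoint-plus-confirmation reading satisfies both the residence
invariant and the scripted-event examples; note that any residence criterion
loses exact time-reversal symmetry at the trajectory boundaries (a final run
longer than the cutoff has no mirror if the initial run is shorter), so the
reversal invariance holds whenever the resting runs at both ends exceed the
cutoff. The rate is events per molecule per time, $n/(N t)$, making
single-molecule and ensemble rates commensurate; with zero events $1/(Nt)$
is reported as the upper limit.

**Permeation and permeability.** A permeation event is a complete traversal:
bulk on one side, through the slab, bulk on the other side. Rebounds count
nothing, and because both bulk regions belong to the same water slab across
the periodic boundary, direct bulk-to-bulk transitions that bypass the slab
are movement within bulk, not permeation. The permeability is
$P = r / (2 c_w)$ with $r$ the event rate per time and area and
$c_w = 33.3679$ nm⁻³ the bulk water concentration; 10 events in 100 ns over
25 nm² give 59.94 μm/s, the unit-chain anchor in the tests.

**Diffusion.** The lateral coefficient comes from the Einstein relation,
$D_\parallel = $ slope/4 of the lateral MSD, fitted over lags between 10 %
and 50 % of the trajectory — below that the motion may be ballistic, above
it poorly sampled. A fit with $R^2 < 0.9$ or with meaningful curvature is
flagged rather than silently reported. Perpendicular transport in a
multilamellar stack is permeation-limited; the Tanner relation combines the
channels harmonically,
$D_\perp = D_\parallel P z_w / (D_\parallel + P z_w)$, with
$z_w$ the water layer thickness (box height minus bilayer thickness);
$D_\perp$ can exceed neither channel. Activation energies come from a
least-squares Arrhenius fit of $\ln P$ vs $1/T$ and are expressed in units
of $k_B T_{\mathrm{ref}}$ with $T_{\mathrm{ref}} = 310$ K — the
physiological reference, which the bare "$k_BT$" unit otherwise leaves
implicit. Binned property summaries weight by simulation length and drop
bins with too little data (for permeation, at most 1 μs total).

## Composition → property regression

Compositions are featurized as molar fractions over eight classes: POPC,
POPE, POPG, POPS and cholesterol explicitly, and sphingomyelins,
cardiolipins and PI lipids grouped by headgroup regardless of acyl chains.
Water, ions, temperature and salt are not features. Two families are
built in: ordinary linear regression and ridge (glmnet, penalty grid
$10^{2}$–$10^{-6}$ searched by seeded 5-fold cross-validation on the 80 %
training split); other regressors can be layered on the same interface but
linear regression is the recommended default for its simplicity and
test-split performance. The linear family is fitted without an intercept:
the fractions sum to one, so an intercept is collinear and would leave the
class coefficients unidentifiable, whereas the no-intercept form recovers
noiseless synthetic coefficients exactly (to machine precision, as the
tests assert) and makes the prediction a transparent fraction-weighted sum.
For cardiolipin-containing membranes an auxiliary per-acyl-chain area is
reported by rescaling the per-molecule area with the chain count ratio
$1/(1 + x_{CL})$ (cardiolipin carries four chains where other lipids carry
two).

## Synthetic fixtures: what they do and do not show

Every generator is seeded and deterministic, and its ground truth is
analytic, never computed by the code under test:

* oriented C–H ensembles place bonds at the fixed polar angle
  $\theta = \arccos\sqrt{(2S+1)/3}$, inverting the order parameter formula;
* slab density profiles carry the closed-form factor
  $|2\rho\sin(qd/2)/q|$ with its first zero at $2\pi/d$;
* leaflet and permeation scripts realize exact event counts under the
  detection rules;
* Ornstein–Uhlenbeck series use the exact discretization
  $x_{t+1} = \phi x_t + \sqrt{1-\phi^2}\,\sigma\varepsilon$;
* Brownian walkers have MSD $= 4Dt$ by construction;
* regression tables are linear in composition with known coefficients.

The schematic bilayer (`makeSyntheticBilayer()`) combines these into a full
trajectory with exact area per lipid, near-exact thickness and order
parameter targets, and `buildMiniDatabank()` writes a three-entry databank
tree (one entry deliberately generated with slow conformational noise so its
$\tau_{\mathrm{rel}}$ exceeds the 1.3 discard threshold) that flows through
analysis, quality evaluation and ranking end to end.

These fixtures are oracles, not membranes: they have no realistic chain
packing, undulations, protrusions or finite-size couplings, their "water" is
a uniform pseudo-density, and their dynamics is white or OU noise rather
than molecular kinetics. Passing tests therefore demonstrate that the
estimators compute their defining quantities correctly and reproducibly —
not that any particular force field is accurate, which is exactly the
question the quality scores are designed to answer on real data.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run on deliberately small problems:
ensembles of tens of lipids and tens of frames, $10^5$-step OU series, 200
Brownian walkers, a three-entry mini-databank. These sizes were chosen so the
stochastic recoveries have comfortable statistical power (e.g. the MSD slope
estimator needs many walkers because long-lag MSD values are strongly
correlated) while the whole suite stays interactive.

Degenerate inputs are errors, not silent results: empty selections, missing
hydrogens, collinear structures in alignment, absent density crossings,
zero experimental form factors, zero-length observation times. Quantities
that are genuinely undefined (a fragment with no scored bonds, a curve with
no first minimum in range) are reported as absent with a diagnostic, never
as zero — a zero would be a (bad) score.

## Known limitations

* Binary MD trajectory formats are not read; the frame-ensemble abstraction
  accepts multi-model PDB (via bio3d) and a plain CSV serialization.
* Hydrogen reconstruction for united-atom force fields is not provided;
  such inputs are rejected.
* The k = 49 calibration is taken as fixed; re-deriving it needs long
  reference trajectories.
* Free-energy-based permeability (inhomogeneous solubility-diffusion) is
  out of scope; only the counting estimator is implemented.
* The regression families shipped are linear and ridge; tree/boosting
  ensembles would need additional dependencies and add little for
  composition-only features.
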