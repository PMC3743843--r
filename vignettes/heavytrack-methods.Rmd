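---
title: "Modelling clustered DNA damage from heavy-ion tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clustered DNA damage from heavy-ion tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heavytrack)
```

## The problem

A single heavy ion (Fe at ~400 MeV/n, LET 200 keV/µm; or C at 290 MeV/n,
70 keV/µm) crossing a fibroblast nucleus deposits its energy in a narrow
track core surrounded by a halo of delta electrons. The double-strand breaks
(DSBs) it induces are therefore strongly clustered along the trajectory,
visible as γH2AX "tracks" whose large foci resolve, after deconvolution
microscopy, into many small closely spaced foci. `heavytrack` provides a
desk-scale simulation and analysis chain for this situation:

1. **dosimetry** — dose ↔ fluence ↔ per-nucleus Poisson traversal counts;
2. **track physics** — stochastic energy-deposition patterns for one
   traversal, calibrated to the nominal LET;
3. **DNA damage** — strand-break scoring on a random 150 bp segment target
   and DSB pairing;
4. **spatial analysis** — radial classification around the trajectory and
   single-linkage focus clustering;
5. **synthetic foci / imaging** — repair-kinetics evolution of focus sets
   and rendering of 3D fluorescence z-stacks;
6. **quantification** — restoration, focus detection, width and cluster
   statistics.

## Dosimetry

At unit density, 1 Gy corresponds to 6.242 keV/µm³, so the fluence carrying
dose $D$ at linear energy transfer $L$ is $\Phi = 6.242\,D/L$ particles/µm².
The nucleus is an oblate ellipsoid (12.67 µm diameter × 2.8 µm depth). For
edge-on (horizontal) irradiation the presented area is taken as the
rectangular silhouette, diameter × depth: with the exact elliptical
silhouette (a π/4 factor) the expected traversal count for 1 Gy Fe would be
~0.87 rather than the ~1.1 the rectangular chord approximation gives; the
rectangular form is retained as the model's convention. The ~5° tilt of the
horizontal geometry (cos 5° ≈ 0.996) is ignored, far below the other
approximations. Per-cell traversal numbers are Poisson, so the fraction of
cells hit at mean $\mu$ is $1 - e^{-\mu}$ — about 0.667 at $\mu = 1.1$,
which rounds to the conventional "~70%".

## Track structure

The transport model is deliberately simple — no event-by-event cross
sections — but is built so that the quantities that matter downstream (LET,
the delta-electron spectrum, the radial energy profile, and the *local
clustering* of depositions) are right.

**Spectrum.** Delta-electron kinetic energies follow the free-electron
(Rutherford) spectrum $dN/dE \propto E^{-2}$ truncated to
$[E_\mathrm{min}, E_\mathrm{max}]$, with $E_\mathrm{max} = 2 m_e c^2
\beta^2\gamma^2$ from the ion's energy per nucleon (1.12 MeV at 416 MeV/n).
The lower cutoff is 10 eV; under $1/E^2$ this makes the fraction of
electrons below 100 eV exactly
$(1/10 - 1/100)/(1/10 - 1/E_\mathrm{max}) = 0.900$.

**Energy budget.** Collisions are drawn until their cumulative energy
reaches LET × path length, the final electron being clamped to the
remainder. A plain Poisson number of collisions would leave ~20% per-track
energy scatter (the $1/E^2$ tail is heavy); the budget scheme pins every
realisation to the nominal LET, which is what "calibrated to the LET" means
here.

**Range-energy model.** A piecewise power law (log-log linear) through
(10 eV, 1 nm), (100 eV, 3 nm), (10 keV, 4 µm), (1.12 MeV, 300 µm). These
anchors satisfy the qualitative constraints the model must honour: sub-5 nm
ranges below 100 eV, nm-to-µm ranges for the bulk of the spectrum, and a
sub-0.1% population reaching ~100 µm.

**Walks, track ends and spurs.** Each electron deposits ~12 eV ionisations
along a persistent random walk. Two features matter and are worth stating
explicitly because the naive alternative (uniform ~60 eV steps) produces
essentially *no* DSBs beyond 1 µm from the axis:

* *Residual-range spacing.* Step lengths follow the CSDA-like law
  $\Delta r_j = R(E_{j-1}) - R(E_j)$: a fast electron deposits sparsely
  while it is fast and finishes in a dense terminal cluster at its range.
  Those track ends, scattered micrometres off-axis by 3–30 keV electrons,
  are where isolated distant DSBs come from.
* *Spur substructure.* Each ~60 eV energy-loss event is resolved into
  ~12 eV sub-ionisations within ~0.8 nm. Opposite-strand breaks within
  10 bp (3.4 nm) almost always originate from one such spur when the track
  environment is sparse; without spurs, sparse path segments cannot pair
  breaks at all.

Primary collision sites are smeared perpendicular to the axis with a 4 nm
impact-parameter spread, and each collision leaves a small on-axis deposit
(`core_ev`, 0 eV in the shipped calibration — all energy is carried by
electrons; the `origin` tag distinguishes collision-site from
electron-mediated depositions when `core_ev > 0`). Emission polar angles
follow the kinematic $\cos\theta = \sqrt{E/E_\mathrm{max}}$, so slow
electrons leave perpendicular and the rare energetic ones are thrown
forward. Walk directions accumulate Gaussian jitter, making slow electrons
tortuous (their blobs locally dense) and fast ones straighter.

The azimuthally averaged radial energy density of the resulting tracks
falls off as $r^{-2}$ over 10 nm–1 µm — the classic penumbra profile, which
is largely insensitive to the details above as long as ranges grow roughly
linearly with energy.

## DNA target and break scoring

DNA is represented as 150 bp linear B-form segments at 13.4 Mbp/µm³
(~89,000 segments/µm³; the whole nucleus would hold ~3 Gbp, a diploid-scale
genome). Each strand is a helical path of point sites (radius 1 nm, rise
0.34 nm/bp, 10.5 bp/turn, strands offset by π), each site a 0.4 nm-radius
sugar-phosphate sphere. Instantiating all ~21 M segments is wasteful;
instead segments are instantiated lazily, cell-by-cell on a 60 nm grid and
only within interaction reach of a deposition or radical, with the exact
same Poisson law (the test suite compares lazy and exhaustive scoring
statistically). The compute-heavy nearest-site search is in C++.

Break rules: a **direct** SSB where the energy assigned to one site
(nearest-site assignment, summed over depositions) exceeds 10 eV strictly;
an **indirect** SSB where an OH radical — generated from water depositions
at `g_oh_per_100ev` per 100 eV, displaced by one isotropic Gaussian jump —
comes within the reaction radius of a site, with probability 0.13 per
encounter. At most one break per (segment, strand, bp) site; depositions
that themselves sit on DNA are not also converted to radicals. A **DSB** is
two opposite-strand SSBs within 10 bp, inclusive ("within 10 bp" is read
inclusively). Pairing maximises the number of DSBs per segment (bounded
search; among maximum matchings the one with smallest total bp separation,
candidates considered in ascending separation with ties to the lower bp
index), so it agrees with a brute-force maximum matching on any realistic
break set.

### Calibration

The radical chemistry is the model's free calibration, and three knobs are
exposed deliberately: the OH yield (`g_oh_per_100ev`), the effective
diffusion length (`diffusion_rms_nm`, representing a scavenging-limited
lifetime), and the reaction radius. The shipped defaults (0.45 per 100 eV,
1.5 nm RMS, 1 nm) were chosen once so that 50-replicate Fe-traversal
simulations land near the reference yields (~84 DSBs per traversal, ~78
within 1 µm of the trajectory, ~6 beyond); with them the model produces
~93 DSBs per traversal, ~88 within 1 µm and ~5.6 beyond. The G-value sits well below the textbook
2.5/100 eV for sparsely ionising radiation because the transport model
already resolves each energy-loss event into several sub-ionisations: at
G = 2.5 every spur would carry multiple radicals and the model
overproduces breaks. These numbers are a calibration of this model, not a
measurement.

Typical problem sizes: one Fe traversal generates ~2.5 MeV of depositions
(~2×10⁵ points after spur splitting), instantiates ~5×10⁵ segments lazily
and takes a few seconds; the 50-replicate yield estimate used by the
acceptance script runs in minutes on one CPU.

## Spatial analysis

Radial distance is perpendicular distance to the (known, in simulation)
track axis. Foci within 1 µm are "track", beyond 2 µm "non-track"
(delta-electron damage), between the two "intermediate" and excluded from
both counts — moving a focus across the 2 µm boundary changes the non-track
count by exactly one. Clustering is single-linkage connected components at
0.5 µm, in 3D by default with a projected-2D mode mirroring scoring on
stacked images; the 1.5 × 1.5 µm² scoring window is treated as a scoring
aid, not a clustering definition, so clusters wider than the window are
flagged, never split. Track qualification uses the strict criteria
length > 8 µm and width > 1 µm on the projected pattern, with patterns
shorter than 0.025 µm treated as indistinguishable from delta-electron foci.

## Synthetic foci and repair kinetics

No kinetic model is fitted anywhere in the source material, so repair is
*emulated*, not estimated: two-class exponential decay with a 2 h half-life
for simple foci and 12 h for foci in clusters of ≥ 4 members, both rates
multiplied by a deficiency factor (1 for NHEJ-proficient, 0.05 for
XLF-deficient cells, which renders counts essentially flat over 72 h). Each
focus draws a single exponential survival time, so counts are monotone
non-increasing in time for every seed by construction. These parameters are
qualitative emulation of the published time-course shapes and are
deliberately not tested against measured focus counts.

The X-ray-like generator places foci uniformly in the nucleus with
truncated-geometric cluster multiplicities (mostly singletons,
$P(m > 7) < 1\%$ at the default $p = 0.5$); the Fe-track-like generator
seeds clusters along the axis with Poisson multiplicities (mean 8, tails
reaching ~30) plus a sparse off-track halo. At realistic per-cell counts
(~35 foci) accidental spatial chaining keeps ≥ 93% of X-ray clusters at ≤ 7
members; at much higher densities chaining would dominate, which is a
property of uniform point processes, not of the generator.

## Imaging and quantification

Stacks mimic the acquisition geometry: 20 slices over 4 µm, 0.065 µm
lateral voxels (100× objective), Gaussian PSF (σ 0.1 µm lateral, 0.3 µm
axial), Poisson shot noise plus Gaussian read noise over a flat background.
Foci are Gaussian spots; because a Gaussian spot blurred by a Gaussian PSF
is again Gaussian, rendering adds the widths in quadrature analytically and
the noiseless volume plus ground-truth table are stored with every stack
for recovery tests.

Quantification is deterministic for a fixed stack: Richardson–Lucy
restoration with the known PSF (fixed iteration count, 10 by default —
proprietary deconvolution internals are not emulated, any standard
restoration demonstrating cluster resolution suffices), light smoothing,
robust background (median/MAD), thresholded 3D local maxima with a minimum
mutual separation of 0.25 µm (below the 0.5 µm cluster linkage so cluster
members remain countable, above the blur scale), and moment-based spot
measurement. Widths are lateral moment FWHMs measured in a window that
adapts to wide spots; spots whose raw-data support is below three voxels
above half maximum are flagged as degenerate rather than measured. Counting
follows the projection workflow (z-maximum projection available via
`max_projection()`); widths use the 3D volume.

What passing the recovery tests shows — and what it does not: detection
recovers ≥ 90% of isolated (≥ 0.6 µm separated) synthetic foci with ≤ 5%
false positives, and resolves rendered cluster members that merge without
restoration. Real images add out-of-focus haze, chromatic effects, staining
variability and cell-to-cell morphology differences that the generator does
not emulate, so these tests validate the *pipeline logic*, not performance
on real data; none of the published per-figure focus counts is reproduced
quantitatively, by design.

## Numerical choices and degenerate inputs

* Zero-dose, zero-fluence, zero-length tracks, empty focus sets and
  noise-only stacks all return well-defined empty results.
* Strict inequalities: 10 eV deposits exactly at the threshold do not
  break; 8.0 µm tracks do not qualify; Δbp = 10 does pair (inclusive
  "within").
* Seeds: every stochastic entry point takes a `seed`; `run_all()` derives
  per-stage child seeds from one master seed, and identical configs produce
  byte-identical outputs (timestamps are excluded from the manifest for
  this reason).
* The chord approximation: dose-per-traversal × mean traversals ≈ nominal
  dose only to within the chord/silhouette approximations; this is
  documented, not asserted.
* The spec-level "~70%" vs the Poisson 66.7% at µ = 1.1 is rounding and is
  left unreconciled.

## Known limitations

Event-by-event electron transport, nuclear fragmentation, base damage and
SSB-complexity classes, chromatin organisation, repair chemistry beyond a
single effective OH species, focus motion over time, and pencil-beam
contaminant composition are all out of scope. Beam purity is metadata. The
vertical-irradiation geometry is supported in dosimetry but damage
simulations model a single horizontal traversal.
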