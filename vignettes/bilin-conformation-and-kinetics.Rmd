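---
title: "Bilin conformation and excited-state dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilin conformation and excited-state dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilindyn)
```

## The problem

Phycobilisomes are the main light-harvesting antennae of cyanobacteria. In
the rod-type CpcL antenna, a single phycocyanin rod is anchored to the
thylakoid membrane by the CpcL linker and hands excitation energy directly
to photosystem I. Each phycocyanin monomer carries three phycocyanobilin
(PCB) chromophores — an open-chain tetrapyrrole with rings A through D —
attached at the alpha-84, beta-82 and beta-155 cysteines. The planarity of
the tetrapyrrole controls how far its conjugated system extends: a flatter
bilin absorbs and emits further to the red. The lowest-energy bilin (the
"red PCB" or terminal emitter) defines the exit point of the energy funnel.

`bilindyn` implements the two quantitative analyses needed to identify that
terminal emitter and characterize the funnel:

1. a **structural arm**: fit planes to the four pyrrole rings of every
   bilin in a coordinate model, compute the three adjacent inter-ring
   angles, map linker–bilin contacts, and rank the bilins by planarity and
   linker engagement;
2. a **spectroscopic arm**: global lifetime analysis of time-resolved
   absorption or fluorescence surfaces — SVD rank estimation, IRF-convolved
   multi-exponential fitting (decay-associated spectra, DAS), and target
   analysis under a first-order compartmental scheme (species-associated
   spectra, SAS).

A synthetic-data module generates both kinds of input with known ground
truth, so the entire pipeline is testable offline.

## Structural arm

### Ring planes and inter-ring angles

Each pyrrole ring is taken as its five-membered ring proper — the nitrogen
and four ring carbons of the wwPDB phycocyanobilin component (`NA`,
`C1A`–`C4A`, and so on). Exocyclic substituents (methyls, vinyls,
propionates, carbonyl oxygens on rings A and D) are excluded. Published
angle tables rarely state which atoms entered the plane fits, so this
minimal convention is configurable via `ring_definitions()` and results
carry a ±3° comparison tolerance against printed integer-rounded values:
the rounding alone contributes ±0.5°, and switching ring conventions moves
the angles by a few degrees more.

`fit_plane()` is a total-least-squares fit: the plane through the centroid
whose normal is the eigenvector of the smallest eigenvalue of the centered
second-moment matrix, minimizing the summed squared orthogonal distances.
Sets with fewer than three points, or whose second-smallest eigenvalue
vanishes relative to the largest (collinear points), are rejected as
degenerate. The reported normal is oriented towards the next ring's
centroid for reproducible signs, but the inter-ring angle uses
`acos(|n1 . n2|)`, so it lives in [0, 90]° and is unaffected by either
normal's sign.

The per-bilin summary is

```{r}
bilin_conformation(make_tetrapyrrole(26, 7, 8))
```

`planarity_score = -(theta_AB + theta_BC + theta_CD)` is the simplest
aggregate that is monotone in every angle (higher = flatter); the raw
angles are always reported next to it, and ranking ties are flagged rather
than broken silently.

### Bilin labels

Rod nomenclature (`1I-b82-2`: hexamer 1, trimer layer I, beta-82 site,
monomer 2) is not stored in deposited models, so `assign_bilin_labels()`
derives it operationally:

* the attachment **site** comes from the residue number of the nearest
  cysteine SG in the host chain (itself the polymer chain at minimal
  heavy-atom distance — covalent LINK records are unreliable across
  depositions);
* **hexamer/layer** come from binning bilin centroids along the rod's
  principal axis into trimer layers (nine bilins per trimer), with the
  membrane-proximal end defined by the configured linker chain;
* the **monomer indices of the bottom-trimer beta-82 bilins** — the
  scientifically loaded ones — are set by their arginine-contact signature
  with the membrane-side linker: the bilin contacted by no linker arginine
  within the cutoff is index 2 (the flattened, red-shifted bilin is
  distinguished precisely by its arginine-free linker pocket), and the two
  arginine-contacted bilins are ordered by the highest-numbered arginine
  touching them. Ambiguous signatures raise an error listing the
  candidates.

This heuristic is an operational definition, reported as such in every
output; it is exercised end-to-end on generated toy rods in the tests.

### Contacts and superposition

`contact_map()` records every heavy-atom pair within a plain distance
cutoff (default 4 Å, boundary inclusive) — no angular hydrogen-bond
criterion, matching how bilin–protein interactions are usually tabulated.
`superpose()` is the closed-form (Kabsch) least-squares rigid alignment
with the determinant-corrected rotation; an optional target selection
(e.g. the non-hydrogen atoms of ring D of a homologous bilin pair) is
scored under the fit transform and never refit, mirroring the standard
"align on the conserved subunit, measure the region of interest" practice.

## Spectroscopic arm

### Kinetic model

A first-order compartmental scheme is encoded as a rate matrix `K` with
`K[j,i]` the transfer rate i→j and `K[i,i]` minus the total outflow from i
(transfers plus terminal loss). Populations solve `dc/dt = K c`. When `K`
is diagonalizable with a well-conditioned eigenbasis the populations are
sums of exponentials assembled in closed form; otherwise the code falls
back on adaptive ODE integration. A Gaussian instrument response of FWHM
`w` (default 0.1 ps for the femtosecond transient-absorption presets,
matching a 100 fs pulse) enters analytically through the
exponential-times-erfc convolution, written in a form that stays finite
for large rate × width products. Pre-excitation (negative-time) rows are
retained and fitted through the convolution — they constrain time zero and
the IRF rather than being discarded.

### DAS: global multi-exponential fitting

`global_fit_das()` shares k lifetimes across all wavelengths and solves
the per-wavelength amplitudes by ordinary linear least squares at every
step of a Levenberg–Marquardt search over *log*-lifetimes (variable
projection; positivity by construction). The fit is deterministic given
data and starting values; the default start is log-spaced between the
median time step and the time span. Non-convergence is flagged on the
result, never silently returned. The SVD rank estimate (singular values
above five times the median of the trailing half of the spectrum, with a
floor at 1e-9 of the leading value so noiseless data report their exact
rank) warns when more components are requested than the data support.

### SAS: target analysis

With `c(t) = V exp(Lt) V^{-1} c(0)`, compartment populations are linear
combinations of the same convolved exponentials the DAS fit used, so the
species spectra solve a square linear system mapping modes onto
compartments (`das_to_sas()`). Fitted lifetimes must match the scheme's
eigen-lifetimes within a relative tolerance (default 10%); mismatches
raise an error naming both sets. By construction the SAS reconstruction
equals the DAS reconstruction to numerical precision — that identity is
asserted below 1e-10 in the tests. `fit_target()` instead fits the scheme
directly: free lifetimes set the populations, spectra come from a linear
solve per step. On noiseless data both routes agree.

### The energy-funnel presets and their degeneracy

The default transient-absorption scheme (`scheme_ta_default()`) encodes
the funnel P1 (3.6 ps) and P2 (25 ps) feeding two intermediate red bilins
RS and RL (200 ps each), which feed the terminal emitter T. Choices that
the source data leave open, fixed here once:

* **P2 lifetime.** Reported values differ between 25 ps and 40 ps in
  different summaries of the same experiment; the default uses 25 ps, and
  the scheme constructor accepts any value.
* **Terminal lifetime.** Transient absorption bounds it only as
  `> 1200 ps`; the default uses 1999 ps, the value resolved by the
  time-resolved fluorescence analysis of the same complex
  (`scheme_fl_default()`: 101/401/401/1999 ps). Any fitted lifetime
  exceeding half the measurement window is flagged as poorly determined.
* **Branching fractions.** The donor outflow split between RS and RL is
  not reported; the presets use 50/50. Because RS and RL then have
  identical population kinetics, the model surface has SVD rank 4, not 5 —
  the two 200-ps compartments are spectrally distinct but kinetically
  degenerate. This is intrinsic to the published topology, not an artifact:
  a four-component DAS describes such data completely, and the
  five-compartment target fit has an unconstrained direction. The
  implementation therefore reports per-parameter standard errors (huge
  along the degenerate direction) instead of pretending uniqueness; the
  well-determined quantities — the distinct lifetimes and the terminal
  component — are what the tests assert.

Component-to-bilin annotation (`annotate_components()`) applies the
deterministic rule: fastest component → bilins with no linker contact;
slowest → the top-ranked red-PCB candidate; intermediates → the remaining
linker-contacting bilins by ascending planarity score. Each assignment
records which rule fired.

## Synthetic data

`make_tetrapyrrole()` places four regular-pentagon rings on a common axis,
rotating each successive ring about that axis by the prescribed
inter-plane angle. Because the axis lies in every ring plane, the fitted
plane angles equal the construction angles exactly at zero jitter; that
round-trip identity (below 1e-6°, and in practice at machine precision) is
the generator's contract and is swept over random angle triples in the
tests. Optional isotropic Gaussian jitter emulates coordinate error.

`make_surface()` multiplies the scheme's concentration profiles by
Gaussian spectral bands and adds seeded i.i.d. Gaussian noise scaled to
the signal maximum. TA mode pairs every bleach with a positive
excited-state-absorption lobe 40 nm to the red at half amplitude, so fits
face realistic sign structure. The presets use bleach positions
631/637/644/668/669 nm (TA, 550–700 nm probe window, time axis −1 to
6000 ps, dense linear sampling through the IRF then logarithmic — 91 × 76
points) and emission bands 645/651/669/672 nm (fluorescence). All
generators are pure functions of their arguments including the seed, and
they restore the caller's RNG state.

What the generator does **not** emulate: probe chirp/dispersion, coherent
artifacts around time zero, detector saturation, scattering, or
wavelength-correlated noise. Passing the recovery tests therefore
demonstrates correctness of the estimators under the stated noise model,
not robustness to every instrumental imperfection of real surfaces.

## Validation strategy and problem sizes

The raw experimental surfaces behind the published lifetimes are not
publicly deposited, so the spectroscopic analysis is validated by
parameter recovery on synthetic surrogates generated at the published
operating point: funnel lifetimes 3.6/25/200/200/1999 ps, 1% noise,
twenty seeds, 91 × 76 surfaces. Under those conditions the four distinct
lifetimes are recovered with median relative error well under 10% and the
direct target fit recovers the terminal lifetime within 15%. Deterministic
numerics are checked against independent oracles: plane fits against a
1°-grid search on the unit sphere, concentration profiles against
adaptive ODE integration (below 1e-8), superposition against applied
random rotations and an independent reference implementation, and the
DAS↔SAS reconstruction identity below 1e-10.

The structural analyses that reproduce published numbers from deposited
models (PDB 8HFQ and 7SC8: bottom-trimer ring C–D angles, the 0.5 Å ring-D
RMSD after CpcB-reference superposition, the 40-chain composition) run
whenever those coordinate files are placed under
`inst/extdata/deposited/`; the package does not download them, and the
corresponding acceptance checks report their absence explicitly rather
than passing vacuously.

## Known limitations

* The label-assignment heuristic presumes a single rod; branched or
  core-containing antenna models would need an explicit chain-role map.
* The planarity score is an unweighted angle sum; it intentionally adds no
  excitonic or electrostatic modelling, and no spectral prediction is made
  from geometry.
* `das_to_sas()` requires as many fitted components as compartments and a
  diagonalizable scheme; kinetically degenerate topologies should use
  `fit_target()` and read the standard errors.
* Anisotropy, chirp correction, and coherent-artifact modelling are out of
  scope.
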