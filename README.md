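# bilindyn

Quantitative analysis of phycocyanobilin (PCB) chromophore conformation in
phycobilisome rods and of the energy-transfer kinetics that those
conformations produce.

In rod-type CpcL phycobilisomes, a phycocyanin rod anchored to the membrane
by the CpcL linker transfers excitation energy directly to photosystem I.
Each phycocyanin monomer carries three open-chain tetrapyrrole chromophores
(rings A–D). How flat a bilin is — measured by the three acute angles
θ_AB, θ_BC, θ_CD between the least-squares planes of adjacent pyrrole
rings — sets how red-shifted it absorbs and emits; the flattest,
most linker-engaged bilin acts as the terminal emitter ("red PCB") of the
energy funnel. `bilindyn` provides:

* **Structural arm** — parse PDB/mmCIF models, extract and label bilins,
  fit total-least-squares ring planes, compute inter-ring angles and the
  planarity score −(θ_AB + θ_BC + θ_CD), map linker contacts within a
  distance cutoff, superpose homologous subunits (Kabsch) and score a
  target selection (e.g. ring-D atoms), and rank red-PCB candidates.
* **Spectroscopic arm** — SVD rank estimation of time × wavelength
  surfaces; decay-associated spectra (DAS) by IRF-convolved global
  multi-exponential fitting with variable projection
  (S(t,λ) = Σ_k A_k(λ) · [exp(−t/τ_k) ⊛ IRF]); species-associated spectra
  (SAS) under a first-order compartmental scheme dc/dt = K c, by either a
  linear mode-to-compartment transform of the DAS or a direct target fit;
  deterministic component-to-bilin annotation.
* **Synthetic data** — tetrapyrroles with prescribed inter-ring angles and
  kinetic-scheme surfaces with known ground truth, so every stage is
  testable offline.

## Worked example

Round-trip a synthetic bilin built with the flattened-bilin geometry
(θ = 26°, 7°, 8°) through the plane-fitting analysis:

```r
library(bilindyn)
bilin_conformation(make_tetrapyrrole(26, 7, 8))
#> # A tibble: 1 × 6
#>   label theta_ab theta_bc theta_cd planarity_score max_ring_rms
#>   <chr>    <dbl>    <dbl>    <dbl>           <dbl>        <dbl>
#> 1 bilin       26     7.00     8.00           -41.0 0.0000000267
```

The three inter-ring angles are recovered exactly; `planarity_score`
(higher = flatter) is the primary ranking key for red-PCB candidates.

Fit a synthetic transient-absorption surface generated from the
energy-funnel scheme P1(3.6 ps)/P2(25 ps) → RS/RL(200 ps) → T(1999 ps)
with a 100 fs IRF and 1% noise:

```r
surf <- make_surface_preset("cpcl_ta", noise_sigma = 0.01, seed = 1)
fit  <- global_fit_das(surf, 4, irf = irf_model(fwhm = 0.1))
fit
#> Global multi-exponential fit (4 components)
#>   lifetimes (ps): 3.659, 25.71, 200.6, 2001
#>   residual rms: 0.00934; converged: TRUE
```

Four lifetimes suffice because the two 200-ps compartments are kinetically
degenerate (they share one exponential); the fit recovers
3.6/25/200/1999 ps within a few percent at this noise level. `tidy(fit)`
returns the DAS in long format and `autoplot(fit)` draws them. A direct
compartmental fit of the published topology, initialized from the DAS,
recovers the terminal-emitter lifetime and exposes the intrinsically
undetermined fifth direction through its standard errors
(`fit_target(...)`, `tidy()` on the result).

The config-driven pipeline (`run_pipeline("config.yaml")`, or
`Rscript inst/exec/bilindyn.R run config.yaml`) chains both arms and
writes `report.json`, `angles.tsv`, `contacts.tsv`, `das.tsv`, `sas.tsv`
with full provenance (seed, config and input checksums); re-running an
identical config reproduces the reports byte for byte.

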