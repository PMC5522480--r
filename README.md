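# helicoil

Analysis toolkit for pH-switchable polypeptides whose secondary structure
is controlled by the hydrogen-bonding pattern of their side-chains.
Side-chain 1,2,3-triazoles present both an H-bond donor (C5–H) and an
acceptor (N3) — a *binary* H-bonding (BHB) pattern that competes with the
backbone amide network and keeps the chain a random coil. Protonation at
N3 (pKa ≈ 4) removes the acceptor, leaving a donor-only (*unitary*, UHB)
triazolium, and the backbone folds into an α-helix. `helicoil` implements
the quantitative analyses that characterise this coil↔helix transition
for people working on synthetic polypeptides, peptidomimetics and
responsive biomaterials:

* **Topology & charges** — residue/atom bookkeeping for model cationic
  polypeptides (one terminal trimethylammonium, +1 e, per side-chain;
  +1 e more per protonated triazolium), donor/acceptor role tables.
* **Helix geometry** — axis/radius/twist/rise fits of C<sub>α</sub>
  traces and RMSD to the ideal α-helix
  (r = 0.23 nm, γ = 100°, rise 0.15 nm), per frame and as time traces.
* **Hydrogen bonds** — geometric detection (d(D···A) ≤ 0.35 nm,
  ∠H–D–A ≤ 30°) and the backbone–backbone / backbone–water /
  backbone–side-chain partition per residue, with chain-end accounting
  (an ideal n-mer helix has exactly n−4 backbone bonds and four dangling
  N–H / C=O groups per end).
* **Hydration** — g(r) between the backbone centre of mass and water
  oxygens (0.04 nm bins, minimum-image, five-block error averaging) and
  water depletion-zone detection.
* **SANS** — forward model
  I(q) = s·φ·P<sub>cyl</sub>(q)·S(q) + A·q<sup>−n</sup> + B with an
  orientationally averaged cylinder form factor and a rescaled-MSA
  charged-sphere structure factor (Hayter–Penfold type; the analytic
  Percus–Yevick hard-sphere S(q) is included as an independent
  cross-check), simultaneous multi-contrast fitting, and the
  contrast-variation estimator: the slope of fitted particle SLD vs
  solvent SLD equals the water volume fraction inside the particle.
* **Synthetic data** — ideal helices, self-avoiding coils, folding
  trajectories, solvated frames with planted depletion zones, noisy
  multi-contrast SANS series and titration tables, all seeded, so every
  estimator is testable as planted-parameter recovery.

## Worked example

Helix geometry of an ideal 10-mer:

```r
library(helicoil)
fit <- fit_helix(generate_ideal_helix(10), n_exclude = 0)
fit
#> HelixFit: radius 0.2300 nm, twist 100.00 deg (right-handed), rise 0.1500 nm, RMSD_helix 0.0000 nm
```

Contrast-variation SANS: simulate the helical-state study condition
(cylinder R = 13 Å, L = 75 Å, internal water fraction 0.51, measured at
100/75/50 % D₂O with 2 % noise), fit all three curves jointly, then
regress particle SLD on solvent SLD:

```r
ser <- simulate_contrast_series(preset = "pH2", relative_noise = 0.02, seed = 11)
fit <- fit_contrast_series(ser)
signif(fit$estimates[c("radius", "length", "power_exp")], 4)
#> radius    length power_exp
#>  12.97     74.02     3.595
wf <- water_fraction_from_slds(fit$per_curve$sld_particle,
                               fit$per_curve$sld_solvent)
c(phi_water = wf$phi_water, r2 = wf$r_squared, sld_dry = wf$sld_dry)
#> phi_water        r2   sld_dry
#> 0.5108    0.9999993  1.788
```

The fitted radius and length recover the planted 13 Å / 75 Å to ~1 %,
the shared power-law exponent lands on the planted 3.6, and the SLD
regression slope returns the planted water fraction 0.51: at the study's
noise level the pipeline resolves the ~1.3 nm-radius cylinder and its
water content. A pKa fit works the same way:
`fit_pka(simulate_titration(4.1))$pka` returns `4.1`.

Full pipelines (`run_conformation_pipeline()`, `run_sans_pipeline()`)
chain the stages, echo their resolved configuration and serialise to
JSON via `write_report_json()`. See `vignettes/methods.Rmd` for the
models, assumptions and numerical choices.

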