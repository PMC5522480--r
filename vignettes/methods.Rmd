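---
title: "Models and methods behind helicoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind helicoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helicoil)
```

## The scientific problem

Cationic polypeptides carrying side-chain 1,2,3-triazoles sit on a
switchable boundary between two secondary structures. The neutral triazole
presents both a hydrogen-bond donor (the C5--H) and an acceptor (the ring
N3) -- a *binary* H-bonding (BHB) pattern that competes with the backbone
amide network, so the chain stays a random coil. Protonating N3 (pKa near
4, so under mildly acidic conditions) yields a triazolium with donors only
-- a *unitary* (UHB) pattern -- and the backbone folds into an
$\alpha$-helix. `helicoil` implements the quantitative analyses that
characterise this coil--helix transition from three directions:

1. **helix geometry** of C$_\alpha$ traces (radius, per-residue twist and
   rise, RMSD to an ideal helix),
2. **hydrogen-bond partitioning** into backbone--backbone (B--B),
   backbone--water (B--W) and backbone--side-chain (B--S) classes, with
   chain-end accounting,
3. **hydration structure** via the radial distribution function between
   the backbone centre of mass and water oxygens, and
4. **small-angle neutron scattering** of the chains in solution: a
   cylinder form factor with a charged-sphere structure factor, fitted
   simultaneously at several D$_2$O/H$_2$O contrasts, from which the water
   volume fraction inside the scattering particle follows by linear
   regression of particle SLD on solvent SLD.

Because no trajectory or beamline data ship with the package, a
first-class synthetic-data generator produces every input with *known
planted parameters*, so each estimator is validated as a recovery problem.

## Helix geometry

An ideal $\alpha$-helix has ~3.6 residues per turn; the package uses
radius 0.23 nm and twist 100$^\circ$ as the ideal reference, with the
textbook 0.15 nm per-residue rise (only radius and twist are constrained
by the reference geometry; the rise is the standard value). `fit_helix`
estimates the axis from the second differences of the trace: for points on
a helix these vectors are purely radial, so the null direction of their
SVD is the axis -- exact on noiseless input. The axis point and radius
then come from an algebraic (Kasa) circle fit of the projected points,
also exact on exact circles, followed by a Nelder--Mead refinement of
(axis direction, centre) that minimises the variance of the perpendicular
distances; the refinement only matters under noise. Twist is the mean
signed rotation of consecutive projected points about the axis (reported
as a magnitude in $(0, 180]$ with a separate handedness sign,
right-handed positive); rise is the mean absolute axial step.

`rmsd_to_ideal_helix` builds an ideal reference of matching length and
superposes it by least squares (Kabsch, via bio3d) before taking the
C$_\alpha$ RMSD; superposition is per frame, the standard practice when no
fixed laboratory frame is meaningful. The test suite checks this route
against an independently written quaternion (Horn) superposition oracle.
A collinear trace has no curvature signal; it is returned as a flagged
degenerate fit with radius 0 rather than an error. Chain ends deviate
from ideal geometry, so trajectory analyses exclude `n_exclude = 2`
residues per end by default; synthetic acceptance checks on exact helices
use 0.

## Hydrogen bonds

The geometric criterion is the conventional MD-analysis default: donor to
acceptor heavy-atom distance $\le$ 0.35 nm and H--donor--acceptor angle
$\le 30^\circ$, both config-exposed since the underlying convention is a
choice, not physics. Donor/acceptor eligibility follows the ligand
taxonomy: a triazolium N3 never accepts, an ester only accepts, water
both donates (two H) and accepts. Each donor hydrogen forms at most one
bond per frame (closest acceptor wins, ties to the lower atom id) to
prevent double counting in dense water. Per-residue statistics divide
per-frame class counts by the number of *included* residues; excluded
terminal residues contribute neither bonds nor denominator. On an ideal
$n$-mer helix the i$\to$i+4 register gives exactly $n-4$ B--B bonds, so
four N--H at the N-terminus and four C=O at the C-terminus dangle --
`count_dangling_backbone_groups` reports exactly that, and a brute-force
pair-enumeration oracle confirms it in the tests.

## Hydration RDF

$g(r)$ between the mass-weighted backbone centre of mass (per frame) and
water oxygens uses minimum-image distances in the cubic box, a 0.04 nm
bin width, and exact shell volumes with the mean instantaneous water
number density, so uniformly random waters give $g = 1$. Standard errors
come from block averaging over five contiguous blocks (s.d. across blocks
over $\sqrt{5}$); one block leaves errors undefined and is reported as
zero with a warning flag. The depletion radius is the outer edge of the
initial run of bins with $g$ below 0.1 -- a near-zero threshold chosen
because the depleted zone of a packed helical backbone is essentially
empty, recovering a planted exclusion radius to within one bin.

## SANS model

Units are fixed internally: $q$ in Å$^{-1}$, lengths in Å, SLDs in
$10^{-6}$ Å$^{-2}$, intensities in cm$^{-1}$. The pure-water SLDs are
derived from coherent scattering lengths ($b_D = 6.671$, $b_H = -3.739$,
$b_O = 5.803$ fm) and a 30 Å$^3$ molecular volume (6.38 for D$_2$O,
$-0.56$ for H$_2$O); solvent mixtures interpolate linearly in volume
fraction.

The particle is a rigid cylinder; the orientationally averaged form
factor uses 76-point Gauss--Legendre quadrature (validated against a
$10^6$-point trapezoidal integration in the tests). Interparticle
correlations use a charged-sphere structure factor of the
Hayter--Penfold type: the mean-spherical approximation for a hard core
with a DLVO screened-Coulomb tail, here computed by direct numerical
solution of the Ornstein--Zernike equation (Anderson-accelerated Picard
iteration on a 32.8-diameter grid with FFT sine transforms) rather than
the historical algebraic closed form; the two are the same physics, and
at $Z = 0$ the MSA closure *is* the Percus--Yevick hard-sphere equation,
which the package also provides analytically as an independent
cross-check (the suite requires agreement to $10^{-4}$). The
Hansen--Hayter rescaling step -- mapping to an effective larger diameter
at unchanged number density whenever the unrescaled contact value of
$g$ is negative -- is applied by root-finding on the scale factor.

The composite model is
$$I(q) = s\,\phi\,P_\mathrm{cyl}(q)\,S(q; d_\mathrm{eff}) + A q^{-n} + B,$$
with $d_\mathrm{eff}$ the equivalent-volume-sphere diameter of the
cylinder. The direct product coupling is an approximation for
non-spherical particles (the decoupling $\beta(q)$ correction is a known
limitation, deferred); the $A q^{-n}$ term absorbs the low-$q$
surface-scattering decay of large aggregates ($n$ between 3 and 4)
additively instead of masking the window. Inside `composite_intensity`
the structure factor is evaluated at geometrically spaced
effective-diameter nodes (3% spacing) and interpolated linearly in
$\log d$ -- the interpolation error is far below measurement noise and
makes fitting tractable; `hayter_penfold_sq` itself is never
interpolated.

## Fitting and contrast variation

All fits are bounded Levenberg--Marquardt (`minpack.lm`) on
$\sum((I_\mathrm{model} - I)/\sigma_I)^2$, with up to five jittered
multi-starts; remaining starts are skipped once one converges with
reduced $\chi^2 < 2$, which guards against local minima of the
$P \times S$ landscape without paying the full cost on easy problems.
Parameter uncertainties come from the finite-difference Jacobian at the
optimum, inverted in column-scaled space because the parameters span many
orders of magnitude.

In the joint multi-contrast fit the geometry (R, L) and power-law
exponent are shared; particle SLD, power-law amplitude and background
float per curve. Two identifiability choices deserve note:

* `scale` is held fixed -- it is exactly degenerate with the SLD
  contrast ($I \propto s\,\Delta\rho^2$), and the particle volume
  fraction is known from sample preparation in a real experiment;
* each per-curve particle SLD is bounded above by its solvent SLD,
  selecting the physical branch of the $\Delta\rho^2$ sign ambiguity (a
  hydrogenous polypeptide in D$_2$O-majority solvents always sits below
  the solvent SLD).

The particle volume fraction, effective charge and Debye length enter
the structure factor as fixed nuisance parameters; no printed values
exist for them, so the synthetic presets adopt plausible dilute-solution
values ($\phi = 0.005$, $Z = 20$, $\lambda_D = 30$ Å) and the fits hold
them at the preset values.

For a particle containing a volume fraction $\phi_w$ of solvent water,
$\mathrm{SLD}_p = \phi_w \mathrm{SLD}_s + (1 - \phi_w)\mathrm{SLD}_{dry}$,
so regressing fitted particle SLDs on solvent SLDs across contrasts gives
$\phi_w$ as the slope and the dry SLD as intercept$/(1 - \phi_w)$.
Slopes outside $[0, 1]$ (possible under noise) are clipped and flagged,
not rejected.

## What the generator emulates -- and what it does not

The generator reproduces the *statistical structure the analyses assume*,
not the physics that produced it:

* Ideal helices place C$_\alpha$ exactly on the parametric cylinder;
  backbone N/H/C/O are set from fixed offsets in a discrete local frame
  of the trace, derived once from a helix built with canonical internal
  coordinates ($\phi = -57^\circ$, $\psi = -47^\circ$), so the
  i$\to$i+4 H-bond geometry is canonical.
* Coils are fixed-step (0.38 nm) self-avoiding walks with a 0.4 nm
  non-bonded exclusion; "folding" trajectories interpolate the trace
  from coil to helix starting at 40% of the frames -- geometry, not
  dynamics.
* Thermal motion is isotropic Gaussian displacement (default s.d.
  0.02 nm, which keeps a helix within the observed RMSD band of a stable
  folded state).
* Water is geometric (O plus two H at 0.1 nm, 104.5$^\circ$, uniform
  placement outside a planted depletion sphere and a 0.25 nm steric
  shell). Waters within 0.45 nm of the peptide point one O--H at their
  nearest peptide atom -- a minimal stand-in for hydration-shell
  ordering, without which geometric H-bond detection on randomly
  oriented waters would undercount backbone--water bonds; bulk waters
  are oriented at random. There are no O--O correlations, and the
  default box (6 nm edge for the 10-mer) and water counts are chosen
  only to satisfy the analyses' sampling demands.
* SANS curves are the package's own forward model plus relative Gaussian
  noise, with presets for the two study conditions: helical
  ("pH2": R = 13 Å, L = 75 Å, $\phi_w$ = 0.51) and coil
  ("pH8": R = 13 Å, L = 62 Å, $\phi_w$ = 0.59), measured at 100/75/50%
  D$_2$O with a dry-polypeptide SLD of 1.8 (a typical protonated-polymer
  value).

Passing recovery tests therefore demonstrates the *estimators* are
correct and unbiased at realistic noise, not that real trajectories or
real beamline data would yield these numbers.

## Problem sizes and determinism

The default test and acceptance workloads run in minutes on one CPU:
10-mer chains, tens of frames, a few thousand waters per frame ($10^5$
RDF samples), 120-point q grids, and ten-seed recovery ensembles for the
contrast-variation study. Every stochastic generator takes an explicit
seed and restores the global RNG state afterwards; identical
configuration plus seeds reproduce results bit-for-bit.

## Known limitations

* The structure-factor coupling ignores the cylinder's anisotropy
  (no $\beta(q)$ decoupling correction).
* No instrument resolution smearing or polydispersity; curves are
  treated as fully reduced.
* The MSA solver truncates the potential at 32.8 diameters; extremely
  weak screening (Debye length $\gg$ diameter) loses tail weight.
* The H-bond criterion is purely geometric; no energetic scoring.
* Side-chains are coarse pseudo-atom chains -- sufficient for
  donor/acceptor bookkeeping and charges, not for packing analyses.
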