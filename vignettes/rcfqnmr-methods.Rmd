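---
title: "Quantifying RCF aromatic monomers by internal-standard 1H NMR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RCF aromatic monomers by internal-standard 1H NMR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcfqnmr)
```

## The problem

Reductive catalytic fractionation (RCF) converts the lignin in woody
biomass into a small family of 4-substituted phenolic monomers. Measuring
how much of each monomer a reaction produced is routine but laborious by
chromatography: many of the syringyl-type standards are not commercially
available, response factors drift, and crude oils need liquid-liquid
extraction first. A single 1H NMR experiment on the crude reaction liquor,
with a weighed internal standard, can instead give per-compound masses in
minutes: each aromatic proton contributes equally to the spectrum, so a
compound's integral per proton against the internal standard's integral per
proton is a molar ratio, and

$$ m_a \;=\; \frac{I_a}{I_{IS}}\cdot\frac{n_{IS}}{n_a}\cdot
   \frac{M_a}{M_{IS}}\cdot m_{IS} $$

turns integrals into milligrams (`mass_from_integral()`). Yields are then
expressed as wt% of a stated basis mass via the aliquot scaling in
`sample_prep()`.

The difficulty is spectral, not arithmetic: in poplar RCF oils twelve
compounds share a narrow aromatic region, and several resonances collide.
This package encodes the compound panel, the integration windows, and the
correction and interference rules that make region integration quantitative
in spite of those collisions — plus a simulator that generates spectra of
exactly known composition so every rule is testable end to end.

## The compound panel

`default_panel()` covers PS, PSOH, PG, PGOH (the four primary monomers),
ES, EG, PES, PEG (minor 4-ethyl/4-propenyl products), p-hydroxybenzoic acid
and methyl paraben (poplar hydroxybenzoates), phenol, and the internal
standard 1,3,5-tri-tert-butylbenzene (TTB, 3 aromatic + 27 tert-butyl
protons). Molar masses are always computed from molecular formulas with
standard atomic weights, so every number is auditable.

Quantification windows follow the published aromatic assignments. Where a
single band is printed for several compounds the band is split into
disjoint adjacent sub-windows (PS/PSOH/ES inside 6.46-6.50 ppm; PG/PGOH
inside 6.77-6.82 ppm; pHBA/MP inside 7.87-7.93 ppm), because the quantifier
never lets one spectral point contribute to two windows. The exact
per-compound bounds are instrument- and lab-dependent, so the panel is an
editable YAML file (`write_panel()`/`read_panel()`) and all defaults are
overridable; the TTB aromatic shift, which the assignments do not fix, is
placed at 7.30 ppm by convention. Known collisions are stored as explicit
overlap annotations (`overlap_pairs()`): PEG's G5 under the PG window, EG's
G2 under the PGOH window, phenol across the whole G2 region, ES against the
adjacent PS/PSOH band, pHBA/MP sharing printed ranges, and the aliphatic
alpha/beta collisions.

## From FID to integrals

`process_fid()` applies exponential apodization `exp(-pi * lb * t)`
(default 0.3 Hz), halves the first point, zero-fills (default one level),
Fourier transforms, and zero-order-phases on the tallest peak, so a
noise-free line of natural width $r_2$ emerges as an absorption Lorentzian
of FWHM $r_2 + lb$ Hz. `calibrate_ppm()` references the axis to the TTB
singlet. `integrate_region()` integrates a window trapezoidally after
subtracting a local linear baseline through the window endpoints
(`endpoints_linear`, the default): crude oils carry a broad oligomer
background, and a local chord is the minimal defensible correction. A
window spanning fewer than 8 digital points is refused rather than silently
under-sampled. When a spectrum arrives without frequency metadata the
package assumes 400 MHz and records that assumption.

## Corrections: making region integration quantitative

At a typical 1.3 Hz effective linewidth the S-band sub-windows are only a
few linewidths wide, so a raw region integral captures only part of its own
compound and picks up tails of its neighbours. Three deterministic,
logged corrections deal with this; none of them is line-shape fitting — the
only parameter ever taken from the spectrum is a single effective
linewidth, measured from the area/height ratio of the TTB singlet under the
same window-and-baseline model used everywhere else.

1. **Internal-standard tail subtraction.** TTB's position and amount are
   known exactly, so its predicted Lorentzian leakage into every window is
   subtracted analytically. This matters most for the ethyl-beta window
   (1.13-1.20 ppm), which sits downfield of the large tert-butyl singlet.

2. **The 50% PEG rule.** The PEG G5 doublet-of-doublets straddles the lower
   edge of the PG G2 window, placing half its (one-proton) area inside it.
   Since PEG's clean G2 singlet also integrates one proton, subtracting 50%
   of the PEG G2 integral from the raw PG G2 integral removes the
   contamination exactly; `correct_pg_integral()` floors at zero and flags
   flooring. This correction is applied first, in integral space, before
   any other.

3. **Coverage and overlap unmixing.** For each annotated cluster of
   overlapping windows (PS/PSOH/ES, PG/PGOH, pHBA/MP) the measured
   integrals are related to the per-compound total areas by a small matrix
   whose entries are the analytic fractions of each compound's multiplet
   contributing to each baseline-corrected window — the endpoint chord is a
   linear operator, so these fractions include the chord term exactly.
   Solving the linear system (a one-dimensional "cluster" reduces to a pure
   finite-window coverage correction) recovers each compound's full area.
   This is the natural generalisation of the 50% rule: fixed coefficients,
   no free parameters, every adjustment logged in the result's
   `corrections` attribute.

## Interference gating and the aliphatic fallback

ES is reported only when its narrow window shows an interior local maximum
(tolerance 0.005 ppm) standing above noise; otherwise it is flagged "not
distinguishable", mirroring the practical difficulty of seeing ES next to
the much larger PS/PSOH singlets.

Phenol's ortho/para multiplet (6.77-6.85 ppm) sits directly on the PG and
PGOH windows. `detect_phenol_interference()` looks at phenol's separate
meta window (7.14-7.22 ppm): a baseline-corrected peak more than
`snr_threshold` (default 10) times the noise — estimated robustly from the
signal-free 9.5-10 ppm region — declares interference and flags every
G2-window quantification unreliable. An ethyl side-chain signal in the
aliphatic profile likewise flags PGOH, because EG's G2 is buried under it.

When the G2 route is gated, `quantify_g_from_aliphatic()` recovers the
G-type monomers from side-chain windows, which separate by chain rather
than ring type: total propyl from the gamma triplet window (0.86-0.93 ppm)
minus the PS amount known from its clean singlet gives PG; the clean
hydroxypropyl-gamma window (3.45-3.58 ppm — the only hydroxypropyl window
free of collisions, since alpha overlaps ethyl-alpha and beta overlaps
propenyl-gamma) minus PSOH gives PGOH; ethyl-beta minus ES gives EG. A
negative inference beyond 10% of the side-chain total is flagged and
floored. When no direct or fallback route exists, EG is estimated as
`ES x (PG/PS)` (`estimate_eg_yield()`), always flagged as an estimate.

Because pHBA and methyl paraben share their printed windows, their
individual values carry a `shared_printed_window` flag and the result also
reports their sum (`hb_total_yield` attribute), which is the robust
quantity.

## The simulator: what it emulates and what it does not

`simulate_fid()` builds first-order (weak-coupling) multiplets — singlets,
doublets at $\pm J/2$, doublets-of-doublets, and unresolved multiplets as a
Gaussian-weighted comb of nine sub-lines spanning the stated envelope
width — and synthesises the FID as a sum of decaying complex exponentials
(rate $\pi r_2$, default $r_2$ = 1 Hz) plus seeded complex Gaussian noise.
Defaults (400 MHz, 2 s acquisition, 20 ppm window, one zero-fill) give
0.25 Hz/point digital resolution. Ground truth carries concentrations,
masses, and the analytic integral every panel window would show, summed
over *all* compounds' lines, so overlap corrections can be validated
exactly.

Six scenario presets (`simulate_oil()`) emulate the selectivity regimes RCF
conditions produce: `propyl_selective` (roughly 2:1 PS:PSOH, the
high-severity base case), `mixed_50_50`, `oh_selective` (over 90%
hydroxypropyl, low-temperature conditions), `h2free_propenyl` (PES/PEG
dominated with only ~0.2 wt% PS/PG), `pdc_three_chain` (ethyl, propyl and
hydroxypropyl co-produced with phenol present — the hard case for the G2
region), and `phenol_rich`. Concentrations are fixed at the published or
typical yields for each regime under the default preparation (0.5 mL of
50 mL liquor into a 1 mL tube with 1 mg TTB; 400 mg lignin basis, a
typical Klason content for a 2 g poplar charge), so 1 mg/mL in the tube is
25 wt%. The default noise level (`noise_sigma = 0.05`) keeps spectral
signal-to-noise well above 50 for monomers at or above roughly 0.2 wt%.

The simulator deliberately does **not** model strong coupling (all
quantification windows are singlets or well-separated doublets),
relaxation weighting (d1/T1 saturation), 13C satellites, solvent peaks, or
the dimer/oligomer background that real crude oils carry (a broad hump can
be emulated through the baseline, but is off by default). Passing tests
therefore demonstrate that the integration, correction and gating logic is
self-consistent and recovers known compositions under realistic linewidths,
noise and overlap — not that real-oil accuracy will match, since real
spectra add oligomer background and shift variability that only the
interference flags can signal.

## Numerical choices

* Linewidth estimation solves the TTB area/height relation by
  `uniroot` on [1e-5, 1.5 x window half-width] ppm; if bracketing fails it
  falls back to the infinite-window Lorentzian relation $w = 2I/(\pi h)$.
* Cluster unmixing uses `solve()` on 2x2/3x3 matrices that are strongly
  diagonally dominant for the default windows; a negative solution (possible
  at very low concentration under noise) is floored at zero and flagged.
* Adjacent windows share edges; points are assigned by closed-interval
  selection and windows are validated disjoint, so no point is counted
  twice.
* Noise is `mad`-scaled, with a floor of 1e-4 times the maximum intensity
  so thresholds stay meaningful for noise-free synthetic spectra.
* Calibration shifts the axis rigidly so the maximum point in the search
  window lands exactly on the reference shift; a second calibration after
  any rigid shift reproduces the original axis bit-for-bit, which is what
  makes quantification invariant under axis translation.

## Problem sizes used in the test-suite

Property tests use 1 s acquisitions (8k points) so that every window keeps
at least 8 digital points; scenario tests use the full 2 s default (16k
points, 32k after zero-fill). The parameter-recovery study runs 50 jittered
mixtures cycling through all six scenarios with per-mixture seeds; the
noise-scaling property uses 60 replicate seeds per condition on 0.25 s
FIDs. These sizes were chosen to exercise every code path at realistic
digital resolution while keeping the default check fast.

## Known limitations

* Accuracy for compounds quantified in windows much narrower than ~5
  linewidths (ES, and the pHBA/MP doublets near their window edges) is
  several percent even noise-free; the cluster unmixing bounds but does not
  eliminate neighbour-tail bias from resonances outside the annotated
  clusters (e.g. G5/G6 tails a few linewidths from a G2 window).
* The phenol detector keys on the 7.14-7.22 ppm window only; an oil with an
  unknown interferent there would gate the G2 region unnecessarily
  (conservative failure).
* The PEG 50% rule is exact only insofar as the G5 multiplet actually
  straddles the PG window edge symmetrically; a lab observing a different
  split should edit the panel windows and, if needed, the rule's
  coefficient at the call site.
* Yields require an explicit `basis_mass_mg`; the package never guesses the
  wt% denominator.
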