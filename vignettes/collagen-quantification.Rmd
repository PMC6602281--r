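---
title: "Quantifying collagen lysine modifications, cross-links and tissue stiffness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen lysine modifications, cross-links and tissue stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collagenQ)
```

## The measurement problem

Type I collagen is post-translationally modified at specific helical and
telopeptidyl lysines: hydroxylation to hydroxylysine (Hyl, +15.99491 Da),
O-glycosylation of Hyl to galactosyl- (G-Hyl, +162.05282 Da over Hyl) and
glucosylgalactosyl-hydroxylysine (GG-Hyl, +324.10565 Da over Hyl), and, at
the telopeptides, oxidative deamination by lysyl oxidase to the aldehyde
allysine (−1.03163 Da vs Lys). The aldehydes condense with helical Lys/Hyl
(and His) into the immature reducible cross-links that stabilise the
fibril. Genetic perturbations of the hydroxylation machinery shift all
three layers — site occupancy, glycoform balance, cross-link spectrum —
and ultimately tissue mechanics. This package implements the
quantification chain for all of them from standard instrument outputs.

## Site occupancy from extracted-ion chromatograms

Each monitored site is carried by one marker peptide. The modification
states allowed at a site are enumerated into *occupancy classes*; each
class has a theoretical m/z per charge state, and the class abundances are
the peak areas of the corresponding EICs:

$$\mathrm{occ}_c = 100 \cdot \frac{A_c}{\sum_{c'} A_{c'}},\qquad
\mathrm{Lys} + \mathrm{Hyl} + \mathrm{G\text{-}Hyl} + \mathrm{GG\text{-}Hyl} = 100\%.$$

Design points:

* **Extraction window.** An absolute ±0.02 m/z window (not ppm), the
  precision the underlying QTOF method states. None of the shipped sites'
  class ladders collide at this window over charges 1–3 (this is asserted
  by a test).
* **Isobaric collapse.** On the two-lysine peptide GDKGETGEQGDRGIKGHR the
  positional isomers Lys+Hyl and Hyl+Lys are isobaric; EIC areas cannot
  separate them, so they form one joint class, reported as in occupancy
  tables for such sites (Lys + Lys, Lys + Hyl, Hyl + Hyl).
* **Aldehyde pooling.** Telopeptidyl allysine species are mass-distinct
  (−1.03163 Da) and get their own EIC, but report into the Lys occupancy
  class, since the aldehyde arises from Lys and is tallied with it.
* **Charge summation.** When several charge states are queried for one
  class their areas are summed; ratios remain well defined. Single-charge
  mode is a matter of passing one charge.
* **Glycoform profile.** The hydroxylated classes renormalised to 100%
  (Hyl + G-Hyl + GG-Hyl). Profiles are computed **per sample and then
  averaged** across a group, not computed from group-mean occupancies; the
  two differ whenever occupancy varies between samples, and the per-sample
  convention is the one consistent with how such tables are produced from
  replicate animals.
* **Peptide masses.** Residue masses from a 6-decimal IUPAC monoisotopic
  element table; peptide mass = Σ residues + H₂O − NH₃ for pyroglutamate
  starts; per-site fixed 4-Hyp positions shift the base mass. One known
  caveat: for the α2(I) N-telopeptide pQYSDKGVSSGPGPM the z = 2 precursor
  computed from standard residue masses is 696.8086, about 0.007 m/z above
  the value printed in the source spectra (696.8019); the composition
  behind the printed value is not stated, we do not force agreement, and
  quantification relies only on the internally consistent Lys/Lysald/Hyl
  deltas, which are exact.
* **Sequences.** Only two marker sequences are literature-printed; the
  rest of the shipped site table uses representative collagen-like
  stand-ins flagged `sequence_source = "synthetic"`. Occupancy is a ratio
  within a site, so it is insensitive to the base sequence; users with
  real instrument data should supply their own site CSV.

## Cross-link assembly, fragments and quantification

Cross-link formulas follow the condensation bookkeeping

$$F = \sum_i F_{\text{component } i} - n_{\mathrm{H_2O}}\cdot\mathrm{H_2O}
      + n_{\mathrm{H_2}}\cdot\mathrm{H_2} + F_{\text{glycan}},$$

with components as free amino acids. The built-in recipes (LNL, HLNL,
G-/GG-HLNL, HHMD, d-HHMD, ACP, dehydro precursors) live in an editable CSV
resource. MS/MS fragment candidates combine up to three neutral losses
from {NH₃, H₂O, HCOOH} (each loss checked for elemental feasibility) with
component-release cleavages modelled as heterolytic release of one intact
component with a single H transfer to the charged fragment — which places
free His from HHMD/d-HHMD at m/z 156.08. The compositions of the larger
reporter fragments seen for these species are not published, so the
spectrum matcher scores within-tolerance matches (default 0.02 m/z, the
MS1 value, since no MS2 tolerance is stated) rather than asserting
compositions; the best-supported precursor-matching candidate wins, ties
are `ambiguous`.

HPLC quantification converts window-summed radioactivity counts to moles
via the label's specific activity and counting efficiency, then divides by
collagen moles:

$$\mathrm{level} = \frac{\text{counts}/(SA \cdot \varepsilon \cdot
  n_{\text{labels}})}{n_{\text{collagen}}}\ \text{mol/mol}.$$

Choices here:

* **Two labels on the tetrafunctional species.** HHMD and d-HHMD carry two
  borohydride-reduced bonds per molecule, so their counts are divided by 2
  before mole conversion. This is consistent with the factor 2 these
  species carry in the total-aldehyde sum (HLNL + LNL + 2·HHMD +
  2·d-HHMD); because the literature does not state the division outright,
  `labels_per_molecule` is configurable.
* **Elution windows are method-relative.** Published elution positions are
  not absolute, so the window table is a user resource; the synthetic
  generator and the quantifier deliberately share one table.
* **Collagen moles** default to 4-Hyp moles / 300 Hyp residues per triple
  helix; only the denominator convention matters for mol/mol ratios and
  the constant is configurable.
* **Total-aldehyde rounding.** Evaluating the aldehyde sum on rounded
  group means gives 1.97 (at WT-like levels 0.53/0/0.72/0) where
  per-sample evaluation before rounding gives ≈1.99; the package computes
  per sample and the tests assert the identity within ±0.02.

## Thin-layer Hertz nanoindentation

For a sphere of radius $R$ indenting a layer of thickness $h$ to depth
$\delta$:

$$F(\delta) = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}\,
  C(\chi),\qquad \chi = \frac{\sqrt{R\delta}}{h},$$

with the Dimitriadis finite-thickness polynomial
$C(\chi) = 1 + 1.133\chi + 1.283\chi^2 + 0.769\chi^3 + 0.0975\chi^4$
(bonded case; $C(0)=1$ recovers plain Hertz). Defaults: $R = 5\ \mu$m
microspherical tip, $h = 40\ \mu$m cryo-section, $\nu = 0.45$ (nearly
incompressible soft tissue).

* **Boundary case.** The bonded coefficient set is the default because
  cryo-sections adhere to the slide; the free-slip set is selectable.
* **Fitting.** Force is linear in $E$, so the single-parameter
  least-squares problem is solved exactly on the basis
  $g(\delta) = F(E{=}1,\delta)$; a constant force offset can be co-fitted
  for imperfectly zeroed curves, and contact-point detection is otherwise
  out of scope (curves are assumed pre-zeroed). The closed-form Hertz
  inversion at the deepest point is reported as the starting value.
* **Validity cut.** Points deeper than 10% of the layer thickness are
  excluded by default (configurable), keeping the polynomial correction in
  its accurate range.
* **Round trip.** Fitting noiseless forward curves recovers E to better
  than 0.1% across 1–100 kPa and maximum depths 0.1–2 µm (tested).

```{r hertz-example}
cv  <- simulate_force_curves(12.04e3, rel_noise = 0.05, seed = 4)[[1]]
summary(fit_hertz(cv$depth, cv$force, R = 5e-6, h = 40e-6, nu = 0.45))
```

## The synthetic cohort generator

Every instrument stream has a generator that is a pure function of its
arguments and seed, and attaches its ground truth as an attribute so
recovery tests never re-derive truth from the fixture:

* **MS1 chromatograms**: one Gaussian elution peak per occupancy class at
  its theoretical m/z, areas proportional to the class fractions,
  multiplicative log-normal area noise (default CV 5%), uniform m/z jitter
  bounded at 0.005, and an optional co-eluting heavy internal-standard
  channel (+6.02013 Da neutral, six ¹³C). Peak centres are aligned to the
  retention-time grid so that, noise off, discrete peak areas are exactly
  proportional to the set fractions and occupancies are recovered to
  numerical precision.
* **Per-sample occupancancy draws** use truncated normals per class around
  the set-point means with the per-class SDs, renormalised to 100 — chosen
  over a Dirichlet because reference tables publish per-class SDs, which
  truncated normals honour directly (a Dirichlet mode is available).
* **HPLC traces**: Gaussian count peaks centred in each species window,
  window-normalised so integrated counts equal level × collagen mol × SA ×
  labels exactly; optional Poisson count noise.
* **Force curves**: forward Dimitriadis–Hertz curves with optional
  relative force noise.
* **Cohort defaults** emulate the murine skin study design the shipped
  set-point tables describe: genotypes WT/Het/KO with n = 3 per genotype
  for MS occupancy and AFM and n = 10 for cross-links; occupancy vectors,
  cross-link levels (mol/mol) and regional moduli (kPa, mean/SE) ship as
  CSV resources and are the generators' default effect sizes.

What passing the recovery tests shows — and does not. The generator
reproduces the *statistical structure* the analysis assumes: correct
ratios, additive class peaks, independent multiplicative noise, Poisson
counts. It does not emulate chromatographic drift and co-elution,
isotope-envelope overlap, detector saturation, in-source decay, or
baseline structure in HPLC traces; passing set-point recovery therefore
validates the arithmetic and the extraction logic, not robustness to
those instrument artefacts.

## Group statistics

Report tables carry per-genotype mean with SD (MS and cross-link tables)
or SE (AFM tables) and pairwise two-sided Welch t-tests of each group
against the reference genotype, tiered at 0.05/0.01/0.001/0.0001. The
source tables this emulates do not name their test; Welch's t-test is our
interpretation, chosen as the default that does not assume equal
variances, and no multiplicity correction is applied across the two
pairwise comparisons (matching the two-comparison reporting structure).
The null calibration of the test at small n is itself under test (type-I
error within [0.03, 0.07] at α = 0.05 over 2000 simulated null cohorts).

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the pipeline at deliberate
desk scale: single sites or small site panels, n = 2–5 samples per
genotype, 40-fraction HPLC traces, 100-point force curves, 50-curve
Monte-Carlo recovery and 2000-replicate null calibration — sizes chosen so
the whole suite completes in seconds while still exercising every stage
end to end. Degenerate inputs fail loudly rather than silently: all-zero
class areas flag "site not detected", fully unmodified sites refuse a
glycoform profile, overlapping HPLC windows and non-positive calibrations
are errors, and a non-converged modulus fit is flagged rather than
replaced by a fallback.

## Known limitations

* Monoisotopic masses only; no isotope envelopes, no adducts other than
  protons.
* No retention-time alignment or cross-sample normalisation; occupancy is
  within-sample ratio quantification by design.
* Mature trivalent cross-links (pyridinolines, pyrroles) are absent from
  the recipe set — skin chemistry is dominated by the immature species
  modelled here — though the recipe CSV is user-extensible.
* MS2 fragment *intensities* are not modelled; assignment uses m/z
  matching only.
* The viscoelastic (time-dependent) part of tissue response is outside the
  Hertz model; fitted E is an effective elastic modulus.
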