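---
title: "Betalain fingerprinting: model, tolerances and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Betalain fingerprinting: model, tolerances and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betalains)
```

## The identification model

Betalains — betacyanins, betacyanin derivatives and betaxanthins — are
identified here from feature-resolved positive-mode MS/MS spectra by four
orthogonal lines of evidence, mirroring how high-resolution LC-MS/MS
dereplication of these pigments is done in practice:

1. **Precursor mass accuracy.** Every ion is treated as [M+H]⁺ (charge +1);
   for a formula with composition $c$ the theoretical ion is
   $m/z = \sum_e c_e\,m_e + m_{H^+}$ with full-precision monoisotopic atomic
   masses and $m_{H^+} = 1.007276466$ Da. Accuracy is the signed
   $\mathrm{ppm} = (m_\mathrm{obs} - m_\mathrm{theo})/m_\mathrm{theo}\times10^6$.
2. **Diagnostic fragments.** Eight core ions (m/z 211.07, 194.04, 179.08,
   178.05, 166.05, 138.05, 132.04, 106.06) map to the shared
   betalamic-acid/pyridine core and gate the screen; the aglycone ion 389.09
   types intact betacyanins, 345.10 decarboxylated and 343.09 dehydrogenated
   derivatives (which cannot show 389.09, their aglycone frame having lost
   CO₂ or H₂), and 211.07 with a small precursor types betaxanthins.
3. **Retention order.** Relative retention time (rt divided by the run's
   betanin rt) is column-gradient-robust; 15R *iso* epimers elute after
   their 15S parents on C18 reversed phase, which is the only evidence that
   separates epimer pairs with identical formula and fragments.
4. **Neutral losses in multistage MS.** Consecutive MSⁿ precursor
   differences are matched against a residue table (glucosyl 162.0528,
   pentosyl/glutaryl 132.0423, hydroxymethylglutaryl 144.0423, malonyl
   86.0004, feruloyl 176.0473, coumaroyl 146.0368, glucuronosyl 176.0321,
   sulfo 79.9568, CO₂ 43.9898, H₂ 2.0157, H₂O 18.0106 Da), and an unknown's
   composition is proposed as terminal match + assigned losses.

The bundled catalog transcribes the 86 betalains of red pitaya
(*Hylocereus costaricensis*) verbatim, including its printing quirks (a
"106.6" entry that is evidently 106.06, duplicated 166.05 entries, the
variant spelling "descarboxy", a duplicated printed label 75). Records are
never silently "corrected"; consistency is instead checked explicitly by
`validate_catalog()`, which reproduces the theoretical m/z column within
0.0005 Da, the ppm column within 0.05 ppm and the relative-rt column within
0.01 for all 86 records.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| fragment `mz_tol` | 0.01 | Da | fragments are curated at 2 decimals from a 60,000-resolution instrument; ±0.01 Da separates every pair of distinct curated ions |
| `min_core` | 2 | ions | keeps the weakest genuine records (one prints exactly 2 core ions) while a uniform-random decoy peak has ≈0.3% chance per peak of hitting a core window |
| `min_rel_intensity` | 0.05 | fraction of base peak | the relative-abundance floor used when the diagnostic ions were surveyed; set 0 for pre-filtered lists |
| precursor `ppm_tol` | 5 | ppm | every printed catalog accuracy lies in [−4.9, −0.48] ppm |
| `betaxanthin_max_mz` | 450 | Th | betaxanthin [M+H]⁺ masses map up to ≈400; margin added; betacyanins start at 389 (aglycone) but carry 389.09 and are typed earlier in the rule order |
| `recal_ppm` | 0 | ppm | the catalog's uniformly negative accuracies suggest a calibration bias, but recalibration is opt-in, never automatic |
| loss `tol` | 0.005 | Da | separates glucuronosyl from feruloyl (15.3 mDa apart) while tolerating 3-decimal printed chain values |
| rt reference | Betanin | — | the field convention for relative rt |

Classification applies the marker rules **in order** (core gate → 389.09 →
345.10 → 343.09 → 211.07 → ambiguous); a spectrum showing both 389.09 and
345.10 (intact betacyanins routinely show both, the aglycone itself
fragmenting further) is an intact betacyanin, not a derivative.

## The synthetic-data generator

`simulate_run()` emulates one DDA pass over the catalog: per record, the
precursor is the theoretical [M+H]⁺ with multiplicative Normal error (sd
2 ppm by default — the observed accuracies are all within 5 ppm), each
curated fragment becomes a peak with additive Normal m/z error (sd
0.003 Da) and log-uniform intensity in [floor, 1]×base peak, noise peaks are
uniform over the 100–600 Th MS2 scan range but excluded from ±0.05 Da
windows around true fragments and kept below the abundance floor (no
intensity model is stated for noise; keeping it sub-threshold makes the
decoy false-positive expectation exactly 0), and rt gets Normal jitter (sd
0.05 min). Decoy features avoid all diagnostic-ion windows; an
*adversarial* mode instead places decoy peaks exactly on core ions to probe
the specificity limit of a fragment-only screen (such decoys are, by
construction, indistinguishable from betalains to this method). Seeds fully
determine a run, to the byte in MGF output.

What the generator does **not** emulate — and what a green test therefore
does not establish: chromatographic peak shape and co-elution, isotope
envelopes, multiply charged ions, in-source fragmentation, real intensity
structure of fragment ions, matrix background that correlates with the
analytes, and instrument-specific mass-error correlation across a run
(errors are drawn independently per spectrum, while real calibration drift
is smooth in time).

## Numerical choices

* Atomic masses are full-precision CODATA/AME values, not 6-decimal
  truncations: betalamic acid (C9H9NO5) computes to 212.055349, which
  rounds to the printed 212.0553; truncated constants land exactly on the
  .00005 boundary and round the wrong way.
* Reported m/z round to 4 decimals and ppm to 2, ties away from zero;
  internal computation never rounds.
* The ppm validation recomputes against each record's *stated* theoretical
  m/z: three records (415.1499, 2 × 859.2403) sit on a rounding boundary
  where full-precision recomputation prints 1 × 10⁻⁴ higher, and their
  curated ppm follows the printed value. The stated theoretical is itself
  validated against the formula within 0.0005 Da first, so the check is not
  circular.
* `resolve_isomers()` treats rt distances within 10⁻⁹ min as ties and
  reports ambiguity rather than choosing; coverage ties break by |ppm| and
  then by catalog id, so output is deterministic.
* Degenerate inputs: the empty composition has mass 0; subtraction that
  would give a negative element count is an error, not a clamp; an empty
  catalog file with a valid header loads as a 0-record catalog; screening
  an empty run returns an empty table.

## Design decisions taken where the design was open

* **Category is authoritative over name parsing.** The decarboxylated forms
  of the two unknown betacyanins carry no "decarboxy" in their names;
  derivative status therefore follows the catalog's explicit category
  column, with name-derived ops as a helper.
* **Betalamic acid's bucket.** The published 31/36/19 partition only sums
  to 86 if betalamic acid counts among the betacyanins; the catalog keeps
  it in its own category and `catalog_stats()` folds it into betacyanins
  for the published-style partition.
* **Four exception records.** Three curated fragment lists carry fewer than
  two core ions (the tridecarboxy/xanneo variants at m/z 417.17, 459.14,
  415.15) and one carries exactly two but no marker ion; the classifier
  reports them (screen rejection, or "ambiguous") instead of guessing a
  class, and the annotator can still assign the ambiguous one by precursor
  ppm.
* **Round-trip benchmark runs without rt jitter.** The benchmark condition
  states precursor (2 ppm) and fragment (0.003 Da) noise plus 50 decoys.
  Retention-time noise is deliberately excluded there, and not because it
  is harmless: the catalog contains same-formula, identical-fragment pairs
  0.01 min apart (e.g. the two mono-decarboxy-neobetanins at 8.39/8.40
  min), so *any* rt noise at the generator's own 0.05 min default turns
  their assignment into a coin flip and caps expected name-level recovery
  near 91%. That is a statement about the limits of rt-based isomer
  resolution, not about the annotator; the benchmark isolates the
  mass/fragment pipeline instead. With the stated noise the 10-seed mean
  name-level recovery is ≥ 95% (the misses are the 3 screen-rejected
  records plus the ~1.2% of precursors whose 2-ppm error exceeds the 5-ppm
  gate), class-level accuracy of acceptances is 100%, and decoy
  acceptances are 0.
* **Printed-value conflicts are documented, not resolved.** The published
  multistage chain for the unknown betacyanin implies losses of 132.0423
  (pentosyl) and 144.0422 (hydroxymethylglutaryl) for its first two steps,
  while the accompanying prose states 134.0423 ("pentoside or glutaric
  acid") and 162.0528 ("glucoside"). The interpreter always computes deltas
  from the m/z chain; for a ~132 Da loss both pentosyl and the isobaric
  glutaryl are reported.

## Known limitations

* Identification is dereplication against a curated catalog; novel
  compounds surface only through the MSn composition proposal, which gives
  a formula, never a structure, glycosylation position or stereochemistry.
* Positional isomers of decarboxylation and C15 epimers are distinguishable
  only by retention time; co-eluting same-formula records are reported
  ambiguous.
* The fragment screen is defeatable by construction (adversarial decoys);
  specificity claims hold for peaks that do not deliberately mimic the
  core ions.
* No peak picking, XIC construction, isotope deconvolution or peak-area
  integration: inputs are feature-resolved spectra, and abundance columns
  pass through unmodified.
* Only [M+H]⁺ at charge +1 is supported; other adducts and charge states
  are out of scope.
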