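---
title: "Rule-based fragment prediction and identification of acylpolyamine toxins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based fragment prediction and identification of acylpolyamine toxins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyfrag)
```

## The problem

Acylpolyamine toxins are low molecular mass neuroactive compounds found in
spider and wasp venoms. They are modular: an aromatic acyl *head* (for
example an indolyl-3-acetyl or 4-hydroxybenzoyl group), a polyamine
*backbone* of one to ten methylene chains separated by nitrogen atoms, a
basic *tail* (a terminal amine, a quaternary ammonium group, a guanidino
group, or an amino acid such as arginine), and optionally an amino-acid
*linker* between the head and the backbone. Because reference MS/MS
spectra for this compound class are essentially absent from general
spectral libraries, identification rests on exact mass arithmetic over the
building blocks, on rule-based fragment prediction, and on orthogonal
evidence such as retention time and hydrogen/deuterium exchange (HDX).

`polyfrag` implements that tool chain: a molecular-formula engine, the
generic nomenclature of the compound class, rule-based prediction of
precursor and fragment ions, peak-list annotation, a local compound
registry, and a stepwise identification workflow that proposes structures
for unknowns.

## Generic nomenclature

A generic name encodes the full constitution: head abbreviation, one
digit per backbone chain (the number of methylene units between two
nitrogens), a bracketed token naming the substituent on the nitrogen
*between* chain *k* and chain *k+1*, and a tail token. `IndAc4333` is an
indolylacetyl head on a 4-3-3-3 backbone with the default terminal NH2;
`4-OH-IndAc3(OH)335(NMe3)+` carries an N-hydroxyl on the second backbone
nitrogen and a fixed quaternary trimethylammonium tail.

Two grammar decisions deserve a note. First, the bracket after digit *k*
binds the *following* nitrogen. This is the only reading consistent with
the fragment arithmetic: the first a-type fragment of
`4-OH-IndAc3(OH)335(NMe3)+` contains no oxygen beyond the head (the
hydroxyl arrives with the second nitrogen), which is what its accurate
mass demands. A corollary is that the head-amide nitrogen can never carry
a substituent, and a bracket before the first digit is rejected. Second,
chains are single digits (1–9); longer chains would make the digit string
ambiguous and are not represented.

Head abbreviations (including ring-substituent prefixes such as
`2,4-(OH)2-`) are opaque registry tokens matched longest-first; no
chemistry is parsed inside them. Typographic variants from manuscripts
(`(OH)_2_`, Unicode dashes, caret superscripts) are normalized before
matching.

## Mass arithmetic

All masses come from a pinned monoisotopic table (H 1.00782503, C 12
exactly, N 14.00307401, O 15.99491462, F 18.99840322, S 31.97207117 Da),
with electron mass 0.00054858 Da and proton mass 1.00727646 Da. Ion m/z
is computed as

$$ m/z = \frac{\sum m_\text{atoms} + n_{H^+}\, m(\mathrm{H}) - z\, m_e}{z} $$

i.e. every charge carries a one-electron deficit. The electron-mass
correction matters at this mass range: omitting it shifts a singly charged
ion by roughly 1 ppm at m/z 500, which is the same order as the mass
errors being interpreted. With this table, published reference
measurements for this compound class reproduce to ±0.02 ppm of their
printed two-decimal mass errors; the residual ±0.01–0.02 ppm is the
rounding freedom of the (unknown) atomic-mass table used for the printed
values, and is accepted. m/z values are reported to five decimals and ppm
errors to two, matching the precision conventions of the field.

Multiply charged ions are serialized in the bracketed form
`[C27H50N6O3]2+`; a bare trailing digit before the sign would be
ambiguous with an element count.

## Fragment rules

The validated core is the a-type series: head-retaining even-electron
cations formed by intramolecular nucleophilic substitution at protonated
amino groups. `a_k` contains the head (plus linker, if any) and backbone
units 1..k, with m/z equal to its atom-sum minus one electron mass. Two
head diagnostics complete the family: `a0`, the head acylium cation, and
`a'` = `a0` − CO. These ions, together with the precursor species
(`[M+H]+`, `[M+2H]2+` and the trifluoroacetic-acid adduct for neutrals;
`M+`, `[M+H]2+` and the TFA association adduct for fixed cations), are
validated against published accurate-mass measurements in the test suite.

The remaining ion types named for this compound class — b, c, y, z and the
tail/linker t-ions — are emitted from configurable rules whose exact
offsets are *conventions of this package*, reconstructed from the usual
even-electron bookkeeping: `y_j` is the protonated tail-side amine
complementary to `a_{n-j}` (so that m/z(a) + m/z(y) equals the protonated
precursor plus one proton mass), `c_k = a_k + N(s)H2` where `s` is the
next nitrogen's substituent, `b_k = c_k − H2`, `z_j = y_j − N(s)H2 − H`,
and t-ions come from per-block diagnostic tables (empty by default,
user-extensible). Each type can be switched off individually via
`fragment_rules()`, and no validated result depends on them. They should
be revisited whenever reference spectra with confidently labeled b/c/t
ions become available.

Fragments are predicted singly charged only — consistent with the
observation that printed fragment assignments in this compound class are
1+ — and intensities are never predicted.

## HDX accounting

In a deuterated mobile phase every labile proton (N–H, O–H) exchanges, and
so do the protons acquired on ionization. The number of exchangeable
protons of a structure is the sum of the head's labile protons, one per
backbone N–H or N–OH (none for N–Me), the tail's, and the linker's. The
observed full-scan mass shift is that count plus the number of ionizing
protons: 0 for `M+`, 1 for `[M+H]+` and `[M+H]2+`, 2 for `[M+2H]2+`. This
single extra unit is what distinguishes, for example, a dimethylamine tail
(no labile proton) from an N-ethylamine tail (one) at identical elemental
composition — the basis of `infer_tail_from_neutral_loss()`.

Three exchangeable-proton values are *provisional conventions*, not
derivable from the reference data used to validate the mass arithmetic:
the arginine tail (7), the guanidino tail (4) and the asparagine linker
(3, amide NH plus side-chain NH2). They are flagged `provisional` in the
block registry and only affect HDX bookkeeping, never masses.

## Spectra, annotation and similarity

Peak lists are read from Mascot Generic Format or two-column TSV;
annotation links each observed peak to the predicted ion with the smallest
absolute ppm error within tolerance (default 5 ppm, which covers the worst
published fragment error of ~3.3 ppm for this compound class with margin;
ties go to the lower-m/z prediction). Annotation is a function of m/z
only. Spectral similarity is a cosine over square-root-transformed
intensities of ppm-matched peak pairs — square-root weighting
de-emphasizes base peaks, as in standard library-search practice. A
reference match requires score ≥ 0.80 *and* ≥ 50% of the reference peaks
matched; both thresholds are declared conventions, since "the spectra
match" has no published quantitative criterion for this workflow, and both
are configurable.

## Compound registry and search semantics

Registry records carry a structure-reliability level (S-1
synthesis-confirmed … S-5 unknown structure) and a data-comparability
level (C-1 standardized MS/MS available … C-4 nothing comparable). C-1
requires an embedded reference spectrum; only S-5 permits a missing
formula. Formula search is exact on element counts *and* charge: a fixed
cation is indexed under its cation formula, so a query with the
corresponding neutral formula finds nothing — mirroring how quaternary
toxins are indexed in practice and why precursor-floor search (`floor` of
any stored precursor m/z) is the route that finds them.

The retention-time filter keeps candidates within 2% of the observed
value. The tolerance base is deliberately the *observed* Rt (the
published phrasing is ambiguous between observed- and candidate-based
windows; at the documented window of 8.89 ± 0.18 min both readings agree,
and the observed-based one is simpler to reason about). Records without a
standardized Rt pass through flagged "not comparable" rather than being
excluded.

## The identification flow

`identify_compound()` walks the decision chart used for venom-toxin
annotation, recording every executed step in a trace:

* **Q1** registry search by formula and by floored precursor m/z, with an
  accurate-mass guard: floor matches whose stored precursor deviates by
  more than 10 ppm are excluded (this reproduces the documented ~50 ppm
  exclusion of a wrong floor-hit candidate).
* **Q2** retention-time plausibility (2% window; skipped without an
  observed Rt, "not comparable" without a stored one).
* **Q3** reference-spectrum comparison where a record has one.
* **Q4/Q8** polyamine triage: N count ≥ 3 and ring-and-double-bond
  equivalents in a plausible range (3–15) when a formula is supplied.
* **Q5** predicted-fragment support. All surviving candidates are
  evaluated and ranked lexicographically by (number of matched a-family
  ions, total matched predictions, −mean |ppm|); a candidate needs at
  least two matched a-family ions to count as supported. Ties are
  reported, never silently broken.
* **Q6** fingerprint comparison against registry entries sharing the
  identical backbone-unit composition (compared as the sequence of unit
  formulas, so head- and tail-variant siblings are recognized); absence of
  such an entry yields "not comparable", not failure.
* **Q7** HDX consistency, when an observed shift is supplied; inconsistent
  candidates are dropped.
* **Q9** head detection from the a′/a0/a1 diagnostic ions, ranked by
  matched count then mean |ppm|.
* **Q10** bounded stepwise assembly from the detected head: a depth-first
  search extends the a-series one backbone unit at a time (chains 1–9,
  substituents H/OH/Me on all nitrogens but the first), requiring a
  supporting peak for every extension, and closes with any registered tail
  whose assembled precursor matches the observed one within 5 ppm, up to
  10 units. Assembled candidates then pass through Q5–Q7 like any others.

Verdicts are `identified_by_reference` (Q3 pass),
`supported_by_prediction` (registry candidate with Q5 support),
`proposed_new_structure` (assembled candidate), or `unresolved`. A
structure proposal therefore always implies a detected head and a-series
support, and a reference identification always implies a spectrum match.

One intrinsic limitation is worth stating plainly: a backbone nitrogen
carrying a methyl group is elementally identical to an unmethylated
nitrogen with one extra backbone methylene, at every fragment. Candidates
differing only in such placements tie on all mass evidence; the b/c/z ions
(whose composition depends on the substituent position) and the HDX count
(methylation removes a labile proton) are the discriminating observables.
Without an HDX shift, such alternatives are reported as ties — which is
the honest answer.

## The synthetic-spectrum generator

`synth_spectrum()` emits the peaks the fragmentation rules predict for a
structure — by default every predicted fragment type plus the surviving
singly charged precursor — with three noise controls: Gaussian m/z jitter
with a standard deviation in ppm (default study condition 2 ppm, matching
a calibrated instrument's typical relative mass error of below 2 ppm),
uniform decoy peaks at 10% of the true peak count, and fixed intensities
descending toward high m/z (mimicking the dominant low-mass head ions of
measured spectra of this class; arbitrary but fixed, since the rules
predict no intensities). `random_structure()` draws assemblies uniformly
from the registered blocks: 2–6 units, chains 1–9, per-nitrogen
substitution probability 0.25 (split evenly between OH and Me), any
registered tail — deliberately broader and noisier in composition than the
published corpus, to stress the parser and the assembly search.

What passing tests on these spectra do and do not show: they demonstrate
that the arithmetic, grammar, annotation and search machinery are
internally consistent and invertible under realistic mass error, and that
the workflow recovers generating structures when the predicted fragments
are present. They do not validate fragment *occurrence* or intensity on
real instruments (real spectra lose fragments in a compound-dependent
way), nor matrix effects on retention times, nor the provisional b/c/z/t
rules against measured assignments.

## Numerical choices and problem sizes

Tolerances: 5 ppm fragment matching, 10 ppm precursor guard, 2% Rt,
similarity 0.80 / 50% matched; all configurable through
`identify_config()`. Degenerate inputs are errors, not guesses: empty
spectra cannot be compared, subtraction below zero atoms names the
element, unparseable name suffixes are reported verbatim. The test suite
exercises the formula-oracle equivalence on 1000 random assemblies, series
invariants on 50, name round-trips on ~110, and structure recovery on 100
synthetic spectra (expecting at least 95 recovered, with the true HDX
shift supplied as the workflow's Q7 input); these sizes keep the default
run around a minute and a half on one CPU while estimating the recovery
rate to a few percent.
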