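# polyfrag

Rule-based MS/MS fragment-ion prediction and identification of
acylpolyamine spider-venom toxins.

Acylpolyamines — the dominant low molecular mass (< 1000 Da) toxins of
spider and wasp venoms — are modular molecules: an aromatic acyl **head**,
a polyamine **backbone** of 1–10 methylene chains joined by nitrogen
atoms (optionally N-hydroxylated or N-methylated), a basic **tail**
(terminal amine, quaternary ammonium, guanidino group, or an amino acid),
and optionally an amino-acid **linker**. They are nearly absent from
general spectral libraries, so identifying them from UHPLC-HR-ESI-MS/MS
data relies on exact mass arithmetic over the building blocks rather than
library lookup. `polyfrag` is that calculator and workflow, for mass
spectrometrists and venom chemists:

* **Formula engine** — integer element-count algebra (H, C, N, O, F, S)
  with electron-mass-corrected ion m/z:
  `m/z = (Σ m_atoms + n_H⁺·m(H) − z·m_e) / z`, and ppm errors against
  theoretical values.
* **Generic nomenclature** — parser/formatter for names such as
  `4-OH-IndAc3(OH)335(NMe3)+` or `2,4-(OH)2-PhAcAsn533Arg`, where digits
  are methylene chain lengths and a bracket after digit *k* names the
  substituent on the nitrogen between chains *k* and *k+1*.
* **Fragment prediction** — the a-type series (head-retaining
  even-electron cations, with the `a0` acylium and `a′ = a0 − CO` head
  diagnostics), precursor species incl. `[M+2H]²⁺`/`[M+H]²⁺` and
  trifluoroacetic-acid adducts, plus configurable b/c/y/z/t rules.
* **HDX accounting** — exchangeable-proton counts and the observed
  mass shift in deuterated mobile phase (labile protons + ionizing
  protons), including tail disambiguation from an observed neutral loss.
* **Spectra** — MGF/TSV peak-list I/O, ppm-tolerance annotation,
  square-root-intensity cosine similarity.
* **Registry & workflow** — a local compound registry (reliability levels
  S-1…S-5, comparability C-1…C-4, formula/precursor search, 2% Rt filter)
  and a stepwise identification flow that either matches a known
  compound or assembles a new structure head-first from its fragment
  ladder.

## Worked example

Predict everything the calculator knows about the quaternary toxin
`4-OH-IndAc3(OH)335(NMe3)+`, then annotate a measured peak list:

```r
library(polyfrag)
rep <- predict_ions("4-OH-IndAc3(OH)335(NMe3)+")
rep
#> Prediction report for 4-OH-IndAc3(OH)335(NMe3)+
#>   formula:           C27H49N6O3+
#>   monoisotopic mass: 505.38661 Da
#>   exchangeable H:    6
#>   precursor ions:
#>     M+                 C27H49N6O3+         505.38607
#>     [M+H]2+            [C27H50N6O3]2+      253.19667
#>     [(M+H)+CF3CO2]+    C29H50F3N6O5+       619.37893
#>   fragments:
#>     a'  0   C9H8NO+           146.06004
#>     a0  0   C10H8NO2+         174.05495
#>     a   1   C13H15N2O2+       231.11280
#>     ...
#>     a   4   C24H40N5O3+       446.31257
```

The report says: the intact cation is C27H49N6O3⁺ at m/z 505.38607; in
deuterated solvent it shifts by 6 units (two labile protons on the head,
four on the backbone, none on the quaternary tail); and its head-anchored
fragment ladder starts at the a′ diagnostic 146.06004 and climbs by one
backbone unit per a-ion. Annotating the measured peaks:

```r
sp <- new_spectrum(
  c(146.06041, 231.11341, 304.16639, 361.22422, 446.31402, 505.38680),
  c(900, 800, 700, 600, 500, 400))
pred <- rbind(rep$fragments[, c("ion_type", "index", "formula", "mz")],
              data.frame(ion_type = rep$precursor_ions$label, index = NA,
                         formula = rep$precursor_ions$formula,
                         mz = rep$precursor_ions$mz))
annotate_spectrum(sp, pred, tol_ppm = 5)
#> <annotated spectrum> 6/6 peaks annotated (tol 5.0 ppm), 9 predictions unmatched
#>    146.06041  a' 0   C9H8NO+           +2.53 ppm
#>    231.11341  a  1   C13H15N2O2+       +2.62 ppm
#>    304.16639  a  2   C16H22N3O3+       +2.70 ppm
#>    361.22422  a  3   C19H29N4O3+       +2.22 ppm
#>    446.31402  a  4   C24H40N5O3+       +3.26 ppm
#>    505.38680  M+     C27H49N6O3+       +1.45 ppm
```

Every measured peak lands within a few ppm of a predicted ion — the
complete a-series plus the surviving precursor, which is the evidence
pattern that supports this structure. The full identification workflow
(`identify_compound()`) automates the same reasoning against a compound
registry, including retention-time filtering, HDX checks, and head-first
assembly of unknowns; see the vignette in `vignettes/` for the model and
its assumptions.

A thin command-line front end wraps the same functions:

```sh
inst/cli/polyfrag predict --name "IndAc4333"
inst/cli/polyfrag fixtures --dir fixtures --seed 1
inst/cli/polyfrag identify --spectrum spec.mgf --precursor 505.38687 \
    --registry fixtures/registry.json --hdx-shift 6
```

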