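# glaquant

Monitoring the yield and quality of a recombinant coagulation factor IX
(rFIX) product by DIA/SWATH mass spectrometry, in R.

rFIX is a heavily post-translationally modified biopharmaceutical whose
clinical efficacy depends on γ-carboxylation of the twelve glutamates of its
GLA domain (Gla, +43.98983 Da per site, "+44"). Because downstream anion
exchange purification enriches for γ-carboxylated molecules, measuring the
product only after purification hides what the bioreactor actually made.
`glaquant` implements a transition-level DIA quantification workflow for the
bioreactor supernatant and the purified product:

* **Mass calculus** for peptidoforms: monoisotopic neutral masses, precursor
  m/z at any charge (`(M + z·1.007276)/z`), b/y fragment ladders with
  neutral-loss variants (−SO₃, −CO₂), glycopeptide Y ions (Y0 = bare
  peptide, Y1 = +HexNAc, Y2 = +Hex), diagnostic immonium ions, glycan
  composition arithmetic (Hex, HexNAc, Fuc, NeuAc, NeuGc, Xyl), in-silico
  digestion (trypsin/GluC/AspN/chymotrypsin), and enumeration of
  carboxyforms (0..K γ-carboxylations) and methyl-ester derivatization
  states (methanolic HCl esterifies the free carboxyl inventory:
  #Asp + #free Glu + 2·#Gla + C-terminus).
* **Ion libraries and SWATH schemes**: long-format transition libraries with
  TSV round-tripping, isolation-window geometry, and detection of
  co-isolated co-eluting precursors that must be quantified together.
* **Label-free quantification**: RT-windowed top-N transition summation per
  peptidoform class, peptide FDR filtering at 1%, protein rollup, and
  normalization to the trypsin autolysis peptide VATVSLPR (421.7584²⁺).
* **Stoichiometry**: per-family carboxyform percentage profiles
  (`% at k = 100 · Σ intensity(k) / Σ intensity(family)`), PTM variant
  abundance relative to product abundance, time-course matrices.
* **Statistics**: one-tailed pooled-variance t tests, the two-stage linear
  step-up FDR procedure for multiple t tests, and a protein-level
  differential-abundance screen (log2 features → median-polish run
  summaries → equal-variance t → BH).
* **A synthetic fed-batch generator** that simulates two 13-day bioreactor
  conditions (differing in yield, viability, carboxyform occupancy and
  host-cell-protein release), a purification endpoint, and renders them
  into transition tables — so the whole pipeline runs and is validated
  without any external data.

## Worked example

```r
library(glaquant)

# the trypsin autolysis reference used for normalization
precursor_mz("VATVSLPR", z = 2)
#> [1] 421.7583

# carboxyforms of a GLA-domain tryptic peptide: +44 Da per step
enumerate_carboxyforms("LEEFVQGNLER", gla_sites = c(2, 3, 10))$neutral_mass
#> [1] 1332.667 1376.657 1420.647 1464.637

# Y ions of the methylated T38/39 glycopeptide
glycopeptide_y_ions("TTEFWK", "Methyl;1:HexNAc1Hex1NeuAc1")$mz
#> [1]  825.4141 1028.4935 1190.5463 1481.6417

# end-to-end synthetic run: simulate, render, quantify, profile, compare
res <- run_pipeline()
res$profiles |> dplyr::filter(sample == "A_purified_r1", family == "CSFEEAR")
#> # A tibble: 3 × 6
#>   sample        family      k intensity    pct defined
#>   <chr>         <chr>   <int>     <dbl>  <dbl> <lgl>
#> 1 A_purified_r1 CSFEEAR     0      1.66  0.608 TRUE
#> 2 A_purified_r1 CSFEEAR     1     52.9  19.4   TRUE
#> 3 A_purified_r1 CSFEEAR     2    218.   80.0   TRUE
```

The first number is the reference peptide's theoretical 2+ m/z; the
carboxyform masses step by exactly 43.98983 Da; the Y-ion series gives the
bare methylated peptide (Y0), +HexNAc (Y1) and +HexNAc+Hex (Y2).  The
pipeline output shows a purified sample dominated by the fully carboxylated
form of the CSFEEAR family — purification enriches for carboxylated
species, which is exactly why supernatant monitoring matters.

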