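# indikit

Computational toolkit for engineering a stabilized indoxyl
glycosyltransferase and assessing an indican-based route to blue denim.

Indigo, the dye of blue denim, requires dithionite and alkaline conditions
to apply. Indican (indoxyl-β-D-glucoside) is a mild drop-in alternative:
a plant UDP-glucose glycosyltransferase (UGT) glucosylates indoxyl to
indican, and on the yarn indican is cleaved back — enzymatically or by
light — to indoxyl, which dimerizes to indigo in situ. Making this route
real poses two computational problems, and this package implements both
ends:

**Enzyme stabilization design**

- Consensus mutagenesis: from a gapped alignment of >60%-identity
  homologs, call substitutions at positions where the wildtype residue is
  underrepresented (frequency ≤ 0.30) and a clear family consensus exists
  (modal frequency ≥ 0.50, coverage ≥ 0.70), with differential
  sequence-logo output and active-site exclusion.
- Structure screens: geometric disulfide-pair scanning (Cα ≤ 7.5 Å,
  Cβ 3.0–5.0 Å prefilter; modelled Sγ over a χ1 sweep; accept when
  d(S–S) = 2.05 ± 0.35 Å and |χ3| ∈ [60°, 120°]; strain score
  ((Δd/0.35)² + ((|χ3|−87°)/30°)²), B-factor flexible-segment detection
  (z-normalized sliding windows), and loop-graft candidate selection by
  Kabsch anchor superposition.
- DSF melt analysis: Boltzmann-sigmoid fitting
  F(T) = base + amp / (1 + exp((Tm − T)/slope)) with
  aggregation-decay truncation, a derivative cross-check, replicate
  aggregation (mean ± SEM), ΔTm versus wildtype, and combination planning
  for multi-mutant variants.

**Process analytics**

- Kinetics: linear calibration, conversion, total turnover number,
  first-order photolysis fitting A(t) = A₀·e^(−kt), and zero- versus
  first-order model comparison.
- Techno-economics: recipe costing per kg product or per pair of jeans
  from a bulk price table, tornado sensitivity, seeded Monte-Carlo price
  uncertainty, breakeven bisection, and market-scale tank projection.
- Colorimetry: reflectance → XYZ (CIE 1964 10° observer, D65) → CIELAB,
  with swatch mean ± SD and reference-population box statistics.

Seeded synthetic-data generators (`gen_msa`, `gen_structure`,
`gen_melt_curves`, `gen_decay`, `gen_price_distributions`,
`gen_reflectance`) emulate each data type with planted ground truth and
JSON sidecars, so the whole pipeline runs and is tested without any
external data.

## Worked example

Design calls from a synthetic homolog family, a melt-shift measurement,
and the market-scale projection:

```r
library(indikit)

## consensus calls on an 18-homolog alignment with three planted signals
sites <- data.frame(position = c(75, 86, 222), wt = c("E", "Q", "G"),
                    consensus = c("P", "K", "D"))
msa <- gen_msa(seed = 11, n_homologs = 18, ref_length = 460,
               planted_calls = sites)
call_consensus(column_profiles(msa$alignment))
#>   ref_position wt_residue proposed_residue wt_frequency consensus_frequency coverage
#> 1           75          E                P            0           0.6111111        1
#> 2           86          Q                K            0           0.6111111        1
#> 3          222          G                D            0           0.6111111        1

## melt-temperature shift of a stabilized variant vs wildtype (3 replicates)
melt <- gen_melt_curves(seed = 11,
                        data.frame(name = c("WT", "stable"),
                                   tm = c(52.4, 65.5), slope = 1.5),
                        replicates = 3)
fits <- lapply(melt$curves, fit_melt_sigmoid)
wt <- aggregate_variant(Filter(function(f) f$variant == "WT", fits), 0)
aggregate_variant(Filter(function(f) f$variant == "stable", fits),
                  wt$tm_mean)
#> stable: Tm = 65.46 +/- 0.027 C (n = 3), dTm = +13.09 C

## tanks needed to replace the world indigo market with indican
market_scale(annual_dye_tonnes = 50000, dye_molar_mass = 262.3,
             product_molar_mass = 295.3, mol_ratio = 2,
             batch_titer = 0.065, tank_volume_m3 = 100, cycle_days = 2)
#> $tanks_exact      321.3849
#> $tanks_reported   320
#> $annual_product_tonnes  112581
```

The three planted design sites come back exactly (wildtype frequency 0,
consensus frequency 11/18); the fitted ΔTm recovers the 13.1 °C separation
built into the curves; and at a 65 mM batch titer, 100 m³ tanks cycled
every second day, replacing 50,000 t/yr of indigo needs ≈ 321 tanks — 320
at two significant figures.

A thin command-line front end covering the main operations ships in
`inst/cli/indikit`:

```sh
Rscript inst/cli/indikit simulate msa --seed 5 --out sim/
Rscript inst/cli/indikit consensus --msa sim/msa.fasta --ref REF --out calls.csv
Rscript inst/cli/indikit market-scale --titer 0.065 --tank 100 --cycle 2
```

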