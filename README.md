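# hbttc

One Health screening thresholds for organic chemicals in freshwater.

Ecological and human risk assessment of waterborne chemicals are usually run
separately and can disagree about what concentration is "safe". `hbttc`
derives a single **Human-Biota threshold of toxicological concern** — a
freshwater concentration protective of aquatic ecosystems *and* of people
drinking water abstracted from the same body — as the minimum of two
branches:

* **Ecological branch.** Acute/chronic toxicity endpoints for algae,
  invertebrates and fish are aggregated into per-cell geometric means; an
  assessment factor AF ∈ {10000, 5000, 1000, 100, 50, 10, 1–5} is selected
  from the data-availability pattern and the predicted no-effect
  concentration is PNEC = basis / AF. For a group of chemicals sharing a
  Verhaar mode-of-action class, the class threshold (eco-TTC) is the 5th
  percentile of the log10 PNEC distribution, estimated empirically, by
  normal MLE (μ̂ + z₀.₀₅ σ̂) and by logistic MLE (loĉ + ŝ·ln(0.05/0.95)),
  back-transformed, minimum taken.
* **Human branch.** A toxicological standard TL (Cramer-class TTC dose,
  ADI/TDI/RfD/benchmark dose, or NOAEL/100) becomes a drinking-water
  quality standard QS = 0.1·TL·bw/wu (bw = 70 kg, wu = 2 L/day);
  carcinogens — chemicals with an oral slope factor SF — instead get
  QS = (10⁻⁶/SF)·bw/wu at the 1-in-a-million acceptable cancer risk.

Intended users: environmental risk assessors and modellers who need
defensible screening levels for data-poor chemicals (generic thresholds by
Verhaar × Cramer class) or data-rich ones (compound-specific thresholds
from a hazard profile), reproducibly and in batch.

## Worked example

```r
library(hbttc)

# three acute trophic levels + a chronic datum NOT on the most sensitive
# acute taxon -> AF 1000 applied to the lowest acute geometric mean
rec <- endpoint_records("benzene-like",
  c("algae", "invertebrate", "fish", "algae"),
  c("acute", "acute", "acute", "chronic"),
  c(29, 10, 5.3, 2.1), unit = "mg/L")
p <- derive_pnec(rec)
p
#> PNEC for benzene-like: 0.0053 mg/L (5300 ng/L)
#>   rule 3-acute+1-chronic-other: AF 1000 on fish/acute geomean 5.3 mg/L (n = 1)

# human branch from a NOAEL: TL = NOAEL/100, QS = 0.1 * TL * 70 / 2
qs <- compound_qs(hazard_profile(noael = 1.0))
qs
#> Human QS: 0.035 mg/L (35 ug/L), basis noael
#>   TL 0.01 mg/kg bw/day, allocation 0.1, bw 70 kg, wu 2 L/day

# the Human-Biota threshold is the lower branch
compound_hbttc(p, qs)
#>    chemical_id hbttc_mg_L limiting_branch pnec_mg_L qs_mg_L qs_basis
#> 1 benzene-like     0.0053             eco    0.0053   0.035    noael
```

The PNEC (5.3 µg/L) sits below the drinking-water quality standard
(35 µg/L), so the ecological branch limits and 0.0053 mg/L is the
threshold protective of both receptors.

Generic thresholds for all 15 Verhaar × Cramer combinations rebuild from
the packaged reference constants; the eco branch undercuts every quality
standard, collapsing them to 5 distinct values:

```r
tab <- builtin_generic_hbttc()
tab[!duplicated(tab$verhaar_class), c("verhaar_class", "hbttc_ng_L", "eco_method")]
#>    verhaar_class hbttc_ng_L eco_method
#> 1              1     5.4960  empirical
#> 4              2     9.4550  empirical
#> 7              3     1.2540  empirical
#> 10             4     0.1175   logistic
#> 13             5     4.0120  empirical
```

## Command line

Each pipeline stage is a subcommand of the installed `inst/cli/hbttc`
launcher (or call `hbttc_cli()` in R):

```sh
hbttc simulate --seed 1 --n 50 --out endpoints.csv
hbttc derive-pnec --in endpoints.csv --out pnec.csv
hbttc derive-ecottc --in pnec_by_class.csv --out ecottc.csv
hbttc derive-qs --cramer-class 1 --bw 70        # -> 105 ug/L
hbttc derive-hbttc generic --builtin-tables
```

All tables are plain CSV; configuration is JSON (`read_config()`); errors
go to stderr with non-zero exit status (2 = some input rows rejected).

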