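# epimax

Penetrance tables with maximum prevalence or heritability for bivariate
epistasis models.

## What it does, and for whom

Researchers evaluating epistasis-detection methods need simulated
case–control data whose gene–gene interaction is known exactly. The standard
interchange object is a **penetrance table**: for each of the 3^n genotypes
of an n-locus interaction, the probability P(D | gᵢ) of expressing the
phenotype. Simulators such as GAMETES turn such a table into genotype
samples, but building a table that combines a prescribed interaction model
with realistic population parameters is the hard part — prescribing both
prevalence *and* heritability usually yields an incompatible system.

epimax takes a bivariate epistasis model — one penetrance expression
fᵢ(x, y) per genotype, all sharing a baseline-effect variable x and a
genotypic-effect variable y — together with per-locus minor allele
frequencies, fixes **one** population parameter, and **maximizes the
other**, subject to every penetrance lying in [0, 1]. Under Hardy–Weinberg
and linkage equilibrium:

- prevalence  `P(D) = Σᵢ fᵢ(x, y) · P(gᵢ)`
- heritability `h² = (1 − P)/P · Σᵢ (fᵢ(x, y) − P)² · P(gᵢ)`
  (genetic variance over the disease odds; see the vignette for the
  convention and its relation to the Bernoulli-variance form)

For models whose expressions are monotonically non-decreasing and sortable
on the positive quadrant — both properties are verified automatically — the
constrained maximum is attained exactly where the largest penetrance
expression equals 1, so the problem reduces to a two-equation system that
is solved to machine precision at any interaction order (additive models
are exercised through order 12).

## Worked example

The classical second-order additive model (penetrance x(1+y)^(g₁+g₂)) at
MAF 0.25 for both loci, maximizing prevalence under heritability 0.2:

```r
library(epimax)
m   <- additive_model(2)                    # or parse_model("model.csv")
tab <- find_max_prevalence(m, c(0.25, 0.25), h2_target = 0.2)
tab
#> Penetrance table: order 2, MAF = (0.25, 0.25), model 'additive2'
#>   solved variables: x = 0.00192942, y = 3.77137
#>   prevalence = 0.0274902, heritability = 0.2
#>        BB     Bb     bb
#> AA 0.0019 0.0092 0.0439
#> Aa 0.0092 0.0439 0.2096
#> aa 0.0439 0.2096 1.0000
```

The solved variables are the model coordinates at which the table is
realized; the reported prevalence (≈ 0.0275) is the *largest* this model
can reach at heritability 0.2, and every smaller value is achievable. The
maximum penetrance is exactly 1 (the binding constraint of the
maximization). Write the table for a downstream simulator:

```r
write_gametes(tab, "table.txt")   # GAMETES 2.x attribute-model layout
write_table_csv(tab, "table.csv") # two-column genotype,penetrance CSV
```

The same pipeline runs from a shell via the bundled wrapper:

```sh
Rscript inst/cli/epimax.R find --command max-prevalence \
    --model model.csv --maf 0.25,0.25 --target 0.2 \
    --out table.txt --format gametes
Rscript inst/cli/epimax.R zoo --family additive --order 4 --out model4.csv
```

Exit codes: 0 success, 2 parse/argument error, 3 model-validation failure,
4 no solution, 5 I/O error.

Other entry points: `find_max_heritability()` (fix prevalence, maximize
heritability), `genotype_probabilities()` (exact Hardy–Weinberg genotype
frequencies), `validate_monotone()` / `validate_sortable()` (admissibility
reports), `table_prevalence()` / `table_heritability()` (recompute
parameters from any numeric table), and the model generators
`additive_model()`, `multiplicative_model()`, `threshold_model()`,
`incompatible_model()`.

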