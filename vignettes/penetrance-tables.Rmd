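---
title: "Computing maximum-prevalence and maximum-heritability penetrance tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing maximum-prevalence and maximum-heritability penetrance tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimax)
```

## The problem

Simulation studies of epistasis detection need case–control data whose
gene–gene interaction structure is known in advance. The standard way to
encode an interaction among $n$ biallelic loci is a *penetrance table*: for
each of the $3^n$ multilocus genotypes $g_i$, the probability
$P(D \mid g_i)$ of expressing the phenotype. Data simulators such as GAMETES
consume such tables directly, but they struggle to *construct* tables that
combine a prescribed interaction model with realistic population parameters,
especially beyond two or three loci.

epimax starts from a *bivariate epistasis model*: one arithmetic expression
$f_i(x, y)$ per genotype, all sharing a baseline-effect variable $x$ and a
genotypic-effect variable $y$ (often written $\alpha$ and $\theta$). Under
Hardy–Weinberg equilibrium at each locus and linkage equilibrium among loci,
a genotype's population frequency is the product of its per-locus
frequencies $q^2$, $2pq$, $p^2$ (with $p$ the minor allele frequency), and
the two population parameters of interest are

* prevalence: $P(D) = \sum_i P(D \mid g_i)\, P(g_i)$, and
* broad-sense heritability:
  $h^2 = \dfrac{1 - P(D)}{P(D)} \sum_i \big(P(D \mid g_i) - P(D)\big)^2 P(g_i)$,

i.e. the genetic variance of the penetrances divided by the disease odds
$P(D)/(1 - P(D))$ (see *Conventions* below).

Prescribing *both* parameters and solving the resulting two-equation system
frequently yields an incompatible system, because a model cannot realize
every $(P(D), h^2)$ pair. epimax instead fixes one parameter and
*maximizes* the other, which succeeds for any value the model can reach at
all, and makes the achievable region explicit: everything between 0 and the
returned maximum.

## The maximization reduction

The method requires two admissibility conditions on the model, both checked
by the package over the open positive quadrant $x > 0,\ y > 0$:

1. **Monotonicity** (`validate_monotone()`): every $f_i$ is monotonically
   non-decreasing in both variables, i.e. both partial derivatives are
   non-negative.
2. **Sortability** (`validate_sortable()`): the distinct expressions admit a
   single total order valid on the whole quadrant.

For such a model, every penetrance grows together with the variables, so a
constrained maximum of prevalence (or heritability) is attained exactly when
the *largest* expression hits its ceiling — penetrances are probabilities,
so that ceiling is 1. The problem therefore reduces to a two-equation
system: the constraint (heritability or prevalence equal to its target)
plus `max expression = 1`. `find_max_prevalence()` and
`find_max_heritability()` build and solve these systems and return a
`penetrance_table`; solutions with negative components are discarded, since
the admissibility conditions only hold on the positive quadrant, and any
candidate whose substituted penetrances leave $[0, 1]$ is rejected.

```{r}
tab <- find_max_prevalence(additive_model(2), c(0.25, 0.25), h2_target = 0.2)
tab
```

## How the admissibility proofs work

Expressions are restricted to an arithmetic grammar (`+ - * / ^`,
parentheses, numeric literals, the two variables), so sign questions can
usually be settled symbolically: the package converts the relevant quantity
(a partial derivative, or a difference of two expressions) into a rational
function $n(x,y)/d(x,y)$ with explicit coefficients. If all coefficients of
$n$ and $d$ are non-negative (and $n \neq 0$), the quantity is positive on
the open positive quadrant; all-non-positive numerators certify the
opposite sign. This decides every polynomial-family model in the package.

When the certificate is inconclusive (mixed coefficient signs, or
non-integer exponents), the check falls back to evaluation on a
deterministic sample: a $20 \times 20$ log-spaced grid over
$(10^{-6}, 10^3)^2$ plus 100 fixed pseudo-random points from a dedicated
Park–Miller stream (so results never depend on the session RNG).
Sampling-based conclusions are flagged `"sampled"` in the validation report,
since a sign change could in principle hide between sample points. The
solver entry points require both validations to pass by default;
`solver_config(require_validation = FALSE)` overrides this for models the
user knows to be admissible.

## Solving the system

The max-penetrance equation is linear in $x$ for every model of the common
form $x \cdot g(y)$ — including all three generated families — so $x$ is
eliminated exactly and the constraint becomes univariate in $y$. (If
neither variable can be eliminated linearly, a nested numeric solve is used
instead.) Roots are located by sign-change bracketing over 64 log-spaced
seeds spanning `free_var_bracket` (default $(10^{-12}, 10^6)$ — deliberately
far beyond the $[0, 2]$ neighbourhood usually plotted for these models,
because realistic heritabilities are often reached only at large genotypic
effects), refined by `stats::uniroot()` and polished with damped Newton
steps. All real roots are collected; after the negativity, residual and
penetrance-bound filters, the root maximizing the free parameter is
returned, with exact ties broken by the smallest $y$ for determinism.

Numerics are IEEE double precision. The `digits` setting of
`solver_config()` (default 32) sets the relative step at which root
polishing stops, $10^{-\text{digits}}$, and is floored at machine epsilon,
so the effective working precision tops out near 16 significant digits;
constraint residuals at returned roots are routinely at the
$10^{-15}$–$10^{-17}$ level, far below the default `residual_tol` of
$10^{-12}$. Increasing `digits` never loosens anything; it simply cannot
push below the double-precision floor. Genotype probabilities, by contrast,
are computed exactly: MAFs are rationalized by continued fractions and the
per-genotype frequencies carried as integer numerator/denominator pairs
(exact below $2^{53}$), so $\sum_i P(g_i) = 1$ holds identically and
contributes no error to the solve.

Duplicate penetrance expressions — ubiquitous in high-order models — are
collapsed before any symbolic work, with their genotype probabilities
aggregated exactly. An additive model of order 10 has $3^{10} = 59049$
rows but only 21 distinct expressions; deduplication is what keeps such
orders tractable (the order-10 solve runs in about a second).

## Conventions

**Heritability denominator.** Two variance-standardizations of a binary
trait circulate in the simulation literature: dividing the genetic variance
$V_g = \sum_i (f_i - P)^2 P(g_i)$ by the Bernoulli phenotypic variance
$P(1-P)$, or by the disease odds $P/(1-P)$. The two differ by the factor
$(1-P)^2$ — negligible for rare phenotypes, but material at prevalences of
a few percent. epimax uses the odds denominator,
$h^2 = V_g (1-P)/P$: it is the convention under which the classical
second-order additive reference solution (MAF 0.25, $h^2 = 0.2$, maximum
prevalence) reproduces exactly — solved variables $(x, y) =
(0.0019, 3.7714)$ to four decimals, prevalence $0.0275$, and a recomputed
heritability of exactly $0.2$ — whereas the Bernoulli form yields a
different root ($y \approx 3.4702$) and assigns the reference table a
heritability of $0.2115$. The squared deviation in $V_g$ is used throughout,
including inside the maximization system. Users needing the Bernoulli form
can recover it as `table_heritability(tab) / (1 - table_prevalence(tab))^2`.

**Canonical genotype order.** Rows follow the mixed-radix base-3
enumeration: digit $k$ is the minor-allele count at locus $k$
(0 = homozygous major `AA`, 1 = heterozygous `Aa`, 2 = homozygous minor
`aa`), with the last locus varying fastest — the layout in which two-locus
tables are conventionally printed. Genotype labels are validated for shape
but are otherwise cosmetic: only row order matters to the solver.

**Variables.** Any alphabetic token in a model CSV is a variable name;
multi-letter tokens are single variables. Exactly two distinct variables
must appear (the method is defined for bivariate models), sorted
lexicographically for determinism, so permuting the CSV rows never changes
the inferred pair. The programmatic constructor additionally accepts an
explicit `variables =` pair of which the expressions may use a subset,
which admits degenerate test models such as all-constant penetrances.

## The model families

`additive_model()`, `multiplicative_model()` and `threshold_model()`
generate, at any interaction order, the families used throughout the test
suite; `incompatible_model()` is the standard two-locus counter-example
(expressions $x$, $xy$, $x/y$) that fails both admissibility checks, kept
as a negative control. The second-order additive form is the classical
table whose penetrance is $x(1+y)^{g_1+g_2}$; only its generalization to
$n$ loci, $x(1+y)^{\sum g_k}$, is fully standard. For the other two
families the literature names the models but not their $n$-locus forms, so
the package fixes conventions matching their usual characterizations and
documents them as such: the threshold model is first-degree in each
variable ($x$ unless every locus carries at least one minor allele, else
$x(1+y)$), and the multiplicative model's degree grows with the genotype,
via the exponent $\prod_k g_k$. Quantitative precision claims in the
acceptance checks are therefore confined to the additive family; the other
two are exercised through property-based tests (admissibility,
grid-maximality, constraint round-trips) that do not depend on the chosen
exponent convention.

These generators are the package's synthetic-data backbone: tests and the
acceptance script run the solver on generated models at the reference
conditions (MAF 0.25 and the 0.1/0.4 MAF, 0.1/0.8 heritability grid at
orders 3–4) rather than on stored fixtures. What the generated families do
*not* emulate is everything the Hardy–Weinberg/linkage-equilibrium
assumptions exclude — linkage disequilibrium, population structure,
inbreeding, locus-specific effect sizes ($\theta_1 \neq \theta_2$ variants
are out of scope) — so passing tests say nothing about models outside the
monotone-sortable bivariate class.

## Degenerate inputs and failure modes

* A model whose expressions tie everywhere (e.g. all constant) makes the
  max-penetrance equation vacuous or unsatisfiable; the solver reports an
  under-determined or no-solution error rather than inventing a root.
* Infeasibility is reported distinctly: "no root anywhere in the search
  bracket" (the target exceeds what the model can reach) versus "roots
  exist but violate the $[0,1]$ penetrance bounds", with per-candidate
  rejection reasons in the error message.
* MAF 0.5 is allowed (the minor/major boundary); MAF 0 is rejected, since a
  monomorphic locus makes its genotype rows meaningless. Heritability is
  undefined at prevalence 0 or 1 and raises a domain error.
* Near-degenerate targets (prevalence close to 1) are handled but leave
  essentially no variance headroom; the maximum heritability tends to 0.

## Problem sizes used by the checks

The bundled tests solve the generated families at orders 1–5 for
admissibility, orders 2–4 for the precision grid, order 10 for the
capability check (59049 genotypes, about a second), and compare solver
results against independent oracles: ordered-allele enumeration for
genotype probabilities, explicit per-genotype loops for the population
parameters, bisection on those loops for roots, and a $200 \times 200$
log-spaced grid for maximality. The acceptance script scans additive orders
ascending until failure, capped at order 12 ($3^{12} = 531441$ genotypes)
to keep the full run around a minute.

## Limitations

* The method is strictly bivariate; models with more than two variables or
  per-locus effect variables are rejected at parse time.
* Only one parameter can be prescribed; prescribing both prevalence and
  heritability simultaneously is exactly the incompatible-system trap the
  maximization approach exists to avoid, and is deliberately unsupported.
* Population samples are not generated — write the table with
  `write_gametes()` and hand it to a dedicated simulator.
* The GAMETES writer targets the 2.x plain-text attribute-model layout with
  `#`-prefixed annotation lines; all formatting is isolated in one writer
  so a dialect adjustment is a one-function change. Byte-level layouts of
  specific GAMETES releases should be verified by users who depend on
  them.
* Arithmetic is double precision; targets extremely close to 0 or 1 may
  need a tighter `residual_tol` judgment than the default, and exact
  rational probability bookkeeping switches itself off (with a flag) in
  the rare regimes where the integers would exceed $2^{53}$.
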