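---
title: "Target-space overlap analysis: model, filters, and null calibration"
author: "tomspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-space overlap analysis: model, filters, and null calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomspace)
```

## The question the method answers

Traditional oriental medicine (TOM) formulas are fixed combinations of
herbs, each herb contributing tens of chemical compounds, each compound
hitting many protein targets. Small-molecule drugs for the same indication
hit their own target sets — and routinely cause side effects that are in
turn treated with further drugs. The method implemented here asks a
set-level question: how much of the pooled target space of the drugs
treating a disease (and of the drugs treating those drugs' side effects) is
covered by the target space of a single herbal formula nominally used for
that disease?

Everything reduces to set algebra over gene symbols, so the package's
central object is the `TargetSpace`: a deduplicated, normalized
(whitespace-stripped, uppercased) set of gene symbols with provenance tags
recording which filters produced it.

## The support statistic

For a drug module with pooled target space $X$ and a formula with target
space $Y$, the overlap score is the *support*

$$\mathrm{Support}(X \to Y) \;=\; \frac{|X \cap Y|}{|X|},$$

the fraction of the drug module's targets that the formula also hits. The
drug space is always the denominator; it must be non-empty, and `support()`
treats an empty one as an error rather than returning `NaN`. The statistic
is a descriptive coverage ratio in $[0,1]$, not a significance test —
calibration against chance is delegated to the resampling null below.

## Weighted aggregation across modules

One analysis compares a formula against a *main-indication* module (drugs
treating the disease the formula is used for) and $m$ *side-effect* modules
(drugs treating the side effects of the main module's drugs). The overall
score is the convex combination

$$W = \sum_i w_i X_i, \qquad \sum_i w_i = 1,$$

with the main-indication support given weight $w_\text{main} = 0.5$ and the
remaining $0.5$ split equally across the $m$ side-effect supports. The
default of 50% encodes the judgement that treating the intended indication
matters as much as all side-effect coverage combined; `mainWeight` is a
parameter of `weightedAverage()` for users who weigh differently. With
$w_\text{main} = 1/(m+1)$ the score reduces to the plain mean; with no side
modules it equals the main support.

### Rounding at report time

Supports are held at full floating precision everywhere; rounding to two
decimals happens only when `report.tsv` is written. The convention is *half
away from zero*. The choice is deliberate: reference support tables in this
field print ties like $0.605 \to 0.61$ and $0.725 \to 0.73$, which
round-half-even would print as $0.60$ and $0.72$. Because values such as
$0.605$ are not exactly representable in binary floating point (they sit a
hair *below* the tie), the implementation adds a $10^{-9}$ guard before
truncating: `floor(x * 100 + 0.5 + 1e-9) / 100`. The guard is far larger
than accumulated arithmetic error ($\sim 10^{-13}$ at this scale) and far
smaller than any honest sub-tie difference, so it only rescues exact
decimal ties.

## ADMET triage of herbal ingredients

Before a formula's space is built, its compounds pass three independent
exclusion rules based on categorical ADMET predictions:

| rule | trigger value(s) | default |
|---|---|---|
| AMES mutagenicity | `toxic` | on |
| carcinogenicity | `danger` | on |
| hERG channel inhibition | `inhibitor`, `strong inhibitor` | on |

Both hERG tiers are risk tiers; `weak inhibitor` is folded into the
non-risk class at load time. Exclusion operates at the *compound* level: an
herb contributes whatever non-toxic compounds it retains. Every rule a
compound triggers is recorded in the exclusion log, not just the first, so
the audit trail (`exclusions.tsv`) explains each removal completely.

Compounds with no annotation row are kept by default (`unknownPolicy =
"keep"`): the rules act on positive toxicity predictions, and a missing
prediction is not evidence of toxicity. This is a genuine design choice —
upstream prediction services simply lack some structures — and the
conservative alternative (`"drop"`) is one argument away.

## CYP exclusion

Cytochrome P450 isozymes appear constantly in compound-target data because
they metabolize xenobiotics, not because they mediate therapeutic effect,
so they are excluded from target spaces. The matching rule is the symbol
pattern `CYP` followed by a digit (`CYP3A4`, `CYP2D6`, ...). A bare `CYP`
prefix is deliberately insufficient — it would wrongly catch tokens that
merely begin with those letters — and UGT-family symbols, which also appear
in metabolic contexts, are retained.

Exclusion is applied *symmetrically* to formula and module spaces. The
alternative — excluding CYPs only from the overlap count while leaving them
in the drug-space denominator — would deflate every support by a constant
factor and make supports incomparable across modules with different CYP
content. Whether the original analyses excluded CYPs from the denominator
is not documented; the symmetric choice is recorded in
`run-metadata.json` of every run so downstream readers see it. A validity
check on `TargetSpace` guarantees that no object tagged `cyp_excluded` can
ever hold a CYP symbol.

## The resampling null

An observed support is calibrated by re-running the identical computation
with the drug space replaced by random ones: `sampleNull()` draws
`nDraws` (default 1000) independent sets of $k$ distinct genes, uniformly
without replacement within a draw, from a gene universe (default: the union
of all genes in the drug-target table; a curated universe file can override
it), and records $|R \cap Y|/k$ for each. $k$ is matched to the cardinality
of the observed drug module, mirroring the published construction of 1000
random 84-gene spaces from a ~3000-gene drug-target universe.

Because the draw is uniform without replacement, the overlap count is
exactly hypergeometric, giving the closed-form check implemented in
`hypergeometricMoments()`:

$$E[S] = \frac{m}{N}, \qquad
  \mathrm{Var}[S] = \frac{k \,\frac{m}{N}\!\left(1-\frac{m}{N}\right)
  \frac{N-k}{N-1}}{k^2},$$

with $N$ the universe size and $m$ the number of universe genes inside the
formula space. The test suite verifies the sampler against this closed form
(mean within three standard errors at 1000 draws; variance within 20% at
$10^4$ draws) and verifies the closed form itself against exhaustive
enumeration of all $\binom{N}{k}$ draws at tiny $N$.

Two reporting conventions are fixed and recorded in the run metadata:

* **variance** is the population variance of the draws (divide by
  `nDraws`), matching "the variance of the 1000 support values" read
  literally;
* **empirical p** is the add-one upper tail,
  $p = (1 + \#\{S_i \ge s_\text{obs}\})/(n+1)$, never exactly zero, so an
  observation above every draw reports $1/(n+1)$.

Draws are reproducible from an integer seed (Mersenne-Twister); the
sampler saves and restores the global RNG state, so calling it never
perturbs an enclosing simulation. The pipeline derives per-formula seeds as
`seed`, `seed + 1`, ... in formula order, which makes whole reports
byte-identical across reruns.

## The synthetic-data generator

`generateDataset()` exists so that every pipeline stage is testable without
any external database. It emulates the *structure* of curated data:

* a universe of `universeSize = 3000` synthetic symbols, a fraction
  `cypFraction = 0.05` of them CYP-styled so the exclusion path is
  exercised;
* drug modules whose spaces are **mutually disjoint** subsets of the
  universe — disjointness is what makes planted overlaps exact rather than
  probabilistic;
* per formula, a target space containing exactly `plantedOverlaps[i]` genes
  of module $i$'s space plus filler genes outside every module space, so
  the expected raw support is exactly
  $\text{plantedOverlaps}[i]/\text{moduleSizes}[i]$;
* herb/compound scaffolding (4–14 herbs per formula, 6–50 compounds per
  herb, spanning the range seen in curated four-herb to fourteen-herb
  formulas) over which the formula's genes are distributed, each gene
  carried by `redundancy` compounds (default 1, so excluding a compound
  removes its genes predictably; higher values model the many-compounds-
  per-target redundancy of real data);
* ADMET annotations flagging an exact `toxicFraction = 0.1` of compounds,
  rotating through the three rule triggers;
* a drug-target table with roughly 38 drugs and a ~5% duplicate-edge excess
  per 84-gene module, so association counts exceed distinct-target counts
  as they do in curated modules.

The defaults above are the package's standing study conditions; they mirror
the scale of the published analysis this design follows (a main module of
84 genes, a ~3000-gene universe) and are not tuned per run. The
`truth.json` ledger records, for every (formula, module) pair, the planted
overlap and the exact expected support under each filter combination (none
/ CYP / ADMET / both), computed by direct set algebra over the generated
structures — an oracle the end-to-end tests compare against with zero
tolerance.

What the generator does **not** emulate: real gene-family structure beyond
CYP naming, chemical identity (no SMILES), correlated targets between
modules (module spaces are disjoint, real ones overlap), herb-level
pharmacology, and databases' annotation noise. Passing the synthetic tests
therefore demonstrates algorithmic correctness — exact set algebra,
filtering, weighting, calibration — not that any real formula works.

## Degenerate inputs and edge policies

* A formula with no herbs is an error; a formula whose compounds are all
  filtered away yields an **empty space with a warning**, so batch runs
  complete and report support 0.
* An empty drug-module space is an error everywhere (undefined
  denominator).
* Duplicate association rows are collapsed silently but counted;
  both the edge count and the distinct-target count remain reportable.
* Side-effect module order follows the module file's first-appearance
  order, fixing the report row order deterministically.
* Gene identifiers are treated as opaque normalized tokens; no attempt is
  made to map synonyms or orthologs. If two inputs spell one gene two
  ways beyond case/whitespace, they count as two genes.

## Problem sizes in the shipped tests

The test suite runs the full stack at deliberately small scale — universes
of 400–600 genes, two to three formulas, modules of 20–90 genes, nulls of
100–1000 draws, plus one $10^4$-draw calibration at the published
$N = 3000$, $k = 84$ geometry — sizes chosen so the whole suite completes
in seconds while still covering every code path and the exact-recovery
guarantees. Nothing in the method is size-limited; production runs at
database scale differ only in wall time.

## Limitations

Support measures *coverage*, not affinity, direction, or dose: a formula
touching a target weakly counts the same as a drug inhibiting it strongly.
The statistic also inherits every bias of the input curation — promiscuous,
well-studied targets inflate overlaps, and the null universe choice shifts
the baseline ($m/N$) directly. The weighted average compresses a vector of
module supports to one number and discards which side effects are covered.
These are properties of the method itself, faithfully implemented; the
package surfaces the ingredients (overlap gene lists, per-module supports,
null summaries, exclusion logs) so users can look past the headline score.
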