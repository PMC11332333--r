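---
title: "Marker-anchored phylogenetic profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-anchored phylogenetic profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaPhyloProfile)
```

# The method

Phylogenetic profiling infers functional links between genes from
correlated presence/absence patterns across genomes. Here the anchor is a
noncoding RNA marker — the motivating system is the OLE RNA class of
Bacillota, a ~600-nt structured RNA confined to distinct clades scattered
through the phylum — and the question is which protein families co-occur
with it (candidate pathway partners) and which avoid it (candidate
alternative solutions to the same physiological problem, the way a second
magnesium transporter might substitute for an RNA-regulated one).

The unit of observation is the genome assembly. Every assembly is reduced
to one binary marker indicator X and, per protein family, one binary
presence indicator Y; the analysis is the joint distribution of (X, Y)
over assemblies.

## RNA hit classification

Covariance-model searches report, per hit, a bit score (a log₂ odds of
model versus null) and a truncation flag saying whether the alignment was
clipped at a sequence end. Classification uses only these two values:

| condition | category |
|---|---|
| nontruncated, S ≥ 390 | full_length |
| nontruncated, 310 ≤ S < 390 | variant1 |
| nontruncated, 235 ≤ S < 310 | variant2 |
| truncated, S ≥ 235 | variant2 |
| otherwise | unclassified |

Lower bounds are inclusive and upper bounds exclusive, following the
"at least" / "less than" convention the cutoffs were defined with. The
cutoffs were chosen from the bit-score histogram of a large search
(`scoreHistogram()` reproduces that binning with half-open bins
`[edge, edge + width)`); they are parameters of `rnaThresholds()`, not
constants, but the defaults are the study values and there is no reason
to move them.

One consequence deserves emphasis because it is surprising: **a truncated
hit is variant 2 no matter how high it scores**, even above the
full-length cutoff. A clipped alignment cannot show that a full-length
element is present, so the rule routes all truncated hits ≥ 235 bits to
variant 2; there is deliberately no carve-out.

Assemblies with several hits get the status of the best classified hit
(highest bit score, ties broken by category precedence full_length >
variant1 > variant2, then by target sequence id). The multi-hit rule is
this package's choice — per-assembly resolution has to be defined
somewhere, and best-hit with deterministic tie-breaks is the least
surprising option. Hits below 235 bits are "unclassified" and count as no
marker evidence; they never cause an exclusion.

## Cohorts and the analysis universe

The marker-positive cohort is the full-length carriers; the
marker-negative cohort is assemblies with no classified hit at all.
Variant carriers are excluded from *both* cohorts everywhere downstream
(fractions, mutual information, paralog distributions): they carry the
gene but not its full-length form, so they would blur either cohort they
joined. Assemblies outside the allowed phylum are excluded as
`outside_taxon` — isolated marker hits in distant phyla are more likely
assembly contamination or taxonomy error than biology.

The denominator question — which marker-negative assemblies count — is
genuinely open. The default (`universeMode = "pruned_subtree"`) restricts
the universe to the smallest clade of the species tree containing all
marker-positive assemblies (`mrcaSubtree()`), i.e. the part of the tree
where the marker demonstrably occurs; `"whole_phylum"` uses every
allowed-phylum assembly instead. Both are exposed because the choice
changes cohort sizes, and the pruned-subtree default reproduces the
strong positive ≪ negative asymmetry characteristic of this design.
`mrcaSubtree()` needs at least two marked tips: the clade spanned by a
single tip is just that tip, which is not representable as a tree.

## Protein families

Three constructions, one container (`ProteinFamily`, a set of unique
(assembly, protein) pairs):

* **Reference-query families**: all homology hits of one query at
  e-value ≤ 10⁻¹⁰ (inclusive, matching the search tools' own `--evalue`
  semantics). Families are *not* merged when two queries share hits —
  one query, one family — because merging would change the point count of
  every per-family plot downstream.
* **Cluster families**: clusters from a membership map with ≥ 5 member
  proteins; smaller clusters are discarded and counted.
* **HMM families**: per-target hits of one profile HMM at a per-model
  inclusive bit cutoff. Choosing that cutoff is a judgment call made from
  the score histogram and genomic context; the package supplies
  `scoreHistogram()` and takes the chosen number as input rather than
  pretending to automate the judgment.

Presence for profiling is member count ≥ 1; the same count matrix serves
the paralog analyses (`countParalogs()`, no cap — real families reach
eight copies in one genome), so there is a single source of truth.

## Mutual information

For cell counts n_xy (X = marker, Y = family), p_xy = n_xy/N and
marginals p(x), p(y):

$$I(X;Y) = \sum_{x,y\in\{0,1\}} p_{x,y}\,
\log_2\frac{p_{x,y}}{p(x)\,p(y)}$$

evaluated as the expanded four-term sum, log base 2, so results are in
bits and bounded by min(H(X), H(Y)) ≤ 1.

Empty cells are the crux. Two conventions are implemented:

* `zeroMode = "discard"` (default, the literal study rule): if any
  term's logarithm operand is zero or undefined, the family's MI is
  discarded (`NA`). Note what this silences: a *perfectly* associated
  table has two empty cells, so exactly the strongest signals come back
  `NA`. Discarded families are kept in the output, flagged, never
  dropped, so fraction-based plots remain complete and the strongest
  associations remain visible through their fraction gap.
* `zeroMode = "limit"`: the information-theoretic limit 0·log 0 = 0;
  perfect association scores 1 bit, degenerate marginals score 0.

The discard sentence could also be read per-term (drop only the
offending terms); that reading is numerically identical to `"limit"`, so
both readings are available and the package does not claim to know which
was intended. Rankings sort by MI descending with deterministic
tie-breaks (|f₊ − f₋| descending, then family id), undefined-MI families
at the tail.

Numerical choices: the four-term sum can land a few ulp below zero on
exactly independent tables; since I ≥ 0 always, values in (−10⁻⁹, 0) are
snapped to 0. The implementation is verified against the independent
entropy decomposition H(X) + H(Y) − H(X,Y) to 10⁻¹² on seeded random
tables. The mass-shifting monotonicity property (moving a unit from the
discordant to the concordant diagonal, marginals fixed, does not decrease
I) holds from independence onward, i.e. for tables with
n₀₀·n₁₁ ≥ n₀₁·n₁₀; starting from an anticorrelated table the same move
heads *toward* independence and I correctly falls.

# The synthetic-data generator

`simSpec()` → `simulateCohort()` → `plantFamilies()` → `emitFixtures()`
generates a complete mock study: a random bifurcating tree whose
marker-positive tips form a configurable number of monophyletic clades
(≥ 2, grafted so the marker spans the root of the simulated phylum — a
marker confined to a single clade would collapse the pruned universe onto
that clade and leave no negative cohort); decoy variant carriers and
wrong-phylum carriers so both exclusion paths are always exercised;
families whose presence is drawn independently per assembly with
cohort-conditional probabilities; and per-assembly copy numbers
1 + Poisson(paralog_mean), so presence always implies ≥ 1 member and
`paralog_mean = 0` means exactly one copy.

`emitFixtures()` writes the whole input set in the real tool formats —
covariance-model tblout (scores sampled inside each status's score
interval, truncation flags on alternating variant-2 carriers,
sub-threshold noise hits on a few negatives, a secondary lower-scoring
hit on one positive to exercise best-hit resolution), the 12-column
protein hit table (including duplicate local alignments, one hit exactly
on the inclusive 10⁻¹⁰ cutoff, and per-family decoy hits that fail it), a
per-target HMM table with members above and decoys below the recorded
cutoff, a cluster TSV with one deliberately undersized cluster, newick
tree, taxonomy and id maps — plus the ground truth. All randomness flows
from the single spec seed; emission itself is deterministic, so
re-emitting is byte-identical.

What the simulator does *not* model, and what passing tests therefore do
not show about real data: no sequence evolution (presence is drawn
i.i.d. given cohort, so there is no phylogenetic autocorrelation within
cohorts, while real gene presence is tree-correlated); no horizontal
gene transfer; no assembly incompleteness (real "absence" can be a
sequencing gap); no annotation noise in the id maps. The statistical
recovery tests show the estimator and ranking machinery work under the
assumed two-cohort Bernoulli structure — not that the biological nulls of
a real phylum behave like independent coin flips.

# Problem sizes and determinism

The test suite and acceptance script run entirely on simulated data at
sizes chosen to exercise every code path while keeping a full run in
well under a minute: boundary tables exactly as enumerated; 1,000 random
2×2 tables for the MI oracle; 300 + 300 assemblies with 200 null and 6
planted families for signal recovery (effect sizes 0.9/0.1, the regime
the design targets); 20 seeds of a 20-assembly study with decoys for
end-to-end identity; 500 random trees of 4–12 tips against a brute-force
MRCA oracle. The pipeline writes floating-point output at 6 significant
digits while keeping full precision internally, and identical inputs
reproduce reports byte for byte.

# Known limitations

* Per-assembly status resolution and ranking tie-breaks are this
  package's conventions; a study resolving multi-hit assemblies
  differently would need `assignAssemblyStatus()` adapted.
* MI is reported without p-values or multiple-testing control; with
  thousands of families, the top of the null distribution can reach
  non-trivial MI at small cohort sizes (visible in the worked example,
  where n = 16 assemblies).
* Profiling is not phylogenetically corrected: clade-structured presence
  inflates apparent association relative to a tree-aware co-evolution
  model. The tree is used to fix the universe, not to model the
  correlation structure.
* The parsers cover the per-target tabular dialects only, not alignment
  detail formats (Stockholm, domain tables), and do no format
  auto-detection.
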