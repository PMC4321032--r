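---
title: "Methods: GBS linkage mapping, QTL scanning and synteny anchoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GBS linkage mapping, QTL scanning and synteny anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavemapr)
```

`cavemapr` implements the desk analysis of a genotyping-by-sequencing (GBS)
F2 intercross between two divergent morphotypes — the motivating system is
the Mexican tetra, with cave-dwelling and surface-dwelling forms crossed to
map cave-associated traits such as *Oca2*-linked albinism. The pipeline runs
from raw IUPAC genotype calls to a de-novo linkage map, a binary-trait QTL
scan, cross-species synteny assignment from tabular BLAST-style hits, and
the anchoring of unplaced genome scaffolds onto linkage groups. Because raw
GBS data for such studies are large and external, the package ships a
seeded generator that reproduces the statistical structure every stage
assumes, so the whole pipeline is testable end to end on synthetic data.

## The cross and the marker model

Each marker is a single SNP embedded in a 64-bp GBS tag. The founder panels
(four surface, four cave individuals) are expected to be fixed for
alternate alleles; F1 hybrids are heterozygous; F2 individuals segregate
1:2:1 at a codominant marker. Calls use IUPAC codes: a homozygote is its
nucleotide, a heterozygote is the two-allele ambiguity code (M, R, W, S, Y
or K), and missing data is `NA`.

### Marker screening (`screen_markers()`)

Screening applies the selection rules in a fixed order:

1. **Parental consensus.** A founder allele is assigned when at least three
   of the four panel individuals share a nucleotide (`ceiling(3n/4)` for
   other panel sizes; heterozygote codes never form a consensus). Markers
   where the allele pair cannot be assigned — both parents `NA`, a single
   assignable parent, or identical parental alleles — are unsuitable. We
   fold the one-parent case into the "no parent" category: without both
   alleles the F2 cohort cannot be coded.
2. **Informativeness.** Markers whose scored F2 individuals all share one
   genotype class are discarded.
3. **Segregation distortion.** The Pearson chi-square against 1:2:1
   (2 df) is compared with a cutoff of 50; larger values are discarded.
   Missing F2 calls are excluded from the chi-square total — the
   convention is unstated in such studies, and excluding them keeps the
   statistic well defined under missingness.

F1 confirmation (three of four F1s sharing the expected heterozygote code)
is advisory: the flag is reported, and `require_f1 = TRUE` upgrades it to a
discard. Only the three rules above are applied by default because they are
the stated discard rules of the protocol being reproduced.

The `QcReport` is a telescoping chain (each stage equals the previous
minus its removals), and `qc_report()` exposes the same arithmetic for
externally supplied stage counts.

## Two-point linkage and the Kosambi map function

Distances use the Kosambi map function,
$d = 25\,\ln\frac{1+2r}{1-2r}$ cM, with inverse
$r = \tfrac12\tanh(d/50)$, which accommodates moderate crossover
interference and is the function used by the emulated protocol.

The recombination fraction for a marker pair is the maximum-likelihood
estimate for an F2 intercross with codominant markers, computed by EM over
the 9-cell joint genotype table. Every cell carries a known number of
recombinant gametes except the double heterozygote, which mixes the two
phase classes; its E-step weight is $r^2/(r^2+(1-r)^2)$. EM starts at
$r_0 = 0.25$ and stops at $|\Delta r| < 10^{-8}$ or 200 iterations; the
estimate is clamped to $[0, 0.5]$. Two LOD scores are attached:

* the **linkage LOD**, $\log_{10} L(\hat r) - \log_{10} L(0.5)$, used as a
  weight during ordering; and
* the **independence LOD**, the G-squared statistic of the 3×3
  independence test divided by $2\ln 10$, used for grouping. The protocol
  we reproduce names this statistic without defining it (it is internal to
  the commercial mapping software); the G-squared form is the natural
  contingency-table statistic and, unlike the linkage LOD, is robust to
  segregation distortion.

The full pairwise scan is vectorised: the nine count matrices come from
nine cross-products of indicator matrices, and the EM loop runs
elementwise over all pairs at once, so roughly half a million pairs cost a
few seconds.

## Grouping, ordering, and the mapping protocol

**Grouping** is single-linkage clustering: markers are connected when a
path of pairs meets the independence-LOD threshold. `grouping_ladder()`
exposes the partition at every integer threshold up to the configured
maximum (default 50). When no threshold is given, `build_map()` sweeps the
ladder and picks the threshold opening the *longest stable plateau* of the
count of groups with at least `min_size` markers. The rationale: chance
linkage bridges dissolve just above the noise floor of the independence
LOD, while real chromosomes only fragment at much higher thresholds, so
the chromosome-level partition persists across a wide band of thresholds.
(The original protocol chose thresholds by eye, guided by the karyotype
number; the plateau rule is our deterministic surrogate.)

**Ordering** within a group is incremental insertion: seed with the
highest-LOD pair, then repeatedly insert the unplaced marker with the
strongest linkage to the current order at the position minimising the
weighted least-squares criterion
$\sum_{ij} w_{ij}\,(d_{ij}(\text{order}) - d^{K}_{ij})^2$, where
$d^{K}_{ij}$ is the Kosambi distance of the pairwise estimate,
$w_{ij}$ the linkage LOD, and $d_{ij}(\text{order})$ comes from cumulative
adjacent distances. Each insertion triggers a local width-3 permutation
polish around the insertion point; the completed order gets full polish
passes until no window improves. Orientation of a group is arbitrary, so
orders are canonicalised with the lexicographically smaller terminal
marker first; ties anywhere break deterministically by marker id.

**Final positions** are re-fitted by non-negative weighted least squares
on the inter-marker gaps, over pairs with $\hat r < 0.2$. This cutoff is a
measured compromise between two opposite biases. Adjacent-pair cumulative
distances overestimate length (estimation noise passes through the convex
Kosambi transform; about +20% at the default design), while pairs spanning
many intervals underestimate it, because two-point Kosambi distances are
sub-additive over multi-interval spans when meioses are simulated with
independent intervals — which is exactly the generator's model, chosen so
that per-interval mapping with the Kosambi function is self-consistent.
Fitting over pairs up to $\hat r < 0.4$ shrank group lengths by roughly a
quarter on the default design; restricting to $\hat r < 0.2$ keeps enough
pairs for noise averaging while limiting the span bias to a few percent.

**The round-based protocol** (`build_map()`, default 3 rounds) mirrors the
published workflow: drop groups that are too small (`min_size`, default
10 markers) or too sparse (mean intermarker distance above 4 cM); split
suspiciously large groups at the lowest ladder threshold that separates
them into exactly two components of at least `split_min` markers (20 in
round one, 10 in round two); trim terminal markers whose distal gap
exceeds `max(10 cM, 3 × mean spacing)`; re-order and repeat. Splitting is
attempted only on groups at least 1.5× the median group size: an
unrestricted rule would dismember genuine chromosomes, since almost any
linkage chain separates cleanly at *some* threshold, whereas fused
chromosomes show up specifically as outlier-large groups. Every
elimination is logged in an audit table so that placed + eliminated =
input markers always holds.

## Binary-trait QTL scanning

Genotype probabilities along the map come from the standard
forward–backward algorithm on the three-state chain {SS, SC, CC} with
prior (¼, ½, ¼), transitions from the Kosambi inverse of inter-position
distances, and an emission error ε (default 0.001): the observed class has
probability 1−ε, the others ε/2, and missing calls emit uniformly.
Evaluation positions are the typed markers plus a pseudomarker grid
(default 1 cM).

The 0/1 phenotype is scanned under a Gaussian working model, the default
treatment of a binary-coded trait in the standard QTL software this
reproduces; it recovers the double-digit LOD scale expected for a fully
penetrant Mendelian trait, and a logistic variant is deliberately out of
scope. Three methods are provided: marker regression (typed markers only,
missing individuals dropped), Haley–Knott regression on the class
probabilities, and EM interval mapping with a three-component Gaussian
mixture. At positions where every genotype is certain the EM scan
short-circuits to the Haley–Knott computation, which is the same model
there.

Two numerical floors keep the working likelihood finite where a fully
penetrant trait separates the classes perfectly: residual variance in the
regression LODs is floored at $10^{-4}$ (so marker regression and
Haley–Knott stay exactly equal at complete-data markers), and the EM
mixture's common σ is floored at $10^{-2}$. Perfect-separation LOD scores
are therefore large but finite and mutually consistent.

Permutation thresholds shuffle phenotype labels and take empirical
quantiles of the genome-wide maximum LOD. For the regression methods the
permuted scans are computed in batch — RSS for all permutations at a
position is one projection onto the position's orthonormal design basis —
so 1000 permutations cost a few matrix products. EM permutations are
refit one by one and are correspondingly slower; since the null maximum-
LOD distributions of the three methods coincide for a 0/1 trait under the
Gaussian working model, thresholds are computed with Haley–Knott by
default and applied to all methods (standard practice with the emulated
software).

## Synteny assignment from tabular hits

Hits arrive as standard 12-column tabular alignments for three routes: the
64-bp tag aligned directly to the target genome, a ~2-kb genomic flank
(`extract_flank()` centres the tag in a window clipped at scaffold ends),
and the transcript carrying the tag. Rows above the e-value cutoff
(default 10) are dropped at parse time.

Resolution is two-tier and deliberately order-independent:

1. collapse to one alignment per (marker, target) pair — lowest e-value,
   ties broken by identity, then alignment length, then target position
   (the tail of that chain is our addition, for determinism);
2. build per-linkage-group **support sets** from markers with a single
   surviving hit;
3. resolve each multi-hit marker: the top hit (lowest e-value, identity
   breaking ties) is retained if supported; otherwise a supported non-top
   hit is retained instead; otherwise the top hit is retained without
   support; if no top hit can be determined and nothing is supported, the
   marker is unresolved and discarded.

"Support" means target identity only (the same chromosome), not positional
proximity — matching the wording of the protocol being reproduced. Support
sets are built once from single-hit markers and not propagated
iteratively, which keeps resolution independent of processing order.
`combine_routes()` treats the per-route retained hits as a fresh candidate
set and re-applies the same resolution; exact ties across routes break by
route priority genomic > transcriptomic > direct, reflecting the routes'
observed information content. Any surviving single hit counts as "robust";
a stricter e-value knob is available but off by default, since the source
protocol quantifies robustness only through the search cutoff.

`synteny_stats()` reports per-chromosome link counts and links/Mb, flags
linkage groups harbouring five or more links with a chromosome, compares
links/Mb between chromosomes with and without a ≥10-link single-group
concentration using the pooled-variance two-sample t test (the published
comparison reports pooled degrees of freedom), and emits the Oxford count
matrix and a Circos-format link file.

## Scaffold anchoring

`anchor_scaffolds()` assigns each scaffold the modal linkage group of its
mapped markers (a tie makes it ambiguous and non-colocalized), and
measures colinearity as the tie-adjusted Kendall τ between scaffold bp and
map cM, whose sign gives the orientation. The headline colocalization
percentage counts scaffolds with at least two mapped markers in the
denominator: singletons are trivially colocalized and would inflate the
statistic, and the published 87.3% value does not state its denominator,
so both variants are reported. Anchoring figures follow the convention of
showing only scaffolds with four or more mapped markers.

`map_summary()` reports both candidate definitions of the map-wide mean
intermarker distance — total length over (markers − groups), and the mean
of per-group means — because the published map-wide value (1.052 cM)
matches neither exactly and no reconciliation is attempted.

## The synthetic-data generator

`simulate_cross()` emulates the study design: 25 chromosomes (the
karyotype number), 170 F2 individuals, founder and F1 panels of four, and
a fully penetrant recessive trait locus on chromosome 13 (albinism's
linkage group in the motivating system). Values the study does not state
were fixed once at field-realistic levels:

* `chrom_length_cM = 84` — 25 × 84 = 2100 cM, matching the ~2110-cM
  genome-wide map;
* `markers_per_chromosome = 40` (evenly tiled), giving a ~1000-marker
  panel at ~2.15-cM spacing;
* `error_rate = 0.005` and `missing_rate = 0.02`, typical of filtered GBS
  genotype matrices;
* artifact fractions 5% parent-unassignable, 2% monomorphic, 5% distorted
  with selection coefficient 0.6 against the cave homozygote — present but
  minor, since the headline raw-data discard rates of a real GBS run are
  dominated by sequencing pathologies that are out of scope here;
* physical scale 500 kb/cM with 4-Mb scaffold tiles (teleost genomes are
  ~1.2–1.7 Gb over ~2100–2700 cM), giving ≈3.8 markers per scaffold at
  default density, near the published 3.50; each scaffold gets a random
  planted orientation so anchoring can be tested against ground truth.

Meioses are simulated as Markov chains with independent intervals whose
per-interval recombination probability is the Kosambi inverse of the true
gap. This makes mapping with the Kosambi function self-consistent at the
interval level (the protocol maps with Kosambi and specifies no
interference model) — but note the multi-interval sub-additivity it
induces, discussed under ordering. Genotyping error is a symmetric swap to
a uniformly chosen other genotype class; missingness is applied after
error, independently. Artifacts are planted on disjoint marker sets and
recorded in the ground truth. The same seed yields bit-identical output;
all pipeline randomness derives from one seed through fixed per-stage
substreams, and nothing reads the wall clock.

`simulate_hit_tables()` emits the three alignment routes against a
fictitious 25-chromosome target with a known true correspondence: a
conserved fraction of markers get a true-target hit (always the lowest
e-value), decoys add one or two paralog hits on other chromosomes at
higher e-values, and no query exceeds three targets.

What the generator does **not** emulate: read-level sequencing,
restriction-site biology, quality scores, linked (haplotype-block)
distortion, population structure in the founders, or genuinely ambiguous
paralogous tags. Passing tests therefore demonstrate the correctness of
the algorithms under the stated statistical model, not robustness to every
pathology of real GBS data.

## Problem sizes and known limitations

The test suite and the acceptance script run the full default design
(25 × 40 markers, n = 170) for map recovery; QTL power uses 100 replicate
crosses on a 5-chromosome genome with 1000-permutation thresholds; filter
calibration uses 10,000 simulated null markers; the EM estimator is
cross-checked against a 10⁻⁴-step likelihood grid on 1000 random tables.
These sizes keep a complete run in the tens of seconds to a few minutes
while leaving Monte-Carlo error well inside the asserted margins.

Known limitations: recovered map length runs a few percent short of the
simulated truth (QC and trimming remove some terminal markers, and
residual two-point sub-additivity remains); EM interval-mapping LOD
scores for a perfectly separating trait are floor-dependent and should be
read as "very large" rather than as calibrated likelihoods; ordering is a
heuristic (insertion + local polish) and is not guaranteed to find the
global optimum for poorly informative groups; and the resolution of
multi-hit markers inherits whatever biases the hit tables carry — decoys
with better e-values than the true target on an unsupported group are
retained, exactly as in the protocol being reproduced.
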