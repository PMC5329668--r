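---
title: "Epitope-based HLA matching from serological typings: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope-based HLA matching from serological typings: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(epimatch)
```

## The matching problem

Eplet mismatch counts (HLAMatchmaker) and PIRCHE-II counts both require
two-field HLA genotypes at the five classical loci A, B, C, DRB1 and
DQB1, because the scores are defined on protein sequences and
sequence-derived annotations. Serological split-level typing — the
resolution routinely available for deceased donors — identifies only an
antigen, i.e. a set of alleles. `epimatch` treats the unknown
high-resolution genotype as a latent variable and integrates the
epitope score over it, with a population haplotype-frequency table as
the prior.

## Genotype imputation

### Candidate enumeration

For a phenotype (per-locus sets of one or two typing values, serotypes
or alleles, with loci possibly absent), `enumerate_candidates()` builds
all unordered pairs of five-locus allele vectors that *reproduce the
phenotype exactly*: at every covered locus each phenotype value is
carried by at least one of the two haplotypes and neither haplotype
projects outside the phenotype's values. Loci absent from the input are
unconstrained and get filled in by the imputation — this is how
locus-omission inputs are handled. A single value at a locus is read as
homozygosity at the typed resolution (the serological convention); the
`single_as_unknown` flag provides the "second value unknown" reading
instead.

The frequency of a candidate pair is the product of its two haplotype
frequencies, literally, with no Hardy–Weinberg factor of 2 for
heterozygous pairs. The factor would change the *relative* weights of
homozygous versus heterozygous candidates, so the default is the plain
product; `hw_factor = TRUE` applies the factor for users who want the
Hardy–Weinberg sampling model.

### Step-wise linkage breakdown

When the full-haplotype scheme yields no candidate — the typing's
antigen combination does not co-occur on any table haplotype — the
linkage between loci is relaxed in a fixed order of schemes:

1. A-B-C-DRB1-DQB1
2. A-B-C | DRB1-DQB1
3. A | B-C | DRB1-DQB1
4. A | B-C | DRB1 | DQB1
5. A | B | C | DRB1 | DQB1

Under a broken scheme each chromosome is assembled from independent
blocks; a block's marginal frequency is the sum of table frequencies
over all haplotypes agreeing with it at the block's loci, and a
chromosome's frequency is the product of its blocks' marginals. All
cross-block phase assignments are enumerated (they are distinct
chromosome pairs, deduplicated on the unordered genotype). Under scheme
5 the construction reduces to per-locus allele frequencies, and the
package asserts this equivalence in its tests. The fallback is global:
one scheme per imputation call, the first scheme with a nonempty
candidate set wins. A per-haplotype mixture of schemes (one side tight,
one relaxed) is a conceivable alternative reading of "subsets" of a
typing; we implement and document the global reading, which is the
simplest one consistent with an ordered scheme list.

If even scheme 5 produces nothing — some input antigen maps to no
allele present anywhere in the table — the typing is *unimputable*. This
is a typed result, counted and excluded downstream, never a silent
default: with real, truncated frequency tables a small percentage of
couples cannot be estimated, and the package reports that fraction.

Candidate enumeration is combinatorial under scheme 5 on rich tables, so
a hard cap (`max_candidates`, default 10^6 pairs) aborts enumeration
with an explicit error rather than exhausting memory.

### Weighting

Absolute candidate frequencies are normalized to weights summing to 1
within the candidate set. For a donor-recipient couple both sides are
imputed independently and the engine score is computed on every
(donor candidate × recipient candidate) pair of full five-locus
genotypes; the reported value is the doubly-weighted sum. This is
multiple imputation rather than best-guess imputation: rare but
compatible genotypes contribute according to their likelihood instead of
being discarded in favor of the single most frequent one. For an
in-table two-field input the candidate set collapses to the true
genotype with weight exactly 1, so the observed value equals the
reference score exactly — the mechanism behind the improvement seen when
recipients are typed at two-field resolution.

## Epitope engines

**Eplets.** A mismatched eplet is present on at least one donor HLA
molecule and absent from all recipient HLA molecules. Comparison is
interlocus: annotations of all ten alleles on each side are pooled, so
an eplet carried by the recipient at any locus neutralizes it
everywhere. A `per_class` option restricts pooling to within class I and
class II separately, a variant found in practice. Eplet definitions are
consumed as a registry (allele → eplet names CSV); deriving eplets from
structures is out of scope.

**PIRCHE-II.** From each mismatched donor allele (two-field identity
against the recipient's allele list) the protein is scanned into
overlapping peptides (default 15-mers, step 1 — the class-II convention;
the window is configurable because the choice is conventional, not
forced). Each peptide is scored against each recipient DRB1 allele by a
binding predictor returning a nonameric core and an IC50; predictions
with IC50 strictly below 1000 nM count as relevant binders; a binder is
discarded when its core occurs as a substring of any recipient HLA
protein at any of the five loci (the self filter); surviving cores are
deduplicated globally into the PIRCHE-II set. Whether deduplication
should instead be per recipient DRB1 allele is not standardized; the
global rule is the default and `count_per_drb1` switches to per-DRB1
summation.

The binding predictor is a contract, `function(peptide, drb1_allele) ->
(core, ic50)`. Production use wires a real class-II predictor through
`adapter_predictor()`; the package default is `mock_predictor()`, a
deterministic, seed-free stand-in that picks the core by minimizing a
fixed string hash of (window, allele) and draws the IC50 from a
log-uniform transform of a differently-salted hash of the chosen core.
The salt matters: deriving the IC50 from the *minimizing* hash itself
would make almost every peptide a binder (a minimum of several uniforms
is small), whereas the decorrelated hash yields a reproducible mix of
binders and non-binders (about 64% below 1000 nM, since the transform is
log-uniform on (1, 50000) nM).

## Validation machinery

The virtual population sampler assigns each individual two haplotypes
drawn from the table. The default policy is i.i.d. sampling proportional
to frequency; a `finite_pool` policy discretizes the table into a pool
of haplotype copies and draws without replacement, for users who want a
literal finite-pool model. Couples are formed by drawing a random donor
per recipient and redrawing until the allocation rule holds — at most 3
broad-antigen mismatches at HLA-A plus HLA-B and at most 1 at HLA-DR,
computed on antigen *sets* so a homozygous individual contributes a
single antigen. A retry cap (default 10^5) turns an impossible recipient
into a typed error instead of an endless loop.

Observed (imputed) and reference (true-genotype) values are compared as
`ln(observed) − ln(reference)`, on the premise that epitope load acts on
alloreactive risk roughly logarithmically; |delta| > 1 marks a high
deviation. Two issues require explicit numerical policy:

* **Zeros.** `ln(0)` is undefined and fully matched couples do produce
  zero counts. The default policy excludes those couples and reports how
  many were excluded; an `add_one` policy (`ln(x + 1)`) is available.
  Neither is hidden in the output.
* **"Delta of zero".** After weighted sums, exact float equality is
  meaningless; a couple counts as zero-delta iff |delta| < 1e-12. The
  single-candidate collapse produces weights of exactly 1.0, so truly
  exact cases remain exact.

Percentile spreads are two-sided around the median: the level-L spread
runs from the empirical quantile at (50 − L/2)% to the quantile at
(50 + L/2)%, computed with linear interpolation between order statistics
(quantile type 7), fixed and named in the output so runs are comparable.

## Synthetic worlds and study conditions

`generate_world()` builds a complete input set from one seed: per-locus
alleles; a serology map where consecutive groups of `alleles_per_split`
alleles share a split antigen (degeneracy 1 makes serology injective —
useful for exactness checks — and degeneracy ≥ 2 creates real
imputation ambiguity); proteins derived from a per-locus base sequence
by ~10% point substitutions, so alleles share most of their sequence
and the PIRCHE self filter is genuinely exercised; eplet registries
where alleles of one split share a core eplet set plus a private eplet;
and a frequency table with Dirichlet-sampled frequencies at small
concentration (default 0.5), giving the few-common-many-rare profile of
published tables.

Two parameterizations are used throughout the tests:

* **Oracle worlds** (3-6 alleles/locus, 15-40 haplotypes, proteins of
  21 residues): small enough that exhaustive brute-force enumerators,
  set-algebra eplet recomputation and a straight-line PIRCHE pipeline
  verify every computed quantity exactly.
* **Study world** (5 alleles/locus, degeneracy 2, 60 haplotypes,
  proteins of 30 residues, 40-60 couples): a table sparse relative to
  the 3125-combination allele space, mimicking the regime of real
  five-locus tables where a split typing typically resolves to a
  handful of genotypes. Under these conditions the zero-delta fraction
  at split level, its increase when the recipient is typed at two-field
  resolution, and its collapse when HLA-C or HLA-DQ is omitted all
  reproduce the direction and rough magnitude expected of the method.

What passing tests on these worlds shows — and what it does not: the
combinatorics, weighting, fallback logic and statistics are verified
against independent oracles, and the qualitative behavior of the
estimation under typing degradation is reproduced. The synthetic worlds
do not model real linkage-disequilibrium structure, real serological
dictionaries, real eplet biology or a real binding predictor, so
numerical agreement with any particular published cohort is out of
scope; real frequency tables, serology dictionaries, registries and
predictors plug into the same parsers and contracts.

## Known limitations

* Serological *broad*-level input is accepted by the matcher but far
  less informative; genotype-list strings and allele code inputs are
  not supported.
* The five loci are fixed; DRB3/4/5, DQA1 and DPB1 are rejected.
* The linkage fallback is global per typing, not per haplotype.
* Memoized engine scores assume the resources (registry, proteins,
  predictor) are constant per cache; no concurrency semantics are
  specified.
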