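---
title: "Data-driven mutation categorization: models and methods"
author: "ddcat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven mutation categorization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mutational signature analysis decomposes a cohort's somatic single base
substitution counts into signatures (probability vectors over mutation
categories) and per-sample exposures. The field's standard categorization
uses 96 categories: the pyrimidine-collapsed substitution plus one flanking
base on each side. There is, however, evidence that sequence context beyond
the immediate neighbours carries information about mutational processes.
`ddcat` treats the categorization itself as an object to be learned: it
represents each mutation as a 7-mer mutation sequence — an 8-character
string holding three 5' flanking bases, the original (C or T) base, the new
base, and three 3' flanking bases — and searches for a set of 96 degenerate
patterns over these sequences that maximizes the agreement between inferred
signature exposures and the expression of DNA-damage-repair (DDR) genes,
under the working assumption that tumours exposed to similar mutational
processes express the repair machinery involved in those processes at
similar levels.

## The pattern language and assignment rules

A category is an 8-symbol pattern. Each flank symbol is a single base, a
two-base IUPAC code (R, Y, S, W, K, M) or the wildcard N; position 4 must
be exactly C or T; position 5 is a single base or pair disjoint from
position 4; three-base IUPAC codes are never allowed. The valid sequence
universe has $2 \times 3 \times 4^6 = 24{,}576$ members. Every
categorization carries the all-wildcard joker pattern `NNNNNNNN`, which
guarantees that each sequence matches at least one category.

A sequence is assigned to the matching category (no mismatches) that is
best under three criteria applied lexicographically:

1. **size** — the number of universe sequences matching the pattern;
2. **span** — the inclusive distance between the first and last non-N
   symbol;
3. **reach** — the largest offset of any non-N symbol from the mutated
   site (position 4 on the left, position 5 on the right).

Smaller wins at each step. Only the third criterion's direction is forced
by the canonical worked example (`TGTCTAAC` against `NSTCTANN` and
`NNNCTARC`, both of size 128 and span 5, goes to `NSTCTANN`, whose non-N
symbols sit closer to the mutation); we adopt "smaller wins" for all three
as the specificity-first reading: smaller categories are more specific,
more compact patterns are preferred, and context closer to the mutation is
preferred. Sizes are counted over the valid universe, which makes the
criterion well defined for the joker (size 24,576, so it loses every
tie-break and acts as a fallback). Residual ties after all three criteria
are broken uniformly at random and flagged *ambiguous*; the ambiguous
fraction of the 24,576-sequence table is the categorization's *conflict
rate*. Categorizations entering the genetic algorithm must keep this rate
below 1%.

The full assignment table is precomputed once per categorization and all
catalog construction is table lookup; the genetic algorithm evaluates
thousands of categorizations, so per-mutation pattern scans would be
prohibitive. Internally the matcher exploits the product structure of the
universe (64 left flanks x 6 substitutions x 64 right flanks) and conflict
resolution updates only the replaced category's match column.

## Catalogs, opportunities, factorization

Mutation tables (1-based coordinates, ICGC-style columns) are validated
against the reference genome; the +-3 window is extracted and
reverse-complemented when the reference base is a purine, so position 4 is
always C or T. Records with reference mismatches, ambiguous window bases or
out-of-bounds windows are rejected and tallied.

Signatures are learned from the row-normalized WGS catalog $V$ by
non-negative matrix factorization under generalized Kullback–Leibler
divergence, $V \approx WH$, using multiplicative updates (epsilon-floored
denominators at $10^{-12}$; convergence at relative objective change
$<10^{-6}$ or 2000 iterations; best of 10 random restarts for reported
reconstruction errors, 3 restarts inside the genetic algorithm where only
the ranking of categorizations matters). Rows of $H$ are normalized to
probability vectors with a compensating rescale of $W$, which leaves $WH$
unchanged.

Because WGS and WES samples see different context inventories, signatures
learned on the genome are renormalized before exome refitting: the
*opportunity vector* $U$ counts, per category, the (position, alternative
base) pairs available in the region — each position with a full,
ambiguity-free 7-mer window contributes three potential mutation sequences.
A signature row is multiplied elementwise by $U_{WES}/U_{WGS}$ and
renormalized to sum to one. Exome membership is decided by the central
base's position (flanks may extend outside the exon): it is simple,
deterministic, and matches exon-centric counting. WES exposures are then
refit per sample by non-negative least squares (Lawson–Hanson, via
`pracma::lsqnonneg`).

The number of signatures $K^*$ is chosen by a deliberately simplified
cross-validation selector (`cv2k_lite`): a fraction (default 10%) of catalog
entries is hidden, masked KL-NMF imputes them for each candidate $K$, and
the smallest $K$ within one standard error of the best mean imputation
error wins. The full error curve is returned so that an externally computed
$K^*$ can be substituted. The full published CV2K procedure is intentionally
out of scope.

## Fitness: cross-validated regularized CCA

Exposures $W$ and gene expression $E$ (restricted to a gene set, e.g. the
DDR-like genes) are two views of the same samples. We score their agreement
by canonical correlation analysis with ridge regularization, solved as a
generalized eigenproblem on the training covariance matrices (both views
centred and scaled by training statistics; default ridge 0.1 on both
views; linear kernel). In each of 10 folds the weight vectors are learned
on the training rows and the Pearson correlation of the **first** pair of
canonical variates is computed on the held-out rows; the weights are
oriented so the training correlation is positive, making held-out
correlations signed. The regularization strength and the use of the first
component only are our choices — neither is forced by the method — and both
are configurable. A unit test verifies that the first canonical pair
coincides with `mixOmics::rcc` (ridge) and approaches `stats::cancor` as
the ridge vanishes.

The fitness of a categorization on a dataset is the mean held-out
correlation over all folds and all $K \in [K^*-2,\, K^*+2]$ (clamped below
at 1), where each $K$ runs the full pipeline: WGS NMF, opportunity
renormalization, WES NNLS, CCA. $K^*$ is computed once per dataset on the
standard-categorization catalog and held fixed for all individuals
(recomputing it per categorization would multiply the cost of every
generation; the policy is exposed as a configuration choice). Fold
assignments are fixed per dataset, so fitness values are comparable across
individuals and generations.

## The genetic algorithm

Individuals are categorizations (95 sampled categories plus the joker,
conflict rate < 1%). Ancestor categories are sampled as an interval of
`n_symbols` consecutive non-N symbols covering positions 4 and 5, with
`n_symbols` drawn from {3,...,7} with weights $(1, c, 1, 1, 1)$ and
$c = 10$ — the weight-vector notation in the source method is read as this
categorical distribution, which matches its expectation. We additionally
require the interval to cover position 5 (not only position 4): an
all-wildcard new base would violate the disjointness constraint.

Per generation, individuals are ranked 1 (worst) to $S$ (best) per dataset
and on the average ranking; a parent is drawn from a uniformly chosen
ranking with probability proportional to $\mathrm{rank}^{power}$
($power = 5$), without replacement within a crossover pair. The two top
individuals of the average ranking pass unchanged (elitism), which makes
the best fitness non-decreasing when fitness values are cached — caching is
keyed by the categorization's pattern multiset and elites are never
re-scored. With probability $q = 0.8$ an offspring is a crossover: a
random fraction up to 40% of the 95 categories comes from the lower-fitness
parent, the rest from the higher-fitness one, duplicates are collapsed and
fresh categories fill any shortfall. Otherwise the parent is mutated: each
category independently with probability $m = 0.05$ gets one symbol replaced
by an intersecting symbol (single base to a containing pair, or pair to one
of its bases; position 4 never mutates; position 5 stays disjoint from the
original base). Conflict resolution after every operation greedily replaces
the category involved in the most ambiguous ties with a freshly sampled
one — the source method states that conflicting categories are replaced but
not which; greedy most-involved-first converges quickly in practice.
Defaults follow the published parameters: population 40, 100 ancestors
(top 40 kept by truncation on the average ranking), 500 generations.

## The synthetic data generator

The generator is the package's test bed and defines its study conditions.
It emulates: a uniform-composition random genome (default 200 kb, GC 0.5)
with a 25% exome of 500 bp exons; `kTrue = 3` planted signatures, each
putting 90% of its mass uniformly on the sequences matching three
generating degenerate patterns (specificity up to three bases from the
mutation) and 10% uniformly elsewhere, redrawn if two signatures' supports
overlap (cosine >= 0.3); cohorts of 30 WGS and 30 WES samples with
Dirichlet-distributed exposures, Poisson mutation burdens (mean 500 for
WGS, scaled by the exome/genome eligible-position ratio, about 125, for
WES); and expression for the WES samples built as
$\mathrm{softplus}(4\,c\,W_{true}B) + \mathcal{N}(0, 0.1)$ for 40 coupled
"DDR-like" genes plus 20 exposure-independent control genes. Mutations are
placed at real genome positions carrying the drawn 7-mer context (on either
strand), so FASTA extraction, strand collapsing and opportunity counting
are exercised end to end, and every emitted record re-extracts to its
intended mutation sequence by construction.

These sizes were chosen as the smallest at which the recovery ladder is
stable: the cross-validation selector recovers $K^* = 3$, NMF recovers the
planted signatures up to permutation (row-wise cosine > 0.9), NNLS
recovers per-sample exposures (cosine > 0.9), and the held-out CCA
correlation of the pipeline's exposures sits within 0.1 of the oracle value
computed from the true exposures. What the generator deliberately does not
model: mutational-process biology (replication timing, strand bias),
copy-number or clonality structure, non-uniform genome composition, and
indels or doublet substitutions. Passing tests therefore demonstrate the
correctness of the machinery and the recoverability of planted structure,
not biological performance on real cohorts.

## Numerical and design choices

* **Coordinates** — mutation tables are 1-based; BED regions are 0-based
  half-open on disk and imported as 1-based `GRanges`.
* **Duplicates** — duplicate records are counted as-is; a `dedup` flag is
  available. Non-SNV rows are filtered with a logged tally.
* **Ties in ranking** — dense ranks with stable (first-wins) order; the
  ranking scheme does not otherwise specify tie handling.
* **Degenerate inputs** — zero-mutation samples are rejected by name;
  categories unobservable in the source opportunity regime get ratio 0
  with a warning; empty categories give zero rows in the transformation
  matrix and are reported.
* **Randomness** — every entry point takes an explicit seed or inherits
  the caller's RNG stream; a seeded helper restores the stream afterwards,
  so nested seeded calls do not disturb outer reproducibility. Genetic
  algorithm runs are bit-reproducible from `config$seed`.
* **Problem sizes in the test suite** — the bundled fixture uses the 200 kb
  genome and 30 + 30 samples described above; the genetic algorithm
  recovery check runs S = 10 for 20 generations with 25 ancestors. These
  are the package's declared study conditions for desk-scale validation.

## Known limitations

The category count is fixed at 96 (matching the standard categorization so
that comparisons are not confounded by category number); variable-M
searches are future work. The CCA view uses a single canonical component
by default. `cv2k_lite` is a stand-in selector: on real cohorts a more
careful rank selection is advisable. Fitness optimizes DDR-gene agreement
only; processes without an expression footprint (e.g. purely environmental
ones) are down-weighted by construction.
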