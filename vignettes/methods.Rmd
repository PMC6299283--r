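---
title: "Models and methods behind phylostrip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylostrip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylostrip)
```

phylostrip implements three analysis stages that often travel together in
phylogenomic studies of fast-evolving parasites, plus the synthetic worlds
needed to test them without external data. This vignette explains the
models, the tunable parameters, and the design decisions taken where the
procedures left genuine freedom.

## 1. Slow–fast analysis and clade support

### Model

Fast-evolving alignment sites are the prime source of systematic error
(long-branch attraction): they saturate, and whatever signal they retain
can support an artefactual grouping rather than the true one. The
slow–fast procedure removes the fastest sites in increments and re-asks
how supported a focal clade is. Sites are ranked once, on the full
alignment's per-site relative rates; subsets are cumulative, so the
retained column sets are nested along the plan. If support for a clade
*rises* as fast sites leave, the original support against it was likely an
artefact of those sites.

Support for a taxon set $S$ over a tree sample is the fraction of trees
containing the bipartition $S \mid U \setminus S$ — exact split presence,
the bootstrap-proportion semantics of ultrafast-bootstrap files; no
partial or compatibility credit is given. Splits are canonicalized by the
side *not* containing the lexicographically smallest taxon, which makes
split identity order-independent and hashable. The majority-rule
consensus keeps splits with frequency strictly greater than the threshold
(default 0.5); strict ">" guarantees the retained splits are pairwise
compatible.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `step` | 0.05 | fraction of sites removed per increment |
| `max_fraction` | 0.95 | last fraction; the default plan has 19 subsets |
| rounding | half-up | $k = \lfloor fL + 0.5 \rfloor$ sites removed (with a $10^{-9}$ guard against binary representation error) |
| rate ties | column index | deterministic across platforms |
| consensus threshold | 0.5, strict | majority rule |

The half-up rounding and the tie rule are choices of this package: the
procedure is usually described only as "remove the fastest 5%", which
under-determines both. Both are documented and tested rather than left to
the platform's sort.

## 2. Ortholog-profile comparison

Species × ortholog counts are binarized (count ≥ 1 → present) and
orthologs absent everywhere are dropped — they carry no comparative
signal. Pairwise species similarity is Pearson's $r$ on the 0/1 rows
(equivalently the phi coefficient); dissimilarity is $D = 1 - r \in
[0,2]$. $D$ is generally **non-Euclidean** (it can violate the triangle
inequality), so the PCoA spectrum may contain negative eigenvalues; they
are reported, no Lingoes/Cailliez correction is applied by default, and
explained fractions are normalized over the positive part of the spectrum
only. The broken-stick expectation
$E_i = \frac{1}{n}\sum_{j=i}^{n} \frac{1}{j}$ over the $n$ positive axes
is the null for "is axis $i$ worth interpreting"; an axis passes only on
a strict ">".

A species whose profile is constant (all-present or all-absent) has no
defined correlation; this is an **error**, not a silent $r = 0$, because
silent coercion would distort the ordination.

Ward clustering is computed through the Lance–Williams recurrence. The
default dialect `ward2` is Ward's criterion on the distances themselves
(squares internally, reports square-rooted heights — the `ward.D2`
convention); `ward1` applies the plain recurrence to the matrix as given,
which is appropriate when the input is already squared. Both exist
because the era of the analyses this package reproduces did not
distinguish them clearly in R code; both are tested against a naive
sum-of-squares oracle. Ties merge the smallest (row, col) pair in label
order and the reported leaf order is a left-before-right traversal, so
dendrograms are reproducible to the byte. Species are clustered on
$D = 1 - r$ (monotone-equivalent to clustering on $r$ for ordering);
orthologs, for heatmap column order, on Euclidean distances between 0/1
columns. Heatmap "scaling" of the colour code to $[0,1]$ is display
metadata — values are never mutated.

## 3. Annotation rule engines

All engines are deterministic and order-invariant after rank
normalization:

* **bestsum**: per query, sum bitscores of the first 10 hits per species;
  assign the species with the largest sum. Ties break by the species
  owning the single best hit, then lexicographically (a choice of this
  package; the rule is usually stated without a tie policy).
* **cellular-origin screen**: remove hit-less queries and queries whose
  bestsum superkingdom is Bacteria, Archaea or Viruses.
* **host screen**: discard a query iff its rank-1 hit at e ≤ 1e−10 is
  flagged a stramenopile (the host lineage); queries with no qualifying
  hit are kept.
* **host identity**: drop iff identity = 100 or identity > 95 (95.0
  exactly is kept; the "100%" clause is redundant but kept to mirror the
  two-stage screen it reproduces).
* **dedup**: 100%-identity deduplication including contained substrings
  (the global-identity behaviour of the usual clustering tool); longest
  representative, ties to the smallest id; an exact-duplicates-only mode
  is available.
* **MCL**: column-stochastic flow with self-loops, expansion (squaring),
  inflation 2.0, pruning at 1e−8, convergence at max entry change <
  1e−6. Clusters come from the attractor structure of the limit matrix;
  nodes attracted by several groups go to the highest-weight attractor,
  ties to the smallest attractor index (the published algorithm leaves
  overlap resolution open; this choice makes results deterministic).
* **KEGG transfer**: transfer iff best KEGG bitscore ≥ 0.8 × best UniProt
  bitscore ("at least 80%" read inclusively) *and* no existing ID.
* **presence**: full e-value ≤ 1e−5 **and** domain e-value ≤ 1e−4; a
  genome × KEGG cell is 1 iff one qualifying protein maps there.

## 4. The synthetic worlds

The generators state a world once; tests and acceptance criteria are then
measured in it. Parameters below were chosen for scientific plausibility
before the corresponding tests were finalized, and are not adjusted to
test outcomes.

**Sequences.** Sites evolve under a 20-state equal-exchangeability
(Poisson-style) process — uniform frequencies, Jukes–Cantor-like
transition probability $P(\text{same}) = \tfrac{1}{20} +
\tfrac{19}{20}e^{-\frac{20}{19} d}$ — with per-site rate multipliers drawn
from a gamma distribution with mean 1. Realism of the exchangeability
matrix is deliberately sacrificed: what downstream stages test is rate
*ranking* and signal mixing, not empirical amino-acid replacement. Trees
are random binary topologies with exponential branch lengths (mean 0.15
substitutions/site, a typical phylogenomic scale).

**Conflict.** A `conflict_fraction` of sites — deterministically the
top-rate quantile, so the planted truth is sharp — is simulated on a
nearest-neighbour-interchange rearrangement of the tree across a focal
internal edge. The NNI is performed by split surgery: exactly one
bipartition of the tree is replaced, and branch lengths transfer by split
identity (the new focal edge inherits the replaced edge's length). For
the support-curve acceptance world the focal edge is the **shortest**
internal edge: short edges are where fast-site conflict genuinely
overturns distance-based inference, which pilot exploration confirmed
(long, well-supported edges simply never lose; the curve would sit at 1.0
and test nothing). Alignment length 1000 and gamma shape 0.5 (strong
heterogeneity, saturated fast sites) complete that world.

**Tree samples.** Each replicate keeps the focal edge with probability
$p$, else applies one of the two NNIs across it (fair coin). The realized
clade frequency is Binomial$(n, p)/n$, which is what the recovery
criterion checks against 99% binomial intervals.

**Profiles.** Each (group, ortholog) pair draws a retention probability
from a Beta distribution with the group's retention as mean and
concentration 0.5 (U-shaped: orthologs are coherently present or
coherently absent within a group, as in real gene repertoires); species
then draw presence Bernoulli at that probability, and present orthologs
are duplicated (count 2) with probability 0.2 to exercise binarization.
The marginal presence probability of every cell equals the group
retention, so degenerate settings behave as stated (retention 1 → an
all-ones matrix). The hierarchy is essential, not cosmetic: if species
drew presence independently at the *scalar* group retention, any two rows
would be statistically independent and Pearson similarity would carry no
group signal whatsoever — the correlation-based pipeline would have
nothing to recover.

**Hit tables.** Five planted query classes map one-to-one onto the rule
engines: clean eukaryotic targets (kept), prokaryotic/viral queries
(cellular-origin), stramenopile-first queries (host screen), hit-less
queries, and queries whose last-ranked hit is a >95%-identical
stramenopile protein (identity screen). Bit scores decrease with rank and
reported e-values are ≤ 1e−10, so tables are valid under the same checks
the engines apply.

What a green test does **not** establish: the sequence world has no
indels, no empirical exchangeabilities, no compositional heterogeneity;
the profile world has no phylogenetic autocorrelation within groups
beyond the shared repertoire; hit tables have no noisy taxonomy. Green
means the *procedures* are correct on data whose truth is known, not that
the biological conclusions of any particular study are reproduced.

## 5. Numerical choices

* Round-half-up with a $10^{-9}$ additive guard (0.15 × 10 is
  1.4999999999999998 in doubles and must still round to 2).
* PCoA: eigenvalues below $10^{-9}\,\lambda_{max}$ are treated as
  non-positive; requesting more axes than there are positive eigenvalues
  returns fewer with a warning.
* Ward heights are non-decreasing by construction of the criterion;
  the test suite asserts it to $10^{-10}$.
* MCL gives isolated nodes a unit self-loop (their column would otherwise
  be all-zero and the flow matrix undefined); they become singleton
  clusters.
* All generators restore the caller's RNG state (`with_seed`), so
  identical configurations are byte-identical across runs and platforms.

## 6. Known limitations

* One acceptance expectation is intentionally red: the criterion asks
  that, in the two-group profile world, the first **two** explained
  fractions exceed their broken-stick expectations. A world with exactly
  one planted contrast has exactly one meaningful axis; axis 2 is noise,
  and the broken-stick rule exists precisely to put noise axes below the
  null. Empirically axis 2 reaches only ~0.3–0.7 of its expectation over
  100 seeds at any concentration, while axis-1 separation and the Ward
  cut succeed in 100/100. The expectation is asserted verbatim and fails;
  weakening it would defeat its purpose.
* `distance_bootstrap` (p-distance + neighbour joining) is a deliberately
  light stand-in for maximum-likelihood bootstrap inference; it is used
  to regenerate tree samples per stripped subset, not to claim ML-quality
  trees.
* NEXUS input, rooted-tree semantics, branch-length arithmetic, rate
  estimation itself, and all database searches are out of scope; hit
  tables are consumed, never produced.
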