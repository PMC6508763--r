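---
title: "Inferring Boolean implication networks from expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Boolean implication networks from expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolimpl)
```

# The model

Most meta-analyses of public expression compendia summarize gene pairs
symmetrically, by correlation. Boolean implication analysis asks a
different, directional question: across thousands of heterogeneous
samples, is a quadrant of the two-gene scatter *empty*? If no sample
ever shows gene A low together with gene B high, the data support the
asymmetric rule "A low ⇒ B low" even when the overall correlation is
weak — the information sits in where the points are *not*.

The pipeline has three stages.

**1. Step thresholds.** For each gene, the expression values (assumed
already normalized, on the log2 scale) are sorted ascending and a rising
one-step function is fitted: for every breakpoint $k \in [1, n-1]$ the
two segments are fitted by their means $m_1, m_2$ and scored by the
residual sum of squares

$$\mathrm{SSE}(k) = \sum_{i \le k} (x_i - m_1)^2 + \sum_{i > k} (x_i - m_2)^2,$$

and the minimizing $k$ wins, ties going to the smallest $k$ for
determinism. `fitStep()` computes this in one vectorized pass over
cumulative sums; the test suite holds it to an exhaustive breakpoint
scan. The threshold is placed at the midpoint $t = (m_1 + m_2)/2$. The
step's x-location between the two adjacent sorted values would be an
alternative placement; the midpoint is the natural location of the
fitted step's jump and makes the shift property exact (adding a constant
$c$ to a gene's values moves $t$ by exactly $c$ and leaves every call
unchanged).

**2. Ternary calls.** Each value is called high if above $t + 0.5$, low
if below $t - 0.5$, intermediate inside the band (`discretize()`). The
0.5 log2-unit margin — a ±1.4-fold band around the threshold — absorbs
values too close to the threshold to call confidently; intermediates are
simply excluded from pair counting. The margin is exposed as a parameter
but defaults to 0.5.

**3. Sparse-quadrant classification.** For an ordered pair (A, B), the
samples where both genes are called low or high populate four quadrants
with counts $a_{00}, a_{01}, a_{10}, a_{11}$ (first index A, 0 = low).
For a quadrant with observed count $O$, row margin $R$ (samples with A
in that state), column margin $C$, and pairwise-complete total $n$:

$$E = \frac{R\,C}{n}, \qquad
  S = \frac{E - O}{\sqrt{E}}, \qquad
  e = \frac{1}{2}\left(\frac{O}{R} + \frac{O}{C}\right).$$

The quadrant is *sparse* when $S > 3$ and $e < 0.1$ (both configurable;
these defaults are deliberate and should rarely be changed — the whole
calculus of the six classes is calibrated to them). $S$ measures
depletion below independence in units of the Poisson scale; $e$ is the
leakage of the implication, the fraction of the implicated margins that
violate the rule. Exactly one sparse quadrant gives one of the four
asymmetric classes (`lolo`, `lohi`, `hilo`, `hihi`, named by the
implication "A state ⇒ B state"); both off-diagonal quadrants sparse
gives `eqv` (equivalent), both diagonal quadrants `opo` (opposite). Any
other pattern — nothing sparse, an adjacent sparse pair, three or more —
is classified `none`: the six classes are the only meaningful outcomes
and ambiguous patterns are not guessed.

A quadrant whose row or column margin is zero is untestable and treated
as not sparse. Upstream of that, `buildNetwork()` only considers
*dynamic* genes: at least `minLow` low and `minHigh` high calls, default
$\max(3, \lceil 0.025\,n \rceil)$. Without this gate a gene that is
never low (say) would generate vacuous "implications" from an empty
margin. The 2.5% floor scales the gate with the compendium; the
absolute floor of 3 keeps tiny studies from passing genes on one or two
stray calls.

Because the network stores ordered pairs, every asymmetric edge appears
with its contrapositive (A lolo B is stored alongside B hihi A) and
symmetric edges appear in both orders. This makes per-gene relationship
profiles (`countRelationships()`) well defined, and implies two exact
bookkeeping invariants the tests assert: the network-wide totals of
`lolo` and `hihi` are equal, and the totals of `eqv` and `opo` are even.

# Universes and candidate logical invariants

A *universe* is a coherent subset of samples — all root samples, all
leaf samples, or the entire compendium (`makeUniverses()`). A Boolean
rule that held for *all possible* samples of a universe would be a
logical invariant of that universe; from finite data that is
unverifiable, so `evaluateInvariant()` only ever labels a relationship a
*candidate* invariant: it passes the sparseness thresholds within that
universe. The report also counts violations — the universe's samples
landing in the quadrant(s) the globally assigned relationship forbids.

By default the global discretization thresholds are reused inside each
universe (`rediscretize = FALSE`), so a universe's report describes the
tissue composition of the global scatter's quadrants; refitting
thresholds per universe is available but changes the question being
asked (a gene bimodal globally is often unimodal within one tissue,
where a refitted step is mostly noise).

# Comparing two networks

`compareNetworks()` reproduces a head-to-head protocol for the same
platform processed two ways (e.g. two normalization schemes): match
probes by shared identifier, count each probe's relationships of each of
the six types in both networks, and compare the paired counts per type.
The significance test is a two-sided Wilcoxon signed-rank on the paired
per-probe counts with zero-difference pairs dropped — chosen because the
data are paired, integer-valued and heavily skewed, so a paired t-test's
normality assumption is untenable; the reported direction is the sign of
the median nonzero difference (positive = network Y found more). Scatter
data are exported as $\log_2(\text{count}+1)$ so probes with zero counts
remain plottable. Probes present in only one table get zero counts in
the other; an empty identifier intersection is an error rather than a
silent empty comparison.

# Duplicate-file quality control

Public compendia assembled from many submissions can contain the same
array scan deposited twice under different names, which silently
double-weights those samples in any meta-analysis. `findDuplicates()`
hashes each file's bytes (md5 by default, streaming; sha256 available)
and groups identical digests. `duplicate_count` is defined as the number
of *redundant copies* (group size − 1, summed), so removing
`duplicate_count` files leaves `unique_count` distinct ones and the two
always sum to the number of files scanned.

# The synthetic generator

`generateExpression()` draws studies with known ground truth, emulating
the statistical structure this method presumes in real compendia:

* **Bimodal dynamic genes.** Each dynamic gene switches between a low
  mode (default mean 4) and a high mode (default mean 9, log2 scale)
  with within-mode sd 0.5. The defaults keep the modes ≈5 log2 units
  apart — far outside each other's ±0.5 intermediate band — matching the
  clean separation of strongly regulated genes on expression arrays. The
  spec validates separability as
  `highMean − lowMean > 2·margin + 4·noiseSd`.
* **Tissue-driven co-activation.** Samples get tissue labels (default
  root/shoot/leaf/flower at 0.3/0.2/0.3/0.2); each dynamic gene is
  active with probability 0.9 in a random subset of tissues and 0.1
  elsewhere, producing the block correlation structure that real
  tissue compendia show. Explicit per-gene, per-tissue activation
  probabilities can be supplied to build specific scenarios (e.g. a
  flower-restricted and a root-restricted gene, which are `hilo` in the
  full compendium but untestable inside the root universe).
* **Planted implications.** For a planted pair, gene B's states are
  overwritten to satisfy the requested class given gene A's states;
  each covered sample independently violates the rule with probability
  ε, the violation landing in the forbidden quadrant — so ε is the
  direct analogue of the classifier's error rate $e$. Planted
  antecedent genes default to balanced activation ($p = 0.5$ in every
  tissue) so that ε maps onto $e$ without a tissue-composition
  distortion of the margins; supplying `activationProbs` for the gene
  overrides this. Samples an asymmetric rule does not cover are drawn
  fair-coin so the permitted quadrants stay populated.
* **Flat genes.** Non-dynamic genes are unimodal Gaussians with sd 0.2
  (`flatSd`), the residual-variation scale of unexpressed or
  constitutive probes after normalization; their spread stays almost
  entirely within the intermediate band, so the dynamic gate excludes
  them, as it should.

What the generator does *not* emulate: probe-level normalization
artifacts (the systematic differences between summarization schemes that
motivate the network-comparison module), missing-value structure beyond
missing-at-random, batch effects, and continuous gradations of
expression between the two modes. A pipeline that passes these tests is
therefore validated for its *logic* — thresholding, counting,
classification, bookkeeping — not certified to recover biology from any
particular real compendium.

# Numerical and design notes

* Ties in the step fit (equal SSE at several breakpoints) go to the
  smallest breakpoint; values exactly on a band boundary ($t \pm$
  margin) are intermediate (strict inequalities both sides).
* A constant gene is a degenerate fit (threshold at the common value,
  SSE 0) and can never be dynamic.
* Genes with fewer than 2 non-missing values are an error at
  `discretize()`; drop them first. Missing cells propagate as missing
  calls and are excluded pairwise: a sample missing in either gene of a
  pair leaves that pair's counts only. This pairwise-complete choice is
  the minimal assumption; it means two pairs' counts may rest on
  different sample subsets.
* RNA-seq abundances enter through `transformTPM()`:
  $\log_2(\mathrm{TPM})$ above 1 TPM, $\mathrm{TPM} - 1$ below — the
  two branches agree (at 0) at TPM = 1, so the map is continuous and
  monotone, and sub-1 abundances are compressed into $[-1, 0)$ instead
  of running to $-\infty$.
* `buildNetwork()` accumulates all pairs' quadrant counts with four
  indicator-matrix products, so cost scales with genes² in matrix
  arithmetic rather than an R-level pair loop.

# Validation problem sizes

The test suite validates the step fit against an exhaustive breakpoint
scan on 1,000 random vectors (lengths 2–200), the classifier against a
brute-force reimplementation on all 135,750 count tables with total ≤
40, planted-class recovery at n = 300 samples and ε = 0.02 over 200
replicates per class (with the ε = 0.25 counter-check and a 100-replicate
null), and the comparison module on a 500-probe planted shift. These
sizes make every property a deterministic, seeded computation that runs
in well under a minute each.
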