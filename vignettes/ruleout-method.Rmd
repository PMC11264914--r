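---
title: "Ruling out bacterial species from 16S amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ruling out bacterial species from 16S amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleout16S)
```

## The problem

A 16S rRNA amplicon covers one or two hypervariable regions of a roughly
1500 nt gene — typically 150 to 500 nt. That fragment is rarely enough to
*assign* a bacterial species: distinct species can be identical over a
short region. It is, however, often enough to *rule species out*.
Microbiologists describing new isolates use exactly this logic: a strain
whose full-length 16S gene is less than 97.5% identical to the type strain
of an established species cannot belong to that species. This package
turns that reasoning into a per-read, per-species **rule-out probability**:
the probability that the read could *not* have arisen from a given
species' type strain. Species that cannot be ruled out are reported as
compatible; when several remain, all are reported.

## The model

For a read aligned to a type-strain gene of full length $L$, the
alignment (semi-global, free end gaps) yields $x$ mismatches over $n$
columns. The unobserved remainder of the gene has $m = L - n$ positions.
We place a Jeffreys prior $\mathrm{Beta}(1/2, 1/2)$ on the per-position
mismatch rate $\theta$, so after the observation

$$\theta \mid x, n \sim \mathrm{Beta}(x + 0.5,\; n - x + 0.5),$$

and the number $K$ of additional mismatches among the $m$ unobserved
positions is beta-binomial:

$$P(K = k) = \binom{m}{k}
  \frac{B(k + \alpha,\; m - k + \beta)}{B(\alpha, \beta)},
  \qquad \alpha = x + 0.5,\ \beta = n - x + 0.5 .$$

The total full-gene mismatch count is $x + K$; everything downstream is a
functional of this distribution.

**Hard criterion.** With threshold identity $\theta^\ast$ (default
0.975), the rule-out probability is the tail
$P\{x + K > (1 - \theta^\ast) L\}$. The budget $(1 - \theta^\ast) L$ is
kept real-valued and the inequality strict, so a total landing exactly on
the budget is not ruled out; this makes results bit-reproducible and
unambiguous when the budget is an integer. The tail is computed as one
minus the probability of the compatible outcomes, so when that residual
mass underflows the function returns exactly 1.0 — a fully observed gene
($n = L$) always returns an exact 0/1 indicator.

A worked pair of examples (322 nt amplicon, $L = 1500$):

```{r examples}
# 2 mismatches in 322 columns: 99.4% identity in the observed region
posterior_from_observation(2, 322)[c("alpha", "beta")]
hard_ruleout_probability(total_mismatch_distribution(2, 322, 1500))
# 82 mismatches already exceed the full-gene budget of 37.5
hard_ruleout_probability(total_mismatch_distribution(82, 322, 1500))
```

The low-mismatch value depends mildly on the assumed gene length: over
$L \in [1450, 1550]$ it moves between about 0.0028 and 0.0033.

**Soft criterion.** Whole-genome comparisons show that the probability of
two genomes being the same species (by average nucleotide identity) rises
smoothly with 16S identity $d$, well described by an exponential with a
half-maximum near $d_{1/2} = 0.991$:

$$f(d) = 2^{-(1 - d)/(1 - d_{1/2})},$$

which is 1 at $d = 1$ and $1/2$ at $d = d_{1/2}$. Base 2 is a pure
parameterization choice — any exponential with the same half-max point is
the same curve. The soft rule-out probability integrates $f$ over the
total-mismatch distribution,

$$1 - \sum_k P(K = k)\, f\!\left(\frac{L - x - k}{L}\right),$$

rather than evaluating $f$ at a point estimate; integration propagates
the (often substantial) uncertainty in the unobserved region.
`fit_half_max()` recovers $d_{1/2}$ from labeled (identity, same-species)
pairs by one-dimensional maximum likelihood.

**Variable mismatch rates.** Hypervariable regions are, by construction,
more variable than the rest of the gene, so a constant-rate extrapolation
from a variable region overstates full-gene divergence. Given a
per-position mismatch-rate profile for a type strain (estimated from
full-length variant sequences by `estimate_position_rates()`, with
$+0.5/+1$ pseudocounts so no position has rate zero and the log ratio is
always finite), `rate_log_ratio()` summarizes the difference as
$\hat\rho = \overline{r}_{\text{outside}} / \overline{r}_{\text{inside}}$.
The posterior is then adjusted by scaling its mean by $\hat\rho$ while
preserving the concentration $\alpha + \beta$ (clamping the mean just
below 1):
$\alpha' = \min(\hat\rho\,\alpha,\ \alpha + \beta - \epsilon)$,
$\beta' = \alpha + \beta - \alpha'$, with $\epsilon = 10^{-6}$. The
summary statistic (the log rate ratio) is the principled part; how it
enters the posterior is a design choice of this package, made so that
$\hat\rho = 1$ reduces *exactly* to the constant-rate algorithm — a
property the test suite asserts.

## Alignment conventions

Candidate species are those aligning with identity strictly above 90%
(`alignment_params(min_identity = 0.90)`). Alignment is semi-global:
global with zero-cost terminal gaps on both sequences, so the unsequenced
flanks of the gene cost nothing. Bookkeeping rules, chosen so that one
number ("differences") feeds the probability model:

* terminal-gap columns are excluded from both $n$ and $x$;
* internal gap columns count as mismatches;
* IUPAC degenerate codes match any base they denote (primers and some
  reference genes contain them; counting them as mismatches would inflate
  $x$);
* $L$ is the full reference gene length, not the aligned span, because
  the extrapolation targets the entire gene.

Scoring defaults are match $+5$, mismatch $-4$, linear gap $-8$. The
engine is `Biostrings::pairwiseAlignment(type = "overlap")` behind this
contract; the test suite pins its optimal scores to an exhaustive
dynamic-programming oracle on random short pairs. One consequence of free
end gaps worth knowing: a read end that mismatches badly can be trimmed
into a terminal gap instead of being charged as mismatches, exactly as a
semi-global search tool would do.

## Compatibility calls

A read is *compatible* with a species when its rule-out probability is
below 0.5 (the probabilities are strongly bimodal near 0 and 1 in
practice, so the cutoff is uncritical). `best_species_call()` selects the
compatible species with the lowest probability, breaking ties
lexicographically; the full table keeps every non-ruled-out species,
since distinct species with identical regions are genuinely
indistinguishable from the data.

## Region tools

`primer_match()` / `extract_region()` trim full-length genes to the
region a primer pair amplifies (F27/R228, F27/R534, F515/R806 are built
in as `builtin_primer_pairs()`). Matching is ungapped Hamming with
IUPAC-aware comparison and a default tolerance of one mismatch per
primer; the leftmost best-scoring site wins, the reverse primer is
reverse-complemented before searching, and primer bases are excluded from
the extracted region. `indistinguishable_pairs()` flags species pairs
whose records align with 0 or 1 mismatches — the fundamental resolution
limit of the marker gene within a region.

## What the synthetic generator does and does not emulate

`simulate_database()` draws an ancestral gene uniformly at random and
derives each further species by independent per-site substitution
(default 10% divergence, uniform choice among the three alternative
bases); `simulate_reads()` slices a window (default $[100, 422)$, a
322 nt V1-V2-sized region) and applies i.i.d. substitutions at the
`inside_rate` (default 0.002, a small within-species plus error rate).
This matches the generative assumptions of the mismatch model exactly —
which is the point: it validates the inference machinery, parameter
recovery, and the end-to-end pipeline with known truth. It does *not*
emulate real 16S data: no position-specific conservation structure, no
indels, no chimeras, no quality-dependent errors, and uniform base
composition. Passing tests therefore demonstrate correctness of the
computation, not field accuracy of the defaults on real communities.

Problem sizes used by the test suite are desk scale by design: 10-species
databases, 100 reads, $10^4$ labeled pairs for curve recovery, $10^6$
Monte-Carlo draws for the distribution check, and 200 random pairs for
the alignment oracle.

## Numerical and degenerate-input choices

* Beta-binomial terms are computed with `lchoose`/`lbeta` in log space.
* Rule-out probabilities are computed from the small complementary sum
  where possible and clamped to $[0, 1]$.
* An empty database, or a read with no candidate above the identity
  floor, yields a sentinel row with empty species and probability 1.0 —
  "every known species is ruled out" is a legal, informative outcome.
* `(x, n) = (0, 0)` returns the bare prior; $n = L$ returns a point mass.
* A rate profile covering the whole gene has no outside region and is an
  error for `rate_log_ratio()`; uncovered profile positions inherit the
  mean covered rate.
* Generators take an integer seed and are byte-reproducible; reads use
  `seed + 1` so databases and reads vary independently.

## Known limitations

Species sharing a region-identical 16S sequence can never be separated,
only co-reported. The constant-rate algorithm inherits the bias of
extrapolating from a hypervariable window; the variable-rate adjustment
corrects the mean but keeps the beta-binomial form. Reference databases
are taken at face value — no name reconciliation or taxonomy handling
above species. The all-vs-all candidate search is quadratic and intended
for desk-scale databases, not k-mer-indexed search over tens of
thousands of type strains.
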