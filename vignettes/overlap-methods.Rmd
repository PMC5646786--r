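---
title: "Testing cross-species convergence of sweep-candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing cross-species convergence of sweep-candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepOverlap)
```

## The model

Selective-sweep screens produce, per species, a list of candidate genes
under putative positive selection. Given two such lists — say the AMH
candidates (contrasted against archaic hominin genomes) and a pooled
list from domesticated species (each contrasted against its wild
relative) — we ask whether their overlap exceeds chance.

The null model treats the two lists as independent uniform draws
without replacement, of sizes $a$ and $b$, from a shared universe of
$n$ distinct protein-coding genes. Conditioning on the first draw makes
the intersection size $V$ hypergeometric,

$$P(V=v)=\frac{\binom{a}{v}\binom{n-a}{b-v}}{\binom{n}{b}},\qquad
\mathbb{E}[V]=\frac{ab}{n},\qquad
\mathrm{Var}[V]=\frac{ab}{n}\Big(1-\frac{a}{n}\Big)\frac{n-b}{n-1},$$

and the evidence against the null is the upper tail $P(V\ge v)$ at the
observed overlap $v$. The "greater than or equal" convention is the one
used throughout; the strict tail is deliberately not exposed, because
mixing the two conventions is the classic off-by-one error in overlap
testing.

Although both draws are random under this null, the package implements
the reduced fixed-set form and then *validates the reduction
empirically*: the Monte Carlo module offers both a fixed-set sampler
(first set held at $\{1..a\}$, so a trial is one draw of $b$ indices
and a count of those $\le a$) and a literal two-subset sampler; a
two-sample Kolmogorov–Smirnov test in the suite confirms that the two
produce the same intersection-size law. The fixed-set sampler is what
makes $10^6$ trials routine.

## Key parameters and defaults

* **Universe size `n = 19500`** (default in the shipped battery
  configuration): an average count of protein-coding genes across the
  mammalian genomes compared. The test is only as meaningful as this
  simplification; sensitivity to $n$ can be probed by editing one YAML
  field.
* **Tail convention:** $P(V \ge v)$, always.
* **Monte Carlo replicates `reps = 1e6`** by default in
  `estimate_tail()`, the scale at which a tail of a few per mille is
  estimated with a relative error of a few percent. The test suite uses
  $10^5$; the acceptance script uses the full $10^6$.
* **Confidence intervals:** normal approximation to the binomial, which
  at $reps \ge 10^4$ is indistinguishable from exact intervals for the
  fractions involved; intervals are reported even when the count is
  small, as a deliberate honesty measure.
* **Synteny thresholds `min_shared = 4`, `max_insertions = 1`**, with 4
  flanking protein-coding genes per side when available. Published
  synteny validations of this kind are presented as worked examples
  rather than as a numeric rule, so the criterion here is an explicit,
  tunable parameter: half of the canonical 4+4 flank set must be
  shared, in a consistent order (either orientation), tolerating one
  unshared gene between consecutive shared flanks. Strand is ignored;
  only gene order matters.

## Numerical choices

Binomial coefficients are computed as `lchoose()` sums in log-space and
exponentiated once per mass point, so the tail at $n = 19500$ is exact
to machine precision; tail sums add at most $\min(a,b)+1$ non-negative
doubles, and the suite verifies normalization to $10^{-12}$ and
agreement of analytic and pmf-summed moments to a relative $10^{-10}$
at full scale. The implementation is cross-checked against two
independent routes: the classical hypergeometric functions in base R,
and (for $n \le 12$) a brute-force enumeration of *all* subset pairs.
Values of $v$ outside the support return probability 0 from the pmf,
and tails clamp to $[0,1]$; `v = 0` and the pigeonhole bound
$v \le a+b-n$ return exactly 1.

Symbol canonicalization is minimal by design: whitespace stripping,
case-folding to uppercase, and a single alias-table lookup. No fuzzy
matching, Greek-letter or hyphen rewriting is attempted — nomenclature
ambiguity is resolved only through explicit, versioned alias tables, so
every harmonization decision is auditable. Alias tables must be
functional and their targets fixed points, which makes normalization
idempotent. Species labels are a closed vocabulary validated at parse
time, so a typo cannot silently contaminate a pool. Records with an
unknown gene class are retained (published candidate tables rarely
annotate biotype) and counted in a message.

## The synthetic-data generator

`generate_pools()` emulates exactly the structure the statistics
assume: uniform draws without replacement from a universe of synthetic
`G00001`-style symbols (disjoint from real gene symbols, so packaged
fixtures cannot cross-contaminate), with three controlled perturbations:

* **planted overlap** — a set of symbols deterministically forced into
  all designated pools (exact planting, not probabilistic, so power
  statements are crisp);
* **alias noise** — a fraction of records emitted under a variant
  spelling, resolvable through the returned alias table;
* **non-coding contaminants** — extra miRNA/antisense records that the
  filtering stage must remove.

A truth table accompanies every generated data set, so tests compare
pipeline output against recorded intent rather than against the
generator's internals. `generate_neighborhoods()` does the same for the
synteny stage, with planted rearrangements (insertion, inversion,
shuffle, translocation) whose expected verdict is known by
construction.

What the generator does *not* model: linkage between neighboring genes
in sweep regions (real candidate lists are clustered, not uniform),
study-specific ascertainment, incomplete orthology between genomes, or
any sequence-level process. Passing tests therefore demonstrate that
the statistics behave correctly *under their own null and alternative*,
not that the null is an adequate description of any particular pair of
published screens — choosing comparable screens remains a scientific
judgement.

## Calibration of a discrete test

One design point deserves a note. The intersection statistic is
discrete (at $n=19500$, $a=691$, $b=742$ the largest mass point is
about 0.08), so the exact tail p-value cannot be uniformly distributed
under the null — its CDF is a step function touching the diagonal from
below. A naive KS test of raw null p-values against $U(0,1)$ would
reject essentially always, for this known structural reason. The suite
therefore checks calibration in the two forms that are correct for
discrete tests: the type-I bound $P(p \le \alpha) \le \alpha$ at
conventional levels, and exact uniformity of the randomized
probability-integral transform $P(V > v) + U \cdot P(V = v)$. Power is
checked by planting 25 shared genes (pushing the expected overlap to
roughly 51 against a null mean of 26.3), which the exact test must
detect at $p < 0.01$ in at least 95% of seeds.

## Problem sizes used by the suite

The test suite runs Monte Carlo estimates at $10^5$ replicates,
null-calibration across 500 generator seeds and power across 200, and
brute-force enumeration up to $n = 12$; the acceptance script runs the
four headline simulations at the full $10^6$ replicates. These sizes
keep every check comfortably reproducible on a laptop while leaving
Monte Carlo error well below the decision thresholds involved.

## Known limitations

* Great-ape, wolf and wisent comparisons are size-driven (`a`, `b`,
  `v` quoted from the literature) because the underlying lists exist
  only as PDF supplements; the battery recomputes their significance,
  not their overlaps.
* The universe-size simplification (one $n$ for all species pairs)
  ignores real variation in annotated gene counts.
* The synteny criterion validates local gene order only; it cannot
  distinguish a tandem duplicate adjacent to the original, and it
  assumes neighborhoods were extracted from assemblies of comparable
  annotation quality.
* Multi-pool significance is handled pairwise; no joint $>2$-set
  intersection distribution is implemented.
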