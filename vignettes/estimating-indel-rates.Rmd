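---
title: "Estimating substitution and indel rates from k-mer statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating substitution and indel rates from k-mer statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelrates)
```

## The problem

Alignment-free methods summarize genomes by their k-mer content and compare
sequences through inexpensive set statistics. Most of the statistical theory
behind these methods assumes a substitution-only mutation process; when the
divergence between two sequences also involves insertions and deletions, a
substitution-only estimator attributes every disrupted k-mer to substitution
and overestimates the substitution rate, sometimes grossly.

`indelrates` implements a mutation model with three parameters — a
per-position substitution probability $p_s$, a per-position deletion
probability $p_d$, and a mean insertion length $g$ — together with
closed-form estimators that disentangle the three signals using only simple
counting statistics of the two sequences. No full alignment of the input
pair is ever computed.

## The mutation channel

The channel takes a string $S$ of length $L$ over $\{A,C,G,T\}$ and
processes every position independently:

1. an operation is drawn from $\{\mathrm{Sub}, \mathrm{Del},
   \mathrm{Stay}\}$ with probabilities $p_s$, $p_d$, $1 - p_s - p_d$;
2. substituted positions are replaced by a uniformly random *different*
   base;
3. every position $i$ draws an insertion length $I_i$ from a geometric
   distribution on $\{0, 1, 2, \dots\}$ with mean $g$ (success probability
   $1/(1+g)$), and an insert string of i.i.d. uniform bases of that length;
4. the insert string for position $i$ is placed immediately before position
   $i$ (prepended for $i = 1$); deletions are applied last.

The geometric support starting at zero is forced by the moment structure of
the model: it makes the probability that a given position carries no
insertion equal to $1/(1+g)$, which is what produces the $(g+1)^{k-1}$
factor in the expectations below. At $g = 0$ the insertion process
degenerates to "never insert".

`mutate_sequence()` returns the complete ground truth of one invocation —
per-position operations, insertion lengths and strings, and the *track* map
from original to mutated coordinates — so downstream statistics can be
counted exactly rather than re-inferred. Random draws are consumed in a
fixed order (operations, substitution choices, insertion lengths, insert
bases), making every record reproducible from `(S, params, seed)`.

A *k-span* is an interval $[i, i+k-1]$ of positions of $S$; there are $L_0
= L - k + 1$ of them. The channel's observables are:

* $N$ — the number of k-spans with no mutation at all (all positions Stay,
  no insertion attached to an interior position $j \in [i+1, i+k-1]$;
  insertions attached to $i$ or $i+k$ land outside the span's residues);
* $D$ — the number of k-spans whose only mutation is exactly one deletion;
* $L'$ and $c_{A}'$ — the length and 'A'-count of the mutated string, and
  $P = L' - 4c_A'$.

## Expectations and estimators

With $c_A$ the number of 'A's in $S$, the expected observables are

$$E[L'] = L(1+g-p_d), \qquad
  E[N] = L_0 \frac{(1-p_s-p_d)^k}{(g+1)^{k-1}}, \qquad
  E[D] = L_0 \frac{k (1-p_s-p_d)^{k-1} p_d}{(g+1)^{k-1}},$$
$$E[c_A'] = c_A(1-p_s-p_d) + \frac{p_s (L - c_A)}{3} + \frac{gL}{4}, \qquad
  E[P] = (L-4c_A)\Big(1 - \tfrac{4}{3}p_s - p_d\Big).$$

Because $E[D]/E[N] = k p_d / (1 - p_s - p_d)$, these equations form a
*linear* system in $(p_s, p_d, g)$. Substituting the observed statistics
for their expectations and solving gives the closed-form estimators of
`estimate_rates()`:

$$\hat p_s = \frac{3\,[kN(L'-L+4c_A-4c_A') + D(L'-4c_A')]}
                  {(4c_A-L)(D+4kN)}, \qquad
  \hat p_d = \frac{D\,[3(L'-4c_A') + L-4c_A]}{(L-4c_A)(D+4kN)}, \qquad
  \hat g = \frac{L'}{L} - 1 + \hat p_d.$$

`estimate_rates_alt()` is the algebraically identical reformulation through
$P$, $Q = kN+D$, $R = k(L-4c_A)N$, $T = 4kN+D$; it is kept as an
independent code path and the test suite cross-checks the two to $10^{-10}$
relative. Feeding the exact expectations through either inverse returns the
generating parameters to floating round-off — the test suite asserts
$10^{-9}$ over a thousand fuzzed settings.

```{r}
counts <- expected_counts(1e6, 3e5, mutation_params(0.05, 0.05, 0.05), k = 21)
estimate_rates(counts)[, c("ps_hat", "pd_hat", "g_hat")]
```

Two degeneracies are intrinsic. When $4c_A = L$ (exactly 25% 'A'), $E[P] =
0$ and the system loses a dimension; `estimate_rates()` raises a classed
error at exact equality, and estimates become increasingly unstable as the
composition approaches the quarter point. When $D + 4kN = 0$ there is no
surviving k-span signal at all. Estimates are deliberately reported
*unclamped*: a negative $\hat p_s$ is a diagnostic of an ill-conditioned
input, not a value to silently truncate (an optional `clamp` flag truncates
for downstream consumers that need valid probabilities).

## Concentration bounds

`concentration_bounds()` evaluates the theoretical tail bounds on the three
estimators: sums of terms $a\,k\,e^{-\delta^2 E[D]/(3k)}$,
$b\,k\,e^{-\delta^2 E[N]/(3k)}$, a Bernstein-type sub-exponential term for
$P$, and for $\hat g$ an extra length-concentration term
$4 e^{-\theta_1 L \delta^2}$, with $\theta_1 = \min(g^2/(2(g+1)^2), p_d/3)$
and $\theta_2 = \max(g+1, 8)$.

Three numerical choices deserve a note:

* **Constant grouping of the $P$-term.** The printed grouping of the
  sub-exponential constant is typographically fragile in the source
  derivation; the implementation uses $\exp(-\delta^2 E[P]^2 /
  (72 L e^{24\theta_2+1}))$ and exposes the triple $(72, 24, 1)$ as the
  `p_constants` argument so other readings can be evaluated without code
  changes. Since $\theta_2 \ge 8$, this term is essentially equal to its
  prefactor at any realistic $L$, so the capped bounds are often the
  vacuous 1; the uncapped values (also returned) still carry information —
  they decrease monotonically in $L$, which the tests assert.
* **Composition precondition.** The underlying theorem is stated for $4c_A
  < L$, but only $E[P]^2$ enters the expressions, and relabeling the
  distinguished character maps $4c_A > L$ onto the stated case. The
  calculator therefore accepts any $4c_A \neq L$ — which also covers the
  30% 'A' composition used throughout the recovery experiments.
* **Capping.** Probabilities are capped at 1; raw values are exposed
  alongside.

## Observing N and D from raw sequences

$N$ and $D$ are defined in the coordinates of $S$'s k-spans and are not
directly observable from a pair of FASTA files. `estimate_counts()`
implements the practical observer:

1. extract all k-mers of $S$ and of $S'$ (`extract_kmers()`);
2. build the node-centric de Bruijn graph on each distinct k-mer set and
   extract its unitigs — maximal non-branching paths (`build_unitigs()`);
3. align every mutated-side unitig inside every reference-side unitig with
   semi-global (infix) alignment, in which leading and trailing target
   characters are free (`infix_align()`);
4. classify every window of $k$ consecutive target characters that is fully
   covered by an alignment: all-match windows with no interior
   query-insertion count toward $\hat N$; windows with exactly one deleted
   character, all others matching, and no interior insertion count toward
   $\hat D$ (`count_windows()`);
5. accumulate window contributions across all unitig pairs into global
   counts.

Unitigs, not k-mers, are the unit of comparison because an isolated
mutation at the edge of a k-mer cannot be typed from k-mer content alone;
only context beyond $k$ characters resolves whether it was a substitution,
an insertion, or a deletion.

The alignment core is a full-matrix dynamic program for the distance
(quadratic, like the reference approach it follows — efficiency of this
step is an open problem) plus a banded traceback whose band radius is the
edit distance plus one, which provably contains the optimal path. The test
suite checks it against a naive quadratic DP oracle on random string pairs.

Design choices the underlying description leaves open, and how they are
resolved here:

* **Window deduplication.** A target window can be covered by alignments of
  several query unitigs. Each window coordinate (per reference unitig) is
  counted at most once, keeping the classification from the
  lowest-edit-distance alignment, ties broken toward `N` then `D`.
  Double-counting would bias $\hat N$ upward.
* **Alignment acceptance.** Unitig pairs with edit distance above
  $\lceil 0.35\,|query| \rceil$ are discarded as spurious (`max_dist_frac`);
  without a threshold, unrelated pairs contribute noise windows.
* **Strands.** The channel never reverse-complements, so the graph is built
  on the forward strand only; a `canonical` flag adds reverse-complement
  k-mers for real-data use.
* **Repeats.** Unitig construction collapses repeated k-mers, so $\hat N$
  can undercount on repetitive sequences; the observer warns with the
  repeat fraction. Windows are counted in unitig-local coordinates.
* **Edges.** Windows only partially covered by the aligned region are
  ignored.

At the calibration scale used in the tests (a 100 kb pair at rates 0.01,
$k = 21$) the observer recovers $N$ and $D$ to well within 5% and the
downstream estimates are nearly indistinguishable from those computed with
ground-truth counts; the count error grows with the mutation rate, which
the suite asserts as a monotone trend over the 0.01–0.05 grid at reduced
scale (30 kb).

## The experiment harness

`run_experiment()` reproduces the standard sensitivity sweeps as tidy
tables: k-mer size, sequence length, base composition, a rate grid, and a
comparison against the substitution-only baseline
`smm_substitution_rate()`, $1 - (N/L_0)^{1/k}$, which conflates indel
signal into substitutions and therefore overestimates $p_s$ whenever
$p_d$ or $g$ is non-zero.

Every (setting, replicate) run draws its seed deterministically from the
master seed via `derive_seed()`, so a single row of a sweep can be
reproduced in isolation and the whole table is byte-identical across runs.
Each replicate generates a fresh reference sequence; the headline
recovery computation in `scripts/acceptance.R` instead follows the
one-reference/many-mutations protocol of the original k-sweep study.

```{r, eval = FALSE}
cfg <- experiment_config(mode = "k_sweep", L = 1e5, k = c(11, 21, 31),
                         ps = 0.05, pd = 0.05, g = 0.05,
                         replicates = 10, seed = 1)
tab <- run_experiment(cfg)
summarize_experiment(tab)
autoplot(tab)
```

## What the synthetic generator does and does not emulate

The generator draws i.i.d. bases with a configurable composition (default
30% 'A', the rest equal — the composition of the recovery studies, chosen
because it keeps the composition statistic $P$ safely away from its
degenerate zero). Real genomes are not i.i.d.: they contain repeats, skewed
local composition, and context-dependent mutation processes. Passing the
simulation-based tests therefore demonstrates correctness of the
estimators *under the model*, and calibration of the observer on
low-repeat sequences; it does not certify accuracy on highly repetitive
genomes (where unitig collapse undercounts) or under context-dependent
rates, which the model explicitly excludes.

## Problem sizes used by the test and acceptance suites

The package's own studies run at the generating conditions of the original
experiments where those matter (1 Mb references, 30% 'A', $k = 21$, 20
replicates at rates 0.05; 10 replicates at rates 0.01), and at reduced
scale where the assertion is qualitative: the composition sweep runs at
100 kb, the observer calibration at 100 kb with the rate-trend check at
30 kb, and the Monte-Carlo moment checks at 10 kb with 500 replicates.
These sizes are the package's choice of a scale at which the stochastic
tolerances (3–4 standard errors) are already tight.

## Known limitations

* The estimators assume the geometric-insertion indel channel; rate
  heterogeneity along the sequence, context dependence, and inversions or
  rearrangements are out of scope.
* The observer is quadratic in sequence length and intended for
  bacterial-scale inputs; efficient counting of $N$ and $D$ from sketches
  is an open problem.
* Estimates are undefined at exactly 25% 'A' and unstable near it; with
  $p_d = 0$, $D = 0$ and the deletion estimator degenerates gracefully
  ($\hat p_d = 0$) but carries no information about the boundary.
* The discarded alternative estimators based on single-insertion /
  single-substitution span counts (roots of degree-$k$ polynomials) are
  intentionally not implemented.
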