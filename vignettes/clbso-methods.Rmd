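---
title: "Hybrid swarm gene selection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid swarm gene selection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clbso)
```

## The selection problem and the wrapper objective

Given a samples × genes expression matrix with binary class labels, the
package searches for a small gene subset on which a classifier predicts the
class well. A subset is encoded as a binary mask $X \in \{0,1\}^n$ and
scored by

$$f(X) = w_1 \cdot \mathrm{acc}(X) - w_2 \cdot \frac{|X|}{n},$$

where $\mathrm{acc}(X)$ is the $k$-fold cross-validated accuracy of the
wrapped classifier on the *training split only*, restricted to the genes
with $X_j = 1$, and $|X|$ is the subset size. The accuracy term dominates
($w_1 = 0.99$ by default); the size term ($w_2 = 0.01$) breaks ties among
equally accurate subsets toward parsimony. Data are split 60/20/20 into
train/validation/test with per-class stratification; the optimizer never
sees validation or test labels, so the test metrics reported afterwards are
honest estimates. An empty mask is never scored: the optimizer repairs
empty candidates by switching on one uniformly chosen gene.

Evaluations are memoized on the exact bit pattern. The swarm revisits masks
constantly, and the objective is deterministic given the folds and the
classifier, so a cache lookup is exact, not an approximation.

## One swarm, three behaviours

Every member of the swarm is a mask that passes through up to three
proposal/acceptance steps per iteration. Acceptance is always *strict
greedy*: a candidate replaces the incumbent only when its fitness is
strictly higher. This gives elitism — best-so-far fitness is non-decreasing
— at the price of no uphill-escape mechanism other than the proposal
distributions themselves.

**Pheromone-guided local search.** A per-gene pheromone $\tau_j$ starts at
0.5, decays by $(1-\rho)$ each iteration and receives a deposit
$\Delta\tau_j = \frac{1}{N}\sum_i X_{ij}\,\max(f_i,0)/F_{\max}$ (zero when
the population best $F_{\max} \le 0$, since ratios to a non-positive best
are meaningless). The deposit is bounded in $[0,1]$, rewards genes that
appear in good masks, and is scale-free in fitness. Pheromone is clamped to
$[0.01, 0.99]$: the clamp keeps the toggle distribution

$$p_j = \frac{\tau_j^\alpha (1-\tau_j)^\beta}{\sum_k \tau_k^\alpha (1-\tau_k)^\beta}$$

strictly positive everywhere and prevents absorbing states. Each member
draws `n_toggles` (default 1) distinct genes from $p$ and flips them. With
the default $\alpha = \beta = 1$ the distribution peaks for genes the swarm
is undecided about ($\tau \approx 0.5$) and treats the two decided regimes
($\tau$ near either clamp) symmetrically.

**Lévy-flight global search.** The continuous step is sampled with the
Mantegna scheme at stability index 1.5: $\mathrm{step}_j = s\,\sigma\,
u_j/|v_j|^{1/1.5}$ with $u_j \sim N(0, \sigma_u^2)$, $v_j \sim N(0,1)$ and
$\sigma_u$ the Mantegna constant. The steps are symmetric about zero and
heavy-tailed — across $10^5$ draws the 99.9th percentile of $|\mathrm{step}|$
exceeds 20× the median — so most moves perturb nothing (a step that leaves
every component on the same side of the threshold is a no-op) while
occasional long jumps flip several genes at once. The step is added
directly to the 0/1 mask and re-thresholded at $T = 0.5$; no persistent
continuous position is kept between iterations, which keeps the encoding
closed over phases. The Mantegna sampler is the package's choice of
heavy-tailed generator; it is the de facto standard realization of Lévy
flights in binary metaheuristics, and its linear scaling in $s$ is exact
(doubling $s$ doubles every step for matched draws).

**Comprehensive learning.** After the two behaviours have run, each gene
is credited per behaviour: $S^A_j = \sum_i (f^A_i/F_{\max}) X_{ij}$ with
$f^A_i$ the fitness of member $i$ immediately after its ant step, and
likewise $S^G_j$ with post-grasshopper fitnesses; the $X_{ij}$ are the
current (post-grasshopper) masks. The normalized weights
$W_A = \sum_j S^A_j / \sum_j (S^A_j + S^G_j)$ and $W_G = 1 - W_A$ blend the
two recorded proposals into one more candidate per member:

$$x_{ij} = X_{ij} + W_A\,A_{ij} + W_G\,G_{ij},$$

binarized at the same threshold $T$. The proposals are encoded as *signed
moves* relative to the incumbent, $A_{ij} = (\text{ant candidate bit}) -
X_{ij} \in \{-1, 0, +1\}$: raw 0/1 proposals added to $X$ could only ever
increase components and would saturate the threshold, whereas signed deltas
make $W_A = 1$ reproduce the ant proposal exactly (a property the test
suite checks bit by bit). When both score sums are zero — early runs where
no fitness is positive — the weights fall back to $(0.5, 0.5)$. Acceptance
of the blended candidate is the same strict greedy rule as the other
phases.

Setting `comprehensive_learning = FALSE` in `clbso_control()` ablates this
phase. Randomness is drawn from named per-phase streams
(init/ant/levy/cl) derived from the master seed, so the ablation leaves the
other phases' draws bit-identical — with/without comparisons at the same
seed are genuinely paired.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `n_pop` | 50 | swarm size; the reference configuration for expression data |
| `max_iter` | 100 | iterations; enough for the greedy phases to converge on problems of ~10²–10⁴ genes |
| `p_init` | 0.5 | initial inclusion probability; unbiased start |
| `rho` | 0.1 | pheromone decay; memory of ~10 iterations |
| `alpha`, `beta` | 1, 1 | toggle-distribution exponents; symmetric treatment of pheromone and its complement |
| `s` | 0.1 | Lévy step size, in units of the binary coordinate |
| `sigma` | 1 | Lévy scale; at 1 the step magnitude is governed by `s` alone |
| `threshold` | 0.5 | binarization cutoff; midpoint of the coordinate |
| `weights` | (0.99, 0.01) | accuracy vs parsimony; accuracy-dominant wrapper convention |
| `n_toggles` | 1 | genes flipped per ant step; minimal local move |
| `tau_min`, `tau_max` | 0.01, 0.99 | pheromone clamps; keep the toggle distribution positive |

The wrapped classifier defaults to a linear-kernel SVM (`e1071::svm`,
`cost = 1`, no internal rescaling — expression inputs are assumed on a
comparable scale). Linear SVM is deterministic given its inputs, which the
seed contract requires; any classifier honouring the small fit/predict
adapter contract can be swapped in, and a nearest-centroid adapter is
included for fast tests. The inner CV default is 10 folds; analyses in this
vignette and the test suite use 5 folds on small synthetic data, where
10 folds would leave 3–4 samples per held-out fold.

## What the synthetic generator emulates — and what it does not

`synthetic_expression()` plants `n_informative` genes whose class means
differ by `effect_size` ($\delta$) noise standard deviations (means at
$\pm\delta/2$, unit variance), optional redundant genes
$R = \rho_{dup} P + \sqrt{1-\rho_{dup}^2}\,\varepsilon$ correlated with an
informative parent $P$, and independent standard-Gaussian noise genes. This
captures the features the selection problem depends on — sparse signal,
redundancy, high-dimensional noise — and makes ground truth available, so
recovery is quantifiable and classifier-agnostic.

It deliberately omits microarray- and sequencing-specific structure:
probe-level artifacts, intensity-dependent variance, batch effects,
correlated noise blocks, non-Gaussian tails. Passing the recovery
benchmarks here shows the optimizer works on clean sparse-signal problems;
it does not certify performance on real expression data, where
normalization and batch handling (out of scope for this package) dominate.

## Benchmark problem sizes

The package's standing benchmark, used by the acceptance tests and
`scripts/acceptance.R`, is 60 samples × 100 genes with 5 informative genes
at $\delta = 2.0$, balanced classes, weights 0.99/0.01 and 5-fold inner CV,
optimized by a swarm of 20 for 100 iterations, ten replicates. The swarm
size is scaled down from the reference 50 to keep a ten-replicate benchmark
comfortably runnable on a laptop core. The exhaustive-search oracle uses 10
genes (1,023 non-empty masks enumerated directly) with a deterministic
surrogate objective, so optimizer output can be compared with the certain
global optimum.

## Numerical and degenerate-input choices

- Zero-denominator metrics: precision with no predicted positives, recall
  with no true positives, and F-measure at precision = recall = 0 are all
  defined as 0.
- Degenerate $F_{\max} \le 0$: pheromone deposits and success scores are
  zeroed and the blend weights fall back to (0.5, 0.5).
- Best-so-far tie-breaking is deterministic: higher fitness, then fewer
  selected genes, then lexicographically smallest mask.
- Split sizes use largest-remainder rounding per class, so a 60/20/20 split
  of 100 samples is exactly 60/20/20 and class ratios are preserved within
  one sample per role; CV folds differ in size by at most one.
- Missing values are a hard load error, never imputed. Non-binary labels
  are rejected with the observed classes listed.
- The memoization key is the exact set of selected gene indices; two masks
  collide only if they are identical.

## Known limitations

**Selection overfitting at small n.** With ~36 training samples, the inner
cross-validated accuracy of good subsets saturates at 1.0, and the search
then actively hunts among thousands of masks for the smallest
CV-perfect one. Some noise genes separate the particular training samples
by chance, so minimal CV-perfect subsets typically mix truly informative
genes with one or two such passengers — and once a passenger is
load-bearing for CV accuracy, single-gene removals cannot evict it (any
removal drops accuracy and greedy acceptance refuses). On the standing
benchmark the selected subsets therefore overlap the planted 5-gene
support only partially (mean truth-Jaccard near 0.2, as
`scripts/acceptance.R` reports) even while mean held-out accuracy exceeds
0.95. This is a property of the wrapper
objective at this sample size, not of the search heuristic: a perfect
optimizer of $f$ would return an even smaller, partly overfit subset. The
same mechanism caps run-to-run stability: distinct seeds settle on
different minimal subsets that share the strong informative genes but not
the passengers. Larger samples, repeated/nested CV, or a stability-aware
objective would raise both numbers, but all three change the objective and
are out of scope here.

**Greedy acceptance.** Strict improvement gives clean elitism invariants
but cannot traverse fitness plateaus wider than one proposal, which is why
the Lévy jumps and the blended comprehensive-learning candidates matter:
they are the only multi-gene moves available.

**Binary labels only.** The fitness, metrics and final evaluation all
assume a two-class problem; multi-class labels are rejected at load.
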