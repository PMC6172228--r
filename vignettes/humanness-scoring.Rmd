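---
title: "Statistical humanness scoring and humanization of antibody variable regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical humanness scoring and humanization of antibody variable regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humab)
library(dplyr)
```

## The problem

Therapeutic antibodies are usually raised in mice and must be *humanized*
before clinical use: their sequences are mutated toward human-like
statistics while the antigen-binding loops (the Complementarity-Determining
Regions, CDRs) are preserved. Any computational humanization protocol rests
on a *humanness score* — a function that separates human from non-human
variable-region sequences. `humab` implements three families of such
scores on fixed-length, AHo-numbered alignments of VH and VL domains
(149 positions per chain, 298 for the combined VHVL alignment), the
ROC machinery to calibrate them, and CDR-preserving sequence optimization
under the statistical score.

## The multivariate Gaussian (MG) model

An aligned sequence of length $L$ over the 20-letter amino-acid alphabet
is one-hot encoded as a binary vector $y \in \{0,1\}^N$ with $N = 20L$:
position $i$ owns a block of 20 bits, one per amino acid in the fixed
alphabetical ordering, and a gap leaves its block at zero. The gap is
thus a representable 21st categorical state that carries no bit, keeping
$N = 20L$ exactly.

The learning ensemble of $M$ encoded sequences is treated as draws from a
multivariate normal $\mathcal N(\mu, \Sigma)$ with a conjugate
Normal-Inverse-Wishart prior on $(\mu, \Sigma)$. Integrating the
parameters out gives the posterior predictive density of a new sequence
$y$ — a multivariate Student-$t$:

$$
p(y \mid X) \;=\; t_N\!\left(\nu,\; \langle\mu\rangle_{\rm post},\; S\right),
\qquad
\nu = \frac{M}{1-\lambda} + 2,
\qquad
S = \Bigl(1 + \tfrac{1-\lambda}{M}\Bigr)\,\langle\Sigma\rangle_{\rm post},
$$

with posterior moments

$$
\langle\mu\rangle_{\rm post} = \lambda\,\eta + (1-\lambda)\,\bar x,
\qquad
\langle\Sigma\rangle_{\rm post} = \lambda U + (1-\lambda)\bar C
 + \lambda(1-\lambda)(\bar x - \eta)(\bar x - \eta)^{\!\top}.
$$

Here $\bar x$ and $\bar C$ are the empirical mean and ($1/M$-normalized)
covariance of the encodings, and $(\eta, U)$ are the moments of a
*uniformly distributed* one-hot sample. The **MG score** of a sequence is
$\log p(y \mid X)$; higher means more human-like when the model is
learned on human sequences. It is a log *density*, not a log
probability, and routinely exceeds zero by thousands of nats at full
chain length. `mg_max()` returns the density at the mode
$y = \langle\mu\rangle_{\rm post}$, an upper bound over all inputs;
whether such a published maximum refers to the mode or to the best
valid one-hot vector is ambiguous, and the mode bound is what this
package computes (the mode is generally not a valid encoding, so the
bound need not be attained by any sequence).

Design choices worth knowing:

* **Prior over 21 states.** The "uniform sample" behind $(\eta, U)$ is
  uniform over the 21 states *including the gap*: $\eta_i = 1/21$ and $U$
  block-diagonal with within-position blocks
  $\tfrac1{21}I - \tfrac1{441}J$. Uniformity over the 20 amino acids
  alone would make block sums constant and $U$ singular; including the
  null state gives smallest eigenvalue $1/441 > 0$, which the density
  needs at every $\lambda > 0$.
* **$\lambda$ is the single regularization knob.** The NIW
  hyperparameters are not exposed separately; the implementation targets
  the posterior-predictive form above directly, with
  $\lambda \in (0, 1]$ interpolating between the data moments and the
  prior moments. $\lambda = 0$ is rejected rather than pseudo-inverted:
  with $M < N$ (the practical regime) the empirical covariance alone is
  singular. Degenerate alignment columns need no special casing — the
  $\lambda U$ term keeps the scale positive definite.
* **Biased covariance.** $\bar C$ uses the $1/M$ normalizer, matching
  the moment-matching form of the posterior expressions, so the
  $\lambda$ scale is interpretable.
* **$\lambda = 1$ limit.** The degrees of freedom diverge and the score
  becomes the normal log-density at the prior moments; the
  implementation switches to the exact Gaussian limit rather than
  evaluating the $t$ form at infinite $\nu$.

Correlation ablations (`ablate_correlations()`) zero either every
cross-position block of $\langle\Sigma\rangle_{\rm post}$ (`all_off`,
an independent-sites model) or only the blocks coupling VH with VL
positions (`interchain_off`), then refactorize. The regularization
weight is deliberately kept: re-selecting $\lambda$ for an ablated model
is an explicit, separate step, since published ablation analyses
re-optimize it (reported optima 0.027 and 0.067 bracket the default
search grid, 21 log-spaced values in $[0.005, 0.5]$).

## Distance baselines

$T_k$ is the mean Hamming distance from a query to its $k$ nearest
reference sequences; $T_{\rm all}$ averages over the whole ensemble.
Gaps count as an ordinary 21st symbol in the Hamming sum, and the
$k$-nearest selection uses the smallest $k$ distance *values*, so ties
cannot make the score depend on reference ordering. A CDR mask may be
excluded from the sum (the framework-only variant). The two-reference
score is implemented as
$s(A) = \bar d^{(m)}(A) - \bar d^{(h)}(A)$, i.e. positive when the query
is closer to the human ensemble. The published definition writes the
difference the other way round while stating that positive values
indicate human; since a human sequence necessarily has the *smaller*
human-ensemble distance, the two statements conflict, and this package
adopts the stated interpretation (positive ⇒ human) over the stated
formula, recording the flip here and in the function documentation.

## Classifier calibration

`roc_curve()` sweeps every distinct score value (plus $\pm\infty$) as a
threshold, with an explicit direction argument because MG scores point
up (higher = human) and distances point down. AUC is the trapezoid
area, equal to the Mann-Whitney concordance with ties counted one half.
Youden's index is implemented as its standard definition
$J = \mathrm{TPR} - \mathrm{FPR}$; a published variant that replaces
specificity by $TN/(TN+FN)$ is available behind
`formula = "printed"` but is presumed a typo, because the published
threshold diagnostics are consistent with $\mathrm{TPR}-\mathrm{FPR}$
and not with the variant. MCC with a zero denominator is defined as 0.
Threshold ties at equal Youden break toward classifying fewer
positives — conservative for humanization use, where a false "human"
call is the costlier error. The selected threshold is meant to be
frozen and carried unchanged to later query sets.

`select_lambda()` fits one model per grid value and picks the maximal
validation AUC. It requires explicit validation databases: whether a
published selection used held-out data or the test sets themselves is
ambiguous, so the API never silently reuses anything.

## CDR definitions

CDR positions follow the IMGT boundaries expressed in AHo coordinates:
VH 27–40, 58–68, 107–138; in the combined VHVL numbering (VL at
150–298) the VL CDRs are 176–189, 207–217, 257–287. A standalone VL
mask is obtained by shifting the combined VL ranges by −149. The six
printed ranges total 113 positions; published prose elsewhere counts
111 fixed positions (hence 187 rather than 185 mutable ones). The
discrepancy cannot be resolved from the ranges themselves; this package
follows the printed ranges and documents both numbers.

## Humanization

The optimization objective is the energy $E = -\log p(y \mid X)$, with
CDR positions frozen.

**Steepest descent** (`humanize_sd()`) evaluates, at every step, all
single mutations at all free positions and applies the best strictly
improving one, stopping when none improves — the nearest local optimum,
plus the optimal path to it (useful as a ranked list of "best next
mutations" at increasing distance from the murine origin). Ties break
toward the lowest position, then the alphabetically first residue, so
the procedure is fully deterministic. Deltas are computed incrementally
(below) and the trajectory is cross-checked against full rescoring in
the test suite.

**Simulated annealing** (`humanize_samc()`) proposes a uniform free
position and a uniform alternative residue, accepting with the
Metropolis probability $\min(1, e^{-\Delta E / T})$. The temperature
ladder starts at $T = 25.1$ and drops by $\Delta T = 0.5$ after a fixed
number of proposals per level until falling below $0.1$. The published
schedule spends $3.74\times10^6$ proposals per level (about
$1.9\times10^8$ total — cluster scale) and is available as the
`"full"` preset; the default `"desk"` preset keeps the identical
temperature ladder at 20,000 proposals per level. The *best-ever*
sequence, not the final one, is the headline output, since low-$T$
trapping can end a run off-optimum. One seeded generator drives the
whole run; identical seeds give byte-identical trajectories.

Gap proposals are excluded by default (`allow_gaps = TRUE` enables
them): whether humanization may introduce or remove gaps is unstated in
the sources, and the default avoids indel artifacts in a fixed-length
framework. An optional `alphabet` argument restricts proposal residues,
which the test suite uses to build exhaustively enumerable landscapes.

**Fast deltas.** A point mutation flips at most two bits of $y$. With
$S^{-1}$ materialized once per run and $v = S^{-1}(y - \mu)$ cached,
the change of the Mahalanobis form is $O(1)$ per proposal and the cache
update on acceptance is $O(N)$ (`mg_score_context()`,
`mg_score_delta()`, `mg_apply_mutation()`). Scoring alone never
materializes $S^{-1}$ — it uses triangular solves on the cached
Cholesky factor; both paths are tested to agree to $10^{-9}$. The
cached quadratic form is refreshed exactly at every temperature change
to stop incremental rounding drift over millions of updates.

`compare_to_reference()` scores a predicted humanization against an
experimentally humanized reference position by position: with residues
(original, humanized, predicted), the patterns (A,A,A) → TN,
(A,A,B)/(A,B,C) → FP, (A,B,A) → FN, (A,B,B) → TP, whence
$HD(p,h) = FP + FN$ and the usual rates.

## Synthetic data: what it emulates and what it does not

All tests run on generated ensembles, so the generators are first-class,
tested code:

* `profile_model()` / `sample_profile_db()` — independent per-site
  categorical profiles. Random profiles use a symmetric Dirichlet with
  concentration 0.1 over the amino acids, giving a median
  dominant-residue mass near 0.5 — emulating the strong per-column
  conservation of immunoglobulin framework positions — plus a fixed
  2% per-site gap probability so gap-handling code paths are always
  exercised.
* `coupled_model()` / `sample_coupled_db()` — a Potts-like Boltzmann
  distribution with per-site fields and sparse pairwise couplings,
  sampled by vectorized parallel single-site Gibbs chains (per-chain
  burn-in 100 sweeps, thinning 10 sweeps between draws). Exactness is
  certified against full enumeration of the $21^2$ state space at
  $L = 2$; mixing at the small lengths used in testing is fast.
* `make_species_pair()` — two coupled models sharing a random base
  profile: a `divergence` fraction of positions receives a field
  perturbation in the murine model, and couplings are placed at shared
  position pairs within the VH-like block, within the VL-like block and
  (optionally) across them, with each species drawing its own random
  permutation-matrix coupling table scaled by `coupling_strength`. The
  two ensembles therefore differ in covariation structure, not only in
  marginals — which is exactly what an independent-sites ablation
  cannot see. Defaults (`L = 30`, `divergence = 0.2`,
  `coupling_strength = 3`) are the fixture conditions used throughout
  the tests.

These generators make no attempt to emulate germline gene structure,
V(D)J recombination, somatic hypermutation statistics, or the length-298
AHo geometry of real repertoires. Passing tests therefore demonstrate
the *statistical machinery* — inference, scoring, calibration,
optimization — not classification performance on real immunoglobulin
data, which depends on curated learning repertoires outside the scope
of this package.

## Problem sizes and numerical tolerances

The test suite and the acceptance script work at desk scale, chosen so
the full suite runs in well under a minute of compute per file: species
fixtures at $L = 30$ with 400+400 learning, 200+200 validation and
200+200 test sequences ($N = 600$, comfortably in the $M < N$ regime
where regularization matters); toy optimization landscapes of at most
$4^4 = 256$ enumerable sequences; 100-model density-oracle batches at
$N \le 12$. Score agreement with the independent $t$-density oracle is
required at $10^{-8}$, sparse deltas at $10^{-9}$, the $N = 2$
normalization integral (computed in whitened coordinates, where the
integrand is radial) at $10^{-3}$, and Monte-Carlo assertions
(Gibbs exactness, Boltzmann occupancy) use pooled-cell chi-square
statistics at the 3-sigma level.

## Known limitations

* With realistic repertoire sizes $M \ll N$, learning-set scores sit
  far above test-set scores (overfitting of the learning ensemble);
  score *thresholds* must therefore be calibrated on held-out data,
  never on the learning set.
* The MG score is a sequence-statistics quantity only: it knows nothing
  of stability, solubility, expression or immunogenicity, and high-score
  proposals are candidates for further modelling, not final designs.
* The model scores full chains; it has no notion of paratope beyond the
  frozen CDR mask.
* Scores are densities: only comparisons under the same model (same
  $L$, $\lambda$, learning set) are meaningful.
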