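---
title: "Methods: the seqkernel string kernel and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the seqkernel string kernel and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqkernel)
```

## The model

`seqkernel` scores the similarity of two protein sequences without
aligning them. The construction is a convolution string kernel: every
contiguous k-mer of one sequence is compared with every contiguous
k-mer of the other, a k-mer pair is scored by the product of
per-position amino-acid similarities, and all of these scores are
summed.

The amino-acid similarity is not a log-odds matrix. Alignment methods
need additive scores because dynamic programming sums them along an
alignment path; a kernel multiplies per-position terms instead, so it
works directly with the *odds ratios*
$SM2(i,j) = SM(i,j) / (P(i)\,P(j))$, where $SM$ holds raw substitution
counts and $P(i)$ is its $i$-th row sum. Both row sums appear in the
denominator: that is the only normalisation that keeps $SM2$
symmetric, and symmetry of the Gram matrix is a precondition for being
a kernel at all. An NCBI-format integer matrix stores
$\mathrm{round}(\log_2 SM2)$, so `from_log_odds()` recovers an
approximation of $SM2$ as $2^{BL}$; the rounding is why the package
warns and re-checks positive definiteness on that route.

The amino-acid kernel is the Hadamard (entrywise) power
$K1 = SM2^{\circ\beta}$ with $\beta > 0$. The sequence kernel is

$$K_3(S,T) = \sum_{k=1}^{p}\; \sum_{u^k \subset S}\; \sum_{v^k \subset T}
  \;\prod_{i=1}^{k} K1(u_i, v_i), \qquad p = \min(k_{max}, |S|, |T|),$$

over contiguous (gap-free) k-mers, followed by the correlation
normalisation $\hat K_3 = K_3(S,T)/\sqrt{K_3(S,S)K_3(T,T)}$ and the
distance $D = \sqrt{2 - 2\hat K_3}$, a metric bounded by $\sqrt 2$.

Assumptions worth keeping in mind: the kernel sees sequences as bags of
positioned k-mers, ignores gaps entirely, and weights all k equally (a
weighted sum over k is a deliberate non-goal). Validity as a kernel
requires $SM2$ positive definite and $\beta > 0$.

## Parameters

* **`beta`** (dimensionless Hadamard exponent, default **0.2**). Small
  `beta` flattens `K1` toward the all-ones matrix; in the limit the
  kernel depends only on the sequence lengths (see below). Large `beta`
  sharpens the diagonal. The default 0.2 is the recommended operating
  point for fold-recognition use.
* **`k_max`** (residues, default **10**). Truncates the sum over k-mer
  lengths. The effective truncation for a pair is
  `min(k_max, |S|, |T|)`: the sum can never include k-mers longer than
  the shorter sequence, so `k_max` and the natural bound are combined
  rather than treated as alternatives. Runtime grows linearly in
  `k_max`.
* **substitution matrix** (default `default_ratio_matrix()`). The
  packaged matrix is synthetic (see below); `from_log_odds()` accepts
  real BLOSUM-family matrices, and `identity_ratio_matrix()` is a valid
  and surprisingly serviceable input — with it the kernel counts
  exactly matching k-mer pairs.

## The degenerate length-only regime

As $\beta \to 0$ every entry of $K1$ tends to 1. The all-ones matrix is
rank 1, hence *not* positive definite and not a kernel, but it admits a
closed form: $K_3(S,T) = \sum_{k=1}^{k_{max}} (n-k+1)(m-k+1)$, a
function of the lengths alone, and the normalised value is exactly 1
for any two sequences of equal length. The package therefore never
reaches this regime silently by a tiny `beta`; it is exposed only as an
explicit diagnostic (`ones_ratio_matrix()`, CLI `--matrix ones`, which
rejects a simultaneous `--beta`). `limit_semikernel()` provides the
closed form, and the test suite checks the kernel reproduces it
exactly.

## Numerical choices

* **Recursion.** `k3_recursive()` exploits
  $K_2^k(u,v) = K_2^{k-1}(u',v')\,K1(u_k,v_k)$: layer $k$ is an
  elementwise shift-multiply of layer $k-1$ with the base matrix
  $K1[s_i, t_j]$, giving $O(nmk_{max})$ work with two layers in memory.
  The brute-force enumeration `k3_naive()` ($O(nmk_{max}^2)$) is kept
  as the independent oracle; the suite checks agreement to relative
  $10^{-9}$ on hundreds of randomized instances.
* **Accumulation** is in double precision, per-k layers summed in
  increasing k. A non-finite accumulation raises an error advising a
  smaller `beta` or `k_max` rather than propagating `Inf`.
* **Clamping.** Self-normalisation makes $\hat K_3(S,S) = 1$
  analytically; round-off excursions in $(1, 1+10^{-9}]$ are clamped to
  1 before the distance transform, and anything larger raises an error
  (it indicates an invalid kernel upstream, not round-off).
* **Positive definiteness** is declared when the smallest eigenvalue
  exceeds $10^{-8}$ times the largest. The threshold is *positive*, so
  positive-semidefinite matrices with a numerically zero eigenvalue —
  the all-ones matrix — are reported as not definite, which is the
  scientifically meaningful answer for "is this a kernel".
* **Zero overlap.** With the identity matrix two sequences sharing no
  residue give $K_3 = 0$; the correlation kernel returns 0 flagged with
  `zero_overlap` instead of erroring, since the distance $\sqrt 2$ is
  still meaningful.

## Evaluation procedures

ROC analysis sweeps a threshold over all pairwise distances; pairs at
or below it are called positive. In pooled mode a pair is truly
positive when its members share a group, whatever the group; per-group
mode restricts positives to one named group, every other pair
(including pairs inside other groups) counting as negative — pooled
negatives likewise include any pair with differing labels. The AUC is
the midrank Mann–Whitney statistic, which the suite verifies equals the
trapezoidal area under the stepwise curve and matches the independent
`pROC` implementation; ties therefore contribute 1/2, making the
all-tied AUC exactly 0.5.

Classification experiments split every group at random into halves
(the extra member of an odd group goes to training), assign each test
sequence to the group with the smallest *mean* distance to its training
members, and summarise a confusion matrix by its trace over its total.
Two interpretation choices were genuinely open and are fixed as
follows: the "mean normalised distance" is the arithmetic mean of the
already self-normalised kernel distances (no further normalisation is
applied, none being defined), and ties between group means break to the
lexicographically smallest label, making runs bit-reproducible under a
seed. The default of 1000 repeats is configurable; tests use at most
100\. The RANDOM baseline assigns iid uniform(0,1) distances and
classifies at the 1/G chance level for G balanced groups.

## Synthetic data: what it does and does not emulate

`make_families()` draws one random ancestor per family (length uniform
on 100–200 by default, iid uniform residues) and derives each member by
point substitutions at `substitution_rate` (to a uniformly chosen
*different* residue) plus single-residue insertions/deletions at
`indel_rate` (default 0.05). Defaults — 4 families × 10 members,
`substitution_rate` 0.5 — give within-family identity around 25–30%
against a ~5% random background: a desk-scale stand-in for curated fold
datasets of low-identity relatives.

What it deliberately does not emulate: empirical residue composition
(the background is uniform; substitute your own matrix-derived
frequencies if composition matters), block indels (the kernel is
gap-free, so indel realism is secondary), and real fold constraints —
members diverge neutrally from one ancestor, with no selection. Passing
tests on this generator show the machinery is correct and calibrated;
they do not certify performance on real proteins, where composition
bias, domain architecture and true structural convergence all matter.

The problem sizes used throughout the tests — sequences up to ~300
residues, 40–50 sequence sets, ≤200 randomized oracle comparisons, 100
classification repeats — were chosen as the smallest scales at which
every property under test is well resolved.

## Known limitations

* Cost is $O(nmk_{max})$ *per pair*: fine for datasets of hundreds of
  sequences, not for database-scale search.
* Kernel scores carry no significance estimate (nothing like an
  E-value); ranking quality is assessed externally via ROC/AUC.
* Gap-free k-mers and the unweighted sum over k are design choices
  inherited from the kernel's definition; weighted variants are out of
  scope.
* At moderate divergence the pooled-AUC advantage of the kernel over a
  random baseline measured by the acceptance suite is around 0.2 —
  clearly above chance, but far from the separation a structural
  comparison achieves; sequence-only fold recognition at low identity
  remains intrinsically hard.
* The packaged substitution matrix is synthetic (deterministic,
  positive definite by construction, BLOSUM-like diagonal dominance).
  It exists so the package is usable and testable without downloads;
  analyses of real proteins should supply a real matrix via
  `from_log_odds()`.
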