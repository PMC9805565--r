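---
title: "Methods: smooth alignment, joint MSA/MRF learning, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smooth alignment, joint MSA/MRF learning, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models the package implements, the conventions
and numerical choices behind them, the design decisions that were genuinely
open, and what the synthetic-family experiments do and do not demonstrate.

# The smooth alignment kernel

## Model

Classic pairwise alignment maximizes, over monotone alignment paths, the sum
of match scores $a_{ij}$ for aligned residue pairs plus gap penalties for
unmatched residues.  The smooth relaxation replaces that maximum with a log
partition function at temperature $T$:

$$ S(a) \;=\; T \,\log \sum_{\text{paths } \pi} \exp\!\big(\mathrm{score}(\pi)/T\big), $$

which induces a Gibbs distribution $p(\pi) \propto e^{\mathrm{score}(\pi)/T}$
over paths.  Two properties make this useful inside learning pipelines:

* $S$ is smooth in $a$, and $\partial S / \partial a_{ij}$ equals the
  posterior probability that residues $i$ and $j$ are aligned — the expected
  match-indicator matrix under $p(\pi)$.  `smooth_posterior()` returns this
  matrix exactly (a reverse sweep over the dynamic program, not a numerical
  derivative).
* As $T \to 0$, $S$ decreases to the hard optimum and the posterior
  concentrates on the optimal path; at larger $T$ many plausible alignments
  contribute, which is valuable early in training when the score function is
  still poor.

## The path space and the dynamic program

The recursion is the standard three-state affine machine — match $M$,
deletion $D$ (query residue unmatched), insertion $I$ (other-sequence
residue unmatched) — with logsumexp in place of max.  A path is a monotone
move sequence; with affine gaps, `open` is charged when a gap state is
entered from a different state and `extend` when it is re-entered, so the
cost of a mixed gap segment depends on how deletions and insertions are
interleaved.  Linear gap mode is exactly the specialization
`open == extend == gap` (the test suite asserts agreement to 1e-8).

Conventions, each isolated behind `align_params()`:

* **Local mode** (Smith–Waterman): paths begin and end with a match; the
  empty path is valid with score 0; the final value aggregates over all
  match-ending cells plus the empty path.
* **Global mode** (Needleman–Wunsch): paths consume both sequences
  completely; terminal gaps are charged like internal ones.
* **Restricted turns**: the transition deletion→insertion is forbidden, so
  of the two orderings of an adjacent insertion/deletion pair only
  insertion-first is counted.  Without this, path counting double-counts
  equivalent gap arrangements, which biases the smooth distribution toward
  near-diagonal alignments.  The exact transition to forbid is a convention;
  forbidding the opposite ordering would be equivalent by symmetry.

Because these conventions determine the partition function, the package
ships a brute-force oracle (`enumerate_paths()`, `brute_force_smooth_score()`,
`brute_force_posterior()`) that enumerates the *same* path space
definitionally and is tested against the dynamic program across all
mode combinations at tolerance 1e-8.

## Numerics

* All sums are logsumexp with the shifted-max identity.
* Disallowed states carry a finite sentinel of $-10^9$ rather than
  $-\infty$, so every quantity stays differentiable; the sentinel is far
  below any reachable score (inputs are validated finite, and the stated
  operating range is scores up to about $\pm 10^3$ at temperatures down to
  about $10^{-2}$).
* Temperature is applied by scaling scores and penalties by $1/T$ inside the
  recursion and multiplying the result by $T$, so the $T \to 0$ limit
  recovers the hard score on the same scale.
* Hard-alignment traceback breaks ties with the fixed priority
  match > insertion > deletion, and local mode takes the first maximal end
  cell in row-major order, so results are bitwise deterministic.
* Batched alignment slices each padded score matrix to its true lengths
  before the recursion, making padding invariance structural rather than a
  masking convention.

## Gradients without autodiff

R has no automatic differentiation, so the package computes every gradient
in closed form.  The posterior is the exact first derivative of the smooth
score (reverse sweep).  Training additionally needs the derivative *of the
posterior* with respect to the scores — a Hessian of the smooth score.  The
C++ core obtains the required vector–Jacobian products by running the
forward and reverse sweeps on dual numbers (forward-over-reverse), seeding
the tangent with the incoming cotangent; symmetry of the Hessian makes this
directional derivative exactly the needed VJP.  All of this is verified
against central finite differences in the test suite.

# The learned alignment module

Each residue is embedded by a single linear convolution of window $2w+1$
(zero-padded, so position $i$ depends only on residues $i-w..i+w$) applied
to the one-hot sequence; the score matrix between the query and sequence
$k$ is the dot-product matrix of their embeddings.  Running the smooth
aligner on every score matrix and contracting each posterior with its
one-hot sequence yields the *soft MSA*: for each sequence and query column,
an expected residue distribution whose missing mass is gap probability.

Choices and defaults:

* Alphabets: 20 amino acids + `X` (all-zero one-hot) for protein; `ACGU` +
  `N` for RNA.  Unknown symbols contribute nothing to scores or profiles.
* The convolution is linear (no activation, single layer) — the minimal
  architecture that lets a score express $k$-mer context rather than plain
  residue identity.  Depth/nonlinearity were deliberately left out; the
  convolution's job here is alignment scoring, not representation learning.
* `filters` defaults to 512 and `window_half_width` to 9 in the
  configuration surface; the synthetic studies use 64 filters and $w=5$,
  which the recovery experiments show is ample at family sizes of a few
  hundred sequences and 30 columns (and an order of magnitude faster).
* Initialization: kernel entries $\mathcal N(0, (\mathrm{gain}/\sqrt{\mathrm{fan\_in}})^2)$.
  Because the implied score $a_{ij} = f(x_i)^\top f(y_j)$ is a PSD quadratic
  form in the one-hot windows, a *random* encoder already scores identical
  windows positively — alignment signal exists before any training.  The
  training loops use gain 2 so that confident matches sit well above the gap
  penalties: the posterior then saturates on them, which (see below) is what
  protects the bootstrap phase from its degenerate optimum.
* Training alignment mode: global with affine gaps (`open = -3`,
  `extend = -0.3`, temperature 1).  The synthetic families are full-length
  homologs, for which global alignment is the right model and keeps every
  sequence in play; local mode remains available for domain-in-context
  inputs.

# The MRF and masked-language-model training

The pairwise model over query columns is a Potts model: site fields $v_i$
($L \times A$) and couplings $W_{ij}$ stored as one flat
$(LA)\times(LA)$ symmetric matrix with zero diagonal blocks, parameterized
as $W = (\tilde W + \tilde W^\top)/2$ with diagonal blocks zeroed so
symmetry is structural.

The masked-language-modelling loss masks each (sequence, column) entry
independently at rate 0.15 (re-drawn until every sequence has at least one
mask).  Masked entries are replaced by the all-zero profile — they
contribute nothing to any neighbour's energy.  The conditional at column
$i$ is the softmax over residues of
$v_i + \sum_{j \ne i} W_{ij}\, p_{sj}$, evaluated against the pre-mask
profile as target; profile mass not assigned to any residue (gap or
insertion mass) is spread uniformly over the alphabet in the target, so
unaligned content is deliberately unpredictable and the model is rewarded
for aligning residues it can explain.  The regularizer is
$(\lambda_v \lVert v\rVert^2 + \tfrac{1}{2}\lambda_w (L-1)(A-1) \lVert W\rVert^2)/B$
with $\lambda_v = 0.01$, $\lambda_w = 0.001$ — the conventional scaling that
penalizes couplings in proportion to their number.  $\lambda_w$ larger by a
factor of ten visibly suppresses true couplings at these family sizes
(recovery drops), which is why the default is the smaller value.

Contact scores are Frobenius norms of the coupling blocks with the standard
average-product correction
$\mathrm{score}_{ij} = \lVert W_{ij}\rVert_F - r_i r_j / \bar r$; APC
removes the rank-one background that conservation and sampling noise induce
(it annihilates exactly rank-one raw matrices, which the tests verify).
Pairs closer than 6 positions along the chain are excluded from ranking and
truth at evaluation time.

# The two training phases

**Alignment bootstrap (BasicAlign).**  The exported objective
`basic_align_loss()` is the column-agreement (purity) loss: the sum of
squared differences between each sequence's soft profile row and the column
mean.  This objective has a degenerate global optimum — aligning nothing
makes every profile row equal the (zero) column mean — and that optimum is
first-order downhill from essentially everywhere, because each sequence's
own residue always sits above the column mean.  Two measures make the
bootstrap useful anyway, both documented as this package's own design:

1. `run_basic_align()` descends purity **plus a coverage term**
   (`coverage_weight` × total gap mass, default 4), which removes the
   degenerate minimum outright while leaving the purity signal to decide
   *where* residues align.
2. The gain-2 initialization keeps correct matches saturated, so the purity
   gradient acts mainly on genuinely ambiguous regions.

Even so, purity alone has further degenerate directions (for example,
merging two columns that prefer the same residue raises purity), so the
bootstrap is run for a deliberately modest number of steps (default 30, Adam
at 0.003) and treated strictly as an initializer.

**Joint training (TrainMRF).**  The masked-language-modelling loss is then
descended jointly in the MRF (Adam, 0.01) and the encoder (Adam, 0.001,
through the posterior's Hessian–vector products), 150 steps, full batch.
Unlike purity, this objective genuinely anchors the true alignment: columns
predict best when residues are placed where the fields and couplings that
generated them live, and gap mass costs $\log A$ per masked entry, so the
phase both repairs residual misalignment from the bootstrap and resists
collapse.  On the synthetic studies it raises ground-truth match-pair
recovery substantially over the bootstrap output (the acceptance script
recomputes this as `msa_match_recovery`).

**Fixed-alignment baseline (MLM-GREMLIN).**  The identical training loop
with hard one-hot profiles from a fixed alignment and no encoder.  Both
entry points share one core, so running the joint trainer with a frozen
encoder on fixed profiles reproduces the baseline's loss trajectory
bit-for-bit — a tested invariant, not an approximation.

# The synthetic study design

`simulate_family()` generates families with complete ground truth:

1. **Planted MRF** (`plant_mrf()`): 20 contact pairs at separation ≥ 6
   among $L = 30$ columns; each pair's coupling block puts weight
   `strength` on a random residue permutation.  Site fields are
   $\mathcal N(0, 3.0)$ at non-contact columns and $\mathcal N(0, 1.5)$ at
   contact columns.  The split reflects two facts that hold in real
   families and are both *required* for the experiment to be meaningful:
   columns must be conserved for the family to be alignable from sequence
   alone (with near-uniform columns, Gibbs samples from the model are
   essentially independent sequences and carry no alignment signal
   whatsoever), while covariation is only observable where residues vary,
   so contact columns must not be frozen by their fields — co-evolving
   positions in real proteins are likewise less conserved than structural
   anchors.
2. **Gibbs sampling**: independent single-site chains, one per sequence,
   30 burn-in sweeps from uniform starts.  Column marginals and pairwise
   mutual information are validated against the model in the tests.
3. **Indel corruption**: per non-query sequence, deletions i.i.d. at 5%,
   insertions at 5% per slot with geometric(0.5) lengths and uniform
   residues; the query is left intact so its coordinate system defines the
   columns.  The exact match path of every corrupted sequence is recorded
   and exactly inverts the corruption (tested on every draw).
4. **Strength calibration** (`calibrate_strength()`): bisection on
   `strength` until the fixed-alignment baseline on the true alignment
   recovers a target fraction (default 0.9) of planted contacts in its
   top-20 predictions.  Recovery is not perfectly monotone in strength —
   very strong couplings slow the Gibbs mixing — so the bisection returns
   the smallest tested strength that met the target, and a warning (plus
   the upper bound) if none did.

What the generator does **not** emulate: phylogenetic correlation between
sequences (chains are independent — a star topology), indel hotspots or
length variation beyond the i.i.d. model, compositional biases of real
proteins, and alignments whose truth is structural rather than
generative.  Passing the synthetic studies therefore demonstrates that the
machinery — differentiable alignment, joint training, contact extraction —
works as designed under controlled conditions; it does not certify
performance on natural families, where signal strength, depth and alignment
difficulty vary enormously.

# Problem sizes and runtime

The studies use $L = 30$, 400 sequences, 20 contacts, 64 filters, $w = 5$,
30 bootstrap steps and 150 joint steps — sizes at which the full pipeline
(calibration, family, baseline, control, joint training, evaluation) runs
in a few minutes on one CPU, which keeps the whole experiment comfortably
reproducible as part of routine testing while leaving wide margins on every
threshold it is checked against.

# Known limitations

* The bootstrap objective's degeneracies are managed, not removed: very
  long bootstrap runs will still distort an alignment, and the defaults
  assume families with meaningful conservation.
* The MRF has no explicit gap state; gap mass is simply unexplained
  probability.  Columns with heavy gap content therefore contribute mostly
  uniform targets.
* Memory for couplings is $O(L^2 A^2)$, which is fine at domain scale
  ($L \lesssim 300$ for proteins) but not for full-length multi-domain
  sequences.
* The aligner is quadratic-time per pair with no banding, and the posterior
  and VJP sweeps cost a small constant multiple of the forward pass.
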