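---
title: "Fused sequence-profile representations for sub-nuclear localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused sequence-profile representations for sub-nuclear localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnucfuse)
```

## The problem

Proteins of the cell nucleus carry out their function in distinct
sub-nuclear compartments — nucleolus, chromatin, nuclear speckles, the
nuclear pore complex and others — and mislocalization is implicated in
disease. Predicting the compartment from sequence is a multi-class
classification problem whose difficulty is dominated by how the variable
length protein sequence is turned into a fixed-length numeric vector.
`subnucfuse` implements a family of such representations, a weighted
fusion of two of them with per-class balance factors found by a genetic
algorithm, supervised dimension reduction by linear discriminant analysis
(LDA), and a cosine-similarity k-nearest-neighbor (KNN) classifier, with
stratified cross-validation and jackknife evaluation.

## Single representations

**Dipeptide composition (DipC, 420D).** For a sequence of length $L$ over
the 20-letter alphabet (alphabetical order throughout), the first 20
components are residue frequencies $aa_i / L$ and the remaining 400 are
ordered-dipeptide frequencies $cr_i / (L-1)$. Both blocks sum to one. The
dipeptide $(a, b)$ is stored at position $20 + 20(\mathrm{index}(a) - 1) +
\mathrm{index}(b)$; any fixed bijection over ordered pairs would do, and
this row-major layout is chosen because it is canonical and directly
testable. Sequences with $L < 2$ are rejected rather than imputed.

**Pseudo-amino acid composition (PseAAC, $20 + 2\lambda$ D).** The
amphiphilic form: 20 composition components followed by $\lambda$ tiers of
sequence-order correlation factors, hydrophobicity and hydrophilicity
interleaved within each tier,

$$\tau_{2k-1} = \frac{1}{L-k} \sum_{i=1}^{L-k} h_1(R_i)\, h_1(R_{i+k}),
\qquad
\tau_{2k} = \frac{1}{L-k} \sum_{i=1}^{L-k} h_2(R_i)\, h_2(R_{i+k}),$$

with both scales standardized to zero mean and unit population standard
deviation over the 20 residues. The final vector is normalized by the
shared denominator $\sum f + w \sum \tau$ so all components sum to one.
Note the correlation factors are signed: they are products of centered
scale values, so only the composition block is guaranteed nonnegative.
Defaults are $\lambda = 10$ (a 40D vector; requires $L \ge 11$) and
$w = 0.05$, the conventional weighting in the PseAAC literature. The
scales (Tanford-style hydrophobicity, Hopp–Woods-style hydrophilicity)
ship as data in `pseaac_scales()` and are arguments of
`encode_pseaac()`, since different published servers use slightly
different tables.

**Compressed PSSM (210D).** A position-specific scoring matrix from an
iterative profile search is an $L \times 20$ integer matrix $P$ of
log-odds scores, with columns remapped on read to alphabetical residue
order whatever the source layout. Because $L$ varies, the package forms
$M = P^\top P$, a symmetric $20 \times 20$ (400-entry) matrix independent
of length, and keeps its 210 non-redundant entries — the lower triangle
including the diagonal, read row by row. Scores are used as read; no
scaling or squashing is applied before the product, so the magnitude of
$M$ grows with $L$. (Generating PSSMs is out of scope; the package reads
the standard ASCII report or a plain 20-column TSV.)

## Fusion with per-class balance factors

For a dataset with $n$ locations, a composition-type block $A_i$ (DipC or
PseAAC) and a profile block $B_i$ are fused per class $i$ as

$$V_i = [\, r_i A_i,\; (1 - r_i) B_i \,], \qquad r_i \in (0, 1),$$

giving the 630D DipPSSM or 250D PseAAPSSM representation. $r_i = 0.5$
recovers the usual equal-importance concatenation; the point of the
per-class factor is that different compartments are better characterized
by different information sources.

A subtlety the fusion definition leaves open is prediction time: a query
protein has no class, hence no factor. Two modes are provided.
*Candidate-class* weighting (the default, and the only label-free option)
fuses both vectors with the factor of the training neighbor's class, so
every comparison happens in that class's weighted space. *True-label*
weighting fuses every sample with its own class factor and is exposed for
fitness evaluation during optimization, where all samples are labeled.
The true-label mode must be interpreted with care: at extreme factors a
sample weighted into one block is nearly orthogonal to samples weighted
into the other, so class identity leaks into the geometry and
cross-validated error under this mode can collapse to zero for almost any
assignment of distinct factors. This is why it is not the default
anywhere, including inside the optimizer.

Both blocks are used on their natural scales by default, because the
fusion weight applies directly to the representations. The raw $P^\top P$
magnitudes are orders of magnitude larger than frequency blocks, so under
cosine similarity the profile block dominates any mid-range factor; an
optional per-feature z-scoring (`standardize = TRUE`, always fitted on
training folds only) puts the blocks on comparable scales and makes
intermediate factors effective. It is off by default throughout.

## Searching for the balance vector

The balance vector $R = (r_1, \dots, r_n)$ is found by minimizing the
fitness error, one minus the overall success rate of a stratified K-fold
cross-validation (default $K = 3$ inside the search, $k = 1$ neighbors)
of the fused candidate-class KNN classifier. The partition is drawn once
per search seed and frozen, so the optimizer sees a deterministic
function; block Gram matrices are precomputed once, making each fitness
evaluation $O(N^2)$ without re-encoding.

The initial population is produced greedily: draw a random order of the
$n$ coordinates, start all factors at 0.5, and scan each coordinate in
turn over the grid $0, 0.01, \dots, 1$ (endpoints clamped to
$[10^{-6}, 1 - 10^{-6}]$ to respect the open interval), keeping the value
with the lowest fitness error; ties keep the smallest grid value. Fifty
such restarts form the default initial population. A real-coded genetic
algorithm then refines it: tournament selection of size 2, arithmetic
crossover ($\beta p_1 + (1-\beta) p_2$ with uniform $\beta$), additive
Gaussian mutation (sd 0.05) reflected into the open interval, generational
replacement with one elite, stopping after 100 generations or 20 without
improvement. All operator choices beyond "selection, crossover, mutation,
replacement" are fixed here for reproducibility; every random draw stems
from the single integer seed in `search_config()`.

A known limitation, demonstrated in the package's own experiments: when
the two blocks live on very different scales, the fitness can contain
coordinate-coupled basins (improving one class's factor only pays off if
a second class's factor moves simultaneously), which a one-coordinate
scan cannot cross and which a GA population whose restarts all converged
to the same point cannot recombine out of. On synthetic data with the
class signal split to extremes, the search recovers the correct extreme
factors in most but not all seeded draws (7 of 10 under the default
configuration). Standardizing the blocks removes the basin but also
flattens the fitness on well-separated data, in which case the recovered
factors are tie-determined rather than signal-determined. This is an
honest property of the search as specified, not a tuning target.

## Dimension reduction

LDA maximizes $J(W) = |W^\top S_B W| / |W^\top S_W W|$ with the standard
within- and between-class scatter matrices; the columns of the projection
solve the generalized eigenproblem $S_B w = \lambda S_W w$, so at most
$C - 1$ informative components exist for $C$ classes (8 components for a
nine-location dataset). The solver whitens with the symmetric inverse
square root of $S_W$ and eigendecomposes the whitened $S_B$ — the
contract is the residual of the generalized eigenequation, not the
algorithm. Because the fused representation has $d = 630$ dimensions and
typical datasets have fewer samples, $S_W$ is usually singular; the
default policy adds a ridge of $10^{-6}\,\mathrm{tr}(S_W)/d$ to its
diagonal before solving and records the value in the model. With
`ridge = "off"` a singular $S_W$ is a hard error. Column signs are fixed
(largest-magnitude entry positive) so serialized models reproduce.

## Classification and evaluation

The KNN classifier ranks training samples by cosine similarity
$\cos(u, v) = u \cdot v / (\|u\| \|v\|)$ and takes the majority label of
the $k$ most similar, with deterministic tie rules: similarity ties at
the neighborhood boundary resolve to the smaller training index, vote
ties to the class with the larger summed similarity, then the smaller
class code. The neighborhood size is chosen by scanning $k = 1..10$ for
the best mean overall success rate — a model-selection loop in the
evaluator, not part of the model itself.

Evaluation is repeated stratified K-fold cross-validation (default 10
folds; 5 repeats by default, with 50 the full-scale setting, chosen as a
balance of precision against runtime for routine use) and the
deterministic jackknife ($K = N$). Every trainable stage — z-scoring if
enabled, LDA, the stored KNN table, and true-label fusion — is fitted on
training folds only; held-out folds are predicted with candidate-class
weighting, and a leakage test asserts that corrupting held-out features
after fitting changes nothing fitted. Reported per class are the
one-vs-rest sensitivity (identical, on pooled predictions, to the
per-class success rate $T(i)/N(i)$), specificity, accuracy and Matthews
correlation coefficient, with MCC defined as 0 when its denominator
vanishes, plus the overall success rate $\sum_i T(i) / \sum_i N(i)$. The
balance vector is, by default, optimized once per run rather than inside
every repeat; re-optimizing per split is available
(`optimize_balance()` on each training subset) and the once-per-run
default is a deliberate, documented shortcut matching common practice.

## Synthetic study conditions

Real benchmark corpora for this task require profile searches against
large sequence databases, so the package ships a generator,
`generate_synthetic()`, that emulates the statistical structure the
method assumes: classes separable through residue composition and/or
profile columns. Per class, a residue profile
$\mathrm{softmax}(s_c \cdot \gamma \cdot z_c)$ (with $z_c$ standard
normal, $\gamma$ the concentration, $s_c$ the class's `signal_split`)
generates i.i.d. sequences; PSSMs are a shared baseline column profile
plus a class shift of magnitude $(1 - s_c)$ times `pssm_profile_shift`
plus Gaussian noise, rounded and clipped to the typical log-odds range
$[-16, 13]$. `signal_split` therefore places each class's discriminative
signal in the composition block ($s_c = 1$), the profile block
($s_c = 0$) or between.

Defaults — 3 classes of 15 proteins, lengths 30–60, concentration 1,
shift 3, noise sd 1, split 0.5 — were chosen once to resemble a small,
clearly structured localization dataset in which both blocks carry
signal; they make the default conditions nearly separable, which is the
regime the qualitative claims (fusion at least as good as either block;
LDA helping or not hurting at every $k$) are tested in. What the
generator does *not* emulate: homology between proteins within a class,
realistic dipeptide autocorrelation, position-dependent PSSM structure
along the sequence, and the long-tailed class-size imbalance of real
nuclear corpora. Passing tests on this generator demonstrate the
machinery is correct and the orderings hold under its assumptions; they
do not certify accuracy levels on real proteomes.

For the balance-recovery experiment specifically, two classes carry their
signal purely in the composition block and two purely in the profile
block (`signal_split = c(1, 1, 0, 0)`): with a single class at an
extreme, the other block still separates it — deviation from the shared
baseline is itself a signal — and the recovery question would be
ill-posed.

## Numerical choices and degenerate inputs

* Grid endpoints and all search iterates are confined to
  $[10^{-6}, 1 - 10^{-6}]$; operator outputs outside are reflected back.
* Zero-norm vectors make cosine similarity undefined and are rejected at
  fit and predict time with the offending row named.
* MCC with a zero denominator is 0; per-class SE/SP are `NA` only if a
  class is absent from the evaluated pool.
* Non-standard residues (B, Z, X, U, O, `*`) abort a read under the
  default `strict` policy or are removed, with a count, under
  `skip-unknown`; an emptied sequence is an error.
* PSSM dialect rows with the wrong field count fail with the 1-based row
  number; positions in all error messages are 1-based.
* Eigenvalues of the whitened problem are clamped at zero before ranking;
  the retained dimension is additionally capped by the rank of $S_B$.

## Reproducibility

Every stochastic stage takes an integer seed and restores the caller's
RNG state afterwards. Fold partitions, greedy scans, GA runs and the
generator are bit-reproducible given their seeds; the jackknife is
seed-free by construction. The CLI (`simulate`, `encode`, `optimize`,
`evaluate`) echoes its configuration into a manifest next to every
output.
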