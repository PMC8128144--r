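---
title: "Methods: ensemble drug-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble drug-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmaf)
```

## The prediction problem

Drug repositioning asks which approved drugs might treat which diseases.
The data are a binary association matrix $Y \in \{0,1\}^{m \times n}$
($Y_{ij} = 1$ iff drug $i$ is recorded to treat disease $j$), a drug-drug
similarity matrix $S^r \in [0,1]^{m \times m}$ (chemical, e.g. Tanimoto on
2D fingerprints) and a disease-disease similarity matrix
$S^d \in [0,1]^{n \times n}$ (phenotypic, e.g. text-mined OMIM similarity).
Both similarity inputs are symmetric with unit diagonal. The zeros of $Y$
are *unlabeled*, not negative: most unknown pairs are untested. The task is
to rank unknown pairs so that true but unrecorded associations come first.

Two structural assumptions drive everything downstream: similar drugs tend
to treat similar diseases (so similarity graphs carry signal about $Y$),
and $Y$ is approximately low-rank (therapeutic classes and disease families
induce block structure). The package combines three predictors that exploit
these assumptions in different ways and fuses their outputs, on the
observation that their errors are partly independent.

## Stage 1: weighted K-nearest-known-neighbor completion

New drugs and diseases have all-zero profiles, and sparse rows give every
downstream method little to work with. `wknkn_complete()` replaces each
zero with a likelihood estimate from the entity's $K$ nearest *known*
neighbors — entities with at least one recorded association. For drug $p$
with ranked known neighbors $r_1, \dots, r_K$ (by similarity, descending):

$$Y_r(p) = \frac{\sum_{i=1}^{K} T^{\,i-1} S^r(r_i, r_p)\, Y(r_i)}{\sum_{i=1}^{K} S^r(r_i, r_p)},$$

symmetrically $Y_d(q)$ for diseases, then
$Y \leftarrow \max(Y, (Y_r + Y_d)/2)$ elementwise. Known positives are
never erased, and because $T \le 1$ the weights are dominated by the
similarity normalization, keeping every entry in $[0,1]$.

Parameter defaults are $K = 5$ neighbors and decay $T = 0.5$
(dimensionless). Choices the formulas leave open, resolved here:

* **"Known"** means at least one association in the *training* matrix.
  This reading is what makes the de-novo scenario work: a new drug borrows
  profiles only from drugs that have something to lend.
* **Self-exclusion.** An entity is never its own neighbor; with unit
  self-similarity it would dominate the weight mass and leak its own
  (empty) profile.
* **Ties** in similarity break by ascending index, so results are
  deterministic; fewer than $K$ known neighbors means all are used; no
  known neighbors (or all zero similarity) leaves the contribution at
  zero rather than failing.
* Completion uses the **input** similarities, not the learned ones: it is
  the first stage, and the similarity learner consumes its output.

The completed matrix is a distinct artifact (`completed = TRUE`);
re-completing a completed matrix is refused, so the fractional entries can
never be mistaken for binary input.

## Stage 2: linear neighborhood similarity

Input similarities are noisy and their scales are not comparable across
the two sides. The pipeline therefore learns, for each entity, sparse
reconstruction weights over its neighborhood and uses those as a directed
similarity graph. With $x_i$ the entity's feature vector and
$N(x_i)$ its $K$ nearest neighbors by Euclidean distance:

$$\min_{\omega_i}\; \omega_i^\top (G_i + \lambda I)\,\omega_i
\quad \text{s.t.} \quad \textstyle\sum_j \omega_{i,j} = 1,\; \omega_{i,j} \ge 0,$$

where $G_i[j,l] = (x_i - x_j)\cdot(x_i - x_l)$ is the neighborhood Gram
matrix (symmetric PSD by construction). The row-stacked solutions form
$S^{r*}$ (drugs) and $S^{d*}$ (diseases): each row a probability vector
supported on at most $K$ entries, zero diagonal, *not* symmetric — and
used as produced, since label propagation wants a row-stochastic operator.

Decisions taken where the formulation is open:

* **Feature vectors** are the rows (drugs) / columns (diseases) of the
  WKNKN-completed association matrix. Interaction profiles are the one
  feature space both sides share, and completion has just made them
  non-degenerate for new entities; this also keeps the pipeline
  self-contained (no raw chemistry needed after the input similarities).
* **$\lambda = 1$** (default) regularizes toward even weight spread;
  $K = 100$ neighbors, capped at $p - 1$ for small datasets.
* The QP is solved by dual active-set quadratic programming
  (`quadprog`); $G_i + \lambda I$ is positive definite for $\lambda > 0$.
  For $\lambda = 0$ with singular $G_i$ a vanishing ridge ($10^{-10}$,
  escalated on failure) makes the solve well-posed; the minimizer may then
  be non-unique and only its objective value is meaningful.
* Tiny negative weights from floating point are clipped at zero and the
  row renormalized, preserving the simplex invariant exactly.

## Stage 3: three base predictors

**Label propagation (LPRIA).** Iterating
$Y_{t+1} = \alpha S^{*} Y_t + (1-\alpha) Y_0$ converges, for
$0 < \alpha < 1$ and row-stochastic $S^{*}$, to
$(1-\alpha)(I - \alpha S^{*})^{-1} Y_0$. The default implementation is the
closed form via one linear solve per side (never an explicit inverse);
$I - \alpha S^{*}$ is strictly diagonally dominant, hence nonsingular. The
iterative mode is retained as an independent check (the two agree to
$10^{-8}$ in the test suite). Drug-side and disease-side propagations are
averaged. Every iterate is a convex combination of values in $[0,1]$, so
scores are probabilities. Default $\alpha = 0.5$: equal weight to retained
initial labels and absorbed neighbor labels.

**Graph-regularized NMF (NMFRIA).** Factors $W \ge 0$ ($m \times k$),
$H \ge 0$ ($n \times k$) minimize

$$\|Y - WH^\top\|_F^2 + \lambda_l(\|W\|_F^2 + \|H\|_F^2)
 + \lambda_r \operatorname{Tr}(W^\top L_r W)
 + \lambda_d \operatorname{Tr}(H^\top L_d H)$$

by multiplicative updates, e.g.
$w_{ik} \leftarrow w_{ik}\,
 \frac{(YH + \lambda_r S^{r*}W)_{ik}}{(WH^\top H + \lambda_l W + \lambda_r D_r W)_{ik}}$,
with prediction $Y^{**} = WH^\top$. Defaults: $k = 100$ (capped at
$\min(m,n) - 1$), $\lambda_l = 2$, $\lambda_r = \lambda_d = 10^{-4}$,
at most 2000 sweeps or relative objective change below $10^{-6}$.
Numerical choices:

* The learned graphs are directed, but the Laplacian quadratic form needs
  symmetry to be non-negative; the graph terms therefore use
  $S_\mathrm{sym} = (S^{*} + S^{*\top})/2$ and $D = \mathrm{rowsum}(S_\mathrm{sym})$ —
  the standard graph-regularization construction, which keeps the
  objective well-defined and the multiplicative updates monotone
  (the suite asserts a non-increasing trace on every tested instance).
* Initialization is uniform on $[0, \sqrt{\bar{Y}/k}]$ from a stored seed:
  reproducible and scale-matched so the first reconstruction has the right
  magnitude. The factorization objective is non-convex; a fixed seed makes
  runs comparable, not globally optimal.
* Update denominators are floored at $10^{-12}$ to avoid $0/0$; the
  reconstruction can exceed 1 and is clipped only at the fusion stage.

**Network consistency projection (NCPRIA).** Scores each pair by how
consistently the drug's similarity row projects onto the disease's
association column and vice versa:

$$Y^{***}(i,j) = \frac{S^{r*}(i,:)\cdot Y(:,j)/\lVert Y(:,j)\rVert
 + Y(i,:)\cdot S^{d*}(:,j)/\lVert Y(i,:)\rVert}
 {\lVert S^{r*}(i,:)\rVert + \lVert S^{d*}(:,j)\rVert}.$$

Exact zeros of $Y$ are first replaced with $10^{-30}$ so no norm vanishes;
the replacement is applied uniformly, inside the norms too, which turns
scores for genuinely empty rows/columns from undefined into a
similarity-mean value. With all entries non-negative, Cauchy–Schwarz bounds
every score in $[0,1]$. A drug row of $S^{r*}$ and disease column of
$S^{d*}$ both identically zero leaves the score undefined and raises an
error naming the pair.

## Stage 4: noisy-OR fusion

$$R_t = 1 - (1 - Y^{*})(1 - Y^{**})(1 - Y^{***}).$$

Interpreting the three scores as independent detection probabilities,
$R_t$ is the probability that at least one detector fires: it dominates
each input elementwise, is monotone in each, permutation-invariant, and
stays in $[0,1]$. NMF scores above 1 are **clipped**, not rescaled, before
fusion: clipping is local and parameter-free and only affects pairs the
factorization already scores as near-certain, whereas min-max rescaling
would let a single outlier deform every score. Sensitivity to this choice
is confined to the clipped entries.

## Evaluation harness

`make_folds()` partitions the known pairs into near-equal folds
(sizes differ by at most one), repeatedly and reproducibly.
`cross_validate()` removes each fold, reruns the *entire* pipeline —
completion and similarity learning included — on the training matrix only,
and computes a pooled AUC with the held-out pairs as positives and every
pair unknown in the full matrix as negatives; training positives are
excluded from both sides. Fold AUCs are averaged per repeat, then across
repeats. Two conventions the protocol statement leaves open are fixed as:
the negative set is global (all unknown pairs pooled, with a per-drug
breakdown available from the de-novo harness) and ranking ties get
Mann–Whitney half credit. AUC is computed as the trapezoidal area under
the ROC swept over distinct score thresholds, which equals that
tie-adjusted Mann–Whitney statistic exactly (asserted to $10^{-12}$).

Leakage is excluded by construction: the training matrix is rebuilt from
the fold plan's own pair list, so the pipeline never reads a held-out
cell's value — the suite verifies that planting sentinel values in all
held-out cells leaves every output bit-identical.

`de_novo_drug_test()` deletes *all* associations of each drug in turn,
refits, and ranks the drug's removed associations against its unknown
diseases; per-drug AUCs are reported alongside an AUC pooled over all
drugs' score sets (the aggregation convention is unstated in the protocol;
pooling is reported as the headline with the per-drug table attached).

## The synthetic generator

`simulate_network()` emulates the *structure* of curated drug-disease gold
standards (hundreds of drugs and diseases, a few percent density, block-like
co-indication structure, similarities correlated with the association
pattern) at desk scale. Each entity gets one dominant latent group of $r$
(main loading $\mathrm{Unif}(0.6, 1)$, background $\mathrm{Unif}(0, 0.01)$);
$P \propto UV^\top$ is rescaled so $\mathrm{mean}(\min(P,1))$ equals the
target density exactly (monotone root-solve), $Y \sim \mathrm{Bernoulli}(P)$;
similarities are factor-row cosines plus symmetric Gaussian noise
($\sigma$ = `similarity_noise`), clipped to $[0,1]$ with unit diagonal.
The group contrast was set so that the planted structure itself is
informative: scoring held-out positives with the true $P$ separates them
from unknown pairs at AUC $\approx 0.91$–$0.93$ under the reference
conditions, leaving the pipeline a learnable but non-trivial target.
Structure and noise use independent seeded substreams, so the noise level
can vary with the planted pattern held fixed.

What the generator does **not** emulate: real degree distributions (hub
drugs, rare diseases), chemistry-specific similarity geometry, correlated
measurement error between the two similarity inputs, and biased curation
(popular drugs being better annotated). Passing tests therefore show the
method recovers planted low-rank, similarity-consistent structure — they
do not certify performance on any particular real dataset, where the gold
standard's own conventions (aggregation, candidate sets) also move the AUC.

## Reference problem sizes

The test suite exercises the equation-level oracles on $6\times5$ to
$8\times6$ instances (50 replicates where the checks are exact), and the
end-to-end recovery property on the reference synthetic instance —
$150$ drugs $\times$ $100$ diseases, rank 6, density 0.06,
$\sigma = 0.1$, 10% of positives hidden, medians over three seeds — the
scale at which the planted-structure regime is stable while a full
pipeline fit stays in the seconds range. `scripts/acceptance.R` recomputes
the same quantities plus a $2\times$5-fold cross-validation and an 8-drug
de-novo test on a $60\times40$ instance.

## Known limitations

* All matrices are dense; the implementation targets $m, n$ up to a few
  thousand, not genome-scale interactomes.
* The NMF stage is non-convex; different seeds give slightly different
  factors (the ensemble damps, but does not remove, this variance).
* Fusion assumes the three base scores are independent detectors; they are
  trained on the same completed matrix and graphs, so $R_t$ is best read
  as a ranking score, not a calibrated probability.
* Only AUC-based evaluation is provided; no early-retrieval metrics.
* One similarity source per side; multi-similarity integration is out of
  scope.
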