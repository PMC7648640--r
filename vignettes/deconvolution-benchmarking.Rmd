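---
title: "Benchmarking cell-type deconvolution pipelines: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cell-type deconvolution pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deconvbench)
```

## The problem

Bulk transcriptomes average over the cell types present in a sample.
Reference-based deconvolution inverts that average: given a bulk
expression vector $t$ and a signature matrix $C$ whose columns are
cell-type-specific expression profiles, it estimates the mixing
proportions $p$ in the linear model

$$ t \approx C\,p, \qquad p \ge 0,\; \textstyle\sum_k p_k = 1 . $$

Many estimators of $p$ exist, and their accuracy depends not only on the
regression family but on everything upstream: the scale of the data
(linear, log, sqrt, variance-stabilized), the scaling/normalization of
$t$ and $C$, the marker genes the signature is restricted to, and whether
the reference actually contains every cell type present in the mixture.
`deconvbench` makes that whole grid testable. Single cells with known
labels are summed into *pseudo-bulk* mixtures, so the true composition
$P_E$ is known exactly and every pipeline can be scored by the RMSE and
Pearson correlation between $P_E$ and its estimates $P_C$.

## Pipeline stages and their parameters

**Quality control** (`qc_filter`) applies, in order: removal of all-zero
and zero-variance genes; removal of cells whose library size,
mitochondrial fraction or ribosomal fraction lies more than 3 MADs from
the median; retention of genes with a count above 1 in at least 5% of the
remaining cells; retention of cell types with at least 50 remaining
cells. All four thresholds are arguments. Two details are implementation
choices the underlying procedure leaves open: the MAD uses the normal
consistency constant 1.4826 and operates two-sided on raw library sizes
and linear fractions (a flag switches to upper-sided filtering, which
some pipelines prefer for mitochondrial content); and the cell-level MAD
rule is iterated to its fixed point, because a single pass is not
idempotent — removing outliers moves the median, and we want
`qc_filter(qc_filter(x))` to equal `qc_filter(x)` exactly.

**Splitting** (`split_train_test`) divides each cell type 50:50 with a
seeded shuffle (odd counts send the extra cell to training). The
`by_donor` mode assigns half the donors to each split first, so no
individual contributes cells to both halves.

**Reference building** (`build_reference`) takes per-type arithmetic
means of raw counts over the training cells. The reference is built
un-transformed and un-normalized; the transform/normalization grid is
applied afterwards, to $C$ and $T$ alike.

**Marker selection** (`rank_genes`, `select_markers`). Statistics are
computed on TMM-normalized log2 counts-per-million with pseudo-count 1.
Classic marker pipelines use mean–variance-weighted moderated linear
models here; we substitute a Welch t-test of each type against the
rest, because the selection criteria that matter downstream (the 30%
prevalence filter, the fold change against the second-highest-expressing
type, BH-adjusted p < 0.05) are preserved while the exact p-values of the
moderated fit are not needed by anything this package asserts. One
genuinely open point is marker assignment. The fold change of type $k$
is defined against the highest *other* type, so a real marker of type A
also shows a large *negative* fold change in every other type; assigning
genes to the type with the largest absolute fold change would therefore
misfire. We assign positively first — at most one type can exceed all
others by the threshold — and only genes with no positive assignment can
become *negative markers* of the single type they are depleted in (low
in that type, high in all others). This reproduces both marker classes
the benchmark describes, and `pos_fc` then removes exactly the negative
ones. Fold-change thresholds default to 2; the presets lower them to 1.8
(kidney-like) and 1.5 (PBMC-like), the conventional relaxation for
tissues whose cell types are more closely related.

`marker_specificity` reports the percentage of `all`-strategy markers
that would also qualify for a *secondary* type: some other type's mean
exceeds the highest remaining type (primary excluded) by the same fold
threshold. No significance condition is imposed on the secondary
contrast — the one-vs-rest test has no power for the middle type of an
expression gradient, which is precisely the non-specific pattern the
statistic is meant to count. On the pancreas-like fixture about a
quarter of markers are non-specific, comparable to the 7–38% seen in
real tissue data.

**Pseudo-bulk generation** (`generate_mixtures`). Each mixture draws a
number of types $k$ uniformly from its range (2–5 by default, 2–8 in the
kidney preset), draws the types, then draws a composition uniformly from
the grid simplex (multiples of 0.05 with minimum 0.05; the kidney preset
uses the finer 0.01 step over 0.01–0.99). Uniformity over compositions is implemented by exact
marginal sampling of integer compositions rather than sequential
proportion draws, which would be biased toward early picks. Proportions
convert to cell counts by largest-remainder rounding (exact when the
pool size is a grid multiple, e.g. 100 × 0.05). Infeasible compositions
(a type with too few test cells) are rejected and redrawn —
composition-only, the drawn $k$ and types are kept. Cells are sampled
without replacement within a mixture and their raw counts summed.

**Transforms and normalizations.** `transform_expression` implements
linear, `log1p`, square root, and a variance-stabilizing transform. The
VST is a *functional* stand-in, not a numerical clone of any external
implementation: per-gene dispersions are estimated by moments on
size-factor-normalized counts, the trend $\alpha(\mu) = a_1/\mu + a_0$
is fitted by least squares, and the closed-form NB stabilizer
$\log_2\!\big((1 + a_1 + 2 a_0 q + 2\sqrt{a_0 q (1 + a_1 + a_0 q)})/(4
a_0)\big)$ is applied after median-of-ratios normalization. Only
qualitative VST behaviour (a flat variance–mean trend) is asserted
anywhere. `normalize_expression` provides the closed-form strategies:
column/row scaling, column/global min-max and z-scores, quantile
normalization (ties receive the mean of the spanned reference values),
upper quartile (75th percentile of the nonzero values; fails loudly when
a quartile is zero, the known failure mode on sparse single-cell
matrices), TPM (unit lengths by default, reducing to CPM for UMI data),
TMM with the method's canonical defaults (30%/5% two-sided trims,
inverse-variance weights, reference column closest to the mean upper
quartile, factors scaled to geometric mean 1), the LogNormalize-style
column scaling whose final exponentiation returns linear values, and
median-of-ratios size factors. Hand implementations are tested against
edgeR, limma and DESeq2 as independent oracles. Single-cell-specific
normalizations (scran, scater, Linnorm, SCTransform) are published
methods in their own right and are reachable only by passing a function
as `scalingT`/`scalingC`.

One contract needed interpretation: median-of-ratios is documented as
requiring linear-scale integer counts, yet the benchmark applies it as a
reference-matrix scaling, and a reference of per-type *means* is not
integer. The geometric-mean ratio construction is well defined for any
positive values, so `normalize_expression` enforces linearity (through
`check_compatibility`) and non-negativity but not integrality.

`check_compatibility` records the excluded grid cells instead of
erroring mid-grid: median-of-ratios off linear scale, upper quartile on
sparse input, z-scored (negative) matrices with solvers whose model
assumes non-negative expression (`nnls`, `qp`, `dwls`). Skips carry
their reason into every report.

**Solvers.** All regression families are implemented from their
definitions; no deconvolution package is wrapped. `ols` (minimum-norm on
rank-deficient references, with a warning), `nnls` (Lawson–Hanson active
set), `qp` (active-set least squares on the probability simplex — both
constraints in-solver), `rlr` (IRLS with Huber weights, tuning constant
1.345, scale from the residual MAD), ridge/lasso/elastic net (closed
form and coordinate descent, $\lambda$ by cross-validation over genes),
`svr` (CIBERSORT-style linear $\nu$-SVR: features and mixture z-scored,
$\nu \in \{0.25, 0.5, 0.75\}$, the model with the lowest reconstruction
RMSE wins) and `dwls` (NNLS-initialized iterations of weighted NNLS with
weights $1/(Cp)^2$ capped at a damping constant chosen once by
cross-validation on gene subsets). Because no libsvm binding is
available in the target environment, the $\nu$-SVR solves its *primal*
— a $(k+2)$-dimensional convex problem — by smoothed-hinge BFGS with a
continuation schedule on the smoothing temperature, using the libsvm
per-sample cost convention; during development it was verified to agree
with an independent libsvm implementation to four decimals across the
$\nu$ grid. The original DWLS ships its own internal marker selection;
here the framework's marker module decides the gene set for every bulk
solver, DWLS included, so strategies stay comparable across methods.

Raw coefficients become proportions by clipping negatives to zero and
renormalizing; an all-zero coefficient vector is flagged degenerate and
scored as missing rather than silently uniform.

## The synthetic world

`generate_dataset` draws counts from a negative binomial
($\mathrm{Var} = \mu + \alpha\mu^2$; single-cell counts are
over-dispersed, and NB sparsity at low means makes extra zero-inflation
unnecessary). A gene's relative expression is a shared lognormal
baseline (log-sd 0.4) times a type-specific lognormal deviation (log-sd
1.1); the two sds set the baseline between-type profile correlation at
roughly 0.05–0.15, and `correlation_pairs` raise it for chosen pairs
(configured similarity is monotone in realized correlation; 0.85 yields
roughly 0.7 on the PBMC-like preset). Marker genes are disjoint random
blocks per type with *no* type deviation and a multiplicative fold
change in their own type — without zeroing the deviation, a planted
"marker" with fold change 4 would be overtaken by the type noise in a
third of cases and marker recall would be meaningless. Donor effects are
gene-wise multiplicative lognormal (log-sd 0.15), small enough that
cells cluster by type rather than donor, which is asserted as a test.
Library sizes are lognormal per cell (log-sd 0.25) around a per-type
mean.

Preset depths anchor to typical published medians for these
tissue/protocol combinations (about 3.9k counts/cell pancreas-like,
1.1k PBMC-like, 0.9k kidney-like) with only ±7% variation between types. This matters: large
per-type depth differences would make column normalization re-weight
proportions by depth and manufacture a normalization sensitivity the
real datasets do not show. Fixtures append 20 all-zero genes and eight
10×-library outlier cells so QC always has real work to do.

What a green test does **not** establish: the generator has no gene–gene
correlation beyond the type/donor structure, no batch effects, no cell
cycle, no ambient RNA, and markers are cleanly disjoint by construction.
Absolute RMSE values here are therefore optimistic relative to real
tissue; the package asserts the *relative* claims (linear beats log,
normalization insensitivity among the sensible choices, `all` beats
`random5`, removal inflates error) and one scaled-down absolute headline
(median per-mixture RMSE of NNLS/linear/column below 0.05).

## Missing cell types

`removal_experiment` re-runs deconvolution after dropping one reference
column, restricted to mixtures that truly contain the victim. On the
bulk path the victim's markers leave the signature too; for single-cell
references only the cells are dropped (both behaviours are in
`drop_cell_type`). Per remaining type it reports the RMSE fold change
against the full-reference baseline and flags types at or above 2×. The
two correlation hypotheses reproduce on the PBMC-like fixture: dropping
one member of the similarity-0.85 pair hits its partner hardest (the
missing signal flows to the most correlated column), while dropping the
type unrelated to all others broadly distorts everything.

## Numerical notes

Grid proportions are exact integer multiples of the step; ground-truth
columns sum to 1 within 1e-12. Active-set solvers fall back to
minimum-norm KKT solutions on duplicated columns instead of failing.
Ties in marker ranking break by average expression then gene id, so
every run is deterministic. One master seed derives per-stage seeds by
hashing the stage name (`stage_seed`), keeping stages independently
reproducible; all derived seeds stay below $2^{31}$.

## Known limitations

The VST is deliberately only functionally equivalent to published
implementations. The penalized-regression cross-validation selects
$\lambda$ per mixture, which is slow for large grids. FARDEEP, EPIC,
MuSiC, SCDC, Bisque, dtangle, DSA, ssKL/ssFrobenius, DCQ, deconvSeq and
CellMix are out of scope as reimplementations; `register_solver` exists
so wrapped external methods can ride the same grid. Memory/runtime
profiling of external tools and the flow-cytometry-validated bulk
cohort analysis are likewise out of scope, though `read_counts` accepts
any gene × sample table for the latter.
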