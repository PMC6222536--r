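---
title: "Feature-based cytokine recognition: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based cytokine recognition: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytorec)
```

## The problem

Cytokines — secreted signalling proteins such as interleukins and
interferons — are expensive to identify experimentally, while their primary
sequences are cheap to obtain. `cytorec` implements a sequence-based
recognition pipeline: protein sequences (and, where available, their
PSI-BLAST evolutionary profiles and PSI-PRED secondary-structure
predictions) are mapped to fixed-width numeric vectors from four feature
families, concatenated into frozen combination recipes, and classified with
a support-vector machine. The package also ships the full evaluation
harness (metrics, stratified and repeated cross-validation, grid search,
ratio-controlled splits) and a synthetic-data generator so that every stage
can be exercised and tested without external databases.

## Feature families

### Weighted n-gram composition (420-D)

For a sequence of length $L$, the count $T(g)$ of each contiguous segment
$g$ of length $n \in \{1, 2\}$ is normalised by its number of windows
($L$ for monomers, $L-1$ for dimers) and weighted by
$20^n / (20 + 20^2)$:

$$ F_{n\text{-gram}}(g) \;=\; \frac{20^{|g|}}{20 + 20^2} \cdot
   \frac{T(g)}{L - |g| + 1}. $$

The 20 monomer slots therefore sum to $20/420$ and the 400 dimer slots to
$400/420$, so the whole vector sums to exactly 1 — a property the tests
assert for every generated sequence. The per-order weight could equally be
read as a global constant; the per-feature reading is the only one in which
the prefactor changes the vector at all, and an SVM is insensitive to the
difference (it is a per-block rescaling).

### Type-I pseudo amino-acid composition (30-D)

Composition alone cannot distinguish sequences that are permutations of one
another. The PseAAC vector augments the 20 relative frequencies $f(a)$ with
$\lambda$ sequence-order correlation factors

$$ b_g = \frac{1}{L-g} \sum_{i=1}^{L-g} \frac{1}{3}\Big[
   (H_1(a_i)-H_1(a_{i+g}))^2 + (H_2(a_i)-H_2(a_{i+g}))^2 +
   (M(a_i)-M(a_{i+g}))^2 \Big], $$

where $H_1$, $H_2$ and $M$ are z-score-normalised hydrophilicity
(Hopp–Woods), hydrophobicity (Tanford/Chou) and side-chain mass. All
$20+\lambda$ slots share the denominator $\sum f + w \sum b$, so the vector
sums to 1. Defaults are $\lambda = 10$ and $w = 0.05$, the standard
parameterisation of the 30-D type-I vector; both are arguments.

Two points were genuinely open and are resolved as follows. First, the
frequencies $f(a)$ enter *raw*, not z-scored: z-scored frequencies can make
the shared denominator zero or negative, destroying the probability-like
contract, and the raw form is the standard type-I definition. Second, no
property table is prescribed anywhere, so the package ships the canonical
Chou-lineage constants (`pseaac_property_table()`) and accepts any
replacement via `read_property_table()`; because the three scales are
z-scored over the 20 residues, rescaling any column by a positive constant
provably leaves the output unchanged (tested).

### PSSM features (20 + 380 = 400-D)

Raw log-odds scores $a_{ij}$ from a PSI-BLAST ASCII PSSM are squashed with
the logistic $A_{ij} = 1/(1+e^{-a_{ij}})$ — the standard map taking
log-odds into $(0,1)$. The 20 `pssm20` features are the column means of
$A$. The 380 `pssm380` features are lagged cross-column correlations: for
each ordered residue pair $(s,t)$, $s \ne t$, with lag $g = |s-t|$,

$$ \frac{1}{L-g} \sum_{i=1}^{L-g}
   \frac{(A_{is}-\bar A_s)(A_{i+g,t}-\bar A_t)}{\sigma_s \, \sigma_t}, $$

with **population** standard deviations (divisor $L$). The divisor matters:
population variance is the only choice for which the same expression at
$s=t$ (lag 0) is *exactly* 1 for every non-degenerate column — the identity
that justifies discarding the 20 diagonal cells as uninformative, leaving
380 features. This identity is regression-tested on random profiles. The
380 features are ordered lexicographically by $(s,t)$ over the PSI-BLAST
residue order `A R N D C Q E G H I L K M F P S T W Y V`; any fixed order
would serve the classifier, but the schema must be frozen for reproducible
feature tables. Profiles shorter than 20 rows are rejected (the largest lag
is 19), as are constant columns ($\sigma = 0$).

### Secondary-structure features (18-D)

From an H/E/C state string and its $L \times 3$ probability matrix
(column order C, H, E, as in `.ss2` files) the package computes, in frozen
order: state frequencies (3); positional sums $\sum_i \mathrm{pos}_i /
(L(L-1))$ per state (3) — the denominator deliberately uses the full length
$L$ including coil positions for all three states; maximal run lengths
divided by $L$ (3); six transition-matrix features; and the three
probability column means. For the transition matrix, coil positions are
removed and maximal H/E runs collapse to single $\alpha$/$\beta$ tokens;
adjacent token pairs are counted and the rows filled as
$\big(T(\alpha\alpha), T(\alpha\beta)\big)/(T(\alpha\alpha)+T(\alpha\beta))$
and $\big(T(\beta\alpha), T(\beta\beta)\big)/(T(\beta\beta)+T(\beta\alpha))$.
A row with denominator 0 (a prediction lacking H or E, or a single segment)
is zero-filled rather than raising an error: real predictions do lack
states, and zero is the conventional "no signal" encoding that keeps the
pipeline total. Note that after collapsing, $\alpha\alpha$ and $\beta\beta$
pairs cannot occur, so those counts are always 0; the full formula is kept
for transparency.

The worked reference: on the string `EEEEHHEEHHHCC` the maximal runs are 3
(H), 4 (E), 2 (C), the segment sequence is $\beta\alpha\beta\alpha$, and
the TPM rows are $(0,1)$ and $(1,0)$.

```{r sss-example}
maxrun_features("EEEEHHEEHHHCC") * 13
transition_matrix("EEEEHHEEHHHCC")$tpm
```

## Combination recipes

Recipes are frozen concatenations with asserted dimensions:
`sp` = sss18 + pseaac30 (48), `pssm` = pssm20 + pssm380 (400),
`psp` = pssm400 + sp48 (448), `pspn` = ngram420 + psp448 (868). Internal
part order is fixed for reproducibility only; the SVM is order-insensitive.
No scaling happens at combination time — almost all features already live
in $[0,1]$, and standardisation is an explicit classifier option
(`scale =`, default off).

## Evaluation harness

Metrics are accuracy, sensitivity, specificity, precision, F-score and the
Matthews correlation coefficient. One degenerate case has a fixed
convention: when nothing is predicted positive ($TP = FP = 0$) the Matthews
coefficient is $-1$, the poorest value. Any *other* vanishing denominator
returns 0 together with a flag in `degenerate`, so cross-validation
aggregates never crash on an unlucky fold.

Cross-validation partitions are seeded and stratified by class by default —
plain random folding can produce single-class folds at a 1:9 class ratio —
with `stratified = FALSE` available (and required for leave-one-out, where
$k$ exceeds the class sizes). Fold aggregation is the mean of per-fold
metrics, not pooled confusion counts; both are defensible, and the
per-fold mean is the convention adopted here. Repeated CV reports both the
within-repetition fold SD and the SD across repetition means, because the
two spreads answer different questions. Grid search scores all
$(C, \gamma)$ cells on one shared seeded fold assignment (cells are
compared on identical partitions) with ties broken toward the smaller $C$,
then the smaller $\gamma$; the default lattice is $2^{-5} \ldots 2^5$ in
both axes (121 cells, inner 3-fold).

`ratio_split` uses every row, so it requires the dataset's own class totals
to match the requested positive fraction within rounding — requesting a 1:9
split from balanced data is a composition error rather than a silent
subsample.

The SVM itself is the libsvm solver via `e1071` (the same solver family
the surrounding literature uses); `svm_train`/`predict` enforce the
package's schema and label contracts around it. Models can be persisted in
the LIBSVM text format; the reader evaluates the decision function directly
from the stored support vectors, and tests assert its predictions equal
`e1071`'s exactly.

## The synthetic generator

`gen_data()` / `gen_dataset()` emulate the real data regime — two classes,
lengths $\ge 20$, optional imbalance — with three independent,
class-conditioned signals:

* **Composition** (`effect_size`): negatives draw residues uniformly;
  positives apply an exponential tilt $p_a \propto e^{\text{effect}}$ for
  the fixed hydrophobic subset {F, I, L, M, V}. At `effect_size = 0` the
  classes are exchangeable by construction; the tilt form was chosen
  because it reduces to uniform smoothly and scales cleanly.
* **Profiles** (`pssm_noise`, `pssm_signal`): +5 on the true residue
  column, $-1$ elsewhere, plus integer-rounded Gaussian noise (SD 2 by
  default) — the class signal reaches the profile features only through
  the sequence, as with a real profile of an unaligned singleton.
* **Structure** (`structure_bias`): a 3-state Markov chain (stay
  probability 0.8) whose transitions into H are tilted by
  $e^{\text{bias}}$ for positives; emitted `.ss2` rows put 0.8 on the
  realised state.

Defaults are 100 + 100 sequences of length 30–60, `effect_size = 1`,
`structure_bias = 0.3`, `pssm_noise = 2` — sizes chosen so the full
pipeline (including the 121-cell grid search) runs comfortably on one CPU
while leaving the class signal clearly measurable. Everything derives
deterministically from one master seed; identical configurations write
byte-identical directories.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: homology structure within classes, realistic
cytokine motifs, position-dependent conservation in profiles, or any
coupling between sequence, profile and structure beyond the shared class
label. In particular, under this generator the 380 lagged profile
correlations are pure noise (the signal is i.i.d. across positions), and
at desk scale they measurably *dilute* a linear-kernel classifier: with
`effect_size = 2`, 10-fold CV accuracy is 1.00 on the 48-D `sp` vector but
only ≈ 0.59 on the 448-D `psp` vector. On real evolutionary profiles these
correlations carry genuine signal; the synthetic result is a property of
the generator's independence assumptions, not of the feature definition.
The acceptance suite therefore asserts the behaviours that *are*
generator-valid: chance-level accuracy at zero effect, monotone accuracy
in effect size, and exact worked-example and dimension checks.

## Numerical choices and degenerate inputs

* Ambiguity codes (B, J, O, U, X, Z) are rejected with the sequence id and
  position named — no silent remapping exists that all consumers agree on.
* All residue orderings are frozen constants (`AA_ALPHABETICAL` for
  n-gram/PseAAC slots, `PSSM_RESIDUE_ORDER` for profile features).
* Feature tables are written with 17 significant digits so the numeric
  payload round-trips bit-exactly; registered schema names are re-validated
  against the header on read.
* Population (divisor-$n$) standard deviations are used wherever a spread
  is computed over a *complete* set (the 20 residues of a property table,
  the $L$ rows of a profile column, the $k$ folds of a CV run).
* `.ss2` rows whose probabilities sum outside $[0.99, 1.01]$ are kept but
  flagged with a classed warning; synthetic rows sum to 1 exactly.
* Error taxonomy: every package error is classed
  (`cytorec_parse_error`, `cytorec_schema_error`, `cytorec_length_error`,
  `cytorec_composition_error`, ...) so callers and the CLI can map
  validation failures (exit 1) apart from usage failures (exit 2).

## Problem sizes used by the test and acceptance suites

Oracle-equivalence suites run each feature family against an independent
naive re-implementation on 100 seeded random inputs (sequences of length
20–45, profiles of 20–28 rows) at tolerance $10^{-12}$. Pipeline-level
checks use 200 sequences of length 30–60; the grid search evaluates the
full 11 × 11 lattice with inner 3-fold CV. These sizes are the package's
chosen desk-scale study conditions: large enough for the binomial null
band ($0.5 \pm 3\sqrt{0.25/200}$) to be meaningful, small enough to keep
the whole suite in a few minutes.

## Known limitations

* Headline accuracies from the motivating application (≈ 0.91 on a real
  cytokine/non-cytokine corpus) require the UniProt-derived dataset and
  real PSI-BLAST/PSI-PRED output, which this package deliberately does not
  produce; it parses their formats instead.
* Only binary classification; no probability calibration; no feature
  selection (the package computes full vectors and frozen concatenations).
* PSSM parsing supports the `-out_ascii_pssm` dialect (and files with the
  trailing percentage columns); other profile formats are out of scope.
* The LIBSVM text reader supports unscaled binary C-classification models
  — exactly what the package writes.
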