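---
title: "Surprisal analysis of expression time courses: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprisal analysis of expression time courses: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surprisal)
```

## The model

Surprisal analysis treats the transcriptome as a physico-chemical system
relaxing toward maximal entropy under constraints. The measured expression
level of gene $i$ at condition $T$ (a time point or disease stage) is
modelled on the natural-log scale as

$$\ln X_i(T) \;=\; \sum_{\alpha=0}^{t-1} G_{i\alpha}\,\lambda_\alpha(T),$$

where $G_{i\alpha}$ is the condition-independent extent of participation of
gene $i$ in transcription pattern $\alpha$ and $\lambda_\alpha(T)$ is the
Lagrange multiplier — the condition-dependent weight — of that pattern.
Pattern $\alpha = 0$ is the *steady state* (balanced state): the
maximal-entropy expression distribution that persists across all
conditions. Patterns $\alpha \ge 1$ are *deviation* patterns, the
constraints that keep the system away from balance; in cancer series they
carry the transformation signatures. Because the sum over genes of
$G_{i\alpha}G_{i\beta}$ is $\delta_{\alpha\beta}$ (the weight vectors are
orthonormal), the fit is exactly a singular value decomposition of the
$m \times t$ log-expression matrix: $G$ holds the left singular vectors,
and we fold the singular value $\omega_\alpha$ into the multiplier,
$\lambda_\alpha(T) = \omega_\alpha V_{T\alpha}$. Both conventions (unit-norm
$G$ with $\omega$-scaled $\lambda$, or $\omega$-scaled $G$ with unit-norm
$\lambda$) reconstruct identically; the package fixes the former, so a
$G_{i\alpha}$ is always comparable across patterns.

Two assumptions matter. First, *no centering*: the dominant uncentered
component **is** the steady state, and the near-constancy of
$\lambda_0(T)$ across conditions is a finding, not an artifact. Centering
the matrix before the SVD would delete exactly the term of interest.
Second, positivity: logs must exist, which is why the CSV reader floors
missing and non-positive signals (default 1.0 signal unit, configurable)
and reports how many cells it touched.

Because at most $t$ singular values can be non-zero, a series with $t$
conditions can support at most $t$ phenotypes — a four-stage series yields
a $4 \times 4$ multiplier matrix and at most four non-negligible patterns.
All $t$ patterns are always returned (zero patterns as exact zeros);
`effectiveRank()` reports how many exceed $10^{-10}\,\omega_0$.

## Two numerical routes

`surprisalDecompose()` offers `full_svd` (thin SVD of the $m\times t$
matrix) and `small_matrix` (eigendecomposition of the $t \times t$ product
$Y^\top Y$, back-projecting $G = Y V \Omega^{-1}$). The small-matrix route
is the economical one when $m$ is tens of thousands and $t$ of the order of
ten; the two agree to $10^{-8}$ after sign normalization, which the test
suite checks on one hundred random instances. Numerical details:

* **Sign convention.** An SVD is sign-ambiguous per component. We fix:
  for $\alpha = 0$, flip so $\sum_i G_{i0} < 0$ — steady-state weights are
  predominantly negative, $\lambda_0(T)$ is negative, and their product
  reproduces positive log expression; the most stable transcripts are then
  the *most negative* $G_{i0}$. For $\alpha \ge 1$, flip so the
  largest-magnitude entry of $\lambda_\alpha$ is positive, ties broken
  toward the earliest condition. Output is deterministic regardless of the
  LAPACK backend's choices.
* **Zero patterns.** Eigenvalues of $Y^\top Y$ that are zero in exact
  arithmetic surface as roundoff of order machine epsilon times the
  largest eigenvalue — about $10^{-8}\,\omega_0$ on the singular-value
  scale. The small-matrix route flushes eigenvalues below
  $10^{-14}\lambda_{\max}$ to exact zeros and completes the corresponding
  $G$ columns by deterministic Gram–Schmidt over the standard basis, so
  $G$ is orthonormal even for rank-deficient input (including the all-zero
  matrix). The flush means this route cannot resolve genuine singular
  values below $\sim 10^{-7}\,\omega_0$ relative; use `full_svd` if such
  components matter.
* **Degenerate ties** $\omega_\alpha = \omega_\beta$ leave a
  non-identifiable subspace; ordering then falls back to the
  eigen-solver's stable ordering plus the sign convention, which keeps
  repeated runs identical but does not make the individual vectors
  meaningful.
* More conditions than genes is refused with advice to transpose, rather
  than silently reinterpreting the axes.

## Stability diagnostics

A transcript whose expression is well reproduced by the steady-state term
alone — significant negative $G_{i0}$, small $G_{i\alpha}$ for
$\alpha\ge 1$ — is *stable*: its level changes only by a small fraction
across the series. `steadyStateResidual()` quantifies this as
$\max_T |\ln X_i(T) - G_{i0}\lambda_0(T)|$, and `stabilityScatter()`
returns the $(G_{i0}, G_{i1})$ plane in which stable transcripts sit at
large negative $G_{i0}$ with $G_{i1}$ near zero.

## Profiling and selection

`sortPattern()` orders one pattern's weights non-increasingly (ties broken
by gene name in the C locale, so results do not depend on the session
locale). Selections come in two forms. *Bounds* (`selectByBounds()`): the
two-horizontal-lines selection over the sorted profile; bounds are strict
by default — a gene sitting exactly on the line is excluded — with an
`inclusive` switch. *Extremes* (`selectExtremes()`): the $n$ most negative
(the "most stable" reading of the steady state), most positive, or largest
magnitude. "Most stable" is deliberately most-*negative* $G_{i0}$ rather
than largest $|G_{i0}|$, because stable transcripts carry the lowest
$G_{i0}$ under the sign convention; the magnitude mode exists for
robustness checks. Whether "most contributing and up-regulated" for a
deviation pattern should mean positive $G_{i1}$ alone or positive $G_{i1}$
together with an expression increase is not fixed by the method; both the
positive-extreme and the bounds selection are provided and neither is
hard-wired. Every selection records the parameters that produced it, so a
downstream heatmap is reproducible from its provenance file alone.

## Connectivity and heatmap comparison

STRING protein-links files carry integer combined scores 0–999;
`parseStringLinks()` divides by 1000 into the benchmarked association
probabilities the field quotes (0.999, 0.507, ...). Columns are located by
header name, so both the minimal three-column dialect and the full
per-channel file parse. The evidence-channel combination formula is *not*
re-implemented — combined scores are consumed as computed by the database.
Choices: duplicate records for a pair keep the **maximum** score (the
combined score expresses higher confidence when more evidence supports an
association) with a warning; unmapped protein IDs are dropped with a
count; self-links are dropped. In score matrices, a pair absent from the
database is `NA` — *missing*, rendered as white, excluded from
correlations — and never 0, which would assert evidence of no association.
The diagonal is missing by the same logic.

The theoretical counterpart is `productHeatmap()`: cell $ij$ is the
*signed* product $G_{i\alpha}G_{j\alpha}$, so stable×stable (both
negative) is positive and sign encodes correlation vs anti-correlation
within a pattern; the map is exactly rank 1 and symmetric. Magnitude-only
rendering was considered and rejected because the sign is the information.
`pairHeatmaps()` forces the two maps onto one identically ordered gene
axis (reindexing the connectivity matrix; a gene-set mismatch is an error
naming the difference). For a combined stable + deviating axis,
`combinedAxis()` reproduces the canonical block layout: stable block first
by ascending $G_{i0}$, then the deviating block by descending $G_{i1}$.
`correlateHeatmaps()` uses **rank** (Spearman) correlation over mutually
present upper-triangle cells — weight products and probabilities live on
incomparable scales, so only monotone association is claimed — and
reports the cell count. At least three shared cells are required. Note a
uniform score block (e.g. a fixture at density 1) has no rank variance and
hence no defined correlation; the pipeline records `NA` for such a block
and relies on the combined axis, which mixes high, low and missing cells.

## The synthetic generator

`generatePlantedDataset()` writes the structure the method is meant to
find into a matrix where the truth is known exactly:

$$\ln X = u_0\,p_0^\top + u_1\,p_1^\top + \varepsilon .$$

* $u_0$: baseline log expression, $\mathcal N(6, 0.6)$ nat for background
  and deviating genes ($\approx$ signal 400, the scale of a
  target-intensity-normalized array), $\mathcal N(9, 0.2)$ for the planted
  stable group — stable, housekeeping-like transcripts are the highly
  expressed ones.
* $p_0$: near-constant across conditions (1% tilt) — the balanced state
  persists through every stage.
* $u_1$: zero except for the deviating genes, half $+$ and half $-$ the
  deviation amplitude (default 4 nat, i.e. roughly a 7-fold shift between
  the ends of the series — the scale of strongly transformation-associated
  transcripts); $p_1$ is monotone and mean-centered, mimicking progressive
  transformation.
* $\varepsilon$: i.i.d. Gaussian on the log scale, sd 0.05 by default —
  multiplicative, scale-proportional noise that keeps signals positive.

$u_1$ is orthogonalized against $u_0$ *within the deviating support* (so
stable genes keep exactly zero deviating weight) and $p_1$ against $p_0$;
the normalized planted components are then exactly the SVD factors of the
noise-free matrix, and recovery is scored by a plain cosine. The default
amplitude was chosen so that, at the default noise level and problem size
(m = 2000, t = 4, 100 + 100 planted genes), the second singular component
recovers the planted deviation vector with $|\cos| \ge 0.99$ with margin —
a perturbation-theory argument: the noise matrix contributes singular
values of order $\sigma(\sqrt m + \sqrt t) \approx 2.3$, to be compared
with the planted $\omega_1 \approx 15$.

What the generator does **not** emulate: probe-level artifacts and
summarization noise, detection calls, batch effects, heavy-tailed or
gene-dependent noise, more than one deviation pattern, and correlated
background genes. Green tests on planted data therefore demonstrate that
the machinery recovers structure of the assumed form at realistic
noise — not that any particular biological dataset has that form.
`generateLinksFixture()` plays the corresponding role for connectivity: a
high-score stable block (density configurable), a sparse low-score
background at one tenth of that density, everything else missing —
the pattern in which balanced-state transcripts form a densely connected
functional network.

## Pipeline and problem sizes

`runPipeline()` chains decompose → profile → connect → heatmap, writing
every intermediate as TSV (values at 17 significant digits, so re-reading
is bit-exact) plus a checksummed manifest; any stage can be re-entered
from the saved files, which is the cyclical mode of use. Outputs are
byte-identical across repeated runs at a fixed config. The CLI at
`inst/cli/surprisal.R` is a thin wrapper over these functions.

The test suite runs entirely on generated data: planted datasets of 120 –
2000 genes, route-equivalence sweeps over one hundred random matrices up
to 300 × 10, a 5000 × 12 reconstruction case (the largest series shape the
package targets by default), and a thousand random profiles checked
against brute-force selection oracles. The full suite completes in well
under a minute; the acceptance script in a few seconds.

## Known limitations

* No error bars on $G$ and $\lambda$, and no model selection for the
  number of constraints; patterns beyond the first few are typically
  noise-dominated and should be read with the singular-value spectrum in
  hand.
* The quantitative theory–database comparison is a single rank
  correlation; it deliberately stops short of a calibrated significance
  statement.
* Live database retrieval is out of scope: connectivity comes from a
  links flat file plus an ID map, which also keeps analyses reproducible.
* One decomposition per matrix: comparing patients means running the
  analysis per patient and comparing selections/heatmaps downstream.
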