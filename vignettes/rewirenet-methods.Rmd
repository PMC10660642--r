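---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rewirenet` quantifies condition-dependent, cell-type-specific gene
regulation: which genes change expression, which transcription factors (TFs)
change activity, how the inferred regulatory network around each gene and
around a focal TF changes, and how regulation and protein cooperation rewire
together. This vignette is the package's own account of the models, the
parameters that matter, the synthetic data the test suite runs on, and the
choices made where the design was genuinely open.

## 1. Differential expression

Within one cell type, case and control cells are compared per gene with a
two-sided Wilcoxon rank-sum test on the log-normalized layer
(`value = ln(1 + scale * count / cell_total)`, `scale = 1e4` counts per
cell). Midranks are used for ties. When both groups have at most 8 cells the
p-value comes from exact enumeration of all group assignments of the pooled
ranks (valid under ties); otherwise from the normal approximation with tie
correction and continuity correction. The two regimes agree closely at
moderate sizes; the exact path exists so that small-group p-values are never
approximation artifacts.

Genes enter testing only if their average log2 fold change — the
Seurat-style `log2(mean(expm1(x)) + 1)` difference between groups — clears
`lfc_min = 0.1` in absolute value. Tested genes are Bonferroni-adjusted over
the tested set (Benjamini–Hochberg is available behind the `adjust` flag),
and `significant` marks `p_adj < alpha = 0.05`. Both gates are the standard
single-cell marker-test settings and are exposed in `pipeline_config()`.

Cells are pooled across replicates within a cell type (the convention of the
marker-test tools this stage mirrors). Pooling treats cells as exchangeable
units; with strong between-replicate variation this is anticonservative,
which is why the generator pairs its replicate jitter across conditions (see
section 6) — the test suite's null calibration holds under that design, and
says nothing about unpaired designs with large batch effects.

## 2. Gene-set scores

`module_score()` implements binned-control scoring: genes are sorted into 24
equal-frequency bins of average expression, each gene-set member draws up to
`n_ctrl = 100` control genes from its own bin (seeded sampling, pooled,
deduplicated), and the per-cell score is the set mean minus the control
mean. The construction is invariant to adding a constant to every value.
`signature_score()` is the simpler signed variant for up/down signatures:
the per-cell mean of `sign x centered lognorm expression` over members;
flipping all signs negates all scores.

## 3. TF activity from signed regulons

Activity is estimated per cell by a multivariate linear model: ordinary
least squares of the cell's lognorm profile on an intercept plus the signed
gene x TF regulon design. A TF's activity is the t-statistic of its
coefficient — not the raw coefficient — so that activities are comparable
across TFs with different target-set sizes and modes, and invariant to
rescaling the profile. TFs with fewer than `min_targets = 5` targets matched
in the expression matrix are dropped and reported. Degenerate fits are
handled explicitly: a rank-deficient design aborts with the collinear
columns named; a zero-residual (perfect-fit) profile yields `NA` activities
rather than infinite t-statistics.

Summarization averages activities per (TF, cell type, condition), then
scales and centers across TFs within each (cell type, condition). The
percent change between conditions, `100 * (case − control) / max(|control|,
1e-8)`, is computed on the scaled averages by default (`pct_on = "mean"`
switches to unscaled); the scaling axis is an interpretation — the
upstream convention says only "scaled and centered" — and is flagged as
such. TFs whose control average is within `eps = 1e-8` of zero get an
infinite sentinel and are excluded from ranking. Priorities come from the
linear-interpolation quartiles of the percent-change distribution over all
(TF, cell type) pairs of the run: above Q3 means stronger activity in the
case condition, below Q1 stronger in the control.

## 4. Network inference by message passing

Three evidence layers enter: a TF x gene motif prior, a symmetric TF x TF
PPI prior, and the gene x gene Pearson coexpression of the analyzed cells
(zero-variance genes get zero correlations, not `NaN`). Each layer is first
normalized to the mean of its within-row and within-column z-scores
(zero-variance slices fall back to the whole-matrix z-score; a constant
matrix maps to zeros). Each round then computes two continuous Tanimoto
similarity messages,

- responsibility `R = T(PPI, W)` — does the TF's cooperativity profile look
  like the gene's in-edge profile?
- availability `A = T(W, coexpr)` — does the TF's target profile look like
  the gene's coexpression profile?

with `T(x, y) = <x,y> / sqrt(||x||² + ||y||² − |<x,y>|)`, and blends
`W ← (1−α) W + α (R+A)/2`. The averaged-message form is the consensus of
the responsibility and availability evidence, applied inside the damped
update rather than as a separate post-hoc average — that is the computation
the underlying algorithm family performs. The PPI and coexpression layers
are damped the same way toward their W-implied similarities
(`T(W, W)` over genes and over TFs respectively) and **re-standardized every
round**. Re-standardization matters twice over: the Tanimoto similarity of
aligned vectors scales with their norm, so without it the iteration has no
bounded attractor and diverges; and it keeps every layer on the z-score
scale the edge weights are defined on.

**Iteration budget.** After `k` rounds the companion layers retain only a
`(1−α)^k` share of the original data evidence, so the iteration drifts
toward a data-independent consensus as `k` grows — run long enough, the case
and control networks of the same cell type become nearly identical and every
condition difference is erased. The informative regime is the first
`~1/α` rounds. The defaults, `alpha = 0.1`, `max_iter = 6`, `tol = 1e-3` on
the mean absolute change of W, keep just over half of the prior weight while
integrating the similarity messages; they were fixed once, from pilot runs
measuring whether planted condition structure survives inference, and all
planted-recovery tests in the suite run at these defaults. `alpha = 0` is a
testing mode that freezes W at the normalized motif prior exactly.

The change statistic is not monotone: it typically rises for a few rounds
while the companion layers re-standardize, then falls. The `grn` object
records the per-round deltas and a `monotone_after_burnin` diagnostic flag;
the property suite logs the flag rather than asserting it.

After the loop all three layers are standardized once more, so final edge
weights are z-score-like interaction strengths with a meaningful null at 0
(this is also what makes "positive edges" and "presence = weight > 0"
principled downstream). A consequence worth knowing: the total edge weight
of every inferred network is ~0 by construction, so *total* differential
targeting per cell type is near zero and the informative summaries are the
per-gene differences and the positive/negative mass split.

## 5. Targeting, communities, rewiring

**Targeting.** A gene's score is the sum of its in-degree edge weights,
negative weights included (a `positive_only` flag exists for sensitivity
analysis). The case-minus-control difference satisfies two identities used
as tests: it sums to the total edge-weight difference, and it is
antisymmetric under condition swap. "Normalized" differential targeting is
implemented as within-cell-type z-scoring — an interpretation, emitted
alongside the raw difference and both summary conventions (per-gene mean and
z-score total). Selection is strictly above the linear-interpolation third
quartile, so an all-tied profile selects nothing. Over-representation of a
focal gene set among selected genes uses the upper-tail hypergeometric test.

**Communities.** Community detection runs on the strictly positive edges.
Barber bipartite modularity is maximized by a deterministic optimizer:
BRIM-style alternating label sweeps (each side takes its best community
given the other side, ties to the lowest community id; a node whose best
attachment is negative detaches into a singleton) interleaved with greedy
community merges, from two initializations (gene singletons and a
fast-greedy seeding), best final score wins. The `seed` argument is recorded
for provenance but the optimizer itself has no randomness, so partitions are
bit-reproducible. On all graphs small enough to enumerate every partition,
the optimizer attains the exhaustive optimum (asserted in the suite).
Differential communities maximize the same intra-community sum over
`D_ij = w_case,ij/m_case − k_ctrl,i d_ctrl,j/m_ctrl²`; nodes absent from the
control contribute a zero null term, and the objective is invariant to
uniformly rescaling either network. The focal TF's community membership
(both TFs and genes by default; `genes_only` behind a flag) feeds the
cell-type x cell-type Jaccard matrix.

**Rewiring.** For each (focal-TF target that is also a protein of the
cooperativity layer, mechanism protein) pair, the regulatory weight comes
from the condition's regulatory network and the cooperativity weight from
its TF–TF layer (a user-supplied per-condition protein network is accepted
instead). Presence is strictly positive weight — 0 is the natural null of
the standardized networks; the threshold is configurable. Each axis changes
as gained/lost/stable between control and case; the four reported categories
pair a cooperation change with regulation altered/stable. Pairs whose
cooperation is stable fall outside the four-category report
(`regulation_only_change` or `unchanged`). The full 16-row mapping is
committed as a truth table in the test suite, and swapping case and control
maps gained to lost on both axes (an involution, also tested).

## 6. What the synthetic generator emulates

`synthetic_truth()` + `plant_perturbation()` + `simulate_counts()` produce a
two-condition, multi-cell-type single-nucleus study with full ground truth:

- **Counts** are negative binomial with per-gene dispersion (0.2–0.5),
  lognormal baseline means, a x4 marker elevation defining cell-type
  identity, lognormal library-size variation (σ = 0.3), expected depth 5000
  counts per cell, and three pseudo-replicates per condition realized as
  lognormal jitter (σ = 0.1) of the baseline means. The jitter is paired
  across conditions (replicate r shares its jitter in case and control, like
  littermate pairs), which makes the no-effect null exchangeable — the
  pooled Wilcoxon test is calibrated under this design and the suite's null
  check depends on it.
- **DE genes**: `n_de_per_type` genes per cell type shift by `±de_lfc` in
  the case condition (alternating sign).
- **Active TF**: one TF's regulon targets shift by 0.5 log2 units
  mode-consistently in case cells, so the planted activity change is
  positive by construction.
- **Module**: a 3-TF x `module_size` block, present in the case motif prior
  only and tied together by a case-only shared lognormal latent factor
  (σ = 0.5 × `module_boost`) in one cell type — a condition-specific
  regulatory module visible to both the prior and the coexpression layer.
  A single-TF module is not reliably recoverable by in-degree differences
  (one TF's gain is offset by the availability loss of the other TFs to the
  now highly self-correlated module genes); the multi-TF design reflects
  that co-regulated modules in this framework are multi-TF objects.
- **Rewired pairs**: four (target, mechanism protein) pairs, one per
  category. The category-to-edit mapping is documented in
  `apply_truth_to_priors()`: the focal TF → target motif edge and the
  target ↔ mechanism PPI edge are present/absent per condition according to
  the intended flags; cooperating pairs additionally share a private block
  of anchor target genes (similar regulatory profiles are what the TF–TF
  layer can detect); targets whose focal regulation is absent are handed to
  a decoy regulator with a mutually exclusive expression program, and the
  focal, mechanism, and target profiles are controlled (blanked outside
  their planted structure) so presence in the inferred network tracks the
  planted flags rather than background motif density.

Community detection is additionally exercised on three direct edge-list
benchmarks: a 4-block bipartite stochastic block model (20 TFs x 40 genes,
`p_in = 0.9`, `p_out = 0.05`), a planted case-only 4 x 8 unit-weight
biclique on a diffuse Bernoulli(0.2) x Uniform(0.3, 0.6) background, and a
configuration-model-like null (expected-strength weights `k_i d_j / m` with
5% lognormal noise — degree structure, no communities).

**What the generator does not emulate**: ambient RNA, doublets, batch
effects, realistic gene names, cell-type proportions, zero-inflation beyond
NB sampling, or unpaired replicate designs. Passing tests therefore show
the pipeline recovers structure of the planted kinds under NB noise at
these scales; they do not certify behavior on real tissue atlases.

Problem sizes in the suite are the study conditions stated above: 500
genes x 200 cells/group for DE calibration and recovery, 50 activity
simulations at 40 cells/group, 100 SBM seeds, 50 planted-module seeds, 20
null seeds, and the default 10 TF x 100 gene x 3 cell-type pipeline for the
end-to-end checks.

## 7. Numerical choices and degenerate inputs

- Quantiles are linear-interpolation (type 7) everywhere a quartile rule
  appears; selection above Q3 is strict, so ties at Q3 are excluded.
- z-scores of constant vectors are defined as 0; `normalize_prior()` of a
  constant matrix is all zeros.
- Tanimoto similarity of two all-zero vectors is 0; non-finite ratios are
  mapped to 0.
- The Wilcoxon exact path enumerates `C(n, nx)` assignments (≤ 12870), with
  a 1e-9 slack on the deviation comparison to absorb midrank float error.
- Zero-total cells abort log-normalization with the cell named; absent
  genes, missing cell types, mismatched gene universes, unassigned nodes,
  and absent focal TFs all abort with the offending identifiers listed.
- All randomness flows through explicit seeds; stage seeds derive
  deterministically from the master seed, and the run manifest records
  parameters, stage seeds, and output checksums so a rerun can be verified
  bit-identical.

## 8. Known limitations

- The message-passing budget trades evidence integration against condition
  contrast; a different α should be accompanied by re-running the
  planted-recovery suite rather than trusting the default budget.
- Pooled-cell DE is anticonservative under strong unpaired replicate
  effects; a pseudobulk-per-sample path is the natural extension and is not
  implemented.
- The four-category rewiring report excludes regulation-only changes by
  construction; users who care about those should read the full
  classification column.
- Percent-change prioritization of TF activity is unstable when control
  activities are near zero; the sentinel mechanism excludes such TFs from
  ranking rather than guessing.
- Atlas-scale quantities from real tissue runs (community sizes, Jaccard
  values between specific cell types, TF counts from external regulon
  databases) depend on external data resources and optimizer scale and are
  out of scope for the synthetic suite.
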