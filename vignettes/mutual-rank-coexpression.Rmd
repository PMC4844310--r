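---
title: "Mutual-rank coexpression meta-analysis and the endosperm exclusivity screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-rank coexpression meta-analysis and the endosperm exclusivity screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmr)
```

## The problem

Candidate gene discovery by guilt-by-association starts from a small set of
*bait* genes with a known, tightly defined expression context — here, genes
expressed exclusively in the endosperm of the developing cereal grain with a
peak around 3–4 days after pollination (DAP), the window of endosperm
cellularisation — and asks which other genes track the baits' expression
across public expression experiments. Two obstacles make this harder than a
single correlation screen:

* public experiments are heterogeneous: some survey many tissues with one
  time point, others sample one tissue densely through time, and absolute
  correlation values are not comparable across such designs;
* a correlation that is high in one experiment may be an artifact of that
  design (few distinct conditions inflate chance correlation).

`coexmr` addresses both with the *mutual rank* statistic computed per
experiment and combined across experiments, plus an explicit
expression-exclusivity screen for the developmental context.

## The mutual-rank statistic

Within one experiment, let $r_{ab}$ be the Pearson correlation of genes $a$
and $b$ over replicate-level samples (pairwise-complete when values are
missing). Ranking every other gene by descending correlation with $a$ gives
$\mathrm{rank}(a \to b)$; the reciprocal ordering gives
$\mathrm{rank}(b \to a)$. The mutual rank is their geometric mean:

$$\mathrm{MR}(a,b) = \sqrt{\mathrm{rank}(a \to b)\cdot\mathrm{rank}(b \to a)}$$

MR is low (minimum 1) only when each gene sits near the top of the *other's*
ranking, which suppresses hub effects where one promiscuously varying gene
correlates with everything. Being rank-based, MR is comparable across
experiments with very different designs, which raw $r$ is not.

Conventions, all deterministic:

* ranks are over descending raw $r$ (negative correlations rank last; the
  screen looks for co-regulated genes, not antagonists);
* the self-pair is excluded before ranking; ties receive average ranks;
* a correlation is only computed from at least `min_pairs` (default 4)
  pairwise-complete observations, and zero-variance genes are excluded with
  a recorded reason.

## Cross-experiment combination

Per-experiment MRs against a bait are combined with the geometric mean over
contributing experiments (equivalently, the arithmetic mean of $\log
\mathrm{MR}$), the natural average for a ratio-scale rank product; a
conservative `max` policy is available. Coverage is accounted for
explicitly: by default a gene must be scoreable in *every* experiment in
which the bait itself is measured (`min_coverage = "bait"`), so a gene
cannot earn a good combined MR by being absent from the experiments that
would contradict it.

Candidates are genes whose combined MR is strictly below a threshold
(defaults 20 and 50) against **every** bait simultaneously; baits are
excluded from candidacy, and members are reported in ascending order of
their worst-case (max-over-baits) MR. Strict `<` at the threshold and the
lexicographic tie-break make candidate tables reproducible byte for byte.

## The exclusivity screen

The screen operationalizes "expressed exclusively during grain development,
restricted to the endosperm, peaking at 3–4 DAP" as a rule over condition
(tissue × stage × genotype) group means:

* **floor** — a gene counts as expressed in a group only when the group mean
  exceeds an expression floor; by default the 25th percentile of each
  experiment's value distribution, a robust proxy for array background. The
  floor is per-experiment because background levels differ between arrays.
* **exclusivity** — in every experiment whose design contains both target
  (endosperm/caryopsis) and off-target tissue, every off-target group mean
  must stay at or below
  $\mathrm{floor} + \rho_x\,(\text{best target mean} - \mathrm{floor})$,
  with `exclusivity_ratio` $\rho_x = 0.15$ by default. Published array
  studies rarely state a presence threshold; a ratio on group means is
  robust to background shifts and tunable.
* **indeterminate** — a gene never observed alongside off-target tissue
  cannot be called exclusive or non-exclusive; absence of contrast is not
  evidence. This third status is never silently merged into either verdict.
* **peak** — the expressed target group with the highest mean; ties break
  toward the earlier stage, consistent with the focus on early endosperm
  development.

Verdicts are rendered as compact labels in the style of a published
expression-survey table, e.g. `3-4 DAP, 5-10 DAP, endosperm`. Two rendering
rules are worth stating because the underlying data cannot force them:

* fine-grained stages (a daily time-course) are folded into canonical stage
  windows (`before anthesis`, `1-2 DAP`, `3-4 DAP`, `5-10 DAP`,
  `11-20 DAP`) by midpoint containment, so a gene expressed at 3 and 4 DAP
  daily reads `3-4 DAP`;
* tissue restriction is claimed only from experiments containing at least
  two distinct tissues — a single-tissue time-course cannot witness
  restriction.

Stage labels order by their midpoint on the DAP axis; interval labels such
as `3-4 DAP` or `2 to 4 DAP` parse numerically (the hyphen is a range
separator), and pre-pollination states (`before anthesis`, `vegetative`)
take negative midpoints from a configurable vocabulary.

Genotype contrasts (`compare_genotypes()`) report per-genotype mean ± SE and
the linear-scale fold change $2^{\bar{x}_B - \bar{x}_A}$ under the package's
log2 input contract; the SE of a single replicate is reported as
not-available rather than a misleading 0. The package performs no
normalization and no differential-expression testing: inputs are assumed
RMA-style log2 values, and the genotype comparison is descriptive, as in the
source figures it mirrors.

## The synthetic atlas

`make_atlas()` generates a multi-experiment atlas in which the answer is
known, so every stage of the pipeline is testable without downloading any
accession. The default emulates the mix of public designs the analysis is
meant for, at the study's own scale:

* `SIM-TD` — tissue-diverse survey: leaf, root, seedling, embryo,
  endosperm; 3 replicates each (15 samples);
* `SIM-TC` — dense early time-course: caryopsis sampled daily 1–10 DAP,
  3 replicates (30 samples);
* `SIM-RS` — reproductive series: anther, pistil, lemma before anthesis
  plus an endosperm series from before anthesis to 11–20 DAP, 3 replicates
  (24 samples).

The planted module (6 genes including the 3 baits by default) follows one
shared stage template — maximal over 3–4 DAP, declining linearly to
baseline by 10 DAP, silent before 3 DAP and in off-target tissue — scaled
per gene (amplitude 6 log2 units × U(0.8, 1.2) above a baseline of 4).
Module coexpression is controlled by a single knob $\rho$ (default 0.95)
acting in two places: the shared template enters each gene's condition
profile with weight $\rho$ (blended with a gene-private profile at
$1-\rho$), and replicate noise (sd 0.2 log2 units) contains a shared
per-sample latent factor with loading $\sqrt{\rho}$. A latent-factor
construction is always positive semi-definite and needs no explicit
correlation matrix. The template is deliberately *shared*: profile-shape
heterogeneity between module genes would dilute exactly the mutual
coexpression the module is planted to carry.

Background genes get a per-gene overall level (baseline + U(0, 7)) plus
moderate, incoherent per-group jitter (sd U(0.25, 1.25) log2 units, drawn
independently per experiment). Two deliberate exclusions define what
"unrelated background" means here:

* no background gene carries a strong, reproducible preference for the
  target condition — such a gene would be genuinely coexpressed with the
  module, i.e. not background;
* jitter is capped well below the planted amplitude, so no background gene
  mimics the on/off contrast of the module at group level.

`rho = 0` is the null control: the module structure is absent, "module"
genes are drawn from the background model, and the truth exclusivity flags
are false. This is a discontinuity, not the $\rho \to 0$ limit, and it is
intentional: endosperm-exclusive genes are intrinsically correlated by
their shared on/off pattern, so the only meaningful "no planted
correlation" control removes the planted profile altogether.

What the generator does **not** emulate: probe-level effects, array
background and saturation, cross-hybridization, batch structure, and
genuinely coexpressed non-module pathways. Passing recovery tests on this
atlas therefore demonstrates the pipeline's statistical behavior under
known truth, not performance on any real accession — in real data,
candidate lists can legitimately contain unplanned genes that share the
baits' context.

## Recovery behavior and a known statistical limit

On the default conditions (module 6 incl. 3 baits, $\rho = 0.95$, noise sd
0.2, 3 experiments, 500 background genes), the pipeline recovers the
planted module at combined MR < 20 with recall 1.0 in every seeded run we
compute, and the null control returns zero candidates. Precision is
usually 1.0, but a measurable minority of runs (about one in five over a
100-seed sweep) admits exactly one false positive. This is a rank-statistics
floor, not a fixable defect: among ~500 interchangeable background genes,
the best chance alignment of reciprocal ranks across three experiments
occasionally clears a geometric-mean MR of 20 — replacing the background
with pure i.i.d. noise makes it slightly *worse*, confirming the mechanism
is permutation chance rather than background structure. With only three
recoverable module genes, a single false positive drops that run's
precision to 0.75. The practical reading for real analyses: at this
problem size an MR < 20 list is short and high-recall but may carry an
occasional chance entry, which is one reason the original analysis
inspected candidate profiles individually and used multiple accessions.

## Numerical and degenerate-input choices

* Duplicate gene rows (array probe sets mapping many-to-one) collapse by
  `max_mean` by default — the highest-signal row is conventionally
  retained; `first` and `error` policies are available.
* Missing values: configurable token (default `"NA"`); correlations use
  pairwise-complete observations; groups with all values missing are
  omitted from profiles.
* `exclusivity_ratio = 0` with an unbounded floor reduces the screen to
  "expressed in target groups only": the tolerated off-target bound
  degenerates to the floor itself (the 0 × ∞ case resolves to "no
  tolerated off-target signal").
* All table writers emit fixed column orders, deterministic row orders
  (ascending combined MR, lexicographic tie-breaks) and 6-significant-digit
  numerics, so identical runs are byte-identical and write→read round-trips
  agree to that precision.
* Generated atlases are a pure function of their spec (including the
  seed); generation restores the caller's RNG state.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
oracle comparisons use 50 random experiments of up to 20 genes × 10
samples; recovery sweeps use 20 replicate atlases of 506 genes ×
69 samples across the three default designs, plus 20 matched null
atlases. These sizes exercise every code path at full statistical scale
for the study conditions while keeping a complete run in the low minutes
on one CPU.
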