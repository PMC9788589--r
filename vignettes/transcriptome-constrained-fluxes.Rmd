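---
title: "Transcriptome-constrained metabolic flux analysis across disease states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-constrained metabolic flux analysis across disease states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxgem)
```

# The problem

Bulk RNA-seq tells us which metabolic enzymes a tissue expresses; a
genome-scale metabolic model (GEM) tells us which reactions those enzymes can
catalyze and how they are stoichiometrically coupled. `fluxgem` combines the
two: it extracts a context-specific model per condition from expression data,
predicts a unique steady-state flux distribution per condition guided by that
expression, and then asks comparative questions across conditions —
which subsystems change structurally, which change functionally, and in what
order the conditions arrange themselves along a pseudo-temporal trajectory.
The package is organized around an eight-state liver-disease design (four
alcohol-related states of increasing severity, a healthy control, and three
non-alcohol-related disease states), but every step is generic.

# Context-specific model extraction

Each reaction in a GEM carries a GPR (gene-protein-reaction) rule: a boolean
expression over genes in which `AND` encodes an enzyme complex and `OR`
encodes isozymes. Scoring a rule against per-gene expression replaces `AND`
with `min` (a complex is limited by its scarcest subunit) and `OR` with `max`
(any isozyme suffices). `AND` binds tighter than `OR`; both are
case-insensitive; a gene absent from the expression table scores 0 with a
warning, on the view that absent evidence should not support a reaction.

Extraction applies a strict threshold on the per-state score: a reaction is
kept when its rule, evaluated on the per-gene **maximum TPM within the
state**, exceeds 1 TPM. Reactions with no rule at all (exchanges, spontaneous
reactions) are retained by default, since the rule-based procedure has no
evidence to exclude them; `keep_no_gpr = FALSE` drops them instead. Every kept
reaction carries exactly one provenance tag: `expression_supported`,
`no_gpr_retained`, or `task_rescued`.

Extraction can disconnect essential functions, so a list of metabolic tasks
("produce these outputs from these inputs at steady state") guards viability.
`check_task()` decides feasibility with an LP over the extended network
(temporary uptakes capped at the stated maxima, temporary demands required at
the stated minima) at a residual tolerance of 1e-6. `gap_fill()` restores any
failing task by re-admitting excluded reactions: an exhaustive size-ordered
subset search returns a true minimal-cardinality rescue set whenever the
candidate pool is small (at most 20 candidates, within a fixed probe budget),
with ties broken lexicographically on reaction ids; past that, a greedy rule
(add the reaction that most reduces the unmet demand) takes over and is
flagged in the result.

```{r extraction-example, eval = FALSE}
scores <- score_reactions(model, profile)          # per-state GPR scores
ctx <- threshold_extract(model, scores, threshold = 1)
ctx <- gap_fill(ctx, model, tasks)
```

# Flux prediction: an objective from expression, then a unique flux

A liver GEM has no self-evident objective like biomass. The package therefore
builds one from expression (the SPOT construction): find the steady-state
flux pattern `v >= 0` (reversible reactions split into forward/backward
components, each carrying the reaction's score) maximizing the uncentered
cosine `v.g / (||v|| ||g||)` with the score vector `g`. The method literature
describes this quantity as a Pearson correlation; the printed formula is the
uncentered cosine, and that formula is what is implemented (a mean-centered
variant sits behind `centered = TRUE` without any claim of equivalence).
Because the ratio is scale-invariant, the optimum over the cone
`{S v = 0, v >= 0}` intersected with the unit ball is the Euclidean
projection of `g` onto the cone, normalized — a strictly convex quadratic
program with a unique solution. The achieved cosine is reported alongside
the unit direction `f'`.

Flux prediction then proceeds in the E-Flux2 pattern:

1. **Bounds from expression.** A reaction with score `g_j` is bounded to
   `[0, g_j]` (irreversible) or `[-g_j, g_j]` (reversible). Rule-less
   reactions keep their model bounds — in practice this covers exchange
   reactions, which are not enzyme-limited. The score plays the role of both
   the lower and upper expression bound; the symmetric convention for
   reversible reactions is a documented choice, as no separate minimum score
   exists.
2. **FBA.** Maximize `f'.v` subject to `S v = 0` and the bounds, giving the
   optimum `z*`.
3. **l2 uniqueness.** Over the optimal face `f'.v = z*`, minimize
   `sum(v_j^2)`. The strictly convex objective makes the result unique, so
   two solves with permuted reaction order agree to 1e-5.

All linear programs are solved through a dual active-set quadratic-program
core: the LP optimum is obtained by an exact regularization path (minimize
`eps/2 ||v||^2 - f'.v` with decreasing `eps` until the achieved objective
stabilizes), which for small enough `eps` lands exactly on the least-norm
maximizer. This needs finite bounds, which metabolic models provide, and it is
deterministic — no simplex pivoting rules, no solver-seed sensitivity.
Tolerances are centralized in `fluxgem_tol()`: feasibility 1e-6, uniqueness
agreement 1e-5, objective convergence 1e-9.

A reaction is **measurable** when its predicted flux magnitude exceeds
0.1 mmol/gDW/h (strict) in at least one state; measurable reactions are kept
across all states' columns.

# Comparative statistics

*Structural comparison.* Context models over one parent are compared as
binary presence vectors on the union reaction set; Hamming similarity is
`1 - disagreements/total`. Models are rank-ordered by reactions, metabolites,
genes, and unique gene rules, where rules are counted after canonicalization
(operands sorted, nested same-operator nodes flattened), so `G1 AND G2` and
`G2 AND G1` are one rule. The subsystem coverage screen flags a subsystem
when some model pair differs by more than 10% — the denominator is the larger
count of the pair, which keeps the measure symmetric; this denominator is a
documented choice. A drill-down collects the flagged subsystems' reactions
that are *not* common to all models, maps them to unique canonical rules, and
reports per-model counts with z-scored (across states; zero-variance genes
map to zero) expression of the rules' genes.

*Functional comparison.* Fluxes are summed per subsystem as magnitudes
(`|v|`), because the sign of a reversible flux is a solver convention; a
signed option exists. Differential activity across states is screened with
pairwise two-sided Wilcoxon rank-sum tests, using the per-reaction fluxes
within a subsystem as replicate units — a pragmatic choice (one model per
state leaves no biological replicates) that is recorded in the output rather
than silently assumed. P-values are exact when `n + m <= 16` without ties and
use the normal approximation with continuity and tie corrections otherwise;
raw p < 0.05 is the screening rule, with Benjamini–Hochberg available but off
by default to match the screening character of the analysis. Hierarchical
clustering of flux rows z-scores each row, uses 1 − Pearson correlation as
the distance and average linkage (the common heatmap default; both are
configurable), and cuts the tree at k = 2 for all measurable fluxes and
k = 4 for transport fluxes. Per transport cluster, a frequency table of
canonical gene rules identifies the dominant rule (lexicographic tie-break,
flagged), and an import/export map classifies each transported species by
flux-oriented direction relative to a designated interior compartment
(default `"c"`), keeping only species moved in exactly one direction.

# Trajectories

State-level profiles (log2 mean TPM for genes; predicted measurable fluxes,
which share units and are left unscaled) are reduced by PCA — always
centered, component signs fixed so the largest-magnitude loading is positive,
making outputs byte-reproducible. The minimum spanning tree over Euclidean
distances in the retained PC space orders the states; a depth-first traversal
from a chosen root (default the healthy state) yields the pseudo-temporal
ordering, and nodes of tree degree >= 3 are reported as branch points.
Kruskal's algorithm with (weight, edge-label) ordering makes the tree
deterministic under ties. The number of retained PCs is the smallest
explaining 90% of variance, floored at two — without the floor a single
dominant axis can swallow the cutoff and collapse genuine branch structure.
The gene-level matrix is log-transformed rather than per-gene unit-scaled:
with many flat background genes, unit scaling would hand every pure-noise
gene the same weight as a signal gene.

# What the synthetic generator emulates — and what it does not

The generator builds the whole study at desk scale, so every stage is
testable without any external download.

* **Network.** Linear import → conversion → export pathways over three
  compartments (extracellular, cytosol, organelle), each with exchange
  reactions at both ends; every third pathway routes through the organelle
  (adding two transports) and every fourth has a reversible conversion.
  Internal and transport reactions get dedicated GPR rules — single gene,
  AND pair, or OR pair in configurable proportions (default 50/25/25).
  Dedicated (unshared) genes are what make the score-activity contract exact:
  a reaction's noiseless score exceeds 1 TPM exactly when the reaction is
  active. The price is that rule-frequency tables on synthetic data are
  tie-heavy; the dominant-rule analysis is exercised separately on a
  constructed fixture with realistic rule sharing.
* **Planted structure.** Pathway 1 is the GSH-like chain whose flux is
  scaled by monotone multipliers across the four ALD states (defaults 2, 4,
  8, 16 — a geometric ladder so each severity step is distinguishable);
  pathway 2 is perturbed in the NALD states (2, 4, 8 across NASH, HCV,
  compensated cirrhosis), giving the trajectory a recoverable branch at
  healthy; pathway 3 is active only in ALD states (structural divergence
  between context models); the last two pathways are dormant everywhere
  (their reactions must stay out of every context model except by task
  rescue).
* **Ground truth fluxes.** A base feasible flux is sampled by a
  random-objective LP with per-pathway capacity caps (uniform 2–5
  mmol/gDW/h), scaled per state by the multipliers with small multiplicative
  jitter (s.d. 3%) on unplanted pathways, and re-projected onto the
  steady-state polytope; the residual guarantee is 1e-8.
* **Expression.** Each gene's designed state-level TPM is 10 per unit of its
  reaction's flux magnitude, floored at 0.2 TPM for inactive reactions — one
  decade above and five-fold below the 1-TPM threshold respectively. Three
  hundred background genes with log-normal means absorb the rest of the
  library so designed TPMs live on the absolute scale; designed TPMs are
  renormalized per state to sum to one million, making the noiseless
  round-trip through TPM normalization exact. Counts are negative-binomial
  (dispersion 0.1, the RNA-seq convention; 0 returns expectations), with
  gene lengths log-uniform on 500–5000 bases and per-state sample sizes
  mirroring the cohort design (10/18/11/12/10/9/10/9).

What it does **not** emulate: human transcriptome scale (hundreds rather
than tens of thousands of genes), shared regulation between pathways,
isoform-level effects, batch structure, or clinical covariates. Passing
recovery tests on this generator therefore demonstrates that the pipeline's
machinery is correct and well-calibrated, not that the biological
conclusions of any particular study transfer.

# Numerical choices and degenerate inputs

* Strict inequalities at both decision thresholds (1 TPM, 0.1 mmol/gDW/h).
* All-zero expression columns normalize to zero with a warning; constant
  matrices are an error for PCA (no variance to decompose); constant rows
  z-score to zero and are treated as uncorrelated in clustering.
* A zero score vector makes the SPOT construction degenerate: it returns a
  flagged zero objective instead of failing.
* A fully tied Wilcoxon comparison (zero rank variance) reports p = 1.
* Equality constraints are rank-reduced before the QP solve, with dropped
  rows verified against the solution.
* One integer seed drives everything; reruns with the same configuration are
  byte-identical (the run manifest's timestamp aside).

# Problem sizes

The shipped analysis and tests run the default study: ~63 reactions, ~52
metabolites, ~60 model genes plus 300 background genes, 89 samples over 8
states. The end-to-end recovery checks use one full pipeline run for the
recovery and rank-correlation criteria and 100 seeded replicates for the
trajectory-recovery rate; a replicate takes on the order of a second. These
sizes are the package's chosen desk-scale study design; all stages accept
larger inputs through the same interfaces.

# Known limitations

* The exact-regularization LP path requires finite bounds; models with
  unbounded reactions must be capped first (conventional GEM practice).
* Gap-fill minimality is guaranteed only within the exhaustive-search
  budget; greedy rescues are flagged but not minimal-certified.
* The subsystem screen's replicate unit (reactions within a subsystem)
  answers "does this subsystem's flux distribution differ", not a
  patient-level hypothesis; with one model per state nothing stronger is
  available.
* The SPOT optimality certificate is a convexity argument plus sampled
  verification, not an enumeration of the cone's extreme rays.
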