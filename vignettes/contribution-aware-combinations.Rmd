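---
title: "Contribution-aware search for multi-drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contribution-aware search for multi-drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdcombo)
```

## Scope and model

`ctdcombo` searches for small sets of drugs whose combined, direction-aware
effect on a disease gene module best matches a desired *counteraction
vector*: `-1` for genes whose activated signal should be suppressed, `+1`
for genes whose depleted function should be restored. The package ships
ten lung-adenocarcinoma driver modules (RTK activation, EGFR exon-20,
KRAS–MAPK, STK11/KEAP1, BRAF–MAPK, PI3K/AKT/mTOR, ERBB3–NRG1, DNA-damage
response, RET/NTRK fusions, SMARCA4 deficiency) spanning 44 distinct
genes; user modules load from YAML/JSON. Counteraction magnitudes are
always exactly 1 — the model deliberately encodes *direction*, not dose.

Three modeling layers sit on top of the input interaction records.

**Regulation bias.** Interaction databases report the same drug–gene pair
with conflicting directions across studies. We classify each action label
as up, down, or non-directional (ten directional labels by default; note
that *increasing* degradation or ubiquitination lowers the gene product
and therefore counts as downregulation), sum evidence counts per
direction, and resolve each pair to the bounded ratio
$r_{g,j} = (U - V)/(U + V) \in [-1, 1]$. Pairs with total evidence below
`min_evidence` (default 1) or $|r| <$ `ambiguity_threshold` (default 0.2)
are zeroed — a conservative stance: balanced conflicts carry no usable
direction. Both knobs are exposed because reasonable curation policies
differ; weighting by reported reference counts (rather than one vote per
row) is likewise a choice, and collapses to row-counting when counts are
absent.

**Additive effect with saturation.** A combination's per-gene effect is
the clipped sum $\hat e_g = \mathrm{clip}(\sum_{j \in S} r_{g,j}, -1, 1)$
over the *distinct* drugs of the chromosome — a drug cannot be taken
twice in a set-based model, so duplicate slots collapse. Clipping encodes
saturation; no other pharmacological interaction (synergy, antagonism,
dose, PK/PD) is modeled, which is the model's most important limitation.

**Attribution.** Per gene, credit for $\hat e_g$ is allocated across the
drugs either proportionally,
$a_{g,j} = \hat e_g\, r_{g,j} / S_g$ with $S_g = \sum_k r_{g,k}$ (all
zero when $S_g = 0$), or as the Shapley value of the cooperative game
$f_g(T) = \mathrm{clip}(\sum_{k\in T} r_{g,k}, -1, 1)$. Proportional
attribution is exact for efficiency, sign-preserving, and fast — it is
the search default. Shapley attribution is the audit path when clipping
or redundancy matters: with at most 7 active drugs the exact value is
computed by subset enumeration (`2^7` coalitions at most), and a
Monte-Carlo estimator over sampled orderings (256 by default, seeded) is
provided for parity with larger settings; its deviation from exact is
measured empirically in the test suite rather than assumed.

## The composite fitness

$$J = \alpha\,\mathrm{MAE} + \beta R_{waste} + \gamma R_{mis}
  + \eta R_{entropy} + \lambda R_{count} + \kappa R_{cost} - \tau\,Cov$$

| term | meaning | default weight |
|---|---|---|
| MAE | mean $|c_g - \hat e_g|$ over scenario genes | $\alpha = 1$ |
| $R_{waste}$ | same-direction credit beyond $|C_i|$ (overshoot) | $\beta = 0.2$ |
| $R_{mis}$ | credit opposing the target direction | $\gamma = 0.2$ |
| $R_{entropy}$ | Shannon entropy of same-direction credit shares | $\eta = 0.05$ |
| $Cov$ | direction-correct fulfillment, capped at $\omega_i$ per gene | $\tau = 0.2$ |
| $R_{count}$ | #drugs with credited usage above $\varepsilon$ | $\lambda = 0.05$ |
| $R_{cost}$ | summed user costs of used drugs | $\kappa = 0$, then 1 |

Design decisions a maintainer should know about:

* **Masked evaluation.** Every term, including the MAE denominator, runs
  over scenario genes only ($C_i \neq 0$). Off-target genes would
  otherwise dilute the error, and an "MAE of 0" should mean exactly that
  the module is fully counteracted.
* **Magnitudes in the penalties.** Waste and mismatch sum absolute
  credited values, making both symmetric for up- and downregulated
  targets and keeping the penalties non-negative.
* **Coverage.** Implemented as
  $\sum_i \omega_i \min(|C_i|, m_i)/|C_i|$ with $m_i$ the
  same-direction credit mass — direction-correct fulfillment capped at
  $\omega_i$, so overshoot earns nothing.
* **Normalization.** Before weighting, waste/mismatch/entropy are divided
  by the number of scenario genes, coverage by $\sum_i \omega_i$, and the
  count term by the slot budget $K$, putting all weighted terms on
  comparable $O(1)$ scales. The scheme is configurable rather than
  canonical.
* **Entropy** uses the natural logarithm with $0\log 0 := 0$; genes with
  no same-direction credit contribute 0.
* $\varepsilon = 10^{-9}$ in the count/cost indicators; $\mathrm{sgn}(0)$
  is 0, so zero attributions belong to neither sign class.

With $\alpha = 1$ and all other weights 0 the composite ranking equals
the plain MAE ranking — this baseline is wired into
`compare_mae_only()`, which runs the full and MAE-only objectives under
identical seeds and budgets for every (scenario, combination size) cell;
with the ten packaged scenarios and sizes 1–6 the grid has 60 cells.

## The genetic algorithm and the cycle pipeline

Chromosomes are $K$ slots over the drug library plus an empty sentinel,
giving variable combination size inside a fixed-length encoding.
Operators the search literature leaves open were fixed as: tournament
selection (size 3) — robust for categorical fitness landscapes; uniform
crossover (rate 0.9) — slots carry no positional meaning; per-slot
mutation (rate 0.2) to a uniformly random allele; one elite individual,
which guarantees the best-so-far curve is monotone non-increasing.
Evaluations are memoized per active drug set, so on small libraries the
GA's cost is bounded by the number of distinct combinations rather than
by population × generations. Each of the (default 10) repeats runs under
seed `base + run - 1`; identical seeds give bit-identical outputs.

The default cycle schedule mirrors a coarse-to-fine screen: cycle 1
searches the *union* of all scenarios (one consistent direction per gene
is enforced) with population 500 × 100 iterations, combination ceiling
raised to 7 and no cost term; cycles 2 and 3 refine each scenario at
250 × 70 and 150 × 10 with the cost term active. Between cycles the
library can only shrink: drugs whose credited usage never exceeds
$\varepsilon$ in any retained solution are dropped. The original
workflow's manual literature vetting between cycles is out of scope here;
its effect is modeled by user-supplied exclusion and cost files applied
by `screen_library()`.

After search, solutions are de-duplicated by unordered drug set within
(scenario, cycle); `pareto_filter()` keeps the best MAE per combination
size (ties broken by lower composite J, then lexicographic drug set, for
determinism) and marks non-dominated points — equal-MAE ties resolve
toward the smaller combination. `group_alternatives()` partitions
scenario genes by their coverage pattern across candidate drugs and lists
every drug under each gene cluster it fully supports in the desired
direction; groups are lettered by decreasing cluster size. Hierarchical
clustering of the effect matrix (`cluster_effects()`) defaults to average
linkage on Euclidean distances, with rows/columns pre-sorted by label so
the result is invariant to input order; a 1×n matrix degenerates to an
identity ordering with no dendrogram.

## What the synthetic generator does and does not emulate

`fixture_spec()` / `generate_interaction_file()` emit CTD-shaped
interaction tables whose per-pair report counts are chosen so that
conflict resolution reproduces a known ground-truth matrix cell-for-cell
(bias magnitudes are snapped to the representable grid
$\{1, 0.8, 0.6, 0.5, 1/3\}$ with at most 9 reports per direction);
`conflict_rate` controls the fraction of pairs with opposing reports.
`plant_scenario()` builds libraries containing a known combination that
reproduces the counteraction vector exactly, surrounded by decoys chosen
to stress individual fitness terms — null players, opposing drugs,
partial drugs that help some genes and hurt another — and certifies by
exhaustive enumeration that the planted set is the *unique* zero-MAE
solution before returning (retrying seeds otherwise).

The generator reproduces the data's *shape* — conflicting directions,
sparse coverage, non-directional actions, malformed rows — but not its
biology: no realistic gene–gene correlation, no study-level metadata, no
bias toward well-studied drugs. Passing tests therefore demonstrate that
the machinery is correct and that the search recovers known optima under
controlled conditions; they say nothing about whether real interaction
snapshots support any particular clinical hypothesis.

## Problem sizes used by the tests and the acceptance script

Module tests run on matrices of roughly 5–12 drugs × 4–10 genes with GA
budgets of 20–80 individuals over 4–20 generations — small enough that
exhaustive enumeration can serve as the oracle. The acceptance checks
use: the packaged 10-scenario registry; a 44-gene × 15-drug synthetic
matrix with a 12 × 3 × 1-run GA per comparison cell; 1000 random
fixtures for attribution efficiency; 25 fixtures for the Monte-Carlo
deviation bound; 100 random libraries (6–10 drugs, $K = 3$, fine-search
budget 150 × 10 × 10 runs) for the enumeration benchmark; and a planted
2-drug optimum among 10 decoys for the recovery check. These sizes are
the package's chosen proof-of-concept conditions; scale the schedules up
for real libraries.

## Known limitations

Beyond the saturation-only interaction model noted above: evidence
aggregation pools cell types, doses and diseases, so a bias is a
literature summary, not a context-specific response; scenarios are
binary-direction literature modules, not patient profiles (though the
scenario interface accepts any gene → direction mapping); the GA is a
heuristic and offers no global-optimality guarantee outside the small
libraries where the enumeration oracle verifies it; and weight settings,
while fixed a priori and exposed in `fitness_weights()`, necessarily
shape which trade-offs win ties.
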