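---
title: "Permutation-null analysis of temporal-cohort wiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-null analysis of temporal-cohort wiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortwiring)
```

## The question and the model

Neuroblast lineages produce neurons in a stereotyped birth order, and
neurons born in the same temporal window (a *cohort*) often share
molecular identity. This package asks a connectomic version of that
observation: **do neurons of the same temporal cohort receive synaptic
input from the same presynaptic partners, more than expected by
chance?** Two idealised alternatives frame the analysis:

* **sharp model** — cohorts form discrete blocks; within-cohort neurons
  draw partners from a shared pool, across-cohort neurons do not;
* **graded model** — partner composition drifts continuously with birth
  rank, with no block boundaries;
* **null model** — partner choice is independent of birth order.

The data model is deliberately small: a *neuron catalog* of annotations
(side, segment, source type, sensory class, morphological class,
lineage, hemilineage, birth order, cohort, left–right homolog), a
directed weighted *synapse table* `(pre_id, post_id, count)` with
positive integer counts, and rooted-tree *skeletons* with a marked soma
and neuropil-entry node.

## The core statistic

For a set of analyzed neurons, `build_input_matrix()` tabulates each
neuron's inputs as a vector over a **shared, sorted presynaptic
universe** (the union of presynaptic ids observed over the analyzed set,
identical column order for every row). In `count` mode entries are
synapse counts; in `binary` mode they are presence/absence bits.

For each pair of neurons the observed Euclidean distance `d` between
their input vectors is compared to a **permutation null**: in each of
`n_perm` permutations, every row is independently shuffled over the
universe (preserving its in-degree and its multiset of synapse counts,
and destroying partner identity), and the pair distance is recomputed.
With `m` and `s` the mean and (n−1) standard deviation of the shuffled
distances,

```
z = (d − m) / s
```

A pair is called **similar** when `z < −1.96` and **different** when
`z > +1.96` (thresholds derived from `alpha = 0.05` two-tailed via
`qnorm`, not hard-coded). Negative z means the observed distance is
smaller than chance, i.e. shared partners beyond chance. Pairs whose
null has zero spread (e.g. a one-column universe) are flagged
`undefined` and never called significant.

Two properties follow from the construction and are exercised in the
test suite:

* **Conservation** — every shuffled row is a permutation of the
  original row, so in-degree and count multisets are preserved exactly.
* **Exchangeability/calibration** — under wiring with no partner
  structure, the observed vector is exchangeable with its shuffles, so
  the similar-call rate approaches `alpha/2`.

```{r example}
g <- generate_connectome(synth_config(seed = 1, hemisegments = "L"))
ids <- g$truth$analyzed$L
sub <- inputs_onto(g$edges, target_set("lineage", ids))
res <- distance_analysis(sub, ids, catalog = g$catalog,
                         n_perm = 100, seed = 2)
table(truth_same_cohort =
        outer(g$truth$cohort[ids], g$truth$cohort[ids], "==")[upper.tri(res$z)],
      called_similar = res$similar[upper.tri(res$z)])
```

## Input accounting

Before the distance statistic, the package reproduces the bookkeeping
that motivates it: `compose_by_source_type()` (interneuron / sensory /
brain-or-SEZ / unknown-fragment percentages, exact-100 sum),
`sensory_breakdown()`, `synapse_histogram()` with configurable bins and
`ks_compare()` (exact Kolmogorov–Smirnov p when both samples are ≤ 25
and tie-free, asymptotic otherwise), `class_composition()`, and two
filters used to define analysis sets:

* `lr_pair_filter()` — a left–right pair of presynaptic neurons is
  retained when one member makes **≥ 4** synapses onto a target and the
  other makes **≥ 2** onto the hemisegmentally homologous target (either
  role assignment qualifies; midline neurons play both roles). The
  thresholds are parameters (`thr_high`, `thr_low`).
* `highly_connected()` — neurons making **≥ 10** synapses onto the
  target set (parameter `min_syn`), expanded to both pair members.

## Birth order from morphology

`cortex_neurite_length()` measures the along-skeleton geodesic from the
soma to the neuropil-entry node (sum of parent–child segment lengths on
the unique tree path, found by least-common-ancestor climb; an
`igraph` shortest-path computation serves as an independent oracle in
the tests, not in the package code). `birth_order_correlation()` then
reports the Pearson correlation of that length with birth rank
(`stats::cor.test`; ≥ 3 complete pairs required, zero variance is an
error).

## The synthetic generator

`generate_connectome(synth_config(...))` produces a catalog, edge
table, chain skeletons, and a ground-truth record, deterministically
from one seed (`withr::with_seed`; regeneration is bit-identical).
Defaults and their rationale:

| parameter | default | rationale |
|---|---|---|
| `n_neurons`, `cohort_breaks` | 13, (2, 7) | one lineage of 13 neurons: 2 early non-cohort cells, a 5-neuron early cohort, a 6-neuron late cohort |
| `universe_size` | 200 | enough candidate partners that disjoint cohort pools are feasible |
| `p_within`, `p_across` | 0.8, 0.05 | the sharp-model contrast the recovery tests assume |
| `pool_size`, `pool_overlap` | 30, 0 | disjoint pools give the sharpest contrast; overlap softens toward graded |
| `drift_rate` | 0.2 | graded model: per-rank partner turnover |
| `count_geom_p`, `count_max` | 0.8, 30 | truncated geometric counts: ~80% of edges carry one synapse, none above 30 |
| `count_strong_frac` | 0 | optional strong-edge mixture (uniform 10–`count_max`), off by default (see limitations) |
| `sensory_frac`, `interneuron_frac` | 0.19, 0.61 | universe source-type composition, so dropout variants are exercised |
| `mirror_noise` | 0.1 | per-edge probability that the right hemisegment resamples instead of copying the left |
| `paired_partner_frac` | 0 | fraction of partner channels emitted as explicit L/R id pairs |
| `skeleton_base/slope/noise_sd` | 10, 5, 2 | cortex neurite length grows with birth rank plus Gaussian noise |

Two design choices deserve explanation:

* **Partner channels are midline (side M) identities by default.**
  Left and right hemisegment neurons synapse onto the *same* partner
  ids, so at `mirror_noise = 0` a neuron and its contralateral homolog
  have *identical* input vectors over the shared universe — the
  behaviour the mirroring contract requires. Emitting distinct L/R
  partner ids for every channel would make that impossible (the two
  sides would never share a column). `paired_partner_frac` exists to
  emit a fraction of channels as explicit bilateral pairs where the
  left–right pairing rule itself is under test.
* **The strong-edge count component is off by default.** Real
  reconstructed wiring contains multi-synapse contacts whose strength
  is *partner-correlated* (the same partner is strong onto both members
  of a pair). The generator's count law is attached to edges
  independently of partner identity, so a strong-edge mixture behaves
  as heavy-tailed noise on the count vectors: it dilutes the identity
  signal the permutation statistic measures rather than emulating
  correlated strong contacts. It is therefore an explicit opt-in
  (used, for example, to give the pairing filters multi-synapse
  contacts to act on) and not part of the default study conditions.

## Binary versus count mode

The permutation null shuffles partner identity while keeping each
neuron's count multiset. A pair is called *different* when its vectors
are anti-aligned beyond chance — for count vectors this can be driven
purely by synapse *weights* (two neurons contacting the same partners
but concentrating their strong synapses on different ones). Binarising
removes exactly that information, so weight-driven difference calls
must vanish in binary mode; the test suite checks this on a
constructed dataset in which two cohorts share a near-identical partner
set but concentrate strong contacts on different partner blocks.
Conversely, when differences are *identity-driven* (disjoint partner
sets, as in the sharp generator), binarisation does not remove them —
the generator cannot produce weight-driven differences at all, because
its counts are independent of identity.

## Numerical choices

* Distances via `stats::dist` (double precision); the null uses the
  sample (n−1) standard deviation over `n_perm = 100` shuffles by
  default.
* Significance thresholds derived from `alpha` via `qnorm(1 - alpha/2)`.
* Matrix CSVs are written with 15 significant digits (`formatC`,
  `format = "g"`) and round-trip exactly through
  `read_labeled_matrix()`.
* All stochastic steps take an explicit integer seed and run under
  `withr::with_seed`, so identical seed + inputs give bit-identical
  results; `run_pipeline()`'s `report.json` is byte-identical across
  reruns except its timestamp field.

## Limitations

* The calibration check compares a pooled similar-call rate to a
  binomial confidence interval; pairs within one replicate share rows
  and are weakly dependent, so the interval is approximate.
* Per-edge synapse counts are i.i.d. given edge presence; the generator
  cannot represent partner-correlated contact strength (see above), nor
  spatially structured synapse placement.
* Skeletons are straight chains with a fixed topology; they exercise
  path-length arithmetic, not reconstruction artefacts (breaks, loops
  are rejected by `skeleton()`, not repaired).
* The z-score normal reference is an approximation to the discrete
  permutation distribution, poorest for very small universes; the
  `undefined` flag handles the degenerate zero-spread case only.
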