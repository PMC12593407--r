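---
title: "Active transfer learning for reaction-condition exploration: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active transfer learning for reaction-condition exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlrxn)
```

## The problem and the model

Adapting a catalytic reaction to a new, harder substrate pair means searching
a combinatorial space of discrete reagent choices — here precatalyst × ligand
× additive × solvent, 18,270 combinations at the packaged catalog's sizes —
with a budget of a few plate-sized batches (3, 6 or 24 reactions). atlrxn
implements an active transfer learning protocol for this setting: a model
trained on reactions from a *related* substrate pair (the source domain)
seeds the search, and each observed batch refines it.

The learner is intentionally humble. Each of 100 ensemble members is a random
forest of 10 depth-one trees (stumps), trained as a classifier for
"does condition *c* yield strictly more than the previously optimized
condition's yield y₀?". Three modeling commitments follow from the transfer
setting:

* **Depth one.** A stump can only express one marginal statement per tree
  ("electron-poor ligands help"). Such statements are the part of source
  knowledge most likely to survive the domain shift; deeper trees would
  encode source-specific conjunctions that transfer poorly.
* **Classification, not regression.** With ~72 source reactions and batches
  of 6, calibrated regression is out of reach; a binary improves/doesn't
  target is learnable and directly actionable. The cost is that a 1-point
  and a 30-point improvement look alike (a `ratchet_threshold` option raises
  y₀ to the best yield observed so far; off by default since the protocol's
  target is defined against the fixed baseline).
* **An ensemble that votes.** Individual forests vary with their seeds;
  proposing the conditions most nominated across 100 members (each voting
  for its top N by predicted improvement probability) suppresses that
  variance without adding an exploration term — selection stays greedy.

After a batch is observed, two updates run in order. *Pruning*: every tree
that classified any failed condition (yield ≤ y₀) as an improvement is
deleted; members left empty are dropped. *Generation training*: 100 fresh
forests are fit to the target-domain records collected so far and appended,
tagged with the iteration number. The ensemble therefore accumulates
generations — the source generation's surviving trees and each target
generation — and `descriptor_usage()` reports which reagent classes each
generation's split features consult, the package's view of "what has been
learned so far".

## Featurization

A condition vector concatenates: amine-substrate descriptors, acid-substrate
descriptors, ligand descriptors, solvent descriptors, precatalyst one-hot,
additive-cation one-hot, additive-anion one-hot. Salt ions are encoded
independently (MgCl₂ and MgBr₂ share a cation bit) so stumps can generalize
across salts; the designated "none" additive sets both ion blocks to zero
rather than occupying a level. Substrate descriptor blocks are constant
within a single-pair target campaign but kept by default because source
records may span several pairs; descriptors are consumed as given, without
standardization (trees are scale-invariant).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_models` | 100 | forests/generation | enough members for stable vote tallies |
| `trees_per_model` | 10 | trees | unspecified upstream; small forests keep 100 members cheap |
| `max_depth` | 1 | levels | transferability (see above); configurable for target generations |
| `mtry` | ⌊√p⌋ | features/split | standard forest default |
| `batch_size` | 6 | reactions | HTE plate practicality (3/6/24) |
| `votes_per_model` (N) | `batch_size` | candidates | proposals are insensitive to N; simplest coupling |
| `n_iterations` | 3 | batches | the (n classes − 1) rule of thumb with 4 varied classes |
| `threshold_percent` | — | % yield | the previously optimized condition's assay yield |

Two ambiguities in the protocol are exposed as options rather than silently
resolved: `train_window` ("cumulative", default, trains each generation on
all target records so far; "latest_batch" trains on the newest batch only —
cumulative stabilizes fits on tiny samples), and `prune_scope` ("batch",
default, prunes only on the current batch's failures, matching the
iteration-by-iteration narrative; "cumulative" re-prunes against all
failures). "A tree suggested a failed condition" is read as "classifies it
positive (routed leaf probability > 0.5)": top-N membership is a
model-level act, and positive classification is the only per-tree criterion
computable from a single tree. Pruning at whole-forest granularity was
considered and rejected as the default: it deletes ten trees for one
offender and empties small ensembles quickly.

## Determinism and numerical choices

Member *i* of generation *g* trains with seed `seed + g·n_models + i`; all
other randomness (bootstraps, feature subsets, synthetic noise) flows from R's
RNG after `set.seed(seed)`, so a campaign against a deterministic oracle is
bit-reproducible, and traces serialize to byte-identical files (numbers are
written with 17 significant digits, which round-trip doubles exactly).
Tie-breaks are fixed everywhere: split search takes the first feature in
sampled order and the lowest threshold; within-member rankings and batch
selection break ties by enumeration order (lexicographic by catalog
position). Splits require a strict Gini decrease (> 1e−12), so a single-class
training set — common in early target iterations with no successes —
produces leaf-only stumps predicting the empirical positive rate (zero), a
documented fallback rather than an error. Degenerate inputs: an exhausted
candidate pool ends the campaign with status `"pool_exhausted"` instead of
erroring; oracle failures (NA yields) are recorded but excluded from labeling.

## The synthetic world

`make_landscape_pair()` generates ground truth the protocol can be tested
against. A landscape maps a condition to yield: base (20%) + one main effect
per reagent + sparse cross-class pairwise interactions, Gaussian noise
(sd 5 points) added before clipping to [0, 100]. Defaults encode the
structure the method assumes:

* **Ligand dominance.** Main-effect scales (sd, percent yield): ligand 15,
  solvent 6, precatalyst 5, cation 4, anion 4. Additive effects are the sum
  of independent cation and anion draws; "none" is exactly 0.
* **Descriptor-linked effects.** For ligand and solvent, 80% of effect
  variance (`rho_descriptor`) comes from a random linear map of the catalog
  descriptors, the rest is idiosyncratic. Without this link, descriptors
  would be arbitrary labels and no featurized model could generalize across
  reagents — the premise of descriptor featurization is that physical
  descriptors carry reactivity information.
* **Interactions.** 5% of cross-class id pairs carry an interaction drawn at
  half the mean main-effect scale; pure additivity would make depth-one trees
  trivially sufficient and hide differences between protocols.
* **Source–target structure.** The target landscape is drawn first; the
  source copies the shared classes (default: ligand) exactly and mixes the
  other classes' effects with fresh draws so that corr(source, target) =
  1 − `divergence` (variance-preserving). Drawing the target first keeps it
  fixed across a divergence grid, so baselines that ignore the source are
  constant and comparisons are paired.
* **Source dataset.** 72 distinct conditions, 80% biased toward the source's
  best ligand (a source dataset dominated by its most successful ligand),
  observed with noise.

What the simulator does **not** emulate: real descriptor values (the packaged
catalog's descriptors are synthetic draws with a fixed seed), mechanistic
chemistry, heteroscedastic or systematic assay error, and substrate-dependent
effect structure. A green benchmark therefore establishes that the protocol's
machinery extracts shared structure faster than its baselines *in a world
with that structure* — not that any particular laboratory yield is
reproducible.

## Benchmark design

`benchmark_strategies()` compares ATL against uniform random selection, pure
active learning (no source), pure transfer (source ensemble never updated)
and a cheating oracle-greedy upper bound, on a shared budget, with all
per-replicate randomness seeded identically across strategies (common random
numbers). By default the classification threshold is the target-landscape
yield of the best source condition — the "previously optimized condition",
faithful to practice. One caveat discovered at design time: across a
divergence grid that threshold is confounded with source relevance (at
divergence 0 the inherited baseline is already near-optimal, so nothing can
"improve" on it, every batch fails, and pruning empties the ensemble — a
threshold effect, not a transfer effect). Grid comparisons therefore pin the
threshold (the acceptance suite uses a mid-scale 40%) identically across grid
points so that only source relevance varies; the single-pair ATL-vs-random
comparison keeps the faithful source-derived policy.

## Known limitations

* Transfer helps only when the source is relevant; the divergence knob is the
  simulator's stand-in for a relevance measure that does not exist for real
  domains.
* Greedy, classification-based acquisition cannot distinguish large from
  marginal improvements and carries no explicit exploration.
* With an all-negative target history the target generations are
  uninformative leaf stumps, and proposals fall back toward the surviving
  source trees and enumeration-order tie-breaking.
* The pruning rule is aggressive at high thresholds: when nothing can beat
  the baseline, it removes precisely the trees that pointed at the best
  (but insufficient) regions.
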