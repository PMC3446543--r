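---
title: "Valence-conditioned recall dynamics: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valence-conditioned recall dynamics: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recalldyn)
```

## The scientific problem

Rumination in depression is characterised not only by a negative bias but by
the *persistence* of negative mental states: trains of negatively valenced
thought that are easy to enter and hard to leave. Free recall of emotionally
valenced word lists offers an objective window on this structure, because
the *order* in which items are retrieved reflects the organisation of the
underlying associative networks. `recalldyn` implements three
valence-conditioned summaries of recall order for two-arm (treatment vs.
wait-list control), two-timepoint (T1 pre, T2 post) trials:

* **Pstart(v)** — the probability that the first retained recall of a list
  belongs to valence category $v$ (positive, negative, neutral). It indexes
  the affective state of the mental context at retrieval onset:
  $\widehat{P}_{\mathrm{start}}(v) = \frac{\#\{\text{lists starting with } v\}}{\#\{\text{nonempty lists}\}}$.
* **Pstay(v)** — the probability that a retained transition starting from a
  category-$v$ item lands on another category-$v$ item, indexing the
  strength of within-valence associations:
  $\widehat{P}_{\mathrm{stay}}(v) = \frac{\#\{v \to v \text{ transitions}\}}{\#\{\text{transitions out of } v\}}$.
  Terminal recalls contribute no transition.
* **Pstop(v)** — the per-recall stopping hazard: the probability that a
  retained category-$v$ recall is the last of its list, indexing the
  "stickiness" of the valenced context toward which retrieval drifts:
  $\widehat{P}_{\mathrm{stop}}(v) = \frac{\#\{\text{lists ending with } v\}}{\#\{\text{retained } v \text{ recalls}\}}$.

Two readings of "stopping" coexist in the free-recall literature: the hazard
above, and the *terminal share* (the distribution of the last-recalled
category across lists, which sums to one). Both are implemented —
`pooled_pstop()` and `terminal_category_distribution()` — with the hazard as
the primary definition, because it conditions on the opportunity set (every
$v$ recall is an opportunity to stop) rather than only on list endings.

Per-valence recall percentages (`recall_percentage()`) complete the summary
table: distinct category-$v$ targets recalled over category-$v$ targets
presented, on the percent scale.

### Pooling

All estimators pool **counts** over every participant and list in a design
cell before dividing. With only three lists per participant per assessment,
per-participant proportions are too unstable to average; pooled counts give
the cell-level estimate directly. The consequence — participants with more
retained recalls carry more weight — is intentional and matches the
counting definitions above. Lists whose retained sequence is empty are
dropped from dynamics denominators (they carry no information about recall
order) but still count in recall-percentage denominators. No outliers are
removed anywhere.

### Scoring

Raw recall words are classified in output order: first occurrence of a list
target → `target` (with its category); first occurrence of a buffer word →
`buffer`; later occurrence of an already-recalled list word → `repetition`;
anything else → `intrusion`. Only `target` events enter the *retained*
category sequence, so a transition jumps over excluded events — the
standard convention in free-recall scoring. A recalled buffer is excluded
rather than treated as a neutral target, because buffers exist to absorb
primacy/recency and are excluded from analysis. Matching is exact after
normalization (lowercase, trimmed, ASCII punctuation stripped); no spelling
correction or stemming is applied, trading leniency for reproducibility.

## Permutation inference

Probabilities pooled over unbalanced counts are poor material for ANOVA, so
group-by-time inference uses permutation analogues built by subtracting the
conditions of interest:

* within-group change: $\Delta_g = M(g, T2) - M(g, T1)$;
* interaction: $\Delta_{\mathrm{MBCT}} - \Delta_{\mathrm{control}}$
  (difference of differences).

The null is generated by relabelling the design factors and recomputing the
statistic, 1000 iterations by default. Exchange respects the dependence
structure: **group labels permute between participants** (arm sizes
preserved) and **time labels flip within participants**, all lists of an
assessment moving together. The within-group test flips time labels only;
the interaction test applies both swaps jointly. A group-swap-only
alternative was evaluated during design and performed indistinguishably
(measured power 0.925 vs 0.915 on simulated effect trials), so the joint
scheme is the sole interaction default.

P-values use add-one smoothing,
$p = \frac{1 + \#\{|T^*| \ge |T_{\mathrm{obs}}|\}}{1 + B}$,
two-sided by default, so they are strictly positive and valid under
Monte-Carlo sampling. Ties are counted as exceedances (comparison with a
$10^{-12}$ slack). A permuted replicate that leaves a pooled cell empty is
redrawn and the redraw count reported; if more than half the replicates
would need redrawing the dataset is declared degenerate and the test fails
loudly rather than imputing.

`exact_test()` enumerates the complete assignment space (all $2^k$ time
flips of the tested group, or all group relabellings crossed with all time
flips for the interaction, capacity-guarded) with the identity included and
no smoothing. It exists as the small-sample oracle against which the
Monte-Carlo test is validated; the test suite checks agreement within three
Monte-Carlo standard errors on twenty 9-participant fixtures.

## The generative model

The simulator is a **category-level Markov model with item depletion**, not
a full retrieved-context (TCM/CMR) model: recall starts in a category drawn
from `start_probs`, items are drawn uniformly without replacement within
the current category, recall stops after a category-$c$ item with hazard
`stop_hazard[c]`, and otherwise the next category follows row $c$ of the
`stay_switch` matrix. When a category is exhausted its probability mass is
renormalized over the remaining categories. This is deliberately the
*minimal* process for which Pstart, Pstay and Pstop are sufficient
descriptions: in the depletion-free limit the pooled estimators recover the
start vector, the stay diagonal and the hazards exactly (the test suite
verifies recovery within 0.02 at 500 items per category and 10,000
sequences), which makes parameter recovery a meaningful validation surface.
Under realistic depletion (6 items per category) pooled metrics are
attenuated relative to the raw parameters; they are then validated against
a Monte-Carlo oracle (`expected_metrics_oracle()`) rather than the
parameters themselves. How a real participant's retrieval handles depletion
is unknowable from the published record; renormalization is this package's
modelling choice.

### Default parameters and why

The defaults of `markov_params()` define the baseline (T1) condition of the
simulated trial and were fixed once, on the following grounds, before the
validation suite was frozen:

* `stop_hazard = 0.12` for every category. The reference design presents 18
  targets per list and participants recalled about 43.6% (T1) to 48.4% (T2)
  of words overall, i.e. roughly 8.3 recalls per list; a geometric stopping
  process with hazard $\approx 1/8.3 \approx 0.12$ reproduces that.
* `stay_switch` diagonal 0.30 (off-diagonal 0.35 each). Study lists are
  constructed so that no two same-valence words are adjacent at
  presentation, which suppresses temporal-contiguity-driven valence
  clustering; baseline stay probability at approximately the 1/3 chance
  level encodes "little baseline clustering".
* `start_probs = (0.30, 0.40, 0.30)` (positive, negative, neutral). The
  recall task follows a laboratory stressor administered to participants
  with recurrent depression, so a modest mood-congruent negative onset bias
  is the realistic baseline.
* `max_recalls = 22`, the list length; it never binds in practice (only 18
  targets exist).

A design-phase power analysis under these conditions (300 simulated trials)
measured: probability that one simulated trial reproduces all five planted
effect signs 0.98, interaction power at the default planted magnitude
0.92, joint 0.91. These magnitudes are properties of the chosen baseline;
the published record does not constrain the true per-cell effect sizes, so
the planted-effect defaults are illustrative, not calibrated to the study.

`effect_cell_params(effect = 0.15)` encodes the qualitative treatment
pattern as T1→T2 drifts: MBCT negative stay diagonal down and positive
diagonal up, control reversed, MBCT negative stop hazard down. Row
stochasticity is restored by rescaling off-diagonal mass, diagonals are
clipped to [0.02, 0.96], and hazards are floored at 0.01 — with the default
baseline hazard 0.12, a planted drop of 0.15 therefore realises as a drop
to 0.01.

The trial simulator reproduces the reference design exactly: 29 MBCT vs 23
control participants, three lists of 22 words per assessment, two
word-disjoint counterbalanced list sets (one per timepoint). Block
randomization (block size 5, ratio 3:2, partial final block drawn without
replacement from a fresh block) is provided as its own operation
(`block_randomize()`); the default simulator fixes the realised arm sizes
29/23 because those are the observed study counts. Per-participant RNG
substreams are derived from the single design seed, so simulated trials are
bit-reproducible.

## Stimulus-list construction

`build_stimulus_lists()` assembles lists from an ANEW-style norms table
(word, valence, arousal, frequency, length) under the composition
constraints: 22 words = 6 positive + 6 negative + 6 neutral targets + 4
neutral buffers; buffers at the list edges; no two consecutive targets of
the same valence; per-list category means near the normative targets
(positive valence 7.5 / arousal 5.8, negative 2.6 / 5.5, neutral
5.18 / 3.84); and between-list balance of mean valence, arousal, length and
log frequency. Choices the published record leaves open, and how they were
fixed:

* **Buffer split**: four buffers "at the beginning and end" is read as 2+2,
  symmetric primacy/recency control. Configurable via `buffer_split`.
* **Ordering constraint scope**: enforced over the 18 targets only;
  buffers, being neutral, would make a neutral target adjacent to a buffer
  generically unsatisfiable. Configurable via `order_includes_buffers`.
* **Selection windows**: categories are selected from disjoint valence
  windows (positive ≥ 6.7, negative ≤ 4.1, neutral 4.5–5.9), roughly
  mean ± 2 SD of the normative targets; the cutoffs are configurable
  because no published cutoffs exist.
* **Balance scope**: mean/balance checks are computed over target words
  (buffers are excluded from analysis, so balancing them is immaterial).

The construction algorithm is stratified sampling within windows, greedy
swap repair against the mean/balance tolerances (restarted up to 25 times,
4000 proposals each), then shuffle-until-valid ordering with a 10,000-try
cap — simple, deterministic under the seed, and ample at this scale.
`validate_stimulus_list()` re-checks every constraint independently and
never raises on failure, so it can audit externally supplied lists. The
bundled `synthetic_word_norms()` generates pronounceable pseudo-words with
the right normative structure; no proprietary norms database is
redistributed.

## Numerical and degenerate-input conventions

* Estimates are exact ratios of integer counts; numerators and denominators
  are reported alongside every value.
* Undefined quantities (empty cell, zero transitions out of a category)
  raise classed errors (`rdyn_undefined_error`) rather than returning NaN;
  the pipeline-level table (`dynamics_table()`, `run_full_analysis()`)
  converts these to explicit NA entries so report bundles are complete.
* Probability vectors are validated to $10^{-8}$; sum-to-one invariants of
  Pstart and the terminal distribution hold to $10^{-12}$.
* All randomness flows through explicit seeds; identical inputs and seed
  give byte-identical outputs (the suite checks file-level md5 equality).

## Validation problem sizes

The automated suite exercises: exact-vs-Monte-Carlo agreement on twenty
9-participant fixtures (2000 permutations each); type-I error of the
interaction test on 1000 simulated null trials at the default design
(rejection rate required within 5% ± 1.5% at $\alpha = 0.05$);
depletion-free parameter recovery at 500 items per category and 10,000
sequences (tolerance 0.02); depletion-matched recovery against a
20,000-sequence Monte-Carlo oracle (3 MC standard errors); and directional
fidelity over 100 simulated effect trials. These sizes were chosen to keep
Monte-Carlo error comfortably below the tolerances being asserted.

## What the synthetic data do and do not show

The simulator emulates the design parameters (arm sizes, list structure,
two timepoints), valence-clustered transitions, category-dependent
stopping, and configurable group-by-time parameter drifts, with optional
intrusion/repetition injection to exercise the scorer. It does **not**
emulate semantic structure within categories, serial-position effects,
practice effects from T1 to T2, participant heterogeneity in the Markov
parameters, dropout, or transcription noise in spoken recall. Passing
validation therefore demonstrates that the estimators and tests are
correct, calibrated and powered *for data generated by the category-Markov
process at the reference design size* — it cannot certify empirical claims
about any real trial, whose raw data are not publicly available.

## Known limitations

* With three lists per assessment, per-participant estimates are
  unreliable by construction; everything here is cell-pooled, and no
  individual-differences analysis is offered.
* The hazard and terminal-share readings of Pstop can disagree; both are
  computed, and reports should state which is shown.
* Exact enumeration for the interaction grows as
  $\binom{n}{n_1} 2^n$ and is only feasible for roughly a dozen
  participants; beyond that, only the Monte-Carlo test is available.
* The neutral category is computed throughout but reported in an appendix
  table by the pipeline, since the primary contrasts concern negative and
  positive material.
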