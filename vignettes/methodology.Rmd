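---
title: "From crisp rules to tuned fuzzy classifiers: the fuzzydx methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From crisp rules to tuned fuzzy classifiers: the fuzzydx methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diagnostic decision support asks for classifiers that a clinician can read:
a short list of rules over named measurements, with graded rather than
knife-edge boundaries. `fuzzydx` builds such classifiers automatically from
a labelled tabular dataset in six stages. The first three operate on crisp
(Boolean) models, the last three on fuzzy ones:

1. **Extraction** — induce a decision tree and flatten its root-to-leaf
   paths into a weighted disjunctive normal form (wDNF) rule base.
2. **Selection** — keep the `n` most useful rules, at least one per class.
3. **Reduction** — merge same-feature predicates so every rule is
   *fuzzifiable*.
4. **Fuzzification** — translate predicates into linguistic terms
   (Low/Medium/High) and build a weighted fuzzy rule base.
5. **Configuration** — assemble a fuzzy inference system (FIS) from the
   rule base and a set of logical parameters.
6. **Adaptation** — tune membership-function positions by derivative-free
   optimisation of a mean-squared-error objective.

```{r, eval = FALSE}
library(fuzzydx)
gt <- synthetic_ground_truth()
ds <- generate_synthetic(gt$features, gt$rulebase, 500, seed = 1)
fit <- fuzzydx(class ~ ., data = ds$data)
summary(fit)
```

## Stage 1: rule extraction

The tree is grown top-down in the C4.5 style. Candidate tests are binary
numeric splits `x <= v / x > v` at midpoints between consecutive sorted
distinct values, and multiway equality splits for categorical features. The
candidate maximising the **gain ratio** (information gain divided by split
information) is chosen, among candidates with positive gain whose children
all hold at least `min_leaf` items (default 2). Ties are broken by feature
order, then by the lower threshold, so induction is fully deterministic.
Leaves predict their majority class; leaf ties fall back to the globally
most frequent class and then lexicographic order.

No error-based pruning is applied by default. In this methodology the
selection stage already plays the generalisation role: pruning before
selecting would remove exactly the weak, over-specific rules that selection
is designed to discard with an explicit, inspectable criterion.

Each leaf becomes one rule; its **weight** is the number of correctly
classified training items at that leaf (the coverage figure printed in
brackets when rule bases are displayed). An `"equal"` weighting mode sets
all weights to 1 instead; coverage is the default because downstream
ranking and reporting use it. Tree paths are disjoint and exhaustive, so
the extracted base is mutually exclusive and covers every training item —
a property that is checked (`check_mutual_exclusivity()`), not assumed,
because hand-written or post-selection bases can violate it. When several
rules fire, classification resolves deterministically: highest weight,
then longest antecedent, then rule order. A record that fires no rule is
an explicit abstention, which every metric counts as a misclassification.

## Stage 2: selection

Two ranking criteria are provided. **Most-confident** orders rules by
confidence — the fraction of matching training items whose class matches
the consequent — with ties preferring the longer antecedent, then higher
coverage, then original order. A rule matching no item has confidence 0 by
definition, keeping the ranking total. **Longest-match** orders rules that
match at least one item by antecedent length (ties by coverage), placing
never-matching rules last; length is used directly rather than an
item-weighted variant, with match count only as a tie key.

`select_rules()` keeps exactly `n` rules: every represented class retains
its top-ranked rule first, and remaining slots are filled walking down the
global ranking. The per-class-tops-then-global-fill policy is this
package's choice for allocating slots beyond the per-class minimum.
Ranking is computed on the training fold only, consistent with the
exchangeability rationale behind the confidence criterion. Because the
surviving rules mention only some features, selection implicitly performs
feature selection; only those features are fuzzified later.

## Stage 3: reduction

A rule is *fuzzifiable* when each numeric feature appears in at most two
predicates forming a lone upper bound (`x < v`), a lone lower bound
(`x > v`), or a non-empty interval (`x < v1` and `x > v2` with
`v1 > v2`). Tree paths that test a feature repeatedly violate this, so
reduction merges *comparable* predicate pairs: two lower bounds collapse
to `x > max(v1, v2)`, two upper bounds to `x < min(v1, v2)`.

Two conventions deserve a note. First, comparability is taken by bounding
direction, including same-operator pairs such as `{>, >}` — tree paths
routinely produce these, and without them reduction could not always reach
the admissible forms. The package logs a message when a same-operator merge
fires. Second, the merged predicate is always strict, even when the
surviving source predicate was non-strict (`x >= 5` and `x >= 3` merge to
`x > 5`). The boundary point is knowingly allowed to drift: crisp
boundaries are discharged at fuzzification anyway, so only behaviour *at*
a threshold can change, never on either side of it. Tests of semantic
preservation therefore compare firing on items drawn off the thresholds.
For the same reason, a lone non-strict bound (say `x >= v`) counts as the
lower-bound form when fuzzifiability is checked: forms are classified by
direction, not strictness.

Contradictory bounds (upper at or below lower) raise an error rather than
dropping the rule silently; tree-derived rules can never trigger this, so
it flags a malformed hand-written base. Categorical predicates are never
touched — a conjunctive rule cannot meaningfully constrain one categorical
feature twice, and rules reject such duplicates at construction.

## Stage 4: fuzzification

Each feature used by the reduced rules becomes a linguistic variable; the
class becomes the output variable with one term per class. Numeric
predicate groups map **by form only**: upper bound → `Low`, interval →
`Medium`, lower bound → `High`. The mapping keys on (feature, form), so
two rules with `x < 5` and `x < 8` share one `Low` term: the crisp
thresholds are discharged and retained only as term metadata. A variable
therefore carries between one and three terms. The universe of a shared
feature is deliberately **not** sub-partitioned by overlapping thresholds
from different rules — extra cut points would multiply terms, overfit the
universe of discourse and erode exactly the interpretability the method
exists to provide. The labels Low/Medium/High are linearly ordered but
their meaning is local to the rules that generated them. Rule weights and
the rule count carry over unchanged.

Categorical `==` predicates become one term per assigned value; `!=`
predicates are rejected at this stage (the crisp engine accepts them, but
only assigned values have a fuzzy translation, and the package's own tree
extractor never emits `!=`).

## Initial membership functions

The crisp stages say nothing about shapes, so initialisation is this
package's construction. For a variable with universe width `W` and
`overlap` fraction `o` (default 0.1), transitions have half-width
`d = o * W` and are centred on the **mean** of the crisp thresholds that
generated the term. `Low` is 1 up to `v - d`, ramping to 0 at `v + d`;
`High` mirrors it; `Medium` is a trapezoid rising across the lower
threshold and falling across the upper one, collapsing to a triangle when
the interval is narrower than `2d`. Breakpoints are clamped to the
universe (with a tiny nudge preserving strict ordering) so that the
adaptation stage can treat the universe as a hard bound. `overlap` must
lie in (0, 0.5): at 0.5 a transition would span half the universe and the
terms degenerate. When one variable hosts both `Low` and `High`, their
transitions may initially overlap; no repair is attempted — that is the
adaptation stage's job. Categorical and output terms are singletons at
positions 0, 1, 2, … in declaration order, which also defines the numeric
class encoding used by the objective below.

## Stage 5: the inference engine

Inference is single-pass (no rule chaining): fuzzify inputs, evaluate each
rule's activation with the configured t-norm (`min` default, `product`
available) times the rule weight when weights are enabled, aggregate
activations per output term (`max` default, `sum` available), defuzzify.
The default defuzzifier is the centre of gravity over singletons,
`sum(a_t * s_t) / sum(a_t)`; mean-of-maxima is available, and centre of
area is implemented by grid integration for Mamdani-style piecewise-linear
consequents (the generated pipeline always produces singleton outputs, so
COA is exercised only by hand-assembled systems). Defaults — singleton
reasoning, min t-norm, max s-norm, min implication, COGS, weights off —
mirror a proof-of-concept diagnostic setup.

Classification returns the output term with the maximal aggregated
activation. The confidence `chi` is defined in this package as the winning
activation divided by the total activation — a normalised dominance score
in [0, 1]; the notion of a confidence score is standard, its formula here
is our choice. Ties go to the term whose singleton lies nearest the
defuzzified value, then declaration order. Zero total activation is an
abstention rather than a default class.

Systems round-trip through IEC 61131-7 Fuzzy Control Language
(`export_fcl()` / `import_fcl()`); `WITH` clauses are emitted exactly when
rule weights participate in inference, so the flag survives the round
trip.

## Stage 6: adaptation

The tuner is adaptive-step cyclic coordinate descent, a derivative-free
search maintaining one step size per parameter. Parameters are the
breakpoint abscissae of the numeric input variables' membership functions
— ordinates are left alone so every term keeps its shape semantics — plus
rule weights when enabled. Each cycle probes every parameter at ±its step;
the best strictly improving probe is accepted and that step doubles
(`expand_factor` 2), otherwise the step halves (`shrink_factor` 0.5).
These constants are conventional for adaptive step-size searches and are
config-exposed. Probes violating an invariant — breakpoint ordering,
universe bounds, weight outside [0, 1] — count as non-improving. The
search stops after `max_iterations` cycles (default 50) or when every step
falls below `tolerance` times its parameter's range; it is fully
deterministic, and the recorded objective trajectory is non-increasing by
construction.

The objective is the mean squared error between the defuzzified output and
the encoded true class. An abstaining item contributes the maximum squared
encoding distance — a defined, bounded penalty that makes the objective
total without dominating it.

## The synthetic-data generator

`generate_synthetic()` draws numeric features uniformly over their
universes and categorical ones uniformly over their categories, labels
each record with a known crisp rule base or FIS, and flips labels with a
configurable noise probability. Uniform marginals are the simplest
distribution that exercises thresholds everywhere in the universe. The
default scenario (`synthetic_ground_truth()`) is one informative marker
split at a threshold plus two uninformative features — the minimal setting
in which selection must discard irrelevant attributes. What this generator
does *not* emulate matters for reading the test results: real clinical
data has correlated features, non-uniform marginals, class overlap beyond
simple label noise, and measurement error. Passing tests show the pipeline
recovers known structure under clean conditions; they do not certify
performance on real cohorts.

## Numerical choices and degenerate inputs

* Entropy and gain ratio use base-2 logarithms; splits need gain above
  `1e-12` and a positive split information to be considered, and a small
  tolerance on gain-ratio comparisons keeps float noise from flipping the
  deterministic tie-break.
* Constant numeric columns get a ±0.5 universe so the interval stays
  non-degenerate; a constant class column is a warning (learning on it is
  refused downstream by the two-class precondition).
* Missing values are rejected with the offending row index, never imputed:
  every stage's semantics assume complete records.
* Stratified fold assignment shuffles within class and deals round-robin,
  so per-class fold sizes differ by at most one; the fold partition, the
  generator, and the tuner are all reproducible from integer seeds.
  Stratification itself is a package choice — plain k-fold is not offered.
* Problem sizes used in the shipped checks (hundreds to a couple of
  thousand generated records, tenfold cross-validation, 50-cycle tuning)
  were chosen as the smallest sizes at which the studied effects are
  stable; all scale linearly if enlarged.

## Known limitations

* Under label noise, most-confident ranking favours small pure leaves
  (confidence 1 on a handful of records) over large, slightly impure
  generalising rules, and the longer-antecedent tie-break amplifies this.
  Raising `min_leaf` so the tree cannot grow tiny pure leaves is the
  practical control; on noise-free data, where the tree recovers the
  generating structure exactly, the issue does not arise.
* One categorical predicate per feature per rule; disjunctive or negated
  antecedents are out of scope, as are Takagi–Sugeno consequents and
  smooth (gaussian/bell) membership functions — the piecewise-linear
  variant covers triangles and trapezoids, and the membership-function
  seam admits further variants.
* FCL identifiers cannot carry arbitrary characters, so exported names are
  sanitised; a round trip preserves behaviour but may rename variables
  containing spaces.
* The tuner is a local search: it inherits coordinate descent's
  vulnerability to non-axis-aligned valleys. The optimizer sits behind an
  interface so gradient-based or evolutionary tuners can be swapped in.
* Multi-objective tuning (accuracy jointly with confidence and
  interpretability) is not implemented; the objective is plain MSE.
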