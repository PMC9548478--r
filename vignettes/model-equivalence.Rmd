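---
title: "Deciding conceptual model equivalence with simplicial representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding conceptual model equivalence with simplicial representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screp)
```

## The model and its assumptions

`screp` compares mathematical models of biological systems through their
conceptual structure alone. A model is a **simplicial representation**: a
labelled abstract simplicial complex whose vertices are model components
(each mapped to a positive integer by an ordering bijection over the
component universe shared by all models under comparison) and whose
simplices are the conceptual interconnections between components. The
encoding assumes that

* the component universe is fixed before comparison — a labelled simplex
  means the same concepts in every representation;
* the simplex family is closed under taking faces (an interconnection
  entails all its sub-interconnections);
* conceptual symmetry is structural symmetry: two components are candidates
  for identification exactly when swapping their vertices, holding all
  others fixed, leaves the complex invariant (an *exchange automorphism*).

The third point is the method's crux. The group generated by a set of
exchange transpositions acts simplicially on the complex; the quotient of
the complex by that action — vertices the orbits, simplices the projection
images — realizes all the identifications at once. These actions are
deliberately *nonregular* in the classical sense (a regular action cannot
move two vertices of a simplex onto each other, which is precisely what an
identification needs); `is_regular_action()` exists to demonstrate this on
worked examples, not as a pipeline step.

Iterating quotient-then-rescan reaches the **final orbit space**, the
fixpoint with no exchangeable vertices. Equivalence of two models is then a
label-consistent simplicial isomorphism between their final orbit spaces;
when one exists, the package emits the witnessing sequence of partial
operations (stage-wise vertex identifications on both sides, then the
closing vertex substitutions) so the verdict can be audited and replayed.

```{r pipeline}
K <- fixture("square_cycle")
final_orbit_space(K)
```

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `enforce_shared_components` | `decide_equivalence()`, `candidate_vertex_bijections()` | `TRUE` | Vertices of the two finals that share a model component must be matched to each other. Turning it off only enlarges the bijection search; it rarely yields meaningful new equivalences, but both behaviours are reachable. |
| `assume_meaningful` | `decide_equivalence()` | `TRUE` | Whether an isomorphism is taken as establishing equivalence. The software cannot judge whether the paired component sets are conceptually admissible; with `FALSE` the verdict is `NA` and the `component_pairings` are handed to the domain expert. |
| `allowed_pairs` | `restricted_final_orbit_space()` | — | Unordered component pairs whose identification is conceptually valid; an exchangeable vertex pair is merged only if every cross pair of merged components is allowed. |
| `representative_rule` | `fundamental_domain()` | `"min"` | Which orbit member represents the orbit. Any rule gives an isomorphic domain; `"min"` (canonical key order) makes output deterministic. |
| `budget` | `is_regular_action()` | `10^4` | The regularity check enumerates the generated group and per-simplex tuples; it is a worked-example tool and errors rather than run unbounded. |
| `edge_density`, `n_vertices`, `seed` | `random_complex()` | — | See below. |

## Design choices where the design was open

**Vertex identity through quotients.** One data type carries original and
quotient vertices: an identifier is a set of positive integers, nested
after quotienting (the orbit vertex is the set of its members'
identifiers). A singleton set collapses to its member — the standard
convention that a vertex *v* and the set {*v*} are interchangeable — so
trivial orbits keep their vertex unchanged, the quotient under the trivial
action *equals* the input, and the pairwise identification operations
produce *structurally identical* output to the single-transposition orbit
space. Flattening an identifier (the union of its integers) gives the
component label used for matching.

**Identification preconditions vs. exchangeability.** The pairwise
operations check their own preconditions (equal (deleted) neighbourhoods
and matching co-faces) directly, while symmetry detection compares the
transposition image of the simplex family. That these coincide — adjacent
pairs satisfy the adjacent-identification preconditions iff exchangeable,
nonadjacent ones the nonadjacent preconditions — is *tested*, exhaustively
over all 7,580 complexes on at most 5 vertices, rather than assumed. The
co-face condition quantifies over all nonempty subsets of the common
neighbourhood; the implementation checks only subsets that occur as
simplex supports, which is equivalent (both sides of the biconditional
require a simplex witness) and avoids exponential blowup.

**Simultaneous vs. batched identification.** Each reduction stage applies
*all* exchangeable pairs of the current complex at once. Applying any
subset first and continuing is also legal; that every batching reaches an
isomorphic final complex is strongly suggested by the theory (projected
transpositions remain exchangeable in the quotient) but not stated as a
uniqueness theorem, so the package treats confluence as a tested
conjecture: the suite checks it on 200 random complexes with random
batches.

**Restricted equivalence, forward not backward.** When some
identifications are conceptually invalid, the prescription "work backwards
from the finals removing invalid identifications" is procedurally
underspecified. `restricted_final_orbit_space()` instead re-runs the
forward fixpoint admitting only allowed component pairs; the reduction
trace lets a user audit exactly which identifications occurred. On
complexes where an inadmissible early merge would enable a later
admissible one the two procedures could differ; no such example is known,
and the forward variant has the advantage of being well defined.

**Clique completion.** Model files often specify only the 1-skeleton, with
higher simplices "formed as cliques incrementally". This is read as the
flag complex of the graph — every set of pairwise-adjacent vertices spans
a simplex — with the incremental phrasing taken as an implementation
order, not a semantic restriction admitting partial completions.

**Isomorphism search.** Finals are small (post-reduction), so the search
enumerates vertex bijections with degree and maximal-co-face pruning plus
the shared-component constraint, in canonical vertex order for stable
output. No canonical-labelling machinery is warranted at these sizes; the
pruned search is validated against a brute-force all-bijections oracle.

## What the synthetic generator emulates — and what it does not

`random_complex(n, p)` draws an Erdős–Rényi graph on `n` singleton
vertices with edge probability `p`, optionally flag-completed — matching
how models in this domain are actually specified (components and pairwise
interconnections first, cliques filled in). Defaults in the test suite use
`n ≤ 8` and densities 0.2–0.95, the scale of the published
developmental-patterning representations (tens of components at most) and
the scale at which exhaustive oracles remain feasible.
`plant_exchangeable()` duplicates the closed star of a chosen vertex
(plus, in adjacent mode, the joint co-faces), the minimal construction
guaranteeing the identification preconditions, giving ground truth for
detection and recovery tests.

A green suite therefore establishes correctness of the combinatorial
machinery on desk-scale complexes with planted or incidental symmetry. It
does **not** establish: performance on representations orders of magnitude
larger; meaningfulness of any particular identification (a human
judgement by design); or behaviour on the specific published nine-model
collection, whose simplex lists are defined in companion material and are
accepted only as user-supplied input files.

## Numerical and degenerate-input conventions

* The void complex (no vertices, no simplices) is a legal value with
  dimension `-Inf`; the empty simplex is excluded.
* All comparisons are exact set/string operations; there are no floating
  tolerances anywhere.
* Serialization sorts simplices by (cardinality, lexicographic key) and
  vertex keys in C-locale byte order, so equal complexes produce
  byte-identical files regardless of construction order or session locale.
* Ties in the bijection search are broken by canonical vertex order;
  `fundamental_domain()` defaults to minimal representatives. Reductions
  are bounded by the vertex count (each stage strictly decreases it) and
  assert that bound.
* `--seed` / `seed` arguments snapshot and restore the RNG state, so
  library calls do not perturb a caller's random stream.

## Known limitations

* Equivalence search is exponential in the final orbit-space size in the
  worst case; it is intended for post-reduction complexes with at most a
  few dozen vertices.
* `is_regular_action()` is enumeration-based and guarded by an explicit
  budget; it is a pedagogical check, not a scalable decision procedure.
* Vertex split and inclusion are not standalone public operations; they
  are exercised implicitly as the inverses recorded in reduction traces.
* The distance on G-representations is the symmetric-difference
  cardinality only; no metric-space machinery beyond the axioms (which the
  suite verifies) is provided.
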