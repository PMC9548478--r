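# screp — comparing models of biological systems as labelled simplicial complexes

Biological systems typically accumulate many ostensibly different
mathematical models — reaction–diffusion systems, gradient models, and so
on — that may nonetheless rest on the same conceptual structure. `screp`
compares models at that conceptual level, independently of mathematical
formalism or model outputs. It is aimed at systems and developmental
biologists who want to decide whether two models of a process (say, a
Turing-pattern model and a positional-information model of developmental
patterning) are *conceptually equivalent*, and at methodologists studying
design principles across model collections.

## The representation and the method

A model is encoded as a **simplicial representation**: a labelled abstract
simplicial complex *K* whose vertices are model components (morphogens,
diffusion of a morphogen, boundary conditions, …; each component mapped to
a positive integer by an ordering bijection Ord) and whose simplices encode
the conceptual interconnections — dyadic interactions are edges, triadic
interactions are 2-simplices, and so on.

Two components are candidates for conceptual identification exactly when
their vertices sit in symmetric positions: when the transposition (u v),
fixing every other vertex, is an automorphism of *K* (an **exchange
automorphism**, making u and v **exchangeable**). The set *M* of all such
transpositions generates a group G = ⟨M⟩ acting simplicially on *K*, and
identifying the symmetric components means forming the **orbit space**
*K/G*, whose vertices are the G-orbits G·v and whose simplices are the
projection images of the simplices of *K*. Iterating — the quotient may
expose new symmetry — terminates in the **final orbit space** K̂ with no
exchangeable vertices. Two models *K*, *L* are equivalent iff a
label-consistent simplicial isomorphism K̂ → L̂ exists; the isomorphism
induces the closing vertex substitutions, and the whole construction emits
the witnessing sequence of invertible partial operations
(adjacent/nonadjacent-vertex identifications and vertex substitutions).

The package also implements the group-theoretic encoding of a model: the
**G-representation** G_K = (2^K, △), the elementary abelian 2-group of all
simplex subsets under symmetric difference, with its minimal generating
set {{σ} : σ ∈ K}, the induced identification/substitution homomorphisms
φ1/φ2/φ5, and the model distance |K △ L|.

## Worked example

```r
library(screp)

K <- close_under_faces(list(c(1, 2, 3)))   # the full triangle on components 1,2,3
exchangeable_pairs(K)
# [[1]] "{1}" "{2}"   [[2]] "{1}" "{3}"   [[3]] "{2}" "{3}"

orbit_space(K, list(c(1, 2)))$complex      # identify components 1 and 2
# Simplicial representation: 2 vertices, 3 simplices, dimension 1
#   {3}  {{1},{2}}  {3}|{{1},{2}}

final_orbit_space(fixture("square_cycle"))
# Reduction trace: 2 stage(s)
#   stage 1: 2 transposition(s): ({1} {3}) ({2} {4})
#   stage 2: 1 transposition(s): ({{1},{3}} {{2},{4}})
# Final orbit space:
# Simplicial representation: 1 vertices, 1 simplices, dimension 0
#   {{{1},{3}},{{2},{4}}}

decide_equivalence(K, close_under_faces(list(4)))
# Equivalence verdict: EQUIVALENT
#   reduction: 1 stage(s) for K, 0 for L; 1 isomorphism(s)
#   component pairings (first isomorphism):
#     {1,2,3} ~ {4}
```

Reading the output: the triangle's three components are mutually
exchangeable, so one reduction stage collapses it to a single vertex whose
nested label records everything that was merged; the 4-cycle needs two
stages (opposite corners first, then the two resulting orbit vertices).
The verdict says the triangle and a one-component model are conceptually
equivalent — both reduce to a single concept — and reports which component
sets were paired, which a domain scientist must still judge for meaning
(`assume_meaningful = FALSE` withholds the verdict pending that sign-off).

## Command line

```sh
inst/cli/screp fixture triangle -o K.json
inst/cli/screp exchanges K.json
inst/cli/screp final K.json -o Khat.json     # + Khat.json.trace.json
inst/cli/screp compare K.json L.json
inst/cli/screp distance K.json L.json
```

Complexes are exchanged as a small JSON dialect (`components`, `vertices`,
`simplices`, `maximal_only`, `clique_complete`); the writer is canonical,
so equal complexes serialize byte-identically.

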