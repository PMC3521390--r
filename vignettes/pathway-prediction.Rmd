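---
title: "Pathway prediction as shortest-path search in compound-vector space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway prediction as shortest-path search in compound-vector space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vecpath)
```

## The model

`vecpath` predicts biochemical reaction pathways between two compounds
without traversing any pre-existing reaction network. It rests on three
representations.

**Compounds are path-count vectors.** A 2D structure is a labelled graph
(atoms as nodes, bonds as edges, hydrogens explicit). For a depth range
$l$–$u$ (the *representation-depth*), the feature vector $D_l^u(c)$
counts, for every labelled simple path with between $l$ and $u$ bonds
occurring anywhere in the corpus, how many times that path occurs in
compound $c$. Depth-0 paths are single atoms; each undirected path is
counted once. Methane at depth 0–2 is
$(1\,(\mathrm{C}),\ 4\,(\mathrm{H}),\ 4\,(\mathrm{C{-}H}),\ 6\,(\mathrm{H{-}C{-}H}))$,
with zeros at any oxygen-indexed label the corpus contributes.

```{r methane}
mf <- methane_fixture()
enumerate_paths(mf$graph, l = 0, u = 2)
```

**Reactions are operator vectors.** A reaction acting on a main
substrate $i$ and main product $j$ becomes a rule $R = (U, O)$ with
substrate vector $U = D_l^u(i)$ and operator
$O = D_l^u(j) - D_l^u(i)$. Applying the reaction to any compound vector
is addition of $O$, allowed only under two gates:

* *substrate inclusion*: $c_k \ge u_k$ for all $k$ — a linear-time
  surrogate for (NP-hard) subgraph inclusion;
* *non-negativity*: $c_k + o_k \ge 0$ for all $k$ — counts of
  substructures cannot go negative.

**Pathways are shortest paths.** With compound vectors as nodes and rule
applications as unit-cost edges, predicting a pathway from a start $S$
to a goal $G$ is a shortest-path problem in integer-vector space, solved
by A* with evaluation $f(t) = p(t) + h'(t)$ where $p$ is the path length
so far and $h'$ an admissible estimate of the remaining distance. The
goal test is exact vector equality on pop.

## Heuristics

* `bf` — $h' \equiv 0$: breadth-first search, the exhaustive reference.
* `mh` — normalized Manhattan distance
  $h'(t) = \mathrm{MH}(t, G)\,/\,\lVert O_{max}\rVert_1$. One rule
  application changes the vector by at most the largest operator 1-norm,
  so the quotient never exceeds the true distance. We fix the 1-norm as
  the operator norm because that is the norm in which the per-application
  displacement bound holds.
* `lp` — the continuous relaxation of the operator-count integer
  program: minimize $\sum_k w_k$ subject to
  $G - t = \sum_k w_k O_k$, $w_k \ge 0$. The integer program (rule $k$
  applied $w_k$ times, order and gates ignored) already lower-bounds the
  true distance; relaxing $w_k$ to reals can only lower the optimum
  further, so the LP value is admissible and computable in polynomial
  time. An infeasible relaxation *proves* the goal unreachable and the
  node is pruned — this is why the LP search can return `unreachable`
  where uninformed searches can only exhaust a depth budget on an
  infinite state space.

Both heuristics are consistent ($h'(t) \le 1 + h'(t')$ along every
edge), so closed nodes are never reopened; the search still carries
reopening logic for user-supplied heuristics and counts it in the
diagnostics.

### Integer tightening of the LP value

True distances are integers, so `lp_h()` returns
$\lceil \mathrm{LP} - 10^{-6} \rceil$ by default: still admissible and
consistent, but pruning harder. The raw LP value is available with
`ceiling = FALSE`. The subtraction guards against a solver value sitting
a rounding error above an exact integer.

### The LP solver

The constraint matrix has one row per vocabulary label but rank at most
the number of rules, so the equality system is always heavily redundant
and degenerate. `solve_relaxation()` uses a dense two-phase primal
simplex with Bland's anti-cycling rule, written for exactly this
problem class: rows untouched by every operator are resolved directly
(a nonzero target there is an immediate infeasibility), rows with
negative right-hand side are negated, redundant rows are dropped after
phase 1, and artificial variables are never allowed to re-enter.
Feasibility is decided at $10^{-7}$ relative to the constraint scale;
objective comparisons in callers use $10^{-6}$. An iteration-limit stop
raises an error distinct from infeasibility, because the two have
opposite meanings for the search. The tests cross-check the solver
against `pracma::linprog` where that routine converges, against
hand-derived optima, and against bounded exhaustive enumeration of the
integer program.

## Search mechanics

* **Tie-breaking.** Equal $f$ is broken by smaller $h'$, then by
  insertion order (FIFO). This makes results deterministic, reduces the
  zero heuristic exactly to textbook breadth-first search, and pops the
  goal first within the final $f$-tier — so with any of the built-in
  heuristics the search expands only nodes with $f < d^*$. Together with
  pointwise dominance ($0 \le h'_{MH} \le h'_{LP}$) this yields the
  expansion-count ordering LP $\le$ MH $\le$ BF verified in the tests.
* **Duplicate states.** A best-cost map keyed on the state vector; a
  successor is enqueued only if it improves the known cost.
* **All-shortest enumeration.** After the first goal pop fixes $d^*$,
  the search keeps expanding while the frontier minimum satisfies
  $f \le d^*$, recording a predecessor DAG. Every distinct optimal
  rule-id sequence is then read off the DAG (default cap 100
  sequences). Distinctness is at the level of rule-id sequences.
* **Limits.** `max_depth` (default 20) and `max_expansions` (default
  $10^6$) bound the search; the state space is infinite whenever some
  operator ray is unbounded, so an uninformed search cannot otherwise
  terminate on an unreachable goal. A frontier exhausted after depth
  pruning reports `limit-exceeded`, never `unreachable`: only an empty
  frontier without pruning (or an infeasible LP at the start) proves
  unreachability.

## Featurization choices

* Simple paths (no repeated atom), each undirected occurrence counted
  once; this reproduces $\binom{4}{2} = 6$ for H–C–H in methane, where
  directed walks would give 12.
* Labels join element symbols with `-`, `=`, `#`, `:` (single, double,
  triple, aromatic); the canonical rendering is the lexicographic
  minimum (C locale) of the forward and reversed strings, so `O=C-H`
  prints as `H-C=O`. Counts are unaffected by the naming choice.
* Hydrogens are made explicit before enumeration
  (`add_implicit_hydrogens()`: C 4, N 3, O 2, S 2, halogens 1; aromatic
  bonds count 1.5 with the per-atom total rounded to nearest). Structure
  files routinely omit hydrogens, but H-containing paths carry most of
  the signal at small depths.
* Charges, isotopes and stereochemistry are ignored; disconnected
  fragments of one record contribute to one bag of paths.
* The vocabulary for a search session is built over all structures
  involved (rule compounds, start, goal), so out-of-vocabulary labels
  cannot arise; when featurizing against a frozen vocabulary, foreign
  labels are counted, reported, and excluded — never silently dropped.

## Rule-set deduplication

Reversible reactions contribute both directions (`_f`, `_r`). Rules
identical in the exact $(U, O)$ pair merge with concatenated provenance;
zero operators (the main structure unchanged by the reaction) are
dropped and tallied. Rules sharing $O$ but differing in $U$ are
*reported* but kept distinct: $U$ gates applicability, so merging them
would change the search space. The dedup report carries all three
tallies.

## Synthetic fixtures

The generators stand in for curated reaction databases and provide
ground truth that is recorded at generation time by breadth-first
search with full optimal-tier enumeration, then re-derived
independently in the tests.

* `gen_edit_network(n, seed)` grows a tree of compounds from a random
  small alkane by valence-legal edits (attach C/O/N/Cl, remove a
  terminal heavy atom, toggle a C–C bond order), each edit one reaction,
  reversible with probability 1/2. Ancestor/descendant queries are
  solvable by construction; one random pair may be unreachable, which
  exercises the pruning paths. True distances are bounded by the edit
  tree depth, so ground truth is recorded under a search cap of
  `max(8, n + 2)`.
* `gen_ring_pathway(n, seed)` emulates a closed degradation circuit:
  a pentane scaffold with one distinct monovalent substituent per ring
  position, consecutive positions linked by one-step group
  substitutions, closing back to the start; a few reversible cross-links
  are added for $n \ge 10$. Distinct substituents make every edge
  operator distinct and keep the substrate gates selective, so optimal
  route tiers are small and route agreement is a meaningful check. All
  $n(n-1)$ ordered pairs are recorded; $n = 20$ gives the 380-pair
  design.
* `gen_two_route_fixture()` chlorinates one end of propane and aminates
  the other; the two substitutions commute exactly in vector space
  (their sites are more than two bonds apart, asserted at construction),
  and the gates block every other sequence, so the optimal tier is
  exactly two two-step routes — the canonical test for all-shortest
  enumeration.

What the fixtures do *not* emulate: multi-substrate reactions, cofactor
balancing, realistic enzyme chemistry, or database-scale vocabulary
sizes. Passing tests therefore demonstrate correctness of the
representation and search machinery, not predictive accuracy on real
metabolic data, which depends on the coverage of the supplied reaction
table.

## Test problem sizes

The test suite works at deliberately small scale so each oracle stays
exhaustive: path-count equivalence on 200 random molecules of up to 12
heavy atoms (depths 0–1, 0–2, 0–3) against an independent
`igraph`-based enumeration; search equivalence, admissibility,
consistency and expansion ordering on 100 seeded six-compound edit
networks at depth 0–2 with a search cap of 8; circuit reconstruction on
the 20-node ring (all 380 ordered pairs); and the LP-vs-IP bound on 50
instances small enough for exhaustive integer enumeration. Depth 0–2 is
the fixture default because it keeps vocabularies (and hence LP
instances) small while still distinguishing all generated compounds;
depth 0–3 is exercised in the featurizer equivalence suite.

## Known limitations

* The substrate-inclusion gate is a relaxation of subgraph inclusion:
  vector dominance does not imply the substrate is a subgraph, so
  predicted routes are candidate pathways, not certainties.
* Different compounds can share a vector at small depths; increasing
  the representation-depth sharpens both compound identity and rule
  distinctness at the cost of dimensionality.
* Costs are unit per rule application; thermodynamics, enzyme
  availability and kinetics are out of scope.
* Aromaticity is taken from the bond-type flag in the input file; no
  perception is attempted.
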