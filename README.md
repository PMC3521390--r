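# vecpath

De novo prediction of biochemical (metabolic) reaction pathways between
two compounds, for cheminformatics and pathway-engineering work where no
curated reaction network connects the endpoints. Given 2D structures
(MDL MOL/SDF V2000) and a table of known enzyme reactions, `vecpath`
finds the shortest sequences of reaction applications that transform a
start compound into a goal compound — including sequences that traverse
intermediates absent from any database.

## The method

A compound `c` becomes a feature vector `D_l^u(c)` counting every
labelled simple path with between `l` and `u` bonds ("depth `l-u`") in
its hydrogen-explicit structure graph. A reaction with main substrate
`i` and product `j` becomes a rule `R = (U, O)` with substrate gate
`U = D_l^u(i)` and operator `O = D_l^u(j) − D_l^u(i)`; applying the
reaction to any compound vector `C` is the addition `C + O`, permitted
when `C ≥ U` (substrate inclusion) and `C + O ≥ 0` entrywise. Pathway
prediction is then a shortest-path search in integer-vector space,
solved by A* with `f(t) = p(t) + h'(t)` and one of three admissible
heuristics:

- `bf` — zero heuristic (breadth-first, exhaustive reference);
- `mh` — Manhattan distance to the goal divided by the largest operator
  1-norm `||O_max||`;
- `lp` — the continuous relaxation of the operator-count integer
  program: minimize `Σ w_k` subject to `G − t = Σ w_k O_k`, `w ≥ 0`.
  The tightest of the three; an infeasible relaxation proves the goal
  unreachable and prunes the node.

The search returns the shortest distance, optionally *all* optimal rule
sequences, and diagnostics (expansions, branchings, heuristic calls,
peak frontier).

## Worked example

The methane feature vector at depth 0–2 (one C, four H, four C–H bonds,
six H–C–H paths — the count of unordered H pairs on the carbon):

```r
library(vecpath)
mf <- methane_fixture()
enumerate_paths(mf$graph, l = 0, u = 2)
#>     C     H   C-H H-C-H
#>     1     4     4     6
```

A pathway query on a synthetic 8-compound closed-circuit network
(pentane scaffolds with distinct substituents; each reaction swaps one
group for the next):

```r
fx <- gen_ring_pathway(8, seed = 42)
fx$ruleset
#> <rule_set: 8 rules over 39 dims (depth 0-2), ||O_max||1 = 30>
#>   from 8 reaction pairs -> 8 directed reactions; dropped 0 zero-operator, merged 0 identical-vector
#>   0 operator(s) shared across substrates (0 rules, kept distinct)

res <- astar(fx$vectors$C01, fx$vectors$C04, fx$ruleset,
             heuristic = "lp", enumerate_all = TRUE)
res
#> <search_result: found, distance 3, 1 optimal path(s)>
#>   expansions 3, branchings 3, heuristic calls 4, max frontier 1
res$paths
#> [[1]]
#> [1] "E01_f" "E02_f" "E03_f"
```

Three rule applications (`E01`, `E02`, `E03`, forward direction) reach
the goal; the LP heuristic expanded exactly the three on-path nodes.
Replaying any returned sequence with `replay_path()` re-checks both
constraint conditions at every step.

A command-line wrapper over the same functions ships in
`inst/cli/vecpath.R`:

```sh
Rscript inst/cli/vecpath.R search --sdf compounds.sdf --reactions reactions.tsv \
    --start C01 --goal C04 --depth 0-2 --heuristic lp --all-shortest
```

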