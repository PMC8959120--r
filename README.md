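# rewirenet

Adaptive rewiring of coupled logistic-map networks: a simulator and analysis
toolkit for studying how brain-like network complexity — small-worldness,
modularity, rich clubs — emerges when a network's wiring chases the
synchronization structure of its own activity, and how far that emergence
survives nonuniform node parameters.

## Who this is for

Researchers in network/computational neuroscience and complex systems who
want to simulate activity-dependent structural plasticity at the network
level, measure the resulting graph topology over time (whole network and
minority/majority partitions), and compare populations of evolved models.

## The model

Each of *n* nodes carries an activation *x* ∈ [−1, 1] updated by a coupled
chaotic logistic map

x<sub>i</sub><sup>t+1</sup> = 1 − α<sub>i</sub> [ (1 − ε<sub>i</sub>) (x<sub>i</sub><sup>t</sup>)² + (ε<sub>i</sub>/|B<sub>i</sub>|) Σ<sub>j∈B<sub>i</sub></sub> (x<sub>j</sub><sup>t</sup>)² ]

with amplitude α (chaoticity), coupling strength ε, and neighbor set
B<sub>i</sub>. After every 20 updates one **adaptive rewiring** attempt is
made: a random pivot drops the edge to its most activity-dissimilar neighbor
and wires to its most similar non-neighbor, conserving the edge count.
Networks start as uniform random graphs G(300, 5200) with Uniform(0, 1)
activations. Five parameter *families* perturb the first 50 nodes (the
minority): BL (uniform baseline α = 1.8, ε = 0.4), LC (α = 1.7), MC
(α = 1.9), SC (ε = 0.3), HC (ε = 0.5); for a given instantiation index all
families share the identical initialization (matched comparison).

The toolkit computes edge density, global clustering, average path length,
small-world index, fast-greedy modularity and degree assortativity per
checkpoint for four scopes (whole / minority / majority / interpartition),
normalizes them against matched random-graph ensembles, profiles rich clubs
against degree-preserving nulls with Wilcoxon significance flags, and
compares evolved models via NetSimile signatures (Canberra distance) and the
Heller–Heller–Gorfine permutation test of distributional association, with
family-level contrast and differentiation scores.

## Worked example

```r
library(rewirenet)

man <- run_manifest(family = "BL", instantiation = 1, seed = 7,
                    attempts = 80000, cadence = 1000)
sim <- simulate_network(man)
print(sim)
#> Adaptive rewiring simulation: family BL, instantiation 1
#>   300 nodes, 5200 edges, 80000/80000 rewiring attempts done
#>   metric checkpoints: 81 (cadence 1000)

summary(sim)   # windowed means over attempts >= 60000
#>            scope edge_density clustering path_length small_world modularity assortativity
#> 1 interpartition       0.1217     0.0000       3.090      0.0000     0.5865       -0.6975
#> 2       majority       0.1127     0.6347       2.212      0.2869     0.6234        0.6225
#> 3       minority       0.1389     0.7069       2.865      0.2480     0.5095        0.6882
#> 4          whole       0.1159     0.6461       2.155      0.2998     0.6107        0.6887

subset(growth_factors(sim), scope == "whole")
#>   scope        metric   initial windowed_mean   factor
#> 2 whole    clustering  0.115858         0.646     5.58
#> 3 whole   path_length  1.898283         2.155     1.14
#> 5 whole    modularity  0.129023         0.611     4.73
```

Reading: starting from a random graph (clustering 0.116, the density),
adaptive rewiring raises whole-network clustering 5.6× and modularity 4.7×
while average path length inflates only 14% — the network has become a
modular small world. Assortativity climbs from ≈0 to ≈0.69: hubs wire to
hubs. A rich-club profile of the final state confirms it:

```r
set.seed(42)
rc <- rich_club(sim$adjacency, null_count = 200)
range(rc$k[rc$significant])
#> [1] 19 62       # significant rich clubs across club sizes 19..62
```

Perturbed families differentiate: a hyper-coupled minority (HC, ε = 0.5)
synchronizes internally and densifies far above the network average, while
more-chaotic (MC) and sub-coupled (SC) minorities shed edges — occasionally
to the point of isolating a node, which terminates that model (recorded,
frozen, excluded from family summaries). Batteries of runs are orchestrated
by `run_battery()` / `battery_summary()`, and model populations are compared
with `dissimilarity_matrix()`, `family_contrast()` and
`differentiation_scores()`.

A command-line wrapper for shell pipelines is installed at
`system.file("cli", "rewirenet", package = "rewirenet")` with subcommands
`simulate`, `summarize`, `richclub`, `compare`, `plot`.

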