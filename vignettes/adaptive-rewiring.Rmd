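---
title: "Adaptive rewiring of coupled logistic-map networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive rewiring of coupled logistic-map networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewirenet)
```

## The model

`rewirenet` simulates the structural evolution of a sparse binary network
whose nodes are chaotic oscillators, under *adaptive rewiring*: the network
repeatedly disconnects dynamically dissimilar node pairs and connects
similar ones — a network-level rendering of "what fires together, wires
together". Starting from an Erdős–Rényi random graph, this feedback between
activity and topology is known to produce the hallmarks of large-scale brain
connectivity: high clustering at near-random path length (small-worldness),
modules, and a rich club of interconnected hubs. The package's focus is the
nonuniform case: a *minority* subset of nodes carries perturbed dynamical
parameters, emulating function-specific modulation (sensory input, memory
traces), and the question is whether network complexity still develops and
how the minority differentiates structurally.

### Dynamics

Each node $i$ carries an activation $x_i \in [-1, 1]$ evolving in discrete
time by a coupled logistic map,

$$x_i^{t+1} \;=\; 1 - \alpha_i\!\left[(1-\varepsilon_i)\,(x_i^t)^2 +
  \frac{\varepsilon_i}{|B_i|}\sum_{j\in B_i}(x_j^t)^2\right],$$

where $B_i$ is the current neighbor set, $\alpha_i \in (0,2]$ the amplitude
(degree of chaoticity) and $\varepsilon_i \in [0,1)$ the coupling strength
(the fraction of the next state contributed by the neighbors' mean map).
After one update every activation lies in $[1-\max\alpha,\,1]$; the package
never clips. With $\varepsilon \equiv 0$ the network decouples into
independent logistic maps $x^{t+1} = 1 - \alpha x^2$.

The amplitude inside the neighbor sum is the *receiving* node's $\alpha_i$
by default, which admits the closed vector form
$X^{+} = 1 - \alpha \odot [(1-\varepsilon)\odot X^2 +
\varepsilon \odot (A X^2) \oslash (A\mathbf{1})]$.
The alternative convention — each neighbor contributes its own $\alpha_j$ —
is available via `neighbor_amplitude = "neighbor"` in `coupled_step()` and
`run_manifest()`; for all five stock parameter families except LC and MC the
two coincide because $\alpha$ is uniform.

### Rewiring

After every `updates_per_rewiring` updates (default 20) one rewiring attempt
is made: a pivot node is drawn uniformly at random, its activation distances
$d_j = |x_j - x_{\mathrm{pivot}}|$ are computed, and the pivot is
disconnected from its most distant neighbor and connected to its most
similar non-neighbor (similarity $s = 1 - d$). Ties at either argmax break
at the lowest node index; ties have measure zero under the continuous
dynamics, so the rule only pins down reproducibility. Each attempt conserves
the edge count exactly.

Two pathologies terminate a model cleanly rather than crash it:

* **no non-neighbor** — the pivot is already connected to all other nodes;
* **isolated node** — a rewiring stripped a node's last edge, making the
  neighbor average undefined at the next update.

Termination is absorbing: the state freezes, the metric series stops at the
termination attempt, and terminated models are excluded from summary tables
and family comparisons. We deliberately do not prevent isolation at rewiring
time; pathological breakdown is treated as an informative outcome of network
evolution rather than an error to engineer away. In practice the
more-chaotic (MC) and sub-coupled (SC) families lose a minority-driven
fraction of runs this way within the first ~15,000 attempts; the termination record carries the
attempt index, reason and node.

### Parameter families and matched initialization

The reference configuration is 300 nodes, 5,200 edges (density 0.116), the
first 50 nodes forming the minority. The majority always sits at
$\alpha = 1.8$, $\varepsilon = 0.4$; the five families perturb the minority
only:

| family | minority $\alpha$ | minority $\varepsilon$ | reading |
|---|---|---|---|
| BL | 1.8 | 0.4 | baseline, fully uniform |
| LC | 1.7 | 0.4 | less chaotic minority |
| MC | 1.9 | 0.4 | more chaotic minority |
| SC | 1.8 | 0.3 | sub-coupled minority |
| HC | 1.8 | 0.5 | hyper-coupled minority |

Initial graphs are uniform $G(n, m)$ draws (exactly $m$ edges; connectivity
is not enforced — at density 0.116 disconnection of the initial graph is
vanishingly rare) and initial activations are i.i.d. Uniform(0, 1). The seed
policy derives named substreams from one master seed; the initialization
substream depends only on the instantiation index, never on the family, so
for a given instantiation all families start from the *identical* graph and
activations (matched comparison), while pivot draws and baseline ensembles
use their own streams.

## Network statistics

Six statistics are checkpointed for four scopes — the whole network, the
minority and majority induced subgraphs, and the interpartition scope (all
nodes, crossing edges only):

* **edge density**: realized fraction of possible edges; for the
  interpartition scope the denominator is the number of cross pairs
  $|V_{\min}||V_{\mathrm{maj}}|$, each cross edge counted once (the ordinary
  $n(n-1)$ denominator is wrong for a bipartite edge set);
* **global clustering** (transitivity): closed over connected triplets,
  $\operatorname{Tr}(A^3) / (\sum A^2 - \operatorname{Tr}A^2)$, 0 when no
  triplet exists;
* **average path length** with the convention $d_{ij}=0$ for disconnected
  pairs (which *shortens* averages on fragmented graphs — kept deliberately
  for comparability with the adaptive-rewiring literature);
* **small-world index** $C/\mathrm{PL}$, optionally normalized by matched
  random graphs;
* **modularity** of the partition found by fast-greedy (Clauset–Newman–Moore)
  agglomeration, with the standard normalization by the edge count $|E|$;
* **degree assortativity** (Newman's remaining-degree correlation), flagged
  `NA` on regular graphs and excluded from aggregates.

Statistics are normalized by the mean over an ensemble (default 100) of
random graphs matched to the scope: $G(n_s, m_s)$ with
$m_s = \mathrm{round}(\binom{n_s}{2} \cdot \rho)$ at the whole-network pair
density $\rho$ — the initial condition of every scope — and a random
bipartite ensemble for the interpartition scope. Assortativity passes
through unnormalized (its random-graph expectation is 0). Normalizing each
scope to its own matched ensemble is one of two defensible readings (the
other matches every scope to whole-network draws); it is the only one under
which the whole-network and majority normalized densities sit at 1, as
expected.

The **rich-club profile** is computed on final states: for each club size
$k$, RC($k$) is the edge density among nodes of degree $\ge k$, normalized
by the mean profile of 200 degree-preserving randomizations (double-edge
swaps, 10$\times$edge-count attempts — a standard mixing heuristic). Each
$k$ is flagged
significant when a one-sided one-sample Wilcoxon signed-rank test places the
observed RC($k$) above the null distribution at $\alpha = 0.01$; with
ensembles of 200 the exact distribution is unnecessary, so the normal
approximation with continuity correction is used. Significance is undefined
where fewer than two nodes survive the cutoff, or where all null values
coincide with the observed one (a complete graph, for instance).

## Checkpoint cadence and numerical choices

The statistics can be computed after every attempt; for long runs this
dominates runtime while adding no information to windowed means, so the
cadence is configurable (`cadence`, default 1,000 attempts, plus attempt 0
and the termination attempt). Windowed summaries use all checkpoints from
60,000 attempts onward, unweighted — past that point the whole-network
statistics have plateaued.

All dynamics run in double precision with no clipping. The compiled inner
loop keeps the edge list sorted so that every node's neighbor contributions
accumulate in ascending index order: the floating-point trajectory is then a
pure function of the initial state and the pivot sequence, *independent of
the checkpoint cadence*. This matters because the dynamics are chaotic — a
one-ulp difference in summation order grows into a macroscopically different
(though statistically equivalent) trajectory within a few hundred updates.
With a fixed master seed, full trajectories are bit-reproducible.

The scaled defaults used by the acceptance harness — 3 instantiations per
family, 200,000 attempts (150,000 for MC), cadence 1,000, 100-graph
baselines — were chosen because windowed means stabilize after the 60,000
attempt transient; they are the package's desk-scale rendering of the full
design (10 instantiations × 1 million attempts).

## Comparing evolved models

A model's *anatomical* connectivity is its adjacency matrix; its
*functional* connectivity $F$ is the matrix of momentary absolute activation
differences, thresholded to a binary graph at the anatomical edge budget
(keeping the most similar pairs) when a graph representation is needed.

**NetSimile** signatures summarize a graph by 7 per-node features (degree,
local clustering, mean neighbor degree, mean neighbor clustering, egonet
edges, egonet outgoing edges, egonet neighbor count), each aggregated by
median, mean, standard deviation, skewness and kurtosis (35 entries;
skewness and kurtosis of a zero-variance feature are set to 0 so signatures
stay finite on vertex-transitive graphs). Distances between signatures are
Canberra; dissimilarity matrices over a model collection are normalized to
$[0,1]$ by their maximum.

**HHG** tests distributional association between two models' node-feature
clouds, paired by shared node identity, via the Heller–Heller–Gorfine
statistic on the two Euclidean distance matrices with a permutation p-value
(default 1,000 permutations; the add-one estimator). In this package's
reading a *higher* p-value is taken as *lower* resemblance — an
acknowledged unorthodoxy, which is why it is only reported alongside the
NetSimile distances (composite matrices carry HHG in the lower and NetSimile
in the upper triangle). What to feed HHG is a genuinely open design choice
(node features, signature vectors, or raw connectivity distances); per-node
feature matrices are the default here, and precomputed distance matrices can
be passed directly.

**Contrast** is the mean dissimilarity over a family-by-family block, with
the *actual* block size as denominator: within-family blocks include their
zero diagonal, and families shrunk by terminated-model exclusion average
over their remaining members rather than being padded. The
**differentiation** score of family $f_i$ is
$(1 - \mathrm{Contrast}(f_i,f_i)) \big/ \overline{(1 -
\mathrm{Contrast}(f_i,f_j))}_{j\neq i}$; values above 1 mean the family's
members resemble each other more than they resemble outsiders. It requires
dissimilarities in $[0,1]$ and is therefore not computed from HHG p-values.

## What the generator emulates — and what it does not

The synthetic stage generates exactly the study conditions: fixed-size
uniform random graphs, uniform initial activations, the five named families,
matched initializations, and the two null ensembles (fixed-edge-count random
graphs for normalization, degree-preserving randomizations for rich clubs).
It does not emulate features of real neural data — weighted or directed
connectivity, spatial embedding, transmission delays, noise — so passing
tests certify the rewiring-and-measurement machinery, not biological
realism.

## Known limitations

* The average-path-length convention ($d=0$ for disconnected pairs) biases
  the statistic downward on fragmented subgraphs; minority subgraphs of
  terminated or strongly depleted models should be read with care.
* Some reference values the acceptance harness checks against ascribe
  nearly identical minority-subgraph statistics to all five families,
  including the fully uniform baseline. Under the model as implemented here,
  baseline nodes are exchangeable: no mechanism can single out the minority
  indices, and simulated baseline minority densities indeed stay at the
  whole-network level (no exact activation ties ever arise that could let
  the low-index tie-break bias wiring). The hyper- and sub-coupled
  perturbations, by contrast, produce strong and opposite minority effects:
  the HC minority densifies to ~6–7× the whole-network level, with a
  correspondingly large normalized small-world index. The package stands by
  the exchangeability argument; the one spot check tied to the
  uniform-minority reference value is left failing rather than tuning the
  model toward it.
* HHG is quadratic per pair and permutation; at 300 nodes and 1,000
  permutations a single pairwise comparison takes minutes in pure R. Use
  fewer permutations for exploration, or subsample nodes.
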