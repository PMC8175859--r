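# gfsnet

Differential analysis of weighted structural brain networks by a global,
multi-feature node-importance score.

## The problem

Structural connectomes built from diffusion imaging are weighted undirected
graphs: nodes are brain regions (e.g., the 90 regions of the AAL atlas) and
the weight of an edge is the number of reconstructed white-matter fibers
between two regions (the *fiber-number*, FN, matrix). A disease that thins
the fiber bundles around particular regions should leave a signature in the
network's topology — but any single centrality index captures only one
facet of a node's role, and in sparse, noisy clinical networks an index
that depends only on direct (1-hop) connections is fragile: drop a few
low-count edges and the ranking changes.

`gfsnet` addresses both problems for researchers comparing two groups of
connectomes (e.g., patients vs. controls):

1. **2hop-connectivity** (`s_2hop`): a node-importance score from a random
   walk with restart whose transition operator mixes 1-step and 2-step
   moves, so relevance can flow between regions that have lost their direct
   connection. For each node \(v_j\) the walker takes a 1-hop move with
   probability \(\alpha_1(j)\,c\), a 2-hop move with probability
   \(\alpha_2(j)\,c\), and restarts with probability \(1-c\):

   \[ r_{t+1} = c\left(\alpha_1 P^\top + \alpha_2 (P^2)^\top\right) r_t + (1-c)\, r_0, \]

   with \(P = D_G^{-1} W\) row-stochastic and, per node,
   \(\alpha_1 = |N_1| / (|N_1| + |N_2|)\) — the fraction of 1-hop among
   1- and 2-hop neighbours. The iteration is a contraction with closed-form
   fixed point \((1-c)(I - cA)^{-1} r_0\); the package implements both and
   tests them against each other. Rows of the steady-state matrix
   \(\Pi = (1-c)(I - cA)^{-1}\) are the stationary distributions of walks
   restarted at each node, and a node's score is the stationary mass it
   receives across all starts, \(S_{2hop}(v_i) = \sum_j \pi_{ji}\).

2. **Global Feature Score (GFS)**: a convex combination of five min-max
   normalized per-node features — degree centrality, betweenness
   centrality, closeness centrality, number of maximal cliques, and
   2hop-connectivity:

   \[ GFS(v_i) = \textstyle\sum_{k=1}^{5} w_k \, F_k(v_i), \qquad w_k \ge 0,\ \sum w_k = 1, \]

   with equal weights \(1/5\) by default, or weights fitted to an external
   cognitive score (e.g., MMSE) by nonnegative least squares.

Groups are compared on their average FN matrices: nodes are ranked by
\(\Delta GFS = GFS_{\text{group A}} - GFS_{\text{group B}}\), so with
controls as group A the regions most weakened in the case group rank
first. Canonical correlation analysis (`cca_first()`) relates GFS-derived
variables to cognitive scale scores.

## Worked example

A synthetic two-group study: 90 regions at 15% edge density, 10 subjects
per group, where regions R1–R5 have all incident fiber counts attenuated
to 20% in the case group.

```r
library(gfsnet)

spec <- synthetic_spec(
  n_nodes = 90, edge_density = 0.15, n_subjects = 10,
  affected_nodes = 1:5, attenuation = 0.2,
  subject_noise_cv = 0.2, seed = 7
)
pair <- make_group_pair(spec)
cmp <- compare_groups(pair$control, pair$case, top_k = 5)
cmp
#> <group_comparison> 90 nodes; top 5 nodes by GFS difference:
#> # A tibble: 5 × 3
#>   node   delta  rank
#>   <chr>  <dbl> <int>
#> 1 R1    0.157      1
#> 2 R2    0.135      2
#> 3 R4    0.124      3
#> 4 R5    0.0725     4
#> 5 R3    0.0212     5
```

All five planted regions occupy the top five ranks: their GFS in the
case-group average network is 0.02–0.16 lower than in the control average,
while unaffected regions differ only by subject noise.
`autoplot(cmp$ranking)` draws the ranking; `cmp$features_a` holds the full
five-feature table.

The same workflow from a shell, via the bundled entry point (installed
under `exec/`):

```sh
gfsnet simulate --n 90 --density 0.15 --affected 5 --attenuation 0.2 \
  --subjects 10 --seed 7 -o study
gfsnet compare --group-a study/control --group-b study/case \
  --c 0.85 --min-weight 1 --top-k 5 -o results
gfsnet cca --x gfs_subjects.tsv --y scales.tsv -o results
```

`compare` writes `features.tsv`, `gfs.tsv`, `delta_ranking.tsv` and a
`manifest.json` with parameters and input hashes.

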