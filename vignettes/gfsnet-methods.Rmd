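---
title: "Methods: 2-hop restart walks and the Global Feature Score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2-hop restart walks and the Global Feature Score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfsnet)
```

## The data model

`gfsnet` operates on weighted undirected graphs \(G(V, E, W)\): a set of
labelled nodes (brain regions under an atlas parcellation), and a
symmetric nonnegative weight matrix whose entry \(w_{ij}\) is the fiber
count between regions \(i\) and \(j\). Self-loops are excluded — the edge
set is defined between distinct regions only — so `weighted_graph()`
enforces symmetry, nonnegativity and a zero diagonal, and
`clean_graph()` restores those invariants on raw input: it zeroes the
diagonal, removes edges below a denoising threshold, and symmetrizes
matrices whose asymmetry is within a relative tolerance (deterministic
tractography pipelines can emit near-symmetric counts). Asymmetry beyond
the tolerance is an error rather than a silent fix.

Two ordering conventions hold throughout: node order is input file order,
and every downstream vector and table is aligned to it.

A group of subjects is represented by its element-wise mean matrix
(`average_group()`). Each subject is thresholded *before* averaging and
the averaged matrix is not re-thresholded: the average of several
thresholded integer matrices is informative at values below the per-subject
threshold, and discarding that mass would re-sparsify the group network
arbitrarily. This ordering is a package decision — with a per-subject
threshold of 1 on integer counts it is nearly a no-op, but it matters if
a user raises `min_weight`.

## Local features

Four classical per-node indices are computed on the positive-weight
skeleton:

* **Degree centrality** \(C_D(v_i) = d(v_i)/(n-1)\), with \(d\) the count
  of distinct neighbours. Weights are not summed, so one heavy bundle
  counts the same as one light one.
* **Betweenness centrality**: the sum over unordered node pairs (excluding
  pairs containing \(v_i\)) of the fraction of shortest paths through
  \(v_i\). Pairs in different components contribute zero. Summing ordered
  pairs would exactly double every value and leave every ranking
  unchanged; unordered summation is used.
* **Closeness centrality**: on a connected graph,
  \((n-1)/\sum_j d(v_j, v_i)\). Because that expression is undefined when
  some distances are infinite, disconnected graphs use the reachable-set
  scaling \(\frac{r-1}{\sum d}\cdot\frac{r-1}{n-1}\) (the Wasserman–Faust
  form), which coincides with the plain formula on connected graphs and
  sends isolated nodes to 0.
* **Maximal clique count** \(N_{MC}(v_i)\): the number of maximal cliques
  containing \(v_i\), enumerated by pivoting Bron–Kerbosch (via igraph).
  An isolated node is its own maximal clique and scores 1; enumeration is
  exponential in the worst case, so a configurable cap aborts pathological
  inputs.

Shortest paths are unweighted by default, matching the unweighted degree
count; a weighted mode with edge length \(1/w\) (stronger connections are
shorter) is available, since either convention is defensible for fiber
networks. Both are tested; rankings on the synthetic study are not
sensitive to the choice.

## The 2-hop restart walk

The walk's transition matrix is the weighted row normalization
\(P = D_G^{-1}W\), \(d_i = \sum_j w_{ij}\); rows of isolated nodes become
unit self-vectors so \(P\) stays stochastic. The 2-hop operator is the raw
matrix square \(P^2\). The walk iterates

\[ r_{t+1} = c\,(\alpha_1 P^\top + \alpha_2 (P^2)^\top)\, r_t + (1-c)\,r_0 \]

from a unit start vector \(r_0\). Two conventions deserve comment:

* **Per-node mixing.** \(\alpha_1\) is defined per node as the fraction of
  1-hop among 1- and 2-hop neighbours, where the 2-hop set \(N_2\) is the
  *exact*-distance-2 set: self and direct neighbours excluded. The mixed
  operator is \(A = \mathrm{diag}(\alpha_1)P + \mathrm{diag}(\alpha_2)P^2\);
  each row of \(A\) is a convex combination of stochastic rows, hence
  stochastic, so every convergence argument for scalar mixing carries
  over unchanged. A scalar mode (`alpha_mode = "scalar"`) is kept both as
  the simpler variant and because `scalar_alpha1 = 1` reduces the method
  exactly to the classical random walk with restart — a reduction the
  test suite asserts to \(10^{-12}\).
* **\(N_2\) vs \(P^2\).** The neighbour *counting* uses the
  exact-distance-2 set, while the 2-step *operator* keeps the full
  \(P^2\), including return-to-self mass. Replacing \(P^2\) by a pruned
  operator would destroy row-stochasticity or require renormalization;
  keeping the raw square keeps the Markov structure intact.

Since each row of \(A\) is stochastic, \(\|A^\top x\|_1 \le \|x\|_1\) and
the iteration is an affine map with Lipschitz constant \(c < 1\) in L1:
it contracts to the unique fixed point

\[ r_\infty = (1-c)\left(I - cA^\top\right)^{-1} r_0, \]

with residual after \(t\) steps bounded by \(2c^t\). `rwr_iterate()`
implements the iteration (L1 tolerance `1e-10`, cap 1000 iterations —
at the default \(c\) the geometric bound meets that tolerance in under
160 iterations); `rwr_closed_form()` implements the linear solve. The two
are redundant on purpose: the closed form is the executable proof of
convergence, and the suite checks their agreement on random graphs up to
100 nodes at \(c \in \{0.15, 0.5, 0.85\}\) in both mixing modes.

Stacking the stationary vectors of all starts gives the steady-state
matrix, computed in one solve: \(\Pi = (1-c)(I - cA)^{-1}\), each row a
probability vector.

### Scoring from \(\Pi\), and a deliberate asymmetry

Each row of \(\Pi\) sums to 1 by construction, so aggregating row \(i\)
over its columns yields the constant 1 for every node — a quantity that
cannot rank anything. The package therefore scores node \(v_i\) by the
**column** sum \(S_{2hop}(v_i) = \sum_j \pi_{ji}\): the total stationary
mass \(v_i\) receives across walks restarted at every node, the standard
relevance aggregate for restart walks, and the reading consistent with
"larger score = more important node". The literal row-sum mode is retained
(`s2hop_scores(Pi, "row_sum")`) so the degeneracy is visible and tested,
not silently papered over. In both modes the scores total exactly \(n\).

### Parameters

| parameter | default | meaning |
|---|---|---|
| `c` | 0.85 | continuation probability; \(1-c\) is the restart probability. No canonical value exists for fiber networks; 0.85 is the common restart-walk convention and is exposed everywhere. `c = 1` is rejected (the stationary solution is no longer unique). `c = 0` gives \(\Pi = I\). |
| `alpha_mode` | `per_node` | hop-mixing convention (see above). |
| `tol` | 1e-10 | L1 stopping tolerance of the iteration. |
| `max_iter` | 1000 | iteration cap; exceeded caps warn with the final residual. |
| `min_weight` | 1 | per-subject denoising threshold on fiber counts: any traced fiber forms an edge. |

The solver is fully deterministic: no randomness anywhere.

## The Global Feature Score

Each feature vector is min-max normalized to \([0,1]\) per network —
the only normalization that puts a bounded centrality, an unbounded
betweenness and an integer clique count on a common scale with both
endpoints attained. A constant feature has no information to contribute;
it maps to all zeros (with a warning) rather than an arbitrary constant.
Constancy is judged with a relative tolerance of \(10^{-12}\), because an
analytically constant feature (e.g., \(S_{2hop}\) on a graph whose mixed
operator is doubly stochastic) otherwise has its floating-point noise
amplified to the full unit interval.

GFS is the convex combination of the five normalized features, equal
weights \(1/5\) by default. `fit_gfs_weights()` offers the data-driven
alternative: nonnegative least squares of an external per-node-matched
score on the five features, rescaled to sum to 1, so the fitted GFS is
still a convex combination and monotone in every feature; an all-zero fit
falls back to equal weights with a warning. NNLS was chosen over ordinary
least squares precisely to preserve those two properties.

Two group-average networks are compared by \(\Delta GFS\) per node, sorted
descending; ties break by input label order so output is bit-for-bit
reproducible. `cca_first()` reports the first canonical correlation
between a GFS-derived block and an external block (e.g., cognitive scale
scores), computed on centred data with zero-variance columns dropped;
only the first canonical pair is reported and no significance test is
attached. How per-node scores are matched to per-subject observations is
a study-design question left to the caller: the function accepts any two
conformable observation tables.

## The synthetic study generator

`synthetic_spec()` + `make_group_pair()` emulate the measurement the
pipeline is designed for: two groups of sparse integer fiber-count
networks in which a designated node subset is structurally weakened in
one group.

* One Erdős–Rényi base topology per study (resampled until connected),
  integer log-normal weights — fiber counts are positive and
  right-skewed. Both groups share the base, so the *only* systematic
  group difference is the planted one.
* Case subjects scale every edge incident to an affected node by the
  attenuation factor **before** noise: the deficit is structural, not a
  measurement artifact.
* Per-subject noise is multiplicative log-normal per edge with mean 1;
  its coefficient of variation is the single noise knob. Counts are
  re-rounded to nonnegative integers.

Defaults (90 nodes, 15% density, median present-edge count 30, 10
subjects/group, 5 affected nodes at attenuation 0.2, CV 0.2) describe a
moderately sparse atlas-scale study with a strong focal deficit; the
median count of 30 is a realistic magnitude for atlas-scale fiber counts
and only sets the scale on which rounding noise acts. The generator does
**not** reproduce anatomical realism — no distance-dependent wiring, no
hub/module structure, no hemispheric symmetry, no tractography artifacts
(gyral bias, crossing-fiber dropout). Passing the recovery test therefore
shows the pipeline detects focal attenuation against i.i.d. noise on a
homogeneous topology; it does not certify sensitivity on real
connectomes, where confounds are correlated and effects diffuse.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle:
matrix-power geodesic counting (itself cross-checked against exhaustive
path enumeration on tiny graphs) for betweenness and closeness,
all-subsets enumeration for maximal cliques — around a thousand random
graphs of up to 8 nodes; the closed form against the iteration on random
connected graphs of 5–100 nodes; a direct classical-restart-walk solve
for the scalar reduction; a grid-plus-simplex correlation maximizer for
CCA; and hand-derived fixtures (the two-node graph, three- and four-node
paths) asserted to \(10^{-10}\). The end-to-end recovery experiment uses
20 independently seeded studies at the default spec, plus 20 null studies
(attenuation 1) whose recovery must stay within a binomial chance band
and whose \(|\Delta GFS|\) must be exchangeable between designated and
undesignated nodes under permutation. These sizes keep the whole suite
around half a minute while exercising every code path at meaningful
scale.

## Known limitations

* Min-max normalization is per network, so GFS values are comparable
  *within* a network and as differences between two aligned networks, not
  as absolute scores across unrelated studies.
* The 2-hop operator stops at \(k = 2\); no \(k\)-hop generalization is
  provided.
* Group comparison is purely descriptive: \(\Delta GFS\) ranks nodes but
  carries no inferential statement (no permutation test, no FDR). Use the
  synthetic generator to calibrate expectations for a given effect size.
* Clique enumeration can be exponential; the cap makes this an explicit
  error instead of a hang on adversarial dense graphs.
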