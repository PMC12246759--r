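---
title: "Network fragmentation and survey outcomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network fragmentation and survey outcomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragnet)
```

## The problem this package addresses

Town-level online social networks differ in how strongly they split into
communities. In a highly fragmented town network, most ties run inside
communities and few run between them, which favours epistemic echo chambers:
people source information mainly from structurally similar peers. fragnet
implements the full quantitative chain needed to study how such
fragmentation relates to individual exposure to, and beliefs about, true and
fake health-related claims: a size-adjusted modularity index on crawled
friendship graphs, the crawl design itself with its coverage accounting,
survey outcome construction, and town-clustered regression — plus a
synthetic-study generator so that every stage can be validated end to end
with known ground truth.

## The fragmentation index

For an undirected simple graph with $L$ edges and a partition of its nodes
into communities $k = 1, \dots, K$, write $L_k^w$ for the number of edges
with both endpoints in community $k$ and $L_k$ for the number of edge
endpoints adjacent to members of $k$ (each internal edge contributes two
endpoints, each boundary edge one, so $\sum_k L_k = 2L$). Modularity is the
classical Newman–Girvan quantity

$$Q = \sum_k \left[ \frac{L_k^w}{L} - \left(\frac{L_k}{2L}\right)^2 \right],$$

the within-community edge fraction minus its expectation under a
degree-preserving null. $Q$ is not comparable across networks of different
sizes: its attainable maximum depends on the community degree distribution.
The index therefore normalizes by the value the same partition would attain
if every edge were internal while community degree totals stayed fixed,

$$Q_{\max} = 1 - \sum_k \left(\frac{L_k}{2L}\right)^2, \qquad
  F = \frac{Q}{Q_{\max}} \le 1,$$

with $F = 1$ exactly when no edge crosses a community boundary. `modularity_q()`,
`max_modularity()` and `fragmentation_index()` implement these directly by
edge counting; the test suite checks them against an independent
implementation over every partition into up to three blocks of small random
graphs.

Two readings of "edges adjacent to members of community $k$" are possible —
counting each boundary edge once, or counting degree endpoints. We use the
degree-endpoint convention (internal edges count twice), the standard one in
the modularity literature; it is the only choice under which $Q \le Q_{\max}$
holds for every graph and partition, which the normalization requires.

Partitions come from the Louvain algorithm (`louvain_partition()`, backed by
igraph's implementation): greedy local moves followed by community
aggregation, a heuristic for an NP-hard objective. Because the heuristic's
visit order is randomized, the run is seeded: identical (graph, seed,
resolution) always returns an identical, canonically relabelled partition.
The resolution parameter defaults to 1 (the classical objective) and is
exposed because no other value has a principled claim here. A
single-community outcome makes $F$ a 0/0 ratio; `fragmentation_index()`
raises an error in that case and the pipeline records the town as missing
rather than guessing.

## Emulating the crawl

The data-collection design being emulated selects, for each town, up to 18
seed accounts — one per age-group-by-gender stratum (three equal age bands
spanning 18–65, two genders) in each of three rounds — subject to at least
100 same-town friends and at most 500 total friends, then performs
breadth-first sampling to depth 2 from each seed and merges the results.
`select_seed_accounts()` draws uniformly among eligible, not-yet-chosen
candidates per stratum; exhausted strata simply yield fewer seeds.

`bfs_ego_sample()` records all nodes within two hops. For edges, the rule
mirrors what friend-list crawling can actually see: an edge is included only
if at least one endpoint lies strictly inside the frontier, because only
those nodes' adjacency lists are fetched. Edges between two
exactly-at-depth-2 nodes are invisible. The equal-span age bands (18–33,
34–49, 50–65) and the without-replacement reuse rule across rounds are
package choices where the design description is silent.

Coverage of the merged crawl is reported as four bounds
(`coverage_bounds()`): nodes and edges each relative to the whole citizen
population (lower bound) and to the platform's town user base (upper bound).
The edge denominators take `population × avg_degree / 2` expected ties, with
`avg_degree = 100` by default; the platform-restricted denominator is scaled
by the user share and by the average share of a user's friends living in the
same town. The value 100 is of the order of the Dunbar number and matches
the arithmetic of the published coverage figures this package reproduces;
both parameters are explicit arguments, and all denominators are returned
for audit.

## Survey outcomes

Respondents see a battery of nine statements — items 1–5 fake, items 6–9
true — and first mark which they have encountered, then rate encountered
ones on a 1–4 reliability Likert scale with a "difficult to say" option.
`recode_attitude()` maps 1→−2, 2→−1, 3→+1, 4→+2; "difficult to say" and
never-encountered both become 0, neutralizing skipped items while keeping
the respondent. `derive_outcomes()` builds the eight outcome variables:
encounter shares (of 5 fake, of 4 true), attitude sums (fake in [−10, 10],
true in [−8, 8]), agreement shares (agree = Likert 3 or 4), the attitude
difference `att_fake − att_true` (individual polarization; the sign
convention is fake minus true), and the misinformation error — the share of
fake statements agreed with plus the share of true statements disagreed
with, in [0, 2].

Two "don't know" rules coexist deliberately: in attitude sums a DK item
contributes 0, while a stricter analysis may drop any respondent with a DK
answer entirely (`drop_dk = TRUE`). The retain-with-zeros behaviour is the
default because it preserves observations and matches how the attitude
variables are defined; the flag exists because the eligibility rules for
covariate missingness are stated separately and a conservative analyst may
prefer whole-row exclusion. Town eligibility applies strictly more than 10
respondents (`filter_towns()`; a town with exactly 10 is dropped).

## Inference

`fit_ols_cluster()` fits OLS and reports CR1 cluster-robust standard errors:
the sandwich $(X'X)^{-1} \left[\sum_g X_g' e_g e_g' X_g\right] (X'X)^{-1}$
scaled by $\frac{G}{G-1}\cdot\frac{N-1}{N-K}$, with p-values from a
$t_{G-1}$ distribution. CR1 with $G-1$ degrees of freedom is the
conventional, mildly conservative choice for designs where the regressor of
interest varies only at the cluster (town) level; CR0 is available via
`type = "CR0"`. With one observation per cluster CR1 reduces algebraically
to HC1, which the tests assert numerically against an independent
implementation. Rank-deficient designs fail loudly, naming the collinear
columns.

`predicted_contrast()` turns fitted coefficients into worked-example
quantities by exact linear algebra: the predicted outcome difference between
two covariate profiles, with unspecified terms held equal (they cancel). It
is antisymmetric under profile swap and requires every named term to exist
in the model. `paired_t_one_tailed()` wraps the classical paired t test for
the re-crawl stability check; the direction of the one-tailed alternative is
a flag (default: mean difference greater than zero) because the published
description does not state it. `robustness_subset()` retains towns whose
edge coverage strictly exceeds a threshold (default 0.15), the conventional
fidelity cut for graph-sample structure preservation.

## The synthetic-data generator

The observational study has no data-generating process to copy, so the
generator uses the minimal process whose aggregates obey the fitted linear
model exactly in expectation: each statement is encountered with probability

$$p_{is} = \mathrm{clamp}_{[0,1]}\left( b_s + \beta^{enc}_F (F_j - \bar F) +
  \beta^{enc}_{VK} (VK_i - \overline{VK}) + \gamma'(x_i - \bar x) \right),$$

a linear probability model whose per-class mean share then has exactly the
slope $\beta^{enc}_F$ on fragmentation. Centering keeps the per-statement
baselines $b_s$ interpretable as pooled encounter rates and does not change
any slope. Clamping events are counted and a warning fires if more than 5%
of probabilities needed clamping — with the default configuration none do.
Conditional on encounter, the Likert answer comes from an ordered logit with
fixed cutpoints (−1.5, 0, 1.5) whose latent mean shifts linearly with
fragmentation and platform use — the simplest mechanism producing monotone
attitude effects — plus a 5% "difficult to say" probability.

Defaults are the study conditions: per-statement baseline encounter rates
follow the observed "never came across" pattern of the nine-item battery
(fake items 0.97/0.34/0.47/0.33/0.22; true 0.78/0.49/0.63/0.08);
fragmentation slopes are +0.057 (fake) and −0.068 (true) per unit $F$ with
platform-use slopes +0.044 and +0.030; the latent attitude shift per unit
$F$ is −1.0 for true statements (strongly negative) and +0.3 for fake
(weak positive), with platform-use shifts −0.3/+0.1; town fragmentation
spans 0.293–0.799; respondent counts per town are uniform on 11–200; and
control covariates match the observed survey marginals (62% female, mean
age ≈ 37, 61.7% platform use, and so on). Controls are generated
independently of fragmentation — no confounding — so the regression's
estimand equals the generating slope; a confounded variant would be a
deliberate extension, not a default.

Town graphs come from planted-partition (stochastic block model) draws
(`generate_sbm_town()`), with the planted communities returned for oracle
checks. `generate_roster()` attaches ages (uniform 16–70), balanced genders
and friend counts (same-town = graph degree; total adds Poisson out-of-town
noise), patching stratum coverage so every age-gender cell has an eligible
seed whenever the graph's degrees allow one.

What the generator does **not** emulate: degree heavy tails and hubs,
overlapping or nested communities, homophily between respondent covariates
and network position, bot accounts, and temporal network change. Passing
tests therefore demonstrate the correctness and calibration of the
machinery under a clean community-structured world, not the realism of any
particular empirical estimate.

## Numerical and reproducibility choices

* All randomized stages take explicit integer seeds; one global seed is
  expanded with `stage_seed()`, a counter-based mix kept exact in double
  precision and reduced modulo a 31-bit prime, so adding a town or stage
  never perturbs another's stream.
* Louvain community labels are canonicalized to first-appearance order over
  the sorted node vector, so equal groupings compare `identical()`.
* `fragmentation_index()` treats $Q_{\max}$ at or below machine epsilon as
  degenerate rather than dividing.
* Duplicate and self-loop edges are dropped silently on construction but
  counted on the returned object; edge files round-trip through a
  canonical (sorted within and across rows) representation.
* Probability clamping in the generator is logged; the default effects never
  clamp, so linearity of the aggregate model is exact.

## Problem sizes used in the validation suite

The package's own validation uses deliberately scaled designs: exhaustive
modularity cross-checks on 6–8-node graphs over all ≤3-block partitions;
Louvain recovery on 100-node four-block planted partitions (100 replicates);
a five-point between-community mixing grid at 50 replicates per point for
the monotonicity of mean $F$; effect recovery on 160 towns × 120 respondents
over 20 replicates (each planted slope within ±3 cluster-robust SEs);
type-I calibration at 40 towns × 50 respondents over 500 null replicates;
and crawl fidelity on 20 towns of 240 nodes comparing 6-seed against
18-seed merges. The `analysis/` workflow runs the full 166-town study shape
with 11–200 respondents per town. These sizes give stable Monte Carlo
behaviour while keeping a complete run of tests plus workflow in a few
minutes on a single core.

## Known limitations

* $F$ is conditional on the Louvain partition; a different heuristic (or
  resolution) yields a numerically different index. The stability analysis
  in `analysis/03_fragment.R` quantifies re-crawl variability, not
  algorithmic uncertainty.
* The BFS crawl oversamples high-degree nodes by construction; the package
  documents and asserts this bias rather than correcting it, since
  community structure is preserved better than other graph statistics under
  such sampling.
* Cluster-robust inference is asymptotic in the number of towns; with few
  towns (the six-town demonstration pipeline) coefficients are reported but
  their p-values deserve no weight.
* The linear probability model can in principle clamp; effect
  configurations far from the defaults should heed the clamping warning.
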