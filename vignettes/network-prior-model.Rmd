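---
title: "A calibrated network prior for rare-variant gene discovery"
author: "pgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A calibrated network prior for rare-variant gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgnet)
```

# The problem

Case/control exome studies of complex disease face a power problem: the
causal mechanism is spread over a set of genes, each gene carries only a
handful of rare coding variants, and single-gene tests rarely reach
significance. Protein–protein interaction (PPI) networks help, because
disease genes tend to cluster in them — but PPI networks are noisy and
incomplete, so treating the network as a hard structure imports its errors
into the result.

`pgnet` takes the middle road: the network enters a hierarchical
probabilistic graphical model only as a *calibrated prior*. Gene–gene edges
can raise a gene's posterior, but by construction they can never raise it
past a fixed ceiling (default 0.02), an order of magnitude below the
detection threshold (default 0.2). A gene is only ever *called* on the
strength of its own genotype evidence; the network can merely tip the
balance for genes that already have some.

# The model

For variants $i$, individuals $j$ and genes $g$, with observed genotype
counts $D_{ij} \in \{0,1,2\}$ and case/control labels $\mathrm{pheno}_j$:

* $X_i \in \{0,1\}$ — whether variant $i$ damages the protein
  (shared across individuals; uninformative prior $P(X_i{=}1) = 0.5$);
* $Y_{ij} = X_i D_{ij}$ — whether variant $i$ affects individual $j$
  (a deterministic link, instantiated only where $D_{ij} > 0$);
* $Q_{gj} \in \{0,1,2\}$ — dysfunction level of gene $g$ in individual
  $j$ (normal / partial, e.g. haploinsufficiency / complete);
* $H_g \in \{0,1\}$ — whether gene $g$ is disease associated
  (**the main output**; prior $\tau = 0.0025$);
* $G_{gj} = H_g Q_{gj}$ — whether gene $g$ is relevant *in* individual
  $j$.

The joint factorizes as
$P(X, G, H, Q, \mathrm{pheno} \mid D) \propto
P(\mathrm{pheno}\mid G)\, P(G \mid H, Q)\, P(Q \mid X, D)\, P(X)\, P(H)$,
with factor tables:

* $\phi_2(Q \mid \mathbf{Y})$: mode at $S = \min(2, \sum_i Y_{ij})$ with
  mass $1 - \epsilon_Q$ ($\epsilon_Q = 0.01$), leak split over the other
  two states. The leak keeps every message strictly positive, which loopy
  BP needs. This near-deterministic capped-sum table is this package's
  parametrization of the aggregation step; it is one of the two places
  where a published model left the exact form open (see *Design choices*).
* $\phi_3(G, H, Q) = \mathbf{1}[G = H\,Q]$ — exact indicator: a gene can
  be relevant in a patient only if it is relevant overall *and*
  dysfunctional in that patient.
* $\phi_4(\mathrm{pheno} \mid c)$, a noisy-OR in the number
  $c = \#\{g : G_{gj} \ge 1\}$ of relevant genes:
  $P(\mathrm{case} \mid c) = 1 - (1 - \epsilon_{bg})(1 - p)^c$ with
  penetrance $p = 0.7$ per active gene and background (phenocopy) rate
  $\epsilon_{bg} = 0.01$. Patients should have some affected genes,
  controls few or none; both knobs are disease-dependent parameters.
* $\rho(k) = \gamma^k$ ($\gamma = 0.9$), a cardinality penalty on the
  number of active genes, encouraging sparse mechanisms.
* $\Theta$, the directed pairwise network priors described next.

# The calibrated network prior

Every gene starts from the small prior $\tau$. The largest evidence the
network may contribute, $M_c$, is defined by requiring that prior plus
maximal contribution land exactly on the ceiling $c_0 = 0.02$:

$$\frac{\tau}{1-\tau}\cdot\frac{M_c}{1-M_c} = \frac{c_0}{1-c_0},$$

```{r}
maxContribution(PriorConfig())   # 399/448 at the defaults
```

For each ordered pair of interacting genes $(j \to i)$ there is one
*directed, asymmetric* factor: $P(H_i{=}1 \mid H_j{=}0) = 0.5$
(an inactive neighbour says nothing) and $P(H_i{=}1 \mid H_j{=}1) =
\delta$. The strength $\delta$ is set by the degree $d$ of the *target*:
a neighbourhood is significantly enriched when the number $a$ of active
neighbours is binomially improbable under the null,
$P(\mathrm{Bin}(d, \tau) \ge a) \le 0.05 / N_\mathrm{genes}$, and
$\delta$ solves $(\delta/(1-\delta))^{a_{\min}} = M_c/(1-M_c)$: exactly
$a_{\min}$ active neighbours contribute exactly $M_c$. Higher-degree
genes need more active neighbours, so hubs get a smaller $\delta$ and
cannot be lit up by bulk weak signal.

```{r}
minActiveNeighbours(c(10, 100))
deltaForDegree(c(10, 100))
```

$\delta$ is additionally capped at 0.9 so that even a sole neighbour has
bounded influence, and during inference the *sum* of incoming network
log-odds into each gene is re-capped at $\log(M_c/(1-M_c))$ on every
sweep — calibration fixes what a just-significant neighbourhood may say,
the runtime cap handles neighbourhoods that turn out more active than
that. Second-order interactions (neighbours of neighbours) enter by
running the same construction on the distance-2 closure of the network,
with no extra decay for distance-2 pairs (the closure keeps the capping
algebra uniform; whether the original construction down-weighted them is
unknown, and this is the simpler choice).

Two further conventions close the low-degree corner: the binomial upper
tail is taken as zero for counts exceeding the degree, so for degrees
where no count up to $d$ reaches significance (d = 1, 2 at the defaults)
$a_{\min} = d + 1$ and $\delta$ stays moderate; and the tail is computed
exactly (no approximation), keeping $a_{\min}$ integer-stable.

# Inference

Marginals come from loopy belief propagation with damping
$\alpha = 0.5$ (convex combination in probability space — this keeps
damped messages normalized by construction; log space would need
renormalization). Messages are stored as normalized rows or log-odds;
beliefs are aggregated in log space.

The schedule is two-tier: the variant-tier messages (X, Y, Q) are the
most numerous and the slowest to change, while the gene/phenotype tier
(G, H, pheno, network priors, cardinality prior) is tightly coupled and
fast-moving. Each outer sweep therefore updates the variant tier once and
then iterates the gene tier up to 10 times or until its marginals move
less than `innerTol`. Convergence is declared on *marginals* (they are
the output contract), not raw messages, at `convergenceTol = 1e-4`; the
outer loop is capped at 200 sweeps. Update order is fixed (variants in
input order, genes lexicographically), making every fit bit-reproducible.

Three factors touch many variables but depend only on a sum, and are
handled as counting factors:

* the phenotype factor $\phi_4$ over all of an individual's G variables,
* the cardinality prior $\rho$ over all H variables,
* the aggregation factor $\phi_2$ over a gene's carried variants.

`countingFactorMessages()` implements the generic binary sum tree
(internal nodes hold distributions over partial sums; FFT convolutions
above a size cutoff give $O(n \log^2 n)$ total work), with
`countingFactorMessagesNaive()` as the quadratic reference. Inside the
engine two exact simplifications replace the generic machinery: the
geometric $\rho$ factorizes into per-gene unaries
($\gamma^{\sum h} = \prod_g \gamma^{h_g}$), and the noisy-OR $\phi_4$
decomposes as $1 - A r^c$, a difference of two log-linear terms, giving
closed-form leave-one-out messages in $O(n)$ per individual. Both
identities are asserted against the generic tree and naive
implementations to $10^{-12}$ in the test suite, so the generic
operations remain first-class, tested code.

Directed network factors send messages *one way only*: toward their
target, computed from the source gene's belief; the message toward the
source is uniform. This is the point of the directed construction — a
gene must not be pushed down because its neighbours are off. Because
exact leave-one-out across the runtime cap is ill-defined, the message a
source sends along $j \to i$ excludes the reverse edge's contribution
from the uncapped sum before re-capping, which prevents two-gene
feedback at the cap.

## Accuracy, measured

The engine is compared against exhaustive enumeration of the joint
(`exactMarginals()`, the brute-force oracle) in the test suite:

* On tree-structured fixtures BP is exact; agreement is asserted at
  $10^{-6}$ and measured at $\sim 10^{-11}$.
* On small loopy fixtures (loops from variants shared between
  individuals — the loop type rare-variant cohorts actually produce)
  gene marginals agree within 0.02. The variant tier carries a larger
  intrinsic error, up to $\sim 0.065$ on adversarial fixtures in which
  every individual shares variants with every other; gene marginals
  there reach $\sim 0.03$. These are fixed-point properties, not
  schedule artifacts: the same values are reached for damping weights
  0–0.8 and inner-loop depths 1–50. The bounds asserted in the tests are
  the measured ones; loopy BP is approximate and the tolerance is
  documented rather than hidden.
* Enumeration multiplies *both* directed tables of each gene pair, which
  penalizes a gene whose neighbour is off — exactly what the one-way
  message flow is designed not to do. Fixtures with network edges are
  therefore tested against the directed prior's own contracts (neighbour
  clamped off leaves the focal gene at its prior; neighbour clamped on
  gives positive but capped evidence; the ceiling holds under exhaustive
  neighbour-state enumeration) rather than against enumeration.

# The simulator

`simulateScenario()` generates the study conditions end to end:

1. **Genotypes.** Allele frequencies are drawn from a bounded Pareto
   spectrum on $[1/(2N), 0.01]$ with shape 0.25 — a rare-skewed site
   frequency spectrum in which the vast majority of variants are rare —
   and genotypes per individual as $\mathrm{Bin}(2, f)$ under
   Hardy–Weinberg. Defaults: 1000 genes, Poisson(30) variants per gene,
   population of 20000. A fifth of variants are labeled harmful,
   standing in for a selection-coefficient cutoff: the coefficient plays
   no further role downstream, only the label does.
2. **Causal set.** Drawn from the joint first/second-degree
   neighbourhood of a random seed gene (the neighbourhood must exceed
   the requested set size), or by topology: the periphery of a star
   (center excluded), a fraction of the largest clique, or a chain grown
   under four rules (adjacent to the last pick; no edges to earlier
   picks except the last; lowest-degree candidates preferred; internal
   picks need degree ≥ 2).
3. **Phenotypes.** Each individual's burden is the allele count over
   harmful variants in causal genes; the top 1000 burdens are the
   patient subpopulation (ties broken by id), from which n/2 cases are
   drawn against n/2 healthy controls. The 1000 is the package's scaling
   of a much larger published design (3000 patients out of 900000) to a
   20000-individual population, kept large enough that 400-case cohorts
   are drawable.

The a-priori power reasoning behind the spectrum shape: with shape 0.25
the mean allele frequency is $\sim 10^{-3}$, so a 10-gene mechanism with
$\sim 60$ harmful variants gives an expected causal burden of
$\sim 0.2$ alleles per individual — a diseased subpopulation dominated
by single-allele carriers, with heavy-tailed variation across genes.
Some causal genes end up easy (many carriers), some hard (few), which is
the regime where a network prior should, and in the benchmark does, beat
per-gene testing without either method saturating.

What the simulator does *not* emulate: linkage disequilibrium, realistic
demography (the population-genetic forward simulation this stands in for
is far beyond desk scale), covariates, common variants, and any
correlation between harmfulness and frequency. Passing benchmarks
therefore show that the model recovers network-clustered sparse
mechanisms from rare-variant burden signal under Hardy–Weinberg
independence — not that it is robust to stratification or LD.

`generateSyntheticNetwork()` provides the gene graph: a
preferential-attachment core (heavy-tailed degrees, so the
degree-dependent $\delta$ is exercised) with a planted 36-clique, a
50-leaf hub star and a 30-gene low-degree path so that every topology
sampler has its substrate. It is a synthetic stand-in for a real PPI
network, which is an external resource.

# Problem sizes and runtime

The shipped benchmark (`runBenchmark()`) uses 5 replicates of: 1000-gene
network, 10 causal genes, 400 cases + 400 controls sampled from a
population of 20000 — roughly 12000 segregating variants per cohort.
One fit converges in ~20–40 outer sweeps, about 15 s; a full benchmark
replicate (simulate + fit + baseline) runs in ~20 s. The exhaustive
oracle is used only on fixtures with at most a few thousand joint
configurations.

# Design choices and limitations

* The exact published forms of the aggregation ($\phi_2$) and phenotype
  ($\phi_4$) tables were not available; the capped-sum CPT and the
  noisy-OR are this package's parametrizations, chosen to be monotone,
  strictly positive, and functions of a count (which the counting-factor
  machinery requires). They are replacements, not reproductions, and
  both are exposed as configuration.
* $\phi_4$ counts a gene once whether $G = 1$ or $G = 2$; whether the
  original design distinguished them is unknown.
* The cardinality prior is geometric — log-linear penalties compose
  exactly with sum-tree message passing and add one interpretable knob.
* Per-variant harmfulness priors are fixed at 0.5; a per-variant prior
  hook exists in the model configuration but informed priors
  (e.g. from damage predictors) are future work.
* Only first- and second-order network context is used; genes further
  apart do not interact in the prior. Mechanisms that are near but not
  tightly interconnected in the network are the known weak spot.
* Isolated genes receive no pair priors (their posterior rests entirely
  on their data), matching the degree-$\ge 1$ domain of the calibration.
* The burden baseline is a carrier-level Fisher exact test — deliberate
  plumbing so benchmarks run self-contained, not a substitute for
  dedicated rare-variant association tests.
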