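# pgnet — network-prior graphical model for rare-variant gene discovery

`pgnet` identifies sets of genes driving a complex disease from
case/control coding-variant data. Instead of testing genes one at a time,
or diffusing summary statistics over a protein–protein interaction (PPI)
network, it models variants, genes and phenotypes jointly in a
hierarchical factor graph in which the network enters only as a
**calibrated prior**: interacting genes encourage each other, but the
network alone can never push a gene's posterior past a fixed ceiling
(0.02 by default, far below the 0.2 detection threshold). The method
returns posterior marginal probabilities per gene rather than a fixed
list, so uncertainty is carried through to the end.

It is aimed at statistical geneticists and methods developers working on
rare-variant association in complex disease who want network evidence
with explicit false-positive guarantees, plus a self-contained simulator
to benchmark against.

## The model

For variant $i$, individual $j$, gene $g$, with genotypes
$D_{ij} \in \{0,1,2\}$ and labels $\mathrm{pheno}_j$:

$$P(X,G,H,Q,\mathrm{pheno}\mid D)\ \propto\
P(\mathrm{pheno}\mid G)\,P(G\mid H,Q)\,P(Q\mid X,D)\,P(X)\,P(H)$$

where $X_i$ flags damaging variants, $Q_{gj}\in\{0,1,2\}$ is the
dysfunction level of gene $g$ in individual $j$, $H_g$ is the
gene–disease indicator (the output), $G_{gj}=H_g Q_{gj}$ its per-patient
relevance, and $P(\mathrm{pheno}\mid G)$ is a noisy-OR in the number of
relevant genes. $P(H)$ combines a small per-gene prior
$\tau = 0.0025$, a sparsity cardinality penalty $\gamma^k$, and directed
degree-calibrated pair factors from the network: the pair strength
$\delta$ solves $(\delta/(1-\delta))^{a_{\min}} = M_c/(1-M_c)$, where
$a_{\min}$ is the smallest binomially-significant number of active
neighbours for the gene's degree and $M_c$ is the maximal contribution
satisfying $\frac{\tau}{1-\tau}\cdot\frac{M_c}{1-M_c}=\frac{0.02}{0.98}$.
Aggregated network evidence is additionally capped at $M_c$ during
inference. Marginals are computed by damped loopy belief propagation
(α = 0.5) with a two-tier schedule and $O(n\log^2 n)$ counting-factor
messages. The methods vignette
(`vignettes/network-prior-model.Rmd`) derives all of this.

## Worked example

Simulate a disease scenario on a synthetic scale-free network (200 genes,
5 causal genes drawn from one network neighbourhood, 100 cases + 100
controls sampled from a population of 4000), fit the model, and score the
recovery:

```r
library(pgnet)

net <- generateSyntheticNetwork(200, seed = 7, cliqueSize = 10,
                                starLeaves = 12, pathLength = 10)
sc  <- simulateScenario(net,
           PopulationConfig(nGenes = 200, nIndividuals = 4000,
                            variantsPerGene = 10),
           P = 5, n = 200, topK = 200, seed = 7)
sc
#> DiseaseScenario (neighbourhood): 5 causal genes; cohort 200 individuals x 764 variants

fit <- fitNetworkModel(sc@cohort, net)
fit
#> MarginalTable over 200 genes, 764 variants; converged after 24 sweeps
#> top genes: g0014=1.000, g0058=1.000, g0086=1.000, g0146=1.000, g0160=0.999

sc@causalGenes
#> [1] "g0014" "g0058" "g0086" "g0146" "g0160"

cm <- confusionMetrics(detectAtThreshold(fit)$detected, sc@causalGenes)
cm[c("tp", "fp", "fn", "sensitivityPct", "precisionPct")]
#> $tp: 5   $fp: 0   $fn: 0   $sensitivityPct: 100   $precisionPct: 100
```

The five genes with posterior ≈ 1 are exactly the five simulated causal
genes; every other gene stays near its prior. `detectAtThreshold()` calls
genes at marginal ≥ 0.2 (suggestive band ≥ 0.05), `topPSelection()`
ranks instead, and `burdenBaseline()` provides a carrier exact-test
baseline for comparison. `runBenchmark()` wraps the whole
simulate/fit/score loop over replicates.

A command-line front end over the same functions is installed at
`inst/scripts/pgnet.R` with subcommands `run`, `simulate` and
`evaluate` (YAML config, TSV in/out).

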