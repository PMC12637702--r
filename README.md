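# bncoherence

Stability analysis of synchronously updated Boolean gene-regulatory
networks, for researchers who model phenotypes as attractors. Classical
robustness measures average over all states of a network, yet a cell spends
its life *at* an attractor — so this package separates three quantities and
measures the tension between them:

- **basin coherence** ψ<sub>B</sub> — the mean probability, over all states
  of a basin of attraction, that a single-gene flip leaves the system in the
  same basin;
- **attractor coherence** ψ<sub>A</sub> — the same probability averaged only
  over the attractor's own states;
- the **coherence gap** ΔAUC = AUC:BC − AUC:AC — the difference between the
  areas under the binned conditional curves E[ψ<sub>B</sub> | s] and
  E[ψ<sub>A</sub> | s] of relative basin size s, with 0.5 the
  fully-random baseline.

For a state x of a network F with basin map D<sub>F</sub>,

ψ<sub>x</sub> = (1/N) Σ<sub>i</sub> 1[D<sub>F</sub>(x) = D<sub>F</sub>(x ⊕ e<sub>i</sub>)],

and ψ<sub>B</sub>, ψ<sub>A</sub>, ψ<sub>F</sub> average ψ<sub>x</sub> over a
basin, an attractor, and the full state space. Alongside the coherence
machinery the package provides canalization analytics (canalizing
variables, layer structure, canalizing depth, nested canalizing functions,
bias and average sensitivity), random-network ensembles stratified by
degree, depth or NCF layer structure, Monte-Carlo basin estimation for
large models, BoolNet-style rule-file IO, and a null-model pipeline for
curated biological networks with source-node fixing and paired stability
tests.

## Worked example

Two 3-node networks with *identical* basin structure but opposite attractor
stability:

```r
library(bncoherence)

F <- network(fixtureF())   # (x1|x2|x3, x1&(x2|x3), !x1&!x2&!x3)
attractorRecords(F, networkId = "F")
#>   network_id attractor_key period relative_basin_size basin_coherence attractor_coherence exact_flag
#> 1          F           100      1               0.625       0.6666667           0.3333333       TRUE
#> 2          F           110      1               0.375       0.4444444           0.3333333       TRUE

G <- network(fixtureG())   # (x1&(x2|x3), x1&(x2|x3), x1|(x2&x3))
attractorRecords(G, networkId = "G")
#>   network_id attractor_key period relative_basin_size basin_coherence attractor_coherence exact_flag
#> 1          G           000      1               0.625       0.6666667           1.0000000       TRUE
#> 2          G           111      1               0.375       0.4444444           0.6666667       TRUE

networkCoherence(F, basinDecomposition(F))   # 14/24 for both networks
#> [1] 0.5833333
```

Both networks have fixed-point basins of sizes 5 and 3 (relative sizes
0.625 and 0.375) with basin coherences 2/3 and 4/9, so their overall
robustness is identical — yet in F a perturbation of either attractor
escapes its basin 2 times in 3 (ψ<sub>A</sub> = 1/3), while G's major
attractor is unconditionally stable (ψ<sub>A</sub> = 1). Ensemble versions
of this comparison:

```r
res <- runEnsemble(ensembleSpec(nNodes = 12, inDegree = 3,
                                ruleClass = "ncf", size = 1000, seed = 1))
res
#> EnsembleSpec: 1000 networks, 12 nodes, in-degree 3, rules ncf, seed 1
#>   3480 attractor records; AUC:BC 0.7585 (+51.7%), AUC:AC 0.7061, gap 0.0524
```

Nested canalizing rules lift basin coherence ~52% above the random
baseline, but the attractor curve rises less — canalization stabilises the
journey more than the destination.

## Command-line use

Thin wrappers over the same functions live in
`system.file("cli", package = "bncoherence")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ensemble.R", package="bncoherence"))')" \
    --n-nodes 12 --degree 3 --rule-class ncf-layer --layer-structure 1-2-2 \
    --size 1000 --seed 7 --out records.tsv --summary summary.json
```

`bio.R` analyses a directory of `.bnet` rule files against matched null
models; `fixtures.R` exports the worked examples with expected-value
sidecars.

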