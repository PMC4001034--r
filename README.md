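# csagen

Declarative generation of neuronal-network connectivity in R: the
connection-set algebra (CSA) as lazy, possibly-infinite expressions, plus
the generic connection-generator iteration protocol that lets any
simulator-like consumer stream the concrete connections out — including
per-rank partitioning for parallel simulators, an XML serialization
dialect with a pluggable parser registry, a mock simulator kernel, and a
command-line tool that materializes edge lists and runs connection-count
scaling benchmarks.

## Who this is for

Computational neuroscientists (and anyone wiring large graphs) who want to
*describe* connectivity — "random Erdős–Rényi at p = 0.1, without
self-connections, with distance-dependent delays" — independently of any
simulator, population size or process layout, and then have that
description realized reproducibly, serially or partitioned over ranks.

## The algebra in one paragraph

A **mask** is a Boolean indicator `M(i, j)` over pairs of 0-based
source/target indices, possibly with infinite support: `delta()` is the
one-to-one (diagonal) mask, `random_mask(p, seed)` an infinite matrix of
independent Bernoulli(p) realizations, `cross_mask(S, T)` the Cartesian
product of two index sets, plus explicit lists and the full mask.  Masks
combine with set operators (`&`, `|`, `-`).  A **connection-set**
`C = (M, V0, V1, ...)` attaches **value sets** `V_k(i, j) -> real` (weights,
delays, ...); its **arity** is the number of value sets.  Intersecting an
infinite expression with a Cartesian product cuts out the finite part:
`{0..6} x {0..6} ∩ δ` is the 7-element diagonal.  Random masks are
counter-based — membership is a pure hash of `(seed, i, j)` — so a
realization is a fixed set, identical across ranks, windows and machines.

## Worked example

```r
library(csagen)

# Erdős–Rényi at p = 0.1 without self-connections,
# constant weight 2.0 and a uniform random delay
er <- cset(random_mask(0.1, seed = 42) - delta(),
           vs_constant(2.0), vs_uniform(0.5, 1.5, seed = 7))

g <- connection_generator(er)
cg_set_mask(g, mask_spec(0:999, 0:999))   # cut to 1000 x 1000 indices
df <- cg_collect(g)
nrow(df)
#> [1] 99759
head(df, 3)
#>   source target value_1   value_2
#> 1      2      0       2 0.8128087
#> 2      9      0       2 0.9627839
#> 3     17      0       2 1.3017918
```

99,759 connections against an expectation of `0.1 * (1000^2 - 1000) =
99,900` (within one standard deviation, ±300); every stream is sorted
target-major, and `value_1`/`value_2` carry the weight and delay.  The
mock kernel translates indices to simulator GIDs and emulates a parallel
run — the stored connection set is independent of the rank count:

```r
net <- network()
cg_connect(net, g, population(1001:2000), population(1001:2000),
           param_map = c(weight = 0, delay = 1), n_ranks = 4)
network_stats(net)$n_connections
#> [1] 99759
```

Connection counts scale as the expressions promise — slope 2 on a log-log
plot for the random mask, slope 1 for one-to-one:

```r
bench_population_scaling("random", c(100L, 1000L, 10000L), p = 0.1, seed = 0)
#> Connection-count benchmark (random, p = 0.1, seed = 0)
#>      n   count seconds
#>    100    1023   0.002
#>   1000  100057   0.034
#>  10000 9997332   2.325
#> count slope (ratio of logs, last/first): 1.9950
```

Expressions serialize to XML (`serialize_csa()` / `from_xml()`), with
seeds embedded so a document reproduces identical connectivity anywhere;
the dialect is documented in `inst/xml-dialect.md`.  The command-line tool
wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","csagen.R",package="csagen"))')" \
  build --expr random --p 0.1 --seed 42 --sources 0:1000 --targets 0:1000 \
  --ranks 4 --out edges.tsv
```

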