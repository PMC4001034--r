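---
title: "Declarative connectivity with the connection-set algebra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declarative connectivity with the connection-set algebra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csagen)
```

## The model

A network's wiring is a set of edges between a source population $P_s$ and a
target population $P_t$, each population enumerated by consecutive
non-negative indices starting at 0.  A **connection-set**

$$C = (M,\, V_0, V_1, \dots)$$

couples a **mask** $M$ — a Boolean indicator $M(i, j)$ over index pairs
stating which connections exist — with zero or more **value sets**
$V_k(i, j) \in \mathbb{R}$ that attach a parameter (weight, delay, time
constant, ...) to every connection.  The number of value sets is the
connection-set's **arity**; an arity-0 connection-set is interchangeable
with its mask, and `csagen` treats them identically everywhere.

Masks may have *infinite* support.  That is the key abstraction: the
one-to-one mask $\delta$ ($i = j$) encodes the concept of self- or
one-to-one connectivity without reference to any population size, and the
random mask $\rho(p)$ is an infinite matrix of independent Bernoulli($p$)
realizations — Erdős–Rényi connectivity as a fixed set rather than a
sampling procedure.  Expressions combine masks with the set operators
$\cap$, $\cup$ and $-$ (in code: `csa_intersect()`, `csa_union()`,
`csa_difference()`, or the overloaded `&`, `|`, `-`).  Intersecting with
the Cartesian product of two finite index sets (`cross_mask()`) cuts a
finite connection matrix out of an infinite structure:

```{r}
cut <- csa_intersect(cross_mask(0:6, 0:6), delta())
g <- connection_generator(cut)
cg_set_mask(g, mask_spec(0:99, 0:99))
nrow(cg_collect(g))          # 7 connections on the diagonal
no_self <- random_mask(0.1, seed = 42) - delta()
```

Everything is lazy: an expression is a tree of indicators, and the only
ways to materialize connections are membership queries and windowed
iteration.

## Why the random mask is counter-based

$\rho(p)$ must behave as a *set*: the same pair queried twice — or queried
by two different parallel ranks, or inside two different windows — must
give the same answer.  A conventional stream RNG cannot provide this
without coordinating state across consumers.  `csagen` therefore derives
membership from a stateless avalanche hash (the splitmix64 finalizer)
applied to the counters `(seed, stream, i, j)` and mapped to $(0, 1)$; the
pair is present iff that uniform deviate is `< p`.  Consequences:

* two expressions with equal `(p, seed)` denote the identical infinite
  mask (this equality is deliberate and documented);
* partitioning targets over ranks, restricting windows, or re-iterating
  never changes a realization — the multiset union over ranks equals the
  serial stream exactly, which the test suite checks exhaustively;
* random *value* sets (`vs_uniform()`, the noise term of
  `vs_distance_delay()`) use the same construction on separate hash
  streams, so mask membership and values never share deviates.

The uniform deviate is centered in its bin, $u = (h_{53} + 1/2) \cdot
2^{-53} \in (0,1)$, so $u < p$ has probability $p$ to within $2^{-53}$ and
$u$ is never exactly 0 (which matters when the deviate is pushed through
$\Phi^{-1}$ for Gaussian noise).

## Tunable parameters

* `p` — inclusion probability of `random_mask()`, dimensionless in
  $[0,1]$.  No default: it is the scientific quantity under study.
* `seed` — non-negative integer; defaults to 0 everywhere and is mandatory
  in serialized form, so any XML document reproduces bit-identical
  connectivity on any machine.
* `vs_distance_delay(pos_s, pos_t, velocity, base, sigma, lo, hi, seed)` —
  delays $V(i,j) = \mathrm{base} + \lVert x_i - y_j \rVert / \mathrm{velocity}
  + \mathrm{clip}(\mathcal{N}(0, \sigma),\, lo,\, hi)$.  `velocity` is in
  distance units per time unit, `base` and the clip bounds in the delay's
  time units.  Defaults `sigma = 0, lo = hi = 0` disable the noise.
  Positions come from tables (`read_positions()`: TSV with `id, x, y[, z]`,
  ids being 0-based population indices) or from arbitrary functions;
  function-backed positions cannot be serialized.

## The generator protocol

A `connection_generator` is modeled on a projection between populations.
The consumer announces the available indices with `cg_set_mask()` — or, on
a parallel simulator, `cg_set_masks(list_of_windows, local_rank)`, where
every rank passes *all* ranks' windows so a generator may skip non-local
work — then calls `cg_start()` and `cg_next()` until `NULL`.  Design
points, each pinned by a test:

* **Order** is target-major: streams ascend strictly in `(target, source)`,
  all sources iterated per target, matching how simulator kernels build
  per-target connection lists.
* **`cg_size()`** returns the exact count when it is knowable without
  iteration (explicit lists; one-to-one, Cartesian-product and full masks
  cut by interval windows) and the sentinel `-1` otherwise; a non-negative
  return is never wrong.  `-1` was chosen because the protocol's integer
  return type admits no missing value.
* **`cg_start()` is restartable** (it resets the cursor); changing masks
  mid-iteration is an error, after exhaustion it is allowed.
* **Overlapping target windows** across ranks warn rather than fail —
  disjointness is the typical contract, not a hard requirement; the
  warning is detected by a single sorted sweep over all ranks' intervals.
* Row evaluation is vectorized per target (the random-mask row scan runs
  in C++), so `cg_collect()`/`cg_count()` avoid per-connection overhead
  while `cg_next()` retains the one-at-a-time protocol semantics.

## Serialization and the parser registry

Expressions serialize to a purpose-built XML dialect (root tag `CSA`,
documented in `inst/xml-dialect.md`); the historical MathML-based schema is
not reconstructible and was not attempted.  Real attributes are written
with 17 significant digits so round-trips are bit-exact; the suite checks
stream equality of 100 random expressions after a round trip.  Parsing
dispatches on the document's root tag through a registry
(`select_cg_implementation(tag, library)`); plugins register in-process
(`register_cg_library()`), re-binding a tag warns and replaces (last
registration wins), and unknown elements are rejected rather than
dropped.  `from_xml()` returns a generator with masks *unset* — the
consumer, not the document, knows its windows.

## The mock kernel

`cg_connect(net, g, pre, post, param_map, n_ranks)` emulates a parallel
simulator in-process: GIDs are mapped to 0-based indices in user-list
order (the list order is the contract; contiguous-range compression via
`interval_set_from_ids()` is an optimization), targets are distributed
round-robin (`rank_of_target(j, R) = j mod R`, injectable for other
layouts), each rank's stream is drained through the public protocol, and
connections are stored as `(source GID, target GID, named parameters)`
with names taken from `param_map`.  Per-rank chunks are concatenated in
rank order, so the stored table is deterministic; the *set* of connections
is independent of `n_ranks` by construction, and tests assert it including
parameter values.  Arbitrary arities are supported; `strict_arity = TRUE`
reproduces the historical kernel restriction to arities 0 and 2 for
fidelity testing.  Repeated identical pairs are stored as multi-edges and
flagged by `network_stats()` rather than deduplicated.

## Benchmarks and the sizes used

The benchmarks measure *connection counts*, whose scaling exponents are
hardware-independent: wall-clock times are recorded but never asserted.
Slopes use the ratio-of-logarithms convention between the last and first
point, $\log(C_\mathrm{last}/C_\mathrm{first}) /
\log(x_\mathrm{last}/x_\mathrm{first})$.  The random mask at fixed $p$
creates $O(n^2)$ connections (expected count slope 2); the one-to-one mask
$O(n)$ (slope exactly 1).  The test suite evaluates the random-mask slope
between $n = 100$ and $n = 10{,}000$ ($10^8$ candidate pairs, about a
second through the C++ row scan) and runs the strong-scaling invariants —
per-rank counts summing exactly to the serial count for rank counts up to
48 — at $n = 4{,}800$, where the expected count is $0.1 \cdot 4800^2
\approx 2.3$ million.  These sizes exercise the same asymptotics as
published experiments an order of magnitude larger while keeping the suite
fast; nothing in the implementation is size-specific.

CLI range specifications are half-open (`"0:7"` means indices 0–6),
matching common tooling; internally all windows are closed intervals, and
the conversion is tested.

## What the generated data do and do not show

All inputs here are synthetic by nature — the algebra *is* the generative
model, and the worked examples (the six-pair mask, the 7-element diagonal
cut, $\rho(0.5) - \delta$) are fixed by construction.  Passing tests
demonstrate set-theoretic correctness, determinism, partition invariance
and the count asymptotics.  They do not demonstrate wall-clock performance
of a C++ simulator pipeline, real MPI communication behavior, or fidelity
to any biological connectivity data.

## Known limitations

* Value sets cannot be combined under set operators; they attach only at
  the top of an expression.  Merge semantics under $\cup$ of two
  parameterized operands are genuinely ambiguous, so the restriction is
  enforced with an error instead of a guess.
* The elementary-set inventory is $\delta$, $\rho(p)$, Cartesian products,
  explicit lists and the full mask; fan-in/fan-out and block masks, and
  geometric masks beyond the Euclidean distance-delay value set, are out
  of scope.
* Ranks are emulated sequentially in one process; no communicator is
  passed through the interface, and strong-scaling *timings* are therefore
  informational only (emulated ranks add overhead instead of removing it).
* Only real-valued connection parameters are supported; integer parameters
  travel as doubles.
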