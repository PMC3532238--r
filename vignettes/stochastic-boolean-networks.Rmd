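---
title: "Stochastic Boolean networks: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic Boolean networks: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbnet)
```

## The model

A probabilistic Boolean network (PBN) describes `n` genes with binary
expression states. Gene `i` is updated by one of `l(i)` Boolean predictor
functions `f_j^i`, each chosen independently per transition with selection
probability `c_j^i` (summing to 1 per gene). A joint choice across genes
selects one of `N = prod(l(i))` constituent Boolean networks, with
probability `P_j = prod_i c_{j(i)}^i`; the dynamics are therefore a Markov
chain on the `2^n` joint states, with a row-stochastic transition matrix
`A`. Three extensions are covered:

* **Random gene perturbation.** At each transition every gene flips
  independently with probability `p`; when at least one gene flips
  (probability `1-(1-p)^n`), the flip *replaces* the Boolean update. This
  makes the chain ergodic, so a unique stationary distribution exists.
* **Deterministic-asynchronous updating (DA-PBN).** Each gene carries a
  fixed updating period and changes state only at multiples of it;
  functions are redrawn independently at every update event and applied to
  the full pre-update state.
* **Stochastic (bitstream) realization — the SBN.** Probabilities are
  encoded as the fraction of 1's in random binary sequences of length `L`.
  Each gene's candidate functions are evaluated position-wise on the
  present-state streams, and a stochastic multiplexer, driven by a control
  sequence distributed as `(c_1^i, ..., c_{l(i)}^i)`, picks the applied
  function per bit position. Decoding the joint output streams of one run
  yields an entire transition-matrix row at once, so the full matrix costs
  `O(n L 2^n)` — crucially independent of `N`, which grows exponentially
  in `n`.

The analytic route exploits the independence of the PBN: each row of `A`
factorizes into per-gene marginals `P(x_i' = 1 | s)`, computed in
`O(n 2^n)` per row, and equals the brute-force mixture `sum_j P_j A_j`
(both are verified against each other in the test suite).

## Perturbation convention

The closed form used by `perturbed_transition_matrix()` is

```
Atilde[s,s'] = (1-p)^n A[s,s'] + [s' != s] p^H(s,s') (1-p)^(n - H(s,s'))
```

with `H` the Hamming distance. This corresponds to perturbation bits that
are i.i.d. Bernoulli(`p`), with the all-zero pattern routed to the Boolean
update. The convention is not the only conceivable one (e.g. a uniform
distribution over non-zero flip patterns would also yield total flip
probability `1-(1-p)^n`), but it is the one the bitstream wrapper
implements physically — `n` independent perturbation streams, XOR with the
present state, an `n`-input OR as the bus-multiplexer control — and the
two routes are held to agree by a distinguishing test at `p = 0.2` that
separates the two conventions by many standard errors. Rows of the
perturbed matrix sum to 1 analytically, and the diagonal obeys
`Atilde[s,s] = (1-p)^n A[s,s]` exactly.

## Bitstream kernel

Streams are *non-Bernoulli*: `make_bitstream(p, L)` places exactly
`round(p*L)` ones (ties to even) in uniformly random positions, and
`make_selector_stream()` fixes per-value counts by largest-remainder
apportionment of `probs * L` (ties broken by index order). Encoded values
therefore carry no sampling variance themselves, and circuit outputs have
variance at most that of i.i.d. Bernoulli sampling at equal `L` (verified
empirically for a two-gate circuit at `p = 0.1` and `0.5`, `L = 1000`,
200 replicates). Two practical consequences:

* a probability smaller than `1/(2L)` is not representable
  (`round(p*L) = 0`); a warning is emitted, which matters for small
  perturbation rates — use `L >= 1/(2p)`;
* fan-out shares the same physical stream, so reconverging paths remain
  exactly correlated; per-bit evaluation of a gate DAG coincides with
  truth-table evaluation, which is what makes the multiplexer selection
  exact in distribution.

Fresh selector and perturbation streams are drawn for every input state
and every time frame. Reusing streams across rows or frames would
correlate transitions and break the Markov semantics; the per-frame
regeneration is the choice consistent with an unbiased estimate of
`A^t`.

## Steady state and attractors

Two routes are provided and cross-checked:

* **Matrix iteration / eigen-analysis.** `iterate_distribution()` applies
  `d_t = d_0 A^t`; `stationary_distribution()` takes the dominant left
  eigenvector. Both are practical up to roughly `n = 12`–`14` (the matrix
  is `2^n` square).
* **Time-frame expansion.** The temporal iteration of the SBN is unrolled
  into identical copies connected in series; the state streams of frame
  `t` feed frame `t+1`, and the decoded distribution is monitored. This
  estimates the stationary distribution without ever forming the matrix,
  which is the route that scales to larger `n`.

**Convergence metric.** The change between decoded distributions is
measured in norm-infinity, with threshold `threshold` (default `1e-3`).
The sequence length should satisfy `L >= 100/threshold` so that the
stream resolution sits two orders of magnitude below the threshold; this
is enforced as a warning, not an error, because shorter streams are still
useful for exploration. Note that the *statistical* fluctuation of a
decoded entry is of order `sqrt(d(1-d)/L)`, which for small networks with
concentrated mass can exceed the threshold; in that regime convergence is
declared when the fluctuation band crosses the threshold, and the
returned distribution is accurate to sampling error rather than to the
threshold itself.

**Cycle detection.** Unperturbed networks may never satisfy a
successive-frame threshold (periodic orbits), so both
`time_frame_expansion()` and `detect_attractors()` search lags
`k = 1, ..., cycle_window` (default 10) and declare the smallest `k`
whose lag-`k` norm-infinity difference falls below the threshold on two
consecutive frames; the first detection wins. This single rule covers the
three behaviours that occur in practice: an ergodic chain with a positive
spectral gap converges monotonically and reports period 1; a genuinely
periodic orbit reports its period (the 12-gene examples in the test suite
report period 3); and a damped oscillation — e.g. the two-gene p53–Mdm2
model, whose second eigenvalue is negative — is reported with the period
of its transient argmax cycle, which is exactly the oscillatory signature
of interest in that system. The reported states are the most probable
state of each phase at the detection point.

`pseudo_attractor_report()` post-processes a perturbed stationary
distribution: every state with probability at least `min_prob` (default
0.01) that is not an attractor is annotated with its nearest attractor(s)
by Hamming distance and the differing genes; ties report all nearest
attractors.

## State index conventions

Two conventions coexist in the field and both are first-class here,
because published state numbers use one while printed matrices use the
other. The `"matrix"` convention (package-internal: first-listed gene =
most significant bit, 0-based) orders a two-gene matrix 00, 01, 10, 11.
The `"eq10"` convention (gene `i` contributes `2^(i-1)`, 1-based) is the
coding under which the 12-gene T-cell network's published states 1730,
1224, 1768, 711 and 1736 are written; `encode_state()`,
`decode_state()` and `convert_state_index()` translate between them, and
every exported matrix or distribution carries a convention tag.

## The random-network generator

`generate_random_pbn()` defines the benchmarking conditions: per gene a
function count uniform on `1:4` (four being the typical upper bound for
the number of predictors of a real gene), gates drawn uniformly from
{BUFFER, NOT, AND, NAND, OR, NOR, XOR, XNOR} with inputs sampled without
replacement, and selection probabilities drawn from a symmetric
Dirichlet(1) — the uniform distribution on the simplex, chosen because no
more specific law is implied by "randomly generated" and symmetry is the
neutral default. These networks emulate the *combinatorics* of inferred
regulatory models (small in-degree, mixed activating/inhibiting logic,
few predictors per gene); they do not emulate degree heterogeneity,
canalyzing-function bias, or the correlated function choices of
context-sensitive PBNs, so tests passing on them certify the estimator's
statistics, not biological realism of any particular network.

## Numerical choices

* **Norm 2** of a matrix difference is the spectral norm (largest
  singular value). For the published two-gene example the difference
  matrix is rank one, where spectral and Frobenius norms coincide — the
  test suite checks both readings against the printed value.
* Selection probabilities must sum to 1 within `1e-9`; violating inputs
  are rejected rather than silently renormalized, since renormalization
  hides data errors.
* `min_sequence_length()` scans the sequence-length grid in steps of 10
  from below with 5 repetitions per point (median), mirroring how the
  minimum-length benchmarks are tabulated; a cap (default 20000) returns
  a flagged result instead of searching forever.
* Genes due simultaneously in a DA-PBN update synchronously from the
  pre-update state; the staged (asynchronous) SBN is built per the update
  schedule over one macro period (the LCM of the periods), buffering the
  genes not due. Perturbation of a staged network is rejected: the
  asynchronous model is defined without a perturbation term, and
  inventing an interleaving would not be grounded.
* Truth-table rows enumerate a function's inputs in binary with the
  first-listed input varying slowest.

## Problem sizes used in the tests

The suite works at deliberately modest scale so that every statistical
check re-runs from scratch: exact-vs-enumeration equivalence on 50 random
networks with `n <= 4` (tolerance `1e-12`); bitstream fidelity at
`L = 10^4` (20 seeds) and `L = 10^5`; unbiasedness over 100 seeds at
`L = 1000`; the `L^(-1/2)` error law across `L = 10^3, 10^4, 10^5`
(log–log slope within `-0.5 ± 0.15`); steady-state agreement between the
time-frame, iteration and eigenvector routes on the two-gene model at
`L = 10^5`; and the full `n = 12` (4096-state) pipeline on a synthetic
network with a designed period-3 orbit. The published 12-gene T-cell
truth tables are supplementary data of the source study and are not
redistributed here; `load_tcell_network()` accepts that file and the
analysis functions reproduce its published orbit and pseudo-attractor
analysis once it is supplied.

## Known limitations

* Exact matrices and eigen-analysis are limited to roughly `n <= 14` by
  memory; beyond that only the time-frame route applies.
* Only independent PBNs are supported — no context-sensitive switching,
  no inference from data, no intervention/control policies.
* The bitstream estimator's error is `O(L^(-1/2))`; probabilities below
  `1/(2L)` quantize to zero, so extreme rates need proportionally longer
  sequences.
* The reported cycle period under perturbation can reflect the damped
  transient or, at small `L`, stream noise; the returned distribution is
  the quantity with a guarantee (sampling error plus threshold).

## A worked example

```{r example}
model <- fixture_p53_mdm2()
A <- transition_matrix_exact(model)
round(A, 4)

At <- perturbed_transition_matrix(A, p = 0.01)
round(At, 4)

sbn <- build_sbn(model, perturbation = 0.01)
res <- time_frame_expansion(sbn, c(0, 0),
                            convergence_config(threshold = 1e-3, L = 1e5),
                            seed = 1)
res
round(stationary_distribution(At), 4)
```

The stationary mass concentrates on the states 10 (p53 on, Mdm2 off) and
01 (p53 off, Mdm2 on), and the transient from any definite state
alternates between them — the oscillatory p53–Mdm2 signature — while
random perturbation keeps a small probability on the remaining states.
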