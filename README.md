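# sbnet

Stochastic Boolean networks (SBNs) for gene regulatory network analysis.

## The problem

Probabilistic Boolean networks (PBNs) model a gene regulatory network as
`n` binary genes, each updated by one of several Boolean predictor
functions `f_j^i` chosen independently per transition with probability
`c_j^i`. A joint choice selects one of `N = ∏ l(i)` constituent Boolean
networks, so the dynamics form a Markov chain on the `2^n` joint states
with transition matrix

```
A = Σ_j P_j A_j ,   P_j = ∏_i c_{j(i)}^i .
```

`N` grows exponentially with `n`, which makes the direct computation of
`A` — and of the steady-state distribution that underpins perturbation
and intervention analysis — expensive for realistic networks.

An SBN sidesteps `N` entirely: probabilities are encoded as the fraction
of 1's in random bitstreams of length `L` (non-Bernoulli streams with
exactly `round(pL)` ones), each gene's candidate functions are evaluated
position-wise, and a stochastic multiplexer selects the applied function
per bit with the probabilities `c_j^i`. One run of the network decodes an
entire row of `A` at once, giving `O(n L 2^n)` for the full matrix, and a
time-frame-expanded SBN (identical copies chained in series) estimates
the stationary distribution without forming the matrix at all. Random
gene perturbation — every gene flips independently with probability `p`
per transition — is realized by XOR gates and an OR-controlled bus
multiplexer, and analytically by

```
Ã[s,s'] = (1-p)^n A[s,s'] + [s'≠s] p^H(s,s') (1-p)^(n-H(s,s')) ,
```

with `H` the Hamming distance. Deterministic-asynchronous PBNs (per-gene
update periods) are supported both as direct simulation and as a staged
SBN. The package is aimed at systems biologists studying attractor
structure, perturbation response and pseudo-attractors of logical GRN
models.

## A worked example: the p53–Mdm2 network

The bundled two-gene model (`fixture_p53_mdm2()`) encodes the
damage-response circuit in which p53 promotes Mdm2 expression and Mdm2
drives p53 degradation; each gene has four predictor functions with
selection probabilities 0.5/0.4/0.09/0.01.

```r
library(sbnet)
model <- fixture_p53_mdm2()
A <- transition_matrix_exact(model)
round(A, 4)
#>        00     01     10     11
#> 00 0.0099 0.0001 0.9801 0.0099
#> 01 0.0900 0.0100 0.8100 0.0900
#> 10 0.0900 0.8100 0.0100 0.0900
#> 11 0.2500 0.2500 0.2500 0.2500
```

Row "01" reads: from the state p53 = 0, Mdm2 = 1 the network moves to
"10" with probability 0.81, to "00" or "11" with 0.09 each, and stays
with probability 0.01 — the high-probability flow 01 → 10 → 01 is the
oscillation observed experimentally. The bitstream estimate of the same
matrix at `L = 10000` agrees to a few parts in a thousand:

```r
set.seed(1)
Ah <- sbn_transition_matrix(build_sbn(model), L = 10000)
c(norm1_diff(A, Ah), norm2_diff(A, Ah), norminf_diff(A, Ah))
#> 0.0032 0.0043 0.0076
```

With perturbation `p = 0.01` the chain becomes ergodic; the
time-frame-expanded SBN estimates its stationary distribution without the
matrix, and matches the dominant left eigenvector:

```r
At <- perturbed_transition_matrix(A, p = 0.01)
sbn <- build_sbn(model, perturbation = 0.01)
res <- time_frame_expansion(sbn, c(0, 0),
                            convergence_config(threshold = 1e-3, L = 1e5),
                            seed = 1)
res
#> Time-frame expansion: cycle of period 10 detected after 40 frame(s)
#>   (L = 100000, threshold = 0.001)
#>   top states: 10 (0.4237), 01 (0.3694), 00 (0.1035)
round(stationary_distribution(At), 4)
#>     00     01     10     11
#> 0.1042 0.3677 0.4238 0.1042
```

About 79% of the stationary mass sits on the two oscillation states 10
and 01. `detect_attractors()` reports cycles from matrix iteration (the
unperturbed model shows the period-2 argmax alternation between 10 and
01), and `pseudo_attractor_report()` annotates high-probability
non-attractor states of a perturbed steady state with their nearest
attractor and the genes in which they differ — for the published 12-gene
T-cell network (whose supplementary truth tables can be loaded with
`load_tcell_network()`), that analysis flags single-gene neighbours of
the three known attractors.

Networks are exchanged as JSON (`save_network()` / `load_network()`;
see `inst/extdata/p53_mdm2.json`), matrices as labelled TSV, and a CLI
wrapper (`inst/scripts/sbn-cli`, or `sbn_cli()` from R) exposes
`exact-matrix`, `sbn-matrix`, `steady-state`, `attractors`,
`pseudo-attractors`, `random-net`, `norms` and `async-sim`.

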