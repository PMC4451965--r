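# dsrloops

Structural detection of the positive feedback loops that can underlie
multistationarity in biochemical reaction networks.

## The problem

Bistability — and multistationarity in general — is a core mechanism in cell
signalling, but positive feedback loops, which are *necessary* for it, are
abundant in realistic reaction networks. Most of them have nothing to do with
an observed bistability. `dsrloops` implements an automated, parameter-free
procedure that classifies the positive feedback loops of a network into those
that can carry multistationarity and those that cannot: a loop is *relevant*
exactly when breaking all relevant loops (removing one influence edge from
each) provably excludes multiple positive steady states.

The method needs only the network structure and qualitative kinetics:

* the **stoichiometric matrix** `A` (n species × m reactions,
  `a_ij = beta_ij − alpha_ij`), with rank `s` computed exactly;
* the **influence matrix** `Z`: the sign pattern of `∂v_j/∂x_i` for rates
  that are strictly monotone in every variable (mass-action kinetics gives
  `z_ij = +1` exactly on the reactant support). Every nonzero entry owns a
  symbolic variable `g[i,j]`.

From these it computes, with exact integer/rational arithmetic throughout:

1. the **injectivity polynomial** `p = det(M~)`, where `M = A Zᵗ` and the
   rows indexed by the pivots of the Gauss-reduced (RREF) basis of the
   conservation laws (left kernel of `A`) are replaced by that basis. If `p`
   is nonzero and single-signed, the species-formation map is injective on
   every positive stoichiometric compatibility class: the network **cannot**
   be multistationary. Terms of the "wrong sign" `(−1)^(s+1)` are the only
   carriers of possible multistationarity.
2. the **signed DSR-graph**: bipartite digraph with edges `X_i → r_j`
   (sign of `z_ij`) and `r_j → X_i` (sign of `a_ij`). Each wrong-sign term
   fixes `s` species→reaction edges; completing them with a perfect matching
   of existing reaction→species edges closes a **2s-nucleus** (disjoint
   circuit cover of the 2s nodes). A nucleus `D = C_1 ∪ … ∪ C_a` has sign
   `σ(D)ℓ(D) = (−1)^{a_2} ∏ ℓ(C_i)`, with `a_2` the number of circuits with
   an even number of species nodes; if none of its circuits is a positive
   feedback loop this sign is forced to `(−1)^s`.
3. the **relevant loops**: the positive circuits occurring in wrong-sign
   nuclei of wrong-sign terms.

## Worked example

The classical mitotic-trigger toy model (Cdk1–cyclin B1 shuttling between
cytoplasm and nucleus plus nuclear phosphorylation) with a self-activating
phosphorylation rate:

```r
library(dsrloops)
fx  <- get_fixture("mitosis_z1")
rep <- find_relevant_loops(fx$network, fx$influence)
rep
```

prints

```
Network: 3 species, 4 reactions, rank s = 2
Injectivity polynomial: 5 terms (3 positive, 2 negative), wrong sign (-1)^(s+1) = -
Verdict: INCONCLUSIVE (terms of both signs; multi-stationarity cannot be excluded)
Wrong-sign terms: 2
  g[1,1]*g[3,3] (1 nuclei, 1 wrong-sign)
  g[2,2]*g[3,3] (1 nuclei, 1 wrong-sign)
Relevant positive feedback loops: 1 (of 3 positive loops in the DSR-graph)
  r3 -(+)-> Xnuc_p -(+)-> r3  motif (+,+)
```

Read: the degree-2 polynomial `+g[1,1]*g[2,3] -g[1,1]*g[3,3] +g[1,1]*g[3,4]
-g[2,2]*g[3,3] +g[2,2]*g[3,4]` has two negative (wrong-sign) terms, each
realized by one wrong-sign 4-nucleus, and of the three positive feedback
loops in the DSR-graph only the phosphorylation self-activation loop
(`Xnuc_p → r3 → Xnuc_p`) appears in them — it alone can account for the
bistability of this model. With the alternative kinetics `mitosis_z2`
(phosphorylation rate independent of the phosphorylated form) the verdict is
`INJECTIVE`: no kinetics with that influence pattern admits two positive
steady states in a compatibility class.

Further fixtures reproduce the published analyses of a Ring1B/Bmi1
ubiquitination model (2 relevant loops: self-ubiquitination of Z and R), a
two-site phosphorylation cycle (2 loops, one with 4 species nodes and two
negative edges), a 2-layer cascade (3 loops, one spanning 5 species) and a
caspase-activation apoptosis model (2 loops).

## Command line

```sh
Rscript -e 'dsrloops::main()' analyze network.rxn --mass-action --format json
Rscript -e 'dsrloops::main()' analyze --fixture apoptosis
Rscript -e 'dsrloops::main()' polynomial --fixture mitosis_z1
Rscript -e 'dsrloops::main()' graph --fixture mitosis_z1 --out dsr.dot
Rscript -e 'dsrloops::main()' fixtures
```

Reaction lists are plain text (`id: 2 A + B -> C`, `id: A <-> B`, `0` for an
empty side); influence tables are TSVs with species rows, reaction-id
columns and `+`/`-`/`0` cells (see `inst/extdata/` for examples).

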