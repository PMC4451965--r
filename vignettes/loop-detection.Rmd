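---
title: "Finding the positive feedback loops that matter: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding the positive feedback loops that matter: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsrloops)
```

## The model and its assumptions

A reaction network is a set of species $X_1,\dots,X_n$ and reactions
$r_j\colon \sum_i \alpha_{ij} X_i \to \sum_i \beta_{ij} X_i$ with
nonnegative integer stoichiometric coefficients. Its dynamics
$\dot x = A v(x)$ factor through the stoichiometric matrix
$A = (\beta_{ij} - \alpha_{ij})$ and a rate vector $v(x)$. Trajectories are
confined to stoichiometric compatibility classes
$(x_0 + \mathrm{im}\,A) \cap \mathbb{R}^n_{\ge 0}$, cut out by the
conservation laws (the left kernel of $A$). A network is *multistationary*
when some class contains two distinct positive steady states.

The only assumption on the kinetics is **strict monotonicity**: each rate
$v_j$ is strictly increasing, strictly decreasing, or constant in each
concentration $x_i$. This holds for mass-action and Michaelis–Menten
kinetics and is encoded in the influence matrix $Z$, whose entry is
$\pm\gamma_{ij}$ (a symbolic variable carrying only a sign) or $0$. A rate
that is non-monotone in some variable has no representation in this
formalism; the sign-table reader deliberately accepts only `+`, `-`, `0`
and rejects anything else rather than guessing a convention.

## The injectivity polynomial

Let $s = \operatorname{rank} A$ (computed exactly over the rationals) and
let $\omega^1,\dots,\omega^d$ ($d = n - s$) be a basis of
$(\mathrm{im}\,A)^\perp$. The package interprets "Gauss-reduced" as the
**reduced row echelon form**: leading entries $1$, strictly increasing
pivot positions $i_1 < \dots < i_d$ (each vector's first nonzero entry),
pivot columns zero elsewhere. RREF pins the basis uniquely, which makes the
polynomial below — and everything derived from it — bit-for-bit
reproducible; any other normalization would rescale coefficients without
changing signs, but reproducibility is worth fixing a canonical choice.

Form the symbolic $n \times n$ matrix $M = A Z^t$, replace row $i_j$ by
$\omega^j$, and expand
$p = \det(\widetilde M)$, a multilinear polynomial of degree $s$ in the
$\gamma_{ij}$ with exact integer (in general rational) coefficients. If $p$
is nonzero and single-signed, $x \mapsto A v(x)$ is injective on every
positive compatibility class and the network cannot be multistationary
(verdict `INJECTIVE`); both signs present is `INCONCLUSIVE` (the test
cannot decide multistationarity, only fail to exclude it); identically zero
is `DEGENERATE`.

Because every 2s-nucleus of the signed DSR-graph without a positive
feedback loop contributes sign $(-1)^s$, the terms with the **wrong sign**
$(-1)^{s+1}$ are precisely the ones that require a positive loop — and
empirically they are few.

### Numerical choices

* **No floating point anywhere in the polynomial path.** Coefficients are
  exact: the RREF rows are cleared to integers (the common denominator is
  divided back out of the final, gcd-reduced coefficients), and all
  intermediate values are integers well below $2^{53}$, so doubles behave
  as exact integers at these sizes (n ≤ ~15).
* **Expansion strategy.** The determinant is expanded column by column with
  memoization on the set of still-unused rows — $O(2^n\,n)$ symbolic steps
  instead of $n!$. Because column $k$ of $M$ only contains variables
  $\gamma_{k,\cdot}$, monomial keys can be built append-only in species
  order, and species indices in a monomial are distinct by construction.
  Terms with repeated reaction indices cancel exactly during accumulation,
  as the theory predicts; the suite asserts no such term survives.
* **Canonical ordering.** Monomials are keyed by their factor list sorted
  by species index and polynomials print in sorted-key order, so renderings
  are stable golden-file material.
* The naive $n!$ permutation-sum determinant exists only in the test suite
  (`helper-oracle.R`), with a deliberately different representation, as an
  independent oracle.

## The DSR-graph, nuclei and relevant loops

The DSR-graph has an edge $X_i \to r_j$ labelled $z_{ij}$ for each nonzero
influence and $r_j \to X_i$ labelled $a_{ij}$ for each nonzero
stoichiometric entry; the signed graph keeps only signs. Circuits alternate
species and reaction nodes; a positive circuit is a positive feedback loop.
Circuit positivity uses only edge signs; the integer magnitudes of
$a_{ij}$ enter solely the nucleus-expansion coefficients.

Node ids place reactions before species, so the minimal node of any circuit
is a reaction node; the canonical rotation starts there. This single
convention drives circuit deduplication, motif signatures, and
deterministic output order. Circuit enumeration is a rooted DFS restricted
to nodes at or above the root — at fixture scale (≤ 26 nodes) the cycle
counts are small and the simple algorithm is preferable to a full
Johnson implementation.

For a wrong-sign term $\gamma_{i_1 j_1}\cdots\gamma_{i_s j_s}$ the package
fixes the $s$ edges $X_{i_k} \to r_{j_k}$ and enumerates, by backtracking
over reactions in index order, every perfect matching of existing
$r_{j} \to X_{i}$ edges back onto the term's species. Each matching gives a
functional digraph in which every node has in- and out-degree one, i.e. a
disjoint circuit cover of the $2s$ nodes — a 2s-nucleus. Nuclei whose sign
$\sigma(D)\ell(D) = (-1)^{a_2}\prod \ell(C_i)$ is wrong are kept, and the
positive circuits inside them are the **relevant loops**. A loop appearing
in both right- and wrong-sign nuclei is still reported (relevance, not
exclusivity, is the criterion); provenance (which terms produced each loop)
is recorded in the report, but the canonical output is the deduplicated
set.

The global nucleus expansion (`nucleus_expansion`) rebuilds the entire
polynomial from the graph by enumerating all elementary circuits and all
node-disjoint collections totalling $s$ species nodes. It shares nothing
with the determinant path beyond the input matrices, and exact equality of
the two expansions — asserted on every fixture, including the rank-7
ubiquitination model, and on hundreds of seeded random networks — is the
strongest internal consistency check the theory offers. A discrepancy
would be reported as a convention error, never silently rescaled.

## Motif signatures

A loop's motif is its cyclic edge-sign tuple read from a reaction node, so
odd positions are reaction-node labels. Rotations by an even number of
positions describe the same motif; the package canonicalizes to the
lexicographically smallest rotation with `+` ordered before `-`. Thus
`(-,-,+,+)` and `(+,+,-,-)` print identically as `(+,+,-,-)`.

## What the synthetic generator emulates — and what it does not

`random_network(seed, n_max, m_max)` produces networks with stoichiometric
coefficients in $\{0,1,2\}$ (sparse, mass-action-like), no empty reactions,
a nonzero stoichiometric matrix, and a sign table whose support is a
superset of the reactant support: reactant influences are positive with
probability $0.85$ (else negative, exercising non-standard monotone
kinetics such as inhibitions), and non-reactant influences appear with
probability $0.1$ (product feedback, as in the ubiquitination model's
rates). Sizes stay at $n \le 6$ so the $n!$ oracle remains tractable.

These networks are *algebraic* test material: they exercise every code path
(ranks from 0 to full, catalysts, inflows/outflows, mixed signs) but are
not biologically plausible mechanisms. A green property suite therefore
establishes correctness of the symbolic machinery, not that any particular
biological conclusion holds; the biological validation lives in the seven
transcribed fixtures with their published expected outputs.

## Degenerate inputs and edge cases

* Reactions `0 -> 0` are rejected; single-sided reactions (inflow/outflow)
  are legal and exercised by the apoptosis fixture.
* Catalysts (species on both sides) keep their influence edge
  ($\alpha > 0$) but contribute no reaction→species edge ($a = 0$); this
  asymmetry is what makes, e.g., the apoptosis activation loop work.
* A full-rank $A$ has an empty kernel basis and no replaced rows; a zero
  $A$ has rank 0 and $p \equiv$ constant.
* An all-zero influence matrix gives a DSR-graph with no species→reaction
  edges and (for $s > 0$) the zero polynomial (`DEGENERATE`).

## Known limitations

* The procedure is one-directional: it can prove the *absence* of
  multistationarity (injectivity) but never its presence; relevant loops of
  a network not known to be multistationary lack that interpretation.
* Only strictly monotone kinetics are representable.
* No SBML import; networks enter as plain-text reaction lists.
* The exact expansion is exponential in $n$ in the worst case; it is
  instantaneous at fixture scale (n ≤ 11) but dense influence matrices on
  much larger networks would need the sparsity the method exploits.
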