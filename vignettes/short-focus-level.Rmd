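---
title: "Multiple testing on gene-set DAGs with the Short Focus Level procedure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple testing on gene-set DAGs with the Short Focus Level procedure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfltest)
```

## The testing problem

Gene Ontology style vocabularies organise gene sets in a directed acyclic
graph (DAG): parents are more general processes, children more specific
ones, and — once annotations are propagated along the true-path rule —
every child's gene set is a subset of each of its parents'.  The
*self-contained* null hypothesis for a term,

> $H_i$: no gene annotated to term $i$ is differentially expressed,

therefore carries logical structure: the null of a parent implies the null
of each child (a set with no differentially expressed genes has no subset
with any).  Two consequences follow.  First, any multiplicity correction
that ignores the structure (plain Bonferroni–Holm) wastes power and can
produce incoherent output, with a child called significant while its more
general parent is not.  Second, the hypothesis family is *restricted*:
distinct index sets $I \ne J$ can satisfy $H_I = H_J$ for the intersection
hypotheses $H_I = \bigcap_{i \in I} H_i$, so the deduplicated closure has
fewer than $2^m - 1$ members.

The Focus Level approach controls the familywise error rate (FWER)
strongly over this family while guaranteeing a *coherent* significant
subgraph (every ancestor of a rejected term is rejected).  The user picks
a *focus level* $F$: an antichain of terms (FL1: no focus term is an
offspring of another) whose ancestors and offspring cover the graph (FL2).
Terms above $F$ are handled bottom-up by inheritance; terms at and below
$F$ are handled top-down by closed testing over all unions of gene sets
from the focus level down — which is exponentially expensive and rules out
the most natural default, the root focus level.

The Short Focus Level (SFL) procedure replaces the top-down closed test
with a sequentially rejective *graphical weighted-Bonferroni* procedure
that performs at most one test per term.

## The graphical machinery

A weighted test graph is a pair $(\alpha, G)$: local thresholds
$\alpha_1, \dots, \alpha_m$ with $\sum_i \alpha_i \le \alpha$, and edge
weights $0 \le g_{ij} \le 1$, $g_{ii} = 0$, $\sum_k g_{ik} \le 1$.  When
$H_j$ is rejected its threshold is recycled along its outgoing edges,

$$\alpha_\ell \leftarrow \alpha_\ell + \alpha_j g_{j\ell}, \qquad
  g_{\ell k} \leftarrow \frac{g_{\ell k} + g_{\ell j} g_{j k}}
                             {1 - g_{\ell j} g_{j \ell}},$$

with the weight set to 0 when the denominator is nonpositive.  These are
the standard update rules of graphical sequentially rejective tests; the
package pins them with three independent checks rather than trusting the
transcription: the complete symmetric graph reproduces Holm's procedure
exactly for random p-values, the active thresholds never sum above
$\alpha$, and on unrestricted families the sequential procedure equals the
brute-force closed test (all in the test suite).

Removing a set of hypotheses through the same rule yields the local levels
$\alpha_i(I)$ that the graph implicitly assigns to the intersection
hypothesis $H_I$; the result is order-invariant (asserted numerically, not
assumed) and monotone: removing more hypotheses never shrinks a survivor's
level, which is the monotonicity condition
$\alpha_i(I) \le \alpha_i(J)$ for $H_I \subset H_J$ that FWER control of
the restricted shortcut rests on.

## The SFL graph

`build_sfl_graph()` translates a DAG plus focus level into $(\alpha, G)$:

* each of the $m_F$ focus terms holds $\alpha/m_F$; below-focus terms hold 0;
* each parent-to-child edge in the focus-and-below subgraph has weight
  $1/m_i$ ($m_i$ = the parent's child count in that subgraph);
* each *terminal* term (childless within the subgraph) gains recycling
  edges to all focus terms with weight $1/m_F$ — or $1/(m_F - 1)$ to the
  other focus terms when the terminal is itself a focus term; a lone focus
  terminal keeps its mass.

"Terminal" is deliberately defined with respect to the focus-and-below
subgraph, not the whole DAG, since the recycling edges exist to return
mass that has cascaded past the deepest testable terms.  An
offspring-free focus level makes every focus term terminal, the graph
collapses to the complete symmetric graph, and the whole procedure —
including adjusted p-values — reduces to Bonferroni–Holm, which the test
suite asserts exactly.

## Running the restricted shortcut

Restricted families need care beyond the plain sequential procedure: the
local threshold of a hypothesis must remain effectively zero until every
hypothesis implying it has been rejected, or coherence and FWER control
break.  `restricted_sequential()` implements the stagewise shortcut: with
$M$ the current unrejected set, it forms the canonical minimal
representation $I$ of $H_M$ — the minimum-cardinality subcollection of the
*maximal* members of $M$ whose evidence union equals that of $M$, with a
lexicographic tie-break — and rejects an $H_j$, $j \in I$, whenever
$p_j \le \alpha_j(I)$, recomputing $I$ after each of at most $m$ stages.
Because members of $I$ are always maximal among the unrejected
hypotheses, no term is ever tested before all of its parents are
rejected.

Two semantics were candidates for the cascade, and the package decides
between them by oracle, not by taste.  The first ("escrow") runs the
plain sequential procedure with an eligibility gate, letting recycled
mass accumulate silently at ineligible terms.  The second is the
stagewise minimal-representation procedure above.  Against the
brute-force restricted closed test (`closed_test_oracle()`, which
enumerates the deduplicated closure and tests every node at its canonical
index set's levels) the escrow variant is strictly weaker in
configurations where the levels of the minimal representation recycle
mass held by unrejected non-members; the stagewise procedure agrees with
the closed test exactly on every generic-position family tried (hundreds
of random nested DAGs under a fixed seed), so it is the one `sfl()` uses.
The eligibility hook remains available on `sequential_reject()` as a
general mechanism.

One scope limit is worth stating plainly.  Exact agreement with the
closed test holds for families in *generic position* — every term carries
at least one gene private to it, the typical situation when terms have
direct annotations.  For degenerate families in which a term's gene set
is exactly a union of other terms' (children partitioning their parent),
the closed test can re-use an already-rejected term's p-value at a
closure node, which no $m$-step path can imitate; there the shortcut is
occasionally conservative, and the suite asserts the safe direction: its
rejections are always a subset of the closed test's.  FWER control is
unaffected.

## Above the focus level, and adjusted p-values

Ancestors of the focus level are rejected as soon as any of their
focus-level offspring is rejected — the logical inheritance direction —
with adjusted p-value the minimum over those offspring.

Below-focus adjusted p-values have no closed form, so `sfl()` defines
them operationally: the adjusted p of a term is the smallest overall
level $\alpha'$ at which the procedure would reject it.  Rejection sets
are nested in $\alpha'$ (asserted as a property test), so the value is
well defined and a 20-step bisection resolves it to about $10^{-6}$;
level weights are cached across bisection calls since they scale linearly
in $\alpha'$.  Inside `sfl()` the ancestors inherit these
procedure-consistent values rather than bare Holm-adjusted focus
p-values, which keeps the two reported invariants — coherence of the
rejected set, and adjusted p nondecreasing from parent to child — true by
construction; standalone `run_bottomup()` retains the plain Holm
inheritance for users composing the passes themselves.

A related caution: recycling does *not* make the focus level uniformly
dominate Holm.  A rejected focus term's mass travels through its
offspring and returns to the focus level only via rejected terminals; if
the offspring p-values are large the mass strands mid-graph, and Holm —
which hands the mass directly to the surviving focus terms — can reject a
focus term the SFL does not.  The closed-test oracle agrees with the SFL
here, so this is a property of the graph construction, not a bug; the
package therefore asserts Holm *equivalence* for offspring-free focus
levels and nothing stronger.

## Self-contained set tests

`stouffer_combine()` maps one-sided per-gene p-values to normal scores
and refers $\sum_i z_i / \sqrt{k}$ to the standard normal upper tail.
The $\sqrt{k}$ scaling is the classical form and is uniform under the
null (simulation-checked); combining with the unscaled mean score, which
some descriptions suggest literally, is not null-uniform and is kept only
behind `method = "mean"` for comparison experiments.  Inputs of exactly 0
or 1 are clipped to $10^{-15}$ from the boundary — far below any level in
use — to keep the quantiles finite, with a warning.  `fisher_combine()`
refers $-2\sum \log p_i$ to $\chi^2_{2k}$.

`global_test()` is a quadratic-form score test of association between an
expression submatrix and a phenotype:
$Q = (y - \bar y)^\top R\, (y - \bar y)$ with
$R = X_S X_S^\top / |S|$ on the column-centred submatrix.  Its
`"asymptotic"` p-value refers $Q$ to a gamma distribution whose first two
moments are computed *exactly* under the permutation null of the
phenotype, via closed-form permutation moments of quadratic forms (the
fifteen equality patterns of the four-index sum, Möbius-inverted on the
partition lattice); the moment code is verified in the suite against
exhaustive enumeration of all $6! = 720$ permutations at $n = 6$.  The
`"permutation"` method draws `n_perm` phenotype permutations and applies
the add-one correction $(b + 1)/(B + 1)$; the two methods agree to within
0.02 on a fixed fixture, and both are null-uniform by a
Kolmogorov–Smirnov check.  The two-moment gamma is accurate in the
moderate tails that thresholds live in; for very large sets at small $n$
its extreme tail is approximate, which is why the FWER simulations below
are part of the acceptance suite rather than taken on trust.

## What the simulators emulate

`simulate_sim2()` generates the Gaussian benchmark: $Y \sim N(0,1)$ over
$n = 20$ samples by default, a $n \times 100$ standard normal expression
matrix, 14 nested gene sets (`sim2_genesets()`, root plus three mid-level
terms covering specific terms of 8–40 genes), and signal $r\,Y$ added to
the genes of three designated sets (defaults $r = 0.5$), making nine sets
truly associated by inheritance.  `simulate_sim1()` generates the count
benchmark: a fixed six-term nested topology whose leaf sets receive 1 to
`max_size` genes with $j$-way sharing probability proportional to
$2^{-j}$ (many-way overlap discouraged, as in real ontologies), parents
adding fresh genes to their children's, negative-binomial counts with
variance $\mu + \mu^2/d$, $d = 10$, group sizes binomial with both groups
forced $\ge 2$, and per-gene log2 effects $\beta_i \sim$
Poisson($\lambda$) in leaf sets selected with probability 0.5 each.  The
control means are drawn log-normal (log-mean 3, log-sd 1.5, median about
20 counts) as a documented stand-in for resampling a real count data set;
absolute power under this stand-in is not comparable across
implementations, so the count study is used for qualitative checks
(moment validity, null behaviour, monotone power) only.

Neither generator emulates library-size variation, gene–gene correlation
beyond shared signal, or annotation noise, so passing simulations say
nothing about those aspects of real data.  More broadly, absolute power
for the Gaussian design is sensitive to the per-set test's tail behaviour
and to the focus level, both of which differ across published
implementations of this class of methods; the claims this package treats
as verifiable — and asserts under fixed seeds — are FWER control under the
complete null ($\le \alpha$ plus twice the Monte Carlo error at 2,000
replicates), coherence, nestedness in $\alpha$, closed-test equivalence,
Holm equivalence, and power monotone in $r$.  The per-term power values
themselves are recomputed, from scratch, by `scripts/acceptance.R`.

Problem sizes used by the shipped checks: 1,000 replicates for the
power study and 2,000 for the null FWER study at $n = 20$ samples and 100
genes; 200 random DAGs of up to 7 terms for the oracle equivalence; the
closure utilities are exercised up to the 14-generator system (16,383
subsets).  One master seed drives a per-replicate seed stream, so results
are reproducible and independent of evaluation order.

## Numerical and degenerate-input decisions

* Threshold comparisons use $p_j \le \alpha_j + 10^{-12}$; a level-zero
  test never rejects, which also sidesteps the $p = 0$ pathology.
* Regularity sums are checked to $10^{-12}$; the weight-update denominator
  $1 - g_{\ell j} g_{j \ell} \le 0$ yields weight 0.
* Closure enumeration is capped at 20 generators; the canonical index-set
  search caps its exact set-cover phase at 22 free candidates — far above
  anything the oracle duties need.
* Two terms with identical gene content are rejected by `infer_hasse()`
  (they would be one hypothesis under two names); `merge_duplicate_sets()`
  collapses them explicitly with a warning when that is intended.
* Terms with fewer than `min_set_size` genes (default 5, the conventional
  floor for set testing) are pruned before focus validation, with edges
  rerouted so the surviving reachability order is preserved.
* A closure node's count is reported two ways: `n_nodes` deduplicates by
  gene content (the statistically distinct hypotheses) and `n_structural`
  counts one node per antichain of maximal generating terms (the closed
  graph as a term-level object).  For the shipped 14-set system these are
  383 and 574: the mid-level sets there are exact unions of their
  children, so many structurally distinct unions coincide as gene sets.

## Known limitations

Automatic focus-level selection (balancing atom counts per focus term) is
a documented stub; the root focus level is the recommended default, and
that is precisely the regime the shortcut was built to make affordable.
Only is_a-style parent/child structure is modelled.  The closed-test
oracle is exponential by design and refuses families beyond 20
generators.  Competitive (enrichment-style) set tests are out of scope:
the logical assumptions the DAG correction relies on hold only for
self-contained nulls.
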