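---
title: "Coexistence hierarchies under toxin-mediated exclusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexistence hierarchies under toxin-mediated exclusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotox)
```

## The consumer-resource-toxin model

`cotox` analyses microbial communities through a deliberately minimal
structural model.  A community of $S$ taxa is described by two sign tables:

* a **food table** $R \in \{-1, 0, 1\}^{S \times M}$, where
  $\rho_{i\alpha} = +1$ means taxon $i$ produces resource $\alpha$,
  $\rho_{i\alpha} = -1$ that it requires $\alpha$ to grow, and $0$ neither;
* a **toxin table** $T \in \{-1, 0, 1\}^{S \times T}$, where $+1$ marks a
  producer of a toxin and $-1$ a taxon sensitive to it.

Quantitative abundances, stoichiometry and kinetic rates are abstracted
away: the analysis is purely structural, asking which *sets* of taxa can in
principle persist together.  Two strong assumptions make the toxin layer
tractable: a sensitive taxon cannot persist in the presence of any producer
of that toxin (inhibition dominates any replication rate), and toxins
cannot be neutralized.  A "toxin" here is an abstraction for any
interaction that enforces mutual exclusion — amensalism, predation,
interference competition — not only a literal chemical.

Because one signed cell encodes one relation, a taxon can never both
produce and require the same resource, nor both produce and be sensitive to
the same toxin.  This is an encoding constraint, asserted rather than
silently repaired (`validateModel()` reports violations with coordinates).

## Organizations

A taxa set $O$ is an **organization** when

1. *(self-maintenance)* every resource required by a member is produced by
   some member: $\forall i \in O, \forall \alpha \in \delta_i\;
   \exists j \in O: \alpha \in \epsilon_j$, and
2. *(toxin compatibility)* no member is sensitive to a toxin produced
   within the set.

Closure, the second half of the classical chemical-organization pair, is
vacuous here because taxa are self-replicators that never generate new
taxa.  The empty set satisfies both conditions vacuously and is counted as
an organization throughout the package; reported counts therefore include
it.

`enumerateOrganizations()` offers two routes.  The brute-force route tests
the predicate on every subset, vectorized over bitmask unions (a doubling
sweep computes the required/produced unions of all $2^S$ subsets in $S$
vector operations); it is refused above `maxTaxa` (default 20).  The
constructive route grows self-maintaining sets from each taxon by
branching over the producers of the first unmet resource (memoized on the
taxa bitmask), closes the family under pairwise unions — unions of
self-maintaining sets are self-maintaining — and finally removes
toxin-conflicted sets.  The constructive route exists for models where the
power set is uncomfortable; its correctness contract is *equivalence with
brute force*, which the test suite asserts on the worked examples and on
random models up to twelve taxa.

## The extended hierarchy

With toxins, the union of two organizations need not be an organization,
so the set of organizations loses its lattice structure.  It is restored
by adding, as explicit nodes, all pairwise unions and intersections of
organizations that fail the predicate:

* **non-persistent unions** (red) mark coexistence boundaries; they only
  arise when toxins are active;
* **non-persistent intersections** (yellow) mark shared sub-communities
  that are not independently self-sustaining.

`buildExtendedHierarchy()` classifies nodes with precedence organization
> union > intersection.  A set that is simultaneously a pairwise union
and a pairwise intersection of organizations is provably an organization
(each member is reproducible in one of the intersected organizations, and
toxin-freeness is inherited from the covering measurement), so on
consistent input the three statuses are mutually exclusive.  Unions and
intersections are taken *pairwise over organizations only*, not iterated
over derived sets; iterating the union closure was checked to change node
counts only marginally on random ensembles while complicating the node
semantics, and the pairwise inventory matches the worked example.

Cover edges follow the Hasse convention: $x \to y$ iff $x \subset y$ with
no node strictly between.  The implementation computes the strict-subset
relation on bitmasks and prunes transitive pairs with a boolean matrix
product; a literal triple-loop oracle backs it in the tests.  Because a
toxin acting in a set also acts in every superset, no organization can
appear above a non-persistent union on any upward path — a structural
invariant asserted across random ensembles.

### Interaction clusters and elementary organizations

The **interaction cluster** of an organization is the set of its taxa
appearing in no strictly contained organization; every organization is the
disjoint union of its cluster and the organizations below it.  Clusters
that are themselves organizations are *context-free* (they can stand
alone); the rest are *context-dependent*.  All taxa of a cluster are
connected through resource dependencies (if a cluster split into two
halves with no dependency from one to the other, removing one half would
leave a smaller organization, contradicting the definition);
`clusterDependencyGraph()` exposes that graph and the tests assert
connectivity.  Organizations introducing a non-empty cluster are
**elementary**; all others are unions of elementary ones, which
`elementaryOrganizations()` verifies before returning.

The empty cluster of a non-elementary organization is classified
context-free by the letter of the definition (the empty set is an
organization); consumers interested in the cluster inventory should filter
on non-empty clusters, as the examples do.

## Reaction-network form and minimal producing sets

`toReactionNetwork()` renders a model as explicit reactions: one
replicator per taxon (`b + f1 + f2 + f4 -> 2 b + n f3`), one spontaneous
death outflow per taxon, and one kill reaction per sensitive pair
(`a + t1 -> t1`).  The product coefficient `n` stays symbolic by default —
the analysis only needs it "sufficiently high" — with an integer override
for downstream tools.

The taxa-only reduced network replaces resources by **minimal producing
sets**: inclusion-minimal sets of taxa that jointly produce everything a
consumer requires.  Enumerating them is the minimal hitting set problem
(NP-hard), so the exact route (ascending-cardinality subset search with
superset pruning) is capped at 20 candidate suppliers, and a seeded greedy
heuristic — take the supplier resolving the most unmet resources, break
ties uniformly, then prune redundant members so the result is locally
minimal — serves larger instances.  Organization enumeration through the
reduced network equals enumeration from the tables, which the tests check
on random models.

## Random models and what they emulate

`randomCRTModel()` fills each food cell independently with $+$ at
probability `pFoodProduce`, $-$ at `pFoodRequire` (defaults $1/3$ each, an
uninformative choice giving the three signs equal weight) and each toxin
cell with `pToxinProduce` / `pToxinSensitive` (defaults $0.1$, sparse
antagonism).  Cells are drawn row-major under one explicit seed, so a seed
fully determines a model on any platform.

These ensembles emulate the *combinatorial* structure of cross-feeding and
antagonism: independent, unstructured sparse interactions.  They do not
emulate phylogenetic correlation between rows, modular or nested
interaction structure, abundance-dependent effects, or environmental
resource supply — so green tests on these ensembles certify the algorithms
and the structural theorems, not ecological realism of any particular
community.  Node-count distributions across such ensembles are extremely
dispersed (single models range from a handful to several hundred
organizations at the default study point), which is why
`runParameterStudy()` reports the standard error of the mean alongside
every mean.

## Measurement experiments

A measurement is a taxa set observed as a stable composition, assumed to
be an organization of an unknown model.  Three schemes are simulated
(`drawMeasurements()`): **novel** — organizations drawn uniformly without
replacement (an idealized upper bound); **neutral** — uniform draws with
replacement; **random** — a random initial set (each taxon included with
probability 0.5) reduced by `generateOrganization()`, which removes
toxin victims in one pass computed from the producers present in the
*initial* set and then iteratively removes starved taxa, all unsupported
taxa per round, to a fixed point.  The one-pass toxin rule reflects the
rapid-toxin assumption; victims are never re-added even if their
producers later starve, a deliberate tie-break because the true largest
contained organization is not always well defined once removal cascades
interact.  An initial set that collapses to the empty set counts as a
measurement of the empty organization, not as a discarded trial.

`updateReconstruction()` maintains the pairwise unions and intersections
of the measured sets that are not measured themselves (*additional
unions* / *additional intersections*); sets appearing in both collections
are *additional organizations* and provably true.  Three counting
policies are exposed by `recoveryCurve()` because two natural readings of
"recovered" exist: `plus_additional_orgs` (default; counts only provable
discoveries, so recovery never inflates) and `plus_all_candidates`
(counts all candidate discoveries, matched against ground truth), beside
`measured_only`.  `falseDiscoveryRate()` reports the fraction of a
candidate category that is not a true organization; without toxins the
union FDR is identically zero, and an empty category yields a flagged
`NA` rather than an exception.

## Inferring minimal toxin and food tables

**Toxins.**  Every non-persistent union is decomposed into pairs of
organizations; the componentwise-minimal sub-pairs of their set
differences that occur jointly in no organization are the **taxa
impairings** (`findImpairings()`).  An exact set-cover search
(`minimalImpairingCover()`) returns all minimum-cardinality impairing
subsets explaining every union, and `impairingsToToxinTables()` expands a
cover into toxin tables — one fresh toxin per impairing, two orientations
each, cartesian product over the cover.  Each alternative is verified
against the input classification: organizations must stay conflict-free,
non-persistent unions must conflict.  Impairings with multi-taxon sides
extrapolate beyond the pairwise case (the whole side produces, the whole
other side is sensitive) and are flagged, because an organization that
contains parts of both sides would be spuriously killed.  For the same
reason the round-trip property is exercised through the cover step: the
full impairing set may contain pairs whose joint absence is caused by
starvation rather than by any toxin, and a table realizing those would
contradict the organization list.

**Food.**  `inferFoodTable()` searches for a table whose *implied*
organization set — self-maintaining subsets containing no impairing —
equals the measured set exactly.  Phase 1 gives every taxon whose
singleton is unmeasured one private required resource, eliminating the
smallest spurious organizations; a taxon appearing in no measurement
keeps a producer-less requirement and is thereby excluded everywhere.
Phase 2 chooses producers: for each requiring taxon the candidate
producer sets are exactly the minimal hitting sets of its measured
contexts (every producer set of a correct table contains one, and
shrinking to it never removes a measured organization from the implied
set), and the search branches over up to `maxSlots` requirement slots per
taxon, evaluating exactness by exhaustive enumeration over the taxa
universe (capped at 16 taxa).  Phase 3 merges slots with identical
producer sets into shared resources, which provably leaves the implied
set unchanged.  Candidates are ranked by resource count, then signed-entry
count, with a seeded jitter breaking remaining ties deterministically;
when no exact table exists within the budget a best-effort table is
returned with the residual set difference attached, under a warning.
Minimality is heuristic: the search minimizes within its move set and
makes no global optimality claim.

## Numerical and engineering choices

* All taxa sets are canonicalized to C-locale radix-sorted unique label
  vectors; set lists are ordered by cardinality, then lexicographically,
  so every output is deterministic and diffable.
* Subset machinery uses multi-word integer bitmasks with 30 payload bits
  per word, safe for R's 32-bit integers at any $M$ or $T$.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; replicate $r$ of grid point $i$ in
  `runParameterStudy()` uses `seed + (i - 1) * replicates + r`.
* Degenerate inputs are first-class: empty models, toxin-free models
  (zero-column toxin tables), the empty organization, empty clusters and
  empty impairing covers all round-trip through the serializers.

The test suite and the acceptance script use problem sizes chosen to keep
exhaustive cross-checks exact: oracle comparisons run at up to 12 taxa,
ensemble statistics use 100 models of 10 taxa (the worked-example scale),
and recovery experiments use 50 models with 2.5 neutral draws per
organization.

## Known limitations

* The toxin model is binary and non-neutralizable; hierarchies in which a
  superset of a broken union persists (higher-order detoxification)
  cannot be represented.
* The constructive enumerator's completeness is certified empirically
  against brute force, not proved; brute force remains the ground truth.
* Food-table inference assumes the measured set is union-closed modulo
  impairings (any real organization set is); inconsistent measurement
  sets yield flagged best-effort results.
* Greedy producing sets are locally, not globally, minimal.
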