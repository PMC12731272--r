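# cotox — coexistence hierarchies of microbial communities with toxin-mediated exclusion

Microbial communities persist as self-sustaining sub-communities held
together by cross-feeding and pulled apart by antagonism.  `cotox`
analyses this structurally, with no kinetic parameters: a community is a
**consumer-resource-toxin (CRT) model**, two sign tables over the same
taxa — a food table `R ∈ {−1,0,1}^(S×M)` (`+` produce, `−` require) and a
toxin table `T ∈ {−1,0,1}^(S×T)` (`+` produce, `−` sensitive).  A taxa
set `O` is an **organization** when every required resource of every
member is produced within the set
(`∀ i ∈ O, ∀ α ∈ δᵢ ∃ j ∈ O: α ∈ εⱼ`) and no member is sensitive to a
toxin produced within the set.  Organizations are the candidate
persistent compositions; arranged by inclusion, together with their
pairwise unions and intersections that fail the predicate (non-persistent
unions/intersections), they form the **extended hierarchy** — a Hasse
diagram mapping all routes along which a community can assemble or
collapse.

The package is aimed at theoretical ecologists and microbiome researchers
who want to enumerate organizations, dissect hierarchies into interaction
clusters and elementary organizations, transform models into reaction
networks (exact and greedy minimal producing sets — the NP-hard hitting
set step), simulate how many measurements reconstruction of a hierarchy
takes (with false-discovery rates for candidate discoveries), and infer
parsimonious toxin and food tables back from measured compositions.

## Worked example

The built-in five-taxon community (`crtFixture("fig1")`) has four food
resources and one toxin: `c` produces `t1`, to which `a` is sensitive.

```r
library(cotox)
fig1 <- crtFixture("fig1")
orgs <- enumerateOrganizations(fig1)   # toxin-aware
sapply(orgs, paste, collapse = ",")
#> [1] ""        "a"       "a,b,d"   "a,b,e"   "b,c,d"   "a,b,d,e" "b,c,d,e"
```

Seven organizations survive the toxin (the empty community counts).
Without toxins there are ten — the toxin erases `{a,b,c,d}`, `{a,b,c,e}`
and `{a,b,c,d,e}`.  The extended hierarchy shows what remains of them:

```r
h <- buildExtendedHierarchy(orgs, fig1)
h
#> ExtendedHierarchy (toxin-aware): 7 organizations, 2 non-persistent unions,
#>   5 non-persistent intersections, 23 cover edges
subset(hierarchyNodes(h), status == "non_persistent_union")
#>         taxa size               status
#> 11   a,b,c,d    4 non_persistent_union
#> 14 a,b,c,d,e    5 non_persistent_union
```

The two red nodes are unions of surviving organizations that cannot
persist — the fingerprint of the hidden antagonism.  Inference reads it
back:

```r
reds <- nodeSets(h)[nodeStatus(h) == "non_persistent_union"]
findImpairings(orgs, reds)[[1]]
#> Impairing: ({a}, {c})
```

`a` and `c` can never coexist; one toxin produced by either of them (two
table alternatives) explains both red nodes.  The food side is recovered
by `inferFoodTable()`, which searches for a minimal table whose implied
organization set equals the measurements exactly:

```r
res <- inferFoodTable(orgs, findImpairings(orgs, reds), seed = 1)
res$phase1Resources             # separate requirements introduced first
#> [1] 4
foodTable(res$solutions[[1]]$model)
#>   r1 r2 r3 r4
#> a  1  0  0  0
#> b -1 -1  0  1
#> c  1  0 -1  0
#> d  0  1  1 -1
#> e  0  1  0 -1
```

Four resources suffice — the same number as the generating table, though
the cross-feeding details differ (they are not identifiable from the
organization set alone).  The table provably re-implies exactly the seven
measured organizations.

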