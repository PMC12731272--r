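Package: cotox
Title: Coexistence Hierarchies of Microbial Communities with
    Toxin-Mediated Exclusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing consumer-resource-toxin (CRT) models of
    microbial communities with chemical organization theory.  A community
    is encoded as two sign tables (taxa x food resources, taxa x toxins);
    the package enumerates all self-maintaining, toxin-compatible taxa
    sets (organizations), builds the extended hierarchy of organizations
    together with their non-persistent unions and intersections,
    transforms models into explicit reaction networks via exact or greedy
    minimal producing sets, simulates measurement experiments that
    reconstruct the hierarchy from observed community compositions, and
    infers parsimonious toxin and food-resource tables from measured
    organization sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-sets.R'
    'model-core.R'
    'model-io.R'
    'random-model.R'
    'organizations.R'
    'hierarchy.R'
    'reaction-network.R'
    'measurement.R'
    'inference.R'
    'fixtures.R'
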