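Package: treestack
Title: Hierarchy-Linked Stacked Barplots for Compositional Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multiresolution stacked barplots for compositional omics data
    (microbiome profiles, cell-type compositions) linked to a taxonomic or
    cell-type hierarchy. Provides a rooted-tree data model with Newick and
    taxonomy-table ingestion, explicit view states for collapsing subtrees
    and painting them from a cycling palette, sample arrangement by
    complete-linkage hierarchical clustering (Euclidean or Bray-Curtis) with
    centroid or medoid representative selection, a pure layout engine for the
    linked tree and bar panels with a nearest-node (Voronoi) hover query, and
    deterministic SVG export. A synthetic community generator with planted
    fold changes supports fully reproducible, download-free examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    vegan
Suggests:
    testthat (>= 3.0.0),
    xml2,
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'abundance.R'
    'arrangement.R'
    'hierarchy.R'
    'synth.R'
    'view-state.R'
    'layout.R'
    'render.R'
    'cli.R'
    'treestack-package.R'
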