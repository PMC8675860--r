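Package: ppanet
Title: Pathway-Based Protein-Protein Association Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds pathway-based protein-protein association (PPA) networks
    by projecting shared pathway membership of compound targets into an
    undirected protein graph, and characterises them topologically: diameter,
    average path length, clustering coefficient and its per-degree scaling
    C(k), average nearest-neighbour degree, assortativity, and degree,
    betweenness and closeness centrality. Identifies hub nodes and
    centrality outliers as key targets, and extracts a tripartite
    compound-target-pathway core subnetwork around them. Includes a
    deterministic synthetic-data generator for bipartite memberships and
    closed-form fixture graphs, readers and writers for GMT, TSV, Pajek,
    GraphML and edge-list formats, and an end-to-end pipeline emitting a
    machine-readable JSON report. Designed for network-pharmacology studies
    of multi-target natural products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, xml2, yaml
Suggests: testthat (>= 3.0.0), igraph, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
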