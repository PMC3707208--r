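Package: gammaclust
Title: Multilevel Gamma-Clustering, Tree Transformation and Layout for
    Dense Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural visualization of large, dense biological networks.
    Detects gamma-dense clusters (quasi-cliques) with a GRASP heuristic,
    builds a multilevel cluster hierarchy with per-level density parameters,
    transforms the hierarchy into a rooted shortest-path tree, and draws the
    tree with a hierarchy-aware force-directed layout (level-dependent edge
    lengths, concentric initialization, repulsion cutoff, position-averaging
    damping). Includes gene co-expression network construction by Pearson
    correlation thresholding, seeded synthetic-network generators for
    benchmarking, degree-coloured SVG rendering, and drill-down queries that
    recover the hidden original edges of any cluster.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
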