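Package: hydrotopo
Title: Laguerre Tessellation Analysis of Water Networks in Solvated Biomolecular Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Laguerre (power) diagrams of fully solvated molecular systems
    (protein, lipids, ions, water reduced to oxygen sites) inside a bounded region,
    and derives topological and metric descriptors from the resulting cell complex:
    water-network connected components and inclusion statistics, protein-surface
    genus via the Euler characteristic, node-disjoint and widest water paths through
    channels (Dijkstra search with a distance-to-protein cost potential), contact
    areas and domain volumes, and calibration of the water oxygen weight against an
    explicit-hydrogen reference. Includes seeded generators of synthetic toy systems
    (random packings, hydrated slabs, barrel-and-plug assemblies, torus clusters,
    water corridors) with voxel-oracle-validated ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
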