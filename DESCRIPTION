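Package: anguimorph
Title: Body-Shape Morphometrics and Phylogenetic Comparative Methods for
    Anguilliform Fishes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of the locomotory system of
    eels (Anguilliformes) from measurements of extant and fossil specimens.
    Computes the vertebrate shape index (VSI) and its component aspect
    ratios, estimates lateral-tendon and myoseptal lengths from ossified
    myoseptal bones (epineural and epipleural bones) preserved in fossils,
    builds principal-component morphospaces with convex-hull overlap
    detection, time-calibrates composite phylogenies from fossil tip
    occurrences and node-age constraints, estimates phylogenetic signal
    (Blomberg's K with a permutation test, Pagel's lambda by maximum
    likelihood), and reconstructs ancestral states of continuous traits by
    squared-change parsimony on trees with polytomies.  A seeded synthetic
    data generator produces specimen tables, tendon observations, Yule
    trees and Brownian-motion traits with the group structure the analyses
    assume, so the whole pipeline is testable without museum data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
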