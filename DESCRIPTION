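Package: rnaPhyloProfile
Title: Phylogenetic Profiling of Protein Families Anchored on a Noncoding RNA Marker
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ncRNA-anchored phylogenetic profiling of bacterial
    genome assemblies. Parses covariance-model RNA homology search tables
    (Infernal tblout), 12-column protein homology hit tables (BLAST/DIAMOND
    tabular), profile-HMM per-target tables (HMMER tblout) and cluster
    membership maps (MMseqs2 TSV); classifies RNA hits into full-length and
    variant categories by bit score and truncation; partitions assemblies
    into marker-positive and marker-negative cohorts on a species tree with
    taxonomic and variant-carrier exclusions; builds protein families from
    homology hits, cluster maps or thresholded HMM hits; counts per-genome
    paralogs; and ranks families by fractional presence and binary mutual
    information (log base 2) to find proteins whose occurrence is correlated
    or anticorrelated with the RNA. Includes a seeded synthetic-data
    generator that emits format-faithful mock search outputs with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
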