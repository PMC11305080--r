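Package: epigraft
Title: Epitope Grafting and Proteome-Wide Deimmunization for Immunogen Design
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for structure-guided immunogen design by epitope grafting.
    Computes per-residue buried surface area of an antigen against multiple
    binding partners from complex structures (PDB/mmCIF), selects contiguous
    epitope stretches supported by at least a minimum number of partners,
    transplants them onto a homologous scaffold by global sequence alignment,
    and eliminates every k-mer (default 9-mer) shared with a reference
    proteome by constrained greedy point mutation drawn from species-variant
    diversity, while keeping the transplanted epitope intact. Includes a
    seeded synthetic-data generator (decoy proteomes with planted windows,
    toy two-chain complexes with controllable interface geometry, and
    species-variant alignments) so the whole pipeline is testable without
    external downloads, plus a single-configuration pipeline driver with
    provenance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, SequenceMatching, Alignment
RoxygenNote: 7.3.3
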