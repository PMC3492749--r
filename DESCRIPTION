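Package: ribomlst
Title: Gene-by-Gene Ribosomal Multilocus Sequence Typing from Genome Assemblies
Version: 0.1.0
Authors@R:
    person("rMLST", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for ribosomal multilocus sequence typing
    (rMLST) of bacterial genome assemblies. Curates and indexes alleles of the
    53 ribosomal-protein (rps) loci, locates them on assembly contigs with a
    built-in seed-and-extend local-alignment search (nucleotide and six-frame
    translated modes), tags loci as complete, partial, missing or pseudogene
    through an iterative stringency-relaxing discovery loop, builds allelic
    profiles and ribosomal sequence types (rSTs), exports codon-aware per-locus
    alignments as XMFA, reconstructs neighbour-joining trees from p-distances
    with pairwise deletion, and computes Hunter-Gaston discriminatory indices
    and Nei-Gojobori dN/dS statistics. Includes a deterministic synthetic
    assembly generator with a ground-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
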