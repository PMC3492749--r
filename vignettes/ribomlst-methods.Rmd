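---
title: "Methods and design notes for ribomlst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ribomlst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribomlst)
```

# The model

Ribosomal multilocus sequence typing (rMLST) characterises a bacterial
isolate by the allelic variation of the 53 genes encoding ribosomal protein
subunits (*rps* genes). These loci are present in essentially all bacteria,
scattered around the chromosome, and under stabilising selection, which makes
them usable simultaneously for deep phylogeny and for strain-level typing.
The unit of analysis is the **allele**: a distinct coding sequence observed
at a locus, indexed by an arbitrary integer. An isolate's **profile** is its
vector of allele ids over the 53 loci, and identical complete profiles share
a ribosomal sequence type (rST).

`ribomlst` implements the whole gene-by-gene workflow on assembled contigs:

1. a curated allele database (`allele_db()`) per scheme locus;
2. a seed-and-extend local-alignment search of contigs against known
   alleles, in nucleotide and six-frame translated modes;
3. an iterative, stringency-relaxing tagging loop that grows the database
   to a fixpoint (`iterative_discovery()`);
4. profiles, rSTs and corpus tagging summaries;
5. codon-aware per-locus alignment, XMFA export and concatenation;
6. p-distance / neighbour-joining phylogenetics and diversity statistics
   (Hunter–Gaston index, Nei–Gojobori dN/dS).

# Allele curation

An allele must be uppercase DNA over `{A,C,G,T}`, a multiple of 3 long,
and free of stop codons before the final codon. Ambiguity characters
disqualify a sequence from allele definition (they are tolerated downstream
by pairwise deletion in distance computations). A terminal stop codon is
retained when present. Start codons other than ATG/GTG/TTG raise a warning
flag rather than a rejection: fixing genes to "common start sites" is an
annotation problem this package deliberately does not attempt, so tolerance
is the only defensible default. Allele ids are sequential integers per
locus, assigned in insertion order and never reassigned; `define_allele()`
is idempotent on known sequences.

# The search engine

Production rMLST services delegate this step to BLAST; `ribomlst` ships its
own engine so the behaviour is fully specified and testable.

* **Seeding.** Exact shared words between contig and allele — 15 nt by
  default in nucleotide mode, 3 aa in translated mode. Seeds are clustered
  by diagonal; each cluster yields one candidate window with a ±60 bp pad.
  For genes much shorter than ~15 words (the smallest large-subunit genes
  are nearer 100 bp) a 15-mer seed cannot survive realistic divergence, so
  the effective word is capped near 1/15 of the allele length, quantised to
  {8, 11, 15} so one genome needs at most three k-mer indexes. In
  amino-acid space, where 3-mers match everywhere by chance, a diagonal
  cluster must hold at least 3 seeds before it is aligned (the classic
  multi-hit heuristic; the floor drops to 1 for peptides under 40 aa).
* **Extension.** Each window is aligned locally against the allele with
  affine gaps, match +2 / mismatch −3 / gap open 5 / gap extend 2 — the
  classic blastn defaults. A +1/−2 scheme was considered and rejected: its
  expected column score turns negative below 2/3 identity, so local
  alignments fragment before the relaxation ladder's 50 % floor is reached;
  +2/−3 stays extendable down to 60 % identity, and deeper divergence is
  the translated phase's job. The dynamic-programming primitive is
  `Biostrings::pairwiseAlignment`; the test suite checks it against an
  independent pure-R Smith–Waterman oracle at the same scoring.
* **Thresholds.** Default identity ≥ 0.70 over alignment columns and
  subject coverage ≥ 0.50. Coverage is measured against the *allele*
  length: that is the standard MLST reading and the one that makes partial
  genes detectable.
* **Overlap resolution.** Overlapping candidate hits on one contig region
  keep only the best score (ties: lowest allele id, then leftmost). This
  resolution runs *before* thresholding, so relaxing `min_identity` can
  only add hits, never remove one — a property the tests enforce. The cost
  is a rare edge case: a region whose best-scoring candidate fails the
  thresholds reports nothing even if a weaker passing hit overlaps it.
* **Translated mode.** Both sides are conceptually translated under
  bacterial code 11; identity and coverage are computed in amino-acid
  space and coordinates mapped back to nucleotides. Scoring is match +2 /
  mismatch −1 / gap open 10 / extend 1, with stops at −4 so alignments do
  not cross reading-frame boundaries. No tblastx parameterisation is
  published for this workflow; these are this package's documented choices.

With a 15 nt word, a synonymously saturated gene (a substitution roughly
every third position, nucleotide identity ≈ 2/3) structurally cannot seed in
nucleotide mode, while its protein is identical — exactly the situation the
translated phase exists for, and the behaviour the tests construct via
`saturate_synonymous()`.

# The tagging loop

`scan_isolate()` produces one primary tag per locus — the hit maximising
identity × coverage, ties to the lowest allele id then the leftmost
coordinate — plus paralogue-flagged secondary tags for further
non-overlapping qualifying hits. Status assignment:

* **complete** — the aligned allele span, extended to full allele bounds on
  the contig, lies inside the contig and passes curation;
* **partial** — the extension runs off a contig end;
* **pseudogene** — full-length but frameshifted or containing an internal
  stop (ambiguity-laden extractions land here too, since they equally
  cannot be defined as alleles);
* **missing** — no qualifying hit in any phase.

`iterative_discovery()` wraps this in the stringency ladder: start at 70 %
identity, rescan to a fixpoint (a pass that defines no new allele and
completes no new locus), relax by 5 %, repeat down to 50 %, then run the
same ladder with translated search. Coverage stays at 0.50 throughout.
New alleles are defined **only** from complete extractions — partials and
pseudogenes never enter the database. Genomes are processed in input order
and loci in catalogue order, so allele numbering is reproducible for a
fixed corpus ordering. A later complete hit supersedes an earlier partial
or pseudogene tag. The non-convergence guard is 100 passes per level.
As an offline analogue of periodically cross-checking new alleles against
an external database, a new allele identical to an allele of a *different*
locus raises a warning.

# Alignment and concatenation

`align_locus()` aligns alleles by codon: translate, align peptides
progressively, back-translate. The guide tree is average-linkage clustering
on a shared amino-acid 4-mer distance. Profiles are merged by globally
aligning their consensus peptides and projecting the resulting gaps into
every member row. This is deliberately lighter than full profile-profile
dynamic programming: rMLST alleles are close homologues in which indels are
rare and codon-sized, and the invariants that matter — every row de-gaps to
its input, every gap run is codon-sized and codon-placed — are enforced by
construction and by tests. XMFA blocks carry headers
`> isolate:start-end + locus` (1-based inclusive, always the coding
strand); `read_xmfa(write_xmfa(x))` is an identity. Concatenation pads
isolates absent from a block with gaps and records per-locus column
provenance.

# Distances, trees, diversity

`p_distance()` removes, per sequence pair, every column in which either row
carries a gap or an ambiguous symbol (pairwise deletion) and divides
mismatches by the remaining sites; a pair with no comparable sites is
flagged undefined rather than 0. `neighbor_joining()` is a Saitou–Nei
implementation with a deterministic tie-break (the pair whose cluster
representatives sort first lexicographically) and negative-branch clamping
(deficit moved to the sibling). On additive matrices it recovers the
generating topology with path lengths to 1e-9, which the test suite checks
against 100 random trees. A protein-mode distance is available for
deep-divergence datasets where multiple substitutions and extreme AT/GC
composition distort nucleotide distances.

The Hunter–Gaston index is `1 − Σ n_j(n_j−1) / N(N−1)`. The Nei–Gojobori
machinery counts synonymous/nonsynonymous *sites* per codon (fractions of
the nine single-base mutants; substitutions creating stops count as
nonsynonymous) and *differences* by averaging over all orderings of the
differing positions, excluding pathways through stop codons (renormalising;
if every pathway is blocked, all are used). Codons containing gaps,
ambiguity or stops in either sequence are dropped pairwise. Proportions are
Jukes–Cantor corrected (`d = −3/4 ln(1 − 4p/3)`, undefined and reported
saturated at `p ≥ 3/4`). The variance of dN − dS comes from a seeded
codon-position bootstrap (default 1000 replicates) because the analytic
variance of the original software is not reproduced verbatim;
`Z = (dN − dS)/se` and the one-sided p-value from the upper normal tail
test neutrality against positive selection.

# The synthetic world

`generate_scheme()` + `build_corpus()` produce the test substrate: valid
ancestral CDSs per locus (standard start, sense codons, terminal stop, with
lengths drawn from the catalogue's per-locus ranges), evolved variants with
exactly `n` substitutions (modes: unconstrained, synonymous-only,
strictly nonsynonymous), and genomes assembled as contigs with genes
embedded among uniform-composition spacers (GC 0.5 by default,
configurable to exercise compositional extremes; spacers 120–280 bp; 35 %
of genes on the minus strand; genes distributed round-robin over the
contigs). Everything is a pure function of the seed.

Intended statuses are constructed, not sampled: a *missing* locus is
omitted; a *partial* locus keeps its 5' 60 % (by default) and is placed
flush against a contig end on the plus strand (a minus-strand cut would not
abut the contig end, so the generator forces the orientation); a
*pseudogene* receives a single-base deletion in its longest homopolymer
run, emulating the dominant error mode of early pyrosequencing chemistry.
Substitution noise, when enabled, applies to spacers only — this keeps the
manifest's intended statuses exact, which is what makes manifest-equality
tests meaningful.

What the generator does **not** emulate: read-level error profiles and
assembly artefacts, repeat-induced misassembly, mobile elements, horizontal
transfer, compositional heterogeneity along the chromosome, and real
inter-locus length/diversity structure. A green recovery test therefore
establishes that the algorithms are correct on the stated world, not that
the pipeline is robust to every real draft assembly.

# Numerical choices and degenerate inputs

* Identity is matches over alignment columns (gaps included), the common
  BLAST convention.
* The scheme's per-locus length ranges are curation sanity checks
  (roughly 0.5–2 × a typical bacterial length), not biological bounds.
* Ties in rST assignment cannot arise (profiles are compared exactly);
  numbering is first-seen order, a documented convention since none is
  standard.
* Empty tag tables are an error in `tagging_summary()`; a profile built
  from no tags is all-missing; `hunter_gaston()` of fewer than two
  isolates is undefined (`NA`), as is a p-distance over zero comparable
  sites.
* All RNG-consuming functions either take a `seed` argument and restore
  the caller's RNG state afterwards, or document that they consume the
  current stream (so corpus generation composes deterministically).

# Known limitations

* The search engine is tuned for the rMLST regime (genes ≥ ~100 bp,
  divergence up to ~35 % nucleotide / seedable protein identity). It is not
  a general homology search: no E-values, no masking, no HSP chaining.
* Nucleotide search below ~70 % identity depends on chance 15-mer seeds,
  as any word-seeded method does; the translated ladder is the intended
  rescue, mirroring the original workflow's blastn-then-tblastx design.
* The progressive aligner assumes in-frame, stop-free inputs (enforced) and
  rare indels; it is not suitable for aligning pseudogenes or partials,
  which are excluded from profiles and alignments by design.
* `tagging_summary()` means are reported to 3 decimals with integer modes,
  mirroring the conventional tagging-status table layout.
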