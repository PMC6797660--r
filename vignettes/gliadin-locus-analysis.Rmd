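---
title: "Methods: alpha-gliadin locus analysis with gliadinkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alpha-gliadin locus analysis with gliadinkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the models and
procedures each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices that shape the results.

## The biological setting

α-Gliadins are monomeric wheat gluten proteins encoded by large tandem
arrays at the *Gli-2* loci. Each protein follows a fixed anatomy: a signal
peptide, a proline/glutamine-rich repetitive domain, a first
poly-glutamine run (poly-Q I), a short non-repetitive domain, a second run
(poly-Q II), and a conserved C-terminal domain; A-genome proteins end in
GIFGTN. Glutamine is encoded only by CAA and CAG, which has two
consequences the package is built around:

1. the poly-Q runs are codon microsatellites whose lengths vary greatly
   between gene copies, and account for most protein-size variation;
2. a single C→T transition at codon base 1 turns CAA into TAA and CAG into
   TAG — an instant premature stop. In a protein where a large fraction of
   codons encode Q, this is the dominant pseudogenization channel, and the
   package annotates every internal stop with that context.

Most copies in a *Gli-2* array are pseudogenes (by premature stops,
frameshifts, terminal truncations, transposable-element insertions, or
unresolved assembly gaps), and pseudogene transcripts are further depressed
by nonsense-mediated decay, so expression concentrates on the few intact
genes.

## Gene anatomy

`find_orf()` scans the three forward frames for the longest ATG-initiated,
stop-terminated ORF (ties: leftmost). Only the + strand is scanned; inputs
are assumed pre-oriented by upstream locus annotation. `min_orf_codons = 50`
separates real (even truncated) gliadin fragments from noise ORFs.

`segment_domains()` defines a poly-Q region as a maximal glutamine run of
at least `min_run = 5` residues after the signal peptide. Runs may absorb
at most `max_interruptions = 1` non-Q residue when flanked by at least 3 Q
on each side; published domain figures mark poly-Q regions without stating
a boundary rule, so this merging rule is the package's operational
definition (configurable via `segmentation_params()`). The first two
qualifying runs are poly-Q I and II; the other domains are derived from
their positions. The signal peptide is modelled as a fixed 20 residues
(configurable) rather than predicted; comparative figures mark mature
termini without stating a cleavage rule, and 20 is the canonical gliadin
signal length.

`polyq_profile()` counts Q inside each region and reports the
glutamine-codon fraction of the CDS as (#CAA + #CAG) / total codons,
including the terminal stop codon in the denominator.

## The codon-aware aligner

Mutation-event detection rests on pairwise global alignment of a candidate
gene against an intact reference. A generic affine-gap aligner fails on
this gene family in two specific ways we observed directly:

* inside a CAA/CAG microsatellite, an in-frame length difference (a
  multiple of 3) is often split into two gaps of non-multiple-of-3 length,
  because re-pairing a few codons avoids CAA-vs-CAG mismatches; this
  fabricates frameshifts and breaks the codon register on which stop
  detection depends;
* charged end gaps make a 5′-truncated gene align by scattering internal
  deletions instead of leaving a clean terminal overhang.

`align_global()` therefore implements a Needleman–Wunsch variant with
three properties (in C++, states tracking gap length mod 3):

* affine gaps (`gap_open = -5`, `gap_extend = -2`, `match = 2`,
  `mismatch = -3`);
* an extra `frameshift_penalty = -30` charged when an **internal** gap run
  closes at a length that is not a multiple of 3 — in-frame poly-Q and
  repeat-count variation then aligns as 3-periodic gaps and the reading
  frame survives across it, while true frameshifting indels still align as
  the short non-3 gap they are (no cheaper representation exists);
* free end gaps, so terminal truncations appear as clean unaligned
  reference overhangs.

Ties break in a fixed state order, making alignments deterministic. A band
(`band = 200` beyond the length difference) accelerates the dynamic
program; it comfortably covers terminal truncations (absorbed by the
length-difference term) plus internal poly-Q drift. Pass `band = 0` for
sequences with large unexcised insertions (the reference pseudo-alignment
used for trees does this internally).

## Pseudogene classification

`classify_gene()` runs the cascade:

1. **Assembly gaps**: runs of ≥ 10 `N` are typed `gap`.
2. **TE excision**: iterative best-hit local alignment against the TE
   library (Biostrings); a hit of ≥ 100 bp at ≥ 80% identity is excised
   and the scan repeats, so nested insertions resolve from the inside out.
   Catalogue lengths are TE-excised lengths. A cheap exact 24-mer
   prescreen skips library elements that cannot reach the identity/length
   floor.
3. **Reference choice**: among the supplied intact genes, candidates are
   shortlisted by shared 15-mers and the global alignment score decides
   between the top two (ties: input order). With no reference, stop
   detection falls back to frame 0.
4. **Truncations**: ≥ 15 bp of reference unaligned at an end →
   `deletion_5prime` / `deletion_3prime`.
5. **Frameshifts**: each maximal internal indel with length mod 3 ≠ 0 is
   one event; in-frame indels are not events.
6. **Premature stops**: every query base inherits the reference
   reading-frame phase from the column it aligns to, and bases inserted
   relative to the reference continue the phase of the preceding aligned
   base. Query codons are then read wherever three consecutive bases carry
   phases 0,1,2. This matters: projecting the query onto the reference
   grid instead would silently drop stops that sit inside query-specific
   poly-Q extensions (insertions relative to the reference). The codon
   aligned to the reference's terminal stop is never counted. Each stop
   records its codon, whether an adjacent in-frame codon is CAA/CAG
   (`next_to_Q`, the strict-adjacency definition used by printed
   catalogues), whether it lies in a reference poly-Q region (reported
   separately, since narrative counts of "in poly-Q regions or next to Q"
   mix the two definitions), and `q_to_stop_transition`: the stop is TAA
   with reference codon CAA, or TAG with CAG — one C→T at base 1. Note the
   transition call compares homologous codons, so it is exact against a
   progenitor-like reference and conservative against a diverged paralog
   whose Q-codon choice differs at that position.

A gene is a pseudogene iff at least one event was detected; stops created
by frameshifts count like any other internal stop, which matches how
printed catalogues type rows as "frameshift and stop codon".

## Epitope scanning

`scan_protein()` slides a 9-residue window and reports Hamming distance
≤ `max_mismatch` (0 or 1) against each configured epitope; overlapping
occurrences, including of the same epitope, are each counted — required
for 33-mer-like regions, which contain six overlapping copies of three
epitopes within 33 residues. `detect_clusters()` reports maximal sets of
mutually overlapping exact hits with span ≤ 33, ≥ 6 hits and ≥ 2 distinct
epitopes (all configurable). Only the four spelled-out DQ2.5 9-mers are
built in; other epitopes (e.g. the DQ8 family) must arrive via
`read_epitope_config()` so no unverifiable sequence is hard-coded.

## Phylogeny

`pairwise_distance()` implements p-distance (default) and Jukes–Cantor
with pairwise deletion of gap/`N` sites. The distance model behind
published α-gliadin trees is not stated, so the package does not treat any
published topology as a target; p-distance is the assumption-free default
and JC the correction for multiple hits. `nj_tree()` is the Saitou–Nei
agglomeration with the Q-criterion, row-major first-minimum tie-break
(deterministic), and negative branch estimates clamped to zero (deficit
kept in the `"clamped"` attribute). `bootstrap_support()` resamples
alignment columns with replacement and reports, per internal edge of the
point tree, the percentage of replicate trees containing the same
bipartition; fixed seeds reproduce supports exactly. Alignments are an
input; `reference_align()` offers a reference-guided pseudo-alignment
(projection onto a common reference) adequate for closely related family
members, and `filter_alignment_coverage()` drops rows under 70% non-gap
sites, since pseudogenes with large deletions distort distances.

## Expression

A read is assignable to a gene iff its best cost-optimal alignment
(mismatch 2, indels 3) covers ≥ 90% of the read at ≥ 99% identity —
identity defined as matches / alignment columns, the package's operational
reading of stringent-mapping tool settings. The engine seeds candidate
placements with 15-mers (top three diagonals per gene by seed votes) and
rescores each with a banded dynamic program, global in the read with free
soft-clipping only past gene ends, clipped bases counting against the
length fraction. Ambiguous reads (cost ties across genes) follow
`ambiguous_policy`: `discard` (default, conservative), `split`
(fractional) or seeded `random` — the multi-mapping behaviour of the
original mapping tool being unstated, the three policies bound the answer.
FPKM is reads × 10⁹ / (total_assigned × length), one single-end read = one
fragment, so the conservation identity
Σ fpkm·length·total/10⁹ = total holds exactly.

## The synthetic-data generator

`sim_config()` fixes the study conditions; every stage of the pipeline is
exercised against its ground truth. The generator emulates:

* the two-poly-Q prolamin architecture, with poly-Q I drawn from 9–30 and
  poly-Q II from 6–16 Q (published intact-gene ranges are 9–41 and 6–32;
  the defaults sit inside them), CAA:CAG usage 2:1 (no published codon
  ratio; 2:1 reflects the genome-wide CAA bias in wheat prolamins and is
  configurable);
* planted DQ2.5 epitopes in the repetitive domain (defaults: Glia-α1a and
  Glia-α3, the A-genome pattern). The filler repeat unit is glutamine- and
  tyrosine-free by design so a planted epitope can never be extended or
  duplicated across a junction — planted-epitope truth stays exact;
* per-gene mutation events at the frequencies of the published wild emmer
  catalogue: stop gains 0.7 (1 + Poisson(1.1) stops when present, matching
  59 stops across 28 stop-bearing genes), frameshifts 0.175, 5′ truncations
  0.2, 3′ truncations 0.05, TE insertions 0.1, assembly gaps 0.05. Every
  stop gain is a C→T at base 1 of a CAA/CAG codon. Event sites are chosen
  disjoint and inside the retained region, so each injected event remains
  detectable and truth labels stay exact;
* shared ancestry: all genes of a cohort read their Q codons from one
  ancestral CAA/CAG stream (per run, from the run start), because real
  paralogs inherit codon choices from a common ancestor — without this,
  the C→T transition call against a non-progenitor reference would be
  undecidable for roughly a third of stops, an artifact of independent
  codon sampling, not of the biology;
* background divergence as synonymous third-position substitutions at rate
  0.3 per fourfold-degenerate codon, giving ~90–95% pairwise identity —
  the paralog-divergence regime in which a stringent 99%-identity mapper
  can separate family members, and consistent with the deep splits visible
  in published α-gliadin trees. Synonymous-only divergence never alters
  the protein, so domain, poly-Q and epitope truth survive it;
* expression with intact baseline abundance 1 and pseudogene multiplier
  δ = 0.1 (the NMD-depression factor; published profiles show intact genes
  at FPKM > 10⁴ and most pseudogenes far below), 100-bp single-end reads,
  substitution errors at 0.5%.

What it does **not** emulate: slippage dynamics of the microsatellites,
sequence evolution along a tree (divergence is star-like from one
ancestor), non-synonymous divergence between paralogs, indel sequencing
errors, paired-end fragments, and reversion events. Passing tests
therefore demonstrate correctness of the pipeline's logic under realistic
lesion spectra and divergence levels — not robustness to every artifact of
real assemblies.

The TE library is five synthetic elements (150–600 bp with terminal-repeat
decorations) whose labels (Ada, Manor, Sabrina, Fatima, Inga) are
mnemonics for wheat TE families; the sequences are deterministic and
synthetic.

## Locus summaries and orthology

`summarize_catalogue()` is pure aggregation; blank count cells in printed
tables parse as 0, the only reading under which "28 of 31 pseudogenes
carry a stop" is consistent with the row data. `gene_density()` is
span/genes in kb — published per-locus figures derived from first-to-last
gene distances do not always equal any division of the printed numbers, so
the package states its definition and leaves the discrepancy visible
rather than tuning to match. `shared_te_orthology()` calls a gene pair
orthologous when both carry the same TE label at the same gene-relative
offset (± 30 bp) inside the CDS, or when their upstream intergenic
intervals share ≥ 2 TE labels in the same order — explicit,
configurable operationalizations of the shared-insertion reasoning used to
pair genes between homologous loci.

## Problem sizes and determinism

The test suite and the acceptance script use desk-scale sizes chosen to
make the statistics decisive while keeping runs short: cohorts of 200
genes for classifier recovery, 50,000 reads for expression, 200 bootstrap
replicates, additive matrices of 4–12 taxa. All randomness flows from
explicit seeds; reruns are byte-identical, including FASTA output and the
pipeline's JSON report. Genome-scale analyses (multi-megabase locus
reconstruction, tens of millions of reads) are out of scope; the
property-based synthetic suites stand in for them.

## Known limitations

* The frameshift penalty makes in-frame repeat variation align cleanly,
  but two true frameshifts closer than a codon apart can merge into one
  reported event.
* `q_to_stop_transition` against a diverged (non-progenitor) reference is
  a lower bound: stops inside query-specific poly-Q extensions have no
  aligned reference codon and are conservatively flagged `FALSE`.
* The read mapper models substitutions and short indels within a ±4
  diagonal band; structural differences larger than that within a read are
  treated as unmappable.
* Orthology calls use TE labels, not TE sequence similarity; a mislabelled
  library propagates to the calls.
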