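---
title: "Methods: reciprocal-best-hit orthology, re-annotation and distance phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reciprocal-best-hit orthology, re-annotation and distance phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoclock)
```

## The inference chain

`orthoclock` re-implements, as a tested and reusable pipeline, the
comparative-genomics chain used to catalogue circadian-clock genes across
plant genomes: protein-space database search with E-value ranking, iterative
cross-species reciprocal-best-hit (RBH) classification with gene-family
expansion, splice-site-aware re-annotation of gene models, codon-preserving
multiple alignment, and neighbour-joining trees with bootstrap support. Every
stage is exercised against a birth--death simulator of gene families whose
ground truth (gene tree, event list, per-pair orthology) is known, so the
whole chain is testable without any database downloads.

## Sequence search

Searches run in protein space: at deep divergences (monocots and dicots
separated on the order of 140 My) synonymous sites are saturated and the
orthology signal lives in amino-acid similarity, so CDS records are
translated before searching and genomic records are not searchable. The
engine is full Smith--Waterman (no heuristic seeding) with BLOSUM62 and
affine gaps (open 11, extend 1) via Biostrings. E-values use the
Karlin--Altschul form $E = K m n e^{-\lambda S}$ with the published ungapped
BLOSUM62 constants ($\lambda = 0.3176$, $K = 0.134$) applied to gapped
scores. That is a deliberate approximation: absolute E-values are biased,
but the pipeline only consumes hit *rankings* and *E-value ratios*, which
the monotone transform preserves. The reporting threshold defaults to
$E \le 10^{-5}$.

Determinism matters more here than in a general search tool, because calls
must be bit-reproducible: hits sort by (E-value ascending, bit score
descending, subject id ascending), and permuting database records never
changes a hit list.

## Reciprocal-best-hit classification

Seed genes (the "Arabidopsis role") are searched against every other
species; the top hit and every hit with a *similar* E-value join the search
frontier, so each discovered candidate is itself subjected to cross-species
reciprocal searches. The procedure reaches a fixed point because
(gene, target-species) pairs are never re-searched. Calls:

* **orthologue** -- mutual top hits between two species. Mutual-top-hit
  components are additionally checked for full clique consistency (each
  member the top hit of every other member in its species); components that
  fail keep their per-pair calls but carry a `partial_clique` warning in the
  evidence trail.
* **orthologue with ambiguity flag** -- one-to-many situations: a home
  species paralogue of the mutual partner also resolves to the same gene, or
  a gene's forward top hit reciprocates to its home-species paralogue
  (co-orthologues). These are never silently resolved to one-to-one.
* **paralogue** -- same-species genes that are similar-E-value co-members
  and/or reciprocate to the same partner set.
* **unresolved** -- everything else that co-occurs in the graph.

"Similar E-value" is not a standard quantity; the default is a ratio of 10
(one order of magnitude), with a fallback window of 2 bits below the top bit
score when the top E-value underflows to zero. Both are configurable. The
all-species clique reading of orthologue confirmation, and the
ratio-10 default, are design choices of this package: they are the
strictest readings that still recover one-to-many families, and the
warnings make the weaker evidence visible rather than suppressed.

A species whose database yields no hit at all is recorded as an *absence*
(the pattern of a basal lineage simply lacking a family) rather than an
error.

## Gene-model re-annotation

Gene models are 1-based closed intervals on the forward strand with a strand
flag (GFF3 convention); all internal logic is transcript-oriented after
strand normalisation. Validation enforces the two sequence-intrinsic
curation rules: GT..AG intron boundaries (strand-aware) and ORF maintenance
(no internal stops; complete models begin ATG, end with a stop, and are
divisible by 3). Non-canonical splice sites (GC--AG, AT--AC) are rejected
outright; the rule is stated without exceptions and a relaxation would
silently change downstream structure comparisons.

Re-annotation aligns evidence CDS (transcripts or homologues) to the genomic
sequence with an exact spliced-alignment dynamic programme: global in the
evidence (every evidence base must be matched, mismatched or explicitly
deleted), free end gaps in the genomic, and an intron move that may skip any
GT..AG genomic interval of at least 4 nt at a flat penalty. Scoring defaults
are match +2, mismatch -3, gap open 5, gap extend 2, intron penalty 4. The
intron penalty is intentionally small: it must undercut both a short
terminal-exon mismatch (so 1--2 nt terminal exons anchor correctly) and an
evidence deletion of the same span, while staying above zero so intron count
is minimised. Models whose evidence is not fully represented, or whose
spliced CDS fails the ORF rules, are flagged partial -- never returned as
silently valid.

One identifiability caveat: two intron placements that splice to the same
CDS (possible when the bases flanking a boundary repeat inside the intron)
are indistinguishable from (genomic, CDS) evidence alone. The round-trip
contract is therefore splice-equivalence -- the recovered model splices to
the true CDS with the true number of canonical introns -- which on the
simulator's fixtures coincides with exact coordinate recovery.

Structure comparison maps intron positions of two models into shared
protein-alignment coordinates (codon index + phase) and reports conserved
introns with length ratios, lineage-specific gains, and UTR length
differences; it is symmetric up to label swap.

## Codon-preserving alignment

Protein alignment is standard progressive alignment: pairwise shared 3-mer
distances, a neighbour-joining guide tree, and profile--profile
Needleman--Wunsch (BLOSUM62, affine gaps, deterministic tie-breaks:
diagonal, then gap in the second profile) at each merge. Equivalence with
any particular legacy aligner's output is *not* a contract -- the
downstream invariants are: rows ungap to their inputs exactly, and the
nucleotide projection preserves codon structure. Stop codons are trimmed
before alignment and never aligned. Back-translation replaces each aligned
residue by its source codon and each gap by `---`, and refuses (with the
gene and position named) any CDS that does not translate to its protein
row. Complete-deletion (`mask_incomplete_columns()`) removes every codon
column containing a gap or ambiguity symbol in any row, the conventional
preparation for distance estimation, and commutes with row reordering.

## Distances, trees, support

Distances are Tamura--Nei (TN93) with parameters shared across pairs
("composite likelihood" style): base frequencies are pooled over the whole
alignment once, and each pair's transition/transversion proportions enter
the closed-form TN93 distance under those shared frequencies. The two-row
case collapses to the plain pairwise TN93 estimator, the Jukes--Cantor
limit is recovered on JC-simulated data within 2% at a few kb, and
divergence recovery on TN93 data is within sampling error at 50 kb --
these, not numeric equality with any GUI implementation, are the contract.
Pairs whose corrected distance diverges are flagged *saturated*; tree
building refuses such matrices rather than guessing.

Tree estimation is Saitou--Nei neighbour joining with the Studier--Keppler
Q criterion, lexicographic tie-breaks on the joined label pair
(bit-reproducibility again), and negative branch estimates clamped to zero
with a warning. Bootstrap support resamples *codon columns* by default --
sites within a codon are not independent, and resampling whole codons keeps
the resampled alignments in frame; nucleotide-column resampling is
available as a switch. The default is 2000 replicates with supports shown
when they exceed 50%; supports below the display threshold are retained in
the object and only suppressed by the Newick renderer. Rooting places the
root on the edge separating a monophyletic outgroup; a non-monophyletic
outgroup is an error unless the manual root-edge override is set, which
roots on the first label's branch (the fallback used when no true outgroup
exists in a family). Pseudogene-flagged records are excluded from tree
input, with the removal count reported.

## The synthetic-data generator

`simulate_family()` draws duplications and losses as Poisson processes
along the branches of a species tree (rates per unit branch length, i.e.
per expected substitution per site), evolves the ancestral CDS along the
resulting gene tree under TN93 (Jukes--Cantor by default), and emits the
full ground truth: the gene tree with speciation/duplication node labels,
the event list, the per-pair orthology relation (orthologue iff the last
common event is a speciation), true gene models and GT..AG genomic
sequences. The default six-species tree (three grasses, two dicots, moss as
the basal outgroup) keeps every pairwise path at or below ~0.5
substitutions per site -- the regime in which protein-space RBH calling is
informative; the default rates (duplication 0.3, loss 0.1 per unit branch
length) produce the mix of single-copy families, lineage-specific
duplicates and absences that the classifier must handle, at roughly one
event per third family.

Three deliberate constraints keep simulated genes analysable end-to-end:
the start codon is pinned to ATG, the terminal stop codon is retained, and
internal codons that mutate into stops are redrawn from their parent codon
(rejection sampling). This biases per-site substitution counts by well
under a percent at the divergences used and keeps every simulated CDS a
clean ORF. Intron positions are drawn once per family from the ancestral
CDS and shared by all members (structures are conserved within families;
lineage-specific gains are constructed explicitly in tests), while intron
lengths and interiors are per-gene.

What the generator does *not* emulate -- and hence what green tests do not
establish about real data: indel evolution inside coding sequence
(alignment difficulty here is driven by substitution divergence only),
codon-usage and GC-content structure, rate heterogeneity among sites,
non-canonical splice sites, UTRs and alternative isoforms, and assembly or
annotation artefacts. The catalogue fixture is transcribed printed data,
not a computation, and the pipeline's precision/recall numbers are
statements about the simulator's regime.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed, and fixed-seed runs are
byte-identical down to the pipeline manifest checksums. The test-suite and
acceptance-script problem sizes are chosen to estimate each property
stably at desk scale: 50 replicate families for classifier
precision/recall, 100+ fixtures for re-annotation round-trips, 2 kb
alignments with 200 bootstrap replicates (the 2000-replicate default is the
published convention for final trees) over 20 simulation repeats for
support calibration, and 50 kb sequences for distance recovery.

## Known limitations

* RBH classification cannot see hidden paralogy: when duplication precedes
  speciation and losses are asymmetric, cross-species paralogues can be
  mutually nearest neighbours and will be called orthologues -- tree-based
  reconciliation, deliberately out of scope, is the usual remedy.
* The E-value layer is a ranking device, not a calibrated significance
  estimate.
* `reannotate()` searches one locus; it is not a genome-wide gene finder,
  and with homologue (rather than self) evidence the recovered boundaries
  inherit the evidence's divergence.
* The progressive aligner has no iterative refinement; badly gapped
  families should be aligned externally and imported.
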