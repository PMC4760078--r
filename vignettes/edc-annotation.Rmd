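---
title: "Annotating simple EDC genes in sauropsid genomes"
author: "EDCtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating simple EDC genes in sauropsid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EDCtools)
```

## The biological problem

The Epidermal Differentiation Complex (EDC) is a gene cluster, delimited by
S100A genes, that encodes the structural proteins of cornifying epidermal
keratinocytes. In sauropsids (reptiles and birds) most of these genes are
"simple" EDC (SEDC) genes with a stereotyped two-exon architecture: a short
noncoding exon 1 driven by a TATA-box promoter, a single intron, and a
second exon containing a short 5' UTR and the entire coding sequence.
Because the encoded proteins have extremely biased amino-acid compositions
(glycine/serine-rich, cysteine/proline-rich, aromatic-rich, or the
beta-sheet-forming beta-keratins) and highly repetitive sequences, generic
gene predictors annotate them poorly, and a bespoke rule-based screen is the
established approach.

EDCtools implements that screen as a tested, reproducible pipeline:

1. **Gene finding** — a six-frame ORF scan constrained by the SEDC signals,
   plus a translated seed-and-extend homology search with iterative query
   expansion and frameshift-aware pseudogene detection.
2. **Protein characterization** — composition profiles, combined bias
   metrics, tandem repeats, terminal motif profiles, beta-core detection,
   and family classification.
3. **Locus analysis** — gene order, EDC delimitation by the S100A anchors,
   synteny links and collinear blocks between two loci, and detection of
   family members translocated outside the EDC.
4. **Phylogeny** — a distance-based companion analysis for beta-keratin
   core segments with classical bootstrap support.
5. **Simulation** — a synthetic-genome generator that plants SEDC genes
   with machine-readable ground truth, so every stage can be benchmarked
   without external downloads.

## The gene model and the scanning rules

A candidate SEDC gene must satisfy three rules, applied identically by the
simulator and the scanner:

* the conceptual translation encodes a protein of **50–500 amino acids**
  (bounds inclusive), beginning at the first ATG of its open segment
  (internal ATGs are suppressed; one ORF per stop codon per frame);
* a **splice acceptor AG** ends 10–30 nt upstream of the A of the start
  codon. The 5' UTR length is counted from the base after the AG to the
  base before the ATG, bounds inclusive, and the *innermost* qualifying AG
  is taken;
* a **noncoding exon 1**, defined by a TATA box followed by a GT splice
  donor at a distance of 60–90 nt, lies within a configurable window
  (default 1000 nt) upstream of the acceptor. Distance is measured from
  the first base of the TATA motif to the first base of the GT, and the
  qualifying TATA/donor pair nearest the acceptor is taken.

Conventions the literature leaves open were fixed once and are shared by
generator and scanner, so that exact-coordinate recovery is well defined:
the TATA motif defaults to the canonical consensus `TATA[AT]A` (a regular
expression parameter); coordinates are 1-based inclusive throughout, with
GFF3 output in the standard 1-based inclusive convention; the CDS interval
includes the stop codon; intron length must be at least 20 nt.

ORFs whose CDS would contain an ambiguous base are rejected; ORFs running
into an assembly gap (an N run of at least 10 nt) or the scaffold edge are
kept as *partial* candidates. Overlapping same-strand models are resolved
by highest homology score, then longest CDS, then leftmost position.

## Translated homology search

`translatedSearch()` reimplements a tBLASTn-style search: exact 4-mer word
seeds (plus single-substitution neighbors scoring at least 13 under
BLOSUM62) are located in all six frame translations, seeded regions are
merged, and each region is extended by local affine-gap alignment
(BLOSUM62, gap open 11, gap extension 1 — the conventional operating point
of translated searches; all parameters are configurable). HSPs scoring at
least 55 are reported. `iterateAnnotation()` runs rounds of scanning in
which the translations of newly found models join the query set
(deduplicated at 100% identity) until a fixpoint; homology clusters not
explained by any ORF model trigger a local rescue scan with a relaxed
minimum protein length (20 aa), and rescued models that fail the exon-1
rules are retained as partial models with homology evidence, because the
homology screen is logically independent of the promoter/splice rules.

## Pseudogene detection

`detectPseudogene()` aligns a genomic locus to an intact reference protein
with a frameshift-aware dynamic program: codon steps consume 3 nt;
frameshifting steps consume 2 or 4 nt at a penalty (default 12); stop
codons aligned to a reference residue are scored as stop emissions
(penalty 8); whole-codon indels have linear per-codon cost (10), which
keeps the recurrence vectorizable. The alignment is global in the
reference with free end gaps on the DNA. Premature stops and frameshifts
on the optimal path are reported in reference codon coordinates; loci
scoring below 30% of the reference self-score are reported as
*unalignable*, which is distinct from *intact*.

## Composition classes and family assignment

Family classification uses a fixed precedence: (1) a homology-based family
assignment at \(\ge\) 35% identity; (2) *beta-keratin* when a 34-residue
window has mean Chou–Fasman beta-sheet propensity above threshold;
(3) *CP-rich* when the combined cysteine+proline fraction exceeds 0.5
(anchored to the observation that C+P exceeds half of all residues in the
most biased SEDC proteins); (4) *GS-rich* when glycine+serine exceeds 0.5;
(5) *aromatic-rich* when F+W+Y+H reaches 0.25 — a placeholder default, as
no numeric definition of "aromatic-rich" is established; otherwise
*other*. Histidine is counted among the aromatics deliberately, because
EDAA-type proteins are rich in histidine and tyrosine.

The beta-core propensity threshold defaults to **1.30**. The mean
Chou–Fasman beta propensity of typical (unbiased) protein sequence is
about 1.03 with a standard deviation of roughly 0.06 for a 34-residue
window mean, so a cutoff near 1.1 fires on a large fraction of ordinary
proteins once many windows are scanned; 1.30 sits more than four standard
deviations above the unbiased mean while remaining well below the window
means of genuine beta-cores (about 1.4–1.5). A profile mode (position
specific scoring over user-supplied curated cores) is available when a
seed alignment exists.

## The synthetic genome

`buildTruthSet()` emulates the architecture the annotation procedure is
designed for: tandem family blocks of two-exon genes between two S100A
anchor intervals, decoy ORFs without the flanking signals, pseudogenized
copies carrying a recorded premature stop or frameshift, N-run gaps
truncating a gene, and translocated family copies planted outside the
anchors next to a named non-EDC anchor. Family members descend from a
common ancestor protein (15% within-family divergence by default), which
makes homology search and ortholog linking meaningful. "Unbiased"
background proteins use average globular-protein residue frequencies.

Background sequence is generated so that the planted genes are the *only*
qualifying structures: filler carries no TATA motif, introns end with a
stop-codon block covering all three frames (so the planted ATG is always
the first start of its open segment), 5' UTRs are G-free (so the planted
acceptor is the innermost AG), and after assembly the scaffold is
re-scanned and any accidental qualifying structure is disrupted by single
background-base edits or synonymous codon substitutions inside planted
CDS (silent for the planted protein). Every edit is validated by a local
re-scan before it is accepted, and rare draws whose signals cannot be
disentangled are rejected and rebuilt from a re-derived seed,
deterministically. This is what makes "precision = recall = 1 at
coordinate tolerance 0" a meaningful, reproducible benchmark rather than a
statistical accident.

What the simulator does *not* emulate: sequencing error, nucleotide-level
evolution along a phylogeny (divergence is protein-level and positional),
repeat-induced assembly collapse, GC heterogeneity, and transcriptional
evidence. Passing the recovery benchmark therefore shows the scanner
implements its rules exactly; it does not show that the rules themselves
capture every real SEDC gene, where gaps, diverged signals and assembly
artifacts dominate the error budget.

## Phylogeny companion

Beta-keratin relationships are assessed on the unambiguously aligned core
segment of the alignment (exposed as a column-range parameter, 1-based
inclusive, because any such range is specific to the alignment at hand).
`progressiveAlign()` builds a guide tree by UPGMA on 3-mer count distances
and aligns profiles with global affine-gap dynamic programming; merge
orientation is canonicalized so the result does not depend on input
order. Distances are p, Poisson (\(-\ln(1-p)\)) or the protein Kimura
correction (\(-\ln(1 - p - 0.2p^2)\)); pairs sharing fewer than 10
non-gap columns are flagged missing. Trees are built by neighbor joining
(negative branch lengths clamped to zero with the deficit moved to the
sister branch) and supported by classical bootstrap over alignment
columns. Classical bootstrap supports are conservative relative to
ultrafast-bootstrap values; the conventional interpretive thresholds
(\(\ge\) 90 supported, \(\ge\) 95 strongly supported) are still applied
by `cladeSupport()`. Maximum-likelihood tree search is deliberately out of
scope; the distance companion answers the same monophyly questions at
desk scale.

## Reproducibility and problem sizes

Every stochastic step takes an explicit integer seed, and derived seeds
are computed with a deterministic mixing function, so identical
configurations yield bit-identical outputs (including GFF3 files). The
test-suite and acceptance benchmarks run at deliberately modest sizes
chosen to exercise every code path while completing quickly on one CPU:
the default synthetic genome carries 12 genes in 3 families on a ~12 kb
scaffold; oracle-equivalence checks use 4–5 kb scaffolds; pseudogene
typing uses 100 simulated single-mutation loci of 80 codons;
classification accuracy uses 1000 draws of 150 residues per class; the
clade benchmark uses two families of 8 taxa with 60-residue sequences,
within-family identity ~0.8 and between-family identity ~0.4, with 200
bootstrap replicates per run.

## Known limitations

* Real scaffolds violate the clean-background assumptions; on genuine
  genomic sequence the scanner reports what the rules imply, including
  partial and overlapping candidates near assembly gaps.
* The expression evidence of real studies (RNA-seq support) enters only as
  an optional per-gene flag; no read processing is provided.
* Exon 1 is delimited only by its TATA box and donor; its true 5' end is
  not modeled, and the scanner reports the TATA-to-donor span.
* The translated search uses exact-word seeding with a single-substitution
  neighborhood; extremely diverged homologs (<~30% identity) may require
  iterative rounds or external search results to be found.
* Frameshift positions inside homopolymeric or repetitive codon context are
  fundamentally ambiguous; the aligner reports one optimal placement, which
  can differ from the mutated base by more than one codon in such runs.
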