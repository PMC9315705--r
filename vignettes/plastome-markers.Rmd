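---
title: "Comparative plastome analysis and diagnostic marker design with plastmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis and diagnostic marker design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastmarker)
```

## The problem this package addresses

Chloroplast genomes of closely related grasses — sugarcane (*Saccharum*)
and its interbreeding relatives are the motivating case — are small
(~141 kb), structurally frozen, and maternally inherited. Within such a
species complex the plastomes are nearly identical: they differ by tens of
SNPs and short InDels, with no rearrangements. That makes them ideal both
for resolving maternal phylogeny and for building cheap PCR markers that
assign a sample to its species: an InDel shifts a band on an agarose gel,
and a SNP can be converted into a band shift with a CAPS or dCAPS assay.

`plastmarker` implements the full desk-side workflow on assembled genomes:

1. **Quadripartite structure**: find the two identical inverted repeats
   (IRa/IRb) that separate the large and small single-copy regions
   (LSC/SSC), and rotate every genome into a canonical LSC-first frame.
2. **SSR scan**: perfect microsatellites with the classic MISA thresholds.
3. **Collinear alignment and variant calling**: a banded global aligner
   merged center-star around a reference; SNPs and left-aligned InDel
   events; region classification (CDS / intron / tRNA / rRNA / intergenic
   spacer, labelled by flanking genes).
4. **Nucleotide diversity**: DnaSP-style sliding-window Pi, per-region and
   per-species summaries, hotspot listing.
5. **Diagnostic variants and markers**: sites fixed within species and
   differing between them; InDel marker design; dCAPS design with
   in-silico PCR and restriction digestion as the validation oracle.
6. **Phylogeny**: shared single-copy protein-coding genes, concatenated,
   neighbor-joining with a seeded bootstrap.
7. **A simulator** that generates the whole world above with ground truth,
   so every stage is testable without downloading anything.

## The models and their assumptions

### Structure detection

The two IRs of a plastome evolve in concert and are expected to be exact
reverse complements. Detection therefore looks only for *exact* inverted
repeats: seed 20-mers matched between the doubled sequence (to handle the
circular origin) and its reverse complement, grouped by anti-diagonal and
extended maximally. The longest pair wins; ties between distinct maximal
pairs raise an error rather than picking silently, because a ~22.8 kb IR
is unique in real plastomes and ambiguity signals a pathological input.
The default minimum IR length (1,000 bp) excludes short dispersed
repeats. Boundary placement is maximal exact extension, which can differ
from annotation-based conventions by a base or two when a junction base
happens to be complementary; segment length totals are unaffected. The
SSC is reported in the orientation found — plastomes exist as two
"flip-flop" isomers and the package does not fabricate a strand.

### Alignment and variant semantics

Because the genomes are collinear and near-identical, multiple alignment
reduces to banded global pairwise alignment against a reference (Gotoh
affine gaps: match +1, mismatch −2, gap open −5, gap extend −1, band 200
columns) merged center-star. The band makes alignment linear-time; a best
path touching the band edge, or genomes differing in length by more than
1%, aborts with a collinearity error — at that point you should supply an
externally computed alignment (`read_alignment()`), which the rest of the
pipeline accepts verbatim.

Variant semantics mirror haploid genome comparison: one SNP per
polymorphic substitution column; consecutive gap columns in a sample
merged into one InDel event; events anchored on the preceding reference
base and left-aligned, so a gap placed anywhere in a homopolymer yields
the same record. Cells with `N` are missing data: they never create
alleles and exclude a sample's call at that site. Read-level quality
filters from mapping-based pipelines have no analogue here and are
deliberately absent — the inputs are assemblies, not reads.

### Nucleotide diversity

Pi in a window is the mean over sequence pairs of differences per
compared site. Complete deletion (drop a column if any sequence has a gap
or `N` in the window) is the default, matching DnaSP's site handling;
pairwise deletion is available behind a flag. Windows advance over
*alignment* coordinates (500/250 bp defaults); since InDels are sparse the
difference from reference coordinates is at most tens of bp. Per-region
averages weight windows (by midpoint assignment), not sites — a tolerance
source when comparing against site-weighted numbers; because a window is
assigned by its midpoint, a junction-straddling window can bleed
single-copy variation into an IR mean, so the summary also reports
`pi_sites`, the exact Pi over each region's own columns (this is the
quantity that is exactly zero for invariant IRs). Per-species Pi is
computed on each species' subset of rows over the whole alignment.

### Marker design

A variant is *diagnostic* when every sample inside each species carries
one allele and at least two species differ; no frequency threshold is
used, matching the "species-specific" usage in this literature. The
induced partition of species gives the marker's category: three-way,
two-vs-rest, or one-vs-rest.

InDel markers need only resolvable length differences (default ≥ 10 bp on
2–3% agarose; published plastome markers go down to 15 bp) and primers on
flanks that are conserved across *all* samples — any variant, gap or `N`
under a primer disqualifies the site.

dCAPS design enumerates, for each enzyme, strand and placement of the
recognition site over the SNP: the site bases beyond the SNP must already
match the template; site bases under the primer may be introduced as
deliberate mismatches (at most 1, never at the 3' terminus; the primer's
3' end sits one base before the SNP). A placement that needs zero
introduced mismatches is a plain CAPS marker and is flagged as such.
Every candidate is verified end-to-end by in-silico PCR plus digestion on
one representative genome per species, and emitted only if exactly one
allele's product is cut and the band patterns differ by the resolvability
threshold. Primer acceptance rules are deliberately lightweight (length
18–26, GC 30–70%, Wallace-rule Tm 2(A+T)+4(G+C) in 50–68 °C, homopolymer
≤ 5): band sizes, the quantity markers are scored on, do not depend on a
thermodynamic model. `relaxed_rules()` exists for toy constructs whose
flanks could never satisfy field rules.

In-silico PCR finds primer binding sites with an exactly matching
3'-terminal base and up to two mismatches elsewhere, in either
orientation, on circular or linear templates; the smallest convergent
product ≤ 5 kb wins, several equally small distinct products raise an
ambiguity error, and primer bases (including deliberate mismatches) are
incorporated into the product — which is precisely what makes a dCAPS
assay work. Products are reported on the template's top strand.

Digestion cuts once per physical site occurrence, at the enzyme's
top-strand offset. For staggered palindromic cutters (both shipped
enzymes, TaqI `T^CGA` and XbaI `T^CTAGA`) this convention cannot
simultaneously make reverse-complement digestion an exact mirror: the
mirrored cut shifts by `site_length − 2·offset` (2 bp). Fragment sizes of
a reverse-complemented product are therefore reversed only to within that
stagger — far below gel resolution — while fragment sums are always exact.

### Phylogeny

Genes present exactly once in every taxon (IR-duplicated genes are
excluded by definition) are spliced on the coding strand, aligned per
gene, and concatenated with recorded partitions. The tree is Saitou–Nei
neighbor joining on p-distances or JC69 distances with pairwise deletion,
a deliberate desk-scale stand-in for maximum-likelihood inference: for
near-identical plastomes the topology is carried by shared SNPs, which
distance methods recover, and NJ is exact on additive distances. The
bootstrap resamples alignment columns via site-pattern compression (a
multinomial draw over distinct column patterns), making 1,000 seeded
replicates essentially free; supports are bipartition frequencies in
percent. Partition records are carried for interoperability; per-partition
models are out of scope.

## The synthetic world

The generator's defaults state the world the package is built for, not a
tunable benchmark:

* segment lengths LSC 83,000 / SSC 12,500 / IR 22,800 bp (total 141,100);
* a miniature but realistic gene template: intron-containing genes
  (`rps16`, `ycf3` with two introns, `rps12`), `rps19` exactly 35 bp
  inside IRb, `ndhF` spanning the IRb/SSC junction by 29 bp, and
  IR-duplicated rRNA/tRNA genes mirrored between the repeats;
* six species plus a divergent outgroup on the tree
  `((spontaneum,((sinense,barberi),(officinarum,robustum))),outgroup)`,
  with per-species SNP/InDel totals against the reference fixed at the
  published values (spontaneum 68/43 including two fixed long insertions
  of 27 and 50 bp, robustum 20/12, sinense and barberi 22/10 each,
  officinarum 10/5). Internal tree edges carry part of those totals
  (path sums are preserved) because at least ~4 shared sites per edge are
  needed before a 95% bootstrap is even arithmetically reachable;
* substitutions with transition:transversion weight 2:1, InDel lengths
  1 + Geometric (mean 3), insertions and deletions equally likely;
* mild within-species polymorphism only in the two wild species
  (about 2 and 5 private SNPs per sample for spontaneum and robustum),
  chosen to echo the observed ranking of within-species diversity;
* the outgroup at 200 SNPs / 30 InDels — far closer than a real
  intergeneric comparison, but large enough to exercise every code path
  while keeping alignment trivially collinear;
* planted, flank-protected diagnostic events: one species-diagnostic SNP
  embedded in a `TCTAG`+G context (so one allele completes an XbaI site
  outright and a TaqI site with one introduced mismatch — the engineered
  analogue of the SNP contexts real dCAPS markers sit in), and two
  diagnostic deletions of 15 and 20 bp;
* planted SSR motifs with run-blocking flanking bases so the scanner must
  find exactly the planted run.

Mutations are placed uniformly in the single-copy regions. The IRs stay
free of variation by default because that is the observed state (IR
nucleotide diversity of exactly zero across a whole species complex);
requesting `ir_snps > 0` plants substitutions that are mirrored into the
other repeat (concerted evolution), and `mirror_ir = FALSE` breaks the
invariant on purpose for negative tests. Every event is padded so events
never interact, and InDel truth records are stored left-aligned — the
same normal form the caller produces — which is what makes recall and
precision exactly 1 a fair expectation rather than a fuzzy target.

What the generator does **not** emulate: sequencing or assembly error,
rate heterogeneity along the genome (hotspots arise only by planting),
rearrangements, codon-aware evolution, recombination, and realistic
intergeneric divergence. A green recovery test therefore establishes that
the pipeline is internally consistent on clean assemblies of the stated
structure — not that it tolerates misassembled or structurally variant
input.

## Numerical and degenerate-input choices

* All internal coordinates are 1-based closed (the IRanges convention used
  across Bioconductor); conversions happen only at I/O boundaries (BED is
  written 0-based half-open, VCF 1-based with anchor bases).
* Alignment scoring treats `N` as a mismatch; variant calling then drops
  `N` sites, so an `N` can locally perturb gap placement but never creates
  a call.
* Q-matrix ties in NJ and equal-score alignment paths are resolved
  deterministically (first index; match preferred over gaps), and every
  stochastic step (bootstrap, simulation) takes an explicit seed — reruns
  are byte-identical, which the pipeline manifest checks via md5.
* A window larger than the alignment degrades to a single whole-alignment
  window with a warning; an empty variant list writes a header-only VCF;
  a primer with no binding site is a no-amplification *result*, while an
  ambiguous amplification is an *error*.

## Known limitations

* The aligner assumes collinearity; genomes with rearrangements or IR
  expansion/contraction beyond the band must come with an external
  alignment.
* Mismatched (non-identical) IR pairs are not detected as IRs.
* Primer design ignores dimer/hairpin thermodynamics and multiplexing.
* Per-region Pi averages are window-weighted, not site-weighted.
* The NJ stand-in is not a substitute for ML on deeper phylogenies; it is
  adequate precisely in the near-identical regime this package targets.

## A worked example

```{r example, eval = FALSE}
library(plastmarker)

## simulate the stated world (or read your own FASTA with read_sequences)
sim <- simulate_plastome_set(sim_config(), seed = 1)

## structure of the reference
detect_quadripartite(sim$ancestor)
#> quadripartite structure (141,100 bp): LSC 83000 | IRb 22800 | SSC 12500 | IRa 22800

## align, call, classify
aln <- align_plastomes(sim$genomes, "reference")
v   <- call_variants(aln)
v   <- classify_regions(v, sim$ancestor$annotations, length(sim$ancestor))
dv  <- diagnostic_variants(v, sim$groups)

## sliding-window diversity
prof <- sliding_pi(aln)
summarize_pi(prof, aln, structure = sim$ancestor$structure,
             groups = sim$groups)$by_region

## markers from the planted diagnostic SNP
snp <- dv[dv$pos == sim$truth$pos[sim$truth$planted &
                                  sim$truth$kind == "SNP"][1], ]
design_dcaps(aln, snp, sim$groups, variants = v)

## phylogeny from the whole-genome alignment
tree <- nj_tree(aln$seqs, "JC69", bootstrap_n = 1000, seed = 1,
                outgroup = "outgroup_1")
```

The same flow, end to end with files on disk and a manifest, is
`run_all()`; `scripts/acceptance.R` in the source repository is exactly
that call on the default world.
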