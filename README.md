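# plastmarker

Comparative analysis of near-identical chloroplast genomes and design of
species-diagnostic PCR markers, in R.

Plastomes within a species complex — sugarcane (*Saccharum*) and its
relatives are the motivating system — are ~141 kb circles that differ by
only tens of SNPs and short InDels. That regime admits a complete,
deterministic desk-side workflow on assembled genomes, which this package
implements end to end:

* **Quadripartite structure**: detection of the inverted-repeat pair
  (IRa/IRb) and the large/small single-copy regions (LSC/SSC) by maximal
  exact inverted-repeat search on the circle; canonical LSC-first
  rotation; IR-junction gene context (e.g. which gene sits how many bp
  from the LSC/IRb border).
* **Microsatellites**: MISA-style perfect SSR scanning with the classic
  thresholds (mono ≥ 10, di ≥ 5, tri ≥ 5, tetra ≥ 4, penta ≥ 3, hexa ≥ 3
  copies), primitive motifs only, per-region summaries.
* **Variants**: banded global alignment (Gotoh affine gaps, band 200)
  merged center-star around a reference; SNP and left-aligned InDel
  calls; classification into CDS / intron / tRNA / rRNA / intergenic with
  flanking-gene spacer labels; VCF output.
* **Diversity**: DnaSP-style sliding-window nucleotide diversity
  (Pi; 500/250 bp windows, complete deletion), per-region and per-species
  summaries, hotspot listing (Pi > 0.01).
* **Markers**: species-diagnostic variants (fixed within species,
  differing between); InDel marker design with conserved flanks; dCAPS
  design (mismatch primer completing a TaqI/XbaI site for exactly one
  allele), validated by in-silico PCR and restriction digestion.
* **Phylogeny**: shared single-copy protein-coding genes, concatenated
  supermatrix, neighbor-joining (p-distance or JC69) with a seeded,
  site-pattern-compressed bootstrap.
* **Simulator**: a seeded plastome-evolution generator with
  machine-readable ground truth (per-sample mutation lists, planted SSRs,
  planted diagnostic sites, true tree), so the whole pipeline is testable
  with no external data.

The core statistic for diversity is per-window
Pi = mean over pairs (i,j) of d_ij / L, with d_ij the Hamming distance and
L the compared sites after complete deletion of gap/N columns. dCAPS
design follows the classic construction: a primer ending one base before
the SNP carries at most one introduced mismatch that completes a
restriction site (T^CGA for TaqI, T^CTAGA for XbaI) for exactly one
allele, converting the SNP into a gel-resolvable fragment-length
difference.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "plastmarker", load_package = "installed")'
```

The suite checks every stage against independent oracles (brute-force
inverted-repeat search, regex SSR scan, exhaustive pairwise alignment,
all-pairs Pi, a brute-force neighbor-joining implementation) and runs
parameter-recovery simulations against the generator's ground truth.

## A worked example

```r
library(plastmarker)

sim <- simulate_plastome_set(sim_config(), seed = 1)
detect_quadripartite(sim$ancestor)
#> quadripartite structure (141,100 bp): LSC 83000 | IRb 22800 | SSC 12500 | IRa 22800

aln <- align_plastomes(sim$genomes, "reference")
v   <- diagnostic_variants(call_variants(aln), sim$groups)

snp <- v[v$pos == sim$truth$pos[sim$truth$planted & sim$truth$kind == "SNP"][1], ]
d <- design_dcaps(aln, snp, sim$groups, variants = v)
d[, c("id", "enzyme", "strand", "cut_allele", "introduced", "is_caps", "product_size")]
#>    id enzyme strand cut_allele introduced is_caps product_size
#> 1 d01   TaqI      +          A          1   FALSE          100
#> 2 d02   XbaI      +          A          0    TRUE          100
#> 3 d03   XbaI      -          A          0    TRUE          100
```

Read: the planted species-diagnostic SNP admits one true dCAPS design
(TaqI; one introduced primer mismatch completes `TCGA` for the A allele
only) and two plain CAPS designs (the A allele completes `TCTAGA`
outright). Each row carries per-species predicted fragment sizes; a
digested 100 bp product vs an uncut one separates the target species on a
2–3% gel. `validate_marker()` re-runs the assay on every genome and
returns a verdict.

The file-based pipeline (`run_all()`) executes all stages from one
configuration and writes TSV/VCF/BED/newick outputs plus a manifest with
md5 checksums; reruns with the same seed are byte-identical.

## Acceptance script

`scripts/acceptance.R` simulates the package's stated world (full-size
genomes, published per-species mutation budgets) from the given seed and
runs the complete pipeline — structure, SSRs, alignment, variants,
diversity, marker design and validation, phylogeny — failing on any stage
error:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
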