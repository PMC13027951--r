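---
title: "Comparative mitogenomics with mitocomp: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

# Scope and data model

`mitocomp` analyses annotated circular mitochondrial genomes, with the
stinkhorn fungi (Phallales, Basidiomycota) as its reference system. A
genome is a `mitogenome`: a nucleotide sequence over `A/C/G/T/N` plus a
set of features, each with a canonical gene label (the 15 conserved
protein-coding genes `cox1-3`, `cob`, `nad1-6`, `nad4L`, `atp6/8/9`,
`rps3`; the rRNAs `rnl`/`rns`; tRNAs `trnX` with one-letter amino-acid
codes), a kind (PCG, rRNA, tRNA), a strand, an exon list and a copy
index for duplicated genes.

Coordinates are 1-based inclusive throughout, the GenBank convention.
An individual exon never wraps the origin; a feature spanning the
origin of a circular genome carries two exons, exactly as a GenBank
`join(90..100,1..20)` does. This forces one definitional choice: we
count as an intron every *positive-length* gap between consecutive
exons on the circle. A genuinely split gene with `k+1` exons therefore
has `k` introns, while an origin-spanning join — whose two exons are
adjacent on the circle — has none. Annotation `intron` features, where
present in a source file, are not trusted independently: exon structure
is authoritative, since the intron census is derivable from it alone.

GenBank reading/writing is scoped to the flat-file subset that
organelle records actually use (LOCUS/FEATURES/ORIGIN; `join`,
`complement`; `/gene`, `/product`, anticodon notes) and round-trips the
data model losslessly; the test suite also cross-checks written files
against an independent parser. Gene labels are normalized through an
explicit synonym table shipped as data
(`extdata/gene_synonyms.tsv`), because the common annotation pipelines
(MITOS, Mfannot, manual curation) emit different vocabularies for the
same genes. Unknown labels are kept verbatim and flagged, never
dropped.

# Composition statistics and the four-way partition

Strand asymmetry uses the standard skew statistics on the deposited
plus strand of the whole molecule:

  AT skew = (A − T)/(A + T),  GC skew = (G − C)/(G + C).

An undefined denominator yields an explicit `NA`, never 0. `N` bases
are excluded from both skew and GC denominators. Reported precision
follows the field's tables: GC to 1 decimal, skews to 4 decimals,
percentages rounded half-up to integers, size ratios to 2 decimals.
Half-up rounding is deliberate: published tables round 40.586% to 41%,
which R's default half-even rounding also gives here, but half-up is
the convention those tables use and is applied uniformly.

Every base of the genome receives exactly one of four classes with
fixed precedence

  `PCG_EXON` > `RNA_CODING` > `INTRONIC` > `INTERGENIC`,

so overlapping annotations resolve deterministically regardless of
feature order. "Exonic" means protein-coding exons only; rRNA and tRNA
bases form the separate RNA-coding class. The published five-genome
comparison table prints only three of the four region lengths; the
RNA-coding length is forced by the invariant that the four classes sum
to the genome length, and `phallales_reference_summaries()` reconstructs
it that way. The intron census is reported under three conventions
(PCG-only, rRNA-only, combined) because published totals are not always
explicit about whether rRNA introns are included — for the genome with
introns in both, 23 + 7 = 30 only under the combined convention.

# Codon usage

Coding sequences are handled under the mold/protozoan mitochondrial
genetic code (NCBI translation table 4: `TGA` = Trp, stops `TAA`/`TAG`),
taken from Biostrings. Tabulation counts every codon including the
start and stop, so total codon count equals total CDS length divided by
three exactly. Alternative start codons (`TTA`, `ATT`, `ATA`) are data,
not errors, and are reported as found; internal stops warn but the gene
is still counted. Ranked output reports both raw counts and per-mille
frequencies, since published figures are not explicit about their
normalization, and ties are flagged explicitly (two codons sharing a
count is a real phenomenon in these genomes, not an artifact).

# Evolutionary rates

## Kimura two-parameter distance

For an aligned pair, sites with a gap or ambiguity in either row are
excluded pairwise; `P` and `Q` are the transition and transversion
proportions over retained sites and

  d = −½ ln[(1 − 2P − Q) √(1 − 2Q)].

When either logarithm argument is non-positive the distance is
saturated and reported as undefined (`NA` plus a flag) rather than
clamped. The standard error uses Kimura's delta-method variance, which
the simulation tests use for 3-standard-error coverage checks.

## Nei–Gojobori (1986) Ka/Ks

The counting method is implemented in full rather than wrapped from an
external tool, with these conventions:

* **Sites.** At each codon position the synonymous fraction is the
  share of the three possible changes that preserve the amino acid;
  changes creating a stop codon are skipped while the denominator stays
  3, so they fall on the nonsynonymous side and S + N = 3 × codons holds
  exactly per sequence. S and N are averaged over the two sequences.
* **Differences.** Codons differing at k positions are averaged over
  all k! minimal mutational pathways with equal weight; pathways that
  pass through a stop codon are excluded. If every pathway were blocked
  the average would fall back to all pathways — the tests show this
  cannot occur under table 4 with non-stop endpoints, since the two
  stops differ at a single position.
* **Gaps.** Whole codon pairs containing any gap or ambiguity are
  deleted pairwise (for K2P, deletion is per site). This keeps the most
  data and is deterministic; a shared terminal stop codon is dropped.
* **Correction.** pS = Sd/S and pN = Nd/N receive the Jukes–Cantor
  correction −¾ ln(1 − 4p/3); p ≥ ¾ is reported undefined. A ratio with
  Ks = 0 (or 0/0 for identical sequences) is undefined, not infinite.

Per-gene summaries average over all unordered species pairs, excluding
undefined pairs and reporting their count; the per-gene Ka/Ks is the
mean of per-pair ratios (the alternative — ratio of mean Ka to mean Ks —
is not what pairwise tools report, and the choice is labeled in the
output).

Pathway averaging is verified against an exhaustive permutation oracle
on all 64×64 codon pairs, and the whole estimator against simulations
with known parameters (below).

# Circular gene order

Orders are extracted by sorting features around the circle, then
normalized: if most protein-coding genes sit on the minus strand the
circle is reversed (sequence orientation is an artifact of deposition),
and the order is linearized at an anchor gene, `cox1` by default, with
copy indices renumbered in position order. Rotating the origin or
reverse-complementing the genome therefore leaves the normalized order
unchanged, and normalization is idempotent. Comparison can ignore
surplus duplicate copies (a tRNA present twice in one taxon, once in
another) so that conserved backbones compare as identical. The
breakpoint distance counts circular adjacencies — unordered signed
neighbor pairs, so (x,y) ≡ (−y,−x) — present in one order but not the
other; it is zero on identical orders, symmetric, and satisfies the
triangle inequality. tRNA clusters are derived from the intergenic
context of the order (maximal tRNA runs between non-tRNA genes), never
hard-coded; the published six-cluster assignment ships as an
expectation fixture the derivation is tested against.

# Supermatrices

Three datasets are built from per-gene codon-aware alignments: `PCG12`
(codon positions 1+2 of the 15 protein-coding genes), `PCG12R` (PCG12
plus the two rRNA alignments) and `AA` (table-4 translations). Terminal
stop codons are trimmed before both the position-12 extraction and the
translation, keeping the 2:1 length relation between PCG12 and AA exact
— mirroring the published 8,442 nt / 4,221 aa pair, whose arithmetic
structure (not its absolute size, which depends on alignment trimming
that is out of scope) is the invariant the package maintains.
Alignment and trimming themselves are consumed, not computed: the
package expects pre-aligned input, and the simulator produces gap-free
same-length gene sets so the pipeline is testable end to end. Genes are
concatenated in the fixed conserved genomic order by default, making
output byte-deterministic; a taxon missing a gene receives an all-gap
block, and the partition map (exported RAxML-style) always tiles the
matrix exactly. The neighbor-joining tree on pairwise K2P distances is
a sanity check standing in for the full likelihood/Bayesian inference
workflow, which is out of scope; negative NJ branch lengths are clamped
to zero with a warning.

# The simulator: study conditions, not dials

`generate_genome()` builds Phallales-like annotated genomes whose
defaults are the study conditions reported for this order: circular
molecules in the 41–100 kb range; GC ≈ 24.5% with positive AT and GC
skew (imposed by asymmetric base frequencies, G slightly over C and A
slightly over T); 15 protein-coding genes and 2 rRNAs in the conserved
order `cox1-nad4-cox3-atp8-nad4L-nad5-rnl-cox2-nad2-nad3-nad1-nad6-cob-
rns-atp6-rps3-atp9`; 24 core tRNAs in six clusters between fixed gene
pairs, containing the shared `trnM/L/R/S` doublings (the two `trnM`
copies share an anticodon; the `L/R/S` pairs are distinct isotypes);
optional private extra copies (`trnI/T/D/F`) inserted next to their
first occurrence; introns concentrated in `cox1`, `cob` and `rnl`; and
large intergenic tracts. Default gene lengths are realistic for fungal
mitogenomes (e.g. `cox1` 1,608 bp, `nad5` 1,983 bp, `atp8` 159 bp);
tRNAs default to 72 bp, the modal length range, with no secondary-
structure realism. Coding sequences are valid table-4 ORFs: configured
start codon, no internal stop, terminal `TAA`.

All bookkeeping is exact integer accounting: the realized four-way
partition equals the plan with no drift, and a `region_budget` rescales
the per-gene tables so the realized region totals match a target budget
to the base pair (residuals are absorbed by the largest entry; coding
lengths stay multiples of 3). An infeasible budget errors with the
residual rather than silently adjusting. All randomness flows from one
explicit seed through a local RNG, so identical specs give
byte-identical GenBank output.

Sequence evolution supports two modes. `K2P_site` draws each site's
final state from the exact K2P transition probabilities at divergence
`d` and ts/tv ratio κ, so the expected number of substitutions per site
equals `d` (verified by estimator recovery: 3-standard-error coverage
at d ∈ {0.05, 0.2, 0.5} on 10 kb sequences). `codon_NG` is a
proposal–acceptance process: point mutations proposed with κ bias,
stop-creating changes (and changes to the terminal stop) rejected,
nonsynonymous changes accepted with probability ω. Its branch length is
calibrated in *proposals* per nucleotide site, not substitutions — the
realized substitution rate depends on ω — which is sufficient for what
the package asserts about it: recovering the *ranks* of per-gene ω and
the purifying-selection signature Ka/Ks < 1.

`make_phallales_panel()` assembles the seven-taxon comparison: one
ancestral gene set evolved down a fixed seven-taxon tree whose
earliest-branching tip is the *Lysurus* analogue (per-gene ω from 0.02
for `atp9` to 0.55 for `rps3`), with the evolved coding and rRNA
sequences planted into seven generated genomes that carry the published
duplication configuration and per-taxon intron plans (24 PCG introns
with 9 in `cox1` for the *L. mokusin* analogue, 30 combined for the
*P. indusiatus* analogue including 6 in `rnl` and 1 in `rns`, down to 5
for the *P. rigidiindusiatus* analogue). Genomes and alignments are
therefore mutually consistent, and both are byte-reproducible from the
seed.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: intron-encoded homing endonuclease ORFs,
repeat families and tandem repeats (supported as planned repeats but
with no default model), horizontal transfer, tRNA secondary structure,
alignment uncertainty (simulated genes evolve without indels, so
"alignments" are exact), and base-compositional heterogeneity along the
molecule. Real-data values that depend on the deposited genomes
(per-species skews, per-gene rate values, the deep phylogeny) are
covered by the property-based suite, not reproduced numerically.

# Numerical and testing choices

Problem sizes in the test suite were chosen to make the checks sharp
but cheap: 10 kb sequences and 200 replicates for distance recovery,
2,000 codons and 100 replicates for the purifying-selection check,
1,000 random pairs for closed-form K2P agreement (to 12 decimals), the
full 64×64 codon-pair table plus 100 random 300-codon pairs for the
pathway-enumeration oracle, and 100 random rotations for circular-order
invariance. The unit-test genome spec is a scaled-down genome (~15 kb)
with the same structure as the defaults; the acceptance-grade checks
use the full-size panel.

Degenerate inputs are handled explicitly rather than numerically:
empty sequences, all-ambiguous alignments and absent anchors are
errors or warnings with named subjects; saturated distances, undefined
skews and 0/0 ratios are `NA` markers that downstream means exclude
(reporting how many pairs were excluded) rather than propagate.

# Known limitations

* GenBank support covers the organelle-record subset, not the full
  INSDC grammar (no remote accessions, fuzzy locations beyond `<`/`>`
  trimming, or `order()` locations).
* NG86 is the only Ka/Ks estimator; no maximum-likelihood dN/dS, no
  rate heterogeneity.
* The codon-mode branch length is a proposal intensity, so absolute Ka
  and Ks values from the simulator are not calibrated targets — only
  their ordering and ratio regime are.
* The NJ tree is a sanity instrument; the package deliberately stops
  short of model selection and ML/Bayesian inference, exporting
  inference-ready files instead.
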