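# mitocomp

Comparative analysis of fungal mitochondrial genomes, built around the
stinkhorns (Phallales, Basidiomycota) — a group whose mitogenomes
combine a strictly conserved gene complement and order with enormous
size variation (roughly 41–100 kb within one order) driven almost
entirely by introns and intergenic DNA.

The package is aimed at organelle genomicists who have annotated
circular mitogenomes (GenBank flat files) and/or per-gene alignments
and want the standard comparative battery as tested, scriptable
functions:

* **Composition** — GC content; AT skew `(A−T)/(A+T)` and GC skew
  `(G−C)/(G+C)` on the deposited strand; a per-base partition of the
  genome into protein-coding exons, RNA-coding (rRNA + tRNA), intronic
  and intergenic classes (precedence `PCG_EXON > RNA_CODING > INTRONIC
  > INTERGENIC`, the four lengths always summing to genome size); an
  intron census per gene; strain-size arithmetic.
* **Codon usage** — tabulation of the 15 protein-coding genes under the
  mold/protozoan mitochondrial code (translation table 4, `TGA` = Trp),
  including start/stop codon surveys with per-gene exceptions.
* **Evolutionary rates** — Kimura 2-parameter distance
  `d = −½ ln[(1−2P−Q)√(1−2Q)]` with pairwise site deletion and
  delta-method standard errors, and a full Nei–Gojobori (1986) Ka/Ks
  implementation: per-codon synonymous site fractions from the code,
  equal-weight averaging over minimal mutational pathways (stop-passing
  pathways excluded), Jukes–Cantor correction, pairwise-mean gene
  summaries. Ka/Ks < 1 indicates purifying selection.
* **Gene order** — normalization of circular signed gene orders
  (rotation- and reversal-invariant, anchored at `cox1`),
  duplicate-tolerant order comparison, circular breakpoint distance,
  tRNA duplication reports with anticodon identity, and tRNA clusters
  derived from intergenic context.
* **Supermatrices** — the three standard phylogenomic datasets from
  per-gene alignments: `PCG12` (codon positions 1+2), `PCG12R`
  (+ rRNAs), `AA` (translated), with exact partition maps
  (`|PCG12| = 2·|AA|` by construction), relaxed-PHYLIP/FASTA/RAxML
  partition output, and a neighbor-joining sanity tree on K2P
  distances.
* **Simulation** — a seeded generator of Phallales-like annotated
  mitogenomes (conserved gene order, six tRNA clusters with the shared
  `trnM/L/R/S` doublings, exact region budgets, valid table-4 ORFs) and
  sequence evolution under a K2P site model or a codon model with
  selection strength ω, including evolution down a tree. The
  seven-taxon `make_phallales_panel()` ties it all together.

## Worked example

```r
library(mitocomp)

panel <- make_phallales_panel(1)   # 7 genomes + per-gene alignments

summarize_genome(panel$genomes$Lysurus_mokusin_sim)
#> <genome_summary> SIM_Lysurus_moku (Lysurus_mokusin_sim)
#>   total 96,963 bp | GC 25.1% | AT skew 0.0228 | GC skew 0.0805
#>   15 PCGs, 24 tRNAs, 2 rRNAs, 24 introns
#>   exonic 14565 | RNA-coding 6548 | intronic 37750 | intergenic 38100 bp
```

A 97 kb circular genome at ~25% GC with positive skews; its 24 introns
and 38 kb of intergenic DNA are what make it more than twice the size
of the smallest genome in the panel, while the coding complement stays
fixed. The same proportions, as integer percentages of the genome:

```r
proportion_table(summarize_genome(panel$genomes$Lysurus_mokusin_sim))
#> protein_coding     rna_coding       intronic     intergenic
#>             15              7             39             39
```

Gene order and tRNA duplications across the seven genomes:

```r
paste(extract_order(panel$genomes$Phallus_rugulosus_sim,
                    include_trna = FALSE)$order$label, collapse = "-")
#> "cox1-nad4-cox3-atp8-nad4L-nad5-rnl-cox2-nad2-nad3-nad1-nad6-cob-rns-atp6-rps3-atp9"

duplication_events(panel$genomes)
#> <duplication_report>
#>   shared: trnL, trnM, trnR, trnS
#>   private Phallus_hadriani_sim: trnT
#>   private Phallus_rigidiindusiatus_sim: trnD
#>   private Phallus_rugulosus_sim: trnI
#>   private Phallus_dongsun_sim: trnF
```

Every taxon shows the same protein/rRNA backbone and the four shared
tRNA doublings; four taxa each add one private extra tRNA copy. Per-gene
rates over all 21 species pairs:

```r
rate_summary(panel$alignments[c("atp9", "cob", "rps3")])
#>   gene          ka        ks      ka_ks        k2p n_pairs ...
#> 1 atp9 0.001644675 0.1545462 0.01284014 0.03150337      21
#> 2  cob 0.011119460 0.1196420 0.10551050 0.03058069      21
#> 3 rps3 0.053098459 0.1246331 0.44816586 0.06663984      21
```

All Ka/Ks are below 1 (purifying selection), with `atp9` the most
constrained and `rps3` the least — the ordering the panel was generated
under.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mitocomp.R` (`summarize`, `partition`, `introns`,
`codon-usage`, `gene-order`, `duplications`, `kaks`, `k2p`,
`gene-panel`, `supermatrix`, `nj-tree`, `simulate-genome`,
`simulate-panel`).

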