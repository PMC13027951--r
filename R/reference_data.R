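# Published comparison values for the five newly sequenced Phallales
# mitogenomes, shipped as plain-text tables: the genome-feature comparison
# (sizes, GC, skews, gene counts, region lengths), the strain-size
# comparison for the two species with a second sequenced strain, and the
# six intergenic tRNA clusters of the conserved gene order.

#' Published Phallales reference tables
#'
#' @param name which table: `"table1"` (per-species genome statistics),
#'   `"strains"` (strain sizes for Lysurus mokusin and Phallus
#'   indusiatus), or `"clusters"` (the six tRNA clusters with their
#'   flanking genes).
#' @return a data.frame.
#' @export
phallales_reference <- function(name = c("table1", "strains", "clusters")) {
  name <- match.arg(name)
  file <- switch(name, table1 = "phallales_table1.tsv",
                 strains = "phallales_strains.tsv",
                 clusters = "trna_clusters.tsv")
  utils::read.delim(system.file("extdata", file, package = "mitocomp"),
                    stringsAsFactors = FALSE)
}

#' Genome summaries reconstructed from the published comparison table
#'
#' Builds `genome_summary`-shaped objects from the printed per-species
#' statistics; the RNA-coding length, not printed, is forced by the
#' partition sum invariant (total = exonic + RNA-coding + intronic +
#' intergenic).
#' @return named list of `genome_summary` objects.
#' @export
phallales_reference_summaries <- function() {
  t1 <- phallales_reference("table1")
  out <- lapply(seq_len(nrow(t1)), function(i) {
    r <- t1[i, ]
    structure(list(
      record_id = r$species, species_name = r$species,
      total_size_bp = r$total_size_bp, gc_percent = r$gc_percent,
      at_skew = r$at_skew, gc_skew = r$gc_skew,
      n_pcg = r$n_pcg, n_trna = r$n_trna, n_rrna = r$n_rrna,
      n_introns = r$n_introns,
      exonic_bp = r$exonic_bp,
      rna_coding_bp = r$total_size_bp - r$exonic_bp - r$intronic_bp -
        r$intergenic_bp,
      intronic_bp = r$intronic_bp,
      intergenic_bp = r$intergenic_bp), class = "genome_summary")
  })
  stats::setNames(out, t1$species)
}
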