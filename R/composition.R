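# Genome-level composition statistics and the four-way region partition.
#
# "Exonic" means protein-coding exons only; rRNA/tRNA bases form a separate
# RNA-coding class; the remaining bases are intronic (strictly between two
# exons of the same feature) or intergenic. The four class lengths always
# sum to the genome length.

#' Base composition and GC content
#'
#' @param seq nucleotide string.
#' @return list with `counts` (named A/C/G/T/N) and `gc_percent`
#'   (100*(G+C)/(A+C+G+T), N excluded from the denominator, 1 decimal).
#' @export
base_composition <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  cnt <- base_counts(seq)
  acgt <- sum(cnt[c("A", "C", "G", "T")])
  if (acgt == 0L) stop("sequence has no unambiguous bases")
  list(counts = cnt,
       gc_percent = round_half_up(100 * sum(cnt[c("G", "C")]) / acgt, 1))
}

base_counts <- function(seq) {
  ch <- split_chars(toupper(seq))
  tab <- table(factor(ch, levels = c("A", "C", "G", "T", "N")))
  stats::setNames(as.integer(tab), names(tab))
}

#' AT and GC strand skew
#'
#' AT skew = (A - T)/(A + T), GC skew = (G - C)/(G + C), computed on the
#' given (deposited plus) strand. An undefined denominator yields `NA`,
#' never 0.
#' @param seq nucleotide string.
#' @return list with `at_skew` and `gc_skew`.
#' @export
skew <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  cnt <- base_counts(seq)
  at <- cnt[["A"]] + cnt[["T"]]; gc <- cnt[["G"]] + cnt[["C"]]
  list(at_skew = if (at > 0) (cnt[["A"]] - cnt[["T"]]) / at else NA_real_,
       gc_skew = if (gc > 0) (cnt[["G"]] - cnt[["C"]]) / gc else NA_real_)
}

REGION_CLASSES <- c("PCG_EXON", "RNA_CODING", "INTRONIC", "INTERGENIC")

#' Partition a genome into coding, RNA, intronic and intergenic bases
#'
#' Every base gets exactly one class, with precedence
#' PCG_EXON > RNA_CODING > INTRONIC > INTERGENIC. Intronic bases are those
#' strictly between two exons of the same feature (circular wrap
#' respected); everything unannotated is intergenic.
#' @param record a validated `mitogenome`.
#' @return list with `classes` (factor vector, one element per base) and
#'   `lengths` (named totals per class).
#' @export
partition_regions <- function(record) {
  L <- nchar(record$sequence)
  cls <- rep.int(4L, L)                       # INTERGENIC
  paint <- function(pos, value) cls[pos] <<- value
  # lowest precedence first so later paints win
  for (f in record$features) {
    n <- nrow(f$exons)
    if (n > 1L) for (i in seq_len(n - 1L)) {
      g <- circ_gap(f$exons[i, "end"], f$exons[i + 1L, "start"], L)
      if (g > 0L)
        paint(((f$exons[i, "end"] + seq_len(g) - 1L) %% L) + 1L, 3L)
    }
  }
  for (f in record$features) if (f$kind != "PCG")
    for (i in seq_len(nrow(f$exons)))
      paint(circ_positions(f$exons[i, "start"], f$exons[i, "end"], L), 2L)
  for (f in record$features) if (f$kind == "PCG")
    for (i in seq_len(nrow(f$exons)))
      paint(circ_positions(f$exons[i, "start"], f$exons[i, "end"], L), 1L)
  classes <- factor(REGION_CLASSES[cls], levels = REGION_CLASSES)
  list(classes = classes,
       lengths = stats::setNames(as.integer(table(classes)), REGION_CLASSES))
}

#' Summarize a mitogenome
#'
#' Assembles size, GC content, AT/GC skews (4 decimals), feature counts,
#' the intron census total (exon gaps across PCGs and rRNAs) and the four
#' region lengths. Warns when the protein-coding gene count is not the
#' conserved 15 of Phallales.
#' @param record a validated `mitogenome`.
#' @return object of class `genome_summary`.
#' @export
summarize_genome <- function(record) {
  kinds <- vapply(record$features, `[[`, character(1), "kind")
  L <- nchar(record$sequence)
  comp <- base_composition(record$sequence)
  sk <- skew(record$sequence)
  part <- partition_regions(record)
  n_pcg <- sum(kinds == "PCG")
  if (n_pcg != 15L)
    warning("record ", record$record_id, " has ", n_pcg,
            " protein-coding genes (conserved Phallales complement is 15)",
            call. = FALSE)
  n_intr <- sum(vapply(record$features[kinds != "tRNA"], n_introns,
                       integer(1), L = L))
  structure(list(
    record_id = record$record_id,
    species_name = record$species_name,
    total_size_bp = L,
    gc_percent = comp$gc_percent,
    at_skew = round_half_up(sk$at_skew, 4),
    gc_skew = round_half_up(sk$gc_skew, 4),
    n_pcg = n_pcg,
    n_trna = sum(kinds == "tRNA"),
    n_rrna = sum(kinds == "rRNA"),
    n_introns = n_intr,
    exonic_bp = part$lengths[["PCG_EXON"]],
    rna_coding_bp = part$lengths[["RNA_CODING"]],
    intronic_bp = part$lengths[["INTRONIC"]],
    intergenic_bp = part$lengths[["INTERGENIC"]]
  ), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("<genome_summary> ", x$record_id, " (", x$species_name, ")\n", sep = "")
  cat(sprintf("  total %s bp | GC %.1f%% | AT skew %.4f | GC skew %.4f\n",
              format(x$total_size_bp, big.mark = ","), x$gc_percent,
              x$at_skew, x$gc_skew))
  cat(sprintf("  %d PCGs, %d tRNAs, %d rRNAs, %d introns\n",
              x$n_pcg, x$n_trna, x$n_rrna, x$n_introns))
  cat(sprintf("  exonic %d | RNA-coding %d | intronic %d | intergenic %d bp\n",
              x$exonic_bp, x$rna_coding_bp, x$intronic_bp, x$intergenic_bp))
  invisible(x)
}

#' Region proportions as integer percentages
#'
#' Each class length over the total, times 100, rounded half-up to the
#' nearest integer percent (rounded values need not sum to 100).
#' @param summary a `genome_summary`, or a list with the four `_bp` region
#'   fields and `total_size_bp`.
#' @return named numeric vector (protein_coding, rna_coding, intronic,
#'   intergenic).
#' @export
proportion_table <- function(summary) {
  tot <- summary$total_size_bp
  if (is.null(tot) || tot <= 0) stop("total_size_bp must be positive")
  v <- c(protein_coding = summary$exonic_bp,
         rna_coding = summary$rna_coding_bp,
         intronic = summary$intronic_bp,
         intergenic = summary$intergenic_bp)
  round_half_up(100 * v / tot)
}

#' Compare two genome (or strain) sizes
#'
#' @param a,b `genome_summary` objects or bare sizes in bp.
#' @return list with `difference_bp` (absolute) and `size_ratio`
#'   (larger/smaller, 2 decimals).
#' @export
compare_strains <- function(a, b) {
  sa <- if (is.list(a)) a$total_size_bp else a
  sb <- if (is.list(b)) b$total_size_bp else b
  if (sa <= 0 || sb <= 0) stop("sizes must be positive")
  list(difference_bp = abs(sa - sb),
       size_ratio = round_half_up(max(sa, sb) / min(sa, sb), 2))
}

#' Intron census across genomes
#'
#' Gene-by-species matrix of intron counts for the 15 protein-coding genes
#' and the two rRNAs, with per-species totals reported under the PCG-only,
#' rRNA-only and combined conventions.
#' @param records list of validated `mitogenome` objects.
#' @return object of class `intron_census`: list with `counts` (matrix),
#'   `intronless` (genes with zero introns in every genome) and `totals`
#'   (data.frame species/pcg/rrna/combined).
#' @export
intron_census <- function(records) {
  genes <- CORE_ORDER
  species <- vapply(records, `[[`, character(1), "species_name")
  m <- matrix(0L, nrow = length(genes), ncol = length(records),
              dimnames = list(genes, species))
  for (j in seq_along(records)) {
    rec <- records[[j]]
    L <- nchar(rec$sequence)
    for (f in rec$features)
      if (f$kind != "tRNA" && f$gene_label %in% genes)
        m[f$gene_label, j] <- m[f$gene_label, j] + n_introns(f, L)
  }
  rrna <- rownames(m) %in% c("rnl", "rns")
  totals <- data.frame(
    species = species,
    pcg = colSums(m[!rrna, , drop = FALSE]),
    rrna = colSums(m[rrna, , drop = FALSE]),
    combined = colSums(m),
    row.names = NULL)
  structure(list(counts = m,
                 intronless = rownames(m)[rowSums(m) == 0L],
                 totals = totals),
            class = "intron_census")
}

#' @export
print.intron_census <- function(x, ...) {
  cat("<intron_census> ", ncol(x$counts), " genomes\n", sep = "")
  print(x$counts)
  cat("intronless in all:", paste(x$intronless, collapse = ", "), "\n")
  invisible(x)
}
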