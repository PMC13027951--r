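# Codon, start-codon and stop-codon tabulation of the protein-coding genes
# under the mold/protozoan mitochondrial genetic code (NCBI translation
# table 4: TGA = Trp, stops TAA/TAG). Counts include start and stop codons
# so that total codon count = total CDS length / 3 exactly.

#' A genetic code table
#'
#' @param table_id NCBI translation table number (default 4, the
#'   mold/protozoan mitochondrial code).
#' @return object of class `genetic_code`: list with `table_id`, `codons`
#'   (named character vector of 64 one-letter amino acids, "*" = stop) and
#'   `stops`.
#' @export
genetic_code <- function(table_id = 4L) {
  key <- paste0("code_", table_id)
  if (is.null(.mitocomp_env[[key]])) {
    codons <- Biostrings::getGeneticCode(as.character(table_id))
    stopifnot(length(codons) == 64L)
    .mitocomp_env[[key]] <- structure(
      list(table_id = as.integer(table_id), codons = codons,
           stops = names(codons)[codons == "*"]),
      class = "genetic_code")
  }
  .mitocomp_env[[key]]
}

ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    paste0), c("A", "C", "G", "T"), paste0))

#' Tabulate codon usage of a set of coding sequences
#'
#' @param genes named character vector (or list) of spliced CDS nucleotide
#'   strings, each with length divisible by 3.
#' @param code a [genetic_code()] (default table 4).
#' @return object of class `codon_usage`: per-codon counts (all 64 codons),
#'   per-amino-acid totals, per-gene start and stop codons, and the total
#'   codon count. Internal stop codons are warned about (with the gene
#'   name) but still counted.
#' @export
tabulate_codons <- function(genes, code = genetic_code(4L)) {
  genes <- unlist(as.list(genes))
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    names(genes) <- paste0("gene", seq_along(genes))
  counts <- stats::setNames(integer(64L), sort(ALL_CODONS))
  starts <- stops <- character(0)
  for (g in names(genes)) {
    s <- toupper(genes[[g]])
    if (nchar(s) %% 3L != 0L)
      stop("CDS length of ", g, " (", nchar(s), ") is not divisible by 3")
    cod <- split_codons(s)
    internal <- cod[-length(cod)]
    if (any(internal %in% code$stops))
      warning("internal stop codon(s) in ", g, call. = FALSE)
    valid <- cod[cod %in% names(counts)]
    tab <- table(valid)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    starts[g] <- cod[1]
    stops[g] <- cod[length(cod)]
  }
  aa <- code$codons[names(counts)]
  aa_totals <- tapply(counts, aa, sum)
  structure(list(counts = counts,
                 aa_totals = stats::setNames(as.integer(aa_totals),
                                             names(aa_totals)),
                 starts = starts, stops = stops,
                 n_codons = sum(counts), table_id = code$table_id),
            class = "codon_usage")
}

#' Rank codons by usage
#'
#' @param table a `codon_usage`.
#' @param code the [genetic_code()] used for amino-acid annotation.
#' @return data.frame (codon, amino_acid, count, per_mille, rank, tied)
#'   sorted by descending count with alphabetical tie-break; `tied` marks
#'   codons whose count is shared with at least one other codon.
#' @export
rank_codons <- function(table, code = genetic_code(table$table_id)) {
  if (sum(table$counts) == 0L) stop("empty codon table")
  ord <- order(-table$counts, names(table$counts))
  cnt <- table$counts[ord]
  shared <- table(table$counts)
  data.frame(
    codon = names(cnt),
    amino_acid = unname(code$codons[names(cnt)]),
    count = as.integer(cnt),
    per_mille = round_half_up(1000 * as.integer(cnt) / sum(cnt), 2),
    rank = seq_along(cnt),
    tied = as.vector(shared[as.character(cnt)] > 1L),
    row.names = NULL)
}

#' Modal start and stop codons across species, with exceptions
#'
#' @param tables named list of `codon_usage` objects, one per species.
#' @return list with `summary` (data.frame species/modal_start/modal_stop)
#'   and `exceptions` (data.frame species/gene/which/codon listing every
#'   gene whose start or stop departs from its species' mode).
#' @export
start_stop_summary <- function(tables) {
  empty <- data.frame(species = character(0), gene = character(0),
                      which = character(0), codon = character(0))
  if (!length(tables))
    return(list(summary = data.frame(species = character(0),
                                     modal_start = character(0),
                                     modal_stop = character(0)),
                exceptions = empty))
  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  rows <- exc <- list()
  for (sp in names(tables)) {
    t <- tables[[sp]]
    if (!length(t$starts)) {
      rows[[sp]] <- data.frame(species = sp, modal_start = NA_character_,
                               modal_stop = NA_character_)
      next
    }
    ms <- modal(t$starts); me <- modal(t$stops)
    rows[[sp]] <- data.frame(species = sp, modal_start = ms, modal_stop = me)
    for (g in names(t$starts)) {
      if (t$starts[[g]] != ms)
        exc[[length(exc) + 1L]] <- data.frame(species = sp, gene = g,
                                              which = "start",
                                              codon = t$starts[[g]])
      if (t$stops[[g]] != me)
        exc[[length(exc) + 1L]] <- data.frame(species = sp, gene = g,
                                              which = "stop",
                                              codon = t$stops[[g]])
    }
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       exceptions = if (length(exc))
         do.call(rbind, c(exc, list(make.row.names = FALSE)))
       else empty)
}
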