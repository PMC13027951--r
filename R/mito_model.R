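# Data model for annotated circular mitogenomes.
#
# Coordinates are 1-based inclusive throughout (GenBank convention). An
# individual exon never wraps the origin: a feature spanning the origin of a
# circular record carries two exons, e.g. (90..100) + (1..20). Exons are
# stored in transcription order as given by the source location string; for
# a minus-strand feature the spliced sequence is the reverse complement of
# the concatenated exons.

#' Construct a mitogenome feature
#'
#' @param gene_label canonical gene name (see [normalize_gene_label()]).
#' @param kind one of "PCG", "rRNA", "tRNA".
#' @param exons two-column integer matrix (start, end), 1-based inclusive,
#'   one row per exon, in transcription order.
#' @param strand "+" or "-".
#' @param anticodon tRNA anticodon 3-mer, or NA.
#' @param copy_index positive integer distinguishing duplicate labels.
#' @return object of class `mito_feature`.
#' @export
mito_feature <- function(gene_label, kind, exons, strand = "+",
                         anticodon = NA_character_, copy_index = 1L) {
  kind <- match.arg(kind, c("PCG", "rRNA", "tRNA"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, "start"] > exons[, "end"]))
    stop("exon start > end for ", gene_label,
         " (wrap-around exons must be split in two)")
  structure(list(gene_label = gene_label, kind = kind, exons = exons,
                 strand = strand, anticodon = anticodon,
                 copy_index = as.integer(copy_index)),
            class = "mito_feature")
}

#' Construct an annotated mitogenome record
#'
#' @param record_id record identifier.
#' @param species_name organism name.
#' @param sequence nucleotide string over A/C/G/T/N (upper-cased on input).
#' @param features list of [mito_feature()] objects.
#' @param topology "circular" or "linear".
#' @param validate run [validate_mitogenome()] on the result.
#' @return object of class `mitogenome`.
#' @export
mitogenome <- function(record_id, species_name, sequence, features = list(),
                       topology = c("circular", "linear"), validate = TRUE) {
  topology <- match.arg(topology)
  rec <- structure(list(record_id = record_id, species_name = species_name,
                        topology = topology, sequence = toupper(sequence),
                        features = features),
                   class = "mitogenome")
  if (validate) validate_mitogenome(rec)
  rec
}

feature_length <- function(f) sum(f$exons[, "end"] - f$exons[, "start"] + 1L)

# lengths of the gaps between consecutive exons on the circle (0 = adjacent,
# as for a wrap-around join); introns are the positive-length gaps
exon_gaps <- function(f, L) {
  n <- nrow(f$exons)
  if (n < 2L) return(integer(0))
  vapply(seq_len(n - 1L), function(i) {
    circ_gap(f$exons[i, "end"], f$exons[i + 1L, "start"], L)
  }, integer(1))
}

#' Number of introns of a feature
#'
#' Counted as the positive-length gaps between consecutive exons on the
#' circle, so an origin-spanning two-exon join contributes none.
#' @param f a `mito_feature`.
#' @param L genome length.
#' @return non-negative integer.
#' @export
n_introns <- function(f, L) sum(exon_gaps(f, L) > 0L)

#' Validate a mitogenome record
#'
#' Errors on coordinate violations and duplicate (label, copy) pairs; warns
#' when a tRNA length falls outside the 61-88 bp range seen in validated
#' fungal mitogenomes, or when a wrap-around feature occurs on a linear
#' record.
#' @param record a `mitogenome`.
#' @return the record, invisibly.
#' @export
validate_mitogenome <- function(record) {
  L <- nchar(record$sequence)
  if (L == 0L) stop("empty sequence")
  if (!grepl("^[ACGTN]*$", record$sequence))
    stop("sequence contains characters outside A/C/G/T/N")
  keys <- character(0)
  for (f in record$features) {
    if (any(f$exons < 1L) || any(f$exons > L))
      stop("feature ", f$gene_label, " has coordinates outside [1, ", L, "]")
    n <- nrow(f$exons)
    if (n > 1L) {
      gaps <- exon_gaps(f, L)
      if (record$topology == "linear" &&
          any(f$exons[-1L, "start"] < f$exons[-n, "end"]))
        stop("feature ", f$gene_label,
             " wraps the origin of a linear record")
      covered <- unlist(lapply(seq_len(n), function(i)
        circ_positions(f$exons[i, "start"], f$exons[i, "end"], L)))
      if (anyDuplicated(covered))
        stop("overlapping exons in feature ", f$gene_label)
    }
    key <- paste(f$gene_label, f$copy_index)
    if (key %in% keys)
      stop("duplicate (gene_label, copy_index): ", key)
    keys <- c(keys, key)
    if (f$kind == "tRNA") {
      len <- feature_length(f)
      if (len < 61L || len > 88L)
        warning("tRNA ", f$gene_label, " length ", len,
                " outside the validated 61-88 bp range", call. = FALSE)
    }
  }
  invisible(record)
}

#' Spliced, strand-corrected sequence of a gene
#'
#' @param record a `mitogenome`.
#' @param label canonical gene label.
#' @param copy copy index (default 1).
#' @return nucleotide string in coding orientation; its length equals the
#'   sum of the exon lengths.
#' @export
extract_gene_sequence <- function(record, label, copy = 1L) {
  f <- find_feature(record, label, copy)
  s <- paste(vapply(seq_len(nrow(f$exons)), function(i) {
    substring(record$sequence, f$exons[i, "start"], f$exons[i, "end"])
  }, character(1)), collapse = "")
  if (f$strand == "-") revcomp(s) else s
}

find_feature <- function(record, label, copy = 1L) {
  for (f in record$features)
    if (f$gene_label == label && f$copy_index == copy) return(f)
  stop("no feature '", label, "' copy ", copy, " in record ",
       record$record_id)
}

#' Rotate the origin of a circular record
#'
#' Moves the origin so that old position `offset + 1` becomes position 1;
#' features are shifted accordingly and exons newly straddling the origin
#' are split in two. Genome content is unchanged.
#' @param record a circular `mitogenome`.
#' @param offset integer in [0, length).
#' @return rotated `mitogenome`.
#' @export
rotate_record <- function(record, offset) {
  if (record$topology != "circular") stop("can only rotate a circular record")
  L <- nchar(record$sequence)
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(record)
  newpos <- function(p) ((p - 1L - offset) %% L) + 1L
  seq2 <- paste0(substring(record$sequence, offset + 1L, L),
                 substring(record$sequence, 1L, offset))
  feats <- lapply(record$features, function(f) {
    ex <- list()
    for (i in seq_len(nrow(f$exons))) {
      s <- newpos(f$exons[i, "start"]); e <- newpos(f$exons[i, "end"])
      if (s <= e) ex[[length(ex) + 1L]] <- c(s, e)
      else {                      # exon now straddles the origin
        ex[[length(ex) + 1L]] <- c(s, L)
        ex[[length(ex) + 1L]] <- c(1L, e)
      }
    }
    f$exons <- matrix(as.integer(unlist(lapply(ex, identity))), ncol = 2L,
                      byrow = TRUE, dimnames = list(NULL, c("start", "end")))
    f
  })
  mitogenome(record$record_id, record$species_name, seq2, feats,
             topology = "circular", validate = FALSE)
}

#' Reverse complement a whole record
#'
#' Flips the sequence, all strands, and all coordinates; spliced gene
#' sequences extracted from the result are unchanged.
#' @param record a `mitogenome`.
#' @return reverse-complemented `mitogenome`.
#' @export
revcomp_record <- function(record) {
  L <- nchar(record$sequence)
  feats <- lapply(record$features, function(f) {
    ex <- f$exons[rev(seq_len(nrow(f$exons))), , drop = FALSE]
    f$exons <- cbind(start = L - ex[, "end"] + 1L,
                     end   = L - ex[, "start"] + 1L)
    f$strand <- if (f$strand == "+") "-" else "+"
    f
  })
  mitogenome(record$record_id, record$species_name, revcomp(record$sequence),
             feats, topology = record$topology, validate = FALSE)
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("<mitogenome> ", x$record_id, " (", x$species_name, ")\n", sep = "")
  cat("  ", x$topology, ", ", format(nchar(x$sequence), big.mark = ","),
      " bp, ", length(x$features), " features\n", sep = "")
  kinds <- table(vapply(x$features, `[[`, character(1), "kind"))
  if (length(kinds))
    cat("  ", paste(names(kinds), as.integer(kinds), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
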