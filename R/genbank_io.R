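# GenBank flat-file I/O, scoped to annotated organelle records: LOCUS /
# DEFINITION / FEATURES (source, gene, CDS, tRNA, rRNA with join/complement
# locations) / ORIGIN. Written files round-trip losslessly through
# read_genbank(). Text is UTF-8 with Unix newlines.

#' Read an annotated mitogenome from a GenBank flat file
#'
#' CDS, tRNA and rRNA features (plus `gene` features not shadowed by one of
#' those) are mapped to [mito_feature()]s; multi-interval `join(...)`
#' locations, including origin-spanning joins on circular records, become
#' exon lists; labels are normalized with [normalize_gene_label()], and
#' unknown labels are kept verbatim with a warning.
#'
#' @param path file path.
#' @return a `mitogenome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L)
    stop("malformed GenBank file (line ", if (length(locus_i)) locus_i[2] else 1,
         "): expected exactly one LOCUS line")
  toks <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  record_id <- toks[2]
  seq_len_declared <- suppressWarnings(as.integer(toks[3]))
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"

  species <- ""
  org_i <- grep("/organism=", lines)
  if (length(org_i))
    species <- sub('.*?/organism="([^"]*)".*', "\\1", lines[org_i[1]])
  else {
    def_i <- grep("^DEFINITION", lines)
    if (length(def_i))
      species <- trimws(sub("^DEFINITION\\s*", "", lines[def_i[1]]))
  }

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1L)
    stop("malformed GenBank file: missing ORIGIN block")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i][1] else length(lines) + 1L
  seq_lines <- lines[(origin_i + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence))
    stop("malformed GenBank file (line ", origin_i, "): empty sequence block")
  if (!is.na(seq_len_declared) && nchar(sequence) != seq_len_declared)
    stop("declared length ", seq_len_declared, " but sequence has ",
         nchar(sequence), " bp")

  feat_i <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(origin_i - 1L)]
    feats <- parse_feature_block(block, feat_i[1], nchar(sequence), topology)
  }
  mitogenome(record_id, species, sequence, feats, topology = topology)
}

parse_feature_block <- function(block, offset, L, topology) {
  # group physical lines into feature entries: a new entry starts with a
  # key in columns 6-20
  entries <- list(); cur <- NULL
  for (j in seq_along(block)) {
    line <- block[j]
    if (!nzchar(trimws(line))) next
    if (grepl("^ {5}\\S", line)) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      key <- trimws(substr(line, 1, 20))
      cur <- list(key = key, text = trimws(substring(line, 21)), line = j + offset)
    } else if (grepl("^ {21}", line) || grepl("^\\s+\\S", line)) {
      if (is.null(cur))
        stop("malformed GenBank file (line ", j + offset,
             "): continuation before any feature key")
      cur$text <- c(cur$text, trimws(line))
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur

  raw <- list()
  for (en in entries) {
    if (!en$key %in% c("CDS", "tRNA", "rRNA", "gene")) next
    # location = leading lines up to the first qualifier
    qual_start <- which(grepl("^/", en$text))[1]
    loc_txt <- paste(en$text[seq_len(if (is.na(qual_start)) length(en$text)
                                     else qual_start - 1L)], collapse = "")
    quals <- if (is.na(qual_start)) character(0) else
      en$text[qual_start:length(en$text)]
    loc <- parse_location(loc_txt, en$line)
    label_raw <- qualifier_value(quals, "gene") %||%
      qualifier_value(quals, "product") %||% ""
    anticodon <- parse_anticodon(quals)
    raw[[length(raw) + 1L]] <- list(key = en$key, loc = loc,
                                    label_raw = label_raw,
                                    anticodon = anticodon, line = en$line)
  }

  # gene-key entries only stand in when no CDS/tRNA/rRNA carries the label
  norm <- normalize_gene_label(vapply(raw, `[[`, character(1), "label_raw"))
  labels <- norm$label
  typed <- vapply(raw, function(r) r$key != "gene", logical(1))
  keep <- typed | !(labels %in% labels[typed])
  if (any(!norm$known[keep] & nzchar(labels[keep])))
    warning("unrecognized gene label(s) kept verbatim: ",
            paste(unique(labels[keep][!norm$known[keep]]), collapse = ", "),
            call. = FALSE)

  feats <- list(); copy_seen <- integer(0)
  for (i in which(keep)) {
    r <- raw[[i]]
    lab <- labels[i]
    if (!nzchar(lab)) lab <- paste0("unknown_", r$key)
    kind <- switch(r$key,
                   CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   gene = if (is_trna_label(lab)) "tRNA"
                          else if (lab %in% c("rnl", "rns")) "rRNA" else "PCG")
    if (any(r$loc$exons > L))
      stop("feature at line ", r$line, " (", lab,
           ") has coordinates beyond sequence length ", L)
    cnt <- copy_seen[lab]; if (is.na(cnt)) cnt <- 0L
    copy_seen[lab] <- cnt + 1L
    feats[[length(feats) + 1L]] <-
      mito_feature(lab, kind, r$loc$exons, strand = r$loc$strand,
                   anticodon = r$anticodon, copy_index = cnt + 1L)
  }
  feats
}

qualifier_value <- function(quals, name) {
  pat <- paste0("^/", name, "=")
  hit <- grep(pat, quals)
  if (!length(hit)) return(NULL)
  v <- sub(pat, "", quals[hit[1]])
  gsub('"', "", v)
}

parse_anticodon <- function(quals) {
  note <- qualifier_value(quals, "note")
  if (!is.null(note) && grepl("anticodon:", note))
    return(tolower(sub(".*anticodon:\\s*([A-Za-z]{3}).*", "\\1", note)))
  ac <- qualifier_value(quals, "anticodon")
  if (!is.null(ac) && grepl("seq:", ac))
    return(tolower(sub(".*seq:([A-Za-z]{3}).*", "\\1", ac)))
  NA_character_
}

parse_location <- function(txt, line) {
  txt <- gsub("\\s", "", txt)
  strand <- "+"
  if (grepl("^complement\\(", txt)) {
    strand <- "-"
    txt <- sub("^complement\\((.*)\\)$", "\\1", txt)
  }
  if (grepl("^join\\(", txt)) txt <- sub("^join\\((.*)\\)$", "\\1", txt)
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  ivs <- lapply(parts, function(p) {
    if (grepl("^<?\\d+\\.\\.>?\\d+$", p)) {
      as.integer(strsplit(gsub("[<>]", "", p), "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      rep(as.integer(p), 2L)
    } else stop("malformed location '", p, "' at line ", line)
  })
  exons <- do.call(rbind, ivs)
  colnames(exons) <- c("start", "end")
  list(exons = exons, strand = strand)
}

#' Write a mitogenome to a GenBank flat file
#'
#' The record is validated first; origin-spanning exons are serialized as a
#' two-interval `join`, minus-strand features with `complement(...)`.
#' @param record a `mitogenome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  validate_mitogenome(record)
  L <- nchar(record$sequence)
  con <- file(path, "wb")              # force Unix newlines
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con, sep = "\n")
  w(sprintf("LOCUS       %-16s %d bp    DNA     %-8s UNA 01-JAN-2026",
            record$record_id, L, record$topology))
  w("DEFINITION  ", record$species_name, " mitochondrion.")
  w("ACCESSION   ", record$record_id)
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     %-16s%s", "source", paste0("1..", L)))
  w(sprintf("                     /organism=\"%s\"", record$species_name))
  for (f in record$features) {
    key <- switch(f$kind, PCG = "CDS", rRNA = "rRNA", tRNA = "tRNA")
    loc <- location_string(f)
    w(sprintf("     %-16s%s", key, loc))
    w(sprintf("                     /gene=\"%s\"", f$gene_label))
    if (f$kind == "PCG")
      w("                     /transl_table=4")
    if (!is.na(f$anticodon))
      w(sprintf("                     /note=\"anticodon:%s\"", f$anticodon))
  }
  w("ORIGIN")
  for (s in seq(1L, L, 60L)) {
    chunk <- substring(record$sequence, s, min(s + 59L, L))
    grp <- substring(chunk, seq(1, nchar(chunk), 10),
                     pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w(sprintf("%9d %s", s, tolower(paste(grp, collapse = " "))))
  }
  w("//")
  invisible(path)
}

location_string <- function(f) {
  ivs <- apply(f$exons, 1L, function(r)
    if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "..", r[2]))
  loc <- if (length(ivs) > 1L) paste0("join(", paste(ivs, collapse = ","), ")")
         else ivs
  if (f$strand == "-") paste0("complement(", loc, ")") else loc
}

#' Write spliced gene sequences to a FASTA file
#'
#' @param record a `mitogenome`.
#' @param path output path.
#' @param labels gene labels to write (default: all features).
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(record, path, labels = NULL) {
  feats <- record$features
  if (!is.null(labels))
    feats <- Filter(function(f) f$gene_label %in% labels, feats)
  seqs <- vapply(feats, function(f)
    extract_gene_sequence(record, f$gene_label, f$copy_index), character(1))
  names(seqs) <- vapply(feats, function(f)
    if (f$copy_index > 1L) paste0(f$gene_label, ".", f$copy_index)
    else f$gene_label, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read an aligned (or plain) FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @param aa read as amino-acid sequences.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta_alignment <- function(path, aa = FALSE) {
  x <- if (aa) Biostrings::readAAStringSet(path)
       else Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param aa write as amino-acid sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, aa = FALSE) {
  set <- if (aa) Biostrings::AAStringSet(seqs) else Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
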