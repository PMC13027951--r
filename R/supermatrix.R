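# Phylogenetic supermatrix construction: codon positions 1+2 (PCG12),
# PCG12 plus the rRNA alignments (PCG12R), and translated amino acids
# (AA), concatenated with a partition map, exported as relaxed PHYLIP /
# FASTA / RAxML-style partition files, with a neighbor-joining sanity
# tree over K2P distances.

#' Keep codon positions 1 and 2 of a codon-aware alignment
#'
#' @param alignment named character vector of equal-length rows, length
#'   divisible by 3.
#' @return alignment of 2/3 the length (columns 1,2,4,5,7,8,...).
#' @export
codon_positions_12 <- function(alignment) {
  n <- unique(nchar(alignment))
  if (length(n) != 1L) stop("rows have unequal lengths")
  if (n %% 3L != 0L) stop("alignment length ", n, " is not codon-aware")
  idx <- which(seq_len(n) %% 3L != 0L)
  vapply(alignment, function(s)
    paste(split_chars(s)[idx], collapse = ""), character(1))
}

#' Translate a codon-aware alignment to amino acids
#'
#' All-gap codons ("---") become the gap residue "-". A terminal stop
#' column (every row ending in a stop or an all-gap codon) is dropped
#' before translation; if only some rows end in a stop those stops are
#' translated to "*" with a warning. An internal stop is an error naming
#' the taxon and codon position.
#'
#' @param alignment named character vector, equal lengths divisible by 3.
#' @param code a [genetic_code()] (table 4 by default, so TGA = Trp).
#' @param gene gene label used in error messages.
#' @return named character vector of amino-acid rows.
#' @export
translate_alignment <- function(alignment, code = genetic_code(4L),
                                gene = "") {
  n <- unique(nchar(alignment))
  if (length(n) != 1L) stop("rows have unequal lengths")
  if (n %% 3L != 0L) stop("alignment length ", n, " is not codon-aware")
  codons <- lapply(alignment, split_codons)
  nc <- n / 3L
  terminal <- vapply(codons, function(x) x[nc], character(1))
  if (any(terminal %in% code$stops)) {
    if (all(terminal %in% code$stops | terminal == "---")) {
      codons <- lapply(codons, function(x) x[-nc])
      nc <- nc - 1L
    } else {
      warning("terminal stop codons in only some rows",
              if (nzchar(gene)) paste0(" of ", gene) else "",
              "; translating as '*'", call. = FALSE)
    }
  }
  out <- vapply(seq_along(codons), function(i) {
    x <- codons[[i]]
    aa <- character(length(x))
    for (k in seq_along(x)) {
      cdn <- x[k]
      if (cdn == "---") { aa[k] <- "-"; next }
      if (!grepl("^[ACGT]{3}$", cdn)) { aa[k] <- "X"; next }
      r <- code$codons[[cdn]]
      if (r == "*" && k < length(x))
        stop("internal stop codon in ",
             if (nzchar(gene)) paste0(gene, ", ") else "",
             "taxon ", names(codons)[i], ", codon ", k)
      aa[k] <- r
    }
    paste(aa, collapse = "")
  }, character(1))
  stats::setNames(out, names(alignment))
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in a fixed configured order (default: the
#' conserved Phallales genomic order, then alphabetical for anything
#' else), so identical inputs give byte-identical output regardless of
#' list order. A taxon missing a gene receives an all-gap block.
#'
#' @param alignments named list: gene -> named character vector of rows.
#' @param taxa taxon order (default: first-seen order across genes).
#' @param gene_order preferred gene order.
#' @param name dataset name.
#' @param alphabet "nucleotide" or "amino-acid".
#' @return object of class `supermatrix`: list with `name`, `taxa`, `rows`
#'   (named character vector), `partitions` (data.frame gene/start/end)
#'   and `alphabet`.
#' @export
concatenate_alignments <- function(alignments, taxa = NULL,
                                   gene_order = CORE_ORDER,
                                   name = "concat",
                                   alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  genes <- names(alignments)
  genes <- c(intersect(gene_order, genes), sort(setdiff(genes, gene_order)))
  if (is.null(taxa)) {
    taxa <- character(0)
    for (g in genes) taxa <- union(taxa, names(alignments[[g]]))
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list(); at <- 0L
  for (g in genes) {
    aln <- alignments[[g]]
    w <- unique(nchar(aln))
    if (length(w) != 1L) stop("gene ", g, " has rows of unequal length")
    gapblock <- strrep("-", w)
    block <- vapply(taxa, function(t)
      if (t %in% names(aln)) aln[[t]] else gapblock, character(1))
    rows <- paste0(rows, block)
    parts[[length(parts) + 1L]] <- data.frame(gene = g, start = at + 1L,
                                              end = at + w)
    at <- at + w
  }
  names(rows) <- taxa
  structure(list(name = name, taxa = taxa, rows = rows,
                 partitions = do.call(rbind,
                                      c(parts, list(make.row.names = FALSE))),
                 alphabet = alphabet),
            class = "supermatrix")
}

#' Build one of the three standard supermatrix datasets
#'
#' PCG12 = codon positions 1+2 of the protein-coding genes; PCG12R = PCG12
#' plus the rRNA alignments; AA = translated amino acids. By construction
#' |PCG12| = 2 x |AA| and |PCG12R| - |PCG12| = total rRNA columns.
#'
#' @param pcg_alignments named list of codon-aware CDS alignments.
#' @param rrna_alignments named list of rRNA alignments (for PCG12R).
#' @param dataset "PCG12", "PCG12R" or "AA".
#' @param code a [genetic_code()].
#' @return a `supermatrix`.
#' @export
build_supermatrix <- function(pcg_alignments, rrna_alignments = NULL,
                              dataset = c("PCG12", "PCG12R", "AA"),
                              code = genetic_code(4L)) {
  dataset <- match.arg(dataset)
  # work on the stop-trimmed alignment so PCG12 and AA stay in 2:1 step
  trimmed <- lapply(names(pcg_alignments), function(g) {
    aln <- pcg_alignments[[g]]
    nc <- unique(nchar(aln))
    if (length(nc) != 1L || nc %% 3L != 0L)
      stop("gene ", g, " is not a codon-aware alignment")
    term <- vapply(aln, function(s) substring(s, nc - 2L, nc), character(1))
    if (all(term %in% code$stops | term == "---"))
      aln <- vapply(aln, function(s) substring(s, 1L, nc - 3L), character(1))
    aln
  })
  names(trimmed) <- names(pcg_alignments)
  if (dataset == "AA") {
    aa <- lapply(names(trimmed), function(g)
      translate_alignment(trimmed[[g]], code, gene = g))
    names(aa) <- names(trimmed)
    return(concatenate_alignments(aa, name = "AA", alphabet = "amino-acid"))
  }
  p12 <- lapply(trimmed, codon_positions_12)
  if (dataset == "PCG12")
    return(concatenate_alignments(p12, name = "PCG12"))
  if (is.null(rrna_alignments)) stop("PCG12R needs rRNA alignments")
  concatenate_alignments(c(p12, rrna_alignments), name = "PCG12R")
}

#' Write a supermatrix as relaxed PHYLIP, FASTA and a partition file
#'
#' @param sm a `supermatrix`.
#' @param prefix output path prefix; writes `<prefix>.phy`,
#'   `<prefix>.fasta` and `<prefix>.partitions` (RAxML-style,
#'   `DNA, gene = start-end`).
#' @return invisible character vector of the written paths.
#' @export
write_supermatrix <- function(sm, prefix) {
  nchr <- unique(nchar(sm$rows))
  phy <- file.path(paste0(prefix, ".phy"))
  con <- file(phy, "wb"); on.exit(close(con))
  writeLines(paste(length(sm$taxa), nchr), con)
  writeLines(paste(format(sm$taxa, width = max(nchar(sm$taxa)) + 2L),
                   sm$rows), con)
  close(con); on.exit()
  fa <- paste0(prefix, ".fasta")
  write_fasta(sm$rows, fa, aa = sm$alphabet == "amino-acid")
  type <- if (sm$alphabet == "amino-acid") "AA" else "DNA"
  part <- paste0(prefix, ".partitions")
  writeLines(sprintf("%s, %s = %d-%d", type, sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), part)
  invisible(c(phy, fa, part))
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param alignment named character vector of aligned rows.
#' @return list with `matrix` (symmetric, zero diagonal, NA where the
#'   distance is saturated) and `undefined` (logical mask).
#' @export
k2p_matrix <- function(alignment) {
  taxa <- names(alignment)
  n <- length(taxa)
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- k2p_distance(alignment[[i]], alignment[[j]])
    m[i, j] <- m[j, i] <- if (d$defined) d$d_k2p else NA_real_
  }
  list(matrix = m, undefined = is.na(m) & !diag(n))
}

#' Neighbor-joining sanity tree from a distance matrix
#'
#' Classical neighbor joining (via ape); negative branch lengths are
#' clamped to zero with a warning.
#' @param dm a distance matrix (plain symmetric matrix or the list
#'   returned by [k2p_matrix()]).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  m <- if (is.list(dm)) dm$matrix else dm
  if (nrow(m) < 3L) stop("need at least 3 taxa")
  if (any(is.na(m))) {
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
    stop("undefined distances between: ",
         paste(rownames(m)[bad[, 1]], colnames(m)[bad[, 2]],
               sep = "~", collapse = ", "))
  }
  tr <- ape::nj(m)
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0", call. = FALSE)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
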