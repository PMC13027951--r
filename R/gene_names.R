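# Gene-label normalization. Mitochondrial annotation pipelines (MITOS,
# Mfannot, manual curation) emit different vocabularies for the same gene;
# everything downstream works on the canonical lower-case forms
# cox1..cox3, cob, nad1..nad6, nad4L, atp6/8/9, rps3, rnl, rns and trnX
# (X = one-letter amino acid code). Unknown labels are kept verbatim and
# flagged, never dropped.

#' The 15 canonical protein-coding gene labels, in published Phallales order
#' @export
PCG_LABELS <- c("cox1", "nad4", "cox3", "atp8", "nad4L", "nad5", "cox2",
                "nad2", "nad3", "nad1", "nad6", "cob", "atp6", "rps3", "atp9")

#' Canonical gene labels of the Phallales core order (PCGs + rRNAs)
#'
#' The 17-element conserved arrangement cox1-nad4-cox3-atp8-nad4L-nad5-rnl-
#' cox2-nad2-nad3-nad1-nad6-cob-rns-atp6-rps3-atp9.
#' @export
CORE_ORDER <- c("cox1", "nad4", "cox3", "atp8", "nad4L", "nad5", "rnl",
                "cox2", "nad2", "nad3", "nad1", "nad6", "cob", "rns",
                "atp6", "rps3", "atp9")

AA3_TO_1 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
              gln = "Q", glu = "E", gly = "G", his = "H", ile = "I",
              leu = "L", lys = "K", met = "M", phe = "F", pro = "P",
              ser = "S", thr = "T", trp = "W", tyr = "Y", val = "V")

.mitocomp_env <- new.env(parent = emptyenv())

#' Gene-name synonym table
#'
#' @return data.frame with columns `synonym` and `canonical`, as shipped in
#'   `extdata/gene_synonyms.tsv`.
#' @export
gene_synonym_table <- function() {
  if (is.null(.mitocomp_env$synonyms)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp")
    .mitocomp_env$synonyms <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .mitocomp_env$synonyms
}

#' Normalize a gene label to its canonical form
#'
#' @param x character vector of raw labels (gene names or products).
#' @return list with `label` (canonical or verbatim input) and `known`
#'   (logical: whether the label was recognized).
#' @export
normalize_gene_label <- function(x) {
  syn <- gene_synonym_table()
  out <- character(length(x))
  known <- logical(length(x))
  key <- tolower(trimws(x))
  for (i in seq_along(x)) {
    k <- key[i]
    hit <- match(k, syn$synonym)
    if (!is.na(hit)) {
      out[i] <- syn$canonical[hit]; known[i] <- TRUE
    } else if (grepl("^trn[a-z]$", k)) {
      out[i] <- paste0("trn", toupper(substr(k, 4, 4))); known[i] <- TRUE
    } else if (grepl("^trn[A-Za-z]", trimws(x[i]))) {
      # trnM(cat), trnL2, trnS-uga ...
      out[i] <- paste0("trn", toupper(substr(trimws(x[i]), 4, 4)))
      known[i] <- TRUE
    } else if (grepl("^trna-", k)) {
      aa3 <- substr(k, 6, 8)
      if (aa3 %in% names(AA3_TO_1)) {
        out[i] <- paste0("trn", AA3_TO_1[[aa3]]); known[i] <- TRUE
      } else {
        out[i] <- x[i]
      }
    } else {
      out[i] <- x[i]
    }
  }
  list(label = out, known = known)
}

is_trna_label <- function(x) grepl("^trn[A-Z]$", x)
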