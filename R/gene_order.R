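# Circular gene-order normalization and comparison. Orders are linearized
# at an anchor gene (cox1 by default) after choosing the orientation in
# which the majority of protein-coding genes sit on the plus strand, so
# rotating or fully reverse-complementing a genome leaves the normalized
# order unchanged. Duplicate labels are disambiguated by position-order
# copy indices.

#' Extract the normalized circular gene order of a record
#'
#' @param record a validated `mitogenome` with at least one feature.
#' @param include_trna include tRNA genes (FALSE gives the PCG + rRNA
#'   backbone).
#' @param anchor gene label used for linearization; if absent the
#'   lexicographically smallest protein-coding label is used with a
#'   warning.
#' @return object of class `gene_order`: list with `taxon`, `order`
#'   (data.frame label/strand/copy in circular order from the anchor) and
#'   `anchor`.
#' @export
extract_order <- function(record, include_trna = TRUE, anchor = "cox1") {
  feats <- record$features
  if (!include_trna)
    feats <- Filter(function(f) f$kind != "tRNA", feats)
  if (!length(feats)) stop("record has no features to order")
  start <- vapply(feats, function(f) f$exons[1, "start"], integer(1))
  feats <- feats[order(start)]
  df <- data.frame(
    label = vapply(feats, `[[`, character(1), "gene_label"),
    strand = vapply(feats, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  norm <- normalize_order_df(df, anchor, record$record_id)
  structure(list(taxon = record$species_name, order = norm$df,
                 anchor = norm$anchor),
            class = "gene_order")
}

normalize_order_df <- function(df, anchor, id = "") {
  pcg <- !grepl("^trn", df$label) & !df$label %in% c("rnl", "rns")
  if (any(pcg) && mean(df$strand[pcg] == "-") > 0.5) {
    df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    df$strand <- ifelse(df$strand == "+", "-", "+")
  }
  if (!anchor %in% df$label) {
    cand <- sort(df$label[pcg])
    if (!length(cand)) cand <- sort(df$label)
    warning("anchor '", anchor, "' absent from ", id,
            "; using '", cand[1], "'", call. = FALSE)
    anchor <- cand[1]
  }
  i <- which(df$label == anchor)[1]
  if (i > 1L) df <- df[c(i:nrow(df), 1:(i - 1L)), , drop = FALSE]
  df$copy <- stats::ave(seq_len(nrow(df)), df$label, FUN = seq_along)
  rownames(df) <- NULL
  df
  list(df = df, anchor = anchor)
}

signed_labels <- function(ord) paste0(ifelse(ord$order$strand == "-", "-", ""),
                                      ord$order$label)

#' Compare two normalized gene orders
#'
#' @param a,b `gene_order` objects.
#' @param ignore_duplicates drop surplus copies of any label present more
#'   often in one taxon than the other before comparing.
#' @return list with `identical` (logical), `divergence_at` (1-based index
#'   of the first differing position, or NA), and the compared label
#'   vectors `a_labels`, `b_labels`.
#' @export
orders_identical <- function(a, b, ignore_duplicates = FALSE) {
  da <- a$order; db <- b$order
  if (ignore_duplicates) {
    keep <- function(d, other) {
      cnt_other <- table(other$label)
      k <- stats::ave(seq_len(nrow(d)), d$label, FUN = seq_along)
      lim <- as.integer(cnt_other[d$label])
      lim[is.na(lim)] <- 0L
      d[k <= lim, , drop = FALSE]
    }
    da2 <- keep(da, db); db2 <- keep(db, da)
    da <- da2; db <- db2
  }
  la <- paste0(ifelse(da$strand == "-", "-", ""), da$label)
  lb <- paste0(ifelse(db$strand == "-", "-", ""), db$label)
  if (length(la) != length(lb))
    return(list(identical = FALSE, divergence_at = min(length(la),
                                                       length(lb)) + 1L,
                a_labels = la, b_labels = lb))
  diff <- which(la != lb)
  list(identical = !length(diff),
       divergence_at = if (length(diff)) diff[1] else NA_integer_,
       a_labels = la, b_labels = lb)
}

# canonical form of one circular adjacency between signed elements;
# (x -> y) and (-y -> -x) are the same adjacency
adjacency_set <- function(keys, strands) {
  n <- length(keys)
  nxt <- c(2:n, 1L)
  vapply(seq_len(n), function(i) {
    j <- nxt[i]
    fwd <- paste0(strands[i], keys[i], ">", strands[j], keys[j])
    flip <- function(s) if (s == "-") "+" else "-"
    rev <- paste0(flip(strands[j]), keys[j], ">", flip(strands[i]), keys[i])
    min(fwd, rev)
  }, character(1))
}

#' Breakpoint distance between two circular gene orders
#'
#' Counts the adjacencies (unordered signed neighbor pairs on the circle)
#' present in `a` but not in `b`. Duplicate labels are disambiguated by
#' their position-order copy index. The two orders must carry the same
#' label multiset; with `reconcile = TRUE` surplus duplicate copies present
#' in only one taxon are dropped first (as in [orders_identical()]).
#'
#' @param a,b `gene_order` objects.
#' @param reconcile drop unmatched duplicate copies before comparing.
#' @return non-negative integer.
#' @export
breakpoint_distance <- function(a, b, reconcile = FALSE) {
  da <- a$order; db <- b$order
  if (reconcile) {
    keep <- function(d, other) {
      cnt_other <- table(other$label)
      k <- stats::ave(seq_len(nrow(d)), d$label, FUN = seq_along)
      lim <- as.integer(cnt_other[d$label])
      lim[is.na(lim)] <- 0L
      d <- d[k <= lim, , drop = FALSE]
      d$copy <- stats::ave(seq_len(nrow(d)), d$label, FUN = seq_along)
      d
    }
    da2 <- keep(da, db); db2 <- keep(db, da)
    da <- da2; db <- db2
  }
  ka <- paste0(da$label, ".", da$copy); kb <- paste0(db$label, ".", db$copy)
  if (!identical(sort(ka), sort(kb))) {
    sym <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("gene orders have different label multisets: ",
         paste(sym, collapse = ", "))
  }
  adj_a <- adjacency_set(ka, da$strand)
  adj_b <- adjacency_set(kb, db$strand)
  length(setdiff(adj_a, adj_b))
}

#' tRNA (and other) duplication events across genomes
#'
#' @param records list of validated `mitogenome` objects.
#' @return object of class `duplication_report`: list with `per_taxon`
#'   (named list of duplicated labels), `shared` (labels duplicated in
#'   every genome), `private` (per-taxon labels duplicated there but not
#'   shared by all), and `anticodons` (data.frame taxon/label/anticodons/
#'   identical for each duplicate pair).
#' @export
duplication_events <- function(records) {
  per_taxon <- list(); ac_rows <- list()
  for (rec in records) {
    labs <- vapply(rec$features, `[[`, character(1), "gene_label")
    dups <- sort(unique(labs[duplicated(labs)]))
    per_taxon[[rec$species_name]] <- dups
    for (d in dups) {
      acs <- vapply(rec$features[labs == d], `[[`, character(1), "anticodon")
      if (all(!is.na(acs)))
        ac_rows[[length(ac_rows) + 1L]] <- data.frame(
          taxon = rec$species_name, label = d,
          anticodons = paste(acs, collapse = "/"),
          identical = length(unique(acs)) == 1L)
    }
  }
  shared <- Reduce(intersect, per_taxon)
  private <- lapply(per_taxon, setdiff, y = shared)
  structure(list(
    per_taxon = per_taxon, shared = shared, private = private,
    anticodons = if (length(ac_rows))
      do.call(rbind, c(ac_rows, list(make.row.names = FALSE)))
    else data.frame(taxon = character(0), label = character(0),
                    anticodons = character(0), identical = logical(0))),
    class = "duplication_report")
}

#' @export
print.duplication_report <- function(x, ...) {
  cat("<duplication_report>\n  shared: ",
      paste(x$shared, collapse = ", "), "\n", sep = "")
  for (t in names(x$private))
    if (length(x$private[[t]]))
      cat("  private ", t, ": ", paste(x$private[[t]], collapse = ", "),
          "\n", sep = "")
  invisible(x)
}

#' Derive tRNA clusters from a gene order
#'
#' Groups maximal runs of consecutive tRNA genes between two non-tRNA
#' genes of the circular order; nothing about cluster membership is
#' hard-coded.
#' @param ord a `gene_order` (with tRNAs included).
#' @return data.frame with columns cluster, upstream_gene,
#'   downstream_gene, trnas (comma-separated labels in order).
#' @export
trna_clusters <- function(ord) {
  lab <- ord$order$label
  is_t <- grepl("^trn", lab)
  if (!any(is_t))
    return(data.frame(cluster = integer(0), upstream_gene = character(0),
                      downstream_gene = character(0), trnas = character(0)))
  n <- length(lab)
  rows <- list()
  i <- 1L
  while (i <= n) {
    if (is_t[i] && (i == 1L || !is_t[i - 1L])) {
      j <- i
      while (is_t[(j %% n) + 1L]) j <- j + 1L   # run may wrap the circle
      run <- ((i:j - 1L) %% n) + 1L
      up <- lab[((i - 2L) %% n) + 1L]
      down <- lab[(j %% n) + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = length(rows) + 1L, upstream_gene = up,
        downstream_gene = down, trnas = paste(lab[run], collapse = ","))
      i <- j + 1L
    } else i <- i + 1L
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' One-line order strings for a set of records
#'
#' @param records list of `mitogenome` objects.
#' @param include_trna include tRNAs.
#' @return named character vector, one arrangement string per taxon.
#' @export
order_strings <- function(records, include_trna = TRUE) {
  out <- vapply(records, function(r) {
    o <- extract_order(r, include_trna = include_trna)
    paste(signed_labels(o), collapse = "-")
  }, character(1))
  names(out) <- vapply(records, `[[`, character(1), "species_name")
  out
}
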