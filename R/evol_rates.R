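# Substitution-rate estimation: Kimura 2-parameter distances with pairwise
# site deletion, and Nei-Gojobori (1986) Ka/Ks with equal weighting over
# minimal mutational pathways and Jukes-Cantor correction, under an
# arbitrary genetic code (table 4 by default).

PURINES <- c("A", "G")

is_transition <- function(a, b) {
  (a %in% PURINES) == (b %in% PURINES)   # given a != b
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either row carries a gap or an ambiguous base are excluded
#' pairwise. P and Q are the transition and transversion proportions over
#' the retained sites and d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]. When the
#' argument of a logarithm is non-positive the distance is saturated and
#' reported as `NA` with `defined = FALSE`. The standard error follows
#' Kimura's (1980) delta-method variance.
#'
#' @param row_a,row_b aligned nucleotide strings of equal length.
#' @return list with `P`, `Q`, `d_k2p`, `se`, `n_sites`, `defined`.
#' @export
k2p_distance <- function(row_a, row_b) {
  a <- split_chars(toupper(row_a)); b <- split_chars(toupper(row_b))
  if (length(a) != length(b)) stop("rows have unequal lengths")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no unambiguous non-gap site shared by the two rows")
  diff <- a != b
  ts <- diff & (a %in% PURINES) == (b %in% PURINES)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(P = P, Q = Q, d_k2p = NA_real_, se = NA_real_,
                n_sites = n, defined = FALSE))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1; c2 <- 1 / w2; c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  list(P = P, Q = Q, d_k2p = d, se = sqrt(max(v, 0)), n_sites = n,
       defined = TRUE)
}

# ---- Nei-Gojobori (1986) machinery -----------------------------------------

# Per-codon synonymous site count: at each of the 3 positions, the fraction
# of the 3 possible changes that are synonymous; changes creating a stop
# codon are skipped while the denominator stays 3, so they fall on the
# nonsynonymous side and S + N = 3 * codons holds exactly.
ng86_site_table <- function(code) {
  key <- paste0("ng86_sites_", code$table_id)
  if (!is.null(.mitocomp_env[[key]])) return(.mitocomp_env[[key]])
  nt <- c("A", "C", "G", "T")
  syn <- stats::setNames(numeric(64L), names(code$codons))
  for (cdn in names(code$codons)) {
    if (code$codons[[cdn]] == "*") { syn[[cdn]] <- NA_real_; next }
    s <- 0
    ch <- split_chars(cdn)
    for (pos in 1:3) for (b in setdiff(nt, ch[pos])) {
      alt <- ch; alt[pos] <- b
      altc <- paste(alt, collapse = "")
      if (code$codons[[altc]] == "*") next
      if (code$codons[[altc]] == code$codons[[cdn]]) s <- s + 1 / 3
    }
    syn[[cdn]] <- s
  }
  .mitocomp_env[[key]] <- syn
  syn
}

PERMS <- list(`1` = matrix(1L, 1, 1),
              `2` = rbind(c(1L, 2L), c(2L, 1L)),
              `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair. Pathways passing through a stop codon are excluded; in the
# degenerate case where every pathway is blocked (cannot occur under table
# 4 with non-stop endpoints) all pathways are used.
ng86_pair_diff <- function(ca, cb, code) {
  cha <- split_chars(ca); chb <- split_chars(cb)
  pos <- which(cha != chb)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- PERMS[[as.character(k)]]
  tally <- function(exclude_stops) {
    sd <- nd <- 0; used <- 0L
    for (r in seq_len(nrow(paths))) {
      cur <- cha
      psd <- pnd <- 0
      blocked <- FALSE
      for (step in paths[r, seq_len(k)]) {
        nxt <- cur; nxt[pos[step]] <- chb[pos[step]]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (exclude_stops && code$codons[[c2]] == "*" && c2 != cb) {
          blocked <- TRUE; break
        }
        if (code$codons[[c1]] == code$codons[[c2]]) psd <- psd + 1
        else pnd <- pnd + 1
        cur <- nxt
      }
      if (!blocked) { sd <- sd + psd; nd <- nd + pnd; used <- used + 1L }
    }
    if (used == 0L) return(NULL)
    c(sd = sd / used, nd = nd / used)
  }
  tally(TRUE) %||% tally(FALSE)
}

# cached 64x64 lookup of pathway-averaged (sd, nd)
ng86_pair_tables <- function(code) {
  key <- paste0("ng86_pairs_", code$table_id)
  if (!is.null(.mitocomp_env[[key]])) return(.mitocomp_env[[key]])
  cods <- names(code$codons)
  sd <- nd <- matrix(NA_real_, 64, 64, dimnames = list(cods, cods))
  for (i in seq_len(64L)) for (j in seq_len(64L)) {
    if (code$codons[[i]] == "*" || code$codons[[j]] == "*") next
    v <- ng86_pair_diff(cods[i], cods[j], code)
    sd[i, j] <- v[["sd"]]; nd[i, j] <- v[["nd"]]
  }
  .mitocomp_env[[key]] <- list(sd = sd, nd = nd)
  .mitocomp_env[[key]]
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of coding sequences
#'
#' Synonymous site fractions are computed from the genetic code and
#' averaged over the two sequences; codon differences at more than one
#' position are averaged over all minimal mutational pathways with equal
#' weight, excluding pathways through stop codons. Proportions are
#' corrected with the Jukes-Cantor formula. Codon pairs containing a gap,
#' an ambiguous base, or a stop codon are excluded pairwise (a shared
#' terminal stop is simply dropped); an internal stop is an error.
#'
#' @param codons_a,codons_b CDS strings of equal length divisible by 3.
#' @param code a [genetic_code()].
#' @return object of class `gene_pair_rates`: list with `Sd`, `Nd`, `S`,
#'   `N`, `pS`, `pN`, `Ka`, `Ks`, `ka_ks` and `n_codons_used`. `Ka`/`Ks`
#'   are `NA` when the corrected rate is undefined (p >= 3/4); `ka_ks` is
#'   `NA` when `Ks` is 0 or undefined.
#' @export
ng86_kaks <- function(codons_a, codons_b, code = genetic_code(4L)) {
  a <- toupper(codons_a); b <- toupper(codons_b)
  if (nchar(a) != nchar(b)) stop("sequences have unequal lengths")
  ca <- split_codons(a); cb <- split_codons(b)
  for (nmseq in list(c("a", list(ca)), c("b", list(cb)))) {
    cods <- nmseq[[2]]
    stops <- which(cods %in% code$stops)
    if (any(stops < length(cods)))
      stop("internal stop codon in sequence ", nmseq[[1]], " at codon ",
           stops[stops < length(cods)][1])
  }
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb) &
    !(ca %in% code$stops) & !(cb %in% code$stops)
  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) stop("no comparable codon pairs")
  sites <- ng86_site_table(code)
  S_a <- sum(sites[ca]); S_b <- sum(sites[cb])
  S <- (S_a + S_b) / 2
  N <- 3 * length(ca) - S
  pt <- ng86_pair_tables(code)
  idx <- cbind(match(ca, rownames(pt$sd)), match(cb, colnames(pt$sd)))
  Sd <- sum(pt$sd[idx]); Nd <- sum(pt$nd[idx])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  ka_ks <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(Sd = Sd, Nd = Nd, S = S, N = N, pS = pS, pN = pN,
                 Ka = Ka, Ks = Ks, ka_ks = ka_ks,
                 n_codons_used = length(ca)),
            class = "gene_pair_rates")
}

#' @export
print.gene_pair_rates <- function(x, ...) {
  cat(sprintf(
    "<gene_pair_rates> %d codons | Sd %.2f Nd %.2f | S %.1f N %.1f | Ka %s Ks %s Ka/Ks %s\n",
    x$n_codons_used, x$Sd, x$Nd, x$S, x$N,
    format(x$Ka, digits = 4), format(x$Ks, digits = 4),
    format(x$ka_ks, digits = 4)))
  invisible(x)
}

#' Per-gene, per-species length / GC / skew panel
#'
#' @param gene_seqs named list: gene label -> named character vector of
#'   (possibly gap-containing) sequences per species. Gaps are removed
#'   before computing statistics; a species missing a gene is recorded as
#'   absent.
#' @return list with `per_species` (data.frame gene/species/length_bp/
#'   gc_percent/at_skew/gc_skew) and `per_gene` (data.frame gene/mean_gc/
#'   max_length_diff/n_species).
#' @export
gene_panel_stats <- function(gene_seqs) {
  rows <- list()
  for (g in names(gene_seqs)) {
    v <- gene_seqs[[g]]
    for (sp in names(v)) {
      s <- gsub("-", "", toupper(v[[sp]]), fixed = TRUE)
      if (!nzchar(s)) next
      comp <- base_composition(s); sk <- skew(s)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, species = sp, length_bp = nchar(s),
        gc_percent = comp$gc_percent,
        at_skew = round_half_up(sk$at_skew, 4),
        gc_skew = round_half_up(sk$gc_skew, 4))
    }
  }
  per_species <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  agg <- lapply(split(per_species, per_species$gene), function(d)
    data.frame(gene = d$gene[1],
               mean_gc = round_half_up(mean(d$gc_percent), 2),
               max_length_diff = max(d$length_bp) - min(d$length_bp),
               n_species = nrow(d)))
  per_gene <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  per_gene <- per_gene[match(names(gene_seqs), per_gene$gene), ]
  rownames(per_gene) <- NULL
  list(per_species = per_species, per_gene = per_gene)
}

#' Per-gene mean Ka, Ks, Ka/Ks and K2P over all species pairs
#'
#' Means are arithmetic means over all unordered species pairs for which
#' the quantity is defined; the number of excluded (undefined) pairs is
#' reported per gene. Per-gene Ka/Ks is the mean of per-pair ratios.
#'
#' @param alignments named list: gene label -> named character vector of
#'   codon-aware aligned CDS rows (equal lengths, divisible by 3).
#' @param code a [genetic_code()].
#' @return data.frame with columns gene, ka, ks, ka_ks, k2p, n_pairs,
#'   n_undefined_kaks, n_undefined_k2p. A gene with no defined pair gets
#'   `NA` means.
#' @export
rate_summary <- function(alignments, code = genetic_code(4L)) {
  rows <- list()
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    taxa <- names(aln)
    if (length(taxa) < 2L) stop("gene ", g, " has fewer than 2 taxa")
    ka <- ks <- kk <- dd <- numeric(0)
    und_kaks <- und_k2p <- 0L
    for (i in seq_len(length(taxa) - 1L)) for (j in (i + 1L):length(taxa)) {
      r <- ng86_kaks(aln[[i]], aln[[j]], code)
      if (!is.na(r$Ka) && !is.na(r$Ks)) { ka <- c(ka, r$Ka); ks <- c(ks, r$Ks) }
      if (!is.na(r$ka_ks)) kk <- c(kk, r$ka_ks) else und_kaks <- und_kaks + 1L
      d <- k2p_distance(aln[[i]], aln[[j]])
      if (d$defined) dd <- c(dd, d$d_k2p) else und_k2p <- und_k2p + 1L
    }
    mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, ka = mean_or_na(ka), ks = mean_or_na(ks),
      ka_ks = mean_or_na(kk), k2p = mean_or_na(dd),
      n_pairs = length(taxa) * (length(taxa) - 1L) / 2L,
      n_undefined_kaks = und_kaks, n_undefined_k2p = und_k2p)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
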