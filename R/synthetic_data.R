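# Seeded generator for Phallales-like annotated mitogenomes and for
# sequence sets evolved under known parameters, so every pipeline stage is
# testable with a known ground truth. Defaults emulate the published
# study conditions: circular genomes of 41-100 kb at ~24.5% GC with
# positive AT and GC skew, 15 protein-coding genes + 2 rRNAs in the
# conserved order, 24-25 tRNAs in six clusters with the shared trnM/L/R/S
# doublings, introns concentrated in cox1/cob/rnl, and large intergenic
# tracts.

# base frequencies with G > C and A > T, giving GC ~ gc and positive skews
phallales_base_freqs <- function(gc = 0.245) {
  c(A = (1 - gc) * 0.515, C = gc * 0.46, G = gc * 0.54, T = (1 - gc) * 0.485)
}

# default per-gene coding lengths (bp, incl. start and stop codons);
# realistic for fungal mitogenomes
default_pcg_lengths <- c(
  cox1 = 1608, nad4 = 1482, cox3 = 810, atp8 = 159, nad4L = 267,
  nad5 = 1983, cox2 = 750, nad2 = 1737, nad3 = 420, nad1 = 1086,
  nad6 = 660, cob = 1161, atp6 = 780, rps3 = 1437, atp9 = 225)

# anticodons for the core tRNA set; second isotypes of L/R/S differ, the
# two trnM copies share one anticodon
trna_anticodons <- c(
  trnW = "tca", trnD = "gtc", trnR = "acg", trnC = "gca", trnN = "gtt",
  trnA = "tgc", trnF = "gaa", trnY = "gta", trnM = "cat", trnL = "tag",
  trnG = "tcc", trnE = "ttc", trnT = "tgt", trnI = "gat", trnK = "ttt",
  trnS = "tga", trnQ = "ttg", trnH = "gtg", trnV = "tac", trnP = "tgg")
trna_anticodons2 <- c(trnL = "taa", trnR = "tct", trnS = "gct",
                      trnM = "cat", trnT = "tgt", trnI = "tat",
                      trnD = "atc", trnF = "aaa")

#' The published Phallales gene-order template
#'
#' The conserved arrangement of 15 PCGs, 2 rRNAs and 24 core tRNAs in six
#' clusters, optionally with extra private tRNA copies inserted after
#' their first occurrence.
#' @param extra_duplications tRNA labels to add one extra copy of
#'   (e.g. "trnI").
#' @return data.frame with columns label, kind.
#' @export
phallales_gene_template <- function(extra_duplications = character(0)) {
  lab <- c("cox1", "nad4", "cox3", "atp8",
           "trnW", "trnD",
           "nad4L", "nad5",
           "trnR", "trnC", "trnN",
           "rnl", "cox2",
           "trnA", "trnF", "trnY", "trnM", "trnL", "trnG", "trnM", "trnE",
           "trnT", "trnI", "trnK",
           "nad2", "nad3",
           "trnS", "trnQ", "trnH",
           "nad1", "nad6", "cob", "rns",
           "trnV", "trnL", "trnR",
           "atp6",
           "trnS", "trnP",
           "rps3", "atp9")
  for (d in extra_duplications) {
    i <- which(lab == d)[1]
    if (is.na(i)) stop("unknown tRNA label in duplication plan: ", d)
    lab <- append(lab, d, after = i)
  }
  kind <- ifelse(grepl("^trn", lab), "tRNA",
                 ifelse(lab %in% c("rnl", "rns"), "rRNA", "PCG"))
  data.frame(label = lab, kind = kind, stringsAsFactors = FALSE)
}

#' Specification for one simulated mitogenome
#'
#' Lengths are exact integer budgets: the realized genome matches the plan
#' with no drift. When `region_budget` is supplied the per-gene length
#' tables are rescaled so that the four realized region totals equal it
#' exactly.
#'
#' @param species_name,record_id identifiers.
#' @param gc_fraction GC fraction of non-coding tracts (default 0.245).
#' @param pcg_lengths named coding lengths (bp, multiples of 3).
#' @param rrna_lengths named lengths for rnl and rns.
#' @param trna_length tRNA gene length (default 72 bp, the modal range).
#' @param intron_plan named list: gene -> integer vector of intron lengths.
#' @param intergenic_total total intergenic bp, split randomly over the
#'   gaps between consecutive features.
#' @param extra_duplications private tRNA copies (see
#'   [phallales_gene_template()]).
#' @param region_budget optional list(exonic, rna_coding, intronic,
#'   intergenic) of exact region totals in bp.
#' @param start_codon start codon used for every CDS.
#' @param gene_sequences optional named list of pre-made sequences
#'   (CDS/rRNA) planted verbatim; their lengths override the length
#'   tables.
#' @param rng_seed integer seed; generation is deterministic given the
#'   spec.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(species_name = "Phallales sp. sim",
                        record_id = "SIM000001",
                        gc_fraction = 0.245,
                        pcg_lengths = default_pcg_lengths,
                        rrna_lengths = c(rnl = 3300, rns = 1520),
                        trna_length = 72L,
                        intron_plan = list(
                          cox1 = c(1450, 1300, 1500, 1250),
                          cob = c(1400, 1350),
                          rnl = 1500),
                        intergenic_total = 15000L,
                        extra_duplications = character(0),
                        region_budget = NULL,
                        start_codon = "ATG",
                        gene_sequences = NULL,
                        rng_seed = 1L) {
  structure(list(species_name = species_name, record_id = record_id,
                 gc_fraction = gc_fraction, pcg_lengths = pcg_lengths,
                 rrna_lengths = rrna_lengths,
                 trna_length = as.integer(trna_length),
                 intron_plan = intron_plan,
                 intergenic_total = as.integer(intergenic_total),
                 extra_duplications = extra_duplications,
                 region_budget = region_budget,
                 start_codon = start_codon,
                 gene_sequences = gene_sequences,
                 rng_seed = as.integer(rng_seed)),
            class = "genome_spec")
}

# scale an integer vector to a new exact total, keeping proportions;
# optionally forcing multiples of `mult`
rescale_exact <- function(x, total, mult = 1L, min_value = mult) {
  v <- pmax(round(x / sum(x) * total / mult) * mult, min_value)
  resid <- total - sum(v)
  i <- which.max(v)
  v[i] <- v[i] + resid            # residual absorbed by the largest entry
  if (v[i] < min_value) stop("region budget too small: residual ", resid)
  stats::setNames(as.integer(v), names(x))
}

# random codon sampler: codon frequencies proportional to the product of
# AT-rich base frequencies, stop codons excluded
sample_cds <- function(len, freqs, code, start_codon) {
  stopifnot(len %% 3L == 0L, len >= 6L)
  p <- apply(expand.grid(b1 = names(freqs), b2 = names(freqs),
                         b3 = names(freqs), stringsAsFactors = FALSE),
             1L, function(r) freqs[[r[1]]] * freqs[[r[2]]] * freqs[[r[3]]])
  cods <- apply(expand.grid(b1 = names(freqs), b2 = names(freqs),
                            b3 = names(freqs), stringsAsFactors = FALSE),
                1L, paste, collapse = "")
  keep <- !(cods %in% code$stops)
  n_mid <- len / 3L - 2L
  mid <- sample(cods[keep], n_mid, replace = TRUE, prob = p[keep])
  paste0(start_codon, paste(mid, collapse = ""), "TAA")
}

sample_bases <- function(len, freqs) {
  if (len == 0L) return("")
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
        collapse = "")
}

#' Generate a Phallales-like annotated mitogenome
#'
#' Builds a circular record following the conserved gene-order template.
#' Coding sequences are valid table-4 ORFs (configured start codon, no
#' internal stop, terminal TAA); introns and intergenic tracts are random
#' tracts at the spec's base composition. All bookkeeping is exact: the
#' realized region partition equals the plan. Deterministic for a fixed
#' spec (including its seed).
#'
#' @param spec a [genome_spec()].
#' @return a validated `mitogenome`.
#' @export
generate_genome <- function(spec) {
  with_seed(spec$rng_seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  code <- genetic_code(4L)
  freqs <- phallales_base_freqs(spec$gc_fraction)
  tmpl <- phallales_gene_template(spec$extra_duplications)
  n_trna <- sum(tmpl$kind == "tRNA")

  pcg_len <- spec$pcg_lengths
  rrna_len <- spec$rrna_lengths
  intron_plan <- spec$intron_plan
  intergenic_total <- spec$intergenic_total
  trna_len <- spec$trna_length

  # planted sequences override the length tables
  planted <- spec$gene_sequences %||% list()
  for (g in names(planted)) {
    if (g %in% names(pcg_len)) pcg_len[[g]] <- nchar(planted[[g]])
    if (g %in% names(rrna_len)) rrna_len[[g]] <- nchar(planted[[g]])
  }

  if (!is.null(spec$region_budget)) {
    b <- spec$region_budget
    if (!is.null(b$exonic))
      pcg_len <- rescale_exact(pcg_len, b$exonic, mult = 3L, min_value = 9L)
    if (!is.null(b$rna_coding)) {
      rrna_budget <- b$rna_coding - n_trna * trna_len
      if (rrna_budget < 200L)
        stop("rna_coding budget too small: residual ", rrna_budget)
      rrna_len <- rescale_exact(rrna_len, rrna_budget, min_value = 100L)
    }
    if (!is.null(b$intronic)) {
      ilen <- unlist(intron_plan)
      if (b$intronic == 0L) intron_plan <- list()
      else {
        if (!length(ilen)) stop("intronic budget with an empty intron plan")
        ilen <- rescale_exact(ilen, b$intronic, min_value = 30L)
        at <- 0L
        intron_plan <- lapply(stats::setNames(nm = names(intron_plan)),
                              function(g) {
          k <- length(spec$intron_plan[[g]])
          out <- ilen[(at + 1L):(at + k)]
          at <<- at + k
          as.integer(out)
        })
      }
    }
    if (!is.null(b$intergenic)) intergenic_total <- as.integer(b$intergenic)
  }

  # intergenic gaps: one before each feature, random positive split
  n_gap <- nrow(tmpl)
  w <- stats::rgamma(n_gap, shape = 1.2)
  gaps <- floor(w / sum(w) * intergenic_total)
  resid <- intergenic_total - sum(gaps)
  if (resid > 0) {
    add <- sample(seq_len(n_gap), resid, replace = resid > n_gap)
    for (i in add) gaps[i] <- gaps[i] + 1L
  }

  seq_parts <- character(0)
  feats <- list()
  pos <- 0L
  copy_seen <- integer(0)
  intron_used <- stats::setNames(rep(0L, length(intron_plan)),
                                 names(intron_plan))
  for (i in seq_len(n_gap)) {
    g <- gaps[i]
    if (g > 0L) { seq_parts <- c(seq_parts, sample_bases(g, freqs)); pos <- pos + g }
    lab <- tmpl$label[i]; kind <- tmpl$kind[i]
    cnt <- copy_seen[lab]; if (is.na(cnt)) cnt <- 0L
    copy_seen[lab] <- cnt + 1L
    copy <- cnt + 1L

    if (kind == "tRNA") {
      body <- planted[[paste0(lab, ".", copy)]] %||%
        sample_bases(trna_len, freqs)
      ac <- if (copy > 1L) trna_anticodons2[[lab]] else
        trna_anticodons[[lab]] %||% NA_character_
      feats[[length(feats) + 1L]] <-
        mito_feature(lab, "tRNA", c(pos + 1L, pos + nchar(body)),
                     anticodon = ac, copy_index = copy)
      seq_parts <- c(seq_parts, body); pos <- pos + nchar(body)
      next
    }

    body <- if (kind == "PCG") {
      planted[[lab]] %||% sample_cds(pcg_len[[lab]], freqs, code,
                                     spec$start_codon)
    } else {
      planted[[lab]] %||% sample_bases(rrna_len[[lab]], freqs)
    }
    introns <- intron_plan[[lab]] %||% integer(0)
    if (length(introns)) {
      # split the body into length(introns)+1 exon chunks of >= 3 bp
      n_ex <- length(introns) + 1L
      blen <- nchar(body)
      cuts <- sort(sample(seq(3L, blen - 3L, by = 3L), n_ex - 1L))
      chunk_end <- c(cuts, blen)
      chunk_start <- c(1L, cuts + 1L)
      exons <- matrix(0L, n_ex, 2L,
                      dimnames = list(NULL, c("start", "end")))
      for (k in seq_len(n_ex)) {
        ex_seq <- substring(body, chunk_start[k], chunk_end[k])
        exons[k, ] <- c(pos + 1L, pos + nchar(ex_seq))
        seq_parts <- c(seq_parts, ex_seq); pos <- pos + nchar(ex_seq)
        if (k < n_ex) {
          il <- introns[k]
          seq_parts <- c(seq_parts, sample_bases(il, freqs))
          pos <- pos + il
        }
      }
      feats[[length(feats) + 1L]] <-
        mito_feature(lab, kind, exons, copy_index = copy)
    } else {
      feats[[length(feats) + 1L]] <-
        mito_feature(lab, kind, c(pos + 1L, pos + nchar(body)),
                     copy_index = copy)
      seq_parts <- c(seq_parts, body); pos <- pos + nchar(body)
    }
  }
  rec <- mitogenome(spec$record_id, spec$species_name,
                    paste(seq_parts, collapse = ""), feats,
                    topology = "circular", validate = FALSE)
  suppressWarnings(validate_mitogenome(rec))
  rec
}

#' Specification for sequence evolution
#'
#' @param mode "K2P_site" (per-site K2P substitution process with expected
#'   divergence `d`) or "codon_NG" (proposal process where synonymous
#'   changes are accepted at rate 1, nonsynonymous at rate `omega`, and
#'   stop-creating changes rejected; `d` is the expected number of
#'   proposed mutations per nucleotide site).
#' @param d branch length (see mode).
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous acceptance ratio (codon mode).
#' @param rng_seed integer seed.
#' @return object of class `evolve_spec`.
#' @export
evolve_spec <- function(mode = c("K2P_site", "codon_NG"), d = 0.1,
                        kappa = 2, omega = 0.2, rng_seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, d = d, kappa = kappa, omega = omega,
                 rng_seed = as.integer(rng_seed)),
            class = "evolve_spec")
}

NT <- c("A", "C", "G", "T")
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

# K2P transition probabilities after divergence d with ts/tv ratio kappa:
# beta*t = d/(kappa+2), alpha*t = kappa*beta*t
k2p_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt)          # each of the two targets
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

#' Evolve a sequence under a seeded substitution model
#'
#' @param seq nucleotide string (a valid CDS in codon mode).
#' @param spec an [evolve_spec()].
#' @return mutated sequence of the same length.
#' @export
evolve <- function(seq, spec) {
  with_seed(spec$rng_seed, evolve_impl(seq, spec))
}

evolve_impl <- function(seq, spec) {
  ch <- split_chars(toupper(seq))
  if (spec$mode == "K2P_site") {
    pr <- k2p_probs(spec$d, spec$kappa)
    u <- stats::runif(length(ch))
    is_acgt <- ch %in% NT
    ts <- is_acgt & u < pr[["ts"]]
    tv1 <- is_acgt & u >= pr[["ts"]] & u < pr[["ts"]] + pr[["tv"]]
    tv2 <- is_acgt & u >= pr[["ts"]] + pr[["tv"]] &
      u < pr[["ts"]] + 2 * pr[["tv"]]
    out <- ch
    out[ts] <- TRANSITION_OF[ch[ts]]
    # the two transversion targets of each base, in fixed order
    tv_first <- c(A = "C", G = "C", C = "A", T = "A")
    tv_second <- c(A = "T", G = "T", C = "G", T = "G")
    out[tv1] <- tv_first[ch[tv1]]
    out[tv2] <- tv_second[ch[tv2]]
    return(paste(out, collapse = ""))
  }
  # codon_NG mode
  code <- genetic_code(4L)
  L <- length(ch)
  if (L %% 3L != 0L) stop("codon mode needs a CDS (length divisible by 3)")
  cods <- split_codons(paste(ch, collapse = ""))
  if (any(cods[-length(cods)] %in% code$stops))
    stop("codon mode input has an internal stop codon")
  n_events <- stats::rpois(1L, spec$d * L)
  if (n_events > 0L) {
    sites <- sample.int(L, n_events, replace = TRUE)
    u_kind <- stats::runif(n_events)
    u_acc <- stats::runif(n_events)
    u_tv <- stats::runif(n_events)
    p_ts <- spec$kappa / (spec$kappa + 2)
    for (e in seq_len(n_events)) {
      i <- sites[e]
      base <- ch[i]
      if (!base %in% NT) next
      newb <- if (u_kind[e] < p_ts) TRANSITION_OF[[base]] else {
        tvs <- setdiff(NT, c(base, TRANSITION_OF[[base]]))
        if (u_tv[e] < 0.5) tvs[1] else tvs[2]
      }
      ci <- (i - 1L) %/% 3L + 1L
      off <- (i - 1L) %% 3L + 1L
      old_cod <- cods[ci]
      if (old_cod %in% code$stops) next            # keep the terminal stop
      new_cod <- old_cod
      substr(new_cod, off, off) <- newb
      if (new_cod %in% code$stops) next            # reject stop-creating
      syn <- code$codons[[new_cod]] == code$codons[[old_cod]]
      if (!syn && u_acc[e] >= spec$omega) next     # purifying rejection
      cods[ci] <- new_cod
      ch[i] <- newb
    }
  }
  paste(ch, collapse = "")
}

#' Evolve a sequence down a tree
#'
#' Recursively applies [evolve()] along every edge of a rooted `phylo`
#' tree; edge lengths are branch lengths in the units of the chosen mode.
#'
#' @param seq ancestral sequence.
#' @param tree a rooted `phylo` with edge lengths.
#' @param spec an [evolve_spec()] (its `d` is ignored; per-edge lengths
#'   are used).
#' @return named character vector of tip sequences.
#' @export
evolve_on_tree <- function(seq, tree, spec) {
  with_seed(spec$rng_seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- character(n_tip + tree$Nnode)
    seqs[root] <- seq
    # visit edges in breadth-first order so parents are filled first
    edge_order <- integer(0); queue <- root
    while (length(queue)) {
      node <- queue[1]; queue <- queue[-1]
      kids <- which(tree$edge[, 1] == node)
      edge_order <- c(edge_order, kids)
      queue <- c(queue, tree$edge[kids, 2])
    }
    for (k in edge_order) {
      par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      sp <- spec; sp$d <- tree$edge.length[k]
      seqs[child] <- evolve_impl(seqs[par], sp)
    }
    stats::setNames(seqs[seq_len(n_tip)], tree$tip.label)
  })
}

#' Generate the seven-taxon Phallales-like comparison panel
#'
#' Seven annotated genomes sharing the published gene order, with the four
#' shared tRNA doublings (trnM/L/R/S) in every taxon and one private extra
#' tRNA copy (trnI, trnT, trnD, trnF) in four of them; plus per-gene
#' alignments obtained by evolving one ancestral gene set on a fixed
#' 7-taxon tree whose earliest-branching tip is the Lysurus analogue. The
#' evolved coding and rRNA sequences are planted into the corresponding
#' genomes, so genomes and alignments are mutually consistent. Fully
#' deterministic for a fixed seed.
#'
#' @param rng_seed integer seed.
#' @return object of class `phallales_panel`: list with `genomes` (named
#'   list of `mitogenome`), `alignments` (gene -> named character vector,
#'   codon-aware for the 15 PCGs) and `tree` (the generating `phylo`).
#' @export
make_phallales_panel <- function(rng_seed = 1L) {
  taxa <- c("Lysurus_mokusin_sim", "Phallus_indusiatus_sim",
            "Phallus_hadriani_sim", "Phallus_rigidiindusiatus_sim",
            "Phallus_rugulosus_sim", "Phallus_dongsun_sim",
            "Phallus_echinovolvatus_sim")
  newick <- paste0(
    "(Lysurus_mokusin_sim:0.10,(Phallus_rugulosus_sim:0.06,",
    "(Phallus_indusiatus_sim:0.045,((Phallus_dongsun_sim:0.02,",
    "Phallus_hadriani_sim:0.02):0.015,(Phallus_rigidiindusiatus_sim:0.02,",
    "Phallus_echinovolvatus_sim:0.02):0.015):0.01):0.01):0.04);")
  tree <- ape::read.tree(text = newick)

  extra_dups <- list(Lysurus_mokusin_sim = character(0),
                     Phallus_indusiatus_sim = character(0),
                     Phallus_hadriani_sim = "trnT",
                     Phallus_rigidiindusiatus_sim = "trnD",
                     Phallus_rugulosus_sim = "trnI",
                     Phallus_dongsun_sim = "trnF",
                     Phallus_echinovolvatus_sim = character(0))
  intron_plans <- list(
    Lysurus_mokusin_sim = list(            # 24 PCG introns, cox1 max 9
      cox1 = rep(1650L, 9), cob = rep(1600L, 5), nad5 = rep(1550L, 3),
      nad1 = rep(1500L, 2), cox2 = rep(1450L, 2), nad4 = 1500L,
      cox3 = 1450L, nad2 = 1400L),
    Phallus_indusiatus_sim = list(         # 23 PCG + 6 rnl + 1 rns = 30
      cox1 = rep(1850L, 8), cob = rep(1800L, 6), nad5 = rep(1750L, 3),
      nad1 = rep(1700L, 2), cox2 = rep(1650L, 2), nad4 = 1600L,
      cox3 = 1550L, rnl = rep(1500L, 6), rns = 1400L),
    Phallus_hadriani_sim = list(           # 14
      cox1 = rep(2600L, 6), cob = rep(2550L, 4), nad5 = rep(2500L, 2),
      nad1 = 2450L, cox2 = 2400L),
    Phallus_rigidiindusiatus_sim = list(   # 5
      cox1 = rep(1250L, 3), cob = rep(1240L, 2)),
    Phallus_rugulosus_sim = list(          # 16
      cox1 = rep(1520L, 6), cob = rep(1500L, 5), nad5 = rep(1480L, 2),
      nad1 = 1470L, cox2 = 1460L, nad4 = 1450L),
    Phallus_dongsun_sim = list(            # 11
      cox1 = rep(1500L, 5), cob = rep(1450L, 3), nad5 = rep(1400L, 2),
      nad1 = 1350L),
    Phallus_echinovolvatus_sim = list(     # 8
      cox1 = rep(1200L, 4), cob = rep(1150L, 2), nad5 = rep(1100L, 2)))
  intergenic <- c(Lysurus_mokusin_sim = 38100L,
                  Phallus_indusiatus_sim = 14400L,
                  Phallus_hadriani_sim = 37900L,
                  Phallus_rigidiindusiatus_sim = 12800L,
                  Phallus_rugulosus_sim = 15600L,
                  Phallus_dongsun_sim = 15000L,
                  Phallus_echinovolvatus_sim = 12500L)

  with_seed(rng_seed, {
    code <- genetic_code(4L)
    freqs <- phallales_base_freqs()
    ancestor_cds <- lapply(default_pcg_lengths, function(l)
      sample_cds(l, freqs, code, "ATG"))
    ancestor_rrna <- list(rnl = sample_bases(3300L, freqs),
                          rns = sample_bases(1520L, freqs))
    # per-gene selective constraint: atp9 strongly purifying, rps3 weak
    omegas <- c(cox1 = 0.12, nad4 = 0.15, cox3 = 0.08, atp8 = 0.15,
                nad4L = 0.08, nad5 = 0.15, cox2 = 0.12, nad2 = 0.2,
                nad3 = 0.15, nad1 = 0.12, nad6 = 0.2, cob = 0.1,
                atp6 = 0.15, rps3 = 0.55, atp9 = 0.02)
    alignments <- list()
    for (g in names(ancestor_cds)) {
      sp <- evolve_spec("codon_NG", kappa = 2, omega = omegas[[g]],
                        rng_seed = stats::runif(1) * 1e6)
      alignments[[g]] <- evolve_on_tree(ancestor_cds[[g]], tree, sp)
    }
    for (g in names(ancestor_rrna)) {
      sp <- evolve_spec("K2P_site", kappa = 2,
                        rng_seed = stats::runif(1) * 1e6)
      alignments[[g]] <- evolve_on_tree(ancestor_rrna[[g]], tree, sp)
    }
    genomes <- list()
    for (t in taxa) {
      planted <- lapply(alignments, `[[`, t)
      gspec <- genome_spec(
        species_name = t,
        record_id = paste0("SIM_", substr(t, 1, 12)),
        intron_plan = intron_plans[[t]],
        intergenic_total = intergenic[[t]],
        extra_duplications = extra_dups[[t]],
        gene_sequences = planted,
        rng_seed = floor(stats::runif(1) * 1e6))
      genomes[[t]] <- generate_genome(gspec)
    }
    structure(list(genomes = genomes, alignments = alignments, tree = tree),
              class = "phallales_panel")
  })
}
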