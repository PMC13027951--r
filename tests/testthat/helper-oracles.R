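# Independent oracles and shared fixtures. Oracles are written in a
# deliberately different style from the package code paths they check.

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n, with_ambiguous = FALSE) {
  pool <- c("A", "C", "G", "T", if (with_ambiguous) c("N", "-"))
  paste(sample(pool, n, replace = TRUE,
               prob = c(rep(1, 4), if (with_ambiguous) c(0.05, 0.05))),
        collapse = "")
}

# --- K2P oracle: explicit site-pair classification + direct closed form ----
oracle_k2p <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  keep <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  va <- va[keep]; vb <- vb[keep]
  pair <- paste0(va, vb)
  ts <- c("AG", "GA", "CT", "TC")
  P <- sum(pair %in% ts) / length(pair)
  Q <- sum(va != vb) / length(pair) - P
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(list(d = NA_real_, defined = FALSE))
  list(d = -0.5 * log(arg1 * sqrt(arg2)), defined = TRUE)
}

# --- NG86 oracle: literal enumeration over permutations --------------------
oracle_code <- Biostrings::getGeneticCode("4")
oracle_stops <- names(oracle_code)[oracle_code == "*"]

oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracle_code[[alt]] == "*") next
      if (oracle_code[[alt]] == oracle_code[[codon]]) s <- s + 1
    }
  }
  s / 3
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# returns c(sd, nd, n_paths_used, n_paths_total)
oracle_pathways <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0, used = 0, total = 0))
  perms <- all_perms(pos)
  sd_tot <- nd_tot <- 0; used <- 0
  for (p in perms) {
    cur <- ca; sd <- nd <- 0; ok <- TRUE
    for (site in p) {
      nxt <- cur
      substr(nxt, site, site) <- substr(cb, site, site)
      if (oracle_code[[nxt]] == "*" && nxt != cb) { ok <- FALSE; break }
      if (oracle_code[[cur]] == oracle_code[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; used <- used + 1 }
  }
  if (used == 0) {          # fallback convention: use all pathways
    for (p in perms) {
      cur <- ca; sd <- nd <- 0
      for (site in p) {
        nxt <- cur
        substr(nxt, site, site) <- substr(cb, site, site)
        if (oracle_code[[cur]] == oracle_code[[nxt]]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; used <- used + 1
    }
  }
  c(sd = sd_tot / used, nd = nd_tot / used, used = used,
    total = length(perms))
}

random_cds <- function(n_codons) {
  pool <- setdiff(names(oracle_code), oracle_stops)
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# --- shared fixtures -------------------------------------------------------
# one toy annotated record used across files: 1000 bp, one intronless
# 300 bp PCG, one 70 bp tRNA
toy_record <- function() {
  set.seed(99)
  seqs <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  pcg <- mitocomp::mito_feature("cox1", "PCG", c(101L, 400L))
  trna <- mitocomp::mito_feature("trnM", "tRNA", c(501L, 570L),
                                 anticodon = "cat")
  mitocomp::mitogenome("TOY1", "Toy species", seqs, list(pcg, trna))
}

# the panel is expensive enough to share across test files
.fixture_env <- new.env()
get_panel <- function(seed = 1) {
  key <- paste0("panel_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- suppressWarnings(
      mitocomp::make_phallales_panel(seed))
  .fixture_env[[key]]
}

small_spec <- function(seed = 1, ...) {
  mitocomp::genome_spec(
    pcg_lengths = c(cox1 = 300, nad4 = 300, cox3 = 150, atp8 = 90,
                    nad4L = 90, nad5 = 300, cox2 = 150, nad2 = 300,
                    nad3 = 120, nad1 = 240, nad6 = 120, cob = 240,
                    atp6 = 150, rps3 = 240, atp9 = 90),
    rrna_lengths = c(rnl = 600, rns = 300),
    intron_plan = list(cox1 = c(150, 120), cob = 100),
    intergenic_total = 2000L,
    rng_seed = seed, ...)
}
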