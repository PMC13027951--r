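# Circular gene-order normalization, comparison and duplications.

make_order <- function(labels, strands = NULL, taxon = "t") {
  strands <- strands %||% rep("+", length(labels))
  df <- data.frame(label = labels, strand = strands,
                   stringsAsFactors = FALSE)
  df$copy <- stats::ave(seq_len(nrow(df)), df$label, FUN = seq_along)
  structure(list(taxon = taxon, order = df, anchor = labels[1]),
            class = "gene_order")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# independent adjacency oracle: literal set of normalized neighbor strings
oracle_adjacencies <- function(ord) {
  d <- ord$order
  key <- paste0(d$label, ".", d$copy)
  sgn <- d$strand
  n <- nrow(d)
  out <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x <- paste0(sgn[i], key[i], ">", sgn[j], key[j])
    fl <- function(s) if (s == "-") "+" else "-"
    y <- paste0(fl(sgn[j]), key[j], ">", fl(sgn[i]), key[i])
    out[i] <- min(x, y)
  }
  out
}

test_that("the simulated backbone order equals the conserved 17-gene arrangement", {
  p <- get_panel()
  for (g in p$genomes) {
    o <- extract_order(g, include_trna = FALSE)
    expect_equal(o$order$label, CORE_ORDER)
    expect_true(all(o$order$strand == "+"))
  }
})

test_that("normalized orders are invariant to rotation and reversal", {
  p <- get_panel()
  rec <- p$genomes[[1]]
  base <- extract_order(rec)
  set.seed(5)
  for (off in sample(nchar(rec$sequence), 5)) {
    o <- extract_order(rotate_record(rec, off))
    expect_equal(o$order, base$order)
  }
  orc <- extract_order(revcomp_record(rec))
  expect_equal(orc$order, base$order)
  # idempotence of normalization on an already-normalized order
  renorm <- mitocomp:::normalize_order_df(base$order[, c("label", "strand")],
                                          base$anchor)
  expect_equal(renorm$df, base$order)
})

test_that("a missing anchor falls back to the smallest PCG with a warning", {
  seqs <- strrep("ACGT", 300)
  feats <- list(mito_feature("nad2", "PCG", c(1L, 300L)),
                mito_feature("cob", "PCG", c(401L, 700L)),
                mito_feature("rnl", "rRNA", c(801L, 1100L)))
  rec <- mitogenome("X", "sp", seqs, feats)
  expect_warning(o <- extract_order(rec), "anchor 'cox1' absent")
  expect_equal(o$order$label[1], "cob")
})

test_that("duplicate-tolerant comparison skips surplus copies only", {
  a <- make_order(c("cox1", "trnI", "nad4", "trnI", "cob"))
  b <- make_order(c("cox1", "trnI", "nad4", "cob"))
  expect_false(orders_identical(a, b)$identical)
  r <- orders_identical(a, b, ignore_duplicates = TRUE)
  expect_true(r$identical)
  c2 <- make_order(c("cox1", "nad4", "trnI", "cob"))
  r2 <- orders_identical(b, c2)
  expect_false(r2$identical)
  expect_equal(r2$divergence_at, 2L)
  expect_true(orders_identical(b, b)$identical)
})

test_that("breakpoint distance equals the adjacency set-difference oracle", {
  a <- make_order(c("cox1", "nad4", "cox3", "atp8", "cob"))
  expect_equal(breakpoint_distance(a, a), 0L)
  # one adjacent transposition
  b <- make_order(c("cox1", "cox3", "nad4", "atp8", "cob"))
  expect_equal(breakpoint_distance(a, b),
               length(setdiff(oracle_adjacencies(a), oracle_adjacencies(b))))
  set.seed(11)
  labs <- c("cox1", paste0("g", 1:7))
  for (i in 1:20) {
    x <- make_order(c("cox1", sample(labs[-1])))
    y <- make_order(c("cox1", sample(labs[-1])))
    z <- make_order(c("cox1", sample(labs[-1])))
    expect_equal(breakpoint_distance(x, y),
                 length(setdiff(oracle_adjacencies(x),
                                oracle_adjacencies(y))))
    expect_equal(breakpoint_distance(x, y), breakpoint_distance(y, x))
    expect_lte(breakpoint_distance(x, z),
               breakpoint_distance(x, y) + breakpoint_distance(y, z))
  }
  expect_error(breakpoint_distance(a, make_order(c("cox1", "nad4"))),
               "different label multisets")
})

test_that("duplication events split into shared and private sets", {
  p <- get_panel()
  d <- duplication_events(p$genomes)
  expect_setequal(d$shared, c("trnM", "trnL", "trnR", "trnS"))
  priv <- d$private[lengths(d$private) > 0]
  expect_length(priv, 4L)
  expect_equal(sort(unname(unlist(priv))),
               c("trnD", "trnF", "trnI", "trnT"))
  # anticodon identity: the two trnM copies share, trnL/R/S copies differ
  ac <- d$anticodons[d$anticodons$taxon == names(p$genomes)[1], ]
  expect_true(ac$identical[ac$label == "trnM"])
  expect_false(any(ac$identical[ac$label %in% c("trnL", "trnR", "trnS")]))
  # no duplicates anywhere -> empty report
  rec <- mitogenome("X", "sp", strrep("ACGT", 300),
                    list(mito_feature("cox1", "PCG", c(1L, 300L)),
                         mito_feature("cob", "PCG", c(401L, 700L))))
  d0 <- duplication_events(list(rec))
  expect_length(d0$shared, 0L)
  expect_length(unlist(d0$per_taxon), 0L)
  # random duplicate injection equals direct counting
  labs <- vapply(p$genomes[[3]]$features, `[[`, character(1), "gene_label")
  expect_setequal(d$per_taxon[[3]], unique(labs[duplicated(labs)]))
})

test_that("tRNA clusters derived from context match the published assignment", {
  p <- get_panel()
  # a taxon without private duplications carries exactly the six clusters
  o <- extract_order(p$genomes$Lysurus_mokusin_sim)
  cl <- trna_clusters(o)
  ref <- phallales_reference("clusters")
  expect_equal(nrow(cl), 6L)
  expect_equal(cl$upstream_gene, ref$upstream_gene)
  expect_equal(cl$downstream_gene, ref$downstream_gene)
  expect_equal(cl$trnas, ref$trnas)
})
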