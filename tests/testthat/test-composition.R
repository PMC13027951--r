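# Composition statistics, region partition, strain arithmetic.

test_that("GC content matches direct character counting", {
  expect_equal(base_composition("ATGC")$gc_percent, 50.0)
  expect_equal(base_composition("AATT")$gc_percent, 0.0)
  expect_error(base_composition(""), "empty")
  set.seed(21)
  s <- random_dna(10000)
  v <- strsplit(s, "")[[1]]
  expect_equal(base_composition(s)$gc_percent,
               round(100 * sum(v %in% c("G", "C")) / length(v), 1))
  # N excluded from the denominator
  expect_equal(base_composition("GGNN")$gc_percent, 100.0)
})

test_that("skews follow their defining formulas with explicit undefined markers", {
  expect_equal(skew("AATT")$at_skew, 0)
  expect_equal(skew("GGCC")$gc_skew, 0)
  s <- skew("AAAA")
  expect_equal(s$at_skew, 1.0)
  expect_true(is.na(s$gc_skew))
})

test_that("reverse complement negates both skews", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_dna(sample(100:2000, 1))
    a <- skew(s); b <- skew(revcomp(s))
    expect_equal(b$at_skew, -a$at_skew)
    expect_equal(b$gc_skew, -a$gc_skew)
  }
})

test_that("region partition applies the fixed class precedence", {
  rec <- toy_record()
  p <- partition_regions(rec)
  expect_equal(unname(p$lengths),
               c(300L, 70L, 0L, 630L))
  # a two-exon gene contributes its exact gap as intronic
  f <- mito_feature("nad5", "PCG", rbind(c(1L, 100L), c(201L, 300L)))
  rec2 <- mitogenome("Y", "sp", strrep("ACGT", 250), list(f))
  p2 <- partition_regions(rec2)
  expect_equal(p2$lengths[["INTRONIC"]], 100L)
  expect_equal(p2$lengths[["PCG_EXON"]], 200L)
})

test_that("partition agrees with naive per-base labeling on a simulated genome", {
  rec <- suppressWarnings(generate_genome(small_spec(17)))
  L <- nchar(rec$sequence)
  # naive oracle: per-base best class by explicit scan with precedence
  lab <- rep("INTERGENIC", L)
  prec <- c(PCG_EXON = 1, RNA_CODING = 2, INTRONIC = 3, INTERGENIC = 4)
  set_best <- function(pos, cl)
    lab[pos] <<- ifelse(prec[cl] < prec[lab[pos]], cl, lab[pos])
  for (f in rec$features) {
    cl <- if (f$kind == "PCG") "PCG_EXON" else "RNA_CODING"
    for (k in seq_len(nrow(f$exons)))
      set_best(f$exons[k, 1]:f$exons[k, 2], cl)
    if (nrow(f$exons) > 1L)
      for (k in seq_len(nrow(f$exons) - 1L)) {
        gap <- (f$exons[k, 2] + 1L):(f$exons[k + 1L, 1] - 1L)
        if (f$exons[k + 1L, 1] - f$exons[k, 2] > 1L)
          set_best(gap, "INTRONIC")
      }
  }
  p <- partition_regions(rec)
  expect_equal(as.character(p$classes), lab)
  expect_equal(sum(p$lengths), L)
})

test_that("genome summary satisfies the partition sum and intron invariants", {
  rec <- suppressWarnings(generate_genome(small_spec(23)))
  s <- suppressWarnings(summarize_genome(rec))
  expect_equal(s$exonic_bp + s$rna_coding_bp + s$intronic_bp +
                 s$intergenic_bp, s$total_size_bp)
  expect_equal(s$n_pcg, 15L)
  expect_equal(s$n_rrna, 2L)
  # introns: 2 in cox1 + 1 in cob from the plan
  expect_equal(s$n_introns, 3L)
  # intronless plan gives zero introns
  sp0 <- small_spec(24)
  sp0$intron_plan <- list()
  s0 <- suppressWarnings(summarize_genome(generate_genome(sp0)))
  expect_equal(s0$n_introns, 0L)
  expect_equal(s0$intronic_bp, 0L)
})

test_that("rotating the origin changes nothing in the summary", {
  rec <- suppressWarnings(generate_genome(small_spec(29)))
  s1 <- suppressWarnings(summarize_genome(rec))
  set.seed(3)
  for (off in sample(nchar(rec$sequence), 3)) {
    s2 <- suppressWarnings(summarize_genome(rotate_record(rec, off)))
    s2$record_id <- s1$record_id
    expect_equal(unclass(s2), unclass(s1))
  }
})

test_that("proportions round half-up to the printed integer percentages", {
  mk <- function(tot, ex, rna, intr, igs)
    list(total_size_bp = tot, exonic_bp = ex, rna_coding_bp = rna,
         intronic_bp = intr, intergenic_bp = igs)
  expect_equal(proportion_table(mk(83590, 0, 0, 46803, 0))[["intronic"]], 56)
  expect_equal(proportion_table(mk(93486, 0, 0, 0, 37942))[["intergenic"]], 41)
  expect_equal(unname(proportion_table(mk(100, 25, 25, 25, 25))),
               c(25, 25, 25, 25))
})

test_that("strain comparison reproduces the published differences and ratios", {
  expect_equal(compare_strains(101135, 99150)$difference_bp, 1985)
  expect_equal(compare_strains(93486, 41465)$size_ratio, 2.25)
  same <- compare_strains(50000, 50000)
  expect_equal(same$difference_bp, 0)
  expect_equal(same$size_ratio, 1.00)
})

test_that("intron census equals the per-feature gap structure", {
  p <- get_panel()
  ic <- intron_census(p$genomes)
  # structural oracle: exon_count - 1 per gene when all gaps are real
  for (t in names(p$genomes)) {
    rec <- p$genomes[[t]]
    for (f in rec$features) {
      if (f$kind == "tRNA") next
      expect_equal(ic$counts[f$gene_label, rec$species_name],
                   nrow(f$exons) - 1L)
    }
  }
  expect_equal(ic$totals$combined, unname(colSums(ic$counts)))
  expect_true(all(c("atp6", "atp8", "atp9", "nad3", "nad4L", "nad6",
                    "rps3") %in% ic$intronless))
  # an all-intronless set gives an all-zero matrix
  sp <- small_spec(41); sp$intron_plan <- list()
  rec0 <- suppressWarnings(generate_genome(sp))
  expect_true(all(intron_census(list(rec0))$counts == 0L))
})

test_that("published region percentages are reproduced from the reference table", {
  s <- phallales_reference_summaries()
  pct <- sapply(s, proportion_table)
  expect_equal(pct["intronic", "Lysurus mokusin"], 40)
  expect_equal(pct["intronic", "Phallus indusiatus"], 56)
  expect_equal(pct["intronic", "Phallus rugulosus"], 39)
  expect_equal(pct["intergenic", "Phallus hadriani"], 41)
  expect_equal(pct["intronic", "Phallus hadriani"], 38)
  expect_equal(pct["intronic", "Phallus rigidiindusiatus"], 15)
  expect_equal(pct["protein_coding", "Phallus rigidiindusiatus"], 38)
})
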