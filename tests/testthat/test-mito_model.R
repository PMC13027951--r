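# Data model, GenBank I/O and gene extraction.

minimal_gb <- function(loc = "1..30", key = "CDS", topo = "circular") {
  seqs <- paste(rep("acgtacgtac", 10), collapse = "")
  lines <- c(
    sprintf("LOCUS       MINI0001 100 bp    DNA     %s UNA 01-JAN-2026", topo),
    "DEFINITION  Minimal record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "                     /organism=\"Minimal organism\"",
    sprintf("     %-16s%s", key, loc),
    "                     /gene=\"cox1\"",
    "ORIGIN",
    sprintf("%9d %s", 1, paste(substring(seqs, seq(1, 51, 10),
                                         seq(10, 60, 10)), collapse = " ")),
    sprintf("%9d %s", 61, paste(substring(seqs, seq(61, 91, 10),
                                          seq(70, 100, 10)), collapse = " ")),
    "//")
  f <- tempfile(fileext = ".gb")
  writeLines(lines, f)
  f
}

test_that("a single-feature GenBank file parses to one PCG of the right length", {
  rec <- read_genbank(minimal_gb())
  expect_s3_class(rec, "mitogenome")
  expect_equal(nchar(rec$sequence), 100L)
  expect_equal(rec$topology, "circular")
  expect_equal(rec$species_name, "Minimal organism")
  expect_length(rec$features, 1L)
  f <- rec$features[[1]]
  expect_equal(f$gene_label, "cox1")
  expect_equal(f$kind, "PCG")
  expect_equal(mitocomp:::feature_length(f), 30L)
})

test_that("an origin-spanning join becomes one two-exon feature with no intron", {
  rec <- read_genbank(minimal_gb(loc = "join(90..100,1..20)"))
  f <- rec$features[[1]]
  expect_equal(nrow(f$exons), 2L)
  expect_equal(mitocomp:::feature_length(f), 31L)
  expect_equal(n_introns(f, 100L), 0L)
  expect_equal(nchar(extract_gene_sequence(rec, "cox1")), 31L)
})

test_that("coordinates beyond the sequence are a validation error", {
  expect_error(read_genbank(minimal_gb(loc = "50..150")),
               "beyond sequence length")
})

test_that("gene labels are normalized across annotation vocabularies", {
  n <- normalize_gene_label(c("COX1", "cytochrome c oxidase subunit 1",
                              "ND4L", "tRNA-Met", "trnM(cat)", "orf1234"))
  expect_equal(n$label[1:5], c("cox1", "cox1", "nad4L", "trnM", "trnM"))
  expect_true(all(n$known[1:5]))
  expect_false(n$known[6])
  expect_equal(n$label[6], "orf1234")
})

test_that("extraction is verbatim on +, reverse-complemented on -, spliced over introns", {
  seqs <- paste(rep("ACGTTGCAGG", 20), collapse = "")   # 200 bp
  plus <- mito_feature("cox1", "PCG", c(1L, 30L))
  minus <- mito_feature("cob", "PCG", c(41L, 70L), strand = "-")
  spliced <- mito_feature("nad1", "PCG",
                          rbind(c(81L, 110L), c(161L, 190L)))
  rec <- mitogenome("X", "sp", seqs, list(plus, minus, spliced))
  expect_equal(extract_gene_sequence(rec, "cox1"), substring(seqs, 1, 30))
  expect_equal(extract_gene_sequence(rec, "cob"),
               revcomp(substring(seqs, 41, 70)))
  # hand-spliced: concatenation of the two exons, 50 bp intron removed
  expect_equal(extract_gene_sequence(rec, "nad1"),
               paste0(substring(seqs, 81, 110), substring(seqs, 161, 190)))
  expect_equal(nchar(extract_gene_sequence(rec, "nad1")),
               mitocomp:::feature_length(spliced))
  expect_equal(n_introns(spliced, 200L), 1L)
})

test_that("reverse-complementing a record leaves every extracted gene unchanged", {
  rec <- suppressWarnings(generate_genome(small_spec(11)))
  rc <- revcomp_record(rec)
  for (f in rec$features) {
    expect_equal(extract_gene_sequence(rc, f$gene_label, f$copy_index),
                 extract_gene_sequence(rec, f$gene_label, f$copy_index))
  }
})

test_that("records round-trip losslessly through GenBank files", {
  for (seed in 1:10) {
    rec <- suppressWarnings(generate_genome(small_spec(seed)))
    f <- tempfile(fileext = ".gb")
    write_genbank(rec, f)
    rec2 <- suppressWarnings(read_genbank(f))
    expect_identical(rec$sequence, rec2$sequence)
    expect_identical(rec$record_id, rec2$record_id)
    expect_identical(rec$topology, rec2$topology)
    expect_identical(rec$species_name, rec2$species_name)
    expect_equal(rec$features, rec2$features)
    unlink(f)
  }
})

test_that("a written record is read identically by an independent parser", {
  rec <- suppressWarnings(generate_genome(small_spec(5)))
  f <- tempfile(fileext = ".gb")
  write_genbank(rec, f)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from Bio import SeqIO",
    "r = SeqIO.read(sys.argv[1], 'genbank')",
    "feats = [f for f in r.features if f.type in ('CDS','tRNA','rRNA')]",
    "print(len(r.seq), len(feats))",
    "for f in sorted(feats, key=lambda f: int(f.location.start)):",
    "    print(int(f.location.start)+1, int(f.location.end), f.location.strand)"
  ), py)
  out <- system2("python", c(py, f), stdout = TRUE, stderr = FALSE)
  head <- as.integer(strsplit(out[1], " ")[[1]])
  expect_equal(head[1], nchar(rec$sequence))
  expect_equal(head[2], length(rec$features))
  got <- do.call(rbind, lapply(strsplit(out[-1], " "), as.integer))
  want <- do.call(rbind, lapply(rec$features, function(fe)
    c(min(fe$exons[, "start"]), max(fe$exons[, "end"]),
      if (fe$strand == "+") 1L else -1L)))
  want <- want[order(want[, 1]), ]
  expect_equal(got, want)
  unlink(c(f, py))
})

test_that("validation enforces unique copies and warns on odd tRNA lengths", {
  seqs <- strrep("ACGT", 50)
  f1 <- mito_feature("trnM", "tRNA", c(1L, 72L), anticodon = "cat")
  f2 <- mito_feature("trnM", "tRNA", c(101L, 172L), anticodon = "cat")
  expect_error(mitogenome("X", "sp", seqs, list(f1, f2)),
               "duplicate \\(gene_label, copy_index\\)")
  f2$copy_index <- 2L
  expect_silent(mitogenome("X", "sp", seqs, list(f1, f2)))
  short <- mito_feature("trnG", "tRNA", c(1L, 40L))
  expect_warning(mitogenome("X", "sp", seqs, list(short)),
                 "outside the validated 61-88")
})

test_that("rotation preserves content and splits exons at the new origin", {
  rec <- suppressWarnings(generate_genome(small_spec(3)))
  rot <- rotate_record(rec, 1234L)
  expect_equal(nchar(rot$sequence), nchar(rec$sequence))
  for (f in rec$features)
    expect_equal(extract_gene_sequence(rot, f$gene_label, f$copy_index),
                 extract_gene_sequence(rec, f$gene_label, f$copy_index))
})
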