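# Readers/writers and the coordinate conventions every stage relies on.

test_that("read_fasta parses records, uppercases, and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgt"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1)
  expect_equal(recs$x$residues, "ACGT")
  expect_equal(recs$x$length, 4L)

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">a", "ACGT", ">b", "AC1T"), f)
  expect_error(read_fasta(f), "line 4")

  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA write/read round-trips, including wrapping", {
  seqs <- list(haplotype_sequence("s1", random_dna_str(157)),
               haplotype_sequence("s2", random_dna_str(70)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f, width = 60)
  back <- read_fasta(f)
  expect_equal(back$s1$residues, seqs[[1]]$residues)
  expect_equal(back$s2$residues, seqs[[2]]$residues)
})

test_that("GFF3 disk coordinates are 1-based inclusive, memory 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1"), f)
  ft <- read_gff3(f)
  expect_equal(ft$start, 0L)
  expect_equal(ft$end, 10L)
})

test_that("GFF3 write/read round-trips coordinates, strand and attributes", {
  ft <- feature_table(
    id = c("g1", "s1"), kind = c("gene", "SSR"),
    seqid = "chrA", start = c(0L, 250L), end = c(120L, 274L),
    strand = c("-", "."),
    attributes = list(c(family = "RGA08", cds_start = "0"),
                      c(motif = "CT")))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ft, f)
  back <- read_gff3(f)
  expect_equal(back$id, ft$id)
  expect_equal(back$kind, ft$kind)
  expect_equal(back$start, ft$start)
  expect_equal(back$end, ft$end)
  expect_equal(back$strand, ft$strand)
  expect_equal(back$attributes[[1]][["family"]], "RGA08")
  expect_equal(back$attributes[[1]][["cds_start"]], "0")
  expect_equal(back$attributes[[2]][["motif"]], "CT")
})

test_that("GFF3 validation rejects unknown seqids and out-of-range features", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t5\t500\t.\t+\t.\tID=g1"), f)
  expect_error(read_gff3(f, seq_lengths = c(chr1 = 100)), "beyond")
  expect_error(read_gff3(f, seq_lengths = c(chrZ = 1000)), "seqid")
  expect_silent(read_gff3(f, seq_lengths = c(chr1 = 1000)))
})

test_that("EMBL flat files parse ID/FT/SQ with join/complement locations", {
  f <- withr::local_tempfile(fileext = ".embl")
  writeLines(c(
    "ID   TESTREC; SV 1; linear; genomic DNA; STD; PLN; 60 BP.",
    "FT   CDS             complement(10..30)",
    "FT                   /locus_tag=\"gene1\"",
    "FT   repeat_region   40..50",
    "SQ   Sequence 60 BP;",
    paste0("     ", paste(rep("acgtaagcta", 6), collapse = " "), "  60"),
    "//"), f)
  locus <- read_embl_flat(f)
  expect_s3_class(locus, "AnnotatedLocus")
  expect_equal(locus$sequence$length, 60L)
  g <- locus$genes$gene1
  expect_equal(g$strand, "-")
  expect_equal(unname(g$cds[1, ]), c(9L, 30L))
  expect_equal(locus$features$kind[locus$features$id == "gene1"], "gene")
  expect_true("repeat_element" %in% locus$features$kind)
})

test_that("EMBL join locations resolve into ordered exon ranges", {
  f <- withr::local_tempfile(fileext = ".embl")
  writeLines(c(
    "ID   J1; SV 1; linear; DNA; STD; PLN; 100 BP.",
    "FT   CDS             join(1..9,20..40)",
    "FT                   /locus_tag=\"j\"",
    "SQ   Sequence 100 BP;",
    paste0("     ", paste(rep("acgtacgtac", 10), collapse = "")),
    "//"), f)
  locus <- read_embl_flat(f)
  expect_equal(nrow(locus$genes$j$cds), 2)
  expect_equal(unname(locus$genes$j$cds[, 1]), c(0L, 19L))
  expect_equal(unname(locus$genes$j$cds[, 2]), c(9L, 40L))
})

test_that("EMBL parser rejects missing sequence blocks and odd operators", {
  f <- withr::local_tempfile(fileext = ".embl")
  writeLines(c("ID   X; 10 BP.", "FT   CDS             1..9"), f)
  expect_error(read_embl_flat(f), "sequence")

  writeLines(c("ID   X; 30 BP.",
               "FT   CDS             gap(1..9)",
               "SQ   Sequence 30 BP;",
               "     acgtacgtacacgtacgtacacgtacgtac",
               "//"), f)
  expect_error(read_embl_flat(f), "location")
})

test_that("extract_cds concatenates, reverse-complements, and flags frame", {
  seq <- haplotype_sequence("s", "ATGAAATTTGGG")
  g_plus <- gene_model("gp", "s", "+", as_r(0, 6))
  expect_equal(as.character(extract_cds(g_plus, seq)), "ATGAAA")

  g_minus <- gene_model("gm", "s", "-", as_r(0, 6))
  expect_equal(as.character(extract_cds(g_minus, seq)), "TTTCAT")

  g8 <- gene_model("g8", "s", "+", as_r(0, 8))
  cds <- extract_cds(g8, seq)
  expect_true(attr(cds, "incomplete_codon"))

  g_empty <- gene_model("ge", "s", "+", as_r(0, 6))
  g_empty$cds <- g_empty$cds[0, , drop = FALSE]
  expect_error(extract_cds(g_empty, seq), "no CDS")
})

test_that("minus-strand extraction equals reverse complement of plus-strand", {
  for (i in 1:5) {
    s <- haplotype_sequence("s", random_dna_str(60))
    st <- sample(0:20, 1); en <- st + 3 * sample(5:10, 1)
    gp <- gene_model("p", "s", "+", as_r(st, en))
    gm <- gene_model("m", "s", "-", as_r(st, en))
    expect_equal(as.character(extract_cds(gm, s)),
                 dna_revcomp(as.character(extract_cds(gp, s))))
  }
})

test_that("annotated_locus validates feature and gene extents", {
  s <- haplotype_sequence("s", random_dna_str(100))
  ft <- feature_table(id = "f1", kind = "misc", seqid = "s",
                      start = 90L, end = 150L, strand = ".")
  expect_error(annotated_locus(s, ft), "beyond")
  expect_error(feature_table(id = "f", kind = "nonsense", seqid = "s",
                             start = 0L, end = 5L, strand = "."),
               "unknown feature kind")
})
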