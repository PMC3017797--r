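# Anchoring, chaining, base-level refinement, SNP/indel cataloguing.

test_that("identical sequences give a single main-diagonal anchor", {
  set.seed(2)
  s <- random_dna_str(1000)
  an <- find_anchors(s, s, k = 15, both_strands = FALSE)
  expect_equal(nrow(an), 1)
  expect_equal(an$pos_a, 0L)
  expect_equal(an$pos_b, 0L)
  expect_equal(an$length, 1000L)
  expect_equal(an$diagonal, 0L)
})

test_that("an insertion splits anchors across two diagonals", {
  set.seed(3)
  a <- random_dna_str(1200)
  b <- paste0(substr(a, 1, 500), random_dna_str(100),
              substr(a, 501, 1200))
  an <- find_anchors(a, b, both_strands = FALSE)
  expect_setequal(unique(an$diagonal), c(0L, -100L))
})

test_that("repetitive seeds are filtered by k-mer frequency", {
  polya <- strrep("A", 1000)
  an <- find_anchors(polya, polya, max_kmer_freq = 10)
  expect_equal(nrow(an), 0)
})

test_that("anchors must be seeded with at least 8-mers", {
  expect_error(find_anchors("ACGTACGT", "ACGTACGT", k = 7), "k must be")
})

test_that("chaining produces one block for identical sequences", {
  set.seed(4)
  s <- random_dna_str(3000)
  bl <- chain_blocks(find_anchors(s, s))
  expect_length(bl, 1)
  expect_equal(bl[[1]]$range_a, c(0, 3000))
})

test_that("a gap beyond max_gap splits the chain into two blocks", {
  set.seed(5)
  left <- random_dna_str(3000); right <- random_dna_str(3000)
  a <- paste0(left, right)
  b <- paste0(left, random_dna_str(5000), right)   # 5 kb insertion
  bl <- chain_blocks(find_anchors(a, b), max_gap = 2000, min_block = 500)
  expect_length(bl, 2)
  expect_lt(bl[[1]]$range_a[2], 3100)
  expect_gt(bl[[2]]$range_b[1], 7900)
})

test_that("chained blocks are monotone and non-overlapping", {
  set.seed(6)
  for (rep in 1:3) {
    a <- random_dna_str(8000)
    # haplotype with substitutions and two structural edits
    b <- mutate_positions(a, sample(8000, 60))
    b <- paste0(substr(b, 1, 2500), random_dna_str(3000),
                substr(b, 2501, 5500), substr(b, 6100, 8000))
    bl <- chain_blocks(find_anchors(a, b), max_gap = 1500)
    if (length(bl) < 2) next
    for (i in seq_len(length(bl) - 1)) {
      expect_lte(bl[[i]]$range_a[2], bl[[i + 1]]$range_a[1])
      expect_lte(bl[[i]]$range_b[2], bl[[i + 1]]$range_b[1])
    }
  }
})

test_that("refinement of an identical block reports identity 1, no events", {
  set.seed(7)
  s <- random_dna_str(2000)
  bl <- chain_blocks(find_anchors(s, s))
  r <- refine_block(s, s, bl[[1]])
  expect_equal(r$block$identity, 1.0)
  expect_equal(r$block$snp_count, 0L)
  expect_equal(nrow(r$indels), 0)
})

test_that("planted substitutions are recovered as SNPs with exact identity", {
  set.seed(8)
  a <- random_dna_str(1000)
  idx <- sample(50:950, 10)
  b <- mutate_positions(a, idx)
  bl <- chain_blocks(find_anchors(a, b))
  r <- refine_block(a, b, bl[[1]])
  expect_equal(r$block$snp_count, 10L)
  expect_equal(r$block$identity, 0.99)
  expect_setequal(r$snps$pos_a, idx - 1L)
})

test_that("planted indel lengths and SNP counts are recovered exactly", {
  set.seed(9)
  for (rep in 1:5) {
    a <- random_dna_str(6000)
    ins_len <- sample(20:400, 1); del_len <- sample(20:400, 1)
    nsnp <- 15
    b <- mutate_positions(a, sample(c(200:1800, 4200:5800), nsnp))
    b <- paste0(substr(b, 1, 2000), random_dna_str(ins_len),
                substr(b, 2001, 3500),
                substr(b, 3501 + del_len, 6000))
    bl <- chain_blocks(find_anchors(a, b))
    expect_length(bl, 1)
    r <- refine_block(a, b, bl[[1]])
    expect_setequal(r$indels$length, c(ins_len, del_len))
    expect_equal(sort(r$indels$carrier),
                 sort(c("B", "A")))   # insertion carried by B, deletion by A
    expect_equal(r$block$snp_count, nsnp)
  }
})

test_that("identity equals 1 - SNPs / aligned columns", {
  set.seed(10)
  a <- random_dna_str(3000)
  b <- mutate_positions(a, sample(3000, 25))
  b <- paste0(substr(b, 1, 1500), random_dna_str(60), substr(b, 1501, 3000))
  r <- refine_block(a, b, chain_blocks(find_anchors(a, b))[[1]])
  st <- alignment_stats(r$aligned_a, r$aligned_b)
  expect_equal(r$block$identity, 1 - r$block$snp_count / st$aligned_columns)
  expect_equal(r$block$snp_count, st$mismatches)
})

test_that("refined score matches unbanded dynamic programming on small pairs", {
  skip_if_not_installed("Biostrings")
  set.seed(11)
  for (rep in 1:6) {
    a <- random_dna_str(1500)
    b <- mutate_positions(a, sample(1500, 15))
    if (rep %% 2 == 0)
      b <- paste0(substr(b, 1, 700), substr(b, 701 + sample(10:120, 1), 1500))
    bl <- chain_blocks(find_anchors(a, b))
    r <- refine_block(a, b, bl[[1]])
    full <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substr(a, bl[[1]]$range_a[1] + 1, bl[[1]]$range_a[2])),
      Biostrings::DNAString(substr(b, bl[[1]]$range_b[1] + 1, bl[[1]]$range_b[2])),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 6, gapExtension = 1)
    expect_equal(r$score, Biostrings::score(full))
  }
})

test_that("nucleotide diversity is substitutions over aligned columns", {
  set.seed(12)
  a <- random_dna_str(200)
  r_same <- refine_block(a, a,
                         chain_blocks(find_anchors(a, a),
                                      min_block = 100)[[1]])
  expect_equal(nucleotide_diversity(r_same), 0)

  b <- mutate_positions(a, sample(30:170, 2))
  r <- refine_block(a, b, chain_blocks(find_anchors(a, b), min_block = 100)[[1]])
  expect_equal(nucleotide_diversity(r), 0.01)

  expect_error(nucleotide_diversity(r, mask = as_r(5000, 5100)),
               "no eligible columns")
})

test_that("diversity mask restricts to coding columns", {
  set.seed(13)
  a <- random_dna_str(2000)
  b <- mutate_positions(a, c(100, 900, 1500))      # 1-based: 0-based 99/899/1499
  r <- refine_block(a, b, chain_blocks(find_anchors(a, b))[[1]])
  masked <- nucleotide_diversity(r, mask = as_r(0, 1000))
  expect_equal(masked, 2 / 1000)
})

test_that("dotplot export writes one row per anchor with inversions flagged", {
  set.seed(14)
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- find_anchors("ACGTACGTACGT", strrep("T", 12), both_strands = FALSE)
  export_dotplot(empty, f)
  expect_equal(length(readLines(f)), 1)   # header only

  core <- random_dna_str(3000)
  a <- core
  b <- paste0(substr(core, 1, 1000),
              dna_revcomp(substr(core, 1001, 2000)),
              substr(core, 2001, 3000))
  an <- find_anchors(a, b)
  export_dotplot(an, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nrow(an))
  expect_true(any(tab$strand == "-"))
  inv <- tab[tab$strand == "-", ]
  expect_true(all(inv$pos_b >= 950 & inv$pos_b + inv$length <= 2050))
})
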