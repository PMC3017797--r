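# Gene completeness classification, identity matrix, allele assignment,
# clade clustering, NB-LRR domain annotation, coding microsatellites.

mk_gene <- function(disruptions = character(), q = NA, s = NA) {
  gene_model("g", "chr", "+", as_r(0, 300), disruptions = disruptions,
             q_cov = q, s_cov = s)
}

test_that("classification follows the documented precedence on all rule combinations", {
  # independent expectation coded directly from the rules
  expected_label <- function(q, s, nf, dis) {
    if (q < 0.3 || (nf > 3 && q < 0.5) || dis > 2) "remnant"
    else if (dis >= 1) "pseudogene"
    else if (q < 0.8) "fragment"
    else if (s >= 0.8) "complete"
    else "fragment"
  }
  grid <- expand.grid(q = c(0.2, 0.4, 0.6, 0.85, 0.95),
                      s = c(0.5, 0.9),
                      nf = c(1L, 4L),
                      dis = c(0L, 1L, 3L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    model <- mk_gene(rep("frameshift", g$dis))
    got <- classify_gene(model, list(q_cov = g$q, s_cov = g$s,
                                     n_fragments = g$nf))
    expect_equal(got$label, expected_label(g$q, g$s, g$nf, g$dis),
                 info = paste(g, collapse = "/"))
  }
})

test_that("classification examples: complete, remnant, pseudogene", {
  expect_equal(classify_gene(mk_gene(), list(q_cov = 0.9, s_cov = 0.9,
                                             n_fragments = 1))$label,
               "complete")
  expect_equal(classify_gene(mk_gene(), list(q_cov = 0.25, s_cov = 0.9,
                                             n_fragments = 1))$label,
               "remnant")
  expect_equal(classify_gene(mk_gene("inframe_stop"),
                             list(q_cov = 0.95, s_cov = 0.95,
                                  n_fragments = 1))$label,
               "pseudogene")
})

test_that("classification without evidence falls back to disruptions with warning", {
  expect_warning(cl <- classify_gene(mk_gene("frameshift")), "evidence")
  expect_equal(cl$label, "pseudogene")
})

test_that("identity matrix is symmetric with unit diagonal", {
  set.seed(31)
  a <- random_sense_cds(200)
  b <- mutate_positions(a, sample(600, 60))     # ~10% divergence
  m <- pairwise_identity_matrix(list(x = a, y = b, z = a))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_equal(m["x", "z"], 1)
  expect_equal(m["x", "y"], 0.9, tolerance = 0.01)
  expect_error(pairwise_identity_matrix(list(a)), "at least two")
  expect_error(pairwise_identity_matrix(list(a = a, b = "")), "empty")
})

test_that("reciprocal best identity defines allelic pairs across haplotypes", {
  m <- matrix(c(1, 0.99, 0.99, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  al <- assign_alleles(m, c(g1 = "A", g2 = "B"))
  expect_equal(nrow(al$pairs), 1)
  expect_equal(al$pairs$gene_a, "g1")
  expect_equal(al$pairs$gene_b, "g2")
})

test_that("near-tied cross-haplotype identities flag ambiguity, not pairing", {
  # recent duplication: A1 and A2 on one haplotype both ~98% to B1
  ids <- c("A1", "A2", "B1")
  m <- matrix(c(1, 0.98, 0.981,
                0.98, 1, 0.979,
                0.981, 0.979, 1), 3, 3, dimnames = list(ids, ids))
  al <- assign_alleles(m, c(A1 = "A", A2 = "A", B1 = "B"))
  expect_equal(nrow(al$pairs), 0)
  expect_true(any(vapply(al$ambiguous, function(x) "B1" %in% x, TRUE)))
})

test_that("simulated pairs and one-sided paralogs are resolved exactly", {
  set.seed(32)
  base <- random_sense_cds(300)
  paralog <- function() mutate_positions(base, sample(900, 60))
  cds <- list()
  hap <- character()
  for (i in 1:5) {                       # 5 allele pairs at ~99%
    p <- paralog()
    cds[[paste0("P", i, "_A")]] <- p
    cds[[paste0("P", i, "_B")]] <- mutate_positions(p, sample(900, 8))
    hap[paste0("P", i, "_A")] <- "A"; hap[paste0("P", i, "_B")] <- "B"
  }
  for (i in 1:3) {                       # 3 paralogs unique to A
    cds[[paste0("U", i, "_A")]] <- paralog()
    hap[paste0("U", i, "_A")] <- "A"
  }
  m <- pairwise_identity_matrix(cds)
  al <- assign_alleles(m, hap)
  expect_equal(nrow(al$pairs), 5)
  expect_equal(sort(al$pairs$gene_a), paste0("P", 1:5, "_A"))
  expect_equal(sub("_A", "", al$pairs$gene_a),
               sub("_B", "", al$pairs$gene_b))
  expect_setequal(al$unpaired, paste0("U", 1:3, "_A"))
})

test_that("allele pairing never joins genes of the same haplotype and is order-stable", {
  set.seed(33)
  base <- random_sense_cds(200)
  cds <- list(x1 = base,
              x2 = mutate_positions(base, sample(600, 5)),
              y1 = mutate_positions(base, sample(600, 40)),
              y2 = mutate_positions(base, sample(600, 45)))
  hap <- c(x1 = "A", x2 = "B", y1 = "A", y2 = "B")
  m <- pairwise_identity_matrix(cds)
  al1 <- assign_alleles(m, hap)
  for (i in seq_len(nrow(al1$pairs)))
    expect_true(hap[al1$pairs$gene_a[i]] != hap[al1$pairs$gene_b[i]])
  perm <- c("y2", "x1", "y1", "x2")
  al2 <- assign_alleles(m[perm, perm], hap)
  expect_equal(al1$pairs[order(al1$pairs$gene_a), ],
               al2$pairs[order(al2$pairs$gene_a), ],
               ignore_attr = TRUE)
})

test_that("clade clustering separates planted families at the cut level", {
  set.seed(34)
  t1 <- random_sense_cds(250)
  t2 <- mutate_positions(t1, sample(750, 225))   # ~70% identity
  cds <- list(c1a = mutate_positions(t1, sample(750, 40)),
              c1b = mutate_positions(t1, sample(750, 40)),
              c2a = mutate_positions(t2, sample(750, 40)),
              c2b = mutate_positions(t2, sample(750, 40)),
              c2c = mutate_positions(t2, sample(750, 40)))
  m <- pairwise_identity_matrix(cds)
  cl <- cluster_clades(m, cut_identity = 0.80)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[c("c1a", "c1b")])), 1)
  expect_equal(length(unique(cl[c("c2a", "c2b", "c2c")])), 1)
  expect_true(cl["c1a"] != cl["c2a"])

  # a tight family collapses to one clade
  one <- cluster_clades(m[c("c2a", "c2b", "c2c"), c("c2a", "c2b", "c2c")],
                        cut_identity = 0.80)
  expect_equal(length(unique(one)), 1)
})

test_that("clade labels are invariant under input permutation", {
  set.seed(35)
  t1 <- random_sense_cds(150); t2 <- mutate_positions(t1, sample(450, 140))
  cds <- list(a = t1, b = mutate_positions(t1, sample(450, 10)),
              c = t2, d = mutate_positions(t2, sample(450, 10)))
  m <- pairwise_identity_matrix(cds)
  cl <- cluster_clades(m)
  perm <- c("c", "a", "d", "b")
  cl_p <- cluster_clades(m[perm, perm])
  # same partition regardless of order
  expect_equal(cl["a"] == cl["b"], cl_p["a"] == cl_p["b"])
  expect_equal(cl["a"] == cl["c"], cl_p["a"] == cl_p["c"])
  expect_equal(cl["c"] == cl["d"], cl_p["c"] == cl_p["d"])
})

test_that("NB-ARC motifs are found in order and LRR consensus units count exactly", {
  set.seed(36)
  cfg <- simulation_config(seed = 44)
  anc <- simulate_ancestor(cfg)
  meta_prot <- translate_cds(attr(anc, "meta")$templates$clade1)
  prot <- sub("[*]$", "", meta_prot)
  ann <- annotate_nblrr(prot)
  expect_equal(ann$nbarc_motifs$motif,
               c("P-loop", "RNBS-A", "kinase-2", "RNBS-B", "RNBS-C",
                 "GLPL", "RNBS-D", "MHD"))
  expect_true(all(diff(ann$nbarc_motifs$start) > 0))
  expect_equal(ann$n_lrr, 15)
  expect_true(all(ann$lrr_repeats$score >= 0.7))
  expect_equal(length(ann$exposed_positions), 15 * 5)
})

test_that("proteins without aliphatic residues have no LRR repeats", {
  prot <- paste(rep(c("G", "S", "E", "R", "D"), 60), collapse = "")
  ann <- annotate_nblrr(prot)
  expect_equal(ann$n_lrr, 0)
})

test_that("short or stop-containing proteins degrade gracefully", {
  expect_warning(ann <- annotate_nblrr("MKKE"), "shorter")
  expect_equal(ann$n_lrr, 0)
  long_with_stop <- paste0(strrep("GSERD", 30), "*", strrep("GSERD", 10))
  expect_warning(annotate_nblrr(long_with_stop), "stop")
})

test_that("coding microsatellites report amino-acid tracts and compounds", {
  expect_equal(nrow(detect_coding_ssr(random_sense_cds(80))$loci), 0)

  set.seed(37)
  flank1 <- random_sense_cds(40); flank2 <- random_sense_cds(40)
  cds <- paste0(flank1, strrep("TCT", 9), flank2)
  got <- detect_coding_ssr(cds)
  ser <- got$loci[got$loci$motif == "TCT", ]
  expect_equal(ser$repeat_count, 9L)
  expect_equal(ser$aa, "S")
  expect_equal(ser$tract, "Sx9")

  cds2 <- paste0(flank1, strrep("GAT", 4), strrep("GCT", 4),
                 strrep("GAA", 6), "TAA")
  got2 <- detect_coding_ssr(cds2)
  expect_equal(nrow(got2$compound), 1)
  expect_equal(got2$compound$motifs, "(GAT)4(GCT)4(GAA)6")
  expect_equal(got2$compound$tract, "Dx4-Ax4-Ex6")
})

test_that("pN/pS flags the undefined ratio and detects synonymous-only change", {
  set.seed(38)
  a <- random_sense_cds(60)
  same <- pairwise_dnds(a, a)
  expect_false(same$ratio_defined)

  # plant synonymous-only changes via the package's own opportunity scan:
  # third-position TTT->TTC style edits found by brute force
  cc <- strsplit(a, "")[[1]]
  gc <- Biostrings::GENETIC_CODE
  planted <- 0
  for (i in seq(1, length(cc) - 2, by = 3)) {
    if (planted >= 5) break
    cod <- paste(cc[i:(i + 2)], collapse = "")
    for (nt in setdiff(c("A", "C", "G", "T"), cc[i + 2])) {
      alt <- paste0(substr(cod, 1, 2), nt)
      if (!is.na(gc[alt]) && gc[alt] == gc[cod] && gc[cod] != "*") {
        cc[i + 2] <- nt; planted <- planted + 1; break
      }
    }
  }
  b <- paste(cc, collapse = "")
  r <- pairwise_dnds(a, b)
  expect_equal(r$ratio, 0)
  expect_gt(r$p_s, 0)
})
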