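# LTR retroelement structure, SSR scanning/matching, composition profiles.

make_ltr_element <- function(ltr_len = 300, internal_len = 2000,
                             tsd = "ACGTC", n_ltr_mut = 0) {
  ltr <- random_dna_str(ltr_len)
  substr(ltr, 1, 2) <- "TG"
  substr(ltr, ltr_len - 1, ltr_len) <- "CA"
  ltr3 <- if (n_ltr_mut > 0)
    mutate_positions(ltr, sample(3:(ltr_len - 2), n_ltr_mut)) else ltr
  elem <- paste0(ltr, random_dna_str(internal_len), ltr3)
  seq <- paste0(random_dna_str(400), tsd, elem, tsd, random_dna_str(400))
  list(seq = seq, element_start = 400 + nchar(tsd),
       element_end = 400 + nchar(tsd) + nchar(elem), ltr_len = ltr_len)
}

test_that("a random sequence yields no LTR calls", {
  set.seed(21)
  expect_length(detect_ltr(random_dna_str(3000)), 0)
})

test_that("a planted LTR element is recovered with exact lengths and TSD", {
  set.seed(22)
  el <- make_ltr_element(ltr_len = 300, internal_len = 2000, tsd = "ACGTC")
  calls <- detect_ltr(el$seq)
  expect_length(calls, 1)
  cl <- calls[[1]]
  expect_equal(unname(cl$ltr5_range[2] - cl$ltr5_range[1]), 300)
  expect_equal(unname(cl$ltr3_range[2] - cl$ltr3_range[1]), 300)
  expect_equal(unname(cl$element_range), c(el$element_start, el$element_end))
  expect_equal(cl$tsd_left, "ACGTC")
  expect_equal(cl$tsd_right, "ACGTC")
  expect_true(cl$tg_ca_5)
  expect_true(cl$tg_ca_3)
  expect_equal(cl$ltr_identity, 1.0)
})

test_that("planted LTR structure is recovered across divergence levels", {
  set.seed(23)
  for (nmut in c(3, 10, 25)) {
    el <- make_ltr_element(ltr_len = 400, internal_len = 1500,
                           tsd = "TTAC", n_ltr_mut = nmut)
    calls <- detect_ltr(el$seq)
    expect_length(calls, 1)
    cl <- calls[[1]]
    expect_equal(unname(cl$ltr5_range[2] - cl$ltr5_range[1]), 400)
    expect_equal(cl$tsd_left, "TTAC")
    expect_false(is.null(cl$insertion_time))
    expect_equal(cl$insertion_time$method, "ltr_K2P")
  }
})

test_that("detect_ltr validates its parameters", {
  expect_error(detect_ltr(random_dna_str(500), min_ltr = 20), "min_ltr")
  expect_error(detect_ltr(random_dna_str(500), min_identity = 0.5),
               "min_identity")
  expect_error(detect_ltr(random_dna_str(100), search_range = c(0, 100),
                          min_ltr = 60), "search_range")
})

test_that("SSR scan reports maximal perfect repeats, no homopolymers", {
  expect_equal(nrow(scan_ssr(strrep("A", 60))), 0)

  set.seed(24)
  s <- paste0(random_dna_str(100), strrep("CT", 12), random_dna_str(100))
  loci <- scan_ssr(s)
  hit <- loci[loci$start == 100, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$motif, "AG")      # canonical rotation over both strands
  expect_equal(hit$repeat_count, 12L)
  expect_equal(hit$end, 124L)
})

test_that("nested SSR reports are suppressed: a (CTCT)n run reports once as CT", {
  set.seed(25)
  s <- paste0(random_dna_str(80), strrep("CTCT", 6), random_dna_str(80))
  loci <- scan_ssr(s)
  inside <- loci[loci$start >= 78 & loci$end <= 106, ]
  expect_equal(nrow(inside), 1)
  expect_equal(inside$unit_length, 2L)
  expect_equal(inside$repeat_count, 12L)
})

test_that("every reported perfect locus revalidates against the sequence", {
  set.seed(26)
  units <- c("CT", "TAA", "GATA", "AATGC", "ACGTAT")
  s <- random_dna_str(200)
  for (u in units) s <- paste0(s, strrep(u, 6), random_dna_str(150))
  loci <- scan_ssr(s)
  expect_gte(nrow(loci), length(units))
  for (i in seq_len(nrow(loci))) {
    run <- substr(s, loci$start[i] + 1, loci$end[i])
    expect_equal(run, strrep(loci$unit[i], loci$repeat_count[i]))
  }
})

test_that("SSR scanning is strand-symmetric", {
  set.seed(27)
  s <- paste0(random_dna_str(120), strrep("AGC", 7), random_dna_str(60),
              strrep("CT", 9), random_dna_str(120))
  fwd <- scan_ssr(s)
  rev <- scan_ssr(dna_revcomp(s))
  expect_equal(nrow(fwd), nrow(rev))
  n <- nchar(s)
  mirrored <- data.frame(motif = rev$motif, start = n - rev$end,
                         end = n - rev$start)
  ord_f <- order(fwd$start); ord_m <- order(mirrored$start)
  expect_equal(fwd$motif[ord_f], mirrored$motif[ord_m])
  expect_equal(fwd$start[ord_f], mirrored$start[ord_m])
})

test_that("SSR matching pairs loci through colinearity and reports deltas", {
  set.seed(28)
  left <- random_dna_str(800); mid <- random_dna_str(700)
  right <- random_dna_str(800)
  a <- paste0(left, strrep("CT", 10), mid, strrep("TAA", 6), right)
  b_same <- a
  bl <- chain_blocks(find_anchors(a, b_same))
  m0 <- match_ssr_pairs(scan_ssr(a), scan_ssr(b_same), bl)
  expect_true(all(m0$repeat_delta == 0))
  expect_true(!any(m0$heterozygous))

  # expansion 10 -> 14 units on haplotype B
  b <- paste0(left, strrep("CT", 14), mid, strrep("TAA", 6), right)
  bl <- chain_blocks(find_anchors(a, b))
  m <- match_ssr_pairs(scan_ssr(a), scan_ssr(b), bl)
  hit <- m[m$motif == "AG", ]
  expect_equal(hit$repeat_delta, 4L)
  expect_true(hit$heterozygous)

  # an extreme expansion (upper bound seen in real data) still matches
  b46 <- paste0(left, strrep("CT", 56), mid, strrep("TAA", 6), right)
  bl <- chain_blocks(find_anchors(a, b46))
  m46 <- match_ssr_pairs(scan_ssr(a), scan_ssr(b46), bl)
  expect_equal(m46$repeat_delta[m46$motif == "AG"], 46L)
})

test_that("coding-range exclusion removes SSRs from the common report", {
  set.seed(29)
  a <- paste0(random_dna_str(500), strrep("CT", 10), random_dna_str(500))
  bl <- chain_blocks(find_anchors(a, a))
  m_all <- match_ssr_pairs(scan_ssr(a), scan_ssr(a), bl)
  m_ex <- match_ssr_pairs(scan_ssr(a), scan_ssr(a), bl,
                          exclude_a = as_r(450, 600),
                          exclude_b = as_r(450, 600))
  expect_gt(nrow(m_all), nrow(m_ex))
})

test_that("GC profile tracks composition and finds planted AT-rich islands", {
  gc1 <- gc_profile(strrep("GC", 300), window = 100, step = 50)
  expect_true(all(gc1$gc == 1))
  gc0 <- gc_profile(strrep("AT", 300), window = 100, step = 50)
  expect_true(all(gc0$gc == 0))
  expect_error(gc_profile(random_dna_str(300), window = 50), "window")
  expect_error(gc_profile(random_dna_str(80), window = 100), "window")

  set.seed(30)
  s <- paste0(random_dna_str(6000, gc = 0.4), random_dna_str(4000, gc = 0.3),
              random_dna_str(6000, gc = 0.4))
  prof <- gc_profile(s, window = 1000, step = 200)
  island <- prof$center > 6500 & prof$center < 9500
  expect_true(mean(prof$gc[island] < 0.35) > 0.9)
  expect_true(mean(prof$gc[!island]) > 0.37)
})
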