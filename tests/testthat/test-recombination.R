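# Sliding-window identity profiles, breakpoint calls, duplicated
# intergenic sequence scanning.

test_that("a recombinant identical to one parent profiles at 1.0 with no calls", {
  set.seed(41)
  pa <- random_dna_str(2000)
  pb <- mutate_positions(pa, sample(2000, 100))
  prof <- identity_profile(pa, list(A = pa, B = pb))
  expect_true(all(prof$tracks[, "A"] == 1))
  expect_true(all(prof$tracks[, "B"] < 1))
  expect_equal(nrow(call_breakpoints(prof)), 0)
})

test_that("profile input validation", {
  expect_error(identity_profile("ACGT", list(a = "ACGT")), "two parents")
  expect_error(identity_profile(random_dna_str(500),
                                list(a = "ACGT", b = "ACGT"), window = 20),
               "window")
})

test_that("a planted chimera produces crossing tracks and one breakpoint", {
  set.seed(42)
  ch <- make_chimera(len = 2000, junction = 1000, divergence = 0.05)
  prof <- identity_profile(ch$chimera, list(W = ch$parent_a, X = ch$parent_b))
  left <- prof$centers < 800; right <- prof$centers > 1200
  expect_gt(mean(prof$tracks[left, "W"]), mean(prof$tracks[left, "X"]))
  expect_gt(mean(prof$tracks[right, "X"]), mean(prof$tracks[right, "W"]))
  bp <- call_breakpoints(prof)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$left_parent, "W")
  expect_equal(bp$right_parent, "X")
  expect_lte(abs(bp$position - 1000), 100 / 2 + 10)
})

test_that("single-window label flips never produce calls", {
  # constructed profile: parent A dominant with isolated one-window flips
  centers <- seq(50, 1950, by = 10)
  n <- length(centers)
  ta <- rep(0.99, n); tb <- rep(0.95, n)
  flip <- c(30, 90, 150)
  tb[flip] <- 1.0                      # B wins at isolated windows
  prof <- structure(list(recombinant = "r", parents = c("A", "B"),
                         centers = centers,
                         tracks = cbind(A = ta, B = tb),
                         window = 100, step = 10),
                    class = "IdentityProfile")
  expect_equal(nrow(call_breakpoints(prof, min_run = 3)), 0)
})

test_that("breakpoint error stays within window/2 + step on random chimeras", {
  set.seed(43)
  n_ok <- 0; n <- 25
  for (i in 1:n) {
    junction <- sample(600:1400, 1)
    ch <- make_chimera(len = 2000, junction = junction,
                       divergence = runif(1, 0.03, 0.08))
    prof <- identity_profile(ch$chimera,
                             list(P = ch$parent_a, Q = ch$parent_b))
    bp <- call_breakpoints(prof)
    if (nrow(bp) == 1 && abs(bp$position - junction) <= 100 / 2 + 10)
      n_ok <- n_ok + 1
  }
  expect_gte(n_ok, round(0.95 * n))
})

test_that("duplicated intergenic probe occurrences are found above threshold", {
  set.seed(44)
  probe <- random_dna_str(1000)
  copies <- list(mutate_positions(probe, sample(1000, 20)),   # 0.98
                 mutate_positions(probe, sample(1000, 100)),  # 0.90
                 mutate_positions(probe, sample(1000, 200)),  # 0.80
                 mutate_positions(probe, sample(1000, 400)))  # 0.60
  hap <- paste0(random_dna_str(500), copies[[1]], random_dna_str(500),
                copies[[2]], random_dna_str(500), copies[[3]],
                random_dna_str(500), copies[[4]], random_dna_str(500))
  hits <- find_duplicated_intergenic(list(h1 = hap), probe,
                                     min_identity = 0.7)
  expect_equal(nrow(hits), 3)
  expect_true(all(hits$identity >= 0.7))

  none <- find_duplicated_intergenic(list(h1 = random_dna_str(4000)), probe)
  expect_equal(nrow(none), 0)
  expect_error(find_duplicated_intergenic(list(h1 = hap), "ACGT"),
               "200")
})

test_that("reverse-strand probe copies are located on forward coordinates", {
  set.seed(45)
  probe <- random_dna_str(600)
  hap <- paste0(random_dna_str(400), dna_revcomp(probe), random_dna_str(400))
  hits <- find_duplicated_intergenic(list(h = hap), probe)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 400)
  expect_equal(hits$end, 1000)
})

test_that("intergenic recombination scan links breakpoints to repeat hits", {
  set.seed(46)
  sim <- simulate_haplotype_pair(simulation_config(seed = 46))
  A <- sim$locus_a; B <- sim$locus_b; tr <- sim$truth
  an <- find_anchors(A$sequence, B$sequence)
  bl <- chain_blocks(an)
  ref <- lapply(bl, function(b) refine_block(A$sequence, B$sequence, b))
  indels <- do.call(rbind, lapply(ref, `[[`, "indels"))
  hits <- find_duplicated_intergenic(
    list(A = A$sequence$residues, B = B$sequence$residues), tr$probe)
  cand <- scan_intergenic_recombination(
    lapply(ref, `[[`, "block"), indels, hits,
    seq_a = A$sequence, seq_b = B$sequence)
  expect_gte(length(cand), 1)
  # resolution is bounded by paralog bridging: the event must be placed
  # inside or just beyond the deleted span on A, or near the fused
  # junction on B
  del <- tr$intergenic$deleted_range
  placed <- vapply(cand, function(ev) {
    (ev$pos_a >= del[1] - 2500 && ev$pos_a <= del[2] + 2500) ||
      abs(ev$pos_b - tr$intergenic$junction_b) <= 5000
  }, TRUE)
  expect_true(any(placed))
  # every candidate is anchored to at least one duplicated-repeat copy
  expect_true(all(vapply(cand, function(ev) nrow(ev$hits) >= 1, TRUE)))

  none <- scan_intergenic_recombination(
    lapply(ref, `[[`, "block"), indels, hits[0, , drop = FALSE])
  expect_length(none, 0)
})

test_that("profiles are deterministic", {
  set.seed(47)
  ch <- make_chimera()
  p1 <- identity_profile(ch$chimera, list(a = ch$parent_a, b = ch$parent_b))
  p2 <- identity_profile(ch$chimera, list(a = ch$parent_a, b = ch$parent_b))
  expect_identical(p1$tracks, p2$tracks)
})
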