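# Structural annotation of LTR retroelements and SSR (microsatellite)
# scanning.
#
# LTR elements are found by comparing a candidate region against itself:
# a pair of direct repeats near the two ends of the region is the LTR
# pair; TG...CA termini and 4-6 bp target-site duplications (TSDs) in
# the flanks complete the structural call, and the K2P distance between
# the two LTRs dates the insertion (LTRs are identical at insertion).

#' Detect LTR retroelement structure in a candidate region
#'
#' @param sequence DNA string or [haplotype_sequence()].
#' @param search_range 0-based half-open interval `c(start, end)` to
#'   examine (default: the whole sequence).
#' @param min_ltr minimum LTR length (>= 50).
#' @param min_identity minimum identity between the two LTR copies
#'   (>= 0.7).
#' @param tsd_range TSD lengths to try, longest first (4-6 bases; exact
#'   match required unless `tsd_mismatch = 1`, which also reports
#'   near-TSDs with one mismatch).
#' @param k seed length for the self-comparison.
#' @param date_min_ltr only LTR pairs at least this long are dated
#'   (short LTRs give unstable K2P estimates).
#' @param tsd_mismatch 0 (exact TSD) or 1 (allow one mismatch,
#'   reported with `tsd_exact = FALSE`).
#' @param rate substitution rate for insertion dating.
#' @return list of `LTRElementCall` objects with fields `element_range`,
#'   `ltr5_range`, `ltr3_range` (0-based half-open, full-sequence
#'   coordinates), `ltr_identity`, `tg_ca_5`, `tg_ca_3`, `tsd_left`,
#'   `tsd_right`, `tsd_exact`, `insertion_time` ([date_insertion()]
#'   result or `NULL`).
#' @export
detect_ltr <- function(sequence, search_range = NULL, min_ltr = 100,
                       min_identity = 0.8, tsd_range = c(4, 6), k = 13,
                       date_min_ltr = 300, tsd_mismatch = 0, rate = 9e-9) {
  if (min_ltr < 50) stop("min_ltr must be >= 50", call. = FALSE)
  if (min_identity < 0.7) stop("min_identity must be >= 0.7", call. = FALSE)
  res <- if (is.character(sequence)) sequence else sequence$residues
  if (is.null(search_range)) search_range <- c(0L, nchar(res))
  if (diff(search_range) < 2 * min_ltr)
    stop("search_range shorter than twice min_ltr", call. = FALSE)
  slice <- substr(res, search_range[1] + 1, search_range[2])
  n <- nchar(slice)
  an <- anchor_scan(slice, slice, k, max_kmer_freq = 25)
  an <- an[an$pos_b - an$pos_a >= min_ltr, , drop = FALSE]
  if (!nrow(an)) return(list())
  # candidate diagonals ranked by anchored coverage
  cov <- tapply(an$length, an$diagonal, sum)
  diags <- as.integer(names(sort(cov, decreasing = TRUE)))
  calls <- list(); used <- matrix(integer(), 0, 2)
  for (d in diags) {
    grp <- an[an$diagonal == d, , drop = FALSE]
    if (sum(grp$length) < min_ltr * min_identity * 0.5) next
    s5 <- min(grp$pos_a); e5 <- max(grp$pos_a + grp$length)
    s3 <- s5 - d; e3 <- e5 - d
    pad <- 150
    wa <- c(max(0, s5 - pad), min(e5 + pad, s3))   # clip: windows disjoint
    wb <- c(max(s3 - pad, e5), min(n, e3 + pad))
    if (diff(wa) < min_ltr || diff(wb) < min_ltr) next
    al <- local_align(substr(slice, wa[1] + 1, wa[2]),
                      substr(slice, wb[1] + 1, wb[2]))
    if (is.null(al)) next
    ltr5 <- c(wa[1] + al$start_a, wa[1] + al$end_a)     # 0-based half-open
    ltr3 <- c(wb[1] + al$start_b, wb[1] + al$end_b)
    # polish boundaries to TG...CA termini: a local alignment can over-
    # or under-run by several bases when flanking bases match by chance,
    # and the two copies need not over-run by the same amount. Each
    # boundary gets its own candidate shifts (positions showing the
    # canonical dinucleotide, nearest first); the outer pair (5' LTR
    # start, 3' LTR end) is disambiguated by the presence of an exact
    # target-site duplication, and the inner boundaries follow their
    # copy's outer shift as closely as possible.
    shifts <- c(0L, as.vector(rbind(-(1:12), 1:12)))   # nearest first
    at2 <- function(p) substr(slice, p + 1, p + 2)
    gs <- search_range[1]
    cand <- function(pred) {
      out <- shifts[vapply(shifts, pred, TRUE)]
      if (length(out)) out else 0L
    }
    s5c <- cand(function(d) at2(ltr5[1] + d) == "TG")
    s3c <- cand(function(d) at2(ltr3[1] + d) == "TG")
    e5c <- cand(function(d) at2(ltr5[2] + d - 2) == "CA")
    e3c <- cand(function(d) at2(ltr3[2] + d - 2) == "CA")
    ds5 <- s5c[1]; de3 <- e3c[1]
    if (length(s5c) > 1 || length(e3c) > 1) {
      combos <- expand.grid(ds = s5c, de = e3c)
      combos <- combos[order(abs(combos$ds) + abs(combos$de)), ]
      for (ci in seq_len(nrow(combos))) {
        tt <- find_tsd(res, gs + ltr5[1] + combos$ds[ci],
                       gs + ltr3[2] + combos$de[ci], tsd_range, 0)
        if (isTRUE(tt$exact)) {
          ds5 <- combos$ds[ci]; de3 <- combos$de[ci]
          break
        }
      }
    }
    ds3 <- s3c[which.min(abs(s3c - ds5))]
    de5 <- e5c[which.min(abs(e5c - de3))]
    ltr5 <- ltr5 + c(ds5, de5); ltr3 <- ltr3 + c(ds3, de3)
    # identity and dating use an alignment of the polished ranges, not
    # the raw local alignment (which may include flanking columns)
    al <- align_global(substr(slice, ltr5[1] + 1, ltr5[2]),
                       substr(slice, ltr3[1] + 1, ltr3[2]))
    st <- alignment_stats(al$aligned_a, al$aligned_b)
    if (ltr5[2] - ltr5[1] < min_ltr || is.na(st$identity) ||
        st$identity < min_identity) next
    if (any(used[, 1] < ltr3[2] & used[, 2] > ltr5[1])) next
    used <- rbind(used, c(ltr5[1], ltr3[2]))
    elem <- c(ltr5[1], ltr3[2])
    gs <- search_range[1]
    tsd <- find_tsd(res, gs + elem[1], gs + elem[2], tsd_range, tsd_mismatch)
    timing <- NULL
    if (min(ltr5[2] - ltr5[1], ltr3[2] - ltr3[1]) >= date_min_ltr) {
      timing <- tryCatch(
        date_insertion(k2p(al$aligned_a, al$aligned_b), rate = rate),
        error = function(e) NULL)
    }
    has_tg <- function(r) substr(slice, r[1] + 1, r[1] + 2) == "TG"
    has_ca <- function(r) substr(slice, r[2] - 1, r[2]) == "CA"
    calls[[length(calls) + 1]] <- structure(list(
      element_range = gs + elem, ltr5_range = gs + ltr5,
      ltr3_range = gs + ltr3, ltr_identity = st$identity,
      tg_ca_5 = has_tg(ltr5) && has_ca(ltr5),
      tg_ca_3 = has_tg(ltr3) && has_ca(ltr3),
      tsd_left = tsd$left, tsd_right = tsd$right, tsd_exact = tsd$exact,
      insertion_time = timing), class = "LTRElementCall")
  }
  calls[order(vapply(calls, function(x) x$element_range[1], 0))]
}

# local affine alignment via Biostrings; returns 0-based half-open hit
# coordinates within each input plus the gapped alignment strings
local_align <- function(a, b, match = 1, mismatch = -2,
                        gap_open = 6, gap_ext = 1) {
  if (!nchar(a) || !nchar(b)) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = gap_open, gapExtension = gap_ext)
  if (Biostrings::score(pa) <= 0) return(NULL)
  p <- pa@pattern@range; s <- pa@subject@range
  list(start_a = p@start - 1L, end_a = p@start - 1L + p@width,
       start_b = s@start - 1L, end_b = s@start - 1L + s@width,
       aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# search flanks of [start, end) for a 4-6 bp duplication
find_tsd <- function(res, start, end, tsd_range = c(4, 6), mismatch = 0) {
  for (L in seq(max(tsd_range), min(tsd_range))) {
    if (start - L < 0 || end + L > nchar(res)) next
    left <- substr(res, start - L + 1, start)
    right <- substr(res, end + 1, end + L)
    d <- sum(chars(left) != chars(right))
    if (d == 0) return(list(left = left, right = right, exact = TRUE))
    if (d <= mismatch) return(list(left = left, right = right, exact = FALSE))
  }
  list(left = NULL, right = NULL, exact = NA)
}

#' Scan a sequence for perfect microsatellites (SSRs)
#'
#' Reports maximal perfect tandem repeats with unit sizes 2-6.
#' Mononucleotide runs are excluded, and nested reports are suppressed by
#' only reporting primitive units (a (CTCT)n run is reported once, as
#' CT). The motif is canonicalised to the lexicographically minimal
#' rotation over both strands, so the scan is strand-symmetric.
#'
#' @param sequence DNA string or [haplotype_sequence()].
#' @param min_repeats named vector of minimum repeat counts per unit
#'   length (names "2".."6"; all >= 3).
#' @return data.frame of `SSRLocus` rows: `motif` (canonical), `unit`
#'   (as found), `unit_length`, `repeat_count`, `start`, `end` (0-based
#'   half-open), `perfect`.
#' @export
scan_ssr <- function(sequence,
                     min_repeats = c(`2` = 6, `3` = 5, `4` = 4,
                                     `5` = 4, `6` = 4)) {
  if (any(min_repeats < 3)) stop("min_repeats must all be >= 3", call. = FALSE)
  res <- if (is.character(sequence)) sequence else sequence$residues
  rows <- list()
  for (u in 2:6) {
    minr <- min_repeats[[as.character(u)]]
    if (is.null(minr)) next
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, minr - 1)
    m <- gregexpr(pat, res, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      unit <- substr(res, m[i], m[i] + u - 1)
      if (!is_primitive_unit(unit)) next
      count <- len[i] %/% u
      rows[[length(rows) + 1]] <- data.frame(
        motif = canonical_motif(unit), unit = unit, unit_length = u,
        repeat_count = count, start = m[i] - 1L,
        end = m[i] - 1L + u * count, perfect = TRUE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), unit = character(),
                      unit_length = integer(), repeat_count = integer(),
                      start = integer(), end = integer(),
                      perfect = logical()))
  out <- do.call(rbind, rows)
  # suppress loci fully contained in a locus with a shorter unit
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    inside <- out$start >= out$start[i] & out$end <= out$end[i] &
      seq_len(nrow(out)) != i
    keep[inside & out$unit_length >= out$unit_length[i]] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE when the unit is not itself a tandem repeat of a shorter unit
# (this also excludes homopolymer units such as "AA")
is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (p in seq_len(u - 1)) {
    if (u %% p != 0) next
    if (identical(strrep(substr(unit, 1, p), u / p), unit)) return(FALSE)
  }
  TRUE
}

#' Match SSR loci between haplotypes through colinear blocks
#'
#' Maps each sequence-A locus into sequence-B coordinates via the nearest
#' anchor of the enclosing colinear block and pairs it with a same-motif
#' locus within `tolerance` bases. Loci inside `exclude_a`/`exclude_b`
#' (typically RGA coding ranges, where orthology is ambiguous) are left
#' out of the common-SSR report.
#'
#' @param loci_a,loci_b data.frames from [scan_ssr()].
#' @param blocks list of `ColinearBlock` from [chain_blocks()].
#' @param tolerance maximum projected-position discrepancy (bases).
#' @param exclude_a,exclude_b optional 0-based half-open interval
#'   matrices of regions to exclude.
#' @return data.frame of `SSRMatch` rows: motif, positions and repeat
#'   counts on both haplotypes, `repeat_delta` (B minus A) and
#'   `heterozygous` (`repeat_delta != 0`).
#' @export
match_ssr_pairs <- function(loci_a, loci_b, blocks, tolerance = 300,
                            exclude_a = NULL, exclude_b = NULL) {
  empty <- data.frame(motif = character(), start_a = integer(),
                      start_b = integer(), count_a = integer(),
                      count_b = integer(), repeat_delta = integer(),
                      heterozygous = logical())
  if (!nrow(loci_a) || !nrow(loci_b)) return(empty)
  if (!is.null(exclude_a))
    loci_a <- loci_a[!in_ranges(loci_a$start, exclude_a), , drop = FALSE]
  if (!is.null(exclude_b))
    loci_b <- loci_b[!in_ranges(loci_b$start, exclude_b), , drop = FALSE]
  used_b <- rep(FALSE, nrow(loci_b))
  rows <- list()
  for (i in seq_len(nrow(loci_a))) {
    pos <- loci_a$start[i]
    proj <- project_position(pos, blocks)
    if (is.na(proj)) next
    cand <- which(!used_b & loci_b$motif == loci_a$motif[i] &
                  abs(loci_b$start - proj) <= tolerance)
    if (!length(cand)) next
    j <- cand[which.min(abs(loci_b$start[cand] - proj))]
    used_b[j] <- TRUE
    delta <- loci_b$repeat_count[j] - loci_a$repeat_count[i]
    rows[[length(rows) + 1]] <- data.frame(
      motif = loci_a$motif[i], start_a = pos, start_b = loci_b$start[j],
      count_a = loci_a$repeat_count[i], count_b = loci_b$repeat_count[j],
      repeat_delta = delta, heterozygous = delta != 0L)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# project a sequence-A position into B via the nearest anchor of the
# enclosing colinear block; NA when no block covers the position
project_position <- function(pos, blocks) {
  for (b in blocks) {
    if (pos >= b$range_a[1] && pos < b$range_a[2]) {
      an <- b$anchors
      j <- which.min(abs(an$pos_a - pos))
      return(an$pos_b[j] + (pos - an$pos_a[j]))
    }
  }
  NA_integer_
}

#' GC-content profile in sliding windows
#'
#' @param sequence DNA string or [haplotype_sequence()].
#' @param window window size (>= 100); @param step step size.
#' @return data.frame with `center` (0-based) and `gc` (fraction of
#'   unambiguous bases that are G or C; N excluded from the denominator).
#' @export
gc_profile <- function(sequence, window = 1000, step = 500) {
  if (window < 100) stop("window must be >= 100", call. = FALSE)
  res <- if (is.character(sequence)) sequence else sequence$residues
  n <- nchar(res)
  if (window > n) stop("window longer than sequence", call. = FALSE)
  cc <- chars(res)
  is_gc <- cumsum(c(0, cc %in% c("G", "C")))
  is_at <- cumsum(c(0, cc %in% c("A", "T")))
  starts <- seq(0, n - window, by = step)
  gc <- is_gc[starts + window + 1] - is_gc[starts + 1]
  at <- is_at[starts + window + 1] - is_at[starts + 1]
  data.frame(center = as.integer(starts + window %/% 2),
             gc = ifelse(gc + at > 0, gc / (gc + at), NA_real_))
}
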