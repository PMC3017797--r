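# Haplotype colinearity: k-mer anchoring, monotone chaining into colinear
# blocks, base-level refinement, and SNP/indel cataloguing.

#' Find exact-match anchors between two sequences
#'
#' Seeds shared k-mers whose frequency in either sequence does not exceed
#' `max_kmer_freq` (suppressing repetitive seeds) and merges overlapping
#' seeds on a common diagonal into maximal runs. Reverse-strand anchors
#' are reported (for detecting inversions) but are never chained into
#' forward colinear blocks.
#'
#' @param seq_a,seq_b DNA strings (or [haplotype_sequence()] records).
#' @param k seed length (>= 8); @param max_kmer_freq repetitive-seed cap.
#' @param both_strands also search `seq_b`'s reverse complement.
#' @return data.frame with `pos_a`, `pos_b`, `length`, `strand`,
#'   `diagonal` (0-based positions; for `-` anchors `pos_b` is on the
#'   forward strand of `seq_b`).
#' @export
find_anchors <- function(seq_a, seq_b, k = 15, max_kmer_freq = 8,
                         both_strands = TRUE) {
  if (k < 8) stop("k must be >= 8", call. = FALSE)
  a <- if (is.character(seq_a)) seq_a else seq_a$residues
  b <- if (is.character(seq_b)) seq_b else seq_b$residues
  fwd <- anchor_scan(a, b, k, max_kmer_freq)
  fwd$strand <- rep("+", nrow(fwd))
  out <- fwd
  if (both_strands) {
    rev <- anchor_scan(a, dna_revcomp(b), k, max_kmer_freq)
    if (nrow(rev)) {
      # map back to forward coordinates of seq_b
      rev$pos_b <- nchar(b) - (rev$pos_b + rev$length)
      rev$strand <- "-"
      rev$diagonal <- rev$pos_a - rev$pos_b
      out <- rbind(fwd, rev)
    }
  }
  out[order(out$pos_a, out$pos_b), , drop = FALSE]
}

anchor_scan <- function(a, b, k, max_kmer_freq) {
  empty <- data.frame(pos_a = integer(), pos_b = integer(),
                      length = integer(), strand = character(),
                      diagonal = integer())
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(empty[, c(1, 2, 3, 5)])
  ka <- substring(a, 1:(na - k + 1), k:na)
  kb <- substring(b, 1:(nb - k + 1), k:nb)
  fa <- table(ka); fb <- table(kb)
  keep <- intersect(names(fa)[fa <= max_kmer_freq],
                    names(fb)[fb <= max_kmer_freq])
  # seeds containing ambiguity codes are not anchors
  keep <- keep[grepl("^[ACGT]+$", keep)]
  ia <- which(ka %in% keep)
  if (!length(ia)) return(empty[, c(1, 2, 3, 5)])
  idx_b <- split(seq_along(kb) - 1L, kb)
  pb_list <- idx_b[ka[ia]]
  lens <- lengths(pb_list)
  hits_a <- rep(ia - 1L, lens)
  hits_b <- unlist(pb_list, use.names = FALSE)
  if (!length(hits_a)) return(empty[, c(1, 2, 3, 5)])
  d <- hits_a - hits_b
  ord <- order(d, hits_a)
  hits_a <- hits_a[ord]; d <- d[ord]
  # merge overlapping/contiguous seeds per diagonal into maximal runs
  new_run <- c(TRUE, diff(d) != 0 | diff(hits_a) > k)
  run_id <- cumsum(new_run)
  starts <- tapply(hits_a, run_id, min)
  ends <- tapply(hits_a, run_id, max) + k
  diags <- tapply(d, run_id, `[`, 1)
  data.frame(pos_a = as.integer(starts),
             pos_b = as.integer(starts - diags),
             length = as.integer(ends - starts),
             diagonal = as.integer(diags))
}

#' Chain anchors into coarse colinear blocks
#'
#' Finds the highest-scoring monotone chain (score = anchored bases) by
#' dynamic programming, removes its anchors and any anchor overlapping
#' its footprint, and repeats; chains are broken where the inter-anchor
#' gap on either sequence exceeds `max_gap`, and blocks spanning less
#' than `min_block` on sequence A are dropped. Only forward-strand
#' anchors are chained.
#'
#' @param anchors data.frame from [find_anchors()].
#' @param max_gap maximum unanchored gap within a block (bases).
#' @param min_block minimum block span on sequence A (bases).
#' @return list of `ColinearBlock` objects, ordered by `range_a`; each
#'   has `range_a`, `range_b` (0-based half-open), `anchors`, and
#'   `identity`/`snp_count`/`gap_count` fields filled by [refine_block()].
#' @export
chain_blocks <- function(anchors, max_gap = 5000, min_block = 500) {
  an <- anchors[anchors$strand == "+", , drop = FALSE]
  blocks <- list()
  while (nrow(an)) {
    ch <- best_chain(an, max_gap)
    if (is.null(ch)) break
    sub <- an[ch, , drop = FALSE]
    ra <- c(min(sub$pos_a), max(sub$pos_a + sub$length))
    rb <- c(min(sub$pos_b), max(sub$pos_b + sub$length))
    if (ra[2] - ra[1] >= min_block) {
      blocks[[length(blocks) + 1]] <- structure(
        list(range_a = ra, range_b = rb, anchors = sub,
             identity = NA_real_, snp_count = NA_integer_,
             gap_count = NA_integer_),
        class = "ColinearBlock")
    }
    drop <- (an$pos_a < ra[2] & an$pos_a + an$length > ra[1]) |
            (an$pos_b < rb[2] & an$pos_b + an$length > rb[1])
    an <- an[!drop, , drop = FALSE]
    if (ra[2] - ra[1] < min_block && !any(drop)) break
  }
  blocks[order(vapply(blocks, function(b) b$range_a[1], 0))]
}

# best monotone chain under the gap constraint; returns row indices
best_chain <- function(an, max_gap) {
  n <- nrow(an)
  if (!n) return(NULL)
  ord <- order(an$pos_a, an$pos_b)
  an <- an[ord, ]
  ea <- an$pos_a + an$length; eb <- an$pos_b + an$length
  dp <- as.numeric(an$length); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)[-1]) {
    cand <- which(an$pos_a[1:(i - 1)] < an$pos_a[i] &
                  an$pos_b[1:(i - 1)] < an$pos_b[i] &
                  an$pos_a[i] - ea[1:(i - 1)] <= max_gap &
                  an$pos_b[i] - eb[1:(i - 1)] <= max_gap &
                  eb[1:(i - 1)] <= an$pos_b[i] + an$length[i])
    if (length(cand)) {
      j <- cand[which.max(dp[cand])]
      dp[i] <- dp[j] + an$length[i]
      prev[i] <- j
    }
  }
  i <- which.max(dp)
  chain <- integer()
  while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
  ord[chain]
}

#' Refine a colinear block to a base-level alignment
#'
#' Blocks small enough for full dynamic programming are aligned globally
#' with affine gaps; larger blocks are aligned piecewise through their
#' anchors (exact anchor matches fixed, inter-anchor segments aligned
#' globally), so large blocks never silently truncate.
#'
#' @param seq_a,seq_b full haplotype strings.
#' @param block a `ColinearBlock` from [chain_blocks()].
#' @param band optional band half-width for the full-DP path.
#' @param max_dp_cells cell-count threshold above which the anchored
#'   piecewise mode is used.
#' @return list with the updated `block` (identity, snp_count,
#'   gap_count), `aligned_a`/`aligned_b`, `score`, `snps` (data.frame
#'   `pos_a`, `pos_b`, `base_a`, `base_b`) and `indels` (data.frame
#'   `pos_a`, `pos_b`, `length`, `carrier`, `annotation`; carrier is the
#'   haplotype bearing the extra sequence).
#' @export
refine_block <- function(seq_a, seq_b, block, band = NULL,
                         max_dp_cells = 2.5e7) {
  a <- if (is.character(seq_a)) seq_a else seq_a$residues
  b <- if (is.character(seq_b)) seq_b else seq_b$residues
  sa <- substr(a, block$range_a[1] + 1, block$range_a[2])
  sb <- substr(b, block$range_b[1] + 1, block$range_b[2])
  if (as.numeric(nchar(sa)) * nchar(sb) <= max_dp_cells) {
    al <- align_global(sa, sb, band = band)
  } else {
    al <- align_through_anchors(sa, sb, block)
  }
  st <- alignment_stats(al$aligned_a, al$aligned_b)
  ev <- alignment_events(al$aligned_a, al$aligned_b,
                         block$range_a[1], block$range_b[1])
  block$identity <- st$identity
  block$snp_count <- st$mismatches
  block$gap_count <- nrow(ev$indels)
  list(block = block, aligned_a = al$aligned_a, aligned_b = al$aligned_b,
       score = al$score, snps = ev$snps, indels = ev$indels)
}

# piecewise alignment through the block's (trimmed, non-overlapping) anchors
align_through_anchors <- function(sa, sb, block) {
  an <- block$anchors
  an$pos_a <- an$pos_a - block$range_a[1]
  an$pos_b <- an$pos_b - block$range_b[1]
  an <- an[order(an$pos_a), , drop = FALSE]
  # trim to strictly increasing, non-overlapping anchors
  kept <- list(); ea <- 0; eb <- 0
  for (i in seq_len(nrow(an))) {
    t <- max(ea - an$pos_a[i], eb - an$pos_b[i], 0)
    pa <- an$pos_a[i] + t; pb <- an$pos_b[i] + t; L <- an$length[i] - t
    if (L <= 0) next
    kept[[length(kept) + 1]] <- c(pa, pb, L)
    ea <- pa + L; eb <- pb + L
  }
  aa <- character(); ab <- character(); score <- 0; ca <- 0; cb <- 0
  for (kk in kept) {
    ga <- substr(sa, ca + 1, kk[1]); gb <- substr(sb, cb + 1, kk[2])
    if (nchar(ga) || nchar(gb)) {
      seg <- align_global(ga, gb)
      aa <- c(aa, seg$aligned_a); ab <- c(ab, seg$aligned_b)
      score <- score + seg$score
    }
    anc <- substr(sa, kk[1] + 1, kk[1] + kk[3])
    aa <- c(aa, anc); ab <- c(ab, anc)
    score <- score + kk[3]  # match score 1 per anchored base
    ca <- kk[1] + kk[3]; cb <- kk[2] + kk[3]
  }
  ga <- substr(sa, ca + 1, nchar(sa)); gb <- substr(sb, cb + 1, nchar(sb))
  if (nchar(ga) || nchar(gb)) {
    seg <- align_global(ga, gb)
    aa <- c(aa, seg$aligned_a); ab <- c(ab, seg$aligned_b)
    score <- score + seg$score
  }
  list(score = score, aligned_a = paste(aa, collapse = ""),
       aligned_b = paste(ab, collapse = ""))
}

# SNP and indel events from a gapped alignment, in full-sequence coordinates
alignment_events <- function(aligned_a, aligned_b, off_a = 0, off_b = 0) {
  ca <- chars(aligned_a); cb <- chars(aligned_b)
  ga <- ca == "-"; gb <- cb == "-"
  pos_a <- cumsum(!ga) - 1L + off_a   # coordinate of the base in this column
  pos_b <- cumsum(!gb) - 1L + off_b
  mm <- which(!ga & !gb & ca != cb &
              ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T"))
  snps <- data.frame(pos_a = pos_a[mm], pos_b = pos_b[mm],
                     base_a = ca[mm], base_b = cb[mm])
  gap <- ga | gb
  indels <- data.frame(pos_a = integer(), pos_b = integer(),
                       length = integer(), carrier = character(),
                       annotation = character())
  if (any(gap)) {
    r <- rle(gap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      s <- starts[i]
      carrier <- if (ga[s]) "B" else "A"   # gap in A => extra sequence in B
      indels <- rbind(indels, data.frame(
        pos_a = if (ga[s]) pos_a[s] + 1L else pos_a[s],
        pos_b = if (gb[s]) pos_b[s] + 1L else pos_b[s],
        length = r$lengths[i], carrier = carrier,
        annotation = ""))
    }
  }
  list(snps = snps, indels = indels)
}

#' Nucleotide diversity of a refined alignment
#'
#' Substitution count divided by aligned non-gap columns, optionally
#' restricted to a mask of sequence-A intervals (e.g. coding columns).
#'
#' @param refined result of [refine_block()], or a list with
#'   `aligned_a`/`aligned_b` plus a block, or a list of several refined
#'   blocks (pooled).
#' @param mask optional 2-column matrix of 0-based half-open intervals on
#'   sequence A.
#' @return diversity as a fraction.
#' @export
nucleotide_diversity <- function(refined, mask = NULL) {
  if (!is.null(refined$aligned_a)) refined <- list(refined)
  subs <- 0; cols <- 0
  for (r in refined) {
    ca <- chars(r$aligned_a); cb <- chars(r$aligned_b)
    ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
    if (!is.null(mask)) {
      pos_a <- cumsum(ca != "-") - 1L + r$block$range_a[1]
      ok <- ok & in_ranges(pos_a, mask)
    }
    subs <- subs + sum(ok & ca != cb)
    cols <- cols + sum(ok)
  }
  if (cols == 0) stop("no eligible columns: diversity undefined",
                      call. = FALSE)
  subs / cols
}

#' Export anchors as a dotplot coordinate file
#'
#' @param anchors data.frame from [find_anchors()].
#' @param path output TSV path.
#' @return the path, invisibly. Columns: `pos_a`, `pos_b`, `length`,
#'   `strand`; inverted matches carry strand `-`.
#' @export
export_dotplot <- function(anchors, path) {
  write.table(anchors[, c("pos_a", "pos_b", "length", "strand"),
                      drop = FALSE],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
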