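# Unequal-recombination detection: sliding-window percent-identity
# profiles of candidate parental sequences along a putative recombinant,
# breakpoint calls at identity-rank shifts, and the scan for breakpoints
# mediated by duplicated intergenic sequences.

#' Windowed identity profile of parents along a recombinant
#'
#' Each parent is globally aligned to the recombinant; identity is then
#' computed in sliding windows on recombinant coordinates, with gap
#' columns counted as mismatches. Windows where a parent covers less
#' than half the positions are masked for that parent.
#'
#' @param recombinant DNA string (or [haplotype_sequence()]).
#' @param parents named list of >= 2 parent DNA strings.
#' @param window window size (>= 50); @param step step size.
#' @return list of class `IdentityProfile`: `centers` (0-based window
#'   centers on the recombinant), `tracks` (windows x parents identity
#'   matrix, `NA` where masked), `window`, `step`.
#' @export
identity_profile <- function(recombinant, parents, window = 100,
                             step = 10) {
  if (length(parents) < 2) stop("need at least two parents", call. = FALSE)
  if (window < 50) stop("window must be >= 50", call. = FALSE)
  rec <- if (is.character(recombinant)) recombinant else recombinant$residues
  n <- nchar(rec)
  if (is.null(names(parents)))
    names(parents) <- paste0("parent", seq_along(parents))
  starts <- seq(0, n - window, by = step)
  tracks <- matrix(NA_real_, length(starts), length(parents),
                   dimnames = list(NULL, names(parents)))
  for (p in names(parents)) {
    par <- parents[[p]]
    par <- if (is.character(par)) par else par$residues
    al <- align_global(par, rec)
    ca <- chars(al$aligned_a); cb <- chars(al$aligned_b)
    keep <- cb != "-"                       # columns with a recombinant base
    match_v <- as.numeric(ca[keep] == cb[keep] & ca[keep] != "-")
    cover_v <- as.numeric(ca[keep] != "-")
    cm <- cumsum(c(0, match_v)); cc <- cumsum(c(0, cover_v))
    idw <- (cm[starts + window + 1] - cm[starts + 1]) / window
    cvw <- (cc[starts + window + 1] - cc[starts + 1]) / window
    idw[cvw < 0.5] <- NA_real_
    tracks[, p] <- idw
  }
  structure(list(recombinant = if (is.character(recombinant)) "recombinant"
                 else recombinant$id,
                 parents = names(parents),
                 centers = as.integer(starts + window %/% 2),
                 tracks = tracks, window = window, step = step),
            class = "IdentityProfile")
}

#' Call recombination breakpoints from an identity profile
#'
#' Labels each window with its best-matching parent, finds maximal runs
#' of constant label, and emits a breakpoint at the midpoint between
#' adjacent runs of different labels when both runs span at least
#' `min_run` windows and the mean identity advantage of the winning
#' parent is at least `min_delta` on both sides. Single-window label
#' flips therefore never produce calls.
#'
#' @param profile an [identity_profile()].
#' @param min_delta minimum mean identity advantage (fraction).
#' @param min_run minimum run length (windows).
#' @return data.frame of `BreakpointCall` rows: `position` (recombinant
#'   coordinate), `left_parent`, `right_parent`, `delta_left`,
#'   `delta_right`, `run_left`, `run_right`.
#' @export
call_breakpoints <- function(profile, min_delta = 0.02, min_run = 3) {
  tr <- profile$tracks
  empty <- data.frame(position = integer(), left_parent = character(),
                      right_parent = character(), delta_left = numeric(),
                      delta_right = numeric(), run_left = integer(),
                      run_right = integer())
  usable <- rowSums(!is.na(tr)) >= 2
  if (!any(usable)) return(empty)
  lab <- rep(NA_character_, nrow(tr))
  for (i in which(usable)) {
    v <- tr[i, ]
    best <- which.max(v)
    # ties leave the window unlabelled
    if (sum(v == v[best], na.rm = TRUE) == 1) lab[i] <- colnames(tr)[best]
  }
  idx <- which(!is.na(lab))
  if (length(idx) < 2 * min_run) return(empty)
  r <- rle(lab[idx])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  calls <- empty
  for (i in seq_len(length(r$values) - 1)) {
    if (r$lengths[i] < min_run || r$lengths[i + 1] < min_run) next
    lp <- r$values[i]; rp <- r$values[i + 1]
    if (lp == rp) next
    li <- idx[starts[i]:ends[i]]; ri <- idx[starts[i + 1]:ends[i + 1]]
    dl <- mean(tr[li, lp] - tr[li, rp], na.rm = TRUE)
    dr <- mean(tr[ri, rp] - tr[ri, lp], na.rm = TRUE)
    if (is.na(dl) || is.na(dr) || dl < min_delta || dr < min_delta) next
    pos <- as.integer(round((profile$centers[idx[ends[i]]] +
                             profile$centers[idx[starts[i + 1]]]) / 2))
    calls <- rbind(calls, data.frame(
      position = pos, left_parent = lp, right_parent = rp,
      delta_left = dl, delta_right = dr,
      run_left = r$lengths[i], run_right = r$lengths[i + 1]))
  }
  calls
}

#' Find occurrences of a duplicated intergenic probe sequence
#'
#' Locates all local-alignment occurrences of the probe on both strands
#' of each haplotype at identity >= `min_identity`, non-overlapping
#' best-first.
#'
#' @param haplotypes named list of DNA strings or
#'   [haplotype_sequence()] records.
#' @param probe_sequence the duplicated sequence (>= 200 bp).
#' @param min_identity identity threshold over aligned columns.
#' @param min_coverage minimum fraction of the probe covered by the hit.
#' @param k seed length for candidate location.
#' @return data.frame of `IntergenicRepeatHit` rows: `haplotype`,
#'   `start`, `end` (0-based half-open, forward strand), `strand`,
#'   `identity`.
#' @export
find_duplicated_intergenic <- function(haplotypes, probe_sequence,
                                       min_identity = 0.7,
                                       min_coverage = 0.5, k = 13) {
  if (nchar(probe_sequence) < 200)
    stop("probe must be at least 200 bp", call. = FALSE)
  empty <- data.frame(haplotype = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric())
  rows <- empty
  plen <- nchar(probe_sequence)
  for (h in names(haplotypes)) {
    seqh <- haplotypes[[h]]
    seqh <- if (is.character(seqh)) seqh else seqh$residues
    for (strand in c("+", "-")) {
      target <- if (strand == "+") seqh else dna_revcomp(seqh)
      an <- anchor_scan(probe_sequence, target, k, max_kmer_freq = 50)
      if (!nrow(an)) next
      # one candidate region per diagonal cluster: distinct copies of the
      # probe sit on well-separated diagonals even when adjacent in
      # position
      an <- an[order(an$diagonal, an$pos_b), , drop = FALSE]
      grp <- cumsum(c(1, diff(an$diagonal) > 400 | diff(an$pos_b) > 2 * plen))
      for (g in unique(grp)) {
        sub <- an[grp == g, , drop = FALSE]
        w0 <- max(0, min(sub$pos_b) - plen %/% 2)
        w1 <- min(nchar(target), max(sub$pos_b + sub$length) + plen %/% 2)
        al <- local_align(probe_sequence, substr(target, w0 + 1, w1))
        if (is.null(al)) next
        st <- alignment_stats(al$aligned_a, al$aligned_b)
        if (is.na(st$identity) || st$identity < min_identity) next
        if ((al$end_a - al$start_a) / plen < min_coverage) next
        s <- w0 + al$start_b; e <- w0 + al$end_b
        if (strand == "-") { tmp <- s; s <- nchar(seqh) - e; e <- nchar(seqh) - tmp }
        rows <- rbind(rows, data.frame(haplotype = h, start = s, end = e,
                                       strand = strand,
                                       identity = st$identity))
      }
    }
    # non-overlapping best-first within a haplotype
    hr <- rows[rows$haplotype == h, , drop = FALSE]
    if (nrow(hr) > 1) {
      hr <- hr[order(-hr$identity), , drop = FALSE]
      keep <- rep(TRUE, nrow(hr))
      for (i in seq_len(nrow(hr))[-1]) {
        prior <- which(keep[seq_len(i - 1)])
        if (any(hr$start[prior] < hr$end[i] & hr$end[prior] > hr$start[i]))
          keep[i] <- FALSE
      }
      rows <- rbind(rows[rows$haplotype != h, , drop = FALSE],
                    hr[keep, , drop = FALSE])
    }
  }
  rows <- rows[order(rows$haplotype, rows$start), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Scan colinearity breakpoints for intergenic-repeat-mediated events
#'
#' Reports every colinearity discontinuity (boundary between adjacent
#' colinear blocks, or indel of at least `min_indel` bases) that lies
#' within `flank` bases of a duplicated-intergenic-sequence hit on
#' either haplotype. When the haplotype sequences are supplied, an
#' identity profile of the two nearest repeat copies against the fused
#' junction region is attached to each candidate.
#'
#' @param blocks list of `ColinearBlock` (refined or coarse).
#' @param indels data.frame of indel events (from [refine_block()]).
#' @param repeat_hits data.frame from [find_duplicated_intergenic()].
#' @param flank distance threshold (bases).
#' @param min_indel minimum indel size treated as a breakpoint.
#' @param hap_a,hap_b the `haplotype` labels in `repeat_hits` that
#'   correspond to sequence A and B coordinates.
#' @param seq_a,seq_b optional haplotype strings for profile evidence.
#' @return list of candidate events, each with `type`, `pos_a`, `pos_b`,
#'   `hits` (nearby repeat occurrences) and optional `profile`.
#' @export
scan_intergenic_recombination <- function(blocks, indels, repeat_hits,
                                          flank = 2000, min_indel = 5000,
                                          hap_a = "A", hap_b = "B",
                                          seq_a = NULL, seq_b = NULL) {
  cand <- list()
  bp <- data.frame(type = character(), pos_a = integer(), pos_b = integer())
  if (length(blocks) > 1) {
    for (i in seq_len(length(blocks) - 1)) {
      bp <- rbind(bp, data.frame(
        type = "block_boundary",
        pos_a = as.integer(round((blocks[[i]]$range_a[2] +
                                  blocks[[i + 1]]$range_a[1]) / 2)),
        pos_b = as.integer(round((blocks[[i]]$range_b[2] +
                                  blocks[[i + 1]]$range_b[1]) / 2))))
    }
  }
  if (!is.null(indels) && nrow(indels)) {
    # nearby indel fragments are one event: a large deletion spanning
    # paralogous sequence is often split across bridging alignments
    ind <- indels[order(indels$pos_a), , drop = FALSE]
    end_a <- ind$pos_a + ifelse(ind$carrier == "A", ind$length, 0L)
    run_end <- cummax(end_a)
    grp <- cumsum(c(1, ind$pos_a[-1] - run_end[-nrow(ind)] > 2000))
    for (g in unique(grp)) {
      sub <- ind[grp == g, , drop = FALSE]
      if (sum(sub$length) < min_indel) next
      lead <- sub[which.max(sub$length), ]
      bp <- rbind(bp, data.frame(type = "large_indel",
                                 pos_a = lead$pos_a, pos_b = lead$pos_b))
    }
  }
  for (i in seq_len(nrow(bp))) {
    ref_pos <- ifelse(repeat_hits$haplotype == hap_a, bp$pos_a[i],
                      bp$pos_b[i])
    near <- repeat_hits[
      abs((repeat_hits$start + repeat_hits$end) / 2 - ref_pos) <=
        flank + (repeat_hits$end - repeat_hits$start) / 2, , drop = FALSE]
    if (!nrow(near)) next
    ev <- list(type = bp$type[i], pos_a = bp$pos_a[i], pos_b = bp$pos_b[i],
               hits = near, profile = NULL)
    if (!is.null(seq_a) && !is.null(seq_b) && nrow(near) >= 2) {
      # profile the two nearest copies against the fused junction region
      # on the haplotype that lacks the segment (B in this convention)
      copies <- near[order(abs((near$start + near$end) / 2 -
                                 ifelse(near$haplotype == hap_a,
                                        bp$pos_a[i], bp$pos_b[i]))), ]
      copies <- head(copies, 2)
      getseq <- function(hit) {
        src <- if (hit$haplotype == hap_a) seq_a else seq_b
        src <- if (is.character(src)) src else src$residues
        s <- substr(src, hit$start + 1, hit$end)
        if (hit$strand == "-") dna_revcomp(s) else s
      }
      parents <- list(copy1 = getseq(copies[1, ]), copy2 = getseq(copies[2, ]))
      carrier <- if (is.character(seq_b)) seq_b else seq_b$residues
      w0 <- max(0, bp$pos_b[i] - 1500)
      w1 <- min(nchar(carrier), bp$pos_b[i] + 1500)
      fused <- substr(carrier, w0 + 1, w1)
      ev$profile <- tryCatch(identity_profile(fused, parents),
                             error = function(e) NULL)
    }
    cand[[length(cand) + 1]] <- ev
  }
  cand
}
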