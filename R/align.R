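# Pairwise global alignment wrapper around the compiled banded
# Needleman-Wunsch/Gotoh kernel. Default scores are tuned for ~99%-identity
# haplotype comparisons: match +1, mismatch -2, gap open -6, gap extend -1
# (a gap of length L costs 6 + L).

#' Global pairwise alignment with affine gaps
#'
#' Banded global alignment of two DNA strings. When the optimal path
#' touches the band boundary the band is doubled and the alignment is
#' recomputed, so the result is never silently truncated; with
#' `band = NULL` the full dynamic-programming matrix is used.
#'
#' @param a,b character scalars (DNA, uppercase).
#' @param match,mismatch,gap_open,gap_ext scoring parameters (costs given
#'   as positive `gap_open`/`gap_ext`; a gap of length L costs
#'   `gap_open + L * gap_ext`).
#' @param band integer half-width of the diagonal band beyond the
#'   corner-to-corner drift; `NULL` (default) starts at
#'   `abs(nchar(a) - nchar(b)) + 128` and doubles whenever the optimal
#'   path touches the band edge, so the reported alignment never
#'   reflects a truncated search.
#' @return list with `score`, `aligned_a`, `aligned_b` (gapped strings of
#'   equal length) and `band` actually used.
#' @export
align_global <- function(a, b, match = 1L, mismatch = -2L,
                         gap_open = 6L, gap_ext = 1L, band = NULL) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  full <- max(nchar(a), nchar(b)) + 1L
  if (is.null(band)) band <- 128L
  band <- as.integer(min(band, full))
  na <- nchar(a); nb <- nchar(b)
  repeat {
    # the diagonal band spans the corner-to-corner drift plus the band on
    # each side; for drift-dominated problems (one big indel) the full
    # rectangular DP is smaller, so use it instead
    band_cells <- (max(na, nb) + 1) * (abs(na - nb) + 2 * band + 1)
    rect_cells <- (na + 1) * (nb + 1)
    if (band_cells > 4e7 && rect_cells < band_cells) {
      res <- biostrings_global(a, b, match, mismatch, gap_open, gap_ext)
      res$band_hit <- FALSE
      band <- full
      break
    }
    res <- align_global_cpp(a, b, as.integer(match), as.integer(mismatch),
                            as.integer(gap_open), as.integer(gap_ext), band)
    if (!res$band_hit || band >= full) break
    band <- as.integer(min(band * 2L, full))
  }
  list(score = res$score, aligned_a = res$aligned_a,
       aligned_b = res$aligned_b, band = band)
}

# full-DP global alignment through Biostrings, same scoring convention
biostrings_global <- function(a, b, match, mismatch, gap_open, gap_ext) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE),
    gapOpening = gap_open, gapExtension = gap_ext)
  list(score = as.integer(round(Biostrings::score(pa))),
       aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)))
}

#' Identity and differences of a gapped alignment
#'
#' Identity is computed over aligned non-gap columns; gap runs are
#' reported separately as indels (see [refine_block()]).
#'
#' @param aligned_a,aligned_b equal-length gapped strings.
#' @return list with `matches`, `mismatches`, `aligned_columns` (non-gap),
#'   `identity`, and `gap_columns`.
#' @export
alignment_stats <- function(aligned_a, aligned_b) {
  ca <- chars(aligned_a); cb <- chars(aligned_b)
  stopifnot(length(ca) == length(cb))
  gap <- ca == "-" | cb == "-"
  amb <- !gap & (!(ca %in% c("A", "C", "G", "T")) | !(cb %in% c("A", "C", "G", "T")))
  ok <- !gap & !amb
  m <- sum(ok & ca == cb)
  mm <- sum(ok & ca != cb)
  list(matches = m, mismatches = mm, aligned_columns = m + mm,
       identity = if (m + mm > 0) m / (m + mm) else NA_real_,
       gap_columns = sum(gap))
}
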