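# Small shared helpers: DNA string utilities and interval arithmetic.
# Sequences are plain uppercase character scalars throughout the package;
# Biostrings objects are created only at alignment/translation boundaries.

IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Reverse complement of a DNA string
#'
#' @param x character scalar of IUPAC nucleotide codes.
#' @return character scalar.
#' @export
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a CDS to protein
#'
#' Trailing incomplete codons are dropped. Codons containing N or other
#' ambiguity codes translate to `X`.
#'
#' @param cds character scalar, coding sequence on the coding strand.
#' @return character scalar amino-acid sequence (stop as `*`).
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# random DNA of length n at a given GC fraction
random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# canonical SSR motif: lexicographically minimal rotation over both strands
canonical_motif <- function(motif) {
  rots <- function(m) {
    k <- nchar(m)
    vapply(seq_len(k), function(i)
      paste0(substr(m, i, k), substr(m, 1, i - 1)), character(1))
  }
  min(c(rots(motif), rots(dna_revcomp(motif))))
}

# validate that a DNA string uses only IUPAC codes; returns uppercase string
check_iupac <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- regmatches(x, regexpr(sprintf("[^%s]", paste(IUPAC_CODES, collapse = "")), x))
  if (length(bad) && nzchar(bad))
    stop(sprintf("illegal character '%s' in %s", bad, what), call. = FALSE)
  x
}

# 0-based half-open interval container as a 2-column matrix [start, end)
as_ranges <- function(starts, ends) {
  m <- cbind(start = as.integer(starts), end = as.integer(ends))
  if (any(m[, "end"] < m[, "start"]))
    stop("interval end < start", call. = FALSE)
  m
}

ranges_width <- function(r) sum(r[, "end"] - r[, "start"])

# is position p (0-based) inside any interval of r?
in_ranges <- function(p, r) {
  if (is.null(r) || nrow(r) == 0) return(rep(FALSE, length(p)))
  out <- rep(FALSE, length(p))
  for (i in seq_len(nrow(r)))
    out <- out | (p >= r[i, 1] & p < r[i, 2])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
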