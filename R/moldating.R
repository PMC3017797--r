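# Synonymous-site counting and molecular dating.
#
# Two clocks are implemented:
#   * coding divergence:  T = pS / (2 r),  pS = Sd / S from Nei-Gojobori
#     (1986) pathway counting, r = synonymous substitutions/site/year
#     (default 4.5e-9 for banana coding sequences);
#   * LTR insertion age:  T = K / (2 r),  K = Kimura 2-parameter distance
#     between the element's two LTRs, r = 9e-9 /site/year (noncoding,
#     2x the coding rate).

.codon_cache <- new.env(parent = emptyenv())

genetic_code_table <- function() {
  if (is.null(.codon_cache$gc)) .codon_cache$gc <- Biostrings::GENETIC_CODE
  .codon_cache$gc
}

codon_aa <- function(codon) {
  gc <- genetic_code_table()
  unname(gc[codon])
}

is_stop <- function(codon) identical(unname(genetic_code_table()[codon]), "*")

# fraction of synonymous sites in one codon: for each position, the number
# of the 3 one-step changes that preserve the amino acid, divided by 3.
# Changes creating stop codons count as nonsynonymous; stop codons have
# no defined sites and return NA.
codon_syn_sites <- function(codon) {
  key <- paste0("S_", codon)
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  gc <- genetic_code_table()
  aa <- gc[codon]
  if (is.na(aa) || aa == "*") { .codon_cache[[key]] <- NA_real_; return(NA_real_) }
  b <- chars(codon)
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      mut <- b; mut[pos] <- nt
      maa <- gc[paste(mut, collapse = "")]
      if (!is.na(maa) && maa == aa) s <- s + 1 / 3
    }
  }
  .codon_cache[[key]] <- s
  s
}

#' Build a codon alignment from two aligned coding sequences
#'
#' @param cds_a,cds_b equal-length aligned CDS strings (gaps allowed,
#'   length a multiple of 3).
#' @return object of class `CodonAlignment`: paired codon vectors and
#'   `usable_codons`, the number of codon pairs free of gaps, ambiguity
#'   codes and stop codons.
#' @export
codon_alignment <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("aligned CDS lengths differ", call. = FALSE)
  if (nchar(cds_a) %% 3 != 0)
    stop("aligned CDS length not a multiple of 3", call. = FALSE)
  n <- nchar(cds_a) / 3
  starts <- 3 * (seq_len(n) - 1) + 1
  ca <- substring(cds_a, starts, starts + 2)
  cb <- substring(cds_b, starts, starts + 2)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  clean <- clean & !vapply(ca, is_stop, TRUE) & !vapply(cb, is_stop, TRUE)
  structure(list(codons_a = ca, codons_b = cb, usable = clean,
                 usable_codons = sum(clean)),
            class = "CodonAlignment")
}

# Sd/Nd for one codon pair, averaged over all d! substitution pathways;
# pathways passing through a stop codon are excluded and the remainder
# re-weighted equally (if every pathway hits a stop, all are used).
codon_pair_diffs <- function(ca, cb) {
  diff_pos <- which(chars(ca) != chars(cb))
  d <- length(diff_pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  gc <- genetic_code_table()
  perms <- if (d == 1) list(diff_pos) else {
    idx <- list()
    gen <- function(rem, acc) {
      if (!length(rem)) { idx[[length(idx) + 1]] <<- acc; return() }
      for (i in seq_along(rem)) gen(rem[-i], c(acc, rem[i]))
    }
    gen(diff_pos, integer()); idx
  }
  tallies <- lapply(perms, function(ord) {
    cur <- chars(ca); tb <- chars(cb)
    sd <- 0; nd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- tb[pos]
      aa1 <- gc[paste(cur, collapse = "")]
      aa2 <- gc[paste(nxt, collapse = "")]
      if (is.na(aa2) || aa2 == "*") { ok <- FALSE; break }
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, ok = as.numeric(ok))
  })
  tl <- do.call(rbind, tallies)
  valid <- tl[, "ok"] == 1
  if (!any(valid)) valid <- rep(TRUE, nrow(tl))  # all pathways hit a stop
  c(sd = mean(tl[valid, "sd"]), nd = mean(tl[valid, "nd"]))
}

#' Nei-Gojobori synonymous/nonsynonymous counting
#'
#' Counts synonymous (S) and nonsynonymous (N) sites, averaged between
#' the two sequences, and synonymous (Sd) and nonsynonymous (Nd)
#' differences with multi-hit codons averaged over all substitution
#' pathways (pathways through stop codons excluded). Codon pairs with
#' gaps, ambiguity codes or stop codons are skipped.
#'
#' @param alignment a [codon_alignment()], or a CDS string (aligned to
#'   `cds_b`) when `cds_b` is given.
#' @param cds_b optional second aligned CDS string.
#' @return object of class `SynonymyCount` with fields `S`, `N`, `Sd`,
#'   `Nd` and `usable_codons`; `S + N == 3 * usable_codons`.
#' @export
nei_gojobori <- function(alignment, cds_b = NULL) {
  if (!inherits(alignment, "CodonAlignment"))
    alignment <- codon_alignment(alignment, cds_b)
  ca <- alignment$codons_a[alignment$usable]
  cb <- alignment$codons_b[alignment$usable]
  ssv <- syn_sites_vector()
  S <- sum((ssv[ca] + ssv[cb]) / 2)
  Sd <- 0; Nd <- 0
  for (i in which(ca != cb)) {
    key <- paste0("D_", ca[i], cb[i])
    dd <- .codon_cache[[key]]
    if (is.null(dd)) {
      dd <- codon_pair_diffs(ca[i], cb[i])
      .codon_cache[[key]] <- dd
    }
    Sd <- Sd + dd["sd"]; Nd <- Nd + dd["nd"]
  }
  n <- length(ca)
  structure(list(S = S, N = 3 * n - S, Sd = unname(Sd), Nd = unname(Nd),
                 usable_codons = n),
            class = "SynonymyCount")
}

#' @export
print.SynonymyCount <- function(x, ...) {
  cat(sprintf("<SynonymyCount: %d codons, S=%.2f N=%.2f Sd=%.2f Nd=%.2f>\n",
              x$usable_codons, x$S, x$N, x$Sd, x$Nd))
  invisible(x)
}

#' Synonymous and nonsynonymous p-distances
#'
#' @param count a `SynonymyCount` from [nei_gojobori()].
#' @param jukes_cantor apply the Jukes-Cantor multiple-hit correction
#'   (default `FALSE`: the raw proportion is reported).
#' @return list with `p_s = Sd/S`, `p_n = Nd/N` and `valid`.
#' @export
p_distance <- function(count, jukes_cantor = FALSE) {
  if (count$S <= 0) stop("no synonymous sites: p-distance undefined",
                         call. = FALSE)
  p_s <- count$Sd / count$S
  p_n <- if (count$N > 0) count$Nd / count$N else NA_real_
  if (jukes_cantor) {
    jc <- function(p) {
      if (is.na(p)) return(NA_real_)
      if (p >= 0.75) stop("p-distance saturated for Jukes-Cantor correction",
                          call. = FALSE)
      -3 / 4 * log(1 - 4 * p / 3)
    }
    p_s <- jc(p_s); p_n <- jc(p_n)
  }
  list(p_s = p_s, p_n = p_n, valid = TRUE)
}

#' Kimura 2-parameter distance
#'
#' K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q) with P and Q the transition
#' and transversion proportions over columns where both sequences have an
#' unambiguous base.
#'
#' @param aligned_a,aligned_b equal-length aligned strings.
#' @return list with `k2p`, `P`, `Q`, `eligible_columns` and `valid`.
#'   Saturated alignments (either logarithm argument non-positive) raise
#'   an error.
#' @export
k2p <- function(aligned_a, aligned_b) {
  ca <- chars(aligned_a); cb <- chars(aligned_b)
  if (length(ca) != length(cb)) stop("aligned lengths differ", call. = FALSE)
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0) stop("no eligible columns for K2P", call. = FALSE)
  pur <- c("A", "G")
  diff <- ok & ca != cb
  ts <- sum(diff & ((ca %in% pur) == (cb %in% pur)))
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    stop("K2P saturation: substitution fractions too high (P=",
         signif(P, 3), ", Q=", signif(Q, 3), ")", call. = FALSE)
  list(k2p = -0.5 * log(a1) - 0.25 * log(a2), P = P, Q = Q,
       eligible_columns = n, valid = TRUE)
}

#' Date haplotype divergence from a synonymous p-distance
#'
#' T = pS / (2 r), reported in million years.
#'
#' @param p_s synonymous p-distance (proportion).
#' @param rate synonymous substitution rate per site per year
#'   (default 4.5e-9, the banana coding-sequence rate).
#' @return object of class `DatingResult` with `T_my`, `rate`, `method`.
#' @export
date_divergence <- function(p_s, rate = 4.5e-9) {
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (p_s < 0) stop("p_s must be nonnegative", call. = FALSE)
  structure(list(T_my = p_s / (2 * rate) / 1e6, rate = rate,
                 method = "coding_pS"),
            class = "DatingResult")
}

#' Date an LTR retroelement insertion from its LTR divergence
#'
#' T = K / (2 r) in million years, with K the Kimura 2-parameter distance
#' between the element's 5' and 3' LTRs, which were identical at
#' insertion time.
#'
#' @param k2p_value K2P distance (substitutions/site) or the list
#'   returned by [k2p()].
#' @param rate substitution rate per site per year (default 9e-9,
#'   noncoding, twice the coding rate).
#' @return object of class `DatingResult` with `method = "ltr_K2P"`.
#' @export
date_insertion <- function(k2p_value, rate = 9e-9) {
  if (is.list(k2p_value)) {
    if (!isTRUE(k2p_value$valid)) stop("invalid K2P estimate", call. = FALSE)
    k2p_value <- k2p_value$k2p
  }
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (is.na(k2p_value) || k2p_value < 0)
    stop("invalid K for insertion dating", call. = FALSE)
  structure(list(T_my = k2p_value / (2 * rate) / 1e6, rate = rate,
                 method = "ltr_K2P"),
            class = "DatingResult")
}

#' @export
print.DatingResult <- function(x, ...) {
  cat(sprintf("<DatingResult %s: T = %.3f MY at r = %g /site/yr>\n",
              x$method, x$T_my, x$rate))
  invisible(x)
}

#' Per-pair and concatenated dating table for allelic CDS pairs
#'
#' Mirrors a divergence-time supplementary table: one row per allelic
#' pair with length, S, N, Sd, Nd, pS and T, plus a `concatenated` row
#' computed on the pooled alignment (the headline estimate).
#'
#' @param pairs list of two-element lists/character vectors, each holding
#'   an aligned CDS pair (equal lengths, multiple of 3), named by pair.
#' @param rate synonymous substitution rate (default 4.5e-9).
#' @return data.frame with columns `gene_pair`, `length`, `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `T_my`.
#' @export
dating_table <- function(pairs, rate = 4.5e-9) {
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    ng <- nei_gojobori(p[[1]], p[[2]])
    ps <- if (ng$S > 0) ng$Sd / ng$S else NA_real_
    data.frame(gene_pair = nm, length = nchar(p[[1]]), S = ng$S, N = ng$N,
               Sd = ng$Sd, Nd = ng$Nd, pS = ps,
               T_my = if (is.na(ps)) NA_real_ else date_divergence(ps, rate)$T_my)
  })
  cat_a <- paste(vapply(pairs, function(p) p[[1]], character(1)), collapse = "")
  cat_b <- paste(vapply(pairs, function(p) p[[2]], character(1)), collapse = "")
  ngc <- nei_gojobori(cat_a, cat_b)
  psc <- ngc$Sd / ngc$S
  rows[[length(rows) + 1]] <- data.frame(
    gene_pair = "concatenated", length = nchar(cat_a), S = ngc$S, N = ngc$N,
    Sd = ngc$Sd, Nd = ngc$Nd, pS = psc,
    T_my = date_divergence(psc, rate)$T_my)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
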