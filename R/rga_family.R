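# NB-LRR (RGA) gene family analysis: completeness classification,
# pairwise identity, allelic pairing, clade clustering, domain
# annotation and coding microsatellites.

#' Classify a gene model by completeness
#'
#' Rules evaluated most-degraded-first:
#' \itemize{
#'   \item remnant: Qcov < 0.3, or more than three alignment fragments
#'     with Qcov < 0.5, or more than two expression-preventing
#'     disruptions;
#'   \item pseudogene: at least one disruption (missing start/stop,
#'     non-canonical splice, frameshift, in-frame stop, TE insertion);
#'   \item fragment: Qcov < 0.8;
#'   \item complete: canonical CDS with Qcov >= 0.8 and Scov >= 0.8.
#' }
#'
#' @param model a [gene_model()] (its `disruptions` are used).
#' @param evidence optional list/row with `q_cov`, `s_cov`,
#'   `n_fragments`; defaults to the model's own coverage fields with one
#'   fragment. Without any coverage evidence the gene is classified on
#'   disruptions alone, with a warning.
#' @return list of class `GeneClass` with `label` and optional
#'   `sublabel` (`N_terminal`/`C_terminal`, taken from evidence
#'   `terminus` when present).
#' @export
classify_gene <- function(model, evidence = NULL) {
  q <- evidence$q_cov %||% model$q_cov
  s <- evidence$s_cov %||% model$s_cov
  nf <- evidence$n_fragments %||% 1L
  dis <- length(model$disruptions)
  if (is.null(q) || is.na(q)) {
    warning("no similarity evidence for ", model$id,
            ": classifying on disruptions alone")
    label <- if (dis > 2) "remnant" else if (dis >= 1) "pseudogene"
             else "complete"
    return(structure(list(label = label, sublabel = NULL),
                     class = "GeneClass"))
  }
  label <-
    if (q < 0.3 || (nf > 3 && q < 0.5) || dis > 2) "remnant"
    else if (dis >= 1) "pseudogene"
    else if (q < 0.8) "fragment"
    else if (q >= 0.8 && (is.na(s) || s >= 0.8)) "complete"
    else "fragment"
  structure(list(label = label, sublabel = evidence$terminus %||% NULL),
            class = "GeneClass")
}

#' Pairwise identity matrix of a CDS set
#'
#' Global alignment with affine gaps for every pair; identity over
#' aligned non-gap columns.
#'
#' @param cds_list named list/character vector of CDS strings (>= 2).
#' @return symmetric numeric matrix with unit diagonal.
#' @export
pairwise_identity_matrix <- function(cds_list) {
  cds_list <- as.list(cds_list)
  n <- length(cds_list)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  if (any(!nzchar(unlist(cds_list)))) stop("empty sequence", call. = FALSE)
  ids <- names(cds_list) %||% paste0("seq", seq_len(n))
  m <- diag(1, n); dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- align_global(cds_list[[i]], cds_list[[j]])
      m[i, j] <- m[j, i] <- alignment_stats(al$aligned_a, al$aligned_b)$identity
    }
  }
  m
}

#' Assign allelic pairs across haplotypes by reciprocal best identity
#'
#' Genes are paired when each is the other's best cross-haplotype match
#' at identity >= `min_identity`. When a gene's best and second-best
#' cross-haplotype identities differ by at most `tie_margin`, the genes
#' involved are flagged ambiguous rather than paired (the signature of a
#' recent within-haplotype duplication). Remaining genes are reported as
#' haplotype-specific paralogs.
#'
#' @param matrix identity matrix from [pairwise_identity_matrix()].
#' @param haplotype_of_gene named character vector (`"A"`/`"B"`) keyed
#'   by gene id.
#' @param min_identity minimum identity for an allelic pair.
#' @param tie_margin near-tie window for the ambiguity flag.
#' @return list of class `AllelicPairing`: `pairs` (data.frame gene_a,
#'   gene_b, identity), `ambiguous` (list of character vectors of gene
#'   ids), `unpaired` (character vector).
#' @export
assign_alleles <- function(matrix, haplotype_of_gene, min_identity = 0.90,
                           tie_margin = 0.01) {
  ids <- rownames(matrix)
  hap <- haplotype_of_gene[ids]
  stopifnot(!any(is.na(hap)))
  cross_best <- function(g, exclude = character()) {
    others <- ids[hap != hap[g] & !(ids %in% exclude)]
    if (!length(others)) return(NULL)
    v <- matrix[g, others]
    ord <- order(v, decreasing = TRUE)
    list(best = others[ord[1]], best_id = v[ord[1]],
         second_id = if (length(v) > 1) v[ord[2]] else -Inf)
  }
  pairs <- list(); ambiguous <- list(); flagged <- character()
  for (g in ids) {
    cb <- cross_best(g)
    if (is.null(cb) || cb$best_id < min_identity) next
    # near-tie between best and second-best cross-haplotype partner:
    # the gene cannot be assigned an allele; its tied partners are
    # reported with it but remain eligible for their own pairings
    if (cb$best_id - cb$second_id <= tie_margin &&
        is.finite(cb$second_id) && cb$second_id >= min_identity) {
      others <- ids[hap != hap[g]]
      v <- matrix[g, others]
      tied <- others[v >= cb$best_id - tie_margin]
      ambiguous[[length(ambiguous) + 1]] <- sort(c(g, tied))
      flagged <- union(flagged, g)
    }
  }
  ambiguous <- unique(ambiguous)
  for (g in ids) {
    if (g %in% flagged) next
    cb <- cross_best(g, exclude = flagged)
    if (is.null(cb) || cb$best_id < min_identity) next
    partner <- cb$best
    cbp <- cross_best(partner, exclude = flagged)
    if (!is.null(cbp) && identical(cbp$best, g) && hap[g] == "A") {
      pairs[[length(pairs) + 1]] <- data.frame(
        gene_a = g, gene_b = partner, identity = unname(cb$best_id))
    }
  }
  pairdf <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(), gene_b = character(),
               identity = numeric())
  paired <- c(pairdf$gene_a, pairdf$gene_b)
  structure(list(pairs = pairdf, ambiguous = ambiguous,
                 unpaired = setdiff(ids, c(paired, flagged))),
            class = "AllelicPairing")
}

#' Cluster the gene family into clades
#'
#' Average-linkage hierarchical clustering on distance = 1 - identity,
#' cut at `1 - cut_identity`. Clade labels are deterministic: clades are
#' numbered by their smallest member position in the matrix row order.
#'
#' @param matrix identity matrix.
#' @param cut_identity identity level separating clades (default 0.80,
#'   between typical inter-clade ~70% and intra-clade >90% identities).
#' @param linkage hclust agglomeration method.
#' @return named integer vector of clade labels.
#' @export
cluster_clades <- function(matrix, cut_identity = 0.80,
                           linkage = "average") {
  d <- as.dist(1 - matrix)
  hc <- hclust(d, method = linkage)
  raw <- cutree(hc, h = 1 - cut_identity)
  # relabel clades by their smallest member position in matrix row order
  lev <- unique(raw)
  firsts <- vapply(lev, function(k) min(which(raw == k)), 0L)
  newlab <- order(order(firsts))
  out <- newlab[match(raw, lev)]
  names(out) <- names(raw)
  out
}

# default NB-ARC motif seed patterns (regular expressions on the protein),
# in their canonical N- to C-terminal order; users may override
default_nbarc_patterns <- function() {
  c("P-loop"  = "GG[AVSL]GKTT",
    "RNBS-A"  = "F[DN][LIVMC][KRQ]\\w{1,3}W",
    "kinase-2" = "[KR]\\w[LIVMF][LIVMF][LIVMF][LIVMF]DD[LIVM][WD]",
    "RNBS-B"  = "[GS][SN][KR][LIVM][LIVM][LIVM]TTR",
    "RNBS-C"  = "[LIVM]\\w{2}[LIVM]\\wP[DE]\\w{2}[SA]W",
    "GLPL"    = "G[LG]PL[AG]",
    "RNBS-D"  = "[FLC][LIVM]\\wC\\w{2}[FY]P",
    "MHD"     = "[LIVM]\\wHD[LIVM]{2}")
}

#' Annotate NB-LRR domain structure of a protein
#'
#' Locates the NB-ARC motifs (P-loop, RNBS-A, kinase-2, RNBS-B, RNBS-C,
#' GLPL, RNBS-D, MHD) by ordered best match of configurable seed
#' patterns, and calls LRR repeats by scanning for the consensus
#' `LxxLxxLxxLxLxx(N/C/T)x(x)LxxIPxx` (L = aliphatic residue
#' L/I/V/M/F, one optional extra x). Each candidate repeat is scored as
#' the fraction of constrained positions satisfied and accepted at
#' `min_score`. The x positions of the `LxxLxLxx` core are reported as
#' solvent-exposed positions.
#'
#' @param protein amino-acid string (translated CDS; annotation stops at
#'   the first internal stop, with a warning).
#' @param motif_patterns named character vector of NB-ARC regexes (in
#'   order); defaults to [default_nbarc_patterns()].
#' @param min_score LRR acceptance score (default 0.7; the consensus is
#'   a manual-curation guide, so a tolerance is required).
#' @return list of class `NBLRRAnnotation`: `nbarc_motifs` (data.frame
#'   motif, start, end; 0-based half-open protein coordinates, only
#'   motifs found), `lrr_repeats` (data.frame start, end, score),
#'   `exposed_positions` (0-based protein positions), `n_lrr`.
#' @export
annotate_nblrr <- function(protein, motif_patterns = NULL,
                           min_score = 0.7) {
  if (is.null(motif_patterns)) motif_patterns <- default_nbarc_patterns()
  stop_at <- regexpr("*", protein, fixed = TRUE)
  if (stop_at > 0 && stop_at < nchar(protein)) {
    warning("internal stop codon: annotating up to first stop")
    protein <- substr(protein, 1, stop_at - 1)
  }
  protein <- sub("\\*$", "", protein)
  if (nchar(protein) < 50) {
    warning("sequence shorter than minimal domain span")
    return(structure(list(
      nbarc_motifs = data.frame(motif = character(), start = integer(),
                                end = integer()),
      lrr_repeats = data.frame(start = integer(), end = integer(),
                               score = numeric()),
      exposed_positions = integer(), n_lrr = 0L),
      class = "NBLRRAnnotation"))
  }
  # ordered motif search: each motif sought downstream of the previous
  motifs <- data.frame(motif = character(), start = integer(),
                       end = integer())
  from <- 1
  for (nm in names(motif_patterns)) {
    m <- regexpr(motif_patterns[[nm]], substr(protein, from, nchar(protein)),
                 perl = TRUE)
    if (m > 0) {
      st <- from + m - 1
      motifs <- rbind(motifs, data.frame(
        motif = nm, start = st - 1L,
        end = st - 1L + attr(m, "match.length")))
      from <- st + attr(m, "match.length")
    }
  }
  lrr <- scan_lrr(protein, min_score)
  exposed <- integer()
  for (i in seq_len(nrow(lrr$repeats))) {
    # LxxLxLxx core occupies unit positions 7..14; x at 8,9,11,13,14
    exposed <- c(exposed, lrr$repeats$start[i] + c(7L, 8L, 10L, 12L, 13L))
  }
  structure(list(nbarc_motifs = motifs, lrr_repeats = lrr$repeats,
                 exposed_positions = exposed, n_lrr = nrow(lrr$repeats)),
            class = "NBLRRAnnotation")
}

# score every start position against the 23/24-residue LRR consensus and
# greedily accept non-overlapping repeats left to right
scan_lrr <- function(protein, min_score) {
  aa <- chars(protein)
  n <- length(aa)
  aliph <- c("L", "I", "V", "M", "F")
  nct <- c("N", "C", "T")
  unit_score <- function(start, extra) {
    # positions within the unit (1-based): constrained sites
    L_pos <- c(1, 4, 7, 10, 12)
    p15 <- 15
    tail_L <- if (extra) 18 else 17
    tail_I <- if (extra) 21 else 20
    tail_P <- if (extra) 22 else 21
    len <- if (extra) 24 else 23
    if (start + len - 1 > n) return(NA_real_)
    w <- aa[start:(start + len - 1)]
    checks <- c(w[L_pos] %in% aliph, w[p15] %in% nct,
                w[tail_L] %in% aliph, w[tail_I] %in% aliph,
                w[tail_P] == "P")
    mean(checks)
  }
  reps <- data.frame(start = integer(), end = integer(), score = numeric())
  i <- 1
  while (i <= n - 22) {
    s23 <- unit_score(i, FALSE); s24 <- unit_score(i, TRUE)
    s23 <- if (is.na(s23)) -1 else s23
    s24 <- if (is.na(s24)) -1 else s24
    if (max(s23, s24) >= min_score) {
      len <- if (s24 > s23) 24L else 23L
      reps <- rbind(reps, data.frame(start = i - 1L, end = i - 1L + len,
                                     score = max(s23, s24)))
      i <- i + len
    } else i <- i + 1
  }
  list(repeats = reps)
}

#' Detect coding microsatellites in a CDS
#'
#' Scans an in-frame CDS for trinucleotide repeats, reports the encoded
#' amino-acid tract, and merges adjacent same-frame units into compound
#' reports (e.g. `(GAT)n(GCT)n(GAA)n`).
#'
#' @param cds_text in-frame CDS string.
#' @param min_repeats minimum unit count (default 3; coding tracts as
#'   short as three residues are biologically meaningful).
#' @return list with `loci` (data.frame motif, start, end, repeat_count,
#'   frame, aa, tract) and `compound` (data.frame start, end, motifs,
#'   tract for merged runs of >= 2 adjacent loci).
#' @export
detect_coding_ssr <- function(cds_text, min_repeats = 3) {
  n <- nchar(cds_text)
  m <- gregexpr(sprintf("([ACGT]{3})\\1{%d,}", min_repeats - 1), cds_text,
                perl = TRUE)[[1]]
  loci <- data.frame(motif = character(), start = integer(),
                     end = integer(), repeat_count = integer(),
                     frame = integer(), aa = character(),
                     tract = character())
  if (m[1] != -1) {
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      unit <- substr(cds_text, m[i], m[i] + 2)
      if (!is_primitive_unit(unit)) next
      start0 <- m[i] - 1L
      # snap to reading frame: shift so the repeated codon is in frame
      shift <- (3 - start0 %% 3) %% 3
      count <- (len[i] - shift) %/% 3
      if (count < min_repeats) next
      fstart <- start0 + shift
      codon <- substr(cds_text, fstart + 1, fstart + 3)
      aa <- codon_aa(codon)
      loci <- rbind(loci, data.frame(
        motif = codon, start = fstart, end = fstart + 3L * count,
        repeat_count = count, frame = 0L, aa = aa,
        tract = sprintf("%sx%d", aa, count)))
    }
  }
  compound <- data.frame(start = integer(), end = integer(),
                         motifs = character(), tract = character())
  if (nrow(loci) > 1) {
    loci <- loci[order(loci$start), , drop = FALSE]
    grp <- cumsum(c(1, loci$start[-1] != loci$end[-nrow(loci)]))
    for (g in unique(grp)) {
      sub <- loci[grp == g, , drop = FALSE]
      if (nrow(sub) < 2) next
      compound <- rbind(compound, data.frame(
        start = min(sub$start), end = max(sub$end),
        motifs = paste(sprintf("(%s)%d", sub$motif, sub$repeat_count),
                       collapse = ""),
        tract = paste(sub$tract, collapse = "-")))
    }
  }
  rownames(loci) <- NULL
  list(loci = loci, compound = compound)
}

#' Pairwise pN/pS for a codon alignment
#'
#' @param alignment a [codon_alignment()] or aligned CDS string (with
#'   `cds_b`).
#' @param cds_b optional second aligned CDS.
#' @return list with `p_n`, `p_s`, `ratio` (pN/pS; `NA` with
#'   `ratio_defined = FALSE` when pS = 0).
#' @export
pairwise_dnds <- function(alignment, cds_b = NULL) {
  ng <- nei_gojobori(alignment, cds_b)
  p_s <- if (ng$S > 0) ng$Sd / ng$S else NA_real_
  p_n <- if (ng$N > 0) ng$Nd / ng$N else NA_real_
  defined <- !is.na(p_s) && p_s > 0
  list(p_n = p_n, p_s = p_s,
       ratio = if (defined) p_n / p_s else NA_real_,
       ratio_defined = defined)
}
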