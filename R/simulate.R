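# Haplotype-pair simulator.
#
# Emulates the structure the comparative analysis assumes: one ancestral
# locus carrying conserved flanking genes, a central tandem array of
# NB-LRR (RGA) genes in two clades, interspersed MTERF fragments,
# duplicated ~1-kb intergenic repeats and perfect SSRs, descended into
# two haplotypes under a neutral clock (synonymous CDS rate 4.5e-9
# substitutions/site/yr, noncoding rate 9e-9/site/yr), with planted LTR
# retroelement insertions (paired LTRs + TSDs), SSR slippage, and
# intragenic/intergenic unequal-recombination events. Every planted
# event is recorded in a ground-truth table.

#' Simulation configuration
#'
#' Defaults describe the study conditions the analysis pipeline targets:
#' two haplotypes separated by 1 MY under the coding/noncoding rates
#' above, an RGA array with two clades (~70% inter-clade, ~94%
#' intra-clade identity), three dateable LTR insertions at 0.3, 1.2 and
#' 2.2 MY, slipped SSR loci, and one intragenic plus one intergenic
#' recombination event.
#'
#' @param seed RNG seed (integer).
#' @param ancestor_length approximate ancestor size in bases (intergenic
#'   spacers are sized to reach it).
#' @param n_rga number of RGA copies in the array (>= 0; the first two
#'   are clade 1 on the plus strand, the rest clade 2 on the minus
#'   strand).
#' @param n_lrr LRR units in the RGA template.
#' @param divergence_T haplotype divergence time in million years.
#' @param rate_coding synonymous substitutions/synonymous site/year.
#' @param rate_noncoding substitutions/site/year for noncoding DNA.
#' @param paralog_divergence per-copy substitution proportion separating
#'   paralogs within a clade (ancestral duplication age).
#' @param clade_divergence substitution proportion separating the two
#'   clade templates.
#' @param retro_events data.frame with columns `hap` ("A"/"B"), `age`
#'   (MY), `tsd` (TSD length 4-6), `ltr_len`, `internal_len`.
#' @param ssr_loci data.frame with columns `unit` (motif as planted),
#'   `count` (ancestral repeat count) and `delta` (slippage applied to
#'   haplotype B).
#' @param intergenic_repeat_copies number of extra copies of the 1-kb
#'   intergenic repeat inside the cluster (besides the reference copy
#'   upstream of the MTERF gene).
#' @param intragenic_recombination plant a chimeric RGA on haplotype B.
#' @param intergenic_recombination delete the region between two
#'   intergenic repeat copies on haplotype B (unequal crossover).
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              ancestor_length = 60000L,
                              n_rga = 8L,
                              n_lrr = 15L,
                              divergence_T = 1,
                              rate_coding = 4.5e-9,
                              rate_noncoding = 9e-9,
                              paralog_divergence = 0.06,
                              clade_divergence = 0.30,
                              retro_events = data.frame(
                                hap = c("A", "A", "B"),
                                age = c(0.3, 1.2, 2.2),
                                tsd = c(4L, 4L, 5L),
                                ltr_len = c(382L, 382L, 447L),
                                internal_len = c(800L, 800L, 700L)),
                              ssr_loci = data.frame(
                                unit = c("CT", "GA", "AT", "TAA", "CT",
                                         "GATA"),
                                count = c(12L, 10L, 9L, 8L, 12L, 5L),
                                delta = c(0L, 1L, -2L, 4L, 46L, 0L)),
                              intergenic_repeat_copies = 3L,
                              intragenic_recombination = TRUE,
                              intergenic_recombination = TRUE) {
  if (rate_coding <= 0 || rate_noncoding <= 0)
    stop("rates must be positive", call. = FALSE)
  if (divergence_T < 0) stop("divergence_T must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "SimulationConfig")
}

# ---- protein/CDS template machinery -----------------------------------

AA_ALIPHATIC <- c("L", "I", "V", "M", "F")
# filler alphabet avoids aliphatic and N/C/T so spurious LRR starts score low
AA_FILLER <- c("S", "E", "D", "K", "Q", "H", "Y", "N", "T", "A")

# codon choice weighted by the 40% GC background so coding and noncoding
# base composition match
reverse_translate <- function(protein) {
  gc <- genetic_code_table()
  base_p <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  picks <- vapply(chars(protein), function(aa) {
    cods <- names(gc)[gc == aa]
    w <- vapply(cods, function(cd) prod(base_p[chars(cd)]), 0)
    sample(cods, 1, prob = w)
  }, character(1))
  paste(picks, collapse = "")
}

random_aa <- function(n, alphabet = AA_FILLER) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# one LRR consensus unit (23 aa): LxxLxxLxxLxLxx(N/C/T)xLxxIPxx
lrr_unit <- function() {
  x <- function(n) chars(random_aa(n))
  L <- function() sample(AA_ALIPHATIC, 1)
  paste(c(L(), x(2), L(), x(2), L(), x(2), L(), x(1), L(), x(2),
          sample(c("N", "C", "T"), 1), x(1), L(), x(2), L(), "P", x(2)),
        collapse = "")
}

# NB-ARC motif literals matching default_nbarc_patterns(), in order
nbarc_literals <- function() {
  c("GGVGKTT", "FDLKAW", "KRLLVFDDVW", "GSKIIVTTR", "LHEVGPDESAW",
    "GLPLA", "FLYCKSFP", "MTHDLL")
}

# RGA template protein: CC filler, NB-ARC motifs, n_lrr LRR units
rga_template_protein <- function(n_lrr = 15) {
  nb <- nbarc_literals()
  paste0("M", random_aa(110),
         paste(vapply(nb, function(m) paste0(m, random_aa(28)),
                      character(1)), collapse = ""),
         paste(replicate(n_lrr, lrr_unit()), collapse = ""),
         random_aa(20))
}

# apply n random substitutions to a CDS without creating internal stops
# or touching the start/stop codons; transitions twice as likely as
# transversions
mutate_cds <- function(cds, n) {
  cc <- chars(cds)
  L <- length(cc)
  done <- 0; tries <- 0
  while (done < n && tries < 50 * n + 100) {
    tries <- tries + 1
    p <- sample(3:(L - 3), 1)           # spare start and stop codons
    new <- draw_substitution(cc[p])
    codon_i <- (p - 1) %/% 3
    cod <- cc[(codon_i * 3 + 1):(codon_i * 3 + 3)]
    cod[(p - 1) %% 3 + 1] <- new
    if (is_stop(paste(cod, collapse = ""))) next
    cc[p] <- new
    done <- done + 1
  }
  paste(cc, collapse = "")
}

# transition with probability 2/3, either transversion with 1/6
draw_substitution <- function(base) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tvs <- list(A = c("C", "T"), G = c("C", "T"),
              C = c("A", "G"), T = c("A", "G"))
  if (runif(1) < 2 / 3) ts[[base]] else sample(tvs[[base]], 1)
}

# per-codon synonymous one-step changes, computed once
codon_opp_cache <- function() {
  if (!is.null(.codon_cache$opp)) return(.codon_cache$opp)
  gc <- genetic_code_table()
  nts <- c("A", "C", "G", "T")
  opp <- list()
  for (cod in names(gc)) {
    if (gc[cod] == "*") next
    b <- chars(cod)
    off <- integer(); from <- character(); to <- character()
    for (p in 1:3) {
      for (nt in setdiff(nts, b[p])) {
        mut <- b; mut[p] <- nt
        if (identical(unname(gc[paste(mut, collapse = "")]),
                      unname(gc[cod]))) {
          off <- c(off, p - 1L); from <- c(from, b[p]); to <- c(to, nt)
        }
      }
    }
    opp[[cod]] <- list(off = off, from = from, to = to)
  }
  .codon_cache$opp <- opp
  opp
}

# numeric lookup of synonymous-site fractions for all sense codons
syn_sites_vector <- function() {
  if (!is.null(.codon_cache$ssv)) return(.codon_cache$ssv)
  gc <- genetic_code_table()
  v <- vapply(names(gc), codon_syn_sites, 0)
  .codon_cache$ssv <- v
  v
}

# all one-step synonymous substitution opportunities of a CDS:
# data.frame(pos [0-based within CDS], from, to)
synonymous_opportunities <- function(cds) {
  opp <- codon_opp_cache()
  n <- nchar(cds) %/% 3
  cods <- substring(cds, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
  ol <- opp[cods]
  lens <- vapply(ol, function(x) if (is.null(x)) 0L else length(x$off),
                 integer(1))
  if (sum(lens) == 0)
    return(data.frame(pos = integer(), from = character(),
                      to = character()))
  codon_idx <- rep(seq_len(n), lens)
  data.frame(
    pos = (codon_idx - 1L) * 3L +
      unlist(lapply(ol, `[[`, "off"), use.names = FALSE),
    from = unlist(lapply(ol, `[[`, "from"), use.names = FALSE),
    to = unlist(lapply(ol, `[[`, "to"), use.names = FALSE))
}

# ---- ancestor assembly ------------------------------------------------

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$parts <- character(); env$len <- 0L
  env$features <- list(); env$genes <- list()
  env
}

b_add_seq <- function(b, s) {
  b$parts[[length(b$parts) + 1]] <- s
  at <- b$len
  b$len <- b$len + nchar(s)
  at
}

b_add_gene <- function(b, id, cds, strand, kind = "gene",
                       attrs = character()) {
  genomic <- if (strand == "-") dna_revcomp(cds) else cds
  at <- b_add_seq(b, genomic)
  rng <- as_ranges(at, at + nchar(genomic))
  b$genes[[id]] <- gene_model(id, "locus", strand, rng, rng,
                              q_cov = 1, s_cov = 1)
  b$features[[length(b$features) + 1]] <- feature_table(
    id = id, kind = kind, seqid = "locus", start = at,
    end = at + nchar(genomic), strand = strand,
    attributes = list(c(attrs, cds_start = as.character(at),
                        cds_end = as.character(at + nchar(genomic)))))
  at
}

b_add_feature <- function(b, id, kind, s, strand = ".",
                          attrs = character()) {
  at <- b_add_seq(b, s)
  b$features[[length(b$features) + 1]] <- feature_table(
    id = id, kind = kind, seqid = "locus", start = at,
    end = at + nchar(s), strand = strand, attributes = list(attrs))
  at
}

#' Simulate the ancestral locus
#'
#' Builds one annotated ancestor: conserved flanking genes, a central
#' tandem RGA array (two clades; single-exon CDS from templates carrying
#' the NB-ARC motif seeds and the LRR consensus), interspersed MTERF
#' fragments, duplicated 1-kb intergenic repeats, planted perfect SSRs
#' and 40%-GC background intergenic sequence.
#'
#' @param config a [simulation_config()].
#' @return an [annotated_locus()]; simulation metadata (templates, SSR
#'   and insertion-site registries) is attached as attribute `meta`.
#' @export
simulate_ancestor <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  b <- new_builder()
  meta <- list()

  n_rga <- config$n_rga
  # fixed-size components; remaining length becomes intergenic spacers
  cds_flank <- 1200L; cds_mterf <- 1800L; igr_len <- 1000L
  rga_len <- 3L * (nchar(rga_template_protein(config$n_lrr)) + 1L)
  n_spacers <- 9L + max(n_rga, 1L)
  fixed <- 4L * cds_flank + cds_mterf + n_rga * rga_len +
    (config$intergenic_repeat_copies + 1L) * igr_len + 2L * 600L + 2000L
  spacer_len <- max(300L, as.integer((config$ancestor_length - fixed) /
                                       n_spacers))

  # clade templates: clade 2 derived from clade 1 by clade_divergence
  prot1 <- rga_template_protein(config$n_lrr)
  tmpl1 <- paste0(reverse_translate(prot1), "TAA")
  tmpl2 <- mutate_cds(tmpl1, round(nchar(tmpl1) * config$clade_divergence))
  # clade 2 coding microsatellites: polyserine tract between LRR 10 and
  # 11, compound (GAT)(GCT)(GAA) before the stop codon
  if (config$n_lrr >= 11) {
    lrr_start_aa <- 1 + 110 + sum(nchar(nbarc_literals())) + 8 * 28
    ins_aa <- lrr_start_aa + 10 * 23         # after LRR10
    ins_nt <- 3 * ins_aa
    tmpl2 <- paste0(substr(tmpl2, 1, ins_nt), strrep("TCT", 9),
                    substr(tmpl2, ins_nt + 1, nchar(tmpl2)))
  }
  tmpl2 <- paste0(substr(tmpl2, 1, nchar(tmpl2) - 3),
                  strrep("GAT", 4), strrep("GCT", 4), strrep("GAA", 6),
                  "TAA")
  meta$templates <- list(clade1 = tmpl1, clade2 = tmpl2)

  ssr_cfg <- config$ssr_loci
  ssr_i <- 0L
  meta$ssr <- data.frame(unit = character(), count = integer(),
                         delta = integer(), pos = integer())
  spacer <- function(with_ssr = FALSE) {
    s <- random_dna(spacer_len, gc = 0.4)
    if (with_ssr && ssr_i < nrow(ssr_cfg)) {
      ssr_i <<- ssr_i + 1L
      run <- strrep(ssr_cfg$unit[ssr_i], ssr_cfg$count[ssr_i])
      at <- spacer_len %/% 2
      s <- paste0(substr(s, 1, at), run, substr(s, at + 1, spacer_len))
      pos0 <- b$len + at
      meta$ssr <<- rbind(meta$ssr, data.frame(
        unit = ssr_cfg$unit[ssr_i], count = ssr_cfg$count[ssr_i],
        delta = ssr_cfg$delta[ssr_i], pos = pos0))
    }
    b_add_seq(b, s)
  }

  meta$retro_sites <- integer()
  retro_site <- function() {
    s <- random_dna(spacer_len, gc = 0.4)
    meta$retro_sites <<- c(meta$retro_sites, b$len + spacer_len %/% 2)
    b_add_seq(b, s)
  }

  probe <- random_dna(igr_len, gc = 0.4)
  meta$probe <- probe
  meta$igr_copies <- integer()
  igr_divs <- c(0.05, 0.15, 0.25, 0.10, 0.20)
  add_igr <- function(copy_idx) {
    s <- if (copy_idx == 0) probe else {
      cc <- chars(probe)
      nmut <- round(igr_len * igr_divs[((copy_idx - 1) %% length(igr_divs)) + 1])
      at <- sample(igr_len, nmut)
      cc[at] <- vapply(cc[at], draw_substitution, character(1))
      paste(cc, collapse = "")
    }
    pos <- b_add_feature(b, sprintf("igr%d", copy_idx), "intergenic_repeat",
                         s, attrs = c(copy = as.character(copy_idx)))
    meta$igr_copies <<- c(meta$igr_copies, pos)
  }

  flank_gene <- function(id) {
    prot <- paste0("M", random_aa(cds_flank / 3 - 2,
                                  c(AA_FILLER, AA_ALIPHATIC)))
    b_add_gene(b, id, paste0(reverse_translate(prot), "TGA"),
               sample(c("+", "-"), 1))
  }

  # ---- left flank: three conserved genes, SSR-bearing spacers ----
  spacer(TRUE)
  flank_gene("GF1"); spacer(TRUE)
  flank_gene("GF2"); retro_site()
  flank_gene("GF3"); spacer(TRUE)

  # ---- central RGA cluster ----
  meta$rga <- data.frame(id = character(), clade = integer(),
                         strand = character())
  mterf_prot <- paste0("M", random_aa(cds_mterf / 3 - 2,
                                      c(AA_FILLER, AA_ALIPHATIC)))
  mterf_cds <- paste0(reverse_translate(mterf_prot), "TAA")
  frag_i <- 0L
  igr_in_cluster <- 0L
  frag_after <- intersect(c(1L, 3L), seq_len(max(n_rga - 1L, 0L)))
  igr_after <- unique(pmax(pmin(c(2L, 5L, n_rga - 1L), n_rga - 1L), 1L))
  igr_after <- head(setdiff(igr_after, frag_after),
                    config$intergenic_repeat_copies)
  for (i in seq_len(n_rga)) {
    clade <- if (i <= 2) 1L else 2L
    strand <- if (clade == 1L) "+" else "-"
    tmpl <- if (clade == 1L) tmpl1 else tmpl2
    nmut <- round(nchar(tmpl) * config$paralog_divergence)
    cds <- mutate_cds(tmpl, nmut)
    id <- paste0("RGA_", LETTERS[i])
    b_add_gene(b, id, cds, strand,
               attrs = c(family = "RGA08", clade = as.character(clade)))
    meta$rga <- rbind(meta$rga, data.frame(id = id, clade = clade,
                                           strand = strand))
    # interleave cluster furniture between RGA genes
    if (i %in% frag_after) {
      frag_i <- frag_i + 1L
      frag <- substr(mterf_cds, 200, 800)
      b_add_feature(b, sprintf("MTERF_f%d", frag_i), "fragment", frag, "-")
      spacer(TRUE)
    } else if (i %in% igr_after) {
      igr_in_cluster <- igr_in_cluster + 1L
      add_igr(igr_in_cluster)
      spacer(TRUE)
    } else if (i < n_rga) {
      spacer(TRUE)
      if (i == 4L) retro_site()
    }
  }

  # ---- right flank: reference intergenic repeat 2 kb upstream of the
  # complete MTERF gene, then a kinase-like gene ----
  spacer(FALSE); retro_site()
  add_igr(0L)
  b_add_seq(b, random_dna(2000, gc = 0.4))
  b_add_gene(b, "MTERF1", mterf_cds, "+")
  spacer(TRUE)
  flank_gene("GF4")
  spacer(FALSE)

  features <- if (length(b$features)) do.call(rbind, b$features)
              else feature_table()
  locus <- annotated_locus(
    haplotype_sequence("ancestor", paste(b$parts, collapse = "")),
    features, b$genes)
  attr(locus, "meta") <- meta
  locus
}

# ---- haplotype divergence ---------------------------------------------

# apply one structural edit (deletion of del_len at pos, then insertion of
# ins_text) to a locus; features/genes beyond the edit shift, features
# overlapping a deletion are dropped, features spanning a pure insertion
# point are extended
apply_edit <- function(locus, pos, del_len, ins_text) {
  res <- locus$sequence$residues
  new_res <- paste0(substr(res, 1, pos), ins_text,
                    substr(res, pos + del_len + 1, nchar(res)))
  shift <- nchar(ins_text) - del_len
  shift_iv <- function(s, e) {
    if (e <= pos) return(c(s, e))
    if (s >= pos + del_len) return(c(s + shift, e + shift))
    if (del_len == 0 && s < pos && e > pos) return(c(s, e + shift))
    NULL   # overlaps a deletion (or replaced span): drop
  }
  f <- locus$features
  keep <- rep(TRUE, nrow(f))
  for (i in seq_len(nrow(f))) {
    iv <- shift_iv(f$start[i], f$end[i])
    if (is.null(iv)) keep[i] <- FALSE
    else { f$start[i] <- iv[1]; f$end[i] <- iv[2] }
  }
  dropped <- f$id[!keep]
  f <- f[keep, , drop = FALSE]
  genes <- list()
  for (g in locus$genes) {
    iv <- shift_iv(g$exons[1, 1], g$exons[nrow(g$exons), 2])
    if (is.null(iv)) { dropped <- c(dropped, g$id); next }
    d <- iv[1] - g$exons[1, 1]
    g$exons <- g$exons + d; g$cds <- g$cds + d
    genes[[g$id]] <- g
  }
  out <- annotated_locus(haplotype_sequence(locus$sequence$id, new_res),
                         f, genes)
  attr(out, "dropped") <- dropped
  out
}

# net coordinate shift of an ancestor-coordinate point under a set of
# non-overlapping edits (NA when the point was deleted)
shift_point <- function(p, edits) {
  out <- p
  for (pp in seq_along(p)) {
    x <- p[pp]; s <- 0; dead <- FALSE
    for (e in edits) {
      if (x >= e$pos + e$del) s <- s + nchar(e$ins) - e$del
      else if (x >= e$pos && x < e$pos + e$del) dead <- TRUE
    }
    out[pp] <- if (dead) NA_integer_ else x + s
  }
  out
}

# genome positions of a gene's CDS in coding order (0-based); for minus
# strand the list is reversed and bases are complemented on write-back
gene_genome_positions <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$cds)), function(i)
    seq(gene$cds[i, 1], gene$cds[i, 2] - 1L)))
  if (identical(gene$strand, "-")) rev(pos) else pos
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Poisson synonymous-only substitutions on one gene; returns the updated
# char vector and the number applied
evolve_gene_cds <- function(cc, gene, rate, t_years) {
  cds_pos <- gene_genome_positions(gene)
  cds <- paste(if (identical(gene$strand, "-"))
    COMPLEMENT[cc[cds_pos + 1]] else cc[cds_pos + 1], collapse = "")
  nn <- nchar(cds) %/% 3
  starts <- 3 * (seq_len(nn) - 1) + 1
  ssv <- syn_sites_vector()
  s_sites <- sum(ssv[substring(cds, starts, starts + 2)], na.rm = TRUE)
  n_s <- rpois(1, s_sites * rate * t_years)
  if (n_s == 0) return(list(cc = cc, n = 0L, s_sites = s_sites))
  opp <- synonymous_opportunities(cds)
  n_s <- min(n_s, nrow(opp))
  chosen <- opp[sample(nrow(opp), n_s), , drop = FALSE]
  # one change per CDS position
  chosen <- chosen[!duplicated(chosen$pos), , drop = FALSE]
  for (r in seq_len(nrow(chosen))) {
    gp <- cds_pos[chosen$pos[r] + 1]
    nt <- chosen$to[r]
    cc[gp + 1] <- if (identical(gene$strand, "-")) COMPLEMENT[[nt]] else nt
  }
  list(cc = cc, n = nrow(chosen), s_sites = s_sites)
}

# LTR retroelement with LTRs diverged to the requested age
build_retro <- function(ltr_len, internal_len, age_my, rate) {
  core <- chars(random_dna(ltr_len, gc = 0.4))
  core[1:2] <- c("T", "G"); core[(ltr_len - 1):ltr_len] <- c("C", "A")
  ltr5 <- core; ltr3 <- core
  n_mut <- rpois(1, 2 * rate * age_my * 1e6 * (ltr_len - 4))
  if (n_mut > 0) {
    # site-independent Poisson: positions drawn with replacement, so
    # multiple hits (and back-mutations) occur at their natural rate and
    # the K2P multiple-hit correction is well-specified
    at <- sample(3:(ltr_len - 2), n_mut, replace = TRUE)
    for (p in at) {
      if (runif(1) < 0.5) ltr5[p] <- draw_substitution(ltr5[p])
      else ltr3[p] <- draw_substitution(ltr3[p])
    }
  }
  paste0(paste(ltr5, collapse = ""), random_dna(internal_len, gc = 0.4),
         paste(ltr3, collapse = ""))
}

#' Diverge an ancestor into two haplotypes with ground truth
#'
#' Each haplotype independently accumulates Poisson substitutions:
#' noncoding sites at `rate_noncoding * T`, CDS sites as synonymous
#' one-step changes with expectation `rate_coding * T` per synonymous
#' site (so the expected synonymous p-distance between haplotypes is
#' `2 r T`). Configured SSR slippage, LTR retroelement insertions
#' (exact LTR pair diverged to the element age, flanking TSD) and
#' recombination events are then applied, and every planted event is
#' recorded in the returned truth table.
#'
#' @param ancestor result of [simulate_ancestor()] (with its `meta`
#'   attribute).
#' @param config the same [simulation_config()].
#' @return list with `locus_a`, `locus_b` ([annotated_locus()]) and
#'   `truth` (class `TruthTable`).
#' @export
diverge_haplotypes <- function(ancestor, config) {
  meta <- attr(ancestor, "meta")
  if (is.null(meta)) stop("ancestor lacks simulation metadata", call. = FALSE)
  set.seed(config$seed + 7919L)
  t_years <- config$divergence_T * 1e6
  L <- ancestor$sequence$length

  ssr_ranges <- if (nrow(meta$ssr))
    as_ranges(meta$ssr$pos,
              meta$ssr$pos + nchar(meta$ssr$unit) * meta$ssr$count)
  else NULL
  cds_ranges <- do.call(rbind, lapply(ancestor$genes, function(g) g$cds))

  subs_truth <- data.frame(hap = character(), class = character(),
                           count = integer())
  loci <- list()
  for (hap in c("A", "B")) {
    cc <- chars(ancestor$sequence$residues)
    # noncoding substitutions (SSR runs kept perfect)
    p0 <- seq_len(L) - 1L
    elig <- !in_ranges(p0, cds_ranges)
    if (!is.null(ssr_ranges)) elig <- elig & !in_ranges(p0, ssr_ranges)
    n_nc <- rpois(1, sum(elig) * config$rate_noncoding * t_years)
    if (n_nc > 0) {
      at <- sample(p0[elig], min(n_nc, sum(elig)))
      cc[at + 1] <- vapply(cc[at + 1], draw_substitution, character(1))
    }
    n_syn <- 0L
    for (g in ancestor$genes) {
      ev <- evolve_gene_cds(cc, g, config$rate_coding, t_years)
      cc <- ev$cc; n_syn <- n_syn + ev$n
    }
    subs_truth <- rbind(subs_truth,
                        data.frame(hap = hap,
                                   class = c("noncoding", "coding_syn"),
                                   count = c(n_nc, n_syn)))
    loci[[hap]] <- annotated_locus(
      haplotype_sequence(paste0("hap", hap), paste(cc, collapse = "")),
      ancestor$features, ancestor$genes)
  }

  # ---- structural edits, in ancestor coordinates ----
  edits <- list(A = list(), B = list())
  retro_truth <- data.frame(hap = character(), start = integer(),
                            end = integer(), ltr_len = integer(),
                            tsd = character(), age = numeric())
  re <- config$retro_events
  if (!is.null(re) && nrow(re) && length(meta$retro_sites)) {
    site_i <- setNames(c(0L, 0L), c("A", "B"))
    used <- integer()
    for (k in seq_len(nrow(re))) {
      free <- setdiff(seq_along(meta$retro_sites), used)
      if (!length(free)) break
      site <- meta$retro_sites[free[1]]; used <- c(used, free[1])
      hap <- re$hap[k]
      tsd_len <- re$tsd[k]
      tsd_text <- substr(loci[[hap]]$sequence$residues, site + 1,
                         site + tsd_len)
      elem <- build_retro(re$ltr_len[k], re$internal_len[k], re$age[k],
                          config$rate_noncoding)
      edits[[hap]][[length(edits[[hap]]) + 1]] <-
        list(pos = site + tsd_len, del = 0L,
             ins = paste0(elem, tsd_text), tag = "retro",
             elem_len = nchar(elem))
      retro_truth <- rbind(retro_truth, data.frame(
        hap = hap, start = site + tsd_len,
        end = site + tsd_len + nchar(elem), ltr_len = re$ltr_len[k],
        tsd = tsd_text, age = re$age[k]))
    }
  }

  ssr_truth <- meta$ssr
  if (nrow(ssr_truth)) {
    ssr_truth$motif <- vapply(ssr_truth$unit, canonical_motif, character(1))
    for (i in seq_len(nrow(ssr_truth))) {
      d <- ssr_truth$delta[i]
      if (d == 0) next
      u <- nchar(ssr_truth$unit[i]); cnt <- ssr_truth$count[i]
      edits$B[[length(edits$B) + 1]] <- list(
        pos = ssr_truth$pos[i], del = u * cnt,
        ins = strrep(ssr_truth$unit[i], cnt + d), tag = "ssr")
    }
  }

  intragenic <- NULL
  rga_ids <- meta$rga$id
  if (isTRUE(config$intragenic_recombination) && length(rga_ids) >= 6) {
    target <- rga_ids[length(rga_ids)]
    parents <- rga_ids[c(5, 6)]
    cds_p1 <- extract_cds(ancestor$genes[[parents[1]]], ancestor$sequence)
    cds_p2 <- extract_cds(ancestor$genes[[parents[2]]], ancestor$sequence)
    bp <- (nchar(cds_p1) %/% 2 %/% 3) * 3
    chim <- paste0(substr(cds_p1, 1, bp),
                   substr(cds_p2, bp + 1, nchar(cds_p2)))
    tg <- ancestor$genes[[target]]
    genomic <- if (identical(tg$strand, "-")) dna_revcomp(chim) else chim
    edits$B[[length(edits$B) + 1]] <- list(
      pos = tg$cds[1, 1], del = tg$cds[nrow(tg$cds), 2] - tg$cds[1, 1],
      ins = genomic, tag = "chimera")
    intragenic <- list(recombinant = target, parents = parents,
                       breakpoint_cds = bp)
  }

  intergenic <- NULL
  if (isTRUE(config$intergenic_recombination) &&
      length(meta$igr_copies) >= 3) {
    # crossover between cluster copies 2 and 3: B loses the region
    # between their midpoints, fusing the two copies into one
    del_s <- meta$igr_copies[2] + 500L
    del_e <- meta$igr_copies[3] + 500L
    edits$B[[length(edits$B) + 1]] <- list(pos = del_s,
                                           del = del_e - del_s,
                                           ins = "", tag = "igr_recomb")
    inside <- vapply(ancestor$genes, function(g)
      g$cds[1, 1] >= del_s && g$cds[nrow(g$cds), 2] <= del_e, TRUE)
    intergenic <- list(deleted_range = c(del_s, del_e),
                       deleted_genes = names(inside)[inside])
  }

  # apply edits in coordinate-descending order
  for (hap in c("A", "B")) {
    ed <- edits[[hap]]
    if (!length(ed)) next
    ord <- order(vapply(ed, `[[`, 0, "pos"), decreasing = TRUE)
    for (e in ed[ord]) {
      target_gene <- if (identical(e$tag, "chimera"))
        loci[[hap]]$genes[[intragenic$recombinant]] else NULL
      loci[[hap]] <- apply_edit(loci[[hap]], e$pos, e$del, e$ins)
      if (identical(e$tag, "retro")) {
        # record the new element as a repeat feature
        loci[[hap]]$features <- rbind(loci[[hap]]$features, feature_table(
          id = sprintf("te_%s_%d", hap, e$pos), kind = "repeat_element",
          seqid = loci[[hap]]$sequence$id, start = e$pos,
          end = e$pos + e$elem_len, strand = "+",
          attributes = list(c(planted = "ltr_retroelement"))))
      } else if (identical(e$tag, "chimera") && !is.null(target_gene)) {
        # re-register the recombinant gene (its edit replaced the CDS)
        rng <- as_ranges(e$pos, e$pos + nchar(e$ins))
        loci[[hap]]$genes[[target_gene$id]] <- gene_model(
          target_gene$id, target_gene$seqid, target_gene$strand, rng, rng,
          q_cov = 1, s_cov = 1)
        loci[[hap]]$features <- rbind(loci[[hap]]$features, feature_table(
          id = target_gene$id, kind = "gene",
          seqid = loci[[hap]]$sequence$id, start = e$pos,
          end = e$pos + nchar(e$ins), strand = target_gene$strand,
          attributes = list(c(family = "RGA08"))))
      }
    }
  }

  # ---- truth table in final per-haplotype coordinates ----
  shift_a <- function(p) shift_point(p, edits$A)
  shift_b <- function(p) shift_point(p, edits$B)
  if (nrow(retro_truth)) {
    for (i in seq_len(nrow(retro_truth))) {
      sh <- if (retro_truth$hap[i] == "A") shift_a else shift_b
      # shift by the *other* edits: element start is already its final
      # position relative to its own insertion (pos + tsd); exclude self
      own <- retro_truth$start[i]
      eds <- edits[[retro_truth$hap[i]]]
      eds <- Filter(function(e) e$pos != own, eds)
      retro_truth$start[i] <- shift_point(own, eds)
      retro_truth$end[i] <- retro_truth$start[i] +
        (retro_truth$end[i] - own)
    }
  }
  if (nrow(ssr_truth)) {
    ssr_truth$pos_a <- shift_a(ssr_truth$pos)
    ssr_truth$pos_b <- vapply(seq_len(nrow(ssr_truth)), function(i) {
      eds <- Filter(function(e) e$pos != ssr_truth$pos[i], edits$B)
      as.integer(shift_point(ssr_truth$pos[i], eds))
    }, integer(1))
    ssr_truth$count_a <- ssr_truth$count
    ssr_truth$count_b <- ssr_truth$count + ssr_truth$delta
  }
  igr_truth <- data.frame(
    copy = c(seq_along(meta$igr_copies) - 1L)[0], hap = character(),
    start = integer())
  copies <- meta$igr_copies
  names_copy <- seq_along(copies)       # cluster copies 1..k, ref copy 0 last
  copy_ids <- c(head(seq_along(copies), -1), 0L)
  for (i in seq_along(copies)) {
    sa <- shift_a(copies[i]); sb <- shift_b(copies[i])
    if (!is.na(sa))
      igr_truth <- rbind(igr_truth, data.frame(copy = copy_ids[i],
                                               hap = "A", start = sa))
    if (!is.na(sb))
      igr_truth <- rbind(igr_truth, data.frame(copy = copy_ids[i],
                                               hap = "B", start = sb))
  }

  genes_a <- names(loci$A$genes); genes_b <- names(loci$B$genes)
  chim_id <- if (!is.null(intragenic)) intragenic$recombinant else character()
  pair_ids <- setdiff(intersect(genes_a, genes_b), chim_id)
  truth <- structure(list(
    substitutions = subs_truth,
    allele_pairs = data.frame(gene = pair_ids,
                              id_a = pair_ids, id_b = pair_ids),
    unpaired = data.frame(
      id = setdiff(genes_a, genes_b),
      hap = rep("A", length(setdiff(genes_a, genes_b)))),
    ambiguous = chim_id,
    clades = meta$rga[, c("id", "clade")],
    ssr = ssr_truth,
    retro = retro_truth,
    intragenic = intragenic,
    intergenic = c(intergenic,
                   list(junction_b = if (!is.null(intergenic))
                     shift_b(intergenic$deleted_range[1] - 1L) + 1L
                     else NA_integer_)),
    igr_hits = igr_truth,
    probe = meta$probe,
    templates = meta$templates), class = "TruthTable")
  list(locus_a = loci$A, locus_b = loci$B, truth = truth)
}

#' Simulate a haplotype pair in one call
#'
#' @param config a [simulation_config()].
#' @return as [diverge_haplotypes()], plus `ancestor`.
#' @export
simulate_haplotype_pair <- function(config = simulation_config()) {
  anc <- simulate_ancestor(config)
  out <- diverge_haplotypes(anc, config)
  out$ancestor <- anc
  out
}

#' Write a simulated haplotype pair and its truth table to disk
#'
#' Emits `haplotypes.fasta` (both haplotypes), one GFF3 per haplotype
#' (gene features carry `cds_start`/`cds_end` attributes in 0-based
#' half-open coordinates so gene models can be rebuilt), `probe.fasta`,
#' and TSV truth tables. The fixture round-trips through
#' [load_fixture()].
#'
#' @param pair result of [simulate_haplotype_pair()] /
#'   [diverge_haplotypes()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
emit_fixture <- function(pair, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(list(pair$locus_a$sequence, pair$locus_b$sequence),
              file.path(out_dir, "haplotypes.fasta"))
  for (nm in c("locus_a", "locus_b")) {
    locus <- pair[[nm]]
    f <- locus$features
    f$seqid <- locus$sequence$id
    # refresh gene-model attributes
    for (i in seq_len(nrow(f))) {
      g <- locus$genes[[f$id[i]]]
      if (!is.null(g)) {
        at <- f$attributes[[i]]
        at <- at[!names(at) %in% c("cds_start", "cds_end")]
        f$attributes[[i]] <- c(at, cds_start = as.character(g$cds[1, 1]),
                               cds_end = as.character(g$cds[nrow(g$cds), 2]))
      }
    }
    write_gff3(f, file.path(out_dir, paste0(locus$sequence$id, ".gff3")))
  }
  write_fasta(list(haplotype_sequence("probe", pair$truth$probe)),
              file.path(out_dir, "probe.fasta"))
  tr <- pair$truth
  wt <- function(df, name) write.table(
    df, file.path(out_dir, paste0("truth_", name, ".tsv")), sep = "\t",
    quote = FALSE, row.names = FALSE)
  wt(tr$substitutions, "substitutions")
  wt(tr$allele_pairs, "allele_pairs")
  wt(tr$clades, "clades")
  if (nrow(tr$ssr)) wt(tr$ssr, "ssr")
  if (nrow(tr$retro)) wt(tr$retro, "retro")
  wt(tr$igr_hits, "igr_hits")
  invisible(out_dir)
}

#' Load a fixture written by [emit_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `locus_a`, `locus_b`, `probe`.
#' @export
load_fixture <- function(dir) {
  seqs <- read_fasta(file.path(dir, "haplotypes.fasta"))
  lens <- vapply(seqs, `[[`, 0L, "length")
  out <- list()
  for (i in 1:2) {
    s <- seqs[[i]]
    f <- read_gff3(file.path(dir, paste0(s$id, ".gff3")),
                   seq_lengths = setNames(lens, names(seqs)))
    genes <- features_to_genes(f)
    nm <- if (i == 1) "locus_a" else "locus_b"
    out[[nm]] <- annotated_locus(s, f, genes)
  }
  out$probe <- read_fasta(file.path(dir, "probe.fasta"))[[1]]$residues
  out
}

# rebuild gene models from gene features carrying cds_start/cds_end
features_to_genes <- function(features) {
  genes <- list()
  for (i in seq_len(nrow(features))) {
    if (features$kind[i] != "gene") next
    at <- features$attributes[[i]]
    if (is.null(at[["cds_start"]]) || is.null(at[["cds_end"]])) next
    rng <- as_ranges(as.integer(at[["cds_start"]]),
                     as.integer(at[["cds_end"]]))
    genes[[features$id[i]]] <- gene_model(
      features$id[i], features$seqid[i], features$strand[i], rng, rng)
  }
  genes
}
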