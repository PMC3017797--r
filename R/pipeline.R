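# End-to-end orchestration: load -> colinearity -> repeats -> dating ->
# RGA family analysis -> recombination -> report.

#' Pipeline configuration
#'
#' @param locus_a,locus_b [annotated_locus()] objects, or paths to a
#'   fixture directory entry loaded by the caller.
#' @param pairing optional data.frame (`gene_a`, `gene_b`) of allelic
#'   CDS pairs used for dating; when absent the pairs assigned by
#'   [assign_alleles()] are used.
#' @param probe optional duplicated-intergenic probe sequence; when
#'   absent the copy-0 `intergenic_repeat` feature of locus A is used.
#' @param evidence optional data.frame (`id`, `q_cov`, `s_cov`,
#'   `n_fragments`) of reference-protein similarity for classification.
#' @param out_dir optional directory for stage TSV outputs.
#' @param k,max_kmer_freq,max_gap,min_block anchoring/chaining settings.
#' @param min_identity_allele,tie_margin allele assignment settings.
#' @param cut_identity clade cut level.
#' @param rate_coding,rate_noncoding clock rates (per site per year).
#' @param window,step,min_delta,min_run breakpoint-profile settings.
#' @param cluster_margin margin around the outermost RGA features when
#'   deriving cluster boundaries (bases).
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(locus_a, locus_b, pairing = NULL, probe = NULL,
                            evidence = NULL, out_dir = NULL,
                            k = 15, max_kmer_freq = 8, max_gap = 5000,
                            min_block = 500,
                            min_identity_allele = 0.90, tie_margin = 0.01,
                            cut_identity = 0.80,
                            rate_coding = 4.5e-9, rate_noncoding = 9e-9,
                            window = 100, step = 10, min_delta = 0.02,
                            min_run = 3, cluster_margin = 1000) {
  stopifnot(inherits(locus_a, "AnnotatedLocus"),
            inherits(locus_b, "AnnotatedLocus"))
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full haplotype comparison
#'
#' Stages run in dependency order: anchoring and block chaining,
#' base-level refinement with SNP/indel cataloguing, nucleotide
#' diversity, SSR scan and cross-haplotype matching, LTR structural
#' annotation and insertion dating, RGA identity matrix with allele
#' assignment, clade clustering and classification, allelic-pair
#' synonymous dating, and recombination scanning. The same
#' configuration always yields the same report.
#'
#' @param config a [pipeline_config()].
#' @return list of class `ComparisonReport` with elements `blocks`,
#'   `refined`, `diversity`, `ssr`, `ltr`, `rga` (matrix, alleles,
#'   clades, classification), `dating`, `recombination`,
#'   `region_stats`, and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  A <- config$locus_a; B <- config$locus_b
  report <- list(config = config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # ---- colinearity ----
  anchors <- stage("anchors",
    find_anchors(A$sequence, B$sequence, k = config$k,
                 max_kmer_freq = config$max_kmer_freq))
  blocks <- stage("chaining",
    chain_blocks(anchors, max_gap = config$max_gap,
                 min_block = config$min_block))
  refined <- stage("refinement", lapply(blocks, function(b)
    refine_block(A$sequence, B$sequence, b)))
  blocks <- lapply(refined, `[[`, "block")
  indels <- do.call(rbind, c(list(data.frame()),
                             lapply(refined, `[[`, "indels")))

  cds_a <- do.call(rbind, lapply(A$genes, function(g) g$cds))
  report$diversity <- stage("diversity", list(
    overall = nucleotide_diversity(refined),
    coding = tryCatch(nucleotide_diversity(refined, mask = cds_a),
                      error = function(e) NA_real_)))

  # ---- SSR ----
  rga_ids_a <- rga_gene_ids(A); rga_ids_b <- rga_gene_ids(B)
  rga_cds_a <- do.call(rbind, c(list(matrix(0L, 0, 2)),
    lapply(A$genes[rga_ids_a], function(g) g$cds)))
  rga_cds_b <- do.call(rbind, c(list(matrix(0L, 0, 2)),
    lapply(B$genes[rga_ids_b], function(g) g$cds)))
  loci_ssr_a <- stage("ssr_scan", scan_ssr(A$sequence))
  loci_ssr_b <- scan_ssr(B$sequence)
  report$ssr <- list(
    loci_a = loci_ssr_a, loci_b = loci_ssr_b,
    matches = stage("ssr_match",
      match_ssr_pairs(loci_ssr_a, loci_ssr_b, blocks,
                      exclude_a = rga_cds_a, exclude_b = rga_cds_b)))

  # ---- LTR retroelements ----
  ltr_calls <- list()
  for (side in c("A", "B")) {
    locus <- if (side == "A") A else B
    reps <- locus$features[locus$features$kind == "repeat_element", ,
                           drop = FALSE]
    for (i in seq_len(nrow(reps))) {
      rng <- c(max(0L, reps$start[i] - 20L),
               min(locus$sequence$length, reps$end[i] + 20L))
      calls <- stage("ltr", detect_ltr(locus$sequence, rng,
                                       rate = config$rate_noncoding))
      for (cl in calls) {
        cl$haplotype <- side; cl$feature <- reps$id[i]
        ltr_calls[[length(ltr_calls) + 1]] <- cl
      }
    }
  }
  report$ltr <- ltr_calls

  # ---- RGA family ----
  cds_set <- c(
    setNames(lapply(A$genes[rga_ids_a], extract_cds, sequence = A$sequence),
             paste0(rga_ids_a, "_A")),
    setNames(lapply(B$genes[rga_ids_b], extract_cds, sequence = B$sequence),
             paste0(rga_ids_b, "_B")))
  rga <- list()
  if (length(cds_set) >= 2) {
    mat <- stage("identity_matrix",
                 pairwise_identity_matrix(lapply(cds_set, as.character)))
    hap_of <- setNames(c(rep("A", length(rga_ids_a)),
                         rep("B", length(rga_ids_b))), rownames(mat))
    rga$matrix <- mat
    rga$alleles <- stage("alleles",
      assign_alleles(mat, hap_of, min_identity = config$min_identity_allele,
                     tie_margin = config$tie_margin))
    rga$clades <- stage("clades",
                        cluster_clades(mat, cut_identity = config$cut_identity))
  }
  rga$classification <- stage("classification",
    rbind(classify_locus_genes(A, "A", config$evidence),
          classify_locus_genes(B, "B", config$evidence)))
  report$rga <- rga

  # ---- dating ----
  pairing <- config$pairing
  if (is.null(pairing) && !is.null(rga$alleles) &&
      nrow(rga$alleles$pairs)) {
    pairing <- data.frame(gene_a = sub("_A$", "", rga$alleles$pairs$gene_a),
                          gene_b = sub("_B$", "", rga$alleles$pairs$gene_b))
  }
  if (!is.null(pairing) && nrow(pairing)) {
    pairs <- list()
    for (i in seq_len(nrow(pairing))) {
      ca <- as.character(extract_cds(A$genes[[pairing$gene_a[i]]],
                                     A$sequence))
      cb <- as.character(extract_cds(B$genes[[pairing$gene_b[i]]],
                                     B$sequence))
      pairs[[paste(pairing$gene_a[i], pairing$gene_b[i], sep = "/")]] <-
        align_cds_pair(ca, cb)
    }
    report$dating <- stage("dating",
                           dating_table(pairs, rate = config$rate_coding))
  }

  # ---- recombination ----
  probe <- config$probe %||% locus_probe(A)
  recomb <- list()
  if (!is.null(probe)) {
    hits <- stage("intergenic_repeats", find_duplicated_intergenic(
      list(A = A$sequence, B = B$sequence), probe))
    recomb$repeat_hits <- hits
    recomb$candidates <- stage("recomb_scan", scan_intergenic_recombination(
      blocks, indels, hits, seq_a = A$sequence, seq_b = B$sequence))
  }
  # intragenic: profile each ambiguous gene against its two best
  # cross-haplotype matches
  if (!is.null(rga$alleles) && length(rga$alleles$ambiguous)) {
    profiles <- list()
    for (amb in rga$alleles$ambiguous) {
      g <- amb[1]
      others <- setdiff(amb, g)
      if (length(others) < 2) {
        v <- sort(rga$matrix[g, setdiff(rownames(rga$matrix), g)],
                  decreasing = TRUE)
        others <- names(v)[1:2]
      }
      prof <- stage("intragenic_profile", identity_profile(
        cds_set[[g]], setNames(lapply(others, function(o)
          as.character(cds_set[[o]])), others),
        window = config$window, step = config$step))
      profiles[[g]] <- list(
        profile = prof,
        breakpoints = call_breakpoints(prof, min_delta = config$min_delta,
                                       min_run = config$min_run))
    }
    recomb$intragenic <- profiles
  }
  report$recombination <- recomb

  # ---- region statistics ----
  report$region_stats <- rbind(
    summarize_locus_regions(A, "A", config$cluster_margin),
    summarize_locus_regions(B, "B", config$cluster_margin))
  report$blocks <- blocks
  report$refined <- refined
  report$indels <- indels

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  structure(report, class = "ComparisonReport")
}

rga_gene_ids <- function(locus) {
  f <- locus$features
  fam <- vapply(seq_len(nrow(f)), function(i) {
    at <- f$attributes[[i]]
    identical(unname(at["family"]), "RGA08")
  }, TRUE)
  ids <- f$id[f$kind == "gene" & fam]
  ids <- union(ids, grep("^RGA", names(locus$genes), value = TRUE))
  intersect(names(locus$genes), ids)
}

locus_probe <- function(locus) {
  f <- locus$features
  ig <- f[f$kind == "intergenic_repeat", , drop = FALSE]
  if (!nrow(ig)) return(NULL)
  ref <- which(vapply(ig$attributes, function(a)
    identical(unname(a["copy"]), "0"), TRUE))
  i <- if (length(ref)) ref[1] else 1L
  substr(locus$sequence$residues, ig$start[i] + 1, ig$end[i])
}

# pairwise-align a CDS pair and drop gap columns so downstream codon
# counting sees a gapless in-frame alignment (exact when the pair has
# no indels; a frame approximation otherwise)
align_cds_pair <- function(ca, cb) {
  if (nchar(ca) == nchar(cb)) return(list(ca, cb))
  al <- align_global(ca, cb)
  x <- chars(al$aligned_a); y <- chars(al$aligned_b)
  keep <- x != "-" & y != "-"
  xa <- paste(x[keep], collapse = ""); xb <- paste(y[keep], collapse = "")
  trim <- nchar(xa) - nchar(xa) %% 3
  list(substr(xa, 1, trim), substr(xb, 1, trim))
}

classify_locus_genes <- function(locus, hap, evidence = NULL) {
  rows <- lapply(locus$genes, function(g) {
    ev <- NULL
    if (!is.null(evidence)) {
      m <- evidence[evidence$id == g$id, , drop = FALSE]
      if (nrow(m)) ev <- as.list(m[1, ])
    }
    cl <- classify_gene(g, ev)
    data.frame(id = g$id, haplotype = hap, label = cl$label,
               strand = g$strand)
  })
  do.call(rbind, c(list(data.frame()), rows))
}

#' Region composition statistics for one locus
#'
#' Splits the locus into the RGA cluster (outermost RGA feature
#' footprint plus a margin) and its flanking regions, and reports per
#' region: size, percent exon/intron/TE/SSR/intergenic (overlaps
#' resolved by the precedence exon > intron > TE > SSR > intergenic),
#' gene counts by strand, and gene density.
#'
#' @param locus an [annotated_locus()].
#' @param cluster_boundaries 0-based half-open `c(start, end)` of the
#'   cluster, or `NULL` to derive from RGA features with `margin`.
#' @param margin margin around the outermost RGA features (bases).
#' @param label prefix for region names.
#' @return data.frame, one row per region.
#' @export
summarize_regions <- function(locus, cluster_boundaries = NULL,
                              margin = 1000, label = locus$sequence$id) {
  L <- locus$sequence$length
  if (is.null(cluster_boundaries)) {
    ids <- rga_gene_ids(locus)
    f <- locus$features[locus$features$id %in% ids, , drop = FALSE]
    cluster_boundaries <- if (nrow(f))
      c(max(0L, min(f$start) - margin), min(L, max(f$end) + margin))
    else c(0L, 0L)
  }
  if (any(cluster_boundaries < 0) || any(cluster_boundaries > L))
    stop("cluster boundaries outside sequence", call. = FALSE)
  regions <- list()
  cb <- cluster_boundaries
  if (cb[2] > cb[1]) {
    if (cb[1] > 0) regions$flank_left <- c(0L, cb[1])
    regions$cluster <- cb
    if (cb[2] < L) regions$flank_right <- c(cb[2], L)
  } else regions$whole <- c(0L, L)

  # composition classes with precedence exon > intron > TE > SSR
  cls <- integer(L)   # 0 intergenic, 4 exon, 3 intron, 2 TE, 1 SSR
  paint <- function(cls, r, v) {
    if (nrow(r) == 0) return(cls)
    for (i in seq_len(nrow(r))) {
      s <- r[i, 1] + 1L; e <- r[i, 2]
      if (e >= s) cls[s:e] <- pmax(cls[s:e], v)
    }
    cls
  }
  f <- locus$features
  gene_rows <- f[f$kind %in% c("gene", "pseudogene"), , drop = FALSE]
  cls <- paint(cls, as.matrix(gene_rows[, c("start", "end")]), 3L)  # body
  for (g in locus$genes) cls <- paint(cls, g$exons, 4L)
  cls <- paint(cls, as.matrix(
    f[f$kind == "repeat_element", c("start", "end"), drop = FALSE]), 2L)
  cls <- paint(cls, as.matrix(
    f[f$kind == "SSR", c("start", "end"), drop = FALSE]), 1L)

  rows <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    seg <- cls[(r[1] + 1):r[2]]
    size <- r[2] - r[1]
    in_region <- gene_rows$start >= r[1] & gene_rows$end <= r[2]
    data.frame(
      region = paste(label, nm, sep = ":"), start = r[1], end = r[2],
      size = size,
      pct_exon = 100 * mean(seg == 4), pct_intron = 100 * mean(seg == 3),
      pct_te = 100 * mean(seg == 2), pct_ssr = 100 * mean(seg == 1),
      pct_intergenic = 100 * mean(seg == 0),
      n_genes = sum(in_region),
      n_genes_plus = sum(in_region & gene_rows$strand == "+"),
      n_genes_minus = sum(in_region & gene_rows$strand == "-"),
      gene_density_per_10kb = 1e4 * sum(in_region) / size)
  })
  do.call(rbind, rows)
}

summarize_locus_regions <- function(locus, hap, margin) {
  summarize_regions(locus, margin = margin, label = hap)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, name) {
    if (!is.null(x) && is.data.frame(x) && nrow(x))
      write.table(x, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  wt(report$region_stats, "region_stats")
  wt(report$dating, "dating")
  wt(report$ssr$matches, "ssr_matches")
  wt(report$rga$classification, "classification")
  if (!is.null(report$rga$alleles)) wt(report$rga$alleles$pairs, "alleles")
  wt(report$indels, "indels")
  export_blocks_gff3(report$blocks, report$indels,
                     file.path(out_dir, "colinearity.gff3"))
  for (side in c("A", "B")) {
    calls <- Filter(function(x) identical(x$haplotype, side), report$ltr)
    loci <- if (side == "A") report$ssr$loci_a else report$ssr$loci_b
    export_repeats_gff3(calls, loci,
                        file.path(out_dir,
                                  sprintf("repeats_hap%s.gff3", side)),
                        seqid = paste0("hap", side))
  }
  for (g in names(report$recombination$intragenic)) {
    bp <- report$recombination$intragenic[[g]]$breakpoints
    if (NROW(bp))
      export_breakpoints_gff3(bp,
                              file.path(out_dir,
                                        paste0("breakpoints_", g, ".gff3")),
                              seqid = g)
  }
  if (length(report$ltr)) {
    ltab <- do.call(rbind, lapply(report$ltr, function(x) data.frame(
      haplotype = x$haplotype, feature = x$feature,
      start = x$element_range[1], end = x$element_range[2],
      ltr_len = x$ltr5_range[2] - x$ltr5_range[1],
      ltr_identity = x$ltr_identity,
      tg_ca_5 = x$tg_ca_5, tg_ca_3 = x$tg_ca_3,
      tsd = if (!is.null(x$tsd_left))
        paste(x$tsd_left, x$tsd_right, sep = "/") else "-",
      age_my = if (!is.null(x$insertion_time))
        round(x$insertion_time$T_my, 3) else NA_real_)))
    wt(ltab, "ltr_elements")
  }
  invisible(out_dir)
}

# ---- GFF3 emission of derived features --------------------------------
# These are analysis outputs, not part of the Feature model, so they are
# written directly in GFF3 dialect (1-based inclusive on disk).

gff3_record <- function(seqid, type, start0, end0, strand, id, extra = "") {
  paste(seqid, "haplorga", type, start0 + 1L, end0, ".", strand, ".",
        paste0("ID=", id, if (nzchar(extra)) paste0(";", extra) else ""),
        sep = "\t")
}

#' Export colinear blocks and indels as GFF3
#'
#' Blocks are written as `colinear_block` features on sequence A (with
#' the matched B interval in attributes) and indel events as `indel`
#' features on their carrier haplotype.
#'
#' @param blocks list of `ColinearBlock`; @param indels indel data.frame
#'   from [refine_block()]; @param path output file;
#' @param seqid_a,seqid_b sequence names.
#' @export
export_blocks_gff3 <- function(blocks, indels, path,
                               seqid_a = "hapA", seqid_b = "hapB") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    writeLines(gff3_record(
      seqid_a, "colinear_block", b$range_a[1], b$range_a[2], "+",
      sprintf("block%02d", i),
      sprintf("matched_b=%s:%d-%d;identity=%s;snp_count=%s",
              seqid_b, b$range_b[1] + 1L, b$range_b[2],
              format(b$identity, digits = 4), b$snp_count)), con)
  }
  for (i in seq_len(NROW(indels))) {
    carrier_seq <- if (indels$carrier[i] == "A") seqid_a else seqid_b
    s <- if (indels$carrier[i] == "A") indels$pos_a[i] else indels$pos_b[i]
    writeLines(gff3_record(
      carrier_seq, "indel", s, s + indels$length[i], ".",
      sprintf("indel%03d", i),
      sprintf("length=%d;carrier=%s", indels$length[i],
              indels$carrier[i])), con)
  }
  invisible(path)
}

#' Export LTR element calls and SSR loci as GFF3
#'
#' @param ltr_calls list of `LTRElementCall`; @param ssr_loci data.frame
#'   from [scan_ssr()]; @param path output file; @param seqid sequence
#'   name.
#' @export
export_repeats_gff3 <- function(ltr_calls, ssr_loci, path,
                                seqid = "hapA") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(ltr_calls)) {
    x <- ltr_calls[[i]]
    extra <- sprintf("ltr5=%d-%d;ltr3=%d-%d;ltr_identity=%s",
                     x$ltr5_range[1] + 1L, x$ltr5_range[2],
                     x$ltr3_range[1] + 1L, x$ltr3_range[2],
                     format(x$ltr_identity, digits = 4))
    if (!is.null(x$tsd_left))
      extra <- paste0(extra, ";tsd=", x$tsd_left, "/", x$tsd_right)
    if (!is.null(x$insertion_time))
      extra <- paste0(extra, ";insertion_my=",
                      format(x$insertion_time$T_my, digits = 4))
    writeLines(gff3_record(seqid, "ltr_retrotransposon",
                           x$element_range[1], x$element_range[2], "+",
                           sprintf("ltr%02d", i), extra), con)
  }
  for (i in seq_len(NROW(ssr_loci))) {
    writeLines(gff3_record(
      seqid, "SSR", ssr_loci$start[i], ssr_loci$end[i], ".",
      sprintf("ssr%03d", i),
      sprintf("motif=%s;repeat_count=%d", ssr_loci$motif[i],
              ssr_loci$repeat_count[i])), con)
  }
  invisible(path)
}

#' Export breakpoint calls as GFF3
#'
#' @param breakpoints data.frame from [call_breakpoints()]; @param path
#'   output file; @param seqid recombinant sequence name.
#' @export
export_breakpoints_gff3 <- function(breakpoints, path, seqid) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(NROW(breakpoints))) {
    b <- breakpoints[i, ]
    writeLines(gff3_record(
      seqid, "recombination_breakpoint", b$position, b$position + 1L, ".",
      sprintf("bp%02d", i),
      sprintf("left_parent=%s;right_parent=%s;delta=%s",
              b$left_parent, b$right_parent,
              format(min(b$delta_left, b$delta_right), digits = 3))), con)
  }
  invisible(path)
}
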