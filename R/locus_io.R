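# Core data model and readers/writers.
#
# Conventions used everywhere in the package:
#  * in-memory coordinates are 0-based half-open intervals [start, end)
#  * all file formats (FASTA headers aside) use 1-based inclusive
#    coordinates: GFF3 and EMBL feature tables
#  * minus-strand features keep forward-strand coordinates; only
#    extraction reverse-complements
#  * residues are stored uppercase; IUPAC ambiguity codes are accepted on
#    input and treated as N (excluded) by all distance computations.

FEATURE_KINDS <- c("gene", "pseudogene", "fragment", "remnant",
                   "repeat_element", "SSR", "domain", "intergenic_repeat",
                   "misc")

#' Construct a haplotype sequence record
#'
#' @param id character label.
#' @param residues DNA string (IUPAC codes, any case).
#' @return object of class `HaplotypeSequence` with fields `id`,
#'   `residues` (uppercase) and `length`.
#' @export
haplotype_sequence <- function(id, residues) {
  residues <- check_iupac(residues, sprintf("sequence '%s'", id))
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "HaplotypeSequence")
}

#' @export
print.HaplotypeSequence <- function(x, ...) {
  cat(sprintf("<HaplotypeSequence %s: %d bp>\n", x$id, x$length))
  invisible(x)
}

#' Construct a feature table
#'
#' @param id,kind,seqid,start,end,strand vectors (recycled); coordinates
#'   0-based half-open; `kind` one of the supported feature kinds;
#'   strand one of `+`, `-`, `.`.
#' @param attributes list of named character vectors (one per feature).
#' @return data.frame with one row per feature and a list-column
#'   `attributes`.
#' @export
feature_table <- function(id = character(), kind = character(),
                          seqid = character(), start = integer(),
                          end = integer(), strand = character(),
                          attributes = NULL) {
  n <- max(length(id), length(start))
  if (n == 0)
    return(data.frame(id = character(), kind = character(),
                      seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      attributes = I(list())))
  bad <- setdiff(unique(kind), FEATURE_KINDS)
  if (length(bad))
    stop("unknown feature kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(end < start) || any(start < 0))
    stop("feature with end < start or negative start", call. = FALSE)
  if (is.null(attributes)) attributes <- rep(list(character()), n)
  df <- data.frame(id = id, kind = kind, seqid = seqid,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, stringsAsFactors = FALSE)
  df$attributes <- attributes
  df
}

#' Construct a gene model
#'
#' @param id gene id; @param seqid sequence id; @param strand `+` or `-`.
#' @param exons,cds 2-column matrices of 0-based half-open intervals
#'   (`as_ranges()`); CDS must lie within exons; intervals sorted and
#'   disjoint.
#' @param disruptions character vector from
#'   `missing_start`, `missing_stop`, `noncanonical_splice`, `frameshift`,
#'   `inframe_stop`, `TE_insertion`.
#' @param q_cov,s_cov query/subject coverage fractions of the best
#'   reference-protein hit, or `NA`.
#' @return object of class `GeneModel`.
#' @export
gene_model <- function(id, seqid, strand, exons, cds = exons,
                       disruptions = character(), q_cov = NA_real_,
                       s_cov = NA_real_) {
  ok_dis <- c("missing_start", "missing_stop", "noncanonical_splice",
              "frameshift", "inframe_stop", "TE_insertion")
  if (length(setdiff(disruptions, ok_dis)))
    stop("unknown disruption type", call. = FALSE)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in gene ", id, call. = FALSE)
  for (i in seq_len(nrow(cds)))
    if (!any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2]))
      stop("CDS interval outside exons in gene ", id, call. = FALSE)
  if (!all(is.na(q_cov)) && (q_cov < 0 || q_cov > 1))
    stop("q_cov outside [0,1]", call. = FALSE)
  structure(list(id = id, seqid = seqid, strand = strand, exons = exons,
                 cds = cds, disruptions = disruptions,
                 q_cov = q_cov, s_cov = s_cov,
                 classification = NA_character_),
            class = "GeneModel")
}

#' Construct an annotated locus
#'
#' Bundles a haplotype sequence with its feature table and gene models;
#' every feature must lie within the sequence.
#'
#' @param sequence a [haplotype_sequence()].
#' @param features a [feature_table()].
#' @param genes named list of [gene_model()] objects.
#' @return object of class `AnnotatedLocus`.
#' @export
annotated_locus <- function(sequence, features = feature_table(),
                            genes = list()) {
  if (nrow(features) && any(features$end > sequence$length))
    stop(sprintf("feature beyond sequence length of '%s'", sequence$id),
         call. = FALSE)
  for (g in genes)
    if (nrow(g$exons) && max(g$exons[, 2]) > sequence$length)
      stop("gene model beyond sequence length", call. = FALSE)
  if (length(genes)) names(genes) <- vapply(genes, `[[`, "", "id")
  structure(list(sequence = sequence, features = features, genes = genes),
            class = "AnnotatedLocus")
}

#' @export
print.AnnotatedLocus <- function(x, ...) {
  cat(sprintf("<AnnotatedLocus %s: %d bp, %d features, %d gene models>\n",
              x$sequence$id, x$sequence$length, nrow(x$features),
              length(x$genes)))
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' @param path file path.
#' @return list of [haplotype_sequence()] records, named by id (first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^>", lines)))
    stop("empty or headerless FASTA: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  ids <- sub("\\s.*", "", sub("^>", "", lines[hdr]))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  grp <- cumsum(hdr)
  bad <- which(!hdr & grepl(sprintf("[^%s[:space:]]",
                paste(c(IUPAC_CODES, tolower(IUPAC_CODES)), collapse = "")),
                lines))
  if (length(bad))
    stop(sprintf("illegal character in FASTA at line %d: %s",
                 bad[1], lines[bad[1]]), call. = FALSE)
  seqs <- vapply(seq_along(ids), function(i) {
    paste(gsub("\\s", "", lines[!hdr & grp == i]), collapse = "")
  }, character(1))
  out <- lapply(seq_along(ids), function(i) haplotype_sequence(ids[i], seqs[i]))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs list of [haplotype_sequence()] records.
#' @param path output path; @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    starts <- seq(1, max(s$length, 1), by = width)
    writeLines(substring(s$residues, starts,
                         pmin(starts + width - 1, s$length)), con)
  }
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' Disk coordinates (1-based inclusive) are converted to the in-memory
#' 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param seq_lengths optional named vector; when given, features on
#'   unknown seqids or beyond the sequence end raise a validation error.
#' @return a [feature_table()] (kind taken from the GFF3 type column;
#'   types outside the supported set load as `misc` with the original
#'   type kept in attribute `orig_type`).
#' @export
read_gff3 <- function(path, seq_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) return(feature_table())
  start1 <- GenomicRanges::start(gr); end1 <- GenomicRanges::end(gr)
  seqid <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  type <- as.character(mc$type)
  extra <- setdiff(colnames(mc), c("source", "type", "score", "phase"))
  attrs <- lapply(seq_along(gr), function(i) {
    vals <- lapply(extra, function(k) {
      v <- mc[[k]][i]
      if (is.list(v)) v <- unlist(v)
      v <- as.character(v)
      v[!is.na(v)]
    })
    names(vals) <- extra
    unlist(vals[lengths(vals) > 0]) %||% character()
  })
  ids <- vapply(seq_along(attrs), function(i)
    attrs[[i]][["ID"]] %||% sprintf("feat%04d", i), character(1))
  attrs <- lapply(attrs, function(a) a[names(a) != "ID"])
  kind <- ifelse(type %in% FEATURE_KINDS, type, "misc")
  for (i in which(kind == "misc" & type != "misc"))
    attrs[[i]]["orig_type"] <- type[i]
  if (!is.null(seq_lengths)) {
    unknown <- setdiff(unique(seqid), names(seq_lengths))
    if (length(unknown))
      stop("GFF3 seqid not among loaded sequences: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(end1 > seq_lengths[seqid]))
      stop("GFF3 feature beyond sequence length", call. = FALSE)
  }
  feature_table(id = ids, kind = kind, seqid = seqid,
                start = start1 - 1L, end = end1, strand = strand,
                attributes = attrs)
}

#' Write a feature table to GFF3
#'
#' In-memory 0-based half-open intervals are written as 1-based inclusive
#' coordinates; reading the file back with [read_gff3()] reproduces the
#' input collection.
#'
#' @param features a [feature_table()].
#' @param path output path; @param source value for column 2.
#' @export
write_gff3 <- function(features, path, source = "haplorga") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(features))) {
    at <- features$attributes[[i]]
    at <- at[names(at) != "ID"]
    enc <- function(x) gsub(";", "%3B", gsub("=", "%3D", gsub("%", "%25", x)))
    astr <- paste0("ID=", enc(features$id[i]))
    if (length(at))
      astr <- paste(c(astr, paste0(enc(names(at)), "=", enc(unname(at)))),
                    collapse = ";")
    writeLines(paste(features$seqid[i], source, features$kind[i],
                     features$start[i] + 1L, features$end[i],
                     ".", features$strand[i], ".", astr, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an EMBL flat file into an annotated locus
#'
#' Supports the ID/FT/SQ blocks and the location operators `join`,
#' `complement` and `order`; any other operator raises a parse error.
#' CDS features become gene models; `repeat_region` features become
#' `repeat_element` features; other feature keys load as `misc`.
#'
#' @param path EMBL flat file.
#' @return an [annotated_locus()].
#' @export
read_embl_flat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  idline <- grep("^ID", lines, value = TRUE)
  seq_id <- if (length(idline)) {
    sub("[;\\s].*", "", trimws(sub("^ID\\s+", "", idline[1])))
  } else "embl_record"
  sq <- grep("^SQ", lines)
  if (!length(sq)) stop("EMBL file without sequence (SQ) block: ", path,
                        call. = FALSE)
  seq_lines <- lines[(sq[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  hseq <- haplotype_sequence(seq_id, residues)

  # feature table: key lines start at col 6, continuation lines are
  # location text or /qualifiers
  ft <- lines[grepl("^FT", lines)]
  feats <- list(); cur <- NULL
  flush <- function(cur, feats) {
    if (!is.null(cur)) feats[[length(feats) + 1]] <- cur
    feats
  }
  for (ln in ft) {
    key <- substr(ln, 6, 20)
    rest <- trimws(substr(ln, 21, nchar(ln)))
    if (nzchar(trimws(key))) {
      feats <- flush(cur, feats)
      cur <- list(key = trimws(key), loc = rest, quals = character())
    } else if (!is.null(cur)) {
      if (startsWith(rest, "/")) cur$quals <- c(cur$quals, rest)
      else cur$loc <- paste0(cur$loc, rest)
    }
  }
  feats <- flush(cur, feats)

  genes <- list(); frows <- list(); gi <- 0
  for (fe in feats) {
    loc <- parse_embl_location(fe$loc)
    quals <- parse_embl_qualifiers(fe$quals)
    qv <- function(k) if (k %in% names(quals)) quals[[k]] else NULL
    fid <- qv("locus_tag") %||% qv("gene") %||% qv("note") %||%
      sprintf("%s_%03d", fe$key, length(frows) + 1)
    if (fe$key == "CDS") {
      gi <- gi + 1
      genes[[fid]] <- gene_model(fid, seq_id, loc$strand, loc$ranges,
                                 loc$ranges)
      frows[[length(frows) + 1]] <- feature_table(
        id = fid, kind = "gene", seqid = seq_id,
        start = min(loc$ranges[, 1]), end = max(loc$ranges[, 2]),
        strand = loc$strand, attributes = list(quals))
    } else {
      kind <- if (fe$key == "repeat_region") "repeat_element" else "misc"
      frows[[length(frows) + 1]] <- feature_table(
        id = fid, kind = kind, seqid = seq_id,
        start = min(loc$ranges[, 1]), end = max(loc$ranges[, 2]),
        strand = loc$strand, attributes = list(quals))
    }
  }
  features <- if (length(frows)) do.call(rbind, frows) else feature_table()
  annotated_locus(hseq, features, genes)
}

parse_embl_qualifiers <- function(quals) {
  kv <- regmatches(quals, regexec('^/([A-Za-z_]+)="?([^"]*)"?$', quals))
  kv <- kv[lengths(kv) == 3]
  setNames(vapply(kv, `[[`, "", 3), vapply(kv, `[[`, "", 2))
}

# recursive EMBL location parser for join/complement/order and a..b spans;
# returns list(ranges = 0-based half-open matrix, strand)
parse_embl_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  parse1 <- function(s, strand) {
    m <- regmatches(s, regexec("^(complement|join|order)\\((.*)\\)$", s))[[1]]
    if (length(m) == 3) {
      op <- m[2]; inner <- m[3]
      if (op == "complement") {
        r <- parse1(inner, strand)
        r$strand <- if (r$strand == "-") "+" else "-"
        return(r)
      }
      # split on top-level commas
      depth <- 0; parts <- c(); last <- 1; cs <- chars(inner)
      for (i in seq_along(cs)) {
        if (cs[i] == "(") depth <- depth + 1
        if (cs[i] == ")") depth <- depth - 1
        if (cs[i] == "," && depth == 0) {
          parts <- c(parts, substr(inner, last, i - 1)); last <- i + 1
        }
      }
      parts <- c(parts, substr(inner, last, nchar(inner)))
      sub <- lapply(parts, parse1, strand = strand)
      strands <- unique(vapply(sub, `[[`, "", "strand"))
      return(list(ranges = do.call(rbind, lapply(sub, `[[`, "ranges")),
                  strand = if (length(strands) == 1) strands else "."))
    }
    m <- regmatches(s, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", s))[[1]]
    if (length(m) == 3)
      return(list(ranges = as_ranges(as.integer(m[2]) - 1L, as.integer(m[3])),
                  strand = strand))
    m <- regmatches(s, regexec("^(\\d+)$", s))[[1]]
    if (length(m) == 2)
      return(list(ranges = as_ranges(as.integer(m[2]) - 1L, as.integer(m[2])),
                  strand = strand))
    stop("unsupported EMBL location: ", loc, call. = FALSE)
  }
  r <- parse1(loc, "+")
  r$ranges <- r$ranges[order(r$ranges[, 1]), , drop = FALSE]
  r
}

#' Extract the coding sequence of a gene model
#'
#' Concatenates the CDS intervals (forward-strand order) and
#' reverse-complements the result for minus-strand genes.
#'
#' @param gene a [gene_model()].
#' @param sequence a [haplotype_sequence()] or character scalar.
#' @return character scalar with attribute `incomplete_codon` set to
#'   `TRUE` when the length is not a multiple of 3 (such genes are
#'   pseudogene/fragment candidates, not errors).
#' @export
extract_cds <- function(gene, sequence) {
  res <- if (is.character(sequence)) sequence else sequence$residues
  if (!nrow(gene$cds)) stop("gene ", gene$id, " has no CDS intervals",
                            call. = FALSE)
  parts <- vapply(seq_len(nrow(gene$cds)), function(i)
    substr(res, gene$cds[i, 1] + 1, gene$cds[i, 2]), character(1))
  cds <- paste(parts, collapse = "")
  if (identical(gene$strand, "-")) cds <- dna_revcomp(cds)
  attr(cds, "incomplete_codon") <- (nchar(cds) %% 3) != 0
  cds
}
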