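# Independent oracles and small fixture builders shared across tests.

SENSE_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_sense_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

random_dna_str <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_positions <- function(s, idx, alphabet = c("A", "C", "G", "T")) {
  cc <- strsplit(s, "")[[1]]
  for (i in idx) cc[i] <- sample(setdiff(alphabet, cc[i]), 1)
  paste(cc, collapse = "")
}

# ---- brute-force Nei-Gojobori pathway enumerator ----------------------
# Written independently of the package implementation: explicit
# permutation list, explicit path walk through intermediate codons,
# same stop-codon pathway exclusion convention.

brute_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  if (is.na(gc[codon]) || gc[codon] == "*") return(NA_real_)
  s <- 0
  for (p in 1:3) {
    orig <- substr(codon, p, p)
    for (nt in setdiff(c("A", "C", "G", "T"), orig)) {
      mut <- codon
      substr(mut, p, p) <- nt
      if (!is.na(gc[mut]) && gc[mut] == gc[codon]) s <- s + 1 / 3
    }
  }
  s
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

brute_pair_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  res <- list()
  for (ord in all_permutations(pos)) {
    cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[nxt] == "*") { valid <- FALSE; break }
      if (gc[cur] == gc[nxt]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- c(sd, nd, valid)
  }
  m <- do.call(rbind, res)
  use <- m[, 3] == 1
  if (!any(use)) use <- rep(TRUE, nrow(m))
  c(sd = mean(m[use, 1]), nd = mean(m[use, 2]))
}

brute_nei_gojobori <- function(cds_a, cds_b) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cds_a) / 3
  S <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_len(n)) {
    c1 <- substr(cds_a, 3 * i - 2, 3 * i)
    c2 <- substr(cds_b, 3 * i - 2, 3 * i)
    if (!grepl("^[ACGT]{3}$", c1) || !grepl("^[ACGT]{3}$", c2)) next
    if (gc[c1] == "*" || gc[c2] == "*") next
    used <- used + 1
    S <- S + (brute_codon_sites(c1) + brute_codon_sites(c2)) / 2
    d <- brute_pair_diffs(c1, c2)
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
  }
  list(S = S, N = 3 * used - S, Sd = unname(Sd), Nd = unname(Nd),
       usable_codons = used)
}

# build a chimeric sequence from two diverged parents with a known junction
make_chimera <- function(len = 2000, junction = 1000, divergence = 0.05) {
  pa <- random_dna_str(len)
  pb <- mutate_positions(pa, sample(len, round(len * divergence)))
  list(parent_a = pa, parent_b = pb,
       chimera = paste0(substr(pa, 1, junction),
                        substr(pb, junction + 1, len)))
}

# 0-based half-open interval matrix (mirrors the package-internal helper)
as_r <- function(s, e) cbind(start = as.integer(s), end = as.integer(e))
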