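# Independent brute-force oracles. These deliberately share no code with the
# package internals: translation uses a hand-written codon table, enumeration
# and filtering are naive set-based loops.

CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  g <- expand.grid(b, b, b, stringsAsFactors = FALSE)
  codons <- sort(paste0(g[[1]], g[[2]], g[[3]]))
  aa <- setNames(rep(NA_character_, 64), codons)
  assign_aa <- function(cds, a) aa[cds] <<- a
  assign_aa(c("TTT", "TTC"), "F"); assign_aa(c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), "L")
  assign_aa(c("ATT", "ATC", "ATA"), "I"); assign_aa("ATG", "M")
  assign_aa(c("GTT", "GTC", "GTA", "GTG"), "V")
  assign_aa(c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"), "S")
  assign_aa(c("CCT", "CCC", "CCA", "CCG"), "P")
  assign_aa(c("ACT", "ACC", "ACA", "ACG"), "T")
  assign_aa(c("GCT", "GCC", "GCA", "GCG"), "A")
  assign_aa(c("TAT", "TAC"), "Y"); assign_aa(c("TAA", "TAG", "TGA"), "*")
  assign_aa(c("CAT", "CAC"), "H"); assign_aa(c("CAA", "CAG"), "Q")
  assign_aa(c("AAT", "AAC"), "N"); assign_aa(c("AAA", "AAG"), "K")
  assign_aa(c("GAT", "GAC"), "D"); assign_aa(c("GAA", "GAG"), "E")
  assign_aa(c("TGT", "TGC"), "C"); assign_aa("TGG", "W")
  assign_aa(c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"), "R")
  assign_aa(c("GGT", "GGC", "GGA", "GGG"), "G")
  aa
})

oracle_translate <- function(nt) {
  n <- nchar(nt)
  codons <- substring(nt, seq(1, n, 3), pmin(seq(3, n + 2, 3), n))
  paste(CODON_TABLE[codons], collapse = "")
}

# naive enumeration of all chimeras of a parental family, mirroring the
# published filter sequence with plain loops and set operations
oracle_enumerate <- function(family) {
  par_nt <- vapply(family, function(g) paste0(g$exon1_cds, g$exon2_cds),
                   character(1))
  par_aa <- vapply(par_nt, function(s) sub("\\*$", "", oracle_translate(s)),
                   character(1))
  out <- character(0)
  for (d in family) for (a in family) {
    bmax <- min(nchar(d$exon2_cds), nchar(a$exon2_cds)) - 1L
    pair_seen <- character(0)
    if (bmax < 1L) next
    for (b in seq_len(bmax)) {
      cds <- paste0(d$exon1_cds,
                    substr(d$exon2_cds, 1, b),
                    substr(a$exon2_cds, b + 1, nchar(a$exon2_cds)))
      if (nchar(cds) %% 3 != 0) next
      aa <- oracle_translate(cds)
      stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
      if (length(stops) != 1 || stops[1] != nchar(aa)) next
      prot <- sub("\\*$", "", aa)
      mat <- substr(prot, d$mature_start, d$mature_start + d$mature_len - 1)
      ncys <- lengths(regmatches(mat, gregexpr("C", mat)))
      if (nchar(mat) != d$mature_len || ncys != d$n_cys) next
      if (cds %in% par_nt) next
      if (prot %in% par_aa) next
      if (cds %in% pair_seen) next
      pair_seen <- c(pair_seen, cds)
      out <- c(out, cds)
    }
  }
  # global: drop protein-identical-to-any-parental, then nt dedup
  keep <- vapply(out, function(s) !(sub("\\*$", "", oracle_translate(s)) %in% par_aa),
                 logical(1))
  unique(out[keep])
}

# naive digestion: walk the protein residue by residue
oracle_digest <- function(protein, cleave_after, blocked_by_next = character(0)) {
  aa <- strsplit(protein, "")[[1]]
  frags <- character(0)
  cur <- ""
  for (i in seq_along(aa)) {
    cur <- paste0(cur, aa[i])
    cut <- aa[i] %in% cleave_after && i < length(aa) &&
      !(aa[i + 1] %in% blocked_by_next)
    if (cut) { frags <- c(frags, cur); cur <- "" }
  }
  c(frags, cur)
}

# naive window scan for peptide presence in a proteome
oracle_in_proteome <- function(peptide, proteome, max_mm = 0) {
  p <- strsplit(peptide, "")[[1]]
  L <- length(p)
  for (prot in proteome) {
    s <- strsplit(prot, "")[[1]]
    if (length(s) < L) next
    for (off in 0:(length(s) - L))
      if (sum(s[off + seq_len(L)] != p) <= max_mm) return(TRUE)
  }
  FALSE
}

# minimal mismatch over all windows of a proteome
oracle_min_mismatch <- function(peptide, proteome) {
  p <- strsplit(peptide, "")[[1]]
  L <- length(p)
  best <- Inf
  for (prot in proteome) {
    s <- strsplit(prot, "")[[1]]
    if (length(s) < L) next
    for (off in 0:(length(s) - L))
      best <- min(best, sum(s[off + seq_len(L)] != p))
  }
  best
}

# brute-force best split of a read between two parents at fixed offsets
oracle_best_split <- function(read, left, right, off_l, off_r) {
  r <- strsplit(read, "")[[1]]
  l <- strsplit(left, "")[[1]][off_l + seq_along(r)]
  rr <- strsplit(right, "")[[1]][off_r + seq_along(r)]
  L <- length(r)
  best <- NULL
  for (b in 0:L) {
    ml <- if (b > 0) sum(r[1:b] != l[1:b]) else 0L
    mr <- if (b < L) sum(r[(b + 1):L] != rr[(b + 1):L]) else 0L
    if (is.null(best) || ml + mr < best$tot)
      best <- list(b = b, ml = ml, mr = mr, tot = ml + mr)
  }
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_protein <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                           n, replace = TRUE), collapse = "")

# small synthetic family used across tests
family_small <- function(n = 3, seed = 7, identity = 0.9)
  make_family(n_genes = n, identity = identity, seed = seed)
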