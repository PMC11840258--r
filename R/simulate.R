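AA_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- vapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAStringSet(cd),
                                       no.init.codon = TRUE)), character(1))
  split(codons, aa)
})

random_codon_for <- function(aa) {
  opts <- AA_CODONS[[aa]]
  opts[sample.int(length(opts), 1L)]
}

#' Generate a synthetic defensin-like gene family
#'
#' Emulates the mouse Defa family for testing without downloads: `n_genes`
#' two-exon genes encoding a ~92-aa pre-pro-protein (19-aa signal peptide,
#' pro region, 33-aa mature peptide with six cysteines at family-conserved
#' offsets), with high inter-gene nucleotide identity. Generation works
#' backwards from a random valid ancestor (mature peptide with the cysteine
#' scaffold, then codons), then mutates each gene at random non-constrained
#' nucleotide positions to hit the target identity; mutations that would
#' create a stop codon, touch the scaffold cysteines or the stop codon, or
#' change the mature cysteine count are rejected, so every gene satisfies the
#' gene-model invariants by construction.
#'
#' @param n_genes family size (default 28, the mouse Defa count).
#' @param identity target mean pairwise nucleotide identity (default 0.90).
#' @param prepro_len,signal_len,mature_len protein segmentation in aa
#'   (defaults 92 / 19 / 33).
#' @param n_cys conserved cysteines in the mature region (default 6).
#' @param exon1_frac fraction of the CDS in exon 1 (default 0.52; the exon
#'   boundary must stay upstream of the mature-peptide coding region).
#' @param seed RNG seed; the family is byte-identical per seed.
#' @return list of [defensin_gene()] objects with attribute `config`.
#' @export
make_family <- function(n_genes = 28L, identity = 0.90, prepro_len = 92L,
                        signal_len = 19L, mature_len = 33L, n_cys = 6L,
                        exon1_frac = 0.52, seed = 1L) {
  if (identity < 0.55)
    stop("identity too low to conserve the cysteine scaffold")
  set.seed(seed)
  mature_start <- prepro_len - mature_len + 1L
  cds_len <- prepro_len * 3L + 3L
  exon1_len <- min(floor(cds_len * exon1_frac),
                   (mature_start - 1L) * 3L)

  # ancestor protein: no cysteines outside the scaffold
  alphabet <- setdiff(strsplit("ARNDQEGHILKMFPSTWYV", "")[[1]], "C")
  prot <- sample(alphabet, prepro_len, replace = TRUE)
  prot[1] <- "M"
  cys_at <- mature_start - 1L +
    as.integer(round(seq(2L, mature_len - 1L, length.out = n_cys)))
  prot[cys_at] <- "C"
  anc <- c(vapply(prot, random_codon_for, character(1), USE.NAMES = FALSE),
           sample(c("TAA", "TGA", "TAG"), 1L))
  anc_nt <- strsplit(paste(anc, collapse = ""), "")[[1]]

  frozen <- c(as.vector(vapply(cys_at, function(a) (a - 1L) * 3L + 1:3,
                               integer(3))),
              (prepro_len * 3L) + 1:3)          # cysteine codons + stop codon
  mature_nt <- ((mature_start - 1L) * 3L + 1L):(prepro_len * 3L)
  mutable <- setdiff(seq_len(cds_len), frozen)
  n_mut <- max(1L, round(cds_len * (1 - identity) / 2))
  bases <- c("A", "C", "G", "T")

  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    nt <- anc_nt
    done <- 0L; tries <- 0L
    while (done < n_mut && tries < 50L * n_mut) {
      tries <- tries + 1L
      pos <- mutable[sample.int(length(mutable), 1L)]
      new <- sample(setdiff(bases, nt[pos]), 1L)
      old <- nt[pos]
      nt[pos] <- new
      codon_i <- (pos - 1L) %/% 3L
      codon <- paste(nt[codon_i * 3L + 1:3], collapse = "")
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(codon), no.init.codon = TRUE))
      bad <- aa == "*" || (aa == "C" && pos %in% mature_nt) ||
        (pos <= 3L && aa != "M")
      if (bad) nt[pos] <- old else done <- done + 1L
    }
    cds <- paste(nt, collapse = "")
    genes[[g]] <- defensin_gene(sprintf("SynDefa%02d", g),
                                substr(cds, 1L, exon1_len),
                                substr(cds, exon1_len + 1L, cds_len),
                                signal_len = signal_len,
                                mature_len = mature_len,
                                mature_start = mature_start,
                                n_cys = n_cys)
  }
  attr(genes, "config") <- list(n_genes = n_genes, identity = identity,
                                prepro_len = prepro_len,
                                signal_len = signal_len,
                                mature_len = mature_len, n_cys = n_cys,
                                exon1_len = exon1_len, seed = seed)
  genes
}

#' Mean pairwise nucleotide identity of a family
#'
#' @param family list of [defensin_gene()] objects.
#' @return mean over gene pairs of the fraction of identical CDS positions.
#' @export
family_identity <- function(family) {
  seqs <- lapply(family, function(g) strsplit(g$cds, "")[[1]])
  n <- length(seqs)
  if (n < 2L) return(1)
  tot <- 0; cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + mean(seqs[[i]] == seqs[[j]])
    cnt <- cnt + 1L
  }
  tot / cnt
}

#' Write / read a family as FASTA plus metadata TSV
#'
#' @param family list of [defensin_gene()] objects.
#' @param fasta,tsv file paths.
#' @return `family` (write) or the reconstructed family (read).
#' @export
write_family <- function(family, fasta, tsv) {
  ids <- vapply(family, `[[`, character(1), "gene_id")
  cds <- vapply(family, `[[`, character(1), "cds")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(cds, ids)),
                              fasta)
  meta <- data.frame(gene_id = ids,
                     exon1_len = vapply(family, function(g)
                       nchar(g$exon1_cds), integer(1)),
                     signal_len = vapply(family, `[[`, integer(1), "signal_len"),
                     mature_start = vapply(family, `[[`, integer(1), "mature_start"),
                     mature_len = vapply(family, `[[`, integer(1), "mature_len"))
  write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(family)
}

#' @rdname write_family
#' @export
read_family <- function(fasta, tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- read.delim(tsv, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    cds <- as.character(seqs[[meta$gene_id[i]]])
    defensin_gene(meta$gene_id[i],
                  substr(cds, 1L, meta$exon1_len[i]),
                  substr(cds, meta$exon1_len[i] + 1L, nchar(cds)),
                  signal_len = meta$signal_len[i],
                  mature_len = meta$mature_len[i],
                  mature_start = meta$mature_start[i])
  })
}

#' Assemble a chimera-spiked transcript pool
#'
#' Builds the molecule-fraction truth for a simulated Paneth-cell mRNA pool:
#' the gene family occupies `family_fraction` of all molecules (85.19% by
#' default, the measured Defa share), of which `chimera_fraction` (0.24% by
#' default) is chimeric; parental abundances are log-normal with the most
#' abundant gene rescaled to `dominant_share` of the family (Defa24-like);
#' the non-family remainder is spread log-normally over `n_background`
#' synthetic background transcripts.
#'
#' The chimeric load is carried by an active subset of the enumerated
#' chimeras, sized so each active chimera averages `chimera_tpm_mean` TPM
#' (detected chimeras typically sit at 5-10 TPM); the remaining enumerated
#' chimeras are present in the reference but absent from the pool, exactly as
#' most theoretical chimeras are never observed in a given sample.
#'
#' @param family list of [defensin_gene()] objects.
#' @param chimeras `ChimeraSet` or members data frame (`id`, `cds`); may be
#'   `NULL` only when `chimera_fraction = 0`.
#' @param chimera_fraction chimeric fraction of family molecules.
#' @param family_fraction family fraction of all molecules.
#' @param dominant_share family-molecule share of the most abundant parental.
#' @param sdlog log-normal spread of parental abundances.
#' @param chimera_tpm_mean target mean TPM per active chimera; sets the size
#'   of the active subset.
#' @param chimera_sdlog log-normal spread among active chimeras.
#' @param n_active_chimeras explicit active-subset size (overrides
#'   `chimera_tpm_mean`).
#' @param n_background,background_len_range background transcript count and
#'   length range (nt).
#' @param n_molecules optionally sample a finite pool of this many molecules
#'   (multinomial); adds a `count` column.
#' @param seed RNG seed.
#' @return `transcript_pool` data frame: `id`, `sequence`, `role`,
#'   `donor_id`, `acceptor_id`, `fraction` (+ `count`). Active chimeras have
#'   `fraction > 0`; inactive ones are omitted.
#' @export
make_pool <- function(family, chimeras = NULL, chimera_fraction = 0.0024,
                      family_fraction = 0.8519, dominant_share = 0.164,
                      sdlog = 1.5, chimera_tpm_mean = 7.5,
                      chimera_sdlog = 0.3, n_active_chimeras = NULL,
                      n_background = 20L,
                      background_len_range = c(500L, 2000L),
                      n_molecules = NULL, seed = 1L) {
  set.seed(seed)
  if (chimera_fraction >= 1) stop("chimera_fraction must be < 1")
  ch <- if (inherits(chimeras, "ChimeraSet")) chimeras$members else chimeras
  if (chimera_fraction > 0 && (is.null(ch) || nrow(ch) == 0L))
    stop("chimera_fraction > 0 but the chimera set is empty")

  ids <- vapply(family, `[[`, character(1), "gene_id")
  w <- rlnorm(length(ids), 0, sdlog)
  w <- w / sum(w)
  if (length(ids) > 1L && !is.null(dominant_share)) {
    # pin the most abundant gene to its configured family share; the others
    # fill the remainder proportionally, water-filling-capped just below it
    # so the pinned gene stays dominant
    top <- which.max(w)
    cap <- 0.99 * dominant_share
    rest <- w[-top] / sum(w[-top]) * (1 - dominant_share)
    capped <- rep(FALSE, length(rest))
    repeat {
      over <- rest > cap + 1e-15
      if (!any(over)) break
      deficit <- sum(rest[over] - cap)
      rest[over] <- cap
      capped <- capped | over
      free <- !capped & rest > 0
      if (!any(free)) break    # infeasible for small families: renormalised
      rest[free] <- rest[free] * (1 + deficit / sum(rest[free]))
    }
    w[-top] <- rest
    w[top] <- dominant_share
    w <- w / sum(w)
  }
  parental <- data.frame(id = ids,
                         sequence = vapply(family, `[[`, character(1), "cds"),
                         role = "parental", donor_id = NA_character_,
                         acceptor_id = NA_character_,
                         fraction = w * family_fraction * (1 - chimera_fraction),
                         stringsAsFactors = FALSE)
  pool <- parental
  if (chimera_fraction > 0) {
    load_tpm <- chimera_fraction * family_fraction * 1e6
    n_active <- if (!is.null(n_active_chimeras)) n_active_chimeras
                else max(1L, round(load_tpm / chimera_tpm_mean))
    n_active <- min(n_active, nrow(ch))
    act <- sort(sample.int(nrow(ch), n_active))
    cw <- rlnorm(n_active, 0, chimera_sdlog)
    cw <- cw / sum(cw)
    pool <- rbind(pool,
                  data.frame(id = ch$id[act], sequence = ch$cds[act],
                             role = "chimera",
                             donor_id = ch$donor_id[act],
                             acceptor_id = ch$acceptor_id[act],
                             fraction = cw * family_fraction * chimera_fraction,
                             stringsAsFactors = FALSE))
  }
  if (family_fraction < 1 && n_background > 0L) {
    lens <- sample(background_len_range[1]:background_len_range[2],
                   n_background, replace = TRUE)
    bseq <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    bw <- rlnorm(n_background, 0, sdlog)
    bw <- bw / sum(bw)
    pool <- rbind(pool,
                  data.frame(id = sprintf("Background%02d", seq_len(n_background)),
                             sequence = bseq, role = "background",
                             donor_id = NA_character_,
                             acceptor_id = NA_character_,
                             fraction = bw * (1 - family_fraction),
                             stringsAsFactors = FALSE))
  }
  pool$fraction <- pool$fraction / sum(pool$fraction)
  if (!is.null(n_molecules))
    pool$count <- as.integer(rmultinom(1, n_molecules, pool$fraction))
  rownames(pool) <- NULL
  class(pool) <- c("transcript_pool", class(pool))
  pool
}

mutate_read <- function(read, positions) {
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    cur <- substr(read, p, p)
    substr(read, p, p) <- sample(setdiff(bases, cur), 1L)
  }
  read
}

#' Simulate short reads from a transcript pool
#'
#' Draws reads with uniform fragment start positions; each transcript's read
#' probability is proportional to its molecule abundance times the number of
#' valid start positions (`length - read_len + 1`). Substitution errors are
#' planted per base at `error_rate` (no indels). Deterministic per seed; the
#' truth table records each read's source transcript, start and error count.
#'
#' @param pool a [make_pool()] data frame (uses `count` if present, else
#'   `fraction`).
#' @param n_reads number of reads (fragments in paired mode).
#' @param read_len read length in nt (the study regime is 60-80).
#' @param error_rate per-base substitution rate.
#' @param paired also emit a reverse-complemented mate from the fragment end.
#' @param fragment_len fragment length in paired mode.
#' @param seed RNG seed.
#' @return list with `reads` (named character; in paired mode `mate1` and
#'   `mate2`) and `truth` (data frame `read_id`, `source_id`, `role`, `start`,
#'   `n_errors`).
#' @export
simulate_reads <- function(pool, n_reads = 1e5, read_len = 70L,
                           error_rate = 0.001, paired = FALSE,
                           fragment_len = NULL, seed = 1L) {
  set.seed(seed)
  span <- if (paired) {
    if (is.null(fragment_len)) fragment_len <- 2L * read_len
    fragment_len
  } else read_len
  ok <- nchar(pool$sequence) >= span
  if (!all(ok)) stop("read/fragment longer than the shortest pool transcript")
  ab <- if (!is.null(pool$count)) pool$count else pool$fraction
  wt <- ab * (nchar(pool$sequence) - span + 1)
  ti <- sample.int(nrow(pool), n_reads, replace = TRUE, prob = wt)
  nstart <- nchar(pool$sequence)[ti] - span + 1L
  start <- 1L + floor(runif(n_reads) * nstart)
  frag <- substring(pool$sequence[ti], start, start + span - 1L)
  ids <- sprintf("read%07d", seq_len(n_reads))

  add_errors <- function(reads) {
    nerr <- rbinom(length(reads), read_len, error_rate)
    idx <- which(nerr > 0L)
    for (i in idx)
      reads[i] <- mutate_read(reads[i],
                              sample.int(read_len, nerr[i]))
    list(reads = reads, n_errors = nerr)
  }
  if (!paired) {
    e <- add_errors(frag)
    truth <- data.frame(read_id = ids, source_id = pool$id[ti],
                        role = pool$role[ti], start = start,
                        n_errors = e$n_errors, stringsAsFactors = FALSE)
    return(list(reads = setNames(e$reads, ids), truth = truth,
                read_len = read_len))
  }
  m1 <- substr(frag, 1L, read_len)
  m2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substr(frag, span - read_len + 1L, span))))
  e1 <- add_errors(m1); e2 <- add_errors(m2)
  truth <- data.frame(read_id = ids, source_id = pool$id[ti],
                      role = pool$role[ti], start = start,
                      n_errors = e1$n_errors + e2$n_errors,
                      stringsAsFactors = FALSE)
  list(reads = setNames(e1$reads, paste0(ids, "/1")),
       mate2 = setNames(e2$reads, paste0(ids, "/2")),
       truth = truth, read_len = read_len)
}

#' Write reads to FASTQ
#'
#' @param reads named character vector of read sequences.
#' @param path output path (`.gz` for compressed).
#' @param quality constant per-base quality character.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(quality, n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}
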