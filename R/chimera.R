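#' Defensin gene model
#'
#' A two-exon alpha-defensin gene in CDS orientation. The CDS (exon-1 part
#' plus exon-2 part, stop codon included) must translate cleanly: length
#' divisible by 3, exactly one stop codon at the end, and exactly `n_cys`
#' cysteines in the mature region. The pre-pro-protein is ~92 aa: a 19-aa
#' signal peptide, a pro region, and the ~33-aa mature peptide (encoded by
#' exon 2) that carries the six disulfide-forming cysteines.
#'
#' @param gene_id gene identifier.
#' @param exon1_cds,exon2_cds nucleotide strings (A/C/G/T); their
#'   concatenation is the CDS including the stop codon.
#' @param signal_len signal peptide length in aa (default 19).
#' @param mature_len mature peptide length in aa (default 33).
#' @param mature_start 1-based aa offset of the mature peptide in the
#'   pre-pro-protein; default places it at the C terminus.
#' @param n_cys required cysteine count in the mature region (default 6).
#' @return an object of class `DefensinGene`.
#' @export
defensin_gene <- function(gene_id, exon1_cds, exon2_cds, signal_len = 19L,
                          mature_len = 33L, mature_start = NULL, n_cys = 6L) {
  exon1_cds <- toupper(exon1_cds); exon2_cds <- toupper(exon2_cds)
  cds <- paste0(exon1_cds, exon2_cds)
  chk <- check_frame_and_stop(cds)
  if (!chk$pass)
    stop("gene ", gene_id, ": invalid CDS (", chk$reason, ")")
  prepro <- translate_cds(cds)
  if (is.null(mature_start))
    mature_start <- nchar(prepro) - mature_len + 1L
  if (mature_start < 1L || mature_start + mature_len - 1L > nchar(prepro))
    stop("gene ", gene_id, ": mature region outside pre-pro-protein")
  mature <- substr(prepro, mature_start, mature_start + mature_len - 1L)
  if (cys_count(mature) != n_cys)
    stop("gene ", gene_id, ": mature region has ", cys_count(mature),
         " cysteines, expected ", n_cys)
  structure(list(gene_id = gene_id, exon1_cds = exon1_cds,
                 exon2_cds = exon2_cds, cds = cds, prepro = prepro,
                 signal_len = as.integer(signal_len),
                 mature_start = as.integer(mature_start),
                 mature_len = as.integer(mature_len),
                 mature = mature, n_cys = as.integer(n_cys)),
            class = "DefensinGene")
}

#' @export
print.DefensinGene <- function(x, ...) {
  cat("DefensinGene", x$gene_id, "| CDS", nchar(x$cds), "nt (exon1",
      nchar(x$exon1_cds), "+ exon2", nchar(x$exon2_cds), ") | pre-pro",
      nchar(x$prepro), "aa | mature", x$mature_len, "aa at",
      x$mature_start, "\n")
  invisible(x)
}

translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

translate_many <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

cys_count <- function(aa) {
  nchar(aa) - nchar(gsub("C", "", aa, fixed = TRUE))
}

cys_offsets <- function(aa) {
  as.integer(gregexpr("C", aa, fixed = TRUE)[[1]])
}

#' Reading-frame and stop-codon check
#'
#' Passes iff the sequence length is a multiple of 3 and translation contains
#' exactly one stop codon, located at the end.
#'
#' @param cds nucleotide string (A/C/G/T only; anything else is an error).
#' @return list with `pass` (logical) and `reason` (`NA` or one of
#'   `"frameshift"`, `"premature_stop"`, `"no_stop"`).
#' @export
check_frame_and_stop <- function(cds) {
  cds <- toupper(cds)
  if (!nzchar(cds)) stop("empty sequence")
  if (grepl("[^ACGT]", cds)) stop("non-ACGT characters in sequence")
  if (nchar(cds) %% 3L != 0L)
    return(list(pass = FALSE, reason = "frameshift"))
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           no.init.codon = TRUE))
  nstop <- nchar(aa) - nchar(gsub("*", "", aa, fixed = TRUE))
  if (nstop == 0L) return(list(pass = FALSE, reason = "no_stop"))
  if (nstop > 1L || !endsWith(aa, "*"))
    return(list(pass = FALSE, reason = "premature_stop"))
  list(pass = TRUE, reason = NA_character_)
}

#' Cysteine-structure check of a mature peptide
#'
#' `count6` passes iff the mature region contains exactly `n_cys` cysteines.
#' `parental_pattern` additionally requires the cysteine offsets to equal one
#' of the supplied parental offset vectors (the stricter reading of "typical
#' cysteine structure").
#'
#' @param mature_peptide amino-acid string of the mature region.
#' @param mode `"count6"` (default) or `"parental_pattern"`.
#' @param parental_offsets list of integer vectors of parental cysteine
#'   offsets (required for `parental_pattern`).
#' @param n_cys expected cysteine count.
#' @return logical.
#' @export
check_cysteine_structure <- function(mature_peptide,
                                     mode = c("count6", "parental_pattern"),
                                     parental_offsets = NULL, n_cys = 6L) {
  mode <- match.arg(mode)
  if (cys_count(mature_peptide) != n_cys) return(FALSE)
  if (mode == "count6") return(TRUE)
  if (is.null(parental_offsets))
    stop("parental_pattern mode needs parental_offsets")
  off <- cys_offsets(mature_peptide)
  any(vapply(parental_offsets, function(p) identical(off, as.integer(p)),
             logical(1)))
}

# all candidate crossover products of one ordered pair, with filter ledger
pair_candidates <- function(donor, acceptor, cys_mode = "count6") {
  len_d <- nchar(donor$exon2_cds); len_a <- nchar(acceptor$exon2_cds)
  bmax <- min(len_d, len_a) - 1L
  empty <- data.frame(donor_id = character(), acceptor_id = character(),
                      breakpoint = integer(), cds = character(),
                      protein = character(), mature_peptide = character(),
                      stringsAsFactors = FALSE)
  ledger <- data.frame(donor_id = character(), acceptor_id = character(),
                       breakpoint = integer(), filter = character(),
                       stringsAsFactors = FALSE)
  if (bmax < 1L) return(list(members = empty, rejected = ledger))
  b <- seq_len(bmax)
  cds <- paste0(donor$exon1_cds,
                substring(donor$exon2_cds, 1L, b),
                substring(acceptor$exon2_cds, b + 1L, len_a))
  reason <- rep(NA_character_, bmax)

  inframe <- nchar(cds) %% 3L == 0L
  reason[!inframe] <- "frameshift"
  ok <- inframe

  protein <- rep(NA_character_, bmax)
  mature <- rep(NA_character_, bmax)
  if (any(ok)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds[ok]), no.init.codon = TRUE))
    nstop <- nchar(aa) - nchar(gsub("*", "", aa, fixed = TRUE))
    good_stop <- nstop == 1L & endsWith(aa, "*")
    reason[ok][!good_stop] <- "premature_stop"
    protein[ok] <- sub("\\*$", "", aa)
    ok[ok] <- good_stop
  }
  if (any(ok)) {
    ms <- donor$mature_start; ml <- donor$mature_len
    mature[ok] <- substr(protein[ok], ms, ms + ml - 1L)
    cys_ok <- vapply(mature[ok], function(m) {
      nchar(m) == ml && check_cysteine_structure(
        m, mode = cys_mode,
        parental_offsets = list(cys_offsets(donor$mature),
                                cys_offsets(acceptor$mature)),
        n_cys = donor$n_cys)
    }, logical(1), USE.NAMES = FALSE)
    reason[ok][!cys_ok] <- "cysteine"
    ok[ok] <- cys_ok
  }
  if (any(ok)) {
    par_nt <- c(donor$cds, acceptor$cds)
    hit <- cds[ok] %in% par_nt
    reason[ok][hit] <- "parental_nt"
    ok[ok] <- !hit
  }
  if (any(ok)) {
    par_aa <- c(donor$prepro, acceptor$prepro)
    hit <- protein[ok] %in% par_aa
    reason[ok][hit] <- "parental_protein"
    ok[ok] <- !hit
  }
  if (any(ok)) {
    # per-pair nucleotide dedup keeping the smallest breakpoint
    dup <- rep(FALSE, bmax)
    dup[ok] <- duplicated(cds[ok])
    reason[dup] <- "pair_duplicate"
    ok[dup] <- FALSE
  }
  members <- data.frame(donor_id = rep(donor$gene_id, sum(ok)),
                        acceptor_id = rep(acceptor$gene_id, sum(ok)),
                        breakpoint = b[ok], cds = cds[ok],
                        protein = protein[ok],
                        mature_peptide = mature[ok],
                        stringsAsFactors = FALSE)
  rej <- data.frame(donor_id = rep(donor$gene_id, sum(!ok)),
                    acceptor_id = rep(acceptor$gene_id, sum(!ok)),
                    breakpoint = b[!ok], filter = reason[!ok],
                    stringsAsFactors = FALSE)
  list(members = members, rejected = rej)
}

#' Chimeric transcripts of one donor/acceptor pair
#'
#' Enumerates every crossover product of a donor and an acceptor gene: for
#' each nucleotide breakpoint `b` in `[1, exon2_len - 1]` the candidate CDS is
#' the donor's exon 1 plus the first `b` nt of the donor's exon-2 CDS followed
#' by the acceptor's exon-2 CDS from the same offset (ungapped homologous
#' coordinates). Candidates are filtered: in frame with a single terminal stop
#' codon; intact cysteine structure of the mature region; different from both
#' parentals at the nucleotide and the protein level; per-pair nucleotide
#' duplicates collapsed to the smallest breakpoint.
#'
#' @param donor,acceptor [defensin_gene()] objects. Exon 1 always comes from
#'   the donor; a self-pair therefore yields no candidates (every product
#'   equals the parental).
#' @param cys_mode cysteine filter mode, see [check_cysteine_structure()].
#' @return data frame of chimeric transcripts (`donor_id`, `acceptor_id`,
#'   `breakpoint`, `cds`, `protein`, `mature_peptide`).
#' @export
generate_pair_chimeras <- function(donor, acceptor, cys_mode = "count6") {
  pair_candidates(donor, acceptor, cys_mode)$members
}

#' Enumerate all theoretical chimeric transcripts of a gene family
#'
#' Runs [generate_pair_chimeras()] over every ordered pair of parentals
#' (including self-pairs, which contribute nothing), merges the per-pair
#' results, removes candidates whose protein equals ANY parental
#' pre-pro-protein, and collapses global nucleotide duplicates to a single
#' member whose provenance lists all contributing (donor, acceptor,
#' breakpoint) origins.
#'
#' @param parentals list of [defensin_gene()] objects (at least 2).
#' @param cys_mode cysteine filter mode.
#' @return a `ChimeraSet`: list with `members` (data frame with `id`,
#'   `donor_id`, `acceptor_id`, `breakpoint`, `cds`, `protein`,
#'   `mature_peptide`, `origins`), `rejected` (per-candidate filter ledger)
#'   and `stats` (named counts per filter).
#' @export
enumerate_all <- function(parentals, cys_mode = "count6") {
  if (length(parentals) < 2L) stop("need at least 2 parental genes")
  ids <- vapply(parentals, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate parental gene ids")
  mem <- list(); rej <- list()
  for (d in parentals) for (a in parentals) {
    res <- pair_candidates(d, a, cys_mode)
    mem[[length(mem) + 1L]] <- res$members
    rej[[length(rej) + 1L]] <- res$rejected
  }
  members <- do.call(rbind, mem)
  rejected <- do.call(rbind, rej)

  # global: drop proteins identical to any parental
  par_aa <- vapply(parentals, `[[`, character(1), "prepro")
  hit <- members$protein %in% par_aa
  if (any(hit)) {
    rejected <- rbind(rejected,
                      data.frame(donor_id = members$donor_id[hit],
                                 acceptor_id = members$acceptor_id[hit],
                                 breakpoint = members$breakpoint[hit],
                                 filter = "global_parental_protein",
                                 stringsAsFactors = FALSE))
    members <- members[!hit, , drop = FALSE]
  }
  n_parental_protein_global <- sum(hit)

  # global nucleotide dedup, provenance of all origins
  origin <- sprintf("%s|%s|%d", members$donor_id, members$acceptor_id,
                    members$breakpoint)
  first <- !duplicated(members$cds)
  origins <- vapply(split(origin, factor(members$cds,
                                         levels = members$cds[first])),
                    paste, character(1), collapse = ";")
  n_dup_global <- sum(!first)
  if (n_dup_global > 0L)
    rejected <- rbind(rejected,
                      data.frame(donor_id = members$donor_id[!first],
                                 acceptor_id = members$acceptor_id[!first],
                                 breakpoint = members$breakpoint[!first],
                                 filter = "global_duplicate",
                                 stringsAsFactors = FALSE))
  members <- members[first, , drop = FALSE]
  members$origins <- unname(origins)
  members$id <- sprintf("%s|%s|b%d", members$donor_id, members$acceptor_id,
                        members$breakpoint)
  members <- members[, c("id", "donor_id", "acceptor_id", "breakpoint",
                         "cds", "protein", "mature_peptide", "origins")]
  rownames(members) <- NULL
  stats <- c(table(factor(rejected$filter,
                          levels = c("frameshift", "premature_stop",
                                     "cysteine", "parental_nt",
                                     "parental_protein", "pair_duplicate",
                                     "global_parental_protein",
                                     "global_duplicate"))))
  stats <- c(generated = nrow(members) + nrow(rejected), stats,
             members = nrow(members))
  structure(list(members = members, rejected = rejected, stats = stats),
            class = "ChimeraSet")
}

#' @export
print.ChimeraSet <- function(x, ...) {
  cat("ChimeraSet:", nrow(x$members), "members from",
      x$stats[["generated"]], "candidates\n")
  print(x$stats)
  invisible(x)
}

#' Junction position of a chimeric transcript in protein coordinates
#'
#' The last residue wholly encoded by the donor, in pre-pro-protein
#' coordinates: `floor((exon1_len + breakpoint_nt) / 3)`. The corresponding
#' position within the mature peptide is also returned (may be < 1 when the
#' junction lies upstream of the mature region).
#'
#' @param exon1_len donor exon-1 CDS length in nt.
#' @param breakpoint nucleotide breakpoint offset from the exon-2 CDS start.
#' @param mature_start 1-based aa offset of the mature peptide.
#' @return list with `prepro_aa` and `mature_aa`.
#' @export
junction_position <- function(exon1_len, breakpoint, mature_start = 60L) {
  prepro_aa <- (exon1_len + breakpoint) %/% 3L
  list(prepro_aa = as.integer(prepro_aa),
       mature_aa = as.integer(prepro_aa - mature_start + 1L))
}

#' Write a chimera set to FASTA and TSV
#'
#' @param set a `ChimeraSet`.
#' @param nt_fasta,aa_fasta,ledger_tsv output paths (any may be `NULL`).
#' @return `set`, invisibly.
#' @export
write_chimera_set <- function(set, nt_fasta = NULL, aa_fasta = NULL,
                              ledger_tsv = NULL) {
  m <- set$members
  if (!is.null(nt_fasta)) {
    x <- Biostrings::DNAStringSet(setNames(m$cds, m$id))
    Biostrings::writeXStringSet(x, nt_fasta)
  }
  if (!is.null(aa_fasta)) {
    x <- Biostrings::AAStringSet(setNames(m$protein, m$id))
    Biostrings::writeXStringSet(x, aa_fasta)
  }
  if (!is.null(ledger_tsv))
    write.table(set$rejected, ledger_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(set)
}
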