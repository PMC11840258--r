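#' Proteolytic enzymes
#'
#' Cleavage specificities used for in-solution digests of defensin
#' pre-pro-proteins:
#' * `trypsin`: after K or R, not before P;
#' * `gluc`: endoproteinase Glu-C, after E (ammonium bicarbonate buffer
#'   specificity; set `gluc_d = TRUE` for additional D cleavage);
#' * `elastase`: broad specificity, after A, V, S, G, L or I.
#'
#' @param name enzyme name.
#' @param gluc_d also cleave after D for Glu-C.
#' @return list with `name`, `cleave_after`, `blocked_by_next`.
#' @export
enzyme <- function(name = c("trypsin", "gluc", "elastase"), gluc_d = FALSE) {
  if (is.list(name)) return(name)
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     stop("unknown enzyme '", name,
                          "'; supported: trypsin, gluc, elastase"))
  switch(name,
    trypsin = list(name = "trypsin", cleave_after = c("K", "R"),
                   blocked_by_next = "P"),
    gluc = list(name = "gluc",
                cleave_after = if (gluc_d) c("E", "D") else "E",
                blocked_by_next = character(0)),
    elastase = list(name = "elastase",
                    cleave_after = c("A", "V", "S", "G", "L", "I"),
                    blocked_by_next = character(0)))
}

#' In-silico proteolytic digestion
#'
#' Cleaves after any residue in the enzyme's `cleave_after` set unless the
#' next residue is in `blocked_by_next`. At `missed_cleavages = 0` and without
#' length filtering the fragments concatenate exactly to the input protein.
#' Peptides with `missed_cleavages > 0` are merges of adjacent fragments.
#'
#' @param protein amino-acid string (no stop symbol).
#' @param enz enzyme name or [enzyme()] object.
#' @param missed_cleavages maximal missed cleavages per peptide.
#' @param min_len,max_len retained peptide length range (aa); `max_len`
#'   approximates the observable peptide mass window.
#' @return data frame `peptide`, `start`, `end` (1-based, inclusive, in
#'   protein coordinates), `n_missed`.
#' @export
digest <- function(protein, enz = "trypsin", missed_cleavages = 0L,
                   min_len = 4L, max_len = 60L) {
  enz <- enzyme(enz)
  protein <- toupper(protein)
  if (grepl("*", protein, fixed = TRUE)) stop("protein contains a stop symbol")
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% enz$cleave_after)
  cut_after <- cut_after[cut_after < n]
  if (length(enz$blocked_by_next))
    cut_after <- cut_after[!aa[cut_after + 1L] %in% enz$blocked_by_next]
  bounds <- c(0L, cut_after, n)            # fragment i = (bounds[i]+1) .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- list()
  for (mc in 0:min(missed_cleavages, nfrag - 1L)) {
    i <- seq_len(nfrag - mc)
    start <- bounds[i] + 1L
    end <- bounds[i + mc + 1L]
    out[[mc + 1L]] <- data.frame(peptide = substring(protein, start, end),
                                 start = start, end = end, n_missed = mc,
                                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  len <- res$end - res$start + 1L
  res <- res[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Junction-spanning peptides
#'
#' Subset of digestion peptides having at least `min_overhang` residues
#' strictly on each side of the chimeric junction. The junction position is
#' the last residue wholly encoded by the donor (see [junction_position()]);
#' a peptide ending exactly at the junction has zero right overhang and is
#' excluded.
#'
#' @param peptides data frame from [digest()] (needs `start`, `end`).
#' @param junction_aa junction residue position in the same coordinates as
#'   the peptide offsets.
#' @param min_overhang minimal residues on each side (default 1).
#' @return the qualifying subset of `peptides`.
#' @export
junction_peptides <- function(peptides, junction_aa, min_overhang = 1L) {
  left <- junction_aa - peptides$start + 1L
  right <- peptides$end - junction_aa
  out <- peptides[left >= min_overhang & right >= min_overhang, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Peptide uniqueness against a parental proteome
#'
#' `TRUE` iff no window of any proteome entry matches the peptide with at most
#' `max_mismatches` substitutions (an ungapped near-substring search, the
#' stand-in for a protein BLAST of junction peptides against the genome-encoded
#' proteome).
#'
#' @param peptide amino-acid string.
#' @param proteome character vector of parental protein sequences.
#' @param max_mismatches allowed substitutions per window.
#' @return logical.
#' @export
uniqueness_check <- function(peptide, proteome, max_mismatches = 0L) {
  if (length(proteome) == 0L) stop("proteome is empty")
  peptide <- toupper(peptide)
  L <- nchar(peptide)
  if (all(nchar(proteome) < L)) {
    warning("peptide longer than every proteome entry")
    return(TRUE)
  }
  p <- strsplit(peptide, "")[[1]]
  for (prot in toupper(proteome)) {
    n <- nchar(prot)
    if (n < L) next
    s <- strsplit(prot, "")[[1]]
    for (off in 0:(n - L)) {
      if (sum(s[off + seq_len(L)] != p) <= max_mismatches) return(FALSE)
    }
  }
  TRUE
}

#' Peptide evidence report for a chimeric protein
#'
#' Digests a chimeric protein with each enzyme and flags every theoretical
#' peptide for junction spanning and for uniqueness against the parental
#' proteome. A chimera is "provable" iff at least one peptide carries both
#' flags: only a junction-spanning peptide absent from every parental protein
#' demonstrates translation of the chimera.
#'
#' @param protein chimeric protein sequence (no stop symbol).
#' @param junction_aa junction position in `protein` coordinates.
#' @param parental_proteome character vector of parental proteins.
#' @param enzymes enzyme names (default all three digests).
#' @param missed_cleavages,min_len,max_len digestion parameters.
#' @param max_mismatches uniqueness stringency (default exact).
#' @param min_overhang junction overhang (default 1).
#' @return list with `peptides` (data frame with `enzyme`, `peptide`, `start`,
#'   `end`, `spans_junction`, `unique_vs_parentals`) and `provable` (logical).
#' @export
evidence_report <- function(protein, junction_aa, parental_proteome,
                            enzymes = c("trypsin", "gluc", "elastase"),
                            missed_cleavages = 0L, min_len = 4L,
                            max_len = 60L, max_mismatches = 0L,
                            min_overhang = 1L) {
  rows <- lapply(enzymes, function(e) {
    pep <- digest(protein, e, missed_cleavages, min_len, max_len)
    if (nrow(pep) == 0L) return(NULL)
    pep$enzyme <- e
    pep$spans_junction <- (junction_aa - pep$start + 1L) >= min_overhang &
      (pep$end - junction_aa) >= min_overhang
    pep$unique_vs_parentals <- vapply(pep$peptide, uniqueness_check,
                                      logical(1), proteome = parental_proteome,
                                      max_mismatches = max_mismatches,
                                      USE.NAMES = FALSE)
    pep[, c("enzyme", "peptide", "start", "end", "n_missed",
            "spans_junction", "unique_vs_parentals")]
  })
  peptides <- do.call(rbind, rows)
  if (is.null(peptides))
    peptides <- data.frame(enzyme = character(), peptide = character(),
                           start = integer(), end = integer(),
                           n_missed = integer(), spans_junction = logical(),
                           unique_vs_parentals = logical(),
                           stringsAsFactors = FALSE)
  rownames(peptides) <- NULL
  list(peptides = peptides,
       provable = any(peptides$spans_junction & peptides$unique_vs_parentals))
}

#' Append a C-terminal purification tag
#'
#' Models the His6 knock-in design: appending a GSG linker plus His6 to the
#' acceptor parent's C terminus tags the parental protein and every chimera
#' that uses that parent as acceptor, while junction logic is unchanged.
#'
#' @param protein amino-acid string.
#' @param linker,tag appended segments.
#' @return tagged protein string.
#' @export
tag_cterm <- function(protein, linker = "GSG", tag = "HHHHHH") {
  paste0(protein, linker, tag)
}
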