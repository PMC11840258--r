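#' Build a k-mer reference index
#'
#' Indexes every k-mer of every transcript for read classification. Each
#' transcript carries a role: `parental` and `chimera` transcripts are
#' reported in TPM output, `decoy` transcripts participate in read assignment
#' and EM but are excluded from reporting. The role assignment reproduces the
#' decoy-aware index configurations of transcript quantifiers (parentals-only;
#' parentals + chimeras; chimeras as decoys; parentals as decoys).
#'
#' @param transcripts named character vector of sequences, or a data frame
#'   with columns `id`, `sequence` and optionally `role`.
#' @param k k-mer size (default 21; must not exceed any sequence length).
#' @param roles optional character vector of roles (`parental`, `chimera`,
#'   `decoy`, `background`), recycled; overrides a `role` column.
#' @return a `ref_index` object.
#' @export
build_index <- function(transcripts, k = 21L, roles = NULL) {
  if (is.data.frame(transcripts)) {
    ids <- transcripts$id
    seqs <- toupper(transcripts$sequence)
    if (is.null(roles)) roles <- transcripts$role
  } else {
    ids <- names(transcripts)
    seqs <- toupper(unname(unlist(transcripts)))
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("transcripts must be named")
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(roles)) roles <- "parental"
  roles <- rep_len(roles, length(ids))
  if (any(nchar(seqs) < k)) stop("every sequence must be at least k long")
  obj <- list(transcripts = data.frame(id = ids, sequence = seqs,
                                       role = roles, length = nchar(seqs),
                                       stringsAsFactors = FALSE),
              k = as.integer(k))
  obj$ptr <- cpp_build_index(obj$transcripts$sequence, obj$k)
  structure(obj, class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat("ref_index:", nrow(x$transcripts), "transcripts, k =", x$k, "|",
      paste(names(table(x$transcripts$role)), table(x$transcripts$role),
            collapse = ", "), "\n")
  invisible(x)
}

index_ptr <- function(index) {
  # external pointers do not survive serialisation; rebuild when stale
  if (is.null(index$ptr) ||
      isTRUE(tryCatch(cpp_index_size(index$ptr) >= 0, error = function(e) FALSE)) == FALSE)
    index$ptr <- cpp_build_index(index$transcripts$sequence, index$k)
  index$ptr
}

#' Transcripts containing a k-mer
#'
#' @param index a `ref_index`.
#' @param kmer nucleotide string of length `k`.
#' @return character vector of transcript ids.
#' @export
kmer_hits <- function(index, kmer) {
  idx <- cpp_lookup_kmer(index_ptr(index), toupper(kmer))
  index$transcripts$id[idx]
}

read_input_to_char <- function(reads) {
  if (inherits(reads, "XStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    return(as.character(Biostrings::readDNAStringSet(reads, format = fmt)))
  }
  setNames(as.character(reads), names(reads))
}

#' Quantify reads against a reference index
#'
#' Each read is assigned to the weighted equivalence class of transcripts
#' matching it with at most `max_mismatches` substitutions (anchor k-mer
#' lookup + exact mismatch verification). Within a class, a transcript
#' matching with `m` mismatches carries the substitution-error likelihood
#' weight `(error_rate / 3)^m` relative to a perfect match, so a read that a
#' sequencing error makes look chimeric can still be explained by an abundant
#' parental; in a family of near-identical genes this error-aware weighting
#' is what keeps rare-transcript estimates unbiased. Class counts are
#' resolved to transcript counts by EM (uniform start; stops after
#' `em_maxit` iterations or when the largest change in read-origin
#' probabilities falls below `em_tol`). TPM is count / effective length,
#' normalised to 1e6 over the reported (non-decoy) transcripts; effective
#' length is `length - read_len + 1`, floored at 1.
#'
#' @param reads character vector of read sequences, a `DNAStringSet`, or a
#'   FASTA/FASTQ path.
#' @param index a [build_index()] object.
#' @param max_mismatches maximal substitutions for a valid assignment.
#' @param error_rate assumed per-base substitution error rate of the
#'   sequencer, used to weight imperfect matches; with `error_rate = 0` only
#'   perfect matches are used.
#' @param read_len read length used for effective lengths (default: median
#'   observed).
#' @param em_maxit,em_tol EM stopping rule.
#' @param em_init `"sparse_chimera"` (default) starts transcripts with role
#'   `chimera` at a negligible share (`1e-4` in total) and everything else
#'   uniform; `"uniform"` starts all transcripts equal. The sparse start
#'   selects the parsimonious EM basin: a chimera only keeps mass when
#'   junction-spanning reads that no parental can explain within
#'   `max_mismatches` demand it (such reads restore its abundance in a single
#'   iteration), whereas reads that one sequencing error away from a parental
#'   stay parental.
#' @param sample_id label stored in the result.
#' @return a `QuantResult`: list with `table` (data frame `id`, `role`,
#'   `length`, `efflen`, `count`, `tpm`), `n_reads`, `n_assigned`,
#'   `sample_id`.
#' @export
quantify <- function(reads, index, max_mismatches = 1L, error_rate = 0.001,
                     read_len = NULL, em_maxit = 1000L, em_tol = 1e-8,
                     em_init = c("sparse_chimera", "uniform"),
                     sample_id = "sample") {
  em_init <- match.arg(em_init)
  reads <- read_input_to_char(reads)
  tr <- index$transcripts
  n_t <- nrow(tr)
  if (length(reads) == 0L) {
    warning("empty read set")
    tab <- data.frame(id = tr$id, role = tr$role, length = tr$length,
                      efflen = NA_real_, count = 0, tpm = 0,
                      stringsAsFactors = FALSE)
    tab$tpm[tab$role == "decoy"] <- NA_real_
    return(structure(list(table = tab, n_reads = 0L, n_assigned = 0L,
                          sample_id = sample_id), class = "QuantResult"))
  }
  if (is.null(read_len)) read_len <- median(nchar(reads))
  cls <- cpp_classify(index_ptr(index), toupper(reads), as.integer(max_mismatches))
  assigned <- !is.na(cls$class_id)
  memb <- cls$classes
  n_c <- as.numeric(tabulate(cls$class_id, nbins = length(memb)))

  efflen <- pmax(tr$length - read_len + 1, 1)

  count <- numeric(n_t)
  if (length(memb)) {
    ci <- rep.int(seq_along(memb), lengths(memb))
    ti <- unlist(memb)
    mm <- unlist(cls$class_mm)
    # substitution-error likelihood relative to a perfect match
    wt <- if (error_rate > 0) (error_rate / (3 * (1 - error_rate)))^mm
          else as.numeric(mm == 0)
    keep <- wt > 0
    A <- Matrix::sparseMatrix(i = ci[keep], j = ti[keep], x = wt[keep],
                              dims = c(length(memb), n_t))
    live <- Matrix::rowSums(A) > 0
    n_live <- n_c * live
    is_chim <- tr$role == "chimera"
    if (em_init == "sparse_chimera" && any(is_chim) && !all(is_chim)) {
      theta <- rep(1, n_t)
      theta[is_chim] <- 1e-4 / sum(is_chim) * sum(!is_chim)
      theta <- theta / sum(theta)
    } else {
      theta <- rep(1 / n_t, n_t)
    }
    for (it in seq_len(em_maxit)) {
      denom <- as.numeric(A %*% theta)
      w <- ifelse(denom > 0, n_live / denom, 0)
      theta_new <- theta * as.numeric(Matrix::crossprod(A, w))
      theta_new <- theta_new / sum(theta_new)
      delta <- max(abs(theta_new - theta))
      theta <- theta_new
      if (delta < em_tol) break
    }
    count <- theta * sum(n_live)
  }
  tpm <- count / efflen
  rep_mask <- tr$role != "decoy"
  s <- sum(tpm[rep_mask])
  tpm <- if (s > 0) tpm / s * 1e6 else tpm
  tpm[!rep_mask] <- NA_real_
  tab <- data.frame(id = tr$id, role = tr$role, length = tr$length,
                    efflen = efflen, count = count, tpm = tpm,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_reads = length(reads),
                 n_assigned = sum(assigned), sample_id = sample_id),
            class = "QuantResult")
}

#' @export
print.QuantResult <- function(x, ...) {
  cat("QuantResult", x$sample_id, "|", x$n_assigned, "/", x$n_reads,
      "reads assigned |", nrow(x$table), "transcripts\n")
  invisible(x)
}

#' Split-read support for a chimeric junction
#'
#' Anchors a read against two parent sequences by their best ungapped offsets
#' (minimal full-length mismatches, ties to the smallest offset), then finds
#' the in-read breakpoint minimising total mismatches with the left part
#' matched to `parent_left` and the right part to `parent_right` (ties to the
#' smallest breakpoint). The call is `supported` only when each side carries
#' at most `floor(read length / 4)` mismatches.
#'
#' @param read read sequence.
#' @param parent_left_seq,parent_right_seq parent transcript sequences (at
#'   least as long as the read).
#' @return list with `breakpoint_in_read` (nt contributed by the left parent;
#'   equals the read length when the whole read matches the left parent),
#'   `mismatches_left`, `mismatches_right`, `offset_left`, `offset_right`
#'   (0-based anchor offsets) and `supported`.
#' @export
split_read_support <- function(read, parent_left_seq, parent_right_seq) {
  read <- toupper(read)
  pl <- toupper(parent_left_seq); pr <- toupper(parent_right_seq)
  L <- nchar(read)
  if (nchar(pl) < L || nchar(pr) < L)
    stop("read longer than a parent sequence")
  al <- cpp_best_offset(read, pl)
  ar <- cpp_best_offset(read, pr)
  sp <- cpp_best_split(read, pl, pr, al[1], ar[1])
  lim <- L %/% 4L
  list(breakpoint_in_read = sp[1],
       mismatches_left = sp[2], mismatches_right = sp[3],
       offset_left = al[1], offset_right = ar[1],
       supported = sp[2] <= lim && sp[3] <= lim)
}

#' Screen a read set for chimera-supporting split reads
#'
#' Reads with a full-length match to any parental transcript (at most
#' `max_mismatches` substitutions) are canonical and skipped. Every remaining
#' read is tested with [split_read_support()] over ordered pairs of the
#' `top_parents` parentals with the fewest full-length mismatches; the best
#' supported call (minimal total mismatches, requiring the two parents to
#' differ and an overhang of at least `min_overhang` nt on each side) is
#' reported.
#'
#' @param reads character vector / `DNAStringSet` / FASTQ path.
#' @param parentals named character vector of parental transcript sequences,
#'   or a `ref_index` over parentals only.
#' @param max_mismatches mismatches tolerated for a canonical full-length
#'   match (default 0).
#' @param top_parents number of candidate parents per read side.
#' @param min_overhang minimal nt on each side of the split.
#' @return data frame of split-read calls (possibly empty): `read_id`,
#'   `parent_left`, `parent_right`, `breakpoint_in_read`, `mismatches_left`,
#'   `mismatches_right`.
#' @export
screen_split_reads <- function(reads, parentals, max_mismatches = 0L,
                               top_parents = 4L, min_overhang = 5L) {
  reads <- read_input_to_char(reads)
  if (inherits(parentals, "ref_index")) index <- parentals
  else index <- build_index(parentals, k = min(21L, min(nchar(parentals))))
  seqs <- setNames(index$transcripts$sequence, index$transcripts$id)
  empty <- data.frame(read_id = character(), parent_left = character(),
                      parent_right = character(),
                      breakpoint_in_read = integer(),
                      mismatches_left = integer(),
                      mismatches_right = integer(), stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  cls <- cpp_classify(index_ptr(index), toupper(reads),
                      as.integer(max_mismatches))
  cand <- which(is.na(cls$class_id))
  calls <- list()
  for (i in cand) {
    r <- toupper(reads[i]); L <- nchar(r)
    if (any(nchar(seqs) < L)) next
    fits <- vapply(seqs, function(s) cpp_best_offset(r, s)[2], integer(1))
    top <- names(sort(fits))[seq_len(min(top_parents, length(fits)))]
    best <- NULL
    for (p1 in top) for (p2 in top) {
      if (p1 == p2) next
      sp <- split_read_support(r, seqs[[p1]], seqs[[p2]])
      if (!sp$supported) next
      if (sp$breakpoint_in_read < min_overhang ||
          L - sp$breakpoint_in_read < min_overhang) next
      tot <- sp$mismatches_left + sp$mismatches_right
      if (is.null(best) || tot < best$tot)
        best <- list(p1 = p1, p2 = p2, sp = sp, tot = tot)
    }
    if (!is.null(best))
      calls[[length(calls) + 1L]] <-
        data.frame(read_id = ids[i], parent_left = best$p1,
                   parent_right = best$p2,
                   breakpoint_in_read = best$sp$breakpoint_in_read,
                   mismatches_left = best$sp$mismatches_left,
                   mismatches_right = best$sp$mismatches_right,
                   stringsAsFactors = FALSE)
  }
  if (length(calls)) do.call(rbind, calls) else empty
}

#' Occurrence distribution of chimeras across samples
#'
#' Summarises a chimera-by-sample detection matrix: how many chimeras were
#' never detected, detected in at most `floor(frac_lo * n)` samples, detected
#' in at least `ceil(frac_hi * n)` samples (overridable with `threshold_hi`),
#' and detected in the fixed band `[band[1], band[2]]` samples; percentages of
#' the total and of the detected chimeras are rounded to 2 decimals.
#'
#' @param mat logical or numeric matrix (rows chimeras, columns samples);
#'   values > `min_tpm` count as detected.
#' @param frac_lo,frac_hi fractional thresholds (defaults 1/3 and 2/3).
#' @param band fixed detection band, default `c(1, 50)`.
#' @param threshold_hi absolute override of the upper threshold (e.g. 100).
#' @param min_tpm detection cutoff on the matrix values (default 0).
#' @return list of counts and percentages.
#' @export
occurrence_summary <- function(mat, frac_lo = 1/3, frac_hi = 2/3,
                               band = c(1L, 50L), threshold_hi = NULL,
                               min_tpm = 0) {
  mat <- as.matrix(mat)
  n_samples <- ncol(mat)
  if (n_samples == 0L) stop("n_samples is zero")
  det <- rowSums(mat > min_tpm)
  n_total <- length(det)
  lo <- floor(frac_lo * n_samples)
  hi <- if (!is.null(threshold_hi)) threshold_hi else ceiling(frac_hi * n_samples)
  never <- sum(det == 0)
  n_detected <- n_total - never
  in_band <- sum(det >= band[1] & det <= band[2])
  le_lo <- sum(det <= lo)
  ge_hi <- sum(det >= hi)
  pct <- function(x, denom) if (denom > 0) round(100 * x / denom, 2) else NA_real_
  list(n_samples = n_samples, n_total = n_total, n_detected = n_detected,
       lo_threshold = lo, hi_threshold = hi,
       never = never, never_pct_total = pct(never, n_total),
       in_band = in_band,
       in_band_pct_total = pct(in_band, n_total),
       in_band_pct_detected = pct(in_band, n_detected),
       le_lo = le_lo, le_lo_pct_total = pct(le_lo, n_total),
       ge_hi = ge_hi, ge_hi_pct_total = pct(ge_hi, n_total))
}

#' Donor/acceptor TPM totals per parental gene
#'
#' Sums chimera TPM by the donor and by the acceptor parent; per parent the
#' reported total is donor + acceptor TPM, and the grand total over all
#' parents (chimeric copies per million) is attached.
#'
#' @param quant a `QuantResult`, or a data frame with columns `id` and `tpm`.
#' @param chimeras a `ChimeraSet`, or a data frame mapping `id` to `donor_id`
#'   and `acceptor_id`.
#' @return data frame (`parent`, `donor_tpm`, `acceptor_tpm`, `total_tpm`)
#'   with attribute `grand_total` (sum of chimera TPM as donor side, i.e. the
#'   chimeric load per million).
#' @export
donor_acceptor_totals <- function(quant, chimeras) {
  tab <- if (inherits(quant, "QuantResult")) quant$table else quant
  map <- if (inherits(chimeras, "ChimeraSet")) chimeras$members else chimeras
  ch <- if (!is.null(tab$role)) tab[tab$role == "chimera", , drop = FALSE]
        else tab
  missing <- setdiff(ch$id, map$id)
  if (length(missing))
    stop("chimera id(s) missing from parent map: ",
         paste(head(missing, 5), collapse = ", "))
  m <- map[match(ch$id, map$id), , drop = FALSE]
  parents <- sort(unique(c(m$donor_id, m$acceptor_id)))
  donor_tpm <- vapply(parents, function(p) sum(ch$tpm[m$donor_id == p]),
                      numeric(1))
  acceptor_tpm <- vapply(parents, function(p) sum(ch$tpm[m$acceptor_id == p]),
                         numeric(1))
  out <- data.frame(parent = parents, donor_tpm = donor_tpm,
                    acceptor_tpm = acceptor_tpm,
                    total_tpm = donor_tpm + acceptor_tpm,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "grand_total") <- sum(ch$tpm)
  out
}
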