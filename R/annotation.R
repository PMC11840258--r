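#' Gene record tables
#'
#' Annotation records are plain data frames with one row per (gene, source)
#' with columns `gene_id`, `source`, `chrom`, `start`, `end`, `strand` and
#' optionally `biotype` (default `"protein_coding"`). Coordinates are 1-based
#' inclusive, the convention used by GTF and genome browsers. Internally,
#' interval arithmetic uses 0-based half-open coordinates; see
#' [to_zero_based()].
#'
#' @param gene_id,source,chrom,strand character vectors (recycled).
#' @param start,end integer vectors, 1-based inclusive, `start <= end`.
#' @param biotype one of `"protein_coding"`, `"pseudogene"`, `"syntenic"`.
#' @return a data frame of gene records.
#' @export
gene_record <- function(gene_id, source, chrom, start, end, strand,
                        biotype = "protein_coding") {
  rec <- data.frame(gene_id = as.character(gene_id),
                    source = as.character(source),
                    chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    biotype = as.character(biotype),
                    stringsAsFactors = FALSE)
  validate_gene_records(rec)
  rec
}

validate_gene_records <- function(records) {
  need <- c("gene_id", "source", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("gene records lack column(s): ", paste(miss, collapse = ", "))
  bad <- records$end < records$start
  if (any(bad))
    stop("end < start for gene(s): ",
         paste(unique(records$gene_id[bad]), collapse = ", "))
  if (!all(records$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(records)
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' External coordinates (GTF, `chr8:21,515,561-22,225,487` style) are 1-based
#' inclusive; internal interval arithmetic is 0-based half-open. The two
#' converters are exact inverses.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param start0,end0 0-based half-open coordinates.
#' @return a list with converted `start` and `end`.
#' @export
to_zero_based <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' Genomic span length
#'
#' Length in bp of a 1-based inclusive interval, `end - start + 1`.
#' The Defa locus chr8:21,515,561-22,225,487 spans 709,927 bp (0.71 MB).
#'
#' @param start,end 1-based inclusive coordinates (vectorised).
#' @return integer bp lengths.
#' @seealso [format_mb()] for the megabase rendering.
#' @export
span_length <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(end < start)) stop("end < start")
  as.integer(end - start + 1)
}

#' @param bp length in bp.
#' @param digits decimals in the MB rendering.
#' @rdname span_length
#' @export
format_mb <- function(bp, digits = 2) {
  sprintf(paste0("%.", digits, "f MB"), bp / 1e6)
}

#' Default gene-name aliases
#'
#' Retired gene symbols mapped to their current names. Defa6 only exists as a
#' historical MGI record whose sequence matches Defa24, so Defa6 records are
#' folded into Defa24 before merging.
#'
#' @export
defa_aliases <- c(Defa6 = "Defa24")

#' Merge gene models from multiple annotation sources
#'
#' For each gene, takes the earliest start and the latest end observed across
#' sources (the maximal gene extent), recording which source contributed each
#' boundary. All records of one gene must agree on chromosome and strand.
#'
#' @param records a gene-record data frame (see [gene_record()]); one row per
#'   (gene, source).
#' @param aliases named character vector mapping retired gene ids to current
#'   ones, applied before grouping. Default [defa_aliases].
#' @return a data frame with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `start_source`, `end_source`, `sources` (comma-joined),
#'   `n_sources`.
#' @export
merge_gene_models <- function(records, aliases = defa_aliases) {
  validate_gene_records(records)
  records$gene_id <- ifelse(records$gene_id %in% names(aliases),
                            unname(aliases[records$gene_id]),
                            records$gene_id)
  merged <- lapply(split(records, records$gene_id), function(g) {
    if (length(unique(g$chrom)) > 1L || length(unique(g$strand)) > 1L)
      stop("conflicting chrom/strand across sources for gene ",
           g$gene_id[1])
    i_start <- which.min(g$start)
    i_end <- which.max(g$end)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = g$start[i_start], end = g$end[i_end],
               strand = g$strand[1],
               start_source = g$source[i_start],
               end_source = g$source[i_end],
               sources = paste(sort(unique(g$source)), collapse = ","),
               n_sources = length(unique(g$source)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Filter and collapse predicted genes
#'
#' Size filter plus overlap collapse used for in-silico alpha-defensin
#' predictions in non-model species: predictions shorter than `min_len` or
#' longer than `max_len` bp are dropped, then any pair of intervals with
#' reciprocal overlap of at least `overlap_frac` is collapsed into its union
#' span, iterating to a fixpoint in coordinate order.
#'
#' Reciprocal means the shared bases must cover at least `overlap_frac` of
#' BOTH intervals (so a tiny interval cannot absorb a large one); set
#' `reciprocal = FALSE` for the single-sided rule.
#'
#' @param records gene-record data frame sorted by chrom, start.
#' @param min_len,max_len retained length range in bp (inclusive).
#' @param overlap_frac overlap fraction triggering collapse.
#' @param reciprocal require the fraction on both intervals (default) or on
#'   either one.
#' @return filtered/collapsed gene-record data frame; collapsed rows carry the
#'   member ids joined by `|` in `gene_id`.
#' @export
filter_predictions <- function(records, min_len = 500, max_len = 3000,
                               overlap_frac = 0.75, reciprocal = TRUE) {
  validate_gene_records(records)
  len <- span_length(records$start, records$end)
  records <- records[len >= min_len & len <= max_len, , drop = FALSE]
  if (nrow(records) == 0L) return(records)
  out <- do.call(rbind, lapply(split(records, records$chrom),
                               collapse_chrom, overlap_frac, reciprocal))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

collapse_chrom <- function(g, overlap_frac, reciprocal) {
  g <- g[order(g$start, g$end), , drop = FALSE]
  repeat {
    n <- nrow(g)
    if (n < 2L) return(g)
    ir <- IRanges::IRanges(g$start, g$end)
    ov <- IRanges::findOverlaps(ir, ir)
    ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
    if (length(ov) == 0L) return(g)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    shared <- IRanges::width(IRanges::pintersect(ir[q], ir[s]))
    fq <- shared / IRanges::width(ir)[q]
    fs <- shared / IRanges::width(ir)[s]
    hit <- if (reciprocal) fq >= overlap_frac & fs >= overlap_frac
           else fq >= overlap_frac | fs >= overlap_frac
    if (!any(hit)) return(g)
    i <- which(hit)[1L]
    a <- q[i]; b <- s[i]
    g$start[a] <- min(g$start[a], g$start[b])
    g$end[a] <- max(g$end[a], g$end[b])
    g$gene_id[a] <- paste(unique(c(g$gene_id[a], g$gene_id[b])),
                          collapse = "|")
    g$source[a] <- paste(sort(unique(c(g$source[a], g$source[b]))),
                         collapse = ",")
    g <- g[-b, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
  }
}

#' Read annotation sources
#'
#' Reads gene records from GTF files (gene features, attribute `gene_id`;
#' requires the rtracklayer package) or 6-column BED-like TSVs with columns
#' chrom, start, end, name, source, strand (1-based inclusive coordinates).
#'
#' @param path file path.
#' @param source source label; for GTF defaults to the file's `source` column,
#'   for TSV to the 5th column.
#' @param format `"auto"` (by extension), `"gtf"` or `"tsv"`.
#' @return a gene-record data frame.
#' @export
read_gene_source <- function(path, source = NULL, format = c("auto", "gtf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  if (format == "gtf") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr[gr$type == "gene"])
    data.frame(gene_id = df$gene_id,
               source = if (is.null(source)) as.character(df$source) else source,
               chrom = as.character(df$seqnames),
               start = df$start, end = df$end,
               strand = as.character(df$strand),
               biotype = if (!is.null(df$gene_biotype)) df$gene_biotype
                         else "protein_coding",
               stringsAsFactors = FALSE)
  } else {
    x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(x) < 6) stop("BED-like TSV needs 6 columns")
    gene_record(gene_id = x[[4]],
                source = if (is.null(source)) x[[5]] else source,
                chrom = x[[1]], start = x[[2]], end = x[[3]], strand = x[[6]])
  }
}

#' Write merged gene models as GTF plus provenance TSV
#'
#' @param merged output of [merge_gene_models()].
#' @param gtf_path,provenance_path output paths (either may be `NULL` to skip).
#' @return `merged`, invisibly.
#' @export
write_merged_annotation <- function(merged, gtf_path = NULL,
                                    provenance_path = NULL) {
  if (!is.null(gtf_path)) {
    attrs <- sprintf('gene_id "%s";', merged$gene_id)
    lines <- paste(merged$chrom, "defchimera", "gene", merged$start,
                   merged$end, ".", merged$strand, ".", attrs, sep = "\t")
    writeLines(lines, gtf_path)
  }
  if (!is.null(provenance_path))
    write.table(merged, provenance_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(merged)
}
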