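#' Construct a table of CNV calls
#'
#' The central data structure of the package is a plain `data.frame` with one
#' row per copy-number event in one sample. Coordinates are 0-based half-open
#' (`start` inclusive, `end` exclusive), the convention of the BED format.
#' Copy-number status is restricted to the alphabet \{0, 1, 3, 4\}: deletions
#' carry 0 (homozygous) or 1 (heterozygous) copies, duplications 3
#' (heterozygous) or 4, where 4 stands for four or more copies. Copy number 2
#' is the diploid reference state and is not a CNV.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open interval per call.
#' @param copy_number Integer vector with values in \{0, 1, 3, 4\}.
#' @param sample_id Character vector (recycled) of sample identifiers.
#' @param source Character vector (recycled); caller or pipeline-stage label.
#' @param filter_pass Logical vector (recycled); did the call pass filters.
#' @param svtype Optional character vector ("DEL"/"DUP"). When `NULL` it is
#'   inferred from `copy_number` (0,1 -> DEL; 3,4 -> DUP).
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `svtype`,
#'   `copy_number`, `sample_id`, `source`, `filter_pass`.
#' @export
#' @examples
#' cnv_calls("chr1", 100, 200, copy_number = 1, sample_id = "S1")
cnv_calls <- function(chrom = character(), start = integer(), end = integer(),
                      copy_number = integer(), sample_id = "",
                      source = "unknown", filter_pass = TRUE, svtype = NULL) {
  n <- length(chrom)
  if (is.null(svtype)) svtype <- svtype_from_cn(copy_number)
  out <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    svtype = rep_len(as.character(svtype), n),
    copy_number = rep_len(as.integer(copy_number), n),
    sample_id = rep_len(as.character(sample_id), n),
    source = rep_len(as.character(source), n),
    filter_pass = rep_len(as.logical(filter_pass), n),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(out)
  out
}

#' Map copy-number status to structural-variant type
#'
#' @param copy_number Integer vector in \{0, 1, 3, 4\}.
#' @return Character vector "DEL"/"DUP".
#' @export
svtype_from_cn <- function(copy_number) {
  cn <- as.integer(copy_number)
  bad <- !cn %in% c(0L, 1L, 3L, 4L)
  if (any(bad)) {
    stop("copy_number must be in {0, 1, 3, 4}; got ",
         paste(unique(cn[bad]), collapse = ", "),
         if (any(cn[bad] == 2L)) " (copy number 2 is diploid, not a CNV)" else "")
  }
  ifelse(cn <= 1L, "DEL", "DUP")
}

#' Validate a CNV call table
#'
#' Checks the structural invariants: required columns, non-empty chromosome
#' names, `0 <= start < end`, copy numbers in \{0,1,3,4\}, and consistency of
#' `svtype` with `copy_number` (DEL <-> \{0,1\}, DUP <-> \{3,4\}).
#'
#' @param calls A CNV call `data.frame` (see [cnv_calls()]).
#' @return `calls`, invisibly, if valid; otherwise an error.
#' @export
validate_cnv_calls <- function(calls) {
  required <- c("chrom", "start", "end", "svtype", "copy_number",
                "sample_id", "source", "filter_pass")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols)) {
    stop("CNV call table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(calls) == 0) return(invisible(calls))
  if (any(!nzchar(calls$chrom) | is.na(calls$chrom))) {
    stop("chromosome names must be non-empty")
  }
  bad <- which(!(calls$start >= 0 & calls$start < calls$end))
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  expected <- svtype_from_cn(calls$copy_number)
  mism <- which(expected != calls$svtype)
  if (length(mism)) {
    stop("svtype inconsistent with copy_number at row(s) ",
         paste(utils::head(mism, 5), collapse = ", "))
  }
  invisible(calls)
}

#' Sort a call table by genomic position
#'
#' Orders rows by (chrom, start, end, sample_id); chromosome order is
#' lexicographic unless a `chrom_order` is supplied.
#'
#' @param calls CNV call table.
#' @param chrom_order Optional character vector giving chromosome order.
#' @return The sorted table.
#' @export
sort_calls <- function(calls, chrom_order = NULL) {
  if (nrow(calls) == 0) return(calls)
  chrom_key <- if (is.null(chrom_order)) calls$chrom else
    factor(calls$chrom, levels = chrom_order)
  ord <- order(chrom_key, calls$start, calls$end,
               if ("sample_id" %in% names(calls)) calls$sample_id else NULL)
  out <- calls[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Internal: CNV call table (0-based half-open) -> GRanges (1-based closed).
calls_to_gr <- function(calls) {
  GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end)
  )
}

# Internal: intervals data.frame (chrom/start/end, 0-based half-open) -> GRanges.
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Internal: GRanges -> 0-based half-open data.frame.
gr_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}
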