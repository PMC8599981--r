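#' Parameters for callset merging
#'
#' @param max_breakpoint_distance Two same-type calls are clustered when both
#'   their start and end positions differ by at most this many bp (default
#'   100), a positional-clustering stand-in for dedicated SV merging tools.
#' @param adjacency_gap Maximum gap (bp) at which same-type segments are
#'   considered adjacent during consolidation; 0 means book-ended segments
#'   merge.
#' @return List of class `merge_parameters`.
#' @export
merge_parameters <- function(max_breakpoint_distance = 100L, adjacency_gap = 0L) {
  stopifnot(max_breakpoint_distance >= 0, adjacency_gap >= 0)
  structure(list(max_breakpoint_distance = as.integer(max_breakpoint_distance),
                 adjacency_gap = as.integer(adjacency_gap)),
            class = "merge_parameters")
}

#' Merge one sample's callsets from multiple callers
#'
#' Single-linkage clustering of same-type calls: a call joins a cluster when
#' some member has both breakpoints within `max_breakpoint_distance`. Each
#' cluster is collapsed into one call spanning the earliest start and latest
#' end among members, with the `source` column listing the contributing
#' callers (comma-separated, deduplicated, sorted). Calls of different SV
#' types never merge. The merged copy number is the minimum over members for
#' deletions and the maximum for duplications.
#'
#' @param ... CNV call tables (or a single list of them), all for one sample.
#' @param params [merge_parameters()].
#' @return A merged, sorted CNV call table.
#' @export
merge_caller_callsets <- function(..., params = merge_parameters()) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  calls <- do.call(rbind, sets)
  if (is.null(calls) || nrow(calls) == 0) return(cnv_calls())
  validate_cnv_calls(calls)
  sids <- unique(calls$sample_id)
  if (length(sids) > 1) {
    stop("callsets carry mixed sample IDs: ", paste(sids, collapse = ", "))
  }
  d <- params$max_breakpoint_distance
  out <- list()
  for (svt in unique(calls$svtype)) {
    for (chrom in unique(calls$chrom[calls$svtype == svt])) {
      sub <- calls[calls$svtype == svt & calls$chrom == chrom, , drop = FALSE]
      sub <- sub[order(sub$start, sub$end), , drop = FALSE]
      cluster <- rep(NA_integer_, nrow(sub))
      n_clust <- 0L
      for (i in seq_len(nrow(sub))) {
        assigned <- FALSE
        if (n_clust > 0) {
          for (cl in seq_len(n_clust)) {
            members <- which(cluster == cl)
            if (any(abs(sub$start[members] - sub$start[i]) <= d &
                    abs(sub$end[members] - sub$end[i]) <= d)) {
              cluster[i] <- cl
              assigned <- TRUE
              break
            }
          }
        }
        if (!assigned) {
          n_clust <- n_clust + 1L
          cluster[i] <- n_clust
        }
      }
      for (cl in seq_len(n_clust)) {
        members <- sub[cluster == cl, , drop = FALSE]
        cn <- if (svt == "DEL") min(members$copy_number) else
          min(max(members$copy_number), 4L)
        out[[length(out) + 1L]] <- cnv_calls(
          chrom = chrom, start = min(members$start), end = max(members$end),
          copy_number = cn, sample_id = sids,
          source = paste(sort(unique(members$source)), collapse = ","))
      }
    }
  }
  sort_calls(do.call(rbind, out))
}

#' Consolidate one sample's calls into non-overlapping segments
#'
#' The per-sample cleanup required before burden analysis, since downstream
#' association tools do not accept overlapping CNVs within a sample:
#' \enumerate{
#'   \item same-type segments that overlap or are adjacent (gap at most
#'     `adjacency_gap`, default book-ended) are merged into their union; the
#'     merged copy number is the minimum for deletions and the maximum
#'     (capped at 4) for duplications;
#'   \item any merged deletion and merged duplication that still overlap each
#'     other are both removed entirely — the conflicting region carries
#'     irreconcilable copy-number evidence;
#'   \item the result is non-overlapping and sorted.
#' }
#' The operation is idempotent and never increases the event count.
#'
#' @param calls CNV call table for one sample.
#' @param params [merge_parameters()].
#' @return Consolidated CNV call table.
#' @export
consolidate_sample_cnvs <- function(calls, params = merge_parameters()) {
  if (nrow(calls) == 0) return(calls)
  validate_cnv_calls(calls)
  if (length(unique(calls$sample_id)) > 1) {
    stop("consolidate_sample_cnvs operates on one sample at a time")
  }
  gap <- params$adjacency_gap
  merged <- list()
  for (svt in c("DEL", "DUP")) {
    sub <- calls[calls$svtype == svt, , drop = FALSE]
    if (nrow(sub) == 0) next
    gr <- calls_to_gr(sub)
    red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L)
    hits <- GenomicRanges::findOverlaps(gr, red, maxgap = gap)
    cn <- vapply(seq_along(red), function(j) {
      members <- sub$copy_number[S4Vectors::queryHits(hits)[
        S4Vectors::subjectHits(hits) == j]]
      if (svt == "DEL") min(members) else min(max(members), 4L)
    }, integer(1))
    merged[[svt]] <- cnv_calls(
      chrom = as.character(GenomicRanges::seqnames(red)),
      start = GenomicRanges::start(red) - 1L,
      end = GenomicRanges::end(red),
      copy_number = cn, sample_id = calls$sample_id[1],
      source = "consolidated")
  }
  del <- merged[["DEL"]]; dup <- merged[["DUP"]]
  if (!is.null(del) && !is.null(dup) && nrow(del) && nrow(dup)) {
    drop_del <- integer(0); drop_dup <- integer(0)
    for (chrom in intersect(unique(del$chrom), unique(dup$chrom))) {
      di <- which(del$chrom == chrom); ui <- which(dup$chrom == chrom)
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(del$start[di] + 1L, del$end[di]),
        IRanges::IRanges(dup$start[ui] + 1L, dup$end[ui]))
      drop_del <- c(drop_del, di[unique(S4Vectors::queryHits(hits))])
      drop_dup <- c(drop_dup, ui[unique(S4Vectors::subjectHits(hits))])
    }
    if (length(drop_del)) del <- del[-drop_del, , drop = FALSE]
    if (length(drop_dup)) dup <- dup[-drop_dup, , drop = FALSE]
  }
  sort_calls(rbind(if (!is.null(del)) del, if (!is.null(dup)) dup))
}

#' Assemble consolidated per-sample callsets into a cohort table
#'
#' Concatenates consolidated callsets across samples and sorts by position
#' (ties broken by sample ID). Every sample must appear in the phenotype
#' table when one is given.
#'
#' @param callsets A list of consolidated CNV call tables, or a single
#'   cohort-wide call table.
#' @param phenotypes Optional phenotype table; samples missing from it are an
#'   error.
#' @return A sorted cohort CNV table with attribute `event_counts` (named
#'   per-sample event counts).
#' @export
build_cohort_table <- function(callsets, phenotypes = NULL) {
  tab <- if (is.data.frame(callsets)) callsets else do.call(rbind, callsets)
  if (is.null(tab)) tab <- cnv_calls()
  validate_cnv_calls(tab)
  if (!is.null(phenotypes)) {
    missing <- setdiff(unique(tab$sample_id), phenotypes$sample_id)
    if (length(missing)) {
      stop("sample(s) absent from phenotype table: ",
           paste(missing, collapse = ", "))
    }
  }
  tab <- sort_calls(tab)
  counts <- table(tab$sample_id)
  attr(tab, "event_counts") <- stats::setNames(as.integer(counts), names(counts))
  tab
}
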