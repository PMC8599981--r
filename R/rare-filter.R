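#' Parameters for rare-CNV identification
#'
#' Mirrors the frequency-exclusion semantics of PLINK's CNV module: an event
#' is dropped when more than `overlap_fraction` of its length lies on bases
#' where the cohort event count exceeds `count_threshold` (derived as
#' `floor(frequency * n_samples)` when not given explicitly).
#'
#' @param frequency Cohort frequency cutoff (default 0.01, i.e. rare = <1%).
#' @param overlap_fraction Fraction of event length that must exceed the
#'   count threshold to trigger exclusion (default 0.5).
#' @param count_threshold Optional explicit count threshold overriding the
#'   derived one.
#' @return List of class `rare_filter_parameters`.
#' @export
rare_filter_parameters <- function(frequency = 0.01, overlap_fraction = 0.5,
                                   count_threshold = NULL) {
  stopifnot(frequency > 0, frequency < 1,
            overlap_fraction > 0, overlap_fraction <= 1,
            is.null(count_threshold) || count_threshold >= 1)
  structure(list(frequency = frequency, overlap_fraction = overlap_fraction,
                 count_threshold = if (is.null(count_threshold)) NULL else
                   as.integer(count_threshold)),
            class = "rare_filter_parameters")
}

#' Derive the frequency-exclusion count threshold
#'
#' `floor(frequency * n_samples)`; e.g. a 1% cutoff on a 3,800-sample cohort
#' gives 38, and on subgroups of 978, 1,247 and 1,566 samples gives 9, 12 and
#' 15 respectively.
#'
#' @param n_samples Number of samples in the (sub)cohort.
#' @param frequency Frequency cutoff.
#' @return Integer count threshold; an error if the result would be 0 (the
#'   filter would exclude every event).
#' @export
frequency_threshold <- function(n_samples, frequency = 0.01) {
  stopifnot(n_samples >= 1)
  thr <- as.integer(floor(frequency * n_samples))
  if (thr < 1) {
    stop("frequency threshold of ", frequency, " on ", n_samples,
         " samples yields count 0; every event would be excluded")
  }
  thr
}

# Internal: per-base event-count coverage for one chromosome as an Rle.
cohort_base_counts <- function(cohort, chrom) {
  sub <- cohort[cohort$chrom == chrom, , drop = FALSE]
  IRanges::coverage(IRanges::IRanges(sub$start + 1L, sub$end))
}

#' Exclude common CNVs by cohort frequency
#'
#' For every base of the genome the number of cohort events (any type, any
#' sample, including the event under test itself) covering that base is
#' computed; an event is excluded when the fraction of its length lying on
#' bases with count strictly greater than the threshold is strictly greater
#' than `overlap_fraction`. A threshold of 38 therefore tolerates 38
#' carriers. Retained events are returned unchanged.
#'
#' @param cohort Consolidated cohort CNV table.
#' @param params [rare_filter_parameters()].
#' @param n_samples Number of samples used to derive the count threshold when
#'   `params$count_threshold` is `NULL`; defaults to the number of distinct
#'   sample IDs in `cohort`.
#' @return The rare subset of `cohort`, with attribute `n_excluded`.
#' @export
frequency_filter <- function(cohort, params = rare_filter_parameters(),
                             n_samples = NULL) {
  if (nrow(cohort) == 0) return(cohort)
  validate_cnv_calls(cohort)
  thr <- params$count_threshold
  if (is.null(thr)) {
    if (is.null(n_samples)) n_samples <- length(unique(cohort$sample_id))
    thr <- frequency_threshold(n_samples, params$frequency)
  }
  keep <- logical(nrow(cohort))
  for (chrom in unique(cohort$chrom)) {
    counts <- cohort_base_counts(cohort, chrom)
    idx <- which(cohort$chrom == chrom)
    high_ir <- methods::as(counts > thr, "IRanges")  # runs of bases above threshold
    for (i in idx) {
      ev <- IRanges::IRanges(cohort$start[i] + 1L, cohort$end[i])
      ov <- IRanges::intersect(high_ir, ev)
      frac_high <- sum(IRanges::width(ov)) / IRanges::width(ev)
      keep[i] <- !(frac_high > params$overlap_fraction)
    }
  }
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Restrict CNVs to accessible (P-class) genome
#'
#' An event is retained only when 100% of its span is covered by the union of
#' P-labeled mask intervals ("passed" regions of the accessibility mask).
#' Events on chromosomes absent from the mask are excluded and counted.
#'
#' @param cnvs CNV call table.
#' @param mask Mask table from [read_mask()].
#' @return The subset of `cnvs` residing entirely in P regions, with
#'   attributes `n_excluded` and `n_no_mask_chrom`.
#' @export
apply_accessibility_mask <- function(cnvs, mask) {
  if (nrow(cnvs) == 0) return(cnvs)
  validate_cnv_calls(cnvs)
  p_mask <- mask[mask$label == "P", , drop = FALSE]
  keep <- logical(nrow(cnvs))
  n_no_chrom <- 0L
  for (chrom in unique(cnvs$chrom)) {
    idx <- which(cnvs$chrom == chrom)
    if (!chrom %in% mask$chrom) {
      n_no_chrom <- n_no_chrom + length(idx)
      next
    }
    p_sub <- p_mask[p_mask$chrom == chrom, , drop = FALSE]
    if (nrow(p_sub) == 0) next
    p_ir <- IRanges::reduce(IRanges::IRanges(p_sub$start + 1L, p_sub$end))
    ev <- IRanges::IRanges(cnvs$start[idx] + 1L, cnvs$end[idx])
    uncovered <- IRanges::width(ev) -
      vapply(seq_along(ev), function(j) {
        sum(IRanges::width(IRanges::intersect(p_ir, ev[j])))
      }, integer(1))
    keep[idx] <- uncovered == 0L
  }
  out <- cnvs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "n_no_mask_chrom") <- n_no_chrom
  out
}

#' Base composition of an accessibility mask
#'
#' Fraction of masked bases per class; fractions sum to 1 over the masked
#' span. The 1000 Genomes pilot accessibility mask, for reference scale,
#' splits roughly as P 89.0%, N 5.3%, L 1.4%, H 0.6%, Z 3.7%.
#'
#' @param mask Mask table.
#' @return Named numeric vector of per-class fractions over
#'   `c("P","N","L","H","Z")` (absent classes are 0).
#' @export
mask_composition <- function(mask) {
  if (nrow(mask) == 0) stop("empty mask")
  widths <- tapply(mask$end - mask$start, factor(mask$label, levels = MASK_CLASSES),
                   sum, default = 0)
  frac <- as.numeric(widths) / sum(widths)
  stats::setNames(frac, MASK_CLASSES)
}

#' Identify rare CNVs: mask restriction plus frequency exclusion
#'
#' Convenience pipeline combining [apply_accessibility_mask()] and
#' [frequency_filter()]. The default order applies the accessibility mask
#' first and the frequency exclusion second; the order is configurable.
#'
#' @param cohort Consolidated cohort CNV table.
#' @param mask Mask table (or `NULL` to skip masking).
#' @param params [rare_filter_parameters()].
#' @param n_samples Cohort size for threshold derivation (see
#'   [frequency_filter()]).
#' @param order `"mask_first"` (default) or `"frequency_first"`.
#' @return Rare CNV table.
#' @export
identify_rare_cnvs <- function(cohort, mask = NULL,
                               params = rare_filter_parameters(),
                               n_samples = NULL,
                               order = c("mask_first", "frequency_first")) {
  order <- match.arg(order)
  if (is.null(n_samples)) n_samples <- length(unique(cohort$sample_id))
  if (order == "mask_first") {
    if (!is.null(mask)) cohort <- apply_accessibility_mask(cohort, mask)
    frequency_filter(cohort, params, n_samples = n_samples)
  } else {
    cohort <- frequency_filter(cohort, params, n_samples = n_samples)
    if (!is.null(mask)) cohort <- apply_accessibility_mask(cohort, mask) else cohort
  }
}
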