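#' Directional concordance between two CNV callsets
#'
#' Computes the fraction of the primary callset's events recalled by a
#' secondary callset. Under the `"1bp"` criterion an event is recalled when
#' any secondary event overlaps it by at least one base. Under a fractional
#' criterion `f` it is recalled when the union of overlapping secondary
#' events covers at least `f` of its length (so splitting a secondary event
#' into book-ended pieces changes nothing). Coverage of the primary by the
#' secondary makes the comparison directional: swapping the roles generally
#' changes the answer. Matching is type-agnostic by default, as when callsets
#' are compared as plain intervals; set `type_aware = TRUE` to require equal
#' `svtype`.
#'
#' @param primary,secondary CNV call tables (or plain interval data frames
#'   with `chrom`, `start`, `end`).
#' @param criterion `"1bp"` or a number in (0, 1] giving the required covered
#'   fraction.
#' @param type_aware Require matching SV type.
#' @return List of class `concordance_result`: `fraction_recalled`,
#'   `n_primary`, `n_recalled`, `criterion`.
#' @export
pairwise_concordance <- function(primary, secondary, criterion = "1bp",
                                 type_aware = FALSE) {
  if (nrow(primary) == 0) stop("empty primary callset; recall is undefined")
  frac <- NULL
  if (!identical(criterion, "1bp")) {
    frac <- as.numeric(criterion)
    if (is.na(frac) || frac <= 0 || frac > 1) {
      stop("criterion must be \"1bp\" or a fraction in (0, 1]")
    }
  }
  types <- if (type_aware) intersect(unique(primary$svtype),
                                     c("DEL", "DUP")) else "any"
  recalled <- logical(nrow(primary))
  for (ty in types) {
    p_idx <- if (type_aware) which(primary$svtype == ty) else seq_len(nrow(primary))
    sec <- if (type_aware) secondary[secondary$svtype == ty, , drop = FALSE] else
      secondary
    if (!length(p_idx) || nrow(sec) == 0) next
    p_gr <- intervals_to_gr(primary[p_idx, , drop = FALSE])
    s_gr <- IRanges::reduce(intervals_to_gr(sec))
    if (is.null(frac)) {
      hits <- GenomicRanges::findOverlaps(p_gr, s_gr)
      recalled[p_idx[unique(S4Vectors::queryHits(hits))]] <- TRUE
    } else {
      cov_int <- GenomicRanges::intersect(p_gr, s_gr, ignore.strand = TRUE)
      hits <- GenomicRanges::findOverlaps(p_gr, cov_int)
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      w <- pmin(GenomicRanges::end(p_gr)[q], GenomicRanges::end(cov_int)[s]) -
        pmax(GenomicRanges::start(p_gr)[q], GenomicRanges::start(cov_int)[s]) + 1L
      covered <- tapply(w, factor(q, levels = seq_along(p_gr)), sum, default = 0L)
      recalled[p_idx] <- as.numeric(covered) >=
        frac * GenomicRanges::width(p_gr) - 1e-9
    }
  }
  structure(list(fraction_recalled = mean(recalled),
                 n_primary = nrow(primary),
                 n_recalled = sum(recalled),
                 criterion = if (is.null(frac)) "1bp" else frac),
            class = "concordance_result")
}

#' All-pairs concordance matrix over labeled callsets
#'
#' Evaluates every ordered pair of callsets (both directions, since the
#' comparison is asymmetric) under each criterion; the diagonal is 1 by
#' construction.
#'
#' @param callsets Named list of CNV call tables; names label the matrix.
#' @param criteria List/vector of criteria as in [pairwise_concordance()]
#'   (default `list("1bp", 0.5)`).
#' @param type_aware Passed to [pairwise_concordance()].
#' @return A `data.frame` with one row per (criterion, primary, secondary):
#'   `criterion`, `primary`, `secondary`, `fraction_recalled`, `n_primary`.
#' @export
concordance_matrix <- function(callsets, criteria = list("1bp", 0.5),
                               type_aware = FALSE) {
  if (length(callsets) < 2) stop("need at least 2 callsets")
  labels <- names(callsets)
  if (is.null(labels) || any(!nzchar(labels))) stop("callsets must be named")
  if (anyDuplicated(labels)) stop("duplicate callset labels")
  rows <- list()
  for (crit in criteria) {
    for (p in labels) {
      for (s in labels) {
        res <- pairwise_concordance(callsets[[p]], callsets[[s]],
                                    criterion = crit, type_aware = type_aware)
        rows[[length(rows) + 1L]] <- data.frame(
          criterion = if (identical(crit, "1bp")) "1bp" else
            paste0("frac", crit),
          primary = p, secondary = s,
          fraction_recalled = res$fraction_recalled,
          n_primary = res$n_primary, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance (%s overlap): %d/%d primary events recalled (%.1f%%)\n",
              if (identical(x$criterion, "1bp")) "1bp" else
                paste0(100 * x$criterion, "%"),
              x$n_recalled, x$n_primary, 100 * x$fraction_recalled))
  invisible(x)
}
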