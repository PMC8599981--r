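#' Parameters for the across-chromosome coverage check
#'
#' Default tuning: 25-mers, 20 kb
#' repetitive-free regions, 20 regions per chromosome, a sample failed when
#' the standard deviation of its chromosome coverages exceeds 15% of the
#' average coverage, and a chromosome flagged as an outlier when its coverage
#' deviates from the median by more than 25% (midway between the euploid
#' expectation of 0% and the ~50% deviation of a trisomy or monosomy).
#'
#' @param k k-mer length (bp).
#' @param region_length Length of a repetitive-free region (bp).
#' @param regions_per_chromosome Maximum regions sought per chromosome.
#' @param sd_fraction Sample fails when sd > `sd_fraction` x mean coverage.
#' @param outlier_fraction Chromosome flagged when
#'   |coverage - median| > `outlier_fraction` x median.
#' @return A list of class `qc_parameters`.
#' @export
qc_parameters <- function(k = 25L, region_length = 20000L,
                          regions_per_chromosome = 20L,
                          sd_fraction = 0.15, outlier_fraction = 0.25) {
  stopifnot(k >= 1, region_length >= k, regions_per_chromosome >= 1,
            sd_fraction > 0, sd_fraction < 1,
            outlier_fraction > 0, outlier_fraction < 1)
  structure(list(k = as.integer(k), region_length = as.integer(region_length),
                 regions_per_chromosome = as.integer(regions_per_chromosome),
                 sd_fraction = sd_fraction,
                 outlier_fraction = outlier_fraction),
            class = "qc_parameters")
}

# Internal: per-position flag of canonically unique k-mers for one genome.
# Returns a list per chromosome of logical vectors over k-mer start offsets
# (0-based); TRUE when the k-mer contains no ambiguous base and its canonical
# form (lexicographic min of the k-mer and its reverse complement) occurs
# exactly once in the whole reference, both strands considered.
kmer_unique_flags <- function(reference, k) {
  seqs <- as.character(reference)
  per_chrom <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(list(fwd = character(), rc = character()))
    starts <- seq_len(L - k + 1L)
    fwd <- substring(s, starts, starts + k - 1L)
    rc_full <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    # k-mer at forward offset i corresponds to reverse-strand substring
    # starting at L - (i + k) + 1 in the reverse-complemented sequence
    rc <- substring(rc_full, L - starts - k + 2L, L - starts + 1L)
    list(fwd = fwd, rc = rc)
  })
  all_fwd <- unlist(lapply(per_chrom, `[[`, "fwd"), use.names = FALSE)
  all_rc <- unlist(lapply(per_chrom, `[[`, "rc"), use.names = FALSE)
  canon <- ifelse(all_fwd <= all_rc, all_fwd, all_rc)
  dup <- duplicated(canon) | duplicated(canon, fromLast = TRUE)
  has_n <- grepl("[^ACGT]", all_fwd)
  uniq <- !dup & !has_n
  lens <- vapply(per_chrom, function(p) length(p$fwd), integer(1))
  split_idx <- rep(seq_along(lens), lens)
  out <- split(uniq, factor(split_idx, levels = seq_along(lens)))
  names(out) <- names(reference)
  out
}

#' Find repetitive-free regions of a reference genome
#'
#' A repetitive-free region is a window of `region_length` bp in which every
#' fully contained k-mer has a unique position in the entire reference
#' (counting both strands: a k-mer and its reverse complement are the same
#' object). k-mers containing ambiguous bases disqualify their window. Up to
#' `regions_per_chromosome` non-overlapping regions are returned per
#' chromosome: the chromosome is partitioned into that many equal bins and
#' the leftmost qualifying window starting in each bin is taken; remaining
#' slots are filled by a greedy left-to-right scan. The search is
#' deterministic. Read depth averaged over such regions estimates true fold
#' coverage free of mapping ambiguity.
#'
#' @param reference A [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences.
#' @param params [qc_parameters()].
#' @return A `data.frame` of regions (`chrom`, `start`, `end`, 0-based
#'   half-open); chromosomes shorter than `region_length` contribute none.
#' @export
find_repetitive_free_regions <- function(reference, params = qc_parameters()) {
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)
  if (length(reference) == 0) stop("empty reference")
  if (is.null(names(reference)) || any(!nzchar(names(reference)))) {
    stop("reference chromosomes must be named")
  }
  if (anyDuplicated(names(reference))) stop("duplicate chromosome names")
  k <- params$k
  L_reg <- params$region_length
  flags <- kmer_unique_flags(reference, k)
  out <- list()
  for (chrom in names(reference)) {
    chrom_len <- Biostrings::width(reference)[names(reference) == chrom]
    if (chrom_len < L_reg) next
    u <- flags[[chrom]]
    # window starting at 0-based s qualifies iff k-mer offsets s..s+L_reg-k
    # (0-based) are all unique; check via cumulative sum of failures
    n_kpos <- length(u)
    win_kmers <- L_reg - k + 1L
    n_win <- chrom_len - L_reg + 1L
    if (n_win < 1 || n_kpos < win_kmers) next
    bad <- cumsum(c(0L, !u))
    s0 <- seq_len(n_win)  # 1-based window start
    ok <- (bad[s0 + win_kmers] - bad[s0]) == 0L
    qualifying <- which(ok)  # 1-based window starts
    if (!length(qualifying)) next
    chosen <- integer(0)
    overlaps_chosen <- function(s) {
      any(abs(chosen - s) < L_reg)
    }
    bins <- floor(seq(0, n_win, length.out = params$regions_per_chromosome + 1L))
    for (b in seq_len(params$regions_per_chromosome)) {
      lo <- bins[b] + 1L; hi <- bins[b + 1L]
      if (hi < lo) next
      cand <- qualifying[qualifying >= lo & qualifying <= hi]
      for (s in cand) {
        if (!overlaps_chosen(s)) { chosen <- c(chosen, s); break }
      }
    }
    if (length(chosen) < params$regions_per_chromosome) {
      for (s in qualifying) {
        if (length(chosen) >= params$regions_per_chromosome) break
        if (!overlaps_chosen(s)) chosen <- c(chosen, s)
      }
    }
    chosen <- sort(chosen)
    if (length(chosen)) {
      out[[chrom]] <- data.frame(chrom = chrom, start = chosen - 1L,
                                 end = chosen - 1L + L_reg,
                                 stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate per-chromosome fold coverage over given regions
#'
#' Computes the mean per-base depth over the union of each chromosome's
#' repetitive-free regions from a bedGraph-style depth track.
#'
#' @param depth Depth track (`chrom`, `start`, `end`, `depth`; 0-based
#'   half-open, piecewise-constant depth).
#' @param regions Regions data.frame from [find_repetitive_free_regions()].
#' @return Named numeric vector of fold coverages, one per chromosome with at
#'   least one region; chromosomes with no regions are absent.
#' @export
chromosome_coverage <- function(depth, regions) {
  if (nrow(regions) == 0) return(stats::setNames(numeric(0), character(0)))
  chroms <- unique(regions$chrom)
  cov <- stats::setNames(numeric(length(chroms)), chroms)
  for (chrom in chroms) {
    reg <- regions[regions$chrom == chrom, , drop = FALSE]
    reg_gr <- IRanges::reduce(IRanges::IRanges(reg$start + 1L, reg$end))
    dep <- depth[depth$chrom == chrom, , drop = FALSE]
    if (nrow(dep) == 0) stop("depth track has no data for chromosome ", chrom)
    dep_gr <- IRanges::IRanges(dep$start + 1L, dep$end)
    hits <- IRanges::findOverlaps(dep_gr, reg_gr)
    if (length(hits) == 0) stop("depth track does not cover regions on ", chrom)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    w <- pmin(IRanges::end(dep_gr)[q], IRanges::end(reg_gr)[s]) -
      pmax(IRanges::start(dep_gr)[q], IRanges::start(reg_gr)[s]) + 1L
    total_bases <- sum(as.numeric(IRanges::width(reg_gr)))
    if (sum(w) < total_bases) {
      stop("depth track does not cover all region bases on ", chrom)
    }
    cov[chrom] <- sum(dep$depth[q] * w) / total_bases
  }
  cov
}

#' Flag chromosomes with outlying coverage
#'
#' A chromosome is an outlier when its coverage deviates from the median of
#' all chromosome coverages by more than `outlier_fraction` of the median.
#' Outliers typically indicate aneuploidy: a trisomy sits near 1.5x (50%
#' above the median), a monosomy near 0.5x. The overall mean and standard
#' deviation (population form, dividing by n) are computed over non-outlier
#' chromosomes only.
#'
#' @param coverages Named numeric vector of per-chromosome fold coverages.
#' @param params [qc_parameters()].
#' @return List with `outliers` (character vector of chromosome names),
#'   `mean` and `sd` over non-outlier chromosomes, and the per-chromosome
#'   `flagged` logical vector.
#' @export
detect_outlier_chromosomes <- function(coverages, params = qc_parameters()) {
  if (length(coverages) < 2) stop("need coverage for at least 2 chromosomes")
  med <- stats::median(coverages)
  flagged <- abs(coverages - med) > params$outlier_fraction * med
  if (all(flagged)) stop("all chromosomes flagged as outliers; no baseline")
  keep <- coverages[!flagged]
  m <- mean(keep)
  s <- sqrt(mean((keep - m)^2))
  list(outliers = names(coverages)[flagged], mean = m, sd = s,
       flagged = flagged)
}

#' Coverage profile of one sample
#'
#' Runs outlier detection over per-chromosome coverages and records the
#' pass/fail verdict: a sample passes when the standard deviation of its
#' non-outlier chromosome coverages is at most `sd_fraction` (default 15%) of
#' their mean. Failure indicates uneven coverage that compromises CNV
#' calling; whole-chromosome aneuploidy shows up as outlier chromosomes
#' rather than as a failed sample.
#'
#' @param coverages Named numeric vector of per-chromosome fold coverages.
#' @param params [qc_parameters()].
#' @param sample_id Optional label carried in the result.
#' @return A list of class `coverage_profile` with `coverages`, `outliers`,
#'   `mean`, `sd`, `pass`, `sample_id`.
#' @export
coverage_profile <- function(coverages, params = qc_parameters(),
                             sample_id = NA_character_) {
  det <- detect_outlier_chromosomes(coverages, params)
  if (sum(!det$flagged) < 2) stop("fewer than 2 non-outlier chromosomes")
  if (det$mean <= 0) stop("non-positive mean coverage")
  structure(list(sample_id = sample_id, coverages = coverages,
                 outliers = det$outliers, mean = det$mean, sd = det$sd,
                 pass = det$sd <= params$sd_fraction * det$mean,
                 sd_fraction = params$sd_fraction),
            class = "coverage_profile")
}

#' Sample-level coverage QC verdict
#'
#' @param profile A `coverage_profile` (or a named coverage vector, in which
#'   case the profile is built first).
#' @param params [qc_parameters()].
#' @return Logical: `TRUE` when the sample passes (sd does not exceed
#'   `sd_fraction` of the mean; the comparison is strict per the rule
#'   "greater than").
#' @export
sample_qc <- function(profile, params = qc_parameters()) {
  if (!inherits(profile, "coverage_profile")) {
    profile <- coverage_profile(profile, params)
  }
  profile$pass
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("Coverage profile", if (!is.na(x$sample_id)) paste0("for ", x$sample_id),
      "\n  chromosomes:", length(x$coverages),
      "\n  outliers:", if (length(x$outliers)) paste(x$outliers, collapse = ", ") else "none",
      "\n  mean (non-outlier):", format(x$mean, digits = 4),
      "\n  sd:", format(x$sd, digits = 4),
      "\n  verdict:", if (x$pass) "PASS" else
        sprintf("FAIL (sd > %.0f%% of mean)", 100 * x$sd_fraction), "\n")
  invisible(x)
}
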