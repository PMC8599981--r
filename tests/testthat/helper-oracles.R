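# Independent brute-force oracles used to validate the package's optimized
# implementations. These deliberately use different mechanics from the
# package code (hash counts via table(), explicit per-base arrays, full
# enumeration) and must stay that way.

# Reverse complement of a character DNA string, base R only.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
}

# Brute-force k-mer census: for each chromosome, a logical vector over k-mer
# start offsets marking canonical k-mers that occur exactly once in the whole
# reference (both strands; ambiguous bases disqualify). Counting is done with
# table() over canonical strings.
oracle_kmer_unique <- function(seqs, k) {
  seqs <- as.character(seqs)
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1) return(character())
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  })
  canon <- lapply(kmers, function(km) {
    vapply(km, function(x) {
      rc <- oracle_revcomp(x)
      if (x <= rc) x else rc
    }, character(1), USE.NAMES = FALSE)
  })
  counts <- table(unlist(canon, use.names = FALSE))
  lapply(seq_along(seqs), function(i) {
    km <- kmers[[i]]
    ok <- !grepl("[^ACGT]", km)
    ok & as.integer(counts[canon[[i]]]) == 1L
  })
}

# All qualifying window starts (0-based) per chromosome: every k-mer fully
# inside the window is unique. Checked against sorted bad positions with
# findInterval, not the package's cumsum path.
oracle_qualifying_windows <- function(seqs, k, region_length) {
  uniq <- oracle_kmer_unique(seqs, k)
  lapply(seq_along(uniq), function(i) {
    L <- nchar(as.character(seqs)[i])
    n_win <- L - region_length + 1L
    if (n_win < 1) return(integer())
    bad <- which(!uniq[[i]])  # 1-based k-mer offsets
    span <- region_length - k  # k-mer offsets s .. s + span must be clean
    qualifies <- vapply(seq_len(n_win), function(s) {
      if (!length(bad)) return(TRUE)
      j <- findInterval(s - 1L, bad) + 1L  # first bad >= s
      j > length(bad) || bad[j] > s + span
    }, logical(1))
    which(qualifies) - 1L
  })
}

# Reproduce the documented deterministic placement over an oracle-derived
# qualifying set: equal bins with leftmost qualifying window per bin, then
# greedy left-to-right fill, non-overlapping.
oracle_place_regions <- function(qualifying0, n_win, region_length, n_regions) {
  qualifying <- qualifying0 + 1L
  chosen <- integer(0)
  ok <- function(s) !length(chosen) || all(abs(chosen - s) >= region_length)
  bins <- floor(seq(0, n_win, length.out = n_regions + 1L))
  for (b in seq_len(n_regions)) {
    cand <- qualifying[qualifying >= bins[b] + 1L & qualifying <= bins[b + 1L]]
    for (s in cand) if (ok(s)) { chosen <- c(chosen, s); break }
  }
  for (s in qualifying) {
    if (length(chosen) >= n_regions) break
    if (ok(s)) chosen <- c(chosen, s)
  }
  sort(chosen) - 1L
}

# Per-base brute-force frequency filter: explicit integer count array over a
# small genome, then the >threshold / >overlap_fraction rule per event.
oracle_frequency_filter <- function(cohort, count_threshold, overlap_fraction,
                                    genome_length = NULL) {
  keep <- logical(nrow(cohort))
  for (chrom in unique(cohort$chrom)) {
    idx <- which(cohort$chrom == chrom)
    L <- if (is.null(genome_length)) max(cohort$end[idx]) else genome_length
    counts <- integer(L)
    for (i in idx) {
      b <- (cohort$start[i] + 1L):cohort$end[i]
      counts[b] <- counts[b] + 1L
    }
    for (i in idx) {
      b <- (cohort$start[i] + 1L):cohort$end[i]
      frac_high <- mean(counts[b] > count_threshold)
      keep[i] <- !(frac_high > overlap_fraction)
    }
  }
  keep
}

# Exhaustive one-sided permutation p-value by direct enumeration of all
# case-index subsets.
oracle_exact_perm_p <- function(values, is_case) {
  n <- length(values); n1 <- sum(is_case)
  obs <- mean(values[is_case]) - mean(values[!is_case])
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2, function(ix) mean(values[ix]) - mean(values[-ix]))
  mean(stats >= obs - 1e-12)
}

# Random CNV call table for property tests.
random_calls <- function(n, sample_id = "S1", chroms = c("chr1", "chr2"),
                         max_pos = 10000L, max_len = 800L) {
  start <- sample.int(max_pos - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  cn <- sample(c(0L, 1L, 3L, 4L), n, replace = TRUE)
  cnv_calls(chrom = sample(chroms, n, replace = TRUE), start = start,
            end = start + len, copy_number = cn, sample_id = sample_id)
}
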