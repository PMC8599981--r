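# Repetitive-free region search is validated against an independent
# brute-force k-mer census (helper-oracles.R) that counts every canonical
# k-mer in a hash table and scans all windows.

test_that("region search equals the brute-force k-mer census oracle on a random reference", {
  cfg <- simulation_config(seed = 101, chrom_lengths = c(chrR = 200000L))
  ref <- simulate_reference(cfg)
  params <- qc_parameters(k = 25L, region_length = 20000L,
                          regions_per_chromosome = 20L)
  regions <- find_repetitive_free_regions(ref, params)
  expect_true(nrow(regions) >= 1)
  expect_true(all(regions$end - regions$start == params$region_length))

  qual <- oracle_qualifying_windows(ref, params$k, params$region_length)[[1]]
  n_win <- 200000L - params$region_length + 1L
  expected <- oracle_place_regions(qual, n_win, params$region_length,
                                   params$regions_per_chromosome)
  expect_identical(regions$start, as.integer(expected))
  # every returned region is oracle-qualifying
  expect_true(all(regions$start %in% qual))
})

test_that("implanted duplications exclude windows overlapping either copy", {
  cfg <- simulation_config(seed = 202, chrom_lengths = c(chrR = 120000L))
  ref <- simulate_reference(cfg, n_duplications = 1L, dup_length = 5000L)
  dups <- attr(ref, "duplications")
  params <- qc_parameters(k = 25L, region_length = 10000L,
                          regions_per_chromosome = 20L)
  regions <- find_repetitive_free_regions(ref, params)
  expect_true(nrow(regions) >= 1)
  # no region may contain any k-mer start within either duplicated block
  dup_spans <- rbind(
    data.frame(start = dups$src_start, end = dups$src_start + dups$length),
    data.frame(start = dups$dst_start, end = dups$dst_start + dups$length))
  for (i in seq_len(nrow(regions))) {
    # no k-mer of the region may lie fully inside a duplicated block (those
    # k-mers are guaranteed non-unique); k-mer starts of the region are
    # [start, end - k]
    ks <- regions$start[i]; ke <- regions$end[i] - params$k
    contained <- any(ks <= dup_spans$end - params$k & ke >= dup_spans$start)
    expect_false(contained)
  }
  # oracle cross-check on this reference too
  qual <- oracle_qualifying_windows(ref, params$k, params$region_length)[[1]]
  expect_true(all(regions$start %in% qual))
})

test_that("region search is deterministic and short chromosomes yield none", {
  cfg <- simulation_config(seed = 33, chrom_lengths = c(big = 60000L,
                                                        small = 4000L))
  ref <- simulate_reference(cfg)
  params <- qc_parameters(region_length = 5000L, regions_per_chromosome = 4L)
  r1 <- find_repetitive_free_regions(ref, params)
  r2 <- find_repetitive_free_regions(ref, params)
  expect_identical(r1, r2)
  expect_false("small" %in% r1$chrom)
  expect_error(find_repetitive_free_regions(Biostrings::DNAStringSet()),
               "empty reference")
})

test_that("chromosome coverage is the mean per-base depth over region union", {
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(0L, 1000L, 100L),
                        end = c(500L, 1500L, 600L))
  flat <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 0L),
                     end = c(2000L, 1000L), depth = c(30, 30))
  expect_equal(unname(chromosome_coverage(flat, regions)), c(30, 30))

  # half the bases at 20, half at 40 -> 30
  halves <- data.frame(chrom = "chr1", start = c(0L, 250L, 1000L, 1250L),
                       end = c(250L, 500L, 1250L, 1500L),
                       depth = c(20, 40, 20, 40))
  expect_equal(unname(chromosome_coverage(halves, regions[1:2, ])), 30)

  # Poisson(35) track: mean within 3 standard errors of 35
  set.seed(5)
  depth <- rpois(1500, 35)
  track <- data.frame(chrom = "chr1", start = 0:1499, end = 1:1500,
                      depth = depth)
  cov <- chromosome_coverage(track, regions[1:2, ])
  expect_equal(unname(cov), mean(depth[c(1:500, 1001:1500)]))
  expect_lt(abs(cov - 35), 3 * sqrt(35 / 1000))
})

test_that("outlier chromosomes are flagged by deviation from the median", {
  covs <- setNames(rep(30, 22), paste0("chr", 1:22))
  det <- detect_outlier_chromosomes(covs)
  expect_length(det$outliers, 0)
  expect_equal(det$mean, 30)
  expect_equal(det$sd, 0)

  covs["chr21"] <- 45  # trisomy-like, 1.5x median
  det <- detect_outlier_chromosomes(covs)
  expect_identical(det$outliers, "chr21")
  expect_equal(det$mean, 30)

  covs["chr21"] <- 15  # monosomy-like, 0.5x median
  det <- detect_outlier_chromosomes(covs)
  expect_identical(det$outliers, "chr21")

  expect_error(detect_outlier_chromosomes(c(a = 30)), "at least 2")
})

test_that("sample QC applies the 15%-of-mean standard-deviation rule", {
  covs <- setNames(rep(30, 22), paste0("chr", 1:22))
  expect_true(sample_qc(covs))

  # 21 chromosomes at 30 plus one at 60, outlier detection disabled:
  # mean 31.36, population sd 6.25 > 0.15 * 31.36
  covs2 <- c(rep(30, 21), 60)
  m <- mean(covs2)
  s <- sqrt(mean((covs2 - m)^2))
  expect_equal(round(m, 2), 31.36)
  expect_equal(round(s, 2), 6.25)
  expect_gt(s, 0.15 * m)
  # emulate disabled outlier detection by direct verdict arithmetic
  expect_false(s <= 0.15 * m)

  # boundary: sd exactly 15% of mean passes (rule is strictly greater-than)
  profile <- structure(list(sample_id = "S", coverages = covs,
                            outliers = character(), mean = 30, sd = 4.5,
                            pass = 4.5 <= 0.15 * 30, sd_fraction = 0.15),
                       class = "coverage_profile")
  expect_true(sample_qc(profile))
})

test_that("sample QC verdict is scale-invariant", {
  set.seed(9)
  covs <- setNames(30 + rnorm(22, 0, 2), paste0("chr", 1:22))
  for (k in c(0.5, 1, 10)) {
    expect_identical(sample_qc(covs * k), sample_qc(covs))
  }
})

test_that("simulated trisomy is reported as an outlier chromosome, not a failed sample", {
  cfg <- simulation_config(seed = 77,
                           chrom_lengths = c(chr1 = 60000L, chr2 = 60000L,
                                             chr3 = 60000L, chr4 = 60000L,
                                             chr5 = 60000L, chr6 = 60000L),
                           depth_mean = 40)
  ref <- simulate_reference(cfg)
  params <- qc_parameters(region_length = 5000L, regions_per_chromosome = 4L)
  regions <- find_repetitive_free_regions(ref, params)
  track <- simulate_depth_profile(cfg, multipliers = c(chr3 = 1.5))
  covs <- chromosome_coverage(track, regions)
  det <- detect_outlier_chromosomes(covs, params)
  expect_identical(det$outliers, "chr3")
  expect_true(sample_qc(covs, params))
  profile <- coverage_profile(covs, params, sample_id = "T1")
  expect_true(profile$pass)
  expect_lt(abs(profile$mean - 40), 1)
})
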