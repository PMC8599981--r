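test_that("generator output is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(seed = 31, n_samples = 10, n_cases = 5,
                           n_pool_cnvs = 30,
                           chrom_lengths = c(chr1 = 100000L, chr2 = 60000L))
  expect_identical(as.character(simulate_reference(cfg)),
                   as.character(simulate_reference(cfg)))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_identical(simulate_depth_profile(cfg), simulate_depth_profile(cfg))
  expect_identical(simulate_mask(cfg), simulate_mask(cfg))
})

test_that("implanted reference duplications are seen >= 2 times genome-wide", {
  cfg <- simulation_config(seed = 55, chrom_lengths = c(chrA = 60000L,
                                                        chrB = 50000L))
  ref <- simulate_reference(cfg, n_duplications = 1L, dup_length = 2000L)
  dups <- attr(ref, "duplications")
  expect_equal(nrow(dups), 1L)
  k <- 25L
  uniq <- oracle_kmer_unique(ref, k)
  src_idx <- which(names(ref) == dups$src_chrom[1])
  # every k-mer fully inside the source block occurs at least twice
  offs <- (dups$src_start[1] + 1L):(dups$src_start[1] + dups$length[1] - k + 1L)
  expect_true(all(!uniq[[src_idx]][offs]))
})

test_that("cohort genotypes recover configured allele frequencies", {
  cfg <- simulation_config(seed = 63, n_samples = 1000, n_cases = 500,
                           n_pool_cnvs = 30L, af_shape1 = 2, af_shape2 = 4,
                           chrom_lengths = c(chr1 = 500000L, chr2 = 400000L))
  sim <- simulate_cohort(cfg)
  key <- paste(sim$truth$chrom, sim$truth$start, sim$truth$end)
  pool_key <- paste(sim$pool$chrom, sim$pool$start, sim$pool$end)
  carriers <- as.integer(table(factor(key, levels = pool_key)))
  expected <- 1 - (1 - sim$pool$af)^2
  se <- sqrt(pmax(expected * (1 - expected), 1e-6) / 1000)
  within <- abs(carriers / 1000 - expected) <= 3 * se
  # essentially all loci inside a 3-standard-error band
  expect_gte(mean(within), 0.9)
})

test_that("a null effect leaves case and control burdens exchangeable", {
  cfg <- simulation_config(seed = 17, n_samples = 60, n_cases = 30,
                           n_pool_cnvs = 60, burden_effect = 0,
                           chrom_lengths = c(chr1 = 400000L, chr2 = 300000L))
  sim <- simulate_cohort(cfg)
  f <- compute_burden_features(sim$truth, sim$phenotypes, "DelDup")
  res <- permutation_test(as.numeric(f$n_events), f$status == "case",
                          n_permutations = 500, seed = 3)
  expect_gt(res$p_value, 0.001)
})

test_that("the injected duplication excess matches its expectation", {
  cfg <- simulation_config(seed = 251, n_samples = 200, n_cases = 100,
                           n_pool_cnvs = 100, burden_effect = 16,
                           chrom_lengths = c(chr1 = 1000000L,
                                             chr2 = 800000L))
  sim <- simulate_cohort(cfg)
  f <- compute_burden_features(sim$truth, sim$phenotypes, "Dup")
  diff <- mean(f$n_events[f$status == "case"]) -
    mean(f$n_events[f$status == "control"])
  # Poisson(16) per case: se of the group-mean difference ~ sqrt(16/100 + var0)
  expect_lt(abs(diff - 16), 3 * sqrt(16 / 100 + 16 / 100) + 1)
})

test_that("zero noise reproduces truth; full splitting conserves unions", {
  cfg <- simulation_config(seed = 5, n_samples = 8, n_cases = 4,
                           n_pool_cnvs = 25,
                           chrom_lengths = c(chr1 = 150000L),
                           callers = list(
                             clean = list(fn_rate = 0, jitter_sd = 0,
                                          split_rate = 0),
                             splitter = list(fn_rate = 0, jitter_sd = 0,
                                             split_rate = 1)))
  sim <- simulate_cohort(cfg)
  obs <- simulate_caller_observations(sim$truth, cfg)
  clean <- sort_calls(obs$clean)
  truth <- sort_calls(sim$truth)
  expect_equal(clean[, c("chrom", "start", "end", "copy_number", "sample_id")],
               truth[, c("chrom", "start", "end", "copy_number", "sample_id")])
  # splitter: every truth event is exactly covered by its book-ended pieces
  sp <- obs$splitter
  expect_equal(nrow(sp), 2L * nrow(truth) - sum((truth$end - truth$start) < 2))
  for (sid in unique(truth$sample_id)) {
    t_s <- truth[truth$sample_id == sid, , drop = FALSE]
    s_s <- sp[sp$sample_id == sid, , drop = FALSE]
    expect_equal(sum(s_s$end - s_s$start), sum(t_s$end - t_s$start))
  }
})

test_that("depth tracks carry the configured coverage and aneuploidy", {
  cfg <- simulation_config(seed = 8, depth_mean = 37,
                           chrom_lengths = c(chr1 = 60000L, chr2 = 60000L,
                                             chr3 = 60000L, chr4 = 60000L,
                                             chr5 = 60000L))
  ref <- simulate_reference(cfg)
  params <- qc_parameters(region_length = 5000L, regions_per_chromosome = 4L)
  regions <- find_repetitive_free_regions(ref, params)
  track <- simulate_depth_profile(cfg)
  covs <- chromosome_coverage(track, regions)
  expect_true(all(abs(covs - 37) / 37 < 0.01))
  expect_true(sample_qc(covs, params))
  tri <- simulate_depth_profile(cfg, multipliers = c(chr2 = 1.5))
  covs_tri <- chromosome_coverage(tri, regions)
  det <- detect_outlier_chromosomes(covs_tri, params)
  expect_identical(det$outliers, "chr2")
})

test_that("fixture directories are complete, loss-free and deterministic", {
  cfg <- simulation_config(seed = 21, n_samples = 6, n_cases = 3,
                           n_pool_cnvs = 20,
                           chrom_lengths = c(chr1 = 80000L, chr2 = 60000L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixtures(cfg, d1)
  write_fixtures(cfg, d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_identical(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_true(all(c("reference.fa", "cohort_genotyped.vcf", "phenotypes.tsv",
                    "truth.bed", "mask.bed", "manifest.txt") %in% files))

  # round-trips through the package readers without loss
  truth <- read_cnv_bed(file.path(d1, "truth.bed"))
  phe <- read_phenotypes(file.path(d1, "phenotypes.tsv"))
  expect_setequal(unique(truth$sample_id), intersect(phe$sample_id, truth$sample_id))
  v <- read_cnv_vcf(file.path(d1, "cohort_genotyped.vcf"))
  expect_equal(nrow(v$records), 20L)
  for (sid in phe$sample_id) {
    calls <- vcf_to_sample_calls(v, sid)
    t_s <- sort_calls(truth[truth$sample_id == sid, , drop = FALSE])
    expect_equal(calls[, c("chrom", "start", "end", "copy_number")],
                 t_s[, c("chrom", "start", "end", "copy_number")])
  }
  mask <- read_mask(file.path(d1, "mask.bed"))
  comp <- mask_composition(mask)
  expect_equal(sum(comp), 1)
  # composition recovers the configured class proportions to within the
  # segment-length granularity of the mask
  expect_lt(max(abs(comp - cfg$mask_proportions[names(comp)])), 0.1)
  big_mask <- simulate_mask(simulation_config(seed = 4))
  classes <- c("P", "N", "L", "H", "Z")
  expect_lt(max(abs(mask_composition(big_mask)[classes] -
                      simulation_config(seed = 4)$mask_proportions[classes])),
            0.02)
  depth_file <- list.files(d1, pattern = "bedgraph$", full.names = TRUE)[1]
  expect_gt(nrow(read_depth_track(depth_file)), 0)
})
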