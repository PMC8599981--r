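#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator. The defaults describe a desk-scale
#' whole-genome cohort: four chromosomes totalling ~2.8 Mb, 400 samples (200
#' cases, 200 controls) carrying genotypes drawn from a pool of 300
#' population CNVs whose allele frequencies are Beta-distributed and skewed
#' toward rarity, ~85% deletions (the deletion:duplication ratio typical of
#' WGS CNV callsets), log-normal event lengths with median ~3 kb, three
#' pseudo-callers with complementary noise profiles, 37x mean depth (a
#' realistic WGS cohort average), and accessibility-mask class proportions of
#' P/N/L/H/Z = 89/5.3/1.4/0.6/3.7%. The case/control burden effect
#' (`burden_effect`, expected extra private duplications per case) defaults
#' to 0, i.e. the null.
#'
#' @param seed Integer seed; all generator output is bit-reproducible given
#'   the seed.
#' @param n_samples,n_cases Cohort size and number of cases.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param n_pool_cnvs Size of the population CNV pool.
#' @param del_fraction Fraction of pool CNVs that are deletions.
#' @param length_meanlog,length_sdlog Log-normal event-length parameters (bp
#'   scale).
#' @param min_length Minimum event length (bp).
#' @param af_shape1,af_shape2 Beta parameters of the allele-frequency
#'   distribution.
#' @param group_weights Named sampling weights for ancestry groups.
#' @param burden_effect Expected extra private duplications per case
#'   (Poisson mean; 0 disables the effect).
#' @param effect_channel `"dup_count"` (default) or `"del_count"`: which
#'   event type carries the injected effect.
#' @param callers Named list of caller noise profiles, each with `fn_rate`,
#'   `jitter_sd` (bp) and `split_rate`.
#' @param depth_mean Mean fold coverage of simulated depth tracks.
#' @param mask_proportions Named fractions over classes P/N/L/H/Z.
#' @param mask_segment Mean mask segment length (bp).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 400L, n_cases = 200L,
                              chrom_lengths = c(chr1 = 1000000L,
                                                chr2 = 800000L,
                                                chr3 = 600000L,
                                                chr4 = 400000L),
                              n_pool_cnvs = 300L,
                              del_fraction = 0.85,
                              length_meanlog = log(3000), length_sdlog = 0.8,
                              min_length = 200L,
                              af_shape1 = 0.5, af_shape2 = 5,
                              group_weights = c(AA = 978, Hispanic = 1247,
                                                NHW = 1566, Other = 9),
                              burden_effect = 0,
                              effect_channel = c("dup_count", "del_count"),
                              callers = list(
                                rd_small = list(fn_rate = 0.05, jitter_sd = 30,
                                                split_rate = 0.1),
                                rd_large = list(fn_rate = 0.10, jitter_sd = 50,
                                                split_rate = 0.0),
                                pe_sr = list(fn_rate = 0.05, jitter_sd = 10,
                                             split_rate = 0.0)),
                              depth_mean = 37,
                              mask_proportions = c(P = 0.89, N = 0.053,
                                                   L = 0.014, H = 0.006,
                                                   Z = 0.037),
                              mask_segment = 10000L) {
  effect_channel <- match.arg(effect_channel)
  stopifnot(n_cases <= n_samples, n_samples >= 1,
            all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
            del_fraction >= 0, del_fraction <= 1,
            burden_effect >= 0, depth_mean > 0,
            abs(sum(mask_proportions) - 1) < 1e-6)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_cases = as.integer(n_cases),
                 chrom_lengths = chrom_lengths,
                 n_pool_cnvs = as.integer(n_pool_cnvs),
                 del_fraction = del_fraction,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 min_length = as.integer(min_length),
                 af_shape1 = af_shape1, af_shape2 = af_shape2,
                 group_weights = group_weights,
                 burden_effect = burden_effect,
                 effect_channel = effect_channel,
                 callers = callers, depth_mean = depth_mean,
                 mask_proportions = mask_proportions,
                 mask_segment = as.integer(mask_segment)),
            class = "simulation_config")
}

#' Simulate a reference genome
#'
#' Generates i.i.d. random-base chromosome sequences, optionally implanting
#' duplicated blocks (a block copied verbatim to a second locus) so that
#' k-mer-uniqueness scanning has known repetitive regions to avoid. At the
#' default chromosome sizes random 25-mers are essentially always unique, so
#' a duplication-free simulated chromosome of a few hundred kb yields
#' abundant repetitive-free regions.
#'
#' @param config [simulation_config()].
#' @param n_duplications Number of duplicated blocks to implant.
#' @param dup_length Length (bp) of each duplicated block.
#' @param seed Seed (defaults to `config$seed`).
#' @return A [Biostrings::DNAStringSet]; implanted blocks are recorded in
#'   attribute `duplications` (`data.frame` of source and destination loci).
#' @export
simulate_reference <- function(config = simulation_config(),
                               n_duplications = 0L, dup_length = 5000L,
                               seed = config$seed) {
  set.seed(seed)
  lens <- config$chrom_lengths
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  dups <- data.frame(src_chrom = character(), src_start = integer(),
                     dst_chrom = character(), dst_start = integer(),
                     length = integer(), stringsAsFactors = FALSE)
  if (n_duplications > 0) {
    if (any(lens < 2L * dup_length + 2L)) {
      stop("chromosomes too short for requested duplication length")
    }
    for (i in seq_len(n_duplications)) {
      src_chrom <- sample(names(lens), 1)
      dst_chrom <- sample(names(lens), 1)
      repeat {
        src_start <- sample.int(lens[[src_chrom]] - dup_length, 1)
        dst_start <- sample.int(lens[[dst_chrom]] - dup_length, 1)
        if (src_chrom != dst_chrom ||
            abs(src_start - dst_start) >= dup_length) break
      }
      block <- substring(seqs[[src_chrom]], src_start, src_start + dup_length - 1L)
      substring(seqs[[dst_chrom]], dst_start, dst_start + dup_length - 1L) <- block
      dups[i, ] <- list(src_chrom, src_start - 1L, dst_chrom, dst_start - 1L,
                        as.integer(dup_length))
    }
  }
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- names(lens)
  attr(ref, "duplications") <- dups
  ref
}

# Internal: draw one pool CNV (chrom, start, end) with log-normal length.
draw_pool_interval <- function(config) {
  lens <- config$chrom_lengths
  chrom <- sample(names(lens), 1, prob = lens / sum(lens))
  L <- max(config$min_length,
           round(stats::rlnorm(1, config$length_meanlog, config$length_sdlog)))
  L <- min(L, floor(lens[[chrom]] / 10))
  start <- sample.int(lens[[chrom]] - L, 1) - 1L
  list(chrom = chrom, start = as.integer(start), end = as.integer(start + L))
}

#' Simulate a cohort of CNV genotypes with phenotypes
#'
#' Draws a pool of population CNVs (positions, log-normal lengths, Beta
#' allele frequencies, DEL/DUP types); pool events overlapping an existing
#' pool event of the *other* type are re-drawn so the truth set is
#' conflict-free by construction. Each sample's genotype at each pool CNV is
#' binomial in the allele frequency; zygosity maps to copy number (DEL het 1,
#' DEL hom 0, DUP het 3, DUP hom 4). Case status is assigned to `n_cases`
#' random samples and ancestry groups by the configured weights. When
#' `burden_effect > 0`, each case additionally receives Poisson-distributed
#' private duplications (or deletions, per `effect_channel`) placed clear of
#' pool events, injecting a case/control burden difference of known expected
#' size.
#'
#' @param config [simulation_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `truth` (cohort CNV call table of every planted event),
#'   `pool` (pool table with `af`), and `phenotypes`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = config$seed) {
  set.seed(seed)
  lens <- config$chrom_lengths
  # --- pool ---
  pool <- data.frame(chrom = character(), start = integer(), end = integer(),
                     svtype = character(), af = numeric(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(config$n_pool_cnvs)) {
    svtype <- if (stats::runif(1) < config$del_fraction) "DEL" else "DUP"
    for (try in 1:100) {
      iv <- draw_pool_interval(config)
      conflict <- any(pool$chrom == iv$chrom & pool$svtype != svtype &
                      pool$start < iv$end & iv$start < pool$end)
      if (!conflict) break
    }
    pool[i, c("chrom", "start", "end", "svtype")] <-
      list(iv$chrom, iv$start, iv$end, svtype)
  }
  pool$af <- stats::rbeta(config$n_pool_cnvs, config$af_shape1, config$af_shape2)
  pool$id <- sprintf("pool_%04d", seq_len(nrow(pool)))

  # --- phenotypes ---
  sample_ids <- sprintf("S%04d", seq_len(config$n_samples))
  status <- rep("control", config$n_samples)
  status[sample(config$n_samples, config$n_cases)] <- "case"
  group <- sample(names(config$group_weights), config$n_samples, replace = TRUE,
                  prob = config$group_weights)
  phenotypes <- data.frame(sample_id = sample_ids, family_id = sample_ids,
                           status = status, group = group,
                           stringsAsFactors = FALSE)

  # --- genotypes -> truth events ---
  n_alt <- matrix(stats::rbinom(nrow(pool) * config$n_samples, 2,
                                rep(pool$af, each = config$n_samples)),
                  nrow = config$n_samples)
  rows <- list()
  for (s in seq_len(config$n_samples)) {
    carried <- which(n_alt[s, ] > 0)
    if (length(carried)) {
      hom <- n_alt[s, carried] >= 2
      cn <- ifelse(pool$svtype[carried] == "DEL",
                   ifelse(hom, 0L, 1L), ifelse(hom, 4L, 3L))
      rows[[length(rows) + 1L]] <- cnv_calls(
        chrom = pool$chrom[carried], start = pool$start[carried],
        end = pool$end[carried], copy_number = cn,
        sample_id = sample_ids[s], source = "truth")
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else cnv_calls()

  # --- injected burden effect: private events in cases ---
  if (config$burden_effect > 0) {
    eff_type <- if (config$effect_channel == "dup_count") "DUP" else "DEL"
    eff_cn <- if (eff_type == "DUP") 3L else 1L
    extra_rows <- list()
    for (s in which(status == "case")) {
      n_extra <- stats::rpois(1, config$burden_effect)
      placed <- 0L
      guard <- 0L
      sample_events <- truth[truth$sample_id == sample_ids[s], , drop = FALSE]
      while (placed < n_extra && guard < 1000L * max(n_extra, 1L)) {
        guard <- guard + 1L
        iv <- draw_pool_interval(config)
        clash <- any(pool$chrom == iv$chrom &
                     pool$start < iv$end & iv$start < pool$end) ||
          any(sample_events$chrom == iv$chrom &
              sample_events$start < iv$end & iv$start < sample_events$end)
        if (clash) next
        newc <- cnv_calls(chrom = iv$chrom, start = iv$start, end = iv$end,
                          copy_number = eff_cn, sample_id = sample_ids[s],
                          source = "truth_effect")
        sample_events <- rbind(sample_events, newc)
        extra_rows[[length(extra_rows) + 1L]] <- newc
        placed <- placed + 1L
      }
    }
    if (length(extra_rows)) truth <- rbind(truth, do.call(rbind, extra_rows))
  }
  list(truth = sort_calls(truth), pool = pool, phenotypes = phenotypes)
}

#' Simulate noisy caller observations of a truth cohort
#'
#' Each configured pseudo-caller re-emits the truth events subject to
#' Bernoulli missed calls (`fn_rate`), Gaussian breakpoint jitter
#' (`jitter_sd` bp, rounded; intervals re-clamped to length at least 1 and
#' start at least 0), and — with probability `split_rate` — splitting of an
#' event into two book-ended pieces whose union is the jittered interval
#' (emulating read-depth callers fragmenting large CNVs).
#'
#' @param truth Truth cohort CNV table from [simulate_cohort()].
#' @param config [simulation_config()] (supplies `callers`).
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return Named list (one element per caller) of cohort-wide CNV call
#'   tables with `source` set to the caller name.
#' @export
simulate_caller_observations <- function(truth,
                                         config = simulation_config(),
                                         seed = config$seed + 1L) {
  set.seed(seed)
  out <- list()
  for (caller in names(config$callers)) {
    prof <- config$callers[[caller]]
    kept <- truth[stats::runif(nrow(truth)) >= prof$fn_rate, , drop = FALSE]
    if (nrow(kept) == 0) { out[[caller]] <- cnv_calls(); next }
    js <- prof$jitter_sd
    start <- pmax(0L, as.integer(round(kept$start + stats::rnorm(nrow(kept), 0, js))))
    end <- as.integer(round(kept$end + stats::rnorm(nrow(kept), 0, js)))
    end <- pmax(end, start + 1L)
    obs <- cnv_calls(chrom = kept$chrom, start = start, end = end,
                     copy_number = kept$copy_number,
                     sample_id = kept$sample_id, source = caller)
    split <- stats::runif(nrow(obs)) < prof$split_rate & (obs$end - obs$start) >= 2L
    if (any(split)) {
      sp <- obs[split, , drop = FALSE]
      cut <- sp$start + vapply(sp$end - sp$start,
                               function(w) sample.int(w - 1L, 1), integer(1))
      left <- sp; left$end <- cut
      right <- sp; right$start <- cut
      obs <- rbind(obs[!split, , drop = FALSE], left, right)
    }
    out[[caller]] <- sort_calls(obs)
  }
  out
}

#' Simulate a per-base depth track
#'
#' Per-base Poisson depth with mean `depth_mean` scaled by an optional
#' per-chromosome multiplier (1.5 emulates a trisomy, 0.5 a monosomy),
#' returned as a run-length-compressed bedGraph-style table.
#'
#' @param config [simulation_config()].
#' @param multipliers Named per-chromosome multipliers (default 1
#'   everywhere).
#' @param seed Seed (defaults to `config$seed + 2`).
#' @return Depth track `data.frame` (`chrom`, `start`, `end`, `depth`).
#' @export
simulate_depth_profile <- function(config = simulation_config(),
                                   multipliers = NULL,
                                   seed = config$seed + 2L) {
  set.seed(seed)
  lens <- config$chrom_lengths
  rows <- list()
  for (chrom in names(lens)) {
    mult <- if (!is.null(multipliers) && chrom %in% names(multipliers))
      multipliers[[chrom]] else 1
    depth <- stats::rpois(lens[[chrom]], config$depth_mean * mult)
    r <- rle(depth)
    ends <- cumsum(r$lengths)
    rows[[chrom]] <- data.frame(chrom = chrom,
                                start = c(0L, ends[-length(ends)]),
                                end = ends, depth = r$values,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an accessibility mask
#'
#' Partitions each chromosome into segments of geometric length (mean
#' `mask_segment` bp) and assigns each segment a class label with the
#' configured proportions, defaulting to the class split of the 1000 Genomes
#' pilot accessibility mask (P 89%, N 5.3%, L 1.4%, H 0.6%, Z 3.7%).
#'
#' @param config [simulation_config()].
#' @param seed Seed (defaults to `config$seed + 3`).
#' @return Mask table (`chrom`, `start`, `end`, `label`).
#' @export
simulate_mask <- function(config = simulation_config(),
                          seed = config$seed + 3L) {
  set.seed(seed)
  rows <- list()
  for (chrom in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[chrom]]
    pos <- 0L
    while (pos < L) {
      seg <- max(1L, stats::rgeom(1, 1 / config$mask_segment))
      end <- min(L, pos + seg)
      rows[[length(rows) + 1L]] <- data.frame(chrom = chrom, start = pos,
                                              end = end, label = NA_character_,
                                              stringsAsFactors = FALSE)
      pos <- end
    }
  }
  mask <- do.call(rbind, rows)
  # assign classes by remaining base budget (in shuffled segment order) so
  # the realized composition tracks the configured proportions to within a
  # segment length
  budget <- config$mask_proportions * sum(mask$end - mask$start)
  for (i in sample.int(nrow(mask))) {
    lab <- names(budget)[which.max(budget)]
    mask$label[i] <- lab
    budget[lab] <- budget[lab] - (mask$end[i] - mask$start[i])
  }
  rownames(mask) <- NULL
  class(mask) <- c("mask_track", class(mask))
  mask
}

#' Write a complete fixture directory
#'
#' Simulates and writes every input the pipeline consumes: reference FASTA,
#' per-caller per-sample CNV VCFs, a multi-sample genotyped VCF, depth
#' bedGraphs for a subset of samples, a mask BED, the phenotype TSV, the
#' truth table (BED with sample column), and a manifest recording the seed
#' and key parameters. Byte-identical across runs with the same
#' configuration.
#'
#' @param config [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param n_depth_samples How many samples receive a depth bedGraph.
#' @return `dir`, invisibly; files are listed in `manifest.txt`.
#' @export
write_fixtures <- function(config = simulation_config(), dir,
                           n_depth_samples = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- simulate_reference(config)
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fa"))
  sim <- simulate_cohort(config)
  write_phenotypes(sim$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_cnv_bed(sim$truth, file.path(dir, "truth.bed"), sample_col = TRUE)

  obs <- simulate_caller_observations(sim$truth, config)
  for (caller in names(obs)) {
    cdir <- file.path(dir, caller)
    if (!dir.exists(cdir)) dir.create(cdir)
    for (sid in unique(sim$phenotypes$sample_id)) {
      calls <- obs[[caller]]
      calls <- calls[calls$sample_id == sid, , drop = FALSE]
      if (nrow(calls) == 0) next
      gt <- matrix(ifelse(calls$copy_number %in% c(0L, 4L), "1/1", "0/1"),
                   ncol = 1, dimnames = list(NULL, sid))
      write_cnv_vcf(calls, file.path(cdir, paste0(sid, ".vcf")),
                    genotypes = gt, contigs = config$chrom_lengths)
    }
  }

  # multi-sample genotyped VCF over the pool
  gt <- matrix("0/0", nrow = nrow(sim$pool), ncol = config$n_samples,
               dimnames = list(NULL, sim$phenotypes$sample_id))
  key <- paste(sim$truth$chrom, sim$truth$start, sim$truth$end)
  pool_key <- paste(sim$pool$chrom, sim$pool$start, sim$pool$end)
  m <- match(key, pool_key)
  hit <- which(!is.na(m))
  for (i in hit) {
    hom <- sim$truth$copy_number[i] %in% c(0L, 4L)
    gt[m[i], sim$truth$sample_id[i]] <- if (hom) "1/1" else "0/1"
  }
  write_cnv_vcf(sim$pool, file.path(dir, "cohort_genotyped.vcf"),
                genotypes = gt, contigs = config$chrom_lengths)

  depth_samples <- utils::head(sim$phenotypes$sample_id, n_depth_samples)
  for (i in seq_along(depth_samples)) {
    track <- simulate_depth_profile(config, seed = config$seed + 100L + i)
    write_depth_track(track, file.path(dir,
                                       paste0(depth_samples[i], ".depth.bedgraph")))
  }

  mask <- simulate_mask(config)
  write_mask(mask, file.path(dir, "mask.bed"))

  manifest <- c(
    sprintf("seed: %d", config$seed),
    sprintf("n_samples: %d", config$n_samples),
    sprintf("n_cases: %d", config$n_cases),
    sprintf("n_pool_cnvs: %d", config$n_pool_cnvs),
    sprintf("burden_effect: %g", config$burden_effect),
    sprintf("depth_mean: %g", config$depth_mean),
    sprintf("chromosomes: %s",
            paste(sprintf("%s=%d", names(config$chrom_lengths),
                          config$chrom_lengths), collapse = ",")),
    "files:",
    sprintf("  - %s", sort(list.files(dir, recursive = TRUE)))
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
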