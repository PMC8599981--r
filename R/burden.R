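BURDEN_FEATURES <- c("n_events", "prop_samples", "total_kb", "avg_kb")
EVENT_CLASSES <- c("DelDup", "Del", "Dup")
BURDEN_GROUPS <- c("ALL", "AA", "Hispanic", "NHW")

# Internal: subset a cohort table to one event class.
subset_event_class <- function(cohort, event_class) {
  if (!event_class %in% EVENT_CLASSES) {
    stop("unknown event class: ", event_class,
         " (expected one of ", paste(EVENT_CLASSES, collapse = ", "), ")")
  }
  switch(event_class,
         DelDup = cohort,
         Del = cohort[cohort$svtype == "DEL", , drop = FALSE],
         Dup = cohort[cohort$svtype == "DUP", , drop = FALSE])
}

#' Per-sample CNV burden features
#'
#' For one event class (DelDup = deletions and duplications together, Del,
#' Dup) computes the four burden features per sample: event count, total
#' event length in kb, average event length in kb (undefined, `NA`, for
#' samples with no events), plus the has-event indicator used for the
#' proportion-of-samples feature. Samples present in the phenotype table but
#' absent from the cohort contribute zero counts.
#'
#' @param cohort Consolidated cohort CNV table (per-sample segments must not
#'   overlap).
#' @param phenotypes Phenotype table (defines the sample universe and order).
#' @param event_class One of `"DelDup"`, `"Del"`, `"Dup"`.
#' @return A `data.frame` with one row per phenotype sample: `sample_id`,
#'   `status`, `group`, `n_events`, `total_kb`, `avg_kb`, `has_event`.
#' @export
compute_burden_features <- function(cohort, phenotypes,
                                    event_class = "DelDup") {
  sub <- subset_event_class(cohort, event_class)
  sid <- factor(sub$sample_id, levels = phenotypes$sample_id)
  if (anyNA(sid)) {
    stop("cohort sample(s) absent from phenotype table: ",
         paste(unique(sub$sample_id[is.na(sid)]), collapse = ", "))
  }
  n_events <- as.integer(table(sid))
  lengths_kb <- (sub$end - sub$start) / 1000
  total_kb <- as.numeric(tapply(lengths_kb, sid, sum, default = 0))
  avg_kb <- ifelse(n_events > 0, total_kb / n_events, NA_real_)
  data.frame(sample_id = phenotypes$sample_id,
             status = phenotypes$status,
             group = phenotypes$group,
             n_events = n_events,
             total_kb = total_kb,
             avg_kb = avg_kb,
             has_event = n_events > 0,
             stringsAsFactors = FALSE)
}

#' One-sided permutation test for a case/control mean difference
#'
#' The observed statistic is `mean(values[cases]) - mean(values[controls])`
#' (`NA` values, e.g. undefined per-sample average lengths, are dropped
#' within each group). Case/control labels are permuted uniformly and the
#' p-value estimated as `(1 + #{permuted statistic >= observed}) /
#' (1 + n_permutations)`, which never returns 0. When the number of distinct
#' label assignments `choose(n, n_cases)` does not exceed `n_permutations`
#' (and `exhaustive` is `"auto"`), all assignments are enumerated instead and
#' the p-value is exact: `#{assignments with statistic >= observed} /
#' #assignments`. Permuted statistics that are undefined (a permuted group
#' with only `NA` values) count as not exceeding the observed value.
#'
#' @param values Numeric per-sample statistic (one per sample).
#' @param is_case Logical vector, `TRUE` for cases.
#' @param n_permutations Number of random permutations (default 500,000).
#' @param seed Optional integer seed for reproducibility.
#' @param alternative `"greater"` (cases exceed controls; default, the
#'   convention of the burden test this mirrors) or `"two.sided"`.
#' @param exhaustive `"auto"`, `TRUE` or `FALSE`.
#' @return List with `p_value`, `observed`, `n_permutations` (actual draws or
#'   enumerated assignments), `exhaustive`.
#' @export
permutation_test <- function(values, is_case, n_permutations = 500000L,
                             seed = NULL,
                             alternative = c("greater", "two.sided"),
                             exhaustive = "auto") {
  alternative <- match.arg(alternative)
  stopifnot(length(values) == length(is_case))
  n <- length(values)
  n_case <- sum(is_case)
  if (n_case == 0 || n_case == n) stop("need at least one case and one control")
  stat_fun <- function(case_idx) {
    x_case <- values[case_idx]
    x_ctrl <- values[-case_idx]
    m1 <- mean(x_case, na.rm = TRUE)
    m0 <- mean(x_ctrl, na.rm = TRUE)
    s <- m1 - m0
    if (alternative == "two.sided") abs(s) else s
  }
  observed <- stat_fun(which(is_case))
  if (is.nan(observed)) return(list(p_value = 1, observed = NA_real_,
                                    n_permutations = 0L, exhaustive = FALSE))
  n_assign <- choose(n, n_case)
  use_exhaustive <- isTRUE(exhaustive) ||
    (identical(exhaustive, "auto") && n_assign <= n_permutations)
  if (use_exhaustive) {
    combos <- utils::combn(n, n_case)
    stats <- apply(combos, 2, stat_fun)
    n_ge <- sum(stats >= observed - 1e-12, na.rm = TRUE)
    p <- n_ge / ncol(combos)
    return(list(p_value = p, observed = observed,
                n_permutations = ncol(combos), exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  n_ge <- 0L
  for (b in seq_len(n_permutations)) {
    s <- stat_fun(sample.int(n, n_case))
    if (!is.nan(s) && s >= observed - 1e-12) n_ge <- n_ge + 1L
  }
  list(p_value = (1 + n_ge) / (1 + n_permutations), observed = observed,
       n_permutations = as.integer(n_permutations), exhaustive = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests` at full precision; for the standard 96-cell burden grid
#' (2 CNV sets x 4 features x 3 event classes x 4 groups) with alpha 0.05 the
#' threshold rounds to 0.000521 at 3 significant figures.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests.
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0) stop("alpha must be positive")
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

# Internal: burden statistic vector for a feature from a feature table.
feature_values <- function(features, feature) {
  switch(feature,
         n_events = as.numeric(features$n_events),
         prop_samples = as.numeric(features$has_event),
         total_kb = features$total_kb,
         avg_kb = features$avg_kb,
         stop("unknown burden feature: ", feature))
}

#' Run the full case/control burden analysis grid
#'
#' Evaluates every combination of CNV set (all vs rare), burden feature
#' (event count, proportion of samples with at least one event, total length
#' in kb, average length in kb), event class (DelDup, Del, Dup) and sample
#' group (ALL plus each ancestry group present in the phenotypes) — 96 cells
#' when all four groups are present. Each cell reports the case mean, control
#' mean and one-sided permutation p-value; cells whose group has no samples
#' (or no cases/controls) are marked unavailable with `NA` p-values. The
#' significance flag applies the Bonferroni threshold over the number of
#' evaluated cells. With a fixed `seed` the grid is bit-reproducible; cells
#' are processed in a fixed deterministic order.
#'
#' @param all_cohort Consolidated cohort table of all CNVs.
#' @param rare_cohort Rare-CNV subset table.
#' @param phenotypes Phenotype table.
#' @param n_permutations Permutations per cell (default 500,000).
#' @param seed Integer seed.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param groups Groups to analyse (default ALL, AA, Hispanic, NHW).
#' @return A `data.frame` with one row per cell: `cnv_set`, `feature`,
#'   `event_class`, `group`, `n_case`, `n_control`, `mean_case`,
#'   `mean_control`, `p_value`, `significant`; attribute `bonferroni` holds
#'   the threshold.
#' @export
run_burden_grid <- function(all_cohort, rare_cohort, phenotypes,
                            n_permutations = 500000L, seed = 1L,
                            alpha = 0.05, groups = BURDEN_GROUPS) {
  sets <- list(all = all_cohort, rare = rare_cohort)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (set_name in names(sets)) {
    for (event_class in EVENT_CLASSES) {
      features <- compute_burden_features(sets[[set_name]], phenotypes,
                                          event_class)
      for (feature in BURDEN_FEATURES) {
        vals <- feature_values(features, feature)
        for (group in groups) {
          in_group <- if (group == "ALL") rep(TRUE, nrow(features)) else
            features$group == group
          g_vals <- vals[in_group]
          g_case <- features$status[in_group] == "case"
          available <- sum(in_group) > 0 && any(g_case) && any(!g_case)
          if (available) {
            test <- permutation_test(g_vals, g_case,
                                     n_permutations = n_permutations)
            mean_case <- mean(g_vals[g_case], na.rm = TRUE)
            mean_control <- mean(g_vals[!g_case], na.rm = TRUE)
            p <- test$p_value
          } else {
            mean_case <- mean_control <- p <- NA_real_
          }
          rows[[length(rows) + 1L]] <- data.frame(
            cnv_set = set_name, feature = feature, event_class = event_class,
            group = group, n_case = sum(g_case), n_control = sum(!g_case),
            mean_case = mean_case, mean_control = mean_control, p_value = p,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  grid <- do.call(rbind, rows)
  n_tests <- sum(!is.na(grid$p_value))
  thr <- bonferroni_threshold(alpha, max(n_tests, 1L))
  grid$significant <- !is.na(grid$p_value) & grid$p_value < thr
  attr(grid, "bonferroni") <- thr
  attr(grid, "n_tests") <- n_tests
  grid
}

#' Summarise a burden grid as a feature-by-group table
#'
#' Reshapes [run_burden_grid()] output into the conventional presentation:
#' one block per feature and group with case mean, control mean and p-value
#' per (set, event class) column.
#'
#' @param grid Output of [run_burden_grid()].
#' @return A `data.frame` in long format sorted by feature, group, class,
#'   set.
#' @export
summarize_burden_grid <- function(grid) {
  ord <- order(match(grid$feature, BURDEN_FEATURES),
               match(grid$group, BURDEN_GROUPS),
               match(grid$event_class, EVENT_CLASSES),
               match(grid$cnv_set, c("all", "rare")))
  out <- grid[ord, c("feature", "group", "event_class", "cnv_set",
                     "mean_case", "mean_control", "p_value", "significant")]
  rownames(out) <- NULL
  out
}
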