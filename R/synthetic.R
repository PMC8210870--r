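#' Default antibiotic administration policy for simulated cohorts
#'
#' One row per canonical class, giving the per-patient probability of
#' receiving a course in each era (`prob_pre`, `prob_covid`), the day window
#' in which the course may start, and the course-duration range (days).
#' The fluoroquinolone row emulates bacterial prophylaxis: near-universal, a
#' long course starting around day 0; the other classes emulate sporadic
#' escalation courses started later. Era skew is introduced by making
#' `prob_pre` and `prob_covid` differ.
#'
#' @param fq_covid_boost additive increase of the fluoroquinolone course
#'   probability in the covid era (default 0, capped at 1); a convenience for
#'   building era-skewed policies.
#' @return data.frame with columns `antibiotic_class`, `prob_pre`,
#'   `prob_covid`, `start_min`, `start_max`, `dur_min`, `dur_max`.
#' @export
default_antibiotic_policy <- function(fq_covid_boost = 0) {
  p <- data.frame(
    antibiotic_class = antibiotic_classes(),
    prob_pre   = c(0.85, 0.30, 0.20, 0.35, 0.30, 0.10, 0.20),
    prob_covid = c(0.85, 0.30, 0.20, 0.35, 0.30, 0.10, 0.20),
    start_min  = c(0, 4, 4, 4, 4, 6, 8),
    start_max  = c(2, 20, 20, 20, 20, 20, 20),
    dur_min    = c(10, 3, 3, 3, 3, 5, 3),
    dur_max    = c(20, 8, 7, 10, 8, 12, 8),
    stringsAsFactors = FALSE)
  p$prob_covid[1] <- min(1, p$prob_covid[1] + fq_covid_boost)
  p
}

#' Configuration for a synthetic two-era cohort
#'
#' Describes a longitudinal hospital cohort: patients assigned to one of two
#' eras, stool samples collected roughly twice weekly (alternating 3- and
#' 4-day gaps) from admission through `max_day`, genus-level counts drawn by
#' a logistic-normal-multinomial scheme, and daily antibiotic administration
#' records drawn from a per-class course policy. Era effects are planted
#' additively in clr space on the taxa in `effect_taxa`, so downstream
#' parameter recovery is exact in expectation.
#'
#' @param n_patients_pre,n_patients_covid patients per era (positive).
#' @param n_taxa number of genus-level taxa (default 123).
#' @param max_day last sampling day relative to day 0 = first chemotherapy
#'   day (default 28).
#' @param depth_mean mean sequencing depth, reads (default 20000).
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   distribution (default 8).
#' @param low_depth_frac fraction of samples drawn at a failed-depth 100-499
#'   reads to exercise the 500-read filter (default 0.02).
#' @param effect_taxa integer indices (into the abundance-ranked taxa) that
#'   carry a planted era effect.
#' @param effect_size_clr signed clr-unit effect per effect taxon (recycled).
#' @param patient_sd_clr sd of per-patient, per-taxon random intercepts in
#'   clr units (default 0.5).
#' @param day_slope_clr sd of per-taxon linear time trends, clr units per day
#'   (default 0.02).
#' @param noise_sd_clr sd of per-sample, per-taxon noise in clr units
#'   (default 1).
#' @param baseline_log_sd sd of the taxon baseline log-abundances (default
#'   2); baselines are sorted decreasing, so taxon 1 is the most abundant.
#' @param antibiotic_policy policy data.frame, see
#'   [default_antibiotic_policy()].
#' @param seed integer seed; the seed fully determines the simulated cohort.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients_pre = 25, n_patients_covid = 9,
                          n_taxa = 123, max_day = 28,
                          depth_mean = 20000, depth_dispersion = 8,
                          low_depth_frac = 0.02,
                          effect_taxa = integer(0), effect_size_clr = numeric(0),
                          patient_sd_clr = 0.5, day_slope_clr = 0.02,
                          noise_sd_clr = 1, baseline_log_sd = 2,
                          antibiotic_policy = default_antibiotic_policy(),
                          seed = 1) {
  stopifnot(n_patients_pre >= 1, n_patients_covid >= 1, n_taxa >= 2,
            max_day >= 1)
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (length(effect_taxa) > n_taxa)
    stop("more effect taxa than taxa")
  if (length(effect_taxa) > 0) {
    if (any(effect_taxa < 1 | effect_taxa > n_taxa))
      stop("effect_taxa indices out of range")
    effect_size_clr <- rep_len(effect_size_clr, length(effect_taxa))
  }
  structure(list(n_patients_pre = n_patients_pre,
                 n_patients_covid = n_patients_covid,
                 n_taxa = n_taxa, max_day = max_day,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 low_depth_frac = low_depth_frac,
                 effect_taxa = as.integer(effect_taxa),
                 effect_size_clr = effect_size_clr,
                 patient_sd_clr = patient_sd_clr,
                 day_slope_clr = day_slope_clr,
                 noise_sd_clr = noise_sd_clr,
                 baseline_log_sd = baseline_log_sd,
                 antibiotic_policy = antibiotic_policy,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a two-era longitudinal cohort with ground truth
#'
#' Per sample, the latent log-composition is
#' `baseline + era_effect + patient_intercept + slope * day + noise`; a
#' softmax maps it to composition and counts are drawn multinomially at a
#' negative-binomial depth. Antibiotic courses are drawn per patient and
#' class from the policy and recorded in long format. The same seed gives a
#' bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @return List with `table` (a [count_table]), `exposures` (long data.frame
#'   `patient_id, day, antibiotic_class`), and `truth` (list: `true_effect`
#'   named per-taxon clr effect, zero off the planted set; `patient_intercepts`
#'   matrix; `config`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  cf <- config
  p <- cf$n_taxa
  taxa <- sprintf("g__Taxon%03d", seq_len(p))
  baseline <- sort(stats::rnorm(p, 0, cf$baseline_log_sd), decreasing = TRUE)
  effect <- numeric(p)
  effect[cf$effect_taxa] <- cf$effect_size_clr
  slopes <- stats::rnorm(p, 0, cf$day_slope_clr)

  n_pat <- cf$n_patients_pre + cf$n_patients_covid
  patients <- sprintf("P%03d", seq_len(n_pat))
  eras <- rep(c("pre", "covid"), c(cf$n_patients_pre, cf$n_patients_covid))
  admission <- sample(-3:0, n_pat, replace = TRUE)
  intercepts <- matrix(stats::rnorm(n_pat * p, 0, cf$patient_sd_clr), n_pat, p,
                       dimnames = list(patients, taxa))

  # twice-weekly sampling: alternating 3/4-day gaps from a start offset
  sample_days <- function(adm) {
    d <- adm + sample(1:3, 1)
    gaps <- rep_len(if (stats::runif(1) < 0.5) c(3L, 4L) else c(4L, 3L), 40)
    days <- cumsum(c(d, gaps))
    days[days <= cf$max_day & days >= adm]
  }

  rows <- list(); meta <- list(); si <- 0L
  for (k in seq_len(n_pat)) {
    for (day in sample_days(admission[k])) {
      si <- si + 1L
      eta <- baseline + intercepts[k, ] + slopes * day +
        stats::rnorm(p, 0, cf$noise_sd_clr)
      if (eras[k] == "covid") eta <- eta + effect
      pr <- exp(eta - max(eta))
      pr <- pr / sum(pr)
      depth <- if (stats::runif(1) < cf$low_depth_frac)
        sample(100:499, 1)
      else max(1L, stats::rnbinom(1, mu = cf$depth_mean,
                                  size = cf$depth_dispersion))
      rows[[si]] <- drop(stats::rmultinom(1, depth, pr))
      meta[[si]] <- data.frame(sample_id = sprintf("S%04d", si),
                               patient_id = patients[k], era = eras[k],
                               admission_day = admission[k],
                               collection_day = day,
                               stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  metadata <- do.call(rbind, meta)
  rownames(counts) <- metadata$sample_id
  colnames(counts) <- taxa

  # antibiotic courses per patient and class
  pol <- cf$antibiotic_policy
  ex <- list(); ei <- 0L
  for (k in seq_len(n_pat)) {
    for (r in seq_len(nrow(pol))) {
      prob <- if (eras[k] == "covid") pol$prob_covid[r] else pol$prob_pre[r]
      if (stats::runif(1) >= prob) next
      start <- sample(pol$start_min[r]:pol$start_max[r], 1)
      dur <- sample(pol$dur_min[r]:pol$dur_max[r], 1)
      days <- seq(start, start + dur - 1)
      days <- days[days >= admission[k] & days <= cf$max_day]
      if (!length(days)) next
      ei <- ei + 1L
      ex[[ei]] <- data.frame(patient_id = patients[k], day = days,
                             antibiotic_class = pol$antibiotic_class[r],
                             stringsAsFactors = FALSE)
    }
  }
  exposures <- if (ei > 0) do.call(rbind, ex) else
    data.frame(patient_id = character(0), day = integer(0),
               antibiotic_class = character(0), stringsAsFactors = FALSE)
  rownames(exposures) <- NULL

  list(table = count_table(counts, metadata),
       exposures = exposures,
       truth = list(true_effect = stats::setNames(effect, taxa),
                    patient_intercepts = intercepts,
                    baseline = stats::setNames(baseline, taxa),
                    config = config))
}

#' Write a simulated cohort to the three input TSVs plus a truth JSON
#'
#' Produces `counts.tsv` (BIOM-style taxon-major), `metadata.tsv`,
#' `exposures.tsv`, and `truth.json` under `dir`.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             exposures = file.path(dir, "exposures.tsv"),
             truth = file.path(dir, "truth.json"))
  write_count_table(sim$table, paths["counts"], paths["metadata"])
  utils::write.table(sim$exposures, paths["exposures"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(true_effect = as.list(sim$truth$true_effect),
                seed = sim$truth$config$seed,
                effect_taxa = sim$truth$config$effect_taxa)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
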