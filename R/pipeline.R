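#' Configuration for the end-to-end era analysis pipeline
#'
#' Collects every tunable of the analysis with its standard default:
#' pseudocount 1, 500-read sample filter, 0.01% taxon filter, 50 taxa kept on
#' sPLS-DA component 1, decay factor 2, 999 permutations, volcano thresholds
#' |effect| > 2 and q < 0.05.
#'
#' @param counts,metadata,exposures input TSV paths (used when `simulation`
#'   is NULL).
#' @param simulation optional [cohort_config()]; when given, inputs are
#'   simulated instead of read from disk.
#' @param pseudocount clr pseudocount.
#' @param min_sample_reads,min_taxon_frac filter thresholds.
#' @param keep sPLS-DA component-1 keep count.
#' @param n_components sPLS-DA components to fit.
#' @param scale scale columns before sPLS-DA.
#' @param decay exposure decay factor.
#' @param n_perm permutation count for PERMANOVA / dispersion tests.
#' @param effect_threshold,q_threshold volcano thresholds.
#' @param seed master seed; every stochastic stage derives its own sub-seed
#'   from it.
#' @param out_dir optional output directory for the report and side tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL, exposures = NULL,
                            simulation = NULL,
                            pseudocount = 1, min_sample_reads = 500,
                            min_taxon_frac = 1e-4, keep = 50,
                            n_components = 2, scale = TRUE, decay = 2,
                            n_perm = 999, effect_threshold = 2,
                            q_threshold = 0.05, seed = 1, out_dir = NULL) {
  if (is.null(simulation) &&
      (is.null(counts) || is.null(metadata) || is.null(exposures)))
    stop("provide either the three input paths or a simulation config")
  structure(list(counts = counts, metadata = metadata, exposures = exposures,
                 simulation = simulation, pseudocount = pseudocount,
                 min_sample_reads = min_sample_reads,
                 min_taxon_frac = min_taxon_frac, keep = keep,
                 n_components = n_components, scale = scale, decay = decay,
                 n_perm = n_perm, effect_threshold = effect_threshold,
                 q_threshold = q_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic sub-seed per stage, derived from the master seed so stages
# can be rerun in isolation; kept below 2^31
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  (as.integer(master) * 1009L + h) %% .Machine$integer.max
}

#' Run the full era analysis pipeline
#'
#' Stages, in order: read (or simulate) inputs; filter low-depth samples and
#' rare taxa; clr transform; Aitchison-distance PCA and era PERMANOVA;
#' sPLS-DA (component-1 keep, default 50); leave-one-out selection stability
#' and AUROC (cross-validated and apparent); antibiotic-exposure encoding and
#' decayed scores; per-class era Welch t-tests; exposure PCA covariates;
#' per-taxon covariate-adjusted regressions on the 100%-stable set; BH
#' correction; volcano selection; leave-one-patient-out robustness; and the
#' week-binned dispersion test. A stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages (default TRUE).
#' @return A `pipeline_report` list with per-stage results, the config echo,
#'   and all seeds used. Re-running with the same config and inputs gives a
#'   bit-identical report.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say("stage %-22s %.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  input <- stage("input", {
    if (!is.null(cf$simulation)) {
      sim <- simulate_cohort(cf$simulation)
      list(table = sim$table, exposures = sim$exposures)
    } else {
      list(table = read_count_table(cf$counts, cf$metadata),
           exposures = utils::read.delim(cf$exposures,
                                         stringsAsFactors = FALSE))
    }
  })

  filtered <- stage("filter", filter_table(input$table, cf$min_sample_reads,
                                           cf$min_taxon_frac))
  clr <- stage("clr", clr_transform(filtered, cf$pseudocount))
  meta <- filtered$metadata

  d <- stage("aitchison", aitchison_distance(clr))
  ord <- stage("pca", pca(unclass(clr), n_components = min(3, ncol(clr))))
  perm <- stage("permanova",
                permanova(d, meta$era, n_perm = cf$n_perm,
                          seed = stage_seed(cf$seed, "permanova")))

  keep_eff <- min(cf$keep, ncol(clr))
  spl <- stage("splsda",
               fit_splsda(unclass(clr), meta$era,
                          n_components = cf$n_components,
                          keep = keep_eff, scale = cf$scale))
  stab <- stage("stability",
                loocv_stability(unclass(clr), meta$era, keep = keep_eff,
                                scale = cf$scale))
  auc_cv <- stage("auroc_cv", auroc(stab$cv_scores, meta$era))
  auc_apparent <- stage("auroc_apparent", auroc(spl$scores[, 1], meta$era))

  expo <- stage("exposure", exposure_matrix(meta, input$exposures,
                                            decay = cf$decay))
  ttests <- stage("exposure_ttests",
                  per_class_era_ttests(expo$scores, meta$era))

  candidates <- stab$stable
  if (length(candidates) == 0) {
    warning("no taxa at stability 1.0; falling back to the full component-1 ",
            "selection")
    candidates <- spl$selected[[1]]
  }
  reg <- stage("regression",
               fit_taxon_models(clr, candidates, meta$era,
                                meta$collection_day, expo$abx_pc1,
                                expo$abx_pc2))
  volcano <- stage("volcano",
                   volcano_select(reg, cf$effect_threshold, cf$q_threshold))
  lopo <- stage("leave_one_patient_out",
                leave_one_patient_out(clr, meta, candidates,
                                      expo$abx_pc1, expo$abx_pc2,
                                      cf$effect_threshold, cf$q_threshold))
  weeks <- week_bins(meta$collection_day)
  disp <- stage("week_dispersion", {
    if (length(unique(weeks[table(weeks)[as.character(weeks)] >= 2])) >= 2)
      dispersion_test(d, weeks, n_perm = cf$n_perm,
                      seed = stage_seed(cf$seed, "dispersion"))
    else NULL
  })

  report <- list(
    config = unclass(cf),
    n_samples = nrow(clr), n_taxa = ncol(clr),
    filter = list(samples_in = nrow(input$table$counts),
                  taxa_in = ncol(input$table$counts),
                  samples_kept = nrow(clr), taxa_kept = ncol(clr)),
    pca_var_explained = ord$var_explained,
    permanova = unclass(perm),
    splsda = list(keep = keep_eff,
                  top_loadings = top_loadings(spl, 1, keep_eff),
                  auroc_cv = auc_cv, auroc_apparent = auc_apparent),
    stability = list(frequency = stab$frequency, n_folds = stab$n_folds,
                     stable = stab$stable),
    exposure = list(decay = cf$decay, era_ttests = ttests,
                    pc_var_explained = if (!is.null(expo$pca))
                      expo$pca$var_explained else NULL),
    regression = reg,
    volcano = volcano,
    robustness = list(fraction = lopo$fraction, n_runs = lopo$n_runs,
                      robust_taxa = lopo$robust_taxa),
    final_taxa = list(
      covid = intersect(volcano$covid_taxa, lopo$robust_taxa),
      pre = intersect(volcano$pre_taxa, lopo$robust_taxa)),
    week_dispersion = if (!is.null(disp))
      list(f = disp$f, p = disp$p, n_permutations = disp$n_permutations)
    else NULL,
    seeds = list(master = cf$seed,
                 permanova = stage_seed(cf$seed, "permanova"),
                 dispersion = stage_seed(cf$seed, "dispersion")))
  class(report) <- "pipeline_report"
  if (!is.null(cf$out_dir)) write_report(report, cf$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %d samples x %d taxa after filtering\n",
              x$n_samples, x$n_taxa))
  cat(sprintf("  PERMANOVA (era): pseudo-F = %.2f, R2 = %.4f, p = %.4g\n",
              x$permanova$pseudo_f, x$permanova$r2, x$permanova$p))
  cat(sprintf("  sPLS-DA: keep %d, AUROC %.1f%% (cross-validated) / %.1f%% (apparent)\n",
              x$splsda$keep, 100 * x$splsda$auroc_cv,
              100 * x$splsda$auroc_apparent))
  cat(sprintf("  stability-1.0 taxa: %d of %d\n",
              length(x$stability$stable), x$splsda$keep))
  cat(sprintf("  final era-associated taxa: covid = {%s}, pre = {%s}\n",
              paste(x$final_taxa$covid, collapse = ", "),
              paste(x$final_taxa$pre, collapse = ", ")))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` plus TSV side tables (regression results, stability
#' frequencies, top loadings, robustness fractions) under `dir`.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the report path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$regression, file.path(dir, "regression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$splsda$top_loadings,
                     file.path(dir, "loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stab <- data.frame(feature = names(report$stability$frequency),
                     frequency = unname(report$stability$frequency))
  utils::write.table(stab, file.path(dir, "stability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rob <- data.frame(taxon = names(report$robustness$fraction),
                    fraction = unname(report$robustness$fraction))
  utils::write.table(rob, file.path(dir, "robustness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  volc <- report$regression
  volc$neg_log10_q <- -log10(pmax(volc$q, .Machine$double.xmin))
  utils::write.table(volc[, c("taxon", "beta_era", "neg_log10_q")],
                     file.path(dir, "volcano.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path <- file.path(dir, "report.json")
  slim <- report
  slim$regression <- NULL
  jsonlite::write_json(.jsonable(unclass(slim)), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.jsonable <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, .jsonable))
  if (is.matrix(x)) return(as.data.frame(x))
  x
}

#' Per-class era comparison of decayed exposure scores
#'
#' Welch two-sample t-test of each antibiotic class's decaying-average score
#' between the two eras. Classes with zero variance in both eras get t = 0,
#' p = 1 with a warning.
#'
#' @param scores samples x classes score matrix (from [exposure_matrix()]).
#' @param era era label per sample (both eras present).
#' @return data.frame with columns `antibiotic_class`, `t`, `p`,
#'   `mean_pre`, `mean_covid`.
#' @export
per_class_era_ttests <- function(scores, era) {
  era <- .era_factor(era)
  if (nlevels(era) < 2 || any(tabulate(era, 2) == 0))
    stop("both eras must be present")
  pre <- era == levels(era)[1]
  out <- lapply(colnames(scores), function(cl) {
    a <- scores[pre, cl]; b <- scores[!pre, cl]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      warning("zero variance in both eras for ", cl, "; p set to 1")
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(b, a)   # covid minus pre orientation
    }
    data.frame(antibiotic_class = cl, t = unname(tt$statistic),
               p = tt$p.value, mean_pre = mean(a), mean_covid = mean(b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
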