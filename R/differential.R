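#' Covariate-adjusted per-taxon era regressions
#'
#' Fits, for every candidate taxon, an ordinary least squares model of the
#' clr-transformed abundance on era (pre = 0, covid = 1), sample collection
#' day, and the first two antibiotic-history PCA axes. Two-sided p values for
#' the era coefficient come from the t distribution with n - 5 degrees of
#' freedom; Benjamini-Hochberg correction is applied across the candidate
#' taxa only. Samples, not patients, are the units of analysis.
#'
#' @param clr clr matrix (samples x taxa).
#' @param candidate_taxa character vector of taxon labels (subset of the clr
#'   columns); typically the 100%-stable sPLS-DA selection.
#' @param era character/factor era per sample (`"pre"`/`"covid"`).
#' @param collection_day integer day per sample.
#' @param abx_pc1,abx_pc2 antibiotic-history PCA covariates per sample.
#' @return data.frame (one row per candidate taxon) with columns `taxon`,
#'   `beta_era`, `se`, `p`, `q`, `beta_day`, `beta_abx_pc1`, `beta_abx_pc2`,
#'   `n_samples`.
#' @export
fit_taxon_models <- function(clr, candidate_taxa, era, collection_day,
                             abx_pc1, abx_pc2) {
  clr <- unclass(clr)
  missing_taxa <- setdiff(candidate_taxa, colnames(clr))
  if (length(missing_taxa))
    stop("candidate taxa not in clr matrix: ",
         paste(missing_taxa, collapse = ", "))
  n <- nrow(clr)
  if (n <= 6) stop("need more than 6 samples for a 5-parameter model")
  era01 <- as.integer(.era_factor(era)) - 1L
  if (length(unique(era01)) < 2) stop("all samples are from one era")
  X <- cbind(intercept = 1, era = era01, day = collection_day,
             abx_pc1 = abx_pc1, abx_pc2 = abx_pc2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design matrix")
  Y <- clr[, candidate_taxa, drop = FALSE]
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se_era <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- beta["era", ] / se_era
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  data.frame(taxon = candidate_taxa,
             beta_era = unname(beta["era", ]),
             se = unname(se_era),
             p = unname(pval),
             q = bh_adjust(unname(pval)),
             beta_day = unname(beta["day", ]),
             beta_abx_pc1 = unname(beta["abx_pc1", ]),
             beta_abx_pc2 = unname(beta["abx_pc2", ]),
             n_samples = n,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH step-up with monotonicity enforced:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @return q values in the input order; an empty input returns an empty
#'   vector.
#' @export
bh_adjust <- function(pvalues) {
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  ord <- order(pvalues, decreasing = TRUE)
  q <- pmin(1, cummin(pvalues[ord] * m / seq(m, 1)))
  q[order(ord)]
}

#' Volcano selection of strong, significant taxa
#'
#' A taxon is selected when `|beta_era| > effect_threshold` (strict) and
#' `q < q_threshold` (strict). Selected taxa are split by coefficient sign:
#' positive = covid-era associated, negative = pre-era associated.
#'
#' @param results data.frame from [fit_taxon_models()].
#' @param effect_threshold absolute effect-size threshold (default 2).
#' @param q_threshold adjusted-p threshold (default 0.05).
#' @return List with character vectors `covid_taxa` and `pre_taxa`.
#' @export
volcano_select <- function(results, effect_threshold = 2, q_threshold = 0.05) {
  hit <- abs(results$beta_era) > effect_threshold & results$q < q_threshold
  list(covid_taxa = results$taxon[hit & results$beta_era > 0],
       pre_taxa = results$taxon[hit & results$beta_era < 0])
}

#' Leave-one-patient-out robustness screen
#'
#' Re-runs the full per-taxon regression battery once per patient, each run
#' excluding all of that patient's samples. BH correction and the volcano
#' thresholds are re-applied within each run. A taxon's stability fraction is
#' the share of runs in which it passed both thresholds; the robust set is
#' the taxa passing in every run.
#'
#' @param clr clr matrix (samples x taxa).
#' @param metadata data.frame aligned to the clr rows with columns
#'   `patient_id`, `era`, `collection_day`.
#' @param candidate_taxa taxon labels to model.
#' @param abx_pc1,abx_pc2 antibiotic-history covariates per sample.
#' @param effect_threshold,q_threshold volcano thresholds (defaults 2, 0.05).
#' @return An object of class `robustness_report`: list with `fraction`
#'   (named per-taxon), `n_runs`, `robust_taxa` (fraction exactly 1), and
#'   `per_run` (logical matrix taxa x runs).
#' @export
leave_one_patient_out <- function(clr, metadata, candidate_taxa,
                                  abx_pc1, abx_pc2,
                                  effect_threshold = 2, q_threshold = 0.05) {
  patients <- unique(metadata$patient_id)
  if (length(patients) < 3) stop("need at least 3 patients")
  hits <- matrix(FALSE, length(candidate_taxa), length(patients),
                 dimnames = list(candidate_taxa, patients))
  for (k in seq_along(patients)) {
    keep <- metadata$patient_id != patients[k]
    if (length(unique(metadata$era[keep])) < 2)
      stop("dropping patient ", patients[k], " removes an entire era")
    res <- fit_taxon_models(clr[keep, , drop = FALSE], candidate_taxa,
                            metadata$era[keep],
                            metadata$collection_day[keep],
                            abx_pc1[keep], abx_pc2[keep])
    sel <- volcano_select(res, effect_threshold, q_threshold)
    hits[, k] <- candidate_taxa %in% c(sel$covid_taxa, sel$pre_taxa)
  }
  frac <- rowMeans(hits)
  structure(list(fraction = frac, n_runs = length(patients),
                 robust_taxa = candidate_taxa[frac == 1], per_run = hits),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report: %d leave-one-patient-out runs, %d taxa robust\n",
              x$n_runs, length(x$robust_taxa)))
  invisible(x)
}
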