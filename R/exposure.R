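#' Canonical antibacterial antibiotic classes
#'
#' The seven antibacterial classes tracked by the exposure-history encoding,
#' in the fixed column order used throughout the package.
#'
#' @return Character vector of the 7 canonical class names.
#' @export
antibiotic_classes <- function() {
  c("fluoroquinolones",
    "cephalosporins_3plus",
    "metronidazole",
    "piperacillin_tazobactam",
    "iv_vancomycin_daptomycin_linezolid",
    "oral_vancomycin",
    "carbapenems")
}

#' Encode daily antibiotic exposure series for one sample
#'
#' Builds, for each of the 7 canonical classes, a binary vector over the days
#' from hospital admission through the day before sample collection
#' (oldest-first). A day is 1 if the class was administered on that day,
#' regardless of dose. Day 0 is the first day of chemotherapy; negative days
#' are pre-chemotherapy admission days and are included in the window.
#' Records on days outside the window are ignored with a warning.
#'
#' @param admission_day,collection_day integer days,
#'   `admission_day <= collection_day`.
#' @param records data.frame with columns `day` and `antibiotic_class`
#'   (values must be canonical class names); rows are administration days.
#' @return Named list of 7 binary integer vectors, each of length
#'   `collection_day - admission_day`, names = [antibiotic_classes()]. Each
#'   vector carries a `days` attribute with the day indices it covers.
#' @export
encode_exposures <- function(admission_day, collection_day, records = NULL) {
  if (admission_day > collection_day)
    stop("admission_day must be <= collection_day")
  days <- seq(admission_day, collection_day - 1)
  len <- length(days)
  classes <- antibiotic_classes()
  out <- lapply(classes, function(cl) {
    v <- integer(len)
    attr(v, "days") <- days
    v
  })
  names(out) <- classes
  if (!is.null(records) && nrow(records) > 0) {
    bad <- setdiff(unique(records$antibiotic_class), classes)
    if (length(bad))
      stop("unknown antibiotic class(es): ", paste(bad, collapse = ", "))
    inside <- records$day %in% days
    if (any(!inside))
      warning(sprintf("%d record(s) outside the exposure window ignored",
                      sum(!inside)))
    records <- records[inside, , drop = FALSE]
    for (i in seq_len(nrow(records))) {
      cl <- records$antibiotic_class[i]
      j <- records$day[i] - admission_day + 1
      out[[cl]][j] <- 1L
    }
  }
  out
}

#' Decaying-average summary of a binary exposure series
#'
#' Collapses a daily 0/1 exposure series (oldest-first, ending the day before
#' sample collection) to a single score:
#' `sum_j s[last - j] * decay^(-j)` for `j = 0 .. length-1`. The most recent
#' completed day carries full weight and each earlier day is down-weighted by
#' one decay factor; with `decay = 2` a day weighs twice the day before it.
#' The sum is not normalized, so the score lies in
#' `[0, decay/(decay - 1))`.
#'
#' @param s binary numeric vector, oldest day first (as produced by
#'   [encode_exposures()]); an empty series scores 0.
#' @param decay decay factor, must be > 1 (defaults to 2; 1.5 is the standard
#'   sensitivity value).
#' @return The decayed exposure score.
#' @export
decaying_summary <- function(s, decay = 2) {
  if (decay <= 1) stop("decay factor must be > 1")
  len <- length(s)
  if (len == 0) return(0)
  sum(rev(s) * decay^(-(seq_len(len) - 1)))
}

#' Per-sample antibiotic exposure score matrix and PCA covariates
#'
#' Encodes each sample's exposure series from long-format administration
#' records, summarizes every class with the decaying average, and runs PCA on
#' the resulting samples x 7 score matrix. The first two PCA axes are the
#' antibiotic-history covariates used in the per-taxon regressions. If the
#' score matrix is constant (e.g. an antibiotic-naive cohort) the covariates
#' are set to 0 with a warning.
#'
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `admission_day`, `collection_day`.
#' @param records data.frame with columns `patient_id`, `day`,
#'   `antibiotic_class` (long format, one row per administration day).
#' @param decay decay factor passed to [decaying_summary()].
#' @return List with `scores` (samples x 7 matrix, canonical column order,
#'   rownames = sample ids), `abx_pc1`, `abx_pc2` (named numeric vectors),
#'   `pca` (the `pca_result`, or NULL when degenerate), `decay`.
#' @export
exposure_matrix <- function(samples, records, decay = 2) {
  classes <- antibiotic_classes()
  scores <- matrix(0, nrow(samples), length(classes),
                   dimnames = list(samples$sample_id, classes))
  for (i in seq_len(nrow(samples))) {
    rec <- records[records$patient_id == samples$patient_id[i], , drop = FALSE]
    # administrations on/after the collection day are expected in the record
    # stream (the patient's course continues); drop them without the
    # out-of-window warning encode_exposures raises for direct use
    rec <- rec[rec$day >= samples$admission_day[i] &
                 rec$day < samples$collection_day[i], , drop = FALSE]
    series <- encode_exposures(samples$admission_day[i],
                               samples$collection_day[i], rec)
    scores[i, ] <- vapply(series, decaying_summary, numeric(1), decay = decay)
  }
  if (all(apply(scores, 2, stats::sd) == 0)) {
    warning("exposure score matrix is constant; PCA covariates set to 0")
    z <- stats::setNames(rep(0, nrow(scores)), rownames(scores))
    return(list(scores = scores, abx_pc1 = z, abx_pc2 = z, pca = NULL,
                decay = decay))
  }
  pc <- pca(scores, n_components = 2)
  pc1 <- stats::setNames(pc$scores[, 1], rownames(scores))
  pc2 <- if (ncol(pc$scores) >= 2)
    stats::setNames(pc$scores[, 2], rownames(scores))
  else stats::setNames(rep(0, nrow(scores)), rownames(scores))
  list(scores = scores, abx_pc1 = pc1, abx_pc2 = pc2, pca = pc, decay = decay)
}
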