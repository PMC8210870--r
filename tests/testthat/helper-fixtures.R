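# shared fixture builders; everything is generated in code

# tiny count table with explicit values
toy_table <- function(counts = NULL, n_samples = 3, n_taxa = 4, seed = 1) {
  if (is.null(counts)) {
    set.seed(seed)
    counts <- matrix(rpois(n_samples * n_taxa, 600), n_samples, n_taxa)
  }
  n_samples <- nrow(counts); n_taxa <- ncol(counts)
  rownames(counts) <- sprintf("S%02d", seq_len(n_samples))
  colnames(counts) <- sprintf("g__T%02d", seq_len(n_taxa))
  meta <- data.frame(
    sample_id = rownames(counts),
    patient_id = sprintf("P%02d", rep_len(seq_len(max(2, n_samples %/% 2)),
                                          n_samples)),
    era = rep_len(c("pre", "covid"), n_samples),
    admission_day = -1L,
    collection_day = seq_len(n_samples) + 2L,
    stringsAsFactors = FALSE)
  count_table(counts, meta)
}

# small planted-signal design for sPLS-DA / regression tests:
# feature 1 carries the class difference, the rest are noise
planted_design <- function(n_per_class = 30, n_features = 10, delta = 3,
                           noise_sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c("pre", "covid"), each = n_per_class)
  X <- matrix(rnorm(n * n_features, 0, noise_sd), n,
              dimnames = list(sprintf("S%03d", 1:n),
                              sprintf("g__T%02d", 1:n_features)))
  X[y == "covid", 1] <- X[y == "covid", 1] + delta
  list(X = X, y = y)
}

# the recovery-benchmark generator configuration: ~30 patients, ~200+
# samples, 123 taxa, 4 planted |clr| = 3 effects on well-quantified taxa
# (depletions need an abundant baseline to be measurable above the
# pseudocount floor), era-skewed fluoroquinolone prophylaxis
recovery_config <- function(seed, null = FALSE) {
  cohort_config(
    n_patients_pre = 18, n_patients_covid = 12,
    n_taxa = 123,
    effect_taxa = if (null) integer(0) else c(5L, 8L, 30L, 45L),
    effect_size_clr = if (null) numeric(0) else c(-3, -3, 3, 3),
    antibiotic_policy = default_antibiotic_policy(fq_covid_boost = 0.15),
    seed = seed)
}

recovery_planted_taxa <- sprintf("g__Taxon%03d", c(5, 8, 30, 45))

# exhaustive label-permutation PERMANOVA oracle, computed from scratch via
# coordinates (valid for Euclidean distance matrices): classic one-way
# MANOVA sums of squares on the raw coordinates
permanova_coord_oracle <- function(coords, labels) {
  n <- nrow(coords)
  groups <- unique(labels)
  a <- length(groups)
  sstot <- sum(sweep(coords, 2, colMeans(coords))^2)
  ssw <- 0
  for (g in groups) {
    sub <- coords[labels == g, , drop = FALSE]
    ssw <- ssw + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  ssa <- sstot - ssw
  list(f = (ssa / (a - 1)) / (ssw / (n - a)), r2 = ssa / sstot)
}

all_label_orderings <- function(labels) {
  n <- length(labels)
  perm_idx <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_idx(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  lapply(perm_idx(seq_len(n)), function(ix) labels[ix])
}
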