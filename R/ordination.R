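#' Principal component analysis with a deterministic sign convention
#'
#' Columns are centered internally (never scaled); scores and loadings come
#' from the singular value decomposition of the centered matrix. Signs are
#' fixed so that the largest-magnitude loading of each component is positive,
#' making results reproducible across platforms.
#'
#' @param x numeric matrix, observations in rows (>= 2).
#' @param n_components number of components to return; truncated to the
#'   matrix rank with a warning if larger.
#' @return An object of class `pca_result`: list with `scores`
#'   (n x k), `loadings` (p x k), and `var_explained` (length-k fractions of
#'   total variance).
#' @export
pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  tol <- max(dim(x)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  if (n_components > rank) {
    warning(sprintf("n_components reduced from %d to rank %d",
                    n_components, rank))
    n_components <- max(rank, 1L)
  }
  k <- n_components
  d <- sv$d[seq_len(k)]
  load <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k, k)
  rownames(scores) <- rownames(x)
  rownames(load) <- colnames(x)
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(k))
  total_var <- sum(sv$d^2)
  ve <- if (total_var > 0) d^2 / total_var else rep(0, k)
  structure(list(scores = scores, loadings = load, var_explained = ve),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

# squared-distance matrix from a dist object or symmetric matrix
.sqdist <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m))) stop("distance matrix must be symmetric")
  m^2
}

#' One-way PERMANOVA (adonis-style permutation test)
#'
#' Partitions the total sum of squared inter-sample distances into among- and
#' within-group components (Anderson's method) and assesses the pseudo-F by
#' permuting sample labels while holding the distance matrix fixed. The p
#' value is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d a [stats::dist] or symmetric distance matrix.
#' @param labels group label per sample; at least 2 groups, each non-empty.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive if TRUE, enumerate every distinct labelling instead of
#'   sampling (small n only); `n_perm` is ignored.
#' @return An object of class `permanova_result`: list with `pseudo_f`, `r2`,
#'   `p`, `n_permutations`, `seed`, `ss_among`, `ss_within`, `ss_total`, `df`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1, exhaustive = FALSE) {
  d2 <- .sqdist(d)
  n <- nrow(d2)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must match distance matrix")
  groups <- unique(labels)
  a <- length(groups)
  if (a < 2) stop("need at least 2 groups")
  f_stat <- function(lab) {
    ss_within <- 0
    for (g in groups) {
      idx <- which(lab == g)
      ng <- length(idx)
      if (ng == 0) return(NA_real_)
      ss_within <- ss_within + sum(d2[idx, idx]) / (2 * ng)
    }
    ss_total <- sum(d2) / (2 * n)
    ss_among <- ss_total - ss_within
    (ss_among / (a - 1)) / (ss_within / (n - a))
  }
  ss_within <- 0
  for (g in groups) {
    idx <- which(labels == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_total <- sum(d2) / (2 * n)
  ss_among <- ss_total - ss_within
  f_obs <- (ss_among / (a - 1)) / (ss_within / (n - a))
  if (exhaustive) {
    perms <- .all_permutations(n)
    f_perm <- apply(perms, 1, function(ix) f_stat(labels[ix]))
    # the identity permutation is among the enumerated ones; p is the exact
    # proportion of labellings with F >= F_obs
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    f_perm <- replicate(n_perm, f_stat(sample(labels)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_f = f_obs, r2 = ss_among / ss_total, p = p,
                 n_permutations = n_used, seed = seed,
                 ss_among = ss_among, ss_within = ss_within,
                 ss_total = ss_total, df = c(among = a - 1, within = n - a)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$r2, x$p, x$n_permutations))
  invisible(x)
}

.all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ], n, after = pos - 1L)
  }
  out
}

.save_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Homogeneity of multivariate dispersion (betadisper-style)
#'
#' Embeds the distance matrix by principal-coordinates analysis, computes each
#' sample's distance to its group centroid in that space (axes with negative
#' eigenvalues contribute negatively to the squared distance, clamped at zero
#' if the total goes negative), then tests equality of mean centroid distance
#' across groups with a one-way ANOVA F whose null distribution is obtained by
#' permuting the group labels of the distance values.
#'
#' Uses the group centroid rather than the spatial median.
#'
#' @param d a [stats::dist] or symmetric distance matrix.
#' @param groups group label per sample; at least 2 groups of size >= 2
#'   (singleton groups are dropped with a warning).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return An object of class `dispersion_result`: list with `distances`
#'   (per retained sample), `groups`, `f`, `p`, `n_permutations`, `seed`.
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = 1) {
  d2 <- .sqdist(d)
  n <- nrow(d2)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must match distance matrix")
  tab <- table(groups)
  if (any(tab < 2)) {
    singles <- names(tab)[tab < 2]
    warning("dropping singleton group(s): ", paste(singles, collapse = ", "))
    keep <- !(groups %in% singles)
    d2 <- d2[keep, keep, drop = FALSE]
    groups <- groups[keep]
    n <- nrow(d2)
  }
  if (length(unique(groups)) < 2) stop("need at least 2 groups of size >= 2")

  # PCoA: double-center -d2/2, keep real and "imaginary" axes separately
  ct <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * ct %*% d2 %*% ct
  eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-10
  pos <- eg$values > tol
  neg <- eg$values < -tol
  ypos <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), sum(pos), sum(pos))
  yneg <- eg$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eg$values[neg]), sum(neg), sum(neg))

  zdist <- numeric(n)
  for (gp in unique(groups)) {
    idx <- which(groups == gp)
    cpos <- colMeans(ypos[idx, , drop = FALSE])
    dpos <- rowSums(sweep(ypos[idx, , drop = FALSE], 2, cpos)^2)
    dneg <- 0
    if (ncol(yneg) > 0) {
      cneg <- colMeans(yneg[idx, , drop = FALSE])
      dneg <- rowSums(sweep(yneg[idx, , drop = FALSE], 2, cneg)^2)
    }
    zdist[idx] <- sqrt(pmax(dpos - dneg, 0))
  }

  f_of <- function(lab) {
    gm <- tapply(zdist, lab, mean)
    ns <- tapply(zdist, lab, length)
    grand <- mean(zdist)
    ss_b <- sum(ns * (gm - grand)^2)
    ss_w <- sum((zdist - gm[lab])^2)
    k <- length(gm)
    (ss_b / (k - 1)) / (ss_w / (n - k))
  }
  f_obs <- f_of(groups)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  f_perm <- replicate(n_perm, f_of(sample(groups)))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  structure(list(distances = zdist, groups = groups, f = f_obs, p = p,
                 n_permutations = n_perm, seed = seed),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("dispersion test: F = %.3f, p = %.4g (%d permutations)\n",
              x$f, x$p, x$n_permutations))
  invisible(x)
}

#' Bin chemotherapy days into study weeks
#'
#' Week 1 covers hospitalization (including pre-chemotherapy admission days)
#' through day 7, week 2 days 8-14, week 3 days 15-21, and week 4 day 22 and
#' later.
#'
#' @param collection_days integer vector of days (day 0 = first day of
#'   chemotherapy; negative values are admission days before chemotherapy).
#' @return Integer vector of week labels in 1..4.
#' @export
week_bins <- function(collection_days) {
  w <- findInterval(collection_days, c(8, 15, 22)) + 1L
  pmin(pmax(w, 1L), 4L)
}
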