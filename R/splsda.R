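#' Sparse partial least squares discriminant analysis
#'
#' Fits an sPLS-DA model of clr abundances against a binary class label
#' (era). Classes are one-hot encoded; per component the full weight vector
#' is computed from the cross-covariance between the (deflated) predictor
#' matrix and the class indicators, the `keep` largest-magnitude entries are
#' retained by soft-thresholding the rest to zero, the sparse weight vector is
#' renormalized, and the weight/indicator-loading pair is iterated to
#' convergence before deflation. Ties in |weight| at the keep boundary are
#' broken lexicographically by feature label, so the fit is deterministic.
#'
#' The component-1 sign is fixed so that a positive loading means higher
#' abundance in the second class level (`"covid"` when `y` has levels
#' pre/covid).
#'
#' @param X numeric matrix, samples x features (clr abundances).
#' @param y binary class labels; a factor, or character coerced with `"pre"`
#'   before `"covid"` when both are present.
#' @param n_components number of components (default 2).
#' @param keep integer vector (recycled) of features to retain per component;
#'   default 50.
#' @param scale center and unit-variance scale the columns of `X` before
#'   fitting (default TRUE); constant columns get scale 1.
#' @param tol,max_iter convergence controls for the inner iteration.
#' @return An object of class `splsda_model`: list with `loadings` (features
#'   x components, exactly `keep[k]` nonzeros per column, unit norm),
#'   `scores` (samples x components), `selected` (list of feature labels per
#'   component), `keep`, `classes`, `y`, `center`, `scale_`, `scale`.
#' @export
fit_splsda <- function(X, y, n_components = 2, keep = 50, scale = TRUE,
                       tol = 1e-9, max_iter = 500) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- .era_factor(y)
  if (nlevels(y) != 2 || any(tabulate(y, 2) == 0))
    stop("need exactly 2 classes, both present")
  n <- nrow(X); p <- ncol(X)
  keep <- rep_len(as.integer(keep), n_components)
  if (any(keep > p)) stop("keep exceeds number of features")
  if (any(keep < 1)) stop("keep must be >= 1")

  ctr <- colMeans(X)
  scl <- if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  Xd <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Y <- stats::model.matrix(~ y - 1)          # n x 2 one-hot
  Yd <- sweep(Y, 2, colMeans(Y))

  loadings <- matrix(0, p, n_components,
                     dimnames = list(colnames(X),
                                     paste0("comp", seq_len(n_components))))
  scores <- matrix(0, n, n_components,
                   dimnames = list(rownames(X), colnames(loadings)))
  selected <- vector("list", n_components)

  for (h in seq_len(n_components)) {
    M <- crossprod(Xd, Yd)                   # p x 2 cross-covariance
    sv <- svd(M, nu = 1, nv = 1)
    a <- sv$v[, 1]
    u <- rep(0, p)
    for (it in seq_len(max_iter)) {
      u_old <- u
      w <- drop(M %*% a)
      u <- .sparsify(w, keep[h], colnames(X))
      a <- drop(crossprod(M, u))
      a <- a / sqrt(sum(a^2))
      if (sqrt(sum((u - u_old)^2)) < tol) break
    }
    t_h <- drop(Xd %*% u)
    # deflate X (and Y, regression mode)
    tt <- sum(t_h^2)
    if (tt > 0) {
      c_h <- drop(crossprod(Xd, t_h)) / tt
      Xd <- Xd - tcrossprod(t_h, c_h)
      d_h <- drop(crossprod(Yd, t_h)) / tt
      Yd <- Yd - tcrossprod(t_h, d_h)
    }
    loadings[, h] <- u
    scores[, h] <- t_h
    selected[[h]] <- colnames(X)[u != 0]
  }

  # orient component 1: positive loading <=> higher in second class level
  if (mean(scores[y == levels(y)[2], 1]) < mean(scores[y == levels(y)[1], 1])) {
    loadings[, 1] <- -loadings[, 1]
    scores[, 1] <- -scores[, 1]
  }
  structure(list(loadings = loadings, scores = scores, selected = selected,
                 keep = keep, classes = levels(y), y = y,
                 center = ctr, scale_ = scl, scale = scale),
            class = "splsda_model")
}

# order class levels pre < covid when those labels are used
.era_factor <- function(y) {
  if (is.factor(y)) return(droplevels(y))
  y <- as.character(y)
  lev <- sort(unique(y))
  if (setequal(lev, c("pre", "covid"))) lev <- c("pre", "covid")
  factor(y, levels = lev)
}

# keep the `keep` largest |w|, soft-threshold the rest to zero, unit-norm.
# Boundary ties broken lexicographically by feature label.
.sparsify <- function(w, keep, labels) {
  p <- length(w)
  if (keep >= p) {
    lambda <- 0
    kept <- seq_len(p)
  } else {
    ord <- order(-abs(w), labels)
    kept <- ord[seq_len(keep)]
    lambda <- abs(w)[ord[keep + 1]]
  }
  u <- rep(0, p)
  u[kept] <- sign(w[kept]) * pmax(abs(w[kept]) - lambda, 0)
  nrm <- sqrt(sum(u^2))
  if (nrm == 0) {
    # all kept weights tied with the threshold; fall back to hard selection
    u[kept] <- w[kept]
    nrm <- sqrt(sum(u^2))
    if (nrm == 0) return(u)
  }
  u / nrm
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("splsda_model: %d components, keep = %s, classes = %s/%s\n",
              ncol(x$loadings), paste(x$keep, collapse = ","),
              x$classes[1], x$classes[2]))
  invisible(x)
}

#' Predict component scores for new samples
#'
#' Applies the training centering/scaling and the fitted component-1 loading
#' vector. Only component 1 is used for class scoring.
#'
#' @param object an `splsda_model`.
#' @param newdata matrix or vector of features in training column order.
#' @param ... unused.
#' @return Numeric vector of component-1 scores.
#' @export
predict.splsda_model <- function(object, newdata, ...) {
  nd <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  nd <- sweep(sweep(nd, 2, object$center), 2, object$scale_, "/")
  drop(nd %*% object$loadings[, 1])
}

#' Top loadings of a fitted component
#'
#' Features ordered by decreasing |loading|; equal |loading| values are
#' ordered lexicographically by feature label. A positive loading on
#' component 1 indicates association with the second class level (covid era
#' under the standard coding).
#'
#' @param m an `splsda_model`.
#' @param component component index (default 1).
#' @param k number of features to return (default 50); if it exceeds the
#'   number of nonzero loadings, all nonzero loadings are returned with a
#'   warning.
#' @return data.frame with columns `feature`, `loading`, `direction` (the
#'   class the sign points to).
#' @export
top_loadings <- function(m, component = 1, k = 50) {
  if (component > ncol(m$loadings)) stop("component not fitted")
  v <- m$loadings[, component]
  nz <- which(v != 0)
  if (k > length(nz)) {
    warning(sprintf("k = %d exceeds %d nonzero loadings; returning all",
                    k, length(nz)))
    k <- length(nz)
  }
  ord <- nz[order(-abs(v[nz]), names(v)[nz])][seq_len(k)]
  data.frame(feature = names(v)[ord], loading = unname(v[ord]),
             direction = ifelse(v[ord] > 0, m$classes[2], m$classes[1]),
             stringsAsFactors = FALSE)
}

#' Leave-one-out selection stability and cross-validated scores
#'
#' For each sample, refits component 1 of the sPLS-DA model on the remaining
#' samples, records the selected feature set, and scores the left-out sample
#' with the fold's loading vector (sign-aligned across folds). Stability is
#' the fraction of folds in which a feature was selected; the paper-style
#' candidate set is the subset at stability exactly 1.
#'
#' @inheritParams fit_splsda
#' @param keep number of features kept on component 1 (default 50).
#' @return An object of class `stability_report`: list with `frequency`
#'   (named per-feature selection frequency), `n_folds`, `stable` (features
#'   at frequency 1), `cv_scores` (LOOCV-predicted component-1 score per
#'   sample), `y`.
#' @export
loocv_stability <- function(X, y, n_components = 1, keep = 50, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- .era_factor(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  counts <- integer(ncol(X)); names(counts) <- colnames(X)
  cv_scores <- rep(NA_real_, n)
  n_folds <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      warning(sprintf("fold %d skipped: training set lost a class", i))
      next
    }
    fit <- fit_splsda(X[-i, , drop = FALSE], ytr, n_components = 1,
                      keep = keep, scale = scale)
    sel <- fit$selected[[1]]
    counts[sel] <- counts[sel] + 1L
    cv_scores[i] <- predict(fit, X[i, ])
    n_folds <- n_folds + 1L
  }
  freq <- counts / n_folds
  structure(list(frequency = freq, n_folds = n_folds,
                 stable = names(freq)[freq == 1], cv_scores = cv_scores,
                 y = y),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: %d folds, %d features at stability 1.0\n",
              x$n_folds, length(x$stable)))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' AUROC is the probability that a randomly chosen positive-class score
#' exceeds a randomly chosen negative-class score, with ties counting 1/2.
#' The positive class is the second level of `y` (covid era under the
#' standard coding).
#'
#' @param scores numeric scores, higher = more positive-class.
#' @param y binary labels (both classes present).
#' @return The AUROC as a fraction in \[0, 1\].
#' @export
auroc <- function(scores, y) {
  y <- .era_factor(y)
  if (nlevels(y) != 2) stop("AUROC undefined: need both classes")
  pos <- scores[y == levels(y)[2]]
  neg <- scores[y == levels(y)[1]]
  if (length(pos) == 0 || length(neg) == 0)
    stop("AUROC undefined: need both classes")
  r <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}
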