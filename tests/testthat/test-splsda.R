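test_that("keep = all features reduces sPLS-DA to dense PLS-DA", {
  d <- planted_design(n_per_class = 20, n_features = 8, delta = 2, seed = 3)
  fit <- fit_splsda(d$X, d$y, n_components = 1, keep = 8)
  # dense PLS-DA component-1 weight: dominant left singular vector of the
  # scaled cross-covariance (independent closed form, no iteration)
  Xs <- scale(d$X)
  Y <- model.matrix(~ factor(d$y, c("pre", "covid")) - 1)
  Yc <- scale(Y, scale = FALSE)
  w <- svd(crossprod(Xs, Yc))$u[, 1]
  cosine <- abs(sum(w * fit$loadings[, 1]))
  expect_gt(cosine, 1 - 1e-8)
  expect_equal(sum(fit$loadings[, 1] != 0), 8)
})

test_that("a perfectly separating feature is selected at keep = 1", {
  d <- planted_design(n_per_class = 25, n_features = 12, delta = 8,
                      noise_sd = 0.5, seed = 5)
  fit <- fit_splsda(d$X, d$y, n_components = 1, keep = 1)
  # oracle: exhaustive single-feature check by between-class separation
  sep <- apply(scale(d$X), 2, function(col)
    abs(mean(col[d$y == "covid"]) - mean(col[d$y == "pre"])))
  expect_identical(fit$selected[[1]], names(which.max(sep)))
  expect_identical(fit$selected[[1]], "g__T01")
  # positive loading points at the covid class (feature higher in covid)
  expect_gt(fit$loadings["g__T01", 1], 0)
})

test_that("fit is invariant to sample duplication and column shifts", {
  d <- planted_design(n_per_class = 15, n_features = 6, seed = 7)
  fit1 <- fit_splsda(d$X, d$y, n_components = 2, keep = 4)
  fit2 <- fit_splsda(rbind(d$X, d$X), c(d$y, d$y), n_components = 2, keep = 4)
  expect_equal(fit1$loadings, fit2$loadings, tolerance = 1e-6)

  # adding a constant to a feature column cannot change component-1 scores
  shifted <- d$X
  shifted[, 3] <- shifted[, 3] + 100
  fit3 <- fit_splsda(shifted, d$y, n_components = 2, keep = 4)
  expect_equal(fit3$scores[, 1], fit1$scores[, 1], tolerance = 1e-8)

  expect_error(fit_splsda(d$X, rep("pre", nrow(d$X))), "2 classes")
  expect_error(fit_splsda(d$X, d$y, keep = 99), "keep")
})

test_that("top_loadings orders by |loading| with lexicographic ties", {
  d <- planted_design(n_per_class = 20, n_features = 10, seed = 9)
  fit <- fit_splsda(d$X, d$y, n_components = 1, keep = 6)
  tl <- top_loadings(fit, 1, 6)
  expect_equal(nrow(tl), 6)
  expect_true(all(diff(abs(tl$loading)) <= 1e-12))
  expect_setequal(tl$feature, fit$selected[[1]])
  expect_warning(top_loadings(fit, 1, 10), "nonzero")

  # duplicated feature -> exactly tied |loading|, ordered by label
  X2 <- cbind(d$X, `g__T00` = d$X[, 1])
  fit2 <- fit_splsda(X2, d$y, n_components = 1, keep = 11)
  tl2 <- top_loadings(fit2, 1, 11)
  pair <- tl2$feature[abs(abs(tl2$loading) - abs(tl2$loading[1])) < 1e-9]
  tie <- tl2[tl2$feature %in% c("g__T00", "g__T01"), "feature"]
  expect_identical(tie, sort(tie))
})

test_that("loocv stability flags planted features and reports folds", {
  d <- planted_design(n_per_class = 30, n_features = 10, delta = 4, seed = 11)
  st <- loocv_stability(d$X, d$y, keep = 3)
  expect_equal(st$n_folds, 60)
  expect_equal(unname(st$frequency["g__T01"]), 1)
  expect_true("g__T01" %in% st$stable)
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
  expect_lte(length(st$stable), 3)

  # pure noise: leave-one-out barely perturbs rankings, so individual noise
  # features can still reach frequency 1.0 within one dataset; the honest
  # null signature is that the *identity* of the stable set churns across
  # replicate datasets (a planted set would be identical every time)
  set.seed(13)
  stable_sets <- lapply(1:3, function(i) {
    X <- matrix(rnorm(40 * 12), 40,
                dimnames = list(NULL, sprintf("g__T%02d", 1:12)))
    y <- rep(c("pre", "covid"), 20)
    loocv_stability(X, y, keep = 3)$stable
  })
  expect_gt(length(unique(unlist(stable_sets))),
            max(lengths(stable_sets)))
})

test_that("planted cohorts reach stability 1.0 for all planted taxa", {
  # scaled-down version of the selection-stability property: clr effect 3,
  # 60+ samples per class, planted taxa stable in every replicate
  ok <- vapply(1:3, function(s) {
    cfg <- cohort_config(n_patients_pre = 9, n_patients_covid = 9,
                         n_taxa = 40, effect_taxa = c(4L, 10L),
                         effect_size_clr = c(3, -3), seed = 100 + s)
    sim <- simulate_cohort(cfg)
    clr <- clr_transform(filter_table(sim$table))
    st <- loocv_stability(unclass(clr), attr(clr, "metadata")$era, keep = 15)
    all(c("g__Taxon004", "g__Taxon010") %in% st$stable)
  }, logical(1))
  expect_true(all(ok))
})

test_that("auroc matches hand values and the all-pairs oracle", {
  expect_equal(auroc(c(1, 2, 3, 4), c("pre", "covid", "pre", "covid")), 0.75)
  expect_equal(auroc(c(-1, -2, 5, 6), rep(c("pre", "covid"), each = 2)), 1)
  expect_equal(auroc(rep(2, 6), rep(c("pre", "covid"), 3)), 0.5)
  expect_error(auroc(1:3, rep("covid", 3)), "both classes")

  pairs_oracle <- function(scores, y) {
    pos <- scores[y == "covid"]; neg <- scores[y == "pre"]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  set.seed(17)
  for (i in 1:5) {
    y <- sample(c("pre", "covid"), 15, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(15), 1))   # rounded -> ties occur
    expect_equal(auroc(s, y), pairs_oracle(s, y))
  }
})
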