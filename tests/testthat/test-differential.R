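# builds a clr-like response matrix plus covariates with known structure
make_reg_data <- function(n = 40, beta_era = 3, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  era <- rep(c("pre", "covid"), each = n / 2)
  day <- sample(1:28, n, replace = TRUE)
  pc1 <- rnorm(n); pc2 <- rnorm(n)
  y1 <- beta_era * (era == "covid") + rnorm(n, 0, noise_sd)
  y2 <- rnorm(n)
  clr <- cbind(g__A = y1, g__B = y2)
  rownames(clr) <- sprintf("S%02d", 1:n)
  list(clr = clr, era = era, day = day, pc1 = pc1, pc2 = pc2)
}

test_that("per-taxon OLS matches the normal-equations oracle", {
  d <- make_reg_data(n = 18, beta_era = 1.3, noise_sd = 0.8, seed = 2)
  res <- fit_taxon_models(d$clr, c("g__A", "g__B"), d$era, d$day, d$pc1, d$pc2)
  X <- cbind(1, as.integer(d$era == "covid"), d$day, d$pc1, d$pc2)
  for (i in 1:2) {
    y <- d$clr[, i]
    bhat <- solve(t(X) %*% X, t(X) %*% y)            # normal equations
    resid <- y - X %*% bhat
    s2 <- sum(resid^2) / (nrow(X) - 5)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    p <- 2 * pt(abs(bhat[2] / se), nrow(X) - 5, lower.tail = FALSE)
    expect_equal(res$beta_era[i], bhat[2], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(res$se[i], se, tolerance = 1e-8)
    expect_equal(res$p[i], p, tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_true(all(res$q >= res$p))
})

test_that("regression recovers a planted era effect and adjusts covariates", {
  d <- make_reg_data(n = 40, beta_era = 3, noise_sd = 0.1, seed = 3)
  res <- fit_taxon_models(d$clr, c("g__A", "g__B"), d$era, d$day, d$pc1, d$pc2)
  a <- res[res$taxon == "g__A", ]
  expect_equal(a$beta_era, 3, tolerance = 0.15)
  expect_lt(a$q, 1e-6)

  # effect entirely mediated by a covariate shrinks toward zero once adjusted
  set.seed(4)
  n <- 60
  era <- rep(c("pre", "covid"), each = n / 2)
  pc1 <- 1.5 * (era == "covid") + rnorm(n, 0, 0.3)   # era-correlated exposure
  y <- 2 * pc1 + rnorm(n, 0, 0.2)                    # taxon tracks exposure
  clr <- cbind(g__M = y); rownames(clr) <- sprintf("S%02d", 1:n)
  adj <- fit_taxon_models(clr, "g__M", era, rep(1:4, 15), pc1, rnorm(n))
  unadj <- fit_taxon_models(clr, "g__M", era, rep(1:4, 15),
                            rnorm(n), rnorm(n))
  expect_lt(abs(adj$beta_era), abs(unadj$beta_era))

  expect_error(fit_taxon_models(d$clr, "g__Z", d$era, d$day, d$pc1, d$pc2),
               "g__Z")
  expect_error(fit_taxon_models(d$clr[1:6, ], "g__A", d$era[1:6], d$day[1:6],
                                d$pc1[1:6], d$pc2[1:6]), "6 samples")
  expect_error(fit_taxon_models(d$clr, "g__A", rep("pre", 40), d$day,
                                d$pc1, d$pc2), "one era")
  expect_error(fit_taxon_models(d$clr, "g__A", d$era, rep(1, 40),
                                rep(1, 40), rep(1, 40)), "rank-deficient")
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  # exhaustive small grids against the reference step-up implementation
  set.seed(5)
  grid <- c(0, 0.001, 0.01, 0.04, 0.05, 0.2, 0.5, 0.9, 1)
  for (len in 1:6) for (rep in 1:20) {
    p <- sample(grid, len, replace = TRUE)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("volcano selection applies strict thresholds and sign split", {
  res <- data.frame(taxon = c("a", "b", "c", "d"),
                    beta_era = c(2.0, -2.5, 3.0, 2.4),
                    q = c(0.01, 0.01, 0.06, 0.04))
  sel <- volcano_select(res)
  expect_identical(sel$covid_taxa, "d")   # beta exactly 2 not selected
  expect_identical(sel$pre_taxa, "b")     # q = 0.06 not selected
})

test_that("leave-one-patient-out screens per-patient-driven effects", {
  set.seed(6)
  n_pat <- 8; per <- 6; n <- n_pat * per
  meta <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     patient_id = rep(sprintf("P%d", 1:n_pat), each = per),
                     era = rep(c("pre", "covid"), each = n / 2),
                     collection_day = rep(seq(3, 3 + (per - 1) * 3, by = 3),
                                          n_pat))
  pc1 <- rnorm(n); pc2 <- rnorm(n)
  covid <- meta$era == "covid"

  # homogeneous effect: every covid patient shifted -> fraction 1.0
  homog <- 3 * covid + rnorm(n, 0, 0.2)
  # effect carried by patient P5's samples only
  single <- ifelse(meta$patient_id == "P5", 6, 0) + rnorm(n, 0, 0.2)
  clr <- cbind(g__H = homog, g__S = single)
  rownames(clr) <- meta$sample_id

  rob <- leave_one_patient_out(clr, meta, c("g__H", "g__S"), pc1, pc2)
  expect_equal(rob$n_runs, n_pat)
  expect_equal(unname(rob$fraction["g__H"]), 1)
  expect_identical(rob$robust_taxa, "g__H")
  # the single-patient taxon fails at least the run dropping P5
  expect_false(rob$per_run["g__S", "P5"])
  expect_lte(rob$fraction["g__S"], (n_pat - 1) / n_pat)

  # dropping a patient that removes an entire era is an input error
  meta2 <- meta; meta2$patient_id[meta2$era == "covid"] <- "P9"
  meta2$patient_id[1:12] <- c(rep("P1", 6), rep("P2", 6))
  expect_error(leave_one_patient_out(clr, meta2, "g__H", pc1, pc2), "P9")
})
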