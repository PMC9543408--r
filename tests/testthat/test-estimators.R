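test_that("ANCOVA solves the normal equations of the 6-subject fixture", {
  y6 <- c(18, 22, 20, 15, 17, 14)
  bl <- c(28, 33, 30, 29, 32, 27)
  arm <- rep(c("placebo", "active"), each = 3)
  y <- cbind(matrix(c(25, 24, 23, 22, 21, 20), 6, 5), y6)
  ds <- hand_dataset(y, arm, bl)
  est <- ancova_fit(ds)
  # independent closed-form OLS on the 3x3 normal equations
  X <- cbind(1, as.numeric(arm == "active"), bl)
  bhat <- solve(crossprod(X), crossprod(X, y6))
  resid <- y6 - X %*% bhat
  s2 <- sum(resid^2) / (6 - 3)
  se <- sqrt(s2 * solve(crossprod(X))[2, 2])
  expect_equal(est$estimate, unname(bhat[2, 1]), tolerance = 1e-10)
  expect_equal(est$se, unname(se), tolerance = 1e-10)
})

test_that("ANCOVA degenerate and invariance properties hold", {
  bl <- c(30, 31, 29, 28, 33, 27, 32, 26)
  arm <- rep(c("placebo", "active"), 4)
  y <- cbind(matrix(20, 8, 5), bl)     # last visit == baseline exactly
  ds <- hand_dataset(y, arm, bl)
  est <- suppressWarnings(ancova_fit(ds))   # zero-residual fit warns
  expect_equal(est$estimate, 0, tolerance = 1e-10)
  expect_equal(est$se, 0, tolerance = 1e-8)

  # adding a constant to every last-visit outcome leaves delta unchanged
  y2 <- y; y2[, 6] <- y2[, 6] + 7
  est2 <- suppressWarnings(ancova_fit(hand_dataset(y2, arm, bl)))
  expect_equal(est2$estimate, est$estimate, tolerance = 1e-10)

  expect_error(ancova_fit(hand_dataset(y[1:4, ], arm[1:4], bl[1:4])),
               "at least 3 subjects")
})

test_that("complete-case ANCOVA keeps intermediate-visit gaps and drops
          missing endpoints", {
  y <- matrix(rep(c(24, 23, 22, 21, 20, 19), each = 10), 10, 6)
  y[1, 3] <- NA                 # intermediate gap: still a complete case
  y[2, 6] <- NA                 # missing endpoint: excluded
  ds <- hand_dataset(y, rep(c("placebo", "active"), 5),
                     baseline = rep(30, 10))
  est <- suppressWarnings(ancova_complete_cases(ds))
  expect_equal(est$n_used, 9L)

  cds <- simulate_trial(complete_config(12), 3)$dataset
  expect_effect_close(ancova_complete_cases(cds), ancova_fit(cds))
})

test_that("LOCF estimators reduce to their plain counterparts on complete
          data and shift as hand-computed for a single dropout", {
  cds <- simulate_trial(complete_config(15), 5)$dataset
  expect_equal(ancova_locf(cds)$estimate, ancova_fit(cds)$estimate)
  expect_equal(mmrm_locf(cds)$estimate, mmrm_plain(cds)$estimate,
               tolerance = 1e-8)

  # single dropout carrying an extreme early value: closed-form OLS delta
  bl <- c(30, 31, 29, 28, 33, 27, 32, 26)
  arm <- rep(c("placebo", "active"), 4)
  y <- matrix(rep(c(26, 25, 24, 23, 22, 21), each = 8), 8, 6) +
    0.1 * seq_len(8)
  ds0 <- hand_dataset(y, arm, bl)
  y1 <- y
  y1[2, 2:6] <- NA            # active subject discontinues after visit 1
  ds1 <- hand_dataset(y1, arm, bl, disc_reason = c("none", "LoE",
                                                   rep("none", 6)),
                      disc_visit = c(NA, 1L, rep(NA, 6)))
  locf_est <- ancova_locf(ds1)$estimate
  ylocf <- y
  ylocf[2, 2:6] <- y[2, 1]    # the carried value
  X <- cbind(1, as.numeric(arm == "active"), bl)
  bhat <- solve(crossprod(X), crossprod(X, ylocf[, 6]))
  expect_equal(locf_est, unname(bhat[2, 1]), tolerance = 1e-10)
})

test_that("MI-based ANCOVA collapses to single-fit ANCOVA without missing
          data and is seed-deterministic", {
  cds <- simulate_trial(complete_config(12), 4)$dataset
  mi <- ancova_mi(cds, m = 5, seed = 1)
  expect_equal(mi$estimate, ancova_fit(cds)$estimate)
  expect_equal(mi$diagnostics$B, 0)

  ds <- simulate_trial(sim_config(n_per_arm = 30), 9)$dataset
  a <- ancova_mi(ds, m = 4, seed = 42)
  b <- ancova_mi(ds, m = 4, seed = 42)
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$se, b$se)
  c_ <- ancova_mi(ds, m = 4, seed = 43)
  expect_false(isTRUE(all.equal(a$estimate, c_$estimate)))
})

test_that("J2R pipeline equals plain MMRM when no cells are imputable", {
  cds <- simulate_trial(complete_config(15), 6)$dataset
  j <- mmrm_j2r(cds, m = 3, seed = 2)
  p <- mmrm_plain(cds)
  expect_equal(j$estimate, p$estimate)
  expect_equal(j$se, p$se)
  expect_equal(j$diagnostics$B, 0)
})

test_that("single-pattern PMMM is exactly plain MMRM", {
  cds <- simulate_trial(complete_config(15), 8)$dataset
  pm <- pmmm(cds)
  pl <- mmrm_plain(cds)
  expect_equal(pm$estimate, pl$estimate, tolerance = 1e-8)
  expect_equal(pm$se, pl$se, tolerance = 1e-8)
  expect_equal(unname(unlist(pm$diagnostics$pattern_weights)), 1)
})

test_that("PMMM weights are sample pattern frequencies and sum to one", {
  ds <- simulate_trial(sim_config(n_per_arm = 80), 15)$dataset
  pm <- suppressWarnings(pmmm(ds))
  w <- unlist(pm$diagnostics$pattern_weights)
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))
  expect_true(is.finite(pm$estimate) && pm$se > 0)
})

test_that("sparse patterns are merged towards the completer pattern", {
  pats <- c(rep("COMPLETER_QUASI", 10), rep("LATE_DROPOUT", 6),
            "EARLY_DROPOUT")   # a single early dropout: inestimable
  arm <- factor(rep(c("placebo", "active"), length.out = 17))
  mg <- estimandr:::merge_sparse_patterns(pats, arm)
  expect_false("EARLY_DROPOUT" %in% mg$patterns)
  expect_match(mg$merges[1], "EARLY_DROPOUT")
})

test_that("principal stratum with cutoff 1 reduces to plain MMRM and a
          perfectly predictive covariate recovers the never-event set", {
  ds <- simulate_trial(sim_config(n_per_arm = 40), 33)$dataset
  ps1 <- suppressWarnings(principal_stratum(ds, ps_config(cutoff = 1)))
  pl <- suppressWarnings(mmrm_plain(ds))
  expect_equal(ps1$estimate, pl$estimate, tolerance = 1e-8)

  # baseline separates events from non-events perfectly
  n <- 40
  bl <- seq(20, 39.5, by = 0.5)
  ie <- bl > stats::median(bl)          # top half discontinues
  arm <- rep(c("placebo", "active"), n / 2)
  y <- matrix(25, n, 6) + stats::rnorm(n * 6, 0, 1)
  y <- pmin(pmax(y, 0), 60)
  dv <- ifelse(ie, 4L, NA_integer_)
  for (i in which(ie)) y[i, 5:6] <- NA
  ds2 <- hand_dataset(y, arm, bl,
                      disc_reason = ifelse(ie, "LoE", "none"),
                      disc_visit = dv)
  est <- suppressWarnings(principal_stratum(ds2))
  expect_equal(est$diagnostics$stratum_size, sum(!ie))
  expect_equal(est$n_used, sum(!ie))
})

test_that("no observed events makes the stratum the whole population", {
  cds <- simulate_trial(complete_config(12), 10)$dataset
  expect_warning(ps <- principal_stratum(cds), "no intercurrent events")
  expect_equal(ps$estimate, mmrm_plain(cds)$estimate, tolerance = 1e-8)
})

test_that("every estimator carries its estimand labels", {
  expect_setequal(estimandr:::methods_to_estimands("MMRM"), c("E1", "E3"))
  expect_setequal(estimandr:::methods_to_estimands("MMRM_J2R"),
                  c("E3", "E4"))
  expect_setequal(estimandr:::methods_to_estimands("PMMM"), c("E3", "E5"))
  expect_equal(estimandr:::methods_to_estimands("PRINCIPAL_STRATUM"), "E6")
  ds <- simulate_trial(sim_config(n_per_arm = 30), 2)$dataset
  est <- suppressWarnings(mmrm_plain(ds))
  expect_setequal(est$estimand_labels, c("E1", "E3"))
})
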