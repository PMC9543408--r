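test_that("design matrix has the expected columns and rows", {
  ds <- simulate_trial(sim_config(n_per_arm = 30), 6)$dataset
  bd <- build_design(ds, mmrm_spec())
  # intercept + treatment + 5 visits + 5 interactions + baseline
  expect_equal(ncol(bd$X), 13)
  expect_equal(length(bd$y), sum(!is.na(ds$outcomes)))

  pats <- estimandr:::dataset_patterns(ds)
  expect_setequal(unique(pats),
                  c("COMPLETER_QUASI", "LATE_DROPOUT", "EARLY_DROPOUT"))
  bdp <- build_design(ds, mmrm_spec(include_pattern_terms = TRUE))
  # + 2 pattern main effects + 2 pattern-by-treatment interactions
  expect_equal(ncol(bdp$X), 17)

  # a subject observed at visits {1, 3} contributes exactly two rows
  y <- matrix(22, 8, 6)
  y[1, c(2, 4, 5, 6)] <- NA
  ds2 <- hand_dataset(y, rep(c("placebo", "active"), 4), rep(30, 8))
  bd2 <- build_design(ds2)
  expect_equal(sum(bd2$subject == 1), 2L)
  expect_equal(bd2$visit[bd2$subject == 1], c(1L, 3L))
})

test_that("analytic REML gradient matches numerical differentiation", {
  ds <- simulate_trial(sim_config(n_per_arm = 15,
                                  schedule = visit_schedule(4)),
                       12)$dataset
  keep <- rowSums(!is.na(ds$outcomes)) > 0
  ds <- estimandr:::subset_trial(ds, keep)
  info <- estimandr:::design_info(ds, mmrm_spec())
  prep <- estimandr:::engine_prepare(ds$outcomes, info)
  v0 <- apply(ds$outcomes, 2, var, na.rm = TRUE)
  theta <- estimandr:::chol_to_theta(estimandr:::chol_psd(diag(v0)))
  g <- attr(estimandr:::engine_eval(theta, prep, want_grad = TRUE), "grad")
  h <- 1e-6
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    num <- (as.numeric(estimandr:::engine_eval(tp, prep)) -
              as.numeric(estimandr:::engine_eval(tm, prep))) / (2 * h)
    expect_equal(g[k], num, tolerance = 1e-4)
  }
})

test_that("REML fit matches the direct-likelihood oracle on a small
          unbalanced dataset", {
  cfg <- sim_config(n_per_arm = 8, schedule = visit_schedule(3))
  ds <- simulate_trial(cfg, 101)$dataset
  nv <- naive_reml(ds)
  fit <- suppressWarnings(reml_fit(ds, reltol = 1e-12))
  expect_equal(fit$reml_loglik, nv$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(nv$beta), tolerance = 1e-4)
})

test_that("with complete balanced data the saturated fit reproduces
          per-cell sample means", {
  cfg <- complete_config(20, baseline_coef = 0)
  ds <- simulate_trial(cfg, 17)$dataset
  fit <- reml_fit(ds, mmrm_spec(include_baseline = FALSE))
  b <- fit$beta
  for (v in 1:6) {
    mu_p <- b[["(Intercept)"]] + (if (v > 1) b[[paste0("visit", v)]] else 0)
    mu_a <- mu_p + b[["armactive"]] +
      (if (v > 1) b[[paste0("armactive:visit", v)]] else 0)
    cell_p <- mean(ds$outcomes[ds$subjects$arm == "placebo", v])
    cell_a <- mean(ds$outcomes[ds$subjects$arm == "active", v])
    expect_equal(mu_p, cell_p, tolerance = 1e-6)
    expect_equal(mu_a, cell_a, tolerance = 1e-6)
  }
})

test_that("duplicating every subject doubles the information: identical
          GLS beta and halved covariance at a fixed covariance matrix", {
  ds <- simulate_trial(sim_config(n_per_arm = 15), 23)$dataset
  keep <- rowSums(!is.na(ds$outcomes)) > 0
  ds <- estimandr:::subset_trial(ds, keep)
  n <- nrow(ds$subjects)
  s2 <- rbind(ds$subjects, ds$subjects)
  s2$subject_id <- sprintf("D%04d", seq_len(2 * n))
  ds2 <- trial_dataset(s2, rbind(ds$outcomes, ds$outcomes), ds$schedule,
                       "placebo", validate = FALSE)
  # exact property: at any fixed covariance, duplication leaves the GLS
  # coefficients unchanged and exactly halves their covariance
  spec <- mmrm_spec()
  i1 <- estimandr:::design_info(ds, spec)
  i2 <- estimandr:::design_info(ds2, spec)
  p1 <- estimandr:::engine_prepare(ds$outcomes, i1)
  p2 <- estimandr:::engine_prepare(ds2$outcomes, i2)
  v0 <- apply(ds$outcomes, 2, var, na.rm = TRUE)
  th <- estimandr:::chol_to_theta(estimandr:::chol_psd(diag(v0)))
  e1 <- estimandr:::engine_eval(th, p1)
  e2 <- estimandr:::engine_eval(th, p2)
  expect_equal(attr(e2, "beta"), attr(e1, "beta"), tolerance = 1e-10)
  cov1 <- chol2inv(attr(e1, "A_chol"))
  cov2 <- chol2inv(attr(e2, "A_chol"))
  expect_equal(cov2, cov1 / 2, tolerance = 1e-10)
  # full REML refit: the restricted-likelihood penalty does not scale
  # with n, so the estimates agree only up to O(1/n)
  f1 <- reml_fit(ds, reltol = 1e-12)
  f2 <- reml_fit(ds2, reltol = 1e-12)
  expect_equal(unname(f2$beta), unname(f1$beta), tolerance = 0.02)
  expect_equal(unname(diag(f2$beta_cov)), unname(diag(f1$beta_cov)) / 2,
               tolerance = 0.1)
})

test_that("fits are invariant to subject ordering", {
  ds <- simulate_trial(sim_config(n_per_arm = 12), 31)$dataset
  keep <- rowSums(!is.na(ds$outcomes)) > 0
  ds <- estimandr:::subset_trial(ds, keep)
  perm <- rev(seq_len(nrow(ds$subjects)))
  dsp <- trial_dataset(ds$subjects[perm, ], ds$outcomes[perm, ],
                       ds$schedule, "placebo", validate = FALSE)
  f1 <- reml_fit(ds, reltol = 1e-12)
  f2 <- reml_fit(dsp, reltol = 1e-12)
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-8)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("treatment-effect contrasts combine coefficients as
          delta_F = beta_arm + beta_arm:visitF", {
  nm <- c("(Intercept)", "armactive", paste0("visit", 2:6),
          paste0("armactive:visit", 2:6), "baseline")
  beta <- setNames(numeric(13), nm)
  beta["armactive"] <- 2
  beta["armactive:visit6"] <- -3
  fake <- structure(list(beta = beta, beta_cov = diag(13), V = 6L,
                         arms = "active",
                         spec = mmrm_spec(), patterns = character()),
                    class = "mmrm_fit")
  d6 <- treatment_effect_at_visit(fake, 6)
  expect_equal(d6$estimate, -1)           # 2 + (-3)
  expect_equal(d6$se, sqrt(2))            # identity covariance, two 1s
  d1 <- treatment_effect_at_visit(fake, 1)
  expect_equal(d1$estimate, 2)            # beta_arm alone at visit 1
  expect_equal(d1$se, 1)
  expect_true(d6$ci_low <= d6$estimate && d6$estimate <= d6$ci_high)
  expect_error(treatment_effect_at_visit(fake, 7), "unknown visit")
})

test_that("pattern-specific contrasts add the pattern interaction and
          weighted averages follow", {
  nm <- c("(Intercept)", "armactive", paste0("visit", 2:6),
          paste0("armactive:visit", 2:6), "baseline",
          "patternLATE_DROPOUT", "patternEARLY_DROPOUT",
          "armactive:patternLATE_DROPOUT", "armactive:patternEARLY_DROPOUT")
  beta <- setNames(numeric(17), nm)
  beta["armactive"] <- -1
  beta["armactive:visit6"] <- -3          # completer delta = -4
  beta["armactive:patternLATE_DROPOUT"] <- 2    # late delta = -2
  beta["armactive:patternEARLY_DROPOUT"] <- 3   # early delta = -1
  fake <- structure(list(beta = beta, beta_cov = diag(17), V = 6L,
                         arms = "active", spec = mmrm_spec(TRUE),
                         patterns = c("LATE_DROPOUT", "EARLY_DROPOUT")),
                    class = "mmrm_fit")
  ds <- vapply(list(NULL, "LATE_DROPOUT", "EARLY_DROPOUT"), function(p)
    treatment_effect_at_visit(fake, 6, pattern = p)$estimate, 0)
  expect_equal(ds, c(-4, -2, -1))
  w <- c(0.6, 0.25, 0.15)
  expect_equal(sum(w * ds), -3.05)
  # identity contrast covariance, weights (0.5, 0.5, 0)
  expect_equal(sqrt(drop(c(0.5, 0.5, 0) %*% diag(3) %*% c(0.5, 0.5, 0))),
               sqrt(0.5))
})

test_that("REML agrees with an established GLS implementation on complete
          data", {
  cfg <- complete_config(25)
  ds <- simulate_trial(cfg, 7)$dataset
  bd <- build_design(ds)
  df <- data.frame(y = bd$y, visit = factor(bd$visit),
                   subject = bd$subject,
                   arm = ds$subjects$arm[bd$subject],
                   baseline = ds$subjects$baseline[bd$subject])
  g <- nlme::gls(y ~ arm * visit + baseline, data = df,
                 correlation = nlme::corSymm(form = ~as.integer(visit) |
                                               subject),
                 weights = nlme::varIdent(form = ~1 | visit),
                 method = "REML")
  cg <- coef(g)
  fit <- reml_fit(ds)
  ct <- treatment_effect_at_visit(fit, 6)
  expect_equal(ct$estimate, cg[["armactive"]] + cg[["armactive:visit6"]],
               tolerance = 1e-5)
  expect_equal(unname(fit$beta["baseline"]), cg[["baseline"]],
               tolerance = 1e-5)
})
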