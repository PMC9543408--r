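# The eight analysis methods, each returning a uniform effect_estimate
# (treatment-minus-reference contrast at the last scheduled visit, points
# MADRS10; negative favours the experimental arm).

method_order <- c("ANCOVA_CC", "ANCOVA_LOCF", "ANCOVA_MI", "MMRM",
                  "MMRM_LOCF", "MMRM_J2R", "PMMM", "PRINCIPAL_STRATUM")

new_effect_estimate <- function(method, estimate, se, ci_low, ci_high,
                                visit, n_used, diagnostics = list()) {
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = ci_low, ci_high = ci_high, visit = visit,
                 estimand_labels = methods_to_estimands(method),
                 n_used = n_used, diagnostics = diagnostics),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: %.3f (SE %.3f, 95%% CI %.3f to %.3f), n = %d [%s]\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$n_used,
              paste(x$estimand_labels, collapse = ", ")))
  invisible(x)
}

#' ANCOVA of the last-visit outcome on treatment and baseline
#'
#' Ordinary least squares of the end-of-trial score on the treatment
#' indicator and the baseline score; the treatment coefficient is the
#' adjusted difference in means at end of trial, with a 95%
#' normal-approximation CI.
#'
#' @param dataset A `trial_dataset`.
#' @param subjects Optional logical/integer subset of subjects.
#' @param arm Non-reference arm to contrast (default: the first).
#' @param method_label Method tag carried on the result.
#' @return An `effect_estimate`.
#' @export
ancova_fit <- function(dataset, subjects = NULL, arm = NULL,
                       method_label = "ANCOVA") {
  if (!is.null(subjects)) dataset <- subset_trial(dataset, subjects)
  V <- dataset$schedule$n_visits
  s <- dataset$subjects
  yv <- dataset$outcomes[, V]
  keep <- !is.na(yv) & !is.na(s$baseline)
  s <- s[keep, , drop = FALSE]; yv <- yv[keep]
  s$arm <- droplevels(s$arm)
  cnt <- table(s$arm)
  if (length(cnt) < 2L || any(cnt < 3L))
    stop("ANCOVA requires at least 3 subjects with end-of-trial outcome ",
         "per arm")
  fit <- stats::lm(yv ~ arm + baseline, data = cbind(s, yv = yv))
  arm <- arm %||% levels(s$arm)[2L]
  term <- paste0("arm", arm)
  est <- stats::coef(fit)[[term]]
  se <- sqrt(stats::vcov(fit)[term, term])
  z <- stats::qnorm(0.975)
  new_effect_estimate(method_label, est, se, est - z * se, est + z * se,
                      visit = V, n_used = nrow(s),
                      diagnostics = list(n_per_arm = as.list(cnt)))
}

#' ANCOVA on complete cases
#'
#' Subjects with observed baseline and end-of-trial outcome; intermediate
#' visits are irrelevant.  Valid for the no-dropout (hypothetical) contrast
#' only under MCAR.
#'
#' @inheritParams ancova_fit
#' @return An `effect_estimate` with method `"ANCOVA_CC"`.
#' @export
ancova_complete_cases <- function(dataset, arm = NULL) {
  ancova_fit(dataset, arm = arm, method_label = "ANCOVA_CC")
}

#' ANCOVA after LOCF imputation
#' @inheritParams ancova_fit
#' @return An `effect_estimate` with method `"ANCOVA_LOCF"`.
#' @export
ancova_locf <- function(dataset, arm = NULL) {
  imp <- locf_impute(dataset)
  out <- ancova_fit(imp$datasets[[1L]], arm = arm,
                    method_label = "ANCOVA_LOCF")
  out$diagnostics$locf_notes <- imp$notes
  out
}

#' MMRM after LOCF imputation
#' @inheritParams ancova_fit
#' @return An `effect_estimate` with method `"MMRM_LOCF"`.
#' @export
mmrm_locf <- function(dataset, arm = NULL) {
  imp <- locf_impute(dataset)
  fit <- reml_fit(imp$datasets[[1L]])
  ct <- treatment_effect_at_visit(fit, fit$V, arm = arm)
  new_effect_estimate("MMRM_LOCF", ct$estimate, ct$se, ct$ci_low,
                      ct$ci_high, visit = fit$V,
                      n_used = fit$n_subjects_used,
                      diagnostics = list(converged = fit$converged,
                                         locf_notes = imp$notes))
}

#' ANCOVA after predictive-mean-matching multiple imputation
#'
#' [pmm_multiple_impute()] with m completed datasets, an ANCOVA per
#' dataset, and Rubin's-rules pooling (t-based CI).
#'
#' @inheritParams ancova_fit
#' @param m Number of imputations (default 10).
#' @param seed Integer seed.
#' @param donors PMM donor-pool size.
#' @return An `effect_estimate` with method `"ANCOVA_MI"`.
#' @export
ancova_mi <- function(dataset, m = 10L, seed, arm = NULL, donors = 5L) {
  if (!anyNA(dataset$outcomes)) {
    out <- ancova_fit(dataset, arm = arm, method_label = "ANCOVA_MI")
    out$diagnostics$m <- 0L
    out$diagnostics$B <- 0
    return(out)
  }
  imp <- pmm_multiple_impute(dataset, m = m, seed = seed, donors = donors)
  res <- lapply(imp$datasets, function(d)
    ancova_fit(d, arm = arm, method_label = "ANCOVA_MI"))
  pooled <- rubin_pool(vapply(res, `[[`, 0, "estimate"),
                       vapply(res, `[[`, 0, "se"))
  new_effect_estimate("ANCOVA_MI", pooled$qbar, pooled$se, pooled$ci_low,
                      pooled$ci_high, visit = dataset$schedule$n_visits,
                      n_used = res[[1L]]$n_used,
                      diagnostics = list(m = m, B = pooled$B, W = pooled$W,
                                         df = pooled$df))
}

#' MMRM without imputation
#'
#' Direct-likelihood MMRM; the visit-V treatment contrast is valid for the
#' hypothetical (no-discontinuation) effect under MAR.
#'
#' @inheritParams ancova_fit
#' @return An `effect_estimate` with method `"MMRM"`.
#' @export
mmrm_plain <- function(dataset, arm = NULL) {
  fit <- reml_fit(dataset)
  ct <- treatment_effect_at_visit(fit, fit$V, arm = arm)
  new_effect_estimate("MMRM", ct$estimate, ct$se, ct$ci_low, ct$ci_high,
                      visit = fit$V, n_used = fit$n_subjects_used,
                      diagnostics = list(converged = fit$converged))
}

#' MMRM after jump-to-reference multiple imputation
#'
#' [j2r_multiple_impute()], an MMRM refit per completed dataset (all arms),
#' and Rubin pooling of the visit-V contrast.  With no imputable cells the
#' result equals [mmrm_plain()] exactly (between-imputation variance 0).
#'
#' @inheritParams ancova_mi
#' @param draws `"marginal"` or `"joint"` reference error draws.
#' @return An `effect_estimate` with method `"MMRM_J2R"`.
#' @export
mmrm_j2r <- function(dataset, m = 10L, seed, arm = NULL,
                     draws = c("marginal", "joint")) {
  draws <- match.arg(draws)
  imp <- j2r_multiple_impute(dataset, m = m, seed = seed, draws = draws)
  if (sum(imp$imputed_cells) == 0L) {
    fit <- reml_fit(dataset)
    ct <- treatment_effect_at_visit(fit, fit$V, arm = arm)
    return(new_effect_estimate("MMRM_J2R", ct$estimate, ct$se, ct$ci_low,
                               ct$ci_high, visit = fit$V,
                               n_used = fit$n_subjects_used,
                               diagnostics = list(m = m, B = 0,
                                                  n_imputed = 0L)))
  }
  warm <- NULL
  est <- se <- numeric(m)
  nu <- NA_integer_
  for (i in seq_len(m)) {
    fit <- reml_fit(imp$datasets[[i]], start_sigma = warm)
    warm <- fit$sigma
    ct <- treatment_effect_at_visit(fit, fit$V, arm = arm)
    est[i] <- ct$estimate; se[i] <- ct$se; nu <- fit$n_subjects_used
  }
  pooled <- rubin_pool(est, se)
  new_effect_estimate("MMRM_J2R", pooled$qbar, pooled$se, pooled$ci_low,
                      pooled$ci_high, visit = dataset$schedule$n_visits,
                      n_used = nu,
                      diagnostics = list(m = m, B = pooled$B, W = pooled$W,
                                         df = pooled$df,
                                         n_imputed = sum(imp$imputed_cells)))
}

# merge sparse dropout patterns towards the completer pattern
# (EARLY -> LATE -> COMPLETER_QUASI); a pattern needs >= min_per_cell
# subjects in every arm for its treatment interaction to be estimable
merge_sparse_patterns <- function(patterns, arm, min_per_cell = 2L) {
  merges <- character()
  repeat {
    pats <- intersect(rev(pattern_levels), unique(patterns))  # early first
    bad <- NULL
    for (p in setdiff(pats, "COMPLETER_QUASI")) {
      cnt <- table(factor(arm[patterns == p], levels = levels(arm)))
      if (any(cnt < min_per_cell)) { bad <- p; break }
    }
    if (is.null(bad)) break
    target <- if (bad == "EARLY_DROPOUT" &&
                  "LATE_DROPOUT" %in% patterns[patterns != bad])
      "LATE_DROPOUT" else "COMPLETER_QUASI"
    patterns[patterns == bad] <- target
    merges <- c(merges, paste(bad, "->", target))
  }
  list(patterns = patterns, merges = merges)
}

#' Pattern-mixture mixed model
#'
#' MMRM with dropout-pattern main effects and pattern-by-treatment
#' interactions (patterns share the placebo time profile).  The
#' pattern-specific visit-V effects `delta_VP = beta1 + beta3V + beta6P`
#' are averaged with weights equal to the pattern relative frequencies in
#' the analyzed sample (treated as fixed); the SE is `sqrt(w' C w)` with C
#' the covariance of the pattern-specific contrasts from the coefficient
#' covariance.  Patterns with fewer than 2 subjects in any arm are merged
#' (early -> late -> completers) and the merge is recorded.
#'
#' @inheritParams ancova_fit
#' @return An `effect_estimate` with method `"PMMM"`.
#' @export
pmmm <- function(dataset, arm = NULL) {
  keep <- rowSums(!is.na(dataset$outcomes)) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with no observed post-baseline ",
            "outcome excluded from the pattern-mixture analysis")
    dataset <- subset_trial(dataset, keep)
  }
  raw_pat <- dataset_patterns(dataset)
  mg <- merge_sparse_patterns(raw_pat, dataset$subjects$arm)
  patterns <- mg$patterns
  pats <- intersect(pattern_levels, unique(patterns))
  V <- dataset$schedule$n_visits
  fit <- reml_fit(dataset, mmrm_spec(include_pattern_terms = TRUE),
                  patterns = patterns)
  arm <- arm %||% fit$arms[1L]
  w <- as.numeric(table(factor(patterns, levels = pats))) / length(patterns)
  cts <- lapply(pats, function(p)
    treatment_effect_at_visit(fit, V, arm = arm, pattern = p))
  Tm <- vapply(cts, `[[`, numeric(length(fit$beta)), "contrast_vector")
  deltas <- vapply(cts, `[[`, 0, "estimate")
  Cmat <- t(Tm) %*% fit$beta_cov %*% Tm
  est <- sum(w * deltas)
  se <- sqrt(drop(w %*% Cmat %*% w))
  z <- stats::qnorm(0.975)
  new_effect_estimate("PMMM", est, se, est - z * se, est + z * se,
                      visit = V, n_used = fit$n_subjects_used,
                      diagnostics = list(
                        pattern_weights = stats::setNames(as.list(w), pats),
                        pattern_deltas = stats::setNames(as.list(deltas),
                                                         pats),
                        merges = mg$merges, converged = fit$converged))
}

#' Configuration of the principal-stratum analysis
#'
#' @param covariates Predictors of the intercurrent event (columns of the
#'   subject table; default baseline only).
#' @param cutoff Probability threshold in (0, 1), or `"AUTO"`: the
#'   empirical quantile of the predicted probabilities equal to the
#'   observed event-free fraction.
#' @param ie_definition `"ANY"` discontinuation, or a character vector of
#'   reason codes.
#' @return A `principal_stratum_config`.
#' @export
ps_config <- function(covariates = "baseline", cutoff = "AUTO",
                      ie_definition = "ANY") {
  if (is.numeric(cutoff) && (cutoff <= 0 || cutoff > 1))
    stop("numeric cutoff must lie in (0, 1]")
  structure(list(covariates = covariates, cutoff = cutoff,
                 ie_definition = ie_definition),
            class = "principal_stratum_config")
}

# ridge-penalized logistic fit (Newton), fallback under separation
ridge_logistic <- function(X, y, lambda = 1e-3, iter = 50L) {
  b <- numeric(ncol(X))
  for (k in seq_len(iter)) {
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    wdiag <- pmax(p * (1 - p), 1e-8)
    H <- crossprod(X, X * wdiag) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * b
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  drop(stats::plogis(X %*% b))
}

#' Principal-stratum (CACE-style) analysis
#'
#' A logistic regression of the intercurrent-event indicator on the
#' configured covariates, fitted on all subjects pooled across arms, gives
#' a propensity to experience the event; subjects below the cutoff form
#' the predicted stratum of patients who would not experience it, and the
#' MMRM treatment contrast is estimated on that stratum without
#' imputation.  Under separation a ridge-penalized fit is used with a
#' warning (the ranking, hence the selection, is unaffected).
#'
#' @inheritParams ancova_fit
#' @param config A [ps_config()].
#' @param seed Unused placeholder for interface uniformity (the analysis is
#'   deterministic).
#' @return An `effect_estimate` with method `"PRINCIPAL_STRATUM"`.
#' @export
principal_stratum <- function(dataset, config = ps_config(), seed = NULL,
                              arm = NULL) {
  s <- dataset$subjects
  ie <- if (identical(config$ie_definition, "ANY")) {
    s$disc_reason != "none" & !is.na(s$disc_visit)
  } else s$disc_reason %in% config$ie_definition
  if (all(ie))
    stop("no event-free subjects: the principal stratum is empty")
  if (!any(ie)) {
    # no intercurrent events: the stratum is the whole population
    warning("no intercurrent events observed; stratum = all subjects")
    fit <- reml_fit(dataset)
    ct <- treatment_effect_at_visit(fit, fit$V, arm = arm)
    return(new_effect_estimate("PRINCIPAL_STRATUM", ct$estimate, ct$se,
                               ct$ci_low, ct$ci_high, visit = fit$V,
                               n_used = fit$n_subjects_used,
                               diagnostics = list(cutoff = NA,
                                                  stratum_size =
                                                    nrow(s))))
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(s[, config$covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  fitg <- suppressWarnings(stats::glm.fit(X, as.numeric(ie),
                                          family = stats::binomial()))
  prob <- fitg$fitted.values
  if (!isTRUE(fitg$converged) || any(prob < 1e-8) || any(prob > 1 - 1e-8)) {
    warning("separation or non-convergence in the event model; ",
            "using a ridge-penalized fit")
    prob <- ridge_logistic(X, as.numeric(ie))
  }
  cutoff <- config$cutoff
  if (identical(cutoff, "AUTO"))
    cutoff <- stats::quantile(prob, probs = mean(!ie), names = FALSE)
  stratum <- if (is.numeric(config$cutoff) && config$cutoff == 1)
    rep(TRUE, length(prob)) else prob < cutoff
  cnt <- table(droplevels(s$arm[stratum]))
  if (length(cnt) < nlevels(droplevels(s$arm)) || any(cnt < 3L))
    stop("predicted principal stratum has fewer than 3 subjects in an arm")
  sub <- subset_trial(dataset, stratum)
  fit <- reml_fit(sub)
  ct <- treatment_effect_at_visit(fit, fit$V, arm = arm)
  new_effect_estimate("PRINCIPAL_STRATUM", ct$estimate, ct$se, ct$ci_low,
                      ct$ci_high, visit = fit$V,
                      n_used = fit$n_subjects_used,
                      diagnostics = list(cutoff = cutoff,
                                         stratum_size = sum(stratum),
                                         converged = fit$converged))
}
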