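new_imputation_set <- function(method, datasets, seed, imputed_cells,
                               notes = character()) {
  structure(list(method = method, m = length(datasets), datasets = datasets,
                 seed = seed, imputed_cells = imputed_cells, notes = notes),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("imputation_set:", x$method, "with m =", x$m, "completed dataset(s);",
      sum(x$imputed_cells), "cell(s) imputed per dataset\n")
  if (length(x$notes)) cat(paste0("- ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Last observation carried forward
#'
#' Fills each missing post-baseline cell with the most recent previously
#' observed post-baseline value (monotone tails get the last available
#' outcome; intermittent gaps the immediately preceding one).  Cells before
#' the first observed post-baseline value are carried from the baseline
#' score; the number of baseline-carried cells is recorded in the notes.
#' LOCF is deterministic single imputation (m = 1) and idempotent.
#'
#' @param dataset A `trial_dataset`.
#' @return An `imputation_set` with one completed dataset.
#' @export
locf_impute <- function(dataset) {
  y <- dataset$outcomes
  V <- dataset$schedule$n_visits
  imputed <- is.na(y)
  from_baseline <- 0L
  for (i in seq_len(nrow(y))) {
    last <- dataset$subjects$baseline[i]
    for (j in seq_len(V)) {
      if (is.na(y[i, j])) {
        y[i, j] <- last
        if (j == 1L || all(is.na(dataset$outcomes[i, seq_len(j - 1L)])))
          from_baseline <- from_baseline + 1L
      } else last <- y[i, j]
    }
  }
  out <- dataset; out$outcomes <- y
  new_imputation_set("LOCF", list(out), seed = NA_integer_,
                     imputed_cells = imputed,
                     notes = sprintf("%d cell(s) carried from baseline",
                                     from_baseline))
}

# one Bayesian-bootstrap PMM pass for a single visit column
pmm_impute_visit <- function(ycol, X, mis, donors) {
  obs <- which(!mis)
  Xo <- X[obs, , drop = FALSE]
  qr_o <- qr(Xo)
  rank_ok <- qr_o$rank
  Xo <- Xo[, qr_o$pivot[seq_len(rank_ok)], drop = FALSE]
  Xm <- X[-obs, qr_o$pivot[seq_len(rank_ok)], drop = FALSE]
  n_o <- length(obs); p <- ncol(Xo)
  fit <- stats::lm.fit(Xo, ycol[obs])
  beta_hat <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- max(n_o - p, 1L)
  sigma2_star <- rss / stats::rchisq(1L, df)
  XtXinv <- chol2inv(chol(crossprod(Xo) + diag(1e-10, p)))
  beta_star <- beta_hat +
    drop(t(chol(sigma2_star * XtXinv)) %*% stats::rnorm(p))
  pred_obs <- drop(Xo %*% beta_hat)
  pred_mis <- drop(Xm %*% beta_star)
  k <- min(donors, n_o)
  vapply(pred_mis, function(pm) {
    d <- abs(pred_obs - pm)
    # uniform tie-break among equidistant donors via random secondary key
    pool <- order(d, stats::runif(n_o))[seq_len(k)]
    ycol[obs[pool[sample.int(k, 1L)]]]
  }, numeric(1L))
}

#' Multiple imputation by predictive mean matching
#'
#' Chained-equations predictive mean matching: visits are swept in
#' increasing order; for each visit with missing values, the observed
#' values are regressed on treatment, baseline and the current completed
#' values of all other visits; regression parameters are drawn from their
#' approximate posterior (normal/inverse-chi-squared, noninformative
#' prior); each missing cell receives the observed value of one of the
#' `donors` closest cases by predicted mean.  Imputed values therefore
#' always lie within the observed support of the visit.
#'
#' @param dataset A `trial_dataset`.
#' @param m Number of completed datasets (>= 2).
#' @param seed Integer seed; imputation i uses substream (seed, i).
#' @param donors Donor-pool size (default 5).
#' @param sweeps Chained-equation sweeps per imputation (default 10).
#' @return An `imputation_set` with `m` completed datasets.
#' @export
pmm_multiple_impute <- function(dataset, m = 10L, seed, donors = 5L,
                                sweeps = 10L) {
  if (m < 2L) stop("m must be >= 2 for multiple imputation")
  y0 <- dataset$outcomes
  V <- dataset$schedule$n_visits
  mis <- is.na(y0)
  n_obs_visit <- colSums(!mis)
  if (any(n_obs_visit == 0L))
    stop("visit ", which(n_obs_visit == 0L)[1L],
         " has no observed values; PMM cannot proceed")
  if (any(n_obs_visit < donors + 2L))
    warning("visit(s) ",
            paste(which(n_obs_visit < donors + 2L), collapse = ", "),
            " have fewer than donors + 2 observed values; ",
            "donor pool reduced")
  s <- dataset$subjects
  arm_mm <- stats::model.matrix(~arm, data = s)[, -1L, drop = FALSE]
  base_X <- cbind(1, arm_mm, s$baseline)
  datasets <- vector("list", m)
  for (imp in seq_len(m)) {
    datasets[[imp]] <- with_seed(stream_seed(seed, "pmm", imp), {
      y <- y0
      # initial fill: random observed values of the same visit
      for (j in which(colSums(mis) > 0L)) {
        ov <- y0[!mis[, j], j]
        y[mis[, j], j] <- sample(ov, sum(mis[, j]), replace = TRUE)
      }
      for (sw in seq_len(sweeps)) {
        for (j in which(colSums(mis) > 0L)) {
          X <- cbind(base_X, y[, -j, drop = FALSE])
          y[mis[, j], j] <- pmm_impute_visit(y0[, j], X, mis[, j], donors)
        }
      }
      out <- dataset; out$outcomes <- y
      out
    })
  }
  new_imputation_set("PMM_MI", datasets, seed = seed, imputed_cells = mis)
}

#' Jump-to-reference multiple imputation
#'
#' Fits an MMRM on the reference (placebo) arm only, with intercept, visit
#' indicators and baseline as fixed effects and an unstructured covariance.
#' For each non-reference subject, missing outcomes after the recorded
#' treatment discontinuation are imputed as the reference fixed-part
#' prediction at that visit plus a random error drawn from the reference
#' error distribution -- by default an independent per-visit marginal
#' normal draw with variance `Sigma_ref[j, j]`; `draws = "joint"` draws the
#' post-discontinuation block jointly from `Sigma_ref`.  Imputed values are
#' neither rounded nor clipped.  Reference-arm missing cells and
#' pre-discontinuation intermittent cells are considered MAR and left
#' missing (handled by the downstream MMRM likelihood).
#'
#' @param dataset A `trial_dataset`.
#' @param m Number of completed datasets (>= 2).
#' @param seed Integer seed; imputation i uses substream (seed, i).
#' @param draws `"marginal"` (default) or `"joint"` error draws.
#' @return An `imputation_set`; `ref_fit` attribute carries the
#'   reference-arm model.
#' @export
j2r_multiple_impute <- function(dataset, m = 10L, seed,
                                draws = c("marginal", "joint")) {
  draws <- match.arg(draws)
  if (m < 2L) stop("m must be >= 2 for multiple imputation")
  s <- dataset$subjects
  V <- dataset$schedule$n_visits
  is_ref <- s$arm == dataset$reference_arm
  ref <- subset_trial(dataset, is_ref)
  ref_fit <- reml_fit(ref, mmrm_spec(), include_treatment = FALSE)
  beta <- ref_fit$beta
  fixed_pred <- function(baseline, j) {
    beta[["(Intercept)"]] +
      (if (j >= 2L) beta[[paste0("visit", j)]] else 0) +
      beta[["baseline"]] * baseline
  }
  Sg <- ref_fit$sigma
  # imputable cells: non-reference subjects, visits after disc_visit, missing
  targets <- lapply(seq_len(nrow(s)), function(i) {
    d <- s$disc_visit[i]
    if (is_ref[i] || is.na(d) || d >= V) return(integer())
    post <- (d + 1L):V
    post[is.na(dataset$outcomes[i, post])]
  })
  any_cells <- sum(lengths(targets))
  imputed <- matrix(FALSE, nrow(s), V)
  for (i in seq_along(targets)) imputed[i, targets[[i]]] <- TRUE
  datasets <- vector("list", m)
  for (imp in seq_len(m)) {
    datasets[[imp]] <- with_seed(stream_seed(seed, "j2r", imp), {
      y <- dataset$outcomes
      for (i in seq_along(targets)) {
        js <- targets[[i]]
        if (!length(js)) next
        mu <- vapply(js, fixed_pred, numeric(1L), baseline = s$baseline[i])
        err <- if (draws == "marginal") {
          stats::rnorm(length(js), 0, sqrt(diag(Sg)[js]))
        } else {
          drop(t(chol(Sg[js, js, drop = FALSE])) %*%
                 stats::rnorm(length(js)))
        }
        y[i, js] <- mu + err
      }
      out <- dataset; out$outcomes <- y
      out
    })
  }
  out <- new_imputation_set("J2R_MI", datasets, seed = seed,
                            imputed_cells = imputed,
                            notes = sprintf("%d cell(s) imputed per dataset",
                                            any_cells))
  attr(out, "ref_fit") <- ref_fit
  out
}

#' Pool multiply-imputed estimates by Rubin's rules
#'
#' `qbar = mean(estimates)`, within-imputation variance `W = mean(ses^2)`,
#' between-imputation variance `B = var(estimates)`, total variance
#' `T = W + (1 + 1/m) B`, degrees of freedom
#' `df = (m - 1) (1 + W / ((1 + 1/m) B))^2` (infinite when B = 0, in which
#' case the normal quantile is used for the 95% CI).
#'
#' @param estimates Vector of m point estimates.
#' @param ses Vector of m standard errors (>= 0).
#' @return An object of class `rubin_pooled`: `qbar`, `W`, `B`, `T`, `df`,
#'   `se`, `ci_low`, `ci_high`.
#' @export
rubin_pool <- function(estimates, ses) {
  m <- length(estimates)
  if (m < 2L) stop("Rubin pooling requires m >= 2 estimates")
  if (length(ses) != m) stop("estimates and ses must have equal length")
  if (any(ses < 0)) stop("standard errors must be non-negative")
  qbar <- mean(estimates)
  W <- mean(ses^2)
  B <- stats::var(estimates)
  Tt <- W + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    tq <- stats::qt(0.975, df)
  } else {
    df <- Inf
    tq <- stats::qnorm(0.975)
  }
  se <- sqrt(Tt)
  structure(list(qbar = qbar, W = W, B = B, T = Tt, df = df, se = se,
                 ci_low = qbar - tq * se, ci_high = qbar + tq * se,
                 m = m), class = "rubin_pooled")
}

#' @export
print.rubin_pooled <- function(x, ...) {
  cat(sprintf(
    "pooled estimate %.3f (total SE %.3f; W %.3f, B %.3f, df %s)\n",
    x$qbar, x$se, x$W, x$B, format(round(x$df, 1))))
  invisible(x)
}

#' Write an imputation set to a directory of CSVs
#'
#' Numbered completed datasets plus a manifest (method, m, seed, number of
#' imputed cells).
#'
#' @param imp An `imputation_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputation_set <- function(imp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(imp$m))
    write_trial_csv(imp$datasets[[i]], file.path(dir, sprintf("imp_%02d.csv",
                                                              i)))
  manifest <- data.frame(method = imp$method, m = imp$m,
                         seed = imp$seed %||% NA,
                         n_imputed_cells = sum(imp$imputed_cells))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
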