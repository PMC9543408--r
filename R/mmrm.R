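#' Specification of a mixed model for repeated measures
#'
#' The saturated MMRM models only post-baseline outcomes: visit-specific
#' intercepts and treatment effects, the baseline score as an uncentred
#' covariate, and an unstructured within-subject covariance estimated by
#' REML.  Random intercepts plus an unrestricted serial covariance are not
#' jointly identified, so the marginal covariance is fitted as a single
#' unstructured V x V matrix (`UNSTRUCTURED_TOTAL`), which spans the same
#' marginal model.  With `include_pattern_terms` the pattern-mixture
#' extension adds dropout-pattern main effects (level offsets) and
#' pattern-by-treatment interactions; patterns share the visit-time
#' profile.
#'
#' @param include_pattern_terms Add pattern terms (default `FALSE`).
#' @param reference_pattern Reference pattern level (completers and
#'   quasicompleters).
#' @param include_baseline Include the baseline covariate (default `TRUE`).
#' @return An object of class `mmrm_spec`.
#' @export
mmrm_spec <- function(include_pattern_terms = FALSE,
                      reference_pattern = "COMPLETER_QUASI",
                      include_baseline = TRUE) {
  structure(list(include_pattern_terms = isTRUE(include_pattern_terms),
                 reference_pattern = reference_pattern,
                 include_baseline = isTRUE(include_baseline),
                 estimation = "REML",
                 covariance = "UNSTRUCTURED_TOTAL"),
            class = "mmrm_spec")
}

# Internal description of the design: subject-level covariate matrix Zc
# and, per design column, which covariate it multiplies (col_cov) and the
# visit it is restricted to (col_visit; 0 = all visits).  The design row
# for subject i at visit v is Zc[i, col_cov] * (col_visit %in% c(0, v)).
design_info <- function(dataset, spec, include_treatment = TRUE,
                        patterns = NULL) {
  s <- dataset$subjects
  V <- dataset$schedule$n_visits
  arms_act <- if (include_treatment) active_arms(dataset) else character()
  if (include_treatment) {
    cnt <- table(droplevels(s$arm))
    if (any(cnt == 0L)) stop("arm with zero subjects")
  }
  q_names <- "const"
  Zc <- matrix(1, nrow(s), 1L)
  for (a in arms_act) {
    Zc <- cbind(Zc, as.numeric(s$arm == a))
    q_names <- c(q_names, paste0("trt_", a))
  }
  if (spec$include_baseline) {
    Zc <- cbind(Zc, s$baseline)
    q_names <- c(q_names, "baseline")
  }
  pat_act <- character()
  if (spec$include_pattern_terms) {
    stopifnot(!is.null(patterns))
    pat_act <- setdiff(intersect(pattern_levels, unique(patterns)),
                       spec$reference_pattern)
    for (p in pat_act) {
      Zc <- cbind(Zc, as.numeric(patterns == p))
      q_names <- c(q_names, paste0("pat_", p))
    }
    for (a in arms_act) for (p in pat_act) {
      Zc <- cbind(Zc, as.numeric(s$arm == a & patterns == p))
      q_names <- c(q_names, paste0("trt_", a, ":pat_", p))
    }
  }
  colnames(Zc) <- q_names
  ci <- function(nm) match(nm, q_names)
  col_cov <- ci("const"); col_visit <- 0L; col_names <- "(Intercept)"
  for (a in arms_act) {
    col_cov <- c(col_cov, ci(paste0("trt_", a)))
    col_visit <- c(col_visit, 0L)
    col_names <- c(col_names, paste0("arm", a))
  }
  for (f in seq_len(V)[-1L]) {
    col_cov <- c(col_cov, ci("const")); col_visit <- c(col_visit, f)
    col_names <- c(col_names, paste0("visit", f))
  }
  for (a in arms_act) for (f in seq_len(V)[-1L]) {
    col_cov <- c(col_cov, ci(paste0("trt_", a)))
    col_visit <- c(col_visit, f)
    col_names <- c(col_names, paste0("arm", a, ":visit", f))
  }
  if (spec$include_baseline) {
    col_cov <- c(col_cov, ci("baseline")); col_visit <- c(col_visit, 0L)
    col_names <- c(col_names, "baseline")
  }
  for (p in pat_act) {
    col_cov <- c(col_cov, ci(paste0("pat_", p)))
    col_visit <- c(col_visit, 0L)
    col_names <- c(col_names, paste0("pattern", p))
  }
  for (a in arms_act) for (p in pat_act) {
    col_cov <- c(col_cov, ci(paste0("trt_", a, ":pat_", p)))
    col_visit <- c(col_visit, 0L)
    col_names <- c(col_names, paste0("arm", a, ":pattern", p))
  }
  list(Zc = Zc, col_cov = col_cov, col_visit = as.integer(col_visit),
       col_names = col_names, V = V, arms = arms_act, patterns = pat_act)
}

#' Build the MMRM design from a trial dataset
#'
#' One row per observed subject-visit cell: visit indicators for visits
#' 2..V (visit 1 is the reference level), treatment indicators per
#' non-reference arm, their interactions, the uncentred baseline, and
#' optional pattern terms.  Subjects with no observed post-baseline outcome
#' are excluded with a warning.
#'
#' @param dataset A `trial_dataset`.
#' @param spec An [mmrm_spec()].
#' @return A list: `y`, `X` (design matrix with named columns), `subject`
#'   (row index into the retained subjects), `visit`, and internals used by
#'   the fitter.
#' @export
build_design <- function(dataset, spec = mmrm_spec()) {
  keep <- rowSums(!is.na(dataset$outcomes)) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with no observed post-baseline ",
            "outcome excluded from the model fit")
    dataset <- subset_trial(dataset, keep)
  }
  patterns <- if (spec$include_pattern_terms) dataset_patterns(dataset)
  info <- design_info(dataset, spec, patterns = patterns)
  obs <- !is.na(dataset$outcomes)
  subject <- rep(seq_len(nrow(obs)), times = rowSums(obs))
  visit <- unlist(apply(obs, 1L, which, simplify = FALSE), use.names = FALSE)
  d <- length(info$col_cov)
  X <- matrix(0, length(subject), d, dimnames = list(NULL, info$col_names))
  for (c in seq_len(d)) {
    on <- info$col_visit[c] == 0L | info$col_visit[c] == visit
    X[, c] <- info$Zc[subject, info$col_cov[c]] * on
  }
  list(y = dataset$outcomes[cbind(subject, visit)], X = X,
       subject = subject, visit = visit, info = info,
       subject_id = dataset$subjects$subject_id[subject])
}

# log-Cholesky parameterisation of the unstructured covariance
theta_to_chol <- function(theta, V) {
  L <- matrix(0, V, V)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L
}

chol_to_theta <- function(L) {
  M <- L
  diag(M) <- log(diag(M))
  M[lower.tri(M, diag = TRUE)]
}

# Pattern-grouped sufficient statistics.  Subjects sharing an observed-
# visit set s have design blocks X_i = P[s, ] * z_i' (entrywise), so all
# REML pieces reduce to small per-group cross-products:
#   A_g  = (P' W P) o Sz              (o = Hadamard)
#   b_g  = diag(P' W Syz)
#   q_g  = sum(W o Syy)
engine_prepare <- function(y_mat, info) {
  V <- info$V
  d <- length(info$col_cov)
  Pmat <- matrix(0, V, d)
  for (c in seq_len(d))
    Pmat[, c] <- as.numeric(info$col_visit[c] == 0L |
                              info$col_visit[c] == seq_len(V))
  Zt <- info$Zc[, info$col_cov, drop = FALSE]
  obs <- !is.na(y_mat)
  key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(nrow(y_mat)), key)
  stats_list <- lapply(groups, function(idx) {
    s <- which(obs[idx[1L], ])
    Yg <- y_mat[idx, s, drop = FALSE]
    Zg <- Zt[idx, , drop = FALSE]
    list(s = s, n = length(idx), P = Pmat[s, , drop = FALSE],
         Sz = crossprod(Zg), Syy = crossprod(Yg), Syz = crossprod(Yg, Zg))
  })
  list(stats = stats_list, d = d, V = V, N = sum(obs))
}

# Negative restricted log-likelihood (with constants) and, optionally, its
# analytic gradient in the log-Cholesky parameters.
engine_eval <- function(theta, prep, want_grad = FALSE) {
  V <- prep$V; d <- prep$d
  L <- theta_to_chol(theta, V)
  Sigma <- tcrossprod(L)
  A <- matrix(0, d, d); b <- numeric(d)
  qss <- 0; logdet <- 0
  Ws <- vector("list", length(prep$stats))
  for (g in seq_along(prep$stats)) {
    st <- prep$stats[[g]]
    Cc <- tryCatch(chol(Sigma[st$s, st$s, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(Cc))
      return(structure(1e10, grad = rep(0, length(theta)), bad = TRUE))
    W <- chol2inv(Cc)
    Ws[[g]] <- W
    logdet <- logdet + st$n * 2 * sum(log(diag(Cc)))
    PW <- crossprod(st$P, W)                       # d x k
    A <- A + (PW %*% st$P) * st$Sz
    b <- b + diag(PW %*% st$Syz)
    qss <- qss + sum(W * st$Syy)
  }
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA))
    return(structure(1e10, grad = rep(0, length(theta)), bad = TRUE))
  beta <- backsolve(cA, backsolve(cA, b, transpose = TRUE))
  ldA <- 2 * sum(log(diag(cA)))
  rq <- qss - sum(b * beta)
  negll <- 0.5 * (logdet + ldA + rq + (prep$N - d) * log(2 * pi))
  out <- structure(negll, beta = beta, A_chol = cA, Sigma = Sigma)
  if (want_grad) {
    Ainv <- chol2inv(cA)
    M <- matrix(0, V, V)
    for (g in seq_along(prep$stats)) {
      st <- prep$stats[[g]]; W <- Ws[[g]]; P <- st$P
      Q1 <- st$n * W - W %*% P %*% (Ainv * st$Sz) %*% crossprod(P, W)
      SyzB <- st$Syz %*% (beta * t(P))             # k x k: Syz diag(b) P'
      Rrr <- st$Syy - SyzB - t(SyzB) +
        P %*% ((st$Sz * tcrossprod(beta)) %*% t(P))
      Q2 <- W %*% Rrr %*% W
      M[st$s, st$s] <- M[st$s, st$s] + (Q1 - Q2)
    }
    M <- (M + t(M)) / 2
    G <- M %*% L                                   # d(negll)/dL entries
    diag(G) <- diag(G) * diag(L)                   # chain rule for log-diag
    attr(out, "grad") <- G[lower.tri(G, diag = TRUE)]
  }
  out
}

#' Fit the MMRM by REML
#'
#' Maximises the restricted likelihood over the unstructured within-subject
#' covariance (log-Cholesky parameterisation, quasi-Newton with analytic
#' gradient, coefficients profiled out by generalised least squares).  Each
#' subject contributes the sub-matrix of the covariance at their observed
#' visits (direct-likelihood handling of intermittent and monotone
#' missingness, valid under MAR).  Inference uses the normal approximation.
#'
#' @param dataset A `trial_dataset`.
#' @param spec An [mmrm_spec()].
#' @param start_sigma Optional V x V starting covariance (warm start).
#' @param include_treatment Internal: drop treatment terms (used for the
#'   reference-arm model of jump-to-reference imputation).
#' @param reltol Relative convergence tolerance of the REML log-likelihood.
#' @param max_iter Maximum quasi-Newton iterations.
#' @param patterns Optional per-subject pattern labels (e.g. after merging
#'   sparse patterns); defaults to [classify_pattern()] on each subject.
#' @return An object of class `mmrm_fit`: `beta`, `beta_cov`, `sigma`,
#'   `reml_loglik`, `n_subjects_used`, `converged`.
#' @export
reml_fit <- function(dataset, spec = mmrm_spec(), start_sigma = NULL,
                     include_treatment = TRUE, reltol = 1e-8,
                     max_iter = 200L, patterns = NULL) {
  keep <- rowSums(!is.na(dataset$outcomes)) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with no observed post-baseline ",
            "outcome excluded from the model fit")
    if (!is.null(patterns)) patterns <- patterns[keep]
    dataset <- subset_trial(dataset, keep)
  }
  if (spec$include_pattern_terms && is.null(patterns))
    patterns <- dataset_patterns(dataset)
  if (!spec$include_pattern_terms) patterns <- NULL
  info <- design_info(dataset, spec, include_treatment = include_treatment,
                      patterns = patterns)
  V <- info$V
  prep <- engine_prepare(dataset$outcomes, info)
  d <- prep$d
  if (prep$N <= d + V * (V + 1) / 2)
    stop("too few observed cells (", prep$N, ") for ", d,
         " coefficients plus ", V * (V + 1) / 2, " covariance parameters")
  if (is.null(start_sigma)) {
    v0 <- apply(dataset$outcomes, 2L, stats::var, na.rm = TRUE)
    v0[!is.finite(v0) | v0 <= 0] <- mean(v0[is.finite(v0) & v0 > 0]) %||% 1
    start_sigma <- diag(v0, V)
  }
  theta0 <- chol_to_theta(chol_psd(start_sigma))
  fn <- function(th) as.numeric(engine_eval(th, prep))
  gr <- function(th) attr(engine_eval(th, prep, want_grad = TRUE), "grad")
  run <- function(th) stats::optim(th, fn, gr, method = "BFGS",
                                   control = list(maxit = max_iter,
                                                  reltol = reltol))
  opt <- run(theta0)
  if (opt$convergence != 0) {
    jit <- with_seed(1L, stats::rnorm(length(theta0), 0, 0.1))
    opt2 <- run(theta0 + jit)
    if (opt2$value < opt$value) opt <- opt2
  }
  converged <- opt$convergence == 0
  final <- engine_eval(opt$par, prep)
  if (isTRUE(attr(final, "bad")))
    stop("singular design or degenerate covariance at the REML optimum ",
         "(empty pattern-by-arm cell?); merge sparse patterns or simplify ",
         "the model")
  beta <- attr(final, "beta")
  names(beta) <- info$col_names
  beta_cov <- chol2inv(attr(final, "A_chol"))
  dimnames(beta_cov) <- list(info$col_names, info$col_names)
  structure(list(
    beta = beta, beta_cov = beta_cov, sigma = attr(final, "Sigma"),
    reml_loglik = -as.numeric(final),
    n_subjects_used = n_subjects(dataset),
    n_obs = prep$N,
    converged = converged,
    spec = spec, V = V, arms = info$arms,
    patterns = info$patterns,
    reference_arm = dataset$reference_arm,
    pattern_labels = patterns,
    subject_arm = dataset$subjects$arm), class = "mmrm_fit")
}

# nearest convenient PD Cholesky for start values
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) out <- chol(S + diag(1e-6 * max(diag(S), 1), nrow(S)))
  t(out)
}

#' Visit-specific treatment effect from a fitted MMRM
#'
#' The contrast `delta_F = beta_arm (+ beta_arm:visitF for F >= 2)
#' (+ beta_arm:patternP for a non-reference pattern)`, its standard error
#' from the coefficient covariance, and a 95% normal-approximation CI.
#'
#' @param fit An `mmrm_fit`.
#' @param visit Visit index F (1..V).
#' @param arm Non-reference arm (default: the first).
#' @param pattern Optional pattern level for pattern-mixture fits.
#' @return An object of class `contrast_result`: `estimate`, `se`,
#'   `ci_low`, `ci_high`, `visit`, `contrast_vector`.
#' @export
treatment_effect_at_visit <- function(fit, visit, arm = NULL,
                                      pattern = NULL) {
  stopifnot(inherits(fit, "mmrm_fit"))
  if (length(fit$arms) == 0L)
    stop("fit has no treatment terms")
  arm <- arm %||% fit$arms[1L]
  if (!arm %in% fit$arms) stop("unknown arm: ", arm)
  if (!(visit %in% seq_len(fit$V))) stop("unknown visit: ", visit)
  cvec <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
  cvec[paste0("arm", arm)] <- 1
  if (visit >= 2L) cvec[paste0("arm", arm, ":visit", visit)] <- 1
  if (!is.null(pattern) && pattern != fit$spec$reference_pattern) {
    nm <- paste0("arm", arm, ":pattern", pattern)
    if (!nm %in% names(fit$beta)) stop("unknown pattern: ", pattern)
    cvec[nm] <- 1
  }
  est <- sum(cvec * fit$beta)
  se <- sqrt(drop(cvec %*% fit$beta_cov %*% cvec))
  z <- stats::qnorm(0.975)
  structure(list(estimate = est, se = se,
                 ci_low = est - z * se, ci_high = est + z * se,
                 visit = visit, arm = arm, pattern = pattern,
                 contrast_vector = cvec), class = "contrast_result")
}

#' Coefficient table of a fitted MMRM
#'
#' @param fit An `mmrm_fit`.
#' @return Data frame: term, estimate, se, z, ci bounds (CSV-exportable).
#' @export
coef_table <- function(fit) {
  se <- sqrt(diag(fit$beta_cov))
  z <- stats::qnorm(0.975)
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(se),
             ci_low = unname(fit$beta - z * se),
             ci_high = unname(fit$beta + z * se), row.names = NULL)
}

#' @export
print.mmrm_fit <- function(x, ...) {
  cat("MMRM (REML, unstructured covariance): ", x$n_subjects_used,
      " subjects, ", x$n_obs, " observed cells\n", sep = "")
  cat("REML log-likelihood:", format(x$reml_loglik), "\n")
  print(coef_table(x), digits = 4)
  invisible(x)
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("delta at visit %d: %.3f (SE %.3f, 95%% CI %.3f to %.3f)\n",
              x$visit, x$estimate, x$se, x$ci_low, x$ci_high))
  invisible(x)
}
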