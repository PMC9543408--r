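# Shared fixtures and independent oracles.

# Literal implementation of the three dropout-pattern rules, written in
# terms of the visit at which the monotone missing tail starts (independent
# of the trailing-run formulation used by classify_pattern).
oracle_classify <- function(mask) {
  obs <- as.logical(mask)
  V <- length(obs)
  r <- 0L
  while (r < V && !obs[V - r]) r <- r + 1L
  tail_start <- V - r + 1L
  if (r == V) return("UNCLASSIFIABLE")           # no post-baseline data
  if (obs[V]) return("COMPLETER_QUASI")          # all or intermittent
  if (tail_start == V) return("COMPLETER_QUASI") # only last visit missing
  if (tail_start == V - 1L) return("LATE_DROPOUT")
  "EARLY_DROPOUT"                                # tail from mid-trial
}

# Direct-likelihood REML oracle: per-subject explicit inversions, log-SD +
# Fisher-z correlation parameterisation, generic numerical optimizer.
naive_reml <- function(dataset, spec = mmrm_spec()) {
  bd <- build_design(dataset, spec)
  V <- dataset$schedule$n_visits
  d <- ncol(bd$X)
  N <- length(bd$y)
  subj <- split(seq_len(N), bd$subject)
  build_sigma <- function(par) {
    sds <- exp(par[1:V])
    R <- diag(V)
    R[lower.tri(R)] <- tanh(par[-(1:V)])
    R[upper.tri(R)] <- t(R)[upper.tri(R)]
    outer(sds, sds) * R
  }
  negll <- function(par) {
    S <- build_sigma(par)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
      return(1e10)
    A <- matrix(0, d, d); b <- numeric(d); q <- 0; ld <- 0
    for (r in subj) {
      s <- bd$visit[r]
      Si <- solve(S[s, s, drop = FALSE])
      Xi <- bd$X[r, , drop = FALSE]; yi <- bd$y[r]
      A <- A + t(Xi) %*% Si %*% Xi
      b <- b + drop(t(Xi) %*% Si %*% yi)
      q <- q + drop(t(yi) %*% Si %*% yi)
      ld <- ld + as.numeric(determinant(S[s, s, drop = FALSE])$modulus)
    }
    beta <- solve(A, b)
    0.5 * (ld + as.numeric(determinant(A)$modulus) + q - sum(b * beta) +
             (N - d) * log(2 * pi))
  }
  v0 <- apply(dataset$outcomes, 2, stats::var, na.rm = TRUE)
  par0 <- c(0.5 * log(v0), rep(0, V * (V - 1) / 2))
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  opt <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt <- stats::optim(opt$par, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  S <- build_sigma(opt$par)
  A <- matrix(0, d, d); b <- numeric(d)
  for (r in subj) {
    s <- bd$visit[r]
    Si <- solve(S[s, s, drop = FALSE])
    Xi <- bd$X[r, , drop = FALSE]
    A <- A + t(Xi) %*% Si %*% Xi
    b <- b + drop(t(Xi) %*% Si %*% bd$y[r])
  }
  list(loglik = -opt$value, beta = drop(solve(A, b)), sigma = S)
}

# Hand-built dataset: outcomes is an n x V matrix (NA = missing).
hand_dataset <- function(outcomes, arm, baseline,
                         disc_reason = rep("none", nrow(outcomes)),
                         disc_visit = rep(NA_integer_, nrow(outcomes)),
                         reference = "placebo", validate = TRUE) {
  n <- nrow(outcomes)
  trial_dataset(
    data.frame(subject_id = sprintf("H%03d", seq_len(n)), arm = arm,
               baseline = baseline, disc_reason = disc_reason,
               disc_visit = disc_visit, stringsAsFactors = FALSE),
    outcomes, visit_schedule(ncol(outcomes)), reference,
    validate = validate)
}

# complete-data generator configuration (no events, no blanking)
complete_config <- function(n_per_arm, ...) {
  sim_config(n_per_arm = n_per_arm, dropout_model = list(),
             intermittent_prob = 0, ...)
}

expect_effect_close <- function(a, b, tol = 1e-8) {
  expect_equal(a$estimate, b$estimate, tolerance = tol)
  expect_equal(a$se, b$se, tolerance = tol)
}
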