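#' AR(1) within-subject covariance matrix
#'
#' Shorthand for serially correlated visit errors: `sd[i]*sd[j]*rho^|i-j|`.
#'
#' @param sd Per-visit error SD (points); recycled to length `n_visits`.
#' @param rho Lag-1 correlation in (-1, 1).
#' @param n_visits Number of post-baseline visits.
#' @return A positive-definite `n_visits` x `n_visits` matrix (points^2).
#' @export
ar1_cov <- function(sd, rho, n_visits) {
  stopifnot(abs(rho) < 1, all(sd > 0))
  sd <- rep_len(sd, n_visits)
  outer(sd, sd) * rho^abs(outer(seq_len(n_visits), seq_len(n_visits), "-"))
}

default_dropout_model <- function() {
  # discrete-time logistic hazards per discontinuation reason; intercepts
  # are on the per-visit log-odds scale, score_coef multiplies the current
  # latent MADRS10 score centred at score_center.  LoE risk increases with
  # the current score (worse depression); AE risk is concentrated early.
  list(
    LoE = list(intercept = c(placebo = -3.3, active = -3.8),
               score_coef = 0.10, visits = NULL),
    AE = list(intercept = c(placebo = -4.8, active = -4.2),
              score_coef = 0, visits = 1:2),
    drug_unrelated = list(intercept = -4.9, score_coef = 0, visits = NULL),
    unknown = list(intercept = -5.6, score_coef = 0, visits = NULL),
    efficacy = list(intercept = -6.5, score_coef = -0.05, visits = NULL),
    insufficient_compliance = list(intercept = -6.2, score_coef = 0,
                                   visits = NULL)
  )
}

#' Configuration of the synthetic-trial generator
#'
#' Defaults emulate a short-term antidepressant trial: two parallel arms,
#' six weekly post-baseline visits, MADRS10 baselines around 30 (severity
#' cut-off truncation at 10), a placebo response of roughly 8 points by
#' week 6 and a drug effect growing to -4 points at week 6, subject random
#' intercepts plus AR(1) serial errors, LoE-dominated score-dependent
#' discontinuation totalling roughly a quarter of subjects, and sparse
#' intermittent (MCAR) missingness.
#'
#' @param n_per_arm Subjects per arm.
#' @param arms Arm labels; the first is the reference (placebo).
#' @param schedule A [visit_schedule()].
#' @param baseline_mean,baseline_sd Baseline MADRS10 distribution (points);
#'   draws are truncated to `[baseline_min, 60]`.
#' @param baseline_min Lower truncation bound of baseline (severity
#'   cut-off), default 10.
#' @param baseline_coef Slope of post-baseline outcomes on centred baseline.
#' @param arm_visit_means Arm x visit matrix of mean outcomes (points),
#'   rownames = arms.
#' @param sigma_b SD of the subject random intercept (points).
#' @param serial_cov V x V within-subject error covariance (points^2), or a
#'   `list(sd =, rho =)` AR(1) shorthand.
#' @param dropout_model Per-reason discrete-time logistic hazards; see
#'   `default_dropout_model` in the source for the element layout.
#' @param score_center Centring constant for score-dependent hazards.
#' @param intermittent_prob Probability that an otherwise observed
#'   post-baseline cell is blanked (MCAR), never the baseline.
#' @param post_ie_mechanism Post-discontinuation behaviour of the
#'   treatment-policy potential outcomes: `"MAR_CONTINUATION"` (course
#'   continues as if no event), `"J2R_SWITCH"` (fixed part jumps to the
#'   reference profile), or `"RETAINED_SLOPE"` (the deviation from the arm
#'   profile at the event visit is carried forward).
#' @param integer_scores Round generated scores to integers (default
#'   `FALSE`, keeping Gaussian parameter recovery exact in expectation).
#' @param master_seed Default seed for [simulate_trial()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_arm = 50L,
                       arms = c("placebo", "active"),
                       schedule = visit_schedule(6L),
                       baseline_mean = 30, baseline_sd = 5,
                       baseline_min = 10,
                       baseline_coef = 0.5,
                       arm_visit_means = NULL,
                       sigma_b = 5,
                       serial_cov = list(sd = 5, rho = 0.6),
                       dropout_model = default_dropout_model(),
                       score_center = 25,
                       intermittent_prob = 0.03,
                       post_ie_mechanism = c("MAR_CONTINUATION", "J2R_SWITCH",
                                             "RETAINED_SLOPE"),
                       integer_scores = FALSE,
                       master_seed = 20260101L) {
  post_ie_mechanism <- match.arg(post_ie_mechanism)
  V <- schedule$n_visits
  if (is.null(arm_visit_means)) {
    placebo <- baseline_mean - c(2, 3.5, 5, 6, 7, 8)[seq_len(min(V, 6L))]
    if (V > 6L) placebo <- c(placebo, rep(placebo[6L], V - 6L))
    effect <- -4 * seq_len(V) / V
    arm_visit_means <- rbind(placebo,
                             matrix(rep(placebo, length(arms) - 1L),
                                    nrow = length(arms) - 1L, byrow = TRUE) +
                               rep(1, length(arms) - 1L) %o% effect)
    rownames(arm_visit_means) <- arms
  }
  arm_visit_means <- as.matrix(arm_visit_means)
  if (is.null(rownames(arm_visit_means))) rownames(arm_visit_means) <- arms
  if (!all(arms %in% rownames(arm_visit_means)) ||
      ncol(arm_visit_means) != V || !all(is.finite(arm_visit_means)))
    stop("arm_visit_means must be a finite arms x n_visits matrix")
  if (is.list(serial_cov))
    serial_cov <- ar1_cov(serial_cov$sd, serial_cov$rho, V)
  serial_cov <- as.matrix(serial_cov)
  if (!isTRUE(all.equal(serial_cov, t(serial_cov))) ||
      any(eigen(serial_cov, symmetric = TRUE,
                only.values = TRUE)$values <= 1e-12) && any(serial_cov != 0))
    stop("serial_cov must be symmetric positive definite")
  if (intermittent_prob < 0 || intermittent_prob > 1)
    stop("intermittent_prob must lie in [0, 1]")
  structure(list(
    n_per_arm = as.integer(n_per_arm), arms = arms, schedule = schedule,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    baseline_min = baseline_min, baseline_coef = baseline_coef,
    arm_visit_means = arm_visit_means[arms, , drop = FALSE],
    sigma_b = sigma_b, serial_cov = serial_cov,
    dropout_model = dropout_model, score_center = score_center,
    intermittent_prob = intermittent_prob,
    post_ie_mechanism = post_ie_mechanism,
    integer_scores = isTRUE(integer_scores),
    master_seed = as.integer(master_seed)), class = "sim_config")
}

#' Read a generator configuration from a YAML or JSON file
#'
#' Scalar fields override [sim_config()] defaults; `arm_visit_means` may be
#' given as a list of per-arm rows and `serial_cov` as `{sd, rho}`.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("package 'yaml' is required to read YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("package 'jsonlite' is required to read JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config extension: ", ext)
  if (!is.null(raw$schedule))
    raw$schedule <- visit_schedule(raw$schedule$n_visits,
                                   raw$schedule$weeks %||%
                                     seq_len(raw$schedule$n_visits))
  if (!is.null(raw$arm_visit_means) && is.list(raw$arm_visit_means))
    raw$arm_visit_means <- do.call(rbind, raw$arm_visit_means)
  do.call(sim_config, raw)
}

clip01_60 <- function(x) pmin(pmax(x, 0), 60)

maybe_round <- function(x, config) if (config$integer_scores) round(x) else x

# latent (pre-clipping) fixed+random trajectory components
draw_latent <- function(config, seed) {
  V <- config$schedule$n_visits
  arms <- config$arms
  n <- config$n_per_arm * length(arms)
  arm <- factor(rep(arms, each = config$n_per_arm), levels = arms)
  baseline <- with_seed(stream_seed(seed, "baseline"), {
    # truncated normal via inverse CDF
    lo <- stats::pnorm(config$baseline_min, config$baseline_mean,
                       config$baseline_sd)
    hi <- stats::pnorm(60, config$baseline_mean, config$baseline_sd)
    stats::qnorm(stats::runif(n, lo, hi), config$baseline_mean,
                 config$baseline_sd)
  })
  b <- with_seed(stream_seed(seed, "ranef"),
                 stats::rnorm(n, 0, config$sigma_b))
  e <- with_seed(stream_seed(seed, "resid"), {
    if (all(config$serial_cov == 0)) matrix(0, n, V)
    else matrix(stats::rnorm(n * V), n, V) %*% chol(config$serial_cov)
  })
  fixed <- config$arm_visit_means[as.character(arm), , drop = FALSE] +
    config$baseline_coef * (baseline - config$baseline_mean)
  list(arm = arm, baseline = baseline, b = b, e = e,
       latent = fixed + b + e)
}

#' Simulate complete (no-missingness) trial data
#'
#' Generates `Y_ij = mu[arm, j] + gamma * (baseline_i - baseline_mean) +
#' b_i + e_ij` with subject random intercepts and serially correlated visit
#' errors; scores are clipped to \[0, 60\] (latent values are kept for the
#' dropout hazards) and rounded only when `integer_scores`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$master_seed`).
#' @return A list: `dataset` (complete `trial_dataset`) and `truth` (a
#'   partial truth record carrying the latent components).
#' @export
simulate_complete <- function(config, seed = config$master_seed) {
  lat <- draw_latent(config, seed)
  V <- config$schedule$n_visits
  n <- length(lat$baseline)
  y <- maybe_round(clip01_60(lat$latent), config)
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    arm = lat$arm,
    baseline = maybe_round(clip01_60(lat$baseline), config),
    disc_reason = "none", disc_visit = NA_integer_,
    stringsAsFactors = FALSE)
  ds <- trial_dataset(subjects, y, config$schedule, config$arms[1L],
                      validate = FALSE)
  truth <- structure(list(
    config = config, seed = seed, arm = lat$arm, baseline = subjects$baseline,
    latent = lat$latent, b = lat$b, e = lat$e,
    hypothetical = y, policy = y,
    ie_visit = rep(NA_integer_, n), ie_reason = rep("none", n)),
    class = "truth_record")
  list(dataset = ds, truth = truth)
}

hazard_prob <- function(reason_spec, arm, visit, score, config) {
  ic <- reason_spec$intercept
  a0 <- if (length(ic) > 1L) {
    key <- if (as.character(arm) %in% names(ic)) as.character(arm)
           else if (arm == config$arms[1L]) names(ic)[1L] else names(ic)[2L]
    ic[[key]]
  } else ic[[1L]]
  vis_ok <- is.null(reason_spec$visits) || visit %in% reason_spec$visits
  if (!vis_ok) return(0)
  stats::plogis(a0 + (reason_spec$score_coef %||% 0) *
                  (score - config$score_center))
}

#' Apply intercurrent events and missingness to complete data
#'
#' Draws reason-specific treatment discontinuation from discrete-time
#' logistic hazards evaluated on the current latent score (LoE risk rises
#' with a worse score; AE risk is restricted to an early window); the first
#' triggered reason fixes the discontinuation visit and blanks all later
#' outcomes.  Independent intermittent (MCAR) blanking is then applied to
#' remaining observed cells.  Treatment-policy potential outcomes after the
#' event follow `config$post_ie_mechanism`.
#'
#' @param complete The list returned by [simulate_complete()].
#' @param config The same [sim_config()].
#' @param seed Integer seed (defaults to `config$master_seed`).
#' @return A list: `dataset` (with missingness) and `truth` (complete
#'   `truth_record` with both potential-outcome matrices).
#' @export
apply_intercurrent_events <- function(complete, config,
                                      seed = config$master_seed) {
  ds <- complete$dataset; truth <- complete$truth
  V <- config$schedule$n_visits
  n <- n_subjects(ds)
  arm <- truth$arm
  reasons <- names(config$dropout_model)
  ie_visit <- rep(NA_integer_, n)
  ie_reason <- rep("none", n)
  udrop <- with_seed(stream_seed(seed, "dropout"),
                     matrix(stats::runif(n * (V) * length(reasons)),
                            nrow = n))
  for (i in seq_len(n)) {
    k <- 0L
    for (j in seq_len(max(V - 1L, 1L))) {
      hit <- FALSE
      for (r in seq_along(reasons)) {
        k <- (j - 1L) * length(reasons) + r
        p <- hazard_prob(config$dropout_model[[r]], arm[i], j,
                         truth$latent[i, j], config)
        if (p > 0 && udrop[i, k] < p) {
          ie_visit[i] <- j; ie_reason[i] <- reasons[r]; hit <- TRUE
          break
        }
      }
      if (hit) break
    }
  }
  # treatment-policy potential outcomes after the event
  policy_latent <- truth$latent
  ref <- config$arms[1L]
  for (i in which(!is.na(ie_visit))) {
    d <- ie_visit[i]
    if (d >= V) next
    post <- (d + 1L):V
    policy_latent[i, post] <- switch(
      config$post_ie_mechanism,
      MAR_CONTINUATION = truth$latent[i, post],
      J2R_SWITCH = config$arm_visit_means[ref, post] +
        config$baseline_coef * (truth$baseline[i] - config$baseline_mean) +
        truth$b[i] + truth$e[i, post],
      RETAINED_SLOPE = {
        own_fix <- config$arm_visit_means[as.character(arm[i]), ] +
          config$baseline_coef * (truth$baseline[i] - config$baseline_mean)
        own_fix[post] + (truth$latent[i, d] - own_fix[d])
      })
  }
  policy <- maybe_round(clip01_60(policy_latent), config)
  y <- policy
  for (i in which(!is.na(ie_visit)))
    if (ie_visit[i] < V) y[i, (ie_visit[i] + 1L):V] <- NA_real_
  if (config$intermittent_prob > 0) {
    uint <- with_seed(stream_seed(seed, "intermittent"),
                      matrix(stats::runif(n * V), n, V))
    y[!is.na(y) & uint < config$intermittent_prob] <- NA_real_
  }
  subjects <- ds$subjects
  subjects$disc_reason <- ie_reason
  subjects$disc_visit <- ie_visit
  out_ds <- trial_dataset(subjects, y, config$schedule, ref,
                          validate = FALSE)
  truth$policy <- policy
  truth$ie_visit <- ie_visit
  truth$ie_reason <- ie_reason
  list(dataset = out_ds, truth = truth)
}

#' Simulate a full synthetic trial
#'
#' Convenience wrapper: [simulate_complete()] then
#' [apply_intercurrent_events()] under one master seed.
#'
#' @inheritParams simulate_complete
#' @return A list: `dataset`, `truth`.
#' @export
simulate_trial <- function(config, seed = config$master_seed) {
  apply_intercurrent_events(simulate_complete(config, seed), config, seed)
}

#' True estimand value from a truth record
#'
#' Finite-sample mean contrast (arm minus reference, points MADRS10,
#' negative favours the experimental arm) at the last scheduled visit,
#' computed from the relevant potential-outcome matrix: `"HYPOTHETICAL"`
#' (no-event world), `"TREATMENT_POLICY"` (configured post-event
#' mechanism), `"WHILE_ON_TREATMENT"` (last on-treatment value), or
#' `"PRINCIPAL_STRATUM"` (subjects without an event under their own
#' assignment).
#'
#' @param truth A `truth_record`.
#' @param estimand One of the four labels above.
#' @param arm Experimental arm (default: first non-reference arm).
#' @return The true contrast in points.
#' @export
true_estimand_value <- function(truth,
                                estimand = c("HYPOTHETICAL",
                                             "TREATMENT_POLICY",
                                             "WHILE_ON_TREATMENT",
                                             "PRINCIPAL_STRATUM"),
                                arm = NULL) {
  estimand <- match.arg(estimand)
  cfg <- truth$config
  arms <- cfg$arms
  arm <- arm %||% arms[2L]
  V <- cfg$schedule$n_visits
  is_arm <- truth$arm == arm
  is_ref <- truth$arm == arms[1L]
  pick_last <- function(mat, sel) mean(mat[sel, V])
  switch(estimand,
    HYPOTHETICAL = pick_last(truth$hypothetical, is_arm) -
      pick_last(truth$hypothetical, is_ref),
    TREATMENT_POLICY = pick_last(truth$policy, is_arm) -
      pick_last(truth$policy, is_ref),
    WHILE_ON_TREATMENT = {
      last_on <- ifelse(is.na(truth$ie_visit), V,
                        pmin(truth$ie_visit, V))
      v <- truth$hypothetical[cbind(seq_along(last_on), last_on)]
      mean(v[is_arm]) - mean(v[is_ref])
    },
    PRINCIPAL_STRATUM = {
      keep <- is.na(truth$ie_visit)
      if (!any(keep & is_arm) || !any(keep & is_ref))
        stop("principal stratum empty in one arm")
      pick_last(truth$hypothetical, keep & is_arm) -
        pick_last(truth$hypothetical, keep & is_ref)
    })
}

#' Write a truth record sidecar CSV
#'
#' Long format: subject, visit, hypothetical and treatment-policy potential
#' outcomes, event visit and reason.
#'
#' @param truth A `truth_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  n <- length(truth$baseline); V <- truth$config$schedule$n_visits
  long <- data.frame(
    subject = rep(seq_len(n), each = V),
    visit = rep.int(seq_len(V), n),
    hypothetical = as.vector(t(truth$hypothetical)),
    policy = as.vector(t(truth$policy)),
    ie_visit = rep(truth$ie_visit, each = V),
    ie_reason = rep(truth$ie_reason, each = V))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}
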