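#' Visit schedule for a longitudinal trial
#'
#' Post-baseline visits are indexed 1..V; baseline is a separate
#' measurement and never part of the outcome vector.
#'
#' @param n_visits Number of post-baseline visits (V >= 2).
#' @param weeks Week number of each visit; strictly increasing, length V.
#' @return An object of class `visit_schedule`.
#' @export
visit_schedule <- function(n_visits, weeks = seq_len(n_visits)) {
  n_visits <- as.integer(n_visits)
  if (length(n_visits) != 1L || is.na(n_visits) || n_visits < 2L)
    stop("`n_visits` must be a single integer >= 2")
  weeks <- as.numeric(weeks)
  if (length(weeks) != n_visits || any(diff(weeks) <= 0))
    stop("`weeks` must have length n_visits and be strictly increasing")
  structure(list(n_visits = n_visits, last_visit = n_visits, weeks = weeks),
            class = "visit_schedule")
}

#' Construct a longitudinal trial dataset
#'
#' The container used by every estimator in the package: one row per subject
#' in `subjects`, an n x V outcome matrix (`NA` = missing), and a visit
#' schedule.  MADRS10 scores lie in \[0, 60\] (lower = less severe
#' depression).  A recorded discontinuation at visit d implies a monotone
#' missing tail: outcomes at visits d+1..V are all `NA`.
#'
#' @param subjects Data frame with columns `subject_id`, `arm`, `baseline`,
#'   `disc_reason` (`"none"` if no discontinuation), `disc_visit`
#'   (`NA` if none).
#' @param outcomes Numeric matrix, subjects x visits, `NA` for missing.
#' @param schedule A [visit_schedule()].
#' @param reference_arm Arm label used as the comparator (placebo).
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(subjects, outcomes, schedule, reference_arm,
                          validate = TRUE) {
  stopifnot(inherits(schedule, "visit_schedule"))
  subjects <- as.data.frame(subjects)
  outcomes <- as.matrix(outcomes)
  storage.mode(outcomes) <- "double"
  dimnames(outcomes) <- NULL
  arms <- unique(as.character(subjects$arm))
  if (!reference_arm %in% arms && nrow(subjects) > 0)
    stop("reference_arm '", reference_arm, "' not present in data")
  subjects$arm <- factor(as.character(subjects$arm),
                         levels = c(reference_arm, setdiff(arms, reference_arm)))
  subjects$subject_id <- as.character(subjects$subject_id)
  if (is.null(subjects$disc_reason)) subjects$disc_reason <- "none"
  if (is.null(subjects$disc_visit)) subjects$disc_visit <- NA_integer_
  subjects$disc_visit <- as.integer(subjects$disc_visit)
  x <- structure(list(schedule = schedule, subjects = subjects,
                      outcomes = outcomes, reference_arm = reference_arm),
                 class = "trial_dataset")
  if (validate) validate_trial_dataset(x)
  x
}

#' Validate a trial dataset's invariants
#'
#' Checks score bounds, outcome dimensions, non-missing baselines, and the
#' monotone-tail convention (no observed outcome after the recorded
#' discontinuation visit).
#'
#' @param x A `trial_dataset`.
#' @param require_two_arms Require at least two arms (default `TRUE`).
#' @return `x`, invisibly; errors name the offending subject.
#' @export
validate_trial_dataset <- function(x, require_two_arms = TRUE) {
  s <- x$subjects; y <- x$outcomes; V <- x$schedule$n_visits
  if (nrow(s) != nrow(y))
    stop("subjects and outcomes disagree on the number of subjects")
  if (nrow(s) == 0L) return(invisible(x))
  if (ncol(y) != V)
    stop("outcomes must have one column per scheduled visit (V = ", V, ")")
  if (anyDuplicated(s$subject_id))
    stop("duplicated subject_id values")
  if (require_two_arms && nlevels(droplevels(s$arm)) < 2L)
    stop("dataset must contain at least two arms")
  if (anyNA(s$baseline))
    stop("missing baseline for subject(s): ",
         paste(s$subject_id[is.na(s$baseline)], collapse = ", "))
  bad <- which(s$baseline < 0 | s$baseline > 60)
  if (length(bad))
    stop("baseline outside [0, 60] for subject ", s$subject_id[bad[1L]])
  obs <- !is.na(y)
  out_of_range <- obs & (y < 0 | y > 60)
  if (any(out_of_range)) {
    i <- which(rowSums(out_of_range) > 0)[1L]
    j <- which(out_of_range[i, ])[1L]
    stop("score outside [0, 60] for subject ", s$subject_id[i],
         " at visit ", j, " (score = ", y[i, j], ")")
  }
  d <- s$disc_visit
  for (i in seq_len(nrow(s))) {
    if (!is.na(d[i]) && d[i] < V && any(obs[i, (d[i] + 1L):V]))
      stop("subject ", s$subject_id[i], ": outcome observed after ",
           "discontinuation visit ", d[i], " (monotone-tail violation)")
  }
  invisible(x)
}

n_subjects <- function(x) nrow(x$subjects)

arm_levels <- function(x) levels(x$subjects$arm)

# non-reference arms, in level order
active_arms <- function(x) setdiff(arm_levels(x), x$reference_arm)

subset_trial <- function(x, idx) {
  trial_dataset(x$subjects[idx, , drop = FALSE],
                x$outcomes[idx, , drop = FALSE],
                x$schedule, x$reference_arm, validate = FALSE)
}

#' Read a long-format trial CSV
#'
#' Expects columns `subject_id`, `arm`, `baseline`, `visit`, `score`,
#' `disc_reason`, `disc_visit`; one row per subject-visit, empty `score` =
#' missing.  Rows for a subject must cover all scheduled visits.
#'
#' @param path File path.
#' @param reference_arm Comparator arm label.
#' @return A validated [trial_dataset()].
#' @export
read_trial_csv <- function(path, reference_arm) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = list(subject_id = "character"))
  need <- c("subject_id", "arm", "baseline", "visit", "score",
            "disc_reason", "disc_visit")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    sch <- visit_schedule(2L)
    return(trial_dataset(
      data.frame(subject_id = character(), arm = character(),
                 baseline = numeric(), disc_reason = character(),
                 disc_visit = integer()),
      matrix(numeric(), 0L, 2L), sch, reference_arm, validate = FALSE))
  }
  V <- max(raw$visit)
  ids <- unique(raw$subject_id)
  sub_rows <- split(seq_len(nrow(raw)), factor(raw$subject_id, levels = ids))
  y <- matrix(NA_real_, length(ids), V)
  subj <- data.frame(subject_id = ids, arm = NA_character_,
                     baseline = NA_real_, disc_reason = NA_character_,
                     disc_visit = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    rows <- raw[sub_rows[[k]], ]
    if (!setequal(rows$visit, seq_len(V)))
      stop("subject ", ids[k], ": rows do not cover all scheduled visits 1..",
           V)
    rows <- rows[order(rows$visit), ]
    y[k, ] <- ifelse(is.na(rows$score) | rows$score == "", NA_real_,
                     suppressWarnings(as.numeric(rows$score)))
    subj$arm[k] <- as.character(rows$arm[1L])
    subj$baseline[k] <- rows$baseline[1L]
    subj$disc_reason[k] <- as.character(rows$disc_reason[1L])
    dv <- rows$disc_visit[1L]
    subj$disc_visit[k] <- if (is.na(dv) || dv == "") NA_integer_
                          else as.integer(dv)
  }
  subj$disc_reason[is.na(subj$disc_reason) | subj$disc_reason == ""] <- "none"
  sch <- visit_schedule(V)
  validate_trial_dataset(
    trial_dataset(subj, y, sch, reference_arm, validate = FALSE))
}

#' Write a trial dataset as a long-format CSV
#'
#' Inverse of [read_trial_csv()]: `read_trial_csv(write_trial_csv(d))`
#' reproduces `d` exactly (scores round-trip bit-exactly; rows ordered by
#' subject then visit).
#'
#' @param dataset A `trial_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  s <- dataset$subjects; y <- dataset$outcomes
  V <- dataset$schedule$n_visits; n <- nrow(s)
  fmt_score <- function(v) {
    ifelse(is.na(v), "",
           ifelse(v == round(v), sprintf("%d", as.integer(round(v))),
                  sprintf("%.17g", v)))
  }
  long <- data.frame(
    subject_id = rep(s$subject_id, each = V),
    arm = rep(as.character(s$arm), each = V),
    baseline = rep(s$baseline, each = V),
    visit = rep.int(seq_len(V), n),
    score = fmt_score(as.vector(t(y))),
    disc_reason = rep(s$disc_reason, each = V),
    disc_visit = rep(s$disc_visit, each = V),
    stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Classify a subject's missingness pattern
#'
#' Three dropout patterns partition classifiable subjects, driven only by
#' the length of the trailing run of missing post-baseline outcomes:
#' completers/quasicompleters (last visit observed, or only the last visit
#' missing; earlier visits may be intermittently missing), late dropout
#' (monotone missing tail of exactly the last two visits), and early
#' dropout (monotone tail of three or more visits, i.e. starting by
#' mid-trial).  An all-missing vector is unclassifiable.
#'
#' @param mask Logical (or 0/1) vector of length V; `TRUE` = observed.
#' @return One of `"COMPLETER_QUASI"`, `"LATE_DROPOUT"`, `"EARLY_DROPOUT"`,
#'   `"UNCLASSIFIABLE"`.
#' @export
classify_pattern <- function(mask) {
  obs <- as.logical(mask)
  if (anyNA(obs)) stop("mask must not contain NA")
  V <- length(obs)
  if (V < 3L) stop("patterns are defined for schedules with V >= 3")
  r <- trailing_missing_run(obs)
  if (r == V) return("UNCLASSIFIABLE")
  if (r <= 1L) return("COMPLETER_QUASI")
  if (r == 2L) return("LATE_DROPOUT")
  "EARLY_DROPOUT"
}

pattern_levels <- c("COMPLETER_QUASI", "LATE_DROPOUT", "EARLY_DROPOUT")

# per-subject pattern labels for a dataset (vector, may contain
# "UNCLASSIFIABLE")
dataset_patterns <- function(dataset) {
  apply(!is.na(dataset$outcomes), 1L, classify_pattern)
}

#' Summarise missing data in a trial
#'
#' @param dataset A `trial_dataset`.
#' @return A list with the subjects x visits observation mask, per-arm
#'   per-visit observed/missing counts, and the trial-level missing
#'   fraction, of class `missingness_summary`.
#' @export
missingness_summary <- function(dataset) {
  mask <- !is.na(dataset$outcomes)
  rownames(mask) <- dataset$subjects$subject_id
  arm <- droplevels(dataset$subjects$arm)
  per_arm <- lapply(levels(arm), function(a) {
    m <- mask[arm == a, , drop = FALSE]
    rbind(observed = colSums(m), missing = colSums(!m))
  })
  names(per_arm) <- levels(arm)
  structure(list(
    mask = mask,
    per_arm_visit = per_arm,
    n_per_arm = table(arm),
    missing_fraction = if (length(mask)) mean(!mask) else 0
  ), class = "missingness_summary")
}

#' Tabulate intercurrent events (treatment discontinuations) by arm
#'
#' Counts and percentages of discontinuation reasons per arm; percentages
#' are taken against the randomized N of the whole trial, the convention
#' used when reporting discontinuation burden.  Reasons with zero count are
#' kept as structural zeros.
#'
#' @param dataset A `trial_dataset`.
#' @return A data frame: arm, reason, n, pct (of trial N), plus attribute
#'   `trial_n`.
#' @export
ie_table <- function(dataset) {
  s <- dataset$subjects
  N <- nrow(s)
  canonical <- c("AE", "AE+LoE", "drug_unrelated", "LoE", "unknown",
                 "efficacy", "insufficient_compliance")
  present <- setdiff(unique(s$disc_reason), "none")
  reasons <- union(canonical, present)
  arm <- droplevels(s$arm)
  out <- expand.grid(arm = levels(arm), reason = reasons,
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(a, r) sum(arm == a & s$disc_reason == r),
                  out$arm, out$reason)
  out$pct <- if (N > 0) round(100 * out$n / N, 1) else 0
  attr(out, "trial_n") <- N
  out
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("trial_dataset:", n_subjects(x), "subjects,",
      x$schedule$n_visits, "post-baseline visits\n")
  cat("arms:", paste(arm_levels(x), collapse = ", "),
      "(reference:", x$reference_arm, ")\n")
  ms <- missingness_summary(x)
  cat(sprintf("missing outcome cells: %.1f%%\n", 100 * ms$missing_fraction))
  invisible(x)
}
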