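#' Default biomarker frequency table for simulated tumors
#'
#' Gene x alteration-class sampling weights emulating a mixed solid-tumor
#' case series: a handful of clinically actionable markers (hormone-receptor
#' expression, PTEN loss, mTOR-pathway activation, ERBB2 amplification)
#' against a background of common but -- under the bundled calibration
#' knowledge base -- non-actionable passenger events. Weights are relative
#' sampling probabilities, not population frequencies.
#'
#' @return data.frame with columns `gene`, `alteration_class`, `weight`.
#' @export
default_alteration_pool <- function() {
  data.frame(
    gene = c("ER", "PR", "PTEN", "MTOR", "ERBB2",
             "TP53", "KRAS", "MYC", "CCND1", "FGFR1",
             "PRKDC", "CDKN2A", "APC", "EGFR", "BRAF", "RB1"),
    alteration_class = c("expression_positive", "expression_positive",
                         "copy_loss", "mutation_activating", "amplification",
                         "mutation_loss", "mutation_activating",
                         "amplification", "amplification", "amplification",
                         "amplification", "copy_loss", "mutation_loss",
                         "expression_high", "mutation_activating",
                         "copy_loss"),
    weight = c(0.45, 0.35, 0.30, 0.15, 0.20,
               0.50, 0.30, 0.25, 0.30, 0.20,
               0.10, 0.20, 0.20, 0.15, 0.20, 0.15),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic exceptional-responder cohort
#'
#' Describes the statistical shape of the simulated case series: cohort
#' size, a zero-truncated geometric number of treatment lines per patient
#' (mean 3, right-censored at 14), a shifted-Poisson number of pathogenic
#' alterations per tumor (mean 4, at least 1), a biomarker frequency table,
#' and a logistic score-outcome model
#' `P(success) = plogis(intercept + slope * score / 100)`.
#' The default slope is calibrated (see [calibrate_outcome_model()]) so the
#' simulated cohorts reproduce a score-outcome discrimination of AUC about
#' 0.85; the intercept places the class-conditional crossing point -- and
#' hence the Youden-optimal operating threshold -- near a matching score of
#' 25%, with an unmatched (score 0) regimen succeeding about 4% of the
#' time. An exceptional-responder series is enriched for molecularly guided
#' therapy, so by default 80% of treatment lines draw preferentially from
#' drugs with a rule matching the tumor.
#'
#' @param n_patients number of simulated patients.
#' @param mean_lines mean treatment lines per patient (geometric, >= 1).
#' @param max_lines right-censoring bound on lines per patient.
#' @param mean_alterations mean pathogenic alterations per tumor (>= 1).
#' @param max_alterations right-censoring bound on alterations per tumor.
#' @param alteration_pool data.frame `gene`, `alteration_class`, `weight`.
#' @param single_agent_prob,two_drug_prob probability that a treatment line
#'   uses one resp. two drugs (the remainder uses three).
#' @param targeted_line_prob probability that a line is drawn
#'   preferentially from drugs with a rule matching the tumor (emulating
#'   molecularly guided therapy); the remainder are drawn uniformly.
#' @param targeted_weight sampling weight multiplier for matching drugs
#'   within a targeted line.
#' @param outcome_intercept,outcome_slope logistic outcome-model
#'   coefficients on the score/100 scale.
#' @param seed integer seed; a fixed seed makes [generate_cohort()] output
#'   byte-identical.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 70, mean_lines = 3, max_lines = 14,
                        mean_alterations = 4, max_alterations = 8,
                        alteration_pool = default_alteration_pool(),
                        single_agent_prob = 0.55, two_drug_prob = 0.30,
                        targeted_line_prob = 0.8, targeted_weight = 25,
                        outcome_intercept = -3.2, outcome_slope = 9.375,
                        seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (mean_lines < 1 || mean_alterations < 1)
    stop("mean_lines and mean_alterations must be >= 1", call. = FALSE)
  if (nrow(alteration_pool) == 0)
    stop("alteration_pool must be non-empty", call. = FALSE)
  if (!all(alteration_pool$alteration_class %in% .ALTERATION_CLASSES))
    stop("alteration_pool contains unknown alteration classes", call. = FALSE)
  if (any(alteration_pool$weight <= 0))
    stop("alteration_pool weights must be positive", call. = FALSE)
  if (single_agent_prob < 0 || two_drug_prob < 0 ||
        single_agent_prob + two_drug_prob > 1)
    stop("drug-count probabilities must be a sub-distribution", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 mean_lines = mean_lines, max_lines = as.integer(max_lines),
                 mean_alterations = mean_alterations,
                 max_alterations = as.integer(max_alterations),
                 alteration_pool = alteration_pool,
                 single_agent_prob = single_agent_prob,
                 two_drug_prob = two_drug_prob,
                 targeted_line_prob = targeted_line_prob,
                 targeted_weight = targeted_weight,
                 outcome_intercept = outcome_intercept,
                 outcome_slope = outcome_slope,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Sample a response class and TTF consistent with a drawn success label,
# mirroring the observed category mix: successful lines are complete
# responses (1/3) or partial responses / durable stabilizations (2/3);
# unsuccessful lines split 40/60 between 6-12-month stabilization and
# progression or short stabilization.
.sample_response <- function(success) {
  if (success) {
    u <- stats::runif(1)
    if (u < 0.33) list(response = "CR", ttf = 12 + stats::rgamma(1, 2, 0.2))
    else if (u < 0.80) list(response = "PR", ttf = stats::rgamma(1, 3, 0.25))
    else list(response = "SD", ttf = 12 + stats::rexp(1, 1 / 6))
  } else {
    u <- stats::runif(1)
    if (u < 0.40) list(response = "SD", ttf = stats::runif(1, 6, 11.9))
    else if (u < 0.88) list(response = "PD", ttf = stats::rexp(1, 1 / 3))
    else list(response = "SD", ttf = stats::runif(1, 0, 5.9))
  }
}

#' Generate a synthetic cohort of profiles and treatment records
#'
#' Simulates `n_patients` tumors from the biomarker frequency table, draws
#' each patient's treatment lines (a mix of molecularly guided and
#' unguided regimens over the knowledge-base drugs), scores every line
#' through [matching_score()], and samples its outcome from the logistic
#' score-outcome model. All randomness flows from `spec$seed` through a
#' single generator stream; a fixed seed reproduces the cohort exactly.
#'
#' @param spec a [cohort_spec()].
#' @param kb a `knowledge_base` (default: the bundled calibration KB).
#' @param config a [scoring_config()].
#' @return list with `profiles` (named list of [patient_profile()]) and
#'   `records` (data.frame: `patient_id`, `regimen`, `response`,
#'   `ttf_months`, `score_percent`).
#' @export
generate_cohort <- function(spec, kb = calibration_kb(),
                            config = scoring_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  pool <- spec$alteration_pool
  set.seed(spec$seed)
  drugs <- kb$drugs$drug_id
  n_drugs <- length(drugs)
  if (n_drugs < 3) stop("knowledge base must hold at least 3 drugs", call. = FALSE)
  # Per-drug actionable genes (non-resistance rules) for targeted sampling.
  active_rules <- kb$rules[kb$rules$match_type != "resistance", , drop = FALSE]
  rule_key <- paste(active_rules$drug_id, active_rules$gene,
                    active_rules$alteration_class)
  profiles <- vector("list", spec$n_patients)
  recs <- list()
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("SYN%03d", i)
    n_alt <- min(nrow(pool), spec$max_alterations,
                 1 + stats::rpois(1, spec$mean_alterations - 1))
    rows <- sample.int(nrow(pool), n_alt, prob = pool$weight)
    prof <- patient_profile(
      pid,
      data.frame(gene = pool$gene[rows],
                 alteration_class = pool$alteration_class[rows],
                 pathogenic = TRUE, detail = "synthetic",
                 stringsAsFactors = FALSE),
      diagnosis = "synthetic solid tumor")
    profiles[[i]] <- prof
    bio <- scoreable_biomarkers(prof)
    matches_tumor <- vapply(drugs, function(d)
      any(paste(d, bio$gene, bio$alteration_class) %in% rule_key), logical(1))
    n_lines <- min(stats::rgeom(1, 1 / spec$mean_lines) + 1, spec$max_lines)
    for (l in seq_len(n_lines)) {
      k <- sample.int(3, 1, prob = c(spec$single_agent_prob,
                                     spec$two_drug_prob,
                                     1 - spec$single_agent_prob - spec$two_drug_prob))
      targeted <- stats::runif(1) < spec$targeted_line_prob
      w <- if (targeted) 1 + (spec$targeted_weight - 1) * matches_tumor
           else rep(1, n_drugs)
      ids <- drugs[sample.int(n_drugs, k, prob = w)]
      score <- matching_score(regimen(ids), prof, kb, config)$score_percent
      p_succ <- stats::plogis(spec$outcome_intercept +
                                spec$outcome_slope * score / 100)
      rr <- .sample_response(stats::runif(1) < p_succ)
      recs[[length(recs) + 1]] <- data.frame(
        patient_id = pid, regimen = paste(sort(ids), collapse = "+"),
        response = rr$response, ttf_months = round(rr$ttf, 1),
        score_percent = score, stringsAsFactors = FALSE)
    }
  }
  names(profiles) <- vapply(profiles, `[[`, character(1), "patient_id")
  list(profiles = profiles, records = do.call(rbind, recs))
}

#' Calibrate the outcome-model slope to a target AUC
#'
#' Finds the logistic slope `b` such that the mean simulated score-outcome
#' AUC over `n_reps` cohorts hits the target. Candidate slopes are assessed
#' on cohorts generated from seeds `seed + 1 .. seed + n_reps`; because the
#' same seeds (hence the same tumors, regimens and scores) are reused for
#' every candidate, the mean AUC is monotone in `b` up to the outcome
#' draws and a bisection search converges. Deterministic given `seed`.
#'
#' @param spec a [cohort_spec()]; its `outcome_slope` is ignored.
#' @param kb a `knowledge_base`.
#' @param target_auc desired mean AUC, in (0.5, 1) (0.5 returns slope 0).
#' @param n_reps cohorts per candidate slope.
#' @param seed base seed for the evaluation cohorts.
#' @param tol acceptable |mean AUC - target|.
#' @param b_max upper end of the search interval.
#' @param max_iter bisection iterations.
#' @return list with `slope`, `mean_auc`, `n_reps`.
#' @export
calibrate_outcome_model <- function(spec, kb = calibration_kb(),
                                    target_auc = 0.85, n_reps = 10,
                                    seed = 1000L, tol = 0.02,
                                    b_max = 30, max_iter = 25) {
  if (target_auc < 0.5 || target_auc >= 1)
    stop("target_auc must lie in [0.5, 1)", call. = FALSE)
  if (target_auc == 0.5)
    return(list(slope = 0, mean_auc = 0.5, n_reps = n_reps))
  mean_auc <- function(b) {
    aucs <- vapply(seq_len(n_reps), function(r) {
      s <- spec
      s$outcome_slope <- b
      s$seed <- as.integer(seed + r)
      g <- generate_cohort(s, kb)
      labels <- classify_outcome(g$records$response, g$records$ttf_months)
      if (length(unique(labels)) < 2) return(NA_real_)
      roc_and_auc(g$records$score_percent, labels)$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  hi <- mean_auc(b_max)
  if (hi < target_auc - tol)
    stop(sprintf(paste0("target AUC %.2f unreachable: the score distribution ",
                        "only supports a mean AUC of %.3f at slope %.1f"),
                 target_auc, hi, b_max), call. = FALSE)
  lo_b <- 0; hi_b <- b_max
  best <- list(slope = b_max, mean_auc = hi)
  for (it in seq_len(max_iter)) {
    mid <- (lo_b + hi_b) / 2
    a <- mean_auc(mid)
    if (abs(a - target_auc) < abs(best$mean_auc - target_auc))
      best <- list(slope = mid, mean_auc = a)
    if (abs(a - target_auc) <= tol) break
    if (a < target_auc) lo_b <- mid else hi_b <- mid
  }
  if (abs(best$mean_auc - target_auc) > tol)
    stop(sprintf("calibration did not reach target %.2f (best mean AUC %.3f at slope %.2f)",
                 target_auc, best$mean_auc, best$slope), call. = FALSE)
  list(slope = best$slope, mean_auc = best$mean_auc, n_reps = n_reps)
}

#' Write a generated cohort to disk
#'
#' Emits `profiles.tsv`, `patients.tsv` and `cohort.tsv` in the package's
#' TSV dialects, suitable for [load_profiles()] and [load_cohort()].
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prof_rows <- do.call(rbind, lapply(cohort$profiles, function(p)
    cbind(patient_id = p$patient_id, p$alterations)))
  .write_tsv(prof_rows, file.path(dir, "profiles.tsv"))
  meta <- do.call(rbind, lapply(cohort$profiles, function(p)
    data.frame(patient_id = p$patient_id, diagnosis = p$diagnosis,
               age_years = p$age_years, age_class = p$age_class,
               stringsAsFactors = FALSE)))
  .write_tsv(meta, file.path(dir, "patients.tsv"))
  .write_tsv(cohort$records, file.path(dir, "cohort.tsv"))
  invisible(dir)
}
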