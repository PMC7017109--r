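#' Classify treatment outcomes as successful or unsuccessful
#'
#' A regimen counts as a therapeutic success when it produced a complete or
#' partial response (any duration) or stable disease lasting at least 12
#' months; every other outcome (progressive disease, or stable disease
#' shorter than 12 months) is unsuccessful.
#'
#' @param response character vector of RECIST classes (`CR`, `PR`, `SD`,
#'   `PD`), or a data.frame with columns `response` and `ttf_months`.
#' @param ttf_months time to treatment failure in months (ignored for
#'   `CR`/`PR`/`PD`).
#' @return character vector, `"successful"` or `"unsuccessful"`.
#' @export
#' @examples
#' classify_outcome("PR", 11)   # successful: response, regardless of TTF
#' classify_outcome("SD", 8)    # unsuccessful: stable disease under 12 months
#' classify_outcome("SD", 12)   # successful: boundary is >= 12 months
classify_outcome <- function(response, ttf_months = NULL) {
  if (is.data.frame(response)) {
    ttf_months <- response$ttf_months
    response <- response$response
  }
  if (!all(response %in% .RESPONSE_CLASSES))
    stop(sprintf("unknown response class '%s'",
                 setdiff(response, .RESPONSE_CLASSES)[1]), call. = FALSE)
  if (is.null(ttf_months)) ttf_months <- rep(NA_real_, length(response))
  ttf_months <- as.numeric(ttf_months)
  if (any(response == "SD" & is.na(ttf_months)))
    stop("stable disease requires ttf_months to be classified", call. = FALSE)
  ifelse(response %in% c("CR", "PR") |
           (response == "SD" & !is.na(ttf_months) & ttf_months >= 12),
         "successful", "unsuccessful")
}

#' Tabulate a treatment cohort by response category and outcome label
#'
#' @param records data.frame with columns `response` and `ttf_months`.
#' @return list with `categories` (named counts: `complete_response`,
#'   `partial_response_or_sd_ge12`, `sd_6_to_12`, `pd_or_sd_lt6`), `labels`
#'   (counts of `successful` / `unsuccessful`) and `n`. Category counts sum
#'   to `n`; label counts are the sums of their categories.
#' @export
summarize_outcomes <- function(records) {
  resp <- records$response
  ttf <- as.numeric(records$ttf_months)
  if (!all(resp %in% .RESPONSE_CLASSES))
    stop("unknown response class in records", call. = FALSE)
  cr <- resp == "CR"
  pr_sd12 <- resp == "PR" | (resp == "SD" & ttf >= 12)
  sd612 <- resp == "SD" & ttf >= 6 & ttf < 12
  pd_sdlt6 <- resp == "PD" | (resp == "SD" & ttf < 6)
  categories <- c(complete_response = sum(cr),
                  partial_response_or_sd_ge12 = sum(pr_sd12),
                  sd_6_to_12 = sum(sd612),
                  pd_or_sd_lt6 = sum(pd_sdlt6))
  labels <- c(successful = sum(cr) + sum(pr_sd12),
              unsuccessful = sum(sd612) + sum(pd_sdlt6))
  list(categories = categories, labels = labels, n = nrow(records))
}

.as_success_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (!all(labels %in% c("successful", "unsuccessful")))
    stop("labels must be 'successful'/'unsuccessful' (or logical)", call. = FALSE)
  labels == "successful"
}

#' Confusion matrix of the score at a threshold
#'
#' A record is predicted favorable when its score strictly exceeds the
#' threshold (`score > threshold`); with integer percentage scores and the
#' conventional 25% cut this keeps a score of exactly 25 on the unfavorable
#' side. Set `strict = FALSE` for a `>=` rule.
#'
#' @param scores numeric vector of matching scores (percent).
#' @param labels outcome labels (`"successful"`/`"unsuccessful"` or logical
#'   success indicator), same length as `scores`.
#' @param threshold_percent decision threshold.
#' @param strict use `>` (default) rather than `>=`.
#' @return An object of class `confusion_matrix`: `tp`, `fp`, `fn`, `tn`,
#'   `threshold_percent`. `tp + fp + fn + tn == length(scores)`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold_percent,
                                   strict = TRUE) {
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length", call. = FALSE)
  pos <- .as_success_logical(labels)
  pred <- if (strict) scores > threshold_percent else scores >= threshold_percent
  structure(list(tp = sum(pred & pos), fp = sum(pred & !pos),
                 fn = sum(!pred & pos), tn = sum(!pred & !pos),
                 threshold_percent = threshold_percent),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @param threshold_percent threshold annotation (default `NA`).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fp, fn, tn, threshold_percent = NA_real_) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 threshold_percent = threshold_percent),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix @ %s%%: tp=%d fp=%d fn=%d tn=%d>\n",
              format(x$threshold_percent), x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

.metric_with_ci <- function(x, n, conf_level) {
  if (n == 0)
    return(list(estimate = NA_real_, percent = NA_integer_,
                ci_lower = NA_real_, ci_upper = NA_real_,
                ci_lower_percent = NA_integer_, ci_upper_percent = NA_integer_,
                defined = FALSE, x = x, n = n))
  ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
  list(estimate = x / n, percent = round_half_up(100 * x / n),
       ci_lower = ci[1], ci_upper = ci[2],
       ci_lower_percent = round_half_up(100 * ci[1]),
       ci_upper_percent = round_half_up(100 * ci[2]),
       defined = TRUE, x = x, n = n)
}

#' Diagnostic performance indices with exact binomial confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each with
#' a Clopper-Pearson (exact binomial) confidence interval and half-up
#' integer percentages. A zero denominator yields a flagged undefined
#' metric (`defined = FALSE`) rather than `NaN`.
#'
#' @param cm a `confusion_matrix`.
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `performance_metrics` with elements
#'   `sensitivity`, `specificity`, `ppv`, `npv` (each: `estimate`,
#'   `percent`, `ci_lower`, `ci_upper`, `ci_lower_percent`,
#'   `ci_upper_percent`, `defined`) and the input `cm`.
#' @export
performance_metrics <- function(cm, conf_level = 0.95) {
  out <- list(
    sensitivity = .metric_with_ci(cm$tp, cm$tp + cm$fn, conf_level),
    specificity = .metric_with_ci(cm$tn, cm$tn + cm$fp, conf_level),
    ppv = .metric_with_ci(cm$tp, cm$tp + cm$fp, conf_level),
    npv = .metric_with_ci(cm$tn, cm$tn + cm$fn, conf_level),
    cm = cm, conf_level = conf_level)
  class(out) <- "performance_metrics"
  out
}

#' @export
print.performance_metrics <- function(x, ...) {
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    if (v$defined)
      cat(sprintf("%-12s %3d%% (%d-%d%%) [%d/%d]\n", m, v$percent,
                  v$ci_lower_percent, v$ci_upper_percent, v$x, v$n))
    else
      cat(sprintf("%-12s undefined (zero denominator)\n", m))
  }
  invisible(x)
}

# Tie-corrected normal-approximation two-sided p for the rank-sum statistic,
# with continuity correction (halving the gap to the mean before scaling).
.u_normal_p <- function(u1, n1, n2, pooled) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- max(abs(u1 - mu) - 0.5, 0) / sqrt(sigma2)
  2 * stats::pnorm(-z)
}

#' Mann-Whitney U test by rank sums
#'
#' U is computed from midranks, so ties contribute half a pair. The
#' reported `U` is the smaller-direction statistic (conventional); both
#' directions are returned. For small problems (`n1 * n2 <=
#' exact_limit`) the two-sided p-value is obtained by exhaustive
#' enumeration of all group assignments of the pooled values; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples (e.g. scores of successful vs unsuccessful
#'   regimens); both non-empty.
#' @param exact_limit largest `n1 * n2` for which the exact permutation
#'   distribution is enumerated.
#' @return list with `U`, `U_greater` (pairs where `x > y`, ties half),
#'   `U_less`, `p`, `method`, `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, exact_limit = 100) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0)
    stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs x > y (ties: 1/2)
  u2 <- n1 * n2 - u1
  if (n1 * n2 <= exact_limit) {
    cb <- utils::combn(n1 + n2, n1)
    R1 <- colSums(matrix(r[cb], nrow = n1))
    u_all <- R1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(u1 - mu) - sqrt(.Machine$double.eps))
    method <- "exact enumeration"
  } else {
    p <- .u_normal_p(u1, n1, n2, pooled)
    method <- "normal approximation (tie-corrected)"
  }
  list(U = min(u1, u2), U_greater = u1, U_less = u2, p = p,
       method = method, n1 = n1, n2 = n2)
}

#' ROC curve and AUC of the matching score
#'
#' The ROC is built from every distinct observed score used as a strict
#' (`>`) threshold, descending, closed with a final point at threshold
#' `-Inf` so the curve runs from (0, 0) to (1, 1). The AUC is computed by
#' the Mann-Whitney identity -- the fraction of
#' (successful, unsuccessful) pairs ordered correctly, ties counting one
#' half -- which equals trapezoidal integration of the empirical ROC. The
#' p-value tests AUC = 0.5 via the tie-corrected normal approximation of
#' the rank-sum statistic.
#'
#' @inheritParams confusion_at_threshold
#' @return list with `roc` (data.frame: `threshold`, `tpr`, `fpr`), `auc`,
#'   `auc_p`, `n_successful`, `n_unsuccessful`.
#' @export
roc_and_auc <- function(scores, labels) {
  pos <- .as_success_logical(labels)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0)
    stop("need at least one successful and one unsuccessful record", call. = FALSE)
  thresholds <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thresholds, function(t) sum(scores > t & pos) / n1, numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores > t & !pos) / n2, numeric(1))
  r <- rank(scores)
  u1 <- sum(r[pos]) - n1 * (n1 + 1) / 2
  auc <- u1 / (n1 * n2)
  list(roc = data.frame(threshold = thresholds, tpr = tpr, fpr = fpr),
       auc = auc,
       auc_p = .u_normal_p(u1, n1, n2, scores),
       n_successful = n1, n_unsuccessful = n2)
}

#' Operating threshold maximizing the Youden index
#'
#' Scans every candidate threshold (each distinct observed score, plus one
#' point below the minimum) and returns the one maximizing
#' sensitivity + specificity - 1 under the strict `score > threshold`
#' prediction rule. Ties are broken toward the lowest threshold, which
#' makes the choice deterministic.
#'
#' @inheritParams confusion_at_threshold
#' @return the selected threshold (numeric scalar).
#' @export
youden_threshold <- function(scores, labels) {
  pos <- .as_success_logical(labels)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0)
    stop("need at least one successful and one unsuccessful record", call. = FALSE)
  candidates <- sort(unique(c(scores, min(scores) - 1)))
  j <- vapply(candidates, function(t)
    sum(scores > t & pos) / n1 - sum(scores > t & !pos) / n2, numeric(1))
  candidates[which.max(j)]  # which.max returns the first (= lowest) maximum
}

#' Load a treatment-history cohort table
#'
#' Expected tab-delimited columns: `patient_id`, `regimen` (drug ids joined
#' by `+`), `response` (CR/PR/SD/PD), `ttf_months`, and optionally
#' `score_percent` (computed from a knowledge base and profiles when
#' absent; see [evaluate_cohort()]).
#'
#' @param path path to the TSV file.
#' @return data.frame of treatment records.
#' @export
load_cohort <- function(path) {
  rec <- .read_tsv(path)
  need <- c("patient_id", "regimen", "response", "ttf_months")
  if (!all(need %in% names(rec)))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(rec)), collapse = ", ")), call. = FALSE)
  rec$ttf_months <- as.numeric(rec$ttf_months)
  if ("score_percent" %in% names(rec))
    rec$score_percent <- as.integer(rec$score_percent)
  if (!all(rec$response %in% .RESPONSE_CLASSES))
    stop(sprintf("%s: unknown response class", path), call. = FALSE)
  rec
}

#' End-to-end retrospective evaluation of a cohort
#'
#' Classifies each record's outcome, fills in missing matching scores from
#' a knowledge base and profiles when needed, dichotomizes at the given (or
#' Youden-optimal) threshold, and assembles the full performance report:
#' confusion matrix, sensitivity/specificity/PPV/NPV with exact binomial
#' confidence intervals, ROC curve with AUC, and the Mann-Whitney
#' comparison of score distributions between successful and unsuccessful
#' lines.
#'
#' @param records data.frame of treatment records (see [load_cohort()]).
#' @param threshold decision threshold in percent; `NULL` selects the
#'   Youden-optimal threshold from the data.
#' @param kb,profiles knowledge base and named profile list used to score
#'   records lacking `score_percent`.
#' @param config a [scoring_config()].
#' @return A list of class `performance_report`: `threshold`, `cm`,
#'   `metrics`, `roc`, `auc`, `auc_p`, `mann_whitney`, `score_summary`
#'   (per-label median/mean), `n`.
#' @export
evaluate_cohort <- function(records, threshold = NULL, kb = NULL,
                            profiles = NULL, config = scoring_config()) {
  if (is.null(records$score_percent) || anyNA(records$score_percent)) {
    if (is.null(kb) || is.null(profiles))
      stop("records lack score_percent; supply kb and profiles to compute scores",
           call. = FALSE)
    todo <- which(is.na(records$score_percent %||% rep(NA, nrow(records))))
    if (is.null(records$score_percent))
      records$score_percent <- NA_integer_
    for (i in todo) {
      prof <- profiles[[records$patient_id[i]]]
      if (is.null(prof))
        stop(sprintf("no profile for patient '%s'", records$patient_id[i]),
             call. = FALSE)
      records$score_percent[i] <- matching_score(
        regimen(records$regimen[i], max_drugs = .Machine$integer.max),
        prof, kb, config)$score_percent
    }
  }
  labels <- classify_outcome(records$response, records$ttf_months)
  scores <- records$score_percent
  if (is.null(threshold)) threshold <- youden_threshold(scores, labels)
  cm <- confusion_at_threshold(scores, labels, threshold)
  roc <- roc_and_auc(scores, labels)
  mw <- mann_whitney(scores[labels == "successful"],
                     scores[labels == "unsuccessful"])
  succ <- scores[labels == "successful"]
  fail <- scores[labels == "unsuccessful"]
  structure(list(threshold = threshold, cm = cm,
                 metrics = performance_metrics(cm),
                 roc = roc$roc, auc = roc$auc, auc_p = roc$auc_p,
                 mann_whitney = mw,
                 score_summary = data.frame(
                   label = c("successful", "unsuccessful"),
                   n = c(length(succ), length(fail)),
                   median = c(stats::median(succ), stats::median(fail)),
                   mean = c(mean(succ), mean(fail))),
                 n = nrow(records)),
            class = "performance_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report: n=%d, threshold=%s%%, AUC=%.3f (p=%.2g)>\n",
              x$n, format(x$threshold), x$auc, x$auc_p))
  print(x$cm)
  print(x$metrics)
  cat(sprintf("Mann-Whitney U=%.1f, p=%.2g (%s)\n", x$mann_whitney$U,
              x$mann_whitney$p, x$mann_whitney$method))
  invisible(x)
}
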