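#' Scoring configuration
#'
#' Houses the weights of the hit-score scheme. The defaults -- a direct
#' match contributes 1.0, an indirect (same-pathway) match 0.5, and each
#' biomarker's total contribution is capped at 1.0 -- are the minimal
#' convention under which a regimen matching every scoreable biomarker
#' directly scores exactly 100% and single direct hits score
#' `100 / n_biomarkers`.
#'
#' @param direct_weight contribution of a direct match, in (0, 1\].
#' @param indirect_weight contribution of an indirect match;
#'   `0 < indirect_weight <= direct_weight`.
#' @param per_biomarker_cap maximum total contribution of one biomarker
#'   across all drugs of a regimen; `>= direct_weight`. Prevents double
#'   counting so that full coverage is exactly 100%.
#' @param modifiers_enabled character vector of modifier ids applied after
#'   the raw ratio, in registry order (see [modifier_registry()]). Default
#'   none.
#' @param drug_count_factor per-additional-drug multiplicative factor used
#'   by the `drug_count_penalty` modifier; 1.0 (no penalty) by default.
#' @param max_drugs largest admissible regimen size.
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(direct_weight = 1.0, indirect_weight = 0.5,
                           per_biomarker_cap = 1.0,
                           modifiers_enabled = character(0),
                           drug_count_factor = 1.0,
                           max_drugs = 3L) {
  if (!(indirect_weight > 0 && indirect_weight <= direct_weight &&
          direct_weight <= per_biomarker_cap))
    stop("weights must satisfy 0 < indirect_weight <= direct_weight <= per_biomarker_cap",
         call. = FALSE)
  if (drug_count_factor < 0 || drug_count_factor > 1)
    stop("drug_count_factor must lie in [0, 1]", call. = FALSE)
  structure(list(direct_weight = direct_weight,
                 indirect_weight = indirect_weight,
                 per_biomarker_cap = per_biomarker_cap,
                 rounding = "half_up",
                 modifiers_enabled = modifiers_enabled,
                 drug_count_factor = drug_count_factor,
                 max_drugs = as.integer(max_drugs)),
            class = "scoring_config")
}

#' Construct a drug regimen
#'
#' @param drug_ids character vector of distinct drug tokens (matched
#'   case-insensitively); a single `"a+b+c"` string is also accepted.
#' @param label display label; defaults to the sorted ids joined by `+`.
#' @param max_drugs largest admissible size (default 3).
#' @return An object of class `regimen`. Drug order never affects any score;
#'   ids are stored sorted.
#' @export
regimen <- function(drug_ids, label = NULL, max_drugs = 3L) {
  if (length(drug_ids) == 1 && grepl("+", drug_ids, fixed = TRUE))
    drug_ids <- .split_tokens(drug_ids, sep = "+")
  drug_ids <- tolower(trimws(drug_ids))
  if (length(drug_ids) < 1) stop("a regimen needs at least one drug", call. = FALSE)
  if (anyDuplicated(drug_ids))
    stop("duplicate drugs in regimen", call. = FALSE)
  if (length(drug_ids) > max_drugs)
    stop(sprintf("regimen exceeds the maximum of %d drugs", max_drugs),
         call. = FALSE)
  ids <- sort(drug_ids)
  structure(list(drug_ids = ids,
                 label = if (is.null(label)) paste(ids, collapse = "+") else label),
            class = "regimen")
}

.as_regimen <- function(x, config) {
  if (inherits(x, "regimen")) x else regimen(x, max_drugs = config$max_drugs)
}

#' Per-biomarker hit contributions of one drug
#'
#' For each scoreable biomarker of the profile the drug contributes the
#' direct weight if a direct rule matches the (gene, alteration class)
#' pattern, else the indirect weight if an indirect rule matches, else 0;
#' a rule's `weight_override` replaces the default. If any resistance rule
#' of the drug matches any scoreable biomarker, the drug is nullified: all
#' of its contributions are 0.
#'
#' @param drug_id drug token present in `kb`.
#' @param profile a `patient_profile`.
#' @param kb a `knowledge_base`. Indirect rules must already be present
#'   (explicitly curated or added via [derive_indirect_rules()]).
#' @param config a [scoring_config()].
#' @return numeric vector of contributions, one per scoreable biomarker, in
#'   profile order, named by gene.
#' @export
drug_hits <- function(drug_id, profile, kb, config = scoring_config()) {
  drug_id <- tolower(drug_id)
  if (!drug_id %in% kb$drugs$drug_id)
    stop(sprintf("unknown drug '%s'", drug_id), call. = FALSE)
  bio <- scoreable_biomarkers(profile)
  r <- kb$rules[kb$rules$drug_id == drug_id, , drop = FALSE]
  out <- numeric(nrow(bio))
  names(out) <- bio$gene
  if (nrow(bio) == 0 || nrow(r) == 0) return(out)
  # A resistance rule matching any profile alteration (scoreable or not)
  # nullifies the drug outright.
  res_rules <- r[r$match_type == "resistance", , drop = FALSE]
  if (nrow(res_rules)) {
    akey <- paste(profile$alterations$gene, profile$alterations$alteration_class)
    if (any(paste(res_rules$gene, res_rules$alteration_class) %in% akey))
      return(out)
  }
  bkey <- paste(bio$gene, bio$alteration_class)
  rkey <- paste(r$gene, r$alteration_class)
  idx <- match(bkey, rkey)
  hitrule <- r[idx[!is.na(idx)], , drop = FALSE]
  if (any(hitrule$match_type == "resistance")) return(out)
  w <- ifelse(!is.na(hitrule$weight_override), hitrule$weight_override,
              ifelse(hitrule$match_type == "direct",
                     config$direct_weight, config$indirect_weight))
  out[!is.na(idx)] <- w
  out
}

#' Hit-score breakdown of a regimen
#'
#' The effect of the drugs in a combination is additive per biomarker, but
#' each biomarker's total is capped (default 1.0) so that two drugs hitting
#' the same target do not count twice. The numerator is the sum of the
#' capped contributions; the denominator is the maximum attainable hit score
#' of the profile, `direct_weight * (number of scoreable biomarkers)` --
#' which makes 100% mean "every alteration matched".
#'
#' @inheritParams drug_hits
#' @param regimen a [regimen()] or character vector of drug ids.
#' @return A list of class `hit_breakdown`: `breakdown` (data.frame with one
#'   row per scoreable biomarker: gene, alteration_class, contribution,
#'   contributing drugs), `numerator`, `denominator`.
#' @export
regimen_hit_score <- function(regimen, profile, kb, config = scoring_config()) {
  reg <- .as_regimen(regimen, config)
  bio <- scoreable_biomarkers(profile)
  if (nrow(bio) == 0)
    stop(sprintf("profile %s has no scoreable biomarkers; the matching score is undefined",
                 profile$patient_id), call. = FALSE)
  hits <- vapply(reg$drug_ids, drug_hits, numeric(nrow(bio)),
                 profile = profile, kb = kb, config = config)
  hits <- matrix(hits, nrow = nrow(bio),
                 dimnames = list(bio$gene, reg$drug_ids))
  capped <- pmin(config$per_biomarker_cap, rowSums(hits))
  contributing <- apply(hits > 0, 1, function(z)
    paste(reg$drug_ids[z], collapse = ","))
  breakdown <- data.frame(gene = bio$gene,
                          alteration_class = bio$alteration_class,
                          contribution = unname(capped),
                          drugs = unname(contributing),
                          stringsAsFactors = FALSE)
  structure(list(breakdown = breakdown,
                 numerator = sum(capped),
                 denominator = config$direct_weight * nrow(bio)),
            class = "hit_breakdown")
}

#' Matching score of a regimen against a profile
#'
#' The matching score is the percentage of the profile's maximum attainable
#' hit score achieved by the regimen: the capped sum of direct and indirect
#' per-biomarker hits, divided by the denominator defined by the scoreable
#' biomarker count, multiplied by any enabled clinical modifier factors, and
#' rounded half-up to an integer percent. 0% means no molecular match; 100%
#' means every pathogenic alteration is covered.
#'
#' @inheritParams regimen_hit_score
#' @return An object of class `matching_score_result` with fields `regimen`,
#'   `breakdown`, `numerator`, `denominator`, `modifiers_applied`
#'   (data.frame id/factor) and `score_percent` (integer 0..100).
#' @export
#' @examples
#' kb <- calibration_kb()
#' p51 <- patient51_profile()
#' matching_score("tamoxifen", p51, kb)$score_percent              # 17
#' matching_score(c("anastrozole", "everolimus"), p51, kb)$score_percent  # 42
matching_score <- function(regimen, profile, kb, config = scoring_config()) {
  reg <- .as_regimen(regimen, config)
  hb <- regimen_hit_score(reg, profile, kb, config)
  res <- structure(list(regimen = reg,
                        breakdown = hb$breakdown,
                        numerator = hb$numerator,
                        denominator = hb$denominator,
                        modifiers_applied = data.frame(id = character(0),
                                                       factor = numeric(0),
                                                       stringsAsFactors = FALSE),
                        score_percent = round_half_up(
                          100 * hb$numerator / hb$denominator)),
                   class = "matching_score_result")
  if (length(config$modifiers_enabled))
    res <- apply_modifiers(res, profile, reg, kb, config)
  res
}

#' @export
print.matching_score_result <- function(x, ...) {
  cat(sprintf("<matching_score %s: %d%% (%.3g / %.3g", x$regimen$label,
              x$score_percent, x$numerator, x$denominator))
  if (nrow(x$modifiers_applied))
    cat(sprintf("; modifiers %s",
                paste(sprintf("%s=%.3g", x$modifiers_applied$id,
                              x$modifiers_applied$factor), collapse = ", ")))
  cat(")>\n")
  matched <- x$breakdown[x$breakdown$contribution > 0, , drop = FALSE]
  if (nrow(matched))
    cat("  matched:", paste(sprintf("%s(%.2g:%s)", matched$gene,
                                    matched$contribution, matched$drugs),
                            collapse = " "), "\n")
  invisible(x)
}
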