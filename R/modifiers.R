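# Clinical modifier registry.
#
# The raw matching ratio can be tuned by multiplicative clinical factors in
# [0, 1] before rounding. The platform this models treats such tuning as an
# expert-reviewed rule system whose exact content is not public, so the
# registry is pluggable: each modifier is a function
# (profile, regimen, kb, config) -> factor, applied in registration order
# for the ids listed in `config$modifiers_enabled`.

.modifier_registry <- new.env(parent = emptyenv())
.modifier_registry$fns <- list()   # named list; names preserve registration order

#' Register a clinical score modifier
#'
#' @param id modifier token.
#' @param fn function `(profile, regimen, kb, config)` returning one numeric
#'   factor in \[0, 1\].
#' @param overwrite replace an existing modifier of the same id?
#' @return `id`, invisibly.
#' @export
register_modifier <- function(id, fn, overwrite = FALSE) {
  stopifnot(is.character(id), length(id) == 1, is.function(fn))
  if (!overwrite && id %in% names(.modifier_registry$fns))
    stop(sprintf("modifier '%s' is already registered", id), call. = FALSE)
  .modifier_registry$fns[[id]] <- fn
  invisible(id)
}

#' List registered modifier ids
#'
#' Two modifiers ship with the package: `eligibility_zero` (factor 0 when
#' the regimen contains an adult-only drug for a pediatric patient, a drug
#' the patient is allergic to, or a drug with no administration route the
#' patient accepts; else 1) and `drug_count_penalty` (factor
#' `drug_count_factor^(n_drugs - 1)`, an optional preference for minimal
#' regimens; identity at the default factor of 1).
#'
#' @return character vector of ids, in registration order.
#' @export
modifier_registry <- function() {
  names(.modifier_registry$fns)
}

.builtin_modifiers <- function() {
  register_modifier("eligibility_zero", function(profile, regimen, kb, config) {
    d <- kb$drugs[match(regimen$drug_ids, kb$drugs$drug_id), , drop = FALSE]
    if (any(is.na(d$drug_id))) return(0)
    if (profile$age_class == "pediatric" && any(d$adult_only)) return(0)
    if (any(d$drug_id %in% profile$allergies)) return(0)
    if (!is.null(profile$accepted_routes)) {
      ok <- vapply(d$routes, function(r)
        length(intersect(.split_tokens(r), profile$accepted_routes)) > 0,
        logical(1))
      if (!all(ok)) return(0)
    }
    1
  }, overwrite = TRUE)
  register_modifier("drug_count_penalty", function(profile, regimen, kb, config) {
    config$drug_count_factor ^ (length(regimen$drug_ids) - 1)
  }, overwrite = TRUE)
}

#' Apply enabled clinical modifiers to a score result
#'
#' Multiplies the pre-rounding ratio by each enabled modifier's factor in
#' registry order and re-rounds once, after all factors. With no modifiers
#' enabled the result is returned unchanged.
#'
#' @param result a `matching_score_result`.
#' @param profile,regimen,kb,config the scoring context.
#' @return The updated `matching_score_result` with `modifiers_applied`
#'   filled in.
#' @export
apply_modifiers <- function(result, profile, regimen, kb,
                            config = scoring_config()) {
  enabled <- config$modifiers_enabled
  if (length(enabled) == 0) return(result)
  known <- modifier_registry()
  unknown <- setdiff(enabled, known)
  if (length(unknown))
    stop(sprintf("unknown modifier id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  reg <- .as_regimen(regimen, config)
  ids <- known[known %in% enabled]
  factors <- vapply(ids, function(id)
    .modifier_registry$fns[[id]](profile, reg, kb, config), numeric(1))
  if (any(factors < 0 | factors > 1))
    stop("modifier factors must lie in [0, 1]", call. = FALSE)
  result$modifiers_applied <- data.frame(id = ids, factor = unname(factors),
                                         stringsAsFactors = FALSE)
  result$score_percent <- round_half_up(
    100 * result$numerator / result$denominator * prod(factors))
  result
}
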