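#' Regimen enumeration constraints
#'
#' @param max_drugs largest regimen size (default 3; the combination space
#'   is exhaustively enumerable at this size even for a couple of hundred
#'   drugs).
#' @param require_adult_ok drop adult-only drugs for pediatric profiles?
#' @param excluded_drugs drug ids removed outright (in addition to the
#'   profile's allergies).
#' @param required_routes optional route set a drug must serve; `NULL`
#'   defers to the profile's `accepted_routes` (and to no restriction when
#'   that is also `NULL`).
#' @param max_per_class named integer vector limiting how many drugs of a
#'   given class one regimen may contain; the default caps hormone agents at
#'   one per regimen, all other classes unlimited.
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(max_drugs = 3L, require_adult_ok = TRUE,
                           excluded_drugs = character(0),
                           required_routes = NULL,
                           max_per_class = c(hormone = 1L)) {
  max_drugs <- as.integer(max_drugs)
  if (max_drugs < 1) stop("max_drugs must be >= 1", call. = FALSE)
  if (!is.null(required_routes) && !all(required_routes %in% .ROUTES))
    stop("required_routes must be a subset of the route vocabulary", call. = FALSE)
  structure(list(max_drugs = max_drugs,
                 require_adult_ok = isTRUE(require_adult_ok),
                 excluded_drugs = tolower(excluded_drugs),
                 required_routes = required_routes,
                 max_per_class = max_per_class),
            class = "constraint_set")
}

#' Drugs a profile may receive
#'
#' Removes excluded drugs and the profile's allergies, adult-only drugs for
#' pediatric profiles, and drugs with no administration route the patient
#' accepts. Pure function of its arguments.
#'
#' @param kb a `knowledge_base`.
#' @param profile optional `patient_profile`; `NULL` applies only the
#'   constraint-set filters.
#' @param constraints a [constraint_set()].
#' @return sorted character vector of eligible drug ids.
#' @export
filter_eligible <- function(kb, profile = NULL,
                            constraints = constraint_set()) {
  d <- kb$drugs
  keep <- !d$drug_id %in% constraints$excluded_drugs
  routes_needed <- constraints$required_routes
  if (!is.null(profile)) {
    keep <- keep & !d$drug_id %in% profile$allergies
    if (constraints$require_adult_ok && profile$age_class == "pediatric")
      keep <- keep & !d$adult_only
    if (is.null(routes_needed)) routes_needed <- profile$accepted_routes
  }
  if (!is.null(routes_needed)) {
    keep <- keep & vapply(d$routes, function(r)
      length(intersect(.split_tokens(r), routes_needed)) > 0, logical(1))
  }
  sort(d$drug_id[keep])
}

#' Enumerate all admissible regimens
#'
#' Yields every subset of the eligible drugs of size 1 to `max_drugs`
#' exactly once, ordered by size and then lexicographically by drug ids,
#' minus any subset violating a per-class cap. Without class caps the count
#' is `sum(choose(n_eligible, 1:max_drugs))`.
#'
#' The return value is a compact index representation (class `regimen_set`)
#' rather than a materialized list: at a 230-drug catalogue and triplets the
#' space holds about two million regimens. Use [length()] for the count,
#' [regimen_labels()] for display labels, and `as.list()` for small sets.
#'
#' @inheritParams filter_eligible
#' @param eligible optional pre-computed eligible drug-id vector; defaults
#'   to `filter_eligible(kb, NULL, constraints)`.
#' @return A `regimen_set`: list with `drug_ids` (sorted) and `combos`
#'   (per-size index matrices, columns in lexicographic order).
#' @export
enumerate_regimens <- function(kb, constraints = constraint_set(),
                               eligible = NULL) {
  if (is.null(eligible)) eligible <- filter_eligible(kb, NULL, constraints)
  eligible <- sort(tolower(eligible))
  n <- length(eligible)
  if (n == 0)
    return(structure(list(drug_ids = character(0), combos = list()),
                     class = "regimen_set"))
  kmax <- min(constraints$max_drugs, n)
  combos <- .combination_index(n, kmax)
  caps <- constraints$max_per_class
  caps <- caps[!is.na(caps)]
  if (length(caps)) {
    cls <- kb$drugs$drug_class[match(eligible, kb$drugs$drug_id)]
    for (cl in names(caps)) {
      if (caps[[cl]] >= kmax) next
      member <- as.integer(!is.na(cls) & cls == cl)
      combos <- lapply(combos, function(m) {
        cnt <- colSums(matrix(member[m], nrow = nrow(m)))
        m[, cnt <= caps[[cl]], drop = FALSE]
      })
    }
  }
  structure(list(drug_ids = eligible, combos = combos), class = "regimen_set")
}

#' @export
length.regimen_set <- function(x) {
  sum(vapply(x$combos, ncol, integer(1)))
}

#' Display labels of an enumerated regimen set
#'
#' @param x a `regimen_set`.
#' @return character vector of `+`-joined drug ids, in enumeration order.
#' @export
regimen_labels <- function(x) {
  unlist(lapply(x$combos, function(m) {
    if (ncol(m) == 0) return(character(0))
    parts <- lapply(seq_len(nrow(m)), function(r) x$drug_ids[m[r, ]])
    do.call(paste, c(parts, sep = "+"))
  }), use.names = FALSE)
}

#' @export
as.list.regimen_set <- function(x, ...) {
  unlist(lapply(x$combos, function(m)
    lapply(seq_len(ncol(m)), function(j) x$drug_ids[m[, j]])),
    recursive = FALSE)
}

#' @export
print.regimen_set <- function(x, ...) {
  cat(sprintf("<regimen_set: %d drugs, %s regimens up to size %d>\n",
              length(x$drug_ids), format(length(x), big.mark = ","),
              length(x$combos)))
  invisible(x)
}

#' Rank all admissible regimens for a patient
#'
#' Scores every enumerated regimen with [matching_score()] semantics and
#' returns the top of the ranking. Ties are broken deterministically:
#' higher score first, then fewer drugs, then lexicographic label. Scoring
#' is vectorized over the whole combination space via a per-drug
#' contribution matrix, so exhaustive triplet ranking over a
#' hundreds-of-drugs catalogue stays well inside interactive time; results
#' are identical to scoring each regimen one at a time.
#'
#' @inheritParams matching_score
#' @param constraints a [constraint_set()].
#' @param top_n number of rows to return (`Inf` for the full ranking).
#' @return data.frame with columns `rank`, `regimen` (label), `n_drugs`,
#'   `score_percent`, `matched_biomarkers`.
#' @export
rank_regimens <- function(profile, kb, constraints = constraint_set(),
                          config = scoring_config(), top_n = 10) {
  bio <- scoreable_biomarkers(profile)
  if (nrow(bio) == 0)
    stop(sprintf("profile %s has no scoreable biomarkers; ranking is undefined",
                 profile$patient_id), call. = FALSE)
  eligible <- filter_eligible(kb, profile, constraints)
  if (length(eligible) == 0)
    stop("no eligible drugs for this profile", call. = FALSE)
  rs <- enumerate_regimens(kb, constraints, eligible = eligible)

  fast_ok <- all(config$modifiers_enabled %in%
                   c("eligibility_zero", "drug_count_penalty"))
  if (!fast_ok) {
    # User-registered modifiers: score one regimen at a time.
    labels <- regimen_labels(rs)
    regs <- as.list(rs)
    score <- integer(length(regs))
    matched <- integer(length(regs))
    ksz <- lengths(regs)
    for (i in seq_along(regs)) {
      res <- matching_score(regimen(regs[[i]], max_drugs = constraints$max_drugs),
                            profile, kb, config)
      score[i] <- res$score_percent
      matched[i] <- sum(res$breakdown$contribution > 0)
    }
  } else {
    M <- t(vapply(rs$drug_ids, drug_hits, numeric(nrow(bio)),
                  profile = profile, kb = kb, config = config))
    M <- matrix(M, nrow = length(rs$drug_ids))  # drugs x biomarkers
    # eligibility_zero can only trigger here through route/age/allergy
    # conflicts already removed by filter_eligible, so its regimen factor is
    # always 1 on the enumerated set.
    score <- integer(0); matched <- integer(0); ksz <- integer(0)
    labels <- regimen_labels(rs)
    for (k in seq_along(rs$combos)) {
      cm <- rs$combos[[k]]
      m <- ncol(cm)
      if (m == 0) next
      S <- matrix(0, nrow = m, ncol = nrow(bio))
      for (r in seq_len(k)) S <- S + M[cm[r, ], , drop = FALSE]
      S <- pmin(S, config$per_biomarker_cap)
      num <- rowSums(S)
      fac <- if ("drug_count_penalty" %in% config$modifiers_enabled)
        config$drug_count_factor ^ (k - 1) else 1
      score <- c(score, round_half_up(
        100 * num / (config$direct_weight * nrow(bio)) * fac))
      matched <- c(matched, rowSums(S > 0))
      ksz <- c(ksz, rep.int(k, m))
    }
  }

  ord <- order(-score, ksz, labels, method = "radix")
  if (is.finite(top_n)) ord <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(rank = seq_along(ord),
             regimen = labels[ord],
             n_drugs = ksz[ord],
             score_percent = score[ord],
             matched_biomarkers = matched[ord],
             stringsAsFactors = FALSE)
}
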