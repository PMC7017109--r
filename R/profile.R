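#' Construct a patient molecular profile
#'
#' A profile is a gene-level, pre-interpreted description of one tumor:
#' which genes are altered, how (alteration class), and whether each call is
#' pathogenic. No genomic coordinates or raw variant calls are modeled --
#' inputs are assumed to come from a clinical report. Negative or normal
#' findings (class `expression_negative`, or `pathogenic = FALSE`) are kept
#' for reporting but never enter the matching-score denominator.
#'
#' @param patient_id unique case token.
#' @param alterations data.frame with columns `gene`, `alteration_class`
#'   (closed vocabulary: mutation_activating, mutation_loss, amplification,
#'   copy_loss, fusion, expression_positive, expression_high,
#'   expression_negative, other), `pathogenic` (logical) and optional
#'   `detail` free text. Order is preserved.
#' @param diagnosis free-text histology.
#' @param age_years optional non-negative age.
#' @param age_class `"adult"` or `"pediatric"`.
#' @param allergies drug ids the patient cannot receive.
#' @param accepted_routes optional subset of `c("oral", "iv", "other")`;
#'   `NULL` means no route restriction.
#' @return An object of class `patient_profile`.
#' @export
patient_profile <- function(patient_id, alterations, diagnosis = "",
                            age_years = NA_real_,
                            age_class = c("adult", "pediatric"),
                            allergies = character(0),
                            accepted_routes = NULL) {
  age_class <- match.arg(age_class)
  if (!nzchar(patient_id)) stop("patient_id must be non-empty", call. = FALSE)
  alterations <- .norm_alterations(alterations, patient_id)
  if (!is.na(age_years) && age_years < 0)
    stop("age_years must be non-negative", call. = FALSE)
  if (!is.null(accepted_routes) && !all(accepted_routes %in% .ROUTES))
    stop(sprintf("accepted_routes must be a subset of {%s}",
                 paste(.ROUTES, collapse = ", ")), call. = FALSE)
  structure(list(patient_id = patient_id, diagnosis = diagnosis,
                 age_years = age_years, age_class = age_class,
                 alterations = alterations,
                 allergies = tolower(allergies),
                 accepted_routes = accepted_routes),
            class = "patient_profile")
}

.norm_alterations <- function(alterations, patient_id = "?") {
  empty <- data.frame(gene = character(0), alteration_class = character(0),
                      pathogenic = logical(0), detail = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(alterations) || nrow(as.data.frame(alterations)) == 0)
    return(empty)
  a <- as.data.frame(alterations, stringsAsFactors = FALSE)
  if (is.null(a$detail)) a$detail <- ""
  a$gene <- toupper(as.character(a$gene))
  a$pathogenic <- as.logical(a$pathogenic)
  if (any(!nzchar(a$gene) | is.na(a$gene)))
    stop(sprintf("patient %s: empty gene symbol in alteration %d",
                 patient_id, which(!nzchar(a$gene))[1]), call. = FALSE)
  bad <- which(!a$alteration_class %in% .ALTERATION_CLASSES)
  if (length(bad))
    stop(sprintf("patient %s: unknown alteration class '%s' (row %d)",
                 patient_id, a$alteration_class[bad[1]], bad[1]), call. = FALSE)
  if (any(is.na(a$pathogenic)))
    stop(sprintf("patient %s: pathogenic must be TRUE or FALSE", patient_id),
         call. = FALSE)
  key <- paste(a$gene, a$alteration_class)
  if (anyDuplicated(key))
    stop(sprintf("patient %s: duplicate alteration row for %s",
                 patient_id, key[duplicated(key)][1]), call. = FALSE)
  rownames(a) <- NULL
  a[, c("gene", "alteration_class", "pathogenic", "detail")]
}

#' Load patient profiles from disk
#'
#' The TSV dialect has one row per alteration with header
#' `patient_id, gene, alteration_class, pathogenic, detail`; rows are grouped
#' by patient preserving file order. Case metadata may be supplied in a
#' companion table (`patients.tsv`: `patient_id, diagnosis, age_years,
#' age_class`, plus optional comma-separated `allergies` and
#' `accepted_routes` columns). The JSON form is an array of profile objects
#' with an `alterations` array each.
#'
#' @param path path to `profiles.tsv` or a `.json` file.
#' @param format `"json"` or `"tsv"`; guessed from the file extension when
#'   missing.
#' @param patients_path optional path to the case-metadata TSV.
#' @return A named list of [patient_profile()] objects (names = patient ids).
#' @export
load_profiles <- function(path, format = c("json", "tsv"),
                          patients_path = NULL) {
  if (missing(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  } else {
    format <- match.arg(format)
  }
  if (!file.exists(path))
    stop(sprintf("profile path '%s' does not exist", path), call. = FALSE)
  meta <- NULL
  if (!is.null(patients_path)) meta <- .read_tsv(patients_path)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    profiles <- lapply(seq_len(nrow(doc)), function(i) {
      row <- doc[i, ]
      patient_profile(
        patient_id = row$patient_id,
        alterations = as.data.frame(row$alterations[[1]],
                                    stringsAsFactors = FALSE),
        diagnosis = if (is.null(row$diagnosis)) "" else row$diagnosis,
        age_years = if (is.null(row$age_years)) NA_real_ else row$age_years,
        age_class = if (is.null(row$age_class)) "adult" else row$age_class,
        allergies = if (is.null(row$allergies[[1]])) character(0)
                    else unlist(row$allergies),
        accepted_routes = if (is.null(row$accepted_routes[[1]])) NULL
                          else unlist(row$accepted_routes))
    })
    names(profiles) <- vapply(profiles, `[[`, character(1), "patient_id")
    return(profiles)
  }
  rows <- .read_tsv(path)
  need <- c("patient_id", "gene", "alteration_class", "pathogenic")
  if (!all(need %in% names(rows)))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(rows)), collapse = ", ")),
         call. = FALSE)
  if (nrow(rows) == 0) return(structure(list(), names = character(0)))
  if (is.null(rows$detail)) rows$detail <- ""
  rows$pathogenic <- toupper(rows$pathogenic) %in% c("TRUE", "T", "1", "YES")
  ids <- unique(rows$patient_id)
  profiles <- lapply(ids, function(id) {
    sub <- rows[rows$patient_id == id, c("gene", "alteration_class",
                                         "pathogenic", "detail"), drop = FALSE]
    m <- if (!is.null(meta)) meta[meta$patient_id == id, , drop = FALSE] else NULL
    has <- function(col) !is.null(m) && nrow(m) == 1 && col %in% names(m) &&
      !is.na(m[[col]]) && nzchar(m[[col]])
    patient_profile(
      patient_id = id,
      alterations = sub,
      diagnosis = if (has("diagnosis")) m$diagnosis else "",
      age_years = if (has("age_years")) as.numeric(m$age_years) else NA_real_,
      age_class = if (has("age_class")) m$age_class else "adult",
      allergies = if (has("allergies")) .split_tokens(m$allergies) else character(0),
      accepted_routes = if (has("accepted_routes")) .split_tokens(m$accepted_routes) else NULL)
  })
  names(profiles) <- ids
  profiles
}

#' Scoreable biomarkers of a profile
#'
#' The matching-score denominator is defined by this list: alterations that
#' are pathogenic and are actual aberrations (a negative expression finding,
#' e.g. a Her2-negative status, is not an alteration and is excluded). The
#' filter is pure: output rows are a subset of the input in the same order.
#'
#' @param profile a `patient_profile`.
#' @return data.frame of scoreable alteration rows (possibly zero rows).
#' @export
scoreable_biomarkers <- function(profile) {
  a <- profile$alterations
  keep <- a$pathogenic & a$alteration_class != "expression_negative"
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient_profile %s: %s, %s, %d alterations (%d scoreable)>\n",
              x$patient_id,
              if (nzchar(x$diagnosis)) x$diagnosis else "unknown diagnosis",
              x$age_class, nrow(x$alterations),
              nrow(scoreable_biomarkers(x))))
  invisible(x)
}
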