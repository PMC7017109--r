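#' Construct a drug-biomarker knowledge base
#'
#' A knowledge base holds the three tables the matching engine consumes:
#' the drug catalogue, gene-to-pathway membership, and match rules linking a
#' drug to a (gene, alteration class) pattern as a direct, indirect or
#' resistance match. All invariants are checked on construction; a knowledge
#' base object is therefore always valid.
#'
#' @param drugs data.frame with columns `drug_id` (unique lowercase token),
#'   `name`, `drug_class` (one of cytotoxic, targeted_small_molecule,
#'   antibody, hormone, immunotherapy, other), `adult_only` (logical),
#'   `routes` (comma-separated subset of oral, iv, other) and
#'   `contraindication_flags` (comma-separated free tokens, may be empty).
#' @param pathways data.frame in long form with columns `pathway_id` and
#'   `gene`, one row per member gene. A gene may belong to several pathways.
#' @param rules data.frame with columns `drug_id`, `gene`, `alteration_class`,
#'   `match_type` (direct, indirect, resistance), `weight_override` (numeric
#'   in \[0, 1\] or `NA` for the configured default; must be `NA` for
#'   resistance rules, which nullify rather than weight) and `evidence_tag`.
#'   Direct rules require evidence from `ic50_nanomolar`, `antibody_epitope`
#'   or `sensitivity_biomarker`; `(drug_id, gene, alteration_class)` is
#'   unique.
#' @param version free-form version string.
#'
#' @return An object of class `knowledge_base`.
#' @seealso [load_kb()], [derive_indirect_rules()], [query_rules()]
#' @export
#' @examples
#' kb <- knowledge_base(
#'   drugs = data.frame(drug_id = "everolimus", name = "everolimus",
#'                      drug_class = "targeted_small_molecule",
#'                      adult_only = FALSE, routes = "oral",
#'                      contraindication_flags = ""),
#'   pathways = data.frame(pathway_id = "PI3K_AKT_MTOR",
#'                         gene = c("MTOR", "PTEN", "PIK3CA")),
#'   rules = data.frame(drug_id = "everolimus", gene = "MTOR",
#'                      alteration_class = "mutation_activating",
#'                      match_type = "direct", weight_override = NA_real_,
#'                      evidence_tag = "ic50_nanomolar"))
knowledge_base <- function(drugs, pathways = NULL, rules = NULL,
                           version = "1") {
  drugs <- .norm_drugs(drugs)
  pathways <- .norm_pathways(pathways)
  rules <- .norm_rules(rules)
  kb <- structure(list(version = as.character(version), drugs = drugs,
                       pathways = pathways, rules = rules),
                  class = "knowledge_base")
  validate_kb(kb)
}

.empty_drugs <- function() {
  data.frame(drug_id = character(0), name = character(0),
             drug_class = character(0), adult_only = logical(0),
             routes = character(0), contraindication_flags = character(0),
             stringsAsFactors = FALSE)
}

.empty_pathways <- function() {
  data.frame(pathway_id = character(0), gene = character(0),
             stringsAsFactors = FALSE)
}

.empty_rules <- function() {
  data.frame(drug_id = character(0), gene = character(0),
             alteration_class = character(0), match_type = character(0),
             weight_override = numeric(0), evidence_tag = character(0),
             stringsAsFactors = FALSE)
}

.norm_drugs <- function(drugs) {
  if (is.null(drugs) || nrow(as.data.frame(drugs)) == 0) return(.empty_drugs())
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  if (is.null(drugs$name)) drugs$name <- drugs$drug_id
  if (is.null(drugs$adult_only)) drugs$adult_only <- FALSE
  if (is.null(drugs$routes)) drugs$routes <- "other"
  if (is.null(drugs$contraindication_flags)) drugs$contraindication_flags <- ""
  drugs$drug_id <- tolower(as.character(drugs$drug_id))
  drugs$adult_only <- as.logical(drugs$adult_only)
  drugs$contraindication_flags[is.na(drugs$contraindication_flags)] <- ""
  rownames(drugs) <- NULL
  drugs[, names(.empty_drugs())]
}

.norm_pathways <- function(pathways) {
  if (is.null(pathways) || nrow(as.data.frame(pathways)) == 0)
    return(.empty_pathways())
  pathways <- as.data.frame(pathways, stringsAsFactors = FALSE)
  pathways$pathway_id <- as.character(pathways$pathway_id)
  pathways$gene <- toupper(as.character(pathways$gene))
  rownames(pathways) <- NULL
  pathways[, names(.empty_pathways())]
}

.norm_rules <- function(rules) {
  if (is.null(rules) || nrow(as.data.frame(rules)) == 0) return(.empty_rules())
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  if (is.null(rules$weight_override)) rules$weight_override <- NA_real_
  rules$drug_id <- tolower(as.character(rules$drug_id))
  rules$gene <- toupper(as.character(rules$gene))
  wo <- rules$weight_override
  wo[is.character(wo) & !nzchar(wo)] <- NA
  rules$weight_override <- as.numeric(wo)
  rownames(rules) <- NULL
  rules[, names(.empty_rules())]
}

#' Validate a knowledge base
#'
#' Checks every structural invariant: unique non-empty drug ids, closed
#' vocabularies for drug class, routes, alteration class, match type and
#' evidence tag, no dangling `drug_id` in rules, unique
#' `(drug_id, gene, alteration_class)` rule keys, weight overrides in
#' \[0, 1\] and absent on resistance rules, and non-empty pathway genes.
#' Validation does not depend on record order.
#'
#' @param kb a `knowledge_base` object (or equivalently-shaped list).
#' @param file label used in error messages, defaults to `"<knowledge_base>"`.
#' @return `kb`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending record index and field.
#' @export
validate_kb <- function(kb, file = "<knowledge_base>") {
  d <- kb$drugs; p <- kb$pathways; r <- kb$rules
  if (any(!nzchar(d$drug_id) | is.na(d$drug_id)))
    .stop_load(file, which(!nzchar(d$drug_id))[1], "drug_id", "empty drug_id")
  if (anyDuplicated(d$drug_id))
    .stop_load(file, which(duplicated(d$drug_id))[1], "drug_id",
               sprintf("duplicate drug_id '%s'", d$drug_id[duplicated(d$drug_id)][1]))
  bad <- which(!d$drug_class %in% .DRUG_CLASSES)
  if (length(bad))
    .stop_load(file, bad[1], "drug_class",
               sprintf("unknown drug class '%s'", d$drug_class[bad[1]]))
  if (any(is.na(d$adult_only)))
    .stop_load(file, which(is.na(d$adult_only))[1], "adult_only",
               "must be TRUE or FALSE")
  for (i in seq_len(nrow(d))) {
    rt <- .split_tokens(d$routes[i])
    if (length(rt) == 0 || !all(rt %in% .ROUTES))
      .stop_load(file, i, "routes",
                 sprintf("routes must be a non-empty subset of {%s}",
                         paste(.ROUTES, collapse = ", ")))
  }
  if (nrow(p)) {
    if (any(!nzchar(p$gene) | is.na(p$gene)))
      .stop_load(file, which(!nzchar(p$gene))[1], "gene", "empty gene symbol")
    if (any(!nzchar(p$pathway_id) | is.na(p$pathway_id)))
      .stop_load(file, which(!nzchar(p$pathway_id))[1], "pathway_id",
                 "empty pathway_id")
    key <- paste(p$pathway_id, p$gene)
    if (anyDuplicated(key))
      .stop_load(file, which(duplicated(key))[1], "gene",
                 "duplicate pathway membership row")
  }
  if (nrow(r)) {
    miss <- which(!r$drug_id %in% d$drug_id)
    if (length(miss))
      .stop_load(file, miss[1], "drug_id",
                 sprintf("rule references unknown drug '%s'", r$drug_id[miss[1]]))
    bad <- which(!r$alteration_class %in% .ALTERATION_CLASSES)
    if (length(bad))
      .stop_load(file, bad[1], "alteration_class",
                 sprintf("unknown alteration class '%s'", r$alteration_class[bad[1]]))
    bad <- which(!r$match_type %in% .MATCH_TYPES)
    if (length(bad))
      .stop_load(file, bad[1], "match_type",
                 sprintf("unknown match type '%s'", r$match_type[bad[1]]))
    bad <- which(!r$evidence_tag %in% .EVIDENCE_TAGS)
    if (length(bad))
      .stop_load(file, bad[1], "evidence_tag",
                 sprintf("unknown evidence tag '%s'", r$evidence_tag[bad[1]]))
    bad <- which(r$match_type == "direct" & !r$evidence_tag %in% .DIRECT_EVIDENCE)
    if (length(bad))
      .stop_load(file, bad[1], "evidence_tag",
                 "direct rules require ic50_nanomolar, antibody_epitope or sensitivity_biomarker evidence")
    bad <- which(!is.na(r$weight_override) &
                   (r$weight_override < 0 | r$weight_override > 1))
    if (length(bad))
      .stop_load(file, bad[1], "weight_override", "must lie in [0, 1]")
    bad <- which(r$match_type == "resistance" & !is.na(r$weight_override))
    if (length(bad))
      .stop_load(file, bad[1], "weight_override",
                 "resistance rules nullify; they carry no weight")
    key <- paste(r$drug_id, r$gene, r$alteration_class)
    if (anyDuplicated(key))
      .stop_load(file, which(duplicated(key))[1], "drug_id",
                 sprintf("duplicate rule key '%s'", key[duplicated(key)][1]))
  }
  invisible(kb)
}

#' Load a knowledge base from disk
#'
#' JSON is the canonical serialization (one document holding drugs, pathways
#' as `{pathway_id, member_genes}` objects, and rules). The TSV form is a
#' directory holding `drugs.tsv`, `pathways.tsv` (one `pathway_id`, `gene`
#' row per membership) and `rules.tsv`, tab-delimited with a header row;
#' lines starting with `#` are ignored.
#'
#' @param path path to the `.json` file, or to the directory of TSV files.
#' @param format `"json"` or `"tsv"`; guessed from `path` when missing.
#' @return A validated [knowledge_base()] object. Loading is deterministic
#'   and independent of record order in the files.
#' @export
load_kb <- function(path, format = c("json", "tsv")) {
  if (missing(format)) {
    format <- if (dir.exists(path)) "tsv" else "json"
  } else {
    format <- match.arg(format)
  }
  if (!file.exists(path))
    stop(sprintf("knowledge base path '%s' does not exist", path), call. = FALSE)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
    drugs <- if (length(doc$drugs)) {
      d <- as.data.frame(doc$drugs, stringsAsFactors = FALSE)
      if (is.list(d$routes))
        d$routes <- vapply(d$routes, .join_tokens, character(1))
      if (is.list(d$contraindication_flags))
        d$contraindication_flags <- vapply(d$contraindication_flags,
                                           .join_tokens, character(1))
      d
    } else NULL
    pathways <- if (length(doc$pathways)) {
      pw <- doc$pathways
      data.frame(
        pathway_id = rep(pw$pathway_id, lengths(pw$member_genes)),
        gene = unlist(pw$member_genes, use.names = FALSE),
        stringsAsFactors = FALSE)
    } else NULL
    rules <- if (length(doc$rules)) as.data.frame(doc$rules,
                                                  stringsAsFactors = FALSE) else NULL
    kb <- knowledge_base(drugs, pathways, rules,
                         version = if (is.null(doc$version)) "1" else doc$version)
  } else {
    fp <- function(f) file.path(path, f)
    drugs <- if (file.exists(fp("drugs.tsv"))) {
      d <- .read_tsv(fp("drugs.tsv"))
      d$adult_only <- toupper(d$adult_only) %in% c("TRUE", "T", "1", "YES")
      d
    } else NULL
    pathways <- if (file.exists(fp("pathways.tsv"))) .read_tsv(fp("pathways.tsv")) else NULL
    rules <- if (file.exists(fp("rules.tsv"))) .read_tsv(fp("rules.tsv")) else NULL
    version <- "1"
    if (file.exists(fp("version.tsv"))) {
      version <- .read_tsv(fp("version.tsv"))$version[1]
    }
    kb <- knowledge_base(drugs, pathways, rules, version = version)
  }
  validate_kb(kb, file = path)
}

#' Write a knowledge base to disk
#'
#' @param kb a `knowledge_base`.
#' @param path target `.json` file (json format) or directory (tsv format).
#' @param format `"json"` (canonical, round-trips exactly) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    pw <- kb$pathways
    pathways <- if (nrow(pw)) {
      ids <- unique(pw$pathway_id)
      list(pathway_id = ids,
           member_genes = lapply(ids, function(i) pw$gene[pw$pathway_id == i]))
    } else list()
    doc <- list(version = kb$version,
                drugs = kb$drugs,
                pathways = if (length(pathways))
                  data.frame(pathway_id = pathways$pathway_id,
                             stringsAsFactors = FALSE) else list(),
                rules = kb$rules)
    if (length(pathways)) doc$pathways$member_genes <- pathways$member_genes
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    .write_tsv(kb$drugs, file.path(path, "drugs.tsv"))
    .write_tsv(kb$pathways, file.path(path, "pathways.tsv"))
    .write_tsv(kb$rules, file.path(path, "rules.tsv"))
    .write_tsv(data.frame(version = kb$version), file.path(path, "version.tsv"))
  }
  invisible(path)
}

#' Derive indirect match rules from pathway co-membership
#'
#' For every direct rule (drug d, gene g) and every gene g' that shares at
#' least one pathway with g, an indirect rule (d, g') is generated for each
#' activating alteration class (activating mutation, amplification, fusion,
#' high expression) -- unless any explicit rule for (d, g') already exists,
#' in which case the curated rule stands untouched. Loss-of-function classes
#' are never auto-derived because pathway membership alone does not give the
#' direction of the dependency. The operation is pure and idempotent.
#'
#' @param kb a `knowledge_base`.
#' @param activating_classes alteration classes eligible for derivation.
#' @return A new `knowledge_base` containing the original rules plus the
#'   derived indirect rules (evidence tag `"pathway"`, default weight).
#' @export
derive_indirect_rules <- function(kb, activating_classes = .ACTIVATING_CLASSES) {
  direct <- kb$rules[kb$rules$match_type == "direct", , drop = FALSE]
  if (nrow(direct) == 0 || nrow(kb$pathways) == 0) return(kb)
  pw <- kb$pathways
  existing_pairs <- unique(paste(kb$rules$drug_id, kb$rules$gene))
  new_rules <- list()
  for (i in seq_len(nrow(direct))) {
    g <- direct$gene[i]
    d <- direct$drug_id[i]
    shared <- unique(pw$pathway_id[pw$gene == g])
    if (length(shared) == 0) next
    co <- setdiff(unique(pw$gene[pw$pathway_id %in% shared]), g)
    co <- co[!paste(d, co) %in% existing_pairs]
    if (length(co) == 0) next
    new_rules[[length(new_rules) + 1]] <- data.frame(
      drug_id = d,
      gene = rep(co, each = length(activating_classes)),
      alteration_class = rep(activating_classes, times = length(co)),
      match_type = "indirect",
      weight_override = NA_real_,
      evidence_tag = "pathway",
      stringsAsFactors = FALSE)
  }
  if (length(new_rules) == 0) return(kb)
  add <- do.call(rbind, new_rules)
  add <- add[!duplicated(paste(add$drug_id, add$gene, add$alteration_class)), ,
             drop = FALSE]
  add <- add[order(add$drug_id, add$gene, add$alteration_class), , drop = FALSE]
  knowledge_base(kb$drugs, kb$pathways, rbind(kb$rules, add),
                 version = kb$version)
}

#' Look up the match rules applying to one alteration
#'
#' @param kb a `knowledge_base`.
#' @param drug_id drug token (case-insensitive); must exist in `kb`.
#' @param gene gene symbol of the alteration.
#' @param alteration_class alteration class of the alteration.
#' @return The matching rule rows (possibly zero rows), ordered by
#'   (gene, match_type).
#' @export
query_rules <- function(kb, drug_id, gene, alteration_class) {
  drug_id <- tolower(drug_id)
  if (!drug_id %in% kb$drugs$drug_id)
    stop(sprintf("unknown drug '%s'", drug_id), call. = FALSE)
  gene <- toupper(gene)
  r <- kb$rules
  hit <- r[r$drug_id == drug_id & r$gene == gene &
             r$alteration_class == alteration_class, , drop = FALSE]
  hit <- hit[order(hit$gene, hit$match_type), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat(sprintf("<knowledge_base v%s: %d drugs, %d pathway memberships, %d rules>\n",
              x$version, nrow(x$drugs), nrow(x$pathways), nrow(x$rules)))
  invisible(x)
}
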