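# Internal helpers shared across modules.

# Closed vocabularies. Loaders reject anything outside these; silent coercion
# would corrupt the score denominator downstream.
.DRUG_CLASSES <- c("cytotoxic", "targeted_small_molecule", "antibody",
                   "hormone", "immunotherapy", "other")
.ROUTES <- c("oral", "iv", "other")
.ALTERATION_CLASSES <- c("mutation_activating", "mutation_loss", "amplification",
                         "copy_loss", "fusion", "expression_positive",
                         "expression_high", "expression_negative", "other")
.MATCH_TYPES <- c("direct", "indirect", "resistance")
.EVIDENCE_TAGS <- c("ic50_nanomolar", "antibody_epitope", "pathway",
                    "sensitivity_biomarker", "clinical")
.DIRECT_EVIDENCE <- c("ic50_nanomolar", "antibody_epitope", "sensitivity_biomarker")
# Pathway co-membership only licenses a derived indirect rule when the
# alteration is plausibly activating; loss-of-function needs explicit curation.
.ACTIVATING_CLASSES <- c("mutation_activating", "amplification", "fusion",
                         "expression_high")
.RESPONSE_CLASSES <- c("CR", "PR", "SD", "PD")

#' Round half away from zero to the nearest integer
#'
#' Scores are reported as integer percentages with ties rounded up
#' (12.5 -> 13), unlike [base::round()] which rounds half to even.
#' A tiny epsilon guards exact-half values against floating-point slop.
#'
#' @param x numeric vector, assumed non-negative.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5 + sqrt(.Machine$double.eps)))
}

# Split a comma- (or plus-) separated token list into a trimmed character
# vector; "" and NA give character(0).
.split_tokens <- function(x, sep = ",") {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, sep, fixed = TRUE)[[1]])
}

.join_tokens <- function(x, sep = ",") {
  if (length(x) == 0) "" else paste(x, collapse = sep)
}

.stop_load <- function(file, record, field, msg) {
  stop(sprintf("%s: record %s, field '%s': %s", file, record, field, msg),
       call. = FALSE)
}

# read.delim wrapper for the package's TSV dialect: tab-separated, UTF-8,
# header row required, '#' comment lines ignored, no factor coercion.
.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", blank.lines.skip = TRUE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

# Vectorised combination index generator: all k-subsets of 1..n for
# k = 1..kmax, each matrix k x choose(n, k) with strictly increasing rows,
# columns in lexicographic order. Avoids utils::combn's per-column R loop,
# which is too slow at the 230-drug scale.
.combination_index <- function(n, kmax) {
  out <- vector("list", kmax)
  m <- matrix(seq_len(n), nrow = 1)
  out[[1]] <- m
  k <- 1
  while (k < kmax) {
    last <- m[k, ]
    counts <- n - last
    idx <- rep.int(seq_along(counts), counts)
    m <- rbind(m[, idx, drop = FALSE], sequence(counts) + last[idx])
    k <- k + 1
    out[[k]] <- m
  }
  out
}
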