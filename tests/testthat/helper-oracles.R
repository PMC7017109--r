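# Independent brute-force oracles and random fixture builders.
# These deliberately re-derive every quantity with naive loops and share no
# code with the package internals.

# Naive matching-score evaluator: triple loop over biomarkers, drugs and
# rules, applying the weighting conventions directly.
oracle_score <- function(drug_ids, profile, kb,
                         direct_weight = 1, indirect_weight = 0.5, cap = 1) {
  alts <- profile$alterations
  bio <- alts[alts$pathogenic & alts$alteration_class != "expression_negative", ,
              drop = FALSE]
  stopifnot(nrow(bio) > 0)
  total <- 0
  for (i in seq_len(nrow(bio))) {
    s <- 0
    for (d in drug_ids) {
      rules <- kb$rules[kb$rules$drug_id == d, , drop = FALSE]
      nulled <- FALSE
      for (j in seq_len(nrow(rules))) {
        if (rules$match_type[j] == "resistance" &&
              any(alts$gene == rules$gene[j] &
                    alts$alteration_class == rules$alteration_class[j]))
          nulled <- TRUE
      }
      if (nulled) next
      w <- 0
      for (j in seq_len(nrow(rules))) {
        if (rules$match_type[j] != "resistance" &&
              rules$gene[j] == bio$gene[i] &&
              rules$alteration_class[j] == bio$alteration_class[i]) {
          w <- if (!is.na(rules$weight_override[j])) rules$weight_override[j]
               else if (rules$match_type[j] == "direct") direct_weight
               else indirect_weight
        }
      }
      s <- s + w
    }
    total <- total + min(s, cap)
  }
  as.integer(floor(100 * total / (direct_weight * nrow(bio)) + 0.5))
}

# Exhaustive enumerate-and-sort ranking oracle.
oracle_rank <- function(profile, kb, max_drugs = 2) {
  ids <- sort(kb$drugs$drug_id)
  regs <- list()
  for (k in seq_len(max_drugs)) {
    cb <- utils::combn(ids, k)
    for (j in seq_len(ncol(cb))) regs[[length(regs) + 1]] <- cb[, j]
  }
  score <- vapply(regs, oracle_score, integer(1), profile = profile, kb = kb)
  label <- vapply(regs, paste, character(1), collapse = "+")
  nd <- lengths(regs)
  ord <- order(-score, nd, label, method = "radix")
  data.frame(regimen = label[ord], n_drugs = nd[ord],
             score_percent = score[ord], stringsAsFactors = FALSE)
}

# Trapezoidal ROC integration, independent of the rank-based AUC.
oracle_trapezoid_auc <- function(scores, labels) {
  pos <- labels == "successful"
  ts <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- sapply(ts, function(t) sum(scores > t & pos) / sum(pos))
  fpr <- sapply(ts, function(t) sum(scores > t & !pos) / sum(!pos))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Pair-counting U (x > y pairs, ties half) by explicit double loop.
oracle_u_pairs <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Exhaustive Youden scan over every threshold between -1 and max(scores).
oracle_youden <- function(scores, labels) {
  pos <- labels == "successful"
  cand <- sort(unique(c(scores, min(scores) - 1)))
  best <- -Inf; best_t <- NA
  for (t in cand) {
    j <- sum(scores > t & pos) / sum(pos) - sum(scores > t & !pos) / sum(!pos)
    if (j > best + 1e-12) { best <- j; best_t <- t }
  }
  best_t
}

toy_alteration_classes <- c("mutation_activating", "amplification",
                            "copy_loss", "expression_positive")

# Random small knowledge base for property tests.
random_toy_kb <- function(seed, n_drugs = 6, n_genes = 5,
                          p_resistance = 0.15) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  drugs <- data.frame(
    drug_id = paste0("d", seq_len(n_drugs)),
    name = paste0("drug ", seq_len(n_drugs)),
    drug_class = sample(c("cytotoxic", "targeted_small_molecule", "other"),
                        n_drugs, replace = TRUE),
    adult_only = FALSE, routes = "oral", contraindication_flags = "",
    stringsAsFactors = FALSE)
  rules <- list()
  for (d in drugs$drug_id) {
    n_r <- sample(0:3, 1)
    if (n_r == 0) next
    pat <- expand.grid(gene = genes, alteration_class = toy_alteration_classes,
                       stringsAsFactors = FALSE)
    pat <- pat[sample.int(nrow(pat), n_r), , drop = FALSE]
    mt <- sample(c("direct", "indirect", "resistance"), n_r, replace = TRUE,
                 prob = c(0.5, 1 - 0.5 - p_resistance, p_resistance))
    rules[[d]] <- data.frame(
      drug_id = d, gene = pat$gene, alteration_class = pat$alteration_class,
      match_type = mt,
      weight_override = ifelse(mt != "resistance" & runif(n_r) < 0.3,
                               round(runif(n_r), 2), NA_real_),
      evidence_tag = ifelse(mt == "direct", "sensitivity_biomarker",
                            ifelse(mt == "indirect", "pathway", "clinical")),
      stringsAsFactors = FALSE)
  }
  knowledge_base(drugs, NULL, do.call(rbind, rules), version = "toy")
}

random_toy_profile <- function(seed, n_bio = 4, n_genes = 5) {
  set.seed(seed + 10000)
  pat <- expand.grid(gene = paste0("G", seq_len(n_genes)),
                     alteration_class = toy_alteration_classes,
                     stringsAsFactors = FALSE)
  pat <- pat[sample.int(nrow(pat), n_bio), , drop = FALSE]
  patient_profile(paste0("T", seed),
                  data.frame(gene = pat$gene,
                             alteration_class = pat$alteration_class,
                             pathogenic = TRUE, detail = "",
                             stringsAsFactors = FALSE))
}

# Pad a knowledge base with rule-less filler drugs up to n_total drugs.
expand_kb <- function(kb, n_total) {
  extra <- n_total - nrow(kb$drugs)
  stopifnot(extra >= 0)
  filler <- data.frame(
    drug_id = sprintf("filler%03d", seq_len(extra)),
    name = sprintf("filler compound %03d", seq_len(extra)),
    drug_class = "targeted_small_molecule",
    adult_only = FALSE, routes = "oral", contraindication_flags = "",
    stringsAsFactors = FALSE)
  knowledge_base(rbind(kb$drugs, filler), kb$pathways, kb$rules,
                 version = kb$version)
}
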