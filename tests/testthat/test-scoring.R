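kb <- calibration_kb()
p51 <- patient51_profile()

test_that("the published worked-example scores reproduce exactly", {
  expect_equal(matching_score("tamoxifen", p51, kb)$score_percent, 17L)
  combo <- matching_score(c("anastrozole", "everolimus"), p51, kb)
  expect_equal(combo$score_percent, 42L)
  expect_equal(combo$numerator, 2.5)
  expect_equal(combo$denominator, 6)
  hit <- combo$breakdown[combo$breakdown$contribution > 0, ]
  expect_equal(hit$gene, c("ER", "PR", "PTEN"))
  expect_equal(hit$contribution, c(1, 0.5, 1))
  for (reg in list(c("fluorouracil", "doxorubicin", "cyclophosphamide"),
                   "capecitabine", "cisplatin"))
    expect_equal(matching_score(reg, p51, kb)$score_percent, 0L)
})

test_that("per-drug hits follow the direct/indirect weighting", {
  expect_equal(unname(drug_hits("tamoxifen", p51, kb)),
               c(1, 0, 0, 0, 0, 0))
  expect_equal(sum(drug_hits("capecitabine", p51, kb)), 0)
  ever <- drug_hits("everolimus", p51, kb)
  expect_equal(unname(ever[names(ever) == "PTEN"]), 1)
  expect_equal(sum(ever), 1)
  expect_error(drug_hits("nosuchdrug", p51, kb), "unknown drug")
})

test_that("per-biomarker contributions are capped across drugs", {
  both <- matching_score(c("tamoxifen", "anastrozole"), p51, kb)
  er <- both$breakdown[both$breakdown$gene == "ER", ]
  expect_equal(er$contribution, 1)     # 1 + 1 capped at 1
  expect_equal(both$numerator, 1.5)    # ER 1.0 + PR 0.5
  expect_equal(both$score_percent, 25L)
})

test_that("a full direct match scores exactly 100 and empty profiles error", {
  prof <- patient_profile("full", data.frame(
    gene = c("ER", "PTEN"), alteration_class = c("expression_positive", "copy_loss"),
    pathogenic = TRUE, detail = "", stringsAsFactors = FALSE))
  expect_equal(matching_score(c("tamoxifen", "everolimus"), prof, kb)$score_percent,
               100L)
  empty <- patient_profile("none", data.frame(
    gene = "ERBB2", alteration_class = "expression_negative",
    pathogenic = FALSE, detail = "", stringsAsFactors = FALSE))
  expect_error(matching_score("tamoxifen", empty, kb), "no scoreable biomarkers")
})

test_that("drug order never changes the result and scores stay in [0, 100]", {
  for (seed in 1:8) {
    tkb <- random_toy_kb(seed)
    prof <- random_toy_profile(seed)
    ids <- sample(tkb$drugs$drug_id, 3)
    s1 <- matching_score(ids, prof, tkb)
    s2 <- matching_score(rev(ids), prof, tkb)
    expect_equal(s1$score_percent, s2$score_percent)
    expect_gte(s1$score_percent, 0)
    expect_lte(s1$score_percent, 100)
    expect_identical(s1$score_percent == 0L, s1$numerator == 0)
  }
})

test_that("adding a drug never decreases the score (default config)", {
  for (seed in 1:10) {
    tkb <- random_toy_kb(seed, p_resistance = 0)  # resistance breaks monotonicity by design
    prof <- random_toy_profile(seed)
    ids <- sort(sample(tkb$drugs$drug_id, 3))
    s1 <- matching_score(ids[1], prof, tkb)$score_percent
    s2 <- matching_score(ids[1:2], prof, tkb)$score_percent
    s3 <- matching_score(ids, prof, tkb)$score_percent
    expect_gte(s2, s1)
    expect_gte(s3, s2)
    singles <- vapply(ids, function(d)
      matching_score(d, prof, tkb)$score_percent, integer(1))
    expect_gte(s3, max(singles))
  }
})

test_that("matching_score agrees with the brute-force oracle on random toy KBs", {
  for (seed in 1:20) {
    tkb <- random_toy_kb(seed)
    prof <- random_toy_profile(seed, n_bio = sample(2:5, 1))
    for (k in 1:3) {
      ids <- sample(tkb$drugs$drug_id, k)
      expect_equal(matching_score(ids, prof, tkb)$score_percent,
                   oracle_score(ids, prof, tkb),
                   info = sprintf("seed %d, regimen %s", seed,
                                  paste(ids, collapse = "+")))
    }
  }
})

test_that("a matching resistance marker nullifies the whole drug", {
  drugs <- data.frame(drug_id = c("inh", "other"), name = c("inh", "other"),
                      drug_class = "targeted_small_molecule",
                      adult_only = FALSE, routes = "oral",
                      contraindication_flags = "", stringsAsFactors = FALSE)
  rules <- data.frame(
    drug_id = c("inh", "inh", "other"),
    gene = c("G1", "G2", "G1"),
    alteration_class = c("mutation_activating", "mutation_activating",
                         "mutation_activating"),
    match_type = c("direct", "resistance", "direct"),
    weight_override = NA_real_,
    evidence_tag = c("ic50_nanomolar", "clinical", "ic50_nanomolar"),
    stringsAsFactors = FALSE)
  rkb <- knowledge_base(drugs, NULL, rules)
  prof <- patient_profile("R", data.frame(
    gene = c("G1", "G2"), alteration_class = "mutation_activating",
    pathogenic = TRUE, detail = "", stringsAsFactors = FALSE))
  expect_equal(sum(drug_hits("inh", prof, rkb)), 0)   # nullified by G2
  expect_equal(matching_score("inh", prof, rkb)$score_percent, 0L)
  # combination partner is unaffected
  expect_equal(matching_score(c("inh", "other"), prof, rkb)$score_percent, 50L)
})

test_that("weight overrides replace the configured defaults", {
  drugs <- data.frame(drug_id = "d1", name = "d1", drug_class = "other",
                      adult_only = FALSE, routes = "oral",
                      contraindication_flags = "", stringsAsFactors = FALSE)
  rules <- data.frame(drug_id = "d1", gene = "G1",
                      alteration_class = "amplification",
                      match_type = "direct", weight_override = 0.75,
                      evidence_tag = "sensitivity_biomarker",
                      stringsAsFactors = FALSE)
  okb <- knowledge_base(drugs, NULL, rules)
  prof <- patient_profile("W", data.frame(
    gene = c("G1", "G2"), alteration_class = "amplification",
    pathogenic = TRUE, detail = "", stringsAsFactors = FALSE))
  expect_equal(matching_score("d1", prof, okb)$numerator, 0.75)
  expect_equal(matching_score("d1", prof, okb)$score_percent, 38L)  # 37.5 rounds up
})

test_that("modifiers multiply the ratio before a single final rounding", {
  # identity when none are enabled
  base <- matching_score(c("anastrozole", "everolimus"), p51, kb)
  expect_equal(nrow(base$modifiers_applied), 0)

  # adult-only drug for a pediatric patient zeroes the score
  ped <- patient_profile("kid", scoreable_biomarkers(p51),
                         age_class = "pediatric")
  cfg <- scoring_config(modifiers_enabled = "eligibility_zero")
  res <- matching_score("tamoxifen", ped, kb, cfg)
  expect_equal(res$score_percent, 0L)
  expect_equal(res$modifiers_applied$factor, 0)

  # ratio 0.5 with one 0.9 factor -> 45
  prof <- patient_profile("half", data.frame(
    gene = c("ER", "G0"), alteration_class = c("expression_positive", "other"),
    pathogenic = TRUE, detail = "", stringsAsFactors = FALSE))
  cfg <- scoring_config(modifiers_enabled = "drug_count_penalty",
                        drug_count_factor = 0.9)
  res <- matching_score(c("tamoxifen", "capecitabine"), prof, kb, cfg)
  expect_equal(res$score_percent, 45L)

  # unknown ids are a configuration error
  bad <- scoring_config(modifiers_enabled = "no_such_modifier")
  expect_error(matching_score("tamoxifen", p51, kb, bad), "unknown modifier")
})

test_that("half-up rounding is applied to the final percentage", {
  prof <- patient_profile("H", data.frame(
    gene = paste0("G", 1:8), alteration_class = "amplification",
    pathogenic = TRUE, detail = "", stringsAsFactors = FALSE))
  drugs <- data.frame(drug_id = "d1", name = "d1", drug_class = "other",
                      adult_only = FALSE, routes = "oral",
                      contraindication_flags = "", stringsAsFactors = FALSE)
  rules <- data.frame(drug_id = "d1", gene = "G1",
                      alteration_class = "amplification",
                      match_type = "direct", weight_override = NA_real_,
                      evidence_tag = "sensitivity_biomarker",
                      stringsAsFactors = FALSE)
  expect_equal(matching_score("d1", prof, knowledge_base(drugs, NULL, rules)
                              )$score_percent, 13L)  # 12.5 -> 13, not 12
})
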