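{
  "version": "calibration-1",
  "drugs": [
    {"drug_id": "tamoxifen", "name": "tamoxifen", "drug_class": "hormone", "adult_only": true, "routes": "oral", "contraindication_flags": ""},
    {"drug_id": "anastrozole", "name": "anastrozole", "drug_class": "hormone", "adult_only": true, "routes": "oral", "contraindication_flags": ""},
    {"drug_id": "everolimus", "name": "everolimus", "drug_class": "targeted_small_molecule", "adult_only": false, "routes": "oral", "contraindication_flags": ""},
    {"drug_id": "trastuzumab", "name": "trastuzumab", "drug_class": "antibody", "adult_only": false, "routes": "iv", "contraindication_flags": "cardiomyopathy"},
    {"drug_id": "fluorouracil", "name": "fluorouracil", "drug_class": "cytotoxic", "adult_only": false, "routes": "iv", "contraindication_flags": ""},
    {"drug_id": "doxorubicin", "name": "doxorubicin", "drug_class": "cytotoxic", "adult_only": false, "routes": "iv", "contraindication_flags": "cardiomyopathy"},
    {"drug_id": "cyclophosphamide", "name": "cyclophosphamide", "drug_class": "cytotoxic", "adult_only": false, "routes": "iv,oral", "contraindication_flags": ""},
    {"drug_id": "capecitabine", "name": "capecitabine", "drug_class": "cytotoxic", "adult_only": false, "routes": "oral", "contraindication_flags": ""},
    {"drug_id": "paclitaxel", "name": "paclitaxel", "drug_class": "cytotoxic", "adult_only": false, "routes": "iv", "contraindication_flags": ""},
    {"drug_id": "cisplatin", "name": "cisplatin", "drug_class": "cytotoxic", "adult_only": false, "routes": "iv", "contraindication_flags": "renal_impairment"}
  ],
  "pathways": [
    {"pathway_id": "PI3K_AKT_MTOR", "member_genes": ["PIK3CA", "AKT1", "MTOR", "PTEN"]},
    {"pathway_id": "HORMONE_SIGNALING", "member_genes": ["ER", "PR"]}
  ],
  "rules": [
    {"drug_id": "tamoxifen", "gene": "ER", "alteration_class": "expression_positive", "match_type": "direct", "weight_override": null, "evidence_tag": "sensitivity_biomarker"},
    {"drug_id": "anastrozole", "gene": "ER", "alteration_class": "expression_positive", "match_type": "direct", "weight_override": null, "evidence_tag": "sensitivity_biomarker"},
    {"drug_id": "anastrozole", "gene": "PR", "alteration_class": "expression_positive", "match_type": "indirect", "weight_override": null, "evidence_tag": "pathway"},
    {"drug_id": "everolimus", "gene": "PTEN", "alteration_class": "copy_loss", "match_type": "direct", "weight_override": null, "evidence_tag": "sensitivity_biomarker"},
    {"drug_id": "everolimus", "gene": "MTOR", "alteration_class": "mutation_activating", "match_type": "direct", "weight_override": null, "evidence_tag": "ic50_nanomolar"},
    {"drug_id": "trastuzumab", "gene": "ERBB2", "alteration_class": "amplification", "match_type": "direct", "weight_override": null, "evidence_tag": "antibody_epitope"},
    {"drug_id": "trastuzumab", "gene": "ERBB2", "alteration_class": "expression_positive", "match_type": "direct", "weight_override": null, "evidence_tag": "antibody_epitope"}
  ]
}
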